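#' Tunable parameters of the segmentation fit
#'
#' Collects every tunable of the piecewise-linear fit. Quantities expressed
#' "in noise units" are multiplied by the (estimated or supplied) noise sd at
#' fit time, so the resolution of the line search tracks the measured data
#' quality.
#'
#' @param window_size Probes per fitting window.
#' @param fork_rate_range Admissible replication-fork rates, kb/min. A TTR
#'   slope corresponds to traversing the signal range at this rate over one
#'   S phase; faster forks give shallower slopes.
#' @param s_phase_minutes S-phase duration (minutes) used for the fork-rate
#'   to slope conversion.
#' @param noise_sd Measurement noise sd in signal units; `NULL` means
#'   estimate it from the data with [estimate_noise_mad()].
#' @param noise_floor_frac Lower bound on the working noise sd, as a fraction
#'   of the signal range, so vote bands and penalties stay well defined on
#'   near-noiseless input.
#' @param hough_slope_bins Log-spaced slope magnitudes per sign in the Hough
#'   accumulator (plus the zero-slope bin).
#' @param hough_intercept_bin Intercept bin width, in noise-sd units.
#' @param hough_vote_band Half-width of the band within which a probe votes
#'   for a line, in noise-sd units.
#' @param hough_vote_min Minimum votes for a candidate line; `NULL` means
#'   `max(5, window_size / 25)`.
#' @param hough_per_row Local maxima retained per slope row of the
#'   accumulator.
#' @param max_candidates Total candidate lines kept per window (best votes
#'   first).
#' @param breakpoint_penalty Cost added per breakpoint in the dynamic
#'   program, in squared signal units; `NULL` means
#'   `penalty_scale * noise_sd^2 * log(window_size)`.
#' @param penalty_scale Multiplier for the default breakpoint penalty.
#' @param max_breakpoints_per_window Cap on breakpoints in one window's DP.
#' @param prefilter Apply a running-median-3 filter before fitting.
#' @param refine Refine each window by constrained least squares (slopes
#'   boxed to the admissible range, breakpoints free within their probe gap).
#' @param refine_shift Also try moving each breakpoint one probe gap left or
#'   right during refinement; `NULL` (default) enables this only when the
#'   estimated noise is at the numerical floor, where the one-gap move is
#'   resolvable.
#' @param final_polish After all windows are assembled, re-fit every level,
#'   slope and breakpoint of the whole block jointly by constrained least
#'   squares (breakpoints stay within their probe gaps); windowed fitting
#'   freezes each junction with only its window's data, which this pass
#'   corrects.
#' @param gap_factor Probe gaps wider than `gap_factor` times the median
#'   spacing split the chromosome into independently fitted blocks.
#' @param signal_range Signal range used for the slope conversion; `NULL`
#'   means the observed range of the values being fitted.
#' @return An object of class `tor_fit_params`.
#' @export
fit_parameters <- function(window_size = 300,
                           fork_rate_range = c(0.25, 4),
                           s_phase_minutes = 480,
                           noise_sd = NULL,
                           noise_floor_frac = 0.005,
                           hough_slope_bins = 24,
                           hough_intercept_bin = 0.5,
                           hough_vote_band = 1.5,
                           hough_vote_min = NULL,
                           hough_per_row = 3,
                           max_candidates = 30,
                           breakpoint_penalty = NULL,
                           penalty_scale = 2,
                           max_breakpoints_per_window = 20,
                           prefilter = TRUE,
                           refine = TRUE,
                           refine_shift = NULL,
                           final_polish = TRUE,
                           gap_factor = 10,
                           signal_range = NULL) {
  stopifnot(
    window_size >= 8,
    length(fork_rate_range) == 2, fork_rate_range[1] > 0,
    fork_rate_range[1] < fork_rate_range[2],
    s_phase_minutes > 0,
    is.null(noise_sd) || noise_sd > 0,
    hough_slope_bins >= 2,
    hough_intercept_bin > 0, hough_vote_band > 0,
    is.null(breakpoint_penalty) || breakpoint_penalty >= 0,
    penalty_scale >= 0,
    max_breakpoints_per_window >= 1
  )
  structure(as.list(environment()), class = "tor_fit_params")
}

#' Admissible slope bounds from the fork-rate range
#'
#' Converts fork rates (kb/min) into signal-slope magnitudes (signal units
#' per bp): a fork moving at rate v covers `v * 1000 * s_phase_minutes` bp in
#' one S phase, so traversing the full signal range at that rate has slope
#' `signal_range / (v * 1000 * s_phase_minutes)`. The fastest fork gives the
#' minimum slope and the slowest the maximum.
#'
#' @param params A [fit_parameters()].
#' @param signal_range Signal range in signal units.
#' @return List with `slope_min` and `slope_max` (signal units per bp).
#' @export
slope_bounds <- function(params, signal_range) {
  stopifnot(signal_range > 0)
  v <- params$fork_rate_range
  list(
    slope_min = signal_range / (v[2] * 1000 * params$s_phase_minutes),
    slope_max = signal_range / (v[1] * 1000 * params$s_phase_minutes)
  )
}

#' Robust noise-sd estimate from raw ToR values
#'
#' Median absolute deviation of the first differences of the probe-ordered
#' series, scaled by `1.4826 / sqrt(2)`. Differencing cancels the piecewise-
#' linear trend (segment slopes contribute sparse outliers that the MAD
#' resists), and differences of i.i.d. Gaussian noise have sd `sigma *
#' sqrt(2)`, hence the scale factor.
#'
#' @param values Numeric vector of raw values in probe order (>= 8).
#' @return Estimated noise sd in signal units (0 for an exactly constant
#'   series).
#' @export
estimate_noise_mad <- function(values) {
  if (length(values) < 8) stop("need at least 8 values to estimate noise")
  stats::mad(diff(values), constant = 1.4826) / sqrt(2)
}

#' Running-median prefilter
#'
#' Window-3 running median over the values (endpoints kept as-is), a light
#' guard against single-probe outliers before line detection. A no-op when
#' disabled via `params$prefilter`.
#'
#' @param signal A [probe_signal()].
#' @param params A [fit_parameters()].
#' @return A `probe_signal` with filtered values (positions unchanged).
#' @export
prefilter <- function(signal, params = fit_parameters()) {
  stopifnot(inherits(signal, "probe_signal"))
  if (!isTRUE(params$prefilter)) return(signal)
  v <- as.numeric(stats::runmed(signal$values, 3, endrule = "keep"))
  probe_signal(signal$chromosome, signal$positions, v, signal$sample_id)
}

.vote_min <- function(params, n) {
  params$hough_vote_min %||% max(4, n %/% 50)
}

# Constant-line candidates at local running-mean levels. Adjacent CTR levels
# can sit within ~2 noise sd of each other, too close to separate as modes of
# the Hough intercept histogram, but a short running mean estimates each
# plateau's level with sd(noise)/sqrt(win) precision; the DP then decides
# where each level applies.
.level_lines <- function(y, noise_sd, wins = c(9, 21), stride = 1,
                         collapse = 0.35) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  width <- collapse * noise_sd
  out <- lapply(wins[wins <= n], function(win) {
    starts <- seq(1, n - win + 1, by = stride)
    lev <- (cs[starts + win] - cs[starts]) / win
    # quantize to `width`-wide bins; keep bins supported by >= 2 windows
    # (plateau levels recur across overlapping windows, ramp transients do not)
    q <- floor(lev / width)
    tab <- table(q)
    keep <- as.numeric(names(tab)[tab >= 2])
    vapply(keep, function(b) mean(lev[q == b]), numeric(1))
  })
  lev2 <- sort(unlist(out))
  if (!length(lev2)) return(NULL)
  # merge the per-scale level sets on the same quantization grid
  q2 <- floor(lev2 / width)
  lev2 <- vapply(unique(q2), function(b) mean(lev2[q2 == b]), numeric(1))
  data.frame(slope = 0, intercept = lev2, votes = 0L)
}

# Sloped "bridge" candidates at local level changes. Short, steep TTRs (a few
# probes) collect too few Hough votes to surface, yet the DP needs a sloped
# line intersecting both flanking levels near the junction to switch between
# them. A two-sided local-mean scan flags level changes; each flagged gap
# contributes bridge lines connecting the left and right local means over a
# few trial widths, slopes clamped into the admissible range.
.junction_lines <- function(x, y, bounds, noise_sd, halves = c(4, 8),
                            z = 1.5, widths = c(1, 3, 8), max_peaks = 16) {
  n <- length(x)
  sp <- stats::median(diff(x))
  cs <- c(0, cumsum(y))
  peaks <- list()
  for (half in halves) {
    if (n < 2 * half + 2) next
    g <- half:(n - half)            # candidate gaps (between probe g, g+1)
    lmean <- (cs[g + 1] - cs[g - half + 1]) / half
    rmean <- (cs[g + half + 1] - cs[g + 1]) / half
    d <- rmean - lmean
    thr <- z * noise_sd * sqrt(2 / half)
    ad <- abs(d)
    is_peak <- ad > thr &
      ad >= c(0, ad[-length(ad)]) & ad >= c(ad[-1], 0)
    pk <- which(is_peak)
    if (length(pk)) {
      gg <- g[pk]
      peaks[[length(peaks) + 1]] <- cbind(
        d = d[pk],
        z = ad[pk] / (noise_sd * sqrt(2 / half)),
        xmid = (x[gg] + x[gg + 1]) / 2,
        ymid = (lmean[pk] + rmean[pk]) / 2
      )
    }
  }
  if (!length(peaks)) return(NULL)
  pm <- do.call(rbind, peaks)
  pm <- pm[order(-pm[, "z"]), , drop = FALSE]
  # keep every decisive level change, and at most max_peaks marginal ones
  keep <- pm[, "z"] >= 3 | seq_len(nrow(pm)) <= max_peaks
  pm <- pm[keep, , drop = FALSE]
  rows <- lapply(widths, function(wd) {
    sl <- pm[, "d"] / (wd * sp)
    sl <- sign(sl) * pmin(pmax(abs(sl), bounds$slope_min), bounds$slope_max)
    cbind(sl, pm[, "ymid"] - sl * (pm[, "xmid"] - x[1]))
  })
  mat <- unique(do.call(rbind, rows))
  data.frame(slope = mat[, 1], intercept = mat[, 2], votes = 0L)
}

#' Detect candidate lines in a window with a Hough transform
#'
#' Builds an accumulator over (slope, intercept): the slope grid is the zero
#' slope plus log-spaced magnitudes of both signs within the admissible
#' fork-rate-implied range; intercepts (value of the line at the first probe)
#' are binned at `hough_intercept_bin * noise_sd`. A probe votes for every
#' line passing within `hough_vote_band * noise_sd` of its value. Local
#' maxima of each slope row with enough votes are returned, best first.
#'
#' @param positions,values Probe positions (bp) and values in the window
#'   (>= 4 probes).
#' @param params A [fit_parameters()].
#' @param noise_sd Noise sd in signal units (after flooring).
#' @param bounds Slope bounds as returned by [slope_bounds()]; computed from
#'   `params` and the value range when omitted.
#' @return Data frame with columns `slope` (signal units per bp), `intercept`
#'   (line value at the first probe position) and `votes`. May be empty.
#' @export
hough_lines <- function(positions, values, params = fit_parameters(),
                        noise_sd = NULL, bounds = NULL) {
  n <- length(positions)
  stopifnot(n >= 4, length(values) == n)
  rng <- params$signal_range %||% diff(range(values))
  if (rng <= 0) rng <- 1
  if (is.null(noise_sd)) {
    noise_sd <- max(if (n >= 8) estimate_noise_mad(values) else 0,
                    params$noise_floor_frac * rng)
  }
  bounds <- bounds %||% slope_bounds(params, rng)
  x <- positions - positions[1]
  mags <- exp(seq(log(bounds$slope_min), log(bounds$slope_max),
                  length.out = params$hough_slope_bins))
  slopes <- c(0, mags, -mags)
  w <- params$hough_intercept_bin * noise_sd
  # the slope grid is discrete: a true line lying between rows drifts away
  # from the nearest grid line by up to half the inter-row slope step over a
  # characteristic segment span; widen each row's vote band accordingly
  ratio <- (bounds$slope_max / bounds$slope_min)^(1 /
             max(params$hough_slope_bins - 1, 1))
  char_span <- 8 * stats::median(diff(x))
  thr <- .vote_min(params, n)

  out <- vector("list", length(slopes))
  for (si in seq_along(slopes)) {
    m <- slopes[si]
    band <- params$hough_vote_band * noise_sd +
      0.5 * (ratio - 1) * abs(m) * char_span
    band_bins <- max(1L, as.integer(ceiling(band / w)))
    r <- values - m * x
    b0 <- min(r)
    idx <- as.integer(floor((r - b0) / w)) + 1L
    nb <- max(idx)
    counts <- tabulate(idx, nbins = nb)
    if (nb == 1L) {
      votes <- counts
    } else {
      cs <- cumsum(counts)
      hi <- pmin(seq_len(nb) + band_bins, nb)
      lo <- pmax(seq_len(nb) - band_bins, 1L)
      votes <- cs[hi] - c(0, cs)[lo]
    }
    left <- c(-Inf, votes[-nb])
    right <- c(votes[-1], -Inf)
    keep <- which(votes >= thr & votes > left & votes >= right)
    if (length(keep)) {
      ord <- keep[order(-votes[keep])]
      ord <- ord[seq_len(min(length(ord), params$hough_per_row))]
      out[[si]] <- data.frame(slope = m,
                              intercept = b0 + (ord - 0.5) * w,
                              votes = votes[ord])
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(slope = numeric(0), intercept = numeric(0),
                      votes = integer(0)))
  }
  cand <- do.call(rbind, out)
  cand <- cand[order(-cand$votes, abs(cand$slope), cand$intercept), ,
               drop = FALSE]
  rownames(cand) <- NULL
  utils::head(cand, params$max_candidates)
}

# Candidate lines through the anchor point (the committed breakpoint a
# restarted window must continue from): the flat continuation plus lines
# rising/falling from the anchor to each candidate level over a few trial
# widths. Without these the DP cannot express a segment boundary falling at
# the window start.
.anchor_lines <- function(anchor, x, levels, bounds, widths = c(1, 2, 4, 8)) {
  sp <- stats::median(diff(x))
  rows <- list(cbind(0, anchor$value))
  dv <- levels[abs(levels - anchor$value) >= 1e-12] - anchor$value
  for (wd in widths) {
    sl <- dv / (wd * sp)
    sl <- sign(sl) * pmin(pmax(abs(sl), bounds$slope_min), bounds$slope_max)
    rows[[length(rows) + 1]] <-
      cbind(sl, anchor$value + sl * (x[1] - anchor$pos))
  }
  mat <- unique(do.call(rbind, rows))
  data.frame(slope = mat[, 1], intercept = mat[, 2], votes = 0L)
}

# Deterministic fallback/insurance lines: window-median constant and the
# least-squares line with slope clamped into the admissible range.
.fallback_lines <- function(x, y, bounds) {
  out <- data.frame(slope = 0, intercept = stats::median(y), votes = 0L)
  vx <- stats::var(x)
  if (is.finite(vx) && vx > 0) {
    sl <- stats::cov(x, y) / vx
    asl <- abs(sl)
    if (asl >= bounds$slope_min / 2) {
      sl <- sign(sl) * min(max(asl, bounds$slope_min), bounds$slope_max)
      ic <- mean(y) - sl * mean(x - x[1]) # intercept at x[1]
      out <- rbind(out, data.frame(slope = sl, intercept = ic, votes = 0L))
    }
  }
  out
}

# ---- dynamic programming over candidate lines -------------------------------

# Piecewise-linear evaluation given knots tau (length m+1), knot values vv
# (length m+1) and per-segment slopes s (length m). Probes exactly on an
# interior knot take the left segment.
.pw_eval <- function(xq, tau, vv, s) {
  seg <- findInterval(xq, tau, left.open = TRUE)
  seg[seg < 1] <- 1L
  seg[seg > length(s)] <- length(s)
  vv[seg] + s[seg] * (xq - tau[seg])
}

# Constrained least-squares refinement of one window's piecewise fit.
# Free parameters: v0 (unless anchored), TTR slopes (boxed to the admissible
# magnitude range, sign fixed), and interior knots (boxed to a probe gap).
.refit_window <- function(x, y, tau, s, types, gaps, bounds, anchored,
                          gap_lo, gap_hi, factr = 1e3, maxit = 400) {
  m <- length(s)
  ttr <- which(types == "TTR")
  n_int <- m - 1
  free_v0 <- !anchored

  par <- numeric(0); lower <- numeric(0); upper <- numeric(0)
  scale <- numeric(0)
  v0_fix <- attr(tau, "v0")
  spacing <- stats::median(diff(x))
  if (free_v0) {
    par <- c(par, v0_fix); lower <- c(lower, -Inf); upper <- c(upper, Inf)
    scale <- c(scale, max(abs(v0_fix), 1))
  }
  for (i in ttr) {
    if (s[i] >= 0) {
      lo <- bounds$slope_min; hi <- bounds$slope_max
    } else {
      lo <- -bounds$slope_max; hi <- -bounds$slope_min
    }
    par <- c(par, min(max(s[i], lo), hi)); lower <- c(lower, lo)
    upper <- c(upper, hi)
    scale <- c(scale, bounds$slope_max)
  }
  if (n_int > 0) {
    par <- c(par, tau[2:m]); lower <- c(lower, gap_lo); upper <- c(upper, gap_hi)
    scale <- c(scale, rep(spacing, n_int))
  }

  decode <- function(p) {
    k <- 0
    v0 <- if (free_v0) { k <- k + 1; p[k] } else v0_fix
    ss <- s
    for (i in ttr) { k <- k + 1; ss[i] <- p[k] }
    tt <- tau
    if (n_int > 0) {
      tt[2:m] <- p[(k + 1):(k + n_int)]
      tt <- cummax(tt)  # numerical guard; boxes already enforce order
    }
    list(v0 = v0, s = ss, tau = tt)
  }
  fn <- function(p) {
    d <- decode(p)
    vv <- d$v0 + c(0, cumsum(d$s * diff(d$tau)))
    sum((y - .pw_eval(x, d$tau, vv, d$s))^2)
  }
  gr <- function(p) {
    d <- decode(p)
    vv <- d$v0 + c(0, cumsum(d$s * diff(d$tau)))
    seg <- findInterval(x, d$tau, left.open = TRUE)
    seg[seg < 1] <- 1L; seg[seg > m] <- m
    res <- -2 * (y - (vv[seg] + d$s[seg] * (x - d$tau[seg])))
    g <- numeric(length(p))
    k <- 0
    if (free_v0) { k <- k + 1; g[k] <- sum(res) }
    # per-segment residual sums (tail sums give the chain-rule terms)
    rs <- rowsum(cbind(res, res * (x - d$tau[seg])), seg)
    present <- as.integer(rownames(rs))
    res_by_seg <- numeric(m); xres_by_seg <- numeric(m)
    res_by_seg[present] <- rs[, 1]
    xres_by_seg[present] <- rs[, 2]
    tail_after <- rev(cumsum(rev(res_by_seg)))         # sum over seg >= i
    for (i in ttr) {
      k <- k + 1
      later <- if (i < m) tail_after[i + 1] else 0
      g[k] <- xres_by_seg[i] + (d$tau[i + 1] - d$tau[i]) * later
    }
    if (n_int > 0) {
      for (r in seq_len(n_int)) {
        k <- k + 1
        later <- if (r + 1 <= m) tail_after[r + 1] else 0
        g[k] <- (d$s[r] - d$s[r + 1]) * later
      }
    }
    g
  }

  if (!length(par)) {
    d <- decode(par)
    vv <- d$v0 + c(0, cumsum(d$s * diff(d$tau)))
    return(list(tau = d$tau, values = vv, s = d$s, sse = fn(par)))
  }
  par <- pmin(pmax(par, lower), upper)
  fit <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = factr,
                                     parscale = scale))
  d <- decode(fit$par)
  vv <- d$v0 + c(0, cumsum(d$s * diff(d$tau)))
  list(tau = d$tau, values = vv, s = d$s, sse = fit$value)
}

#' Fit one window by dynamic programming over candidate lines
#'
#' Chooses an ordered sequence of candidate lines minimizing the sum of
#' squared residuals plus `breakpoint_penalty` per breakpoint, with
#' transitions only at the intersection of consecutive lines (which makes the
#' fit continuous by construction) and at most one transition per probe gap.
#' Ties prefer fewer segments, then the leftmost breakpoint. The selected
#' piecewise model is then refined by constrained least squares: CTR segments
#' stay flat, TTR slopes stay inside the admissible range, and each
#' breakpoint may move within its probe gap (optionally also one gap left or
#' right).
#'
#' @param positions,values Probe positions and values of the window.
#' @param candidates Candidate lines (data frame with `slope`, `intercept` at
#'   the first probe) from [hough_lines()]; deterministic fallback lines are
#'   always appended, so an empty set falls back to a single best line.
#' @param params A [fit_parameters()].
#' @param noise_sd Noise sd (floored); estimated from the window if missing.
#' @param anchor Optional `list(pos, value)` fixing the fit's starting point
#'   (used to continue from the previous window's last committed breakpoint).
#' @param values_fit Values the constrained least-squares refinement is fit
#'   to; defaults to `values`. [segment_signal()] passes the raw values here
#'   while line detection and the DP run on the prefiltered ones, so the
#'   final fit is unbiased by the filter.
#' @return List of class `tor_window_fit`: `tau` (knot positions, bp),
#'   `values` (knot values), `slopes`, `types` ("CTR"/"TTR" per segment),
#'   `fitted`, `objective` (DP objective: SSE on candidate lines + penalty
#'   per breakpoint), `sse` (after refinement) and `fallback` flag.
#' @export
dp_segment_window <- function(positions, values, candidates = NULL,
                              params = fit_parameters(), noise_sd = NULL,
                              anchor = NULL, values_fit = NULL) {
  x <- as.numeric(positions); y <- as.numeric(values)
  yr <- if (is.null(values_fit)) y else as.numeric(values_fit)
  n <- length(x)
  stopifnot(n >= 2, length(y) == n)
  rng <- params$signal_range %||% max(diff(range(y)), .Machine$double.eps)
  bounds <- slope_bounds(params, rng)
  if (is.null(noise_sd)) {
    noise_sd <- max(if (n >= 8) estimate_noise_mad(y) else 0,
                    params$noise_floor_frac * rng)
  }
  penalty <- params$breakpoint_penalty %||%
    (params$penalty_scale * noise_sd^2 * log(max(params$window_size, n)))

  if (is.null(candidates) && n >= 4) {
    candidates <- hough_lines(x, y, params, noise_sd, bounds)
  }
  fallback <- is.null(candidates) || nrow(candidates) == 0
  jl <- .junction_lines(x, y, bounds, noise_sd)
  ll <- .level_lines(y, noise_sd)
  # only levels plausible as the near-edge destination are worth edge lines
  near_levels <- function(target, k = 4) {
    lv <- ll$intercept
    if (is.null(lv) || !length(lv)) return(numeric(0))
    lv[order(abs(lv - target))][seq_len(min(k, length(lv)))]
  }
  head_mean <- mean(y[1:min(6, n)])
  tail_mean <- mean(y[max(1, n - 5):n])
  al <- if (!is.null(anchor)) {
    .anchor_lines(anchor, x, c(near_levels(head_mean), head_mean), bounds)
  } else {
    # head lines: a segment boundary may fall right after the first probe
    .anchor_lines(list(pos = x[1], value = y[1]), x, near_levels(head_mean),
                  bounds)
  }
  # tail lines: likewise for a boundary just before the last probe
  tl <- .anchor_lines(list(pos = x[n], value = y[n]), x,
                      near_levels(tail_mean), bounds)
  cand <- rbind(
    if (!is.null(candidates) && nrow(candidates))
      candidates[, c("slope", "intercept")],
    if (!is.null(jl)) jl[, c("slope", "intercept")],
    if (!is.null(ll)) ll[, c("slope", "intercept")],
    if (!is.null(al)) al[, c("slope", "intercept")],
    if (!is.null(tl)) tl[, c("slope", "intercept")],
    .fallback_lines(x, y, bounds)[, c("slope", "intercept")]
  )
  # collapse near-duplicate lines (resolution: noise units)
  key <- paste(signif(cand$slope, 3),
               round(cand$intercept / (0.2 * noise_sd)))
  cand <- cand[!duplicated(key), , drop = FALSE]
  m <- cand$slope; b <- cand$intercept; K <- nrow(cand)

  # residuals of each probe against each line
  pred <- outer(x - x[1], m) + matrix(b, n, K, byrow = TRUE)
  R <- (y - pred)^2

  # anchor pseudo-residual: ties the first line to the committed start point
  ares <- if (is.null(anchor)) numeric(K) else {
    4 * (anchor$value - (b + m * (anchor$pos - x[1])))^2
  }

  # intersections of line pairs, indexed by the probe gap that contains them
  gap_pairs <- vector("list", max(n - 1, 1))
  if (K > 1 && n > 1) {
    ut <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
    jj <- ut[, 1]; kk <- ut[, 2]
    dm <- m[jj] - m[kk]
    ok <- dm != 0
    jj <- jj[ok]; kk <- kk[ok]
    xi <- x[1] + (b[kk] - b[jj]) / dm[ok]
    g <- findInterval(xi, x)
    keep <- g >= 1 & g <= n - 1
    if (any(keep)) {
      pairs <- cbind(c(jj[keep], kk[keep]), c(kk[keep], jj[keep]),
                     c(xi[keep], xi[keep]))
      gidx <- c(g[keep], g[keep])
      for (gg in unique(gidx)) {
        gap_pairs[[gg]] <- pairs[gidx == gg, , drop = FALSE]
      }
    }
  }

  kmax <- min(params$max_breakpoints_per_window, n - 1) + 1L
  dp <- matrix(Inf, K, kmax)
  dp[, 1] <- R[1, ] + ares
  # sparse transition log: per probe, the (to-line, n-segments, from-line)
  # triples where a transition was taken
  tlog <- vector("list", n)
  for (i in 2:n) {
    pf <- gap_pairs[[i - 1]]
    if (!is.null(pf) && kmax > 1) {
      src <- dp   # transition sources: values before this probe's updates
      log_i <- vector("list", nrow(pf))
      for (r in seq_len(nrow(pf))) {
        j <- pf[r, 1]; k <- pf[r, 2]
        val <- src[j, -kmax] + penalty
        # prefer a transition on ties (leftmost breakpoint)
        upd <- which(val <= dp[k, -1])
        if (length(upd)) {
          dp[k, upd + 1L] <- val[upd]
          nu <- length(upd)
          log_i[[r]] <- matrix(c(rep.int(k, nu), upd + 1L, rep.int(j, nu)),
                               nu, 3)
        }
      }
      log_i <- log_i[!vapply(log_i, is.null, logical(1))]
      if (length(log_i)) tlog[[i]] <- do.call(rbind, log_i)
    }
    dp <- dp + R[i, ]
  }

  # best terminal state; ties prefer fewer segments, then the earlier line
  best <- which(dp == min(dp), arr.ind = TRUE)
  best <- best[order(best[, 2], best[, 1]), , drop = FALSE][1, ]
  j <- best[1]; sseg <- best[2]
  objective <- dp[j, sseg]

  # backtrack probe assignments and transition gaps (later log rows overwrote
  # earlier ones, so scan each probe's log bottom-up for the winning entry)
  lines_rev <- j
  gaps_rev <- integer(0); xint_rev <- numeric(0)
  si <- sseg
  for (i in n:2) {
    li <- tlog[[i]]
    if (is.null(li)) next
    hit <- which(li[, 1] == j & li[, 2] == si)
    if (length(hit)) {
      f <- li[hit[length(hit)], 3]
      pf <- gap_pairs[[i - 1]]
      row <- pf[pf[, 1] == f & pf[, 2] == j, , drop = FALSE][1, ]
      gaps_rev <- c(gaps_rev, i - 1L)
      xint_rev <- c(xint_rev, row[3])
      j <- f; si <- si - 1L
      lines_rev <- c(lines_rev, j)
    }
  }
  line_seq <- rev(lines_rev)
  gaps <- rev(gaps_rev)
  xint <- rev(xint_rev)

  t0 <- if (is.null(anchor)) x[1] else anchor$pos
  tau <- c(t0, xint, x[n])
  sl <- m[line_seq]
  types <- ifelse(sl == 0, "CTR", "TTR")
  v0 <- if (is.null(anchor)) {
    b[line_seq[1]] + sl[1] * (t0 - x[1])
  } else {
    anchor$value
  }

  finish <- function(tau, vv, sl, sse) {
    structure(list(
      tau = tau, values = vv, slopes = sl, types = ifelse(sl == 0, "CTR", "TTR"),
      fitted = .pw_eval(x, tau, vv, sl),
      objective = objective, sse = sse, fallback = fallback,
      gaps = gaps, noise_sd = noise_sd, penalty = penalty
    ), class = "tor_window_fit")
  }

  if (!isTRUE(params$refine)) {
    vv <- v0 + c(0, cumsum(sl * diff(tau)))
    return(finish(tau, vv, sl, sum((y - .pw_eval(x, tau, vv, sl))^2)))
  }

  eps <- 1e-9 * max(diff(x))
  run_refit <- function(gaps_use, tau_init, factr = 1e3, maxit = 400) {
    gl <- x[gaps_use] + eps
    gh <- x[gaps_use + 1L] - eps
    tt <- tau_init
    attr(tt, "v0") <- v0
    .refit_window(x, yr, tt, sl, types, gaps_use, bounds,
                  anchored = !is.null(anchor), gap_lo = gl, gap_hi = gh,
                  factr = factr, maxit = maxit)
  }
  fit <- run_refit(gaps, tau)

  # near-noiseless data has a sharp SSE landscape where moving a breakpoint
  # across one probe gap can matter; under real noise the one-gap move is
  # far below the noise floor, so the extra pass defaults to off there
  clean <- noise_sd <= 2 * params$noise_floor_frac * rng
  do_shift <- params$refine_shift %||% clean
  if (isTRUE(do_shift) && length(gaps) > 0) {
    t_factr <- if (clean) 1e3 else 1e6
    t_maxit <- if (clean) 400 else 150
    moved <- FALSE
    for (r in seq_along(gaps)) {
      # neighbouring-gap moves, plus re-inits at the current gap's edges
      # (the SSE has kinks where a knot crosses a probe; L-BFGS-B can stall
      # short of a boundary optimum, e.g. a sharp single-gap junction)
      trials <- list(list(d = -1L, at = NA), list(d = 1L, at = NA),
                     list(d = 0L, at = "lo"), list(d = 0L, at = "hi"))
      for (tr in trials) {
        g2 <- gaps
        g2[r] <- gaps[r] + tr$d
        if (g2[r] < 1L || g2[r] > n - 1L) next
        if (any(duplicated(g2)) || is.unsorted(g2, strictly = TRUE)) next
        tau2 <- fit$tau
        tau2[r + 1] <- if (is.na(tr$at)) {
          (x[g2[r]] + x[g2[r] + 1L]) / 2
        } else if (tr$at == "lo") {
          x[g2[r]] + 2 * eps
        } else {
          x[g2[r] + 1L] - 2 * eps
        }
        tau2 <- sort(tau2)
        alt <- run_refit(g2, tau2, factr = t_factr, maxit = t_maxit)
        if (alt$sse < fit$sse - 1e-12 * max(1, fit$sse)) {
          fit <- alt
          gaps <- g2
          moved <- TRUE
        }
      }
    }
    if (moved) fit <- run_refit(gaps, fit$tau)    # tight final polish
  }
  finish(fit$tau, fit$values, fit$s, fit$sse)
}

#' Segment a whole chromosome into a continuous piecewise-linear ToR map
#'
#' Runs the full pipeline on one chromosome: noise estimation (MAD),
#' running-median prefilter, then sliding fitting windows of
#' `params$window_size` probes. Each window is fitted with
#' [dp_segment_window()]; all of its segments except the last are committed
#' and the next window starts at the last committed breakpoint, anchored to
#' its value so the whole-chromosome map is exactly continuous. Probe gaps
#' larger than `gap_factor` times the median spacing split the chromosome
#' into independently fitted blocks.
#'
#' @param signal A [probe_signal()] with at least 8 probes.
#' @param params A [fit_parameters()].
#' @return An object of class `tor_segmentation`: per-probe `fitted` values,
#'   a `segments` table (`start`, `end`, `value_start`, `value_end`, `slope`,
#'   `type`, `block`), the estimated `noise_sd` and the parameters used.
#'   Returns `NULL` with a warning for signals with fewer than 8 probes.
#' @export
segment_signal <- function(signal, params = fit_parameters()) {
  stopifnot(inherits(signal, "probe_signal"))
  n <- length(signal$positions)
  if (n < 8) {
    warning("chromosome ", signal$chromosome,
            " has fewer than 8 probes; skipped")
    return(NULL)
  }
  rng <- params$signal_range %||% diff(range(signal$values))
  if (rng <= 0) rng <- max(abs(signal$values[1]), 1)
  noise_sd <- params$noise_sd %||% estimate_noise_mad(signal$values)
  noise_sd <- max(noise_sd, params$noise_floor_frac * rng)
  # fix the working range/noise so every window sees identical settings
  params$signal_range <- rng
  bounds <- slope_bounds(params, rng)
  filt <- prefilter(signal, params)

  pos <- filt$positions; val <- filt$values
  spc <- stats::median(diff(pos))
  block_id <- cumsum(c(1, as.integer(diff(pos) > params$gap_factor * spc)))

  seg_rows <- list()
  for (bl in unique(block_id)) {
    idx <- which(block_id == bl)
    if (length(idx) < 8) {
      warning("block of ", length(idx), " probes in ", signal$chromosome,
              " is too short to fit; skipped")
      next
    }
    xb <- pos[idx]; yb <- val[idx]; yrawb <- signal$values[idx]
    nb <- length(xb)
    a <- 1L; anchor <- NULL
    repeat {
      b <- min(a + params$window_size - 1L, nb)
      win <- dp_segment_window(xb[a:b], yb[a:b], candidates = NULL,
                               params = params, noise_sd = noise_sd,
                               anchor = anchor, values_fit = yrawb[a:b])
      nsw <- length(win$types)
      # the window's last segment is truncated by the window edge and its
      # closing junction is poorly determined; keep both out of the committed
      # map and refit them with full context in the next window
      commit <- if (b == nb) seq_len(nsw) else seq_len(max(nsw - 2L, 1L))
      for (i in commit) {
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          start = win$tau[i], end = win$tau[i + 1],
          value_start = win$values[i], value_end = win$values[i + 1],
          slope = win$slopes[i], type = win$types[i], block = bl,
          stringsAsFactors = FALSE
        )
      }
      if (b == nb) break
      last <- commit[length(commit)]
      anchor <- list(pos = win$tau[last + 1], value = win$values[last + 1])
      a_new <- which(xb > anchor$pos)[1]
      if (is.na(a_new) || a_new <= a) a_new <- b + 1L
      a <- a_new
      if (a > nb) break
    }
  }
  if (!length(seg_rows)) {
    warning("no block of ", signal$chromosome, " could be fitted")
    return(NULL)
  }
  seg <- do.call(rbind, seg_rows)
  seg <- .merge_segments(seg)

  # final polish: windowed fitting freezes each junction once its window is
  # committed; one whole-block constrained refit (breakpoints confined to
  # their probe gaps) re-estimates all levels and slopes from every probe
  if (isTRUE(params$final_polish)) {
    seg <- .polish_blocks(seg, pos, signal$values, bounds)
  }

  fitted <- .segmentation_fitted(seg, pos)
  structure(list(
    chromosome = signal$chromosome,
    sample_id = signal$sample_id,
    positions = signal$positions,
    fitted = fitted,
    segments = seg,
    noise_sd = noise_sd,
    range = rng,
    params = params
  ), class = "tor_segmentation")
}

# whole-block constrained refit of an assembled segmentation
.polish_blocks <- function(seg, pos, values, bounds) {
  out <- lapply(unique(seg$block), function(bl) {
    sb <- seg[seg$block == bl, , drop = FALSE]
    sel <- pos >= sb$start[1] & pos <= sb$end[nrow(sb)]
    x <- pos[sel]; y <- values[sel]
    n <- length(x)
    m <- nrow(sb)
    if (m < 2 || n < 8) return(sb)
    tau <- c(sb$start[1], sb$start[-1], sb$end[m])
    gidx <- pmin(pmax(findInterval(tau[2:m], x), 1L), n - 1L)
    eps <- 1e-9 * max(diff(x))
    tt <- tau
    attr(tt, "v0") <- sb$value_start[1]
    fit <- .refit_window(x, y, tt, sb$slope, sb$type, gidx, bounds,
                         anchored = FALSE,
                         gap_lo = x[gidx] + eps, gap_hi = x[gidx + 1L] - eps)
    data.frame(
      start = fit$tau[-(m + 1)], end = fit$tau[-1],
      value_start = fit$values[-(m + 1)], value_end = fit$values[-1],
      slope = fit$s, type = sb$type, block = bl,
      stringsAsFactors = FALSE
    )
  })
  .merge_segments(do.call(rbind, out))
}

# merge adjacent same-type segments within a block (CTR+CTR share their level
# by continuity; TTR+TTR only when the slopes agree) and drop zero-length ones
.merge_segments <- function(seg) {
  seg <- seg[seg$end > seg$start, , drop = FALSE]
  if (nrow(seg) < 2) return(seg)
  out <- seg[1, , drop = FALSE]
  for (i in 2:nrow(seg)) {
    cur <- seg[i, ]
    prev <- out[nrow(out), ]
    same_block <- cur$block == prev$block
    mergeable <- same_block && cur$type == prev$type &&
      ((cur$type == "CTR" &&
          abs(cur$value_start - prev$value_end) < 1e-9) ||
         (cur$type == "TTR" && abs(cur$slope - prev$slope) < 1e-12 &&
            abs(cur$value_start - prev$value_end) < 1e-9))
    if (mergeable) {
      out$end[nrow(out)] <- cur$end
      out$value_end[nrow(out)] <- cur$value_end
    } else {
      out <- rbind(out, cur)
    }
  }
  rownames(out) <- NULL
  out
}

.segmentation_fitted <- function(seg, positions) {
  idx <- findInterval(positions, seg$start, left.open = TRUE)
  idx[idx < 1] <- 1L
  bad <- positions > seg$end[idx] & idx < nrow(seg)
  idx[bad] <- idx[bad] + 1L
  seg$value_start[idx] + seg$slope[idx] * (positions - seg$start[idx])
}

# segment index containing each position (probes on a junction belong to the
# left segment); NA outside the segmented territory
.segment_index <- function(seg, positions) {
  idx <- findInterval(positions, seg$start, left.open = TRUE)
  idx[idx < 1] <- NA_integer_
  ok <- !is.na(idx)
  bad <- ok & positions > seg$end[pmax(idx, 1L)]
  nxt <- pmin(idx + 1L, nrow(seg))
  fix <- bad & seg$start[nxt] <= positions & positions <= seg$end[nxt]
  idx[fix] <- idx[fix] + 1L
  idx[bad & !fix] <- NA_integer_
  # positions exactly at a block's first breakpoint
  first_hit <- is.na(idx) & positions %in% seg$start
  if (any(first_hit)) {
    idx[first_hit] <- match(positions[first_hit], seg$start)
  }
  idx
}

#' @export
print.tor_segmentation <- function(x, ...) {
  tab <- table(x$segments$type)
  cat(sprintf(
    "<tor_segmentation> %s %s: %d probes, %d segments (%s), noise sd %.4g\n",
    x$sample_id, x$chromosome, length(x$positions), nrow(x$segments),
    paste(names(tab), as.integer(tab), sep = "=", collapse = ", "),
    x$noise_sd
  ))
  invisible(x)
}
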