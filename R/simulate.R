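#' Specification of a synthetic ToR profile
#'
#' Describes the generative model for synthetic time-of-replication signals:
#' an alternating sequence of constant-ToR regions (CTRs, flat segments) and
#' temporal transition regions (TTRs, sloped segments whose slope corresponds
#' to a replication-fork rate), sampled on an even probe grid and confined to
#' the signal range. Defaults reproduce the benchmark regime: 3200 probes at
#' 40 kb spacing, S/G1 ratios spanning 1-2, fork rates 0.25-4 kb/min.
#'
#' @param n_probes Number of probes per signal.
#' @param probe_spacing Distance between adjacent probes, bp.
#' @param signal_low,signal_high Bounds of the clean signal (S/G1 units).
#' @param ctr_length_range CTR lengths are drawn log-uniformly over this range
#'   (in probes); at 40 kb spacing the default 10-100 probes spans the
#'   0.4-4 Mb scale typical of constant-timing domains.
#' @param fork_rate_range Admissible fork rates in kb/min; a TTR's slope is
#'   the signal range traversed at that rate over the S phase.
#' @param s_phase_minutes S-phase duration used to convert fork rate into
#'   signal slope per bp.
#' @param noise_sd_frac Default noise level for [add_gaussian_noise()], as a
#'   fraction of the signal range.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_probes = 3200,
                            probe_spacing = 40000,
                            signal_low = 1.0,
                            signal_high = 2.0,
                            ctr_length_range = c(10, 100),
                            fork_rate_range = c(0.25, 4),
                            s_phase_minutes = 480,
                            noise_sd_frac = 0.15) {
  stopifnot(
    n_probes >= 2, probe_spacing > 0,
    signal_low < signal_high,
    length(ctr_length_range) == 2, ctr_length_range[1] >= 1,
    ctr_length_range[1] <= ctr_length_range[2],
    length(fork_rate_range) == 2, fork_rate_range[1] > 0,
    fork_rate_range[1] < fork_rate_range[2],
    s_phase_minutes > 0,
    noise_sd_frac >= 0, noise_sd_frac < 1
  )
  structure(as.list(environment()), class = "simulation_spec")
}

# per-bp slope magnitude bounds implied by the fork-rate range
.spec_slope_bounds <- function(spec) {
  rng <- spec$signal_high - spec$signal_low
  list(
    slope_min = rng / (spec$fork_rate_range[2] * 1000 * spec$s_phase_minutes),
    slope_max = rng / (spec$fork_rate_range[1] * 1000 * spec$s_phase_minutes)
  )
}

#' Simulate a clean piecewise-linear ToR signal with known truth
#'
#' Draws an alternating CTR/TTR architecture: CTR levels uniform over the
#' signal range, CTR lengths log-uniform over `ctr_length_range`, TTR slopes
#' log-uniform over the admissible fork-rate-implied magnitude range with the
#' sign chosen toward the next CTR level. Adjacent segments share their
#' junction probe, so the clean signal is exactly continuous, and TTR
#' excursions are truncated at the signal bounds rather than crossing them.
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed; the same seed reproduces the signal exactly.
#' @param chromosome,sample_id Labels for the generated [probe_signal()].
#' @return A list with elements `signal` (a `probe_signal` holding the clean
#'   values) and `truth` (class `ground_truth`): `clean_values`, per-probe
#'   `true_type` ("CTR"/"TTR", junction probes belong to the left segment),
#'   `true_breakpoints` (probe indices of segment junctions),
#'   `dist_to_segment_end` (bp to the nearest junction or chromosome end),
#'   and a `segments` table.
#' @export
simulate_clean_signal <- function(spec = simulation_spec(), seed = NULL,
                                  chromosome = "chrSim",
                                  sample_id = "simulated") {
  stopifnot(inherits(spec, "simulation_spec"))
  sb <- .spec_slope_bounds(spec)
  step_max <- sb$slope_max * spec$probe_spacing
  rng <- spec$signal_high - spec$signal_low
  if (step_max >= rng) {
    stop("fork_rate_range incompatible with probe_spacing: a single probe ",
         "step at the slowest fork rate would exceed the signal range")
  }
  with_seed(seed, {
    n <- spec$n_probes
    values <- numeric(n)
    type <- character(n)
    seg_start <- integer(0); seg_end <- integer(0); seg_type <- character(0)

    draw_ctr_len <- function() {
      lo <- spec$ctr_length_range[1]; hi <- spec$ctr_length_range[2]
      max(1L, as.integer(round(exp(stats::runif(1, log(lo), log(hi))))))
    }

    i <- 1L
    level <- stats::runif(1, spec$signal_low, spec$signal_high)
    repeat {
      # CTR segment: probes i .. j at `level`
      len <- min(draw_ctr_len(), n - i + 1L)
      j <- i + len - 1L
      values[i:j] <- level
      type[i:j] <- "CTR"
      if (i > 1L) type[i] <- "TTR"   # junction probe belongs to the left segment
      seg_start <- c(seg_start, i); seg_end <- c(seg_end, j)
      seg_type <- c(seg_type, "CTR")
      if (j >= n) break

      # TTR segment: probes j .. k, linear from `level` toward a new level
      d <- exp(stats::runif(1, log(sb$slope_min), log(sb$slope_max))) *
        spec$probe_spacing
      target <- stats::runif(1, spec$signal_low, spec$signal_high)
      dir <- if (target >= level) 1 else -1
      n_up <- floor((spec$signal_high - level) / d)
      n_dn <- floor((level - spec$signal_low) / d)
      n_max <- if (dir > 0) n_up else n_dn
      if (n_max < 1) {        # no room toward the target: reflect
        dir <- -dir
        n_max <- if (dir > 0) n_up else n_dn
      }
      if (n_max < 1) {        # boxed in on both sides: extend the CTR to the end
        values[j:n] <- level
        type[j:n] <- "CTR"
        seg_end[length(seg_end)] <- n
        break
      }
      n_ttr <- max(1L, as.integer(round(abs(target - level) / d)))
      n_ttr <- min(n_ttr, n_max, n - j)
      if (n_ttr < 1L) break   # chromosome ends inside the CTR junction
      k <- j + n_ttr
      values[(j + 1L):k] <- level + dir * d * seq_len(n_ttr)
      type[(j + 1L):k] <- "TTR"
      seg_start <- c(seg_start, j); seg_end <- c(seg_end, k)
      seg_type <- c(seg_type, "TTR")
      level <- values[k]
      if (k >= n) break
      i <- k   # next CTR shares the junction probe k
    }

    positions <- spec$probe_spacing * seq_len(n)
    # interior junctions: starts of every segment after the first
    bp_idx <- if (length(seg_start) > 1) seg_start[-1] else integer(0)
    ends_bp <- c(positions[1], positions[bp_idx], positions[n])
    dist <- vapply(positions,
                   function(p) min(abs(p - ends_bp)), numeric(1))

    truth <- structure(
      list(
        clean_values = values,
        true_type = type,
        true_breakpoints = bp_idx,
        dist_to_segment_end = dist,
        segments = data.frame(start_idx = seg_start, end_idx = seg_end,
                              type = seg_type, stringsAsFactors = FALSE)
      ),
      class = "ground_truth"
    )
    list(
      signal = probe_signal(chromosome, positions, values, sample_id),
      truth = truth
    )
  })
}

#' Add white Gaussian noise to a probe signal
#'
#' @param signal A [probe_signal()].
#' @param sd_frac Noise standard deviation as a fraction of the signal range.
#' @param seed Integer seed for reproducible noise.
#' @param range Signal range defining the noise scale; defaults to the
#'   observed range of `signal$values`. Pass the generating spec's range
#'   (`signal_high - signal_low`) to match a simulation exactly.
#' @return A new `probe_signal` with `values + N(0, (sd_frac * range)^2)`.
#' @export
add_gaussian_noise <- function(signal, sd_frac, seed = NULL, range = NULL) {
  stopifnot(inherits(signal, "probe_signal"))
  if (!is.numeric(sd_frac) || length(sd_frac) != 1 || sd_frac < 0) {
    stop("`sd_frac` must be a single non-negative number")
  }
  rng <- range %||% diff(base::range(signal$values))
  if (sd_frac == 0) return(signal)
  with_seed(seed, {
    noisy <- signal$values +
      stats::rnorm(length(signal$values), 0, sd_frac * rng)
    probe_signal(signal$chromosome, signal$positions, noisy, signal$sample_id)
  })
}

#' Build a segmentation object from simulator ground truth
#'
#' Converts the exact generating architecture of a simulated signal into a
#' `tor_segmentation`, useful as a perfect-fit reference for classification
#' and region-assignment checks.
#'
#' @param sim Output of [simulate_clean_signal()].
#' @return A `tor_segmentation` whose fitted values equal the clean signal.
#' @export
segmentation_from_truth <- function(sim) {
  sg <- sim$truth$segments
  pos <- sim$signal$positions
  cv <- sim$truth$clean_values
  seg <- data.frame(
    start = pos[sg$start_idx],
    end = pos[sg$end_idx],
    value_start = cv[sg$start_idx],
    value_end = cv[sg$end_idx],
    type = sg$type,
    block = 1L,
    stringsAsFactors = FALSE
  )
  seg$slope <- ifelse(seg$type == "CTR", 0,
                      (seg$value_end - seg$value_start) /
                        pmax(seg$end - seg$start, 1))
  structure(
    list(
      chromosome = sim$signal$chromosome,
      sample_id = sim$signal$sample_id,
      positions = pos,
      fitted = cv,
      segments = seg[, c("start", "end", "value_start", "value_end",
                         "slope", "type", "block")],
      noise_sd = 0,
      range = max(cv) - min(cv),
      params = NULL
    ),
    class = "tor_segmentation"
  )
}
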