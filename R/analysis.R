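# Rescale a map's fitted ToR to [0, 1] by its own range, the common scale on
# which "fraction of S-phase length" comparisons are made.
.normalize_tor <- function(x) {
  r <- range(x)
  if (r[2] <= r[1]) stop("cannot normalize a constant ToR map")
  (x - r[1]) / (r[2] - r[1])
}

.annot_key <- function(a) paste(a$chromosome, a$position, sep = ":")

#' Fraction of shared probes with similar ToR between two maps
#'
#' Both maps are rescaled to `[0, 1]` by their own fitted range (so ToR is a
#' fraction of S-phase length), matched on chromosome + position, and the
#' fraction of shared probes whose ToR differs by less than `threshold_frac`
#' of the phase length is returned.
#'
#' @param a,b Per-probe annotations ([classify_probes()] output) of the two
#'   samples.
#' @param threshold_frac Similarity threshold as a fraction of S-phase
#'   length.
#' @return Fraction of shared probes with `|ToR_a - ToR_b| <
#'   threshold_frac`.
#' @export
compare_tor_maps <- function(a, b, threshold_frac = 0.30) {
  ka <- .annot_key(a); kb <- .annot_key(b)
  ia <- match(kb, ka)
  shared <- which(!is.na(ia))
  if (length(shared) < 100) {
    stop("fewer than 100 shared probes between the two maps")
  }
  ta <- .normalize_tor(a$fitted_tor)[ia[shared]]
  tb <- .normalize_tor(b$fitted_tor)[shared]
  mean(abs(ta - tb) < threshold_frac)
}

#' Fraction of shared defined probes with identical activity type
#'
#' Probes undefined in either map are excluded; the agreement fraction is
#' computed over the defined intersection.
#'
#' @inheritParams compare_tor_maps
#' @export
compare_activity_types <- function(a, b) {
  ka <- .annot_key(a); kb <- .annot_key(b)
  ia <- match(kb, ka)
  shared <- which(!is.na(ia))
  ta <- a$activity[ia[shared]]
  tb <- b$activity[shared]
  ok <- ta != "undefined" & tb != "undefined"
  if (!any(ok)) stop("no probes are defined in both maps")
  mean(ta[ok] == tb[ok])
}

#' Select ToR-matched CTR/TTR probe pairs
#'
#' Draws target ToR values uniformly over the observed ToR span and, for each
#' target, takes the as-yet-unused CTR probe and TTR probe closest to it.
#' A draw whose two selected probes differ in ToR by more than `tolerance`
#' is discarded without consuming the probes. This yields two probe sets with
#' near-identical, near-uniform ToR distributions, removing the ToR
#' confounder when contrasting CTRs with TTRs.
#'
#' @param ctr_pool,ttr_pool Per-probe annotations restricted to the CTR and
#'   TTR pools respectively (rows with other activities are dropped).
#' @param n_pairs Number of pairs requested (600-1000 is the typical working
#'   range).
#' @param tolerance Maximum |CTR ToR - TTR ToR| within a pair, in the units
#'   of `fitted_tor` (default 1% of the pooled ToR span).
#' @param seed Integer seed.
#' @return Data frame of class `paired_probes` with one row per accepted
#'   pair: CTR and TTR probe coordinates and ToRs, plus the drawn target.
#'   Fewer than `n_pairs` rows (with a warning) when a pool is exhausted.
#' @export
select_matched_pairs <- function(ctr_pool, ttr_pool, n_pairs = 1000,
                                 tolerance = NULL, seed = NULL) {
  if ("activity" %in% names(ctr_pool)) {
    ctr_pool <- ctr_pool[ctr_pool$activity == "CTR", , drop = FALSE]
  }
  if ("activity" %in% names(ttr_pool)) {
    ttr_pool <- ttr_pool[ttr_pool$activity == "TTR", , drop = FALSE]
  }
  if (!nrow(ctr_pool) || !nrow(ttr_pool)) stop("empty probe pool")
  span <- range(c(ctr_pool$fitted_tor, ttr_pool$fitted_tor))
  tolerance <- tolerance %||% (0.01 * max(span[2] - span[1],
                                          .Machine$double.eps))
  with_seed(seed, {
    co <- order(ctr_pool$fitted_tor)
    to <- order(ttr_pool$fitted_tor)
    cv <- ctr_pool$fitted_tor[co]; cfree <- rep(TRUE, length(cv))
    tv <- ttr_pool$fitted_tor[to]; tfree <- rep(TRUE, length(tv))

    nearest_free <- function(vals, free, target) {
      iv <- which(free)
      if (!length(iv)) return(NA_integer_)
      vv <- vals[iv]
      j <- findInterval(target, vv)
      cand <- unique(pmin(pmax(c(j, j + 1L), 1L), length(vv)))
      iv[cand[which.min(abs(vv[cand] - target))]]
    }

    rows <- vector("list", n_pairs)
    got <- 0L
    attempts <- 0L
    max_attempts <- 20L * n_pairs
    while (got < n_pairs && attempts < max_attempts) {
      attempts <- attempts + 1L
      target <- stats::runif(1, span[1], span[2])
      ic <- nearest_free(cv, cfree, target)
      it <- nearest_free(tv, tfree, target)
      if (is.na(ic) || is.na(it)) break  # a pool is exhausted
      if (abs(cv[ic] - tv[it]) > tolerance) {
        next  # discarded draw; probes stay in their pools
      }
      cfree[ic] <- FALSE; tfree[it] <- FALSE
      got <- got + 1L
      ci <- co[ic]; ti <- to[it]
      rows[[got]] <- data.frame(
        target_tor = target,
        ctr_chromosome = ctr_pool$chromosome[ci],
        ctr_position = ctr_pool$position[ci],
        ctr_tor = ctr_pool$fitted_tor[ci],
        ttr_chromosome = ttr_pool$chromosome[ti],
        ttr_position = ttr_pool$position[ti],
        ttr_tor = ttr_pool$fitted_tor[ti],
        stringsAsFactors = FALSE
      )
    }
    if (got < n_pairs) {
      warning("only ", got, " of ", n_pairs, " requested pairs could be ",
              "formed within tolerance")
    }
    out <- if (got) do.call(rbind, rows[seq_len(got)]) else
      data.frame(target_tor = numeric(0))
    attr(out, "tolerance") <- tolerance
    attr(out, "seed") <- seed
    class(out) <- c("paired_probes", class(out))
    out
  })
}

#' Keep probes far from every gene
#'
#' @param probes Per-probe annotation (or any data frame with `chromosome`
#'   and `position`).
#' @param genes Regions data frame (`chromosome`, `start`, `end`, half-open).
#' @param min_dist Minimum genomic distance in bp; probes within a gene or
#'   within `min_dist` of one are removed.
#' @return The intergenic subset of `probes`.
#' @export
filter_intergenic <- function(probes, genes, min_dist = 20000) {
  if (is.null(genes) || nrow(genes) == 0) return(probes)
  keep <- rep(TRUE, nrow(probes))
  for (cc in unique(probes$chromosome)) {
    pi <- which(probes$chromosome == cc)
    g <- genes[genes$chromosome == cc, , drop = FALSE]
    if (!nrow(g)) next
    pr <- IRanges::IRanges(start = probes$position[pi],
                           width = 1L)
    gr <- IRanges::reduce(IRanges::IRanges(start = g$start + 1L,
                                           end = g$end))
    inside <- IRanges::countOverlaps(pr, gr) > 0
    hits <- IRanges::distanceToNearest(pr, gr)
    d <- rep(Inf, length(pi))
    d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance + 1
    d[inside] <- 0
    keep[pi] <- d > min_dist
  }
  probes[keep, , drop = FALSE]
}

#' Windowed feature density around probes
#'
#' Counts features (e.g. sequence-read positions) falling within a window
#' centred on each probe, or, when `weights` are supplied (e.g. per-site
#' methylation percentages), returns the mean weight in the window (`NA`
#' for an empty window).
#'
#' @param feature_positions Numeric vector of feature positions (bp) on the
#'   probes' chromosome.
#' @param probe_positions Numeric vector of probe positions (bp).
#' @param window_bp Full window width in bp; the window is
#'   `[pos - window_bp/2, pos + window_bp/2]`.
#' @param weights Optional per-feature weights.
#' @return Numeric vector, one density (count or mean weight) per probe.
#' @export
window_feature_density <- function(feature_positions, probe_positions,
                                   window_bp, weights = NULL) {
  stopifnot(window_bp > 0)
  o <- order(feature_positions)
  f <- feature_positions[o]
  half <- window_bp / 2
  hi <- findInterval(probe_positions + half, f)
  lo <- findInterval(probe_positions - half - 0.5, f)
  n_in <- hi - lo
  if (is.null(weights)) return(n_in)
  w <- weights[o]
  cw <- c(0, cumsum(w))
  out <- (cw[hi + 1] - cw[lo + 1]) / n_in
  out[n_in == 0] <- NA_real_
  out
}

#' CTR-residence enrichment with matched random controls
#'
#' Computes the percentage of regions (e.g. expressed genes) residing in
#' CTRs, and compares it with `n_random` control sets in which each region is
#' re-placed at a random defined location on the same chromosome, with the
#' same length, and in the same ToR bin (bin width `tor_bin_frac` of the
#' fitted range). Regions assigned "undefined" are removed before the
#' calculation.
#'
#' @param regions Regions data frame (`chromosome`, `start`, `end`).
#' @param results A single `tor_segmentation` or a named list of them (one
#'   per chromosome).
#' @param n_random Number of control sets.
#' @param tor_bin_frac ToR bin width as a fraction of the fitted range.
#' @param ctr_margin,ttr_margin Undefined margins in bp.
#' @param max_tries Placement attempts per region before the ToR-bin
#'   constraint is dropped for that region (dropped placements are counted
#'   and reported with a warning).
#' @param seed Integer seed.
#' @param keep_placements Also return every control placement (one data
#'   frame per null set).
#' @return List with `observed` (% of defined regions in CTRs), `null`
#'   (vector of control percentages), `p` (empirical upper-tail p with the
#'   (k+1)/(n+1) correction), `n_regions`, `n_relaxed` (placements made
#'   without the ToR constraint), and optionally `placements`.
#' @export
ctr_residence_enrichment <- function(regions, results, n_random = 100,
                                     tor_bin_frac = 0.10,
                                     ctr_margin = 120000,
                                     ttr_margin = 180000,
                                     max_tries = 1000, seed = NULL,
                                     keep_placements = FALSE) {
  if (inherits(results, "tor_segmentation")) {
    results <- stats::setNames(list(results), results$chromosome)
  }
  stopifnot(all(regions$chromosome %in% names(results)))
  assign1 <- function(chrom, start, end) {
    assign_regions(results[[chrom]],
                   data.frame(chromosome = chrom, start = start, end = end),
                   ctr_margin, ttr_margin)
  }
  obs <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    assign1(regions$chromosome[i], regions$start[i], regions$end[i])
  }))
  defined <- obs$activity != "undefined"
  if (!any(defined)) stop("no region has a defined activity type")
  obs <- obs[defined, , drop = FALSE]
  observed <- 100 * mean(obs$activity == "CTR")

  # ToR bin per region, on the map's own normalized scale
  tor_bin <- function(chrom, tor) {
    r <- range(results[[chrom]]$fitted)
    floor((tor - r[1]) / max(r[2] - r[1], .Machine$double.eps) /
            tor_bin_frac)
  }
  obs$bin <- mapply(tor_bin, obs$chromosome, obs$tor)
  span <- lapply(results, function(rs) {
    c(min(rs$segments$start), max(rs$segments$end))
  })

  with_seed(seed, {
    n_relaxed <- 0L
    null_pct <- numeric(n_random)
    placements <- if (keep_placements) vector("list", n_random)
    for (s in seq_len(n_random)) {
      hit_ctr <- logical(nrow(obs))
      placed_rows <- if (keep_placements) vector("list", nrow(obs))
      for (i in seq_len(nrow(obs))) {
        chrom <- obs$chromosome[i]
        len <- obs$end[i] - obs$start[i]
        sp <- span[[chrom]]
        placed <- NULL
        for (try in seq_len(max_tries)) {
          st <- floor(stats::runif(1, sp[1], max(sp[2] - len, sp[1] + 1)))
          cand <- assign1(chrom, st, st + len)
          if (cand$activity != "undefined" &&
              tor_bin(chrom, cand$tor) == obs$bin[i]) {
            placed <- cand
            break
          }
        }
        if (is.null(placed)) {  # relax the ToR constraint for this region
          n_relaxed <- n_relaxed + 1L
          repeat {
            st <- floor(stats::runif(1, sp[1], max(sp[2] - len, sp[1] + 1)))
            cand <- assign1(chrom, st, st + len)
            if (cand$activity != "undefined") { placed <- cand; break }
          }
        }
        hit_ctr[i] <- placed$activity == "CTR"
        if (keep_placements) placed_rows[[i]] <- placed
      }
      null_pct[s] <- 100 * mean(hit_ctr)
      if (keep_placements) placements[[s]] <- do.call(rbind, placed_rows)
    }
    if (n_relaxed > 0) {
      warning(n_relaxed, " control placement(s) made without the ToR-bin ",
              "constraint")
    }
    out <- list(
      observed = observed,
      null = null_pct,
      p = (sum(null_pct >= observed) + 1) / (n_random + 1),
      n_regions = nrow(obs),
      n_relaxed = n_relaxed
    )
    if (keep_placements) out$placements <- placements
    out
  })
}

#' Paired t-test on a feature across ToR-matched CTR/TTR pairs
#'
#' Two-sided paired t-test on (TTR value - CTR value) over pairs for which
#' the feature is available on both sides. When the differences have zero
#' variance the degenerate result is reported directly (t = 0, p = 1 for a
#' zero mean; p below the machine floor otherwise).
#'
#' @param pairs A `paired_probes` data frame from [select_matched_pairs()].
#' @param features Data frame with `chromosome`, `position`, `value` giving
#'   the per-probe feature (e.g. a windowed density).
#' @return List with `mean_difference`, `statistic`, `p_value`, `n_pairs`.
#' @export
paired_difference_test <- function(pairs, features) {
  fkey <- paste(features$chromosome, features$position, sep = ":")
  cidx <- match(paste(pairs$ctr_chromosome, pairs$ctr_position, sep = ":"),
                fkey)
  tidx <- match(paste(pairs$ttr_chromosome, pairs$ttr_position, sep = ":"),
                fkey)
  cv <- features$value[cidx]
  tv <- features$value[tidx]
  ok <- !is.na(cv) & !is.na(tv)
  if (sum(ok) < 10) stop("fewer than 10 complete pairs")
  d <- tv[ok] - cv[ok]
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(mean_difference = 0, statistic = 0, p_value = 1,
                  n_pairs = length(d)))
    }
    return(list(mean_difference = mean(d),
                statistic = sign(mean(d)) * Inf,
                p_value = 0, n_pairs = length(d)))
  }
  tt <- stats::t.test(d)
  list(mean_difference = unname(tt$estimate),
       statistic = unname(tt$statistic),
       p_value = tt$p.value,
       n_pairs = length(d))
}
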