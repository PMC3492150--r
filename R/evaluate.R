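#' Root-mean-square error as percent of signal range
#'
#' @param fitted,clean Per-probe fitted and clean (true) values, equal
#'   length.
#' @param range Signal range used for normalization.
#' @return `sqrt(mean((fitted - clean)^2)) / range * 100`.
#' @export
rmse_percent <- function(fitted, clean, range) {
  if (length(fitted) != length(clean)) {
    stop("`fitted` and `clean` must have equal length")
  }
  stopifnot(range > 0)
  sqrt(mean((fitted - clean)^2)) / range * 100
}

#' Classification accuracy as a function of distance from segment ends
#'
#' For each true activity type and each distance bin, the fraction of probes
#' whose called type equals the true type. Distance is measured to the
#' nearest true segment end; the comparison uses the raw per-probe segment
#' type (no undefined margins), so every probe has a call. Bins are
#' `bin_width` probes wide up to `max_bin` probes, beyond which probes are
#' pooled.
#'
#' @param called Character vector of called types ("CTR"/"TTR"), probe-for-
#'   probe aligned with the truth.
#' @param truth A `ground_truth` from [simulate_clean_signal()].
#' @param probe_spacing Probe spacing in bp (to express distance in probes).
#' @param bin_width Bin width in probes.
#' @param max_bin Pooling threshold in probes.
#' @return Data frame with columns `type`, `dist_probes` (lower bin edge),
#'   `n`, `accuracy`.
#' @export
accuracy_by_distance <- function(called, truth, probe_spacing,
                                 bin_width = 1, max_bin = 10) {
  stopifnot(length(called) == length(truth$true_type))
  dist_probes <- truth$dist_to_segment_end / probe_spacing
  bin <- pmin(floor(dist_probes / bin_width) * bin_width, max_bin)
  correct <- called == truth$true_type
  out <- list()
  for (ty in sort(unique(truth$true_type))) {
    sel <- truth$true_type == ty
    for (bb in sort(unique(bin[sel]))) {
      s2 <- sel & bin == bb
      out[[length(out) + 1]] <- data.frame(
        type = ty, dist_probes = bb, n = sum(s2),
        accuracy = mean(correct[s2])
      )
    }
  }
  do.call(rbind, out)
}

#' Pooled typing accuracy beyond type-specific distances
#'
#' Fraction of probes correctly typed among those farther than
#' `ctr_min_probes` (for true-CTR probes) or `ttr_min_probes` (for true-TTR
#' probes) from the nearest true segment end. With `type` set, restricts to
#' that true type only.
#'
#' @inheritParams accuracy_by_distance
#' @param ctr_min_probes,ttr_min_probes Exclusive distance thresholds in
#'   probes.
#' @param type Optional: "CTR" or "TTR" to restrict the numerator and
#'   denominator to one true type.
#' @return A fraction in `[0, 1]` (`NaN` if no probe qualifies).
#' @export
typing_accuracy <- function(called, truth, probe_spacing,
                            ctr_min_probes = 3, ttr_min_probes = 4.5,
                            type = NULL) {
  dist_probes <- truth$dist_to_segment_end / probe_spacing
  far <- ifelse(truth$true_type == "CTR",
                dist_probes > ctr_min_probes,
                dist_probes > ttr_min_probes)
  if (!is.null(type)) far <- far & truth$true_type == type
  mean((called == truth$true_type)[far])
}

# raw per-probe segment-type call of a segmentation (margins disabled)
.called_types <- function(result) {
  seg <- result$segments
  idx <- .segment_index(seg, result$positions)
  seg$type[idx]
}

#' Sample autocorrelation of a probe-ordered series
#'
#' @param values Numeric vector in probe order.
#' @param max_lag Largest lag (needs `length(values) >= max_lag + 2`).
#' @return Numeric vector of autocorrelations at lags `1..max_lag`.
#' @export
autocorrelation <- function(values, max_lag) {
  if (length(values) < max_lag + 2) stop("series too short for max_lag")
  if (stats::sd(values) == 0) {
    stop("autocorrelation is undefined for a constant series")
  }
  as.numeric(stats::acf(values, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)[-1]
}

#' Run the simulation benchmark
#'
#' For each noise level: simulate `n_signals` clean profiles, add Gaussian
#' noise, segment each, and aggregate the RMSE of the recovered signal
#' (percent of range) and the typing accuracy as a function of distance from
#' the true segment ends. Optionally re-tunes the breakpoint-penalty scale
#' per noise level on a few pilot signals (grid 2/4/8) before the main run.
#' Fully reproducible under `seed`.
#'
#' @param n_signals Signals per noise level.
#' @param spec A [simulation_spec()].
#' @param noise_levels Noise sds as fractions of the signal range.
#' @param params A [fit_parameters()].
#' @param seed Integer seed driving all randomness.
#' @param tune_penalty Re-tune `penalty_scale` per noise level.
#' @param n_pilot Pilot signals used for tuning.
#' @return Object of class `tor_benchmark`: `rmse` (per-level mean/sd),
#'   `pooled` (per-level pooled and per-type accuracy beyond the margin
#'   distances), `accuracy` (per-level accuracy-by-distance tables),
#'   `counts` (raw per-distance tallies), `penalty_scales`, `failures`,
#'   plus the spec, params and seed used.
#' @export
run_benchmark <- function(n_signals = 100, spec = simulation_spec(),
                          noise_levels = c(0.02, 0.05, 0.10, 0.15, 0.20),
                          params = fit_parameters(), seed = 1,
                          tune_penalty = TRUE, n_pilot = 3) {
  rng <- spec$signal_high - spec$signal_low
  params$signal_range <- rng
  seeds <- with_seed(seed, {
    matrix(sample.int(.Machine$integer.max - 1, 2 * (n_signals + n_pilot)),
           ncol = 2)
  })

  run_one <- function(i, noise, par) {
    sim <- simulate_clean_signal(spec, seed = seeds[i, 1])
    noisy <- add_gaussian_noise(sim$signal, noise, seed = seeds[i, 2],
                                range = rng)
    fit <- segment_signal(noisy, par)
    list(
      rmse = rmse_percent(fit$fitted, sim$truth$clean_values, rng),
      called = .called_types(fit),
      truth = sim$truth
    )
  }

  rmse_rows <- list(); pooled_rows <- list(); acc_tabs <- list()
  count_rows <- list(); scales <- numeric(0); failures <- list()
  for (noise in noise_levels) {
    par <- params
    if (isTRUE(tune_penalty) && n_pilot > 0) {
      grid <- c(1, 2, 4, 8)
      pilot_rmse <- vapply(grid, function(sc) {
        p2 <- par; p2$penalty_scale <- sc; p2$breakpoint_penalty <- NULL
        mean(vapply(seq_len(n_pilot), function(i) {
          run_one(n_signals + i, noise, p2)$rmse
        }, numeric(1)))
      }, numeric(1))
      par$penalty_scale <- grid[which.min(pilot_rmse)]
      par$breakpoint_penalty <- NULL
    }
    scales <- c(scales, par$penalty_scale)

    rmse <- rep(NA_real_, n_signals)
    called_all <- list(); truth_all <- list()
    for (i in seq_len(n_signals)) {
      res <- tryCatch(run_one(i, noise, par), error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <- list(noise = noise, signal = i,
                                                 message = conditionMessage(res))
        next
      }
      rmse[i] <- res$rmse
      called_all[[i]] <- res$called
      truth_all[[i]] <- res$truth
    }
    ok <- !is.na(rmse)
    rmse_rows[[length(rmse_rows) + 1]] <- data.frame(
      noise = noise, mean_rmse = mean(rmse[ok]), sd_rmse = stats::sd(rmse[ok]),
      n_signals = sum(ok)
    )
    called <- unlist(called_all[ok])
    truth <- list(
      true_type = unlist(lapply(truth_all[ok], `[[`, "true_type")),
      dist_to_segment_end = unlist(lapply(truth_all[ok], `[[`,
                                          "dist_to_segment_end"))
    )
    pooled_rows[[length(pooled_rows) + 1]] <- data.frame(
      noise = noise,
      pooled_accuracy = typing_accuracy(called, truth, spec$probe_spacing),
      ctr_accuracy = typing_accuracy(called, truth, spec$probe_spacing,
                                     type = "CTR"),
      ttr_accuracy = typing_accuracy(called, truth, spec$probe_spacing,
                                     type = "TTR")
    )
    acc <- accuracy_by_distance(called, truth, spec$probe_spacing)
    acc$noise <- noise
    acc_tabs[[length(acc_tabs) + 1]] <- acc
  }

  structure(list(
    rmse = do.call(rbind, rmse_rows),
    pooled = do.call(rbind, pooled_rows),
    accuracy = do.call(rbind, acc_tabs),
    penalty_scales = stats::setNames(scales, noise_levels),
    failures = failures,
    spec = spec, params = params, seed = seed,
    noise_levels = noise_levels, n_signals = n_signals
  ), class = "tor_benchmark")
}

#' @export
print.tor_benchmark <- function(x, ...) {
  cat("<tor_benchmark>", x$n_signals, "signals x",
      format(x$spec$n_probes), "probes, seed", x$seed, "\n")
  df <- merge(x$rmse, x$pooled, by = "noise")
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}
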