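#' Classify probes as CTR, TTR or undefined
#'
#' Each probe inherits the activity type of the segment containing it unless
#' its distance to the nearer segment end falls below that type's margin, in
#' which case the call is withheld ("undefined"). Chromosome (block) ends
#' count as segment ends. The default margins reflect the distances beyond
#' which simulated calls are reliable: 120 kb inside CTRs, 180 kb inside
#' TTRs.
#'
#' @param result A `tor_segmentation` from [segment_signal()].
#' @param ctr_margin,ttr_margin Undefined margins in bp for CTR and TTR
#'   segments respectively (0 disables the margin).
#' @return Data frame (per-probe annotation) with columns `chromosome`,
#'   `position`, `fitted_tor`, `activity` ("CTR"/"TTR"/"undefined") and
#'   `dist_to_breakpoint` (bp to the nearest segment end).
#' @export
classify_probes <- function(result, ctr_margin = 120000, ttr_margin = 180000) {
  stopifnot(inherits(result, "tor_segmentation"),
            ctr_margin >= 0, ttr_margin >= 0)
  seg <- result$segments
  pos <- result$positions
  idx <- .segment_index(seg, pos)
  dist <- pmin(abs(pos - seg$start[idx]), abs(seg$end[idx] - pos))
  margin <- ifelse(seg$type[idx] == "CTR", ctr_margin, ttr_margin)
  activity <- ifelse(dist < margin, "undefined", seg$type[idx])
  activity[is.na(idx)] <- "undefined"   # probes in unfitted blocks, if any
  data.frame(
    chromosome = result$chromosome,
    position = pos,
    fitted_tor = result$fitted,
    activity = activity,
    dist_to_breakpoint = dist,
    stringsAsFactors = FALSE
  )
}

#' Assign ToR and activity type to genomic regions
#'
#' A region's ToR is the fitted value at its midpoint (`floor((start +
#' end) / 2)`); its activity type is that of the segment containing the
#' midpoint, provided at least part of the region reaches that segment's
#' defined (non-margin) zone — otherwise "undefined". Regions use the
#' half-open `[start, end)` convention; a midpoint exactly on a breakpoint
#' belongs to the left segment.
#'
#' @param result A `tor_segmentation`.
#' @param regions Data frame with columns `chromosome`, `start`, `end` (and
#'   optionally `name`), e.g. from [read_regions_bed()].
#' @param ctr_margin,ttr_margin Undefined margins in bp (see
#'   [classify_probes()]).
#' @return `regions` with added columns `tor` and `activity`.
#' @export
assign_regions <- function(result, regions,
                           ctr_margin = 120000, ttr_margin = 180000) {
  stopifnot(inherits(result, "tor_segmentation"))
  seg <- result$segments
  mid <- floor((regions$start + regions$end) / 2)
  idx <- .segment_index(seg, mid)
  if (any(is.na(idx))) {
    stop("region midpoint outside the segmented territory (first offender: ",
         which(is.na(idx))[1], ")")
  }
  tor <- seg$value_start[idx] + seg$slope[idx] * (mid - seg$start[idx])
  margin <- ifelse(seg$type[idx] == "CTR", ctr_margin, ttr_margin)
  def_lo <- seg$start[idx] + margin
  def_hi <- seg$end[idx] - margin
  reaches_defined <- pmin(regions$end, def_hi) > pmax(regions$start, def_lo) &
    def_hi > def_lo
  activity <- ifelse(reaches_defined, seg$type[idx], "undefined")
  out <- regions
  out$tor <- tor
  out$activity <- activity
  out
}

#' @rdname assign_regions
#' @param chromosome,start,end A single region's coordinates.
#' @return `assign_region()` returns a list with `tor` and `activity` for a
#'   single region.
#' @export
assign_region <- function(result, chromosome, start, end,
                          ctr_margin = 120000, ttr_margin = 180000) {
  df <- assign_regions(
    result,
    data.frame(chromosome = chromosome, start = start, end = end,
               stringsAsFactors = FALSE),
    ctr_margin, ttr_margin
  )
  list(tor = df$tor[1], activity = df$activity[1])
}
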