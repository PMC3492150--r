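#' Construct a per-chromosome probe signal
#'
#' A probe signal is the raw material of all downstream fitting: ordered probe
#' midpoint positions (1-based bp) on one chromosome together with the
#' normalized S/G1 ratio measured at each probe. On the raw array scale the
#' ratio spans roughly 1 (late replicating) to 2 (early replicating).
#'
#' @param chromosome Chromosome identifier (passed through verbatim; no
#'   "chr" normalization is applied).
#' @param positions Integer-ish vector of probe midpoint positions in bp,
#'   strictly increasing.
#' @param values Numeric vector of normalized S/G1 ratios, finite, same
#'   length as `positions`.
#' @param sample_id Free-text sample label.
#' @return An object of class `probe_signal`: a list with elements
#'   `chromosome`, `positions`, `values`, `sample_id`.
#' @export
probe_signal <- function(chromosome, positions, values, sample_id = "sample") {
  positions <- as.numeric(positions)
  values <- as.numeric(values)
  if (length(positions) != length(values)) {
    stop("`positions` and `values` must have equal length")
  }
  if (length(positions) < 2) {
    stop("a probe signal needs at least 2 probes")
  }
  if (any(!is.finite(positions)) || any(!is.finite(values))) {
    stop("positions and values must all be finite")
  }
  if (any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing within a chromosome")
  }
  structure(
    list(
      chromosome = as.character(chromosome)[1],
      positions = positions,
      values = values,
      sample_id = as.character(sample_id)[1]
    ),
    class = "probe_signal"
  )
}

#' @export
print.probe_signal <- function(x, ...) {
  cat(sprintf(
    "<probe_signal> %s: %d probes, %s:%s-%s, values [%.3f, %.3f]\n",
    x$sample_id, length(x$positions), x$chromosome,
    format(min(x$positions), scientific = FALSE),
    format(max(x$positions), scientific = FALSE),
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Read a tab-delimited per-probe ToR table
#'
#' Reads a plain tab-separated table with one row per probe (chromosome,
#' position in bp, normalized S/G1 value), returning one [probe_signal()] per
#' chromosome. Rows with missing values are dropped (count reported), rows
#' are sorted by position, and duplicate positions are collapsed by the mean
#' of their values.
#'
#' @param path Path to the TSV file (with header).
#' @param column_map Named character vector mapping the roles `chromosome`,
#'   `position`, `value` to column names in the file.
#' @param sample_id Sample label attached to each returned signal.
#' @return Named list of `probe_signal`, one per chromosome (chromosomes with
#'   fewer than 2 usable probes are excluded with a warning).
#' @export
read_probe_table <- function(path,
                             column_map = c(chromosome = "chrom",
                                            position = "position",
                                            value = "value"),
                             sample_id = "sample") {
  if (!file.exists(path)) stop("file not found: ", path)
  need <- c("chromosome", "position", "value")
  if (!all(need %in% names(column_map))) {
    stop("column_map must name columns for: ", paste(need, collapse = ", "))
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(unname(column_map[need]), names(tab))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  }
  chrom <- tab[[column_map[["chromosome"]]]]
  pos_raw <- tab[[column_map[["position"]]]]
  val_raw <- tab[[column_map[["value"]]]]

  pos <- suppressWarnings(as.numeric(pos_raw))
  val <- suppressWarnings(as.numeric(val_raw))
  # unparseable = non-empty text that fails numeric conversion (empty/NA is a
  # missing value, handled by the drop rule below)
  bad_pos <- which(is.na(pos) & !(is.na(pos_raw) | trimws(pos_raw) == "" |
                                    toupper(trimws(pos_raw)) %in% c("NA", "NAN")))
  bad_val <- which(is.na(val) & !(is.na(val_raw) | trimws(val_raw) == "" |
                                    toupper(trimws(val_raw)) %in% c("NA", "NAN")))
  bad <- sort(unique(c(bad_pos, bad_val)))
  if (length(bad)) {
    stop("unparseable row at line ", bad[1] + 1L, " of ", path)
  }
  if (any(pos[!is.na(pos)] != floor(pos[!is.na(pos)]))) {
    stop("positions must be integer bp coordinates")
  }

  keep <- !is.na(pos) & is.finite(val)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(n_drop, " row(s) with missing values dropped from ", path)
  }
  chrom <- chrom[keep]; pos <- pos[keep]; val <- val[keep]

  out <- list()
  for (cc in unique(chrom)) {
    sel <- chrom == cc
    p <- pos[sel]; v <- val[sel]
    o <- order(p)
    p <- p[o]; v <- v[o]
    if (anyDuplicated(p)) {
      v <- as.numeric(tapply(v, p, mean))
      p <- sort(unique(p))
    }
    if (length(p) < 2) {
      warning("chromosome ", cc, " has < 2 probes; excluded")
      next
    }
    out[[cc]] <- probe_signal(cc, p, v, sample_id = sample_id)
  }
  out
}

# Integer boundary positions of a segmentation, 0-based half-open BED space.
# A probe's footprint is the single base [pos - 1, pos); segment boundaries
# between probes are rounded to the nearest base.
.bed_boundaries <- function(seg, first_pos, last_pos) {
  inner <- if (nrow(seg) > 1) round(seg$start[-1]) - 1 else numeric(0)
  c(first_pos - 1, inner, last_pos)
}

#' Write segments as BED6
#'
#' One record per fitted segment; the name field carries the activity type
#' (CTR/TTR), the score the segment's mean fitted ToR rescaled to 0-1000
#' over the result's fitted range. Coordinates are 0-based half-open with a
#' single-bp probe footprint `[pos - 1, pos)`.
#'
#' @param result A `tor_segmentation` from [segment_signal()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_segments_bed <- function(result, path) {
  stopifnot(inherits(result, "tor_segmentation"))
  seg <- result$segments
  if (is.null(seg) || nrow(seg) == 0) stop("empty segmentation result")
  lines <- NULL
  vr <- range(result$fitted)
  span <- max(vr[2] - vr[1], .Machine$double.eps)
  rows <- vector("list", length(unique(seg$block)))
  for (bl in unique(seg$block)) {
    sb <- seg[seg$block == bl, , drop = FALSE]
    pin <- result$positions[result$positions >= sb$start[1] &
                              result$positions <= sb$end[nrow(sb)]]
    bnd <- .bed_boundaries(sb, pin[1], pin[length(pin)])
    mean_tor <- vapply(seq_len(nrow(sb)), function(i) {
      inseg <- result$positions >= sb$start[i] & result$positions <= sb$end[i]
      if (!any(inseg)) (sb$value_start[i] + sb$value_end[i]) / 2
      else mean(result$fitted[inseg])
    }, numeric(1))
    rows[[bl]] <- data.frame(
      chrom = result$chromosome,
      start = bnd[-length(bnd)],
      end = bnd[-1],
      name = sb$type,
      score = round((mean_tor - vr[1]) / span * 1000),
      strand = ".",
      stringsAsFactors = FALSE
    )
  }
  bed <- do.call(rbind, rows)
  bed <- bed[bed$end > bed$start, , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write per-probe fitted ToR as bedGraph
#'
#' Each probe contributes one interval covering its single-bp footprint
#' `[pos - 1, pos)` with the fitted ToR value; intervals are sorted and
#' non-overlapping.
#'
#' @inheritParams write_segments_bed
#' @export
write_fitted_bedgraph <- function(result, path) {
  stopifnot(inherits(result, "tor_segmentation"))
  if (length(result$fitted) == 0) stop("empty segmentation result")
  df <- data.frame(
    chrom = result$chromosome,
    start = result$positions - 1,
    end = result$positions,
    value = format(result$fitted, digits = 10, trim = TRUE, scientific = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a per-probe annotation table
#'
#' TSV with columns chrom, position, raw (if available), fitted ToR, activity
#' type and distance to the nearest breakpoint.
#'
#' @param annotation Data frame from [classify_probes()].
#' @param path Output file path.
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read genomic regions from a BED file
#'
#' Only the first four columns are used; coordinates stay in BED's 0-based
#' half-open convention, which is also the package's `[start, end)` region
#' convention.
#'
#' @param path Path to a BED file (no header).
#' @return Data frame with columns `chromosome`, `start`, `end`, `name`.
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED file needs at least 3 columns: ", path)
  out <- data.frame(
    chromosome = as.character(tab[[1]]),
    start = as.numeric(tab[[2]]),
    end = as.numeric(tab[[3]]),
    name = if (ncol(tab) >= 4) as.character(tab[[4]]) else
      paste0("region_", seq_len(nrow(tab))),
    stringsAsFactors = FALSE
  )
  if (any(out$start < 0) || any(out$end <= out$start)) {
    stop("invalid region coordinates in ", path)
  }
  out
}
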