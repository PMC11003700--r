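## ROSE-style super-enhancer calling: drop TSS-proximal peaks, stitch the
## remainder within 12.5 kb, score stitched regions by input-subtracted
## signal, and cut the ranked curve at the inflection where the tangent
## slope of the unit-scaled curve reaches 1.

#' Filter peaks to those distal from every TSS
#'
#' Retains peaks whose anchor lies more than `tss_exclusion` bp from every
#' TSS on the same chromosome (peaks on chromosomes without genes are
#' retained).
#'
#' @param peaks Peak data frame.
#' @param genes Gene-model data frame.
#' @param tss_exclusion Minimum distance in bp (default 2500).
#' @return The distal subset of `peaks`.
#' @export
distal_filter <- function(peaks, genes, tss_exclusion = 2500) {
  validate_peaks(peaks)
  genes <- validate_genes(genes)
  if (nrow(peaks) == 0L) return(peaks)
  anchors <- peak_anchor(peaks)
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    tss <- genes$tss[genes$chrom == peaks$chrom[i]]
    length(tss) == 0L || min(abs(anchors[i] - tss)) > tss_exclusion
  }, TRUE)
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stitch peaks into enhancer regions
#'
#' Greedy chaining per chromosome: consecutive peaks (sorted by start)
#' merge when the gap `next.start - prev.end` is at most
#' `stitch_distance`; overlapping peaks always merge. Spans run from the
#' first constituent's start to the last constituent's end.
#'
#' @param peaks Peak data frame.
#' @param stitch_distance Maximum gap in bp (default 12500).
#' @return Object of class `"stitched_enhancers"`: `regions` (data frame
#'   `region_id`, `chrom`, `start`, `end`, `n_constituents`,
#'   `constituents` comma-joined peak names) and `constituent_peaks` (the
#'   input peaks plus a `region_id` column).
#' @export
stitch <- function(peaks, stitch_distance = 12500) {
  validate_peaks(peaks)
  peaks <- peaks[order(peaks$chrom, peaks$start, peaks$end), ,
                 drop = FALSE]
  rownames(peaks) <- NULL
  region_id <- integer(nrow(peaks))
  next_id <- 0L
  for (ch in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == ch)
    cur_end <- -Inf
    for (i in idx) {
      if (peaks$start[i] - cur_end > stitch_distance) next_id <- next_id + 1L
      region_id[i] <- next_id
      cur_end <- max(cur_end, peaks$end[i])
    }
  }
  peaks$region_id <- region_id
  regions <- do.call(rbind, lapply(split(peaks, region_id), function(df) {
    data.frame(region_id = df$region_id[1], chrom = df$chrom[1],
               start = min(df$start), end = max(df$end),
               n_constituents = nrow(df),
               constituents = paste(df$name, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(regions))
    regions <- data.frame(region_id = integer(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_constituents = integer(),
                          constituents = character())
  regions <- regions[order(regions$region_id), , drop = FALSE]
  rownames(regions) <- NULL
  structure(list(regions = regions, constituent_peaks = peaks),
            class = "stitched_enhancers")
}

#' @export
print.stitched_enhancers <- function(x, ...) {
  cat("Stitched enhancers:", nrow(x$regions), "region(s) from",
      nrow(x$constituent_peaks), "peak(s)")
  if (!is.null(x$regions$is_super))
    cat(";", sum(x$regions$is_super), "super")
  cat("\n")
  invisible(x)
}

#' Score stitched regions by input-subtracted signal
#'
#' Per region, RPKM of the ChIP track summed over the constituent peak
#' intervals minus the RPKM of the matched input track over the same
#' intervals, floored at 0 (negative enrichment is noise). Adds ascending
#' signal ranks (ties broken by region order so ranks are unique).
#'
#' @param stitched A `"stitched_enhancers"` object.
#' @param chip_track,input_track `"coverage_track"` objects with
#'   `total_reads` set.
#' @return The object with `signal` and `rank` columns on `$regions`.
#' @export
score_stitched <- function(stitched, chip_track, input_track) {
  stopifnot(inherits(stitched, "stitched_enhancers"),
            inherits(chip_track, "coverage_track"),
            inherits(input_track, "coverage_track"))
  pk <- stitched$constituent_peaks
  chip_raw <- input_raw <- len <- numeric(nrow(stitched$regions))
  for (j in seq_len(nrow(stitched$regions))) {
    rid <- stitched$regions$region_id[j]
    sub <- pk[pk$region_id == rid, , drop = FALSE]
    chip_raw[j] <- sum(.track_interval_sum(chip_track, sub$chrom[1],
                                           sub$start, sub$end))
    input_raw[j] <- sum(.track_interval_sum(input_track, sub$chrom[1],
                                            sub$start, sub$end))
    len[j] <- sum(sub$end - sub$start)
  }
  sig <- pmax(0, rpkm_value(chip_raw, len, chip_track$total_reads) -
                 rpkm_value(input_raw, len, input_track$total_reads))
  stitched$regions$signal <- sig
  stitched$regions$rank <- rank(sig, ties.method = "first")
  stitched
}

## Tangent point of the unit-scaled ranked curve: the position where a
## line of slope 1 slid up from below touches the (convex) curve, i.e.
## argmin of scaled_signal - scaled_rank; the numerical slope crosses 1
## there. Returns NA for a flat curve. Ties take the highest rank.
.tangent_cutoff_index <- function(y) {
  n <- length(y)
  rng <- max(y) - min(y)
  if (rng == 0) return(NA_integer_)
  d <- (y - min(y)) / rng - seq(0, 1, length.out = n)
  max(which(d == min(d)))
}

#' Call super-enhancers at the rank-curve inflection
#'
#' Signals are sorted ascending and both rank and signal rescaled to
#' \[0, 1\]. The cutoff sits where a line of tangent slope 1 touches the
#' scaled rank curve (the point minimizing scaled signal minus scaled
#' rank, where the numerical slope crosses 1; rank ties resolve to the
#' higher rank). Regions with signal strictly above the cutoff signal
#' are super. All-equal signals have a flat curve, no tangent point and
#' no supers; fewer than two regions: all typical.
#'
#' @param stitched A scored `"stitched_enhancers"` (see
#'   [score_stitched()]).
#' @return The object with an `is_super` column and a `cutoff_signal`
#'   element (NA when no cutoff was found).
#' @export
call_supers <- function(stitched) {
  stopifnot(inherits(stitched, "stitched_enhancers"))
  if (is.null(stitched$regions$signal))
    stop("regions are unscored; run score_stitched() first")
  sig <- stitched$regions$signal
  n <- length(sig)
  if (n < 2L) {
    message("fewer than 2 stitched regions; all typical")
    stitched$regions$is_super <- rep(FALSE, n)
    stitched$cutoff_signal <- NA_real_
    return(stitched)
  }
  y <- sort(sig)
  i <- .tangent_cutoff_index(y)
  cutoff <- if (is.na(i)) NA_real_ else y[i]
  stitched$regions$is_super <- if (is.na(cutoff)) rep(FALSE, n)
                               else sig > cutoff
  stitched$cutoff_signal <- cutoff
  stitched
}

#' Export the ranked enhancer table and super-enhancer BED
#'
#' @param stitched A called `"stitched_enhancers"`.
#' @param tsv_path Ranked-table TSV path (NULL to skip).
#' @param bed_path BED6 path for super-enhancers only (NULL to skip).
#' @return `stitched`, invisibly.
#' @export
write_enhancer_table <- function(stitched, tsv_path = NULL,
                                 bed_path = NULL) {
  reg <- stitched$regions
  if (!is.null(tsv_path)) {
    utils::write.table(reg[order(-reg$rank), ], tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed_path)) {
    sup <- reg[reg$is_super, , drop = FALSE]
    bed <- .new_peaks(sup$chrom, sup$start, sup$end,
                      paste0("SE_", sup$region_id),
                      score = sup$signal, strand = ".")
    write_peaks(bed, bed_path, format = "BED6")
  }
  invisible(stitched)
}
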