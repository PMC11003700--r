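## Binned signal quantification around peak centers. Bin values are the
## per-base mean of the coverage track over the bin, so a track that is
## already normalized (e.g. RPKM bedGraph) yields matrices in the same
## units. The peak-center "accumulated" score is the sum of bin means.

#' Anchor position of each peak
#'
#' The called summit when present, otherwise the interval midpoint
#' `floor((start + end) / 2)`.
#'
#' @param peaks A peak data frame.
#' @return Numeric vector of anchor base positions.
#' @export
peak_anchor <- function(peaks) {
  validate_peaks(peaks)
  ifelse(!is.na(peaks$summit_offset),
         peaks$start + peaks$summit_offset,
         floor((peaks$start + peaks$end) / 2))
}

#' Reads per kilobase per million mapped reads
#'
#' `raw_count / ((region_len_bp / 1000) * (total_reads / 1e6))`.
#'
#' @param raw_count Read (or signal) count in the region.
#' @param region_len_bp Region length in bp (> 0).
#' @param total_reads Library size (> 0).
#' @return RPKM value(s); vectorized over `raw_count`/`region_len_bp`.
#' @export
#' @examples
#' rpkm_value(50, 100, 1e7)  # 50
rpkm_value <- function(raw_count, region_len_bp, total_reads) {
  if (any(region_len_bp <= 0)) stop("region length must be positive")
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  raw_count / ((region_len_bp / 1000) * (total_reads / 1e6))
}

## Internal: prefix-integral machinery for one chromosome's steps.
## Returns a function F(p) = integral of the step value over [0, p),
## vectorized over p; value is 0 in gaps and outside the steps.
.step_integral_fun <- function(df) {
  if (nrow(df) == 0L) return(function(p) numeric(length(p)))
  w <- df$end - df$start
  cum <- c(0, cumsum(df$value * w))
  function(p) {
    i <- findInterval(p, df$start)
    out <- numeric(length(p))
    hit <- i > 0L
    if (any(hit)) {
      ii <- i[hit]
      out[hit] <- cum[ii] + df$value[ii] *
        pmin(pmax(p[hit] - df$start[ii], 0), w[ii])
    }
    out
  }
}

## Integral of a track over [start, end) intervals on one chromosome.
.track_interval_sum <- function(track, chrom, start, end) {
  df <- track$steps[[chrom]]
  if (is.null(df)) return(numeric(length(start)))
  f <- .step_integral_fun(df)
  f(end) - f(start)
}

#' Compute a binned signal matrix around peak centers
#'
#' For each peak, bins of `bin_size` bp tile
#' `[anchor - flank, anchor + flank)`; a bin's value is the per-base mean
#' of the track over the bin. Flanks extending past position 0 or past the
#' covered region contribute 0, so all rows have equal width. Peaks on
#' chromosomes absent from the track get an all-zero row with a warning.
#'
#' @param track A `"coverage_track"`.
#' @param peaks Peak data frame.
#' @param flank Half-width in bp (default 3000); must be a multiple of
#'   `bin_size`.
#' @param bin_size Bin width in bp (default 10).
#' @param normalize `"none"` (default; track units pass through) or
#'   `"rpkm"` (bin sums rescaled by bin length and the track's
#'   `total_reads`).
#' @return Object of class `"signal_matrix"`: a list with `values`
#'   (peaks x bins), `peak_ids`, `bin_size`, `flank`, `anchor`, `units`.
#' @export
compute_matrix <- function(track, peaks, flank = 3000, bin_size = 10,
                           normalize = c("none", "rpkm")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(track, "coverage_track"))
  validate_peaks(peaks)
  if (flank %% bin_size != 0) stop("flank must be a multiple of bin_size")
  nbins <- as.integer(2 * flank / bin_size)
  n <- nrow(peaks)
  values <- matrix(0, nrow = n, ncol = nbins)
  if (n > 0L) {
    anchors <- peak_anchor(peaks)
    unknown <- !(peaks$chrom %in% names(track$steps))
    if (any(unknown))
      warning("peak(s) on chromosome(s) absent from track: ",
              paste(unique(peaks$chrom[unknown]), collapse = ", "),
              "; rows set to zero")
    for (ch in unique(peaks$chrom[!unknown])) {
      idx <- which(peaks$chrom == ch)
      f <- .step_integral_fun(track$steps[[ch]])
      for (i in idx) {
        edges <- anchors[i] - flank + bin_size * (0:nbins)
        values[i, ] <- diff(f(pmax(edges, 0))) / bin_size
      }
    }
  }
  units <- "track"
  if (normalize == "rpkm") {
    values <- rpkm_value(values * bin_size, bin_size, track$total_reads)
    units <- "RPKM"
  }
  mids <- seq(-flank + bin_size / 2, flank - bin_size / 2, by = bin_size)
  dimnames(values) <- list(peaks$name, mids)
  structure(list(values = values, peak_ids = peaks$name,
                 bin_size = bin_size, flank = flank,
                 anchor = "peak_center", units = units),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("Signal matrix:", nrow(x$values), "peaks x", ncol(x$values),
      "bins (", x$bin_size, "bp bins, +-", x$flank, "bp around",
      x$anchor, "), units:", x$units, "\n")
  invisible(x)
}

#' Accumulated signal at the peak center
#'
#' Sum of bin values within `+-center_window` of the anchor (100 bins at
#' the 10 bp / 500 bp defaults).
#'
#' @param mat A `"signal_matrix"`.
#' @param center_window Half-width in bp; must be a multiple of the matrix
#'   bin size and at most the flank.
#' @return Named numeric vector, one score per peak.
#' @export
peak_center_score <- function(mat, center_window = 500) {
  stopifnot(inherits(mat, "signal_matrix"))
  if (center_window %% mat$bin_size != 0)
    stop("center_window must be a multiple of the bin size")
  if (center_window > mat$flank)
    stop("center_window exceeds the matrix flank")
  nside <- mat$flank / mat$bin_size
  w <- center_window / mat$bin_size
  cols <- (nside - w + 1L):(nside + w)
  out <- rowSums(mat$values[, cols, drop = FALSE])
  names(out) <- mat$peak_ids
  out
}

#' Metagene profile: per-bin mean over peaks
#'
#' @param mat A `"signal_matrix"` with at least one row.
#' @return Object of class `"metagene_profile"` with `positions` (bin
#'   midpoints relative to the anchor), `mean_signal`, `n_peaks`.
#' @export
metagene <- function(mat) {
  stopifnot(inherits(mat, "signal_matrix"))
  if (nrow(mat$values) == 0L)
    stop("metagene of an empty matrix is undefined")
  structure(list(positions = as.numeric(colnames(mat$values)),
                 mean_signal = colMeans(mat$values),
                 n_peaks = nrow(mat$values)),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("Metagene profile over", x$n_peaks, "peaks,",
      length(x$positions), "bins; summit mean:",
      format(mean(x$mean_signal[order(abs(x$positions))[1:2]])), "\n")
  invisible(x)
}

#' @export
plot.metagene_profile <- function(x, ..., xlab = "distance from peak center (bp)",
                                  ylab = "mean signal", type = "l") {
  graphics::plot(x$positions, x$mean_signal, type = type, xlab = xlab,
                 ylab = ylab, ...)
  invisible(x)
}

#' Percent signal change at the profile summit
#'
#' The summit value of a profile is the mean of its two central bins; the
#' change is `(1 - kd / ctrl) * 100`, so a positive value is a percent
#' decrease after knockdown.
#'
#' @param profile_ctrl,profile_kd `"metagene_profile"` objects on the same
#'   bin grid.
#' @return Percent decrease (negative = increase).
#' @export
summit_change <- function(profile_ctrl, profile_kd) {
  stopifnot(inherits(profile_ctrl, "metagene_profile"),
            inherits(profile_kd, "metagene_profile"))
  if (length(profile_ctrl$mean_signal) != length(profile_kd$mean_signal))
    stop("profiles have different shapes")
  central <- function(p) {
    o <- order(abs(p$positions))[1:2]
    mean(p$mean_signal[o])
  }
  s_ctrl <- central(profile_ctrl)
  if (s_ctrl <= 0) stop("control summit signal must be positive")
  (1 - central(profile_kd) / s_ctrl) * 100
}

#' Export a signal matrix as TSV
#'
#' Header row holds bin midpoints relative to the anchor; first column the
#' peak ids.
#'
#' @param mat A `"signal_matrix"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(mat, path) {
  df <- data.frame(peak_id = mat$peak_ids, mat$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a metagene profile as 2-column TSV
#' @param profile A `"metagene_profile"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(data.frame(position = profile$positions,
                                mean_signal = profile$mean_signal),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
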