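#' Analysis configuration
#'
#' Collects every numeric threshold used across the pipeline in one
#' auditable place. Defaults are the values used throughout the analyses
#' this package implements: the 1.5-fold / padj 0.05 differential-expression
#' cut, the -1 kb..+100 bp promoter window, the 5 kb TSS-proximity bin,
#' +-3 kb / 10 bp signal matrices with a +-500 bp peak-center window,
#' two-way k-means segmentation, 12.5 kb super-enhancer stitching with a
#' 2.5 kb TSS exclusion, the 1.2x / 1.1x occupancy-change bins, and the
#' (-10, 10] additive Bliss band.
#'
#' @param de_fold_threshold Linear fold-change magnitude above which a gene
#'   is called differentially expressed (default 1.5).
#' @param de_padj_threshold Adjusted p-value below which a gene is called
#'   differentially expressed (default 0.05).
#' @param promoter_upstream,promoter_downstream Promoter window extent in bp
#'   upstream/downstream of the TSS (defaults 1000 and 100).
#' @param tss_near_bin Distance in bp defining "near the TSS" for
#'   distance-distribution reporting (default 5000).
#' @param matrix_flank Half-width in bp of signal matrices around peak
#'   centers (default 3000).
#' @param matrix_bin Bin size in bp for signal matrices (default 10).
#' @param center_window Half-width in bp of the peak-center scoring window
#'   (default 500, i.e. 1000 bp total).
#' @param cluster_k Number of k-means clusters for chromatin-state
#'   segmentation (default 2).
#' @param stitch_distance Maximum gap in bp for stitching enhancer
#'   constituents (default 12500).
#' @param tss_exclusion Minimum distance in bp from any TSS for a peak to
#'   count as distal in super-enhancer calling (default 2500).
#' @param occupancy_change_fold Fold change beyond which an occupancy change
#'   is called up/down (default 1.2).
#' @param occupancy_stable_fold Fold change within which occupancy is called
#'   stable (default 1.1; must be < `occupancy_change_fold`).
#' @param synergy_additive_band Two-element numeric; average Bliss scores in
#'   `(band[1], band[2]]` are additive (default `c(-10, 10)`).
#' @param random_seed Integer seed used by seeded operations (default 1).
#'
#' @return A list of class `"analysis_config"`.
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$stitch_distance
analysis_config <- function(de_fold_threshold = 1.5,
                            de_padj_threshold = 0.05,
                            promoter_upstream = 1000,
                            promoter_downstream = 100,
                            tss_near_bin = 5000,
                            matrix_flank = 3000,
                            matrix_bin = 10,
                            center_window = 500,
                            cluster_k = 2,
                            stitch_distance = 12500,
                            tss_exclusion = 2500,
                            occupancy_change_fold = 1.2,
                            occupancy_stable_fold = 1.1,
                            synergy_additive_band = c(-10, 10),
                            random_seed = 1L) {
  cfg <- list(
    de_fold_threshold = de_fold_threshold,
    de_padj_threshold = de_padj_threshold,
    promoter_upstream = promoter_upstream,
    promoter_downstream = promoter_downstream,
    tss_near_bin = tss_near_bin,
    matrix_flank = matrix_flank,
    matrix_bin = matrix_bin,
    center_window = center_window,
    cluster_k = cluster_k,
    stitch_distance = stitch_distance,
    tss_exclusion = tss_exclusion,
    occupancy_change_fold = occupancy_change_fold,
    occupancy_stable_fold = occupancy_stable_fold,
    synergy_additive_band = synergy_additive_band,
    random_seed = as.integer(random_seed)
  )
  dists <- c("promoter_upstream", "promoter_downstream", "tss_near_bin",
             "matrix_flank", "matrix_bin", "center_window",
             "stitch_distance", "tss_exclusion")
  for (d in dists) {
    if (!is.numeric(cfg[[d]]) || length(cfg[[d]]) != 1L || cfg[[d]] <= 0)
      stop("config field '", d, "' must be a single positive number")
  }
  if (cfg$matrix_flank %% cfg$matrix_bin != 0)
    stop("matrix_flank must be divisible by matrix_bin")
  if (cfg$occupancy_stable_fold >= cfg$occupancy_change_fold)
    stop("occupancy_stable_fold must be smaller than occupancy_change_fold")
  if (length(cfg$synergy_additive_band) != 2L ||
      diff(cfg$synergy_additive_band) <= 0)
    stop("synergy_additive_band must be an increasing pair")
  class(cfg) <- "analysis_config"
  cfg
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
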