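## Chromatin-state segmentation of TF peaks: k-means over standardized
## multi-mark signal matrices, then mark-semantics labeling (high
## H3K4me3:H3K4me1 ratio = promoter-like).

#' Build a per-peak feature table from multiple mark matrices
#'
#' Concatenates the binned rows of each mark's signal matrix, with each
#' mark's block standardized column-wise to zero mean / unit variance
#' across peaks (zero-variance columns become all-zero). Standardizing per
#' mark puts marks with different dynamic ranges on a common scale before
#' clustering.
#'
#' @param matrices Named list of `"signal_matrix"` objects sharing an
#'   identical peak order.
#' @return Numeric matrix `n_peaks x (n_marks * n_bins)` with an attribute
#'   `feature_description`.
#' @export
build_feature_table <- function(matrices) {
  if (length(matrices) == 0L) stop("no matrices supplied")
  ids <- matrices[[1]]$peak_ids
  for (m in matrices) {
    if (!inherits(m, "signal_matrix")) stop("inputs must be signal matrices")
    if (!identical(m$peak_ids, ids))
      stop("matrices do not share an identical peak order")
  }
  blocks <- lapply(names(matrices), function(nm) {
    v <- matrices[[nm]]$values
    mu <- colMeans(v)
    sdv <- apply(v, 2, stats::sd)
    z <- sweep(v, 2, mu, "-")
    z <- sweep(z, 2, ifelse(sdv > 0, sdv, 1), "/")
    z[, sdv == 0] <- 0
    colnames(z) <- paste0(nm, ".", seq_len(ncol(z)))
    z
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- ids
  attr(out, "feature_description") <-
    paste0("standardized per-mark bins: ",
           paste(names(matrices), collapse = ", "))
  out
}

## Deterministic initialization: seeded pick of the first center, then
## greedy farthest-point for the rest.
.farthest_point_init <- function(x, k, seed) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- withr_seed_sample(seed, n)
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2, x[idx[1], ], "-")^2)
    for (j in 2:k) {
      idx[j] <- which.max(d2)
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j], ], "-")^2))
    }
  }
  idx
}

## Draw a single index in 1..n from a local RNG state (leaves the global
## RNG untouched).
withr_seed_sample <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample.int(n, 1L)
}

#' Segment peaks by k-means on a feature table
#'
#' Deterministic given `seed`: the first center is a seeded draw, the
#' remaining centers are greedy farthest points, and Lloyd iterations run
#' to convergence from there. Degenerate inputs where fewer than `k`
#' distinct rows exist are assigned entirely to cluster 1.
#'
#' @param features Matrix from [build_feature_table()] (rows = peaks).
#' @param k Number of clusters (default 2).
#' @param seed Integer seed for the initialization.
#' @return Object of class `"cluster_assignment"`: `peak_ids`, `cluster`
#'   (1..k per peak), `withinss`, `labels` (NULL until
#'   [label_clusters()]), `feature_description`.
#' @export
kmeans_segment <- function(features, k = 2, seed = 1) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < k) stop("fewer peaks (", n, ") than clusters (", k, ")")
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  uniq <- unique(features)
  if (k == 1L || nrow(uniq) < k) {
    cluster <- rep(1L, n)
    withinss <- sum(sweep(features, 2, colMeans(features), "-")^2)
    if (k > 1L && nrow(uniq) < k)
      warning("fewer than k distinct feature rows; all peaks in cluster 1")
  } else {
    centers <- features[.farthest_point_init(features, k, seed), ,
                        drop = FALSE]
    km <- suppressWarnings(
      stats::kmeans(features, centers = centers, iter.max = 100,
                    algorithm = "Lloyd"))
    cluster <- km$cluster
    withinss <- km$withinss
  }
  structure(list(peak_ids = ids, cluster = as.integer(cluster), k = k,
                 withinss = withinss, labels = NULL,
                 feature_description =
                   attr(features, "feature_description")),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment:", length(x$peak_ids), "peaks in", x$k,
      "cluster(s)\n")
  tab <- table(x$cluster)
  for (cl in names(tab)) {
    lab <- if (!is.null(x$labels)) paste0(" (", x$labels[[cl]], ")") else ""
    cat("  cluster ", cl, lab, ": ", tab[[cl]], " peaks\n", sep = "")
  }
  invisible(x)
}

#' Label clusters as promoter-like or enhancer-like
#'
#' Uses mark semantics: for each cluster the ratio
#' `mean(H3K4me3 score) / (mean(H3K4me1 score) + eps)` is computed over
#' its peaks; with k = 2 the higher-ratio cluster is `promoter_like` and
#' the other `enhancer_like`. For k > 2, the top-ratio cluster is
#' promoter-like, the bottom enhancer-like, the rest (and any ties)
#' `unlabeled`.
#'
#' @param assignment A `"cluster_assignment"`.
#' @param center_scores Named list with per-peak peak-center scores for at
#'   least `H3K4me3` and `H3K4me1` (see [peak_center_score()]), in the
#'   assignment's peak order.
#' @param eps Pseudocount guarding against an all-zero H3K4me1 cluster.
#' @return The assignment with a `labels` element (cluster -> label).
#' @export
label_clusters <- function(assignment, center_scores, eps = 1e-8) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  for (mark in c("H3K4me3", "H3K4me1")) {
    if (is.null(center_scores[[mark]]))
      stop("center_scores must contain '", mark, "'")
    if (length(center_scores[[mark]]) != length(assignment$peak_ids))
      stop("score length for '", mark, "' does not match the peak count")
  }
  cl <- assignment$cluster
  clusters <- sort(unique(cl))
  ratio <- vapply(clusters, function(g) {
    mean(center_scores$H3K4me3[cl == g]) /
      (mean(center_scores$H3K4me1[cl == g]) + eps)
  }, 0)
  labels <- stats::setNames(rep("unlabeled", length(clusters)),
                            as.character(clusters))
  if (anyDuplicated(ratio) == 0L) {
    labels[which.max(ratio)] <- "promoter_like"
    labels[which.min(ratio)] <- "enhancer_like"
  }
  assignment$labels <- as.list(labels)
  assignment$cluster_ratio <- stats::setNames(ratio,
                                              as.character(clusters))
  assignment
}

#' Active-enhancer peak filter
#'
#' Active enhancers are H3K27ac peaks that do not overlap (by >= 1 bp,
#' half-open coordinates) any H3K4me3 peak.
#'
#' @param h3k27ac_peaks,h3k4me3_peaks Peak data frames.
#' @return The subset of `h3k27ac_peaks` with no H3K4me3 overlap.
#' @export
active_enhancer_peaks <- function(h3k27ac_peaks, h3k4me3_peaks) {
  validate_peaks(h3k27ac_peaks)
  validate_peaks(h3k4me3_peaks)
  if (nrow(h3k27ac_peaks) == 0L || nrow(h3k4me3_peaks) == 0L)
    return(h3k27ac_peaks)
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(.peaks_gr(h3k27ac_peaks),
                                 .peaks_gr(h3k4me3_peaks),
                                 minoverlap = 1L))
  out <- h3k27ac_peaks[hits == 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a cluster assignment as TSV (and optional BED)
#'
#' @param assignment A labeled or unlabeled `"cluster_assignment"`.
#' @param path TSV output path (peak_id, cluster, label).
#' @param peaks Optional peak data frame (assignment order) to also write
#'   a BED6 with the label in the name field.
#' @param bed_path BED output path, used when `peaks` is given.
#' @return `path`, invisibly.
#' @export
write_cluster_assignment <- function(assignment, path, peaks = NULL,
                                     bed_path = NULL) {
  lab <- if (is.null(assignment$labels)) rep("unlabeled", assignment$k)
         else unlist(assignment$labels)
  df <- data.frame(peak_id = assignment$peak_ids,
                   cluster = assignment$cluster,
                   label = lab[as.character(assignment$cluster)])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(peaks) && !is.null(bed_path)) {
    bed <- peaks
    bed$name <- paste0(df$peak_id, "|", df$label)
    write_peaks(bed, bed_path, format = "BED6")
  }
  invisible(path)
}
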