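## Two-set peak overlap with min-linkage component counting: build the
## bipartite overlap graph, take connected components, and count the
## overlap as sum over components of min(|A_i|, |B_i|) -- the "min"
## connected-peaks semantics of ChIP peak-overlap tools.

## Union-find over 1..n.
.uf_new <- function(n) seq_len(n)
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Overlap analysis between two peak sets
#'
#' Builds a bipartite graph with an edge whenever a peak of A and a peak
#' of B share at least `min_overlap_bp` bases, takes its connected
#' components, and reports `n_overlap_min`, the sum over components of
#' `min(|A_i|, |B_i|)`. Peaks with no overlap partner are unique to their
#' side.
#'
#' @param peaks_a,peaks_b Peak data frames.
#' @param min_overlap_bp Minimum shared bases for an edge (default 1).
#' @return Object of class `"overlap_result"`: `n_a`, `n_b`, `components`
#'   (list of `list(a = , b = )` index vectors into the inputs),
#'   `n_overlap_min`, `unique_a`, `unique_b`, plus the input peak names.
#' @export
find_overlaps <- function(peaks_a, peaks_b, min_overlap_bp = 1) {
  validate_peaks(peaks_a)
  validate_peaks(peaks_b)
  na <- nrow(peaks_a); nb <- nrow(peaks_b)
  comps <- list()
  if (na > 0L && nb > 0L) {
    ## disjoint chromosome sets between A and B are legitimate input
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(.peaks_gr(peaks_a),
                                  .peaks_gr(peaks_b),
                                  minoverlap = as.integer(min_overlap_bp)))
    qa <- S4Vectors::queryHits(hits)
    qb <- S4Vectors::subjectHits(hits) + na   # B nodes offset by n_a
    parent <- .uf_new(na + nb)
    for (e in seq_along(qa)) {
      ra <- .uf_find(parent, qa[e])
      rb <- .uf_find(parent, qb[e])
      if (ra != rb) parent[rb] <- ra
    }
    touched <- unique(c(qa, qb))
    if (length(touched)) {
      roots <- vapply(touched, function(i) .uf_find(parent, i), 0L)
      for (grp in split(touched, roots)) {
        comps[[length(comps) + 1L]] <-
          list(a = sort(grp[grp <= na]), b = sort(grp[grp > na] - na))
      }
    }
  }
  n_min <- sum(vapply(comps, function(cp) min(length(cp$a),
                                              length(cp$b)), 0))
  in_a <- sum(vapply(comps, function(cp) length(cp$a), 0L))
  in_b <- sum(vapply(comps, function(cp) length(cp$b), 0L))
  structure(list(n_a = na, n_b = nb, components = comps,
                 n_overlap_min = n_min,
                 unique_a = na - in_a, unique_b = nb - in_b,
                 names_a = peaks_a$name, names_b = peaks_b$name),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Overlap result: |A| =", x$n_a, ", |B| =", x$n_b, ";",
      length(x$components), "component(s); min-count overlap =",
      x$n_overlap_min, "; unique:", x$unique_a, "A,", x$unique_b, "B\n")
  invisible(x)
}

#' Fraction of one side's peaks that overlap the other set
#'
#' @param result An `"overlap_result"`.
#' @param side `"A"` or `"B"`.
#' @return Fraction of that side's peaks belonging to any component.
#' @export
overlap_fraction <- function(result, side = c("A", "B")) {
  side <- match.arg(side)
  n <- if (side == "A") result$n_a else result$n_b
  if (n == 0L) stop("side ", side, " is empty")
  key <- tolower(side)
  sum(vapply(result$components, function(cp) length(cp[[key]]), 0L)) / n
}

#' Per-tag counts among overlapped peaks
#'
#' Tags (e.g. promoter / enhancer / super_enhancer membership) are counted
#' over the overlapped peaks of one side (those belonging to a component);
#' a peak may carry several tags, so percentages can total more than 100.
#'
#' @param result An `"overlap_result"`.
#' @param categories Data frame `peak_id`, `tag` (one row per tag a peak
#'   carries; peaks may appear multiple times or not at all).
#' @param side Side whose overlapped peaks are counted (default `"A"`).
#' @return Data frame `tag`, `count`, `percentage` (1 decimal, of the
#'   overlapped-peak count); attribute `n_overlapped`.
#' @export
overlap_by_category <- function(result, categories, side = c("A", "B")) {
  side <- match.arg(side)
  key <- tolower(side)
  nm <- if (side == "A") result$names_a else result$names_b
  idx <- unlist(lapply(result$components, `[[`, key))
  n_over <- length(idx)
  if (n_over == 0L) stop("no overlapped peaks to categorize")
  over_ids <- nm[idx]
  tags <- unique(categories$tag)
  counts <- vapply(tags, function(tg) {
    length(intersect(over_ids, categories$peak_id[categories$tag == tg]))
  }, 0L)
  out <- data.frame(tag = tags, count = as.integer(counts),
                    percentage = round(100 * counts / n_over, 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_overlapped") <- n_over
  out
}

#' Export an overlap result
#'
#' Writes a TSV of components (component id, side, peak name) and a JSON
#' summary of the counts.
#'
#' @param result An `"overlap_result"`.
#' @param tsv_path,json_path Output paths (either may be NULL to skip).
#' @return `result`, invisibly.
#' @export
write_overlap_result <- function(result, tsv_path = NULL,
                                 json_path = NULL) {
  if (!is.null(tsv_path)) {
    rows <- do.call(rbind, lapply(seq_along(result$components), function(i) {
      cp <- result$components[[i]]
      data.frame(component = i,
                 side = c(rep("A", length(cp$a)), rep("B", length(cp$b))),
                 peak = c(result$names_a[cp$a], result$names_b[cp$b]))
    }))
    if (is.null(rows)) rows <- data.frame(component = integer(),
                                          side = character(),
                                          peak = character())
    utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(n_a = result$n_a, n_b = result$n_b,
                              n_components = length(result$components),
                              n_overlap_min = result$n_overlap_min,
                              unique_a = result$unique_a,
                              unique_b = result$unique_b),
                         json_path, auto_unbox = TRUE)
  }
  invisible(result)
}
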