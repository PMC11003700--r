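## The integrative step: cross element-classified TF binding with
## differential expression into regulatory quadrants, bin cofactor
## occupancy changes between conditions, and compare peak-class
## distributions between conditions.

#' Classify differential-expression direction
#'
#' `up` when `fold_change >= fold_threshold` and `padj < padj_threshold`;
#' `down` when `fold_change <= -fold_threshold` and
#' `padj < padj_threshold`; otherwise `not_de`. Fold comparisons are
#' inclusive at the boundary, the padj comparison strict.
#'
#' @param fold_change Signed linear fold changes (see [read_de_table()]).
#' @param padj Adjusted p-values.
#' @param fold_threshold,padj_threshold Cutoffs (defaults 1.5, 0.05).
#' @return Character vector in `{"up", "down", "not_de"}`.
#' @export
classify_de <- function(fold_change, padj, fold_threshold = 1.5,
                        padj_threshold = 0.05) {
  ifelse(padj < padj_threshold & fold_change >= fold_threshold, "up",
         ifelse(padj < padj_threshold & fold_change <= -fold_threshold,
                "down", "not_de"))
}

#' Build the regulatory-quadrant summary
#'
#' Crosses bound element classes with DE direction. A gene bound at both a
#' promoter and an enhancer contributes to both element tallies;
#' percentages are within each element class over its (up + down) DE-bound
#' genes, reported to 1 decimal, and are NA when a class has no DE bound
#' genes.
#'
#' @param de DE data frame (see [read_de_table()]).
#' @param gene_to_elements Data frame `gene_id`, `element_class`
#'   ("promoter"/"enhancer"), one row per bound element class per gene
#'   (derive it from annotated, clustered peaks).
#' @param fold_threshold,padj_threshold Passed to [classify_de()].
#' @return Object of class `"quadrant_summary"`: `counts` (data frame
#'   `element_class`, `direction`, `count`, `percentage`), `n_de`,
#'   `n_de_bound`, `n_dual_bound`, `n_unbound_de`, `n_bound_not_de`, and
#'   `calls` (per-gene data frame `gene_id`, `de_direction`,
#'   `bound_promoter`, `bound_enhancer`, `quadrants`).
#' @export
build_quadrants <- function(de, gene_to_elements, fold_threshold = 1.5,
                            padj_threshold = 0.05) {
  de <- validate_de_table(de)
  dirn <- classify_de(de$fold_change, de$padj, fold_threshold,
                      padj_threshold)
  g2e <- unique(gene_to_elements[c("gene_id", "element_class")])
  if (!all(g2e$element_class %in% c("promoter", "enhancer")))
    stop("element_class must be 'promoter' or 'enhancer'")
  bound_prom <- de$gene_id %in% g2e$gene_id[g2e$element_class == "promoter"]
  bound_enh <- de$gene_id %in% g2e$gene_id[g2e$element_class == "enhancer"]
  is_de <- dirn != "not_de"
  counts <- expand.grid(element_class = c("promoter", "enhancer"),
                        direction = c("down", "up"),
                        stringsAsFactors = FALSE)
  counts$count <- mapply(function(ec, dr) {
    bound <- if (ec == "promoter") bound_prom else bound_enh
    sum(bound & dirn == dr)
  }, counts$element_class, counts$direction)
  for (ec in c("promoter", "enhancer")) {
    sel <- counts$element_class == ec
    tot <- sum(counts$count[sel])
    counts$percentage[sel] <- if (tot > 0)
      round(100 * counts$count[sel] / tot, 1) else NA_real_
  }
  quadrants <- mapply(function(p, e, d) {
    if (d == "not_de") {
      if (p || e) "bound_not_de" else "not_de_unbound"
    } else if (!p && !e) "unbound_de"
    else paste(c(if (p) paste0("promoter_", d),
                 if (e) paste0("enhancer_", d)), collapse = ";")
  }, bound_prom, bound_enh, dirn)
  calls <- data.frame(gene_id = de$gene_id, de_direction = dirn,
                      bound_promoter = bound_prom,
                      bound_enhancer = bound_enh,
                      quadrants = quadrants, stringsAsFactors = FALSE)
  structure(list(counts = counts,
                 n_de = sum(is_de),
                 n_de_bound = sum(is_de & (bound_prom | bound_enh)),
                 n_dual_bound = sum(is_de & bound_prom & bound_enh),
                 n_unbound_de = sum(is_de & !bound_prom & !bound_enh),
                 n_bound_not_de = sum(!is_de & (bound_prom | bound_enh)),
                 calls = calls),
            class = "quadrant_summary")
}

#' @export
print.quadrant_summary <- function(x, ...) {
  cat("Regulatory quadrants (", x$n_de_bound, "of", x$n_de,
      "DE genes bound;", x$n_dual_bound, "bound at both element types)\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Bin occupancy changes between conditions
#'
#' With ratio `r = signal_kd / signal_ctrl`: `down` when `r <= 1/1.2`,
#' `up` when `r >= 1.2`, `stable` when `1/1.1 < r < 1.1`; the two
#' remaining bands `(1/1.2, 1/1.1]` and `[1.1, 1.2)` are genuinely
#' uncovered by the three rules and are reported `unclassified` rather
#' than silently absorbed.
#'
#' @param signal_ctrl,signal_kd Peak-center scores per peak (control must
#'   be positive).
#' @param change_fold Up/down threshold (default 1.2).
#' @param stable_fold Stable band half-width (default 1.1).
#' @return Character vector in `{"down", "stable", "up", "unclassified"}`.
#' @export
bin_occupancy_change <- function(signal_ctrl, signal_kd,
                                 change_fold = 1.2, stable_fold = 1.1) {
  if (any(signal_ctrl <= 0)) stop("control signal must be positive")
  r <- signal_kd / signal_ctrl
  ifelse(r <= 1 / change_fold, "down",
         ifelse(r >= change_fold, "up",
                ifelse(r > 1 / stable_fold & r < stable_fold, "stable",
                       "unclassified")))
}

#' Occupancy-change table for a peak set
#'
#' @param peak_ids Peak identifiers.
#' @param signal_ctrl,signal_kd Peak-center scores in the two conditions.
#' @inheritParams bin_occupancy_change
#' @return Data frame `peak_id`, `signal_ctrl`, `signal_kd`, `category`.
#' @export
occupancy_table <- function(peak_ids, signal_ctrl, signal_kd,
                            change_fold = 1.2, stable_fold = 1.1) {
  data.frame(peak_id = peak_ids, signal_ctrl = signal_ctrl,
             signal_kd = signal_kd,
             category = bin_occupancy_change(signal_ctrl, signal_kd,
                                             change_fold, stable_fold),
             stringsAsFactors = FALSE)
}

#' Chi-square comparison of promoter/enhancer peak distributions
#'
#' Pearson chi-square on the 2x2 table of (promoter, enhancer) counts in
#' two conditions, df = 1, no continuity correction.
#'
#' @param counts_ctrl,counts_kd Length-2 numeric vectors
#'   `(n_promoter, n_enhancer)` per condition.
#' @return List `statistic`, `df`, `p_value`.
#' @export
compare_class_distribution <- function(counts_ctrl, counts_kd) {
  tab <- rbind(ctrl = counts_ctrl, kd = counts_kd)
  if (any(tab < 0)) stop("negative counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in the 2x2 table")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}
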