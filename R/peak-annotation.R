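## Positional peak annotation: exclusive promoter/distal assignment
## against strand-aware promoter windows, nearest-gene mapping, and
## distance-to-TSS reporting.

#' Strand-aware promoter window around each TSS
#'
#' For a + gene the window is `[tss - upstream, tss + downstream)`; for a
#' - gene it is mirrored about the TSS,
#' `[tss - downstream + 1, tss + upstream + 1)`. Windows are clipped at 0.
#'
#' @param genes Gene-model data frame (see [validate_genes()]).
#' @param upstream,downstream Window extent in bp (defaults 1000 / 100).
#' @return Data frame `gene_id`, `chrom`, `start`, `end`.
#' @export
#' @examples
#' g <- validate_genes(data.frame(gene_id = "g", chrom = "chr1",
#'                                strand = "+", start = 5000, end = 7000))
#' promoter_window(g)  # [4000, 5100)
promoter_window <- function(genes, upstream = 1000, downstream = 100) {
  genes <- validate_genes(genes)
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream + 1)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream + 1)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(start, 0), end = end,
             stringsAsFactors = FALSE)
}

## Signed anchor-to-TSS distance; positive = downstream of the TSS in the
## gene's orientation.
.signed_distance <- function(anchor, tss, strand) {
  d <- anchor - tss
  ifelse(strand == "-", -d, d)
}

#' Annotate peaks as promoter or distal with a nearest gene
#'
#' A peak is promoter-class when its interval overlaps any promoter window
#' by >= 1 bp; the assigned gene is then the overlapping-promoter gene
#' whose TSS is nearest the peak anchor, otherwise the nearest-TSS gene on
#' the peak's chromosome. The reported distance is anchor - TSS with the
#' sign flipped for minus-strand genes (negative = upstream). Peaks on a
#' chromosome with no genes are distal with NA gene and distance. Ties in
#' TSS distance break toward the smaller TSS coordinate, then gene_id, so
#' results do not depend on gene-list order.
#'
#' @param peaks Peak data frame.
#' @param genes Gene-model data frame (>= 1 gene).
#' @param upstream,downstream Promoter window extent (see
#'   [promoter_window()]).
#' @return Data frame `peak_id`, `element_class` ("promoter"/"distal"),
#'   `gene_id`, `distance_to_tss`.
#' @export
annotate_peaks <- function(peaks, genes, upstream = 1000,
                           downstream = 100) {
  validate_peaks(peaks)
  genes <- validate_genes(genes)
  if (nrow(genes) == 0L) stop("gene model is empty")
  ## deterministic gene ordering, so input order cannot matter
  genes <- genes[order(genes$chrom, genes$tss, genes$gene_id), ,
                 drop = FALSE]
  n <- nrow(peaks)
  anchors <- peak_anchor(peaks)
  out <- data.frame(peak_id = peaks$name,
                    element_class = rep("distal", n),
                    gene_id = rep(NA_character_, n),
                    distance_to_tss = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  prom <- promoter_window(genes, upstream, downstream)
  prom_gr <- GenomicRanges::GRanges(prom$chrom,
                                    IRanges::IRanges(prom$start + 1L,
                                                     prom$end))
  hits <- GenomicRanges::findOverlaps(.peaks_gr(peaks), prom_gr,
                                      minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (ch in unique(peaks$chrom)) {
    pidx <- which(peaks$chrom == ch)
    gsub_idx <- which(genes$chrom == ch)
    if (length(gsub_idx) == 0L) next
    tss <- genes$tss[gsub_idx]
    for (i in pidx) {
      over_genes <- sh[qh == i]
      if (length(over_genes) > 0L) {
        cand <- over_genes            # rows of `genes`
        out$element_class[i] <- "promoter"
      } else {
        cand <- gsub_idx
      }
      dd <- abs(anchors[i] - genes$tss[cand])
      best <- cand[order(dd, genes$tss[cand], genes$gene_id[cand])][1]
      out$gene_id[i] <- genes$gene_id[best]
      out$distance_to_tss[i] <- .signed_distance(anchors[i],
                                                 genes$tss[best],
                                                 genes$strand[best])
    }
  }
  out
}

#' Fractions of peaks near vs far from the TSS
#'
#' @param annotations Output of [annotate_peaks()] (>= 1 row); rows with
#'   NA distance are dropped.
#' @param near Distance cutoff in bp (default 5000).
#' @return List with `fraction_within` (|distance| <= near),
#'   `fraction_beyond`, and `n`.
#' @export
tss_distance_fractions <- function(annotations, near = 5000) {
  d <- annotations$distance_to_tss
  d <- d[!is.na(d)]
  if (length(d) == 0L) stop("no annotated distances")
  within <- mean(abs(d) <= near)
  list(fraction_within = within, fraction_beyond = 1 - within,
       n = length(d))
}

#' Counts and percentages per element class
#'
#' Percentages are reported to 1 decimal, `round(100 * count / total, 1)`.
#' Classes may overlap (a peak can carry both a promoter and an enhancer
#' tag under the overlap-reporting scheme), so percentages need not sum
#' to 100.
#'
#' @param x Either a named numeric vector of per-class counts, or an
#'   [annotate_peaks()] data frame (classes tabulated from
#'   `element_class`).
#' @param total Denominator (> 0); defaults to `nrow(x)` for a data frame.
#' @return Data frame `class`, `count`, `percentage`.
#' @export
#' @examples
#' class_fractions(c(promoter = 9299), 19707)  # 47.2
class_fractions <- function(x, total = NULL) {
  if (is.data.frame(x)) {
    counts <- table(x$element_class)
    counts <- stats::setNames(as.numeric(counts), names(counts))
    if (is.null(total)) total <- nrow(x)
  } else {
    counts <- x
    if (is.null(total)) stop("total is required for count input")
  }
  if (is.null(total) || total <= 0) stop("total must be positive")
  if (any(counts > total)) stop("count exceeds total")
  data.frame(class = names(counts), count = as.numeric(counts),
             percentage = round(100 * as.numeric(counts) / total, 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Export peak annotations as TSV
#' @param annotations Output of [annotate_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
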