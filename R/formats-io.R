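## On-disk formats. All genomic coordinates are BED-style: 0-based,
## half-open [start, end). Minus-strand TSSs are end - 1 in this convention.

#' Validate a peak data frame
#'
#' Peaks are plain data frames with columns `chrom`, `start`, `end`,
#' `name`, `score`, `strand` and `summit_offset` (NA when no summit was
#' called). `summit_offset` is measured in bp from `start` and must lie in
#' `[0, end - start)`.
#'
#' @param peaks A data frame of peaks.
#' @return The validated data frame, invisibly usable in pipelines.
#' @export
validate_peaks <- function(peaks) {
  req <- c("chrom", "start", "end", "name", "score", "strand",
           "summit_offset")
  miss <- setdiff(req, names(peaks))
  if (length(miss))
    stop("peak table is missing columns: ", paste(miss, collapse = ", "))
  if (any(is.na(peaks$chrom) | !nzchar(peaks$chrom)))
    stop("peak chrom must be non-empty")
  bad <- which(!(peaks$start >= 0 & peaks$start < peaks$end))
  if (length(bad))
    stop("invalid peak coordinates (need 0 <= start < end) at row ", bad[1])
  so <- peaks$summit_offset
  ok <- is.na(so) | (so >= 0 & so < peaks$end - peaks$start)
  if (!all(ok))
    stop("summit_offset outside [0, width) at row ", which(!ok)[1])
  peaks
}

.new_peaks <- function(chrom, start, end, name, score = 0, strand = ".",
                       summit_offset = NA_real_) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   name = as.character(name), score = as.numeric(score),
                   strand = as.character(strand),
                   summit_offset = as.numeric(summit_offset),
                   stringsAsFactors = FALSE)
  validate_peaks(df)
}

#' Read a BED6 or narrowPeak file
#'
#' @param path File path.
#' @param format `"narrowPeak"` (ENCODE 10-column; field 10 is the summit
#'   offset, -1 meaning absent) or `"BED6"`.
#' @return A peak data frame in file order (see [validate_peaks()]).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t200\tp1\t50\t.\t3.2\t7.1\t5.0\t40", tf)
#' read_peaks(tf)
read_peaks <- function(path, format = c("narrowPeak", "BED6")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  need <- if (format == "narrowPeak") 10L else 6L
  if (length(lines) == 0L) {
    return(.new_peaks(character(), numeric(), numeric(), character(),
                      numeric(), character(), numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < need))
    stop("malformed ", format, " line ", which(nf < need)[1], " in ", path,
         ": expected >= ", need, " fields")
  m <- do.call(rbind, lapply(fields, `[`, seq_len(need)))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric coordinate at line ",
         which(is.na(start) | is.na(end))[1], " in ", path)
  bad <- which(start >= end)
  if (length(bad))
    stop("start >= end at line ", bad[1], " in ", path)
  summit <- rep(NA_real_, length(lines))
  if (format == "narrowPeak") {
    s <- suppressWarnings(as.numeric(m[, 10]))
    summit <- ifelse(!is.na(s) & s >= 0, s, NA_real_)
  }
  .new_peaks(m[, 1], start, end, m[, 4],
             suppressWarnings(as.numeric(m[, 5])), m[, 6], summit)
}

#' Write peaks to BED6 or narrowPeak
#'
#' @param peaks A peak data frame.
#' @inheritParams read_peaks
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("narrowPeak", "BED6")) {
  format <- match.arg(format)
  validate_peaks(peaks)
  base <- cbind(peaks$chrom, format(peaks$start, scientific = FALSE,
                                    trim = TRUE),
                format(peaks$end, scientific = FALSE, trim = TRUE),
                peaks$name, as.character(peaks$score), peaks$strand)
  if (format == "narrowPeak") {
    summit <- ifelse(is.na(peaks$summit_offset), -1, peaks$summit_offset)
    base <- cbind(base, "0", "-1", "-1",
                  format(summit, scientific = FALSE, trim = TRUE))
  }
  writeLines(apply(base, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Construct a coverage track
#'
#' A coverage track holds, per chromosome, sorted non-overlapping
#' `(start, end, value)` steps plus the total mapped-read count of the
#' source library (used for RPKM scaling). Gaps between steps are implicit
#' zeros.
#'
#' @param steps Data frame with columns `chrom`, `start`, `end`, `value`.
#' @param total_reads Total mapped reads in the source library (> 0).
#' @param resolution_note Free-text provenance note.
#' @return An object of class `"coverage_track"`.
#' @export
coverage_track <- function(steps, total_reads, resolution_note = "") {
  req <- c("chrom", "start", "end", "value")
  miss <- setdiff(req, names(steps))
  if (length(miss))
    stop("track steps missing columns: ", paste(miss, collapse = ", "))
  if (!is.numeric(total_reads) || length(total_reads) != 1L ||
      total_reads <= 0)
    stop("total_reads must be a single positive number")
  if (any(steps$value < 0)) stop("negative coverage value")
  if (any(steps$start >= steps$end)) stop("step with start >= end")
  by_chrom <- split(steps[c("start", "end", "value")],
                    as.character(steps$chrom))
  by_chrom <- lapply(by_chrom, function(df) {
    df <- df[order(df$start, df$end), , drop = FALSE]
    if (nrow(df) > 1L && any(df$start[-1] < df$end[-nrow(df)]))
      stop("overlapping coverage steps")
    rownames(df) <- NULL
    df
  })
  structure(list(steps = by_chrom, total_reads = total_reads,
                 resolution_note = resolution_note),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("Coverage track:", sum(vapply(x$steps, nrow, 0L)), "steps on",
      length(x$steps), "chromosome(s);", format(x$total_reads),
      "total reads\n")
  invisible(x)
}

#' Read a 4-column bedGraph file into a coverage track
#'
#' @param path bedGraph path (chrom, start, end, value; no track line).
#' @inheritParams coverage_track
#' @return A `"coverage_track"`.
#' @export
read_bedgraph <- function(path, total_reads, resolution_note = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  coverage_track(df, total_reads, resolution_note)
}

#' Write a coverage track as bedGraph
#'
#' @param track A `"coverage_track"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  chroms <- names(track$steps)
  rows <- lapply(chroms, function(ch) {
    df <- track$steps[[ch]]
    if (nrow(df) == 0L) return(character())
    paste(ch, format(df$start, scientific = FALSE, trim = TRUE),
          format(df$end, scientific = FALSE, trim = TRUE),
          format(df$value, scientific = FALSE, trim = TRUE), sep = "\t")
  })
  writeLines(unlist(rows), path)
  invisible(path)
}

#' Read a gene model TSV
#'
#' Expected columns: `gene_id`, `chrom`, `strand` (+/-), `start`, `end`
#' (0-based half-open span). The TSS is derived from the strand: `start`
#' for + genes, `end - 1` for - genes.
#'
#' @param path TSV path with a header row.
#' @return Data frame with the input columns plus `tss`.
#' @export
read_gene_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_genes(df)
}

#' Validate a gene-model data frame (adds the `tss` column)
#' @param genes Data frame with `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @return The data frame with a `tss` column.
#' @export
validate_genes <- function(genes) {
  req <- c("gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(req, names(genes))
  if (length(miss))
    stop("gene model missing columns: ", paste(miss, collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (any(genes$start >= genes$end)) stop("gene with start >= end")
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes
}

#' Write a gene model TSV
#' @param genes Gene-model data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(genes, path) {
  utils::write.table(genes[c("gene_id", "chrom", "strand", "start", "end")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Expected columns: `gene_id`, `fold_change` (signed linear ratio;
#' positive x means x-fold up, negative -x means 1/x; no-change is encoded
#' +1, magnitudes below 1 are invalid), `padj` in \[0,1\], and
#' `mean_expr_cpm` (>= 0).
#'
#' @param path TSV path with header.
#' @return Validated data frame.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_de_table(df)
}

#' Validate a differential-expression data frame
#' @param de Data frame with `gene_id`, `fold_change`, `padj`,
#'   `mean_expr_cpm`.
#' @return The validated data frame.
#' @export
validate_de_table <- function(de) {
  req <- c("gene_id", "fold_change", "padj", "mean_expr_cpm")
  miss <- setdiff(req, names(de))
  if (length(miss))
    stop("DE table missing columns: ", paste(miss, collapse = ", "))
  if (any(abs(de$fold_change) < 1))
    stop("fold_change magnitude below 1 (encode no-change as +1)")
  if (any(de$padj < 0 | de$padj > 1)) stop("padj outside [0, 1]")
  if (any(de$mean_expr_cpm < 0)) stop("negative mean expression")
  de
}

#' Write a differential-expression TSV
#' @param de Validated DE data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de[c("gene_id", "fold_change", "padj",
                          "mean_expr_cpm")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a checkerboard dose matrix
#'
#' Viability is percent of the DMSO control; row 1 / column 1 hold the
#' single-agent doses (first dose 0 for each drug), so cell \[1,1\] is the
#' untreated control.
#'
#' @param drug_a_doses,drug_b_doses Strictly increasing dose vectors
#'   starting at 0. Drug A indexes rows, drug B columns.
#' @param viability Numeric matrix `length(a) x length(b)` of % viability.
#' @return Object of class `"dose_matrix"`.
#' @export
dose_matrix <- function(drug_a_doses, drug_b_doses, viability) {
  viability <- as.matrix(viability)
  if (nrow(viability) != length(drug_a_doses) ||
      ncol(viability) != length(drug_b_doses))
    stop("viability matrix dimensions do not match dose vectors")
  for (d in list(drug_a_doses, drug_b_doses)) {
    if (d[1] != 0) stop("first dose of each drug must be 0")
    if (any(diff(d) <= 0)) stop("dose vectors must be strictly increasing")
  }
  if (any(viability < 0)) stop("negative viability")
  structure(list(drug_a_doses = drug_a_doses, drug_b_doses = drug_b_doses,
                 viability = viability), class = "dose_matrix")
}

#' Read a checkerboard viability CSV
#'
#' First row holds drug B doses (first cell is a label), first column drug
#' A doses, body is % viability relative to DMSO.
#'
#' @param path CSV path.
#' @return A `"dose_matrix"`.
#' @export
read_dose_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  b <- as.numeric(raw[1, -1])
  a <- as.numeric(raw[-1, 1])
  v <- as.matrix(raw[-1, -1])
  storage.mode(v) <- "numeric"
  dimnames(v) <- NULL
  dose_matrix(a, b, v)
}

#' Write a checkerboard viability CSV
#' @param dm A `"dose_matrix"`.
#' @param path Output path.
#' @param label Top-left corner label.
#' @return `path`, invisibly.
#' @export
write_dose_matrix <- function(dm, path, label = "doseA\\doseB") {
  stopifnot(inherits(dm, "dose_matrix"))
  header <- paste(c(label, dm$drug_b_doses), collapse = ",")
  body <- apply(cbind(dm$drug_a_doses, dm$viability), 1, paste,
                collapse = ",")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @export
print.dose_matrix <- function(x, ...) {
  cat("Dose matrix:", length(x$drug_a_doses), "x", length(x$drug_b_doses),
      "doses (drug A x drug B), viability % of control\n")
  invisible(x)
}

## Internal: peaks -> GRanges (1-based closed for IRanges machinery).
.peaks_gr <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(peaks$start + 1L, peaks$end))
}
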