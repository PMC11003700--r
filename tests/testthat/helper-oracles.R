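# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive (per-base loops, all-pairs scans, exhaustive
# enumeration) and share no code with the implementations they check.

make_peaks <- function(chrom, start, end, name = NULL, score = 0,
                       summit = NA_real_) {
  if (is.null(name)) name <- paste0("p", seq_along(start))
  validate_peaks(data.frame(chrom = as.character(chrom),
                            start = as.numeric(start),
                            end = as.numeric(end),
                            name = as.character(name),
                            score = rep_len(as.numeric(score),
                                            length(start)),
                            strand = rep_len(".", length(start)),
                            summit_offset = rep_len(as.numeric(summit),
                                                    length(start)),
                            stringsAsFactors = FALSE))
}

make_track <- function(chrom, start, end, value, total_reads = 1e6) {
  coverage_track(data.frame(chrom = chrom, start = start, end = end,
                            value = value, stringsAsFactors = FALSE),
                 total_reads)
}

make_genes <- function(chrom, strand, start, end, id = NULL) {
  if (is.null(id)) id <- paste0("g", seq_along(start))
  validate_genes(data.frame(gene_id = id, chrom = chrom,
                            strand = strand, start = start, end = end,
                            stringsAsFactors = FALSE))
}

# Random non-overlapping step track on one chromosome.
rand_track <- function(chrom = "chr1", max_pos = 300, max_steps = 8) {
  n_br <- sample(2:(max_steps + 1), 1)
  br <- sort(sample(0:max_pos, n_br))
  while (any(diff(br) == 0)) br <- sort(sample(0:max_pos, n_br))
  k <- length(br) - 1
  keep <- runif(k) < 0.7
  start <- br[-length(br)][keep]
  end <- br[-1][keep]
  if (length(start) == 0) { start <- 0; end <- 1 }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   value = round(runif(length(start), 0, 5), 2))
  coverage_track(df, 1e6)
}

rand_peaks <- function(n, chrom = "chr1", max_pos = 300,
                       max_width = 40) {
  start <- sample(0:(max_pos - 2), n, replace = TRUE)
  width <- sample(1:max_width, n, replace = TRUE)
  make_peaks(chrom, start, start + width)
}

# Per-base value lookup in a track (linear scan).
oracle_base_value <- function(track, chrom, pos) {
  df <- track$steps[[chrom]]
  if (is.null(df)) return(0)
  hit <- df$start <= pos & pos < df$end
  if (any(hit)) df$value[which(hit)[1]] else 0
}

# Naive per-base signal matrix: iterate every base of every bin.
oracle_matrix <- function(track, peaks, flank, bin_size) {
  nbins <- 2 * flank / bin_size
  anchors <- ifelse(!is.na(peaks$summit_offset),
                    peaks$start + peaks$summit_offset,
                    floor((peaks$start + peaks$end) / 2))
  out <- matrix(0, nrow(peaks), nbins)
  for (i in seq_len(nrow(peaks))) {
    for (b in seq_len(nbins)) {
      lo <- anchors[i] - flank + (b - 1) * bin_size
      tot <- 0
      for (pos in lo:(lo + bin_size - 1)) {
        if (pos >= 0) tot <- tot + oracle_base_value(track,
                                                     peaks$chrom[i], pos)
      }
      out[i, b] <- tot / bin_size
    }
  }
  out
}

# All-pairs overlap graph + BFS components; min-linkage count.
oracle_overlap <- function(a, b, min_bp = 1) {
  na <- nrow(a); nb <- nrow(b)
  adj <- vector("list", na + nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (a$chrom[i] == b$chrom[j]) {
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_bp) {
        adj[[i]] <- c(adj[[i]], na + j)
        adj[[na + j]] <- c(adj[[na + j]], i)
      }
    }
  }
  seen <- rep(FALSE, na + nb)
  comps <- list()
  for (s in which(lengths(adj) > 0)) {
    if (seen[s]) next
    queue <- s; members <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      members <- c(members, v)
      queue <- c(queue, adj[[v]])
    }
    comps[[length(comps) + 1]] <- members
  }
  n_min <- 0; in_a <- 0; in_b <- 0
  for (m in comps) {
    ka <- sum(m <= na); kb <- sum(m > na)
    n_min <- n_min + min(ka, kb)
    in_a <- in_a + ka; in_b <- in_b + kb
  }
  list(n_overlap_min = n_min, unique_a = na - in_a, unique_b = nb - in_b,
       n_components = length(comps), in_a = in_a, in_b = in_b)
}

# Independent tangent-point super-enhancer caller (explicit loops).
oracle_supers <- function(signals) {
  n <- length(signals)
  if (n < 2) return(rep(FALSE, n))
  y <- sort(signals)
  if (max(y) == min(y)) return(rep(FALSE, n))
  best_d <- Inf; best_i <- NA
  for (i in seq_len(n)) {
    ys <- (y[i] - min(y)) / (max(y) - min(y))
    x <- (i - 1) / (n - 1)
    d <- ys - x
    if (d <= best_d) { best_d <- d; best_i <- i }   # ties -> higher rank
  }
  signals > y[best_i]
}

# Exhaustive minimum-WCSS 2-partition of rows of x.
oracle_best_2partition <- function(x) {
  n <- nrow(x)
  best <- NULL; best_ss <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {   # peak 1 fixed in group 0
    g <- c(0, as.integer(intToBits(mask))[1:(n - 1)])
    if (length(unique(g)) < 2) next
    ss <- 0
    for (grp in unique(g)) {
      rows <- x[g == grp, , drop = FALSE]
      ctr <- colMeans(rows)
      ss <- ss + sum(sweep(rows, 2, ctr, "-")^2)
    }
    if (ss < best_ss) { best_ss <- ss; best <- g }
  }
  list(groups = best, wcss = best_ss)
}

# Minimal scored stitched-enhancer object around a signal vector.
scored <- function(signals) {
  n <- length(signals)
  structure(list(
    regions = data.frame(region_id = seq_len(n),
                         chrom = "chr1",
                         start = seq_len(n) * 1e5,
                         end = seq_len(n) * 1e5 + 1000,
                         n_constituents = 1,
                         constituents = paste0("p", seq_len(n)),
                         signal = signals,
                         rank = rank(signals, ties.method = "first")),
    constituent_peaks = NULL), class = "stitched_enhancers")
}

# Greedy stitching by explicit scan.
oracle_stitch_count <- function(peaks, dist) {
  total <- 0
  for (ch in unique(peaks$chrom)) {
    df <- peaks[peaks$chrom == ch, ]
    df <- df[order(df$start, df$end), ]
    cur_end <- -Inf
    for (i in seq_len(nrow(df))) {
      if (df$start[i] - cur_end > dist) total <- total + 1
      cur_end <- max(cur_end, df$end[i])
    }
  }
  total
}
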