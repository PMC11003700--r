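## Synthetic regulome generator. Emits a toy two-chromosome genome with a
## gene model, planted promoter-like / enhancer-like TF binding with
## matching histone-mark coverage, promoter-biased and enhancer-restricted
## cofactors, knockdown tracks with planted fold changes, a DE table with
## planted regulatory quadrants, checkerboard dose matrices with planted
## Bliss excess, and a machine-readable truth object. Everything flows
## from one seed through named per-stage streams, so adding an output
## never perturbs the others.

#' Synthetic-data generator configuration
#'
#' The defaults define the study conditions every recovery test runs
#' under; `noise_scale` rescales all stochastic components at once
#' (`noise_scale = 0` gives a fully deterministic dataset that pipelines
#' must recover exactly).
#'
#' @param n_genes Total genes (split over two chromosomes; default 200).
#' @param gene_spacing Distance between gene slots in bp (default 14000).
#' @param gene_length Gene span in bp (default 2000).
#' @param n_promoter_bound,n_enhancer_bound,n_dual_bound Genes with TF
#'   binding at the promoter only / a distal enhancer only / both
#'   (defaults 60, 50, 10; the rest are unbound not_de fillers).
#' @param peak_half_width Half-width of called peak intervals in bp
#'   (default 300).
#' @param bump_sd Gaussian coverage-bump standard deviation in bp
#'   (default 150; bumps are truncated at +-3 sd).
#' @param step Coverage step size in bp (default 10).
#' @param amp_tf,amp_me3,amp_me1,amp_k27,amp_cof,amp_cross,amp_input
#'   Coverage-bump amplitudes (arbitrary normalized units): TF, H3K4me3,
#'   H3K4me1, H3K27ac, cofactors, the weak opposite-class mark bump, and
#'   the flat input level.
#' @param amp_spread_sd Log-normal per-peak amplitude spread (default 0.3).
#' @param bin_noise_sd Log-normal per-step multiplicative noise (default
#'   0.15).
#' @param enhancer_offset Distance from TSS to the distal enhancer center
#'   in bp (default 6000, i.e. beyond the 5 kb near-TSS bin).
#' @param tf_kd_factor TF amplitude multiplier after knockdown (default
#'   0.5, a 50% summit decrease).
#' @param cofa_kd_factor Cofactor-A multiplier after knockdown (default
#'   0.95, a 5% decrease).
#' @param cofa_promoter_fraction Fraction of TF promoter peaks carrying
#'   cofactor A (default 0.7).
#' @param occupancy_down_fold Planted fold decrease of "down" cofactor-B
#'   peaks after knockdown (default 1.5).
#' @param occupancy_amp_noise Per-peak multiplicative noise on knockdown
#'   cofactor-B amplitudes (default 0.03).
#' @param n_super Planted super-enhancer clusters (default 6).
#' @param super_amp_mult Amplitude multiplier of super constituents
#'   (default 6).
#' @param super_spacing Spacing of the 3 super constituents in bp
#'   (default 2000).
#' @param fc_down,fc_up Planted linear fold changes for promoter-bound
#'   (down) and enhancer-bound (up) genes (defaults -2, +2).
#' @param fc_log_sd Log-normal spread on planted fold changes (default
#'   0.1).
#' @param doses Checkerboard dose vector starting at 0 (both drugs).
#' @param planted_excess Named numeric of planted Bliss excess (points)
#'   per emitted dose matrix (default `c(additive = 0, synergistic = 15)`).
#' @param viability_noise_sd Multiplicative viability noise (default
#'   0.03).
#' @param read_length Nominal read length used to convert integrated
#'   coverage into the declared library size (default 100).
#' @param noise_scale Global multiplier on `amp_spread_sd`,
#'   `bin_noise_sd`, `occupancy_amp_noise`, `fc_log_sd` and
#'   `viability_noise_sd` (default 1).
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_genes = 200, gene_spacing = 14000,
                         gene_length = 2000,
                         n_promoter_bound = 60, n_enhancer_bound = 50,
                         n_dual_bound = 10,
                         peak_half_width = 300, bump_sd = 150, step = 10,
                         amp_tf = 30, amp_me3 = 40, amp_me1 = 40,
                         amp_k27 = 35, amp_cof = 25, amp_cross = 3,
                         amp_input = 2,
                         amp_spread_sd = 0.3, bin_noise_sd = 0.15,
                         enhancer_offset = 6000,
                         tf_kd_factor = 0.5, cofa_kd_factor = 0.95,
                         cofa_promoter_fraction = 0.7,
                         occupancy_down_fold = 1.5,
                         occupancy_amp_noise = 0.03,
                         n_super = 6, super_amp_mult = 6,
                         super_spacing = 2000,
                         fc_down = -2, fc_up = 2, fc_log_sd = 0.1,
                         doses = c(0, 0.1, 0.3, 1, 3),
                         planted_excess = c(additive = 0,
                                            synergistic = 15),
                         viability_noise_sd = 0.03,
                         read_length = 100,
                         noise_scale = 1) {
  cfg <- as.list(environment())
  for (f in c("amp_spread_sd", "bin_noise_sd", "occupancy_amp_noise",
              "fc_log_sd", "viability_noise_sd"))
    cfg[[f]] <- cfg[[f]] * noise_scale
  n_bound <- n_promoter_bound + n_enhancer_bound + n_dual_bound
  if (n_bound > n_genes) stop("bound gene counts exceed n_genes")
  if (n_genes %% 2 != 0) stop("n_genes must be even (two chromosomes)")
  class(cfg) <- "synth_config"
  cfg
}

## Checkerboard with Hill-curve single agents and a uniform planted
## Bliss excess (percentage points) on every combination cell; uses the
## current RNG state for the multiplicative viability noise.
.dose_grid <- function(delta, doses, noise_sd) {
  e_a <- 0.6 * doses / (doses + 1)
  e_b <- 0.5 * doses / (doses + 0.5)
  e <- outer(e_a, e_b, bliss_expected)
  e[-1, -1] <- pmin(e[-1, -1] + delta / 100, 0.995)
  v <- 100 * (1 - e)
  if (noise_sd > 0)
    v <- v * exp(stats::rnorm(length(v), 0, noise_sd))
  v[1, 1] <- 100
  dose_matrix(doses, doses, v)
}

#' Simulate one checkerboard viability matrix with planted Bliss excess
#'
#' Single agents follow fixed Hill curves (maximum inhibitions 0.6 and
#' 0.5); every combination cell receives the Bliss-expected inhibition
#' plus `delta` percentage points, then multiplicative viability noise.
#'
#' @param delta Planted excess over Bliss independence, in percentage
#'   points.
#' @param seed Integer seed.
#' @param doses Shared dose vector starting at 0.
#' @param noise_sd Multiplicative log-normal viability noise (default
#'   0.03).
#' @return A `"dose_matrix"`.
#' @export
simulate_dose_matrix <- function(delta, seed,
                                 doses = c(0, 0.1, 0.3, 1, 3),
                                 noise_sd = 0.03) {
  .with_seed(.stream_seed(seed, "dose"),
             .dose_grid(delta, doses, noise_sd))
}

## Deterministic stream seed per stage name.
.stream_seed <- function(seed, name) {
  streams <- c(genes = 11L, occupancy = 37L, de = 41L,
               dose = 53L, cofa = 61L)
  off <- if (name %in% names(streams)) streams[[name]]
         else 23L + sum(utf8ToInt(name)) * 131L   # per-track streams
  as.integer((as.numeric(seed) * 97 + off * 7919) %%
               (.Machine$integer.max - 1)) + 1L
}

## Run expr with a locally seeded RNG, restoring global state after.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Gaussian coverage bump as 10 bp steps, truncated at +-3 sd.
.gauss_bump <- function(chrom, center, amp, sd, step) {
  half <- 3 * sd
  starts <- seq(center - half, center + half - step, by = step)
  mids <- starts + step / 2 - center
  data.frame(chrom = chrom, start = starts, end = starts + step,
             value = amp * exp(-mids^2 / (2 * sd^2)),
             stringsAsFactors = FALSE)
}

## Flat input segment.
.flat_segment <- function(chrom, center, amp, halfwidth) {
  data.frame(chrom = chrom, start = center - halfwidth,
             end = center + halfwidth, value = amp,
             stringsAsFactors = FALSE)
}

.assemble_track <- function(bumps, noise_sd, read_length) {
  steps <- do.call(rbind, bumps)
  if (noise_sd > 0)
    steps$value <- steps$value * exp(stats::rnorm(nrow(steps), 0,
                                                  noise_sd))
  integral <- sum(steps$value * (steps$end - steps$start))
  coverage_track(steps, max(1, round(integral / read_length)))
}

## Fixed 20-slot role pattern (P promoter-bound, E enhancer-bound, D dual,
## F filler); slots at pattern position 19 are the enhancer-bound genes
## hosting planted super-enhancer clusters (their successor is a filler,
## keeping stitched clusters isolated).
.role_pattern <- c("P", "P", "P", "E", "F", "E", "F", "D", "F", "P",
                   "F", "E", "F", "P", "E", "F", "P", "F", "E", "F")

#' Generate a synthetic regulome dataset with ground truth
#'
#' See [synth_config()] for the planted design. With `out_dir` set, all
#' on-disk formats are written (narrowPeak peak sets, bedGraph tracks
#' with a `library_sizes.tsv` sidecar, gene model / DE TSVs, dose CSVs, a
#' pipeline `config.yaml`, and `truth.json`); regeneration with the same
#' seed is byte-identical.
#'
#' @param config A `"synth_config"`.
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if missing), or NULL for an
#'   in-memory dataset only.
#' @return A list with `genes`, `peaks` (named list of peak data frames),
#'   `tracks` (named list of coverage tracks), `de`, `dose` (named list
#'   of dose matrices), `truth`, `config`, `seed`, and `files` (named
#'   paths, when written).
#' @export
simulate_regulome <- function(config = synth_config(), seed = 1,
                              out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  n_per_chrom <- cfg$n_genes / 2
  chroms <- c("chr1", "chr2")

  ## ---- gene model (deterministic geometry; strands seeded) ----
  slot <- rep(seq_len(n_per_chrom), times = 2)
  chrom <- rep(chroms, each = n_per_chrom)
  tss <- 10000 + (slot - 1) * cfg$gene_spacing + 1000
  strand <- .with_seed(.stream_seed(seed, "genes"),
                       sample(c("+", "-"), cfg$n_genes, replace = TRUE))
  start <- ifelse(strand == "+", tss, tss - cfg$gene_length + 1)
  genes <- validate_genes(data.frame(
    gene_id = sprintf("g%03d", seq_len(cfg$n_genes)),
    chrom = chrom, strand = strand,
    start = start, end = start + cfg$gene_length,
    stringsAsFactors = FALSE))
  roles <- rep(.role_pattern, length.out = cfg$n_genes)
  ## trim the pattern to the configured counts (pattern gives 3:2.5:0.5:4
  ## per 10 genes; excess bound genes become fillers deterministically)
  for (r in c("P", "E", "D")) {
    want <- switch(r, P = cfg$n_promoter_bound, E = cfg$n_enhancer_bound,
                   D = cfg$n_dual_bound)
    idx <- which(roles == r)
    if (length(idx) < want)
      stop("role pattern cannot supply ", want, " genes of role ", r)
    roles[idx[seq_along(idx) > want]] <- "F"
  }
  se_host <- which(rep(seq_along(.role_pattern),
                       length.out = cfg$n_genes) == 19L & roles == "E")
  se_host <- se_host[seq_len(min(cfg$n_super, length(se_host)))]

  ## ---- element geometry ----
  prom_genes <- which(roles %in% c("P", "D"))
  enh_genes <- which(roles %in% c("E", "D"))
  hw <- cfg$peak_half_width
  mk_peaks <- function(gene_idx, centers, prefix, amp) {
    if (length(gene_idx) == 0L)
      return(.new_peaks(character(), numeric(), numeric(), character()))
    .new_peaks(genes$chrom[gene_idx], centers - hw, centers + hw,
               paste0(prefix, "_", genes$gene_id[gene_idx]),
               score = amp, strand = ".", summit_offset = hw)
  }
  prom_centers <- genes$tss[prom_genes]
  enh_centers <- genes$tss[enh_genes] + cfg$enhancer_offset

  tf_prom <- mk_peaks(prom_genes, prom_centers, "TFp", cfg$amp_tf)
  tf_enh <- mk_peaks(enh_genes, enh_centers, "TFe", cfg$amp_tf)
  tf_peaks <- rbind(tf_prom, tf_enh)

  ## H3K27ac peak set: bound promoters, single enhancer constituents,
  ## and high-amplitude super-enhancer clusters planted in the
  ## intergenic space of each host's filler neighbor (they stitch with
  ## the host's own enhancer into one super region, and sit > 11 kb from
  ## any TF peak so signal matrices are unaffected)
  k27_prom <- mk_peaks(prom_genes, prom_centers, "K27p", cfg$amp_k27)
  enh_constituents <- mk_peaks(enh_genes, enh_centers, "K27e",
                               cfg$amp_k27)
  se_offsets <- cfg$enhancer_offset +
    c(-cfg$super_spacing, 0, cfg$super_spacing)
  se_cluster <- do.call(rbind, lapply(se_host, function(g) {
    ctr <- genes$tss[g + 1L] + se_offsets   # g+1 is a filler, same chrom
    pk <- mk_peaks(rep(g, 3), ctr, paste0("K27se", 1:3),
                   cfg$amp_k27 * cfg$super_amp_mult)
    pk
  }))
  if (is.null(se_cluster))
    se_cluster <- .new_peaks(character(), numeric(), numeric(),
                             character())
  k27_peaks <- rbind(k27_prom, enh_constituents, se_cluster)
  me3_peaks <- mk_peaks(seq_len(cfg$n_genes), genes$tss, "K4me3",
                        cfg$amp_me3)
  me1_peaks <- rbind(enh_constituents, se_cluster)
  me1_peaks$name <- sub("^K27", "K4me1_", me1_peaks$name)
  me1_peaks$score <- cfg$amp_me1

  ## per-peak log-normal amplitude spread (one stream; fixed draw order)
  if (cfg$amp_spread_sd > 0) {
    spread_sets <- .with_seed(.stream_seed(seed, "amps"), {
      sp <- function(df) {
        df$score <- df$score * exp(stats::rnorm(nrow(df), 0,
                                                cfg$amp_spread_sd))
        df
      }
      list(tf_prom = sp(tf_prom), tf_enh = sp(tf_enh),
           k27_prom = sp(k27_prom),
           enh_constituents = sp(enh_constituents),
           se_cluster = sp(se_cluster),
           me3 = sp(me3_peaks), me1 = sp(me1_peaks))
    })
    tf_prom <- spread_sets$tf_prom
    tf_enh <- spread_sets$tf_enh
    k27_prom <- spread_sets$k27_prom
    enh_constituents <- spread_sets$enh_constituents
    se_cluster <- spread_sets$se_cluster
    me3_peaks <- spread_sets$me3
    me1_peaks <- spread_sets$me1
    tf_peaks <- rbind(tf_prom, tf_enh)
    k27_peaks <- rbind(k27_prom, enh_constituents, se_cluster)
  }

  cofa_idx <- .with_seed(.stream_seed(seed, "cofa"),
                         sort(sample(seq_len(nrow(tf_prom)),
                                     round(cfg$cofa_promoter_fraction *
                                             nrow(tf_prom)))))
  cofa_peaks <- tf_prom[cofa_idx, , drop = FALSE]
  cofa_peaks$name <- sub("^TFp", "cofA", cofa_peaks$name)
  cofb_peaks <- tf_enh
  cofb_peaks$name <- sub("^TFe", "cofB", cofb_peaks$name)

  ## ---- planted occupancy categories for cofactor B ----
  n_b <- nrow(cofb_peaks)
  occ_cat <- rep(c("down", "stable"), length.out = n_b)
  occ_factor <- ifelse(occ_cat == "down", 1 / cfg$occupancy_down_fold, 1)
  occ_noise <- .with_seed(.stream_seed(seed, "occupancy"),
                          exp(stats::rnorm(n_b, 0,
                                           cfg$occupancy_amp_noise)))

  ## ---- coverage tracks ----
  bump_at <- function(peaks, amp_mult = 1) {
    centers <- peak_anchor(peaks)
    lapply(seq_len(nrow(peaks)), function(i)
      .gauss_bump(peaks$chrom[i], centers[i],
                  peaks$score[i] * amp_mult, cfg$bump_sd, cfg$step))
  }
  cross_bumps <- function(peaks, amp) {
    centers <- peak_anchor(peaks)
    lapply(seq_len(nrow(peaks)), function(i)
      .gauss_bump(peaks$chrom[i], centers[i], amp, cfg$bump_sd,
                  cfg$step))
  }
  per_peak_mult <- function(peaks, mult) {
    p <- peaks
    p$score <- p$score * mult
    p
  }
  track_spec <- list(
    H3K4me3 = c(bump_at(me3_peaks), cross_bumps(me1_peaks,
                                                cfg$amp_cross)),
    H3K4me1 = c(bump_at(me1_peaks), cross_bumps(k27_prom,
                                                cfg$amp_cross)),
    H3K27ac = bump_at(k27_peaks),
    TF_ctrl = bump_at(tf_peaks),
    TF_kd = bump_at(per_peak_mult(tf_peaks, cfg$tf_kd_factor)),
    cofA_ctrl = bump_at(cofa_peaks),
    cofA_kd = bump_at(per_peak_mult(cofa_peaks, cfg$cofa_kd_factor)),
    cofB_ctrl = bump_at(cofb_peaks),
    cofB_kd = bump_at(per_peak_mult(cofb_peaks, occ_factor * occ_noise)),
    input = list(do.call(rbind, lapply(
      seq_len(nrow(k27_peaks)), function(i)
        .flat_segment(k27_peaks$chrom[i], peak_anchor(k27_peaks)[i],
                      cfg$amp_input, 500))))
  )
  ## one RNG stream per track, so adding a track never perturbs others
  tracks <- stats::setNames(lapply(names(track_spec), function(nm) {
    .with_seed(.stream_seed(seed, paste0("track_", nm)),
               .assemble_track(track_spec[[nm]],
                               noise_sd = cfg$bin_noise_sd,
                               read_length = cfg$read_length))
  }), names(track_spec))

  ## ---- DE table with planted quadrants ----
  de <- .with_seed(.stream_seed(seed, "de"), {
    fc <- numeric(cfg$n_genes)
    padj <- numeric(cfg$n_genes)
    spread <- exp(stats::rnorm(cfg$n_genes, 0, cfg$fc_log_sd))
    dual_dir <- rep(c("down", "up"), length.out = sum(roles == "D"))
    dir <- rep("not_de", cfg$n_genes)
    dir[roles == "P"] <- "down"
    dir[roles == "E"] <- "up"
    dir[roles == "D"] <- dual_dir
    fc[dir == "down"] <- -abs(cfg$fc_down) * spread[dir == "down"]
    fc[dir == "up"] <- abs(cfg$fc_up) * spread[dir == "up"]
    padj[dir != "not_de"] <- 10^stats::runif(sum(dir != "not_de"),
                                             -6, -3.5)
    fillers <- which(dir == "not_de")
    fc[fillers] <- sample(c(-1, 1), length(fillers), replace = TRUE) *
      pmin(1 + abs(stats::rnorm(length(fillers))) * 0.05, 1.19)
    padj[fillers] <- stats::runif(length(fillers), 0.2, 1)
    ## a few high-fold genes killed by padj, to exercise the p-value rule
    edge <- fillers[seq_len(min(10L, length(fillers)))]
    fc[edge] <- sample(c(-1, 1), length(edge), replace = TRUE) * 1.8
    padj[edge] <- stats::runif(length(edge), 0.1, 0.9)
    list(df = validate_de_table(data.frame(
      gene_id = genes$gene_id, fold_change = fc, padj = padj,
      mean_expr_cpm = exp(stats::rnorm(cfg$n_genes, 4, 1)),
      stringsAsFactors = FALSE)), dir = dir)
  })

  ## ---- dose matrices with planted Bliss excess ----
  dose <- .with_seed(.stream_seed(seed, "dose"), {
    out <- list()
    for (nm in names(cfg$planted_excess)) {
      out[[nm]] <- .dose_grid(cfg$planted_excess[[nm]], cfg$doses,
                              cfg$viability_noise_sd)
    }
    out
  })

  bound_elements <- lapply(seq_len(cfg$n_genes), function(g) {
    c(if (roles[g] %in% c("P", "D")) "promoter",
      if (roles[g] %in% c("E", "D")) "enhancer")
  })
  truth <- list(
    seed = seed,
    peak_class = stats::setNames(
      c(rep("promoter_like", nrow(tf_prom)),
        rep("enhancer_like", nrow(tf_enh))), tf_peaks$name),
    gene_role = stats::setNames(roles, genes$gene_id),
    gene_direction = stats::setNames(de$dir, genes$gene_id),
    gene_bound_elements = stats::setNames(bound_elements,
                                          genes$gene_id),
    occupancy_category = stats::setNames(occ_cat, cofb_peaks$name),
    super_hosts = genes$gene_id[se_host],
    super_constituents = lapply(se_host, function(g)
      c(paste0("K27e_", genes$gene_id[g]),
        paste0("K27se", 1:3, "_", genes$gene_id[g]))),
    planted_excess = as.list(cfg$planted_excess),
    tf_kd_factor = cfg$tf_kd_factor,
    cofa_kd_factor = cfg$cofa_kd_factor)

  chrom_sizes <- data.frame(
    chrom = chroms,
    size = 10000 + (n_per_chrom - 1) * cfg$gene_spacing + 1000 +
      cfg$enhancer_offset + cfg$super_spacing + 3 * cfg$bump_sd + 1000,
    stringsAsFactors = FALSE)
  result <- list(genes = genes, chrom_sizes = chrom_sizes,
                 peaks = list(TF = tf_peaks, H3K4me3 = me3_peaks,
                              H3K4me1 = me1_peaks, H3K27ac = k27_peaks,
                              cofA = cofa_peaks, cofB = cofb_peaks),
                 tracks = tracks, de = de$df, dose = dose,
                 truth = truth, config = cfg, seed = seed,
                 files = NULL)
  if (!is.null(out_dir)) result$files <- .write_synth(result, out_dir)
  result
}

## Write every on-disk representation of a simulated dataset.
.write_synth <- function(sim, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  p <- function(...) file.path(out_dir, paste0(...))
  files <- list(genes = p("genes.tsv"), de = p("de_table.tsv"),
                truth = p("truth.json"),
                library_sizes = p("library_sizes.tsv"),
                config = p("config.yaml"))
  write_gene_model(sim$genes, files$genes)
  write_de_table(sim$de, files$de)
  files$chrom_sizes <- p("chrom_sizes.tsv")
  utils::write.table(sim$chrom_sizes, files$chrom_sizes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(sim$peaks)) {
    files[[paste0("peaks_", nm)]] <- p("peaks_", nm, ".narrowPeak")
    write_peaks(sim$peaks[[nm]], files[[paste0("peaks_", nm)]])
  }
  lib <- data.frame(track = character(), total_reads = numeric())
  for (nm in names(sim$tracks)) {
    f <- p("track_", nm, ".bedgraph")
    files[[paste0("track_", nm)]] <- f
    write_bedgraph(sim$tracks[[nm]], f)
    lib <- rbind(lib, data.frame(track = nm,
                                 total_reads =
                                   sim$tracks[[nm]]$total_reads))
  }
  utils::write.table(lib, files$library_sizes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(sim$dose)) {
    files[[paste0("dose_", nm)]] <- p("dose_", nm, ".csv")
    write_dose_matrix(sim$dose[[nm]], files[[paste0("dose_", nm)]])
  }
  jsonlite::write_json(sim$truth, files$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  yaml::write_yaml(list(
    data_dir = ".",   # resolved relative to the config file
    seed = sim$seed,
    thresholds = unclass(analysis_config())[
      setdiff(names(analysis_config()), "random_seed")]),
    files$config)
  files
}
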