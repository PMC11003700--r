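## End-to-end orchestration: chromatin-state segmentation of TF peaks,
## positional annotation, cofactor overlap, super-enhancer calling,
## quadrant integration, occupancy binning, Bliss scoring, and a
## machine-readable summary report with a run manifest.

#' Segment and label TF peaks from mark coverage tracks
#'
#' Computes signal matrices for each mark around the TF peak centers,
#' builds the standardized feature table, k-means segments it, and labels
#' the clusters from the H3K4me3 : H3K4me1 peak-center score ratio.
#'
#' @param tf_peaks TF peak data frame.
#' @param mark_tracks Named list of `"coverage_track"`s; must include
#'   `H3K4me3` and `H3K4me1` (additional marks, e.g. `H3K27ac`, join the
#'   feature table).
#' @param cfg An [analysis_config()].
#' @param seed Seed for the k-means initialization (default
#'   `cfg$random_seed`).
#' @return A labeled `"cluster_assignment"` with an extra `peak_label`
#'   element (per-peak promoter_like / enhancer_like / unlabeled).
#' @export
classify_tf_peaks <- function(tf_peaks, mark_tracks,
                              cfg = analysis_config(),
                              seed = cfg$random_seed) {
  mats <- lapply(mark_tracks, compute_matrix, peaks = tf_peaks,
                 flank = cfg$matrix_flank, bin_size = cfg$matrix_bin)
  features <- build_feature_table(mats)
  assignment <- kmeans_segment(features, k = cfg$cluster_k, seed = seed)
  scores <- lapply(mats, peak_center_score,
                   center_window = cfg$center_window)
  assignment <- label_clusters(assignment, scores)
  lab <- unlist(assignment$labels)
  assignment$peak_label <- unname(lab[as.character(assignment$cluster)])
  assignment
}

#' Derive per-gene bound element classes
#'
#' A gene is promoter-bound when a TF peak annotated to it is
#' promoter-class, and enhancer-bound when a distal TF peak annotated to
#' it carries the enhancer_like chromatin-state label.
#'
#' @param annotation Output of [annotate_peaks()] for the TF peaks.
#' @param peak_label Per-peak chromatin-state labels in the same order
#'   (see [classify_tf_peaks()]).
#' @return Data frame `gene_id`, `element_class` (one row per bound
#'   class per gene), suitable for [build_quadrants()].
#' @export
derive_gene_elements <- function(annotation, peak_label) {
  if (length(peak_label) != nrow(annotation))
    stop("peak_label length does not match the annotation")
  prom <- annotation$element_class == "promoter"
  enh <- annotation$element_class == "distal" &
    peak_label == "enhancer_like" & !is.na(annotation$gene_id)
  out <- rbind(
    data.frame(gene_id = annotation$gene_id[prom],
               element_class = "promoter", stringsAsFactors = FALSE),
    data.frame(gene_id = annotation$gene_id[enh],
               element_class = "enhancer", stringsAsFactors = FALSE))
  unique(out[!is.na(out$gene_id), , drop = FALSE])
}

.read_run_config <- function(config_path) {
  if (!file.exists(config_path))
    stop("config file not found: ", config_path)
  conf <- yaml::read_yaml(config_path)
  dir <- conf$data_dir %||% "."
  if (!grepl("^/", dir))
    dir <- file.path(dirname(normalizePath(config_path)), dir)
  conf$data_dir <- normalizePath(dir)
  thr <- conf$thresholds %||% list()
  conf$cfg <- do.call(analysis_config,
                      c(thr[names(thr) %in%
                              names(formals(analysis_config))],
                        list(random_seed = conf$seed %||% 1L)))
  conf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.require_file <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  path
}

#' Run the full analysis pipeline from a config file
#'
#' The YAML config names a `data_dir` (resolved relative to the config
#' file) laid out as written by [simulate_regulome()]: a gene model, TF /
#' mark / cofactor peak sets and coverage tracks with a
#' `library_sizes.tsv` sidecar, a DE table, and dose CSVs. All numeric
#' thresholds come from the config's `thresholds` block (see
#' [analysis_config()]). Writes per-stage tables, `report.json` and
#' `manifest.json` into `out_dir`; the report is deterministic given the
#' config and seed.
#'
#' @param config_path Path to the YAML config.
#' @param out_dir Output directory (default `<data_dir>/results`).
#' @param stages Character vector of stages to run (default all of
#'   cluster, annotate, overlap, superenh, integrate, occupancy,
#'   synergy; earlier stages required by later ones run regardless).
#' @return The report, invisibly (a nested list).
#' @export
run_pipeline <- function(config_path,
                         out_dir = NULL,
                         stages = c("cluster", "annotate", "overlap",
                                    "superenh", "integrate", "occupancy",
                                    "synergy")) {
  conf <- .read_run_config(config_path)
  cfg <- conf$cfg
  dd <- conf$data_dir
  if (is.null(out_dir)) out_dir <- file.path(dd, "results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list()
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }
  inputs <- stage("load", {
    lib <- utils::read.table(
      .require_file(file.path(dd, "library_sizes.tsv")),
      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    total_reads <- stats::setNames(lib$total_reads, lib$track)
    trk <- function(nm) read_bedgraph(
      .require_file(file.path(dd, paste0("track_", nm, ".bedgraph"))),
      total_reads[[nm]])
    pks <- function(nm) read_peaks(
      .require_file(file.path(dd, paste0("peaks_", nm, ".narrowPeak"))))
    list(genes = read_gene_model(.require_file(file.path(dd,
                                                         "genes.tsv"))),
         de = read_de_table(.require_file(file.path(dd,
                                                    "de_table.tsv"))),
         tf = pks("TF"), k27 = pks("H3K27ac"), cofa = pks("cofA"),
         cofb = pks("cofB"),
         marks = list(H3K4me3 = trk("H3K4me3"),
                      H3K4me1 = trk("H3K4me1"),
                      H3K27ac = trk("H3K27ac")),
         tf_ctrl = trk("TF_ctrl"), tf_kd = trk("TF_kd"),
         cofb_ctrl = trk("cofB_ctrl"), cofb_kd = trk("cofB_kd"),
         input = trk("input"),
         dose = {
           fl <- list.files(dd, "^dose_.*\\.csv$", full.names = TRUE)
           stats::setNames(lapply(fl, read_dose_matrix),
                           sub("^dose_(.*)\\.csv$", "\\1",
                               basename(fl)))
         })
  })
  counts$n_tf_peaks <- nrow(inputs$tf)
  counts$n_genes <- nrow(inputs$genes)

  assignment <- stage("cluster", {
    a <- classify_tf_peaks(inputs$tf, inputs$marks, cfg)
    write_cluster_assignment(a, file.path(out_dir, "clusters.tsv"),
                             peaks = inputs$tf,
                             bed_path = file.path(out_dir,
                                                  "clusters.bed"))
    a
  })
  report$cluster_sizes <- as.list(table(assignment$peak_label))

  annotation <- stage("annotate", {
    an <- annotate_peaks(inputs$tf, inputs$genes,
                         upstream = cfg$promoter_upstream,
                         downstream = cfg$promoter_downstream)
    write_annotations(an, file.path(out_dir, "annotation.tsv"))
    an
  })
  report$class_fractions <- class_fractions(annotation)
  report$tss_distance <- tss_distance_fractions(annotation,
                                                near = cfg$tss_near_bin)

  superenh <- stage("superenh", {
    distal <- distal_filter(inputs$k27, inputs$genes,
                            tss_exclusion = cfg$tss_exclusion)
    st <- stitch(distal, stitch_distance = cfg$stitch_distance)
    st <- score_stitched(st, inputs$marks$H3K27ac, inputs$input)
    st <- call_supers(st)
    write_enhancer_table(st,
                         tsv_path = file.path(out_dir, "enhancers.tsv"),
                         bed_path = file.path(out_dir,
                                              "super_enhancers.bed"))
    st
  })
  report$super_enhancers <- list(
    n_stitched = nrow(superenh$regions),
    n_super = sum(superenh$regions$is_super),
    cutoff_signal = superenh$cutoff_signal)

  overlaps <- stage("overlap", {
    ## promoter/enhancer/super tags for the TF peaks, overlap-report style
    tags <- rbind(
      data.frame(peak_id = annotation$peak_id[
        annotation$element_class == "promoter"], tag = "promoter"),
      data.frame(peak_id = assignment$peak_ids[
        assignment$peak_label == "enhancer_like"], tag = "enhancer"))
    sup <- superenh$regions[superenh$regions$is_super, , drop = FALSE]
    if (nrow(sup) > 0) {
      sup_pk <- .new_peaks(sup$chrom, sup$start, sup$end,
                           paste0("SE_", sup$region_id))
      in_super <- find_overlaps(inputs$tf, sup_pk)
      idx <- unlist(lapply(in_super$components, `[[`, "a"))
      if (length(idx))
        tags <- rbind(tags, data.frame(peak_id = inputs$tf$name[idx],
                                       tag = "super_enhancer"))
    }
    res <- list()
    for (nm in c("cofa", "cofb")) {
      ov <- find_overlaps(inputs$tf, inputs[[nm]])
      write_overlap_result(ov,
                           tsv_path = file.path(out_dir,
                                                paste0("overlap_", nm,
                                                       ".tsv")),
                           json_path = file.path(out_dir,
                                                 paste0("overlap_", nm,
                                                        ".json")))
      res[[nm]] <- list(
        n_overlap_min = ov$n_overlap_min,
        fraction_of_cofactor = overlap_fraction(ov, "B"),
        by_category = overlap_by_category(ov, tags, side = "A"))
    }
    res
  })
  report$overlap <- lapply(overlaps, function(x)
    list(n_overlap_min = x$n_overlap_min,
         fraction_of_cofactor = x$fraction_of_cofactor,
         by_category = x$by_category))

  quadrants <- stage("integrate", {
    g2e <- derive_gene_elements(annotation, assignment$peak_label)
    q <- build_quadrants(inputs$de, g2e,
                         fold_threshold = cfg$de_fold_threshold,
                         padj_threshold = cfg$de_padj_threshold)
    utils::write.table(q$counts, file.path(out_dir, "quadrants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    q
  })
  report$quadrants <- list(counts = quadrants$counts,
                           n_de = quadrants$n_de,
                           n_de_bound = quadrants$n_de_bound,
                           n_dual_bound = quadrants$n_dual_bound)

  occupancy <- stage("occupancy", {
    m_ctrl <- compute_matrix(inputs$cofb_ctrl, inputs$cofb,
                             flank = cfg$matrix_flank,
                             bin_size = cfg$matrix_bin)
    m_kd <- compute_matrix(inputs$cofb_kd, inputs$cofb,
                           flank = cfg$matrix_flank,
                           bin_size = cfg$matrix_bin)
    occ <- occupancy_table(inputs$cofb$name,
                           peak_center_score(m_ctrl, cfg$center_window),
                           peak_center_score(m_kd, cfg$center_window),
                           change_fold = cfg$occupancy_change_fold,
                           stable_fold = cfg$occupancy_stable_fold)
    utils::write.table(occ, file.path(out_dir, "occupancy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    occ
  })
  report$occupancy <- as.list(table(occupancy$category))
  report$tf_summit_decrease_pct <- stage("metagene", {
    m_ctrl <- compute_matrix(inputs$tf_ctrl, inputs$tf,
                             flank = cfg$matrix_flank,
                             bin_size = cfg$matrix_bin)
    m_kd <- compute_matrix(inputs$tf_kd, inputs$tf,
                           flank = cfg$matrix_flank,
                           bin_size = cfg$matrix_bin)
    summit_change(metagene(m_ctrl), metagene(m_kd))
  })

  report$synergy <- stage("synergy", {
    lapply(inputs$dose, function(dm) {
      s <- bliss_score(dm)
      list(average_score = s$average_score,
           classification = s$classification)
    })
  })

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  input_files <- list.files(dd, full.names = TRUE)
  input_files <- input_files[!dir.exists(input_files)]
  manifest <- list(
    config = conf[setdiff(names(conf), "cfg")],
    thresholds = unclass(cfg),
    package_version = as.character(utils::packageVersion("regquad")),
    input_digests = as.list(tools::md5sum(input_files)),
    stage_counts = counts,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

#' Recover planted truth from a simulated dataset
#'
#' Runs the analysis stages directly on an in-memory
#' [simulate_regulome()] dataset and compares the results with its
#' planted truth. Used to calibrate and validate the pipeline on known
#' ground truth.
#'
#' @param sim A [simulate_regulome()] result.
#' @param cfg An [analysis_config()] (defaults to the standard
#'   thresholds, seeded from the simulation seed).
#' @return List of metrics: `cluster_accuracy`, `quadrant_recall`,
#'   `quadrant_precision`, `occupancy_recovery`, `se_recall`,
#'   `se_n_called`, `tf_summit_decrease_pct`, `cofa_summit_decrease_pct`,
#'   and `synergy` (average score per planted matrix).
#' @export
evaluate_synthetic_recovery <- function(sim,
                                        cfg = analysis_config(
                                          random_seed = sim$seed)) {
  marks <- sim$tracks[c("H3K4me3", "H3K4me1", "H3K27ac")]
  assignment <- classify_tf_peaks(sim$peaks$TF, marks, cfg)
  truth_class <- sim$truth$peak_class[assignment$peak_ids]
  cluster_accuracy <- mean(assignment$peak_label == truth_class)

  annotation <- annotate_peaks(sim$peaks$TF, sim$genes,
                               upstream = cfg$promoter_upstream,
                               downstream = cfg$promoter_downstream)
  g2e <- derive_gene_elements(annotation, assignment$peak_label)
  quad <- build_quadrants(sim$de, g2e,
                          fold_threshold = cfg$de_fold_threshold,
                          padj_threshold = cfg$de_padj_threshold)
  pairs <- function(bound, dirn) {
    keep <- dirn %in% c("up", "down") & lengths(bound) > 0
    unlist(lapply(which(keep), function(i)
      paste0(names(bound)[i], ":", bound[[i]], "_", dirn[i])))
  }
  planted <- pairs(sim$truth$gene_bound_elements,
                   sim$truth$gene_direction)
  calls <- quad$calls
  pred_bound <- lapply(seq_len(nrow(calls)), function(i)
    c(if (calls$bound_promoter[i]) "promoter",
      if (calls$bound_enhancer[i]) "enhancer"))
  names(pred_bound) <- calls$gene_id
  predicted <- pairs(pred_bound,
                     stats::setNames(calls$de_direction, NULL))
  quadrant_recall <- if (length(planted))
    length(intersect(planted, predicted)) / length(planted) else NA
  quadrant_precision <- if (length(predicted))
    length(intersect(planted, predicted)) / length(predicted) else NA

  sc <- function(track, peaks) peak_center_score(
    compute_matrix(track, peaks, flank = cfg$matrix_flank,
                   bin_size = cfg$matrix_bin), cfg$center_window)
  occ <- bin_occupancy_change(sc(sim$tracks$cofB_ctrl, sim$peaks$cofB),
                              sc(sim$tracks$cofB_kd, sim$peaks$cofB),
                              change_fold = cfg$occupancy_change_fold,
                              stable_fold = cfg$occupancy_stable_fold)
  truth_occ <- sim$truth$occupancy_category[sim$peaks$cofB$name]
  occupancy_recovery <- mean(occ == truth_occ)

  distal <- distal_filter(sim$peaks$H3K27ac, sim$genes,
                          tss_exclusion = cfg$tss_exclusion)
  st <- call_supers(score_stitched(
    stitch(distal, stitch_distance = cfg$stitch_distance),
    sim$tracks$H3K27ac, sim$tracks$input))
  called <- st$regions[st$regions$is_super, , drop = FALSE]
  called_sets <- lapply(strsplit(called$constituents, ","), sort)
  truth_sets <- lapply(sim$truth$super_constituents, sort)
  se_recall <- if (length(truth_sets))
    mean(vapply(truth_sets, function(ts)
      any(vapply(called_sets, identical, TRUE, y = ts)), TRUE)) else NA

  mg <- function(track, peaks) metagene(
    compute_matrix(track, peaks, flank = cfg$matrix_flank,
                   bin_size = cfg$matrix_bin))
  tf_dec <- summit_change(mg(sim$tracks$TF_ctrl, sim$peaks$TF),
                          mg(sim$tracks$TF_kd, sim$peaks$TF))
  cofa_dec <- summit_change(mg(sim$tracks$cofA_ctrl, sim$peaks$cofA),
                            mg(sim$tracks$cofA_kd, sim$peaks$cofA))

  list(cluster_accuracy = cluster_accuracy,
       quadrant_recall = quadrant_recall,
       quadrant_precision = quadrant_precision,
       occupancy_recovery = occupancy_recovery,
       se_recall = se_recall, se_n_called = nrow(called),
       tf_summit_decrease_pct = tf_dec,
       cofa_summit_decrease_pct = cofa_dec,
       synergy = lapply(sim$dose,
                        function(d) bliss_score(d)$average_score),
       quadrant_counts = quad$counts)
}
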