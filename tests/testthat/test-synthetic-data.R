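# A reduced generator configuration keeps the routine test run fast; the
# full-size defaults are exercised by the acceptance suite.
small_cfg <- function(...) synth_config(n_genes = 60,
                                        n_promoter_bound = 18,
                                        n_enhancer_bound = 15,
                                        n_dual_bound = 3,
                                        n_super = 2, ...)

test_that("the same seed reproduces byte-identical files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_regulome(small_cfg(), seed = 5, out_dir = d1)
  simulate_regulome(small_cfg(), seed = 5, out_dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = paste("md5 of", f))
  }
  sim3 <- simulate_regulome(small_cfg(), seed = 6, out_dir = NULL)
  sim5 <- simulate_regulome(small_cfg(), seed = 5, out_dir = NULL)
  expect_false(identical(sim3$de$fold_change, sim5$de$fold_change))
})

test_that("emitted files parse cleanly through the readers", {
  dd <- withr::local_tempdir()
  sim <- simulate_regulome(small_cfg(), seed = 2, out_dir = dd)
  expect_warning(genes <- read_gene_model(file.path(dd, "genes.tsv")),
                 regexp = NA)
  expect_equal(genes, sim$genes)
  expect_equal(read_de_table(file.path(dd, "de_table.tsv")), sim$de)
  lib <- read.table(file.path(dd, "library_sizes.tsv"), header = TRUE,
                    sep = "\t")
  for (nm in names(sim$peaks)) {
    pk <- read_peaks(file.path(dd, paste0("peaks_", nm,
                                          ".narrowPeak")))
    expect_equal(pk$name, sim$peaks[[nm]]$name)
  }
  for (nm in names(sim$tracks)) {
    tr <- lib$total_reads[lib$track == nm]
    expect_warning(
      trk <- read_bedgraph(file.path(dd, paste0("track_", nm,
                                                ".bedgraph")), tr),
      regexp = NA)
    ## planted coverage integrates to the declared library size
    steps <- do.call(rbind, trk$steps)
    integral <- sum(steps$value * (steps$end - steps$start))
    expect_lt(abs(integral / sim$config$read_length -
                    trk$total_reads) / trk$total_reads, 0.01)
  }
  dm <- read_dose_matrix(file.path(dd, "dose_synergistic.csv"))
  expect_equal(dm$viability, sim$dose$synergistic$viability,
               tolerance = 1e-6)
  truth <- jsonlite::read_json(file.path(dd, "truth.json"))
  expect_equal(truth$seed, 2)
  expect_equal(length(truth$peak_class), nrow(sim$peaks$TF))
})

test_that("DE marginals match the planted design exactly", {
  sim <- simulate_regulome(small_cfg(), seed = 8)
  dirs <- classify_de(sim$de$fold_change, sim$de$padj)
  planted <- unname(sim$truth$gene_direction)
  ## at default noise the planted fold changes sit far from the
  ## thresholds, so the marginals agree to within one gene
  expect_lte(sum(dirs != planted), 1)
  expect_equal(sum(planted == "down"),
               sim$config$n_promoter_bound + 2)   # half the duals
  expect_equal(sum(planted == "up"),
               sim$config$n_enhancer_bound + 1)
})

test_that("a zero-noise dataset is recovered exactly end to end", {
  sim <- simulate_regulome(small_cfg(noise_scale = 0), seed = 3)
  m <- evaluate_synthetic_recovery(sim)
  expect_equal(m$cluster_accuracy, 1)
  expect_equal(m$quadrant_recall, 1)
  expect_equal(m$quadrant_precision, 1)
  expect_equal(m$occupancy_recovery, 1)
  expect_equal(m$se_recall, 1)
  expect_equal(m$se_n_called, 2)
  expect_equal(m$tf_summit_decrease_pct, 50, tolerance = 1e-6)
  expect_equal(m$synergy$additive, 0, tolerance = 1e-9)
  expect_equal(m$synergy$synergistic, 15, tolerance = 1e-9)
})
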