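sm <- function(values, ids = NULL) {
  if (is.null(ids)) ids <- paste0("p", seq_len(nrow(values)))
  structure(list(values = values, peak_ids = ids, bin_size = 10,
                 flank = ncol(values) * 5, anchor = "peak_center",
                 units = "track"), class = "signal_matrix")
}

test_that("feature table standardizes per mark and checks peak order", {
  x <- matrix(c(1, 2, 6, 3, 5, 10), nrow = 3)   # 3 peaks x 2 bins
  ft <- build_feature_table(list(m = sm(x)))
  expect_equal(unname(ft[, 1]), unname((x[, 1] - mean(x[, 1])) /
                                         sd(x[, 1])))
  expect_equal(unname(ft[, 2]), unname((x[, 2] - mean(x[, 2])) /
                                         sd(x[, 2])))

  const <- sm(matrix(4, 3, 2))
  expect_equal(unname(build_feature_table(list(m = const))),
               matrix(0, 3, 2), ignore_attr = TRUE)

  two <- build_feature_table(list(a = sm(x), b = sm(x)))
  expect_equal(ncol(two), 4)

  bad <- sm(x, ids = c("q1", "q2", "q3"))
  expect_error(build_feature_table(list(a = sm(x), b = bad)),
               "peak order")
})

test_that("kmeans_segment recovers the exhaustive best 2-partition", {
  feats <- rbind(c(10, 0), c(10.5, 0.2), c(0, 10), c(0.3, 9.5))
  rownames(feats) <- paste0("p", 1:4)
  a <- kmeans_segment(feats, k = 2, seed = 1)
  expect_equal(a$cluster[1], a$cluster[2])
  expect_equal(a$cluster[3], a$cluster[4])
  expect_true(a$cluster[1] != a$cluster[3])

  set.seed(21)
  for (rep in 1:25) {
    ## two displaced blobs: the global optimum is well defined and
    ## reachable, so Lloyd must match the exhaustive minimum
    x <- rbind(matrix(rnorm(9), 3, 3), matrix(rnorm(9) + 5, 3, 3))
    x <- x[sample(6), ]
    a <- kmeans_segment(x, k = 2, seed = rep)
    oracle <- oracle_best_2partition(x)
    ## compare partitions up to label swap via pair-joined relation
    same_impl <- outer(a$cluster, a$cluster, "==")
    same_oracle <- outer(oracle$groups, oracle$groups, "==")
    expect_equal(sum(a$withinss), oracle$wcss, tolerance = 1e-8)
    expect_equal(same_impl, same_oracle)
  }
})

test_that("kmeans_segment handles k = 1, degenerate rows and determinism", {
  x <- matrix(rnorm(10), 5, 2)
  expect_equal(kmeans_segment(x, k = 1, seed = 1)$cluster, rep(1L, 5))
  expect_error(kmeans_segment(x[1:2, , drop = FALSE], k = 3), "fewer")

  same <- matrix(1, 4, 2)
  expect_warning(a <- kmeans_segment(same, k = 2, seed = 1), "distinct")
  expect_equal(a$cluster, rep(1L, 4))

  set.seed(99)
  x <- matrix(rnorm(40), 20, 2)
  a1 <- kmeans_segment(x, k = 2, seed = 7)
  a2 <- kmeans_segment(x, k = 2, seed = 7)
  expect_identical(a1$cluster, a2$cluster)
  expect_identical(a1$withinss, a2$withinss)
})

test_that("label_clusters uses the H3K4me3:H3K4me1 ratio with a tie rule", {
  a <- structure(list(peak_ids = paste0("p", 1:4),
                      cluster = c(1L, 1L, 2L, 2L), k = 2,
                      withinss = 0, labels = NULL),
                 class = "cluster_assignment")
  scores <- list(H3K4me3 = c(10, 10, 1, 1), H3K4me1 = c(1, 1, 10, 10))
  lab <- label_clusters(a, scores)
  expect_equal(lab$labels[["1"]], "promoter_like")
  expect_equal(lab$labels[["2"]], "enhancer_like")

  tie <- label_clusters(a, list(H3K4me3 = rep(5, 4),
                                H3K4me1 = rep(5, 4)))
  expect_equal(unlist(tie$labels), c(`1` = "unlabeled",
                                     `2` = "unlabeled"))
  expect_error(label_clusters(a, list(H3K4me3 = c(1, 1, 1, 1))),
               "H3K4me1")
})

test_that("active_enhancer_peaks excludes any >= 1 bp overlap, half-open", {
  k27 <- make_peaks("chr1", c(0, 0, 500), c(100, 100, 600),
                    name = c("a", "b", "c"))
  me3_hit <- make_peaks("chr1", 50, 150)
  me3_abut <- make_peaks("chr1", 100, 200)
  expect_equal(nrow(active_enhancer_peaks(k27[1, ], me3_hit)), 0)
  expect_equal(active_enhancer_peaks(k27[1, ], me3_abut)$name, "a")

  set.seed(31)
  for (rep in 1:30) {
    a <- rand_peaks(12, max_pos = 400)
    b <- rand_peaks(8, max_pos = 400)
    got <- active_enhancer_peaks(a, b)
    keep <- vapply(seq_len(nrow(a)), function(i)
      all(pmin(a$end[i], b$end) - pmax(a$start[i], b$start) < 1), TRUE)
    expect_equal(got$name, a$name[keep])
    ## subset of input and idempotent
    expect_true(all(got$name %in% a$name))
    expect_equal(active_enhancer_peaks(got, b), got)
  }
})
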