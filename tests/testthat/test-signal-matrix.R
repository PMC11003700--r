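test_that("peak anchors prefer the summit and fall back to the midpoint", {
  pk <- make_peaks("chr1", c(100, 100, 0), c(200, 200, 1),
                   summit = c(40, NA, NA))
  expect_equal(peak_anchor(pk), c(140, 150, 0))
})

test_that("rpkm_value evaluates the formula and is (inversely) linear", {
  expect_equal(rpkm_value(50, 100, 1e7), 50)
  expect_equal(rpkm_value(0, 123, 5e6), 0)
  expect_equal(rpkm_value(7, 250, 2e6), 14)
  expect_error(rpkm_value(1, 0, 1e6), "length")
  expect_error(rpkm_value(1, 100, 0), "total_reads")
  r1 <- rpkm_value(3, 500, 1e6)
  expect_equal(rpkm_value(6, 500, 1e6), 2 * r1)
  expect_equal(rpkm_value(3, 500, 2e6), r1 / 2)
})

test_that("compute_matrix handles constant, point and empty inputs", {
  trk <- make_track("chr1", 0, 20000, 2.0)
  pk <- make_peaks("chr1", 9000, 10000)
  m <- compute_matrix(trk, pk, flank = 3000, bin_size = 10)
  expect_equal(ncol(m$values), 600)
  expect_equal(unname(m$values[1, ]), rep(2, 600))

  ## single covered base at the anchor: its 10 bp bin averages to 0.5
  trk1 <- make_track("chr1", 9500, 9501, 5.0)
  m1 <- compute_matrix(trk1, pk, flank = 3000, bin_size = 10)
  expect_equal(sum(m1$values), 0.5)
  expect_equal(unname(m1$values[1, 301]), 0.5)

  m0 <- compute_matrix(trk, pk[0, ], flank = 3000, bin_size = 10)
  expect_equal(nrow(m0$values), 0)

  expect_warning(
    mu <- compute_matrix(trk, make_peaks("chrX", 100, 200), flank = 100,
                         bin_size = 10),
    "absent")
  expect_equal(unname(mu$values[1, ]), rep(0, 20))
})

test_that("compute_matrix matches the per-base oracle on random cases", {
  set.seed(101)
  for (rep in 1:60) {
    trk <- rand_track(max_pos = 250)
    pk <- rand_peaks(3, max_pos = 250)
    flank <- sample(c(20, 40, 60), 1)
    m <- compute_matrix(trk, pk, flank = flank, bin_size = 10)
    o <- oracle_matrix(trk, pk, flank = flank, bin_size = 10)
    expect_equal(unname(m$values), o, tolerance = 1e-9)
    expect_equal(sum(m$values), sum(o), tolerance = 1e-9)
  }
})

test_that("peak_center_score sums the central window bins", {
  trk <- make_track("chr1", 0, 20000, 2.0)
  pk <- make_peaks("chr1", 9000, 10000)
  m <- compute_matrix(trk, pk, flank = 3000, bin_size = 10)
  expect_equal(unname(peak_center_score(m, 500)), 200)

  m$values[] <- rep(c(1, 0), length.out = length(m$values))
  expect_equal(unname(peak_center_score(m, 500)), 50)
  m$values[] <- 0
  expect_equal(unname(peak_center_score(m, 500)), 0)
  expect_error(peak_center_score(m, 505), "multiple")
  expect_error(peak_center_score(m, 3500), "exceeds")

  ## random matrices vs direct summation
  set.seed(11)
  for (rep in 1:20) {
    v <- matrix(runif(5 * 60), 5, 60)
    mm <- structure(list(values = v, peak_ids = letters[1:5],
                         bin_size = 10, flank = 300,
                         anchor = "peak_center", units = "track"),
                    class = "signal_matrix")
    w <- sample(c(10, 50, 100), 1)
    direct <- rowSums(v[, (30 - w / 10 + 1):(30 + w / 10)])
    expect_equal(unname(peak_center_score(mm, w)), direct)
  }
})

test_that("metagene is the column mean and fails on empty input", {
  v <- rbind(c(1, 3), c(3, 5))
  m <- structure(list(values = v, peak_ids = c("a", "b"), bin_size = 10,
                      flank = 10, anchor = "peak_center",
                      units = "track"),
                 class = "signal_matrix")
  colnames(m$values) <- c(-5, 5)
  expect_equal(unname(metagene(m)$mean_signal), c(2, 4))
  m1 <- m; m1$values <- m1$values[1, , drop = FALSE]
  expect_equal(unname(metagene(m1)$mean_signal), c(1, 3))
  m0 <- m; m0$values <- m0$values[0, , drop = FALSE]
  expect_error(metagene(m0), "empty")

  set.seed(3)
  big <- matrix(rnorm(1000 * 20), 1000, 20)
  colnames(big) <- seq_len(20)
  mb <- m; mb$values <- big
  expect_equal(unname(metagene(mb)$mean_signal),
               unname(apply(big, 2, mean)))
})

test_that("summit_change reports percent decrease of the central bins", {
  prof <- function(vals) {
    structure(list(positions = c(-15, -5, 5, 15), mean_signal = vals,
                   n_peaks = 1), class = "metagene_profile")
  }
  expect_equal(summit_change(prof(c(0, 10, 10, 0)),
                             prof(c(0, 5, 5, 0))), 50)
  expect_equal(summit_change(prof(c(1, 2, 2, 1)),
                             prof(c(1, 2, 2, 1))), 0)
  expect_equal(summit_change(prof(c(0, 20, 20, 0)),
                             prof(c(0, 19, 19, 0))), 5)
  expect_error(summit_change(prof(c(0, 0, 0, 0)),
                             prof(c(0, 1, 1, 0))), "positive")
})
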