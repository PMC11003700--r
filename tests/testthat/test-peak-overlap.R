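test_that("find_overlaps applies min-linkage component semantics", {
  a <- make_peaks("chr1", c(0, 50), c(100, 150), name = c("a1", "a2"))
  b <- make_peaks("chr1", 40, 60, name = "b1")
  ov <- find_overlaps(a, b)
  expect_equal(length(ov$components), 1)
  expect_equal(ov$n_overlap_min, 1)
  expect_equal(ov$unique_a, 0)
  expect_equal(ov$unique_b, 0)

  dis <- find_overlaps(a, make_peaks("chr1", 1000, 1100))
  expect_equal(dis$n_overlap_min, 0)
  expect_equal(dis$unique_a, 2)
  expect_equal(dis$unique_b, 1)

  same <- find_overlaps(a, a)
  expect_equal(same$n_overlap_min, 2)

  empty <- find_overlaps(a[0, ], b)
  expect_equal(empty$n_overlap_min, 0)
  expect_equal(length(empty$components), 0)
})

test_that("find_overlaps equals the brute-force graph oracle", {
  set.seed(51)
  for (rep in 1:60) {
    na <- sample(0:15, 1); nb <- sample(1:15, 1)
    chroms <- sample(c("chr1", "chr2"), 2)
    a <- if (na) rand_peaks(na, chrom = sample(chroms, na, TRUE),
                            max_pos = 200) else
      make_peaks(character(), numeric(), numeric(), character())
    b <- rand_peaks(nb, chrom = sample(chroms, nb, TRUE), max_pos = 200)
    minbp <- sample(1:5, 1)
    ov <- find_overlaps(a, b, min_overlap_bp = minbp)
    o <- oracle_overlap(a, b, min_bp = minbp)
    expect_equal(ov$n_overlap_min, o$n_overlap_min)
    expect_equal(ov$unique_a, o$unique_a)
    expect_equal(ov$unique_b, o$unique_b)
    expect_equal(length(ov$components), o$n_components)
    ## symmetry of the min-count
    expect_equal(find_overlaps(b, a,
                               min_overlap_bp = minbp)$n_overlap_min,
                 ov$n_overlap_min)
  }
  ## one larger instance
  a <- rand_peaks(300, max_pos = 5000, max_width = 60)
  b <- rand_peaks(300, max_pos = 5000, max_width = 60)
  ov <- find_overlaps(a, b)
  o <- oracle_overlap(a, b)
  expect_equal(ov$n_overlap_min, o$n_overlap_min)
  expect_equal(ov$unique_a, o$unique_a)
})

test_that("adding a peak to A never decreases the min-count", {
  set.seed(53)
  for (rep in 1:20) {
    a <- rand_peaks(8, max_pos = 300)
    b <- rand_peaks(8, max_pos = 300)
    base <- find_overlaps(a, b)$n_overlap_min
    extra <- rbind(a, rand_peaks(1, max_pos = 300))
    extra$name <- paste0("p", seq_len(nrow(extra)))
    expect_gte(find_overlaps(extra, b)$n_overlap_min, base)
  }
})

test_that("overlap_fraction reports per-side membership", {
  a <- make_peaks("chr1", c(0, 200, 400), c(100, 300, 500))
  b <- make_peaks("chr1", c(50, 250, 1000, 2000),
                  c(80, 260, 1100, 2100))
  ov <- find_overlaps(a, b)
  expect_equal(overlap_fraction(ov, "B"), 0.5)
  expect_equal(overlap_fraction(ov, "A"), 2 / 3)
  none <- find_overlaps(a, make_peaks("chr2", 0, 10))
  expect_equal(overlap_fraction(none, "A"), 0)
  expect_error(overlap_fraction(find_overlaps(a[0, ], b), "A"), "empty")
})

test_that("overlap_by_category reproduces printed-style percentages", {
  ## synthetic set shaped like the printed 105 / 2,250 of 2,352 worked
  ## example: tags overlap, so percentages need not total 100
  n <- 2352
  a <- make_peaks("chr1", seq(0, by = 200, length.out = n),
                  seq(0, by = 200, length.out = n) + 100,
                  name = paste0("m", seq_len(n)))
  b <- a; b$name <- paste0("g", seq_len(n))
  ov <- find_overlaps(a, b)
  cats <- rbind(
    data.frame(peak_id = paste0("m", 1:105), tag = "promoter"),
    data.frame(peak_id = paste0("m", 103:2352), tag = "enhancer"))
  tab <- overlap_by_category(ov, cats, side = "A")
  expect_equal(tab$percentage[tab$tag == "promoter"], 4.5)
  expect_equal(tab$percentage[tab$tag == "enhancer"],
               round(100 * 2250 / 2352, 1))
  expect_equal(attr(tab, "n_overlapped"), 2352)

  untag <- overlap_by_category(ov, data.frame(peak_id = "none",
                                              tag = "promoter"))
  expect_equal(untag$count, 0)
  expect_error(overlap_by_category(find_overlaps(
    a[1:2, ], make_peaks("chr2", 0, 10)), cats), "no overlapped")
})
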