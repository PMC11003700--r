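test_that("promoter windows mirror about the TSS and clip at zero", {
  g <- make_genes(rep("chr1", 3), c("+", "-", "+"),
                  c(5000, 3000, 300), c(7000, 5001, 2300))
  w <- promoter_window(g)
  expect_equal(w$start, c(4000, 4901, 0))
  expect_equal(w$end, c(5100, 6001, 400))
})

test_that("annotate_peaks assigns promoter class and signed distances", {
  g <- make_genes(c("chr1", "chr1"), c("+", "+"), c(5000, 40000),
                  c(7000, 42000), id = c("gA", "gB"))
  pk <- make_peaks("chr1", c(5000, 19900), c(5100, 20100),
                   name = c("prom", "dist"))
  an <- annotate_peaks(pk, g)
  expect_equal(an$element_class, c("promoter", "distal"))
  expect_equal(an$gene_id, c("gA", "gA"))
  expect_equal(an$distance_to_tss, c(50, 15000))

  ## minus-strand sign flip: anchor downstream of a minus TSS is negative
  gm <- make_genes("chr1", "-", 4000, 6001, id = "gM")   # tss 6000
  am <- annotate_peaks(make_peaks("chr1", 6040, 6060), gm)
  expect_equal(am$distance_to_tss, -50)
  expect_error(annotate_peaks(pk, g[0, ]), "empty")
})

test_that("annotate_peaks matches a brute-force nearest-TSS scan", {
  set.seed(41)
  for (rep in 1:40) {
    ng <- sample(3:8, 1)
    gs <- sort(sample(seq(0, 5e4, by = 100), ng))
    g <- make_genes("chr1", sample(c("+", "-"), ng, TRUE), gs,
                    gs + sample(500:2000, ng, TRUE))
    pk <- rand_peaks(6, max_pos = 5e4, max_width = 300)
    an <- annotate_peaks(pk, g)
    anchors <- peak_anchor(pk)
    w <- promoter_window(g)
    for (i in seq_len(nrow(pk))) {
      over <- which(pmin(pk$end[i], w$end) -
                      pmax(pk$start[i], w$start) >= 1)
      expect_equal(an$element_class[i],
                   if (length(over)) "promoter" else "distal")
      cand <- if (length(over)) over else seq_len(ng)
      d <- abs(anchors[i] - g$tss[cand])
      expect_equal(abs(an$distance_to_tss[i]), min(d))
    }
    ## invariant to gene-list order
    perm <- sample(ng)
    expect_equal(annotate_peaks(pk, g[perm, ]), an)
  }
})

test_that("tss_distance_fractions counts the near bin correctly", {
  an <- data.frame(distance_to_tss = c(1000, 6000, 2000, 10000))
  f <- tss_distance_fractions(an, near = 5000)
  expect_equal(f$fraction_within, 0.5)
  expect_equal(f$fraction_beyond, 0.5)
  expect_equal(tss_distance_fractions(
    data.frame(distance_to_tss = rep(0, 4)))$fraction_within, 1)
  expect_error(tss_distance_fractions(
    data.frame(distance_to_tss = NA_real_)), "no annotated")
  set.seed(4)
  d <- sample(-2e4:2e4, 200)
  f <- tss_distance_fractions(data.frame(distance_to_tss = d))
  expect_equal(f$fraction_within, sum(abs(d) <= 5000) / 200)
})

test_that("class_fractions reproduces printed-style percentages", {
  expect_equal(class_fractions(c(promoter = 9299), 19707)$percentage,
               47.2)
  expect_equal(class_fractions(c(promoter = 6723), 11844)$percentage,
               56.8)
  expect_equal(class_fractions(c(x = 0), 10)$percentage, 0)
  expect_error(class_fractions(c(x = 5), 0), "positive")
  expect_error(class_fractions(c(x = 11), 10), "exceeds")
  ## complements of a disjoint split sum to 100
  expect_equal(class_fractions(c(a = 9299), 19707)$percentage +
                 class_fractions(c(b = 19707 - 9299),
                                 19707)$percentage, 100)
})

test_that("positional annotation partitions peaks into promoter/distal", {
  set.seed(43)
  g <- make_genes("chr1", rep("+", 5), seq(5000, 85000, by = 20000),
                  seq(5000, 85000, by = 20000) + 2000)
  pk <- rand_peaks(40, max_pos = 9e4, max_width = 500)
  an <- annotate_peaks(pk, g)
  expect_equal(nrow(an), 40)
  expect_true(all(an$element_class %in% c("promoter", "distal")))
  cf <- class_fractions(an)
  expect_equal(sum(cf$count), 40)
})
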