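test_that("classify_de applies the fold and padj thresholds", {
  expect_equal(classify_de(1.6, 0.01), "up")
  expect_equal(classify_de(1.4, 0.001), "not_de")
  expect_equal(classify_de(-1.6, 0.2), "not_de")
  expect_equal(classify_de(-1.5, 0.049), "down")
  expect_equal(classify_de(1.5, 0.05), "not_de")   # padj strict
  expect_equal(classify_de(c(2, -2, 1.1), c(0.01, 0.01, 0.01)),
               c("up", "down", "not_de"))
})

test_that("build_quadrants reproduces printed-style percentages", {
  ## 521 promoter-down / 434 promoter-up, 368 enhancer-up /
  ## 189 enhancer-down, with some genes bound at both element types
  n_pd <- 521; n_pu <- 434; n_eu <- 368; n_ed <- 189
  gid <- function(p, n) paste0(p, seq_len(n))
  de <- validate_de_table(data.frame(
    gene_id = c(gid("pd", n_pd), gid("pu", n_pu), gid("eu", n_eu),
                gid("ed", n_ed), gid("x", 50)),
    fold_change = c(rep(-2, n_pd), rep(2, n_pu), rep(2, n_eu),
                    rep(-2, n_ed), rep(1, 50)),
    padj = c(rep(0.001, n_pd + n_pu + n_eu + n_ed), rep(0.8, 50)),
    mean_expr_cpm = 10))
  g2e <- rbind(
    data.frame(gene_id = c(gid("pd", n_pd), gid("pu", n_pu)),
               element_class = "promoter"),
    data.frame(gene_id = c(gid("eu", n_eu), gid("ed", n_ed)),
               element_class = "enhancer"),
    ## dual-bound: 30 promoter-down genes also enhancer-bound
    data.frame(gene_id = gid("pd", 30), element_class = "enhancer"))
  q <- build_quadrants(de, g2e)
  cnt <- q$counts
  get <- function(ec, d) cnt[cnt$element_class == ec &
                               cnt$direction == d, ]
  expect_equal(get("promoter", "down")$count, 521)
  expect_equal(get("promoter", "down")$percentage, 54.6)
  expect_equal(get("promoter", "up")$percentage, 45.4)
  expect_equal(get("enhancer", "up")$count, 368)
  expect_equal(get("enhancer", "down")$count, 189 + 30)  # duals add in
  expect_equal(q$n_dual_bound, 30)
  expect_equal(q$n_de, n_pd + n_pu + n_eu + n_ed)
  expect_equal(q$n_de_bound, n_pd + n_pu + n_eu + n_ed)
  expect_equal(q$n_unbound_de, 0)

  ## percentages within an element class sum to 100
  for (ec in c("promoter", "enhancer"))
    expect_equal(sum(cnt$percentage[cnt$element_class == ec]), 100,
                 tolerance = 0.1)

  ## pure printed pairs, no dual binding
  q2 <- build_quadrants(
    validate_de_table(data.frame(
      gene_id = c(gid("e", 557)),
      fold_change = c(rep(2, 368), rep(-2, 189)),
      padj = 0.001, mean_expr_cpm = 1)),
    data.frame(gene_id = gid("e", 557), element_class = "enhancer"))
  expect_equal(q2$counts$percentage[q2$counts$element_class ==
                                      "enhancer"], c(33.9, 66.1))
  ## class with no DE bound genes reports NA percentages
  expect_true(all(is.na(
    q2$counts$percentage[q2$counts$element_class == "promoter"])))
})

test_that("bin_occupancy_change covers the stated bins and their gaps", {
  expect_equal(bin_occupancy_change(100, 80), "down")
  expect_equal(bin_occupancy_change(100, 130), "up")
  expect_equal(bin_occupancy_change(100, 95), "stable")
  expect_equal(bin_occupancy_change(100, 87), "unclassified")
  expect_equal(bin_occupancy_change(100, 115), "unclassified")
  expect_error(bin_occupancy_change(0, 10), "positive")

  ## partition of the ratio line minus the two uncovered bands
  r <- seq(0.5, 2, by = 0.001)
  cat <- bin_occupancy_change(rep(1, length(r)), r)
  expect_true(all(cat[r <= 1 / 1.2] == "down"))
  expect_true(all(cat[r >= 1.2] == "up"))
  expect_true(all(cat[r > 1 / 1.1 & r < 1.1] == "stable"))
  expect_true(all(cat[(r > 1 / 1.2 & r <= 1 / 1.1) |
                        (r >= 1.1 & r < 1.2)] == "unclassified"))
  ## monotone in the knockdown signal
  kd <- seq(150, 50, by = -1)
  lev <- c(up = 3, unclassified = 2, stable = 2, down = 1)
  expect_true(all(diff(lev[bin_occupancy_change(rep(100, length(kd)),
                                                kd)]) <= 0))
})

test_that("compare_class_distribution is the uncorrected 2x2 chi-square", {
  h <- compare_class_distribution(c(10, 10), c(10, 10))
  expect_equal(h$statistic, 0)
  expect_equal(h$p_value, 1)
  expect_equal(h$df, 1)
  expect_equal(compare_class_distribution(c(30, 10),
                                          c(10, 30))$statistic, 20)
  expect_equal(suppressWarnings(compare_class_distribution(
    c(1, 0), c(0, 1)))$statistic, 2)
  expect_error(compare_class_distribution(c(0, 0), c(1, 1)),
               "marginal")
})
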