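test_that("simulated tables are deterministic and identity under zero shift/noise", {
  sp <- small_expr_spec(condition_shifts = list(mut = c(X = 0, A = 0)),
                        gene_noise_sd = 0, replicate_noise_sd = 0)
  t1 <- simulate_expression(sp, 4)
  t2 <- simulate_expression(sp, 4)
  expect_identical(t1, t2)
  rt <- log2_ratio_table(t1, "mut", "control")
  expect_true(all(rt$log2_ratio == 0))
  t3 <- simulate_expression(sp, 5)
  expect_false(identical(t1$control_r1, t3$control_r1))
})

test_that("the X-class median shift is recovered by the ratio median", {
  sp <- expression_spec(genes_per_chromosome = c(I = 500L, X = 1000L),
                        condition_shifts = list(mut = c(X = 0.062, A = 0)),
                        gene_noise_sd = 0.3)
  tab <- simulate_expression(sp, 101)
  rt <- log2_ratio_table(tab, "mut", "control")
  med_x <- median(rt$log2_ratio[rt$chrom == "X"])
  expect_lt(abs(med_x - 0.062), 0.02)
})

test_that("the 1-RPKM filter removes low-expressed genes and zero means", {
  tab <- data.frame(gene_id = c("g1", "g2", "g3"),
                    chrom = c("I", "X", "II"),
                    position_mb = c(1, 2, 3),
                    cond_r1 = c(2, 4, 0.5), cond_r2 = c(2, 4, 0.5),
                    ctrl_r1 = c(2, 2, 0.5), ctrl_r2 = c(2, 2, 0.5))
  rt <- log2_ratio_table(tab, "cond", "ctrl")
  expect_equal(rt$gene_id, c("g1", "g2"))
  expect_equal(rt$log2_ratio, c(0, 1))
  expect_equal(attr(rt, "n_filtered"), 1L)
  # property: no gene with grand mean <= 1 survives in any ratio table
  sp <- small_expr_spec(baseline_log2_mean = 0.5, baseline_log2_sd = 1.5)
  sim <- simulate_expression(sp, 6)
  rt2 <- log2_ratio_table(sim, "treatment", "control")
  cols <- grep("_r\\d+$", names(sim), value = TRUE)
  gm <- rowMeans(sim[, cols])
  expect_true(all(gm[match(rt2$gene_id, sim$gene_id)] > 1))
  expect_error(log2_ratio_table(sim, "absent", "control"), "not present")
})

test_that("rank-sum p-values match the worked 3-vs-3 example and symmetry cases", {
  w <- wilcoxon_rank_sum(c(0.1, 0.2, 0.3), c(-0.1, 0, 0.05), "greater")
  expect_equal(w$p_value, 0.05)     # x takes the top 3 of C(6,3)=20 splits
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3), "two.sided")
  expect_equal(same$p_value, 1)
  big <- wilcoxon_rank_sum(rnorm(200, 5), rnorm(200, 0), "greater")
  expect_lt(big$p_value, 1e-10)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")
})

test_that("exact path equals exhaustive enumeration for combined n <= 10", {
  set.seed(64)
  for (i in 1:20) {
    nx <- sample(1:5, 1); ny <- sample(1:5, 1)
    # draw from a small integer set to force ties
    x <- sample(1:4, nx, replace = TRUE)
    y <- sample(1:4, ny, replace = TRUE)
    for (alt in c("greater", "less", "two.sided")) {
      expect_equal(wilcoxon_rank_sum(x, y, alt)$p_value,
                   enum_rank_sum_p(x, y, alt),
                   tolerance = 1e-12)
    }
  }
})

test_that("implementation agrees with stats::wilcox.test on both paths", {
  set.seed(65)
  # tie-free exact path
  x <- rnorm(5); y <- rnorm(6)
  expect_equal(wilcoxon_rank_sum(x, y, "two.sided")$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(x, y, "greater")$p_value,
               wilcox.test(x, y, alternative = "greater", exact = TRUE)$p.value,
               tolerance = 1e-12)
  # approximation path with ties
  xt <- sample(1:10, 40, replace = TRUE); yt <- sample(1:10, 35, replace = TRUE) + 1
  expect_equal(wilcoxon_rank_sum(xt, yt, "two.sided")$p_value,
               suppressWarnings(wilcox.test(xt, yt, exact = FALSE,
                                            correct = TRUE)$p.value),
               tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(xt, yt, "greater")$p_value,
               suppressWarnings(wilcox.test(xt, yt, alternative = "greater",
                                            exact = FALSE, correct = TRUE)$p.value),
               tolerance = 1e-12)
})

test_that("chromosome shift tests recover generated X and autosome shifts", {
  sp <- small_expr_spec(condition_shifts = list(mut = c(X = 0.062, A = -0.059)))
  tab <- simulate_expression(sp, 7)
  rt <- log2_ratio_table(tab, "mut", "control")
  rep <- chromosome_shift_tests(rt)
  med <- rep$medians
  expect_lt(abs(med$median[med$class == "X"] - 0.062), 0.02)
  expect_lt(abs(med$median[med$class == "autosomes"] + 0.059), 0.02)
  p_main <- rep$tests$p_value[rep$tests$comparison == "X vs autosomes"]
  expect_lt(p_main, 0.001)
  # degenerate: all ratios zero -> medians zero, nothing significant
  rt0 <- make_ratio_table(sprintf("g%d", 1:60),
                          rep(c("I", "II", "III", "IV", "V", "X"), each = 10),
                          rep(0, 60))
  rep0 <- chromosome_shift_tests(rt0)
  expect_true(all(rep0$medians$median == 0))
  expect_true(all(rep0$tests$p_value > 0.05))
  expect_error(chromosome_shift_tests(make_ratio_table("g1", "I", 0.1)),
               "missing chromosome class")
})

test_that("a single shifted autosome is flagged against the rest of the genome", {
  sp <- small_expr_spec(condition_shifts = list(mut = c(V = 0.4)))
  tab <- simulate_expression(sp, 8)
  rt <- log2_ratio_table(tab, "mut", "control")
  rep <- chromosome_shift_tests(rt)
  expect_lt(rep$tests$p_value[rep$tests$comparison == "V vs rest"], 0.001)
  # X (unshifted) should not test greater than autosomes that include V
  expect_gt(rep$tests$p_value[rep$tests$comparison == "X vs autosomes"], 0.05)
})

test_that("X region assignment follows the half-open boundary convention", {
  expect_equal(xterritory:::assign_region(c(2, 4, 15.75, 17, 3.999)),
               c("left", "middle", "right", "right", "left"))
  sp <- small_expr_spec(condition_shifts = list(mut = c(X = 0.08)))
  tab <- simulate_expression(sp, 9)
  rt <- log2_ratio_table(tab, "mut", "control")
  rc <- region_compare(rt)
  expect_equal(rc$medians$region, c("left", "middle", "right"))
  expect_equal(sum(rc$medians$n), sum(rt$chrom == "X"))
  # uniform shift: no pairwise significance between regions
  expect_true(all(rc$tests$p_value > 0.05))
  rt_no_left <- rt[!(rt$chrom == "X" & rt$position_mb < 4), ]
  class(rt_no_left) <- class(rt)
  expect_error(region_compare(rt_no_left), "empty region")
})

test_that("quadrant analysis matches hand enumeration and symmetry", {
  ids <- sprintf("g%d", 1:8)
  ra <- make_ratio_table(ids, c(rep("X", 4), rep("II", 4)),
                         c(0.5, 0.2, -0.3, 0.05, 0.15, -0.2, -0.4, 0.3))
  rb <- make_ratio_table(ids, c(rep("X", 4), rep("II", 4)),
                         c(0.4, -0.15, -0.2, 0.2, 0.11, 0.12, -0.5, 0.02))
  q <- quadrant_analysis(ra, rb, cutoff = 0.1)
  # hand enumeration: X genes: (up,up), (up,down), (down,down), (band,.)
  xq <- q[q$class == "X", ]
  expect_equal(xq$count[xq$category == "up_up"], 1L)
  expect_equal(xq$count[xq$category == "up_down"], 1L)
  expect_equal(xq$count[xq$category == "down_down"], 1L)
  expect_equal(xq$count[xq$category == "within_band"], 1L)
  aq <- q[q$class == "autosomes", ]
  expect_equal(aq$count[aq$category == "up_up"], 1L)   # (0.15, 0.11)
  expect_equal(aq$count[aq$category == "down_up"], 1L) # (-0.2, 0.12)
  expect_equal(aq$count[aq$category == "down_down"], 1L)
  expect_equal(aq$count[aq$category == "within_band"], 1L)
  # all genes up in both tables
  rup <- make_ratio_table(ids, rep("X", 8), rep(0.3, 8))
  qup <- quadrant_analysis(rup, rup, cutoff = 0.1)
  expect_equal(qup$fraction[qup$category == "up_up"], 1)
  # cutoff 0 under symmetric independent noise: ~25% per quadrant, summing to 1
  set.seed(21)
  ids2 <- sprintf("s%d", 1:1000)
  rs1 <- make_ratio_table(ids2, rep("I", 1000), rnorm(1000, 0, 0.3))
  rs2 <- make_ratio_table(ids2, rep("I", 1000), rnorm(1000, 0, 0.3))
  q0 <- quadrant_analysis(rs1, rs2, cutoff = 0)
  expect_equal(sum(q0$fraction), 1, tolerance = 1e-12)
  quads <- q0$fraction[q0$category != "within_band"]
  expect_true(all(abs(quads - 0.25) < 0.03))
  expect_error(quadrant_analysis(rs1, make_ratio_table("zz", "I", 0.1)),
               "empty join")
})

test_that("quadrant fractions per class sum to at most 1 with a positive cutoff", {
  set.seed(22)
  ids <- sprintf("g%d", 1:500)
  ra <- make_ratio_table(ids, rep(c("X", "III"), 250), rnorm(500, 0, 0.2))
  rb <- make_ratio_table(ids, rep(c("X", "III"), 250), rnorm(500, 0, 0.2))
  q <- quadrant_analysis(ra, rb, cutoff = 0.1)
  for (cl in unique(q$class)) {
    expect_equal(sum(q$fraction[q$class == cl]), 1, tolerance = 1e-12)
    expect_lte(sum(q$fraction[q$class == cl & q$category != "within_band"]), 1)
  }
})

test_that("correlation summary reports r and R-squared per chromosome class", {
  set.seed(23)
  n <- 2000
  chroms <- sample(c("I", "II", "III", "IV", "V", "X"), n, replace = TRUE)
  ids <- sprintf("g%d", 1:n)
  a <- rnorm(n, 0, 0.3)
  ra <- make_ratio_table(ids, chroms, a)
  # identity and negation
  cs1 <- correlation_summary(ra, ra)
  expect_true(all(abs(cs1$pearson_r - 1) < 1e-12))
  expect_true(all(abs(cs1$r_squared - 1) < 1e-12))
  rn <- make_ratio_table(ids, chroms, -a)
  cs2 <- correlation_summary(ra, rn)
  expect_true(all(abs(cs2$pearson_r + 1) < 1e-12))
  expect_true(all(abs(cs2$r_squared - 1) < 1e-12))
  # constructed target r = 0.65: b = 0.7 a + noise with matched variance
  noise_sd <- 0.7 * sd(a) * sqrt(1 / 0.65^2 - 1)
  rb <- make_ratio_table(ids, chroms, 0.7 * a + rnorm(n, 0, noise_sd))
  cs3 <- correlation_summary(ra, rb)
  r_all <- cs3$pearson_r[cs3$class == "autosomes"]
  expect_lt(abs(r_all - 0.65), 0.03)
  expect_equal(cs3$r_squared, cs3$pearson_r^2, tolerance = 1e-12)
  # R-squared equals the regression R-squared (independent lm cross-check)
  xsub <- merge(ra, rb, by = "gene_id")
  xx <- xsub[xsub$chrom.x == "X", ]
  fit <- summary(lm(log2_ratio.y ~ log2_ratio.x, data = xx))
  expect_equal(cs3$r_squared[cs3$class == "X"], fit$r.squared, tolerance = 1e-9)
  expect_error(correlation_summary(ra, make_ratio_table(ids, chroms, rep(1, n))),
               "zero variance")
})
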