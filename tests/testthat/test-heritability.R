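test_that("block partition attributes variance correctly in limiting designs", {
  # all variance between blocks
  bp <- suppressWarnings( # R flags the F test on an exact fit
    block_partition(c(0, 0, 0, 2, 2, 2), rep(c("b1", "b2"), each = 3))
  )
  expect_equal(bp$stats$pct_block, 100)
  expect_equal(bp$residuals, rep(1, 6)) # re-centered on the grand mean

  # identical block means: no block variance
  bp2 <- block_partition(c(1, 2, 3, 1, 2, 3), rep(c("b1", "b2"), each = 3))
  expect_equal(bp2$stats$pct_block, 0)
  expect_equal(bp2$stats$f_block, 0)

  # single block is flagged, not an error
  bp3 <- block_partition(c(1, 2, 3), rep("b1", 3))
  expect_equal(bp3$stats$pct_block, 0)
  expect_true(is.na(bp3$stats$f_block))
})

test_that("block share recovers a known generating percentage", {
  # 5 blocks x 200 males, block variance 3% of total
  set.seed(201)
  reps <- 60
  pb <- replicate(reps, {
    blocks <- rep(1:5, each = 200)
    b_eff <- rnorm(5, 0, sqrt(0.03))
    y <- b_eff[blocks] + rnorm(1000, 0, sqrt(0.97))
    block_partition(y, blocks)$stats$pct_block
  })
  expect_gt(mean(pb), 1.5)
  expect_lt(mean(pb), 4.5)
})

test_that("heritability has the right closed forms in degenerate designs", {
  # zero within-line variance: H2 = 1
  h <- heritability(c(0, 0, 2, 2), c("l1", "l1", "l2", "l2"))
  expect_equal(h$h2, 1)

  # constant trait: defined as 0
  h0 <- heritability(rep(5, 6), rep(c("l1", "l2", "l3"), each = 2))
  expect_equal(h0$h2, 0)

  expect_error(heritability(1:4, paste0("l", 1:4)), "singleton")
  expect_error(heritability(1:4, rep("l1", 4)), "2 lines")
})

test_that("balanced-design estimator equals the intraclass correlation and anova(lm) mean squares", {
  set.seed(5)
  n_l <- 10L
  n_m <- 6L
  y <- rnorm(n_l * n_m)
  lines <- rep(paste0("l", seq_len(n_l)), each = n_m)
  h <- heritability(y, lines)

  an <- anova(lm(y ~ factor(lines)))
  ms_l <- an$`Mean Sq`[1]
  ms_e <- an$`Mean Sq`[2]
  expect_equal(h$f_line, ms_l / ms_e, tolerance = 1e-12)
  expect_equal(h$p_line, an$`Pr(>F)`[1], tolerance = 1e-12)
  # balanced: n0 = n_m, the classical intraclass correlation
  s2l <- (ms_l - ms_e) / n_m
  expect_equal(h$h2, s2l / (s2l + ms_e), tolerance = 1e-12)
})

test_that("the unbalanced n0 coefficient matches the textbook formula", {
  set.seed(6)
  n_i <- c(3L, 8L, 5L, 12L)
  lines <- rep(paste0("l", 1:4), times = n_i)
  y <- rnorm(sum(n_i)) + rep(rnorm(4), times = n_i)
  h <- heritability(y, lines)
  an <- anova(lm(y ~ factor(lines)))
  N <- sum(n_i)
  n0 <- (N - sum(n_i^2) / N) / 3
  s2l <- (an$`Mean Sq`[1] - an$`Mean Sq`[2]) / n0
  expect_equal(h$sigma2_line, s2l, tolerance = 1e-12)
})

test_that("H2 estimates are centered on the generating value and respond monotonically", {
  set.seed(301)
  reps <- 80
  for (h2_true in c(0, 0.10)) {
    est <- replicate(reps, {
      d <- simulate_trait_panel(n_lines = 80, males_per_line = 12, h2 = h2_true)
      heritability(d$value, d$line_id)$h2
    })
    expect_lt(abs(mean(est) - h2_true), 0.025)
  }
  # monotone in the generating variance (in expectation over a grid)
  means <- vapply(c(0, 0.05, 0.15), function(h2_true) {
    mean(replicate(40, {
      d <- simulate_trait_panel(n_lines = 60, males_per_line = 10, h2 = h2_true)
      heritability(d$value, d$line_id)$h2
    }))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("negative estimates occur under the null and the line test is calibrated", {
  set.seed(302)
  est <- replicate(150, {
    d <- simulate_trait_panel(n_lines = 40, males_per_line = 6, h2 = 0)
    h <- heritability(d$value, d$line_id)
    c(h$h2, h$p_line)
  })
  expect_gt(mean(est[1, ] < 0), 0.2) # null estimates go negative often
  expect_lt(abs(mean(est[2, ] < 0.05) - 0.05), 0.05)
})

test_that("decompose_trait chains block and line and hits the deterministic limits", {
  # deterministic line effect, no noise: P_L ~ 0
  d <- tibble::tibble(
    line_id = rep(paste0("l", 1:6), each = 4),
    block_id = rep(c("b1", "b2"), times = 12),
    value = rep(c(1, 2, 3, 4, 5, 6), each = 4) + rep(c(0, 0.01), times = 12)
  )
  out <- decompose_trait(d, value)
  expect_lt(out$p_line, 1e-10)
  expect_gt(out$h2_pct, 99)
  expect_equal(out$mean, mean(d$value))

  # arcsin switch works on proportion traits
  dp <- dplyr::mutate(d, value = value / 10)
  out2 <- decompose_trait(dp, value, arcsin = TRUE)
  expect_equal(out2$mean, mean(dp$value)) # mean reported on the raw scale
})

test_that("Bonferroni critical values match the published families", {
  expect_equal(bonferroni(0.05, 25), 0.002)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(signif(bonferroni(0.05, 2.4e6), 3), 2.08e-8)
  expect_error(bonferroni(1.2, 10), "alpha")
  expect_error(bonferroni(0.05, 0), "n_tests")
})

test_that("line-mean correlations behave on constructed vectors", {
  x <- tibble::tibble(line_id = paste0("l", 1:8), value = 1:8)
  expect_equal(line_mean_correlation(x, x)$r, 1)

  y <- tibble::tibble(line_id = paste0("l", 1:4), value = c(1, -1, -1, 1))
  z <- tibble::tibble(line_id = paste0("l", 1:4), value = c(1, 1, -1, -1))
  expect_equal(line_mean_correlation(y, z)$r, 0)

  expect_error(
    line_mean_correlation(x[1:2, ], x[1:2, ]),
    "at least 3 shared lines"
  )
  # intersection of lines is used
  w <- tibble::tibble(line_id = paste0("l", 3:10), value = 3:10)
  expect_equal(line_mean_correlation(x, w)$n, 6L)
})

test_that("duration means drop short copulations and empty lines", {
  ev <- tibble::tibble(
    line_id = c("l1", "l1", "l1", "l2"),
    duration = c(4.9, 10, 20, 3)
  )
  expect_warning(out <- copulation_duration_means(ev), "l2")
  expect_equal(out$value, 15)
  expect_equal(out$n_pairs, 2L)

  ev2 <- tibble::tibble(line_id = "l1", duration = c(1, 2))
  expect_warning(out2 <- copulation_duration_means(ev2), "l1")
  expect_equal(nrow(out2), 0L)
})

test_that("generated durations carry the configured negative coupling to E-to-A", {
  panel <- small_panel()
  true_ea <- panel$truth$true_e_to_a
  dm <- copulation_duration_means(panel$durations)
  x <- tibble::tibble(line_id = names(true_ea), value = unname(true_ea))
  r <- line_mean_correlation(x, dm)$r
  expect_lt(r, 0) # sign recovered
})
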