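test_that("correlation PCA has the expected spectral structure", {
  set.seed(31)
  X <- matrix(rnorm(2000 * 10), 2000, 10)
  pca <- correlation_pca(X)
  expect_true(all(abs(pca$values - 1) < 0.15)) # near-identity correlation
  expect_equal(sum(pca$values), 10, tolerance = 1e-8) # trace identity

  # duplicated column forces a leading eigenvalue >= 2
  X2 <- cbind(X, X[, 1])
  pca2 <- correlation_pca(X2)
  expect_gte(pca2$values[1], 2 - 1e-8)

  # constant columns are dropped with a warning
  X3 <- cbind(X[, 1:3], const = 1)
  expect_warning(pca3 <- correlation_pca(X3), "constant")
  expect_length(pca3$values, 3L)

  expect_error(correlation_pca(X[1:2, ]), "at least 3 lines")
})

test_that("Kaiser retention counts eigenvalues above 1", {
  expect_equal(kaiser_retain(c(2.5, 1.2, 0.9, 0.4)), 2L)
  expect_warning(k0 <- kaiser_retain(c(0.9, 0.5)), "nothing retained")
  expect_equal(k0, 0L)
  expect_error(kaiser_retain(c(1, 2)), "descending")
})

test_that("a panel built from 7 latent factors typically retains 7", {
  set.seed(32)
  hits <- replicate(5, {
    # every variable loads on exactly one of 7 latent factors
    Ltrue <- matrix(0, 25, 7)
    for (m in 1:7) Ltrue[((m - 1) * 3 + 1):(m * 3), m] <- 1
    Ltrue[cbind(22:25, 4:7)] <- 1
    F <- matrix(rnorm(400 * 7), 400, 7)
    X <- F %*% t(Ltrue) + matrix(rnorm(400 * 25, 0, 0.5), 400, 25)
    pca <- correlation_pca(X)
    kaiser_retain(pca$values)
  })
  expect_gte(sum(hits == 7L), 4)
})

test_that("principal-component loadings scale eigenvectors by root eigenvalues", {
  set.seed(33)
  X <- matrix(rnorm(200 * 6), 200, 6)
  pca <- correlation_pca(X)
  fm <- pc_factor(pca, 3)
  for (m in 1:3) {
    expect_equal(
      unname(fm$loadings[, m]),
      pca$vectors[, m] * sqrt(pca$values[m])
    )
  }
  expect_equal(fm$variance_explained, 100 * pca$values[1:3] / 6, ignore_attr = TRUE)
  expect_error(pc_factor(pca, 7), "1\\.\\.6")

  # rank-1 structure: one factor reproduces the generating weights up to sign
  w <- c(3, 2, 1, 0.5)
  f <- rnorm(500)
  X1 <- outer(f, w) + matrix(rnorm(500 * 4, 0, 0.05), 500, 4)
  pca1 <- correlation_pca(X1)
  fm1 <- pc_factor(pca1, 1)
  ld <- fm1$loadings[, 1] * sign(fm1$loadings[1, 1])
  expect_true(all(ld > 0.97)) # standardized rank-1: all near-unit loadings
})

test_that("varimax conserves communalities and is orthogonal", {
  set.seed(34)
  for (i in 1:10) {
    L <- matrix(rnorm(25 * 4), 25, 4)
    rot <- varimax_rotate(L)
    expect_lt(max(abs(rowSums(rot^2) - rowSums(L^2))), 1e-8)
    R <- attr(rot, "rotation")
    expect_lt(max(abs(t(R) %*% R - diag(4))), 1e-10)
    expect_true(all(diff(attr(rot, "criterion_trace")) >= -1e-12))
  }
})

test_that("varimax matches the stats oracle and solves the 45-degree toy exactly", {
  set.seed(35)
  for (i in 1:5) {
    L <- matrix(rnorm(25 * 3), 25, 3)
    mine <- varimax_rotate(L)
    ref <- stats::varimax(L, normalize = TRUE, eps = 1e-12)
    cm <- ethoscan:::varimax_criterion(mine)
    cr <- ethoscan:::varimax_criterion(unclass(ref$loadings))
    expect_gt(cm, cr - 1e-3) # at least as good as the oracle's optimum
  }

  # two orthogonal simple factors mixed by 45 degrees
  S <- cbind(c(rep(1, 6), rep(0, 6)), c(rep(0, 6), rep(1, 6)))
  ang <- pi / 4
  M <- S %*% matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2)
  rec <- varimax_rotate(M, kaiser_normalize = FALSE)
  # grid-search oracle over rotation angles
  crit_at <- function(a) {
    G <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
    ethoscan:::varimax_criterion(M %*% G)
  }
  best_grid <- max(vapply(seq(0, pi / 2, length.out = 5000), crit_at, numeric(1)))
  expect_gt(ethoscan:::varimax_criterion(rec), best_grid - 1e-6)
  # axis-aligned solution recovered up to column order/sign
  expect_equal(sort(round(abs(rec), 6)[abs(rec) > 0.5]), rep(1, 12))

  # already-simple structure: rotation changes nothing materially
  simple <- varimax_rotate(S, kaiser_normalize = FALSE)
  expect_lt(max(abs(abs(simple) - S)), 1e-8)
})

test_that("factor model end-to-end: rotation invariants on synthetic line means", {
  panel <- small_panel()
  tr <- male_transitions(panel$observations)
  lm_ <- line_mean_transitions(tr, adjust_block = TRUE)
  fm_un <- fit_factor_model(lm_, rotate = FALSE)
  fm_rot <- varimax_rotate(fm_un)

  # communalities invariant under rotation
  expect_lt(max(abs(fm_rot$communalities - fm_un$communalities)), 1e-8)
  # total variance explained invariant under rotation
  expect_equal(sum(fm_rot$variance_explained), sum(fm_un$variance_explained),
    tolerance = 1e-8
  )
  # loading-vector correlation between the first two factors is computable
  r12 <- cor(fm_rot$loadings[, 1], fm_rot$loadings[, 2])
  expect_true(is.finite(r12))

  tl <- tidy(fm_rot)
  expect_equal(nrow(tl), nrow(fm_rot$loadings) * ncol(fm_rot$loadings))
  gl <- glance(fm_rot)
  expect_true(gl$rotated)

  wide <- loading_table(fm_rot)
  expect_true(all(c("from", "to", "F1") %in% names(wide)))
})

test_that("factor scores are centered, reproducible, and separate built-in groups", {
  set.seed(36)
  # two groups of lines differing along one latent direction
  g <- rep(c(0, 4), each = 40)
  X <- cbind(
    g + rnorm(80), g + rnorm(80), g + rnorm(80),
    rnorm(80), rnorm(80)
  )
  colnames(X) <- paste0("v", 1:5)
  fm <- fit_factor_model(X, k = 2)
  df <- as.data.frame(X)
  df$line_id <- paste0("l", 1:80)
  sc <- factor_scores(df, fm)
  expect_lt(max(abs(colMeans(sc[, c("F1", "F2")]))), 1e-8)

  # a line at the variable-wise mean scores zero
  at_mean <- as.data.frame(rbind(colMeans(X)))
  # scores computed against the fitted standardization
  Z <- (as.matrix(at_mean) - fm$center) / fm$scale
  expect_lt(max(abs(Z)), 1e-12)

  # duplicate lines get identical scores
  expect_equal(unlist(sc[1, c("F1", "F2")]), unlist(factor_scores(df, fm)[1, c("F1", "F2")]))

  # group separation along the dominant factor
  sep <- abs(mean(sc$F1[g == 4]) - mean(sc$F1[g == 0]))
  expect_gt(sep, 1)

  bad <- df
  names(bad)[1] <- "other"
  expect_error(factor_scores(bad, fm), "lacks model variable")
})
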