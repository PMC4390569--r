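make_geno <- function(dosage, chrom = NULL) {
  n_v <- nrow(dosage)
  ethoscan:::new_ethoscan_genotypes(
    tibble::tibble(
      variant_id = rownames(dosage) %||% paste0("v", seq_len(n_v)),
      chrom = chrom %||% rep("2L", n_v),
      pos = seq_len(n_v) * 10L,
      ref = "A", alt = "T"
    ),
    `rownames<-`(dosage, rownames(dosage) %||% paste0("v", seq_len(n_v)))
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("TSV and VCF genotype readers produce identical matrices", {
  panel <- small_panel()
  dir <- withr::local_tempdir()
  write_panel(panel, dir)
  g_tsv <- read_genotypes(file.path(dir, "genotypes.tsv"))
  expect_equal(unname(g_tsv$dosage), unname(panel$genotypes$dosage))
  expect_equal(g_tsv$variants$variant_id, panel$genotypes$variants$variant_id)

  skip_if_not_installed("vcfR")
  g_vcf <- read_genotypes(file.path(dir, "genotypes.vcf"))
  expect_equal(g_vcf$dosage, g_tsv$dosage)
  expect_equal(g_vcf$variants$pos, g_tsv$variants$pos)
})

test_that("heterozygous calls follow the configured policy", {
  skip_if_not_installed("vcfR")
  d <- matrix(c(0, 2, 1, 0), 2, 2, dimnames = list(c("v1", "v2"), c("l1", "l2")))
  g <- make_geno(d) # heterozygous call sits at v1 x l2
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(g, path)
  miss <- read_genotypes(path, het_policy = "missing")
  expect_true(is.na(miss$dosage["v1", "l2"]))
  expect_equal(miss$dosage["v2", "l1"], 2)
  dose <- read_genotypes(path, het_policy = "dosage")
  expect_equal(dose$dosage["v1", "l2"], 1)
})

test_that("minor-line-count filtering removes monomorphic and rare variants", {
  d <- rbind(
    mono = rep(0, 166),
    rare = c(rep(2, 4), rep(0, 162)),
    common = c(rep(2, 80), rep(0, 86))
  )
  colnames(d) <- paste0("l", 1:166)
  g <- make_geno(d)
  expect_message(f4 <- filter_variants(g, 4), "removed")
  expect_setequal(f4$variants$variant_id, c("rare", "common")) # 4/162 split kept
  expect_message(f5 <- filter_variants(g, 5), "removed")
  expect_setequal(f5$variants$variant_id, "common")
  f0 <- filter_variants(g, 0)
  expect_equal(nrow(f0$dosage), 3L) # threshold 0 is the identity
})

test_that("the scan matches closed-form regression on a perfect fit", {
  d <- matrix(c(0, 0, 2, 2), 1, 4, dimnames = list("v1", paste0("l", 1:4)))
  g <- make_geno(d)
  ph <- tibble::tibble(line_id = paste0("l", 1:4), value = c(0, 0, 1, 1))
  res <- assoc_scan(ph, g)
  expect_equal(res$beta, 0.5, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-10)

  # genotype orthogonal to phenotype: effect ~ 0, P ~ 1
  d2 <- matrix(c(0, 2, 0, 2), 1, 4, dimnames = list("v1", paste0("l", 1:4)))
  ph2 <- tibble::tibble(line_id = paste0("l", 1:4), value = c(1, 1, -1, -1))
  res2 <- assoc_scan(ph2, make_geno(d2))
  expect_equal(res2$beta, 0, tolerance = 1e-12)
  expect_equal(res2$p_value, 1, tolerance = 1e-10)
})

test_that("vectorized and per-variant paths agree with lm to 1e-10", {
  set.seed(41)
  n <- 60L
  lines <- paste0("l", seq_len(n))
  y <- rnorm(n)
  G <- matrix(2 * rbinom(20 * n, 1, 0.3), 20, n, dimnames = list(paste0("v", 1:20), lines))
  cov <- tibble::tibble(line_id = lines, c1 = rnorm(n), c2 = rbinom(n, 1, 0.5))
  ph <- tibble::tibble(line_id = lines, value = y)

  res <- assoc_scan(ph, make_geno(G), covariates = cov)
  for (i in c(1, 7, 20)) {
    fit <- lm(y ~ G[i, ] + cov$c1 + cov$c2)
    co <- summary(fit)$coefficients
    expect_equal(res$beta[i], co[2, 1], tolerance = 1e-10)
    expect_equal(res$se[i], co[2, 2], tolerance = 1e-10)
    expect_equal(res$p_value[i], co[2, 4], tolerance = 1e-10)
  }

  # force the per-variant (missing-data) path and compare with lm on complete cases
  G_na <- G
  G_na[3, 1:5] <- NA
  res_na <- assoc_scan(ph, make_geno(G_na), covariates = cov)
  keep <- !is.na(G_na[3, ])
  fit3 <- lm(y[keep] ~ G_na[3, keep] + cov$c1[keep] + cov$c2[keep])
  expect_equal(res_na$beta[3], summary(fit3)$coefficients[2, 1], tolerance = 1e-10)
  expect_equal(res_na$n[3], sum(keep))
  # other variants are unaffected by one variant's missingness
  expect_equal(res_na$beta[1], res$beta[1], tolerance = 1e-12)
})

test_that("permuting line labels destroys a causal signal", {
  set.seed(42)
  n <- 100L
  lines <- paste0("l", seq_len(n))
  g <- 2 * rbinom(n, 1, 0.3)
  y <- 0.5 * g + rnorm(n)
  G <- matrix(g, 1, n, dimnames = list("causal", lines))
  ph <- tibble::tibble(line_id = lines, value = y)
  p_obs <- assoc_scan(ph, make_geno(G))$p_value
  expect_lt(p_obs, 1e-4)
  perm_p <- replicate(30, {
    ph_perm <- tibble::tibble(line_id = lines, value = sample(y))
    assoc_scan(ph_perm, make_geno(G))$p_value
  })
  expect_gt(mean(perm_p > 0.05), 0.8) # null-distributed after permutation
})

test_that("power at the causal variant rises with effect size", {
  set.seed(43)
  n <- 120L
  lines <- paste0("l", seq_len(n))
  mean_logp <- vapply(c(0, 0.3, 0.6), function(eff) {
    mean(replicate(25, {
      g <- 2 * rbinom(n, 1, 0.3)
      y <- eff * g + rnorm(n)
      G <- matrix(g, 1, n, dimnames = list("v", lines))
      -log10(assoc_scan(tibble::tibble(line_id = lines, value = y), make_geno(G))$p_value)
    }))
  }, numeric(1))
  expect_true(all(diff(mean_logp) > 0))
})

test_that("QQ coordinates follow the uniform reference", {
  expect_equal(qq_points(0.5)$expected, -log10(0.5))
  set.seed(44)
  pts <- qq_points(runif(5000))
  expect_lt(max(abs(pts$expected - pts$observed)[pts$expected < 2]), 0.35)
  expect_warning(qq_points(c(0, 0.5)), "clamped")
  expect_error(qq_points(c(-0.1)), "\\[0, 1\\]")
})

test_that("hit tables apply the strict Bonferroni and suggestive tiers", {
  res <- tibble::tibble(
    variant_id = paste0("v", 1:4),
    chrom = "2L", pos = 1:4, n = 100,
    beta = 1, se = 1, t = 1,
    p_value = c(1e-9, 5e-6, 0.01, NA)
  )
  hits <- significant_hits(res, alpha = 0.05, n_tests = 2.4e6)
  expect_equal(signif(attr(hits, "critical_p"), 3), 2.08e-8)
  expect_equal(hits$tier, c("significant", "suggestive"))

  empty <- significant_hits(res[0, ])
  expect_equal(nrow(empty), 0L)
})
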