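#' Panel-average joint transition matrix used as the generator base
#'
#' The panel-wide mean joint transition probabilities between the five
#' condensed categories, renormalized to sum to exactly 1 (the published
#' per-cell means are rounded to 2 significant digits, so their raw sum
#' drifts from 1). Copulation is strongly absorbing (E to E carries most
#' of the mass) and disengagement is the next most common state.
#'
#' @return A 5 x 5 joint probability matrix (rows: from, columns: to)
#'   summing to 1.
#' @export
dgrp_base_transitions <- function() {
  m <- matrix(
    c(
      0.23,   0.025,  0.023,  0.0049, 0.015,
      0.019,  0.022,  0.014,  0.0034, 0.0093,
      0.017,  0.012,  0.042,  0.087,  0.015,
      0.0039, 0.0029, 0.0080, 0.0050, 0.0030,
      0.017,  0.0023, 0.0043, 0.0020, 0.69
    ),
    nrow = 5, byrow = TRUE,
    dimnames = list(MMP_CATEGORIES, MMP_CATEGORIES)
  )
  m / sum(m)
}

#' Specification of a synthetic courtship study
#'
#' Bundles every ground-truth parameter of the synthetic study design:
#' panel size and replication, the base transition structure,
#' between-line and between-block dispersion, the two-group noninitiator
#' structure, the causal variant, and the copulation-duration coupling.
#' Defaults emulate the real study design: 166 inbred lines, 10-15 males
#' per line assayed across 5 blocks, 30 scans per male, a fifth of lines
#' carrying a ~12% noninitiator rate, and a biallelic causal variant
#' acting on the copulation-to-disengagement (E to A) transition.
#'
#' @param n_lines Number of inbred lines.
#' @param males_per_line Integer range (length-2) of males per line,
#'   sampled uniformly.
#' @param n_blocks Number of experimental blocks; lines are assigned to
#'   blocks at random.
#' @param T Scans per male.
#' @param base_joint 5 x 5 joint base matrix (summing to 1).
#' @param concentration Dirichlet concentration for between-line variation
#'   of conditional transition rows; smaller values give more line
#'   variance and larger realized heritability. The default was calibrated
#'   once so the realized broad-sense heritability of the E-to-E joint
#'   phenotype is near 0.095 at the default design.
#' @param block_weight Mixing weight of a block-specific tilt matrix into
#'   each male's transition rows; calibrated so the block share of MMP
#'   variance is a few percent.
#' @param block_concentration Dirichlet concentration of the block tilt
#'   matrices around the base.
#' @param noninit_frac_lines Fraction of lines with a nonzero
#'   noninitiator rate (the "threshold" group).
#' @param noninit_rate Within-line noninitiator probability for threshold
#'   lines.
#' @param n_variants Number of biallelic variants to simulate.
#' @param causal_effect Amount of conditional probability moved from
#'   E-to-E onto E-to-A in lines homozygous for the causal allele.
#' @param duration_r Target correlation between line-mean copulation
#'   duration and the line's true E-to-A rate (negative: lines that
#'   disengage from copulation sooner copulate for less time).
#' @param duration_mean Panel mean copulation duration, minutes.
#' @param duration_pairs Pairs assayed per line in the duration assay.
#' @param tie_rule Emulate the scan-sampling tie rule (when the chain
#'   advances between scans the more copulation-like ordinal of the
#'   category is recorded).
#' @return A list of class `ethoscan_spec`.
#' @export
panel_spec <- function(n_lines = 166L,
                       males_per_line = c(10L, 15L),
                       n_blocks = 5L,
                       T = 30L,
                       base_joint = dgrp_base_transitions(),
                       concentration = 22,
                       block_weight = 0.35,
                       block_concentration = 80,
                       noninit_frac_lines = 0.2,
                       noninit_rate = 0.122,
                       n_variants = 1000L,
                       causal_effect = 0.05,
                       duration_r = -0.35,
                       duration_mean = 20,
                       duration_pairs = 10L,
                       tie_rule = TRUE) {
  stopifnot(
    n_lines >= 2L, length(males_per_line) == 2L, males_per_line[1] >= 1L,
    males_per_line[1] <= males_per_line[2],
    n_blocks >= 1L, T >= 2L,
    all(base_joint >= 0), abs(sum(base_joint) - 1) < 1e-8,
    concentration > 0, block_weight >= 0, block_weight <= 1,
    noninit_frac_lines >= 0, noninit_frac_lines <= 1,
    noninit_rate >= 0, noninit_rate <= 1,
    n_variants >= 1L, causal_effect >= 0,
    duration_r >= -1, duration_r <= 1
  )
  structure(
    list(
      n_lines = as.integer(n_lines),
      males_per_line = as.integer(males_per_line),
      n_blocks = as.integer(n_blocks),
      T = as.integer(T),
      base_joint = base_joint,
      concentration = concentration,
      block_weight = block_weight,
      block_concentration = block_concentration,
      noninit_frac_lines = noninit_frac_lines,
      noninit_rate = noninit_rate,
      n_variants = as.integer(n_variants),
      causal_effect = causal_effect,
      duration_r = duration_r,
      duration_mean = duration_mean,
      duration_pairs = as.integer(duration_pairs),
      tie_rule = tie_rule
    ),
    class = "ethoscan_spec"
  )
}

# one Dirichlet draw; zero alphas stay exactly zero
rdirichlet_row <- function(alpha) {
  g <- numeric(length(alpha))
  pos <- alpha > 0
  g[pos] <- rgamma(sum(pos), shape = alpha[pos])
  s <- sum(g)
  if (s == 0) stop("degenerate Dirichlet draw (all-zero alphas)", call. = FALSE)
  g / s
}

#' Simulate per-line conditional transition matrices
#'
#' Draws each line's row-conditional transition matrix from independent
#' Dirichlet distributions centered on the base conditional rows with a
#' common concentration: row alpha = concentration * base_row. Smaller
#' concentration means more between-line dispersion, hence a larger
#' realized heritability of the transition phenotypes.
#'
#' @param spec An [panel_spec()] object.
#' @param seed Integer seed; the draw is deterministic given it.
#' @return A list of `n_lines` row-stochastic 5 x 5 matrices, named
#'   `line_001`...
#' @export
simulate_line_matrices <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "ethoscan_spec"))
  set.seed(seed)
  base_cond <- joint_to_conditional(spec$base_joint)
  out <- lapply(seq_len(spec$n_lines), function(i) {
    m <- t(apply(base_cond, 1, function(row) rdirichlet_row(spec$concentration * row)))
    dimnames(m) <- list(MMP_CATEGORIES, MMP_CATEGORIES)
    m
  })
  names(out) <- sprintf("line_%03d", seq_len(spec$n_lines))
  out
}

#' Simulate one male's scan-sampled ordinal sequence
#'
#' With probability `noninit_rate` the male is a noninitiator and every
#' scan is drawn uniformly from ordinal scores \{1, 2\} (he never engages).
#' Otherwise a length-T category chain is run from starting state A (the
#' pair begins separated by the divider), and each category is mapped back
#' to an ordinal score uniformly within its preimage; under the tie rule,
#' a scan where the chain has advanced records the more copulation-like
#' ordinal of the category.
#'
#' @param cond 5 x 5 row-stochastic conditional matrix.
#' @param noninit_rate Probability the male never initiates.
#' @param T Number of scans.
#' @param tie_rule Apply the tie rule (default `TRUE`).
#' @return Integer vector of T ordinal scores in 1..8. Uses the current
#'   RNG stream (seed management belongs to the caller).
#' @export
simulate_male <- function(cond, noninit_rate = 0, T = 30L, tie_rule = TRUE) {
  stopifnot(is.matrix(cond), all(dim(cond) == c(5L, 5L)), all(cond >= 0),
            max(abs(rowSums(cond) - 1)) < 1e-8)
  if (noninit_rate > 0 && runif(1) < noninit_rate) {
    return(sample(1:2, T, replace = TRUE))
  }
  preimage <- list(1:2, 3:4, 5L, 6L, 7:8)
  states <- integer(T)
  states[1] <- 1L # category A
  for (t in 2:T) {
    states[t] <- sample.int(5L, 1L, prob = cond[states[t - 1L], ])
  }
  ordinal <- integer(T)
  for (t in seq_len(T)) {
    pre <- preimage[[states[t]]]
    if (tie_rule && t > 1L && states[t] > states[t - 1L]) {
      ordinal[t] <- max(pre)
    } else {
      ordinal[t] <- if (length(pre) == 1L) pre else sample(pre, 1L)
    }
  }
  ordinal
}

#' Simulate a complete synthetic courtship study
#'
#' Generates an entire study bundle with known ground truth: a long-format
#' observation table (scan-sampled ordinal scores for every male), a
#' biallelic genotype matrix with one designated causal variant acting on
#' the E-to-A conditional rate, per-line covariates (a Wolbachia-like
#' binary and one continuous axis, both phenotype-neutral), per-pair
#' copulation durations negatively coupled to the line's true E-to-A
#' rate, and the full ground truth needed to score parameter recovery.
#'
#' @param spec An [panel_spec()] object.
#' @param seed Integer seed; the whole bundle is reproducible from it.
#' @return A list of class `ethoscan_panel`: `observations`, `genotypes`
#'   (an `ethoscan_genotypes`), `covariates`, `durations`, `truth` (list:
#'   line matrices, per-line noninitiator rates, block assignment and tilt
#'   matrices, causal variant id/effect, true per-line E-to-A conditional
#'   rate), and `spec`.
#' @export
simulate_panel <- function(spec = panel_spec(), seed = 1L) {
  stopifnot(inherits(spec, "ethoscan_spec"))
  line_mats <- simulate_line_matrices(spec, seed = seed)
  set.seed(seed + 1L)
  line_ids <- names(line_mats)
  n <- spec$n_lines

  # two-group noninitiator structure
  n_thresh <- round(spec$noninit_frac_lines * n)
  thresh_lines <- sample(line_ids, n_thresh)
  noninit_rate <- setNames(rep(0, n), line_ids)
  noninit_rate[thresh_lines] <- spec$noninit_rate

  # genotypes: inbred biallelic calls, allele frequency uniform in [.05, .5]
  freq <- runif(spec$n_variants, 0.05, 0.5)
  dosage <- matrix(
    2 * rbinom(spec$n_variants * n, 1L, rep(freq, times = n)),
    nrow = spec$n_variants, ncol = n,
    dimnames = list(sprintf("var_%05d", seq_len(spec$n_variants)), line_ids)
  )
  causal_id <- rownames(dosage)[which.min(abs(freq - 0.3))]
  carriers <- line_ids[dosage[causal_id, ] == 2]

  # causal effect: shift conditional E row mass from E->E to E->A
  for (ln in carriers) {
    m <- line_mats[[ln]]
    shift <- min(spec$causal_effect, m["E", "E"])
    m["E", "A"] <- m["E", "A"] + shift
    m["E", "E"] <- m["E", "E"] - shift
    line_mats[[ln]] <- m
  }
  true_ea <- vapply(line_mats, function(m) m["E", "A"], numeric(1))

  # block structure: each line sits in one block; blocks tilt the rows
  block_of <- setNames(sample(rep_len(seq_len(spec$n_blocks), n)), line_ids)
  base_cond <- joint_to_conditional(spec$base_joint)
  block_mats <- lapply(seq_len(spec$n_blocks), function(b) {
    m <- t(apply(base_cond, 1, function(row) rdirichlet_row(spec$block_concentration * row)))
    dimnames(m) <- list(MMP_CATEGORIES, MMP_CATEGORIES)
    m
  })

  n_males <- sample(seq(spec$males_per_line[1], spec$males_per_line[2]), n, replace = TRUE)
  obs <- purrr::map2_dfr(line_ids, n_males, function(ln, nm) {
    eff <- (1 - spec$block_weight) * line_mats[[ln]] +
      spec$block_weight * block_mats[[block_of[[ln]]]]
    purrr::map_dfr(seq_len(nm), function(j) {
      seq_ord <- simulate_male(eff, noninit_rate[[ln]], spec$T, spec$tie_rule)
      tibble::tibble(
        line_id = ln,
        block_id = paste0("block_", block_of[[ln]]),
        trial_id = paste0("trial_", ((j - 1L) %/% 8L) + 1L),
        arena = as.character(((j - 1L) %% 8L) + 1L),
        male_id = sprintf("%s_m%02d", ln, j),
        timepoint = 0:(spec$T - 1L),
        ordinal_score = seq_ord
      )
    })
  })

  # phenotype-neutral covariates (Wolbachia-like binary, one continuous axis)
  covariates <- tibble::tibble(
    line_id = line_ids,
    wolbachia = rbinom(n, 1L, 0.5),
    rel_axis1 = rnorm(n)
  )

  # copulation durations: line means negatively coupled to true E->A rate
  x <- as.vector(scale(true_ea))
  r <- spec$duration_r
  sigma_line <- 2.5 # between-line duration spread, minutes
  if (abs(r) > 0 && abs(r) < 1 && sd(x) > 0) {
    slope <- r * sigma_line # corr r: signal sd |r|*sigma, noise sd sqrt(1-r^2)*sigma
    noise_sd <- sqrt(1 - r^2) * sigma_line
    line_dur <- spec$duration_mean + slope * x + rnorm(n, 0, noise_sd)
  } else {
    line_dur <- spec$duration_mean + rnorm(n, 0, sigma_line)
  }
  durations <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(
      line_id = line_ids[i],
      pair = seq_len(spec$duration_pairs),
      duration = pmax(rnorm(spec$duration_pairs, line_dur[i], 1.5), 0)
    )
  })

  structure(
    list(
      observations = obs,
      genotypes = new_ethoscan_genotypes(
        tibble::tibble(
          variant_id = rownames(dosage),
          chrom = ifelse(rownames(dosage) == causal_id, "3R", "2L"),
          pos = seq_len(spec$n_variants) * 100L,
          ref = "A", alt = "T"
        ),
        dosage
      ),
      covariates = covariates,
      durations = durations,
      truth = list(
        line_matrices = line_mats,
        noninit_rate = noninit_rate,
        threshold_lines = sort(thresh_lines),
        block_of = block_of,
        block_matrices = block_mats,
        causal_variant = causal_id,
        causal_effect = spec$causal_effect,
        true_e_to_a = true_ea,
        line_duration_mean = setNames(line_dur, line_ids)
      ),
      spec = spec
    ),
    class = "ethoscan_panel"
  )
}

#' @export
print.ethoscan_panel <- function(x, ...) {
  cat(sprintf(
    "<synthetic panel>  %d lines, %d males, %d scans each; %d variants (causal: %s)\n",
    x$spec$n_lines, length(unique(x$observations$male_id)),
    x$spec$T, x$spec$n_variants, x$truth$causal_variant
  ))
  invisible(x)
}

#' Simulate per-male trait values with a known heritability
#'
#' Direct Gaussian simulation of a single quantitative trait at the study
#' design: line effects with variance `h2` and residuals with variance
#' `1 - h2` (total variance 1), optionally with block effects layered on
#' top. Used for calibration and estimator-recovery checks where the full
#' behavioral chain is unnecessary.
#'
#' @param n_lines Number of lines.
#' @param males_per_line Males per line (scalar).
#' @param h2 Generating broad-sense heritability in \[0, 1).
#' @param n_blocks Number of blocks (lines split evenly); block effects
#'   have standard deviation `block_sd`.
#' @param block_sd Between-block standard deviation (default 0).
#' @return Tibble: `line_id`, `block_id`, `value`. Uses the current RNG
#'   stream.
#' @export
simulate_trait_panel <- function(n_lines = 166L, males_per_line = 12L, h2 = 0.1,
                                 n_blocks = 1L, block_sd = 0) {
  stopifnot(h2 >= 0, h2 < 1)
  line_ids <- sprintf("line_%03d", seq_len(n_lines))
  block_of <- rep_len(seq_len(n_blocks), n_lines)
  line_eff <- rnorm(n_lines, 0, sqrt(h2))
  block_eff <- rnorm(n_blocks, 0, block_sd)
  tibble::tibble(
    line_id = rep(line_ids, each = males_per_line),
    block_id = paste0("block_", rep(block_of, each = males_per_line)),
    value = rep(line_eff, each = males_per_line) +
      rep(block_eff[block_of], each = males_per_line) +
      rnorm(n_lines * males_per_line, 0, sqrt(1 - h2))
  )
}

#' Write a synthetic panel to disk in the pipeline's input formats
#'
#' Emits `observations.tsv`, `genotypes.tsv`, `genotypes.vcf`,
#' `covariates.tsv`, `durations.tsv`, and `ground_truth.json` under `dir`.
#'
#' @param panel An `ethoscan_panel` from [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "ethoscan_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(panel$observations, file.path(dir, "observations.tsv"), progress = FALSE)
  geno_tbl <- dplyr::bind_cols(
    panel$genotypes$variants,
    tibble::as_tibble(panel$genotypes$dosage)
  )
  readr::write_tsv(geno_tbl, file.path(dir, "genotypes.tsv"), progress = FALSE)
  write_genotypes_vcf(panel$genotypes, file.path(dir, "genotypes.vcf"))
  readr::write_tsv(panel$covariates, file.path(dir, "covariates.tsv"), progress = FALSE)
  readr::write_tsv(panel$durations, file.path(dir, "durations.tsv"), progress = FALSE)
  truth <- panel$truth
  truth$line_matrices <- lapply(truth$line_matrices, function(m) unname(as.vector(t(m))))
  truth$block_matrices <- lapply(truth$block_matrices, function(m) unname(as.vector(t(m))))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write an inbred-line genotype matrix as minimal VCF 4.2
#'
#' One sample column per line; calls are `0/0`, `1/1`, or `./.`
#' (dosage 1, if present, is written as `0/1`).
#'
#' @param geno An `ethoscan_genotypes` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "ethoscan_genotypes"))
  v <- geno$variants
  d <- geno$dosage
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d) & d == 0] <- "0/0"
  gt[!is.na(d) & d == 1] <- "0/1"
  gt[!is.na(d) & d == 2] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ethoscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      colnames(d)
    ), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(d)), function(i) {
    paste(c(
      v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i], v$alt[i],
      ".", "PASS", ".", "GT", gt[i, ]
    ), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
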