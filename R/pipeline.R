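#' Run the full courtship-pattern analysis end to end
#'
#' Orchestrates every stage on a set of inputs: per-male scoring, per-male
#' and line-mean transition matrices, variance decomposition of the MMP
#' score and all 25 transition phenotypes, the noninitiator mixture
#' comparison, the factor analysis of transition structure, the
#' copulation-duration correlation (if durations are supplied), and the
#' line-means association scan (if genotypes are supplied). All stages are
#' deterministic given the inputs and `seed`.
#'
#' @param observations Long-format observation table (see
#'   [read_observations()]).
#' @param durations Optional per-pair copulation durations (`line_id`,
#'   `duration`, minutes).
#' @param genotypes Optional `ethoscan_genotypes` object.
#' @param covariates Optional per-line covariates for the scan.
#' @param assoc_phenotype Transition column scanned against genotypes
#'   (default `"E_A"`, the most heritable transition).
#' @param alpha,n_tests Bonferroni family for the transition table.
#' @param min_minor_lines Variant filter threshold (see
#'   [filter_variants()]).
#' @param exclude_noninitiators Drop noninitiating males before the
#'   transition analyses (default `FALSE`: they are retained, since
#'   noninitiation is itself line-dependent biology).
#' @param seed Seed for the (only) stochastic stage, mixture
#'   initialization under k-means; the default quantile init is fully
#'   deterministic.
#' @return A list of class `ethoscan_run`: `scores`, `transitions`,
#'   `line_means`, `mmp_decomposition`, `transition_decomposition`,
#'   `noninit_proportions`, `mixture_comparison`, `mixture_fits`,
#'   `factor_model`, `factor_scores`, `duration_correlation` (or NULL),
#'   `assoc` (or NULL), `hits` (or NULL).
#' @export
run_pipeline <- function(observations,
                         durations = NULL,
                         genotypes = NULL,
                         covariates = NULL,
                         assoc_phenotype = "E_A",
                         alpha = 0.05,
                         n_tests = 25L,
                         min_minor_lines = 4L,
                         exclude_noninitiators = FALSE,
                         seed = 1L) {
  observations <- validate_observations(observations)
  scores <- score_males(observations)

  noninit <- noninitiator_proportions(scores)
  fits <- list(
    exponential = fit_exponential(noninit$prop_noninitiator),
    normal2 = fit_normal2(noninit$prop_noninitiator, seed = seed)
  )
  mixture_comparison <- compare_fits(fits)

  if (exclude_noninitiators) {
    keep <- scores |>
      dplyr::filter(!.data$noninitiator) |>
      dplyr::select(dplyr::all_of(male_key_cols()))
    observations <- dplyr::semi_join(observations, keep, by = male_key_cols())
  }

  transitions <- male_transitions(observations)
  line_means <- line_mean_transitions(transitions, adjust_block = TRUE)

  mmp_decomposition <- decompose_trait(scores, .data$mmp_score,
    trait_name = "MMP (summary)"
  )
  transition_decomposition <- decompose_transitions(transitions,
    alpha = alpha, n_tests = n_tests
  )

  fm <- fit_factor_model(line_means)
  fs <- factor_scores(line_means, fm)

  duration_correlation <- NULL
  if (!is.null(durations)) {
    dur_means <- copulation_duration_means(durations)
    pheno <- line_means |>
      dplyr::select("line_id", value = dplyr::all_of(assoc_phenotype))
    duration_correlation <- line_mean_correlation(pheno, dur_means)
  }

  assoc <- NULL
  hits <- NULL
  if (!is.null(genotypes)) {
    geno <- filter_variants(genotypes, min_minor_lines)
    pheno <- line_means |>
      dplyr::select("line_id", value = dplyr::all_of(assoc_phenotype))
    assoc <- assoc_scan(pheno, geno, covariates = covariates)
    hits <- significant_hits(assoc)
  }

  structure(
    list(
      scores = scores,
      transitions = transitions,
      line_means = line_means,
      mmp_decomposition = mmp_decomposition,
      transition_decomposition = transition_decomposition,
      noninit_proportions = noninit,
      mixture_comparison = mixture_comparison,
      mixture_fits = fits,
      factor_model = fm,
      factor_scores = fs,
      duration_correlation = duration_correlation,
      assoc = assoc,
      hits = hits
    ),
    class = "ethoscan_run"
  )
}

#' @export
print.ethoscan_run <- function(x, ...) {
  cat("<ethoscan run>\n")
  cat(sprintf(
    "  %d males in %d lines; MMP H2 = %.2f%% (P = %.3g)\n",
    nrow(x$scores), nrow(x$line_means),
    x$mmp_decomposition$h2_pct, x$mmp_decomposition$p_line
  ))
  best <- x$mixture_comparison$model[1]
  cat(sprintf(
    "  noninitiator distribution: %s preferred (dAIC = %.2f)\n",
    best, x$mixture_comparison$delta_aic[2]
  ))
  cat(sprintf(
    "  factor model: %d factor(s), %.1f%% variance\n",
    ncol(x$factor_model$loadings), sum(x$factor_model$variance_explained)
  ))
  if (!is.null(x$assoc)) {
    cat(sprintf(
      "  association scan: %d variants, %d significant hit(s)\n",
      nrow(x$assoc), sum(x$hits$tier == "significant", na.rm = TRUE)
    ))
  }
  invisible(x)
}
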