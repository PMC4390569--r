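#' Partition trait variance attributable to experimental block
#'
#' One-way fixed-effect ANOVA of a per-male trait on block. Reports the
#' percent of the total sum of squares attributable to block
#' (`pct_block = 100 * SS_block / SS_total`), the block F ratio and its P
#' value, and returns the block-adjusted residuals (observed value minus
#' block mean, re-centered on the grand mean) used by the downstream line
#' analysis.
#'
#' @param values Numeric per-male trait values.
#' @param blocks Block labels, same length as `values`.
#' @return A list with `stats` (one-row tibble: `pct_block`, `f_block`,
#'   `p_block`) and `residuals` (numeric, same length and order as input).
#'   With a single block, `pct_block` is 0 and the F statistic is `NA`.
#' @export
block_partition <- function(values, blocks) {
  stopifnot(length(values) == length(blocks))
  keep <- is.finite(values) & !is.na(blocks)
  if (!all(keep)) stop("values/blocks contain missing entries", call. = FALSE)
  blocks <- factor(blocks)
  if (nlevels(blocks) < 2L) {
    return(list(
      stats = tibble::tibble(pct_block = 0, f_block = NA_real_, p_block = NA_real_),
      residuals = values - mean(values) + mean(values)
    ))
  }
  fit <- lm(values ~ blocks)
  an <- anova(fit)
  ss_block <- an$`Sum Sq`[1]
  ss_total <- sum(an$`Sum Sq`)
  stats <- tibble::tibble(
    pct_block = 100 * ss_block / ss_total,
    f_block = an$`F value`[1],
    p_block = an$`Pr(>F)`[1]
  )
  list(
    stats = stats,
    residuals = values - ave(values, blocks) + mean(values)
  )
}

#' Broad-sense heritability by method-of-moments variance components
#'
#' One-way random-effects ANOVA of (block-adjusted) per-male values on
#' line. The among-line variance component is estimated from the expected
#' mean squares, `sigma2_L = (MS_line - MS_error) / n0`, with the
#' unbalanced-design coefficient `n0 = (N - sum(n_i^2) / N) / (a - 1)`
#' where `n_i` are the per-line sample sizes and `a` the number of lines.
#' Broad-sense heritability is `H2 = sigma2_L / (sigma2_L + sigma2_e)`.
#' Estimates are deliberately NOT truncated at zero: under weak line
#' effects `MS_line` can fall below `MS_error` and the estimate goes
#' negative, which is informative about sampling noise.
#'
#' @param values Numeric per-male values (typically block residuals).
#' @param lines Line labels, same length as `values`.
#' @return One-row tibble: `h2` (proportion, may be negative), `f_line`,
#'   `p_line`, `sigma2_line`, `sigma2_error`, `n_lines`, `n_males`.
#' @export
heritability <- function(values, lines) {
  stopifnot(length(values) == length(lines))
  lines <- factor(lines)
  a <- nlevels(lines)
  if (a < 2L) stop("need at least 2 lines", call. = FALSE)
  n_i <- as.vector(table(lines))
  N <- length(values)
  if (N - a < 1L) {
    stop("no within-line degrees of freedom (all lines are singletons)", call. = FALSE)
  }
  grand <- mean(values)
  line_means <- tapply(values, lines, mean)
  ss_line <- sum(n_i * (line_means - grand)^2)
  ss_error <- sum((values - line_means[as.integer(lines)])^2)
  ms_line <- ss_line / (a - 1)
  ms_error <- ss_error / (N - a)
  n0 <- (N - sum(n_i^2) / N) / (a - 1)
  sigma2_line <- (ms_line - ms_error) / n0
  denom <- sigma2_line + ms_error
  h2 <- if (denom == 0) 0 else sigma2_line / denom # constant trait: no variance at all
  f_line <- ms_line / ms_error
  p_line <- pf(f_line, a - 1, N - a, lower.tail = FALSE)
  tibble::tibble(
    h2 = h2, f_line = f_line, p_line = p_line,
    sigma2_line = sigma2_line, sigma2_error = ms_error,
    n_lines = a, n_males = N
  )
}

#' Full variance decomposition of one trait (block, then line)
#'
#' Chains [block_partition()] and [heritability()]: block effects are
#' removed first as a fixed effect, then line enters as a random effect on
#' the block residuals. This sequential residualization mirrors reporting
#' of block percent-variance separately from heritability.
#'
#' @param data A data frame with one row per male.
#' @param trait Column (tidy-eval) holding the trait value.
#' @param line,block Columns (tidy-eval) holding line and block labels.
#' @param trait_name Label used in the output; defaults to the trait
#'   column's name.
#' @param arcsin If `TRUE`, apply [arcsin_transform()] to the trait first
#'   (only valid for proportions).
#' @return One-row tibble with columns `trait`, `pct_block`, `f_block`,
#'   `p_block`, `h2_pct` (heritability as a percent), `f_line`, `p_line`,
#'   `mean` (raw trait mean).
#' @examples
#' panel <- simulate_panel(panel_spec(n_lines = 20, n_variants = 10), seed = 1)
#' scores <- score_males(panel$observations)
#' decompose_trait(scores, mmp_score, line_id, block_id)
#' @export
decompose_trait <- function(data, trait, line = line_id, block = block_id,
                            trait_name = NULL, arcsin = FALSE) {
  values <- dplyr::pull(data, {{ trait }})
  lines <- dplyr::pull(data, {{ line }})
  blocks <- dplyr::pull(data, {{ block }})
  if (is.null(trait_name)) trait_name <- rlang::as_name(rlang::enquo(trait))
  raw_mean <- mean(values)
  if (arcsin) values <- arcsin_transform(values)
  bp <- block_partition(values, blocks)
  h <- heritability(bp$residuals, lines)
  tibble::tibble(
    trait = trait_name,
    pct_block = bp$stats$pct_block,
    f_block = bp$stats$f_block,
    p_block = bp$stats$p_block,
    h2_pct = 100 * h$h2,
    f_line = h$f_line,
    p_line = h$p_line,
    mean = raw_mean
  )
}

#' Variance decomposition of all 25 transition phenotypes
#'
#' Applies [decompose_trait()] to each of the 25 joint transition
#' probabilities, producing the transition-level heritability table
#' (one row per from/to pair) with Bonferroni significance stars for the
#' configured test family.
#'
#' @param transitions Per-male transition tibble from [male_transitions()].
#' @param alpha Familywise error rate for the Bonferroni family.
#' @param n_tests Number of tests in the family (default 25, the
#'   transition phenotypes).
#' @param arcsin Analyze arcsine-square-root transformed probabilities.
#' @return A 25-row tibble: `from`, `to`, the [decompose_trait()] columns,
#'   and `significant` (logical, `p_line <= alpha / n_tests`).
#' @export
decompose_transitions <- function(transitions, alpha = 0.05, n_tests = 25L,
                                  arcsin = FALSE) {
  cols <- transition_cols()
  stopifnot(all(c(cols, "line_id", "block_id") %in% names(transitions)))
  crit <- bonferroni(alpha, n_tests)
  purrr::map_dfr(cols, function(cl) {
    decompose_trait(transitions, dplyr::all_of(cl), trait_name = cl, arcsin = arcsin)
  }) |>
    tidyr::separate_wider_delim("trait", "_", names = c("from", "to"), cols_remove = FALSE) |>
    dplyr::mutate(significant = .data$p_line <= crit) |>
    dplyr::relocate("from", "to")
}

#' Bonferroni-corrected critical P value
#'
#' @param alpha Familywise error rate in (0, 1).
#' @param n_tests Number of tests in the family (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni(0.05, 25) # 0.002
#' bonferroni(0.05, 2.4e6) # 2.083e-08
#' @export
bonferroni <- function(alpha, n_tests) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  if (!is.finite(n_tests) || n_tests < 1) {
    stop("`n_tests` must be >= 1", call. = FALSE)
  }
  alpha / n_tests
}

#' Pearson correlation between two sets of line means
#'
#' Correlates two per-line trait tables on the intersection of their lines
#' (e.g. a transition probability against copulation duration measured in
#' an independent assay).
#'
#' @param x,y Data frames with columns `line_id` and `value`, or named
#'   numeric vectors keyed by line.
#' @return One-row tibble: `r`, `p_value` (two-sided t test), `n` shared
#'   lines.
#' @export
line_mean_correlation <- function(x, y) {
  x <- as_line_values(x)
  y <- as_line_values(y)
  shared <- intersect(names(x), names(y))
  if (length(shared) < 3L) {
    stop("need at least 3 shared lines (got ", length(shared), ")", call. = FALSE)
  }
  ct <- cor.test(x[shared], y[shared], method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate),
    p_value = ct$p.value,
    n = length(shared)
  )
}

as_line_values <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("line_id", "value") %in% names(x)))
    setNames(x$value, as.character(x$line_id))
  } else {
    stopifnot(!is.null(names(x)))
    x
  }
}

#' Per-line mean copulation duration
#'
#' Averages copulation durations per line after dropping events shorter
#' than `min_duration` minutes (brief couplings are scored as failed
#' intromission attempts, not copulations). Lines with no surviving events
#' are excluded with a warning.
#'
#' @param events Data frame with columns `line_id` and `duration`
#'   (minutes).
#' @param min_duration Minimum duration retained, in minutes (default 5).
#' @return Tibble: `line_id`, `value` (mean duration), `n_pairs`.
#' @export
copulation_duration_means <- function(events, min_duration = 5) {
  stopifnot(all(c("line_id", "duration") %in% names(events)))
  if (any(events$duration < 0)) stop("durations must be nonnegative", call. = FALSE)
  all_lines <- unique(as.character(events$line_id))
  kept <- dplyr::filter(events, .data$duration >= min_duration)
  out <- kept |>
    dplyr::summarise(
      value = mean(.data$duration),
      n_pairs = dplyr::n(),
      .by = "line_id"
    ) |>
    dplyr::mutate(line_id = as.character(.data$line_id))
  dropped <- setdiff(all_lines, out$line_id)
  if (length(dropped)) {
    warning("line(s) with no copulations >= ", min_duration, " min excluded: ",
      paste(head(dropped, 5L), collapse = ", "),
      call. = FALSE
    )
  }
  out
}
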