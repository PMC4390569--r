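#' Condense ordinal courtship scores into behavior categories
#'
#' Maps the 8-point ordinal male mating progression (MMP) scale onto five
#' condensed categories: scores 1-2 (no movement / movement without
#' engagement) become A, 3-4 (orienting / pursuing) become B, 5 (wing
#' vibration) becomes C, 6 (genital licking) becomes D, and 7-8 (attempted
#' or successful copulation) become E. The condensation exists because scan
#' sampling every 30 s cannot reliably distinguish the paired behaviors.
#'
#' @param ordinal_score Integer vector with values in 1..8.
#' @return Character vector of categories in `A`..`E`, same length as input.
#' @examples
#' condense_score(1:8)
#' @export
condense_score <- function(ordinal_score) {
  check_ordinal(ordinal_score)
  map <- c("A", "A", "B", "B", "C", "D", "E", "E")
  map[ordinal_score]
}

#' Summed MMP score of one male's scan-sampled sequence
#'
#' The MMP summary score is the sum of the ordinal score over all scans.
#' For the standard 30-scan assay it ranges from 30 (male never moves)
#' to 240 (pair copulating at every scan).
#'
#' @param ordinal_seq Integer vector of ordinal scores in 1..8, length >= 1.
#' @return A single integer.
#' @examples
#' mmp_score(rep(1L, 30)) # 30
#' mmp_score(rep(8L, 30)) # 240
#' @export
mmp_score <- function(ordinal_seq) {
  if (length(ordinal_seq) == 0L) {
    stop("`ordinal_seq` must be non-empty", call. = FALSE)
  }
  check_ordinal(ordinal_seq)
  as.integer(sum(ordinal_seq))
}

#' Flag males that never initiate courtship
#'
#' A noninitiator never scores above 2 (movement) at any scan: he may move
#' but never orients toward, pursues, or courts the female.
#'
#' @inheritParams mmp_score
#' @return `TRUE` if every score is <= 2.
#' @examples
#' flag_noninitiator(c(1, 2, 1, 2)) # TRUE
#' flag_noninitiator(c(1, 3, 1))    # FALSE
#' @export
flag_noninitiator <- function(ordinal_seq) {
  if (length(ordinal_seq) == 0L) {
    stop("`ordinal_seq` must be non-empty", call. = FALSE)
  }
  check_ordinal(ordinal_seq)
  all(ordinal_seq <= 2)
}

#' Arcsine square-root transform of a proportion
#'
#' Classical variance-stabilizing transform for proportion data,
#' `asin(sqrt(p))`; used as an optional analysis scale for the
#' frequency-of-behavior traits.
#'
#' @param p Numeric vector of proportions in \[0, 1\].
#' @return `asin(sqrt(p))`, in radians (0 to pi/2).
#' @examples
#' arcsin_transform(c(0, 0.25, 1)) # 0, pi/6, pi/2
#' @export
arcsin_transform <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  asin(sqrt(p))
}

#' Per-male summary of an observation table
#'
#' Collapses a validated long-format observation table into one row per male
#' with the ordinal sequence length, summed MMP score, noninitiator flag,
#' and the per-scan frequency of each ordinal score and condensed category
#' (the Table-2-style frequency traits).
#'
#' @param observations A data frame with columns `line_id`, `block_id`,
#'   `trial_id`, `arena`, `male_id`, `timepoint`, `ordinal_score`
#'   (as returned by [read_observations()]).
#' @param frequencies If `TRUE` (default), append per-male frequency columns
#'   `freq_1`..`freq_8` and `freq_A`..`freq_E`.
#' @return A tibble with one row per male: the five key columns, `n_obs`,
#'   `mmp_score`, `noninitiator`, and optionally the frequency columns.
#' @examples
#' obs <- simulate_panel(panel_spec(n_lines = 4, n_variants = 10), seed = 1)$observations
#' score_males(obs)
#' @export
score_males <- function(observations, frequencies = TRUE) {
  observations <- validate_observations(observations)
  keys <- male_key_cols()
  out <- observations |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "timepoint")))) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      mmp_score = as.integer(sum(.data$ordinal_score)),
      noninitiator = all(.data$ordinal_score <= 2),
      .by = dplyr::all_of(keys)
    )
  if (frequencies) {
    freq <- observations |>
      dplyr::summarise(
        {
          sc <- .data$ordinal_score
          n <- length(sc)
          f_ord <- tabulate(sc, nbins = 8L) / n
          f_cat <- tabulate(match(condense_score(sc), MMP_CATEGORIES), nbins = 5L) / n
          tibble::as_tibble(as.list(setNames(
            c(f_ord, f_cat),
            c(paste0("freq_", 1:8), paste0("freq_", MMP_CATEGORIES))
          )))
        },
        .by = dplyr::all_of(keys)
      )
    out <- dplyr::left_join(out, freq, by = keys)
  }
  out
}

check_ordinal <- function(x) {
  if (any(!is.finite(x)) || any(x != as.integer(x)) || any(x < 1) || any(x > 8)) {
    bad <- which(!is.finite(x) | x != suppressWarnings(as.integer(x)) | x < 1 | x > 8)
    stop(
      "ordinal scores must be integers in 1..8; offending position(s): ",
      paste(head(bad, 5L), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(x)
}
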