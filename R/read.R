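#' Read a long-format scan-sampling observation table
#'
#' Reads one row per (male, timepoint) from TSV or CSV. Column names can be
#' remapped via `col_map` so files produced elsewhere need not be renamed.
#' Records are validated: ordinal scores must be integers in 1..8 and each
#' male's timepoints must be unique and contiguous from 0. Males flagged in
#' an optional `exclude` column (injured/dead flies) are dropped at read
#' time.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter; `NULL` (default) infers `\t` for `.tsv`
#'   and `,` for `.csv`.
#' @param col_map Named character vector mapping required internal names
#'   (`line_id`, `block_id`, `trial_id`, `arena`, `male_id`, `timepoint`,
#'   `ordinal_score`) to the file's column names. Defaults to identity.
#' @param strict If `TRUE` (default), males with missing timepoints are
#'   excluded with a warning; if `FALSE` they are kept.
#' @return A validated observation tibble.
#' @export
read_observations <- function(path, delim = NULL, col_map = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)

  required <- c(male_key_cols(), "timepoint", "ordinal_score")
  if (is.null(col_map)) col_map <- setNames(required, required)
  missing_map <- setdiff(required, names(col_map))
  if (length(missing_map)) {
    stop("`col_map` must cover column(s): ", paste(missing_map, collapse = ", "),
      call. = FALSE
    )
  }
  missing_cols <- setdiff(unname(col_map[required]), names(raw))
  if (length(missing_cols)) {
    stop("input is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  obs <- raw |>
    dplyr::rename(!!!setNames(unname(col_map[required]), required))

  if ("exclude" %in% names(obs)) {
    excl <- as.logical(obs$exclude)
    excl[is.na(excl)] <- FALSE
    if (any(excl)) {
      message("dropping ", sum(excl), " observation row(s) marked exclude")
    }
    obs <- obs[!excl, , drop = FALSE]
    obs$exclude <- NULL
  }
  validate_observations(obs, strict = strict)
}

#' Validate an observation table
#'
#' Checks the structural invariants of a long-format observation table:
#' required columns present, integer ordinal scores in 1..8, no duplicated
#' (male, timepoint) pairs, and per-male timepoints contiguous from 0.
#'
#' @inheritParams score_males
#' @param strict If `TRUE`, males with non-contiguous timepoints are
#'   excluded with a warning; if `FALSE`, they are kept as-is.
#' @return The validated (possibly filtered) tibble, with key columns as
#'   character and `timepoint`/`ordinal_score` as integers.
#' @export
validate_observations <- function(observations, strict = TRUE) {
  required <- c(male_key_cols(), "timepoint", "ordinal_score")
  missing_cols <- setdiff(required, names(observations))
  if (length(missing_cols)) {
    stop("observation table is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  obs <- tibble::as_tibble(observations) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(male_key_cols()), as.character))

  sc <- obs$ordinal_score
  bad <- which(!is.finite(sc) | sc != suppressWarnings(as.integer(sc)) | sc < 1 | sc > 8)
  if (length(bad)) {
    stop("ordinal_score out of range or non-integer at row(s): ",
      paste(head(bad, 10L), collapse = ", "),
      call. = FALSE
    )
  }
  tp <- obs$timepoint
  if (any(!is.finite(tp) | tp != suppressWarnings(as.integer(tp)) | tp < 0)) {
    stop("timepoint must be a nonnegative integer index", call. = FALSE)
  }
  obs <- dplyr::mutate(obs,
    timepoint = as.integer(.data$timepoint),
    ordinal_score = as.integer(.data$ordinal_score)
  )

  dup <- obs |>
    dplyr::count(dplyr::across(dplyr::all_of(c(male_key_cols(), "timepoint")))) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop("duplicated (male, timepoint) pair(s), e.g. male ",
      dup$male_id[1], " timepoint ", dup$timepoint[1],
      call. = FALSE
    )
  }

  per_male <- obs |>
    dplyr::summarise(
      contiguous = identical(sort(.data$timepoint), seq(0L, length(.data$timepoint) - 1L)),
      .by = dplyr::all_of(male_key_cols())
    )
  bad_males <- dplyr::filter(per_male, !.data$contiguous)
  if (nrow(bad_males)) {
    if (strict) {
      warning(
        nrow(bad_males), " male(s) with non-contiguous timepoints excluded (e.g. male ",
        bad_males$male_id[1], " of line ", bad_males$line_id[1], ")",
        call. = FALSE
      )
      obs <- dplyr::anti_join(obs, bad_males, by = male_key_cols())
    } else {
      warning(nrow(bad_males), " male(s) have non-contiguous timepoints (kept: strict = FALSE)",
        call. = FALSE
      )
    }
  }
  obs
}

#' Write an observation table or per-male summary to TSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_output <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
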