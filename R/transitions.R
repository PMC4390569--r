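#' Count first-order transitions in a condensed behavior sequence
#'
#' Tallies the 5 x 5 matrix of transitions between successive scans,
#' including self-transitions: `counts[x, y]` is the number of positions i
#' with `seq[i] == x` and `seq[i+1] == y`. A length-T sequence yields
#' T - 1 transitions.
#'
#' @param condensed_seq Character (or factor) vector of categories `A`..`E`,
#'   length >= 2.
#' @return A 5 x 5 integer matrix with dimnames `A`..`E` (rows: state at t,
#'   columns: state at t + 1).
#' @examples
#' count_transitions(c("A", "A", "B", "B", "E"))
#' @export
count_transitions <- function(condensed_seq) {
  condensed_seq <- as.character(condensed_seq)
  if (length(condensed_seq) < 2L) {
    stop("need at least 2 observations to count transitions", call. = FALSE)
  }
  idx <- match(condensed_seq, MMP_CATEGORIES)
  if (anyNA(idx)) {
    stop("sequence contains categories outside A..E", call. = FALSE)
  }
  n <- length(idx)
  from <- factor(idx[-n], levels = 1:5)
  to <- factor(idx[-1], levels = 1:5)
  counts <- table(from, to)
  m <- matrix(as.integer(counts), 5, 5,
    dimnames = list(MMP_CATEGORIES, MMP_CATEGORIES)
  )
  m
}

#' Convert transition counts to joint transition probabilities
#'
#' Divides every cell by the total number of transitions, so the 25 entries
#' of the resulting matrix sum to 1. This whole-matrix (joint) normalization
#' is the phenotype scale used throughout: each cell is the proportion of
#' all of a male's scan-to-scan transitions that were x -> y, not a
#' row-conditional probability. See [joint_to_conditional()] for the
#' row-stochastic view.
#'
#' @param counts A 5 x 5 nonnegative count matrix, e.g. from
#'   [count_transitions()].
#' @return A 5 x 5 numeric matrix summing to 1.
#' @export
transition_probabilities <- function(counts) {
  stopifnot(is.matrix(counts), all(dim(counts) == c(5L, 5L)))
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  n <- sum(counts)
  if (n == 0) stop("no transitions to normalize (n_transitions = 0)", call. = FALSE)
  m <- counts / n
  dimnames(m) <- list(MMP_CATEGORIES, MMP_CATEGORIES)
  m
}

#' Per-male transition probability phenotypes
#'
#' Builds each male's joint transition probability matrix from the
#' observation table and returns it flattened to the 25 phenotype columns
#' `A_A`, `A_B`, ..., `E_E` (row-major: from-state then to-state), one row
#' per male. These 25 columns are the transition phenotypes analysed for
#' heritability.
#'
#' @inheritParams score_males
#' @return A tibble with the five male key columns, `n_transitions`, and 25
#'   probability columns summing to 1 within each row.
#' @export
male_transitions <- function(observations) {
  observations <- validate_observations(observations)
  keys <- male_key_cols()
  observations |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys, "timepoint")))) |>
    dplyr::summarise(
      {
        seq_cat <- condense_score(.data$ordinal_score)
        probs <- transition_probabilities(count_transitions(seq_cat))
        tibble::as_tibble(c(
          list(n_transitions = length(seq_cat) - 1L),
          as.list(setNames(as.vector(t(probs)), transition_cols()))
        ))
      },
      .by = dplyr::all_of(keys)
    )
}

#' Line-mean transition matrices
#'
#' Averages the 25 per-male transition probabilities within each line
#' (unweighted arithmetic mean over males), optionally after removing block
#' effects per phenotype. Because every male's matrix sums to 1, each line
#' mean also sums to 1 (block adjustment preserves this: residuals are
#' re-centered on the grand mean).
#'
#' @param transitions Per-male transition tibble from [male_transitions()].
#' @param adjust_block If `TRUE`, each of the 25 phenotypes is replaced by
#'   its block-adjusted value (residual from block means plus grand mean)
#'   before averaging.
#' @return A tibble with `line_id`, `n_males`, and the 25 mean probability
#'   columns.
#' @export
line_mean_transitions <- function(transitions, adjust_block = FALSE) {
  cols <- transition_cols()
  stopifnot(all(cols %in% names(transitions)), "line_id" %in% names(transitions))
  if (nrow(transitions) == 0L) stop("no males supplied", call. = FALSE)
  x <- transitions
  if (adjust_block) {
    stopifnot("block_id" %in% names(x))
    x <- x |>
      dplyr::mutate(dplyr::across(
        dplyr::all_of(cols),
        ~ adjust_for_block(.x, x$block_id)
      ))
  }
  x |>
    dplyr::summarise(
      n_males = dplyr::n(),
      dplyr::across(dplyr::all_of(cols), mean),
      .by = "line_id"
    )
}

# residualize on block means, re-centered on the grand mean
adjust_for_block <- function(values, blocks) {
  values - ave(values, blocks) + mean(values)
}

#' Convert a joint transition matrix to a row-conditional one
#'
#' Rescales each row of a joint matrix (entries summing to 1 over all 25
#' cells) to sum to 1, giving P(next state | current state). Rows with zero
#' total mass get a self-loop by default, since a never-visited state has
#' no observed exits.
#'
#' @param joint 5 x 5 nonnegative matrix.
#' @param zero_row One of "self" (default: put probability 1 on the
#'   diagonal) or "error".
#' @return A row-stochastic 5 x 5 matrix.
#' @export
joint_to_conditional <- function(joint, zero_row = c("self", "error")) {
  zero_row <- match.arg(zero_row)
  stopifnot(is.matrix(joint), all(dim(joint) == c(5L, 5L)), all(joint >= 0))
  rs <- rowSums(joint)
  out <- joint
  for (i in seq_len(5L)) {
    if (rs[i] > 0) {
      out[i, ] <- joint[i, ] / rs[i]
    } else if (zero_row == "self") {
      out[i, ] <- 0
      out[i, i] <- 1
    } else {
      stop("row ", MMP_CATEGORIES[i], " has zero mass", call. = FALSE)
    }
  }
  dimnames(out) <- list(MMP_CATEGORIES, MMP_CATEGORIES)
  out
}

#' Reshape one row of transition phenotypes to a 5 x 5 matrix
#'
#' @param row A named numeric vector, one-row data frame, or list holding
#'   the 25 columns `A_A`..`E_E`.
#' @return A 5 x 5 numeric matrix (rows: from, columns: to).
#' @export
transition_row_to_matrix <- function(row) {
  if (is.data.frame(row)) {
    stopifnot(nrow(row) == 1L)
    row <- unlist(row[transition_cols()])
  }
  v <- unlist(row)[transition_cols()]
  if (anyNA(v)) stop("row must contain all 25 transition columns", call. = FALSE)
  matrix(v, 5, 5, byrow = TRUE, dimnames = list(MMP_CATEGORIES, MMP_CATEGORIES))
}

#' Export an edge-weighted ethogram as GraphViz DOT
#'
#' Writes a directed graph over the five condensed behavior categories with
#' edge pen width proportional to the transition probability, the standard
#' visual for edge-weighted ethograms. Edges below `min_edge` are omitted.
#' Node and edge order is deterministic (A..E, row-major).
#'
#' @param probs 5 x 5 probability matrix (joint or conditional).
#' @param path Output file; `NULL` returns the DOT text invisibly without
#'   writing.
#' @param min_edge Minimum probability for an edge to be drawn.
#' @param scale Pen width per unit probability.
#' @return The DOT source as a character vector of lines, invisibly.
#' @export
export_ethogram_dot <- function(probs, path = NULL, min_edge = 0, scale = 10) {
  stopifnot(is.matrix(probs), all(dim(probs) == c(5L, 5L)))
  lines <- c(
    "digraph ethogram {",
    "  rankdir=LR;",
    "  node [shape=circle, fontsize=14];",
    paste0("  ", MMP_CATEGORIES, ";")
  )
  for (i in seq_len(5L)) {
    for (j in seq_len(5L)) {
      p <- probs[i, j]
      if (p >= min_edge && p > 0) {
        lines <- c(lines, sprintf(
          '  %s -> %s [penwidth=%.4f, label="%.3f"];',
          MMP_CATEGORIES[i], MMP_CATEGORIES[j], scale * p, p
        ))
      }
    }
  }
  lines <- c(lines, "}")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Export an ethogram as GraphML (via igraph)
#'
#' @inheritParams export_ethogram_dot
#' @param path Output `.graphml` file.
#' @return `path`, invisibly.
#' @export
export_ethogram_graphml <- function(probs, path, min_edge = 0) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("the igraph package is required for GraphML export", call. = FALSE)
  }
  stopifnot(is.matrix(probs), all(dim(probs) == c(5L, 5L)))
  keep <- probs
  keep[keep < min_edge] <- 0
  g <- igraph::graph_from_adjacency_matrix(keep, mode = "directed", weighted = TRUE, diag = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
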