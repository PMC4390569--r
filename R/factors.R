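#' Principal components of line-mean transition probabilities
#'
#' Eigendecomposition of the correlation matrix of the line-by-phenotype
#' matrix (standardizing each phenotype, the convention expected by the
#' downstream factor analysis). Constant columns carry no correlation
#' structure and are dropped with a warning.
#'
#' @param line_means A data frame with `line_id` plus numeric phenotype
#'   columns (e.g. from [line_mean_transitions()]), or a plain numeric
#'   matrix with lines as rows.
#' @return A list: `values` (eigenvalues, descending), `vectors`
#'   (columns are eigenvectors), `center`, `scale`, `variables` (names of
#'   columns used), `n_lines`.
#' @export
correlation_pca <- function(line_means) {
  X <- phenotype_matrix(line_means)
  if (nrow(X) < 3L) stop("need at least 3 lines", call. = FALSE)
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
      paste(colnames(X)[sds == 0], collapse = ", "),
      call. = FALSE
    )
    X <- X[, sds > 0, drop = FALSE]
  }
  R <- cor(X)
  eig <- eigen(R, symmetric = TRUE)
  list(
    values = eig$values,
    vectors = eig$vectors,
    center = colMeans(X),
    scale = apply(X, 2, sd),
    variables = colnames(X),
    n_lines = nrow(X)
  )
}

#' Number of components retained under the Kaiser criterion
#'
#' @param eigenvalues Numeric vector sorted in descending order.
#' @return Count of eigenvalues strictly greater than 1. A zero count is
#'   flagged with a warning.
#' @export
kaiser_retain <- function(eigenvalues) {
  if (is.unsorted(rev(eigenvalues))) {
    stop("eigenvalues must be sorted in descending order", call. = FALSE)
  }
  k <- sum(eigenvalues > 1)
  if (k == 0L) warning("no eigenvalue exceeds 1; nothing retained", call. = FALSE)
  k
}

#' Unrotated principal-component factor loadings
#'
#' Principal-component factoring: the loading of variable j on factor m is
#' `eigenvector[j, m] * sqrt(eigenvalue_m)`, so squared loadings on a
#' factor sum to its eigenvalue and each factor explains
#' `eigenvalue / p * 100` percent of the total standardized variance.
#'
#' @param pca Result of [correlation_pca()].
#' @param k Number of factors to keep (e.g. from [kaiser_retain()]).
#' @return An object of class `ethoscan_factors`: `loadings`
#'   (p x k matrix), `variance_explained` (percent per factor),
#'   `communalities`, `rotated = FALSE`, plus the PCA standardization info
#'   needed for scoring.
#' @export
pc_factor <- function(pca, k) {
  p <- length(pca$values)
  if (k < 1L || k > p) stop("`k` must be in 1..", p, call. = FALSE)
  L <- pca$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(pca$values[seq_len(k)]), k)
  rownames(L) <- pca$variables
  colnames(L) <- paste0("F", seq_len(k))
  new_ethoscan_factors(L, pca, rotated = FALSE, rotation_iterations = 0L)
}

#' Varimax rotation of a factor loading matrix
#'
#' Orthogonal rotation maximizing the varimax criterion (the sum over
#' factors of the variance of squared loadings), which drives each
#' variable toward loading on few factors. Implemented as cyclic pairwise
#' planar (Jacobi) rotations, each solved in closed form; the criterion is
#' checked to be non-decreasing after every sweep. Kaiser normalization
#' (rows scaled to unit communality during rotation) is applied by
#' default. Sign convention: each factor's largest-magnitude loading is
#' made positive, then factors are ordered by decreasing explained
#' variance, so results are reproducible run to run.
#'
#' @param fm An `ethoscan_factors` object from [pc_factor()], or a bare
#'   loading matrix.
#' @param tol Stop when a full sweep improves the criterion by less.
#' @param max_iter Maximum number of sweeps.
#' @param kaiser_normalize Scale rows to unit length during rotation.
#' @return The rotated `ethoscan_factors` (or matrix in, matrix out), with
#'   `rotation` (the orthogonal k x k matrix), `criterion_trace`, and
#'   `rotation_iterations`. With a single factor the input is returned
#'   unchanged.
#' @export
varimax_rotate <- function(fm, tol = 1e-10, max_iter = 100L, kaiser_normalize = TRUE) {
  is_obj <- inherits(fm, "ethoscan_factors")
  L <- if (is_obj) fm$loadings else as.matrix(fm)
  k <- ncol(L)
  if (k < 2L) {
    if (is_obj) {
      fm$rotated <- TRUE
      fm$rotation <- diag(1)
      fm$criterion_trace <- varimax_criterion(L)
      return(fm)
    }
    return(L)
  }
  h <- sqrt(rowSums(L^2))
  W <- L
  if (kaiser_normalize) {
    nz <- h > 0
    W[nz, ] <- L[nz, ] / h[nz]
  }
  R <- diag(k)
  crit_trace <- varimax_criterion(W)
  converged <- FALSE
  sweeps <- 0L
  for (sweeps in seq_len(max_iter)) {
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        ang <- varimax_pair_angle(W[, a], W[, b])
        if (abs(ang) < 1e-14) next
        # the quartic stationary condition fixes |angle| but conventions
        # differ on its sign; evaluate both directions and keep the gain
        base_crit <- varimax_criterion(W[, c(a, b)])
        best <- NULL
        for (s in c(ang, -ang)) {
          G <- matrix(c(cos(s), -sin(s), sin(s), cos(s)), 2, 2)
          cand <- W[, c(a, b)] %*% G
          if (varimax_criterion(cand) > base_crit + 1e-15) {
            base_crit <- varimax_criterion(cand)
            best <- G
          }
        }
        if (!is.null(best)) {
          W[, c(a, b)] <- W[, c(a, b)] %*% best
          R[, c(a, b)] <- R[, c(a, b)] %*% best
        }
      }
    }
    crit <- varimax_criterion(W)
    if (crit < crit_trace[length(crit_trace)] - 1e-12) {
      stop("varimax criterion decreased across a sweep; numerical fault", call. = FALSE)
    }
    improved <- crit - crit_trace[length(crit_trace)]
    crit_trace <- c(crit_trace, crit)
    if (improved < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("varimax did not converge in ", max_iter, " sweeps", call. = FALSE)
  Lr <- L %*% R
  # sign convention and ordering by explained variance
  for (m in seq_len(k)) {
    j <- which.max(abs(Lr[, m]))
    if (Lr[j, m] < 0) {
      Lr[, m] <- -Lr[, m]
      R[, m] <- -R[, m]
    }
  }
  ord <- order(colSums(Lr^2), decreasing = TRUE)
  Lr <- Lr[, ord, drop = FALSE]
  R <- R[, ord, drop = FALSE]
  colnames(Lr) <- paste0("F", seq_len(k))
  if (!is_obj) {
    attr(Lr, "rotation") <- R
    attr(Lr, "criterion_trace") <- crit_trace
    return(Lr)
  }
  out <- fm
  out$loadings <- Lr
  out$rotated <- TRUE
  out$rotation <- R
  out$criterion_trace <- crit_trace
  out$rotation_iterations <- sweeps
  out$variance_explained <- 100 * colSums(Lr^2) / length(fm$communalities)
  out$communalities <- rowSums(Lr^2)
  out
}

# raw varimax criterion: sum over factors of the variance of squared loadings
varimax_criterion <- function(L) {
  p <- nrow(L)
  sum(apply(L^2, 2, function(u) sum(u^2) / p - (sum(u) / p)^2))
}

# closed-form optimal planar rotation angle for one column pair
# (standard varimax quartic solution)
varimax_pair_angle <- function(x, y) {
  p <- length(x)
  u <- x^2 - y^2
  v <- 2 * x * y
  A <- sum(u)
  B <- sum(v)
  C <- sum(u^2 - v^2)
  D <- sum(2 * u * v)
  num <- D - 2 * A * B / p
  den <- C - (A^2 - B^2) / p
  atan2(num, den) / 4
}

#' Factor scores for each line (regression method)
#'
#' Scores standardized line means on the rotated factors by the regression
#' (Thurstone) method: `scores = Z R^{-1} L` with Z the standardized data,
#' R the phenotype correlation matrix, and L the rotated loadings. Columns
#' have mean zero by construction.
#'
#' @param line_means The same data frame or matrix the model was fitted on
#'   (must contain the model's variables).
#' @param fm A (typically rotated) `ethoscan_factors` object.
#' @return A tibble with `line_id` (if available) and one column per
#'   factor.
#' @export
factor_scores <- function(line_means, fm) {
  stopifnot(inherits(fm, "ethoscan_factors"))
  X <- phenotype_matrix(line_means)
  missing_vars <- setdiff(rownames(fm$loadings), colnames(X))
  if (length(missing_vars)) {
    stop("line_means lacks model variable(s): ",
      paste(head(missing_vars, 5L), collapse = ", "),
      call. = FALSE
    )
  }
  X <- X[, rownames(fm$loadings), drop = FALSE]
  Z <- scale(X, center = fm$center[rownames(fm$loadings)],
             scale = fm$scale[rownames(fm$loadings)])
  R <- cor(X)
  B <- tryCatch(
    solve(R, fm$loadings),
    error = function(e) {
      # fewer lines than variables makes R singular; use the pseudoinverse
      MASS::ginv(R) %*% fm$loadings
    }
  )
  S <- Z %*% B
  colnames(S) <- colnames(fm$loadings)
  out <- tibble::as_tibble(S)
  if (is.data.frame(line_means) && "line_id" %in% names(line_means)) {
    out <- dplyr::bind_cols(tibble::tibble(line_id = line_means$line_id), out)
  }
  out
}

#' Fit the full factor model of transition structure
#'
#' Convenience wrapper: correlation PCA, Kaiser retention (or a fixed
#' `k`), principal-component factoring, and varimax rotation.
#'
#' @inheritParams correlation_pca
#' @param k Number of factors; `NULL` (default) uses the Kaiser criterion.
#' @param rotate Apply varimax rotation (default `TRUE`).
#' @return A rotated `ethoscan_factors` object with the PCA attached as
#'   `$pca`.
#' @export
fit_factor_model <- function(line_means, k = NULL, rotate = TRUE) {
  pca <- correlation_pca(line_means)
  if (is.null(k)) k <- kaiser_retain(pca$values)
  fm <- pc_factor(pca, k)
  if (rotate && k >= 2L) fm <- varimax_rotate(fm)
  fm$pca <- pca
  fm
}

new_ethoscan_factors <- function(L, pca, rotated, rotation_iterations) {
  structure(
    list(
      loadings = L,
      variance_explained = 100 * colSums(L^2) / length(pca$variables),
      communalities = rowSums(L^2),
      eigenvalues = pca$values,
      center = pca$center,
      scale = pca$scale,
      rotated = rotated,
      rotation_iterations = rotation_iterations
    ),
    class = "ethoscan_factors"
  )
}

#' @export
print.ethoscan_factors <- function(x, ...) {
  cat(sprintf(
    "<factor model>  %d variables, %d factor(s)%s\n",
    nrow(x$loadings), ncol(x$loadings),
    if (x$rotated) ", varimax-rotated" else " (unrotated)"
  ))
  cat(
    "variance explained (%):",
    paste(sprintf("%.2f", x$variance_explained), collapse = ", "), "\n"
  )
  invisible(x)
}

#' Tidy factor loadings to long format
#'
#' @param x An `ethoscan_factors` object.
#' @param ... Unused.
#' @return Tibble: `variable`, `factor`, `loading`, `communality`.
#' @exportS3Method generics::tidy
tidy.ethoscan_factors <- function(x, ...) {
  L <- x$loadings
  tibble::tibble(
    variable = rep(rownames(L), ncol(L)),
    factor = rep(colnames(L), each = nrow(L)),
    loading = as.vector(L),
    communality = rep(unname(x$communalities), ncol(L))
  )
}

#' One-row summary of a factor model
#'
#' @inheritParams tidy.ethoscan_factors
#' @return One-row tibble: `n_factors`, `total_variance_pct`, `rotated`,
#'   `rotation_iterations`.
#' @exportS3Method generics::glance
glance.ethoscan_factors <- function(x, ...) {
  tibble::tibble(
    n_factors = ncol(x$loadings),
    total_variance_pct = sum(x$variance_explained),
    rotated = x$rotated,
    rotation_iterations = x$rotation_iterations
  )
}

#' Table of factor loadings in wide (report) shape
#'
#' @param fm An `ethoscan_factors` object fitted on transition phenotypes.
#' @return A tibble with `from`, `to` (when variables are transition
#'   columns) or `variable`, then one column per factor named
#'   `F1 (xx.xx)` style is avoided: columns are `F1`..`Fk` and the percent
#'   variance is stored in the `variance_explained` attribute.
#' @export
loading_table <- function(fm) {
  stopifnot(inherits(fm, "ethoscan_factors"))
  L <- fm$loadings
  vars <- rownames(L)
  out <- tibble::as_tibble(L)
  if (all(grepl("^[A-E]_[A-E]$", vars))) {
    out <- dplyr::bind_cols(
      tibble::tibble(
        from = substr(vars, 1, 1),
        to = substr(vars, 3, 3)
      ),
      out
    )
  } else {
    out <- dplyr::bind_cols(tibble::tibble(variable = vars), out)
  }
  attr(out, "variance_explained") <- fm$variance_explained
  out
}

phenotype_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
    return(x)
  }
  stopifnot(is.data.frame(x))
  num <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  num <- num[, setdiff(names(num), c("n_males", "n_transitions", "n_obs")), drop = FALSE]
  as.matrix(num)
}
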