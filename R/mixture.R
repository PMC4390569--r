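#' Per-line proportion of noninitiating males
#'
#' @param scores Per-male summary tibble from [score_males()] (needs
#'   `line_id` and `noninitiator`).
#' @return Tibble: `line_id`, `n_males`, `prop_noninitiator`.
#' @export
noninitiator_proportions <- function(scores) {
  stopifnot(all(c("line_id", "noninitiator") %in% names(scores)))
  scores |>
    dplyr::summarise(
      n_males = dplyr::n(),
      prop_noninitiator = mean(.data$noninitiator),
      .by = "line_id"
    )
}

#' Maximum-likelihood exponential fit
#'
#' Fits an exponential distribution to nonnegative data by maximum
#' likelihood (`rate = 1 / mean`) and reports the log-likelihood and AIC
#' (`2k - 2 logL`, k = 1).
#'
#' @param x Nonnegative numeric data, n >= 2, with positive mean.
#' @return An object of class `ethoscan_fit` with elements `model`,
#'   `params`, `logLik`, `aic`, `k`, `n`, `converged`, `n_iter`,
#'   `data_hash`.
#' @export
fit_exponential <- function(x) {
  check_fit_data(x, min_n = 2L)
  if (any(x < 0)) stop("exponential fit requires nonnegative data", call. = FALSE)
  m <- mean(x)
  if (m <= 0) {
    stop("all-zero data: exponential rate is undefined ",
      "(consider a zero-inflation floor on the proportions)",
      call. = FALSE
    )
  }
  rate <- 1 / m
  ll <- sum(log(rate) - rate * x)
  new_ethoscan_fit(
    model = "exponential",
    params = tibble::tibble(term = "rate", estimate = rate),
    logLik = ll, k = 1L, n = length(x),
    converged = TRUE, n_iter = 0L, data = x
  )
}

#' Two-component Gaussian mixture fit by EM
#'
#' Fits a two-component Normal mixture (k = 5 free parameters: two means,
#' two standard deviations, one mixing weight) by
#' expectation-maximization. Components are ordered so `mu1 <= mu2`.
#' Because per-line noninitiator proportions pile up at exactly zero, the
#' component variances are floored at `var_floor` to keep the likelihood
#' bounded. Initialization is a quantile split (lower/upper half of the
#' sorted data) by default, or k-means.
#'
#' @param x Numeric data, n >= 4.
#' @param init "quantile" (default) or "kmeans".
#' @param tol Convergence tolerance on the log-likelihood increase.
#' @param max_iter Maximum EM iterations.
#' @param var_floor Lower bound on component variances.
#' @param seed Optional integer seed (only consulted for k-means
#'   initialization; the quantile split is deterministic).
#' @return An `ethoscan_fit` (see [fit_exponential()]) with params
#'   `mu1`, `sigma1`, `mu2`, `sigma2`, `pi2` (weight of the upper
#'   component) and the per-iteration log-likelihood trace in
#'   `$trace`.
#' @export
fit_normal2 <- function(x, init = c("quantile", "kmeans"), tol = 1e-8,
                        max_iter = 500L, var_floor = 1e-6, seed = NULL) {
  check_fit_data(x, min_n = 4L)
  init <- match.arg(init)
  n <- length(x)

  if (init == "quantile") {
    ord <- sort(x)
    lower <- ord[seq_len(floor(n / 2))]
    upper <- ord[(floor(n / 2) + 1L):n]
    mu <- c(mean(lower), mean(upper))
    v <- pmax(c(var(lower), var(upper)), var_floor)
    v[is.na(v)] <- var_floor
    w <- c(0.5, 0.5)
  } else {
    if (!is.null(seed)) set.seed(seed)
    km <- suppressWarnings(stats::kmeans(x, centers = 2L, nstart = 5L))
    mu <- as.vector(km$centers)
    v <- pmax(tapply(x, km$cluster, var), var_floor)
    v[is.na(v)] <- var_floor
    w <- as.vector(table(km$cluster)) / n
  }

  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # E step: responsibilities via log densities for numerical safety
    ld <- cbind(
      log(w[1]) + dnorm(x, mu[1], sqrt(v[1]), log = TRUE),
      log(w[2]) + dnorm(x, mu[2], sqrt(v[2]), log = TRUE)
    )
    mx <- pmax(ld[, 1], ld[, 2])
    lse <- mx + log(exp(ld[, 1] - mx) + exp(ld[, 2] - mx))
    ll <- sum(lse)
    if (length(trace) > 0 && ll < trace[length(trace)] - 1e-8) {
      stop("EM log-likelihood decreased; this indicates a numerical fault", call. = FALSE)
    }
    trace <- c(trace, ll)
    r <- exp(ld - lse) # n x 2, rows sum to 1
    # M step
    nk <- colSums(r)
    w <- nk / n
    mu <- colSums(r * x) / nk
    v <- pmax(colSums(r * (x - rep(mu, each = n))^2) / nk, var_floor)
    if (abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # order components so mu1 <= mu2
  o <- order(mu)
  mu <- mu[o]
  v <- v[o]
  w <- w[o]
  fit <- new_ethoscan_fit(
    model = "normal2",
    params = tibble::tibble(
      term = c("mu1", "sigma1", "mu2", "sigma2", "pi2"),
      estimate = c(mu[1], sqrt(v[1]), mu[2], sqrt(v[2]), w[2])
    ),
    logLik = trace[length(trace)], k = 5L, n = n,
    converged = converged, n_iter = iter, data = x
  )
  fit$trace <- trace
  fit
}

#' Rank candidate distribution fits by AIC
#'
#' Orders fits of the same data by ascending AIC and reports each model's
#' AIC difference from the best. Refuses to compare fits made on different
#' data.
#'
#' @param ... Two or more `ethoscan_fit` objects fitted to identical data.
#' @return Tibble ordered by AIC: `model`, `k`, `logLik`, `aic`,
#'   `delta_aic`. Ties keep the input order.
#' @export
compare_fits <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !inherits(fits[[1]], "ethoscan_fit")) {
    fits <- fits[[1]]
  }
  if (length(fits) < 2L) stop("need at least 2 fits to compare", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "ethoscan_fit")))
  hashes <- vapply(fits, function(f) f$data_hash, character(1))
  if (length(unique(hashes)) != 1L) {
    stop("fits were made on different data; AICs are not comparable", call. = FALSE)
  }
  tbl <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(model = f$model, k = f$k, logLik = f$logLik, aic = f$aic)
  })
  tbl <- tbl[order(tbl$aic), ]
  tbl$delta_aic <- tbl$aic - tbl$aic[1]
  tbl
}

new_ethoscan_fit <- function(model, params, logLik, k, n, converged, n_iter, data) {
  structure(
    list(
      model = model, params = params, logLik = logLik,
      aic = 2 * k - 2 * logLik, k = k, n = n,
      converged = converged, n_iter = n_iter,
      data_hash = hash_numeric(data)
    ),
    class = "ethoscan_fit"
  )
}

# order-sensitive content hash; enough to detect mismatched data in
# compare_fits without a digest dependency
hash_numeric <- function(x) {
  paste(length(x), format(sum(x), digits = 15), format(sum(x^2), digits = 15),
    format(sum(seq_along(x) * x), digits = 15),
    sep = "|"
  )
}

check_fit_data <- function(x, min_n) {
  if (!is.numeric(x) || length(x) < min_n) {
    stop("need at least ", min_n, " numeric observations", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("data contain non-finite values", call. = FALSE)
  invisible(x)
}

#' @export
print.ethoscan_fit <- function(x, ...) {
  cat(sprintf(
    "<%s fit>  n = %d, k = %d, logLik = %.3f, AIC = %.3f, converged: %s (%d iter)\n",
    x$model, x$n, x$k, x$logLik, x$aic, x$converged, x$n_iter
  ))
  print(x$params)
  invisible(x)
}

#' Tidy a distribution fit
#'
#' @param x An `ethoscan_fit` object.
#' @param ... Unused.
#' @return A tibble of parameter estimates (`term`, `estimate`).
#' @exportS3Method generics::tidy
tidy.ethoscan_fit <- function(x, ...) {
  x$params
}

#' One-row model summary of a distribution fit
#'
#' @inheritParams tidy.ethoscan_fit
#' @return One-row tibble: `model`, `n`, `k`, `logLik`, `AIC`,
#'   `converged`, `n_iter`.
#' @exportS3Method generics::glance
glance.ethoscan_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, n = x$n, k = x$k, logLik = x$logLik,
    AIC = x$aic, converged = x$converged, n_iter = x$n_iter
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
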