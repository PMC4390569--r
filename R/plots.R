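#' Plot an edge-weighted ethogram
#'
#' Draws the five condensed behavior categories on a circle with directed
#' edges whose width is proportional to the transition probability;
#' self-transitions are shown as node-size halos since loops do not render
#' informatively as segments.
#'
#' @param probs 5 x 5 probability matrix.
#' @param min_edge Edges below this probability are not drawn.
#' @return A ggplot object.
#' @export
plot_ethogram <- function(probs, min_edge = 0.005) {
  stopifnot(is.matrix(probs), all(dim(probs) == c(5L, 5L)))
  angle <- seq(pi / 2, by = -2 * pi / 5, length.out = 5)
  nodes <- tibble::tibble(
    cat = MMP_CATEGORIES,
    x = cos(angle), y = sin(angle),
    self = diag(probs)
  )
  edges <- tidyr::expand_grid(from = MMP_CATEGORIES, to = MMP_CATEGORIES) |>
    dplyr::mutate(p = as.vector(t(probs))) |>
    dplyr::filter(.data$from != .data$to, .data$p >= min_edge) |>
    dplyr::left_join(dplyr::select(nodes, "cat", x0 = "x", y0 = "y"), by = c(from = "cat")) |>
    dplyr::left_join(dplyr::select(nodes, "cat", x1 = "x", y1 = "y"), by = c(to = "cat"))
  ggplot2::ggplot() +
    ggplot2::geom_curve(
      data = edges,
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
        linewidth = .data$p
      ),
      curvature = 0.15, alpha = 0.6,
      arrow = ggplot2::arrow(length = ggplot2::unit(6, "pt"))
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$self),
      color = "steelblue"
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = 1.18 * .data$x, y = 1.18 * .data$y, label = .data$cat),
      size = 5
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 3), name = "P(transition)") +
    ggplot2::scale_size(range = c(3, 14), name = "P(self)") +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void()
}

#' QQ plot of association-scan P values
#'
#' @param results An [assoc_scan()] table or a numeric vector of P values.
#' @return A ggplot object.
#' @export
plot_qq <- function(results) {
  p <- if (is.data.frame(results)) results$p_value else results
  pts <- qq_points(p)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey50") +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](italic(P))),
      y = expression(Observed ~ -log[10](italic(P)))
    ) +
    ggplot2::theme_minimal()
}

#' Manhattan plot of an association scan
#'
#' @param results An [assoc_scan()] table.
#' @param threshold Genome-wide significance line (P scale); `NULL` for
#'   none.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, threshold = NULL) {
  stopifnot(all(c("chrom", "pos", "p_value") %in% names(results)))
  dat <- results |>
    dplyr::filter(!is.na(.data$p_value)) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::mutate(idx = dplyr::row_number())
  gg <- ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$idx, y = -log10(.data$p_value), color = .data$chrom
  )) +
    ggplot2::geom_point(size = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = "variant (ordered by position)", y = expression(-log[10](italic(P)))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    gg <- gg + ggplot2::geom_hline(
      yintercept = -log10(threshold),
      linetype = "dashed", color = "red"
    )
  }
  gg
}

#' Histogram of per-line noninitiator proportions with fitted curves
#'
#' Overlays the fitted exponential and two-Normal mixture densities on the
#' distribution of per-line noninitiator proportions.
#'
#' @param proportions Tibble from [noninitiator_proportions()].
#' @param fits A list of `ethoscan_fit` objects (as in
#'   `run_pipeline()$mixture_fits`).
#' @return A ggplot object.
#' @export
plot_noninitiator_fit <- function(proportions, fits) {
  x <- proportions$prop_noninitiator
  grid <- seq(max(min(x) - 0.02, -0.05), max(x) + 0.05, length.out = 400)
  dens <- purrr::map_dfr(fits, function(f) {
    d <- switch(f$model,
      exponential = {
        rate <- f$params$estimate[f$params$term == "rate"]
        ifelse(grid >= 0, rate * exp(-rate * grid), 0)
      },
      normal2 = {
        p <- setNames(f$params$estimate, f$params$term)
        (1 - p["pi2"]) * dnorm(grid, p["mu1"], p["sigma1"]) +
          p["pi2"] * dnorm(grid, p["mu2"], p["sigma2"])
      },
      stop("unknown model: ", f$model)
    )
    tibble::tibble(model = f$model, x = grid, density = d)
  })
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = tibble::tibble(x = x),
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      bins = 30, fill = "grey80", color = "grey60"
    ) +
    ggplot2::geom_line(
      data = dens,
      ggplot2::aes(x = .data$x, y = .data$density, color = .data$model),
      linewidth = 0.9
    ) +
    ggplot2::coord_cartesian(ylim = c(0, stats::quantile(dens$density, 0.995))) +
    ggplot2::labs(x = "proportion of noninitiating males per line", y = "density") +
    ggplot2::theme_minimal()
}

#' Scatter plot of line scores on two factors
#'
#' @param scores Tibble from [factor_scores()].
#' @param color Optional per-line numeric vector (e.g. line-mean MMP
#'   score) named by line, used as the point color.
#' @param factors Length-2 character vector of factor columns to plot.
#' @return A ggplot object.
#' @export
plot_factor_scores <- function(scores, color = NULL, factors = c("F1", "F2")) {
  stopifnot(all(factors %in% names(scores)))
  dat <- scores
  gg <- ggplot2::ggplot(dat, ggplot2::aes(
    x = .data[[factors[1]]], y = .data[[factors[2]]]
  ))
  if (!is.null(color) && "line_id" %in% names(dat)) {
    dat$color_val <- unname(color[as.character(dat$line_id)])
    gg <- ggplot2::ggplot(dat, ggplot2::aes(
      x = .data[[factors[1]]], y = .data[[factors[2]]], color = .data$color_val
    )) +
      ggplot2::scale_color_viridis_c(name = "line mean")
  }
  gg +
    ggplot2::geom_point(size = 1.6, alpha = 0.8) +
    ggplot2::labs(x = factors[1], y = factors[2]) +
    ggplot2::theme_minimal()
}
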