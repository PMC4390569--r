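#' Read an inbred-line genotype matrix
#'
#' Reads genotypes for fully inbred lines either from a wide TSV (columns
#' `variant_id`, `chrom`, `pos`, `ref`, `alt`, then one column per line
#' with calls 0/2/NA) or from a VCF (via the vcfR package). Homozygous
#' reference is coded 0 and homozygous alternate 2; heterozygous calls —
#' residual heterozygosity in an inbred panel — are treated per
#' `het_policy`.
#'
#' @param path File path.
#' @param format "tsv" or "vcf"; default inferred from the extension.
#' @param het_policy "missing" (default: heterozygous calls become NA) or
#'   "dosage" (coded 1).
#' @return An `ethoscan_genotypes` list: `variants` (tibble: `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`), `dosage` (variants x lines numeric
#'   matrix), `call_rate` (per variant).
#' @export
read_genotypes <- function(path, format = NULL, het_policy = c("missing", "dosage")) {
  het_policy <- match.arg(het_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("the vcfR package is required to read VCF", call. = FALSE)
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    gt <- vcfR::extract.gt(v, element = "GT")
    # normalize separators and strip anything after the genotype field
    gt_clean <- gsub("\\|", "/", gt)
    dosage <- matrix(NA_real_, nrow(gt_clean), ncol(gt_clean),
      dimnames = dimnames(gt_clean)
    )
    dosage[gt_clean %in% c("0/0", "0")] <- 0
    dosage[gt_clean %in% c("1/1", "1")] <- 2
    het <- gt_clean %in% c("0/1", "1/0")
    if (het_policy == "dosage") dosage[het] <- 1
    ids <- fix[, "ID"]
    no_id <- is.na(ids) | ids == "."
    ids[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
    variants <- tibble::tibble(
      variant_id = unname(ids),
      chrom = unname(fix[, "CHROM"]),
      pos = as.integer(fix[, "POS"]),
      ref = unname(fix[, "REF"]),
      alt = unname(fix[, "ALT"])
    )
    rownames(dosage) <- variants$variant_id
  } else {
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    meta_cols <- c("variant_id", "chrom", "pos", "ref", "alt")
    missing_cols <- setdiff(meta_cols, names(tbl))
    if (length(missing_cols)) {
      stop("genotype TSV missing column(s): ",
        paste(missing_cols, collapse = ", "),
        call. = FALSE
      )
    }
    variants <- dplyr::select(tbl, dplyr::all_of(meta_cols)) |>
      dplyr::mutate(
        variant_id = as.character(.data$variant_id),
        pos = as.integer(.data$pos)
      )
    dosage <- as.matrix(tbl[, setdiff(names(tbl), meta_cols), drop = FALSE])
    storage.mode(dosage) <- "double"
    rownames(dosage) <- variants$variant_id
    if (het_policy == "missing") dosage[dosage == 1] <- NA_real_
    bad <- !(dosage %in% c(0, 1, 2)) & !is.na(dosage)
    if (any(bad)) stop("genotype dosages must be 0, 1, 2 or missing", call. = FALSE)
  }
  new_ethoscan_genotypes(variants, dosage)
}

new_ethoscan_genotypes <- function(variants, dosage) {
  structure(
    list(
      variants = variants,
      dosage = dosage,
      call_rate = rowMeans(!is.na(dosage))
    ),
    class = "ethoscan_genotypes"
  )
}

#' @export
print.ethoscan_genotypes <- function(x, ...) {
  cat(sprintf(
    "<genotypes>  %d variant(s) x %d line(s); mean call rate %.3f\n",
    nrow(x$dosage), ncol(x$dosage), mean(x$call_rate)
  ))
  invisible(x)
}

#' Filter variants by minor-genotype line count
#'
#' Removes variants whose rarer homozygous class is carried by fewer than
#' `min_minor_lines` lines (among non-missing calls). Monomorphic variants
#' are always removed for any threshold >= 1.
#'
#' @param geno An `ethoscan_genotypes` object.
#' @param min_minor_lines Minimum minor-class line count (default 4).
#' @return The filtered `ethoscan_genotypes`; the number removed is
#'   reported via `message()`.
#' @export
filter_variants <- function(geno, min_minor_lines = 4L) {
  stopifnot(inherits(geno, "ethoscan_genotypes"))
  if (min_minor_lines <= 0) {
    return(geno)
  }
  minor <- apply(geno$dosage, 1, function(g) {
    g <- g[!is.na(g)]
    n_alt <- sum(g >= 1)
    min(n_alt, length(g) - n_alt)
  })
  keep <- minor >= min_minor_lines
  message(sum(!keep), " variant(s) removed by minor-line-count filter (< ",
    min_minor_lines, ")")
  new_ethoscan_genotypes(
    geno$variants[keep, , drop = FALSE],
    geno$dosage[keep, , drop = FALSE]
  )
}

#' Line-means association scan
#'
#' Regresses per-line phenotype means on genotype dosage, one variant at a
#' time, by ordinary least squares with optional user-supplied per-line
#' covariates (e.g. inversion karyotype, Wolbachia infection status, or
#' relatedness axes). The genotype coefficient's two-sided t test is
#' reported. Internally the phenotype and each genotype vector are
#' residualized on the covariates (Frisch-Waugh-Lovell), which makes the
#' scan a single vectorized pass over variants; the result is identical to
#' the per-variant multiple regression.
#'
#' @param phenotype Data frame with `line_id` and `value` (line means), or
#'   a named numeric vector keyed by line.
#' @param geno An `ethoscan_genotypes` object; its dosage columns must be
#'   named by line.
#' @param covariates Optional data frame with `line_id` plus numeric
#'   covariate columns.
#' @param min_lines Variants with fewer non-missing lines are skipped
#'   (default 3; with covariates the residual degrees of freedom must also
#'   stay positive).
#' @return Tibble, one row per tested variant: `variant_id`, `chrom`,
#'   `pos`, `n`, `beta`, `se`, `t`, `p_value`, ordered as in the input.
#' @export
assoc_scan <- function(phenotype, geno, covariates = NULL, min_lines = 3L) {
  stopifnot(inherits(geno, "ethoscan_genotypes"))
  y_all <- as_line_values(phenotype)
  lines <- intersect(names(y_all), colnames(geno$dosage))
  if (length(lines) == 0L) stop("no overlapping lines between phenotype and genotypes", call. = FALSE)
  y <- y_all[lines]
  G <- geno$dosage[, lines, drop = FALSE]

  C <- matrix(1, length(lines), 1) # intercept
  if (!is.null(covariates)) {
    stopifnot("line_id" %in% names(covariates))
    cov <- covariates[match(lines, as.character(covariates$line_id)), , drop = FALSE]
    if (anyNA(cov$line_id)) stop("covariates missing for some lines", call. = FALSE)
    num <- as.matrix(cov[, vapply(cov, is.numeric, logical(1)), drop = FALSE])
    C <- cbind(C, num)
  }
  q <- ncol(C)

  if (!anyNA(G) && !anyNA(y)) {
    # vectorized path: residualize phenotype and all genotype columns at once
    n <- length(y)
    df <- n - q - 1L
    if (n < min_lines || df < 1L) stop("too few lines for the scan", call. = FALSE)
    qrC <- qr(C)
    if (qrC$rank < ncol(C)) stop("covariates are rank-deficient", call. = FALSE)
    yr <- qr.resid(qrC, y)
    GR <- qr.resid(qrC, t(G)) # lines x variants
    sgg <- unname(colSums(GR^2))
    sgy <- unname(colSums(GR * yr))
    ok <- sgg > .Machine$double.eps * n
    beta <- ifelse(ok, sgy / sgg, NA_real_)
    rss <- sum(yr^2) - ifelse(ok, beta * sgy, 0)
    se <- ifelse(ok, sqrt(rss / df / sgg), NA_real_)
    tval <- beta / se
    res <- tibble::tibble(
      variant_id = geno$variants$variant_id,
      n = n, beta = beta, se = se, t = tval,
      p_value = 2 * pt(abs(tval), df, lower.tail = FALSE)
    )
    return(
      dplyr::left_join(
        res,
        dplyr::select(geno$variants, "variant_id", "chrom", "pos"),
        by = "variant_id"
      ) |>
        dplyr::relocate("variant_id", "chrom", "pos")
    )
  }

  res <- purrr::map_dfr(seq_len(nrow(G)), function(i) {
    g <- G[i, ]
    ok <- !is.na(g) & !is.na(y)
    n <- sum(ok)
    df <- n - q - 1L
    if (n < min_lines || df < 1L || var(g[ok]) == 0) {
      return(tibble::tibble(
        variant_id = geno$variants$variant_id[i], n = n,
        beta = NA_real_, se = NA_real_, t = NA_real_, p_value = NA_real_
      ))
    }
    Ck <- C[ok, , drop = FALSE]
    qrC <- qr(Ck)
    if (qrC$rank < ncol(Ck)) {
      return(tibble::tibble(
        variant_id = geno$variants$variant_id[i], n = n,
        beta = NA_real_, se = NA_real_, t = NA_real_, p_value = NA_real_
      ))
    }
    yr <- qr.resid(qrC, y[ok])
    gr <- qr.resid(qrC, g[ok])
    sgg <- sum(gr^2)
    if (sgg < .Machine$double.eps * n) {
      return(tibble::tibble(
        variant_id = geno$variants$variant_id[i], n = n,
        beta = NA_real_, se = NA_real_, t = NA_real_, p_value = NA_real_
      ))
    }
    beta <- sum(gr * yr) / sgg
    rss <- sum((yr - beta * gr)^2)
    se <- sqrt(rss / df / sgg)
    tval <- beta / se
    tibble::tibble(
      variant_id = geno$variants$variant_id[i], n = n,
      beta = beta, se = se, t = tval,
      p_value = 2 * pt(abs(tval), df, lower.tail = FALSE)
    )
  })
  dplyr::left_join(
    res,
    dplyr::select(geno$variants, "variant_id", "chrom", "pos"),
    by = "variant_id"
  ) |>
    dplyr::relocate("variant_id", "chrom", "pos")
}

#' QQ-plot coordinates for a set of P values
#'
#' Pairs the sorted observed `-log10(P)` with the uniform expectation
#' `-log10((i - 0.5) / n)`. Zero P values are clamped to the smallest
#' representable double with a warning.
#'
#' @param pvalues Numeric vector of P values in \[0, 1\].
#' @return Tibble: `expected`, `observed`, both on the `-log10` scale,
#'   ascending.
#' @export
qq_points <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  n <- length(pvalues)
  if (n < 1L) stop("need at least one P value", call. = FALSE)
  if (any(pvalues < 0 | pvalues > 1)) stop("P values must lie in [0, 1]", call. = FALSE)
  if (any(pvalues == 0)) {
    warning("P value(s) of exactly 0 clamped to the machine floor", call. = FALSE)
    pvalues[pvalues == 0] <- .Machine$double.xmin
  }
  tibble::tibble(
    expected = -log10((seq_len(n) - 0.5) / n),
    observed = -log10(sort(pvalues, decreasing = FALSE))
  ) |>
    dplyr::arrange(.data$expected)
}

#' Bonferroni-significant and suggestive association hits
#'
#' @param results An [assoc_scan()] result table.
#' @param alpha Familywise error rate (default 0.05).
#' @param n_tests Bonferroni denominator; defaults to the number of tested
#'   (non-NA) variants in `results`.
#' @param suggestive Suggestive-tier P cutoff (default 1e-5); set `NULL`
#'   to disable.
#' @return The rows of `results` with `p_value <= alpha / n_tests`
#'   (`tier = "significant"`), plus rows at `p_value <= suggestive`
#'   (`tier = "suggestive"`), sorted by P.
#' @export
significant_hits <- function(results, alpha = 0.05, n_tests = NULL, suggestive = 1e-5) {
  stopifnot("p_value" %in% names(results))
  if (is.null(n_tests)) n_tests <- sum(!is.na(results$p_value))
  if (n_tests < 1L) {
    return(dplyr::mutate(results[0, ], tier = character(0)))
  }
  crit <- bonferroni(alpha, n_tests)
  out <- results |>
    dplyr::filter(!is.na(.data$p_value)) |>
    dplyr::mutate(tier = dplyr::case_when(
      .data$p_value <= crit ~ "significant",
      !is.null(suggestive) & .data$p_value <= (suggestive %||% 0) ~ "suggestive",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(.data$tier)) |>
    dplyr::arrange(.data$p_value)
  attr(out, "critical_p") <- crit
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
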