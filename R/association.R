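#' Read a genotype dosage table
#'
#' Tab-delimited interchange format: columns `marker`, `lg` (linkage group;
#' `"U"` for unmapped), `cM` (may be `NA` for unmapped markers), then one
#' 0/1/2 dosage column per genotype, `NA` for missing calls.
#'
#' @param path file path.
#' @return a tibble, validated.
#' @export
read_genotypes <- function(path) {
  tbl <- readr::read_tsv(path, na = "NA", show_col_types = FALSE,
                         col_types = readr::cols(
                           marker = readr::col_character(),
                           lg = readr::col_character(),
                           cM = readr::col_double(),
                           .default = readr::col_double()
                         ))
  validate_genotype_table(tbl)
}

validate_genotype_table <- function(tbl) {
  stopifnot(all(c("marker", "lg", "cM") %in% names(tbl)))
  if (anyDuplicated(tbl$marker)) stop("duplicated marker ids")
  d <- dosage_matrix(tbl)
  bad <- d[!is.na(d)]
  if (length(bad) && any(!bad %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1, 2 or missing")
  }
  tbl$lg <- as.character(tbl$lg)
  tbl
}

# markers x genotypes numeric matrix from the interchange tibble
dosage_matrix <- function(tbl) {
  cols <- setdiff(names(tbl), c("marker", "lg", "cM", "maf", "filtered",
                                "filter_reason"))
  m <- as.matrix(tbl[cols])
  rownames(m) <- tbl$marker
  m
}

#' Minor allele frequencies of a genotype table
#'
#' Per marker, from non-missing dosages: `MAF = min(p, 1 - p)` with `p` the
#' mean dosage divided by two.
#'
#' @param tbl genotype tibble (see [read_genotypes()]).
#' @return numeric vector, `NA` for markers with no data.
#' @export
marker_maf <- function(tbl) {
  d <- dosage_matrix(tbl)
  p <- rowMeans(d, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA
  unname(pmin(p, 1 - p))
}

#' Flag markers below a minor-allele-frequency threshold
#'
#' Markers with `MAF < threshold` (strictly) segregate too weakly to test
#' and are flagged out of the scan; markers with no data at all are flagged
#' with reason `"no data"`. All rows are kept so the exclusion report is the
#' table itself.
#'
#' @param tbl genotype tibble.
#' @param threshold MAF cutoff (default 0.05).
#' @return the tibble with columns `maf`, `filtered`, `filter_reason`
#'   appended.
#' @export
maf_filter <- function(tbl, threshold = 0.05) {
  maf <- marker_maf(tbl)
  tbl$maf <- maf
  tbl$filtered <- is.na(maf) | maf < threshold
  tbl$filter_reason <- dplyr::case_when(
    is.na(maf) ~ "no data",
    maf < threshold ~ sprintf("MAF %.4f < %.2f", maf, threshold),
    TRUE ~ NA_character_
  )
  tbl
}

#' Population-structure covariates from genotype data
#'
#' Top principal-component scores of the column-centered genotype matrix
#' (genotypes x markers); missing dosages are mean-imputed for this step
#' only. With `n_axes = 0` an empty matrix is returned and downstream models
#' regress the phenotype on the marker alone.
#'
#' @param tbl genotype tibble.
#' @param n_axes number of structure axes.
#' @return numeric matrix (genotypes x `n_axes`), rownames = genotype ids.
#' @export
structure_covariates <- function(tbl, n_axes = 2L) {
  d <- t(dosage_matrix(tbl))  # genotypes x markers
  if (n_axes >= nrow(d)) stop("n_axes must be smaller than the genotype count")
  if (n_axes == 0) {
    return(matrix(numeric(0), nrow = nrow(d), ncol = 0,
                  dimnames = list(rownames(d), NULL)))
  }
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- mu[idx[, 2]]
  keep <- apply(d, 2, stats::var) > 0
  pc <- stats::prcomp(d[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  out <- pc$x[, seq_len(n_axes), drop = FALSE]
  rownames(out) <- rownames(d)
  out
}

#' Single-marker association scan
#'
#' For each retained marker, ordinary least squares of the phenotype on
#' additive dosage plus intercept and structure covariates; the p-value is
#' the two-sided t-test on the dosage coefficient. Missing dosages are
#' mean-imputed marker-wise (keeping n constant) by default; the
#' complete-case alternative drops genotypes per marker. Markers whose
#' dosage is collinear with the covariates are skipped with a reason;
#' numerically perfect fits are reported at the `-log10 p` cap of 15.
#'
#' @param phenotype named numeric vector (names = genotype ids) or a tibble
#'   with columns `genotype_id` and `value`.
#' @param tbl genotype tibble, ideally already through [maf_filter()] (it is
#'   applied with defaults otherwise).
#' @param covariates structure covariate matrix from
#'   [structure_covariates()], or `NULL`.
#' @param alpha genome-wide significance level for the Bonferroni threshold.
#' @param missing one of `"impute"` (marker-mean) or `"complete"`.
#' @param log10p_cap reporting cap for `-log10 p`.
#' @return an `si_scan` tibble: per marker `lg`, `cM`, `maf`, `n_used`,
#'   `estimate`, `log10p` (`-log10` p-value), `tested`, `reason`;
#'   attributes `alpha`, `m_tested`, `threshold` (Bonferroni, `-log10`
#'   scale), `phenotype_label`.
#' @export
marker_scan <- function(phenotype, tbl, covariates = NULL, alpha = 0.05,
                        missing = c("impute", "complete"),
                        log10p_cap = 15) {
  missing <- match.arg(missing)
  if (is.data.frame(phenotype)) {
    phenotype <- stats::setNames(phenotype$value, phenotype$genotype_id)
  }
  if (!"filtered" %in% names(tbl)) tbl <- maf_filter(tbl)
  d <- dosage_matrix(tbl)
  ids <- colnames(d)
  if (!is.null(names(phenotype))) {
    if (!all(ids %in% names(phenotype))) {
      stop("phenotype missing for some genotypes in the table")
    }
    y <- phenotype[ids]
  } else {
    stopifnot(length(phenotype) == ncol(d))
    y <- phenotype
  }
  keep_g <- is.finite(y)
  if (sum(keep_g) < 10) stop("need a finite phenotype for at least 10 genotypes")
  y <- y[keep_g]
  d <- d[, keep_g, drop = FALSE]
  n <- length(y)
  X0 <- cbind(`(Intercept)` = rep(1, n),
              if (!is.null(covariates)) covariates[ids[keep_g], , drop = FALSE])
  q <- ncol(X0)

  res <- tibble::tibble(marker = tbl$marker, lg = tbl$lg, cM = tbl$cM,
                        maf = tbl$maf, n_used = NA_integer_,
                        estimate = NA_real_, log10p = NA_real_,
                        tested = FALSE,
                        reason = ifelse(tbl$filtered, tbl$filter_reason,
                                        NA_character_))
  test_idx <- which(!tbl$filtered)
  if (!length(test_idx)) {
    return(finish_scan(res, alpha, log10p_cap))
  }

  if (missing == "impute") {
    g <- d[test_idx, , drop = FALSE]
    mu <- rowMeans(g, na.rm = TRUE)
    na_idx <- which(is.na(g), arr.ind = TRUE)
    if (nrow(na_idx)) g[na_idx] <- mu[na_idx[, 1]]
    # Frisch-Waugh: residualise phenotype and all markers on the covariate
    # block once, then the per-marker OLS t-test is a simple regression of
    # the residuals with n - q - 1 denominator df
    qr0 <- qr(X0)
    yr <- qr.resid(qr0, y)
    gr <- t(qr.resid(qr0, t(g)))
    sxx <- rowSums(gr^2)
    ok <- sxx > 1e-10
    beta <- rowSums(gr * rep(yr, each = nrow(gr))) / sxx
    df <- n - q - 1
    rss <- sum(yr^2) - beta^2 * sxx
    rss <- pmax(rss, 0)
    sigma2 <- rss / df
    tstat <- beta / sqrt(sigma2 / sxx)
    logp <- -(stats::pt(abs(tstat), df, lower.tail = FALSE, log.p = TRUE) +
                log(2)) / log(10)
    logp[!is.finite(logp) | logp > log10p_cap] <- log10p_cap
    res$n_used[test_idx] <- n
    res$estimate[test_idx[ok]] <- beta[ok]
    res$log10p[test_idx[ok]] <- logp[ok]
    res$tested[test_idx[ok]] <- TRUE
    res$reason[test_idx[!ok]] <- "collinear with covariates"
  } else {
    for (i in test_idx) {
      gi <- d[i, ]
      use <- !is.na(gi)
      ni <- sum(use)
      if (ni <= q + 1) { res$reason[i] <- "too few complete cases"; next }
      X <- cbind(X0[use, , drop = FALSE], dosage = gi[use])
      fit <- stats::lm(y[use] ~ X - 1)
      cf <- summary(fit)$coefficients
      if (!"Xdosage" %in% rownames(cf) || anyNA(fit$coefficients)) {
        res$reason[i] <- "collinear with covariates"
        next
      }
      logp <- -stats::pf(cf["Xdosage", "t value"]^2, 1, fit$df.residual,
                         lower.tail = FALSE, log.p = TRUE) / log(10)
      res$n_used[i] <- ni
      res$estimate[i] <- cf["Xdosage", "Estimate"]
      res$log10p[i] <- min(logp, log10p_cap, na.rm = TRUE)
      res$tested[i] <- TRUE
    }
  }
  finish_scan(res, alpha, log10p_cap)
}

finish_scan <- function(res, alpha, log10p_cap) {
  m <- sum(res$tested)
  attr(res, "alpha") <- alpha
  attr(res, "m_tested") <- m
  attr(res, "threshold") <- if (m >= 1) bonferroni_threshold(alpha, m) else NA_real_
  attr(res, "log10p_cap") <- log10p_cap
  class(res) <- c("si_scan", class(res))
  res
}

#' Bonferroni significance threshold on the -log10 scale
#'
#' @param alpha genome-wide significance level, in (0, 1).
#' @param m_tested number of tested markers.
#' @return `-log10(alpha / m_tested)`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m_tested) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (any(m_tested < 1)) stop("m_tested must be at least 1")
  -log10(alpha / m_tested)
}

#' Manhattan-ordered association table
#'
#' Markers ordered by linkage group then map position, unmapped markers
#' (`lg == "U"`) in a trailing block, with the Bonferroni above-threshold
#' flag. This is the coordinate export behind a Manhattan plot.
#'
#' @param scan an `si_scan` from [marker_scan()].
#' @return tibble `marker`, `lg`, `cM`, `log10p`, `above_threshold`.
#' @export
manhattan_table <- function(scan) {
  stopifnot(inherits(scan, "si_scan"))
  thr <- attr(scan, "threshold")
  out <- scan[scan$tested, c("marker", "lg", "cM", "log10p")]
  unmapped <- out$lg == "U" | is.na(out$cM)
  lg_num <- suppressWarnings(as.numeric(out$lg))
  ord <- order(unmapped, lg_num, out$cM)
  out <- out[ord, ]
  out$above_threshold <- out$log10p >= thr
  attr(out, "threshold") <- thr
  out
}

#' Manhattan plot of an association scan
#'
#' @param object an `si_scan`.
#' @param ... unused.
#' @return a ggplot of `-log10 p` by map position per linkage group, with
#'   the Bonferroni threshold line.
#' @export
#' @method autoplot si_scan
autoplot.si_scan <- function(object, ...) {
  tab <- manhattan_table(object)
  tab <- tab[!is.na(tab$cM) & tab$lg != "U", ]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$cM, y = .data$log10p,
                                    colour = .data$lg)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = attr(tab, "threshold"),
                        colour = "red", linetype = 2) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$lg), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "map position (cM) by linkage group",
                  y = expression(-log[10] * italic(P))) +
    ggplot2::theme_minimal()
}
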