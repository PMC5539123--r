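#' Build the augmented quantile series for an SI50 fit
#'
#' Ordinal compatibility scores from a group of crosses rarely look normal:
#' plotted against their quantile positions they trace a sigmoid, which is
#' what the SI50 index models. Scores are sorted ascending and placed at
#' empirical quantile coordinates `x_i = i / (n + 1)`; every score is
#' incremented by one (zeros are not representable under the logistic), and
#' the asymptotes are anchored by 100 artificial points on each side: scores
#' of 0 (augmented to 1) at x = -100..-1 and scores of 10 (augmented to 11)
#' at x = 101..200.
#'
#' @param scores integer vector of ordinal scores in `[0, 10]`, length >= 2.
#' @return a `quantile_series` tibble with columns `x`, `y`, `artificial`;
#'   attribute `n_real` counts the observed points.
#' @export
build_quantile_series <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 2) stop("need at least 2 scores to build a quantile series")
  if (any(scores < 0 | scores > 10)) stop("scores must lie in [0, 10]")
  n <- length(scores)
  real <- tibble::tibble(
    x = seq_len(n) / (n + 1),
    y = sort(scores) + 1,
    artificial = FALSE
  )
  anchors <- tibble::tibble(
    x = c(-100:-1, 101:200),
    y = rep(c(1, 11), each = 100),
    artificial = TRUE
  )
  out <- dplyr::bind_rows(anchors[1:100, ], real, anchors[101:200, ])
  attr(out, "n_real") <- n
  class(out) <- c("quantile_series", class(out))
  out
}

#' Fit the four-parameter logistic SI50 model
#'
#' Fits `Y = A + (B - A) / (1 + exp((D - x) / C))` to an augmented quantile
#' series by Levenberg--Marquardt least squares. `A` and `B` are the lower
#' and upper asymptotes (pinned near 1 and 11 by the artificial anchor
#' points), `C` a scaling parameter, and `D` the inflection point: the
#' quantile at which half the compatibility reactions are half-compatible,
#' reported as the SI50 index of the group. Starting values are
#' self-derived from the series (`A0 = min y`, `B0 = max y`, `D0` = x at the
#' median real score, `C0` = a quarter of the real x-range).
#'
#' @param series a `quantile_series` from [build_quantile_series()], or a
#'   raw score vector (converted automatically).
#' @param weights optional observation weights passed to the least-squares
#'   fit; the default is unweighted.
#' @param max_iter maximum optimizer iterations.
#' @return an `si50_fit`: coefficients `A`, `B`, `C`, `D` (SI50),
#'   `r_squared` (see [si50_r_squared()]), `converged`, `n_iterations`, the
#'   series, and the underlying `nls` object.
#' @export
fit_si50 <- function(series, weights = NULL, max_iter = 200L) {
  if (!inherits(series, "quantile_series")) {
    series <- build_quantile_series(series)
  }
  real <- series[!series$artificial, ]
  if (length(unique(series$y)) == 1) {
    stop("degenerate series: all scores identical, the curve has no inflection")
  }
  st <- list(
    A = min(series$y),
    B = max(series$y),
    C = (max(real$x) - min(real$x)) / 4,
    D = real$x[which.min(abs(real$y - stats::median(real$y)))]
  )
  w <- sqrt(if (is.null(weights)) rep(1, nrow(series)) else weights)
  # plogis keeps the curve finite at the far-out anchor coordinates where
  # exp((D - x)/C) would overflow once C gets small
  curve_fn <- function(par, x) {
    par[["A"]] + (par[["B"]] - par[["A"]]) *
      stats::plogis((x - par[["D"]]) / par[["C"]])
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = st,
      fn = function(par) w * (series$y - curve_fn(par, series$x)),
      control = minpack.lm::nls.lm.control(maxiter = max_iter, ptol = 1e-8)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(A = NA_real_, B = NA_real_, C = NA_real_,
                          D = NA_real_, r_squared = NA_real_,
                          converged = FALSE, n_iterations = NA_integer_,
                          series = series, nls = NULL,
                          message = conditionMessage(fit)),
                     class = "si50_fit"))
  }
  co <- fit$par
  conv <- fit$info %in% 1:3 && is.finite(co[["D"]])
  out <- structure(list(A = co[["A"]], B = co[["B"]],
                        C = co[["C"]], D = co[["D"]],
                        r_squared = NA_real_, converged = conv,
                        n_iterations = fit$niter,
                        series = series, nls = fit,
                        message = if (!conv) fit$message else NULL),
                   class = "si50_fit")
  out$r_squared <- tryCatch(si50_r_squared(out), error = function(e) NA_real_)
  out
}

#' Goodness of fit of an SI50 model
#'
#' Computed over the real (non-artificial) points only:
#' `R^2 = 1 - sum(r^2) / sum((x - mean(x))^2)` where `r` are the residuals
#' of the fitted curve at the real points and `x` the observed cross scores.
#' The denominator uses deviations of the scores themselves, so unlike a
#' conventional coefficient of determination this quantity can be negative
#' for a fit worse than the mean.
#'
#' @param fit an `si50_fit`.
#' @return the R-squared value.
#' @export
si50_r_squared <- function(fit) {
  stopifnot(inherits(fit, "si50_fit"))
  if (!isTRUE(fit$converged)) return(NA_real_)
  real <- fit$series[!fit$series$artificial, ]
  pred <- fit$A + (fit$B - fit$A) * stats::plogis((real$x - fit$D) / fit$C)
  denom <- sum((real$y - mean(real$y))^2)
  if (denom == 0) stop("R-squared undefined: all observed scores identical")
  1 - sum((real$y - pred)^2) / denom
}

#' @export
print.si50_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<si50_fit> not converged:", x$message %||% "optimizer flagged", "\n")
    return(invisible(x))
  }
  cat(sprintf("<si50_fit> SI50 = %.3f (A = %.2f, B = %.2f, C = %.3f), R2 = %.3f\n",
              x$D, x$A, x$B, x$C, x$r_squared))
  invisible(x)
}

#' @export
#' @rdname fit_si50
#' @method tidy si50_fit
tidy.si50_fit <- function(x, ...) {
  tibble::tibble(term = c("A", "B", "C", "D"),
                 estimate = c(x$A, x$B, x$C, x$D))
}

#' @export
#' @rdname fit_si50
#' @method glance si50_fit
glance.si50_fit <- function(x, ...) {
  tibble::tibble(si50 = x$D, r_squared = x$r_squared,
                 converged = x$converged,
                 n_real = attr(x$series, "n_real"),
                 n_iterations = x$n_iterations)
}

#' Quantile curve and fitted logistic
#'
#' @param object an `si50_fit`.
#' @param ... unused.
#' @return a ggplot of the real quantile points with the fitted curve.
#' @export
#' @method autoplot si50_fit
autoplot.si50_fit <- function(object, ...) {
  real <- object$series[!object$series$artificial, ]
  grid <- tibble::tibble(x = seq(0, 1, length.out = 200))
  grid$y <- object$A + (object$B - object$A) *
    stats::plogis((grid$x - object$D) / object$C)
  ggplot2::ggplot(real, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$D, linetype = 2) +
    ggplot2::labs(x = "quantile", y = "compatibility score + 1",
                  title = sprintf("SI50 = %.3f", object$D)) +
    ggplot2::theme_minimal()
}

#' SI50 table for all family pairs of a diallel
#'
#' Fits one SI50 curve per within-family score set and per ordered
#' between-family score set (female family x male family), using
#' [subset_scores()]. Groups with fewer than `min_n` observed scores, or
#' whose scores are all identical, are reported but skipped.
#'
#' @param d a [diallel] object with family metadata.
#' @param min_n minimum number of real scores required to attempt a fit.
#' @param include_selfs include self-pollinations in within-family sets.
#' @return tibble with one row per family pair: `family_a` (female),
#'   `family_b` (male), `type` ("within"/"between"), `n`, `si50`, `A`, `B`,
#'   `C`, `r_squared`, `converged`, `skipped`, `reason`.
#' @export
group_si50 <- function(d, min_n = 10L, include_selfs = FALSE) {
  stopifnot(inherits(d, "diallel"))
  fams <- sort(unique(d$meta$family))
  grid <- expand.grid(family_a = fams, family_b = fams,
                      stringsAsFactors = FALSE)
  purrr::pmap_dfr(grid, function(family_a, family_b) {
    sc <- subset_scores(d, family_a, family_b, include_selfs = include_selfs)
    row <- tibble::tibble(
      family_a = family_a, family_b = family_b,
      type = if (family_a == family_b) "within" else "between",
      n = length(sc), si50 = NA_real_, A = NA_real_, B = NA_real_,
      C = NA_real_, r_squared = NA_real_, converged = NA,
      skipped = TRUE, reason = NA_character_
    )
    if (length(sc) < min_n) {
      row$reason <- sprintf("only %d scores (floor %d)", length(sc), min_n)
      return(row)
    }
    if (length(unique(sc)) == 1) {
      row$reason <- "degenerate: all scores identical"
      return(row)
    }
    fit <- fit_si50(sc)
    row$si50 <- fit$D; row$A <- fit$A; row$B <- fit$B; row$C <- fit$C
    row$r_squared <- fit$r_squared
    row$converged <- fit$converged
    row$skipped <- !isTRUE(fit$converged)
    if (row$skipped) row$reason <- "fit did not converge"
    row
  })
}
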