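#' Pollination profiles of a diallel
#'
#' Each genotype's profile concatenates its matrix row (scores as pollen
#' recipient against every genotype, selfs included) and its column (scores
#' as pollen donor), so both pollination roles -- and any reciprocal
#' asymmetry -- inform similarity. Missing cells stay missing in the
#' profile. `mode` restricts the profile to one role if wanted.
#'
#' @param d a [diallel] object.
#' @param mode `"concat"` (default), `"female"` (rows only) or `"male"`
#'   (columns only).
#' @return numeric matrix, one row per genotype (`n x 2n` for `"concat"`).
#' @export
build_profiles <- function(d, mode = c("concat", "female", "male")) {
  stopifnot(inherits(d, "diallel"))
  mode <- match.arg(mode)
  m <- d$scores
  storage.mode(m) <- "double"
  out <- switch(mode,
    concat = cbind(m, t(m)),
    female = m,
    male = t(m)
  )
  rownames(out) <- rownames(m)
  out
}

#' Pairwise Euclidean distance with missing-value removal
#'
#' Distance between two profiles is computed over their jointly scored
#' coordinates and rescaled up proportionally to the missing fraction:
#' `d(a, b) = sqrt(p / m * sum_shared (a - b)^2)` with `p` the profile
#' length and `m` the number of jointly present coordinates (the
#' pairwise-complete convention). With no missing values this is the plain
#' Euclidean distance.
#'
#' @param profiles profile matrix from [build_profiles()] (rows =
#'   genotypes), or a [diallel] object.
#' @param rescale apply the `p/m` proportional rescaling (default); with
#'   `FALSE` the raw sum over shared coordinates is used.
#' @param ... passed to [build_profiles()] when a diallel is given.
#' @return symmetric distance matrix with zero diagonal.
#' @export
cc_distance <- function(profiles, rescale = TRUE, ...) {
  if (inherits(profiles, "diallel")) profiles <- build_profiles(profiles, ...)
  present <- !is.na(profiles)
  shared <- tcrossprod(present * 1)
  if (any(shared == 0)) {
    bad <- which(shared == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("profiles of %s and %s share no scored coordinate",
                 rownames(profiles)[bad[1]], rownames(profiles)[bad[2]]))
  }
  if (rescale) {
    dm <- as.matrix(stats::dist(profiles))  # dist() applies p/m rescaling
  } else {
    p0 <- profiles
    p0[is.na(p0)] <- 0
    # sum over shared coords only: zero-filled cross terms drop the rest
    g <- tcrossprod(p0)
    sa <- tcrossprod(p0^2, present * 1)
    dm <- sqrt(pmax(sa + t(sa) - 2 * g, 0))
  }
  dimnames(dm) <- list(rownames(profiles), rownames(profiles))
  diag(dm) <- 0
  dm
}

#' Principal components of the pollination-distance structure
#'
#' Each genotype's feature vector is its row of the Euclidean distance
#' matrix; features are column-centered but not variance-scaled, then
#' decomposed by SVD. Component scores are the projections and variance
#' fractions come from the squared singular values. On diallel data these
#' components summarise similarity of pollination behaviour and, once
#' matched across replicate years, are reported as Compatibility Components
#' (CCs).
#'
#' @param dist_matrix symmetric distance matrix from [cc_distance()].
#' @param k number of components to retain (default all).
#' @param center center the feature columns before SVD (default; the
#'   uncentered variant is kept for sensitivity checks).
#' @return a `cc_result`: `scores` (n x k matrix), `variance_fraction`,
#'   `cumulative_variance`, `labels`, `degenerate` flag.
#' @export
cc_pca <- function(dist_matrix, k = NULL, center = TRUE) {
  stopifnot(is.matrix(dist_matrix), nrow(dist_matrix) == ncol(dist_matrix))
  n <- nrow(dist_matrix)
  if (is.null(k)) k <- n
  if (k > n) stop("k must not exceed the number of genotypes")
  x <- scale(dist_matrix, center = center, scale = FALSE)
  sv <- svd(x)
  tot <- sum(sv$d^2)
  degenerate <- tot < .Machine$double.eps * n
  vf <- if (degenerate) rep(0, k) else (sv$d^2 / tot)[seq_len(k)]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- rownames(dist_matrix)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 variance_fraction = vf,
                 cumulative_variance = cumsum(vf),
                 labels = colnames(scores),
                 degenerate = degenerate),
            class = "cc_result")
}

#' Derive components from a diallel in one step
#'
#' Convenience wrapper: profiles -> missing-value Euclidean distance ->
#' unscaled PCA.
#'
#' @param d a [diallel] object.
#' @param k components to retain.
#' @param mode profile mode, see [build_profiles()].
#' @return a `cc_result`.
#' @export
derive_components <- function(d, k = NULL, mode = "concat") {
  cc_pca(cc_distance(build_profiles(d, mode = mode)), k = k)
}

#' @export
print.cc_result <- function(x, ...) {
  k <- min(6, length(x$variance_fraction))
  cat(sprintf("<cc_result> %d genotypes x %d components\n", nrow(x$scores),
              ncol(x$scores)))
  cat("  cumulative variance:",
      paste(sprintf("%s %.0f%%", x$labels[1:k],
                    100 * x$cumulative_variance[1:k]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @rdname cc_pca
#' @method tidy cc_result
tidy.cc_result <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "genotype_id") %>%
    tidyr::pivot_longer(-"genotype_id", names_to = "component",
                        values_to = "score")
}

#' @export
#' @rdname cc_pca
#' @method glance cc_result
glance.cc_result <- function(x, ...) {
  tibble::tibble(component = x$labels,
                 variance_fraction = x$variance_fraction,
                 cumulative_variance = x$cumulative_variance)
}

#' Match components across two replicates
#'
#' Principal components are reproducible across replicate years but their
#' order need not be: a component explaining ~13% of variance one year can
#' swap rank with its neighbour the next. Components are therefore matched
#' by greedy assignment on descending absolute Pearson correlation between
#' score vectors, the sign of each matched replicate-2 component is flipped
#' so the correlation is positive, and matched pairs are relabelled CC1..CCn
#' in replicate-1 variance order.
#'
#' @param r1,r2 `cc_result` objects over the same genotypes.
#' @param n_components how many leading components to match (default 4).
#' @return a `cc_match`: `match` tibble (`cc`, `component_rep1`,
#'   `component_rep2`, `correlation`, `sign`), plus `r1` and sign-aligned,
#'   reordered `r2` score matrices restricted to the matched components.
#' @export
match_components <- function(r1, r2, n_components = 4L) {
  stopifnot(inherits(r1, "cc_result"), inherits(r2, "cc_result"))
  g1 <- rownames(r1$scores); g2 <- rownames(r2$scores)
  if (!setequal(g1, g2)) stop("replicates cover different genotype sets")
  s1 <- r1$scores[g1, seq_len(n_components), drop = FALSE]
  s2 <- r2$scores[g1, seq_len(n_components), drop = FALSE]
  cm <- stats::cor(s1, s2)
  # greedy: repeatedly take the strongest remaining |correlation|, retiring
  # its row (replicate-1 component) and column (replicate-2 component)
  amap <- integer(n_components)
  masked <- abs(cm)
  for (step in seq_len(n_components)) {
    ij <- which(masked == max(masked), arr.ind = TRUE)[1, ]
    amap[ij[1]] <- ij[2]
    masked[ij[1], ] <- -Inf
    masked[, ij[2]] <- -Inf
  }
  corr <- cm[cbind(seq_len(n_components), amap)]
  sgn <- ifelse(corr >= 0, 1, -1)
  aligned <- sweep(s2[, amap, drop = FALSE], 2, sgn, `*`)
  labels <- paste0("CC", seq_len(n_components))
  colnames(aligned) <- labels
  s1m <- s1
  colnames(s1m) <- labels
  structure(list(
    match = tibble::tibble(
      cc = labels,
      component_rep1 = paste0("PC", seq_len(n_components)),
      component_rep2 = paste0("PC", amap),
      correlation = abs(corr),
      sign = sgn
    ),
    scores_rep1 = s1m,
    scores_rep2 = aligned
  ), class = "cc_match")
}

#' @export
print.cc_match <- function(x, ...) {
  cat("<cc_match>\n")
  print(as.data.frame(x$match), row.names = FALSE)
  invisible(x)
}

#' Cluster genotypes in component space
#'
#' Agglomerative hierarchical clustering (Ward criterion) on the Euclidean
#' distances of the first `n_components` component scores, cut at
#' `n_clusters`.
#'
#' @param scores a `cc_result`, `cc_match` (replicate-1 scores used) or a
#'   numeric score matrix.
#' @param n_clusters number of clusters to cut.
#' @param n_components leading components used for the distance.
#' @return tibble (`genotype_id`, `cluster`); the `hclust` tree is attached
#'   as attribute `"tree"`.
#' @export
cluster_genotypes <- function(scores, n_clusters = 4L, n_components = 4L) {
  if (inherits(scores, "cc_result")) scores <- scores$scores
  if (inherits(scores, "cc_match")) scores <- scores$scores_rep1
  k <- min(n_components, ncol(scores))
  if (n_clusters > nrow(scores)) stop("more clusters than genotypes")
  tree <- stats::hclust(stats::dist(scores[, seq_len(k), drop = FALSE]),
                        method = "ward.D2")
  cl <- stats::cutree(tree, k = n_clusters)
  out <- tibble::tibble(genotype_id = rownames(scores),
                        cluster = unname(cl))
  attr(out, "tree") <- tree
  out
}

#' Scatter of genotypes in component space
#'
#' @param object a `cc_result`.
#' @param components pair of components to plot.
#' @param colour optional vector (named by genotype id) for point colour,
#'   e.g. family or cluster labels.
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @method autoplot cc_result
autoplot.cc_result <- function(object, components = c(1, 2), colour = NULL,
                               ...) {
  df <- tibble::tibble(
    genotype_id = rownames(object$scores),
    x = object$scores[, components[1]],
    y = object$scores[, components[2]]
  )
  lab <- sprintf("%s (%.0f%%)", object$labels[components],
                 100 * object$variance_fraction[components])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(colour)) {
    df$colour <- colour[df$genotype_id]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                          colour = .data$colour))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
}
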