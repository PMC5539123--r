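#' Construct a diallel compatibility matrix
#'
#' A diallel cross scores every genotype against every other (and itself) in
#' both pollination directions. Scores are ordinal on a 0--10 rubric
#' (0 = fully incompatible, 4 = half-compatible, 7 = three-quarters
#' compatible, 10 = fully compatible); cells that could not be scored are
#' missing. Rows are the pollen recipient (female) and columns the pollen
#' donor (male), so `scores[i, j]` is the reaction of pollen from genotype
#' `j` on stigmas of genotype `i`. The diagonal holds self-pollinations.
#'
#' @param scores square numeric matrix of integer scores in `[0, 10]` with
#'   `NA` for missing cells; dimnames give the genotype ids (row and column
#'   order must agree).
#' @param family named character vector (names = genotype ids) or a data
#'   frame with columns `genotype_id` and `family` assigning each genotype to
#'   a half-sib family.
#' @param replicate single string tagging the replicate (e.g. a year).
#'
#' @return An object of class `diallel`: the validated integer score matrix
#'   plus a `meta` tibble (`genotype_id`, `family`) and the replicate tag.
#' @export
diallel <- function(scores, family = NULL, replicate = NA_character_) {
  if (!is.matrix(scores) || nrow(scores) != ncol(scores)) {
    stop_diallel("not_square", "`scores` must be a square matrix")
  }
  ids <- rownames(scores)
  if (is.null(ids) || is.null(colnames(scores))) {
    stop_diallel("missing_ids", "`scores` must carry genotype ids as dimnames")
  }
  if (!identical(ids, colnames(scores))) {
    stop_diallel("id_mismatch", "row and column genotype ids must be identical")
  }
  if (anyDuplicated(ids) || any(!nzchar(ids))) {
    stop_diallel("duplicate_id", "genotype ids must be unique and non-empty")
  }
  vals <- scores[!is.na(scores)]
  if (length(vals) && (any(vals < 0 | vals > 10) || any(vals != round(vals)))) {
    stop_diallel("score_range",
                 "scores must be integers in [0, 10]; got values outside the rubric")
  }
  storage.mode(scores) <- "integer"

  if (is.null(family)) {
    fam <- rep(NA_character_, length(ids))
  } else if (is.data.frame(family)) {
    idx <- match(ids, family$genotype_id)
    if (anyNA(idx)) {
      stop_diallel("unknown_genotype",
                   paste("no family entry for genotype(s):",
                         paste(ids[is.na(idx)], collapse = ", ")))
    }
    fam <- as.character(family$family[idx])
  } else {
    fam <- as.character(family[ids])
  }
  structure(
    list(scores = scores,
         meta = tibble::tibble(genotype_id = ids, family = fam),
         replicate = as.character(replicate)),
    class = "diallel"
  )
}

stop_diallel <- function(code, msg) {
  stop(structure(class = c(paste0("sicompat_", code), "sicompat_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' @export
print.diallel <- function(x, ...) {
  n <- nrow(x$scores)
  n_missing <- sum(is.na(x$scores))
  cat(sprintf("<diallel> %d x %d genotypes, replicate %s\n", n, n,
              x$replicate))
  fams <- table(x$meta$family, useNA = "ifany")
  cat("  families:", paste(sprintf("%s (%d)", names(fams), fams),
                           collapse = ", "), "\n")
  cat(sprintf("  scored cells: %d, missing: %d (%.1f%%)\n",
              n * n - n_missing, n_missing, 100 * n_missing / (n * n)))
  invisible(x)
}

#' Read a diallel matrix from delimited text
#'
#' Expects the wide interchange format: a header row of genotype ids, a first
#' column of genotype ids, female (recipient) rows by male (donor) columns,
#' `NA` or empty for missing.
#'
#' @param path file path (tab-delimited).
#' @param family optional metadata: path to a two-column tab-delimited file
#'   (`genotype_id`, `family`) or a data frame.
#' @param replicate replicate tag attached to the matrix.
#' @return a [diallel] object.
#' @export
read_diallel <- function(path, family = NULL, replicate = NA_character_) {
  raw <- utils::read.delim(path, check.names = FALSE, row.names = 1,
                           na.strings = c("NA", ""))
  m <- as.matrix(raw)
  if (is.character(family) && length(family) == 1) {
    family <- utils::read.delim(family, colClasses = "character")
  }
  diallel(m, family = family, replicate = replicate)
}

#' Write a diallel matrix to delimited text
#'
#' Inverse of [read_diallel()]; round-trips scores, missing mask and
#' genotype order.
#'
#' @param d a [diallel] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diallel <- function(d, path) {
  stopifnot(inherits(d, "diallel"))
  out <- data.frame(genotype_id = rownames(d$scores), d$scores,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Long-form view of a diallel matrix
#'
#' One row per cell: `female_id`, `male_id`, their families, the score
#' (`NA` when unscored), whether the cell is a self-pollination, and the
#' replicate tag. This is the interchange format used by brute-force
#' cross-checks and by the grouped SI50 fits.
#'
#' @param x a [diallel] object.
#' @param ... unused.
#' @return a tibble with `n^2` rows.
#' @export
#' @method as_tibble diallel
as_tibble.diallel <- function(x, ...) {
  ids <- x$meta$genotype_id
  fam <- stats::setNames(x$meta$family, ids)
  tibble::tibble(
    female_id = rep(ids, times = length(ids)),
    male_id = rep(ids, each = length(ids)),
    female_family = unname(fam[rep(ids, times = length(ids))]),
    male_family = unname(fam[rep(ids, each = length(ids))]),
    score = as.integer(x$scores[cbind(rep(seq_along(ids), times = length(ids)),
                                      rep(seq_along(ids), each = length(ids)))]),
    is_self = rep(ids, times = length(ids)) == rep(ids, each = length(ids)),
    replicate = x$replicate
  )
}

#' Flag large reciprocal differences
#'
#' A cross is scored in both directions (A female x B male and B female x
#' A male). Under a purely gametophytic model reciprocal scores should agree
#' up to scoring noise; a difference greater than three rubric points is
#' treated as a genuinely different compatibility reaction and flagged.
#' Pairs with either direction missing are skipped; selfs are never flagged.
#'
#' @param d a [diallel] object.
#' @return tibble with one row per flagged unordered pair: `id_a`, `id_b`,
#'   `score_fw` (a female x b male), `score_rev`, `abs_difference`.
#' @export
reciprocal_flags <- function(d) {
  stopifnot(inherits(d, "diallel"))
  m <- d$scores
  ids <- rownames(m)
  n <- length(ids)
  if (n < 2) {
    return(tibble::tibble(id_a = character(), id_b = character(),
                          score_fw = integer(), score_rev = integer(),
                          abs_difference = integer()))
  }
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  fw <- m[pairs]
  rev <- m[pairs[, c(2, 1), drop = FALSE]]
  keep <- !is.na(fw) & !is.na(rev) & abs(fw - rev) > 3L
  tibble::tibble(
    id_a = ids[pairs[keep, 1]],
    id_b = ids[pairs[keep, 2]],
    score_fw = fw[keep],
    score_rev = rev[keep],
    abs_difference = abs(fw - rev)[keep]
  )
}

#' Correlation between two replicate diallels
#'
#' Pearson (default) correlation over cells scored in both replicates,
#' optionally restricted to a subset of crosses: all shared cells, cells
#' within one half-sib family, or one genotype's crosses as female or as
#' male parent. Genotypes present in only one replicate are dropped before
#' matching cells.
#'
#' @param m1,m2 [diallel] objects (e.g. two years).
#' @param subset one of `"all"`, `"family"`, `"female"`, `"male"`.
#' @param who family label (for `subset = "family"`) or genotype id (for
#'   `"female"` / `"male"`).
#' @param method correlation method passed to [stats::cor()]; the index is
#'   reported as Pearson's R by default, `"spearman"` is available.
#' @return tibble with `estimate`, `n_shared`, `method`.
#' @export
replicate_correlation <- function(m1, m2,
                                  subset = c("all", "family", "female", "male"),
                                  who = NULL,
                                  method = c("pearson", "spearman")) {
  stopifnot(inherits(m1, "diallel"), inherits(m2, "diallel"))
  subset <- match.arg(subset)
  method <- match.arg(method)
  shared <- intersect(rownames(m1$scores), rownames(m2$scores))
  a <- m1$scores[shared, shared, drop = FALSE]
  b <- m2$scores[shared, shared, drop = FALSE]
  keep <- matrix(TRUE, length(shared), length(shared),
                 dimnames = list(shared, shared))
  if (subset == "family") {
    fam <- stats::setNames(m1$meta$family, m1$meta$genotype_id)[shared]
    if (is.null(who) || !who %in% fam) {
      stop_diallel("unknown_family", paste("unknown family:", who))
    }
    keep <- outer(fam == who, fam == who, `&`)
  } else if (subset == "female") {
    if (is.null(who) || !who %in% shared) {
      stop_diallel("unknown_genotype", paste("unknown genotype:", who))
    }
    keep[,] <- FALSE; keep[who, ] <- TRUE
  } else if (subset == "male") {
    if (is.null(who) || !who %in% shared) {
      stop_diallel("unknown_genotype", paste("unknown genotype:", who))
    }
    keep[,] <- FALSE; keep[, who] <- TRUE
  }
  use <- keep & !is.na(a) & !is.na(b)
  n_shared <- sum(use)
  if (n_shared < 3) {
    stop_diallel("undefined_correlation",
                 sprintf("only %d shared scored cells (need >= 3)", n_shared))
  }
  tibble::tibble(
    estimate = stats::cor(a[use], b[use], method = method),
    n_shared = n_shared,
    method = method
  )
}

#' Extract scores for a family pair
#'
#' All non-missing scores whose female parent belongs to `family_a` and male
#' parent to `family_b`. With `family_a == family_b` this is the
#' within-family score set (both cross directions are present by
#' construction); self-pollinations are excluded unless `include_selfs`.
#'
#' @param d a [diallel] object with family metadata.
#' @param family_a,family_b half-sib family labels (female, male side).
#' @param include_selfs keep the diagonal when `family_a == family_b`.
#' @return integer vector of scores.
#' @export
subset_scores <- function(d, family_a, family_b, include_selfs = FALSE) {
  stopifnot(inherits(d, "diallel"))
  fams <- unique(d$meta$family)
  missing_fam <- setdiff(c(family_a, family_b), fams)
  if (length(missing_fam)) {
    stop_diallel("unknown_family",
                 paste("unknown family label(s):",
                       paste(missing_fam, collapse = ", ")))
  }
  rows <- d$meta$family == family_a
  cols <- d$meta$family == family_b
  m <- d$scores[rows, cols, drop = FALSE]
  if (!include_selfs) {
    selfs <- outer(d$meta$genotype_id[rows], d$meta$genotype_id[cols], `==`)
    m[selfs] <- NA_integer_
  }
  as.integer(m[!is.na(m)])
}

#' Heat map of a diallel matrix
#'
#' Genotypes are ordered by half-sib family blocks on both axes; pollen
#' donors run horizontally, recipients vertically, matching the usual
#' presentation of diallel compatibility data.
#'
#' @param object a [diallel] object.
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @method autoplot diallel
autoplot.diallel <- function(object, ...) {
  ord <- order(object$meta$family, object$meta$genotype_id)
  ids <- object$meta$genotype_id[ord]
  long <- as_tibble.diallel(object)
  long$female_id <- factor(long$female_id, levels = rev(ids))
  long$male_id <- factor(long$male_id, levels = ids)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$male_id, y = .data$female_id,
                                     fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 10), na.value = "white") +
    ggplot2::labs(x = "pollen donor (male)", y = "pollen recipient (female)",
                  fill = "score",
                  title = sprintf("Diallel compatibility (%s)",
                                  object$replicate)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
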