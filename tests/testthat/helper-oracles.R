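# Fixture builders and independent brute-force oracles used across tests.

# random diallel matrix with family labels, optional missing cells
rand_diallel <- function(n = 6, seed = 1, missing_rate = 0.1,
                         families = 2, replicate = "r1") {
  set.seed(seed)
  ids <- sprintf("G%02d", seq_len(n))
  m <- matrix(sample(0:10, n * n, replace = TRUE), n, n,
              dimnames = list(ids, ids))
  m[matrix(runif(n * n) < missing_rate, n, n)] <- NA_integer_
  fam <- setNames(sprintf("FAM-%d", rep_len(seq_len(families), n)), ids)
  diallel(m, family = fam, replicate = replicate)
}

# exhaustive double loop over ordered pairs, counting each unordered pair once
oracle_reciprocal_count <- function(m) {
  n <- nrow(m)
  cnt <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && !is.na(m[i, j]) && !is.na(m[j, i]) &&
        abs(m[i, j] - m[j, i]) > 3) {
      cnt <- cnt + 1
    }
  }
  cnt
}

# textbook Pearson correlation from first principles
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# gamete-enumeration oracle for the compatibility rule: walk the full
# cartesian product of the pollen parent's allele copies across loci
oracle_compatible_fraction <- function(pollen, stigma) {
  loci <- names(pollen)
  combos <- expand.grid(lapply(pollen[loci], identity))
  rejected <- apply(combos, 1, function(g) {
    all(vapply(seq_along(loci),
               function(k) g[k] %in% stigma[[loci[k]]], logical(1)))
  })
  1 - mean(rejected)
}

# pairwise-complete Euclidean distance, written out longhand
oracle_distance <- function(a, b) {
  shared <- !is.na(a) & !is.na(b)
  sqrt(length(a) / sum(shared) * sum((a[shared] - b[shared])^2))
}

# scores drawn from the four-parameter logistic quantile curve, on the raw
# 0-10 scale, with optional Gaussian scoring noise before rounding
logistic_scores <- function(n, D, C = 0.05, noise_sd = 0) {
  x <- seq_len(n) / (n + 1)
  y <- 10 / (1 + exp((D - x) / C))
  pmin(10L, pmax(0L, as.integer(round(y + rnorm(n, 0, noise_sd)))))
}

# small genotype tibble in the interchange layout
make_genotype_tbl <- function(dosage, lg = NULL, cM = NULL) {
  m <- nrow(dosage)
  tibble::tibble(
    marker = rownames(dosage) %||% sprintf("m%03d", seq_len(m)),
    lg = as.character(lg %||% rep(1, m)),
    cM = cM %||% seq_len(m)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(dosage))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
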