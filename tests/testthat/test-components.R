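test_that("profiles concatenate female and male roles and propagate the
           missing mask", {
  d <- rand_diallel(n = 3, seed = 1, missing_rate = 0)
  p <- build_profiles(d)
  expect_equal(dim(p), c(3, 6))
  expect_equal(unname(p[1, ]), unname(c(d$scores[1, ], d$scores[, 1])))

  m <- d$scores
  m["G01", "G03"] <- NA_integer_
  dm <- diallel(m)
  pm <- build_profiles(dm)
  expect_true(is.na(pm["G01", 3]))      # row segment of genotype 1
  expect_true(is.na(pm["G03", 3 + 1]))  # column segment of genotype 3

  # symmetric matrix: both segments coincide
  ms <- matrix(c(0L, 5L, 5L, 0L), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  ps <- build_profiles(diallel(ms))
  expect_equal(ps[, 1:2], ps[, 3:4])
})

test_that("missing-value Euclidean distance matches the stated formula and
           the textbook distance when complete", {
  a <- c(1, 2, NA); b <- c(1, 0, 5)
  pr <- rbind(a = a, b = b)
  dm <- cc_distance(pr)
  expect_equal(dm["a", "b"], sqrt(6), tolerance = 1e-12)
  expect_equal(dm["a", "b"], oracle_distance(a, b))

  set.seed(2)
  full <- matrix(rnorm(40), 5, 8, dimnames = list(letters[1:5], NULL))
  expect_equal(cc_distance(full), as.matrix(dist(full)), ignore_attr = TRUE)
  expect_equal(cc_distance(full), cc_distance(full, rescale = FALSE))

  holes <- full
  holes[sample(40, 12)] <- NA
  dm2 <- cc_distance(holes)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(dm2[i, j], oracle_distance(holes[i, ], holes[j, ]))
  }

  # a pair with zero shared coordinates is a hard, named error
  x <- rbind(p = c(1, NA), q = c(NA, 2))
  expect_error(cc_distance(x), "share no scored coordinate")
})

test_that("unscaled PCA reproduces an independent eigendecomposition and
           orders variance fractions", {
  set.seed(3)
  pts <- matrix(rnorm(12), 4, 3)
  dm <- as.matrix(dist(pts))
  res <- cc_pca(dm)
  expect_true(all(diff(res$variance_fraction) <= 1e-12))
  expect_lte(sum(res$variance_fraction), 1 + 1e-12)

  # eigen-oracle on the centered feature covariance
  x <- scale(dm, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(x), symmetric = TRUE)$values
  expect_equal(res$variance_fraction, ev[1:4] / sum(ev), tolerance = 1e-9)
  # scores are orthogonal projections
  expect_equal(crossprod(res$scores)[lower.tri(diag(4))],
               rep(0, 6), tolerance = 1e-8)

  # duplicated genotypes land on identical scores
  d <- rand_diallel(n = 5, seed = 4, missing_rate = 0)
  m <- d$scores
  m2 <- rbind(cbind(m, dup = m[, 5]), dup = c(m[5, ], m[5, 5]))
  dimnames(m2) <- list(c(rownames(m), "dup2"), c(rownames(m), "dup2"))
  dm2 <- cc_distance(build_profiles(diallel(m2)))
  r2 <- cc_pca(dm2, k = 4)
  expect_equal(r2$scores["G05", ], r2$scores["dup2", ], tolerance = 1e-8)
})

test_that("component matching recovers a constructed rank switch and sign
           flips, and is always a bijection", {
  d <- rand_diallel(n = 12, seed = 6, missing_rate = 0.05)
  r1 <- derive_components(d)
  # replicate 2 = replicate 1 with components 3 and 4 swapped
  r2 <- r1
  r2$scores[, c(3, 4)] <- r2$scores[, c(4, 3)]
  mt <- match_components(r1, r2)
  expect_equal(mt$match$component_rep2, c("PC1", "PC2", "PC4", "PC3"))
  expect_equal(mt$match$correlation, rep(1, 4), tolerance = 1e-10)

  # full sign flip: identity matching, all signs -1, aligned scores positive
  r3 <- r1
  r3$scores <- -r3$scores
  mt3 <- match_components(r1, r3)
  expect_equal(mt3$match$component_rep2, paste0("PC", 1:4))
  expect_equal(mt3$match$sign, rep(-1, 4))
  expect_equal(unname(mt3$scores_rep2), unname(mt3$scores_rep1),
               tolerance = 1e-10)

  # independent random scores still produce a bijection
  set.seed(7)
  for (rep in 1:5) {
    rr <- r1
    rr$scores <- matrix(rnorm(length(r1$scores)), nrow = nrow(r1$scores),
                        dimnames = dimnames(r1$scores))
    mm <- match_components(r1, rr)
    expect_setequal(mm$match$component_rep2, paste0("PC", 1:4))
  }
  # mismatched genotype sets are rejected
  r4 <- r1
  rownames(r4$scores)[1] <- "other"
  expect_error(match_components(r1, r4), "different genotype sets")
})

test_that("Ward clustering recovers separated groups and ignores input
           order", {
  set.seed(8)
  centers <- rbind(c(0, 0, 0, 0), c(20, 0, 0, 0), c(0, 20, 0, 0),
                   c(0, 0, 20, 0))
  scores <- centers[rep(1:4, each = 6), ] + matrix(rnorm(96, 0, 0.5), 24, 4)
  rownames(scores) <- sprintf("g%02d", 1:24)
  cl <- cluster_genotypes(scores, n_clusters = 4)
  truth <- rep(1:4, each = 6)
  expect_equal(length(unique(paste(cl$cluster, truth))), 4)

  # permutation invariance up to relabeling
  p <- sample(24)
  clp <- cluster_genotypes(scores[p, ], n_clusters = 4)
  joined <- merge(cl, clp, by = "genotype_id")
  expect_equal(length(unique(paste(joined$cluster.x, joined$cluster.y))), 4)

  # n_clusters = n gives singletons
  cls <- cluster_genotypes(scores[1:5, ], n_clusters = 5)
  expect_equal(sort(cls$cluster), 1:5)
  expect_error(cluster_genotypes(scores[1:3, ], n_clusters = 4),
               "more clusters than genotypes")
})

test_that("with complete data the pipeline equals the computation on
           complete profiles, and shared SI genotypes sit closer in CC
           space", {
  d <- rand_diallel(n = 8, seed = 9, missing_rate = 0)
  pr <- build_profiles(d)
  expect_equal(cc_distance(pr), cc_distance(pr, rescale = FALSE))

  # genotypes with identical S and Z pairs are nearer in component space
  # than genotypes sharing neither allele at either locus
  gaps <- replicate(5, {
    s <- sample(1e6, 1)
    cfg <- sim_config(n_families = 2L, family_sizes = c(10L, 10L),
                      n_founders = 8L, n_lg = 2L, markers_per_lg = 10L,
                      loci = list(si_locus("S", 1, 10, 5),
                                  si_locus("Z", 2, 10, 5)),
                      seed = s)
    pop <- simulate_population(cfg)
    res <- derive_components(simulate_diallel(pop), k = 4)
    sz <- si_genotypes(pop)
    key <- vapply(sz, function(g)
      paste(sort(g$S), sort(g$Z), collapse = "-"), character(1))
    dd <- as.matrix(dist(res$scores))
    same <- outer(key, key, `==`) & upper.tri(dd)
    disjoint <- outer(seq_along(sz), seq_along(sz), Vectorize(function(i, j) {
      !any(sz[[i]]$S %in% sz[[j]]$S) && !any(sz[[i]]$Z %in% sz[[j]]$Z)
    })) & upper.tri(dd)
    if (!any(same) || !any(disjoint)) return(NA_real_)
    median(dd[disjoint]) - median(dd[same])
  })
  expect_gt(mean(gaps, na.rm = TRUE), 0)
})
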