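# small, fast simulation config used throughout
tiny_cfg <- function(seed, ...) {
  sim_config(n_families = 2L, family_sizes = c(6L, 6L), n_founders = 8L,
             n_lg = 2L, markers_per_lg = 40L,
             loci = list(si_locus("S", 1, 20, 6), si_locus("Z", 2, 30, 6)),
             seed = seed, ...)
}

test_that("compatibility rule reproduces the two-locus model classes", {
  # one gamete (S1 Z1) of four is rejected
  expect_equal(compatible_fraction(pollen = list(S = c(1, 2), Z = c(1, 2)),
                                   stigma = list(S = c(1, 3), Z = c(1, 3))),
               0.75)
  # half-compatible: both S alleles shared, one Z allele shared
  expect_equal(compatible_fraction(pollen = list(S = c(1, 2), Z = c(1, 2)),
                                   stigma = list(S = c(1, 2), Z = c(1, 3))),
               0.5)
  # selfing of a double heterozygote: fully incompatible
  g <- list(S = c(1, 2), Z = c(3, 4))
  expect_equal(compatible_fraction(g, g), 0)
  # no shared S allele: fully compatible regardless of Z
  expect_equal(compatible_fraction(pollen = list(S = c(1, 2), Z = c(1, 2)),
                                   stigma = list(S = c(3, 4), Z = c(1, 2))),
               1)
  expect_error(compatible_fraction(list(S = c(1, 2)), list(Z = c(1, 2))),
               "same named SI loci")
})

test_that("compatibility fraction matches exhaustive gamete enumeration up
           to three loci and six alleles", {
  set.seed(42)
  for (rep in 1:60) {
    n_loci <- sample(1:3, 1)
    loci <- paste0("L", seq_len(n_loci))
    pollen <- setNames(lapply(loci, function(l) sample(1:6, 2)), loci)
    stigma <- setNames(lapply(loci, function(l) sample(1:6, 2)), loci)
    expect_equal(compatible_fraction(pollen, stigma),
                 oracle_compatible_fraction(pollen, stigma))
  }
  # with two loci and full heterozygosity only {0, 1/2, 3/4, 1} can occur
  set.seed(7)
  vals <- replicate(200, {
    pollen <- list(S = sample(1:4, 2), Z = sample(1:4, 2))
    stigma <- list(S = sample(1:4, 2), Z = sample(1:4, 2))
    compatible_fraction(pollen, stigma)
  })
  expect_true(all(vals %in% c(0, 0.5, 0.75, 1)))
})

test_that("strict SI never produces an individual homozygous at every SI
           locus (a jointly matching gamete is always rejected)", {
  # under complementary action a pollen gamete is rejected only when it is
  # matched at ALL loci, so single-locus homozygotes can arise from
  # three-quarter-compatible matings; joint homozygosity cannot
  for (s in 11:13) {
    pop <- simulate_population(tiny_cfg(seed = s, self_fertility_leak = 0))
    for (g in si_genotypes(pop)) {
      expect_false(all(vapply(g, function(p) p[1] == p[2], logical(1))))
    }
  }
})

test_that("the compatibility relation is asymmetric for some pairs", {
  pop <- simulate_population(tiny_cfg(seed = 12))
  lat <- compatibility_matrix(pop)
  expect_gt(sum(abs(lat - t(lat)) > 1e-12), 0)
})

test_that("a marker at the SI position co-segregates with the inherited
           allele within families", {
  # place a locus exactly on a marker position so the flanking markers sit
  # within a fraction of a cM
  cfg <- sim_config(n_families = 2L, family_sizes = c(10L, 10L),
                    n_founders = 8L, n_lg = 1L, markers_per_lg = 81L,
                    lg_length_cM = 80,
                    loci = list(si_locus("S", 1, 40, 6)), seed = 13)
  pop <- simulate_population(cfg)
  tbl <- genotype_table(pop)
  truth <- pop$truth
  # brute-force co-segregation: correlation between allele dosage of the
  # most common S allele and dosage of the marker nearest the locus
  near <- tbl[which.min(abs(tbl$cM - 40)), ]
  dos <- as.numeric(near[1, truth$genotype_id[match(unique(truth$genotype_id),
                                                    truth$genotype_id)]])
  tt <- truth[match(colnames(tbl)[-(1:3)], truth$genotype_id), ]
  top_allele <- as.integer(names(sort(table(c(tt$allele_1, tt$allele_2)),
                                      decreasing = TRUE))[1])
  a_dos <- (tt$allele_1 == top_allele) + (tt$allele_2 == top_allele)
  dos <- as.numeric(near[1, tt$genotype_id])
  # ancestral chromosomes carry the SI allele, so a coincident marker tags
  # allele groups strongly; require a clearly non-null association
  expect_gt(abs(cor(dos, a_dos)), 0.3)
})

test_that("distant markers show no more SI association than unlinked ones", {
  # markers >= 50 cM from the locus behave like the permutation null
  cfg <- sim_config(n_families = 2L, family_sizes = c(12L, 12L),
                    n_founders = 10L, n_lg = 2L, markers_per_lg = 30L,
                    lg_length_cM = 100,
                    loci = list(si_locus("S", 1, 0, 6)), seed = 21)
  cors_far <- c()
  cors_perm <- c()
  for (s in 1:10) {
    cfg$seed <- 20 + s
    pop <- simulate_population(cfg)
    tbl <- genotype_table(pop)
    tt <- pop$truth[match(colnames(tbl)[-(1:3)], pop$truth$genotype_id), ]
    a_dos <- (tt$allele_1 == 1) + (tt$allele_2 == 1)
    if (var(a_dos) == 0) next
    far <- tbl[tbl$lg == 1 & tbl$cM >= 50, ]
    d <- as.matrix(far[, tt$genotype_id])
    keep <- apply(d, 1, var) > 0
    cors_far <- c(cors_far, abs(cor(t(d[keep, ]), a_dos)))
    cors_perm <- c(cors_perm, abs(cor(t(d[keep, ]), sample(a_dos))))
  }
  # same magnitude, not systematically larger than the permuted baseline
  expect_lt(mean(cors_far), mean(cors_perm) + 0.05)
})

test_that("dosage is the haplotype sum and the genotype table round-trips", {
  pop <- simulate_population(tiny_cfg(seed = 14))
  tbl <- genotype_table(pop)
  ind <- pop$individuals[[3]]
  keep <- !pop$map_internal[[1]]$is_si
  expect_equal(as.numeric(tbl[tbl$lg == 1, ind$id][[1]]),
               (ind$h1[[1]] + ind$h2[[1]])[keep])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(pop, path)
  back <- read_genotypes(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))
  # MAF from the table equals allele counting on haplotypes
  maf <- marker_maf(tbl)
  h <- sapply(pop$individuals, function(i) i$h1[[1]][keep][5] + i$h2[[1]][keep][5])
  p <- sum(h) / (2 * length(h))
  expect_equal(unname(maf[5]), min(p, 1 - p))
})

test_that("simulated diallels follow the latent fractions and the seed fixes
           every emitted byte", {
  cfg <- tiny_cfg(seed = 15, score_noise_sd = 0, replicate_noise_sd = 0,
                  missing_rate = 0, self_fertility_leak = 0)
  pop <- simulate_population(cfg)
  d <- simulate_diallel(pop)
  lat <- compatibility_matrix(pop)
  expect_equal(unname(d$scores), unname(round(10 * lat)))
  expect_true(all(diag(d$scores) == 0))  # selfs fully incompatible at leak 0

  # determinism: identical seed, identical files
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  pop1 <- simulate_population(tiny_cfg(seed = 99))
  d1 <- simulate_diallel(pop1)
  write_diallel(d1, p1); write_genotypes(pop1, paste0(p1, ".g"))
  pop2 <- simulate_population(tiny_cfg(seed = 99))
  d2 <- simulate_diallel(pop2)
  write_diallel(d2, p2); write_genotypes(pop2, paste0(p2, ".g"))
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(readLines(paste0(p1, ".g")), readLines(paste0(p2, ".g")))
})

test_that("families built from allele-disjoint founders are mutually
           fully compatible on average", {
  # two mothers sharing no SI alleles: between-family latent scores should
  # be near 10 while within-family crosses include incompatible classes
  found <- replicate(10, NULL)
  cfg <- tiny_cfg(seed = 31)
  pop <- simulate_population(cfg)
  sz <- si_genotypes(pop)
  fam <- vapply(pop$individuals, `[[`, "", "family")
  lat <- 10 * compatibility_matrix(pop)
  between <- lat[fam == "HSF-1", fam == "HSF-2"]
  within <- lat[fam == "HSF-1", fam == "HSF-1"]
  diag(within) <- NA
  expect_gt(mean(between), mean(within, na.rm = TRUE))
})
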