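#' Describe a self-incompatibility locus
#'
#' Grass gametophytic SI is controlled by unlinked, multi-allelic loci (S and
#' Z in ryegrass) acting complementarily: a pollen gamete is rejected only
#' when its allele at *every* SI locus is matched in the stigma's diploid
#' genotype.
#'
#' @param name locus name, e.g. `"S"`.
#' @param linkage_group linkage group (chromosome) carrying the locus.
#' @param position_cM map position on that linkage group, centimorgans.
#' @param n_alleles number of distinct founder alleles in the population.
#' @return an `si_locus` list.
#' @export
si_locus <- function(name, linkage_group, position_cM, n_alleles = 8L) {
  stopifnot(nzchar(name), linkage_group >= 1, position_cM >= 0, n_alleles >= 2)
  structure(list(name = name, linkage_group = as.integer(linkage_group),
                 position_cM = as.numeric(position_cM),
                 n_alleles = as.integer(n_alleles)),
            class = "si_locus")
}

#' Simulation configuration
#'
#' Parameterises the forward simulation of a polycross-derived half-sib
#' population segregating for multi-locus gametophytic SI. Defaults emulate
#' the study design the analysis is built for: four half-sib families
#' totalling 52 genotypes fathered by a shared pollen cloud, two SI loci
#' (S on LG 1 at 20 cM, Z on LG 2 at 54 cM) with a polyallelic series,
#' roughly 2,000 biallelic SNPs across 7 linkage groups, ordinal 0--10
#' scoring noise, year-to-year replicate noise and ~8% unscored cells.
#'
#' @param n_families number of half-sib families (one mother each).
#' @param family_sizes integer vector of progeny counts per family.
#' @param n_founders size of the founder pool; mothers are the first
#'   `n_families` founders, the pollen cloud is every founder except the
#'   mother of the family in hand.
#' @param loci list of [si_locus()] specifications.
#' @param n_lg number of linkage groups.
#' @param lg_length_cM map length of each linkage group (recycled).
#' @param markers_per_lg evenly spaced biallelic markers per linkage group.
#' @param n_ancestral number of ancestral chromosomes per linkage group from
#'   which founder haplotypes are mosaicked; defaults to the largest SI
#'   allele series. Each SI allele rides one ancestral chromosome, which is
#'   what puts markers near an SI locus in linkage disequilibrium with it.
#' @param mosaic_generations expected number of historical meioses separating
#'   founder haplotypes from the ancestral chromosomes (controls ancestral
#'   block length).
#' @param score_noise_sd Gaussian sd of ordinal scoring error on the 0--10
#'   latent scale (scores are rounded and clipped after noise).
#' @param replicate_noise_sd additional per-cell sd applied independently in
#'   each replicate (year effects).
#' @param missing_rate probability a cell goes unscored, in `[0, 1)`.
#' @param self_fertility_leak per-gamete probability that an incompatible
#'   pollen gamete fertilises anyway (partial self-compatibility), `[0, 1)`.
#' @param seed integer random seed; mandatory, every downstream draw is
#'   reproducible from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_families = 4L,
                       family_sizes = c(11L, 12L, 14L, 15L),
                       n_founders = 20L,
                       loci = list(si_locus("S", 1, 20), si_locus("Z", 2, 54)),
                       n_lg = 7L,
                       lg_length_cM = 90,
                       markers_per_lg = 286L,
                       n_ancestral = NULL,
                       mosaic_generations = 12,
                       score_noise_sd = 0.75,
                       replicate_noise_sd = 0.5,
                       missing_rate = 0.08,
                       self_fertility_leak = 0.02,
                       seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("`seed` is mandatory: simulations must be reproducible")
  }
  lg_length_cM <- rep_len(lg_length_cM, n_lg)
  if (length(family_sizes) != n_families) {
    stop("`family_sizes` must have one entry per family")
  }
  if (n_founders < n_families + 1) {
    stop("need more founders than families (mothers plus a pollen cloud)")
  }
  for (r in list(missing_rate = missing_rate,
                 self_fertility_leak = self_fertility_leak)) {
    if (r < 0 || r >= 1) stop("rates must lie in [0, 1)")
  }
  if (score_noise_sd < 0 || replicate_noise_sd < 0) {
    stop("noise standard deviations must be non-negative")
  }
  for (l in loci) {
    if (l$linkage_group > n_lg) stop("SI locus on a linkage group beyond `n_lg`")
    if (l$position_cM > lg_length_cM[l$linkage_group]) {
      stop(sprintf("locus %s lies beyond the end of LG %d", l$name,
                   l$linkage_group))
    }
  }
  pos <- vapply(loci, function(l) paste(l$linkage_group, l$position_cM),
                character(1))
  if (anyDuplicated(pos)) stop("distinct SI loci must occupy distinct positions")
  if (is.null(n_ancestral)) {
    n_ancestral <- max(vapply(loci, `[[`, integer(1), "n_alleles"))
  }
  structure(list(
    n_families = as.integer(n_families),
    family_sizes = as.integer(family_sizes),
    n_founders = as.integer(n_founders),
    loci = loci,
    n_lg = as.integer(n_lg),
    lg_length_cM = lg_length_cM,
    markers_per_lg = as.integer(markers_per_lg),
    n_ancestral = as.integer(n_ancestral),
    mosaic_generations = mosaic_generations,
    score_noise_sd = score_noise_sd,
    replicate_noise_sd = replicate_noise_sd,
    missing_rate = missing_rate,
    self_fertility_leak = self_fertility_leak,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Internal map: per LG, sorted positions of markers plus SI loci, with the SI
# slots flagged so they are co-inherited with the surrounding haplotype but
# never emitted as markers.
build_map <- function(cfg) {
  lapply(seq_len(cfg$n_lg), function(lg) {
    L <- cfg$lg_length_cM[lg]
    pos <- seq(0, L, length.out = cfg$markers_per_lg)
    name <- sprintf("M%d_%04d", lg, seq_along(pos))
    type <- rep("marker", length(pos))
    for (l in cfg$loci) {
      if (l$linkage_group == lg) {
        pos <- c(pos, l$position_cM)
        name <- c(name, l$name)
        type <- c(type, "si")
      }
    }
    ord <- order(pos, type)  # SI slot sorts after a coincident marker
    list(pos = pos[ord], name = name[ord], is_si = type[ord] == "si",
         length_cM = L)
  })
}

# Ancestral chromosomes: one 0/1 marker haplotype per ancestor per LG, with
# ancestor a carrying SI allele ((a - 1) %% n_alleles) + 1 at any SI slot.
build_ancestors <- function(cfg, map) {
  lapply(seq_len(cfg$n_lg), function(lg) {
    mp <- map[[lg]]
    h <- matrix(stats::rbinom(cfg$n_ancestral * length(mp$pos), 1, 0.5),
                nrow = cfg$n_ancestral)
    if (any(mp$is_si)) {
      for (j in which(mp$is_si)) {
        l <- cfg$loci[[match(mp$name[j], vapply(cfg$loci, `[[`, "", "name"))]]
        h[, j] <- ((seq_len(cfg$n_ancestral) - 1L) %% l$n_alleles) + 1L
      }
    }
    h
  })
}

# Poisson crossover process (Haldane, no interference) deciding, at each map
# position, which of two source haplotypes contributes.
crossover_phase <- function(pos, length_cM, rate = 1) {
  k <- stats::rpois(1, rate * length_cM / 100)
  start <- stats::rbinom(1, 1, 0.5)
  if (k == 0) return(rep.int(start, length(pos)))
  cuts <- sort(stats::runif(k, 0, length_cM))
  (start + findInterval(pos, cuts)) %% 2L
}

# A founder haplotype: mosaic of ancestral chromosomes with block structure
# set by `mosaic_generations` rounds of historical recombination.
mosaic_haplotype <- function(cfg, map, anc, lg) {
  mp <- map[[lg]]
  k <- stats::rpois(1, cfg$mosaic_generations * mp$length_cM / 100)
  cuts <- sort(stats::runif(k, 0, mp$length_cM))
  seg <- findInterval(mp$pos, cuts) + 1L
  src <- sample.int(cfg$n_ancestral, length(cuts) + 1L, replace = TRUE)
  anc[[lg]][cbind(src[seg], seq_along(mp$pos))]
}

# One meiosis: recombine an individual's two haplotypes on every LG.
meiosis <- function(ind, map) {
  lapply(seq_along(map), function(lg) {
    phase <- crossover_phase(map[[lg]]$pos, map[[lg]]$length_cM)
    ifelse(phase == 0L, ind$h1[[lg]], ind$h2[[lg]])
  })
}

si_slots <- function(map) {
  out <- list()
  for (lg in seq_along(map)) {
    for (j in which(map[[lg]]$is_si)) {
      out[[map[[lg]]$name[j]]] <- c(lg = lg, idx = j)
    }
  }
  out
}

# Named list of diploid SI allele pairs for one individual.
extract_si_alleles <- function(ind, slots) {
  lapply(slots, function(s) {
    c(ind$h1[[s["lg"]]][s["idx"]], ind$h2[[s["lg"]]][s["idx"]])
  })
}

gamete_si_alleles <- function(gam, slots) {
  lapply(slots, function(s) gam[[s["lg"]]][s["idx"]])
}

# A single pollen gamete is rejected iff its allele at EVERY SI locus is
# present in the stigma's diploid genotype (complementary action).
gamete_rejected <- function(gam_alleles, stigma_alleles) {
  all(vapply(names(gam_alleles),
             function(l) gam_alleles[[l]] %in% stigma_alleles[[l]],
             logical(1)))
}

#' Expected compatible fraction of a pollination
#'
#' For a pollen parent and a stigma (recipient) genotype, enumerates the
#' pollen parent's gametic SI-allele combinations -- equiprobable because the
#' SI loci segregate independently -- and scores each gamete incompatible iff
#' its allele at every SI locus occurs in the stigma's diploid genotype.
#' With two loci and both parents heterozygous everywhere the result is one
#' of 0 (fully incompatible, e.g. selfing), 1/2, 3/4 or 1 (fully
#' compatible); the function generalises to any number of loci.
#'
#' The relation is directional: swapping pollen and stigma parents can
#' change the fraction, which is what generates genuine reciprocal-cross
#' differences in diallel data.
#'
#' @param pollen,stigma named lists giving, per SI locus, the diploid allele
#'   pair (length-2 vector). Locus names must agree between the two records.
#' @return the compatible fraction in `[0, 1]`.
#' @export
#' @examples
#' compatible_fraction(pollen = list(S = c(1, 2), Z = c(1, 2)),
#'                     stigma = list(S = c(1, 3), Z = c(1, 3)))  # 0.75
compatible_fraction <- function(pollen, stigma) {
  loci <- names(pollen)
  if (is.null(loci) || !setequal(loci, names(stigma))) {
    stop("pollen and stigma records must carry the same named SI loci")
  }
  bad <- vapply(loci, function(l) length(pollen[[l]]) != 2 ||
                  length(stigma[[l]]) != 2, logical(1))
  if (any(bad)) {
    stop(sprintf("locus %s must carry exactly two alleles per record",
                 paste(loci[bad], collapse = ", ")))
  }
  # incompatible gametes factorise over loci: per locus, the number of the
  # pollen parent's two allele copies matched in the stigma (0, 1 or 2)
  matched <- vapply(loci, function(l) sum(pollen[[l]] %in% stigma[[l]]),
                    numeric(1))
  1 - prod(matched) / 2^length(loci)
}

#' Simulate a half-sib SI population
#'
#' Forward simulation of one polycross generation. Founder haplotypes are
#' mosaics of a small pool of ancestral chromosomes (each SI allele tied to
#' one ancestral chromosome at its map position, creating the marker-SI
#' linkage disequilibrium that association mapping exploits). Each half-sib
#' family is one mother pollinated by the cloud of remaining founders;
#' pollen gametes are formed by meiosis with Haldane recombination and are
#' accepted only if SI-compatible with the mother's stigma, except with
#' probability `self_fertility_leak`. Under a zero leak every individual in
#' the population is heterozygous at every SI locus.
#'
#' @param cfg a [sim_config()].
#' @return an `si_population`: individuals with their genomes, the marker
#'   map, the founder list and a `truth` tibble of per-genotype SI alleles
#'   for recovery studies.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  map <- build_map(cfg)
  anc <- build_ancestors(cfg, map)
  slots <- si_slots(map)

  new_founder <- function(id) {
    h1 <- lapply(seq_len(cfg$n_lg), function(lg) mosaic_haplotype(cfg, map, anc, lg))
    for (try in 1:200) {
      h2 <- lapply(seq_len(cfg$n_lg), function(lg) mosaic_haplotype(cfg, map, anc, lg))
      f <- list(id = id, h1 = h1, h2 = h2)
      a <- extract_si_alleles(f, slots)
      if (all(vapply(a, function(p) p[1] != p[2], logical(1)))) return(f)
    }
    stop("could not draw an SI-heterozygous founder; increase `n_ancestral`")
  }
  founders <- lapply(seq_len(cfg$n_founders),
                     function(i) new_founder(sprintf("FND%02d", i)))

  individuals <- list()
  for (fam in seq_len(cfg$n_families)) {
    mother <- founders[[fam]]
    stigma <- extract_si_alleles(mother, slots)
    cloud <- setdiff(seq_len(cfg$n_founders), fam)
    for (k in seq_len(cfg$family_sizes[fam])) {
      pollen_gam <- NULL
      for (attempt in 1:1000) {
        father <- founders[[sample(cloud, 1)]]
        gam <- meiosis(father, map)
        ok <- !gamete_rejected(gamete_si_alleles(gam, slots), stigma) ||
          stats::runif(1) < cfg$self_fertility_leak
        if (ok) { pollen_gam <- gam; break }
      }
      if (is.null(pollen_gam)) {
        stop(sprintf(
          "unsatisfiable configuration: mother of family %d rejected 1000 pollen gametes (zero leak?)",
          fam))
      }
      egg <- meiosis(mother, map)
      individuals[[length(individuals) + 1L]] <- list(
        id = sprintf("HSF%d_%02d", fam, k),
        family = sprintf("HSF-%d", fam),
        h1 = egg, h2 = pollen_gam
      )
    }
  }

  marker_map <- dplyr::bind_rows(lapply(seq_len(cfg$n_lg), function(lg) {
    mp <- map[[lg]]
    tibble::tibble(marker = mp$name[!mp$is_si], lg = as.character(lg),
                   cM = mp$pos[!mp$is_si])
  }))

  truth <- dplyr::bind_rows(lapply(individuals, function(ind) {
    a <- extract_si_alleles(ind, slots)
    tibble::tibble(
      genotype_id = ind$id, family = ind$family,
      locus = names(a),
      linkage_group = vapply(cfg$loci, `[[`, integer(1), "linkage_group")[
        match(names(a), vapply(cfg$loci, `[[`, "", "name"))],
      position_cM = vapply(cfg$loci, `[[`, numeric(1), "position_cM")[
        match(names(a), vapply(cfg$loci, `[[`, "", "name"))],
      allele_1 = vapply(a, `[`, integer(1), 1),
      allele_2 = vapply(a, `[`, integer(1), 2)
    )
  }))

  structure(list(individuals = individuals, founders = founders,
                 map = marker_map, map_internal = map, si_slots = slots,
                 truth = truth, cfg = cfg),
            class = "si_population")
}

#' @export
print.si_population <- function(x, ...) {
  cat(sprintf("<si_population> %d genotypes in %d half-sib families, %d markers on %d LGs\n",
              length(x$individuals), x$cfg$n_families, nrow(x$map), x$cfg$n_lg))
  cat("  SI loci:", paste(vapply(x$cfg$loci, function(l)
    sprintf("%s (LG %d, %.0f cM, %d alleles)", l$name, l$linkage_group,
            l$position_cM, l$n_alleles), character(1)), collapse = "; "), "\n")
  invisible(x)
}

#' Per-genotype SI allele pairs
#'
#' @param pop an `si_population`.
#' @return named list (by genotype id) of named lists of allele pairs.
#' @export
si_genotypes <- function(pop) {
  stopifnot(inherits(pop, "si_population"))
  out <- lapply(pop$individuals, extract_si_alleles, slots = pop$si_slots)
  names(out) <- vapply(pop$individuals, `[[`, "", "id")
  out
}

#' Expected compatibility matrix of a population
#'
#' Latent (noise-free) compatible fractions for every recipient x donor
#' pair, rows = stigma (female), columns = pollen donor (male).
#'
#' @param pop an `si_population`.
#' @return numeric matrix with genotype-id dimnames.
#' @export
compatibility_matrix <- function(pop) {
  sz <- si_genotypes(pop)
  n <- length(sz)
  loci <- names(sz[[1]])
  incompat <- matrix(1, n, n)
  for (l in loci) {
    a1 <- vapply(sz, function(g) g[[l]][1], numeric(1))
    a2 <- vapply(sz, function(g) g[[l]][2], numeric(1))
    # matched[i, j]: how many of donor j's two copies occur in stigma i
    m <- outer(a1, a1, `==`) | outer(a2, a1, `==`)
    m2 <- outer(a1, a2, `==`) | outer(a2, a2, `==`)
    incompat <- incompat * (m + m2) / 2
  }
  lat <- 1 - incompat
  dimnames(lat) <- list(names(sz), names(sz))
  lat
}

#' Simulate one replicate diallel of a population
#'
#' The latent score of a cross is 10 x its compatible fraction; observed
#' scores add replicate (year) noise and ordinal scoring noise, are rounded
#' to the 0--10 rubric and clipped, and cells go missing independently at
#' the configured rate. Selfs (the diagonal) are scored.
#'
#' @param pop an `si_population`.
#' @param replicate replicate tag written into the matrix.
#' @return a [diallel] object.
#' @export
simulate_diallel <- function(pop, replicate = "rep1") {
  cfg <- pop$cfg
  lat <- 10 * compatibility_matrix(pop)
  n <- nrow(lat)
  obs <- lat +
    stats::rnorm(n * n, 0, cfg$replicate_noise_sd) +
    stats::rnorm(n * n, 0, cfg$score_noise_sd)
  obs <- matrix(pmin(10L, pmax(0L, as.integer(round(obs)))), n, n,
                dimnames = dimnames(lat))
  obs[stats::runif(n * n) < cfg$missing_rate] <- NA_integer_
  fam <- stats::setNames(vapply(pop$individuals, `[[`, "", "family"),
                         vapply(pop$individuals, `[[`, "", "id"))
  diallel(obs, family = fam, replicate = replicate)
}

#' Marker dosage table of a simulated population
#'
#' One row per marker: id, linkage group, map position, then one 0/1/2
#' dosage column per genotype (sum of the two haplotype alleles).
#'
#' @param pop an `si_population`.
#' @return a tibble in the genotype interchange format read by
#'   [read_genotypes()].
#' @export
genotype_table <- function(pop) {
  stopifnot(inherits(pop, "si_population"))
  ids <- vapply(pop$individuals, `[[`, "", "id")
  dosage <- do.call(rbind, lapply(seq_along(pop$map_internal), function(lg) {
    keep <- !pop$map_internal[[lg]]$is_si
    d <- vapply(pop$individuals,
                function(ind) ind$h1[[lg]][keep] + ind$h2[[lg]][keep],
                numeric(sum(keep)))
    d
  }))
  colnames(dosage) <- ids
  dplyr::bind_cols(pop$map, tibble::as_tibble(dosage))
}

#' Write genotype dosages and map to tab-delimited text
#'
#' @param pop an `si_population` (or a genotype table from
#'   [genotype_table()] / [read_genotypes()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(pop, path) {
  tbl <- if (inherits(pop, "si_population")) genotype_table(pop) else pop
  readr::write_tsv(tbl, path, na = "NA")
  invisible(path)
}
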