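#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a nested list and returns a fully defaulted,
#' range-checked `run_config`. Exactly one input mode is allowed:
#' `"simulate"` (the forward SI simulator provides diallels and genotypes)
#' or `"files"` (paths to diallel matrices, a metadata table and a genotype
#' table). The seed is mandatory and is recorded in every output header.
#'
#' @param config file path or list. Recognised top-level fields: `mode`,
#'   `seed`, `replicates`, `sim` (fields of [sim_config()]), `files`
#'   (`diallels`, `meta`, `genotypes`), `cc` (`mode`, `n_components`,
#'   `n_clusters`), `si50` (`min_n`), `gwas` (`alpha`, `maf`,
#'   `structure_axes`), `output_dir`.
#' @return a `run_config` list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  bad_field <- function(field, msg) {
    stop(sprintf("config field `%s`: %s", field, msg))
  }
  mode <- config$mode %||% "simulate"
  if (!mode %in% c("simulate", "files")) {
    bad_field("mode", "must be 'simulate' or 'files'")
  }
  if (is.null(config$seed)) bad_field("seed", "is required")
  seed <- suppressWarnings(as.integer(config$seed))
  if (is.na(seed)) bad_field("seed", "must be an integer")

  replicates <- as.integer(config$replicates %||% 2L)
  if (replicates < 1) bad_field("replicates", "must be >= 1")

  sim <- NULL
  if (mode == "simulate") {
    sim_args <- config$sim %||% list()
    if (!is.null(sim_args$loci)) {
      sim_args$loci <- lapply(sim_args$loci, function(l) {
        do.call(si_locus, l)
      })
    }
    sim_args$seed <- seed
    sim <- tryCatch(do.call(sim_config, sim_args),
                    error = function(e) bad_field("sim", conditionMessage(e)))
  } else {
    f <- config$files %||% list()
    if (is.null(f$diallels) || !length(f$diallels)) {
      bad_field("files.diallels", "at least one diallel path is required")
    }
    if (is.null(f$genotypes)) bad_field("files.genotypes", "is required")
    for (p in c(unlist(f$diallels), f$meta, f$genotypes)) {
      if (!file.exists(p)) bad_field("files", paste("missing file:", p))
    }
    replicates <- length(f$diallels)
  }

  cc <- config$cc %||% list()
  cc$mode <- cc$mode %||% "concat"
  cc$n_components <- as.integer(cc$n_components %||% 4L)
  cc$n_clusters <- as.integer(cc$n_clusters %||% 4L)
  if (!cc$mode %in% c("concat", "female", "male")) {
    bad_field("cc.mode", "must be concat, female or male")
  }
  if (cc$n_components < 1) bad_field("cc.n_components", "must be >= 1")

  si50 <- config$si50 %||% list()
  si50$min_n <- as.integer(si50$min_n %||% 10L)

  gwas <- config$gwas %||% list()
  gwas$alpha <- gwas$alpha %||% 0.05
  gwas$maf <- gwas$maf %||% 0.05
  gwas$structure_axes <- as.integer(gwas$structure_axes %||% 2L)
  if (gwas$alpha <= 0 || gwas$alpha >= 1) bad_field("gwas.alpha", "must lie in (0, 1)")
  if (gwas$maf < 0 || gwas$maf > 0.5) bad_field("gwas.maf", "must lie in [0, 0.5]")
  if (gwas$structure_axes < 0) bad_field("gwas.structure_axes", "must be >= 0")

  structure(list(mode = mode, seed = seed, replicates = replicates,
                 sim = sim, files = config$files, cc = cc, si50 = si50,
                 gwas = gwas, output_dir = config$output_dir),
            class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param cfg a `run_config` (or plain list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (inherits(cfg$sim, "sim_config")) {
    sim <- unclass(cfg$sim)
    sim$loci <- lapply(sim$loci, unclass)
    sim$seed <- NULL
    x$sim <- sim
  }
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Run the full compatibility-mapping pipeline
#'
#' Orchestrates every stage under one seed: simulate (or read) the diallel
#' replicates and genotypes; QC (reciprocal flags, between-replicate
#' correlation); grouped SI50 fits; pollination profiles, missing-value
#' Euclidean distance and unscaled PCA per replicate; component matching
#' across replicates and Ward clustering; MAF filtering, structure
#' covariates and a single-marker scan per matched component per replicate;
#' and, in simulation mode, a truth-based localization summary for the SI
#' loci. Intermediate tables are written to `output_dir` when configured.
#'
#' @param config a `run_config`, list, or YAML path (see
#'   [validate_run_config()]).
#' @return an `si_run` list with elements `config`, `population` (simulate
#'   mode), `diallels`, `qc`, `si50`, `components`, `match`, `clusters`,
#'   `genotypes`, `scans`, `significant`, `localization`, `log`.
#' @export
run_si_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_run_config(config)
  log <- character()
  note <- function(...) {
    msg <- sprintf(...)
    log[[length(log) + 1L]] <<- msg
    invisible(msg)
  }

  # --- inputs ---------------------------------------------------------------
  pop <- NULL
  if (cfg$mode == "simulate") {
    pop <- simulate_population(cfg$sim)
    diallels <- lapply(seq_len(cfg$replicates),
                       function(r) simulate_diallel(pop, sprintf("rep%d", r)))
    geno <- genotype_table(pop)
    note("simulated %d genotypes, %d markers, %d replicate diallel(s)",
         length(pop$individuals), nrow(geno), cfg$replicates)
  } else {
    meta <- if (!is.null(cfg$files$meta)) {
      utils::read.delim(cfg$files$meta, colClasses = "character")
    } else NULL
    diallels <- lapply(seq_along(cfg$files$diallels), function(r) {
      read_diallel(cfg$files$diallels[[r]], family = meta,
                   replicate = sprintf("rep%d", r))
    })
    geno <- read_genotypes(cfg$files$genotypes)
    note("read %d diallel replicate(s) and %d markers", length(diallels),
         nrow(geno))
  }

  # --- QC -------------------------------------------------------------------
  flags <- lapply(diallels, reciprocal_flags)
  qc <- list(reciprocal_flags = flags)
  for (r in seq_along(flags)) {
    note("replicate %d: %d reciprocal-difference flags (|diff| > 3)", r,
         nrow(flags[[r]]))
  }
  if (length(diallels) >= 2) {
    qc$replicate_correlation <- replicate_correlation(diallels[[1]],
                                                      diallels[[2]])
    note("between-replicate correlation R = %.2f over %d shared cells",
         qc$replicate_correlation$estimate, qc$replicate_correlation$n_shared)
  }

  # --- SI50 tables ----------------------------------------------------------
  si50_tables <- lapply(diallels, group_si50, min_n = cfg$si50$min_n)
  si50_tbl <- dplyr::bind_rows(
    lapply(seq_along(si50_tables), function(r) {
      dplyr::mutate(si50_tables[[r]], replicate = sprintf("rep%d", r),
                    .before = 1)
    })
  )
  note("SI50 fits: %d groups, %d skipped", nrow(si50_tbl),
       sum(si50_tbl$skipped))

  # --- Compatibility Components --------------------------------------------
  comps <- lapply(diallels, derive_components, mode = cfg$cc$mode)
  match <- NULL
  if (length(comps) >= 2) {
    match <- match_components(comps[[1]], comps[[2]],
                              n_components = cfg$cc$n_components)
    phen <- list(match$scores_rep1, match$scores_rep2)
    note("matched components: %s",
         paste(sprintf("%s=%s/%s (r=%.2f)", match$match$cc,
                       match$match$component_rep1, match$match$component_rep2,
                       match$match$correlation), collapse = ", "))
  } else {
    s <- comps[[1]]$scores[, seq_len(cfg$cc$n_components), drop = FALSE]
    phen <- list(s)
  }
  clusters <- cluster_genotypes(comps[[1]], n_clusters = cfg$cc$n_clusters,
                                n_components = cfg$cc$n_components)

  # --- GWAS -----------------------------------------------------------------
  geno_f <- maf_filter(geno, threshold = cfg$gwas$maf)
  note("MAF filter: %d of %d markers retained (threshold %.2f)",
       sum(!geno_f$filtered), nrow(geno_f), cfg$gwas$maf)
  covars <- if (cfg$gwas$structure_axes > 0) {
    structure_covariates(geno_f[!geno_f$filtered, ],
                         n_axes = cfg$gwas$structure_axes)
  } else NULL
  scans <- list()
  for (r in seq_along(phen)) {
    rep_tag <- sprintf("rep%d", r)
    scans[[rep_tag]] <- lapply(
      stats::setNames(colnames(phen[[r]]), colnames(phen[[r]])),
      function(cc) {
        marker_scan(phen[[r]][, cc], geno_f, covariates = covars,
                    alpha = cfg$gwas$alpha)
      })
  }
  significant <- dplyr::bind_rows(lapply(names(scans), function(r) {
    dplyr::bind_rows(lapply(names(scans[[r]]), function(cc) {
      mt <- manhattan_table(scans[[r]][[cc]])
      hits <- mt[mt$above_threshold, ]
      if (nrow(hits)) dplyr::mutate(hits, replicate = r, component = cc,
                                    .before = 1)
    }))
  }))
  note("significant marker associations: %d", nrow(significant))

  # --- localization against simulated truth ---------------------------------
  localization <- NULL
  if (!is.null(pop)) {
    localization <- localize_si_loci(pop, phen, scans)
    note("localization: %s",
         paste(sprintf("%s %s: top marker %.1f cM away (%s)",
                       localization$replicate, localization$locus,
                       localization$distance_cM,
                       ifelse(localization$hit, "hit", "miss")),
               collapse = "; "))
  }

  run <- structure(list(config = cfg, population = pop, diallels = diallels,
                        qc = qc, si50 = si50_tbl, components = comps,
                        match = match, clusters = clusters,
                        genotypes = geno_f, scans = scans,
                        significant = significant,
                        localization = localization, log = log),
                   class = "si_run")
  if (!is.null(cfg$output_dir)) write_run_outputs(run, cfg$output_dir)
  run
}

#' Locate SI loci from component scans and simulated truth
#'
#' For each simulated SI locus, finds the component whose scores are best
#' explained by the locus's allele composition (R-squared of a regression
#' on per-allele presence indicators), then reports where that component's
#' association scan peaks and whether the peak lies within `window_cM` of
#' the true position on the true linkage group.
#'
#' @param pop the simulated `si_population` (carries the truth).
#' @param phenotypes list (per replicate) of component score matrices.
#' @param scans nested list of `si_scan` objects, `scans[[replicate]][[cc]]`.
#' @param window_cM hit window around the true position.
#' @return tibble: `replicate`, `locus`, `component`, `allele_r2`,
#'   `top_marker`, `top_lg`, `top_cM`, `top_log10p`, `distance_cM`, `hit`.
#' @export
localize_si_loci <- function(pop, phenotypes, scans, window_cM = 10) {
  stopifnot(inherits(pop, "si_population"))
  truth <- pop$truth
  out <- list()
  for (r in seq_along(phenotypes)) {
    scores <- phenotypes[[r]]
    ids <- rownames(scores)
    for (locus in unique(truth$locus)) {
      tl <- truth[truth$locus == locus, ]
      tl <- tl[match(ids, tl$genotype_id), ]
      alleles <- sort(unique(c(tl$allele_1, tl$allele_2)))
      Z <- vapply(alleles, function(a) {
        (tl$allele_1 == a) + (tl$allele_2 == a)
      }, numeric(nrow(tl)))
      r2 <- apply(scores, 2, function(y) {
        summary(stats::lm(y ~ Z))$r.squared
      })
      best <- names(which.max(r2))
      sc <- scans[[r]][[best]]
      tested <- sc[sc$tested, ]
      top <- tested[which.max(tested$log10p), ]
      dist_cM <- if (identical(as.character(top$lg),
                               as.character(tl$linkage_group[1])) &&
                     !is.na(top$cM)) {
        abs(top$cM - tl$position_cM[1])
      } else {
        Inf
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        replicate = sprintf("rep%d", r), locus = locus, component = best,
        allele_r2 = unname(r2[best]), top_marker = top$marker,
        top_lg = top$lg, top_cM = top$cM, top_log10p = top$log10p,
        distance_cM = dist_cM, hit = dist_cM <= window_cM
      )
    }
  }
  dplyr::bind_rows(out)
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_core <- unclass(run$config)
  cfg_core$output_dir <- NULL  # hash the analysis settings, not the paths
  header <- sprintf("# sicompat %s | seed %d | config %s",
                    as.character(utils::packageVersion("sicompat")),
                    run$config$seed, rlang::hash(cfg_core))
  emit <- function(df, name) {
    path <- file.path(dir, name)
    writeLines(header, path)
    suppressWarnings(readr::write_tsv(df, path, append = TRUE,
                                      col_names = TRUE))
  }
  for (r in seq_along(run$diallels)) {
    write_diallel(run$diallels[[r]], file.path(dir, sprintf("diallel_rep%d.tsv", r)))
    emit(run$qc$reciprocal_flags[[r]], sprintf("reciprocal_flags_rep%d.tsv", r))
  }
  emit(run$si50, "si50_groups.tsv")
  for (r in seq_along(run$components)) {
    emit(glance(run$components[[r]]), sprintf("cc_variance_rep%d.tsv", r))
    emit(tidy(run$components[[r]]), sprintf("cc_scores_rep%d.tsv", r))
  }
  if (!is.null(run$match)) emit(run$match$match, "cc_match.tsv")
  emit(run$clusters, "clusters.tsv")
  for (r in names(run$scans)) {
    for (cc in names(run$scans[[r]])) {
      emit(manhattan_table(run$scans[[r]][[cc]]),
           sprintf("scan_%s_%s.tsv", r, cc))
    }
  }
  if (nrow(run$significant %||% tibble::tibble())) {
    emit(run$significant, "significant_markers.tsv")
  }
  if (!is.null(run$localization)) emit(run$localization, "localization.tsv")
  writeLines(c(header, run$log), file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.si_run <- function(x, ...) {
  cat("<si_run>\n")
  for (line in x$log) cat(" -", line, "\n")
  invisible(x)
}
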