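# Config-driven pipeline surface tying the stages together:
# simulate / harmonize / graft / fit / paths. Each runner takes a run
# config (JSON file or list), derives its module seed from the top-level
# seed, and stamps every output with the seed and a config hash so reruns
# are auditable.

#' Read and validate a run configuration
#'
#' @param path JSON config file.
#' @return Named list with attribute `hash` (md5 of the file content).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  attr(cfg, "hash") <- unname(tools::md5sum(path))
  cfg
}

config_hash <- function(config) {
  h <- attr(config, "hash")
  if (!is.null(h)) return(h)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

# per-module deterministic substream offsets from one top-level seed
module_seed <- function(config, module) {
  base <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  offs <- c(simulate = 0L, harmonize = 101L, graft = 211L, fit = 307L,
            paths = 401L)
  (base + offs[[module]]) %% .Machine$integer.max
}

stamp_lines <- function(config) {
  c(paste0("# seed: ", if (!is.null(config$seed)) config$seed else NA),
    paste0("# config_hash: ", config_hash(config)))
}

write_stamped_table <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp_lines(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a delimited trait table
#'
#' Tab-delimited UTF-8 text with a header row; lines starting with `#`
#' are treated as comments.
#'
#' @param path Input file.
#' @return Data frame.
#' @export
read_trait_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Simulate a tree and trait table from a run config
#'
#' Config block `simulate` holds [simulation_config()] fields. Writes
#' `tree.nwk`, `traits.tsv` and `truth.json` into `outdir`.
#'
#' @param config Run config (list or path).
#' @param outdir Output directory (created if needed).
#' @return Invisible list with the simulated `tree` and `traits`.
#' @export
pipeline_simulate <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  args <- as.list(config$simulate)
  args$seed <- module_seed(config, "simulate")
  if (!is.null(args$beta)) args$beta <- unlist(args$beta)
  if (!is.null(args$care_effect)) args$care_effect <- unlist(args$care_effect)
  if (!is.null(args$class_temps)) {
    args$class_temps <- lapply(args$class_temps, unlist)
  }
  sc <- do.call(simulation_config, args)
  tree <- simulate_tree(sc)
  traits <- simulate_traits(tree, sc)
  writeLines(write_newick(tree), file.path(outdir, "tree.nwk"))
  write_stamped_table(traits, file.path(outdir, "traits.tsv"), config)
  truth <- attr(traits, "truth")
  truth$config_hash <- config_hash(config)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(tree = tree, traits = traits))
}

#' Harmonize a raw trait table
#'
#' Applies per-class newborn-size conversions (config block
#' `conversions`: class -> `{kind, a, b, density}` acting on the
#' `newborn_size` column) and, when `qc_filter` is true, the allometric
#' brain-data filter. Writes the harmonized table and a QC report, and
#' logs per-class exclusion counts.
#'
#' @param config Run config (list or path) with `trait_table` path.
#' @param outdir Output directory.
#' @return Invisible list with `table` and `qc` report.
#' @export
pipeline_harmonize <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_trait_table(config$trait_table)
  if (nrow(tab) == 0) {
    warning("empty input table; writing empty outputs")
  }
  if (!is.null(config$conversions) && nrow(tab) > 0) {
    tab$newborn_mass_g <- NA_real_
    for (klass in names(config$conversions)) {
      cv <- config$conversions[[klass]]
      idx <- tab$class_name == klass
      if (!any(idx)) next
      raw <- tab$newborn_size[idx]
      tab$newborn_mass_g[idx] <- switch(
        cv$kind,
        length_weight = length_to_mass(
          raw, conversion_spec("length_weight", a = cv$a, b = cv$b)),
        egg_sphere = egg_diameter_to_mass(
          raw, if (!is.null(cv$density)) cv$density else 1),
        egg_to_hatchling = egg_to_hatchling_mass(
          raw, conversion_spec("egg_to_hatchling", a = cv$a, b = cv$b)),
        identity = raw,
        stop("unknown conversion kind '", cv$kind, "' for class ", klass))
    }
    unknown <- setdiff(unique(tab$class_name), names(config$conversions))
    if (length(unknown)) {
      stop("classes without a conversion entry: ",
           paste(unknown, collapse = ", "))
    }
  }
  qc <- NULL
  if (isTRUE(config$qc_filter) && nrow(tab) > 0) {
    spc <- tab
    if (!"genus" %in% names(spc)) {
      spc$genus <- sub("_.*$", "", spc$species)
    }
    res <- qc_filter_brain(spc)
    qc <- res$report
    n_before <- nrow(tab)
    tab <- tab[tab$species %in% res$kept$species, , drop = FALSE]
    message("qc_filter_brain: removed ", n_before - nrow(tab), " of ",
            n_before, " species")
  }
  write_stamped_table(tab, file.path(outdir, "harmonized.tsv"), config)
  if (!is.null(qc)) {
    write_stamped_table(qc, file.path(outdir, "qc_report.tsv"), config)
  }
  for (klass in unique(tab$class_name)) {
    message("class ", klass, ": ", sum(tab$class_name == klass),
            " species retained")
  }
  invisible(list(table = tab, qc = qc))
}

#' Graft class trees into a supertree
#'
#' Config fields: `subtrees` (named map clade id -> Newick file) and
#' optionally `schedule` (JSON path; defaults to the packaged vertebrate
#' schedule). Writes `supertree.nwk`.
#'
#' @param config Run config (list or path).
#' @param outdir Output directory.
#' @return Invisible supertree `phylo`.
#' @export
pipeline_graft <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  subtrees <- lapply(config$subtrees, function(p) {
    parse_newick(paste(readLines(p), collapse = ""))
  })
  schedule <- if (!is.null(config$schedule)) {
    read_graft_schedule(config$schedule)
  } else {
    default_graft_schedule()
  }
  if (length(subtrees) == 1L) {
    st <- subtrees[[1]]
  } else {
    st <- graft_supertree(subtrees, schedule)
  }
  writeLines(c(stamp_lines(config), write_newick(st)),
             file.path(outdir, "supertree.nwk"))
  invisible(st)
}

#' Fit a phylogenetic mixed model from a run config
#'
#' Config fields: `trait_table`, `tree`, `model` (response, fixed terms,
#' log10/zscore/interaction settings), optional `priors` and `chain`
#' blocks. Writes a per-parameter summary table and a JSON result.
#'
#' @param config Run config (list or path).
#' @param outdir Output directory.
#' @return Invisible `pglmm_fit`.
#' @export
pipeline_fit <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_trait_table(config$trait_table)
  tree <- parse_newick(paste(readLines(config$tree), collapse = ""))
  m <- config$model
  cv <- shared_path_covariance(tree, taxa_order = tab$species)
  frame <- prepare_model_frame(
    tab, variables = unlist(m$variables),
    log10_vars = if (!is.null(m$log10)) unlist(m$log10) else character(0),
    zscore = if (!is.null(m$zscore)) unlist(m$zscore) else TRUE,
    interactions = if (!is.null(m$interactions)) unlist(m$interactions)
    else character(0),
    taxa_order = cv$taxa)
  message("model frame: ", nrow(frame), " species (",
          attr(frame, "n_dropped"), " dropped for missing data)")
  pr <- if (!is.null(config$priors)) do.call(prior_spec, as.list(config$priors))
  else prior_spec()
  ch_args <- if (!is.null(config$chain)) as.list(config$chain) else list()
  ch_args$seed <- module_seed(config, "fit")
  ch <- do.call(chain_spec, ch_args)
  fit <- fit_pglmm(stats::as.formula(m$formula), frame, cv,
                   priors = pr, chain = ch)
  write_stamped_table(cbind(parameter = rownames(fit$summary),
                            fit$summary),
                      file.path(outdir, "pglmm_summary.tsv"), config)
  jsonlite::write_json(
    list(seed = ch$seed, config_hash = config_hash(config),
         n = fit$n, stored_draws = ch$stored,
         posterior_mean = as.list(setNames(fit$summary$posterior_mean,
                                           rownames(fit$summary))),
         lambda = fit$lambda_signal[c("mean", "ci_lower", "ci_upper")]),
    file.path(outdir, "pglmm_result.json"), auto_unbox = TRUE, digits = NA)
  if (isTRUE(config$write_draws)) {
    write_stamped_table(as.data.frame(fit$samples),
                        file.path(outdir, "pglmm_draws.tsv"), config)
  }
  invisible(fit)
}

#' Run a phylogenetic path analysis from a run config
#'
#' Config fields: `trait_table`, `tree`, `paths` block with `variables`
#' (six trait columns), optional `residualize_on` (regress listed
#' variables on body mass first), optional `candidates` JSON path.
#' Writes the ranked model table and averaged coefficients.
#'
#' @param config Run config (list or path).
#' @param outdir Output directory.
#' @return Invisible `averaged_paths`.
#' @export
pipeline_paths <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_trait_table(config$trait_table)
  tree <- parse_newick(paste(readLines(config$tree), collapse = ""))
  pb <- config$paths
  cv <- shared_path_covariance(tree, taxa_order = tab$species)
  vars <- unlist(pb$variables)
  frame <- prepare_model_frame(
    tab, variables = unique(c(vars, "body_mass_g")),
    log10_vars = intersect(c("body_mass_g", "brain_mass_g",
                             "newborn_mass_g", "bmr"), names(tab)),
    zscore = TRUE, taxa_order = cv$taxa)
  if (!is.null(pb$residualize_on)) {
    for (v in unlist(pb$residualize)) {
      frame[[v]] <- residualize(frame[[v]], frame[[pb$residualize_on]])
    }
  }
  if (!is.null(pb$rename)) {
    for (nm in names(pb$rename)) names(frame)[names(frame) ==
                                                pb$rename[[nm]]] <- nm
  }
  dags <- build_candidate_set(pb$candidates)
  fits <- lapply(dags, fit_path_model, frame = frame, cov = cv)
  avg <- rank_and_average(fits)
  write_stamped_table(avg$table, file.path(outdir, "path_ranking.tsv"),
                      config)
  jsonlite::write_json(
    list(seed = module_seed(config, "paths"),
         config_hash = config_hash(config),
         coefficients = avg$coefficients),
    file.path(outdir, "path_coefficients.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(avg)
}
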