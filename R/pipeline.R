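#' Configuration of a full pipeline run
#'
#' Collects everything one end-to-end run needs: either paths to real
#' inputs (newick tree, per-cruise count TSVs, metadata TSV) or a
#' [synthetic_config()] — exactly one of the two — plus the analysis
#' parameters of every stage.
#'
#' @param tree_path,counts_paths,metadata_path paths to real inputs
#'   (`counts_paths`: named character vector, names = cruise ids).
#' @param synthetic a [synthetic_config()] (alternative to the paths).
#' @param biomass_mode synthetic biomass mode, see
#'   [simulate_site_biomass()].
#' @param depth rarefaction depth: `"min"` (observed minimum site total)
#'   or an explicit integer.
#' @param n_rand,pool,pair_set betaMPTI parameters, see [beta_mpti()].
#' @param alpha significance level for backward selection and slope flags.
#' @param protect protected terms of the hypothesis-I backward selection.
#' @param env_terms cruise/pair-level environmental covariates entering
#'   the selections (log-transformed pair means).
#' @param signal_variables variables for the phylogenetic Mantel
#'   correlogram.
#' @param seed master seed.
#' @param outdir output directory.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(tree_path = NULL, counts_paths = NULL,
                       metadata_path = NULL, synthetic = NULL,
                       biomass_mode = "site", depth = "min",
                       n_rand = 999L, pool = "pair", pair_set = "between",
                       alpha = 0.05, protect = "log_bray_curtis",
                       env_terms = c("log_temperature", "log_salinity",
                                     "log_nitrogen", "log_phosphate",
                                     "log_par", "log_chla"),
                       signal_variables = c("temperature", "salinity",
                                            "nitrogen", "phosphate",
                                            "par", "chla"),
                       seed = 1L, outdir = tempfile("betabef_run")) {
  have_paths <- !is.null(tree_path) || !is.null(counts_paths) ||
    !is.null(metadata_path)
  if (have_paths && !is.null(synthetic))
    stop("supply either real-data paths or a synthetic config, not both")
  if (!have_paths && is.null(synthetic))
    stop("supply real-data paths or a synthetic config")
  if (have_paths &&
      (is.null(tree_path) || is.null(counts_paths) || is.null(metadata_path)))
    stop("real-data runs need tree_path, counts_paths and metadata_path")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  structure(list(tree_path = tree_path, counts_paths = counts_paths,
                 metadata_path = metadata_path, synthetic = synthetic,
                 biomass_mode = biomass_mode, depth = depth,
                 n_rand = as.integer(n_rand), pool = pool,
                 pair_set = pair_set, alpha = alpha, protect = protect,
                 env_terms = env_terms,
                 signal_variables = signal_variables,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  path
}

.model_tsv <- function(model, path) {
  df <- model$coefficients
  df$model_type <- model$model_type
  df$marginal_r2 <- model$marginal_r2
  df$n <- model$n
  .write_tsv(df, path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load, depth standardization, pair-table
#' construction, betaMPTI, the hypothesis-I mixed model with backward
#' selection, per-cruise slopes, the hypothesis-II cross-cruise
#' regression, the beta-diversity-vs-assembly model, and the phylogenetic
#' Mantel correlogram. All randomness derives from `config$seed`:
#' identical config implies byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with every intermediate and fitted object
#'   (`pairs`, `assembly`, `effects`, `h1_model`, `h2_model`,
#'   `beta_assembly_model`, `correlogram`, `manifest`). Side effect:
#'   writes `pairs.tsv`, `cruise_assembly.tsv`, `cruise_effects.tsv`,
#'   `h1_model.tsv`, `h2_model.tsv`, `beta_assembly_model.tsv`,
#'   `correlogram.tsv`, `selection_trace.txt` and `manifest.json` under
#'   `config$outdir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_msgs <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_msgs <<- c(log_msgs, msg)
  }
  collect_warn <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      log_msgs <<- c(log_msgs, paste("warning:", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  }
  checksums <- NULL
  pairs_exact <- NULL
  if (!is.null(config$synthetic)) {
    note("stage simulate: %d cruises x %d sites, regime %s",
         config$synthetic$n_cruises, config$synthetic$n_sites,
         config$synthetic$regime)
    dataset <- simulate_bef_dataset(config$synthetic,
                                    mode = config$biomass_mode)
    tree <- dataset$tree
    tables <- dataset$tables
    metadata <- dataset$metadata
    pairs_exact <- dataset$pairs_exact
  } else {
    note("stage load: %d count tables", length(config$counts_paths))
    tree <- read_phylogeny(config$tree_path)
    cruises <- names(config$counts_paths) %||%
      sprintf("C%02d", seq_along(config$counts_paths))
    tables <- Map(read_counts, config$counts_paths, cruises)
    metadata <- read_metadata(config$metadata_path)
    checksums <- as.list(tools::md5sum(c(config$tree_path,
                                         config$counts_paths,
                                         config$metadata_path)))
  }
  check_dataset(tables, metadata, tree)

  depth <- if (identical(config$depth, "min"))
    min(vapply(tables, function(t) min(rowSums(t)), numeric(1)))
  else as.integer(config$depth)
  note("stage rarefy: depth %d", as.integer(depth))
  tables <- lapply(tables, function(tab)
    subsample_counts(tab, depth,
                     seed = derive_seed(config$seed, "rarefy",
                                        cruise_id(tab))))

  note("stage betadiv: building pair table")
  pairs <- build_pair_table(tables, metadata)
  if (!is.null(pairs_exact)) {
    key <- function(d) paste(d$cruise_id, d$site_a, d$site_b)
    m <- match(key(pairs), key(pairs_exact))
    pairs$summed_biomass <- pairs_exact$summed_biomass[m]
    pairs$bray_curtis <- pairs_exact$bray_curtis[m]
  }

  note("stage assembly: betaMPTI with %d shuffles, pool '%s'",
       config$n_rand, config$pool)
  assembly <- collect_warn(
    pairwise_assembly(pairs, tables, tree, n_rand = config$n_rand,
                      pool = config$pool, pair_set = config$pair_set,
                      seed = derive_seed(config$seed, "assembly")))
  pairs <- assembly$pairs

  note("stage bef: hypothesis-I mixed model and per-cruise slopes")
  pairs_t <- collect_warn(prepare_pairs(pairs))
  terms1 <- intersect(union(config$protect, config$env_terms),
                      names(pairs_t))
  h1 <- collect_warn(backward_select(pairs_t, terms = terms1,
                                     protect = config$protect,
                                     alpha = config$alpha))
  effects <- collect_warn(fit_cruise_slopes(pairs_t, alpha = config$alpha))
  ba <- collect_warn(beta_vs_assembly(pairs_t))

  note("stage bef: hypothesis-II cross-cruise regression")
  cruise_cov <- do.call(rbind, lapply(split(pairs_t, pairs_t$cruise_id),
    function(d) {
      cov <- lapply(intersect(config$env_terms, names(d)),
                    function(v) mean(d[[v]], na.rm = TRUE))
      names(cov) <- intersect(config$env_terms, names(d))
      data.frame(cruise_id = d$cruise_id[1], cov)
    }))
  h2 <- collect_warn(cross_cruise_regression(effects,
                                             covariates = cruise_cov,
                                             alpha = config$alpha))

  note("stage signal: phylogenetic Mantel correlogram")
  nd <- collect_warn(niche_distances(tables, metadata,
                                     variables = config$signal_variables))
  pd <- cophenetic_distances(tree)[rownames(nd), rownames(nd)]
  correlogram <- mantel_correlogram(nd, pd, n_perm = config$n_rand,
                                    seed = derive_seed(config$seed,
                                                       "signal"),
                                    alpha = config$alpha)

  .write_tsv(pairs, file.path(config$outdir, "pairs.tsv"))
  .write_tsv(assembly$cruise, file.path(config$outdir,
                                        "cruise_assembly.tsv"))
  .write_tsv(as.data.frame(effects),
             file.path(config$outdir, "cruise_effects.tsv"))
  .model_tsv(h1, file.path(config$outdir, "h1_model.tsv"))
  .model_tsv(h2, file.path(config$outdir, "h2_model.tsv"))
  .model_tsv(ba, file.path(config$outdir, "beta_assembly_model.tsv"))
  .write_tsv(as.data.frame(correlogram),
             file.path(config$outdir, "correlogram.tsv"))
  writeLines(c("hypothesis I removals:",
               utils::capture.output(print(h1$selection_trace,
                                           row.names = FALSE)),
               "hypothesis II removals:",
               utils::capture.output(print(h2$selection_trace,
                                           row.names = FALSE))),
             file.path(config$outdir, "selection_trace.txt"))

  cfg_echo <- config
  cfg_echo$synthetic <- if (!is.null(config$synthetic))
    unclass(config$synthetic)
  manifest <- list(config = unclass(cfg_echo), seed = config$seed,
                   depth = as.integer(depth),
                   package_version = as.character(
                     utils::packageVersion("betabef")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   input_checksums = checksums, log = log_msgs)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(pairs = pairs, assembly = assembly, effects = effects,
                 h1_model = h1, h2_model = h2, beta_assembly_model = ba,
                 correlogram = correlogram, manifest = manifest,
                 outdir = config$outdir))
}

#' Read a run configuration from YAML
#'
#' Thin wrapper so pipeline runs can be described in a config file; keys
#' mirror the arguments of [run_config()] and [synthetic_config()] (the
#' latter under a `synthetic:` block).
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's value.
#' @param outdir optional output directory overriding the file's value.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL, outdir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic))
    y$synthetic <- do.call(synthetic_config, y$synthetic)
  if (!is.null(y$counts_paths)) y$counts_paths <- unlist(y$counts_paths)
  if (!is.null(seed)) y$seed <- seed
  if (!is.null(outdir)) y$outdir <- outdir
  do.call(run_config, y)
}
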