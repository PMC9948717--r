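#' Configuration for the synthetic multi-cruise generator
#'
#' Bundles and validates all knobs of the synthetic-data generator, which
#' emulates a repeated marine transect design: `n_cruises` cruises each
#' sampling the same `n_sites` sites, with an ASV count table per cruise,
#' a shared regional phylogeny, environmental covariates, and site
#' biomasses carrying a planted per-cruise beta-diversity effect.
#'
#' The assembly `regime` controls how taxa are sampled into sites:
#' `"neutral"` draws sites from cruise-level relative abundances unrelated
#' to the phylogeny; `"homogenizing"` weights taxa by a Gaussian kernel
#' around one shared trait optimum per cruise (all sites select the same
#' clade); `"diversifying"` gives each site its own optimum, spread across
#' the trait range (sites select different clades).
#'
#' @param n_cruises number of cruises (default 14).
#' @param n_sites sites per cruise (default 6).
#' @param n_taxa number of taxa on the regional phylogeny (default 100).
#' @param depth reads per site (default 13129, the minimum-depth floor the
#'   rarefaction step standardizes to); must be >= 1000.
#' @param regime `"neutral"`, `"homogenizing"` or `"diversifying"`.
#' @param selection_strength non-negative Gaussian selection strength;
#'   scalar or one value per cruise; ignored under `"neutral"`.
#' @param trait_sigma Brownian-motion rate of the selected trait.
#' @param biomass_intercept per-cruise intercepts of the planted
#'   log-biomass model (scalar recycled; default `log(40)`, i.e. summed
#'   pair biomass around 40 ug C/L).
#' @param biomass_slope per-cruise planted beta-diversity effects b_c
#'   (scalar recycled; default 0.17).
#' @param noise_sd lognormal noise sd of the biomass model (default 0.25).
#' @param seed integer master seed; every cruise and stage derives its own
#'   sub-stream from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cruises = 14L, n_sites = 6L, n_taxa = 100L,
                             depth = 13129L,
                             regime = c("neutral", "homogenizing",
                                        "diversifying"),
                             selection_strength = 5, trait_sigma = 1,
                             biomass_intercept = log(40),
                             biomass_slope = 0.17,
                             noise_sd = 0.25, seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(n_cruises >= 1, n_sites >= 2, n_taxa >= 3, depth >= 1000,
            all(selection_strength >= 0), trait_sigma > 0, noise_sd >= 0)
  if (length(biomass_intercept) == 1L)
    biomass_intercept <- rep(biomass_intercept, n_cruises)
  if (length(biomass_slope) == 1L)
    biomass_slope <- rep(biomass_slope, n_cruises)
  if (length(selection_strength) == 1L)
    selection_strength <- rep(selection_strength, n_cruises)
  if (length(biomass_intercept) != n_cruises ||
      length(biomass_slope) != n_cruises ||
      length(selection_strength) != n_cruises)
    stop("per-cruise parameter vectors must have length n_cruises")
  structure(list(n_cruises = as.integer(n_cruises),
                 n_sites = as.integer(n_sites),
                 n_taxa = as.integer(n_taxa), depth = as.integer(depth),
                 regime = regime, selection_strength = selection_strength,
                 trait_sigma = trait_sigma,
                 biomass_intercept = biomass_intercept,
                 biomass_slope = biomass_slope,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate a pure-birth phylogeny
#'
#' Yule (constant birth rate 1, no extinction) tree with `n_taxa` uniquely
#' labeled tips and strictly positive branch lengths; stands in for the
#' 16S ML tree of a regional species pool.
#'
#' @param n_taxa number of tips, >= 3.
#' @param seed integer seed (identical seed, identical tree).
#' @return A `phylo` object.
#' @export
simulate_phylogeny <- function(n_taxa, seed = 1L) {
  if (!is.numeric(n_taxa) || n_taxa < 3)
    stop("n_taxa must be >= 3")
  tree <- with_seed(seed, ape::rphylo(as.integer(n_taxa), birth = 1, death = 0))
  tree$tip.label <- sprintf("t%04d", seq_len(as.integer(n_taxa)))
  validate_phylogeny(tree)
}

# per-cruise site trait optima for the selection regimes
.site_optima <- function(trait, regime, n_sites) {
  if (regime == "homogenizing") {
    rep(trait[sample.int(length(trait), 1L)], n_sites)
  } else { # diversifying: spread optima across the trait range
    as.numeric(stats::quantile(trait, probs = seq(0.05, 0.95,
                                                  length.out = n_sites)))
  }
}

#' Simulate per-cruise community count tables
#'
#' Evolves a niche trait on the phylogeny by Brownian motion, assigns each
#' site an environmental optimum according to the assembly regime, weights
#' taxa by `exp(-s * (trait - optimum)^2)` (selection regimes) or by
#' cruise-level broken-stick relative abundances perturbed per site
#' (neutral), and draws `depth` reads per site from a multinomial.
#'
#' @param tree regional phylogeny with at least `cfg$n_taxa` tips; the
#'   first `n_taxa` tips are used.
#' @param cfg a [synthetic_config()].
#' @return Named list of `community_table`s, one per cruise
#'   (`"C01"`, `"C02"`, ...), every row summing to `cfg$depth`.
#' @export
simulate_communities <- function(tree, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (length(tree$tip.label) < cfg$n_taxa)
    stop("phylogeny has fewer tips than cfg$n_taxa")
  if (length(tree$tip.label) > cfg$n_taxa)
    tree <- ape::keep.tip(tree, tree$tip.label[seq_len(cfg$n_taxa)])
  trait <- with_seed(derive_seed(cfg$seed, "trait"),
                     ape::rTraitCont(tree, model = "BM",
                                     sigma = cfg$trait_sigma))
  cruises <- sprintf("C%02d", seq_len(cfg$n_cruises))
  sites <- sprintf("S%d", seq_len(cfg$n_sites))
  out <- lapply(seq_len(cfg$n_cruises), function(cix) {
    with_seed(derive_seed(cfg$seed, "cruise", cix), {
      counts <- matrix(0L, cfg$n_sites, cfg$n_taxa,
                       dimnames = list(sites, tree$tip.label))
      if (cfg$regime == "neutral") {
        # lognormal species-abundance distribution: the high-variance tail
        # gives every site the rare-taxon turnover real ASV tables show
        base <- stats::rlnorm(cfg$n_taxa, 0, 2)
        for (s in seq_len(cfg$n_sites)) {
          w <- base * stats::rlnorm(cfg$n_taxa, 0, 0.5)
          counts[s, ] <- stats::rmultinom(1, cfg$depth, w / sum(w))
        }
      } else {
        opt <- .site_optima(trait, cfg$regime, cfg$n_sites)
        s_c <- cfg$selection_strength[cix]
        for (s in seq_len(cfg$n_sites)) {
          w <- exp(-s_c * (trait - opt[s])^2) *
            stats::rlnorm(cfg$n_taxa, 0, 0.25)
          counts[s, ] <- stats::rmultinom(1, cfg$depth, w / sum(w))
        }
      }
      community_table(counts, cruise_id = cruises[cix])
    })
  })
  stats::setNames(out, cruises)
}

# environmental covariates on oceanographically plausible shelf-sea
# gradients; one row per cruise-site
.simulate_environment <- function(cruises, sites, seed) {
  do.call(rbind, lapply(seq_along(cruises), function(cix) {
    with_seed(derive_seed(seed, "env", cix), {
      n <- length(sites)
      data.frame(
        cruise = cruises[cix], site = sites,
        temperature = stats::runif(1, 18, 28) + stats::rnorm(n, 0, 1),
        salinity = 33.5 + stats::rnorm(n, 0, 0.5),
        nitrogen = stats::rlnorm(n, log(2), 0.8),
        phosphate = stats::rlnorm(n, log(0.2), 0.6),
        par = stats::rlnorm(n, log(400), 0.5),
        chla = stats::rlnorm(n, log(0.3), 0.7),
        hnf_biomass_ugC_L = cells_to_biomass(
          stats::rlnorm(n, log(1e6), 0.5), "hnf"))
    })
  }))
}

#' Simulate site biomass and environmental metadata
#'
#' Attaches biomass to the simulated communities under a planted
#' beta-diversity effect. Two modes:
#' \describe{
#'   \item{`"site"`}{site-level generator: site biomass
#'     `= exp(intercept_c / 2) * mBC^slope_c * lognormal(0, noise_sd)`,
#'     where `mBC` is the site's mean Bray-Curtis dissimilarity to the
#'     cruise's other sites. Pair-level sums then associate with pair
#'     Bray-Curtis with the sign of `slope_c`, but not as an exact linear
#'     model.}
#'   \item{`"pair-exact"`}{emits pair-level observations directly with
#'     `log(summed_biomass) = intercept_c + slope_c * log(BC) +
#'     N(0, noise_sd)`, for exact recovery of the planted slope by the
#'     regression stage. Site-level biomasses in the metadata are set to
#'     the constant `exp(intercept_c / 2)` placeholder (pair sums come
#'     from the returned `pairs` table, not from the metadata).}
#' }
#'
#' @param tables list of `community_table`s from [simulate_communities()].
#' @param cfg the same [synthetic_config()].
#' @param mode `"site"` or `"pair-exact"`.
#' @return List with `metadata` (a [read_metadata()]-shaped `data.frame`)
#'   and `pairs` (`NULL` in `"site"` mode; in `"pair-exact"` mode a
#'   `data.frame` `cruise_id`, `site_a`, `site_b`, `bray_curtis`,
#'   `summed_biomass`).
#' @export
simulate_site_biomass <- function(tables, cfg,
                                  mode = c("site", "pair-exact")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "synthetic_config"))
  if (length(tables) != cfg$n_cruises)
    stop("tables and cfg$n_cruises disagree")
  cruises <- unname(vapply(tables, cruise_id, character(1)))
  sites <- rownames(tables[[1]])
  env <- .simulate_environment(cruises, sites, cfg$seed)
  biomass <- numeric(0)
  pair_rows <- list()
  for (cix in seq_along(tables)) {
    tab <- tables[[cix]]
    bc <- as.matrix(vegan::vegdist(unclass(tab), method = "bray"))
    b0 <- cfg$biomass_intercept[cix]
    b1 <- cfg$biomass_slope[cix]
    if (mode == "site") {
      mbc <- rowSums(bc) / (nrow(bc) - 1)
      noise <- with_seed(derive_seed(cfg$seed, "biomass", cix),
                         stats::rlnorm(nrow(bc), 0, cfg$noise_sd))
      biomass <- c(biomass, exp(b0 / 2) * mbc^b1 * noise)
    } else {
      biomass <- c(biomass, rep(exp(b0 / 2), nrow(bc)))
      idx <- utils::combn(nrow(bc), 2)
      eps <- with_seed(derive_seed(cfg$seed, "biomass", cix),
                       stats::rnorm(ncol(idx), 0, cfg$noise_sd))
      pair_rows[[cix]] <- data.frame(
        cruise_id = cruises[cix],
        site_a = sites[idx[1, ]], site_b = sites[idx[2, ]],
        bray_curtis = bc[t(idx)],
        summed_biomass = exp(b0 + b1 * log(bc[t(idx)]) + eps))
    }
  }
  metadata <- data.frame(cruise = env$cruise, site = env$site,
                         biomass_ugC_L = biomass,
                         hnf_biomass_ugC_L = env$hnf_biomass_ugC_L,
                         temperature = env$temperature,
                         salinity = env$salinity, nitrogen = env$nitrogen,
                         phosphate = env$phosphate, par = env$par,
                         chla = env$chla)
  list(metadata = metadata,
       pairs = if (mode == "pair-exact") {
         p <- do.call(rbind, pair_rows); rownames(p) <- NULL; p
       })
}

#' Simulate a complete multi-cruise dataset
#'
#' Convenience wrapper: phylogeny, per-cruise count tables, metadata with
#' planted biomass, and (in `"pair-exact"` mode) exact pair-level
#' observations, all from one master seed.
#'
#' @param cfg a [synthetic_config()].
#' @param mode biomass mode, see [simulate_site_biomass()].
#' @return List with `tree`, `tables`, `metadata`, `pairs_exact`
#'   (`NULL` unless `mode = "pair-exact"`), `config`.
#' @export
simulate_bef_dataset <- function(cfg, mode = c("site", "pair-exact")) {
  mode <- match.arg(mode)
  tree <- simulate_phylogeny(cfg$n_taxa, seed = derive_seed(cfg$seed, "tree"))
  tables <- simulate_communities(tree, cfg)
  bio <- simulate_site_biomass(tables, cfg, mode = mode)
  list(tree = tree, tables = tables, metadata = bio$metadata,
       pairs_exact = bio$pairs, config = cfg)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `tree.nwk`, one `counts_cruise<k>.tsv` per cruise,
#' `metadata.tsv`, and `truth.tsv` (regime and planted per-cruise
#' intercepts/slopes).
#'
#' @param dataset result of [simulate_bef_dataset()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_synthetic <- function(dataset, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_phylogeny(dataset$tree, file.path(outdir, "tree.nwk"))
  for (k in seq_along(dataset$tables))
    write_counts(dataset$tables[[k]],
                 file.path(outdir, sprintf("counts_cruise%02d.tsv", k)))
  write_metadata(dataset$metadata, file.path(outdir, "metadata.tsv"))
  cfg <- dataset$config
  truth <- data.frame(cruise_id = vapply(dataset$tables, cruise_id,
                                         character(1)),
                      regime = cfg$regime,
                      selection_strength = cfg$selection_strength,
                      biomass_intercept = cfg$biomass_intercept,
                      biomass_slope = cfg$biomass_slope)
  utils::write.table(truth, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
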