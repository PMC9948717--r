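#' Subsample a count table to a common sequencing depth
#'
#' Standardizes all sites of a cruise to the same number of reads by a
#' single without-replacement draw (multivariate hypergeometric) per site,
#' the usual "rarefy once to the minimum depth" step applied before
#' computing compositional dissimilarities.
#'
#' @param table a [community_table()].
#' @param depth target reads per site; must not exceed any site's total.
#' @param seed integer seed for the draw (one draw, reproducible).
#' @return A `community_table` in which every row sums to `depth` and no
#'   cell exceeds its input value.
#' @export
subsample_counts <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "community_table"),
            is.numeric(depth), length(depth) == 1L, depth >= 1)
  totals <- rowSums(table)
  low <- which(totals < depth)
  if (length(low) > 0)
    stop(sprintf("depth %d exceeds the %d reads of site '%s' (cruise %s)",
                 as.integer(depth), as.integer(totals[low[1]]),
                 rownames(table)[low[1]], cruise_id(table)))
  # vegan warns when the smallest nonzero count exceeds 1 (a heuristic for
  # spotting relative abundances); counts are validated integers here
  out <- with_seed(seed, withCallingHandlers(
    vegan::rrarefy(unclass(table), sample = depth),
    warning = function(w) {
      if (grepl("smallest count", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  community_table(out, cruise_id = cruise_id(table))
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' \eqn{BC(x, y) = 1 - 2 \sum_i \min(x_i, y_i) / (\sum_i x_i + \sum_i y_i)},
#' the abundance-based beta-diversity index computed on depth-standardized
#' counts; 0 for identical compositions, 1 for disjoint taxon sets.
#'
#' @param x,y non-negative count vectors of equal length.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  if (sum(x) == 0 && sum(y) == 0)
    stop("Bray-Curtis undefined: both communities are empty")
  as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
}

#' Pooled alpha diversity of two communities
#'
#' Richness and Shannon entropy (nats) of the combined composition of a
#' site pair, used as covariates when checking that beta-diversity effects
#' are not driven by the pooled alpha diversity of the pair.
#'
#' @param x,y non-negative count vectors of equal length.
#' @return Named list with `richness` (taxa present in the pooled counts)
#'   and `shannon` (entropy of pooled relative abundances, nats).
#' @export
pooled_alpha <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  z <- x + y
  if (sum(z) == 0) stop("alpha diversity undefined: both communities empty")
  list(richness = sum(z > 0),
       shannon = as.numeric(vegan::diversity(z, index = "shannon")))
}

# carbon per cell, g C/cell
.carbon_factors <- c(bacteria = 2e-14, hnf = 4.7e-12)

#' Convert cell densities to carbon biomass
#'
#' Applies the standard carbon conversion factors: 2e-14 g C/cell for
#' heterotrophic bacteria and 4.7e-12 g C/cell for heterotrophic
#' nanoflagellates (HNF).
#'
#' @param density cell density, cells/L; non-negative.
#' @param organism `"bacteria"` or `"hnf"`.
#' @return Biomass in ug C/L.
#' @export
cells_to_biomass <- function(density, organism = c("bacteria", "hnf")) {
  organism <- match.arg(organism)
  if (any(density < 0)) stop("cell density must be non-negative")
  density * .carbon_factors[[organism]] * 1e6
}

.env_vars <- c("temperature", "salinity", "nitrogen", "phosphate", "par",
               "chla")

#' Build the site-pair observation table
#'
#' For every unordered pair of sites within each cruise (15 pairs for a
#' 6-site cruise) computes the Bray-Curtis dissimilarity, the summed
#' bacterial biomass of the two sites, the pooled alpha diversity of the
#' combined composition, and the pairwise means of the environmental
#' covariates (and of HNF biomass). The `beta_mpti` column is `NA` until
#' filled by [pairwise_assembly()].
#'
#' @param tables list of `community_table`s (one per cruise), typically
#'   depth-standardized with [subsample_counts()].
#' @param metadata metadata `data.frame` (see [read_metadata()]).
#' @return A `data.frame`, one row per site pair, with columns `cruise_id`,
#'   `site_a`, `site_b`, `bray_curtis`, `summed_biomass`, `beta_mpti`,
#'   `pooled_richness`, `pooled_shannon`, `hnf_biomass`, and the six
#'   environmental means. A covariate mean is `NA` if either site is `NA`.
#' @export
build_pair_table <- function(tables, metadata) {
  check_dataset(tables, metadata)
  rows <- lapply(tables, function(tab) {
    cr <- cruise_id(tab)
    sites <- rownames(tab)
    meta <- metadata[metadata$cruise == cr, , drop = FALSE]
    meta <- meta[match(sites, meta$site), , drop = FALSE]
    pairs <- utils::combn(seq_along(sites), 2)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      alpha <- pooled_alpha(tab[i, ], tab[j, ])
      env <- lapply(c(.env_vars, hnf_biomass = "hnf_biomass_ugC_L"),
                    function(v) (meta[[v]][i] + meta[[v]][j]) / 2)
      names(env) <- c(.env_vars, "hnf_biomass")
      data.frame(cruise_id = cr, site_a = sites[i], site_b = sites[j],
                 bray_curtis = bray_curtis(tab[i, ], tab[j, ]),
                 summed_biomass = meta$biomass_ugC_L[i] + meta$biomass_ugC_L[j],
                 beta_mpti = NA_real_,
                 pooled_richness = alpha$richness,
                 pooled_shannon = alpha$shannon,
                 env)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
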