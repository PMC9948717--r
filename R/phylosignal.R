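#' Abundance-weighted niche value per taxon
#'
#' A taxon's habitat preference along one environmental variable: the
#' mean of the variable over all cruise-sites, weighted by the taxon's
#' relative abundance there. Taxa never observed are excluded with a
#' warning.
#'
#' @param tables list of `community_table`s.
#' @param metadata metadata `data.frame` (see [read_metadata()]).
#' @param variable metadata column name, e.g. `"temperature"`.
#' @return Named numeric vector of niche values, one per observed taxon.
#' @export
niche_values <- function(tables, metadata, variable) {
  if (!variable %in% names(metadata))
    stop("variable '", variable, "' absent from metadata")
  check_dataset(tables, metadata)
  taxa <- unique(unlist(lapply(tables, colnames)))
  wsum <- stats::setNames(numeric(length(taxa)), taxa)
  wval <- wsum
  for (tab in tables) {
    meta <- metadata[metadata$cruise == cruise_id(tab), , drop = FALSE]
    env <- meta[[variable]][match(rownames(tab), meta$site)]
    rel <- unclass(tab) / rowSums(tab)
    ok <- is.finite(env)
    if (!any(ok)) next
    wsum[colnames(tab)] <- wsum[colnames(tab)] + colSums(rel[ok, , drop = FALSE])
    wval[colnames(tab)] <- wval[colnames(tab)] +
      colSums(rel[ok, , drop = FALSE] * env[ok])
  }
  absent <- wsum == 0
  if (any(absent)) {
    warning(sum(absent), " never-observed taxa excluded from niche values")
    wsum <- wsum[!absent]; wval <- wval[!absent]
  }
  wval / wsum
}

#' Euclidean niche distances over standardized variables
#'
#' Builds the between-taxon habitat-difference matrix used by the Mantel
#' correlogram: niche values for each selected variable, z-standardized
#' across taxa, then Euclidean distance.
#'
#' @param tables list of `community_table`s.
#' @param metadata metadata `data.frame`.
#' @param variables metadata columns (default: the six environmental
#'   covariates).
#' @return Symmetric taxon x taxon distance matrix.
#' @export
niche_distances <- function(tables, metadata,
                            variables = c("temperature", "salinity",
                                          "nitrogen", "phosphate", "par",
                                          "chla")) {
  vals <- sapply(variables, function(v)
    suppressWarnings(niche_values(tables, metadata, v)))
  keep <- apply(vals, 2, function(x) stats::sd(x) > 0)
  z <- scale(vals[, keep, drop = FALSE])
  as.matrix(stats::dist(z))
}

#' Phylogenetic Mantel correlogram
#'
#' Tests for phylogenetic signal in habitat preferences: partitions the
#' between-taxon phylogenetic distances into classes and, per class,
#' correlates the niche distances with a within-class membership
#' indicator. Negative Mantel r in the shortest classes means closely
#' related taxa have more similar niches than average (phylogenetic
#' signal). P-values come from permuting taxon identities and are
#' Holm-corrected across classes.
#'
#' @param niche_dist taxon x taxon niche distance matrix.
#' @param phylo_dist taxon x taxon phylogenetic (cophenetic) distance
#'   matrix, same taxa in the same order (or named and reorderable).
#' @param n_classes number of distance classes (default: Sturges' rule on
#'   the number of taxon pairs).
#' @param n_perm number of label permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @param alpha significance level applied to Holm-adjusted p-values.
#' @return A `data.frame` of class `mantel_correlogram`: `class_index`,
#'   `lower`, `upper`, `n_pairs`, `mantel_r`, `p_value`, `p_adjusted`,
#'   `significant`. Classes with fewer than 3 pairs get `NA` statistics.
#' @export
mantel_correlogram <- function(niche_dist, phylo_dist, n_classes = NULL,
                               n_perm = 999L, seed = NULL, alpha = 0.05) {
  niche_dist <- as.matrix(niche_dist)
  phylo_dist <- as.matrix(phylo_dist)
  if (!is.null(rownames(niche_dist)) && !is.null(rownames(phylo_dist))) {
    if (!setequal(rownames(niche_dist), rownames(phylo_dist)))
      stop("matrices cover different taxa")
    phylo_dist <- phylo_dist[rownames(niche_dist), rownames(niche_dist)]
  }
  n <- nrow(niche_dist)
  if (n != nrow(phylo_dist) || n < 4L)
    stop("need two matching distance matrices over >= 4 taxa")
  if (max(abs(niche_dist - t(niche_dist))) > 1e-8 ||
      max(abs(phylo_dist - t(phylo_dist))) > 1e-8)
    stop("distance matrices must be symmetric")
  low <- lower.tri(niche_dist)
  dphy <- phylo_dist[low]
  dnic <- niche_dist[low]
  if (is.null(n_classes)) n_classes <- grDevices::nclass.Sturges(dphy)
  breaks <- seq(min(dphy), max(dphy), length.out = n_classes + 1L)
  breaks[length(breaks)] <- breaks[length(breaks)] + 1e-9 # right-open last class
  cls <- findInterval(dphy, breaks, rightmost.closed = FALSE,
                      all.inside = FALSE)
  cls[cls > n_classes] <- n_classes

  class_r <- function(nd) { # nd: niche distances in lower-tri order
    vapply(seq_len(n_classes), function(k) {
      ind <- as.numeric(cls == k)
      if (sum(ind) < 3 || stats::sd(ind) == 0 || stats::sd(nd) == 0)
        return(NA_real_)
      stats::cor(nd, ind)
    }, numeric(1))
  }
  r_obs <- class_r(dnic)
  perm_ge <- integer(n_classes)
  perm_n <- integer(n_classes)
  with_seed(seed, for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    nd <- niche_dist[p, p][low]
    r_b <- class_r(nd)
    ok <- !is.na(r_b) & !is.na(r_obs)
    perm_ge[ok] <- perm_ge[ok] + (abs(r_b[ok]) >= abs(r_obs[ok]))
    perm_n[ok] <- perm_n[ok] + 1L
  })
  p_val <- ifelse(is.na(r_obs), NA_real_, (perm_ge + 1) / (perm_n + 1))
  p_adj <- stats::p.adjust(p_val, method = "holm")
  out <- data.frame(class_index = seq_len(n_classes),
                    lower = breaks[-length(breaks)],
                    upper = breaks[-1],
                    n_pairs = tabulate(cls, n_classes),
                    mantel_r = r_obs, p_value = p_val, p_adjusted = p_adj,
                    significant = !is.na(p_adj) & p_adj <= alpha)
  structure(out, class = c("mantel_correlogram", "data.frame"),
            n_perm = as.integer(n_perm))
}

#' @export
print.mantel_correlogram <- function(x, ...) {
  cat(sprintf("Phylogenetic Mantel correlogram: %d distance classes, %d permutations\n",
              nrow(x), attr(x, "n_perm")))
  print.data.frame(x, digits = 3, row.names = FALSE, ...)
  invisible(x)
}

#' @export
plot.mantel_correlogram <- function(x, ...) {
  mid <- (x$lower + x$upper) / 2
  plot(mid, x$mantel_r, type = "b",
       pch = ifelse(x$significant, 19, 21),
       xlab = "Phylogenetic distance class midpoint",
       ylab = "Mantel r", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
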