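#' Cophenetic (patristic) distance matrix of a phylogeny
#'
#' Pairwise tip-to-tip distances: the sum of branch lengths along the path
#' connecting two tips. All between-community MPD computations are driven
#' off this matrix.
#'
#' @param tree a `phylo` with branch lengths.
#' @return Symmetric taxon x taxon matrix with zero diagonal.
#' @export
cophenetic_distances <- function(tree) {
  validate_phylogeny(tree)
  ape::cophenetic.phylo(tree)
}

# mean pairwise distance from integer index sets into D
.mpd_idx <- function(D, ia, ib, pair_set) {
  if (pair_set == "between") {
    mean(D[ia, ib, drop = FALSE])
  } else {
    u <- union(ia, ib)
    n <- length(u)
    if (n < 2L) stop("union pair set needs >= 2 distinct taxa")
    sum(D[u, u]) / (n * (n - 1))
  }
}

#' Between-community mean pairwise phylogenetic distance
#'
#' The observed MPD of a site pair: with `pair_set = "between"` (default),
#' the mean of \eqn{d(i, j)} over all ordered cross-community pairs
#' \eqn{i \in A, j \in B} — taxa shared by both communities contribute
#' zero-distance self pairs, as in the standard betaMPD construction. With
#' `pair_set = "union"`, the mean over all unordered pairs of distinct taxa
#' in \eqn{A \cup B}.
#'
#' @param dist cophenetic distance matrix (see [cophenetic_distances()]).
#' @param taxa_a,taxa_b character vectors of taxon names; non-empty, all
#'   present in `dist`.
#' @param pair_set `"between"` or `"union"`.
#' @return MPD in branch-length units.
#' @export
mpd_between <- function(dist, taxa_a, taxa_b,
                        pair_set = c("between", "union")) {
  pair_set <- match.arg(pair_set)
  if (length(taxa_a) == 0 || length(taxa_b) == 0)
    stop("taxon sets must be non-empty")
  ia <- match(taxa_a, rownames(dist))
  ib <- match(taxa_b, rownames(dist))
  if (anyNA(ia) || anyNA(ib))
    stop("taxa absent from the distance matrix: ",
         paste(utils::head(c(taxa_a[is.na(ia)], taxa_b[is.na(ib)]), 5),
               collapse = ", "))
  .mpd_idx(dist, ia, ib, pair_set)
}

#' betaMPTI: tip-shuffle null-model z-score of between-community MPD
#'
#' Quantifies the deviation of the observed between-community mean pairwise
#' phylogenetic distance from a null distribution obtained by shuffling tip
#' labels. `beta_mpti = (MPD_obs - mean(MPD_null)) / sd(MPD_null)`.
#' Negative values mean the taxa of the two communities are more closely
#' related than expected at random (homogenizing selection); positive
#' values mean less related (diversifying selection).
#'
#' The null pool — the set of tips whose labels are shuffled — is
#' configurable. `"pair"` shuffles within the union of the two communities'
#' taxa and asks whether cross-community taxa are unusually related *given*
#' the pool; `"all"` shuffles the full tree (the regional species pool) and
#' additionally detects that the pool itself is clustered; `"cruise"`
#' shuffles within a supplied intermediate pool.
#'
#' @param tree a `phylo`, or a precomputed cophenetic distance matrix.
#' @param taxa_a,taxa_b character vectors of taxon names (presence-based
#'   community membership).
#' @param n_rand number of tip shuffles (default 999).
#' @param pool `"pair"`, `"cruise"` or `"all"`.
#' @param pool_taxa taxon names of the pool when `pool = "cruise"`.
#' @param pair_set passed to [mpd_between()].
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return An object of class `beta_mpti`: list with `mpd_obs`, `null`
#'   (list `mpd_values`, `mean`, `sd`), `beta_mpti` (`NA` with a
#'   `degenerate_null` warning when the null has zero spread), `n_rand`,
#'   `pool`, `pair_set`.
#' @export
beta_mpti <- function(tree, taxa_a, taxa_b, n_rand = 999L,
                      pool = c("pair", "cruise", "all"), pool_taxa = NULL,
                      pair_set = c("between", "union"), seed = NULL) {
  pool <- match.arg(pool)
  pair_set <- match.arg(pair_set)
  D <- if (is.matrix(tree)) tree else cophenetic_distances(tree)
  taxa_a <- unique(taxa_a); taxa_b <- unique(taxa_b)
  if (length(union(taxa_a, taxa_b)) < 2L)
    stop("need >= 2 distinct taxa across the two communities")
  pool_ids <- switch(pool,
    pair = union(taxa_a, taxa_b),
    cruise = {
      if (is.null(pool_taxa)) stop("pool = 'cruise' requires pool_taxa")
      unique(pool_taxa)
    },
    all = rownames(D))
  if (!all(c(taxa_a, taxa_b) %in% pool_ids))
    stop("community taxa must be contained in the null pool")
  sub <- D[pool_ids, pool_ids, drop = FALSE]
  ia <- match(taxa_a, pool_ids)
  ib <- match(taxa_b, pool_ids)
  obs <- .mpd_idx(sub, ia, ib, pair_set)
  np <- length(pool_ids)
  null_vals <- with_seed(seed, vapply(seq_len(n_rand), function(r) {
    p <- sample.int(np)
    .mpd_idx(sub, p[ia], p[ib], pair_set)
  }, numeric(1)))
  mu <- mean(null_vals)
  sdev <- stats::sd(null_vals)
  z <- if (isTRUE(sdev > 0)) (obs - mu) / sdev else NA_real_
  if (is.na(z))
    warning(structure(class = c("degenerate_null", "warning", "condition"),
                      list(message = "null distribution has zero spread; betaMPTI is NA",
                           call = sys.call())))
  structure(list(mpd_obs = obs,
                 null = list(mpd_values = null_vals, mean = mu, sd = sdev),
                 beta_mpti = z, n_rand = as.integer(n_rand),
                 pool = pool, pair_set = pair_set),
            class = "beta_mpti")
}

#' @export
print.beta_mpti <- function(x, ...) {
  cat(sprintf(
    "betaMPTI = %s  (MPD_obs = %.4f, null mean = %.4f, null sd = %.4f, %d shuffles, pool = %s)\n",
    ifelse(is.na(x$beta_mpti), "NA (degenerate null)",
           sprintf("%.3f", x$beta_mpti)),
    x$mpd_obs, x$null$mean, x$null$sd, x$n_rand, x$pool))
  invisible(x)
}

#' Fill betaMPTI for every site pair of every cruise
#'
#' Computes one tip-shuffle betaMPTI z-score per site pair, using
#' presence/absence taxon sets from the (rarefied) count tables, and the
#' per-cruise mean betaMPTI that the cross-cruise regression uses. Each
#' pair draws from its own RNG stream derived from
#' `(seed, cruise, site_a, site_b)`, so results do not depend on execution
#' order.
#'
#' @param pairs pair table from [build_pair_table()].
#' @param tables list of `community_table`s, same cruises as `pairs`.
#' @param tree a `phylo` containing all observed taxa as tips.
#' @param n_rand,pool,pair_set see [beta_mpti()].
#' @param seed integer base seed.
#' @return List of class `pairwise_assembly`: `pairs` (the input with
#'   `beta_mpti` filled; degenerate nulls left `NA` with a warning) and
#'   `cruise` (`data.frame` of `cruise_id`, `mean_beta_mpti`, `n_pairs`,
#'   `n_missing`).
#' @export
pairwise_assembly <- function(pairs, tables, tree, n_rand = 999L,
                              pool = c("pair", "cruise", "all"),
                              pair_set = c("between", "union"), seed = 1L) {
  pool <- match.arg(pool)
  pair_set <- match.arg(pair_set)
  D <- cophenetic_distances(tree)
  tabs <- stats::setNames(tables, vapply(tables, cruise_id, character(1)))
  n_missing <- 0L
  for (r in seq_len(nrow(pairs))) {
    cr <- pairs$cruise_id[r]
    tab <- tabs[[cr]]
    if (is.null(tab)) stop("no count table for cruise ", cr)
    ta <- colnames(tab)[tab[pairs$site_a[r], ] > 0]
    tb <- colnames(tab)[tab[pairs$site_b[r], ] > 0]
    pool_taxa <- if (pool == "cruise") colnames(tab)[colSums(tab) > 0] else NULL
    if (length(union(ta, tb)) < 2L) { # e.g. both sites collapsed to one taxon
      n_missing <- n_missing + 1L
      warning(sprintf("pair %s/%s-%s has < 2 distinct taxa; betaMPTI set NA",
                      cr, pairs$site_a[r], pairs$site_b[r]))
      pairs$beta_mpti[r] <- NA_real_
      next
    }
    res <- withCallingHandlers(
      beta_mpti(D, ta, tb, n_rand = n_rand, pool = pool,
                pool_taxa = pool_taxa, pair_set = pair_set,
                seed = derive_seed(seed, cr, pairs$site_a[r], pairs$site_b[r])),
      degenerate_null = function(w) invokeRestart("muffleWarning"))
    if (is.na(res$beta_mpti)) {
      n_missing <- n_missing + 1L
      warning(sprintf("degenerate null for pair %s/%s-%s; betaMPTI set NA",
                      cr, pairs$site_a[r], pairs$site_b[r]))
    }
    pairs$beta_mpti[r] <- res$beta_mpti
  }
  cruise <- do.call(rbind, lapply(split(pairs, pairs$cruise_id), function(d) {
    data.frame(cruise_id = d$cruise_id[1],
               mean_beta_mpti = mean(d$beta_mpti, na.rm = TRUE),
               n_pairs = nrow(d),
               n_missing = sum(is.na(d$beta_mpti)))
  }))
  rownames(cruise) <- NULL
  structure(list(pairs = pairs, cruise = cruise),
            class = "pairwise_assembly")
}

#' @export
print.pairwise_assembly <- function(x, ...) {
  cat(sprintf("betaMPTI for %d site pairs in %d cruises (%d degenerate)\n",
              nrow(x$pairs), nrow(x$cruise), sum(x$cruise$n_missing)))
  print(x$cruise, ...)
  invisible(x)
}
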