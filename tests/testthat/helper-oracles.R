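# Independent oracles and small fixtures used across the suite.

# naive double-loop mean pairwise distance; deliberately unoptimized
naive_mpd <- function(D, taxa_a, taxa_b, pair_set = "between") {
  if (pair_set == "between") {
    acc <- 0
    for (i in taxa_a) for (j in taxa_b) acc <- acc + D[i, j]
    acc / (length(taxa_a) * length(taxa_b))
  } else {
    u <- union(taxa_a, taxa_b)
    acc <- 0; n <- 0
    for (i in seq_along(u)) for (j in seq_along(u)) if (i != j) {
      acc <- acc + D[u[i], u[j]]; n <- n + 1
    }
    acc / n
  }
}

# all permutations of 1..n (n <= 7)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# exhaustive tip-shuffle null over a small pool
exhaustive_null <- function(D, taxa_a, taxa_b, pool_ids,
                            pair_set = "between") {
  sub <- D[pool_ids, pool_ids, drop = FALSE]
  ia <- match(taxa_a, pool_ids)
  ib <- match(taxa_b, pool_ids)
  perms <- all_perms(length(pool_ids))
  apply(perms, 1, function(p)
    naive_mpd(sub, p[ia], p[ib], pair_set = pair_set))
}

tree_abc <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# 6-tip tree with two tight cherries on long stems: a clearly clustered pool
tree_clustered <- function() ape::read.tree(
  text = "(((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1):2,(E:0.1,F:0.1):2);")

# a tiny 2-cruise dataset with hand-set counts and metadata
toy_dataset <- function() {
  mk <- function(cruise, counts) {
    m <- matrix(counts, nrow = 3, byrow = TRUE,
                dimnames = list(c("S1", "S2", "S3"),
                                c("t1", "t2", "t3", "t4")))
    community_table(m, cruise)
  }
  tables <- list(mk("C01", c(5L, 3L, 2L, 0L,
                             0L, 4L, 4L, 2L,
                             1L, 1L, 4L, 4L)),
                 mk("C02", c(2L, 2L, 3L, 3L,
                             6L, 2L, 1L, 1L,
                             0L, 0L, 5L, 5L)))
  metadata <- data.frame(
    cruise = rep(c("C01", "C02"), each = 3),
    site = rep(c("S1", "S2", "S3"), 2),
    biomass_ugC_L = c(20, 25, 30, 18, 22, 27),
    hnf_biomass_ugC_L = c(4, 5, 6, 3, 4, 5),
    temperature = c(20, 22, 24, 19, 21, 23),
    salinity = c(33, 34, 35, 33.5, 34.5, 34),
    nitrogen = c(1, 2, 3, 1.5, 2.5, 2),
    phosphate = c(0.1, 0.2, 0.3, 0.15, 0.25, 0.2),
    par = c(300, 400, 500, 350, 450, 420),
    chla = c(0.2, 0.3, 0.4, 0.25, 0.35, 0.3))
  list(tables = tables, metadata = metadata)
}

# pair table following an exact log-log law, for regression fixtures
exact_pairs <- function(intercept, slope, cruise = "C01",
                        bc = seq(0.2, 0.9, length.out = 15)) {
  data.frame(cruise_id = cruise,
             site_a = sprintf("A%02d", seq_along(bc)),
             site_b = sprintf("B%02d", seq_along(bc)),
             bray_curtis = bc,
             summed_biomass = exp(intercept + slope * log(bc)),
             beta_mpti = NA_real_)
}
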