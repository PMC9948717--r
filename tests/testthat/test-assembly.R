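test_that("cophenetic distances are path sums with zero diagonal", {
  D <- cophenetic_distances(tree_abc())
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 4)
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_equal(D, t(D))
})

test_that("between-community MPD matches hand-computed values", {
  D <- cophenetic_distances(tree_abc())
  expect_equal(mpd_between(D, c("A", "B"), "C"), 4)
  expect_equal(mpd_between(D, "A", "A"), 0) # single shared taxon
  expect_equal(mpd_between(D, c("A", "B"), c("A", "C")), 2.5) # (0+4+2+4)/4
  expect_equal(mpd_between(D, c("A", "B"), c("A", "C"), pair_set = "union"),
               (2 + 4 + 4) * 2 / 6)
  expect_error(mpd_between(D, character(0), "C"), "non-empty")
  expect_error(mpd_between(D, "Z", "C"), "absent")
})

test_that("optimized MPD equals the naive double-loop oracle", {
  withr::with_seed(21, for (k in 1:20) {
    tree <- simulate_phylogeny(sample(5:20, 1), seed = k)
    D <- cophenetic_distances(tree)
    tips <- tree$tip.label
    a <- sample(tips, sample(seq_along(tips), 1))
    b <- sample(tips, sample(seq_along(tips), 1))
    for (ps in c("between", "union")) {
      if (ps == "union" && length(union(a, b)) < 2) next
      expect_lt(abs(mpd_between(D, a, b, pair_set = ps) -
                      naive_mpd(D, a, b, pair_set = ps)), 1e-9)
    }
  })
})

test_that("between-set MPD agrees with picante's comdist", {
  tree <- simulate_phylogeny(15, seed = 3)
  D <- cophenetic_distances(tree)
  withr::with_seed(8, {
    a <- sample(tree$tip.label, 6)
    b <- sample(tree$tip.label, 5)
  })
  comm <- matrix(0, 2, 15, dimnames = list(c("A", "B"), tree$tip.label))
  comm["A", a] <- 1; comm["B", b] <- 1
  ref <- as.numeric(picante::comdist(comm, D, abundance.weighted = FALSE))
  expect_equal(mpd_between(D, a, b), ref, tolerance = 1e-9)
})

test_that("clustered communities give negative betaMPTI; sampled null matches exhaustive enumeration", {
  tree <- tree_clustered()
  D <- cophenetic_distances(tree)
  a <- c("A", "B"); b <- c("C", "D") # one tight clade vs regional pool of 6
  res <- beta_mpti(tree, a, b, n_rand = 999, pool = "all", seed = 42)
  expect_lt(res$beta_mpti, 0)

  exh <- exhaustive_null(D, a, b, pool_ids = tree$tip.label)
  z_exh <- (mpd_between(D, a, b) - mean(exh)) / sd(exh)
  expect_lt(z_exh, 0)
  # 999-draw null agrees with the exhaustive permutation distribution
  expect_lt(abs(res$null$mean - mean(exh)), 3 * sd(exh) / sqrt(999))
  expect_lt(abs(res$null$sd - sd(exh)), 3 * sd(exh) / sqrt(2 * 999))
})

test_that("betaMPTI is invariant to branch-length scale and taxon relabeling", {
  tree <- simulate_phylogeny(20, seed = 9)
  a <- tree$tip.label[1:6]; b <- tree$tip.label[5:11]
  z0 <- beta_mpti(tree, a, b, n_rand = 199, seed = 7)$beta_mpti

  scaled <- tree
  scaled$edge.length <- tree$edge.length * 137.5
  z1 <- beta_mpti(scaled, a, b, n_rand = 199, seed = 7)$beta_mpti
  expect_equal(z0, z1, tolerance = 1e-12)

  relab <- tree
  relab$tip.label <- paste0("x_", tree$tip.label)
  z2 <- beta_mpti(relab, paste0("x_", a), paste0("x_", b),
                  n_rand = 199, seed = 7)$beta_mpti
  expect_equal(z0, z2, tolerance = 1e-12)
})

test_that("degenerate nulls warn and report NA", {
  tree <- tree_abc()
  expect_warning(res <- beta_mpti(tree, c("A", "B", "C"), c("A", "B", "C"),
                                  n_rand = 99, pool = "pair", seed = 1),
                 "zero spread")
  expect_true(is.na(res$beta_mpti))
  expect_error(beta_mpti(tree, "A", "A"), ">= 2 distinct taxa")
})

test_that("pairwise assembly fills one betaMPTI per pair, presence-based and order-independent", {
  cfg <- synthetic_config(n_cruises = 2, n_sites = 6, n_taxa = 25,
                          depth = 1200, regime = "neutral", seed = 14)
  d <- simulate_bef_dataset(cfg)
  pairs <- build_pair_table(d$tables, d$metadata)
  asm <- pairwise_assembly(pairs, d$tables, d$tree, n_rand = 99, seed = 5)
  expect_equal(as.integer(table(asm$pairs$cruise_id)), c(15L, 15L))
  expect_equal(asm$cruise$n_pairs, c(15L, 15L))
  expect_equal(asm$cruise$mean_beta_mpti,
               tapply(asm$pairs$beta_mpti, asm$pairs$cruise_id, mean,
                      na.rm = TRUE),
               ignore_attr = TRUE)

  # abundance enters only through presence/absence
  x10 <- lapply(d$tables, function(t) community_table(unclass(t) * 10L,
                                                      cruise_id(t)))
  asm10 <- pairwise_assembly(pairs, x10, d$tree, n_rand = 99, seed = 5)
  expect_equal(asm$pairs$beta_mpti, asm10$pairs$beta_mpti)

  # per-pair RNG substreams: a reshuffled pair order yields identical values
  perm <- withr::with_seed(3, sample(nrow(pairs)))
  asm_perm <- pairwise_assembly(pairs[perm, ], d$tables, d$tree,
                                n_rand = 99, seed = 5)
  m1 <- asm$pairs[order(asm$pairs$cruise_id, asm$pairs$site_a,
                        asm$pairs$site_b), "beta_mpti"]
  m2 <- asm_perm$pairs[order(asm_perm$pairs$cruise_id, asm_perm$pairs$site_a,
                             asm_perm$pairs$site_b), "beta_mpti"]
  expect_equal(m1, m2)
})
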