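test_that("Yule tree generator is sized, labeled and seed-deterministic", {
  tree <- simulate_phylogeny(50, seed = 1)
  expect_length(tree$tip.label, 50)
  expect_false(anyDuplicated(tree$tip.label) > 0)
  expect_true(all(tree$edge.length > 0))
  t2 <- simulate_phylogeny(50, seed = 1)
  expect_identical(ape::write.tree(tree), ape::write.tree(t2))
  expect_false(identical(ape::write.tree(tree),
                         ape::write.tree(simulate_phylogeny(50, seed = 2))))
  expect_error(simulate_phylogeny(2, seed = 1), "n_taxa")
})

test_that("community simulation draws exactly `depth` reads per site", {
  for (rg in c("neutral", "homogenizing", "diversifying")) {
    cfg <- synthetic_config(n_cruises = 3, n_sites = 4, n_taxa = 30,
                            depth = 1000, regime = rg, seed = 8)
    tabs <- simulate_communities(simulate_phylogeny(30, seed = 1), cfg)
    expect_length(tabs, 3)
    for (t in tabs) expect_true(all(rowSums(t) == 1000))
  }
})

test_that("synthetic datasets are bit-reproducible under a fixed seed", {
  cfg <- synthetic_config(n_cruises = 2, n_taxa = 20, depth = 1000, seed = 77)
  d1 <- simulate_bef_dataset(cfg)
  d2 <- simulate_bef_dataset(cfg)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  expect_identical(d1$tables, d2$tables)
  expect_identical(d1$metadata, d2$metadata)
})

test_that("config validation enforces vector lengths and depth floor", {
  expect_error(synthetic_config(n_cruises = 4, biomass_slope = c(0.1, 0.2)),
               "length n_cruises")
  expect_error(synthetic_config(depth = 500), "depth")
  expect_error(synthetic_config(noise_sd = -1), "noise_sd")
})

test_that("pair-exact biomass mode returns its planted slope exactly", {
  cfg <- synthetic_config(n_cruises = 3, n_taxa = 25, depth = 1000,
                          biomass_slope = 0.17, biomass_intercept = 1,
                          noise_sd = 0, seed = 4)
  d <- simulate_bef_dataset(cfg, mode = "pair-exact")
  eff <- suppressWarnings(fit_cruise_slopes(
    within(d$pairs_exact, beta_mpti <- NA_real_)))
  expect_equal(eff$slope, rep(0.17, 3), tolerance = 1e-8)
})

test_that("site biomass mode recovers the planted positive association", {
  cfg <- synthetic_config(n_cruises = 8, n_taxa = 40, depth = 1500,
                          biomass_slope = 0.6, noise_sd = 0.1, seed = 10)
  d <- simulate_bef_dataset(cfg, mode = "site")
  pairs <- build_pair_table(d$tables, d$metadata)
  rho <- cor(pairs$bray_curtis, pairs$summed_biomass, method = "spearman")
  expect_gt(rho, 0)
})

test_that("stronger homogenizing selection drives mean betaMPTI more negative", {
  mean_z <- function(strength) {
    z <- unlist(lapply(1:6, function(k) {
      cfg <- synthetic_config(n_cruises = 1, n_taxa = 30, depth = 1000,
                              regime = "homogenizing",
                              selection_strength = strength, trait_sigma = 1,
                              seed = derive_seed(900 + strength * 10, k))
      d <- simulate_bef_dataset(cfg)
      pairs <- build_pair_table(d$tables, d$metadata)
      suppressWarnings(pairwise_assembly(pairs, d$tables, d$tree,
                                         n_rand = 199, pool = "all",
                                         seed = k))$pairs$beta_mpti
    }))
    c(mean(z, na.rm = TRUE), sd(z, na.rm = TRUE) / sqrt(sum(!is.na(z))))
  }
  weak <- mean_z(0.5); mid <- mean_z(2); strong <- mean_z(8)
  tol_wm <- 2 * sqrt(weak[2]^2 + mid[2]^2)
  tol_ms <- 2 * sqrt(mid[2]^2 + strong[2]^2)
  expect_lt(mid[1], weak[1] + tol_wm)
  expect_lt(strong[1], mid[1] + tol_ms)
  expect_lt(strong[1], weak[1]) # overall monotone trend is unambiguous
})

test_that("synthetic writer emits the full file set and round-trips", {
  cfg <- synthetic_config(n_cruises = 2, n_taxa = 15, depth = 1000, seed = 3)
  d <- simulate_bef_dataset(cfg)
  out <- withr::local_tempdir()
  write_synthetic(d, out)
  expect_setequal(list.files(out),
                  c("tree.nwk", "counts_cruise01.tsv", "counts_cruise02.tsv",
                    "metadata.tsv", "truth.tsv"))
  tab <- read_counts(file.path(out, "counts_cruise01.tsv"), "C01")
  expect_identical(unclass(tab), unclass(d$tables[[1]]))
  meta <- read_metadata(file.path(out, "metadata.tsv"))
  expect_equal(meta$biomass_ugC_L, d$metadata$biomass_ugC_L, tolerance = 1e-9)
})
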