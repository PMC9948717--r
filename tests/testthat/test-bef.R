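test_that("per-cruise slopes interpolate a noise-free log-log fixture", {
  pairs <- exact_pairs(intercept = 1, slope = 0.17)
  eff <- suppressWarnings(fit_cruise_slopes(pairs)) # perfect fit by design
  expect_s3_class(eff, "cruise_effects")
  expect_equal(eff$slope, 0.17, tolerance = 1e-8)
  expect_equal(eff$n_pairs, 15L)
})

test_that("degenerate or underpowered cruises are handled as specified", {
  const <- exact_pairs(1, 0.2, bc = rep(0.5, 6))
  expect_error(suppressWarnings(fit_cruise_slopes(const)), "zero variance")

  two <- exact_pairs(1, 0.2, bc = c(0.3, 0.6))
  expect_warning(expect_error(fit_cruise_slopes(two), "fewer than 3"),
                 "fewer than 3")

  zero_bc <- exact_pairs(1, 0.2, bc = c(0, seq(0.2, 0.8, length.out = 14)))
  expect_warning(prepared <- prepare_pairs(zero_bc), "Bray-Curtis 0")
  expect_equal(nrow(prepared), 14)
})

test_that("mixed model reduces to pooled OLS when cruises are exchangeable", {
  pairs <- withr::with_seed(5, {
    p <- do.call(rbind, lapply(sprintf("C%02d", 1:6), function(cr)
      exact_pairs(1, 0.2, cruise = cr,
                  bc = runif(15, 0.2, 0.9))))
    p$summed_biomass <- p$summed_biomass * rlnorm(nrow(p), 0, 0.2)
    p
  })
  expect_warning(m <- fit_mixed(pairs), "singular|fixed-intercept")
  expect_identical(m$model_type, "lm")
  pooled <- lm(log(summed_biomass) ~ log(bray_curtis), data = pairs)
  expect_equal(unname(coef(m)), unname(coef(pooled)), tolerance = 1e-6)
  expect_true(m$marginal_r2 >= 0 && m$marginal_r2 <= 1)
})

test_that("mixed model recovers a common planted slope with cruise intercept noise", {
  pairs <- withr::with_seed(9, {
    do.call(rbind, lapply(1:10, function(k) {
      p <- exact_pairs(1 + rnorm(1, 0, 0.5), 0.2,
                       cruise = sprintf("C%02d", k),
                       bc = runif(15, 0.2, 0.9))
      p$summed_biomass <- p$summed_biomass * rlnorm(nrow(p), 0, 0.1)
      p
    }))
  })
  m <- fit_mixed(pairs)
  expect_identical(m$model_type, "lmm")
  est <- m$coefficients[m$coefficients$term == "log_bray_curtis", ]
  expect_lt(abs(est$estimate - 0.2), 3 * est$se)
  expect_gt(m$random_variance, 0)
})

test_that("backward selection respects alpha limits and protection", {
  d <- withr::with_seed(2, {
    n <- 120
    d <- data.frame(cruise_id = "C01", prot = rnorm(n), x1 = rnorm(n),
                    x2 = rnorm(n), x3 = rnorm(n))
    d$y <- 2 * d$x1 + rnorm(n)
    d
  })
  terms <- c("prot", "x1", "x2", "x3")

  full <- backward_select(d, terms, protect = "prot", alpha = 1,
                          response = "y", random = NULL)
  expect_setequal(setdiff(full$coefficients$term, "(Intercept)"), terms)
  expect_equal(nrow(full$selection_trace), 0)

  only_prot <- backward_select(d, terms, protect = "prot", alpha = 0,
                               response = "y", random = NULL)
  expect_setequal(setdiff(only_prot$coefficients$term, "(Intercept)"), "prot")
  expect_equal(nrow(only_prot$selection_trace), 3)

  sel <- backward_select(d, terms, protect = "prot", alpha = 0.05,
                         response = "y", random = NULL)
  expect_true("prot" %in% sel$coefficients$term) # retained despite p ~ 0.5
  expect_true("x1" %in% sel$coefficients$term)
})

test_that("backward selection usually recovers exactly the planted signal", {
  # two orthogonal null covariates: success rate is 1 - P(min p < alpha)
  # = 0.95^2 ~ 0.90; assert above its 3-sigma binomial floor
  hits <- 0
  for (r in 1:50) {
    d <- withr::with_seed(1000 + r, {
      n <- 120
      d <- data.frame(prot = rnorm(n), x1 = rnorm(n), x2 = rnorm(n),
                      x3 = rnorm(n))
      d$y <- 2 * d$x1 + rnorm(n)
      d
    })
    m <- backward_select(d, c("prot", "x1", "x2", "x3"), protect = "prot",
                         alpha = 0.05, response = "y", random = NULL)
    kept <- setdiff(m$coefficients$term, "(Intercept)")
    hits <- hits + setequal(kept, c("prot", "x1"))
    expect_true("prot" %in% kept)
  }
  expect_gte(hits / 50, 0.90 - 3 * sqrt(0.9 * 0.1 / 50))
})

test_that("cross-cruise regression recovers an exact planted betaMPTI effect", {
  mpti <- seq(-2, 0.5, length.out = 10)
  eff <- data.frame(cruise_id = sprintf("C%02d", 1:10),
                    slope = 0.3 + 0.79 * mpti,
                    mean_beta_mpti = mpti)
  m <- cross_cruise_regression(eff)
  expect_equal(unname(coef(m)["mean_beta_mpti"]), 0.79, tolerance = 1e-8)
  expect_error(cross_cruise_regression(eff[1:2, ]), ">= 3 cruises")
})

test_that("beta diversity vs assembly model demands a varying regressor", {
  pairs <- exact_pairs(1, 0.2)
  pairs$beta_mpti <- -1
  pairs <- rbind(pairs, within(exact_pairs(1, 0.2, cruise = "C02"),
                               beta_mpti <- -1))
  expect_error(beta_vs_assembly(pairs), "degenerate regressor")

  pairs2 <- withr::with_seed(6, {
    p <- do.call(rbind, lapply(1:8, function(k)
      exact_pairs(1, 0.2, cruise = sprintf("C%02d", k),
                  bc = runif(15, 0.15, 0.9))))
    # beta diversity rises with betaMPTI plus noise
    p$beta_mpti <- 2 * log(p$bray_curtis) + rnorm(nrow(p), 0, 0.3)
    p
  })
  m <- suppressWarnings(beta_vs_assembly(pairs2))
  est <- m$coefficients[m$coefficients$term == "beta_mpti", ]
  expect_gt(est$estimate, 0)
  expect_lt(est$p_value, 0.05)
})
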