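# Independent -2 log likelihood for the univariate AE model, written from
# the bivariate-normal density directly (loops, solve, det): the oracle the
# vectorized FIML implementation is checked against.
nll_ae_oracle <- function(par, tp) {
  mu <- par[1]; vA <- par[2]; vE <- par[3]
  V <- vA + vE
  ll <- 0
  for (g in c("MZ", "DZ")) {
    cw <- if (g == "MZ") vA else 0.5 * vA
    S <- matrix(c(V, cw, cw, V), 2)
    if (V <= 0 || det(S) <= 0) return(1e10)
    Si <- solve(S); ld <- log(det(S))
    sub <- tp[tp$zygosity == g & !is.na(tp$y1) & !is.na(tp$y2), ]
    for (i in seq_len(nrow(sub))) {
      r <- c(sub$y1[i] - mu, sub$y2[i] - mu)
      ll <- ll + 2 * log(2 * pi) + ld + drop(r %*% Si %*% r)
    }
  }
  ll
}

test_that("FIML AE fit matches an independent direct-search optimizer", {
  tp <- make_pairs(60, 40, A = 0.4, E = 0.6, seed = 19)
  fit <- fit_univariate(tp, "AE", covariates = character(0))
  # oracle evaluated at the package's estimates reproduces its -2LL
  par_hat <- c(fit$coefficients[1], fit$components["A"], fit$components["E"])
  expect_equal(nll_ae_oracle(par_hat, tp), fit$m2ll, tolerance = 1e-8)
  # independent Nelder-Mead minimisation finds no better optimum
  opt <- stats::optim(c(0, 0.5, 0.5), nll_ae_oracle, tp = tp,
                      control = list(maxit = 5000, reltol = 1e-12))
  opt <- stats::optim(opt$par, nll_ae_oracle, tp = tp,
                      control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(fit$m2ll, opt$value, tolerance = 1e-6)
})

test_that("saturated FIML reduces to closed-form moments on complete data", {
  tp <- make_pairs(120, 80, A = 0.3, C = 0.2, E = 0.5, seed = 20)
  sat <- fit_saturated(tp, covariates = character(0))
  for (g in c("MZ", "DZ")) {
    i <- if (g == "MZ") 1 else 2
    sub <- tp[tp$zygosity == g, ]
    # ML moments (denominator n)
    n <- nrow(sub)
    expect_equal(sat$means[i, 1], mean(sub$y1), tolerance = 1e-4)
    expect_equal(sat$means[i, 2], mean(sub$y2), tolerance = 1e-4)
    expect_equal(sat$variances[i, 1], mean((sub$y1 - mean(sub$y1))^2),
                 tolerance = 1e-3)
    expect_equal(sat$covariances[i],
                 mean((sub$y1 - mean(sub$y1)) * (sub$y2 - mean(sub$y2))),
                 tolerance = 1e-3)
  }
  # homogeneity holds by construction here
  expect_true(all(sat$homogeneity$p > 0.001))
})

test_that("saturated twin correlations recover the generating co-twin correlation", {
  tp <- make_pairs(800, 300, A = 0.5, E = 0.5, seed = 23)
  sat <- fit_saturated(tp, covariates = character(0))
  expect_near(unname(sat$correlations["MZ", "r"]), 0.5, 0.06)
  expect_near(unname(sat$correlations["DZ", "r"]), 0.25, 0.09)
  expect_lt(sat$correlations["MZ", "lower"], sat$correlations["MZ", "r"])
  expect_gt(sat$correlations["MZ", "upper"], sat$correlations["MZ", "r"])
})

test_that("incomplete pairs enter through their marginal likelihood", {
  tp <- make_pairs(300, 150, A = 0.4, E = 0.6, seed = 24)
  fit_complete <- fit_univariate(tp, "AE", covariates = character(0))
  tp_miss <- tp
  drop_idx <- seq(1, nrow(tp), by = 10)
  tp_miss$y2[drop_idx] <- NA
  fit_miss <- fit_univariate(tp_miss, "AE", covariates = character(0))
  expect_equal(fit_miss$n_obs, fit_complete$n_obs - length(drop_idx))
  # estimates barely move when 10% of co-twins go missing at random
  expect_near(fit_miss$shares["A"], fit_complete$shares["A"], 0.05)
  # dropping rows entirely gives a worse-determined but similar fit
  expect_true(fit_miss$converged)
})

test_that("E-only model carries the total variance and zero co-twin covariance", {
  tp <- make_pairs(100, 50, A = 0.3, E = 0.7, seed = 25)
  fit <- fit_univariate(tp, "E", covariates = character(0))
  expect_named(fit$components, "E")
  expect_near(unname(fit$components["E"]), var(c(tp$y1, tp$y2)), 0.05)
  expect_equal(unname(fit$shares["E"]), 1)
})

test_that("C and D together are rejected as unidentified", {
  tp <- make_pairs(30, 30, A = 0.5, E = 0.5, seed = 26)
  expect_error(fit_univariate(tp, "ACDE"), "not identified")
})

test_that("likelihood is monotone along the model ladder", {
  tp <- make_pairs(200, 120, A = 0.35, C = 0.1, E = 0.55, seed = 27)
  sat <- fit_saturated(tp)
  ace <- fit_univariate(tp, "ACE")
  ae <- fit_univariate(tp, "AE")
  ce <- fit_univariate(tp, "CE")
  e <- fit_univariate(tp, "E")
  tol <- 1e-6
  expect_lte(sat$m2ll, ace$m2ll + tol)
  expect_lte(ace$m2ll, ae$m2ll + tol)
  expect_lte(ace$m2ll, ce$m2ll + tol)
  expect_lte(ae$m2ll, e$m2ll + tol)
  # saturated vs full model comparison has 6 degrees of freedom
  cmp <- compare_models(sat, ace)
  expect_equal(cmp$df, 6)
  expect_gte(cmp$chi2, 0)
})

test_that("model comparison: identity gives chi2 = 0, p = 1; non-nested rejected", {
  tp <- make_pairs(80, 40, A = 0.4, E = 0.6, seed = 28)
  ae1 <- fit_univariate(tp, "AE")
  ae2 <- fit_univariate(tp, "AE")
  cmp <- compare_models(ae1, ae2)
  expect_equal(cmp$chi2, 0, tolerance = 1e-6)
  expect_equal(cmp$p, 1)
  ce <- fit_univariate(tp, "CE")
  expect_error(compare_models(ae1, ce), "not nested")
})

test_that("heritability is the standardized A share; degenerate cases handled", {
  fake <- structure(list(components = c(A = 0.18, C = 0.09, E = 0.09)),
                    class = "twin_fit")
  h <- heritability(fake)
  expect_equal(h$h2, 0.5)
  expect_equal(sum(h$shares), 1)
  fake0 <- structure(list(components = c(A = 0, E = 1)), class = "twin_fit")
  expect_equal(heritability(fake0)$h2, 0)
  fake36 <- structure(list(components = c(A = 0.36, E = 0.64)), class = "twin_fit")
  expect_equal(heritability(fake36)$h2, 0.36)
  bad <- structure(list(components = c(A = 0.2, E = -0.3)), class = "twin_fit")
  expect_error(heritability(bad), "positive")
})

test_that("ACE recovers generating shares and direct-symmetric estimates can go negative", {
  tp <- make_pairs(900, 350, A = 0.36, E = 0.64, seed = 29)
  fit <- fit_univariate(tp, "ACE", covariates = character(0))
  expect_near(unname(fit$shares["A"] + fit$shares["C"]), 0.36, 0.09)
  expect_near(unname(fit$shares["E"]), 0.64, 0.06)
  # on CE-generated data the A estimate is free to be slightly negative
  tps <- lapply(1:6, function(s) make_pairs(400, 250, C = 0.29, E = 0.71, seed = 100 + s))
  a_hats <- vapply(tps, function(tp) {
    fit_univariate(tp, "ACE", covariates = character(0))$components["A"]
  }, numeric(1))
  expect_true(any(a_hats < 0))
  expect_lt(abs(mean(a_hats)), 0.12)
})

test_that("profile CIs bracket the estimate and tighten with sample size", {
  tp_small <- make_pairs(120, 60, A = 0.4, E = 0.6, seed = 33)
  tp_big <- make_pairs(900, 400, A = 0.4, E = 0.6, seed = 33)
  f_s <- fit_univariate(tp_small, "AE", covariates = character(0))
  f_b <- fit_univariate(tp_big, "AE", covariates = character(0))
  ci_s <- profile_ci(f_s, "h2")
  ci_b <- profile_ci(f_b, "h2")
  expect_lt(ci_s[1], f_s$shares["A"]); expect_gt(ci_s[2], f_s$shares["A"])
  expect_lt(ci_b[1], f_b$shares["A"]); expect_gt(ci_b[2], f_b$shares["A"])
  expect_lt(diff(ci_b), diff(ci_s))
  # profile -2LL at a bound sits qchisq(0.95, 1) above the minimum
  bump <- aesthetwin:::profile_neg2ll_at(f_b, "share_A", ci_b[2]) - f_b$m2ll
  expect_equal(bump, qchisq(0.95, 1), tolerance = 1e-2)
  # raw-component profiling works too
  ci_raw <- profile_ci(f_b, "A")
  expect_lt(ci_raw[1], f_b$components["A"]); expect_gt(ci_raw[2], f_b$components["A"])
})

test_that("covariate effects on the means are recovered", {
  tp <- make_pairs(500, 250, A = 0.4, E = 0.6, seed = 35)
  # inject known sex and age effects
  sex_eff <- 0.5; age_eff <- 0.02
  sexnum <- as.numeric(factor(tp$sex)) - 1
  agec1 <- tp$age1 - mean(c(tp$age1, tp$age2))
  agec2 <- tp$age2 - mean(c(tp$age1, tp$age2))
  tp$y1 <- tp$y1 + sex_eff * sexnum + age_eff * agec1
  tp$y2 <- tp$y2 + sex_eff * sexnum + age_eff * agec2
  fit <- fit_univariate(tp, "AE", covariates = c("sex", "age"))
  expect_near(unname(fit$coefficients["sex"]), sex_eff, 0.15)
  expect_near(unname(fit$coefficients["age"]), age_eff, 0.005)
  expect_near(unname(fit$shares["A"]), 0.4, 0.08)
})
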