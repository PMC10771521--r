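SA_fig <- matrix(c(0.35, 0.18, 0.18, 0.31), 2)
SE_fig <- matrix(c(0.65, 0.09, 0.09, 0.69), 2)

test_that("derived quantities match brute-force covariance algebra", {
  fit <- structure(list(traits = c("t1", "t2"),
                        Sigma_A = SA_fig, Sigma_C = matrix(0, 2, 2),
                        Sigma_E = SE_fig), class = "mv_fit")
  expect_equal(bivariate_heritability(fit, 1, 2), 0.18 / (0.18 + 0.09),
               tolerance = 1e-12)
  expect_equal(genetic_correlation(fit, 1, 2), 0.18 / sqrt(0.35 * 0.31),
               tolerance = 1e-12)
  expect_equal(environmental_correlation(fit, 1, 2), 0.09 / sqrt(0.65 * 0.69),
               tolerance = 1e-12)
  # random PSD component matrices: matches cov2cor
  set.seed(7)
  for (i in 1:5) {
    L <- matrix(rnorm(4), 2); S <- crossprod(L) + diag(0.1, 2)
    f <- structure(list(traits = c("a", "b"), Sigma_A = S,
                        Sigma_C = matrix(0, 2, 2), Sigma_E = diag(2)),
                   class = "mv_fit")
    expect_equal(genetic_correlation(f, "a", "b"), cov2cor(S)[1, 2],
                 tolerance = 1e-12)
  }
  # perfect pleiotropy: rank-1 A gives rhoA = 1
  S1 <- tcrossprod(c(0.6, 0.4))
  f1 <- structure(list(traits = c("a", "b"), Sigma_A = S1,
                       Sigma_C = matrix(0, 2, 2), Sigma_E = diag(2)),
                  class = "mv_fit")
  expect_equal(genetic_correlation(f1, 1, 2), 1, tolerance = 1e-12)
  # degenerate inputs are flagged
  fneg <- structure(list(traits = c("a", "b"), Sigma_A = diag(c(-0.1, 0.3)),
                         Sigma_C = matrix(0, 2, 2), Sigma_E = diag(2)),
                    class = "mv_fit")
  expect_error(genetic_correlation(fneg, 1, 2), "non-positive")
  expect_equal(bivariate_heritability(f1, 1, 1), S1[1, 1] / (S1[1, 1] + 1),
               tolerance = 1e-12)
})

test_that("null cross-trait A covariance is recovered as ~0", {
  w <- make_mv_pairs(500, 250, Sigma_A = diag(c(0.4, 0.4)),
                     Sigma_E = diag(c(0.6, 0.6)), seed = 41)
  fit <- fit_multivariate(w, mv_spec(c("t1", "t2")))
  expect_lt(abs(fit$Sigma_A[1, 2]), 0.08)
  expect_lt(abs(genetic_correlation(fit, 1, 2)), 0.2)
})

test_that("bivariate FIML matches an independent direct-search optimizer", {
  w <- make_mv_pairs(60, 40, Sigma_A = SA_fig, Sigma_E = SE_fig, seed = 42)
  spec <- mv_spec(c("t1", "t2"))
  fit <- fit_multivariate(w, spec)
  # Nelder-Mead from a neutral start on the same objective surface,
  # via the exported likelihood pieces reconstructed here
  obj <- function(th) aesthetwin:::mv_neg2ll(th, aesthetwin:::mv_prep(w, spec$traits, TRUE), spec)
  th0 <- c(0, 0, 0.2, 0.05, 0.2, 0.8, 0.05, 0.8)
  opt <- stats::optim(th0, obj, control = list(maxit = 20000, reltol = 1e-13))
  opt <- stats::optim(opt$par, obj, control = list(maxit = 20000, reltol = 1e-13))
  expect_lte(fit$m2ll, opt$value + 1e-5)
})

test_that("implied phenotypic covariance reproduces the sample covariance", {
  w <- make_mv_pairs(1000, 400, Sigma_A = SA_fig, Sigma_E = SE_fig, seed = 43)
  fit <- fit_multivariate(w, mv_spec(c("t1", "t2")), standardize = FALSE)
  emp <- cov(rbind(as.matrix(w[, c("t1_1", "t2_1")]),
                   as.matrix(w[, c("t1_2", "t2_2")])))
  expect_near(unname(fit$Sigma_P), unname(emp), 0.08)
})

test_that("per-trait component inclusion zeroes the excluded blocks", {
  w <- make_mv_pairs(300, 200, Sigma_A = diag(c(0.4, 0)),
                     Sigma_C = diag(c(0, 0.3)),
                     Sigma_E = diag(c(0.6, 0.7)), seed = 44)
  spec <- mv_spec(c("t1", "t2"), A_traits = "t1", C_traits = "t2")
  fit <- fit_multivariate(w, spec)
  expect_equal(fit$Sigma_A[2, 2], 0)
  expect_equal(fit$Sigma_A[1, 2], 0)
  expect_equal(fit$Sigma_C[1, 1], 0)
  expect_gt(fit$Sigma_A[1, 1], 0.2)
  expect_gt(fit$Sigma_C[2, 2], 0.1)
  # full ACE on two traits has 11 free parameters; the paper-sized chain
  expect_equal(aesthetwin:::mv_npar(mv_spec(c("t1", "t2"), C_traits = c("t1", "t2"))), 11)
})

test_that("model chain: saturated (28 par) vs full bivariate ACE on 17 df", {
  w <- make_mv_pairs(250, 150, Sigma_A = SA_fig, Sigma_E = SE_fig, seed = 45)
  sat <- fit_mv_saturated(w, c("t1", "t2"))
  expect_equal(sat$npar, 28)
  full <- fit_multivariate(w, mv_spec(c("t1", "t2"), C_traits = c("t1", "t2")))
  ae <- fit_multivariate(w, mv_spec(c("t1", "t2")))
  cmp <- compare_models(sat, full)
  expect_equal(cmp$df, 17)
  expect_gte(cmp$chi2, -1e-6)
  # -2LL non-decreasing along the chain
  expect_lte(sat$m2ll, full$m2ll + 1e-6)
  expect_lte(full$m2ll, ae$m2ll + 1e-6)
  # AE-generated data: the specified AE submodel survives the LRT mostly
  cmp2 <- compare_models(full, ae)
  expect_equal(cmp2$df, 3)
})

test_that("cross-twin cross-trait correlations follow the moment formula", {
  # rank-1 A across traits: MZ cross-twin cross-trait covariance = sigma_A12
  SA <- tcrossprod(c(sqrt(0.5), sqrt(0.5)))  # all entries 0.5
  w <- make_mv_pairs(4000, 1000, Sigma_A = SA, Sigma_E = diag(c(0.5, 0.5)),
                     seed = 46)
  cc <- cross_twin_cross_trait_correlations(w, c("t1", "t2"))
  expect_near(cc$MZ[1, 2], 0.5, 0.04)
  expect_near(cc$DZ[1, 2], 0.25, 0.05)
  # symmetrization: swapping twin order leaves the matrices unchanged
  w_sw <- w
  w_sw[, c("t1_1", "t1_2", "t2_1", "t2_2")] <- w[, c("t1_2", "t1_1", "t2_2", "t2_1")]
  cc_sw <- cross_twin_cross_trait_correlations(w_sw, c("t1", "t2"))
  expect_near(cc_sw$MZ, cc$MZ, 1e-12)
  # A = C = 0 generator: everything ~ 0
  w0 <- make_mv_pairs(800, 400, Sigma_A = matrix(0, 2, 2),
                      Sigma_E = diag(c(1, 1)), seed = 47)
  cc0 <- cross_twin_cross_trait_correlations(w0, c("t1", "t2"))
  expect_lt(max(abs(cc0$MZ)), 0.1)
})

test_that("delta-method CIs for derived quantities enclose the estimate", {
  w <- make_mv_pairs(400, 200, Sigma_A = SA_fig, Sigma_E = SE_fig, seed = 48)
  fit <- fit_multivariate(w, mv_spec(c("t1", "t2")), hessian = TRUE)
  rho <- genetic_correlation(fit, 1, 2, ci = TRUE)
  ci <- attr(rho, "ci")
  expect_equal(attr(rho, "ci_method"), "delta")
  expect_lt(ci[1], as.numeric(rho)); expect_gt(ci[2], as.numeric(rho))
  h2b <- bivariate_heritability(fit, 1, 2, ci = TRUE)
  expect_true(all(is.finite(attr(h2b, "ci"))))
})
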