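# Univariate Classical Twin Design models by full-information maximum
# likelihood. Variance components are parameterized directly ("direct
# symmetric"): free in sign, so small negative estimates are representable
# and the likelihood-ratio chi-square keeps its standard reference
# distribution (no boundary mixture).

# ---- data preparation --------------------------------------------------

# Builds per-zygosity blocks of complete pairs and singletons, with the
# design matrix of the mean model (intercept + optional sex + centred age).
prep_pairs <- function(pairs, covariates = c("sex", "age"), standardize = FALSE) {
  stopifnot(all(c("family_id", "zygosity", "y1", "y2") %in% names(pairs)))
  if (!all(pairs$zygosity %in% c("MZ", "DZ"))) stop("zygosity must be MZ or DZ")
  if (length(covariates) > 0) {
    covariates <- match.arg(covariates, c("sex", "age"), several.ok = TRUE)
  }

  y1 <- pairs$y1; y2 <- pairs$y2
  if (standardize) {
    all_y <- c(y1, y2)
    mu <- mean(all_y, na.rm = TRUE); s <- stats::sd(all_y, na.rm = TRUE)
    y1 <- (y1 - mu) / s; y2 <- (y2 - mu) / s
  }
  use_sex <- "sex" %in% covariates && "sex" %in% names(pairs) &&
    length(unique(stats::na.omit(pairs$sex))) > 1
  use_age <- "age" %in% covariates &&
    (("age1" %in% names(pairs)) || ("age" %in% names(pairs)))
  if ("age" %in% names(pairs) && !("age1" %in% names(pairs))) {
    pairs$age1 <- pairs$age; pairs$age2 <- pairs$age
  }
  sexnum <- if (use_sex) as.numeric(factor(pairs$sex)) - 1 else rep(0, nrow(pairs))
  age_c <- if (use_age) {
    m <- mean(c(pairs$age1, pairs$age2), na.rm = TRUE)
    list(a1 = pairs$age1 - m, a2 = pairs$age2 - m)
  } else list(a1 = rep(0, nrow(pairs)), a2 = rep(0, nrow(pairs)))

  mkX <- function(age) {
    X <- cbind(intercept = rep(1, nrow(pairs)))
    if (use_sex) X <- cbind(X, sex = sexnum)
    if (use_age) X <- cbind(X, age = age)
    X
  }
  X1 <- mkX(age_c$a1); X2 <- mkX(age_c$a2)

  out <- list(p = ncol(X1), covariates = c(if (use_sex) "sex", if (use_age) "age"),
              n_obs = sum(!is.na(y1)) + sum(!is.na(y2)))
  for (g in c("MZ", "DZ")) {
    gi <- pairs$zygosity == g
    comp <- gi & !is.na(y1) & !is.na(y2)
    s1 <- gi & !is.na(y1) & is.na(y2)
    s2 <- gi & is.na(y1) & !is.na(y2)
    out[[g]] <- list(
      y1 = y1[comp], y2 = y2[comp], X1 = X1[comp, , drop = FALSE],
      X2 = X2[comp, , drop = FALSE],
      ys = c(y1[s1], y2[s2]),
      Xs = rbind(X1[s1, , drop = FALSE], X2[s2, , drop = FALSE]),
      order_s = c(rep(1L, sum(s1)), rep(2L, sum(s2))),
      n_comp = sum(comp), n_sing = sum(s1) + sum(s2)
    )
  }
  out
}

BIG_NLL <- 1e10

# -2 log likelihood for per-group bivariate normal with means mu1/mu2 and
# covariance [v1 c; c v2]; singletons contribute their marginal.
neg2ll_groups <- function(prep, moments) {
  nll <- 0
  for (g in c("MZ", "DZ")) {
    d <- prep[[g]]
    m <- moments[[g]]
    v1 <- m$v1; v2 <- m$v2; c12 <- m$c12
    det <- v1 * v2 - c12^2
    if (!is.finite(det) || v1 <= 0 || v2 <= 0 || det <= 1e-12 * max(v1 * v2, 1e-12)) {
      return(BIG_NLL + sum(abs(c(v1, v2, c12))))
    }
    if (d$n_comp > 0) {
      r1 <- d$y1 - m$mu1
      r2 <- d$y2 - m$mu2
      q <- (v2 * r1^2 - 2 * c12 * r1 * r2 + v1 * r2^2) / det
      nll <- nll + d$n_comp * (2 * log(2 * pi) + log(det)) + sum(q)
    }
    if (d$n_sing > 0) {
      vs <- ifelse(d$order_s == 1L, v1, v2)
      rs <- d$ys - m$mus
      nll <- nll + sum(log(2 * pi) + log(vs) + rs^2 / vs)
    }
  }
  nll
}

# Co-twin covariance weights of the components under the CTD.
ctd_weights <- function(components) {
  w <- list(MZ = c(A = 1, C = 1, D = 1, E = 0),
            DZ = c(A = 0.5, C = 1, D = 0.25, E = 0))
  lapply(w, function(x) x[components])
}

uni_moments <- function(prep, b, comps, components) {
  w <- ctd_weights(components)
  V <- sum(comps)
  lapply(stats::setNames(c("MZ", "DZ"), c("MZ", "DZ")), function(g) {
    d <- prep[[g]]
    list(mu1 = drop(d$X1 %*% b), mu2 = drop(d$X2 %*% b),
         mus = drop(d$Xs %*% b),
         v1 = V, v2 = V, c12 = sum(w[[g]] * comps))
  })
}

uni_neg2ll <- function(theta, prep, components) {
  p <- prep$p
  b <- theta[seq_len(p)]
  comps <- theta[-seq_len(p)]
  neg2ll_groups(prep, uni_moments(prep, b, comps, components))
}

# Moment-based starting values for the variance components.
uni_start <- function(prep, components) {
  all_y <- c(prep$MZ$y1, prep$MZ$y2, prep$MZ$ys, prep$DZ$y1, prep$DZ$y2, prep$DZ$ys)
  V <- stats::var(all_y)
  cmz <- if (prep$MZ$n_comp > 2) stats::cov(prep$MZ$y1, prep$MZ$y2) else V / 2
  cdz <- if (prep$DZ$n_comp > 2) stats::cov(prep$DZ$y1, prep$DZ$y2) else V / 4
  est <- c(A = 2 * (cmz - cdz), C = 2 * cdz - cmz,
           D = 4 * cdz - cmz, E = V - cmz)
  if ("D" %in% components) est["A"] <- 4 * cdz - cmz  # ADE moment solution
  if ("D" %in% components) est["D"] <- 2 * (cmz - 2 * cdz)
  s <- est[components]
  s[!is.finite(s)] <- V / length(components)
  # keep the start strictly inside the PD region
  tot <- sum(s)
  if (tot <= 0) s <- rep(V / length(components), length(components))
  s["E"] <- max(s["E"], 0.1 * V)
  s
}

run_optim <- function(par, fn, ..., n_restarts = 3) {
  best <- stats::optim(par, fn, ..., method = "BFGS",
                       control = list(maxit = 1000, reltol = 1e-12))
  jitter_grid <- list(c(0.6, 1.4), c(1.5, 0.7), c(0.9, 1.1))
  for (i in seq_len(min(n_restarts, length(jitter_grid)))) {
    f <- rep_len(jitter_grid[[i]], length(par))
    cand <- tryCatch(stats::optim(par * f + 0.01 * (i - 2), fn, ..., method = "BFGS",
                                  control = list(maxit = 1000, reltol = 1e-12)),
                     error = function(e) NULL)
    if (!is.null(cand) && cand$value < best$value - 1e-9) best <- cand
  }
  best
}

# ---- fitting -----------------------------------------------------------

#' Fit a univariate twin variance-component model by FIML
#'
#' Estimates the mean model (intercept plus optional sex and centred-age
#' covariates, coefficients shared across co-twins) and the variance
#' components jointly by maximizing the full-information Gaussian
#' likelihood. Expected co-twin covariance is \code{A + C + D} for MZ pairs
#' and \code{0.5 A + C + 0.25 D} for DZ pairs; incomplete pairs contribute
#' their univariate marginal likelihood. Components are unconstrained in
#' sign (direct symmetric approach); C and D cannot be requested together
#' (not identified in the classical twin design).
#'
#' @param pairs a \code{twin_pairs} data.frame (\code{family_id, zygosity,
#'   sex, age1, age2, y1, y2}; either member may be NA).
#' @param components model string or character vector: one of "ACE", "ADE",
#'   "AE", "CE", "DE", "E" (E is always included).
#' @param covariates subset of \code{c("sex", "age")} entering the means.
#' @param standardize z-scale the phenotype across all individuals first?
#' @param n_restarts jittered optimizer restarts beyond the moment start.
#' @return object of class \code{twin_fit}: \code{components} (named
#'   estimates), \code{shares} (standardized, summing to 1),
#'   \code{coefficients}, \code{m2ll}, \code{npar}, \code{aic},
#'   \code{n_obs}, \code{converged}.
#' @export
fit_univariate <- function(pairs, components = "AE",
                           covariates = c("sex", "age"),
                           standardize = FALSE, n_restarts = 3) {
  comp_set <- if (length(components) == 1) strsplit(components, "")[[1]] else components
  comp_set <- unique(comp_set)
  if (!all(comp_set %in% c("A", "C", "D", "E"))) stop("components must be among A, C, D, E")
  if (!"E" %in% comp_set) comp_set <- c(comp_set, "E")
  if (all(c("C", "D") %in% comp_set)) {
    stop("C and D cannot both be included: not identified in the classical twin design")
  }
  comp_set <- intersect(c("A", "C", "D", "E"), comp_set)  # canonical order
  prep <- prep_pairs(pairs, covariates, standardize)

  b0 <- c(mean(c(prep$MZ$y1, prep$MZ$y2, prep$MZ$ys,
                 prep$DZ$y1, prep$DZ$y2, prep$DZ$ys)), rep(0, prep$p - 1))
  s0 <- uni_start(prep, comp_set)
  theta0 <- c(b0, s0)
  opt <- run_optim(theta0, uni_neg2ll, prep = prep, components = comp_set,
                  n_restarts = n_restarts)
  b <- opt$par[seq_len(prep$p)]
  comps <- stats::setNames(opt$par[-seq_len(prep$p)], comp_set)
  npar <- length(opt$par)
  fit <- list(
    model = paste(comp_set, collapse = ""),
    components = comps,
    shares = comps / sum(comps),
    coefficients = stats::setNames(b, c("intercept", prep$covariates)),
    m2ll = opt$value, npar = npar, aic = opt$value + 2 * npar,
    n_obs = prep$n_obs,
    n_pairs = c(MZ = prep$MZ$n_comp + prep$MZ$n_sing,
                DZ = prep$DZ$n_comp + prep$DZ$n_sing),
    converged = opt$convergence == 0,
    prep = prep, comp_set = comp_set
  )
  class(fit) <- "twin_fit"
  fit
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("Univariate %s twin model (FIML), -2LL = %.3f, AIC = %.3f, npar = %d\n",
              x$model, x$m2ll, x$aic, x$npar))
  cat("variance components:\n"); print(round(x$components, 4))
  cat("standardized shares:\n"); print(round(x$shares, 4))
  if (!x$converged) cat("WARNING: optimizer did not report convergence\n")
  invisible(x)
}

# ---- saturated model ---------------------------------------------------

sat_build <- function(theta, prep, equal_means, equal_vars) {
  p_cov <- prep$p - 1
  bc <- if (p_cov > 0) theta[seq_len(p_cov)] else numeric(0)
  rest <- if (p_cov > 0) theta[-seq_len(p_cov)] else theta
  if (equal_means) {
    m <- matrix(rest[1], 2, 2); rest <- rest[-1]
  } else {
    m <- matrix(rest[1:4], 2, 2, byrow = TRUE)  # rows MZ/DZ, cols order
    rest <- rest[-(1:4)]
  }
  if (equal_vars) {
    v <- matrix(rest[1], 2, 2); rest <- rest[-1]
  } else {
    v <- matrix(rest[1:4], 2, 2, byrow = TRUE)
    rest <- rest[-(1:4)]
  }
  cc <- rest[1:2]
  list(bc = bc, m = m, v = v, cc = cc)
}

sat_neg2ll <- function(theta, prep, equal_means, equal_vars) {
  par <- sat_build(theta, prep, equal_means, equal_vars)
  gidx <- c(MZ = 1, DZ = 2)
  moments <- lapply(stats::setNames(names(gidx), names(gidx)), function(g) {
    i <- gidx[[g]]
    d <- prep[[g]]
    cov_part <- function(X) if (length(par$bc) > 0)
      drop(X[, -1, drop = FALSE] %*% par$bc) else 0
    list(mu1 = par$m[i, 1] + cov_part(d$X1),
         mu2 = par$m[i, 2] + cov_part(d$X2),
         mus = par$m[i, d$order_s] + cov_part(d$Xs),
         v1 = par$v[i, 1], v2 = par$v[i, 2], c12 = par$cc[i])
  })
  neg2ll_groups(prep, moments)
}

fit_sat_inner <- function(prep, equal_means = FALSE, equal_vars = FALSE) {
  all_y <- c(prep$MZ$y1, prep$MZ$y2, prep$MZ$ys, prep$DZ$y1, prep$DZ$y2, prep$DZ$ys)
  m0 <- mean(all_y); v0 <- stats::var(all_y)
  theta0 <- c(rep(0, prep$p - 1),
              if (equal_means) m0 else rep(m0, 4),
              if (equal_vars) v0 else rep(v0, 4),
              0.5 * v0, 0.25 * v0)
  opt <- run_optim(theta0, sat_neg2ll, prep = prep,
                  equal_means = equal_means, equal_vars = equal_vars,
                  n_restarts = 2)
  list(opt = opt, npar = length(theta0),
       par = sat_build(opt$par, prep, equal_means, equal_vars))
}

#' Fit the saturated twin model and test its homogeneity assumptions
#'
#' Maximizes the bivariate-normal FIML likelihood with unstructured means
#' and covariance per zygosity group (plus shared covariate effects on the
#' means). Twin correlations are extracted per group with Fisher-z 95% CIs.
#' Homogeneity of means and variances across twin order and zygosity is
#' tested by likelihood-ratio comparison against equated submodels.
#'
#' @inheritParams fit_univariate
#' @param min_pairs soft minimum of complete pairs per zygosity (warn below).
#' @return object of class \code{twin_saturated}: group means/variances/
#'   covariances, \code{correlations} with CIs, \code{m2ll}, \code{npar},
#'   \code{homogeneity} LRT table.
#' @export
fit_saturated <- function(pairs, covariates = c("sex", "age"),
                          standardize = FALSE, min_pairs = 20) {
  prep <- prep_pairs(pairs, covariates, standardize)
  if (prep$MZ$n_comp < min_pairs || prep$DZ$n_comp < min_pairs) {
    warning("fewer than ", min_pairs, " complete pairs in a zygosity group")
  }
  full <- fit_sat_inner(prep)
  eqm <- fit_sat_inner(prep, equal_means = TRUE)
  eqv <- fit_sat_inner(prep, equal_vars = TRUE)

  corr <- lapply(stats::setNames(1:2, c("MZ", "DZ")), function(i) {
    g <- c("MZ", "DZ")[i]
    r <- full$par$cc[i] / sqrt(full$par$v[i, 1] * full$par$v[i, 2])
    n <- prep[[g]]$n_comp
    z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
    se <- 1 / sqrt(max(n - 3, 1))
    c(r = r, lower = tanh(z - 1.96 * se), upper = tanh(z + 1.96 * se))
  })
  homog <- data.frame(
    test = c("equal means (order x zygosity)", "equal variances (order x zygosity)"),
    chi2 = c(eqm$opt$value - full$opt$value, eqv$opt$value - full$opt$value),
    df = c(3, 3)
  )
  homog$p = stats::pchisq(pmax(homog$chi2, 0), homog$df, lower.tail = FALSE)
  out <- list(
    means = full$par$m, variances = full$par$v, covariances = full$par$cc,
    cov_coefficients = stats::setNames(full$par$bc, prep$covariates),
    correlations = do.call(rbind, corr),
    m2ll = full$opt$value, npar = full$npar,
    aic = full$opt$value + 2 * full$npar,
    n_obs = prep$n_obs, converged = full$opt$convergence == 0,
    homogeneity = homog, prep = prep
  )
  class(out) <- "twin_saturated"
  out
}

#' @export
print.twin_saturated <- function(x, ...) {
  cat(sprintf("Saturated twin model (FIML), -2LL = %.3f, npar = %d\n", x$m2ll, x$npar))
  cat("twin correlations:\n"); print(round(x$correlations, 3))
  cat("homogeneity tests:\n"); print(x$homogeneity)
  invisible(x)
}

# ---- model comparison & derived quantities -----------------------------

#' Likelihood-ratio comparison of two nested twin models
#'
#' \code{chi2} is the difference in -2 log likelihood between the more
#' parsimonious model and the full model, referred to a chi-square with the
#' difference in free-parameter count.
#'
#' @param full the richer model (a \code{twin_fit}, \code{twin_saturated} or
#'   \code{mv_fit}).
#' @param reduced the nested, more parsimonious model on the same data.
#' @return data.frame with \code{chi2}, \code{df}, \code{p},
#'   \code{delta_aic}.
#' @export
compare_models <- function(full, reduced) {
  if (!is.null(full$n_obs) && !is.null(reduced$n_obs) &&
      full$n_obs != reduced$n_obs) {
    stop("models were fitted on different data (observation counts differ)")
  }
  if (!is.null(full$comp_set) && !is.null(reduced$comp_set) &&
      !all(reduced$comp_set %in% full$comp_set)) {
    stop("reduced model is not nested in the full model")
  }
  df <- full$npar - reduced$npar
  if (df < 0) stop("'full' has fewer parameters than 'reduced'")
  chi2 <- reduced$m2ll - full$m2ll
  if (chi2 < -1e-4) warning("reduced model fits better than full: check convergence")
  chi2 <- max(chi2, 0)
  data.frame(chi2 = chi2, df = df,
             p = if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE),
             delta_aic = reduced$aic - full$aic)
}

#' Heritability and standardized variance shares
#'
#' \code{h2 = sigma2_A / (sigma2_A + sigma2_C|D + sigma2_E)}; analogous
#' shares for the other components. Profile-likelihood CIs are computed on
#' the share scale when requested.
#'
#' @param fit a \code{twin_fit}.
#' @param ci compute profile-likelihood 95% CIs for each share?
#' @param level confidence level.
#' @return list with \code{h2}, \code{shares}, and (if requested) \code{ci}
#'   (one row per component share).
#' @export
heritability <- function(fit, ci = FALSE, level = 0.95) {
  total <- sum(fit$components)
  if (total <= 0) stop("total phenotypic variance must be positive")
  shares <- fit$components / total
  out <- list(h2 = if ("A" %in% names(shares)) unname(shares["A"]) else 0,
              shares = shares)
  if (ci) {
    out$ci <- do.call(rbind, lapply(names(shares), function(cm) {
      iv <- profile_ci(fit, paste0("share_", cm), level = level)
      data.frame(component = cm, estimate = unname(shares[cm]),
                 lower = unname(iv[1]), upper = unname(iv[2]),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }
  out
}

# Profile -2LL with one quantity fixed: target is either a raw component
# ("A") or a standardized share ("share_A"). Reparameterizes as
# (log total, free shares) when profiling a share.
profile_neg2ll_at <- function(fit, parameter, value) {
  prep <- fit$prep
  comp_set <- fit$comp_set
  p <- prep$p
  if (startsWith(parameter, "share_")) {
    cm <- sub("^share_", "", parameter)
    stopifnot(cm %in% comp_set)
    others <- setdiff(comp_set, cm)
    k_free <- length(others) - 1  # last share implied by sum-to-one
    obj <- function(th) {
      b <- th[seq_len(p)]
      logT <- th[p + 1]
      Tot <- exp(logT)
      sh <- stats::setNames(numeric(length(comp_set)), comp_set)
      sh[cm] <- value
      if (k_free > 0) sh[others[seq_len(k_free)]] <- th[p + 1 + seq_len(k_free)]
      sh[others[length(others)]] <- 1 - sum(sh[c(cm, others[seq_len(k_free)])])
      uni_neg2ll(c(b, sh[comp_set] * Tot), prep, comp_set)
    }
    sh_hat <- fit$shares
    th0 <- c(fit$coefficients, log(max(sum(fit$components), 1e-8)),
             if (k_free > 0) sh_hat[others[seq_len(k_free)]])
    opt <- stats::optim(th0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-11))
    opt$value
  } else {
    stopifnot(parameter %in% comp_set)
    others <- setdiff(comp_set, parameter)
    obj <- function(th) {
      b <- th[seq_len(p)]
      comps <- stats::setNames(numeric(length(comp_set)), comp_set)
      comps[parameter] <- value
      comps[others] <- th[-seq_len(p)]
      uni_neg2ll(c(b, comps[comp_set]), prep, comp_set)
    }
    th0 <- c(fit$coefficients, fit$components[others])
    opt <- stats::optim(th0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-11))
    opt$value
  }
}

#' Profile-likelihood confidence interval for a twin-model parameter
#'
#' Finds the parameter values at which the profiled -2 log likelihood rises
#' by the chi-square(1) quantile (3.841 at 95%) above its minimum, by
#' bracketing plus bisection (\code{uniroot}). A bound that cannot be
#' bracketed inside the search range is reported as NA (open-ended).
#'
#' @param fit a converged \code{twin_fit}.
#' @param parameter a raw component ("A", "C", "D", "E") or a standardized
#'   share ("share_A", ..., "h2" is an alias for "share_A").
#' @param level confidence level.
#' @param span search half-width (default: generous multiple of the
#'   estimate's scale).
#' @return numeric \code{c(lower, upper)}.
#' @export
profile_ci <- function(fit, parameter, level = 0.95, span = NULL) {
  if (parameter == "h2") parameter <- "share_A"
  est <- if (startsWith(parameter, "share_")) {
    unname(fit$shares[sub("^share_", "", parameter)])
  } else unname(fit$components[parameter])
  if (!is.finite(est)) stop("unknown parameter: ", parameter)
  target <- fit$m2ll + stats::qchisq(level, 1)
  if (is.null(span)) {
    span <- if (startsWith(parameter, "share_")) 1.2 else
      max(3 * abs(est), 2 * sum(abs(fit$components)))
  }
  f <- function(v) profile_neg2ll_at(fit, parameter, v) - target
  find_bound <- function(dir) {
    lo <- est; hi <- est + dir * span
    flo <- -stats::qchisq(level, 1); fhi <- f(hi)
    steps <- 0
    while (fhi < 0 && steps < 4) {
      hi <- hi + dir * span; fhi <- f(hi); steps <- steps + 1
    }
    if (fhi < 0) return(NA_real_)
    stats::uniroot(f, lower = min(lo, hi), upper = max(lo, hi),
                   f.lower = if (dir > 0) flo else fhi,
                   f.upper = if (dir > 0) fhi else flo,
                   tol = 1e-5)$root
  }
  c(lower = find_bound(-1), upper = find_bound(1))
}
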