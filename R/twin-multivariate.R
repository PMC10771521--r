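# Multivariate (direct symmetric) ACE models across traits/domains by FIML.
# Component covariance matrices Sigma_A / Sigma_C / Sigma_E are parameterized
# directly; per-trait component inclusion zeroes that trait's row and column
# in the excluded component, which is how "A for scenes and faces only, C
# for abstract images" style specifications are expressed.

#' Multivariate twin model specification
#'
#' @param traits trait (column-stem) names, in order.
#' @param A_traits traits carrying an additive-genetic component (cross-trait
#'   A covariances exist only among these).
#' @param C_traits traits carrying a shared-environment component.
#' @return list of class \code{mv_spec}. The unique-environment block is
#'   always full.
#' @export
mv_spec <- function(traits, A_traits = traits, C_traits = character(0)) {
  stopifnot(length(traits) >= 2, all(A_traits %in% traits), all(C_traits %in% traits))
  structure(list(traits = traits, A_traits = A_traits, C_traits = C_traits),
            class = "mv_spec")
}

# Index helpers for packing/unpacking symmetric blocks.
sym_n <- function(k) k * (k + 1) / 2
sym_fill <- function(vec, members, traits) {
  t_n <- length(traits)
  m <- matrix(0, t_n, t_n, dimnames = list(traits, traits))
  if (length(members) == 0) return(m)
  idx <- match(members, traits)
  pos <- 1
  for (i in seq_along(idx)) for (j in i:length(idx)) {
    m[idx[i], idx[j]] <- m[idx[j], idx[i]] <- vec[pos]
    pos <- pos + 1
  }
  m
}
sym_extract <- function(m, members, traits) {
  idx <- match(members, traits)
  out <- numeric(0)
  for (i in seq_along(idx)) for (j in i:length(idx)) {
    out <- c(out, m[idx[i], idx[j]])
  }
  out
}

mv_unpack <- function(theta, spec) {
  t_n <- length(spec$traits)
  nA <- sym_n(length(spec$A_traits))
  nC <- sym_n(length(spec$C_traits))
  nE <- sym_n(t_n)
  mu <- theta[seq_len(t_n)]
  off <- t_n
  SA <- sym_fill(theta[off + seq_len(nA)], spec$A_traits, spec$traits); off <- off + nA
  SC <- sym_fill(theta[off + seq_len(nC)], spec$C_traits, spec$traits); off <- off + nC
  SE <- sym_fill(theta[off + seq_len(nE)], spec$traits, spec$traits)
  list(mu = mu, Sigma_A = SA, Sigma_C = SC, Sigma_E = SE)
}

mv_npar <- function(spec) {
  length(spec$traits) + sym_n(length(spec$A_traits)) +
    sym_n(length(spec$C_traits)) + sym_n(length(spec$traits))
}

# Stack family observation vectors (twin1 traits, twin2 traits) and group
# rows by missing pattern for FIML.
mv_prep <- function(pairs_multi, traits, standardize = TRUE) {
  cols1 <- paste0(traits, "_1"); cols2 <- paste0(traits, "_2")
  missing_cols <- setdiff(c(cols1, cols2), names(pairs_multi))
  if (length(missing_cols) > 0) {
    stop("missing trait columns: ", paste(missing_cols, collapse = ", "))
  }
  Y <- as.matrix(pairs_multi[, c(cols1, cols2)])
  if (standardize) {
    for (k in seq_along(traits)) {
      v <- c(Y[, k], Y[, k + length(traits)])
      mu <- mean(v, na.rm = TRUE); s <- stats::sd(v, na.rm = TRUE)
      Y[, k] <- (Y[, k] - mu) / s
      Y[, k + length(traits)] <- (Y[, k + length(traits)] - mu) / s
    }
  }
  groups <- list()
  for (g in c("MZ", "DZ")) {
    Yg <- Y[pairs_multi$zygosity == g, , drop = FALSE]
    obs <- !is.na(Yg)
    keep <- rowSums(obs) > 0
    Yg <- Yg[keep, , drop = FALSE]; obs <- obs[keep, , drop = FALSE]
    pat <- apply(obs, 1, function(x) paste(as.integer(x), collapse = ""))
    groups[[g]] <- lapply(split(seq_len(nrow(Yg)), pat), function(rows) {
      idx <- which(obs[rows[1], ])
      list(idx = idx, Y = Yg[rows, idx, drop = FALSE], n = length(rows))
    })
  }
  list(groups = groups, t_n = length(traits), traits = traits,
       n_obs = sum(!is.na(Y)))
}

mv_neg2ll <- function(theta, prep, spec) {
  par <- mv_unpack(theta, spec)
  t_n <- prep$t_n
  SP <- par$Sigma_A + par$Sigma_C + par$Sigma_E
  W <- list(MZ = par$Sigma_A + par$Sigma_C, DZ = 0.5 * par$Sigma_A + par$Sigma_C)
  mu_full <- rep(par$mu, 2)
  nll <- 0
  for (g in c("MZ", "DZ")) {
    Sg <- rbind(cbind(SP, W[[g]]), cbind(W[[g]], SP))
    for (blk in prep$groups[[g]]) {
      S <- Sg[blk$idx, blk$idx, drop = FALSE]
      ch <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(ch)) return(BIG_NLL + sum(theta^2))
      R <- sweep(blk$Y, 2, mu_full[blk$idx])
      z <- backsolve(ch, t(R), transpose = TRUE)
      nll <- nll + blk$n * (length(blk$idx) * log(2 * pi) +
                              2 * sum(log(diag(ch)))) + sum(z^2)
    }
  }
  nll
}

# Moment starts: within/cross-twin covariance blocks by zygosity.
mv_start <- function(pairs_multi, spec, standardize) {
  traits <- spec$traits
  t_n <- length(traits)
  cols1 <- paste0(traits, "_1"); cols2 <- paste0(traits, "_2")
  Y1 <- as.matrix(pairs_multi[, cols1]); Y2 <- as.matrix(pairs_multi[, cols2])
  if (standardize) {
    for (k in seq_len(t_n)) {
      v <- c(Y1[, k], Y2[, k]); mu <- mean(v, na.rm = TRUE); s <- stats::sd(v, na.rm = TRUE)
      Y1[, k] <- (Y1[, k] - mu) / s; Y2[, k] <- (Y2[, k] - mu) / s
    }
  }
  cross <- function(zy) {
    i <- pairs_multi$zygosity == zy
    W <- stats::cov(Y1[i, , drop = FALSE], Y2[i, , drop = FALSE],
                    use = "pairwise.complete.obs")
    (W + t(W)) / 2
  }
  SP <- stats::cov(rbind(Y1, Y2), use = "pairwise.complete.obs")
  Wmz <- cross("MZ"); Wdz <- cross("DZ")
  SA <- 2 * (Wmz - Wdz); SC <- 2 * Wdz - Wmz
  SE <- SP - Wmz
  mask <- function(S, members) {
    keep <- traits %in% members
    S[!keep, ] <- 0; S[, !keep] <- 0
    S
  }
  SA <- mask(SA, spec$A_traits); SC <- mask(SC, spec$C_traits)
  diag(SE) <- pmax(diag(SE), 0.1 * diag(SP))
  mu0 <- colMeans(rbind(Y1, Y2), na.rm = TRUE)
  c(mu0, sym_extract(SA, spec$A_traits, traits),
    sym_extract(SC, spec$C_traits, traits),
    sym_extract(SE, traits, traits))
}

#' Fit a multivariate direct-symmetric twin model by FIML
#'
#' Jointly models several traits per individual across MZ and DZ pairs. The
#' expected within-individual covariance is
#' \code{Sigma_A + Sigma_C + Sigma_E}; the cross-twin block is
#' \code{Sigma_A + Sigma_C} for MZ pairs and \code{0.5 Sigma_A + Sigma_C}
#' for DZ pairs, which implies the cross-twin cross-trait covariances the
#' model exploits. Component matrices are unconstrained symmetric (direct
#' symmetric approach); missing trait values are handled by dropping the
#' corresponding rows of the per-family mean and covariance (FIML).
#'
#' @param pairs_multi wide per-family data.frame: \code{family_id},
#'   \code{zygosity}, and \code{<trait>_1} / \code{<trait>_2} columns.
#' @param spec an [mv_spec()].
#' @param standardize z-scale each trait across all individuals first
#'   (default TRUE, so components are on the correlation-like scale)?
#' @param n_restarts jittered optimizer restarts.
#' @param hessian store the numerical Hessian (needed for delta-method CIs)?
#' @return object of class \code{mv_fit}: \code{Sigma_A}, \code{Sigma_C},
#'   \code{Sigma_E}, \code{means}, \code{m2ll}, \code{npar}, \code{aic},
#'   \code{converged}.
#' @export
fit_multivariate <- function(pairs_multi, spec, standardize = TRUE,
                             n_restarts = 2, hessian = FALSE) {
  stopifnot(inherits(spec, "mv_spec"))
  prep <- mv_prep(pairs_multi, spec$traits, standardize)
  theta0 <- mv_start(pairs_multi, spec, standardize)
  opt <- run_optim(theta0, mv_neg2ll, prep = prep, spec = spec,
                  n_restarts = n_restarts)
  par <- mv_unpack(opt$par, spec)
  H <- NULL
  if (hessian) {
    H <- stats::optimHess(opt$par, mv_neg2ll, prep = prep, spec = spec)
  }
  out <- list(
    spec = spec, traits = spec$traits,
    means = stats::setNames(par$mu, spec$traits),
    Sigma_A = par$Sigma_A, Sigma_C = par$Sigma_C, Sigma_E = par$Sigma_E,
    Sigma_P = par$Sigma_A + par$Sigma_C + par$Sigma_E,
    m2ll = opt$value, npar = mv_npar(spec),
    aic = opt$value + 2 * mv_npar(spec),
    n_obs = prep$n_obs, converged = opt$convergence == 0,
    theta = opt$par, hessian = H, prep = prep
  )
  class(out) <- "mv_fit"
  out
}

#' @export
print.mv_fit <- function(x, ...) {
  cat(sprintf("Multivariate twin model (%d traits, FIML), -2LL = %.3f, npar = %d\n",
              length(x$traits), x$m2ll, x$npar))
  cat("Sigma_A:\n"); print(round(x$Sigma_A, 3))
  cat("Sigma_C:\n"); print(round(x$Sigma_C, 3))
  cat("Sigma_E:\n"); print(round(x$Sigma_E, 3))
  invisible(x)
}

#' Saturated multivariate twin model (unstructured per-zygosity moments)
#'
#' Free mean vector (length 2 x traits) and unstructured covariance matrix
#' per zygosity group, fitted by FIML. The baseline of the multivariate
#' model-comparison chain: e.g. 28 free parameters for two traits, so the
#' full bivariate ACE (11 parameters) is tested on 17 degrees of freedom,
#' and the trivariate ACE (21 parameters) against its saturated model (54)
#' on 33.
#'
#' @inheritParams fit_multivariate
#' @param traits trait stems to include.
#' @return list with \code{m2ll}, \code{npar}, \code{aic}, per-group moments.
#' @export
fit_mv_saturated <- function(pairs_multi, traits, standardize = TRUE) {
  prep <- mv_prep(pairs_multi, traits, standardize)
  t2 <- 2 * length(traits)
  nS <- sym_n(t2)
  unpack <- function(theta) {
    lapply(stats::setNames(1:2, c("MZ", "DZ")), function(i) {
      off <- (i - 1) * (t2 + nS)
      mu <- theta[off + seq_len(t2)]
      S <- sym_fill(theta[off + t2 + seq_len(nS)], seq_len(t2), seq_len(t2))
      list(mu = mu, S = S)
    })
  }
  obj <- function(theta) {
    par <- unpack(theta)
    nll <- 0
    for (g in c("MZ", "DZ")) {
      for (blk in prep$groups[[g]]) {
        S <- par[[g]]$S[blk$idx, blk$idx, drop = FALSE]
        ch <- tryCatch(chol(S), error = function(e) NULL)
        if (is.null(ch)) return(BIG_NLL + sum(theta^2))
        R <- sweep(blk$Y, 2, par[[g]]$mu[blk$idx])
        z <- backsolve(ch, t(R), transpose = TRUE)
        nll <- nll + blk$n * (length(blk$idx) * log(2 * pi) +
                                2 * sum(log(diag(ch)))) + sum(z^2)
      }
    }
    nll
  }
  # moment start per group (complete-pair moments, ridge for safety)
  theta0 <- numeric(0)
  cols1 <- paste0(traits, "_1"); cols2 <- paste0(traits, "_2")
  Y <- as.matrix(pairs_multi[, c(cols1, cols2)])
  if (standardize) {
    for (k in seq_along(traits)) {
      v <- c(Y[, k], Y[, k + length(traits)])
      mu <- mean(v, na.rm = TRUE); s <- stats::sd(v, na.rm = TRUE)
      Y[, k] <- (Y[, k] - mu) / s
      Y[, k + length(traits)] <- (Y[, k + length(traits)] - mu) / s
    }
  }
  for (g in c("MZ", "DZ")) {
    Yg <- Y[pairs_multi$zygosity == g, , drop = FALSE]
    mu0 <- colMeans(Yg, na.rm = TRUE)
    S0 <- stats::cov(Yg, use = "pairwise.complete.obs")
    S0[is.na(S0)] <- 0
    S0 <- S0 + diag(0.05 * mean(diag(S0)), t2)
    theta0 <- c(theta0, mu0, sym_extract(S0, seq_len(t2), seq_len(t2)))
  }
  opt <- run_optim(theta0, obj, n_restarts = 1)
  npar <- length(theta0)
  list(m2ll = opt$value, npar = npar, aic = opt$value + 2 * npar,
       n_obs = prep$n_obs, converged = opt$convergence == 0,
       moments = unpack(opt$par))
}

# Delta-method CI for a scalar function of the mv_fit parameters; the
# parameter covariance is 2 * inverse Hessian of the -2LL surface.
mv_delta_ci <- function(fit, gfun, level = 0.95) {
  if (is.null(fit$hessian)) return(c(NA_real_, NA_real_))
  V <- tryCatch(2 * solve(fit$hessian), error = function(e) NULL)
  if (is.null(V)) return(c(NA_real_, NA_real_))
  th <- fit$theta
  eps <- pmax(1e-5, 1e-5 * abs(th))
  g0 <- gfun(th)
  grad <- vapply(seq_along(th), function(i) {
    tp <- th; tp[i] <- tp[i] + eps[i]
    (gfun(tp) - g0) / eps[i]
  }, numeric(1))
  se <- sqrt(max(drop(t(grad) %*% V %*% grad), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(g0 - z * se, g0 + z * se)
}

#' Bivariate heritability between two traits
#'
#' The share of the phenotypic covariance between two traits accounted for
#' by additive-genetic covariance:
#' \code{h2_b = sigma_Aij / (sigma_Aij + sigma_Cij + sigma_Eij)}. Values
#' outside \code{[0, 1]} are clipped with a flag attribute.
#'
#' @param fit an \code{mv_fit}.
#' @param trait_i,trait_j trait names or indices.
#' @param ci compute a delta-method CI (requires \code{hessian = TRUE} at
#'   fit time)?
#' @param level confidence level.
#' @return the share (with \code{attr(, "clipped")} if it fell outside
#'   \code{[0,1]} and, if requested, \code{attr(, "ci")} with
#'   \code{attr(, "ci_method") = "delta"}).
#' @export
bivariate_heritability <- function(fit, trait_i, trait_j, ci = FALSE, level = 0.95) {
  i <- if (is.character(trait_i)) match(trait_i, fit$traits) else trait_i
  j <- if (is.character(trait_j)) match(trait_j, fit$traits) else trait_j
  tot <- fit$Sigma_A[i, j] + fit$Sigma_C[i, j] + fit$Sigma_E[i, j]
  if (abs(tot) < 1e-12) stop("phenotypic covariance between the traits is zero")
  val <- fit$Sigma_A[i, j] / tot
  out <- min(max(val, 0), 1)
  if (val != out) attr(out, "clipped") <- val
  if (ci) {
    gfun <- function(th) {
      p <- mv_unpack(th, fit$spec)
      p$Sigma_A[i, j] / (p$Sigma_A[i, j] + p$Sigma_C[i, j] + p$Sigma_E[i, j])
    }
    attr(out, "ci") <- mv_delta_ci(fit, gfun, level)
    attr(out, "ci_method") <- "delta"
  }
  out
}

#' Genetic correlation between two traits
#'
#' \code{rhoA = sigma_A1A2 / sqrt(sigma2_A1 * sigma2_A2)}: the correlation
#' between the additive-genetic influences on the two traits. Undefined
#' (error) when either A variance is non-positive.
#'
#' @inheritParams bivariate_heritability
#' @return the correlation (optionally with a delta-method CI attribute).
#' @export
genetic_correlation <- function(fit, trait_i, trait_j, ci = FALSE, level = 0.95) {
  component_correlation(fit, trait_i, trait_j, "Sigma_A", ci, level)
}

#' Environmental correlation between two traits
#'
#' \code{rhoE = sigma_E1E2 / sqrt(sigma2_E1 * sigma2_E2)}.
#'
#' @inheritParams bivariate_heritability
#' @return the correlation (optionally with a delta-method CI attribute).
#' @export
environmental_correlation <- function(fit, trait_i, trait_j, ci = FALSE, level = 0.95) {
  component_correlation(fit, trait_i, trait_j, "Sigma_E", ci, level)
}

component_correlation <- function(fit, trait_i, trait_j, comp, ci, level) {
  i <- if (is.character(trait_i)) match(trait_i, fit$traits) else trait_i
  j <- if (is.character(trait_j)) match(trait_j, fit$traits) else trait_j
  S <- fit[[comp]]
  if (S[i, i] <= 0 || S[j, j] <= 0) {
    stop("non-positive ", comp, " variance: correlation undefined")
  }
  out <- S[i, j] / sqrt(S[i, i] * S[j, j])
  if (ci) {
    gfun <- function(th) {
      p <- mv_unpack(th, fit$spec)
      M <- p[[comp]]
      M[i, j] / sqrt(M[i, i] * M[j, j])
    }
    attr(out, "ci") <- mv_delta_ci(fit, gfun, level)
    attr(out, "ci_method") <- "delta"
  }
  out
}

#' Empirical cross-twin cross-trait correlation matrices
#'
#' Pearson correlation of twin 1's trait i with twin 2's trait j, per
#' zygosity, symmetrized by averaging the two twin orderings (so swapping
#' twin order leaves the result unchanged).
#'
#' @param pairs_multi wide multi-trait pair table (see
#'   [fit_multivariate()]).
#' @param traits trait stems.
#' @param min_pairs minimum complete pairs per zygosity.
#' @return list with one traits x traits matrix per zygosity.
#' @export
cross_twin_cross_trait_correlations <- function(pairs_multi, traits, min_pairs = 20) {
  lapply(stats::setNames(c("MZ", "DZ"), c("MZ", "DZ")), function(g) {
    sub <- pairs_multi[pairs_multi$zygosity == g, ]
    Y1 <- as.matrix(sub[, paste0(traits, "_1")])
    Y2 <- as.matrix(sub[, paste0(traits, "_2")])
    if (sum(stats::complete.cases(cbind(Y1, Y2))) < min_pairs) {
      stop("fewer than ", min_pairs, " complete ", g, " pairs")
    }
    M12 <- stats::cor(Y1, Y2, use = "pairwise.complete.obs")
    M <- (M12 + t(M12)) / 2
    dimnames(M) <- list(traits, traits)
    M
  })
}
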