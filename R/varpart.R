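#' Crossed random-effect variance components of ratings
#'
#' Fits the Gaussian crossed random-intercept model
#' \code{rating ~ 1 + (1|individual) + (1|image) + (1|individual:image) +
#' (1|exposure) + (1|exposure:individual) + (1|exposure:image)} by REML
#' (through \pkg{lme4}), on the ratings of one twin per pair so familial
#' resemblance cannot inflate the individual component. Exposure is the
#' presentation index (first vs second showing). Terms that are not
#' identifiable from the design are dropped with a warning: without any
#' repeated presentation the individual-by-image interaction and all
#' exposure terms are confounded with the residual.
#'
#' @param tab a single-domain \code{ratings_table}, already restricted to
#'   one member per family (use \code{twin_order}); if both members are
#'   present, twin-order-1 members are kept with a message.
#' @param include_exposure include the exposure terms (default: only when
#'   repeats exist)?
#' @return list of class \code{vc_fit}: \code{components} (named variances:
#'   img, ind, img_ind, exp, ind_exp, img_exp, res), \code{vpc} shares,
#'   \code{converged}, \code{messages}, and the underlying \code{lmer} fit.
#' @export
fit_crossed_vc <- function(tab, include_exposure = NULL) {
  if (length(unique(tab$domain)) != 1) stop("fit_crossed_vc expects one domain")
  if (length(unique(tab$twin_order)) > 1) {
    message("both twin orders present; keeping twin_order == 1")
    tab <- tab[tab$twin_order == 1, ]
  }
  has_repeats <- any(tab$presentation == 2)
  if (is.null(include_exposure)) include_exposure <- has_repeats
  msgs <- character(0)
  if (include_exposure && !has_repeats) {
    msgs <- c(msgs, "no repeated presentations: exposure terms dropped")
    include_exposure <- FALSE
  }
  d <- data.frame(rating = tab$rating,
                  ind = factor(tab$individual_id),
                  img = factor(tab$image_id),
                  exposure = factor(tab$presentation))
  if (has_repeats) {
    form <- rating ~ 1 + (1 | ind) + (1 | img) + (1 | ind:img)
    if (include_exposure) {
      form <- stats::update(form, . ~ . + (1 | exposure) + (1 | exposure:ind) +
                              (1 | exposure:img))
    }
  } else {
    msgs <- c(msgs, "no repeats: individual:image interaction merged into residual")
    form <- rating ~ 1 + (1 | ind) + (1 | img)
  }
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            check.nlev.gtreq.5 = "ignore")
  fit <- suppressMessages(lme4::lmer(form, data = d, REML = TRUE, control = ctrl))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v) == 0) 0 else v
  }
  comps <- c(img = get("img"), ind = get("ind"),
             img_ind = get("ind:img"), exp = get("exposure"),
             ind_exp = get("exposure:ind"), img_exp = get("exposure:img"),
             res = get("Residual"))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  if (!conv) msgs <- c(msgs, unlist(fit@optinfo$conv$lme4$messages))
  structure(list(components = comps, vpc = vpc(comps), converged = conv,
                 messages = msgs, fit = fit), class = "vc_fit")
}

#' Variance partitioning coefficients
#'
#' Each component's share of the total rating variance,
#' \code{VPC_e = sigma2_e / sum(sigma2)}. Shares sum to 1 exactly.
#'
#' @param components named nonnegative variances (as from
#'   [fit_crossed_vc()]).
#' @return named shares summing to 1.
#' @export
vpc <- function(components) {
  stopifnot(is.numeric(components), all(is.finite(components)))
  total <- sum(components)
  if (total <= 0) stop("total variance must be positive")
  components / total
}

#' Method-of-moments variance components for a balanced crossed design
#'
#' Classical two-way random-effects ANOVA estimator for a complete balanced
#' individuals x images design with a single presentation: expected mean
#' squares give \code{sigma2_ind = (MSA - MSE)/n_img},
#' \code{sigma2_img = (MSB - MSE)/n_ind}, \code{sigma2_res = MSE} (the
#' interaction is confounded with the residual without repeats). Serves as
#' an independent oracle for the likelihood fit.
#'
#' @param tab a single-domain, single-presentation, complete balanced
#'   \code{ratings_table} (one member per family).
#' @return named variances (ind, img, res), truncated at zero.
#' @export
vc_mom_balanced <- function(tab) {
  d <- data.frame(y = tab$rating, ind = factor(tab$individual_id),
                  img = factor(tab$image_id))
  a <- nlevels(d$ind); b <- nlevels(d$img)
  if (nrow(d) != a * b) stop("design is not complete/balanced")
  ybar <- mean(d$y)
  yi <- tapply(d$y, d$ind, mean)
  yj <- tapply(d$y, d$img, mean)
  ssa <- b * sum((yi - ybar)^2)
  ssb <- a * sum((yj - ybar)^2)
  sse <- sum((d$y - yi[d$ind] - yj[d$img] + ybar)^2)
  msa <- ssa / (a - 1); msb <- ssb / (b - 1); mse <- sse / ((a - 1) * (b - 1))
  c(ind = max(0, (msa - mse) / b), img = max(0, (msb - mse) / a), res = mse)
}
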