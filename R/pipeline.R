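#' Residualize scores on covariates by ordinary least squares
#'
#' Regresses \code{scores} on the supplied covariate matrix (with an
#' intercept) and returns the residuals, which are orthogonal to every
#' covariate. With an empty covariate set this is a centred passthrough.
#' Used by the sensitivity stage: aesthetic metrics are residualized on
#' control-task typicality/bias (plus sex and age) before re-running the
#' twin models.
#'
#' @param scores numeric vector.
#' @param covariates data.frame or matrix of covariates (may be NULL/empty).
#' @return residual scores.
#' @export
residualize <- function(scores, covariates = NULL) {
  stopifnot(is.numeric(scores))
  if (is.null(covariates) || NCOL(covariates) == 0) {
    return(scores - mean(scores, na.rm = TRUE))
  }
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qr_X$pivot[seq_len(qr_X$rank)])]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  ok <- stats::complete.cases(X) & is.finite(scores)
  res <- rep(NA_real_, length(scores))
  res[ok] <- stats::lm.fit(X[ok, , drop = FALSE], scores[ok])$residuals
  res
}

#' Pipeline configuration
#'
#' @param sim_configs named list of [sim_config()] objects, one per domain
#'   to analyse (names are the domain labels).
#' @param r_intra_min intra-individual reliability exclusion threshold.
#' @param iqr_mult metric outlier fence multiplier.
#' @param seed master seed for every random stage.
#' @param sensitivity_loading confound loading for the simulated control
#'   task (NULL skips the sensitivity stage).
#' @param out_dir directory for the JSON report (NULL: in-memory only).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim_configs, r_intra_min = 0.5, iqr_mult = 3,
                            seed = 1L, sensitivity_loading = 0.4,
                            out_dir = NULL) {
  stopifnot(length(sim_configs) >= 1, !is.null(names(sim_configs)))
  structure(list(sim_configs = sim_configs, r_intra_min = r_intra_min,
                 iqr_mult = iqr_mult, seed = as.integer(seed),
                 sensitivity_loading = sensitivity_loading, out_dir = out_dir),
            class = "pipeline_config")
}

# Model-ladder choice: ACE when r_DZ >= r_MZ / 2 (tie -> ACE), else ADE;
# final model = most parsimonious submodel whose LRT against the full
# model does not reject at alpha.
choose_full_model <- function(r_mz, r_dz) {
  if (is.na(r_mz) || is.na(r_dz)) return("ACE")
  if (r_dz >= r_mz / 2) "ACE" else "ADE"
}

run_ladder <- function(pairs, sat, alpha = 0.05) {
  r_mz <- sat$correlations["MZ", "r"]; r_dz <- sat$correlations["DZ", "r"]
  full_name <- choose_full_model(r_mz, r_dz)
  full <- fit_univariate(pairs, full_name)
  subnames <- if (full_name == "ACE") c("AE", "CE", "E") else c("AE", "DE", "E")
  fits <- stats::setNames(lapply(subnames, function(m) fit_univariate(pairs, m)),
                          subnames)
  lrt <- lapply(fits, function(f) compare_models(full, f))
  ok <- vapply(lrt, function(x) x$p >= alpha, logical(1))
  # most parsimonious acceptable submodel; fall back to the full model
  final_name <- if (any(ok)) rev(subnames[ok])[1] else full_name
  list(full_model = full_name, full = full, submodels = fits,
       lrt = do.call(rbind, lrt),
       sat_vs_full = compare_models(sat, full),
       final_model = final_name,
       final = if (final_name == full_name) full else fits[[final_name]])
}

#' Run the full analysis pipeline on simulated twin rating data
#'
#' Sequences the stages end to end for each configured domain: simulate
#' ratings, rating-level QC (zero-sd and low-reliability exclusions),
#' repeat-averaging, aesthetic metrics (pairwise agreement with UR pairs,
#' taste-typicality, evaluation-bias), metric-level 3 x IQR outlier
#' filtering, crossed variance partitioning, the agreement ANOVA (when 2+
#' domains are present), the univariate saturated + model-ladder twin fits
#' per trait, the multivariate twin model across domains (when 2+ domains),
#' and an optional sensitivity stage that residualizes the metrics on
#' simulated control scores and refits the final univariate models.
#'
#' @param config a [pipeline_config()].
#' @return an \code{analysis_report} list; also written as JSON to
#'   \code{out_dir} when configured.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(domains = names(config$sim_configs), stages = list())
  metrics_by_domain <- list()
  agree_by_domain <- list()
  pair_tables <- list()
  log_lines <- character(0)
  log_add <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("{\"stage\": \"%s\", \"message\": \"%s\"}", stage, msg))
  }

  for (dom in names(config$sim_configs)) {
    cfg <- config$sim_configs[[dom]]
    cfg$domain <- dom
    cfg$seed <- config$seed + match(dom, names(config$sim_configs))
    traits <- simulate_twin_traits(cfg)
    ratings <- simulate_ratings(cfg, traits)
    log_add("simulate", sprintf("%s: %d ratings", dom, nrow(ratings)))

    qc <- apply_exclusions(ratings, r_intra_min = config$r_intra_min)
    log_add("qc", sprintf("%s: retained %d of %d individuals", dom,
                          qc$report$counts$retained, qc$report$counts$n_individuals))
    mat <- average_repeats(qc$table)
    metr <- individual_metrics(mat)
    # metric-level outlier fences, per domain
    keep <- metric_outlier_filter(metr$taste_typicality_z, config$iqr_mult) &
      metric_outlier_filter(metr$evaluation_bias, config$iqr_mult)
    keep[is.na(keep)] <- FALSE
    n_out <- sum(!keep)
    metr <- metr[keep, ]
    log_add("metrics", sprintf("%s: %d metric outliers removed", dom, n_out))

    agree <- pair_agreement_table(mat, seed = config$seed)
    agree_keep <- metric_outlier_filter(agree$z_inter, config$iqr_mult)
    agree <- agree[agree_keep, ]
    agree_by_domain[[dom]] <- agree

    vc <- fit_crossed_vc(qc$table[qc$table$twin_order == 1, ])

    dom_out <- list(qc = qc$report$counts, vpc = as.list(vc$vpc),
                    vc_converged = vc$converged, n_pairs_agreement = nrow(agree))
    uni <- list()
    for (trait in c("taste_typicality_z", "evaluation_bias")) {
      mm <- metr; mm$y <- mm[[trait]]
      tp <- traits_to_pairs(mm[, c("family_id", "twin_order", "zygosity",
                                   "sex", "age", "y")], "y")
      sat <- fit_saturated(tp)
      lad <- run_ladder(tp, sat)
      h <- heritability(lad$final)
      uni[[trait]] <- list(
        r_mz = unname(sat$correlations["MZ", "r"]),
        r_dz = unname(sat$correlations["DZ", "r"]),
        full_model = lad$full_model, final_model = lad$final_model,
        h2 = h$h2, shares = as.list(h$shares),
        m2ll = lad$final$m2ll, aic = lad$final$aic,
        sat_vs_full = as.list(lad$sat_vs_full)
      )
      pair_tables[[paste(dom, trait, sep = ".")]] <- tp
    }
    dom_out$univariate <- uni
    metrics_by_domain[[dom]] <- metr
    report$stages[[dom]] <- dom_out
  }

  # agreement ANOVA pooling the per-domain pair records
  if (length(agree_by_domain) >= 1) {
    all_agree <- do.call(rbind, agree_by_domain)
    anova_res <- agreement_anova(all_agree)
    report$agreement_anova <- list(
      eta_p2 = anova_res$eta_p2,
      marginal_r = stats::setNames(anova_res$emmeans_class$r_inter,
                                   anova_res$emmeans_class$pair_class)
    )
  }

  # multivariate model across domains on taste-typicality z
  if (length(metrics_by_domain) >= 2) {
    doms <- names(metrics_by_domain)
    wide <- NULL
    for (dom in doms) {
      mm <- metrics_by_domain[[dom]]
      mm$y <- mm$taste_typicality_z
      tp <- traits_to_pairs(mm[, c("family_id", "twin_order", "zygosity",
                                   "sex", "age", "y")], "y")
      names(tp)[names(tp) %in% c("y1", "y2")] <- paste0(dom, "_", 1:2)
      keep_cols <- c("family_id", "zygosity", paste0(dom, "_", 1:2))
      wide <- if (is.null(wide)) tp[, keep_cols] else
        merge(wide, tp[, keep_cols], by = c("family_id", "zygosity"), all = TRUE)
    }
    mv <- fit_multivariate(wide, mv_spec(doms))
    report$multivariate <- list(
      Sigma_A = mv$Sigma_A, Sigma_C = mv$Sigma_C, Sigma_E = mv$Sigma_E,
      m2ll = mv$m2ll, aic = mv$aic,
      rhoA = tryCatch(genetic_correlation(mv, 1, 2), error = function(e) NA_real_),
      h2_b = tryCatch(bivariate_heritability(mv, 1, 2), error = function(e) NA_real_)
    )
  }

  # sensitivity: residualize on simulated control scores and refit
  if (!is.null(config$sensitivity_loading)) {
    dom <- names(config$sim_configs)[1]
    cfg <- config$sim_configs[[dom]]
    cfg$domain <- dom
    cfg$seed <- config$seed + 1L
    traits <- simulate_twin_traits(cfg)
    ctrl <- simulate_control_scores(traits, config$sensitivity_loading,
                                    seed = config$seed)
    metr <- metrics_by_domain[[dom]]
    idx <- match(metr$individual_id, ctrl$individual_id)
    covs <- data.frame(control_typicality = ctrl$control_typicality[idx],
                       control_bias = ctrl$control_bias[idx],
                       sex = metr$sex, age = metr$age)
    metr$y <- residualize(metr$taste_typicality_z, covs)
    tp <- traits_to_pairs(metr[, c("family_id", "twin_order", "zygosity",
                                   "sex", "age", "y")], "y")
    fit <- fit_univariate(tp, "AE", covariates = character(0))
    report$sensitivity <- list(loading = config$sensitivity_loading,
                               h2_residualized = heritability(fit)$h2)
  }

  report$log <- log_lines
  report$seed <- config$seed
  class(report) <- c("analysis_report", "list")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass_deep(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

# jsonlite chokes on matrices with dimnames inside deeply classed lists;
# flatten conservatively.
unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  if (is.matrix(x)) return(apply(x, 1, function(r) as.list(r), simplify = FALSE))
  x
}
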