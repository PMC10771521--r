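#' Pairwise aesthetic agreement between two raters
#'
#' Pearson correlation of the two individuals' repeat-averaged rating vectors
#' over the images both rated, plus its Fisher z value. A constant rating
#' vector makes the correlation undefined; the pair is returned with NA and a
#' warning so callers can drop it.
#'
#' @param mat a [average_repeats()] rating matrix.
#' @param member1,member2 individual ids (rows of \code{mat}).
#' @param pair_class optional class label (MZ, DZ or UR) carried through.
#' @return one-row data.frame: ids, \code{pair_class}, \code{n_images},
#'   \code{r_inter}, \code{z_inter}.
#' @export
pairwise_agreement <- function(mat, member1, member2, pair_class = NA_character_) {
  x <- mat[member1, ]
  y <- mat[member2, ]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("fewer than 3 shared images for pair ", member1, "/", member2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant rating vector in pair ", member1, "/", member2)
    r <- NA_real_
  } else {
    r <- stats::cor(x, y)
  }
  z <- if (is.na(r)) NA_real_ else suppressWarnings(fisher_z(r))
  data.frame(member1 = member1, member2 = member2, pair_class = pair_class,
             n_images = length(x), r_inter = r, z_inter = z,
             stringsAsFactors = FALSE)
}

#' Construct sex-matched, age-matched unrelated (UR) pairs
#'
#' Pseudo-randomly pairs every second twin member with a first member from a
#' different family of the same sex, choosing matches greedily by nearest
#' age (ties broken by a seed-determined shuffle). Each individual is used in
#' at most one UR pair; leftovers are reported in the \code{unpaired}
#' attribute.
#'
#' @param meta per-individual metadata (\code{individual_id, family_id,
#'   twin_order, sex, age}), e.g. \code{attr(mat, "meta")}.
#' @param seed integer seed making the construction deterministic.
#' @return data.frame of UR pairs (\code{member1} = a twin-order-2 member,
#'   \code{member2} = a twin-order-1 member of another family).
#' @export
make_unrelated_pairs <- function(meta, seed = 1L) {
  set.seed(seed)
  out <- list()
  unpaired <- character(0)
  for (sx in unique(meta$sex)) {
    a <- meta[meta$sex == sx & meta$twin_order == 2, ]
    b <- meta[meta$sex == sx & meta$twin_order == 1, ]
    if (nrow(a) == 0 || nrow(b) == 0) {
      unpaired <- c(unpaired, a$individual_id, b$individual_id)
      next
    }
    a <- a[sample(nrow(a)), ]; a <- a[order(a$age), ]
    b <- b[sample(nrow(b)), ]
    used_b <- rep(FALSE, nrow(b))
    for (i in seq_len(nrow(a))) {
      cand <- which(!used_b & b$family_id != a$family_id[i])
      if (length(cand) == 0) { unpaired <- c(unpaired, a$individual_id[i]); next }
      j <- cand[which.min(abs(b$age[cand] - a$age[i]))]
      used_b[j] <- TRUE
      out[[length(out) + 1]] <- data.frame(
        member1 = a$individual_id[i], member2 = b$individual_id[j],
        sex = sx, age_diff = abs(b$age[j] - a$age[i]), stringsAsFactors = FALSE
      )
    }
    unpaired <- c(unpaired, b$individual_id[!used_b])
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(member1 = character(0), member2 = character(0),
               sex = character(0), age_diff = numeric(0))
  attr(res, "unpaired") <- unpaired
  res
}

#' Agreement records for all MZ, DZ and UR pairs of a rating matrix
#'
#' @param mat a [average_repeats()] rating matrix.
#' @param seed seed for the UR construction.
#' @return data.frame of [pairwise_agreement()] records with a
#'   \code{pair_class} factor (pairs with undefined correlations dropped) and
#'   a \code{domain} column.
#' @export
pair_agreement_table <- function(mat, seed = 1L) {
  meta <- attr(mat, "meta")
  recs <- list()
  for (fam in unique(meta$family_id)) {
    mem <- meta[meta$family_id == fam, ]
    if (nrow(mem) != 2) next
    recs[[length(recs) + 1]] <-
      pairwise_agreement(mat, mem$individual_id[1], mem$individual_id[2],
                         pair_class = mem$zygosity[1])
  }
  ur <- make_unrelated_pairs(meta, seed = seed)
  for (i in seq_len(nrow(ur))) {
    recs[[length(recs) + 1]] <-
      pairwise_agreement(mat, ur$member1[i], ur$member2[i], pair_class = "UR")
  }
  out <- do.call(rbind, recs)
  out <- out[!is.na(out$r_inter), ]
  out$domain <- attr(mat, "domain")
  out
}

#' Taste-typicality (mean-minus-two) of one individual
#'
#' Pearson correlation between the individual's repeat-averaged ratings and
#' the image-wise mean rating over every other individual, excluding the
#' individual and their co-twin (hence "mean minus two"), so familial
#' resemblance cannot leak into the reference.
#'
#' @param mat a [average_repeats()] rating matrix.
#' @param individual individual id.
#' @param cotwin co-twin id to exclude from the reference mean (NULL if the
#'   co-twin is absent from the matrix).
#' @return list with \code{r} (the mm2 correlation) and \code{z} (Fisher z).
#' @export
taste_typicality_mm2 <- function(mat, individual, cotwin = NULL) {
  drop <- c(individual, cotwin)
  others <- setdiff(rownames(mat), drop)
  if (length(others) < 3) stop("need at least 3 individuals outside the family")
  ref <- colMeans(mat[others, , drop = FALSE], na.rm = TRUE)
  x <- mat[individual, ]
  ok <- is.finite(x) & is.finite(ref)
  if (stats::sd(ref[ok]) == 0 || stats::sd(x[ok]) == 0) {
    warning("constant vector: mm2 undefined for ", individual)
    return(list(r = NA_real_, z = NA_real_))
  }
  r <- stats::cor(x[ok], ref[ok])
  list(r = r, z = suppressWarnings(fisher_z(r)))
}

#' Evaluation-bias of one individual
#'
#' The individual's mean repeat-averaged rating across all images of the
#' domain.
#'
#' @param mat a [average_repeats()] rating matrix.
#' @param individual individual id.
#' @return mean rating.
#' @export
evaluation_bias <- function(mat, individual) {
  mean(mat[individual, ], na.rm = TRUE)
}

#' Per-individual metric table (taste-typicality and evaluation-bias)
#'
#' @param mat a [average_repeats()] rating matrix.
#' @return data.frame with metadata, \code{taste_typicality} (r),
#'   \code{taste_typicality_z} and \code{evaluation_bias} per individual.
#' @export
individual_metrics <- function(mat) {
  meta <- attr(mat, "meta")
  res <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$individual_id[i]
    cotwin <- meta$individual_id[meta$family_id == meta$family_id[i] &
                                   meta$individual_id != id]
    if (length(cotwin) == 0) cotwin <- NULL
    tt <- taste_typicality_mm2(mat, id, cotwin)
    data.frame(individual_id = id, taste_typicality = tt$r,
               taste_typicality_z = tt$z,
               evaluation_bias = evaluation_bias(mat, id),
               stringsAsFactors = FALSE)
  })
  out <- merge(meta, do.call(rbind, res), by = "individual_id", sort = FALSE)
  out$domain <- attr(mat, "domain")
  out
}

#' Principal axes of the rating matrix
#'
#' Singular value decomposition of the unscaled, image-centred rating matrix
#' (one member per pair, to avoid familial confounding). For
#' interpretability the first axis is flipped so its scores correlate
#' positively with evaluation-bias, and the second so its scores correlate
#' positively with taste-typicality (Fisher z), whenever those metrics are
#' available.
#'
#' @param mat a [average_repeats()] rating matrix.
#' @param first_members_only restrict to twin-order-1 individuals?
#' @return list with \code{scores}, \code{loadings}, \code{var_explained}
#'   (shares of total variance) and the metric table used for sign fixing.
#' @export
principal_axes <- function(mat, first_members_only = TRUE) {
  meta <- attr(mat, "meta")
  if (first_members_only) {
    keep <- meta$individual_id[meta$twin_order == 1]
    sub <- mat[rownames(mat) %in% keep, , drop = FALSE]
  } else {
    sub <- mat
  }
  if (nrow(sub) < 3) stop("need at least 3 individuals for principal axes")
  metr <- individual_metrics(mat)
  metr <- metr[match(rownames(sub), metr$individual_id), ]
  pc <- stats::prcomp(sub, center = TRUE, scale. = FALSE)
  scores <- pc$x
  loadings <- pc$rotation
  flip_to <- function(k, target) {
    if (k > ncol(scores) || all(is.na(target))) return()
    r <- suppressWarnings(stats::cor(scores[, k], target, use = "complete.obs"))
    if (is.finite(r) && r < 0) {
      scores[, k] <<- -scores[, k]
      loadings[, k] <<- -loadings[, k]
    }
  }
  flip_to(1, metr$evaluation_bias)
  flip_to(2, metr$taste_typicality_z)
  list(scores = scores, loadings = loadings,
       var_explained = pc$sdev^2 / sum(pc$sdev^2),
       metrics = metr)
}

# Partial eta squared CI by inverting the noncentral-F distribution.
partial_eta_sq_ci <- function(Fval, df1, df2, level = 0.95) {
  alpha <- 1 - level
  lims <- vapply(c(1 - alpha / 2, alpha / 2), function(p) {
    if (stats::pf(Fval, df1, df2, ncp = 0) < p) return(0)
    stats::uniroot(function(ncp) stats::pf(Fval, df1, df2, ncp = ncp) - p,
                   interval = c(0, 1e6), tol = 1e-8)$root
  }, numeric(1))
  lims / (lims + df1 + df2 + 1)
}

#' Pair-class by domain ANOVA on Fisher-z agreement
#'
#' Type III two-way ANOVA (sum-to-zero contrasts) of \code{z_inter} on pair
#' class (MZ/DZ/UR) and visual domain, with partial eta squared and its CI
#' for each term, estimated marginal means per class/domain (back-transformed
#' to r for reporting), Bonferroni-adjusted pairwise contrasts (multipliers:
#' 3 class, 3 domain, 9 class-within-domain) and Cohen's d for the class
#' contrasts.
#'
#' @param pairs data.frame with \code{z_inter}, \code{pair_class},
#'   \code{domain}.
#' @param level confidence level for effect-size CIs.
#' @return list with \code{anova} (type III table), \code{eta_p2},
#'   \code{emmeans_class}, \code{emmeans_domain}, \code{contrasts_class},
#'   \code{contrasts_domain}, \code{contrasts_class_by_domain},
#'   \code{cohens_d}, and the fitted \code{lm}.
#' @export
agreement_anova <- function(pairs, level = 0.95) {
  stopifnot(all(c("z_inter", "pair_class", "domain") %in% names(pairs)))
  pairs$pair_class <- factor(pairs$pair_class)
  pairs$domain <- factor(pairs$domain)
  if (any(table(pairs$pair_class, pairs$domain) == 0)) {
    stop("empty cell(s) in the pair-class by domain design")
  }
  single_domain <- nlevels(pairs$domain) < 2
  form <- if (single_domain) z_inter ~ pair_class else z_inter ~ pair_class * domain
  fit <- stats::lm(form, data = pairs,
                   contrasts = if (single_domain) list(pair_class = "contr.sum")
                               else list(pair_class = "contr.sum", domain = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  terms <- setdiff(rownames(a3), c("(Intercept)", "Residuals"))
  df_res <- a3["Residuals", "Df"]
  eta <- do.call(rbind, lapply(terms, function(tr) {
    Fv <- a3[tr, "F value"]
    d1 <- a3[tr, "Df"]
    ci <- partial_eta_sq_ci(Fv, d1, df_res, level)
    data.frame(term = tr, F = Fv, df1 = d1, df2 = df_res,
               eta_p2 = a3[tr, "Sum Sq"] / (a3[tr, "Sum Sq"] + a3["Residuals", "Sum Sq"]),
               lower = ci[1], upper = ci[2], stringsAsFactors = FALSE)
  }))
  # emmeans notes that class marginal means average over the interaction;
  # that averaging is exactly the reported quantity, so keep the output quiet
  em_class <- suppressMessages(emmeans::emmeans(fit, "pair_class"))
  ct_class <- summary(emmeans::contrast(em_class, "pairwise", adjust = "bonferroni"))
  em_class_df <- as.data.frame(em_class)
  em_class_df$r_inter <- fisher_z_inverse(em_class_df$emmean)
  sdp <- stats::sigma(fit)
  ct_class$cohens_d <- ct_class$estimate / sdp
  out <- list(anova = a3, eta_p2 = eta,
              emmeans_class = em_class_df,
              contrasts_class = ct_class, sigma = sdp, fit = fit)
  if (!single_domain) {
    em_dom <- suppressMessages(emmeans::emmeans(fit, "domain"))
    em_cbd <- suppressMessages(emmeans::emmeans(fit, "pair_class", by = "domain"))
    # rbind pools the 3 x 3 = 9 class-within-domain contrasts into one
    # Bonferroni family, matching the stated multiplier of 9
    ct_cbd <- summary(rbind(emmeans::contrast(em_cbd, "pairwise", by = "domain")),
                      adjust = "bonferroni")
    out$emmeans_domain <- as.data.frame(em_dom)
    out$contrasts_domain <- summary(emmeans::contrast(em_dom, "pairwise",
                                                      adjust = "bonferroni"))
    out$contrasts_class_by_domain <- ct_cbd
  }
  out
}
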