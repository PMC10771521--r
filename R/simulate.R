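#' Simulation configuration for twin-structured rating data
#'
#' Builds the full generative specification used by [simulate_twin_traits()]
#' and [simulate_ratings()]. Two latent per-individual traits drive the
#' rating layer: a taste-typicality weight (how strongly an individual tracks
#' the shared image values) and an evaluation bias (the individual's offset
#' on the rating scale). Each trait decomposes into additive-genetic (A),
#' shared-environment (C), dominance (D) and unique-environment (E) parts,
#' supplied either as per-trait variance vectors or as full cross-trait
#' covariance matrices.
#'
#' The rating layer then adds, per individual x image x presentation:
#' a grand mean, a shared image value, the individual's bias, the
#' typicality-weighted image value, an individual-by-image idiosyncrasy, an
#' exposure (presentation) effect and residual noise. The layers are additive
#' before any clipping, so with \code{clip = FALSE} the crossed variance
#' components of the generated ratings match the configured values exactly
#' in expectation.
#'
#' @param n_mz_pairs,n_dz_pairs numbers of monozygotic / dizygotic pairs.
#' @param n_images number of distinct images per domain.
#' @param n_repeats how many images are presented twice (\code{<= n_images}).
#' @param traits names of the latent traits; defaults to the two phenotypes
#'   the rating layer consumes.
#' @param Sigma_A,Sigma_C,Sigma_D,Sigma_E trait covariance matrices (or
#'   scalars/vectors recycled onto the diagonal). Must be symmetric PSD.
#' @param grand_mean grand mean of the rating scale.
#' @param image_sd sd of the shared per-image values (rating units).
#' @param taste_sd sd of the individual-by-image idiosyncrasy.
#' @param exposure_sd sd of the presentation (exposure) effect.
#' @param exposure_ind_sd,exposure_img_sd sds of the exposure-by-individual
#'   and exposure-by-image interactions (default 0).
#' @param residual_sd sd of the per-presentation residual.
#' @param typicality_scale multiplier mapping the latent typicality trait to
#'   the individual's extra weight on the shared image values.
#' @param bias_scale multiplier mapping the latent bias trait to the
#'   individual's rating offset.
#' @param rating_scale length-2 bounds of the rating scale.
#' @param clip clip generated ratings to \code{rating_scale}? Kept off for
#'   model-validation runs because clipping distorts variances.
#' @param round round ratings to integers (Likert emulation)?
#' @param sex_ratio proportion of female (same-sex) pairs.
#' @param age_range pair ages are drawn uniformly in this range (years).
#' @param domain domain label attached to generated ratings.
#' @param seed integer seed; every downstream draw is derived from it.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_mz_pairs = 560, n_dz_pairs = 215,
                       n_images = 65, n_repeats = 15,
                       traits = c("typicality", "bias"),
                       Sigma_A = diag(c(0.36, 0.30)),
                       Sigma_C = diag(c(0, 0)),
                       Sigma_D = diag(c(0, 0)),
                       Sigma_E = diag(c(0.64, 0.70)),
                       grand_mean = 4,
                       image_sd = 0.8,
                       taste_sd = 0.7,
                       exposure_sd = 0.05,
                       exposure_ind_sd = 0,
                       exposure_img_sd = 0,
                       residual_sd = 0.6,
                       typicality_scale = 0.45,
                       bias_scale = 0.8,
                       rating_scale = c(1, 7),
                       clip = FALSE,
                       round = FALSE,
                       sex_ratio = 0.76,
                       age_range = c(21, 68),
                       domain = "scenes",
                       seed = 1L) {
  k <- length(traits)
  as_cov <- function(x, name) {
    if (is.matrix(x)) m <- x else m <- diag(rep_len(as.numeric(x), k), nrow = k)
    if (!all(dim(m) == c(k, k))) stop(sprintf("%s must be %d x %d", name, k, k))
    dimnames(m) <- list(traits, traits)
    check_psd(m, name)
    m
  }
  cfg <- list(
    n_mz_pairs = as.integer(n_mz_pairs), n_dz_pairs = as.integer(n_dz_pairs),
    n_images = as.integer(n_images), n_repeats = as.integer(n_repeats),
    traits = traits,
    Sigma_A = as_cov(Sigma_A, "Sigma_A"), Sigma_C = as_cov(Sigma_C, "Sigma_C"),
    Sigma_D = as_cov(Sigma_D, "Sigma_D"), Sigma_E = as_cov(Sigma_E, "Sigma_E"),
    grand_mean = grand_mean, image_sd = image_sd, taste_sd = taste_sd,
    exposure_sd = exposure_sd, exposure_ind_sd = exposure_ind_sd,
    exposure_img_sd = exposure_img_sd, residual_sd = residual_sd,
    typicality_scale = typicality_scale, bias_scale = bias_scale,
    rating_scale = rating_scale, clip = isTRUE(clip), round = isTRUE(round),
    sex_ratio = sex_ratio, age_range = age_range, domain = domain,
    seed = as.integer(seed)
  )
  if (cfg$n_repeats > cfg$n_images) stop("n_repeats must be <= n_images")
  if (rating_scale[1] >= rating_scale[2]) stop("rating_scale lower bound must be < upper")
  tot <- diag(cfg$Sigma_A) + diag(cfg$Sigma_C) + diag(cfg$Sigma_D) + diag(cfg$Sigma_E)
  if (any(tot <= 0)) stop("each trait needs total variance A+C+D+E > 0")
  both_cd <- diag(cfg$Sigma_C) > 0 & diag(cfg$Sigma_D) > 0
  if (any(both_cd)) {
    warning("C and D both positive for trait(s) ", paste(traits[both_cd], collapse = ", "),
            ": the classical twin design cannot identify both")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Twin rating simulation: %d MZ + %d DZ pairs, %d images (%d repeated), domain '%s'\n",
              x$n_mz_pairs, x$n_dz_pairs, x$n_images, x$n_repeats, x$domain))
  cat("traits:", paste(x$traits, collapse = ", "), "\n")
  for (nm in c("Sigma_A", "Sigma_C", "Sigma_D", "Sigma_E")) {
    cat(nm, "diag:", paste(signif(diag(x[[nm]]), 3), collapse = ", "), "\n")
  }
  invisible(x)
}

# Draw n rows from N(0, Sigma), robust to singular Sigma.
rmvn <- function(n, Sigma) {
  k <- ncol(Sigma)
  if (n == 0) return(matrix(numeric(0), 0, k))
  if (all(Sigma == 0)) return(matrix(0, n, k))
  MASS::mvrnorm(n, mu = rep(0, k), Sigma = Sigma)
}

#' Simulate latent twin traits with known A/C/D/E structure
#'
#' Draws per-individual latent trait vectors for MZ and DZ same-sex pairs.
#' MZ co-twins share identical additive-genetic (and dominance) draws; DZ
#' co-twins' additive draws correlate 0.5 and dominance draws 0.25; the
#' shared-environment draw is common to a family regardless of zygosity and
#' the unique-environment draw is independent per individual. Expected
#' co-twin covariance is therefore \code{Sigma_A + Sigma_C + Sigma_D} for MZ
#' and \code{0.5 Sigma_A + Sigma_C + 0.25 Sigma_D} for DZ, and each
#' individual's total trait covariance is the sum of all four components.
#'
#' @param config a [sim_config()].
#' @return a data.frame of class \code{twin_traits}: one row per individual
#'   with \code{family_id}, \code{individual_id}, \code{twin_order},
#'   \code{zygosity}, \code{sex}, \code{age} and one column per trait.
#' @export
simulate_twin_traits <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_fam <- config$n_mz_pairs + config$n_dz_pairs
  zyg <- rep(c("MZ", "DZ"), c(config$n_mz_pairs, config$n_dz_pairs))
  traits <- config$traits
  k <- length(traits)

  draw_pair_component <- function(Sigma, rho_shared) {
    # shared part with covariance rho*Sigma plus independent (1-rho)*Sigma
    shared <- rmvn(n_fam, rho_shared * Sigma)
    list(t1 = shared + rmvn(n_fam, (1 - rho_shared) * Sigma),
         t2 = shared + rmvn(n_fam, (1 - rho_shared) * Sigma))
  }
  mz <- zyg == "MZ"
  # A: identical for MZ, correlation 0.5 for DZ
  A_mz <- rmvn(sum(mz), config$Sigma_A)
  A1 <- A2 <- matrix(0, n_fam, k)
  A1[mz, ] <- A_mz; A2[mz, ] <- A_mz
  A_dz <- draw_pair_component(config$Sigma_A, 0.5)
  A1[!mz, ] <- A_dz$t1[!mz, , drop = FALSE]
  A2[!mz, ] <- A_dz$t2[!mz, , drop = FALSE]
  # D: identical for MZ, correlation 0.25 for DZ
  D_mz <- rmvn(sum(mz), config$Sigma_D)
  D1 <- D2 <- matrix(0, n_fam, k)
  D1[mz, ] <- D_mz; D2[mz, ] <- D_mz
  D_dz <- draw_pair_component(config$Sigma_D, 0.25)
  D1[!mz, ] <- D_dz$t1[!mz, , drop = FALSE]
  D2[!mz, ] <- D_dz$t2[!mz, , drop = FALSE]
  # C shared within family; E independent
  Cc <- rmvn(n_fam, config$Sigma_C)
  E1 <- rmvn(n_fam, config$Sigma_E)
  E2 <- rmvn(n_fam, config$Sigma_E)

  y1 <- A1 + Cc + D1 + E1
  y2 <- A2 + Cc + D2 + E2
  sex <- ifelse(stats::runif(n_fam) < config$sex_ratio, "F", "M")
  age <- round(stats::runif(n_fam, config$age_range[1], config$age_range[2]))

  fam <- sprintf("fam%04d", seq_len(n_fam))
  out <- data.frame(
    family_id = rep(fam, each = 2),
    individual_id = paste0(rep(fam, each = 2), "_", rep(1:2, n_fam)),
    twin_order = rep(1:2, n_fam),
    zygosity = rep(zyg, each = 2),
    sex = rep(sex, each = 2),
    age = rep(age, each = 2),
    stringsAsFactors = FALSE
  )
  vals <- matrix(NA_real_, 2 * n_fam, k)
  vals[out$twin_order == 1, ] <- y1
  vals[out$twin_order == 2, ] <- y2
  colnames(vals) <- traits
  out <- cbind(out, as.data.frame(vals))
  class(out) <- c("twin_traits", "data.frame")
  out
}

#' Simulate a long-format rating table from latent twin traits
#'
#' Each rating is \code{grand_mean + image value + bias + typicality-weighted
#' image value + individual-by-image idiosyncrasy + exposure effect +
#' residual}, optionally clipped/rounded to the rating scale. The bias term
#' is \code{bias_scale} times the individual's latent bias trait and the
#' extra image weight is \code{typicality_scale} times the latent typicality
#' trait, so the downstream evaluation-bias and taste-typicality metrics
#' inherit the configured A/C/D/E structure.
#'
#' @param config the [sim_config()] the traits were generated from.
#' @param traits output of [simulate_twin_traits()] (regenerated from
#'   \code{config} when omitted).
#' @return a long-format \code{ratings_table} data.frame with columns
#'   \code{family_id, individual_id, twin_order, zygosity, sex, age, domain,
#'   image_id, presentation, rating}.
#' @export
simulate_ratings <- function(config, traits = simulate_twin_traits(config)) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(traits) != 2L * (config$n_mz_pairs + config$n_dz_pairs)) {
    stop("traits/config mismatch: wrong number of individuals")
  }
  need <- c("typicality", "bias")
  if (!all(need %in% names(traits))) {
    stop("traits must contain 'typicality' and 'bias' columns")
  }
  set.seed(config$seed + 1L)
  n_ind <- nrow(traits)
  n_img <- config$n_images
  img_ids <- sprintf("img%03d", seq_len(n_img))
  v_img <- stats::rnorm(n_img, 0, config$image_sd)
  w_ind <- 1 + config$typicality_scale * traits$typicality
  b_ind <- config$bias_scale * traits$bias
  idio <- matrix(stats::rnorm(n_ind * n_img, 0, config$taste_sd), n_ind, n_img)
  e_exp <- stats::rnorm(2, 0, config$exposure_sd)
  e_exp_ind <- matrix(stats::rnorm(n_ind * 2, 0, config$exposure_ind_sd), n_ind, 2)
  e_exp_img <- matrix(stats::rnorm(n_img * 2, 0, config$exposure_img_sd), n_img, 2)

  pres_of_img <- c(rep(2L, config$n_repeats), rep(1L, n_img - config$n_repeats))
  rows_per_ind <- sum(pres_of_img)
  img_idx <- rep(seq_len(n_img), pres_of_img)
  pres_idx <- unlist(lapply(pres_of_img, seq_len), use.names = FALSE)

  ind_idx <- rep(seq_len(n_ind), each = rows_per_ind)
  ii <- rep(img_idx, n_ind)
  pp <- rep(pres_idx, n_ind)
  mu <- config$grand_mean + v_img[ii] * w_ind[ind_idx] + b_ind[ind_idx] +
    idio[cbind(ind_idx, ii)] + e_exp[pp] +
    e_exp_ind[cbind(ind_idx, pp)] + e_exp_img[cbind(ii, pp)]
  rating <- mu + stats::rnorm(length(mu), 0, config$residual_sd)
  if (config$round) rating <- round(rating)
  if (config$clip) {
    rating <- pmin(pmax(rating, config$rating_scale[1]), config$rating_scale[2])
  }

  out <- data.frame(
    family_id = traits$family_id[ind_idx],
    individual_id = traits$individual_id[ind_idx],
    twin_order = traits$twin_order[ind_idx],
    zygosity = traits$zygosity[ind_idx],
    sex = traits$sex[ind_idx],
    age = traits$age[ind_idx],
    domain = config$domain,
    image_id = img_ids[ii],
    presentation = pp,
    rating = rating,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ratings_table", "data.frame")
  out
}

#' Simulate control-task typicality and bias scores
#'
#' Generates per-individual control scores (e.g., typicality and bias from a
#' non-aesthetic rating task) that correlate with the corresponding latent
#' aesthetic traits at a configured loading, with an independent residual
#' part. Used to exercise the sensitivity (residualisation) stage with a
#' known confound strength.
#'
#' @param traits output of [simulate_twin_traits()].
#' @param confound_loading target correlation with the aesthetic traits, in
#'   \code{[0, 1]}.
#' @param seed integer seed.
#' @return data.frame with \code{individual_id}, \code{control_typicality},
#'   \code{control_bias}.
#' @export
simulate_control_scores <- function(traits, confound_loading, seed = 1L) {
  if (!is.numeric(confound_loading) || confound_loading < 0 || confound_loading > 1) {
    stop("confound_loading must be in [0, 1]")
  }
  stopifnot(all(c("typicality", "bias") %in% names(traits)))
  set.seed(seed)
  n <- nrow(traits)
  lam <- confound_loading
  mk <- function(x) {
    z <- as.numeric(scale(x))
    lam * z + sqrt(1 - lam^2) * stats::rnorm(n)
  }
  data.frame(
    individual_id = traits$individual_id,
    control_typicality = mk(traits$typicality),
    control_bias = mk(traits$bias),
    stringsAsFactors = FALSE
  )
}

#' Reshape latent traits (or individual metrics) to a twin-pair table
#'
#' @param traits a data.frame with \code{family_id, twin_order, zygosity,
#'   sex, age} and the column named by \code{trait}.
#' @param trait name of the trait column to widen.
#' @return a \code{twin_pairs} data.frame: \code{family_id, zygosity, sex,
#'   age1, age2, y1, y2} (one row per family; missing members give NA).
#' @export
traits_to_pairs <- function(traits, trait) {
  stopifnot(trait %in% names(traits))
  fams <- unique(traits$family_id)
  o1 <- traits[traits$twin_order == 1, ]
  o2 <- traits[traits$twin_order == 2, ]
  i1 <- match(fams, o1$family_id)
  i2 <- match(fams, o2$family_id)
  out <- data.frame(
    family_id = fams,
    zygosity = ifelse(!is.na(i1), o1$zygosity[i1], o2$zygosity[i2]),
    sex = ifelse(!is.na(i1), o1$sex[i1], o2$sex[i2]),
    age1 = o1$age[i1],
    age2 = o2$age[i2],
    y1 = o1[[trait]][i1],
    y2 = o2[[trait]][i2],
    stringsAsFactors = FALSE
  )
  class(out) <- c("twin_pairs", "data.frame")
  out
}

#' Write a simulated ratings table plus its ground-truth sidecar
#'
#' Writes the long-format CSV consumed by [read_ratings()] and a JSON file
#' recording the full generative configuration (all variances and the seed),
#' so oracle tests can compare recovered quantities against the truth.
#'
#' @param config the [sim_config()] used.
#' @param ratings output of [simulate_ratings()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(config, ratings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "ratings.csv")
  truth <- file.path(dir, "ground_truth.json")
  utils::write.csv(as.data.frame(ratings), csv, row.names = FALSE)
  cfg <- unclass(config)
  cfg$Sigma_A <- as.data.frame(cfg$Sigma_A); cfg$Sigma_C <- as.data.frame(cfg$Sigma_C)
  cfg$Sigma_D <- as.data.frame(cfg$Sigma_D); cfg$Sigma_E <- as.data.frame(cfg$Sigma_E)
  jsonlite::write_json(cfg, truth, auto_unbox = TRUE, digits = NA)
  invisible(c(ratings = csv, ground_truth = truth))
}
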