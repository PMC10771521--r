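test_that("pairwise agreement equals the brute-force Pearson formula", {
  tab <- make_ratings_fixture(n_ind = 6, n_img = 10, n_rep = 0, seed = 3)
  m <- average_repeats(tab)
  rec <- pairwise_agreement(m, "ind01", "ind02")
  expect_equal(rec$r_inter, pearson_brute(m["ind01", ], m["ind02", ]),
               tolerance = 1e-12)
  expect_equal(rec$z_inter, atanh(rec$r_inter), tolerance = 1e-12)
  # anti-correlated vectors
  m2 <- m
  m2["ind02", ] <- -m2["ind01", ]
  expect_equal(pairwise_agreement(m2, "ind01", "ind02")$r_inter, -1)
  # identical vectors clip for the z transform
  m2["ind02", ] <- m2["ind01", ]
  rec2 <- suppressWarnings(pairwise_agreement(m2, "ind01", "ind02"))
  expect_equal(rec2$r_inter, 1)
  expect_true(is.finite(rec2$z_inter))
})

test_that("unrelated pairs are sex-matched, cross-family and deterministic", {
  cfg <- sim_config(n_mz_pairs = 25, n_dz_pairs = 25, n_images = 5,
                    n_repeats = 0, seed = 14)
  tr <- simulate_twin_traits(cfg)
  meta <- tr[, c("individual_id", "family_id", "twin_order", "sex", "age")]
  ur <- make_unrelated_pairs(meta, seed = 2)
  expect_identical(ur, make_unrelated_pairs(meta, seed = 2))
  fam <- function(id) meta$family_id[match(id, meta$individual_id)]
  sex <- function(id) meta$sex[match(id, meta$individual_id)]
  expect_true(all(fam(ur$member1) != fam(ur$member2)))
  expect_true(all(sex(ur$member1) == sex(ur$member2)))
  ids <- c(ur$member1, ur$member2)
  expect_equal(anyDuplicated(ids), 0)
  expect_true(all(meta$twin_order[match(ur$member1, meta$individual_id)] == 2))
  expect_true(all(meta$twin_order[match(ur$member2, meta$individual_id)] == 1))
})

test_that("greedy age matching attains the optimal total on separated-age fixtures", {
  meta <- data.frame(
    individual_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    family_id = c("f1", "f2", "f3", "f4", "f5", "f6"),
    twin_order = c(2, 2, 2, 1, 1, 1),
    sex = "F",
    age = c(20, 30, 40, 41, 29, 21),
    stringsAsFactors = FALSE
  )
  ur <- make_unrelated_pairs(meta, seed = 1)
  # brute force over all assignments
  best <- Inf
  for (p in combinat_perms(3)) {
    tot <- sum(abs(meta$age[1:3] - meta$age[3 + p]))
    best <- min(best, tot)
  }
  expect_equal(sum(ur$age_diff), best)
})

test_that("odd-one-out individuals are reported unpaired", {
  meta <- data.frame(individual_id = c("m2", "m1", "f2"),
                     family_id = c("f1", "f2", "f3"),
                     twin_order = c(2, 1, 2),
                     sex = c("M", "M", "F"), age = c(30, 31, 40),
                     stringsAsFactors = FALSE)
  ur <- make_unrelated_pairs(meta, seed = 1)
  expect_equal(nrow(ur), 1)
  expect_true("f2" %in% attr(ur, "unpaired"))
})

test_that("mm2 equals the brute-force leave-two-out computation", {
  tab <- make_ratings_fixture(n_ind = 6, n_img = 8, n_rep = 0, seed = 31)
  m <- average_repeats(tab)
  # ind01's co-twin is ind02 (same family)
  got <- taste_typicality_mm2(m, "ind01", "ind02")
  ref <- colMeans(m[setdiff(rownames(m), c("ind01", "ind02")), ])
  expect_equal(got$r, pearson_brute(m["ind01", ], ref), tolerance = 1e-12)
  expect_equal(got$z, atanh(got$r), tolerance = 1e-12)
  # an individual whose ratings equal the leave-two-out mean exactly
  m2 <- m
  m2["ind01", ] <- ref
  expect_equal(suppressWarnings(taste_typicality_mm2(m2, "ind01", "ind02")$r), 1)
})

test_that("metric invariances: shift moves bias exactly, leaves mm2 and agreement", {
  tab <- make_ratings_fixture(n_ind = 6, n_img = 8, n_rep = 0, seed = 32)
  m <- average_repeats(tab)
  shifted <- m
  shifted["ind03", ] <- shifted["ind03", ] + 2.5
  expect_equal(taste_typicality_mm2(shifted, "ind03", "ind04")$r,
               taste_typicality_mm2(m, "ind03", "ind04")$r, tolerance = 1e-12)
  expect_equal(pairwise_agreement(shifted, "ind03", "ind04")$r_inter,
               pairwise_agreement(m, "ind03", "ind04")$r_inter, tolerance = 1e-12)
  expect_equal(evaluation_bias(shifted, "ind03"),
               evaluation_bias(m, "ind03") + 2.5, tolerance = 1e-12)
  # evaluation bias is the arithmetic row mean
  expect_equal(evaluation_bias(m, "ind05"), mean(m["ind05", ]), tolerance = 1e-15)
})

test_that("metrics correlate with the latent traits they are built to capture", {
  cfg <- sim_config(n_mz_pairs = 150, n_dz_pairs = 60, n_images = 40,
                    n_repeats = 0, seed = 15)
  mat <- average_repeats(simulate_ratings(cfg))
  metr <- individual_metrics(mat)
  tr <- simulate_twin_traits(cfg)
  idx <- match(metr$individual_id, tr$individual_id)
  expect_gt(cor(metr$evaluation_bias, tr$bias[idx]), 0.9)
  expect_gt(cor(metr$taste_typicality_z, tr$typicality[idx]), 0.6)
})

test_that("principal axes: rank-1 bias structure loads fully on axis 1", {
  # pure bias differences: every row is a constant offset of the same profile
  base <- seq(1, 5, length.out = 10)
  m <- do.call(rbind, lapply(1:6, function(i) base + i))
  rownames(m) <- sprintf("ind%02d", 1:6)
  colnames(m) <- sprintf("img%02d", 1:10)
  meta <- data.frame(individual_id = rownames(m),
                     family_id = sprintf("fam%02d", rep(1:3, each = 2)),
                     twin_order = rep(1:2, 3), zygosity = "MZ", sex = "F",
                     age = 30, stringsAsFactors = FALSE)
  mat <- structure(m, meta = meta, domain = "scenes",
                   class = c("rating_matrix", "matrix"))
  pa <- suppressWarnings(principal_axes(mat, first_members_only = FALSE))
  expect_equal(pa$var_explained[1], 1, tolerance = 1e-10)
  # orthogonality of scores on a generic matrix
  tab <- make_ratings_fixture(n_ind = 8, n_img = 10, n_rep = 0, seed = 44)
  pa2 <- principal_axes(average_repeats(tab), first_members_only = FALSE)
  expect_lt(abs(sum(pa2$scores[, 1] * pa2$scores[, 2])), 1e-8)
  # sign convention: axis 1 correlates positively with evaluation bias
  expect_gte(cor(pa2$scores[, 1], pa2$metrics$evaluation_bias), 0)
})

test_that("agreement ANOVA: flat means give F ~ 0; balanced type III = type I", {
  set.seed(5)
  n <- 40
  d <- data.frame(
    z_inter = rnorm(3 * 3 * n, mean = 0.6, sd = 0.2),
    pair_class = rep(c("MZ", "DZ", "UR"), each = 3 * n),
    domain = rep(rep(c("abstract", "scenes", "faces"), each = n), 3)
  )
  res <- agreement_anova(d)
  Fclass <- res$eta_p2$F[res$eta_p2$term == "pair_class"]
  expect_lt(Fclass, 3)
  expect_lt(res$eta_p2$eta_p2[res$eta_p2$term == "pair_class"], 0.02)
  # balanced design: type III sums of squares equal sequential (type I)
  fit1 <- stats::aov(z_inter ~ pair_class * domain, data = d)
  ss1 <- summary(fit1)[[1]][["Sum Sq"]]
  ss3 <- res$anova[c("pair_class", "domain", "pair_class:domain"), "Sum Sq"]
  expect_equal(unname(ss3), unname(ss1[1:3]), tolerance = 1e-8)
})

test_that("one-way reduction of the ANOVA matches hand-computed sums of squares", {
  d <- data.frame(z_inter = c(1, 2, 3, 2, 3, 4, 5, 6, 7),
                  pair_class = rep(c("UR", "DZ", "MZ"), each = 3),
                  domain = "scenes")
  res <- agreement_anova(d)
  # closed-form one-way ANOVA
  groups <- split(d$z_inter, d$pair_class)
  gm <- mean(d$z_inter)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  Fhand <- (ssb / 2) / (ssw / 6)
  expect_equal(res$eta_p2$F[1], Fhand, tolerance = 1e-10)
  # marginal means are computed on z and reported back-transformed to r
  mz_mean <- mean(groups$MZ)
  got <- res$emmeans_class$r_inter[res$emmeans_class$pair_class == "MZ"]
  expect_equal(got, tanh(mz_mean), tolerance = 1e-10)
})

test_that("MZ > DZ > UR agreement ordering emerges when traits are heritable", {
  cfg <- sim_config(n_mz_pairs = 600, n_dz_pairs = 600, n_images = 40,
                    n_repeats = 0, taste_sd = 0.45, seed = 16)
  mat <- average_repeats(simulate_ratings(cfg))
  agree <- pair_agreement_table(mat, seed = 3)
  mns <- tapply(agree$z_inter, agree$pair_class, mean)
  expect_gt(mns["MZ"], mns["DZ"])
  expect_gt(mns["DZ"], mns["UR"])
})
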