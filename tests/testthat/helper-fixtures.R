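# Shared fixture builders: everything is generated in code at test time.

# Absolute-tolerance closeness check (expect_equal's tolerance is relative,
# which is too strict for Monte-Carlo comparisons against small targets).
expect_near <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}

# A tiny hand-constructed ratings table: n_ind individuals, n_img images,
# the first n_rep images presented twice.
make_ratings_fixture <- function(n_ind = 6, n_img = 8, n_rep = 4, seed = 42,
                                 rating_fun = NULL) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_ind)) {
    fam <- sprintf("fam%02d", ceiling(i / 2))
    ord <- 2 - i %% 2
    for (j in seq_len(n_img)) {
      for (p in seq_len(if (j <= n_rep) 2 else 1)) {
        r <- if (is.null(rating_fun)) sample(1:7, 1) else rating_fun(i, j, p)
        rows[[length(rows) + 1]] <- data.frame(
          family_id = fam, individual_id = sprintf("ind%02d", i),
          twin_order = ord, zygosity = if (ceiling(i / 2) %% 2) "MZ" else "DZ",
          sex = if (ceiling(i / 2) %% 2) "F" else "M", age = 30 + ceiling(i / 2),
          domain = "scenes", image_id = sprintf("img%02d", j),
          presentation = p, rating = r, stringsAsFactors = FALSE
        )
      }
    }
  }
  validate_ratings(do.call(rbind, rows), bounded = FALSE)
}

# Single-trait twin-pair table simulated at given A/C/D/E variances.
make_pairs <- function(n_mz, n_dz, A = 0, C = 0, D = 0, E = 1, seed = 1) {
  cfg <- sim_config(n_mz_pairs = n_mz, n_dz_pairs = n_dz, traits = "y",
                    Sigma_A = A, Sigma_C = C, Sigma_D = D, Sigma_E = E,
                    seed = seed)
  traits_to_pairs(simulate_twin_traits(cfg), "y")
}

# Wide two-trait pair table from a bivariate generator.
make_mv_pairs <- function(n_mz, n_dz, Sigma_A, Sigma_E,
                          Sigma_C = matrix(0, 2, 2), seed = 1,
                          traits = c("t1", "t2")) {
  cfg <- sim_config(n_mz_pairs = n_mz, n_dz_pairs = n_dz, traits = traits,
                    Sigma_A = Sigma_A, Sigma_C = Sigma_C,
                    Sigma_D = matrix(0, 2, 2), Sigma_E = Sigma_E, seed = seed)
  tr <- simulate_twin_traits(cfg)
  w <- NULL
  for (trait in traits) {
    tp <- traits_to_pairs(tr, trait)
    names(tp)[names(tp) %in% c("y1", "y2")] <- paste0(trait, "_", 1:2)
    keep <- c("family_id", "zygosity", paste0(trait, "_", 1:2))
    w <- if (is.null(w)) tp[, keep] else merge(w, tp[, keep],
                                               by = c("family_id", "zygosity"))
  }
  w
}

# All permutations of 1..n (for brute-force assignment oracles at tiny n).
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = k)
    }
  }
  out
}

# Direct two-pass Pearson correlation, independent of stats::cor.
pearson_brute <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
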