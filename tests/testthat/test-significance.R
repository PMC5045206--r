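test_that("shuffling pairings is seeded, preserves multisets, and recomputes weights", {
  set.seed(2)
  rs <- random_paired_set(n = 12)
  s1 <- shuffle_pairings(rs, seed = 99)
  s2 <- shuffle_pairings(rs, seed = 99)
  expect_identical(s1$site_row, s2$site_row)
  expect_identical(sort(s1$site_row), sort(rs$site_row))
  expect_identical(s1$tf_row, rs$tf_row)
  expect_equal(s1$pair_weight,
               unname(rs$tf_weight[s1$tf_id] * rs$site_weight[s1$site_id]))
})

test_that("re-pairing is uniform over slots", {
  rs <- random_paired_set(n = 5, random_weights = FALSE)
  set.seed(123)
  counts <- matrix(0, 5, 5)
  n_sh <- 10000
  for (r in seq_len(n_sh)) {
    sh <- shuffle_pairings(rs)
    counts[cbind(seq_len(5), match(sh$site_id, rs$site_id))] <-
      counts[cbind(seq_len(5), match(sh$site_id, rs$site_id))] + 1
  }
  # each site visits each slot ~ n_sh/5 times; 5 sigma binomial band
  expected <- n_sh / 5
  band <- 5 * sqrt(n_sh * 0.2 * 0.8)
  expect_true(all(abs(counts - expected) < band))
})

test_that("null distribution flags degenerate pairs and has nonnegative means", {
  s <- paired_alignment_set(paste0("t", 1:6), paste0("s", 1:6),
                            rep("K", 6), c("A", "C", "G", "T", "A", "C"))
  model <- identity_model(0.5)
  null <- null_distribution(s, model, n_shuffles = 50, seed = 1)
  expect_equal(unname(null$mean[1, 1]), 0, tolerance = 1e-12)
  expect_equal(unname(null$sd[1, 1]), 0, tolerance = 1e-12)
  expect_true(null$flagged[1, 1])

  set.seed(8)
  rs <- random_paired_set(n = 10)
  n2 <- null_distribution(rs, substitution_model("BLOSUM45", 0.5),
                          n_shuffles = 100, seed = 3)
  expect_true(all(n2$mean >= 0, na.rm = TRUE))
  expect_error(null_distribution(rs, model, n_shuffles = 1), class = "configuration_error")
})

test_that("trace correction fits identity on matching data and absorbs inflation", {
  dims <- c(8, 10)
  E <- matrix(runif(80, 0.1, 0.5), dims[1], dims[2])
  null <- structure(list(mean = E, sd = E / 10, flagged = matrix(FALSE, 8, 10),
                         trace_alpha = 1, trace_beta = 0,
                         corrected_mean = E, corrected_sd = E / 10),
                    class = "mi_null_model")
  same <- phylo_trace_correction(E, null)
  expect_equal(same$trace_alpha, 1, tolerance = 1e-9)
  expect_equal(same$trace_beta, 0, tolerance = 1e-9)
  expect_equal(same$corrected_mean, E, tolerance = 1e-9)

  # observed = 2 x null mean everywhere -> alpha ~ 2, sd doubled
  infl <- phylo_trace_correction(2 * E, null)
  expect_equal(infl$trace_alpha, 2, tolerance = 1e-6)
  expect_equal(infl$corrected_sd, 2 * null$sd, tolerance = 1e-9)

  # correction never increases any Z-score
  set.seed(40)
  obs <- E + matrix(rnorm(80, 0.05, 0.1), 8, 10)
  obs[obs < 0] <- 0
  corr <- phylo_trace_correction(obs, null)
  z_raw <- (obs - null$corrected_mean) / null$corrected_sd
  z_cor <- (obs - corr$corrected_mean) / corr$corrected_sd
  expect_true(all(z_cor <= z_raw + 1e-12))

  # too few usable pairs: skipped with a warning
  tiny <- structure(list(mean = E[1:2, 1:2], sd = E[1:2, 1:2] / 10,
                         flagged = matrix(FALSE, 2, 2),
                         trace_alpha = 1, trace_beta = 0,
                         corrected_mean = E[1:2, 1:2], corrected_sd = E[1:2, 1:2] / 10),
                    class = "mi_null_model")
  expect_warning(phylo_trace_correction(E[1:2, 1:2], tiny), "skipped")
})

test_that("Z-scores follow the definition and exclude sigma = 0 pairs", {
  E <- matrix(0.2, 2, 2)
  sd <- matrix(c(0.1, 0.1, 0.1, 0), 2, 2)
  null <- structure(list(mean = E, sd = sd, flagged = sd == 0,
                         trace_alpha = 1, trace_beta = 0,
                         corrected_mean = E, corrected_sd = sd),
                    class = "mi_null_model")
  obs <- matrix(c(0.2, 0.5, 0.2 + 3 * 0.1, 0.9), 2, 2)
  z <- z_score_matrix(obs, null)
  expect_equal(z[1, 1], 0)
  expect_equal(z[2, 1], 3)
  expect_equal(z[1, 2], 3)
  expect_true(is.na(z[2, 2]))
  expect_error(z_score_matrix(obs[1, , drop = FALSE], null), class = "validation_error")
})

test_that("Bernoulli cutoff reproduces hand-evaluated binomial tails", {
  z <- c(6, 1, 0, -1)
  res <- bernoulli_cutoff(z)
  # independent evaluation by direct binomial summation
  p1 <- pnorm(6, lower.tail = FALSE)
  p2 <- pnorm(1, lower.tail = FALSE)
  B1 <- sum(dbinom(1:4, 4, p1))
  B2 <- sum(dbinom(2:4, 4, p2))
  expect_equal(B1, 3.95e-9, tolerance = 1e-2)
  expect_equal(B2, 0.121, tolerance = 1e-2)
  expect_equal(res$log10_curve[1], log10(B1), tolerance = 1e-9)
  expect_equal(res$log10_curve[2], log10(B2), tolerance = 1e-9)
  expect_equal(res$k_star, 1L)

  # all Z <= 0: nothing to report
  null_res <- bernoulli_cutoff(c(-0.5, -1, -2))
  expect_equal(null_res$k_star, 0L)
  expect_equal(null_res$log10_p_min, 0)

  expect_error(bernoulli_cutoff(numeric(0)), class = "validation_error")
  expect_error(bernoulli_cutoff(c(1, 2)), class = "validation_error")
})

test_that("Bernoulli curve stays finite for extreme Z-scores (no underflow)", {
  z <- c(80, 70, 60, rep(0.5, 100))
  res <- bernoulli_cutoff(z, M = 1480)
  expect_true(all(is.finite(res$log10_curve[1:3])))
  expect_lt(res$log10_curve[1], -1000)
  expect_gt(res$log10_curve[1], -1e6)
})

test_that("scrambling preserves residue multisets and gap positions", {
  set.seed(77)
  rs <- random_paired_set(n = 10, gap_rate = 0.15)
  same <- scramble_rows(rs, 0, seed = 1)
  expect_identical(same$tf_row, rs$tf_row)

  scr <- scramble_rows(rs, 1, seed = 1)
  for (k in seq_len(n_records(rs))) {
    expect_equal(sort(strsplit(scr$tf_row[k], "")[[1]]),
                 sort(strsplit(rs$tf_row[k], "")[[1]]))
    expect_identical(gregexpr("-", scr$tf_row[k], fixed = TRUE)[[1]],
                     gregexpr("-", rs$tf_row[k], fixed = TRUE)[[1]])
  }
  expect_identical(scr$site_row, rs$site_row)
  expect_error(scramble_rows(rs, 1.2), class = "validation_error")
})

test_that("analysis is deterministic given identical seeds and inputs", {
  set.seed(1)
  ds <- generate_coupled_dataset(synthetic_spec(
    n_subfamilies = 3, records_per_subfamily = 8, n_protein_cols = 12,
    n_site_cols = 6, planted_pairs = data.frame(site_col = 2, prot_col = 5),
    seed = 5))
  set <- weight_paired_set(ds$set)
  model <- substitution_model("BLOSUM45", 0.5)
  r1 <- analyze_paired_set(set, model, n_shuffles = 100, seed = 42)
  r2 <- analyze_paired_set(set, model, n_shuffles = 100, seed = 42)
  expect_identical(r1$Z, r2$Z)
  expect_identical(r1$ranked, r2$ranked)
  expect_identical(r1$k_star, r2$k_star)
})

test_that("negative control with more shuffled replicates is reproducible and weaker than intact", {
  ds <- generate_coupled_dataset(synthetic_spec(
    n_subfamilies = 4, records_per_subfamily = 15, n_protein_cols = 14,
    n_site_cols = 8,
    planted_pairs = data.frame(site_col = c(2, 6), prot_col = c(4, 10)),
    noise_rate = 0.05, seed = 6))
  set <- weight_paired_set(ds$set)
  model <- substitution_model("BLOSUM45", 0.5)
  intact <- analyze_paired_set(set, model, n_shuffles = 300, seed = 9)
  nc1 <- negative_control(set, model, shuffle_seed = 4, n_shuffles = 300, seed = 9)
  nc2 <- negative_control(set, model, shuffle_seed = 4, n_shuffles = 300, seed = 9)
  expect_identical(nc1$log10_p_min, nc2$log10_p_min)
  expect_lt(intact$log10_p_min, nc1$log10_p_min)
})
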