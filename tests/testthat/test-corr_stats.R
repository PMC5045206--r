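test_that("BLOSUM-derived transition models are row-stochastic with plausible structure", {
  for (nm in c("BLOSUM45", "BLOSUM62")) {
    m <- substitution_model(nm, 0.5)
    expect_equal(unname(rowSums(m$P)), rep(1, 20), tolerance = 1e-9)
    expect_true(all(m$P >= 0))
    expect_true(all(diag(m$P) > 1 / 20))
  }
  # self-substitution dominates each row, with the known exception of M,
  # whose row is topped by L (high leucine background frequency)
  m45 <- substitution_model("BLOSUM45", 0.5)
  winners <- colnames(m45$P)[apply(m45$P, 1, which.max)]
  others <- setdiff(rownames(m45$P), "M")
  expect_equal(winners[match(others, rownames(m45$P))], others)
  expect_equal(winners[rownames(m45$P) == "M"], "L")

  idm <- substitution_model("identity", 0.5)
  expect_equal(unname(idm$P), diag(20))
  expect_error(substitution_model("BLOSUM40"), class = "configuration_error")
})

test_that("weighted counts match a brute-force double loop and exclude gapped cells", {
  set <- paired_alignment_set(c("t1", "t2"), c("s1", "s2"),
                              c("K", "K"), c("C", "C"),
                              c(t1 = 1.0, t2 = 0.5), c(s1 = 1, s2 = 1))
  cnt <- weighted_counts(set, 1, 1)
  expect_equal(cnt$N_ij["K", "C"], 1.5)
  expect_equal(cnt$N_effective, 1.5)

  set.seed(5)
  rs <- random_paired_set(n = 15)
  for (idx in list(c(1, 1), c(3, 2), c(6, 4))) {
    cnt <- weighted_counts(rs, idx[1], idx[2])
    brute <- matrix(0, 20, 4, dimnames = list(AA20, NT4))
    for (k in seq_len(n_records(rs))) {
      a <- substr(rs$tf_row[k], idx[1], idx[1])
      n <- substr(rs$site_row[k], idx[2], idx[2])
      if (a != "-" && n != "-") brute[a, n] <- brute[a, n] + rs$pair_weight[k]
    }
    expect_equal(cnt$N_ij, brute, tolerance = 1e-12)
    expect_equal(sum(cnt$N_ij), cnt$N_effective)
    expect_equal(cnt$N_i, rowSums(brute))
    expect_equal(cnt$N_j, colSums(brute))
  }
  expect_error(weighted_counts(rs, 0, 1), class = "validation_error")
})

test_that("positional frequencies implement the pseudocount formula", {
  model <- substitution_model("BLOSUM45", 0.5)
  N <- setNames(rep(0, 20), AA20)
  N[c("K", "E")] <- c(3, 1)
  f <- positional_frequency(N, 4, model)
  # independent hand evaluation of the formula
  expected <- sapply(AA20, function(a) {
    ps <- sum(sapply(AA20, function(b) N[b] * model$P[b, a]))
    (N[[a]] + 0.5 * ps) / (4 * 1.5)
  })
  expect_equal(unname(f), unname(expected), tolerance = 1e-12)
  expect_equal(sum(f), 1, tolerance = 1e-12)

  # kappa = 0 reduces to raw frequencies
  m0 <- substitution_model("BLOSUM45", 0)
  expect_equal(unname(positional_frequency(N, 4, m0)), unname(N) / 4)
  # identity model: pseudocounts cancel for any kappa
  expect_equal(unname(positional_frequency(N, 4, identity_model(0.7))),
               unname(N) / 4, tolerance = 1e-12)
  # nucleotide column: uniform pseudocount
  Nn <- c(A = 2, C = 0, G = 1, T = 1)
  fn <- positional_frequency(Nn, 4, model)
  expect_equal(unname(fn), unname((Nn + 0.5 * 4 / 4) / (4 * 1.5)))
  expect_error(positional_frequency(N, 0, model), class = "degenerate_error")
})

test_that("joint frequencies are normalised and marginally consistent on random inputs", {
  model <- substitution_model("BLOSUM45", 0.5)
  set.seed(9)
  for (rep in 1:20) {
    rs <- random_paired_set(n = 10)
    cnt <- weighted_counts(rs, sample(6, 1), sample(4, 1))
    if (cnt$N_effective <= 0) next
    f_i <- positional_frequency(cnt$N_i, cnt$N_effective, model)
    f_j <- positional_frequency(cnt$N_j, cnt$N_effective, model)
    f_ij <- joint_frequency(cnt$N_ij, cnt$N_i, cnt$N_effective, model)
    expect_equal(sum(f_i), 1, tolerance = 1e-9)
    expect_equal(sum(f_j), 1, tolerance = 1e-9)
    expect_equal(sum(f_ij), 1, tolerance = 1e-9)
    expect_equal(unname(rowSums(f_ij)), unname(f_i), tolerance = 1e-9)
    expect_equal(unname(colSums(f_ij)), unname(f_j), tolerance = 1e-9)
  }
  # kappa = 0: joint reduces to raw proportions
  m0 <- substitution_model("BLOSUM45", 0)
  rs <- random_paired_set(n = 8, gap_rate = 0)
  cnt <- weighted_counts(rs, 1, 1)
  expect_equal(joint_frequency(cnt$N_ij, cnt$N_i, cnt$N_effective, m0),
               cnt$N_ij / cnt$N_effective)
})

test_that("mutual information reproduces closed-form and hand-computed values", {
  m0 <- identity_model(0)
  # constant protein column -> I = 0
  s1 <- paired_alignment_set(paste0("t", 1:4), paste0("s", 1:4),
                             rep("K", 4), c("A", "C", "G", "T"))
  st <- column_pair_stats(s1, 1, 1, m0)
  expect_equal(st$I, 0, tolerance = 1e-12)

  # perfect bijective association of two binary variables -> ln 2
  s2 <- paired_alignment_set(paste0("t", 1:4), paste0("s", 1:4),
                             c("K", "K", "E", "E"), c("C", "C", "T", "T"))
  expect_equal(column_pair_stats(s2, 1, 1, m0)$I, log(2), tolerance = 1e-12)

  # 6 records [K,K,K,E,E,E] x [C,C,T,T,T,T]: hand-evaluated double sum
  s3 <- paired_alignment_set(paste0("t", 1:6), paste0("s", 1:6),
                             c("K", "K", "K", "E", "E", "E"),
                             c("C", "C", "T", "T", "T", "T"))
  hand <- 2 / 6 * log((2 / 6) / (0.5 * 1 / 3)) +
    1 / 6 * log((1 / 6) / (0.5 * 2 / 3)) +
    3 / 6 * log((3 / 6) / (0.5 * 2 / 3))
  expect_equal(column_pair_stats(s3, 1, 1, m0)$I, hand, tolerance = 1e-12)
  expect_equal(hand, 0.3182, tolerance = 1e-3)
})

test_that("MI equals the brute-force oracle on random weighted instances", {
  model <- substitution_model("BLOSUM45", 0.5)
  set.seed(31)
  for (rep in 1:25) {
    kappa <- sample(c(0, 0.5), 1)
    m <- substitution_model("BLOSUM45", kappa)
    rs <- random_paired_set(n = sample(6:15, 1))
    i <- sample(6, 1); j <- sample(4, 1)
    cnt <- weighted_counts(rs, i, j)
    if (cnt$N_effective <= 0) next
    f_i <- positional_frequency(cnt$N_i, cnt$N_effective, m)
    f_j <- positional_frequency(cnt$N_j, cnt$N_effective, m)
    f_ij <- joint_frequency(cnt$N_ij, cnt$N_i, cnt$N_effective, m)
    got <- mutual_information(f_ij, f_i, f_j)
    want <- oracle_mi(rs$tf_row, rs$site_row, rs$pair_weight, i, j, m$P, kappa)
    expect_equal(got, want, tolerance = 1e-10)
    # compiled matrix path agrees with the R path
    cm <- correlation_matrix(rs, m)
    expect_equal(cm[j, i], want, tolerance = 1e-10)
  }
})

test_that("kappa = 0 MI is symmetric under exchanging the two columns", {
  # swap roles: treat the site column as the 'protein' side by recoding bases
  # as residues; with uniform pseudocounts off (kappa = 0) MI is symmetric
  m0 <- identity_model(0)
  set.seed(13)
  rs <- random_paired_set(n = 12, gap_rate = 0)
  recode <- c(A = "A", C = "C", G = "G", T = "T")
  aa_as_nt <- c(K = "A", E = "C", D = "G", R = "T")
  for (j in 1:2) {
    cnt <- weighted_counts(rs, 1, j)
    f_i <- positional_frequency(cnt$N_i, cnt$N_effective, m0)
    f_j <- positional_frequency(cnt$N_j, cnt$N_effective, m0)
    f_ij <- joint_frequency(cnt$N_ij, cnt$N_i, cnt$N_effective, m0)
    expect_equal(mutual_information(f_ij, f_i, f_j),
                 mutual_information(t(f_ij), f_j, f_i), tolerance = 1e-12)
  }
})

test_that("identity substitution model makes results kappa-independent", {
  set.seed(17)
  rs <- random_paired_set(n = 10)
  for (kap in c(0.25, 0.5, 2)) {
    cm_k <- correlation_matrix(rs, identity_model(kap))
    cm_0 <- correlation_matrix(rs, identity_model(0))
    expect_equal(cm_k, cm_0, tolerance = 1e-10)
  }
})

test_that("chi-squared summands sum to the Pearson statistic and flag deviations", {
  # O = 10, E = 2 -> summand 32, overrepresented
  N_ij <- matrix(0, 20, 4, dimnames = list(AA20, NT4))
  N_ij["K", "C"] <- 10; N_ij["K", "T"] <- 10
  N_ij["E", "C"] <- 2; N_ij["E", "T"] <- 38
  cs <- chi2_summands(N_ij, rowSums(N_ij), colSums(N_ij), sum(N_ij))
  tab <- N_ij[c("K", "E"), c("C", "T")]
  want <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  expect_equal(sum(cs$summand), unname(want), tolerance = 1e-9)
  expect_equal(cs$direction["K", "C"], "+")
  expect_equal(cs$direction["E", "C"], "-")

  # O = E everywhere -> all zero
  even <- matrix(0, 20, 4, dimnames = list(AA20, NT4))
  even[c("K", "E"), ] <- 5
  cse <- chi2_summands(even, rowSums(even), colSums(even), sum(even))
  expect_true(all(cse$summand == 0))
  expect_true(all(cse$direction == ""))

  # direct arithmetic check of one cell: O = 10 against E = 4*5/10 = 2 -> 32
  O <- matrix(0, 20, 4, dimnames = list(AA20, NT4))
  O["A", "A"] <- 10
  cs2 <- chi2_summands(O, N_i = setNames(c(4, rep(0, 19)), AA20),
                       N_j = c(A = 5, C = 0, G = 0, T = 0), N_effective = 10)
  expect_equal(cs2$summand["A", "A"], 32)
  expect_equal(cs2$direction["A", "A"], "+")
  expect_false(cs2$highlight["A", "A"])
  expect_true(chi2_summands(O, setNames(c(4, rep(0, 19)), AA20),
                            c(A = 5, C = 0, G = 0, T = 0), 10,
                            cutoff = 30)$highlight["A", "A"])
})

test_that("column information content follows the logo convention", {
  expect_equal(column_information_content(rep(0.25, 4)), 0)
  one <- c(1, rep(0, 19))
  expect_equal(column_information_content(one), log2(20))
  expect_equal(column_information_content(c(0.5, 0.5, 0, 0)), 1)
})

test_that("correlation_matrix has the right shape and matches per-pair calls", {
  set.seed(3)
  rs <- random_paired_set(n = 10, Lp = 5, Ls = 3, gap_rate = 0)
  model <- substitution_model("BLOSUM45", 0.5)
  cm <- correlation_matrix(rs, model)
  expect_equal(dim(cm), c(3L, 5L))
  for (i in c(1, 4)) for (j in c(1, 3)) {
    expect_equal(cm[j, i], column_pair_stats(rs, i, j, model)$I, tolerance = 1e-10)
  }
})
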