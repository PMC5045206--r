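#' Randomly re-pair TF rows with site rows
#'
#' Permutes the site side of the set uniformly at random against the TF side
#' (fixed points allowed), recomputing each pair weight as the product of the
#' TF's weight and the new partner site's weight. The multisets of TF rows
#' and of site rows are unchanged; only the linkage is destroyed. This is the
#' elementary move of the permutation null.
#'
#' @param set a `paired_alignment_set`.
#' @param seed optional integer seed (omit to use the current RNG state).
#' @return the re-paired `paired_alignment_set`.
#' @export
shuffle_pairings <- function(set, seed = NULL) {
  if (n_records(set) < 2L) tfsc_error("need >= 2 records to shuffle", "size_error")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n_records(set))
  paired_alignment_set(set$tf_id, set$site_id[perm],
                       set$tf_row, set$site_row[perm],
                       set$tf_weight, set$site_weight)
}

#' Permutation null distribution of mutual information
#'
#' Re-pairs TFs and sites `n_shuffles` times and records, for every column
#' pair, the mean and standard deviation of the resulting MI. One global
#' sequence of permutations is shared by all column pairs (each permutation
#' is scored for every pair). Pairs whose null s.d. is zero (e.g. a constant
#' column) are flagged as not assessable.
#'
#' @param set a weighted `paired_alignment_set`.
#' @param model a [substitution_model()].
#' @param n_shuffles number of re-pairings (default 10000; >= 200 recommended
#'   for a stable s.d.).
#' @param seed integer RNG seed.
#' @param base log base for MI.
#' @return object of class `mi_null_model`: matrices `mean` and `sd`
#'   (site cols x protein cols), `flagged` (sd == 0 or unusable), and the
#'   shuffle count and seed. Trace-correction slots are filled by
#'   [phylo_trace_correction()].
#' @export
null_distribution <- function(set, model, n_shuffles = 10000, seed = 1,
                              base = exp(1)) {
  if (n_shuffles < 2) tfsc_error("n_shuffles must be >= 2", "configuration_error")
  n <- n_records(set)
  set.seed(seed)
  perms <- matrix(0L, n_shuffles, n)
  for (s in seq_len(n_shuffles)) perms[s, ] <- sample.int(n)
  enc <- encode_set(set)
  mom <- null_moments_cpp(enc$prot, enc$site, enc$w_tf, enc$w_site,
                          perms, model$P, model$P_nt, model$kappa, base)
  dn <- list(site_col = seq_len(set$n_site_cols),
             prot_col = seq_len(set$n_protein_cols))
  dimnames(mom$mean) <- dimnames(mom$sd) <- dn
  structure(list(mean = mom$mean, sd = mom$sd,
                 flagged = is.na(mom$sd) | mom$sd == 0,
                 n_shuffles = n_shuffles, seed = seed, base = base,
                 trace_alpha = 1, trace_beta = 0,
                 corrected_mean = mom$mean, corrected_sd = mom$sd),
            class = "mi_null_model")
}

#' Affine correction of the null for shared phylogenetic history
#'
#' Shared ancestry inflates observed MI above the re-pairing null even for
#' functionally unrelated columns. To absorb this phylogenetic trace, the
#' observed MI of the bulk of pairs (the upper `q_exclude` fraction of
#' observed values is left out, so genuinely coupled pairs do not drive the
#' fit) is regressed on the raw null means, and the null is widened by the
#' fitted affine map: `E' = alpha E + beta`, `sd' = alpha sd`, with floors
#' `alpha >= 1`, `beta >= 0` so the correction can only ever weaken
#' Z-scores, never strengthen them.
#'
#' @param observed_I observed MI matrix from [correlation_matrix()].
#' @param null an `mi_null_model`.
#' @param q_exclude fraction of top observed values excluded from the fit
#'   (default 0.05).
#' @return the null model with `trace_alpha`, `trace_beta`,
#'   `corrected_mean`, `corrected_sd` filled in.
#' @export
phylo_trace_correction <- function(observed_I, null, q_exclude = 0.05) {
  if (!all(dim(observed_I) == dim(null$mean)))
    tfsc_error("observed matrix and null have different shapes", "validation_error")
  usable <- is.finite(observed_I) & is.finite(null$mean) & !null$flagged
  if (sum(usable) < 10L) {
    warning("fewer than 10 usable column pairs; phylogenetic trace correction skipped")
    return(null)
  }
  obs <- observed_I[usable]
  en <- null$mean[usable]
  cut <- stats::quantile(obs, 1 - q_exclude, names = FALSE)
  bulk <- obs <= cut
  fit <- stats::lm.fit(cbind(1, en[bulk]), obs[bulk])
  alpha <- max(1, fit$coefficients[2L])
  beta <- max(0, fit$coefficients[1L])
  null$trace_alpha <- unname(alpha)
  null$trace_beta <- unname(beta)
  null$corrected_mean <- alpha * null$mean + beta
  null$corrected_sd <- alpha * null$sd
  null
}

#' Z-scores of observed mutual information against the null
#'
#' `Z = (I - E') / sd'` with the (trace-corrected) null mean and s.d.
#' Pairs with zero or undefined null s.d. are returned as `NA` and excluded
#' from ranking downstream.
#'
#' @param observed_I observed MI matrix.
#' @param null an `mi_null_model` (corrected or raw).
#' @return Z matrix of the same shape.
#' @export
z_score_matrix <- function(observed_I, null) {
  if (!all(dim(observed_I) == dim(null$mean)))
    tfsc_error("observed matrix and null have different shapes", "validation_error")
  z <- (observed_I - null$corrected_mean) / null$corrected_sd
  z[null$flagged | !is.finite(z)] <- NA_real_
  z
}

# log of the upper binomial tail P(Bin(M, p) >= k), evaluated by
# log-sum-exp over the term logs so that astronomically small tails
# (|log10 p| ~ 1e4) do not underflow.
#' @noRd
log_binom_tail <- function(M, k, logp, log1mp) {
  if (logp == 0) return(0)          # p = 1: tail is 1
  if (!is.finite(logp)) return(-Inf) # p = 0, k >= 1
  j <- k:M
  terms <- lchoose(M, j) + j * logp + (M - j) * log1mp
  m <- max(terms)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(terms - m)))
}

#' Bernoulli cutoff: how many top Z-scores to report
#'
#' For each candidate count k, computes the probability
#' `B(k) = P(Binomial(M, p_k) >= k)` of seeing at least k Z-scores as large
#' as the k-th one among M standard-normal draws, where `p_k` is the upper
#' normal tail at the k-th largest Z. The reported count `k*` is the
#' minimiser of B (smallest k on ties) over the positive-Z prefix of the
#' ranking: the most surprising prefix. Candidates with `Z <= 0` are never
#' selectable -- a pair at or below its null mean is not a correlated pair,
#' and because the empirical left tail of permutation Z-scores is shorter
#' than Gaussian, `B(k)` near `k = M` is always spuriously small (at
#' `k = M` it degenerates to `p_min^M`), which would otherwise swallow the
#' argmin. All computation is in log space. When no Z is positive there is
#' nothing to report and `k* = 0` with p = 1.
#'
#' @param z_values numeric Z-scores sorted in non-increasing order
#'   (`NA` not allowed).
#' @param M universe size (default `length(z_values)`).
#' @return list with `k_star`, `log10_curve` (log10 B(k) for every
#'   k = 1..length(z_values)), and `log10_p_min` (0 when `k_star = 0`).
#' @export
bernoulli_cutoff <- function(z_values, M = length(z_values)) {
  if (!length(z_values)) tfsc_error("empty Z-score list", "validation_error")
  if (is.unsorted(rev(z_values), strictly = FALSE))
    tfsc_error("z_values must be sorted in non-increasing order", "validation_error")
  K <- length(z_values)
  logp <- stats::pnorm(z_values, lower.tail = FALSE, log.p = TRUE)
  log1mp <- stats::pnorm(z_values, lower.tail = TRUE, log.p = TRUE)
  logB <- vapply(seq_len(K), function(k) log_binom_tail(M, k, logp[k], log1mp[k]),
                 numeric(1))
  log10B <- pmin(logB / log(10), 0)
  n_pos <- sum(z_values > 0)
  k_star <- if (n_pos == 0L) 0L else which.min(log10B[seq_len(n_pos)])
  list(k_star = k_star, log10_curve = log10B,
       log10_p_min = if (k_star > 0) log10B[k_star] else 0)
}

#' Analyse a weighted paired set end to end
#'
#' The statistical core of the pipeline: observed MI matrix, permutation
#' null, optional phylogenetic-trace correction, Z-scores, ranking, and the
#' Bernoulli cutoff. Input weighting (and any file IO) is left to the
#' caller; see [run_correlation_pipeline()] for the full tool.
#'
#' @param set a weighted, deduplicated `paired_alignment_set`.
#' @param model a [substitution_model()].
#' @param n_shuffles permutation count for the null.
#' @param seed integer RNG seed.
#' @param base log base for MI (Z-scores are invariant to it).
#' @param trace_correction apply [phylo_trace_correction()] (default TRUE).
#' @return object of class `correlation_result`: the observed matrix, the
#'   null, the Z matrix, `ranked` (data frame sorted by decreasing Z with
#'   columns `site_col`, `prot_col`, `I`, `E_null`, `sd_null`, `Z`),
#'   `k_star`, `log10_curve`, `selected` (top `k_star` rows) and run
#'   parameters.
#' @export
analyze_paired_set <- function(set, model, n_shuffles = 10000, seed = 1,
                               base = exp(1), trace_correction = TRUE) {
  observed <- correlation_matrix(set, model, base)
  null <- null_distribution(set, model, n_shuffles, seed, base)
  if (trace_correction) null <- phylo_trace_correction(observed, null)
  z <- z_score_matrix(observed, null)
  idx <- which(!is.na(z), arr.ind = TRUE)
  ranked <- data.frame(site_col = idx[, 1L], prot_col = idx[, 2L],
                       I = observed[idx], E_null = null$corrected_mean[idx],
                       sd_null = null$corrected_sd[idx], Z = z[idx])
  ranked <- ranked[order(-ranked$Z, ranked$site_col, ranked$prot_col), ]
  rownames(ranked) <- NULL
  cut <- bernoulli_cutoff(ranked$Z, M = nrow(ranked))
  structure(list(observed = observed, null = null, Z = z, ranked = ranked,
                 k_star = cut$k_star, log10_curve = cut$log10_curve,
                 log10_p_min = cut$log10_p_min,
                 selected = utils::head(ranked, cut$k_star),
                 params = list(n_shuffles = n_shuffles, seed = seed,
                               base = base, kappa = model$kappa,
                               blosum = model$name,
                               trace_correction = trace_correction,
                               trace_alpha = null$trace_alpha,
                               trace_beta = null$trace_beta)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(paste0("correlation_result: %d assessable column pairs, ",
                     "k* = %d selected (min log10 p = %.2f), ",
                     "trace alpha = %.3f beta = %.4f\n"),
              nrow(x$ranked), x$k_star, x$log10_p_min,
              x$params$trace_alpha, x$params$trace_beta))
  if (x$k_star > 0) {
    cat("top pairs (site_col, prot_col, Z):\n")
    print(utils::head(x$selected[, c("site_col", "prot_col", "Z")], 10))
  }
  invisible(x)
}

#' Negative control: the B-cutoff minimum after one re-pairing
#'
#' Shuffles the TF-site pairings once and runs the full analysis on the
#' shuffled data. On sound input the shuffled minimum log10 p-value is
#' orders of magnitude closer to zero than the intact one, confirming that
#' the reported correlations derive from the pairing and not from column
#' composition.
#'
#' @inheritParams analyze_paired_set
#' @param shuffle_seed seed for the single diagnostic re-pairing.
#' @return list with `log10_p_min`, `k_star`, and the full shuffled-run
#'   `result`.
#' @export
negative_control <- function(set, model, shuffle_seed = 1, n_shuffles = 10000,
                             seed = 1, base = exp(1), trace_correction = TRUE) {
  shuffled <- shuffle_pairings(set, shuffle_seed)
  res <- analyze_paired_set(shuffled, model, n_shuffles, seed, base, trace_correction)
  list(log10_p_min = if (res$k_star > 0) res$log10_p_min else min(res$log10_curve),
       k_star = res$k_star, result = res)
}

#' Scramble protein rows in a fraction of records
#'
#' Simulates misalignment / corrupted input: in `ceiling(fraction * n)`
#' randomly chosen records the protein-row residues are randomly permuted
#' across columns (gaps keep their positions); site rows are untouched.
#'
#' @param set a `paired_alignment_set`.
#' @param fraction fraction of records to scramble, in `[0, 1]`.
#' @param seed optional integer seed.
#' @return the perturbed `paired_alignment_set`.
#' @export
scramble_rows <- function(set, fraction, seed = NULL) {
  if (fraction < 0 || fraction > 1)
    tfsc_error("fraction must be in [0, 1]", "validation_error")
  if (!is.null(seed)) set.seed(seed)
  n <- n_records(set)
  k <- ceiling(fraction * n)
  if (k == 0L) return(set)
  pick <- sample.int(n, k)
  rows <- set$tf_row
  for (r in pick) {
    ch <- strsplit(rows[r], "", fixed = TRUE)[[1L]]
    res <- which(ch != GAP_CHAR)
    ch[res] <- ch[res[sample.int(length(res))]]
    rows[r] <- paste(ch, collapse = "")
  }
  paired_alignment_set(set$tf_id, set$site_id, rows, set$site_row,
                       set$tf_weight, set$site_weight)
}
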