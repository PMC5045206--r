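#' Weighted nucleotide-amino-acid counts for one column pair
#'
#' Counts each record's (residue at protein column `i`, base at site column
#' `j`) combination, weighted by the record's pair weight. Records with a gap
#' at either column are excluded from this pair's counts, so the effective
#' total weight `N_effective` varies across column pairs.
#'
#' @param set a `paired_alignment_set`.
#' @param i protein column (1-based).
#' @param j site column (1-based).
#' @return list with `N_ij` (20x4 matrix, residues x bases), `N_i`, `N_j`
#'   (marginal weighted counts), and `N_effective`. `N_effective = 0` marks
#'   the pair unusable.
#' @export
weighted_counts <- function(set, i, j) {
  if (i < 1L || i > set$n_protein_cols || j < 1L || j > set$n_site_cols)
    tfsc_error("column index out of range", "validation_error")
  a <- substr(set$tf_row, i, i)
  n <- substr(set$site_row, j, j)
  keep <- a != GAP_CHAR & n != GAP_CHAR
  N_ij <- matrix(0, 20, 4, dimnames = list(AA_ALPHABET, NT_ALPHABET))
  if (any(keep)) {
    tab <- tapply(set$pair_weight[keep],
                  list(factor(a[keep], AA_ALPHABET), factor(n[keep], NT_ALPHABET)),
                  sum)
    tab[is.na(tab)] <- 0
    N_ij[] <- tab
  }
  list(N_ij = N_ij, N_i = rowSums(N_ij), N_j = colSums(N_ij),
       N_effective = sum(N_ij))
}

#' Pseudocounted positional frequencies
#'
#' Estimates the frequency of each symbol in one alignment column from
#' weighted counts, supplementing the N observed (weighted) sequences with
#' `kappa * N` pseudo-observations spread by the substitution model:
#' `f(a) = (N(a) + kappa * sum_b N(b) P(b->a)) / (N (1 + kappa))`.
#' A 20-long count vector is treated as a protein column (BLOSUM-derived
#' `P`); a 4-long vector as a nucleotide column (uniform `P = 1/4`, i.e.
#' `f(n) = (N(n) + kappa N / 4) / (N (1 + kappa))`).
#'
#' @param N named weighted count vector (length 20 or 4).
#' @param N_effective total weight of usable records.
#' @param model a [substitution_model()].
#' @return frequency vector summing to 1.
#' @export
positional_frequency <- function(N, N_effective, model) {
  if (!(N_effective > 0)) tfsc_error("degenerate column: N_effective <= 0", "degenerate_error")
  kappa <- model$kappa
  pseudo <- if (length(N) == 20L) as.vector(crossprod(model$P, N))
            else as.vector(crossprod(model$P_nt, N))
  f <- (N + kappa * pseudo) / (N_effective * (1 + kappa))
  stats::setNames(f, names(N))
}

#' Pseudocounted joint nucleotide-amino-acid frequencies
#'
#' Joint analogue of [positional_frequency()] under the null-hypothesis
#' factorisation of the substitution process into the residue model times
#' the base model, `P(b, m -> a, n) = P(b -> a) P_nt(m -> n)`; with the
#' uniform base model this is
#' `f(a,n) = (N_ij(a,n) + (kappa/4) sum_b P(b->a) N_i(b)) / (N (1 + kappa))`.
#' Its marginals equal the positional frequencies exactly.
#'
#' @param N_ij 20x4 weighted count matrix.
#' @param N_i length-20 marginal counts of the protein column.
#' @param N_effective total weight of usable records.
#' @param model a [substitution_model()].
#' @return 20x4 joint frequency matrix summing to 1.
#' @export
joint_frequency <- function(N_ij, N_i, N_effective, model) {
  if (!(N_effective > 0)) tfsc_error("degenerate column pair: N_effective <= 0", "degenerate_error")
  kappa <- model$kappa
  pseudo <- crossprod(model$P, N_ij %*% model$P_nt)
  (N_ij + kappa * pseudo) / (N_effective * (1 + kappa))
}

#' Mutual information between two alignment columns
#'
#' `I = sum_{a,n} f(a,n) log( f(a,n) / (f_i(a) f_j(n)) )`, the
#' Kullback-Leibler divergence of the joint from the product of marginals.
#' Cells with zero joint frequency contribute zero. Natural log by default;
#' the base only rescales I (downstream Z-scores are base-invariant).
#'
#' @param f_ij joint frequency matrix.
#' @param f_i,f_j marginal frequency vectors (rows / columns of `f_ij`).
#' @param base logarithm base (default `exp(1)` for nats; use 2 for bits).
#' @return nonnegative mutual information (up to float tolerance).
#' @export
mutual_information <- function(f_ij, f_i, f_j, base = exp(1)) {
  fexp <- outer(f_i, f_j)
  use <- f_ij > 0
  sum(f_ij[use] * log(f_ij[use] / fexp[use])) / log(base)
}

#' Chi-squared summands of a nucleotide-amino-acid contingency table
#'
#' Per-cell `(O - E)^2 / E` with `O = N_ij(a,n)` and
#' `E = N_i(a) N_j(n) / N_effective`, annotated with the direction of the
#' deviation and a highlight flag for summands at or above `cutoff`. Cells
#' with `E = 0` (hence `O = 0`) score 0. The summands identify which
#' specific residue-base combinations drive a correlated column pair; the
#' highlight cutoff is an arbitrary display threshold.
#'
#' @param N_ij,N_i,N_j,N_effective weighted counts as from [weighted_counts()].
#' @param cutoff highlight threshold (default 50).
#' @return list with matrices `summand`, `direction` (`"+"` over-, `"-"`
#'   under-represented, `""` at expectation) and logical `highlight`.
#' @export
chi2_summands <- function(N_ij, N_i, N_j, N_effective, cutoff = 50) {
  E <- outer(N_i, N_j) / N_effective
  s <- matrix(0, nrow(N_ij), ncol(N_ij), dimnames = dimnames(N_ij))
  pos <- E > 0
  s[pos] <- (N_ij[pos] - E[pos])^2 / E[pos]
  dir <- matrix("", nrow(N_ij), ncol(N_ij), dimnames = dimnames(N_ij))
  dir[N_ij > E] <- "+"
  dir[N_ij < E] <- "-"
  list(summand = s, direction = dir, highlight = s >= cutoff, expected = E)
}

#' Mutual-information summands of a column pair
#'
#' The per-cell terms `f(a,n) log(f(a,n)/(f_i(a) f_j(n)))` whose sum is the
#' column-pair MI; exported alongside the chi-squared summands in
#' contingency reports.
#'
#' @inheritParams mutual_information
#' @return matrix of summands (zero where `f_ij = 0`).
#' @export
mi_summands <- function(f_ij, f_i, f_j, base = exp(1)) {
  fexp <- outer(f_i, f_j)
  s <- matrix(0, nrow(f_ij), ncol(f_ij), dimnames = dimnames(f_ij))
  use <- f_ij > 0
  s[use] <- f_ij[use] * log(f_ij[use] / fexp[use]) / log(base)
  s
}

#' Information content of an alignment column
#'
#' Sequence-logo convention: `IC = log2(|alphabet|) + sum f log2 f` bits,
#' ranging from 0 (uniform column) to `log2 20 ~ 4.32` for a single-residue
#' protein column (or 2 bits for a single-base site column).
#'
#' @param f normalized frequency vector (length gives the alphabet size).
#' @return information content in bits.
#' @export
column_information_content <- function(f) {
  size <- length(f)
  f <- f[f > 0]
  log2(size) + sum(f * log2(f))
}

#' Full column-pair statistics for one (site column, protein column) pair
#'
#' Bundles the weighted counts, pseudocounted frequencies, MI and
#' chi-squared summands for in-depth inspection of a single pair.
#'
#' @inheritParams weighted_counts
#' @param model a [substitution_model()].
#' @param base log base for MI.
#' @param chi2_cutoff highlight threshold for chi-squared summands.
#' @return object of class `column_pair_stats`.
#' @export
column_pair_stats <- function(set, i, j, model, base = exp(1), chi2_cutoff = 50) {
  cnt <- weighted_counts(set, i, j)
  if (!(cnt$N_effective > 0))
    tfsc_error("degenerate column pair: no usable records", "degenerate_error")
  f_i <- positional_frequency(cnt$N_i, cnt$N_effective, model)
  f_j <- positional_frequency(cnt$N_j, cnt$N_effective, model)
  f_ij <- joint_frequency(cnt$N_ij, cnt$N_i, cnt$N_effective, model)
  structure(c(cnt, list(
    i = i, j = j,
    f_i = f_i, f_j = f_j, f_ij = f_ij,
    I = mutual_information(f_ij, f_i, f_j, base),
    chi2 = chi2_summands(cnt$N_ij, cnt$N_i, cnt$N_j, cnt$N_effective, chi2_cutoff),
    mi_summand = mi_summands(f_ij, f_i, f_j, base)
  )), class = "column_pair_stats")
}

#' Mutual-information matrix over all column pairs
#'
#' Computes the weighted, pseudocounted MI for every (site column, protein
#' column) combination. Pairs with no usable records (all gapped) are `NA`.
#'
#' @param set a weighted `paired_alignment_set`.
#' @param model a [substitution_model()].
#' @param base log base for MI.
#' @return `n_site_cols x n_protein_cols` matrix; rows are site columns,
#'   columns are protein columns.
#' @export
correlation_matrix <- function(set, model, base = exp(1)) {
  enc <- encode_set(set)
  out <- mi_matrix_cpp(enc$prot, enc$site, enc$w_tf, enc$w_site,
                       seq_len(n_records(set)), model$P, model$P_nt,
                       model$kappa, base)
  dimnames(out) <- list(site_col = seq_len(set$n_site_cols),
                        prot_col = seq_len(set$n_protein_cols))
  out
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
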