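# Independent oracles and small fixture builders. The MI oracle evaluates the
# weighted-count / pseudocount / double-sum formulas by explicit loops; it
# shares no code with the package's vectorized or compiled paths.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
NT4 <- c("A", "C", "G", "T")

oracle_mi <- function(tf_rows, site_rows, w, i, j, P, kappa, base = exp(1)) {
  a <- substr(tf_rows, i, i)
  n <- substr(site_rows, j, j)
  keep <- a != "-" & n != "-"
  a <- a[keep]; n <- n[keep]; w <- w[keep]
  N <- sum(w)
  Nij <- matrix(0, 20, 4, dimnames = list(AA20, NT4))
  for (k in seq_along(a)) Nij[a[k], n[k]] <- Nij[a[k], n[k]] + w[k]
  Ni <- rowSums(Nij)
  Nj <- colSums(Nij)
  fi <- numeric(20); names(fi) <- AA20
  for (x in AA20) {
    ps <- 0
    for (b in AA20) ps <- ps + Ni[b] * P[b, x]
    fi[x] <- (Ni[x] + kappa * ps) / (N * (1 + kappa))
  }
  fj <- (Nj + kappa * N / 4) / (N * (1 + kappa))
  mi <- 0
  for (x in AA20) {
    ps <- 0
    for (b in AA20) ps <- ps + P[b, x] * Ni[b]
    for (y in NT4) {
      f <- (Nij[x, y] + kappa / 4 * ps) / (N * (1 + kappa))
      if (f > 0) mi <- mi + f * log(f / (fi[x] * fj[y]))
    }
  }
  unname(mi) / log(base)
}

# Random weighted paired set with optional gaps; low per-column diversity so
# pseudocounts matter.
random_paired_set <- function(n = 12, Lp = 6, Ls = 4, gap_rate = 0.08,
                              random_weights = TRUE) {
  prot <- replicate(Lp, sample(sample(AA20, 4), n, replace = TRUE))
  site <- replicate(Ls, sample(sample(NT4, 3), n, replace = TRUE))
  if (gap_rate > 0) {
    prot[matrix(runif(n * Lp) < gap_rate, n)] <- "-"
    site[matrix(runif(n * Ls) < gap_rate, n)] <- "-"
  }
  ids <- sprintf("%02d", seq_len(n))
  tfw <- if (random_weights) setNames(runif(n, 0.2, 2), paste0("t", ids))
         else setNames(rep(1, n), paste0("t", ids))
  stw <- if (random_weights) setNames(runif(n, 0.2, 2), paste0("s", ids))
         else setNames(rep(1, n), paste0("s", ids))
  paired_alignment_set(paste0("t", ids), paste0("s", ids),
                       apply(prot, 1, paste, collapse = ""),
                       apply(site, 1, paste, collapse = ""),
                       tfw, stw)
}

# Tiny deterministic set used across io/corr tests.
toy_set <- function() {
  paired_alignment_set(
    tf_id = c("tf1", "tf1", "tf2", "tf3"),
    site_id = c("sA", "sB", "sA", "sC"),
    tf_row = c("KRDE", "KRDE", "ERDA", "KHD-"),
    site_row = c("ACGT", "ACGA", "TCGT", "ACTT"))
}

identity_model <- function(kappa = 0.5) substitution_model("identity", kappa)
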