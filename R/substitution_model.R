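#' Residue transition probabilities from a BLOSUM score matrix
#'
#' Builds the row-stochastic matrix `P(b -> a)` used to spread amino-acid
#' pseudocount mass. BLOSUM score matrices are rounded log-odds
#' `s(a,b) ~ log(q(a,b)/(p(a) p(b))) / lambda`; the implied target
#' frequencies are recovered by solving for the unique scale `lambda` and
#' background vector `p` with `sum_b p(b) exp(lambda s(a,b)) = 1` for every
#' `a` and `sum(p) = 1` (the standard inverse construction for a valid
#' scoring matrix). Then `P(b -> a) = q(a,b)/p(b) = p(a) exp(lambda s(a,b))`,
#' with rows renormalised to sum exactly to 1.
#'
#' The nucleotide side uses the uniform model `P(m -> n) = 1/4`; under the
#' `"identity"` override both sides use identity matrices, so pseudocounts
#' cancel exactly and any `kappa` reproduces the raw frequencies.
#'
#' @param name one of the BLOSUM matrices shipped with Biostrings
#'   (`"BLOSUM45"`, `"BLOSUM50"`, `"BLOSUM62"`, `"BLOSUM80"`, `"BLOSUM100"`)
#'   or `"identity"`.
#' @param kappa pseudocount fraction: the observed column of total weight N
#'   is supplemented by `kappa * N` pseudo-observations. Default 0.5.
#' @return object of class `substitution_model`: list with `P` (20x20,
#'   rows = source residue b, cols = target a), `P_nt` (4x4 nucleotide
#'   model), `kappa`, `name`, and for BLOSUM models the fitted `lambda` and
#'   background `p`.
#' @export
substitution_model <- function(name = "BLOSUM45", kappa = 0.5) {
  if (kappa < 0) tfsc_error("kappa must be >= 0", "configuration_error")
  if (identical(name, "identity")) {
    P <- diag(20)
    dimnames(P) <- list(AA_ALPHABET, AA_ALPHABET)
    P_nt <- diag(4)
    dimnames(P_nt) <- list(NT_ALPHABET, NT_ALPHABET)
    return(structure(list(P = P, P_nt = P_nt, kappa = kappa, name = name),
                     class = "substitution_model"))
  }
  known <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100")
  if (!name %in% known)
    tfsc_error(sprintf("unknown substitution matrix '%s' (use one of %s, identity)",
                       name, paste(known, collapse = ", ")),
               "configuration_error")
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  S <- get(name, envir = env)[AA_ALPHABET, AA_ALPHABET]
  fit <- solve_blosum_background(S)
  P <- sweep(exp(fit$lambda * S), 2, fit$p, "*")
  P <- P / rowSums(P)
  dimnames(P) <- list(AA_ALPHABET, AA_ALPHABET)
  P_nt <- matrix(0.25, 4, 4, dimnames = list(NT_ALPHABET, NT_ALPHABET))
  structure(list(P = P, P_nt = P_nt, kappa = kappa, name = name,
                 lambda = fit$lambda, background = stats::setNames(fit$p, AA_ALPHABET)),
            class = "substitution_model")
}

# Solve sum_b p_b exp(lambda * S[a,b]) = 1 (all a) and sum(p) = 1 for
# lambda > 0 with p > 0; the valid root is unique for a sensible matrix.
#' @noRd
solve_blosum_background <- function(S) {
  f <- function(lam) {
    p <- tryCatch(solve(exp(lam * S), rep(1, nrow(S))),
                  error = function(e) rep(NA_real_, nrow(S)))
    sum(p) - 1
  }
  grid <- seq(0.05, 1.5, by = 0.01)
  vals <- vapply(grid, f, numeric(1))
  ok <- which(!is.na(vals[-length(vals)]) & !is.na(vals[-1]) &
                sign(vals[-length(vals)]) != sign(vals[-1]))
  for (k in ok) {
    lam <- stats::uniroot(f, c(grid[k], grid[k + 1]), tol = 1e-12)$root
    p <- solve(exp(lam * S), rep(1, nrow(S)))
    if (all(p > 0)) return(list(lambda = lam, p = p / sum(p)))
  }
  tfsc_error("could not recover target frequencies from score matrix",
             "configuration_error")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("substitution_model: %s, kappa = %g", x$name, x$kappa))
  if (!is.null(x$lambda)) cat(sprintf(", lambda = %.4f", x$lambda))
  cat("\n")
  invisible(x)
}
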