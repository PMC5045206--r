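#' Specification for a synthetic paired-alignment dataset
#'
#' Describes a family of TFs falling into subfamilies (a star of clades, the
#' simplest topology exhibiting shared ancestry) whose members carry, at a
#' set of planted column pairs, subfamily-specific nucleotide-amino-acid
#' combinations -- the signature of genuine recognition coupling. All other
#' columns evolve independently of the pairing. The defaults mirror the
#' scale of a real family-wide analysis: 5 subfamilies, a 74-column
#' DNA-binding-domain block and 20-column sites.
#'
#' @param n_subfamilies number of clades (default 5).
#' @param records_per_subfamily records per clade (default 40).
#' @param n_protein_cols,n_site_cols alignment widths (defaults 74 and 20).
#' @param planted_pairs data frame with columns `site_col`, `prot_col`
#'   (1-based) or `NULL` for the default 6 pairs spread over the block;
#'   an empty data frame plants nothing (null datasets).
#' @param coupling_tables list (one per planted pair) of data frames with
#'   columns `nt`, `aa`, one row per subfamily; `NULL` for defaults that
#'   assign every subfamily a distinct combination.
#' @param background_entropy number of distinct symbols in each background
#'   column's repertoire (default 3).
#' @param noise_rate probability that a record deviates from its subfamily's
#'   planted combination (default 0.1).
#' @param within_subfamily_divergence probability that a background-column
#'   cell is redrawn from the column profile instead of copying the clade
#'   ancestor (default 0.2).
#' @param dyad_symmetry if `TRUE`, every planted site column `j` gets a
#'   complementary partner column at `n_site_cols + 1 - j` (0-based indices
#'   of partners sum to `n_site_cols - 1`), mimicking palindromic operators.
#'   Off by default.
#' @param seed integer RNG seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subfamilies = 5, records_per_subfamily = 40,
                           n_protein_cols = 74, n_site_cols = 20,
                           planted_pairs = NULL, coupling_tables = NULL,
                           background_entropy = 3, noise_rate = 0.1,
                           within_subfamily_divergence = 0.2,
                           dyad_symmetry = FALSE, seed = 1) {
  if (noise_rate < 0 || noise_rate > 1)
    tfsc_error("noise_rate must be in [0, 1]", "validation_error")
  if (within_subfamily_divergence < 0 || within_subfamily_divergence > 1)
    tfsc_error("within_subfamily_divergence must be in [0, 1]", "validation_error")
  if (n_subfamilies < 1 || records_per_subfamily < 1)
    tfsc_error("need >= 1 subfamily and >= 1 record per subfamily", "validation_error")
  if (is.null(planted_pairs)) {
    planted_pairs <- data.frame(
      site_col = round(seq(2, n_site_cols - 1, length.out = 6)),
      prot_col = round(seq(5, n_protein_cols - 4, length.out = 6)))
  }
  planted_pairs <- as.data.frame(planted_pairs)
  if (nrow(planted_pairs)) {
    if (any(planted_pairs$site_col < 1 | planted_pairs$site_col > n_site_cols) ||
        any(planted_pairs$prot_col < 1 | planted_pairs$prot_col > n_protein_cols))
      tfsc_error("planted pair indices out of range", "validation_error")
    if (anyDuplicated(planted_pairs$site_col) || anyDuplicated(planted_pairs$prot_col))
      tfsc_error("planted site/protein columns must be distinct", "validation_error")
  }
  if (is.null(coupling_tables)) {
    residues <- c("E", "K", "D", "A", "Q", "M", "V", "R")
    coupling_tables <- lapply(seq_len(nrow(planted_pairs)), function(t) {
      k <- seq_len(n_subfamilies)
      data.frame(nt = NT_ALPHABET[(k + t - 2L) %% 4L + 1L],
                 aa = residues[(k - 1L) %% length(residues) + 1L])
    })
  }
  if (length(coupling_tables) != nrow(planted_pairs))
    tfsc_error("one coupling table per planted pair required", "validation_error")
  for (tab in coupling_tables) {
    if (nrow(tab) != n_subfamilies)
      tfsc_error("coupling table must have one row per subfamily", "validation_error")
    if (n_subfamilies >= 2 && nrow(unique(tab)) < 2)
      tfsc_error("coupling table must assign distinct combinations to >= 2 subfamilies",
                 "validation_error")
  }
  structure(list(n_subfamilies = n_subfamilies,
                 records_per_subfamily = records_per_subfamily,
                 n_protein_cols = n_protein_cols, n_site_cols = n_site_cols,
                 planted_pairs = planted_pairs, coupling_tables = coupling_tables,
                 background_entropy = background_entropy, noise_rate = noise_rate,
                 within_subfamily_divergence = within_subfamily_divergence,
                 dyad_symmetry = dyad_symmetry, seed = seed),
            class = "synthetic_spec")
}

# One background column: repertoire of `entropy` symbols with a Dirichlet(1)
# profile; each clade ancestor draws from the profile; records copy their
# ancestor or, with probability `div`, redraw from the profile.
#' @noRd
background_column <- function(alphabet, entropy, subfam, div) {
  m <- min(entropy, length(alphabet))
  rep_syms <- sample(alphabet, m)
  g <- stats::rgamma(m, 1)
  probs <- g / sum(g)
  anc <- sample(rep_syms, max(subfam), replace = TRUE, prob = probs)
  x <- anc[subfam]
  redraw <- stats::runif(length(x)) < div
  if (any(redraw)) x[redraw] <- sample(rep_syms, sum(redraw), replace = TRUE, prob = probs)
  x
}

#' Generate a paired alignment set with planted couplings
#'
#' Emits one TF and one site per record (ids `tf_###` / `site_###`, a
#' one-to-one pairing), deterministic given the spec's seed. Background
#' columns carry subfamily structure (clade ancestors plus within-clade
#' drift) but are drawn independently on the protein and site sides, so any
#' cross-side correlation they show is pure phylogenetic trace; planted
#' columns carry their subfamily's nucleotide-amino-acid combination except
#' with probability `noise_rate`, where base and residue are redrawn
#' independently.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `set` (a `paired_alignment_set`, weights 1) and
#'   `truth` (class `truth_table`: `planted` data frame, per-record
#'   `subfamily`, and the spec).
#' @export
generate_coupled_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  S <- spec$n_subfamilies
  n <- S * spec$records_per_subfamily
  subfam <- rep(seq_len(S), each = spec$records_per_subfamily)
  prot <- matrix("", n, spec$n_protein_cols)
  site <- matrix("", n, spec$n_site_cols)
  div <- spec$within_subfamily_divergence
  for (i in seq_len(spec$n_protein_cols))
    prot[, i] <- background_column(AA_ALPHABET, spec$background_entropy, subfam, div)
  for (j in seq_len(spec$n_site_cols))
    site[, j] <- background_column(NT_ALPHABET, spec$background_entropy, subfam, div)
  planted <- spec$planted_pairs
  for (t in seq_len(nrow(planted))) {
    tab <- spec$coupling_tables[[t]]
    i <- planted$prot_col[t]
    j <- planted$site_col[t]
    nt <- tab$nt[subfam]
    aa <- tab$aa[subfam]
    noisy <- stats::runif(n) < spec$noise_rate
    if (any(noisy)) {
      nt[noisy] <- sample(NT_ALPHABET, sum(noisy), replace = TRUE)
      aa[noisy] <- sample(unique(tab$aa), sum(noisy), replace = TRUE)
    }
    site[, j] <- nt
    prot[, i] <- aa
  }
  if (spec$dyad_symmetry && nrow(planted)) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (j in planted$site_col) {
      j2 <- spec$n_site_cols + 1L - j
      if (!(j2 %in% planted$site_col)) site[, j2] <- comp[site[, j]]
    }
  }
  ids <- sprintf("%03d", seq_len(n))
  set <- paired_alignment_set(paste0("tf_", ids), paste0("site_", ids),
                              apply(prot, 1, paste, collapse = ""),
                              apply(site, 1, paste, collapse = ""))
  truth <- structure(list(planted = planted, subfamily = subfam, spec = spec),
                     class = "truth_table")
  list(set = set, truth = truth)
}

#' Score recovery of planted pairs
#'
#' Compares the pairs selected by the Bernoulli cutoff with the planted
#' ground truth: precision (fraction of selected pairs that were planted),
#' recall (fraction of planted pairs selected), and the Z-rank of every
#' planted pair.
#'
#' @param result a `correlation_result` from [analyze_paired_set()].
#' @param truth the matching `truth_table`.
#' @return list with `precision`, `recall`, `n_overlap`, and `ranks`
#'   (data frame: planted pair, its rank in the Z ranking, selected flag;
#'   rank `NA` if the pair was not assessable).
#' @export
recovery_report <- function(result, truth) {
  planted <- truth$planted
  key <- function(j, i) paste(j, i, sep = ",")
  sel <- key(result$selected$site_col, result$selected$prot_col)
  all_ranked <- key(result$ranked$site_col, result$ranked$prot_col)
  pk <- key(planted$site_col, planted$prot_col)
  ranks <- match(pk, all_ranked)
  overlap <- sum(pk %in% sel)
  list(precision = if (length(sel)) overlap / length(sel) else NA_real_,
       recall = if (nrow(planted)) overlap / nrow(planted) else NA_real_,
       n_overlap = overlap,
       ranks = data.frame(site_col = planted$site_col,
                          prot_col = planted$prot_col,
                          rank = ranks, selected = pk %in% sel))
}

#' Write a synthetic dataset to disk
#'
#' Emits `tf.fasta`, `sites.fasta`, `pairs.tsv` and `truth.json` under
#' `dir`, in the exact formats [read_paired_alignments()] consumes.
#'
#' @param dataset output of [generate_coupled_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("tf.fasta", "sites.fasta", "pairs.tsv", "truth.json"))
  write_paired_alignments(dataset$set, paths[1L], paths[2L], paths[3L])
  jsonlite::write_json(list(planted = dataset$truth$planted,
                            subfamily = dataset$truth$subfamily),
                       paths[4L], auto_unbox = TRUE, digits = NA)
  invisible(stats::setNames(as.list(paths), c("tf", "sites", "pairs", "truth")))
}
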