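#' Configuration for a correlation-pipeline run
#'
#' @param tf_fasta,site_fasta,pairs_tsv input paths
#'   (see [read_paired_alignments()]).
#' @param out_dir output directory for result artifacts.
#' @param kappa pseudocount fraction (default 0.5).
#' @param blosum substitution matrix name (default "BLOSUM45").
#' @param n_shuffles permutation count for the null (default 10000).
#' @param seed integer RNG seed.
#' @param site_weights `"gsc"` or `"uniform"` weighting of the site side.
#' @param trace_correction apply the phylogenetic-trace correction.
#' @param chi2_cutoff highlight threshold for contingency reports.
#' @param base log base for MI.
#' @return object of class `run_config`.
#' @export
run_config <- function(tf_fasta, site_fasta, pairs_tsv, out_dir,
                       kappa = 0.5, blosum = "BLOSUM45", n_shuffles = 10000,
                       seed = 1, site_weights = c("gsc", "uniform"),
                       trace_correction = TRUE, chi2_cutoff = 50,
                       base = exp(1)) {
  site_weights <- match.arg(site_weights)
  if (kappa < 0 || n_shuffles < 2 || chi2_cutoff < 0 || base <= 1)
    tfsc_error("configuration parameter out of range", "configuration_error")
  structure(list(tf_fasta = tf_fasta, site_fasta = site_fasta,
                 pairs_tsv = pairs_tsv, out_dir = out_dir, kappa = kappa,
                 blosum = blosum, n_shuffles = n_shuffles, seed = seed,
                 site_weights = site_weights,
                 trace_correction = trace_correction,
                 chi2_cutoff = chi2_cutoff, base = base),
            class = "run_config")
}

#' Run the full correlation pipeline
#'
#' read -> deduplicate -> NJ trees & GSC weights -> MI matrix -> permutation
#' null -> trace correction -> Z-scores -> Bernoulli cutoff, then writes all
#' artifacts under `config$out_dir`: `results.json` (parameters, ranked
#' pairs, B-curve, k*), `heatmap.tsv` (Z matrix), `b_curve.tsv`,
#' `conservation_vs_z.tsv`, and one contingency report per selected pair
#' under `contingency/`. Identical configs (including seed) give
#' byte-identical `results.json`. Stages are logged to stderr.
#'
#' @param config a [run_config()].
#' @return the `correlation_result`, invisibly, with the weighted set
#'   attached as attribute `set`.
#' @export
run_correlation_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  message("[read] ", config$tf_fasta, " + ", config$site_fasta)
  set <- read_paired_alignments(config$tf_fasta, config$site_fasta, config$pairs_tsv)
  n0 <- n_records(set)
  set <- deduplicate_pairs(set)
  message(sprintf("[dedup] %d records -> %d unique pairs", n0, n_records(set)))
  message(sprintf("[weights] GSC (TF) / %s (sites)", config$site_weights))
  set <- weight_paired_set(set, config$site_weights)
  model <- substitution_model(config$blosum, config$kappa)
  message(sprintf("[analyze] %s, kappa = %g, %d shuffles, seed %d",
                  config$blosum, config$kappa, config$n_shuffles, config$seed))
  result <- analyze_paired_set(set, model, config$n_shuffles, config$seed,
                               config$base, config$trace_correction)
  message(sprintf("[b-cutoff] k* = %d, min log10 p = %.2f",
                  result$k_star, result$log10_p_min))
  write_result_artifacts(result, set, model, config)
  attr(result, "set") <- set
  invisible(result)
}

#' @noRd
write_result_artifacts <- function(result, set, model, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  header <- paste0("# protein columns are 1-based over the alignment block; ",
                   "site columns are listed 1-based (site_col) and 0-based (site_col0); ",
                   "dyad-symmetric site partners satisfy site_col0 + site_col0' = ",
                   set$n_site_cols - 1)
  ranked <- result$ranked
  ranked$site_col0 <- ranked$site_col - 1L
  out <- list(
    parameters = config[setdiff(names(config), "out_dir")],
    trace_alpha = result$params$trace_alpha,
    trace_beta = result$params$trace_beta,
    n_assessable_pairs = nrow(ranked),
    k_star = result$k_star,
    log10_p_min = result$log10_p_min,
    ranked_pairs = ranked,
    b_curve_log10 = result$log10_curve)
  jsonlite::write_json(out, file.path(config$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  hm <- file.path(config$out_dir, "heatmap.tsv")
  writeLines(header, hm)
  z <- result$Z
  tab <- cbind(data.frame(site_col = seq_len(nrow(z)),
                          site_col0 = seq_len(nrow(z)) - 1L),
               as.data.frame(z))
  names(tab)[-(1:2)] <- paste0("p", seq_len(ncol(z)))
  suppressWarnings(utils::write.table(tab, hm, sep = "\t", quote = FALSE,
                                      row.names = FALSE, na = "NA", append = TRUE))

  bc <- file.path(config$out_dir, "b_curve.tsv")
  writeLines(header, bc)
  suppressWarnings(utils::write.table(
    data.frame(k = seq_along(result$log10_curve), log10_p = result$log10_curve),
    bc, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))

  cz <- file.path(config$out_dir, "conservation_vs_z.tsv")
  writeLines(header, cz)
  suppressWarnings(utils::write.table(
    conservation_vs_z_table(result, set, model),
    cz, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))

  if (result$k_star > 0) {
    cdir <- file.path(config$out_dir, "contingency")
    dir.create(cdir, showWarnings = FALSE)
    for (r in seq_len(result$k_star)) {
      j <- result$selected$site_col[r]
      i <- result$selected$prot_col[r]
      write_contingency_report(set, i, j, model,
                               file.path(cdir, sprintf("pair_j%d_i%d.txt", j, i)),
                               chi2_cutoff = config$chi2_cutoff,
                               base = config$base)
    }
  }
  invisible(NULL)
}

#' Export a plain-text contingency report for one column pair
#'
#' Three blocks -- weighted counts, chi-squared summands, MI summands --
#' rows = residues, columns = bases. Chi-squared summands at or above the
#' highlight cutoff are marked with `*`.
#'
#' @param set a weighted `paired_alignment_set`.
#' @param i protein column, `j` site column (1-based).
#' @param j site column.
#' @param model a [substitution_model()].
#' @param path output file.
#' @param chi2_cutoff highlight threshold (default 50).
#' @param base log base for MI summands.
#' @return invisibly, the `column_pair_stats`.
#' @export
write_contingency_report <- function(set, i, j, model, path,
                                     chi2_cutoff = 50, base = exp(1)) {
  st <- column_pair_stats(set, i, j, model, base, chi2_cutoff)
  fmt_block <- function(m, digits = 4) {
    rows <- apply(round(m, digits), 1, paste, collapse = "\t")
    paste0(rownames(m), "\t", rows)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# column pair: site_col %d (0-based %d), prot_col %d", j, j - 1L, i),
    sprintf("# N_effective = %.6g, I = %.6g, chi2 highlight cutoff = %g",
            st$N_effective, st$I, chi2_cutoff),
    "", "## weighted counts", paste0("\t", paste(NT_ALPHABET, collapse = "\t")),
    fmt_block(st$N_ij),
    "", "## chi2 summands (* at/above cutoff, +/- over/under-represented)",
    paste0("\t", paste(NT_ALPHABET, collapse = "\t")),
    paste0(rownames(st$N_ij), "\t",
           apply(matrix(paste0(round(st$chi2$summand, 2), st$chi2$direction,
                               ifelse(st$chi2$highlight, "*", "")),
                        nrow(st$N_ij)), 1, paste, collapse = "\t")),
    "", "## MI summands", paste0("\t", paste(NT_ALPHABET, collapse = "\t")),
    fmt_block(st$mi_summand, 6)), con)
  invisible(st)
}

#' Enrichment of structural contacts among selected pairs
#'
#' One-sided Fisher exact test (hypergeometric upper tail) of the overlap
#' between the correlated column pairs and an independently derived list of
#' contacting column pairs, over a stated universe of column pairs. The
#' universe size is an explicit argument because it determines the test's
#' stringency.
#'
#' @param selected_pairs,contact_pairs data frames with columns `site_col`,
#'   `prot_col` identifying column pairs (any consistent convention).
#' @param total_pairs size of the (site column, protein column) universe.
#' @return list with `overlap`, `p_value`, and the 2x2 `table`
#'   (both / selected-only / contact-only / neither).
#' @export
contact_enrichment_test <- function(selected_pairs, contact_pairs, total_pairs) {
  key <- function(df) paste(df$site_col, df$prot_col, sep = ",")
  sel <- unique(key(selected_pairs))
  con <- unique(key(contact_pairs))
  k <- length(intersect(sel, con))
  ns <- length(sel)
  nc <- length(con)
  if (k > min(ns, nc) || total_pairs < length(union(sel, con)))
    tfsc_error("overlap exceeds set sizes or universe too small", "validation_error")
  tab <- matrix(c(k, ns - k, nc - k, total_pairs - ns - nc + k), 2, 2,
                dimnames = list(selected = c("yes", "no"),
                                contact = c("yes", "no")))
  p <- stats::phyper(k - 1, nc, total_pairs - nc, ns, lower.tail = FALSE)
  list(overlap = k, p_value = p, table = tab)
}

#' Conservation-versus-Z table
#'
#' One row per assessable column pair: the protein column's information
#' content (bits, computed from the weighted, pseudocounted frequencies) and
#' the pair's Z-score, with the selected flag. Correlated positions tend to
#' be moderately conserved -- fully conserved columns carry no covariation
#' signal.
#'
#' @param result a `correlation_result`.
#' @param set the analysed `paired_alignment_set`.
#' @param model the [substitution_model()] used.
#' @return data frame: `site_col`, `site_col0`, `prot_col`, `IC_bits`,
#'   `Z`, `selected`.
#' @export
conservation_vs_z_table <- function(result, set, model) {
  ic <- vapply(seq_len(set$n_protein_cols), function(i) {
    a <- substr(set$tf_row, i, i)
    keep <- a != GAP_CHAR
    if (!any(keep)) return(NA_real_)
    N <- tapply(set$pair_weight[keep], factor(a[keep], AA_ALPHABET), sum)
    N[is.na(N)] <- 0
    column_information_content(positional_frequency(N, sum(N), model))
  }, numeric(1))
  ranked <- result$ranked
  sel_key <- paste(result$selected$site_col, result$selected$prot_col)
  data.frame(site_col = ranked$site_col, site_col0 = ranked$site_col - 1L,
             prot_col = ranked$prot_col, IC_bits = ic[ranked$prot_col],
             Z = ranked$Z,
             selected = paste(ranked$site_col, ranked$prot_col) %in% sel_key)
}
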