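#' Construct a paired TF/site alignment set
#'
#' A paired alignment set holds one record per (transcription factor, binding
#' site) pairing: the gapped amino-acid row of the TF's DNA-binding domain and
#' the gapped nucleotide row of the site it binds. One TF may pair with
#' several sites and vice versa, so TF/site rows may repeat across records.
#' Each record carries a pair weight `w(rs) = w(r) * w(s)`, the product of the
#' per-sequence weights of its TF and its site; until weighting has run all
#' weights are 1.
#'
#' @param tf_id,site_id character vectors naming each record's TF and site.
#' @param tf_row,site_row gapped aligned rows; residues over the 20 standard
#'   amino acids, bases over ACGT, `-` for gaps. Case-insensitive.
#' @param tf_weight,site_weight optional named weight vectors (one entry per
#'   distinct id); default 1 for every sequence.
#' @return An object of class `paired_alignment_set`.
#' @seealso [read_paired_alignments()], [assign_pair_weights()]
#' @export
paired_alignment_set <- function(tf_id, site_id, tf_row, site_row,
                                 tf_weight = NULL, site_weight = NULL) {
  n <- length(tf_id)
  stopifnot(length(site_id) == n, length(tf_row) == n, length(site_row) == n)
  if (n == 0L) tfsc_error("paired alignment set must contain >= 1 record", "alignment_shape_error")
  tf_row <- toupper(tf_row)
  site_row <- toupper(site_row)
  if (length(unique(nchar(tf_row))) > 1L)
    tfsc_error("TF alignment rows have unequal lengths", "alignment_shape_error")
  if (length(unique(nchar(site_row))) > 1L)
    tfsc_error("site alignment rows have unequal lengths", "alignment_shape_error")
  validate_alphabet(tf_row, AA_ALPHABET, "amino-acid")
  validate_alphabet(site_row, NT_ALPHABET, "nucleotide")
  if (is.null(tf_weight)) {
    tf_weight <- stats::setNames(rep(1, length(unique(tf_id))), unique(tf_id))
  }
  if (is.null(site_weight)) {
    site_weight <- stats::setNames(rep(1, length(unique(site_id))), unique(site_id))
  }
  if (anyNA(tf_weight[tf_id]))
    tfsc_error("TF id missing from weight vector", "reference_error")
  if (anyNA(site_weight[site_id]))
    tfsc_error("site id missing from weight vector", "reference_error")
  structure(list(
    tf_id = unname(as.character(tf_id)),
    site_id = unname(as.character(site_id)),
    tf_row = unname(tf_row),
    site_row = unname(site_row),
    tf_weight = tf_weight,
    site_weight = site_weight,
    pair_weight = unname(tf_weight[tf_id] * site_weight[site_id]),
    n_protein_cols = unname(nchar(tf_row[1L])),
    n_site_cols = unname(nchar(site_row[1L]))
  ), class = "paired_alignment_set")
}

#' @export
print.paired_alignment_set <- function(x, ...) {
  cat(sprintf(paste0("paired_alignment_set: %d records (%d TFs x %d sites), ",
                     "%d protein cols, %d site cols, total weight N = %.4g\n"),
              n_records(x), length(unique(x$tf_id)), length(unique(x$site_id)),
              x$n_protein_cols, x$n_site_cols, total_weight(x)))
  invisible(x)
}

#' Number of records in a paired alignment set
#' @param set a `paired_alignment_set`.
#' @return integer record count.
#' @export
n_records <- function(set) length(set$tf_id)

#' Total pair weight N of a paired alignment set
#'
#' The summed pair weight over all records; with unit weights this equals the
#' record count. It plays the role of the number of observed sequences in the
#' pseudocounted frequency estimates.
#' @param set a `paired_alignment_set`.
#' @return a nonnegative number.
#' @export
total_weight <- function(set) sum(set$pair_weight)

#' Read paired TF/site alignments from FASTA plus a pairing table
#'
#' The pairing table is a two-column TSV (`tf_id<TAB>site_id`, `#` comments
#' allowed, no header); each row becomes one record of the returned set.
#' Sequences are parsed case-insensitively and normalised to upper case;
#' `U` is rejected (DNA alphabet only). Duplicate FASTA ids are an error
#' rather than being silently suffixed, since pairing integrity depends on
#' unique ids.
#'
#' @param tf_fasta_path,site_fasta_path paths to the gapped FASTA alignments.
#' @param pairing_table_path path to the pairing TSV.
#' @return A `paired_alignment_set` with all weights 1.
#' @export
read_paired_alignments <- function(tf_fasta_path, site_fasta_path, pairing_table_path) {
  tf <- Biostrings::readBStringSet(tf_fasta_path)
  sites <- Biostrings::readBStringSet(site_fasta_path)
  tf_ids <- sub("\\s.*$", "", names(tf))
  site_ids <- sub("\\s.*$", "", names(sites))
  if (anyDuplicated(tf_ids))
    tfsc_error("duplicate ids in TF FASTA", "reference_error")
  if (anyDuplicated(site_ids))
    tfsc_error("duplicate ids in site FASTA", "reference_error")
  tf_seq <- stats::setNames(as.character(tf), tf_ids)
  site_seq <- stats::setNames(as.character(sites), site_ids)
  pairs <- utils::read.table(pairing_table_path, sep = "\t", header = FALSE,
                             comment.char = "#", stringsAsFactors = FALSE,
                             col.names = c("tf_id", "site_id"),
                             colClasses = "character")
  if (nrow(pairs) == 0L)
    tfsc_error("empty pairing table", "reference_error")
  missing_tf <- setdiff(pairs$tf_id, tf_ids)
  missing_site <- setdiff(pairs$site_id, site_ids)
  if (length(missing_tf) || length(missing_site))
    tfsc_error(sprintf("pairing table references unknown ids: %s",
                       paste(c(missing_tf, missing_site), collapse = " ")),
               "reference_error")
  paired_alignment_set(pairs$tf_id, pairs$site_id,
                       tf_seq[pairs$tf_id], site_seq[pairs$site_id])
}

#' Write a paired alignment set to FASTA files and a pairing table
#'
#' Inverse of [read_paired_alignments()]: reading the three emitted files
#' reproduces the records exactly (weights reset to 1).
#'
#' @param set a `paired_alignment_set`.
#' @param tf_fasta_path,site_fasta_path,pairing_table_path output paths.
#' @return invisibly, the set.
#' @export
write_paired_alignments <- function(set, tf_fasta_path, site_fasta_path, pairing_table_path) {
  keep_tf <- !duplicated(set$tf_id)
  keep_site <- !duplicated(set$site_id)
  tf <- Biostrings::BStringSet(stats::setNames(set$tf_row[keep_tf], set$tf_id[keep_tf]))
  sites <- Biostrings::BStringSet(stats::setNames(set$site_row[keep_site], set$site_id[keep_site]))
  Biostrings::writeXStringSet(tf, tf_fasta_path)
  Biostrings::writeXStringSet(sites, site_fasta_path)
  utils::write.table(data.frame(set$tf_id, set$site_id), pairing_table_path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(set)
}

#' Drop duplicate TF-site string pairs
#'
#' Exactly one record is retained per distinct `(tf_row, site_row)` string
#' pair (the first occurrence, order otherwise preserved). Redundant pairs
#' arise when near-identical strains contribute the same domain/site pair;
#' they would otherwise inflate the weighted counts.
#'
#' @param set a `paired_alignment_set`.
#' @return the deduplicated `paired_alignment_set`.
#' @export
deduplicate_pairs <- function(set) {
  key <- paste(set$tf_row, set$site_row, sep = "\r")
  keep <- !duplicated(key)
  paired_alignment_set(set$tf_id[keep], set$site_id[keep],
                       set$tf_row[keep], set$site_row[keep],
                       set$tf_weight, set$site_weight)
}

# Integer encodings of both alignments, for the compiled core.
#' @noRd
encode_set <- function(set) {
  list(prot = encode_rows(set$tf_row, AA_ALPHABET),
       site = encode_rows(set$site_row, NT_ALPHABET),
       w_tf = unname(set$tf_weight[set$tf_id]),
       w_site = unname(set$site_weight[set$site_id]))
}
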