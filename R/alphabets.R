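# Canonical symbol orders used throughout: 20 standard residues, 4 bases.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
NT_ALPHABET <- c("A", "C", "G", "T")
GAP_CHAR <- "-"

#' @noRd
tfsc_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "tfsitecoev_error", "error", "condition")))
}

# Split aligned rows into a character matrix (records x columns).
#' @noRd
rows_to_matrix <- function(rows) {
  if (length(unique(nchar(rows))) > 1L)
    tfsc_error("aligned rows have unequal lengths", "alignment_shape_error")
  do.call(rbind, strsplit(rows, "", fixed = TRUE))
}

# Integer-encode aligned rows against an alphabet: 0-based codes, -1 for gap.
#' @noRd
encode_rows <- function(rows, alphabet) {
  m <- rows_to_matrix(rows)
  codes <- match(m, alphabet) - 1L
  codes[m == GAP_CHAR] <- -1L
  if (anyNA(codes))
    tfsc_error(sprintf("character(s) outside alphabet {%s,-}: %s",
                       paste(alphabet, collapse = ""),
                       paste(unique(m[is.na(codes) & m != GAP_CHAR]), collapse = " ")),
               "alphabet_error")
  matrix(codes, nrow = nrow(m))
}

#' @noRd
validate_alphabet <- function(rows, alphabet, what) {
  chars <- unique(unlist(strsplit(rows, "", fixed = TRUE)))
  bad <- setdiff(chars, c(alphabet, GAP_CHAR))
  if (length(bad))
    tfsc_error(sprintf("invalid %s character(s): %s", what, paste(bad, collapse = " ")),
               "alphabet_error")
  invisible(TRUE)
}
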