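#' Build a position weight matrix from aligned sites
#'
#' Additive log2-odds PWM: per position,
#' `log2( (count + pseudocount) / (n + 4 * pseudocount) / background )`.
#' Score thresholds are dialect-specific to the PWM construction -- a
#' threshold from another scanner's score scale does not transfer; the
#' reproducible content of a scan is the site geometry downstream.
#'
#' @param sites character vector of >= 2 equal-length ACGT sequences.
#' @param background background base frequencies in ACGT order
#'   (default uniform).
#' @param pseudocount per-cell pseudocount (default 0.5).
#' @return object of class `pwm`: 4 x L log2-odds matrix (rows ACGT) with
#'   the inputs as attributes.
#' @export
build_pwm <- function(sites, background = rep(0.25, 4), pseudocount = 0.5) {
  if (length(sites) < 2L) tfsc_error("need >= 2 sites", "size_error")
  sites <- toupper(sites)
  if (length(unique(nchar(sites))) > 1L)
    tfsc_error("sites have unequal lengths", "alignment_shape_error")
  validate_alphabet(sites, NT_ALPHABET, "nucleotide")
  if (any(grepl("-", sites, fixed = TRUE)))
    tfsc_error("gaps not allowed in PWM input", "alphabet_error")
  m <- rows_to_matrix(sites)
  counts <- apply(m, 2, function(col) table(factor(col, NT_ALPHABET)))
  freq <- sweep(counts + pseudocount, 2, length(sites) + 4 * pseudocount, "/")
  lo <- log2(freq / background)
  dimnames(lo) <- list(NT_ALPHABET, NULL)
  structure(lo, class = "pwm", background = background, pseudocount = pseudocount)
}

#' @noRd
revcomp <- function(x) chartr("ACGT", "TGCA", sapply(lapply(strsplit(x, ""), rev), paste, collapse = ""))

#' @noRd
pwm_score <- function(pwm, window) {
  idx <- match(strsplit(window, "", fixed = TRUE)[[1L]], NT_ALPHABET)
  if (anyNA(idx)) return(-Inf)
  sum(pwm[cbind(idx, seq_along(idx))])
}

#' Scan the upstream region of a gene with a PWM
#'
#' Scores every window of both strands in the region
#' `[gene_start - upstream, gene_start + downstream)` (forward-strand
#' 0-based coordinates, clipped to the contig) and reports windows at or
#' above `threshold`. Reverse-strand hits are reported at their
#' forward-strand interval.
#'
#' @param sequence contig sequence (ACGT string).
#' @param gene_start 0-based translation start coordinate.
#' @param pwm a [build_pwm()] object.
#' @param threshold minimum score.
#' @param upstream,downstream region extent around the start
#'   (defaults 400 and 50).
#' @param contig contig id recorded in the calls (default "contig").
#' @return data frame of site calls: `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `score`, `seq`, and a `passed_promoter_filter`
#'   column initialised to `NA` (set by
#'   [promoter_colocalization_filter()]).
#' @export
scan_upstream <- function(sequence, gene_start, pwm, threshold,
                          upstream = 400, downstream = 50, contig = "contig") {
  sequence <- toupper(sequence)
  L <- ncol(pwm)
  lo <- max(0, gene_start - upstream)
  hi <- min(nchar(sequence), gene_start + downstream)
  calls <- list()
  if (hi - lo >= L) {
    for (s in lo:(hi - L)) {
      win <- substr(sequence, s + 1L, s + L)
      for (strand in c("+", "-")) {
        sc <- pwm_score(pwm, if (strand == "+") win else revcomp(win))
        if (sc >= threshold) {
          calls[[length(calls) + 1L]] <-
            data.frame(contig = contig, start = s, end = s + L, strand = strand,
                       score = sc, seq = win, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(calls)) do.call(rbind, calls)
         else data.frame(contig = character(), start = integer(), end = integer(),
                         strand = character(), score = numeric(), seq = character(),
                         stringsAsFactors = FALSE)
  out$passed_promoter_filter <- rep(NA, nrow(out))
  out
}

#' Promoter geometry for the sigma70 co-localization filter
#'
#' The binding sites of the regulators considered here sit between the -35
#' and -10 boxes of sigma70 promoters with an unusually long 19-20 bp spacer
#' (usual spacers are 16-17 bp), and the distance from the site center to
#' the 3' end of the -35 box is fixed within a subfamily: 7 bp for 21-bp
#' sites, 8 bp for 22-bp sites.
#'
#' @param minus35,minus10 consensus hexamers (defaults TTGACA / TATAAT).
#' @param spacer_range allowed spacer lengths in bp (default 19:20).
#' @param max_mismatch_per_box mismatches tolerated in each box (default 2).
#' @param center_to_minus35 named map from site length to required
#'   center-to-box distance in bp (default `c("21" = 7, "22" = 8)`).
#' @return object of class `promoter_geometry`.
#' @export
promoter_geometry <- function(minus35 = "TTGACA", minus10 = "TATAAT",
                              spacer_range = 19:20, max_mismatch_per_box = 2,
                              center_to_minus35 = c("21" = 7, "22" = 8)) {
  structure(list(minus35 = toupper(minus35), minus10 = toupper(minus10),
                 spacer_range = spacer_range,
                 max_mismatch_per_box = max_mismatch_per_box,
                 center_to_minus35 = center_to_minus35),
            class = "promoter_geometry")
}

#' @noRd
hexamer_mismatches <- function(sequence, pattern, at) {
  sub <- substr(sequence, at + 1L, at + nchar(pattern))
  if (nchar(sub) < nchar(pattern)) return(Inf)
  sum(strsplit(sub, "")[[1L]] != strsplit(pattern, "")[[1L]])
}

#' Find candidate sigma70 promoters
#'
#' Reports every placement, on both strands, where the -35 and -10 boxes
#' each match their consensus within `max_mismatch_per_box` and the spacer
#' between them lies in `spacer_range`. Coordinates are forward-strand
#' 0-based half-open; `m35_threeprime` is the coordinate of the 3'-most
#' base of the -35 box on the promoter's own strand.
#'
#' @param sequence contig sequence (ACGT string).
#' @param geometry a [promoter_geometry()].
#' @return data frame: `strand`, `m35_start`, `m35_end`, `m10_start`,
#'   `m10_end`, `spacer`, `m35_threeprime`.
#' @export
find_sigma70_promoters <- function(sequence, geometry = promoter_geometry()) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  b35 <- nchar(geometry$minus35)
  b10 <- nchar(geometry$minus10)
  hits <- list()
  scan_strand <- function(seq, strand) {
    for (s in 0:(nchar(seq) - b35)) {
      if (hexamer_mismatches(seq, geometry$minus35, s) > geometry$max_mismatch_per_box) next
      for (sp in geometry$spacer_range) {
        t <- s + b35 + sp
        if (t + b10 > nchar(seq)) next
        if (hexamer_mismatches(seq, geometry$minus10, t) > geometry$max_mismatch_per_box) next
        if (strand == "+") {
          hits[[length(hits) + 1L]] <<- data.frame(
            strand = "+", m35_start = s, m35_end = s + b35,
            m10_start = t, m10_end = t + b10, spacer = sp,
            m35_threeprime = s + b35 - 1L)
        } else {
          # map reverse-strand coordinates back to the forward strand
          hits[[length(hits) + 1L]] <<- data.frame(
            strand = "-", m35_start = n - (s + b35), m35_end = n - s,
            m10_start = n - (t + b10), m10_end = n - t, spacer = sp,
            m35_threeprime = n - (s + b35))
        }
      }
    }
  }
  scan_strand(sequence, "+")
  if (n >= b35) scan_strand(revcomp(sequence), "-")
  if (!length(hits))
    return(data.frame(strand = character(), m35_start = integer(),
                      m35_end = integer(), m10_start = integer(),
                      m10_end = integer(), spacer = integer(),
                      m35_threeprime = integer(), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Flag site calls lacking a co-localized sigma70 promoter
#'
#' A call passes the filter iff some candidate promoter has (a) a spacer in
#' the allowed range and (b) `|center(site) - 3'-end(-35 box)|` equal to the
#' distance mapped for that site length, where `center = start + (L-1)/2`
#' (fractional for even L; the distance is rounded half-up before the
#' comparison). Calls failing the filter are the likely false positives of
#' a PWM scan: sites of these activator families function from within the
#' promoter, so a candidate without the promoter context is suspect.
#'
#' @param calls data frame from [scan_upstream()].
#' @param promoters data frame from [find_sigma70_promoters()] on the same
#'   contig/coordinate frame.
#' @param geometry a [promoter_geometry()].
#' @return `calls` with `passed_promoter_filter` set.
#' @export
promoter_colocalization_filter <- function(calls, promoters,
                                           geometry = promoter_geometry()) {
  if (!nrow(calls)) return(calls)
  lens <- calls$end - calls$start
  known <- names(geometry$center_to_minus35)
  if (!all(as.character(lens) %in% known))
    tfsc_error(sprintf("no center-to-minus35 distance mapped for site length(s): %s",
                       paste(setdiff(unique(lens), known), collapse = " ")),
               "configuration_error")
  ok_spacer <- promoters$spacer %in% geometry$spacer_range
  passed <- logical(nrow(calls))
  for (r in seq_len(nrow(calls))) {
    L <- lens[r]
    center <- calls$start[r] + (L - 1) / 2
    want <- geometry$center_to_minus35[[as.character(L)]]
    d <- floor(abs(center - promoters$m35_threeprime) + 0.5) # round half-up
    passed[r] <- any(ok_spacer & d == want)
  }
  calls$passed_promoter_filter <- passed
  calls
}
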