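Package: tfsitecoev
Title: Coevolution of Transcription Factors and Their DNA Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects statistically significant covariation between columns of
    a transcription-factor DNA-binding-domain alignment and columns of the
    aligned cognate binding sites. Mutual information between paired columns
    is computed from Gerstein-Sonnhammer-Chothia weighted, pseudocounted
    nucleotide-amino-acid frequencies; significance is assessed against a
    permutation null obtained by re-pairing factors and sites, with an affine
    correction for shared phylogenetic history, and the number of reported
    pairs is set by a Bernoulli (binomial tail) cutoff. Includes a synthetic
    paired-alignment generator with planted couplings for calibration, and a
    sigma70 promoter co-localization filter for screening candidate binding
    sites in upstream regions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
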