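---
title: "Detecting coevolving positions in paired TF / binding-site alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting coevolving positions in paired TF / binding-site alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Transcription factors in a protein family read their DNA binding sites with a
largely conserved fold; specificity differences between subfamilies are carried
by a handful of residues, typically in the recognition helix of a (winged)
helix-turn-helix domain. When a family and its binding motifs are both known
across many genomes, positions of the protein that determine specificity should
*covary* with positions of the site: subfamilies that changed a contact residue
should show a compensating preference at the contacted base. `tfsitecoev`
detects such coupled column pairs from two parallel alignments — one of the
DNA-binding domains, one of the binding sites — linked by a pairing table (a
factor may pair with several sites and vice versa).

This vignette records the statistical model, every tunable that matters, the
design decisions taken where the method leaves room, and the limits of what the
package's own validation can show.

## The statistic

For protein column $i$ and site column $j$ the package computes the mutual
information

$$I_{ij} = \sum_{a}\sum_{n} f_{ij}(a,n)\,
  \log\frac{f_{ij}(a,n)}{f_i(a)\,f_j(n)},$$

where $f_{ij}(a,n)$ is the weighted, pseudocounted frequency of observing
residue $a$ at column $i$ together with base $n$ at column $j$ in one TF-site
pair. Natural logarithms are used internally; the choice is immaterial because
the Z-scores below are invariant to the log base (asserted by a test).

**Sequence weighting.** Sequence databases over-represent well-sampled taxa.
Every record is therefore weighted by $w(rs) = w(r)\,w(s)$, the product of
Gerstein-Sonnhammer-Chothia (GSC) weights of its TF and site sequences. GSC
weights are computed on a neighbor-joining tree (identity distances with
pairwise gap deletion, negative branch estimates clamped to zero, ties broken
toward the lowest-index pair) rooted at the midpoint of the longest
leaf-to-leaf path. The GSC recursion starts each leaf at its own branch length
and shares every deeper edge among the leaves below it in proportion to their
current weights, with an equal split where all current weights are zero.
Weights are normalised to sum to the number of leaves so that the weighted
total $N$ stays commensurate with the record count — this keeps the
pseudocount mass $\kappa N$ on the scale of the data. Whether the original
method weighted the site side at all is not documented; the package treats the
two sides symmetrically by default and offers `site_weights = "uniform"` as
the alternative.

**Pseudocounts.** Columns with few observations produce zero frequencies and
unstable MI. The observed weighted counts are supplemented by a pseudocount
mass of $\kappa N$ ($\kappa = 0.5$ by default) distributed by a substitution
model:

$$f_i(a) = \frac{N_i(a) + \kappa \sum_b N_i(b) P(b \to a)}{N(1+\kappa)},
\qquad
f_{ij}(a,n) = \frac{N_{ij}(a,n) + \kappa \sum_{b,m} N_{ij}(b,m)
  P(b \to a) P_{nt}(m \to n)}{N(1+\kappa)}.$$

This is the unique normalisation under which all frequency vectors sum to one
and the joint marginals reproduce the positional frequencies exactly (both
asserted to $10^{-9}$ on random inputs). The residue model $P(b \to a)$ is
derived from a BLOSUM score matrix; the nucleotide model is uniform,
$P_{nt} = 1/4$. Under the factorised pseudocount the joint null hypothesis
(independence of residue and base) is preserved: pseudocounts never create
spurious coupling.

Because score matrices ship as rounded log-odds rather than probability
tables, the package recovers the implied target frequencies by the standard
inverse construction: solve for the scale $\lambda$ and background vector $p$
with $\sum_b p_b e^{\lambda s_{ab}} = 1$ for every $a$ and $\sum_a p_a = 1$,
then $P(b \to a) = p_a e^{\lambda s_{ab}}$ with rows renormalised. For
BLOSUM45 this yields $\lambda \approx 0.233 \approx \ln 2 / 3$, consistent
with its third-bit units. The default matrix is BLOSUM45, the closest
available to the 30-40% identity regime appropriate for a diverse family;
`BLOSUM50/62/80/100` are selectable. One structural quirk of the derived
model is documented and tested: the methionine row is topped by leucine
rather than by methionine itself, a consequence of leucine's high background
frequency, not an error. An `"identity"` override sets both $P$ and $P_{nt}$
to identity matrices, under which pseudocounts cancel for any $\kappa$ — a
useful algebraic control.

**Gaps.** The method has no gap state: a record contributes to column pair
$(i, j)$ only if it is ungapped at both columns, so the effective $N$ varies
across pairs. Pairs with no usable records are reported as not assessable.

## Significance

Raw MI is biased upward by small samples and by shared phylogenetic history,
so the package calibrates each pair against a permutation null:

1. **Re-pairing null.** TF-site pairings are permuted (default 10,000 times;
   at least a few hundred are needed for a stable s.d.), each permutation is
   scored for every column pair, and the per-pair mean $E(\tilde I_{ij})$ and
   s.d. $\sigma(\tilde I_{ij})$ are recorded. One global permutation stream is
   shared by all column pairs — re-pairing is a property of the record set,
   not of a column pair — which also makes the null 20x cheaper than
   independent streams.
2. **Phylogenetic-trace correction.** Re-pairing destroys the TF-site linkage
   but not the within-column clade structure, so related sequences still
   inflate observed MI relative to the null. The correction regresses the
   observed $I_{ij}$ of the bulk of pairs (the top 5% of observed values are
   excluded so genuine couplings cannot drive the fit) on the raw null means
   and widens the null by the fitted affine map: $E' = \alpha E + \beta$,
   $\sigma' = \alpha\sigma$, with floors $\alpha \ge 1$, $\beta \ge 0$. The
   floors guarantee the correction can only weaken Z-scores; because observed
   MI is nonnegative this monotonicity holds for negative Z too (tested). The
   published description of this step delegates its exact form to earlier
   work; the construction above is this package's explicit, documented
   realisation, and `trace_correction = FALSE` disables it.
3. **Z-scores.** $Z_{ij} = (I_{ij} - E')/\sigma'$. Pairs with $\sigma' = 0$
   (constant columns) are excluded from ranking.
4. **Bernoulli cutoff.** With pairs ranked by decreasing Z, the probability
   $B(k) = P(\mathrm{Bin}(M, p_k) \ge k)$ of seeing at least $k$ of $M$
   standard-normal draws above the $k$-th Z is computed in log space for every
   prefix, and the reported count $k^\*$ minimises $B$. Two numerical points
   matter. First, $B$ is evaluated by log-sum-exp over binomial terms with
   log-tails from `pnorm(log.p = TRUE)`, so $|\log_{10} p|$ of several
   thousand — routinely produced by strong datasets — does not underflow.
   Second, the argmin is restricted to the positive-Z prefix of the ranking:
   a pair at or below its null mean cannot be a reported correlation, and
   because the empirical left tail of permutation Z-scores is shorter than
   Gaussian, $B(k)$ near $k = M$ degenerates toward $p_{\min}^M$ and would
   otherwise always swallow the minimum. When no Z is positive, $k^\* = 0$
   and the p-value is 1.

A calibration caveat the user should know: the per-pair null distribution of
MI is right-skewed, so converting Z-scores through Gaussian tails is
anti-conservative in the extreme right tail. On fully independent synthetic
data the B-cutoff still reports a few dozen pairs with $|\log_{10} p|$ around
10-25 — the same behaviour the method shows on shuffled real data, where the
negative control is orders of magnitude weaker than the intact analysis but
not at p = 1. The B-cutoff minimum is therefore a *contrast* statistic
(intact vs shuffled), not a calibrated family-wise error rate, and the
package's negative-control runner exists precisely to compute that contrast.

## The synthetic generator

`synthetic_spec()` / `generate_coupled_dataset()` emulate the structure such
an analysis sees in practice, at a reproducible, fully known scale:

* **Subfamilies.** Records fall into clades (default 5 subfamilies x 40
  records) generated as a star of clades: each background column draws a
  per-clade ancestral symbol from a column profile, and each record copies
  its ancestor or redraws with probability 0.2. Background profiles use
  3-symbol repertoires with Dirichlet(1) proportions — a realistic mix of
  near-conserved and polymorphic columns. Because protein and site background
  columns are drawn independently given the clade, any cross-side correlation
  they show is pure phylogenetic trace, which is exactly what the GSC
  weighting and the trace correction are meant to absorb.
* **Planted couplings.** At each planted $(j, i)$ pair every subfamily is
  assigned its own nucleotide-residue combination (distinct combinations
  across subfamilies); a record deviates with probability `noise_rate`
  (default 0.1), drawing base and residue independently so the deviation
  carries no coupling.
* **Dyad symmetry** (off by default) mirrors a planted site column into its
  palindromic partner, whose 0-based indices sum to `n_site_cols - 1`.

What the generator does *not* emulate: alignment gaps and misalignment, indel
history, realistic amino-acid substitution processes (no rate variation), and
binding-energy constraints. A green recovery test therefore shows that the
statistical machinery identifies planted subfamily-linked couplings against a
phylogenetic-trace background at this scale — not that real alignments of
comparable size will behave identically.

**Validation scales.** The test suite exercises the reference conditions
(5x40 records, 74x20 columns, 6 planted pairs, noise 0.1) with 1000-shuffle
nulls across 20 replicates for recovery; 50 independent-data replicates at
400 shuffles for the null behaviour; and a 5-level progressive row-scrambling
experiment (20 replicates per level, 400 shuffles) scored by the occurrence
of planted pairs in the top $k^\*$ established on unscrambled data. Two
findings from those runs are worth recording. Recovery degrades monotonically
with the scrambled fraction (mean occurrence roughly 1 → 0.8 → 0.35 → 0.15 →
0 across 0/25/50/75/100%). However, at 200 records the strongest planted pair
survives 50% scrambling only in a minority of replicates: MI decays roughly
quadratically in the coupled fraction, the $\kappa N$ pseudocount mass
dilutes what remains, and GSC up-weights the scrambled (divergent) rows, so
the residual signal sits at the trace noise floor. Survival of top pairs
under heavy scrambling is a large-N phenomenon and should not be expected at
a few hundred records.

## Site scanning and the promoter filter

The companion scanner builds an additive log2-odds PWM
(`log2((count + c)/(n + 4c)/background)`, pseudocount $c = 0.5$) and scores
both strands of the region $[-400, +50)$ around a gene start. Score
thresholds are dialect-specific to the PWM construction — a threshold tuned
for another scanner's score scale does not transfer, so the CLI documents its
threshold as a plain number with no portable meaning. The reproducible
content is the *geometry filter*: the activator families considered here bind
within $\sigma^{70}$ promoters whose -35/-10 boxes (TTGACA/TATAAT, default
mismatch budget 2 per box) are separated by an unusually long 19-20 bp
spacer, with the site center at a fixed distance from the 3' end of the -35
box — 7 bp for 21-bp sites, 8 bp for 22-bp sites. Site centers of even-length
sites are fractional (`start + (L-1)/2`); distances are rounded half-up
before comparison, and all coordinates are 0-based half-open on the forward
strand with box ends mapped to the promoter's own strand. A candidate passes
the filter iff some promoter satisfies both the spacer and the distance rule.
Functional-annotation filtering (co-localisation with the TF's own gene)
requires genome annotation semantics and is out of scope.

## Degenerate inputs and conventions

* Duplicate `(tf_row, site_row)` string pairs are removed before analysis
  (first occurrence kept); duplicate FASTA ids are an error, never silently
  renamed.
* Columns in which every usable record agrees produce $\sigma = 0$ and are
  reported as not assessable rather than given an arbitrary Z.
* Two-taxon trees bisect their single edge; all-zero branch lengths fall back
  to equal GSC weights.
* All in-R indices are 1-based for both protein and site columns; every file
  artifact prints the 0-based site convention alongside (dyad partners then
  sum to `n_site_cols - 1`).
* All randomness flows from explicit integer seeds; identical configurations
  produce byte-identical `results.json`.

## Known limitations

* The Gaussian-tail B-cutoff is anti-conservative under the skewed
  permutation null (see above); treat $k^\*$ on weakly structured data with
  suspicion and always run the negative control.
* The trace correction is a single affine map fitted across all pairs; it
  absorbs the average inflation, not pair-specific clade effects.
* MI cannot separate direct contact from indirect covariation; the
  contact-enrichment test against an independent structural contact list is
  the intended way to ground the selections.
* Weighting assumes the NJ tree is a reasonable summary of redundancy; for
  alignments with extreme gap content the identity distances may be poor.
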