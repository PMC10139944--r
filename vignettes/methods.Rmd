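---
title: "Methods: conservation scoring and paralog-modification statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation scoring and paralog-modification statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

Budding yeast retained several hundred paralogous protein pairs from an
ancient whole-genome duplication. Many residues are identical in both
members of a pair, yet a posttranslational modification —
phosphorylation, ubiquitylation, monoacetylation, N-glycosylation or
succinylation — is documented for only one member. `paraconserv` asks
whether such differentially modified sites sit in more conserved local
sequence context than the identical, unmodified residue of the partner,
using within-species polymorphism across many strain isolates as the
conservation signal. Within-species comparison of paralogs controls for
shared structure and avoids the alignment artifacts of deep cross-species
comparisons.

The inputs are one aligned FASTA per ORF (rows = strains, one designated
reference), a paralog-pair table, a modification-site table (with study
provenance), an optional Newick strain phylogeny, and optional annex
tables (kinase interactions, kinase position-weight matrices, STRIDE
secondary-structure assignments, protein abundances).

## Per-column conservation scores

Five algorithms score each alignment column on $[0,1]$, 1 perfectly
conserved and 0 random. Gaps are `-`, `X`, `B`, `Z`; they are removed
before frequency computation, and a column with no usable symbol yields
`NA` rather than 0 — a zero would masquerade as "random", while `NA` is
skipped by every downstream window average.

* **Shannon entropy**: $1 - H(p)/\log 20$ over the column's amino-acid
  frequencies. Any logarithm base gives the same normalized value; the
  natural log is used.
* **Stereochemically sensitive entropy**: identical, but residues are
  first pooled into nine stereochemical groups (VLIM, FWY, ST, NQ, HKR,
  DE, AG, P, C) and the normalization is $\log 9$. Pooling can only
  lower entropy, so this score is always $\ge$ the Shannon score.
* **Jensen–Shannon divergence**:
  $\mathrm{JSD}(p,q) = H(\tfrac{p+q}{2}) - \tfrac12 H(p) - \tfrac12 H(q)$
  against the background $q$, normalized by its maximum $\log 2$
  (mixture weight $\tfrac12$). The packaged background is the
  BLOSUM62-derived marginal amino-acid frequency vector, renormalized to
  sum to one, with a file override for users who prefer another
  background. Divergence from the no-selection background reads as
  conservation, so this score emphasizes selection pressure rather than
  chemical similarity.
* **Phylogeny-weighted mismatch score**: the package's own
  reference-anchored formulation of a "zoom"-style score,
  $1 - \sum_i w_i\,[a_i \ne a_\mathrm{ref}] / \sum_i w_i$ over non-gap
  comparison strains with $w_i = 1/(d_i + \varepsilon)$, $d_i$ the
  patristic distance to the reference strain. A substitution in a strain
  closely related to the reference is penalized heavily, the same
  substitution in a distant strain only lightly; on a star tree with
  equal branch lengths the score reduces to the fraction of strains
  matching the reference. $\varepsilon$ defaults to $10^{-6}$ times the
  tree diameter (configurable); it exists only to keep the weight of a
  zero-distance strain finite.
* **Karlin substitution-matrix normalization**: the mean over unordered
  symbol pairs of $M(a,b)/\sqrt{M(a,a)M(b,b)}$ (BLOSUM62 by default,
  PAM30 accepted), which lies in $(-1,1)$ and is reranged to $(0,1)$ as
  $(s+1)/2$. Same-symbol pairs contribute exactly 1. Gap-containing
  sequences are excluded from the pair sum and no multiplicative gap
  penalty is ever applied to this score: rare substitutions are already
  penalized by the matrix, and a second penalty would double-count.

The optional **gap penalty** multiplies any of the first four scores by
the column's non-gap fraction.

`score_profile()` evaluates a whole alignment at once with vectorized
counts; the per-column functions are the reference implementations, and
the test suite asserts the two routes agree exactly, including on gapped
and all-gap columns.

## Mapping sites between paralogs

The two reference proteins of a pair are aligned with true global
Needleman–Wunsch under BLOSUM62, gap opening 10 and gap extension 0.5 —
a gap of length $k$ costs $10 + 0.5k$, end gaps included. The
implementation is `Biostrings::pairwiseAlignment(type = "global")`,
whose affine-gap dialect matches this cost exactly (verified against
exhaustive alignment enumeration on short sequences in the tests). A
**site of interest** is an aligned position where both paralogs carry
the identical residue and exactly one member is modified for the given
modification type; the modified member is the *target*. Residue
substitutions of any kind are rejected — even conservative ones such as
serine for threonine — so no assumption about enzyme substrate
preference is smuggled in. Positions modified in both members are
excluded: neither member is an "unmodified paralog", and keeping them
would dilute both roles. Each modification type is enumerated
independently.

## Window statistics

Around each site, three families of local conservation averages are
computed on the ungapped reference coordinates of each protein
separately (windows are residue-adjacent in each protein, not columns of
the pair alignment):

* symmetric means `mean1`–`mean4`: site $\pm k$, i.e. 3, 5, 7, 9
  residues at an interior site;
* one-sided means `meanb1`–`meanb4` and `meana1`–`meana4`: the site plus
  $k$ residues strictly before or after it ($k+1$ positions);
* chemical-similarity averages `chem_b1` / `chem_a1`: the site plus its
  immediate neighbor, stratified by the neighbor's chemical class —
  aliphatic (GAVLIMP), aromatic (FYW), polar uncharged (STCNQ), acidic
  (ED), basic (KRH), a partition of the 20 amino acids.

The site's own score is always included. Windows are clipped at the
termini and the mean is taken over available, non-missing positions; no
padding is used, because padded sentinel values would bias scores near
protein ends. One matched (target, paralog) value pair per site enters
the statistics; pairs with a missing member are dropped and counted.

## The two conservation tests

**Distribution-mean test.** A one-sided paired Wilcoxon signed-rank test
of target minus paralog window scores (alternative: targets larger).
Zero differences are dropped per the signed-rank convention; the null is
enumerated exactly for up to 25 untied nonzero pairs and approximated by
the tie-corrected normal otherwise.

**Paralog-pairing test.** A Monte-Carlo permutation test of whether the
*authentic pairing* advantages targets: compute
$P_\mathrm{auth}$, the fraction of pairs with target strictly greater
than paralog (ties count against the target), re-draw the paralog
assignment as an unrestricted uniform permutation $B$ times, and report
$f$, the fraction of shuffles with $P_\mathrm{auth} > P_s$. The
frequency $f$ has granularity exactly $1/B$ — 0.0001 at the default
$B = 10{,}000$ — and the p-value is $1 - f$, small when the authentic
pairing is advantageous.

The two tests are deliberately complementary, with three regimes
realized by `simulate_scenario_sets()` and asserted in the tests:

| regime | distribution-mean | pairing |
|---|---|---|
| non-overlapping distributions | significant | not significant (every re-pairing also leaves all targets on top) |
| overlapping, pairing advantage | significant | significant |
| matched marginals, pairing advantage | not significant | significant |

The third regime uses a block-cycle pairing of one shared score ladder:
most targets win by one small rung while a few lose by a whole block,
so the rank-weighted signed-rank statistic stays null while the
sign-counting pairing statistic is extreme.

A calibration subtlety, documented rather than hidden: the pairing
test's shuffling null assumes *full* exchangeability of values across
pairs. When pairs share strong baselines (as real paralogs do), the null
is only within-pair exchangeable and the test is mildly anti-conservative.
The packaged type-I experiment therefore uses the fully i.i.d. null
(`conservation_spread = 0`), where both tests hold their nominal level;
the power experiment uses the baseline-structured generator, which is
exactly the situation the pairing test exists to detect.

**Chemical-similarity test.** Because the adjacent residues of target
and paralog can fall into different chemical classes, the pairing
structure cannot be maintained in this stratified analysis; an unpaired
one-sided Mann–Whitney–Wilcoxon test compares the target and paralog
score distributions within each class.

## Positional motif analysis

For a stratum of sites (e.g. phosphoserine), the amino acids at each
relative position b4..b1, a1..a4 are tallied into a 2×20
target/paralog contingency table. Pearson's chi-square is computed with
a Monte-Carlo p-value under fixed margins,
$p = (1 + \#\{X^2_\mathrm{sim} \ge X^2_\mathrm{obs}\})/(B+1)$ (the
add-one estimator avoids impossible zero p-values); columns with zero
total count are dropped. Post hoc, each amino acid's standardized
residual $r = (O-E)/\sqrt{E(1-\mathrm{row}/N)(1-\mathrm{col}/N)}$ is
referred to the standard normal, two-sided, with the direction recorded
as `Target > Paralog` or `Target < Paralog`; since the two rows of a
2×K table carry opposite residuals, the BH family is the K amino acids
of the position. A companion goodness-of-fit test compares either row
with the BLOSUM62-derived background (floored at $10^{-6}$ and
renormalized before expectation).

## Multiple testing

All adjustment is step-up Benjamini–Hochberg. In `run_full_analysis()`
the family is one test × one algorithm across all window statistics and
modification types — the layout of one results heatmap — with the raw
p-values retained in the long-format output so users can re-adjust under
a different family definition. Whether to pool families more broadly is
genuinely underdetermined; the choice is exposed rather than baked in.

## Synthetic data: what it emulates and what it does not

The generators produce every input format the pipeline consumes, all
bit-reproducible from a seed.

* `simulate_alignment()` keeps a consensus residue per column with the
  requested probability and otherwise draws from the background, with
  the reference row fixed at the consensus.
* `simulate_paralog_dataset()` gives both members of a pair an identical
  reference protein and draws one conservation baseline per pair
  (uniform, half-width `conservation_spread = 0.2` around
  `conservation_base = 0.7`), then i.i.d. per-column levels around that
  baseline (half-width `pair_spread = 0.05`). The shared baseline
  encodes the shared evolutionary history of paralogs and is what gives
  the pairing structure meaning; without it a flanking advantage is a
  pure distribution shift that no pairing test can, or should, detect.
  `flank_advantage` adds δ to the target's columns within ±4 of each
  planted site.
* `simulate_motif_dataset()` plants a residue enrichment at one relative
  position of the target flanks (probability multiplied by the
  enrichment factor, renormalized), leaving every other offset
  exchangeable.

Not emulated: real clade structure of yeast isolate panels, gaps and
indel polymorphism in generated alignments (gap handling is tested on
constructed columns instead), linkage between neighboring columns, and
residue substitutions between paralogs (generated pairs are identical at
the reference level so that every position is a candidate site). Passing
calibration on these fixtures shows the statistical machinery is
correct, not that any particular biological dataset will carry signal.

## Numerical choices and degenerate inputs

* Entropies use natural log normalized by log alphabet size; the uniform
  20-letter column scores exactly 0, any monomorphic column exactly 1.
* Undefined columns (all-gap; fewer than two non-gap symbols for the
  Karlin score; gapped reference for the phylogeny score) give `NA`,
  skipped by window means; a window with no defined position is itself
  `NA` and the site is dropped, with counts logged.
* Alignment tie-breaks are delegated to the deterministic traceback of
  the alignment backend, so repeated runs give identical alignments.
* PWM kinase assignment sums raw weights over offsets −5..+4, skips
  offsets outside the protein (no pseudo-residues), and breaks ties by
  kinase identifier order. Raw summation is one of several defensible
  conventions; the scoring hook `score_pwm()` is exported so alternatives
  can be swapped in.
* Strict inequality in the pairing statistic counts ties against the
  target. Wilcoxon zero differences are dropped.
* All Monte-Carlo procedures take explicit seeds and record `B` and the
  seed in the result metadata.

## Problem sizes in the packaged experiments

The test suite runs the calibration experiments at desk scale, chosen so
the statistical claims are sharp while the whole suite stays quick:
type-I error from 500 fixed-seed replicate datasets of 50 pairs (16
strains, 24-residue proteins, shuffle count 200), power from 60
replicates of 200 pairs at δ = 0.1, motif recovery from 500 sites at
5× enrichment, and exhaustive oracles for the alignment (4-letter
alphabet, lengths ≤ 7), the Karlin score (all columns of size ≤ 5) and
the pairing permutation null (all $n!$ pairings, $n \le 6$).

## Known limitations

* The phylogeny-weighted score is this package's own formulation of a
  distance-weighted, reference-anchored conservation score; other
  "zoom"-style weightings exist and will differ numerically while
  sharing the qualitative properties asserted in the tests.
* The pairing test's granularity ($1/B$) bounds how small its p-value
  can be; BH adjustment inherits this floor.
* Windows never cross chain breaks or distinguish secondary-structure
  context; the annex STRIDE analysis addresses structure separately.
* Intron handling, coordinate liftover between genome releases, and the
  curation of modification databases are upstream of this package:
  positions are taken to be 1-based residue indices in the supplied
  reference protein, and residue mismatches are an error by default
  (downgradeable to a logged skip).
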