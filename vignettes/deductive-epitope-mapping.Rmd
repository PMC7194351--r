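---
title: "Deductive epitope mapping: models, assumptions and design choices"
author: "nniomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deductive epitope mapping: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nniomics)
```

## The problem

A polyclonal antibody raised against a short synthetic peptide stains
tissue, but the endogenous antigen it recognizes is unknown. When the
antigen resists purification and mass spectrometry, its epitope can still
be narrowed down deductively, by combining four independent lines of
desk-scale evidence:

1. **Motif census.** If a candidate sequence element (here the tripeptide
   NNI, the C-terminal triplet of the 14-mer immunogen MKPLTGKVKEFNNI) is
   assumed to be part of the epitope, a predicted proteome can be sifted
   for proteins carrying it, and the survivors filtered further by residue
   composition (the *Method of Exclusion*).
2. **Probability calculus.** Apparent sequence coincidences (short motif
   matches between candidate proteins, partial anagrams of the immunogen)
   are either meaningful or chance; exact combinatorics puts numbers on
   "chance".
3. **Conformer geometry.** Whether a short free peptide is a plausible
   spatial mimic of the same residues inside the longer immunogen is
   assessed by comparing labelled interatomic-distance tables between
   energy-minimized models.
4. **Preabsorption panels.** Pre-incubating the antibody with competitor
   peptides and quantifying the residual immunohistochemical staining
   identifies which peptides contain the epitope; a suffix-pattern
   classifier turns the blockade table into an explicit epitope
   hypothesis, and alanine-substitution variants probe individual
   positions.

The package implements each line as a tested, seedable computation, plus
synthetic-data generators so that every analysis can be validated against
planted ground truth without any external download.

## Motif census (`build_sift_report`)

A motif is a run of slots, each a fixed canonical residue or a wildcard
(`motif_pattern("M..........NNI")` is a 14-mer window: M, ten arbitrary
residues, NNI). Matching conventions, chosen once and oracle-tested:

* Coordinates are 1-based and inclusive, the R/Bioconductor convention; a
  hit is C-terminal exactly when `end` equals the protein length.
* Wildcards match any of the 20 canonical residues and **never** the
  ambiguity codes X, B, Z, U, O; fixed slots match only their residue.
  Records containing ambiguity codes stay in the census — conservative
  matching, no record dropping.
* Occurrences are counted **with overlap** by default. Total-occurrence
  census counts need a stated convention; overlap counting is the
  declared one, and a non-overlapping greedy mode is available
  (`overlap = FALSE`). (NNI itself has no nontrivial self-overlap, so the
  choice only matters for self-overlapping patterns.)
* The "initiator methionine" discounted from the methionine pool is
  operationalized as the position-1 M of each record; no signal-peptide
  prediction is attempted, because none can be reconstructed from a
  census definition alone.

The census report collects: motif-ome size (proteins with ≥ 1 hit), total
and C-terminal hits, sub-pattern counts (e.g. FNNI, EFNNI) restricted to
the motif-ome, short-protein count (< 100 aa by default), the
non-initiator methionine pool, anchored-window hits, and the
Method-of-Exclusion survivors.

**Method of Exclusion.** An M-anchored 11-mer window `Mxxxxxxxxxx`
survives iff residues 2–11 are drawn entirely from the allowed set minus
M (`MKPLTGVEF` by default — the unique residues of the reference peptide
less its NNI suffix; the leading M is consumed as the anchor, so a second
M excludes). Survivors are scored by the number of *distinct* allowed
residues in the full 11-mer, repeats counted once (the reference
candidate MLKTGEKPVEP scores 8: M, L, K, T, G, E, P, V). Ties are broken
by (protein id, start) for determinism.

The published census figures for an ovine TrEMBL snapshot (1,100
motif-bearing proteins with 1,181 occurrences among 26,443; 42 FNNI, 7
EFNNI, 3 C-terminal; 25 anchored windows; a 22,207-strong methionine
pool) are database-version-dependent and are therefore *not* test
assertions; the tests instead assert exact agreement with planted counts
on generator proteomes and with brute-force oracles on random ones.

## Probability calculus (`protein_match_prob`, `anagram_window_prob`)

All probabilities default to the **uniform composition** (1/20 per
canonical residue). That choice is deliberate: the headline printed odds
(1 in 146,000; 1 in 11) are exact under uniformity, and empirical
compositions can be supplied where wanted.

* **Window model.** A pattern with $f$ fixed slots has per-window
  probability $p = \prod_{j \in \text{fixed}} \pi_{r_j}$ (uniform:
  $20^{-f}$). Over the $n = L - k + 1$ windows of an $L$-mer,
  the expected count is $np$ and
  $P(\ge 1) = 1 - (1-p)^n$ under an independence approximation
  (Monte-Carlo-checked in the tests). For a 5-fixed-residue match in a
  619 aa protein this gives odds of about 1 in 5,220 — close to, but not
  exactly, the deposited value of 1 in 5,247 whose precise window
  convention is not reconstructable; such single-protein odds are
  therefore treated as *inputs* where the analysis combines them.
* **Combined odds.** Independent match probabilities multiply:
  $1/5247 \times 1/2636 \approx$ 1 in 14 million;
  $1/6201 \times 1/4378 \approx$ 1 in 27 million.
* **Partial anagrams.** The probability that a random $k$-mer is an
  ordered arrangement of $k$ residues drawn (with multiplicity) from a
  multiset $\{m_r\}$ is computed by exact enumeration of size-$k$
  sub-multisets: each count vector $c$ ($0 \le c_r \le m_r$,
  $\sum c_r = k$) contributes $\frac{k!}{\prod_r c_r!} \prod_r \pi_r^{c_r}$,
  and distinct count vectors contribute disjoint strings. For the
  11-residue multiset MKPLTGKVKEF (K×3) at $k = 9$ this counts 3,507,840
  ordered 9-mers out of $20^9$: odds of 1 in 146,000 at the rendering
  granularity. The per-window reading is the headline (it reproduces the
  arithmetic exactly); a per-protein reading would need a stated length.
* **Initial residue.** For a uniformly random ordered $k$-permutation of
  the multiset, $P(\text{first} = r) = m_r / \sum m_r$ by symmetry
  (1/11 for the single M) — independent of $k$, and verified by
  exhaustive enumeration on small multisets in the tests.
* **Renderings.** "1 in N" strings round the reciprocal at a
  magnitude-dependent granularity (nearest million above $10^7$, nearest
  hundred-thousand above $10^6$, nearest thousand above $10^5$, else
  nearest integer), matching how such odds are conventionally quoted;
  `parse_odds()` inverts the rendering.

## Conformer comparison (`chi_squared_compare`)

Energy-minimized peptide models are summarized as labelled interatomic
distances (atom labels a–k; `inst/extdata/atom_selections.csv` documents
a reference labelling). Two tables over an identical pair-label set are
compared with

$$\chi^2 = \sum_{\text{pairs}} \frac{(O - E)^2}{E}, \qquad
  \text{dof} = n_{\text{pairs}} - 1,$$

with a verdict of "indistinguishable" when the statistic falls below the
chi-squared quantile at the configured confidence level (default 99.5%).
Two caveats are implemented as stated rather than "fixed": the statistic
is dimensionally a descriptive index on ångström-valued measurements, not
a count-based goodness-of-fit statistic, and dof = pairs − 1 follows the
reported convention (46 measurements → dof 45; 20 → 19; 8 → 7). The
complementary *big-difference proportion* is the percentage of pairs with
$(O-E)^2$ strictly above 10 Å² (threshold configurable).

Comparison requires explicit pair-label alignment; mismatched label sets
are an error naming the symmetric difference, never positional guessing,
because deposited tables identify measurements by letter pairs. The exact
rule that selected 46 of the 55 possible pairs of 11 atoms in the
reference analysis is unstated, so the pair subset is always taken from
the input file. `distances_from_coordinates()` builds tables from
labelled 3-D coordinates (rigid-motion invariant to 1e-9, by test).

## Preabsorption analysis (`infer_epitope` and friends)

Staining is quantified as the fraction of pixels strictly above a fixed
intensity threshold (`area_fraction`), normalized to percent of the
peptide-free control (`percent_of_control`; the control mean maps to
100). Group summaries are mean ± SEM (sample SD/√n). The unpaired t-test
defaults to the pooled-variance Student form — the source analysis states
only "unpaired t-tests" — with a Welch variant available; it accepts raw
replicates or (n, mean, SEM) summaries with identical results, which
matters because published data often survive only as summaries. IC50 is
reported as a **bound over tested doses** ("≤ 10 ng/ml"-style, "< c_min"
when the lowest dose already halves staining, "not reached" otherwise),
not a fitted midpoint, because bounds are what a sparse dose grid
supports; the 4-parameter logistic is used only inside the synthetic
generator.

**Suffix-pattern inference.** All C-terminal patterns up to `max_len`
slots (fixed residue or wildcard per slot, ≥ 1 fixed) are scored by the
separation accuracy of "blocks iff the pattern matches the C terminus",
ranked by accuracy, then fixed-slot count, then length, then pattern
string. Enumeration is restricted, per offset, to residues actually
observed at that offset in the panel plus the wildcard: a fixed residue
unobserved at its offset matches no panel peptide, so every such pattern
is score-equivalent to an already enumerated no-match pattern and can
never be uniquely optimal; this keeps `max_len = 6` exhaustive-in-effect
and fast. `partial` blockers count as blockers by default;
`highest-conc-only` entries are excluded from the core inference (a
sensitivity mode includes them), and alanine-substitution variants are
analysed in a second pass (`substitution_scan`) that classifies positions
as tolerated or required — required positions outside the contiguous core
are reported as candidate non-contiguous epitope elements. On the bundled
24-peptide blockade panel the top pattern is a C-terminal NNI at
accuracy 1.0, with F classified required-but-non-contiguous, mirroring
the two-stage reasoning the panel was designed for. Degenerate panels
(no blocker/non-blocker contrast) yield a flagged wildcard pattern.

## Synthetic data: what it emulates, and what it does not

* `make_proteome()` plants internal, C-terminal and anchored-window motif
  occurrences into background sequences drawn from a stated composition,
  and **rejection-samples** the background so no unplanned occurrence of
  the motif or window pattern exists (retry cap 200 per protein, clear
  failure beyond). Planted counts are exact by construction; derived
  census fields (sub-pattern counts, methionine pool, short proteins,
  survivors) are recounted on the emitted sequences with plain string
  operations independent of the scan machinery, so manifest checks are
  genuinely two-route. Defaults (50 proteins of 60–300 aa, 12 internal +
  2 C-terminal + 3 anchored plants) keep per-protein motif densities in
  the same regime as a real predicted proteome (order 1 occurrence per
  motif-bearing protein) at test-friendly size.
* `make_distance_tables()` adds per-entry Gaussian jitter (redrawn while
  non-positive) to a base table — a stand-in for conformational
  variability, not a physical model.
* `make_panel_measurements()` uses the 4-parameter logistic
  $100 / (1 + (c/\mathrm{IC50})^h)$ with floor 0 and ceiling 100 — the
  standard inhibition-curve form, chosen because no functional form is
  stated in the source analysis — plus Gaussian replicate noise (default
  SD 5 percent points, n = 4, doses 0.1–1000 ng/ml, matching the design
  of the real titration). `make_panel()` labels random peptides by a
  planted suffix rule with no label noise, so recovery failures isolate
  the inference.
* `make_image()` places exactly `round(f · npixels)` pixels above the
  threshold at zero noise, so `area_fraction` recovers the target
  exactly.

Passing tests on these generators show that the *computations* are
correct and identifiable under the stated models; they do not show that
real immunohistochemistry obeys a clean logistic, that staining noise is
Gaussian, or that a real proteome's composition is uniform.

## Numerical choices and degenerate inputs

* Multinomial ordering counts are computed via `lgamma` and rounded to
  the nearest integer before summation; exact for every multiset size
  used here (counts ≪ 2^53).
* Empty proteome → all-zero census; pattern longer than the protein →
  zero windows and probability 0; `k = 0` anagram → probability 1.
* Both groups constant and equal in the t-test → t = 0, p = 1 (the 0/0
  statistic is resolved by contract); constant but unequal → flagged,
  infinite statistic.
* Zero control mean, empty control group, mismatched pair labels,
  non-M-initial exclusion windows, invalid residues in configuration
  strings: all are errors naming the offending item, not silent fixes.

## Problem sizes used by the test suite

Chosen as the package's own validation design: oracle equivalence on 20
random proteomes of 30 proteins × ≤ 200 residues (plus 20 × 10 × 200 in
the unit tests); planted-census recovery over 20 seeds of 40-protein
proteomes; anagram enumeration over every multiset on a 3-letter
alphabet with multiplicities ≤ 3 (k ≤ 4) plus 5-letter spot checks;
500 null t-tests for the type-I error; 100 synthetic panels and 50
dose-response seeds for recovery; 200 jittered tables per jitter SD.

## Known limitations

* The census counts printed for a specific TrEMBL snapshot cannot be
  asserted without that snapshot; the package asserts the machinery, not
  the snapshot.
* The deposited conformer distance tables are an external download; when
  absent, the conformer pipeline is exercised on synthetic geometry only
  (see README for where to place the download).
* The (O−E)²/E distance index inherits the verdict's dependence on
  measurement units; it is reported as specified, with the caveat stated
  above.
* Suffix-pattern inference assumes the blockade phenotype is determined
  by the peptide's C terminus; epitopes with essential internal or
  N-terminal elements would need the anchored-pattern machinery instead.
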