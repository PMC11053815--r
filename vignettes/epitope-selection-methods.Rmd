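---
title: "Methods: epitope selection, filtering and population coverage in epivax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epitope selection, filtering and population coverage in epivax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Peptide (neoantigen) vaccines against tumours carrying missense mutations
need a short list of mutant peptides that (a) are presented by the HLA
molecules of the target population, (b) are likely to induce
tumour-infiltrating lymphocytes (TILs), (c) carry no obvious safety
liabilities (toxicity, allergenicity, instability), and (d) jointly cover as
much of the population's HLA diversity as possible. `epivax` implements that
selection end to end. Its atomic unit is the **EHLA pair**: one candidate
epitope combined with one HLA allele. Class-I-restricted pairs (EHLA-I,
CD8^+^ targets) are classified and ranked by trainable models; class-II
pairs (EHLA-II, CD4^+^ targets) are filtered on fixed criteria.

## Epitope enumeration

A missense mutation `L858R` (wild-type residue, 1-based position, mutant
residue) is validated against the protein — the stated wild-type residue
must sit at the stated position — and every window of each configured length
that both contains the mutated position and lies fully inside the protein is
emitted, together with its matched wild-type window. Counting windows of
length $L$ around position $p$ in a protein of length $N$:

$$ \#\text{windows}(L) \;=\; \min(p,\, N - L + 1) - \max(1,\, p - L + 1) + 1 , $$

so an interior mutation yields $\sum_L L$ candidates and terminus-adjacent
mutations proportionally fewer. Candidates are crossed with the full allele
panel (27 class-I HLA-A/B alleles and 27 class-II DR/DQ/DP alleles by
default) with no deduplication: the same peptide arising from two mutations
is retained twice, because each analysis run is an independent experiment.

**Window lengths are configurable, defaulting to {9, 10} for class I and
{15} for class II.** The class-I default reconstructs the scale of a
96-mutation analysis of a 1210-residue protein (96 × 19 × 27 = 49,248
pairs before terminus losses); the class-II default is the field's
conventional 15-mer. No single published length set is authoritative, which
is why both are parameters rather than constants.

## Locally computed descriptors

* **Hydropathicity** — the positional Kyte–Doolittle sum
  $\sum_{i=4}^{n-1} \mathrm{KD}(s_i)$ over 1-based positions 4 to $n-1$ of an
  $n$-mer. This windowed sum (distinct from the GRAVY mean) drops the
  anchor-adjacent termini. Peptides shorter than 5 residues are an error,
  not 0: epitopes here are always ≥ 9 residues, so a short input signals a
  caller bug.
* **GRAVY** — mean KD over all residues, in $[-4.5, 4.5]$.
* **Instability index** — Guruprasad's dipeptide statistic
  $(10/L)\sum_i \mathrm{DIWV}(s_i, s_{i+1})$; > 40 conventionally denotes
  instability.
* **Aliphatic index** — Ikai's $100 X_A + 290 X_V + 390 (X_I + X_L)$ over
  mole fractions.
* **Isoelectric point** — the zero of the Henderson–Hasselbalch net-charge
  curve (free termini + ionizable side chains, Bjellqvist pKa set), found by
  bisection on (0, 14) to 1e-4 pH units. The charge curve is strictly
  decreasing in pH, so bisection cannot miss the root.
* **N-end-rule half-life** — table lookup on the N-terminal residue
  (mammalian reticulocyte column, hours; the ">20 h" proline entry is
  recorded as 20).

All constant tables (KD, the 400-entry DIWV matrix, N-end half-lives,
Bjellqvist pKa values, Hellberg z-scales) ship as commented CSVs under
`inst/extdata/constants/` with their original publications named in the
headers.

## The predictor registry

Binding rank and affinity (MHCflurry-style, NetMHCpan-style), binding
stability, class-I immunogenicity, toxicity, allergenicity and IFN-γ
induction are products of external tools and are **not re-implemented**.
Each is a named slot in a registry of functions
`(epitope, allele) -> value`, bound either to

1. a **bring-your-own-scores CSV** (`epitope,allele,feature,value`) holding
   pre-computed values from the real tools, or
2. a **deterministic mock**: a pure 32-bit FNV-1a hash of (epitope, allele,
   feature, seed) mapped into the feature's plausible range (percentile
   ranks in (0, 100], stability in (0, 12] h, labels from a seeded
   Bernoulli). Mocks make every pipeline path testable offline and
   byte-reproducible; they carry no biology.

The **wild-type:mutant rank ratio** is derived, not predicted: the rank
predictor is evaluated on the matched wild-type window and divided by the
mutant window's rank; > 1 means the mutation improved predicted binding.

**Antigenicity** is computed locally as a linear model over
auto-cross-covariance (ACC) features of the Hellberg z-scale series: after
centering each descriptor over the sequence, term $(j,k,l)$ is
$\sum_i a_j(i)\,a_k(i+l)/(n-l)$, flattened lag-major. The default lag is 1
(epitopes are short); the combining weights are a fixed, replaceable package
asset chosen to put typical peptides near the conventional 0.4 threshold —
they make no claim to reproduce any external tool's trained model.
The class-II immunogenicity score's provenance is ambiguous in the
published record, so the registry treats it as an opaque pluggable score on
a 0–100 scale consistent with its < 50 exclusion cutoff.

## The ML layer

The training table is one row per EHLA-I pair: feature columns plus a 0/1
label (1 = experimentally able to induce tumour-specific CD8^+^ T cells).
The reference regime is 109 positives / 654 negatives (~1:6 imbalance).
Eight model families share one harness: random-forest, SVM, Gaussian naive
Bayes and MLP classifiers; linear, logistic, random-forest and
gradient-boosting regressors. Fits go through `randomForest`, `e1071`,
`nnet`, `stats` and `xgboost`; defaults are 100 trees (unlimited depth) for
the forests, an 8-unit single hidden layer with weight decay 1e-3 for the
MLP, and 50 exact-split depth-3 rounds for gradient boosting. The exact
(non-histogram) split method matters on small tables: histogram binning can
place a split at a cluster edge instead of mid-gap and misclassify margin
points.

Cross-validation is **stratified five-fold**: each class is shuffled under
the run seed and dealt round-robin with a rotating offset, so fold sizes
differ by at most one and each fold preserves the class ratio to within one
sample. Stratification is a design choice (an unstratified split of a 1:6
table can starve a fold of positives). Classifiers report per-fold accuracy,
PPV and TPR; a fold with no positive predictions has undefined PPV, which is
excluded from the fold mean with a warning rather than imputed. Regressors
report per-fold AUC of the ROC of their continuous predictions against the
binary labels; AUC is computed by threshold sweep with trapezoidal
integration, which equals the mid-rank Mann–Whitney statistic under ties.

**The regression ranker is fit on the binary label itself.** That is the
only reading under which an ROC over its predictions is well defined, and
scores are deliberately not clipped to [0, 1] — their ordering, not their
scale, is what ranks pairs. Logistic rankers have a known failure mode here:
on well-separated data their scores saturate at 0/1 and cannot rank.
`classify_and_rank()` warns whenever more than half of the scores lie within
1e-6 of 0 or 1.

The feature-combination search evaluates every non-empty subset of the
candidate pool (127 subsets for the 7-feature pool) under a shared seed and
picks the best mean accuracy (classifiers) or AUC (regressors), breaking
ties toward fewer features, then lexicographic names — a deterministic,
parsimony-first rule.

Final models: a random-forest classifier assigns the binary **ID** (1 =
predicted TIL-inducing) with impurity-based importances normalised to sum
to 1, and a linear-regression ranker assigns the real-valued **score**.
Pairs are sorted by ID (descending), score (descending), then
(epitope, allele) ascending for determinism.

## Exclusion filters

Rules evaluate in a fixed order, and a pair failing several rules is
attributed to the first for the audit (rejected + kept always equals the
input count). Class I: toxicity = "Toxin"; half-life ≤ 1 h; instability
index > 40; allergenicity = "Probable Allergen"; ID = 0. Class II: the
first four, then IFN-γ = "Negative", immunogenicity < 50,
antigenicity < 0.4. Comparisons are strict as printed, so boundary values
(exactly 40, 50, 0.4, 1 h) are retained.

One deliberate interpretation is flagged prominently: the published
exclusion table lists "Half-life > 1 h" in its exclusion column, which read
literally would discard every stable peptide and contradicts both the
biology and the accompanying stepwise-filtering text. `epivax` therefore
**retains** pairs with half-life > 1 h and excludes those at or below 1 h.
The threshold, and every rule, can be overridden via YAML
(`filter_rules_from_yaml()`). No binding-rank cutoff is applied to either
class: class-I selection is the model ID's job.

## Population coverage

Given per-region, per-locus allele frequencies, the hit distribution of a
pair set is computed per locus by enumerating unordered diploid genotypes
under Hardy–Weinberg equilibrium: genotype $(i,j)$ has probability $p_i^2$
on the diagonal and $2 p_i p_j$ off it, and any per-locus frequency mass
below 1 is a residual "other" allele that covers nothing (frequencies are
never renormalised). An individual's hit count is the number of
(epitope, allele) pairs whose allele is present in the genotype —
**presence-based**, so a homozygote does not double-count (a dosage-based
switch exists). Per-locus distributions combine across loci by convolution,
assuming locus independence (no haplotype linkage). DRB1/3/4/5 pool into a
single DR locus, and paired α/β class-II names are one unit at one locus.
Pairs whose allele is untyped in a region's table are excluded from that
region's calculation and reported, never silently dropped.

From the hit pmf: coverage = $1 - P(0)$; average hit = $\sum_h h\,P(h)$;
**PC90** interpolates the complementary CDF $S(h) = P(\text{hits} \ge h)$:
with $k$ the integer satisfying $S(k) \ge 0.9 > S(k+1)$,
$\mathrm{PC90} = k + (S(k) - 0.9)/(S(k) - S(k+1))$. This piecewise-linear
rule is a documented dialect choice — published fractional PC90 values do
not specify their interpolation — and a zero-coverage distribution has PC90
defined as 0 (the formula alone would give 0.1, a discontinuity we resolve
in favour of the intuitive value). Regional summaries average regional
coverages **unweighted**, and a "World" row always comes from the world
frequency entry, never from averaging regions.

**Minimal-set optimisation** finds the smallest subset of pairs whose
covered-allele set equals the full list's — a guarantee that coverage is
identical in every region. In the pipeline each pair covers exactly one
allele, making the pair-level optimum one pair per distinct allele; the
underlying solver (`min_set_cover()`) nevertheless accepts arbitrary cover
sets: greedy most-new-elements-first selection (ties: higher score, then
lexicographic label), redundancy pruning in reverse selection order, and an
exact branch-and-bound replacement whenever the allele universe has at most
20 elements. The stepwise filter-coverage audit applies exclusion rules
cumulatively and flags the first rule, if any, that reduces coverage.

## The synthetic generators

Every input has a seeded generator so the full pipeline runs offline:

* **Training table** — 109/654 rows by default. Positives draw binding
  ranks log-normal with median ~1 percentile (negatives uniform on
  (0, 100]), stability gamma with mean 6 h (vs 1.5 h), rank ratios
  log-normal with median ~1.6 (vs ~0.9), antigenicity shifted +0.35;
  immunogenicity and hydropathicity carry only weak shifts. Labels flip
  with probability 0.005. These effect sizes were fixed once so that the
  regime is learnable at the level reported for experimentally derived
  pairs — cross-validated random-forest accuracy near 0.95 and TPR near
  0.9 — without being trivially separable; `effect_scale = 0` produces a
  null table for permutation checks.
* **Protein + mutations** — a random canonical-alphabet protein (default
  1210 residues) with mutations at positions sampled without replacement
  (default 96), wild-type residues read from the protein.
* **Allele frequencies** — per region and locus, a Dirichlet draw scaled to
  a total mass uniform on [0.6, 0.95], leaving residual mass for unlisted
  alleles.

What the generator does **not** emulate: real MHC binding motifs, proteome
background frequencies, linkage between loci, correlated features beyond
the label, or any cancer's actual mutation spectrum. Green tests on
synthetic data therefore demonstrate that the machinery is correct and the
regime learnable — not that any biological conclusion transfers. Real
analyses should feed pre-computed scores from the actual prediction tools
through the CSV registry.

## Problem sizes used by the test suite

The shipped checks run at deliberately modest scale: brute-force coverage
oracles up to 3 loci × 4 alleles; optimizer optimality on 200 random
instances of ≤ 12 pairs × ≤ 8 alleles; physicochemical oracles on 1,000
random peptides (150 for the grid-scanned isoelectric point); enumeration
against the closed form on 10,000 random draws; the CV regime at the full
763-row table over 10 seeds; and the end-to-end demo on a 120-residue
synthetic protein with 6 mutations. The demo fixtures under
`inst/extdata/demo/` are generator output, labelled synthetic in their
headers, and exercise terminus truncation (one mutation sits 3 residues
from the C-terminus).

## Known limitations

* Only missense mutations are supported; frameshifts, insertions and
  deletions are out of scope by design.
* The models predict TIL induction, not clinical benefit.
* Mock predictor values are hash noise; any downstream number computed from
  them (e.g. the demo's coverage) characterises the machinery, not a
  vaccine.
* Coverage quality is bounded by the completeness of the supplied frequency
  table; class-II typing coverage is routinely the binding constraint.
* The exact-cover solver is exponential in principle; above 20 distinct
  alleles the greedy-plus-pruning answer (optimal in all randomized tests,
  but not guaranteed) is returned.
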