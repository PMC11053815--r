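# epivax

Epitope selection and population coverage for peptide-vaccine design.

Tumours driven by missense mutations expose mutant peptides (neoantigens)
that T cells can recognise when presented on HLA molecules. Designing a
peptide vaccine means choosing, from thousands of candidate
epitope–HLA combinations, the few that are likely to induce
tumour-infiltrating lymphocytes, carry no safety liabilities, and jointly
cover the HLA diversity of the target population. `epivax` implements that
selection as a tested R pipeline for immunoinformaticians and vaccine
developers.

The working unit is the **EHLA pair** — one candidate epitope with one HLA
allele. From a protein sequence and a mutation list (`L858R`-style tokens),
the package:

1. **enumerates** every mutant peptide window of configurable lengths
   (default 9/10-mers for MHC class I, 15-mers for class II) containing the
   mutated residue, each with its matched wild-type window, and crosses
   them with built-in 27-allele class-I and class-II panels;
2. **computes descriptors**: positional Kyte–Doolittle hydropathicity
   (sum over window positions 4…n−1), GRAVY, Guruprasad instability index,
   aliphatic index, isoelectric point (Bjellqvist pKa, bisection),
   N-end-rule half-life, and auto-cross-covariance (z-scale) antigenicity
   features; external predictions (binding percentile rank, stability,
   toxicity, allergenicity, IFN-γ) plug in through a registry — either
   pre-computed scores from the real tools (CSV) or deterministic seeded
   mocks for offline runs;
3. **classifies and ranks** class-I pairs with a cross-validated
   random-forest classifier (binary ID: 1 = predicted lymphocyte-inducing)
   and a linear-regression ranker (real-valued score), with an exhaustive
   feature-combination search over stratified five-fold CV and comparison
   families (SVM, naive Bayes, MLP; logistic/RF/gradient-boosting
   regressors);
4. **filters** both classes on exclusion criteria (toxin, half-life ≤ 1 h,
   instability > 40, probable allergen, negative IFN-γ,
   immunogenicity < 50, antigenicity < 0.4, ID = 0) with a per-rule audit;
5. **evaluates population coverage** under a per-locus Hardy–Weinberg
   diploid genotype model: coverage (≥ 1 hit), average epitope/HLA hits,
   and PC90 (hit count carried by ≥ 90% of the population, interpolated on
   the complementary CDF), plus a minimal set-cover optimiser returning the
   fewest pairs that preserve coverage exactly.

Seeded synthetic generators produce every input (training tables at the
109-positive/654-negative reference regime, proteins with mutation lists,
allele frequencies), so the full pipeline runs and is tested with no
network access. See `vignettes/epitope-selection-methods.Rmd` for the
models, assumptions and design decisions.

## Worked example

The bundled demo inputs (`inst/extdata/demo/`, synthetic data generated by
the package's own fixtures module) are a 120-residue protein with six
missense mutations:

```r
library(epivax)
demo <- function(f) system.file("extdata", "demo", f, package = "epivax")

res <- run_pipeline(run_config("DemoCancer",
                               protein   = demo("protein.fasta"),
                               mutations = demo("mutations.txt"),
                               out_dir   = tempdir(), seed = 1))
head(res$pairs_i[, c("mutation", "mutant_sequence", "allele",
                     "mhcflurry_rank", "id_label", "score")], 3)
#>   mutation mutant_sequence      allele mhcflurry_rank id_label    score
#> 1     E58K       QIMKKQDST HLA-A*30:02     0.04884989        1 50.40785
#> 2     E58K       WWGQIMKKQ HLA-A*02:06     0.03027134        1 25.50978
#> 3     G14I      KYVIWPQSDL HLA-B*58:01     0.21848576        1 22.26528
```

2,727 EHLA-I pairs are enumerated (windows per mutation × 27 alleles), of
which 340 survive filtering; the audit attributes every rejection to the
first rule it tripped:

```r
res$audit_i
#>                rule rejected
#> 1          toxicity      289
#> 2         half_life      307
#> 3 instability_index      927
#> 4     allergenicity      362
#> 5                id      502
```

Coverage of the filtered set against the bundled synthetic frequency
table, and the minimal pair set preserving it:

```r
freqs <- read_allele_frequencies(demo("allele_frequencies.csv"))
coverage_metrics(hit_distribution(res$pairs_i_filtered, freqs, "World"))
#> <coverage_report> World: coverage 99.90%, average hit 38.10, PC90 24.43

opt <- optimize_minimal_set(res$pairs_i_filtered, freqs, "World")
coverage_metrics(hit_distribution(opt, freqs, "World"))
#> <coverage_report> World: coverage 99.90%, average hit 3.06, PC90 2.35
nrow(opt)
#> [1] 27
```

The optimised set keeps coverage identical (the covered-allele set is
preserved) while the average hit drops — the filtered list is redundant per
allele, the optimised one minimal. The classifier's feature importances for
this run put binding rank first:

```r
round(res$models$importance, 3)
#>       antigenicity     hydropathicity     mhcflurry_rank  wt_mut_rank_ratio
#>              0.106              0.037              0.473              0.083
#> stability_halflife
#>              0.300
```

The run folder (`DemoCancer/`) contains `CD8 Epitopes.csv`,
`CD8 Filtered Epitopes.csv`, `CD4 Epitopes.csv`, `CD4 Filtered
Epitopes.csv`, `Sequence.txt`, the audit CSVs and a `manifest.yaml`; reruns
with the same config are byte-identical. All numbers above come from the
seeded mock registry — swap in real predictor scores via
`csv_registry()` for biological use.

A thin command-line front-end wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","epivax.R",package="epivax"))')" \
    run --cancer Demo --protein protein.fasta --mutations mutations.txt
```

with subcommands `run`, `train`, `cv-search`, `screen`, `coverage`,
`optimize`, `fixtures`.

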