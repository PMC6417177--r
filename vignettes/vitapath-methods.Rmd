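---
title: "Methods: profiling microbe-mediated vitamin metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling microbe-mediated vitamin metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitapath)
```

`vitapath` implements a complete desk-scale analysis of microbe-mediated
vitamin metabolism in gut metagenomes. This vignette describes the models
and procedures, the parameters that matter, the synthetic-data generator
used for validation, and the numerical and design choices made where the
design was genuinely open.

## The vitamin catalog

Every analysis is parameterised by a *catalog*: the mapping from each of
nine vitamins (biotin BIO, cobalamin COB, folate FOL, menaquinone MEN,
niacin NIA, pantothenate PAN, pyridoxine PYR, riboflavin RIB, thiamine
THI) to the KEGG Orthology (KO) identifiers of its biosynthesis and
transport gene sets, and to the Enzyme Commission (EC) numbers of its
biosynthetic and vitamin-dependent enzymes. The catalog is user-supplied
configuration (`load_catalog()`); the package ships a small illustrative
default (`default_catalog()`) and a synthetic generator
(`synthetic_catalog()`). A KO may belong to several vitamins — shared
enzymes are real — and the downstream summation counts such a gene once
per vitamin category, so per-vitamin sums are well defined even when the
sets overlap. Validation is strict (KO pattern `K#####`, EC pattern of
four dot-separated fields with a numeric first three) because catalog
typos silently zero out pathways otherwise.

## Total normalized pathway abundance

The per-gene normalized abundance in a sample is the number of reads
aligned to the gene divided by the **total** read count of the sample;
the pathway statistic is the sum of these fractions over the genes of one
vitamin's biosynthesis (or transport) set. Three choices deserve note:

- **Denominator.** Whether "total reads" means all sequenced reads or all
  mapped reads is a property of the upstream pipeline, not of this
  statistic. The denominator is therefore an explicit input
  (`sample_totals`); when absent we fall back to the column sum of the
  annotated count table, with a warning, since that is the only
  denominator the table itself can provide.
- **Annotation redundancy.** A gene annotated to two KOs of the same
  (vitamin, category) contributes once to that category; across vitamins
  it contributes to each. Without this rule, annotation redundancy — very
  common in KO assignments — would double-count reads within one pathway.
  The rule is pinned by unit tests.
- **No length normalization.** The statistic is read-fraction based by
  definition; RPKM/TPM-style corrections would change its meaning.

Values are dimensionless fractions in [0, 1], zero exactly when no
annotated gene of the set has reads in the sample. The implementation is
checked against a plain double-loop oracle on randomized 20 × 200 tables.

## Phenotype classification

Per species and vitamin, evidence is the presence of at least one gene
annotated to any KO of the respective set: biosynthesis evidence without
transport evidence gives Producer (P, prototroph), transport without
biosynthesis gives Consumer (C, auxotroph), both give Dual (PC), neither
gives absent. The threshold is deliberately presence/absence — one gene
suffices — because the classification captures *genetic evidence of
capability*; pathway completeness is scored separately from metabolic
reconstructions (below), and conflating the two would make the P call
depend on model coverage. Strains sharing a species name pool their
evidence. The four labels partition species × vitamin exactly, a property
the tests enforce, and `phylum_prevalence()` tallies how the associations
distribute across phyla.

## Co-occurrence network

Spearman's rank correlation is computed between all unordered species
pairs across samples, with average (mid-rank) ties. Classification uses
fixed thresholds: *positive* requires ρ ≥ 0.4 and p < α, *negative*
requires ρ < 0 and p < α, with α = 0.01 by default. The band
0 ≤ ρ < 0.4, and any non-significant or undefined correlation, is
*unclassified* — the thresholds leave this band unnamed, and we keep it
explicit rather than dropping the pairs so that counts always total
`n(n−1)/2`.

Significance of an edge is the Spearman correlation test: for n ≥ 10
samples the t approximation `t = ρ√((n−2)/(1−ρ²))` on n − 2 degrees of
freedom; for n < 10 an exact permutation distribution over all n!
rearrangements. A two-group rank test is sometimes quoted alongside
correlation counts in this literature, but such a test is undefined for a
single correlation; the correlation test is the defensible reading and is
what we implement. Other choices: zeros (absent species) enter the
ranking as ties with no pseudocount; a constant abundance vector leaves
the correlation undefined and the edge unclassified rather than raising
an error; no multiple-testing correction is applied across edges by
default (a `bonferroni_edges` flag enables it) because the group
comparisons, not the edges, are the inferential claims. Compositional
effects of relative abundances are acknowledged and not corrected —
SparCC-style estimators are out of scope — so edge signs near zero should
be read cautiously.

The summary reports counts and percentages of all pairs; the number of
pairs is always computed from the actual species set.

## GPR evaluation and pathway coverage

Genome-scale metabolic models attach to each reaction a boolean
gene–protein–reaction rule: `and` joins subunits of a complex, `or` joins
isozymes. The parser accepts case-insensitive keywords, parentheses and
arbitrary whitespace, with `or` binding loosest; `not` is rejected
because negation does not occur in these reconstructions, and accepting
it would silently break the monotonicity property (adding genes can never
remove a reaction) on which the coverage semantics relies. Parse errors
carry a character position.

Pathway coverage for a species and vitamin is the fraction of the
vitamin's reactions whose rule evaluates true given the species' present
genes. Reactions with missing gene annotation are genuine pathway members
whose evidence is unavailable: they count as absent, stay in the
denominator, and are reported separately — excluding them would inflate
coverage exactly for the least-annotated pathways. "Present genes"
default to every gene mentioned in the species' rules (pure
pathway-completeness mode); callers can intersect with detected genes via
`present_genes`.

Cohort matrices order rows by mean relative abundance in the reference
(healthy) cohort, descending, then append species absent from the
reference cohort ordered by their best abundance elsewhere; ties break
lexicographically so the order is a deterministic function of the
abundance table. A species absent from a cohort is flagged (`NA` weighted
value), which is semantically different from a present species lacking
a reaction (weighted 0); heatmaps render the flag as grey.

## Group statistics

Two-group comparisons use the Mann–Whitney–Wilcoxon test: exact p by full
enumeration when both groups have at most 8 observations and no ties,
otherwise the normal approximation with tie and continuity corrections.
Three or more groups use Kruskal–Wallis with tie correction and a
chi-square reference. Bonferroni correction multiplies by the family
size, capping at 1; the default family is the set of vitamin-categories
tested in one invocation (18 for a full profile: nine vitamins × two
categories). Star labels follow the conventional inclusive thresholds
(`*` ≤ 0.05 down to `****` ≤ 0.0001). Stars are attached to the **raw**
p-value, with the adjusted p reported alongside, so that readers can
apply either convention; this is stated rather than hidden because the
two conventions disagree precisely in the marginal band.

Indicator association pools samples into a binary classification (one
country versus the rest, diseased versus healthy) and regresses abundance
on the 0/1 indicator by OLS, reporting the slope and the model F
statistic — with a single binary predictor, F is exactly the squared
two-sample t statistic, which the tests pin. A logistic direction
(indicator ~ abundance) is provided for the reverse question and reports
the likelihood-ratio chi-square. No confounder adjustment is attempted;
these are deliberately marginal associations.

## The synthetic-data generator

`synthetic_spec()` / `generate_synthetic()` produce every input the
pipeline consumes, with planted structure the pipeline must recover:

- **Species abundances** are log-normal (sdlog 1, a realistic breadth for
  gut communities) and closed to fractions. A planted correlated pair
  shares a latent Gaussian factor with loading √|r| (sign-flipped on one
  member for antagonistic pairs); since Spearman correlation is invariant
  to the monotone exponential, the planted sign and approximate magnitude
  survive the transform, with mild attenuation from closure.
- **Phenotypes** are realized constructively: a species gets a gene
  annotated to a biosynthesis KO iff its planted label has biosynthesis
  evidence, likewise transport, so recovery is exact by construction.
  Unannotated housekeeping genes give every species a gene complement.
- **Read counts** are multinomial per sample over genes, with expected
  weight proportional to the species' relative abundance, half the read
  mass assigned to unannotated background (so sample totals exceed
  annotated sums, exercising the denominator logic), and planted group
  shifts applied multiplicatively to the target gene set's weights before
  the draw.
- **GPR models** contain four reactions per vitamin; planted completeness
  fractions must be exact multiples of 1/4 or the generator raises an
  infeasibility error naming the constraint. Satisfied reactions
  reference the species' own genes, unsatisfied ones reference genes the
  species lacks, so evaluated coverage equals the planted fraction
  exactly.

Defaults — 50 samples per group, 30 species over 4 phyla, 200,000 reads
per sample, a ×2 shift on biotin biosynthesis in the diseased group,
planted correlations 0.9 and −0.8 — describe a modestly powered
case-control study and were fixed once as the validation conditions. All
randomness flows from a single seed; identical seeds give byte-identical
bundles, which the tests verify by file hash.

What the generator does **not** emulate: sequence content, overdispersed
(beyond-multinomial) count noise, compositional coupling between many
simultaneously shifted pathways, phylogenetic correlation between
species, or sparse zero-inflated abundance patterns beyond what
log-normal sampling produces. Passing tests therefore demonstrate that
the machinery is correct and calibrated on data matching its assumptions,
not that real cohorts will show effects of this size.

## Validation suite and problem sizes

Every non-trivial operation is checked against an independent oracle:
mid-rank-then-Pearson for Spearman's ρ (30 tied vectors), exhaustive
enumeration of all C(n+m, n) rank assignments for the Mann–Whitney exact
p (all group sizes up to 7), a direct rank-sum formula for
Kruskal–Wallis H, truth-table recursion for GPR evaluation (100 random
trees), and plain double loops for the abundance summations. Calibration
checks use 2000 null replicates at n = 50/50 (type-I rate must lie in
[0.035, 0.065] at α = 0.05) and 20 generator seeds for end-to-end
recovery. These sizes keep the full suite around a minute while leaving
the Monte-Carlo margins comfortable.

## Known limitations

- Transporter annotation is biologically incomplete (transporters are
  evolutionarily diverse), so Consumer calls inherit the catalog's
  transporter coverage; an empty transport set makes a vitamin's C/PC
  labels unattainable by construction.
- Correlation on relative abundances is compositional; negative edges in
  particular can be induced by closure.
- The OLS indicator association is a marginal test with no confounder
  control, by design.
- Coverage treats annotation-missing reactions as absent; true pathway
  completeness may be higher than reported wherever models are sparse.
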