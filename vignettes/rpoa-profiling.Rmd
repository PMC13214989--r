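---
title: "Species-level profiling of Faecalibacterium from rpoA amplicons: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-level profiling of Faecalibacterium from rpoA amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

*Faecalibacterium* is one of the dominant butyrate-producing genera of the
human gut, and it is not one species: genomic work has split it into a
dozen species-level phylogroups (named species such as *F. prausnitzii*,
*F. taiwanense*, *F. longum*, *F. duncaniae*, plus yet-unclassified
groups). Conventional 16S rRNA amplicon surveys cannot separate these
groups, so their individual distributions and host/diet associations stay
invisible. The single-copy *rpoA* gene (RNA polymerase alpha subunit) is
conserved enough within the genus to design genus-wide primers against,
yet divergent enough between species groups (<94% inter-group nucleotide
identity over the amplified region, >=98% within groups) to resolve them
with a short amplicon.

`rpoaprofiler` implements this profiling method end to end: degenerate
primer design from a multiple alignment, in-silico PCR and specificity
screening, a group-annotated reference library with identity-separation
validation, tiered identity classification of amplicon sequence variants
(ASVs), per-sample composition with prevalence/richness summaries, a
cohort exclusion cascade, and the downstream statistical layer (rank
tests, Bray-Curtis ordination, PAM clustering, envfit-style vector
fitting, PERMANOVA, and multivariable linear diet associations with BH
FDR control). A simulation module generates mock communities and cohorts
so the entire pipeline is testable without downloading any sequence data.

## The classification model

Each ASV is compared against the amplicon regions of a curated reference
library (by default 106 *rpoA* sequences across the 12 species groups of
`faecalibacterium_taxonomy()`). The decision rule is a tiered identity
threshold on the best hit:

* best identity >= 98%: the ASV is assigned to the species group of the
  best-matching reference;
* 95% <= best identity < 98%: "Other Faecalibacterium" (candidate
  uncharacterized species);
* best identity < 95%: "Others".

All thresholds are inclusive on the retained side (98.0% is a species
assignment, 95.0% is "Other Faecalibacterium"). If several references in
different groups attain the best identity at >=98%, the earliest record
in library order wins and the result carries a `tie_flag`; this keeps
classification deterministic and auditable, and group-level composition
is unaffected because such ties essentially never cross the 94%
inter-group ceiling in a validated library.

### The identity definition

The underlying toolchain delegates "identity" to a clustering engine
without printing a formula, so the package fixes one and documents it:

* global alignment with free terminal gaps on both sequences
  ("overlap" alignment), scoring match +1, mismatch -1, gap -2;
* identity = matches / aligned columns, where aligned columns exclude
  the terminal-gap runs but internal gap columns count as mismatching
  columns;
* `N` in a read matches nothing (low-quality bases cannot inflate
  identity);
* among co-optimal (equal-score) alignments, the one with the most
  matches, then the fewest columns, defines the reported identity. All
  three quantities are invariant under swapping the sequences, so
  identity is exactly symmetric — a property a naive traceback does not
  have.

Under this contract a read that is an exact substring of a reference
scores 100%, and planting k substitutions at interior positions of an
L-mer gives exactly 100(L-k)/L. A substitution at the very first or last
aligned base is clipped by the free end gaps (clipping it raises the
score), so the arithmetic applies to interior edits; in practice amplicon
ends are primer-binding sites and are conserved. The kernel is a small
C++ dynamic program over the (score, matches, columns) triple; an
independent plain-R implementation of the same contract serves as the
test oracle.

## Pipeline thresholds

`filter_thresholds()` carries the study defaults, all inclusive exactly
as printed:

| parameter | default | meaning |
|---|---|---|
| `trim_3prime` | 23 nt | index bases trimmed from each read's 3' end |
| `min_asv_len` | 250 bp | shorter reads/ASVs discarded |
| `min_sample_reads` | 10,000 | samples below this are excluded |
| `genus_min_relab` | 1% | 16S genus-level floor for cohort inclusion |
| `kcal_range` | 600–4,000 kcal/day | dietary-outlier exclusion |
| `detection_relab` | 0.5% | detection threshold for prevalence and richness |
| `minor_median` / `minor_prevalence` | 1% / 10% | minor-label rule for the association layer |

The exclusion cascade runs in fixed order — low genus abundance, cancer
history, caloric outliers, low read count — and removes each participant
at the first applicable stage only, which reproduces the stage
arithmetic 660 − 55 − 13 − 3 − 9 = 580 when the categories are disjoint.

Relative abundances are computed over all retained reads, including
"Other Faecalibacterium" and "Others": the primers are genus-specific,
so the amplicon pool itself is the natural denominator. Species richness
uses the same 0.5% detection rule as prevalence; the source work states
the rule explicitly only for prevalence, and adopting it for richness is
the consistent reading.

## The ASV surrogate

Model-based denoising (and chimera removal) is out of scope; the package
uses exact-sequence dereplication across samples with singleton removal
as a deliberately simple ASV surrogate, and accepts externally produced
ASV tables through the same classification entry point. Consequences
worth knowing:

* every distinct error-containing sequence observed at least twice
  becomes its own ASV; with genus-specific primers and a 0.1%
  substitution error rate these variants still classify to the correct
  group (one or two mismatches in a 325-bp amplicon keep identity above
  99%), so composition is barely affected;
* singleton removal discards reads whose error pattern was seen only
  once. Reads from abundant templates are more likely to share an error
  pattern with another read, so retention is slightly biased toward
  abundant groups. On the staggered mock communities used for
  validation (below) this bias plus multinomial noise stays within a
  mean L1 distance of 0.02 from the true composition — but it is a real
  property of dereplication-based calling, and one reason model-based
  denoisers exist.

## The statistical layer

Rank tests are two-sided throughout, with alpha = 0.05. The
Mann-Whitney U test uses exact enumeration when the pooled sample is at
most 16 with no ties and the tie/continuity-corrected normal
approximation otherwise; Kruskal-Wallis applies the usual tie-corrected
H with a chi-square reference, and pairwise follow-ups are
Bonferroni-adjusted by the number of pairs. Bray-Curtis dissimilarity,
principal coordinates (Gower double-centering, no negative-eigenvalue
correction, deterministic axis signs: the largest-magnitude loading on
each axis is positive), one-way PERMANOVA (Anderson's pseudo-F with
seeded label permutations) and envfit-style vector fitting on the first
two axes (least squares, permutation p = (1 + exceedances)/(n_perm + 1))
are implemented in the package and cross-checked against vegan in the
test suite; PAM clustering and silhouettes call the `cluster` package,
with the silhouette-maximizing k selected over a scanned range (ties go
to the smaller k). Permutation counts default to 999 with mandatory
seeds; calibration checks in the tests use 199 permutations, where the
nominal 0.05 level is exactly attainable (p <= 0.05 iff at most 9 of 199
permuted statistics exceed the observed one).

The diet-association layer mirrors a multivariable linear microbiome
framework at the level the method requires: per feature, total-sum-scaled
relative abundance with a half-minimum pseudocount and log transform,
ordinary least squares on each exposure plus covariates (BMI, age, sex by
default), BH FDR across all feature-by-exposure tests, and confidence
tiers at q < 0.1 (high), < 0.25 (moderate), < 0.3 (exploratory). Features
are restricted to non-minor labels (median >= 1% or prevalence >= 10%).
Variance filtering and random effects present in the full framework are
omitted: the cohort is single-timepoint, so there is no grouping
structure to model.

One subtlety the tests make explicit: when a log-linear exposure effect
is injected into a closed composition, renormalization attenuates the
realized log-abundance slope below the injected coefficient (the
normalizer grows with the boosted component). The recovery checks
therefore compare the fitted coefficient against the realized slope on
the generator's true compositions, not against the raw injected value.

## What the simulators emulate — and what they do not

`simulate_reference_library()` builds a library from one random ancestor
core (283 bp between the two 21-bp primer sites, so primer-inclusive
amplicons are 325 bp). Each group mutates a disjoint set of signature
positions (6% of the core), which guarantees every cross-group pair
differs at enough sites to stay below 94% identity; strains within a
group add at most 3 further substitutions, keeping within-group identity
above 98%. Primer-site variants (expansions of the degenerate codes) are
fixed per group so they cannot erode the within-group floor. The
guarantee is enforced by construction and then independently re-verified
by all-pairs alignment in `validate_separation()`.

`simulate_sample_reads()` draws reads multinomially across groups,
uniformly across each group's reference amplicons, applies independent
per-base substitution errors, and appends a random 23-nt index tail so
the 3'-trim step is exercised. Reads are generated pre-merged (paired-end
merging is out of scope) and the default error model is
substitution-only, which keeps the identity arithmetic analytic.

`simulate_cohort()` generates 660 participants with host metadata (age
21–83, sex at the study's ~18/82 ratio, BMI, caloric intake, defecation
frequency, exercise, region, 16S genus-level abundance, cancer history,
18 diet-category intakes), Dirichlet species compositions whose
concentration defaults mimic a community dominated by *F. taiwanense*
and *F. longum* with intermediate *F. prausnitzii*, *F. duncaniae* and
Group 11, and the four exclusion categories at counts 55/13/3/9,
disjoint by default (an overlap switch exists to stress first-stage-wins
counting). Optional injected exposure effects are recorded in the
returned manifest.

None of this is phylogenetically realistic sequence evolution, there are
no quality scores, no chimeras, and no indel errors by default. Passing
the mock-community checks therefore demonstrates that the
classification, accounting and statistical machinery are correct under
the method's own assumptions — not that the wet-lab assay performs this
way on real stool, which is what the original validation experiments
(synthetic constructs, pure cultures, sequenced cohort) established.

## Validation problem sizes

The packaged checks use: a full 106-record/12-group library for
separation and amplicon geometry; staggered five-species mock
communities (one strain per species at 30/25/20/15/10%, 50,000 reads,
0.1% error, 10 seeds) for composition recovery, asserting mean L1 <
0.02; 50 planted-mutation ASVs on a short-amplicon library against a
brute-force R oracle for the 98/95 tier boundaries (including the exact
98.0% and 95.0% cases); enumeration oracles for the exact Mann-Whitney
branch (all split sizes of pooled n <= 10); 1e-8 reconstruction of
Euclidean configurations for PCoA; and 500–1,000-replicate null
calibrations for PERMANOVA and envfit rejection rates at alpha = 0.05.

## Copy-number arithmetic

`log10_copies()` converts a construct mass to gene copies with the
standard dsDNA constant of 650 g/mol/bp:
copies = mass[g] x 6.02214076e23 / (total bp x 650). The validation
construct is modelled as a 2,450-bp vector with a 990-bp *rpoA* insert;
100 pg of that 3,440-bp molecule is 7.43 log10 copies. The exact
vector/insert split is an assumption (only the printed log-copy value
constrains it); the arithmetic is monotone increasing in mass and
decreasing in length, so any geometry reproducing 7.43 at 100 pg is
equivalent for the assay's purpose.

## Known limitations

* The ASV surrogate is not a denoiser; at error rates well above ~0.1%
  per base, singleton filtering and error-variant inflation will distort
  composition. Feed externally denoised ASV tables for real data.
* Identity is defined by one fixed scoring scheme; closed-reference
  engines with different gap economics can tier borderline ASVs (within
  ~0.5% of a threshold) differently.
* PERMANOVA is one-way only, and envfit is restricted to the first two
  ordination axes (the plotted space).
* The association layer fits independent OLS models per feature and
  exposure; it does not model compositional dependence between features.
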