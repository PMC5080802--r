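---
title: "Models and methods behind equimir"
author: "equimir authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind equimir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`equimir` analyses equine (or any) small RNA sequencing data downstream of
alignment: it takes collapsed, placed read tags and produces a non-redundant
miRNA catalog, per-sample expression calls, tissue/breed specificity sets and
a two-group differential-expression table. Adapter trimming and read
alignment are out of scope; the package starts where a BED-like tag table
(or the built-in simulator) begins.

All genomic intervals inside the package are 1-based and closed, the native
convention of `GenomicRanges`/`IRanges` on which every container here is
built. BED-like 0-based half-open starts appear only in the tag TSV
interchange functions, and GFF3 (itself 1-based closed) needs no shift. A
single internal convention avoids off-by-one drift; we chose the Bioconductor
one rather than the BED one because the whole object model is Bioconductor.

# The biogenesis model behind discovery

A genuine miRNA locus leaves a characteristic footprint in small RNA data:
reads pile up on the mature arm of a stem-loop precursor with highly
consistent 5' ends (Drosha/Dicer cut precisely), a minority of reads covers
the star arm offset so that the mature/star duplex carries 2-nt 3' overhangs
on both strands, and the loop is essentially unread because it is degraded.
Random degradation fragments, by contrast, scatter uniformly and fold
unremarkably. Discovery proceeds in three steps.

**Excision** (`exciseCandidates`). Tags on one strand sharing a modal 5'
position with summed count at least `minStackCount` (default 5) form a
stack. The most abundant tag is the putative mature; `window` nt (default
70) of flanking genome on each side is excised and folded. The star arm is
placed at the duplex partner of the mature with the canonical +2 offset.
Because a global fold of 160 nt of sequence occasionally adds a stray base
pair at a mature edge, the duplex geometry is derived from the dominant
pairing diagonal (partners with `i + partner(i)` within 6 of the median),
not from raw edge partners; stacks whose mature is less than 60% paired are
discarded as non-hairpin.

**Folding** (`foldHairpin`). A self-contained Nussinov-style dynamic
program maximizes total pair weight (GC = 3, AU = 2, GU = 1, minimum loop 3)
over non-crossing structures, implemented in C++ with a full traceback to
dot-bracket. The reported "MFE" is the negated optimal weight: a model
score with the right ordering (more and stronger pairs fold lower), not a
thermodynamic free energy in kcal/mol. We deliberately ship our own folder
rather than calling an external structure-prediction binary, so the package
has no runtime system dependencies; the test suite proves the implementation
optimal against an independently written exhaustive recursion on all short
sequences. No minimum sequence length is enforced — the folder is exact at
any length, and the short-sequence regime is exactly where it is verified.

**Scoring** (`scoreCandidate`). Four additive log2 likelihood-ratio terms
against a uniform-fragmentation null:

* *position*: reads concentrated on the mature arm versus its share of the
  hairpin, `log2(((m+1)/(n+2)) / (w_mature/w_hairpin))`;
* *consistency*: the modal 5' fraction of mature reads versus `1/w_mature`;
* *star*: `min(log2(1 + star reads), 4)`, read support on the star arm
  being strong evidence of true Dicer processing;
* *structure*: `min(max(-z, 0), 8)` where `z` is the fold score's z-score
  against 20 refolds of dinucleotide-chunk-shuffled sequence (2-mer chunks
  permuted; a light-weight composition-preserving shuffle).

A fixed offset of 10 is subtracted so that the strongest background stack a
uniform fragment field can produce (all reads on one tag: position ≈ 2.9,
consistency ≈ 4.5, no star, structure ≈ 0) lands well below the conventional
score cutoff of 1, while clean planted loci score 4–7. The offset and caps
were calibrated once on the simulator's positive/negative controls and are
part of the score's definition. Adding mature-arm reads at the modal
position can only raise the first two terms, which gives the documented
monotonicity.

`signalToNoise` repeats excision + scoring on position-permuted tags
(lengths, counts, chromosome and strand preserved; positions uniform) and
reports real versus mean permuted call counts over integer cutoffs −10..10,
the calibration used to justify a score cutoff in practice.

**Stringent criteria mode** (`evaluateCandidate`, `callMirnas(mode =
"dentify")`) computes ten biogenesis criteria — 5'/3' end heterogeneity,
the two-nucleotide 3' overhang check at both duplex ends, duplex and
flanking energies, nucleotide entropy, structural complexity, A/U tailing
and the multimap factor — and requires all of them to pass. The named
criteria follow the high-stringency discovery convention; their numeric
cutoffs are not published, so the defaults here (`hMax = 0.33`,
`mfeMax = −15`, `eMin = 1.5` bits, `sMax = 4`, tailing optional-off, at most
4 genomic hits) are this package's choices, all exposed through
`dentifyThresholds()`. Two remarks on definitions we fixed ourselves: the
flanking-energy comparison is made per nucleotide (duplex density must beat
flank density — raw totals would always favour 140 nt of flank over a 44-nt
duplex), and structural complexity is `log2` of the number of runs in the
dot-bracket over the stem-loop core (a clean helix has few runs, a frayed
fold has many). On clean simulated loci the stringent mode calls a strict
subset of the score-based calls, reproducing the qualitative ordering of
high-stringency versus score-based discovery tools.

Mature length is recorded but not hard-filtered at discovery time; length
selection, if desired, belongs to the expression-filter stage.

# Catalog consolidation

Per-sample calls merge when they lie on the same chromosome and strand and
both their start and end differ by at most 2 nt — isomiR end wobble. We
read the 2-nt rule as applying to both ends simultaneously, and implement
merging as the transitive closure of that relation (union-find), which makes
the grouping provably independent of input order. The representative of a
group is the variant seen in most samples, ties broken by score, then by
coordinate. Groups supported by a single *sample* (however many calls) are
dropped. Tool-specific groups are consolidated first, then unioned across
tools with the same rule, keeping provenance.

Known-miRNA annotation distinguishes: an exact same-strand match (the entry
*is* the known miRNA — not novel); a same-strand match shifted or shortened
by ≤ 2 nt at the ends (`near-identical` — kept novel, with the partner
recorded, matching how slightly-shorter variants of known miRNAs are
reported as novel discoveries); any other same-strand overlap (treated as a
known match); and an antisense overlap (`opposite-strand` — novel, the
biologically interesting case of a miRNA on the opposite strand of a known
one). An entry is never both known and novel.

Genomic clusters chain entries whose hairpin start-to-start distance is at
most 3000 nt (single linkage, strand-agnostic); the anchor choice
(start-to-start) is ours, the distance is the field's convention.
`chromosomeSummary` pools scaffold-like names as "Unplaced".

# Expression

`quantifyTags` counts a tag toward a mature/hairpin combination when it
falls within the mature interval ± 2 nt on the same strand; a tag matching
several combinations (one mature can derive from two hairpins) contributes
its full count to each, so shared-arm expression is visible in every
combination. Normalization is cpm on effective library sizes with TMM
factors computed from the weighted, doubly trimmed (30% on M, 5% on A) mean
of log2 expression ratios against the sample whose upper quartile is closest
to the panel mean. Precision weights use the delta-method binomial variance
on the *proportion* scale, which makes the factor exactly invariant to pure
depth changes (depth is the library size's job); the factors are rescaled to
geometric mean 1 and agree with the reference implementation of the cited
method to within ~1% on biased matrices. Note the direction: a sample in
which a subset of miRNAs is artificially inflated receives a factor *below*
one, shrinking its effective library so the untouched majority is restored.

Two threshold rules drive the expression sets, both configurable:

* *prefilter*: a miRNA is dropped when its cpm is below 1 in at least 90% of
  all samples (computed on library-size-only cpm; TMM is applied afterwards
  for all downstream steps — the pipeline fixes this ordering explicitly);
* *group expression*: a miRNA is expressed in a group when its cpm reaches
  at least 10 in at least 90% of the group's samples. The "≥ 10" reading is
  used (where sources disagree between ≥ and >, the Methods-style statement
  wins); group-specific means expressed in exactly one group, universal in
  all. Group-specific entries with group mean TMM-cpm above 100 are reported
  separately (the "mean expression" is taken on TMM-cpm).

`mdsCoordinates` embeds samples by classical metric scaling of pairwise
root-mean-square of the 500 largest absolute log2 fold changes (leading
logFC), on cpm + 0.5 pseudocount. The 0.5 pseudocount for all log-ratio
work is a package-wide choice.

# Differential expression

The serum two-group path (`runDE`) keeps miRNAs above 10 cpm in 90% of
samples, TMM-normalizes, scales every column to the geometric-mean effective
library size with mean-preserving rounding (this summarizes quantile
adjustment by its contract — equal effective sizes — rather than reproducing
the full quantile mapping), estimates a common negative binomial dispersion
by conditional maximum likelihood given per-group totals (grid search over
φ = 0 and 26 log-spaced values up to 10, refined by golden section;
deterministic), and applies the conditional exact test per miRNA: given the
total t of the two group sums, the first group's sum follows a
beta-binomial-type law free of the mean, and the two-sided p-value sums all
outcomes no more likely than the observed one (minimum-likelihood method,
ties included). At φ = 0 this reduces to the exact binomial test. For large
totals the law is evaluated on a ±12-standard-deviation window around its
mode; the truncated mass is below 10⁻¹⁴ and every truncated outcome is less
likely than any observed one, so p-values are unaffected to well beyond
reported precision. Benjamini–Hochberg FDR (via `p.adjust`) and the
FDR < 0.001 call complete the path; log2 fold changes use normalized group
mean cpm with the 0.5 pseudocount and are therefore always finite.

Covariate screening (`covariateScreen`) routes binary covariates (sex)
through the identical exact-test path and numeric covariates (age,
haemolysis absorbance at 414 nm) through a per-miRNA Spearman rank
correlation on log2(cpm + 0.5) — a deliberately conservative nonparametric
choice, since no specific method is prescribed for covariate checks; a
model-based covariate adjustment is a known limitation, not provided.

# The synthetic-data generator

The generator exists so that every stage has an offline, seeded positive and
negative control; its defaults are the study-like conditions used throughout
the tests.

* **Genomes** are uniform-composition random sequences — no repeats, no GC
  structure.
* **Loci** are perfect inverted-repeat hairpins (22-nt mature, 15-nt loop,
  arm identity 1 by default) carrying exact 2-nt 3' overhang duplex
  geometry, planted on either strand and either arm; a configurable
  fraction is chained within 3000 nt to emulate genomic miRNA clusters.
  Real pre-miRNAs have bulged, imperfect stems; `armIdentity` lets you
  degrade the duplex, but the clean default defines the positive control.
* **Read stacks** split each locus' depth (default 50×) multinomially over
  mature (0.70), star (0.15), loop (0.02) and a uniform remainder; 5' ends
  jitter with a configurable sd (0 in the clean profile), and 10% of reads
  carry 1–3 untemplated 3' A/U nucleotides, recorded in a separate `tail`
  column so the genomic interval always matches the templated sequence.
  Background fragments follow the serum-like two-peak length mixture — 78%
  at 30–32 nt (piRNA-sized) and 4% at 22–23 nt, the remainder uniform over
  the other lengths in 18–35 — at uniform positions; only serum mixtures are
  characterised, so these are configurable defaults, not assertions about
  solid tissues. Multimapper status (nHits) is simulated metadata attached
  to a fraction of background tags, not recomputed by re-alignment: the
  artifact starts downstream of alignment.
* **Count matrices** draw NB counts (Poisson at φ = 0) around log-normal
  relative abundances times uniform library sizes, with multiplicative
  planted group effects and an optional composition-bias block to exercise
  TMM. Metadata (tissue, breed, sex, age, absorbance414) is generated
  alongside.

What passing tests on this generator do *not* show: robustness to repeat
regions, isomiR clouds beyond end wobble, sequencing error, colour-space
artefacts, or imperfect hairpins — none of which the generator emulates.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use 20 planted loci at 50×
depth on a 100-kb two-chromosome genome for discovery controls, an 8,000-
fragment background on a 3-kb genome for the 100-round permutation
calibration, 600 miRNAs × 49 samples (44 + 5, the unbalanced serum design)
with 50 planted effects of |log2FC| 2–4 for DE recovery, and 10,000 null
miRNAs for exact-test calibration. These sizes give stable statistics in a
few minutes on one core while exercising every code path; all of them scale
up through the same functions.

Tie-breaks and degenerate inputs are fixed rather than left to chance:
representative selection breaks ties by score then coordinate; stack
processing orders by count then position; an empty locus set with no
background yields empty tags, not an error; a group with fewer than two
samples warns at expression calling and errors at dispersion estimation
(one sample carries no within-group information); all-zero columns are
rejected by TMM with the offending sample named; p-values of zero totals
are 1 by convention (the only possible outcome).

# Known limitations

* The folding model is a pair-weight maximization, not a nearest-neighbour
  thermodynamic model; energies are comparable only within this package.
* Discovery assumes collapsed tags with correct `nHits` metadata; it never
  re-aligns.
* The catalog's known/novel annotation depends on a user-supplied known-set
  GFF3/GRanges; with an empty known set everything is novel by
  construction.
* `covariateScreen` tests one covariate at a time; confounded covariates
  need a model-based approach outside this package's scope.
* Read-context annotation covers gene-centric categories only (CDS, UTRs,
  introns, 1/5/10-kb flanks as disjoint rings, intergenic); repeat and
  structural-RNA classes are not annotated.
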