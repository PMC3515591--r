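---
title: "mirseq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirseq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirseq)
```

# Scope

`mirseq` implements a complete small RNA sequencing analysis for plant
miRNA work: read cleaning, collapsing to unique tags, genome mapping and
category annotation, known mature miRNA identification, novel hairpin
precursor calling, TPM-normalised differential expression under the
Audic–Claverie Poisson model, and rule-based target prediction. A
first-class synthetic-data module generates a toy genome with planted
hairpins, four condition/tissue libraries with designed effects, and a toy
transcriptome with planted target sites, so every stage can be scored
against a known truth without any external download.

This vignette documents the models, the defaults and why they were
chosen, the numerical choices, and the limits of what the synthetic
benchmark can demonstrate.

# Read cleaning

The cleaning cascade mirrors standard sRNA-seq practice: (1) quality
filtering, (2) 3' adapter trimming, (3) trailing poly-A stripping, (4)
length selection to 18–30 nt.

Quality is judged by mean Phred score with a default cut of 20 and at
most one ambiguous base. These values are explicit, configurable
stand-ins for the loosely-specified "low quality" filters of classic BGI
pipelines; the synthetic generator injects its low-quality reads at mean
Phred below 10, well clear of the boundary, so cleaner and generator
agree by construction rather than by coincidence.

Adapter trimming scans for the leftmost read position where a prefix of
the adapter matches the read suffix, requiring at least 6 bases of
overlap and tolerating one mismatch per ten bases of overlap. Reads with
no detectable adapter are discarded: for a short-insert library the
adapter must appear within the read, and its absence means the 3'
boundary of the insert is unknown. A trailing run of six or more A's is
treated as a ligation/degradation artefact and stripped before the length
test.

# Category annotation

Unique tags are assigned to exactly one category with the fixed priority

rRNA > tRNA > snRNA > snoRNA > miRNA > exon-sense > exon-antisense >
intron-sense > intron-antisense > unannotated.

This single-assignment scheme makes the categories a partition, so unique
and total counts sum to the library totals — the invariant the test suite
checks. ncRNA membership is an exact substring match against the class
reference in either orientation; known-miRNA membership allows up to two
substitutions and a ±2 nt end shift (isomiR-style ends); exonic/intronic
assignment uses each tag's best (fewest-mismatch) genomic alignments,
with sense defined as "tag strand equals annotated gene strand".
Genome mapping allows up to two substitutions and no indels, reported on
both strands; it is implemented as an exact seed-and-extend search (6-mer
index, pigeonhole segmentation) that the tests compare against a
brute-force sliding-window scan.

Multi-mapping tags are categorized by their best hits; when best hits
support several categories the highest-priority one wins. This mirrors
the convention that produces "unannotated" as the residual class.

# Known miRNA identification

Tags are compared to a miRBase-style mature reference under U/T
equivalence. A hit requires at most two substitutions in the overlap; end
offsets up to ±2 nt are tolerated because sequenced mature ends rarely
match the reference ends exactly. The best hit (fewest mismatches, then
smallest absolute offset, then lexicographically smallest id) receives
the tag's full counts, so a read is never credited to two families and
the per-family table stays consistent with the category partition.
Mismatched tags are included in the counts by default; exact-only
counting is available by setting `max_mm = 0`.

# RNA folding

Novel-precursor calling needs a folding engine, and the package embeds
its own: a Zuker-style dynamic program over a nearest-neighbour energy
model (Turner-style stacking table for the six canonical pair types
including G:U; logarithmic hairpin, bulge and internal loop penalties
with a Jacobson–Stockmayer slope of 1.75·RT; an affine multiloop term of
3.4 kcal/mol per closed multiloop plus 0.4 per helix; no dangling ends,
coaxial stacking or terminal-AU terms; interior loops bounded at 30
unpaired bases during the search; minimum hairpin loop of three). The
model is deliberately compact: the package's acceptance decisions depend
on hairpin *classification*, not on matching any particular published
free-energy value, and a compact model keeps the dual implementation
honest — the same parameter set drives the C++ dynamic program and a
pure-R loop-decomposition evaluator (`structure_energy()`), and the test
suite enumerates all nested structures of short sequences as an
independent oracle. Since the open chain has energy zero, reported MFEs
are never positive; ties between co-optimal structures are resolved by
the traceback order, and the invariant actually asserted is that the
returned structure attains the enumerated optimum.

# Novel precursor calling

Unannotated tag alignments are clustered (merge gap 30 nt), extended by
±200 nt flanks, and clipped to scaffold bounds; each window inherits the
count-weighted majority strand of its cluster. Within a window the
putative mature is the most abundant supporting tag of 18–26 nt (ties:
longer tag, then 5'-most occurrence). Windows longer than 400 nt are
folded as a 400-nt subwindow centred on the mature.

From the window fold, the mature/star stem is extracted (the mature plus
its pairing partners, grown outward along directly-enclosing base pairs,
allowing unpaired gaps of up to 5 nt), refolded, and tested:

* the mature must map entirely to one arm (all partners on one side);
* the arm must belong to a single stem: partner positions strictly
  monotone and exactly one terminal hairpin loop inside the innermost
  mature pair — no multibranch between the mature and the loop;
* at least 16 mature positions paired (G:U counts as paired);
* at most 4 unpaired mature bases and mature/star span asymmetry of at
  most 2;
* MFE at most −18 kcal/mol;
* precursor length within 70–365 nt.

The first failed test is reported as the rejection reason. The criteria
bundle is a configurable list (`precursor_criteria()`), with defaults in
the MIREAP tradition; the −18 kcal/mol floor and the 70–365 nt bounds
match the observed extremes of plant pre-miRNA surveys. The structural
tests are evaluated in dependency order (arm before stem topology, which
the topology test needs), so a window can fail "arm" where a strict
reading of the list order would say "multibranch"; the accept/reject
decision is unaffected.

# Differential expression

With pooled libraries and no replicates, the unit of inference is
Poisson sampling of reads. Counts are normalised as transcripts per
million (count / clean-read total × 1e6). Fold changes are
`log2(TPM_treatment / TPM_control)` with both TPMs floored at 0.01 so
zero counts give large but finite values.

Significance uses the Audic–Claverie conditional mass

$$p(y \mid x) = \Big(\frac{N_2}{N_1}\Big)^{y}\,
  \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y}}.$$

The down-regulation tail accumulates $p(y' \mid x)$ for $y' \le y$; the
up-regulation tail is the same accumulation with the two libraries'
roles exchanged ($p(x' \mid y)$ for $x' \le x$); the two-sided p-value is
twice the smaller tail, capped at one. This formulation was chosen over
"twice the smaller tail of a single conditional distribution" because it
is exactly symmetric under exchanging (x, N1) with (y, N2) — a property
a two-library comparison should have and which the role-fixed form
provably lacks — while agreeing with the single-tail form in all
boundary cases (equal counts at equal depths give p = 1; so do empty
observations). Both tails are finite sums computed in log space via
log-gamma, so counts into the millions pose no overflow risk.

A miRNA is called significant at p < 0.01 and |log2FC| > 1. The p-values
are used raw by default; Benjamini–Hochberg adjustment is available
behind a flag (`call_de(..., adjust = TRUE)`) since no specific
adjustment procedure is canonical for this test.

# Target prediction

Plant miRNA targets are near-perfectly complementary, so the duplex
model is ungapped: the miRNA is slid along each transcript and every
window of miRNA length is scored positionwise, position 1 being the
miRNA 5' end. Watson–Crick pairs are matches; G:U pairs are wobbles
weighted 0.5; everything else is a mismatch weighted 1. The five
acceptance criteria are: (i) at most 4 weighted mismatches; (ii) no run
of three or more mismatches; (iii) no adjacent mismatches within
positions 2–12; (iv) no mismatch at positions 10–11; (v) at most 2.5
weighted mismatches in positions 1–12. Under the default semantics a
wobble counts toward the weighted totals of (i) and (v) but does not
trigger the positional rules (ii)–(iv), matching common plant-target
scoring practice; `strict_wobble = TRUE` treats wobbles as mismatches
everywhere. An ungapped model was chosen because the positional rules
are undefined under gaps.

# The synthetic experiment

The generator is the package's benchmark definition, not a tuning knob.
Defaults: 20 planted miRNA hairpins on two 50 kb scaffolds; four
libraries (leaf/root × control/stress) of 1e5 reads; per-miRNA design
abundances log-uniform over three decades normalised to a 13% miRNA read
fraction; per-tissue designed log2 fold changes drawn from {−1.5, 0,
1.5} with nulls four times as likely; contaminant fractions of 6% rRNA,
2% tRNA, 0.3% snRNA, 0.2% snoRNA, 3% exonic, 3% intronic fragments; a
background fragment-length distribution peaking at 24 nt (the canonical
plant sRNA length mode, with the planted matures centred at 21 nt); 0.2%
injected low-quality reads and 0.5% sub-18-nt inserts to exercise
cleaning. Reads are Poisson around their design means (negative-binomial
overdispersion is available but off by default, matching the pipeline's
Poisson inference model). The unannotated genomic class absorbs the
remaining mass, so the expected class proportions sum to one before
sampling.

Planted hairpins are built as mature + 8–20 nt loop + near-reverse-
complement star (up to two designed G:U wobbles), with the stem extended
through 15–40 nt near-complementary flanks. The extension makes the
whole planted locus fold as a single dominant stem of at least 70 nt, so
the called precursor spans essentially the planted coordinates; plain
unstructured tails would leave the called stem shorter than the 70 nt
floor and make locus recovery ill-posed. Minus-strand loci are written
as reverse complements, so the reverse complement of the genomic slice
reproduces the precursor.

What the benchmark does not emulate: sequencing error beyond uniform
substitution (default zero), ligation bias, isomiR end heterogeneity,
repeat-derived multi-mapping ambiguity, and real secondary-structure
context around loci. Passing the synthetic benchmark therefore
demonstrates the internal correctness and calibration of each stage
under its own model assumptions, not performance on real libraries.

# Problem sizes and numerical choices

The test suite and the acceptance script run the generator at reduced
scale — a few thousand reads per library for end-to-end runs, 50 planted
hairpins for the caller benchmark, 20 × 1000 draws for the
differential-expression calibration — sizes chosen so the whole suite
completes in minutes while keeping every Monte-Carlo margin wide
relative to its threshold. Folding is O(n³) and capped at 400 nt per
window; energies compare with a 1e-9 tolerance; Audic–Claverie tails are
log-space sums; deterministic behaviour under a fixed seed is asserted
byte-for-byte on the output manifests.

# Known limitations

* The energy model is compact by design; absolute MFE values differ from
  full Turner 2004 implementations (no dangles, no special hairpins, no
  coaxial stacking). Hairpin classification, which is what the caller
  consumes, is robust to this.
* Without replicates the Audic–Claverie test inherits the Poisson
  assumption; real biological variability inflates its significance, and
  the optional negative-binomial generator mode exists precisely to
  explore that gap.
* The target rules are a word-match filter; no thermodynamic target
  scoring (e.g. duplex free energy or site accessibility) is attempted.
* GO/KEGG annotation of predicted targets requires external database
  services and is out of scope.
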