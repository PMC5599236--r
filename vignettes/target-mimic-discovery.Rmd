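---
title: "Discovering transposon-derived miRNA target mimics: models and methods"
author: "TEmimic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering transposon-derived miRNA target mimics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TEmimic)
```

## The biological question

Transposable-element (TE) transcripts that carry miRNA-binding sites can
behave as competing endogenous RNAs (ceRNAs): they bind a miRNA without
being cleaved and thereby sequester it away from its protein-coding
targets. The canonical plant example is a non-coding transcript whose
miRNA site is disrupted exactly at the cleavage register, so the miRNA
binds but cannot slice — a *target mimic*. This package implements the
computational chain by which such TE-derived mimics are nominated from a
plant transcriptome: quantify TE expression, scan transcripts for
miRNA-binding sites, classify each site as cleavable or mimic, connect TEs
to genes through shared miRNAs and sequence homology, require correlated
tissue expression, check degradome (PARE) evidence, and date the
underlying retrotransposon insertions.

Every stage is testable without external data because the package ships a
synthetic-data generator that plants known structure (mimic sites,
correlations, cleavage peaks, mutated LTR pairs) and emits the ground
truth alongside the files.

## Duplex expectation scoring

A mature miRNA (19–24 nt) is aligned against a candidate transcript site
in the reverse-complement register: miRNA position 1 (5' end) pairs the
3'-most base of the site. Each alignment column is penalised:

| column state        | penalty |
|---------------------|---------|
| Watson–Crick match  | 0       |
| G:U wobble          | 0.5     |
| mismatch            | 1.0     |
| bulged base (gap)   | 2.0     |

and every penalty is doubled when the miRNA position lies in the seed
window, positions 2–13 from the miRNA 5' end. The sum is the *expectation*
score; sites with expectation at or below the cutoff (default 3.0) are
retained. These defaults reproduce the behaviour of the widely used plant
target-prediction servers in their classical (V1-style) parameterisation;
different published server versions use slightly different defaults, so
penalties, seed window, factor and cutoff are all arguments.

At most one bulge of up to 3 nt per duplex is considered (a site longer
than the miRNA implies a target bulge, shorter a miRNA bulge). This covers
the experimentally characterised mimic geometries — central mismatches and
the classical 3-nt bulge at the cleavage site — while keeping the search
space small enough that the scanner can be verified against exhaustive
enumeration. Overlapping hits of one miRNA are resolved deterministically:
lowest expectation, then leftmost start, then shortest site.

Coordinates are 1-based inclusive throughout, the convention of the
R/Bioconductor sequence stack; miRNA positions are 1-based from the 5'
end.

## The mimicry rule

Plant miRNA-guided cleavage cuts the target opposite miRNA positions
10–11. A site whose duplex carries a mismatch or bulge at a miRNA
position inside the *central window* — default 9–12, covering the
scissile register with one position of slack — binds but resists
cleavage and is classified a **mimic**; otherwise it is **cleavable**.
A mismatch at, say, position 14 does not affect the class: only central
defects block slicing. The window is configurable because the literature
varies in how much slack around positions 10–11 it allows.

```{r mimicry}
mir <- "UGAUUGAGCCGCGCCAAUAUC"
site <- as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(chartr("U", "T", mir))))
# disrupt positions 11 (central) and 14 (peripheral)
substr(site, 21 - 11 + 1, 21 - 11 + 1) <- "A"
substr(site, 21 - 14 + 1, 21 - 14 + 1) <- "T"
classifyMimicry(scoreDuplex(mir, site))
```

## Homology patches and orientation

TE-derived regulatory potential presupposes sequence homology between the
TE transcript and the gene transcripts it would compete with. The package
finds local homology patches by Smith–Waterman alignment with affine gaps
(match +1, mismatch −2, gap open −4, gap extend −1; a gap of length
\(k\) costs \(-4 - k\)), run against the gene ("sense") and its reverse
complement ("antisense"). All non-overlapping patches with score at or
above `min_score` (default 20) are reported; after each patch is taken,
its residues are masked and the alignment repeats. The defaults favour
near-exact patches of roughly 20 nt and longer — TE-derived fragments —
rather than sensitive remote homology; they are not tuned to reproduce
any genome-scale fractions, which depend on external data and unstated
aligner settings. Comparison is intended against processed mRNA
sequences; intron-containing input simply makes both sequences longer and
is the caller's choice.

## Expression, the transcribed-TE filter, and pairing

RPKM is computed as
\(\mathrm{count} / \big((\mathrm{length}/10^3)\,(\mathrm{library\ size}/10^6)\big)\)
and held in a `SummarizedExperiment` with the sample-to-tissue map in
`colData`. A TE counts as *transcribed* when its maximum RPKM over all
samples strictly exceeds the threshold (default 1), the standard
maximal-RPKM rule.

A TE–gene *candidate pair* requires (i) at least one predicted site for
the same miRNA on both transcripts and (ii) at least one shared homology
patch; its orientation is that of the highest-scoring patch. Pair
correlation is the Pearson coefficient over tissue-mean expression —
replicates of one tissue are averaged first, treating them as one
expression context — computed on `log2(RPKM + 1)` by default. The log
transform is the standard variance stabilisation for RPKM; raw-scale
correlation is available (`log_transform = FALSE`) because published
analyses do not always state their transform. Pairs with `r` above the
threshold (default 0.5) are flagged.

## Site-density enrichment and the rank-sum test

Binding-site counts are length-corrected to sites per kilobase before
group comparisons. The Wilcoxon rank-sum test is implemented from first
principles because it is part of the evidential chain rather than a
convenience: mid-ranks for ties; for pooled sizes up to 12 the null
distribution of the rank sum W is enumerated exactly over all
\(\binom{n_1+n_2}{n_1}\) assignments; larger samples use the normal
approximation with tie-corrected variance and a continuity correction of
0.5, with two-sided p doubling the smaller tail (capped at 1). The exact
threshold of 12 keeps full enumeration instantaneous while the normal
branch is already accurate there (the maximal two-sided p discrepancy at
\(n_1 = n_2 = 6\) without ties is about 0.016, verified by enumeration in
the test suite).

## Degradome evidence

Degradome/PARE profiles give per-position counts of uncapped 5' ends. For
a predicted site the expected cleavage position is the transcript base
paired to miRNA position 10, derived from the duplex alignment (a bulge
spanning the register makes the point ambiguous, and an interval is
returned). The signal at the site is graded with CleaveLand-style
categories:

* **0** — peak is the unique transcript-wide maximum, more than one read;
* **1** — tied transcript-wide maximum, more than one read;
* **2** — above the transcript mean, more than one read;
* **3** — at or below the mean, more than one read;
* **4** — at most one read.

A site *supports cleavage* when its category is at most 2 **and** the
peak lies within the tolerance (default 1 nt) of the expected position.
Published browser snapshots of degradome evidence do not state numeric
thresholds, so this scheme encodes one explicitly and keeps it
configurable.

## LTR insertion dating

The two long terminal repeats of a retrotransposon are identical at
insertion; divergence between them clocks the insertion age. Divergence D
is the p-distance over aligned non-gap columns (unequal-length input is
globally aligned first: match +1, mismatch −1, −2 per gapped position).
With substitution rate t (default \(1.3\times10^{-8}\) per site per
year, the conventional rate for rice intergenic DNA):

* paired LTRs: \(T = D/(2t)\) — both copies accumulate substitutions;
* solo LTR vs family consensus: \(T = D/t\) — the consensus stands for
  the youngest copy.

The default divergence is the raw p-distance, matching the dating formula
as used in the field; an optional Jukes–Cantor correction
\(D_{JC} = -\tfrac34\ln(1-\tfrac43 p)\) is available behind a flag as the
principled upgrade at larger divergences. Consensus building is
majority-rule per column (ties broken A < C < G < T, gap-majority columns
dropped) and expects pre-aligned input; multiple alignment itself is out
of scope and can be done with any external aligner.

Note a known property of p-distance dating: under independent site
substitutions, coincident hits on both copies remove differences, so the
estimator acquires a downward bias of order \(q^2\) (q = rate × age per
copy). At divergences of a few percent — the regime of the worked
examples below — the bias is negligible relative to Monte-Carlo error;
near p-distance 0.1 it reaches a few percent of the age, which is why the
round-trip recovery test in the suite runs at the younger (solo-LTR
scale) age and why the JC flag exists.

```{r ltr}
estimateAge(0.0962, 1.3e-8, "paired")   # the paired worked example
estimateAge(0.0156, 1.3e-8, "solo")     # the solo worked example
```

## The synthetic-data generator

`simulateDataset()` generates every input the pipeline consumes, with
ground truth. What it emulates, and the default study conditions:

* **Transcripts and sites.** Random-composition genes (60) and TEs (40)
  of 600–1500 nt; 40% of genes carry a planted *cleavable* site (perfect
  complement, optionally one non-central G:U wobble), 25% of TEs carry a
  planted *mimic* site (mismatch at position 11; the first, flagship TE
  carries the two-mismatch 11 + 14 geometry and extra partner genes so
  that a single best candidate exists by construction). Site length is
  21 nt.
* **Expression.** Log2-scale tissue profiles (10 tissues × 3 replicates):
  a per-transcript baseline ~ N(6, 1) plus tissue effects ~ N(0, 2),
  exponentiated to RPKM — giving the heavy-tailed, tissue-specific
  abundance structure that correlation clustering presupposes. Planted
  TE–gene pairs share one tissue profile plus tissue-level noise whose
  variance is chosen in closed form so the expected Pearson r of
  tissue-mean log2 expression equals `target_correlation` (default 0.9);
  the replicate-noise contribution (SD 0.25) is subtracted out of the
  budget. A quarter of TEs are simulated "silent" (baseline 2^-6) to
  exercise the expressed filter.
* **Degradome.** Background counts are Poisson with mean 0.15 per
  position. The expected cleavage position of every cleavable site draws
  from a shifted Poisson, \(2 + \mathrm{Pois}(m-2)\) with
  \(m = \mathrm{enrichment}\times\mathrm{background}\) (default
  enrichment 20): a *detected* cleavage product always leaves at least
  two reads, while the mean stays exactly at the configured enrichment.
  Mimic sites receive background only. The background level was fixed
  once by a pre-build Monte-Carlo of the caller's operating
  characteristics at 20× enrichment and is configurable.
* **LTRs.** Each simulated element mutates a random 1000-nt ancestor
  independently on both copies (paired) or one copy (solo) with per-site
  substitution probability rate × age, uniform over the three alternative
  bases, no indels — the one-shot counterpart of the p-distance dating
  model. Default true ages are the two ages of the worked examples
  (3.7 and 1.2 My).

What it deliberately does **not** emulate: raw reads (inputs are
count/RPKM tables, not FASTQ), splicing and genome coordinates,
GC/composition bias, miRNA-abundance dynamics downstream of mimicry, and
epigenetic state. Passing tests therefore demonstrate correctness of the
discovery computations under the stated statistical model, not robustness
to every property of real libraries.

## Numerical and design choices

* Alphabet: ACGT internally; U is mapped to T on input, so RNA- and
  DNA-spelled inputs are interchangeable everywhere.
* Determinism: a fixed seed makes every simulated file byte-identical;
  pipeline outputs carry no timestamps, and the MANIFEST hashes only the
  analytic parameters, not the output location.
* Tie-breaks: scan hits by (expectation, start, length); bulge placement
  by 5'-most position; consensus ties A < C < G < T; degradome peak ties
  leftmost.
* Degenerate inputs: constant expression vectors raise an explicit
  undefined-correlation error and the pair is skipped with a warning;
  all-identical rank-sum input raises a degenerate-test error; empty
  degradome profiles are an error rather than a category.
* The candidate ranking — number of correlated partners, then lowest
  best expectation, then id — is a convention chosen for determinism;
  no published ranking function exists for this composite evidence.
* Problem sizes in the test suite (oracle scans of 150-nt transcripts,
  100 random sets; 500 LTR pairs; 20 pipeline seeds; 1000 degradome
  cases) are chosen so the full suite verifies each guarantee at tight
  Monte-Carlo error while remaining comfortable to run on a laptop.

## Known limitations

* The duplex model scores complementarity only; it ignores target-site
  accessibility, RNA secondary structure, and translational repression.
* Multi-bulge duplexes (beyond one bulge of 3 nt) are not searched.
* Genome-scale homology fractions and pair counts reported from real
  transcriptome compendia depend on upstream read mapping and aligner
  settings outside this package's scope; the homology module is exact on
  its own terms but makes no claim to reproduce those numbers.
* p-distance dating saturates at large divergence; use the JC flag
  there, and treat ages beyond p ≈ 0.15 with caution.
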