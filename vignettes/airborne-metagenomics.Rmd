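---
title: "Profiling low-biomass airborne metagenomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling low-biomass airborne metagenomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerobiome)
```

## The problem

Air holds on the order of 10^4^ bacterial cells per cubic metre — five
orders of magnitude less than surface seawater. A whole-genome-shotgun
(WGS) survey of airborne microbes therefore has to amplify nanogram-scale
DNA before library construction, and amplification leaves fingerprints in
the reads: pyrosequencing produces *artificial replicates* (near-identical
reads sharing a start position), and phi29-based multiple displacement
amplification (MDA) creates *chimeric molecules* by branch migration,
joining genome segments that were never adjacent. On top of that, a large
share of reads from a diverse, under-sequenced community has no database
match at all, so the taxonomic tables say as much about reference-database
coverage as about the air.

`aerobiome` implements the complete computational side of such a survey:

1. **read QC** — replicate collapsing, low-complexity filtering,
   repeat-coverage filtering;
2. **chimera detection** — a four-rule similarity-based screen for the two
   MDA rearrangement classes;
3. **taxonomy** — a two-tier nucleotide/peptide homology scheme with a
   seven-category tabulation;
4. **GC mixture modelling** — estimating how much of the *unclassified*
   fraction is likely eukaryotic;
5. **functional profiling** — gene-length/read-length-normalized KO and
   COG abundances, category rollups, correlations and PCA ordination;
6. a **synthetic-community simulator** providing truth labels for all of
   the above.

## Read QC

Three per-read filters run in order: replicates, low complexity, repeats.

**Artificial replicates.** The replicate relation used here is the
standard 454 definition: identical first three bases (the flowgram key
anchor), length difference at most 10% of the longer read, and ungapped
identity of the shorter read against the longer read's prefix of at least
90%. Groups are transitive closures; the longest read survives, with ties
broken by smallest identifier so the outcome is order-independent. The
thresholds are configurable in `pipeline_config()`.

**Low complexity.** A DUST-style triplet score is computed over sliding
64-base windows: with triplet counts $c_t$ in a window of $k$ triplets,
$S = \sum_t c_t (c_t - 1) / 2 \,/\, (k - 1)$, and a window is masked when
$S$ exceeds `level/10` with the conventional level 20. The tool this
emulates is named in the field by its algorithm; since only the tool, not
its parameters, is ever reported in survey methods, the widespread
defaults (window 64, level 20) are adopted here. On uniform-random
sequence the expected score is about 0.5, far below the threshold, so
false masking is negligible; dinucleotide tandems score an order of
magnitude above it and are masked completely.

**Repeat coverage.** Precomputed repeat masks can be supplied as BED
intervals from any external masker; absent those, a built-in screen
(exact 15-mer seeds, ungapped extension, matches ≥ 50 bases at ≥ 80%
identity) against a user-supplied repeat library produces the intervals.
The built-in screen is a stand-in: it finds verbatim and lightly diverged
library copies but makes no claim of parity with a full repeat masker.

**The 50% rule.** For both mask types a read is dropped only when the
*union* of its mask intervals covers strictly more than half the read:
a read masked over exactly half its length is kept. Union rather than
summed interval length is used so overlapping masks cannot double-count.

## Chimera detection

MDA chimeras come in two geometries: *inverted* junctions (a segment
joined to the reverse complement of a nearby, overlapping segment — the
overlap survives as an inverted duplication inside the read) and
*transposed direct* junctions (two same-strand segments emitted in
swapped order). Four rules run in order; the first that triggers
determines the verdict:

1. **Internal repeats** — any exact repeat of ≥ 25 bases inside a read,
   forward or reverse direction, flags it. "Reverse direction" is
   interpreted as reverse complement, because branch migration produces
   inverted duplications; a plain-reversal variant is available behind
   `reverse_repeat_mode = "plain"`. The search uses 25-mer hashing
   (a duplicated block of length ≥ 25 exists iff some 25-mer occurs
   twice), with a brute-force all-substring comparator kept in the test
   suite as the oracle. This rule is deliberately conservative and will
   sacrifice reads with genuine repeats.
2. **Propagation** — any read linked to a rule-1 read by a similarity hit
   with identity strictly above 90% over strictly more than 95% of the
   read's own length is also flagged. One pass only: the wording of the
   rule describes a single extension step, so propagated flags do not
   seed further propagation. Coverage is measured against the candidate
   read's length (the plausible reading; the alternative — the seed's
   length — is nearly equivalent given the 10%-length-difference regime
   where this rule fires).
3. **Pair patterns** — from an all-vs-all search, hits between a read
   pair (aligned length ≥ 25, e-value ≤ 1e-5) are reduced to the two
   highest-scoring hits with non-overlapping query intervals.
   Opposite strands with subject intervals overlapping or within 100
   bases: *inverted* pattern. Same (plus) strand with query order
   opposite to subject order: *transposed direct*. Consistent order and
   strand: *collinear*; anything else *ambiguous*. The 100-base
   tolerance and the hit filters are not dictated by the method
   description; they are configurable and recorded in the manifest.
4. **Voting** — a read whose classified neighbours show chimeric
   patterns in strict majority (ties lose) is flagged. This encodes the
   assumption that chimeras are rare; the stage warns when more than 30%
   of reads end up flagged, the regime where the assumption breaks.
   Already-flagged reads still count in their neighbours' denominators.

The all-vs-all table can come from any aligner emitting the
twelve-column tabular dialect; `all_vs_all_hits()` provides a built-in
exact-seed/ungapped-extension matcher so no external binary is needed.
Its bit score ($2\,\mathrm{matches} - 3\,\mathrm{mismatches}$) and
e-value ($mn\,2^{-S}$) are deliberately simple — they exist to drive the
e-value and length filters above, not to reproduce any particular
aligner's statistics.

## Taxonomy

Reads are first screened at the nucleotide level: the ten best hits by
bit score with e-value < 1e-5 are retained, and a read whose retained
hits are *all* eukaryotic is classified `Eukaryota` outright. This tier
exists because large eukaryotic genomes are mostly non-coding: human or
plant reads rarely contain peptides but match genomic DNA well. Ranking
by bit score (rather than e-value) is a choice; the two orders differ
only on rounded e-value ties.

All other reads go through peptides. The stand-in ORF caller reports the
longest stop-to-stop stretch of at least 60 residues in each of the six
frames — a simplification of the frameshift-aware gene callers used on
real pyrosequencing data, and adequate for synthetic reads without indel
errors. Each peptide takes the kingdom of its best protein hit (e-value
< 1e-5; ties broken by lexicographic subject id, making the result
independent of input order). Best-hit rather than lowest-common-ancestor
is the simplest defensible reading and is recorded as such. Peptide
kingdoms transfer to the read: unanimous classified peptides give their
kingdom (unclassified peptides do not veto), conflicting kingdoms give
`Mixed`, no classified peptide gives `Unclassified`. Subjects mapped to
the `other` token (unidentifiable/synthetic database entries) behave as
a kingdom throughout, producing the `Other` category and participating
in `Mixed` conflicts.

Genus profiles are computed over genus-labelled bacterial reads only —
reads without genus resolution leave the denominator, which is recorded
in the output metadata. The *tail share* is the summed abundance of
genera individually below 2%: a single number capturing how much of the
community lives in the long tail.

## GC mixture modelling

Let $U$, $E$ and $PV$ be the binned %(G+C) distributions of the
unclassified, eukaryotic and prokaryotic/viral read groups. Assuming
unclassified reads actually belong to one of the two classified groups,
$U$ should resemble the mixture $X = pE + (1-p)PV$, and

$$\hat p = \arg\min_p \; D_{\mathrm{sym}}(X(p),\, U), \qquad
D_{\mathrm{sym}}(P, Q) = \sum_i (p_i - q_i)\ln\frac{p_i}{q_i}.$$

Choices the definition leaves open, fixed here:

* **bins** — 101 one-percent bins (the last closed at 100%); read-scale
  GC resolution does not support finer binning;
* **log base** — natural; $\hat p$ is base-independent, which is the
  reported quantity;
* **empty bins** — a pseudocount of $10^{-9}$ per bin with
  renormalization keeps the objective finite on the whole grid;
* **grid** — $p \in \{0, 0.001, \dots, 1\}$, ties to the smallest $p$,
  so a two-decimal report is stable against grid placement;
* **GC of a read** — $(G+C)/(A+C+G+T)$ with `N` excluded from both
  numerator and denominator; all-N reads are dropped and counted. How
  ambiguous bases were handled in the original surveys is never stated;
  the exclusion rule is flagged in output metadata.

The full objective curve is returned for plotting and audit. A warning
fires when $D_{\mathrm{sym}}(E, PV) < 0.05$: with nearly identical
components, $p$ is unidentifiable and the argmin is noise. With the
simulator's default components (beta-shaped, means 0.40 and 0.60) and
$n = 50\,000$ reads per group, $\hat p$ recovers the truth within
$\pm 0.02$ — the package's tests verify this across the p grid at 20
seeds each. On real data the corresponding estimates are only as good as
the separation between the observed $E$ and $PV$ distributions, which
the identifiability warning monitors.

## Functional profiling

A KO observed once on a peptide does not mean one gene copy: longer
genes and longer reads both raise the chance of catching a gene on a
read. The normalized mode therefore weights each annotated peptide by
$1/(L_{\mathrm{gene}}^{\mathrm{nt}} + \bar L_{\mathrm{read}} - 1)$ — the
number of read start positions that overlap the gene — and divides by
the sample's total weight, giving relative abundances that sum to one
per sample. The raw-count mode is kept alongside, as surveys
conventionally report both. The package's tests construct two samples
with identical composition and mean read lengths 250 vs 450: normalized
profiles agree within 2% per KO while raw shares do not, which is
precisely the bias the weighting removes.

Category rollups sum member-KO abundances; a KO in several categories
counts once per membership, and rows are renormalized (so rollups are
*not* a partition of the KO mass — the alternative, splitting a KO's
mass across its categories, answers a different question). COG profiles
reuse the identical code path with a COG-to-class map.

Ordination is column-centred, variance-unscaled PCA on the relative
abundances (scaling would let rare KOs dominate). Loadings follow a
deterministic sign convention — the largest-magnitude loading of each
component is made positive — so top-loading lists do not flip between
runs; variance-explained fractions are checked in the tests against a
hand-written eigendecomposition of the covariance matrix to 1e-8.

Resistance/virulence candidate matches are filtered at ≥ 90% identity
over ≥ 90% of the peptide length, both inclusive — unlike the strict
inequalities of the chimera rules, which the tests pin down at the exact
boundaries (90.0/90.0 retained; 0.50 masked kept; 24-base repeat clean;
90.0% propagation identity excluded).

## The synthetic community

The simulator is the package's instrument for making every stage
testable without reference databases:

* **genomes** — iid bases at a per-genome GC target (realized GC within
  ±0.02 of target for the 1 kb minimum length; tighter for realistic
  lengths);
* **reads** — 454-style single-end reads: genome chosen by abundance,
  uniform start, truncated-normal length (mean 350, sd 80, min 50 —
  FLX/Titanium scale), uniform strand; substitution errors off by
  default since none of the filters is error-driven, with a uniform
  rate available for robustness checks;
* **artifacts** — replicates share the original's start with up to 10%
  trailing truncation; inverted chimeras carry a duplicated block drawn
  ≥ 25 bases (detectable by construction) or 10–24 bases for a
  configurable fraction of hard cases; transposed-direct chimeras join
  two same-strand segments, gap ≤ 2 kb, in swapped order — junctions are
  intra-genome and local, following the branch-migration mechanism. No
  quantitative chimera rate is established for MDA libraries, so the
  rate is a free parameter rather than a baked-in constant;
* **hit fabrication** — truth-consistent nucleotide hits and peptide
  annotations, with a configurable no-hit fraction (driving
  `Unclassified`) and conflicting-kingdom noise (driving `Mixed`).

What the simulator does *not* emulate — homopolymer/flowgram errors,
real marker genes, amplification GC bias, database incompleteness
structure — bounds what green tests mean: they certify the algorithms
against their definitions and statistical contracts, not recovery of
any real community's composition.

Problem sizes used by the test-suite and acceptance runs — 5 000 reads
for detector error rates, 150–200 reads for brute-force oracle
equivalence, 50 000 draws per histogram for mixture recovery — were
chosen as the smallest sizes at which the binomial/recovery bounds being
asserted are comfortably away from their noise floors.

## Reporting conventions

`assigned = Total − Unclassified`: the `Mixed` and `Other` categories
count as assigned, since both reflect database matches. The mean
assignment percentage is the unweighted mean of per-sample percentages,
not a pooled ratio. Percentages are rendered by half-up rounding at the
printed precision, with raw values always stored alongside; the
published six-sample table this package ships reproduces its printed
summary figures under exactly these conventions (one bacterial-share
figure in the original is inconsistent with any single rounding rule and
is not asserted). Every stage appends to a read-count ledger
(`reads_in = reads_out + reads_dropped`) that telescopes from raw input
to the final table totals, and the manifest records seed, thresholds
and versions; no timestamps are written, so identical configurations
produce byte-identical output trees.

## Known limitations

* The ORF caller is frame-naive; on reads with real indel errors it
  under-predicts peptides relative to frameshift-aware callers.
* Best-hit taxonomy inherits database bias; it cannot distinguish "the
  best hit" from "the only sequenced relative".
* The built-in matcher is ungapped: diverged or indel-containing
  similarity goes unseen, which matters for propagation recall on real
  data (external aligner output can be substituted anywhere).
* The GC mixture model assumes exactly two components and that
  unclassified reads are draws from the classified groups' GC laws —
  a useful approximation that ignores novel clades with atypical GC.
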