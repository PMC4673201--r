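---
title: "Alignment-free ITD detection and MRD quantification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free ITD detection and MRD quantification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itdseq)
```

# The problem

Internal tandem duplications (ITDs) of the FLT3 juxtamembrane region are
the most common mutation in normal-karyotype AML, and an attractive target
for molecular minimal-residual-disease (MRD) monitoring: each patient's
clone carries a private junction — the point where the second copy of the
duplicated unit begins — that exists on the mutant allele only. Because
amplicon deep sequencing yields hundreds of thousands to millions of read
pairs over a single PCR product, an ITD clone identified at diagnosis can
be re-counted in follow-up samples at sensitivities far beyond fragment
analysis, and the sensitivity scales directly with read depth.

`itdseq` implements this idea without any alignment step. Reads never
touch an aligner: duplications are found *inside* individual merged reads
by a tandem-repeat scan, anchored to the amplicon by exact substring
matching, and quantified by exact counting of two short signatures. This
is what makes the approach fast and applicable straight to the FASTQ files
a sequencer emits.

# The pipeline

## Read merging

Each 2×150 bp pair is merged into one amplicon-spanning read.
Mate 2 is reverse-complemented and the overlap is chosen **among overlaps
of at least `min_overlap` (10) bases whose mismatch fraction is at most
`max_mismatch_frac` (0.1)** as the one maximizing matches − mismatches,
ties to the longer overlap. Disagreeing overlap positions keep the base
with the higher Phred quality (ties to mate 1).

The budget filter is applied *before* the score maximization, not after,
and this matters specifically for ITD reads: a tandem duplication makes
the two mates self-similar at a lag equal to the duplication length, so a
long, heavily-mismatched pseudo-overlap can out-score a short true
overlap. Filtering first keeps the near-exact true overlap ahead; with a
global argmax followed by a filter, precisely the mutant pairs with short
true overlaps would be discarded or, worse, merged at the duplication lag
(which collapses the duplication and fabricates a wild-type-looking
read). Pairs with no acceptable overlap are a counted, normal outcome —
they are excluded from all downstream counting and reported in QC.

No statistical significance test of the overlap is performed. In an
amplicon context every pair comes from the same few-hundred-bp product,
spurious overlaps are rare and short, and the simple score keeps the
contract brute-force checkable; indel-aware overlap alignment is out of
scope (the error model is substitution-dominated).

## Tandem-repeat finding

For a merged read and each candidate period $p \in [15, 150]$, positions
$j$ and $j+p$ are compared; every maximal run of comparisons with at most
`resolution` (default 1) mismatches is found, overlapping runs of the same
period are merged, and a run is reported when its total span (run length
$+\,p$) is at least $2p$ — i.e. **the read contains the duplication in
full** (`copies >= 2`). This containment requirement is not incidental:
it encodes the method's one structural blind spot, discussed below.

Two details depart from a naive scan:

* **Primitivity.** A homopolymer or microsatellite run satisfies *every*
  period, so a run is suppressed at period $p$ when its longest
  exact-match core is exactly periodic at a proper divisor of $p$. The
  core (not the resolution-extended window) is tested, otherwise a
  microsatellite flanked by random sequence escapes the filter at
  resolution 1.
* **Default `min_period = 15`.** The smallest ITD observed across
  patients in practice is 15 bp; periods below that are microsatellite
  territory and biologically implausible as FLT3 ITDs.

The finder is deliberately implemented as a windowed $O(nP)$ scan over
allowed periods rather than an optimal maximal-repetitions algorithm —
at amplicon read lengths (≤ ~300 bp) this is microseconds per read, and
the simple definition admits an exhaustive brute-force oracle against
which the implementation is tested exactly (property-based, both
resolutions, thousands of strings).

## Clone anchoring and the insertion-site convention

A read's repeat only nominates it. To become a clone, the read must
anchor to the reference by exact match of its first and last 20 bases,
and the two anchor offsets must *independently* imply the same
duplication length as the repeat period. The insertion site is then the
anchor offset plus the start of the repeat's longest exact core plus the
period, and the observed duplicated unit must match the reference unit at
that site within one substitution. Reads failing any of these checks are
tallied as unanchored, never guessed.

The (site, unit) description of a tandem duplication is ambiguous: if
`ref[site-1] == ref[site-1-L]`, sites `site` and `site-1` describe the
same mutant sequence. All sites in the package are therefore
**left-aligned** (canonical), both in the caller and in the simulator's
truth records — without this convention, "exact site recovery" would be
ill-posed. Reads whose exact core is shorter than the period (a
sequencing error landed inside the duplication) are dropped at discovery;
they are a small, unbiased loss, and keeping them is what would create
phantom sibling clones at shifted sites.

Junction signatures are constructed from the reference at the canonical
(length, site) key: `k_flank` (12) bases ending at the breakpoint plus 12
bases starting at it. 24 matching bases make a chance occurrence
($4^{-24}$) negligible, while still fitting comfortably inside a mate.
Since error-bearing repeat cores are dropped, the reference-derived
signature coincides with the majority observed junction, and it keeps
exact-substring counting well defined. A clone whose junction signature
occurs in the wild-type reference is invalid and rejected.

Discovery pools reads by (length, site) and requires `min_support` (5)
reads; follow-up counting has **no** support floor — positivity is
governed by the Fisher test. This separates clone discovery (a
diagnosis-sample task at high allele fraction) from MRD counting (a
follow-up task at arbitrarily low fraction), mirroring how diagnosis and
follow-up samples are sequenced in separate runs to avoid
cross-contamination.

## Counting and the ratio

For each sample × clone, reads containing the junction signature are
`itd_reads` and reads containing the 24-base wild-type context centered
on the site are `wt_reads` (a read counts once per signature; a read
containing both counts as ITD). The MRD quantity is the breakpoint read
ratio `itd_reads / wt_reads`, which may exceed 1; no correction is
applied for the over-representation of duplicated alleles.

One subtlety is documented rather than hidden: a tandem insertion
recreates the wild-type junction context *downstream*, at the end of the
second copy, so mutant-allele reads covering that context (but not the
junction) count as wild type. At high allele fractions the measured
breakpoint ratio therefore sits somewhat below the allele-implied ratio
$f/(1-f)$; at MRD-relevant fractions the effect is negligible. The
simulator's truth tables implement exactly the same semantics, and
error-free counting is verified to match them read-for-read.

Deep follow-up samples are counted by a fast path directly on unmerged
mates: a 24-base signature is fully contained in a single mate whenever
it is sequenced at all, so merging is unnecessary for counting (it
remains necessary for discovery, where the full duplication must sit in
one read).

## Fisher positivity, sensitivity, log reduction

Positivity is a one-sided Fisher exact test of

$$\begin{pmatrix} \text{itd} & \text{total}-\text{itd} \\
\text{ctl itd} & \text{ctl total}-\text{ctl itd} \end{pmatrix}$$

against the pooled counts of the same junction in the sample's **in-run
controls** — the other samples of the same run excluding the same
patient. When a run contains designated control/negative samples the pool
is restricted to those (in a dilution experiment, the other ladder
members contain the clone and must not poison the pool). This is a
contamination control: a junction that also shows up across other
patients' libraries at a similar rate is index bleed-through, not
residual disease. Defaults: one-sided, `alpha = 0.05`, no multiple-testing
correction across clones (pass a corrected alpha for a Bonferroni-style
switch); the test's sidedness and level are exposed because no published
convention fixes them.

With no controls at all, positivity falls back to a flagged
`itd_reads >= min_support` rule — multiplexed runs are the intended
design, and a single-sample run needs a defined behavior.

Per-sample **sensitivity** is the smallest junction-read count that would
be called positive at the sample's depth against its controls (binary
search; exact by monotonicity of the tail), expressed as a ratio over the
wild-type breakpoint reads — observable even in a negative sample. This is
the depth↔sensitivity dial: doubling `n_pairs` in the simulator (or
sequencing deeper) lowers the minimal detectable ratio, and the report
prints it so the trade is visible.

Longitudinal reporting expresses each follow-up as the decimal log
reduction $\log_{10}(\text{baseline ratio}/\text{ratio})$ against the
patient's diagnosis baseline. A follow-up with zero junction reads is
reported as below the sample's sensitivity, with no log value. Clones
positive at follow-up but without junction reads at diagnosis are flagged
*emergent*, clones positive at diagnosis but negative at the latest
timepoint *lost* — the two signatures of a mutational shift between
diagnosis and relapse.

# The simulator

`sim_config()`/`simulate_sample()` emulate the focused-PCR + tagmentation
library: per pair, an allele (wild type or one of the configured clones)
is drawn by allele fraction; a fragment length is drawn from a normal
(mean 250 bp, sd 60 bp — transposase tagmentation cuts every few hundred
bp) truncated by resampling to `[read_length + 30, allele length]`; the
fragment start is uniform; both 150-bp mates read the fragment ends; and
iid per-base substitution errors are applied at $10^{-3}$ (the dominant
short-read error mode; indels and learned quality profiles are not
modeled — qualities are constant Q40). Output is deterministic given the
seed, to the byte. Every emitted pair carries a truth record (allele,
fragment coordinates), and `dilution_series()` scales clone fractions to
build the serial-dilution ladder one sample at a time.

Because the fragment cap is the allele length, fragments longer than
`2*read_length - min_overlap` legitimately fail to merge. That is not a
defect; it is the mechanism of the method's known blind spot: a 183-bp
ITD cannot be contained in any merged read built from ~250-bp tagmented
fragments of 150-bp mates, so such a clone yields **zero** calls — the
same failure observed in practice when a long ITD is fragmented inside
during library preparation. The simulator reproduces this cliff exactly,
and a test pins it.

What the simulator does *not* emulate — PCR duplicates and chimeras,
position-dependent quality, indel errors, allele-specific amplification
bias — bounds what passing tests show about real data: they validate the
algorithmic contract (discovery, counting, statistics) and the
depth-sensitivity behavior, not wet-lab artifact robustness.

## Study-condition defaults

The validation experiments run at the conditions of the original study
design wherever stated, scaled to a desk-size compute budget where only
depth matters: the dilution ladder uses a 48-bp clone at allele fraction
0.543 (allele-implied ITD/WT ratio 1.19), dilutions $10^{0} \dots
10^{-4}$ at $10^6$ pairs per rung (the study sequenced up to
$2.4\times10^6$ pair fragments); length/site recovery covers 15–90 bp,
the observed size range, at 20 replicates × 7 lengths and 3,000 pairs
each; type-I control uses 500 negative samples of 2,000 pairs in runs of
10. Clone discovery scans at most 100,000 merged reads per sample
(`max_discovery_reads`) — discovery needs support, not depth.

# Numerical and degenerate-input choices

* Coordinates are 0-based, half-open, on the amplicon forward strand,
  everywhere.
* Primer strings are stored as printed (fluorophore label, hyphens) and
  normalized before matching; `N` is permitted in reads, never in the
  reference.
* A sequence shorter than `2*min_period` yields an empty repeat list, not
  an error; an unmergeable pair and a zero-depth sample are values, not
  errors. `wt_reads = 0` with `itd_reads > 0` gives an infinite ratio
  with a warning; 0/0 is undefined (`NA`).
* Repeat reports are sorted by (start, period); per-read clone nomination
  takes the largest span, ties to the smaller start, then the smaller
  period — fully deterministic.
* For merged overlapping repeat windows the reported `mismatches` counts
  over the union and may exceed `resolution` (each constituent maximal
  window respects the budget); at resolution 0 no merging can occur.
* The package ships a **synthetic** 360-bp amplicon (the real assay
  primers flanking a screened random insert with unique 12-mers, no
  homopolymer ≥ 5, and no period-15+ tandem repeat at ≤ 1 mismatch) as
  its default reference; the biological PCR-product sequence is a
  laboratory input and is supplied by the user as FASTA.

# Known limitations

* ITDs longer than the merged-read span are undetectable **by design**
  (full-containment requirement); this is the documented 183-bp failure
  mode, not a bug to engineer around within this assay geometry.
* The breakpoint ratio is a read-count ratio; duplicated-allele read
  bias and the downstream wild-type context effect mean it is not an
  allele-fraction estimate, especially above ~0.5.
* Clone identity across runs is (length, canonical site); two distinct
  clones identical in both are indistinguishable.
* Merging can, for near-gap fragments, align the two copies of a
  duplication and collapse it (a rare chimeric wild-type-looking read);
  the mismatch-budget-first overlap rule minimizes but cannot eliminate
  this.
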