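---
title: "Calling m5C from RNA bisulfite sequencing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling m5C from RNA bisulfite sequencing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnabs)
```

## The measurement problem

Bisulfite treatment deaminates unmethylated cytosine to uracil, read as
thymine after sequencing, while 5-methylcytosine (m5C) is protected. A
candidate methylation site ("p-m5C") is therefore any reference cytosine at
which aligned reads still report C. The signal is tiny — a handful of
protected cytosines against a background where *every* C position can yield
a false candidate through incomplete conversion, PCR or sequencing error,
or RNA secondary structure that shields whole molecules from the chemistry.
`rnabs` implements the post-alignment half of this experiment: it takes
coordinate-sorted, UMI-tagged alignments of bisulfite-converted RNA reads
plus a reference containing known-unmethylated spike-in controls
(ERCC-like), and produces a high-confidence m5C site set together with the
calibration and artifact statistics needed to trust it.

## Site model

At a reference C with candidate count $i$ (reads reporting C at base
quality $\ge$ Q30) and coverage $j = (C{+}T)$, the methylation level is
$i/j$. Bases other than C/T (mismatches) are excluded from $j$ and tracked
separately. Under the null of no methylation, $i \sim \mathrm{Bin}(j, e)$
where $e$ is the per-base conversion-failure rate; the one-sided tail
$P(X \ge i)$ is the site p-value, and $e$ is calibrated from the spike-in
controls as $1 -$ (observed conversion rate $T/(C{+}T)$ on control
reference Cs). Overlapping mates contribute one observation per fragment
position: the higher-quality base wins, ties to read 1.

## The filter cascade

Candidate sites at $\ge$10x coverage pass through, in order:

1. **Standard filter** — $i \ge 3$, $j \ge 20$, level $\ge 0.1$, all
   boundaries inclusive.
2. **Read C-cutoff with signal/noise** — reads carrying more than $k$
   unconverted cytosines are treated as incomplete-conversion artifacts
   and removed; a site's signal/noise ratio is its candidate count after
   the cutoff over the count before, and sites below 0.9 are dropped as
   artifact-supported. The cutoff $k$ is selected per library from a Gini
   scan (below).
3. **Structure-region exclusion** — sites inside half-open intervals
   supplied as BED-style input (e.g. RNAfold-predicted conversion-resistant
   regions; prediction itself is out of scope) are removed.
4. **Binomial test with BH-FDR** — step-up adjusted p-values, pass at
   $q \le 0.05$, computed per library over the sites reaching this stage.
5. **Replicate concordance** — a site is high-confidence if it passes all
   filters in one replicate and shows $i \ge 1$, $j \ge 10$ after the
   *other* replicate's own C-cutoff.

Each stage is a pure set reduction, so the attrition report (percent of
the 10x starting set surviving each stage) is monotone by construction.

### Gini-guided C-cutoff selection

Incomplete conversion is not uniform: molecules protected by secondary
structure concentrate candidate sites on a few genes. The scan drops reads
with more than $k$ unconverted Cs for each $k$ in 1..30, re-calls sites,
and computes the Gini coefficient of candidate-sites-per-gene (population
pairwise form, $G = \sum_{a,b}|x_a-x_b| / (2n^2\bar x)$, unweighted
counts; genes absent from the annotation are excluded from the vector but
their sites still flow through the cascade). The chosen cutoff is the
**largest** $k$ whose Gini is at or below 0.15: stricter cutoffs remove
the C-laden reads that concentrate artifacts, so the Gini falls as $k$
decreases, and the crossing point is the least stringent cutoff with an
acceptably even site distribution — discarding as few reads as possible.
If no cutoff qualifies, the maximum of the range is used with a warning;
whole-molecule resistant reads typically carry far more unconverted Cs
than any scanned cutoff, so they are removed even then. Cutoffs are chosen
per library and never shared across replicates.

Two readings of the selection rule are possible ("the first cutoff whose
Gini clears the threshold" scanning up, or scanning down); we use the
largest qualifying $k$ because the alternative degenerates to $k = 1$ on
any library whose strictest cutoff has a small Gini — a cutoff of 1
discards every read that carries a genuine m5C plus a single unrelated
conversion failure, needlessly sacrificing true support, and is
incompatible with the per-library cutoffs in the 3–15 range that this
procedure is known to produce on real libraries.

### Signal/noise boundary

Retention is at ratio $\ge 0.9$ (the boundary itself is kept). The ratio
is defined as 0 when the pre-cutoff count is 0.

## Read-level QC

Fixed order: polyX trim (3' homopolymer runs of $\ge$10 nt, any base, in
read orientation), length check ($\ge$50 nt), mean quality ($\ge$Q25),
low-quality fraction ($\le$40% of bases below Q25), then a fixed 6 nt
trim from both read ends against m-bias from random-primer residues, a
length re-check, and finally the mate-overlap requirement (paired mode:
mates must share at least one reference base on their *final trimmed*
coordinates; if either mate fails any rule the fragment is discarded).
Overlap is judged after trimming because the pipeline guarantees
idempotence — a second pass must see the same coordinates and reach the
same verdicts; evaluating overlap on pre-trim coordinates would let a
rerun discard fragments whose mates overlap by fewer bases than the
trim width. For the same reason end-trimmed reads carry an
`end_trimmed` marker and are never re-trimmed. Trimming is
post-alignment with coordinate adjustment (the alternative — trimming
before alignment — is indistinguishable downstream for ungapped
alignments, and post-alignment keeps the operation testable in
isolation). All operations only remove bases or reads; a retained base
and its quality are never altered.

## UMI deduplication and discordance

Reads sharing (reference, read-1 start, conversion orientation, exact
UMI) form a group of presumed PCR amplicons of one molecule; mates are
one template. There is no edit-distance clustering — the grouping oracle
stays trivial, and near-miss UMIs remain separate molecules. Within each
group the most prevalent sequence is retained; ties break by higher
summed base quality, then lexicographically smaller sequence, so
deduplication is deterministic and idempotent. Discordance statistics
compare member reads base-by-base over the span covered by every member:
the discordance ratio is the fraction of *all* groups (depth-1 groups
count as concordant) with at least one position where members disagree; a
group is attributed to nucleotide class N if N appears among the observed
bases at a discordant position (a C/T mismatch increments both classes);
and for discordant positions where some member reports the candidate base
C, the full nucleotide frequency vector is accumulated. A `refs` argument
restricts the analysis to, say, spike-in controls, where every
discordance is attributable to PCR or sequencing error.

## The simulator

The generator exists so that every stage above can be validated against a
known truth. It emulates, per molecule: fragment sampling from random
transcripts; per-cytosine conversion (methylated Cs retained with
probability equal to the site's true level, unmethylated Cs converted
with probability `conversion_rate`); whole-molecule conversion resistance
(binary, probability `resistant_read_fraction` — a deliberate
simplification of structure-protected molecules; per-region resistance is
not modeled); PCR as discrete Bernoulli doubling rounds whose per-molecule
efficiency is scaled by $\max(0, 1 - \beta \cdot f_{C})$ with $f_C$ the
molecule's unconverted-C fraction, so unmethylated (T-bearing) templates
amplify preferentially; per-copy PCR and per-base sequencing substitution
errors; truncated-normal Phred scores with cytosine calls (guanines on
reverse-stored mates) penalized by 3 points, reproducing the quality
asymmetry of bisulfite libraries; and an 8 nt UMI per template, inherited
by copies, with collisions allowed.

Default parameters are the study conditions the package validates
against: paired directional 150 nt reads, fragments 200–300 nt,
conversion rate 0.999, 2% resistant molecules, planted levels uniform on
[0.2, 1], 10 transcripts of 1.2–2 kb with two unmethylated spike-in
controls, PCR at 3 rounds x efficiency 0.07 (about 18% duplicate
fragments, the regime of a well-behaved low-cycle library; amplification
bias $\beta$ = 0.5 — no published magnitude exists for this parameter, so
it is a free setting chosen to make the bias mechanism visible).
`mean_coverage` defaults to 100 unique templates per base: at $j = 100$
the binomial standard error of a level estimate is at most 0.05, so
recovery within $\pm$0.1 is a meaningful expectation, which it is not at
marginal 10–20x coverage. Two replicate libraries are simulated from one
shared truth with offset seeds.

Two placement rules keep parameter recovery interpretable: planted sites
sit in the transcript interior (at least one maximal fragment length from
either end, where the uniform fragment process actually achieves nominal
coverage) and at least one maximal fragment length apart (each fragment
supports at most one site, so per-site estimates are independent). Both
constraints relax stepwise for deliberately tiny test references.

What the simulator does *not* emulate — and what passing its tests
therefore cannot show — includes: expression inequality across genes
(uniform coverage makes the Gini scan landscape much flatter than in real
libraries, where it is shaped by expression and artifact concentration),
spliced or gapped alignments (the caller accepts I/D/N/S CIGARs from real
aligners, but the simulator emits ungapped reads), indels and adapter
contamination, graded per-region conversion resistance, and sequence-
dependent error profiles. Results on real data additionally depend on the
aligner, which is out of scope.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; SAM/GTF I/O converts to
  1-based. Site tables carry both `pos` and `pos1`.
* `gini()` rejects empty or non-positive input; the population $n^2$
  form (not $n(n-1)$) is used and cross-checked against the brute-force
  pairwise sum.
* `binomial_pvalue()` requires $e \in (0,1)$ and $0 \le i \le j$; $i=0$
  gives exactly 1.
* Conversion-rate estimation with no control-mapped reads returns `NA`
  with a warning rather than failing the run; the cascade then assumes a
  0.999 conversion rate.
* Empty reads produced by trimming carry `cigar = "*"` and are removed by
  the following length check.
* A single-replicate run is allowed for exploration; its high-confidence
  set is empty by definition, with a warning.
* Reported problem sizes: module tests run on 4-transcript, 25x
  simulations (a few thousand reads); recovery validation uses the full
  default conditions (10 transcripts, 100x, two replicates) across five
  seeds.

## Known limitations

The binomial site test treats the conversion-failure rate as shared
across positions, while real failure is sequence- and structure-
dependent; the spike-in calibration absorbs resistant control molecules
into a single inflated error rate, which is conservative. Exact-match UMI
grouping slightly overestimates molecule counts under sequencing errors
in the UMI itself. The per-gene Gini uses unweighted site counts;
expression weighting is not implemented. Fisher tests for differential
methylation are two-sided with BH adjustment at $q \le 0.05$ —
directionality is not assessed.
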