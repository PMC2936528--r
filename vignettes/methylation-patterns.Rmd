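---
title: "Models and methods: de novo methylation pattern analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: de novo methylation pattern analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methpatterns)
```

## The scientific problem

De novo DNA methyltransferases (DNMT3A, DNMT3B) do not methylate CpG sites
uniformly: on episomal substrates, per-site methylation efficiencies vary
more than 10-fold in reproducible patterns, and the identity of the bases
immediately flanking the target CpG predicts whether a site is a methylation
hotspot or coldspot.  DNMT3A discriminates mainly through the bases at
offsets -2 and +2 from the CpG (T at -2 and, to a lesser degree, C at +2
mark hotspots; A at -2 marks coldspots), DNMT3B through -1/+1 (G at +1 hot,
C at +1 cold).  The stimulatory factor DNMT3L boosts poorly methylated
sites the most, compressing the spread of the pattern without reordering
it, and acts preferentially on newly replicated (dcm-) DNA strands.

This package implements the full analysis chain for that kind of study —
methylation calling from bisulfite clone sequences, per-site efficiency
statistics, flank extraction and positional enrichment, DNMT3L fold
stimulation, and Markov word-exceptionality scans — together with a
synthetic clone simulator that stands in for the original (undeposited)
clone libraries and provides ground truth for every stage.

## The generative model

A `reference_region` indexes each CpG by the 0-based top-strand position of
its C; CG is its own reverse complement, so one index serves both strands.
dcm (CCWGG) sites are indexed by their methylatable internal C on each
strand (start+1 on the top strand, start+3 in top coordinates for the
bottom strand — CCWGG is self-complementary as a pattern set, so both
strands' occurrences share windows).

The true per-site, per-strand methylation probability is a logistic model:

p(site, strand) = logistic( b0 + sum over offsets of beta(offset, base) )

where the bases are read 5'->3' on the strand being methylated (the
bottom-strand context is the reverse complement of the top-strand window).
The logistic form is the package's own parameterization; what is planted in
it is the enzymes' qualitative preference structure:

* `"3A-like"`: beta(-2,T) = +s, beta(-2,A) = -s, beta(+2,C) = +s/2,
  beta(+2,G) = -s/2.  The +2 effects are planted at half weight because the
  -2 position dominates DNMT3A discrimination in vivo (the reported
  enrichment significances differ by ~8 orders of magnitude between the two
  positions); planting them equally makes the -2/T and +2/C signals trade
  places by region-composition luck, which misrepresents the enzyme.
* `"3B-like"`: beta(+1,G) = +s, beta(+1,C) = -s, beta(-1,T) = +s.
* `"null"`: no flank effects; used for calibration.

DNMT3L stimulation is a saturation transform p' = 1 - (1-p)^k, i.e. k
independent opportunities to methylate.  It fixes 0 and 1, preserves order,
and makes the fold stimulation p'/p strictly decreasing in p — exactly the
observed inverse relation between baseline efficiency and stimulation, and
it provably shrinks max/min spread on any non-constant profile.

Per molecule, de novo events are drawn independently per strand, then
maintenance methylation converts hemimethylated sites to fully methylated
with probability mu, once (no iterative rounds).  This is the simplest
mechanism that produces the observed strand symmetry; at mu = 1 the two
strands become identical, at mu = 0 they are independent draws.  dcm status
is drawn per molecule; dcm+ molecules carry marks on both strands (fully
dcm-methylated plasmid origin), dcm- molecules carry none (newly
replicated DNA loses the bacterial mark).

Bisulfite chemistry: an unmethylated C reads as T with probability c
(conversion), a methylated C reads as T with probability
`inappropriate_conversion`.  Bottom-strand reads are emitted 5'->3' on the
bottom strand, as a sequencer would deliver them.

### Default parameters and where they come from

| parameter | default | rationale |
|---|---|---|
| baseline b0 | `qlogis(0.15)` | de novo draw probability ~15%, the study's strand-level scale |
| strength s | 1.5 (3A-like), 1.6 (3B-like) in the analyses | calibrated once so the simulated top/bottom-decile efficiency ratio matches the reported 5.3-fold (DNMT3A) and 8.3-fold (DNMT3B) contrasts |
| conversion c | 0.991 | the study-level bisulfite conversion efficiency |
| inappropriate conversion | 0 | not reported; assumed negligible |
| n_molecules | 100 (200/strand in the analyses) | reported clone counts of 36-120 per region/strand, recovery analyses at 200 |
| maintenance mu | 0.9 | patterns are "mostly symmetrical": high but imperfect maintenance |
| dcm_plus_fraction | 0.5 | roughly balanced old/new strand sampling |
| flank half-width k | 2 | the informative offsets are -2..+2; offsets beyond that showed nothing |
| n_min | 10 | ranking floor; low-coverage sites make ratios unstable |
| decile fraction | 0.10, size `ceiling(0.10 * N)` | "top/bottom 10%" with a deterministic rounding rule |
| conversion filter | >= 0.95, inclusive | "no less than 95%" reads as inclusive |

Note that with maintenance at mu = 0.9, the *realized* strand-level
efficiency is roughly 1-(1-p)(1-mu p), i.e. about twice the de novo rate —
a simulation at b0 = qlogis(0.15) shows ~30% strand-level methylation.  The
baseline is kept on the de novo scale because that is where the preference
model lives; analyses that need a specific realized level should solve for
b0 accordingly.

## Calling and filtering

Reads must match the reference length (gapless contract; real ClustalW-type
alignments must be pre-trimmed).  Orientation is decided by identity at
reference A/T positions, which bisulfite never touches; the strand by
whether C->T (top) or G->A (bottom) conversion evidence dominates, with a
tie giving NA.  Calls: retained C (top) / retained G (bottom, top
coordinates) = methylated, converted = unmethylated, anything else missing.

Conversion efficiency is converted / (converted + retained) over *eligible*
cytosines: all cytosines of that strand except CpG-context and the
dcm-methylatable internal C of CCWGG.  The dcm exclusion matters: a dcm+
strand legitimately retains those Cs, and counting them as unconverted
would push genuine dcm+ molecules below the 95% filter — the original
analysis cannot have penalized them, since it analyzed dcm+ molecules.
Only the internal C is excluded; the outer C of CCWGG converts normally.
A cytosine that is both CpG- and dcm-context is treated as CpG context.

dcm classification thresholds the retained fraction of strand-appropriate
dcm internal Cs at 0.5; a strand with no CCWGG is NA.

## Pattern statistics

Per-site efficiency is m/n over informative calls in a stratum (strand,
dcm class, filter).  Ranks are descending with average ties; rank agreement
between conditions is the squared Pearson correlation of rank vectors
(squared Spearman), reported with its signed r since r^2 hides direction.

Fold ranges divide the highest by the lowest per-site efficiency.
Zero-count sites enter ratios through the Haldane pseudocount
(m + 0.5)/(n + 1); reported efficiencies are never pseudocounted.

Extreme selection takes the top and bottom `ceiling(f * N)` rankable sites,
ties broken by efficiency then ascending position; if the two sets would
overlap (tiny N, large f) the cold set shrinks — selection is always
deterministic and disjoint.

### Flank extraction and orientation

Flanks are extracted per strand in that strand's own 5'->3' reading (the
"enzyme's-eye" frame) and pooled across strands and regions.  Because the
CG core is palindromic, a shared motif can legitimately sit in either
direct or reverse-complement orientation, so flanks are aligned before
testing: a position frequency matrix (+0.5 pseudocounts) is seeded
progressively — the most extreme site's flank anchors the frame and each
subsequent flank joins in whichever orientation scores the higher
log-likelihood — and then refined batch-wise to a fixed point, flipping
any flank whose reverse complement scores strictly higher.  Ties keep the
current reading, so palindromes stay direct.

The progressive seeding is load-bearing.  If a site is selected on both
strands it contributes a reverse-complement *pair* of flanks; a set closed
under reverse complement has an exactly rc-symmetric frequency matrix, and
a pure batch fixed-point iteration then scores every flank identically in
both orientations and never moves (we verified this deadlock empirically
and it is an exact symmetry, not a numerical accident).  Anchoring on the
most extreme site breaks the tie in the frame most likely to carry the
planted context, because a site's extremity is driven more by its own
strand's context than by the maintenance echo of the other strand whenever
mu < 1.

### Positional enrichment and calibration

Each (offset, base) cell gets a 1-df base-versus-rest chi-square against
the background composition, without continuity correction; direction is the
sign of O - E.  The background is the pooled base composition of the +/-k
flank positions of *all* full-context CpG sites of the region(s), both
strands, excluding the central CG — "the average composition of the
sequence being considered", conditioned on CpG context.  Raw p-values are
reported per cell with a Bonferroni column across the 4 x 2k cells as a
secondary guide.  Per offset, the sequence-logo information content is
2 - H(bits) of the observed base frequencies (2 = perfect conservation,
0 = uniform) with letter heights frequency x IC.

Two calibration facts, measured with this package and worth keeping in
mind when reading outputs:

* On extracted (un-oriented) flank sets under a null model, the enrichment
  cells reach p < 0.05 at a rate of ~0.057 over 200 replicates — the test
  is calibrated where the chi-square approximation holds.
* *Downstream of orientation*, the null rate rises to ~0.18: the alignment
  step maximizes concordance and therefore inflates apparent enrichment,
  exactly as any motif-alignment procedure does.  Oriented-set p-values
  should be read as enrichment descriptions of the aligned motif, not as
  calibrated tests; inference about planted structure rests on parameter
  recovery under simulation, which the test suite exercises end-to-end.
* The 1-df chi-square tail agrees with the exact two-sided binomial within
  a factor of ~3 only while both p-values are moderate (> ~0.01 on the
  exhaustive N <= 30 grid with both expected cells >= 5); in deep tails
  the approximation diverges by orders of magnitude, so small-set
  p-values far below 10^-3 should be quoted as orders of magnitude only.

### DNMT3L statistics

`fold_stimulation` pairs baseline and stimulated site tables: per-site fold
(Haldane-pseudocounted), Spearman trend between baseline efficiency and
fold (negative under saturation), rank agreement, and fold ranges before
and after.  The spread reduction is reported as a finding, never asserted
as an invariant — it is a property of the saturation mechanism, not of
arbitrary inputs.  `group_stimulation_test` is a one-tailed two-sample
Student t-test (stimulated > alone) on per-molecule overall efficiencies,
with the conventional star categories; identical groups give p = 0.5 and
zero variance in both groups gives NA with a warning.

The simulator has a single DNMT3L exponent, so the dcm-stratified
stimulation contrast (old strands unstimulated, new strands stimulated) is
composed in the analysis drivers as a mixture of a dcm+ run with exponent 1
and a dcm- run with exponent k — the chromatin preference of DNMT3L is
represented by stratification only, not mechanism.

## Word exceptionality under the M1 model

For a word w of length h, the expected count under the first-order (M1)
Markov background is the plug-in estimator

E(w) = prod_i N2(w_i w_{i+1}) / prod_{i=2..h-1} N1(w_i),

which reproduces every dinucleotide count exactly — all 2-letter words
score exactly zero, a useful internal control.  The score is
z = (N_obs - E)/sd, and the p-value the two-sided normal tail 2*Phi(-|z|)
(z = 5 ~ 10^-6, z = 10 ~ 10^-23; the two-sided mapping is the only one
consistent with both anchors).

The variance is derived in-package by the delta method: N(w) - E(w) is
linearized in the joint count vector (word, its pairs, its interior
letters), and the asymptotic covariance of any two word counts in a
stationary first-order chain is summed over lags — direct overlap terms
merged base-by-base, geometric tails through the fundamental matrix
Z = (I - P + 1 pi')^{-1}.  Against a 10,000-replicate Monte-Carlo oracle
on a 5 kb sequence the analytic z agrees to |dz| < 0.05, well inside the
0.3 working tolerance; the test suite re-runs that oracle.  Degenerate
cases (expected count 0, an interior letter absent, non-positive variance)
return NA rather than a number.

Pattern scans expand N-degenerate patterns (e.g. NTCGGN, NGCGCN) into
their concrete words and append an aggregate row whose score uses summed
per-word variances; it ignores between-word covariance and is a
descriptive summary, not a calibrated joint test.  Words are counted on
the given strand only, pooled across sequences, windows never crossing
sequence boundaries.  CpG-island metrics follow the strict operational
definition: GC fraction > 0.55 and observed/expected CpG ratio
N(CG) * L / (N(C) * N(G)) > 0.8.

## What the synthetic data does and does not emulate

Emulated: flank-driven per-site probabilities, maintenance strand
symmetry, dcm strand tagging on both strands of old molecules, incomplete
conversion at the study's printed rate, clone-sampling depths in the
study's range, and DNMT3L saturation with its inverse stimulation
relation.  Not emulated: PCR and cloning bias, sequencing errors and
indels, non-CpG methylation, chromatin structure (DNMT3L's chromatin
preference appears only as the dcm stratification), processivity or
iterative methylation rounds (the single-round choice is ours; the
original study does not say), and CpG-spacing effects.  Passing tests
therefore certify the statistical machinery and its calibration on this
generative family — not that real clone libraries satisfy the model.

## Problem sizes and numerical choices

The bundled stand-in regions are synthetic constructions matching the
published coarse properties of the test regions (~500 bp with 48 and 47
CpG sites, ~300 bp with 23, ~500 bp with 12); the original sequences are
not deposited, so every analysis labels these stand-ins `*_synthetic`.
Recovery analyses use 200 molecules per strand per region and pool the two
~500 bp regions, mirroring the original hot/cold analysis; null
calibrations use 200 replicates of site-level binomial draws (the
site-level marginal of the molecule simulator) and 15-seed word scans;
the Monte-Carlo variance oracle uses 10^4 replicates of a 5 kb chain.
All randomness flows through explicit seeds; identical parameters give
byte-identical FASTA/TSV outputs.  Low-coverage sites (n < 10) are flagged
and excluded from ranking; edge CpGs without k bases of context are
simulated at baseline and excluded from flank analyses with a warning.

## Known limitations

The chi-square cells are marginal per-position tests with no dependence
model between offsets; the motif model is positions-independent.  The
oriented-set inflation described above means logo p-values overstate
certainty under the null.  The M1 variance is asymptotic — very short
sequences or near-zero expected counts are flagged NA rather than
approximated.  Exact (compound-Poisson) p-values for rare words are out of
scope, as is any genome-scale island dataset; the scan runs on whatever
FASTA it is given.
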