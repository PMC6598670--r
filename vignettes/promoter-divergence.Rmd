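---
title: "Methods: promoter element content and evolutionary divergence of housekeeping and tissue-specific genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter element content and evolutionary divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`promevo` implements a promoter-characterization analysis for housekeeping
(HK) versus tissue-specific (TS) genes: expression-based classification of
an FPKM matrix, rule-based scanning of promoter elements (CpG islands,
short tandem repeats, G-quadruplex-forming sequences, degenerate consensus
motifs), and evolutionary-rate estimation for orthologous coding and
promoter sequence pairs (Nei–Gojobori dN/dS; promoter substitution rate
dP). This vignette explains the models, the parameters that matter, the
synthetic-data generator the analysis is validated on, and the design
choices made where the procedure was genuinely open.

## Gene classification

The substrate is a transcript-by-tissue matrix of FPKM values with a
transcript-to-gene map. A transcript is *housekeeping-consistent* when

1. it is detected (FPKM at or above a threshold) in **every** tissue;
2. its tissue profile, min–max normalized to $[0,1]$, is compatible with
   Uniform(0,1) by a two-sided one-sample Kolmogorov–Smirnov test with
   $P > 0.1$;
3. every tissue value lies within the fourfold range of the tissue
   average, $[\bar{x}/4,\; 4\bar{x}]$.

A gene is **HK** only if *all* of its transcripts pass (isoform
concordance). A gene is **TS** when it has at least one expressed
transcript and every expressed transcript is restricted to at most three
tissues; everything else is labeled *other*. Labels are mutually exclusive
and exhaustive, and per-transcript evidence (expressed-tissue count, KS
P-value, fold-range flag) is always reported alongside gene labels.

Open choices, and how they were resolved:

* **Detection threshold.** No FPKM cutoff for "detected" is standard; the
  default is 1.0 FPKM, a common transcript-detection convention, and it is
  exposed as a parameter because downstream counts depend on it.
* **KS construction.** "Uniformity across tissues" is tested on the
  min–max-normalized profile against Uniform(0,1). This is the only
  construction that is scale-free (classification is invariant to
  rescaling all FPKM values by a positive constant, which the test suite
  asserts). A constant profile has zero variance and is treated as
  perfectly uniform ($P = 1$).
* **Fourfold range.** Read as the two-sided interval $[\bar x/4, 4\bar x]$:
  an abnormally *low* single tissue violates expression stability just as
  an abnormally high one does.
* **TS at gene level.** TS status requires *all* expressed isoforms to be
  tissue-restricted, mirroring the HK isoform-concordance rule; transcript-
  level flags are also emitted so transcript counts can be tabulated.

## Element scanners

All scanners work in 0-based half-open promoter coordinates; offset 0 is
the distal end of the promoter and the TSS sits immediately 3' of the last
base, so distance to the TSS is `length - position`.

**CpG islands.** A 100-bp window slides by 1 bp; a window is island-like
when its GC fraction exceeds 0.5 and its observed/expected CpG ratio
$n \cdot L / (c \cdot g)$ exceeds 0.6. Runs of overlapping island-like
windows are merged, each merged region is trimmed to its outermost CpG
dinucleotides, and regions at least 200 bp long whose *whole-region* GC and
O/E still clear the thresholds are reported. The merge–trim–revalidate
procedure is fully specified here precisely because windowed island callers
differ in unpublished details; with these rules every reported island
satisfies all three thresholds on recomputation from the raw sequence,
which the tests assert.

**Short tandem repeats.** A locus is a maximal perfect tandem array of a
*primitive* unit of 2–6 bp with at least `min_copies = 7` full copies
("more than six repeat units"). The locus convention pins down a phase
ambiguity: the reported interval starts where the period-$k$ property
begins and spans `copies * k` bases (full copies only). Arrays whose unit
is a power of a shorter unit are reported only for the primitive unit, so
an AC array is never double-reported as ACAC and mononucleotide runs are
never reported. Overlapping loci of *different* primitive units are each
reported separately. Units containing `N` are skipped: an unknown base
cannot be certified a perfect repeat. Canonical unit names (lexicographic
minimum over rotations and reverse-complement rotations) aggregate
equivalent repeats (AC = CA = GT = TG) in summary tables.

**PQS.** A candidate quadruplex is four G-runs of a common length
($\geq 2$) separated by loops of $\geq 0$ bases within a total span of
$\leq 30$ bp, on either strand. "Four units" is read as four G-tracts (the
structural requirement of a tetrad stack); the alternative reading
(minimum G-run length 4) would make a bare `G16` run the minimal hit,
contradicting standard quadruplex-mapper defaults. Each candidate gets a
score rewarding long runs and even loops,
$\sum_{\text{loops}} (10 - |l - \tilde l|) + 10\,(g - 2)$ with $\tilde l$
the median loop, and overlapping candidates are resolved greedily by
descending score (ties: ascending start, ascending end, descending run
length, plus strand first). The raw candidate set is exposed separately
(`pqs_candidates()`) and is validated against a brute-force four-nested-
loop enumerator; cross-element overlap with STRs is deliberately never
deduplicated, so a `GG` dinucleotide array can legitimately count in both
tables.

**Motifs.** Degenerate IUPAC consensus strings are matched
position-by-position at every offset (overlaps included); reverse-strand
hits come from matching the reverse-complemented motif on the forward
sequence. The scanner is validated against full concrete-string expansion
for the consensus motifs used in the analysis.

## Evolutionary rates

**Nei–Gojobori (1986).** Synonymous and nonsynonymous *sites* per codon are
counted by classifying each of the nine single-nucleotide changes against
the standard genetic code (sites per codon always sum to exactly 3);
*differences* between codons differing at 2–3 positions are averaged over
all orderings of the single steps, excluding pathways through stop codons
(if every pathway hits a stop, all pathways are used with stop steps
counted nonsynonymous). Codons containing a gap or ambiguous base in either
sequence are skipped (pairwise deletion). $p_S = S_d/S$ and $p_N = N_d/N$
are Jukes–Cantor corrected, $d = -\tfrac34 \ln(1 - \tfrac43 p)$, and
$\omega = dN/dS$ is reported as undefined when $dS = 0$ or a rate
saturates ($p \geq 3/4$). Single changes that create stop codons count as
nonsynonymous by default; `stop_policy = "exclude"` drops them from both
numerator and denominator, since codon-counting software differs on this
convention. Both policies are tested.

**Selection test.** The variance of $dN - dS$ is estimated by resampling
codon columns with replacement (default 500 replicates, fixed seed), giving
$Z = (dN - dS)/\sqrt{\widehat{Var}(dN) + \widehat{Var}(dS)}$ and a
two-sided normal P-value; a degenerate bootstrap (zero variance, e.g.
identical sequences) returns $P = 1$. The bootstrap is used rather than an
analytical variance because it is assumption-light and its calibration can
be checked directly: under neutral simulations the empirical size at
$\alpha = 0.05$ sits inside the binomial 95% interval (asserted in the
acceptance suite at 100 pairs of 500 codons).

**Promoter divergence.** $dP$ is the mismatch fraction over alignment
columns free of gaps and ambiguous bases in both sequences (pairwise
deletion). The raw proportion is the default — a published TS promoter rate
of 0.64 is only interpretable as an (at most mildly corrected) proportion,
since the Jukes–Cantor transform of 0.64 would be near saturation —
with `correction = "jukes_cantor"` available. Unaligned pairs can be
aligned with `align_global()`, a Needleman–Wunsch aligner with linear gap
penalty (+1/−1/−2) and deterministic tie-breaking (diagonal, then gap in
the second sequence, then gap in the first). It is a nucleotide-level
aligner intended for short-to-moderate sequences; codon-aware alignment is
out of scope, so CDS inputs are expected pre-aligned.

## The synthetic-data generator

Every downstream stage is validated on generated data with recorded ground
truth; the generator is therefore first-class, tested code.

**Expression.** HK-like transcripts are drawn around a base level of 17.1
FPKM — the published mean for housekeeping genes — in every tissue; TS-like
transcripts are expressed above the detection threshold in 1–3 uniformly
chosen tissues and below it elsewhere; "other" transcripts violate one
housekeeping criterion each, in rotation (detected in only a subset of
tissues; a bimodal profile that fails the uniformity test while staying
inside the fourfold band; a single tissue far outside the fourfold range),
with the violated criterion recorded per transcript so classifier errors
can be attributed.

The HK noise model deserves a note. The obvious choice — i.i.d.
multiplicative noise, e.g. log-normal — cannot represent the HK class: a
KS test at cutoff $P > 0.1$ rejects a *uniform* i.i.d. profile 10% of the
time by construction, and a bell-shaped (log-normal) profile far more
often (~32% at cv = 0.1), so no i.i.d. generator can produce a population
of transcripts that passes its own defining screen at high rate. Real HK
gene sets are *selected* by that screen. The generator therefore uses
stratified mean-preserving uniform multiplicative noise: one draw per
equal-probability stratum of Uniform$(1 - a, 1 + a)$ with $a =
\text{cv}\sqrt{3}$, randomly permuted across tissues. The marginal
coefficient of variation is exactly the requested `noise_cv`, while the
normalized profile is close to an ideal uniform grid — the property the
screen selects for. At cv = 0.1 the HK class then passes the KS criterion
essentially always, which is what a set *defined* by passing it looks
like.

**Promoters.** Background bases are i.i.d. with a per-base GC probability
(default 0.45, the genome-average promoter GC). Planted elements — STR
arrays, literal PQS strings, CG-rich island blocks, concrete motif
instances — are written verbatim at recorded intervals, so truth is
recoverable by string comparison. Two details make planted truth *exactly*
recoverable by the scanners: a single flanking base after each planted STR
is forced to break the repeat period (otherwise background extends the
array with probability ~1/4 per side and the maximal locus differs from
the plant), and a 7-bp G-free margin flanks each planted PQS (otherwise a
chance background G-run at loop distance can tie the planted candidate's
score with an earlier start and win the greedy overlap resolution).
An optional `cpg_depletion` factor (first-order Markov suppression of G
after C) emulates the methylation-driven CpG depletion of real genomic
DNA; it matters because an undepleted i.i.d. background has CpG O/E ≈ 1
and the island rule then fires on background alone at GC near 0.5. Island-
density studies use depletion 0.25 (background O/E ≈ 0.3); element-recovery
validation runs at the default (no depletion).

**Divergent pairs.** In codon mode, an ancestor of sense codons receives
single-nucleotide proposals at an expected rate `t` per codon; a
nonsynonymous proposal is accepted with relative probability
$\omega : 1$ against synonymous proposals, and changes creating stops are
rejected. This is an accept/reject scheme, not a full codon substitution
model: it is designed so Nei–Gojobori estimation recovers the sign and
approximate magnitude of $\omega$ (at 2,000 codons and `t = 0.4`, neutral
simulations estimate $\hat\omega \in (0.8, 1.1)$ across seeds, and the
ordering of $\omega \in \{0.2, 1, 5\}$ is always preserved — asserted in
the acceptance suite). In promoter mode each site substitutes to a
uniformly chosen different base with probability `p_site`, so the expected
p-distance equals `p_site` exactly. All generators are seed-deterministic
and never touch the caller's RNG state.

What the generator does **not** emulate: read-level noise and FPKM
estimation error, correlated expression across related tissues, indels
(pairs are gap-free unless aligned externally), regional isochore
structure, repeat-masking, and transition/transversion bias. Passing
tests on synthetic data therefore validate the *rules and estimators*, not
their adequacy for any particular real genome.

## Study conditions and problem sizes

The validation suite and the reproduction script use: 200 random 2-kb
sequences for scanner-oracle equivalence; 100 promoters with planted
elements for recovery; a 200 + 200 + 200 transcript matrix over 21 tissues
(noise cv 0.1) for classification accuracy; 2,000-codon pairs across 20
seeds for $\omega$ recovery; 100 neutral pairs of 500 codons with 500
bootstrap replicates for Z-test calibration; and 10-kb promoter pairs at
`p_site = 0.1` for dP recovery. The `analysis/` drivers run a fuller
narrative study (600 transcripts, 400 promoters planted at the published
per-promoter element densities, 120 ortholog pairs with a shared latent
divergence factor linking dP to dN/dS). These sizes were chosen so each
stage's sampling error is small relative to the quantity being checked
while the whole suite remains quick on a laptop.

## Known limitations

* The KS uniformity test with min–max normalization is exact only for
  tie-free profiles; heavily tied profiles fall back to the asymptotic
  P-value.
* `align_global()` is $O(nm)$ plain R; align long genomic sequences with a
  dedicated aligner first.
* The PQS overlap resolution is a greedy heuristic with a documented
  scoring constant (`max_loop_penalty = 10`); alternative tie-breaking
  schemes exist in published mappers and would select different members of
  the same candidate set.
* Gene-level TS labels require all expressed isoforms to be restricted;
  datasets with pervasive low-level isoform leakage will shift genes from
  TS to *other* unless the detection threshold is raised.
* De novo motif discovery and motif-to-factor annotation are out of scope;
  the motif scanner consumes a given consensus list.
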