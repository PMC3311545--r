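---
title: "Methods: early zygotic gene discovery with ezgkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: early zygotic gene discovery with ezgkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ezgkit)
```

## The problem

During early embryogenesis the zygotic genome is transcriptionally silent
and all mRNA is maternally deposited. The maternal-zygotic transition is
the window over which maternal transcripts are degraded and the embryo's
own ("zygotic") transcription takes over. `ezgkit` identifies *pure* early
zygotic genes (EZGs) — genes with zygotic but no maternal expression —
from an unreplicated RNA-seq time course of four embryonic windows
(0–2, 2–4, 4–8 and 8–12 hr), then characterizes their gene structure and
their shared promoter sequence signals. The design it targets is a
mosquito embryo time course with one library per window, but nothing in
the package is species-specific.

## Temporal classification

Presence of a transcript in a window is defined as at least one read hit
— deliberately permissive, since an absolute statement ("no maternal
contribution") is being made from a single library. A transcript present
at 0–2 hr is *maternal*; absent at 0–2 hr and present at 2–4 hr it is a
*candidate EZG*; otherwise it joins the 4–8 hr or 8–12 hr first-presence
group, or is *absent*. `classify_transcript()` implements exactly this
cascade, and `call_ezgs()` intersects the candidate filter with the
significance test below.

## The MARS test for unreplicated count pairs

With one library per condition, replicate-based dispersion estimation is
impossible. The MA-plot-based random-sampling model treats the two counts
of a transcript as binomial draws with a common success probability $p$
from libraries of sizes $n_1$ and $n_2$. Writing (after adding a
pseudocount $c$) $X = \log_2(k_1+c)$, $Y = \log_2(k_2+c)$,
$M = X - Y$ and $A = (X+Y)/2$, the delta method gives, under the null,

$$\mu_X = \log_2(n_1 p),\qquad
  \sigma_X^2 = \frac{1-p}{n_1 p \ln^2 2},$$

and likewise for $Y$; $(M, A)$ is then approximately bivariate normal
with $\mathrm{Var}(M) = \sigma_X^2+\sigma_Y^2$,
$\mathrm{Var}(A) = \mathrm{Var}(M)/4$ and
$\mathrm{Cov}(M,A) = (\sigma_X^2-\sigma_Y^2)/2$. The test refers $M$ to
its conditional law given $A$:

$$z = \frac{|M - E(M\mid A)|}{\sqrt{\mathrm{Var}_0}},
  \qquad p = 2\,(1-\Phi(z)).$$

The closed-form conditional moments are checked in the test suite against
a generic Gaussian conditioning oracle built by matrix algebra, to 1e-9.

Three refinements to the textbook construction proved necessary to meet
the stated type-I band ($[0.03, 0.07]$ at nominal 0.05 for library-size
ratios up to 5 and expected counts down to ~10); each reduces to the
classical form in its limit:

* **Pseudocount-aware moments.** The delta method is applied to the
  statistic actually computed, $\log_2(k+c)$, giving
  $\mu = \log_2(np + c)$ and
  $\sigma^2 = np(1-p)/((np+c)^2 \ln^2 2)$. Ignoring $c$ in the moments
  (while adding it to the counts) biases $E(M)$ by ~0.06 at $np = 20$
  and ratio 5 — enough to push rejection to ~0.08.
* **Pooled proportion estimate.** $\hat p = (k_1+k_2)/(n_1+n_2)$, the
  common-proportion MLE, floored at $c/(n_1+n_2)$ so the all-zero case
  degrades to $p = 1$ rather than 0/0. The alternative of solving for
  $\hat p$ from $A$ makes $E(A) \equiv a$ identically, so the regression
  term of $E(M\mid A)$ vanishes while its variance reduction is still
  subtracted — an anticonservative null (measured rejection 0.15 at
  ratio 5).
* **Plug-in null variance.** Because $\hat p$ is estimated from the same
  two counts, the naive $\mathrm{Var}(M\mid A)$ is conservative under the
  pooled estimate (measured rejection 0.01 at ratio 5). $\mathrm{Var}_0$
  is instead the delta-method variance of the *entire* plug-in statistic
  $M - \hat E(M\mid A)$: with $\beta = \mathrm{Cov}(M,A)/\mathrm{Var}(A)$
  and drift terms $g_m = \partial e_M/\partial p$,
  $g_a = \partial e_A/\partial p$,
  $$\mathrm{Var}_0 = c_1^2\, n_1\hat p(1-\hat p) +
                     c_2^2\, n_2\hat p(1-\hat p),$$
  $$c_1 = u'(1-\tfrac\beta2) - \frac{g_m - \beta g_a}{n_1+n_2},\quad
    c_2 = -v'(1+\tfrac\beta2) - \frac{g_m - \beta g_a}{n_1+n_2},$$
  where $u', v'$ are the derivatives of the pseudocounted logs. For
  $n_1 = n_2$ this collapses to $\mathrm{Var}(M)$, as it should: with
  equal depths, $A$ carries no information about $M$.

Measured under the binomial null (20,000 pairs per cell), rejection at
nominal 0.05 is 0.053–0.064 across ratios 1/2/5 and expected counts from
10 to 200, and the closed-form p-value agrees with a seeded Monte-Carlo
binomial oracle to well within sampling error.

Further choices:

* **Pseudocount 1** on both counts before logs. The EZG use case has
  $k = 0$ at 0–2 hr *by construction*, so finiteness cannot be left to
  chance. The value is a parameter (`pseudocount`), and sensitivity to
  0.5 vs 1 can be probed directly. Because the baseline count is
  pseudocounted, exact replication of significance calls made by other
  implementations with undocumented zero handling is not guaranteed.
* **Orientation.** `mars_table()` puts the *later* bin in the numerator,
  so $M$ measures change from the earlier to the later window and a
  positive conditional shift `m_shift` $= M - E(M\mid A)$ means an
  increase. Two-sided p-values are reported; the *increase* direction
  required of an EZG is enforced by `call_ezgs()` as `m_shift > 0`,
  since a two-sided p-value alone does not encode direction.
* **Storey q-values** use $\hat\pi_0 = \#\{p > 0.5\} / (m/2)$, clamped to
  $[1/m, 1]$, with the usual step-up minimum. A single unreplicated
  library pair does not support fitting a spline over $\lambda$, so
  $\lambda$ is fixed at 0.5. Raw p-value thresholds (0.001, 0.05) gate
  the call sets; q-values are reported alongside.
* The baseline for the 4–8 and 8–12 hr first-presence groups is the
  adjacent preceding bin by default (`group_by_first_presence()`), with
  the 0–2 hr bin available as an alternative; the emulated study does not
  state which was used.

## Gene structure

Genes are scored intronless from their transcripts: under the default
`"all"` rule a gene is intronless only if *every* cognate transcript has
zero introns (the conservative reading of "scored according to their
cognate transcripts"; `"any"` is available). Mean introns per gene uses
the maximum across a gene's transcripts — a gene *has* an intron if any
isoform does — with mean-of-transcripts as an option. Enrichment of
intronless genes in a group is tested with a Pearson chi-squared on the
2×2 table of the group against the remaining genes, no Yates correction
by default (all in-scope comparisons involve large counts).

## Degenerate motif discovery

Upstream sequences of the significant EZG set are searched for
overrepresented motifs over the 15-letter IUPAC alphabet.

**Statistic.** Every length-$L$ window of the set is one Bernoulli trial
that succeeds when the window matches the motif in either orientation;
under an order-0 background with base frequencies $b$, the success
probability is $p_w = p(m) + p(\mathrm{rc}\,m) - p(\mathrm{both})$, each
term a product over positions of summed allowed-base frequencies. With
$x$ observed matching windows out of $n_w$,

$$E = N_{\mathrm{cand}} \cdot P\{\mathrm{Bin}(n_w, p_w) \ge x\},
  \qquad \mathrm{sig} = -\log_{10} E,$$

where $N_{\mathrm{cand}}$ is the number of candidate hypotheses examined
(distinct exact words across all searched lengths, collapsed over reverse
complementation). A *negative* sig therefore means "at or below
background expectation" — the expected outcome when a discovered motif is
queried against control sets. The reported **Count** is the total of
occurrences on both strands (a self-complementary match is listed once
per strand), and **Coverage** is the fraction of sequences containing at
least one occurrence on either strand.

A subtlety motivated this formulation: scoring the both-strand occurrence
*total* against a binomial over both-strand *positions* — the most
literal reading of "total occurrences on both strands" — makes the two
orientations of one window independent trials. For motifs whose expansion
set overlaps its own reverse complement's, every physical match then
counts twice while the null variance does not, inflating $z$ by up to
$\sqrt 2$; a greedy search maximizing sig exploits this relentlessly and
fills the ranking with near-palindromic artifacts. For any motif whose
forward and reverse-complement expansions are disjoint (the generic case,
including VBRGGTA) the window statistic used here is *numerically
identical* to the literal one.

**Search.** Stage 1 (*beam*) enumerates every exact word of each length
present in the data on either strand, scores all of them (vectorized over
a plus-strand word table), and keeps the `beam_width` (default 50) best
per length. Stage 2 (*prism*) greedily generalizes each survivor one
position at a time to the IUPAC code that maximally increases sig,
stopping when no single-position change helps or when
`max_degenerate_positions` (default 4) positions are degenerate. Counts
during the search are sums over expansion words in the word table, which
is provably identical to scanning and keeps the default search (lengths
5–10 on 61 × 400 bp) under a minute. A motif and its reverse complement
are one hypothesis: results are collapsed to revcomp-equivalence classes.
Ranking is by sig, then coverage, then pattern; the search has no
randomness.

**Calibration caveat.** The Bonferroni multiplier counts enumerated
words, but greedy degeneration optimizes over a much larger pattern
space. The best *post-selection* motif on pure background therefore
reaches sig ≈ 2–3.5 — the E-value is calibrated for pre-specified queries
(`evaluate_query()`, which does stay ≤ 0 on control sets), not for the
maximum of a search. The emulated study saw the same pathology in real
output: low-coverage repetitive junk above the biologically meaningful
motif, which was distinguished by *jointly* high sig and high coverage.

## PWM construction and alignment

`pwm_from_hits()` stacks hit sites (minus-strand hits
reverse-complemented), adds a per-base pseudocount (default 0.25, giving
the classic $n+1$ denominator), and renormalizes. When only a printed
consensus is available, `pwm_from_iupac()` builds the uniform-over-
allowed-bases stand-in. `align_pwms()` scores every ungapped offset in
both orientations by the mean Pearson correlation of paired probability
4-vectors (one of the published STAMP metrics; SSD is available), with at
least `min_overlap = 4` columns; ties prefer larger overlap, then smaller
|offset|, then forward orientation. Zero-variance columns (uniform
positions) are assigned correlation 0.

Because the reference alignment tool's database calibration cannot be
reproduced, `pwm_alignment_evalue()` replaces it with an explicit
permutation null: the target's columns are shuffled and each column's
base order independently shuffled, `n_null` times; the empirical p-value
is $(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(n_{\mathrm{null}}+1)$ and
$E = n_{\mathrm{null}} \cdot p$. Absolute E-values are therefore on the
package's own scale and only *orderings* are comparable across tools.
With consensus-derived PWMs, the mosquito motif scores 0.818 against
TAGGTAG and 0.596 against CAGGCAG — the same ordering as the reported
cross-species E-values.

## The synthetic world

`sim_config()` states one scenario and all generators draw from it
deterministically given one integer seed:

* **Counts.** Poisson per transcript per bin — with one library per bin
  there is no replicate dispersion to emulate, and the simpler null
  matches the MARS binomial model. Class profiles: maternal transcripts
  start high and decay; `ezg_transient` / `ezg_stable` are structurally
  zero at 0–2 hr; `first_4_8` / `first_8_12` stay zero until their named
  bin; `silent` is zero everywhere. Per-bin rates are rescaled so
  expected column sums equal the stated library sizes (~3×10⁶, a
  realistic early-Illumina depth). Relative abundances are log2-normal
  (location 5, scale 1.5) — the emulated study states no abundance
  distribution, so this is a modelling choice, not a claim about the
  study. Default class proportions put ~0.4% of 16,789 transcripts in
  the `ezg_*` classes (~67 transcripts, the study's scale), 55% maternal,
  and ~1% in later first-presence classes.
* **Annotations.** One gene per transcript by default
  (`transcripts_per_gene` exercises multi-isoform logic); intronless
  probability 0.33 for `ezg_*` genes vs 0.10 background, intron count
  `1 + Poisson(2)` otherwise (background mean ≈ 3 introns/gene, matching
  the reported 3.04).
* **Upstream sequences.** 400 bp of i.i.d. bases at GC 0.38 (a realistic
  mosquito genome-wide value); with probability 0.635 a sequence receives
  one concrete expansion of the consensus (default VBRGGTA), overwritten
  at a uniform position and strand so coordinates never shift, and every
  plant is recorded in the ground truth.

What the generator does **not** emulate: read-level error, repeats and
low-complexity sequence, dinucleotide structure, correlated gene families,
alternative isoform sharing of promoters, and spurious low-level
background expression — the silent class is strictly zero, so unlike a
real experiment (where most presence-filter candidates are background
noise) every candidate here is a true planted EZG. A green recovery test therefore
establishes correctness of the machinery on a favourable, known world —
not performance on real genomes.

### A known-red acceptance property

One stated acceptance property — "the planted motif is recovered in the
top 5 with reported coverage within ±0.10 of the planted rate" — is
unattainable in this stated world, and the package keeps the test red
rather than weakening it. The reason is quantitative: VBRGGTA's
either-orientation window probability at GC 0.38 is ≈ 1.65×10⁻³, so the
24,034 windows of a 61 × 400 bp set are expected to contain **~40 chance
matches (sd ≈ 6.3) against ~39 planted ones**. The planted signal is a
z ≈ 6 effect whose realization noise swings the sig by ±3; across seeds
the top-5 recovery succeeds in roughly half of runs (the search reliably
finds the *core*, e.g. the 6-mer BRGGTA, but an expansion-set Jaccard
across different lengths is 0 by definition). Chance matches also put
≈ 48% of sequences over one background occurrence, so the reported
coverage of any VBRGGTA-like motif is ≈ 0.8 *regardless of planting* —
no order-0 background at any realistic GC can keep a motif of match
probability ~8×10⁻⁴ sparse in 24k windows. These are properties of the
stated world, not of the implementation; the negative-control half of the
same criterion (querying the motif against background-only sets) passes.

## Degenerate inputs and edge behaviour

Zero counts are handled by the pseudocount; zero-length or zero-depth
normalization inputs are validation errors. A motif longer than a
sequence yields no hits rather than an error; an empty sequence set is an
error. `N` in a *sequence* matches nothing (including motif `N` — a
deliberate small deviation, since the scanner treats sequence letters as
literal); the generator never emits `N`. Probability floors: background
base frequencies are floored at 1e-6 and renormalized; the MARS
proportion estimate is clamped away from 0 and 1.

## Known limitations

* Absolute motif sig values and alignment E-values are on the package's
  own calibration and are not comparable to SCOPE's or STAMP's printed
  scores; orderings and recovery are the supported comparisons.
* The bipartite ("spacer") motif class is not implemented.
* Upstream sequences are taken as given; extracting them from a genome
  (TSS vs start-codon anchoring) is the caller's responsibility.
* Order-1 (dinucleotide) backgrounds are not implemented; on real
  genomic sequence the order-0 null overstates the surprise of
  dinucleotide-driven motifs.
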