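---
title: "Apportioning allopolyploid transcript abundance by iterative reference curing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Apportioning allopolyploid transcript abundance by iterative reference curing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeocure)
```

## The problem

An allopolyploid such as oilseed rape (*Brassica napus*, genomes A + C)
carries two diverged copies — homoeologues — of most genes, contributed by
its diploid progenitors. Because the homoeologues typically differ by only a
few percent of their bases, transcript assemblies built from such species
collapse the two copies into a single consensus "unigene", and short mRNA-Seq
reads aligned to that consensus cannot be attributed to one parental genome.
Two consequences follow: reads from diverged regions fail to map at all
(the consensus matches neither copy well), and relative expression of the
two homoeologues is unmeasurable.

`homeocure` implements a reference-correction strategy that solves both
problems using only mRNA-Seq reads from the two diploid progenitors:

1. **Curing.** The consensus ("naive") reference is iteratively rewritten
   towards each progenitor genome. Progenitor reads are split in half,
   aligned with a strict mismatch cap, piled up, and a high-confidence
   consensus base is substituted into the reference wherever it disagrees.
   Each cycle unlocks reads that previously exceeded the mismatch cap, so
   the procedure is repeated (six cycles by default).
2. **IHP calling.** The A-cured and C-cured references are compared base by
   base; every position carrying two definite, different bases is an
   inter-homoeologue polymorphism (IHP) — the discriminating signal.
3. **Apportioning.** Polyploid reads are aligned to a combined reference
   holding both cured versions of every unigene. A read spanning an IHP
   matches one version strictly better and is counted to it; a read from an
   identical tract ties and is assigned uniformly at random, so such reads
   split evenly and dilute, but do not bias, the estimate.
4. **Testing.** Per-unigene paired abundances (A vs C across biological
   replicates) are tested for differential homoeologue contribution with a
   quasi-Poisson generalised linear model, followed by Benjamini–Hochberg
   adjustment.

## The aligner and its contract

The internal aligner is deliberately simple: ungapped, fully contained
placements on either strand, at most `max_mismatches` substitutions
(default 3), one best placement per read, uniform random tie-break among
equally good placements (recorded in the `tie_broken` flag). Its contract is
*exact* — the test suite holds it equal to an exhaustive Hamming-distance
scan over every offset and both strands — while the implementation uses
pigeonhole k-mer seeding: a read is cut into `max_mismatches + 1` blocks, so
any acceptable placement matches at least one block exactly, and only seeded
candidates are verified. Below a seed length of 6 the index buys nothing and
the code falls back to the exhaustive scan; both paths satisfy the same
contract, and results are deterministic given the seed.

Two conventions matter downstream:

* `N` in read or reference always counts as a mismatch (it is an absence of
  evidence, not a wildcard);
* mapping quality is not modelled — no downstream step consumes it, and the
  retained information (mismatch count + tie flag) is what the counting
  semantics require.

Indels are out of scope throughout: curing substitutes bases and never
changes sequence length, so the alignment problem the pipeline needs is
purely substitutional.

## Consensus calling and the curing loop

For every covered reference position the pileup accumulates per-base counts
and summed Phred qualities (reverse-strand reads contribute complemented
bases). The consensus candidate is the base with the highest summed quality;
a tie yields `N`. Its consensus quality is defined as

    q(b*) - sum of q(other non-N bases),  floored at 0, capped at 93,

and the base is substituted into the reference only when its supporting
read count is **strictly greater than 3** and its consensus quality is
**strictly greater than 40**. The two thresholds are the pipeline's
high-confidence criteria and both are exclusive boundaries — depth 3 or
summed quality 40 are rejected, and the test suite pins these edges. The
subtraction makes the score an evidence *margin*: opposing reads weaken a
call even when the leading base has a large majority.

Positions that never reach the thresholds keep their naive base. Leaving
them unchanged is the only non-destructive choice: an aggressive `N` would
discard naive information that later cycles (or the other genome) may
confirm.

Reads are split into their first and last 40 bases before curing because a
half-read carries the full mismatch budget across half the length — it can
reach regions twice as diverged as a full read. The two half-alignments are
merged into a single pileup before consensus; overlapping coverage from
distinct reads simply sums qualities.

Each curing run is reproducible: per-cycle tie-break seeds are derived
deterministically from the configured seed and the cycle index, and the
change log records `(unigene, position, old, new, cycle)` for every
substitution, which supports per-cycle reporting and the concerted-change
counter (changes made identically in both genome runs, typically assembly
errors in the naive reference rather than genuine divergence).

## IHPs and their density

`compare_references()` reports a position as an IHP only when both cured
bases are definite (`A/C/G/T`) and different; positions where either genome
remained `N` are silently non-comparable rather than errors. Per-unigene
IHP density uses the **full unigene length** as denominator. Covered length
would be an alternative denominator; full length was chosen because it is
reproducible from the sequences alone, without carrying alignment state
into the summary, and the summary's mean density is computed over the
unigenes that contain at least one IHP (the subset an apportioning analysis
can act on).

## Quantification

Counts are whole reads at their single best placement — there is no
fractional assignment or expectation-maximisation reassignment. This is a
deliberate fidelity choice: the random tie-break already distributes
ambiguous reads evenly, count conservation is exact
(`count_A + count_C` = reads mapped to the pair), and the attenuation it
causes is transparent: a unigene with no IHPs estimates a 50:50 split
regardless of the true bias, and at ~3% divergence with 80-base reads about
9% of reads span no IHP, pulling a true 70% A-share down to roughly 68%.
The test suite measures exactly this attenuated value.

RPKM is `count * 1e9 / (length * total_mapped)`, with the denominator being
the sample's total mapped reads across the whole combined reference (a
genome-wide denominator keeps A and C values of one sample on a common
scale). A zero count is RPKM 0 by convention.

Qualitative calls require unanimity across replicates: `expressed` needs at
least one read in *every* replicate, `non_expressed` zero in every
replicate, anything else is `inconsistent`.

## The paired quasi-Poisson test

For one unigene with `n` replicates the `2n` abundances are modelled with a
log-link GLM with Poisson variance function:

    E[y] = exp(replicate effect + genome effect),  Var[y] = phi * E[y]

The replicate indicators absorb the paired block structure; the genome
indicator carries the effect of interest (log of C relative to A). The
dispersion `phi` is not fixed at 1 but estimated per unigene from the
Pearson statistic over the residual degrees of freedom (`n - 1`), so
coefficient estimates equal the ordinary Poisson ones while standard errors
are dispersion-scaled; the reported p-value is a two-sided Wald t with
`n - 1` degrees of freedom, exactly what `summary.glm` produces for a
`quasipoisson` fit. Per-unigene estimation is the natural reading of
fitting one GLM per paired series; pooled dispersion estimation would gain
stability at low replication at the cost of assuming a common `phi`, and is
left to the user by pre-scaling if desired.

The model is fitted to RPKM values directly. Quasi-likelihood only requires
a mean–variance relationship, not integer responses, and fitting the
normalised values keeps the A and C series on the sample's common scale. A
counts-with-offset mode (`offset_log` in `fit_paired_quasipoisson()`) is
available for users who prefer raw counts with `log(length * depth)`
offsets; it is off by default.

Degenerate inputs are handled explicitly: series that are all-zero in both
genomes are untestable and dropped (reported via an attribute); when the
replicate terms reproduce the data exactly the Pearson dispersion is 0 and
the genome effect is known without error, so `p = 1` for a zero effect and
`p = 0` otherwise. Unigenes without IHPs are excluded from testing when an
IHP table is supplied — with identical sequences the apportioning signal is
pure tie-breaking noise centred on 50:50, so a "significant" result there
could only be a false positive.

Raw p-values are BH-adjusted (`stats::p.adjust`, pinned in the tests
against an independent hand-written step-up implementation to 1e-12), and
bias is called at adjusted p < 0.05: `A_higher` for a negative genome
effect, `C_higher` for a positive one.

## What the synthetic data emulate — and what they do not

The generator produces: ancestral unigenes (i.i.d. uniform bases, lengths
normal around 1 kb, floored at 300 b — a typical unigene-assembly scale);
two genomes diverged by independent per-site substitution at 3% (each
divergent site mutates exactly one genome, chosen evenly); 80-base
single-end reads with uniform starts and strands, per-base substitution
errors at 1%, and a quality profile of Q35 through base 60 decaying to Q20
at the read end (the within-read decay typical of long-cycle sequencing
runs); four biological replicates; and per-unigene A-fractions for
polyploid transcripts. Replicate over-dispersion is gamma–Poisson: a mean-1
gamma multiplier with shape `m / (phi - 1)` gives counts with variance
`phi * m`.

The generator deliberately omits: indels (out of scope by design),
composition bias (real *Brassica* unigenes are not uniform random DNA, so
real k-mer seeding hits more spurious candidates), paralogue families at
~15% divergence (which can cross-map and would require the unigene build to
separate them), expression-dependent coverage during curing (progenitor
coverage is even by default so curing eligibility is uniform), and
library-preparation artefacts. Passing tests therefore demonstrate the
*algorithmic* contracts — recovery, precision, calibration, determinism —
under the stated noise model, not performance on any particular real
tissue.

Default validation problem sizes, chosen so the full pipeline runs in
minutes on one CPU: 200 unigenes × ~1 kb at 30× coverage for
curing/IHP recovery; 80 unigenes (a quarter of them with zero divergence)
for apportioning; 1,000 null + 700 alternative simulated series for test
calibration. At these sizes the measured behaviour is: ≥ 95% of divergent
positions with eligible coverage (> 3 true reads in the relevant
progenitor) corrected, ≥ 99% substitution precision, IHP recall ≥ 90% and
precision ≥ 99%, type-I error within [0.03, 0.07] at nominal 0.05, power
≥ 0.8 at a 4-fold bias with mean abundance 50 and `phi` ≈ 3, and empirical
FDR below the nominal level — each recomputed by
`scripts/acceptance.R` and asserted by the test suite.

## Numerical and interface conventions

* All internal coordinates are 0-based; every file-facing coordinate
  (pileup, IHP, change-log TSVs) is 1-based. Converters live only at the
  read/write boundary.
* Quality encoding is declared, never sniffed (`sanger` offset 33 by
  default, `illumina13` offset 64 converted on load); internally everything
  is Sanger-encoded Phred in [0, 93].
* All stochastic entry points take explicit seeds; derived stage seeds are
  computed from the configured seed with a fixed linear-congruential step,
  so one seed pins every pipeline output byte-for-byte.
* Ambiguity codes other than `N` are rejected at load: every downstream
  rule (mismatch counting, consensus, IHP) is defined over `{A,C,G,T,N}`
  only, and admitting IUPAC codes would silently weaken all of them.

## Known limitations

* Substitution-only: structural differences between homoeologues are
  invisible and may locally depress mapping and curing.
* Unigenes with few or no IHPs are biased towards 50:50 by construction;
  the test-stage IHP filter removes the zero-IHP class but low-IHP unigenes
  remain attenuated.
* The mismatch cap interacts with divergence: regions locally exceeding
  ~3 substitutions per 40-base window are unreachable in early cycles and
  recover only if flanking corrections unlock them (the staged-curing test
  reproduces this walk-through).
* Per-unigene dispersion estimation with few replicates is noisy; with 4
  replicates the Wald t has only 3 degrees of freedom, which the
  calibration tests show is adequate but not generous.

## A short example

```{r example, eval = FALSE}
truth <- simulate_diverged_pair(n_unigenes = 50, seed = 1)
reads_a <- simulate_reads(truth, "A", depth_target = 30, seed = 2)
reads_c <- simulate_reads(truth, "C", depth_target = 30, seed = 3)

pair <- build_cured_pair(truth$ancestral, reads_a, reads_c,
                         curing_config(rng_seed = 4))
ihp <- compare_references(pair$a_ref, pair$c_ref)
ihp_summary(ihp)$mean_density_per_kb

expt <- simulate_paired_experiment(truth, n_replicates = 4, seed = 5)
combined <- build_combined_reference(pair)
quant <- lapply(expt$replicates, quantify_sample, combined = combined)

rpkm_a <- sapply(quant, `[[`, "rpkm_A")
rpkm_c <- sapply(quant, `[[`, "rpkm_C")
rownames(rpkm_a) <- rownames(rpkm_c) <- quant[[1]]$unigene
res <- test_homoeologues(rpkm_a, rpkm_c, ihp_table = ihp)
table(res$bias)
```
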