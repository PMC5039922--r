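---
title: "Detecting subtle allelic imbalance from haplotypes and allelic read depths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting subtle allelic imbalance from haplotypes and allelic read depths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Somatic chromosomal aberrations — amplifications, deletions and copy-neutral
loss of heterozygosity (cn-LOH) — create *allelic imbalance* (AI): the two
parental copies of a genomic segment are no longer equally represented in the
sample's DNA. In a tumor biopsy diluted with normal cells, or in a minor
subclone or premalignant lesion, the aberration may be present in only a
small fraction $f$ of cells. At a heterozygous site inside a cn-LOH region
the expected frequency of the retained haplotype's allele is only
$(1+f)/2$ — at $f = 0.08$ that is $0.54$, a shift far smaller than the
binomial noise of a single site at 30–80× coverage. Methods that test each
site marginally, or that model total coverage, miss such events.

`haploscan` detects them by borrowing strength across sites *along
haplotypes*. The inputs are (i) a VCF with genotypes and the allelic-depth
(`AD`) field for one sample, and (ii) statistically estimated germline
haplotypes for the same sites (a phased VCF, e.g. from a population phasing
tool). No paired normal sample is used anywhere.

## The model

**Markers.** Biallelic heterozygous SNVs with total depth at least
`min_depth` (default 10; the value is a pre-processing choice, exposed as a
flag, since depth filters of this kind are not part of the statistical
model). Each marker carries its reference-allele frequency (RAF)
$r_i = \mathrm{ref}_i / (\mathrm{ref}_i + \mathrm{alt}_i)$.

**Frequency-based phasing.** A genome-wide threshold $t$ — by default the
median RAF, which absorbs global reference bias and should be close to
0.5 — splits each marker: the allele with frequency above $t$ is the
"excess" allele. The concordance indicator is

$$ z_i = \mathbf{1}\{\text{excess allele at } i \text{ lies on estimated
haplotype 1}\}, $$

with $z_i$ missing when $r_i = t$ exactly (a deterministic tie rule;
randomizing a measure-zero-in-practice case would only cost
reproducibility). Under no imbalance $z_i$ is a fair coin; inside an AI
region the excess alleles align with one parental haplotype, so $z$ becomes
a long run of (mostly) constant values — up to switch errors in the
estimated haplotypes.

**Phase concordance** summarizes that alignment as the fraction of
*adjacent* non-missing pairs with $z_i = z_j$ (chromosome boundaries break
pairing; missing markers join their neighbours). Adjacent pairing, rather
than all pairs, is what makes the statistic robust to phasing switch
errors: one long-range switch corrupts exactly one pair. Its null
expectation is 0.5. The windowed scan
(`windowed_concordance_scan()`) is descriptive; inference is done by the
HMM.

**The HMM.** A three-state chain over marker index: `N` (balanced) and two
imbalance orientations `A1`, `A2` (haplotype 1 or 2 in excess). Emissions:
`N` emits $z$ as a fair coin; `A1` emits $z = 1$ with probability
$\gamma \in (0.5, 1)$; `A2` mirrors it; a missing $z$ emits 1 in every
state. Transitions: leaving imbalance carries mass
$q = 1/\texttt{mean\_event\_markers}$ to `N`; within imbalance, mass
$\texttt{switch\_rate}\,(1-q)$ crosses `A1`↔`A2`, absorbing phasing switch
errors without leaving the imbalance state; entry from `N` is solved so the
stationary occupancy of `A1 + A2` equals `prevalence`. Each chromosome
starts at the stationary distribution. Posteriors come from scaled
forward-backward (exact, underflow-free at millions of markers; implemented
in C++), reported as $p_i = P(A1_i) + P(A2_i)$; `viterbi_segments()` gives
the deterministic companion path with ties broken toward `N`.

The chain is homogeneous in *marker index*, not base pairs: exome marker
spacing is wildly uneven and a distance-scaled chain would need its own
calibration, so `mean_event_markers` is simply exposed per design (defaults
200 for WES, 2000 for WGS — roughly a 10 Mb event at either het density).

**Self-calibration of $\gamma$.** The true concordance rate depends on the
unknown fraction $f$ and the depth, so a fixed $\gamma$ cannot be right: at
$f=0.04$, 30×, the per-marker accuracy is only about 0.59, and a fixed
$\gamma = 0.8$ would actually score such markers *against* imbalance.
`estimate_gamma_em()` runs Baum–Welch updates of $\gamma$ alone
(transitions fixed; the constrained M-step clamps to
$[0.5 + 10^{-6},\, 1 - 10^{-6}]$, preserving the EM monotonicity
guarantee). Detection (`detect_ai()`) runs EM by default whenever at least
100 informative markers are present.

**Events.** Maximal runs with $p_i \ge \texttt{posterior\_cut}$ (default
0.90), trimmed of uninformative flanks, kept at
$\ge \texttt{min\_event\_markers}$ (default 10); runs separated by even one
sub-threshold marker are not merged. Each event reports its mean $|r - 0.5|$
and the aberrant-cell fraction that deviation implies under cn-LOH
($f = 2d$); `estimate_fraction()` also inverts the deletion
($f = 4d/(1+2d)$) and amplification ($f = 4d/(1-2d)$, capped at 1) algebra,
since the three mechanisms cannot be told apart without total-copy-number
information, which this model deliberately does not use.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 10 reads | site filter before RAF computation |
| `threshold` | median RAF | excess-allele cut point |
| `prevalence` | 0.05 | prior fraction of markers in AI |
| `mean_event_markers` | 200 (WES) / 2000 (WGS) | expected event length, markers |
| `gamma` | 0.65 (EM start) | concordance emission probability |
| `switch_rate` | 0.02 | A1↔A2 crossing rate inside AI |
| `posterior_cut` | 0.90 | event membership threshold |
| `min_event_markers` | 10 | minimum called-event length |

All are overridable from `run_config()`, a JSON config file, or the
`inst/scripts/haploscan` command line (precedence: flags > file >
defaults). The config format is JSON rather than YAML because the package
stack standardizes on `jsonlite`.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates a single chromosome with: het-site spacing
per preset (WES: exon-like 150 bp islands every ~3 kb with Poisson(1)
markers each, reproducing sparse, bursty spacing without a real capture
BED; WGS: uniform at ~1/1.5 kb); true haplotypes by fair coin; Poisson (or
negative-binomial) depths floored at 1; reference counts binomial — or
beta-binomial with overdispersion `rho` — around the mixture-model expected
RAF; and estimated haplotypes equal to the truth corrupted by a persistent
switch process (default 0.02 per adjacent pair, the scale of
population-phasing switch error at these marker densities). Aberrant-cell
mixing is done analytically through the expected RAF rather than by mixing
reads: the resulting allele-count distribution is identical, and read-level
machinery (mapping bias, GC bias, alignment artifacts) is out of scope. The
genotype emitted to the VCF is *called from the simulated reads* (`0/1`
only when both alleles are seen), so near-pure events lose their markers to
the het filter just as real data would.

Consequently a green sensitivity test establishes that the *statistical*
detection limit at the stated depth, density, noise and phasing-error
levels meets the target; it does not establish robustness to alignment
artifacts, capture-kit idiosyncrasies, or structured phasing error, none of
which the generator produces. The measured limits on this clean synthetic
world sit at or below those reported for real in-silico BAM mixtures, as
they should.

## Numerical choices and degenerate inputs

* Forward–backward uses per-step scaling; posteriors sum to 1 within
  $10^{-9}$ and match exhaustive $3^n$ enumeration within $10^{-10}$ on
  short tracks.
* All-missing tracks return the prior exactly; EM on such a track warns and
  returns its input $\gamma$.
* Viterbi ties go to `N`. Inside missing-data gaps the placement of the
  `A1`→`A2` switch is genuinely ambiguous (all placements equally
  probable); the deterministic tie rule picks one, and the test suite
  checks probability-equality rather than path identity there.
* EM on null data usually drifts $\gamma$ to the 0.5 clamp, but on finite
  tracks it can latch onto a short noise run ($\gamma$ up to ~0.7 on 20k
  null markers). This does not translate into called events: over 100 null
  replicates of 20,000 markers, all replicates call zero events and far
  fewer than 1% of markers reach $p > 0.9$. The event-length minimum, not
  the EM fit, is what controls the false-positive rate.
* `compute_threshold` on an even site count takes the mean of the central
  order statistics; an empty site set is a hard error, as is a zero-overlap
  join between the sample VCF and the phase file.
* Replicate seeds in `purity_grid_experiment()` are derived
  deterministically from the base seed in double precision and reduced
  modulo $2^{31}-1$, so any small base seed reproduces the experiment
  exactly.

## Known limitations

Marker-index (not bp) transitions; a single genome-wide $\gamma$ (a
depth-weighted, per-site emission would extract more from uneven coverage);
no discrimination of cn-LOH vs deletion vs amplification (no coverage
model); no multi-clone deconvolution; the detection criterion of the power
experiment (≥ 50% span overlap at posterior ≥ 0.9) is itself a convention,
exposed as parameters.
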