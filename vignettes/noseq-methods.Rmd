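---
title: "Detecting m6A in deaminated amplicon libraries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting m6A in deaminated amplicon libraries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noseq)
```

## The measurement principle

N6-methyladenosine (m6A) carries a methyl group on the exocyclic amine that
nitrous acid attacks. Treating RNA with sodium nitrite in acidic buffer
therefore deaminates unmethylated adenosines to inosine — which reverse
transcribes like G — while m6A largely resists and keeps its A signal.
Cytidines deaminate to uridine (read as T), and guanosines deaminate, more
slowly, to xanthosine (X), which stalls or blocks reverse transcription.
Complete deamination destroys the library (every molecule acquires blocking
X lesions), so the assay operates in a *partial* regime, with an A-to-I
conversion of roughly 10–50%. Sequencing a treated amplicon then shows, at
every unmethylated A position, a mixture of A and G read-outs in proportion
to the conversion rate, while an m6A site stands out by an abnormally high
residual A fraction.

This package implements the full desk side of that assay: a
deamination-aware aligner, per-position conversion-rate tables, a
probability-based candidate caller with stoichiometry calibration, UMI
redundancy assessment, and a simulator that generates reads with the
statistical structure of a treated library so that every stage can be
exercised, and its operating characteristics measured, without wet-lab
input.

## Alignment of degenerate reads

Partial deamination makes reads systematically mismatch their reference,
so conventional mappers reject exactly the molecules the assay needs. The
aligner uses seed-and-extend with an *asymmetric* substitution matrix over
(read base, reference base):

|       | ref A | ref C | ref G | ref T |
|-------|------:|------:|------:|------:|
| read A | +1 | −1 | +1 | −1 |
| read C | −1 | +1 | −1 | −1 |
| read G | +1 | −1 | +1 | −1 |
| read T | −1 | +1 | −1 | +1 |

The +1 entries beyond the identities encode the chemistry: (G, A) is the
A-to-I signal, (T, C) the C-to-U signal, and (A, G) the minor adenosine
component observed at G positions after xanthosine read-through. The table
is asymmetric where the chemistry is: a read T over a reference C is
rewarded, but a read C over a reference T is penalized, because nothing
converts U back to C. The matrix is one configurable table
(`substitution_matrix()`, `read_substitution_matrix()`), so a different
published variant can be swapped in verbatim.

The reference is indexed by its overlapping k-mers (k = 11 by default,
entries kept in lexicographic order). Seeding is *matrix-compatible* rather
than literal by default: a read k-mer seeds wherever all k pairings score
+1. With literal equality a heavily converted read might contain no exact
11-mer at all and could never be recovered; both modes are available
(`seed_mode` in `align_all()`).

Three retention filters follow the extension:

1. **Perfect score** — the gapless extension over the full read must score
   exactly the read length, i.e. every pairing is deamination-compatible.
2. **Anchor** — the implied reference start must be position 1 of the
   amplicon, fixing the reading frame set by the primer design.
3. **Coverage** — the read must span the whole evaluation window (default:
   the entire reference), so every retained read contributes to every
   position and coverage is constant by construction.

Because the perfect-score filter makes any gap or −1 pairing fatal,
ungapped extension is exhaustive: no gapped alignment could ever pass the
filter, so none is attempted. The compiled core
is verified in the test suite against a brute-force scorer of *all*
ungapped placements and against the exported R primitives
(`seed_matches()`, `extend_and_score()`).

Bookkeeping choices where several conventions would work: a read is
accepted via its first accepted seed in (read offset, reference offset)
lexicographic order (under the anchor filter at most one placement can
survive anyway, so this tie-break is only visible in diagnostics); a
rejected read reports the verdict of its lexicographically first seed,
with the priority out-of-bounds/window → `coverage`, imperfect score →
`score`, off-anchor → `anchor`; reads with no seed at all are `no_seed`,
and reads whose insert contains N are set aside as `n_base` before
alignment since the perfect-score filter is unattainable for them. Reads
longer than the reference are rejected (`coverage`) rather than clipped.
The funnel statistics conserve the input count across these bins.

## Rates and the candidate caller

From the accepted reads, `tabulate_rates()` counts A/C/G/T read-outs per
position. At reference A positions the *A rate* is the fraction of reads
still reading A and the *G rate* the fraction reading G; at C positions
the *T rate* tracks C conversion. Denominators are the total accepted
read count — "fraction of reads" in the plotting sense — so rare
sequencing errors dilute both rates instead of silently renormalizing
them.

`call_sites()` standardizes the A rate at each A position against the
distribution over *all* A positions,

$$z_p = \frac{a_p - \mu}{\sigma}, \qquad P_p = \Phi(z_p),$$

and flags positions with \(P_p\) strictly above the detection threshold
(default 0.95). Conventions, each deliberate:

* \(\mu, \sigma\) include the candidate position (no leave-one-out). This
  is conservative — a strong site inflates \(\sigma\) and so shields the
  remaining positions; a leave-one-out variant is available behind
  `leave_one_out = TRUE`.
* \(\sigma\) is the sample SD (n − 1 denominator).
* The test is one-sided: only abnormally *high* A rates indicate m6A,
  since the chemistry can only protect m6A from conversion. Low-tail
  outliers are surfaced as QC warnings, never as candidates.
* No multiple-testing correction is applied across A positions; an
  amplicon has few of them (the built-in 53-mer has 11). For long
  references this raw 0.95 threshold would need rethinking — a documented
  caveat, not a hidden one.
* A zero-variance rate distribution (e.g. an untreated library) is a hard
  error: the statistic is undefined there, and silently returning "no
  candidates" would mask a failed treatment.

With the threshold at 0.95 the construction nominally leaves 5% of null
positions above the line. In practice the suite measures about 3% under
the no-methylation null: with 11 A positions the mean and SD are
themselves estimated from the sample (which shrinks extreme standardized
values, a small-sample effect), and the lognormal reactivity jitter makes
the high-A-rate tail light. The acceptance test therefore brackets the
null exceedance in [2.5%, 7.5%] rather than pinning it to 5.0%.

## Stoichiometry calibration

For a titration of a single site with known m6A content \(m\) under
conversion rate \(p\), the expected A signal at the site is

$$a(m) = m + (1 - m)(1 - p) = (1 - p) + p\,m,$$

a line with slope \(p\) and intercept \(1 - p\). `fit_calibration()` fits
it by ordinary least squares and exposes inverse prediction (signal →
estimated content, clipped to [0, 1]). The calibration experiment in the
acceptance suite titrates 0–100% in 10% steps with duplicate libraries
per mixture and runs at nominal rates (site jitter off): the jitter term
models *site-to-site* reactivity variance, which has no analogue across
mixtures of the same oligo at the same site — any fixed site-specific
reactivity multiplier is absorbed into the calibrated slope, which is
precisely why quantification requires per-site calibration. MeRIP
enrichment deliberately breaks this linearity (see below), which is why
the package reports enriched samples only qualitatively.

## The simulator

`simulate_reads()` inverts the read-out rules generatively, per molecule:

1. The methylation state of each annotated site is drawn from its
   stoichiometry.
2. Conversion events are drawn independently per base: unmethylated A
   with probability `p_AtoI`, C with `p_CtoU`, G with `p_GtoX`;
   a methylated site converts only if it first "behaves unmethylated"
   (probability `p_m6A_deaminated`, default 0).
3. Every converted G (an X lesion) blocks reverse transcription with
   probability `p_X_block`; the first block along the read truncates it
   there. Truncated reads are *emitted* — they then fail the coverage
   filter downstream, reproducing the survivor bias toward
   under-deaminated molecules that the wet-lab assay shows under harsh
   conditions.
4. Read-out: converted A → G, converted C → T, read-through X → A with
   probability `p_X_reads_A` (default 0.1, matching the mostly-G,
   slightly-A signal seen at G positions), otherwise G; protected m6A → A.
5. A random UMI (default 7 nt) is attached.
6. PCR duplication: each subsequent read is, with probability
   `pcr_duplication_rate`, a re-read of an earlier molecule carrying the
   same sequence and UMI.
7. An optional MeRIP stage resamples reads with weight
   `enrichment_factor` for methylated molecules and
   `background_retention` for unmethylated ones, renormalized to the
   requested read count.

**Reactivity jitter.** Real deamination rates vary site to site. The
simulator multiplies `p_AtoI` and `p_CtoU` by a per-position lognormal
factor (σ = 0.15 by default), redrawn per simulated library (each call
models an independent treatment/amplicon). This term is load-bearing:
without it the probability statistic would detect arbitrarily small
stoichiometries at large read counts, contradicting the observed ~50%
de-novo detection limit; with σ = 0.15 the 50%-stoichiometry site is
detected in roughly 95% of replicate libraries while 25% is usually
missed — the regime the assay actually reports.

**NOm6A.** Nitrosation of m6A (NOm6A) is carried as a formation
probability with configurable read-out (`reads_A`, the default under mild
presets, or `blocks_RT` with a mixing weight) since its base-pairing
behaviour is not established.

**Chemistry presets.** Exact per-condition rate constants are not
published; the presets encode the published *constraints* with mid-range
defaults: `optimal_oligo` (the 50 °C / pH 4.0 / 20 min working point)
with `p_AtoI = 0.30`, `p_CtoU = 0.35`, `p_GtoX = 0.03`; `amplicon` (the
milder 60 °C / pH 5.0 / 10 min biological-sample condition) with
0.15 / 0.20 / 0.01. Both respect A-to-I in the 10–50% working window, C
faster than A, and G an order of magnitude slower. `p_X_block` defaults
to 0.8 and is exposed as a free parameter — the survivor fraction under
harsh conditions is not quantified in the published record. The full
72-condition screening grid (3 temperatures × 4 pH × 6 times) is
enumerated by `condition_grid()` as metadata; no kinetic (Arrhenius-type)
model maps a condition to rates.

**What the simulator does not model:** acid-induced RNA degradation
(beyond X truncation), primer-specific amplification bias, base-quality
structure (qualities are carried but never interpreted), and — by default
— sequencing error, available as a uniform per-base rate
(`seq_error_rate`) for robustness studies. Passing tests on simulated
data therefore demonstrate the statistical machinery under the stated
generative model, not robustness to every artefact of real libraries.

## UMI redundancy

`assess_redundancy()` counts duplicates as reads with *identical* UMI
strings, the assay's own definition; an edit-distance-1 clustering is
available behind a flag (default off). Random 7-nt tags have only
\(4^7 = 16384\) states, so chance collisions impose a baseline
redundancy floor that the report quantifies with a birthday-bound
estimate and subtracts nothing from — it flags saturation once the read
count approaches tag diversity (at 10<sup>4</sup> reads the floor alone
is ~17%). The redundancy-recovery test therefore runs at amplicon-scale
depth (500 reads, where the assay itself operates on "a few hundred
reads" and the floor is ~1.3%), comparing redundancy minus the reported
floor against the generative 10% duplication rate. Duplicate reads are
reported, not removed: rates are computed from all accepted reads, with
an optional pre-rates deduplication left off by default to preserve the
assay's published behaviour.

## Problem sizes and determinism

The test suite and acceptance script size their simulations to the
regimes the statistics need: 10<sup>4</sup> reads for detection-threshold
experiments (binomial noise ≪ jitter), 300–500 reads for null-calibration
and UMI checks (amplicon-realistic depth), 1000 replicate amplicons for
the null exceedance, 100 seeded replicates for the detection-rate check,
and 200 random references × 50 reads for oracle equivalence. All
randomness flows from explicit integer seeds; the same configuration and
seed reproduce stage outputs byte for byte, and the pipeline manifest
records the seed and an MD5 checksum of every file it writes.

## Known limitations

* Single-reference, single-orientation, ungapped alignment only: the
  amplicon's primer design fixes orientation and frame, and the strict
  filters make this exhaustive — but the method is deliberately not a
  transcriptome-wide mapper.
* The de-novo detection floor (~50% stoichiometry at the default working
  point) is a property of the statistic plus site-to-site variance, not
  of read depth; MeRIP enrichment lowers it (to ~5–10% in the simulated
  harness) at the cost of all stoichiometry information.
* The probability statistic assumes enough A positions (≥ 3, realistically
  ~10+) to estimate the null distribution from the amplicon itself.
* Chemistry presets are constraint-faithful defaults, not fitted
  constants; users with calibration data for their condition should set
  `chemistry_model()` rates directly.
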