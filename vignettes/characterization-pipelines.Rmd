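---
title: "Characterization pipelines: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterization pipelines: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprkit)
```

crisprkit implements the computational layer used to characterize compact
CRISPR-Cas effectors whose hallmark activity is PAM-dependent DNA *binding*
rather than cleavage: PAM determination from a randomized plasmid library,
cleavage-site detection by adapter-junction scanning, mature crRNA boundary
mapping from small RNA-seq, interference/plating fold-change statistics,
binding kinetics from bio-layer interferometry (BLI) and magnetic tweezers,
and a minimal per-position quantifier for adenine base editing.  Every
analysis stage has a matching simulator that plants a ground truth, so the
whole pipeline closes the loop simulate → analyze → compare-to-manifest
without any external data.  This vignette explains the underlying models,
the tunable parameters, and the design decisions that were genuinely open.

## The randomized-library PAM assays

The library molecule is `flank5 + N7 + flank3`, where the 7-nt randomized
region sits immediately 5' of a fixed protospacer (the first bases of
`flank3`).  PAM positions are therefore labelled −7…−1, with −1 adjacent
to the protospacer start; reads are handled in a single fixed sequencing
orientation, matching the library design.

**Binding (restriction-protection) readout.**  Effector occupancy blocks a
restriction enzyme whose site overlaps the target, so molecules carrying a
recognized PAM survive digestion and become enriched in sequencing.  For
each PAM `p` the score is the ratio of relative frequencies

$$\mathrm{fold}(p) =
  \frac{n_{\mathrm{sel}}(p)/N_{\mathrm{sel}}}{n_{\mathrm{lib}}(p)/N_{\mathrm{lib}}},$$

normalized to the sequenced initial library to cancel synthesis bias, and
only PAMs with fold **strictly greater than 5** are retained.  Two
numerical choices matter here:

* **No pseudocounts.**  Scored folds are exact ratios.  Adding
  pseudocounts would blunt the strict >5 cut-off; instead, PAMs observed
  fewer than `min_library_count = 5` times in the library are flagged
  *unscorable* and never pass, which serves the same noise-control purpose
  (guarding against near-zero denominators) without distorting the scored
  values.
* **Strictness.**  A fold of exactly 5.0 is excluded; the filter
  implements “>5-fold”, not “≥”.

The retained set is summarized as a position frequency matrix and
per-position information content
$IC_j = 2 + \sum_b f_{jb}\log_2 f_{jb}$ (bits, in $[0,2]$), the quantity a
sequence logo draws.  Whether the matrix should weight each retained PAM
by its selected read count or once per unique PAM is not standardized; both
are implemented, the default is read-count weighting, and the choice is
recorded in the logo TSV header.  The small-sample IC correction is off by
default because enriched sets here carry thousands of observations; it is
available as an option for shallow sets.

**What the binding simulator emulates.**  A plasmid library prep contains
on the order of $10^{10}$ molecules while sequencing samples $10^5$–$10^6$
of them.  In that regime the per-PAM digestion-escape background
concentrates tightly at its expected rate; the sampling noise that matters
is sequencing-side.  `simulate_binding_assay()` therefore computes the
post-selection pool composition exactly (library bias × survival
probability, with survival `match_probability` for consensus-matching PAMs
and `mismatch_probability + escape·(1−mismatch_probability)` otherwise)
and then sequences the selected pool and the initial library
*independently* to `n_reads` each.  A finite `pool_factor` is available to
study small-pool artifacts — with a pool only ~100× the sequencing depth,
single lucky escaper molecules can masquerade as >5-fold PAMs, which is an
artifact of conflating the sequenced sample with the physical pool, not a
property of the assay.  `simulate_binding_selection()` implements the
complementary per-molecule thinning view for an explicit read set.

The empirical digestion-escape rate of the restriction step is not known;
the default `digestion_escape = 0.02` is a deliberate placeholder, exposed
as a parameter, and large enough that the >5-fold filter is doing real
work in every simulation.

**Cleavage readout.**  Cleaved molecules receive a ligated adapter;
cleavage is detected by counting, per read, the offset of the adapter's
5'-most base relative to the first protospacer base, within a 0–30 bp
window.  Offset 0 is defined as the first protospacer base.  Because
cleavage truncates the protospacer itself, the only sequence guaranteed
present in a cleaved read is the constant flank 5' of the randomized
region, so the scanner anchors there and places offset 0 at
`anchor end + pam_length`.  A sample is called *cleaved* at offset $k$
when its junction fraction reaches `min_fraction` (default 1%) **and**
exceeds `min_fold` (default 10×) times the control fraction at $k$, the
control floored at one read to keep the ratio finite.  Matched sample and
control histograms — the background-ligation pattern of a no-effector
control — reproduce the negative verdict.

## Anchored matching instead of read mapping

All assays here are amplicon-scale: reads come from one known construct.
A full read mapper is unnecessary, so the package uses anchored,
alignment-free matching throughout (`anchored_locate()`): the best
(fewest-mismatch) occurrence of a ≥8-nt anchor, ties broken to the
smallest offset with the plus strand preferred, `N` always counting as a
mismatch (conservative for enrichment statistics).  Coordinates are
0-based half-open internally and 1-based inclusive in all user-facing
reports; the only interval file emitted (BED) is 0-based half-open per the
format.  Indel-tolerant alignment and SAM/BAM output are deliberately out
of scope.

## crRNA boundary mapping

Mates are adapter-trimmed (≥6-nt adapter prefix flush with the read 3'
end, ≤1 mismatch, or an internal full-adapter hit), pairs with a trimmed
mate under 15 nt are discarded, and the remaining pairs are merged into
whole molecules by best overlap (≥10 nt, ≤2 mismatches, higher Phred
quality wins at disagreements; containment counts as overlap, which is
what full read-through of a short fragment produces).  Each distinct
molecule is placed on both strands of the reference; molecules with more
than one equally good placement, no placement within 2 mismatches, or
longer than 65 nt (not a mature small RNA) are discarded with full
accounting, so that
`pairs in = placed + merge-failed + multi-mapped + unplaced + overlong`
is user-visible in every run.  The mapping-quality filter of a
conventional mapper is replaced by this strict unique-best-placement rule:
on an amplicon-scale reference a probabilistic MAPQ model adds nothing.
Identical read pairs are collapsed before merging and re-weighted — an
algebraic no-op that keeps deep libraries fast.

Boundaries are the modal 5' and 3' end positions, ties broken toward the
longer molecule; the call carries the weaker of the two modal support
fractions and is rejected below `min_support = 0.2`.  Calls are reported
on the crRNA-encoding strand; the bundled simulators plant plus-strand
spans.  Where a processing site falls inside an annotated repeat, the
package reports the modal 5' end and its offset — it makes no claim about
the biochemical cut position.  The end-noise model is geometric: an end is
exact with probability `end_noise_p` (default 0.8) and otherwise displaced
by a geometric number of nucleotides in a random direction; real
end-processing heterogeneity need not be symmetric, which is one reason
modal (not mean) ends are used.

A tracrRNA is excluded by scanning candidate regions for anti-repeat
complementarity: 12-nt windows whose reverse complement occurs in the
repeat with ≤1 mismatch, merged into runs.  A longer complementary
stretch necessarily contains a passing window, so an empty result is a
sound exclusion; the per-window false-positive rate for exact matches is
$\approx L_\mathrm{repeat} \cdot 4^{-12}$.

## Interference and plating statistics

Fold change is defined exactly as in standard efficiency-of-plating
practice:
$\mathrm{fold} = \overline{T}_\mathrm{condition} / \overline{T}_\mathrm{control}$
on replicate titers (titer = count × dilution factor); with PFU units this
is the EOP.  Two conventions required decisions:

* **Zero-plaque rule.**  A replicate with no plaques or clearings at any
  dilution is assigned a count of 1 at its most concentrated dilution, so
  every titer — and hence every EOP — is finite and positive.
* **Countable-dilution rule.**  When several dilutions of a replicate are
  countable, the dilution whose raw count lies in [3, 300] and is nearest
  30 is used (standard plaque-counting practice; the choice is otherwise
  under-determined).  Folds are computed on titers, not raw spot counts,
  and the choice is recorded in the output metadata.

No confidence intervals or hypothesis tests are attached: these assays are
run in biological triplicate and reported as means; replicate titers are
echoed so users can apply their own inference.

## Binding kinetics and R-loop twist

**BLI dissociation.**  After reference-trace subtraction (pointwise, on
nearest-neighbour-aligned time grids), the dissociation phase is fitted to
$R_0 e^{-k_\mathrm{off} t}$ by Levenberg–Marquardt with $R_0$ free —
forcing $R_0 = 1$ would make the estimate sensitive to baseline offsets
that survive reference subtraction.  Because a "50% dissociated in two
hours" statement can reflect either a fit or an endpoint ratio, the
analytic estimate $k = -\ln(R_\mathrm{end}/R_0)/\Delta t$ is always
reported alongside; the two agree within 1% on clean single-exponential
data, and a half-life of 120 min corresponds to
$k = \ln 2/120 \approx 0.0058 \approx 0.006\ \mathrm{min}^{-1}$.  A
perfectly flat trace defeats the fit's gradient; the analytic estimate
(zero) is returned in that degenerate case.

**Magnetic tweezers.**  The rotation–extension curve of a torsionally
constrained DNA at low force is a symmetric hat; R-loop formation unwinds
the duplex locally and shifts the curve toward negative turns by
(R-loop bp)/(helical pitch).  The apex of each curve is located by a
quadratic fit over the points in the top 30% of extension values — a
naive argmax is defeated by the flat plateau under noise, while the
quadratic vertex is exact for symmetric noiseless data and robust at the
5-nm noise level used in the recovery tests.  The shift is
`apex(post) − apex(pre)`, antisymmetric by construction, and converts to
R-loop size as $|\Delta\mathrm{turns}| \times 10.5$ bp.  The pitch is the
B-DNA standard 10.5 bp/turn, exposed as a parameter since the appropriate
value is never stated in this kind of experiment; a 20-bp R-loop thus
corresponds to ~1.9 turns, i.e. the familiar "~2 turns" at integer
resolution.

## Base-editing quantification

Amplicon reads are placed on the reference in both orientations with a
mismatch budget of 10% per read and **no gapped alignment**: adenine base
editors introduce substitutions, so indel-containing reads are discarded
(and tallied) rather than realigned.  At each protospacer position
(numbered 1…20 from the PAM-proximal end) the base counts are tabulated;
the A→G frequency is defined only at reference-A positions, with non-A
positions flagged rather than scored.  The sequencing-error floor is
deliberately not subtracted — the unedited-control profile is reported
alongside instead — and the editing window is summarized as the positions
reaching at least half the maximum observed frequency.  This quantifier is
transparent and substitution-only by design; it does not attempt numeric
parity with full-featured editing-analysis suites on real (indel-bearing)
data.

## Simulators, determinism and FASTQ conventions

Every simulator draws from its own generator seeded from its
configuration, so a fixed seed yields byte-identical output; seeds are
recorded in the ground-truth manifest written next to the reads.  Read
tibbles carry the molecule's true PAM (or the planted span/profile in the
manifest) so downstream recovery can be asserted exactly.  Sequencing
errors are iid substitutions — no indels, no PCR-amplification bias, no
quality miscalibration — and qualities are constant Q37 (Phred+33) unless
an error model is active, in which case Q = −10·log₁₀(p) rounded.  With
all noise and selection parameters at neutral values every estimator
returns its identity/null result, and the test suite checks that closed
loop module by module.

Passing tests on these simulations demonstrate correctness of the
*computational* procedures under the stated noise models; they do not
certify behavior on real libraries, whose error structure (context-
dependent errors, chimeras, PCR jackpots, ligation biases) is richer than
anything generated here.

## Problem sizes used by the test suite

The packaged checks run the binding pipeline at 2×10⁵ reads per library
(the depth at which all 64 consensus-matching PAMs of a TTTC model are
scorable and recovered exclusively), cleavage scans at 5×10⁴ reads,
exhaustive-recount oracle comparisons at 10⁴ reads, boundary recovery at
10⁴ read pairs over 20 seeds, and editing recovery at 2×10⁴ reads —
sizes chosen so each property is measured at the scale where its expected
statistical margin is comfortable.

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7, n_reads = 200000)
mdl <- pam_model("binding", "TTTCNNN",
                 match_probability = 0.95, mismatch_probability = 0.01)
sim <- simulate_binding_assay(cfg, mdl)
res <- run_pam_bind(sim$selected, sim$library, cfg$flank5, cfg$flank3)
res$passing                     # the >5-fold PAM set
information_content(res$pfm)    # logo heights in bits
```

## Known limitations

* Minus-strand-encoded crRNAs are placed correctly but boundary calls
  assume the mature RNA runs 5'→3' along increasing reference
  coordinates.
* The overlap merger requires a unique best overlap; highly repetitive
  fragments are conservatively dropped as ambiguous.
* The cleavage simulator models blunt ligation at a single offset (±1 bp
  optional jitter); staggered cuts with long overhangs would need a
  two-offset model.
* `interference` fold changes inherit the replicate structure given to
  them; no blocking or batch model is applied.
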