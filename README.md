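# crisprkit

Tidy R pipelines for characterizing compact CRISPR-Cas effectors whose
hallmark activity is PAM-dependent DNA **binding** rather than cleavage.
The package implements, as tested reusable functions, the complete
computational layer of such a characterization study:

* **PAM determination** from a 7-nt randomized plasmid library read out by
  restriction protection: per-PAM enrichment
  `fold(p) = (n_sel(p)/N_sel) / (n_lib(p)/N_lib)` normalized to the
  sequenced initial library, the strict **>5-fold** retention filter, and
  position-frequency / information-content matrices
  (`IC_j = 2 + Σ_b f_jb log2 f_jb` bits) for sequence logos.
* **Cleavage detection** by adapter-junction scanning in the 0–30 bp
  window next to the randomized region, with a fold-over-control verdict
  that reproduces both positive calls and the negative (no-cleavage)
  result pattern.
* **Mature crRNA boundary mapping** from small RNA-seq read pairs:
  adapter trimming, the <15 nt pair filter, overlap merging into whole
  molecules (≤65 nt), unique anchored placement, modal 5'/3' end calling,
  and an anti-repeat scan that excludes a tracrRNA.
* **Interference / plating statistics**: replicate titers with the
  zero-plaque rule ("no plaques at any dilution" counts as 1 PFU), and
  `fold = mean(condition) / mean(control)` — the EOP for phage assays.
* **Binding kinetics**: single-exponential BLI dissociation fits
  (`R0·exp(−k_off·t)`, analytic endpoint estimate reported alongside) and
  magnetic-tweezers rotation-curve shifts converted to R-loop size via
  `bp = |Δturns| × 10.5`.
* **Base-editing quantification**: a minimal substitution-only A→G
  profiler over the protospacer (position 1 = PAM-proximal), with the
  half-maximum editing window.

Every analysis stage has a matching **simulator with a planted
ground-truth manifest** (`sim_config()`, `pam_model()`,
`simulate_binding_assay()`, `simulate_cleavage_reads()`,
`simulate_small_rna_reads()`, `simulate_sensorgram()`,
`simulate_rotation_curves()`, `simulate_amplicon_reads()`), so the entire
pipeline is testable end to end without any external data.  All
user-facing functions take and return tibbles, fitted objects support
`tidy()`/`glance()`, and result types have `autoplot()` methods.

## Worked example: recovering a planted PAM

```r
library(crisprkit)

cfg <- sim_config(seed = 7, n_reads = 200000)
mdl <- pam_model("binding", "TTTCNNN",
                 match_probability = 0.95, mismatch_probability = 0.01)
sim <- simulate_binding_assay(cfg, mdl)
res <- run_pam_bind(sim$selected, sim$library, cfg$flank5, cfg$flank3)
#> selected: 200000 reads counted, 0 discarded; library: 200000 counted, 0 discarded
#> 64 / 16266 scored PAMs pass the >5-fold filter

head(res$enrichment, 3)
#> # A tibble: 3 × 5
#>   pam     selected_count library_count unscorable enrichment_fold
#> 1 TTTCCTT            356             5 FALSE                 71.2
#> 2 TTTCCAT            337             6 FALSE                 56.2
#> 3 TTTCAGG            319             6 FALSE                 53.2

round(information_content(res$pfm), 3)
#> [1] 2 2 2 2 0 0 0
```

All 64 PAMs passing the >5-fold filter carry the planted `TTTC` prefix
(the 7-mer space holds 16 384 PAMs; 64 match `TTTCNNN`), and the logo
shows 2 bits at the four consensus positions and 0 bits at the three
degenerate ones.

The kinetic worked values print as:

```r
fit_dissociation(simulate_sensorgram(k_off = log(2)/120, t_dissoc = 120))
#> k_off = 0.005776 /min (analytic 0.005776 /min), R0 = 0.992, RMS 7.02e-17, n = 600

sh <- rotation_shift(simulate_rotation_curves(20))
#> shift = -1.901 turns
rloop_size(sh)
#> [1] 19.95976
```

A complex that is 50% dissociated after two hours corresponds to
`k_off = ln2/120 ≈ 0.006 min⁻¹`, and a 20-bp R-loop shifts the rotation
curve by ~2 turns at 10.5 bp/turn.

A thin command-line wrapper over the same workflows ships in
`inst/cli/crisprkit.R` (subcommands `simulate`, `pam-bind`, `pam-cleave`,
`crrna`, `interference`, `kinetics`, `editing`; flat YAML configs; exit
codes 0/1/2).

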