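cfg0 <- sim_config()   # default flanks shared across fixtures

test_that("PAM extraction counts anchored reads and discards the rest", {
  mk <- function(pam) paste0(cfg0$flank5, pam, cfg0$flank3)
  reads <- c(mk("TTTCAAA"), mk("TTTCAAA"), mk("GGGGGGG"))
  pc <- extract_pams(reads, cfg0$flank5, cfg0$flank3)
  expect_equal(sort(pc$pam), c("GGGGGGG", "TTTCAAA"))
  expect_equal(pc$count[pc$pam == "TTTCAAA"], 2)
  expect_equal(attr(pc, "total"), 3)

  # anchor absent and N in PAM are both discarded, total unchanged
  reads2 <- c(reads, random_seq(60), mk("TTNCAAA"))
  pc2 <- extract_pams(reads2, cfg0$flank5, cfg0$flank3)
  expect_equal(attr(pc2, "total"), 3)
  expect_equal(attr(pc2, "n_reads_discarded"), 2)
})

test_that("PAM extraction equals the exhaustive brute-force recount", {
  cfg <- sim_config(seed = 17, n_reads = 3000, sequencing_error = 0.01)
  lib <- simulate_initial_library(cfg)
  pc <- extract_pams(lib$reads, cfg$flank5, cfg$flank3)
  oracle <- brute_extract(lib$reads$sequence, cfg$flank5, cfg$flank3)
  expect_equal(attr(pc, "total"), oracle$total)
  expect_equal(attr(pc, "n_reads_discarded"), oracle$discarded)
  got <- setNames(pc$count, pc$pam)
  want <- oracle$counts
  expect_equal(sort(names(got)), sort(names(want)))
  expect_equal(as.integer(got[names(want)]), as.integer(want))
})

test_that("enrichment is the frequency ratio and is scale-invariant", {
  sel <- make_pam_counts(c(TTTCAAA = 20, AAAAAAA = 2, GGGGGGG = 978))
  lib <- make_pam_counts(c(TTTCAAA = 2, AAAAAAA = 20, GGGGGGG = 978))
  e <- compute_enrichment(sel, lib, min_library_count = 1)
  expect_equal(e$enrichment_fold[e$pam == "TTTCAAA"], 10)
  expect_equal(e$enrichment_fold[e$pam == "AAAAAAA"], 0.1)

  same <- compute_enrichment(lib, lib, min_library_count = 1)
  expect_true(all(same$enrichment_fold == 1))

  sel10 <- make_pam_counts(c(TTTCAAA = 200, AAAAAAA = 20, GGGGGGG = 9780))
  lib10 <- make_pam_counts(c(TTTCAAA = 20, AAAAAAA = 200, GGGGGGG = 9780))
  e10 <- compute_enrichment(sel10, lib10, min_library_count = 1)
  expect_equal(e10$enrichment_fold, e$enrichment_fold)

  expect_error(compute_enrichment(make_pam_counts(c(AAAAAAA = 0)), lib),
               "no surviving reads")
})

test_that("rare library PAMs are flagged unscorable, never passed", {
  sel <- make_pam_counts(c(TTTCAAA = 500, CCCCCCC = 500))
  lib <- make_pam_counts(c(TTTCAAA = 500, CCCCCCC = 2, AAAAAAA = 498))
  e <- compute_enrichment(sel, lib, min_library_count = 5)
  expect_true(e$unscorable[e$pam == "CCCCCCC"])
  expect_true(is.na(e$enrichment_fold[e$pam == "CCCCCCC"]))
  expect_false("CCCCCCC" %in% filter_enriched(e, 2))
})

test_that("the enrichment filter is a strict inequality", {
  sel <- make_pam_counts(c(TTTCAAA = 50, AAAAAAA = 950))
  lib <- make_pam_counts(c(TTTCAAA = 10, AAAAAAA = 990))
  e <- compute_enrichment(sel, lib)
  f <- e$enrichment_fold[e$pam == "TTTCAAA"]
  expect_equal(f, 5)                       # constructed to sit on the line
  expect_false("TTTCAAA" %in% filter_enriched(e, 5))
  expect_true("TTTCAAA" %in% filter_enriched(e, 4.999))
  empty <- compute_enrichment(sel, lib)
  expect_length(filter_enriched(empty[0, ], 5), 0)
})

test_that("position frequency matrices and information content are exact", {
  pfm1 <- build_pfm("TTTCAAA")
  expect_equal(pfm1$T[1:3], c(1, 1, 1))
  expect_equal(information_content(pfm1), rep(2, 7))
  expect_equal(pfm1$position, -7:-1)

  pfm2 <- build_pfm(c("TTAAAAA", "TTCAAAA"), weighting = "unique_pam")
  expect_equal(pfm2$T[1:2], c(1, 1))
  expect_equal(pfm2$A[3], 0.5)
  expect_equal(pfm2$C[3], 0.5)
  expect_equal(information_content(pfm2)[3], 1)

  pfm3 <- build_pfm(c("AAAAAAA", "CCCCCCC", "GGGGGGG", "TTTTTTT"),
                    weighting = "unique_pam")
  expect_equal(information_content(pfm3), rep(0, 7))

  # read-count weighting: 3:1 on first base
  pfm4 <- build_pfm(c("ATTTTTT", "CTTTTTT"), weights = c(3, 1))
  expect_equal(pfm4$A[1], 0.75)

  set.seed(71)
  rand <- replicate(50, paste(sample(DNA, 7, replace = TRUE), collapse = ""))
  pfm5 <- build_pfm(rand, weights = sample(1:20, 50, replace = TRUE))
  expect_true(all(abs(rowSums(as.matrix(pfm5[, DNA])) - 1) < 1e-9))
  ic <- information_content(pfm5)
  expect_true(all(ic >= 0 & ic <= 2))
})

test_that("junction scanning matches the brute-force recount and window", {
  cfg <- sim_config(seed = 19, n_reads = 2000, sequencing_error = 0.005)
  mdl <- pam_model("cleavage", "NNNNNNN", match_probability = 0.5,
                   cut_offset = 18)
  sim <- simulate_cleavage_reads(mdl, cfg)
  h <- scan_adapter_junctions(sim$reads, cfg$adapter, cfg$flank5)
  oracle <- brute_junctions(sim$reads$sequence, cfg$adapter, cfg$flank5)
  expect_equal(h$count, as.integer(oracle))
  expect_equal(h$offset[which.max(h$count)], 18)

  # a junction beyond the 0-30 window is ignored
  far <- paste0(cfg0$flank5, "ACGTACG",
                paste(rep("A", 35), collapse = ""), cfg0$adapter)
  h2 <- scan_adapter_junctions(far, cfg0$adapter, cfg0$flank5)
  expect_equal(sum(h2$count), 0)
  expect_error(
    scan_adapter_junctions("ACGT", substr(cfg0$flank5, 3, 14), cfg0$flank5),
    "substring")
})

test_that("cleavage verdicts separate planted cuts from background", {
  cfg <- sim_config(seed = 23, n_reads = 5000)
  cut <- simulate_cleavage_reads(
    pam_model("cleavage", "NNNNNNN", match_probability = 0.5, cut_offset = 7), cfg)
  inert <- simulate_cleavage_reads(
    pam_model("inert", background_ligation = 0.001),
    sim_config(seed = 29, n_reads = 5000))
  hs <- scan_adapter_junctions(cut$reads, cfg$adapter, cfg$flank5)
  hc <- scan_adapter_junctions(inert$reads, cfg$adapter, cfg$flank5)
  v <- call_cleavage(hs, hc)
  expect_true(v$cleaved)
  expect_equal(v$offset, 7)

  expect_false(call_cleavage(hc, hc)$cleaved)      # sample == control
  empty <- scan_adapter_junctions(character(), cfg$adapter, cfg$flank5)
  expect_false(call_cleavage(empty, hc)$cleaved)
  expect_output(print(v), "cleaved at offset 7")
})

test_that("neutral selection leaves almost nothing above the fold filter", {
  cfg <- sim_config(seed = 31, n_reads = 100000)
  neutral <- pam_model("binding", "NNNNNNN", match_probability = 0.9,
                       mismatch_probability = 0.9)
  sim <- simulate_binding_assay(cfg, neutral)
  res <- run_pam_bind(sim$selected, sim$library, cfg$flank5, cfg$flank3,
                      quiet = TRUE)
  frac <- length(res$passing) / max(1, sum(!res$enrichment$unscorable))
  expect_lte(frac, 0.001)
})

test_that("a planted TTN consensus is recovered in the logo", {
  cfg <- sim_config(seed = 37, n_reads = 100000)
  mdl <- pam_model("binding", "TTNNNNN", match_probability = 0.9,
                   mismatch_probability = 0.01)
  sim <- simulate_binding_assay(cfg, mdl)
  res <- run_pam_bind(sim$selected, sim$library, cfg$flank5, cfg$flank3,
                      quiet = TRUE)
  expect_true(all(startsWith(res$passing, "TT")))
  expect_true(all(res$pfm$T[1:2] > 0.9))
  ic <- information_content(res$pfm)
  expect_true(all(ic[1:2] >= 1.5))
  expect_true(all(ic[3:7] <= 0.2))
})
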