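test_that("simulators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 11, n_reads = 500)
  expect_identical(simulate_initial_library(cfg), simulate_initial_library(cfg))
  mdl <- pam_model("cleavage", "NNNNNNN", match_probability = 0.4, cut_offset = 9)
  expect_identical(simulate_cleavage_reads(mdl, cfg),
                   simulate_cleavage_reads(mdl, cfg))
  ref <- with_seed_seq(21, 400)
  expect_identical(
    simulate_small_rna_reads(ref, c(101, 152), cfg),
    simulate_small_rna_reads(ref, c(101, 152), cfg))
  expect_identical(simulate_sensorgram(noise_sd = 0.01, seed = 5),
                   simulate_sensorgram(noise_sd = 0.01, seed = 5))
  expect_identical(simulate_rotation_curves(21, noise_sd = 5, seed = 5),
                   simulate_rotation_curves(21, noise_sd = 5, seed = 5))
})

test_that("uniform-bias libraries are uniform over the PAM space", {
  cfg <- sim_config(seed = 1, n_reads = 163840)
  lib <- simulate_initial_library(cfg)
  counts <- table(factor(lib$reads$pam, levels = all_kmers(7)))
  expect_equal(sum(counts), 163840)
  p <- suppressWarnings(stats::chisq.test(as.vector(counts))$p.value)
  expect_gt(p, 0.01)
})

test_that("degenerate bias, empty libraries and short reads are handled", {
  bias <- matrix(rep(c(0, 0, 0, 1), each = 7), nrow = 7,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  cfg <- sim_config(seed = 2, n_reads = 200, library_bias = bias)
  lib <- simulate_initial_library(cfg)
  pc <- extract_pams(lib$reads, cfg$flank5, cfg$flank3)
  expect_identical(pc$pam, "TTTTTTT")
  expect_equal(attr(pc, "total"), 200)

  empty <- simulate_initial_library(sim_config(seed = 3, n_reads = 0))
  expect_equal(nrow(empty$reads), 0)
  expect_s3_class(empty$manifest, "ground_truth")

  expect_error(simulate_initial_library(sim_config(read_length = 20)),
               "read_length")
  expect_error(sim_config(digestion_escape = 1.5), "probabilities")
  badbias <- bias; badbias[1, ] <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(sim_config(library_bias = badbias), "sum to 1")
})

test_that("binding selection is deterministic at the probability extremes", {
  cfg <- sim_config(seed = 4, n_reads = 4000, digestion_escape = 0)
  lib <- simulate_initial_library(cfg)
  mdl <- pam_model("binding", "TTNNNNN", match_probability = 1,
                   mismatch_probability = 0)
  sel <- simulate_binding_selection(lib$reads, mdl, cfg)
  expect_true(all(startsWith(sel$pam, "TT")))
  expect_equal(nrow(sel), sum(startsWith(lib$reads$pam, "TT")))
})

test_that("selection-free limit preserves PAM frequencies", {
  cfg <- sim_config(seed = 5, n_reads = 20000, digestion_escape = 0)
  lib <- simulate_initial_library(cfg)
  mdl <- pam_model("binding", "TTNNNNN", match_probability = 0.6,
                   mismatch_probability = 0.6)
  sel <- simulate_binding_selection(lib$reads, mdl, cfg)
  # base composition at each PAM position should match the input closely
  f_in <- mean(substr(lib$reads$pam, 1, 1) == "A")
  f_out <- mean(substr(sel$pam, 1, 1) == "A")
  se <- sqrt(f_in * (1 - f_in) / nrow(sel))
  expect_lt(abs(f_out - f_in), 4 * se)
  expect_equal(nrow(sel) / nrow(lib$reads), 0.6, tolerance = 0.05)
})

test_that("cleavage reads carry the adapter exactly as planted", {
  cfg <- sim_config(seed = 6, n_reads = 300)
  sat <- pam_model("cleavage", "NNNNNNN", match_probability = 1, cut_offset = 12)
  sim <- simulate_cleavage_reads(sat, cfg)
  n_occ <- lengths(gregexpr(cfg$adapter, sim$reads$sequence, fixed = TRUE))
  expect_true(all(n_occ == 1))
  pos <- as.integer(gregexpr(cfg$adapter, sim$reads$sequence, fixed = TRUE))
  expect_true(all(pos == nchar(cfg$flank5) + 7 + 12 + 1))

  inert <- simulate_cleavage_reads(pam_model("inert"), cfg)
  h <- scan_adapter_junctions(inert$reads, cfg$adapter, cfg$flank5)
  expect_true(all(h$count == 0))
  expect_error(pam_model("cleavage", cut_offset = 31), "0, 30")
})

test_that("small-RNA pairs reconstruct the planted fragment", {
  ref <- with_seed_seq(31, 600)
  cfg <- sim_config(seed = 7, n_reads = 50, read_length = 75)
  sim <- simulate_small_rna_reads(ref, c(201, 240), cfg, end_noise_p = 1)
  frag <- substr(ref, 201, 240)
  # 40-nt fragment with 75-nt reads: both mates read through into adapter
  expect_true(all(substr(sim$r1$sequence, 41, 46) == substr(cfg$adapter, 1, 6)))
  expect_true(all(substr(sim$r2$sequence, 41, 46) == substr(cfg$adapter, 1, 6)))
  trimmed <- trim_and_filter(sim$r1, sim$r2, cfg$adapter)
  m <- merge_read_pair(trimmed$r1[1, ], trimmed$r2[1, ])
  expect_identical(m$sequence, frag)
  expect_error(simulate_small_rna_reads(ref, c(590, 620), cfg), "within")
})

test_that("sensorgram phases follow their closed forms", {
  s <- simulate_sensorgram(k_obs = 1, k_off = 0, t_assoc = 10, t_dissoc = 30)
  d <- s[s$phase == "dissociation", ]
  expect_equal(diff(range(d$response)), 0)
  s2 <- simulate_sensorgram(k_off = log(2) / 120, t_dissoc = 120)
  d2 <- s2[s2$phase == "dissociation", ]
  expect_equal(d2$response[nrow(d2)] / d2$response[1], 0.5, tolerance = 0.01)
})

test_that("rotation curves plant the stated twist shift", {
  rc0 <- simulate_rotation_curves(0)
  expect_identical(rc0$extension[rc0$curve == "pre"],
                   rc0$extension[rc0$curve == "post"])
  expect_equal(attr(simulate_rotation_curves(21), "planted_shift"), -2)
  expect_equal(attr(simulate_rotation_curves(20), "planted_shift"), -20 / 10.5)
})

test_that("amplicon simulator plants per-position conversions exactly", {
  ref <- amplicon_ref(paste0("CCGTTTC", "TACGTAACCGGTTAACCGGT", "GGCCTTAA"),
                      protospacer = c(8, 27), pam = c(1, 7))
  prof <- rep(0, nchar(ref$sequence))
  sim0 <- simulate_amplicon_reads(ref, prof, 50, seed = 8)
  expect_true(all(sim0$reads$sequence == ref$sequence))
  prof[9] <- 1                     # certain conversion at an A
  sim1 <- simulate_amplicon_reads(ref, prof, 50, seed = 9)
  expect_true(all(substr(sim1$reads$sequence, 9, 9) == "G"))
  bad <- rep(0, nchar(ref$sequence)); bad[8] <- 0.5   # reference T
  expect_error(simulate_amplicon_reads(ref, bad, 10), "non-A")
})

test_that("manifests round-trip through JSON", {
  cfg <- sim_config(seed = 10, n_reads = 10)
  lib <- simulate_initial_library(cfg)
  f <- withr::local_tempfile(fileext = ".json")
  write_manifest(lib$manifest, f)
  back <- read_manifest(f)
  expect_equal(back$kind, "initial_library")
  expect_equal(back$n_reads, 10)
})
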