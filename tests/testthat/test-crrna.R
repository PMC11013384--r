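adapter <- sim_config()$adapter

test_that("adapter trimming and the 15-nt length filter follow the rules", {
  body <- "ACGTACGTACGTACGTACGT"                 # 20 nt
  r1 <- tibble::tibble(id = "a", sequence = paste0(body, adapter),
                       quality = strrep("F", 20 + nchar(adapter)))
  r2 <- tibble::tibble(id = "a", sequence = body, quality = strrep("F", 20))
  tr <- trim_and_filter(r1, r2, adapter)
  expect_identical(tr$r1$sequence, body)         # full adapter removed
  expect_identical(tr$r2$sequence, body)         # adapter-free read unchanged
  expect_equal(tr$n_discarded, 0)

  # a partial adapter prefix at the 3' end is also removed
  r3 <- tibble::tibble(id = "b",
                       sequence = paste0(body, substr(adapter, 1, 8)),
                       quality = strrep("F", 28))
  tr3 <- trim_and_filter(r3, r2, adapter)
  expect_identical(tr3$r1$sequence, body)

  # trimming to 14 nt discards the pair
  short <- tibble::tibble(id = "c", sequence = paste0(substr(body, 1, 14), adapter),
                          quality = strrep("F", 14 + nchar(adapter)))
  tr4 <- trim_and_filter(short, r2, adapter)
  expect_equal(nrow(tr4$r1), 0)
  expect_equal(tr4$n_discarded, 1)
})

test_that("molecules place uniquely or are discarded with full accounting", {
  set.seed(501)
  left <- random_seq(200); mol <- random_seq(40); mid <- random_seq(150)
  ref_unique <- paste0(left, mol, mid)
  ref_dup <- paste0(left, mol, mid, mol, random_seq(60))

  pair <- function(m) list(
    r1 = tibble::tibble(id = "p", sequence = m, quality = strrep("F", nchar(m))),
    r2 = tibble::tibble(id = "p", sequence = revcomp_oracle(m),
                        quality = strrep("F", nchar(m))))

  p <- pair(mol)
  pl <- map_unique(p$r1, p$r2, ref_unique)
  expect_equal(nrow(pl), 1)
  expect_equal(pl$start, 201)
  expect_equal(pl$end, 240)
  expect_equal(pl$strand, "+")

  pl2 <- map_unique(p$r1, p$r2, ref_dup)
  expect_equal(nrow(pl2), 0)
  expect_equal(unname(attr(pl2, "accounting")["multi_mapped"]), 1)

  # reverse-strand placement is reported on forward coordinates
  prc <- pair(revcomp_oracle(mol))
  pl3 <- map_unique(prc$r1, prc$r2, ref_unique)
  expect_equal(pl3$strand, "-")
  expect_equal(c(pl3$start, pl3$end), c(201, 240))

  # molecules longer than the mature-RNA bound are dropped
  long <- substr(ref_unique, 101, 170)           # 70 nt
  p4 <- pair(long)
  pl4 <- map_unique(p4$r1, p4$r2, ref_unique)
  expect_equal(unname(attr(pl4, "accounting")["overlong"]), 1)
})

test_that("pair accounting is conserved through mapping", {
  ref <- with_seed_seq(502, 800)
  cfg <- sim_config(seed = 43, n_reads = 400, read_length = 75)
  sim <- simulate_small_rna_reads(ref, c(301, 352), cfg, end_noise_p = 0.7)
  tr <- trim_and_filter(sim$r1, sim$r2, cfg$adapter)
  pl <- map_unique(tr$r1, tr$r2, ref)
  acc <- attr(pl, "accounting")
  expect_equal(unname(acc["pairs_in"]),
               unname(acc["placed"] + acc["merge_failed"] + acc["overlong"] +
                        acc["multi_mapped"] + acc["unplaced"]))
  expect_equal(sum(pl$weight), unname(acc["placed"]))
})

test_that("boundary calls take modal ends with the longer-molecule tie-break", {
  mk_profile <- function(pos, five, three) {
    structure(tibble::tibble(position = pos, five_prime = five,
                             three_prime = three),
              class = c("end_profile", "tbl_df", "tbl", "data.frame"),
              n_molecules = sum(five))
  }
  prof <- mk_profile(c(1001, 1050, 1052), c(10, 0, 0), c(0, 5, 5))
  call <- call_boundaries(prof)
  expect_equal(call$three_prime, 1052)            # tie resolved to longer
  expect_equal(call$five_prime, 1001)
  expect_equal(call$mature_length, 52)
  expect_equal(call$support_fraction, 0.5)

  # uniform scatter of ends gives no confident call
  scatter <- mk_profile(1:50, rep(1, 50), rep(1, 50))
  expect_null(call_boundaries(scatter, min_support = 0.2))
})

test_that("noiseless simulation recovers the planted span exactly", {
  ref <- with_seed_seq(503, 1500)
  cfg <- sim_config(seed = 47, n_reads = 300, read_length = 75)
  sim <- simulate_small_rna_reads(ref, c(1001, 1052), cfg, end_noise_p = 1)
  res <- run_crrna(sim$r1, sim$r2, ref, cfg$adapter, quiet = TRUE)
  expect_equal(res$call$five_prime, 1001)
  expect_equal(res$call$three_prime, 1052)
  expect_equal(res$call$mature_length, 52)
  expect_equal(res$call$support_fraction, 1)
  expect_equal(tidy(res$call)$mature_length, 52)
})

test_that("anti-repeat scanning finds planted complementarity only", {
  set.seed(504)
  repeat_seq <- "GTTGCAGAACCCGAATAGACGAATGAAGGAATGCAAC"
  anti <- revcomp_oracle(substr(repeat_seq, 10, 23))     # 14-nt anti-repeat
  region <- paste0(random_seq(100), anti, random_seq(80))
  hits <- anti_repeat_scan(region, repeat_seq)
  expect_gte(nrow(hits), 1)
  expect_true(any(hits$start <= 101 & hits$end >= 114))

  # the repeat itself (sense orientation) shows no complementarity
  expect_equal(nrow(anti_repeat_scan(repeat_seq, repeat_seq)), 0)

  # a random 500-mer has no exact 12-nt complementarity (4^-12 per window)
  rand <- with_seed_seq(505, 500)
  expect_equal(nrow(anti_repeat_scan(rand, repeat_seq, max_mismatch = 0)), 0)
})

test_that("boundary BED output uses 0-based half-open coordinates", {
  call <- structure(list(five_prime = 1001, three_prime = 1052,
                         mature_length = 52, support_fraction = 0.9),
                    class = "boundary_call")
  f <- withr::local_tempfile(fileext = ".bed")
  write_boundary_bed(call, f, "plasmid")
  parts <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(parts[1:3], c("plasmid", "1000", "1052"))
})
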