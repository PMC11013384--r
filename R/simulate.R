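#' Simulation configuration for the randomized-PAM library assays
#'
#' Bundles the constant sequence context of the plasmid library (a fixed
#' 5' flank, a randomized PAM region, and the fixed target/flank on its 3'
#' side), the ligation adapter, the per-position base-composition bias of
#' the synthesized library, and the noise model.  The defaults describe a
#' 7-nt fully randomized region read out by 1x80 nt single-end sequencing.
#'
#' @param seed Integer seed; every simulator draws from its own generator
#'   seeded with this value, so a fixed seed gives byte-identical output.
#' @param n_reads Number of reads (or read pairs) to simulate.
#' @param read_length Read length in nt.
#' @param pam_length Length of the randomized PAM region (nt).
#' @param flank5,flank3 Constant sequences 5' and 3' of the randomized
#'   region.  `flank3` begins with the protospacer (the crRNA target), so
#'   PAM positions are labelled -pam_length..-1 with -1 adjacent to the
#'   protospacer start.
#' @param adapter Ligation adapter sequence used by the cleavage assay and
#'   the small-RNA library prep.
#' @param library_bias `pam_length x 4` matrix of per-position base weights
#'   (columns A,C,G,T; rows sum to 1).  Default uniform.
#' @param digestion_escape Probability that an unbound molecule escapes
#'   restriction digestion and survives the protection selection anyway
#'   (incomplete-digestion background).
#' @param sequencing_error Per-base substitution probability.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_reads = 10000L,
                       read_length = 80L,
                       pam_length = 7L,
                       flank5 = "TGTGACCGTCTCCGGGAGCT",
                       flank3 = "GACTTCGGTCTAGCAACTGACTGATCCAGTTTGAGAGTT",
                       adapter = "AGATCGGAAGAGCACACGTC",
                       library_bias = NULL,
                       digestion_escape = 0.02,
                       sequencing_error = 0) {
  if (is.null(library_bias)) {
    library_bias <- matrix(0.25, nrow = pam_length, ncol = 4,
                           dimnames = list(NULL, BASES))
  }
  cfg <- structure(
    list(seed = as.integer(seed), n_reads = as.integer(n_reads),
         read_length = as.integer(read_length),
         pam_length = as.integer(pam_length),
         flank5 = flank5, flank3 = flank3, adapter = adapter,
         library_bias = library_bias,
         digestion_escape = digestion_escape,
         sequencing_error = sequencing_error),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$pam_length >= 1L, cfg$n_reads >= 0L)
  for (p in c(cfg$digestion_escape, cfg$sequencing_error)) {
    if (!is.finite(p) || p < 0 || p > 1) abort("probabilities must lie in [0,1]")
  }
  b <- cfg$library_bias
  if (!is.matrix(b) || nrow(b) != cfg$pam_length || ncol(b) != 4L) {
    abort("library_bias must be a pam_length x 4 matrix")
  }
  if (any(b < 0) || any(abs(rowSums(b) - 1) > 1e-9)) {
    abort("library_bias rows must be non-negative and sum to 1")
  }
  for (s in c(cfg$flank5, cfg$flank3, cfg$adapter)) {
    if (grepl("[^ACGT]", s)) abort("flanks and adapter must be over A,C,G,T")
  }
  invisible(cfg)
}

#' PAM recognition model for binding / cleavage simulations
#'
#' @param mode `"binding"`, `"cleavage"` or `"inert"`.
#' @param consensus Consensus over `A,C,G,T,N` (N = any base), length equal
#'   to the randomized region.
#' @param match_probability Probability that a consensus-matching molecule
#'   is bound (binding mode) or cleaved (cleavage mode).
#' @param mismatch_probability The same probability for non-matching
#'   molecules; must not exceed `match_probability`.
#' @param cut_offset Cleavage position in bp from the protospacer start
#'   (0-30; cleavage mode only).
#' @param background_ligation Random-ligation background rate for inert
#'   simulations (probability a molecule acquires an adapter at a uniform
#'   offset in 0-30).
#' @return A `pam_model` list.
#' @export
pam_model <- function(mode = c("binding", "cleavage", "inert"),
                      consensus = "NNNNNNN",
                      match_probability = 1,
                      mismatch_probability = 0,
                      cut_offset = NULL,
                      background_ligation = 0) {
  mode <- match.arg(mode)
  if (grepl("[^ACGTN]", consensus)) abort("consensus must be over A,C,G,T,N")
  if (mismatch_probability > match_probability) {
    abort("match_probability must be >= mismatch_probability")
  }
  if (mode == "cleavage") {
    if (is.null(cut_offset) || cut_offset < 0 || cut_offset > 30) {
      abort("cleavage mode requires cut_offset in [0, 30]")
    }
  }
  structure(list(mode = mode, consensus = consensus,
                 match_probability = match_probability,
                 mismatch_probability = mismatch_probability,
                 cut_offset = if (is.null(cut_offset)) NULL else as.integer(cut_offset),
                 background_ligation = background_ligation),
            class = "pam_model")
}

# TRUE for PAMs matching a consensus with N wildcards
consensus_match <- function(pams, consensus) {
  pat <- paste0("^", gsub("N", ".", consensus), "$")
  grepl(pat, pams)
}

new_manifest <- function(...) {
  structure(purrr::compact(list(...)), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth manifest>\n")
  utils::str(unclass(x), max.level = 1, give.attr = FALSE)
  invisible(x)
}

#' Write / read a ground-truth manifest as JSON
#' @param manifest A `ground_truth` manifest.
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "ground_truth")
}

# constant-quality string(s); when an error model is active the Phred score
# encodes it (Q = -10 log10 p, rounded), otherwise Q37
.qual_string <- function(len, sequencing_error) {
  q <- if (sequencing_error > 0) round(-10 * log10(sequencing_error)) else 37L
  q <- max(2L, min(60L, as.integer(q)))
  strrep(intToUtf8(q + 33L), len)
}

# apply iid substitution errors to a character vector of sequences
.apply_seq_error <- function(seqs, p) {
  if (p <= 0 || !length(seqs)) return(seqs)
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, p)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    ch <- strsplit(seqs[i], "")[[1]]
    for (p0 in pos) ch[p0] <- sample(setdiff(BASES, ch[p0]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

# draw n random PAMs from the per-position bias matrix
.draw_pams <- function(n, bias) {
  if (n == 0L) return(character())
  cols <- lapply(seq_len(nrow(bias)), function(j) {
    sample(BASES, n, replace = TRUE, prob = bias[j, ])
  })
  do.call(paste0, cols)
}

# pad (with random bases, emulating downstream plasmid backbone) or truncate
# to the read length
.fit_read_length <- function(seqs, read_length) {
  if (!length(seqs)) return(seqs)
  lens <- nchar(seqs)
  short <- which(lens < read_length)
  if (length(short)) {
    pad <- vapply(read_length - lens[short], function(k) {
      paste(sample(BASES, k, replace = TRUE), collapse = "")
    }, character(1))
    seqs[short] <- paste0(seqs[short], pad)
  }
  substr(seqs, 1L, read_length)
}

#' Simulate the initial randomized-PAM plasmid library
#'
#' Each read is `flank5 + PAM + flank3`, with the PAM drawn from the
#' per-position composition bias, fitted to the read length, and subjected
#' to iid substitution errors.  The molecule's true PAM is carried in the
#' `pam` column so that selection simulators can act on the pre-sequencing
#' molecule.
#'
#' @param config A [sim_config()].
#' @return A list with `reads` (read tibble with columns `id`, `sequence`,
#'   `quality`, `pam`) and `manifest` (a `ground_truth` recording the bias
#'   table and seed).
#' @export
simulate_initial_library <- function(config) {
  validate_sim_config(config)
  min_len <- nchar(config$flank5) + config$pam_length + 8L
  if (config$read_length < min_len) {
    abort(sprintf("read_length must be >= %d so the PAM is extractable", min_len))
  }
  reads <- with_sim_seed(config$seed, {
    pams <- .draw_pams(config$n_reads, config$library_bias)
    seqs <- .fit_read_length(paste0(config$flank5, pams, config$flank3),
                             config$read_length)
    seqs <- .apply_seq_error(seqs, config$sequencing_error)
    tibble(
      id = sprintf("lib_%d", seq_len(config$n_reads)),
      sequence = seqs,
      quality = .qual_string(config$read_length, config$sequencing_error),
      pam = pams)
  })
  manifest <- new_manifest(kind = "initial_library", seed = config$seed,
                           n_reads = config$n_reads,
                           library_bias = config$library_bias,
                           pam_length = config$pam_length)
  list(reads = reads, manifest = manifest)
}

# run expr with an isolated, seeded RNG stream
with_sim_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate restriction-protection (binding) selection on a library
#'
#' Effector occupancy blocks restriction digestion, so bound molecules
#' survive.  Consensus-matching molecules survive with
#' `match_probability`; the rest survive with `mismatch_probability` plus
#' the incomplete-digestion background
#' `digestion_escape * (1 - mismatch_probability)`.
#'
#' @param library Read tibble from [simulate_initial_library()] (its `pam`
#'   column is the molecule's true PAM).
#' @param model A [pam_model()] with `mode = "binding"`.
#' @param config The [sim_config()] used for the library.
#' @return A read tibble of surviving molecules.
#' @export
simulate_binding_selection <- function(library, model, config) {
  stopifnot(inherits(model, "pam_model"))
  if (model$mode != "binding") abort("model mode must be 'binding'")
  if (is.list(library) && !is.data.frame(library)) library <- library$reads
  if (!nrow(library)) return(library)
  with_sim_seed(config$seed + 1L, {
    match <- consensus_match(library$pam, model$consensus)
    p <- ifelse(match, model$match_probability,
                model$mismatch_probability +
                  config$digestion_escape * (1 - model$mismatch_probability))
    keep <- stats::runif(nrow(library)) < p
    out <- library[keep, , drop = FALSE]
    out$id <- sprintf("sel_%d", seq_len(nrow(out)))
    out
  })
}

# all pam_length-mers in lexicographic order, with their library-bias
# probabilities
.pam_space <- function(bias) {
  L <- nrow(bias)
  grid <- expand.grid(rep(list(BASES), L), stringsAsFactors = FALSE)[, L:1, drop = FALSE]
  pams <- do.call(paste0, grid[, seq_len(L), drop = FALSE])
  prob <- rep(1, length(pams))
  for (j in seq_len(L)) {
    prob <- prob * bias[j, ][match(substr(pams, j, j), BASES)]
  }
  list(pams = pams, prob = unname(prob))
}

#' Simulate the full restriction-protection assay at pool scale
#'
#' A plasmid library prep holds on the order of 1e10 molecules while
#' sequencing samples 1e5-1e6 of them, so per-PAM digestion escape
#' concentrates at its expected rate instead of producing lucky
#' single-molecule escapers.  This generator emulates that regime: the
#' post-selection pool composition is `library_bias x survival
#' probability` (exact in the default infinite-pool limit, or sampled
#' when a finite `pool_factor` is given), and the selected pool and the
#' initial library are then sequenced independently to `n_reads` reads
#' each — all sampling noise is sequencing-side, as in the assay.  Use
#' [simulate_binding_selection()] instead to thin an explicit read set
#' molecule by molecule.
#'
#' @param config A [sim_config()].
#' @param model A [pam_model()] with `mode = "binding"`.
#' @param pool_factor Molecular pool size as a multiple of `n_reads`;
#'   `Inf` (default) for the exact infinite-pool limit.
#' @return A list with `library` (read tibble), `selected` (read
#'   tibble), and `manifest` recording the planted consensus.
#' @export
simulate_binding_assay <- function(config, model, pool_factor = Inf) {
  stopifnot(inherits(model, "pam_model"))
  if (model$mode != "binding") abort("model mode must be 'binding'")
  validate_sim_config(config)
  out <- with_sim_seed(config$seed + 4L, {
    space <- .pam_space(config$library_bias)
    p_survive <- ifelse(consensus_match(space$pams, model$consensus),
                        model$match_probability,
                        model$mismatch_probability +
                          config$digestion_escape * (1 - model$mismatch_probability))
    survivors <- if (is.finite(pool_factor)) {
      pool <- stats::rmultinom(1, round(pool_factor * config$n_reads), space$prob)[, 1]
      stats::rbinom(length(pool), pool, p_survive)
    } else {
      space$prob * p_survive
    }
    if (sum(survivors) == 0) abort("no molecules survived the selection")
    sel_counts <- stats::rmultinom(1, config$n_reads, survivors)[, 1]
    lib_counts <- stats::rmultinom(1, config$n_reads, space$prob)[, 1]
    materialize <- function(counts, prefix) {
      pams <- sample(rep.int(space$pams, counts))
      seqs <- .fit_read_length(paste0(config$flank5, pams, config$flank3),
                               config$read_length)
      seqs <- .apply_seq_error(seqs, config$sequencing_error)
      tibble(id = sprintf("%s_%d", prefix, seq_along(seqs)), sequence = seqs,
             quality = .qual_string(config$read_length, config$sequencing_error),
             pam = pams)
    }
    list(library = materialize(lib_counts, "lib"),
         selected = materialize(sel_counts, "sel"))
  })
  manifest <- new_manifest(kind = "binding_assay", seed = config$seed,
                           true_consensus = model$consensus,
                           pool_factor = pool_factor,
                           n_reads = config$n_reads)
  list(library = out$library, selected = out$selected, manifest = manifest)
}

#' Simulate adapter-ligation reads of the cleavage assay
#'
#' In `cleavage` mode a molecule whose PAM matches the consensus is cut at
#' `cut_offset` bp from the protospacer start with `match_probability`
#' (non-matching molecules with `mismatch_probability`); cut molecules are
#' read as `flank5 + PAM + protospacer[1..cut_offset] + adapter...`.  In
#' `inert` mode adapters appear only at the `background_ligation` rate, at
#' offsets uniform in 0-30.  Uncut molecules yield ordinary library reads.
#'
#' @param model A [pam_model()] with mode `"cleavage"` or `"inert"`.
#' @param config A [sim_config()]; `flank3` must be at least 31 nt so the
#'   whole 0-30 bp junction window lies in the protospacer-side constant
#'   sequence.
#' @param jitter_1bp Add +/-1 bp uniform jitter to the cut site (default
#'   off).
#' @return A list with `reads` and `manifest` (recording `cut_offset` for
#'   cleavage mode).
#' @export
simulate_cleavage_reads <- function(model, config, jitter_1bp = FALSE) {
  stopifnot(inherits(model, "pam_model"))
  if (!model$mode %in% c("cleavage", "inert")) {
    abort("model mode must be 'cleavage' or 'inert'")
  }
  validate_sim_config(config)
  if (nchar(config$flank3) < 31L) abort("flank3 must span the 0-30 bp window")
  reads <- with_sim_seed(config$seed + 2L, {
    n <- config$n_reads
    pams <- .draw_pams(n, config$library_bias)
    offs <- rep(NA_integer_, n)
    if (model$mode == "cleavage") {
      match <- consensus_match(pams, model$consensus)
      p <- ifelse(match, model$match_probability, model$mismatch_probability)
      cut <- stats::runif(n) < p
      k <- rep(model$cut_offset, n)
      if (jitter_1bp) k <- k + sample(-1:1, n, replace = TRUE)
      offs[cut] <- pmax(0L, pmin(30L, k[cut]))
    } else if (model$background_ligation > 0) {
      lig <- stats::runif(n) < model$background_ligation
      offs[lig] <- sample(0:30, sum(lig), replace = TRUE)
    }
    body <- ifelse(is.na(offs),
                   paste0(config$flank5, pams, config$flank3),
                   paste0(config$flank5, pams,
                          substring(config$flank3, 1L,
                                    ifelse(is.na(offs), 0L, offs)),
                          config$adapter))
    seqs <- .fit_read_length(body, config$read_length)
    seqs <- .apply_seq_error(seqs, config$sequencing_error)
    tibble(id = sprintf("clv_%d", seq_len(n)), sequence = seqs,
           quality = .qual_string(config$read_length, config$sequencing_error),
           pam = pams, cut_offset = offs)
  })
  manifest <- new_manifest(kind = "cleavage_assay", seed = config$seed,
                           mode = model$mode,
                           cut_offset = model$cut_offset,
                           true_consensus = model$consensus)
  list(reads = reads, manifest = manifest)
}

#' Simulate small-RNA paired-end reads around a mature crRNA
#'
#' Fragments are sampled around the planted crRNA span with optional
#' geometric end noise (an end is exact with probability `end_noise_p`;
#' otherwise it is displaced by a geometric number of nt in a random
#' direction).  Reads of `read_length` nt are taken from both fragment
#' ends; fragments shorter than the read length read through into the
#' adapter.
#'
#' @param reference Reference sequence string (e.g. the expression
#'   plasmid).
#' @param crrna_span Length-2 integer vector, 1-based inclusive span of the
#'   mature crRNA on the reference.
#' @param config A [sim_config()] (`n_reads` = number of pairs,
#'   `read_length` default 75 for this assay).
#' @param end_noise_p Geometric parameter; probability an end is exact.
#'   `1` disables end noise.
#' @return A list with `r1`, `r2` (read tibbles) and `manifest` recording
#'   the span.
#' @export
simulate_small_rna_reads <- function(reference, crrna_span, config,
                                     end_noise_p = 0.8) {
  stopifnot(length(crrna_span) == 2L)
  s <- as.integer(crrna_span[1]); e <- as.integer(crrna_span[2])
  if (s < 1L || e > nchar(reference) || s > e) {
    abort("crrna_span must lie within the reference")
  }
  n <- config$n_reads
  L <- config$read_length
  out <- with_sim_seed(config$seed + 3L, {
    jit <- function() {
      if (end_noise_p >= 1) return(integer(n) + 0L)
      d <- stats::rgeom(n, end_noise_p)
      d * sample(c(-1L, 1L), n, replace = TRUE)
    }
    fs <- pmax(1L, pmin(nchar(reference), s + jit()))
    fe <- pmax(1L, pmin(nchar(reference), e + jit()))
    ok <- fs <= fe
    fs <- fs[ok]; fe <- fe[ok]
    frag <- substr(rep(reference, length(fs)), fs, fe)
    # read-through: adapter then random carrier sequence fills short fragments
    filler <- strrep(config$adapter, ceiling(L / nchar(config$adapter)))
    r1 <- substr(paste0(frag, filler), 1L, L)
    r2 <- substr(paste0(reverse_complement(frag), filler), 1L, L)
    r1 <- .apply_seq_error(r1, config$sequencing_error)
    r2 <- .apply_seq_error(r2, config$sequencing_error)
    qual <- .qual_string(L, config$sequencing_error)
    list(
      r1 = tibble(id = sprintf("srna_%d", seq_along(r1)), sequence = r1,
                  quality = substr(qual, 1L, nchar(r1))),
      r2 = tibble(id = sprintf("srna_%d", seq_along(r2)), sequence = r2,
                  quality = substr(qual, 1L, nchar(r2))))
  })
  manifest <- new_manifest(kind = "small_rna", seed = config$seed,
                           crRNA_span = c(s, e), n_pairs = n,
                           end_noise_p = end_noise_p)
  list(r1 = out$r1, r2 = out$r2, manifest = manifest)
}

#' Simulate a bio-layer interferometry sensorgram
#'
#' Association follows `Rmax (1 - exp(-k_obs t))`; dissociation follows
#' `R0 exp(-k_off t)` from the response reached at the end of association.
#' Gaussian noise is added to the response.
#'
#' @param k_obs Observed association rate (per minute).
#' @param k_off Dissociation rate (per minute).
#' @param t_assoc,t_dissoc Phase durations in minutes.
#' @param noise_sd Gaussian noise SD (response units; Rmax = 1).
#' @param seed Integer seed.
#' @param dt Sampling interval in minutes (default 0.2, i.e. 600 points
#'   over a 120-minute dissociation).
#' @return A `sensorgram` tibble with columns `time` (minutes, continuous
#'   across phases), `response`, `phase`.
#' @export
simulate_sensorgram <- function(k_obs = 0.5, k_off = 0.006, t_assoc = 10,
                                t_dissoc = 120, noise_sd = 0, seed = 1L,
                                dt = 0.2) {
  ta <- seq(0, t_assoc, by = dt)
  td <- seq(dt, t_dissoc, by = dt)
  r_assoc <- 1 - exp(-k_obs * ta)
  r0 <- 1 - exp(-k_obs * t_assoc)
  r_dissoc <- r0 * exp(-k_off * td)
  out <- tibble(
    time = c(ta, t_assoc + td),
    response = c(r_assoc, r_dissoc),
    phase = c(rep("association", length(ta)), rep("dissociation", length(td))))
  if (noise_sd > 0) {
    out$response <- with_sim_seed(seed, out$response + stats::rnorm(nrow(out), 0, noise_sd))
  }
  class(out) <- c("sensorgram", class(out))
  out
}

# symmetric hat: plateau of half-width w, linear flanks of slope `slope`
.hat_extension <- function(turns, center, plateau = 1000, half_width = 1.5,
                           slope = 60) {
  excess <- pmax(0, abs(turns - center) - half_width)
  plateau - slope * excess
}

#' Simulate magnetic-tweezers rotation-extension curves
#'
#' The pre-binding curve is a symmetric hat (plateau with linear flanks)
#' centred at 0 turns; R-loop formation unwinds `rloop_bp` bp of duplex,
#' shifting the post-binding curve by `-rloop_bp / pitch_bp_per_turn`
#' turns.  Gaussian noise is added to the extension.
#'
#' @param rloop_bp Planted R-loop size in bp.
#' @param pitch_bp_per_turn Helical pitch (default 10.5 bp/turn, B-DNA).
#' @param noise_sd Extension noise SD (nm).
#' @param seed Integer seed.
#' @param turns Magnet-turn grid (default -10..10 in steps of 0.25).
#' @return A `rotation_curves` tibble with columns `turns`, `extension`
#'   (nm) and `curve` (`"pre"`/`"post"`); the planted shift is stored in
#'   the `planted_shift` attribute.
#' @export
simulate_rotation_curves <- function(rloop_bp, pitch_bp_per_turn = 10.5,
                                     noise_sd = 0, seed = 1L,
                                     turns = seq(-10, 10, by = 0.25)) {
  shift <- -rloop_bp / pitch_bp_per_turn
  pre <- .hat_extension(turns, 0)
  post <- .hat_extension(turns, shift)
  nt <- length(turns)
  out <- tibble(
    turns = c(turns, turns),
    extension = c(pre, post),
    curve = rep(c("pre", "post"), each = nt))
  if (noise_sd > 0) {
    out$extension <- with_sim_seed(seed, out$extension + stats::rnorm(nrow(out), 0, noise_sd))
  }
  attr(out, "planted_shift") <- shift
  class(out) <- c("rotation_curves", class(out))
  out
}

#' Simulate amplicon reads with per-position A-to-G editing
#'
#' Each read is the reference with independent A->G conversions at the
#' stated per-position probabilities, plus iid substitution sequencing
#' error.
#'
#' @param ref An [amplicon_ref()] (or a plain reference string).
#' @param editing_profile Numeric vector of A->G probabilities, one per
#'   reference position (entries at non-A positions must be 0).
#' @param n_reads Number of reads.
#' @param error Per-base substitution error probability.
#' @param seed Integer seed.
#' @return A list with `reads` and `manifest` recording the profile.
#' @export
simulate_amplicon_reads <- function(ref, editing_profile, n_reads,
                                    error = 0, seed = 1L) {
  seq0 <- if (is.list(ref)) ref$sequence else ref
  L <- nchar(seq0)
  stopifnot(length(editing_profile) == L)
  is_a <- strsplit(seq0, "")[[1]] == "A"
  if (any(editing_profile[!is_a] > 0)) {
    abort("editing_profile must be 0 at non-A reference positions")
  }
  reads <- with_sim_seed(seed, {
    seqs <- rep(seq0, n_reads)
    for (j in which(editing_profile > 0)) {
      flip <- stats::runif(n_reads) < editing_profile[j]
      substr(seqs[flip], j, j) <- "G"
    }
    seqs <- .apply_seq_error(seqs, error)
    tibble(id = sprintf("amp_%d", seq_len(n_reads)), sequence = seqs,
           quality = .qual_string(L, error))
  })
  manifest <- new_manifest(kind = "amplicon_editing", seed = seed,
                           editing_profile = editing_profile,
                           n_reads = n_reads)
  list(reads = reads, manifest = manifest)
}
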