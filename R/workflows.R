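#' Read a flat key-value run configuration
#'
#' Configurations are flat YAML files (`key: value` per line).  Keys not
#' understood by the requested workflow are rejected rather than ignored,
#' so typos cannot silently fall back to defaults.
#'
#' @param path Config file path.
#' @param allowed Character vector of permitted keys.
#' @return Named list of config values.
#' @export
read_run_config <- function(path, allowed) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  cfg
}

# provenance block embedded in every report
.provenance <- function(params, counts = NULL) {
  list(tool = "crisprkit",
       version = as.character(utils::packageVersion("crisprkit")),
       params = params, read_accounting = as.list(counts))
}

.write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

.msg <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Binding-based PAM identification workflow
#'
#' Runs the restriction-protection PAM pipeline: extract PAMs from the
#' selected (protected) and initial library read sets, compute per-PAM
#' enrichment, apply the strict `> threshold`-fold filter, and build the
#' read-count-weighted logo matrix of the retained PAMs.  Reports
#' (`enrichment.tsv`, `logo.tsv`, `pam_bind.json`) embed the full
#' parameter set and per-filter read accounting.
#'
#' @param selected,library Read tibbles or FASTQ paths.
#' @param flank5,flank3 Constant anchors around the randomized region.
#' @param pam_length Randomized-region length.
#' @param threshold Enrichment fold threshold (strict `>`).
#' @param min_library_count Minimum library count to score a PAM.
#' @param weighting Logo weighting, `"read_count"` or `"unique_pam"`.
#' @param out_dir Output directory (`NULL` to skip writing).
#' @param quiet Suppress progress messages.
#' @return A list: `enrichment`, `passing` (PAM set), `pfm`, `provenance`.
#' @export
run_pam_bind <- function(selected, library, flank5, flank3, pam_length = 7L,
                         threshold = 5.0, min_library_count = 5L,
                         weighting = "read_count", out_dir = NULL,
                         quiet = FALSE) {
  if (is.character(selected)) selected <- read_fastq(selected)
  if (is.character(library)) library <- read_fastq(library)
  sel <- extract_pams(selected, flank5, flank3, pam_length)
  lib <- extract_pams(library, flank5, flank3, pam_length)
  .msg(quiet, "selected: %d reads counted, %d discarded; library: %d counted, %d discarded",
       attr(sel, "total"), attr(sel, "n_reads_discarded"),
       attr(lib, "total"), attr(lib, "n_reads_discarded"))
  enr <- compute_enrichment(sel, lib, min_library_count)
  passing <- filter_enriched(enr, threshold)
  .msg(quiet, "%d / %d scored PAMs pass the >%g-fold filter",
       length(passing), sum(!enr$unscorable), threshold)
  pfm <- if (length(passing)) {
    counts <- enr$selected_count[match(passing, enr$pam)]
    build_pfm(passing, counts, weighting)
  } else NULL
  prov <- .provenance(
    params = list(pam_length = pam_length, threshold = threshold,
                  min_library_count = min_library_count,
                  weighting = weighting, flank5 = flank5, flank3 = flank3),
    counts = c(selected_counted = attr(sel, "total"),
               selected_discarded = attr(sel, "n_reads_discarded"),
               library_counted = attr(lib, "total"),
               library_discarded = attr(lib, "n_reads_discarded"),
               pams_passing = length(passing)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(as_tibble(enr), file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(pfm)) write_logo_tsv(pfm, file.path(out_dir, "logo.tsv"))
    .write_report(c(prov, list(passing_pams = passing)),
                  file.path(out_dir, "pam_bind.json"))
  }
  list(enrichment = enr, passing = passing, pfm = pfm, provenance = prov)
}

#' Cleavage-detection workflow
#'
#' Scans sample and control read sets for adapter-ligation junctions in
#' the 0-30 bp window next to the randomized region and calls cleavage
#' against the control.
#'
#' @param sample,control Read tibbles or FASTQ paths.
#' @param adapter Ligated adapter sequence.
#' @param target_anchor Constant anchor 5' of the randomized region.
#' @param pam_length Randomized-region length.
#' @param window Countable offset window.
#' @param min_fold,min_fraction Verdict thresholds (see
#'   [call_cleavage()]).
#' @param out_dir Output directory (`NULL` to skip writing).
#' @param quiet Suppress progress messages.
#' @return A list: `sample_hist`, `control_hist`, `call`, `provenance`.
#' @export
run_pam_cleave <- function(sample, control, adapter, target_anchor,
                           pam_length = 7L, window = c(0L, 30L),
                           min_fold = 10, min_fraction = 0.01,
                           out_dir = NULL, quiet = FALSE) {
  if (is.character(sample)) sample <- read_fastq(sample)
  if (is.character(control)) control <- read_fastq(control)
  hs <- scan_adapter_junctions(sample, adapter, target_anchor, pam_length, window)
  hc <- scan_adapter_junctions(control, adapter, target_anchor, pam_length, window)
  verdict <- call_cleavage(hs, hc, min_fold, min_fraction)
  .msg(quiet, "sample junctions in window: %d / %d reads; verdict: %s",
       sum(hs$count), attr(hs, "total_reads"),
       if (verdict$cleaved) sprintf("cleaved at %d", verdict$offset) else "not cleaved")
  prov <- .provenance(
    params = list(adapter = adapter, target_anchor = target_anchor,
                  pam_length = pam_length, window = window,
                  min_fold = min_fold, min_fraction = min_fraction),
    counts = c(sample_reads = attr(hs, "total_reads"),
               sample_junctions = sum(hs$count),
               control_reads = attr(hc, "total_reads"),
               control_junctions = sum(hc$count)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    h <- dplyr::rename(as_tibble(hs), sample_count = "count")
    h$control_count <- hc$count
    utils::write.table(h, file.path(out_dir, "junctions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .write_report(c(prov, list(verdict = unclass(verdict))),
                  file.path(out_dir, "pam_cleave.json"))
  }
  list(sample_hist = hs, control_hist = hc, call = verdict, provenance = prov)
}

#' Mature crRNA boundary-mapping workflow
#'
#' Adapter-trims and length-filters read pairs, merges mates into
#' molecules, places them uniquely on the reference, profiles molecule
#' ends, and calls the mature crRNA span.
#'
#' @param r1,r2 Read tibbles or FASTQ paths (mates row-aligned).
#' @param reference Reference sequence string or FASTA path (first
#'   record).
#' @param adapter Sequencing adapter.
#' @param min_length Minimum trimmed mate length.
#' @param max_length Maximum molecule length.
#' @param max_mismatch Placement mismatch budget.
#' @param min_support Minimum modal support for the boundary call.
#' @param out_dir Output directory (`NULL` to skip writing).
#' @param quiet Suppress progress messages.
#' @return A list: `placements`, `profile`, `call` (may be `NULL`),
#'   `provenance`.
#' @export
run_crrna <- function(r1, r2, reference, adapter, min_length = 15L,
                      max_length = 65L, max_mismatch = 2L, min_support = 0.2,
                      out_dir = NULL, quiet = FALSE) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  if (is.character(reference) && file.exists(reference)) {
    reference <- read_fasta(reference)$sequence[1]
  }
  trimmed <- trim_and_filter(r1, r2, adapter, min_length)
  .msg(quiet, "pairs in: %d, discarded short: %d", nrow(r1), trimmed$n_discarded)
  pl <- map_unique(trimmed$r1, trimmed$r2, reference, max_mismatch, max_length)
  acc <- attr(pl, "accounting")
  .msg(quiet, "placed %d / %d pairs (merge-failed %d, multi %d, unplaced %d, overlong %d)",
       acc["placed"], acc["pairs_in"], acc["merge_failed"],
       acc["multi_mapped"], acc["unplaced"], acc["overlong"])
  prof <- end_profiles(pl)
  call <- call_boundaries(prof, min_support)
  prov <- .provenance(
    params = list(adapter = adapter, min_length = min_length,
                  max_length = max_length, max_mismatch = max_mismatch,
                  min_support = min_support),
    counts = c(pairs_in = nrow(r1), short_discarded = trimmed$n_discarded, acc[-1]))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(as_tibble(prof), file.path(out_dir, "end_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_report(c(prov, list(boundary = if (is.null(call)) NULL else unclass(call))),
                  file.path(out_dir, "crrna.json"))
    if (!is.null(call)) write_boundary_bed(call, file.path(out_dir, "crrna.bed"))
  }
  list(placements = pl, profile = prof, call = call, provenance = prov)
}

#' Interference / plating fold-change workflow
#'
#' Reads a long count table (`condition`, `replicate`, `count`,
#' `dilution_factor`) and reports the fold change of every condition over
#' the named control, with replicate titers echoed.
#'
#' @param counts A tibble or TSV path with the columns above.
#' @param control Name of the negative-control condition.
#' @param units `"CFU"` or `"PFU"` (PFU folds are EOPs).
#' @param out_dir Output directory (`NULL` to skip writing).
#' @return A tibble of fold changes, one row per non-control condition.
#' @export
run_interference <- function(counts, control, units = "CFU", out_dir = NULL) {
  if (is.character(counts)) {
    counts <- as_tibble(utils::read.delim(counts, sep = "\t"))
  }
  need <- c("condition", "replicate", "count", "dilution_factor")
  if (!all(need %in% names(counts))) {
    abort(sprintf("count table needs columns: %s", paste(need, collapse = ", ")))
  }
  mk <- function(cond) {
    d <- counts[counts$condition == cond, , drop = FALSE]
    if (!nrow(d)) abort(sprintf("condition '%s' absent from the table", cond))
    s <- count_series(cond, d$count, d$dilution_factor, d$replicate, units)
    s
  }
  ctrl <- mk(control)
  conds <- setdiff(unique(counts$condition), control)
  out <- bind_rows(lapply(conds, function(cc) as_tibble(fold_change(mk(cc), ctrl))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, file.path(out_dir, "fold_change.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .write_report(c(.provenance(params = list(control = control, units = units)),
                    list(fold_changes = out)),
                  file.path(out_dir, "interference.json"))
  }
  out
}

#' Kinetics workflow: dissociation rate and rotation shift
#'
#' Accepts a sensorgram table (`time`, `response`, `phase`) and/or a
#' rotation-curve table (`turns`, `extension`, `curve`) — as tibbles or
#' TSV paths — and reports the dissociation rate, the rotation shift and
#' the implied R-loop size.
#'
#' @param sensorgram Optional sensorgram input.
#' @param rotation Optional rotation-curve input.
#' @param pitch_bp_per_turn Helical pitch for the R-loop conversion.
#' @param out_dir Output directory (`NULL` to skip writing).
#' @return A list with `dissociation` (`bli_fit` or `NULL`), `shift`
#'   (`rotation_shift` or `NULL`), `rloop_bp`.
#' @export
run_kinetics <- function(sensorgram = NULL, rotation = NULL,
                         pitch_bp_per_turn = 10.5, out_dir = NULL) {
  load_tsv <- function(x) if (is.character(x)) as_tibble(utils::read.delim(x)) else x
  fit <- NULL; shift <- NULL; rloop <- NULL
  if (!is.null(sensorgram)) fit <- fit_dissociation(load_tsv(sensorgram))
  if (!is.null(rotation)) {
    shift <- rotation_shift(load_tsv(rotation))
    rloop <- rloop_size(shift, pitch_bp_per_turn)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_report(c(.provenance(params = list(pitch_bp_per_turn = pitch_bp_per_turn)),
                    list(k_off = if (is.null(fit)) NULL else fit$k_off,
                         k_analytic = if (is.null(fit)) NULL else fit$k_analytic,
                         rms = if (is.null(fit)) NULL else fit$rms,
                         delta_turns = if (is.null(shift)) NULL else shift$delta_turns,
                         rloop_bp = rloop)),
                  file.path(out_dir, "kinetics.json"))
  }
  list(dissociation = fit, shift = shift, rloop_bp = rloop)
}

#' Amplicon base-editing quantification workflow
#'
#' Places amplicon reads on the reference (both strands, substitutions
#' only) and reports the per-position A->G editing profile over the
#' protospacer with its half-maximum editing window.
#'
#' @param reads Read tibble or FASTQ path.
#' @param ref An [amplicon_ref()].
#' @param max_mismatch_fraction Placement mismatch budget per base.
#' @param half_max Window threshold as a fraction of the peak frequency.
#' @param out_dir Output directory (`NULL` to skip writing).
#' @return A list: `placements`, `matrix`, `window`, `provenance`.
#' @export
run_editing <- function(reads, ref, max_mismatch_fraction = 0.1,
                        half_max = 0.5, out_dir = NULL) {
  if (is.character(reads)) reads <- read_fastq(reads)
  pl <- align_amplicons(reads, ref, max_mismatch_fraction)
  mat <- editing_profile(pl, ref)
  win <- window_summary(mat, half_max)
  acc <- attr(pl, "accounting")
  prov <- .provenance(
    params = list(max_mismatch_fraction = max_mismatch_fraction,
                  half_max = half_max, protospacer = ref$protospacer),
    counts = acc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_editing_tsv(mat, file.path(out_dir, "editing_matrix.tsv"))
    .write_report(c(prov, list(window_positions = win)),
                  file.path(out_dir, "editing.json"))
  }
  list(placements = pl, matrix = mat, window = win, provenance = prov)
}

#' Simulation workflow: write synthetic inputs with their manifest
#'
#' Generates the sequencing inputs for one of the supported assays and
#' writes FASTQ/FASTA plus the ground-truth manifest JSON, so the
#' analysis workflows can be exercised from files alone.
#'
#' @param kind `"pam_bind"`, `"pam_cleave"` or `"small_rna"`.
#' @param config A [sim_config()].
#' @param model A [pam_model()] (PAM assays).
#' @param reference,crrna_span Small-RNA assay inputs.
#' @param out_dir Output directory.
#' @return Invisibly, the list of files written.
#' @export
run_simulate <- function(kind = c("pam_bind", "pam_cleave", "small_rna"),
                         config, model = NULL, reference = NULL,
                         crrna_span = NULL, out_dir) {
  kind <- match.arg(kind)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(reads, name) {
    p <- file.path(out_dir, name)
    write_fastq(reads[c("id", "sequence", "quality")], p)
    files <<- c(files, p)
  }
  if (kind == "pam_bind") {
    lib <- simulate_initial_library(config)
    sel <- simulate_binding_selection(lib$reads, model, config)
    put(lib$reads, "library.fastq"); put(sel, "selected.fastq")
    write_manifest(lib$manifest, file.path(out_dir, "manifest.json"))
  } else if (kind == "pam_cleave") {
    smp <- simulate_cleavage_reads(model, config)
    ctl <- simulate_cleavage_reads(pam_model("inert"), config)
    put(smp$reads, "sample.fastq"); put(ctl$reads, "control.fastq")
    write_manifest(smp$manifest, file.path(out_dir, "manifest.json"))
  } else {
    sim <- simulate_small_rna_reads(reference, crrna_span, config)
    put(sim$r1, "r1.fastq"); put(sim$r2, "r2.fastq")
    write_fasta(tibble(id = "reference", sequence = reference),
                file.path(out_dir, "reference.fasta"))
    write_manifest(sim$manifest, file.path(out_dir, "manifest.json"))
  }
  files <- c(files, file.path(out_dir, "manifest.json"))
  invisible(files)
}
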