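#' Extract PAM counts from randomized-library reads
#'
#' Each read is anchored on the constant sequences flanking the randomized
#' region; when both anchors are found at the expected spacing the
#' intervening `pam_length`-mer is counted.  Reads that fail anchoring or
#' contain `N` in the PAM are tallied as discarded.
#'
#' @param reads Read tibble (columns `id`, `sequence`) or character vector
#'   of sequences.
#' @param flank5,flank3 Constant anchor sequences immediately 5' and 3' of
#'   the randomized region.  Long anchors are truncated to
#'   `anchor_length` nt (the part adjacent to the PAM) for matching.
#' @param pam_length Length of the randomized region.
#' @param max_anchor_mismatch Mismatches tolerated per anchor.
#' @param anchor_length Number of anchor bases used for matching.
#' @return A `pam_counts` tibble with columns `pam` and `count`, and
#'   attributes `pam_length`, `total` and `n_reads_discarded`.
#' @examples
#' extract_pams(c("AACCGGTTACGTACGTTTTCAAAGGGTTTCCCAAA"),
#'              flank5 = "AACCGGTTACGTACGT", flank3 = "GGGTTTCCCAAA")
#' @export
extract_pams <- function(reads, flank5, flank3, pam_length = 7L,
                         max_anchor_mismatch = 1L, anchor_length = 12L) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  a5 <- substr(flank5, max(1L, nchar(flank5) - anchor_length + 1L), nchar(flank5))
  a3 <- substr(flank3, 1L, min(anchor_length, nchar(flank3)))
  .check_anchor(a5); .check_anchor(a3)
  if (nchar(a5) + nchar(a3) < 2L) abort("anchors too short")

  loc <- .locate_batch(seqs, a5, max_anchor_mismatch)
  pam_start <- loc$offset + nchar(a5) + 1L          # 1-based PAM start
  pam <- substr(seqs, pam_start, pam_start + pam_length - 1L)
  f3 <- substr(seqs, pam_start + pam_length,
               pam_start + pam_length + nchar(a3) - 1L)
  ok <- !is.na(loc$offset) &
    nchar(pam) == pam_length &
    nchar(f3) == nchar(a3)
  ok[ok] <- .mismatch_count(f3[ok], a3) <= max_anchor_mismatch
  ok[ok] <- !grepl("N", pam[ok], fixed = TRUE)

  counted <- pam[ok]
  tab <- sort(table(counted), decreasing = TRUE)
  out <- tibble(pam = names(tab), count = as.integer(tab))
  structure(out,
            class = c("pam_counts", class(out)),
            pam_length = as.integer(pam_length),
            total = length(counted),
            n_reads_discarded = length(seqs) - length(counted))
}

#' @export
print.pam_counts <- function(x, ...) {
  cat(sprintf("<pam_counts> %d distinct %d-mers, %d reads counted, %d discarded\n",
              nrow(x), attr(x, "pam_length"), attr(x, "total"),
              attr(x, "n_reads_discarded")))
  NextMethod()
}

#' Per-PAM fold enrichment of a selected read set over the initial library
#'
#' Enrichment is the ratio of relative frequencies,
#' `(selected/selected_total) / (library/library_total)`, with no
#' pseudocounts.  PAMs observed fewer than `min_library_count` times in
#' the library are flagged `unscorable` instead of scored, guarding the
#' ratio against near-zero denominators.
#'
#' @param selected,library `pam_counts` tables for the selected and
#'   initial read sets.
#' @param min_library_count Minimum library count required to score a PAM.
#' @return A `pam_enrichment` tibble with columns `pam`, `selected_count`,
#'   `library_count`, `enrichment_fold` (NA when unscorable) and
#'   `unscorable`.
#' @export
compute_enrichment <- function(selected, library, min_library_count = 5L) {
  if (attr(selected, "pam_length") != attr(library, "pam_length")) {
    abort("PAM lengths differ between tables")
  }
  sel_total <- attr(selected, "total")
  lib_total <- attr(library, "total")
  if (lib_total <= 0) abort("library table is empty")
  if (sel_total <= 0) abort("no surviving reads in the selected table")
  out <- dplyr::full_join(
    dplyr::rename(as_tibble(selected), selected_count = "count"),
    dplyr::rename(as_tibble(library), library_count = "count"),
    by = "pam")
  out <- mutate(out,
    selected_count = dplyr::coalesce(.data$selected_count, 0L),
    library_count = dplyr::coalesce(.data$library_count, 0L),
    unscorable = .data$library_count < min_library_count,
    enrichment_fold = dplyr::if_else(
      .data$unscorable, NA_real_,
      (.data$selected_count / sel_total) / (.data$library_count / lib_total)))
  out <- arrange(out, dplyr::desc(.data$enrichment_fold))
  structure(out,
            class = c("pam_enrichment", class(out)),
            selected_total = sel_total, library_total = lib_total,
            min_library_count = as.integer(min_library_count))
}

#' Retain PAMs enriched beyond a fold threshold
#'
#' The filter is a strict inequality (`fold > threshold`); unscorable PAMs
#' never pass.
#'
#' @param table A `pam_enrichment` table.
#' @param threshold Fold threshold (default 5).
#' @return Character vector of passing PAMs.
#' @export
filter_enriched <- function(table, threshold = 5.0) {
  keep <- !table$unscorable & !is.na(table$enrichment_fold) &
    table$enrichment_fold > threshold
  table$pam[keep]
}

#' Position frequency matrix over a set of PAMs
#'
#' @param pams Character vector of equal-length PAMs.
#' @param weights Optional per-PAM weights (e.g. selected read counts).
#' @param weighting `"read_count"` (use `weights`) or `"unique_pam"`
#'   (each PAM counts once).
#' @return A `pam_pfm` tibble with columns `position` (labelled
#'   `-L..-1`, -1 adjacent to the protospacer), `A`, `C`, `G`, `T`;
#'   attributes `n_pams` and `weighting`.
#' @export
build_pfm <- function(pams, weights = NULL,
                      weighting = c("read_count", "unique_pam")) {
  weighting <- match.arg(weighting)
  if (!length(pams)) abort("empty PAM set")
  L <- nchar(pams[1])
  stopifnot(all(nchar(pams) == L))
  w <- if (weighting == "unique_pam" || is.null(weights)) {
    rep(1, length(pams))
  } else {
    stopifnot(length(weights) == length(pams))
    as.numeric(weights)
  }
  rows <- lapply(seq_len(L), function(j) {
    b <- substr(pams, j, j)
    f <- vapply(BASES, function(base) sum(w[b == base]), numeric(1))
    f / sum(w)
  })
  mat <- do.call(rbind, rows)
  out <- as_tibble(as.data.frame(mat))
  names(out) <- BASES
  out <- dplyr::bind_cols(tibble(position = seq_len(L) - L - 1L), out)
  structure(out, class = c("pam_pfm", class(out)),
            n_pams = length(pams), weighting = weighting)
}

#' Per-position information content of a frequency matrix, in bits
#'
#' `IC_j = 2 + sum_b f_jb log2 f_jb` with `0 log 0 = 0`.  An optional
#' small-sample correction (`2/(ln 2) / (2 n)`, subtracted and floored at
#' 0) is off by default: enriched PAM sets here carry thousands of
#' observations.
#'
#' @param pfm A `pam_pfm` (or any table with columns `A`,`C`,`G`,`T`).
#' @param small_sample_correction Apply the correction using the `n_pams`
#'   attribute.
#' @return Numeric vector of per-position bits, in `[0, 2]`.
#' @export
information_content <- function(pfm, small_sample_correction = FALSE) {
  f <- as.matrix(pfm[, BASES])
  plogp <- ifelse(f > 0, f * log2(f), 0)
  ic <- 2 + rowSums(plogp)
  if (small_sample_correction) {
    n <- attr(pfm, "n_pams") %||% abort("pfm lacks an n_pams attribute")
    ic <- pmax(0, ic - (4 - 1) / (2 * log(2) * n))
  }
  pmin(pmax(ic, 0), 2)
}

#' Write a sequence-logo matrix as TSV
#'
#' Emits `position, A, C, G, T, bits` for standard logo plotters, with the
#' weighting mode recorded in a header comment.
#'
#' @param pfm A `pam_pfm`.
#' @param path Output path.
#' @export
write_logo_tsv <- function(pfm, path) {
  out <- mutate(pfm, bits = information_content(pfm))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# weighting=%s n_pams=%d",
                     attr(pfm, "weighting") %||% "unknown",
                     attr(pfm, "n_pams") %||% NA_integer_), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count adapter-ligation junctions in the 0-30 bp target window
#'
#' Offset 0 is the first protospacer base, immediately 3' of the
#' randomized region.  Because cleaved molecules truncate the protospacer,
#' the scan anchors on the constant sequence 5' of the randomized region
#' (`target_anchor`) and places offset 0 at `anchor end + pam_length`; the
#' ligation offset of a read is then the 0-based position of the adapter's
#' 5'-most base relative to offset 0.  Reads without an adapter, or with a
#' junction outside the window, are ignored.
#'
#' @param reads Read tibble or character vector.
#' @param adapter Ligated adapter sequence.
#' @param target_anchor Constant anchor 5' of the randomized region (e.g.
#'   the library `flank5`).
#' @param pam_length Length of the randomized region between anchor and
#'   protospacer.
#' @param window Length-2 integer window of countable offsets.
#' @param max_mismatch Mismatches tolerated per match.
#' @return A `junction_histogram` tibble with columns `offset`
#'   (`window[1]..window[2]`) and `count`; attribute `total_reads`.
#' @export
scan_adapter_junctions <- function(reads, adapter, target_anchor,
                                   pam_length = 7L, window = c(0L, 30L),
                                   max_mismatch = 1L) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  .check_anchor(adapter); .check_anchor(target_anchor)
  if (grepl(adapter, target_anchor, fixed = TRUE)) {
    abort("adapter is a substring of the anchor: junction offsets would be ambiguous")
  }
  anc <- .locate_batch(seqs, target_anchor, max_mismatch)
  ad <- .locate_batch(seqs, adapter, max_mismatch)
  zero <- anc$offset + nchar(target_anchor) + pam_length   # 0-based offset 0
  off <- ad$offset - zero
  off <- off[!is.na(off) & off >= window[1] & off <= window[2]]
  offsets <- seq.int(window[1], window[2])
  counts <- tabulate(match(off, offsets), nbins = length(offsets))
  out <- tibble(offset = offsets, count = as.integer(counts))
  structure(out, class = c("junction_histogram", class(out)),
            total_reads = length(seqs))
}

#' Call cleavage from sample vs control junction histograms
#'
#' The sample is called cleaved at offset `k` when its junction fraction
#' at `k` reaches `min_fraction` and exceeds `min_fold` times the control
#' fraction at `k` (the control fraction floored at `1/total` to keep the
#' ratio finite).
#'
#' @param sample,control `junction_histogram` tables on the same window.
#' @param min_fold Minimum fold over control.
#' @param min_fraction Minimum sample junction fraction.
#' @return A `cleavage_call` list: `cleaved` (logical), `offset` (NA when
#'   not cleaved), `sample_fraction`, `fold_over_control`.
#' @export
call_cleavage <- function(sample, control, min_fold = 10, min_fraction = 0.01) {
  stopifnot(identical(sample$offset, control$offset))
  ns <- attr(sample, "total_reads"); nc <- attr(control, "total_reads")
  if (ns <= 0) {
    return(structure(list(cleaved = FALSE, offset = NA_integer_,
                          sample_fraction = NA_real_,
                          fold_over_control = NA_real_),
                     class = "cleavage_call"))
  }
  fs <- sample$count / ns
  fc <- pmax(control$count, 1L) / max(nc, 1L)
  fold <- fs / fc
  pass <- fs >= min_fraction & fold >= min_fold
  if (any(pass)) {
    k <- which(pass)[which.max(fs[pass])]
    structure(list(cleaved = TRUE, offset = sample$offset[k],
                   sample_fraction = fs[k], fold_over_control = fold[k]),
              class = "cleavage_call")
  } else {
    structure(list(cleaved = FALSE, offset = NA_integer_,
                   sample_fraction = max(fs), fold_over_control = max(fold)),
              class = "cleavage_call")
  }
}

#' @export
print.cleavage_call <- function(x, ...) {
  if (x$cleaved) {
    cat(sprintf("cleaved at offset %d (fraction %.3g, %.1f-fold over control)\n",
                x$offset, x$sample_fraction, x$fold_over_control))
  } else {
    cat("not cleaved\n")
  }
  invisible(x)
}
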