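#' Describe an amplicon reference for base-editing quantification
#'
#' @param sequence Reference amplicon sequence.
#' @param protospacer Length-2 integer vector: 1-based inclusive span of
#'   the protospacer.  Position 1 of the protospacer is its PAM-proximal
#'   end (the PAM lies 5' of the protospacer).
#' @param pam Length-2 integer vector: span of the PAM (must not overlap
#'   the protospacer).
#' @return An `amplicon_ref` list.
#' @export
amplicon_ref <- function(sequence, protospacer, pam = NULL) {
  L <- nchar(sequence)
  p <- as.integer(protospacer)
  if (p[1] < 1L || p[2] > L || p[1] > p[2]) abort("protospacer outside sequence")
  if (!is.null(pam)) {
    q <- as.integer(pam)
    if (q[1] < 1L || q[2] > L || q[1] > q[2]) abort("pam outside sequence")
    if (max(p[1], q[1]) <= min(p[2], q[2])) abort("pam overlaps protospacer")
  }
  structure(list(sequence = sequence, protospacer = p,
                 pam = if (is.null(pam)) NULL else as.integer(pam),
                 pam_side = "5prime"),
            class = "amplicon_ref")
}

#' Place amplicon reads on the reference, both strands, substitutions only
#'
#' Each read is compared to the reference in both orientations (reads the
#' length of the reference directly; shorter reads by anchored placement)
#' and kept in reference orientation when its best mismatch fraction is
#' at most `max_mismatch_fraction`.  Gapped alignment is not attempted:
#' reads that do not place ungapped are discarded and tallied.
#'
#' @param reads Read tibble or character vector.
#' @param ref An [amplicon_ref()].
#' @param max_mismatch_fraction Maximum mismatches per aligned base.
#' @return An `amplicon_placements` tibble with columns `sequence` (in
#'   reference orientation), `start` (1-based on the reference), `strand`,
#'   `mismatches`, `weight`; attribute `accounting` (placed / discarded).
#' @export
align_amplicons <- function(reads, ref, max_mismatch_fraction = 0.1) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  refseq <- ref$sequence
  L <- nchar(refseq)
  tab <- table(seqs)
  uniq <- names(tab); w <- as.integer(tab)
  rows <- vector("list", length(uniq))
  placed <- 0L; discarded <- 0L
  for (i in seq_along(uniq)) {
    s <- uniq[i]
    best <- NULL
    for (strand in c("+", "-")) {
      x <- if (strand == "+") s else reverse_complement(s)
      if (nchar(x) == L) {
        mm <- .mismatch_count(x, refseq)
        cand <- list(start = 1L, mismatches = mm, strand = strand, seq = x)
      } else if (nchar(x) < L) {
        budget <- floor(max_mismatch_fraction * nchar(x))
        hit <- .locate_one(refseq, x, budget)
        # note: pattern/subject swapped -- we look for the read in the ref
        cand <- if (is.null(hit)) NULL else {
          list(start = hit$offset + 1L, mismatches = hit$mismatches,
               strand = strand, seq = x)
        }
      } else cand <- NULL
      if (!is.null(cand) &&
          (is.null(best) || cand$mismatches < best$mismatches)) best <- cand
    }
    if (is.null(best) ||
        best$mismatches > max_mismatch_fraction * nchar(best$seq)) {
      discarded <- discarded + w[i]
      next
    }
    placed <- placed + w[i]
    rows[[i]] <- tibble(sequence = best$seq, start = best$start,
                        strand = best$strand, mismatches = best$mismatches,
                        weight = w[i])
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(sequence = character(), start = integer(),
                  strand = character(), mismatches = integer(),
                  weight = integer())
  }
  structure(out, class = c("amplicon_placements", class(out)),
            accounting = c(n_reads = length(seqs), placed = placed,
                           discarded = discarded))
}

#' Per-position substitution profile over the protospacer
#'
#' Counts, at every protospacer position (1 = PAM-proximal), the reads
#' carrying each base, and reports the A->G conversion frequency at
#' reference-A positions; non-A positions are flagged rather than scored.
#' The sequencing-error floor is not subtracted.
#'
#' @param placements An `amplicon_placements` tibble.
#' @param ref The [amplicon_ref()] used for alignment.
#' @return An `editing_matrix` tibble: `position` (protospacer
#'   coordinate), `ref_base`, `depth`, `n_A`, `n_C`, `n_G`, `n_T`,
#'   `a_to_g` (NA at non-A positions), `is_A`.
#' @export
editing_profile <- function(placements, ref) {
  p <- ref$protospacer
  positions <- seq.int(p[1], p[2])
  refb <- strsplit(substr(ref$sequence, p[1], p[2]), "")[[1]]
  rows <- lapply(seq_along(positions), function(j) {
    pos <- positions[j]
    # reads covering this reference position
    covered <- placements$start <= pos &
      placements$start + nchar(placements$sequence) - 1L >= pos
    b <- substr(placements$sequence[covered],
                pos - placements$start[covered] + 1L,
                pos - placements$start[covered] + 1L)
    wt <- placements$weight[covered]
    cnt <- unname(vapply(BASES, function(bb) sum(wt[b == bb]), numeric(1)))
    depth <- sum(cnt)
    tibble(position = j, ref_base = refb[j], depth = depth,
           n_A = cnt[1], n_C = cnt[2], n_G = cnt[3], n_T = cnt[4],
           a_to_g = if (refb[j] == "A" && depth > 0) cnt[3] / depth else NA_real_,
           is_A = refb[j] == "A")
  })
  out <- bind_rows(rows)
  structure(out, class = c("editing_matrix", class(out)),
            n_reads = sum(placements$weight))
}

#' Editing-window summary of an editing matrix
#'
#' Protospacer positions whose A->G frequency is at least `half_max`
#' times the maximum observed frequency.
#'
#' @param matrix An `editing_matrix`.
#' @param half_max Fraction of the maximum defining the window.
#' @return Integer vector of protospacer positions (empty when nothing is
#'   edited).
#' @export
window_summary <- function(matrix, half_max = 0.5) {
  f <- matrix$a_to_g
  if (all(is.na(f)) || max(f, na.rm = TRUE) == 0) return(integer())
  thr <- half_max * max(f, na.rm = TRUE)
  matrix$position[!is.na(f) & f >= thr]
}

#' Write an editing matrix as TSV
#' @param matrix An `editing_matrix`.
#' @param path Output path.
#' @export
write_editing_tsv <- function(matrix, path) {
  utils::write.table(
    dplyr::transmute(as_tibble(matrix),
                     position = .data$position, ref_base = .data$ref_base,
                     depth = .data$depth, a_to_g_count = .data$n_G,
                     frequency = .data$a_to_g),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
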