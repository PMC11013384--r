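#' Adapter-trim and length-filter small-RNA read pairs
#'
#' The 3' adapter is removed by anchored matching: the longest suffix of
#' the read equal (within `max_mismatch`) to a prefix of the adapter of at
#' least `min_adapter_prefix` nt is cut off; an internal full-adapter
#' occurrence also truncates the read.  Pairs in which either trimmed mate
#' is shorter than `min_length` are discarded.
#'
#' @param r1,r2 Read tibbles of equal length (mates row-aligned).
#' @param adapter Adapter sequence.
#' @param min_length Minimum mate length after trimming (nt).
#' @param min_adapter_prefix Minimum adapter prefix recognized at the read
#'   3' end.
#' @param max_mismatch Mismatches tolerated in the adapter match.
#' @return A list with trimmed `r1`, `r2` and an attribute-free
#'   `n_discarded` count.
#' @export
trim_and_filter <- function(r1, r2, adapter, min_length = 15L,
                            min_adapter_prefix = 6L, max_mismatch = 1L) {
  stopifnot(nrow(r1) == nrow(r2))
  t1 <- .trim_adapter(r1$sequence, adapter, min_adapter_prefix, max_mismatch)
  t2 <- .trim_adapter(r2$sequence, adapter, min_adapter_prefix, max_mismatch)
  keep <- nchar(t1) >= min_length & nchar(t2) >= min_length
  out1 <- r1[keep, , drop = FALSE]; out1$sequence <- t1[keep]
  out2 <- r2[keep, , drop = FALSE]; out2$sequence <- t2[keep]
  out1$quality <- substr(out1$quality, 1L, nchar(out1$sequence))
  out2$quality <- substr(out2$quality, 1L, nchar(out2$sequence))
  list(r1 = out1, r2 = out2, n_discarded = sum(!keep))
}

# cut each read at the start of its 3'-terminal adapter match (or internal
# full-adapter occurrence)
.trim_adapter <- function(seqs, adapter, min_prefix, max_mismatch) {
  if (!length(seqs)) return(seqs)
  cut <- rep(NA_integer_, length(seqs))
  # internal (or terminal) full-adapter occurrence
  loc <- .locate_batch(seqs, adapter, max_mismatch)
  cut <- ifelse(is.na(loc$offset), NA_integer_, loc$offset)
  # partial adapter prefix flush with the read 3' end
  lens <- nchar(seqs)
  la <- nchar(adapter)
  for (k in seq(la - 1L, min_prefix)) {
    open <- is.na(cut) & lens >= k
    if (!any(open)) next
    tail_k <- substr(seqs[open], lens[open] - k + 1L, lens[open])
    hit <- .mismatch_count(tail_k, substr(adapter, 1L, k)) <= max_mismatch
    idx <- which(open)[hit]
    cut[idx] <- lens[idx] - k
  }
  ifelse(is.na(cut), seqs, substr(seqs, 1L, cut))
}

#' Place merged small-RNA molecules uniquely on a reference
#'
#' Mates are merged with [merge_read_pair()]; each distinct merged
#' molecule is then located on both strands of the reference.  Molecules
#' with more than one equally good placement, no placement within
#' `max_mismatch`, or length above `max_length` nt are discarded.
#' Identical read pairs are collapsed before merging and re-weighted, so
#' deep uniform libraries stay fast.
#'
#' @param r1,r2 Trimmed read tibbles (see [trim_and_filter()]).
#' @param reference Reference sequence string.
#' @param max_mismatch Mismatches tolerated in placement.
#' @param max_length Maximum molecule length (nt); longer molecules are
#'   not mature small RNAs and are dropped.
#' @return A `placements` tibble with columns `sequence`, `weight`
#'   (number of supporting pairs), `start`, `end` (1-based inclusive on
#'   the reference), `strand`, `mismatches`; attribute `accounting`
#'   tallies pairs in vs discarded (merge-failed, multi-mapped, unplaced,
#'   overlong).
#' @export
map_unique <- function(r1, r2, reference, max_mismatch = 2L, max_length = 65L) {
  stopifnot(nrow(r1) == nrow(r2))
  key <- paste(r1$sequence, r2$sequence)
  tab <- table(key)
  uniq <- names(tab)
  w <- as.integer(tab)
  parts <- strsplit(uniq, " ", fixed = TRUE)
  acc <- c(pairs_in = length(key), merge_failed = 0L, overlong = 0L,
           multi_mapped = 0L, unplaced = 0L, placed = 0L)
  rows <- vector("list", length(uniq))
  fwd <- Biostrings::DNAString(reference)
  rev <- Biostrings::reverseComplement(fwd)
  for (i in seq_along(uniq)) {
    m <- merge_read_pair(list(sequence = parts[[i]][1]),
                         list(sequence = parts[[i]][2]))
    if (is.null(m)) { acc["merge_failed"] <- acc["merge_failed"] + w[i]; next }
    mol <- m$sequence
    if (nchar(mol) > max_length) { acc["overlong"] <- acc["overlong"] + w[i]; next }
    hit <- .place_unique(mol, fwd, rev, max_mismatch)
    if (is.null(hit)) { acc["unplaced"] <- acc["unplaced"] + w[i]; next }
    if (isTRUE(hit$multi)) { acc["multi_mapped"] <- acc["multi_mapped"] + w[i]; next }
    acc["placed"] <- acc["placed"] + w[i]
    rows[[i]] <- tibble(sequence = mol, weight = w[i], start = hit$start,
                        end = hit$end, strand = hit$strand,
                        mismatches = hit$mismatches)
  }
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(sequence = character(), weight = integer(), start = integer(),
                  end = integer(), strand = character(), mismatches = integer())
  }
  structure(out, class = c("placements", class(out)), accounting = acc,
            reference_length = nchar(reference))
}

# all best-tier placements of a molecule on either strand; multi flag when >1
.place_unique <- function(mol, fwd, rev, max_mismatch) {
  pat <- Biostrings::DNAString(mol)
  L <- length(fwd)
  for (mm in 0:max_mismatch) {
    hits <- list()
    mf <- Biostrings::matchPattern(pat, fwd, max.mismatch = mm, fixed = TRUE)
    for (s in Biostrings::start(mf)) {
      hits[[length(hits) + 1L]] <- list(start = s, end = s + length(pat) - 1L,
                                        strand = "+", mismatches = mm)
    }
    mr <- Biostrings::matchPattern(pat, rev, max.mismatch = mm, fixed = TRUE)
    for (s in Biostrings::start(mr)) {
      # convert reverse-strand coordinates back to the forward reference
      hits[[length(hits) + 1L]] <- list(start = L - (s + length(pat) - 1L) + 1L,
                                        end = L - s + 1L,
                                        strand = "-", mismatches = mm)
    }
    if (length(hits) == 1L) return(hits[[1]])
    if (length(hits) > 1L) {
      # the same exact placement can surface once per strand for palindromes
      keys <- vapply(hits, function(h) paste(h$start, h$end), character(1))
      if (length(unique(keys)) == 1L) return(hits[[1]])
      return(list(multi = TRUE))
    }
  }
  NULL
}

#' Per-position end profiles of placed molecules
#'
#' Counts molecule 5' and 3' ends per reference position (weighted by
#' pair support), on the crRNA-encoding strand convention: for `-`-strand
#' placements the 5' end is the placement `end` coordinate.
#'
#' @param placements A `placements` tibble from [map_unique()].
#' @return An `end_profile` tibble with columns `position`, `five_prime`,
#'   `three_prime`; attribute `n_molecules` (total weight).
#' @export
end_profiles <- function(placements) {
  n <- sum(placements$weight)
  five <- ifelse(placements$strand == "+", placements$start, placements$end)
  three <- ifelse(placements$strand == "+", placements$end, placements$start)
  pos <- sort(unique(c(five, three)))
  prof <- tibble(
    position = pos,
    five_prime = vapply(pos, function(p) sum(placements$weight[five == p]), numeric(1)),
    three_prime = vapply(pos, function(p) sum(placements$weight[three == p]), numeric(1)))
  structure(prof, class = c("end_profile", class(prof)), n_molecules = n)
}

#' Call mature crRNA boundaries from an end profile
#'
#' Boundaries are the modal 5' and 3' end positions; ties are broken
#' toward the position yielding the longer molecule.  The call carries the
#' weaker of the two modal support fractions and is rejected (`NULL`)
#' below `min_support`.
#'
#' @param profile An `end_profile`.
#' @param min_support Minimum modal support fraction.
#' @return A `boundary_call` list (`five_prime`, `three_prime`,
#'   `mature_length`, `support_fraction`), or `NULL` when support is
#'   insufficient.
#' @export
call_boundaries <- function(profile, min_support = 0.2) {
  n <- attr(profile, "n_molecules")
  if (is.null(n) || n == 0) return(NULL)
  modal <- function(counts, prefer_low) {
    top <- which(counts == max(counts))
    i <- if (prefer_low) top[1] else top[length(top)]
    list(pos = profile$position[i], support = counts[i] / n)
  }
  # longer molecule: smallest 5' end, largest 3' end
  m5 <- modal(profile$five_prime, prefer_low = TRUE)
  m3 <- modal(profile$three_prime, prefer_low = FALSE)
  support <- min(m5$support, m3$support)
  if (support < min_support || m3$pos < m5$pos) return(NULL)
  structure(list(five_prime = m5$pos, three_prime = m3$pos,
                 mature_length = m3$pos - m5$pos + 1L,
                 support_fraction = support),
            class = "boundary_call")
}

#' @export
print.boundary_call <- function(x, ...) {
  cat(sprintf("crRNA %d..%d (%d nt), modal support %.2f\n",
              x$five_prime, x$three_prime, x$mature_length,
              x$support_fraction))
  invisible(x)
}

#' Write a boundary call as a BED interval
#'
#' One 0-based half-open interval per called crRNA.
#'
#' @param call A `boundary_call`.
#' @param path Output path.
#' @param reference_id Name for the BED chrom field.
#' @export
write_boundary_bed <- function(call, path, reference_id = "reference") {
  writeLines(sprintf("%s\t%d\t%d\tcrRNA\t%d\t+", reference_id,
                     call$five_prime - 1L, call$three_prime,
                     round(1000 * call$support_fraction)), path)
  invisible(path)
}

#' Scan a candidate region for anti-repeat (tracrRNA-like) complementarity
#'
#' Slides `min_match`-nt windows along the candidate region and reports
#' those whose reverse complement occurs in the repeat with at most
#' `max_mismatch` mismatches; overlapping window hits are merged into
#' runs.  An empty result excludes a tracrRNA anti-repeat in the region.
#'
#' @param candidate_region Sequence string to scan.
#' @param repeat_seq The CRISPR repeat sequence.
#' @param min_match Window length (nt).
#' @param max_mismatch Mismatches tolerated per window.
#' @return A tibble of merged hits (`start`, `end` on the candidate,
#'   1-based inclusive); zero rows when there is no complementarity.
#' @export
anti_repeat_scan <- function(candidate_region, repeat_seq, min_match = 12L,
                             max_mismatch = 1L) {
  L <- nchar(candidate_region)
  empty <- tibble(start = integer(), end = integer())
  if (L < min_match) return(empty)
  starts <- seq_len(L - min_match + 1L)
  wins <- substr(rep(candidate_region, length(starts)), starts,
                 starts + min_match - 1L)
  rc <- reverse_complement(wins)
  rep_subj <- Biostrings::DNAString(repeat_seq)
  hit <- vapply(rc, function(w) {
    length(Biostrings::matchPattern(Biostrings::DNAString(w), rep_subj,
                                    max.mismatch = max_mismatch,
                                    fixed = TRUE)) > 0
  }, logical(1), USE.NAMES = FALSE)
  if (!any(hit)) return(empty)
  hs <- starts[hit]
  runs <- split(hs, cumsum(c(1L, diff(hs) > 1L)))
  bind_rows(lapply(runs, function(r) {
    tibble(start = r[1], end = r[length(r)] + min_match - 1L)
  }))
}
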