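#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join count n across all_of row_number
NULL

BASES <- c("A", "C", "G", "T")

`%+%` <- function(a, b) paste0(a, b)

#' Read and write FASTQ / FASTA files as read tibbles
#'
#' Reads are represented throughout the package as a tibble with columns
#' `id`, `sequence` and (for FASTQ) `quality`, one row per read.  Writing a
#' read tibble and reading it back reproduces it exactly on canonical
#' files.  Gzip-compressed input is read transparently.
#'
#' @param path File path.
#' @param reads A read tibble with columns `id`, `sequence` and, for FASTQ,
#'   `quality` (Phred+33 strings the same length as the sequence).
#' @return `read_fastq()` / `read_fasta()` return a read tibble;
#'   the writers return `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".fastq")
#' write_fastq(tibble::tibble(id = "r1", sequence = "ACGT", quality = "FFFF"), tf)
#' read_fastq(tf)
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(tibble(id = character(), sequence = character(), quality = character()))
  }
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("truncated FASTQ: record %d is incomplete in '%s'",
                  length(lines) %/% 4L + 1L, path))
  }
  i <- seq(1L, length(lines), by = 4L)
  hdr <- lines[i]
  seqs <- lines[i + 1L]
  qual <- lines[i + 3L]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    abort(sprintf("malformed FASTQ: record %d does not start with '@'", bad_hdr[1]))
  }
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    abort(sprintf("FASTQ record %d ('%s'): sequence and quality lengths differ",
                  bad[1], sub("^@", "", hdr[bad[1]])))
  }
  tibble(id = sub("^@", "", hdr), sequence = seqs, quality = qual)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  out <- character(4L * nrow(reads))
  if (nrow(reads)) {
    out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$id)
    out[c(FALSE, TRUE, FALSE, FALSE)] <- reads$sequence
    out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
    out[c(FALSE, FALSE, FALSE, TRUE)] <- reads$quality
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname read_fastq
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  tibble(id = names(ss), sequence = unname(as.character(ss)))
}

#' @rdname read_fastq
#' @export
write_fasta <- function(reads, path) {
  stopifnot(all(c("id", "sequence") %in% names(reads)))
  out <- character(2L * nrow(reads))
  if (nrow(reads)) {
    out[c(TRUE, FALSE)] <- paste0(">", reads$id)
    out[c(FALSE, TRUE)] <- reads$sequence
  }
  writeLines(out, path)
  invisible(path)
}

#' Reverse-complement nucleotide strings
#'
#' Vectorized over its input; `N` complements to `N`.
#'
#' @param sequence Character vector of sequences over `A,C,G,T,N`.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACGT")  # palindrome
#' @export
reverse_complement <- function(sequence) {
  if (!length(sequence)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sequence)))
}

#' Hamming distance between equal-length strings
#'
#' Vectorized over pairs; `N` mismatches every base including `N`?  No —
#' plain character comparison is used, so `N` matches `N` here; the
#' anchored matchers treat `N` conservatively (see [anchored_locate()]).
#'
#' @param a,b Character vectors of equal-length strings (recycled).
#' @return Integer vector of mismatch counts.
#' @export
hamming <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) abort("hamming() requires equal-length strings")
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b, USE.NAMES = FALSE)
}

.check_anchor <- function(anchor) {
  if (nchar(anchor) < 1L || grepl("[^ACGTN]", anchor)) {
    abort("anchor must be a non-empty string over A,C,G,T,N")
  }
}

#' Locate an anchor sequence in a read with bounded mismatches
#'
#' Alignment-free anchored matching: the best (fewest-mismatch) occurrence
#' of `anchor` in the read is reported, ties broken toward the smallest
#' offset with the plus strand preferred.  `N` in either read or anchor
#' counts as a mismatch (conservative for enrichment statistics).  Returns
#' `NULL` when no occurrence has at most `max_mismatch` mismatches.
#'
#' @param read A single sequence string (or a one-row read tibble).
#' @param anchor Anchor sequence over `A,C,G,T,N`.
#' @param max_mismatch Maximum tolerated mismatches.
#' @param search_both_strands Also scan the reverse complement of the read.
#' @return A one-row tibble with `offset` (0-based start of the anchor in
#'   the read, on the reported strand), `mismatches` and `strand`; or
#'   `NULL` if not found.
#' @examples
#' anchored_locate("TTTTACGTACGTTT", "ACGTACGT", max_mismatch = 0)
#' @export
anchored_locate <- function(read, anchor, max_mismatch = 1L,
                            search_both_strands = FALSE) {
  if (is.data.frame(read)) read <- read$sequence
  stopifnot(length(read) == 1L)
  .check_anchor(anchor)
  strands <- if (search_both_strands) c("+", "-") else "+"
  best <- NULL
  for (s in strands) {
    subj <- if (s == "+") read else reverse_complement(read)
    hit <- .locate_one(subj, anchor, max_mismatch)
    if (!is.null(hit) &&
        (is.null(best) || hit$mismatches < best$mismatches)) {
      best <- tibble(offset = hit$offset, mismatches = hit$mismatches, strand = s)
    }
  }
  best
}

# best occurrence of anchor in one subject, + strand, N always a mismatch
.locate_one <- function(subject, anchor, max_mismatch) {
  la <- nchar(anchor); ls <- nchar(subject)
  if (la > ls) return(NULL)
  subj <- Biostrings::DNAString(subject)
  pat <- Biostrings::DNAString(anchor)
  for (mm in 0:max_mismatch) {
    m <- Biostrings::matchPattern(pat, subj, max.mismatch = mm, fixed = TRUE)
    if (length(m)) {
      off <- Biostrings::start(m)[1] - 1L
      nmm <- Biostrings::neditStartingAt(pat, subj, starting.at = off + 1L,
                                         fixed = TRUE)
      return(list(offset = off, mismatches = as.integer(nmm)))
    }
  }
  NULL
}

# Vectorized anchored location over a character vector of reads: returns an
# integer vector of 0-based offsets (NA when absent).  Mismatch tiers are
# scanned in order so each read gets its fewest-mismatch, smallest-offset hit.
.locate_batch <- function(seqs, anchor, max_mismatch = 1L) {
  off <- rep(NA_integer_, length(seqs))
  mmv <- rep(NA_integer_, length(seqs))
  if (!length(seqs)) return(list(offset = off, mismatches = mmv))
  ss <- Biostrings::DNAStringSet(seqs)
  pat <- Biostrings::DNAString(anchor)
  todo <- seq_along(seqs)
  for (mm in 0:max_mismatch) {
    if (!length(todo)) break
    m <- Biostrings::vmatchPattern(pat, ss[todo], max.mismatch = mm, fixed = TRUE)
    st <- Biostrings::startIndex(m)
    found <- lengths(st) > 0L
    if (any(found)) {
      idx <- todo[found]
      off[idx] <- vapply(st[found], function(x) x[[1]], integer(1)) - 1L
      mmv[idx] <- mm
      todo <- todo[!found]
    }
  }
  list(offset = off, mismatches = mmv)
}

# exact mismatch counts of equal-length strings vs one pattern, vectorized;
# N on either side counts as a mismatch
.mismatch_count <- function(x, pattern) {
  L <- nchar(pattern)
  pat <- strsplit(pattern, "")[[1]]
  mm <- integer(length(x))
  for (j in seq_len(L)) {
    cj <- substr(x, j, j)
    mm <- mm + (cj != pat[j] | cj == "N" | pat[j] == "N")
  }
  as.integer(mm)
}

#' Merge a read pair into the sequenced molecule
#'
#' The mate `r2` is reverse-complemented and every overlap of at least
#' `min_overlap` bases (including full containment when the fragment is
#' shorter than a read) is scored; the merge succeeds when a unique best
#' overlap has at most `max_overlap_mismatch` mismatches.  At disagreeing
#' overlap positions the base with the higher Phred quality wins.
#'
#' @param r1,r2 One-row read tibbles (or plain lists with `sequence` and
#'   optionally `quality`); `r2` in sequencing orientation.
#' @param min_overlap Minimum overlap length in nt.
#' @param max_overlap_mismatch Maximum mismatches tolerated in the overlap.
#' @return A one-row read tibble for the merged molecule, or `NULL` when no
#'   unique acceptable overlap exists.
#' @export
merge_read_pair <- function(r1, r2, min_overlap = 10L, max_overlap_mismatch = 2L) {
  g <- function(r, f, d) if (is.data.frame(r)) r[[f]][1] %||% d else r[[f]] %||% d
  s1 <- g(r1, "sequence", NULL); s2 <- g(r2, "sequence", NULL)
  q1 <- g(r1, "quality", strrep("F", nchar(s1)))
  q2 <- g(r2, "quality", strrep("F", nchar(s2)))
  s2c <- reverse_complement(s2)
  q2c <- paste(rev(strsplit(q2, "")[[1]]), collapse = "")

  a <- charToRaw(s1); b <- charToRaw(s2c)
  qa <- as.integer(charToRaw(q1)) - 33L
  qb <- as.integer(charToRaw(q2c)) - 33L
  L1 <- length(a); L2 <- length(b)

  # shift d: position of b's first base relative to a's first base (0-based);
  # negative d lets the reverse mate extend 5' of r1.
  shifts <- seq.int(-(L2 - min_overlap), L1 - min_overlap)
  best <- NULL; best_mm <- Inf; n_best <- 0L
  for (d in shifts) {
    i1 <- max(1L, d + 1L); i2 <- min(L1, d + L2)
    if (i2 - i1 + 1L < min_overlap) next
    ia <- i1:i2; ib <- ia - d
    mm <- sum(a[ia] != b[ib])
    if (mm < best_mm) { best_mm <- mm; best <- d; n_best <- 1L }
    else if (mm == best_mm) n_best <- n_best + 1L
  }
  if (is.null(best) || best_mm > max_overlap_mismatch || n_best > 1L) return(NULL)

  d <- best
  start <- min(0L, d); end <- max(L1, d + L2)
  len <- end - start
  seq_out <- raw(len); q_out <- integer(len)
  pa <- (1:L1) - start; pb <- (d + 1:L2) - start
  seq_out[pa] <- a; q_out[pa] <- qa
  # overlap resolution: higher quality wins; b fills non-overlap positions
  take_b <- rep(TRUE, L2)
  ovl <- which(pb %in% pa)
  if (length(ovl)) {
    agree <- b[ovl] == seq_out[pb[ovl]]
    win_b <- qb[ovl] > q_out[pb[ovl]]
    q_out[pb[ovl]] <- ifelse(agree, pmax(q_out[pb[ovl]], qb[ovl]),
                             pmax(q_out[pb[ovl]], qb[ovl]))
    take_b[ovl] <- !agree & win_b
  }
  idx <- which(take_b | !(pb %in% pa))
  seq_out[pb[idx]] <- b[idx]
  q_out[pb[idx]] <- pmax(q_out[pb[idx]], qb[idx])
  tibble(
    id = g(r1, "id", "merged"),
    sequence = rawToChar(seq_out),
    quality = intToUtf8(pmin(q_out, 60L) + 33L)
  )
}
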