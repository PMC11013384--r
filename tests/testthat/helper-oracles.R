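# Independent brute-force oracles, written in plain R with no shared code
# with the package internals.  They scan every offset explicitly.

DNA <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

revcomp_oracle <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# mismatches with N counting as mismatch on either side
mm_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  sum(x != y | x == "N" | y == "N")
}

# best (fewest mismatches, then smallest offset) occurrence; 0-based offset
brute_locate <- function(seq, anchor, max_mm) {
  la <- nchar(anchor); ls <- nchar(seq)
  if (la > ls) return(NULL)
  best <- NULL
  for (off in 0:(ls - la)) {
    mm <- mm_oracle(substr(seq, off + 1, off + la), anchor)
    if (is.null(best) || mm < best$mm) best <- list(offset = off, mm = mm)
  }
  if (best$mm > max_mm) NULL else best
}

# exhaustive re-count of PAMs, mirroring the documented extraction rules
brute_extract <- function(seqs, flank5, flank3, pam_len = 7, max_mm = 1,
                          anchor_len = 12) {
  a5 <- substr(flank5, max(1, nchar(flank5) - anchor_len + 1), nchar(flank5))
  a3 <- substr(flank3, 1, min(anchor_len, nchar(flank3)))
  pams <- character(0); discarded <- 0
  for (s in seqs) {
    hit <- brute_locate(s, a5, max_mm)
    if (is.null(hit)) { discarded <- discarded + 1; next }
    p0 <- hit$offset + nchar(a5) + 1
    pam <- substr(s, p0, p0 + pam_len - 1)
    f3 <- substr(s, p0 + pam_len, p0 + pam_len + nchar(a3) - 1)
    if (nchar(pam) < pam_len || nchar(f3) < nchar(a3) ||
        mm_oracle(f3, a3) > max_mm || grepl("N", pam, fixed = TRUE)) {
      discarded <- discarded + 1; next
    }
    pams <- c(pams, pam)
  }
  list(counts = table(pams), total = length(pams), discarded = discarded)
}

# exhaustive junction re-count: offset of the adapter 5' base relative to
# the first protospacer base (anchor end + pam_len)
brute_junctions <- function(seqs, adapter, anchor, pam_len = 7,
                            window = c(0, 30), max_mm = 1) {
  counts <- setNames(rep(0, window[2] - window[1] + 1),
                     seq(window[1], window[2]))
  for (s in seqs) {
    ha <- brute_locate(s, anchor, max_mm)
    hd <- brute_locate(s, adapter, max_mm)
    if (is.null(ha) || is.null(hd)) next
    off <- hd$offset - (ha$offset + nchar(anchor) + pam_len)
    if (off >= window[1] && off <= window[2]) {
      counts[as.character(off)] <- counts[as.character(off)] + 1
    }
  }
  counts
}

# all candidate overlaps of r1 with revcomp(r2); returns shifts with the
# minimum mismatch count
brute_overlaps <- function(s1, s2, min_overlap = 10) {
  b <- revcomp_oracle(s2)
  L1 <- nchar(s1); L2 <- nchar(b)
  res <- data.frame(shift = integer(), mm = integer())
  for (d in (-(L2 - min_overlap)):(L1 - min_overlap)) {
    i1 <- max(1, d + 1); i2 <- min(L1, d + L2)
    if (i2 - i1 + 1 < min_overlap) next
    mm <- mm_oracle(substr(s1, i1, i2), substr(b, i1 - d, i2 - d))
    res <- rbind(res, data.frame(shift = d, mm = mm))
  }
  res
}

# pam_counts object built directly for arithmetic tests
make_pam_counts <- function(counts, pam_length = NULL) {
  pam_length <- pam_length %||% nchar(names(counts)[1])
  out <- tibble::tibble(pam = names(counts), count = as.integer(counts))
  structure(out, class = c("pam_counts", class(out)),
            pam_length = as.integer(pam_length),
            total = sum(counts), n_reads_discarded = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed_seq <- function(seed, n) {
  withr::with_seed(seed, random_seq(n))
}

all_kmers <- function(k) {
  g <- expand.grid(rep(list(DNA), k), stringsAsFactors = FALSE)
  sort(do.call(paste0, g))
}
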