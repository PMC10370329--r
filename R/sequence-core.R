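#' Reverse complement of DNA sequences
#'
#' Strict reverse complement over the alphabet \{A,C,G,T,N\}; any other
#' character is an error (sanitize on ingest with the readers, which map
#' unexpected IUPAC codes to N).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements (an involution:
#'   \code{revcomp(revcomp(x)) == x}).
#' @examples
#' revcomp("AAAC")  # "GTTT"
#' @export
revcomp <- function(x) {
  assert_dna(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Phred+33 helpers ------------------------------------------------------

#' Decode a Sanger Phred+33 quality string to integer scores
#' @param qual Quality string (one character per base).
#' @return Integer vector of Phred scores.
#' @export
phred_decode <- function(qual) {
  as.integer(charToRaw(qual)) - 33L
}

#' Encode integer Phred scores as a Sanger Phred+33 quality string
#' @param q Integer vector of Phred scores in [0, 60].
#' @return Quality string.
#' @export
phred_encode <- function(q) {
  stopifnot(all(q >= 0L & q <= 60L))
  rawToChar(as.raw(q + 33L))
}

# Quality trimming ------------------------------------------------------

trim_one <- function(seq, qual, window, min_avg_q, end_q, min_len, adapters) {
  # 1. adapter clip: exact-match search anywhere; clip from the leftmost
  #    adapter start to the read end
  if (length(adapters) > 0L) {
    starts <- vapply(adapters, function(ad) {
      p <- regexpr(ad, seq, fixed = TRUE)
      if (p > 0L) as.integer(p) else NA_integer_
    }, integer(1))
    if (any(!is.na(starts))) {
      cut <- min(starts, na.rm = TRUE)
      seq <- substr(seq, 1L, cut - 1L)
      qual <- qual[seq_len(cut - 1L)]
    }
  }
  n <- length(qual)
  # 2. leading/trailing bases with quality < end_q
  keep_from <- 1L
  while (keep_from <= n && qual[keep_from] < end_q) keep_from <- keep_from + 1L
  keep_to <- n
  while (keep_to >= keep_from && qual[keep_to] < end_q) keep_to <- keep_to - 1L
  if (keep_to < keep_from) {
    seq <- ""
    qual <- integer(0)
  } else {
    seq <- substr(seq, keep_from, keep_to)
    qual <- qual[keep_from:keep_to]
  }
  n <- length(qual)
  # 3. sliding window 5'->3': at the first window whose mean quality drops
  #    below min_avg_q, cut at the first individual base below min_avg_q
  #    within that window (a failing window always contains one)
  if (n >= window) {
    cs <- cumsum(c(0, qual))
    means <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
    fail <- which(means < min_avg_q)
    if (length(fail) > 0L) {
      i <- fail[1L]                       # window start (1-based)
      j <- i
      while (j <= n && qual[j] >= min_avg_q) j <- j + 1L
      seq <- substr(seq, 1L, j - 1L)
      qual <- qual[seq_len(j - 1L)]
    }
  }
  list(seq = seq, qual = qual, keep = nchar(seq) >= min_len)
}

#' Sliding-window quality trimming of short reads
#'
#' Trimmomatic-style trimming with a fixed stage order: adapter clip (exact
#' match anywhere in the read, clipping from the leftmost adapter start),
#' removal of leading/trailing bases with quality below \code{end_q}, a
#' 5'-to-3' sliding-window scan that cuts the read at the first base of
#' quality below \code{min_avg_q} inside the first window whose mean quality
#' drops below \code{min_avg_q}, and finally discarding reads shorter than
#' \code{min_len}. The defaults are the conventional short-read settings for
#' this analysis (window 4, mean quality 15, end quality 2, minimum length
#' 100).
#'
#' Trimming is idempotent and never increases the total retained base count.
#'
#' @param reads A reads data.frame as returned by [read_fastq()]: columns
#'   `read_id`, `sequence`, `quality` (Phred+33 string), `sample_id`.
#' @param window Sliding window size in bases.
#' @param min_avg_q Minimum mean Phred quality within a window.
#' @param end_q Minimum quality for retention at the read ends.
#' @param min_len Minimum read length after trimming; shorter reads are
#'   discarded.
#' @param adapters Character vector of adapter sequences (exact match).
#' @return List with `reads` (the surviving, trimmed reads data.frame) and
#'   `discarded` (read_ids removed by the length filter).
#' @export
quality_trim <- function(reads, window = 4L, min_avg_q = 15, end_q = 2,
                         min_len = 100L, adapters = character(0)) {
  stopifnot(window >= 1L, is.data.frame(reads))
  if (nrow(reads) == 0L) {
    return(list(reads = reads, discarded = character(0)))
  }
  out_seq <- character(nrow(reads))
  out_qual <- character(nrow(reads))
  keep <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    tr <- trim_one(reads$sequence[i], phred_decode(reads$quality[i]),
                   window, min_avg_q, end_q, min_len, adapters)
    out_seq[i] <- tr$seq
    out_qual[i] <- if (length(tr$qual)) phred_encode(tr$qual) else ""
    keep[i] <- tr$keep
  }
  kept <- reads
  kept$sequence <- out_seq
  kept$quality <- out_qual
  list(reads = kept[keep, , drop = FALSE],
       discarded = reads$read_id[!keep])
}
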