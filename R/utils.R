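# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Random uniform-composition DNA string(s).
random_dna <- function(n) {
  vapply(n, function(len) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Hamming distance between two equal-length strings (N counts as mismatch
# against anything but N; callers wanting conservative N handling substitute
# first).
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Vectorized Hamming distance over pairs of equal-length strings.
hamming_pairs <- function(a, b) {
  stopifnot(length(a) == length(b))
  vapply(seq_along(a), function(i) {
    sum(utf8ToInt(a[[i]]) != utf8ToInt(b[[i]]))
  }, integer(1))
}

# Replace bases of `seq` at 1-based `positions` with `new_bases`.
substitute_bases <- function(seq, positions, new_bases) {
  if (length(positions) == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[positions] <- new_bases
  paste(ch, collapse = "")
}

# For each reference base, draw a uniformly random different base.
random_alt_bases <- function(ref_bases) {
  vapply(ref_bases, function(b) {
    sample(setdiff(DNA_BASES, b), 1L)
  }, character(1), USE.NAMES = FALSE)
}

# Uppercase and enforce the {A,C,G,T,N} alphabet: any other character
# (ambiguity codes, U, gaps) is mapped to N with one warning per call.
sanitize_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    warning(sprintf("%d %s(s) contained non-ACGTN characters; mapped to N",
                    sum(bad), what), call. = FALSE)
    x[bad] <- gsub("[^ACGTN]", "N", x[bad])
  }
  x
}

# Assert that sequences use only the package alphabet (ingest contract).
assert_dna <- function(x, what = "sequence") {
  if (any(grepl("[^ACGTN]", x))) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}", what),
         call. = FALSE)
  }
  invisible(x)
}

# Translate a nucleotide string codon-by-codon; returns the 0-based codon
# index of the first stop codon, or NA when none occurs.
first_stop_codon <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(NA_integer_)
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  hit <- which(codons %in% STOP_CODONS)
  if (length(hit) == 0L) NA_integer_ else hit[1L] - 1L
}

# Positions (0-based) of all k-mers of `seq`, as a data.table(kmer, pos).
kmer_table <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(data.table(kmer = character(0), pos = integer(0)))
  starts <- seq_len(n - k + 1L)
  data.table(kmer = substring(seq, starts, starts + k - 1L),
             pos = starts - 1L)
}

# Derive a bounded child seed from a base seed (kept below 2^31).
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}
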