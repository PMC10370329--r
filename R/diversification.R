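# Per-position variant calling from pileups, fixed-window variant
# density, protospacer enrichment and sequence-logo matrices.

#' Per-position base counts from ungapped alignments
#'
#' Tallies A/C/G/T counts per reference position from the
#' reference-oriented read sequences of the alignments; N bases are
#' excluded from the counts (they contribute to depth but not to any
#' base).
#'
#' @param alignments Alignment data.frame ([map_reads()] / [read_sam()]).
#' @param ref_id Reference to pile up.
#' @param ref_length Reference length.
#' @return A `pileup`: list with `ref_id`, `counts` (4 x ref_length
#'   integer matrix, rows A,C,G,T) and `depth` (column sums plus Ns).
#' @export
pileup <- function(alignments, ref_id, ref_length) {
  a <- alignments[alignments$ref_id == ref_id, , drop = FALSE]
  counts <- matrix(0L, nrow = 4L, ncol = ref_length,
                   dimnames = list(DNA_BASES, NULL))
  depth <- integer(ref_length)
  if (nrow(a) > 0L) {
    codes <- lapply(a$seq, utf8ToInt)
    lens <- lengths(codes)
    stopifnot(all(lens == a$aligned_length))
    base_code <- unlist(codes, use.names = FALSE)
    pos <- rep(a$pos, lens) + sequence(lens)      # 1-based ref positions
    # map ASCII codes to base indices: A=65 C=67 G=71 T=84, else NA
    lut <- rep(NA_integer_, 128L)
    lut[c(65L, 67L, 71L, 84L)] <- 1:4
    bi <- lut[base_code]
    depth <- tabulate(pos, nbins = ref_length)
    keep <- !is.na(bi)
    idx <- (pos[keep] - 1L) * 4L + bi[keep]
    tallied <- tabulate(idx, nbins = 4L * ref_length)
    counts[] <- tallied
  }
  structure(list(ref_id = ref_id, counts = counts, depth = depth),
            class = "pileup")
}

#' Call per-position variants from a pileup
#'
#' A position is a variant when any non-reference base is supported by at
#' least `min_alt_reads` aligned reads; all qualifying alternate bases are
#' listed (one row each). The default threshold of one read mirrors
#' unfiltered variant lists used to maximize recovered variation; raise it
#' to suppress the sequencing-error floor (see the methods vignette).
#'
#' @param pile A `pileup`.
#' @param ref_seq Reference sequence (character).
#' @param min_alt_reads Minimum reads supporting the alternate base.
#' @return data.frame `ref_id`, `pos` (0-based), `ref_base`, `alt_base`,
#'   `alt_count`, `total_count`.
#' @export
call_variants <- function(pile, ref_seq, min_alt_reads = 1L) {
  L <- ncol(pile$counts)
  stopifnot(nchar(ref_seq) == L)
  ref_bases <- substring(ref_seq, seq_len(L), seq_len(L))
  ref_idx <- match(ref_bases, DNA_BASES)
  cnt <- pile$counts
  # zero out the reference base per column, then threshold the rest
  has_ref <- !is.na(ref_idx)
  cnt[cbind(ref_idx[has_ref], which(has_ref))] <- 0L
  hit <- which(cnt >= min_alt_reads, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return(data.frame(ref_id = character(0), pos = integer(0),
                      ref_base = character(0), alt_base = character(0),
                      alt_count = integer(0), total_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(
    ref_id = pile$ref_id,
    pos = hit[, "col"] - 1L,
    ref_base = ref_bases[hit[, "col"]],
    alt_base = DNA_BASES[hit[, "row"]],
    alt_count = cnt[hit],
    total_count = pile$depth[hit[, "col"]],
    stringsAsFactors = FALSE)
  out[order(out$pos, out$alt_base), , drop = FALSE]
}

#' Count variants in fixed, non-overlapping windows
#'
#' Windows tile the genome starting at position 0; the final window may be
#' short and is kept (counts are not length-normalized). Variant positions
#' with several alternate bases count once per row of `calls`.
#'
#' @param calls Variant calls from [call_variants()].
#' @param ref_length Reference length.
#' @param window Window size in bp (default 100).
#' @return data.frame `start`, `end` (0-based half-open), `n_variants`;
#'   the window counts sum to `nrow(calls)`.
#' @export
window_variant_counts <- function(calls, ref_length, window = 100L) {
  ref_length <- as.integer(ref_length)
  window <- as.integer(window)
  starts <- seq.int(0L, ref_length - 1L, by = window)
  ends <- pmin(starts + window, ref_length)
  n <- integer(length(starts))
  if (nrow(calls) > 0L) {
    stopifnot(all(calls$pos >= 0L & calls$pos < ref_length))
    w <- calls$pos %/% window + 1L
    n <- tabulate(w, nbins = length(starts))
  }
  data.frame(start = starts, end = ends, n_variants = n)
}

#' Variant enrichment over CRISPR-targeted windows
#'
#' Windows overlapping any protospacer interval by at least one bp are
#' "targeted"; the statistic is the ratio of the mean variant count in
#' targeted windows to the mean in the remaining (background) windows.
#'
#' @param windows Window counts from [window_variant_counts()].
#' @param protospacers data.frame of intervals (`start`, `end`, 0-based
#'   half-open) on the same reference, e.g. [match_spacers()] hits.
#' @return List: `mean_variants_targeted`, `mean_variants_background`,
#'   `ratio`, `n_targeted`, `n_background`, `undefined` (TRUE when the
#'   background mean is zero, in which case `ratio` is NA).
#' @export
protospacer_enrichment <- function(windows, protospacers) {
  stopifnot(nrow(windows) > 0L, nrow(protospacers) > 0L)
  targeted <- vapply(seq_len(nrow(windows)), function(i) {
    any(windows$start[i] < protospacers$end &
          windows$end[i] > protospacers$start)
  }, logical(1))
  if (!any(targeted) || all(targeted)) {
    stop("need at least one targeted and one background window",
         call. = FALSE)
  }
  mt <- mean(windows$n_variants[targeted])
  mb <- mean(windows$n_variants[!targeted])
  undefined <- mb == 0
  list(mean_variants_targeted = mt,
       mean_variants_background = mb,
       ratio = if (undefined) NA_real_ else mt / mb,
       n_targeted = sum(targeted),
       n_background = sum(!targeted),
       undefined = undefined)
}

#' Position frequency matrix and information content over a protospacer
#'
#' Builds the base-count matrix over an interval from reads whose
#' alignments fully span it (spanning-reads-only rule, as used for
#' protospacer sequence logos) and computes per-column information
#' content, `2 - H` bits where `H` is the Shannon entropy of the
#' normalized column.
#'
#' @param alignments Alignment data.frame.
#' @param ref_id Reference id.
#' @param interval `c(start, end)`, 0-based half-open interval on the
#'   reference; at least one alignment must span it.
#' @return A `pfm`: list with `interval`, `counts` (4 x width matrix),
#'   `information` (bits per column, in \[0, 2\]) and `n_reads`.
#' @export
protospacer_logo <- function(alignments, ref_id, interval) {
  st <- interval[1]; en <- interval[2]
  a <- alignments[alignments$ref_id == ref_id &
                    alignments$pos <= st &
                    alignments$pos + alignments$aligned_length >= en, ,
                  drop = FALSE]
  if (nrow(a) == 0L) {
    stop("no alignment fully spans the interval", call. = FALSE)
  }
  w <- en - st
  sub <- substring(a$seq, st - a$pos + 1L, en - a$pos)
  mat <- matrix(unlist(strsplit(sub, ""), use.names = FALSE),
                nrow = nrow(a), byrow = TRUE)
  counts <- vapply(seq_len(w), function(j) {
    tabulate(match(mat[, j], DNA_BASES), nbins = 4L)
  }, integer(4))
  rownames(counts) <- DNA_BASES
  info <- apply(counts, 2L, function(cc) {
    tot <- sum(cc)
    if (tot == 0L) return(0)
    p <- cc[cc > 0L] / tot
    2 + sum(p * log2(p))
  })
  structure(list(interval = c(st, en), counts = counts,
                 information = info, n_reads = nrow(a)),
            class = "pfm")
}
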