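# Read mapping, per-position coverage tracks and RPKM abundance.
#
# The internal mapper is deliberately simple: candidate placements are
# found by exact seed k-mer lookup on both strands and scored by
# substitution count over the full read (ungapped, end-to-end); the best
# placement is reported when its mismatch count is within the rate bound,
# with ties broken uniformly at random under a recorded seed. Users with
# an external mapper can import ungapped SAM via read_sam() instead.

build_kmer_index <- function(seqs, k) {
  idx <- lapply(names(seqs), function(ref) {
    kt <- kmer_table(seqs[[ref]], k)
    kt[, `:=`(ref_id = ref)]
    kt
  })
  out <- data.table::rbindlist(idx)
  data.table::setkey(out, kmer)
  out
}

#' Map reads to reference genomes (best ungapped placement)
#'
#' @param reads Reads data.frame (`read_id`, `sequence`, `sample_id`).
#' @param refs Named [Biostrings::DNAStringSet] or named character vector.
#' @param seed_k Exact seed k-mer size (the read's first k bases on each
#'   strand).
#' @param max_mismatch_rate Maximum substitutions per read base for a
#'   placement to be reported.
#' @param rng_seed Seed for uniform tie-breaking among equally good
#'   placements.
#' @return Alignment data.frame: `read_id`, `sample_id`, `ref_id`, `pos`
#'   (0-based leftmost), `strand`, `mismatches`, `aligned_length`, `seq`
#'   (read in reference orientation). Unmapped reads are omitted.
#' @export
map_reads <- function(reads, refs, seed_k = 15L, max_mismatch_rate = 0.05,
                      rng_seed = 1L) {
  seqs <- if (is.character(refs)) refs else
    setNames(as.character(refs), names(refs))
  stopifnot(all(nchar(reads$sequence) >= seed_k))
  index <- build_kmer_index(seqs, seed_k)
  ref_len <- nchar(seqs)

  rl <- nchar(reads$sequence)
  fwd <- reads$sequence
  rcv <- revcomp(reads$sequence)
  q <- data.table::rbindlist(list(
    data.table(read_idx = seq_len(nrow(reads)), strand = "+",
               kmer = substr(fwd, 1L, seed_k), oriented = fwd),
    data.table(read_idx = seq_len(nrow(reads)), strand = "-",
               kmer = substr(rcv, 1L, seed_k), oriented = rcv)))
  cand <- index[q, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(cand) == 0L) return(empty_alignments())
  cand[, `:=`(read_len = rl[read_idx])]
  cand <- cand[cand$pos + cand$read_len <= ref_len[cand$ref_id], ]
  if (nrow(cand) == 0L) return(empty_alignments())
  # score every candidate: full-read Hamming distance against the reference
  cand[, `:=`(mm = {
    refchunk <- substring(seqs[[.BY$ref_id]], pos + 1L, pos + read_len)
    hamming_pairs(oriented, refchunk)
  }), by = "ref_id"]
  cand <- cand[cand$mm <= floor(max_mismatch_rate * cand$read_len), ]
  if (nrow(cand) == 0L) return(empty_alignments())
  best <- with_seed(rng_seed, {
    cand[, `:=`(rnd = runif(.N))]
    data.table::setorder(cand, read_idx, mm, rnd)
    cand[!duplicated(cand$read_idx), ]
  })
  out <- data.frame(
    read_id = reads$read_id[best$read_idx],
    sample_id = if ("sample_id" %in% names(reads))
      reads$sample_id[best$read_idx] else NA_character_,
    ref_id = best$ref_id,
    pos = best$pos,
    strand = best$strand,
    mismatches = best$mm,
    aligned_length = best$read_len,
    seq = best$oriented,
    stringsAsFactors = FALSE)
  out[order(out$ref_id, out$pos, out$read_id), , drop = FALSE]
}

#' Per-position coverage track for one reference
#'
#' The sum of the depth vector always equals the summed aligned length of
#' the records on the reference (depth conservation). The normalized track
#' divides depth by the total number of (trimmed, filtered) sample reads,
#' the convention used for cross-sample comparison of coverage profiles.
#'
#' @param alignments Alignment data.frame ([map_reads()] or [read_sam()]).
#' @param ref_id Reference to profile.
#' @param ref_length Reference length (bp).
#' @param total_sample_reads Total reads in the sample (normalization
#'   denominator).
#' @return A `coverage_track`: list with `ref_id`, `depth` (integer
#'   vector, one per position) and `normalized`.
#' @export
coverage_track <- function(alignments, ref_id, ref_length,
                           total_sample_reads = NA_real_) {
  a <- alignments[alignments$ref_id == ref_id, , drop = FALSE]
  delta <- numeric(ref_length + 1L)
  if (nrow(a) > 0L) {
    stopifnot(all(a$pos + a$aligned_length <= ref_length))
    add <- tabulate(a$pos + 1L, nbins = ref_length + 1L)
    sub <- tabulate(a$pos + a$aligned_length + 1L, nbins = ref_length + 1L)
    delta <- add - sub
  }
  depth <- cumsum(delta)[seq_len(ref_length)]
  structure(list(ref_id = ref_id,
                 depth = depth,
                 normalized = depth / total_sample_reads),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("Coverage track for %s: %d bp, mean depth %.2f, max %d\n",
              x$ref_id, length(x$depth), mean(x$depth), max(x$depth)))
  invisible(x)
}

#' Reads per kilobase per million sample reads
#'
#' `RPKM = mapped_reads / (length_bp / 1000) / (total_reads / 1e6)`: read
#' counts normalized to reference length in kb and to sample sequencing
#' depth in millions of reads.
#'
#' @param mapped_reads Reads mapped to the reference.
#' @param length_bp Reference length (must be positive).
#' @param total_reads Total sample reads (must be positive).
#' @return The RPKM value.
#' @examples
#' rpkm(1000, 10000, 1e6)  # 100
#' @export
rpkm <- function(mapped_reads, length_bp, total_reads) {
  if (any(length_bp <= 0)) stop("length_bp must be positive", call. = FALSE)
  if (any(total_reads <= 0)) stop("total_reads must be positive",
                                  call. = FALSE)
  mapped_reads / (length_bp / 1000) / (total_reads / 1e6)
}

#' Per-genome, per-sample RPKM abundance table
#'
#' Counts primary read placements per reference and sample and converts
#' them to RPKM. Contigs can be grouped into genome bins (MAGs) with
#' `bins`; a bin's count and length are the sums over its contigs.
#'
#' @param alignments Alignment data.frame with a `sample_id` column.
#' @param ref_lengths Named vector of reference lengths.
#' @param total_reads Named vector: total reads per sample (the
#'   normalization denominator, including unmapped reads).
#' @param bins Optional named character vector mapping `ref_id` to bin
#'   label.
#' @return data.frame `ref_id`, `sample_id`, `mapped_reads`, `length_bp`,
#'   `rpkm` (zero rows for references without reads are included).
#' @export
abundance_table <- function(alignments, ref_lengths, total_reads,
                            bins = NULL) {
  if (is.null(bins)) {
    bins <- setNames(names(ref_lengths), names(ref_lengths))
  }
  stopifnot(all(names(ref_lengths) %in% names(bins)))
  bin_len <- tapply(ref_lengths, bins[names(ref_lengths)], sum)
  samples <- names(total_reads)
  grid <- expand.grid(ref_id = names(bin_len), sample_id = samples,
                      stringsAsFactors = FALSE)
  a <- alignments
  a$bin <- bins[a$ref_id]
  cnt <- table(factor(a$bin, levels = names(bin_len)),
               factor(a$sample_id, levels = samples))
  grid$mapped_reads <- as.integer(cnt[cbind(grid$ref_id, grid$sample_id)])
  grid$length_bp <- as.numeric(bin_len[grid$ref_id])
  grid$rpkm <- rpkm(grid$mapped_reads, grid$length_bp,
                    total_reads[grid$sample_id])
  grid[order(grid$ref_id, grid$sample_id), , drop = FALSE]
}
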