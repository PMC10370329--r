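# Readers and writers for the standard formats every stage touches.
#
# Coordinate convention: 0-based half-open everywhere in memory; GFF3 and
# SAM are converted to 1-based at the serialization boundary, BED stays
# 0-based.

#' Read genome/contig sequences from a FASTA file
#'
#' Sequences are uppercased and restricted to the \{A,C,G,T,N\} alphabet;
#' IUPAC ambiguity codes and other unexpected characters are mapped to N
#' with a warning.
#'
#' @param path FASTA file.
#' @return Named [Biostrings::DNAStringSet] (names are the full header
#'   lines).
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) return(Biostrings::DNAStringSet())
  x <- Biostrings::readDNAStringSet(path)
  ch <- sanitize_dna(as.character(x), what = "FASTA record")
  out <- Biostrings::DNAStringSet(ch)
  names(out) <- names(x)
  out
}

#' Write sequences to a FASTA file
#' @param x Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read short reads from a FASTQ file (Sanger Phred+33)
#'
#' A minimal strict parser for 4-line FASTQ records; malformed records
#' raise an error naming the offending line.
#'
#' @param path FASTQ file.
#' @param sample_id Label of the originating metagenome sample, recorded on
#'   every read.
#' @return data.frame with columns `read_id`, `sequence`, `quality`,
#'   `sample_id`.
#' @export
read_fastq <- function(path, sample_id = NA_character_) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("%s: truncated FASTQ record at line %d", path,
                 length(lines)), call. = FALSE)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0), sample_id = character(0),
                      stringsAsFactors = FALSE))
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop(sprintf("%s: expected '@' header at line %d", path,
                 (bad[1L] - 1L) * 4L + 1L), call. = FALSE)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop(sprintf("%s: expected '+' separator at line %d", path,
                 (bad[1L] - 1L) * 4L + 3L), call. = FALSE)
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop(sprintf("%s: quality length differs from sequence length at line %d",
                 path, (bad[1L] - 1L) * 4L + 4L), call. = FALSE)
  }
  data.frame(read_id = sub("^@", "", sub(" .*$", "", hdr)),
             sequence = sanitize_dna(seqs, what = "FASTQ record"),
             quality = quals,
             sample_id = rep(sample_id, n),
             stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#' @param reads Reads data.frame (see [read_fastq()]).
#' @param path Output file.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  writeLines(sprintf("@%s\n%s\n+\n%s", reads$read_id, reads$sequence,
                     reads$quality), path, sep = "\n")
  invisible(path)
}

# SAM (header + ungapped records) --------------------------------------

#' Write ungapped alignments as SAM
#'
#' Emits a header (`@HD`, one `@SQ` per reference) and one record per
#' alignment with CIGAR `<len>M` and an `NM:i:` mismatch tag. SAM is
#' 1-based; internal 0-based positions are converted on output.
#'
#' @param alignments Alignment data.frame from [map_reads()] (columns
#'   `read_id`, `ref_id`, `pos`, `strand`, `mismatches`, `aligned_length`,
#'   `seq`; `seq` is the read in reference orientation).
#' @param ref_lengths Named integer vector of reference lengths.
#' @param path Output file.
#' @export
write_sam <- function(alignments, ref_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  if (nrow(alignments) > 0L) {
    rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                   alignments$read_id,
                   ifelse(alignments$strand == "-", 16L, 0L),
                   alignments$ref_id,
                   alignments$pos + 1L,
                   alignments$aligned_length,
                   alignments$seq,
                   alignments$mismatches)
  } else {
    rec <- character(0)
  }
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read ungapped alignments from a SAM file
#'
#' Supports the subset written by [write_sam()]: header lines plus mapped,
#' ungapped records (CIGAR `<len>M`). Anything else raises an error naming
#' the line.
#'
#' @param path SAM file.
#' @return List with `refs` (data.frame `ref_id`, `length`) and
#'   `alignments` (data.frame as in [map_reads()], positions 0-based).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  hdr <- lines[is_hdr]
  sq <- hdr[startsWith(hdr, "@SQ")]
  refs <- data.frame(
    ref_id = sub(".*\tSN:([^\t]+).*", "\\1", sq),
    length = as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq)),
    stringsAsFactors = FALSE)
  body_idx <- which(!is_hdr)
  if (length(body_idx) == 0L) {
    return(list(refs = refs, alignments = empty_alignments()))
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop(sprintf("%s: malformed SAM record at line %d", path,
                 body_idx[which(nf < 11L)[1L]]), call. = FALSE)
  }
  cig <- vapply(fields, `[[`, "", 6L)
  bad <- !grepl("^[0-9]+M$", cig)
  if (any(bad)) {
    stop(sprintf("%s: unsupported CIGAR '%s' at line %d (only ungapped <len>M)",
                 path, cig[which(bad)[1L]], body_idx[which(bad)[1L]]),
         call. = FALSE)
  }
  nm <- vapply(fields, function(f) {
    tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1L])) else NA_integer_
  }, integer(1))
  data.frame(
    read_id = vapply(fields, `[[`, "", 1L),
    ref_id = vapply(fields, `[[`, "", 3L),
    pos = as.integer(vapply(fields, `[[`, "", 4L)) - 1L,
    strand = ifelse(bitwAnd(as.integer(vapply(fields, `[[`, "", 2L)), 16L) > 0L,
                    "-", "+"),
    mismatches = nm,
    aligned_length = as.integer(sub("M$", "", cig)),
    seq = vapply(fields, `[[`, "", 10L),
    stringsAsFactors = FALSE) -> aln
  list(refs = refs, alignments = aln)
}

empty_alignments <- function() {
  data.frame(read_id = character(0), ref_id = character(0),
             pos = integer(0), strand = character(0),
             mismatches = integer(0), aligned_length = integer(0),
             seq = character(0), stringsAsFactors = FALSE)
}

# Feature export --------------------------------------------------------

features_to_granges <- function(features) {
  stopifnot(all(c("ref_id", "start", "end") %in% names(features)))
  strand <- if ("strand" %in% names(features)) features$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = features$ref_id,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = strand)
  gr
}

#' Write genomic features as GFF3 (1-based on output)
#'
#' @param features data.frame with `ref_id`, `start`, `end` (0-based
#'   half-open), optional `strand`, `type`, `id`.
#' @param path Output file.
#' @export
write_gff3 <- function(features, path) {
  gr <- features_to_granges(features)
  S4Vectors::mcols(gr)$type <- if ("type" %in% names(features))
    features$type else "region"
  S4Vectors::mcols(gr)$source <- "berrylink"
  if ("id" %in% names(features)) S4Vectors::mcols(gr)$ID <- features$id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write genomic features as BED6 (0-based, as internally)
#'
#' @inheritParams write_gff3
#' @export
write_bed <- function(features, path) {
  gr <- features_to_granges(features)
  if ("id" %in% names(features)) names(gr) <- features$id
  S4Vectors::mcols(gr)$score <- if ("score" %in% names(features))
    features$score else 0
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
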