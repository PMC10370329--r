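# Repeat-anchored spacer mining from unassembled reads.
#
# Spacers are extracted from quality-trimmed reads as the subsequence
# strictly between two consecutive hits of a known repeat on the same
# strand; one-sided ("partial") candidates are excluded from the catalog
# but kept for diagnostics. Candidates are canonicalized to the repeat
# orientation of the repeat set, so minus-strand reads yield the same
# catalog as plus-strand reads. A spacer's support is the number of
# distinct reads yielding it adjacent to its repeat; records below the
# neighbor-support threshold are dropped. Reverse-complement spacer pairs
# arising under different repeats are deliberately kept distinct.

#' Find approximate occurrences of a repeat in a single read
#'
#' Reports every position where the repeat, on either strand, matches the
#' read with at most `max_mismatch` substitutions (ungapped, full repeat
#' inside the read).
#'
#' @param read Read sequence (character).
#' @param repeat_seq Repeat sequence (character); must not exceed the read
#'   length.
#' @param max_mismatch Substitution tolerance.
#' @return data.frame with `position` (0-based start in the read, sorted)
#'   and `strand` (`+` when the repeat matches as given, `-` when its
#'   reverse complement does).
#' @export
find_repeat_hits <- function(read, repeat_seq, max_mismatch = 2L) {
  stopifnot(nchar(repeat_seq) <= nchar(read))
  subj <- Biostrings::DNAString(read)
  hit1 <- clean_matches(Biostrings::matchPattern(
    repeat_seq, subj, max.mismatch = max_mismatch), nchar(read))
  hit2 <- clean_matches(Biostrings::matchPattern(
    revcomp(repeat_seq), subj, max.mismatch = max_mismatch), nchar(read))
  out <- data.frame(
    position = c(hit1, hit2) - 1L,
    strand = rep(c("+", "-"), c(length(hit1), length(hit2))),
    stringsAsFactors = FALSE)
  out[order(out$position, out$strand), , drop = FALSE]
}

clean_matches <- function(m, width) {
  st <- IRanges::start(m)
  en <- IRanges::end(m)
  st[st >= 1L & en <= width]
}

# Bulk variant: 0-based start positions of `pattern` in each read
# (data.table read_idx, pos), full matches only.
bulk_hits <- function(pattern, reads_set, max_mismatch) {
  m <- Biostrings::vmatchPattern(pattern, reads_set,
                                 max.mismatch = max_mismatch)
  idx <- rep(seq_along(m), lengths(m))
  ir <- unlist(m, use.names = FALSE)
  if (length(idx) == 0L) {
    return(data.table(read_idx = integer(0), pos = integer(0)))
  }
  st <- IRanges::start(ir); en <- IRanges::end(ir)
  w <- Biostrings::width(reads_set)[idx]
  keep <- st >= 1L & en <= w
  data.table(read_idx = idx[keep], pos = st[keep] - 1L)
}

#' Mine CRISPR spacers from reads anchored on a repeat set
#'
#' For every repeat whose length is within `approx_repeat_size` +/- 12 and
#' every read, repeat hits are located on both strands (ungapped, at most
#' `max_mismatch` substitutions); the subsequence strictly between two
#' consecutive same-strand hits whose length is inside `spacer_len` is a
#' full spacer candidate, canonicalized to the repeat's orientation.
#' Candidates seen in fewer than `min_neighbor_support` distinct reads are
#' dropped. Each retained spacer inherits the taxon of its repeat. Spacer
#' ids are `repeatID-serial` with serials assigned by descending support,
#' ties broken lexicographically by sequence.
#'
#' @param reads Reads data.frame (columns `read_id`, `sequence`,
#'   `sample_id`), normally quality-trimmed and merged across samples.
#' @param repeat_set Repeat set data.frame from [dereplicate_repeats()].
#' @param approx_repeat_size Centre of the accepted repeat-length window.
#' @param min_neighbor_support Minimum distinct supporting reads.
#' @param spacer_len Length-2 bounds on spacer length.
#' @param max_mismatch Substitution tolerance for repeat hits.
#' @return A `spacer_catalog`: list with `records` (data.frame `spacer_id`,
#'   `repeat_id`, `taxon`, `sequence`, `support`, plus one `support_<sample>`
#'   column per sample), `partials` (count of one-sided candidates, by
#'   repeat), and `provenance` (read count and repeat set size).
#' @export
extract_spacers <- function(reads, repeat_set, approx_repeat_size = 36L,
                            min_neighbor_support = 2L,
                            spacer_len = c(18L, 60L),
                            max_mismatch = 2L) {
  stopifnot(nrow(repeat_set) > 0L)
  samples <- unique(reads$sample_id)
  reads_fwd <- Biostrings::DNAStringSet(reads$sequence)
  reads_rc <- Biostrings::reverseComplement(reads_fwd)
  rc_seqs <- as.character(reads_rc)
  rlen <- nchar(reads$sequence)

  all_records <- list()
  partials <- integer(0)
  for (ri in seq_len(nrow(repeat_set))) {
    rep_seq <- repeat_set$sequence[ri]
    L <- nchar(rep_seq)
    if (abs(L - approx_repeat_size) > 12L) {
      warning(sprintf("repeat %s (length %d) outside the size window; skipped",
                      repeat_set$repeat_id[ri], L), call. = FALSE)
      next
    }
    # hits of the repeat in forward reads and in reverse-complemented reads:
    # the latter are minus-strand anchors, already in repeat orientation
    cand <- list(); n_partial <- 0L
    for (orient in c("fwd", "rc")) {
      seqs <- if (orient == "fwd") reads$sequence else rc_seqs
      hits <- bulk_hits(rep_seq, if (orient == "fwd") reads_fwd else reads_rc,
                        max_mismatch)
      if (nrow(hits) == 0L) next
      data.table::setorder(hits, read_idx, pos)
      nh <- hits[, .N, by = "read_idx"]
      n_partial <- n_partial + sum(nh$N == 1L)
      multi <- nh$read_idx[nh$N >= 2L]
      h <- hits[hits$read_idx %in% multi, ]
      if (nrow(h) == 0L) next
      nxt_pos <- c(h$pos[-1L], NA_integer_)
      nxt_read <- c(h$read_idx[-1L], NA_integer_)
      pair <- which(nxt_read == h$read_idx)
      gap_start <- h$pos[pair] + L          # 0-based
      gap_end <- nxt_pos[pair]
      glen <- gap_end - gap_start
      ok <- glen >= spacer_len[1] & glen <= spacer_len[2]
      if (!any(ok)) next
      idx <- h$read_idx[pair][ok]
      sp <- substring(seqs[idx], gap_start[ok] + 1L, gap_end[ok])
      cand[[orient]] <- data.table(read_idx = idx, sequence = sp)
    }
    partials[repeat_set$repeat_id[ri]] <- n_partial
    if (length(cand) == 0L) next
    cand <- data.table::rbindlist(cand)
    # distinct reads per (sequence): a read yielding the same spacer twice
    # (or on both strands) counts once
    cand <- unique(cand)
    cand[, `:=`(sample = reads$sample_id[cand$read_idx])]
    supp <- cand[, list(support = .N), by = "sequence"]
    per_sample <- cand[, list(n = .N), by = c("sequence", "sample")]
    supp <- supp[supp$support >= min_neighbor_support, ]
    if (nrow(supp) == 0L) next
    data.table::setorder(supp, -support, sequence)
    rec <- data.frame(
      spacer_id = sprintf("%s-%d", repeat_set$repeat_id[ri],
                          seq_len(nrow(supp))),
      repeat_id = repeat_set$repeat_id[ri],
      taxon = repeat_set$taxa[ri],
      sequence = supp$sequence,
      support = supp$support,
      stringsAsFactors = FALSE)
    for (s in samples) {
      ps <- per_sample[per_sample$sample == s, ]
      rec[[paste0("support_", s)]] <-
        ifelse(is.na(match(rec$sequence, ps$sequence)), 0L,
               ps$n[match(rec$sequence, ps$sequence)])
    }
    all_records[[length(all_records) + 1L]] <- rec
  }
  records <- if (length(all_records)) {
    do.call(rbind, c(all_records, list(make.row.names = FALSE)))
  } else {
    data.frame(spacer_id = character(0), repeat_id = character(0),
               taxon = character(0), sequence = character(0),
               support = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(records = records,
                 partials = partials,
                 provenance = list(n_reads = nrow(reads),
                                   n_repeats = nrow(repeat_set))),
            class = "spacer_catalog")
}

#' @export
print.spacer_catalog <- function(x, ...) {
  cat(sprintf("Spacer catalog: %d spacers from %d repeats (%d reads scanned)\n",
              nrow(x$records), x$provenance$n_repeats, x$provenance$n_reads))
  invisible(x)
}

#' Count reads containing each catalog spacer
#'
#' Per spacer, the number of reads containing the spacer sequence on either
#' strand within `max_mismatch` substitutions (a read counts once even if
#' it contains the spacer several times). Used to compare spacer abundance
#' with target phage abundance.
#'
#' @param catalog A `spacer_catalog` (or its `records` data.frame).
#' @param reads Reads data.frame.
#' @param max_mismatch Substitution tolerance (default exact).
#' @return data.frame `spacer_id`, `reads`.
#' @export
spacer_read_coverage <- function(catalog, reads, max_mismatch = 0L) {
  records <- if (inherits(catalog, "spacer_catalog")) catalog$records
             else catalog
  stopifnot(nrow(records) > 0L)
  subj <- Biostrings::DNAStringSet(reads$sequence)
  counts <- vapply(records$sequence, function(sp) {
    f <- Biostrings::vcountPattern(sp, subj, max.mismatch = max_mismatch)
    r <- Biostrings::vcountPattern(revcomp(sp), subj,
                                   max.mismatch = max_mismatch)
    sum(f + r > 0L)
  }, integer(1), USE.NAMES = FALSE)
  data.frame(spacer_id = records$spacer_id, reads = counts,
             stringsAsFactors = FALSE)
}
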