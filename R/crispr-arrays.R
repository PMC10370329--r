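# CRT-style CRISPR array detection and repeat dereplication.

#' Detect CRISPR arrays in an assembled genome
#'
#' A CRT-style detector: exact `seed_k`-mers recurring at a spacing
#' compatible with one repeat plus one spacer seed candidate chains of
#' array units; the seed is then extended left and right into a repeat
#' consensus while the columns stay near-unanimous across copies (a column
#' is accepted when at most `min(max_repeat_mismatch, floor(0.1 n))` copies
#' disagree with the column majority and no copy accumulates more than
#' `max_repeat_mismatch` mismatches against the consensus). Arrays are
#' reported when they reach `min_repeats` units with the repeat length and
#' all spacer lengths inside the configured bounds; chains violating a
#' spacer bound are split into maximal compliant runs. Overlapping calls
#' sharing a repeat interval are merged (the call with more units wins).
#'
#' Repeats on the reverse strand form exact direct repeats on the forward
#' strand too, so single-strand scanning is strand-consistent: running on
#' the reverse-complemented genome yields the same arrays with mirrored
#' coordinates.
#'
#' @param genome Genome sequence (character string or
#'   [Biostrings::DNAString]).
#' @param genome_id Identifier recorded on each array.
#' @param min_repeats Minimum number of repeat units.
#' @param repeat_len Length-2 numeric bounds on the repeat length.
#' @param spacer_len Length-2 numeric bounds on spacer lengths.
#' @param seed_k Exact seed k-mer size.
#' @param max_repeat_mismatch Edit tolerance of each repeat copy against
#'   the consensus.
#' @return List of `crispr_array` objects: `genome_id`,
#'   `repeat_consensus`, `repeat_intervals` (data.frame `start`, `end`,
#'   0-based half-open, genome order), `spacers` (character vector),
#'   `n_units`. Empty list when no array is found.
#' @export
detect_arrays <- function(genome, genome_id = "genome",
                          min_repeats = 3L,
                          repeat_len = c(19L, 48L),
                          spacer_len = c(18L, 60L),
                          seed_k = 8L,
                          max_repeat_mismatch = 2L) {
  g <- as.character(genome)
  n <- nchar(g)
  stopifnot(n > 2L * repeat_len[2])
  d_min <- repeat_len[1] + spacer_len[1]
  d_max <- repeat_len[2] + spacer_len[2]

  kt <- kmer_table(g, seed_k)
  counts <- kt[, .N, by = "kmer"]
  cand <- counts[counts$N >= min_repeats, ]$kmer
  if (length(cand) == 0L) return(list())
  kt <- kt[kt$kmer %in% cand, ]
  data.table::setorder(kt, pos)
  pos_by_kmer <- split(kt$pos, kt$kmer)
  # process seeds in genome order of first occurrence
  ord <- order(vapply(pos_by_kmer, `[`, 0L, 1L))
  pos_by_kmer <- pos_by_kmer[ord]

  covered <- logical(n)
  results <- list()
  for (p in pos_by_kmer) {
    if (all(covered[p + 1L])) next
    chains <- chain_positions(p, d_min, d_max, min_repeats)
    for (ch in chains) {
      if (all(covered[ch + 1L])) next
      arr <- extend_chain(g, ch, seed_k, repeat_len, spacer_len,
                          min_repeats, max_repeat_mismatch, genome_id)
      for (a in arr) {
        results[[length(results) + 1L]] <- a
        for (r in seq_len(nrow(a$repeat_intervals))) {
          covered[(a$repeat_intervals$start[r] + 1L):
                    a$repeat_intervals$end[r]] <- TRUE
        }
      }
    }
  }
  merge_overlapping_arrays(results)
}

# Greedy chaining of seed positions with gaps inside [d_min, d_max].
chain_positions <- function(p, d_min, d_max, min_repeats) {
  chains <- list()
  used <- logical(length(p))
  for (i in seq_along(p)) {
    if (used[i]) next
    ch <- p[i]
    used[i] <- TRUE
    last <- p[i]
    for (j in seq_along(p)) {
      if (used[j]) next
      gap <- p[j] - last
      if (gap >= d_min && gap <= d_max) {
        ch <- c(ch, p[j])
        used[j] <- TRUE
        last <- p[j]
      } else if (p[j] - last > d_max) break
    }
    if (length(ch) >= min_repeats) chains[[length(chains) + 1L]] <- ch
  }
  chains
}

col_majority <- function(bases) {
  tab <- table(bases)
  names(tab)[which.max(tab)]          # which.max: first = alphabetical tie
}

# Extend a chain of seed positions into full repeat copies, derive the
# consensus, and cut the chain into spacer-compliant arrays.
extend_chain <- function(g, ch, k, repeat_len, spacer_len, min_repeats,
                         max_mm, genome_id) {
  nc <- length(ch)
  allow_col <- min(max_mm, floor(0.1 * nc))
  budget <- integer(nc)
  min_gap <- min(diff(ch))

  ext <- function(dir, base) {          # dir -1 = left, +1 = right
    len <- 0L
    repeat {
      off <- len + 1L
      idx <- if (dir < 0L) ch - off + 1L else ch + k + off
      if (any(idx < 1L) || any(idx > nchar(g))) break
      if (base + len + 1L > repeat_len[2]) break
      if (base + len + 1L >= min_gap) break  # never consume the whole spacer
      col <- substring(g, idx, idx)
      maj <- col_majority(col)
      dis <- col != maj
      if (sum(dis) > allow_col) break
      if (any(budget + dis > max_mm)) break
      budget <<- budget + dis
      len <- off
    }
    len
  }
  left <- ext(-1L, k)
  right <- ext(+1L, k + left)
  rep_len <- k + left + right
  if (rep_len < repeat_len[1] || rep_len > repeat_len[2]) {
    # a spurious chained seed occurrence suppresses extension across all
    # copies; retry without a terminal chain member
    if (nc > min_repeats) {
      for (sub in list(ch[-nc], ch[-1L])) {
        arr <- extend_chain(g, sub, k, repeat_len, spacer_len,
                            min_repeats, max_mm, genome_id)
        if (length(arr)) return(arr)
      }
    }
    return(list())
  }

  starts <- ch - left                    # 0-based
  ends <- starts + rep_len
  spacer_lens <- starts[-1L] - ends[-nc]
  ok <- spacer_lens >= spacer_len[1] & spacer_lens <= spacer_len[2]

  # maximal runs of units connected by compliant spacers
  out <- list()
  run_start <- 1L
  breaks <- c(which(!ok), nc)
  for (b in unique(breaks)) {
    units <- run_start:b
    if (length(units) >= min_repeats) {
      st <- starts[units]; en <- ends[units]
      copies <- substring(g, st + 1L, en)
      cols <- t(vapply(copies, function(x) strsplit(x, "")[[1]],
                       character(rep_len)))
      consensus <- paste(apply(cols, 2L, col_majority), collapse = "")
      spc <- substring(g, en[-length(en)] + 1L, st[-1L])
      # tandem repeats present as arrays whose "spacers" are copies of one
      # another (the unit phase is arbitrary); genuine spacers are unique
      if (length(unique(spc)) <= length(spc) / 2) {
        run_start <- b + 1L
        next
      }
      out[[length(out) + 1L]] <- structure(list(
        genome_id = genome_id,
        repeat_consensus = consensus,
        repeat_intervals = data.frame(start = st, end = en),
        spacers = spc,
        n_units = length(units)), class = "crispr_array")
    }
    run_start <- b + 1L
  }
  out
}

merge_overlapping_arrays <- function(arrays) {
  if (length(arrays) <= 1L) return(arrays)
  drop <- logical(length(arrays))
  for (i in seq_along(arrays)) {
    if (drop[i]) next
    for (j in seq_along(arrays)) {
      if (i == j || drop[j] || drop[i]) next
      ai <- arrays[[i]]$repeat_intervals
      aj <- arrays[[j]]$repeat_intervals
      overlap <- any(outer(ai$start, aj$end, `<`) &
                       outer(ai$end, aj$start, `>`))
      if (overlap) {
        # keep the call with more units (ties: the earlier one)
        if (arrays[[j]]$n_units > arrays[[i]]$n_units) drop[i] <- TRUE
        else drop[j] <- TRUE
      }
    }
  }
  kept <- arrays[!drop]
  ord <- order(vapply(kept, function(a) a$repeat_intervals$start[1L], 0L))
  kept[ord]
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("CRISPR array on %s: %d units, repeat %d nt, %d spacers\n",
              x$genome_id, x$n_units, nchar(x$repeat_consensus),
              length(x$spacers)))
  cat(sprintf("  repeat consensus: %s\n", x$repeat_consensus))
  cat(sprintf("  span: %d-%d\n", x$repeat_intervals$start[1L],
              x$repeat_intervals$end[nrow(x$repeat_intervals)]))
  invisible(x)
}

#' Dereplicate CRISPR repeats across genomes into a repeat set
#'
#' Exact duplicates and reverse-complement duplicates collapse to one
#' entry that keeps every contributing taxon and source genome; the
#' retained orientation is the first encountered in the deterministic
#' ordering (taxon, then genome, then array position). Repeat ids are
#' zero-padded serials assigned in that order.
#'
#' @param arrays List of `crispr_array` objects (from [detect_arrays()]
#'   over one or more genomes).
#' @param taxa Named character vector mapping `genome_id` to taxon label;
#'   defaults to the genome ids themselves.
#' @return data.frame with columns `repeat_id`, `sequence`, `taxa`
#'   (comma-joined), `source_genomes` (comma-joined).
#' @export
dereplicate_repeats <- function(arrays, taxa = NULL) {
  if (length(arrays) == 0L) {
    return(data.frame(repeat_id = character(0), sequence = character(0),
                      taxa = character(0), source_genomes = character(0),
                      stringsAsFactors = FALSE))
  }
  gid <- vapply(arrays, `[[`, "", "genome_id")
  if (is.null(taxa)) taxa <- setNames(unique(gid), unique(gid))
  df <- data.frame(
    sequence = vapply(arrays, `[[`, "", "repeat_consensus"),
    genome_id = gid,
    taxon = unname(taxa[gid]),
    start = vapply(arrays, function(a) a$repeat_intervals$start[1L], 0L),
    stringsAsFactors = FALSE)
  df <- df[order(df$taxon, df$genome_id, df$start), , drop = FALSE]

  entries <- list()
  canon <- character(0)                 # retained orientations
  for (i in seq_len(nrow(df))) {
    s <- df$sequence[i]
    rc <- revcomp(s)
    hit <- match(TRUE, canon == s | canon == rc)
    if (is.na(hit)) {
      canon <- c(canon, s)
      entries[[length(entries) + 1L]] <-
        list(sequence = s, taxa = df$taxon[i], genomes = df$genome_id[i])
    } else {
      e <- entries[[hit]]
      e$taxa <- union(e$taxa, df$taxon[i])
      e$genomes <- union(e$genomes, df$genome_id[i])
      entries[[hit]] <- e
    }
  }
  data.frame(
    repeat_id = sprintf("%02d", seq_along(entries)),
    sequence = vapply(entries, `[[`, "", "sequence"),
    taxa = vapply(entries, function(e) paste(e$taxa, collapse = ","), ""),
    source_genomes = vapply(entries, function(e)
      paste(e$genomes, collapse = ","), ""),
    stringsAsFactors = FALSE)
}
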