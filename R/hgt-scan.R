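# Transposon-mediated HGT detection: coverage anomalies, region-to-host
# alignment, short direct/inverted repeats, terminal inverted repeats,
# frameshift pseudogene reports, and fragment-based ANI.

#' Detect discrete high-coverage regions on a genome
#'
#' Finds maximal runs where the (lightly smoothed) depth is at least
#' `fold` times the median depth of the two flanking windows of size
#' `flank`, treating the genome as circular for flank computation (phage
#' assemblies are typically circular). Runs shorter than `min_len` are
#' dropped. Regions within `flank` of the assembly origin are annotated as
#' possible circular-permutation artifacts (terminal redundancy), flagged
#' rather than filtered.
#'
#' @param track A `coverage_track` (see [coverage_track()]).
#' @param fold Fold-change threshold (region median over flank median).
#' @param min_len Minimum region length (bp).
#' @param flank Flanking window size (bp) used for the local background.
#' @param smooth Width of the centered moving-average used to segment the
#'   track (odd integer; raw depth is used for the reported medians).
#' @return data.frame `ref_id`, `start`, `end` (0-based half-open),
#'   `region_median_depth`, `flank_median_depth`, `fold_change`,
#'   `origin_artifact`. Zero rows when nothing qualifies.
#' @export
detect_high_coverage <- function(track, fold = 3, min_len = 200L,
                                 flank = 1000L, smooth = 51L) {
  depth <- track$depth
  n <- length(depth)
  stopifnot(n > 2L * flank)
  empty <- data.frame(ref_id = character(0), start = integer(0),
                      end = integer(0), region_median_depth = numeric(0),
                      flank_median_depth = numeric(0),
                      fold_change = numeric(0), origin_artifact = logical(0),
                      stringsAsFactors = FALSE)
  if (all(depth == 0)) return(empty)
  sm <- as.numeric(stats::filter(depth, rep(1 / smooth, smooth),
                                 sides = 2, circular = TRUE))
  gmed <- stats::median(sm)
  seed_thr <- max(fold * gmed, 1e-9)
  mask <- sm >= seed_thr
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(s = starts[r$values], e = ends[r$values])
  if (nrow(runs) == 0L) return(empty)

  wrap <- function(i) ((i - 1L) %% n) + 1L
  out <- list()
  for (k in seq_len(nrow(runs))) {
    s <- runs$s[k]; e <- runs$e[k]
    fm <- stats::median(depth[wrap(c((s - flank):(s - 1L),
                                     (e + 1L):(e + flank)))])
    thr <- max(fold * fm, 1e-9)
    while (s > 1L && sm[s - 1L] >= thr) s <- s - 1L
    while (e < n && sm[e + 1L] >= thr) e <- e + 1L
    rm_ <- stats::median(depth[s:e])
    fc <- if (fm > 0) rm_ / fm else Inf
    if ((e - s + 1L) >= min_len && fc >= fold) {
      out[[length(out) + 1L]] <- data.frame(
        ref_id = track$ref_id, start = s - 1L, end = e,
        region_median_depth = rm_, flank_median_depth = fm,
        fold_change = fc,
        origin_artifact = (s - 1L) < flank || (n - e) < flank,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out <- out[order(out$start), , drop = FALSE]
  # merge overlapping refined regions
  keep <- !logical(nrow(out))
  for (i in seq_len(nrow(out))[-1L]) {
    prev <- max(which(keep[seq_len(i - 1L)]))
    if (out$start[i] < out$end[prev]) {
      out$end[prev] <- max(out$end[prev], out$end[i])
      keep[i] <- FALSE
    }
  }
  out[keep, , drop = FALSE]
}

# --- seeded, ungapped local alignment (exact seed + X-drop extension) ---

# Extend an exact seed (1-based qpos/spos, length k) along its diagonal in
# both directions with an X-drop rule; scoring is +1 match / -1 mismatch.
diag_extend <- function(q, s, qpos, spos, k, xdrop) {
  nq <- nchar(q); ns <- nchar(s)
  side <- function(av, bv) {
    len <- length(av)
    if (len == 0L) return(c(0L, 0L))
    m <- av == bv
    sc <- cumsum(ifelse(m, 1L, -1L))
    over <- which(cummax(sc) - sc > xdrop)
    lim <- if (length(over)) over[1L] - 1L else len
    if (lim == 0L) return(c(0L, 0L))
    ext <- which.max(sc[seq_len(lim)])
    if (sc[ext] <= 0L) return(c(0L, 0L))
    c(ext, sum(m[seq_len(ext)]))
  }
  rlen <- min(nq - (qpos + k - 1L), ns - (spos + k - 1L))
  r <- side(utf8ToInt(substr(q, qpos + k, qpos + k - 1L + rlen)),
            utf8ToInt(substr(s, spos + k, spos + k - 1L + rlen)))
  llen <- min(qpos - 1L, spos - 1L)
  l <- side(rev(utf8ToInt(substr(q, qpos - llen, qpos - 1L))),
            rev(utf8ToInt(substr(s, spos - llen, spos - 1L))))
  len <- k + l[1L] + r[1L]
  matches <- k + l[2L] + r[2L]
  list(qstart = qpos - l[1L], qend = qpos + k - 1L + r[1L],
       sstart = spos - l[1L], send = spos + k - 1L + r[1L],
       length = len, matches = matches, score = 2L * matches - len)
}

# All seeded ungapped local alignments of q against s (one orientation).
seed_alignments <- function(q, s, k, xdrop) {
  qk <- kmer_table(q, k)
  sk <- kmer_table(s, k)
  names(sk)[2L] <- "spos"
  seeds <- merge(qk, sk, by = "kmer", allow.cartesian = TRUE)
  if (nrow(seeds) == 0L) return(list())
  seeds[, `:=`(diag = spos - pos)]
  data.table::setorder(seeds, diag, pos)
  out <- list()
  last_diag <- NA_integer_; free_from <- 0L
  for (i in seq_len(nrow(seeds))) {
    d <- seeds$diag[i]; qp <- seeds$pos[i] + 1L; sp <- seeds$spos[i] + 1L
    if (!is.na(last_diag) && d == last_diag && qp < free_from) next
    al <- diag_extend(q, s, qp, sp, k, xdrop)
    out[[length(out) + 1L]] <- al
    last_diag <- d
    free_from <- al$qend + 1L
  }
  out
}

#' Locally align a high-coverage region to a host genome
#'
#' Seeded (exact k-mer) ungapped local alignment with X-drop extension on
#' both strands; reports all alignments of at least `min_len` bp and
#' `min_identity` identity. An empty result is itself informative (a
#' coverage anomaly without host homology, e.g. terminal redundancy).
#'
#' @param region_seq Region sequence (character).
#' @param host Host genome (character or [Biostrings::DNAString]).
#' @param min_len Minimum alignment length.
#' @param min_identity Minimum identity.
#' @param k Seed k-mer size.
#' @param xdrop X-drop threshold (score units; match +1, mismatch -1).
#' @return data.frame `region_start`, `region_end`, `host_start`,
#'   `host_end` (0-based half-open), `strand`, `length`, `identity`,
#'   `score`, best first.
#' @export
align_region_to_host <- function(region_seq, host, min_len = 100L,
                                 min_identity = 0.8, k = 12L, xdrop = 20L) {
  host <- as.character(host)
  nh <- nchar(host)
  rows <- list()
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") host else revcomp(host)
    for (al in seed_alignments(region_seq, subj, k, xdrop)) {
      hs <- al$sstart - 1L; he <- al$send
      if (strand == "-") { tmp <- hs; hs <- nh - he; he <- nh - tmp }
      rows[[length(rows) + 1L]] <- data.frame(
        region_start = al$qstart - 1L, region_end = al$qend,
        host_start = hs, host_end = he, strand = strand,
        length = al$length, identity = al$matches / al$length,
        score = al$score, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_local_alignments())
  out <- unique(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  out <- out[out$length >= min_len & out$identity >= min_identity, ,
             drop = FALSE]
  out[order(-out$score, out$region_start), , drop = FALSE]
}

empty_local_alignments <- function() {
  data.frame(region_start = integer(0), region_end = integer(0),
             host_start = integer(0), host_end = integer(0),
             strand = character(0), length = integer(0),
             identity = numeric(0), score = integer(0),
             stringsAsFactors = FALSE)
}

#' Find short direct and inverted repeat pairs between two sequences
#'
#' Enumerates all maximal ungapped pairs within the length bounds and the
#' mismatch budget: a pair is maximal when extending it on either side
#' would exceed `max_mismatch` (or run off a sequence end). Direct pairs
#' compare the two sequences as given; inverted pairs compare `seq_a`
#' against the reverse complement of `seq_b`, with coordinates reported on
#' the forward strand of `seq_b`. Self-comparison (`seq_b` identical to
#' `seq_a`) is permitted; trivially identical self-pairs (the main
#' diagonal, and mirror duplicates) are excluded.
#'
#' Seeding uses the pigeonhole principle (any qualifying pair contains an
#' exact run of `ceiling((min_len - max_mismatch) / (max_mismatch + 1))`
#' bases), so the enumeration is exhaustive for the returned length range.
#'
#' @param seq_a,seq_b Sequences (character).
#' @param min_len,max_len Length bounds on reported pairs.
#' @param max_mismatch Mismatch budget.
#' @param kinds Subset of `c("direct", "inverted")`.
#' @return data.frame `kind`, `a_start`, `a_end`, `b_start`, `b_end`
#'   (0-based half-open), `length`, `mismatches`, `seq_a`, `seq_b` (both
#'   5' to 3' on the + strand of their sequence).
#' @export
find_short_repeats <- function(seq_a, seq_b, min_len = 12L, max_len = 40L,
                               max_mismatch = 1L,
                               kinds = c("direct", "inverted")) {
  self <- identical(seq_a, seq_b)
  na <- nchar(seq_a)
  k <- max(3L, as.integer(ceiling((min_len - max_mismatch) /
                                    (max_mismatch + 1L))))
  rows <- list()
  for (kind in kinds) {
    bb <- if (kind == "direct") seq_b else revcomp(seq_b)
    nb <- nchar(bb)
    ak <- kmer_table(seq_a, k)
    bk <- kmer_table(bb, k)
    names(bk)[2L] <- "bpos"
    seeds <- merge(ak, bk, by = "kmer", allow.cartesian = TRUE)
    if (nrow(seeds) == 0L) next
    half <- max_len + max_mismatch + 2L
    win <- new.env(parent = emptyenv())
    for (si in seq_len(nrow(seeds))) {
      i <- seeds$pos[si] + 1L; j <- seeds$bpos[si] + 1L   # 1-based
      d <- j - i
      if (self && kind == "direct" && d == 0L) next
      alo <- max(1L, 1L - d, i - half)
      ahi <- min(na, nb - d, i + k - 1L + half)
      av <- utf8ToInt(substr(seq_a, alo, ahi))
      bv <- utf8ToInt(substr(bb, alo + d, ahi + d))
      mism <- which(av != bv)
      len <- ahi - alo + 1L
      t <- length(mism)
      p <- c(0L, mism, len + 1L)        # sentinel mismatch positions
      for (w in seq_len(if (t <= max_mismatch) 1L else t - max_mismatch + 1L)) {
        ws <- p[w] + 1L
        we <- p[min(w + max_mismatch + 1L, t + 2L)] - 1L
        wlen <- we - ws + 1L
        if (wlen < min_len || wlen > max_len) next
        # true maximality: windows clipped by the local region (not by a
        # sequence end) are artifacts of the windowing; they are recovered
        # exactly from a better-centred seed, so require the seed inside
        if (ws > i - alo + 1L || we < i - alo + k) next
        a0 <- alo + ws - 2L                       # 0-based
        b0 <- a0 + d
        n_mm <- sum(mism >= ws & mism <= we)
        key <- sprintf("%d:%d:%d", a0, b0, wlen)
        if (!is.null(win[[key]])) next
        win[[key]] <- TRUE
        if (kind == "direct") {
          bs <- b0; be <- b0 + wlen
        } else {
          bs <- nb - (b0 + wlen); be <- nb - b0
        }
        if (self) {
          if (kind == "direct" && a0 > bs) next    # mirror duplicate
          if (kind == "inverted" && a0 > bs) next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          kind = kind, a_start = a0, a_end = a0 + wlen,
          b_start = bs, b_end = be, length = wlen, mismatches = n_mm,
          seq_a = substr(seq_a, a0 + 1L, a0 + wlen),
          seq_b = substr(seq_b, bs + 1L, be),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(kind = character(0), a_start = integer(0),
                      a_end = integer(0), b_start = integer(0),
                      b_end = integer(0), length = integer(0),
                      mismatches = integer(0), seq_a = character(0),
                      seq_b = character(0), stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  out[order(out$kind, out$a_start, out$b_start), , drop = FALSE]
}

#' Rank terminal inverted repeat candidates in a genomic window
#'
#' Searches a window for inverted repeat pairs whose two arms face inward
#' and bracket at least `min_gap` bp (the insertion-sequence transposon
#' geometry), ranked by arm length (descending) then mismatches. Arms are
#' reported 5' to 3' on the + strand with 0-based genome coordinates.
#'
#' @param genome Genome sequence (character).
#' @param window `c(start, end)` 0-based half-open window to scan.
#' @param tir_len Length-2 bounds on arm length.
#' @param max_mismatch Mismatch budget between the arms.
#' @param min_gap Minimum distance bracketed by the arms.
#' @return data.frame as [find_short_repeats()] (coordinates shifted to
#'   the genome), plus `gap`, best candidate first.
#' @export
find_tirs <- function(genome, window, tir_len = c(10L, 40L),
                      max_mismatch = 2L, min_gap = 500L) {
  seg <- substr(genome, window[1] + 1L, window[2])
  rp <- find_short_repeats(seg, seg, min_len = tir_len[1],
                           max_len = tir_len[2],
                           max_mismatch = max_mismatch, kinds = "inverted")
  if (nrow(rp) == 0L) return(cbind(rp, data.frame(gap = integer(0))))
  rp <- rp[rp$b_start - rp$a_end >= min_gap, , drop = FALSE]
  if (nrow(rp) == 0L) return(cbind(rp, data.frame(gap = integer(0))))
  rp$gap <- rp$b_start - rp$a_end
  for (col in c("a_start", "a_end", "b_start", "b_end")) {
    rp[[col]] <- rp[[col]] + window[1]
  }
  rp[order(-rp$length, rp$mismatches, rp$a_start), , drop = FALSE]
}

#' Frameshift report between a phage ORF and its host gene copy
#'
#' Globally aligns the two sequences with affine gaps, locates single-base
#' indels of the host copy relative to the donor ORF, and reports the
#' first in-frame stop codon of the host copy (translated in the donor's
#' frame from the shared start) when it precedes the donor's own stop -
#' the signature of a frameshift pseudogene.
#'
#' @param orf_a Donor ORF (ATG..stop, length a multiple of 3, >= 300 bp).
#' @param orf_b Host copy of the gene (>= 300 bp).
#' @param gap_opening,gap_extension Affine gap penalties (positive).
#' @return List: `indels` (data.frame `position` 0-based in `orf_b` - for
#'   deletions the position of the base following the lost one - and
#'   `type`), `indel_position`, `indel_type` (first single-base indel, NA
#'   when none), `premature_stop_position` (0-based codon index in
#'   `orf_b`, NA when none precedes the donor stop),
#'   `original_stop_position` (donor stop codon index).
#' @export
frame_shift_report <- function(orf_a, orf_b, gap_opening = 3,
                               gap_extension = 1) {
  la <- nchar(orf_a)
  stopifnot(la >= 300L, nchar(orf_b) >= 300L)
  if (la %% 3L != 0L || substr(orf_a, 1L, 3L) != "ATG" ||
      !(substring(orf_a, la - 2L, la) %in% STOP_CODONS)) {
    stop("orf_a must be an intact ORF (ATG..stop, length a multiple of 3)",
         call. = FALSE)
  }
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(orf_a), Biostrings::DNAString(orf_b),
    type = "global", substitutionMatrix = sm,
    gapOpening = gap_opening, gapExtension = gap_extension)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  b_before <- cumsum(as_ != "-")        # b bases consumed up to each column
  gap_runs <- function(v) {
    r <- rle(v == "-")
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    data.frame(start = s[r$values], len = r$lengths[r$values])
  }
  ins <- gap_runs(ap)                   # gaps in a => insertions in b
  del <- gap_runs(as_)                  # gaps in b => deletions from a
  indels <- rbind(
    if (nrow(ins)) data.frame(position = b_before[ins$start] - 1L,
                              type = "insertion", len = ins$len),
    if (nrow(del)) data.frame(position = b_before[del$start],
                              type = "deletion", len = del$len))
  single <- indels[!is.null(indels) & indels$len == 1L, , drop = FALSE]
  if (!is.null(single) && nrow(single) > 0L) {
    single <- single[order(single$position), , drop = FALSE]
  }
  a_stop <- la / 3L - 1L
  s_b <- first_stop_codon(orf_b)
  premature <- if (!is.na(s_b) && s_b < a_stop) s_b else NA_integer_
  list(indels = if (is.null(indels)) {
         data.frame(position = integer(0), type = character(0),
                    len = integer(0))
       } else indels,
       indel_position = if (!is.null(single) && nrow(single))
         single$position[1L] else NA_integer_,
       indel_type = if (!is.null(single) && nrow(single))
         single$type[1L] else NA_character_,
       premature_stop_position = premature,
       original_stop_position = a_stop)
}

#' Average nucleotide identity by the fragment method
#'
#' Cuts `genome_a` into consecutive `frag_len` fragments, aligns each to
#' `genome_b` (best seeded ungapped local alignment, either strand), keeps
#' fragments whose best alignment has identity at least `min_id` over at
#' least `min_cov` of the fragment length, and averages the identities of
#' the kept fragments. One-way (a against b); trailing fragments shorter
#' than 100 bp are not evaluated.
#'
#' @param genome_a,genome_b Genomes (character or
#'   [Biostrings::DNAString]).
#' @param frag_len Fragment length (default 1020).
#' @param min_id Identity filter (fraction).
#' @param min_cov Coverage filter (aligned fraction of the fragment).
#' @param k Seed k-mer size.
#' @param xdrop X-drop threshold for extension.
#' @return List: `ani_percent` (NA when undefined), `n_fragments_used`,
#'   `n_fragments_total`, `undefined`.
#' @export
compute_ani <- function(genome_a, genome_b, frag_len = 1020L,
                        min_id = 0.30, min_cov = 0.70, k = 15L,
                        xdrop = 40L) {
  a <- as.character(genome_a); b <- as.character(genome_b)
  na <- nchar(a)
  starts <- seq.int(1L, na, by = frag_len)
  ends <- pmin(starts + frag_len - 1L, na)
  keep <- (ends - starts + 1L) >= 100L
  starts <- starts[keep]; ends <- ends[keep]
  brc <- revcomp(b)
  ids <- rep(NA_real_, length(starts))
  for (i in seq_along(starts)) {
    frag <- substr(a, starts[i], ends[i])
    flen <- nchar(frag)
    best <- NULL
    for (subj in c(b, brc)) {
      for (al in seed_alignments(frag, subj, k, xdrop)) {
        if (is.null(best) || al$score > best$score) best <- al
      }
    }
    if (is.null(best)) next
    identity <- best$matches / best$length
    if (identity >= min_id && best$length / flen >= min_cov) {
      ids[i] <- identity
    }
  }
  used <- !is.na(ids)
  list(ani_percent = if (any(used)) 100 * mean(ids[used]) else NA_real_,
       n_fragments_used = sum(used),
       n_fragments_total = length(starts),
       undefined = !any(used))
}
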