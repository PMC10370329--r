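# Spacer-to-phage alignment under the full-length identity rule, and
# majority-vote host prediction.

#' Align spacers to phage genomes (full-length, ungapped)
#'
#' Every ungapped placement of each spacer on each phage genome, on either
#' strand, with at most `floor((1 - min_identity) * L)` substitutions over
#' the full spacer length L, is reported as a protospacer hit. Identity is
#' substitution-based over the entire spacer, `(L - mismatches) / L`.
#' Overlapping placements of the same spacer are reported separately.
#' Output order is deterministic: spacer id, phage id, position.
#'
#' @param catalog A `spacer_catalog`, its `records` data.frame, or any
#'   data.frame with `spacer_id`, `sequence` and optionally `taxon`.
#' @param phages Named [Biostrings::DNAStringSet] (or named character) of
#'   phage genomes.
#' @param min_identity Minimum identity over the full spacer length
#'   (default 0.80).
#' @return data.frame of protospacer hits: `spacer_id`, `taxon`,
#'   `phage_id`, `start`, `end` (0-based half-open on the phage), `strand`,
#'   `mismatches`, `identity`.
#' @export
match_spacers <- function(catalog, phages, min_identity = 0.80) {
  records <- if (inherits(catalog, "spacer_catalog")) catalog$records
             else catalog
  if (!"taxon" %in% names(records)) records$taxon <- NA_character_
  if (is.character(phages)) phages <- Biostrings::DNAStringSet(phages)
  hits <- list()
  for (i in seq_len(nrow(records))) {
    sp <- records$sequence[i]
    L <- nchar(sp)
    # epsilon guards the floor against binary representation of 1 - 0.80
    max_mm <- floor((1 - min_identity) * L + 1e-9)
    for (pid in names(phages)) {
      subj <- phages[[pid]]
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") sp else revcomp(sp)
        m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm)
        st <- IRanges::start(m); en <- IRanges::end(m)
        keep <- st >= 1L & en <= length(subj)
        st <- st[keep]
        if (length(st) == 0L) next
        mm <- Biostrings::neditStartingAt(pat, subj, starting.at = st,
                                          with.indels = FALSE)
        hits[[length(hits) + 1L]] <- data.frame(
          spacer_id = records$spacer_id[i],
          taxon = records$taxon[i],
          phage_id = pid,
          start = st - 1L,
          end = st - 1L + L,
          strand = strand,
          mismatches = as.integer(mm),
          identity = (L - mm) / L,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits)) {
    do.call(rbind, c(hits, list(make.row.names = FALSE)))
  } else {
    data.frame(spacer_id = character(0), taxon = character(0),
               phage_id = character(0), start = integer(0),
               end = integer(0), strand = character(0),
               mismatches = integer(0), identity = numeric(0),
               stringsAsFactors = FALSE)
  }
  out[order(out$spacer_id, out$phage_id, out$start), , drop = FALSE]
}

#' Predict the bacterial host of each phage from protospacer hits
#'
#' Per phage, hits are counted by the taxon of the contributing spacers
#' and the host call is the majority taxon. Ties yield `"unassigned"` with
#' the ambiguity flag set; a best taxon supported by a single hit is
#' flagged weak; a runner-up taxon reaching at least half the best count
#' sets the ambiguity flag. Phages without hits are `"unassigned"`.
#'
#' @param hits Protospacer hit data.frame from [match_spacers()].
#' @param phage_ids Optional character vector of all phages to report
#'   (defaults to the phages present in `hits`).
#' @return data.frame `phage_id`, `taxon_call`, `n_best`, `weak_flag`,
#'   `ambiguous_flag`; the per-taxon hit counts are attached as attribute
#'   `"hits_per_taxon"` (long data.frame `phage_id`, `taxon`, `n`).
#' @export
predict_hosts <- function(hits, phage_ids = NULL) {
  if (is.null(phage_ids)) phage_ids <- sort(unique(hits$phage_id))
  counts <- as.data.frame(table(phage_id = hits$phage_id,
                                taxon = hits$taxon),
                          stringsAsFactors = FALSE)
  names(counts)[3L] <- "n"
  counts <- counts[counts$n > 0L, , drop = FALSE]
  out <- lapply(phage_ids, function(pid) {
    cc <- counts[counts$phage_id == pid, , drop = FALSE]
    if (nrow(cc) == 0L) {
      return(data.frame(phage_id = pid, taxon_call = "unassigned",
                        n_best = 0L, weak_flag = FALSE,
                        ambiguous_flag = FALSE, stringsAsFactors = FALSE))
    }
    cc <- cc[order(-cc$n, cc$taxon), , drop = FALSE]
    best <- cc$n[1L]
    tied <- sum(cc$n == best) > 1L
    runner <- if (nrow(cc) > 1L) cc$n[2L] else 0L
    data.frame(
      phage_id = pid,
      taxon_call = if (tied) "unassigned" else cc$taxon[1L],
      n_best = best,
      weak_flag = !tied && best == 1L,
      ambiguous_flag = tied || runner >= best / 2,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "hits_per_taxon") <- counts
  res
}

#' Export the spacer-phage network as node and edge tables
#'
#' Nodes are the spacers with at least one hit (typed by taxon) and the
#' phages; edges connect spacer to phage, weighted by the best identity of
#' the corresponding hits. Ordering is stable.
#'
#' @param hits Protospacer hit data.frame from [match_spacers()].
#' @param predictions Optional host predictions from [predict_hosts()];
#'   when given, each phage node carries its host call.
#' @return List with `nodes` (data.frame `id`, `type`, `taxon`) and
#'   `edges` (data.frame `from` spacer, `to` phage, `weight`).
#' @export
export_network <- function(hits, predictions = NULL) {
  dt <- as.data.table(hits)
  edges <- dt[, list(weight = max(identity)),
              by = c("spacer_id", "taxon", "phage_id")]
  data.table::setorder(edges, spacer_id, phage_id)
  spacer_nodes <- unique(edges[, c("spacer_id", "taxon")])
  phage_ids <- sort(unique(edges$phage_id))
  phage_taxon <- rep(NA_character_, length(phage_ids))
  if (!is.null(predictions)) {
    m <- match(phage_ids, predictions$phage_id)
    phage_taxon <- predictions$taxon_call[m]
  }
  nodes <- data.frame(
    id = c(spacer_nodes$spacer_id, phage_ids),
    type = rep(c("spacer", "phage"),
               c(nrow(spacer_nodes), length(phage_ids))),
    taxon = c(spacer_nodes$taxon, phage_taxon),
    stringsAsFactors = FALSE)
  list(nodes = nodes,
       edges = data.frame(from = edges$spacer_id, to = edges$phage_id,
                          weight = edges$weight, stringsAsFactors = FALSE))
}
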