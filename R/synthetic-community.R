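# Synthetic pink-berry-like community generator.
#
# Emulates the study design this package is built around: a handful of
# host bacteria carrying CRISPR arrays whose spacers partly derive from a
# small set of phage genomes, three samples with stable host but variable
# phage abundance, a planted transposon-mediated HGT insert, elevated
# substitution density inside CRISPR-targeted protospacers, and
# uniform-error short reads. Everything is deterministic under the config
# seed and accompanied by a machine-readable truth table.

default_hosts <- function() {
  lapply(c("Desulfofustis_like", "Thiohalocapsa_like", "Rhodobacteraceae_like"),
         function(lab) {
           list(taxon_label = lab,
                genome_length = 40000L,
                per_sample_abundance = c(6, 6, 6),
                arrays = list(
                  list(repeat_length = 36L, n_spacers = 10L,
                       spacer_length = 34L),
                  list(repeat_length = 36L, n_spacers = 10L,
                       spacer_length = 34L)))
         })
}

default_phages <- function() {
  ab <- list(c(1.0, 1.2, 0.8),
             c(0.1, 2.0, 0.5),
             c(0.0, 0.0, 1.5),
             c(0.8, 0.8, 0.8),
             c(2.0, 0.1, 0.4))
  lapply(seq_along(ab), function(i) {
    list(label = sprintf("phage%02d", i),
         genome_length = 25000L,
         per_sample_abundance = ab[[i]])
  })
}

#' Configuration for a synthetic host/phage community
#'
#' The defaults encode the emulated study conditions: three CRISPR-bearing
#' host genomes (40 kb, two arrays of ten 34-nt spacers between 36-nt
#' repeats each), five 25-kb phage genomes whose abundance varies strongly
#' across three samples (one phage absent from two samples) while hosts
#' stay stable, half of all spacers copied from the phages with two
#' substitutions each, a ~1-kb phage gene (the size of a typical lysin
#' ORF) copied into one host flanked by 17-bp direct repeats and
#' inactivated by a single-nucleotide insertion,
#' population variants planted on the phages at 0.5% per bp inside
#' CRISPR-targeted protospacers versus ~0.17% outside (a threefold ratio),
#' and 250-nt uniform-error reads (4,000 per sample).
#'
#' @param rng_seed Integer seed; all outputs are deterministic given it.
#' @param hosts List of host specs: `taxon_label`, `genome_length`,
#'   `per_sample_abundance`, `arrays` (each with `repeat_length` or an
#'   explicit `repeat_sequence`, `n_spacers`, `spacer_length`).
#' @param phages List of phage specs: `label`, `genome_length`,
#'   `per_sample_abundance`.
#' @param samples Sample labels; abundance vectors must have this length.
#' @param protospacer_plan `fraction_of_spacers_from_phages` in \[0,1\] and
#'   `per_protospacer_mutations` (substitutions planted between spacer and
#'   its phage source).
#' @param hgt_plan NULL to disable, else `donor_phage`, `gene_length`
#'   (multiple of 3, >= 300), `direct_repeat_length`, `dr_mismatches`,
#'   `insertion_offset` (0-based offset of the frameshifting insertion
#'   within the gene copy).
#' @param variant_plan `background_substitution_rate` and
#'   `protospacer_substitution_rate` per bp (the latter must not be
#'   smaller), `allele_frequency` of each planted variant, and optionally
#'   `target_intervals` (data.frame `ref_id`, `start`, `end`) overriding
#'   the planted protospacers as the elevated-rate regions.
#' @param read_plan `read_length`, `n_reads_per_sample`, `error_rate`,
#'   `base_quality` (constant Phred score).
#' @return A `community_config` list.
#' @export
community_config <- function(rng_seed = 1L,
                             hosts = default_hosts(),
                             phages = default_phages(),
                             samples = c("s01", "s02", "s03"),
                             protospacer_plan = list(
                               fraction_of_spacers_from_phages = 0.5,
                               per_protospacer_mutations = 2L),
                             hgt_plan = list(
                               donor_phage = "phage01",
                               gene_length = 1044L,
                               direct_repeat_length = 17L,
                               dr_mismatches = 1L,
                               insertion_offset = 300L),
                             variant_plan = list(
                               background_substitution_rate = 0.005 / 3,
                               protospacer_substitution_rate = 0.005,
                               allele_frequency = 0.5),
                             read_plan = list(
                               read_length = 250L,
                               n_reads_per_sample = 4000L,
                               error_rate = 0.002,
                               base_quality = 35L)) {
  cfg <- list(rng_seed = rng_seed, hosts = hosts, phages = phages,
              samples = samples, protospacer_plan = protospacer_plan,
              hgt_plan = hgt_plan, variant_plan = variant_plan,
              read_plan = read_plan)
  validate_config(cfg)
  class(cfg) <- "community_config"
  cfg
}

validate_config <- function(cfg) {
  ns <- length(cfg$samples)
  for (h in cfg$hosts) {
    stopifnot(length(h$per_sample_abundance) == ns,
              all(h$per_sample_abundance >= 0))
    for (a in h$arrays) {
      array_len <- function(a) {
        rl <- if (!is.null(a$repeat_sequence)) nchar(a$repeat_sequence)
              else a$repeat_length
        (a$n_spacers + 1L) * rl + a$n_spacers * a$spacer_length
      }
      if (array_len(a) + 1000L > h$genome_length) {
        stop("config error: CRISPR array longer than host genome",
             call. = FALSE)
      }
    }
  }
  for (p in cfg$phages) {
    stopifnot(length(p$per_sample_abundance) == ns,
              all(p$per_sample_abundance >= 0))
  }
  for (s in seq_len(ns)) {
    tot <- sum(vapply(cfg$hosts, function(h) h$per_sample_abundance[s], 0)) +
      sum(vapply(cfg$phages, function(p) p$per_sample_abundance[s], 0))
    if (tot <= 0) stop("config error: sample with no positive abundance",
                       call. = FALSE)
  }
  pp <- cfg$protospacer_plan
  stopifnot(pp$fraction_of_spacers_from_phages >= 0,
            pp$fraction_of_spacers_from_phages <= 1,
            pp$per_protospacer_mutations >= 0)
  vp <- cfg$variant_plan
  if (vp$protospacer_substitution_rate < vp$background_substitution_rate) {
    stop("config error: protospacer substitution rate below background",
         call. = FALSE)
  }
  invisible(cfg)
}

# Random ORF: ATG + non-stop codons + TAA.
make_orf <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 300L)
  all_codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L,
                      paste, collapse = "")
  sense <- setdiff(all_codons, STOP_CODONS)
  paste0("ATG",
         paste(sample(sense, len / 3L - 2L, replace = TRUE), collapse = ""),
         "TAA")
}

#' Plant a transposon-style HGT copy of a phage gene into a host genome
#'
#' Copies the donor gene (an intact ORF on the phage) into the host,
#' flanked by two identical direct repeats of `dr_length`; the host copy
#' receives one single-nucleotide insertion placed so that translation in
#' the original frame reaches a stop codon strictly before the original
#' stop (a frameshift pseudogene). The phage receives an imperfect copy of
#' the direct repeat (carrying `dr_mismatches` substitutions) immediately
#' upstream of the gene, the footprint left by the mobilization.
#'
#' @param host_seq Host genome (character).
#' @param phage_seq Donor phage genome (character).
#' @param gene_interval 0-based half-open `c(start, end)` of the donor gene
#'   on the phage; must be an intact ORF (ATG start, stop end, length a
#'   multiple of 3, >= 300 bp).
#' @param dr_length Direct repeat length (default 17).
#' @param dr_mismatches Substitutions carried by the phage-side repeat copy.
#' @param insert_at 0-based host position where the insert replaces
#'   backbone sequence (keeps genome length constant); random if NULL.
#' @param insertion_offset 0-based offset within the gene copy for the
#'   frameshifting insertion; nudged forward if no premature stop results.
#' @return List with `host` (modified), `phage` (modified), and `record`
#'   (truth: host/donor intervals, repeat sequences, insertion position,
#'   premature stop codon index). Uses the current RNG state.
#' @export
plant_hgt <- function(host_seq, phage_seq, gene_interval, dr_length = 17L,
                      dr_mismatches = 1L, insert_at = NULL,
                      insertion_offset = NULL) {
  gs <- gene_interval[1]
  ge <- gene_interval[2]
  gene <- substr(phage_seq, gs + 1L, ge)
  glen <- nchar(gene)
  if (glen %% 3L != 0L || glen < 300L || substr(gene, 1L, 3L) != "ATG" ||
      !(substring(gene, glen - 2L, glen) %in% STOP_CODONS)) {
    stop("config error: donor gene must be an intact ORF (ATG..stop, ",
         "length a multiple of 3, >= 300 bp)", call. = FALSE)
  }
  orig_stop <- glen / 3L - 1L
  if (is.null(insertion_offset)) insertion_offset <- max(30L, glen %/% 6L)

  # find an (offset, base) whose insertion yields a premature in-frame
  # stop; the base must differ from both neighbours so the insertion
  # position is unambiguous under alignment (no homopolymer sliding)
  found <- FALSE
  for (off in insertion_offset + seq(0L, 60L, by = 3L)) {
    flank_bases <- c(substr(gene, off, off), substr(gene, off + 1L, off + 1L))
    for (base in sample(setdiff(DNA_BASES, flank_bases))) {
      cand <- paste0(substr(gene, 1L, off), base,
                     substring(gene, off + 1L))
      s <- first_stop_codon(cand)
      if (!is.na(s) && s < orig_stop) {
        host_copy <- cand
        ins_off <- off
        stop_idx <- s
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  if (!found) stop("config error: could not construct a frameshift stop",
                   call. = FALSE)

  dr <- random_dna(dr_length)
  dr_phage <- if (dr_mismatches > 0L) {
    pos <- sample(dr_length, dr_mismatches)
    substitute_bases(dr, pos,
                     random_alt_bases(substring(dr, pos, pos)))
  } else dr
  insert <- paste0(dr, host_copy, dr)

  hlen <- nchar(host_seq)
  if (is.null(insert_at)) {
    insert_at <- sample(hlen - nchar(insert) - 4000L, 1L) + 2000L
  }
  host_mod <- paste0(substr(host_seq, 1L, insert_at),
                     insert,
                     substring(host_seq, insert_at + nchar(insert) + 1L))
  # phage-side imperfect repeat copy directly upstream of the gene
  stopifnot(gs >= dr_length)
  phage_mod <- paste0(substr(phage_seq, 1L, gs - dr_length),
                      dr_phage,
                      substring(phage_seq, gs + 1L))
  record <- list(
    host_insert_start = insert_at,
    host_insert_end = insert_at + nchar(insert),
    host_gene_start = insert_at + dr_length,
    host_gene_end = insert_at + dr_length + nchar(host_copy),
    donor_gene_start = gs,
    donor_gene_end = ge,
    dr_sequence = dr,
    dr_phage_sequence = dr_phage,
    dr_phage_start = gs - dr_length,
    insertion_offset = ins_off,
    insertion_pos_host = insert_at + dr_length + ins_off,
    premature_stop_codon = stop_idx,
    original_stop_codon = orig_stop)
  list(host = host_mod, phage = phage_mod, record = record)
}

#' Build a synthetic community with ground truth
#'
#' Generates phage and host genomes (i.i.d. uniform ACGT backbones),
#' plants CRISPR arrays as repeat(spacer repeat)^n runs at recorded
#' positions, copies the configured fraction of spacers from phage genomes
#' with exactly the configured number of substitutions, plants the HGT
#' insert, and draws population variants on the phage genomes with an
#' elevated per-bp rate inside CRISPR-targeted intervals. Deterministic
#' given `config$rng_seed`.
#'
#' @param config A [community_config()].
#' @return List of class `community`: `genomes` (named
#'   [Biostrings::DNAStringSet], hosts then phages), `truth` (list of
#'   data.frames: `arrays`, `repeats`, `spacers`, `phage_hosts`,
#'   `variants`, and the `hgt` record), `abundance` (reference-by-sample
#'   weight matrix) and `config`.
#' @export
build_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  with_seed(config$rng_seed, build_community_impl(config))
}

build_community_impl <- function(cfg) {
  phage_ids <- vapply(cfg$phages, `[[`, "", "label")
  phage_seqs <- setNames(
    random_dna(vapply(cfg$phages, function(p) p$genome_length, 0L)),
    phage_ids)
  host_ids <- vapply(cfg$hosts, `[[`, "", "taxon_label")
  host_seqs <- setNames(
    random_dna(vapply(cfg$hosts, function(h) h$genome_length, 0L)),
    host_ids)

  # phage -> true host assignment (round robin)
  phage_hosts <- data.frame(
    phage_id = phage_ids,
    host_taxon = host_ids[(seq_along(phage_ids) - 1L) %% length(host_ids) + 1L],
    stringsAsFactors = FALSE)

  occupied <- lapply(host_ids, function(...) {
    data.frame(start = integer(0), end = integer(0))
  })
  names(occupied) <- host_ids

  # --- HGT insert (before arrays, so arrays avoid it) ---
  hgt_record <- NULL
  if (!is.null(cfg$hgt_plan)) {
    hp <- cfg$hgt_plan
    donor <- hp$donor_phage
    stopifnot(donor %in% phage_ids)
    recipient <- phage_hosts$host_taxon[phage_hosts$phage_id == donor]
    plen <- nchar(phage_seqs[[donor]])
    gstart <- sample(plen - hp$gene_length - 4000L, 1L) + 2000L
    orf <- make_orf(hp$gene_length)
    phage_seqs[[donor]] <- paste0(
      substr(phage_seqs[[donor]], 1L, gstart),
      orf,
      substring(phage_seqs[[donor]], gstart + hp$gene_length + 1L))
    ph <- plant_hgt(host_seqs[[recipient]], phage_seqs[[donor]],
                    c(gstart, gstart + hp$gene_length),
                    dr_length = hp$direct_repeat_length,
                    dr_mismatches = hp$dr_mismatches,
                    insertion_offset = hp$insertion_offset)
    host_seqs[[recipient]] <- ph$host
    phage_seqs[[donor]] <- ph$phage
    hgt_record <- c(ph$record,
                    list(host_id = recipient, donor_phage = donor))
    occupied[[recipient]] <- rbind(
      occupied[[recipient]],
      data.frame(start = ph$record$host_insert_start - 300L,
                 end = ph$record$host_insert_end + 300L))
  }

  # --- CRISPR arrays with planted spacers ---
  arrays <- list(); repeats <- list(); spacers <- list()
  used_spacer_seqs <- character(0)
  frac <- cfg$protospacer_plan$fraction_of_spacers_from_phages
  nmut <- cfg$protospacer_plan$per_protospacer_mutations
  for (h in cfg$hosts) {
    taxon <- h$taxon_label
    my_phages <- phage_hosts$phage_id[phage_hosts$host_taxon == taxon]
    if (length(my_phages) == 0L) my_phages <- phage_ids
    for (ai in seq_along(h$arrays)) {
      a <- h$arrays[[ai]]
      rep_seq <- if (!is.null(a$repeat_sequence)) a$repeat_sequence
                 else random_dna(a$repeat_length)
      rl <- nchar(rep_seq)
      sl <- a$spacer_length
      ns <- a$n_spacers
      n_from_phage <- round(frac * ns)
      from_phage <- rep(FALSE, ns)
      if (n_from_phage > 0L) from_phage[sample(ns, n_from_phage)] <- TRUE
      sp_seq <- character(ns)
      sp_src_phage <- rep(NA_character_, ns)
      sp_src_start <- rep(NA_integer_, ns)
      for (si in seq_len(ns)) {
        repeat {
          if (from_phage[si]) {
            src <- sample(my_phages, 1L)
            plen <- nchar(phage_seqs[[src]])
            st <- sample(plen - sl + 1L, 1L) - 1L          # 0-based
            s <- substr(phage_seqs[[src]], st + 1L, st + sl)
            if (nmut > 0L) {
              pos <- sample(sl, nmut)
              s <- substitute_bases(s, pos,
                                    random_alt_bases(substring(s, pos, pos)))
            }
          } else {
            src <- NA_character_; st <- NA_integer_
            s <- random_dna(sl)
          }
          if (!(s %in% used_spacer_seqs)) break
        }
        used_spacer_seqs <- c(used_spacer_seqs, s)
        sp_seq[si] <- s
        sp_src_phage[si] <- src
        sp_src_start[si] <- st
      }
      array_seq <- paste0(rep_seq,
                          paste0(sp_seq, rep_seq, collapse = ""))
      alen <- nchar(array_seq)
      glen <- nchar(host_seqs[[taxon]])
      # place without overlapping previous inserts
      repeat {
        pos <- sample(glen - alen - 1000L, 1L) + 500L     # 0-based
        occ <- occupied[[taxon]]
        if (!any(pos < occ$end & (pos + alen) > occ$start)) break
      }
      occupied[[taxon]] <- rbind(occupied[[taxon]],
                                 data.frame(start = pos - 300L,
                                            end = pos + alen + 300L))
      host_seqs[[taxon]] <- paste0(
        substr(host_seqs[[taxon]], 1L, pos),
        array_seq,
        substring(host_seqs[[taxon]], pos + alen + 1L))
      unit_starts <- pos + (seq_len(ns + 1L) - 1L) * (rl + sl)
      array_id <- sprintf("%s_array%d", taxon, ai)
      arrays[[length(arrays) + 1L]] <- data.frame(
        genome_id = taxon, taxon = taxon, array_id = array_id,
        repeat_seq = rep_seq, start = pos, end = pos + alen,
        n_units = ns + 1L, stringsAsFactors = FALSE)
      repeats[[length(repeats) + 1L]] <- data.frame(
        genome_id = taxon, array_id = array_id,
        unit_index = seq_len(ns + 1L) - 1L,
        start = unit_starts, end = unit_starts + rl,
        stringsAsFactors = FALSE)
      spacers[[length(spacers) + 1L]] <- data.frame(
        taxon = taxon, genome_id = taxon, array_id = array_id,
        repeat_seq = rep_seq, spacer_index = seq_len(ns) - 1L,
        sequence = sp_seq,
        source = ifelse(from_phage, "phage", "random"),
        phage_id = sp_src_phage,
        phage_start = sp_src_start,
        phage_end = sp_src_start + sl,
        n_mutations = ifelse(from_phage, nmut, NA_integer_),
        stringsAsFactors = FALSE)
    }
  }
  arrays <- do.call(rbind, arrays)
  repeats <- do.call(rbind, repeats)
  spacers <- do.call(rbind, spacers)

  # --- population variants on the phages ---
  vp <- cfg$variant_plan
  targets <- if (!is.null(vp$target_intervals)) {
    vp$target_intervals
  } else {
    ps <- spacers[spacers$source == "phage", , drop = FALSE]
    data.frame(ref_id = ps$phage_id, start = ps$phage_start,
               end = ps$phage_end, stringsAsFactors = FALSE)
  }
  variants <- list()
  for (pid in phage_ids) {
    plen <- nchar(phage_seqs[[pid]])
    rate <- rep(vp$background_substitution_rate, plen)
    tg <- targets[targets$ref_id == pid, , drop = FALSE]
    targeted <- rep(FALSE, plen)
    if (nrow(tg) > 0L) {
      for (r in seq_len(nrow(tg))) {
        targeted[(tg$start[r] + 1L):tg$end[r]] <- TRUE
      }
      rate[targeted] <- vp$protospacer_substitution_rate
    }
    hit <- which(runif(plen) < rate)
    if (length(hit) == 0L) next
    refb <- substring(phage_seqs[[pid]], hit, hit)
    variants[[length(variants) + 1L]] <- data.frame(
      ref_id = pid, pos = hit - 1L, ref_base = refb,
      alt_base = random_alt_bases(refb),
      freq = vp$allele_frequency,
      targeted = targeted[hit], stringsAsFactors = FALSE)
  }
  variants <- if (length(variants)) do.call(rbind, variants) else
    data.frame(ref_id = character(0), pos = integer(0),
               ref_base = character(0), alt_base = character(0),
               freq = numeric(0), targeted = logical(0),
               stringsAsFactors = FALSE)

  genomes <- Biostrings::DNAStringSet(c(host_seqs, phage_seqs))
  abundance <- rbind(
    do.call(rbind, lapply(cfg$hosts, function(h) h$per_sample_abundance)),
    do.call(rbind, lapply(cfg$phages, function(p) p$per_sample_abundance)))
  rownames(abundance) <- c(host_ids, phage_ids)
  colnames(abundance) <- cfg$samples

  structure(list(genomes = genomes,
                 truth = list(arrays = arrays, repeats = repeats,
                              spacers = spacers, phage_hosts = phage_hosts,
                              variants = variants, hgt = hgt_record),
                 abundance = abundance,
                 config = cfg),
            class = "community")
}

#' Simulate uniform-error short reads from a community
#'
#' Reads are drawn from each genome with probability proportional to
#' abundance weight times genome length, from a uniform start position and
#' a uniform strand; planted population variants are applied to each
#' covering read independently at their allele frequency, then each base
#' is substituted with probability `error_rate`. Qualities are constant.
#' Deterministic given `rng_seed`.
#'
#' @param genomes Named [Biostrings::DNAStringSet] or named character
#'   vector.
#' @param abundance Reference-by-sample numeric matrix of relative weights
#'   (rows matching `names(genomes)`), or a named vector for one sample.
#' @param read_plan List with `read_length`, `n_reads_per_sample`,
#'   `error_rate`, `base_quality`.
#' @param rng_seed Integer seed.
#' @param variants Optional data.frame of planted variants
#'   (`ref_id`, `pos`, `alt_base`, `freq`), normally `truth$variants`.
#' @return List with `reads` (data.frame `read_id`, `sequence`, `quality`,
#'   `sample_id`) and `origins` (data.frame mapping each read to its source
#'   interval and strand).
#' @export
simulate_reads <- function(genomes, abundance, read_plan, rng_seed,
                           variants = NULL) {
  seqs <- if (is.character(genomes)) genomes else
    setNames(as.character(genomes), names(genomes))
  if (is.null(dim(abundance))) {
    abundance <- matrix(abundance, ncol = 1L,
                        dimnames = list(names(abundance), "s01"))
  }
  stopifnot(all(rownames(abundance) %in% names(seqs)))
  rl <- read_plan$read_length
  lens <- nchar(seqs)[rownames(abundance)]
  if (rl > min(lens)) stop("read length exceeds shortest genome",
                           call. = FALSE)
  qual_str <- strrep(phred_encode(read_plan$base_quality), rl)

  with_seed(rng_seed, {
    all_reads <- list(); all_origins <- list()
    for (s in colnames(abundance)) {
      w <- abundance[, s] * lens
      stopifnot(any(w > 0))
      counts <- as.vector(stats::rmultinom(1L, read_plan$n_reads_per_sample,
                                           prob = w / sum(w)))
      names(counts) <- rownames(abundance)
      seq_out <- character(0); org <- list()
      for (ref in names(counts)) {
        k <- counts[[ref]]
        if (k == 0L) next
        glen <- lens[[ref]]
        starts <- sample.int(glen - rl + 1L, k, replace = TRUE)  # 1-based
        strands <- ifelse(runif(k) < 0.5, "+", "-")
        rd <- substring(seqs[[ref]], starts, starts + rl - 1L)
        if (!is.null(variants)) {
          v <- variants[variants$ref_id == ref, , drop = FALSE]
          for (vi in seq_len(nrow(v))) {
            p1 <- v$pos[vi] + 1L
            cov <- which(starts <= p1 & p1 <= starts + rl - 1L)
            if (length(cov) == 0L) next
            carriers <- cov[runif(length(cov)) < v$freq[vi]]
            if (length(carriers) == 0L) next
            rel <- p1 - starts[carriers] + 1L
            tmp <- rd[carriers]
            substr(tmp, rel, rel) <- v$alt_base[vi]
            rd[carriers] <- tmp
          }
        }
        if (read_plan$error_rate > 0) {
          nerr <- rbinom(k, rl, read_plan$error_rate)
          for (i in which(nerr > 0L)) {
            pos <- sample.int(rl, nerr[i])
            rd[i] <- substitute_bases(
              rd[i], pos, random_alt_bases(substring(rd[i], pos, pos)))
          }
        }
        minus <- strands == "-"
        if (any(minus)) rd[minus] <- revcomp(rd[minus])
        seq_out <- c(seq_out, rd)
        org[[length(org) + 1L]] <- data.frame(
          ref_id = ref, start = starts - 1L, end = starts - 1L + rl,
          strand = strands, stringsAsFactors = FALSE)
      }
      org <- do.call(rbind, org)
      ids <- sprintf("%s_r%06d", s, seq_along(seq_out))
      all_reads[[s]] <- data.frame(
        read_id = ids, sequence = seq_out,
        quality = rep(qual_str, length(seq_out)),
        sample_id = s, stringsAsFactors = FALSE)
      org$read_id <- ids
      org$sample_id <- s
      all_origins[[s]] <- org[, c("read_id", "ref_id", "start", "end",
                                  "strand", "sample_id")]
    }
    list(reads = do.call(rbind, c(all_reads, list(make.row.names = FALSE))),
         origins = do.call(rbind, c(all_origins,
                                    list(make.row.names = FALSE))))
  })
}
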