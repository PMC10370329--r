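# Shared fixture builders; everything is generated in code at test time.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

mk_reads <- function(seqs, q = 35L, sample_id = "s1",
                     ids = sprintf("r%04d", seq_along(seqs))) {
  data.frame(read_id = ids, sequence = seqs,
             quality = vapply(nchar(seqs),
                              function(n) strrep(phred_encode(q), n),
                              character(1)),
             sample_id = sample_id, stringsAsFactors = FALSE)
}

mk_qual_read <- function(quals, id = "r1", base = "A", sample_id = "s1") {
  data.frame(read_id = id,
             sequence = strrep(base, length(quals)),
             quality = phred_encode(quals),
             sample_id = sample_id, stringsAsFactors = FALSE)
}

# An intact random ORF (ATG .. non-stop codons .. TAA).
rand_orf <- function(len) {
  stopifnot(len %% 3 == 0, len >= 300)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(sense, len / 3 - 2, replace = TRUE),
                      collapse = ""), "TAA")
}

# The study-condition community: 3 hosts x 2 arrays x 10 spacers, half the
# spacers phage-derived with 2 substitutions, error-free 250-nt reads
# giving the hosts ~20x merged coverage.
study_community <- function(seed, error_rate = 0) {
  cfg <- community_config(
    rng_seed = seed,
    read_plan = list(read_length = 250L, n_reads_per_sample = 4000L,
                     error_rate = error_rate, base_quality = 35L))
  comm <- build_community(cfg)
  sim <- simulate_reads(comm$genomes, comm$abundance, cfg$read_plan,
                        rng_seed = seed + 1000L)
  list(cfg = cfg, comm = comm, sim = sim)
}

host_ids <- function(comm) {
  vapply(comm$config$hosts, `[[`, "", "taxon_label")
}

phage_ids <- function(comm) {
  vapply(comm$config$phages, `[[`, "", "label")
}

# Run array detection + dereplication over the community's host genomes.
mine_repeat_set <- function(comm) {
  arrays <- list()
  for (h in host_ids(comm)) {
    arrays <- c(arrays,
                detect_arrays(as.character(comm$genomes[[h]]), genome_id = h))
  }
  dereplicate_repeats(arrays)
}
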