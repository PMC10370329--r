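one_host_cfg <- function(seed, fraction = 0, nmut = 0L, n_spacers = 3L) {
  community_config(
    rng_seed = seed,
    hosts = list(list(taxon_label = "hostA", genome_length = 20000L,
                      per_sample_abundance = 4,
                      arrays = list(list(repeat_length = 36L,
                                         n_spacers = n_spacers,
                                         spacer_length = 34L)))),
    phages = list(list(label = "phageX", genome_length = 20000L,
                       per_sample_abundance = 1)),
    samples = "s1",
    protospacer_plan = list(fraction_of_spacers_from_phages = fraction,
                            per_protospacer_mutations = nmut),
    hgt_plan = NULL,
    read_plan = list(read_length = 150L, n_reads_per_sample = 2000L,
                     error_rate = 0, base_quality = 35L))
}

test_that("planted arrays appear as repeat(spacer repeat)^n at truth intervals", {
  comm <- build_community(one_host_cfg(101, fraction = 0, n_spacers = 3L))
  g <- as.character(comm$genomes[["hostA"]])
  rep_seq <- comm$truth$arrays$repeat_seq[1]
  reps <- comm$truth$repeats
  expect_identical(nrow(reps), 4L)            # 3 spacers -> 4 repeat units
  for (i in seq_len(nrow(reps))) {
    expect_identical(substr(g, reps$start[i] + 1L, reps$end[i]), rep_seq)
  }
  sp <- comm$truth$spacers
  expect_identical(nrow(sp), 3L)
  expect_true(all(sp$source == "random"))
  # spacers sit strictly between consecutive repeat copies
  for (i in seq_len(3L)) {
    expect_identical(substr(g, reps$end[i] + 1L, reps$start[i + 1L]),
                     sp$sequence[i])
  }
})

test_that("phage-derived spacers are exact phage substrings when unmutated", {
  comm <- build_community(one_host_cfg(102, fraction = 1, nmut = 0L,
                                       n_spacers = 5L))
  sp <- comm$truth$spacers
  expect_true(all(sp$source == "phage"))
  for (i in seq_len(nrow(sp))) {
    src <- as.character(comm$genomes[[sp$phage_id[i]]])
    expect_identical(substr(src, sp$phage_start[i] + 1L, sp$phage_end[i]),
                     sp$sequence[i])
  }
})

test_that("the planted-mutation count between spacer and protospacer is exact", {
  comm <- build_community(one_host_cfg(103, fraction = 1, nmut = 2L,
                                       n_spacers = 5L))
  sp <- comm$truth$spacers
  for (i in seq_len(nrow(sp))) {
    src <- as.character(comm$genomes[[sp$phage_id[i]]])
    proto <- substr(src, sp$phage_start[i] + 1L, sp$phage_end[i])
    expect_identical(berrylink:::hamming(proto, sp$sequence[i]), 2L)
  }
})

test_that("community generation is byte-deterministic under a fixed seed", {
  c1 <- build_community(community_config(rng_seed = 104))
  c2 <- build_community(community_config(rng_seed = 104))
  expect_identical(as.character(c1$genomes), as.character(c2$genomes))
  expect_identical(c1$truth, c2$truth)
  s1 <- simulate_reads(c1$genomes, c1$abundance, c1$config$read_plan, 9L)
  s2 <- simulate_reads(c2$genomes, c2$abundance, c2$config$read_plan, 9L)
  expect_identical(s1$reads, s2$reads)
})

test_that("plant_hgt builds a frameshifted pseudogene flanked by direct repeats", {
  set.seed(105)
  host <- rand_seq(20000)
  phage <- rand_seq(20000)
  orf <- rand_orf(600)
  phage <- paste0(substr(phage, 1, 5000), orf, substring(phage, 5601))
  res <- plant_hgt(host, phage, c(5000L, 5600L), dr_mismatches = 0L)
  rec <- res$record
  # identical flank repeats on both sides of the host copy
  left <- substr(res$host, rec$host_insert_start + 1L,
                 rec$host_insert_start + 17L)
  right <- substr(res$host, rec$host_gene_end + 1L, rec$host_gene_end + 17L)
  expect_identical(left, rec$dr_sequence)
  expect_identical(right, rec$dr_sequence)
  expect_identical(rec$dr_phage_sequence, rec$dr_sequence)  # 0 mismatches
  # host copy translation stops strictly before the donor stop
  host_copy <- substr(res$host, rec$host_gene_start + 1L, rec$host_gene_end)
  expect_lt(berrylink:::first_stop_codon(host_copy), rec$original_stop_codon)
  # the frameshift report recovers the recorded insertion
  fs <- frame_shift_report(orf, host_copy)
  expect_identical(fs$indel_type, "insertion")
  expect_identical(fs$indel_position, rec$insertion_offset)
  expect_identical(fs$premature_stop_position, rec$premature_stop_codon)
})

test_that("plant_hgt rejects donor genes that are not intact ORFs", {
  set.seed(106)
  host <- rand_seq(5000)
  phage <- rand_seq(5000)
  expect_error(plant_hgt(host, phage, c(1000L, 1400L)), "config error")
})

test_that("error-free reads are exact substrings of their recorded origin", {
  comm <- build_community(one_host_cfg(107))
  sim <- simulate_reads(comm$genomes, comm$abundance,
                        comm$config$read_plan, rng_seed = 7L)
  org <- sim$origins
  expect_identical(org$read_id, sim$reads$read_id)
  idx <- sample(nrow(org), 200)
  for (i in idx) {
    src <- substr(as.character(comm$genomes[[org$ref_id[i]]]),
                  org$start[i] + 1L, org$end[i])
    if (org$strand[i] == "-") src <- revcomp(src)
    expect_identical(sim$reads$sequence[i], src)
  }
})

test_that("zero abundance yields zero reads and fractions follow the weights", {
  comm <- build_community(community_config(rng_seed = 108))
  ab <- comm$abundance
  plan <- list(read_length = 150L, n_reads_per_sample = 40000L,
               error_rate = 0, base_quality = 35L)
  sim <- simulate_reads(comm$genomes, ab[, "s01", drop = FALSE], plan, 3L)
  tab <- table(factor(sim$origins$ref_id, levels = rownames(ab)))
  # phage03 is absent from sample s01
  expect_identical(unname(tab[["phage03"]]), 0L)
  # multinomial oracle: per-genome fractions within 3 binomial SE
  w <- ab[, "s01"] * Biostrings::width(comm$genomes)[match(
    rownames(ab), names(comm$genomes))]
  p <- w / sum(w)
  n <- sum(tab)
  for (ref in rownames(ab)) {
    se <- sqrt(p[[ref]] * (1 - p[[ref]]) / n)
    expect_lt(abs(tab[[ref]] / n - p[[ref]]), 3 * se + 1e-12)
  }
})

test_that("variant planting is denser inside targeted intervals", {
  cfg <- community_config(
    rng_seed = 109,
    hosts = list(),
    phages = list(list(label = "pg", genome_length = 200000L,
                       per_sample_abundance = 1)),
    samples = "s1",
    protospacer_plan = list(fraction_of_spacers_from_phages = 0,
                            per_protospacer_mutations = 0L),
    hgt_plan = NULL,
    variant_plan = list(
      background_substitution_rate = 0.003,
      protospacer_substitution_rate = 0.009,
      allele_frequency = 0.5,
      target_intervals = data.frame(ref_id = "pg",
                                    start = seq(0L, 99000L, by = 1000L),
                                    end = seq(0L, 99000L, by = 1000L) + 500L)),
    read_plan = list(read_length = 150L, n_reads_per_sample = 100L,
                     error_rate = 0, base_quality = 35L))
  comm <- build_community(cfg)
  v <- comm$truth$variants
  bp_t <- 100 * 500
  bp_b <- 200000 - bp_t
  rate_t <- sum(v$targeted) / bp_t
  rate_b <- sum(!v$targeted) / bp_b
  expect_lt(abs(rate_t - 0.009), 3 * sqrt(0.009 / bp_t))
  expect_lt(abs(rate_b - 0.003), 3 * sqrt(0.003 / bp_b))
})
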