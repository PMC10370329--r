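aln_row <- function(id, pos, seq, ref = "g") {
  data.frame(read_id = id, ref_id = ref, pos = pos, strand = "+",
             mismatches = 0L, aligned_length = nchar(seq), seq = seq,
             stringsAsFactors = FALSE)
}

test_that("pileup columns match the aligned reads and the coverage track", {
  one <- aln_row("r1", 3L, "ACGTN")
  p <- pileup(one, "g", 10)
  expect_identical(p$counts[, 4], c(A = 1L, C = 0L, G = 0L, T = 0L))
  expect_identical(p$counts[, 7], c(A = 0L, C = 0L, G = 0L, T = 1L))
  expect_identical(sum(p$counts[, 8]), 0L)      # N excluded from base counts
  expect_identical(p$depth[8], 1L)              # but present in depth

  set.seed(601)
  ref_len <- 300
  aln <- do.call(rbind, lapply(1:40, function(i) {
    pos <- sample(0:(ref_len - 50), 1)
    aln_row(sprintf("r%d", i), pos, rand_seq(50))
  }))
  p <- pileup(aln, "g", ref_len)
  tr <- coverage_track(aln, "g", ref_len, 40)
  expect_identical(as.integer(colSums(p$counts)), as.integer(tr$depth))
  # brute-force per-read tally oracle
  brute <- matrix(0L, 4, ref_len, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(nrow(aln))) {
    ch <- strsplit(aln$seq[i], "")[[1]]
    for (j in seq_along(ch)) {
      b <- ch[j]
      if (b %in% rownames(brute)) {
        brute[b, aln$pos[i] + j] <- brute[b, aln$pos[i] + j] + 1L
      }
    }
  }
  expect_identical(p$counts, brute)
})

test_that("variant calling thresholds alternate alleles monotonically", {
  set.seed(602)
  ref <- rand_seq(200)
  reads <- substring(ref, c(1, 21, 41), c(120, 140, 160))
  mut <- reads
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, 100, 100))[1]
  substr(mut[1], 100, 100) <- alt               # pos 99 covered by reads 1-3
  substr(mut[2], 80, 80) <- alt
  aln <- do.call(rbind, mapply(aln_row, sprintf("r%d", 1:3),
                               c(0L, 20L, 40L), mut, SIMPLIFY = FALSE))
  p <- pileup(aln, "g", 200)
  expect_identical(nrow(call_variants(pileup(
    do.call(rbind, mapply(aln_row, sprintf("r%d", 1:3), c(0L, 20L, 40L),
                          reads, SIMPLIFY = FALSE)), "g", 200), ref)), 0L)
  v1 <- call_variants(p, ref, min_alt_reads = 1)
  expect_identical(v1$pos, 99L)
  expect_identical(unique(v1$alt_base), alt)
  expect_identical(v1$alt_count, 2L)
  expect_identical(v1$ref_base, substr(ref, 100, 100))
  v3 <- call_variants(p, ref, min_alt_reads = 3)
  expect_identical(nrow(v3), 0L)
  expect_true(all(v3$pos %in% v1$pos))
})

test_that("window counts tile from zero, respect boundaries, and conserve calls", {
  empty <- window_variant_counts(
    data.frame(pos = integer(0)), ref_length = 350)
  expect_identical(empty$start, c(0L, 100L, 200L, 300L))
  expect_identical(empty$end, c(100L, 200L, 300L, 350L))
  expect_true(all(empty$n_variants == 0L))
  calls <- data.frame(pos = c(0L, 99L, 100L, 349L))
  w <- window_variant_counts(calls, 350)
  expect_identical(w$n_variants, c(2L, 1L, 0L, 1L))
  expect_identical(sum(w$n_variants), nrow(calls))
})

test_that("enrichment is ~1 under uniform rates and flags a zero background", {
  set.seed(603)
  n_win <- 500L
  w <- data.frame(start = (0:(n_win - 1)) * 100L,
                  end = (1:n_win) * 100L,
                  n_variants = rbinom(n_win, 100, 0.02))
  proto <- data.frame(start = w$start[seq(10, 490, by = 10)],
                      end = w$start[seq(10, 490, by = 10)] + 34L)
  en <- protospacer_enrichment(w, proto)
  expect_false(en$undefined)
  expect_identical(en$n_targeted + en$n_background, n_win)
  expect_equal(en$ratio, 1, tolerance = 0.25)
  expect_equal(en$ratio, en$mean_variants_targeted / en$mean_variants_background)

  w0 <- w
  w0$n_variants <- ifelse(seq_len(n_win) %in% seq(10, 490, by = 10), 2L, 0L)
  en0 <- protospacer_enrichment(w0, proto)
  expect_true(en0$undefined)
  expect_true(is.na(en0$ratio))
  expect_error(protospacer_enrichment(w, data.frame(start = -200L,
                                                    end = -100L)),
               "targeted")
})

test_that("logo information content reflects column composition", {
  reads <- rep("ACGTACGTACGTACGTACGT", 8)
  aln <- do.call(rbind, mapply(aln_row, sprintf("r%d", 1:8),
                               rep(0L, 8), reads, SIMPLIFY = FALSE))
  lg <- protospacer_logo(aln, "g", c(4, 12))
  expect_identical(dim(lg$counts), c(4L, 8L))
  expect_equal(lg$information, rep(2, 8))
  expect_true(all(lg$information >= 0 & lg$information <= 2))

  # one column split 2/2/2/2 across bases -> 0 bits; 4/4 -> 1 bit
  seqs <- paste0(c("A", "C", "G", "T", "A", "C", "G", "T"),
                 c("A", "A", "A", "A", "C", "C", "C", "C"),
                 "GGGG")
  aln2 <- do.call(rbind, mapply(aln_row, sprintf("r%d", 1:8),
                                rep(0L, 8), seqs, SIMPLIFY = FALSE))
  lg2 <- protospacer_logo(aln2, "g", c(0, 3))
  expect_equal(lg2$information[1], 0)
  expect_equal(lg2$information[2], 1)
  expect_equal(lg2$information[3], 2)

  # spanning-reads-only rule: a short read never contributes
  aln3 <- rbind(aln2, aln_row("short", 1L, "AA"))
  lg3 <- protospacer_logo(aln3, "g", c(0, 3))
  expect_identical(lg3$n_reads, 8L)
  expect_identical(lg3$counts, lg2$counts)
  expect_error(protospacer_logo(aln2, "g", c(100, 120)), "spans")
})

test_that("a planted 50/50 allele column carries ~1 bit under sampling", {
  set.seed(604)
  ref <- rand_seq(400)
  depth <- 60
  starts <- sample(0:(400 - 100), depth, replace = TRUE)
  seqs <- substring(ref, starts + 1, starts + 100)
  # plant a biallelic site at position 200 (1-based), frequency 0.5
  alt <- setdiff(c("A", "C", "G", "T"), substr(ref, 200, 200))[1]
  cover <- which(starts < 199 & starts + 100 >= 200)
  carriers <- cover[runif(length(cover)) < 0.5]
  for (i in carriers) {
    substr(seqs[i], 200 - starts[i], 200 - starts[i]) <- alt
  }
  aln <- do.call(rbind, mapply(aln_row, sprintf("r%d", 1:depth),
                               as.integer(starts), seqs, SIMPLIFY = FALSE))
  lg <- protospacer_logo(aln, "g", c(190, 210))
  expect_equal(lg$information[10], 1, tolerance = 0.35)
  expect_true(all(lg$information[-10] > 1.9))
})
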