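mk_track <- function(depth, ref = "pg") {
  structure(list(ref_id = ref, depth = depth,
                 normalized = depth / sum(depth)),
            class = "coverage_track")
}

test_that("uniform or empty coverage yields no high-coverage regions", {
  set.seed(701)
  expect_identical(nrow(detect_high_coverage(mk_track(rep(0L, 10000)))), 0L)
  flat <- rpois(10000, 20)
  expect_identical(nrow(detect_high_coverage(mk_track(flat))), 0L)
})

test_that("a planted 4x region is found with accurate boundaries", {
  set.seed(702)
  depth <- rpois(30000, 10)
  depth[12000:13500] <- rpois(1501, 40)
  hc <- detect_high_coverage(mk_track(depth))
  expect_identical(nrow(hc), 1L)
  expect_lt(abs(hc$start - 11999L), 100L)
  expect_lt(abs(hc$end - 13500L), 100L)
  expect_gte(hc$fold_change, 3)
  expect_false(hc$origin_artifact)
  # a region hugging the assembly origin is flagged as a possible
  # circular-permutation artifact
  depth2 <- rpois(30000, 10)
  depth2[1:1500] <- rpois(1500, 40)
  hc2 <- detect_high_coverage(mk_track(depth2))
  expect_true(all(hc2$origin_artifact))
})

test_that("a 2x duplication is invisible at fold 3 but found at fold 1.5", {
  set.seed(703)
  depth <- rpois(20000, 15)
  depth[8000:9000] <- rpois(1001, 30)
  expect_identical(nrow(detect_high_coverage(mk_track(depth), fold = 3)), 0L)
  hc <- detect_high_coverage(mk_track(depth), fold = 1.5)
  expect_identical(nrow(hc), 1L)
  expect_lt(abs(hc$start - 7999L), 150L)
})

test_that("region-to-host alignment finds verbatim and diverged copies only", {
  set.seed(704)
  host <- rand_seq(40000)
  region <- substr(host, 20001, 21500)
  hit <- align_region_to_host(region, host)
  expect_gte(nrow(hit), 1L)
  expect_identical(hit$host_start[1], 20000L)
  expect_identical(hit$host_end[1], 21500L)
  expect_identical(hit$identity[1], 1)
  expect_identical(nrow(align_region_to_host(rand_seq(1500), host)), 0L)
  div <- mutate_seq(region, sample(1500, 75))    # 5% divergence
  hd <- align_region_to_host(div, host)
  expect_gte(nrow(hd), 1L)
  expect_equal(hd$identity[1], 0.95, tolerance = 0.022)
  # reverse-complement copies are reported on the minus strand
  hr <- align_region_to_host(revcomp(region), host)
  expect_identical(hr$strand[1], "-")
  expect_identical(hr$host_start[1], 20000L)
})

brute_short_repeats <- function(a, b, minl, maxl, mm, kind) {
  bb <- if (kind == "direct") b else revcomp(b)
  av <- utf8ToInt(a); bv <- utf8ToInt(bb)
  na <- length(av); nb <- length(bv)
  out <- list()
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      L <- min(na - i + 1, nb - j + 1)
      if (L < minl) next
      d <- cumsum(av[i:(i + L - 1)] != bv[j:(j + L - 1)])
      for (len in minl:min(L, maxl)) {
        if (d[len] > mm) next
        extl <- i > 1 && j > 1 &&
          d[len] + (av[i - 1] != bv[j - 1]) <= mm
        extr <- len < L && d[len + 1] <= mm
        if (!extl && !extr) {
          out[[length(out) + 1]] <- sprintf("%d:%d:%d", i - 1, j - 1, len)
        }
      }
    }
  }
  sort(unique(unlist(out)))
}

test_that("short repeat pairs match brute-force enumeration", {
  set.seed(705)
  for (mm in 0:1) {
    a <- rand_seq(400)
    b <- rand_seq(400)
    dr <- rand_seq(17)
    substr(a, 101, 117) <- dr
    substr(b, 201, 217) <- if (mm == 1) mutate_seq(dr, 9) else dr
    got <- find_short_repeats(a, b, min_len = 12, max_len = 40,
                              max_mismatch = mm, kinds = "direct")
    bkey <- brute_short_repeats(a, b, 12, 40, mm, "direct")
    gkey <- sort(sprintf("%d:%d:%d", got$a_start, got$b_start, got$length))
    expect_identical(gkey, bkey)
    # the planted 17-bp direct repeat is reported with its mismatch count
    planted <- got[got$a_start == 100 & got$b_start == 200, ]
    expect_identical(nrow(planted), 1L)
    expect_gte(planted$length, 17L)
    expect_identical(planted$mismatches, mm)
    expect_identical(planted$kind, "direct")
  }
})

test_that("inverted pairs are reported with forward-strand coordinates", {
  set.seed(706)
  a <- rand_seq(500)
  b <- rand_seq(500)
  arm <- rand_seq(20)
  substr(a, 101, 120) <- arm
  substr(b, 301, 320) <- revcomp(arm)
  got <- find_short_repeats(a, b, min_len = 15, max_len = 40,
                            max_mismatch = 0, kinds = "inverted")
  planted <- got[got$a_start <= 100 & got$a_end >= 120, ]
  expect_identical(nrow(planted), 1L)
  expect_identical(planted$mismatches, 0L)
  expect_identical(substr(b, planted$b_start + 1, planted$b_end),
                   revcomp(substr(a, planted$a_start + 1, planted$a_end)))
})

test_that("TIR search ranks the planted transposon arms first", {
  set.seed(707)
  g <- rand_seq(5000)
  arm <- rand_seq(25)
  substr(g, 1501, 1525) <- arm
  substr(g, 2701, 2725) <- revcomp(arm)
  tirs <- find_tirs(g, c(1000, 3500))
  expect_gt(nrow(tirs), 0L)
  top <- tirs[1, ]
  expect_lte(abs(top$a_start - 1500L), 5L)
  expect_lte(abs(top$b_end - 2725L), 5L)
  expect_gte(top$gap, 500L)
  # a window without inverted repeats is empty
  set.seed(708)
  expect_identical(nrow(find_tirs(rand_seq(4000), c(500, 3500),
                                  tir_len = c(14, 40), max_mismatch = 0)), 0L)
})

test_that("frameshift reports recover planted single-base indels", {
  set.seed(709)
  orf <- rand_orf(900)
  expect_identical(frame_shift_report(orf, orf)$indel_type, NA_character_)
  expect_true(is.na(frame_shift_report(orf, orf)$premature_stop_position))
  # unambiguous insertion: the base differs from both neighbours
  off <- 150L
  base <- setdiff(c("A", "C", "G", "T"),
                  c(substr(orf, off, off), substr(orf, off + 1, off + 1)))[1]
  orfb <- paste0(substr(orf, 1, off), base, substring(orf, off + 1))
  fs <- frame_shift_report(orf, orfb)
  expect_identical(fs$indel_type, "insertion")
  expect_identical(fs$indel_position, off)
  if (!is.na(fs$premature_stop_position)) {
    expect_lt(fs$premature_stop_position, fs$original_stop_position)
  }
  orfd <- paste0(substr(orf, 1, off), substring(orf, off + 2))
  expect_identical(frame_shift_report(orf, orfd)$indel_type, "deletion")
  expect_error(frame_shift_report(rand_seq(900), orfb), "intact ORF")
})

test_that("fragment ANI is exact on self and tracks planted divergence", {
  set.seed(710)
  g <- rand_seq(25000)
  self <- compute_ani(g, g)
  expect_identical(self$ani_percent, 100)
  expect_identical(self$n_fragments_used, self$n_fragments_total)
  g2 <- mutate_seq(g, which(runif(25000) < 0.01))
  ani <- compute_ani(g, g2)
  expect_equal(ani$ani_percent, 99.0, tolerance = 0.3)
  unrelated <- compute_ani(g, rand_seq(25000))
  expect_true(unrelated$undefined || unrelated$n_fragments_used <= 1L)
})
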