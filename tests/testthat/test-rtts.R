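test_that("call_rt_stops applies the 5'-adjacent-nucleotide rule", {
  aln <- data.frame(ref = "18S", pos_5prime = 803L)
  prof <- call_rt_stops(aln, "18S", 1869)
  expect_equal(prof$counts[802], 1)
  expect_equal(sum(prof$counts), 1)

  # read starting at position 1: counted, but no site incremented
  aln1 <- data.frame(ref = "18S", pos_5prime = 1L)
  prof1 <- call_rt_stops(aln1, "18S", 1869)
  expect_equal(sum(prof1$counts), 0)
  expect_equal(prof1$total_reads, 1L)

  # 100 planted reads, no noise: tally equals brute-force oracle
  sim <- gen_rtts_reads(rtts_sim_spec(
    planted_sites = data.frame(position = 850, intensity = 100),
    background_rate = 0, n_reads = 100, seed = 5))
  prof2 <- call_rt_stops(sim$alignments, "18S", 1869)
  expect_equal(which.max(prof2$counts), 850L)
  expect_equal(prof2$counts[850], 100)
  expect_equal(prof2$counts, oracle_rt_tally(sim$alignments$pos_5prime, 1869))

  expect_error(call_rt_stops(data.frame(ref = "28S", pos_5prime = 5L),
                             "18S", 1869), "unknown reference")
})

test_that("call_rt_stops is permutation-invariant and conserves reads", {
  sim <- gen_rtts_reads(rtts_sim_spec(
    planted_sites = data.frame(position = c(100, 850), intensity = c(30, 70)),
    background_rate = 0.2, seed = 21))
  aln <- sim$alignments
  p1 <- call_rt_stops(aln, "18S", 1869)
  set.seed(1)
  p2 <- call_rt_stops(aln[sample(nrow(aln)), ], "18S", 1869)
  expect_equal(p1$counts, p2$counts)
  expect_equal(sum(p1$counts), sum(aln$pos_5prime >= 2))
})

test_that("reverse-strand and malformed records are skipped and reported", {
  aln <- data.frame(ref = "18S", pos_5prime = c(100L, 200L, 300L, 5000L),
                    flag = c(0L, 16L, 0L, 0L))
  prof <- call_rt_stops(aln, "18S", 1869)
  expect_equal(unname(prof$skipped["reverse_strand"]), 1L)
  expect_equal(unname(prof$skipped["malformed_position"]), 1L)
  expect_equal(sum(prof$counts), 2)
})

test_that("SAM round trip preserves the profile", {
  sim <- gen_rtts_reads(rtts_sim_spec(
    planted_sites = data.frame(position = c(802, 850), intensity = c(40, 60)),
    background_rate = 0.1, seed = 33))
  sam <- tempfile(fileext = ".sam")
  write_alignments_sam(sim$alignments, sam, 1869)
  back <- read_sam_minimal(sam)
  expect_equal(call_rt_stops(back, "18S", 1869)$counts,
               call_rt_stops(sim$alignments, "18S", 1869)$counts)
  unlink(sam)
})

test_that("top_sites ranks by count with deterministic tie-breaking", {
  counts <- numeric(1869)
  counts[c(850, 802, 700)] <- c(40, 30, 30)
  prof <- rt_stop_profile(counts)
  expect_equal(nrow(top_sites(prof, 0)), 0L)
  t2 <- top_sites(prof, 2)
  expect_equal(t2$position, c(850L, 700L))  # tie at 30: ascending position
  expect_equal(t2$count, c(40, 30))

  # uniform profile, k = reference length: everything returned
  pu <- rt_stop_profile(rep(1, 50))
  expect_equal(top_sites(pu, 50)$position, 1:50)

  # random profiles agree with the exhaustive sort oracle
  set.seed(99)
  for (i in 1:20) {
    cc <- rpois(200, 0.5)
    pr <- rt_stop_profile(cc)
    k <- sample(0:20, 1)
    got <- top_sites(pr, k)
    exp <- oracle_top_sites(cc, k)
    expect_equal(got$position, exp$position)
    expect_equal(got$count, exp$count)
  }
})

test_that("background-free recovery returns exactly the planted set", {
  set.seed(7)
  pos <- sort(sample(2:1869, 15))
  sim <- gen_rtts_reads(rtts_sim_spec(
    planted_sites = data.frame(position = pos, intensity = 25),
    background_rate = 0, seed = 8))
  prof <- call_rt_stops(sim$alignments, "18S", 1869)
  expect_setequal(top_sites(prof, 15)$position, pos)
})

test_that("helix annotation matches the printed ES6S intervals", {
  expect_equal(annotate_site(802), "ES6S_CD")  # base of helix C
  expect_equal(annotate_site(c(681, 735)), c("ES6S_A", "ES6S_A"))
  expect_true(is.na(annotate_site(737)))       # gap 736-739
  expect_error(helix_map(data.frame(label = c("x", "y"),
                                    start = c(1, 5), end = c(10, 8))),
               "overlapping")
})

test_that("region_fraction computes the in-region share of events", {
  counts <- numeric(1869); counts[850] <- 80; counts[500] <- 20
  expect_equal(region_fraction(rt_stop_profile(counts)), 0.8)
  counts2 <- numeric(1869); counts2[750] <- 5
  expect_equal(region_fraction(rt_stop_profile(counts2)), 1.0)
  expect_equal(region_fraction(rt_stop_profile(numeric(1869))), 0)
  expect_error(region_fraction(rt_stop_profile(counts), 910, 700), "start")
})

test_that("compare_profiles stays finite and centres at zero", {
  counts <- numeric(100); counts[c(10, 20)] <- c(5, 10)
  p <- rt_stop_profile(counts)
  cmp <- compare_profiles(p, p)
  expect_true(all(cmp$log2_ratio == 0))

  # doubled count at one position, equal depth elsewhere
  ca <- numeric(100); ca[50] <- 100; ca[60] <- 100
  cb <- numeric(100); cb[50] <- 200; cb[60] <- 100; cb[70] <- 0
  pa <- rt_stop_profile(ca); pb <- rt_stop_profile(cb)
  # normalize depths: compare rate ratios at position 50
  cmp2 <- compare_profiles(pb, pa)
  r50 <- cmp2$log2_ratio[cmp2$position == 50]
  expect_lt(abs(r50 - (log2(201 / 300) - log2(101 / 200))), 1e-12)

  # disjoint supports: finite values via pseudocount
  cx <- numeric(100); cx[10] <- 5
  cy <- numeric(100); cy[90] <- 5
  cmp3 <- compare_profiles(rt_stop_profile(cx), rt_stop_profile(cy))
  expect_true(all(is.finite(cmp3$log2_ratio)))
  expect_error(compare_profiles(p, rt_stop_profile(numeric(50))),
               "differing reference lengths")
})

test_that("track export uses 0-based half-open coordinates", {
  counts <- numeric(100); counts[50] <- 7
  prof <- rt_stop_profile(counts)
  bg <- tempfile(fileext = ".bedgraph")
  write_bedgraph(prof, bg)
  line <- strsplit(readLines(bg), "\t")[[1]]
  expect_equal(as.integer(line[2:3]), c(49L, 50L))
  unlink(bg)
})
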