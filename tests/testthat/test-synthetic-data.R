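test_that("gen_rtts_reads honours the pure RT-stop model and edge cases", {
  # no-noise limit: every read 5' end one nt 3' of the planted site
  spec <- rtts_sim_spec(planted_sites = data.frame(position = 850,
                                                   intensity = 100),
                        background_rate = 0, n_reads = 100, seed = 11)
  sim <- gen_rtts_reads(spec)
  expect_equal(nrow(sim$alignments), 100L)
  expect_true(all(sim$alignments$pos_5prime == 851L))
  expect_equal(sim$truth$expected_fraction, 1)

  # empty case: truth table still emitted
  sim0 <- gen_rtts_reads(rtts_sim_spec(
    planted_sites = data.frame(position = 850, intensity = 1),
    n_reads = 0, seed = 1))
  expect_equal(nrow(sim0$alignments), 0L)
  expect_equal(sim0$truth$position, 850)

  # site at position 1 has no 5'-adjacent nucleotide
  expect_error(rtts_sim_spec(planted_sites = data.frame(position = 1,
                                                        intensity = 1)),
               "position 1")
})

test_that("two-site intensity ratio matches the binomial oracle", {
  spec <- rtts_sim_spec(planted_sites = data.frame(position = c(300, 900),
                                                   intensity = c(7500, 2500)),
                        background_rate = 0, n_reads = 10000, seed = 42)
  sim <- gen_rtts_reads(spec)
  n1 <- sum(sim$alignments$pos_5prime == 301L)
  # binomial oracle: n1 ~ Bin(10000, 0.75)
  expect_lt(abs(n1 - 7500), 3 * sqrt(10000 * 0.75 * 0.25))
  expect_equal(n1 + sum(sim$alignments$pos_5prime == 901L), 10000L)
})

test_that("generators are bit-reproducible given a seed", {
  s <- rtts_sim_spec(planted_sites = data.frame(position = c(100, 500),
                                                intensity = c(5, 5)),
                     background_rate = 0.5, seed = 7)
  expect_identical(gen_rtts_reads(s), gen_rtts_reads(s))
  cs <- count_sim_spec(n_genes = 50, spike_in_count = 5, seed = 3)
  expect_identical(gen_count_matrix(cs), gen_count_matrix(cs))
  us <- utr_sim_spec(n_sequences = 10, seed = 5)
  expect_identical(gen_utrs(us), gen_utrs(us))
  expect_identical(gen_dose_response(1, 2, c(0.5, 1, 2), 0.05, seed = 9),
                   gen_dose_response(1, 2, c(0.5, 1, 2), 0.05, seed = 9))
})

test_that("gen_count_matrix deterministic limits and planted effects", {
  # dispersion 0, no planted effect: P/M ratio identical across conditions
  # up to size factors
  spec <- count_sim_spec(n_genes = 20, spike_in_count = 5, dispersion = 0,
                         true_size_factors = rep(1, 12), seed = 2)
  sim <- gen_count_matrix(spec)
  d <- sim$design
  ctl_p <- sim$counts[, d$condition == "control" & d$fraction == "polysomal"]
  ctl_m <- sim$counts[, d$condition == "control" & d$fraction == "monosomal"]
  trt_p <- sim$counts[, d$condition == "treated" & d$fraction == "polysomal"]
  trt_m <- sim$counts[, d$condition == "treated" & d$fraction == "monosomal"]
  expect_equal(rowMeans(ctl_p) / rowMeans(ctl_m),
               rowMeans(trt_p) / rowMeans(trt_m))

  # size factors (1, 2), dispersion 0: spike counts exactly double
  design2 <- default_polysome_design()[c(1, 2, 4, 5), ]
  design2 <- rbind(design2, design2)
  design2$condition <- rep(c("control", "treated"), each = 4)
  design2$sample_id <- sprintf("s%d", 1:8)
  sf <- rep(c(1, 2), 4)
  spec2 <- count_sim_spec(n_genes = 5, design = design2, spike_in_count = 3,
                          true_size_factors = sf, dispersion = 0, seed = 2)
  sim2 <- gen_count_matrix(spec2)
  spikes <- sim2$counts[sim2$truth$is_spike, ]
  expect_equal(spikes[, 2], 2 * spikes[, 1])

  # missing fraction rejected
  bad <- default_polysome_design()
  bad <- bad[bad$fraction == "monosomal" | bad$condition == "control", ]
  expect_error(count_sim_spec(design = bad), "replicates of each fraction")
})

test_that("planted log2 FC TE is realized on average (Monte-Carlo oracle)", {
  fc <- c(rep(2, 200), rep(0, 1800))
  spec <- count_sim_spec(n_genes = 2000, planted_log2_fc_te = fc,
                         dispersion = 0.05, seed = 101)
  sim <- gen_count_matrix(spec)
  d <- sim$design
  te_of <- function(cond) {
    p <- rowMeans(sim$counts[, d$condition == cond &
                               d$fraction == "polysomal"])
    m <- rowMeans(sim$counts[, d$condition == cond &
                               d$fraction == "monosomal"])
    (p + 0.5) / (m + 0.5)
  }
  realized <- log2(te_of("control") / te_of("treated"))
  expect_lt(abs(mean(realized[1:200]) - 2), 0.1)
  expect_lt(abs(mean(realized[201:2000])), 0.1)
  # spike-ins carry no condition effect by construction
  expect_true(all(sim$truth$planted_log2_fc_te[sim$truth$is_spike] == 0))
})

test_that("gen_utrs plants motifs verbatim and controls GC", {
  sim <- gen_utrs(utr_sim_spec(n_sequences = 100, groups = "g",
                               p_g4 = 1, p_ggc = 0, seed = 13))
  hits <- vapply(sim$sequences, function(s) nrow(scan_g4(s)), integer(1))
  expect_true(all(hits >= 1))

  # GC within 3 SD of the binomial expectation for one long sequence
  sim2 <- gen_utrs(utr_sim_spec(n_sequences = 1, groups = "g",
                                length_meanlog = log(1000),
                                length_sdlog = 0, gc_target = 0.5,
                                p_g4 = 0, p_ggc = 0, seed = 17))
  n <- nchar(sim2$sequences[[1]])
  gc <- gc_content(sim2$sequences[[1]]) / 100
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / n))

  # G-free alphabet: scanners report nothing
  sim3 <- gen_utrs(utr_sim_spec(n_sequences = 20, groups = "g",
                                p_g4 = 0, p_ggc = 0, g_free = TRUE,
                                seed = 19))
  expect_true(all(vapply(sim3$sequences,
                         function(s) nrow(scan_g4(s)) +
                           nrow(scan_ggc_repeats(s)), integer(1)) == 0L))

  # motif longer than sequence
  expect_error(gen_utrs(utr_sim_spec(n_sequences = 5, groups = "g",
                                     length_meanlog = log(8),
                                     length_sdlog = 0, min_length = 1,
                                     p_g4 = 1, seed = 1)),
               "motif longer")
})

test_that("gen_luc_curve rises at the planted onset and shifts cleanly", {
  sim <- gen_luc_curve(curve_sim_spec(onset_time = 9.5,
                                      baseline_noise_sd = 0,
                                      sampling_interval = 0.1))
  inc <- diff(sim$curve$signal)
  first_rise <- sim$curve$time_min[which(inc > 0)[1]]
  expect_equal(first_rise, 9.5)

  expect_error(curve_sim_spec(onset_time = 95, duration = 90),
               "duration")

  # pointwise time shift between onsets 9.53 and 7.89 (delta 1.64 min)
  a <- gen_luc_curve(curve_sim_spec(onset_time = 9.53, duration = 60,
                                    sampling_interval = 0.41))$curve
  b <- gen_luc_curve(curve_sim_spec(onset_time = 7.89, duration = 60,
                                    sampling_interval = 0.41))$curve
  shift_n <- round(1.64 / 0.41)
  n <- nrow(a)
  expect_equal(a$signal[(shift_n + 1):n], b$signal[1:(n - shift_n)])
})

test_that("gen_dose_response follows the median-effect equation", {
  expect_equal(gen_dose_response(2, 3, 2)$fa, 0.5)   # d = Dm
  expect_equal(gen_dose_response(2, 3, 0)$fa, 0)     # d = 0
  expect_equal(gen_dose_response(1, 2, 2)$fa, 4 / 5) # closed form
  expect_error(gen_dose_response(1, 2, -1), "negative dose")
  expect_error(gen_dose_response(0, 2, 1), "Dm")
})
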