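test_that("size_factors implements median-of-ratios with geomean-1 scale", {
  m <- matrix(c(5, 10, 3, 5, 10, 3), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  # sample 2 doubles sample 1 on every reference row
  m2 <- matrix(c(10, 30, 20, 60), ncol = 2)
  f <- unname(size_factors(m2))
  expect_equal(f, c(1 / sqrt(2), sqrt(2)))
  expect_equal(f[2] / f[1], 2)

  # rows containing zeros are excluded from the reference set
  m3 <- rbind(c(0, 5), m2)
  expect_equal(unname(size_factors(m3)), f)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "no usable reference")
})

test_that("planted size factors are recovered from spike-ins (fixed seed)", {
  set.seed(123)
  sf <- c(1, 2, 0.5)
  base <- exp(rnorm(50, log(500), 0.8))
  mu <- outer(base, sf)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.02), nrow = 50)
  rec <- unname(size_factors(counts))
  planted <- sf / exp(mean(log(sf)))
  expect_true(all(abs(rec / planted - 1) < 0.05))
})

test_that("scaling one sample scales its factor and leaves TE invariant", {
  sim <- gen_count_matrix(count_sim_spec(n_genes = 100, spike_in_count = 20,
                                         dispersion = 0.05, seed = 55))
  counts <- sim$counts
  spikes <- grep("^ERCC-", rownames(counts))
  f0 <- size_factors(counts, spikes)
  scaled <- counts
  scaled[, 3] <- scaled[, 3] * 4
  f1 <- size_factors(scaled, spikes)
  # factor of sample 3 scales by 4 relative to every untouched sample
  # (the global geomean-1 rescale shifts all factors together)
  expect_equal(unname((f1 / f0)[3] / (f1 / f0)[1]), 4)
  # TE exactly invariant (pseudocount 0: the ratio is scale-free)
  te0 <- compute_te(normalize_counts(counts, f0), sim$design,
                    pseudocount = 0)
  te1 <- compute_te(normalize_counts(scaled, f1), sim$design,
                    pseudocount = 0)
  expect_equal(te0, te1)
})

test_that("compute_te and fc_te follow their definitions", {
  design <- default_polysome_design()[1:6, ]  # control only
  nc <- matrix(rep(c(8, 8, 8, 8, 8, 8), each = 3), nrow = 3)
  nc[2, 4:6] <- 16  # P = 2M for gene 2
  nc[3, 1:3] <- 0; nc[3, 4:6] <- 10  # M = 0, P = 10
  te <- compute_te(nc, design, pseudocount = 0.5)
  expect_equal(unname(te[1, "control"]), 1)
  expect_lt(abs(te[2, "control"] - 2), 0.07)   # pseudocount nearly negligible
  expect_equal(unname(te[3, "control"]), 21)   # 10.5 / 0.5

  expect_equal(fc_te(2, 2), 0)
  expect_equal(fc_te(4, 2), 1)
  expect_equal(fc_te(2^(-0.7) * 3, 3), -0.7)
  expect_error(fc_te(0, 1), "TE")
  poly <- design$fraction == "polysomal"
  expect_error(compute_te(nc[, poly], design[poly, ]), "lacks")
})

test_that("test_te_change conventions and BH adjustment", {
  # identical replicate vectors in both conditions: p = 1
  m <- matrix(rep(c(1, 2, 3), 2), nrow = 1)
  res <- test_te_change(m, c("a", "a", "a", "b", "b", "b"))
  expect_equal(res$p_value, 1)

  # BH closed form: (0.01, 0.02, 0.03, 0.04) -> all 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))

  # planted shift is detected: median p over 200 planted genes < 0.05
  fc <- c(rep(2, 200), rep(0, 1800))
  sim <- gen_count_matrix(count_sim_spec(n_genes = 2000,
                                         planted_log2_fc_te = fc,
                                         dispersion = 0.05, seed = 77))
  tab <- te_pipeline(sim$counts, sim$design, keep_spikes = FALSE)
  planted <- tab[match(sprintf("gene_%04d", 1:200), tab$gene_id), ]
  expect_lt(median(planted$p_value, na.rm = TRUE), 0.05)
})

test_that("permutation test broadly agrees with Welch on strong signal", {
  set.seed(42)
  m <- rbind(c(rnorm(3, 0, 0.1), rnorm(3, 3, 0.1)),
             c(rnorm(3, 0, 0.1), rnorm(3, 0, 0.1)))
  labs <- rep(c("a", "b"), each = 3)
  pw <- test_te_change(m, labs, method = "welch")$p_value
  pp <- test_te_change(m, labs, method = "permutation", n_perm = 500)$p_value
  expect_lt(pw[1], 0.01)
  # enumeration: only the true assignment and its mirror reach the observed
  # statistic, so p is exactly 2 / choose(6, 3)
  expect_equal(pp[1], 2 / 20)
  expect_gt(pp[2], 0.2)
})

test_that("variance shrinkage matches the limma empirical-Bayes oracle", {
  set.seed(3)
  s2 <- rchisq(400, 4) / 4 * 0.1 * exp(rnorm(400, 0, 0.3))
  mine <- threadscan:::.squeeze_var(s2, 4)
  lim <- limma::squeezeVar(s2, 4)
  expect_equal(mine$df_prior, lim$df.prior, tolerance = 1e-6)
  expect_equal(mine$var_prior, lim$var.prior, tolerance = 1e-6)
  expect_equal(mine$var_post, lim$var.post, tolerance = 1e-6)
})

test_that("moderated test rescues power that Welch lacks at n = 3", {
  fc <- c(rep(2, 100), rep(0, 900))
  sim <- gen_count_matrix(count_sim_spec(n_genes = 1000,
                                         planted_log2_fc_te = fc,
                                         dispersion = 0.05, seed = 6))
  tabm <- te_pipeline(sim$counts, sim$design, keep_spikes = FALSE,
                      test_method = "moderated")
  tabw <- te_pipeline(sim$counts, sim$design, keep_spikes = FALSE,
                      test_method = "welch")
  planted <- sprintf("gene_%04d", 1:100)
  sens_m <- mean(tabm$class[match(planted, tabm$gene_id)] == "TE_down",
                 na.rm = TRUE)
  sens_w <- mean(tabw$class[match(planted, tabw$gene_id)] == "TE_down",
                 na.rm = TRUE)
  expect_gt(sens_m, 0.8)
  expect_gte(sens_m, sens_w)
  # and stays quiet on nulls
  nulls <- setdiff(tabm$gene_id, planted)
  expect_lt(mean(tabm$class[match(nulls, tabm$gene_id)] != "unchanged"),
            0.02)
})

test_that("classify_te applies the printed thresholds and the p gate", {
  expect_equal(classify_te(1.2, 0.01), "TE_down")
  expect_equal(classify_te(-0.8, 0.01), "TE_up")
  expect_equal(classify_te(1.2, 0.2), "unchanged")
  expect_equal(classify_te(0.9, 0.001), "unchanged")   # below down threshold
  expect_equal(classify_te(-0.7, 0.001), "unchanged")  # boundary is strict
  expect_error(classify_te(1, 0.5, down_threshold = -1), "down_threshold")
})

test_that("spike-ins remain null through the whole pipeline", {
  sim <- gen_count_matrix(count_sim_spec(n_genes = 500, spike_in_count = 50,
                                         dispersion = 0.05, seed = 31))
  tab <- te_pipeline(sim$counts, sim$design)
  spk <- tab[tab$is_spike, ]
  expect_lt(median(abs(spk$log2_fc_te)), 0.1)
  expect_true(all(spk$class == "unchanged"))
})

test_that("count matrix and TE table survive a TSV round trip", {
  sim <- gen_count_matrix(count_sim_spec(n_genes = 30, spike_in_count = 5,
                                         dispersion = 0.02, seed = 9))
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(gene_id = rownames(sim$counts), sim$counts,
                   check.names = FALSE)
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_count_matrix(f)
  expect_equal(back, sim$counts)
  tab <- te_pipeline(sim$counts, sim$design)
  f2 <- tempfile(fileext = ".tsv")
  write_te_table(tab, f2)
  back2 <- read_te_table(f2)
  expect_equal(back2$class, tab$class)
  expect_equal(back2$log2_fc_te, tab$log2_fc_te, tolerance = 1e-8)
  unlink(c(f, f2))
})
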