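test_that("default design yields 32 comparison levels, 8 channels per chip", {
  des <- simulate_design(sim_config())
  expect_equal(nrow(des), 32L)
  expect_equal(length(unique(des$channel)), 32L)
  expect_equal(as.vector(table(des$chip)), rep(8L, 4))
  # one red and one green channel per array
  tab <- table(paste(des$chip, des$array), des$dye)
  expect_true(all(tab == 1L))
})

test_that("design honours dye balance and avoids confounding", {
  des <- simulate_design(sim_config())
  # any animal hybridised more than once is labelled with both dyes
  dye_tab <- table(des$animal, des$dye)
  multi <- rowSums(dye_tab) > 1
  expect_true(all(dye_tab[multi, 1] > 0 & dye_tab[multi, 2] > 0))
  # every phenotype and both sexes appear on every chip
  expect_true(all(table(des$chip, des$phenotype) > 0))
  expect_true(all(table(des$chip, des$sex) > 0))
  # herd structure: 11 animals, 4 polled / 3 horned / 4 scurred, 6 M / 5 F
  roster <- unique(des[, c("animal", "phenotype", "sex")])
  expect_equal(nrow(roster), 11L)
  expect_equal(sort(as.vector(table(roster$phenotype))), c(3L, 4L, 4L))
  expect_equal(sort(as.vector(table(roster$sex))), c(5L, 6L))
  # scurred usage: some animals used twice, others three times
  use <- table(des$animal)
  expect_setequal(as.vector(use), c(2L, 3L))
})

test_that("minimal one-chip one-array design has 2 levels and both dyes", {
  des <- simulate_design(sim_config(n_chips = 1, n_arrays_per_chip = 1))
  expect_equal(nrow(des), 2L)
  expect_setequal(des$dye, c("red", "green"))
})

test_that("simulated intensities follow the additive log2 model", {
  # degenerate model: all variances zero pins every corrected intensity at mu
  cfg0 <- sim_config(n_probes = 10, mu = 5, var_g = 0, var_ag = 0,
                     var_dg = 0, var_hg = 0, var_sg = 0, var_e = 0,
                     de_fraction = 0, bad_spot_fraction = 0)
  des <- simulate_design(cfg0)
  sim <- simulate_spots(des, cfg0)
  expect_equal(log2(sim$spots$fg_mean - sim$spots$bg_mean),
               rep(5, nrow(sim$spots)))

  # moments: mean ~ mu, variance ~ sum of components (3 SE tolerance)
  cfg <- sim_config(n_probes = 1500, de_fraction = 0, bad_spot_fraction = 0,
                    seed = 3)
  des <- simulate_design(cfg)
  sim <- simulate_spots(des, cfg)
  y <- log2(sim$spots$fg_mean - sim$spots$bg_mean)
  vtot <- with(cfg, var_g + var_ag + var_dg + var_hg + var_sg + var_e)
  # clustered draws: gene effects dominate, so SE of the mean is governed
  # by the n_probes independent gene draws
  se_mean <- sqrt(cfg$var_g / cfg$n_probes)
  expect_lt(abs(mean(y) - cfg$mu), 3 * se_mean)
  se_var <- vtot * sqrt(2 / cfg$n_probes)
  expect_lt(abs(var(y) - vtot), 3 * se_var)
})

test_that("spot simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_probes = 50)
  des <- simulate_design(cfg)
  a <- simulate_spots(des, cfg, seed = 123)
  b <- simulate_spots(des, cfg, seed = 123)
  expect_identical(a, b)
  c2 <- simulate_spots(des, cfg, seed = 124)
  expect_false(identical(a$spots$fg_mean, c2$spots$fg_mean))
})

test_that("engineered bad spots fail QC at about the configured rate", {
  cfg <- sim_config(n_probes = 800, bad_spot_fraction = 0.1, seed = 21)
  des <- simulate_design(cfg)
  sim <- simulate_spots(des, cfg)
  qc <- apply_qc(sim$spots)
  n <- nrow(sim$spots)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(mean(!qc$passed) - 0.1), 3 * se)
})

test_that("truth table flags are consistent with planted shifts", {
  cfg <- sim_config(n_probes = 500, de_fraction = 0.1, seed = 8)
  des <- simulate_design(cfg)
  tr <- simulate_spots(des, cfg)$truth
  expect_equal(tr$de_PvH, tr$shift_polled != tr$shift_horned)
  expect_equal(tr$de_PvS, tr$shift_polled != tr$shift_scurred)
  expect_equal(tr$de_HvS, tr$shift_horned != tr$shift_scurred)
  planted <- tr$shift_polled != 0 | tr$shift_horned != 0 |
    tr$shift_scurred != 0
  expect_equal(sum(planted), round(0.1 * 500))
  expect_true(all(abs(c(tr$shift_polled, tr$shift_horned,
                        tr$shift_scurred)) %in% c(0, cfg$de_effect_size)))
})

test_that("qPCR generator matches the validation-study layout", {
  q <- simulate_qpcr(seed = 2)
  # 4 biological x 3 technical = 12 Ct values per phenotype per gene
  expect_true(all(table(q$phenotype, q$gene) == 12L))
  expect_identical(simulate_qpcr(seed = 2), q)

  # zero noise: planted ddCt recovered exactly by the GLM
  q0 <- simulate_qpcr(dct = c(Polled = -7.36, Horned = 0, Scurred = 0),
                      noise_sd = 0, seed = 5)
  est <- ddct_fit(q0, "PvH", target = "DSC1")
  expect_equal(est$ddct, -7.36, tolerance = 1e-12)
})

test_that("qPCR estimates under noise are unbiased within Monte-Carlo error", {
  ests <- vapply(1:200, function(s) {
    q <- simulate_qpcr(dct = c(Polled = 0, Horned = 0, Scurred = 0),
                       noise_sd = 0.3, seed = s)
    ddct_fit(q, "PvH", target = "DSC1")$ddct
  }, 0)
  expect_lt(abs(mean(ests)), 3 * sd(ests) / sqrt(length(ests)))
})

test_that("annotation fixtures cover every rule branch deterministically", {
  fx <- generate_annotation_fixtures(n_probes = 12, seed = 4)
  expect_identical(fx, generate_annotation_fixtures(n_probes = 12, seed = 4))
  res <- annotate_probes(fx$probes, fx$genes, fx$blast)
  expect_true(any(res$decision_step == "1"))
  expect_true(any(res$decision_step == "2"))
  expect_true(any(res$decision_step == "3"))
  expect_true(any(res$decision_step == "unassigned"))
  expect_true(any(res$flagged))
  # a probe overlapping two bovine genes produces two overlap rows
  ov <- probe_overlap(fx$probes[fx$probes$probe_id == "AGI003", ],
                      fx$genes[fx$genes$species == "bovine", ])
  expect_equal(nrow(ov), 2L)
})
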