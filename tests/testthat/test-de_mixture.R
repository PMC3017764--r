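test_that("contrast statistics are standardized BLUP differences", {
  td <- tiny_fit_data(n_probes = 25, seed = 51)
  fit <- dyeswap_mm(td$qc, td$design)
  cs <- compute_contrasts(fit)
  expect_equal(nrow(cs), 3L * 25L)
  expect_true(all(cs$se > 0))
  expect_equal(cs$statistic, cs$raw_diff / cs$se)

  # identical profiles give a zero statistic
  fit2 <- list(hg = matrix(c(1, 1, 0.5), 1, 3,
                           dimnames = list("g1",
                                           c("Polled", "Horned", "Scurred"))),
               pev_hg = matrix(c(0.1, 0.1, 0.1, 0.02, 0.02, 0.02), 1, 6,
                               dimnames = list("g1",
                                               c("pev11", "pev22", "pev33",
                                                 "pev12", "pev13", "pev23"))))
  c2 <- compute_contrasts(fit2)
  expect_equal(c2$statistic[c2$contrast == "PvH"], 0)
})

test_that("relabelling dye channels leaves phenotype profiles unchanged", {
  td <- tiny_fit_data(n_probes = 20, seed = 61)
  fit <- dyeswap_mm(td$qc, td$design)
  qc_sw <- td$qc
  qc_sw$dye <- ifelse(qc_sw$dye == "red", "green", "red")
  des_sw <- td$design
  des_sw$dye <- ifelse(des_sw$dye == "red", "green", "red")
  fit_sw <- dyeswap_mm(qc_sw, des_sw)
  expect_equal(fit_sw$hg, fit$hg, tolerance = 1e-6)
  expect_equal(fit_sw$variances, fit$variances, tolerance = 1e-5)
})

test_that("BLUP contrast variance obeys the shrinkage identity", {
  # Var(estimated difference) = 2 var_hg - PEV(difference): the statistic is
  # therefore not unit-variance under the null; the mixture absorbs the scale
  cfg <- sim_config(n_probes = 600, de_fraction = 0, bad_spot_fraction = 0,
                    seed = 71)
  des <- simulate_design(cfg)
  fit <- dyeswap_mm(apply_qc(simulate_spots(des, cfg)$spots), des)
  cs <- compute_contrasts(fit)
  sub <- cs[cs$contrast == "PvH", ]
  pred_var <- 2 * fit$variances[["hg"]] - mean(sub$se^2)
  emp_var <- var(sub$raw_diff)
  se <- emp_var * sqrt(2 / nrow(sub))
  expect_lt(abs(emp_var - pred_var), 4 * se)
})

test_that("EM recovers a planted 90/10 two-component mixture", {
  set.seed(101)
  n <- 5000
  z <- runif(n) < 0.1
  x <- ifelse(z, rnorm(n, 4, 1), rnorm(n, 0, 1))
  mix <- mixture_fit(x, seed = 3)
  se_w <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(mix$weight_alt - 0.1), 3 * se_w)
  expect_lt(abs(mix$mean_alt - 4), 3 * 1 / sqrt(0.1 * n))
  expect_lt(abs(mix$mean_null - 0), 3 * 1 / sqrt(0.9 * n))
  expect_lt(abs(mix$var_null - 1), 0.15)
  expect_lt(abs(mix$var_alt - 1), 0.5)
  # log-likelihood is monotone over EM iterations
  expect_true(all(diff(mix$ll_trace) > -1e-8))
})

test_that("pure-null data yields a negligible alternative weight", {
  set.seed(77)
  x <- rnorm(3000)
  mix <- mixture_fit(x, seed = 5)
  # the secondary component either has tiny weight or is indistinct from
  # the null; either way almost no posterior mass is far from the null
  expect_lt(mean(mix$posterior_alt > 0.9), 0.01)
  de <- call_de(mix, data.frame(gene_id = as.character(1:3000),
                                contrast = "PvH", raw_diff = x,
                                statistic = x), fdr_target = 0.01)
  expect_lt(sum(de$de_flag), 10)
})

test_that("mixture labelling is invariant to sign and to restarts", {
  set.seed(11)
  x <- c(rnorm(900), rnorm(100, -4, 1))
  m1 <- mixture_fit(x, seed = 1)
  m2 <- mixture_fit(x, seed = 42, n_starts = 8)
  expect_equal(abs(m1$mean_null) < abs(m1$mean_alt), TRUE)
  expect_equal(m1$weight_alt, m2$weight_alt, tolerance = 0.02)
  m3 <- mixture_fit(-x, seed = 1)
  expect_equal(m3$mean_alt, -m1$mean_alt, tolerance = 0.05)
  expect_error(mixture_fit(rnorm(20)), "at least 50")
})

test_that("fold_from_log2 uses the negated-reciprocal convention", {
  expect_equal(fold_from_log2(0), 1)
  expect_equal(fold_from_log2(3), 8)
  expect_equal(fold_from_log2(-3), -8)
  expect_equal(round(fold_from_log2(7.36)), 164)
  d <- seq(-5, 5, by = 0.25)
  d <- d[d != 0]
  expect_equal(fold_from_log2(-d), -fold_from_log2(d))
  expect_error(fold_from_log2(NA_real_))
})

test_that("call_de selects the largest set meeting the posterior FDR rule", {
  mk <- function(post) {
    m <- structure(list(posterior_alt = post), class = "mixfit2")
    s <- data.frame(gene_id = as.character(seq_along(post)),
                    contrast = "PvH", raw_diff = rep(1, length(post)),
                    statistic = rep(1, length(post)))
    call_de(m, s, fdr_target = 0.01)
  }
  # all-zero posteriors: empty list, no error
  expect_equal(sum(mk(rep(0, 100))$de_flag), 0L)
  # one certain gene among zeros: exactly that gene
  r <- mk(c(rep(0, 99), 1))
  expect_equal(r$gene_id[r$de_flag], "100")
  # mean(1 - posterior) over the selected set respects the target
  post <- c(rep(0.999, 20), rep(0.9, 30), rep(0.01, 50))
  sel <- mk(post)
  expect_true(mean(1 - sel$posterior[sel$de_flag]) < 0.01)
  # greedy maximality: adding the next-ranked gene would break the target
  k <- sum(sel$de_flag)
  ord <- order(sel$posterior, decreasing = TRUE)
  expect_gte(mean(1 - sel$posterior[ord[seq_len(k + 1)]]), 0.01)
})

test_that("summarise_de counts match brute-force set algebra", {
  res <- data.frame(
    gene_id = c("a", "b", "c", "a", "c", "d", "c", "e"),
    contrast = c("PvH", "PvH", "PvH", "PvS", "PvS", "PvS", "HvS", "HvS"),
    de_flag = TRUE)
  s <- summarise_de(res, chrom_map = c(a = "1", b = "2", c = "1"))
  expect_equal(unname(s$per_contrast), c(3L, 3L, 2L))
  expect_equal(unname(s$overlap["PvH&PvS"]),
               length(intersect(c("a", "b", "c"), c("a", "c", "d"))))
  expect_equal(unname(s$overlap["PvH&PvS&HvS"]), 1L)  # only "c"
  expect_equal(s$total_genes, 5L)
  expect_equal(unname(s$per_chromosome$PvS["unplaced"]), 1L)  # gene "d"

  # disjoint truth sets give zero overlap
  res2 <- data.frame(gene_id = c("a", "b", "c"),
                     contrast = c("PvH", "PvS", "HvS"), de_flag = TRUE)
  s2 <- summarise_de(res2)
  expect_true(all(s2$overlap == 0L))
})
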