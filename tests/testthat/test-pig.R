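test_that("read filters: minimum 16 reads, cap at 1000, seeded subsample", {
  mk <- function(k) data.table::data.table(
    cell_id = "c1", gene_id = "gX", y = 0L, n = 30L,
    read_id = sprintf("r%04d", seq_len(k)))
  expect_null(prepare_gene_reads(mk(15)))
  expect_equal(nrow(prepare_gene_reads(mk(16))), 16L)
  expect_false(attr(prepare_gene_reads(mk(16)), "subsampled"))

  s1 <- prepare_gene_reads(mk(1500), seed = 9)
  expect_equal(nrow(s1), 1000L)
  expect_true(attr(s1, "subsampled"))
  # identical across reruns and independent of the ambient RNG state
  set.seed(123); runif(10)
  s2 <- prepare_gene_reads(mk(1500), seed = 9)
  expect_identical(s1$read_id, s2$read_id)
  # and the caller's RNG stream is untouched
  set.seed(77); before <- runif(1)
  set.seed(77); invisible(prepare_gene_reads(mk(1500), seed = 9))
  expect_identical(runif(1), before)
  # a different seed gives a different subsample
  s3 <- prepare_gene_reads(mk(1500), seed = 10)
  expect_false(identical(s1$read_id, s3$read_id))
})

test_that("joint log-posterior matches direct arithmetic", {
  set.seed(31)
  d <- draw_reads(50, 20, 0.01, 0.1, 0.4)
  # uniform prior: equals the plain log-likelihood
  expect_equal(joint_log_posterior(0.3, 1, 1, d$y, d$n, 0.01, 0.1),
               naive_loglik(d$y, d$n, 0.01, 0.1, 0.3), tolerance = 1e-10)
  # single-record closed form
  expect_equal(joint_log_posterior(0.25, 1, 1, y = 0, n = 1,
                                   p_e = 0, p_c = 1), log(0.75))
  # mixture symmetry: swap components, flip pi, swap hyperparameters
  expect_equal(
    joint_log_posterior(0.3, 2, 5, d$y, d$n, p_e = 0.01, p_c = 0.1),
    joint_log_posterior(0.7, 5, 2, d$y, d$n, p_e = 0.1, p_c = 0.01),
    tolerance = 1e-10)
  expect_error(joint_log_posterior(1.2, 1, 1, 0, 1, 0.1, 0.2), "inside")
  expect_error(joint_log_posterior(0.5, -1, 1, 0, 1, 0.1, 0.2), "positive")
})

test_that("beta mode follows the interior formula and boundary rules", {
  expect_equal(beta_mode(2, 2), 0.5)
  expect_equal(beta_mode(3, 1.5), 0.8)
  expect_equal(beta_mode(1.5, 0.7), 1)
  expect_equal(beta_mode(0.7, 1.5), 0)
  expect_error(beta_mode(0, 1), "positive")
  expect_error(beta_mode(2, -3), "positive")
  # interior formula against the density argmax, and range check
  set.seed(13)
  for (i in 1:50) {
    a <- runif(1, 0.2, 6); b <- runif(1, 0.2, 6)
    m <- beta_mode(a, b)
    expect_gte(m, 0); expect_lte(m, 1)
    if (a > 1 && b > 1) {
      grid <- seq(0.0005, 0.9995, length.out = 4001)
      expect_lt(abs(m - grid[which.max(dbeta(grid, a, b))]), 3e-4)
    }
  }
})

test_that("MAP fit finds near-zero, near-one, and interior fractions", {
  # all-unconverted reads: essentially no new RNA
  r0 <- data.table::data.table(y = rep(0L, 50), n = rep(30L, 50))
  f0 <- fit_pi_g(r0, p_e = 1e-4, p_c = 0.02)
  expect_lt(f0$pi_g_mode, 0.01)
  expect_lt(abs(f0$pi_g_mode - grid_argmax_pi(r0$y, r0$n, 1e-4, 0.02)), 0.01)

  # reads drawn purely from the conversion component
  set.seed(8)
  y1 <- rbinom(50, 30, 0.02)
  r1 <- data.table::data.table(y = y1, n = rep(30L, 50))
  f1 <- fit_pi_g(r1, p_e = 1e-4, p_c = 0.02)
  expect_gt(f1$pi_g_mode, 0.99)

  # interior truth recovered within 0.1
  set.seed(9)
  d <- draw_reads(200, 30, 0.001, 0.02, 0.3)
  f <- fit_pi_g(data.table::as.data.table(d[c("y", "n")]),
                p_e = 0.001, p_c = 0.02)
  expect_lt(abs(f$pi_g_mode - 0.3), 0.1)
  expect_lt(abs(f$pi_g_mode - grid_argmax_pi(d$y, d$n, 0.001, 0.02)), 0.05)
  expect_error(fit_pi_g(data.table::data.table(y = integer(), n = integer()),
                        0.001, 0.02), "no records")
})

test_that("uniform-prior optimiser equals the brute-force grid argmax", {
  set.seed(17)
  for (i in 1:15) {
    d <- draw_reads(sample(30:200, 1), 30, 0.001,
                    runif(1, 0.01, 0.05), runif(1, 0.05, 0.95))
    f <- fit_pi_g(data.table::as.data.table(d[c("y", "n")]),
                  p_e = 0.001, p_c = 0.02, fixed_prior = c(1, 1))
    expect_equal(f$pi_g_point, grid_argmax_pi(d$y, d$n, 0.001, 0.02),
                 tolerance = 2e-3)
  }
})

test_that("fully converted reads pull pi up; unconverted reads pull it down", {
  set.seed(23)
  for (i in 1:8) {
    d <- draw_reads(60, 25, 0.001, 0.03, runif(1, 0.2, 0.8))
    base <- fit_pi_g(data.table::as.data.table(d[c("y", "n")]),
                     0.001, 0.03, fixed_prior = c(1, 1))$pi_g_point
    up <- rbind(d[c("y", "n")], data.frame(y = 25L, n = 25L))
    down <- rbind(d[c("y", "n")], data.frame(y = 0L, n = 25L))
    f_up <- fit_pi_g(data.table::as.data.table(up), 0.001, 0.03,
                     fixed_prior = c(1, 1))$pi_g_point
    f_dn <- fit_pi_g(data.table::as.data.table(down), 0.001, 0.03,
                     fixed_prior = c(1, 1))$pi_g_point
    expect_gte(f_up, base - 1e-4)
    expect_lte(f_dn, base + 1e-4)
  }
})

test_that("estimation degrades gracefully as p_c approaches p_e", {
  set.seed(29)
  p_e <- 0.004; p_c <- 1.5 * p_e
  fits <- lapply(1:20, function(i) {
    d <- draw_reads(100, 30, p_e, p_c, runif(1, 0.1, 0.6))
    fit_pi_g(data.table::as.data.table(d[c("y", "n")]), p_e, p_c)
  })
  fits <- data.table::rbindlist(fits)
  expect_true(all(fits$pi_g_mode >= 0 & fits$pi_g_mode <= 1))
  expect_true(all(fits$quality_flag %in% c("ok", "boundary", "unreliable")))
  # a weak-signal regime yields visibly more flagged estimates
  expect_gt(sum(fits$quality_flag != "ok"), 0L)
})

test_that("fit_pi_g_all applies filters and joins per-cell rates", {
  tr <- simulation_truth(n_genes = 5, reads_per_gene = c(15, 30, 60, 120, 40),
                         cells = "cA", seed = 12)
  rec <- simulate_records(tr)
  rates <- list(structure(list(cell_id = "cA", p_e = 0.001, p_c = 0.02),
                          class = "cell_rates"))
  est <- fit_pi_g_all(rec, rates, seed = 12)
  # the 15-read gene is filtered out, all others estimated
  expect_setequal(est$gene_id, names(tr$pi_g)[-1])
  expect_true(all(est$reads_used >= 16))
  expect_true(all(est$reads_used <= pmin(est$reads_total, 1000)))
})
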