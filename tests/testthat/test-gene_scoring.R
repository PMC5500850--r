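test_that("moderated z converges to the plain z-score as replication grows", {
  # With unit-variance noise the empirical-Bayes posterior variance is
  # essentially the common prior, so the relative RMS difference from
  # the plain pooled-t z-score is governed by the sampling noise of the
  # per-gene variance, ~1/sqrt(2 * df): about 7% at n = 50 per group and
  # below 2% at n = 800.
  rms_at <- function(n, seed) {
    set.seed(seed)
    genes <- sprintf("g%03d", 1:200)
    ctrl <- matrix(rnorm(200 * n, 8, 1), 200, n,
                   dimnames = list(genes, paste0("c", 1:n)))
    trt <- matrix(rnorm(200 * n, 8, 1), 200, n,
                  dimnames = list(genes, paste0("t", 1:n)))
    zmod <- moderated_gene_z(trt, ctrl)
    tt <- apply(cbind(ctrl, trt), 1, function(v) {
      a <- v[1:n]; b <- v[(n + 1):(2 * n)]
      sp <- sqrt(((n - 1) * var(a) + (n - 1) * var(b)) / (2 * n - 2))
      (mean(b) - mean(a)) / (sp * sqrt(2 / n))
    })
    zplain <- limma::zscoreT(tt, df = 2 * n - 2, approx = TRUE,
                             method = "bailey")
    sqrt(mean((zmod - zplain)^2)) / sqrt(mean(zplain^2))
  }
  rms_small <- rms_at(50, 31)
  rms_large <- rms_at(800, 32)
  expect_lt(rms_large, 0.02)
  expect_lt(rms_large, rms_small)
})

test_that("moderated z tracks a planted shift and centers at zero without one", {
  genes <- sprintf("g%03d", 1:100)
  shifted <- genes[1:10]
  z_by_n <- sapply(c(4, 16), function(n) {
    fx <- expression_fixture(100, n_treat = n, n_ctrl = n,
                             shifted_genes = shifted, shift = 3, seed = n)
    z <- moderated_gene_z(fx$treatments, fx$controls)
    mean(z[shifted])
  })
  expect_true(all(z_by_n > 0))
  expect_gt(z_by_n[2], z_by_n[1])     # grows with replication
  # no-shift genes: z centred near zero
  fx0 <- expression_fixture(100, n_treat = 6, n_ctrl = 6, seed = 3)
  z0 <- moderated_gene_z(fx0$treatments, fx0$controls)
  expect_lt(abs(mean(z0)), 0.2)
  expect_error(moderated_gene_z(fx0$treatments, fx0$controls[, 1, drop = FALSE]),
               ">= 2")
})

test_that("saturated gene sets reach the minimal attainable rotation p", {
  fx <- expression_fixture(60, n_treat = 4, n_ctrl = 4,
                           shifted_genes = sprintf("g%03d", 1:15),
                           shift = 6, noise_sd = 0.3, seed = 5)
  set.seed(6)
  res <- rotation_set_test(fx$treatments, fx$controls,
                           list(HOT = sprintf("g%03d", 1:15)), n_rot = 999)
  expect_equal(res$p_mixed, 1 / 1000)
  expect_equal(res$pct_active, 100)
})

test_that("rotation p agrees with the exhaustive sign-flip oracle on a tiny fixture", {
  # 8 genes, set of 4, 3 vs 3 arrays, moderate planted signal
  fx <- expression_fixture(8, n_treat = 3, n_ctrl = 3,
                           shifted_genes = sprintf("g%03d", 1:4),
                           shift = 1.2, noise_sd = 1, seed = 7)
  set.seed(8)
  res <- rotation_set_test(fx$treatments, fx$controls,
                           list(S = sprintf("g%03d", 1:4)), n_rot = 9999)
  y <- cbind(fx$controls, fx$treatments)
  design <- cbind(1, rep(c(0, 1), each = 3))
  oracle <- ptgspace:::signflip_set_test(y, design, 1:4)
  expect_lt(abs(res$p_mixed - oracle$p_mixed), 0.1)
  expect_equal(res$pct_active,
               proportion_active(moderated_gene_z(fx$treatments, fx$controls),
                                 sprintf("g%03d", 1:4)))
})

test_that("proportion active counts |z| beyond sqrt(2)", {
  z <- setNames(c(0, 0, 0, 0), letters[1:4])
  expect_equal(proportion_active(z, letters[1:4]), 0)
  z2 <- setNames(rep(2, 4), letters[1:4])
  expect_equal(proportion_active(z2, letters[1:4]), 100)
  z3 <- setNames(c(2, 0.1, -0.3, 1), letters[1:4])
  expect_equal(proportion_active(z3, letters[1:4]), 25)
  # invariant to unmeasured set members and gene order
  expect_equal(proportion_active(z3, c("zz", letters[4:1])), 25)
  expect_error(proportion_active(z3, c("x", "y")), "overlap")
})

test_that("virtual GI50 calls require both thresholds", {
  res <- virtual_gi50_call(p_all = c(0.01, 0.01, 0.8),
                           pct_active_all = c(30, 20, 90))
  # BH over 3 p-values: q = c(0.015, 0.015, 0.8)
  expect_equal(res$active, c(TRUE, FALSE, FALSE))
})

test_that("gene-based DILI score is the max %act / min p over G,H,I,N", {
  pct <- c(G = 10, H = 40, I = 5, N = 0)
  p <- c(G = 0.2, H = 0.001, I = 0.5, N = 0.9)
  gs <- dili_gene_score(pct, p)
  expect_equal(gs$score, 40)
  expect_equal(gs$p, 0.001)
  expect_equal(dili_gene_score(c(G = 0, H = 0, I = 0, N = 0), p)$score, 0)
  expect_error(dili_gene_score(pct[1:3], p[1:3]), "missing component")

  m_pct <- rbind(e1 = pct, e2 = pct * 2)
  m_p <- rbind(e1 = p, e2 = p / 2)
  df <- dili_gene_score(m_pct, m_p)
  expect_equal(df$score, c(40, 80))
  expect_equal(df$p, c(0.001, 0.0005))
})

test_that("replicate treatments are score-averaged", {
  sc <- data.frame(score = c(10, 20, 30), p = c(0.1, 0.3, 0.5))
  out <- average_replicate_scores(sc, c("t1", "t1", "t2"))
  expect_equal(out$score, c(15, 30))
  expect_equal(out$p, c(0.2, 0.5))
})
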