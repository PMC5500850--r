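test_that("concentration-dependent cytotoxicity is the log-molar difference", {
  expect_equal(concentration_dependent_cytotoxicity(-6, -6), 0)
  expect_equal(concentration_dependent_cytotoxicity(-5, -6), 1)
  expect_equal(concentration_dependent_cytotoxicity(-7, -5), -2)
  expect_error(concentration_dependent_cytotoxicity(NA_real_, -6), "finite")
})

test_that("weighted component cytotoxicity equals the dot-product oracle", {
  # all mass on one instance -> that instance's i_TOX
  p1 <- matrix(c(1, 0), 1, 2, dimnames = list("C1", c("i1", "i2")))
  itox <- c(i1 = 2.5, i2 = -1)
  expect_equal(unname(weighted_component_cytotoxicity(p1, itox)$tox), 2.5)

  # symmetric weights on opposite i_TOX cancel
  p2 <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("C1", c("i1", "i2")))
  expect_equal(unname(weighted_component_cytotoxicity(p2, c(i1 = 1, i2 = -1))$tox), 0)

  # random fixture vs explicit loop oracle
  set.seed(4)
  K <- 6; n <- 25
  p <- matrix(rgamma(K * n, 1), K, n,
              dimnames = list(paste0("C", 1:K), paste0("i", 1:n)))
  p <- p / rowSums(p)
  it <- setNames(rnorm(n), colnames(p))
  rk <- weighted_component_cytotoxicity(p, it)
  oracle <- sapply(rownames(p), function(z) {
    s <- 0
    for (i in colnames(p)) s <- s + unname(p[z, i] * it[i])
    s
  })
  expect_lt(max(abs(rk$tox[names(oracle)] - oracle)), 1e-12)
  expect_equal(rk$order, names(sort(-oracle)))
})

test_that("cumulative AUC selection stops at the 95% rule", {
  # one perfectly separating component -> k = 1, AUC 1
  theta <- cbind(C1 = c(0.9, 0.8, 0.1, 0.2), C2 = c(0.1, 0.2, 0.9, 0.8))
  rownames(theta) <- paste0("i", 1:4)
  rk <- structure(list(order = c("C1", "C2"), tox = c(C1 = 2, C2 = -1)),
                  class = "component_ranking")
  ptgs <- cumulative_auc_selection(rk, theta, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ptgs$selected_components, "C1")
  expect_equal(ptgs$auc_curve[1], 1)
  expect_equal(ptgs$labels, "A")
  expect_error(cumulative_auc_selection(rk, theta, rep(TRUE, 4)),
               "both classes")
})

test_that("component score sums selected theta mass and is monotone", {
  theta <- matrix(c(0.05, 0.03, 0.02, 0.9,
                    0.5, 0.3, 0.2, 0.0), 2, 4, byrow = TRUE,
                  dimnames = list(c("i1", "i2"), paste0("C", 1:4)))
  rk <- structure(list(order = paste0("C", 1:4),
                       tox = setNames(4:1, paste0("C", 1:4))),
                  class = "component_ranking")
  ptgs3 <- structure(list(selected_components = paste0("C", 1:3)),
                     class = "ptgs_definition")
  expect_equal(unname(ptgs_component_score(theta, ptgs3)), c(0.1, 1))
  ptgs1 <- structure(list(selected_components = "C4"),
                     class = "ptgs_definition")
  expect_equal(unname(ptgs_component_score(theta, ptgs1)), c(0.9, 0))
  # monotone in the selected set
  ptgs4 <- structure(list(selected_components = paste0("C", 1:4)),
                     class = "ptgs_definition")
  expect_true(all(ptgs_component_score(theta, ptgs4) >=
                    ptgs_component_score(theta, ptgs3)))
  expect_error(ptgs_component_score(theta, ptgs3, "nope"), "unknown instance")
})

test_that("AUC curve is invariant to component label permutation", {
  set.seed(9)
  theta <- matrix(rgamma(30 * 5, 1), 30, 5)
  theta <- theta / rowSums(theta)
  dimnames(theta) <- list(paste0("i", 1:30), paste0("C", 1:5))
  labels <- rep(c(TRUE, FALSE), 15)
  rk <- structure(list(order = paste0("C", c(3, 1, 5, 2, 4)),
                       tox = setNames(5:1, paste0("C", c(3, 1, 5, 2, 4)))),
                  class = "component_ranking")
  a <- cumulative_auc_selection(rk, theta, labels)
  perm <- sample(5)
  theta2 <- theta[, perm]
  b <- cumulative_auc_selection(rk, theta2, labels)
  expect_equal(a$auc_curve, b$auc_curve)
  expect_equal(a$selected_components, b$selected_components)
})

test_that("score threshold calibration finds the planted mixing point", {
  # perfectly separated clusters with minority positives (as in a
  # mostly non-cytotoxic corpus): prevalence above the threshold first
  # reaches 50% at the upper edge of the negative cluster
  scores <- c(0.1, 0.1, 0.1, 0.2, 0.2, 0.2, 0.8, 0.9)
  labels <- c(rep(FALSE, 6), TRUE, TRUE)
  cal <- calibrate_score_threshold(scores, labels)
  expect_equal(cal$threshold, 0.2)
  expect_equal(mean(labels[scores > cal$threshold]), 1)

  # planted mixture: positive rate 0.05 below score 0.5, 0.55 above.
  # Prevalence among scores > t crosses 50% at t = 4/9 analytically:
  # (0.05 (0.5 - t) + 0.55 * 0.5) / (1 - t) = 0.5  =>  t = 0.444...
  set.seed(12)
  s <- runif(6000)
  l <- runif(6000) < ifelse(s > 0.5, 0.55, 0.05)
  cal2 <- calibrate_score_threshold(s, l, target_positive_fraction = 0.5)
  expect_lt(abs(cal2$threshold - 4 / 9), 0.05)

  expect_warning(calibrate_score_threshold(c(0, 1), c(TRUE, FALSE),
                                           target_positive_fraction = 0.99),
                 "unreachable")
})
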