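test_that("cumulative endpoints sum grades from the bottom up", {
  f <- data.frame(treatment_id = "t1", finding_type = "necrosis",
                  grade = "severe", n_animals = 1)
  ep <- cumulative_endpoints(f)
  expect_equal(unname(ep["t1", paste0("necrosis:", c("present", "minimal",
                                                     "slight", "moderate",
                                                     "severe"))]),
               rep(1L, 5))

  f2 <- data.frame(treatment_id = "t1", finding_type = "fibrosis",
                   grade = c("minimal", "moderate"), n_animals = c(2, 1))
  ep2 <- cumulative_endpoints(f2)
  expect_equal(unname(ep2["t1", paste0("fibrosis:", c("present", "minimal",
                                                      "slight", "moderate",
                                                      "severe"))]),
               c(3L, 3L, 1L, 1L, 0L))

  # empty input -> all-zero table; bad grades named by record
  expect_equal(sum(cumulative_endpoints(f2[0, ], treatments = "t1")), 0)
  bad <- data.frame(treatment_id = "t1", finding_type = "x",
                    grade = "horrid", n_animals = 1)
  expect_error(cumulative_endpoints(bad), "record")

  # monotone by construction on random tables
  set.seed(41)
  rf <- data.frame(treatment_id = sample(paste0("t", 1:10), 60, TRUE),
                   finding_type = sample(c("a", "b"), 60, TRUE),
                   grade = sample(PATHOLOGY_GRADES <- c("present", "minimal",
                                                        "slight", "moderate",
                                                        "severe"), 60, TRUE),
                   n_animals = sample(1:3, 60, TRUE))
  epr <- cumulative_endpoints(rf)
  for (ft in c("a", "b")) {
    cols <- paste0(ft, ":", c("present", "minimal", "slight", "moderate",
                              "severe"))
    expect_true(all(t(apply(epr[, cols], 1, diff)) <= 0))
  }
})

test_that("weighted pathology score is the 1..5 graded sum and is additive", {
  expect_equal(sum(weighted_pathology_score(
    data.frame(treatment_id = character(), finding_type = character(),
               grade = character(), n_animals = integer()),
    treatments = "t1")), 0)
  f1 <- data.frame(treatment_id = "t1", finding_type = "necrosis",
                   grade = "severe", n_animals = 1)
  expect_equal(unname(weighted_pathology_score(f1)["t1", "necrosis:weighted"]), 5)
  f2 <- data.frame(treatment_id = "t1", finding_type = "necrosis",
                   grade = c("minimal", "moderate"), n_animals = c(2, 1))
  expect_equal(unname(weighted_pathology_score(f2)["t1", "necrosis:weighted"]), 8)

  # linearity over disjoint animal groups
  set.seed(42)
  fa <- data.frame(treatment_id = "t1", finding_type = "a",
                   grade = sample(c("present", "slight"), 4, TRUE),
                   n_animals = sample(1:2, 4, TRUE))
  fb <- data.frame(treatment_id = "t1", finding_type = "a",
                   grade = sample(c("moderate", "severe"), 3, TRUE),
                   n_animals = sample(1:2, 3, TRUE))
  s_union <- weighted_pathology_score(rbind(fa, fb))["t1", "a:weighted"]
  s_parts <- weighted_pathology_score(fa)["t1", "a:weighted"] +
    weighted_pathology_score(fb)["t1", "a:weighted"]
  expect_equal(s_union, s_parts)
})

test_that("dichotomization applies grade-specific cutoffs and filters", {
  tbl <- cbind("necrosis:present" = c(3, 2, 5, 0),
               "necrosis:severe" = c(2, 1, 0, 0),
               "necrosis:weighted" = c(3, 2, 9, 1))
  rownames(tbl) <- paste0("t", 1:4)
  di <- dichotomize_endpoints(tbl, min_positive = 1)
  expect_equal(unname(di$labels[, "necrosis:present"]),
               c(TRUE, FALSE, TRUE, FALSE))   # cutoff 3
  expect_equal(unname(di$labels[, "necrosis:severe"]),
               c(TRUE, FALSE, FALSE, FALSE))  # cutoff 2
  expect_equal(unname(di$labels[, "necrosis:weighted"]),
               c(TRUE, FALSE, TRUE, FALSE))   # cutoff 3

  # endpoint with 9 positives dropped at min 10
  tbl2 <- cbind(ep = c(rep(3, 9), rep(0, 11)))
  rownames(tbl2) <- paste0("t", 1:20)
  di2 <- dichotomize_endpoints(tbl2, min_positive = 10)
  expect_equal(di2$dropped, "ep")
  expect_equal(ncol(di2$labels), 0)
})

test_that("endpoint AUC matches the pair-counting oracle and is null-centred", {
  # perfectly separating score
  lab <- matrix(c(rep(TRUE, 5), rep(FALSE, 5)), 10, 1,
                dimnames = list(NULL, "ep"))
  expect_equal(endpoint_auc(c(6:10, 1:5), lab)$auc, 1)

  # hand-ranked 5 vs 5 fixture vs quadratic oracle (with ties)
  set.seed(43)
  sc <- c(3, 1, 4, 4, 2, 2, 5, 1, 3, 2)
  res <- endpoint_auc(sc, lab)
  expect_equal(res$auc, auc_pair_oracle(sc, lab[, 1]))

  # label-independent scores: mean AUC near 0.5
  aucs <- replicate(400, {
    s <- rnorm(40)
    l <- matrix(sample(c(TRUE, FALSE), 40, TRUE), 40, 1,
                dimnames = list(NULL, "ep"))
    if (length(unique(l[, 1])) < 2) NA else endpoint_auc(s, l)$auc
  })
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.02)
})

test_that("planted predictive components are selected; permuted labels are not", {
  exact <- 0
  for (s in 1:5) {
    sim <- simulate_pathology_study(n_compounds = 40, n_components = 8,
                                    n_predictive = 2, effect = 4, seed = s)
    ep <- cumulative_endpoints(sim$findings, treatments = rownames(sim$theta))
    ws <- weighted_pathology_score(sim$findings,
                                   treatments = rownames(sim$theta))
    di <- dichotomize_endpoints(cbind(ep, ws), min_positive = 15)
    sel <- suppressWarnings(
      select_predictive_components(sim$theta, di$labels, cv_repeats = 3,
                                   folds = 3, seed = s))
    exact <- exact + setequal(sel$selected, sim$truth$predictive_components)
  }
  expect_gte(exact, 4)

  # permuted labels: empty (or near-empty) selection
  set.seed(44)
  sim <- simulate_pathology_study(n_compounds = 40, n_components = 8,
                                  n_predictive = 2, effect = 4, seed = 10)
  ep <- cumulative_endpoints(sim$findings, treatments = rownames(sim$theta))
  ws <- weighted_pathology_score(sim$findings, treatments = rownames(sim$theta))
  di <- dichotomize_endpoints(cbind(ep, ws), min_positive = 15)
  perm <- di$labels[sample(nrow(di$labels)), , drop = FALSE]
  rownames(perm) <- rownames(di$labels)
  sel0 <- suppressWarnings(
    select_predictive_components(sim$theta, perm, cv_repeats = 3,
                                 folds = 3, seed = 3))
  expect_lte(length(sel0$selected), 1)
})

test_that("component DILI score sums the selected probabilities", {
  theta <- matrix(c(0.1, 0.2, 0.05, 0.15, 0.5,
                    0.25, 0.25, 0.25, 0.25, 0), 2, 5, byrow = TRUE,
                  dimnames = list(c("t1", "t2"), paste0("C", 1:5)))
  expect_equal(unname(component_dili_score(theta, paste0("C", 1:4))),
               c(0.5, 1))
  expect_equal(unname(component_dili_score(theta, "C5")), c(0.5, 0))
})

test_that("prevalence threshold sits at the planted enrichment point", {
  scores <- c(rep(0.1, 6), rep(0.5, 4))
  labels <- c(rep(FALSE, 6), c(TRUE, TRUE, TRUE, FALSE))
  th <- dili_threshold_from_prevalence(scores, labels, level = 0.5)
  expect_equal(th$threshold, 0.1)
  expect_gte(mean(labels[scores > th$threshold]), 0.5)
})
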