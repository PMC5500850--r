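test_that("corpus generation is seed-deterministic and seed-sensitive", {
  a <- simulate_corpus(n_compounds = 8, n_systems = 1, n_genes = 120,
                       n_sets = 6, K_true = 3, n_toxic = 1, seed = 1)
  b <- simulate_corpus(n_compounds = 8, n_systems = 1, n_genes = 120,
                       n_sets = 6, K_true = 3, n_toxic = 1, seed = 1)
  c <- simulate_corpus(n_compounds = 8, n_systems = 1, n_genes = 120,
                       n_sets = 6, K_true = 3, n_toxic = 1, seed = 2)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$expr, c$expr))
})

test_that("noiseless single-component expression equals the planted effect", {
  sim <- simulate_corpus(n_compounds = 2, n_systems = 1, n_genes = 60,
                         n_sets = 4, K_true = 2, n_toxic = 1, noise_sd = 0,
                         seed = 3)
  inst <- sim$instances
  trt <- inst[!inst$is_control, ]
  ctrl <- inst[inst$is_control & inst$batch_id == trt$batch_id[1], ]
  diff <- sim$expr[, trt$instance_id[1]] - sim$expr[, ctrl$instance_id[1]]
  # with zero noise the differential profile is exactly the mixture of
  # planted component effects
  truth_effect <- numeric(60)
  names(truth_effect) <- rownames(sim$expr)
  th <- sim$truth$theta_true[trt$instance_id[1], ]
  for (k in seq_along(th)) {
    de <- sim$truth$de_genes[[k]]
    truth_effect[de$up] <- truth_effect[de$up] + 2 * th[k]
    truth_effect[de$down] <- truth_effect[de$down] - 2 * th[k]
  }
  expect_equal(unname(diff), unname(truth_effect), tolerance = 1e-12)
})

test_that("generated corpora satisfy every reader invariant round-trip", {
  sim <- simulate_corpus(n_compounds = 6, n_systems = 2, n_genes = 100,
                         n_sets = 5, K_true = 2, n_toxic = 1, seed = 6)
  d <- tempfile(); dir.create(d)
  write_expression_matrix(sim$expr, file.path(d, "expr.tsv"))
  write.csv(sim$instances, file.path(d, "instances.csv"), row.names = FALSE)
  write_gene_sets(sim$sets, file.path(d, "sets.gmt"))
  write.csv(sim$potency, file.path(d, "potency.csv"), row.names = FALSE)

  expect_identical(read_expression_matrix(file.path(d, "expr.tsv")), sim$expr)
  inst <- read_instance_table(file.path(d, "instances.csv"))
  expect_equal(nrow(inst), nrow(sim$instances))
  gmt <- read_gene_sets(file.path(d, "sets.gmt"))
  expect_equal(lapply(gmt, identity)[names(sim$sets)],
               lapply(sim$sets, identity))
  pot <- read_potency_table(file.path(d, "potency.csv"))
  expect_true(all(pot$gi50 <= pot$tgi & pot$tgi <= pot$lc50))
})

test_that("toxic mixture mass tracks planted i_TOX", {
  sim <- simulate_corpus(n_compounds = 60, n_systems = 1, n_genes = 200,
                         n_sets = 10, K_true = 4, n_toxic = 2, seed = 7)
  tox_mass <- rowSums(sim$truth$theta_true[, sim$truth$toxic_components])
  itox <- sim$truth$itox[rownames(sim$truth$theta_true)]
  expect_gt(cor(tox_mass, itox, method = "spearman"), 0.9)
})

test_that("pathology study has a null baseline and a dose trend when planted", {
  # zero planted effect: prevalence flat in dose
  null_sim <- simulate_pathology_study(n_compounds = 60, frac_toxic = 0,
                                       seed = 8)
  ws <- weighted_pathology_score(null_sim$findings,
                                 treatments = null_sim$treatments$treatment_id)
  byd <- split(ws[null_sim$treatments$treatment_id, "grade:weighted"],
               null_sim$treatments$dose)
  m <- vapply(byd, mean, numeric(1))
  expect_lt(max(m) - min(m), 2 * max(vapply(byd, function(x)
    sd(x) / sqrt(length(x)), numeric(1))) + 0.2)

  # strong planted effect: severity increases with dose
  tox_sim <- simulate_pathology_study(n_compounds = 60, frac_toxic = 1,
                                      effect = 4, seed = 9)
  ws2 <- weighted_pathology_score(tox_sim$findings,
                                  treatments = tox_sim$treatments$treatment_id)
  dose_rank <- match(tox_sim$treatments$dose, c("low", "medium", "high"))
  ct <- cor.test(dose_rank, ws2[tox_sim$treatments$treatment_id,
                                "grade:weighted"],
                 method = "spearman", exact = FALSE)
  expect_lt(ct$p.value, 0.01)
  expect_gt(ct$estimate, 0)

  # single compound, single dose is a valid 1-row-per-finding study
  tiny <- simulate_pathology_study(n_compounds = 1, seed = 10)
  expect_equal(nrow(tiny$treatments), 3)
  expect_true(all(tiny$findings$n_animals >= 1))
})

test_that("DILI panel honours the planted margin separation", {
  sim <- simulate_dili_panel(n_positive = 25, n_negative = 10,
                             margin_gap = 2, detect_prob = 1, seed = 11)
  ann <- sim$annotations
  loel <- sim$truth$loel_true
  neg <- ann$dili_class == "negative_control"
  act_neg <- !is.na(loel[ann$compound_id[neg]])
  # negatives activate only above Cmax + margin_gap
  if (any(act_neg)) {
    mn <- loel[ann$compound_id[neg]][act_neg] - ann$cmax[neg][act_neg]
    expect_true(all(mn >= 2))
  }
  # detected positives activate below that band
  pos <- ann$dili_class == "dili_positive"
  mp <- loel[ann$compound_id[pos]] - ann$cmax[pos]
  expect_true(all(mp[!is.na(mp)] < 2))

  # overlapping margins force a sensitivity trade-off at 100% specificity
  lo <- simulate_dili_panel(n_positive = 30, n_negative = 8,
                            detect_prob = 0.5, seed = 12)
  res <- dili_margin_analysis(lo$doses, lo$annotations)
  expect_equal(res$specificity, 100)
  expect_lt(res$sensitivity, 100)
})
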