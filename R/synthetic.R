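# Synthetic corpora with planted ground truth for every pipeline stage:
# a perturbation-transcriptomics corpus with latent components linked to
# compound potency, an in vivo repeated-dose pathology study, and a
# hepatocyte dose-series DILI panel with Cmax annotations.
#
# Generator defaults state the emulated world once: 200 compounds in 3
# cell systems at the 10 uM screening concentration (log10 M = -5),
# GI50 potencies spanning the usual tumour-panel screening range,
# 1:3:10 in vivo and
# 1:5:25 hepatocyte dose ratios, 6 animals per treatment with 3
# profiled. They are not tuned per test.

#' Simulate a perturbation-transcriptomics corpus with planted components
#'
#' Gene sets partition the genes (with a small sampled overlap); each
#' latent component drives a block of sets up or down. Every instance
#' draws a component mixture in which the planted toxic components'
#' mass grows logistically with the concentration-dependent cytotoxicity
#' `i_TOX = concentration - GI50`. Expression is the mixture of
#' component effects on a log2 baseline plus Gaussian noise; each batch
#' carries its own control arrays. A potency table with
#' `gi50 <= tgi <= lc50` is emitted alongside.
#'
#' @param n_compounds,n_systems,n_genes,n_sets Corpus dimensions.
#' @param K_true Number of planted components.
#' @param n_toxic Number of components linked to cytotoxicity
#'   (`< K_true`).
#' @param noise_sd Gaussian noise standard deviation (log2 scale).
#' @param effect_size Log2 shift of a fully active component's genes.
#' @param concentration Screening concentration, log10 molar.
#' @param overlap Extra genes sampled into each set from outside its
#'   block.
#' @param batch_size Treatment instances per batch.
#' @param n_controls_per_batch Control arrays per batch.
#' @param seed Integer seed; generation is deterministic given it.
#' @return List: `expr` (genes x samples, log2), `instances`, `sets`,
#'   `potency`, and `truth` (`K_true`, `phi_true`, `theta_true`,
#'   `toxic_components`, `itox`, `de_genes`, `gi50`).
#' @export
simulate_corpus <- function(n_compounds = 200, n_systems = 3,
                            n_genes = 2000, n_sets = 50, K_true = 8,
                            n_toxic = 3, noise_sd = 0.3, effect_size = 2,
                            concentration = -5, overlap = 5,
                            batch_size = 20, n_controls_per_batch = 3,
                            seed = 1) {
  stopifnot(n_toxic < K_true, n_genes >= n_sets, n_sets >= K_true)
  set.seed(as.integer(seed))
  genes <- sprintf("g%04d", seq_len(n_genes))
  set_names <- sprintf("S%02d", seq_len(n_sets))

  # partitioned sets with sampled overlap
  block <- n_genes %/% n_sets
  sets <- vector("list", n_sets)
  names(sets) <- set_names
  for (s in seq_len(n_sets)) {
    own <- genes[((s - 1) * block + 1):(s * block)]
    extra <- sample(setdiff(genes, own), overlap)
    sets[[s]] <- unique(c(own, extra))
  }
  class(sets) <- "gene_set_collection"

  # components drive blocks of sets, some up, some down
  set_of_comp <- split(set_names, rep_len(seq_len(K_true), n_sets))
  features <- as.vector(rbind(paste0(set_names, "+"), paste0(set_names, "-")))
  phi_true <- matrix(0, K_true, length(features),
                     dimnames = list(paste0("T", seq_len(K_true)), features))
  effect <- matrix(0, n_genes, K_true, dimnames = list(genes, NULL))
  de_genes <- list()
  for (k in seq_len(K_true)) {
    drivers <- set_of_comp[[k]]
    dirs <- rep_len(c("up", "up", "down"), length(drivers))
    feat <- paste0(drivers, ifelse(dirs == "up", "+", "-"))
    phi_true[k, feat] <- 1 / length(feat)
    up <- unique(unlist(sets[drivers[dirs == "up"]], use.names = FALSE))
    dn <- unique(unlist(sets[drivers[dirs == "down"]], use.names = FALSE))
    dn <- setdiff(dn, up)
    effect[up, k] <- effect_size
    effect[dn, k] <- -effect_size
    de_genes[[k]] <- list(up = up, down = dn)
  }
  toxic <- sort(sample(K_true, n_toxic))

  compounds <- sprintf("cpd%03d", seq_len(n_compounds))
  systems <- sprintf("sys%d", seq_len(n_systems))
  gi50 <- setNames(runif(n_compounds, -8, -3), compounds)

  inst <- expand.grid(compound_id = compounds, system_id = systems,
                      stringsAsFactors = FALSE)
  n_inst <- nrow(inst)
  inst$instance_id <- sprintf("i%04d", seq_len(n_inst))
  inst$concentration <- concentration
  inst$is_control <- FALSE
  inst$batch_id <- sprintf("b%03d", rep_len(seq_len(ceiling(n_inst / batch_size)),
                                            n_inst))

  itox <- concentration - gi50[inst$compound_id]
  names(itox) <- inst$instance_id

  # mixture: toxic mass grows logistically with i_TOX
  theta_true <- matrix(0, n_inst, K_true,
                       dimnames = list(inst$instance_id, rownames(phi_true)))
  for (i in seq_len(n_inst)) {
    tmass <- 0.8 * plogis(2 * itox[i])
    g_tox <- rgamma(n_toxic, shape = 1)
    g_rest <- rgamma(K_true - n_toxic, shape = 0.5)
    th <- numeric(K_true)
    th[toxic] <- tmass * g_tox / sum(g_tox)
    th[-toxic] <- (1 - tmass) * g_rest / sum(g_rest)
    theta_true[i, ] <- th
  }

  base <- rnorm(n_genes, mean = 8, sd = 1)
  batches <- unique(inst$batch_id)
  batch_shift <- setNames(rnorm(length(batches), 0, 0.1), batches)

  ctrl <- expand.grid(batch_id = batches,
                      rep = seq_len(n_controls_per_batch),
                      stringsAsFactors = FALSE)
  ctrl$instance_id <- sprintf("ctl%04d", seq_len(nrow(ctrl)))
  ctrl_df <- data.frame(instance_id = ctrl$instance_id,
                        compound_id = "vehicle", system_id = systems[1],
                        concentration = NA_real_, is_control = TRUE,
                        batch_id = ctrl$batch_id, stringsAsFactors = FALSE)
  instances <- rbind(
    inst[, c("instance_id", "compound_id", "system_id", "concentration",
             "is_control", "batch_id")],
    ctrl_df)

  expr <- matrix(NA_real_, n_genes, nrow(instances),
                 dimnames = list(genes, instances$instance_id))
  signal <- effect %*% t(theta_true)  # genes x treatment instances
  for (j in seq_len(nrow(instances))) {
    id <- instances$instance_id[j]
    mu <- base + batch_shift[instances$batch_id[j]]
    if (!instances$is_control[j]) mu <- mu + signal[, id]
    expr[, j] <- mu + rnorm(n_genes, 0, noise_sd)
  }

  potency <- expand.grid(compound_id = compounds, system_id = systems,
                         stringsAsFactors = FALSE)
  potency$gi50 <- gi50[potency$compound_id] + rnorm(nrow(potency), 0, 0.05)
  potency$tgi <- potency$gi50 + 0.5
  potency$lc50 <- potency$gi50 + 1.0

  list(expr = expr, instances = instances, sets = sets, potency = potency,
       truth = list(K_true = K_true, phi_true = phi_true,
                    theta_true = theta_true,
                    toxic_components = rownames(phi_true)[toxic],
                    itox = itox, de_genes = de_genes, gi50 = gi50))
}

#' Simulate a repeated-dose pathology study
#'
#' Treatments are compound x dose (1:3:10 ratios) x duration. A latent
#' toxic activity grows with dose for hepatotoxic compounds, drives the
#' planted predictive components of a mixture profile, and generates
#' ordinal finding grades for 6 animals per treatment from a
#' proportional-odds model (3 of the 6 are nominally profiled).
#'
#' @param n_compounds Number of compounds.
#' @param n_components Components of the mixture profile (default 14).
#' @param n_predictive Planted pathology-predictive components.
#' @param durations Treatment durations in days.
#' @param finding_types Finding types; the first reacts most strongly.
#' @param frac_toxic Fraction of hepatotoxic compounds.
#' @param effect Strength of the dose-activity link.
#' @param baseline Intercept of the proportional-odds model (controls
#'   the background finding rate).
#' @param n_animals,n_profiled Animals per treatment / profiled subset.
#' @param seed Integer seed.
#' @return List: `theta` (treatments x components), `treatments`,
#'   `findings`, and `truth` (`predictive_components`, `activity`).
#' @export
simulate_pathology_study <- function(n_compounds = 24, n_components = 14,
                                     n_predictive = 4, durations = 28,
                                     finding_types = c("necrosis", "fibrosis",
                                                       "hypertrophy"),
                                     frac_toxic = 0.5, effect = 3,
                                     baseline = -3.5, n_animals = 6,
                                     n_profiled = 3, seed = 1) {
  stopifnot(n_predictive < n_components)
  set.seed(as.integer(seed))
  compounds <- sprintf("cpd%03d", seq_len(n_compounds))
  dose_levels <- c(low = 1, medium = 3, high = 10)
  trt <- expand.grid(compound_id = compounds,
                     dose = names(dose_levels),
                     duration = durations, stringsAsFactors = FALSE)
  trt$treatment_id <- sprintf("t%04d", seq_len(nrow(trt)))
  is_toxic <- setNames(runif(n_compounds) < frac_toxic, compounds)
  potency <- setNames(runif(n_compounds, 0.5, 1.5), compounds)
  u <- ifelse(is_toxic[trt$compound_id],
              potency[trt$compound_id] *
                log10(dose_levels[trt$dose] + 1) / log10(11),
              0)
  names(u) <- trt$treatment_id

  # The reported components are a subset of a larger mixture (as when
  # scoring against a selected space), so their probabilities do not
  # sum to one: an implicit background absorbs the remainder. The
  # predictive components' mass grows with toxic activity; the other
  # components' values are drawn independently of it, so only the
  # planted components carry outcome information.
  predictive <- paste0("C", sort(sample(n_components, n_predictive)))
  comp_names <- paste0("C", seq_len(n_components))
  is_pred <- comp_names %in% predictive
  theta <- matrix(NA_real_, nrow(trt), n_components,
                  dimnames = list(trt$treatment_id, comp_names))
  for (i in seq_len(nrow(trt))) {
    m <- min((0.05 + 0.25 * effect / 3 * u[i]) * exp(rnorm(1, 0, 0.2)), 0.55)
    g_pred <- rgamma(n_predictive, shape = 2)
    g_rest <- rgamma(n_components - n_predictive, shape = 1)
    th <- numeric(n_components)
    th[is_pred] <- m * g_pred / sum(g_pred)
    th[!is_pred] <- 0.35 * g_rest / sum(g_rest)
    theta[i, ] <- th
  }

  # proportional-odds ordinal grades per animal
  cutpoints <- c(0, 1, 2.2, 3.4, 4.6)  # offsets for present..severe
  loading <- setNames(seq(1, 0.4, length.out = length(finding_types)),
                      finding_types)
  rows <- list()
  for (i in seq_len(nrow(trt))) {
    for (ft in finding_types) {
      eta <- baseline + effect * 2 * u[i] * loading[ft]
      # P(grade >= g) = plogis(eta - cutpoints[g])
      pg <- plogis(eta - cutpoints)
      counts <- integer(length(PATHOLOGY_GRADES))
      for (a in seq_len(n_animals)) {
        r <- runif(1)
        g <- sum(r < pg)  # 0 = no finding
        if (g > 0) counts[g] <- counts[g] + 1L
      }
      keep <- counts > 0L
      if (any(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          treatment_id = trt$treatment_id[i],
          compound_id = trt$compound_id[i], dose = trt$dose[i],
          duration = trt$duration[i],
          finding_type = ft, grade = PATHOLOGY_GRADES[keep],
          n_animals = counts[keep], stringsAsFactors = FALSE)
    }
  }
  findings <- if (length(rows)) do.call(rbind, rows) else
    data.frame(treatment_id = character(), compound_id = character(),
               dose = character(), duration = numeric(),
               finding_type = character(), grade = character(),
               n_animals = integer(), stringsAsFactors = FALSE)
  rownames(findings) <- NULL
  list(theta = theta, treatments = trt, findings = findings,
       truth = list(predictive_components = predictive, activity = u,
                    is_toxic = is_toxic, n_profiled = n_profiled))
}

#' Simulate a hepatocyte DILI panel with Cmax annotations
#'
#' Each compound gets a three-point dose series in 1:5:25 ratios and a
#' therapeutic Cmax. Negative controls activate, if at all, only at
#' concentrations at least `margin_gap` log10 units above their Cmax;
#' DILI-positive compounds activate below that band with probability
#' `detect_prob`.
#'
#' @param n_positive,n_negative Panel composition.
#' @param margin_gap Planted log10 separation between negative-control
#'   activation and Cmax (default 2, i.e. 100-fold).
#' @param detect_prob Probability that a positive compound activates in
#'   the tested range (1 = perfect separation).
#' @param seed Integer seed.
#' @return List: `doses` (compound_id, concentration, active, score),
#'   `annotations`, `truth` (`loel_true` per compound).
#' @export
simulate_dili_panel <- function(n_positive = 40, n_negative = 10,
                                margin_gap = 2, detect_prob = 0.9,
                                seed = 1) {
  stopifnot(margin_gap > 0)
  set.seed(as.integer(seed))
  n <- n_positive + n_negative
  ids <- sprintf("drug%03d", seq_len(n))
  cls <- c(rep("dili_positive", n_positive), rep("negative_control", n_negative))
  cmax <- runif(n, -7.5, -5.5)
  top <- cmax + runif(n, 1.5, 3)
  severity <- ifelse(cls == "dili_positive" & runif(n) < 0.3,
                     sample(c("withdrawn", "boxed_warning"), n, replace = TRUE),
                     NA_character_)

  act_thresh <- numeric(n)
  for (i in seq_len(n)) {
    if (cls[i] == "negative_control") {
      act_thresh[i] <- if (runif(1) < 0.5) Inf else
        cmax[i] + margin_gap + runif(1, 0, 1)
    } else {
      act_thresh[i] <- if (runif(1) < detect_prob)
        cmax[i] + runif(1, -0.5, 1) else Inf
    }
  }

  rows <- lapply(seq_len(n), function(i) {
    conc <- top[i] - log10(c(25, 5, 1))
    data.frame(compound_id = ids[i], concentration = conc,
               active = conc >= act_thresh[i],
               score = round(plogis(3 * (conc - act_thresh[i])), 4),
               stringsAsFactors = FALSE)
  })
  doses <- do.call(rbind, rows)
  rownames(doses) <- NULL
  annotations <- data.frame(compound_id = ids, cmax = cmax,
                            dili_class = cls, severity_label = severity,
                            stringsAsFactors = FALSE)
  loel_true <- vapply(seq_len(n), function(i) {
    conc <- top[i] - log10(c(25, 5, 1))
    a <- conc >= act_thresh[i]
    if (any(a)) conc[which(a)[1]] else NA_real_
  }, numeric(1))
  list(doses = doses, annotations = annotations,
       truth = list(loel_true = setNames(loel_true, ids),
                    activation_threshold = setNames(act_thresh, ids)))
}

#' Simulate a dose-series expression experiment
#'
#' Small treatment-vs-control expression matrices at rising doses in
#' which a planted active gene list shifts with magnitude growing
#' logistically in `dose - gi50`. Used to exercise gene-based scoring
#' and virtual GI50 calls on a known dose-response.
#'
#' @param genes All measured gene ids.
#' @param active_genes Planted responsive gene ids (subset of `genes`).
#' @param doses Tested concentrations, log10 molar.
#' @param gi50 Potency anchor, log10 molar.
#' @param n_treat,n_ctrl Arrays per dose.
#' @param effect Maximal log2 shift of active genes.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return List per dose: `treatments`, `controls` matrices.
#' @export
simulate_dose_series_expression <- function(genes, active_genes, doses,
                                            gi50 = -6, n_treat = 3,
                                            n_ctrl = 3, effect = 1.5,
                                            noise_sd = 0.4, seed = 1) {
  stopifnot(all(active_genes %in% genes))
  set.seed(as.integer(seed))
  out <- vector("list", length(doses))
  names(out) <- as.character(doses)
  shift <- setNames(numeric(length(genes)), genes)
  for (d in seq_along(doses)) {
    mag <- effect * plogis(2.5 * (doses[d] - gi50))
    shift[] <- 0
    shift[active_genes] <- mag * sample(c(1, -1), length(active_genes),
                                        replace = TRUE)
    ctrl <- matrix(rnorm(length(genes) * n_ctrl, 8, noise_sd),
                   length(genes), n_ctrl,
                   dimnames = list(genes, paste0("c", seq_len(n_ctrl))))
    trt <- matrix(rnorm(length(genes) * n_treat, 8, noise_sd),
                  length(genes), n_treat,
                  dimnames = list(genes, paste0("t", seq_len(n_treat)))) + shift
    out[[d]] <- list(treatments = trt, controls = ctrl, dose = doses[d])
  }
  out
}
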