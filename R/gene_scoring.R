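# Gene-based scoring of expression experiments against the PTGS gene
# lists: empirical-Bayes moderated z-scores, rotation gene-set tests
# with the floormean summary (limma ROAST), proportion-active
# statistics, virtual GI50 calls and the gene-based DILI score.

ACTIVE_Z <- sqrt(2)  # |z| beyond which a gene counts as active

#' Moderated per-gene z-scores for a treatment-vs-control comparison
#'
#' Fits the two-group linear model with limma, shrinks gene variances
#' toward the pooled empirical-Bayes prior, and maps the moderated
#' t-statistics to standard normal z-scores through their augmented-df
#' t distribution.
#'
#' @param treatments Expression matrix (genes x treatment arrays), >= 1
#'   column, log2 scale.
#' @param controls Expression matrix (genes x control arrays), >= 2
#'   columns, same genes.
#' @return Named numeric vector of moderated z-scores (positive = up in
#'   treatment).
#' @export
moderated_gene_z <- function(treatments, controls) {
  treatments <- as.matrix(treatments)
  controls <- as.matrix(controls)
  if (ncol(controls) < 2L) stop("need >= 2 control arrays")
  if (ncol(treatments) < 1L) stop("need >= 1 treatment array")
  if (!identical(rownames(treatments), rownames(controls)))
    stop("gene mismatch between treatments and controls")
  y <- cbind(controls, treatments)
  design <- cbind(Intercept = 1,
                  treat = rep(c(0, 1), c(ncol(controls), ncol(treatments))))
  fit <- limma::eBayes(limma::lmFit(y, design))
  z <- limma::zscoreT(fit$t[, "treat"], df = fit$df.total,
                      approx = TRUE, method = "bailey")
  setNames(as.numeric(z), rownames(y))
}

#' Rotation gene-set tests with the floormean summary
#'
#' Runs the ROAST rotation test (limma) for each gene set on the
#' treatment-vs-control contrast, reporting the non-directional (mixed)
#' rotation p-value `p_mixed = (b + 1) / (n_rot + 1)` and the
#' percentage of set genes active at `|z| > sqrt(2)`. Sets overlapping
#' the measured genes by fewer than `min_overlap` genes are skipped.
#' With fewer than 3 residual degrees of freedom the rotation null is
#' unreliable and the implementation falls back to sign-flip
#' permutation of the effect decomposition, with a warning.
#'
#' @param treatments,controls Expression matrices as in
#'   [moderated_gene_z()].
#' @param gene_sets Named list of gene id vectors.
#' @param n_rot Number of rotations (default 9999).
#' @param min_overlap Minimum measured genes per set (default 2).
#' @return Data frame: `set_name`, `n_genes`, `p_mixed`, `pct_active`.
#' @export
rotation_set_test <- function(treatments, controls, gene_sets,
                              n_rot = 9999, min_overlap = 2) {
  treatments <- as.matrix(treatments)
  controls <- as.matrix(controls)
  if (!identical(rownames(treatments), rownames(controls)))
    stop("gene mismatch between treatments and controls")
  y <- cbind(controls, treatments)
  design <- cbind(Intercept = 1,
                  treat = rep(c(0, 1), c(ncol(controls), ncol(treatments))))
  df_resid <- ncol(y) - 2L
  idx <- lapply(gene_sets, function(g) which(rownames(y) %in% g))
  keep <- lengths(idx) >= min_overlap
  if (any(!keep))
    ptgs_log("rotation test: skipped ", sum(!keep),
             " set(s) below overlap ", min_overlap)
  idx <- idx[keep]
  if (length(idx) == 0L)
    return(data.frame(set_name = character(), n_genes = integer(),
                      p_mixed = numeric(), pct_active = numeric(),
                      stringsAsFactors = FALSE))
  if (df_resid >= 3L) {
    out <- lapply(names(idx), function(nm) {
      r <- limma::roast(y, index = idx[[nm]], design = design, contrast = 2,
                        set.statistic = "floormean", nrot = n_rot)
      data.frame(set_name = nm, n_genes = length(idx[[nm]]),
                 p_mixed = r$p.value["Mixed", "P.Value"],
                 pct_active = 100 * r$p.value["Mixed", "Active.Prop"],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
  } else {
    warning("fewer than 3 residual df; using sign-flip permutation null")
    out <- do.call(rbind, lapply(names(idx), function(nm) {
      sf <- signflip_set_test(y, design, idx[[nm]], n_rot = n_rot)
      data.frame(set_name = nm, n_genes = length(idx[[nm]]),
                 p_mixed = sf$p_mixed, pct_active = sf$pct_active,
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(out) <- NULL
  out
}

# Effect decomposition shared by the sign-flip null: for each gene, the
# contrast effect plus the residual-space coordinates, such that
# effect / sqrt(mean(residual^2)) is the ordinary t-statistic.
#' @noRd
lm_effects <- function(y, design, contrast = 2) {
  p <- ncol(design)
  X <- design[, c(setdiff(seq_len(p), contrast), contrast), drop = FALSE]
  qrX <- qr(X)
  u <- qr.qty(qrX, t(y))      # n x genes
  eff <- u[p, ] * sign(qr.R(qrX)[p, p])
  res <- u[(p + 1):nrow(u), , drop = FALSE]
  cbind(effect = eff, t(res))
}

# Sign-flip analogue of the rotation test: the random rotation direction
# is replaced by a scaled random (or exhaustive) sign vector over the
# effect + residual coordinates. Shares the floormean statistic and the
# empirical-Bayes variance shrinkage with the rotation path.
#' @noRd
signflip_set_test <- function(y, design, index, n_rot = 9999,
                              exhaustive_limit = 4096) {
  eff <- lm_effects(y, design)
  d1 <- ncol(eff)                      # effect + residual df
  df_resid <- d1 - 1L
  s2 <- rowMeans(eff[, -1, drop = FALSE]^2)
  sv <- limma::squeezeVar(s2, df = df_resid)
  df_total <- min(sv$df.prior + df_resid, 1e4)  # scalar prior df
  eset <- eff[index, , drop = FALSE]
  var_post <- sv$var.post[index]
  modt <- eset[, 1] / sqrt(var_post)
  z <- limma::zscoreT(modt, df = df_total, approx = TRUE,
                      method = "bailey")
  chimed <- qnorm(0.75)
  stat_obs <- mean(pmax(abs(z), chimed))
  pct_active <- 100 * mean(abs(z) > ACTIVE_Z)

  if (2^d1 <= exhaustive_limit) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), d1)))
  } else {
    signs <- matrix(sample(c(-1, 1), n_rot * d1, replace = TRUE),
                    n_rot, d1)
  }
  B <- nrow(signs)
  r <- t(signs) / sqrt(d1)            # unit-norm directions
  effr <- eset %*% r                  # set genes x B
  if (is.infinite(sv$df.prior)) {
    # fully shrunk variances: the posterior variance is the prior
    s2r <- matrix(sv$var.prior, nrow(eset), B)
  } else {
    s2r <- (rowSums(eset^2) - effr^2) / df_resid
    s2r <- (sv$df.prior * sv$var.prior + df_resid * s2r) /
      (sv$df.prior + df_resid)
  }
  zr <- limma::zscoreT(effr / sqrt(s2r), df = df_total,
                       approx = TRUE, method = "bailey")
  stat_rot <- colMeans(pmax(abs(zr), chimed))
  p_mixed <- (sum(stat_rot > stat_obs) + 1) / (B + 1)
  list(p_mixed = p_mixed, pct_active = pct_active, stat_obs = stat_obs,
       null = stat_rot)
}

#' Proportion of active genes in a set
#'
#' Percentage of the set's measured genes with `|z| > sqrt(2)`.
#'
#' @param z Named numeric vector of gene z-scores.
#' @param gene_set Character vector of gene ids.
#' @return Percentage in `[0, 100]`.
#' @export
proportion_active <- function(z, gene_set) {
  zz <- z[names(z) %in% gene_set]
  if (length(zz) == 0L) stop("gene set does not overlap the measured genes")
  100 * mean(abs(zz) > ACTIVE_Z)
}

#' Virtual GI50 calls from PTGS_ALL activation
#'
#' An experiment is called active (measured above its virtual GI50
#' level) when its PTGS_ALL rotation q-value is below 0.05 and more than
#' 25% of the PTGS_ALL genes are active. q-values are
#' Benjamini-Hochberg adjusted across the experiment batch.
#'
#' @param p_all Rotation mixed p-values for PTGS_ALL, one per experiment.
#' @param pct_active_all Matching percentages of active PTGS_ALL genes.
#' @param q_cut,pct_cut Decision thresholds (defaults 0.05 and 25).
#' @return Data frame: `q_all`, `pct_active_all`, `active`.
#' @export
virtual_gi50_call <- function(p_all, pct_active_all, q_cut = 0.05,
                              pct_cut = 25) {
  stopifnot(length(p_all) == length(pct_active_all))
  q <- p.adjust(p_all, method = "BH")
  data.frame(q_all = q, pct_active_all = pct_active_all,
             active = q < q_cut & pct_active_all > pct_cut,
             stringsAsFactors = FALSE)
}

#' Gene-based DILI score
#'
#' `score = max(%act)` and `p = min(p_mixed)` over the DILI-predictive
#' component gene lists (canonically G, H, I and N).
#'
#' @param pct_active Named numeric vector (or matrix, experiments x
#'   components) of percent-active values.
#' @param p_mixed Matching rotation mixed p-values.
#' @param components Component labels entering the score.
#' @return List (or data frame for matrix input) with `score` and `p`.
#' @export
dili_gene_score <- function(pct_active, p_mixed,
                            components = c("G", "H", "I", "N")) {
  if (is.matrix(pct_active)) {
    missing <- setdiff(components, colnames(pct_active))
    if (length(missing))
      stop("missing component score(s): ", paste(missing, collapse = ", "))
    data.frame(
      score = apply(pct_active[, components, drop = FALSE], 1L, max),
      p = apply(p_mixed[, components, drop = FALSE], 1L, min)
    )
  } else {
    missing <- setdiff(components, names(pct_active))
    if (length(missing))
      stop("missing component score(s): ", paste(missing, collapse = ", "))
    list(score = max(pct_active[components]), p = min(p_mixed[components]))
  }
}

#' Average scores over replicated treatments
#'
#' @param scores Data frame of numeric score columns.
#' @param treatment Replicate grouping key, one per row.
#' @return Data frame with one row per unique treatment, numeric
#'   columns averaged.
#' @export
average_replicate_scores <- function(scores, treatment) {
  stopifnot(nrow(scores) == length(treatment))
  num <- vapply(scores, is.numeric, logical(1))
  agg <- aggregate(scores[num], by = list(treatment_id = treatment), FUN = mean)
  agg[order(agg$treatment_id), , drop = FALSE]
}
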