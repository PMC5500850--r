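# Fusing the component model with GI50-anchored potency data:
# concentration-dependent cytotoxicity, probability-weighted component
# ranking, cumulative-AUC selection of the predictive space, component
# scoring, and score-threshold calibration.

#' Concentration-dependent cytotoxicity (i_TOX)
#'
#' `i_TOX = log10(assay concentration) - log10(GI50)`, both in log10
#' molar. An instance is cytotoxic when it was measured strictly above
#' the GI50 level, i.e. `i_TOX > 0`.
#'
#' @param conc Assay concentration(s), log10 molar.
#' @param gi50 Matching GI50 value(s), log10 molar.
#' @return Numeric vector of i_TOX values.
#' @export
concentration_dependent_cytotoxicity <- function(conc, gi50) {
  stop_if_not_finite(conc, "concentration")
  stop_if_not_finite(gi50, "gi50")
  conc - gi50
}

#' Rank components by probability-weighted mean cytotoxicity
#'
#' Each component's cytotoxicity is the mean of the training instances'
#' i_TOX values weighted by the normalized probabilities `p(i|z)`:
#' `tox(z) = sum_i p(i|z) * i_TOX(i)`. Components are ordered by
#' descending weighted cytotoxicity, exact ties broken by component id.
#'
#' @param p_i_given_z Matrix K x training instances, rows summing to 1
#'   (see [component_instance_probabilities()]).
#' @param itox Named numeric vector of i_TOX values covering every
#'   training instance.
#' @return A `component_ranking`: list with `order` (component ids,
#'   descending tox) and `tox` (named weighted means).
#' @export
weighted_component_cytotoxicity <- function(p_i_given_z, itox) {
  stopifnot(is.matrix(p_i_given_z))
  missing <- setdiff(colnames(p_i_given_z), names(itox))
  if (length(missing))
    stop("i_TOX undefined for training instance(s): ",
         paste(head(missing, 5), collapse = ", "))
  itox <- itox[colnames(p_i_given_z)]
  stop_if_not_finite(itox, "i_TOX")
  tox <- drop(p_i_given_z %*% itox)
  ord <- rownames(p_i_given_z)[order(-tox, rownames(p_i_given_z))]
  structure(list(order = ord, tox = tox[ord]), class = "component_ranking")
}

#' Select the predictive component space by cumulative ROC-AUC
#'
#' Components are added in ranking order; at each prefix size k the
#' cumulative score `sum of theta over the top-k components` is
#' evaluated as a classifier of the cytotoxic labels by Mann-Whitney
#' AUC. The smallest k whose AUC reaches `frac` of the maximal AUC
#' defines the space. Selected components are labelled `A`, `B`, ... in
#' ranking order (A = highest weighted cytotoxicity).
#'
#' @param ranking A `component_ranking`.
#' @param theta Instance-mixture matrix (instances x components) for the
#'   labelled instances.
#' @param cytotoxic_labels Logical vector (TRUE = above GI50), aligned
#'   with `theta` rows.
#' @param frac Fraction of the maximal AUC to reach (default 0.95).
#' @return A `ptgs_definition`: `selected_components`, `labels`,
#'   `auc_curve`, `tox`, and a `score_threshold` slot (NA until
#'   calibrated with [calibrate_score_threshold()]).
#' @export
cumulative_auc_selection <- function(ranking, theta, cytotoxic_labels,
                                     frac = 0.95) {
  stopifnot(inherits(ranking, "component_ranking"), is.matrix(theta))
  labels <- as.logical(cytotoxic_labels)
  if (length(unique(labels)) < 2L)
    stop("cytotoxic labels must contain both classes")
  comp <- ranking$order
  stopifnot(all(comp %in% colnames(theta)))
  auc_curve <- setNames(numeric(length(comp)), seq_along(comp))
  score <- rep(0, nrow(theta))
  for (k in seq_along(comp)) {
    score <- score + theta[, comp[k]]
    auc_curve[k] <- auc_mw(score, labels)
  }
  k_sel <- which(auc_curve >= frac * max(auc_curve))[1]
  selected <- comp[seq_len(k_sel)]
  structure(list(
    selected_components = selected,
    labels = LETTERS[seq_len(k_sel)],
    auc_curve = unname(auc_curve),
    tox = ranking$tox,
    component_order = comp,
    frac = frac,
    score_threshold = NA_real_
  ), class = "ptgs_definition")
}

#' Component-based PTGS score
#'
#' The probability mass an instance places on the selected components:
#' `score(i) = sum over selected z of theta[i, z]`, in `[0, 1]`.
#'
#' @param theta Instance-mixture matrix with component columns.
#' @param ptgs A `ptgs_definition`.
#' @param instances Instance ids to score (default: all rows).
#' @return Named numeric vector of scores.
#' @export
ptgs_component_score <- function(theta, ptgs, instances = rownames(theta)) {
  stopifnot(is.matrix(theta), inherits(ptgs, "ptgs_definition"))
  missing <- setdiff(instances, rownames(theta))
  if (length(missing))
    stop("unknown instance(s): ", paste(head(missing, 5), collapse = ", "))
  sel <- ptgs$selected_components
  stopifnot(all(sel %in% colnames(theta)))
  rowSums(theta[instances, sel, drop = FALSE])
}

#' Calibrate the score decision threshold
#'
#' Finds the smallest score threshold t such that, among instances
#' scoring strictly above t, the fraction labelled cytotoxic reaches
#' `target_positive_fraction`. Also reports the Youden
#' (sensitivity + specificity - 1 maximizing) threshold.
#'
#' @param scores Numeric scores.
#' @param cytotoxic_labels Logical labels aligned with `scores`.
#' @param target_positive_fraction Target prevalence above the
#'   threshold (default 0.5).
#' @return List with `threshold`, `youden_threshold`, and the
#'   prevalence curve (`cutoffs`, `positive_fraction`).
#' @export
calibrate_score_threshold <- function(scores, cytotoxic_labels,
                                      target_positive_fraction = 0.5) {
  labels <- as.logical(cytotoxic_labels)
  if (length(unique(labels)) < 2L) stop("labels must contain both classes")
  cuts <- sort(unique(scores))
  # fraction positive strictly above each cutoff
  frac_pos <- vapply(cuts, function(t) {
    above <- scores > t
    if (!any(above)) return(NA_real_)
    mean(labels[above])
  }, numeric(1))
  ok <- which(!is.na(frac_pos) & frac_pos >= target_positive_fraction)
  if (length(ok) == 0L) {
    warning("target positive fraction unreachable; returning max score")
    threshold <- max(scores)
  } else {
    threshold <- cuts[ok[1]]
  }
  # Youden threshold
  youden <- vapply(cuts, function(t) {
    sens <- mean(scores[labels] > t)
    spec <- mean(scores[!labels] <= t)
    sens + spec - 1
  }, numeric(1))
  list(threshold = threshold,
       youden_threshold = cuts[which.max(youden)],
       cutoffs = cuts, positive_fraction = frac_pos)
}
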