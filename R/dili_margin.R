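# Safety margins for clinical DILI risk: lowest observable effect level
# (LOEL) from hepatocyte dose series, margin against the therapeutic
# Cmax, threshold calibration on negative-control compounds, and panel
# classification.

#' Lowest observable effect level of a dose series
#'
#' The lowest tested concentration at which the score is active;
#' `NA` when no concentration is active. Non-monotone activity patterns
#' (an inactive dose above an active one) are honoured but logged.
#'
#' @param concentration Tested concentrations, log10 molar, strictly
#'   increasing.
#' @param active Logical activity flags per concentration.
#' @return LOEL in log10 molar, or `NA_real_`.
#' @export
loel_concentration <- function(concentration, active) {
  stopifnot(length(concentration) == length(active),
            length(concentration) >= 1)
  if (is.unsorted(concentration, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  idx <- which(as.logical(active))
  if (length(idx) == 0L) return(NA_real_)
  if (any(!active[idx[1]:length(active)]))
    ptgs_log("non-monotone activity pattern; LOEL = lowest active dose")
  concentration[idx[1]]
}

#' Safety margin relative to therapeutic exposure
#'
#' `margin = log10(LOEL) - log10(Cmax)`, both already log10 molar. An
#' absent LOEL (inactive compound) yields an absent margin.
#'
#' @param loel LOEL in log10 molar (may be `NA`).
#' @param cmax Therapeutic Cmax in log10 molar.
#' @return Margin in log10 units, or `NA_real_` when inactive.
#' @export
safety_margin <- function(loel, cmax) {
  stop_if_not_finite(cmax, "cmax")
  loel - cmax
}

#' Margin decision threshold from negative controls
#'
#' The binding constraint is the negative-control compound with the
#' smallest defined margin: the threshold sits just below it (epsilon
#' 1e-9) so that every negative is called negative — 100% specificity on
#' the calibration set by construction. Inactive negatives impose no
#' constraint; when all negatives are inactive the configured ceiling
#' (default 2 log10 units, the upper bound of the conventional 10-100
#' fold acceptable-margin band) is returned.
#'
#' @param negative_margins Margins of the negative-control compounds
#'   (`NA` = inactive).
#' @param ceiling_margin Fallback threshold when unconstrained.
#' @return Numeric threshold; compounds with margin strictly below it
#'   are DILI-positive.
#' @export
margin_threshold_from_negatives <- function(negative_margins,
                                            ceiling_margin = 2) {
  if (length(negative_margins) == 0L)
    stop("no negative-control compounds supplied")
  defined <- negative_margins[!is.na(negative_margins)]
  if (length(defined) == 0L) return(ceiling_margin)
  min(defined) - 1e-9
}

#' Classify a compound panel and summarize performance
#'
#' A compound is DILI-positive when its margin is strictly below the
#' threshold; inactive compounds (absent margin) are negative.
#' Sensitivity is computed over the annotated `dili_positive` compounds
#' and specificity over the `negative_control` compounds.
#'
#' @param margins Named numeric vector of margins (`NA` = inactive),
#'   names = compound ids.
#' @param threshold Decision threshold from
#'   [margin_threshold_from_negatives()].
#' @param annotations Data frame with `compound_id` and `dili_class`.
#' @return List with `calls` (data frame: compound, margin, call),
#'   `sensitivity` and `specificity` (percentages).
#' @export
classify_and_summarize <- function(margins, threshold, annotations) {
  stopifnot(!is.null(names(margins)))
  missing <- setdiff(names(margins), annotations$compound_id)
  if (length(missing))
    stop("unannotated compound(s): ", paste(head(missing, 5), collapse = ", "))
  call <- ifelse(is.na(margins), "inactive",
                 ifelse(margins < threshold, "positive", "negative"))
  predicted_pos <- call == "positive"
  cls <- annotations$dili_class[match(names(margins), annotations$compound_id)]
  tp <- sum(predicted_pos & cls == "dili_positive")
  fn <- sum(!predicted_pos & cls == "dili_positive")
  tn <- sum(!predicted_pos & cls == "negative_control")
  fp <- sum(predicted_pos & cls == "negative_control")
  list(
    calls = data.frame(compound_id = names(margins), margin = unname(margins),
                       call = unname(call), dili_class = cls,
                       stringsAsFactors = FALSE),
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  )
}

#' Combine DILI calls from two assays
#'
#' A compound shared by both inputs is positive if either assay calls
#' it positive; compounds present in only one input keep that call and
#' are flagged.
#'
#' @param calls_a,calls_b Named character vectors of calls
#'   (`"positive"` / `"negative"` / `"inactive"`).
#' @return Data frame: `compound_id`, `call`, `shared`.
#' @export
combine_predictions <- function(calls_a, calls_b) {
  stopifnot(!is.null(names(calls_a)), !is.null(names(calls_b)))
  ids <- sort(union(names(calls_a), names(calls_b)))
  call <- vapply(ids, function(id) {
    a <- calls_a[id]
    b <- calls_b[id]
    pos <- isTRUE(unname(a == "positive")) || isTRUE(unname(b == "positive"))
    if (pos) "positive"
    else if (!is.na(a) && !is.na(b)) "negative"
    else if (!is.na(a)) unname(a) else unname(b)
  }, character(1))
  call[call == "inactive"] <- "negative"
  data.frame(compound_id = ids, call = unname(call),
             shared = ids %in% intersect(names(calls_a), names(calls_b)),
             stringsAsFactors = FALSE)
}

#' End-to-end DILI margin analysis for a dose-series panel
#'
#' Computes per-compound LOELs from active calls across the dose
#' series, margins against Cmax, the negative-control-calibrated
#' threshold, and the resulting calls and summary.
#'
#' @param doses Data frame with `compound_id`, `concentration` (log10
#'   molar) and `active` (logical), one row per tested dose.
#' @param annotations DILI annotation table (see
#'   [read_dili_annotations()]).
#' @param ceiling_margin Fallback threshold when all negatives are
#'   inactive.
#' @return List with `margins`, `threshold`, `calls`, `sensitivity`,
#'   `specificity`.
#' @export
dili_margin_analysis <- function(doses, annotations, ceiling_margin = 2) {
  ids <- sort(unique(doses$compound_id))
  loel <- vapply(ids, function(id) {
    d <- doses[doses$compound_id == id, , drop = FALSE]
    d <- d[order(d$concentration), , drop = FALSE]
    loel_concentration(d$concentration, d$active)
  }, numeric(1))
  cmax <- annotations$cmax[match(ids, annotations$compound_id)]
  if (anyNA(cmax))
    stop("missing Cmax annotation for: ",
         paste(ids[is.na(cmax)], collapse = ", "))
  margins <- setNames(safety_margin(loel, cmax), ids)
  negs <- annotations$compound_id[annotations$dili_class == "negative_control"]
  threshold <- margin_threshold_from_negatives(
    margins[names(margins) %in% negs], ceiling_margin = ceiling_margin)
  res <- classify_and_summarize(margins, threshold, annotations)
  c(list(margins = margins, loel = setNames(loel, ids),
         threshold = threshold), res)
}
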