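# Ordinal liver-pathology endpoints from findings tables, score-vs-
# pathology association, regularized selection of the DILI-predictive
# components, and the component-based DILI score with its
# prevalence-derived decision threshold.

PATHOLOGY_GRADES <- c("present", "minimal", "slight", "moderate", "severe")
GRADE_WEIGHTS <- setNames(1:5, PATHOLOGY_GRADES)

#' Cumulative pathology endpoints
#'
#' For each finding type and grade threshold g, counts the animals with
#' grade >= g per treatment (present = all grades, ..., severe = only
#' severe). Grade-only aggregates across finding types are computed the
#' same way and named `grade:<g>`.
#'
#' @param findings Data frame with `treatment_id`, `finding_type`,
#'   `grade`, `n_animals` (see [read_pathology_findings()]).
#' @param treatments Optional treatment ids fixing the row universe
#'   (treatments without findings get zero rows).
#' @return Integer matrix, treatments x endpoints, endpoint columns
#'   named `<finding>:<grade>` plus `grade:<grade>`.
#' @export
cumulative_endpoints <- function(findings, treatments = NULL) {
  bad <- !findings$grade %in% PATHOLOGY_GRADES
  if (any(bad))
    stop("unknown grade label in record(s): ",
         paste(which(bad), collapse = ", "))
  if (is.null(treatments))
    treatments <- sort(unique(findings$treatment_id))
  types <- sort(unique(findings$finding_type))
  endpoints <- c(
    as.vector(t(outer(types, PATHOLOGY_GRADES, paste, sep = ":"))),
    paste0("grade:", PATHOLOGY_GRADES)
  )
  out <- matrix(0L, length(treatments), length(endpoints),
                dimnames = list(treatments, endpoints))
  if (nrow(findings) == 0L) return(out)
  g_idx <- match(findings$grade, PATHOLOGY_GRADES)
  for (r in seq_len(nrow(findings))) {
    tr <- as.character(findings$treatment_id[r])
    if (!tr %in% rownames(out)) next
    n <- findings$n_animals[r]
    for (g in seq_len(g_idx[r])) {  # contributes to all thresholds <= grade
      ep <- paste0(findings$finding_type[r], ":", PATHOLOGY_GRADES[g])
      out[tr, ep] <- out[tr, ep] + n
      agg <- paste0("grade:", PATHOLOGY_GRADES[g])
      out[tr, agg] <- out[tr, agg] + n
    }
  }
  out
}

#' Weighted pathology score
#'
#' `score = 1*present + 2*minimal + 3*slight + 4*moderate + 5*severe`
#' over the raw (non-cumulative) grade counts, per treatment and
#' finding type.
#'
#' @param findings Findings data frame as in [cumulative_endpoints()].
#' @param treatments Optional treatment id universe.
#' @return Numeric matrix, treatments x finding types, plus a
#'   `grade:weighted` aggregate column across finding types.
#' @export
weighted_pathology_score <- function(findings, treatments = NULL) {
  bad <- !findings$grade %in% PATHOLOGY_GRADES
  if (any(bad)) stop("unknown grade label")
  if (any(findings$n_animals < 0)) stop("animal counts must be >= 0")
  if (is.null(treatments))
    treatments <- sort(unique(findings$treatment_id))
  types <- sort(unique(findings$finding_type))
  type_cols <- if (length(types)) paste0(types, ":weighted") else character(0)
  out <- matrix(0, length(treatments), length(types) + 1L,
                dimnames = list(treatments, c(type_cols, "grade:weighted")))
  if (nrow(findings) == 0L) return(out)
  w <- GRADE_WEIGHTS[findings$grade] * findings$n_animals
  for (r in seq_len(nrow(findings))) {
    tr <- as.character(findings$treatment_id[r])
    if (!tr %in% rownames(out)) next
    col <- paste0(findings$finding_type[r], ":weighted")
    out[tr, col] <- out[tr, col] + w[r]
    out[tr, "grade:weighted"] <- out[tr, "grade:weighted"] + w[r]
  }
  out
}

#' Dichotomize endpoint scores into binary labels
#'
#' Labels are `value >= cutoff`. Default cutoffs follow the published
#' rules: 3 for `present` and `minimal` grade endpoints, 2 for
#' `slight`/`moderate`/`severe`, and 3 for weighted-score endpoints.
#' Endpoints with fewer than `min_positive` positive treatments are
#' dropped (and logged).
#'
#' @param table Numeric matrix, treatments x endpoints.
#' @param cutoffs Named numeric vector of per-endpoint cutoffs;
#'   unnamed endpoints get the default rule.
#' @param min_positive Minimum positive treatments to retain an
#'   endpoint (default 10).
#' @return List with `labels` (logical matrix over retained endpoints),
#'   `cutoffs` used, and `dropped` endpoint names.
#' @export
dichotomize_endpoints <- function(table, cutoffs = NULL, min_positive = 10) {
  stopifnot(is.matrix(table))
  default_cut <- function(ep) {
    grade <- sub("^.*:", "", ep)
    if (grade %in% c("present", "minimal")) 3
    else if (grade %in% c("slight", "moderate", "severe")) 2
    else 3  # weighted and other aggregate endpoints
  }
  cut_used <- vapply(colnames(table), function(ep) {
    if (!is.null(cutoffs) && ep %in% names(cutoffs)) cutoffs[[ep]]
    else default_cut(ep)
  }, numeric(1))
  labels <- sweep(table, 2L, cut_used, ">=")
  npos <- colSums(labels)
  keep <- npos >= min_positive
  if (any(!keep))
    ptgs_log("dichotomize: dropped ", sum(!keep),
             " endpoint(s) below ", min_positive, " positives")
  list(labels = labels[, keep, drop = FALSE],
       cutoffs = cut_used,
       dropped = colnames(table)[!keep])
}

#' Endpoint-wise AUC with Wilcoxon significance
#'
#' Mann-Whitney AUC (midrank tie correction) of the score against each
#' endpoint's labels, with the two-tailed Wilcoxon rank-sum p-value and
#' Benjamini-Hochberg q across endpoints. One-class endpoints are
#' skipped.
#'
#' @param scores Numeric score per treatment.
#' @param labels Logical matrix, treatments x endpoints.
#' @return Data frame: `endpoint`, `n_positive`, `auc`, `p`, `q`.
#' @export
endpoint_auc <- function(scores, labels) {
  stopifnot(length(scores) == nrow(labels))
  res <- lapply(colnames(labels), function(ep) {
    l <- labels[, ep]
    if (length(unique(l)) < 2L) return(NULL)
    a <- auc_mw(scores, l)
    p <- suppressWarnings(
      wilcox.test(scores[l], scores[!l], alternative = "two.sided")$p.value)
    data.frame(endpoint = ep, n_positive = sum(l), auc = a, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(endpoint = character(), n_positive = integer(),
                      auc = numeric(), p = numeric(), q = numeric()))
  res$q <- p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

# Balanced cross-validation folds guaranteeing both classes per fold
# where feasible; refolds with a fresh shuffle when a fold is
# degenerate.
#' @noRd
cv_folds <- function(y, k) {
  for (try in 1:25) {
    f <- sample(rep_len(seq_len(k), length(y)))
    ok <- all(vapply(seq_len(k), function(i) {
      length(unique(y[f == i])) == 2L
    }, logical(1)))
    if (ok) return(f)
    ptgs_log("degenerate fold; reshuffling")
  }
  stop("cannot build folds with both classes present")
}

# Penalized score test of one component (lassoscore-style
# reconstruction): the elastic-net fit without component j, at the
# cross-validated penalty, chooses the adjustment set; that set is then
# refitted without penalty so the score equations hold exactly, and the
# classical GLM score statistic of adding x_j is computed against it.
#' @noRd
penalized_score_test <- function(x, y, lambda, alpha_mix) {
  K <- ncol(x)
  p_vals <- numeric(K)
  for (j in seq_len(K)) {
    fit_j <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha_mix,
                            lambda = lambda, exclude = j)
    active <- setdiff(which(abs(drop(coef(fit_j, s = lambda))[-1]) > 0), j)
    Xa <- cbind(`(Intercept)` = 1, x[, active, drop = FALSE])
    refit <- suppressWarnings(
      glm.fit(Xa, y, family = binomial(), control = list(maxit = 50)))
    mu <- refit$fitted.values
    w <- pmax(mu * (1 - mu), 1e-10)
    xj <- x[, j]
    U <- sum(xj * (y - mu))
    XtWX <- crossprod(Xa, w * Xa)
    XtWx <- crossprod(Xa, w * xj)
    V <- sum(w * xj^2) -
      drop(crossprod(XtWx, solve(XtWX + diag(1e-8, ncol(Xa)), XtWx)))
    z <- if (V > 1e-12) U / sqrt(V) else 0
    p_vals[j] <- 2 * pnorm(-abs(z))
  }
  setNames(p_vals, colnames(x))
}

# Adaptive two-step (TST) Benjamini-Hochberg within one group at level q.
#' @noRd
tst_bh <- function(p, q) {
  m <- length(p)
  q1 <- q / (1 + q)
  r1 <- sum(p.adjust(p, "BH") <= q1)
  m0 <- max(m - r1, 1L)
  p.adjust(p, "BH") * m0 / m <= q
}

#' Select DILI-predictive components from pathology endpoints
#'
#' Per endpoint, fits an elastic-net regularized logistic model of the
#' dichotomized endpoint on the component probabilities (penalty weight
#' by repeated cross-validated deviance), computes per-component
#' penalized score-test p-values at that penalty, and applies a nested
#' grouped multiplicity adjustment (group screening by BH on per-
#' endpoint Simes p-values, then adaptive two-step BH within surviving
#' endpoint groups). A component is selected when its within-group q
#' passes `q_cut` in an endpoint whose overall model significance
#' (BH-adjusted Wilcoxon p of the fitted score) also passes `q_cut`.
#'
#' @param theta Matrix, treatments x components (mixture probabilities).
#' @param labels Logical matrix, treatments x endpoints.
#' @param cv_repeats Cross-validation repeats (default 10).
#' @param folds Folds per repeat (default 3).
#' @param alpha_mix Elastic-net mixing parameter (default 0.5; 1 =
#'   lasso).
#' @param q_cut Dual significance threshold (default 0.05).
#' @param seed Seed for fold assignment.
#' @return List with `selected` (component ids), `per_endpoint`
#'   (data frame of component/endpoint statistics), and `model_q`
#'   (per-endpoint model significance).
#' @export
select_predictive_components <- function(theta, labels, cv_repeats = 10,
                                         folds = 3, alpha_mix = 0.5,
                                         q_cut = 0.05, seed = 1) {
  stopifnot(is.matrix(theta), is.matrix(labels),
            nrow(theta) == nrow(labels))
  usable <- colnames(labels)[apply(labels, 2L, function(l)
    length(unique(l)) == 2L)]
  if (length(usable) < 2L) stop("need >= 2 endpoints with both classes")
  set.seed(as.integer(seed))
  comp_p <- matrix(NA_real_, length(usable), ncol(theta),
                   dimnames = list(usable, colnames(theta)))
  model_p <- setNames(numeric(length(usable)), usable)
  for (ep in usable) {
    y <- as.numeric(labels[, ep])
    lam <- numeric(cv_repeats)
    for (r in seq_len(cv_repeats)) {
      fid <- cv_folds(y, folds)
      cv <- glmnet::cv.glmnet(theta, y, family = "binomial",
                              alpha = alpha_mix, foldid = fid,
                              type.measure = "deviance")
      lam[r] <- cv$lambda.min
    }
    lambda <- median(lam)
    comp_p[ep, ] <- penalized_score_test(theta, y, lambda, alpha_mix)
    fit <- glmnet::glmnet(theta, y, family = "binomial", alpha = alpha_mix,
                          lambda = lambda)
    sc <- drop(predict(fit, newx = theta, s = lambda))
    model_p[ep] <- if (length(unique(sc)) == 1L) 1 else
      suppressWarnings(wilcox.test(sc[y == 1], sc[y == 0])$p.value)
  }
  model_q <- p.adjust(model_p, method = "BH")

  # nested adjustment: screen endpoint groups by BH on Simes p, then
  # adaptive two-step BH within surviving groups
  simes <- apply(comp_p, 1L, function(p) {
    p <- sort(p)
    min(length(p) * p / seq_along(p))
  })
  group_pass <- p.adjust(simes, "BH") <= q_cut
  R <- sum(group_pass)
  sel_mat <- matrix(FALSE, length(usable), ncol(theta),
                    dimnames = dimnames(comp_p))
  if (R > 0) {
    q_within <- q_cut * R / length(usable)
    for (ep in usable[group_pass])
      sel_mat[ep, ] <- tst_bh(comp_p[ep, ], q_within)
  }
  ok_model <- model_q < q_cut
  selected <- colnames(theta)[colSums(sel_mat[ok_model, , drop = FALSE]) > 0]
  per_endpoint <- data.frame(
    endpoint = rep(usable, each = ncol(theta)),
    component = rep(colnames(theta), times = length(usable)),
    p = as.vector(t(comp_p)),
    selected = as.vector(t(sel_mat)),
    stringsAsFactors = FALSE
  )
  list(selected = selected, per_endpoint = per_endpoint,
       model_p = model_p, model_q = model_q)
}

#' Component-based DILI score
#'
#' Sum of the selected (DILI-predictive) component probabilities per
#' treatment; lies in `[0, 1]`.
#'
#' @param theta Matrix, treatments x components.
#' @param selected Component ids entering the score.
#' @return Named numeric vector of scores.
#' @export
component_dili_score <- function(theta, selected) {
  stopifnot(all(selected %in% colnames(theta)))
  rowSums(theta[, selected, drop = FALSE])
}

#' DILI decision threshold from pathology prevalence
#'
#' The smallest score t such that, among treatments scoring strictly
#' above t, the fraction with positive pathology reaches `level`
#' (default 50%, roughly a two-fold enrichment over a balanced
#' baseline).
#'
#' @param scores Numeric scores per treatment.
#' @param pathology_labels Logical labels per treatment.
#' @param level Target prevalence (default 0.5).
#' @return List with `threshold` and the prevalence curve.
#' @export
dili_threshold_from_prevalence <- function(scores, pathology_labels,
                                           level = 0.5) {
  cal <- calibrate_score_threshold(scores, pathology_labels,
                                   target_positive_fraction = level)
  list(threshold = cal$threshold, cutoffs = cal$cutoffs,
       prevalence = cal$positive_fraction)
}
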