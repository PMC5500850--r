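# Latent Dirichlet allocation over activation counts. Each component is
# a distribution over signed gene-set features (phi) and each instance a
# mixture over components (theta). Inference is collapsed Gibbs sampling
# with random-walk Metropolis updates of the symmetric Dirichlet
# concentration hyperparameters under gamma hyperpriors.

#' @noRd
new_ptgs_model <- function(theta, phi, alpha, beta, feature_vocabulary,
                           instance_ids, hyper_shape, hyper_rate, seed,
                           n_sweeps, burn_in, log_joint = NULL) {
  structure(list(
    K = nrow(phi), theta = theta, phi = phi, alpha = alpha, beta = beta,
    feature_vocabulary = feature_vocabulary, instance_ids = instance_ids,
    hyper_shape = hyper_shape, hyper_rate = hyper_rate, seed = seed,
    n_sweeps = n_sweeps, burn_in = burn_in, log_joint = log_joint
  ), class = "ptgs_model")
}

#' Fit the component model by collapsed Gibbs sampling
#'
#' Posterior means of the instance-mixture (`theta`) and
#' component-emission (`phi`) distributions are accumulated over
#' post-burn-in sweeps (thinned). Hyperparameters `alpha` and `beta` are
#' updated every sweep by a log-normal random-walk Metropolis step
#' against `Gamma(hyper_shape, hyper_rate)` hyperpriors. The collapsed
#' log joint probability is recorded per sweep.
#'
#' Instances with all-zero counts carry no tokens; their `theta` row is
#' the uniform prior mean.
#'
#' @param counts Integer matrix, instances x signed features.
#' @param K Number of components (>= 1).
#' @param n_sweeps Total Gibbs sweeps.
#' @param burn_in Sweeps discarded before accumulating posterior means.
#' @param thin Thinning interval for posterior-mean accumulation.
#' @param alpha,beta Initial concentration hyperparameters.
#' @param update_hyper Update hyperparameters by Metropolis sampling.
#' @param hyper_shape,hyper_rate Gamma hyperprior parameters.
#' @param mh_step Log-normal random-walk proposal step.
#' @param seed Integer seed; the sampler is bit-reproducible given it.
#' @return A `ptgs_model`.
#' @export
fit_components <- function(counts, K, n_sweeps = 2000, burn_in = 1000,
                           thin = 10, alpha = 1, beta = 0.1,
                           update_hyper = TRUE, hyper_shape = 1,
                           hyper_rate = 1, mh_step = 0.1, seed = 1) {
  stopifnot(is.matrix(counts), K >= 1, n_sweeps > burn_in, burn_in >= 0)
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stop("activation counts must be non-negative")
  if (sum(counts) == 0) stop("activation count matrix is empty")
  empty <- rowSums(counts) == 0L
  if (any(empty))
    ptgs_log("fit_components: ", sum(empty),
             " all-zero instance(s) kept with uniform theta")
  set.seed(as.integer(seed))
  fit <- .lda_gibbs_cpp(counts, as.integer(K), as.integer(n_sweeps),
                        as.integer(burn_in), as.integer(thin),
                        alpha, beta, isTRUE(update_hyper),
                        hyper_shape, hyper_rate, mh_step)
  theta <- fit$theta
  phi <- fit$phi
  dimnames(theta) <- list(rownames(counts), paste0("C", seq_len(K)))
  dimnames(phi) <- list(paste0("C", seq_len(K)), colnames(counts))
  new_ptgs_model(theta = theta, phi = phi, alpha = fit$alpha,
                 beta = fit$beta, feature_vocabulary = colnames(counts),
                 instance_ids = rownames(counts),
                 hyper_shape = hyper_shape, hyper_rate = hyper_rate,
                 seed = as.integer(seed), n_sweeps = n_sweeps,
                 burn_in = burn_in, log_joint = fit$log_joint)
}

#' Component-instance probabilities
#'
#' Returns both directions of the component/instance association:
#' `p_z_given_i` is the fitted mixture `theta`; `p_i_given_z` inverts it
#' with a uniform prior over the designated training instances (or a
#' token-count-weighted prior), normalized so each component's row sums
#' to one over the training subset.
#'
#' @param model A `ptgs_model`.
#' @param training_subset Instance ids to normalize over.
#' @param instance_prior `"uniform"` (default) or `"tokens"`; the latter
#'   weights instances by their total activation counts and requires
#'   `counts`.
#' @param counts Activation-count matrix, needed for `"tokens"`.
#' @return List with `p_z_given_i` (instances x K) and `p_i_given_z`
#'   (K x training instances).
#' @export
component_instance_probabilities <- function(model, training_subset,
                                             instance_prior = c("uniform", "tokens"),
                                             counts = NULL) {
  stopifnot(inherits(model, "ptgs_model"))
  instance_prior <- match.arg(instance_prior)
  if (length(training_subset) == 0L) stop("training subset is empty")
  missing <- setdiff(training_subset, model$instance_ids)
  if (length(missing))
    stop("unknown training instance(s): ", paste(head(missing, 5), collapse = ", "))
  th <- model$theta[training_subset, , drop = FALSE]
  w <- rep(1, nrow(th))
  if (instance_prior == "tokens") {
    if (is.null(counts)) stop("token prior requires the count matrix")
    w <- rowSums(counts[training_subset, , drop = FALSE])
  }
  unnorm <- t(th * w)  # K x instances
  p_i_given_z <- unnorm / rowSums(unnorm)
  list(p_z_given_i = model$theta, p_i_given_z = p_i_given_z)
}

#' Choose the component count by annotation retrieval
#'
#' For each candidate K the model is fitted, each compound represented
#' by the mean `theta` of its instances, compound pairs ranked by cosine
#' similarity, and the AUC of retrieving annotation-sharing pairs
#' computed. The K maximizing retrieval AUC is returned.
#'
#' @param counts Activation-count matrix, instances x features.
#' @param candidate_Ks Integer vector of K values to try.
#' @param compound_of Named character: compound id per instance id.
#' @param annotations Data frame with `compound_id` and `annotation`
#'   columns (a compound may carry several).
#' @param seed Seed forwarded to each fit.
#' @param ... Further arguments to [fit_components()].
#' @return List with `K` (chosen), `retrieval_auc` (named by K) and
#'   `fits` (the fitted models).
#' @export
choose_component_count <- function(counts, candidate_Ks, compound_of,
                                   annotations, seed = 1, ...) {
  stopifnot(length(candidate_Ks) >= 1)
  ann_sets <- split(annotations$annotation, annotations$compound_id)
  compounds <- intersect(unique(compound_of), names(ann_sets))
  if (length(compounds) < 2L) stop("need >= 2 annotated compounds")
  pairs <- t(combn(compounds, 2))
  shares <- mapply(function(a, b) {
    length(intersect(ann_sets[[a]], ann_sets[[b]])) > 0
  }, pairs[, 1], pairs[, 2])
  if (!any(shares)) stop("no compound pair shares an annotation")
  if (all(shares)) stop("all compound pairs share annotations; retrieval undefined")

  aucs <- setNames(numeric(length(candidate_Ks)), candidate_Ks)
  fits <- list()
  for (i in seq_along(candidate_Ks)) {
    K <- candidate_Ks[i]
    fit <- fit_components(counts, K = K, seed = seed, ...)
    fits[[as.character(K)]] <- fit
    cm <- rowsum(fit$theta[names(compound_of), , drop = FALSE],
                 group = compound_of)
    cm <- cm / rowSums(cm)
    cm <- cm[compounds, , drop = FALSE]
    sim <- cosine_rows(cm, cm)
    simv <- sim[cbind(match(pairs[, 1], compounds), match(pairs[, 2], compounds))]
    aucs[i] <- auc_mw(simv, shares)
  }
  list(K = candidate_Ks[which.max(aucs)], retrieval_auc = aucs, fits = fits)
}
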