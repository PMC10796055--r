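#' Summary features used for inference
#'
#' The model comparison feeds the classifier the repetition, adjacency and
#' distance indices, the Shape statistic, and turning points restricted to
#' the central region (the centre is where the measure is most diagnostic,
#' so the global turning-point rate is replaced by the central one). Shape
#' is dropped on two-dimensional domains where it is undefined.
#'
#' @param domain an \code{rg_domain}.
#' @return character vector of feature names.
#' @export
abc_features <- function(domain) {
  f <- c("repetitions", "adjacencies", "central_turning_points",
         "distances", "shape")
  if (domain$dim == 2L) setdiff(f, "shape") else f
}

#' Simulate a reference table
#'
#' Draws parameters from each model's prior, generates a response sequence,
#' and records its summary features, \code{n_per_model} times per model.
#' Rows with an undefined feature (a degenerate sequence too short or too
#' frozen to define a statistic) are resimulated so the table is complete.
#' The schema model is excluded, with a warning, on two-dimensional domains
#' where it cannot sample.
#'
#' @param models character vector of model ids (subset of \code{MODELS}).
#' @param domain the target \code{rg_domain}.
#' @param n_per_model simulated sequences per model (>= 100 for inference;
#'   smaller values are allowed for toys).
#' @param length emitted responses per sequence (400 in the model
#'   comparison).
#' @param seed integer seed; the table is reproducible given it.
#' @return an \code{rg_reftable}: data frame of model labels and features,
#'   plus the parameter draws and simulation metadata.
#' @export
simulate_reference_table <- function(models, domain, n_per_model,
                                     length = 400L, seed = 1L) {
  if (domain$dim == 2L && "schema" %in% models) {
    warning("schema model excluded: it cannot sample on 2-D domains")
    models <- setdiff(models, "schema")
  }
  set.seed(seed)
  feats <- abc_features(domain)
  rows <- vector("list", length(models) * n_per_model)
  params <- vector("list", length(models) * n_per_model)
  k <- 0L
  for (m in models) {
    for (i in seq_len(n_per_model)) {
      repeat {
        pp <- draw_params_from_prior(m, domain)
        s <- generate_sequence(m, domain, length = length, params = pp)
        sv <- summarize_sequence(s)[feats]
        if (!anyNA(sv)) break
      }
      k <- k + 1L
      rows[[k]] <- sv
      params[[k]] <- pp
    }
  }
  tab <- as.data.frame(do.call(rbind, rows))
  tab$model <- factor(rep(models, each = n_per_model), levels = models)
  structure(list(table = tab, features = feats, params = params,
                 domain = domain, n_per_model = n_per_model,
                 length = length, seed = seed),
            class = "rg_reftable")
}

#' @export
print.rg_reftable <- function(x, ...) {
  cat("<rg_reftable>", nrow(x$table), "rows,",
      nlevels(x$table$model), "models on", x$domain$family, "\n")
  invisible(x)
}

#' Train the model-choice forest
#'
#' Fits a random-forest classifier (500 trees) that assigns a summary vector
#' to the candidate model most likely to have generated it, and reports its
#' out-of-bag error.
#'
#' @param reftable an \code{rg_reftable} (at least two models).
#' @param num_trees trees in the forest.
#' @param seed forest seed (fixed so retraining is deterministic).
#' @return an \code{rg_classifier} wrapping the \pkg{ranger} forest.
#' @export
train_classifier <- function(reftable, num_trees = 500L, seed = 1L) {
  tab <- reftable$table
  if (nlevels(droplevels(tab$model)) < 2)
    stop("need at least two models in the reference table", call. = FALSE)
  fit <- ranger::ranger(model ~ ., data = tab, num.trees = num_trees,
                        seed = seed, num.threads = 1)
  structure(list(forest = fit, features = reftable$features,
                 models = levels(tab$model), oob_error = fit$prediction.error,
                 seed = seed),
            class = "rg_classifier")
}

#' Classify summary vectors
#'
#' @param classifier an \code{rg_classifier}.
#' @param newdata data frame (or named vector) of summary features.
#' @return factor of predicted model labels.
#' @export
classify <- function(classifier, newdata) {
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  stats::predict(classifier$forest, data = newdata,
                 num.threads = 1)$predictions
}

# Classification + error-regression forests for one candidate set, cached
# by model set so recursive posteriors over many sequences reuse them.
fit_stage <- function(tab, features, num_trees, seed) {
  fit <- ranger::ranger(model ~ ., data = tab, num.trees = num_trees,
                        seed = seed, num.threads = 1)
  oob <- fit$predictions
  err <- tab
  err$model <- NULL
  err$misclassified <- as.numeric(oob != tab$model)
  efit <- ranger::ranger(misclassified ~ ., data = err, num.trees = num_trees,
                         seed = seed, num.threads = 1)
  list(class_forest = fit, err_forest = efit)
}

#' Posterior model probabilities for one sequence
#'
#' Recursive random-forest ABC. At each stage a classification forest over
#' the remaining candidate models picks the best model for the query, and a
#' regression forest -- trained on the classifier's own out-of-bag
#' misclassification indicator -- estimates the probability \eqn{e_k} that
#' this label is wrong for the query. The best model receives a share
#' \eqn{1 - e_k} of the probability mass still unassigned, the mass
#' \eqn{e_k} recurses to the reduced candidate set, and the last remaining
#' model absorbs whatever is left, so the posterior sums to one. With two
#' candidates this reduces to the published ABC-RF posterior \eqn{(1-e, e)}.
#'
#' @param summary named summary vector (complete in the table's features).
#' @param reftable an \code{rg_reftable}.
#' @param num_trees trees per forest.
#' @param seed forest seed.
#' @param cache optional environment; forests are cached per candidate
#'   subset, so batches of sequences reuse them.
#' @return an \code{rg_posterior}: named probabilities (summing to 1),
#'   elimination order, and per-stage error estimates.
#' @export
posterior_for_sequence <- function(summary, reftable, num_trees = 500L,
                                   seed = 1L, cache = NULL) {
  feats <- reftable$features
  if (anyNA(summary[feats]))
    stop("summary vector is incomplete for features: ",
         paste(feats[is.na(summary[feats])], collapse = ", "), call. = FALSE)
  query <- as.data.frame(as.list(summary[feats]))
  tab <- reftable$table
  models <- levels(tab$model)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())

  post <- stats::setNames(numeric(length(models)), models)
  remaining_models <- models
  remaining_mass <- 1
  order_out <- character(0)
  errs <- numeric(0)

  while (length(remaining_models) > 1L) {
    key <- paste(sort(remaining_models), collapse = "|")
    if (is.null(cache[[key]])) {
      sub <- droplevels(tab[tab$model %in% remaining_models, ])
      cache[[key]] <- fit_stage(sub, feats, num_trees, seed)
    }
    stage <- cache[[key]]
    best <- as.character(stats::predict(stage$class_forest, data = query,
                                        num.threads = 1)$predictions)
    e <- stats::predict(stage$err_forest, data = query,
                        num.threads = 1)$predictions
    e <- min(max(e, 0), 1)
    post[best] <- remaining_mass * (1 - e)
    remaining_mass <- remaining_mass * e
    order_out <- c(order_out, best)
    errs <- c(errs, e)
    remaining_models <- setdiff(remaining_models, best)
  }
  post[remaining_models] <- remaining_mass
  structure(list(posterior = post, elimination_order = order_out,
                 stage_errors = errs),
            class = "rg_posterior")
}

#' @export
print.rg_posterior <- function(x, ...) {
  cat("<rg_posterior>\n")
  print(round(x$posterior, 4))
  invisible(x)
}

#' Combine posteriors across conditions
#'
#' Elementwise product of per-condition posterior probabilities over the
#' same model set, renormalised -- the joint evidence when the same
#' generator is assumed to underlie every condition.
#'
#' @param ... \code{rg_posterior} objects (or named probability vectors),
#'   or a single list of them.
#' @return an \code{rg_posterior} with the combined probabilities.
#' @export
combine_posteriors <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) &&
      !inherits(args[[1]], "rg_posterior")) args <- args[[1]]
  vecs <- lapply(args, function(p)
    if (inherits(p, "rg_posterior")) p$posterior else p)
  models <- names(vecs[[1]])
  for (v in vecs[-1])
    if (!setequal(names(v), models))
      stop("posteriors cover different model sets", call. = FALSE)
  prod <- Reduce(`*`, lapply(vecs, function(v) v[models]))
  structure(list(posterior = prod / sum(prod),
                 elimination_order = character(0), stage_errors = numeric(0)),
            class = "rg_posterior")
}

bf_ratio <- function(num, den) {
  if (den == 0) return(Inf)
  num / den
}

#' Class-level Bayes factor by model averaging
#'
#' The ratio of the average posterior probability over one class of models
#' to that over another (Bayesian model averaging with uniform model priors
#' within class).
#'
#' @param posterior an \code{rg_posterior} or named probability vector.
#' @param class_a,class_b disjoint, non-empty model sets.
#' @return the Bayes factor for class A over class B (\code{Inf} when class
#'   B has zero mass).
#' @export
class_bayes_factor <- function(posterior, class_a, class_b) {
  p <- if (inherits(posterior, "rg_posterior")) posterior$posterior else posterior
  if (length(class_a) == 0 || length(class_b) == 0 ||
      length(intersect(class_a, class_b)) > 0)
    stop("classes must be disjoint and non-empty", call. = FALSE)
  bf_ratio(mean(p[class_a]), mean(p[class_b]))
}

#' Feature-level Bayes factors for local samplers
#'
#' Compares models matched in every qualitative feature but the one of
#' interest: multiple chains contrasts \{MC3, MCHMC, MCREC\} with
#' \{MH, HMC, REC\}; gradient-based proposals contrasts \{HMC, MCHMC\} with
#' \{MH, MC3\} (the recycled-momentum models are excluded because no model
#' recycles momentum without gradient-based proposals); recycled momentum
#' contrasts \{REC, MCREC\} with \{HMC, MCHMC\}.
#'
#' @param posterior an \code{rg_posterior} or named probability vector.
#' @param feature \code{"multiple_chains"}, \code{"gradient"}, or
#'   \code{"recycled"}.
#' @return Bayes factor for models with the feature over matched models
#'   without it.
#' @export
feature_bayes_factor <- function(posterior,
                                 feature = c("multiple_chains", "gradient",
                                             "recycled")) {
  feature <- match.arg(feature)
  sets <- switch(feature,
    multiple_chains = list(a = c("MC3", "MCHMC", "MCREC"),
                           b = c("MH", "HMC", "REC")),
    gradient = list(a = c("HMC", "MCHMC"), b = c("MH", "MC3")),
    recycled = list(a = c("REC", "MCREC"), b = c("HMC", "MCHMC")))
  class_bayes_factor(posterior, sets$a, sets$b)
}

#' Model-recovery experiment
#'
#' Trains the classifier on a fresh reference table, classifies held-out
#' simulations of known origin, and reports the confusion matrix, per-model
#' correct-classification rates, and the class-level rate for the local
#' samplers (a local-sampling sequence classified as any local sampler
#' counts as correct).
#'
#' @param models candidate model ids.
#' @param domain the target \code{rg_domain}.
#' @param n_train training simulations per model.
#' @param n_test held-out simulations per model.
#' @param length responses per sequence.
#' @param seed integer seed for both tables and the forest.
#' @param num_trees trees in the classification forest.
#' @return an \code{rg_recovery}: confusion matrix (rows sum to 1),
#'   per-model accuracy, local-class accuracy, and the forest's out-of-bag
#'   (prior) error rate.
#' @export
model_recovery <- function(models, domain, n_train, n_test, length = 400L,
                           seed = 1L, num_trees = 500L) {
  train <- simulate_reference_table(models, domain, n_train, length,
                                    seed = seed)
  test <- simulate_reference_table(models, domain, n_test, length,
                                   seed = seed + 1L)
  cls <- train_classifier(train, num_trees = num_trees, seed = seed)
  pred <- classify(cls, test$table[, cls$features])
  truth <- test$table$model
  confusion <- prop.table(table(truth = truth, predicted = pred), margin = 1)
  acc <- diag(as.matrix(confusion))
  local <- intersect(levels(truth), LOCAL_MODELS)
  local_rate <- if (length(local) > 0)
    mean(pred[truth %in% local] %in% LOCAL_MODELS) else NA_real_
  structure(list(confusion = confusion, accuracy = acc,
                 local_class_rate = local_rate,
                 prior_error_rate = cls$oob_error,
                 n_train = n_train, n_test = n_test),
            class = "rg_recovery")
}

#' @export
print.rg_recovery <- function(x, ...) {
  cat("<rg_recovery> per-model accuracy:\n")
  print(round(x$accuracy, 3))
  cat("local-class rate:", round(x$local_class_rate, 3),
      "| OOB error:", round(x$prior_error_rate, 3), "\n")
  invisible(x)
}
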