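#' Feature-level fusion (IMIM-F)
#'
#' Solves the weighting program on the concatenated all-modality table,
#' removes features whose weight falls at or below `weight_threshold`,
#' scales the surviving features by their weights, and trains a single
#' classifier on the result. With every weight saturated at 1 this reduces
#' exactly to the concatenation baseline.
#'
#' The training table is expected to be normalized into `[0, 1]` already
#' (see [fit_normalizer()]); [lopo_cv()] takes care of that per fold.
#'
#' @param train A normalized `feature_table` of training samples.
#' @param lam Trade-off constant; `NULL` selects it per model via
#'   [select_lambda()] on `lambda_candidates`.
#' @param classifier A [knn_spec()] or [svm_spec()].
#' @param config An [mi_config()].
#' @param weight_threshold Pruning threshold for "invalid" features.
#' @param lambda_candidates Grid used when `lam` is `NULL`.
#' @return A `fusion_model` of mode `"imim_f"`.
#' @export
imim_f <- function(train, lam = NULL, classifier = knn_spec(3),
                   config = model_config(), weight_threshold = 1e-6,
                   lambda_candidates = lambda_grid(10)) {
  train <- as_feature_table(train)
  sel <- NULL
  if (is.null(lam)) {
    sel <- select_lambda(train, lambda_candidates, classifier = classifier,
                         config = config,
                         weight_threshold = weight_threshold)
    lam <- sel$lambda
  }
  model <- build_mi_model(train, config = config)
  sol <- solve_weights(model, lam, weight_threshold = weight_threshold)
  keep <- sol$active_idx
  if (length(keep) == 0L) {
    rlang::abort("all feature weights are zero; try a larger `lam`")
  }
  x <- ft_matrix(train)[, keep, drop = FALSE]
  x <- sweep(x, 2, sol$w[keep], "*")
  structure(
    list(
      mode = "imim_f",
      model = model, solution = sol, lambda_selection = sel,
      kept = keep,
      classifier = fit_classifier(classifier, x, train$label),
      feature_names = ft_feature_names(train),
      classes = levels(droplevels(train$label))
    ),
    class = "fusion_model"
  )
}

#' Classifier-level fusion (IMIM-C)
#'
#' Four steps: (1) per modality, solve the weighting program to obtain the
#' feature weights `w(q)` and the classifier weight `beta_q` (the attained
#' objective); (2) scale each modality's features by `w(q)` — features are
#' scaled, not pruned, at this level; (3) train one classifier per modality
#' on the scaled features; (4) predict by the beta-weighted average of the
#' per-modality class scores, with the betas clipped at zero and normalized
#' to sum to one so the average is scale-free.
#'
#' @inheritParams imim_f
#' @param lam Single value applied to every modality, a named vector/list of
#'   per-modality values, or `NULL` for per-modality selection.
#' @return A `fusion_model` of mode `"imim_c"`.
#' @export
imim_c <- function(train, lam = NULL, classifier = knn_spec(3),
                   config = model_config(), weight_threshold = 1e-6,
                   lambda_candidates = lambda_grid(10)) {
  train <- as_feature_table(train)
  blocks <- ft_split_modalities(train)
  if (length(blocks) < 2L) {
    rlang::warn("single modality: classifier-level fusion reduces to that modality's classifier")
  }
  experts <- purrr::imap(blocks, function(blk, tag) {
    lam_q <- if (is.null(lam)) {
      select_lambda(blk, lambda_candidates, classifier = classifier,
                    config = config,
                    weight_threshold = weight_threshold)$lambda
    } else if (length(lam) > 1L) {
      lam[[tag]]
    } else {
      lam
    }
    model <- build_mi_model(blk, config = config)
    sol <- solve_weights(model, lam_q, weight_threshold = weight_threshold)
    x <- sweep(ft_matrix(blk), 2, sol$w, "*")
    list(
      modality = tag, model = model, solution = sol,
      beta_raw = classifier_weight(model, sol),
      classifier = fit_classifier(classifier, x, blk$label)
    )
  })
  beta <- pmax(0, vapply(experts, `[[`, numeric(1), "beta_raw"))
  if (sum(beta) <= 0) {
    rlang::abort("all classifier weights beta are zero; try a larger `lam`")
  }
  beta <- beta / sum(beta)
  structure(
    list(
      mode = "imim_c",
      experts = experts,
      beta = stats::setNames(beta, names(blocks)),
      feature_names = ft_feature_names(train),
      classes = levels(droplevels(train$label))
    ),
    class = "fusion_model"
  )
}

#' Baseline fusers
#'
#' `fuse_concat()` trains one classifier on the plain concatenated feature
#' table (feature-level baseline); `fuse_average()` trains one classifier
#' per modality and averages their class scores with equal weights
#' (decision-level baseline).
#'
#' @inheritParams imim_f
#' @export
fuse_concat <- function(train, classifier = knn_spec(3)) {
  train <- as_feature_table(train)
  structure(
    list(
      mode = "concat_baseline",
      classifier = fit_classifier(classifier, ft_matrix(train), train$label),
      feature_names = ft_feature_names(train),
      classes = levels(droplevels(train$label))
    ),
    class = "fusion_model"
  )
}

#' @rdname fuse_concat
#' @export
fuse_average <- function(train, classifier = knn_spec(3)) {
  train <- as_feature_table(train)
  blocks <- ft_split_modalities(train)
  if (length(blocks) < 2L) {
    rlang::abort("score-average fusion needs >= 2 modalities")
  }
  experts <- purrr::imap(blocks, function(blk, tag) {
    list(modality = tag,
         classifier = fit_classifier(classifier, ft_matrix(blk), blk$label))
  })
  structure(
    list(
      mode = "average_baseline",
      experts = experts,
      beta = stats::setNames(rep(1 / length(blocks), length(blocks)),
                             names(blocks)),
      feature_names = ft_feature_names(train),
      classes = levels(droplevels(train$label))
    ),
    class = "fusion_model"
  )
}

#' @export
print.fusion_model <- function(x, ...) {
  cat("<fusion_model> mode =", x$mode, "\n")
  if (!is.null(x$beta)) {
    cat("  beta:", paste(sprintf("%s = %.3f", names(x$beta), x$beta),
                         collapse = ", "), "\n")
  }
  if (!is.null(x$solution)) {
    cat("  lambda =", format(x$solution$lam, digits = 4), ", active",
        length(x$kept), "/", length(x$feature_names), "features\n")
  }
  invisible(x)
}

fusion_scores <- function(object, test) {
  test <- as_feature_table(test)
  if (!identical(ft_feature_names(test), object$feature_names)) {
    rlang::abort("feature names of `newdata` do not match the fitted model")
  }
  switch(object$mode,
    imim_f = {
      x <- ft_matrix(test)[, object$kept, drop = FALSE]
      x <- sweep(x, 2, object$solution$w[object$kept], "*")
      score_classifier(object$classifier, x)
    },
    concat_baseline = score_classifier(object$classifier, ft_matrix(test)),
    imim_c = ,
    average_baseline = {
      blocks <- ft_split_modalities(test)
      total <- NULL
      for (ex in object$experts) {
        blk <- blocks[[ex$modality]]
        x <- ft_matrix(blk)
        if (!is.null(ex$solution)) {
          x <- sweep(x, 2, ex$solution$w, "*")
        }
        s <- object$beta[[ex$modality]] * score_classifier(ex$classifier, x)
        total <- if (is.null(total)) s else total + s
      }
      total
    }
  )
}

#' Predict classes and scores from a fusion model
#'
#' @param object A fitted `fusion_model`.
#' @param newdata A `feature_table` with the training feature columns.
#' @param ... Unused.
#' @return A tibble with `.pred_class` and one `.score_<class>` column per
#'   class; score rows sum to 1, and argmax ties break toward the lowest
#'   class index.
#' @export
predict.fusion_model <- function(object, newdata, ...) {
  scores <- fusion_scores(object, newdata)
  # betas sum to one and each expert emits a distribution, so rows already
  # sum to 1 up to float error; renormalize defensively
  scores <- scores / rowSums(scores)
  out <- tibble::as_tibble(scores, .name_repair = "minimal")
  names(out) <- paste0(".score_", object$classes)
  tibble::add_column(
    out,
    .pred_class = score_to_class(scores, object$classes),
    .before = 1
  )
}
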