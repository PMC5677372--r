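#' Select the trade-off constant lambda by cross-validation
#'
#' The dependency/redundancy trade-off has no stable universal value: each
#' feature set carries its own amount of redundancy, so lambda is re-selected
#' per model. For each candidate, the full pipeline (min--max normalization,
#' model build, weight solve, prune-and-scale, classify) is evaluated by
#' leave-one-subject-out cross-validation within `data`, and the candidate
#' with the highest mean accuracy wins; ties break toward the smaller lambda
#' (the sparser solution). The accuracy curve and the mean active-feature
#' count along the grid are returned for inspection.
#'
#' @param data A `feature_table` (raw scale; normalization is refit inside
#'   each inner fold).
#' @param candidate_lams Nonempty positive grid.
#' @param classifier A [knn_spec()] or [svm_spec()].
#' @param config An [mi_config()].
#' @param weight_threshold Pruning threshold.
#' @return A `lambda_selection`: list with `lambda` and a `curve` tibble
#'   (`lambda`, `accuracy`, `n_active`).
#' @export
select_lambda <- function(data, candidate_lams = lambda_grid(10),
                          classifier = knn_spec(3), config = model_config(),
                          weight_threshold = 1e-6) {
  if (length(candidate_lams) == 0L) {
    rlang::abort("`candidate_lams` must be a nonempty grid")
  }
  if (any(candidate_lams <= 0)) {
    rlang::abort("`candidate_lams` must be positive")
  }
  ft <- as_feature_table(data)
  candidate_lams <- sort(candidate_lams)
  if (length(candidate_lams) == 1L) {
    return(structure(
      list(lambda = candidate_lams,
           curve = tibble::tibble(lambda = candidate_lams,
                                  accuracy = NA_real_,
                                  n_active = NA_real_)),
      class = "lambda_selection"
    ))
  }
  subjects <- unique(ft$subject_id)
  acc <- matrix(NA_real_, length(subjects), length(candidate_lams))
  act <- matrix(NA_real_, length(subjects), length(candidate_lams))
  for (s in seq_along(subjects)) {
    test_rows <- ft$subject_id == subjects[s]
    train <- ft_subset_rows(ft, which(!test_rows))
    test <- ft_subset_rows(ft, which(test_rows))
    norm <- fit_normalizer(train)
    train_n <- apply_normalizer(norm, train)
    test_n <- apply_normalizer(norm, test)
    model <- build_mi_model(train_n, config = config)
    x_train <- ft_matrix(train_n)
    x_test <- ft_matrix(test_n)
    for (l in seq_along(candidate_lams)) {
      sol <- solve_weights(model, candidate_lams[l],
                           weight_threshold = weight_threshold)
      keep <- sol$active_idx
      act[s, l] <- length(keep)
      if (length(keep) == 0L) {
        acc[s, l] <- 0
        next
      }
      clf <- fit_classifier(classifier,
                            sweep(x_train[, keep, drop = FALSE], 2,
                                  sol$w[keep], "*"),
                            train_n$label)
      scores <- score_classifier(clf,
                                 sweep(x_test[, keep, drop = FALSE], 2,
                                       sol$w[keep], "*"))
      pred <- score_to_class(scores, clf$classes)
      acc[s, l] <- mean(as.character(pred) == as.character(test_n$label))
    }
  }
  curve <- tibble::tibble(
    lambda = candidate_lams,
    accuracy = colMeans(acc),
    n_active = colMeans(act)
  )
  best <- which(curve$accuracy >= max(curve$accuracy) - 1e-12)[1]
  structure(
    list(lambda = curve$lambda[best], curve = curve),
    class = "lambda_selection"
  )
}

#' @export
print.lambda_selection <- function(x, ...) {
  cat("<lambda_selection> lambda =", format(x$lambda, digits = 4), "\n")
  print(x$curve)
  invisible(x)
}

fit_fusion_mode <- function(mode, train, classifier, lam, config,
                            weight_threshold, lambda_candidates) {
  switch(mode,
    imim_f = imim_f(train, lam = lam, classifier = classifier,
                    config = config, weight_threshold = weight_threshold,
                    lambda_candidates = lambda_candidates),
    imim_c = imim_c(train, lam = lam, classifier = classifier,
                    config = config, weight_threshold = weight_threshold,
                    lambda_candidates = lambda_candidates),
    concat_baseline = fuse_concat(train, classifier = classifier),
    average_baseline = fuse_average(train, classifier = classifier),
    rlang::abort(paste0("unknown fusion mode: ", mode))
  )
}

#' Leave-one-subject-out ("leave-one-proband-out") cross-validation
#'
#' One fold per subject: all samples of the held-out subject form the test
#' set and every training-side statistic — normalization, mutual-information
#' estimation, lambda selection, weights, classifier — is computed on the
#' remaining subjects only. This evaluates subject-independent
#' generalization: with 10 subjects the classification is repeated 10 times
#' and summarized as mean +/- SD over folds.
#'
#' @param data A `feature_table` with samples from >= 2 subjects.
#' @param methods Fusion modes to evaluate, any of `"imim_f"`, `"imim_c"`,
#'   `"concat_baseline"`, `"average_baseline"`.
#' @param classifier A [knn_spec()] or [svm_spec()].
#' @param lam Fixed lambda applied in every fold, or `NULL` for nested
#'   per-fold selection on `lambda_candidates` (leakage-free but slower).
#' @param config An [mi_config()].
#' @param weight_threshold Pruning threshold.
#' @param lambda_candidates Grid for nested selection.
#' @return A `lopo_cv` tibble (`method`, `subject_id`, `accuracy`, `n_test`)
#'   in subject order; `glance()` summarizes to mean/SD per method. The
#'   `"lambda_mode"` attribute records whether lambda was nested or fixed.
#' @export
lopo_cv <- function(data, methods = c("imim_f", "concat_baseline"),
                    classifier = knn_spec(3), lam = NULL,
                    config = model_config(), weight_threshold = 1e-6,
                    lambda_candidates = lambda_grid(10)) {
  ft <- as_feature_table(data)
  subjects <- unique(ft$subject_id)
  if (length(subjects) < 2L) {
    rlang::abort("leave-one-proband-out needs >= 2 subjects")
  }
  rows <- purrr::map(subjects, function(subj) {
    test_rows <- which(ft$subject_id == subj)
    train <- ft_subset_rows(ft, setdiff(seq_len(nrow(ft)), test_rows))
    test <- ft_subset_rows(ft, test_rows)
    norm <- fit_normalizer(train)
    train_n <- apply_normalizer(norm, train)
    test_n <- apply_normalizer(norm, test)
    purrr::map(methods, function(m) {
      fit <- fit_fusion_mode(m, train_n, classifier, lam, config,
                             weight_threshold, lambda_candidates)
      pred <- predict(fit, test_n)
      tibble::tibble(
        method = m, subject_id = subj,
        accuracy = mean(as.character(pred$.pred_class) ==
                          as.character(test_n$label)),
        n_test = nrow(test_n)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  structure(rows,
            lambda_mode = if (is.null(lam)) "nested" else "fixed",
            lam = lam,
            class = c("lopo_cv", class(rows)))
}

#' @method glance lopo_cv
#' @export
glance.lopo_cv <- function(x, ...) {
  dplyr::summarise(
    tibble::as_tibble(x),
    mean_accuracy = mean(.data$accuracy),
    sd_accuracy = stats::sd(.data$accuracy),
    n_folds = dplyr::n(),
    .by = "method"
  )
}

#' Write a cross-validation report
#'
#' Per-fold accuracies as CSV plus a JSON summary (mean, SD, lambda mode).
#'
#' @param cv A [lopo_cv()] result.
#' @param csv_path,json_path Output paths.
#' @export
write_cv_report <- function(cv, csv_path, json_path) {
  utils::write.csv(as.data.frame(cv), csv_path, row.names = FALSE)
  summ <- glance(cv)
  jsonlite::write_json(
    list(
      lambda_mode = attr(cv, "lambda_mode"),
      lambda = attr(cv, "lam"),
      methods = purrr::pmap(summ, function(method, mean_accuracy,
                                           sd_accuracy, n_folds) {
        list(method = method, mean_accuracy = mean_accuracy,
             sd_accuracy = sd_accuracy, n_folds = n_folds)
      })
    ),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(cv)
}
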