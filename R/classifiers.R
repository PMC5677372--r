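#' Classifier specifications
#'
#' Lightweight specs for the two classifiers used throughout: k-nearest
#' neighbours and a soft-margin linear SVM. Both expose the same contract
#' after fitting: `score_classifier()` returns per-class scores in `[0, 1]`
#' that sum to 1 per sample. k-NN scores are neighbour-vote fractions; SVM
#' scores are a softmax over one-vs-rest decision values, so the "score" the
#' fusion layer averages is always a proper distribution over classes.
#'
#' @param k Number of neighbours (typical study values: 1, 3, 5, 10).
#' @return A `classifier_spec`.
#' @export
knn_spec <- function(k = 3L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) rlang::abort("`k` must be a positive integer")
  structure(list(kind = "knn", k = k), class = "classifier_spec")
}

#' @rdname knn_spec
#' @param C Soft-margin cost (typical study values: 1e-1 .. 1e-4).
#' @export
svm_spec <- function(C = 1e-3) {
  if (!is.numeric(C) || length(C) != 1L || C <= 0) {
    rlang::abort("`C` must be a single positive number")
  }
  structure(list(kind = "linear_svm", C = C), class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  if (x$kind == "knn") {
    cat("<classifier_spec> k-NN, k =", x$k, "\n")
  } else {
    cat("<classifier_spec> linear SVM, C =", format(x$C), "\n")
  }
  invisible(x)
}

#' Fit a classifier from a spec
#'
#' @param spec A [knn_spec()] or [svm_spec()].
#' @param x Numeric training matrix (samples x features).
#' @param y Training labels (factor).
#' @return A fitted classifier usable with [score_classifier()].
#' @export
fit_classifier <- function(spec, x, y) {
  if (!inherits(spec, "classifier_spec")) {
    rlang::abort("unknown classifier kind: `spec` must be a classifier_spec")
  }
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  fit <- switch(spec$kind,
    knn = {
      if (spec$k > nrow(x)) {
        rlang::abort("`k` exceeds the number of training samples")
      }
      list(x = x, y = y)
    },
    linear_svm = {
      # one binary machine per class (one-vs-rest); decision values oriented
      # so that positive means "this class"
      machines <- lapply(levels(y), function(lv) {
        yy <- factor(ifelse(y == lv, "target", "rest"),
                     levels = c("target", "rest"))
        m <- e1071::svm(x, yy, kernel = "linear", cost = spec$C,
                        scale = FALSE)
        # libsvm orients the decision value by order of appearance in the
        # training data; fix the sign empirically so positive means "target"
        dv <- attr(stats::predict(m, x, decision.values = TRUE),
                   "decision.values")[, 1]
        sgn <- if (mean(dv[yy == "target"]) >= mean(dv[yy == "rest"])) 1 else -1
        list(model = m, sign = sgn)
      })
      list(machines = machines)
    }
  )
  structure(
    list(spec = spec, fit = fit, classes = levels(y),
         feature_names = colnames(x)),
    class = "fitted_classifier"
  )
}

#' Per-class classification scores
#'
#' @param object A [fit_classifier()] result.
#' @param x Numeric matrix of samples to score.
#' @return Matrix samples x classes; each row is nonnegative and sums to 1.
#' @export
score_classifier <- function(object, x) {
  x <- as.matrix(x)
  k_classes <- length(object$classes)
  scores <- switch(object$spec$kind,
    knn = {
      k <- object$spec$k
      nn <- FNN::get.knnx(object$fit$x, x, k = k)
      idx <- matrix(as.integer(object$fit$y)[nn$nn.index], nrow = nrow(x))
      t(apply(idx, 1, function(row) tabulate(row, nbins = k_classes) / k))
    },
    linear_svm = {
      dv <- vapply(object$fit$machines, function(m) {
        m$sign * attr(stats::predict(m$model, x, decision.values = TRUE),
                      "decision.values")[, 1]
      }, numeric(nrow(x)))
      dv <- matrix(dv, nrow = nrow(x))
      # softmax across the one-vs-rest decision values
      dv <- dv - apply(dv, 1, max)
      ex <- exp(dv)
      ex / rowSums(ex)
    }
  )
  scores <- matrix(scores, nrow = nrow(x))
  colnames(scores) <- object$classes
  scores
}

# argmax with ties broken toward the lowest class index
score_to_class <- function(scores, classes) {
  factor(classes[max.col(scores, ties.method = "first")], levels = classes)
}
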