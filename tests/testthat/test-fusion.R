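test_that("min-max normalization maps, clips and handles constants", {
  tab <- feature_table(cbind(a = c(2, 4, 6), b = c(1, 1, 1)),
                       rep("P1", 3), c("low", "medium", "high"))
  st <- fit_normalizer(tab)
  out <- apply_normalizer(st, tab)
  expect_equal(out$a, c(0, 0.5, 1))
  expect_equal(out$b, c(0, 0, 0)) # constant feature maps to zero
  expect_true(st$constant[["b"]])

  # test values outside the training range clip into [0, 1]
  test <- feature_table(cbind(a = c(8, -1), b = c(5, 5)),
                        rep("P2", 2), c("low", "medium"))
  out2 <- suppressWarnings(apply_normalizer(st, test))
  expect_equal(out2$a, c(1, 0))

  # normalizing an already-normalized [0, 1] column reproduces it
  st2 <- fit_normalizer(out)
  expect_equal(apply_normalizer(st2, out)$a, out$a)

  expect_error(apply_normalizer(list(), tab), "normalizer_state")
  bad <- feature_table(cbind(zz = 1:3), rep("P1", 3),
                       c("low", "medium", "high"))
  expect_error(apply_normalizer(st, bad), "feature names")
})

test_that("classifier adapters honour the score contract", {
  # 3-NN voting 2:1:0 yields vote fractions (2/3, 1/3, 0)
  train_x <- matrix(c(0, 0.1, 0.2, 5, 9), ncol = 1)
  train_y <- factor(c("a", "a", "b", "b", "c"))
  clf <- fit_classifier(knn_spec(3), train_x, train_y)
  sc <- score_classifier(clf, matrix(0.05, 1, 1))
  expect_equal(unname(sc[1, ]), c(2 / 3, 1 / 3, 0))
  expect_equal(sum(sc), 1)

  # 1-NN on the training set itself is perfect
  clf1 <- fit_classifier(knn_spec(1), train_x, train_y)
  sc1 <- score_classifier(clf1, train_x)
  expect_equal(colnames(sc1)[max.col(sc1)], as.character(train_y))

  # linearly separable two-class set: linear SVM fits it perfectly
  withr::with_seed(8, {
    x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 4), 20))
    y <- factor(rep(c("lo", "hi"), each = 20))
  })
  svm <- fit_classifier(svm_spec(1), x, y)
  ssc <- score_classifier(svm, x)
  expect_equal(mean(colnames(ssc)[max.col(ssc)] == y), 1)
  expect_equal(unname(rowSums(ssc)), rep(1, 40), tolerance = 1e-9)

  expect_error(fit_classifier(list(kind = "tree"), x, y), "classifier_spec")
  expect_error(knn_spec(0), "positive")
  expect_error(svm_spec(-1), "positive")
  expect_error(fit_classifier(knn_spec(100), train_x, train_y), "exceeds")
})

test_that("prediction ties break toward the lowest class index", {
  # a test point whose 3 nearest neighbours vote one per class
  train_x <- matrix(c(1, 2, 3, 50), ncol = 1)
  train_y <- factor(c("high", "low", "medium", "low"),
                    levels = c("high", "low", "medium"))
  clf <- fit_classifier(knn_spec(3), train_x, train_y)
  sc <- score_classifier(clf, matrix(2, 1, 1))
  expect_equal(unname(sc[1, ]), rep(1 / 3, 3))
  expect_equal(as.character(score_to_class(sc, clf$classes)), "high")
})

test_that("feature-level fusion reduces to the concatenation baseline when weights saturate", {
  tab <- make_toy_table()
  norm <- fit_normalizer(tab)
  tabn <- apply_normalizer(norm, tab)
  # lambda large enough that every weight hits the box ceiling; the plain
  # plug-in estimator keeps every dependency strictly positive, so the
  # linear term saturates the whole box
  fit_f <- imim_f(tabn, lam = 1e6, classifier = knn_spec(3),
                  config = mi_config())
  expect_equal(unname(fit_f$solution$w), rep(1, 4), tolerance = 1e-6)
  fit_c <- fuse_concat(tabn, classifier = knn_spec(3))
  p1 <- predict(fit_f, tabn)
  p2 <- predict(fit_c, tabn)
  expect_equal(p1$.pred_class, p2$.pred_class)
  expect_equal(p1$.score_high, p2$.score_high)
})

test_that("single-feature weighting equals the bare classifier", {
  tab <- make_toy_table()
  one <- feature_table(cbind(a_inf = tab$a_inf), tab$subject_id, tab$label)
  onen <- apply_normalizer(fit_normalizer(one), one)
  fit <- imim_f(onen, lam = 1e6, classifier = knn_spec(3))
  expect_equal(unname(fit$solution$w), 1, tolerance = 1e-6)
  bare <- fit_classifier(knn_spec(3), ft_matrix(onen), onen$label)
  sc <- score_classifier(bare, ft_matrix(onen))
  expect_equal(predict(fit, onen)$.pred_class,
               score_to_class(sc, bare$classes))
})

test_that("classifier-level fusion weights, reduces and averages correctly", {
  tab <- make_toy_table()
  tabn <- apply_normalizer(fit_normalizer(tab), tab)
  fit <- imim_c(tabn, lam = 1, classifier = knn_spec(3))
  expect_equal(sum(fit$beta), 1)
  expect_true(all(fit$beta >= 0))

  # two modalities holding identical features: fused scores equal either
  dup <- feature_table(cbind(a = tabn$a_inf, b = tabn$a_inf),
                       tabn$subject_id, tabn$label,
                       modality = c("eeg_psd", "ecg"))
  fit_dup <- imim_c(dup, lam = 1, classifier = knn_spec(3))
  expect_equal(unname(fit_dup$beta), c(0.5, 0.5), tolerance = 1e-9)
  solo <- fit_classifier(knn_spec(3), as.matrix(dup$a), dup$label)
  expect_equal(
    unname(as.matrix(predict(fit_dup, dup)[, -1])),
    unname(score_classifier(solo,
                            as.matrix(dup$a * fit_dup$experts[[1]]$solution$w))),
    tolerance = 1e-9
  )

  # degenerate beta = (1, 0): prediction equals the first expert alone
  fit_b <- fit
  fit_b$beta <- c(eeg_psd = 1, ecg = 0)
  x1 <- sweep(ft_matrix(ft_split_modalities(tabn)$eeg_psd), 2,
              fit$experts$eeg_psd$solution$w, "*")
  expect_equal(
    unname(as.matrix(predict(fit_b, tabn)[, -1])),
    unname(score_classifier(fit$experts$eeg_psd$classifier, x1)),
    tolerance = 1e-9
  )

  # hand-set beta and per-class scores: weighted average arithmetic
  fit_h <- fit
  fit_h$beta <- c(eeg_psd = 0.7, ecg = 0.3)
  s1 <- score_classifier(fit$experts$eeg_psd$classifier, x1[1, , drop = FALSE])
  x2 <- sweep(ft_matrix(ft_split_modalities(tabn)$ecg), 2,
              fit$experts$ecg$solution$w, "*")
  s2 <- score_classifier(fit$experts$ecg$classifier, x2[1, , drop = FALSE])
  got <- unname(as.matrix(predict(fit_h, tabn)[1, -1]))
  expect_equal(got, unname(0.7 * s1 + 0.3 * s2), tolerance = 1e-9)

  # single modality reduces (with a warning) to that modality's classifier
  single <- ft_split_modalities(tabn)$eeg_psd
  expect_warning(fit_s <- imim_c(single, lam = 1, classifier = knn_spec(3)),
                 "single modality")
  xs <- sweep(ft_matrix(single), 2, fit_s$experts[[1]]$solution$w, "*")
  expect_equal(
    unname(as.matrix(predict(fit_s, single)[, -1])),
    unname(score_classifier(fit_s$experts[[1]]$classifier, xs)),
    tolerance = 1e-9
  )
})

test_that("score vectors are proper distributions for every fusion mode", {
  tab <- make_toy_table()
  tabn <- apply_normalizer(fit_normalizer(tab), tab)
  fits <- list(
    imim_f(tabn, lam = 1, classifier = knn_spec(3)),
    imim_c(tabn, lam = 1, classifier = knn_spec(3)),
    fuse_concat(tabn, classifier = knn_spec(3)),
    fuse_average(tabn, classifier = knn_spec(3)),
    imim_f(tabn, lam = 1, classifier = svm_spec(1e-1))
  )
  for (fit in fits) {
    sc <- as.matrix(predict(fit, tabn)[, -1])
    expect_equal(unname(rowSums(sc)), rep(1, nrow(sc)), tolerance = 1e-9)
    expect_true(all(sc >= -1e-12))
  }
  bad <- feature_table(matrix(rnorm(nrow(tab) * 2), ncol = 2,
                              dimnames = list(NULL, c("q1", "q2"))),
                       tab$subject_id, tab$label)
  expect_error(predict(fits[[1]], bad), "feature names")
})

test_that("leave-one-proband-out folds are disjoint, exhaustive and leakage-free", {
  tab <- make_toy_table(n_subjects = 4)
  cv <- lopo_cv(tab, methods = "concat_baseline", classifier = knn_spec(3))
  expect_equal(nrow(cv), 4)
  expect_setequal(cv$subject_id, unique(tab$subject_id))
  expect_equal(sum(cv$n_test), nrow(tab)) # folds partition the samples
  expect_error(lopo_cv(make_toy_table(n_subjects = 1)), ">= 2 subjects")

  # a fold's model is bit-identical to a manual fit without the held-out
  # subject, and predicts that subject with the reported accuracy
  cv_f <- lopo_cv(tab, methods = "imim_f", classifier = knn_spec(3), lam = 1)
  held <- unique(tab$subject_id)[1]
  train <- dplyr::filter(tibble::as_tibble(tab), subject_id != held)
  test <- dplyr::filter(tibble::as_tibble(tab), subject_id == held)
  train <- as_feature_table(as.data.frame(train), modality = unname(ft_modality(tab)))
  test <- as_feature_table(as.data.frame(test), modality = unname(ft_modality(tab)))
  norm <- fit_normalizer(train)
  fit <- imim_f(apply_normalizer(norm, train), lam = 1,
                classifier = knn_spec(3))
  pred <- predict(fit, apply_normalizer(norm, test))
  acc_manual <- mean(as.character(pred$.pred_class) ==
                       as.character(test$label))
  expect_equal(cv_f$accuracy[cv_f$subject_id == held], acc_manual)

  # refitting on identical training rows gives identical weights
  fit2 <- imim_f(apply_normalizer(norm, train), lam = 1,
                 classifier = knn_spec(3))
  expect_identical(fit$solution$w, fit2$solution$w)

  summ <- glance(cv_f)
  expect_named(summ, c("method", "mean_accuracy", "sd_accuracy", "n_folds"))
  expect_equal(summ$n_folds, 4L)
})

test_that("cross-validation reports round-trip to disk", {
  tab <- make_toy_table(n_subjects = 3, n_per_class = 8)
  cv <- lopo_cv(tab, methods = c("concat_baseline", "average_baseline"),
                classifier = knn_spec(3), lam = 0.5)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_cv_report(cv, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), 6)
  summ <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(summ$lambda_mode, "fixed")
  expect_equal(nrow(summ$methods), 2)
  expect_setequal(summ$methods$method,
                  c("concat_baseline", "average_baseline"))
})
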