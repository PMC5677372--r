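plug_width <- mi_config(binning = "equal_width") # uncorrected plug-in

# feature table from explicit per-sample vectors (balanced subject layout)
table_from_vectors <- function(..., label) {
  values <- cbind(...)
  feature_table(values, rep("P1", nrow(values)), label)
}

test_that("model construction reproduces the closed-form dependency/redundancy cases", {
  # exact product counts: two features independent of y and of each other
  counts_ind <- array(2, dim = c(2, 2, 2))
  cc <- codes_from_counts(counts_ind)
  tab <- table_from_vectors(x1 = as.numeric(cc[[1]]),
                            x2 = as.numeric(cc[[2]]),
                            label = cc[[3]])
  m <- build_mi_model(tab, config = plug_width)
  expect_equal(unname(m$D), c(0, 0), tolerance = 1e-12)
  expect_equal(m$R[1, 2], 0, tolerance = 1e-12)
  expect_equal(m$gamma, 0, tolerance = 1e-12)

  # duplicated perfectly informative feature: D = (1, 1), R12 = +1 bit
  y <- rep(c(0, 1), 10)
  tab2 <- table_from_vectors(x1 = y, x2 = y, label = y)
  m2 <- build_mi_model(tab2, config = plug_width)
  expect_equal(unname(m2$D), c(1, 1))
  expect_equal(m2$R[1, 2], 1)
  expect_equal(m2$gamma, 1) # |min eig| of antidiagonal 1 matrix

  expect_error(build_mi_model(table_from_vectors(x1 = rnorm(8), x2 = rnorm(8),
                                                 label = rep(1, 8))),
               "constant label")
})

test_that("R entries equal brute-force interaction information calls", {
  # XOR pair plus a copy of the first bit
  withr::with_seed(2, {
    a <- sample(0:1, 60, replace = TRUE)
    b <- sample(0:1, 60, replace = TRUE)
  })
  y <- xor(a, b)
  tab <- table_from_vectors(a = a, b = b, a_copy = a, label = as.integer(y))
  m <- build_mi_model(tab, config = plug_width)
  feats <- list(a, b, a)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_equal(m$R[i, j],
                   interaction_information(feats[[i]], feats[[j]],
                                           as.integer(y),
                                           config = plug_width),
                   tolerance = 1e-12)
    }
  }
  expect_true(isSymmetric(m$R, tol = 1e-10))
  expect_equal(unname(diag(m$R)), rep(0, 3))
  # gamma certificate: R + gamma I is positive semidefinite
  expect_gte(min(eigen(m$R + diag(m$gamma, 3), symmetric = TRUE)$values),
             -1e-8)
})

test_that("the weighting program solves the closed-form box cases", {
  mk <- function(d_vec, r_mat, nms = paste0("f", seq_along(d_vec))) {
    dimnames(r_mat) <- list(nms, nms)
    structure(
      list(D = stats::setNames(d_vec, nms), R = r_mat,
           gamma = max(0, -min(eigen(r_mat, symmetric = TRUE)$values)),
           feature_names = nms, config = mi_config()),
      class = "mi_model"
    )
  }

  # no redundancy: purely linear objective saturates the box
  m1 <- mk(c(0.3, 0.2), matrix(0, 2, 2))
  s1 <- solve_weights(m1, 1)
  expect_equal(unname(s1$w), c(1, 1), tolerance = 1e-6)
  expect_equal(s1$objective, 0.5, tolerance = 1e-6)

  # flat optimal face: minimal-norm tie-break returns the symmetric point
  m2 <- mk(c(1, 1), matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(m2$gamma, 0.5)
  s2 <- solve_weights(m2, 1)
  expect_equal(unname(s2$w), c(0.5, 0.5), tolerance = 1e-4)
  expect_equal(s2$objective, 0.5, tolerance = 1e-8)
  expect_equal(classifier_weight(m2, s2), 0.5, tolerance = 1e-8)

  # single perfectly informative feature
  m3 <- mk(1, matrix(0, 1, 1))
  s3 <- solve_weights(m3, 1)
  expect_equal(unname(s3$w), 1, tolerance = 1e-6)
  expect_equal(classifier_weight(m3, s3), 1, tolerance = 1e-6)

  # w = 0 gives beta = 0
  s0 <- s3
  s0$w[] <- 0
  expect_equal(classifier_weight(m3, s0), 0)

  expect_error(solve_weights(m1, -1), "positive")
  expect_error(solve_weights(m1, 0), "positive")
  expect_error(classifier_weight(m1, s3), "not produced")
})

test_that("solver matches exhaustive grid search and the projected-gradient route", {
  for (seed in c(31, 32, 33)) {
    for (n in c(3, 5)) {
      m <- make_random_model(n, seed)
      lam <- 0.05
      s <- solve_weights(m, lam)
      expect_lte(s$kkt_residual, 1e-6)
      mm <- m$R + diag(m$gamma, n)
      g <- oracle_grid_qp(unname(m$D), mm, lam, step = 0.05)
      # the solver is a global maximizer: never worse than any grid point,
      # and no further from the grid optimum than the value lost by
      # rounding the solution to the grid
      expect_gte(s$objective, g$objective - 1e-9)
      w_round <- round(unname(s$w) / 0.05) * 0.05
      obj_round <- lam * sum(w_round * m$D) -
        drop(crossprod(w_round, mm %*% w_round))
      expect_lte(s$objective - g$objective, s$objective - obj_round + 1e-9)
      expect_lte(s$objective - g$objective, 1e-4 + (s$objective - obj_round))
      # independent solver route agrees on the objective
      s_pg <- solve_weights(m, lam, method = "projected_gradient")
      expect_equal(s_pg$objective, s$objective, tolerance = 1e-5)
    }
  }
})

test_that("gamma certificate and lambda monotonicity hold on random models", {
  lams <- c(0.01, 0.05, 0.2, 1, 5)
  for (seed in 41:45) {
    m <- make_random_model(6, seed)
    expect_gte(min(eigen(m$R + diag(m$gamma, 6), symmetric = TRUE)$values),
               -1e-8)
    wd <- vapply(lams, function(l) {
      s <- solve_weights(m, l)
      sum(s$w * m$D)
    }, numeric(1))
    # the dependency term w'D of the optimum is non-decreasing in lambda
    expect_true(all(diff(wd) >= -1e-7))
  }
})

test_that("redundant copies share weight instead of multiplying it", {
  # one informative feature alone
  lone <- structure(
    list(D = c(f1 = 0.5, z = 0), R = matrix(0, 2, 2,
                                            dimnames = list(c("f1", "z"),
                                                            c("f1", "z"))),
         gamma = 0, feature_names = c("f1", "z"), config = mi_config()),
    class = "mi_model"
  )
  w_lone <- solve_weights(lone, 1)$w[["f1"]]

  # the same feature duplicated three times with full mutual redundancy
  r3 <- matrix(0.5, 3, 3) - diag(0.5, 3)
  dimnames(r3) <- list(paste0("c", 1:3), paste0("c", 1:3))
  copies <- structure(
    list(D = stats::setNames(rep(0.5, 3), paste0("c", 1:3)), R = r3,
         gamma = max(0, -min(eigen(r3, symmetric = TRUE)$values)),
         feature_names = paste0("c", 1:3), config = mi_config()),
    class = "mi_model"
  )
  w_copies <- solve_weights(copies, 1)$w
  expect_lt(sum(w_copies), 3 * w_lone)
})

test_that("weights recover the informative features of the default synthetic table", {
  gen <- gen_feature_table(synth_config())
  ftn <- apply_normalizer(fit_normalizer(gen$table), gen$table)
  m <- build_mi_model(ftn)
  inf_idx <- which(gen$truth$role == "informative")
  noise_idx <- which(gen$truth$role == "noise")
  # diagnostic lambda: the value at which an isolated feature carrying the
  # mean informative dependency saturates at w = 1
  lam_rec <- 2 * m$gamma / mean(m$D[inf_idx])
  s <- solve_weights(m, lam_rec)
  expect_gte(mean(s$w[inf_idx]) - mean(s$w[noise_idx]), 0.2)
  # noise features receive negligible weight
  strong <- active_features(s, threshold = 0.01)
  expect_gte(mean(!(noise_idx %in% strong)), 0.9)
})

test_that("active feature bookkeeping and the lambda grid behave as documented", {
  sol <- list(w = c(a = 0, b = 0.4, c = 1))
  class(sol) <- "weight_solution"
  expect_equal(unname(active_features(sol, 1e-6)), c(2L, 3L))
  expect_equal(length(active_features(sol, 2)), 0L)
  sol$w[] <- 0
  expect_equal(length(active_features(sol, 1e-6)), 0L)
  expect_error(active_features(sol, -1), ">= 0")

  g <- lambda_grid()
  expect_equal(length(g), 30)
  expect_equal(range(g), c(1e-4, 1))

  # active count is non-decreasing along an increasing lambda grid
  m <- make_random_model(6, 51)
  n_act <- vapply(lambda_grid(8), function(l) {
    length(solve_weights(m, l)$active_idx)
  }, integer(1))
  expect_true(all(diff(n_act) >= 0))
})

test_that("lambda selection is internally consistent", {
  # singleton grid short-circuits
  tab <- make_toy_table()
  sel1 <- select_lambda(tab, 0.3)
  expect_equal(sel1$lambda, 0.3)

  sel <- select_lambda(tab, c(1e-3, 1e-2, 1e-1), classifier = knn_spec(3))
  expect_equal(max(sel$curve$accuracy), sel$curve$accuracy[
    sel$curve$lambda == sel$lambda])
  expect_equal(nrow(sel$curve), 3)
  expect_error(select_lambda(tab, numeric(0)), "nonempty")
  expect_error(select_lambda(tab, c(0.1, -1)), "positive")
})

test_that("models and solutions round-trip through JSON", {
  m <- make_random_model(4, 61)
  s <- solve_weights(m, 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_imim_json(m, s, path)
  back <- read_imim_json(path)
  expect_equal(back$model$D, m$D, tolerance = 1e-12)
  expect_equal(unname(back$model$R), unname(m$R), tolerance = 1e-12)
  expect_equal(back$model$gamma, m$gamma, tolerance = 1e-12)
  expect_equal(back$solution$w, s$w, tolerance = 1e-12)
  expect_equal(back$solution$objective, s$objective, tolerance = 1e-12)
  expect_equal(back$solution$lam, s$lam)
})
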