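# Independent oracles: every routine here recomputes a quantity by direct
# summation / exhaustive search, sharing no code with the package paths it
# is used to check.

# entropy of a probability vector by direct summation
oracle_entropy <- function(p, base = 2) {
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

# mutual information from an explicit joint counts matrix, cell by cell
oracle_mi_counts <- function(counts, base = 2) {
  n <- sum(counts)
  pxy <- counts / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  total <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      if (pxy[i, j] > 0) {
        total <- total + pxy[i, j] * log(pxy[i, j] / (px[i] * py[j]))
      }
    }
  }
  total / log(base)
}

# conditional mutual information I(x; y | z) by direct summation over an
# explicit 3-way counts array (dims x, y, z)
oracle_cmi_counts <- function(counts, base = 2) {
  n <- sum(counts)
  total <- 0
  for (k in seq_len(dim(counts)[3])) {
    slab <- counts[, , k]
    nz <- sum(slab)
    if (nz > 0) {
      total <- total + (nz / n) * oracle_mi_counts(slab, base = base)
    }
  }
  total
}

# expand a joint counts array into aligned code vectors (one per dimension)
codes_from_counts <- function(counts) {
  idx <- which(counts > 0, arr.ind = TRUE)
  idx <- idx[rep(seq_len(nrow(idx)), counts[counts > 0]), , drop = FALSE]
  lapply(seq_len(ncol(idx)), function(d) as.integer(idx[, d]))
}

# exhaustive grid search of the box-constrained quadratic objective
# lam * w'D - w' M w over {0, step, ..., 1}^n, chunked over the first
# coordinate so n = 5 stays within memory
oracle_grid_qp <- function(d_vec, m_mat, lam, step = 0.05) {
  n <- length(d_vec)
  g <- seq(0, 1, by = step)
  best <- -Inf
  best_w <- NULL
  rest <- as.matrix(expand.grid(rep(list(g), n - 1L)))
  for (w1 in g) {
    w_all <- cbind(w1, rest)
    obj <- lam * (w_all %*% d_vec) - rowSums((w_all %*% m_mat) * w_all)
    k <- which.max(obj)
    if (obj[k] > best) {
      best <- obj[k]
      best_w <- w_all[k, ]
    }
  }
  list(objective = best, w = unname(best_w))
}

# brute-force sample entropy: explicit double loop over templates
oracle_sampen <- function(x, m = 2L, r) {
  count <- function(mm) {
    n_t <- length(x) - mm + 1L
    cnt <- 0L
    for (i in seq_len(n_t - 1L)) {
      for (j in seq.int(i + 1L, n_t)) {
        if (max(abs(x[i:(i + mm - 1L)] - x[j:(j + mm - 1L)])) < r) {
          cnt <- cnt + 1L
        }
      }
    }
    cnt
  }
  -log(count(m + 1L) / count(m))
}

# independent Welch check: plain averaged periodogram over non-overlapping
# rectangular segments (variance-normalized by Parseval)
oracle_mean_power <- function(x, fs, nseg) {
  starts <- seq(1L, length(x) - nseg + 1L, by = nseg)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- seg - mean(seg)
    acc <- acc + sum(Mod(fft(seg))^2) / nseg^2
  }
  acc / length(starts) # == mean segment variance by Parseval
}

# small balanced feature table for fusion tests: every subject holds every
# class, two modalities, one informative feature per modality plus noise
make_toy_table <- function(n_subjects = 4, n_per_class = 12, seed = 7,
                           effect = 1.5) {
  withr::with_seed(seed, {
    subj <- rep(sprintf("P%d", seq_len(n_subjects)), each = 3 * n_per_class)
    lab <- rep(rep(c("low", "medium", "high"), each = n_per_class),
               n_subjects)
    shift <- effect * (match(lab, c("low", "medium", "high")) - 2)
    n <- length(lab)
    values <- cbind(
      a_inf = shift + rnorm(n),
      a_noise = rnorm(n),
      b_inf = -shift + rnorm(n),
      b_noise = rnorm(n)
    )
    feature_table(values, subj, lab,
                  modality = c("eeg_psd", "eeg_psd", "ecg", "ecg"))
  })
}

# random small mi_model with a valid gamma certificate
make_random_model <- function(n, seed) {
  withr::with_seed(seed, {
    d_vec <- runif(n, 0, 0.6)
    r_mat <- matrix(0, n, n)
    r_mat[upper.tri(r_mat)] <- runif(n * (n - 1) / 2, -0.2, 0.4)
    r_mat <- r_mat + t(r_mat)
    nms <- paste0("f", seq_len(n))
    dimnames(r_mat) <- list(nms, nms)
    structure(
      list(
        D = stats::setNames(d_vec, nms),
        R = r_mat,
        gamma = max(0, -min(eigen(r_mat, symmetric = TRUE)$values)),
        feature_names = nms,
        config = mi_config()
      ),
      class = "mi_model"
    )
  })
}
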