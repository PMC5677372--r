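#' Discretized representation of a variable
#'
#' Wraps an integer code vector together with its number of levels. This is
#' the common currency of the plug-in information estimators: continuous
#' features are first reduced to categories by [discretize()], while the
#' class label (already categorical) is coerced directly.
#'
#' @param x An integer/factor/character vector of category assignments, or an
#'   existing `discrete_codes` object (returned unchanged).
#' @param name Optional identifier of the source variable.
#' @return A `discrete_codes` object: a list with integer `codes` in
#'   `1..n_levels`, the level count `n_levels`, and `source_name`.
#' @export
discrete_codes <- function(x, name = NULL) {
  if (inherits(x, "discrete_codes")) {
    return(x)
  }
  if (length(x) == 0L) {
    rlang::abort("empty sample vector: at least one observation is required")
  }
  if (anyNA(x)) {
    rlang::abort("missing values are not allowed in a discrete variable")
  }
  f <- factor(x)
  structure(
    list(
      codes = as.integer(f),
      n_levels = nlevels(f),
      source_name = name %||% deparse(substitute(x))
    ),
    class = "discrete_codes"
  )
}

#' @export
print.discrete_codes <- function(x, ...) {
  cat(
    "<discrete_codes> ", x$source_name, ": n = ", length(x$codes),
    ", levels = ", x$n_levels, "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
length.discrete_codes <- function(x) length(x$codes)

#' Mutual-information estimator settings
#'
#' @param n_bins Number of bins used to discretize continuous features
#'   (>= 2). Five equal-frequency bins are the default: band-power and HRV
#'   features are strongly right-skewed, and quantile bins keep each cell of
#'   the contingency table populated.
#' @param binning `"equal_frequency"` (quantile bins, ties resolved by stable
#'   sort order so results are machine-independent) or `"equal_width"`.
#' @param log_base Logarithm base: 2 (bits, default) or `exp(1)` (nats).
#' @param miller_madow Apply the Miller--Madow small-sample bias correction
#'   to entropies (default `FALSE`; the plain plug-in estimate is the
#'   reference behaviour and is what the oracle tests check).
#' @return An `mi_config` list.
#' @export
mi_config <- function(n_bins = 5L, binning = c("equal_frequency", "equal_width"),
                      log_base = 2, miller_madow = FALSE) {
  binning <- match.arg(binning)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) {
    rlang::abort("`n_bins` must be an integer >= 2")
  }
  if (!is.numeric(log_base) || length(log_base) != 1L || log_base <= 1) {
    rlang::abort("`log_base` must be a single number > 1")
  }
  structure(
    list(
      n_bins = n_bins, binning = binning,
      log_base = log_base, miller_madow = isTRUE(miller_madow)
    ),
    class = "mi_config"
  )
}

#' Discretize a continuous feature
#'
#' Equal-width binning cuts the observed range into `n_bins` intervals that
#' are closed on the right (the lowest interval also includes its left
#' endpoint), so e.g. `c(0, 0.5, 1)` with two bins codes as `1, 1, 2`.
#' Equal-frequency binning assigns codes by rank, `ceiling(rank * n_bins /
#' n)`, with ties broken by first occurrence (stable sort order) so that a
#' sample of size divisible by `n_bins` fills every bin exactly equally.
#' Constant input collapses to a single level. Unoccupied bins are dropped,
#' so `n_levels` is the number of occupied categories.
#'
#' @param values Finite numeric vector, length >= 2.
#' @param config An [mi_config()].
#' @param name Optional source identifier.
#' @return A [discrete_codes()] object.
#' @export
discretize <- function(values, config = mi_config(), name = NULL) {
  if (!is.numeric(values) || length(values) < 2L) {
    rlang::abort("`values` must be a numeric vector of length >= 2")
  }
  if (!all(is.finite(values))) {
    rlang::abort("`values` must be finite (no NA/NaN/Inf)")
  }
  rng <- range(values)
  if (rng[1] == rng[2]) {
    codes <- rep.int(1L, length(values))
  } else if (config$binning == "equal_width") {
    breaks <- seq(rng[1], rng[2], length.out = config$n_bins + 1L)
    codes <- as.integer(cut(values, breaks = breaks,
                            include.lowest = TRUE, right = TRUE))
  } else {
    r <- rank(values, ties.method = "first")
    codes <- as.integer(ceiling(r * config$n_bins / length(values)))
  }
  # drop empty categories so n_levels counts occupied bins
  f <- factor(codes)
  structure(
    list(
      codes = as.integer(f),
      n_levels = nlevels(f),
      source_name = name %||% "feature"
    ),
    class = "discrete_codes"
  )
}

# counts -> plug-in probability vector/array; validates the invariants the
# downstream estimators rely on (nonnegative, sums to one).
prob_from_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) rlang::abort("empty contingency table")
  p <- counts / n
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-12)
  p
}

plugin_entropy <- function(p, log_base) {
  p <- p[p > 0]
  -sum(p * log(p)) / log(log_base)
}

#' Plug-in (maximum-likelihood) entropy
#'
#' @param x Anything accepted by [discrete_codes()].
#' @param config An [mi_config()]; only `log_base` and `miller_madow` are
#'   used here.
#' @return Entropy H(x) >= 0, at most `log(n_levels)` in the chosen base.
#' @export
entropy <- function(x, config = mi_config()) {
  x <- discrete_codes(x)
  counts <- tabulate(x$codes, nbins = x$n_levels)
  h <- plugin_entropy(prob_from_counts(counts), config$log_base)
  if (config$miller_madow) {
    m <- sum(counts > 0)
    h <- h + (m - 1) / (2 * length(x$codes) * log(config$log_base))
  }
  h
}

# joint code index for two discrete variables (row-major pairing)
pair_codes <- function(a, b, name = "pair") {
  if (length(a$codes) != length(b$codes)) {
    rlang::abort("variables must have equal sample counts")
  }
  joint <- (a$codes - 1L) * b$n_levels + b$codes
  f <- factor(joint)
  structure(
    list(codes = as.integer(f), n_levels = nlevels(f), source_name = name),
    class = "discrete_codes"
  )
}

#' Plug-in mutual information between two discrete variables
#'
#' Estimates I(x; y) by direct summation over the joint contingency table,
#' `sum p(x,y) log( p(x,y) / (p(x) p(y)) )`. The plug-in estimate on a joint
#' table is nonnegative, symmetric in its arguments, and bounded above by
#' `min(H(x), H(y))`.
#'
#' @inheritParams entropy
#' @param y Second variable (same sample count as `x`).
#' @return Mutual information in the units of `config$log_base`.
#' @export
mutual_information <- function(x, y, config = mi_config()) {
  x <- discrete_codes(x)
  y <- discrete_codes(y)
  if (length(x$codes) != length(y$codes)) {
    rlang::abort("`x` and `y` must have equal sample counts")
  }
  counts <- table(x$codes, y$codes)
  pxy <- prob_from_counts(counts)
  px <- rowSums(pxy)
  py <- colSums(pxy)
  pos <- pxy > 0
  mi <- sum(pxy[pos] * log(pxy[pos] / outer(px, py)[pos])) / log(config$log_base)
  if (config$miller_madow) {
    # I = H(x) + H(y) - H(x,y): the per-entropy (m-1)/(2n) corrections
    # combine into a downward shift that cancels the first-order plug-in
    # bias of mutual information
    m_corr <- (sum(px > 0) - 1) + (sum(py > 0) - 1) - (sum(pos) - 1)
    mi <- mi + m_corr / (2 * length(x$codes) * log(config$log_base))
  }
  mi
}

#' Joint mutual information I(xi, xj; y)
#'
#' The two features are pair-encoded into a single discrete variable and the
#' ordinary mutual information with `y` is computed, i.e. the two-feature
#' case of the multivariate dependency between a feature vector and the
#' label. For plug-in estimates on a shared binning this is never smaller
#' than either single-feature mutual information.
#'
#' @inheritParams mutual_information
#' @param xi,xj Feature variables.
#' @param y Label variable.
#' @export
joint_mutual_information <- function(xi, xj, y, config = mi_config()) {
  xi <- discrete_codes(xi)
  xj <- discrete_codes(xj)
  mutual_information(pair_codes(xi, xj), y, config = config)
}

#' Pairwise interaction information (co-information)
#'
#' I(xi; xj; y) = I(xi; y) + I(xj; y) - I(xi, xj; y). Positive values mean
#' the two features carry redundant information about the label; negative
#' values mean synergy (e.g. an XOR system scores -1 bit). The quantity is
#' symmetric under any permutation of its three arguments.
#'
#' @inheritParams joint_mutual_information
#' @export
interaction_information <- function(xi, xj, y, config = mi_config()) {
  xi <- discrete_codes(xi)
  xj <- discrete_codes(xj)
  y <- discrete_codes(y)
  mutual_information(xi, y, config = config) +
    mutual_information(xj, y, config = config) -
    joint_mutual_information(xi, xj, y, config = config)
}

#' Default estimator settings for model building
#'
#' [mi_config()] with the Miller--Madow correction switched on; see
#' [build_mi_model()] for why the model layer defaults to the corrected
#' estimator while the raw estimators default to the plain plug-in.
#'
#' @inheritParams mi_config
#' @export
model_config <- function(n_bins = 5L, binning = "equal_frequency",
                         log_base = 2) {
  mi_config(n_bins = n_bins, binning = binning, log_base = log_base,
            miller_madow = TRUE)
}
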