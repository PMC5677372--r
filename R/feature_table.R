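#' Assemble a feature table
#'
#' The common currency of the pipeline: a tibble with one row per sample,
#' reserved columns `subject_id` and `label`, and one numeric column per
#' feature. Each feature carries a modality tag (`eeg_psd`, `eeg_erp`,
#' `ecg`, or `other`) stored in the `"modality"` attribute; the fusion
#' routines use the tags to split the table into per-modality blocks.
#'
#' @param values Numeric matrix or data frame, samples x features.
#' @param subject_id Per-sample subject identifier.
#' @param label Per-sample class label (coerced to factor; the label is
#'   treated as categorical throughout and never binned).
#' @param modality Per-feature modality tag: either a single tag recycled to
#'   all features or a character vector of length `ncol(values)`.
#' @param feature_names Optional feature names (defaults to the column names
#'   of `values`); must be unique.
#' @return A `feature_table` (a tibble subclass).
#' @export
feature_table <- function(values, subject_id, label, modality = "other",
                          feature_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  feature_names <- feature_names %||% colnames(values) %||%
    paste0("f", seq_len(ncol(values)))
  if (anyDuplicated(feature_names)) {
    rlang::abort("feature names must be unique")
  }
  if (length(modality) == 1L) modality <- rep(modality, ncol(values))
  if (length(modality) != ncol(values)) {
    rlang::abort("`modality` must have one tag per feature")
  }
  if (!all(modality %in% c("eeg_psd", "eeg_erp", "ecg", "other"))) {
    rlang::abort("modality tags must be one of eeg_psd, eeg_erp, ecg, other")
  }
  if (anyNA(values)) {
    rlang::abort("feature values must not contain missing values")
  }
  if (nrow(values) != length(subject_id) || nrow(values) != length(label)) {
    rlang::abort("`subject_id` and `label` must have one entry per sample")
  }
  colnames(values) <- feature_names
  tbl <- tibble::as_tibble(values)
  tbl <- tibble::add_column(
    tbl,
    subject_id = as.character(subject_id),
    label = factor(label),
    .before = 1
  )
  out <- structure(tbl, modality = stats::setNames(modality, feature_names),
                   class = c("feature_table", class(tbl)))
  check_class_coverage(out)
  out
}

#' Interpret a plain data frame as a feature table
#'
#' @param data A data frame containing `subject_id` and `label` columns;
#'   every other column is taken as a feature.
#' @param modality Per-feature modality tags as in [feature_table()].
#' @export
as_feature_table <- function(data, modality = "other") {
  if (inherits(data, "feature_table")) {
    return(data)
  }
  need <- c("subject_id", "label")
  if (!all(need %in% names(data))) {
    rlang::abort("`data` must contain `subject_id` and `label` columns")
  }
  feats <- setdiff(names(data), need)
  feature_table(data[feats], data$subject_id, data$label, modality = modality)
}

check_class_coverage <- function(ft) {
  cover <- table(ft$subject_id, droplevels(ft$label)) > 0
  if (!all(cover)) {
    rlang::warn("some subjects do not contribute samples of every class")
  }
  invisible(ft)
}

#' @export
print.feature_table <- function(x, ...) {
  mod <- attr(x, "modality")
  cat("# A feature_table: ", nrow(x), " samples x ", length(mod),
      " features (", paste(sprintf("%s: %d", names(table(mod)), table(mod)),
                           collapse = ", "), ")\n", sep = "")
  NextMethod()
}

#' @rdname feature_table
#' @param ft A `feature_table`.
#' @export
ft_feature_names <- function(ft) names(attr(ft, "modality"))

#' @rdname feature_table
#' @export
ft_modality <- function(ft) attr(ft, "modality")

#' @rdname feature_table
#' @export
ft_matrix <- function(ft) {
  as.matrix(as.data.frame(ft)[, ft_feature_names(ft), drop = FALSE])
}

# subset the feature columns of a table, keeping class/attributes coherent
ft_select_features <- function(ft, keep) {
  mod <- attr(ft, "modality")[keep]
  feature_table(ft_matrix(ft)[, keep, drop = FALSE],
                ft$subject_id, ft$label, modality = unname(mod),
                feature_names = names(mod))
}

ft_subset_rows <- function(ft, rows) {
  mod <- attr(ft, "modality")
  feature_table(ft_matrix(ft)[rows, , drop = FALSE],
                ft$subject_id[rows], ft$label[rows],
                modality = unname(mod), feature_names = names(mod))
}

#' Split a feature table into per-modality blocks
#'
#' @param ft A `feature_table`.
#' @return Named list of `feature_table`s, one per modality present, in
#'   first-appearance order.
#' @export
ft_split_modalities <- function(ft) {
  mod <- attr(ft, "modality")
  tags <- unique(unname(mod))
  stats::setNames(
    lapply(tags, function(tg) ft_select_features(ft, which(mod == tg))),
    tags
  )
}

#' Min--max (unity-based) normalization
#'
#' `fit_normalizer()` learns per-feature minima and maxima from the training
#' rows only; `apply_normalizer()` maps values through
#' `(x - min) / (max - min)` and clips the result into `[0, 1]`, so test
#' samples outside the training range saturate at the box edge. Features
#' constant on the training data are flagged and map to 0.
#'
#' @param train A `feature_table` of training samples.
#' @return A `normalizer_state` object.
#' @export
fit_normalizer <- function(train) {
  x <- ft_matrix(train)
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  structure(
    list(
      feature_names = colnames(x),
      min = mins, max = maxs,
      constant = maxs - mins <= 0
    ),
    class = "normalizer_state"
  )
}

#' @rdname fit_normalizer
#' @param state A fitted `normalizer_state`.
#' @param table A `feature_table` to transform (training or test).
#' @export
apply_normalizer <- function(state, table) {
  if (!inherits(state, "normalizer_state")) {
    rlang::abort("`state` must be a fitted normalizer_state")
  }
  x <- ft_matrix(table)
  if (!identical(colnames(x), state$feature_names)) {
    rlang::abort("feature names of `table` do not match the fitted state")
  }
  span <- state$max - state$min
  span[state$constant] <- 1 # constant features map to 0 below
  x <- sweep(sweep(x, 2, state$min, "-"), 2, span, "/")
  x[, state$constant] <- 0
  x[x < 0] <- 0
  x[x > 1] <- 1
  mod <- attr(table, "modality")
  feature_table(x, table$subject_id, table$label,
                modality = unname(mod), feature_names = names(mod))
}

#' Read / write feature tables as CSV
#'
#' The CSV carries a header row of feature names plus the reserved columns
#' `subject_id` and `label`; modality tags travel in a sidecar column-layout
#' header line is avoided by writing a companion `<path>.modality.csv`
#' (feature, modality) next to the table.
#'
#' @param ft A `feature_table`.
#' @param path Output CSV path.
#' @export
write_feature_table <- function(ft, path) {
  utils::write.csv(as.data.frame(ft), path, row.names = FALSE)
  mod <- attr(ft, "modality")
  utils::write.csv(
    data.frame(feature = names(mod), modality = unname(mod)),
    paste0(path, ".modality.csv"),
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  data <- utils::read.csv(path, check.names = FALSE)
  side <- paste0(path, ".modality.csv")
  modality <- "other"
  if (file.exists(side)) {
    ms <- utils::read.csv(side)
    modality <- ms$modality[match(setdiff(names(data), c("subject_id", "label")),
                                  ms$feature)]
  }
  as_feature_table(data, modality = modality)
}
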