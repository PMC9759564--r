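#' Construct a tabular dataset
#'
#' The container every other function in the package consumes: an `N x d`
#' numeric feature matrix, a binary label vector (0 = malignant, 1 = benign),
#' field names and a missing-value mask.  Missing cells are stored as `NA`
#' in `features` and flagged in `missing_mask`.
#'
#' @param features numeric matrix, one row per record.
#' @param labels integer/numeric vector of 0/1 labels, one per row.
#'   0 is the negative (malignant) class, 1 the positive (benign) class.
#' @param field_names optional character vector of column identifiers;
#'   defaults to existing column names or `V1..Vd`.
#' @param missing_mask optional logical matrix marking missing cells;
#'   defaults to `is.na(features)`.
#' @param normalized logical; `TRUE` once every non-missing value lies in
#'   `[0, 1]` (set by [minmax_normalize()]).
#' @return an object of class `"tabular_dataset"`.
#' @examples
#' ds <- tabular_dataset(matrix(rnorm(20), 5), labels = c(0, 1, 0, 1, 1))
#' ds
#' @export
tabular_dataset <- function(features, labels, field_names = NULL,
                            missing_mask = NULL, normalized = FALSE) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) < 1L || ncol(features) < 1L)
    stop("need at least one row and one feature")
  labels <- as.integer(labels)
  if (length(labels) != nrow(features))
    stop("labels must have one entry per feature row")
  if (length(unique(labels)) > 2L || !all(labels %in% c(0L, 1L)))
    stop("labels must be binary, coded 0 (malignant) / 1 (benign)")
  if (is.null(field_names)) {
    field_names <- colnames(features)
    if (is.null(field_names))
      field_names <- paste0("V", seq_len(ncol(features)))
  }
  if (length(field_names) != ncol(features))
    stop("field_names length must equal the number of features")
  if (is.null(missing_mask)) missing_mask <- is.na(features)
  missing_mask <- as.matrix(missing_mask)
  if (!identical(dim(missing_mask), dim(features)))
    stop("missing_mask must match the feature matrix dimensions")
  features[missing_mask] <- NA_real_
  if (isTRUE(normalized)) {
    v <- features[!missing_mask]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("normalized = TRUE but values fall outside [0, 1]")
  }
  colnames(features) <- field_names
  structure(
    list(features = features, labels = labels, field_names = field_names,
         missing_mask = missing_mask, normalized = isTRUE(normalized)),
    class = "tabular_dataset")
}

#' @export
print.tabular_dataset <- function(x, ...) {
  cat(sprintf("<tabular_dataset> %d records x %d features%s\n",
              nrow(x$features), ncol(x$features),
              if (x$normalized) " (normalized)" else ""))
  cat(sprintf("  labels: %d malignant (0) / %d benign (1); %d missing cells\n",
              sum(x$labels == 0L), sum(x$labels == 1L), sum(x$missing_mask)))
  invisible(x)
}

#' @export
dim.tabular_dataset <- function(x) dim(x$features)

n_records  <- function(ds) nrow(ds$features)
n_fields   <- function(ds) ncol(ds$features)

subset_rows <- function(ds, idx) {
  tabular_dataset(ds$features[idx, , drop = FALSE], ds$labels[idx],
                  ds$field_names, ds$missing_mask[idx, , drop = FALSE],
                  normalized = ds$normalized)
}

#' Read a delimited clinical table
#'
#' Reads comma-separated text in one of three dialects and returns a
#' [tabular_dataset()].  The two UCI Wisconsin breast-cancer layouts are
#' supported natively:
#'
#' * `"wbc"` (Original): no header; columns are a sample ID, nine integer
#'   cytology features and a class coded 2 (benign) / 4 (malignant);
#'   missing cells are marked `"?"`.
#' * `"wdbc"` (Diagnostic): no header; columns are an ID, a diagnosis coded
#'   `M`/`B`, then thirty real-valued features.
#' * `"generic"`: header row; the label column is named via `label_col` and
#'   must be codeable to 0/1 (numeric 0/1, or `M`/`B`); `"?"` marks missing.
#'
#' The ID column is dropped and the class recoded to 0 = malignant,
#' 1 = benign in all dialects.
#'
#' @param path file path to delimited text.
#' @param dialect one of `"wbc"`, `"wdbc"`, `"generic"`.
#' @param label_col label column name for the generic dialect.
#' @return a `tabular_dataset`.
#' @export
load_uci_table <- function(path, dialect = c("wbc", "wdbc", "generic"),
                           label_col = "class") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- dialect == "generic"
  nf <- utils::count.fields(path, sep = ",", quote = "")
  expected <- switch(dialect, wbc = 11L, wdbc = 32L, generic = nf[1L])
  bad <- which(nf != expected)
  if (length(bad))
    stop(sprintf("malformed row: line %d has %d fields, expected %d",
                 bad[1L], nf[bad[1L]], expected))
  raw <- utils::read.csv(path, header = header, na.strings = "?",
                         stringsAsFactors = FALSE, colClasses = NA)
  if (dialect == "wbc") {
    cls <- raw[[11L]]
    if (!all(cls %in% c(2, 4)))
      stop("unknown class code in WBC file (expected 2/4): ",
           paste(unique(cls[!cls %in% c(2, 4)]), collapse = ", "))
    labels <- ifelse(cls == 4, 0L, 1L)           # 4 = malignant -> 0
    feats <- as.matrix(raw[, 2:10])
    names <- c("clump_thickness", "uniformity_cell_size",
               "uniformity_cell_shape", "marginal_adhesion",
               "single_epithelial_cell_size", "bare_nuclei",
               "bland_chromatin", "normal_nucleoli", "mitoses")
  } else if (dialect == "wdbc") {
    cls <- raw[[2L]]
    if (!all(cls %in% c("M", "B")))
      stop("unknown class code in WDBC file (expected M/B): ",
           paste(unique(cls[!cls %in% c("M", "B")]), collapse = ", "))
    labels <- ifelse(cls == "M", 0L, 1L)
    feats <- as.matrix(raw[, 3:32])
    names <- paste0("f", sprintf("%02d", 1:30))
  } else {
    if (!label_col %in% names(raw))
      stop("label column '", label_col, "' not found")
    cls <- raw[[label_col]]
    if (all(cls %in% c("M", "B"))) {
      labels <- ifelse(cls == "M", 0L, 1L)
    } else if (all(cls %in% c(0, 1))) {
      labels <- as.integer(cls)
    } else stop("unknown class coding in generic file")
    feats <- as.matrix(raw[, setdiff(names(raw), label_col), drop = FALSE])
    names <- colnames(feats)
  }
  storage.mode(feats) <- "double"
  tabular_dataset(feats, labels, field_names = names)
}

#' Write a dataset as canonical CSV
#'
#' Header row, one label column named `class` coded 0/1, missing cells
#' written as `"?"`.  [load_uci_table()] with `dialect = "generic"` reads
#' the result back exactly.
#'
#' @param ds a `tabular_dataset`.
#' @param path output file path.
#' @export
write_dataset <- function(ds, path) {
  df <- as.data.frame(ds$features)
  df[] <- lapply(df, function(col) ifelse(is.na(col), "?", format(col, digits = 17)))
  df$class <- ds$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resolve missing cells
#'
#' @param ds a `tabular_dataset` (not yet normalized).
#' @param policy `"drop_rows"` removes every record containing a missing
#'   cell; `"impute_mean"` replaces each missing cell with the per-feature
#'   mean of the non-missing values.
#' @return a `tabular_dataset` with an all-`FALSE` missing mask.
#' @export
handle_missing <- function(ds, policy = c("drop_rows", "impute_mean")) {
  policy <- match.arg(policy)
  stopifnot(inherits(ds, "tabular_dataset"))
  if (ds$normalized) stop("handle missing values before normalizing")
  if (!any(ds$missing_mask)) return(ds)
  if (policy == "drop_rows") {
    keep <- rowSums(ds$missing_mask) == 0L
    if (!any(keep)) stop("all rows contain missing cells")
    subset_rows(ds, keep)
  } else {
    feats <- ds$features
    for (j in seq_len(ncol(feats))) {
      miss <- ds$missing_mask[, j]
      if (!any(miss)) next
      if (all(miss)) stop("feature '", ds$field_names[j],
                          "' is entirely missing; cannot impute")
      feats[miss, j] <- mean(feats[!miss, j])
    }
    tabular_dataset(feats, ds$labels, ds$field_names,
                    matrix(FALSE, nrow(feats), ncol(feats)))
  }
}

#' Min-max normalize every feature to [0, 1]
#'
#' Each column is mapped by `(x - min) / (max - min)` using the observed
#' column range; constant columns map to 0 so uninformative fields render
#' as empty bars.  Normalization statistics may be taken from a reference
#' dataset (e.g. the training split) for leakage-free use.
#'
#' @param ds a `tabular_dataset` without missing cells.
#' @param stats_from optional `tabular_dataset` supplying the per-column
#'   min/max (defaults to `ds` itself); values outside the reference range
#'   are clipped to `[0, 1]`.
#' @return a normalized `tabular_dataset`.
#' @export
minmax_normalize <- function(ds, stats_from = ds) {
  stopifnot(inherits(ds, "tabular_dataset"))
  if (any(ds$missing_mask)) stop("resolve missing cells before normalizing")
  rng <- feature_ranges(stats_from)
  feats <- apply_ranges(ds$features, rng)
  out <- tabular_dataset(feats, ds$labels, ds$field_names,
                         normalized = TRUE)
  attr(out, "ranges") <- rng
  out
}

feature_ranges <- function(ds) {
  mins <- apply(ds$features, 2L, min, na.rm = TRUE)
  maxs <- apply(ds$features, 2L, max, na.rm = TRUE)
  cbind(min = mins, max = maxs)
}

apply_ranges <- function(feats, rng) {
  span <- rng[, "max"] - rng[, "min"]
  out <- sweep(feats, 2L, rng[, "min"], "-")
  nz <- span > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, span[nz], "/")
  out[, !nz] <- 0
  pmin(pmax(out, 0), 1)
}

#' Train/validation/test split specification
#'
#' Defaults follow the evaluation protocol used throughout the package:
#' 20% of records held out for testing, then 20% of the remaining training
#' records held out for validation, stratified by class.
#'
#' @param test_fraction proportion of records in the test partition.
#' @param validation_fraction_of_train proportion of the non-test records
#'   held out for validation.
#' @param seed integer seed making the split deterministic.
#' @param stratified draw each partition class-proportionally.
#' @export
split_spec <- function(test_fraction = 0.20,
                       validation_fraction_of_train = 0.20,
                       seed = 1L, stratified = TRUE) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            validation_fraction_of_train > 0,
            validation_fraction_of_train < 1)
  structure(list(test_fraction = test_fraction,
                 validation_fraction_of_train = validation_fraction_of_train,
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "split_spec")
}

# Allocate `k` draws across classes proportionally (largest remainder),
# so partition sizes are exact and per-class counts are within +/-1 of
# proportionality.
allocate_stratified <- function(labels, k) {
  tab <- table(labels)
  quota <- k * tab / length(labels)
  base <- floor(quota)
  rem <- k - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  base
}

#' Split a dataset into train / validation / test partitions
#'
#' The test partition receives `floor(test_fraction * N)` records; the
#' validation partition receives the floor of its fraction of the
#' remainder.  Stratification keeps class counts within one of
#' proportionality in every partition.  Deterministic for a fixed seed.
#'
#' @param ds a `tabular_dataset` with at least 5 records.
#' @param spec a [split_spec()].
#' @return a list with `tabular_dataset` elements `train`, `validation`,
#'   `test`.
#' @export
split_dataset <- function(ds, spec = split_spec()) {
  stopifnot(inherits(ds, "tabular_dataset"), inherits(spec, "split_spec"))
  n <- n_records(ds)
  if (n < 5L) stop("need at least 5 records to split")
  n_test <- floor(spec$test_fraction * n)
  n_val <- floor(spec$validation_fraction_of_train * (n - n_test))
  if (n_test < 1L || n_val < 1L || (n - n_test - n_val) < 1L)
    stop("split leaves an empty partition; adjust fractions or add records")
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(spec$seed)
  draw <- function(pool, k) {
    if (!spec$stratified) return(sample(pool, k))
    per_class <- allocate_stratified(ds$labels[pool], k)
    unlist(lapply(names(per_class), function(cl) {
      cand <- pool[ds$labels[pool] == as.integer(cl)]
      sample(cand, per_class[[cl]])
    }), use.names = FALSE)
  }
  idx_test <- draw(seq_len(n), n_test)
  rest <- setdiff(seq_len(n), idx_test)
  idx_val <- draw(rest, n_val)
  idx_train <- setdiff(rest, idx_val)
  list(train = subset_rows(ds, sort(idx_train)),
       validation = subset_rows(ds, sort(idx_val)),
       test = subset_rows(ds, sort(idx_test)))
}

preserve_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}
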