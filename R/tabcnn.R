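#' Fit a CNN classifier to tabular records via image encoding
#'
#' `tabcnn()` is the package's front door: it takes a numeric feature
#' table with a binary outcome, min-max normalizes it, renders every
#' record as a small 2-D image with the configured encoder, builds the
#' 4-block VGG-style network sized for that image, and trains it with
#' SGD.  The returned object predicts on new records by replaying the
#' stored normalization ranges, field order and encoder.
#'
#' @param x an `N x d` numeric matrix or data frame of features, a
#'   [tabular_dataset()], or a formula.
#' @param y length-`N` 0/1 outcome (ignored when `x` is a
#'   `tabular_dataset` or formula).
#' @param encoding an [encoding_config()].
#' @param config a [train_config()].
#' @param normalize_stats `"fit"` computes normalization ranges on the
#'   data given here (leakage-free when this is a training split);
#'   a precomputed range matrix may be supplied instead.
#' @param ... passed between methods.
#' @return an object of class `"tabcnn"` with `print`, `summary`,
#'   `predict` and `plot` methods.
#' @examples
#' ds <- simulate_tabular(sim_spec(n = 60, d = 8, separation = 3, seed = 1))
#' fit <- tabcnn(ds, encoding = encoding_config("combined"),
#'               config = train_config(max_iterations = 60, seed = 1))
#' fit
#' @export
tabcnn <- function(x, ...) UseMethod("tabcnn")

#' @rdname tabcnn
#' @param data data frame holding the formula's variables.
#' @export
tabcnn.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  feats <- stats::model.matrix(x, mf)
  feats <- feats[, colnames(feats) != "(Intercept)", drop = FALSE]
  tabcnn.default(feats, y, ...)
}

#' @rdname tabcnn
#' @export
tabcnn.tabular_dataset <- function(x, ...) {
  ds <- handle_missing(x, "drop_rows")
  tabcnn.default(ds$features, ds$labels, ...)
}

#' @rdname tabcnn
#' @export
tabcnn.default <- function(x, y, encoding = encoding_config("combined"),
                           config = train_config(),
                           normalize_stats = "fit", ...) {
  ds <- tabular_dataset(as.matrix(x), y)
  if (any(ds$missing_mask)) ds <- handle_missing(ds, "drop_rows")
  if (is.matrix(normalize_stats)) {
    norm <- minmax_normalize(ds)   # validates; then override ranges
    norm$features <- apply_ranges(ds$features, normalize_stats)
    attr(norm, "ranges") <- normalize_stats
  } else {
    norm <- minmax_normalize(ds)
  }
  images <- encode_array(norm, encoding)
  arch <- build_architecture(dim(images)[1L], dim(images)[2L],
                             dim(images)[3L])
  fit <- train_cnn(images, norm$labels, arch, config)
  structure(list(fit = fit, encoding = encoding, arch = arch,
                 ranges = attr(norm, "ranges"),
                 field_names = ds$field_names,
                 n = n_records(ds), d = n_fields(ds),
                 config = config),
            class = "tabcnn")
}

#' @export
print.tabcnn <- function(x, ...) {
  cat(sprintf("tabcnn: %s encoding, %dx%dx%d images, %d records x %d fields\n",
              x$encoding$method, x$arch$input[1L], x$arch$input[2L],
              x$arch$input[3L], x$n, x$d))
  print(x$fit)
  invisible(x)
}

#' @export
summary.tabcnn <- function(object, ...) {
  cat("CNN classifier over image-encoded tabular records\n\n")
  print(object$arch)
  h <- object$fit$history
  cat(sprintf("\nTraining: %d steps (budget %d), final loss %.4f, ",
              object$fit$iterations_run, object$config$max_iterations,
              h$loss[nrow(h)]))
  cat(sprintf("training accuracy %.2f%%\n", 100 * h$accuracy[nrow(h)]))
  invisible(object)
}

#' @rdname tabcnn
#' @param object a fitted `tabcnn` model.
#' @param newdata matrix/data frame of records on the original feature
#'   scale (normalization ranges from the fit are replayed and values
#'   clipped to them).
#' @param type `"class"` for 0/1 labels, `"prob"` for benign-class
#'   probabilities.
#' @export
predict.tabcnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  feats <- as.matrix(newdata)
  if (ncol(feats) != object$d)
    stop("newdata must have ", object$d, " feature columns")
  feats <- apply_ranges(feats, object$ranges)
  ds <- tabular_dataset(feats, rep(0L, nrow(feats)),
                        field_names = object$field_names, normalized = TRUE)
  images <- encode_array(ds, object$encoding)
  predict(object$fit, images, type = type)
}

#' @export
plot.tabcnn <- function(x, ...) {
  h <- x$fit$history
  graphics::plot(h$step, h$loss, type = "b", xlab = "SGD step",
                 ylab = "training cross-entropy",
                 main = "tabcnn training history", ...)
  invisible(x)
}
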