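#' Build the 4-block VGG-style architecture for an image size
#'
#' Each of the four convolutional blocks holds a 3x3 same-padding
#' convolution, a ReLU and a 2x2 max pool of stride 2.  Block `L` has
#' `floor(0.5 * L * floor(sqrt(P)))` filters, where `P = h * w` is the
#' spatial pixel count of the input image — for a square image
#' `floor(sqrt(P))` is simply the side length.  The head flattens the last
#' block's activations into one hidden dense layer and a 2-way softmax
#' output.
#'
#' @param h,w input image height and width in pixels (at least 16 so that
#'   four 2x2 pools remain feasible).
#' @param c number of channels, 1 or 3.
#' @param dense_width width of the hidden dense layer.
#' @return an object of class `"cnn_architecture"` describing filters,
#'   spatial sizes per block and the classifier head.
#' @examples
#' build_architecture(32, 32, 1)$filters  # 16 32 48 64
#' @export
build_architecture <- function(h, w, c = 1L, dense_width = 64L) {
  h <- as.integer(h); w <- as.integer(w); c <- as.integer(c)
  if (!c %in% c(1L, 3L)) stop("channels must be 1 or 3")
  if (h < 16L || w < 16L)
    stop("image too small for four 2x2 pools; upscale the encoding ",
         "(need at least 16x16, got ", h, "x", w, ")")
  n_blocks <- 4L
  side <- floor(sqrt(h * w))
  filters <- vapply(seq_len(n_blocks),
                    function(l) as.integer(floor(0.5 * l * side)),
                    integer(1L))
  hh <- h; ww <- w
  trace <- matrix(0L, n_blocks, 2L, dimnames = list(NULL, c("h", "w")))
  for (b in seq_len(n_blocks)) {
    hh <- hh %/% 2L; ww <- ww %/% 2L
    trace[b, ] <- c(hh, ww)
  }
  if (hh < 1L || ww < 1L) stop("image too small for four 2x2 pools")
  structure(list(input = c(h, w, c), n_blocks = n_blocks,
                 kernel = c(3L, 3L), filters = filters,
                 spatial = trace, dense_width = as.integer(dense_width),
                 flat_dim = filters[n_blocks] * hh * ww),
            class = "cnn_architecture")
}

#' @export
print.cnn_architecture <- function(x, ...) {
  cat(sprintf("<cnn_architecture> input %dx%dx%d\n",
              x$input[1L], x$input[2L], x$input[3L]))
  for (b in seq_len(x$n_blocks))
    cat(sprintf("  block %d: conv 3x3 x%d + ReLU + maxpool 2x2/2 -> %dx%d\n",
                b, x$filters[b], x$spatial[b, 1L], x$spatial[b, 2L]))
  cat(sprintf("  head: flatten(%d) -> dense(%d) + ReLU -> softmax(2)\n",
              x$flat_dim, x$dense_width))
  invisible(x)
}

#' Training configuration
#'
#' Defaults are the package's standard settings for the breast-cancer
#' scale of problem: plain SGD with momentum 0.88, L2 penalty 9.4e-7,
#' mini-batches of 8, learning rate 0.02 and up to 1000 update steps.
#' Training may stop early once the full-training-set cross-entropy falls
#' below `early_stop_loss` (checked every `check_every` steps); set it to
#' 0 to always run the full budget.
#'
#' @param max_iterations mini-batch update steps.
#' @param attempts number of independent runs in [run_experiment()].
#' @param learning_rate SGD step size.
#' @param lr_decay per-step exponential decay of the learning rate
#'   (0 = constant rate).
#' @param momentum classical momentum coefficient.
#' @param l2 L2 regularization strength.
#' @param batch_size records per mini-batch.
#' @param early_stop_loss convergence threshold on training loss.
#' @param check_every steps between convergence checks.
#' @param seed integer seed controlling initialization and batch order.
#' @export
train_config <- function(max_iterations = 1000L, attempts = 30L,
                         learning_rate = 0.02, lr_decay = 0,
                         momentum = 0.88, l2 = 9.4e-7, batch_size = 8L,
                         early_stop_loss = 1e-3, check_every = 50L,
                         seed = 1L) {
  stopifnot(max_iterations >= 1L, attempts >= 1L, learning_rate > 0,
            momentum >= 0, momentum < 1, l2 >= 0, batch_size >= 1L,
            check_every >= 1L)
  structure(list(max_iterations = as.integer(max_iterations),
                 attempts = as.integer(attempts),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 momentum = momentum, l2 = l2,
                 batch_size = as.integer(batch_size),
                 early_stop_loss = early_stop_loss,
                 check_every = as.integer(check_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train the CNN on encoded images
#'
#' SGD with momentum on mini-batches sampled uniformly at random;
#' deterministic given `cfg$seed`.  Returns the fitted weights plus a
#' history of the mini-batch loss and accuracy at every logged step.
#'
#' @param images `(H, W, C, N)` array of encoded records with
#'   intensities in `[0, 1]`.
#' @param labels length-`N` 0/1 vector; both classes must be present.
#' @param arch a [build_architecture()] result matching the image shape.
#' @param cfg a [train_config()].
#' @return an object of class `"cnn_fit"` with elements `params`,
#'   `arch`, `history` (data frame of step, loss, accuracy) and
#'   `iterations_run`.
#' @export
train_cnn <- function(images, labels, arch, cfg = train_config()) {
  stopifnot(inherits(arch, "cnn_architecture"), inherits(cfg, "train_config"))
  labels <- as.integer(labels)
  n <- dim(images)[4L]
  if (length(labels) != n) stop("one label per image required")
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class")
  # engine layout is channel-first
  x <- aperm(images, c(3L, 1L, 2L, 4L))
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(cfg$seed)
  params <- init_params(arch)
  velocity <- lapply(params, function(p) p * 0)
  hist_step <- integer(0); hist_loss <- numeric(0); hist_acc <- numeric(0)
  iterations_run <- 0L
  for (it in seq_len(cfg$max_iterations)) {
    batch <- sample.int(n, min(cfg$batch_size, n))
    xb <- x[, , , batch, drop = FALSE]
    yb <- labels[batch]
    fw <- net_forward(xb, arch, params, keep = TRUE)
    grads <- net_backward(fw, yb, arch, params)
    lr <- cfg$learning_rate * if (cfg$lr_decay > 0)
      exp(-cfg$lr_decay * (it - 1L)) else 1
    for (nm in names(params)) {
      g <- grads[[nm]] + cfg$l2 * params[[nm]]
      velocity[[nm]] <- cfg$momentum * velocity[[nm]] - lr * g
      params[[nm]] <- params[[nm]] + velocity[[nm]]
    }
    iterations_run <- it
    if (it %% cfg$check_every == 0L || it == cfg$max_iterations) {
      probs <- net_predict_probs(x, arch, params)
      loss <- cross_entropy(probs, labels)
      acc <- mean((probs[2L, ] > 0.5) == (labels == 1L))
      hist_step <- c(hist_step, it)
      hist_loss <- c(hist_loss, loss)
      hist_acc <- c(hist_acc, acc)
      if (!is.finite(loss)) stop("training diverged (non-finite loss)")
      if (cfg$early_stop_loss > 0 && loss < cfg$early_stop_loss) break
    }
  }
  structure(list(params = params, arch = arch,
                 history = data.frame(step = hist_step, loss = hist_loss,
                                      accuracy = hist_acc),
                 iterations_run = iterations_run, config = cfg),
            class = "cnn_fit")
}

#' @export
print.cnn_fit <- function(x, ...) {
  last <- nrow(x$history)
  cat(sprintf("<cnn_fit> %d steps; final training loss %.4f, accuracy %.1f%%\n",
              x$iterations_run, x$history$loss[last],
              100 * x$history$accuracy[last]))
  invisible(x)
}

#' Predict class probabilities or labels from a fitted CNN
#'
#' @param object a `cnn_fit`.
#' @param images `(H, W, C, N)` array shaped like the training images.
#' @param type `"prob"` for benign-class probabilities, `"class"` for 0/1
#'   labels.
#' @param ... unused.
#' @export
predict.cnn_fit <- function(object, images, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- aperm(images, c(3L, 1L, 2L, 4L))
  probs <- net_predict_probs(x, object$arch, object$params)
  if (type == "prob") probs[2L, ] else as.integer(probs[2L, ] > 0.5)
}
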