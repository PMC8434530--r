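#' Network configuration for an LSTM stage
#'
#' Both detection stages share one topology: an LSTM layer, dropout, a dense
#' ReLU layer, dropout, and a softmax output over three classes. The default
#' sizes are the full-scale ones (150 LSTM units, 30 dense units, dropout
#' 0.5, Adam); stage 1 trains for 50 epochs and stage 2 for 100, so the
#' `epochs` default is per-stage and set by the caller.
#'
#' @param lstm_units Number of LSTM units.
#' @param dense_units Number of units in the dense ReLU layer.
#' @param dropout Dropout fraction applied after the LSTM and dense layers
#'   during training, in `[0, 1)`.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed controlling weight initialization, dropout masks
#'   and minibatch shuffling; a fixed seed gives bit-reproducible training.
#' @return A list of class `net_config`.
#' @export
net_config <- function(lstm_units = 150, dense_units = 30, dropout = 0.5,
                       epochs = 50, batch_size = 256, learning_rate = 1e-3,
                       seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1, epochs >= 1, lstm_units >= 1,
            dense_units >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(lstm_units = as.integer(lstm_units),
                 dense_units = as.integer(dense_units),
                 dropout = dropout, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "net_config")
}

#' Train an LSTM window classifier
#'
#' Fits the sequence-to-one classifier on an array of windows. Training is
#' single-threaded and fully seeded, so repeated calls with identical inputs
#' and configuration produce identical weights.
#'
#' @param x Numeric array of shape `(n_windows, n_channels, n_timesteps)`.
#' @param y Labels: factor or character vector of length `n_windows`.
#' @param config A [net_config()].
#' @param classes Class order for the softmax output; defaults to the sorted
#'   unique labels.
#' @return An object of class `sdb_lstm` with elements `params` (weights),
#'   `classes`, `config` and `history` (per-epoch loss and accuracy).
#' @export
train_lstm <- function(x, y, config = net_config(), classes = NULL) {
  stopifnot(is.array(x), length(dim(x)) == 3)
  if (is.null(classes)) classes <- sort(unique(as.character(y)))
  y <- as.character(y)
  if (dim(x)[1] == 0L || length(y) == 0L) stop("empty training set")
  if (!all(y %in% classes)) stop("labels outside the declared class set")
  if (length(unique(y)) < 2L)
    stop("degenerate training set: only class '", unique(y), "' present")
  y_idx <- match(y, classes) - 1L
  params <- .lstm_init(dim(x)[2], config$lstm_units, config$dense_units,
                       length(classes), config$seed)
  fit <- .lstm_train(params, x, y_idx, config$epochs, config$batch_size,
                     config$learning_rate, config$dropout, config$seed)
  structure(list(params = fit$params, classes = classes, config = config,
                 history = data.frame(epoch = seq_len(config$epochs),
                                      loss = fit$loss,
                                      accuracy = fit$accuracy)),
            class = "sdb_lstm")
}

#' Predict class probabilities for windows
#'
#' @param object A fitted `sdb_lstm`.
#' @param x Array of shape `(n_windows, n_channels, n_timesteps)` matching
#'   the training dimensions.
#' @param ... Unused.
#' @return Matrix `n_windows x n_classes` of softmax probabilities, columns
#'   named by class; each row sums to 1.
#' @export
predict.sdb_lstm <- function(object, x, ...) {
  stopifnot(is.array(x), length(dim(x)) == 3)
  if (dim(x)[1] == 0L)
    return(matrix(numeric(0), 0, length(object$classes),
                  dimnames = list(NULL, object$classes)))
  p <- .lstm_predict(object$params, x, 512L)
  colnames(p) <- object$classes
  p
}

#' @export
print.sdb_lstm <- function(x, ...) {
  cat("<sdb_lstm>", x$config$lstm_units, "LSTM units ->",
      x$config$dense_units, "dense ->", length(x$classes),
      "classes (", paste(x$classes, collapse = ", "), ")\n")
  cat("  final training accuracy:",
      round(tail(x$history$accuracy, 1), 4), "\n")
  invisible(x)
}

#' @importFrom utils tail
NULL
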