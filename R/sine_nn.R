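# Shallow neural-network classifier over multiple-frequency sine mappings
# of interval triples: input -> ReLU hidden layer -> linear 3-class output,
# squared loss against one-hot targets, trained by gradient descent.

#' Multiple-frequency sine feature map
#'
#' Maps an interval triple to `sin(2 * pi * f_k * rr_j)` for each of `K`
#' frequencies and each of the three intervals, plus (by default) the three
#' linear terms `rr_j / axis_max` that make the map injective on the grid
#' domain. Default frequencies are dyadic: periods `base_period * 2^k`,
#' `k = 0..K-1`, spanning 75-9600 ms.
#'
#' @param n_freq Number of sine frequencies `K` (default 8).
#' @param base_period Shortest period in ms (default 75).
#' @param include_linear Append the linear `rr / axis_max` terms.
#' @param axis_max Scale for the linear terms (ms).
#' @return Object of class `sine_feature_map` with `freqs` (cycles/ms),
#'   `periods`, `include_linear`, `axis_max` and `n_features`.
#' @export
sine_feature_map <- function(n_freq = 8, base_period = 75,
                             include_linear = TRUE, axis_max = 6000) {
  periods <- base_period * 2^(seq_len(n_freq) - 1)
  structure(
    list(freqs = 1 / periods, periods = periods,
         include_linear = include_linear, axis_max = axis_max,
         n_features = 3L * (n_freq + as.integer(include_linear))),
    class = "sine_feature_map")
}

#' Featurize interval triples
#'
#' @param triples Triple matrix (columns `rr1`, `rr2`, `rr3`) or a single
#'   length-3 vector; intervals are not clipped.
#' @param map A [sine_feature_map()].
#' @return Numeric matrix, one row per triple, `map$n_features` columns:
#'   for each interval slot the `K` sine features, then the linear terms.
#' @export
featurize <- function(triples, map = sine_feature_map()) {
  if (is.null(dim(triples))) triples <- matrix(triples, nrow = 1)
  n <- nrow(triples)
  blocks <- lapply(1:3, function(j) {
    outer(triples[, j], map$freqs, function(rr, f) sin(2 * pi * f * rr))
  })
  X <- do.call(cbind, blocks)
  if (map$include_linear) X <- cbind(X, triples / map$axis_max)
  X
}

relu <- function(z) z * (z > 0)

nn_forward <- function(params, X) {
  Z1 <- sweep(X %*% params$W1, 2, params$b1, "+")
  A <- relu(Z1)
  Y <- sweep(A %*% params$W2, 2, params$b2, "+")
  list(Z1 = Z1, A = A, Y = Y)
}

# Mean over samples of the summed squared output error, plus its analytic
# gradient; the independent finite-difference check lives in the test suite.
nn_loss_grad <- function(params, X, Target) {
  n <- nrow(X)
  fw <- nn_forward(params, X)
  E <- fw$Y - Target
  loss <- sum(E^2) / n
  dY <- 2 * E / n
  dW2 <- crossprod(fw$A, dY)
  db2 <- colSums(dY)
  dA <- dY %*% t(params$W2)
  dZ1 <- dA * (fw$Z1 > 0)
  dW1 <- crossprod(X, dZ1)
  db1 <- colSums(dZ1)
  list(loss = loss,
       grad = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

cohort_triples <- function(cohort) {
  labs <- character(0)
  trs <- list()
  for (rec in cohort) {
    series <- if (inherits(rec, "rr_series")) rec else rec[[1]]
    lab <- if (inherits(rec, "rr_series")) rec$label else rec[[2]]
    if (is.null(lab)) stop("every training recording needs a label", call. = FALSE)
    tr <- extract_triples(series)
    if (!nrow(tr)) next
    trs[[length(trs) + 1L]] <- tr
    labs <- c(labs, rep(lab, nrow(tr)))
  }
  list(triples = do.call(rbind, trs), labels = labs)
}

#' Train the sine-feature neural network
#'
#' Fits a three-layer network (input, ReLU hidden, linear output) over
#' sine-mapped triples by gradient descent on the squared loss against
#' one-hot diagnosis targets. Weights are randomly initialised from the
#' seed, so training is exactly reproducible.
#'
#' @param x Triple matrix with `labels` supplied, or a labelled cohort
#'   (list of labelled [rr_series()]) from which triples are pooled.
#' @param labels Diagnosis label per triple (when `x` is a matrix).
#' @param map A [sine_feature_map()].
#' @param hidden Hidden-layer width (default 64).
#' @param lr Learning rate (default 0.05).
#' @param epochs Gradient-descent steps over the data (default 400).
#' @param batch_size Minibatch size; `Inf` (default) is full-batch descent.
#' @param seed Integer seed for initialisation and batch shuffling.
#' @return Object of class `sine_nn_model` with weights, the feature map,
#'   hyperparameters, seed, class levels and the per-epoch `loss` trajectory.
#' @export
train_nn <- function(x, labels = NULL, map = sine_feature_map(), hidden = 64,
                     lr = 0.05, epochs = 400, batch_size = Inf, seed = 1) {
  if (is.list(x) && !is.data.frame(x)) {
    ct <- cohort_triples(x)
    x <- ct$triples
    labels <- ct$labels
  }
  classes <- diagnosis_levels()
  if (!all(labels %in% classes)) stop("unknown diagnosis label", call. = FALSE)
  if (length(labels) != nrow(x)) {
    stop("one label per triple required", call. = FALSE)
  }
  X <- featurize(x, map)
  n <- nrow(X)
  d <- ncol(X)
  Target <- matrix(0, n, 3)
  Target[cbind(seq_len(n), match(labels, classes))] <- 1

  set.seed(seed)
  params <- list(
    W1 = matrix(stats::rnorm(d * hidden, sd = sqrt(2 / d)), d, hidden),
    b1 = rep(0, hidden),
    W2 = matrix(stats::rnorm(hidden * 3, sd = sqrt(2 / hidden)), hidden, 3),
    b2 = rep(0, 3))

  loss_traj <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    if (!is.finite(batch_size) || batch_size >= n) {
      lg <- nn_loss_grad(params, X, Target)
      loss_traj[ep] <- lg$loss
      for (nm in names(params)) {
        params[[nm]] <- params[[nm]] - lr * lg$grad[[nm]]
      }
    } else {
      ord <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      bl <- numeric(length(starts))
      for (b in seq_along(starts)) {
        idx <- ord[starts[b]:min(starts[b] + batch_size - 1, n)]
        lg <- nn_loss_grad(params, X[idx, , drop = FALSE],
                           Target[idx, , drop = FALSE])
        bl[b] <- lg$loss
        for (nm in names(params)) {
          params[[nm]] <- params[[nm]] - lr * lg$grad[[nm]]
        }
      }
      loss_traj[ep] <- mean(bl)
    }
    if (!is.finite(loss_traj[ep])) {
      stop(sprintf("training diverged (non-finite loss) at epoch %d", ep),
           call. = FALSE)
    }
  }
  structure(
    c(params,
      list(map = map, class_levels = classes, loss = loss_traj,
           hyper = list(hidden = hidden, lr = lr, epochs = epochs,
                        batch_size = batch_size),
           seed = seed)),
    class = "sine_nn_model")
}

#' @export
print.sine_nn_model <- function(x, ...) {
  cat(sprintf(paste0("<sine_nn_model> %d sine freqs + %s, hidden %d; ",
                     "final loss %.4f after %d epochs (seed %d)\n"),
              length(x$map$freqs),
              if (x$map$include_linear) "linear terms" else "no linear terms",
              x$hyper$hidden, x$loss[length(x$loss)], x$hyper$epochs, x$seed))
  invisible(x)
}

#' Predict diagnoses for interval triples
#'
#' The network always commits to a class (argmax of the raw output
#' scores): unlike the density grid it extrapolates to regions never seen
#' in training rather than abstaining.
#'
#' @param object A trained [train_nn()] model.
#' @param triples Triple matrix or length-3 vector.
#' @param type `"class"` for labels, `"scores"` for the raw 3-column
#'   output matrix.
#' @param ... Unused.
#' @return Character labels, or a numeric score matrix.
#' @export
predict.sine_nn_model <- function(object, triples, type = c("class", "scores"),
                                  ...) {
  type <- match.arg(type)
  if (is.null(dim(triples))) triples <- matrix(triples, nrow = 1)
  X <- featurize(triples, object$map)
  Y <- nn_forward(object, X)$Y
  colnames(Y) <- object$class_levels
  if (type == "scores") return(Y)
  object$class_levels[max.col(Y, ties.method = "first")]
}

#' Classify a recording with the neural network
#'
#' Same rolling three-position appraisal as [classify_series()], but the
#' network votes on every triple, so no interval is left undecided.
#'
#' @param model A trained [train_nn()] model.
#' @param series [rr_series()] with at least 3 intervals.
#' @return A `classification_result` (the `NO_DECISION` fraction is always
#'   0).
#' @export
classify_series_nn <- function(model, series) {
  n <- length(series$intervals)
  if (n < 3L) stop("need at least 3 intervals to classify", call. = FALSE)
  lab <- predict(model, extract_triples(series))
  make_classification_result(rolling_vote(lab, n, model$class_levels),
                             model$class_levels)
}

#' Persist and restore a sine-feature network model
#'
#' JSON container holding the feature map, weights, hyperparameters and
#' training seed.
#'
#' @param model A `sine_nn_model`.
#' @param path File path.
#' @return `write_nn_model()` returns `path` invisibly; `read_nn_model()`
#'   the restored model.
#' @export
write_nn_model <- function(model, path) {
  obj <- list(
    type = "sine_nn_model",
    map = list(freqs = model$map$freqs,
               include_linear = model$map$include_linear,
               axis_max = model$map$axis_max),
    class_levels = model$class_levels,
    W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
    hyper = model$hyper, seed = model$seed,
    final_loss = model$loss[length(model$loss)])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nn_model
#' @export
read_nn_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "sine_nn_model")) {
    stop("not a neural-network model file", call. = FALSE)
  }
  freqs <- as.numeric(obj$map$freqs)
  map <- structure(
    list(freqs = freqs, periods = 1 / freqs,
         include_linear = isTRUE(obj$map$include_linear),
         axis_max = obj$map$axis_max,
         n_features = 3L * (length(freqs) + as.integer(isTRUE(obj$map$include_linear)))),
    class = "sine_feature_map")
  hidden <- length(obj$b1)
  structure(
    list(W1 = matrix(as.numeric(obj$W1), ncol = hidden),
         b1 = as.numeric(obj$b1),
         W2 = matrix(as.numeric(obj$W2), nrow = hidden),
         b2 = as.numeric(obj$b2),
         map = map, class_levels = obj$class_levels,
         loss = as.numeric(obj$final_loss),
         hyper = obj$hyper, seed = obj$seed),
    class = "sine_nn_model")
}
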