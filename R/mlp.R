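## Weighted-cross-entropy MLP for infiltrated vs natural protruding
## regions, plus the rule-based decision for non-protruding segments.

#' Weighted binary cross-entropy loss
#'
#' `-w * y * log(yhat) - (1 - y) * log(1 - yhat)`, elementwise. The class
#' weight `w` up-weights the (rarer) positive class; `w = 1` recovers plain
#' binary cross-entropy. Predictions are clamped away from 0 and 1 before
#' the logarithm.
#'
#' @param y Ground-truth labels in \{0, 1\}.
#' @param y_hat Predicted probabilities in (0, 1).
#' @param w Positive class weight (> 0), default 3.
#' @return Numeric loss, same length as `y`.
#' @export
wce_loss <- function(y, y_hat, w = 3) {
  stopifnot(all(y %in% c(0, 1)), w > 0)
  y_hat <- pmin(pmax(y_hat, 1e-12), 1 - 1e-12)
  -w * y * log(y_hat) - (1 - y) * log(1 - y_hat)
}

relu <- function(x) x * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

mlp_feature_names <- paste0("f", 1:12)

#' Train the region-classification MLP
#'
#' A 12-16-8-1 multilayer perceptron (rectified-linear hidden units,
#' sigmoid output) trained with full-batch adaptive-moment gradient descent
#' on the weighted cross-entropy loss ([wce_loss()]). Features are
#' z-standardised from the training data; the standardisation is stored in
#' the model. Rows with missing features are dropped (and counted); the
#' seed makes training reproducible.
#'
#' @param features Data frame or matrix with the 12 protruding-region
#'   features (columns `f1`..`f12`).
#' @param labels 0/1 vector (1 = infiltrated), one per row.
#' @param w Positive class weight in the loss, default 3.
#' @param seed Integer RNG seed for weight initialisation.
#' @param hidden Hidden layer widths, default c(16, 8).
#' @param lr Learning rate, default 1e-3.
#' @param epochs Full-batch epochs, default 500.
#' @return An object of class `wce_mlp` with the weights, standardisation,
#'   loss trace, and training metadata.
#' @export
train_mlp <- function(features, labels, w = 3, seed = 1L,
                      hidden = c(16L, 8L), lr = 1e-3, epochs = 500L) {
  X <- as.matrix(as.data.frame(features)[, mlp_feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  y <- as.numeric(labels)
  stopifnot(length(y) == nrow(X))
  ok <- stats::complete.cases(X) & is.finite(y)
  n_dropped <- sum(!ok)
  if (n_dropped) message(sprintf("train_mlp: dropped %d rows with missing features", n_dropped))
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  if (!all(is.finite(X))) stop("non-finite feature values in rows: ",
                               paste(head(which(!apply(is.finite(X), 1, all))), collapse = ", "))
  center <- colMeans(X)
  scale_sd <- apply(X, 2, sd)
  scale_sd[scale_sd == 0 | !is.finite(scale_sd)] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale_sd, "/")
  n <- nrow(Z); p <- ncol(Z)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  init <- function(fan_in, fan_out) {
    matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
  }
  dims <- c(p, hidden, 1L)
  W <- lapply(seq_len(length(dims) - 1L), function(i) init(dims[i], dims[i + 1L]))
  b <- lapply(dims[-1], function(d) rep(0, d))
  mW <- lapply(W, function(x) x * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  trace <- numeric(epochs)
  nlayer <- length(W)
  for (ep in seq_len(epochs)) {
    # forward
    A <- vector("list", nlayer + 1L); A[[1]] <- Z
    for (l in seq_len(nlayer)) {
      pre <- A[[l]] %*% W[[l]] + matrix(b[[l]], n, length(b[[l]]), byrow = TRUE)
      A[[l + 1L]] <- if (l < nlayer) relu(pre) else pre   # final layer: logits
    }
    z_out <- A[[nlayer + 1L]][, 1]
    # numerically stable WCE on logits
    trace[ep] <- mean(w * y * softplus(-z_out) + (1 - y) * softplus(z_out))
    # backward
    yhat <- sigmoid(z_out)
    delta <- matrix((w * y + (1 - y)) * yhat - w * y, n, 1) / n
    for (l in rev(seq_len(nlayer))) {
      gW <- crossprod(A[[l]], delta)
      gb <- colSums(delta)
      if (l > 1L) delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      mhW <- mW[[l]] / (1 - beta1^ep); vhW <- vW[[l]] / (1 - beta2^ep)
      mhb <- mb[[l]] / (1 - beta1^ep); vhb <- vb[[l]] / (1 - beta2^ep)
      W[[l]] <- W[[l]] - lr * mhW / (sqrt(vhW) + eps)
      b[[l]] <- b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
  }
  structure(list(
    weights = W, biases = b, hidden = hidden,
    center = center, scale_sd = scale_sd,
    w = w, seed = as.integer(seed), lr = lr, epochs = epochs,
    loss_trace = trace, n_train = n, n_dropped = n_dropped,
    feature_names = mlp_feature_names
  ), class = "wce_mlp")
}

mlp_forward <- function(model, Z) {
  n <- nrow(Z)
  A <- Z
  nlayer <- length(model$weights)
  for (l in seq_len(nlayer)) {
    A <- A %*% model$weights[[l]] +
      matrix(model$biases[[l]], n, length(model$biases[[l]]), byrow = TRUE)
    if (l < nlayer) A <- relu(A)
  }
  sigmoid(A[, 1])
}

#' @export
print.wce_mlp <- function(x, ...) {
  cat(sprintf("<wce_mlp: %d-%s-1, w = %g, trained %d epochs on %d rows (final loss %.4f)>\n",
              length(x$feature_names), paste(x$hidden, collapse = "-"),
              x$w, x$epochs, x$n_train, tail(x$loss_trace, 1)))
  invisible(x)
}

#' @export
summary.wce_mlp <- function(object, ...) {
  cat("Weighted cross-entropy MLP region classifier\n")
  cat(sprintf("  architecture : %d -> %s -> 1 (ReLU hidden, sigmoid output)\n",
              length(object$feature_names), paste(object$hidden, collapse = " -> ")))
  cat(sprintf("  class weight : %g\n", object$w))
  cat(sprintf("  optimisation : Adam, lr %g, %d full-batch epochs, seed %d\n",
              object$lr, object$epochs, object$seed))
  cat(sprintf("  training     : %d rows (%d dropped for missing features)\n",
              object$n_train, object$n_dropped))
  cat(sprintf("  loss trace   : %.4f -> %.4f\n",
              object$loss_trace[1], tail(object$loss_trace, 1)))
  invisible(object)
}

#' Predict infiltration probabilities with a trained MLP
#'
#' @param object A `wce_mlp` model.
#' @param newdata Data frame or matrix with columns `f1`..`f12`. Missing
#'   values are imputed at the training means (z = 0).
#' @param type `"prob"` (default) or `"class"` (threshold 0.5).
#' @param ... Unused.
#' @return Numeric probabilities or 0/1 labels.
#' @export
predict.wce_mlp <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale_sd, "/")
  Z[!is.finite(Z)] <- 0
  p <- mlp_forward(object, Z)
  if (type == "class") as.integer(p >= 0.5) else p
}

#' @export
plot.wce_mlp <- function(x, ...) {
  plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
       xlab = "epoch", ylab = "mean WCE loss",
       main = sprintf("training loss (w = %g)", x$w), ...)
  invisible(x)
}

#' Serialize / restore a trained MLP as JSON
#'
#' @param model A `wce_mlp`.
#' @param path Output (input) JSON path.
#' @return `write_mlp` returns `path` invisibly; `read_mlp` the model.
#' @export
write_mlp <- function(model, path) {
  obj <- unclass(model)
  obj$weights <- lapply(obj$weights, function(m) list(dim = dim(m), data = as.vector(m)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$weights <- lapply(seq_len(nrow(as.data.frame(obj$weights$dim))), function(i) NULL)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  obj$weights <- lapply(raw$weights, function(wl) {
    matrix(unlist(wl$data), unlist(wl$dim)[1], unlist(wl$dim)[2])
  })
  obj$biases <- lapply(raw$biases, function(b) unlist(b))
  obj$center <- unlist(raw$center); names(obj$center) <- mlp_feature_names
  obj$scale_sd <- unlist(raw$scale_sd); names(obj$scale_sd) <- mlp_feature_names
  obj$feature_names <- unlist(raw$feature_names)
  structure(obj, class = "wce_mlp")
}

#' Classify proposed regions
#'
#' Protruding regions are scored by the MLP (infiltrated when the
#' probability reaches 0.5). Non-protruding segments follow the rule:
#' infiltrated when at least one enclosing lymphocyte projects onto the
#' segment (`count_numerator >= 1`).
#'
#' @param model A trained `wce_mlp`.
#' @param feature_table Feature table from [region_features()] (or rows of
#'   several portals bound together).
#' @return The table augmented with `probability`, `label`
#'   (`"infiltrated"`/`"natural"`) and `rule_applied`.
#' @export
predict_regions <- function(model, feature_table) {
  ft <- feature_table
  ft$probability <- NA_real_
  ft$label <- NA_character_
  ft$rule_applied <- NA_character_
  prot <- ft$kind == "protruding"
  if (any(prot)) {
    p <- predict(model, ft[prot, , drop = FALSE], type = "prob")
    ft$probability[prot] <- p
    ft$label[prot] <- ifelse(p >= 0.5, "infiltrated", "natural")
    ft$rule_applied[prot] <- "mlp"
  }
  np <- ft$kind == "non_protruding"
  if (any(np)) {
    ft$label[np] <- ifelse(ft$count_numerator[np] >= 1L, "infiltrated", "natural")
    ft$rule_applied[np] <- "nonprotruding_rule"
  }
  ft
}
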