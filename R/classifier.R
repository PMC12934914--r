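#' Ideation classifier settings
#'
#' A two-hidden-layer feed-forward multinomial classifier trained by
#' full-batch Adam on the softmax cross-entropy with a small L2 penalty.
#'
#' @param hidden_layers widths of the two hidden layers (default 16, 8).
#' @param max_epochs training epochs (full-batch updates).
#' @param learning_rate Adam step size.
#' @param l2 L2 penalty on weights (not biases).
#' @param train_fraction fraction of participants in the training split
#'   (stratified by class), default 0.7.
#' @param cv_folds folds for cross-validated accuracy on the training
#'   portion (default 10); 0 skips cross-validation.
#' @param n_ensemble number of independently initialized networks whose
#'   softmax outputs are averaged (default 3); averaging removes most of the
#'   initialization variance of a small network.
#' @param seed integer seed (initialization and splits).
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(hidden_layers = c(16, 8), max_epochs = 800,
                            learning_rate = 0.02, l2 = 1e-4,
                            train_fraction = 0.7, cv_folds = 10,
                            n_ensemble = 3, seed = 1) {
  if (length(hidden_layers) != 2)
    stop("the classifier uses exactly two hidden layers")
  stopifnot(train_fraction > 0, train_fraction < 1, cv_folds >= 0,
            n_ensemble >= 1)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, l2 = l2,
                 train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds),
                 n_ensemble = as.integer(n_ensemble),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

# --- minimal two-hidden-layer MLP with logistic activations and softmax ----

mlp_init <- function(p, h, K) {
  glorot <- function(nin, nout)
    matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)),
           nin, nout)
  list(W1 = glorot(p, h[1]), b1 = rep(0, h[1]),
       W2 = glorot(h[1], h[2]), b2 = rep(0, h[2]),
       W3 = glorot(h[2], K), b3 = rep(0, K))
}

mlp_forward <- function(par, X) {
  A1 <- stats::plogis(sweep(X %*% par$W1, 2, par$b1, "+"))
  A2 <- stats::plogis(sweep(A1 %*% par$W2, 2, par$b2, "+"))
  Z3 <- sweep(A2 %*% par$W3, 2, par$b3, "+")
  Z3 <- sweep(Z3, 1, apply(Z3, 1, max), "-")
  P <- exp(Z3)
  P <- P / rowSums(P)
  list(A1 = A1, A2 = A2, P = P)
}

mlp_grad <- function(par, X, Y, l2) {
  n <- nrow(X)
  fw <- mlp_forward(par, X)
  D3 <- (fw$P - Y) / n
  D2 <- (D3 %*% t(par$W3)) * fw$A2 * (1 - fw$A2)
  D1 <- (D2 %*% t(par$W2)) * fw$A1 * (1 - fw$A1)
  list(W1 = t(X) %*% D1 + l2 * par$W1, b1 = colSums(D1),
       W2 = t(fw$A1) %*% D2 + l2 * par$W2, b2 = colSums(D2),
       W3 = t(fw$A2) %*% D3 + l2 * par$W3, b3 = colSums(D3))
}

mlp_train_ensemble <- function(X, Y, spec) {
  lapply(seq_len(spec$n_ensemble), function(k)
    mlp_train(X, Y, spec$hidden_layers, spec$max_epochs,
              spec$learning_rate, spec$l2))
}

mlp_predict_ensemble <- function(pars, X, classes) {
  P <- Reduce(`+`, lapply(pars, function(p) mlp_forward(p, X)$P))
  classes[max.col(P, ties.method = "first")]
}

mlp_train <- function(X, Y, h, epochs, lr, l2) {
  par <- mlp_init(ncol(X), h, ncol(Y))
  m <- lapply(par, function(w) w * 0)
  v <- lapply(par, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    g <- mlp_grad(par, X, Y, l2)
    for (k in names(par)) {
      m[[k]] <- b1 * m[[k]] + (1 - b1) * g[[k]]
      v[[k]] <- b2 * v[[k]] + (1 - b2) * g[[k]]^2
      mhat <- m[[k]] / (1 - b1^t)
      vhat <- v[[k]] / (1 - b2^t)
      par[[k]] <- par[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  par
}

# Stratified assignment of indices to `k` groups, balanced within class.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train the suicidal-ideation classifier
#'
#' Small ensemble of two-hidden-layer multinomial neural networks (averaged
#' softmax) predicting the ordinal ideation level from the 30 item scores.
#' Accuracy is estimated honestly before the final fit: participants are
#' split 70/30 (stratified by class), cross-validated accuracy comes from
#' k-fold CV within the training portion, and held-out accuracy from
#' applying the 70%-trained ensemble to the remaining 30%. The returned
#' predictor is then refit on the full baseline sample, the model actually
#' deployed on post-intervention profiles.
#'
#' @param items participants x items matrix (T0 profiles).
#' @param ideation integer outcome levels.
#' @param spec a [classifier_spec()].
#' @return object of class `ideation_classifier`: list with the fitted
#'   parameters, class levels, feature scaling, `cv_accuracy`,
#'   `test_accuracy`, and the index of the held-out participants.
#' @export
train_classifier <- function(items, ideation, spec = classifier_spec()) {
  X <- as.matrix(items)
  y <- as.integer(ideation)
  classes <- sort(unique(y))
  if (length(classes) < 2)
    stop("need at least 2 ideation classes to train a classifier")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  # stratified 70/30 split
  test_idx <- integer(0)
  for (cls in classes) {
    idx <- sample(which(y == cls))
    n_test <- floor(length(idx) * (1 - spec$train_fraction))
    test_idx <- c(test_idx, idx[seq_len(n_test)])
  }
  train_idx <- setdiff(seq_along(y), test_idx)
  ytr <- y[train_idx]
  if (spec$cv_folds > 0 && any(table(ytr) < 2))
    stop("stratification error: class(es) ",
         paste(names(which(table(ytr) < 2)), collapse = ", "),
         " would be absent from some cross-validation training folds")
  ctr <- colMeans(X[train_idx, , drop = FALSE])
  scl <- apply(X[train_idx, , drop = FALSE], 2, stats::sd)
  scl[scl == 0] <- 1
  scale_x <- function(M) sweep(sweep(M, 2, ctr), 2, scl, "/")
  onehot <- function(yy) {
    Y <- matrix(0, length(yy), length(classes))
    Y[cbind(seq_along(yy), match(yy, classes))] <- 1
    Y
  }
  Xtr <- scale_x(X[train_idx, , drop = FALSE])
  cv_accuracy <- NA_real_
  if (spec$cv_folds > 0) {
    fold <- stratified_folds(ytr, spec$cv_folds)
    acc <- numeric(spec$cv_folds)
    for (f in seq_len(spec$cv_folds)) {
      tr <- fold != f
      pars_f <- mlp_train_ensemble(Xtr[tr, , drop = FALSE], onehot(ytr[tr]),
                                   spec)
      pred <- mlp_predict_ensemble(pars_f, Xtr[!tr, , drop = FALSE],
                                   classes)
      acc[f] <- mean(pred == ytr[!tr])
    }
    cv_accuracy <- mean(acc)
  }
  test_accuracy <- NA_real_
  if (length(test_idx)) {
    pars_tr <- mlp_train_ensemble(Xtr, onehot(ytr), spec)
    pred <- mlp_predict_ensemble(pars_tr, scale_x(X[test_idx, , drop = FALSE]),
                                 classes)
    test_accuracy <- mean(pred == y[test_idx])
  }
  # final predictor: refit on the full baseline sample
  pars <- mlp_train_ensemble(scale_x(X), onehot(y), spec)
  structure(list(pars = pars, classes = classes, center = ctr,
                 scale = scl, spec = spec,
                 cv_accuracy = cv_accuracy,
                 test_accuracy = test_accuracy,
                 test_idx = sort(test_idx)),
            class = "ideation_classifier")
}

#' Predict ideation levels for symptom profiles
#'
#' Argmax class of the trained classifier, on the original ideation scale.
#' Prediction is invariant to participant order and deterministic.
#'
#' @param model an `ideation_classifier`.
#' @param items participants x items matrix (values within the 1-7 scale
#'   range; continuous post-intervention severities are allowed).
#' @return integer vector of predicted ideation levels.
#' @export
predict_ideation <- function(model, items) {
  X <- as.matrix(items)
  if (anyNA(X) || any(X < 1) || any(X > 7))
    stop("item values outside the 1-7 scale range")
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  mlp_predict_ensemble(model$pars, Xs, model$classes)
}

#' @export
print.ideation_classifier <- function(x, ...) {
  cat(sprintf(
    "ideation classifier (%d-%d hidden units): cv accuracy %.3f, held-out %.3f\n",
    x$spec$hidden_layers[1], x$spec$hidden_layers[2],
    x$cv_accuracy, x$test_accuracy))
  invisible(x)
}

#' Per-arm ideation level frequencies
#'
#' @param pred integer predicted (or observed) levels.
#' @param levels level set for the table (default 0-5).
#' @return named proportions summing to 1.
#' @export
ideation_frequencies <- function(pred, levels = 0:5) {
  tab <- table(factor(pred, levels = levels))
  stats::setNames(as.numeric(tab) / length(pred), levels)
}
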