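# Shared linear max-margin fitting for the acoustic and skin-color
# detectors: feature standardization + a linear soft-margin SVM with
# class weights inversely proportional to class size.

fit_linear_classifier <- function(pos, neg, C = 1) {
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1)
  if (is.null(dim(neg))) neg <- matrix(neg, nrow = 1)
  if (nrow(pos) == 0L || nrow(neg) == 0L) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  check_positive(C, "C")
  X <- rbind(pos, neg)
  y <- factor(rep(c("pos", "neg"), c(nrow(pos), nrow(neg))),
              levels = c("pos", "neg"))
  mu <- colMeans(X)
  sc <- apply(X, 2, sd)
  sc[!is.finite(sc) | sc == 0] <- 1   # zero-variance dimensions
  Z <- sweep(sweep(X, 2, mu), 2, sc, "/")
  n <- nrow(Z)
  cw <- c(pos = n / (2 * nrow(pos)), neg = n / (2 * nrow(neg)))
  fit <- e1071::svm(Z, y, kernel = "linear", cost = C, scale = FALSE,
                    class.weights = cw)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # align sign so the positive class scores positive on average
  scores <- drop(Z %*% w) + b
  if (mean(scores[y == "pos"]) < mean(scores[y == "neg"])) {
    w <- -w
    b <- -b
  }
  list(weights = w, bias = b, feature_means = mu, feature_scales = sc)
}

decision_values <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Z <- sweep(sweep(X, 2, model$feature_means), 2, model$feature_scales, "/")
  drop(Z %*% model$weights) + model$bias
}
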