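# Exact (O(n^2)) t-distributed stochastic neighbor embedding, adequate at
# cohort scale (hundreds of samples). Conditional probabilities are
# calibrated to the target perplexity by per-point binary search on the
# Gaussian precision; the embedding uses the standard heavy-tailed
# Student-t kernel with early exaggeration and momentum gradient descent.
.tsne <- function(X, perplexity = 30, seed = 1L, maxIter = 1000L,
                  eta = 200, exaggeration = 12, exagIter = 100L,
                  initSd = 1e-2) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  withSeed(seed, {
    Y <- matrix(rnorm(n * 2, sd = initSd), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    for (iter in seq_len(maxIter)) {
      ex <- if (iter <= exagIter) exaggeration else 1
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      M <- (ex * P - Q) * num
      grad <- 4 * (diag(rowSums(M)) - M) %*% Y
      momentum <- if (iter < 250L) 0.5 else 0.8
      gains <- pmax(ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8),
                    0.01)
      dY <- momentum * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}
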