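# Minimize || p - t(S) %*% w ||_2 over the probability simplex by
# accelerated projected gradient (FISTA). S is signatures x 96, p a
# normalized 96-vector. Small dimension (<= panel size), converges far
# below the reporting tolerance.
.simplexLS <- function(p, S, maxIter = 5000L, tol = 1e-12) {
  G <- S %*% t(S)
  b <- as.vector(S %*% p)
  L <- 2 * max(abs(eigen(G, symmetric = TRUE, only.values = TRUE)$values))
  if (L == 0) stop("degenerate signature matrix")
  k <- nrow(S)
  w <- rep(1 / k, k)
  y <- w
  tPrev <- 1
  for (i in seq_len(maxIter)) {
    grad <- 2 * (as.vector(G %*% y) - b)
    wNew <- projectSimplex(y - grad / L)
    tNew <- (1 + sqrt(1 + 4 * tPrev^2)) / 2
    y <- wNew + ((tPrev - 1) / tNew) * (wNew - w)
    if (max(abs(wNew - w)) < tol && i > 2L) { w <- wNew; break }
    w <- wNew
    tPrev <- tNew
  }
  w
}

#' Refit signature exposures by constrained least squares
#'
#' Per eligible sample, minimizes `|| p - w' S ||_2` over `w >= 0`,
#' `sum(w) = 1`, where `p` is the sample's normalized 96-channel frequency
#' vector and `S` the allowed rows of the reference panel. Exposures of
#' signatures outside `allowed` are exactly 0.
#'
#' @param catalogue a [MutationalCatalogue-class] or a samples x 96 count
#'   matrix.
#' @param signatures reference panel (signatures x 96, rows sum to 1).
#' @param allowed signature names permitted nonzero exposure (default:
#'   the full panel).
#' @param onlyEligible when `catalogue` is a [MutationalCatalogue-class],
#'   restrict to samples meeting its mutation filter (default `TRUE`).
#' @return A list of class `ExposureFit`: `exposures` (samples x full
#'   panel, rows sum to 1, disallowed columns identically 0),
#'   `reconstructionError` (per-sample L2 norm of the residual),
#'   `allowed`.
#' @export
refitExposures <- function(catalogue, signatures, allowed = NULL,
                           onlyEligible = TRUE) {
  .checkSignatureMatrix(signatures)
  counts <- if (methods::is(catalogue, "MutationalCatalogue")) {
    m <- catalogueCounts(catalogue)
    if (onlyEligible) m[eligibleSamples(catalogue), , drop = FALSE] else m
  } else catalogue
  if (!nrow(counts)) stop("no eligible samples to refit")
  if (is.null(allowed)) allowed <- rownames(signatures)
  if (!length(allowed)) stop("allowed signature set is empty")
  bad <- setdiff(allowed, rownames(signatures))
  if (length(bad))
    stop("allowed signature(s) not in panel: ", paste(bad, collapse = ", "))
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("all-zero catalogue row(s): ",
                          paste(rownames(counts)[tot == 0], collapse = ", "))
  S <- signatures[allowed, , drop = FALSE]
  expo <- matrix(0, nrow(counts), nrow(signatures),
                 dimnames = list(rownames(counts), rownames(signatures)))
  err <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    p <- counts[i, ] / tot[i]
    w <- .simplexLS(p, S)
    expo[i, allowed] <- w
    err[i] <- sqrt(sum((p - as.vector(w %*% S))^2))
  }
  structure(list(exposures = expo, reconstructionError = setNames(
    err, rownames(counts)), allowed = allowed), class = "ExposureFit")
}

#' @export
print.ExposureFit <- function(x, ...) {
  cat("ExposureFit: ", nrow(x$exposures), " samples, ",
      length(x$allowed), " allowed signatures (",
      paste(x$allowed, collapse = ", "), ")\n", sep = "")
  cat("  mean reconstruction error: ",
      signif(mean(x$reconstructionError), 4), "\n", sep = "")
  invisible(x)
}

#' Cohort-level signature selection rule
#'
#' Retains SBS1 and SBS5 unconditionally, every reference signature
#' cosine-matched by a de novo factor, and every signature whose mean
#' exposure across samples in the initial full-panel fit is at least
#' `threshold` (inclusive). When no stable de novo solution exists
#' (`denovo` is `NULL` or its chosen rank is none), the de novo term is
#' dropped and the rule falls back to SBS1, SBS5 and the mean-exposure
#' criterion alone.
#'
#' @param initialFit `ExposureFit` over the full reference panel.
#' @param signatures the reference panel.
#' @param denovo optional `DenovoSolution` from [extractDenovo()].
#' @param always signature names kept unconditionally.
#' @param threshold mean-exposure retention threshold (default 0.05).
#' @return Character vector of retained signature names, in panel order.
#' @export
selectSignatures <- function(initialFit, signatures, denovo = NULL,
                             always = c("SBS1", "SBS5"), threshold = 0.05) {
  .checkSignatureMatrix(signatures)
  keep <- intersect(always, rownames(signatures))
  meanExpo <- colMeans(initialFit$exposures)
  keep <- union(keep, names(meanExpo)[meanExpo >= threshold])
  if (!is.null(denovo) && !is.na(denovo$chosenK)) {
    matched <- matchSignatures(denovo$factors, signatures)$match
    keep <- union(keep, matched)
  }
  rownames(signatures)[rownames(signatures) %in% keep]
}

#' Match factors to reference signatures by cosine similarity
#'
#' @param factors K x 96 matrix of (de novo) signature profiles.
#' @param reference reference panel (signatures x 96).
#' @return `data.frame` with one row per factor: `factor`, `match` (best
#'   reference name; ties broken by signature-name order and flagged in
#'   `tie`), `cosine`.
#' @export
matchSignatures <- function(factors, reference) {
  .checkSignatureMatrix(reference)
  if (is.null(dim(factors))) factors <- matrix(factors, nrow = 1)
  res <- lapply(seq_len(nrow(factors)), function(i) {
    cs <- apply(reference, 1, cosineSim, y = factors[i, ])
    best <- max(cs)
    cand <- sort(names(cs)[cs == best])
    data.frame(factor = i, match = cand[1L], cosine = best,
               tie = length(cand) > 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# KL-NMF by multiplicative updates; V is channels x samples.
.nmfKL <- function(V, K, maxIter = 200L, tol = 1e-6) {
  eps <- 1e-10
  n <- nrow(V); m <- ncol(V)
  W <- matrix(runif(n * K, 0.1, 1), n, K)
  H <- matrix(runif(K * m, 0.1, 1), K, m)
  klPrev <- Inf
  for (it in seq_len(maxIter)) {
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / (matrix(rowSums(H), n, K, byrow = TRUE) + eps)
    WH <- W %*% H + eps
    H <- H * (t(W) %*% (V / WH)) / (matrix(colSums(W), K, m) + eps)
    if (it %% 10L == 0L) {
      WH <- W %*% H + eps
      kl <- sum(V * log((V + eps) / WH) - V + WH)
      if (abs(klPrev - kl) < tol * abs(klPrev)) break
      klPrev <- kl
    }
  }
  # normalize factors (columns of W) to probability profiles
  cs <- colSums(W)
  list(W = sweep(W, 2, cs, "/"), H = H * cs)
}

# silhouette-based stability of K clustered factors pooled over bootstrap
# runs. Clustering is run-matched: each bootstrap run contributes exactly
# one factor to each cluster (cosine-cost greedy assignment against the
# evolving centroids). This matters for redundant solutions — when a rank
# is too high the runs produce near-duplicate factors whose assignment is
# arbitrary, so the matched-partition silhouette collapses toward 0 and
# the rank is rejected, whereas unconstrained k-means would happily
# report a consistent micro-split.
.factorStability <- function(factors, runIds, K, seed) {
  X <- factors / sqrt(rowSums(factors^2))
  if (K == 1L) {
    centroid <- colMeans(X)
    s <- apply(X, 1, cosineSim, y = centroid)
    cons <- colMeans(factors)
    return(list(avg = mean(s), min = mean(s),
                consensus = matrix(cons / sum(cons), 1)))
  }
  runs <- unique(runIds)
  centroids <- X[runIds == runs[1L], , drop = FALSE]
  assign <- integer(nrow(X))
  for (it in 1:10) {
    for (r in runs) {
      idx <- which(runIds == r)
      cost <- 1 - X[idx, , drop = FALSE] %*% t(centroids)
      # greedy 1-1 assignment on the K x K cost matrix
      left <- seq_len(K); slots <- seq_len(K)
      while (length(left)) {
        m <- which(cost[left, slots, drop = FALSE] ==
                     min(cost[left, slots]), arr.ind = TRUE)[1L, ]
        assign[idx[left[m[1L]]]] <- slots[m[2L]]
        left <- left[-m[1L]]; slots <- slots[-m[2L]]
      }
    }
    newCentroids <- t(vapply(seq_len(K), function(k) {
      v <- colMeans(X[assign == k, , drop = FALSE])
      v / sqrt(sum(v^2))
    }, numeric(ncol(X))))
    if (max(abs(newCentroids - centroids)) < 1e-9) break
    centroids <- newCentroids
  }
  d <- 1 - tcrossprod(X)           # cosine distance
  d[d < 0] <- 0
  sil <- cluster::silhouette(assign, dmatrix = d)
  avg <- mean(sil[, "sil_width"])
  perCluster <- tapply(sil[, "sil_width"], assign, mean)
  cons <- t(vapply(seq_len(K), function(k) {
    v <- colMeans(factors[assign == k, , drop = FALSE])
    v / sum(v)
  }, numeric(ncol(factors))))
  # redundancy guard: a solution whose consensus signatures are mutually
  # near-identical describes fewer processes than K and is not a valid
  # rank-K solution, however tightly its micro-split reproduces
  consNorm <- cons / sqrt(rowSums(cons^2))
  off <- tcrossprod(consNorm); diag(off) <- 0
  if (max(off) > 0.95) {
    avg <- 0
    perCluster <- 0
  }
  list(avg = avg, min = min(perCluster), consensus = cons)
}

#' Stability-based rank choice
#'
#' Applies the selection rule to a per-K stability table: the chosen rank
#' is the largest K whose average silhouette stability plus minimum
#' stability exceeds 1 and whose minimum stability is at least 0.4;
#' `NA` when no K qualifies.
#'
#' @param stability `data.frame` with columns `K`, `avgStability`,
#'   `minStability`.
#' @return The chosen K, or `NA_integer_`.
#' @export
chooseStableRank <- function(stability) {
  ok <- stability$avgStability + stability$minStability > 1 &
    stability$minStability >= 0.4
  if (!any(ok)) return(NA_integer_)
  as.integer(max(stability$K[ok]))
}

#' De novo signature extraction with stability selection
#'
#' For each candidate rank K, runs `nBoot` KL-objective NMF
#' decompositions (multiplicative updates) on Poisson-resampled
#' catalogues, pools the resulting factors, partitions them into K
#' clusters by cosine distance, and scores the partition by silhouette:
#' the solution stability is the average silhouette width and the minimum
#' stability the worst per-cluster average. The chosen rank is the
#' largest K with (average + minimum > 1) and (minimum >= 0.4); when no K
#' qualifies the chosen rank is `NA` and callers fall back to the
#' selection rule without a de novo term ([selectSignatures()]).
#'
#' @param catalogue a [MutationalCatalogue-class] (>= 10 eligible
#'   samples) or a samples x 96 count matrix.
#' @param kRange candidate ranks within 1..12.
#' @param nBoot bootstrap NMF runs per K.
#' @param seed integer seed.
#' @param maxIter,tol NMF iteration controls.
#' @return A list of class `DenovoSolution`: `chosenK`, `factors`
#'   (chosen-K consensus factors, rows sum to 1; `NULL` if none),
#'   `stability` (per-K table), `perK` (consensus factors per K).
#' @export
extractDenovo <- function(catalogue, kRange = 1:4, nBoot = 20L, seed = 1L,
                          maxIter = 200L, tol = 1e-6) {
  if (any(kRange < 1L | kRange > 12L)) stop("kRange must lie in 1..12")
  counts <- if (methods::is(catalogue, "MutationalCatalogue")) {
    m <- catalogueCounts(catalogue)
    m[eligibleSamples(catalogue), , drop = FALSE]
  } else catalogue
  if (nrow(counts) < 10L) stop("need at least 10 eligible samples")
  V <- t(counts)                        # channels x samples
  stab <- data.frame(K = integer(), avgStability = numeric(),
                     minStability = numeric())
  perK <- list()
  for (K in sort(kRange)) {
    factors <- withSeed(seed + K, {
      do.call(rbind, lapply(seq_len(nBoot), function(b) {
        Vb <- matrix(rpois(length(V), lambda = V), nrow(V), ncol(V))
        t(.nmfKL(Vb, K, maxIter = maxIter, tol = tol)$W)
      }))
    })
    fs <- .factorStability(factors, rep(seq_len(nBoot), each = K), K,
                           seed = seed + 1000L + K)
    stab <- rbind(stab, data.frame(K = K, avgStability = fs$avg,
                                   minStability = fs$min))
    cons <- fs$consensus
    colnames(cons) <- sbsChannels()
    perK[[as.character(K)]] <- cons
  }
  chosen <- chooseStableRank(stab)
  structure(list(chosenK = chosen,
                 factors = if (!is.na(chosen)) perK[[as.character(chosen)]],
                 stability = stab, perK = perK),
            class = "DenovoSolution")
}

#' @export
print.DenovoSolution <- function(x, ...) {
  cat("DenovoSolution: chosen K = ",
      if (is.na(x$chosenK)) "none (no stable solution)" else x$chosenK,
      "\n", sep = "")
  print(x$stability, row.names = FALSE)
  invisible(x)
}
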