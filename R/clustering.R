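#' Embed signature exposure profiles in 2-D
#'
#' t-distributed stochastic neighbor embedding of the per-sample signature
#' profiles, deterministic given the seed.
#'
#' @param exposures samples x signatures matrix (row-normalized exposure
#'   profiles), or an `ExposureFit`.
#' @param perplexity t-SNE perplexity; must be below `n/3`.
#' @param seed integer seed.
#' @param maxIter gradient-descent iterations (the conventional 1000 by
#'   default; momentum switches at iteration 250).
#' @return samples x 2 coordinate matrix.
#' @export
embedProfiles <- function(exposures, perplexity = 30, seed = 1L,
                          maxIter = 1000L) {
  if (inherits(exposures, "ExposureFit")) exposures <- exposures$exposures
  n <- nrow(exposures)
  if (n < 10L) stop("need at least 10 samples to embed")
  if (perplexity >= n / 3)
    stop("perplexity (", perplexity, ") must be below n/3 = ", n / 3)
  Y <- .tsne(exposures, perplexity = perplexity, seed = seed,
             maxIter = maxIter)
  rownames(Y) <- rownames(exposures)
  colnames(Y) <- c("tsne1", "tsne2")
  Y
}

#' Gaussian-mixture EM clustering of 2-D coordinates
#'
#' Expectation-maximization fit of a k-component Gaussian mixture with
#' full covariances on the embedding coordinates, initialized from a
#' seeded k-means partition; hard assignments are the maximum-
#' responsibility components. Degenerate fits are re-initialized up to 5
#' times before erroring.
#'
#' @param coords samples x 2 coordinate matrix.
#' @param k number of mixture components (>= 2; `n >= 3k` required).
#' @param seed integer seed.
#' @return A list: `assignment` (integer vector), `responsibilities`
#'   (samples x k, rows sum to 1), `loglik`.
#' @export
clusterEM <- function(coords, k, seed = 1L) {
  n <- nrow(coords)
  if (k < 2L) stop("k must be >= 2")
  if (n < 3L * k) stop("need at least 3 samples per component (n >= 3k)")
  for (attempt in 0:4) {
    km <- withSeed(seed + attempt, kmeans(coords, centers = k,
                                          nstart = 5L, iter.max = 50L))
    z <- matrix(1e-6, n, k)
    z[cbind(seq_len(n), km$cluster)] <- 1
    z <- z / rowSums(z)
    fit <- tryCatch(
      suppressWarnings(mclust::meVVV(data = coords, z = z)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$loglik) || anyNA(fit$z)) {
      # degenerate covariance (e.g. a component collapsing onto nearly
      # coincident points): refit with a weak conjugate prior, which
      # regularizes the covariances deterministically
      fit <- tryCatch(
        suppressWarnings(mclust::meVVV(data = coords, z = z,
                                       prior = mclust::priorControl())),
        error = function(e) NULL)
    }
    if (!is.null(fit) && is.finite(fit$loglik) && !anyNA(fit$z))
      return(list(assignment = max.col(fit$z), responsibilities = fit$z,
                  loglik = fit$loglik))
  }
  stop("EM failed to produce a non-degenerate ", k, "-component fit")
}

#' Consensus APOBEC-enrichment labelling
#'
#' Repeats (embedding + EM clustering) `nRuns` times with per-run seeds
#' derived from the master seed. In each run the APOBEC-associated
#' cluster is the cluster with the highest median collective SBS2+SBS13
#' exposure over its members; a sample is labelled APOBEC-enriched when
#' it falls in that cluster in strictly more than `nRuns / 2` runs.
#'
#' @param exposures samples x signatures matrix containing SBS2 and SBS13
#'   columns, or an `ExposureFit`.
#' @param nRuns number of repetitions (default 100).
#' @param k mixture components per run (default 10, chosen so the APOBEC
#'   cluster is not segmented).
#' @param seed master integer seed; run r uses embedding seed
#'   `seed + r` and EM seed `seed + 100000 + r`.
#' @param perplexity t-SNE perplexity; the default `NULL` uses
#'   `max(30, n/4)` (capped below the n/3 validity bound). Consensus
#'   labelling wants a global-structure-preserving embedding so that the
#'   APOBEC cluster is not segmented across components — the same
#'   consideration that fixes k = 10 — hence a larger perplexity than the
#'   exploratory-visualization default of [embedProfiles()].
#' @param fixedEmbedding reuse a single embedding across runs and repeat
#'   only the EM step.
#' @param keepRuns keep per-run assignments and APOBEC-cluster identities
#'   (attributes `assignments`, `apobecCluster`).
#' @return `data.frame` with columns `sample`, `membershipCount`,
#'   `apobecEnriched`.
#' @export
consensusApobec <- function(exposures, nRuns = 100L, k = 10L, seed = 1L,
                            perplexity = NULL, fixedEmbedding = FALSE,
                            keepRuns = TRUE) {
  if (inherits(exposures, "ExposureFit")) exposures <- exposures$exposures
  if (!all(c("SBS2", "SBS13") %in% colnames(exposures)))
    stop("exposure matrix must contain SBS2 and SBS13 columns")
  n <- nrow(exposures)
  if (k > n / 3) stop("k must not exceed n/3")
  if (is.null(perplexity))
    perplexity <- min(max(30, floor(n / 4)), floor((n - 1) / 3))
  apo <- rowSums(exposures[, c("SBS2", "SBS13"), drop = FALSE])
  counts <- setNames(integer(n), rownames(exposures))
  assignments <- if (keepRuns) matrix(NA_integer_, n, nRuns) else NULL
  apCluster <- integer(nRuns)
  # coarse 300-iteration embeddings: consensus clustering only needs the
  # island structure, which stabilizes long before the fine layout does
  Yfixed <- if (fixedEmbedding)
    embedProfiles(exposures, perplexity, seed = seed, maxIter = 300L) else
    NULL
  for (r in seq_len(nRuns)) {
    Y <- if (fixedEmbedding) Yfixed else
      embedProfiles(exposures, perplexity, seed = seed + r, maxIter = 300L)
    cl <- clusterEM(Y, k = k, seed = seed + 100000L + r)
    med <- tapply(apo, cl$assignment, median)
    ap <- as.integer(names(med)[which.max(med)])
    counts[cl$assignment == ap] <- counts[cl$assignment == ap] + 1L
    if (keepRuns) assignments[, r] <- cl$assignment
    apCluster[r] <- ap
  }
  out <- data.frame(sample = rownames(exposures),
                    membershipCount = unname(counts),
                    apobecEnriched = unname(counts) > nRuns / 2,
                    stringsAsFactors = FALSE)
  if (keepRuns) {
    attr(out, "assignments") <- assignments
    attr(out, "apobecCluster") <- apCluster
  }
  attr(out, "nRuns") <- as.integer(nRuns)
  out
}
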