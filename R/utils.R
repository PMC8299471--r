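#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif rexp rbinom rgamma rbeta rpois rmultinom
#'   quantile median cor cor.test prcomp kmeans fisher.test p.adjust
#'   wilcox.test pchisq dhyper sd dist complete.cases setNames
#' @importFrom utils head read.delim write.table
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so generators behave as pure functions of
# (parameters, seed).
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Mann-Whitney AUROC of a score against binary labels (TRUE = positive).
aurocStat <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  pos <- as.logical(positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("need both classes to compute an AUROC")
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

cosineSim <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  sum(x * y) / (nx * ny)
}

# Euclidean projection of v onto the probability simplex (Duchi et al.).
projectSimplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# Extract a genes x samples matrix of log2(FPKM + 1) values from either a
# SummarizedExperiment produced by simulateExpression() or a plain matrix
# already on the log scale.
logExprMatrix <- function(expr) {
  if (methods::is(expr, "SummarizedExperiment")) {
    an <- SummarizedExperiment::assayNames(expr)
    if (!("logfpkm" %in% an))
      stop("SummarizedExperiment must carry a 'logfpkm' assay")
    return(SummarizedExperiment::assay(expr, "logfpkm"))
  }
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix or a SummarizedExperiment")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames")
  expr
}
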