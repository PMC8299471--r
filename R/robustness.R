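#' Leave-one-gene-out score stability
#'
#' Removes one gene from the program at a time, recomputes the per-sample
#' scores with `scoreFn`, and records the fold change (new / original
#' score) per sample and perturbation. Samples whose original score is
#' exactly 0 get a missing fold change, counted in the report.
#'
#' @inheritParams scoreScaledDifference
#' @param scoreFn scoring function taking `(expr, program)`, e.g.
#'   [scoreScaledDifference()] or [scorePCA()].
#' @return A list of class `StabilityReport` with elements `method`
#'   (`"loo"`), `foldChanges` (perturbation x sample matrix), `summary`
#'   (per-perturbation mean/sd/quantiles of fold changes), `nMissing`.
#' @export
looStability <- function(expr, program, scoreFn = scoreScaledDifference) {
  if (programSize(program) < 2L)
    stop("need at least 2 program genes for leave-one-out")
  x <- logExprMatrix(expr)
  orig <- scoreFn(x, program)
  genes <- c(program@upGenes, program@downGenes)
  fc <- matrix(NA_real_, length(genes), length(orig),
               dimnames = list(genes, names(orig)))
  for (g in genes) {
    up <- setdiff(program@upGenes, g)
    down <- setdiff(program@downGenes, g)
    if (!length(up)) next  # removing the only up gene leaves no valid program
    pert <- GeneProgram(program@name, up = up, down = down,
                        note = program@note)
    newScore <- scoreFn(x, pert)
    fc[g, ] <- ifelse(orig == 0, NA_real_, newScore / orig)
  }
  structure(list(method = "loo", foldChanges = fc,
                 summary = .stabilitySummary(fc, genes),
                 nMissing = sum(is.na(fc)), nRepeats = 1L),
            class = "StabilityReport")
}

.stabilitySummary <- function(fc, labels) {
  data.frame(perturbation = labels,
             mean = apply(fc, 1, mean, na.rm = TRUE),
             sd = apply(fc, 1, sd, na.rm = TRUE),
             q05 = apply(fc, 1, quantile, 0.05, na.rm = TRUE),
             q95 = apply(fc, 1, quantile, 0.95, na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.StabilityReport <- function(x, ...) {
  cat("StabilityReport (", x$method, "): ", nrow(x$summary),
      " perturbations, ", x$nMissing, " missing fold changes\n", sep = "")
  print(head(x$summary))
  invisible(x)
}

#' Jitter-noise score stability
#'
#' Adds uniform noise to the expression of each program gene in each
#' sample and recomputes the scores. The noise amplitude for a gene is
#' `factor * d / 10`, where `d` is the smallest nonzero spacing between
#' that gene's expression values across samples (genes with all-equal
#' values receive no noise); `amplitude` overrides this per-gene law with
#' a fixed amplitude, exposing the exact zero-noise limit. Repeated
#' `nRepeats` times per factor; fold-change variability is summarized per
#' factor.
#'
#' @inheritParams looStability
#' @param factors integer noise levels within 1..200.
#' @param nRepeats repeats per factor.
#' @param seed integer seed (a fixed repeat schedule is derived from it).
#' @param amplitude optional fixed noise amplitude overriding the
#'   factor-scaled law (0 gives fold changes identically 1).
#' @return A list of class `StabilityReport` with `method = "jitter"` and
#'   a per-factor `summary` (mean, sd and quantiles of pooled per-sample
#'   fold changes).
#' @export
jitterStability <- function(expr, program, scoreFn = scoreScaledDifference,
                            factors = c(1L, 50L, 200L), nRepeats = 100L,
                            seed = 1L, amplitude = NULL) {
  if (any(factors < 1L | factors > 200L))
    stop("factors must lie in 1..200")
  if (nRepeats < 1L) stop("nRepeats must be >= 1")
  x <- logExprMatrix(expr)
  genes <- c(program@upGenes, program@downGenes)
  xg <- x[genes, , drop = FALSE]
  spacing <- apply(xg, 1, function(v) {
    d <- diff(sort(unique(v)))
    if (length(d)) min(d) else 0
  })
  orig <- scoreFn(x, program)
  res <- lapply(factors, function(f) {
    amp <- if (is.null(amplitude)) f * spacing / 10 else
      rep(amplitude, length(genes))
    fc <- withSeed(seed + f, {
      vapply(seq_len(nRepeats), function(r) {
        noise <- matrix(runif(length(xg), -1, 1), nrow(xg), ncol(xg)) * amp
        xn <- x
        xn[genes, ] <- xg + noise
        newScore <- scoreFn(xn, program)
        ifelse(orig == 0, NA_real_, newScore / orig)
      }, numeric(length(orig)))
    })
    data.frame(factor = f, mean = mean(fc, na.rm = TRUE),
               sd = sd(as.vector(fc), na.rm = TRUE),
               q05 = quantile(fc, 0.05, na.rm = TRUE),
               q95 = quantile(fc, 0.95, na.rm = TRUE), row.names = NULL)
  })
  structure(list(method = "jitter", summary = do.call(rbind, res),
                 nMissing = sum(orig == 0) * nRepeats * length(factors),
                 nRepeats = as.integer(nRepeats),
                 noiseLaw = if (is.null(amplitude))
                   "uniform(+/- factor * min nonzero spacing / 10)" else
                   sprintf("uniform(+/- %g), fixed", amplitude)),
            class = "StabilityReport")
}

#' Random-gene-program null distribution for a score association
#'
#' Draws `nIter` random programs of `nGenes` genes from the measured gene
#' universe, scores each by mean expression, and computes the Pearson
#' correlation with `target` (e.g. the APOBEC program score). The
#' empirical p-value for the observed correlation uses the add-one rule
#' `(1 + #\{null >= observed\}) / (1 + nIter)` and is one-sided in the
#' direction of a positive association, so it is never exactly 0.
#'
#' @inheritParams scoreScaledDifference
#' @param universe gene symbols to draw from (must exceed `nGenes`).
#' @param target per-sample score vector the correlation is computed
#'   against.
#' @param observed per-sample score vector of the real program whose
#'   association is being tested.
#' @param nGenes genes per random program (35 matches the dormancy
#'   signature size).
#' @param nIter number of random programs.
#' @param seed integer seed.
#' @return A list of class `NullDistribution` with `observedStatistic`,
#'   `nullValues`, `empiricalP`, `nGenesDrawn`.
#' @export
randomProgramNull <- function(expr, universe, target, observed,
                              nGenes = 35L, nIter = 1000L, seed = 1L) {
  x <- logExprMatrix(expr)
  universe <- intersect(universe, rownames(x))
  if (length(universe) <= nGenes)
    stop("gene universe must contain more than nGenes genes")
  if (sd(target) == 0) stop("target score vector has zero variance")
  obs <- cor(observed, target)
  null <- withSeed(seed, vapply(seq_len(nIter), function(i) {
    g <- sample(universe, nGenes)
    cor(colMeans(x[g, , drop = FALSE]), target)
  }, numeric(1)))
  structure(list(observedStatistic = obs, nullValues = null,
                 empiricalP = (1 + sum(null >= obs)) / (1 + nIter),
                 nGenesDrawn = as.integer(nGenes)),
            class = "NullDistribution")
}

#' @export
print.NullDistribution <- function(x, ...) {
  cat("NullDistribution: observed r = ", round(x$observedStatistic, 4),
      ", empirical p = ", signif(x$empiricalP, 4), " (",
      length(x$nullValues), " draws of ", x$nGenesDrawn, " genes)\n",
      sep = "")
  invisible(x)
}
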