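#' Scaled-difference-of-means program score
#'
#' For each sample, `S = (sum of log expression over upregulated genes -
#' sum over downregulated genes) / (N_u + N_d)`. All program genes must be
#' measured; call [restrictToMeasured()] first when in doubt.
#'
#' @param expr log2(FPKM+1) genes x samples matrix or the
#'   SummarizedExperiment from [simulateExpression()].
#' @param program a [GeneProgram-class].
#' @return Named numeric vector of per-sample scores.
#' @export
scoreScaledDifference <- function(expr, program) {
  x <- logExprMatrix(expr)
  genes <- c(program@upGenes, program@downGenes)
  miss <- setdiff(genes, rownames(x))
  if (length(miss))
    stop("program gene(s) not measured: ", paste(miss, collapse = ", "),
         "; restrict the program to measured genes first")
  up <- colSums(x[program@upGenes, , drop = FALSE])
  down <- if (length(program@downGenes))
    colSums(x[program@downGenes, , drop = FALSE]) else 0
  (up - down) / programSize(program)
}

#' PCA-based program score
#'
#' Principal component analysis of the samples in the space of the
#' program's genes (genes centered, not scaled); the score is each
#' sample's coordinate on the first principal component. Because the PC1
#' axis has an arbitrary sign, the score is oriented so that it correlates
#' non-negatively with the scaled-difference score of the same program.
#'
#' @inheritParams scoreScaledDifference
#' @return Named numeric vector of per-sample scores, plus attribute
#'   `varExplained` (fraction of variance on PC1).
#' @export
scorePCA <- function(expr, program) {
  x <- logExprMatrix(expr)
  genes <- c(program@upGenes, program@downGenes)
  miss <- setdiff(genes, rownames(x))
  if (length(miss))
    stop("program gene(s) not measured: ", paste(miss, collapse = ", "))
  if (length(genes) < 2L) stop("need at least 2 program genes for PCA")
  if (ncol(x) < 3L) stop("need at least 3 samples for PCA")
  m <- t(x[genes, , drop = FALSE])
  if (all(apply(m, 2, stats::var) == 0))
    stop("all program genes have zero variance")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  score <- pc$x[, 1L]
  ref <- scoreScaledDifference(x, program)
  r <- suppressWarnings(cor(score, ref))
  if (!is.na(r) && r < 0) score <- -score
  attr(score, "varExplained") <- unname(pc$sdev[1L]^2 / sum(pc$sdev^2))
  score
}

#' Mean-expression program score
#'
#' Arithmetic mean of log expression over the program's genes. Only valid
#' for all-upregulated programs (e.g. APOBEC, exhaustion).
#'
#' @inheritParams scoreScaledDifference
#' @return Named numeric vector of per-sample scores.
#' @export
scoreMeanProgram <- function(expr, program) {
  if (length(program@downGenes))
    stop("mean-expression scoring is defined for all-upregulated programs; '",
         program@name, "' has downregulated genes")
  x <- logExprMatrix(expr)
  miss <- setdiff(program@upGenes, rownames(x))
  if (length(miss))
    stop("program gene(s) not measured: ", paste(miss, collapse = ", "))
  colMeans(x[program@upGenes, , drop = FALSE])
}

#' Proliferation/apoptosis ratio
#'
#' Mean log expression of the proliferation (E2F-target-style) program
#' divided by the mean log expression of the apoptosis program, per
#' sample. A ratio below 1 indicates limited expansion of the lesion.
#'
#' @inheritParams scoreScaledDifference
#' @param proliferation,apoptosis all-upregulated [GeneProgram-class]
#'   objects.
#' @return Named numeric vector of ratios.
#' @export
proliferationApoptosisRatio <- function(expr, proliferation, apoptosis) {
  pm <- scoreMeanProgram(expr, proliferation)
  am <- scoreMeanProgram(expr, apoptosis)
  zero <- am == 0
  if (any(zero))
    stop("apoptosis program mean is 0 for sample(s): ",
         paste(names(am)[zero], collapse = ", "))
  pm / am
}

.quartiles <- function(x, mode) {
  if (mode == "quantile") {
    c(q1 = unname(quantile(x, 0.25)), q3 = unname(quantile(x, 0.75)))
  } else {
    r <- range(x)
    c(q1 = r[1] + 0.25 * diff(r), q3 = r[1] + 0.75 * diff(r))
  }
}

#' Classify samples into dormancy categories
#'
#' A sample shows tumor mass dormancy (TMD-high) when its TMD score is in
#' the upper quartile of the cohort score distribution (inclusive at the
#' boundary) and its proliferation/apoptosis ratio is below the threshold.
#' TMD-high samples are subdivided by the angiogenic (AD) and
#' immunological (ID) score quartiles: both upper -> `A/ID`, AD only ->
#' `AD`, ID only -> `ID`. TMD-high samples in neither upper quartile have
#' no name in the taxonomy and are reported as `MID` with the
#' `unassignedHigh` audit flag set. Samples in the lower TMD quartile with
#' ratio above the threshold are expanding (`NO`); everything else is
#' `MID`. Categories are mutually exclusive and exhaustive.
#'
#' @param tmd,ad,id per-sample score vectors over the same samples.
#' @param ratio per-sample proliferation/apoptosis ratio.
#' @param quartileMode `"quantile"` (75th/25th percentile of the cohort
#'   scores, the default) or `"range"` (min + 0.75/0.25 of the score
#'   range).
#' @param ratioThreshold boundary for the ratio rule; samples exactly at
#'   the threshold satisfy neither `< thr` nor `> thr` and fall to `MID`.
#' @return `data.frame` with columns `sample`, `category` (factor with
#'   levels A/ID, AD, ID, MID, NO), `ratio`, `tmdHigh`, `unassignedHigh`;
#'   quartile thresholds are attached as attribute `thresholds`.
#' @export
classifyDormancy <- function(tmd, ad, id, ratio,
                             quartileMode = c("quantile", "range"),
                             ratioThreshold = 1) {
  quartileMode <- match.arg(quartileMode)
  n <- length(tmd)
  if (length(ad) != n || length(id) != n || length(ratio) != n)
    stop("score vectors must cover the same samples")
  if (anyNA(tmd) || anyNA(ad) || anyNA(id) || anyNA(ratio))
    stop("NA/NaN scores are not classifiable")
  qt <- .quartiles(tmd, quartileMode)
  qa <- .quartiles(ad, quartileMode)
  qi <- .quartiles(id, quartileMode)
  tmdHigh <- tmd >= qt["q3"] & ratio < ratioThreshold
  adHigh <- ad >= qa["q3"]
  idHigh <- id >= qi["q3"]
  category <- rep("MID", n)
  unassigned <- rep(FALSE, n)
  category[tmdHigh & adHigh & idHigh] <- "A/ID"
  category[tmdHigh & adHigh & !idHigh] <- "AD"
  category[tmdHigh & !adHigh & idHigh] <- "ID"
  unassigned[tmdHigh & !adHigh & !idHigh] <- TRUE
  category[!tmdHigh & tmd <= qt["q1"] & ratio > ratioThreshold] <- "NO"
  out <- data.frame(
    sample = if (!is.null(names(tmd))) names(tmd) else as.character(seq_len(n)),
    category = factor(category, levels = c("A/ID", "AD", "ID", "MID", "NO")),
    ratio = unname(ratio), tmdHigh = unname(tmdHigh),
    unassignedHigh = unassigned, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- list(tmd = qt, ad = qa, id = qi,
                                  quartileMode = quartileMode,
                                  ratioThreshold = ratioThreshold)
  out
}

#' Median-split hypoxia score
#'
#' Buffa-style score: for each signature gene, samples above the cohort
#' median expression of that gene contribute +1, samples below -1, and
#' samples exactly at the median 0; the score is the sum over signature
#' genes. Genes that appear in the dormancy or exhaustion signatures are
#' removed before scoring via `exclusion`. Scores are attached to bins of
#' width 10 (`bin = floor(score / 10)`).
#'
#' @inheritParams scoreScaledDifference
#' @param program all-upregulated hypoxia signature.
#' @param exclusion gene symbols to remove before scoring.
#' @return `data.frame` with columns `sample`, `score`, `bin`.
#' @export
hypoxiaScore <- function(expr, program, exclusion = character()) {
  if (length(program@downGenes))
    stop("hypoxia signature must be all-upregulated")
  x <- logExprMatrix(expr)
  genes <- intersect(setdiff(program@upGenes, exclusion), rownames(x))
  if (length(genes) < 5L)
    stop("fewer than 5 hypoxia signature genes remain after exclusion")
  m <- x[genes, , drop = FALSE]
  med <- apply(m, 1, median)
  score <- colSums(sign(m - med))
  data.frame(sample = colnames(m), score = as.integer(score),
             bin = as.integer(floor(score / 10)), stringsAsFactors = FALSE)
}

# per-sample ssGSEA enrichment statistic for one gene set, centered by
# its uniform-membership baseline so that a random gene set scores ~0:
# the rank-power weights make the raw running-sum statistic positively
# biased even for unrelated sets, and the baseline (the expected weighted
# in-set CDF under random membership, a deterministic function of the
# rank multiset) removes that bias.
.ssgseaOne <- function(rnk, ord, inSet, weight) {
  # rnk: expression ranks (1 = lowest); ord: indices sorted by decreasing
  # expression; inSet: logical over genes
  w <- rnk[ord]^weight
  inS <- inSet[ord]
  stepIn <- cumsum(ifelse(inS, w, 0)) / sum(w[inS])
  stepOut <- cumsum(!inS) / sum(!inS)
  n <- length(w)
  baseline <- cumsum(w) / sum(w) - seq_len(n) / n
  sum(stepIn - stepOut) - sum(baseline)
}

#' Single-sample GSEA cell-infiltration scores
#'
#' Rank-based running-sum enrichment statistic per sample and marker set
#' (rank weight exponent `weight`, conventionally 0.25). Because only
#' expression ranks enter, scores are invariant under any strictly
#' monotone transform of a sample's expression values. Combined categories
#' are scored on the union of their member sets' genes.
#'
#' @inheritParams scoreScaledDifference
#' @param markerLibrary [ProgramLibrary-class] of all-upregulated marker
#'   sets.
#' @param weight rank-weight exponent (>= 0).
#' @param combined named list mapping combined categories (e.g.
#'   cytotoxic) to member marker-set names; scored on the gene union.
#' @return samples x cell-type numeric matrix (combined categories
#'   appended as extra columns). Marker sets with fewer than 2 measured
#'   genes are skipped with a warning.
#' @export
ssgseaScores <- function(expr, markerLibrary,
                         weight = 0.25,
                         combined = defaultCellMarkers()$combined) {
  if (weight < 0) stop("weight must be >= 0")
  x <- logExprMatrix(expr)
  sets <- lapply(markerLibrary@programs, function(p) {
    if (length(p@downGenes))
      stop("marker sets must be all-upregulated: ", p@name)
    intersect(p@upGenes, rownames(x))
  })
  keep <- lengths(sets) >= 2L
  if (any(!keep))
    warning("skipping marker set(s) with < 2 measured genes: ",
            paste(names(sets)[!keep], collapse = ", "))
  sets <- sets[keep]
  if (!is.null(combined)) {
    for (cn in names(combined)) {
      members <- intersect(combined[[cn]], names(markerLibrary))
      g <- unique(unlist(lapply(members, function(m)
        intersect(markerLibrary[[m]]@upGenes, rownames(x)))))
      if (length(g) >= 2L) sets[[cn]] <- g
    }
  }
  inSets <- lapply(sets, function(g) rownames(x) %in% g)
  out <- matrix(NA_real_, ncol(x), length(sets),
                dimnames = list(colnames(x), names(sets)))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    rnk <- rank(v, ties.method = "average")
    ord <- order(v, decreasing = TRUE)
    for (k in seq_along(sets))
      out[j, k] <- .ssgseaOne(rnk, ord, inSets[[k]], weight)
  }
  out
}
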