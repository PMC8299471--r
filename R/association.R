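# mutation classes that qualify for driver enrichment analyses
QUALIFYING_CLASSES <- c("Missense", "Nonsense", "Nonstop", "Frame_Shift_Del",
                        "Frame_Shift_Ins", "In_Frame_Ins", "In_Frame_Del")

# sample x gene mutated indicator over qualifying classes
.mutatedMatrix <- function(variants, samples, genes = NULL) {
  v <- variants[variants$variant_classification %in% QUALIFYING_CLASSES, ,
                drop = FALSE]
  if (!is.null(genes)) v <- v[v$gene_symbol %in% genes, , drop = FALSE]
  tab <- table(factor(v$sample_id, levels = samples), v$gene_symbol) > 0
  matrix(tab, nrow = length(samples),
         dimnames = list(samples, colnames(tab)))
}

#' Mutation frequency filter
#'
#' Returns the genes mutated (by a qualifying mutation class: missense,
#' nonsense, nonstop, frameshift ins/del, in-frame ins/del) in at least
#' `minFrac` of samples, either across the whole cohort (`scope = "pan"`)
#' or within each cancer study (`scope = "per_cancer"`). The boundary is
#' inclusive ("at least").
#'
#' @param variants MAF-dialect variant table.
#' @param samples character vector of cohort sample ids (defines the
#'   denominator).
#' @param minFrac minimum mutated-sample fraction, in (0, 1).
#' @param scope `"pan"` or `"per_cancer"`.
#' @param cohort named character vector mapping sample to study (required
#'   for `per_cancer`).
#' @return For `pan`: character vector of genes. For `per_cancer`: named
#'   list of gene vectors per study.
#' @export
mutationFrequencyFilter <- function(variants, samples, minFrac,
                                    scope = c("pan", "per_cancer"),
                                    cohort = NULL) {
  scope <- match.arg(scope)
  if (!length(samples)) stop("empty cohort")
  if (minFrac <= 0 || minFrac >= 1) stop("minFrac must lie in (0, 1)")
  mut <- .mutatedMatrix(variants, samples)
  if (scope == "pan") {
    frac <- colMeans(mut)
    return(colnames(mut)[frac >= minFrac])
  }
  if (is.null(cohort)) stop("per_cancer scope needs a cohort mapping")
  lapply(split(samples, cohort[samples]), function(ss) {
    frac <- colMeans(mut[ss, , drop = FALSE])
    colnames(mut)[frac >= minFrac]
  })
}

.fisher2x2 <- function(a, b, c, d) {
  p <- fisher.test(matrix(c(a, c, b, d), 2))$p.value
  orr <- if (any(c(a, b, c, d) == 0))
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)) else (a * d) / (b * c)
  list(p = p, or = orr)
}

#' Fisher test for driver-mutation enrichment in dormancy
#'
#' Builds, per gene, the 2x2 table of mutated status (qualifying classes)
#' against dormancy group — TMD-high samples (`tmdHigh`, the union of
#' A/ID, AD and ID) versus expanding `NO` samples, MID excluded by
#' default — and computes a two-sided Fisher exact p (hypergeometric) and
#' the sample odds ratio `(a d)/(b c)` with a Haldane–Anscombe +0.5
#' correction when any cell is zero. BH-adjusted q-values are computed
#' over the supplied gene family.
#'
#' @param genes character vector of genes to test (typically the output
#'   of [mutationFrequencyFilter()]).
#' @param calls classification table from [classifyDormancy()].
#' @param variants MAF-dialect variant table.
#' @param includeMid count MID samples in the low-TMD comparison group.
#' @return `data.frame` per gene: `gene`, contingency counts `a` (mutated
#'   & TMD), `b` (mutated & non-TMD), `c`, `d`, `oddsRatio`, `p`, `q`,
#'   `direction` (`enriched`/`depleted`).
#' @export
fisherEnrichment <- function(genes, calls, variants, includeMid = FALSE) {
  tmdSamples <- calls$sample[calls$tmdHigh]
  lowSamples <- if (includeMid) calls$sample[!calls$tmdHigh] else
    calls$sample[calls$category == "NO"]
  if (!length(tmdSamples) || !length(lowSamples))
    stop("both dormancy comparison groups must be non-empty")
  samples <- c(tmdSamples, lowSamples)
  mut <- .mutatedMatrix(variants, samples, genes)
  res <- lapply(genes, function(g) {
    m <- if (g %in% colnames(mut)) mut[, g] else
      setNames(rep(FALSE, length(samples)), samples)
    a <- sum(m[tmdSamples]); b <- sum(m[lowSamples])
    c_ <- length(tmdSamples) - a; d <- length(lowSamples) - b
    ft <- .fisher2x2(a, b, c_, d)
    data.frame(gene = g, a = a, b = b, c = c_, d = d, oddsRatio = ft$or,
               p = ft$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bhAdjust(out$p)
  out$direction <- ifelse(out$oddsRatio >= 1, "enriched", "depleted")
  out
}

# parse "p.Q61R" -> list(ref, pos, alt); NA on malformed strings
.parseProteinChange <- function(pc) {
  m <- regmatches(pc, regexec("^p\\.([A-Za-z\\*])([0-9]+)([A-Za-z\\*]+)$", pc))
  t(vapply(m, function(x) {
    if (length(x) == 4L) c(x[2L], x[3L], x[4L]) else rep(NA_character_, 3)
  }, character(3)))
}

#' Fisher test for hotspot-residue enrichment
#'
#' Like [fisherEnrichment()] but a sample counts as mutated only when it
#' carries a qualifying mutation at the given protein residue of the gene
#' (any alternate amino acid, e.g. both p.Q61R and p.Q61K match residue
#' 61). Records with unparseable `protein_change` strings are skipped and
#' counted in the attribute `skipped`.
#'
#' @param gene gene symbol.
#' @param residue residue position (integer, or a string like `"Q61"`).
#' @inheritParams fisherEnrichment
#' @return One-row `data.frame` as in [fisherEnrichment()] (without `q`),
#'   labelled `gene:residue`, with attribute `skipped`.
#' @export
hotspotEnrichment <- function(gene, residue, calls, variants,
                              includeMid = FALSE) {
  if (is.character(residue)) residue <- as.integer(gsub("[^0-9]", "", residue))
  v <- variants[variants$gene_symbol == gene &
                variants$variant_classification %in% QUALIFYING_CLASSES &
                nzchar(variants$protein_change), , drop = FALSE]
  parsed <- .parseProteinChange(v$protein_change)
  bad <- is.na(parsed[, 2L])
  skipped <- sum(bad)
  hitSamples <- unique(v$sample_id[!bad & as.integer(parsed[, 2L]) == residue])
  tmdSamples <- calls$sample[calls$tmdHigh]
  lowSamples <- if (includeMid) calls$sample[!calls$tmdHigh] else
    calls$sample[calls$category == "NO"]
  a <- sum(tmdSamples %in% hitSamples)
  b <- sum(lowSamples %in% hitSamples)
  c_ <- length(tmdSamples) - a; d <- length(lowSamples) - b
  ft <- .fisher2x2(a, b, c_, d)
  out <- data.frame(gene = paste0(gene, ":", residue), a = a, b = b, c = c_,
                    d = d, oddsRatio = ft$or, p = ft$p,
                    direction = ifelse(ft$or >= 1, "enriched", "depleted"),
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' the family is exactly the vector passed in (one family per analysis).
#'
#' @param p p-values in [0, 1].
#' @return q-values of the same length.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pairwise Pearson correlation matrix with significance
#'
#' Pairwise-complete Pearson correlations between per-sample score
#' vectors, with two-sided p-values from the t transform, BH-adjusted
#' over the upper triangle. Optionally stratified by a grouping label
#' (e.g. tissue).
#'
#' @param scores named list of equal-length per-sample numeric vectors,
#'   or a samples x score data.frame/matrix.
#' @param grouping optional factor over samples; when given, a list of
#'   per-group results is returned.
#' @return A list with matrices `r`, `p`, `q`, `n`; zero-variance cells
#'   are `NA`.
#' @export
correlationMatrix <- function(scores, grouping = NULL) {
  m <- if (is.list(scores) && !is.data.frame(scores))
    do.call(cbind, scores) else as.matrix(scores)
  if (!is.null(grouping)) {
    idx <- split(seq_len(nrow(m)), grouping)
    return(lapply(idx, function(i) correlationMatrix(m[i, , drop = FALSE])))
  }
  k <- ncol(m)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(colnames(m),
                                                        colnames(m)))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    ok <- complete.cases(m[, i], m[, j])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < 3L || sd(m[ok, i]) == 0 || sd(m[ok, j]) == 0) next
    ct <- cor.test(m[ok, i], m[ok, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  q <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  ut <- upper.tri(q)
  q[ut] <- bhAdjust(p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  list(r = r, p = p, q = q, n = n)
}

#' Per-cohort Z-score normalization
#'
#' Within each cohort (cancer study), each gene's log expression values
#' are centered and scaled to unit standard deviation. Genes with zero
#' variance within a cohort are set to 0 there and flagged.
#'
#' @inheritParams scoreScaledDifference
#' @param cohort character/factor of cohort labels per sample (each
#'   cohort needs >= 2 samples).
#' @return genes x samples matrix of Z-scores with attribute
#'   `flaggedGenes` (list per cohort of zero-variance genes).
#' @export
zscoreByCohort <- function(expr, cohort) {
  x <- logExprMatrix(expr)
  if (length(cohort) != ncol(x))
    stop("cohort labels must cover the samples")
  out <- x
  flagged <- list()
  for (g in unique(cohort)) {
    cols <- which(cohort == g)
    if (length(cols) < 2L) stop("cohort '", g, "' has fewer than 2 samples")
    sub <- x[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    sdev <- apply(sub, 1, sd)
    z <- (sub - mu) / sdev
    zero <- sdev == 0
    z[zero, ] <- 0
    flagged[[g]] <- rownames(x)[zero]
    out[, cols] <- z
  }
  attr(out, "flaggedGenes") <- flagged
  out
}

#' Random-forest importance ranking
#'
#' Repeatedly fits a random forest on class-balanced subsamples (all
#' minority-class samples plus an equal number drawn without replacement
#' from the majority class), records the impurity (Gini) importance of
#' every feature and a held-out AUC (stratified 70/30 split within each
#' balanced subsample; held-out rather than out-of-bag because OOB votes
#' are pessimistically biased on balanced designs), and ranks features by
#' mean importance across repeats.
#'
#' @param features samples x feature numeric matrix (e.g. Z-scored
#'   expression of program genes).
#' @param labels binary labels (logical or 2-level factor) per sample.
#' @param nTrees trees per forest.
#' @param nRepeats balanced-resampling repeats.
#' @param balance subsample to balanced classes (default `TRUE`).
#' @param seed integer seed.
#' @return A list of class `ImportanceRanking`: `importance` (data.frame
#'   `feature`, `meanGini`, `rank`), `auc` (per-repeat out-of-bag AUC).
#' @export
rfImportance <- function(features, labels, nTrees = 1000L, nRepeats = 100L,
                         balance = TRUE, seed = 1L) {
  y <- as.factor(labels)
  if (nlevels(y) != 2L) stop("labels must have exactly two classes")
  cls <- levels(y)
  nPer <- min(table(y))
  imp <- matrix(0, ncol(features), nRepeats,
                dimnames = list(colnames(features), NULL))
  auc <- numeric(nRepeats)
  for (r in seq_len(nRepeats)) {
    split <- withSeed(seed + r, {
      idx <- if (balance) {
        unlist(lapply(cls, function(cl) {
          i <- which(y == cl)
          if (length(i) > nPer) sample(i, nPer) else i
        }))
      } else seq_len(nrow(features))
      test <- unlist(lapply(cls, function(cl) {
        i <- idx[y[idx] == cl]
        sample(i, max(1L, round(0.3 * length(i))))
      }))
      list(train = setdiff(idx, test), test = test)
    })
    fit <- withSeed(seed + 50000L + r,
      randomForest::randomForest(
        x = features[split$train, , drop = FALSE], y = y[split$train],
        ntree = nTrees, importance = FALSE))
    imp[, r] <- fit$importance[, "MeanDecreaseGini"]
    votes <- stats::predict(fit, features[split$test, , drop = FALSE],
                            type = "prob")[, cls[2L]]
    auc[r] <- aurocStat(votes, y[split$test] == cls[2L])
  }
  meanGini <- rowMeans(imp)
  structure(list(
    importance = data.frame(feature = names(meanGini),
                            meanGini = unname(meanGini),
                            rank = rank(-meanGini, ties.method = "first"),
                            row.names = NULL, stringsAsFactors = FALSE),
    auc = auc), class = "ImportanceRanking")
}

#' @export
print.ImportanceRanking <- function(x, ...) {
  cat("ImportanceRanking: ", nrow(x$importance), " features, mean OOB AUC ",
      round(mean(x$auc), 4), "\n", sep = "")
  top <- x$importance[order(x$importance$rank), ]
  print(head(top, 10), row.names = FALSE)
  invisible(x)
}

#' Median-shift tests between two groups
#'
#' Per feature (gene): difference of group medians (first level minus
#' second level of `groups`) with a two-sample Wilcoxon rank-sum p-value,
#' BH-corrected across features; significance is flagged at q < 0.01.
#' Constant features get p = 1.
#'
#' @param features samples x feature numeric matrix (e.g. Z-scored
#'   expression).
#' @param groups 2-level factor per sample; the reported difference is
#'   `median(level 1) - median(level 2)`.
#' @return `data.frame`: `feature`, `medianDiff`, `p`, `q`,
#'   `significant`.
#' @export
medianShiftTest <- function(features, groups) {
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("groups must have exactly two levels")
  if (any(table(g) < 3L)) stop("both groups need at least 3 samples")
  res <- lapply(colnames(features), function(f) {
    x1 <- features[g == levels(g)[1L], f]
    x2 <- features[g == levels(g)[2L], f]
    p <- if (sd(c(x1, x2)) == 0) 1 else
      suppressWarnings(wilcox.test(x1, x2)$p.value)
    data.frame(feature = f, medianDiff = median(x1) - median(x2), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bhAdjust(out$p)
  out$significant <- out$q < 0.01
  out
}
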