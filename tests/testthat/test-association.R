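test_that("mutation frequency filter honors class and boundary rules", {
  samples <- paste0("s", 1:500)
  v <- rbind(
    data.frame(sample_id = paste0("s", 1:5), gene_symbol = "G1",
               chrom = "c", pos = 1L, ref_allele = "C", alt_allele = "T",
               variant_classification = "Missense", protein_change = ""),
    data.frame(sample_id = paste0("s", 1:40), gene_symbol = "G2",
               chrom = "c", pos = 2L, ref_allele = "C", alt_allele = "T",
               variant_classification = "Silent", protein_change = ""))
  # 5/500 = exactly 1%: retained (inclusive); Silent-only gene excluded
  got <- mutationFrequencyFilter(v, samples, minFrac = 0.01)
  expect_equal(got, "G1")
  expect_error(mutationFrequencyFilter(v, samples, minFrac = 0),
               "minFrac")
  expect_error(mutationFrequencyFilter(v, character(0), 0.01), "empty")
  # per-cancer scope with a 5% threshold
  cohort <- setNames(rep(c("A", "B"), each = 250), samples)
  per <- mutationFrequencyFilter(v, samples, minFrac = 0.05,
                                 scope = "per_cancer", cohort = cohort)
  expect_equal(per$A, character(0))  # 5/250 = 2% < 5%
})

test_that("Fisher enrichment matches hypergeometric enumeration and uses the
           Haldane-corrected sample odds ratio", {
  # printed-style table: a=10, b=5, c=40, d=95
  calls <- data.frame(
    sample = paste0("s", 1:150),
    category = factor(c(rep("AD", 50), rep("NO", 100)),
                      levels = c("A/ID", "AD", "ID", "MID", "NO")),
    ratio = c(rep(0.5, 50), rep(1.5, 100)),
    tmdHigh = c(rep(TRUE, 50), rep(FALSE, 100)),
    unassignedHigh = FALSE)
  mutSamples <- c(paste0("s", 1:10), paste0("s", 51:55))
  v <- data.frame(sample_id = mutSamples, gene_symbol = "GENE",
                  chrom = "c", pos = 1L, ref_allele = "C",
                  alt_allele = "T", variant_classification = "Missense",
                  protein_change = "")
  res <- fisherEnrichment("GENE", calls, v)
  expect_equal(c(res$a, res$b, res$c, res$d), c(10, 5, 40, 95))
  expect_equal(res$oddsRatio, (10 * 95) / (5 * 40))
  expect_equal(res$p, enumFisherP(10, 5, 40, 95), tolerance = 1e-12)
  expect_equal(res$direction, "enriched")

  # zero cell: +0.5 correction, depleted direction
  v0 <- data.frame(sample_id = paste0("s", 51:60), gene_symbol = "GENE",
                   chrom = "c", pos = 1L, ref_allele = "C",
                   alt_allele = "T", variant_classification = "Missense",
                   protein_change = "")
  res0 <- fisherEnrichment("GENE", calls, v0)
  expect_equal(res0$oddsRatio,
               (0.5 * (90 + 0.5)) / ((10 + 0.5) * (50 + 0.5)))
  expect_equal(res0$direction, "depleted")
})

test_that("Fisher p equals full enumeration over all small-margin tables", {
  for (m1 in c(0:12, 30)) for (m2 in c(0:12, 30)) {
    if (m1 + m2 == 0) next
    for (k in 0:(m1 + m2)) {
      a <- max(0, k - m2)   # one representative observed table per margin
      b <- m1 - a; c_ <- k - a; d <- m2 - c_
      if (min(b, c_, d) < 0) next
      expect_equal(fisher.test(matrix(c(a, c_, b, d), 2))$p.value,
                   enumFisherP(a, b, c_, d), tolerance = 1e-9)
    }
  }
})

test_that("hotspot residue matching is altAA-agnostic and skips malformed
           annotations", {
  calls <- data.frame(
    sample = paste0("s", 1:40),
    category = factor(c(rep("ID", 20), rep("NO", 20)),
                      levels = c("A/ID", "AD", "ID", "MID", "NO")),
    ratio = c(rep(0.5, 20), rep(1.5, 20)),
    tmdHigh = c(rep(TRUE, 20), rep(FALSE, 20)), unassignedHigh = FALSE)
  v <- data.frame(
    sample_id = c("s1", "s2", "s3", "s21"),
    gene_symbol = "HRAS", chrom = "c", pos = 1L, ref_allele = "C",
    alt_allele = "T", variant_classification = "Missense",
    protein_change = c("p.Q61R", "p.Q61K", "p.G13D", "Q61R"))
  res <- hotspotEnrichment("HRAS", "Q61", calls, v)
  expect_equal(res$a, 2)            # Q61R + Q61K both match residue 61
  expect_equal(res$b, 0)            # malformed "Q61R" (no p.) is skipped
  expect_equal(attr(res, "skipped"), 1L)
  res13 <- hotspotEnrichment("HRAS", 13, calls, v)
  expect_equal(res13$a, 1)          # G13D does not match Q61 but matches 13
})

test_that("BH adjustment equals its brute-force definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  withr::with_seed(5, {
    for (i in 1:25) {
      p <- runif(sample(1:40, 1))
      expect_equal(bhAdjust(p), bruteForceBH(p))
    }
  })
})

test_that("correlation matrix: exact identities and null type-I calibration", {
  withr::with_seed(6, x <- rnorm(50))
  cm <- correlationMatrix(list(a = x, b = x, c = -x))
  expect_equal(cm$r["a", "b"], 1)
  expect_equal(cm$r["a", "c"], -1)
  cmz <- correlationMatrix(list(a = x, z = rep(1, 50)))
  expect_true(is.na(cmz$r["a", "z"]))

  hits <- withr::with_seed(7, {
    vapply(1:1000, function(i) {
      cor.test(rnorm(100), rnorm(100))$p.value < 0.05
    }, logical(1))
  })
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})

test_that("per-cohort Z-scores have unit moments and flag constant genes", {
  withr::with_seed(8, {
    x <- matrix(rnorm(50 * 40, 5), 50, 40,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:40)))
  })
  x["g1", ] <- 3                        # constant gene
  cohort <- rep(c("A", "B"), each = 20)
  z <- zscoreByCohort(x, cohort)
  for (g in c("A", "B")) {
    sub <- z[-1, cohort == g]
    expect_lt(max(abs(rowMeans(sub))), 1e-9)
    expect_lt(max(abs(apply(sub, 1, sd) - 1)), 1e-9)
  }
  expect_true(all(z["g1", ] == 0))
  expect_equal(attr(z, "flaggedGenes")$A, "g1")
  # idempotent up to sd re-estimation
  z2 <- zscoreByCohort(z, cohort)
  expect_equal(z2[-1, ], z[-1, ], tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(zscoreByCohort(x, rep(c("A", "B", "C"), c(20, 19, 1))),
               "fewer than 2")
})

test_that("random-forest ranking finds a planted separating feature and is
           null-calibrated", {
  withr::with_seed(9, {
    n <- 80
    labels <- rep(c(TRUE, FALSE), each = n / 2)
    feats <- matrix(rnorm(n * 30), n, 30,
                    dimnames = list(NULL, paste0("f", 1:30)))
    feats[, "f1"] <- ifelse(labels, 2, -2) + rnorm(n, 0, 0.1)
  })
  imp <- rfImportance(feats, labels, nTrees = 200, nRepeats = 10, seed = 3)
  expect_equal(imp$importance$feature[imp$importance$rank == 1], "f1")
  expect_true(all(sort(imp$importance$rank) == 1:30))
  expect_true(all(imp$auc >= 0 & imp$auc <= 1))
  imp2 <- rfImportance(feats, labels, nTrees = 200, nRepeats = 10, seed = 3)
  expect_identical(imp$importance, imp2$importance)

  permLabels <- withr::with_seed(10, sample(labels))
  impNull <- rfImportance(feats, permLabels, nTrees = 200, nRepeats = 20,
                          seed = 4)
  expect_gte(mean(impNull$auc), 0.35)
  expect_lte(mean(impNull$auc), 0.65)
  expect_error(rfImportance(feats, rep(TRUE, n)), "two classes")
})

test_that("median-shift test: identity, antisymmetry and planted power", {
  withr::with_seed(11, {
    g <- factor(rep(c("enr", "non"), each = 100), levels = c("enr", "non"))
    feats <- matrix(rnorm(200 * 20), 200, 20,
                    dimnames = list(NULL, paste0("f", 1:20)))
    feats[g == "enr", "f1"] <- feats[g == "enr", "f1"] + 1
  })
  res <- medianShiftTest(feats, g)
  expect_true(res$significant[res$feature == "f1"])
  expect_gt(res$medianDiff[res$feature == "f1"], 0)
  # swapping group labels negates the difference
  res2 <- medianShiftTest(feats, factor(g, levels = c("non", "enr")))
  expect_equal(res2$medianDiff, -res$medianDiff)
  # identical groups: difference 0, p = 1
  dup <- rbind(feats[1:50, ], feats[1:50, ])
  gdup <- factor(rep(c("a", "b"), each = 50))
  res3 <- medianShiftTest(dup, gdup)
  expect_true(all(res3$medianDiff == 0))
  expect_true(all(res3$p == 1))
})
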