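test_that("scaled difference of means follows the score formula exactly", {
  x <- logMatrix(c(2, 4, 3), c("g1", "g2", "g3"), "s1")
  p <- GeneProgram("p", up = c("g1", "g2"), down = "g3")
  expect_equal(unname(scoreScaledDifference(x, p)), (2 + 4 - 3) / 3)

  # symmetry: equal values with N_u = N_d give 0
  x2 <- logMatrix(rep(5, 4), paste0("g", 1:4), c("s1", "s2"))
  p2 <- GeneProgram("p2", up = c("g1", "g2"), down = c("g3", "g4"))
  expect_equal(unname(scoreScaledDifference(x2, p2)), c(0, 0))

  # linearity: adding c to every gene shifts S by c(Nu - Nd)/(Nu + Nd)
  x3 <- logMatrix(c(1, 2, 3), paste0("g", 1:3), "s1")
  s0 <- scoreScaledDifference(x3, p)
  s1 <- scoreScaledDifference(x3 + 2, p)
  expect_equal(unname(s1 - s0), 2 * (2 - 1) / 3)

  # gene-order invariance
  pRev <- GeneProgram("p", up = c("g2", "g1"), down = "g3")
  expect_equal(scoreScaledDifference(x3, pRev), scoreScaledDifference(x3, p))
  expect_error(scoreScaledDifference(x3, GeneProgram("q", up = "missing")),
               "not measured")
})

test_that("PCA score is sign-oriented and tracks the scaled difference", {
  # two perfectly correlated up-genes: PC1 explains everything and the
  # score ordering equals the gene-mean ordering
  vals <- c(1, 3, 2, 5, 4)
  x <- rbind(g1 = vals, g2 = 2 * vals)
  colnames(x) <- paste0("s", 1:5)
  p <- GeneProgram("p", up = c("g1", "g2"))
  sc <- scorePCA(x, p)
  expect_equal(attr(sc, "varExplained"), 1)
  expect_equal(order(sc), order(colMeans(x)))
  # orientation: correlation with the scaled difference is non-negative,
  # so flipping all loadings cannot change the reported score
  expect_gte(cor(as.vector(sc), scoreScaledDifference(x, p)), 0)
  expect_error(scorePCA(matrix(1, 2, 3, dimnames = list(c("g1", "g2"),
                                                        paste0("s", 1:3))),
               p), "zero variance")
})

test_that("PCA and scaled-difference scores agree on a planted cohort", {
  co <- smallCohort(seed = 7, nSamples = 150)
  tmdR <- restrictToMeasured(co$library[["TMD"]],
                             rownames(co$expr))$program
  r <- cor(scoreScaledDifference(co$expr, tmdR),
           as.vector(scorePCA(co$expr, tmdR)))
  expect_gte(r, 0.8)
})

test_that("mean program score is the arithmetic mean of up genes", {
  x <- logMatrix(c(1, 3), c("g1", "g2"), "s1")
  p <- GeneProgram("p", up = c("g1", "g2"))
  expect_equal(unname(scoreMeanProgram(x, p)), 2)
  # single gene: score equals that gene's value
  expect_equal(unname(scoreMeanProgram(x, GeneProgram("q", up = "g1"))), 1)
  # constant matrix
  xc <- logMatrix(rep(4, 4), c("g1", "g2"), c("s1", "s2"))
  expect_equal(unname(scoreMeanProgram(xc, p)), c(4, 4))
  expect_error(scoreMeanProgram(x, GeneProgram("r", up = "g1", down = "g2")),
               "all-upregulated")
})

test_that("proliferation/apoptosis ratio and its degenerate case", {
  x <- logMatrix(c(4, 4, 2, 2), paste0("g", 1:4), "s1")
  prolif <- GeneProgram("prolif", up = c("g1", "g2"))
  apop <- GeneProgram("apop", up = c("g3", "g4"))
  expect_equal(unname(proliferationApoptosisRatio(x, prolif, apop)), 2)
  xeq <- logMatrix(rep(3, 4), paste0("g", 1:4), "s1")
  expect_equal(unname(proliferationApoptosisRatio(xeq, prolif, apop)), 1)
  x0 <- logMatrix(c(4, 4, 0, 0), paste0("g", 1:4), "s1")
  expect_error(proliferationApoptosisRatio(x0, prolif, apop), "s1")
})

test_that("dormancy classification follows the quartile/ratio rules", {
  # constructed boundary cohort: 8 samples with known quartiles
  tmd <- c(10, 9, 9, 5, 4, 3, 1, 0)
  ad <- c(10, 9, 1, 1, 1, 1, 1, 1)
  id <- c(10, 1, 9, 1, 1, 1, 1, 1)
  ratio <- c(0.5, 0.8, 0.9, 0.8, 1.2, 1.0, 1.2, 1.3)
  names(tmd) <- names(ad) <- names(id) <- names(ratio) <- paste0("s", 1:8)
  calls <- classifyDormancy(tmd, ad, id, ratio)
  expect_equal(as.character(calls$category[1]), "A/ID")  # both upper quartiles
  expect_equal(as.character(calls$category[2]), "AD")    # AD high, ID low
  expect_equal(as.character(calls$category[3]), "ID")    # ID high, AD low
  expect_equal(as.character(calls$category[8]), "NO")    # low tmd, ratio > 1
  expect_equal(as.character(calls$category[6]), "MID")   # ratio exactly 1
  # exhaustive and mutually exclusive
  expect_equal(sum(table(calls$category)), 8)
  expect_false(any(calls$category %in% c("A/ID", "AD", "ID") & !calls$tmdHigh))
  expect_true(all(calls$ratio[calls$category %in% c("A/ID", "AD", "ID")] < 1))
  expect_true(all(calls$ratio[calls$category == "NO"] > 1))

  # tmd high but ratio too large stays MID
  ratio2 <- ratio; ratio2[1] <- 1.2
  calls2 <- classifyDormancy(tmd, ad, id, ratio2)
  expect_equal(as.character(calls2$category[1]), "MID")

  # TMD-high sample in neither AD nor ID upper quartile: flagged MID
  ad3 <- c(10, 0, 1, 1, 2, 3, 1, 1); id3 <- c(10, 0, 9, 1, 2, 3, 1, 1)
  names(ad3) <- names(id3) <- names(tmd)
  calls3 <- classifyDormancy(tmd, ad3, id3, ratio)
  expect_equal(as.character(calls3$category[2]), "MID")
  expect_true(calls3$unassignedHigh[2])
  expect_error(classifyDormancy(c(tmd[-1], NA), ad, id, ratio), "NA")
})

test_that("hypoxia score implements the median +/-1 rule with binning", {
  genes <- paste0("h", 1:6)
  x <- matrix(c(rep(1, 6), rep(2, 6), rep(3, 6)), nrow = 6,
              dimnames = list(genes, c("low", "mid", "high")))
  p <- GeneProgram("hyp", up = genes)
  hs <- hypoxiaScore(x, p)
  expect_equal(hs$score, c(-6L, 0L, 6L))   # the median sample scores 0
  expect_equal(hs$bin, c(-1L, 0L, 0L))
  # all-equal gene contributes 0 everywhere
  x2 <- x; x2["h1", ] <- 7
  hs2 <- hypoxiaScore(x2, p)
  expect_equal(hs2$score, c(-5L, 0L, 5L))
  # bin = floor(score / 10)
  expect_equal(floor(c(14, -3) / 10), c(1, -1))
  expect_error(hypoxiaScore(x, p, exclusion = genes[1:2]), "fewer than 5")
})

test_that("ssGSEA scores are rank-based and monotone-invariant", {
  withr::with_seed(11, {
    x <- matrix(rnorm(200 * 8), 200, 8,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:8)))
  })
  lib <- ProgramLibrary(list(
    GeneProgram("setA", up = paste0("g", 1:10)),
    GeneProgram("setB", up = paste0("g", 11:20)),
    GeneProgram("dupA", up = paste0("g", 1:10))))
  sc <- ssgseaScores(x, lib, combined = NULL)
  # duplicated marker set under two names gives identical columns
  expect_equal(sc[, "setA"], sc[, "dupA"])
  # invariance under a strictly monotone transform of one sample
  x2 <- x; x2[, 3] <- exp(x2[, 3] / 2)
  sc2 <- ssgseaScores(x2, lib, combined = NULL)
  expect_equal(sc2[3, ], sc[3, ])
  # marker sets below 2 measured genes are skipped with a warning
  libBad <- ProgramLibrary(list(GeneProgram("tiny", up = "g1"),
                                GeneProgram("setA", up = paste0("g", 1:10))))
  expect_warning(sc3 <- ssgseaScores(x, libBad, combined = NULL), "tiny")
  expect_equal(colnames(sc3), "setA")
})

test_that("random marker sets score near zero on permuted samples", {
  withr::with_seed(13, {
    x <- matrix(rnorm(300 * 40), 300, 40,
                dimnames = list(paste0("g", 1:300), paste0("s", 1:40)))
    set <- sample(rownames(x), 20)
  })
  lib <- ProgramLibrary(list(GeneProgram("rand", up = set)))
  sc <- ssgseaScores(x, lib, combined = NULL)
  se <- sd(sc[, 1]) / sqrt(nrow(sc))
  expect_lt(abs(mean(sc[, 1])), max(2 * se, 0.05 * diff(range(sc[, 1]))))
})
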