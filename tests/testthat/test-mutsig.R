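test_that("catalogue channels follow the documented fixed order", {
  ch <- sbsChannels()
  expect_length(ch, 96)
  expect_equal(ch[1], "A[C>A]A")
  expect_equal(ch[96], "T[T>G]T")
  expect_false(anyDuplicated(ch) > 0)
})

test_that("catalogue construction pyrimidine-normalizes and conserves counts", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "AACATGTT"))
  # C>T at reference context A_C_A -> A[C>T]A
  v1 <- data.frame(sample_id = "s1", gene_symbol = "g", chrom = "chr1",
                   pos = 3L, ref_allele = "C", alt_allele = "T",
                   variant_classification = "Missense", protein_change = "")
  # G>A at reference context T_G_T -> reverse complement -> A[C>T]A
  v2 <- data.frame(sample_id = "s1", gene_symbol = "g", chrom = "chr1",
                   pos = 6L, ref_allele = "G", alt_allele = "A",
                   variant_classification = "Missense", protein_change = "")
  cat96 <- buildCatalogue(rbind(v1, v2), ref)
  expect_equal(unname(catalogueCounts(cat96)["s1", "A[C>T]A"]), 2L)
  expect_equal(sum(catalogueCounts(cat96)), 2L)

  # full reverse-complement enumeration: every purine-reference SNV maps
  # to the same channel as its pyrimidine mirror
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (ref5 in bases) for (ref3 in bases) for (mid in c("G", "A")) {
    alts <- setdiff(bases, mid)
    for (alt in alts) {
      seqF <- paste0("A", ref5, mid, ref3, "A")
      refSet <- Biostrings::DNAStringSet(setNames(seqF, "c"))
      v <- data.frame(sample_id = "s", gene_symbol = "g", chrom = "c",
                      pos = 3L, ref_allele = mid, alt_allele = alt,
                      variant_classification = "Missense",
                      protein_change = "")
      got <- sbsChannels()[which(catalogueCounts(
        buildCatalogue(v, refSet))["s", ] == 1L)]
      want <- paste0(comp[ref3], "[", comp[mid], ">", comp[alt], "]",
                     comp[ref5])
      expect_equal(got, want)
    }
  }

  # mismatching reference alleles are rejected and reported
  vBad <- v1; vBad$ref_allele <- "G"; vBad$alt_allele <- "T"
  catBad <- buildCatalogue(rbind(v1, vBad), ref)
  expect_equal(sum(catalogueCounts(catBad)), 1L)
  expect_equal(rejectedRecords(catBad)$refMismatch, 1L)

  # TSV round trip
  tmp <- tempfile(fileext = ".tsv")
  writeCatalogue(cat96, tmp)
  expect_identical(catalogueCounts(readCatalogue(tmp)),
                   catalogueCounts(cat96))
})

test_that("signature matrix IO auto-detects the COSMIC orientation", {
  sig <- syntheticSignatures()
  tmp <- tempfile(fileext = ".tsv")
  writeSignatureMatrix(sig, tmp)
  back <- readSignatureMatrix(tmp)
  expect_equal(back, sig, tolerance = 1e-12)
})

test_that("exposure refitting matches a 1-simplex grid-search oracle", {
  sig <- syntheticSignatures(c("SBS2", "SBS5"))
  gridOracle <- function(p, S) {
    ts <- seq(0, 1, by = 1e-3)
    err <- vapply(ts, function(t)
      sum((p - (t * S[1, ] + (1 - t) * S[2, ]))^2), numeric(1))
    ts[which.min(err)]
  }
  for (mix in c(0, 0.17, 0.4, 0.6, 0.83, 1)) {
    p <- mix * sig[1, ] + (1 - mix) * sig[2, ]
    counts <- matrix(round(p * 10000), 1, 96,
                     dimnames = list("s", sbsChannels()))
    fit <- refitExposures(counts, sig)
    expect_lt(abs(fit$exposures[1, "SBS2"] - gridOracle(
      counts[1, ] / sum(counts), sig)), 2e-3)
    expect_lt(abs(fit$exposures[1, "SBS2"] - mix), 0.02)
  }
  # exact single-signature catalogue: exposure 1 on it
  counts <- matrix(round(sig["SBS5", ] * 50000), 1, 96,
                   dimnames = list("s", sbsChannels()))
  fit <- refitExposures(counts, sig)
  expect_lt(abs(fit$exposures[1, "SBS5"] - 1), 1e-4)

  # a disallowed signature that generated mutations gets exposure 0 and a
  # strictly positive reconstruction error
  sig3 <- syntheticSignatures(c("SBS1", "SBS2", "SBS5"))
  p <- 0.7 * sig3["SBS5", ] + 0.3 * sig3["SBS2", ]
  counts <- matrix(round(p * 10000), 1, 96,
                   dimnames = list("s", sbsChannels()))
  fit3 <- refitExposures(counts, sig3, allowed = c("SBS1", "SBS5"))
  expect_identical(unname(fit3$exposures[1, "SBS2"]), 0)
  expect_gt(fit3$reconstructionError[1], 0)
  expect_error(refitExposures(counts, sig3, allowed = character()), "empty")
})

test_that("signature selection implements the SBS1/SBS5/5% zero-out rule", {
  sig <- syntheticSignatures()
  mk <- function(means) {
    expo <- matrix(rep(means, each = 4), 4, length(means),
                   dimnames = list(paste0("s", 1:4), names(means)))
    structure(list(exposures = expo, allowed = names(means)),
              class = "ExposureFit")
  }
  means <- c(SBS1 = 0.02, SBS2 = 0.04, SBS4 = 0.05, SBS5 = 0.30,
             SBS13 = 0.02, SBS18 = 0.47, SBS22 = 0.06, SBS40 = 0.04)
  # SBS1 kept despite 2% mean; 0.04 excluded; exactly 0.05 kept (inclusive)
  allowed <- selectSignatures(mk(means), sig)
  expect_setequal(allowed, c("SBS1", "SBS5", "SBS4", "SBS18", "SBS22"))

  # a de novo factor matching SBS13 pulls it in
  denovo <- list(chosenK = 1L,
                 factors = matrix(sig["SBS13", ], 1, 96,
                                  dimnames = list(NULL, sbsChannels())))
  allowed2 <- selectSignatures(mk(means), sig, denovo = denovo)
  expect_true("SBS13" %in% allowed2)

  # no stable de novo solution: fallback is the mean-exposure rule alone
  allowed3 <- selectSignatures(mk(means), sig,
                               denovo = list(chosenK = NA_integer_))
  expect_setequal(allowed3, allowed)
})

test_that("stability-based rank choice follows the stated selection rule", {
  tab <- data.frame(K = c(2, 3), avgStability = c(0.9, 0.7),
                    minStability = c(0.8, 0.35))
  expect_equal(chooseStableRank(tab), 2L)  # K=3 fails min >= 0.4
  tab2 <- data.frame(K = c(2, 3), avgStability = c(0.9, 0.7),
                     minStability = c(0.8, 0.45))
  expect_equal(chooseStableRank(tab2), 3L)
  tab3 <- data.frame(K = 2, avgStability = 0.5, minStability = 0.45)
  expect_true(is.na(chooseStableRank(tab3)))  # sum must exceed 1
})

test_that("de novo extraction recovers a rank-1 catalogue", {
  sig <- syntheticSignatures()
  withr::with_seed(8, {
    counts <- t(vapply(1:12, function(i)
      as.vector(rmultinom(1, 5000, sig["SBS2", ])), numeric(96)))
  })
  dimnames(counts) <- list(paste0("s", 1:12), sbsChannels())
  dn <- extractDenovo(counts, kRange = 1:2, nBoot = 8, seed = 4)
  expect_equal(dn$chosenK, 1L)
  expect_gte(dormscan:::cosineSim(dn$factors[1, ], sig["SBS2", ]), 0.99)
  dn2 <- extractDenovo(counts, kRange = 1:2, nBoot = 8, seed = 4)
  expect_identical(dn$stability, dn2$stability)
  expect_error(extractDenovo(counts[1:5, ], kRange = 1), "10 eligible")
})

test_that("cosine matching of factors to the reference panel", {
  sig <- syntheticSignatures()
  m <- matchSignatures(sig["SBS13", , drop = FALSE], sig)
  expect_equal(m$match, "SBS13")
  expect_equal(m$cosine, 1)
  # orthogonal profiles score 0 against each other
  a <- rep(0, 96); a[1] <- 1
  b <- rep(0, 96); b[2] <- 1
  expect_equal(dormscan:::cosineSim(a, b), 0)
  # uniform factor vs the uniform reference row scores exactly 1
  mu <- matchSignatures(matrix(rep(1 / 96, 96), 1), sig)
  expect_equal(mu$match, "SBS40")
  expect_equal(mu$cosine, 1)
})

test_that("APOBEC enrichment is calibrated under uniform cytosine mutagenesis
           and degenerate cases are reported", {
  ref <- simulateReference(1, 50000, seed = 6)
  seqc <- as.character(ref)[[1]]
  cpos <- which(strsplit(seqc, "")[[1]] %in% c("C", "G"))
  cpos <- cpos[cpos > 21 & cpos < nchar(seqc) - 21]
  scores <- withr::with_seed(9, {
    vapply(1:60, function(i) {
      pos <- sample(cpos, 80)
      refb <- substring(seqc, pos, pos)
      # deamination-type substitutions (C>T / C>G on the pyrimidine strand)
      altb <- ifelse(refb == "C", sample(c("T", "G"), 80, replace = TRUE),
                     sample(c("A", "C"), 80, replace = TRUE))
      v <- data.frame(sample_id = "s", gene_symbol = "g", chrom = "chr1",
                      pos = pos, ref_allele = refb, alt_allele = altb,
                      variant_classification = "Missense",
                      protein_change = "")
      apobecEnrichment(v, ref)$enrichment
    }, numeric(1))
  })
  expect_gt(mean(scores), 0.95)
  expect_lt(mean(scores), 1.05)

  # no cytosine mutations: missing with a reason code
  vT <- data.frame(sample_id = "s", gene_symbol = "g", chrom = "chr1",
                   pos = 100L, ref_allele = substring(seqc, 100, 100),
                   alt_allele = "N", variant_classification = "Missense",
                   protein_change = "")
  # force a T>x mutation: pick a T position
  tpos <- which(strsplit(seqc, "")[[1]] == "T")[10]
  vT$pos <- tpos; vT$ref_allele <- "T"; vT$alt_allele <- "C"
  res <- apobecEnrichment(vT, ref)
  expect_true(is.na(res$enrichment))
  expect_match(res$reason, "no cytosine")
})
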