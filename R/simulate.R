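#' Simulate a toy reference genome
#'
#' Generates i.i.d. uniform A/C/G/T chromosomes. The toy genome is the
#' context source for trinucleotide catalogues in place of a real genome
#' build; at uniform base composition every pyrimidine-normalized triplet
#' occurs at roughly 1/32 of positions, so all 96 channels are placeable.
#'
#' @param nChroms number of chromosomes.
#' @param chromLen length of each chromosome in bp (>= 100).
#' @param seed integer seed; the result is a pure function of
#'   (parameters, seed).
#' @return A [Biostrings::DNAStringSet] named `chr1..chrN`.
#' @export
simulateReference <- function(nChroms = 2L, chromLen = 60000L, seed = 1L) {
  if (chromLen < 100L) stop("chromLen must be at least 100")
  if (nChroms < 1L) stop("nChroms must be at least 1")
  seqs <- withSeed(seed, vapply(seq_len(nChroms), function(i)
    paste(sample(c("A", "C", "G", "T"), chromLen, replace = TRUE),
          collapse = ""), character(1)))
  names(seqs) <- paste0("chr", seq_len(nChroms))
  Biostrings::DNAStringSet(seqs)
}

# tissue-specific background signature profile over the non-APOBEC
# signatures of the panel: clock-like signatures get stable weight, and a
# tissue-position-dependent blend of two adjacent characteristic
# signatures gets the rest, so that tissues form a ring of distinct
# background profiles (more background structures than clusters, as in
# real pan-cancer signature landscapes).
.tissueBaseProfile <- function(tissueIndex, nTissues, sigNames) {
  nonAp <- setdiff(sigNames, c("SBS2", "SBS13"))
  if (!length(nonAp)) stop("signature panel needs non-APOBEC signatures")
  w <- setNames(rep(0.05, length(nonAp)), nonAp)
  clock <- intersect(c("SBS1", "SBS5"), nonAp)
  w[clock] <- 0.25
  extra <- setdiff(nonAp, clock)
  if (length(extra)) {
    u <- (tissueIndex - 1L) / nTissues * length(extra)
    j <- floor(u)
    frac <- u - j
    w[extra[j %% length(extra) + 1L]] <-
      w[extra[j %% length(extra) + 1L]] + 0.4 * (1 - frac)
    w[extra[(j + 1L) %% length(extra) + 1L]] <-
      w[extra[(j + 1L) %% length(extra) + 1L]] + 0.4 * frac
  } else {
    # only clock-like signatures available: vary their balance by tissue
    w[clock[1L]] <- w[clock[1L]] + 0.10 * tissueIndex
  }
  w / sum(w)
}

.rdirichlet <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate cohort ground truth
#'
#' Draws per-sample tissue, dormancy label, APOBEC-high status and planted
#' signature exposures. Default label frequencies follow the prevalences
#' the pipeline is meant to resolve (A/ID 7%, AD 4.4%, ID 5%, NO 25%,
#' MID remainder); 20% of samples are APOBEC-high with a total SBS2+SBS13
#' exposure of 0.6, all others at most 0.05. Non-APOBEC exposure mass
#' follows a tissue-specific Dirichlet profile, mimicking the
#' tissue-driven structure of real signature landscapes.
#'
#' @param nSamples cohort size.
#' @param tissues tissue labels to sample uniformly from (default 12,
#'   keeping more background tissue structures than consensus clusters).
#' @param fractions named label frequencies for `A/ID`, `AD`, `ID`, `NO`
#'   (MID receives the remainder).
#' @param apobecFraction fraction of samples planted as APOBEC-high.
#' @param apobecTotal total SBS2+SBS13 exposure planted in APOBEC-high
#'   samples.
#' @param apobecBackgroundMax upper bound of the SBS2+SBS13 exposure in
#'   non-APOBEC samples.
#' @param signatures reference panel whose rownames define the exposure
#'   columns; must contain SBS2 and SBS13.
#' @param enrichedDrivers,depletedDrivers driver genes planted as
#'   mutation-enriched / depleted in dormant (TMD-labelled) samples.
#' @param seed integer seed.
#' @return A [CohortTruth-class].
#' @export
simulateTruth <- function(nSamples = 500L,
                          tissues = paste0("tissue", 1:12),
                          fractions = c("A/ID" = 0.07, "AD" = 0.044,
                                        "ID" = 0.05, "NO" = 0.25),
                          apobecFraction = 0.2,
                          apobecTotal = 0.6,
                          apobecBackgroundMax = 0.05,
                          signatures = syntheticSignatures(),
                          enrichedDrivers = c("CASP8", "HRAS"),
                          depletedDrivers = c("TP53", "KRAS"),
                          seed = 1L) {
  .checkSignatureMatrix(signatures)
  sigNames <- rownames(signatures)
  if (!all(c("SBS2", "SBS13") %in% sigNames))
    stop("signature panel must contain SBS2 and SBS13")
  if (sum(fractions) > 1) stop("label fractions exceed 1")
  withSeed(seed, {
    ids <- sprintf("S%04d", seq_len(nSamples))
    tissue <- setNames(sample(tissues, nSamples, replace = TRUE), ids)
    probs <- c(fractions, MID = 1 - sum(fractions))
    label <- setNames(sample(names(probs), nSamples, replace = TRUE,
                             prob = probs), ids)
    apo <- setNames(rep(FALSE, nSamples), ids)
    apo[sample(nSamples, round(apobecFraction * nSamples))] <- TRUE

    nonAp <- setdiff(sigNames, c("SBS2", "SBS13"))
    expo <- matrix(0, nSamples, length(sigNames),
                   dimnames = list(ids, sigNames))
    for (i in seq_len(nSamples)) {
      ti <- match(tissue[i], tissues)
      base <- .tissueBaseProfile(ti, length(tissues), sigNames)
      if (apo[i]) {
        # APOBEC mutagenesis dominates the spectrum; the residual exposure
        # is clock-like rather than tissue-specific, so APOBEC-high tumors
        # form one cluster spanning heterogeneous tissues
        tot <- apobecTotal
        s2 <- tot * rbeta(1, 200, 200)
        clock <- setNames(rep(0.1 / max(length(nonAp) - 2L, 1L),
                              length(nonAp)), nonAp)
        clock[intersect(c("SBS1", "SBS5"), nonAp)] <- 0.45
        bg <- .rdirichlet(300 * clock / sum(clock))
      } else {
        tot <- runif(1, 0, apobecBackgroundMax)
        s2 <- tot * runif(1)
        bg <- .rdirichlet(30 * base)
      }
      expo[i, nonAp] <- (1 - tot) * bg
      expo[i, "SBS2"] <- s2
      expo[i, "SBS13"] <- tot - s2
    }
    expo <- expo / rowSums(expo)
    new("CohortTruth", sampleIds = ids, tissue = tissue,
        dormancyLabel = label, apobecHigh = apo, plantedExposures = expo,
        enrichedDrivers = enrichedDrivers, depletedDrivers = depletedDrivers,
        seed = as.integer(seed))
  })
}

# programs planted per dormancy label / APOBEC state
.activePrograms <- function(label, apobecHigh) {
  dormant <- label %in% c("A/ID", "AD", "ID")
  progs <- character()
  if (dormant) progs <- c(progs, "apoptosis")
  if (label %in% c("AD", "A/ID")) progs <- c(progs, "AD")
  if (label %in% c("ID", "A/ID")) progs <- c(progs, "ID")
  if (label == "NO") progs <- c(progs, "proliferation", "hypoxia_buffa")
  if (apobecHigh) progs <- c(progs, "APOBEC", "exhaustion")
  progs
}

#' Simulate cohort expression with planted programs
#'
#' Log-space additive model per gene g and sample s:
#' `x = baseline(g) + tissueShift(g, tissue(s)) + effectSize * plant(g, s)
#' + Normal(0, noiseSd)`, exponentiated back to an FPKM-like scale.
#' `plant` is +1 for upregulated genes of programs active under the
#' sample's planted label (the AD / ID component programs for the
#' corresponding dormant labels — the TMD score emerges from its
#' constituent genes —, the proliferation and hypoxia programs for
#' expanding `NO` tumors, APOBEC and exhaustion programs for APOBEC-high
#' samples), -1 for downregulated genes, 0 otherwise; contributions of
#' overlapping programs are summed and clamped to [-1, 1]. Dormant samples receive an upshifted apoptosis
#' and downshifted proliferation program so their planted
#' proliferation/apoptosis ratio is below 1 (and conversely for `NO`).
#'
#' @param truth a [CohortTruth-class].
#' @param library program library providing the planted programs.
#' @param markers optional cell-marker library whose genes are added to
#'   the gene universe (unplanted).
#' @param effectSize log2 shift planted per program gene (> 0; 0 allowed
#'   to generate a null cohort).
#' @param tissueSd SD of the per-gene-by-tissue log2 shift.
#' @param noiseSd SD of the i.i.d. log2 noise.
#' @param nGenes total gene universe size (program genes plus `BGxxxx`
#'   background genes).
#' @param seed integer seed.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assays
#'   `fpkm` and `logfpkm` (= log2(fpkm + 1), exactly) and colData columns
#'   `tissue`.
#' @export
simulateExpression <- function(truth, library = defaultPrograms(),
                               markers = defaultCellMarkers()$markers,
                               effectSize = 2, tissueSd = 0.5,
                               noiseSd = 0.5, nGenes = 2000L, seed = 1L) {
  if (effectSize < 0) stop("effectSize must be >= 0")
  progGenes <- unique(unlist(lapply(library@programs, function(p)
    c(p@upGenes, p@downGenes))))
  markGenes <- if (is.null(markers)) character() else
    unique(unlist(lapply(markers@programs, function(p) p@upGenes)))
  core <- unique(c(progGenes, markGenes,
                   truth@enrichedDrivers, truth@depletedDrivers))
  if (nGenes < length(core))
    stop("nGenes smaller than the program/driver gene universe (",
         length(core), ")")
  genes <- c(core, sprintf("BG%04d", seq_len(nGenes - length(core))))
  ids <- truth@sampleIds
  tissues <- sort(unique(truth@tissue))

  withSeed(seed, {
    baseline <- setNames(rnorm(length(genes), 4, 1), genes)
    shift <- matrix(rnorm(length(genes) * length(tissues), 0, tissueSd),
                    length(genes), length(tissues),
                    dimnames = list(genes, tissues))
    plant <- matrix(0, length(genes), length(ids),
                    dimnames = list(genes, ids))
    for (s in ids) {
      for (pn in .activePrograms(truth@dormancyLabel[s],
                                 truth@apobecHigh[s])) {
        p <- library[[pn]]
        miss <- setdiff(c(p@upGenes, p@downGenes), genes)
        if (length(miss))
          stop("program gene(s) missing from the simulated universe: ",
               paste(miss, collapse = ", "))
        plant[p@upGenes, s] <- plant[p@upGenes, s] + 1
        if (length(p@downGenes))
          plant[p@downGenes, s] <- plant[p@downGenes, s] - 1
      }
      # dormant tumors: proliferation program explicitly suppressed
      if (truth@dormancyLabel[s] %in% c("A/ID", "AD", "ID")) {
        pg <- library[["proliferation"]]@upGenes
        plant[pg, s] <- plant[pg, s] - 1
      }
      # expanding tumors: apoptosis program suppressed
      if (truth@dormancyLabel[s] == "NO") {
        ag <- library[["apoptosis"]]@upGenes
        plant[ag, s] <- plant[ag, s] - 1
      }
    }
    plant <- pmin(pmax(plant, -1), 1)
    logx <- baseline + shift[, truth@tissue[ids], drop = FALSE] +
      effectSize * plant +
      matrix(rnorm(length(genes) * length(ids), 0, noiseSd),
             length(genes), length(ids))
    logx <- pmax(logx, 0)
    dimnames(logx) <- list(genes, ids)
    fpkm <- 2^logx - 1
    SummarizedExperiment::SummarizedExperiment(
      assays = list(fpkm = fpkm, logfpkm = logx),
      colData = S4Vectors::DataFrame(tissue = unname(truth@tissue[ids]),
                                     row.names = ids),
      metadata = list(log_base = 2, pseudocount = 1,
                      effectSize = effectSize, tissueSd = tissueSd,
                      noiseSd = noiseSd, seed = as.integer(seed)))
  })
}

# index of usable positions (2..L-1) per pyrimidine-normalized triplet
.contextIndex <- function(reference) {
  chroms <- names(reference)
  seqs <- as.character(reference)
  out <- list()
  for (ci in seq_along(chroms)) {
    s <- seqs[ci]
    L <- nchar(s)
    pos <- 2:(L - 1L)
    tri <- substring(s, pos - 1L, pos + 1L)
    mid <- substr(tri, 2, 2)
    flip <- mid %in% c("A", "G")
    tri[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(tri[flip])))
    df <- data.frame(chrom = chroms[ci], pos = pos, flip = flip,
                     tri = tri, stringsAsFactors = FALSE)
    out[[ci]] <- df
  }
  all <- do.call(rbind, out)
  split(all[c("chrom", "pos", "flip")], all$tri)
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Simulate somatic variants with planted signatures and drivers
#'
#' Per sample, mutation channels are drawn from the multinomial mixture
#' `sum_k exposure(s, k) * signature(k)` and each mutation is placed at a
#' uniformly chosen toy-genome position whose pyrimidine-normalized
#' trinucleotide context matches the drawn channel. Driver gene mutation
#' indicators are drawn per sample with the odds multiplied by `driverOr`
#' in dormant (TMD-labelled) samples for planted enriched drivers and
#' divided by it for depleted drivers; a fraction of RAS-family driver
#' hits carries hotspot protein changes (Q61/G13/G12).
#'
#' @param truth a [CohortTruth-class].
#' @param reference toy genome ([Biostrings::DNAStringSet] from
#'   [simulateReference()]).
#' @param signatures reference panel matching the truth's exposure
#'   columns.
#' @param mutationsPerSample SNVs per sample (>= 50 so samples pass the
#'   catalogue eligibility filter).
#' @param driverOr planted odds ratio for driver enrichment (> 0; 1 means
#'   no planted association).
#' @param baseDriverRate per-sample baseline mutation probability of each
#'   driver gene.
#' @param hotspotFraction fraction of RAS driver hits annotated with a
#'   hotspot protein change.
#' @param seed integer seed.
#' @return A MAF-dialect `data.frame` with columns `sample_id`,
#'   `gene_symbol`, `chrom`, `pos` (1-based), `ref_allele`, `alt_allele`,
#'   `variant_classification`, `protein_change`.
#' @export
simulateVariants <- function(truth, reference,
                             signatures = syntheticSignatures(),
                             mutationsPerSample = 1000L, driverOr = 5,
                             baseDriverRate = 0.10, hotspotFraction = 0.5,
                             seed = 1L) {
  if (mutationsPerSample < 50L)
    stop("mutationsPerSample must be >= 50 (catalogue eligibility filter)")
  if (driverOr <= 0) stop("driverOr must be > 0")
  .checkSignatureMatrix(signatures)
  if (!all(colnames(truth@plantedExposures) %in% rownames(signatures)))
    stop("signature panel does not cover the planted exposure columns")
  sig <- signatures[colnames(truth@plantedExposures), , drop = FALSE]
  idx <- .contextIndex(reference)
  ctx <- channelContext()
  alt <- channelAlt()
  seqs <- as.character(reference)
  bgGenes <- sprintf("BG%04d", 1:200)
  bgClasses <- c("Missense", "Silent", "Nonsense", "Other")
  bgClassProb <- c(0.4, 0.45, 0.05, 0.1)

  withSeed(seed, {
    recs <- vector("list", length(truth@sampleIds) + 1L)
    for (si in seq_along(truth@sampleIds)) {
      s <- truth@sampleIds[si]
      p <- as.vector(truth@plantedExposures[s, ] %*% sig)
      counts <- as.vector(rmultinom(1, mutationsPerSample, p))
      chromV <- posV <- refV <- altV <- character(0)
      for (k in which(counts > 0L)) {
        avail <- idx[[ctx[k]]]
        if (is.null(avail) || nrow(avail) < counts[k])
          stop("toy genome has too few positions with context ", ctx[k],
               "; enlarge the reference")
        take <- avail[sample.int(nrow(avail), counts[k]), , drop = FALSE]
        a <- rep(alt[k], counts[k])
        a[take$flip] <- .COMPLEMENT[a[take$flip]]
        ref <- substring(seqs[take$chrom], take$pos, take$pos)
        chromV <- c(chromV, take$chrom)
        posV <- c(posV, as.character(take$pos))
        refV <- c(refV, ref)
        altV <- c(altV, a)
      }
      n <- length(chromV)
      recs[[si]] <- data.frame(
        sample_id = s, gene_symbol = sample(bgGenes, n, replace = TRUE),
        chrom = chromV, pos = as.integer(posV), ref_allele = refV,
        alt_allele = altV,
        variant_classification = sample(bgClasses, n, replace = TRUE,
                                        prob = bgClassProb),
        protein_change = "", stringsAsFactors = FALSE)
    }

    # driver indicator draws with planted odds multipliers
    drivers <- c(truth@enrichedDrivers, truth@depletedDrivers, "PIK3CA")
    dormant <- truth@dormancyLabel %in% c("A/ID", "AD", "ID")
    hsPool <- list(HRAS = c("p.Q61R", "p.Q61K", "p.G13D"),
                   KRAS = c("p.G12D", "p.G12V", "p.G13D"),
                   NRAS = c("p.Q61R", "p.Q61L"))
    drecs <- list()
    for (g in drivers) {
      o <- baseDriverRate / (1 - baseDriverRate)
      mult <- rep(1, length(truth@sampleIds))
      if (g %in% truth@enrichedDrivers) mult[dormant] <- driverOr
      if (g %in% truth@depletedDrivers) mult[dormant] <- 1 / driverOr
      pr <- (o * mult) / (1 + o * mult)
      hit <- rbinom(length(pr), 1, pr) == 1L
      if (!any(hit)) next
      nh <- sum(hit)
      chrom <- sample(names(reference), nh, replace = TRUE)
      pos <- vapply(chrom, function(cn)
        sample(2:(nchar(seqs[cn]) - 1L), 1L), integer(1))
      ref <- substring(seqs[chrom], pos, pos)
      altb <- vapply(ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
      pc <- rep("", nh)
      if (g %in% names(hsPool)) {
        ishs <- runif(nh) < hotspotFraction
        pc[ishs] <- sample(hsPool[[g]], sum(ishs), replace = TRUE)
      }
      drecs[[g]] <- data.frame(
        sample_id = truth@sampleIds[hit], gene_symbol = g, chrom = chrom,
        pos = pos, ref_allele = ref, alt_allele = altb,
        variant_classification = "Missense", protein_change = pc,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, c(recs[lengths(recs) > 0], unname(drecs)))
    rownames(out) <- NULL
    # de-duplicate on (sample, chrom, pos, alt); collisions are rare
    out[!duplicated(out[c("sample_id", "chrom", "pos", "alt_allele")]), ]
  })
}

#' Simulate clinical and survival data
#'
#' Exponential survival times with the hazard multiplied by `hrNoVsTmd`
#' for `NO`-labelled (expanding) samples; a fixed fraction of samples is
#' censored at an independent uniform fraction of their event time. Age is
#' Normal(60, 10) clipped to [30, 90], gender is balanced, study is the
#' sample's tissue and stage is early/late with probability 1/2,
#' independent of everything else.
#'
#' @param truth a [CohortTruth-class].
#' @param hrNoVsTmd hazard ratio of `NO` samples versus everyone else
#'   (> 0).
#' @param baseRate baseline exponential hazard per day.
#' @param censorFraction fraction of samples censored.
#' @param seed integer seed.
#' @return `data.frame` with columns `sample_id`, `age`, `gender`,
#'   `study`, `stage`, `time` (days, > 0), `event` (1 death, 0 censored).
#' @export
simulateClinical <- function(truth, hrNoVsTmd = 2, baseRate = 1 / 1000,
                             censorFraction = 0.2, seed = 1L) {
  if (hrNoVsTmd <= 0) stop("hrNoVsTmd must be > 0")
  n <- length(truth@sampleIds)
  withSeed(seed, {
    rate <- baseRate * ifelse(truth@dormancyLabel == "NO", hrNoVsTmd, 1)
    t <- rexp(n, rate)
    cens <- runif(n) < censorFraction
    t[cens] <- t[cens] * runif(sum(cens))
    t <- pmax(t, 1e-6)
    data.frame(
      sample_id = truth@sampleIds,
      age = pmin(pmax(round(rnorm(n, 60, 10)), 30), 90),
      gender = sample(c("male", "female"), n, replace = TRUE),
      study = unname(truth@tissue),
      stage = sample(c("early", "late"), n, replace = TRUE),
      time = t, event = as.integer(!cens), stringsAsFactors = FALSE)
  })
}
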