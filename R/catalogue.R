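#' Build a 96-channel SBS catalogue from variants and a reference
#'
#' For each single-nucleotide variant, the 5' and 3' flanking bases are
#' extracted from the reference; purine-reference substitutions are
#' reverse-complemented onto the pyrimidine strand (the alternate allele
#' is complemented accordingly), and the matching channel count is
#' incremented. Records whose stated reference allele disagrees with the
#' genome are rejected; non-SNV records (multi-base or identical alleles)
#' are skipped. Both are reported per sample.
#'
#' @param variants MAF-dialect `data.frame` (see [simulateVariants()] for
#'   the column contract); positions are 1-based and must have both
#'   flanking bases on their chromosome.
#' @param reference [Biostrings::DNAStringSet] reference genome.
#' @param minMutations eligibility threshold for downstream signature
#'   analysis (default 50).
#' @return A [MutationalCatalogue-class]. The row sum of each sample
#'   equals its number of accepted SNVs.
#' @export
buildCatalogue <- function(variants, reference, minMutations = 50L) {
  req <- c("sample_id", "chrom", "pos", "ref_allele", "alt_allele")
  miss <- setdiff(req, colnames(variants))
  if (length(miss))
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  bases <- c("A", "C", "G", "T")
  isSNV <- variants$ref_allele %in% bases & variants$alt_allele %in% bases &
    variants$ref_allele != variants$alt_allele
  v <- variants[isSNV, , drop = FALSE]
  seqs <- as.character(reference)
  lens <- nchar(seqs)
  if (!all(v$chrom %in% names(reference)))
    stop("variant chromosome(s) absent from the reference")
  inRange <- v$pos >= 2L & v$pos <= lens[v$chrom] - 1L
  if (!all(inRange))
    stop("SNV position(s) without both flanking bases on the reference")
  tri <- substring(seqs[v$chrom], v$pos - 1L, v$pos + 1L)
  refOk <- substr(tri, 2, 2) == v$ref_allele
  rej <- v[!refOk, , drop = FALSE]
  v <- v[refOk, , drop = FALSE]
  tri <- tri[refOk]
  alt <- v$alt_allele
  flip <- v$ref_allele %in% c("A", "G")
  if (any(flip)) {
    tri[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(tri[flip])))
    alt[flip] <- .COMPLEMENT[alt[flip]]
  }
  channel <- paste0(substr(tri, 1, 1), "[", substr(tri, 2, 2), ">", alt,
                    "]", substr(tri, 3, 3))
  samples <- sort(unique(variants$sample_id))
  counts <- matrix(0L, length(samples), 96L,
                   dimnames = list(samples, sbsChannels()))
  tab <- table(factor(v$sample_id, levels = samples),
               factor(channel, levels = sbsChannels()))
  counts[, ] <- as.integer(tab)
  nonSNV <- table(factor(variants$sample_id[!isSNV], levels = samples))
  refMis <- table(factor(rej$sample_id, levels = samples))
  rejected <- data.frame(sample = samples,
                         nonSNV = as.integer(nonSNV),
                         refMismatch = as.integer(refMis),
                         stringsAsFactors = FALSE)
  new("MutationalCatalogue", counts = counts, rejected = rejected,
      minMutations = as.integer(minMutations))
}

#' Write / read a catalogue as TSV
#'
#' Plain samples-by-channel TSV; reading a written catalogue reproduces
#' the counts exactly.
#'
#' @param catalogue a [MutationalCatalogue-class].
#' @param path TSV path.
#' @return `writeCatalogue` invisibly returns `path`; `readCatalogue`
#'   returns a [MutationalCatalogue-class] (with an empty rejected
#'   report).
#' @export
writeCatalogue <- function(catalogue, path) {
  df <- data.frame(sample = rownames(catalogue@counts), catalogue@counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCatalogue
#' @param minMutations eligibility threshold for the re-read catalogue.
#' @export
readCatalogue <- function(path, minMutations = 50L) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  m <- m[, sbsChannels(), drop = FALSE]
  new("MutationalCatalogue", counts = m,
      rejected = data.frame(sample = rownames(m),
                            nonSNV = 0L, refMismatch = 0L,
                            stringsAsFactors = FALSE),
      minMutations = as.integer(minMutations))
}

#' APOBEC tCw fold-enrichment score
#'
#' Roberts-style fold enrichment of cytosine mutagenesis at tCw motifs
#' (w = A or T, matched on the pyrimidine-normalized strand):
#' `E = (m_tCw / c_tCw) / (m_C / c_C)`, where `m_tCw` counts C>T/C>G
#' mutations at tCw motifs, `m_C` counts all cytosine mutations, and
#' `c_tCw` / `c_C` count motif / cytosine occurrences (on both strands)
#' within +/- `window` bp of each cytosine mutation. The mutated site's
#' own trinucleotide is excluded from the availability counts (it belongs
#' to the mutation side of the ratio, and a C/G center suppresses motifs
#' at the adjacent positions), which makes the estimator unbiased: under
#' deamination-type mutations placed uniformly over cytosines the
#' expected score is exactly 1.
#'
#' @inheritParams buildCatalogue
#' @param window context half-width in bp (default 20).
#' @return `data.frame` per sample: `sample`, `enrichment`, `mTCW`, `mC`,
#'   `cTCW`, `cC`, `reason` (why the score is missing, if it is).
#' @export
apobecEnrichment <- function(variants, reference, window = 20L) {
  bases <- c("A", "C", "G", "T")
  isSNV <- variants$ref_allele %in% bases & variants$alt_allele %in% bases &
    variants$ref_allele != variants$alt_allele
  v <- variants[isSNV, , drop = FALSE]
  seqs <- as.character(reference)
  lens <- nchar(seqs)
  isC <- v$ref_allele %in% c("C", "G")   # cytosine mutation on either strand
  v <- v[isC, , drop = FALSE]
  if (nrow(v)) {
    tri <- substring(seqs[v$chrom], v$pos - 1L, v$pos + 1L)
    alt <- v$alt_allele
    flip <- v$ref_allele == "G"
    tri[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(tri[flip])))
    alt[flip] <- .COMPLEMENT[alt[flip]]
    v$tcw <- substr(tri, 1, 1) == "T" & substr(tri, 3, 3) %in% c("A", "T") &
      alt %in% c("T", "G")
    # availability windows flank the mutation, excluding its own triplet;
    # the padded variants give edge cytosines their full context so motif
    # availability is not undercounted relative to cytosine availability
    L <- lens[v$chrom]
    v$winL <- substring(seqs[v$chrom], pmax(v$pos - window, 1L),
                        pmax(v$pos - 2L, 0L))
    v$winR <- substring(seqs[v$chrom], v$pos + 2L,
                        pmin(v$pos + window, L))
    v$winLPad <- substring(seqs[v$chrom], pmax(v$pos - window - 1L, 1L),
                           pmax(v$pos - 1L, 0L))
    v$winRPad <- substring(seqs[v$chrom], v$pos + 1L,
                           pmin(v$pos + window + 1L, L))
  }
  motifs <- c("TCA", "TCT", "TGA", "AGA")   # tCw and its reverse complement
  samples <- sort(unique(variants$sample_id))
  out <- lapply(samples, function(s) {
    vs <- v[v$sample_id == s, , drop = FALSE]
    mC <- nrow(vs)
    if (mC == 0L)
      return(data.frame(sample = s, enrichment = NA_real_, mTCW = 0L,
                        mC = 0L, cTCW = 0L, cC = 0L,
                        reason = "no cytosine mutations",
                        stringsAsFactors = FALSE))
    wins <- Biostrings::DNAStringSet(c(vs$winL, vs$winR))
    winsPad <- Biostrings::DNAStringSet(c(vs$winLPad, vs$winRPad))
    cC <- sum(Biostrings::letterFrequency(wins, c("C", "G")))
    cTCW <- sum(vapply(motifs, function(m)
      sum(Biostrings::vcountPattern(m, winsPad)), numeric(1)))
    mTCW <- sum(vs$tcw)
    if (cTCW == 0L)
      return(data.frame(sample = s, enrichment = NA_real_, mTCW = mTCW,
                        mC = mC, cTCW = 0L, cC = cC,
                        reason = "no tCw context in windows",
                        stringsAsFactors = FALSE))
    data.frame(sample = s, enrichment = (mTCW / cTCW) / (mC / cC),
               mTCW = mTCW, mC = mC, cTCW = cTCW, cC = cC, reason = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
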