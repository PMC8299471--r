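#' The 96 SBS channel names in package order
#'
#' Channels are pyrimidine-centered trinucleotide substitutions ordered
#' lexicographically by (substitution class, 5' base, 3' base):
#' substitution classes C>A, C>G, C>T, T>A, T>C, T>G; flanking bases
#' A, C, G, T. The first channel is `A[C>A]A`, the last `T[T>G]T`. This
#' order is fixed and used by every catalogue and signature matrix in the
#' package.
#'
#' @return Character vector of 96 channel names like `"A[C>A]A"`.
#' @export
sbsChannels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  as.vector(vapply(subs, function(s)
    as.vector(outer(bases, bases,
                    function(f, t) paste0(f, "[", s, "]", t))),
    character(16)))
}

# channel -> pyrimidine-strand trinucleotide ("A[C>A]A" -> "ACA")
channelContext <- function(channels = sbsChannels()) {
  paste0(substr(channels, 1, 1), substr(channels, 3, 3),
         substr(channels, 7, 7))
}

# channel -> alternate base on the pyrimidine strand
channelAlt <- function(channels = sbsChannels()) substr(channels, 5, 5)

.checkSignatureMatrix <- function(signatures) {
  if (!is.matrix(signatures) || ncol(signatures) != 96L)
    stop("signature matrix must be signatures x 96 channels")
  if (is.null(rownames(signatures)))
    stop("signature matrix needs signature names as rownames")
  if (any(signatures < 0)) stop("signature probabilities must be >= 0")
  if (any(abs(rowSums(signatures) - 1) > 1e-9))
    stop("signature rows must sum to 1 (tol 1e-9)")
  if (!identical(colnames(signatures), sbsChannels()))
    stop("signature columns must follow sbsChannels() order")
  invisible(signatures)
}

#' Synthetic COSMIC-style reference signatures
#'
#' A deterministic, fully synthetic stand-in for a reference signature
#' panel, built from the qualitative channel preferences associated with
#' each process (e.g. the APOBEC signatures peak at T[C>T]W / T[C>G]W,
#' the clock-like deamination signature at N[C>T]G). The profiles are NOT
#' the COSMIC signatures; they reuse the SBS names only so that selection
#' rules (SBS1/SBS5 always kept, SBS2/SBS13 as the APOBEC pair) can be
#' exercised end to end.
#'
#' @param names subset of the available signature names to return.
#' @return signatures x 96 probability matrix (rows sum to 1).
#' @export
syntheticSignatures <- function(names = c("SBS1", "SBS2", "SBS4", "SBS5",
                                          "SBS13", "SBS18", "SBS22",
                                          "SBS40")) {
  ch <- sbsChannels()
  peak <- function(targets, weight = 0.9, eps = 0.1) {
    x <- rep(eps / 96, 96)
    x[match(targets, ch)] <- x[match(targets, ch)] + weight / length(targets)
    x / sum(x)
  }
  profiles <- list(
    SBS1  = peak(paste0(c("A", "C", "G", "T"), "[C>T]G")),
    SBS2  = peak(c("T[C>T]A", "T[C>T]T"), weight = 0.92, eps = 0.08),
    SBS4  = peak(as.vector(outer(c("A", "C", "G", "T"), c("A", "C"),
                                 function(f, t) paste0(f, "[C>A]", t))),
                 weight = 0.85, eps = 0.15),
    SBS5  = peak(as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                 function(f, t) paste0(f, "[T>C]", t))),
                 weight = 0.7, eps = 0.3),
    SBS13 = peak(c("T[C>G]A", "T[C>G]T"), weight = 0.92, eps = 0.08),
    SBS18 = peak(as.vector(outer(c("A", "C", "G", "T"), c("A", "T"),
                                 function(f, t) paste0(f, "[C>A]", t))),
                 weight = 0.8, eps = 0.2),
    SBS22 = peak(as.vector(outer(c("C", "T"), c("A", "G"),
                                 function(f, t) paste0(f, "[T>A]", t))),
                 weight = 0.88, eps = 0.12),
    SBS40 = rep(1 / 96, 96)
  )
  miss <- setdiff(names, names(profiles))
  if (length(miss)) stop("unknown synthetic signature(s): ",
                         paste(miss, collapse = ", "))
  m <- do.call(rbind, profiles[names])
  colnames(m) <- ch
  .checkSignatureMatrix(m)
}

#' Read a signature matrix from a COSMIC-format TSV
#'
#' Orientation is auto-detected from the header/first column: if the first
#' column contains channel names (with a `[` substitution bracket) the
#' file is channels-as-rows (COSMIC layout) and is transposed; otherwise
#' signatures are taken as rows. Channels are reordered to
#' [sbsChannels()] order.
#'
#' @param path TSV path.
#' @return signatures x 96 probability matrix.
#' @export
readSignatureMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  first <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (any(grepl("[", first, fixed = TRUE))) {
    rownames(m) <- first
    m <- t(m)                         # -> signatures x channels
  } else {
    rownames(m) <- first
  }
  if (!all(sbsChannels() %in% colnames(m)))
    stop("file does not define all 96 SBS channels")
  m <- m[, sbsChannels(), drop = FALSE]
  storage.mode(m) <- "double"
  m <- m / rowSums(m)
  .checkSignatureMatrix(m)
}

#' Write a signature matrix as a COSMIC-format TSV
#'
#' Channels as rows, signatures as columns (the conventional reference
#' layout, re-readable with [readSignatureMatrix()]).
#'
#' @param signatures signatures x 96 matrix.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeSignatureMatrix <- function(signatures, path) {
  .checkSignatureMatrix(signatures)
  df <- data.frame(Type = sbsChannels(), t(signatures),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
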