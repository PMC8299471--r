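#' Gene program with signed membership
#'
#' A `GeneProgram` holds the gene symbols expected to be upregulated
#' (`upGenes`, at least one) and, optionally, downregulated (`downGenes`)
#' in a transcriptional program such as tumor mass dormancy. Symbols are
#' case-sensitive and must be unique within each side and disjoint across
#' sides; no alias resolution is attempted.
#'
#' @slot name single program label.
#' @slot upGenes character vector of upregulated gene symbols.
#' @slot downGenes character vector of downregulated gene symbols (may be
#'   empty).
#' @slot note free-text provenance / description carried through GMT
#'   round trips.
#' @aliases GeneProgram-class
#' @exportClass GeneProgram
setClass("GeneProgram",
  representation(name = "character", upGenes = "character",
                 downGenes = "character", note = "character"))

setValidity("GeneProgram", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@upGenes) < 1L)
    msg <- c(msg, "a program needs at least one upregulated gene")
  if (anyDuplicated(object@upGenes))
    msg <- c(msg, "duplicated symbols in upGenes")
  if (anyDuplicated(object@downGenes))
    msg <- c(msg, "duplicated symbols in downGenes")
  if (length(intersect(object@upGenes, object@downGenes)) > 0L)
    msg <- c(msg, "upGenes and downGenes must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneProgram
#'
#' @param name program label.
#' @param up character vector of upregulated gene symbols (length >= 1).
#' @param down character vector of downregulated gene symbols.
#' @param note description text preserved by [writeGMT()].
#' @return A [GeneProgram-class] object.
#' @examples
#' GeneProgram("TMD", up = c("STAT1", "CXCL9"), down = "VEGFA")
#' @export
GeneProgram <- function(name, up, down = character(), note = ".") {
  new("GeneProgram", name = as.character(name), upGenes = as.character(up),
      downGenes = as.character(down), note = as.character(note))
}

#' @describeIn GeneProgram program label accessor
#' @param x,object a `GeneProgram`.
#' @export
programName <- function(x) x@name

#' @describeIn GeneProgram upregulated gene symbols
#' @export
upGenes <- function(x) x@upGenes

#' @describeIn GeneProgram downregulated gene symbols
#' @export
downGenes <- function(x) x@downGenes

#' @describeIn GeneProgram number of genes (N_u + N_d)
#' @export
programSize <- function(x) length(x@upGenes) + length(x@downGenes)

setMethod("show", "GeneProgram", function(object) {
  cat("GeneProgram \"", object@name, "\": ", length(object@upGenes),
      " up / ", length(object@downGenes), " down genes\n", sep = "")
  cat("  up:   ", paste(head(object@upGenes, 8L), collapse = ", "),
      if (length(object@upGenes) > 8L) ", ..." else "", "\n", sep = "")
  if (length(object@downGenes))
    cat("  down: ", paste(head(object@downGenes, 8L), collapse = ", "),
        if (length(object@downGenes) > 8L) ", ..." else "", "\n", sep = "")
})

#' Library of gene programs
#'
#' A named collection of [GeneProgram-class] objects. Program names are
#' unique; genes may be shared across programs (only within-program
#' disjointness of the up/down sides is enforced).
#'
#' @slot programs named list of `GeneProgram` objects.
#' @slot version free-text version tag.
#' @aliases ProgramLibrary-class
#' @exportClass ProgramLibrary
setClass("ProgramLibrary",
  representation(programs = "list", version = "character"))

setValidity("ProgramLibrary", function(object) {
  msg <- character()
  ok <- vapply(object@programs, function(p) methods::is(p, "GeneProgram"),
               logical(1))
  if (length(object@programs) && !all(ok))
    msg <- c(msg, "all elements must be GeneProgram objects")
  nm <- vapply(object@programs, programName, character(1))
  if (anyDuplicated(nm))
    msg <- c(msg, paste("duplicated program names:",
                        paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  if (length(object@programs) && !identical(unname(nm),
                                            unname(names(object@programs))))
    msg <- c(msg, "list names must equal program names")
  if (length(msg)) msg else TRUE
})

#' Construct a ProgramLibrary
#'
#' @param programs list of [GeneProgram-class] objects.
#' @param version version tag.
#' @return A [ProgramLibrary-class].
#' @export
ProgramLibrary <- function(programs = list(), version = "0") {
  names(programs) <- vapply(programs, programName, character(1))
  new("ProgramLibrary", programs = programs, version = as.character(version))
}

#' @export
setMethod("length", "ProgramLibrary", function(x) length(x@programs))

#' @export
setMethod("names", "ProgramLibrary", function(x) names(x@programs))

#' @export
setMethod("[[", "ProgramLibrary", function(x, i) {
  p <- x@programs[[i]]
  if (is.null(p)) stop("no program named '", i, "' in library")
  p
})

setMethod("show", "ProgramLibrary", function(object) {
  cat("ProgramLibrary (version ", object@version, ") with ",
      length(object@programs), " programs:\n  ",
      paste(names(object@programs), collapse = ", "), "\n", sep = "")
})

#' Assert that a library defines the named programs
#'
#' The scoring pipeline expects at minimum the TMD, ID, AD, exhaustion,
#' APOBEC, proliferation, apoptosis and hypoxia_buffa programs.
#'
#' @param library a [ProgramLibrary-class].
#' @param required character vector of program names that must be present.
#' @return Invisibly `TRUE`; errors listing missing names otherwise.
#' @export
requirePrograms <- function(library,
                            required = c("TMD", "ID", "AD", "exhaustion",
                                         "APOBEC", "proliferation",
                                         "apoptosis", "hypoxia_buffa")) {
  missing <- setdiff(required, names(library))
  if (length(missing))
    stop("library lacks required programs: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Planted ground truth for a synthetic cohort
#'
#' Records everything the synthetic generators plant: per-sample tissue and
#' dormancy label, the planted signature exposure matrix (rows on the
#' 1-simplex), APOBEC-high status, and the driver genes planted as
#' enriched/depleted in dormant samples.
#'
#' @slot sampleIds sample identifiers.
#' @slot tissue named character, tissue label per sample.
#' @slot dormancyLabel named character in `{A/ID, AD, ID, MID, NO}`.
#' @slot apobecHigh named logical, planted APOBEC-enriched status.
#' @slot plantedExposures samples x signatures matrix, rows sum to 1.
#' @slot enrichedDrivers,depletedDrivers gene symbols planted as
#'   mutation-enriched / depleted under tumor mass dormancy.
#' @slot seed integer seed the truth was generated from.
#' @aliases CohortTruth-class
#' @exportClass CohortTruth
setClass("CohortTruth",
  representation(sampleIds = "character", tissue = "character",
                 dormancyLabel = "character", apobecHigh = "logical",
                 plantedExposures = "matrix", enrichedDrivers = "character",
                 depletedDrivers = "character", seed = "integer"))

setValidity("CohortTruth", function(object) {
  msg <- character()
  n <- length(object@sampleIds)
  if (length(object@tissue) != n || length(object@dormancyLabel) != n ||
      length(object@apobecHigh) != n || nrow(object@plantedExposures) != n)
    msg <- c(msg, "per-sample slots must all have one entry per sample")
  if (!all(object@dormancyLabel %in% c("A/ID", "AD", "ID", "MID", "NO")))
    msg <- c(msg, "dormancyLabel outside {A/ID, AD, ID, MID, NO}")
  rs <- rowSums(object@plantedExposures)
  if (any(abs(rs - 1) > 1e-9))
    msg <- c(msg, "plantedExposures rows must sum to 1 (tol 1e-9)")
  if (any(object@plantedExposures < 0))
    msg <- c(msg, "plantedExposures must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortTruth", function(object) {
  cat("CohortTruth: ", length(object@sampleIds), " samples, ",
      length(unique(object@tissue)), " tissues, ",
      ncol(object@plantedExposures), " planted signatures (seed ",
      object@seed, ")\n", sep = "")
  print(table(object@dormancyLabel))
})

#' @describeIn CohortTruth sample identifiers
#' @param x,object a `CohortTruth`.
#' @export
sampleIds <- function(x) x@sampleIds

#' @describeIn CohortTruth planted dormancy labels
#' @export
dormancyLabels <- function(x) x@dormancyLabel

#' @describeIn CohortTruth planted exposure matrix (rows on the simplex)
#' @export
plantedExposures <- function(x) x@plantedExposures

#' @describeIn CohortTruth planted APOBEC-high status
#' @export
apobecHigh <- function(x) x@apobecHigh

#' 96-channel single-base-substitution catalogue
#'
#' Counts of SNVs per sample over the 96 pyrimidine-centered trinucleotide
#' substitution channels (6 substitution classes x 16 flanking contexts;
#' see [sbsChannels()] for the fixed order). Samples with fewer than
#' `minMutations` usable SNVs are flagged as not analysis-eligible.
#'
#' @slot counts samples x 96 integer matrix.
#' @slot rejected data.frame of rejected/skipped record counts per sample
#'   (reference mismatches, non-SNV records).
#' @slot minMutations eligibility threshold (default 50).
#' @aliases MutationalCatalogue-class
#' @exportClass MutationalCatalogue
setClass("MutationalCatalogue",
  representation(counts = "matrix", rejected = "data.frame",
                 minMutations = "integer"))

setValidity("MutationalCatalogue", function(object) {
  msg <- character()
  if (ncol(object@counts) != 96L)
    msg <- c(msg, "counts must have 96 channel columns")
  if (!identical(colnames(object@counts), sbsChannels()))
    msg <- c(msg, "channel columns must follow sbsChannels() order")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MutationalCatalogue", function(object) {
  cat("MutationalCatalogue: ", nrow(object@counts), " samples x 96 channels; ",
      sum(eligibleSamples(object)), " samples with >= ",
      object@minMutations, " mutations\n", sep = "")
})

#' @describeIn MutationalCatalogue counts matrix accessor
#' @param x,object a `MutationalCatalogue`.
#' @export
catalogueCounts <- function(x) x@counts

#' @describeIn MutationalCatalogue logical vector: per-sample totals meet
#'   the minimum-mutation filter
#' @export
eligibleSamples <- function(x) rowSums(x@counts) >= x@minMutations

#' @describeIn MutationalCatalogue per-sample rejected-record report
#' @export
rejectedRecords <- function(x) x@rejected
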