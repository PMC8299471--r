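#' Read gene programs from a GMT file
#'
#' GMT is tab-separated, one gene set per line: name, description, then
#' member genes. Signed programs are encoded as paired lines with
#' `_up`/`_down` suffixes; a pair `<name>_up` + `<name>_down` is merged
#' into one [GeneProgram-class] named `<name>` (the `_up` line's
#' description is kept). Unpaired lines become up-only programs under
#' their full name.
#'
#' @param path path to a GMT file.
#' @param version version tag stored on the returned library.
#' @return A [ProgramLibrary-class].
#' @seealso [writeGMT()]
#' @export
readGMT <- function(path, version = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1L], " has fewer than 3 tab-separated fields ",
         "(name, description, genes...): '", lines[bad[1L]], "'")
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set names in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  empty <- which(vapply(fields, function(f) all(!nzchar(f[-(1:2)])), logical(1)))
  if (length(empty))
    stop("gene set '", nm[empty[1L]], "' (line ", empty[1L],
         ") has an empty gene list")
  desc <- vapply(fields, `[[`, character(1), 2L)
  genes <- lapply(fields, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  names(genes) <- nm
  names(desc) <- nm

  isUp <- grepl("_up$", nm)
  isDown <- grepl("_down$", nm)
  base <- nm
  base[isUp] <- sub("_up$", "", nm[isUp])
  base[isDown] <- sub("_down$", "", nm[isDown])
  paired <- intersect(base[isUp], base[isDown])

  programs <- list()
  for (b in paired) {
    programs[[b]] <- GeneProgram(b, up = genes[[paste0(b, "_up")]],
                                 down = genes[[paste0(b, "_down")]],
                                 note = desc[[paste0(b, "_up")]])
  }
  consumed <- c(paste0(paired, "_up"), paste0(paired, "_down"))
  for (n in setdiff(nm, consumed)) {
    if (n %in% names(programs))
      stop("duplicate program name after up/down merging: ", n)
    programs[[n]] <- GeneProgram(n, up = genes[[n]], note = desc[[n]])
  }
  ProgramLibrary(programs, version = version)
}

#' Write a program library to a GMT file
#'
#' Signed programs (non-empty down side) are written as two lines with
#' `_up`/`_down` suffixes so that [readGMT()] reproduces the library
#' exactly; up-only programs are written as a single line.
#'
#' @param library a [ProgramLibrary-class]; must be non-empty.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeGMT <- function(library, path) {
  stopifnot(methods::is(library, "ProgramLibrary"))
  if (length(library) == 0L) stop("refusing to write an empty library")
  lines <- unlist(lapply(library@programs, function(p) {
    if (length(p@downGenes)) {
      c(paste(c(paste0(p@name, "_up"), p@note, p@upGenes), collapse = "\t"),
        paste(c(paste0(p@name, "_down"), p@note, p@downGenes), collapse = "\t"))
    } else {
      paste(c(p@name, p@note, p@upGenes), collapse = "\t")
    }
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a program to measured genes
#'
#' Expression matrices rarely contain every curated symbol; this
#' intersects both sides of a program with the measured gene universe and
#' reports what was dropped. Errors if no upregulated gene survives.
#'
#' @param program a [GeneProgram-class].
#' @param measured character vector of measured gene symbols.
#' @return A list with elements `program` (the restricted
#'   [GeneProgram-class]) and `dropped` (character vector of symbols not
#'   measured). Idempotent: restricting the result again is a no-op.
#' @export
restrictToMeasured <- function(program, measured) {
  stopifnot(methods::is(program, "GeneProgram"))
  if (!length(measured)) stop("measured gene set is empty")
  up <- intersect(program@upGenes, measured)
  down <- intersect(program@downGenes, measured)
  if (!length(up))
    stop("no upregulated gene of program '", program@name,
         "' is present in the measured gene set")
  dropped <- setdiff(c(program@upGenes, program@downGenes), measured)
  list(program = GeneProgram(program@name, up = up, down = down,
                             note = program@note),
       dropped = dropped)
}

#' Built-in placeholder gene programs
#'
#' A small, clearly-labelled illustrative library covering the program
#' names the pipeline expects (TMD, ID, AD, exhaustion, APOBEC,
#' proliferation, apoptosis, hypoxia_buffa). These are placeholder lists
#' assembled from well-known markers of each process so that the synthetic
#' pipeline is self-contained; analyses of real data should supply full
#' curated signatures via [readGMT()].
#'
#' @return A [ProgramLibrary-class].
#' @export
defaultPrograms <- function() {
  note <- "placeholder signature; supply curated lists via readGMT()"
  ProgramLibrary(list(
    GeneProgram("TMD",
      up = c("STAT1", "CXCL9", "CXCL10", "GZMB", "PRF1", "PLG", "PLAUR",
             "THBS1", "SERPINF1", "IFNG", "EOMES"),
      down = c("VEGFA", "HIF1A", "IL17A", "KDR"), note = note),
    GeneProgram("ID",
      up = c("STAT1", "CXCL9", "CXCL10", "GZMB", "PRF1", "IFNG"),
      down = c("IL17A"), note = note),
    GeneProgram("AD",
      up = c("PLG", "PLAUR", "THBS1", "SERPINF1", "TIMP2"),
      down = c("VEGFA", "HIF1A", "KDR"), note = note),
    GeneProgram("exhaustion",
      up = c("CTLA4", "PDCD1", "TIGIT", "EOMES", "TBX21", "CD244", "LAG3",
             "HAVCR2"), note = note),
    GeneProgram("APOBEC",
      up = c("APOBEC3A", "APOBEC3B", "APOBEC3C", "APOBEC3D", "APOBEC3F",
             "APOBEC3G", "APOBEC3H", "APOBEC1", "AICDA"), note = note),
    GeneProgram("proliferation",
      up = c("MKI67", "E2F1", "CCNE1", "CDC20", "MCM2", "PCNA", "TOP2A",
             "BUB1"), note = note),
    GeneProgram("apoptosis",
      up = c("CASP3", "CASP8", "CASP9", "BAX", "TNFSF10", "FAS", "BID",
             "APAF1"), note = note),
    GeneProgram("hypoxia_buffa",
      up = c("VEGFA", "SLC2A1", "CA9", "LDHA", "PGK1", "ADM", "NDRG1",
             "P4HA1", "ALDOA", "ENO1", "MRPS17", "CDKN3", "ACOT7",
             "TUBB6"), note = note)
  ), version = "dormscan-placeholder-1")
}

#' Built-in placeholder cell-type marker sets
#'
#' Up-only marker programs for microenvironment cell types consumed by
#' [ssgseaScores()], plus the combined categories used for reporting.
#'
#' @return A list with elements `markers` (a [ProgramLibrary-class]) and
#'   `combined` (named list mapping a combined category to its member cell
#'   types).
#' @export
defaultCellMarkers <- function() {
  note <- "placeholder marker set"
  markers <- ProgramLibrary(list(
    GeneProgram("CD8_T", up = c("CD8A", "CD8B", "GZMK", "GZMA", "CCL5"),
                note = note),
    GeneProgram("CD4_T", up = c("CD4", "IL7R", "CD40LG", "TRAT1"),
                note = note),
    GeneProgram("Th1", up = c("TBX21", "IFNG", "IL12RB2", "STAT4"),
                note = note),
    GeneProgram("Th2", up = c("GATA3", "IL4", "IL5", "CCR4"), note = note),
    GeneProgram("Th17", up = c("RORC", "IL17A", "IL22", "CCR6"),
                note = note),
    GeneProgram("Treg", up = c("FOXP3", "IL2RA", "IKZF2", "CTLA4"),
                note = note),
    GeneProgram("NK", up = c("NCR1", "KLRD1", "NKG7", "GNLY"), note = note),
    GeneProgram("Macrophage", up = c("CD68", "CD163", "MSR1", "MRC1"),
                note = note),
    GeneProgram("Dendritic", up = c("ITGAX", "CD1C", "BATF3", "FLT3"),
                note = note)
  ), version = "dormscan-markers-1")
  list(markers = markers,
       combined = list(cytotoxic = c("CD8_T", "NK"),
                       Th = c("Th1", "Th2", "Th17"),
                       dendritic = c("Dendritic")))
}
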