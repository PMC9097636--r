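# Bundled FOXO reference data: forkhead-domain sequences and the named
# distance monitors d1-d6 in each isoform's author numbering.

#' Forkhead-domain sequences of the four human FOXO proteins
#'
#' Bundled copies of the forkhead (FH) domain regions of human FOXO1
#' (UniProt Q12778), FOXO3 (O43524), FOXO4 (P98177) and FOXO6 (A8MYZ6),
#' with their author residue numbering, so that sequence-level analyses run
#' without network access. The four FH regions are colinear (constant
#' numbering offsets, no indels).
#'
#' @param path optional path to an alternative FASTA file with headers
#'   \code{>isoform uniprot start end ...}.
#' @return Data frame: \code{isoform}, \code{uniprot}, \code{start},
#'   \code{end}, \code{sequence}.
#' @export
foxo_fh_sequences <- function(path = NULL) {
  path <- path %||% system.file("extdata", "foxo_fh_domains.fasta",
                                package = "foxdyn", mustWork = TRUE)
  aas <- Biostrings::readAAStringSet(path)
  hdr <- strsplit(names(aas), "\\s+")
  data.frame(isoform = vapply(hdr, `[`, "", 1L),
             uniprot = vapply(hdr, `[`, "", 2L),
             start = as.integer(vapply(hdr, `[`, "", 3L)),
             end = as.integer(vapply(hdr, `[`, "", 4L)),
             sequence = as.character(aas),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Residue-numbering offsets of the colinear FH regions relative to FOXO1.
FOXO_OFFSETS <- c(FOXO1 = 0L, FOXO3 = -3L, FOXO4 = -59L, FOXO6 = -72L)

#' Named distance monitors of the H4/H2/H3 region
#'
#' The six distances used to characterise the mobile helix-4 region of the
#' FOXO forkhead domain, defined in FOXO1 numbering and translated to the
#' other isoforms by the constant FH alignment offset: \describe{
#'   \item{d1}{Lys210 NZ to the Gly201 backbone carbonyl}
#'   \item{d2}{Lys210 NZ to the Asp202 backbone carbonyl}
#'   \item{d3}{Lys210 NZ to the Ser206 hydroxyl oxygen (OG)}
#'   \item{d4}{Tyr196 OH to Lys200 NZ (H4 first-turn hydrogen bond)}
#'   \item{d5}{Asp199 OD1 to Lys200 NZ (H4 first-turn salt bridge)}
#'   \item{d6}{Lys200 NZ to the backbone carbonyl of the C-terminal residue
#'     of H2 (Ser193 in FOXO1), reporting the H4-to-H2 orientation}}
#'
#' @param isoform \code{"FOXO1"}, \code{"FOXO3"}, \code{"FOXO4"} or
#'   \code{"FOXO6"}.
#' @param carbonyl atom used for "carbonyl group" selectors: the backbone
#'   oxygen \code{"O"} (default) or the carbon \code{"C"}.
#' @return Data frame of \code{\link{distance_spec}} rows (labels d1-d6).
#' @export
foxo_distance_specs <- function(isoform = "FOXO1", carbonyl = c("O", "C")) {
  carbonyl <- match.arg(carbonyl)
  isoform <- match.arg(isoform, names(FOXO_OFFSETS))
  off <- FOXO_OFFSETS[[isoform]]
  rbind(
    distance_spec("d1", 210 + off, "NZ", 201 + off, carbonyl),
    distance_spec("d2", 210 + off, "NZ", 202 + off, carbonyl),
    distance_spec("d3", 210 + off, "NZ", 206 + off, "OG"),
    distance_spec("d4", 196 + off, "OH", 200 + off, "NZ"),
    distance_spec("d5", 199 + off, "OD1", 200 + off, "NZ"),
    distance_spec("d6", 200 + off, "NZ", 193 + off, carbonyl))
}
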