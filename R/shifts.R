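# Chemical-shift perturbation, cross-homolog correlation, residue matching
# and titration-response classification.

#' Chemical-shift perturbation between two states
#'
#' Composite amide CSP per residue,
#' \deqn{\mathrm{CSP} = \sqrt{\Delta\delta_H^2 + (\Delta\delta_N/n)^2},}
#' with nitrogen divisor \eqn{n} (default 7, the community-standard ~0.14
#' weighting). Residues assigned in \code{free} but missing or unassigned in
#' \code{bound} are marked broadened (their peak disappeared) and carry no
#' CSP value; residues unassigned in \code{free} are excluded.
#'
#' @param free,bound \code{\link{shift_table}}s of the two states.
#' @param n_scale nitrogen divisor (> 0).
#' @param n_mode \code{"divisor"} applies \eqn{(\Delta\delta_N/n)^2} (the
#'   default); \code{"variance"} applies \eqn{\Delta\delta_N^2/n}, the
#'   alternate reading, for sensitivity analysis.
#' @return Data frame of class \code{csp_profile}: \code{residue},
#'   \code{dH}, \code{dN} (shift changes, ppm), \code{csp} (ppm),
#'   \code{broadened}.
#' @export
compute_csp <- function(free, bound, n_scale = 7,
                        n_mode = c("divisor", "variance")) {
  stopifnot(inherits(free, "shift_table"), inherits(bound, "shift_table"))
  n_mode <- match.arg(n_mode)
  if (n_scale <= 0)
    stop_foxdyn("n_scale must be > 0", "foxdyn_precondition_error")
  fa <- free[free$assigned, , drop = FALSE]
  if (!any(fa$residue %in% bound$residue))
    stop_foxdyn("free and bound tables share no residues",
                "foxdyn_empty_overlap")
  idx <- match(fa$residue, bound$residue)
  b_assigned <- !is.na(idx) & bound$assigned[ifelse(is.na(idx), 1L, idx)]
  dH <- fa$dH - bound$dH[idx]
  dN <- fa$dN - bound$dN[idx]
  csp <- if (n_mode == "divisor")
    sqrt(dH^2 + (dN / n_scale)^2) else sqrt(dH^2 + dN^2 / n_scale)
  broadened <- !b_assigned
  csp[broadened] <- NA_real_
  dH[broadened] <- NA_real_
  dN[broadened] <- NA_real_
  structure(data.frame(residue = fa$residue, dH = dH, dN = dN, csp = csp,
                       broadened = broadened),
            class = c("csp_profile", "data.frame"))
}

#' Pearson correlation of chemical shifts across homologs
#'
#' Correlates the shifts of one nucleus between two proteins over
#' sequence-aligned residue pairs,
#' \deqn{r = \frac{\sum(x-\bar x)(y-\bar y)}
#'   {\sqrt{\sum(x-\bar x)^2 \sum(y-\bar y)^2}}.}
#' Pairs where either residue is unassigned are excluded, never imputed.
#'
#' @param table_a,table_b \code{\link{shift_table}}s.
#' @param mapping a \code{\link{match_residues}} result, or \code{NULL} to
#'   pair residues by identical residue number.
#' @param nucleus \code{"H"} or \code{"N"}.
#' @return Pearson correlation coefficient in [-1, 1].
#' @export
correlate_shifts <- function(table_a, table_b, mapping = NULL,
                             nucleus = c("H", "N")) {
  nucleus <- match.arg(nucleus)
  col <- if (nucleus == "H") "dH" else "dN"
  if (is.null(mapping)) {
    common <- intersect(table_a$residue, table_b$residue)
    pairs <- data.frame(res_a = common, res_b = common)
  } else {
    pairs <- mapping$pairs
  }
  ia <- match(pairs$res_a, table_a$residue)
  ib <- match(pairs$res_b, table_b$residue)
  ok <- !is.na(ia) & !is.na(ib) &
    table_a$assigned[ifelse(is.na(ia), 1L, ia)] &
    table_b$assigned[ifelse(is.na(ib), 1L, ib)]
  x <- table_a[[col]][ia[ok]]
  y <- table_b[[col]][ib[ok]]
  if (length(x) < 3L)
    stop_foxdyn("need >= 3 mapped, mutually assigned residues",
                "foxdyn_precondition_error")
  if (sd(x) == 0 || sd(y) == 0)
    stop_foxdyn("zero shift variance: correlation undefined",
                "foxdyn_undefined_correlation")
  stats::cor(x, y)
}

#' Cross-homolog shift correlation matrix
#'
#' Symmetric matrix of pairwise shift correlations over a set of states,
#' with residue pairing by global sequence alignment of the tables'
#' amino-acid sequences (or by residue number if \code{align = FALSE}).
#'
#' @param tables named list of \code{\link{shift_table}}s.
#' @param nucleus \code{"H"} or \code{"N"}.
#' @param align pair residues by sequence alignment (default) or by number.
#' @return A k x k symmetric correlation matrix with unit diagonal.
#' @export
shift_correlation_matrix <- function(tables, nucleus = c("H", "N"),
                                     align = TRUE) {
  nucleus <- match.arg(nucleus)
  k <- length(tables)
  nm <- names(tables) %||% paste0("state", seq_len(k))
  out <- diag(1, k); dimnames(out) <- list(nm, nm)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    mapping <- NULL
    if (align) {
      sa <- paste(tables[[i]]$aa, collapse = "")
      sb <- paste(tables[[j]]$aa, collapse = "")
      mapping <- match_residues(sa, sb,
                                offset_a = tables[[i]]$residue[1],
                                offset_b = tables[[j]]$residue[1])
    }
    out[i, j] <- out[j, i] <-
      correlate_shifts(tables[[i]], tables[[j]], mapping, nucleus)
  }
  out
}

#' Match residues of two sequences by global alignment
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 10, gap extend 0.5
#' by default, via \code{Biostrings::pairwiseAlignment}). The mapping
#' contains only match/mismatch columns; percent identity is identical
#' columns over the full alignment length, terminal gaps included.
#'
#' @param seq_a,seq_b amino-acid sequences (non-empty strings).
#' @param offset_a,offset_b author-numbering of the first residue of each
#'   sequence (numbering is preserved end-to-end, no renumbering).
#' @param gap_open,gap_extend gap penalties.
#' @param substitution_matrix substitution matrix name.
#' @return List of class \code{residue_mapping}: \code{pairs} (data frame
#'   \code{res_a}, \code{res_b}, \code{aa_a}, \code{aa_b}) and
#'   \code{identity_pct}.
#' @export
match_residues <- function(seq_a, seq_b, offset_a = 1L, offset_b = 1L,
                           gap_open = 10, gap_extend = 0.5,
                           substitution_matrix = "BLOSUM62") {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop_foxdyn("sequences must be non-empty", "foxdyn_precondition_error")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  stopifnot(length(pa) == length(pb))
  ia <- cumsum(pa != "-")
  ib <- cumsum(pb != "-")
  both <- pa != "-" & pb != "-"
  pairs <- data.frame(res_a = ia[both] + offset_a - 1L,
                      res_b = ib[both] + offset_b - 1L,
                      aa_a = pa[both], aa_b = pb[both],
                      stringsAsFactors = FALSE)
  identity_pct <- 100 * sum(pa == pb & pa != "-") / length(pa)
  structure(list(pairs = pairs, identity_pct = identity_pct,
                 alignment_length = length(pa)),
            class = "residue_mapping")
}

#' @export
print.residue_mapping <- function(x, ...) {
  cat(sprintf("Residue mapping: %d aligned pairs, %.1f%% identity over %d columns\n",
              nrow(x$pairs), x$identity_pct, x$alignment_length))
  invisible(x)
}

#' Classify per-residue titration responses
#'
#' Each assigned residue of the free state is placed in exactly one
#' category: \code{broadened} when the bound peak is absent or its
#' bound/free intensity ratio falls below \code{broadening_ratio};
#' \code{strong_csp} when the CSP exceeds \code{csp_strong}; \code{weak_csp}
#' when it exceeds the baseline noise floor; \code{unaffected} otherwise.
#' The per-spectrum summary is the dominant category over affected residues.
#'
#' @param free,bound \code{\link{shift_table}}s of the titration endpoints.
#' @param free_intensities,bound_intensities optional named (by residue) or
#'   aligned numeric vectors of peak intensities; required for the
#'   ratio-based broadening test.
#' @param csp_strong CSP (ppm) separating weak from strong.
#' @param csp_floor CSP (ppm) below which a residue is unaffected.
#' @param broadening_ratio intensity-ratio threshold.
#' @param n_scale nitrogen divisor of the CSP.
#' @return Data frame of class \code{titration_call} (\code{residue},
#'   \code{csp}, \code{intensity_ratio}, \code{category}) with attribute
#'   \code{summary}.
#' @export
classify_titration <- function(free, bound, free_intensities = NULL,
                               bound_intensities = NULL,
                               csp_strong = 0.05, csp_floor = 0.005,
                               broadening_ratio = 0.3, n_scale = 7) {
  prof <- compute_csp(free, bound, n_scale = n_scale)
  ratio <- rep(NA_real_, nrow(prof))
  if (!is.null(free_intensities) || !is.null(bound_intensities)) {
    if (is.null(free_intensities) || is.null(bound_intensities))
      stop_foxdyn("both intensity vectors are required for the ratio test",
                  "foxdyn_precondition_error")
    fi <- as.numeric(free_intensities)
    bi <- as.numeric(bound_intensities)
    nm_f <- names(free_intensities); nm_b <- names(bound_intensities)
    if (!is.null(nm_f)) fi <- fi[match(prof$residue, as.integer(nm_f))]
    if (!is.null(nm_b)) bi <- bi[match(prof$residue, as.integer(nm_b))]
    if (length(fi) != nrow(prof) || length(bi) != nrow(prof))
      stop_foxdyn("intensity vectors must align with the shared residues",
                  "foxdyn_precondition_error")
    ratio <- bi / fi
  }
  category <- ifelse(prof$broadened |
                       (!is.na(ratio) & ratio < broadening_ratio),
                     "broadened",
                     ifelse(prof$csp > csp_strong, "strong_csp",
                            ifelse(prof$csp > csp_floor, "weak_csp",
                                   "unaffected")))
  category <- factor(category, levels = c("unaffected", "weak_csp",
                                          "strong_csp", "broadened"))
  affected <- as.character(category[category != "unaffected"])
  # dominant category; ties resolved toward the more severe response
  severity <- c("broadened", "strong_csp", "weak_csp")
  counts <- vapply(severity, function(s) sum(affected == s), 0L)
  summary_lab <- if (length(affected) == 0L) "no binding" else
    switch(severity[which.max(counts)],
           broadened = "line broadening",
           strong_csp = "strong CSPs",
           weak_csp = "weak CSPs")
  structure(data.frame(residue = prof$residue, csp = prof$csp,
                       intensity_ratio = ratio, category = category),
            summary = summary_lab,
            class = c("titration_call", "data.frame"))
}
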