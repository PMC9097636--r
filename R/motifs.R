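# W-[2-5]-[S/T/C/Y] tryptophan-interaction motifs: sequence scan and 3D
# geometry (heteroatom -> indole-centroid distance d and face/edge angle a).

INDOLE_ATOMS <- c("CG", "CD1", "NE1", "CE2", "CD2", "CE3", "CZ2", "CZ3", "CH2")
RING_SETS <- list(indole9 = INDOLE_ATOMS,
                  pyrrole5 = c("CG", "CD1", "NE1", "CE2", "CD2"),
                  benzene6 = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
XAA_HETEROATOM <- c(S = "OG", T = "OG1", C = "SG", Y = "OH")

#' Scan a sequence for W-[2-5]-[S/T/C/Y] motif candidates
#'
#' Finds tryptophan / Ser-Thr-Cys-Tyr pairs whose side chains could
#' interact: the two residues must be separated by a configurable number of
#' intervening residues (2-5 by default). With \code{bidirectional = TRUE}
#' the hydroxyl/thiol residue may precede or follow the tryptophan.
#'
#' @param sequence amino-acid sequence (1-letter string).
#' @param offset author-style number of the first residue (numbering is
#'   reported, never recomputed).
#' @param spacing admissible counts of residues between the pair.
#' @param xaa_set partner residue types.
#' @param bidirectional scan both orders.
#' @return Data frame: \code{trp} and \code{xaa} (residue numbers),
#'   \code{xaa_type}, \code{spacing}, \code{xaa_after_trp}.
#' @examples
#' find_sequence_motifs("WAAAS")  # one pair, spacing 3
#' @export
find_sequence_motifs <- function(sequence, offset = 1L, spacing = 2:5,
                                 xaa_set = c("S", "T", "C", "Y"),
                                 bidirectional = TRUE) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  w_pos <- which(aa == "W")
  hits <- list()
  for (w in w_pos) {
    for (sp in spacing) {
      for (dir in if (bidirectional) c(1L, -1L) else 1L) {
        x <- w + dir * (sp + 1L)
        if (x < 1L || x > length(aa)) next
        if (!aa[x] %in% xaa_set) next
        hits[[length(hits) + 1L]] <- data.frame(
          trp = w + offset - 1L, xaa = x + offset - 1L,
          xaa_type = aa[x], spacing = sp, xaa_after_trp = dir == 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(trp = integer(), xaa = integer(),
                      xaa_type = character(), spacing = integer(),
                      xaa_after_trp = logical()))
  out <- do.call(rbind, hits)
  out[order(out$trp, out$xaa), , drop = FALSE]
}

# Least-squares plane normal of a set of points (unit vector).
plane_normal <- function(xyz) {
  s <- svd(sweep(xyz, 2, colMeans(xyz)))
  s$v[, 3L]
}

#' Geometry of a tryptophan-interaction motif pair
#'
#' For a (Trp, Xaa) pair the motif geometry is: \eqn{d}, the distance from
#' the Xaa side-chain heteroatom (Ser OG / Thr OG1 / Cys SG / Tyr OH) to the
#' centroid of the tryptophan ring system, and \eqn{\alpha}, the angle
#' between the ring-plane normal and the heteroatom direction, folded to
#' [0, 90] degrees (0 = face-on above the ring, 90 = edge-on in the ring
#' plane). The centroid uses all nine indole heavy atoms by default; the
#' five- or six-membered ring alone is selectable.
#'
#' @param x a \code{\link{structure_record}} or trajectory
#'   (\code{\link{as_trajectory}}); one row is returned per frame.
#' @param trp_residue,xaa_residue residue numbers of the pair.
#' @param ring which atom set defines centroid and plane.
#' @param d_cutoff distance (angstrom) below which the pair is flagged
#'   interacting.
#' @return Data frame of class \code{motif_hit}: \code{frame}, \code{trp},
#'   \code{xaa}, \code{xaa_type}, \code{spacing}, \code{d} (angstrom),
#'   \code{alpha} (degrees), \code{interacting}.
#' @export
evaluate_motif_geometry <- function(x, trp_residue, xaa_residue,
                                    ring = c("indole9", "pyrrole5",
                                             "benzene6"),
                                    d_cutoff = 6) {
  ring <- match.arg(ring)
  frames <- if (inherits(x, "structure_record")) list(x) else {
    if (!inherits(x, "trajectory_frames")) x <- as_trajectory(x)
    x$frames
  }
  ring_atoms <- RING_SETS[[ring]]
  rows <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    trp <- fr[fr$residue_number == trp_residue, , drop = FALSE]
    miss <- setdiff(INDOLE_ATOMS, trp$atom_name)
    if (length(miss))
      stop_foxdyn(paste0("Trp ", trp_residue, " lacks indole atom(s): ",
                         paste(miss, collapse = ", ")),
                  "foxdyn_incomplete_sidechain")
    xaa <- fr[fr$residue_number == xaa_residue, , drop = FALSE]
    xaa_type <- unname(AA3TO1[xaa$residue_name[1]])
    het_name <- XAA_HETEROATOM[xaa_type]
    if (is.na(het_name) || !het_name %in% xaa$atom_name)
      stop_foxdyn(paste0("residue ", xaa_residue,
                         " lacks its side-chain heteroatom (",
                         het_name %||% "?", ")"),
                  "foxdyn_incomplete_sidechain")
    ring_xyz <- coords_matrix(trp[match(ring_atoms, trp$atom_name), ])
    centroid <- colMeans(ring_xyz)
    normal <- plane_normal(ring_xyz)
    het <- as.numeric(coords_matrix(xaa[xaa$atom_name == het_name, ]))
    v <- het - centroid
    d <- vec3_norm(v)
    if (d == 0)
      stop_foxdyn("heteroatom coincides with the ring centroid",
                  "foxdyn_precondition_error")
    cosang <- abs(sum(normal * v) / d)           # fold to [0, 90] degrees
    alpha <- deg(acos(pmin(1, cosang)))
    rows[[f]] <- data.frame(frame = f, trp = trp_residue, xaa = xaa_residue,
                            xaa_type = xaa_type,
                            spacing = abs(xaa_residue - trp_residue) - 1L,
                            d = d, alpha = alpha,
                            interacting = d <= d_cutoff,
                            stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows), class = c("motif_hit", "data.frame"))
}

#' Scan a structure for realised W-[2-5]-[S/T/C/Y] motifs
#'
#' Combines the sequence scan with the 3D geometry: candidate pairs are
#' taken from the model's sequence, then evaluated geometrically; pairs
#' whose side-chain atoms are incomplete in the model are dropped.
#'
#' @param model a \code{\link{structure_record}}.
#' @param spacing,xaa_set,bidirectional see
#'   \code{\link{find_sequence_motifs}}.
#' @param ring,d_cutoff see \code{\link{evaluate_motif_geometry}}.
#' @return A \code{motif_hit} data frame (zero rows if nothing qualifies).
#' @export
scan_structure_motifs <- function(model, spacing = 2:5,
                                  xaa_set = c("S", "T", "C", "Y"),
                                  bidirectional = TRUE, ring = "indole9",
                                  d_cutoff = 6) {
  res <- unique(model[, c("residue_number", "residue_name")])
  res <- res[order(res$residue_number), ]
  aa <- unname(AA3TO1[res$residue_name])
  aa[is.na(aa)] <- "X"
  cand <- find_sequence_motifs(paste(aa, collapse = ""),
                               offset = res$residue_number[1],
                               spacing = spacing, xaa_set = xaa_set,
                               bidirectional = bidirectional)
  # residue numbering inside the model may be non-contiguous; remap
  if (nrow(cand)) {
    cand$trp <- res$residue_number[cand$trp - res$residue_number[1] + 1L]
    cand$xaa <- res$residue_number[cand$xaa - res$residue_number[1] + 1L]
  }
  hits <- list()
  for (k in seq_len(nrow(cand))) {
    h <- tryCatch(evaluate_motif_geometry(model, cand$trp[k], cand$xaa[k],
                                          ring = ring, d_cutoff = d_cutoff),
                  foxdyn_incomplete_sidechain = function(e) NULL)
    if (!is.null(h)) hits[[length(hits) + 1L]] <- h
  }
  if (length(hits) == 0L)
    return(structure(data.frame(frame = integer(), trp = integer(),
                                xaa = integer(), xaa_type = character(),
                                spacing = integer(), d = numeric(),
                                alpha = numeric(), interacting = logical()),
                     class = c("motif_hit", "data.frame")))
  do.call(rbind, hits)
}
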