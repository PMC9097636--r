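# Backbone superposition (Kabsch), RMSD matrices, per-residue fluctuations
# and named distance monitors.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Least-squares rigid transform mapping P onto Q (rows = atoms): returns
# rotation R (applied as x %*% R), translation t, and the residual RMSD.
# Proper rotation enforced (det = +1), no outlier rejection.
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3L, ncol(Q) == 3L)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- cq - drop(cp %*% R)
  rmsd <- sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

# Extract matched backbone coordinates of mapped residues complete in both
# models. Returns NULL when fewer than min_residues usable residues remain.
matched_backbone <- function(mobile, target, mapping = NULL,
                             atoms = BACKBONE_ATOMS, min_residues = 3L) {
  if (is.null(mapping)) {
    common <- intersect(mobile$residue_number, target$residue_number)
    pairs <- data.frame(res_a = common, res_b = common)
  } else {
    pairs <- mapping$pairs
  }
  P <- Q <- NULL
  used <- 0L
  for (k in seq_len(nrow(pairs))) {
    ma <- mobile[mobile$residue_number == pairs$res_a[k] &
                   mobile$atom_name %in% atoms, , drop = FALSE]
    tb <- target[target$residue_number == pairs$res_b[k] &
                   target$atom_name %in% atoms, , drop = FALSE]
    if (!all(atoms %in% ma$atom_name) || !all(atoms %in% tb$atom_name)) next
    P <- rbind(P, coords_matrix(ma[match(atoms, ma$atom_name), ]))
    Q <- rbind(Q, coords_matrix(tb[match(atoms, tb$atom_name), ]))
    used <- used + 1L
  }
  if (used < min_residues) return(NULL)
  list(P = P, Q = Q, n_residues = used)
}

#' Optimal rigid superposition of two point sets
#'
#' Kabsch superposition of matched coordinate rows (no atom selection, no
#' outlier rejection). The rotation is proper (det = +1) even for
#' degenerate, reflection-favouring point sets.
#'
#' @param mobile,target numeric n x 3 matrices of matched points.
#' @return List with \code{rotation} (applied as \code{x \%*\% rotation}),
#'   \code{translation} and \code{rmsd} (angstrom).
#' @export
superpose_coords <- function(mobile, target) {
  kabsch(as.matrix(mobile), as.matrix(target))
}

#' Backbone superposition of two structures
#'
#' Least-squares optimal rigid-body superposition (Kabsch algorithm) over
#' the backbone atoms (N, CA, C, O) of mapped residues, with zero cycles of
#' outlier rejection: every mapped residue with a complete backbone in both
#' models enters the fit, and the reported RMSD is computed over exactly
#' those atoms.
#'
#' @param mobile,target \code{\link{structure_record}}s.
#' @param mapping a \code{\link{match_residues}} result, or \code{NULL} to
#'   pair residues by identical residue number.
#' @return Object of class \code{superposition}: \code{rotation} (3x3,
#'   det +1), \code{translation} (angstrom), \code{rmsd} (angstrom),
#'   \code{n_atoms_used}, and \code{transformed} (the mobile structure after
#'   superposition).
#' @export
superpose_backbone <- function(mobile, target, mapping = NULL) {
  mb <- matched_backbone(mobile, target, mapping)
  if (is.null(mb))
    stop_foxdyn("fewer than 3 mapped residues with complete backbone atoms",
                "foxdyn_insufficient_atoms")
  k <- kabsch(mb$P, mb$Q)
  structure(list(rotation = k$rotation, translation = k$translation,
                 rmsd = k$rmsd, n_atoms_used = nrow(mb$P),
                 n_residues_used = mb$n_residues,
                 transformed = transform_structure(mobile, k$rotation,
                                                   k$translation)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Backbone superposition: rmsd %.4f A over %d atoms (%d residues)\n",
              x$rmsd, x$n_atoms_used, x$n_residues_used))
  invisible(x)
}

#' Pairwise backbone RMSD matrix
#'
#' Entry (i, j) is the backbone RMSD after optimal superposition of model i
#' onto model j. The matrix is symmetric with a zero diagonal.
#'
#' @param models list of \code{\link{structure_record}}s.
#' @param mappings optional list of lists: \code{mappings[[i]][[j]]} is the
#'   \code{\link{match_residues}} result for pair (i, j); \code{NULL} pairs
#'   residues by number.
#' @return Symmetric numeric matrix (angstrom).
#' @export
pairwise_rmsd_matrix <- function(models, mappings = NULL) {
  n <- length(models)
  stopifnot(n >= 2L)
  nm <- names(models) %||% paste0("model", seq_len(n))
  out <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    mp <- if (!is.null(mappings)) mappings[[i]][[j]] else NULL
    sp <- tryCatch(superpose_backbone(models[[i]], models[[j]], mp),
                   foxdyn_error = function(e)
                     stop_foxdyn(paste0("superposition failed for pair (",
                                        nm[i], ", ", nm[j], "): ",
                                        conditionMessage(e)),
                                 class(e)[1]))
    out[i, j] <- out[j, i] <- sp$rmsd
  }
  out
}

#' Per-residue C-alpha deviation from a reference model
#'
#' All models are superposed onto the reference via the backbone; for each
#' aligned residue the root-mean-square over the non-reference models of the
#' C-alpha distance to the reference C-alpha is reported.
#'
#' @param models list of \code{\link{structure_record}}s.
#' @param reference_index which model is the reference.
#' @return Named numeric vector (angstrom), names = residue numbers.
#' @export
per_residue_ca_rmsd <- function(models, reference_index = 1L) {
  stopifnot(length(models) >= 2L)
  ref <- models[[reference_index]]
  others <- models[-reference_index]
  common <- Reduce(intersect, lapply(models, function(m)
    m$residue_number[m$atom_name == "CA"]))
  skipped <- setdiff(Reduce(union, lapply(models, `[[`, "residue_number")),
                     common)
  if (length(skipped))
    warning("residues without C-alpha in every model skipped: ",
            paste(utils::head(sort(skipped), 10), collapse = ", "))
  ca_of <- function(m) {
    sel <- m[m$atom_name == "CA" & m$residue_number %in% common, ]
    coords_matrix(sel[match(common, sel$residue_number), ])
  }
  ref_ca <- ca_of(ref)
  d2 <- matrix(0, length(common), length(others))
  for (k in seq_along(others)) {
    sp <- superpose_backbone(others[[k]], ref)
    d2[, k] <- rowSums((ca_of(sp$transformed) - ref_ca)^2)
  }
  setNames(sqrt(rowMeans(d2)), common)
}

#' Per-atom root-mean-square fluctuation over trajectory frames
#'
#' Frames are superposed (backbone atoms) onto the running mean structure --
#' first onto frame 1, then one refinement pass onto the resulting mean --
#' and the RMSF of each selected atom about its mean position is
#' \eqn{\sqrt{\langle|r_i - \langle r_i\rangle|^2\rangle}}. Rigid-body
#' motion is removed exactly; only internal motion contributes.
#'
#' @param traj a \code{\link{as_trajectory}} object (or list of frames).
#' @param selection atom name(s) reported; default C-alpha.
#' @return Data frame of class \code{rmsf_profile}: \code{residue},
#'   \code{atom}, \code{rmsf} (angstrom).
#' @export
compute_rmsf <- function(traj, selection = "CA") {
  if (!inherits(traj, "trajectory_frames")) traj <- as_trajectory(traj)
  frames <- traj$frames
  n_frames <- length(frames)
  if (n_frames < 2L)
    stop_foxdyn("RMSF needs >= 2 frames", "foxdyn_precondition_error")
  tmpl <- frames[[1L]]
  bb <- which(tmpl$atom_name %in% BACKBONE_ATOMS)
  if (length(bb) < 3L)
    stop_foxdyn("too few backbone atoms to superpose frames",
                "foxdyn_insufficient_atoms")
  X <- vapply(frames, coords_matrix,
              matrix(0, nrow(tmpl), 3))          # atoms x 3 x frames
  align_all <- function(X, ref_bb) {
    for (f in seq_len(dim(X)[3])) {
      k <- kabsch(X[bb, , f], ref_bb)
      X[, , f] <- sweep(X[, , f] %*% k$rotation, 2, k$translation, "+")
    }
    X
  }
  X <- align_all(X, X[bb, , 1L])
  mean_xyz <- apply(X, c(1, 2), mean)
  X <- align_all(X, mean_xyz[bb, ])              # one refinement iteration
  mean_xyz <- apply(X, c(1, 2), mean)
  D <- (X - as.vector(mean_xyz))^2
  dev2 <- D[, 1, ] + D[, 2, ] + D[, 3, ]       # atoms x frames
  rmsf <- sqrt(rowMeans(dev2))
  sel <- tmpl$atom_name %in% selection
  structure(data.frame(residue = tmpl$residue_number[sel],
                       atom = tmpl$atom_name[sel], rmsf = rmsf[sel]),
            class = c("rmsf_profile", "data.frame"))
}

#' Define a named distance monitor
#'
#' @param label monitor name (e.g. \code{"d1"}).
#' @param res_a,atom_a,res_b,atom_b residue number and atom name of the two
#'   selected atoms.
#' @param chain_a,chain_b optional chain identifiers (\code{NA} matches any).
#' @return One-row data frame usable in \code{\link{monitor_distances}}.
#' @export
distance_spec <- function(label, res_a, atom_a, res_b, atom_b,
                          chain_a = NA, chain_b = NA) {
  data.frame(label = label, chain_a = chain_a, res_a = as.integer(res_a),
             atom_a = atom_a, chain_b = chain_b, res_b = as.integer(res_b),
             atom_b = atom_b, stringsAsFactors = FALSE)
}

resolve_atom <- function(frame, chain, res, atom, label, f_idx) {
  sel <- frame$residue_number == res & frame$atom_name == atom
  if (!is.na(chain)) sel <- sel & frame$chain_id == chain
  idx <- which(sel)
  if (length(idx) != 1L)
    stop_foxdyn(sprintf(
      "monitor '%s': selector (res %d, atom %s) resolves to %d atoms in frame %d",
      label, res, atom, length(idx), f_idx), "foxdyn_selector_error")
  idx
}

#' Monitor inter-atomic distances along a trajectory
#'
#' Euclidean distance between two selected atoms, per frame, with summary
#' statistics and a 0.1-angstrom-bin histogram per monitor.
#'
#' @param traj a \code{\link{as_trajectory}} object, list of frames, or a
#'   single \code{\link{structure_record}}.
#' @param specs data frame of monitors (rows from
#'   \code{\link{distance_spec}}, possibly \code{rbind}-ed, e.g.
#'   \code{\link{foxo_distance_specs}}).
#' @return Named list (one element per monitor label): \code{series}
#'   (angstrom per frame), \code{mean}, \code{sd}, \code{histogram}
#'   (data frame \code{mid}, \code{count}).
#' @export
monitor_distances <- function(traj, specs) {
  if (inherits(traj, "structure_record")) traj <- as_trajectory(list(traj))
  if (!inherits(traj, "trajectory_frames")) traj <- as_trajectory(traj)
  frames <- traj$frames
  out <- list()
  for (s in seq_len(nrow(specs))) {
    sp <- specs[s, ]
    series <- numeric(length(frames))
    for (f in seq_along(frames)) {
      fr <- frames[[f]]
      ia <- resolve_atom(fr, sp$chain_a, sp$res_a, sp$atom_a, sp$label, f)
      ib <- resolve_atom(fr, sp$chain_b, sp$res_b, sp$atom_b, sp$label, f)
      series[f] <- sqrt((fr$x[ia] - fr$x[ib])^2 + (fr$y[ia] - fr$y[ib])^2 +
                          (fr$z[ia] - fr$z[ib])^2)
    }
    breaks <- seq(floor(min(series) * 10) / 10 - 0.05,
                  ceiling(max(series) * 10) / 10 + 0.05, by = 0.1)
    h <- hist(series, breaks = breaks, plot = FALSE)
    out[[sp$label]] <- list(series = series, mean = mean(series),
                            sd = if (length(series) > 1L) sd(series) else 0,
                            histogram = data.frame(mid = h$mids,
                                                   count = h$counts))
  }
  out
}
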