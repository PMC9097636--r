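# Structure records and (multi-model) PDB I/O.

#' Construct a structure record
#'
#' A structure record is a flat atom table for one model: atom name, element,
#' residue number (author numbering, preserved end-to-end), residue name,
#' chain identifier, and coordinates in angstrom.
#'
#' @param atom_name atom names (whitespace-stripped, e.g. \code{"CA"}).
#' @param residue_number integer residue numbers.
#' @param residue_name 3-letter residue codes.
#' @param x,y,z coordinates (angstrom, finite).
#' @param chain_id chain identifiers (default \code{"A"}).
#' @param element element symbols; inferred from the atom name when missing.
#' @param model_index model number within a multi-model file.
#' @return A data frame of class \code{structure_record}.
#' @export
structure_record <- function(atom_name, residue_number, residue_name,
                             x, y, z, chain_id = "A", element = NULL,
                             model_index = 1L) {
  n <- length(atom_name)
  if (is.null(element))
    element <- substr(gsub("[^A-Za-z].*$", "", trimws(atom_name)), 1, 1)
  df <- data.frame(atom_name = trimws(atom_name),
                   element = trimws(element),
                   residue_number = as.integer(residue_number),
                   residue_name = rep_len(as.character(residue_name), n),
                   chain_id = rep_len(as.character(chain_id), n),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   stringsAsFactors = FALSE)
  validate_structure_record(df)
  structure(df, model_index = as.integer(model_index),
            class = c("structure_record", "data.frame"))
}

validate_structure_record <- function(df, file = NULL) {
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop_format("non-finite coordinate", file = file)
  key <- paste(df$chain_id, df$residue_number, df$atom_name)
  if (anyDuplicated(key))
    stop_format(paste0("duplicate atom within model: ",
                       key[anyDuplicated(key)]), file = file)
  invisible(df)
}

#' Read a (multi-model) PDB file
#'
#' Returns one \code{\link{structure_record}} per \code{MODEL} block (a
#' single implicit model when the file has none). Parsing of each model is
#' delegated to \code{bio3d::read.pdb}; atom names are whitespace-stripped
#' and coordinates kept in angstrom. Models with differing atom counts are
#' read as-is; the mismatch is only an error once the models are combined
#' into a trajectory (\code{\link{as_trajectory}}).
#'
#' @param path path to a PDB file with ATOM/HETATM records.
#' @return A list of \code{\link{structure_record}} objects.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop_format("file not found", file = path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^(ATOM  |HETATM)", lines)))
    stop_format("no ATOM/HETATM records found", file = path)
  starts <- grep("^MODEL", lines)
  chunks <- if (length(starts) == 0L) {
    list(lines)
  } else {
    ends <- c(starts[-1] - 1L, length(lines))
    Map(function(s, e) lines[s:e], starts, ends)
  }
  out <- vector("list", length(chunks))
  for (i in seq_along(chunks)) {
    chunk <- chunks[[i]][grepl("^(ATOM  |HETATM)", chunks[[i]])]
    if (length(chunk) == 0L)
      stop_format(paste0("model ", i, " contains no atoms"), file = path)
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(c(chunk, "END"), tmp)
    pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(tmp, verbose = FALSE)),
                    error = function(e)
                      stop_format(paste0("unparsable PDB content in model ", i,
                                         ": ", conditionMessage(e)),
                                  file = path))
    a <- pdb$atom
    ele <- a$elesy
    ele[is.na(ele) | !nzchar(trimws(ele))] <- NA
    out[[i]] <- structure_record(
      atom_name = a$elety, residue_number = a$resno, residue_name = a$resid,
      x = a$x, y = a$y, z = a$z,
      chain_id = ifelse(is.na(a$chain), "A", a$chain),
      element = if (all(is.na(ele))) NULL else trimws(ele),
      model_index = i)
  }
  out
}

#' Write structure records as a (multi-model) PDB file
#'
#' @param models a \code{\link{structure_record}} or list of them.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(models, path) {
  if (inherits(models, "structure_record")) models <- list(models)
  multi <- length(models) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(models)) {
    m <- models[[i]]
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    name4 <- ifelse(nchar(m$atom_name) < 4L,
                    sprintf(" %-3s", m$atom_name), m$atom_name)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(m)), name4, m$residue_name, m$chain_id, m$residue_number,
      m$x, m$y, m$z, 1, 0, m$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

topology_key <- function(m) paste(m$chain_id, m$residue_number, m$atom_name)

#' Combine structure models into trajectory frames
#'
#' All frames must share one topology: identical (chain, residue, atom name)
#' sets in identical order.
#'
#' @param models list of \code{\link{structure_record}} objects.
#' @param frame_interval optional time between frames (arbitrary units).
#' @return An object of class \code{trajectory_frames}.
#' @export
as_trajectory <- function(models, frame_interval = NULL) {
  if (inherits(models, "structure_record")) models <- list(models)
  stopifnot(length(models) >= 1L)
  ref <- topology_key(models[[1]])
  for (i in seq_along(models)) {
    k <- topology_key(models[[i]])
    if (length(k) != length(ref) || any(k != ref))
      stop_foxdyn(paste0("topology mismatch: frame ", i,
                         " does not share the topology of frame 1"),
                  "foxdyn_topology_error")
  }
  structure(list(frames = models, frame_interval = frame_interval),
            class = "trajectory_frames")
}

#' @export
length.trajectory_frames <- function(x) length(x$frames)

coords_matrix <- function(m) cbind(m$x, m$y, m$z)

set_coords <- function(m, xyz) {
  m$x <- xyz[, 1]; m$y <- xyz[, 2]; m$z <- xyz[, 3]
  m
}

# Apply a rigid transform y = x %*% R + t (rows are atoms).
transform_structure <- function(m, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- coords_matrix(m) %*% rotation
  set_coords(m, sweep(xyz, 2, translation, "+"))
}
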