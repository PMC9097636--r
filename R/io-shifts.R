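# Chemical-shift assignment tables (TSV and NMR-STAR v3 loop subset).

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Construct a chemical-shift assignment table
#'
#' Per-residue amide proton and nitrogen shifts for one protein state.
#' Residues lacking either shift are kept and flagged unassigned rather than
#' dropped, so downstream comparisons can distinguish "missing" from
#' "absent".
#'
#' @param residue integer residue numbers (strictly increasing after
#'   sorting; duplicates are an error).
#' @param aa 1-letter amino-acid codes.
#' @param dH amide proton shifts (ppm; \code{NA} = unassigned).
#' @param dN amide nitrogen shifts (ppm; \code{NA} = unassigned).
#' @param state_label free-text label of the protein state
#'   (e.g. \code{"FOXO1_FH_free"}).
#' @return A data frame of class \code{shift_table} with columns
#'   \code{residue}, \code{aa}, \code{dH}, \code{dN}, \code{assigned}.
#' @export
shift_table <- function(residue, aa, dH, dN, state_label = "") {
  df <- data.frame(residue = as.integer(residue),
                   aa = as.character(aa),
                   dH = as.numeric(dH), dN = as.numeric(dN),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$residue))
    stop_format(paste0("duplicate residue ",
                       df$residue[anyDuplicated(df$residue)]))
  df <- df[order(df$residue), , drop = FALSE]
  rownames(df) <- NULL
  for (col in c("dH", "dN")) {
    bad <- which(!is.na(df[[col]]) & (df[[col]] < -5 | df[[col]] > 250))
    if (length(bad))
      stop_foxdyn(paste0(col, " = ", df[[col]][bad[1]], " ppm for residue ",
                         df$residue[bad[1]], " is outside [-5, 250] ppm"),
                  "foxdyn_sanity_error")
  }
  df$assigned <- is.finite(df$dH) & is.finite(df$dN)
  structure(df, state_label = state_label,
            class = c("shift_table", "data.frame"))
}

#' Read a chemical-shift table
#'
#' Accepts either the canonical delimited dialect (tab-separated, header
#' \code{residue}, \code{aa}, \code{dH}, \code{dN}, \code{#} comments, empty
#' cells mark unassigned shifts) or an NMR-STAR v3 chemical-shift loop
#' (\code{_Atom_chem_shift} tags), from which amide H and N rows are merged
#' into one entry per residue.
#'
#' @param path path to the file.
#' @param state_label label for the protein state; defaults to the file name.
#' @param sep field separator of the delimited dialect.
#' @return A \code{\link{shift_table}}.
#' @export
read_shift_table <- function(path, state_label = NULL, sep = "\t") {
  if (!file.exists(path)) stop_format("file not found", file = path)
  state_label <- state_label %||% basename(path)
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("_Atom_chem_shift\\.", lines)))
    return(read_star_shifts(lines, path, state_label))
  raw <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("residue", "aa", "dH", "dN")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop_format(paste0("missing column(s): ", paste(miss, collapse = ", ")),
                file = path, line = 1)
  num <- function(v) suppressWarnings(as.numeric(ifelse(trimws(v) %in%
      c("", ".", "NA"), NA, v)))
  res <- num(raw$residue)
  if (anyNA(res)) stop_format("non-numeric residue id", file = path,
                              line = which(is.na(res))[1] + 1L)
  tryCatch(
    shift_table(res, trimws(raw$aa), num(raw$dH), num(raw$dN), state_label),
    foxdyn_format_error = function(e)
      stop_format(conditionMessage(e), file = path))
}

# Minimal NMR-STAR v3 reader: one _Atom_chem_shift loop, H/N amide rows only.
read_star_shifts <- function(lines, path, state_label) {
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  for (ls in loop_starts) {
    i <- ls + 1L
    tags <- character()
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1L
    }
    if (!any(grepl("^_Atom_chem_shift\\.", tags))) next
    col <- function(tag) match(paste0("_Atom_chem_shift.", tag), tags)
    seq_col <- col("Seq_ID"); comp_col <- col("Comp_ID")
    atom_col <- col("Atom_ID"); val_col <- col("Val")
    if (anyNA(c(seq_col, comp_col, atom_col, val_col)))
      stop_format("chemical-shift loop lacks Seq_ID/Comp_ID/Atom_ID/Val tags",
                  file = path, line = ls)
    rows <- list()
    while (i <= length(lines) && !grepl("^\\s*(stop_|loop_)", lines[i])) {
      ln <- trimws(lines[i])
      if (nzchar(ln) && !startsWith(ln, "#")) {
        f <- strsplit(ln, "\\s+")[[1]]
        if (length(f) < length(tags))
          stop_format("short data row in chemical-shift loop",
                      file = path, line = i)
        rows[[length(rows) + 1L]] <- f
      }
      i <- i + 1L
    }
    f <- do.call(rbind, rows)
    atom <- f[, atom_col]
    keep <- atom %in% c("H", "N")
    f <- f[keep, , drop = FALSE]; atom <- atom[keep]
    res <- as.integer(f[, seq_col])
    val <- as.numeric(f[, val_col])
    aa3 <- toupper(f[, comp_col])
    ids <- sort(unique(res))
    dH <- dN <- rep(NA_real_, length(ids))
    aa <- rep(NA_character_, length(ids))
    for (j in seq_along(ids)) {
      sel <- res == ids[j]
      aa[j] <- unname(AA3TO1[aa3[sel][1]]) %||% "X"
      h <- val[sel & atom == "H"]; n <- val[sel & atom == "N"]
      if (length(h)) dH[j] <- h[1]
      if (length(n)) dN[j] <- n[1]
    }
    aa[is.na(aa)] <- "X"
    return(shift_table(ids, aa, dH, dN, state_label))
  }
  stop_format("no _Atom_chem_shift loop found", file = path)
}

#' Write a chemical-shift table in the canonical dialect
#'
#' @param x a \code{\link{shift_table}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_shift_table <- function(x, path) {
  stopifnot(inherits(x, "shift_table"))
  fmt <- function(v) ifelse(is.na(v), "", format(v, trim = TRUE, digits = 10))
  out <- data.frame(residue = x$residue, aa = x$aa,
                    dH = fmt(x$dH), dN = fmt(x$dN))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
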