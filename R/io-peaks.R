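# Peak-intensity tables for pseudo-3D relaxation series.

EXPERIMENT_KINDS <- c("T1", "T1rho", "hetnoe_sat", "hetnoe_ref")

#' Construct a peak-intensity table
#'
#' A peak-intensity table holds one row per (residue, relaxation delay,
#' replicate) of a pseudo-3D relaxation series. Duplicated delays (the
#' repeated plane acquired for error analysis) are kept as separate rows
#' distinguished by the replicate index.
#'
#' @param residue integer residue numbers (author numbering).
#' @param delay relaxation delays in seconds (must be > 0 for T1/T1rho;
#'   ignored convention for hetNOE planes, where 0 is allowed).
#' @param intensity peak intensities (arbitrary units, finite).
#' @param replicate non-negative integer replicate index (default 0).
#' @param experiment_kind one of \code{"T1"}, \code{"T1rho"},
#'   \code{"hetnoe_sat"}, \code{"hetnoe_ref"}.
#' @return A data frame of class \code{peak_table} with attribute
#'   \code{experiment_kind}.
#' @export
peak_table <- function(residue, delay, intensity, replicate = 0L,
                       experiment_kind = "T1") {
  experiment_kind <- match.arg(experiment_kind, EXPERIMENT_KINDS)
  df <- data.frame(residue = as.integer(residue),
                   delay = as.numeric(delay),
                   intensity = as.numeric(intensity),
                   replicate = as.integer(rep_len(replicate, length(residue))))
  validate_peak_table(df, experiment_kind)
  structure(df, experiment_kind = experiment_kind,
            class = c("peak_table", "data.frame"))
}

validate_peak_table <- function(df, experiment_kind, file = NULL) {
  if (!all(is.finite(df$intensity)))
    stop_format("non-finite intensity value",
                file = file, line = which(!is.finite(df$intensity))[1])
  if (experiment_kind %in% c("T1", "T1rho") && any(df$delay <= 0))
    stop_format("relaxation delays must be > 0",
                file = file, line = which(df$delay <= 0)[1])
  if (any(df$replicate < 0))
    stop_format("replicate indices must be >= 0", file = file)
  key <- paste(df$residue, df$delay, df$replicate)
  if (anyDuplicated(key))
    stop_format(paste0("duplicate (residue, delay, replicate) triple: ",
                       key[anyDuplicated(key)]),
                file = file, line = anyDuplicated(key))
  invisible(df)
}

#' Read a peak-intensity table from delimited text
#'
#' The canonical dialect is tab-separated with a header line declaring the
#' columns \code{residue}, \code{delay}, \code{intensity}, \code{replicate},
#' \code{#} comment lines and '.' decimals. Errors name the offending file
#' and line.
#'
#' @param path path to the file.
#' @param experiment_kind experiment the table belongs to (see
#'   \code{\link{peak_table}}).
#' @param sep field separator; use \code{","} for CSV input.
#' @return A \code{\link{peak_table}}.
#' @export
read_peak_table <- function(path, experiment_kind = "T1", sep = "\t") {
  experiment_kind <- match.arg(experiment_kind, EXPERIMENT_KINDS)
  if (!file.exists(path)) stop_format("file not found", file = path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("residue", "delay", "intensity", "replicate")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop_format(paste0("missing column(s): ", paste(miss, collapse = ", ")),
                file = path, line = 1)
  num <- lapply(raw[need], function(col) suppressWarnings(as.numeric(col)))
  for (col in need) {
    bad <- which(!is.finite(num[[col]]))
    if (length(bad))
      stop_format(paste0("non-numeric or non-finite '", col, "' value '",
                         raw[[col]][bad[1]], "'"),
                  file = path, line = bad[1] + 1L)
  }
  df <- data.frame(residue = as.integer(num$residue), delay = num$delay,
                   intensity = num$intensity,
                   replicate = as.integer(num$replicate))
  validate_peak_table(df, experiment_kind, file = path)
  structure(df, experiment_kind = experiment_kind,
            class = c("peak_table", "data.frame"))
}

#' Write a peak-intensity table in the canonical dialect
#'
#' @param x a \code{\link{peak_table}}.
#' @param path output path.
#' @param sep field separator (tab by default).
#' @return \code{path}, invisibly. \code{read_peak_table(write_peak_table(x))}
#'   reproduces \code{x}.
#' @export
write_peak_table <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "peak_table"))
  out <- data.frame(residue = x$residue,
                    delay = format(x$delay, trim = TRUE, scientific = FALSE),
                    intensity = formatC(x$intensity, digits = 17,
                                        format = "g"),
                    replicate = x$replicate)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract one residue's decay series from a peak table
#'
#' Collects the (delay, intensity) points of one residue, keeping duplicated
#' delays as independent observations, and records which index pairs share a
#' delay (the duplicate bookkeeping used for pooled-noise estimation).
#'
#' @param x a \code{\link{peak_table}} of kind T1 or T1rho.
#' @param residue residue number.
#' @return An object of class \code{decay_series}: a list with elements
#'   \code{residue}, \code{t} (s), \code{I}, and \code{duplicate_pairs}
#'   (two-column matrix of indices sharing a delay).
#' @export
decay_series <- function(x, residue) {
  stopifnot(inherits(x, "peak_table"))
  rows <- x[x$residue == residue, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop_foxdyn(paste0("residue ", residue, " not present in table"),
                "foxdyn_missing_residue")
  ord <- order(rows$delay, rows$replicate)
  rows <- rows[ord, , drop = FALSE]
  t <- rows$delay
  if (length(unique(t)) < 3L)
    stop_foxdyn("decay series needs >= 3 distinct delays",
                "foxdyn_precondition_error")
  dup <- which(duplicated(t))
  pairs <- if (length(dup))
    cbind(match(t[dup], t), dup) else matrix(integer(), ncol = 2)
  structure(list(residue = residue, t = t, I = rows$intensity,
                 duplicate_pairs = pairs),
            class = "decay_series")
}
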