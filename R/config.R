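#' Run configuration
#'
#' Central container for the tunable parameters of the pipeline. Defaults
#' reproduce the acquisition and analysis settings of the relaxation and
#' titration experiments the package models: a 1.9 kHz \eqn{^{15}}N
#' spin-lock, 1000 Monte-Carlo replicates resampled at twice the pooled
#' noise, the ~0.14 nitrogen weighting of the composite chemical-shift
#' perturbation (divisor 7), and a 2--5 residue spacing window with a 6
#' angstrom distance cutoff for the tryptophan-interaction motif.
#'
#' @param b0_proton_mhz static field expressed as the proton frequency (MHz).
#' @param spinlock_khz spin-lock field strength (kHz); converted internally
#'   to rad/s as \eqn{\omega_1 = 2\pi \cdot 10^3 \cdot} \code{spinlock_khz}.
#' @param n_mc number of Monte-Carlo replicates (>= 2).
#' @param mc_width_factor multiple of the pooled noise used as the resampling
#'   width in the Monte-Carlo error analysis.
#' @param seed integer RNG seed recorded with every run.
#' @param n_scale nitrogen divisor of the composite CSP (unitless).
#' @param motif_spacing integer vector of admissible between-residue counts
#'   for the W-[2-5]-[S/T/C/Y] motif.
#' @param motif_d_cutoff distance (angstrom) below which a motif pair is
#'   flagged as interacting.
#' @param csp_strong_threshold CSP (ppm) separating weak from strong
#'   perturbations.
#' @param csp_noise_floor CSP (ppm) below which a residue counts as
#'   unaffected.
#' @param broadening_ratio bound/free intensity ratio below which a peak
#'   counts as line-broadened.
#' @param carrier_n_ppm \eqn{^{15}}N carrier position (ppm) used to convert
#'   nitrogen shifts to resonance offsets; must be supplied by the user when
#'   the tilted-field correction is computed from shifts.
#' @return An object of class \code{run_config} (a named list).
#' @seealso \code{\link{read_run_config}}
#' @export
run_config <- function(b0_proton_mhz = 600,
                       spinlock_khz = 1.9,
                       n_mc = 1000L,
                       mc_width_factor = 2,
                       seed = 1L,
                       n_scale = 7,
                       motif_spacing = 2:5,
                       motif_d_cutoff = 6,
                       csp_strong_threshold = 0.05,
                       csp_noise_floor = 0.005,
                       broadening_ratio = 0.3,
                       carrier_n_ppm = NA_real_) {
  if (!is_count(n_mc) || n_mc < 2)
    stop_foxdyn("n_mc must be an integer >= 2", "foxdyn_config_error")
  if (!is.numeric(spinlock_khz) || spinlock_khz <= 0)
    stop_foxdyn("spinlock_khz must be > 0", "foxdyn_config_error")
  if (any(motif_spacing < 1))
    stop_foxdyn("motif_spacing bounds must be >= 1", "foxdyn_config_error")
  structure(list(
    b0_proton_mhz = b0_proton_mhz,
    spinlock_khz = spinlock_khz,
    n_mc = as.integer(n_mc),
    mc_width_factor = mc_width_factor,
    seed = as.integer(seed),
    n_scale = n_scale,
    motif_spacing = as.integer(motif_spacing),
    motif_d_cutoff = motif_d_cutoff,
    csp_strong_threshold = csp_strong_threshold,
    csp_noise_floor = csp_noise_floor,
    broadening_ratio = broadening_ratio,
    carrier_n_ppm = carrier_n_ppm
  ), class = "run_config")
}

#' Read a flat key=value configuration file
#'
#' The accepted dialect is a TOML-compatible flat file: one \code{key = value}
#' pair per line, \code{#} comments, '.' decimal separator. Unknown keys are
#' rejected so typos surface immediately. Values listed as comma-separated
#' numbers (e.g. \code{motif_spacing = 2,3,4,5}) become numeric vectors.
#'
#' @param path path to the configuration file.
#' @param ... overrides applied after the file is read (highest precedence).
#' @return A \code{\link{run_config}} object.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path))
    stop_format("config file not found", file = path)
  lines <- readLines(path, warn = FALSE)
  args <- list()
  known <- names(formals(run_config))
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[[i]])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (!grepl("=", ln, fixed = TRUE))
      stop_format("expected 'key = value'", file = path, line = i)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% known)
      stop_format(paste0("unknown config key '", key, "'"),
                  file = path, line = i)
    val <- gsub("^\"|\"$", "", val)
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    args[[key]] <- if (!anyNA(num)) num else val
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(run_config, args)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-22s %s\n", k, paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
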