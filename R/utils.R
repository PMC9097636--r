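# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_foxdyn <- function(msg, class, ...) {
  stop(structure(class = c(class, "foxdyn_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

# Format-error helper carrying a file/line locator, per the reader contract.
stop_format <- function(msg, file = NULL, line = NULL) {
  loc <- c(if (!is.null(file)) paste0("file '", file, "'"),
           if (!is.null(line)) paste0("line ", line))
  if (length(loc)) msg <- paste0(msg, " (", paste(loc, collapse = ", "), ")")
  stop_foxdyn(msg, "foxdyn_format_error", file = file, line = line)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

vec3_norm <- function(v) sqrt(sum(v^2))

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180
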