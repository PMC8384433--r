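# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Derive a reproducible sub-seed from a root seed
#'
#' All randomized harnesses in the package draw their per-replicate and
#' per-component seeds through this function so that a single root seed
#' determines every random stream. The result always stays below 2^31 - 1.
#'
#' @param seed Integer root seed.
#' @param i Integer stream index (replicate number, component id, ...).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, i) {
  seed <- as.numeric(seed); i <- as.numeric(i)
  as.integer((seed * 48271 + i * 100003 + 12345) %% 2147483629)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Format a number so that it round-trips through text within 1e-12 relative.
fmt_num <- function(x) sprintf("%.15g", x)
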