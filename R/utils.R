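#' @keywords internal
#' @useDynLib ohcasweep, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals do not
#' disturb the caller's random-number stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Derive a deterministic child seed from a master seed
#'
#' Mixes a master seed with an integer salt so every pipeline stage gets its
#' own reproducible stream. Result is kept below 2^31 - 1.
#' @noRd
derive_seed <- function(master, salt) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  as.integer((abs(master) %% 65011 + 1) * 7919 + (salt %% 9973) * 104729) %% 2147483647L
}

stop_config <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

assert_fraction <- function(x, name, open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (open && (x <= 0 || x >= 1)) || (!open && (x < 0 || x > 1))) {
    stop_config("config field '%s' must be a fraction in %s, got %s",
                name, if (open) "(0,1)" else "[0,1]", format(x))
  }
  invisible(x)
}

#' Clip probabilities away from 0 and 1 for log-loss evaluation
#' @noRd
clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# Row-broadcast helpers: apply a per-column vector across every row of a
# matrix without sweep()'s overhead (column-major recycling via rep each=).
bsub <- function(M, v) M - rep(v, each = nrow(M))
bmul <- function(M, v) M * rep(v, each = nrow(M))
badd <- function(M, v) M + rep(v, each = nrow(M))
bdiv <- function(M, v) M / rep(v, each = nrow(M))
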