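#' @keywords internal
"_PACKAGE"

# Canonical 7-network labels, in the fixed order used for tie-breaking and
# block layout throughout the package.
NETWORK_LABELS <- c("VN", "SMN", "DAN", "VAN", "LN", "FPN", "DMN")

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the RNG with `seed`, runs `expr`, and restores the caller's RNG
#' state afterwards, so library functions stay deterministic without
#' clobbering the session's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream-specific child seed from a master seed, staying inside
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587L) + 1L
}

stop_brainfp <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
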