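# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# bound into [0,1] preserving dim/dimnames (pmin/pmax drop them)
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Derive a per-stage seed from a global seed
#'
#' One global seed is expanded into deterministic substreams so each pipeline
#' stage is reproducible in isolation. The derivation is a fixed affine map
#' modulo a Mersenne prime, kept below `.Machine$integer.max`.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character) or index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is_scalar_num(seed))
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  as.integer((as.numeric(seed) * 48271 + as.numeric(stage) * 16807) %% 2147483647)
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic numeric formatting for file output (15 significant digits,
# plain decimal/scientific, independent of options()).
fmt_num <- function(x) {
  out <- formatC(x, digits = 15, format = "g", flag = "")
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  trimws(out)
}
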