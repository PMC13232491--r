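# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Round `x` to `digits` decimal places (or significant digits) using one of
# the display rounding strategies: "round" is half-away-from-zero, "down"
# truncates toward zero, "up" rounds away from zero.
round_value <- function(x, digits, strategy = c("round", "down", "up"),
                        significant = FALSE) {
  strategy <- match.arg(strategy)
  if (!is.finite(x)) stop("cannot round non-finite value")
  if (x == 0) return(0)
  if (significant) {
    digits <- digits - 1L - floor(log10(abs(x)))
  }
  factor <- 10^digits
  scaled <- abs(x) * factor
  # guard against binary representation pushing an exact value below itself
  scaled <- scaled * (1 + 8 * .Machine$double.eps)
  r <- switch(strategy,
    round = floor(scaled + 0.5),
    down  = floor(scaled),
    up    = ceiling(scaled)
  )
  sign(x) * r / factor
}

is_url <- function(x) {
  is.character(x) && length(x) == 1 && grepl("^https?://", x)
}

# Fetch an http(s) URL to a local temporary file; local paths pass through.
local_source <- function(source) {
  if (is_url(source)) {
    dest <- tempfile(fileext = paste0(".", basename(source)))
    status <- utils::download.file(source, dest, quiet = TRUE, mode = "wb")
    if (status != 0) stop("failed to fetch URL: ", source)
    return(dest)
  }
  source
}

`%||%` <- function(a, b) if (is.null(a)) b else a
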