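# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without touching the caller's RNG
# stream. Every stochastic operation in the package takes an explicit seed and
# routes through this, so there is no hidden global state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a child seed from a base seed and a stage offset, kept inside the
# 32-bit integer range R requires.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1000003 + offset) %% 2147483629)
}

parse_iso8601 <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  fallback <- is.na(out)
  if (any(fallback)) {
    out[fallback] <- as.POSIXct(x[fallback], tz = "UTC")
  }
  if (anyNA(out)) stop("unparseable ISO-8601 timestamp(s)", call. = FALSE)
  out
}

format_iso8601 <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

# Clock string "HH:MM" -> minutes past midnight.
clock_to_minutes <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("clock times must be 'HH:MM'", call. = FALSE)
  as.numeric(parts[1]) * 60 + as.numeric(parts[2])
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}
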