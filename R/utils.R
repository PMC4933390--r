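## Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All simulators funnel through this.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a deterministic sub-seed for a named component, kept < 2^31.
subSeed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  (as.integer(seed) * 1009L + as.integer(h %% 1000L)) %% 2147483629L
}

# Maximal runs of TRUE in a logical vector, merged across FALSE gaps of
# length <= mergeGap. Returns a data.frame(start, end), 1-based inclusive.
findRuns <- function(flag, mergeGap = 0L) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(data.frame(start = integer(0), end = integer(0)))
  s <- starts[keep]; e <- ends[keep]
  if (mergeGap > 0L && length(s) > 1L) {
    ms <- s[1]; me <- e[1]; out_s <- integer(0); out_e <- integer(0)
    for (i in seq_along(s)[-1]) {
      if (s[i] - me - 1L <= mergeGap) me <- e[i]
      else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
    }
    s <- c(out_s, ms); e <- c(out_e, me)
  }
  data.frame(start = s, end = e)
}

# stopifnot with a readable message
assertThat <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
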