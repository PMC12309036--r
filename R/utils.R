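# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Gaps between consecutive timestamps, in hours. `t` is POSIXct or numeric
# seconds.
gaps_hours <- function(t) {
  as.numeric(diff(as.numeric(t))) / 3600
}

stop_degenerate <- function(id, n) {
  stop(sprintf("track '%s' degenerate: %d fix(es) remain, need at least 2",
               id, n), call. = FALSE)
}
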