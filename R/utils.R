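# Seed plumbing: every stochastic routine takes an integer seed and evaluates
# under an isolated RNG state so that library code never perturbs (or depends
# on) the caller's random stream.

with_seed <- function(seed, code) {
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
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream label, staying inside
# 32-bit integer range. Cheap string hash (djb2 variant), not cryptographic.
derive_seed <- function(seed, stream, index = 0L) {
  h <- 5381
  for (ch in utf8ToInt(as.character(stream))) h <- (h * 33 + ch) %% 2147483647
  as.integer((as.double(seed) * 48271 + h + as.double(index) * 104729) %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# matrix slice of a [B, T, F] array at timestep t, robust to B == 1 or F == 1
tslice <- function(x, t) {
  d <- dim(x)
  matrix(x[, t, ], nrow = d[1], ncol = d[3])
}

abort_cf <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "crisproff_error")))
}
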