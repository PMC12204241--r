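# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so generators never perturb global draws.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
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
  force(expr)
}

# Deterministic per-stage substream: offsets the master seed by a hash of the
# stage name so toggling one stage never perturbs another stage's draws.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 97651L
  as.integer((as.numeric(seed) + 1009 * h) %% 2147483647)
}

rdirichlet <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s == 0) {
    # degenerate protection for tiny alpha; renormalize a point mass
    g[which.max(alpha)] <- 1
    s <- 1
  }
  g / s
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

POP_GROUPS <- c("AA-NL", "L", "W-NL")
BRAIN_REGIONS <- c("DLPFC", "STG", "AC")
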