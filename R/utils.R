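# Internal numerical and RNG helpers.

# log(sum(exp(x))) without overflow; -Inf components are allowed.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL leaves the global stream
# untouched (and advancing).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = env)), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministically derive n independent substream seeds from one root seed,
# so that consumers (per-model samplers, per-chain runs, response draws) do
# not perturb each other's streams whatever order they run in.
substream_seeds <- function(root, n) {
  if (is.null(root)) return(rep(list(NULL), n))
  as.list(with_seed(root, sample.int(.Machine$integer.max - 1L, n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
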