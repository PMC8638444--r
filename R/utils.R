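## Internal RNG helpers: every stochastic entry point takes `seed = NULL`
## (use the current RNG stream) or an integer for a reproducible, isolated
## draw that leaves the caller's RNG state untouched.

with_seed <- function(seed, code) {
  code <- substitute(code)
  if (is.null(seed)) return(eval(code, parent.frame()))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval(code, parent.frame())
}

## Deterministic sub-stream seed, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) %% 2147483.0) * 977 + (k %% 1000003) * 101 + 1) %% 2147483646L + 1L
}

## Stratified fold assignment: cases and controls are spread across folds as
## evenly as possible. n_f == N gives leave-one-out.
stratified_folds <- function(y, n_f, seed = NULL) {
  N <- length(y)
  if (n_f < 2) stop("need at least 2 folds")
  if (n_f > N) stop("more folds than observations")
  if (n_f == N) return(seq_len(N))
  folds <- integer(N)
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(n_f), length(idx)))
    }
  })
  folds
}

## Total binomial deviance of probabilities p for outcome y (capped away from
## 0/1 so saturated predictions stay finite).
binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}
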