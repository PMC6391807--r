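# Evaluate an expression under a temporary RNG state so seeded helpers do
# not disturb the caller's random stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stratified K-fold assignment: events and censored subjects are split into
# folds separately so no fold is event-free.
make_folds <- function(status, K, seed = NULL) {
  n <- length(status)
  if (K < 2 || K > n) stop("'K' must be between 2 and n")
  if (sum(status == 1) < K)
    stop("fewer events than folds; reduce K")
  with_seed(seed, {
    fold <- integer(n)
    for (s in unique(status)) {
      idx <- which(status == s)
      fold[idx] <- sample(rep_len(seq_len(K), length(idx)))
    }
    fold
  })
}

# Small deterministic fingerprint of a configuration list (polynomial
# rolling hash over its deparsed form, mod a Mersenne prime); embedded in
# output metadata so reruns are verifiable.
config_fingerprint <- function(cfg) {
  txt <- paste(deparse(cfg), collapse = "")
  bytes <- as.integer(charToRaw(txt))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
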