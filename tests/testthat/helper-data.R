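# Small fixtures built in code.

# random censored survival data with a couple of informative predictors
small_surv_data <- function(n = 40, p = 3, seed = 1, beta = NULL,
                            tie_times = FALSE) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("x", seq_len(p))
  if (is.null(beta)) beta <- c(0.8, -0.5, rep(0, p - 2))[seq_len(p)]
  eta <- drop(x %*% beta)
  t_true <- rexp(n, rate = exp(eta))
  cens <- rexp(n, rate = exp(rnorm(n)))
  time <- pmin(t_true, cens)
  status <- as.numeric(cens > t_true)
  if (sum(status) < 2) status[1:2] <- 1
  if (tie_times) time <- round(time, 1) + 0.05  # force exact ties
  list(x = x, y = surv_outcome(time, status), beta = beta)
}

# brute-force partial log-likelihood by direct risk-set enumeration
# (independent of the package's cumulative-sum implementation; Breslow ties)
pl_brute <- function(eta, time, status) {
  out <- 0
  for (i in which(status == 1)) {
    rs <- which(time >= time[i])
    out <- out + eta[i] - log(sum(exp(eta[rs])))
  }
  out
}

# brute-force Harrell C-index over all pairs
cindex_brute <- function(time, status, eta) {
  conc <- usable <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    earlier_event <- (time[i] < time[j] && status[i] == 1) ||
      (time[i] == time[j] && status[i] == 1 && status[j] == 0)
    if (!earlier_event) next
    usable <- usable + 1
    if (eta[i] > eta[j]) conc <- conc + 1
    else if (eta[i] == eta[j]) conc <- conc + 0.5
  }
  conc / usable
}
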