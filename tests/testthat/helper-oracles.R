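# Independent brute-force reference implementations, written as literal
# loops over the definitions so they share no code with the package.

bf_co_trev <- function(x, tau) {
  n <- length(x)
  num <- 0; den <- 0; cnt <- 0
  for (i in seq.int(tau + 1, n)) {
    d <- x[i - tau] - x[i]
    num <- num + d^3
    den <- den + d^2
    cnt <- cnt + 1
  }
  num <- num / cnt; den <- den / cnt
  if (den == 0) return(NA_real_)
  num / den^1.5
}

bf_dk_trev <- function(x, tau) {
  n <- length(x)
  nr <- n - 2 * tau
  acc <- 0
  for (t in seq_len(nr)) {
    a1 <- x[t]; a2 <- x[t + tau]; a3 <- x[t + 2 * tau]
    acc <- acc + (a1 * a1 * a2 - a2 * a3 * a3)
  }
  acc / nr
}

# ordinal-pattern entropy via rank strings (valid for tie-free series)
bf_perm_entropy <- function(x, m, tau) {
  np <- length(x) - (m - 1) * tau
  pats <- character(np)
  for (t in seq_len(np)) {
    w <- x[t + (seq_len(m) - 1) * tau]
    pats[t] <- paste(rank(w), collapse = "-")
  }
  p <- as.numeric(table(pats)) / np
  -sum(p * log(p))
}

bf_transition_matrix <- function(x, k) {
  br <- stats::quantile(x, probs = seq_len(k - 1) / k, names = FALSE)
  n <- length(x)
  s <- integer(n)
  for (i in seq_len(n)) s[i] <- 1L + sum(br <= x[i])
  cnt <- matrix(0, k, k)
  for (i in seq_len(n - 1)) cnt[s[i], s[i + 1]] <- cnt[s[i], s[i + 1]] + 1
  rs <- rowSums(cnt)
  rs[rs == 0] <- 1
  cnt / rs
}

# exact P(longest run of successes >= r in n Bernoulli(p) trials), by
# dynamic programming over the trailing run length (absorbing at r)
bf_run_probability <- function(n, p, r) {
  if (r > n) return(0)
  state <- c(1, numeric(r - 1))  # state[j + 1]: P(trailing run == j, not yet absorbed)
  absorbed <- 0
  for (t in seq_len(n)) {
    nxt <- numeric(r)
    for (j in 0:(r - 1)) {
      pr <- state[j + 1]
      if (pr == 0) next
      nxt[1] <- nxt[1] + pr * (1 - p)
      if (j + 1 >= r) absorbed <- absorbed + pr * p
      else nxt[j + 2] <- nxt[j + 2] + pr * p
    }
    state <- nxt
  }
  absorbed
}

# small synthetic dataset used by several module tests
tiny_dataset <- function(seed = 1, n_birds = 2, renditions = 3, probes = 0) {
  make_dataset(synth_config(n_birds = n_birds,
                            renditions_per_context = renditions,
                            probe_renditions_per_context = probes,
                            seed = seed))
}
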