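# Independent brute-force oracles used across test files. These share no
# code with the package: everything is computed by plain loops so they
# can serve as references for the vectorized implementations.

# d and s for one gene by direct arithmetic
oracle_d <- function(x1, x2, s0 = 0) {
  n1 <- length(x1); n2 <- length(x2)
  r <- mean(x2) - mean(x1)
  s <- sqrt(((1 / n1 + 1 / n2) / (n1 + n2 - 2)) *
              (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)))
  list(d = r / (s + s0), s = s, r = r)
}

# Exhaustive SAM q-values for a small matrix: enumerate every label
# assignment, median null exceedance count / observed count, running
# max from the top |d| rank down.
oracle_sam_q <- function(values, n2, s0) {
  n <- ncol(values)
  G <- nrow(values)
  combs <- combn(n, n2)
  d_for <- function(idx2) {
    sapply(seq_len(G), function(g) {
      x2 <- values[g, idx2]; x1 <- values[g, -idx2]
      oracle_d(x1, x2, s0)$d
    })
  }
  d_obs <- d_for((n - n2 + 1):n)   # observed: group 2 = last n2 columns
  null_absd <- abs(apply(combs, 2, d_for))
  if (is.null(dim(null_absd))) null_absd <- matrix(null_absd, nrow = G)
  ord <- order(abs(d_obs), decreasing = TRUE)
  q <- numeric(G)
  prev <- 0
  for (i in seq_along(ord)) {
    thr <- abs(d_obs[ord[i]])
    nulls <- apply(null_absd, 2, function(col) sum(col >= thr))
    raw <- min(1, median(nulls) / i)
    prev <- max(prev, raw)
    q[ord[i]] <- prev
  }
  list(d = d_obs, q = q)
}

# Hand-rolled Kaplan-Meier product-limit curve
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ut, surv = surv)
}

# Hand-rolled two-group log-rank chi-square
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1L
  ut <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in ut) {
    n <- sum(time >= t); n1 <- sum(time >= t & g)
    d <- sum(time == t & event); d1 <- sum(time == t & event & g)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# scaled-down study configuration used for planted-recovery runs
recovery_config <- function(seed = 7) {
  sim_config(n_genes_universe = 3000, n_estrous_genes = 120,
             per_dataset_de_sizes = c(400, 250, 120, 40, 30),
             planted_overlap = 40, samples_per_group = 10,
             de_log2_effect = 2, noise_sd = 0.5, seed = seed)
}
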