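# Small independent oracles and fixture builders used across tests.

# Tiny expression matrix with deterministic values.
tiny_expr <- function(n_genes = 4, n_samples = 6, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = 7), n_genes, n_samples,
              dimnames = list(paste0("G", seq_len(n_genes)),
                              paste0("S", seq_len(n_samples))))
  m
}

# Breslow log partial likelihood for a single covariate (oracle for Cox).
breslow_loglik <- function(beta, times, events, x) {
  eta <- beta * x
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    d <- which(times == t & events == 1)
    risk <- which(times >= t)
    ll <- ll + sum(eta[d]) - length(d) * log(sum(exp(eta[risk])))
  }
  ll
}

# Plain empirical cumulative/dynamic AUC by exhaustive pair counting
# (valid when there is no censoring).
pair_count_auc <- function(times, events, marker, horizon) {
  case <- which(times <= horizon & events == 1)
  ctrl <- which(times > horizon)
  if (length(case) == 0 || length(ctrl) == 0) return(NA_real_)
  tot <- 0
  for (i in case) for (j in ctrl) {
    tot <- tot + (marker[i] > marker[j]) + 0.5 * (marker[i] == marker[j])
  }
  tot / (length(case) * length(ctrl))
}

# Ordinary pooled-variance two-sample t statistic (oracle for the
# moderated t in the no-shrinkage limit).
pooled_t <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  s2 <- ((n1 - 1) * var(x1) + (n0 - 1) * var(x0)) / (n1 + n0 - 2)
  (mean(x1) - mean(x0)) / sqrt(s2 * (1 / n1 + 1 / n0))
}

# Exponentially censored survival simulator: censoring rate rc gives an
# expected censored fraction rc / (rc + hazard) within each arm.
sim_surv_arm <- function(n, hazard, censor_hazard) {
  t_true <- rexp(n, hazard)
  if (censor_hazard <= 0) return(list(time = t_true, event = rep(1L, n)))
  cens <- rexp(n, censor_hazard)
  list(time = pmin(t_true, cens), event = as.integer(t_true <= cens))
}
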