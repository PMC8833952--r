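# Independent oracles, kept deliberately separate from the implementation
# paths they check.

# Brute-force transcription of the published TMM estimator, written as a
# plain loop with explicit intermediate vectors.
oracle_tmm <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  lib <- colSums(counts)
  f75 <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    f75[j] <- unname(quantile(counts[, j], 0.75)) / lib[j]
  }
  ref <- which.min(abs(f75 - mean(f75)))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    obs <- counts[, j]; rf <- counts[, ref]
    nO <- lib[j]; nR <- lib[ref]
    M <- log2((obs / nO) / (rf / nR))
    A <- (log2(obs / nO) + log2(rf / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - rf) / nR / rf
    ok <- is.finite(M) & is.finite(A) & A > -1e10
    M <- M[ok]; A <- A[ok]; v <- v[ok]
    if (max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f[j] <- 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f / exp(mean(log(f)))
}

# Direct reading of the terminal-SNV discard rule: drop a call iff any
# UNKNOWN SNV sits in the first or last two nucleotides of the aligned read.
oracle_terminal_filter <- function(calls) {
  vapply(seq_len(nrow(calls)), function(i) {
    if (!nzchar(calls$snvs[i])) return(FALSE)
    ann <- regmatches(calls$snvs[i],
                      gregexpr("[A-Z_]+", calls$snvs[i]))[[1]]
    ann <- ann[!ann %in% c("A", "C", "G", "T")]
    rp <- as.integer(strsplit(calls$snv_read_pos[i], ",")[[1]])
    n <- calls$aligned_len[i]
    any(ann == "UNKNOWN" & (rp %in% c(1L, 2L, n - 1L, n)))
  }, NA)
}

# Literal condition table for the six-trend taxonomy.
oracle_trend <- function(g) {
  wn <- g[1]; wt <- g[2]; bn <- g[3]; bt <- g[4]
  if (wn < wt & wt < bn & bn < bt) return("MONOTONIC_INC")
  if (wn > wt & wt > bn & bn > bt) return("MONOTONIC_DEC")
  if (wt == wn | bt == bn) return("UNCLASSIFIED")
  up_w <- wt > wn; up_b <- bt > bn
  if (up_w & up_b) return("UP_BOTH")
  if (!up_w & !up_b) return("DOWN_BOTH")
  if (up_w & !up_b) return("UP_W_DOWN_BAA")
  "DOWN_W_UP_BAA"
}

# Exhaustive concordant-pair AUC.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive hypergeometric upper tail: enumerate every draw of size n
# from the universe and count draws with overlap >= observed.
oracle_hyper_enum <- function(k, set, universe, n) {
  draws <- combn(length(universe), n)
  hits <- 0
  for (j in seq_len(ncol(draws))) {
    ov <- length(intersect(universe[draws[, j]], set))
    if (ov >= k) hits <- hits + 1
  }
  hits / ncol(draws)
}

# Permutation log-rank p-value.
oracle_logrank_perm <- function(records, group, n_perm = 999, seed = 99) {
  set.seed(seed)
  obs <- km_logrank(records, group)$chi2
  cnt <- 0
  for (b in seq_len(n_perm)) {
    if (km_logrank(records, sample(group))$chi2 >= obs - 1e-12) cnt <- cnt + 1
  }
  (cnt + 1) / (n_perm + 1)
}

# Independent exponential-censoring survival simulator for Cox checks
# (binary two-group covariate, censoring rate calibrated analytically).
sim_cox_cohort <- function(n, beta, censor_frac, base_rate = 0.05) {
  x <- rbinom(n, 1, 0.5)
  lam <- base_rate * exp(beta * x)
  t_ev <- rexp(n, lam)
  if (censor_frac > 0) {
    f <- function(rc) mean(rc / (rc + lam)) - censor_frac
    rc <- uniroot(f, c(1e-10, 1e4))$root
    cens <- rexp(n, rc)
    data.frame(x = x, time = pmin(t_ev, cens),
               event = as.integer(t_ev <= cens))
  } else {
    data.frame(x = x, time = t_ev, event = 1L)
  }
}
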