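## Independent oracles used across the test files.  These deliberately
## avoid the package's production code paths.

## pairwise TMRCA matrix at one site by tracing tip lineages through the
## raw event list (oracle for marginal_tree / count_distinct_trees)
oracle_pair_tmrca <- function(arg, site) {
  n <- arg$config$n_samples
  ev <- arg$events
  cur <- as.character(seq_len(n))        # current lineage id per tip
  tm <- matrix(NA_real_, n, n)
  for (i in seq_len(nrow(ev))) {
    if (ev$type[i] == "coal") {
      in1 <- cur == as.character(ev$child1[i])
      in2 <- cur == as.character(ev$child2[i])
      if (any(in1) && any(in2))
        tm[which(in1), which(in2)] <- tm[which(in2), which(in1)] <- ev$time[i]
      cur[in1 | in2] <- as.character(ev$parent1[i])
    } else {
      hit <- cur == as.character(ev$child1[i])
      cur[hit] <- as.character(
        if (site < ev$breakpoint[i]) ev$parent1[i] else ev$parent2[i])
    }
  }
  diag(tm) <- 0
  tm
}

## direct multinomial log-likelihood from pruning-oracle probabilities
oracle_loglik <- function(counts, t2, t3, topology) {
  p <- pruning_probs(t2, t3, topology)
  sum(ifelse(counts > 0, counts * log(p), 0))
}

## brute-force theta MLE: 200-point log grid plus golden-section polish
oracle_mle_theta <- function(counts, topology, lo = 1e-4, hi = 10) {
  lg <- seq(log(lo), log(hi), length.out = 200)
  v <- vapply(lg, function(l)
    marginal_loglik_theta(counts, exp(l), topology), numeric(1))
  i <- which.max(v)
  a <- lg[max(1, i - 1)]; b <- lg[min(200, i + 1)]
  gr <- (sqrt(5) - 1) / 2
  for (it in 1:60) {
    c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
    f1 <- marginal_loglik_theta(counts, exp(c1), topology)
    f2 <- marginal_loglik_theta(counts, exp(c2), topology)
    if (f1 < f2) a <- c1 else b <- c2
  }
  exp((a + b) / 2)
}

## Monte-Carlo estimate of the log marginal likelihood of theta:
## average the pattern likelihood over draws from the coalescent prior
oracle_mc_marginal <- function(counts, theta, topology, n = 1e5) {
  t3 <- rexp(n, 6 / theta)
  t2 <- t3 + rexp(n, 2 / theta)
  pr <- pattern_prob_row(topology, t2, t3)
  pos <- which(counts > 0)
  ll <- as.vector(log(pr[, pos, drop = FALSE]) %*% counts[pos])
  m <- max(ll)
  est <- m + log(mean(exp(ll - m)))
  w <- exp(ll - m)
  se <- sd(w) / (mean(w) * sqrt(n))      # delta-method SE of the log
  list(value = est, se = se)
}

## dense grid-search oracle for the joint (t2, t3) MLE
oracle_mle_times <- function(counts, topology, t2_max = 0.5, n_grid = 120) {
  t2g <- seq(1e-4, t2_max, length.out = n_grid)
  vg <- seq(0, 1, length.out = n_grid)
  best <- c(-Inf, NA, NA)
  for (t2 in t2g) {
    ll <- vapply(vg, function(v)
      loglik_patterns(counts, t2, v * t2, topology), numeric(1))
    i <- which.max(ll)
    if (ll[i] > best[1]) best <- c(ll[i], t2, vg[i] * t2)
  }
  list(loglik = best[1], t2 = best[2], t3 = best[3])
}

## all-pairs recount of incompatible site pairs (oracle for the scan)
oracle_fourgamete_count <- function(mat) {
  bi <- which(apply(mat, 2, function(col) length(unique(col))) == 2)
  cnt <- 0L
  for (ii in seq_along(bi)) for (jj in seq_along(bi)) {
    if (jj <= ii) next
    hap <- unique(paste(mat[, bi[ii]], mat[, bi[jj]]))
    if (length(hap) == 4) cnt <- cnt + 1L
  }
  cnt
}
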