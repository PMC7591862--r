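# Brute-force oracles, independent of the package implementations.

o_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

o_cosine_pos <- function(a, b) {
  a <- ifelse(a < 0, 0, a)
  b <- ifelse(b < 0, 0, b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

o_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

o_mad <- function(x) o_median(abs(x - o_median(x)))

# Normal-equation least squares for value = a + b s + c s^2.
o_quad_fit <- function(s, v) {
  X <- cbind(1, s, s^2)
  beta <- solve(t(X) %*% X, t(X) %*% v)
  res <- v - X %*% beta
  sst <- sum((v - mean(v))^2)
  list(coef = as.numeric(beta),
       r2 = if (sst > 0) 1 - sum(res^2) / sst else NA_real_,
       rmse = sqrt(mean(res^2)))
}

# Pair-counting AUC with half-credit for ties.
o_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive two-sample permutation p for the mean difference.
o_perm_p <- function(x, y, alternative) {
  pool <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pool), n1)
  stats_null <- apply(idx, 2, function(i) mean(pool[i]) - mean(pool[-i]))
  obs <- mean(x) - mean(y)
  b <- switch(alternative,
              greater = sum(stats_null >= obs),
              less = sum(stats_null <= obs),
              two.sided = sum(abs(stats_null) >= abs(obs)))
  b / ncol(idx)
}

o_mean_mats <- function(mats) {
  out <- mats[[1]] * 0
  for (m in mats) out <- out + m
  out / length(mats)
}

# Hand-rolled per-row positive cosine similarity of two square z-matrices
# with the self-entry dropped.
o_similarity <- function(A, B) {
  V <- nrow(A)
  vapply(seq_len(V), function(i) {
    o_cosine_pos(A[i, -i], B[i, -i])
  }, numeric(1))
}
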