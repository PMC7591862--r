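#' Two-sample permutation test
#'
#' Label-shuffling null for a two-sample statistic. When the number of
#' distinct group assignments `choose(n1+n2, n1)` is at most `n_perm` the
#' null is enumerated exhaustively and the p-value is the exact fraction of
#' assignments at least as extreme as the observed one (the identity
#' assignment included, so p is never 0). Otherwise `n_perm` random
#' assignments are drawn and `p = (b + 1) / (n_perm + 1)`.
#'
#' @param x,y Numeric samples (each nonempty).
#' @param statistic `"mean_diff"` (mean of `x` minus mean of `y`) or a
#'   function `f(x, y)`.
#' @param alternative `"greater"`, `"less"` or `"two.sided"` (two-sided
#'   compares absolute statistics).
#' @param n_perm Permutation budget (default 10000).
#' @param seed Seed for the sampled branch.
#' @return An object of class `fca_perm` with the observed statistic,
#'   p-value, exceedance count, and whether enumeration was exhaustive.
#' @export
two_sample_permutation <- function(x, y, statistic = "mean_diff",
                                   alternative = c("greater", "less", "two.sided"),
                                   n_perm = 10000L, seed = 1L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be nonempty", call. = FALSE)
  stat_fun <- if (is.function(statistic)) statistic else {
    if (!identical(statistic, "mean_diff")) {
      stop("unknown statistic: ", statistic, call. = FALSE)
    }
    function(a, b) mean(a) - mean(b)
  }
  pool <- c(x, y)
  n1 <- length(x); n <- length(pool)
  observed <- stat_fun(x, y)
  n_total <- choose(n, n1)
  exhaustive <- is.finite(n_total) && n_total <= n_perm
  if (exhaustive) {
    assignments <- utils::combn(n, n1)
    stats_null <- apply(assignments, 2, function(idx) {
      stat_fun(pool[idx], pool[-idx])
    })
  } else {
    stats_null <- with_local_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n, n1)
        stat_fun(pool[idx], pool[-idx])
      }, numeric(1))
    })
  }
  new_perm_result(observed, stats_null, alternative, exhaustive, seed)
}

fcanomaly_degenerate_perm <- function(observed, seed) {
  structure(list(observed = observed, n_perm = 0L, exceedances = 0L, p = 1,
                 alternative = "greater", exhaustive = TRUE,
                 seed = as.integer(seed)),
            class = "fca_perm")
}

new_perm_result <- function(observed, stats_null, alternative, exhaustive, seed) {
  b <- switch(alternative,
              greater = sum(stats_null >= observed),
              less = sum(stats_null <= observed),
              two.sided = sum(abs(stats_null) >= abs(observed)))
  m <- length(stats_null)
  p <- if (exhaustive) b / m else (b + 1) / (m + 1)
  structure(list(observed = observed, n_perm = m, exceedances = b, p = p,
                 alternative = alternative, exhaustive = exhaustive,
                 seed = as.integer(seed)),
            class = "fca_perm")
}

#' @export
print.fca_perm <- function(x, ...) {
  cat(sprintf("<fca_perm> stat = %.4g, p = %.4g (%s, %s, %d permutations)\n",
              x$observed, x$p, x$alternative,
              if (x$exhaustive) "exhaustive" else "sampled", x$n_perm))
  invisible(x)
}

#' @export
tidy.fca_perm <- function(x, ...) {
  tibble::tibble(statistic = x$observed, p.value = x$p,
                 n_perm = x$n_perm, exceedances = x$exceedances,
                 alternative = x$alternative, exhaustive = x$exhaustive,
                 seed = x$seed)
}

#' Paired sign-flip permutation test
#'
#' Permutation analogue of the paired t-test: under the null the signs of
#' the paired differences are exchangeable, so the mean difference is
#' compared against its sign-flipping distribution. Exhaustive over all
#' `2^n` flips when that is within `n_perm`.
#'
#' @param differences Numeric vector of paired differences with >= 2
#'   nonzero entries.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @param n_perm Permutation budget.
#' @param seed Seed for the sampled branch.
#' @return An `fca_perm`.
#' @export
paired_sign_flip_test <- function(differences,
                                  alternative = c("greater", "less", "two.sided"),
                                  n_perm = 10000L, seed = 1L) {
  alternative <- match.arg(alternative)
  d <- as.numeric(differences)
  if (sum(d != 0) < 2L) {
    stop("need at least 2 nonzero paired differences", call. = FALSE)
  }
  n <- length(d)
  observed <- mean(d)
  exhaustive <- n <= 30 && 2^n <= n_perm
  if (exhaustive) {
    flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stats_null <- as.vector(flips %*% d) / n
  } else {
    stats_null <- with_local_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        mean(d * sample(c(-1, 1), n, replace = TRUE))
      }, numeric(1))
    })
  }
  new_perm_result(observed, stats_null, alternative, exhaustive, seed)
}

#' Mann-Whitney AUC
#'
#' Area under the ROC curve of `scores` as a predictor of the positive
#' label, computed as the Mann-Whitney U statistic over `n1 * n0` pairs with
#' midrank tie handling: `AUC = (sum of positive ranks - n1(n1+1)/2) /
#' (n1 * n0)`.
#'
#' @param scores Numeric predictor values.
#' @param labels Logical (or 0/1) labels; both classes must be present.
#' @return The AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)   # midranks for ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up false discovery rate control at level `q`: rejects all hypotheses
#' whose BH-adjusted p-value is at most `q`.
#'
#' @param p_values Numeric p-values in `[0, 1]` (all finite).
#' @param q Target FDR level (default 0.05).
#' @return A tibble with columns `p`, `p_adjusted`, `reject`, in input
#'   order.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_adjusted = adj, reject = adj <= q)
}
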