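# Independent reference implementations used to cross-check the package.
# These are deliberately naive (explicit loops, no shared code with R/).

# all size-k multisets over `levels`, built by nested recursion
oracle_multisets <- function(levels, k) {
  if (k == 0L) return(matrix(numeric(0), nrow = 1L, ncol = 0L))
  out <- list()
  recurse <- function(prefix, start) {
    if (length(prefix) == k) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (i in start:length(levels)) recurse(c(prefix, levels[i]), i)
  }
  recurse(numeric(0), 1L)
  do.call(rbind, out)
}

# every multiset matching a printed mean/SE pair under half-ULP bands
oracle_reconstruct <- function(mean_printed, se_printed, n_reps = 3,
                               seeds_per_rep = 5) {
  cand <- oracle_multisets(seq(0, 100, by = 100 / seeds_per_rep), n_reps)
  hits <- list()
  for (r in seq_len(nrow(cand))) {
    v <- cand[r, ]
    m <- sum(v) / length(v)
    s <- sqrt(sum((v - m)^2) / (length(v) - 1)) / sqrt(length(v))
    if (abs(m - mean_printed) <= 0.05 && abs(s - se_printed) <= 0.005) {
      hits[[length(hits) + 1L]] <- v
    }
  }
  if (length(hits) == 0L) return(NULL)
  do.call(rbind, hits)
}

# two-loop Gaussian-kernel regression on pre-scaled inputs
oracle_grnn_predict <- function(x_train, y_train, x_query, sigma,
                                lo, range) {
  scale_row <- function(v) (v - lo) / range
  out <- numeric(nrow(x_query))
  for (q in seq_len(nrow(x_query))) {
    zq <- scale_row(x_query[q, ])
    num <- 0
    den <- 0
    for (i in seq_len(nrow(x_train))) {
      zi <- scale_row(x_train[i, ])
      w <- exp(-sum((zq - zi)^2) / (2 * sigma^2))
      num <- num + w * y_train[i]
      den <- den + w
    }
    out[q] <- num / den
  }
  out
}

# two-loop leave-one-out RMSE, scaler from the full training inputs
oracle_loo_rmse <- function(x, y, sigma) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  range <- ifelse(hi > lo, hi - lo, 1)
  err <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    p <- oracle_grnn_predict(x[-i, , drop = FALSE], y[-i],
                             x[i, , drop = FALSE], sigma, lo, range)
    err[i] <- p - y[i]
  }
  sqrt(mean(err^2))
}

# random replicate-style regression instance for property tests
random_grnn_instance <- function(n, p = 3) {
  x <- matrix(runif(n * p, 0, 10), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- runif(n, 0, 100)
  list(x = x, y = y)
}
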