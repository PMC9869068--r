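# fixture builders and independent brute-force oracles shared across tests

rand_ts <- function(T_ = 20, N = 4, seed = 1, tr = 3) {
  set.seed(seed)
  roi_ts(matrix(rnorm(T_ * N), T_, N), tr = tr)
}

# brute-force Pearson correlation from mean-centred dot products
bf_cor <- function(m) {
  n <- ncol(m)
  out <- diag(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    xi <- m[, i] - mean(m[, i]); xj <- m[, j] - mean(m[, j])
    out[i, j] <- out[j, i] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  out
}

# adjacency matrix helpers for graph tests
adj_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (e in edges) { a[e[1], e[2]] <- a[e[2], e[1]] <- 1L }
  dimnames(a) <- list(paste0("n", 1:n), paste0("n", 1:n))
  a
}

complete_adj <- function(n) {
  a <- matrix(1L, n, n) - diag(n)
  dimnames(a) <- list(paste0("n", 1:n), paste0("n", 1:n))
  a
}

er_adj <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1L, p)
  a <- a + t(a)
  dimnames(a) <- list(paste0("n", 1:n), paste0("n", 1:n))
  a
}

# strip class and all attributes except dim, for exact matrix comparisons
as_plain <- function(m) matrix(as.numeric(m), nrow(m))

# event raster wrapper for hand-built binary matrices
raster_from_binary <- function(m) {
  storage.mode(m) <- "integer"
  if (is.null(colnames(m))) colnames(m) <- sprintf("ROI%03d", seq_len(ncol(m)))
  structure(m, threshold_sigma = 1, mode = "point",
            class = c("event_raster", class(matrix())))
}

# correlation edge matrix from random data (valid pearson_r by construction)
rand_fc <- function(N = 6, T_ = 40, seed = 1) {
  pearson_fc(rand_ts(T_, N, seed))
}

# small identity-covariance null cohort
null_cohort <- function(n_per_group, n_rois = 10, seed = 1, T_ = 140) {
  cfg <- generator_config(n_per_group = n_per_group, n_rois = n_rois,
                          n_timepoints = T_, seed = seed)
  simulate_cohort(cfg, spec = block_spec(seq_len(n_rois), 0, 0))
}
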