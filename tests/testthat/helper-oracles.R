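## Independent oracles and fixture builders used across the test suite.
## These never call into the package's own solver/selection code paths.

l1_objective <- function(A, S, X, lambda) {
  0.5 * sum((A %*% S - X)^2) + lambda * sum(abs(S))
}

## Coordinate-descent solver for min 0.5||As - x||^2 + lambda||s||_1,
## run to a duality-gap certificate (gap < gap_tol guarantees the returned
## objective is within gap_tol of the optimum).
cd_lasso_oracle <- function(A, x, lambda, gap_tol = 1e-9, max_sweeps = 1e6) {
  M <- ncol(A)
  s <- numeric(M)
  d <- colSums(A^2)
  dual_gap <- function(s) {
    r <- as.vector(x - A %*% s)
    corr <- max(abs(crossprod(A, r)))
    sc <- if (corr > lambda) lambda / corr else 1
    nu <- sc * r
    primal <- 0.5 * sum(r^2) + lambda * sum(abs(s))
    dual <- 0.5 * sum(x^2) - 0.5 * sum((nu - x)^2)
    primal - dual
  }
  sweeps <- 0L
  repeat {
    for (it in 1:200) {
      for (j in 1:M) {
        r_j <- sum(A[, j] * (x - A %*% s)) + d[j] * s[j]
        s[j] <- sign(r_j) * max(abs(r_j) - lambda, 0) / d[j]
      }
    }
    sweeps <- sweeps + 200L
    if (dual_gap(s) < gap_tol || sweeps >= max_sweeps) break
  }
  s
}

## Exact non-negative lasso oracle for a 2-row A: active-set enumeration over
## supports of size <= 2 (rank(A) = 2 guarantees an optimal solution with at
## most two nonzeros); the best feasible stationary candidate is the optimum.
nn_lasso_oracle <- function(A, x, lambda) {
  M <- ncol(A)
  best_s <- numeric(M)
  best_obj <- 0.5 * sum(x^2)
  consider <- function(idx, vals) {
    if (any(vals < 0)) return()
    s <- numeric(M)
    s[idx] <- vals
    obj <- 0.5 * sum((A %*% s - x)^2) + lambda * sum(s)
    if (obj < best_obj) {
      best_obj <<- obj
      best_s <<- s
    }
  }
  for (j in 1:M)
    consider(j, max(0, (sum(A[, j] * x) - lambda)) / sum(A[, j]^2))
  if (M >= 2) {
    for (j in 1:(M - 1)) for (l in (j + 1):M) {
      G <- crossprod(A[, c(j, l)])
      if (abs(det(G)) < 1e-12) next
      rhs <- crossprod(A[, c(j, l)], x) - lambda
      consider(c(j, l), solve(G, rhs))
    }
  }
  list(s = best_s, objective = best_obj)
}

## Random 2 x M mixing matrix with unit-norm columns.
random_unit_mixing <- function(M) {
  A <- matrix(rnorm(2 * M), 2, M)
  sweep(A, 2, sqrt(colSums(A^2)), "/")
}

## Disjoint-support windowed-tone sources: n_sources blocks of block_len
## features, each holding a Hann-windowed sinusoid. The analytic signal of a
## windowed tone is nearly support-local, so in-block features of a mixture
## are single-component points.
tone_sources <- function(n_sources, block_len = 200, freqs = NULL) {
  K <- n_sources * block_len
  S <- matrix(0, n_sources, K)
  for (m in seq_len(n_sources)) {
    t <- seq_len(block_len)
    f <- if (is.null(freqs)) 5 + 4 * m else freqs[m]
    w <- 0.5 - 0.5 * cos(2 * pi * (t - 1) / (block_len - 1))
    S[m, (m - 1) * block_len + t] <- w * sin(2 * pi * f * t / block_len)
  }
  S
}

## Two-row mixture of tone sources at given mixing angles (degrees from the
## first-row axis). Returns rows, the true mixing matrix and sources.
tone_mixture <- function(angles_deg, block_len = 200, freqs = NULL) {
  S <- tone_sources(length(angles_deg), block_len, freqs)
  a <- angles_deg * pi / 180
  A <- rbind(cos(a), sin(a))
  list(rows = A %*% S, A = A, S = S, block_len = block_len)
}

## Brute-force max/min-angle selection rule, enumerated independently of
## select_components: returns the indices labelled disease and control.
selection_oracle <- function(angles, reference_role) {
  idx_max <- which(angles == max(angles))[1L]
  idx_min <- which(angles == min(angles))[1L]
  if (reference_role == "control") {
    list(disease = idx_max, control = idx_min)
  } else {
    list(disease = idx_min, control = idx_max)
  }
}
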