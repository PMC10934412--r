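# Independent oracles used to cross-check the analysis implementations.

# Eigendecomposition of a 3x3 symmetric matrix by brute force: eigenvalues
# as roots of the characteristic polynomial, eigenvectors from row cross
# products of (S - lambda I).  Deliberately avoids eigen()/svd().
eig3_oracle <- function(S) {
  stopifnot(nrow(S) == 3, ncol(S) == 3)
  tr <- sum(diag(S))
  minors <- det(S[2:3, 2:3]) + det(S[c(1, 3), c(1, 3)]) + det(S[1:2, 1:2])
  # det(S - x I) = -x^3 + tr x^2 - minors x + det(S)
  lam <- sort(Re(polyroot(c(det(S), -minors, tr, -1))), decreasing = TRUE)
  vecs <- sapply(lam, function(l) {
    M <- S - diag(l, 3)
    cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                              a[3] * b[1] - a[1] * b[3],
                              a[1] * b[2] - a[2] * b[1])
    cand <- list(cross(M[1, ], M[2, ]), cross(M[1, ], M[3, ]),
                 cross(M[2, ], M[3, ]))
    v <- cand[[which.max(vapply(cand, function(z) sum(z^2), 0))]]
    v <- v / sqrt(sum(v^2))
    i <- which.max(abs(v))
    if (v[i] < 0) -v else v
  })
  list(values = lam, vectors = vecs)
}

# Normal-equations OLS coefficients (intercept first).
normal_eq_coef <- function(X, y) {
  Xa <- cbind(1, as.matrix(X))
  as.numeric(solve(t(Xa) %*% Xa, t(Xa) %*% y))
}

# 1-D grid search for the through-origin proportionality constant,
# bracketing [k0/10, 10 k0] and refining to 1e-9 relative width.
grid_search_k <- function(d, u, k0) {
  sse <- function(k) sum((d - k * u)^2)
  lo <- k0 / 10; hi <- k0 * 10
  while ((hi - lo) / ((hi + lo) / 2) > 1e-9) {
    ks <- seq(lo, hi, length.out = 41)
    i <- which.min(vapply(ks, sse, 0))
    lo <- ks[max(1, i - 1)]; hi <- ks[min(length(ks), i + 1)]
  }
  (lo + hi) / 2
}

# Two-pass mean / sample sd.
mean_sd_oracle <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  list(mean = m, sd = sqrt(sum((v - m)^2) / (n - 1)))
}
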