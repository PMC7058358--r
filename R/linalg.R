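# Exact linear algebra over the integers.
#
# All structural quantities (kernels, ranks, minors, conservation laws) are
# computed in exact integer arithmetic: stoichiometric coefficients are small
# integers and fraction-free elimination with per-row gcd reduction keeps
# every intermediate value an exactly-representable integer. Floating point
# is confined to optimization and simulation.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

vec_gcd <- function(v) {
  g <- 0
  for (x in v) { g <- gcd2(g, x); if (g == 1) break }
  g
}

lcm2 <- function(a, b) if (a == 0 || b == 0) 0 else abs(a / gcd2(a, b) * b)

# Fraction-free Gauss-Jordan. Returns integer matrix R in reduced echelon
# form up to positive row scaling, pivot columns, and rank.
rref_int <- function(M) {
  M <- matrix(as.numeric(M), nrow = nrow(M))
  m <- nrow(M); n <- ncol(M)
  pivots <- integer(0)
  r <- 1L
  for (col in seq_len(n)) {
    if (r > m) break
    sub <- abs(M[r:m, col])
    nz <- which(sub > 0.5)
    if (!length(nz)) next
    # choose the smallest-magnitude nonzero to limit growth
    pr <- r - 1L + nz[which.min(sub[nz])]
    if (pr != r) M[c(r, pr), ] <- M[c(pr, r), ]
    if (M[r, col] < 0) M[r, ] <- -M[r, ]
    p <- M[r, col]
    for (i in seq_len(m)) {
      if (i != r && M[i, col] != 0) {
        M[i, ] <- M[i, ] * p - M[r, ] * M[i, col]
        g <- vec_gcd(M[i, ])
        if (g > 1) M[i, ] <- M[i, ] / g
      }
    }
    g <- vec_gcd(M[r, ])
    if (g > 1) M[r, ] <- M[r, ] / g
    pivots <- c(pivots, col)
    r <- r + 1L
  }
  list(R = M, pivots = pivots, rank = length(pivots))
}

int_rank <- function(M) {
  if (nrow(M) == 0L || ncol(M) == 0L) return(0L)
  rref_int(M)$rank
}

# Integer basis of ker(M) (columns of the returned matrix). Each basis
# vector has integer entries with gcd 1.
null_basis_int <- function(M) {
  n <- ncol(M)
  if (nrow(M) == 0L) return(diag(n))
  rr <- rref_int(M)
  piv <- rr$pivots
  free <- setdiff(seq_len(n), piv)
  if (!length(free)) return(matrix(0, n, 0))
  R <- rr$R
  L <- 1
  for (i in seq_along(piv)) L <- lcm2(L, R[i, piv[i]])
  out <- matrix(0, n, length(free))
  for (k in seq_along(free)) {
    f <- free[k]
    v <- numeric(n)
    v[f] <- L
    for (i in seq_along(piv)) v[piv[i]] <- -R[i, f] * (L / R[i, piv[i]])
    g <- vec_gcd(v)
    if (g > 1) v <- v / g
    out[, k] <- v
  }
  out
}

left_null_basis_int <- function(M) null_basis_int(t(M))

# Integer determinant by Bareiss fraction-free elimination (exact).
det_bareiss <- function(M) {
  n <- nrow(M)
  if (n == 0L) return(1)
  M <- matrix(as.numeric(M), n)
  sign <- 1
  prev <- 1
  for (k in seq_len(n - 1L)) {
    if (M[k, k] == 0) {
      sw <- which(M[(k + 1L):n, k] != 0)
      if (!length(sw)) return(0)
      i <- k + sw[1L]
      M[c(k, i), ] <- M[c(i, k), ]
      sign <- -sign
    }
    idx <- (k + 1L):n
    M[idx, idx] <- (M[idx, idx] * M[k, k] -
                      outer(M[idx, k], M[k, idx])) / prev
    M[idx, k] <- 0
    prev <- M[k, k]
  }
  sign * M[n, n]
}

# Integer basis of the column space: the pivot columns of M.
col_space_basis <- function(M) {
  rr <- rref_int(M)
  M[, rr$pivots, drop = FALSE]
}
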