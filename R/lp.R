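# Dense two-phase primal simplex with Bland's rule.
#
# Linear programming is the workhorse of every certificate construction in
# this package (region interiority, decrease certificates, flux bounds), so
# the solver must report "optimal" / "infeasible" / "unbounded" reliably on
# small, often degenerate problems with many redundant equality rows.
# Problems here have at most a few hundred variables, so a dense tableau
# is adequate.

.lp_tol <- 1e-9

# min c'x  s.t.  A x = b, x >= 0.  Returns list(status, x, value).
simplex_standard <- function(A, b, c, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {
    if (all(c >= -.lp_tol)) {
      return(list(status = "optimal", x = rep(0, n), value = 0))
    }
    return(list(status = "unbounded", x = NULL, value = -Inf))
  }
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  pivot <- function(Tb, basis, enter, leave_row) {
    piv <- Tb[leave_row, enter]
    Tb[leave_row, ] <- Tb[leave_row, ] / piv
    col <- Tb[, enter]
    col[leave_row] <- 0
    Tb <- Tb - outer(col, Tb[leave_row, ])
    basis[leave_row] <- enter
    list(Tb = Tb, basis = basis)
  }

  run_phase <- function(Tb, basis, cost) {
    # Tb: m x (ncol(cost)+1) tableau rows = B^{-1}[A | b]
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("simplex iteration limit reached")
      cb <- cost[basis]
      nb <- ncol(Tb) - 1L
      red <- cost - as.vector(crossprod(Tb[, seq_len(nb), drop = FALSE], cb))
      enter <- which(red < -.lp_tol)
      if (!length(enter)) {
        return(list(Tb = Tb, basis = basis, status = "optimal"))
      }
      enter <- enter[1L]  # Bland: smallest index
      colv <- Tb[, enter]
      ok <- which(colv > .lp_tol)
      if (!length(ok)) {
        return(list(Tb = Tb, basis = basis, status = "unbounded", enter = enter))
      }
      ratio <- Tb[ok, nb + 1L] / colv[ok]
      best <- min(ratio)
      cand <- ok[ratio <= best + .lp_tol]
      leave <- cand[which.min(basis[cand])]  # Bland tie-break
      res <- pivot(Tb, basis, enter, leave)
      Tb <- res$Tb; basis <- res$basis
    }
  }

  # Phase 1
  Tb <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  # price out artificial basis
  ph1 <- run_phase(Tb, basis, cost1)
  obj1 <- sum(ph1$Tb[, ncol(ph1$Tb)] * cost1[ph1$basis])
  if (obj1 > 1e-7) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  Tb <- ph1$Tb; basis <- ph1$basis
  # drive artificials out of the basis
  drop_rows <- integer(0)
  for (i in seq_len(m)) {
    if (basis[i] > n) {
      row <- Tb[i, seq_len(n)]
      j <- which(abs(row) > .lp_tol)
      if (length(j)) {
        res <- pivot(Tb, basis, j[1L], i)
        Tb <- res$Tb; basis <- res$basis
      } else {
        drop_rows <- c(drop_rows, i)  # redundant constraint
      }
    }
  }
  if (length(drop_rows)) {
    Tb <- Tb[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  Tb <- Tb[, c(seq_len(n), ncol(Tb)), drop = FALSE]

  # Phase 2
  ph2 <- run_phase(Tb, basis, c)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, value = -Inf))
  }
  x <- rep(0, n)
  x[ph2$basis] <- ph2$Tb[, n + 1L]
  list(status = "optimal", x = x, value = sum(c * x))
}

#' Solve a small linear program
#'
#' Minimizes (or maximizes) `obj %*% x` subject to `A_ub %*% x <= b_ub`,
#' `A_eq %*% x == b_eq` and box bounds `lower <= x <= upper`. Variables with
#' `lower = -Inf` are handled by sign splitting.
#'
#' @param obj objective coefficient vector.
#' @param A_ub,b_ub inequality constraints (`<=`), may be `NULL`.
#' @param A_eq,b_eq equality constraints, may be `NULL`.
#' @param lower,upper bounds, recycled over variables. Defaults `0`, `Inf`.
#' @param maximize maximize instead of minimize.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   solution `x`, and objective `value`.
#' @export
lp_solve <- function(obj, A_ub = NULL, b_ub = NULL, A_eq = NULL, b_eq = NULL,
                     lower = 0, upper = Inf, maximize = FALSE) {
  n <- length(obj)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  if (!is.null(A_ub)) A_ub <- matrix(A_ub, ncol = n)
  if (!is.null(A_eq)) A_eq <- matrix(A_eq, ncol = n)

  # x = shift + M %*% u with u >= 0
  cols <- list(); shift <- numeric(n); extra_ub <- list(); extra_b <- numeric(0)
  k <- 0L
  for (i in seq_len(n)) {
    if (is.finite(lower[i])) {
      shift[i] <- lower[i]
      k <- k + 1L
      cols[[length(cols) + 1L]] <- list(i = i, j = k, v = 1)
      if (is.finite(upper[i])) {
        extra_ub[[length(extra_ub) + 1L]] <- c(k, 1)
        extra_b <- c(extra_b, upper[i] - lower[i])
      }
    } else {
      # free (or upper-bounded) variable: x = u+ - u- (+ upper handled below)
      k <- k + 2L
      cols[[length(cols) + 1L]] <- list(i = i, j = k - 1L, v = 1)
      cols[[length(cols) + 1L]] <- list(i = i, j = k, v = -1)
      if (is.finite(upper[i])) {
        extra_ub[[length(extra_ub) + 1L]] <- c(k - 1L, 1)
        extra_b <- c(extra_b, upper[i])  # conservative: u+ <= upper
      }
    }
  }
  M <- matrix(0, n, k)
  for (cc in cols) M[cc$i, cc$j] <- cc$v

  tr <- function(A) A %*% M
  rhs_adj <- function(A, b) b - as.vector(A %*% shift)

  Aub <- NULL; bub <- NULL
  if (!is.null(A_ub)) { Aub <- tr(A_ub); bub <- rhs_adj(A_ub, b_ub) }
  if (length(extra_b)) {
    Ex <- matrix(0, length(extra_b), k)
    for (t in seq_along(extra_ub)) Ex[t, extra_ub[[t]][1L]] <- extra_ub[[t]][2L]
    Aub <- rbind(Aub, Ex); bub <- c(bub, extra_b)
  }
  Aeq <- NULL; beq <- NULL
  if (!is.null(A_eq)) { Aeq <- tr(A_eq); beq <- rhs_adj(A_eq, b_eq) }

  cu <- as.vector(crossprod(M, obj))
  if (maximize) cu <- -cu

  # assemble standard form: slacks for inequalities
  ns <- if (is.null(Aub)) 0L else nrow(Aub)
  A <- rbind(
    if (ns) cbind(Aub, diag(ns)),
    if (!is.null(Aeq)) cbind(Aeq, matrix(0, nrow(Aeq), ns))
  )
  b <- c(bub, beq)
  if (is.null(A)) {
    # only bounds: minimum at u = 0
    if (any(cu < -.lp_tol)) {
      return(list(status = "unbounded", x = NULL,
                  value = if (maximize) Inf else -Inf))
    }
    x <- shift
    return(list(status = "optimal", x = x, value = sum(obj * x)))
  }
  res <- simplex_standard(A, b, c(cu, rep(0, ns)))
  if (res$status != "optimal") {
    if (res$status == "unbounded" && maximize) res$value <- Inf
    return(res)
  }
  u <- res$x[seq_len(k)]
  x <- shift + as.vector(M %*% u)
  const <- sum(obj * shift)
  value <- sum(obj * x)
  list(status = "optimal", x = x, value = value)
}
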