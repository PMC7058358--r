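# Piecewise quadratic-in-rates RLFs via a copositive relaxation.
#
# On region W_k the candidate is V(r) = r'P_k r + 2 c_k' r. Exact copositive
# programming is NP-hard, so each copositivity requirement is relaxed into a
# positive semidefinite block plus an entrywise-nonnegative block:
#   (positivity)  [P_k, c_k; c_k', 0] >= [SH'(A1+A2)SH, SH'xi; xi'SH, 0]
#                 with A1 psd, A2 >= 0, xi >= 0          (SH = Sigma_k H)
#   (decrease)    [Q'P+PQ + SH'(B1+B2)SH, Q'c + SH'zeta; ., 0] <= 0
#                 with B1 psd, B2 >= 0, zeta >= 0, per extremal Q
#   (continuity)  P_k - P_j = lam h' + h lam', c_k - c_j = eta h across
#                 neighboring facets with normal h
#   (kernel)      P_k v = 0, c_k'v = 0 for v in ker Gamma.
# Whenever a facet-continuous PWL certificate with pieces c~_k exists,
# P_k = c~_k c~_k' (c_k = 0) is an explicit feasible point with certificate
# blocks in closed form; otherwise alternating projections between the
# affine set and the cone product search for a feasible point.

new_pwq <- function(Ps, cs, partition, extra = list()) {
  structure(c(list(Ps = Ps, cs = cs, partition = partition), extra),
            class = "crn_pwq")
}

#' @export
evaluate_rlf.crn_pwq <- function(rlf, r) {
  r <- as.matrix(r)
  part <- rlf$partition
  s <- part$H %*% r
  vapply(seq_len(ncol(r)), function(t) {
    sig <- sign(s[, t])
    for (k in seq_len(nrow(part$signatures))) {
      pos <- all(sig * part$signatures[k, ] >= 0)
      neg <- all(sig * part$signatures[k, ] <= 0)
      if (pos || neg) {
        q <- as.numeric(t(r[, t]) %*% rlf$Ps[[k]] %*% r[, t])
        lin <- 2 * sum(rlf$cs[[k]] * r[, t])
        return(q + if (pos) lin else -lin)
      }
    }
    NA_real_
  }, numeric(1))
}

#' @export
print.crn_pwq <- function(x, ...) {
  cat(sprintf("Piecewise quadratic-in-rates candidate over %d regions (%s)\n",
              length(x$Ps), x$seed %||% "unseeded"))
  invisible(x)
}

# neighbor pairs: kept signatures differing in exactly one index whose
# shared facet has relative interior
neighbor_pairs <- function(part, eps = 1e-6) {
  sigs <- part$signatures
  H <- part$H
  mk <- nrow(sigs); nu <- ncol(H)
  out <- list()
  if (mk < 2L) return(out)
  for (k in seq_len(mk - 1L)) for (j in (k + 1L):mk) {
    diffs <- which(sigs[k, ] != sigs[j, ])
    if (length(diffs) != 1L) next
    d <- diffs
    common <- setdiff(seq_len(nrow(H)), d)
    A <- -sigs[k, common] * H[common, , drop = FALSE]
    res <- lp_solve(rep(0, nu), A_ub = A, b_ub = rep(-eps, length(common)),
                    A_eq = H[d, , drop = FALSE], b_eq = 0,
                    lower = -1, upper = 1)
    if (res$status == "optimal") {
      out[[length(out) + 1L]] <- list(k = k, j = j, facet = d)
    }
  }
  out
}

#' Proposition-6 style piecewise quadratic certificate from a PWL one
#'
#' Given a regional PWL certificate with pieces `c_k` over partition `H`
#' (typically a sum-of-currents solution, whose pieces are automatically
#' continuous across facets), builds the explicit feasible point
#' `P_k = c_k c_k'` of the piecewise quadratic semidefinite relaxation,
#' together with its certificate blocks, and reports the worst constraint
#' residual.
#'
#' @param net a `crn_network`.
#' @param cand a regional `crn_pwl` over a partition with `H` containing
#'   every row of Gamma (the default partition qualifies).
#' @param tol residual tolerance.
#' @return a `crn_pwq` with `$status` `"ok"` or `"residuals_exceeded"`.
#' @export
pwq_from_pwl <- function(net, cand, tol = 1e-7) {
  if (!inherits(cand, "crn_pwl") || is.null(cand$partition)) {
    stop("needs a regional PWL candidate over a partition")
  }
  part <- cand$partition
  H <- part$H; sigs <- part$signatures
  ex <- extremals(net)
  p <- nrow(H); nu <- ncol(H)
  mk <- nrow(sigs)
  s <- nrow(ex$pairs)
  # map species rows of Gamma to rows of H
  hrow_of_species <- vapply(seq_len(n_species(net)), function(i) {
    g <- net$Gamma[i, ]
    for (q in seq_len(p)) if (all(H[q, ] == g)) return(q)
    NA_integer_
  }, integer(1))

  worst <- 0
  Ps <- vector("list", mk); cs <- vector("list", mk)
  B2s <- vector("list", mk)
  for (k in seq_len(mk)) {
    ck <- cand$C[k, ]
    Ps[[k]] <- outer(ck, ck)
    cs[[k]] <- rep(0, nu)
    SH <- sigs[k, ] * H
    # positivity multiplier: c_k = SH' xi with xi >= 0 (known exactly for
    # sum-of-currents candidates; otherwise from stored LP certificates,
    # with a projected-gradient fit as fallback)
    xi <- if (!is.null(cand$xi)) {
      as.numeric(cand$xi)
    } else if (!is.null(cand$certificate$xi)) {
      as.numeric(cand$certificate$xi[[k]])
    } else {
      qr_nonneg_fit(t(SH), ck)
    }
    worst <- max(worst, max(abs(crossprod(SH, xi) - ck)), -min(xi, 0))
    # decrease: c_k'Q_l = -lambda_l' SH with lambda_l >= 0, and
    # B2 = lambda xi' + xi lambda' certifies Q'P + PQ + SH'B2 SH = 0
    B2k <- vector("list", s)
    for (l in seq_len(s)) {
      jl <- ex$pairs[l, 1]; il <- ex$pairs[l, 2]
      hq <- hrow_of_species[il]
      if (is.na(hq)) stop("H must contain every row of Gamma for this construction")
      lam <- numeric(p)
      lam[hq] <- -ck[jl] * sigs[k, hq]
      worst <- max(worst, -min(lam, 0))
      B2 <- outer(lam, xi) + outer(xi, lam)
      # residual of the decrease identity
      M <- t(ex$Qs[[l]]) %*% Ps[[k]] + Ps[[k]] %*% ex$Qs[[l]] +
        t(SH) %*% B2 %*% SH
      worst <- max(worst, max(abs(M)))
      B2k[[l]] <- B2
    }
    B2s[[k]] <- B2k
  }
  # continuity across neighboring facets: P_k - P_j = lam h' + h lam'
  nbrs <- neighbor_pairs(part)
  for (nb in nbrs) {
    h <- H[nb$facet, ]
    ck <- cand$C[nb$k, ]; cj <- cand$C[nb$j, ]
    best <- Inf
    for (sg in c(1, -1)) {
      d <- ck - sg * cj
      alpha <- sum(d * h) / sum(h * h)
      best <- min(best, max(abs(d - alpha * h)))
    }
    worst <- max(worst, best)
    # with c_k - c_j = alpha h, lam = alpha c_j + alpha^2/2 h reproduces
    # P_k - P_j exactly; the residual above bounds the continuity defect
  }
  # kernel constraint
  kerG <- null_basis_int(net$Gamma)
  if (ncol(kerG)) {
    for (k in seq_len(mk)) worst <- max(worst, max(abs(Ps[[k]] %*% kerG)))
  }
  new_pwq(Ps, cs, part,
          extra = list(status = if (worst <= tol) "ok" else "residuals_exceeded",
                       residuals = list(max = worst),
                       seed = "pwl-certificate", B2 = B2s))
}

# nonnegative least squares fit of A x ~= b via projected refinement;
# exact when an exact nonnegative solution exists (our use case)
qr_nonneg_fit <- function(A, b, iters = 200L) {
  x <- rep(0, ncol(A))
  AtA <- crossprod(A); Atb <- crossprod(A, b)
  L <- max(eigen(AtA, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  for (t in seq_len(iters)) {
    x <- pmax(x - (AtA %*% x - Atb) / L, 0)
  }
  as.vector(x)
}

#' Construct a piecewise quadratic-in-rates RLF by semidefinite relaxation
#'
#' Tries the explicit Proposition-6 feasible point seeded by a
#' sum-of-currents certificate first; when none is available, solves the
#' semidefinite feasibility problem by alternating projections between the
#' affine constraints and the cone product (PSD blocks by eigenvalue
#' clipping, nonnegative blocks by entrywise clipping). Alternating
#' projections cannot prove infeasibility: a stall is reported as "no PWQ
#' certificate found under this relaxation".
#'
#' @param net a `crn_network`.
#' @param part a `crn_partition` (default `H = Gamma`).
#' @param pwl optional regional PWL certificate seeding the explicit point.
#' @param max_iter,tol alternating projection controls.
#' @param max_vars refuse assembling problems larger than this.
#' @return a `crn_pwq` (status `"ok"`) or a list with `status` `"stalled"`.
#' @export
construct_pwq_sdp <- function(net, part = NULL, pwl = NULL,
                              max_iter = 5000L, tol = 1e-7,
                              max_vars = 4000L) {
  if (is.null(part)) part <- build_partition(net)
  if (is.null(pwl)) {
    soc <- try(construct_soc(net, part), silent = TRUE)
    if (!inherits(soc, "try-error") && inherits(soc, "crn_pwl")) pwl <- soc
  }
  if (!is.null(pwl) && inherits(pwl, "crn_pwl") && !is.null(pwl$partition) &&
      isTRUE(all.equal(pwl$partition$H, part$H))) {
    cand <- pwq_from_pwl(net, pwl, tol = tol)
    if (identical(cand$status, "ok")) return(cand)
  }
  prob <- pwq_problem(net, part, max_vars = max_vars)
  z <- rep(0, prob$nvar)
  res <- NULL
  for (it in seq_len(max_iter)) {
    z <- prob$proj_affine(z)
    z <- prob$proj_cone(z)
    if (it %% 50L == 0L || it == max_iter) {
      res <- pwq_residuals(prob, z)
      if (res$affine < tol && res$cone < tol) {
        out <- pwq_extract(prob, z, part)
        out$residuals <- res
        out$seed <- "alternating-projections"; out$iterations <- it
        kc <- sampled_kernel_check(net, out, n_samples = 500L)
        out$status <- if (kc$pass) "ok" else "feasible_degenerate"
        return(out)
      }
    }
  }
  list(status = "stalled",
       reason = "no PWQ certificate found under this relaxation",
       residuals = res)
}

# ---- generic problem assembly ------------------------------------------

pwq_problem <- function(net, part, max_vars = 4000L) {
  H <- part$H; sigs <- part$signatures
  ex <- extremals(net)
  p <- nrow(H); nu <- ncol(H)
  mk <- nrow(sigs); s <- nrow(ex$pairs)
  kerG <- null_basis_int(net$Gamma)

  blocks <- list(); nvar <- 0L
  add_block <- function(name, q, type, square = TRUE) {
    size <- if (square) q * q else q
    idx <- nvar + seq_len(size)
    nvar <<- nvar + size
    blocks[[name]] <<- list(idx = idx, q = q, type = type, square = square)
    invisible(name)
  }
  for (k in seq_len(mk)) {
    add_block(paste0("P", k), nu, "sym")
    add_block(paste0("c", k), nu, "free", square = FALSE)
    add_block(paste0("A1_", k), p, "psd")
    add_block(paste0("A2_", k), p, "nonneg")
    add_block(paste0("xi", k), p, "nonneg", square = FALSE)
    add_block(paste0("zeta", k), p, "nonneg", square = FALSE)
    add_block(paste0("S", k), nu + 1L, "psd")
    for (l in seq_len(s)) {
      add_block(paste0("B1_", k, "_", l), p, "psd")
      add_block(paste0("B2_", k, "_", l), p, "nonneg")
      add_block(paste0("T", k, "_", l), nu + 1L, "psd")
    }
  }
  nbrs <- neighbor_pairs(part)
  for (t in seq_along(nbrs)) {
    add_block(paste0("lam", t), nu, "free", square = FALSE)
    add_block(paste0("eta", t), 1L, "free", square = FALSE)
  }
  if (nvar > max_vars) {
    stop(sprintf("PWQ problem has %d variables (cap %d); seed it with a PWL certificate",
                 nvar, max_vars))
  }

  rows <- list(); rhs <- numeric(0)
  add_row <- function(entries, b = 0) {
    # entries: list of c(index, coefficient)
    v <- numeric(nvar)
    for (e in entries) v[e[1]] <- v[e[1]] + e[2]
    rows[[length(rows) + 1L]] <<- v
    rhs <<- c(rhs, b)
  }
  bidx <- function(name, a, b = NULL) {
    bl <- blocks[[name]]
    if (is.null(b)) bl$idx[a] else bl$idx[(b - 1L) * bl$q + a]
  }

  for (k in seq_len(mk)) {
    SH <- sigs[k, ] * H
    # (23): P - SH'(A1+A2)SH - S_upper = 0 ; c - SH'xi - S_col = 0 ; S_corner = 0
    for (a in seq_len(nu)) for (b in a:nu) {
      entries <- list(c(bidx(paste0("P", k), a, b), 1),
                      c(bidx(paste0("S", k), a, b), -1))
      for (u in seq_len(p)) for (v in seq_len(p)) {
        co <- -SH[u, a] * SH[v, b]
        if (co != 0) {
          entries <- c(entries, list(c(bidx(paste0("A1_", k), u, v), co),
                                     c(bidx(paste0("A2_", k), u, v), co)))
        }
      }
      add_row(entries)
    }
    for (a in seq_len(nu)) {
      entries <- list(c(bidx(paste0("c", k), a), 1),
                      c(bidx(paste0("S", k), a, nu + 1L), -1))
      for (u in seq_len(p)) {
        if (SH[u, a] != 0) {
          entries <- c(entries, list(c(bidx(paste0("xi", k), u), -SH[u, a])))
        }
      }
      add_row(entries)
    }
    add_row(list(c(bidx(paste0("S", k), nu + 1L, nu + 1L), 1)))
    # (24) per extremal: Q'P + PQ + SH'(B1+B2)SH + T_upper = 0,
    #      Q'c + SH'zeta + T_col = 0, T_corner = 0
    for (l in seq_len(s)) {
      Q <- ex$Qs[[l]]
      for (a in seq_len(nu)) for (b in a:nu) {
        entries <- list(c(bidx(paste0("T", k, "_", l), a, b), 1))
        for (u in seq_len(nu)) {
          if (Q[u, a] != 0) entries <- c(entries, list(c(bidx(paste0("P", k), u, b), Q[u, a])))
          if (Q[u, b] != 0) entries <- c(entries, list(c(bidx(paste0("P", k), a, u), Q[u, b])))
        }
        for (u in seq_len(p)) for (v in seq_len(p)) {
          co <- SH[u, a] * SH[v, b]
          if (co != 0) {
            entries <- c(entries, list(c(bidx(paste0("B1_", k, "_", l), u, v), co),
                                       c(bidx(paste0("B2_", k, "_", l), u, v), co)))
          }
        }
        add_row(entries)
      }
      for (a in seq_len(nu)) {
        entries <- list(c(bidx(paste0("T", k, "_", l), a, nu + 1L), 1))
        for (u in seq_len(nu)) {
          if (Q[u, a] != 0) entries <- c(entries, list(c(bidx(paste0("c", k), u), Q[u, a])))
        }
        for (u in seq_len(p)) {
          if (SH[u, a] != 0) entries <- c(entries, list(c(bidx(paste0("zeta", k), u), SH[u, a])))
        }
        add_row(entries)
      }
      add_row(list(c(bidx(paste0("T", k, "_", l), nu + 1L, nu + 1L), 1)))
    }
    # (26): P v = 0, c'v = 0
    if (ncol(kerG)) {
      for (vv in seq_len(ncol(kerG))) {
        v <- kerG[, vv]
        for (a in seq_len(nu)) {
          entries <- list()
          for (b in seq_len(nu)) {
            if (v[b] != 0) entries <- c(entries, list(c(bidx(paste0("P", k), a, b), v[b])))
          }
          add_row(entries)
        }
        entries <- list()
        for (b in seq_len(nu)) {
          if (v[b] != 0) entries <- c(entries, list(c(bidx(paste0("c", k), b), v[b])))
        }
        add_row(entries)
      }
    }
  }
  # (25) continuity
  for (t in seq_along(nbrs)) {
    nb <- nbrs[[t]]
    h <- H[nb$facet, ]
    for (a in seq_len(nu)) for (b in a:nu) {
      add_row(list(c(bidx(paste0("P", nb$k), a, b), 1),
                   c(bidx(paste0("P", nb$j), a, b), -1),
                   c(bidx(paste0("lam", t), a), -h[b]),
                   c(bidx(paste0("lam", t), b), -h[a])))
    }
    for (a in seq_len(nu)) {
      add_row(list(c(bidx(paste0("c", nb$k), a), 1),
                   c(bidx(paste0("c", nb$j), a), -1),
                   c(bidx(paste0("eta", t), 1), -h[a])))
    }
  }

  # scale normalization: the feasibility problem is a cone (z = 0 is always
  # feasible), so pin the total trace of the P_k to a positive constant
  entries <- list()
  for (k in seq_len(mk)) {
    for (a in seq_len(nu)) entries <- c(entries, list(c(bidx(paste0("P", k), a, a), 1)))
  }
  add_row(entries, b = nu * mk)

  Amat <- do.call(rbind, rows)
  Aginv <- MASS::ginv(Amat)

  proj_affine <- function(z) z - Aginv %*% (Amat %*% z - rhs)
  proj_cone <- function(z) {
    z <- as.numeric(z)
    for (bl in blocks) {
      if (bl$type == "free") next
      if (!bl$square) {
        z[bl$idx] <- pmax(z[bl$idx], 0)
      } else {
        M <- matrix(z[bl$idx], bl$q)
        M <- (M + t(M)) / 2
        if (bl$type == "nonneg") {
          M[M < 0] <- 0
        } else if (bl$type == "sym") {
          # symmetrized above; nothing else to enforce
        } else if (bl$type == "psd") {
          e <- eigen(M, symmetric = TRUE)
          pos <- pmax(e$values, 0)
          M <- e$vectors %*% (pos * t(e$vectors))
        }
        z[bl$idx] <- as.vector(M)
      }
    }
    z
  }
  list(nvar = nvar, blocks = blocks, Amat = Amat, rhs = rhs,
       proj_affine = proj_affine, proj_cone = proj_cone,
       mk = mk, nu = nu)
}

pwq_residuals <- function(prob, z) {
  z <- as.numeric(z)
  affine <- max(abs(prob$Amat %*% z - prob$rhs))
  cone <- 0
  for (bl in prob$blocks) {
    if (bl$type == "free") next
    if (!bl$square) {
      cone <- max(cone, -min(z[bl$idx], 0))
    } else {
      M <- matrix(z[bl$idx], bl$q)
      sym_defect <- max(abs(M - t(M)))
      M <- (M + t(M)) / 2
      if (bl$type == "sym") {
        cone <- max(cone, sym_defect)
      } else if (bl$type == "nonneg") {
        cone <- max(cone, -min(M, 0), sym_defect)
      } else {
        ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
        cone <- max(cone, -min(ev, 0), sym_defect)
      }
    }
  }
  list(affine = affine, cone = cone)
}

pwq_extract <- function(prob, z, part) {
  z <- as.numeric(z)
  Ps <- vector("list", prob$mk); cs <- vector("list", prob$mk)
  for (k in seq_len(prob$mk)) {
    M <- matrix(z[prob$blocks[[paste0("P", k)]]$idx], prob$nu)
    Ps[[k]] <- (M + t(M)) / 2
    cs[[k]] <- z[prob$blocks[[paste0("c", k)]]$idx]
  }
  new_pwq(Ps, cs, part)
}
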