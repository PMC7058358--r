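# Linear-programming construction and verification of PWL RLFs.

# kernel compatibility: ker C == ker Gamma
kernel_match <- function(C, net, tol = 1e-8) {
  kerG <- null_basis_int(net$Gamma)
  if (ncol(kerG) && max(abs(C %*% kerG)) > tol) return(FALSE)
  qr(C)$rank == int_rank(net$Gamma)
}

#' Verify a candidate rate-dependent PWL Lyapunov function
#'
#' Checking a PWL candidate is a finite family of linear programs: for every
#' region of the candidate and every extremal `Q_l`, maximize the directional
#' derivative `c_k' Q_l r` over the region intersected with the unit box. The
#' candidate is an RLF iff every such optimum is (numerically) nonpositive
#' and `ker C = ker Gamma`.
#'
#' @param net a `crn_network`.
#' @param cand a `crn_pwl` (regional or convex) or `crn_maxmin` candidate.
#' @param tol violation tolerance on LP optima.
#' @return list with `pass` (logical), `reason`, `max_violation` and, on
#'   failure, `witness = list(k, l, r)`.
#' @export
verify_pwl <- function(net, cand, tol = 1e-8) {
  ex <- extremals(net)
  rows <- convex_rows(cand)
  nu <- n_reactions(net)

  if (!kernel_match(rows, net)) {
    return(list(pass = FALSE, reason = "kernel mismatch",
                max_violation = NA_real_, witness = NULL))
  }

  regional <- inherits(cand, "crn_pwl") && !cand$convex &&
    !is.null(cand$partition)
  worst <- -Inf; witness <- NULL

  if (regional) {
    part <- cand$partition
    # continuity of V(r) = |c_k' r| across every shared facet: on the facet
    # with normal h the difference of the adjoining pieces must be a
    # multiple of h (up to the sign pairing of the +-regions); a regionally
    # decreasing but discontinuous function is not a Lyapunov function
    for (nb in neighbor_pairs(part)) {
      h <- part$H[nb$facet, ]
      defect <- Inf
      for (sg in c(1, -1)) {
        d <- cand$C[nb$k, ] - sg * cand$C[nb$j, ]
        al <- sum(d * h) / sum(h * h)
        defect <- min(defect, max(abs(d - al * h)))
      }
      if (defect > tol * 10) {
        return(list(pass = FALSE, reason = "discontinuous across facet",
                    max_violation = defect,
                    witness = list(k = nb$k, l = NA, r = NULL,
                                   neighbor = nb$j, facet = nb$facet)))
      }
    }
    for (k in seq_len(nrow(part$signatures))) {
      Ar <- -part$signatures[k, ] * part$H       # region: -Sig H r <= 0
      ck <- cand$C[k, ]
      # V = |c_k' r| on the region: check decrease of +c_k where the piece
      # is nonnegative and of -c_k where it is nonpositive (the piece need
      # not be single-signed on its region)
      for (l in seq_along(ex$Qs)) {
        obj <- as.vector(ck %*% ex$Qs[[l]])
        if (all(obj == 0)) next
        for (sg in c(1, -1)) {
          res <- lp_solve(sg * obj,
                          A_ub = rbind(Ar, -sg * ck),
                          b_ub = rep(0, nrow(Ar) + 1L),
                          lower = -1, upper = 1, maximize = TRUE)
          if (res$status != "optimal") next
          if (res$value > worst) { worst <- res$value; witness <- list(k = k, l = l, r = res$x) }
          if (res$value > tol) {
            return(list(pass = FALSE, reason = "decrease violated",
                        max_violation = res$value, witness = witness))
          }
        }
      }
    }
  } else {
    # convex max form: piece k is active on {c_k' r >= c_j' r, c_k' r >= 0}
    m <- nrow(rows)
    for (k in seq_len(m)) {
      ck <- rows[k, ]
      Ar <- rbind(
        matrix(rows[-k, , drop = FALSE], ncol = nu) -
          matrix(ck, m - 1L, nu, byrow = TRUE),  # (c_j - c_k)' r <= 0
        -ck                                       # c_k' r >= 0
      )
      for (l in seq_along(ex$Qs)) {
        obj <- as.vector(ck %*% ex$Qs[[l]])
        if (all(obj == 0)) next
        res <- lp_solve(obj, A_ub = Ar, b_ub = rep(0, nrow(Ar)),
                        lower = -1, upper = 1, maximize = TRUE)
        if (res$status != "optimal") next
        if (res$value > worst) { worst <- res$value; witness <- list(k = k, l = l, r = res$x) }
        if (res$value > tol) {
          return(list(pass = FALSE, reason = "decrease violated",
                      max_violation = res$value, witness = witness))
        }
      }
    }
    # the zero level set of the max form must be exactly ker Gamma:
    # on {C r <= 0} every piece must vanish identically
    for (k in seq_len(m)) {
      res <- lp_solve(rows[k, ], A_ub = rows, b_ub = rep(0, m),
                      lower = -1, upper = 1, maximize = FALSE)
      if (res$status == "optimal" && res$value < -tol) {
        return(list(pass = FALSE, reason = "kernel mismatch",
                    max_violation = -res$value,
                    witness = list(k = k, l = NA, r = res$x)))
      }
    }
  }
  list(pass = TRUE, reason = "verified", max_violation = max(worst, 0),
       witness = NULL)
}

#' Construct a PWL RLF over a partition by linear programming
#'
#' Over each kept region `W_k` the construction searches for
#' `c_k' = xi_k' Sigma_k H` with `xi_k >= 0`, `1'xi_k = 1` (positivity of
#' the piece on its region) such that every extremal direction certifies
#' decrease through a Farkas multiplier:
#' `c_k' Q_l = -lambda_kl' Sigma_k H` with `lambda_kl >= 0`. Continuity on
#' the steady-state set holds automatically because `ker H = ker Gamma`.
#' With `force_convex`, region maximality `c_k - c_j = Sigma_k H' mu` with
#' `mu >= 0` couples the regions into a single program.
#'
#' @param net a `crn_network`.
#' @param part a `crn_partition` (default: partition of `H = Gamma`).
#' @param force_convex require the regional pieces to form a convex max.
#' @return on success a `crn_pwl` with certificate multipliers in
#'   `$certificate`; on failure a list with `status = "infeasible"` (meaning
#'   no PWL RLF exists over this `H`; other partitions may still work).
#' @export
construct_pwl_lp <- function(net, part = NULL, force_convex = FALSE) {
  if (is.null(part)) part <- build_partition(net)
  cons <- conservation_analysis(net)
  as1 <- !is.null(cons$positive_flux)
  ex <- extremals(net)
  H <- part$H
  p <- nrow(H); nu <- ncol(H)
  sigs <- part$signatures
  mk <- nrow(sigs)
  s <- nrow(ex$pairs)

  if (!force_convex) {
    # regions decouple into one small LP each.  Assemble the equality system
    # of a region once; run a cheap feasibility-only sweep first so that
    # infeasibility (the common negative result) is detected without the
    # vertex-averaging work, then re-solve feasible regions under a fan of
    # objectives and average the vertices (the feasible set is convex, so
    # the average is still certified and is generically full-rank).
    region_system <- function(k) {
      SH <- sigs[k, ] * H
      nv <- p * (1L + s)                        # xi_k, lambda_k1..lambda_ks
      A_eq <- matrix(0, nu * s + 1L, nv)
      b_eq <- numeric(nu * s + 1L)
      for (l in seq_len(s)) {
        jl <- ex$pairs[l, 1]; il <- ex$pairs[l, 2]
        rows_idx <- (l - 1L) * nu + seq_len(nu)
        # gamma_il * (SH e_jl)' xi  + SH' lambda_l = 0
        A_eq[rows_idx, seq_len(p)] <- outer(net$Gamma[il, ], SH[, jl])
        A_eq[rows_idx, p * l + seq_len(p)] <- t(SH)
      }
      A_eq[nu * s + 1L, seq_len(p)] <- 1        # normalization 1'xi = 1
      b_eq[nu * s + 1L] <- 1
      list(SH = SH, A_eq = A_eq, b_eq = b_eq, nv = nv)
    }
    systems <- lapply(seq_len(mk), region_system)
    for (k in seq_len(mk)) {
      sy <- systems[[k]]
      res <- lp_solve(rep(0, sy$nv), A_eq = sy$A_eq, b_eq = sy$b_eq,
                      lower = 0)
      if (res$status != "optimal") {
        return(list(status = "infeasible",
                    reason = sprintf("no PWL RLF over this H (region %d)", k),
                    region = k, as1 = as1))
      }
    }
    # interior point of each region (Chebyshev-style margin LP): the
    # objective fan below prefers pieces that are large at the region's own
    # center, which avoids rank-deficient solutions
    centers <- lapply(seq_len(mk), function(k) {
      SH <- systems[[k]]$SH
      ip <- lp_solve(c(rep(0, nu), -1),
                     A_ub = cbind(-SH, 1),
                     b_ub = rep(0, nrow(SH)),
                     lower = c(rep(-1, nu), 0), upper = c(rep(1, nu), 1))
      if (ip$status == "optimal") ip$x[seq_len(nu)] else rep(0, nu)
    })
    nbrs <- neighbor_pairs(part)
    blk <- p * (1L + s)                     # per-region variable block
    nv <- mk * blk + length(nbrs)           # + one free eta per facet
    A_eq <- matrix(0, 0, nv); b_eq <- numeric(0)
    for (k in seq_len(mk)) {
      sy <- systems[[k]]
      Ak <- matrix(0, nrow(sy$A_eq), nv)
      Ak[, (k - 1L) * blk + seq_len(blk)] <- sy$A_eq
      A_eq <- rbind(A_eq, Ak); b_eq <- c(b_eq, sy$b_eq)
    }
    # continuity of the piecewise function across every shared facet:
    # c_k - c_j must be a multiple of the facet normal h
    for (t in seq_along(nbrs)) {
      nb <- nbrs[[t]]
      h <- H[nb$facet, ]
      Ak <- matrix(0, nu, nv)
      Ak[, (nb$k - 1L) * blk + seq_len(p)] <- t(systems[[nb$k]]$SH)
      Ak[, (nb$j - 1L) * blk + seq_len(p)] <- -t(systems[[nb$j]]$SH)
      Ak[, mk * blk + t] <- -h
      A_eq <- rbind(A_eq, Ak); b_eq <- c(b_eq, rep(0, nu))
    }
    lower <- c(rep(0, mk * blk), rep(-Inf, length(nbrs)))
    # objective fan + averaging (the feasible set is convex, so the average
    # of optimal vertices is still feasible and generically full-rank)
    dirfan <- cbind(1, vapply(1:3, function(t) sin(7 * t * seq_len(nu)),
                              numeric(nu)))
    sols <- list()
    C_of <- function(x) {
      t(vapply(seq_len(mk), function(k)
        as.vector(crossprod(systems[[k]]$SH, x[(k - 1L) * blk + seq_len(p)])),
        numeric(nu)))
    }
    for (d_i in seq_len(ncol(dirfan))) {
      obj <- numeric(nv)
      for (k in seq_len(mk)) {
        dir_k <- if (d_i == 1L) centers[[k]] else dirfan[, d_i]
        obj[(k - 1L) * blk + seq_len(p)] <- as.vector(systems[[k]]$SH %*% dir_k)
      }
      res <- lp_solve(obj, A_eq = A_eq, b_eq = b_eq, lower = lower,
                      maximize = TRUE)
      if (res$status == "optimal") sols[[length(sols) + 1L]] <- res$x
      if (d_i == 1L && res$status != "optimal") {
        return(list(status = "infeasible",
                    reason = "no continuous PWL RLF over this H",
                    as1 = as1))
      }
      # stop early once the averaged solution is already full-rank
      if (length(sols) &&
          kernel_match(C_of(Reduce(`+`, sols) / length(sols)), net)) break
    }
    xbar <- Reduce(`+`, sols) / length(sols)
    Cw <- matrix(0, mk, nu)
    xis <- vector("list", mk); lams <- vector("list", mk)
    for (k in seq_len(mk)) {
      xis[[k]] <- xbar[(k - 1L) * blk + seq_len(p)]
      lams[[k]] <- matrix(xbar[(k - 1L) * blk + p + seq_len(p * s)], nrow = p)
      Cw[k, ] <- as.vector(crossprod(systems[[k]]$SH, xis[[k]]))
    }
    C <- Cw
  } else {
    if (mk > 40L) stop("convex coupling limited to 40 regions")
    # joint LP: xi_k (p per region), lambda_kl (p per region x extremal),
    # mu_k,j,sign (p per ordered region pair and sign of c_j)
    nxi <- p * mk
    nlam <- p * mk * s
    targets <- list()
    for (k in seq_len(mk)) for (j in seq_len(mk)) for (sg in c(1, -1)) {
      if (j == k && sg == 1) next
      targets[[length(targets) + 1L]] <- c(k, j, sg)
    }
    nmu <- p * length(targets)
    nv <- nxi + nlam + nmu
    Aeq <- list(); beq <- numeric(0)
    add_eq <- function(A, b) { Aeq[[length(Aeq) + 1L]] <<- A; beq <<- c(beq, b) }
    SHs <- lapply(seq_len(mk), function(k) sigs[k, ] * H)
    for (k in seq_len(mk)) {
      SH <- SHs[[k]]
      for (l in seq_len(s)) {
        jl <- ex$pairs[l, 1]; il <- ex$pairs[l, 2]
        A <- matrix(0, nu, nv)
        A[, p * (k - 1L) + seq_len(p)] <- outer(net$Gamma[il, ], SH[, jl])
        A[, nxi + p * ((k - 1L) * s + l - 1L) + seq_len(p)] <- t(SH)
        add_eq(A, rep(0, nu))
      }
      A <- matrix(0, 1L, nv); A[1, p * (k - 1L) + seq_len(p)] <- 1
      add_eq(A, 1)
    }
    for (t in seq_along(targets)) {
      k <- targets[[t]][1]; j <- targets[[t]][2]; sg <- targets[[t]][3]
      # c_k - sg*c_j = SH_k' mu,  mu >= 0
      A <- matrix(0, nu, nv)
      A[, p * (k - 1L) + seq_len(p)] <- t(SHs[[k]])
      A[, p * (j - 1L) + seq_len(p)] <-
        A[, p * (j - 1L) + seq_len(p)] - sg * t(SHs[[j]])
      A[, nxi + nlam + p * (t - 1L) + seq_len(p)] <- -t(SHs[[k]])
      add_eq(A, rep(0, nu))
    }
    res <- lp_solve(rep(0, nv), A_eq = do.call(rbind, Aeq), b_eq = beq,
                    lower = 0)
    if (res$status != "optimal") {
      return(list(status = "infeasible",
                  reason = "no convex PWL RLF over this H", as1 = as1))
    }
    xis <- lapply(seq_len(mk), function(k) res$x[p * (k - 1L) + seq_len(p)])
    lams <- NULL
    C <- t(vapply(seq_len(mk),
                  function(k) as.vector(crossprod(SHs[[k]], xis[[k]])),
                  numeric(nu)))
  }

  degenerate <- !kernel_match(C, net)
  cand <- new_pwl_candidate(C, part, convex = force_convex,
                            method = if (as1) "lp" else "lp-as1-fallback",
                            extra = list(certificate = list(xi = xis,
                                                            lambda = lams),
                                         as1 = as1,
                                         degenerate = degenerate))
  if (degenerate) {
    cand$status <- "feasible_degenerate"
  } else {
    cand$status <- "ok"
  }
  cand
}

#' Construct a sum-of-currents (SoC) RLF
#'
#' Searches for positive species weights `xi` such that
#' `V(x) = sum_i xi_i |xdot_i| = ||diag(xi) Gamma R(x)||_1` is an RLF. On
#' the region with current signature `sigma`, decrease along the extremal
#' for the pair (reaction j, reactant i) reduces to the linear constraint
#' `sigma_i * sum_i' sigma_i' xi_i' Gamma_i'j <= 0`, so the weights are
#' found by one LP over all regions with nonempty interior (weights
#' normalized to `xi >= 1`, sum minimized, then scaled to small integers
#' when possible).
#'
#' @param net a `crn_network`.
#' @param part optional pre-built partition of `H = Gamma`.
#' @return a `crn_pwl` with `$xi`, or `list(status = "infeasible")`.
#' @export
construct_soc <- function(net, part = NULL) {
  if (is.null(part)) part <- build_partition(net)
  if (!identical(dim(part$H), dim(net$Gamma)) ||
      max(abs(part$H - net$Gamma)) > 0) {
    stop("the SoC construction requires the default partition H = Gamma")
  }
  G <- net$Gamma
  n <- nrow(G)
  ex <- extremals(net)
  sigs <- part$signatures
  rows <- list()
  for (k in seq_len(nrow(sigs))) {
    sg <- sigs[k, ]
    for (l in seq_len(nrow(ex$pairs))) {
      jl <- ex$pairs[l, 1]; il <- ex$pairs[l, 2]
      rows[[length(rows) + 1L]] <- sg[il] * (sg * G[, jl])
    }
  }
  A <- do.call(rbind, rows)
  # constraints repeat heavily across regions: deduplicate (and drop zero
  # rows) before solving
  A <- unique(A)
  A <- A[rowSums(abs(A)) > 0, , drop = FALSE]
  res <- lp_solve(rep(1, n), A_ub = A, b_ub = rep(0, nrow(A)), lower = 1)
  if (res$status != "optimal") {
    return(list(status = "infeasible", reason = "no SoC RLF"))
  }
  xi <- rationalize_vector(res$x)
  # on region k the active piece is c_k = Gamma' (sigma_k * xi)
  C <- t(vapply(seq_len(nrow(sigs)),
                function(k) as.vector(crossprod(G, sigs[k, ] * xi)),
                numeric(ncol(G))))
  cand <- new_pwl_candidate(C, part, convex = FALSE, method = "soc", xi = xi)
  cand$status <- "ok"
  cand
}

# scale a rational-looking LP vertex to small integers when possible
rationalize_vector <- function(x, max_den = 64L, tol = 1e-7) {
  for (d in seq_len(max_den)) {
    y <- x * d
    if (max(abs(y - round(y))) < tol * d) {
      y <- round(y)
      g <- vec_gcd(y)
      if (g > 1) y <- y / g
      return(y)
    }
  }
  x
}
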