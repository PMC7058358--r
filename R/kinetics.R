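# Admissible kinetics, ODE simulation, and numerical Lyapunov validation.

#' Attach admissible kinetics to a network
#'
#' Builds an evaluable rate map `R(x)` satisfying the admissibility
#' assumptions: each rate depends only on its reactants, vanishes when a
#' reactant is absent, and is strictly increasing in each reactant at
#' positive concentrations. Supported laws (per reaction or for all
#' reactions at once):
#' * `mass_action`: `R_j = k_j prod_i x_i^alpha_ij`;
#' * `michaelis_menten`: `R_j = k_j prod_i (x_i / (Km + x_i))^alpha_ij`;
#' * `hill`: `R_j = k_j prod_i (x_i^h / (Km^h + x_i^h))^alpha_ij`, `h >= 1`.
#'
#' @param net a `crn_network`.
#' @param law law tag recycled over reactions, or a character vector of
#'   length `nu`.
#' @param k positive kinetic constants (recycled).
#' @param Km half-saturation constants for the saturating laws (recycled).
#' @param hill Hill coefficients, `>= 1` (recycled).
#' @return object of class `crn_kinetics` with `$rate(x)` and `$rho(x)`
#'   (the pairwise derivative weights `dR_j/dx_i` in extremal order).
#' @export
make_kinetics <- function(net, law = "mass_action", k = 1, Km = 1, hill = 2) {
  nu <- n_reactions(net)
  law <- rep_len(law, nu)
  k <- rep_len(k, nu); Km <- rep_len(Km, nu); hill <- rep_len(hill, nu)
  if (any(k <= 0)) stop("kinetic constants must be positive")
  if (any(!law %in% c("mass_action", "michaelis_menten", "hill"))) {
    stop("unknown rate law")
  }
  if (any(law == "hill" & hill < 1)) stop("Hill coefficients must be >= 1")
  A <- net$A
  ex <- extremals(net)

  rate <- function(x) {
    x <- pmax(x, 0)
    out <- numeric(nu)
    for (j in seq_len(nu)) {
      ri <- which(A[, j] > 0)
      f <- 1
      for (i in ri) {
        a <- A[i, j]
        f <- f * switch(law[j],
          mass_action = x[i]^a,
          michaelis_menten = (x[i] / (Km[j] + x[i]))^a,
          hill = (x[i]^hill[j] / (Km[j]^hill[j] + x[i]^hill[j]))^a)
      }
      out[j] <- k[j] * f
    }
    out
  }
  # analytic pair weights rho_l = dR_jl / dx_il
  rho <- function(x) {
    x <- pmax(x, 0)
    r <- rate(x)
    vapply(seq_len(nrow(ex$pairs)), function(l) {
      j <- ex$pairs[l, 1]; i <- ex$pairs[l, 2]; a <- A[i, j]
      xi <- x[i]
      # d/dx of the i-factor over the i-factor, times R_j
      switch(law[j],
        mass_action = if (xi > 0) r[j] * a / xi else {
          if (a == 1) {
            others <- setdiff(which(A[, j] > 0), i)
            k[j] * prod(x[others]^A[others, j])
          } else 0
        },
        michaelis_menten = {
          f <- xi / (Km[j] + xi)
          df <- Km[j] / (Km[j] + xi)^2
          if (xi > 0) r[j] * a * df / f else {
            if (a == 1) {
              others <- setdiff(which(A[, j] > 0), i)
              fo <- prod((x[others] / (Km[j] + x[others]))^A[others, j])
              k[j] * fo * df
            } else 0
          }
        },
        hill = {
          h <- hill[j]
          f <- xi^h / (Km[j]^h + xi^h)
          df <- h * Km[j]^h * xi^(h - 1) / (Km[j]^h + xi^h)^2
          if (xi > 0 && f > 0) r[j] * a * df / f else {
            if (a == 1 && h == 1) {
              others <- setdiff(which(A[, j] > 0), i)
              fo <- prod((x[others]^h / (Km[j]^h + x[others]^h))^A[others, j])
              k[j] * fo * df
            } else 0
          }
        })
    }, numeric(1))
  }

  structure(list(rate = rate, rho = rho, law = law, k = k, Km = Km,
                 hill = hill, net = net, pairs = ex$pairs),
            class = "crn_kinetics")
}

#' Simulate network dynamics
#'
#' Integrates `xdot = Gamma R(x)` with a stiff-capable solver and monitors
#' nonnegativity and conservation drift.
#'
#' @param net a `crn_network`.
#' @param kin a `crn_kinetics`.
#' @param x0 nonnegative initial concentrations.
#' @param horizon final time.
#' @param n_out number of output points.
#' @return object of class `crn_trajectory`: `time`, `x` (rows = time
#'   points), `R` (fluxes), `diagnostics`.
#' @export
simulate_network <- function(net, kin, x0, horizon = 100, n_out = 400L) {
  stopifnot(all(x0 >= 0), length(x0) == n_species(net))
  G <- net$Gamma
  f <- function(t, x, parms) list(as.vector(G %*% kin$rate(x)))
  times <- seq(0, horizon, length.out = n_out)
  sol <- deSolve::ode(y = as.numeric(x0), times = times, func = f,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-10)
  xm <- unname(sol[, -1, drop = FALSE])
  neg <- min(xm)
  xm[xm < 0] <- 0
  Rm <- t(apply(xm, 1L, kin$rate))
  if (ncol(G) == 1L) Rm <- matrix(Rm, ncol = 1L)
  laws <- left_null_basis_int(G)
  drift <- if (ncol(laws)) {
    q <- xm %*% laws
    max(abs(sweep(q, 2L, q[1, ]))) / max(1, max(abs(q[1, ])))
  } else 0
  structure(list(time = times, x = xm, R = Rm,
                 diagnostics = list(min_state = neg,
                                    conservation_drift = drift)),
            class = "crn_trajectory")
}

#' Steady state within a stoichiometric class
#'
#' Solves `Gamma R(x) = 0` jointly with the conservation constraints of the
#' class, warm-started from a simulation.
#'
#' @param net a `crn_network`.
#' @param kin a `crn_kinetics`.
#' @param x0 an initial condition identifying the stoichiometric class.
#' @param horizon warm-start simulation horizon.
#' @return list with `x_e`, `residual` (`max |Gamma R(x_e)|`),
#'   `class_values` (conserved quantities) and `converged`.
#' @export
steady_state <- function(net, kin, x0, horizon = 1000) {
  G <- net$Gamma
  laws <- left_null_basis_int(G)
  totals <- if (ncol(laws)) as.vector(t(laws) %*% x0) else numeric(0)
  traj <- simulate_network(net, kin, x0, horizon = horizon, n_out = 200L)
  xw <- traj$x[nrow(traj$x), ]
  fn <- function(x) {
    c(as.vector(G %*% kin$rate(x)),
      if (ncol(laws)) as.vector(t(laws) %*% x) - totals)
  }
  fit <- minpack.lm::nls.lm(par = xw, fn = fn,
                            lower = rep(0, length(xw)),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  x_e <- as.numeric(fit$par)
  residual <- max(abs(G %*% kin$rate(x_e)))
  list(x_e = stats::setNames(x_e, net$species), residual = residual,
       class_values = totals, converged = residual <= 1e-10)
}

#' Dini decrease check of a candidate along a trajectory
#'
#' Computes `V(t) = V(R(x(t)))` on the trajectory grid and returns the
#' largest forward difference quotient. For a valid RLF this never exceeds
#' a small tolerance proportional to the scale of `V`.
#'
#' @param traj a `crn_trajectory`.
#' @param rlf an evaluable candidate (`crn_pwl`, `crn_maxmin`, `crn_pwq`).
#' @param tol_scale tolerance is `tol_scale * (1 + max V)`.
#' @return list with `max_violation`, `pass`, `V` (the sampled values).
#' @export
dini_decrease_check <- function(traj, rlf, tol_scale = 1e-6) {
  V <- evaluate_rlf(rlf, t(traj$R))
  dq <- diff(V) / diff(traj$time)
  mv <- if (length(dq)) max(dq) else 0
  tol <- tol_scale * (1 + max(V))
  list(max_violation = mv, pass = mv <= tol, V = V, tol = tol)
}

#' Safety level of a Lyapunov function for a species bound
#'
#' Finds (by multi-start local minimization) the smallest value of
#' `V(R(x))` on the slice of the stoichiometric class where the watched
#' species equals its bound. Trajectories starting in the class with
#' `V < alpha` can never reach the bound, because V is nonincreasing. The
#' optimization is local, so `alpha` is reported as an upper-bound
#' certificate; pair it with trajectory falsification.
#'
#' @param rlf verified candidate.
#' @param net,kin network and kinetics.
#' @param species species name.
#' @param bound the concentration bound.
#' @param class_x0 a point identifying the stoichiometric class.
#' @param n_starts multi-start count.
#' @return list with `alpha` (`Inf` when the slice is empty:
#'   unbounded-safe), `x_min`, `feasible`.
#' @export
safety_level <- function(rlf, net, kin, species, bound, class_x0,
                         n_starts = 20L) {
  G <- net$Gamma
  n <- n_species(net)
  si <- match(species, net$species)
  if (is.na(si)) stop("unknown species ", species)
  laws <- left_null_basis_int(G)
  E <- rbind(if (ncol(laws)) t(laws), diag(n)[si, , drop = FALSE])
  b <- c(if (ncol(laws)) as.vector(t(laws) %*% class_x0), bound)
  # feasibility of the slice: x >= 0, E x = b
  fs <- lp_solve(rep(0, n), A_eq = E, b_eq = b, lower = 0)
  if (fs$status != "optimal") {
    return(list(alpha = Inf, feasible = FALSE, x_min = NULL))
  }
  # strictly interior start when available
  it <- lp_solve(c(rep(0, n), -1),
                 A_ub = cbind(-diag(n), 1), b_ub = rep(0, n),
                 A_eq = cbind(E, 0), b_eq = b,
                 lower = c(rep(0, n), 0), upper = c(rep(Inf, n), 1))
  x_start <- if (it$status == "optimal") it$x[seq_len(n)] else fs$x
  N <- MASS::Null(t(E))
  if (ncol(N) == 0L) {
    x <- x_start
    return(list(alpha = evaluate_rlf(rlf, kin$rate(x)), feasible = TRUE,
                x_min = x))
  }
  obj <- function(z) {
    x <- x_start + as.vector(N %*% z)
    if (any(x < -1e-12)) return(1e10 + sum(pmin(x, 0)^2))
    evaluate_rlf(rlf, kin$rate(pmax(x, 0)))
  }
  best <- list(value = Inf, x = NULL)
  scale <- max(1, max(abs(x_start)))
  for (t in seq_len(n_starts)) {
    z0 <- if (t == 1L) rep(0, ncol(N)) else stats::rnorm(ncol(N), 0, scale / 2)
    opt <- stats::optim(z0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (opt$value < best$value) {
      best <- list(value = opt$value,
                   x = pmax(x_start + as.vector(N %*% opt$par), 0))
    }
  }
  list(alpha = best$value, feasible = TRUE,
       x_min = stats::setNames(best$x, net$species))
}

#' Flux bound optimization under a Lyapunov level constraint
#'
#' Solves `max r_objective` subject to `r >= 0`,
#' `||C r||_inf <= ||C r_init||_inf` and `r_cap <= cap_value`: an upper
#' bound on a flux that holds for all time and all admissible kinetics,
#' because trajectories cannot leave the Lyapunov level set of their
#' initial flux vector.
#'
#' @param net a `crn_network`.
#' @param C coefficient matrix of an infinity-norm RLF `||C r||_inf` (use
#'   [soc_to_infnorm()] for 1-norm sum-of-currents certificates).
#' @param r_init initial flux vector (sets the level).
#' @param objective index of the maximized flux.
#' @param cap_index,cap_value index and value of the capped flux.
#' @return list with `value`, `argmax`, `level`, `status`.
#' @export
flux_bound <- function(net, C, r_init, objective, cap_index, cap_value) {
  nu <- n_reactions(net)
  level <- max(abs(C %*% r_init))
  obj <- numeric(nu); obj[objective] <- 1
  cap_row <- numeric(nu); cap_row[cap_index] <- 1
  A <- rbind(C, -C, cap_row)
  b <- c(rep(level, 2L * nrow(C)), cap_value)
  res <- lp_solve(obj, A_ub = A, b_ub = b, lower = 0, maximize = TRUE)
  if (res$status == "unbounded") {
    return(list(value = Inf, argmax = NULL, level = level,
                status = "unbounded (C is not a certificate)"))
  }
  list(value = res$value, argmax = res$x, level = level, status = res$status)
}

#' Expand a sum-of-currents certificate to infinity-norm form
#'
#' `||diag(xi) Gamma r||_1 = max_sigma sigma' diag(xi) Gamma r` over sign
#' vectors `sigma`; rows are enumerated over the support of `xi` (capped)
#' and deduplicated up to sign.
#'
#' @param net the network.
#' @param xi positive species weights.
#' @param max_rows cap on the enumeration (2^15 rows).
#' @return matrix `C` with `||C r||_inf = ||diag(xi) Gamma r||_1`.
#' @export
soc_to_infnorm <- function(net, xi, max_rows = 2^15) {
  supp <- which(xi > 0)
  ns <- length(supp)
  if (2^(ns - 1L) > max_rows) stop("too many sign vectors to enumerate")
  W <- diag(xi, nrow = length(xi)) %*% net$Gamma
  sig <- as.matrix(expand.grid(rep(list(c(-1, 1)), ns - 1L)))
  sig <- cbind(1, sig)        # fix first support sign: dedupe +-
  C <- matrix(0, nrow(sig), ncol(net$Gamma))
  for (t in seq_len(nrow(sig))) {
    sv <- numeric(length(xi)); sv[supp] <- sig[t, ]
    C[t, ] <- as.vector(crossprod(W, sv))
  }
  unique(C)
}

#' Translate a flux bound into a concentration bound
#'
#' Inverts a monotone single-substrate rate law on its range.
#'
#' @param law list: `type = "mass_action"` with constant `k`, or
#'   `type = "michaelis_menten"` with `R(c) = a c / (1 + b c)`.
#' @param flux_bound the flux bound to invert.
#' @return list with `concentration` (or `NA`), `reachable`.
#' @export
invert_rate_law <- function(law, flux_bound) {
  if (law$type == "mass_action") {
    return(list(concentration = flux_bound / law$k, reachable = TRUE))
  }
  if (law$type == "michaelis_menten") {
    sup <- if (law$b > 0) law$a / law$b else Inf
    if (flux_bound >= sup) {
      return(list(concentration = NA_real_, reachable = FALSE, supremum = sup))
    }
    return(list(concentration = flux_bound / (law$a - law$b * flux_bound),
                reachable = TRUE))
  }
  stop("unknown law type")
}

#' Search for multistability under randomized mass-action parameters
#'
#' Samples log-uniform kinetic constants, integrates the network from a
#' spread of initial conditions inside a fixed stoichiometric class, and
#' clusters the limits. Returns the first parameter set whose limits split
#' into two separated clusters. Used to exhibit bistability of distributive
#' modification cycles; a failure to find parameters is inconclusive.
#'
#' @param net a `crn_network`.
#' @param x0_sampler function of the draw index returning a nonnegative
#'   initial state; all returned states must share one stoichiometric class.
#' @param n_trials number of parameter draws.
#' @param n_inits initial conditions per draw.
#' @param horizon integration horizon.
#' @param k_range log10 range of the kinetic constants.
#' @param gap relative separation declaring two limits distinct.
#' @return list with `found`, and on success `k`, `limits`, `x0s`.
#' @export
find_bistability <- function(net, x0_sampler, n_trials = 60L, n_inits = 6L,
                             horizon = 2000, k_range = c(-2, 2), gap = 0.2) {
  nu <- n_reactions(net)
  n <- n_species(net)
  for (trial in seq_len(n_trials)) {
    k <- 10^stats::runif(nu, k_range[1], k_range[2])
    kin <- make_kinetics(net, "mass_action", k = k)
    lims <- matrix(NA_real_, n_inits, n)
    x0s <- vector("list", n_inits)
    failed <- FALSE
    for (t in seq_len(n_inits)) {
      x0 <- x0_sampler(t)
      x0s[[t]] <- x0
      traj <- tryCatch(
        simulate_network(net, kin, x0, horizon = horizon, n_out = 60L),
        error = function(e) NULL)
      if (is.null(traj)) { failed <- TRUE; break }
      lims[t, ] <- traj$x[nrow(traj$x), ]
    }
    if (failed || anyNA(lims)) next
    d <- as.matrix(stats::dist(lims))
    scale <- max(1e-8, max(abs(lims)))
    if (max(d) / scale > gap) {
      # confirm: both candidate limits are near-steady and stay separated
      # under continued integration (guards against slow transients)
      ij <- which(d == max(d), arr.ind = TRUE)[1, ]
      a <- lims[ij[1], ]; bpt <- lims[ij[2], ]
      ok <- TRUE
      for (pt in list(a, bpt)) {
        tr2 <- tryCatch(simulate_network(net, kin, pt, horizon = horizon,
                                         n_out = 30L),
                        error = function(e) NULL)
        if (is.null(tr2)) { ok <- FALSE; break }
        res <- max(abs(net$Gamma %*% kin$rate(tr2$x[nrow(tr2$x), ])))
        if (res > 1e-6 * scale) { ok <- FALSE; break }
        if (identical(pt, a)) a <- tr2$x[nrow(tr2$x), ] else bpt <- tr2$x[nrow(tr2$x), ]
      }
      if (ok && sqrt(sum((a - bpt)^2)) / scale > gap / 2) {
        return(list(found = TRUE, k = k, limits = lims, x0s = x0s,
                    trial = trial))
      }
    }
  }
  list(found = FALSE)
}
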