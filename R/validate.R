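# Sampling-based numerical validation of certificates, independent of the
# LP verification path.

#' Sampled decrease oracle for a rate-dependent candidate
#'
#' Draws random rate vectors `r` and random nonnegative pair weights `rho`
#' (supported on the reaction-reactant pairs), forms the admissible
#' rate-space direction `d = sum_l rho_l Q_l r`, and measures the one-sided
#' difference quotient of the candidate along `d`. For piecewise linear
#' candidates the quotient at a small step equals the Dini derivative
#' exactly, so a verified RLF must never produce a positive value beyond
#' tolerance.
#'
#' @param net a `crn_network`.
#' @param cand an evaluable candidate.
#' @param n_samples number of `(rho, r)` draws.
#' @param step relative step of the difference quotient.
#' @return list with `max_violation` and `pass` (tolerance `1e-7` on the
#'   normalized quotient).
#' @export
sampled_decrease_check <- function(net, cand, n_samples = 10000L,
                                   step = 1e-7) {
  ex <- extremals(net)
  nu <- n_reactions(net)
  s <- nrow(ex$pairs)
  Rm <- matrix(stats::rnorm(nu * n_samples), nu, n_samples)
  rho <- matrix(stats::runif(s * n_samples), s, n_samples)
  GR <- net$Gamma %*% Rm                      # species currents per sample
  D <- matrix(0, nu, n_samples)
  for (l in seq_len(s)) {
    jl <- ex$pairs[l, 1]; il <- ex$pairs[l, 2]
    D[jl, ] <- D[jl, ] + rho[l, ] * GR[il, ]
  }
  h <- step * (1 + sqrt(colSums(Rm^2))) / (1 + sqrt(colSums(D^2)))
  V0 <- evaluate_rlf(cand, Rm)
  V1 <- evaluate_rlf(cand, Rm + sweep(D, 2L, h, `*`))
  dq <- (V1 - V0) / h
  norm <- pmax(1, V0)
  mv <- max(dq / norm)
  list(max_violation = mv, pass = mv <= 1e-7)
}

#' Sampled kernel check: V vanishes exactly on ker Gamma
#'
#' Checks `V = 0` on an exact kernel basis and `V > 0` on random vectors
#' with a nonzero component orthogonal to the kernel.
#'
#' @param net a `crn_network`.
#' @param cand an evaluable candidate.
#' @param n_samples number of random non-kernel vectors.
#' @return list with `on_kernel_max`, `off_kernel_min`, `pass`.
#' @export
sampled_kernel_check <- function(net, cand, n_samples = 1000L) {
  nu <- n_reactions(net)
  ker <- null_basis_int(net$Gamma)
  on_max <- if (ncol(ker)) {
    # combinations of basis vectors too
    W <- cbind(ker, ker %*% matrix(stats::rnorm(ncol(ker) * 5), ncol(ker)))
    max(abs(evaluate_rlf(cand, W)))
  } else 0
  Rm <- matrix(stats::rnorm(nu * n_samples), nu, n_samples)
  if (ncol(ker)) {
    # strip near-kernel samples: keep those with substantial image component
    P <- diag(nu) - ker %*% MASS::ginv(ker)
    comp <- sqrt(colSums((P %*% Rm)^2))
    Rm <- Rm[, comp > 0.1, drop = FALSE]
  }
  off_min <- min(evaluate_rlf(cand, Rm))
  list(on_kernel_max = on_max, off_kernel_min = off_min,
       pass = on_max <= 1e-8 && off_min > 1e-10)
}

#' Mono-attractivity sampling
#'
#' Integrates several random initial conditions within one stoichiometric
#' class and checks that they reach the same limit.
#'
#' @param net,kin network and kinetics.
#' @param x0_sampler function of an index returning an initial state in the
#'   class.
#' @param n_inits number of initializations.
#' @param horizon integration horizon.
#' @param tol maximum allowed spread at the horizon.
#' @return list with `spread`, `pass`, `limits`.
#' @export
mono_attractivity_check <- function(net, kin, x0_sampler, n_inits = 10L,
                                    horizon = 2000, tol = 1e-4) {
  lims <- t(vapply(seq_len(n_inits), function(t) {
    traj <- simulate_network(net, kin, x0_sampler(t), horizon = horizon,
                             n_out = 50L)
    traj$x[nrow(traj$x), ]
  }, numeric(n_species(net))))
  spread <- max(apply(lims, 2L, function(col) diff(range(col))))
  list(spread = spread, pass = spread <= tol, limits = lims)
}

# Dirichlet-style random point in the stoichiometric class of x_base:
# redistributes each nonnegative conservation pool across its support.
# Works when the nonnegative laws have 0/1 coefficients (moiety pools);
# leftover species (in no pool) keep their base value.
class_sampler <- function(net, x_base) {
  cons <- conservation_analysis(net)
  laws <- cons$nonneg_laws
  totals <- if (ncol(laws)) as.vector(t(laws) %*% x_base) else numeric(0)
  draw <- function() {
    x <- as.numeric(x_base)
    if (!ncol(laws)) return(x)
    # process pools from smallest support to largest, respecting overlaps
    ord <- order(colSums(laws > 0))
    assigned <- rep(FALSE, length(x))
    for (t in ord) {
      supp <- which(laws[, t] > 0)
      free <- supp[!assigned[supp]]
      if (!length(free)) next
      already <- sum((laws[, t] * x)[assigned & laws[, t] > 0])
      rem <- totals[t] - already
      if (rem < 0) return(NULL)   # overlap clipped: reject and redraw
      w <- stats::rexp(length(free))
      x[free] <- rem * w / sum(w) / laws[free, t]
      assigned[free] <- TRUE
    }
    # the draw must stay in the class of x_base
    if (ncol(laws) &&
        max(abs(as.vector(t(laws) %*% x) - totals)) > 1e-9 * (1 + max(totals))) {
      return(NULL)
    }
    x
  }
  function(i) {
    for (try in 1:100) {
      x <- draw()
      if (!is.null(x)) return(x)
    }
    as.numeric(x_base)
  }
}
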