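# Necessary conditions and structural properties of attractive networks.

#' Jacobians generated by a nonnegative extremal combination
#'
#' For pair weights `rho >= 0` (one per reaction-reactant pair, in the order
#' of [extremals()]), returns the rate-space Jacobian
#' `J_r = sum_l rho_l Q_l` and the species-space Jacobian
#' `J_x = Gamma M(rho)` where `M(rho)` carries `rho_l` at position
#' `(j_l, i_l)`. For any admissible kinetics the true Jacobians arise this
#' way with `rho_l = dR_jl/dx_il`.
#'
#' @param net a `crn_network`.
#' @param rho nonnegative weights (length = number of pairs) or a single
#'   value recycled.
#' @return list with `J_r` (nu x nu), `J_x` (n x n) and `M` (nu x n).
#' @export
jacobian_at <- function(net, rho = 1) {
  ex <- extremals(net)
  s <- nrow(ex$pairs)
  rho <- rep_len(rho, s)
  if (any(rho < 0)) stop("rho must be nonnegative")
  nu <- n_reactions(net); n <- n_species(net)
  M <- matrix(0, nu, n)
  for (l in seq_len(s)) M[ex$pairs[l, 1], ex$pairs[l, 2]] <- rho[l]
  J_r <- matrix(0, nu, nu)
  for (l in seq_len(s)) J_r <- J_r + rho[l] * ex$Qs[[l]]
  J_x <- net$Gamma %*% M
  list(J_r = J_r, J_x = J_x, M = M)
}

#' P0 test on the negative species-space Jacobian
#'
#' A network admitting a PWL RLF must have a P0 negative Jacobian: every
#' principal minor of `-J_x(rho)` is nonnegative for every `rho >= 0`. Each
#' principal minor, indexed by a species subset I, is multilinear in the
#' pair weights: the coefficient of the monomial `prod_{i in I} rho_(j(i),i)`
#' is the exact integer determinant `det(-Gamma[I, J])` with column `j(i)`
#' chosen for species `i`. Because every monomial corresponds to exactly one
#' such reactant assignment, a single negative coefficient already gives a
#' numeric violation witness (put weight 1 on the assigned pairs and
#' epsilon -> 0 elsewhere); all-nonnegative coefficients prove the P0
#' property.
#'
#' @param net a `crn_network`.
#' @param max_size largest principal-minor size examined (default 12);
#'   networks with more species than the cap can only fail or come back
#'   `undetermined`.
#' @return object of class `crn_p0`: `verdict` (`"pass"`, `"fail"`,
#'   `"undetermined"`) plus, on failure, `witness` with the species subset,
#'   a numeric `rho` and the negative minor value.
#' @export
check_p0 <- function(net, max_size = 12L) {
  G <- net$Gamma
  n <- n_species(net)
  ex <- extremals(net)
  s <- nrow(ex$pairs)
  # reactions in which species i is a reactant, with their pair index
  cand <- lapply(seq_len(n), function(i) which(ex$pairs[, 2] == i))

  sizes <- seq_len(min(n, max_size))
  for (sz in sizes) {
    subsets <- utils::combn(n, sz)
    for (c_i in seq_len(ncol(subsets))) {
      I <- subsets[, c_i]
      ls <- cand[I]
      if (any(vapply(ls, length, integer(1)) == 0L)) next
      # iterate the assignment product space
      idx <- rep(1L, sz)
      repeat {
        pairs_sel <- vapply(seq_len(sz), function(t) ls[[t]][idx[t]], integer(1))
        Jcols <- ex$pairs[pairs_sel, 1]
        Mm <- -G[I, Jcols, drop = FALSE]
        d <- det_bareiss(Mm)
        if (d < 0) {
          wit <- p0_witness(net, ex, I, pairs_sel, s)
          return(structure(list(verdict = "fail", witness = wit,
                                max_size = max_size), class = "crn_p0"))
        }
        t <- sz
        while (t >= 1L) {
          idx[t] <- idx[t] + 1L
          if (idx[t] <= length(ls[[t]])) break
          idx[t] <- 1L; t <- t - 1L
        }
        if (t < 1L) break
      }
    }
  }
  verdict <- if (n <= max_size) "pass" else "undetermined"
  structure(list(verdict = verdict,
                 note = if (verdict == "undetermined")
                   sprintf("minors of size > %d not examined", max_size)
                 else "all minor coefficients nonnegative (exact)",
                 max_size = max_size), class = "crn_p0")
}

p0_witness <- function(net, ex, I, pairs_sel, s) {
  for (eps in 10^-(2:9)) {
    rho <- rep(eps, s)
    rho[pairs_sel] <- 1
    Jx <- jacobian_at(net, rho)$J_x
    val <- det(-Jx[I, I, drop = FALSE])
    if (val < -1e-9) {
      return(list(species = net$species[I], species_idx = I,
                  rho = rho, minor = val))
    }
  }
  list(species = net$species[I], species_idx = I, rho = NULL, minor = NA_real_)
}

#' @export
print.crn_p0 <- function(x, ...) {
  cat("P0 necessary condition:", x$verdict, "\n")
  if (!is.null(x$witness)) {
    cat("  violating principal minor on {",
        paste(x$witness$species, collapse = ", "),
        sprintf("} (minor = %.3g)\n", x$witness$minor))
  }
  invisible(x)
}

#' Robust non-degeneracy of the reduced Jacobian
#'
#' Evaluates the species-space Jacobian at unit pair weights (`rho = 1`),
#' reduces it to a basis `S` of `Im(Gamma)` and reports whether the reduced
#' map is nonsingular. For networks with a PWL RLF, nonsingularity at this
#' single point implies nonsingularity of the reduced Jacobian for every
#' admissible kinetics at every interior point. Determinants are computed
#' exactly (integer arithmetic).
#'
#' @param net a `crn_network`.
#' @return list with `nondegenerate` (logical), `det_scaled`
#'   (`det(S' J_x S)`, integer), `vacuous` flag for `Im(Gamma) = {0}`.
#' @export
check_robust_nondegeneracy <- function(net) {
  S <- col_space_basis(net$Gamma)
  if (ncol(S) == 0L) {
    return(list(nondegenerate = TRUE, vacuous = TRUE, det_scaled = 1))
  }
  Jx <- jacobian_at(net, 1)$J_x
  num <- det_bareiss(t(S) %*% Jx %*% S)
  list(nondegenerate = abs(num) > 0.5, vacuous = FALSE, det_scaled = num)
}

#' Siphon enumeration and critical-siphon preclusion
#'
#' A siphon is a species set P such that every reaction producing a member
#' of P has a reactant in P (once empty, it stays empty). Minimal siphons
#' are enumerated by brute force over the subset lattice with minimality
#' pruning. A siphon is trivial when it contains the support of a
#' nonnegative conservation law (decided by an LP); critical otherwise.
#' For networks with a positive steady-state flux (AS1), a critical siphon
#' precludes a PWL RLF when (a) it is a deadlock (every reaction has a
#' reactant in it), (b) the network is a conservative M-network, or (c) the
#' network is conservative and robustly non-degenerate (non-degeneracy
#' instantiated at unit pair weights).
#'
#' @param net a `crn_network`.
#' @param max_species cap on the brute-force enumeration.
#' @return object of class `crn_siphons`.
#' @export
siphon_analysis <- function(net, max_species = 18L) {
  n <- n_species(net)
  if (n > max_species) {
    return(structure(list(minimal_siphons = list(), complete = FALSE,
                          note = "species count exceeds enumeration cap"),
                     class = "crn_siphons"))
  }
  A <- net$A; B <- net$B
  nu <- n_reactions(net)
  minimal <- list()
  is_superset <- function(P) {
    any(vapply(minimal, function(Q) all(Q$idx %in% P), logical(1)))
  }
  for (sz in seq_len(n)) {
    subsets <- utils::combn(n, sz)
    for (c_i in seq_len(ncol(subsets))) {
      P <- subsets[, c_i]
      if (is_superset(P)) next
      producing <- which(colSums(B[P, , drop = FALSE] > 0) > 0)
      ok <- all(colSums(A[P, producing, drop = FALSE] > 0) > 0)
      if (ok) {
        minimal[[length(minimal) + 1L]] <- list(idx = P)
      }
    }
  }
  G <- net$Gamma
  for (t in seq_along(minimal)) {
    P <- minimal[[t]]$idx
    # trivial <=> exists d >= 0, sum d = 1, supp(d) in P, d' Gamma = 0
    nP <- length(P)
    res <- lp_solve(rep(0, nP),
                    A_eq = rbind(t(G[P, , drop = FALSE]), rep(1, nP)),
                    b_eq = c(rep(0, nu), 1), lower = 0)
    minimal[[t]]$species <- net$species[P]
    minimal[[t]]$trivial <- res$status == "optimal"
  }
  critical <- Filter(function(x) !x$trivial, minimal)
  cons <- conservation_analysis(net)
  as1 <- !is.null(cons$positive_flux)
  preclusion <- list(applies = FALSE, clauses = character(0), as1 = as1)
  if (as1 && length(critical)) {
    # (a) critical deadlock
    for (cs in critical) {
      if (all(colSums(A[cs$idx, , drop = FALSE] > 0) > 0)) {
        preclusion$clauses <- c(preclusion$clauses, "a: critical deadlock")
        break
      }
    }
    if (cons$is_conservative) {
      mds <- m_decomposition(net)
      if (!is.null(mds) && !mds$zero_flux) {
        preclusion$clauses <- c(preclusion$clauses, "b: conservative M-network")
      }
      if (check_robust_nondegeneracy(net)$nondegenerate) {
        preclusion$clauses <- c(preclusion$clauses,
                                "c: conservative + robustly non-degenerate (rho = 1)")
      }
    }
    preclusion$applies <- length(preclusion$clauses) > 0
  }
  structure(list(minimal_siphons = minimal, critical = critical,
                 preclusion = preclusion, complete = TRUE),
            class = "crn_siphons")
}

#' @export
print.crn_siphons <- function(x, ...) {
  if (!isTRUE(x$complete)) {
    cat("Siphon analysis incomplete:", x$note, "\n")
    return(invisible(x))
  }
  cat(sprintf("Minimal siphons: %d (%d critical)\n",
              length(x$minimal_siphons), length(x$critical)))
  for (s in x$minimal_siphons) {
    cat("  {", paste(s$species, collapse = ", "), "}",
        if (s$trivial) "trivial" else "CRITICAL", "\n")
  }
  if (isTRUE(x$preclusion$applies)) {
    cat("PWL RLF precluded:", paste(x$preclusion$clauses, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Convert a rate-dependent PWL RLF to concentration coordinates
#'
#' If `(C, H)` specifies a rate-dependent PWL RLF with `C = B Gamma` and
#' `H = G Gamma`, then `(B, G)` specifies a concentration-dependent PWL RLF
#' `V(x) = |b_k'(x - x_e)|` valid inside the stoichiometric class of a
#' steady state `x_e`. Minimum-norm solutions are returned; the rows of `D`
#' span the left kernel of Gamma, so `B + Y t(D)` is equally valid for any
#' `Y` (the function only ever sees `x - x_e`, which is orthogonal to `D`).
#'
#' @param cand a verified `crn_pwl` candidate.
#' @param net the network.
#' @return list with `B`, `G` (NULL for convex-form candidates without a
#'   partition), `D`, and the round-trip residual.
#' @export
rate_to_concentration <- function(cand, net) {
  Gm <- net$Gamma
  Gp <- MASS::ginv(Gm)
  C <- if (inherits(cand, "crn_maxmin")) maxmin_rows(cand) else cand$C
  B <- C %*% Gp
  resid <- max(abs(B %*% Gm - C))
  if (resid > 1e-7) {
    stop("C is not expressible as B Gamma; candidate rows leave the row space")
  }
  G <- NULL
  if (inherits(cand, "crn_pwl") && !is.null(cand$partition)) {
    G <- cand$partition$H %*% Gp
    resid <- max(resid, max(abs(G %*% Gm - cand$partition$H)))
  }
  D <- t(left_null_basis_int(Gm))
  list(B = B, G = G, D = D, residual = resid)
}

#' Violation search for one specific principal minor
#'
#' Examines the principal minor of `-J_x(rho)` on a given species set:
#' enumerates the reactant assignments of the subset and returns the most
#' negative monomial coefficient together with a numeric `rho` witness.
#'
#' @param net a `crn_network`.
#' @param species character vector (or index vector) of species.
#' @return list with `min_coefficient`, `violated`, and (when violated)
#'   `witness` as in [check_p0()].
#' @export
p0_minor_violation <- function(net, species) {
  I <- if (is.character(species)) match(species, net$species) else as.integer(species)
  if (anyNA(I)) stop("unknown species")
  G <- net$Gamma
  ex <- extremals(net)
  cand <- lapply(I, function(i) which(ex$pairs[, 2] == i))
  if (any(vapply(cand, length, integer(1)) == 0L)) {
    return(list(min_coefficient = 0, violated = FALSE))
  }
  sz <- length(I)
  idx <- rep(1L, sz)
  best <- Inf; best_sel <- NULL
  repeat {
    sel <- vapply(seq_len(sz), function(t) cand[[t]][idx[t]], integer(1))
    Mm <- -G[I, ex$pairs[sel, 1], drop = FALSE]
    d <- det_bareiss(Mm)
    if (d < best) { best <- d; best_sel <- sel }
    t <- sz
    while (t >= 1L) {
      idx[t] <- idx[t] + 1L
      if (idx[t] <= length(cand[[t]])) break
      idx[t] <- 1L; t <- t - 1L
    }
    if (t < 1L) break
  }
  out <- list(min_coefficient = best, violated = best < 0)
  if (best < 0) {
    out$witness <- p0_witness(net, ex, I, best_sel, nrow(ex$pairs))
  }
  out
}
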