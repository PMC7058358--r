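# Structural analysis: conservation laws, deficiency, extremal decomposition,
# and orientation of reversible reactions (M-network decomposition).

#' Conservation and flux analysis of a network
#'
#' Computes an exact integer basis of the left kernel of Gamma (conservation
#' laws), a set of independent nonnegative laws (extreme rays of the
#' nonnegative left-kernel cone), whether the network is conservative (every
#' species is supported in some nonnegative law), an integer basis of
#' `ker(Gamma)`, and a strictly positive steady-state flux vector when one
#' exists (the AS1 condition, normalized so that `v >= 1`).
#'
#' @param net a `crn_network`.
#' @return an object of class `crn_conservation` with fields `left_kernel`,
#'   `nonneg_laws`, `is_conservative`, `right_kernel`, `positive_flux`
#'   (`NULL` when no strictly positive flux exists).
#' @export
conservation_analysis <- function(net) {
  G <- net$Gamma
  n <- nrow(G)
  left <- left_null_basis_int(G)    # n x q, columns are laws
  right <- null_basis_int(G)

  # conservative <=> exists d >= 1 with d'Gamma = 0 (scale-invariant
  # surrogate for "every species supported in a nonnegative law")
  cons_lp <- lp_solve(rep(1, n), A_eq = t(G), b_eq = rep(0, ncol(G)),
                      lower = 1)
  is_conservative <- cons_lp$status == "optimal"

  nonneg <- extreme_rays_nonneg(left)

  # AS1: v in ker Gamma with v >> 0, normalized to v >= 1
  nu <- ncol(G)
  flux_lp <- lp_solve(rep(1, nu), A_eq = G, b_eq = rep(0, n), lower = 1)
  positive_flux <- if (flux_lp$status == "optimal") flux_lp$x else NULL

  structure(list(
    left_kernel = left,
    nonneg_laws = nonneg,
    is_conservative = is_conservative,
    right_kernel = right,
    positive_flux = positive_flux
  ), class = "crn_conservation")
}

# Extreme rays of {d >= 0 : d = K z} where K (n x q) spans a linear space.
# Brute force over active-set candidates; adequate for the small kernels of
# biochemical networks.
extreme_rays_nonneg <- function(K) {
  n <- nrow(K); q <- ncol(K)
  if (q == 0L) return(matrix(0, n, 0))
  if (q == 1L) {
    v <- K[, 1]
    if (all(v >= 0)) return(K)
    if (all(v <= 0)) return(-K)
    return(matrix(0, n, 0))
  }
  rays <- list()
  # an extreme ray of the cone {z : K z >= 0} lies on q-1 independent
  # active constraints (rows of K)
  combs <- utils::combn(n, q - 1L)
  for (c_i in seq_len(ncol(combs))) {
    rows <- combs[, c_i]
    sub <- K[rows, , drop = FALSE]
    if (int_rank(sub) != q - 1L) next
    z <- null_basis_int(sub)[, 1]
    for (s in c(1, -1)) {
      d <- as.vector(K %*% (s * z))
      if (all(d >= 0) && any(d > 0)) {
        g <- vec_gcd(d)
        if (g > 1) d <- d / g
        dup <- any(vapply(rays, function(r) all(r == d), logical(1)))
        if (!dup) rays[[length(rays) + 1L]] <- d
      }
    }
  }
  # keep only extreme ones: a ray is extreme if it is not a nonnegative
  # combination of the others; for these small cones, filter by support
  # minimality (supp(extreme ray) is not a strict superset of another's)
  if (length(rays) > 1L) {
    supp <- lapply(rays, function(r) which(r > 0))
    keep <- rep(TRUE, length(rays))
    for (i in seq_along(rays)) {
      for (j in seq_along(rays)) {
        if (i != j && keep[j] &&
            all(supp[[j]] %in% supp[[i]]) &&
            length(supp[[j]]) < length(supp[[i]])) {
          keep[i] <- FALSE
          break
        }
      }
    }
    rays <- rays[keep]
  }
  if (!length(rays)) return(matrix(0, n, 0))
  do.call(cbind, rays)
}

#' @export
print.crn_conservation <- function(x, ...) {
  cat(sprintf("Conservation analysis: %d conservation laws (%d nonnegative), %s\n",
              ncol(x$left_kernel), ncol(x$nonneg_laws),
              if (x$is_conservative) "conservative" else "not conservative"))
  cat(sprintf("ker(Gamma) dimension %d; positive steady-state flux (AS1): %s\n",
              ncol(x$right_kernel),
              if (is.null(x$positive_flux)) "absent"
              else paste(x$positive_flux, collapse = " ")))
  invisible(x)
}

#' Deficiency of a network
#'
#' Deduplicates the reactant and product complexes as coefficient vectors,
#' counts linkage classes as connected components of the undirected complex
#' graph, and reports `deficiency = n_complexes - n_linkage - rank(Gamma)`.
#'
#' @param net a `crn_network`.
#' @return list with `n_complexes`, `n_linkage`, `rank`, `deficiency`.
#' @export
deficiency <- function(net) {
  nu <- n_reactions(net)
  keys <- character(0)
  cid <- function(v) paste(v, collapse = ",")
  edges <- matrix(0L, nu, 2)
  for (j in seq_len(nu)) {
    ka <- cid(net$A[, j]); kb <- cid(net$B[, j])
    for (kk in c(ka, kb)) if (!(kk %in% keys)) keys <- c(keys, kk)
    edges[j, ] <- c(match(ka, keys), match(kb, keys))
  }
  nc <- length(keys)
  # union-find over complexes
  parent <- seq_len(nc)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (j in seq_len(nu)) {
    a <- find(edges[j, 1]); b <- find(edges[j, 2])
    if (a != b) parent[a] <- b
  }
  nl <- length(unique(vapply(seq_len(nc), find, integer(1))))
  rk <- int_rank(net$Gamma)
  list(n_complexes = nc, n_linkage = nl, rank = rk,
       deficiency = nc - nl - rk)
}

#' Extremal rank-one decomposition of the rate Jacobian cone
#'
#' Enumerates the reaction-reactant pairs `P = {(j, i) : alpha_ij > 0}` in
#' column-major order and the associated rank-one matrices
#' `Q_l = e_j %*% t(gamma_i)` (`gamma_i` = row i of Gamma). For every
#' admissible kinetics, `(dR/dx) Gamma` lies in the convex cone spanned by
#' the `Q_l`, so a common Lyapunov function for these `s` linear systems is a
#' Robust Lyapunov Function for the network.
#'
#' @param net a `crn_network`.
#' @return object of class `crn_extremals`: `pairs` (s x 2 matrix of
#'   (reaction, species) indices) and `Qs` (list of nu x nu integer matrices).
#' @export
extremals <- function(net) {
  nu <- n_reactions(net)
  idx <- which(net$A > 0, arr.ind = TRUE)       # rows: (species, reaction)
  ord <- order(idx[, 2], idx[, 1])              # column-major over A
  idx <- idx[ord, , drop = FALSE]
  pairs <- cbind(reaction = idx[, 2], species = idx[, 1])
  Qs <- lapply(seq_len(nrow(pairs)), function(l) {
    Q <- matrix(0, nu, nu)
    Q[pairs[l, 1], ] <- net$Gamma[pairs[l, 2], ]
    Q
  })
  structure(list(pairs = pairs, Qs = Qs), class = "crn_extremals")
}

#' @export
print.crn_extremals <- function(x, ...) {
  cat(sprintf("Extremal set: %d reaction-reactant pairs\n", nrow(x$pairs)))
  invisible(x)
}

#' Orient reversible reactions so the irreversible subnetwork has a
#' one-dimensional flux kernel
#'
#' Searches the orientations of the reversible pairs (lexicographic,
#' forward-as-written first) for one whose irreversible subnetwork
#' stoichiometry `Gamma_tilde` (forward + irreversible columns) has
#' `dim ker = 1` spanned by a nonnegative vector `w` (scaled so the minimum
#' positive entry is 1). When no orientation achieves that, an orientation
#' with `dim ker = 0` is returned flagged `zero_flux` (with `w` identically
#' 1), and the Max-Min construction appends the constant 0 to its rate set.
#' When neither exists the network is not an M-network and `NULL` is
#' returned.
#'
#' @param net a `crn_network`.
#' @param all_orientations return every acceptable orientation instead of
#'   the first (used by the graphical criterion to retry its side
#'   conditions).
#' @return `NULL`, a `crn_mdecomp`, or a list of them.
#' @export
m_decomposition <- function(net, all_orientations = FALSE) {
  pairs <- net$reversible_pairs
  npair <- length(pairs)
  irrev <- setdiff(seq_len(n_reactions(net)),
                   unlist(pairs))
  found <- list()
  zero_flux_hit <- NULL
  for (mask in 0:(2^npair - 1)) {
    fwd <- integer(npair)
    for (p in seq_len(npair)) {
      bit <- bitwAnd(bitwShiftR(mask, npair - p), 1L)
      fwd[p] <- if (bit == 0L) pairs[[p]][1] else pairs[[p]][2]
    }
    cols <- sort(c(fwd, irrev))
    Gt <- net$Gamma[, cols, drop = FALSE]
    ker <- null_basis_int(Gt)
    d <- ncol(ker)
    if (d == 1L) {
      w <- ker[, 1]
      if (all(w <= 0)) w <- -w
      if (all(w >= 0)) {
        pos <- w[w > 0]
        w <- w / min(pos)
        md <- structure(list(
          orientation = fwd, columns = cols, Gamma_tilde = Gt,
          w = w, zero_flux = FALSE, net = net), class = "crn_mdecomp")
        if (!all_orientations) return(md)
        found[[length(found) + 1L]] <- md
      }
    } else if (d == 0L && is.null(zero_flux_hit)) {
      zero_flux_hit <- structure(list(
        orientation = fwd, columns = cols, Gamma_tilde = Gt,
        w = rep(1, length(cols)), zero_flux = TRUE, net = net),
        class = "crn_mdecomp")
      if (all_orientations) found[[length(found) + 1L]] <- zero_flux_hit
    } else if (d == 0L && all_orientations) {
      found[[length(found) + 1L]] <- structure(list(
        orientation = fwd, columns = cols, Gamma_tilde = Gt,
        w = rep(1, length(cols)), zero_flux = TRUE, net = net),
        class = "crn_mdecomp")
    }
  }
  if (all_orientations) return(found)
  zero_flux_hit
}

#' @export
print.crn_mdecomp <- function(x, ...) {
  cat(sprintf("M-decomposition: %d oriented columns%s; w = (%s)\n",
              length(x$columns),
              if (x$zero_flux) " [zero flux kernel]" else "",
              paste(x$w, collapse = ", ")))
  invisible(x)
}
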