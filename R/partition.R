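# Conic partitions of rate space induced by a partitioning matrix H.
#
# A piecewise linear-in-rates candidate is defined over the regions
# W_k = {r : Sigma_k H r >= 0}, where Sigma_k runs over the diagonal +-1
# signature matrices. Only signatures whose region has nonempty interior
# matter; regions come in +- pairs and one representative of each pair is
# kept.

#' Build the conic partition of rate space for a partitioning matrix
#'
#' The default partitioning matrix is `H = Gamma` so regions are orthants of
#' the species "currents" `Gamma r`. Extra rows (e.g. sums/differences of
#' rows of Gamma) refine the partition; they must lie in the row space of
#' Gamma so that `ker H = ker Gamma` is preserved.
#'
#' Nonempty interior of a signature region is decided by strict feasibility
#' (`Sigma H r >= eps`, `max|r| <= 1` with `eps = 1e-6`); the enumeration
#' over the `2^p` signatures is pruned by a depth-first search on signature
#' prefixes, pre-seeded with the sign patterns of randomly sampled rate
#' vectors.
#'
#' @param net a `crn_network`.
#' @param H optional partitioning matrix (`p x nu`); default `Gamma`.
#' @param extra_rows optional matrix of rows appended to the default `H`;
#'   each must lie in the row space of `Gamma`.
#' @param eps strict-feasibility margin for the interior test.
#' @param max_rows refuse partitions with more than this many rows
#'   (signature enumeration is exponential in `p`).
#' @return object of class `crn_partition`: `H`, `signatures` (matrix, one
#'   row per kept region, entries +-1), `m` (total number of regions
#'   including negations).
#' @export
build_partition <- function(net, H = NULL, extra_rows = NULL, eps = 1e-6,
                            max_rows = 20L) {
  G <- net$Gamma
  if (is.null(H)) H <- G
  H <- as.matrix(H)
  if (ncol(H) != ncol(G)) stop("H must have one column per reaction")
  if (!is.null(extra_rows)) {
    extra_rows <- matrix(extra_rows, ncol = ncol(G))
    H <- rbind(H, extra_rows)
  }
  # ker H = ker Gamma: H annihilates ker(Gamma) and rank H = rank Gamma
  kerG <- null_basis_int(G)
  if (ncol(kerG) && max(abs(H %*% kerG)) > 1e-9) {
    stop("rows of H must lie in the row space of Gamma (ker H != ker Gamma)")
  }
  if (qr(H)$rank != int_rank(G)) {
    stop("rank of H differs from rank of Gamma (ker H != ker Gamma)")
  }
  p <- nrow(H)
  if (p > max_rows) {
    stop(sprintf("H has %d rows; signature enumeration capped at %d ",
                 p, max_rows),
         "(use the iterative or graphical construction instead)")
  }
  nu <- ncol(H)

  # sample-based pre-seeding of attainable sign patterns (local RNG stream,
  # global .Random.seed untouched)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(285714L)
  ns <- min(50000L, 2000L * 2^min(p, 12))
  Rm <- matrix(stats::rnorm(ns * nu), ns, nu)
  Sg <- Rm %*% t(H)
  ok <- rowSums(abs(Sg) < 1e-9) == 0
  pats <- sign(Sg[ok, , drop = FALSE])
  pats <- unique(pats)

  sampled_prefix <- function(sig) {
    d <- length(sig)
    if (!nrow(pats)) return(FALSE)
    sub <- pats[, seq_len(d), drop = FALSE]
    any(rowSums(sub == matrix(sig, nrow(sub), d, byrow = TRUE)) == d)
  }
  strict_feasible <- function(sig) {
    d <- length(sig)
    A <- -sig * H[seq_len(d), , drop = FALSE]   # -sig*h'r <= -eps
    res <- lp_solve(rep(0, nu), A_ub = A, b_ub = rep(-eps, d),
                    lower = -1, upper = 1)
    res$status == "optimal"
  }

  kept <- list()
  dfs <- function(sig) {
    d <- length(sig)
    certified <- sampled_prefix(sig)
    if (!certified && !strict_feasible(sig)) return(invisible())
    if (d == p) {
      kept[[length(kept) + 1L]] <<- sig
      return(invisible())
    }
    dfs(c(sig, 1))
    dfs(c(sig, -1))
  }
  # keep the half with leading signature +1; the other half is -Sigma
  dfs(c(1))
  sigs <- do.call(rbind, kept)
  structure(list(H = H, signatures = sigs, m = 2L * nrow(sigs),
                 eps = eps), class = "crn_partition")
}

#' @export
print.crn_partition <- function(x, ...) {
  cat(sprintf("Conic partition: H is %d x %d, %d regions with nonempty interior (%d kept up to sign)\n",
              nrow(x$H), ncol(x$H), x$m, nrow(x$signatures)))
  invisible(x)
}
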