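# Iterative row-growing construction of convex PWL RLFs.

#' Iterative construction of a convex PWL RLF
#'
#' Starts from `C = Gamma` (one row per species current) and repeatedly
#' augments it: for the k-th row `c_k`, every reaction `R_j` in its support
#' and every reactant `X_i` of `R_j` proposes the new row
#' `c* = c_k + sgn(c_kj) gamma_i`, appended unless it equals an existing row
#' (or the zero row). If a full pass over the pending rows adds nothing the
#' algorithm has converged and `V(r) = max(0, max_k c_k' r)` is an RLF.
#' All arithmetic is exact (integer rows). Unlike the LP and graphical
#' constructions, this procedure needs neither a positive steady-state flux
#' nor non-autocatalysis.
#'
#' @param net a `crn_network`.
#' @param n_max iteration cap (number of processed rows).
#' @return a convex `crn_pwl` with `$status = "ok"`, or a list with
#'   `status = "not_converged"` (inconclusive, not a refutation).
#' @export
iterate_convex <- function(net, n_max = 1000L) {
  G <- net$Gamma
  nu <- ncol(G)
  C <- G                       # rows c_1..c_n
  keys <- new.env(parent = emptyenv())
  keyof <- function(v) paste(v, collapse = ",")
  assign(keyof(rep(0, nu)), TRUE, envir = keys)        # c_0 = 0
  for (i in seq_len(nrow(C))) assign(keyof(C[i, ]), TRUE, envir = keys)

  reactants <- lapply(seq_len(nu), function(j) which(net$A[, j] > 0))

  k <- 1L
  flag <- FALSE
  while (k < n_max && !flag) {
    if (k <= nrow(C)) {
      ck <- C[k, ]
      for (j in which(ck != 0)) {
        sg <- sign(ck[j])
        for (i in reactants[[j]]) {
          cstar <- ck + sg * G[i, ]
          key <- keyof(cstar)
          if (!exists(key, envir = keys, inherits = FALSE)) {
            assign(key, TRUE, envir = keys)
            C <- rbind(C, cstar)
          }
        }
      }
    }
    k <- k + 1L
    if (nrow(C) < k) flag <- TRUE
  }
  if (!flag) {
    return(list(status = "not_converged", rows = nrow(C),
                reason = sprintf("iteration cap %d reached", n_max)))
  }
  rownames(C) <- NULL
  cand <- new_pwl_candidate(C, partition = NULL, convex = TRUE,
                            method = "iterate")
  cand$status <- "ok"
  cand
}

# does matrix C contain row v up to sign?
has_row <- function(C, v, up_to_sign = TRUE, tol = 1e-9) {
  hit <- apply(C, 1L, function(r) max(abs(r - v)) < tol ||
                 (up_to_sign && max(abs(r + v)) < tol))
  any(hit)
}
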