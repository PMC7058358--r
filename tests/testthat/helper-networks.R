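# Shared fixtures and independent oracles used across the test files.

a2b <- function() parse_network("A -> B")
ab_rev <- function() parse_network("A <-> B")

# translation core: the P-free subnetwork whose three-piece convex RLF is
# known in closed form
translation_core <- function() {
  parse_network(c("Rib + mRNA <-> C", "C -> mRNA + Rib", "C -> Rib"))
}

# the six extremal matrices of the reduced modification cycle, written out
# explicitly (4x4, one per reaction-reactant pair)
ptm_reduced_extremals <- function() {
  rows <- list(
    c(-1, 0, 0, 1), c(-1, 1, 0, 0), c(1, -1, 0, 0),
    c(0, 1, -1, 0), c(0, 0, -1, 1), c(0, 0, 1, -1))
  at <- c(1, 1, 2, 3, 3, 4)
  lapply(seq_along(rows), function(l) {
    Q <- matrix(0, 4, 4)
    Q[at[l], ] <- rows[[l]]
    Q
  })
}

# the published sum-of-currents function of the full modification cycle:
# consecutive differences of the loop potentials (R1-R-1, R2, R3-R-3, R4),
# i.e. the currents of SE, S+, S+F and S; columns (R1, R-1, R2, R3, R-3, R4)
ptm_soc_published_rows <- function() {
  rbind(
    c(1, -1, -1, 0, 0, 0),
    c(0, 0, 1, -1, 1, 0),
    c(0, 0, 0, 1, -1, -1),
    c(1, -1, 0, 0, 0, -1))
}

# 1-norm function sum_i |c_i' r| as a convex max-form candidate
onenorm_candidate <- function(rows) {
  n <- nrow(rows)
  sig <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  C <- sig %*% rows
  pwl_candidate(unique(C), convex = TRUE)
}

# independent naive siphon oracle: test every nonempty subset directly,
# then keep the inclusion-minimal ones
naive_minimal_siphons <- function(net) {
  n <- length(net$species)
  A <- net$A; B <- net$B
  all_s <- list()
  for (m in seq_len(2^n - 1L)) {
    P <- which(bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) > 0)
    producing <- which(colSums(B[P, , drop = FALSE] > 0) > 0)
    if (all(colSums(A[P, producing, drop = FALSE] > 0) > 0)) {
      all_s[[length(all_s) + 1L]] <- P
    }
  }
  keep <- vapply(all_s, function(P) {
    !any(vapply(all_s, function(Q)
      length(Q) < length(P) && all(Q %in% P), logical(1)))
  }, logical(1))
  all_s[keep]
}

siphon_sets <- function(report) {
  lapply(report$minimal_siphons, function(s) s$idx)
}

same_set_of_sets <- function(a, b) {
  key <- function(s) paste(sort(s), collapse = ",")
  setequal(vapply(a, key, character(1)), vapply(b, key, character(1)))
}

# class-preserving initial condition for the full modification cycle:
# substrate split randomly over free forms, enzymes free
ptm_class_x0 <- function(stot = 10, etot = 10, ftot = 10) {
  w <- stats::runif(2); w <- w / sum(w)
  c(stot * w[1], etot, 0, stot * w[2], ftot, 0)
}
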