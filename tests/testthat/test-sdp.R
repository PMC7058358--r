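test_that("rank-one lift of a PWL certificate is an exact feasible point", {
  # Proposition-6 consistency on three fixtures: P_k = c_k c_k' with the
  # closed-form certificate blocks satisfies every constraint exactly
  for (nm in c("ptm_full", "transcription", "kinetic_proofreading")) {
    net <- fixture(nm)
    soc <- construct_soc(net)
    q <- pwq_from_pwl(net, soc)
    expect_identical(q$status, "ok")
    expect_lt(q$residuals$max, 1e-9)
  }
})

test_that("the quadratic candidate decreases on sampled admissible directions", {
  net <- fixture("ptm_full")
  q <- construct_pwq_sdp(net)
  expect_identical(q$status, "ok")
  ex <- extremals(net)
  set.seed(17)
  worst <- -Inf
  for (t in 1:10000) {
    r <- rnorm(6)
    rho <- runif(nrow(ex$pairs))
    k <- which(apply(q$partition$signatures, 1, function(sg)
      all(sg * sign(net$Gamma %*% r) >= 0) ||
        all(sg * sign(net$Gamma %*% r) <= 0)))[1]
    if (is.na(k)) next
    P <- q$Ps[[k]]
    d <- numeric(6)
    GR <- net$Gamma %*% r
    for (l in seq_len(nrow(ex$pairs))) {
      d[ex$pairs[l, 1]] <- d[ex$pairs[l, 1]] + rho[l] * GR[ex$pairs[l, 2]]
    }
    # d/dt (r'Pr + 2c'r) along rdot = d, with c = 0 for the lifted point
    dv <- 2 * as.numeric(t(r) %*% P %*% d)
    worst <- max(worst, dv / max(1, as.numeric(t(r) %*% P %*% r)))
  }
  expect_lte(worst, 1e-6)
})

test_that("alternating projections find a certificate for reversible binding", {
  ab <- ab_rev()
  part <- build_partition(ab)
  # force the projection path by withholding the PWL seed
  prob <- crnlyap:::pwq_problem(ab, part)
  z <- rep(0, prob$nvar)
  for (it in 1:800) {
    z <- prob$proj_affine(z)
    z <- prob$proj_cone(z)
  }
  res <- crnlyap:::pwq_residuals(prob, z)
  expect_lt(res$affine, 1e-7)
  expect_lt(res$cone, 1e-7)
  out <- crnlyap:::pwq_extract(prob, z, part)
  # P proportional to the rank-one lift of (1,-1)
  P <- out$Ps[[1]] / out$Ps[[1]][1, 1]
  expect_equal(unname(P), rbind(c(1, -1), c(-1, 1)), tolerance = 1e-5)
})

test_that("piecewise quadratic evaluation is even and vanishes on the kernel", {
  net <- fixture("ptm_full")
  q <- construct_pwq_sdp(net)
  ker <- crnlyap:::null_basis_int(net$Gamma)
  expect_lt(max(abs(evaluate_rlf(q, ker))), 1e-10)
  set.seed(4)
  r <- matrix(rnorm(18), 6)
  expect_equal(evaluate_rlf(q, r), evaluate_rlf(q, -r))
  expect_true(all(evaluate_rlf(q, r) > 0))
})
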