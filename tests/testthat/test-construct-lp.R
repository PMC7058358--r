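test_that("sum-of-currents weights for the benchmark networks", {
  # kinetic proofreading, N = 2: published weights (1,1,2,2,2) over
  # (M, L, C0, C1, C2)
  kp <- fixture("kinetic_proofreading", N = 2)
  soc <- construct_soc(kp)
  expect_equal(soc$xi, c(1, 1, 2, 2, 2))
  expect_true(verify_pwl(kp, soc)$pass)

  # distinct-enzyme cascade, n = 2: weight 2 on all substrate forms, 1 on
  # enzymes and complexes
  mc <- fixture("multisite_distinct", n = 2)
  soc2 <- construct_soc(mc)
  expect_equal(soc2$xi, c(rep(2, 3), rep(1, 8)))
  expect_true(verify_pwl(mc, soc2)$pass)

  # A <-> B
  soc3 <- construct_soc(ab_rev())
  expect_equal(soc3$xi, c(1, 1))
  expect_true(verify_pwl(ab_rev(), soc3)$pass)
})

test_that("transcription: published weights verify; LP weights verify", {
  net <- fixture("transcription")
  soc <- construct_soc(net)
  expect_true(verify_pwl(net, soc)$pass)
  # the published weight vector (1,1,1,3) is also in the feasible set:
  # build its regional candidate explicitly and verify it as an RLF
  part <- soc$partition
  xi_pub <- c(1, 1, 1, 3)
  C_pub <- t(vapply(seq_len(nrow(part$signatures)), function(k)
    as.vector(crossprod(net$Gamma, part$signatures[k, ] * xi_pub)),
    numeric(ncol(net$Gamma))))
  cand_pub <- pwl_candidate(C_pub, partition = part)
  expect_true(verify_pwl(net, cand_pub)$pass)
})

test_that("general LP construction on small networks", {
  ab <- ab_rev()
  r <- construct_pwl_lp(ab)
  expect_identical(r$status, "ok")
  # C = (1,-1) up to sign and positive scaling
  cr <- r$C[1, ] / max(abs(r$C[1, ]))
  expect_true(max(abs(cr - c(1, -1))) < 1e-9 || max(abs(cr + c(1, -1))) < 1e-9)
  expect_true(verify_pwl(ab, r)$pass)

  # transcription over the weighted partition recovers a verified RLF
  tr <- fixture("transcription")
  H <- diag(c(1, 1, 1, 3)) %*% tr$Gamma
  r2 <- construct_pwl_lp(tr, build_partition(tr, H = H))
  expect_identical(r2$status, "ok")
  expect_true(verify_pwl(tr, r2)$pass)
})

test_that("distributive double cycle: no PWL RLF over the default partition", {
  dd <- fixture("distributive_double")
  part <- build_partition(dd)
  r <- construct_pwl_lp(dd, part)
  expect_identical(r$status, "infeasible")
  soc <- construct_soc(dd, part)
  expect_identical(soc$status, "infeasible")
})

test_that("the open receptor-gated cycle is not certified by the LP", {
  net <- fixture("receptor_ptm_open")
  r <- construct_pwl_lp(net)
  expect_identical(r$status, "infeasible")
})

test_that("LP certificates agree with the independent LP backend", {
  skip_if_not_installed("pracma")
  # cross-check our simplex against pracma::linprog on the conservativity
  # and positive-flux LPs of the full modification cycle
  net <- fixture("ptm_full")
  G <- net$Gamma
  mine <- lp_solve(rep(1, 6), A_eq = t(G), b_eq = rep(0, 6), lower = 1)
  ref <- pracma::linprog(rep(1, 6), Aeq = t(G),
                         beq = as.vector(-t(G) %*% rep(1, 6)),
                         maxiter = 200)
  expect_equal(mine$value, ref$fval + 6, tolerance = 1e-7)
  mine2 <- lp_solve(rep(1, 6), A_eq = G, b_eq = rep(0, 6), lower = 1)
  ref2 <- pracma::linprog(rep(1, 6), Aeq = G,
                          beq = as.vector(-G %*% rep(1, 6)), maxiter = 200)
  expect_equal(mine2$value, ref2$fval + 6, tolerance = 1e-7)
})
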