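test_that("P0 failure of the distributive double cycle with witness", {
  net <- fixture("distributive_double")
  p0 <- check_p0(net)
  expect_identical(p0$verdict, "fail")
  expect_lt(p0$witness$minor, -1e-9)
  # the witness rho gives a genuinely negative principal minor
  Jx <- jacobian_at(net, p0$witness$rho)$J_x
  I <- p0$witness$species_idx
  expect_lt(det(-Jx[I, I]), -1e-9)
  # the published witness subset is violated too
  v <- p0_minor_violation(net, c("X0", "X1", "X2", "E", "FX1", "EX1"))
  expect_true(v$violated)
  expect_lt(v$witness$minor, -1e-9)
})

test_that("P0 passes on networks with verified certificates", {
  expect_identical(check_p0(ab_rev())$verdict, "pass")
  expect_identical(check_p0(fixture("ptm_full"))$verdict, "pass")
  expect_identical(check_p0(fixture("transcription"))$verdict, "pass")
})

test_that("robust non-degeneracy at unit pair weights", {
  r <- check_robust_nondegeneracy(ab_rev())
  expect_true(r$nondegenerate)
  # reduced 1x1 map is -2 (scaled determinant -4 over basis norm 2)
  expect_equal(r$det_scaled / 2, -2)
  expect_true(check_robust_nondegeneracy(fixture("ptm_full"))$nondegenerate)
  # engineered singular reduced map: duplicated autocatalytic columns whose
  # Jacobian annihilates Im(Gamma)
  dg <- network_from_matrices(A = cbind(c(1, 1), c(1, 1)),
                              B = cbind(c(2, 0), c(2, 0)))
  expect_false(check_robust_nondegeneracy(dg)$nondegenerate)
})

test_that("siphon classification on the benchmark networks", {
  # inflow-outflow chain: no siphons at all
  s0 <- siphon_analysis(parse_network(c("0 -> A", "A -> 0")))
  expect_length(s0$minimal_siphons, 0L)

  # basic enzymatic motif: {S, ES} is minimal and critical; preclusion not
  # applied because there is no positive steady-state flux
  em <- fixture("enzymatic_motif")
  se <- siphon_analysis(em)
  sets <- lapply(se$minimal_siphons, function(x) sort(x$species))
  expect_true(any(vapply(sets, identical, logical(1), c("ES", "S"))))
  crit <- Filter(function(x) !x$trivial, se$minimal_siphons)
  expect_equal(sort(crit[[1]]$species), c("ES", "S"))
  expect_false(se$preclusion$as1)
  expect_false(se$preclusion$applies)

  # full modification cycle: every minimal siphon contains a moiety pool
  sp <- siphon_analysis(fixture("ptm_full"))
  expect_true(all(vapply(sp$minimal_siphons, `[[`, logical(1), "trivial")))
  expect_false(sp$preclusion$applies)
})

test_that("siphon enumeration agrees with the all-subsets oracle", {
  set.seed(86)
  for (t in 1:50) {
    net <- random_network(n = sample(3:10, 1), nu = sample(2:8, 1))
    mine <- siphon_sets(siphon_analysis(net))
    ref <- naive_minimal_siphons(net)
    expect_true(same_set_of_sets(mine, ref))
  }
})

test_that("rate-to-concentration conversion", {
  ab <- ab_rev()
  cand <- construct_pwl_lp(ab)
  rc <- rate_to_concentration(cand, ab)
  # minimum-norm B for C = (-1, 1) is (1/2, -1/2) (sign follows C)
  expect_equal(abs(unname(rc$B[1, ])), c(0.5, 0.5))
  expect_lt(max(abs(rc$B %*% ab$Gamma - cand$C)), 1e-9)
  expect_lt(rc$residual, 1e-9)

  # round trip on the modification cycle, including the partition matrix
  net <- fixture("ptm_full")
  soc <- construct_soc(net)
  rc2 <- rate_to_concentration(soc, net)
  expect_lt(max(abs(rc2$B %*% net$Gamma - soc$C)), 1e-8)
  expect_lt(max(abs(rc2$G %*% net$Gamma - soc$partition$H)), 1e-8)
  # rows of D span the left kernel
  expect_lt(max(abs(rc2$D %*% net$Gamma)), 1e-9)
  expect_equal(nrow(rc2$D), 3L)
})

test_that("concentration-form function decreases along trajectories", {
  set.seed(23)
  for (nm in c("ptm_full", "enzymatic_cycle", "transcription")) {
    net <- fixture(nm)
    cand <- construct_soc(net)
    rc <- rate_to_concentration(cand, net)
    for (rep in 1:5) {
      kin <- make_kinetics(net, "mass_action",
                           k = 10^runif(ncol(net$Gamma), -0.5, 0.5))
      n <- length(net$species)
      x0 <- runif(n, 0.2, 3)
      ss <- steady_state(net, kin, x0)
      if (!ss$converged) next
      tr <- simulate_network(net, kin, x0, horizon = 80, n_out = 300)
      Vhat <- apply(tr$x, 1L, function(x)
        max(abs(rc$B %*% (x - ss$x_e))))
      dq <- diff(Vhat) / diff(tr$time)
      expect_lt(max(dq), 1e-4 * (1 + max(Vhat)))
    }
  }
})

test_that("a P0 pass accompanies every LP-certified fixture", {
  for (nm in c("ptm_full", "transcription", "enzymatic_cycle",
               "kinetic_proofreading", "erk_rkip", "ribosome_flow",
               "phosphotransfer_motif", "three_body_binding")) {
    expect_false(identical(check_p0(fixture(nm))$verdict, "fail"), info = nm)
  }
})
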