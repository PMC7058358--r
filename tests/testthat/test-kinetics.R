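test_that("admissible rate maps obey the structural assumptions", {
  net <- fixture("ptm_full")
  kin <- make_kinetics(net, "mass_action", k = 1)
  # R1 = k * s * e at (s, e) = (2, 3)
  x <- c(2, 3, 0, 0, 0, 0)
  expect_equal(kin$rate(x)[1], 6)
  # zero reactant forces zero rate for every law
  for (law in c("mass_action", "michaelis_menten", "hill")) {
    k2 <- make_kinetics(net, law, k = 2, Km = 0.7, hill = 2)
    r0 <- k2$rate(c(0, 3, 1, 1, 1, 1))
    expect_equal(r0[1], 0)   # R1 needs S
  }
  expect_error(make_kinetics(net, "mass_action", k = -1), "positive")
  expect_error(make_kinetics(net, "hill", hill = 0.5), ">= 1")
})

test_that("finite-difference rate Jacobian matches the reactant pattern", {
  set.seed(14)
  net <- fixture("ptm_full")
  ex <- extremals(net)
  for (law in c("mass_action", "michaelis_menten", "hill")) {
    kin <- make_kinetics(net, law, k = runif(6, 0.5, 2), Km = 1.3, hill = 2)
    for (t in 1:100) {
      x <- runif(6, 0.1, 4)
      h <- 1e-6
      for (l in sample(nrow(ex$pairs), 3)) {
        j <- ex$pairs[l, 1]; i <- ex$pairs[l, 2]
        xp <- x; xp[i] <- xp[i] + h
        fd <- (kin$rate(xp)[j] - kin$rate(x)[j]) / h
        expect_gt(fd, 0)                       # monotone in reactants
        expect_equal(fd, kin$rho(x)[l], tolerance = 1e-3)
      }
      # independence from non-reactants
      i0 <- which(net$A[, 1] == 0)[1]
      xp <- x; xp[i0] <- xp[i0] + 1
      expect_equal(kin$rate(xp)[1], kin$rate(x)[1])
    }
  }
})

test_that("simulation reproduces closed forms and conserves moieties", {
  ab <- a2b()
  kin <- make_kinetics(ab, "mass_action", k = 1)
  tr <- simulate_network(ab, kin, c(1, 0), horizon = 5)
  expect_lt(max(abs(tr$x[, 1] - exp(-tr$time))), 1e-6)

  net <- fixture("ptm_full")
  kinp <- make_kinetics(net, "mass_action", k = 1)
  trp <- simulate_network(net, kinp, c(10, 10, 0, 0, 10, 0), horizon = 100)
  expect_lt(trp$diagnostics$conservation_drift, 1e-6)
  expect_gt(min(trp$x), -1e-9)
})

test_that("steady state of the modification cycle at unit constants", {
  net <- fixture("ptm_full")
  kin <- make_kinetics(net, "mass_action", k = 1)
  ss <- steady_state(net, kin, c(10, 10, 0, 0, 10, 0))
  expect_true(ss$converged)
  expect_lte(ss$residual, 1e-10)
  exact <- (-7 + sqrt(89)) / 2
  expect_equal(unname(ss$x_e["S"]), exact, tolerance = 1e-6)
  expect_equal(unname(ss$x_e["E"]), exact + 5, tolerance = 1e-6)
  expect_equal(unname(ss$x_e["F"]), exact + 5, tolerance = 1e-6)
})

test_that("steady states solve the algebraic system across fixtures", {
  set.seed(40)
  for (nm in c("ptm_full", "enzymatic_cycle", "transcription",
               "phosphotransfer_motif", "simple_binding")) {
    net <- fixture(nm)
    kin <- make_kinetics(net, "mass_action",
                         k = 10^runif(ncol(net$Gamma), -0.5, 0.5))
    x0 <- runif(length(net$species), 0.5, 3)
    ss <- steady_state(net, kin, x0)
    expect_lte(ss$residual, 1e-10)
    # A <-> B with equal constants splits the total evenly
  }
  abr <- ab_rev()
  kin <- make_kinetics(abr, "mass_action", k = c(1, 1))
  ss <- steady_state(abr, kin, c(1, 0))
  expect_equal(unname(ss$x_e), c(0.5, 0.5), tolerance = 1e-8)
})

test_that("Dini decrease holds along trajectories; a wrong function fails", {
  net <- fixture("ptm_full")
  soc <- onenorm_candidate(ptm_soc_published_rows())
  set.seed(61)
  for (t in 1:20) {
    kin <- make_kinetics(net, "mass_action", k = 10^runif(6, -0.5, 0.5))
    tr <- simulate_network(net, kin, ptm_class_x0(), horizon = 60,
                           n_out = 500)
    expect_true(dini_decrease_check(tr, soc)$pass)
  }
  # constant trajectory at the steady state: V stays 0
  kin1 <- make_kinetics(net, "mass_action", k = 1)
  ss <- steady_state(net, kin1, c(10, 10, 0, 0, 10, 0))
  tre <- simulate_network(net, kin1, ss$x_e, horizon = 10)
  expect_lt(max(evaluate_rlf(soc, t(tre$R))), 1e-6)
  # r2 alone is not an RLF: a positive violation is detected
  wrong <- pwl_candidate(matrix(c(0, 0, 1, 0, 0, 0), 1), convex = TRUE)
  kin2 <- make_kinetics(net, "mass_action", k = c(2, 0.5, 1, 1, 1, 3))
  tr2 <- simulate_network(net, kin2, c(10, 2, 0, 0, 4, 0), horizon = 40,
                          n_out = 800)
  expect_false(dini_decrease_check(tr2, wrong)$pass)
})

test_that("safety levels bound the watched species", {
  net <- fixture("ptm_full")
  kin <- make_kinetics(net, "mass_action", k = 1)
  soc <- construct_soc(net)
  x0 <- c(10, 10, 0, 0, 10, 0)
  set.seed(2)
  a25 <- safety_level(soc, net, kin, "S", 2.5, x0, n_starts = 10)
  a30 <- safety_level(soc, net, kin, "S", 3.0, x0, n_starts = 10)
  expect_true(a25$feasible)
  expect_lte(a25$alpha, a30$alpha + 1e-8)      # nested slices
  # a bound above the substrate total is unreachable
  expect_equal(safety_level(soc, net, kin, "S", 11, x0)$alpha, Inf)
  # falsification: class states with V < alpha never exceed the bound
  ss <- steady_state(net, kin, x0)
  tested <- 0
  for (t in 1:50) {
    w <- runif(1, 0, 1)
    xs <- w * ss$x_e + (1 - w) * ptm_class_x0()
    if (evaluate_rlf(soc, kin$rate(xs)) < a25$alpha) {
      tested <- tested + 1
      tr <- simulate_network(net, kin, xs, horizon = 50, n_out = 100)
      expect_lte(max(tr$x[, 1]), 2.5 + 1e-6)
    }
  }
  expect_gt(tested, 0)
})

test_that("flux bounds under the Lyapunov level constraint", {
  kp <- fixture("kinetic_proofreading", N = 2)
  soc <- construct_soc(kp)
  expect_equal(soc$xi, c(1, 1, 2, 2, 2))
  Cw <- diag(soc$xi) %*% kp$Gamma
  r_init <- c(1, 0, 0, 0, 0, 0)
  # published optimum: the terminal flux is bounded by 3 r1*
  fb <- flux_bound(kp, Cw, r_init, objective = 6, cap_index = 1,
                   cap_value = 1)
  expect_equal(fb$value, 3, tolerance = 1e-9)
  # capped flux as objective saturates its cap
  fb2 <- flux_bound(kp, Cw, r_init, objective = 1, cap_index = 1,
                    cap_value = 1)
  expect_equal(fb2$value, 1, tolerance = 1e-9)
  # zero initial flux forces zero
  fb3 <- flux_bound(kp, Cw, rep(0, 6), objective = 6, cap_index = 1,
                    cap_value = 0)
  expect_equal(fb3$value, 0, tolerance = 1e-9)
  # monotone nondecreasing in the cap
  vals <- vapply(c(0.5, 1, 2), function(r1)
    flux_bound(kp, Cw, c(r1, 0, 0, 0, 0, 0), 6, 1, r1)$value, numeric(1))
  expect_true(all(diff(vals) >= -1e-9))
  # the sign-enumerated 1-norm level set gives the tighter bound 2
  Cs <- soc_to_infnorm(kp, soc$xi)
  fb4 <- flux_bound(kp, Cs, r_init, objective = 6, cap_index = 1,
                    cap_value = 1)
  expect_equal(fb4$value, 2, tolerance = 1e-9)
})

test_that("flux bounds translate into concentration bounds", {
  # identity mass-action law
  expect_equal(invert_rate_law(list(type = "mass_action", k = 1), 3)$concentration, 3)
  # saturating law R(c) = c / (0.1 c + 1): flux 3 -> c = 3 / 0.7
  mm <- invert_rate_law(list(type = "michaelis_menten", a = 1, b = 0.1), 3)
  expect_true(mm$reachable)
  expect_equal(mm$concentration, 3 / 0.7, tolerance = 1e-12)
  # beyond the supremum a/b = 10 the bound is unreachable
  un <- invert_rate_law(list(type = "michaelis_menten", a = 1, b = 0.1), 10)
  expect_false(un$reachable)
})
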