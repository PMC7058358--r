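test_that("conservation analysis of the modification cycle", {
  net <- fixture("ptm_full")
  ca <- conservation_analysis(net)
  expect_equal(ncol(ca$left_kernel), 3L)
  expect_true(ca$is_conservative)
  # the three published moiety pools: E+SE, F+S+F, S+SE+S(+)+S+F
  want <- list(c(0, 1, 1, 0, 0, 0), c(0, 0, 0, 0, 1, 1),
               c(1, 0, 1, 1, 0, 1))
  for (w in want) {
    # w must lie in the span of the nonnegative laws
    fit <- qr.solve(ca$nonneg_laws, w)
    expect_lt(max(abs(ca$nonneg_laws %*% fit - w)), 1e-9)
  }
  # positive steady-state flux exists and is an exact kernel vector
  expect_false(is.null(ca$positive_flux))
  expect_lt(max(abs(net$Gamma %*% ca$positive_flux)), 1e-9)
  expect_true(all(ca$positive_flux >= 1))
})

test_that("A -> B has one law and no positive flux", {
  ca <- conservation_analysis(a2b())
  expect_equal(ncol(ca$left_kernel), 1L)
  expect_equal(abs(unname(ca$left_kernel[, 1])), c(1, 1))
  expect_null(ca$positive_flux)
})

test_that("deficiency values of the benchmark networks", {
  expect_equal(deficiency(fixture("transcription"))$deficiency, 1L)
  expect_equal(deficiency(fixture("enzymatic_cycle"))$deficiency, 1L)
  expect_equal(deficiency(fixture("kinetic_proofreading", N = 2))$deficiency, 0L)
  expect_equal(deficiency(fixture("ptm_full"))$deficiency, 1L)
  d <- deficiency(ab_rev())
  expect_equal(d$n_complexes, 2L)
  expect_equal(d$n_linkage, 1L)
  expect_equal(d$rank, 1L)
  expect_equal(d$deficiency, 0L)
  # the distinct-enzyme cascade has deficiency n
  expect_equal(deficiency(fixture("multisite_distinct", n = 2))$deficiency, 2L)
})

test_that("deficiency is nonnegative on random small networks", {
  set.seed(402)
  for (t in 1:1000) {
    net <- random_network(n = sample(2:6, 1), nu = sample(1:6, 1))
    expect_gte(deficiency(net)$deficiency, 0L)
  }
})

test_that("extremals of the reduced cycle equal the six printed matrices", {
  ex <- extremals(fixture("ptm_reduced"))
  want <- ptm_reduced_extremals()
  expect_equal(length(ex$Qs), 6L)
  for (l in 1:6) expect_equal(unname(ex$Qs[[l]]), want[[l]])
})

test_that("extremal count equals nnz(A); rank-one structure", {
  for (nm in c("ptm_full", "transcription", "erk_rkip", "ribosome_flow")) {
    net <- fixture(nm)
    ex <- extremals(net)
    expect_equal(nrow(ex$pairs), sum(net$A > 0))
    for (l in seq_along(ex$Qs)) {
      Q <- ex$Qs[[l]]
      expect_lte(qr(Q)$rank, 1L)
      j <- ex$pairs[l, 1]; i <- ex$pairs[l, 2]
      expect_equal(unname(Q[j, ]), unname(net$Gamma[i, ]))
      expect_true(all(Q[-j, ] == 0))
    }
  }
  exab <- extremals(a2b())
  expect_equal(unname(exab$Qs[[1]]), matrix(-1, 1, 1))
})

test_that("pair-weighted extremal sum reproduces the analytic Jacobian", {
  set.seed(7)
  for (nm in c("ptm_full", "kinetic_proofreading")) {
    net <- fixture(nm)
    kin <- make_kinetics(net, "mass_action", k = runif(ncol(net$Gamma), 0.5, 2))
    x <- runif(nrow(net$Gamma), 0.5, 3)
    rho <- kin$rho(x)
    Jx <- jacobian_at(net, rho)$J_x
    # finite differences of Gamma R(x)
    h <- 1e-6
    Jfd <- vapply(seq_along(x), function(i) {
      xp <- x; xp[i] <- xp[i] + h
      xm <- x; xm[i] <- xm[i] - h
      as.vector(net$Gamma %*% (kin$rate(xp) - kin$rate(xm))) / (2 * h)
    }, numeric(length(x)))
    expect_lt(max(abs(Jx - Jfd)), 1e-5)
  }
})

test_that("orientation search finds the published decompositions", {
  md <- m_decomposition(fixture("ptm_full"))
  expect_false(md$zero_flux)
  expect_equal(md$w, rep(1, 4))
  expect_equal(ncol(md$Gamma_tilde), 4L)

  expect_length(m_decomposition(fixture("multisite_distinct", n = 2),
                                all_orientations = TRUE), 0L)

  md2 <- m_decomposition(fixture("simple_binding"))
  expect_true(md2$zero_flux)
  expect_equal(ncol(null_basis_int(md2$Gamma_tilde)), 0L)
})
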