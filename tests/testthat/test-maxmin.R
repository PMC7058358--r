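test_that("Max-Min construction on the full modification cycle", {
  mm <- graphical_maxmin(fixture("ptm_full"))
  expect_s3_class(mm, "crn_maxmin")
  expect_setequal(mm$labels, c("R1-R-1", "R3-R-3", "R2", "R4"))
  expect_equal(mm$decomposition$w, rep(1, 4))
  expect_true(verify_pwl(fixture("ptm_full"), mm)$pass)
})

test_that("ribosome flow model: R set is all n+1 forward rates", {
  for (n in c(3, 5)) {
    net <- fixture("ribosome_flow", n = n)
    expect_equal(length(net$species), 2L * n)
    expect_equal(ncol(net$Gamma), n + 1L)
    mm <- graphical_maxmin(net)
    expect_s3_class(mm, "crn_maxmin")
    expect_equal(mm$labels, paste0("R", seq_len(n + 1L)))
    expect_true(verify_pwl(net, mm)$pass)
  }
})

test_that("ERK/RKIP network satisfies the graphical conditions", {
  net <- fixture("erk_rkip")
  mm <- graphical_maxmin(net)
  expect_s3_class(mm, "crn_maxmin")
  # one entry per reaction: net rates for the reversible, plain rates else
  expect_equal(length(mm$labels), 7L)
  expect_true(verify_pwl(net, mm)$pass)
})

test_that("phosphorelay and phosphotransfer networks are M-networks", {
  for (nm in list(c("phosphorelay", 3), c("phosphorelay", 4))) {
    net <- fixture(nm[1], n = as.integer(nm[2]))
    mm <- graphical_maxmin(net)
    expect_s3_class(mm, "crn_maxmin")
    expect_true(verify_pwl(net, mm)$pass)
  }
  mm2 <- graphical_maxmin(fixture("phosphotransfer_motif"))
  expect_s3_class(mm2, "crn_maxmin")
  expect_true(verify_pwl(fixture("phosphotransfer_motif"), mm2)$pass)
})

test_that("zero-flux orientations append the constant 0", {
  mm <- graphical_maxmin(fixture("simple_binding"))
  expect_s3_class(mm, "crn_maxmin")
  expect_true(mm$include_zero)
  # V = |r1 - r-1|
  r <- cbind(c(2, 1), c(1, 5))
  expect_equal(evaluate_rlf(mm, r), c(1, 4))
  mm2 <- graphical_maxmin(fixture("binding_inflow"))
  expect_s3_class(mm2, "crn_maxmin")
  expect_true(mm2$include_zero)
  expect_setequal(mm2$labels, c("R1-R-1", "R2-R-2"))
})

test_that("non-M-networks are refused with the failed condition", {
  res <- graphical_maxmin(fixture("multisite_distinct", n = 2))
  expect_identical(res$status, "conditions_not_met")
  expect_match(res$condition, "M-network")
})

test_that("Max-Min value vanishes exactly on the flux kernel", {
  net <- fixture("ptm_full")
  mm <- graphical_maxmin(net)
  ker <- crnlyap:::null_basis_int(net$Gamma)
  expect_lt(max(abs(evaluate_rlf(mm, ker))), 1e-12)
  set.seed(12)
  mix <- ker %*% matrix(rnorm(ncol(ker) * 10), ncol(ker))
  expect_lt(max(abs(evaluate_rlf(mm, mix))), 1e-12)
})
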