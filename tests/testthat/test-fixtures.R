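test_that("fixture catalog counts match the published descriptions", {
  expect_equal(length(fixture("ptm_full")$species), 6L)
  expect_equal(ncol(fixture("ptm_full")$Gamma), 6L)

  rf <- fixture("ribosome_flow", n = 3)
  expect_equal(length(rf$species), 6L)
  expect_equal(ncol(rf$Gamma), 4L)
  expect_equal(ncol(conservation_analysis(rf)$left_kernel), 3L)

  kp <- fixture("kinetic_proofreading", N = 2)
  expect_equal(kp$species, c("M", "L", "C0", "C1", "C2"))
  expect_equal(ncol(kp$Gamma), 6L)

  mc <- fixture("multisite_distinct", n = 2)
  expect_equal(length(mc$species), 11L)
  expect_equal(ncol(mc$Gamma), 12L)

  expect_equal(length(fixture("erk_rkip")$species), 11L)
  expect_equal(ncol(fixture("erk_rkip")$Gamma), 11L)

  expect_error(fixture("nonexistent"), "unknown fixture")
})

test_that("parameterized families stay valid at larger sizes", {
  # re-verify family certificates two sizes up to catch off-by-one bugs
  for (n in c(3, 5)) {
    net <- fixture("phosphorelay", n = n)
    mm <- graphical_maxmin(net)
    expect_s3_class(mm, "crn_maxmin")
    expect_true(verify_pwl(net, mm)$pass, info = paste("relay", n))
  }
  for (n in c(2, 4)) {
    net <- fixture("processive", n = n)
    mm <- graphical_maxmin(net)
    expect_s3_class(mm, "crn_maxmin")
    expect_true(verify_pwl(net, mm)$pass, info = paste("processive", n))
  }
  for (N in c(2, 4)) {
    net <- fixture("kinetic_proofreading", N = N)
    soc <- construct_soc(net)
    expect_equal(soc$xi, c(1, 1, rep(2, N + 1)), info = paste("kpr", N))
    expect_true(verify_pwl(net, soc)$pass, info = paste("kpr", N))
  }
})

test_that("every certified benchmark admits at least one verified method", {
  maxmin_list <- c("ptm_full", "three_body_binding", "enzymatic_cycle",
                   "energy_ptm_cycle", "processive", "phosphotransfer_motif",
                   "phosphotransfer_enzymes", "phosphorelay", "erk_rkip",
                   "ribosome_flow", "all_encompassing", "transcription")
  for (nm in maxmin_list) {
    net <- fixture(nm)
    mm <- graphical_maxmin(net)
    expect_s3_class(mm, "crn_maxmin")
    expect_true(verify_pwl(net, mm)$pass, info = nm)
  }
  # iterative algorithm covers the remaining motifs
  for (nm in c("enzymatic_motif", "energy_ptm_basic")) {
    net <- fixture(nm)
    it <- iterate_convex(net)
    expect_s3_class(it, "crn_pwl")
    expect_true(verify_pwl(net, it)$pass, info = nm)
  }
  # sum-of-currents covers the cascades
  mc <- fixture("multisite_distinct", n = 2)
  expect_true(verify_pwl(mc, construct_soc(mc))$pass)
})

test_that("the analyzer produces the expected verdicts", {
  rep1 <- analyze_network(fixture("ptm_full"))
  expect_identical(rep1$verdict, "attractive")
  expect_s3_class(rep1$certificate, "crn_maxmin")
  expect_length(rep1$screens$siphons$critical, 0L)
  expect_true(rep1$screens$nondegeneracy$nondegenerate)
  expect_equal(report_exit_code(rep1), 0L)

  rep2 <- analyze_network(fixture("distributive_double"))
  expect_identical(rep2$verdict, "excluded")
  expect_match(rep2$exclusion[1], "P0")
  expect_equal(report_exit_code(rep2), 1L)

  rep3 <- analyze_network(fixture("receptor_ptm_open"))
  expect_identical(rep3$verdict, "inconclusive")
  expect_identical(rep3$screens$p0$verdict, "pass")
  expect_equal(report_exit_code(rep3), 2L)
})

test_that("certificates survive a serialization round trip", {
  net <- fixture("ptm_full")
  mm <- graphical_maxmin(net)
  f <- tempfile(fileext = ".json")
  write_certificate(mm, f)
  back <- read_certificate(f)
  set.seed(9)
  r <- matrix(rnorm(18), 6)
  expect_equal(evaluate_rlf(back, r), evaluate_rlf(mm, r))
  soc <- construct_soc(net)
  write_certificate(soc, f)
  back2 <- read_certificate(f)
  expect_equal(evaluate_rlf(back2, r), evaluate_rlf(soc, r))
  unlink(f)
})
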