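test_that("the net binding rate difference is an RLF for simple binding", {
  net <- fixture("simple_binding")
  part <- build_partition(net)
  cand <- pwl_candidate(matrix(c(1, -1), 1), partition = part)
  v <- verify_pwl(net, cand)
  expect_true(v$pass)
})

test_that("a constructed violation fails with a witness", {
  net <- fixture("simple_binding")
  part <- build_partition(net)
  # r1 alone does not decrease (it vanishes only on r1 = 0, not on ker Gamma)
  cand <- pwl_candidate(matrix(c(1, 0), 1), partition = part)
  v <- verify_pwl(net, cand)
  expect_false(v$pass)
  expect_equal(v$reason, "kernel mismatch")
  # correct kernel but wrong decrease direction
  net2 <- a2b()
  cand2 <- pwl_candidate(matrix(-1, 1, 1), convex = TRUE)
  v2 <- verify_pwl(net2, cand2)
  expect_false(v2$pass)
})

test_that("the published modification-cycle sum-of-currents RLF verifies", {
  net <- fixture("ptm_full")
  cand <- onenorm_candidate(ptm_soc_published_rows())
  v <- verify_pwl(net, cand)
  expect_true(v$pass)
  # independent oracle: sampled decrease along admissible directions
  set.seed(31)
  expect_true(sampled_decrease_check(net, cand, n_samples = 10000)$pass)
  expect_true(sampled_kernel_check(net, cand)$pass)
})

test_that("facet-discontinuous regional candidates are rejected", {
  net <- fixture("transcription")
  part <- build_partition(net)
  cand <- construct_pwl_lp(net, part)
  expect_true(verify_pwl(net, cand)$pass)
  # break continuity in one region only: scale a single piece
  bad <- cand
  bad$C[1, ] <- 2 * bad$C[1, ]
  vb <- verify_pwl(net, bad)
  expect_false(vb$pass)
})

test_that("verified candidates pass the sampled decrease oracle", {
  set.seed(55)
  for (nm in c("ptm_full", "transcription", "enzymatic_motif")) {
    net <- fixture(nm)
    cand <- if (nm == "enzymatic_motif") iterate_convex(net)
            else construct_soc(net)
    expect_true(verify_pwl(net, cand)$pass, info = nm)
    expect_true(sampled_decrease_check(net, cand, n_samples = 10000)$pass,
                info = nm)
    kc <- sampled_kernel_check(net, cand)
    expect_true(kc$pass, info = nm)
  }
})
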