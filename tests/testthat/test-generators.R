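test_that("generators are deterministic under a fixed seed and emit valid
           ensembles", {
  gens <- list(
    function() genRandomClouds(P = 6, M = 3, N = 30, seed = 5),
    function() genRandomClouds(P = 6, M = 3, N = 30, center_scale = 2,
                               seed = 5),
    function() genBalls(P = 4, D = 2, N = 25, R = 0.5, M_surface = 10,
                        seed = 5)$ensemble,
    function() genSubspaces(P = 4, D = 2, N = 25, extent = 10, seed = 5),
    function() genCorrelatedClouds(P = 5, M = 3, N = 30, K = 1,
                                   seed = 5)$ensemble)
  for (g in gens) {
    e1 <- g(); e2 <- g()
    expect_identical(SummarizedExperiment::assay(e1),
                     SummarizedExperiment::assay(e2))
    expect_true(validObject(e1))
    expect_gte(nObjects(e1), 4L)
  }
})

test_that("ball samples sit exactly on the stated sphere", {
  g <- genBalls(P = 3, D = 4, N = 40, R = 0.7, M_surface = 25, seed = 7)
  for (i in 1:3) {
    X <- getSamples(g$ensemble, i)
    d <- sqrt(rowSums(sweep(X, 2, g$centers[i, ])^2))
    expect_equal(d, rep(g$radii[i], 25), tolerance = 1e-10)
    expect_equal(g$radii[i], 0.7 * sqrt(sum(g$centers[i, ]^2)),
                 tolerance = 1e-10)
    expect_lt(max(abs(crossprod(g$axes[[i]]) - diag(4))), 1e-8)
  }
  g0 <- genBalls(P = 2, D = 3, N = 20, R = 0, M_surface = 5, seed = 8)
  X <- getSamples(g0$ensemble, 1)
  expect_lt(max(abs(sweep(X, 2, g0$centers[1, ]))), 1e-12)
  expect_error(genBalls(P = 2, D = 20, N = 20, R = 1), "smaller than N")
})

test_that("subspace manifolds collapse at zero extent and lose capacity as
           they grow", {
  e0 <- genSubspaces(P = 3, D = 2, N = 30, extent = 0, seed = 9)
  X <- getSamples(e0, 1)
  expect_lt(max(abs(sweep(X, 2, colMeans(X)))), 1e-12)
  alphas <- vapply(c(0.2, 2, 20), function(ex) {
    ens <- genSubspaces(P = 20, D = 2, N = 200, extent = ex, seed = 10)
    capacity(analyzeEnsemble(ens, n_probes = 120, seed = 11))
  }, 0)
  expect_true(all(diff(alphas) < 0))
})

test_that("manifold scaling is exact about centers and collapses at 0", {
  ens <- genRandomClouds(P = 5, M = 4, N = 30, center_scale = 1, seed = 13)
  expect_equal(SummarizedExperiment::assay(scaleManifolds(ens, 1)),
               SummarizedExperiment::assay(ens), tolerance = 1e-12)
  sc <- scaleManifolds(ens, 0)
  for (id in objectIds(ens)) {
    X <- getSamples(sc, id)
    expect_lt(max(abs(sweep(X, 2, colMeans(getSamples(ens, id))))), 1e-12)
  }
  # scaling multiplies input variability linearly
  v1 <- inputVariability(ens)
  expect_equal(inputVariability(scaleManifolds(ens, 2.5)), 2.5 * v1,
               tolerance = 1e-10)
  expect_equal(inputVariability(sc), 0)
})

test_that("shuffling preserves the sample multiset and is seeded", {
  ens <- genRandomClouds(P = 5, M = 4, N = 12, center_scale = 3, seed = 17)
  sh <- shuffleAssignment(ens, seed = 18)
  a0 <- SummarizedExperiment::assay(ens)
  a1 <- SummarizedExperiment::assay(sh)
  expect_identical(dim(a1), dim(a0))
  expect_equal(a0[, order(colSums(a0))], a1[, order(colSums(a1))],
               tolerance = 1e-12)
  expect_false(identical(a0, a1))
  expect_identical(SummarizedExperiment::assay(shuffleAssignment(ens,
                                                                 seed = 18)),
                   a1)
  expect_identical(sampleCounts(sh), sampleCounts(ens))
})

test_that("center randomization moves centers but never the offsets", {
  g <- genCorrelatedClouds(P = 12, M = 5, N = 100, K = 1, strength = 4,
                           seed = 21)
  ens <- g$ensemble
  rc <- randomizeCenters(ens, seed = 22)
  for (id in objectIds(ens)) {
    X0 <- getSamples(ens, id); X1 <- getSamples(rc, id)
    expect_equal(sweep(X0, 2, colMeans(X0)), sweep(X1, 2, colMeans(X1)),
                 tolerance = 1e-9)
    expect_equal(sum(colMeans(X0)^2), sum(colMeans(X1)^2),
                 tolerance = 1e-9)
  }
  # correlations collapse to the uncorrelated null
  rho0 <- centerCorrelations(objectCenters(ens, grand_center = FALSE))
  rho1 <- centerCorrelations(objectCenters(rc, grand_center = FALSE))
  expect_gt(rho0, 0.5)
  expect_lt(rho1, 5 * sqrt(2 / (pi * 100)))
})

test_that("shuffling collapses structured clouds onto matched random
           clouds", {
  ens <- genRandomClouds(P = 40, M = 5, N = 500, center_scale = 1.5,
                         seed = 31)
  sh <- shuffleAssignment(ens, seed = 32)
  r_sh <- analyzeEnsemble(sh, n_probes = 150, seed = 33)
  # the iid-cloud reference with matched counts (same finite-M regime)
  ref <- genRandomClouds(P = 40, M = 5, N = 500, seed = 34)
  r_ref <- analyzeEnsemble(ref, n_probes = 150, seed = 33)
  expect_lt(abs(capacity(r_sh) - capacity(r_ref)) / capacity(r_ref), 0.10)
  g1 <- manifoldMetrics(r_sh); g2 <- manifoldMetrics(r_ref)
  expect_lt(abs(mean(g1$R_M) - mean(g2$R_M)) / mean(g2$R_M), 0.10)
  expect_lt(abs(mean(g1$D_M) - mean(g2$D_M)) / mean(g2$D_M), 0.10)
})

test_that("measured cloud geometry recovers the analytic baselines", {
  # the D_M = pi M / (2 (pi - 1)) baseline is asymptotic in M; at M = 10
  # the finite-M deficit is well inside the 10% band
  ens <- genRandomClouds(P = 50, M = 10, N = 1000, seed = 41)
  r <- analyzeEnsemble(ens, n_probes = 150, seed = 42)
  bl <- randomBaselines(10)
  expect_lt(abs(capacity(r) - bl$alpha) / bl$alpha, 0.10)
  pm <- manifoldMetrics(r)
  expect_lt(abs(mean(pm$R_M) - bl$R_M) / bl$R_M, 0.10)
  expect_lt(abs(mean(pm$D_M) - bl$D_M) / bl$D_M, 0.10)
})

test_that("input variability matches its construction on known offsets", {
  withr::with_seed(51, {
    N <- 80
    ctr <- rnorm(N); ctr <- 5 * sqrt(N) * ctr / sqrt(sum(ctr^2))
    offs <- matrix(rnorm(6 * N), 6, N)
    offs <- sweep(offs, 2, colMeans(offs))      # exactly centered
    ens <- ActivationEnsemble(list(a = sweep(offs, 2, -ctr),
                                   b = sweep(2 * offs, 2, -ctr)))
    v <- inputVariability(ens)
    expected <- mean(c(1, 2)) * sqrt(mean(rowSums(offs^2))) /
      sqrt(sum(ctr^2))
    expect_equal(v, expected, tolerance = 1e-10)
  })
})
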