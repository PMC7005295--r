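test_that("center correlations hit their exact extremes", {
  expect_equal(centerCorrelations(diag(4)[1:3, ]), 0)
  ctr <- c(1, 2, -1)
  expect_equal(centerCorrelations(rbind(ctr, 2 * ctr, 0.5 * ctr)), 1)
  expect_error(centerCorrelations(rbind(ctr)), "two centers")
  expect_error(centerCorrelations(rbind(ctr, 0 * ctr)), "zero-norm")
})

test_that("iid Gaussian centers match the Monte-Carlo |cos| null", {
  withr::with_seed(7, {
    cs <- matrix(rnorm(50 * 1000), 50, 1000)
    rho <- centerCorrelations(cs)
    # brute-force sampling oracle: the cosine of two random directions in
    # R^N is exactly z1 / sqrt(z1^2 + chi2_{N-1})
    z1 <- rnorm(1e5)
    z <- abs(z1 / sqrt(z1^2 + rchisq(1e5, df = 999)))
    expect_lt(abs(rho - mean(z)), 3 * (sd(z) / sqrt(length(z)) +
                                         sd(z) / sqrt(choose(50, 2))))
  })
})

test_that("axes alignment detects shared axes and respects rotations", {
  withr::with_seed(9, {
    N <- 60
    shared <- rnorm(N); shared <- shared / sqrt(sum(shared^2))
    mk <- function() {
      ctr <- rnorm(N) * 3
      buildFrame(rbind(ctr + shared, ctr - shared))
    }
    frames <- list(a = mk(), b = mk())
    expect_equal(axesAlignment(frames, k_axes = 1), 1)
    # random frames sit at the N-dimensional |cos| null
    rf <- lapply(1:6, function(i) randomManifoldFrame(M = 7, N = 200))
    names(rf) <- letters[1:6]
    al <- axesAlignment(rf, k_axes = 3)
    expect_lt(al, 3 * sqrt(2 / (pi * 200)))
    expect_gt(al, 0)
    # a common rotation changes nothing
    Q <- qr.Q(qr(matrix(rnorm(200 * 200), 200)))
    rfq <- lapply(rf, function(f) {
      new("ManifoldFrame", center = drop(Q %*% f@center),
          centerNorm = f@centerNorm, axes = Q %*% f@axes,
          coords = f@coords, S = f@S)
    })
    expect_equal(axesAlignment(rfq, k_axes = 3), al, tolerance = 1e-10)
    expect_error(axesAlignment(rf, k_axes = 10), "axes")
  })
})

test_that("a planted single common component is recovered", {
  withr::with_seed(21, {
    N <- 300; P <- 40
    u <- rnorm(N); u <- u / sqrt(sum(u^2))
    centers <- outer(5 + abs(rnorm(P)), u) + matrix(rnorm(P * N) * 0.3, P, N)
    # the residual cannot drop below the null cosine floor sqrt(2/(pi N)),
    # ~0.046 here, so the target must sit above it
    cc <- fitCommonComponents(centers, K = "auto", residual_target = 0.06)
    expect_identical(cc@K, 1L)
    expect_gt(abs(sum(cc@U[, 1] * u)), 0.99)
    expect_lte(cc@residualOffdiag, 0.06)
  })
})

test_that("orthogonal centers need no common components", {
  cs <- diag(6)[1:5, ] * 3
  cc <- fitCommonComponents(cs, K = "auto", residual_target = 0.05)
  expect_identical(cc@K, 0L)
  expect_identical(ncol(cc@U), 0L)
})

test_that("a planted rank-2 structure is recovered within 5 degrees", {
  withr::with_seed(31, {
    N <- 400; P <- 50
    U0 <- randomFrameAxes(N, 2)
    # distinct, sign-diverse weights keep the planted plane well-conditioned
    W <- cbind(sample(c(-1, 1), P, TRUE) * (4 + abs(rnorm(P))),
               sample(c(-1, 1), P, TRUE) * (2 + abs(rnorm(P))))
    centers <- W %*% t(U0) + matrix(rnorm(P * N) * 0.05, P, N)
    cc <- fitCommonComponents(centers, K = 2)
    expect_identical(cc@K, 2L)
    # principal angles between the recovered and planted planes
    sv <- svd(crossprod(cc@U, U0))$d
    angles <- acos(pmin(sv, 1)) * 180 / pi
    expect_lt(max(angles), 5)
  })
})

test_that("projection removes the common span and is an idempotent
           contraction", {
  withr::with_seed(41, {
    g <- genCorrelatedClouds(P = 15, M = 4, N = 120, K = 2, strength = 2,
                             seed = 43)
    ens <- g$ensemble
    cc <- fitCommonComponents(objectCenters(ens), K = 2)
    pe <- projectOut(ens, cc)
    ctr <- objectCenters(pe)
    expect_lt(max(abs(ctr %*% cc@U)),
              1e-8 * max(sqrt(rowSums(objectCenters(ens)^2))))
    pe2 <- projectOut(pe, cc)
    expect_equal(SummarizedExperiment::assay(pe2),
                 SummarizedExperiment::assay(pe), tolerance = 1e-12)
    expect_true(all(colSums(SummarizedExperiment::assay(pe)^2) <=
                      colSums(SummarizedExperiment::assay(ens)^2) + 1e-9))
    # K = 0 is the identity
    cc0 <- fitCommonComponents(diag(120)[1:5, ], K = 0)
    expect_identical(projectOut(ens, cc0), ens)
    # planted correlations drop
    expect_lt(centerCorrelations(ctr), centerCorrelations(ens))
  })
})

test_that("decorrelation leaves uncorrelated ensembles unchanged and
           lowers inflated capacity estimates", {
  ens <- genRandomClouds(P = 30, M = 4, N = 250, center_scale = 1,
                         seed = 51)
  r0 <- analyzeEnsemble(ens, n_probes = 120, seed = 52)
  rc <- correctedCapacity(ens, n_probes = 120, seed = 52,
                          residual_target = 0.06)
  expect_lte(reportSettings(rc)$K, 2)
  expect_lt(abs(capacity(rc) - capacity(r0)) / capacity(r0), 0.12)
  # forcing K = 0 reproduces the uncorrected analysis exactly
  rk0 <- analyzeEnsemble(ens, n_probes = 120, seed = 52,
                         correlation_correction = TRUE, K = 0)
  expect_identical(capacity(rk0), capacity(r0))
  # a strong planted component inflates the naive estimate; the corrected
  # one is lower (centers shrink, normalized radii grow)
  g <- genCorrelatedClouds(P = 30, M = 4, N = 250, K = 1, strength = 4,
                           seed = 53)
  rn <- analyzeEnsemble(g$ensemble, n_probes = 120, seed = 54)
  rcc <- correctedCapacity(g$ensemble, n_probes = 120, seed = 54,
                           residual_target = 0.07)
  expect_gte(reportSettings(rcc)$K, 1)
  expect_lt(capacity(rcc), capacity(rn))
})

test_that("fitting is invariant to relabeling and global rotation", {
  withr::with_seed(61, {
    N <- 150
    g <- genCorrelatedClouds(P = 20, M = 3, N = N, K = 1, strength = 3,
                             seed = 62)
    cs <- objectCenters(g$ensemble)
    cc1 <- fitCommonComponents(cs, K = 1)
    cc2 <- fitCommonComponents(cs[sample(20), ], K = 1)
    expect_gt(abs(sum(cc1@U * cc2@U)), 1 - 1e-6)
    Q <- qr.Q(qr(matrix(rnorm(N * N), N)))
    cc3 <- fitCommonComponents(cs %*% t(Q), K = 1)
    expect_gt(abs(sum((Q %*% cc1@U) * cc3@U)), 1 - 1e-6)
  })
})
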