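test_that("the text container round-trips an ensemble", {
  ens <- genRandomClouds(P = 4, M = 3, N = 15, center_scale = 1, seed = 3)
  path <- withr::local_tempdir()
  saveEnsemble(ens, file.path(path, "ens"))
  back <- loadEnsemble(file.path(path, "ens"))
  expect_identical(objectIds(back), objectIds(ens))
  expect_identical(sampleCounts(back), sampleCounts(ens))
  expect_equal(SummarizedExperiment::assay(back),
               SummarizedExperiment::assay(ens), tolerance = 1e-12)
  expect_error(saveEnsemble(ens, file.path(path, "ens")), "exists")
  expect_silent(saveEnsemble(ens, file.path(path, "ens"),
                             overwrite = TRUE))
})

test_that("malformed containers are rejected with the offending object", {
  ens <- genRandomClouds(P = 3, M = 2, N = 8, seed = 5)
  path <- withr::local_tempdir()
  dir <- file.path(path, "bad")
  saveEnsemble(ens, dir)
  # ragged N
  files <- jsonlite::read_json(file.path(dir, "manifest.json"),
                               simplifyVector = TRUE)$files
  x <- as.matrix(data.table::fread(file.path(dir, files[2])))
  data.table::fwrite(data.table::as.data.table(x[, 1:5]),
                     file.path(dir, files[2]), sep = "\t",
                     col.names = FALSE)
  expect_error(loadEnsemble(dir), "cloud002")
  # NaN entries
  saveEnsemble(ens, dir, overwrite = TRUE)
  x[1, 1] <- NaN
  data.table::fwrite(data.table::as.data.table(x),
                     file.path(dir, files[2]), sep = "\t",
                     col.names = FALSE)
  expect_error(loadEnsemble(dir), "non-finite")
  expect_error(loadEnsemble(file.path(path, "nowhere")), "manifest")
})

test_that("feature budgets subsample or project reproducibly", {
  ens <- genRandomClouds(P = 6, M = 3, N = 50, seed = 7)
  s1 <- subsampleFeatures(ens, 20, mode = "subsample", seed = 8)
  s2 <- subsampleFeatures(ens, 20, mode = "subsample", seed = 8)
  expect_identical(SummarizedExperiment::assay(s1),
                   SummarizedExperiment::assay(s2))
  expect_identical(nFeatures(s1), 20L)
  # n = N subsampling is a permutation of the features
  sN <- subsampleFeatures(ens, 50, mode = "subsample", seed = 9)
  a0 <- SummarizedExperiment::assay(ens)
  aN <- SummarizedExperiment::assay(sN)
  expect_equal(a0[order(a0[, 1]), ], aN[order(aN[, 1]), ],
               tolerance = 1e-12)
  p1 <- subsampleFeatures(ens, 20, mode = "project", seed = 10)
  expect_identical(nFeatures(p1), 20L)
  expect_error(subsampleFeatures(ens, 60), "exceeds")
})

test_that("projection and subsampling budgets give consistent capacity on
           dense ensembles", {
  ens <- genRandomClouds(P = 40, M = 3, N = 800, seed = 11)
  a_proj <- capacity(analyzeEnsemble(
    subsampleFeatures(ens, 400, mode = "project", seed = 12),
    n_probes = 120, seed = 13))
  a_sub <- capacity(analyzeEnsemble(
    subsampleFeatures(ens, 400, mode = "subsample", seed = 12),
    n_probes = 120, seed = 13))
  a_full <- capacity(analyzeEnsemble(ens, n_probes = 120, seed = 13))
  expect_lt(abs(a_proj - a_sub) / a_full, 0.10)
  expect_lt(abs(a_proj - a_full) / a_full, 0.10)
})

test_that("the pipeline runs end-to-end, deterministically, from a config", {
  out_dir <- withr::local_tempdir()
  cfg <- list(synth = list(generator = "random_clouds", P = 30, M = 4,
                           N = 300),
              mean_field = TRUE, numerical = FALSE, n_probes = 100,
              seed = 17L, output_dir = out_dir)
  res1 <- runPipeline(cfg)
  expect_lt(abs(capacity(res1[[1]]$capacity) - 0.5) / 0.5, 0.15)
  expect_true(file.exists(file.path(out_dir, "synth_meanfield.json")))
  js <- jsonlite::read_json(file.path(out_dir, "synth_meanfield.json"))
  expect_equal(js$alpha_c, capacity(res1[[1]]$capacity))
  # bit-identical rerun
  res2 <- runPipeline(cfg)
  expect_identical(capacity(res1[[1]]$capacity),
                   capacity(res2[[1]]$capacity))
  expect_identical(res1[[1]]$correlation@rhoCC, res2[[1]]$correlation@rhoCC)
  # config errors are clean
  expect_error(runPipeline(list(mean_field = TRUE)), "config error")
  expect_error(runPipeline(list(input = file.path(out_dir, "nope"))),
               "manifest")
})

test_that("a YAML config round-trips through the reader", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("synth:", "  generator: random_clouds", "  P: 10",
               "  M: 2", "  N: 40", "seed: 3", "n_probes: 25"), path)
  cfg <- readRunConfig(path)
  expect_identical(cfg$seed, 3L)
  expect_identical(cfg$synth$generator, "random_clouds")
  res <- runPipeline(cfg)
  expect_s4_class(res[[1]]$capacity, "CapacityReport")
})

test_that("layer sweeps report telescoping deltas", {
  path <- withr::local_tempdir()
  e1 <- genRandomClouds(P = 15, M = 3, N = 120, seed = 21)
  e2 <- scaleManifolds(e1, 2)
  e3 <- scaleManifolds(e1, 4)
  saveEnsemble(e1, file.path(path, "l1"))
  saveEnsemble(e2, file.path(path, "l2"))
  saveEnsemble(e3, file.path(path, "l3"))
  cfg <- list(inputs = list(pixel = file.path(path, "l1"),
                            mid = file.path(path, "l2"),
                            top = file.path(path, "l3")),
              n_probes = 80, seed = 23L)
  res <- runPipeline(cfg)
  d <- res$deltas
  alphas <- vapply(res[c("pixel", "mid", "top")],
                   function(r) capacity(r$capacity), 0)
  expect_equal(sum(d$d_alpha), unname(alphas["top"] - alphas["pixel"]),
               tolerance = 1e-12)
  # growing manifolds can only lose capacity
  expect_true(all(d$d_alpha <= 0))
})
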