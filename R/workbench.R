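#' Reduce the feature budget of an ensemble
#'
#' Either coordinate subsampling (a fixed random subset of features, shared
#' across objects) or a shared Gaussian random projection.  Dense
#' population codes give very similar results either way; projection is the
#' default since subsampling is fragile for very sparse responses.
#'
#' @param ens an \code{ActivationEnsemble}.
#' @param n target feature count (\eqn{\le N}).
#' @param mode \code{"project"} or \code{"subsample"}.
#' @param seed optional seed.
#' @return an \code{ActivationEnsemble} with \eqn{n} features; the mode is
#'   recorded in its metadata.
#' @export
subsampleFeatures <- function(ens, n, mode = c("project", "subsample"),
                              seed = NULL) {
  mode <- match.arg(mode)
  N <- nFeatures(ens)
  if (n > N) stop("n = ", n, " exceeds the feature count N = ", N)
  out <- if (mode == "project") {
    randomProject(ens, n, seed = seed)
  } else {
    keep <- if (is.null(seed)) sample.int(N, n) else
      withr::with_seed(seed, sample.int(N, n))
    a <- SummarizedExperiment::assay(ens, "activations")[keep, ,
                                                         drop = FALSE]
    ActivationEnsemble(a,
                       object = SummarizedExperiment::colData(ens)$object,
                       metadata = S4Vectors::metadata(ens))
  }
  md <- S4Vectors::metadata(out)
  md$feature_budget <- list(n = n, mode = mode, seed = seed)
  S4Vectors::metadata(out) <- md
  out
}

#' Read a pipeline run configuration
#'
#' YAML configuration for [runPipeline()].  Recognized fields: \code{input}
#' (container path) or \code{synth} (generator name + parameters), optional
#' \code{inputs} (named list of containers for a layer sweep),
#' \code{perturb} (list: \code{scale}, \code{shuffle},
#' \code{randomize_centers}), \code{features} (\code{n}, \code{mode}),
#' toggles \code{mean_field}, \code{numerical},
#' \code{correlation_correction}, numeric knobs \code{n_probes},
#' \code{n_dichotomies}, \code{residual_target}, \code{seed} (master seed)
#' and \code{output_dir}.
#'
#' @param path YAML file.
#' @return a validated config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- .fixYamlN(yaml::read_yaml(path))
  .validateConfig(cfg)
}

# YAML 1.1 parses a bare key `N:` as the boolean FALSE; map it back (no
# field of the run schema is legitimately named FALSE)
.fixYamlN <- function(x) {
  if (!is.list(x)) return(x)
  names(x)[names(x) %in% c("FALSE", "no")] <- "N"
  lapply(x, .fixYamlN)
}

.validateConfig <- function(cfg) {
  defaults <- list(mean_field = TRUE, numerical = FALSE,
                   correlation_correction = FALSE, n_probes = 100,
                   n_dichotomies = 101, residual_target = 0.05,
                   seed = 1L, output_dir = NULL, grand_center = TRUE)
  cfg <- modifyList(defaults, cfg)
  has_input <- !is.null(cfg$input) || !is.null(cfg$inputs) ||
    !is.null(cfg$synth)
  if (!has_input)
    stop("config error: one of 'input', 'inputs' or 'synth' is required")
  if (!is.null(cfg$synth) && is.null(cfg$synth$generator))
    stop("config error: synth block needs a 'generator' field")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.synthFromConfig <- function(synth, seed) {
  gen <- synth$generator
  args <- synth[setdiff(names(synth), "generator")]
  args$seed <- if (is.null(args$seed)) seed else args$seed
  fn <- switch(gen,
               random_clouds = genRandomClouds,
               balls = function(...) genBalls(...)$ensemble,
               subspaces = genSubspaces,
               correlated_clouds = function(...)
                 genCorrelatedClouds(...)$ensemble,
               affine_images = genAffineImageManifolds,
               stop("config error: unknown generator '", gen, "'"))
  do.call(fn, args)
}

#' Run the full analysis pipeline
#'
#' Chains the stages of a run: load or synthesize the ensemble(s), apply
#' optional perturbations (scaling, shuffling, center randomization) and a
#' feature budget, then the requested analyses -- correlation report,
#' mean-field capacity (optionally after center decorrelation) and
#' numerical capacity.  One master seed is fanned deterministically into
#' per-stage streams, so a rerun with the same config is bit-identical.
#' With multiple \code{inputs} (a layer sweep) consecutive deltas of
#' capacity, \eqn{R_M}, \eqn{D_M} and \eqn{\rho_{CC}} are reported.
#'
#' @param config a config list from [readRunConfig()] (or an equivalent
#'   list).
#' @return a list with one element per layer (each holding the ensemble
#'   label, \code{capacity} report, \code{correlation} report and optional
#'   \code{numerical} result) plus \code{deltas} for sweeps; JSON/CSV
#'   outputs are written when \code{output_dir} is set.
#' @export
runPipeline <- function(config) {
  cfg <- .validateConfig(config)
  seeds <- .fanSeeds(cfg$seed, 16L)
  layers <- if (!is.null(cfg$inputs)) {
    lapply(cfg$inputs, loadEnsemble)
  } else if (!is.null(cfg$input)) {
    list(run = loadEnsemble(cfg$input))
  } else {
    list(synth = .synthFromConfig(cfg$synth, seeds[[1]]))
  }
  if (is.null(names(layers)))
    names(layers) <- sprintf("layer%02d", seq_along(layers))
  out <- vector("list", length(layers))
  names(out) <- names(layers)
  for (i in seq_along(layers)) {
    ens <- layers[[i]]
    if (!is.null(cfg$perturb)) {
      pb <- cfg$perturb
      if (!is.null(pb$scale)) ens <- scaleManifolds(ens, pb$scale)
      if (isTRUE(pb$shuffle)) ens <- shuffleAssignment(ens, seeds[[2]])
      if (isTRUE(pb$randomize_centers))
        ens <- randomizeCenters(ens, seeds[[3]])
    }
    if (!is.null(cfg$features))
      ens <- subsampleFeatures(ens, cfg$features$n,
                               mode = cfg$features$mode %||% "project",
                               seed = seeds[[4]])
    res <- list(label = names(layers)[i],
                P = nObjects(ens), N = nFeatures(ens))
    res$correlation <- correlationReport(ens,
                                         grand_center = cfg$grand_center)
    if (isTRUE(cfg$mean_field))
      res$capacity <- analyzeEnsemble(
        ens, n_probes = cfg$n_probes, seed = seeds[[5]],
        grand_center = cfg$grand_center,
        correlation_correction = isTRUE(cfg$correlation_correction),
        residual_target = cfg$residual_target)
    if (isTRUE(cfg$numerical))
      res$numerical <- findCapacity(ens, n_dichotomies = cfg$n_dichotomies,
                                    seed = seeds[[6]])
    out[[i]] <- res
  }
  if (length(out) > 1L) {
    grab <- function(f) vapply(out, f, 0)
    alpha <- grab(function(r) if (is.null(r$capacity)) NA_real_ else
      capacity(r$capacity))
    rM <- grab(function(r) if (is.null(r$capacity)) NA_real_ else
      mean(manifoldMetrics(r$capacity)$R_M))
    dM <- grab(function(r) if (is.null(r$capacity)) NA_real_ else
      mean(manifoldMetrics(r$capacity)$D_M))
    rho <- grab(function(r) r$correlation@rhoCC)
    out$deltas <- data.frame(
      from = names(layers)[-length(layers)], to = names(layers)[-1],
      d_alpha = diff(alpha), d_R_M = diff(rM), d_D_M = diff(dM),
      d_rho_CC = diff(rho))
  }
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(out), "deltas")) {
      r <- out[[nm]]
      if (!is.null(r$capacity))
        writeCapacityReport(r$capacity,
                            file.path(cfg$output_dir,
                                      paste0(nm, "_meanfield")))
      if (!is.null(r$numerical))
        writeNumericalResult(r$numerical,
                             file.path(cfg$output_dir,
                                       paste0(nm, "_numerical")))
      jsonlite::write_json(
        list(label = nm, rho_CC = r$correlation@rhoCC,
             axes_alignment = r$correlation@axesAlignment,
             master_seed = cfg$seed),
        file.path(cfg$output_dir, paste0(nm, "_correlation.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
    }
    if (!is.null(out$deltas))
      data.table::fwrite(out$deltas,
                         file.path(cfg$output_dir, "sweep_deltas.csv"))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
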