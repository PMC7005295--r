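#' Ensemble capacity from per-manifold inverse capacities
#'
#' For a heterogeneous ensemble the classification capacity is the inverse
#' of the arithmetic mean of the per-manifold inverse capacities,
#' \eqn{\alpha_c^{-1} = \langle \alpha_\mu^{-1} \rangle_\mu}.
#'
#' @param alpha_inv numeric vector of per-manifold inverse capacities.
#' @param eps guard against division by zero for ultra-separable ensembles.
#' @return ensemble capacity \eqn{\alpha_c}; when every inverse is zero the
#'   point-manifold bound 2 is returned with a warning.
#' @export
ensembleCapacity <- function(alpha_inv, eps = 1e-12) {
  stopifnot(length(alpha_inv) >= 1, all(alpha_inv >= 0))
  m <- mean(alpha_inv)
  if (m <= eps) {
    warning("all inverse capacities are zero; reporting the alpha = 2 bound")
    return(2)
  }
  1 / m
}

#' Mean-field capacity and geometry of a whole ensemble
#'
#' Builds a frame per manifold, Monte-Carlo-solves the mean-field inner
#' problem over Gaussian probes, and reports the ensemble capacity together
#' with each manifold's effective radius \eqn{R_M}, effective dimension
#' \eqn{D_M} and total extent \eqn{R_M\sqrt{D_M}}.
#'
#' @param ens an \linkS4class{ActivationEnsemble}.
#' @param n_probes probes per manifold (default 100).
#' @param seed integer seed; per-manifold probe streams are derived from it,
#'   making the report deterministic.
#' @param grand_center subtract the grand mean activation before framing.
#' @param correlation_correction project out low-rank common components of
#'   the manifold centers first (see [fitCommonComponents()]).
#' @param K rank for the correction: \code{"auto"} or an integer.
#' @param residual_target auto-rank target for the residual off-diagonal
#'   center cosine.
#' @return a \linkS4class{CapacityReport}.
#' @examples
#' ens <- genRandomClouds(P = 20, M = 5, N = 200, seed = 1)
#' rep <- analyzeEnsemble(ens, n_probes = 50, seed = 2)
#' capacity(rep)
#' @export
analyzeEnsemble <- function(ens, n_probes = 100, seed = NULL,
                            grand_center = TRUE,
                            correlation_correction = FALSE, K = "auto",
                            residual_target = 0.05) {
  stopifnot(is(ens, "ActivationEnsemble"))
  if (nObjects(ens) < 2)
    stop("capacity needs at least P = 2 manifolds")
  settings <- list(n_probes = n_probes, seed = seed,
                   grand_center = grand_center,
                   correlation_correction = correlation_correction,
                   tolerance = 1e-10, K = 0L, residual_offdiag = NA_real_)
  if (correlation_correction) {
    cs <- objectCenters(ens, grand_center = grand_center)
    cc <- fitCommonComponents(cs, K = K, residual_target = residual_target)
    ens <- projectOut(ens, cc)
    settings$K <- cc@K
    settings$residual_offdiag <- cc@residualOffdiag
  }
  frames <- buildFrames(ens, grand_center = grand_center)
  ids <- names(frames)
  seeds <- .fanSeeds(seed, length(frames))
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    st <- .innerBatch(f, n_probes, seeds[[i]])
    use <- !st$interior & st$r2 > 1e-20  # anchors distinct from the center
    a_inv <- mean(st$F)
    R_M <- if (any(use)) sqrt(mean(st$r2[use])) else 0
    D_M <- if (any(use)) mean(st$dm[use]) else 0
    rows[[i]] <- data.frame(
      id = ids[i], M = nrow(f@S), D = frameDim(f),
      alphaInv = a_inv, stderrAlphaInv = sd(st$F) / sqrt(n_probes),
      alpha = 1 / max(a_inv, 1e-12), R_M = R_M, D_M = D_M,
      totalExtent = R_M * sqrt(D_M), nAnchors = sum(use),
      anchorless = !any(use), stringsAsFactors = FALSE)
  }
  pm <- S4Vectors::DataFrame(do.call(rbind, rows))
  alphaC <- ensembleCapacity(pm$alphaInv)
  new("CapacityReport", alphaC = alphaC, perManifold = pm,
      settings = settings)
}

#' Participation ratio of a sample matrix
#'
#' The classical covariance-eigenvalue dimensionality,
#' \eqn{PR = (\sum_i \lambda_i)^2 / \sum_i \lambda_i^2}, a complementary
#' measure of effective dimensionality.
#'
#' @param samples \eqn{M \times N} matrix, samples in rows (\eqn{M \ge 2}).
#' @return scalar in \eqn{[1, \min(M-1, N)]}.
#' @export
participationRatio <- function(samples) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2) stop("participation ratio undefined for M < 2")
  X <- sweep(samples, 2L, colMeans(samples))
  ev <- svd(X, nu = 0, nv = 0)$d^2 / (nrow(samples) - 1)
  sum(ev)^2 / sum(ev^2)
}

# deterministic fan-out of one master seed into per-unit streams
.fanSeeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
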