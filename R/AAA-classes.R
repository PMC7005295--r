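#' ActivationEnsemble: population responses grouped into object manifolds
#'
#' A \linkS4class{SummarizedExperiment} holding one real-valued activation
#' matrix (features \eqn{N} in rows, all samples of all objects in columns)
#' with a mandatory \code{object} column in \code{colData} assigning every
#' sample column to an object manifold.  Each object \eqn{\mu} contributes
#' \eqn{M_\mu \ge 1} sample vectors; all objects share the ambient feature
#' count \eqn{N}.
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso [ActivationEnsemble()] for construction from per-object matrices,
#'   [objectIds()], [getSamples()], [objectCenters()].
#' @export
setClass("ActivationEnsemble", contains = "SummarizedExperiment")

.validActivationEnsemble <- function(object) {
  msg <- NULL
  if (!("activations" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'activations' is missing")
  if (!("object" %in% colnames(SummarizedExperiment::colData(object))))
    msg <- c(msg, "colData column 'object' is missing")
  if (is.null(msg)) {
    a <- SummarizedExperiment::assay(object, "activations")
    if (!all(is.finite(a)))
      msg <- c(msg, "activations contain non-finite values")
    obj <- SummarizedExperiment::colData(object)$object
    if (anyNA(obj)) msg <- c(msg, "object assignment contains NA")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("ActivationEnsemble", .validActivationEnsemble)

#' ManifoldFrame: centered orthonormal coordinate frame of one manifold
#'
#' Decomposes the \eqn{M} samples of one manifold as
#' \code{center + axes \%*\% t(coords)}: an \eqn{N}-vector center, \eqn{D}
#' orthonormal axes spanning the variability subspace (\eqn{D} equals the
#' numerical rank of the centered sample matrix) and the \eqn{M \times D}
#' subspace coefficients.  Slot \code{S} holds the normalized sample set used
#' by the mean-field theory: each row is a sample expressed in \eqn{D+1}
#' coordinates, the first \eqn{D} being the subspace coefficients divided by
#' the center norm and the last identically 1 (the center direction).
#'
#' @slot center numeric \eqn{N}-vector.
#' @slot centerNorm non-negative scalar \eqn{\|center\|}.
#' @slot axes \eqn{N \times D} matrix with orthonormal columns.
#' @slot coords \eqn{M \times D} sample coefficients.
#' @slot S \eqn{M \times (D+1)} normalized sample set.
#' @export
setClass("ManifoldFrame",
  representation(center = "numeric", centerNorm = "numeric",
                 axes = "matrix", coords = "matrix", S = "matrix"))

.validManifoldFrame <- function(object) {
  msg <- NULL
  D <- ncol(object@axes)
  if (length(object@centerNorm) != 1L || object@centerNorm < 0)
    msg <- c(msg, "centerNorm must be a non-negative scalar")
  if (D > 0) {
    g <- crossprod(object@axes)
    if (max(abs(g - diag(D))) > 1e-8)
      msg <- c(msg, "axes are not orthonormal within 1e-8")
  }
  if (ncol(object@coords) != D)
    msg <- c(msg, "coords/axes dimension mismatch")
  if (ncol(object@S) != D + 1L || nrow(object@S) != nrow(object@coords))
    msg <- c(msg, "S must be M x (D+1)")
  if (nrow(object@S) > 0 && max(abs(object@S[, D + 1L] - 1)) > 0)
    msg <- c(msg, "last coordinate of S must be exactly 1")
  if (is.null(msg)) TRUE else msg
}
setValidity("ManifoldFrame", .validManifoldFrame)

#' CapacityReport: ensemble capacity and per-manifold geometry
#'
#' @slot alphaC ensemble classification capacity (inverse of the mean
#'   per-manifold inverse capacity).
#' @slot perManifold \code{DataFrame} with one row per manifold: id, M, D,
#'   alphaInv, stderrAlphaInv, alpha, R_M, D_M, totalExtent, nAnchors,
#'   anchorless flag.
#' @slot settings list of estimator settings (probe count, seed, tolerance,
#'   correlation correction on/off, K used, residual off-diagonal cosine).
#' @export
setClass("CapacityReport",
  representation(alphaC = "numeric", perManifold = "DataFrame",
                 settings = "list"))

#' CommonComponents: low-rank shared structure of manifold centers
#'
#' Orthonormal directions \eqn{u_1 \ldots u_K} shared across manifold
#' centers; projecting the ensemble onto their null space renders the center
#' correlation matrix approximately diagonal.
#'
#' @slot U \eqn{N \times K} matrix with orthonormal columns.
#' @slot K integer rank.
#' @slot residualOffdiag mean absolute off-diagonal center cosine after
#'   projecting out \code{U}.
#' @slot converged logical; \code{FALSE} when the rank cap was reached before
#'   the residual target.
#' @export
setClass("CommonComponents",
  representation(U = "matrix", K = "integer", residualOffdiag = "numeric",
                 converged = "logical"))

.validCommonComponents <- function(object) {
  msg <- NULL
  if (ncol(object@U) != object@K) msg <- c(msg, "ncol(U) != K")
  if (object@K > 0) {
    g <- crossprod(object@U)
    if (max(abs(g - diag(object@K))) > 1e-8)
      msg <- c(msg, "U not orthonormal within 1e-8")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("CommonComponents", .validCommonComponents)

#' CorrelationReport: inter-manifold correlation summary
#'
#' @slot rhoCC mean absolute pairwise cosine between manifold centers.
#' @slot axesAlignment mean absolute cosine between leading variability axes
#'   of manifold pairs.
#' @slot pairwise optional \eqn{P \times P} matrix of absolute center
#'   cosines (empty unless requested).
#' @export
setClass("CorrelationReport",
  representation(rhoCC = "numeric", axesAlignment = "numeric",
                 pairwise = "matrix"))

#' NumericalCapacityResult: capacity measured by separability experiments
#'
#' @slot nC the 50\%-crossing projected dimension.
#' @slot alpha numerical capacity \eqn{P / n_C}.
#' @slot curve data.frame of the separability curve: n, fraction, stderr,
#'   nTrials.
#' @slot settings list (dichotomy count, seed, brackets, flags).
#' @export
setClass("NumericalCapacityResult",
  representation(nC = "numeric", alpha = "numeric", curve = "data.frame",
                 settings = "list"))
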