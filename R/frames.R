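#' Build the normalized coordinate frame of one manifold
#'
#' Centers the samples, extracts the orthonormal axes of variability (via
#' SVD, keeping singular values above \code{1e-10} of the largest, so \eqn{D}
#' is the numerical rank of the centered sample matrix) and forms the
#' normalized \eqn{D+1}-coordinate sample set \eqn{S}: subspace coefficients
#' divided by the center norm, plus a final coordinate fixed at 1 for the
#' center direction.  These are the coordinates in which the mean-field
#' inner problem is posed.
#'
#' @param samples \eqn{M \times N} matrix, samples in rows.
#' @param grand_center optional \eqn{N}-vector subtracted from all samples
#'   before centering (the ensemble grand mean).
#' @param rank_tol relative singular-value threshold defining \eqn{D}.
#' @return a \linkS4class{ManifoldFrame}.
#' @examples
#' f <- buildFrame(matrix(rnorm(50), 5, 10))
#' ncol(frameAxes(f))   # D = 4 for 5 generic samples
#' @export
buildFrame <- function(samples, grand_center = NULL, rank_tol = 1e-10) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  M <- nrow(samples)
  if (M < 1L) stop("need at least one sample")
  if (!all(is.finite(samples))) stop("samples contain non-finite values")
  if (!is.null(grand_center))
    samples <- sweep(samples, 2L, grand_center)
  center <- colMeans(samples)
  cn <- sqrt(sum(center^2))
  if (cn < 1e-12)
    stop("degenerate manifold: zero center norm, normalization undefined")
  X <- sweep(samples, 2L, center)
  if (M == 1L) {
    axes <- matrix(numeric(0), ncol(samples), 0L)
    coords <- matrix(numeric(0), 1L, 0L)
    S <- matrix(1, 1L, 1L)
  } else {
    sv <- svd(X, nu = 0)
    keep <- sv$d > rank_tol * max(sv$d, .Machine$double.xmin)
    D <- sum(keep)
    axes <- sv$v[, keep, drop = FALSE]
    coords <- X %*% axes
    S <- cbind(coords / cn, 1)
  }
  new("ManifoldFrame", center = center, centerNorm = cn, axes = axes,
      coords = coords, S = S)
}

#' @describeIn buildFrame number of variability axes \eqn{D}.
#' @param frame a \code{ManifoldFrame}.
#' @export
frameDim <- function(frame) ncol(frame@axes)

#' @describeIn buildFrame the orthonormal axes (\eqn{N \times D}).
#' @export
frameAxes <- function(frame) frame@axes

#' @describeIn buildFrame the normalized \eqn{M \times (D+1)} sample set.
#' @export
frameS <- function(frame) frame@S

#' @describeIn buildFrame manifold center in feature space.
#' @export
frameCenter <- function(frame) frame@center

#' @describeIn buildFrame reconstruct the (grand-centered) samples from the
#'   frame: \code{center + coords \%*\% t(axes)}.
#' @export
reconstructSamples <- function(frame) {
  sweep(frame@coords %*% t(frame@axes), 2L, -frame@center)
}

setMethod("show", "ManifoldFrame", function(object) {
  cat("ManifoldFrame: M =", nrow(object@S), " D =", frameDim(object),
      " |center| =", signif(object@centerNorm, 4), "\n")
})

#' Frames for every manifold of an ensemble
#'
#' @param ens an \code{ActivationEnsemble}.
#' @param grand_center subtract the ensemble grand mean before framing
#'   (default \code{TRUE}); center statistics then reflect inter-object
#'   structure rather than a shared offset.
#' @return named list of \code{ManifoldFrame}s in object order.
#' @export
buildFrames <- function(ens, grand_center = TRUE) {
  gc_vec <- if (grand_center)
    rowMeans(SummarizedExperiment::assay(ens, "activations")) else NULL
  lapply(sampleList(ens), buildFrame, grand_center = gc_vec)
}
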