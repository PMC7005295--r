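#' Mean absolute center correlation
#'
#' \eqn{\rho_{CC} = \langle |x^\mu \cdot x^\nu| / (\|x^\mu\|\|x^\nu\|)
#' \rangle_{\mu \ne \nu}}: the mean absolute cosine between manifold-center
#' pairs, the summary statistic of inter-manifold center correlations.
#'
#' @param centers \eqn{P \times N} matrix of manifold centers (typically
#'   grand-centered; see [objectCenters()]), or an
#'   \code{ActivationEnsemble}.
#' @param pairwise also return the full \eqn{P \times P} absolute-cosine
#'   matrix.
#' @return scalar in \eqn{[0, 1]}, or list(rho, pairwise) when
#'   \code{pairwise = TRUE}.
#' @export
centerCorrelations <- function(centers, pairwise = FALSE) {
  if (is(centers, "ActivationEnsemble")) centers <- objectCenters(centers)
  centers <- as.matrix(centers)
  P <- nrow(centers)
  if (P < 2) stop("need at least two centers")
  nrm <- sqrt(rowSums(centers^2))
  if (any(nrm < 1e-12)) stop("degenerate zero-norm center")
  U <- centers / nrm
  C <- abs(tcrossprod(U))
  rho <- mean(C[upper.tri(C)])
  if (pairwise) list(rho = rho, pairwise = C) else rho
}

#' Alignment of manifold variability axes
#'
#' Mean absolute cosine between the top \code{k_axes} principal variability
#' axes of every pair of manifolds (all axis pairs across each manifold
#' pair), quantifying axes correlations beyond center correlations.
#'
#' @param frames list of \linkS4class{ManifoldFrame}s (see [buildFrames()]).
#' @param k_axes leading axes per manifold to compare (default 5).
#' @return scalar in \eqn{[0, 1]}.
#' @export
axesAlignment <- function(frames, k_axes = 5) {
  stopifnot(length(frames) >= 2)
  Ds <- vapply(frames, frameDim, 0L)
  if (any(Ds < k_axes)) {
    bad <- names(frames)[which(Ds < k_axes)[1]]
    stop("manifold '", bad, "' has only ", min(Ds),
         " axes; k_axes = ", k_axes, " requested")
  }
  A <- lapply(frames, function(f) f@axes[, seq_len(k_axes), drop = FALSE])
  P <- length(A)
  tot <- 0; cnt <- 0
  for (i in seq_len(P - 1)) for (j in seq((i + 1), P)) {
    cs <- abs(crossprod(A[[i]], A[[j]]))
    tot <- tot + sum(cs); cnt <- cnt + length(cs)
  }
  tot / cnt
}

#' Recover low-rank common components of manifold centers
#'
#' Finds an orthonormal set \eqn{U \in R^{N \times K}} such that the centers
#' projected onto its null space have approximately diagonal correlation
#' structure (center correlation matrix \eqn{C = \Lambda + C_K} with
#' \eqn{C_K} of rank \eqn{K}).  The algorithm is iterative deflation: take
#' the leading singular direction of the current center matrix, project it
#' out, recompute the residual mean absolute off-diagonal cosine, and stop
#' when the residual reaches \code{residual_target} (for \code{K = "auto"})
#' or when \code{K} components have been extracted.
#'
#' @param centers \eqn{P \times N} center matrix (or an ensemble, whose
#'   grand-centered centers are used).
#' @param K \code{"auto"} (smallest rank meeting \code{residual_target},
#'   capped at \code{K_max}; deflation also stops as soon as it fails to
#'   lower the residual, since deflating uncorrelated centers merely
#'   concentrates them into fewer dimensions and raises pairwise cosines)
#'   or a fixed integer \eqn{< P}.  Note the residual cannot drop below the
#'   null cosine floor \eqn{\sqrt{2/(\pi N_{eff})}} of uncorrelated
#'   centers, so targets should sit above it.
#' @param residual_target target residual off-diagonal cosine (in (0,1)).
#' @param K_max rank cap for auto selection.
#' @return a \linkS4class{CommonComponents}; \code{converged(FALSE)} flags
#'   reaching the cap before the target.
#' @export
fitCommonComponents <- function(centers, K = "auto", residual_target = 0.05,
                                K_max = NULL) {
  if (is(centers, "ActivationEnsemble")) centers <- objectCenters(centers)
  centers <- as.matrix(centers)
  P <- nrow(centers); N <- ncol(centers)
  if (is.null(K_max)) K_max <- min(P - 1L, 20L)
  auto <- identical(K, "auto")
  if (!auto) {
    K <- as.integer(K)
    if (K >= P) stop("K must be smaller than the number of manifolds")
    K_max <- K
  }
  if (!auto && K == 0L)
    return(new("CommonComponents", U = matrix(numeric(0), N, 0L), K = 0L,
               residualOffdiag = centerCorrelations(centers),
               converged = TRUE))
  X <- centers
  U <- matrix(numeric(0), N, 0L)
  resid <- centerCorrelations(X)
  k <- 0L
  while (k < K_max && (!auto || resid > residual_target)) {
    sv <- svd(X, nu = 0, nv = 1)
    u <- sv$v[, 1]
    u <- u - if (k > 0) U %*% crossprod(U, u) else 0   # re-orthogonalize
    nu <- sqrt(sum(u^2))
    if (nu < 1e-12) break
    u <- u / nu
    X_new <- X - (X %*% u) %*% t(u)
    nrm <- sqrt(rowSums(X_new^2))
    if (any(nrm < 1e-12)) {            # centers fully explained
      U <- cbind(U, u, deparse.level = 0)
      k <- k + 1L
      X <- X_new
      resid <- 0
      break
    }
    resid_new <- centerCorrelations(X_new)
    if (auto && resid_new >= resid) break  # deflating past the noise floor
    # only concentrates uncorrelated centers; keep the smaller residual
    U <- cbind(U, u, deparse.level = 0)
    X <- X_new
    resid <- resid_new
    k <- k + 1L
  }
  conv <- if (auto) resid <= residual_target else TRUE
  if (auto && !conv) {
    why <- if (k < K_max)
      "deflation stopped improving (null cosine floor reached)" else
        paste0("rank cap K_max = ", K_max, " reached")
    warning("residual target ", residual_target, " not met: ", why,
            "; residual off-diagonal cosine ", signif(resid, 3))
  }
  new("CommonComponents", U = U, K = k, residualOffdiag = resid,
      converged = conv)
}

#' Project an ensemble onto the null space of common components
#'
#' Replaces every sample vector by its component orthogonal to
#' \eqn{span(U)}; manifold centers then satisfy \eqn{|u_k \cdot x^\mu|
#' \approx 0}.  With \eqn{K = 0} this is the identity.  The projection never
#' increases norms and is idempotent.
#'
#' @param ens an \code{ActivationEnsemble}.
#' @param cc a \linkS4class{CommonComponents} (with \eqn{N}-row \code{U}).
#' @return a projected \code{ActivationEnsemble}.
#' @export
projectOut <- function(ens, cc) {
  U <- if (is(cc, "CommonComponents")) cc@U else as.matrix(cc)
  if (ncol(U) == 0L) return(ens)
  if (nrow(U) != nFeatures(ens))
    stop("common-component dimension does not match the ensemble N")
  a <- SummarizedExperiment::assay(ens, "activations")
  a <- a - U %*% crossprod(U, a)
  .replaceActivations(ens, a)
}

#' Capacity after center decorrelation
#'
#' The full corrected pipeline: fit common components on the (grand-
#' centered) manifold centers, project the entire ensemble onto their null
#' space, then run the mean-field analysis.  The capacity of manifolds with
#' low-rank center correlations is predicted by the uncorrelated theory
#' applied to these residual manifolds.
#'
#' @inheritParams analyzeEnsemble
#' @return a \linkS4class{CapacityReport} whose settings record \code{K} and
#'   the residual off-diagonal cosine.
#' @export
correctedCapacity <- function(ens, n_probes = 100, seed = NULL,
                              grand_center = TRUE, K = "auto",
                              residual_target = 0.05) {
  analyzeEnsemble(ens, n_probes = n_probes, seed = seed,
                  grand_center = grand_center,
                  correlation_correction = TRUE, K = K,
                  residual_target = residual_target)
}

#' Correlation summary of an ensemble
#'
#' @param ens an \code{ActivationEnsemble}.
#' @param k_axes leading axes per manifold for the alignment statistic; use
#'   0 to skip (reported as \code{NA}, e.g. for point manifolds).
#' @param pairwise retain the full pairwise \eqn{|cos|} matrix.
#' @param grand_center subtract the grand mean before computing centers.
#' @return a \linkS4class{CorrelationReport}.
#' @export
correlationReport <- function(ens, k_axes = 5, pairwise = FALSE,
                              grand_center = TRUE) {
  cs <- objectCenters(ens, grand_center = grand_center)
  cr <- centerCorrelations(cs, pairwise = pairwise)
  rho <- if (pairwise) cr$rho else cr
  pw <- if (pairwise) cr$pairwise else matrix(numeric(0), 0, 0)
  aa <- NA_real_
  if (k_axes > 0) {
    frames <- buildFrames(ens, grand_center = grand_center)
    k_use <- min(k_axes, min(vapply(frames, frameDim, 0L)))
    aa <- if (k_use >= 1) axesAlignment(frames, k_axes = k_use) else
      NA_real_
  }
  new("CorrelationReport", rhoCC = rho, axesAlignment = aa, pairwise = pw)
}
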