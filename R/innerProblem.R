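#' Draw a Gaussian probe for the mean-field inner problem
#'
#' The probe \eqn{T} is a \eqn{D+1}-vector with i.i.d. standard normal
#' entries; it represents the net field exerted on one manifold's subspace by
#' the anchor points of all other manifolds near capacity.  Its last entry
#' (\code{T0}) lies along the center direction, the first \eqn{D}
#' (\code{deltaT}) along the variability axes.
#'
#' @param D number of variability axes of the probed frame.
#' @param seed optional integer seed for reproducibility.
#' @return list with components \code{T} (length \eqn{D+1}), \code{T0},
#'   \code{deltaT}.
#' @export
sampleProbe <- function(D, seed = NULL) {
  stopifnot(D >= 0)
  Tvec <- if (is.null(seed)) rnorm(D + 1) else
    withr::with_seed(seed, rnorm(D + 1))
  list(T = Tvec, T0 = Tvec[D + 1], deltaT = Tvec[seq_len(D)])
}

#' Solve the mean-field inner problem for one probe
#'
#' Minimizes \eqn{\|V - T\|^2} over signed fields \eqn{V} subject to
#' \eqn{V \cdot s \ge 0} for every row \eqn{s} of the normalized sample set
#' \eqn{S} -- the constraint that every manifold point falls on the correct
#' side of the separating plane.  Since the convex hull of finitely many
#' points is vertex-generated, constraining the sample rows suffices.  The
#' problem is solved exactly through its dual, a non-negative least-squares
#' problem in the constraint multipliers: \eqn{V = T + S^\top\lambda}.
#'
#' When the objective \eqn{F > 0}, the active multipliers define the anchor
#' point \eqn{\tilde s = S^\top\lambda / \sum\lambda}, the unique point of
#' the manifold's convex hull through which it touches the separating plane;
#' \eqn{T - V} is antiparallel to \eqn{\tilde s}.
#'
#' @param probe a probe from [sampleProbe()], or a bare numeric vector of
#'   length \eqn{D+1}.
#' @param frame a \linkS4class{ManifoldFrame} (or an \eqn{M \times (D+1)}
#'   normalized sample matrix).
#' @return list with elements \code{V}, \code{F}, \code{dual_weights}
#'   (length \eqn{M}), \code{anchor} (normalized \eqn{D+1} coordinates, or
#'   \code{NULL} when \eqn{F = 0}), \code{lambda} (\eqn{\|T-V\|/\|\tilde
#'   s\|}).
#' @examples
#' f <- buildFrame(matrix(rnorm(30), 3, 10))
#' sol <- solveInner(sampleProbe(frameDim(f), seed = 1), f)
#' min(frameS(f) %*% sol$V)   # feasibility: >= -1e-6
#' @export
solveInner <- function(probe, frame) {
  S <- if (is(frame, "ManifoldFrame")) frame@S else as.matrix(frame)
  Tvec <- if (is.list(probe)) probe$T else as.numeric(probe)
  if (length(Tvec) != ncol(S))
    stop("probe dimension ", length(Tvec), " does not match frame D+1 = ",
         ncol(S))
  fit <- .nnls_cpp(t(S), -Tvec)
  if (!fit$converged)
    stop("inner solver failed to converge for this probe")
  lam <- as.numeric(fit$x)
  V <- Tvec + drop(crossprod(S, lam))
  Fobj <- sum((V - Tvec)^2)
  out <- list(V = V, F = Fobj, dual_weights = lam, anchor = NULL,
              lambda = 0)
  if (Fobj > 1e-10 && sum(lam) > 0) {
    anchor <- drop(crossprod(S, lam)) / sum(lam)
    out$anchor <- anchor
    out$lambda <- sqrt(Fobj) / sqrt(sum(anchor^2))
    out$F <- Fobj
  } else {
    out$F <- if (Fobj <= 1e-10) 0 else Fobj
  }
  out
}

#' Monte-Carlo estimate of a manifold's inverse capacity
#'
#' Averages the inner-problem objective \eqn{F(T)} over independent Gaussian
#' probes; by the mean-field self-consistency, the manifold's capacity is
#' \eqn{\alpha_\mu = 1/\langle F(T)\rangle_T}.
#'
#' @param frame a \linkS4class{ManifoldFrame}.
#' @param n_probes number of probes (default 100).
#' @param seed optional seed.
#' @return list: \code{alpha_inv}, \code{stderr}, \code{F} (per-probe
#'   objectives).
#' @export
capacityInverse <- function(frame, n_probes = 100, seed = NULL) {
  stopifnot(n_probes >= 1)
  st <- .innerBatch(frame, n_probes, seed)
  list(alpha_inv = mean(st$F), stderr = sd(st$F) / sqrt(n_probes),
       F = st$F)
}

#' Anchor-point geometry of a manifold
#'
#' Runs the inner problem over Gaussian probes and summarizes the anchor
#' statistics: the effective radius \eqn{R_M^2 = \langle\|\delta\tilde
#' S(T)\|^2\rangle} (total variance of the normalized anchor points around
#' the center) and the effective dimension \eqn{D_M = \langle(\delta T \cdot
#' \hat{\delta S}(T))^2\rangle} (spread of the anchors across the manifold
#' axes, via the squared projection of the probe on the anchor direction).
#' Probes with \eqn{F = 0} (interior solutions: the manifold does not touch
#' the plane) define no anchor and are excluded from both averages, as are
#' anchors that coincide with the manifold center (\eqn{\delta\tilde S = 0},
#' e.g. every anchor of a point manifold).
#'
#' @inheritParams capacityInverse
#' @return list: \code{R_M}, \code{D_M}, \code{n_anchors}, \code{anchorless}
#'   (\code{TRUE} when no probe produced an anchor, in which case both
#'   statistics are 0), and the per-probe contributions.
#' @export
anchorStatistics <- function(frame, n_probes = 100, seed = NULL) {
  stopifnot(n_probes >= 1)
  st <- .innerBatch(frame, n_probes, seed)
  use <- !st$interior & st$r2 > 1e-20
  if (!any(use))
    return(list(R_M = 0, D_M = 0, n_anchors = 0L, anchorless = TRUE,
                r2 = st$r2, dm = st$dm))
  list(R_M = sqrt(mean(st$r2[use])), D_M = mean(st$dm[use]),
       n_anchors = sum(use), anchorless = FALSE, r2 = st$r2, dm = st$dm)
}

# shared batched probe loop; returns per-probe F, r2, dm, interior
.innerBatch <- function(frame, n_probes, seed = NULL) {
  S <- frame@S
  d1 <- ncol(S)
  draw <- function() matrix(rnorm(n_probes * d1), n_probes, d1)
  Tmat <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  res <- .inner_batch_cpp(S, Tmat, 1e-10)
  if (!all(res$converged == 1L))
    stop("inner solver failed to converge on probe(s) ",
         paste(head(which(res$converged != 1L), 5L), collapse = ", "))
  list(F = as.numeric(res$F), r2 = as.numeric(res$r2),
       dm = as.numeric(res$dm), interior = res$interior == 1L)
}
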