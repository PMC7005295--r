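#' Random point-cloud manifolds
#'
#' Generates \eqn{P} manifolds of \eqn{M} i.i.d. unit-variance Gaussian
#' sample points in \eqn{N} dimensions, optionally around planted centers of
#' norm \code{center_scale * sqrt(N)} in random directions.  With the
#' default \code{center_scale = 0} the samples are plain i.i.d. points
#' randomly grouped into manifolds -- the analytic random-manifold baseline
#' with capacity \eqn{2/M}, radius \eqn{\sqrt{\pi - 1}} and dimension
#' \eqn{\pi M / (2(\pi - 1))} (see [randomBaselines()]).
#'
#' @param P,M,N manifold count, samples per manifold, feature count.
#' @param center_scale planted-center norm in units of \eqn{\sqrt{N}}
#'   (default 0: no planted center).
#' @param seed integer seed.
#' @return an \code{ActivationEnsemble}.
#' @export
genRandomClouds <- function(P, M, N, center_scale = 0, seed = NULL) {
  stopifnot(P >= 1, M >= 1, N >= 1, center_scale >= 0)
  gen <- function() {
    lapply(seq_len(P), function(mu) {
      X <- matrix(rnorm(M * N), M, N)
      if (center_scale > 0) {
        u <- rnorm(N); u <- u / sqrt(sum(u^2))
        X <- sweep(X, 2L, -center_scale * sqrt(N) * u)
      }
      X
    })
  }
  sm <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  names(sm) <- sprintf("cloud%03d", seq_len(P))
  ActivationEnsemble(sm, metadata = list(
    generator = "random_clouds", P = P, M = M, N = N,
    center_scale = center_scale, seed = seed))
}

#' Ball manifolds with known parameters
#'
#' Each manifold is a \eqn{D}-dimensional sphere of radius
#' \eqn{R \|c_\mu\|} (radius expressed relative to the center norm, as in
#' the theory) around a random center of norm \eqn{\sqrt{N}}, sampled by
#' \code{M_surface} points uniform on the sphere within a random orthonormal
#' \eqn{D}-frame.  The exact parameters are returned alongside the samples
#' for [checkSeparableBalls()].
#'
#' @param P,D,N counts; \eqn{D < N}.
#' @param R radius relative to the center norm.
#' @param M_surface surface samples per ball.
#' @param seed integer seed.
#' @return list: \code{ensemble} (an \code{ActivationEnsemble}),
#'   \code{centers} (\eqn{P \times N}), \code{axes} (list of \eqn{N \times
#'   D}), \code{radii} (absolute).
#' @export
genBalls <- function(P, D, N, R, M_surface = 200, seed = NULL) {
  stopifnot(P >= 1, D >= 1, R >= 0, M_surface >= 1)
  if (D >= N) stop("ball dimension D must be smaller than N")
  gen <- function() {
    centers <- matrix(NA_real_, P, N)
    axes <- vector("list", P)
    sm <- vector("list", P)
    for (mu in seq_len(P)) {
      u <- rnorm(N); u <- u / sqrt(sum(u^2))
      centers[mu, ] <- sqrt(N) * u
      axes[[mu]] <- qr.Q(qr(matrix(rnorm(N * D), N, D)))
      dir <- matrix(rnorm(M_surface * D), M_surface, D)
      dir <- dir / sqrt(rowSums(dir^2))
      offs <- R * sqrt(N) * dir %*% t(axes[[mu]])
      sm[[mu]] <- sweep(offs, 2L, -centers[mu, ])
    }
    list(centers = centers, axes = axes, sm = sm)
  }
  g <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  names(g$sm) <- sprintf("ball%03d", seq_len(P))
  ens <- ActivationEnsemble(g$sm, metadata = list(
    generator = "balls", P = P, D = D, N = N, R = R,
    M_surface = M_surface, seed = seed))
  list(ensemble = ens, centers = g$centers, axes = g$axes,
       radii = rep(R * sqrt(N), P))
}

#' Subspace manifolds (unbounded-extent limit)
#'
#' Each manifold is a symmetric grid of half-width
#' \code{extent * ||center||} along \eqn{D} random orthonormal axes (full
#' factorial, \code{grid_points} per axis), approximating a \eqn{D}-
#' dimensional linear subspace with randomly oriented axes when
#' \code{extent >> 1}; in that limit the capacity is \eqn{1/(D + 1/2)}.
#' \code{extent = 0} reduces to point manifolds.
#'
#' @param P,D,N counts.
#' @param extent half-width in units of the center norm.
#' @param grid_points grid values per axis (default 3: \eqn{-e, 0, +e}).
#' @param seed integer seed.
#' @return an \code{ActivationEnsemble} with \eqn{M = grid\_points^D}.
#' @export
genSubspaces <- function(P, D, N, extent, grid_points = 3, seed = NULL) {
  stopifnot(P >= 1, D >= 1, D < N, extent >= 0, grid_points >= 2)
  grid1 <- seq(-1, 1, length.out = grid_points)
  coords <- as.matrix(expand.grid(rep(list(grid1), D)))
  gen <- function() {
    lapply(seq_len(P), function(mu) {
      u <- rnorm(N); u <- u / sqrt(sum(u^2))
      ctr <- sqrt(N) * u
      A <- qr.Q(qr(matrix(rnorm(N * D), N, D)))
      offs <- (extent * sqrt(N)) * coords %*% t(A)
      sweep(offs, 2L, -ctr)
    })
  }
  sm <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  names(sm) <- sprintf("subsp%03d", seq_len(P))
  ActivationEnsemble(sm, metadata = list(
    generator = "subspaces", P = P, D = D, N = N, extent = extent,
    grid_points = grid_points, seed = seed))
}

#' Clouds with a planted low-rank common center component
#'
#' Adds \eqn{K} shared directions (with per-manifold random coefficients of
#' typical size \code{strength * sqrt(N)} and random signs, keeping the
#' coefficient matrix well-conditioned) to otherwise independent random
#' centers, injecting the low-rank center correlation structure that
#' [fitCommonComponents()] is designed to recover.
#'
#' @param P,M,N counts.
#' @param K planted rank.
#' @param strength coefficient scale of the shared directions, in units of
#'   \eqn{\sqrt{N}}; the independent center part has unit scale.
#' @param center_scale norm scale of the independent center part.
#' @param seed integer seed.
#' @return list: \code{ensemble}, \code{U} (the planted \eqn{N \times K}
#'   orthonormal directions).
#' @export
genCorrelatedClouds <- function(P, M, N, K = 1, strength = 3,
                                center_scale = 1, seed = NULL) {
  stopifnot(K >= 1, K < P)
  gen <- function() {
    U <- qr.Q(qr(matrix(rnorm(N * K), N, K)))
    sm <- lapply(seq_len(P), function(mu) {
      u <- rnorm(N); u <- u / sqrt(sum(u^2))
      ctr <- center_scale * sqrt(N) * u
      coef <- sample(c(-1, 1), K, replace = TRUE) *
        (1 + abs(rnorm(K))) * strength * sqrt(N)
      ctr <- ctr + drop(U %*% coef)
      sweep(matrix(rnorm(M * N), M, N), 2L, -ctr)
    })
    list(U = U, sm = sm)
  }
  g <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  names(g$sm) <- sprintf("corr%03d", seq_len(P))
  ens <- ActivationEnsemble(g$sm, metadata = list(
    generator = "correlated_clouds", P = P, M = M, N = N, K = K,
    strength = strength, seed = seed))
  list(ensemble = ens, U = g$U)
}

#' Scale manifolds about their centers
#'
#' Replaces every sample \eqn{x} by \eqn{c_\mu + s (x - c_\mu)}; centers are
#' unchanged, so only the manifold extent is manipulated.  Capacity is
#' non-increasing in \eqn{s}.
#'
#' @param ens an \code{ActivationEnsemble}.
#' @param s scaling factor (\eqn{\ge 0}; 1 is the identity, 0 collapses each
#'   manifold to its center).
#' @return scaled \code{ActivationEnsemble}.
#' @export
scaleManifolds <- function(ens, s) {
  stopifnot(s >= 0)
  a <- SummarizedExperiment::assay(ens, "activations")
  obj <- SummarizedExperiment::colData(ens)$object
  for (id in objectIds(ens)) {
    j <- which(obj == id)
    ctr <- rowMeans(a[, j, drop = FALSE])
    a[, j] <- ctr + s * (a[, j, drop = FALSE] - ctr)
  }
  .replaceActivations(ens, a)
}

#' Shuffle the assignment of samples to objects
#'
#' Pools all samples and repartitions them uniformly at random, preserving
#' the per-object counts.  Destroys any within-manifold structure: the
#' shuffled ensemble behaves like random point clouds with matched counts.
#'
#' @param ens an \code{ActivationEnsemble}.
#' @param seed optional seed.
#' @return shuffled \code{ActivationEnsemble}.
#' @export
shuffleAssignment <- function(ens, seed = NULL) {
  if (nObjects(ens) < 2) stop("need at least two objects to shuffle")
  a <- SummarizedExperiment::assay(ens, "activations")
  perm <- if (is.null(seed)) sample.int(ncol(a)) else
    withr::with_seed(seed, sample.int(ncol(a)))
  .replaceActivations(ens, a[, perm, drop = FALSE])
}

#' Randomize manifold centers without changing manifold geometry
#'
#' Rigidly translates each manifold so that its center points in a fresh
#' random direction with the original norm; within-manifold offsets (hence
#' \eqn{R_M}, \eqn{D_M}) are untouched while center correlations collapse to
#' the uncorrelated null level.
#'
#' @param ens an \code{ActivationEnsemble}.
#' @param seed optional seed.
#' @return an \code{ActivationEnsemble} with randomized centers.
#' @export
randomizeCenters <- function(ens, seed = NULL) {
  a <- SummarizedExperiment::assay(ens, "activations")
  obj <- SummarizedExperiment::colData(ens)$object
  N <- nrow(a)
  run <- function() {
    for (id in objectIds(ens)) {
      j <- which(obj == id)
      ctr <- rowMeans(a[, j, drop = FALSE])
      nrm <- sqrt(sum(ctr^2))
      u <- rnorm(N); u <- u / sqrt(sum(u^2))
      a[, j] <- a[, j, drop = FALSE] - ctr + nrm * u
    }
    a
  }
  a <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  .replaceActivations(ens, a)
}

#' Input variability of an ensemble
#'
#' Per-manifold root-mean-square sample distance from the manifold center,
#' in units of the center norm, averaged over manifolds ("convention v1").
#' Scales linearly under [scaleManifolds()].
#'
#' @param ens an \code{ActivationEnsemble}.
#' @param grand_center subtract the grand mean first.
#' @return non-negative scalar.
#' @export
inputVariability <- function(ens, grand_center = FALSE) {
  a <- SummarizedExperiment::assay(ens, "activations")
  if (grand_center) a <- a - rowMeans(a)
  obj <- SummarizedExperiment::colData(ens)$object
  vals <- vapply(objectIds(ens), function(id) {
    j <- which(obj == id)
    ctr <- rowMeans(a[, j, drop = FALSE])
    nrm <- sqrt(sum(ctr^2))
    if (nrm < 1e-12) stop("degenerate zero center norm for object ", id)
    sqrt(mean(colSums((a[, j, drop = FALSE] - ctr)^2))) / nrm
  }, 0)
  mean(vals)
}

#' Analytic baselines for random point-cloud manifolds
#'
#' Closed-form expectations for manifolds of \eqn{M} i.i.d. random points:
#' capacity \eqn{2/M}, effective radius \eqn{\sqrt{\pi - 1}} (independent of
#' \eqn{M}) and effective dimension \eqn{\pi M / (2(\pi - 1))}.
#'
#' @param M samples per manifold.
#' @return list: \code{alpha}, \code{R_M}, \code{D_M}.
#' @examples
#' randomBaselines(10)  # alpha 0.2, R_M 1.464, D_M 7.33
#' @export
randomBaselines <- function(M) {
  stopifnot(M >= 1)
  list(alpha = 2 / M, R_M = sqrt(pi - 1), D_M = pi * M / (2 * (pi - 1)))
}
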