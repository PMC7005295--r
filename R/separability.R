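#' Random projection of an ensemble
#'
#' Maps all samples through one shared \eqn{n \times N} matrix of i.i.d.
#' standard normal entries scaled by \eqn{1/\sqrt{n}}, the dimensionality
#' knob of the numerical capacity measurement.
#'
#' @param ens an \code{ActivationEnsemble}.
#' @param n target dimension (\eqn{1 \le n \le N}).
#' @param seed optional seed.
#' @param identity with \code{n == N}, skip the projection entirely.
#' @return projected \code{ActivationEnsemble} with \eqn{n} features.
#' @export
randomProject <- function(ens, n, seed = NULL, identity = FALSE) {
  N <- nFeatures(ens)
  if (n < 1 || n > N) stop("projected dimension must be in [1, N]")
  if (identity && n == N) return(ens)
  a <- SummarizedExperiment::assay(ens, "activations")
  proj <- function() matrix(rnorm(n * N), n, N) / sqrt(n)
  G <- if (is.null(seed)) proj() else withr::with_seed(seed, proj())
  ActivationEnsemble(G %*% a,
                     object = SummarizedExperiment::colData(ens)$object,
                     metadata = S4Vectors::metadata(ens))
}

#' Exact linear-separability check for labeled manifolds
#'
#' Decides whether a weight vector \eqn{w} exists with
#' \eqn{y_\mu (w \cdot x) > 0} for every sample \eqn{x} of every object
#' \eqn{\mu} (homogeneous separation, as in the zero-margin theory).  By
#' Gordan's alternative this holds iff the origin lies outside the convex
#' hull of the unit-normalized, label-signed samples; the distance of the
#' hull from the origin is computed exactly by non-negative least squares,
#' and the certificate \eqn{w = \sum_i \lambda_i y_i x_i} (the max-margin
#' direction) is verified explicitly.  Symmetric under a global label flip.
#'
#' @param ens an \code{ActivationEnsemble} (or \eqn{m \times n} matrix of
#'   points with \code{labels} per row).
#' @param labels \eqn{\pm 1} per object (or per row for a matrix input).
#' @param tol strict-margin tolerance on the normalized hull distance.
#' @param details return the certificate and hull distance as attributes.
#' @return logical; with \code{details}, attributes \code{w} (when
#'   separable) and \code{hull_dist}.
#' @export
checkSeparable <- function(ens, labels, tol = 1e-8, details = FALSE) {
  if (is(ens, "ActivationEnsemble")) {
    labels <- .checkLabels(labels, nObjects(ens))
    X <- t(SummarizedExperiment::assay(ens, "activations"))
    y <- labels[as.integer(SummarizedExperiment::colData(ens)$object)]
  } else {
    X <- as.matrix(ens)
    y <- .checkLabels(labels, nrow(X))
  }
  Z <- X * y
  nrm <- sqrt(rowSums(Z^2))
  if (any(nrm < 1e-300)) stop("zero sample vector; separability undefined")
  Z <- Z / nrm                       # unit-norm normalization
  if (!details && .sep_precheck_cpp(Z) == 1L) return(TRUE)
  A <- t(cbind(Z, 1))                # columns (z_i, 1); b = (0, ..., 0, 1)
  b <- c(numeric(ncol(Z)), 1)
  fit <- .nnls_cpp(A, b, stop_resid = tol / 2, certificate = TRUE)
  if (!fit$converged)
    stop("separability solver did not converge (indeterminate)")
  dist <- fit$rnorm
  sep <- if (fit$status == 1L) TRUE else if (fit$status == 2L) FALSE else
    dist > tol
  if (sep) {
    w <- drop(crossprod(Z, fit$x))   # max-margin direction
    margin <- min(Z %*% w)
    if (margin <= 0) {
      # certificate must validate; fall back to the KKT bound otherwise
      sep <- margin > -tol
      if (!sep) dist <- 0
    }
  }
  if (!details) return(sep)
  structure(sep, hull_dist = dist,
            w = if (sep) drop(crossprod(Z, fit$x)) else NULL)
}

.checkLabels <- function(labels, n) {
  labels <- as.numeric(labels)
  if (length(labels) != n)
    stop("labels must have length ", n)
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1/-1")
  labels
}

#' Draw a random dichotomy (fair-coin labels, all-equal draws rejected)
#' @noRd
.randomDichotomy <- function(P) {
  repeat {
    y <- sample(c(-1, 1), P, replace = TRUE)
    if (length(unique(y)) == 2L) return(y)
  }
}

#' Fraction of separable random dichotomies at a given dimension
#'
#' Projects the ensemble to \eqn{n} dimensions (one fresh random projection
#' per dichotomy trial, so trials are exchangeable), draws random \eqn{\pm 1}
#' object labels, and records the fraction of label assignments that are
#' linearly separable.
#'
#' @param ens an \code{ActivationEnsemble}.
#' @param n projected dimension.
#' @param n_dichotomies trials (default 101).
#' @param seed optional seed.
#' @param early_majority stop once the majority at \code{n_dichotomies}
#'   trials is decided (the vote is unchanged; the fraction estimate then
#'   uses the trials actually run).
#' @return list: \code{fraction}, \code{stderr} (binomial), \code{n_trials},
#'   \code{successes}.
#' @export
fractionSeparable <- function(ens, n, n_dichotomies = 101, seed = NULL,
                              early_majority = FALSE) {
  stopifnot(n_dichotomies >= 1)
  a <- SummarizedExperiment::assay(ens, "activations")
  N <- nrow(a)
  obj_idx <- as.integer(SummarizedExperiment::colData(ens)$object)
  run <- function() {
    P <- nObjects(ens)
    need <- floor(n_dichotomies / 2) + 1
    s <- 0L; t <- 0L
    for (i in seq_len(n_dichotomies)) {
      G <- matrix(rnorm(n * N), n, N) / sqrt(n)
      X <- t(G %*% a)
      y <- .randomDichotomy(P)
      s <- s + checkSeparable(X, y[obj_idx])
      t <- t + 1L
      if (early_majority && (s >= need || (t - s) >= need)) break
    }
    list(s = s, t = t)
  }
  r <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  p <- r$s / r$t
  list(fraction = p, stderr = sqrt(p * (1 - p) / r$t), n_trials = r$t,
       successes = r$s)
}

#' Numerical classification capacity by binary search
#'
#' Measures capacity directly: binary search over the projected dimension
#' \eqn{n}, maintaining brackets by the majority vote of
#' \code{n_dichotomies} separability trials per step, for the smallest
#' \eqn{n} whose separable fraction reaches 50\%.  Capacity is
#' \eqn{\alpha = P/n_c}.
#'
#' @param ens an \code{ActivationEnsemble}.
#' @param n_dichotomies trials per dimension (odd keeps the majority
#'   well-defined; default 101).
#' @param seed optional master seed (fanned per search step).
#' @param n_lo,n_hi initial brackets (default 1 and N).
#' @param early_majority stop each step's trials when its majority is
#'   decided.
#' @return a \linkS4class{NumericalCapacityResult}; when the ensemble is not
#'   separable even at \eqn{n = N} the result carries
#'   \code{settings$upper_bound_flag = TRUE} and \eqn{n_c = N}.
#' @export
findCapacity <- function(ens, n_dichotomies = 101, seed = NULL,
                         n_lo = 1, n_hi = NULL, early_majority = TRUE) {
  P <- nObjects(ens)
  N <- nFeatures(ens)
  if (is.null(n_hi)) n_hi <- N
  stopifnot(n_lo >= 1, n_hi <= N, n_lo <= n_hi)
  seeds <- .fanSeeds(seed, 64L)
  k <- 0L
  curve <- list()
  frac_at <- function(n) {
    k <<- k + 1L
    fr <- fractionSeparable(ens, n, n_dichotomies, seed = seeds[[k]],
                            early_majority = early_majority)
    curve[[length(curve) + 1L]] <<-
      data.frame(n = n, fraction = fr$fraction, stderr = fr$stderr,
                 nTrials = fr$n_trials)
    fr$fraction
  }
  flag <- FALSE
  f_hi <- frac_at(n_hi)
  if (f_hi < 0.5) {
    flag <- TRUE
    nc <- n_hi
  } else {
    f_lo <- if (n_lo == n_hi) f_hi else frac_at(n_lo)
    if (f_lo >= 0.5) {
      nc <- n_lo
    } else {
      lo <- n_lo; hi <- n_hi
      while (hi - lo > 1) {
        mid <- floor((lo + hi) / 2)
        if (frac_at(mid) >= 0.5) hi <- mid else lo <- mid
      }
      nc <- hi
    }
  }
  cv <- do.call(rbind, curve)
  cv <- cv[order(cv$n), , drop = FALSE]
  cv <- cv[!duplicated(cv$n), , drop = FALSE]
  rownames(cv) <- NULL
  new("NumericalCapacityResult", nC = as.numeric(nc), alpha = P / nc,
      curve = cv,
      settings = list(n_dichotomies = n_dichotomies, seed = seed,
                      n_lo = n_lo, n_hi = n_hi,
                      upper_bound_flag = flag))
}

#' Exact linear separability of labeled balls
#'
#' Decides whether \eqn{w} exists with
#' \eqn{y_\mu (w \cdot c_\mu) - R_\mu \|U_\mu^\top w\| > 0} for every ball
#' (center \eqn{c_\mu}, orthonormal axes \eqn{U_\mu}, radius \eqn{R_\mu}) --
#' the worst-case point of each ball must be classified correctly.  Solved
#' by exact cutting-plane alternation: point separability (non-negative
#' least squares on the current surface points) alternates with each ball's
#' worst-case point under the candidate \eqn{w}, until either the sampled
#' points become inseparable (the balls are inseparable, since all sampled
#' points lie inside balls) or \eqn{w} satisfies every ball constraint
#' strictly (a certificate).  With all radii 0 this reduces exactly to
#' [checkSeparable()] on the centers.
#'
#' @param centers \eqn{P \times N} matrix of ball centers.
#' @param axes list of \eqn{N \times D_\mu} orthonormal axis matrices.
#' @param radii numeric \eqn{\ge 0}, absolute radii (same units as the
#'   centers).
#' @param labels \eqn{\pm 1} per ball.
#' @param tol strict-margin tolerance (relative to \eqn{\|w\|} and the
#'   center scale).
#' @param max_iter cutting-plane iteration cap; exceeding it raises an
#'   error (never a silent \code{FALSE}).
#' @return logical.
#' @export
checkSeparableBalls <- function(centers, axes, radii, labels, tol = 1e-8,
                                max_iter = 500L) {
  centers <- as.matrix(centers)
  P <- nrow(centers)
  labels <- .checkLabels(labels, P)
  stopifnot(length(axes) == P, length(radii) == P, all(radii >= 0))
  scale <- max(sqrt(rowSums(centers^2)), 1e-12)
  pts <- centers
  own <- seq_len(P)                    # which ball generated each point
  for (it in seq_len(max_iter)) {
    sep <- checkSeparable(pts, labels[own], tol = tol, details = TRUE)
    if (!sep) return(FALSE)
    w <- attr(sep, "w")
    w <- w / sqrt(sum(w^2))
    viol <- logical(P)
    worst <- matrix(NA_real_, P, ncol(centers))
    for (mu in seq_len(P)) {
      uw <- crossprod(axes[[mu]], w)
      nu <- sqrt(sum(uw^2))
      margin <- labels[mu] * sum(w * centers[mu, ]) - radii[mu] * nu
      if (margin <= tol * scale) {
        viol[mu] <- TRUE
        if (nu > 1e-14)
          worst[mu, ] <- centers[mu, ] -
            labels[mu] * radii[mu] * drop(axes[[mu]] %*% (uw / nu))
        else
          worst[mu, ] <- centers[mu, ]
      }
    }
    if (!any(viol)) return(TRUE)
    add <- which(viol & rowSums(is.na(worst)) == 0)
    if (length(add) == 0L) return(FALSE)
    pts <- rbind(pts, worst[add, , drop = FALSE])
    own <- c(own, add)
  }
  stop("ball separability undecided after ", max_iter,
       " cutting-plane iterations (indeterminate)")
}
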