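# Shared oracles and fixture builders (all fixtures generated in code).

# Independent oracle for the 2-d inner problem: the feasible set
# {V : S V >= 0} is a cone in the plane, so the projection of T is one of
# finitely many closed-form candidates -- T itself, the projection of T
# onto each boundary line {V : s_i . V = 0}, or the apex 0.  Enumerate
# them all and keep the best feasible one; exact to machine precision and
# entirely independent of the active-set route.
coneInnerObjective <- function(S, Tvec) {
  stopifnot(ncol(S) == 2, length(Tvec) == 2)
  feasible <- function(V) min(S %*% V) >= -1e-12 * max(1, sum(abs(V)))
  best <- Inf
  if (feasible(Tvec)) return(0)
  for (i in seq_len(nrow(S))) {
    s <- S[i, ]
    P <- Tvec - sum(s * Tvec) / sum(s^2) * s
    if (feasible(P)) best <- min(best, sum((P - Tvec)^2))
  }
  min(best, sum(Tvec^2))   # apex always feasible
}

# Monte-Carlo oracle for the ball capacity: the exact cone-projection
# objective averaged over sampled probes (independent of the quadrature).
mcBallCapacity <- function(R, D, n = 2e5, seed = 1) {
  withr::with_seed(seed, {
    t0 <- rnorm(n)
    t <- sqrt(rchisq(n, df = D))
    F <- ifelse(t0 >= R * t, 0,
                ifelse(t0 <= -t / R, t^2 + t0^2,
                       (t0 - R * t)^2 / (1 + R^2)))
    1 / mean(F)
  })
}

# Cover's exact count of homogeneously separable dichotomies of P points in
# general position in n dimensions.
coverCount <- function(P, n) 2 * sum(choose(P - 1, seq_len(n) - 1))

# random orthonormal N x D frame
randomFrameAxes <- function(N, D) qr.Q(qr(matrix(rnorm(N * D), N, D)))

# small random manifold frame with controllable sizes
randomManifoldFrame <- function(M = 6, N = 25, seed = NULL) {
  draw <- function() buildFrame(matrix(rnorm(M * N), M, N))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# KKT certificate check for one inner solution; returns character() when
# all conditions hold
kktViolations <- function(S, Tvec, sol, tol = 1e-6) {
  bad <- character()
  if (sol$F < 0) bad <- c(bad, "negative objective")
  if (min(S %*% sol$V) < -tol) bad <- c(bad, "primal infeasible")
  act <- sol$dual_weights > 1e-8
  if (any(act)) {
    if (max(abs((S %*% sol$V)[act])) > tol)
      bad <- c(bad, "complementary slackness")
  }
  if (sol$F > 1e-8) {
    d <- Tvec - sol$V
    a <- sol$anchor
    cosang <- sum(d * a) / sqrt(sum(d^2) * sum(a^2))
    if (abs(cosang + 1) > tol) bad <- c(bad, "T - V not antiparallel to anchor")
    lamv <- drop(crossprod(S, sol$dual_weights))
    if (max(abs(sol$V - Tvec - lamv)) > tol)
      bad <- c(bad, "stationarity")
  }
  bad
}
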