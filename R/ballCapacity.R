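#' Classification capacity of L2 balls
#'
#' Closed-form mean-field capacity of \eqn{D}-dimensional balls of radius
#' \eqn{R} (in units of the center norm).  For a ball the sample-set
#' constraint of the inner problem collapses to a single second-order-cone
#' constraint \eqn{V_0 \ge R\|\delta V\|}, so the objective \eqn{F(T)}
#' depends on the probe only through \eqn{t_0 = T_0} and
#' \eqn{t = \|\delta T\|}, and splits into three exact regions:
#' \describe{
#'   \item{interior}{\eqn{t_0 \ge R t}: \eqn{F = 0};}
#'   \item{touching}{\eqn{-t/R < t_0 < R t}: projection on the cone surface,
#'     \eqn{F = (t_0 - R t)^2 / (1 + R^2)};}
#'   \item{embedded}{\eqn{t_0 \le -t/R}: \eqn{F = t^2 + t_0^2}.}
#' }
#' \eqn{\alpha_{Ball}^{-1}(R, D) = \langle F \rangle} with
#' \eqn{t_0 \sim N(0,1)} and \eqn{t \sim \chi_D}; the Gaussian integral over
#' \eqn{t_0} is analytic and the remaining integral over \eqn{t} is done by
#' adaptive quadrature, which keeps \eqn{D} continuous (the measured
#' effective dimension \eqn{D_M} is real-valued).
#'
#' Limits: \eqn{\alpha_{Ball}(0, D) = 2} (points) and
#' \eqn{\alpha_{Ball}(R \to \infty, D) \to 1/(D + 1/2)} (unbounded
#' subspaces).  Strictly decreasing in both \eqn{R} and \eqn{D}.
#'
#' @param R ball radius relative to the center norm (\eqn{\ge 0}).
#' @param D ball dimension (\eqn{> 0}, possibly non-integer).
#' @param rel_tol relative quadrature tolerance.
#' @return capacity \eqn{\alpha_{Ball}(R, D)}.
#' @examples
#' ballCapacity(0, 5)        # 2: the point limit
#' 1 / ballCapacity(1e6, 4)  # ~ 4.5: the subspace limit D + 1/2
#' @export
ballCapacity <- function(R, D, rel_tol = 1e-8) {
  if (length(R) != 1 || length(D) != 1 || !is.finite(R) || !is.finite(D))
    stop("R and D must be finite scalars")
  if (R < 0) stop("R must be non-negative")
  if (D <= 0) stop("D must be positive")
  if (R == 0) return(2)
  1 / .ballAlphaInv(R, D, rel_tol)
}

# E_t[ inner(t) ] with t ~ chi_D (real D via the gamma density of t^2/2)
.ballAlphaInv <- function(R, D, rel_tol = 1e-8) {
  inner <- function(t) {
    u <- R * t          # upper limit and offset of the touching region
    l <- -t / R         # lower limit
    Phi_u <- pnorm(u); Phi_l <- pnorm(l)
    phi_u <- dnorm(u); phi_l <- dnorm(l)
    # touching: int_l^u (x - u)^2 phi(x) dx / (1 + R^2)
    touch <- ((1 + u^2) * (Phi_u - Phi_l) - (u * phi_u - l * phi_l) +
                2 * u * (phi_u - phi_l)) / (1 + R^2)
    # embedded: t^2 Phi(l) + int_{-inf}^l x^2 phi(x) dx
    emb <- t^2 * Phi_l + (Phi_l - l * phi_l)
    touch + emb
  }
  # chi_D density: t^{D-1} e^{-t^2/2} / (2^{D/2 - 1} Gamma(D/2))
  logc <- -(D / 2 - 1) * log(2) - lgamma(D / 2)
  dchi <- function(t) exp(logc + (D - 1) * log(t) - t^2 / 2)
  f <- function(t) inner(t) * dchi(t)
  up <- sqrt(D) + 12            # chi_D mass is below sqrt(D) + O(1)
  stats::integrate(f, 0, up, rel.tol = rel_tol, abs.tol = 0,
                   subdivisions = 400L)$value
}
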