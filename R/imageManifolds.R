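#' Smooth manifolds from affine warps of procedural images
#'
#' Emulates pixel-level smooth object manifolds: each base image is a
#' procedurally generated smooth random blob (a sum of Gaussian bumps)
#' occupying the middle 75\% of a square frame; the manifold samples are the
#' flattened pixels of the base image warped by an affine transformation
#' with 1 or 2 degrees of freedom (horizontal/vertical translation or
#' shear).  Warp parameters are bounded so that no corner of the object box
#' is displaced by more than \code{max_corner_displacement} pixels, the knob
#' controlling manifold extent.  Interpolation is bilinear with a
#' zero-padded boundary.
#'
#' @param n_base number of base images (one manifold per base image).
#' @param dof degrees of freedom: one of \code{"tx"}, \code{"ty"},
#'   \code{"sx"}, \code{"sy"}, \code{"tx+ty"}, \code{"sx+sy"}.
#' @param max_corner_displacement maximal object-corner displacement, in
#'   pixels (\eqn{\ge 0}).
#' @param grid warp samples per degree of freedom (\eqn{\ge 2}); a 2-dof
#'   manifold has \code{grid^2} samples.
#' @param image_size frame side in pixels (default 64, giving
#'   \eqn{N = 4096} pixel features).
#' @param n_bumps Gaussian bumps per base image.
#' @param seed integer seed.
#' @return an \code{ActivationEnsemble} of flattened warped images.
#' @export
genAffineImageManifolds <- function(n_base, dof = "tx",
                                    max_corner_displacement = 4,
                                    grid = 5, image_size = 64,
                                    n_bumps = 6, seed = NULL) {
  dof <- match.arg(dof, c("tx", "ty", "sx", "sy", "tx+ty", "sx+sy"))
  stopifnot(n_base >= 1, max_corner_displacement >= 0, grid >= 2)
  half_obj <- 0.75 * image_size / 2     # object box half-side, pixels
  if (max_corner_displacement > (image_size - 0.75 * image_size) / 2)
    stop("max_corner_displacement would push the object outside the frame")
  dims <- strsplit(dof, "+", fixed = TRUE)[[1]]
  # per-dof parameter bound from the corner-displacement budget
  budget <- max_corner_displacement / sqrt(length(dims))
  bound <- function(d) {
    if (d %in% c("tx", "ty")) budget else budget / half_obj  # shear slope
  }
  vals <- lapply(dims, function(d) seq(-bound(d), bound(d),
                                       length.out = grid))
  pargrid <- as.matrix(expand.grid(vals))
  colnames(pargrid) <- dims
  gen <- function() {
    lapply(seq_len(n_base), function(b) {
      img <- .proceduralImage(image_size, n_bumps)
      t(apply(pargrid, 1L, function(p) as.numeric(.warpImage(img, p))))
    })
  }
  sm <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  names(sm) <- sprintf("img%03d", seq_len(n_base))
  ActivationEnsemble(sm, metadata = list(
    generator = "affine_images", dof = dof,
    max_corner_displacement = max_corner_displacement, grid = grid,
    image_size = image_size, seed = seed))
}

# smooth random blob: sum of Gaussian bumps confined to the middle 75%
.proceduralImage <- function(size, n_bumps) {
  lo <- size * 0.125; hi <- size * 0.875
  xs <- seq_len(size)
  img <- matrix(0, size, size)
  for (b in seq_len(n_bumps)) {
    cx <- runif(1, lo + size * 0.06, hi - size * 0.06)
    cy <- runif(1, lo + size * 0.06, hi - size * 0.06)
    sdv <- runif(1, size * 0.03, size * 0.09)
    amp <- runif(1, 0.4, 1)
    img <- img + amp * outer(exp(-(xs - cx)^2 / (2 * sdv^2)),
                             exp(-(xs - cy)^2 / (2 * sdv^2)))
  }
  # confine to the object box so warps cannot clip content
  mask_1d <- as.numeric(xs > lo & xs < hi)
  img * outer(mask_1d, mask_1d)
}

# affine warp with named parameters (tx, ty, sx, sy); bilinear, zero padding
.warpImage <- function(img, p) {
  size <- nrow(img)
  ctr <- (size + 1) / 2
  tx <- if ("tx" %in% names(p)) p[["tx"]] else 0
  ty <- if ("ty" %in% names(p)) p[["ty"]] else 0
  sx <- if ("sx" %in% names(p)) p[["sx"]] else 0
  sy <- if ("sy" %in% names(p)) p[["sy"]] else 0
  # forward map about the frame center:
  #   x' = x + sx (y - ctr) + tx ;  y' = y + sy (x - ctr) + ty
  A <- rbind(c(1, sy), c(sx, 1))
  off <- c(tx + ctr - A[1, 1] * ctr - A[2, 1] * ctr,
           ty + ctr - A[1, 2] * ctr - A[2, 2] * ctr)
  m <- rbind(A, off)
  out <- EBImage::affine(EBImage::Image(img), m, filter = "bilinear",
                         bg.col = 0)
  EBImage::imageData(out)
}
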