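#' Construct an ActivationEnsemble
#'
#' Builds the central data container from per-object sample matrices.  Each
#' object manifold is a set of \eqn{M_\mu} population-response vectors in a
#' common \eqn{N}-dimensional feature space.
#'
#' @param samples either a named list of \eqn{M_\mu \times N} matrices
#'   (samples in rows), or a single \eqn{N \times \sum M_\mu} matrix
#'   accompanied by \code{object}.
#' @param object when \code{samples} is a matrix, a vector assigning each
#'   column to an object.
#' @param metadata optional list stored in the container metadata (seed,
#'   creator, generator settings).
#' @return an \linkS4class{ActivationEnsemble}.
#' @examples
#' ens <- ActivationEnsemble(list(a = matrix(rnorm(20), 4, 5),
#'                                b = matrix(rnorm(15), 3, 5)))
#' nObjects(ens)
#' @export
ActivationEnsemble <- function(samples, object = NULL, metadata = list()) {
  if (is.list(samples)) {
    if (is.null(names(samples)) || anyDuplicated(names(samples)))
      names(samples) <- sprintf("obj%03d", seq_along(samples))
    ns <- vapply(samples, ncol, 0L)
    if (length(unique(ns)) > 1L)
      stop("all sample matrices must share the feature count N; got: ",
           paste(unique(ns), collapse = ", "))
    mat <- t(do.call(rbind, samples))
    object <- rep(names(samples), vapply(samples, nrow, 0L))
  } else {
    mat <- as.matrix(samples)
    if (is.null(object) || length(object) != ncol(mat))
      stop("'object' must assign each sample column to an object")
    object <- as.character(object)
  }
  storage.mode(mat) <- "double"
  colnames(mat) <- NULL
  cd <- S4Vectors::DataFrame(object = factor(object, levels = unique(object)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(activations = mat), colData = cd, metadata = metadata)
  new("ActivationEnsemble", se)
}

#' @describeIn ActivationEnsemble object identifiers, in input order.
#' @param x an \code{ActivationEnsemble}.
#' @export
objectIds <- function(x) levels(SummarizedExperiment::colData(x)$object)

#' @describeIn ActivationEnsemble number of object manifolds \eqn{P}.
#' @export
nObjects <- function(x) length(objectIds(x))

#' @describeIn ActivationEnsemble ambient feature count \eqn{N}.
#' @export
nFeatures <- function(x) nrow(x)

#' @describeIn ActivationEnsemble per-object sample counts \eqn{M_\mu}.
#' @export
sampleCounts <- function(x) {
  tab <- table(SummarizedExperiment::colData(x)$object)
  stats::setNames(as.integer(tab[objectIds(x)]), objectIds(x))
}

#' @describeIn ActivationEnsemble the \eqn{M_\mu \times N} sample matrix of
#'   one object (samples in rows).
#' @param id object identifier or index.
#' @export
getSamples <- function(x, id) {
  ids <- objectIds(x)
  if (is.numeric(id)) id <- ids[id]
  keep <- SummarizedExperiment::colData(x)$object == id
  if (!any(keep)) stop("unknown object: ", id)
  t(SummarizedExperiment::assay(x, "activations")[, keep, drop = FALSE])
}

#' @describeIn ActivationEnsemble list of all per-object sample matrices.
#' @export
sampleList <- function(x) {
  a <- SummarizedExperiment::assay(x, "activations")
  obj <- SummarizedExperiment::colData(x)$object
  lapply(stats::setNames(nm = objectIds(x)),
         function(id) t(a[, obj == id, drop = FALSE]))
}

#' Manifold centers of an ensemble
#'
#' Per-object sample means, optionally after subtracting the grand mean
#' activation (over all objects and samples).  Grand centering makes center
#' statistics reflect inter-object structure rather than a common offset.
#'
#' @param x an \code{ActivationEnsemble}.
#' @param grand_center subtract the grand mean first (default \code{TRUE}).
#' @return \eqn{P \times N} matrix of centers, rows named by object.
#' @export
objectCenters <- function(x, grand_center = TRUE) {
  a <- SummarizedExperiment::assay(x, "activations")
  obj <- SummarizedExperiment::colData(x)$object
  if (grand_center) a <- a - rowMeans(a)
  ctr <- vapply(objectIds(x),
                function(id) rowMeans(a[, obj == id, drop = FALSE]),
                numeric(nrow(a)))
  t(ctr)
}

#' Replace the activation matrix, keeping the object structure
#' @noRd
.replaceActivations <- function(x, mat) {
  stopifnot(ncol(mat) == ncol(x))
  SummarizedExperiment::assay(x, "activations", withDimnames = FALSE) <- mat
  x
}

setMethod("show", "ActivationEnsemble", function(object) {
  m <- sampleCounts(object)
  cat("ActivationEnsemble: P =", nObjects(object), "objects, N =",
      nFeatures(object), "features\n")
  cat("  samples per object: ",
      if (length(unique(m)) == 1L) paste0("M = ", m[1]) else
        paste0("M in [", min(m), ", ", max(m), "]"), "\n", sep = "")
  md <- S4Vectors::metadata(object)
  if (length(md))
    cat("  metadata:", paste(names(md), collapse = ", "), "\n")
})

setMethod("show", "CapacityReport", function(object) {
  cat("CapacityReport\n")
  cat("  ensemble capacity alpha_c =", signif(object@alphaC, 4), "\n")
  pm <- object@perManifold
  cat("  manifolds:", nrow(pm), "  mean R_M =",
      signif(mean(pm$R_M), 3), " mean D_M =", signif(mean(pm$D_M), 3), "\n")
  s <- object@settings
  cat("  probes per manifold:", s$n_probes,
      if (isTRUE(s$correlation_correction))
        sprintf(" (centers decorrelated, K = %d)", s$K) else "", "\n")
})

setMethod("show", "CommonComponents", function(object) {
  cat("CommonComponents: K =", object@K,
      " residual off-diagonal |cos| =", signif(object@residualOffdiag, 3),
      if (!object@converged) " [rank cap reached]" else "", "\n")
})

setMethod("show", "CorrelationReport", function(object) {
  cat("CorrelationReport: rho_CC =", signif(object@rhoCC, 4),
      " axes alignment =", signif(object@axesAlignment, 4), "\n")
})

setMethod("show", "NumericalCapacityResult", function(object) {
  cat("NumericalCapacityResult: n_c =", object@nC,
      " alpha =", signif(object@alpha, 4), "\n")
  cat("  curve points:", nrow(object@curve), "\n")
})

#' Accessors for result objects
#'
#' \code{capacity} returns the capacity estimate held by a report object;
#' \code{manifoldMetrics} the per-manifold geometry table.
#'
#' @param x a \code{CapacityReport} or \code{NumericalCapacityResult}.
#' @return \code{capacity}: numeric scalar. \code{manifoldMetrics}: a
#'   \code{DataFrame} (one row per manifold).
#' @export
capacity <- function(x) {
  if (is(x, "CapacityReport")) return(x@alphaC)
  if (is(x, "NumericalCapacityResult")) return(x@alpha)
  stop("no capacity accessor for class ", class(x))
}

#' @rdname capacity
#' @export
manifoldMetrics <- function(x) {
  stopifnot(is(x, "CapacityReport"))
  x@perManifold
}

#' @rdname capacity
#' @export
reportSettings <- function(x) x@settings

#' @rdname capacity
#' @export
separabilityCurve <- function(x) {
  stopifnot(is(x, "NumericalCapacityResult"))
  x@curve
}
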