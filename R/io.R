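#' Save an ensemble as a directory of delimited-text matrices
#'
#' The on-disk container is a directory with one tab-separated matrix per
#' object (\code{<id>.tsv}, samples in rows) and a \code{manifest.json}
#' recording the object order, \code{N}, \code{P}, per-object sample counts
#' and any generator metadata (seed, creator).
#'
#' @param ens an \code{ActivationEnsemble}.
#' @param path directory to create (must not already contain a manifest
#'   unless \code{overwrite}).
#' @param overwrite replace an existing container.
#' @return \code{path}, invisibly.
#' @export
saveEnsemble <- function(ens, path, overwrite = FALSE) {
  mf <- file.path(path, "manifest.json")
  if (file.exists(mf) && !overwrite)
    stop("container already exists at ", path)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ids <- objectIds(ens)
  files <- sprintf("%s.tsv", make.names(ids))
  sl <- sampleList(ens)
  for (i in seq_along(ids))
    data.table::fwrite(data.table::as.data.table(sl[[i]]),
                       file.path(path, files[i]), sep = "\t",
                       col.names = FALSE)
  manifest <- list(
    format = "activation-ensemble/tsv-v1",
    N = nFeatures(ens), P = nObjects(ens),
    objects = ids, files = files,
    M = unname(sampleCounts(ens)),
    metadata = S4Vectors::metadata(ens))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load an ensemble from a text container
#'
#' Validates the container against its manifest: every per-object matrix
#' must exist, share the feature count \eqn{N}, match its declared sample
#' count and contain only finite values; violations are reported with the
#' object id.
#'
#' @param path container directory written by [saveEnsemble()].
#' @return an \code{ActivationEnsemble}.
#' @export
loadEnsemble <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    stop("no manifest.json under ", path, "; not an ensemble container")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  ids <- manifest$objects
  files <- manifest$files
  if (length(ids) == 0L || length(files) != length(ids))
    stop("manifest is malformed: objects/files mismatch")
  sm <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    f <- file.path(path, files[i])
    if (!file.exists(f)) stop("missing sample matrix for object ", ids[i])
    x <- as.matrix(data.table::fread(f, sep = "\t", header = FALSE))
    dimnames(x) <- NULL
    if (!is.null(manifest$N) && ncol(x) != manifest$N)
      stop("object ", ids[i], " has N = ", ncol(x),
           ", manifest declares N = ", manifest$N)
    if (!all(is.finite(x)))
      stop("object ", ids[i], " contains non-finite values")
    sm[[i]] <- x
  }
  ns <- vapply(sm, ncol, 0L)
  if (length(unique(ns)) > 1L)
    stop("ragged feature counts across objects: ",
         paste(unique(ns), collapse = ", "), " (first offender: ",
         ids[which(ns != ns[1])[1]], ")")
  names(sm) <- ids
  md <- manifest$metadata
  ActivationEnsemble(sm, metadata = if (is.null(md)) list() else md)
}

#' Write a capacity report to JSON + CSV
#'
#' Scalars (ensemble capacity, settings) go to \code{<stem>.json}; the
#' per-manifold table (id, M, D, alpha, R_M, D_M, total extent) to
#' \code{<stem>.csv}.
#'
#' @param report a \code{CapacityReport}.
#' @param stem output path without extension.
#' @return the two file paths, invisibly.
#' @export
writeCapacityReport <- function(report, stem) {
  pm <- as.data.frame(manifoldMetrics(report))
  json <- file.path(paste0(stem, ".json"))
  csv <- file.path(paste0(stem, ".csv"))
  jsonlite::write_json(list(alpha_c = capacity(report),
                            mean_R_M = mean(pm$R_M),
                            mean_D_M = mean(pm$D_M),
                            settings = reportSettings(report)),
                       json, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  data.table::fwrite(pm[, c("id", "M", "D", "alpha", "R_M", "D_M",
                            "totalExtent")], csv)
  invisible(c(json = json, csv = csv))
}

#' Write a numerical capacity result to JSON + CSV
#'
#' @param res a \code{NumericalCapacityResult}.
#' @param stem output path without extension.
#' @return file paths, invisibly.
#' @export
writeNumericalResult <- function(res, stem) {
  json <- paste0(stem, ".json")
  csv <- paste0(stem, ".csv")
  jsonlite::write_json(list(n_c = res@nC, alpha = res@alpha,
                            settings = res@settings),
                       json, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  data.table::fwrite(res@curve, csv)
  invisible(c(json = json, csv = csv))
}
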