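# Volume and report I/O. Volumes use the MetaImage dialect (.mhd text header +
# .raw little-endian payload): labels as unsigned 8-bit, dose/kernel values as
# 64-bit float. Reports and provenance go to JSON, DVHs to CSV.

.mhd_type <- c(uchar = "MET_UCHAR", double = "MET_DOUBLE")

.write_mhd <- function(arr, path, spacing, element, extra = list()) {
  stopifnot(element %in% names(.mhd_type))
  raw_path <- sub("\\.mhd$", ".raw", path)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("DimSize =", paste(dim(arr), collapse = " ")),
    paste("ElementSpacing =", paste(rep(spacing, 3), collapse = " ")),
    paste("ElementType =", .mhd_type[[element]]),
    vapply(names(extra), function(k) paste0(k, " = ", extra[[k]]), ""),
    paste("ElementDataFile =", basename(raw_path)))
  writeLines(hdr, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  if (element == "uchar")
    writeBin(as.integer(arr), con, size = 1L, endian = "little")
  else
    writeBin(as.numeric(arr), con, size = 8L, endian = "little")
  invisible(path)
}

.read_mhd <- function(path) {
  hdr <- readLines(path)
  kv <- strsplit(hdr, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, "", 1L)
  val <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) NA_character_ else kv[[i]][2]
  }
  dims <- as.integer(strsplit(val("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(val("ElementSpacing"), "\\s+")[[1]])[1]
  type <- val("ElementType")
  raw_path <- file.path(dirname(path), val("ElementDataFile"))
  con <- file(raw_path, "rb")
  on.exit(close(con))
  n <- prod(dims)
  data <- if (type == "MET_UCHAR")
    readBin(con, "integer", n, size = 1L, signed = FALSE, endian = "little")
  else readBin(con, "numeric", n, size = 8L, endian = "little")
  extra <- setdiff(keys, c("ObjectType", "NDims", "BinaryData",
                           "BinaryDataByteOrderMSB", "DimSize",
                           "ElementSpacing", "ElementType", "ElementDataFile"))
  list(array = array(data, dims), spacing = spacing, type = type,
       meta = setNames(lapply(extra, val), extra))
}

#' Write a label volume to MetaImage (.mhd/.raw)
#'
#' Labels are stored as unsigned 8-bit; provenance (morphology, scale, seed,
#' density) goes into header key-value fields so a written model is
#' re-derivable.
#'
#' @param labels a `label_volume`.
#' @param path output path ending in `.mhd` (a sibling `.raw` is written).
#' @return the path, invisibly.
#' @export
write_label_volume <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  p <- labels$provenance
  .write_mhd(labels$labels, path, labels$grid$spacing, "uchar",
             extra = list(Morphology = p$morphology %||% "unknown",
                          ClusterScale = p$scale %||% NA,
                          Seed = p$seed %||% NA,
                          Density = labels$density))
  invisible(path)
}

#' Read a label volume written by [write_label_volume()]
#' @param path `.mhd` path.
#' @return a `label_volume`.
#' @export
read_label_volume <- function(path) {
  x <- .read_mhd(path)
  structure(list(labels = array(as.integer(x$array), dim(x$array)),
                 grid = grid_spec(x$spacing, dim(x$array), "center"),
                 density = as.numeric(x$meta$Density %||% 1.05),
                 provenance = list(morphology = x$meta$Morphology,
                                   scale = as.numeric(x$meta$ClusterScale),
                                   seed = as.integer(x$meta$Seed))),
            class = "label_volume")
}

#' Write a dose map to MetaImage with a JSON provenance sidecar
#' @param dose a `dose_map`.
#' @param path output `.mhd` path; `<path>.json` holds provenance.
#' @return the path, invisibly.
#' @export
write_dose_map <- function(dose, path) {
  stopifnot(inherits(dose, "dose_map"))
  .write_mhd(dose$dose_Gy, path, dose$grid$spacing, "double")
  jsonlite::write_json(dose$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a dose map written by [write_dose_map()]
#' @param path `.mhd` path.
#' @return a `dose_map`.
#' @export
read_dose_map <- function(path) {
  x <- .read_mhd(path)
  prov_path <- paste0(path, ".json")
  prov <- if (file.exists(prov_path)) jsonlite::read_json(prov_path) else list()
  structure(list(dose_Gy = x$array,
                 grid = grid_spec(x$spacing, dim(x$array), "center"),
                 provenance = prov),
            class = "dose_map")
}

#' Save a dose kernel (MetaImage payload + JSON metadata sidecar)
#'
#' The same reader accepts externally generated kernels: any `.mhd` double
#' volume with an odd cubic shape plus a `.json` sidecar carrying at least
#' `spacing_um` can be dropped in.
#'
#' @param kernel a `dose_kernel`.
#' @param path output `.mhd` path.
#' @return the path, invisibly.
#' @export
save_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "dose_kernel"))
  .write_mhd(kernel$values, path, kernel$spacing_um, "double")
  meta <- kernel[setdiff(names(kernel), "values")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Load a dose kernel saved by [save_kernel()] (or an external kernel)
#' @param path `.mhd` path with a `.json` metadata sidecar.
#' @return a `dose_kernel`.
#' @export
load_kernel <- function(path) {
  x <- .read_mhd(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  if (any(dim(x$array) %% 2L == 0L)) stop("kernel volume must be odd-sized")
  k <- c(list(values = x$array,
              spacing_um = as.numeric(meta$spacing_um %||% x$spacing)),
         meta[setdiff(names(meta), c("values", "spacing_um"))])
  class(k) <- "dose_kernel"
  k
}

#' Write a DVH curve to CSV
#' @param dvh a `dvh_curve` data frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_dvh_csv <- function(dvh, path) {
  utils::write.csv(as.data.frame(dvh), path, row.names = FALSE)
  invisible(path)
}

#' Write pairing analysis reports to JSON
#' @param reports list of `analysis_report` from [analyze_pairings()].
#' @param path output JSON path.
#' @param include_dvh include the DVH curves (default `FALSE`: summary only).
#' @return the path, invisibly.
#' @export
write_reports_json <- function(reports, path, include_dvh = FALSE) {
  out <- lapply(reports, function(r) {
    r <- unclass(r)
    if (!include_dvh) r$dvh <- NULL else r$dvh <- as.data.frame(r$dvh)
    r
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}
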