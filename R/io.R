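# Serialization. HDF5 is the canonical imaging container (layout: /image,
# /mask, /kspace_real, /kspace_imag, /recon, /trace, and a /meta group
# whose attributes carry noise_level, seed, dialect, fraction and the
# schema version). CSV is canonical for cohorts and small explicit
# matrices (complex entries as "a+bi"); JSON for reports, certificates and
# run configs.

CSMRI_SCHEMA <- 1L

#' Write a phantom/acquisition bundle to HDF5
#'
#' @param path output `.h5` file (overwritten).
#' @param image real image matrix, or `NULL`.
#' @param mask a [sampling_mask()], or `NULL`.
#' @param kspace complex k-space matrix, or `NULL`.
#' @param recon reconstructed image matrix, or `NULL`.
#' @param trace objective trace vector, or `NULL`.
#' @param meta named list of scalar metadata (noise_level, seed, ...).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(path, image = NULL, mask = NULL, kspace = NULL,
                         recon = NULL, trace = NULL, meta = list()) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  if (!is.null(image)) rhdf5::h5write(image, path, "image")
  if (!is.null(mask)) {
    rhdf5::h5write(mask$grid * 1L, path, "mask")
    meta$dialect <- mask$dialect
    meta$fraction <- mask$fraction
    meta$mask_seed <- mask$seed
  }
  if (!is.null(kspace)) {
    rhdf5::h5write(Re(kspace), path, "kspace_real")
    rhdf5::h5write(Im(kspace), path, "kspace_imag")
  }
  if (!is.null(recon)) rhdf5::h5write(recon, path, "recon")
  if (!is.null(trace)) rhdf5::h5write(as.numeric(trace), path, "trace")
  rhdf5::h5createGroup(path, "meta")
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "meta")
  rhdf5::h5writeAttribute(CSMRI_SCHEMA, gid, "schema")
  # k-space convention is part of the format contract
  rhdf5::h5writeAttribute("zero-frequency-centered", gid, "kspace_convention")
  for (nm in names(meta)) rhdf5::h5writeAttribute(meta[[nm]], gid, nm)
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param path `.h5` file.
#' @return list with any of `image`, `mask` (a `sampling_mask`), `kspace`,
#'   `recon`, `trace`, and `meta` (named list of attributes).
#' @export
read_bundle <- function(path) {
  if (!file.exists(path)) stop_input(paste("no such file:", path))
  contents <- rhdf5::h5ls(path)$name
  out <- list()
  if ("image" %in% contents) out$image <- rhdf5::h5read(path, "image")
  if ("kspace_real" %in% contents)
    out$kspace <- rhdf5::h5read(path, "kspace_real") + 1i * rhdf5::h5read(path, "kspace_imag")
  if ("recon" %in% contents) out$recon <- rhdf5::h5read(path, "recon")
  if ("trace" %in% contents) out$trace <- as.numeric(rhdf5::h5read(path, "trace"))
  meta <- lapply(rhdf5::h5readAttributes(path, "meta"), as.vector)
  out$meta <- meta
  if ("mask" %in% contents) {
    grid <- rhdf5::h5read(path, "mask") != 0
    out$mask <- structure(list(grid = grid,
                               dialect = meta$dialect %||% "full",
                               fraction = meta$fraction %||% mean(grid),
                               seed = as.integer(meta$mask_seed %||% 0L)),
                          class = "sampling_mask")
  }
  out
}

#' Export an image (or mask) to 8-bit PNG
#'
#' Min-max scaled to the full 8-bit range; a constant image maps to zero.
#' @param image numeric matrix. @param path output `.png`.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  m <- as.matrix(image)
  rng <- range(m)
  scaled <- if (diff(rng) == 0) m * 0 else (m - rng[1]) / diff(rng)
  png::writePNG(scaled, path)
  invisible(path)
}

#' Write/read a complex matrix as CSV
#'
#' One matrix row per line, entries formatted `a+bi` at full double
#' precision; the explicit-matrix interchange format for small systems.
#' @param m real or complex matrix. @param path file path.
#' @return `path` invisibly, or the complex matrix.
#' @export
write_matrix_csv <- function(m, path) {
  m <- as.matrix(m)
  txt <- matrix(sprintf("%.17g%+.17gi", Re(m), Im(m)), nrow(m), ncol(m))
  utils::write.table(txt, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  txt <- as.matrix(utils::read.table(path, sep = ",", colClasses = "character"))
  m <- matrix(as.complex(sub("i$", "i", txt)), nrow(txt), ncol(txt))
  if (all(Im(m) == 0)) Re(m) else m
}

#' Serialize a uniqueness certificate to JSON
#'
#' @param cert a [certify_uniqueness()] certificate. @param path file.
#' @return `path`, invisibly.
#' @export
write_certificate_json <- function(cert, path) {
  stopifnot(inherits(cert, "uniqueness_certificate"))
  enc_vec <- function(v) if (is.null(v)) NULL else
    if (is.complex(v)) list(re = Re(v), im = Im(v)) else list(re = as.numeric(v))
  out <- list(spark_value = cert$spark_value, k = cert$k, unique = cert$unique,
              witness = if (is.null(cert$witness)) NULL else
                list(a1 = enc_vec(cert$witness$a1), a2 = enc_vec(cert$witness$a2)),
              tolerances = cert$tolerances)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write/read a cohort as CSV
#'
#' Column dictionary: `group` (nominal group), `age` (years), `male`,
#' `hypertension` (logical), `plt` (x10^9/L), `dose` (standard/low),
#' `infarct_site` (anterior/posterior), `responsible_artery`,
#' `occlusion_status` (normal/stenosis/occlusion), `occlusion` (0/1
#' indicator), `nihss_*` (integer scores at the five timepoints),
#' `end_label` (logical).
#' @param cohort data.frame. @param path file path.
#' @return `path` invisibly, or the cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in c("male", "hypertension", "end_label"))
    if (cl %in% names(df)) df[[cl]] <- as.logical(df[[cl]])
  df
}
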