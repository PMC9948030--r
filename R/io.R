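#' Read a 4D NIfTI volume as an echo series
#'
#' The voxel grid comes from the image, the repetition time from the NIfTI
#' header's time-step field unless overridden, and the echo time from the
#' caller (NIfTI headers do not carry it).
#'
#' @param path Path to a `.nii`/`.nii.gz` file with 4 dimensions.
#' @param te Echo time in seconds.
#' @param tr Repetition time in seconds; default `NULL` reads the header
#'   time step.
#' @param t0 Time of the first frame (seconds).
#' @return An [echo_series()].
#' @export
read_echo_series <- function(path, te, tr = NULL, t0 = 0) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("'%s' is not a 4D NIfTI volume (field: dim)", path))
  if (is.null(tr)) {
    tr <- RNifti::pixdim(img)[4]
    if (!is.finite(tr) || tr <= 0)
      stop(sprintf("'%s' has no usable time step (field: pixdim[4]); pass 'tr'",
                   path))
  }
  echo_series(array(as.numeric(img), dim = d), te = te, tr = tr, t0 = t0)
}

#' Read a 3D NIfTI label or mask volume
#'
#' @param path Path to a NIfTI file.
#' @param logical Return a logical array (`TRUE` where non-zero)?
#' @return 3D integer or logical array.
#' @export
read_label_volume <- function(path, logical = FALSE) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1]
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop(sprintf("'%s' is not a 3D NIfTI volume (field: dim)", path))
  a <- array(as.numeric(img), dim = d)
  if (logical) a != 0 else array(as.integer(round(a)), dim = d)
}

#' Write a 3D/4D map as NIfTI
#'
#' @param map Numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param tr Time step recorded in the header for 4D data (seconds).
#' @param description Short free-text description (e.g. units) stored in
#'   the header.
#' @param datatype NIfTI storage type; `"float"` (default) or `"double"`
#'   for bit-exact round trips.
#' @return The path, invisibly.
#' @export
write_nifti_map <- function(map, path, tr = NULL, description = "",
                            datatype = "float") {
  img <- RNifti::asNifti(map)
  if (!is.null(tr) && length(dim(map)) == 4L) {
    pd <- RNifti::pixdim(img)
    pd[4] <- tr
    RNifti::pixdim(img) <- pd
  }
  img <- RNifti::asNifti(img, descrip = description)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a gas trace from a TSV/CSV file
#'
#' Expects columns `time_s` and `etco2_mmHg` (optionally `eto2_mmHg`).
#'
#' @param path Path to a tab- or comma-separated file with a header row.
#' @return A [gas_trace()].
#' @export
read_gas_trace <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("time_s", "etco2_mmHg")
  if (!all(need %in% names(df)))
    stop(sprintf("'%s' is missing required columns (fields: %s)", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  gas_trace(df$time_s, df$etco2_mmHg,
            eto2 = if ("eto2_mmHg" %in% names(df)) df$eto2_mmHg else NULL)
}

#' Write a gas trace as TSV
#'
#' @param gas A [gas_trace()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gas_trace <- function(gas, path) {
  utils::write.table(as.data.frame(gas), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a phantom to disk
#'
#' Writes one NIfTI per echo, the label and brain-mask volumes, the
#' ground-truth maps, the gas trace as TSV, and a JSON echo of the
#' specification for provenance. Volumes are stored as double precision so
#' writing then reading reproduces the arrays bit-exactly.
#'
#' @param phantom A `phantom` from [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (i in seq_along(phantom$echoes)) {
    p <- file.path(dir, sprintf("bold_echo%d.nii.gz", i))
    write_nifti_map(phantom$echoes[[i]]$data, p, tr = phantom$spec$tr,
                    description = sprintf("TE=%.0fms", 1000 * phantom$spec$te[i]),
                    datatype = "double")
    paths[[sprintf("echo%d", i)]] <- p
  }
  paths$labels <- write_nifti_map(phantom$labels + 0,
                                  file.path(dir, "labels.nii.gz"),
                                  description = "0=bg 1=GM 2=WM 3=vein",
                                  datatype = "double")
  paths$brain_mask <- write_nifti_map(phantom$brain_mask + 0,
                                      file.path(dir, "brain_mask.nii.gz"),
                                      datatype = "double")
  for (nm in c("cbf", "cbv", "td", "mtt", "cvr")) {
    p <- file.path(dir, sprintf("truth_%s.nii.gz", nm))
    write_nifti_map(phantom$truth[[nm]], p, datatype = "double")
    paths[[paste0("truth_", nm)]] <- p
  }
  paths$gas <- write_gas_trace(phantom$gas, file.path(dir, "etco2.tsv"))
  spec <- phantom$spec
  class(spec) <- NULL
  paths$spec <- file.path(dir, "phantom_spec.json")
  jsonlite::write_json(spec, paths$spec, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Write the maps of a perfusion fit
#'
#' Writes each perfusion map as float32 NIfTI with its units in the header
#' description, plus a JSON sidecar recording the fundamental frequency,
#' VOF voxel list, venous phase, kinetic constants and clamp counts.
#'
#' @param fit A `sinedsc_fit`.
#' @param dir Output directory.
#' @return Named list of written paths, invisibly.
#' @export
write_fit_maps <- function(fit, dir) {
  stopifnot(inherits(fit, "sinedsc_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (nm in names(fit$maps)) {
    m <- fit$maps[[nm]]
    if (is.null(m)) next
    p <- file.path(dir, sprintf("%s.nii.gz", nm))
    unit <- if (nm %in% names(fit$units)) fit$units[[nm]] else ""
    write_nifti_map(m, p, description = unit)
    paths[[nm]] <- p
  }
  paths$suppressed <- write_nifti_map(fit$suppressed + 0,
                                      file.path(dir, "vein_suppressed.nii.gz"))
  side <- list(f_c_hz = fit$f_c, period_s = fit$period, tr_s = fit$tr,
               n_frames_used = fit$n_frames_used,
               dual_echo = fit$dual_echo,
               vof_voxels = unname(apply(fit$vof$voxel_indices, 1, paste,
                                         collapse = ",")),
               venous_delay_s = fit$venous$delay_s,
               venous_phase_rad = fit$venous$phase,
               kappa = fit$config$kappa, rho = fit$config$rho,
               apply_kappa_to_cbf = fit$config$apply_kappa_to_cbf,
               etco2_lag_global_s = fit$lag_global,
               counts = fit$counts, units = as.list(fit$units))
  paths$sidecar <- file.path(dir, "fit_provenance.json")
  jsonlite::write_json(side, paths$sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
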