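#' Summarize a map over labelled regions of interest
#'
#' Per-ROI mean, standard deviation and voxel count, excluding suppressed
#' (e.g. pial-vein) and undefined voxels. ROIs left empty after exclusion
#' are dropped with a warning.
#'
#' @param map 3D numeric map.
#' @param labels 3D integer array of ROI labels; 0 is background.
#' @param exclusion_mask Optional 3D logical array of voxels to exclude.
#' @param roi_names Optional named character vector mapping label values to
#'   names.
#' @return A data frame with columns `roi`, `label`, `n_voxels`, `mean`,
#'   `sd`.
#' @export
roi_summary <- function(map, labels, exclusion_mask = NULL,
                        roi_names = NULL) {
  if (!identical(dim(map), dim(labels)))
    stop("'map' and 'labels' grids do not match")
  keep <- is.finite(map) & labels > 0
  if (!is.null(exclusion_mask)) {
    if (!identical(dim(exclusion_mask), dim(map)))
      stop("'exclusion_mask' grid does not match")
    keep <- keep & !exclusion_mask
  }
  ids <- sort(unique(labels[labels > 0]))
  rows <- lapply(ids, function(id) {
    v <- map[keep & labels == id]
    if (!length(v)) {
      warning(sprintf("ROI %d empty after exclusion; dropped", id))
      return(NULL)
    }
    data.frame(roi = id,
               label = if (!is.null(roi_names) &&
                           as.character(id) %in% names(roi_names))
                 roi_names[[as.character(id)]] else as.character(id),
               n_voxels = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no ROIs survived exclusion")
  rownames(out) <- NULL
  out
}

#' Pearson correlation of ROI means between two methods
#'
#' @param table_a,table_b ROI tables from [roi_summary()]; correlated over
#'   ROIs present in both (matched on `roi`).
#' @return Pearson r; `NA` with a warning if either method has zero
#'   variance over the shared ROIs.
#' @export
pearson_roi <- function(table_a, table_b) {
  shared <- intersect(table_a$roi, table_b$roi)
  if (length(shared) < 3)
    stop("need at least 3 shared ROIs")
  a <- table_a$mean[match(shared, table_a$roi)]
  b <- table_b$mean[match(shared, table_b$roi)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in ROI means; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Normalized 95% limits of agreement
#'
#' Bland-Altman statistics for paired measurements from two methods:
#' differences `d = A - B`, bias `mean(d)`, limits `bias +/- 1.96 sd(d)`
#' (sample sd), all normalized by the grand mean of the pairwise averages
#' `(A + B) / 2` and reported as percentages.
#'
#' @param vals_a,vals_b Paired numeric vectors of equal length (>= 2).
#' @return A list of class `agreement_report` with `pearson_r`,
#'   `bias_percent`, `loa_low_percent`, `loa_high_percent`, `n`.
#' @export
limits_of_agreement <- function(vals_a, vals_b) {
  if (length(vals_a) != length(vals_b) || length(vals_a) < 2)
    stop("'vals_a' and 'vals_b' must be paired with length >= 2")
  ok <- is.finite(vals_a) & is.finite(vals_b)
  a <- vals_a[ok]; b <- vals_b[ok]
  if (length(a) < 2)
    stop("fewer than 2 finite pairs")
  d <- a - b
  norm <- mean((a + b) / 2)
  if (norm == 0)
    stop("zero normalizer (grand mean of pairwise averages)")
  bias <- mean(d)
  half <- 1.96 * stats::sd(d)
  r <- if (stats::sd(a) > 0 && stats::sd(b) > 0) stats::cor(a, b) else NA_real_
  structure(list(pearson_r = r,
                 bias_percent = 100 * bias / norm,
                 loa_low_percent = 100 * (bias - half) / norm,
                 loa_high_percent = 100 * (bias + half) / norm,
                 n = length(a)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d, r = %.3f, bias %.2f%%, 95%% LoA [%.1f%%, %.1f%%]\n",
              x$n, x$pearson_r, x$bias_percent, x$loa_low_percent,
              x$loa_high_percent))
  invisible(x)
}

#' Coefficient of variation
#'
#' Intersubject mode: `sd / mean * 100` across subjects. Test-retest mode:
#' root-mean-square of the within-subject standard deviations divided by
#' the grand mean, times 100; `values` must then be a matrix with one row
#' per subject and one column per replicate.
#'
#' @param values Numeric vector (intersubject) or subjects-by-replicates
#'   matrix (test-retest).
#' @param mode `"intersubject"` or `"test_retest"`.
#' @return Coefficient of variation in percent.
#' @export
coefficient_of_variation <- function(values,
                                     mode = c("intersubject", "test_retest")) {
  mode <- match.arg(mode)
  if (mode == "intersubject") {
    if (length(values) < 2)
      stop("need at least 2 values")
    m <- mean(values)
    if (m == 0) stop("zero mean")
    return(100 * stats::sd(values) / m)
  }
  if (!is.matrix(values) || ncol(values) < 2)
    stop("test-retest mode needs a subjects-by-replicates matrix (>= 2 columns)")
  m <- mean(values)
  if (m == 0) stop("zero mean")
  within_sd <- apply(values, 1, stats::sd)
  100 * sqrt(mean(within_sd^2)) / m
}
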