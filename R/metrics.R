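# Dose-volume metrics in the clinical constraint dialect. The volume
# threshold V(d) counts voxels with dose >= d (closed threshold; the
# convention is fixed here and used consistently by evaluation and tests).

#' Dose metric over a structure
#'
#' Evaluates one scalar dose statistic on a dose grid restricted to a mask:
#' * `"v_pct"` - V(d) as percent of the structure volume receiving `>= doseGy`;
#' * `"v_cc"`  - V(d) in cc;
#' * `"mean"`  - mean structure dose (Gy-RBE);
#' * `"max"`   - maximum voxel dose in the structure (Gy-RBE);
#' * `"sparing"` - S(d): structure volume receiving `< doseGy`, in cc (the
#'   "total volume minus V(d)" low-dose sparing metric).
#'
#' @param dose Numeric 3D dose grid (Gy-RBE).
#' @param mask Logical array on the same grid; must be non-empty.
#' @param metric One of `"v_pct"`, `"v_cc"`, `"mean"`, `"max"`, `"sparing"`.
#' @param doseGy Threshold dose for the volume metrics (ignored for
#'   `mean`/`max`).
#' @param spacing Voxel spacing in mm (needed for the cc metrics).
#' @return Scalar in the metric's native unit (%, cc or Gy).
#' @export
doseMetric <- function(dose, mask, metric = c("v_pct", "v_cc", "mean", "max", "sparing"),
                       doseGy = NA_real_, spacing = NULL) {
  metric <- match.arg(metric)
  if (!identical(dim(dose), dim(mask))) stop("dose and mask must share one grid")
  n <- sum(mask)
  if (n == 0L) stop("dose metric requested on an empty mask")
  dm <- dose[mask]
  if (metric %in% c("v_pct", "v_cc", "sparing") && !is.finite(doseGy)) {
    stop("metric '", metric, "' requires a threshold dose")
  }
  switch(metric,
    v_pct = 100 * sum(dm >= doseGy) / n,
    v_cc = {
      if (is.null(spacing)) stop("cc metrics require the voxel spacing")
      sum(dm >= doseGy) * voxelVolumeCC(spacing)
    },
    mean = mean(dm),
    max = max(dm),
    sparing = {
      if (is.null(spacing)) stop("cc metrics require the voxel spacing")
      sum(dm < doseGy) * voxelVolumeCC(spacing)
    }
  )
}

#' Cumulative dose-volume histogram
#'
#' @param dose Numeric 3D dose grid (Gy-RBE).
#' @param mask Logical array on the same grid; must be non-empty.
#' @param binWidthGy Dose bin width (Gy, `> 0`).
#' @return data.frame with columns `doseGy` and `volumePct`; starts at 100%
#'   at 0 Gy and is monotone non-increasing. `volumePct` at level `x` equals
#'   [doseMetric()] `v_pct` with threshold `x`.
#' @export
dvhCurve <- function(dose, mask, binWidthGy = 0.5) {
  stopifnot(binWidthGy > 0)
  if (!identical(dim(dose), dim(mask))) stop("dose and mask must share one grid")
  n <- sum(mask)
  if (n == 0L) stop("DVH requested on an empty mask")
  dm <- dose[mask]
  levels <- seq(0, max(dm) + binWidthGy, by = binWidthGy)
  pct <- vapply(levels, function(L) 100 * sum(dm >= L) / n, numeric(1))
  data.frame(doseGy = levels, volumePct = pct)
}
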