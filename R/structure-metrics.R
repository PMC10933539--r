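#' Tree height from a point cloud
#'
#' Height is the vertical extent of the cloud: `max(z) - min(z)`. Invariant
#' under translation and rotation about the vertical axis.
#'
#' @param cloud A [point_cloud()].
#' @return Height in metres.
#' @export
tree_height <- function(cloud) {
  check_cloud(cloud)
  max(cloud$z) - min(cloud$z)
}

#' Horizontal cross-section of a cloud
#'
#' Extracts all points whose height above the cloud's lowest point lies in
#' the half-open interval `[z_low, z_high)` and flattens them onto the x-y
#' plane. Heights are always measured relative to `min(z)`, so absolute
#' georeferencing does not matter.
#'
#' @param cloud A [point_cloud()].
#' @param z_low,z_high Slice bounds in metres above the lowest point.
#' @param min_points Minimum points required in the slice (error below this).
#' @return A tibble of class `cross_section` with columns `x`, `y` and
#'   attributes `z_low`, `z_high`.
#' @export
slice_cloud <- function(cloud, z_low, z_high, min_points = 20L) {
  check_cloud(cloud)
  if (z_high <= z_low) stop_bad_arg("z_high (%.3f) must exceed z_low (%.3f)", z_high, z_low)
  rel <- cloud$z - min(cloud$z)
  keep <- rel >= z_low & rel < z_high
  n <- sum(keep)
  if (n < min_points)
    abort(sprintf("insufficient points in slice [%.2f, %.2f): %d < %d", z_low, z_high, n, min_points),
          class = "tlscarbon_insufficient_points", n_points = n)
  out <- tibble::tibble(x = cloud$x[keep], y = cloud$y[keep])
  attr(out, "z_low") <- z_low
  attr(out, "z_high") <- z_high
  class(out) <- unique(c("cross_section", class(out)))
  out
}

#' Fit the least-squares circle to a cross-section
#'
#' Geometric (orthogonal-distance) least-squares circle through a stem
#' cross-section, initialised from the algebraic fit; see
#' [fit_circle_geometric()] for the numerical contract.
#'
#' @param section A `cross_section` from [slice_cloud()] (or any data frame
#'   with `x`, `y`).
#' @param min_points Minimum points for a meaningful fit.
#' @return A `circle_fit` list.
#' @export
fit_circle_ls <- function(section, min_points = 20L) {
  fit_circle_geometric(section$x, section$y, min_points = min_points)
}

#' Stem diameters from a tree point cloud
#'
#' `estimate_dbh()` fits the least-squares circle to the breast-height
#' cross-section (default 1.2-1.4 m above the lowest point) and returns its
#' diameter. `estimate_dtb()` does the same for the above-buttress slice
#' (default 4.0-4.5 m), which avoids basal flare. `estimate_fdbh()` returns
#' the functional DBH: the diameter of a circle with the same area as the
#' convex hull of the breast-height cross-section, `2*sqrt(A/pi)`.
#'
#' @param cloud A [point_cloud()].
#' @param slice Numeric length-2 slice interval `[low, high)` in metres above
#'   the lowest point.
#' @param min_points Minimum points per slice.
#' @return Diameter in metres.
#' @export
estimate_dbh <- function(cloud, slice = c(1.2, 1.4), min_points = 20L) {
  section <- slice_cloud(cloud, slice[1], slice[2], min_points = min_points)
  2 * fit_circle_ls(section, min_points = min_points)$radius
}

#' @rdname estimate_dbh
#' @export
estimate_dtb <- function(cloud, slice = c(4.0, 4.5), min_points = 20L) {
  estimate_dbh(cloud, slice = slice, min_points = min_points)
}

# polygon area by the shoelace formula; vertices in order
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

hull_area_2d <- function(x, y) {
  if (length(x) < 3) stop_bad_arg("convex hull area needs >= 3 points")
  h <- grDevices::chull(x, y)
  a <- shoelace_area(x[h], y[h])
  if (a <= 0)
    stop_bad_arg("degenerate hull: cross-section has zero area",
                 class = "tlscarbon_degenerate")
  a
}

#' @rdname estimate_dbh
#' @export
estimate_fdbh <- function(cloud, slice = c(1.2, 1.4), min_points = 20L) {
  section <- slice_cloud(cloud, slice[1], slice[2], min_points = min_points)
  2 * sqrt(hull_area_2d(section$x, section$y) / pi)
}

#' Crown volume as a 3-D convex hull
#'
#' Volume of the three-dimensional convex hull of all points at height
#' `crown_base` or above (relative to the cloud's lowest point). With
#' `crown_base = "auto"` the crown base is detected as the lowest slice
#' whose horizontal point spread exceeds `auto_spread_factor` times the
#' above-buttress stem radius.
#'
#' @param cloud A [point_cloud()].
#' @param crown_base Height of the crown base (m above lowest point) or
#'   `"auto"`.
#' @param auto_spread_factor Spread multiple used by crown-base detection.
#' @return Crown volume in cubic metres.
#' @export
crown_volume <- function(cloud, crown_base = "auto", auto_spread_factor = 1.5) {
  check_cloud(cloud, min_points = 4L, what = "crown volume")
  if (identical(crown_base, "auto"))
    crown_base <- detect_crown_base(cloud, spread_factor = auto_spread_factor)
  rel <- cloud$z - min(cloud$z)
  keep <- rel >= crown_base
  if (sum(keep) < 4)
    stop_bad_arg("degenerate crown: only %d point(s) at or above crown base %.2f m",
                 sum(keep), crown_base, class = "tlscarbon_degenerate")
  pts <- cbind(cloud$x[keep], cloud$y[keep], cloud$z[keep])
  hull <- tryCatch(.convex_hull_3d_cpp(pts), error = function(e)
    stop_bad_arg("degenerate crown: %s", conditionMessage(e),
                 class = "tlscarbon_degenerate"))
  hull$volume
}

# crown base = lowest 0.5 m slice whose 95th-percentile horizontal radius
# (about the slice's own centroid) exceeds spread_factor x the stem radius
# from the above-buttress slice; falls back to half the tree height if the
# spread never exceeds the threshold (columnar cloud)
detect_crown_base <- function(cloud, spread_factor = 1.5, slice_height = 0.5) {
  h <- tree_height(cloud)
  r_stem <- tryCatch(estimate_dtb(cloud) / 2, error = function(e) NULL)
  if (is.null(r_stem))
    r_stem <- tryCatch(estimate_dbh(cloud) / 2, error = function(e) h / 50)
  rel <- cloud$z - min(cloud$z)
  # start above the buttress region so basal flare is not mistaken for crown
  start <- min(4.5, 0.25 * h)
  breaks <- seq(floor(start / slice_height) * slice_height, h + slice_height,
                by = slice_height)
  for (i in seq_len(length(breaks) - 1)) {
    keep <- rel >= breaks[i] & rel < breaks[i + 1]
    if (sum(keep) < 10) next
    xs <- cloud$x[keep]; ys <- cloud$y[keep]
    rr <- sqrt((xs - median(xs))^2 + (ys - median(ys))^2)
    if (quantile(rr, 0.95) > spread_factor * r_stem) return(breaks[i])
  }
  h / 2
}

#' All structural metrics for one tree
#'
#' Runs every structural estimator (height, DBH, DTB, functional DBH, crown
#' volume, slice-stack woody volume with repeat-fit SD) on one cloud.
#' Individual estimator failures do not abort the tree: the metric is
#' returned as `NA` and the failure reason recorded in the `issues`
#' list-column, so a pipeline over many trees degrades gracefully.
#'
#' @param cloud A [point_cloud()].
#' @param tree_id Identifier for the output row (defaults to the cloud's
#'   source id).
#' @param dbh_slice,dtb_slice Slice intervals (m above lowest point).
#' @param crown_base Passed to [crown_volume()].
#' @param min_cloud_points Clouds below this size get no diameter/volume
#'   estimates (height is still reported).
#' @param volume_config List of arguments forwarded to [estimate_volume()]
#'   (e.g. `slice_height`, `n_repeats`, `branch_allowance`, `seed`).
#' @return One-row tibble: `tree_id`, `h_m`, `dbh_m`, `dtb_m`, `fdbh_m`,
#'   `cv_m3`, `v_m3`, `v_sd_m3`, and `issues` (named character vector of
#'   per-metric failure reasons, empty when all succeeded).
#' @export
compute_all_metrics <- function(cloud, tree_id = NULL,
                                dbh_slice = c(1.2, 1.4), dtb_slice = c(4.0, 4.5),
                                crown_base = "auto", min_cloud_points = 100L,
                                volume_config = list()) {
  check_cloud(cloud)
  tree_id <- tree_id %||% cloud_source(cloud)
  issues <- character(0)
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      issues[[name]] <<- conditionMessage(e)
      NA_real_
    })
  }
  h <- grab("height", tree_height(cloud))
  enough <- nrow(cloud) >= min_cloud_points
  if (!enough) {
    msg <- sprintf("insufficient points: cloud has %d < %d", nrow(cloud), min_cloud_points)
    for (nm in c("dbh", "dtb", "fdbh", "crown_volume", "volume")) issues[[nm]] <- msg
    dbh <- dtb <- fdbh <- cv <- vm <- vs <- NA_real_
  } else {
    dbh <- grab("dbh", estimate_dbh(cloud, slice = dbh_slice))
    dtb <- grab("dtb", estimate_dtb(cloud, slice = dtb_slice))
    fdbh <- grab("fdbh", estimate_fdbh(cloud, slice = dbh_slice))
    cv <- grab("crown_volume", crown_volume(cloud, crown_base = crown_base))
    ve <- grab("volume", do.call(estimate_volume, c(list(cloud = cloud), volume_config)))
    if (is.list(ve)) {
      vm <- ve$volume_mean
      vs <- ve$volume_sd
    } else {
      vm <- vs <- NA_real_
    }
  }
  tibble::tibble(tree_id = tree_id, h_m = h, dbh_m = dbh, dtb_m = dtb,
                 fdbh_m = fdbh, cv_m3 = cv, v_m3 = vm, v_sd_m3 = vs,
                 issues = list(issues))
}
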