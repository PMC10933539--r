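#' Specify a synthetic tree
#'
#' Defines a tall open-grown conifer as a solid of revolution: a tapered
#' trunk with a basal buttress flare, a crown solid (conoid, paraboloid or
#' prolate spheroid) of branch/foliage-surface points, explicit cylindrical
#' branches, sampling density, range noise and an azimuthal occlusion
#' sector. Every structural quantity a downstream estimator targets has a
#' closed-form ground truth, so estimator error can be measured exactly.
#'
#' The trunk radius above the flare follows
#' `r(h) = r_bh * ((H - h)/(H - 1.3))^taper_exponent`, where `r_bh` is set so
#' the full profile (taper + flare) has diameter `dbh_true` at 1.3 m. The
#' flare adds `buttress_extra_radius * (1 - h/flare_height)^2` below
#' `flare_height`.
#'
#' @param total_height Tree height H (m).
#' @param dbh_true True stem diameter at 1.3 m, including flare (m).
#' @param buttress_extra_radius Extra radius at ground level (m), decaying
#'   quadratically to zero at `flare_height`.
#' @param flare_height Height at which the buttress flare vanishes (m).
#' @param taper_exponent Trunk taper exponent (1 = cone above breast height).
#' @param crown_base_height Height of the crown base (m).
#' @param crown_shape One of `"conoid"`, `"paraboloid"`, `"prolate_spheroid"`.
#' @param crown_max_radius Maximum crown radius (m).
#' @param point_spacing Nominal spacing between sampled surface points (m).
#' @param noise_sd Gaussian range-noise standard deviation per coordinate (m).
#' @param occlusion_fraction Angular fraction of the trunk removed as an
#'   azimuthal sector, in `[0, 1)`.
#' @param lean_deg Whole-tree lean from vertical (degrees).
#' @param branch_fraction Branch volume as a fraction of trunk volume; the
#'   branch cylinders' summed volume equals this exactly.
#' @param n_branches Number of explicit branch cylinders.
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return A list of class `tree_spec`.
#' @export
tree_spec <- function(total_height = 45, dbh_true = 1.5,
                      buttress_extra_radius = 0.25, flare_height = 2.5,
                      taper_exponent = 1, crown_base_height = 8,
                      crown_shape = c("conoid", "paraboloid", "prolate_spheroid"),
                      crown_max_radius = 4, point_spacing = 0.05,
                      noise_sd = 0.005, occlusion_fraction = 0,
                      lean_deg = 0, branch_fraction = 0.15,
                      n_branches = 40, seed = 1L) {
  crown_shape <- match.arg(crown_shape)
  spec <- list(total_height = total_height, dbh_true = dbh_true,
               buttress_extra_radius = buttress_extra_radius,
               flare_height = flare_height, taper_exponent = taper_exponent,
               crown_base_height = crown_base_height, crown_shape = crown_shape,
               crown_max_radius = crown_max_radius, point_spacing = point_spacing,
               noise_sd = noise_sd, occlusion_fraction = occlusion_fraction,
               lean_deg = lean_deg, branch_fraction = branch_fraction,
               n_branches = n_branches, seed = as.integer(seed))
  class(spec) <- "tree_spec"
  validate_tree_spec(spec)
  spec
}

validate_tree_spec <- function(spec) {
  chk <- function(ok, constraint) {
    if (!ok) stop_bad_arg("invalid tree_spec: violated constraint '%s'", constraint,
                          class = "tlscarbon_invalid_spec")
  }
  chk(spec$total_height > spec$crown_base_height,
      "total_height > crown_base_height")
  chk(spec$crown_base_height > spec$flare_height,
      "crown_base_height > flare_height")
  chk(spec$flare_height > 1.4, "flare_height > 1.4")
  chk(spec$occlusion_fraction >= 0 && spec$occlusion_fraction < 1,
      "0 <= occlusion_fraction < 1")
  chk(spec$point_spacing > 0, "point_spacing > 0")
  chk(spec$noise_sd >= 0, "noise_sd >= 0")
  chk(spec$dbh_true > 0, "dbh_true > 0")
  chk(spec$buttress_extra_radius >= 0, "buttress_extra_radius >= 0")
  chk(spec$branch_fraction >= 0, "branch_fraction >= 0")
  chk(breast_taper_radius(spec) > 0,
      "dbh_true/2 > buttress flare contribution at 1.3 m")
  invisible(spec)
}

flare_radius <- function(spec, h) {
  ifelse(h < spec$flare_height,
         spec$buttress_extra_radius * (1 - h / spec$flare_height)^2, 0)
}

breast_taper_radius <- function(spec) {
  spec$dbh_true / 2 - flare_radius(spec, 1.3)
}

# full trunk radius profile (taper + flare), vectorised over h
trunk_radius <- function(spec, h) {
  H <- spec$total_height
  r_bh <- breast_taper_radius(spec)
  taper <- r_bh * (pmax(H - h, 0) / (H - 1.3))^spec$taper_exponent
  taper + flare_radius(spec, h)
}

# crown radius profile; u measured from crown base, apex at total_height
crown_radius <- function(spec, h) {
  d <- spec$total_height - spec$crown_base_height
  u <- h - spec$crown_base_height
  R <- spec$crown_max_radius
  out <- rep(0, length(h))
  inside <- u >= 0 & u <= d
  ui <- u[inside]
  out[inside] <- switch(spec$crown_shape,
    conoid = R * (1 - ui / d),
    paraboloid = R * sqrt(pmax(1 - ui / d, 0)),
    prolate_spheroid = R * sqrt(pmax(1 - ((ui - d / 2) / (d / 2))^2, 0)))
  out
}

crown_volume_closed_form <- function(spec) {
  d <- spec$total_height - spec$crown_base_height
  R <- spec$crown_max_radius
  switch(spec$crown_shape,
         conoid = pi * R^2 * d / 3,
         paraboloid = pi * R^2 * d / 2,
         prolate_spheroid = 4 / 3 * pi * R^2 * (d / 2))
}

trunk_volume_closed_form <- function(spec) {
  f <- function(h) trunk_radius(spec, h)^2
  # split at the flare edge where the profile's derivative is discontinuous
  v1 <- integrate(f, 0, spec$flare_height, rel.tol = 1e-11)$value
  v2 <- integrate(f, spec$flare_height, spec$total_height, rel.tol = 1e-11)$value
  pi * (v1 + v2)
}

#' Ground truth for a synthetic tree
#'
#' Closed-form structural truth for a [tree_spec()]: the quantities every
#' estimator in the package targets. Trunk volume is the exact integral of
#' the squared radius profile (adaptive quadrature at 1e-11 relative
#' tolerance); crown volume is the closed form of the chosen crown solid;
#' diameters are read off the radius profile at the measurement-slice
#' midpoints (1.3 m and 4.25 m).
#'
#' @param spec A [tree_spec()].
#' @return One-row tibble with `height_true`, `dbh_true`, `dtb_true`,
#'   `fdbh_true`, `trunk_volume_true`, `branch_volume_true`,
#'   `woody_volume_true`, `crown_volume_true` (m / m^3).
#' @export
tree_ground_truth <- function(spec) {
  validate_tree_spec(spec)
  vt <- trunk_volume_closed_form(spec)
  tibble::tibble(
    height_true = spec$total_height,
    dbh_true = 2 * trunk_radius(spec, 1.3),
    dtb_true = 2 * trunk_radius(spec, 4.25),
    fdbh_true = 2 * trunk_radius(spec, 1.3),
    trunk_volume_true = vt,
    branch_volume_true = spec$branch_fraction * vt,
    woody_volume_true = vt * (1 + spec$branch_fraction),
    crown_volume_true = crown_volume_closed_form(spec))
}

ring_ladder <- function(radius_fun, z_lo, z_hi, spacing, part) {
  hs <- seq(z_lo, z_hi, by = spacing)
  rs <- radius_fun(hs)
  n_az <- pmax(3L, ceiling(2 * pi * rs / spacing))
  n_az[rs <= 0] <- 1L
  phase <- runif(length(hs), 0, 2 * pi)
  h_all <- rep(hs, n_az)
  r_all <- rep(rs, n_az)
  th <- unlist(lapply(seq_along(hs), function(i)
    phase[i] + 2 * pi * seq_len(n_az[i]) / n_az[i]), use.names = FALSE)
  tibble::tibble(x = r_all * cos(th), y = r_all * sin(th), z = h_all,
                 azimuth = th %% (2 * pi), part = part)
}

#' Generate a synthetic tree point cloud with known ground truth
#'
#' Samples the trunk surface of revolution (rings at the point spacing),
#' explicit branch cylinders whose summed volume is exactly
#' `branch_fraction` of the trunk volume, and the crown solid's surface plus
#' sparse interior points. Gaussian noise is then added per coordinate, an
#' azimuthal sector of the trunk is removed to emulate occlusion, and the
#' whole tree is leaned. Deterministic for a fixed spec (one seeded RNG
#' stream per call; the caller's RNG state is untouched).
#'
#' @param spec A [tree_spec()].
#' @return List with elements `cloud` (a [point_cloud()] tibble with a
#'   `part` column: trunk / branch / crown) and `truth`
#'   (a [tree_ground_truth()] row).
#' @export
generate_tree_cloud <- function(spec) {
  validate_tree_spec(spec)
  truth <- tree_ground_truth(spec)
  with_rng(spec$seed, {
    H <- spec$total_height
    sp <- spec$point_spacing

    trunk <- ring_ladder(function(h) trunk_radius(spec, h), 0, H - sp / 2, sp, "trunk")
    trunk <- dplyr::bind_rows(trunk,
      tibble::tibble(x = 0, y = 0, z = H, azimuth = 0, part = "trunk"))
    if (spec$occlusion_fraction > 0) {
      a0 <- runif(1, 0, 2 * pi)
      width <- 2 * pi * spec$occlusion_fraction
      rel <- (trunk$azimuth - a0) %% (2 * pi)
      trunk <- trunk[rel >= width, , drop = FALSE]
    }

    # branch cylinders: radii scaled so total volume hits the stated fraction
    branches <- NULL
    if (spec$branch_fraction > 0 && spec$n_branches > 0) {
      nb <- spec$n_branches
      hb <- runif(nb, spec$crown_base_height, spec$crown_base_height +
                    0.9 * (H - spec$crown_base_height))
      len <- pmax(0.9 * crown_radius(spec, hb), 0.3)
      az <- runif(nb, 0, 2 * pi)
      tilt <- runif(nb, -20, 10) * pi / 180
      scale_c <- sqrt(truth$branch_volume_true / (pi * sum(len^2)))
      rb <- scale_c * sqrt(len)
      branches <- purrr::map_dfr(seq_len(nb), function(i) {
        axis <- c(cos(az[i]) * cos(tilt[i]), sin(az[i]) * cos(tilt[i]), sin(tilt[i]))
        t_steps <- seq(0, len[i], by = max(2 * sp, 0.05))
        n_az <- max(3L, ceiling(2 * pi * rb[i] / max(2 * sp, 0.05)))
        th <- runif(1, 0, 2 * pi) + 2 * pi * seq_len(n_az) / n_az
        # orthonormal frame around the branch axis
        up <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
        e1 <- c(axis[2] * up[3] - axis[3] * up[2],
                axis[3] * up[1] - axis[1] * up[3],
                axis[1] * up[2] - axis[2] * up[1])
        e1 <- e1 / sqrt(sum(e1^2))
        e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
                axis[3] * e1[1] - axis[1] * e1[3],
                axis[1] * e1[2] - axis[2] * e1[1])
        base <- c(trunk_radius(spec, hb[i]) * cos(az[i]),
                  trunk_radius(spec, hb[i]) * sin(az[i]), hb[i])
        g <- expand.grid(t = t_steps, th = th)
        tibble::tibble(
          x = base[1] + g$t * axis[1] + rb[i] * (cos(g$th) * e1[1] + sin(g$th) * e2[1]),
          y = base[2] + g$t * axis[2] + rb[i] * (cos(g$th) * e1[2] + sin(g$th) * e2[2]),
          z = base[3] + g$t * axis[3] + rb[i] * (cos(g$th) * e1[3] + sin(g$th) * e2[3]),
          azimuth = NA_real_, part = "branch")
      })
    }

    # crown envelope surface + sparse interior fill
    crown <- NULL
    if (spec$crown_max_radius > 0) {
      sp_crown <- 2.5 * sp
      crown <- ring_ladder(function(h) crown_radius(spec, h),
                           spec$crown_base_height, H - sp_crown / 2, sp_crown, "crown")
      n_int <- max(20L, ceiling(nrow(crown) * 0.05))
      d <- H - spec$crown_base_height
      u <- numeric(0)
      while (length(u) < n_int) {
        cand <- runif(2 * n_int, 0, d)
        keep <- runif(2 * n_int) < (crown_radius(spec, spec$crown_base_height + cand) /
                                      spec$crown_max_radius)^2
        u <- c(u, cand[keep])
      }
      u <- u[seq_len(n_int)]
      rr <- sqrt(runif(n_int)) * crown_radius(spec, spec$crown_base_height + u)
      tth <- runif(n_int, 0, 2 * pi)
      crown <- dplyr::bind_rows(crown, tibble::tibble(
        x = rr * cos(tth), y = rr * sin(tth), z = spec$crown_base_height + u,
        azimuth = NA_real_, part = "crown"))
    }

    pts <- dplyr::bind_rows(trunk, branches, crown)
    pts$azimuth <- NULL
    if (spec$noise_sd > 0) {
      pts$x <- pts$x + rnorm(nrow(pts), 0, spec$noise_sd)
      pts$y <- pts$y + rnorm(nrow(pts), 0, spec$noise_sd)
      pts$z <- pts$z + rnorm(nrow(pts), 0, spec$noise_sd)
    }
    if (spec$lean_deg != 0) {
      a <- spec$lean_deg * pi / 180
      xz <- cbind(pts$x, pts$z) %*% matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
      pts$x <- xz[, 1]
      pts$z <- xz[, 2]
    }
    cloud <- point_cloud(pts, source_id = sprintf("synthetic_seed%d", spec$seed))
    attr(cloud, "seed") <- spec$seed
    list(cloud = cloud, truth = truth)
  })
}

#' Generate a synthetic site: a cohort of trees with known planting date
#'
#' Draws per-tree specs by jittering a template spec (multiplicative
#' Gaussian jitter on height, diameter, crown size and crown base), builds
#' each tree with its own derived seed, and attaches tree records with
#' `age = scan_year - planting_year`.
#'
#' @param n_trees Number of trees (>= 1).
#' @param planting_year,scan_year Calendar years; scan must be after planting.
#' @param template A [tree_spec()] used as the cohort mean.
#' @param jitter_frac Relative s.d. of the multiplicative jitter (0 = all
#'   trees identical to the template).
#' @param site Site label used in tree ids and records.
#' @param seed Integer seed for the whole site.
#' @return List with `clouds` (named list of point clouds), `records`
#'   (tibble of tree records incl. age), `truths` (tibble of ground truths
#'   keyed by `tree_id`).
#' @export
generate_site <- function(n_trees, planting_year, scan_year,
                          template = tree_spec(), jitter_frac = 0.1,
                          site = "site", seed = 1L) {
  if (n_trees < 1) stop_bad_arg("n_trees must be >= 1, got %d", n_trees)
  if (scan_year <= planting_year)
    stop_bad_arg("scan_year (%d) must be after planting_year (%d)", scan_year, planting_year)
  with_rng(seed, {
    mult <- function() pmax(rnorm(n_trees, 1, jitter_frac), 0.5)
    mH <- mult(); mD <- mult(); mR <- mult(); mB <- mult()
    tree_seeds <- (as.integer(seed) + 7919L * seq_len(n_trees)) %% 2147483647L
    specs <- purrr::map(seq_len(n_trees), function(i) {
      s <- template
      s$total_height <- template$total_height * mH[i]
      s$dbh_true <- template$dbh_true * mD[i]
      s$crown_max_radius <- template$crown_max_radius * mR[i]
      s$crown_base_height <- max(template$crown_base_height * mB[i],
                                 template$flare_height + 0.1)
      s$crown_base_height <- min(s$crown_base_height, 0.6 * s$total_height)
      s$seed <- tree_seeds[i]
      validate_tree_spec(s)
      s
    })
    ids <- sprintf("%s_T%02d", site, seq_len(n_trees))
    built <- purrr::map(specs, generate_tree_cloud)
    clouds <- setNames(purrr::map(built, "cloud"), ids)
    truths <- dplyr::bind_cols(tibble::tibble(tree_id = ids),
                               purrr::map_dfr(built, "truth"))
    records <- tree_records(tibble::tibble(
      site = site, tree_id = ids,
      planting_year = planting_year, scan_year = scan_year),
      source = sprintf("generate_site('%s')", site))
    list(clouds = clouds, records = records, truths = truths, specs = specs)
  })
}

#' Write a generated site to disk
#'
#' Writes one point-cloud file per tree plus `tree_records.csv` and
#' `ground_truth.csv`.
#'
#' @param site_data Result of [generate_site()].
#' @param dir Output directory (created if needed).
#' @param format `"ply"` or `"xyz"`.
#' @param binary Passed to [write_cloud()] for PLY.
#' @return `dir`, invisibly.
#' @export
write_site <- function(site_data, dir, format = c("ply", "xyz"), binary = TRUE) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(site_data$clouds)) {
    write_cloud(site_data$clouds[[id]],
                file.path(dir, paste0(id, ".", format)), format = format,
                binary = binary)
  }
  readr::write_csv(site_data$records[, c("site", "tree_id", "planting_year", "scan_year")],
                   file.path(dir, "tree_records.csv"))
  readr::write_csv(site_data$truths, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}
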