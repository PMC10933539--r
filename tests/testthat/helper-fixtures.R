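# shared in-code fixtures: everything is generated at test time

# a coarse, quick-to-generate synthetic tree spec
fast_spec <- function(...) {
  args <- list(...)
  defaults <- list(total_height = 28, dbh_true = 0.8, buttress_extra_radius = 0.15,
                   flare_height = 2.5, crown_base_height = 8, crown_max_radius = 3,
                   point_spacing = 0.08, noise_sd = 0.003, seed = 42L)
  do.call(tree_spec, utils::modifyList(defaults, args))
}

# noiseless power-taper solid sampled as a ring ladder: apex at z = h,
# basal radius r0; exponent 1 is a cone
make_cone_cloud <- function(h = 30, r0 = 0.5, spacing = 0.03, exponent = 1) {
  hs <- seq(0, h, by = spacing)
  r <- r0 * ((h - hs) / h)^exponent
  n_az <- pmax(3L, ceiling(2 * pi * r / spacing))
  n_az[r <= 0] <- 1L
  th <- unlist(lapply(seq_along(hs), function(i) 2 * pi * seq_len(n_az[i]) / n_az[i]))
  point_cloud(tibble::tibble(x = rep(r, n_az) * cos(th),
                             y = rep(r, n_az) * sin(th),
                             z = rep(hs, n_az)), source_id = "cone")
}

make_cylinder_cloud <- function(h = 10, r = 1, spacing = 0.05) {
  hs <- seq(0, h, by = spacing)
  n_az <- max(8L, ceiling(2 * pi * r / spacing))
  th <- rep(2 * pi * seq_len(n_az) / n_az, times = length(hs))
  point_cloud(tibble::tibble(x = r * cos(th), y = r * sin(th),
                             z = rep(hs, each = n_az)), source_id = "cylinder")
}

circle_points <- function(cx, cy, r, n = 100, noise_sd = 0, arc = c(0, 2 * pi)) {
  th <- seq(arc[1], arc[2], length.out = n)
  list(x = cx + r * cos(th) + rnorm(n, 0, noise_sd),
       y = cy + r * sin(th) + rnorm(n, 0, noise_sd))
}

rotate_z <- function(cloud, deg) {
  a <- deg * pi / 180
  point_cloud(tibble::tibble(
    x = cloud$x * cos(a) - cloud$y * sin(a),
    y = cloud$x * sin(a) + cloud$y * cos(a),
    z = cloud$z), source_id = cloud_source(cloud))
}

# independent quadrature oracle for solids of revolution (midpoint rule)
revolve_volume_oracle <- function(radius_fun, z_lo, z_hi, n = 200000) {
  z <- seq(z_lo, z_hi, length.out = n + 1)
  mid <- (z[-1] + z[-(n + 1)]) / 2
  sum(pi * radius_fun(mid)^2 * diff(z))
}
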