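# Shared fixtures, built once per test run and cached.

.tw_cache <- new.env(parent = emptyenv())

tw_cached <- function(key, expr) {
  if (!exists(key, envir = .tw_cache)) assign(key, expr, envir = .tw_cache)
  get(key, envir = .tw_cache)
}

tw_layout <- function() tw_cached("layout", electrode_layout(8L))

tw_pattern <- function() tw_cached("pattern", adjacent_pattern(tw_layout()))

tw_mesh <- function(target) {
  tw_cached(paste0("mesh", target), build_disk_mesh(0.07, target, tw_layout()))
}

# Homogeneous saline state on a mesh: voltages and Jacobian at 0.98 mA.
tw_saline_state <- function(target) {
  tw_cached(paste0("saline", target), {
    mesh <- tw_mesh(target)
    sigma <- apply_phantom(make_phantom("saline-homog"), mesh)
    list(mesh = mesh, sigma = sigma,
         vh = protocol_voltages(mesh, sigma, tw_pattern(), 0.98e-3),
         J = eit_jacobian(mesh, sigma, tw_pattern(), 0.98e-3))
  })
}

tw_agar_state <- function(target) {
  tw_cached(paste0("agar", target), {
    mesh <- tw_mesh(target)
    sigma <- apply_phantom(make_phantom("agar-homog"), mesh)
    list(mesh = mesh, sigma = sigma,
         vh = protocol_voltages(mesh, sigma, tw_pattern(), 0.98e-3),
         J = eit_jacobian(mesh, sigma, tw_pattern(), 0.98e-3))
  })
}

# Extremum pixel center, in meters.
tw_extremum_xy <- function(img, mode = c("min", "max")) {
  mode <- match.arg(mode)
  v <- img$values
  idx <- if (mode == "min") which(v == min(v), arr.ind = TRUE)[1L, ]
  else which(v == max(v), arr.ind = TRUE)[1L, ]
  c(img$grid$xc[idx[1L]], img$grid$yc[idx[2L]])
}
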