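# Synthetic phantoms mirroring the saline-tank and agar experiments, and
# noise profiles for the multiplexer switching-time scenarios.

#' Construct a phantom specification
#'
#' @param tank_radius_m Tank radius in meters.
#' @param background_sigma Background conductivity in S/m.
#' @param inclusions A `data.frame` with columns `x`, `y` (center, meters),
#'   `radius` (meters) and `sigma` (S/m); may have zero rows.
#' @param name Scenario label.
#' @return An object of class `eit_phantom`.
#' @export
phantom_spec <- function(tank_radius_m, background_sigma,
                         inclusions = data.frame(x = numeric(), y = numeric(),
                                                 radius = numeric(),
                                                 sigma = numeric()),
                         name = "custom") {
  stopifnot(tank_radius_m > 0, background_sigma > 0,
            all(inclusions$sigma > 0), all(inclusions$radius > 0))
  d <- sqrt(inclusions$x^2 + inclusions$y^2)
  if (any(d + inclusions$radius > tank_radius_m))
    stop("inclusions must lie entirely inside the tank")
  if (nrow(inclusions) > 1L) {
    for (i in seq_len(nrow(inclusions) - 1L)) for (j in (i + 1L):nrow(inclusions)) {
      dij <- sqrt((inclusions$x[i] - inclusions$x[j])^2 +
                    (inclusions$y[i] - inclusions$y[j])^2)
      if (dij < inclusions$radius[i] + inclusions$radius[j])
        stop("overlapping inclusions")
    }
  }
  structure(list(tank_radius_m = tank_radius_m,
                 background_sigma = background_sigma,
                 inclusions = inclusions, name = name),
            class = "eit_phantom")
}

#' Reference phantom scenarios
#'
#' The saline scenarios use a 7 cm tank of 0.278 S/m saline with a
#' non-conductive PVC rod (radius 2.1 cm, stand-in conductivity 1e-6 S/m)
#' and/or a copper rod (radius 2.15 cm; true copper conductivity is clipped
#' to 1e3 S/m for finite-element conditioning — only the contrast sign
#' matters in difference imaging).  The agar scenarios use a 0.217 S/m
#' background emulating lower-pelvis tissue, with a saline-filled cavity of
#' radius 2.7, 2.5 or 1.3 cm at a configurable cavity conductivity
#' (1.227, 1.890 or 2.07 S/m in the reference experiments).
#'
#' @param name One of `"saline-homog"`, `"saline-pvc"`, `"saline-copper"`,
#'   `"saline-both"`, `"agar-homog"`, `"agar-large"`, `"agar-medium"`,
#'   `"agar-small"`.
#' @param cavity_sigma Conductivity of the agar-cavity saline filling, S/m.
#' @return An [phantom_spec()] object.
#' @examples
#' make_phantom("agar-large")$inclusions$radius  # 0.027
#' @export
make_phantom <- function(name, cavity_sigma = 1.227) {
  scenarios <- c("saline-homog", "saline-pvc", "saline-copper", "saline-both",
                 "agar-homog", "agar-large", "agar-medium", "agar-small")
  if (!name %in% scenarios)
    stop("unknown scenario '", name, "'; available: ",
         paste(scenarios, collapse = ", "))
  r_tank <- 0.07
  pvc <- c(sigma = 1e-6, radius = 0.021)
  copper <- c(sigma = 1e3, radius = 0.0215)
  inc <- switch(name,
    "saline-homog" = ,
    "agar-homog" = data.frame(x = numeric(), y = numeric(),
                              radius = numeric(), sigma = numeric()),
    "saline-pvc" = data.frame(x = 0.03, y = 0, radius = pvc["radius"],
                              sigma = pvc["sigma"]),
    "saline-copper" = data.frame(x = -0.03, y = 0, radius = copper["radius"],
                                 sigma = copper["sigma"]),
    "saline-both" = data.frame(x = c(0.035, -0.035), y = c(0, 0),
                               radius = c(pvc["radius"], copper["radius"]),
                               sigma = c(pvc["sigma"], copper["sigma"])),
    "agar-large" = data.frame(x = 0, y = 0, radius = 0.027,
                              sigma = cavity_sigma),
    "agar-medium" = data.frame(x = 0, y = 0, radius = 0.025,
                               sigma = cavity_sigma),
    "agar-small" = data.frame(x = 0, y = 0, radius = 0.013,
                              sigma = cavity_sigma))
  rownames(inc) <- NULL
  bg <- if (startsWith(name, "agar")) 0.217 else 0.278
  phantom_spec(r_tank, bg, inc, name = name)
}

#' Map a phantom onto a mesh as a conductivity field
#'
#' Element conductivity is the inclusion value when the element centroid
#' falls inside an inclusion, else the background — a deterministic rule
#' that converges to the exact geometry with mesh refinement.
#'
#' @param spec An [phantom_spec()].
#' @param mesh A [disk_mesh()] with matching radius.
#' @return Per-element conductivity vector (S/m).
#' @export
apply_phantom <- function(spec, mesh) {
  stopifnot(inherits(spec, "eit_phantom"), inherits(mesh, "disk_mesh"))
  if (abs(mesh$radius_m - spec$tank_radius_m) > 1e-12)
    stop("mesh radius does not match the phantom tank radius")
  sigma <- rep(spec$background_sigma, nrow(mesh$triangles))
  inc <- spec$inclusions
  for (i in seq_len(nrow(inc))) {
    d2 <- (mesh$centroids[, 1L] - inc$x[i])^2 +
      (mesh$centroids[, 2L] - inc$y[i])^2
    sigma[d2 <= inc$radius[i]^2] <- inc$sigma[i]
  }
  sigma
}

#' Noise profiles for the multiplexer switching-time scenarios
#'
#' Short switching (1 ms) leaves only a small white component; longer
#' switching lets channel transients and slow voltage drift accumulate.
#' Magnitudes are relative to `reference_v` (a typical channel voltage) and
#' are calibrated so that simulated per-channel SNR falls in the observed
#' brackets: roughly 60 dB at 1 ms, 50 dB at 10 ms and 10 dB at 100 ms —
#' the ordering, not the absolute level, is the contract.
#'
#' @param profile `"1ms"`, `"10ms"` or `"100ms"` switching time.
#' @param seed RNG seed passed to the [noise_model()].
#' @param reference_v Typical channel voltage in volts used to scale the
#'   noise magnitudes (default 1).
#' @return A [noise_model()].
#' @export
make_noise_model <- function(profile = c("1ms", "10ms", "100ms"), seed = NULL,
                             reference_v = 1) {
  profile <- match.arg(profile)
  p <- switch(profile,
    "1ms"   = c(sd = 1e-3,    drift = 0),
    "10ms"  = c(sd = 2.5e-3,  drift = 5e-4),
    "100ms" = c(sd = 0.25,    drift = 0.02))
  noise_model(additive_sd_v = p[["sd"]] * reference_v,
              drift_rate_v = p[["drift"]] * reference_v, seed = seed)
}
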