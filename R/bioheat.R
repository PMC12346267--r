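#' Layered tissue model for photothermal therapy simulation
#'
#' Builds the voxelized flank-tumor model: a 2-cm cube with a 1.1-cm muscle
#' layer at the bottom, 0.075-cm skin on top of it, a nanoparticle-loaded
#' ellipsoidal tumor (semi-axes 3.5, 4, 2.5 mm) whose top is tangent to the
#' skin-muscle interface, and the remainder filled with the coupling medium
#' (air for open-air treatment, water for submerged treatment). Tissue
#' optical properties are generic soft tissue (mu_a = 0.1, mu_s = 100 cm^-1,
#' g = 0.9); the tumor absorption is raised by `tumor_extra_mua`
#' (1.36 cm^-1, the nanoparticle loading at the median dose); water absorbs
#' 0.02 cm^-1. Thermal properties and perfusion rates are literature-typical
#' soft-tissue/water/air values, all overridable; tumor perfusion equals
#' muscle perfusion.
#'
#' @param coupling `"water"` or `"air"`.
#' @param voxel_size voxel edge, mm; must divide `extent`.
#' @param extent cubic domain edge, mm.
#' @param tumor_extra_mua added tumor absorption, cm^-1.
#' @param g scattering anisotropy of the tissue labels.
#' @param isothermal_coupling hold the entire coupling region at its bath
#'   temperature during the thermal solve (default: yes for water — a
#'   controlled bath — and no for air, which is solved as a stagnant
#'   conductor).
#' @param properties optional named list of per-label overrides, e.g.
#'   `list(muscle = list(k = 0.5, w = 1e-3))`; fields `mua`, `mus`, `g`
#'   (optical, cm^-1) and `rho` (kg/m^3), `c` (J/kg/K), `k` (W/m/K),
#'   `w` (perfusion, s^-1).
#' @return object of class `tissue_model`: `labels` (nx x ny x nz integer
#'   array; 1 coupling, 2 skin, 3 muscle, 4 tumor), voxel/extent geometry,
#'   `optical` and `thermal` per-label tables, blood constants, per-label
#'   boundary/initial temperatures and the four standard probe locations
#'   (skin center, tumor-skin boundary, tumor center, tumor-muscle boundary).
#' @export
build_tissue_model <- function(coupling = c("water", "air"), voxel_size = 0.25,
                               extent = 20, tumor_extra_mua = 1.36, g = 0.9,
                               properties = NULL, isothermal_coupling = NULL) {
  coupling <- match.arg(coupling)
  # A temperature-controlled water bath is effectively stirred: treat the
  # whole water region as isothermal at the bath temperature. Still air is a
  # stagnant conducting insulator, so it is solved as part of the domain.
  isothermal_coupling <- isothermal_coupling %||% (coupling == "water")
  n <- extent / voxel_size
  if (abs(n - round(n)) > 1e-9)
    stop_pactherm("voxel_size must divide the domain extent")
  n <- as.integer(round(n))
  # voxel centers; z is depth from the illuminated (top) face
  xc <- (seq_len(n) - 0.5) * voxel_size - extent / 2
  zc <- (seq_len(n) - 0.5) * voxel_size
  muscle_h <- 11; skin_h <- 0.75
  z_muscle_top <- extent - muscle_h
  z_skin_top <- z_muscle_top - skin_h
  if (z_skin_top < 0) stop_pactherm("domain too small for the layer stack")

  # labels[i, j, k]: x = xc[i], y = xc[j], z (depth) = zc[k]
  labels <- array(1L, c(n, n, n))
  for (k in seq_len(n)) {
    if (zc[k] > z_skin_top && zc[k] <= z_muscle_top) labels[, , k] <- 2L
    else if (zc[k] > z_muscle_top) labels[, , k] <- 3L
  }
  tum_c <- c(0, 0, z_muscle_top + 2.5)
  tum_r <- c(3.5, 4, 2.5)
  for (k in seq_len(n)) {
    dz2 <- ((zc[k] - tum_c[3]) / tum_r[3])^2
    if (dz2 > 1) next
    d2 <- outer((xc - tum_c[1])^2 / tum_r[1]^2,
                (xc - tum_c[2])^2 / tum_r[2]^2, "+") + dz2
    sl <- labels[, , k]
    sl[d2 <= 1] <- 4L
    labels[, , k] <- sl
  }

  lab_names <- c("coupling", "skin", "muscle", "tumor")
  optical <- data.frame(
    row.names = lab_names,
    mua = c(if (coupling == "water") 0.02 else 0, 0.1, 0.1, 0.1 + tumor_extra_mua),
    mus = c(0, 100, 100, 100),
    g = c(0, g, g, g))
  thermal <- data.frame(
    row.names = lab_names,
    rho = c(if (coupling == "water") 998 else 1.2, 1109, 1090, 1090),
    c = c(if (coupling == "water") 4182 else 1005, 3391, 3421, 3421),
    k = c(if (coupling == "water") 0.60 else 0.026, 0.37, 0.49, 0.49),
    w = c(0, 0.0012, 0.0008, 0.0008))
  pin_temp <- c(if (coupling == "water") 35 else 20, 37, 37, 37)

  if (!is.null(properties)) {
    for (nm in names(properties)) {
      if (!nm %in% lab_names) stop_pactherm("unknown label in properties: ", nm)
      for (f in names(properties[[nm]])) {
        if (f %in% names(optical)) optical[nm, f] <- properties[[nm]][[f]]
        else if (f %in% names(thermal)) thermal[nm, f] <- properties[[nm]][[f]]
        else stop_pactherm("unknown property field: ", f)
      }
    }
  }
  if (any(optical$mua < 0) || any(optical$mus < 0) || any(abs(optical$g) >= 1))
    stop_pactherm("optical properties must satisfy mua, mus >= 0 and |g| < 1")

  vox_index <- function(pos) {
    i <- pmin(pmax(ceiling((pos[1] + extent / 2) / voxel_size), 1), n)
    j <- pmin(pmax(ceiling((pos[2] + extent / 2) / voxel_size), 1), n)
    k <- pmin(pmax(ceiling(pos[3] / voxel_size), 1), n)
    c(i, j, k)
  }
  probes <- list(
    skin_center = vox_index(c(0, 0, z_skin_top + skin_h / 2)),
    tumor_skin = vox_index(c(0, 0, z_muscle_top + voxel_size / 2)),
    tumor_center = vox_index(c(0, 0, tum_c[3])),
    tumor_muscle = vox_index(c(0, 0, tum_c[3] + tum_r[3] - voxel_size / 2)))

  structure(list(labels = labels, voxel_size = voxel_size, extent = extent,
                 n = n, coupling = coupling, optical = optical,
                 thermal = thermal, pin_temp = pin_temp,
                 blood = list(rho = 1050, c = 3617, T_a = 37),
                 isothermal_coupling = isothermal_coupling,
                 z_skin_top = z_skin_top, z_muscle_top = z_muscle_top,
                 tumor_center = tum_c, tumor_radii = tum_r,
                 probes = probes, z_centers = zc, xy_centers = xc),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  vol <- sum(x$labels == 4L) * x$voxel_size^3
  cat(sprintf("Tissue model (%s-coupled): %d^3 voxels @ %.3g mm, tumor %.1f mm^3\n",
              x$coupling, x$n, x$voxel_size, vol))
  invisible(x)
}

#' Treatment beam description
#'
#' A Gaussian beam clipped by an iris, incident on the top face of the domain
#' along +z. Defaults: 16-mm Gaussian radius through a 9.6-mm-diameter iris
#' at 2.5 W/cm^2.
#'
#' @param gaussian_radius 1/e^2 Gaussian beam radius, mm.
#' @param iris_radius iris radius, mm (<= `gaussian_radius`).
#' @param power_density incident power density, W/cm^2 (> 0).
#' @export
beam_spec <- function(gaussian_radius = 16, iris_radius = 4.8,
                      power_density = 2.5) {
  if (iris_radius > gaussian_radius)
    stop_pactherm("iris_radius must not exceed gaussian_radius")
  if (!(power_density > 0)) stop_pactherm("power_density must be > 0")
  structure(list(gaussian_radius = gaussian_radius, iris_radius = iris_radius,
                 power_density = power_density), class = "beam_spec")
}

#' Monte Carlo absorbed power
#'
#' Runs the voxel photon random walk (exponential free paths in `mu_t`,
#' Henyey-Greenstein scattering, absorption-weighted deposition) and scales
#' the deposited energy fractions so the launched power equals
#' `power_density * iris area`. Deposited plus escaped energy equals the
#' launched energy exactly (photons below the weight threshold deposit their
#' residual locally).
#'
#' @param model a [build_tissue_model()].
#' @param beam a [beam_spec()].
#' @param n_photons number of photon packets (>= 1).
#' @param seed integer; identical seeds give identical deposition.
#' @return object of class `power_map`: `q` (absorbed power density, W/cm^3,
#'   same dims as the model), `escaped_fraction`, `launched_power_W`,
#'   `absorbed_W`.
#' @export
mc_absorbed_power <- function(model, beam = beam_spec(), n_photons = 1e6,
                              seed = 1) {
  stopifnot(inherits(model, "tissue_model"), inherits(beam, "beam_spec"))
  if (n_photons < 1) stop_pactherm("n_photons must be >= 1")
  if (beam$iris_radius >= model$extent / 2)
    stop_pactherm("beam misses the domain: iris wider than the lateral extent")
  res <- .mc_transport_cpp(as.integer(model$labels), rep(model$n, 3L),
                           model$voxel_size, as.matrix(model$optical),
                           beam$gaussian_radius, beam$iris_radius,
                           n_photons, seed)
  launched <- beam$power_density * pi * (beam$iris_radius / 10)^2  # W
  vox_cm3 <- (model$voxel_size / 10)^3
  q <- array(res$absorb_frac * launched / vox_cm3, dim(model$labels))
  structure(list(q = q, escaped_fraction = res$escaped_frac,
                 launched_power_W = launched,
                 absorbed_W = sum(res$absorb_frac) * launched,
                 n_photons = n_photons, model_dims = dim(model$labels)),
            class = "power_map")
}

#' @export
print.power_map <- function(x, ...) {
  cat(sprintf("Power map: %.3g W launched, %.3g W absorbed (%.1f%% escaped), max %.3g W/cm^3\n",
              x$launched_power_W, x$absorbed_W, 100 * x$escaped_fraction, max(x$q)))
  invisible(x)
}

#' Pennes bioheat simulation
#'
#' Solves `rho c dT/dt = div(kappa grad T) + Q + w rho_b c_b (T_a - T)` on
#' the full voxel grid (tissue and coupling medium) with an implicit
#' locally-one-dimensional scheme (three tridiagonal solves per step,
#' unconditionally stable). The outermost voxel shell is held at fixed
#' temperatures by the medium it contains: 20 C for air, 35 C for water,
#' 37 C for tissue; these are also the initial temperatures. Perfusion acts
#' in tissue labels only, pulling toward the arterial temperature
#' `T_a = 37` C.
#'
#' @param model a [build_tissue_model()].
#' @param power a [mc_absorbed_power()] power map on the same grid.
#' @param duration heating duration, minutes.
#' @param dt time step, s (> 0; the scheme is unconditionally stable).
#' @param record_every_s probe-trace recording interval, s.
#' @return object of class `pennes_result`: `times` (s), `traces`
#'   (probe temperature time series, deg C), `T_final` and `T_max`
#'   (3D arrays), plus the model and run parameters.
#' @export
pennes_simulate <- function(model, power, duration = 10, dt = 0.5,
                            record_every_s = 5) {
  stopifnot(inherits(model, "tissue_model"), inherits(power, "power_map"))
  if (!identical(power$model_dims, dim(model$labels)))
    stop_pactherm("power map grid does not match the tissue model")
  if (!(dt > 0)) stop_pactherm("dt must be > 0")
  n_steps <- as.integer(round(duration * 60 / dt))
  rec <- max(1L, as.integer(round(record_every_s / dt)))
  probe_flat <- vapply(model$probes, function(p)
    (p[1] - 1L) + model$n * ((p[2] - 1L) + model$n * (p[3] - 1L)), numeric(1))
  res <- .pennes_lod_cpp(as.integer(model$labels), rep(model$n, 3L),
                         model$voxel_size, as.matrix(model$thermal),
                         model$blood$rho, model$blood$c, model$blood$T_a,
                         model$pin_temp,
                         as.integer(c(isTRUE(model$isothermal_coupling), 0, 0, 0)),
                         as.numeric(power$q) * 1e6,
                         dt, n_steps, rec, as.integer(probe_flat))
  traces <- res$traces
  colnames(traces) <- names(model$probes)
  structure(list(times = res$times, traces = traces,
                 T_final = array(res$T_final, dim(model$labels)),
                 T_max = array(res$T_max, dim(model$labels)),
                 model = model, duration = duration, dt = dt),
            class = "pennes_result")
}

#' @export
print.pennes_result <- function(x, ...) {
  fin <- x$traces[nrow(x$traces), ]
  cat(sprintf("Pennes simulation (%s): %.3g min, dt = %.3g s; final probe temps:\n",
              x$model$coupling, x$duration, x$dt))
  print(round(fin, 2))
  invisible(x)
}

#' Compare open-air and submerged treatment simulations
#'
#' Summarizes two [pennes_simulate()] runs on identical grids: final probe
#' temperatures and their hottest-to-coolest ordering, and the location of
#' the maximum temperature reached anywhere during treatment, reported as
#' depth below the skin surface.
#'
#' @param open_air,submerged `pennes_result`s from air- and water-coupled
#'   models on the same grid.
#' @return object of class `ptt_comparison`: `summary` data.frame (one row
#'   per configuration: hottest probe, max temperature, its depth below the
#'   skin surface in mm) plus per-configuration probe orderings and final
#'   temperatures.
#' @export
compare_configurations <- function(open_air, submerged) {
  stopifnot(inherits(open_air, "pennes_result"), inherits(submerged, "pennes_result"))
  if (!identical(dim(open_air$T_final), dim(submerged$T_final)) ||
      open_air$model$voxel_size != submerged$model$voxel_size)
    stop_pactherm("the two runs are not on identical grids")
  one <- function(res) {
    fin <- res$traces[nrow(res$traces), ]
    ord <- names(sort(fin, decreasing = TRUE))
    imax <- arrayInd(which.max(res$T_max), dim(res$T_max))
    depth <- res$model$z_centers[imax[3]] - res$model$z_skin_top
    list(final = fin, ordering = ord,
         max_T = max(res$T_max), max_depth_mm = depth)
  }
  a <- one(open_air); w <- one(submerged)
  summary <- data.frame(
    configuration = c("open_air", "submerged"),
    hottest_probe = c(a$ordering[1], w$ordering[1]),
    max_T_C = c(a$max_T, w$max_T),
    max_depth_mm = c(a$max_depth_mm, w$max_depth_mm))
  structure(list(summary = summary,
                 open_air = a, submerged = w),
            class = "ptt_comparison")
}

#' @export
print.ptt_comparison <- function(x, ...) {
  print(x$summary)
  cat("open-air ordering:  ", paste(x$open_air$ordering, collapse = " > "), "\n")
  cat("submerged ordering: ", paste(x$submerged$ordering, collapse = " > "), "\n")
  invisible(x)
}
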