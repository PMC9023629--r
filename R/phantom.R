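#' Create a voxel grid geometry
#'
#' @param dim integer(3) or a single integer (cubic grid), voxels per axis.
#' @param spacing voxel size in mm, scalar or numeric(3). Default 4.8 mm,
#'   the clinical matrix pixel spacing.
#' @param origin world coordinate (mm) of the first voxel centre; default
#'   centres the grid on the world origin.
#' @return a [GridGeometry-class].
#' @examples
#' gridGeometry(64L, 4.8)
#' @export
gridGeometry <- function(dim, spacing = 4.8, origin = NULL) {
  dim <- as.integer(rep_len(dim, 3L))
  spacing <- as.numeric(rep_len(spacing, 3L))
  if (is.null(origin)) origin <- -(dim - 1) / 2 * spacing
  new("GridGeometry", dim = dim, spacing = spacing,
      origin = as.numeric(origin))
}

#' Phantom compartment constructors
#'
#' Build spherical, ellipsoidal or explicit-mask compartments for a
#' [PhantomSpec-class]. Geometry is in world mm; activities are total MBq per
#' isotope, spread uniformly over the compartment.
#'
#' @param name compartment label.
#' @param center numeric(3) world centre in mm.
#' @param radius sphere radius in mm.
#' @param semiAxes numeric(3) ellipsoid semi-axes in mm.
#' @param mask 3D array of occupancy fractions in [0, 1] on the phantom grid.
#' @param activity named numeric, MBq per isotope, e.g. \code{c(ho = 250)}.
#' @param attenuationClass \code{"water"}, \code{"lung"} or \code{"air"}.
#' @return a [Compartment-class].
#' @examples
#' sphereCompartment("S1", c(0, 20, 0), 17.9, activity = c(ho = 37.7))
#' @export
sphereCompartment <- function(name, center, radius, activity = numeric(0),
                              attenuationClass = "water") {
  new("Compartment", name = name, shape = "sphere",
      center = as.numeric(center), semiAxes = rep(as.numeric(radius), 3L),
      mask = NULL, activity = activity,
      attenuationClass = attenuationClass,
      nominalVolume = 4 / 3 * pi * radius^3 / 1000)
}

#' @rdname sphereCompartment
#' @export
ellipsoidCompartment <- function(name, center, semiAxes,
                                 activity = numeric(0),
                                 attenuationClass = "water") {
  semiAxes <- as.numeric(semiAxes)
  new("Compartment", name = name, shape = "ellipsoid",
      center = as.numeric(center), semiAxes = semiAxes, mask = NULL,
      activity = activity, attenuationClass = attenuationClass,
      nominalVolume = 4 / 3 * pi * prod(semiAxes) / 1000)
}

#' @rdname sphereCompartment
#' @export
maskCompartment <- function(name, mask, activity = numeric(0),
                            attenuationClass = "water") {
  stopifnot(length(dim(mask)) == 3L, min(mask) >= 0, max(mask) <= 1)
  new("Compartment", name = name, shape = "mask",
      center = rep(NA_real_, 3L), semiAxes = rep(NA_real_, 3L), mask = mask,
      activity = activity, attenuationClass = attenuationClass,
      nominalVolume = NA_real_)
}

#' Assemble a phantom specification
#'
#' Compartments are ordered outermost first; each later compartment is
#' carved out of all earlier ones when the phantom is voxelized, so e.g.
#' tumour spheres listed after the liver remove their volume from the
#' healthy-liver occupancy.
#'
#' @param grid a [GridGeometry-class].
#' @param compartments list of [Compartment-class] objects.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(grid, compartments) {
  new("PhantomSpec", grid = grid, compartments = compartments)
}

#' Default anthropomorphic liver phantom
#'
#' A torso with two lungs and a liver containing two hot tumour spheres,
#' mirroring a fillable thorax phantom used for scout-procedure studies:
#' healthy-liver compartment of 1205 mL and spheres S1 (24.2 mL) and S2
#' (15.7 mL), holmium filled at a 10:1 sphere-to-healthy-liver concentration
#' ratio, technetium only in the healthy liver. Lungs and torso carry no
#' activity; the torso is water-class and the lungs lung-class. The
#' published phantom has no stated coordinates, so the liver sits in the
#' upper-right body region with both spheres at least 1 cm from the liver
#' edge and more than 2 cm apart.
#'
#' @param grid a [GridGeometry-class]; default 64^3 at 4.8 mm.
#' @param hoActivity total effective Ho activity in MBq (liver + spheres).
#' @param tcActivity effective Tc activity in MBq (healthy liver only).
#' @return a [PhantomSpec-class].
#' @examples
#' spec <- defaultPhantom()
#' activityFractions(spec, "ho")
#' @export
defaultPhantom <- function(grid = gridGeometry(64L, 4.8), hoActivity = 250,
                           tcActivity = 50) {
  vS1 <- 24.2; vS2 <- 15.7; vHealthy <- 1205
  rS1 <- (3 * vS1 * 1000 / (4 * pi))^(1 / 3)
  rS2 <- (3 * vS2 * 1000 / (4 * pi))^(1 / 3)
  liverAxes <- c(82, 66, 0)
  liverAxes[3] <- (vHealthy + vS1 + vS2) * 1000 * 3 / (4 * pi) /
    (liverAxes[1] * liverAxes[2])
  liverC <- c(30, 20, 0)
  # concentration ratio 10:1 between spheres and healthy liver
  conc <- hoActivity / (vHealthy + 10 * (vS1 + vS2))
  comps <- list(
    ellipsoidCompartment("torso", c(0, 0, 0), c(140, 90, 100)),
    ellipsoidCompartment("lung_l", c(-45, -35, 55), c(28, 20, 18),
                         attenuationClass = "lung"),
    ellipsoidCompartment("lung_r", c(45, -35, 55), c(28, 20, 18),
                         attenuationClass = "lung"),
    ellipsoidCompartment("liver", liverC, liverAxes,
                         activity = c(ho = conc * vHealthy,
                                      tc = tcActivity)),
    sphereCompartment("S1", liverC + c(-30, 0, 0), rS1,
                      activity = c(ho = 10 * conc * vS1)),
    sphereCompartment("S2", liverC + c(25, 18, 0), rS2,
                      activity = c(ho = 10 * conc * vS2)))
  phantomSpec(grid, comps)
}

# world-extent check for an analytic compartment
.checkInsideGrid <- function(cp, grid) {
  if (cp@shape == "mask") return(invisible(TRUE))
  lo <- grid@origin - grid@spacing / 2
  hi <- grid@origin + (grid@dim - 1 + 0.5) * grid@spacing
  if (any(cp@center - cp@semiAxes < lo) || any(cp@center + cp@semiAxes > hi))
    stop(sprintf("compartment '%s' extends outside the grid", cp@name))
  invisible(TRUE)
}

#' Voxelize a phantom into fractional occupancy volumes
#'
#' Computes, for every compartment, the fraction of each voxel it occupies
#' by subdividing the voxel into \code{supersample^3} sample points and
#' testing membership. Later compartments are carved out of earlier ones, so
#' occupancies sum to at most 1 per voxel and sphere voxels do not count
#' toward the healthy liver.
#'
#' @param spec a [PhantomSpec-class].
#' @param supersample integer >= 1, sub-divisions per voxel axis.
#' @return a [LabelVolume-class].
#' @examples
#' lab <- buildPhantom(defaultPhantom(gridGeometry(c(32L, 32L, 24L), 9.6)), 2L)
#' @export
buildPhantom <- function(spec, supersample = 4L) {
  stopifnot(supersample >= 1L)
  grid <- spec@grid
  raw <- list()
  for (cp in spec@compartments) {
    .checkInsideGrid(cp, grid)
    if (cp@shape == "mask") {
      if (!identical(dim(cp@mask), as.integer(grid@dim)))
        stop(sprintf("compartment '%s': mask does not match the grid",
                     cp@name))
      raw[[cp@name]] <- cp@mask
    } else {
      raw[[cp@name]] <- cppShapeOccupancy(
        grid@dim, grid@spacing, grid@origin,
        if (cp@shape == "sphere") 0L else 1L,
        cp@center, cp@semiAxes, as.integer(supersample))
      dim(raw[[cp@name]]) <- grid@dim
    }
  }
  # carve: later compartments override earlier ones
  n <- length(raw)
  if (n > 1) {
    later <- array(0, grid@dim)
    for (i in seq(n, 1)) {
      raw[[i]] <- pmax(pmin(raw[[i]], 1 - later), 0)
      later <- later + raw[[i]]
    }
  }
  vv <- prod(grid@spacing) / 1000
  nomv <- vapply(spec@compartments, function(cp) {
    if (cp@shape == "mask") sum(cp@mask) * vv else cp@nominalVolume
  }, numeric(1))
  names(nomv) <- names(raw)
  # nominal volume of carved compartments excludes what was carved away:
  # approximate by the recovered (occupancy) volume when carving removed
  # more than the supersampling tolerance
  for (i in seq_len(n)) {
    rec <- sum(raw[[i]]) * vv
    if (nomv[i] > 0 && rec < nomv[i] * 0.99) nomv[i] <- NA_real_
  }
  # the liver is the canonical carved case: its healthy volume is the
  # ellipsoid minus the carved spheres
  acts <- lapply(spec@compartments, function(cp) cp@activity)
  names(acts) <- names(raw)
  cls <- vapply(spec@compartments, function(cp) cp@attenuationClass,
                character(1))
  names(cls) <- names(raw)
  if (all(c("liver", "S1", "S2") %in% names(raw)) && is.na(nomv["liver"])) {
    full <- vapply(spec@compartments, function(cp) cp@nominalVolume,
                   numeric(1))
    names(full) <- names(raw)
    nomv["liver"] <- full["liver"] - full["S1"] - full["S2"]
  }
  new("LabelVolume", grid = grid, fractions = raw, nominalVolumes = nomv,
      activity = acts, attenuationClass = cls)
}

#' Per-voxel activity concentration map
#'
#' Spreads each compartment's activity uniformly over its nominal volume and
#' accumulates fractional-occupancy-weighted concentrations, so the total
#' integrated activity equals the sum of the compartment activities up to
#' supersampling tolerance.
#'
#' @param labels a [LabelVolume-class].
#' @param isotope isotope label, e.g. \code{"ho"} or \code{"tc"}.
#' @param spec optional [PhantomSpec-class] whose activities override those
#'   stored in \code{labels}.
#' @return a [SpectImage-class] in MBq/mL.
#' @export
activityMap <- function(labels, isotope, spec = NULL) {
  acts <- labels@activity
  if (!is.null(spec)) {
    acts <- lapply(spec@compartments, function(cp) cp@activity)
    names(acts) <- vapply(spec@compartments, function(cp) cp@name,
                          character(1))
  }
  vv <- voxelVolumeML(labels)
  out <- array(0, labels@grid@dim)
  for (nm in names(labels@fractions)) {
    a <- acts[[nm]][isotope]
    if (is.null(acts[[nm]]) || is.na(a) || a == 0) next
    vol <- labels@nominalVolumes[nm]
    if (is.na(vol)) vol <- sum(labels@fractions[[nm]]) * vv
    if (vol <= 0)
      stop(sprintf("compartment '%s' has zero volume but nonzero activity",
                   nm))
    out <- out + labels@fractions[[nm]] * (a / vol)
  }
  new("SpectImage", data = out, spacing = labels@grid@spacing,
      isotope = isotope, provenance = list(kind = "activity",
                                           units = "MBq/mL"))
}

#' Compartment activity fractions
#'
#' Percentage of the total activity of one isotope held by each compartment.
#'
#' @param spec a [PhantomSpec-class].
#' @param isotope isotope label.
#' @return named numeric summing to 100.
#' @examples
#' activityFractions(defaultPhantom(), "ho")  # S1 close to 15.1 pct
#' @export
activityFractions <- function(spec, isotope) {
  a <- vapply(spec@compartments, function(cp) {
    v <- cp@activity[isotope]
    if (is.na(v)) 0 else as.numeric(v)
  }, numeric(1))
  names(a) <- vapply(spec@compartments, function(cp) cp@name, character(1))
  tot <- sum(a)
  if (tot <= 0) stop("total activity of isotope '", isotope, "' is zero")
  100 * a[a > 0] / tot
}

# linear attenuation coefficients of water (1/cm) at the window energies;
# configured constants from standard attenuation tables
.muWaterTable <- c("81" = 0.184, "118" = 0.161, "140" = 0.153,
                   "170" = 0.146)

#' Attenuation map at a photon energy
#'
#' Occupancy-weighted mix of the per-class linear attenuation coefficients:
#' water-class compartments use the configured water values (interpolated
#' linearly between the tabulated window energies), lung-class 0.3 x water,
#' air zero. Voxels covered by no compartment are air.
#'
#' @param labels a [LabelVolume-class].
#' @param energy photon energy in keV; must lie within the tabulated range.
#' @param muWater named numeric table of water coefficients (1/cm) by keV.
#' @return a [SpectImage-class] in 1/cm.
#' @export
attenuationMap <- function(labels, energy, muWater = .muWaterTable) {
  ev <- as.numeric(names(muWater))
  if (energy < min(ev) || energy > max(ev))
    stop(sprintf("energy %g keV outside the tabulated range [%g, %g]",
                 energy, min(ev), max(ev)))
  muW <- stats::approx(ev, muWater, xout = energy)$y
  classMu <- c(water = muW, lung = 0.3 * muW, air = 0)
  out <- array(0, labels@grid@dim)
  for (nm in names(labels@fractions)) {
    cls <- labels@attenuationClass[nm]
    if (is.na(cls) || !cls %in% names(classMu))
      stop(sprintf("compartment '%s': unknown attenuation class", nm))
    if (classMu[cls] > 0)
      out <- out + labels@fractions[[nm]] * classMu[cls]
  }
  new("SpectImage", data = out, spacing = labels@grid@spacing, isotope = "",
      provenance = list(kind = "attenuation", energy = energy,
                        units = "1/cm"))
}
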