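# Channel map: receptor and ligand occupy disjoint banks of 14 XS-type
# groups each, the conventional 28-channel layout for complex voxelization.
.CHANNEL_GROUPS <- list(
  CarbonHydrophobe = c("AliphaticCarbonXSHydrophobe",
                       "AromaticCarbonXSHydrophobe"),
  CarbonNonHydrophobe = c("AliphaticCarbonXSNonHydrophobe",
                          "AromaticCarbonXSNonHydrophobe"),
  Nitrogen = "Nitrogen",
  NitrogenDonor = "NitrogenXSDonor",
  NitrogenAcceptor = "NitrogenXSAcceptor",
  NitrogenDonorAcceptor = "NitrogenXSDonorAcceptor",
  OxygenAcceptor = c("Oxygen", "OxygenXSAcceptor", "OxygenXSDonor"),
  OxygenDonorAcceptor = "OxygenXSDonorAcceptor",
  Sulfur = c("Sulfur", "SulfurAcceptor"),
  Phosphorus = "Phosphorus",
  Halogen = c("Fluorine", "Chlorine", "Bromine", "Iodine"),
  Metal = c("Magnesium", "Manganese", "Zinc", "Calcium", "Iron",
            "GenericMetal"),
  Boron = "GenericOther",
  Other = character())

#' Voxel channel map
#'
#' The default 28-channel layout: 14 receptor-side XS type groups followed
#' by 14 ligand-side groups.
#' @return data.frame with columns \code{channel}, \code{side},
#'   \code{group}.
#' @export
voxelChannelMap <- function() {
  groups <- names(.CHANNEL_GROUPS)
  data.frame(channel = seq_len(2L * length(groups)),
             side = rep(c("receptor", "ligand"), each = length(groups)),
             group = rep(groups, 2), stringsAsFactors = FALSE)
}

.channelOfType <- function(xsType, side) {
  groups <- names(.CHANNEL_GROUPS)
  idx <- rep(NA_integer_, length(xsType))
  for (gi in seq_along(groups))
    idx[xsType %in% .CHANNEL_GROUPS[[gi]]] <- gi
  idx[is.na(idx)] <- length(groups)  # "Other"
  if (side == "ligand") idx <- idx + length(groups)
  idx
}

# truncated-Gaussian density kernel: Gaussian exp(-2 x^2) of x = d/r out to
# one vdW radius, then the matching quadratic decay reaching zero at 1.5 r
.densityKernel <- function(d, r) {
  x <- d / r
  v <- numeric(length(x))
  g <- x < 1
  v[g] <- exp(-2 * x[g]^2)
  q <- x >= 1 & x < 1.5
  e2 <- exp(-2)
  v[q] <- 4 * e2 * x[q]^2 - 12 * e2 * x[q] + 9 * e2
  v
}

#' Grid settings constructor
#' @param dim voxels per edge (default 48).
#' @param resolution Angstrom per voxel (default 0.5).
#' @param center optional fixed center; default is the ligand centroid.
#' @return list of grid settings.
#' @export
gridConfig <- function(dim = 48L, resolution = 0.5, center = NULL) {
  stopifnot(dim >= 2, resolution > 0)
  list(dim = as.integer(dim), resolution = resolution, center = center)
}

#' Sample a random rigid augmentation transform
#'
#' Rotation uniform over SO(3) (random unit quaternion), translation
#' components i.i.d. uniform in [-maxShift, +maxShift]. Draws from the
#' current R random stream, so a fixed seed reproduces the sequence.
#'
#' @param maxShift maximum per-axis translation in Angstrom (default 2).
#' @return list with a 3x3 \code{rotation} matrix and 3-vector
#'   \code{translation}.
#' @export
sampleAugmentation <- function(maxShift = 2) {
  stopifnot(maxShift >= 0)
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), nrow = 3, byrow = TRUE)
  list(rotation = R,
       translation = stats::runif(3, -maxShift, maxShift))
}

identityTransform <- function() {
  list(rotation = diag(3), translation = c(0, 0, 0))
}

#' Voxelize a complex into a multi-channel density grid
#'
#' Deposits, for every heavy atom, a radially decreasing compactly
#' supported density kernel (Gaussian to one vdW radius, quadratic decay to
#' zero at 1.5 radii) into the channel of its side and XS type group. The
#' grid is centered on the ligand centroid unless the config overrides the
#' center. An optional rigid transform (rotation about the grid center plus
#' translation) implements training-time augmentation. Atoms whose kernels
#' fall outside the grid are silently truncated; the fraction of heavy
#' atoms whose center landed inside is recorded as the coverage statistic.
#'
#' @param complex a \linkS4class{ComplexStructure}.
#' @param config grid settings from \code{\link{gridConfig}}.
#' @param transform optional transform from \code{\link{sampleAugmentation}}.
#' @return a \linkS4class{VoxelGrid}.
#' @export
voxelize <- function(complex, config = gridConfig(),
                     transform = NULL) {
  stopifnot(is(complex, "ComplexStructure"))
  n <- config$dim
  res <- config$resolution
  lig <- complex@ligandAtoms
  center <- config$center
  if (is.null(center)) {
    heavy <- lig[!lig$isHydrogen, , drop = FALSE]
    center <- if (nrow(heavy)) colMeans(heavy[, c("x", "y", "z")])
              else c(0, 0, 0)
  }
  cmap <- voxelChannelMap()
  dens <- array(0, dim = c(n, n, n, nrow(cmap)))
  # voxel center coordinates along one axis, grid centered at `center`
  axis0 <- (seq_len(n) - (n + 1) / 2) * res

  depositSide <- function(atoms, side) {
    atoms <- atoms[!atoms$isHydrogen, , drop = FALSE]
    if (!nrow(atoms)) return(0L)
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, as.numeric(center))
    if (!is.null(transform))
      xyz <- xyz %*% t(transform$rotation) +
        matrix(transform$translation, nrow(xyz), 3, byrow = TRUE)
    chan <- .channelOfType(atoms$xsType, side)
    inside <- 0L
    half <- (n - 1) / 2 * res
    for (a in seq_len(nrow(atoms))) {
      r <- atoms$vdwRadius[a]
      sup <- 1.5 * r
      p <- xyz[a, ]
      if (all(abs(p) <= half + res / 2)) inside <- inside + 1L
      ix <- which(abs(axis0 - p[1]) <= sup)
      iy <- which(abs(axis0 - p[2]) <= sup)
      iz <- which(abs(axis0 - p[3]) <= sup)
      if (!length(ix) || !length(iy) || !length(iz)) next
      dx2 <- (axis0[ix] - p[1])^2
      dy2 <- (axis0[iy] - p[2])^2
      dz2 <- (axis0[iz] - p[3])^2
      d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
      dens[ix, iy, iz, chan[a]] <<-
        dens[ix, iy, iz, chan[a]] + .densityKernel(d, r)
    }
    inside
  }

  nin <- depositSide(complex@receptorAtoms, "receptor") +
         depositSide(complex@ligandAtoms, "ligand")
  nHeavy <- sum(!complex@receptorAtoms$isHydrogen) +
            sum(!complex@ligandAtoms$isHydrogen)
  new("VoxelGrid", densities = dens, resolution = res,
      center = as.numeric(center), channelMap = cmap,
      coverage = if (nHeavy) nin / nHeavy else 1)
}
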