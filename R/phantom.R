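# evaluate expr under a local RNG seed without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Map Hounsfield units to material and density
#'
#' Four-material segmentation (air / lung / soft tissue / bone) with a
#' continuous, monotone piecewise-linear HU-to-density calibration anchored
#' at rho(-1000) = 0.0012 (air), rho(0) = 1.000 (water) and rho(1000) = 1.80
#' g/cm^3, extended with constant slope above 1000. Values outside
#' \[-1024, 3000\] are clamped with a warning, never an error.
#'
#' @param hu Hounsfield units (vectorized)
#' @return list with integer \code{materialId} (codes into
#'   [materialNames()]) and \code{density} in g/cm^3
#' @examples
#' huToMaterial(0)      # soft tissue at 1.000 g/cm^3
#' huToMaterial(-1000)  # air at 0.0012 g/cm^3
#' @export
huToMaterial <- function(hu) {
  if (any(hu < -1024 | hu > 3000, na.rm = TRUE))
    warning("HU outside [-1024, 3000] clamped")
  hu <- pmin(pmax(hu, -1024), 3000)
  mat <- ifelse(hu < -900, 1L, ifelse(hu < -200, 2L, ifelse(hu < 150, 3L, 4L)))
  hc <- pmax(hu, -1000)
  density <- ifelse(hc < 0, 0.0012 + (hc + 1000) * (1.000 - 0.0012) / 1000,
             ifelse(hc < 1000, 1.000 + hc * 0.80 / 1000,
                    1.80 + (hc - 1000) * 0.80 / 1000))
  list(materialId = mat, density = density)
}

#' Extract the skin-voxel layer
#'
#' All non-air voxels whose center lies within \code{layerMm} (Euclidean)
#' of the center of an air voxel; volume borders count as air. With
#' \code{layerMm} equal to one voxel pitch this is exactly the face-adjacent
#' tissue shell; a larger layer gives a superset.
#'
#' @param phantom a [VoxelPhantom-class]
#' @param layerMm skin-layer depth in mm (default 3)
#' @return logical 3-D array
#' @export
extractSkinMask <- function(phantom, layerMm = 3) {
  stopifnot(is(phantom, "VoxelPhantom"), layerMm > 0)
  .skin_mask(phantom@materialId, phantom@spacingMm, layerMm)
}

.skin_mask <- function(materialId, spacingMm, layerMm) {
  d <- dim(materialId)
  air <- materialId == 1L
  # pad with air so the volume border behaves as an air boundary
  pad <- array(TRUE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- air
  nmax <- floor(layerMm / spacingMm)
  reach <- array(FALSE, d)
  for (dx in -nmax[1]:nmax[1]) for (dy in -nmax[2]:nmax[2])
    for (dz in -nmax[3]:nmax[3]) {
      if (dx == 0 && dy == 0 && dz == 0) next
      if (sqrt(sum((c(dx, dy, dz) * spacingMm)^2)) > layerMm + 1e-9) next
      sx <- pmin(pmax(seq_len(d[1]) + dx, 0L), d[1] + 1L) + 1L
      sy <- pmin(pmax(seq_len(d[2]) + dy, 0L), d[2] + 1L) + 1L
      sz <- pmin(pmax(seq_len(d[3]) + dz, 0L), d[3] + 1L) + 1L
      reach <- reach | pad[sx, sy, sz]
    }
  reach & !air
}

#' Build a phantom from a Hounsfield grid
#'
#' Runs the HU-to-material calibration and skin-layer extraction and wraps
#' the result in a validated [VoxelPhantom-class]. Voxel (i,j,k) (0-based)
#' has its center at \code{originMm + (c(i,j,k) + 0.5) * spacingMm}, room
#' frame, origin at the isocenter.
#'
#' @param hu 3-D array of Hounsfield units
#' @param spacingMm voxel pitch per axis, mm (recycled to length 3)
#' @param originMm corner of voxel (0,0,0), mm
#' @param skinLayerMm skin-layer depth passed to [extractSkinMask()]
#' @return a [VoxelPhantom-class]
#' @export
phantomFromHu <- function(hu, spacingMm, originMm, skinLayerMm = 3) {
  spacingMm <- rep(spacingMm, length.out = 3)
  mm <- huToMaterial(hu)
  mat <- array(mm$materialId, dim(hu))
  ph <- new("VoxelPhantom", hu = hu, materialId = mat,
            density = array(mm$density, dim(hu)),
            skinMask = .skin_mask(mat, spacingMm, skinLayerMm),
            spacingMm = spacingMm, originMm = originMm)
  ph
}

#' Synthetic CT torso
#'
#' Desk-scale stand-in for a body-phantom CT: an elliptical soft-tissue
#' cylinder (lateral semi-axis 150 mm, anterior-posterior 100 mm, centered
#' 20 mm below the isocenter so the posterior surface sits 60 cm from the
#' under-table source at the PA pose), two lung ellipsoids near -750 HU, a
#' spine column near +700 HU, surrounded by air. Mild Gaussian HU texture
#' is added inside the body; deterministic for a given seed.
#'
#' @param nx,ny,nz grid size (each >= 32)
#' @param spacingMm isotropic voxel pitch, mm
#' @param seed RNG seed for the HU texture
#' @return a [VoxelPhantom-class]
#' @export
synthCtTorso <- function(nx = 128, ny = 128, nz = 64, spacingMm = 3, seed = 1) {
  stopifnot(nx >= 32, ny >= 32, nz >= 32)
  spacing <- rep(spacingMm, length.out = 3)
  center <- c(0, -20, 0)
  origin <- center - c(nx, ny, nz) * spacing / 2 - c(0, 0, 0)
  xs <- origin[1] + (seq_len(nx) - 0.5) * spacing[1]
  ys <- origin[2] + (seq_len(ny) - 0.5) * spacing[2]
  zs <- origin[3] + (seq_len(nz) - 0.5) * spacing[3]
  X <- array(rep(xs, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(ys, each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(zs, each = nx * ny), c(nx, ny, nz))
  hu <- array(-1000, c(nx, ny, nz))
  body <- ((X - center[1]) / 150)^2 + ((Y - center[2]) / 100)^2 <= 1
  hu[body] <- 40
  for (sgn in c(-1, 1)) {
    lung <- ((X - sgn * 55) / 45)^2 + ((Y - (center[2] + 15)) / 55)^2 +
      (Z / 70)^2 <= 1
    hu[lung & body] <- -750
  }
  spine <- (X^2 + (Y - (center[2] - 62))^2) <= 15^2
  hu[spine & body] <- 700
  noise <- .with_seed(seed, stats::rnorm(sum(body), 0, 15))
  hu[body] <- hu[body] + noise
  hu <- pmin(pmax(hu, -1000), 1500)
  phantomFromHu(hu, spacing, origin, skinLayerMm = max(spacing))
}
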