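.pkg_cache <- new.env(parent = emptyenv())

#' Load the photon cross-section table
#'
#' Reads the cross-section CSV shipped with the package (see
#' \code{inst/extdata/xsec_materials.csv} and the build script under
#' \code{inst/scripts/}) into a validated [MaterialTable-class]. Cached per
#' session.
#'
#' @return a [MaterialTable-class]
#' @export
materialTable <- function() {
  if (!is.null(.pkg_cache$mat)) return(.pkg_cache$mat)
  path <- system.file("extdata", "xsec_materials.csv", package = "fluorodose",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  eg <- sort(unique(df$energy_keV))
  pick <- function(col) {
    m <- vapply(MATERIALS, function(mm) {
      sub <- df[df$material == mm, ]
      sub[[col]][order(sub$energy_keV)]
    }, numeric(length(eg)))
    dimnames(m) <- list(NULL, MATERIALS)
    m
  }
  tab <- new("MaterialTable", energyKeV = eg, materials = MATERIALS,
             muRho = pick("mu_rho"), mutrRho = pick("mutr_rho"),
             fPe = pick("f_pe"), fCo = pick("f_co"), fRa = pick("f_ra"))
  .pkg_cache$mat <- tab
  tab
}

# log-log interpolation of a tabulated coefficient; vectorized in energy
.loglog_interp <- function(egrid, values, energy) {
  exp(stats::approx(log(egrid), log(values), xout = log(energy),
                    rule = 1)$y)
}

.material_code <- function(material) {
  code <- match(material, MATERIALS)
  if (any(is.na(code)))
    stop("unknown material: ", paste(material[is.na(code)], collapse = ", "))
  code
}

#' Linear attenuation coefficient
#'
#' Looks up the mass attenuation coefficient for a material at the given
#' photon energy (log-log interpolation between grid points) and scales by
#' mass density: mu = (mu/rho)(E) x rho, in 1/cm. Linear in density by
#' construction.
#'
#' @param material one of [materialNames()]
#' @param energyKeV photon energy, 5--150 keV (vectorized)
#' @param density mass density in g/cm^3
#' @return linear attenuation coefficient(s), 1/cm
#' @examples
#' attenuationCoefficient("water", 100, 1.0)  # ~0.171 /cm
#' @export
attenuationCoefficient <- function(material, energyKeV, density) {
  stopifnot(length(material) == 1, density > 0)
  if (any(energyKeV < 5 | energyKeV > 150))
    stop("energy outside the 5-150 keV table range")
  tab <- materialTable()
  code <- .material_code(material)
  .loglog_interp(tab@energyKeV, tab@muRho[, code], energyKeV) * density
}

#' Mass energy-transfer coefficient
#'
#' @inheritParams attenuationCoefficient
#' @return mu_tr/rho in cm^2/g
#' @export
energyTransferCoefficient <- function(material, energyKeV) {
  stopifnot(length(material) == 1)
  if (any(energyKeV < 5 | energyKeV > 150))
    stop("energy outside the 5-150 keV table range")
  tab <- materialTable()
  code <- .material_code(material)
  .loglog_interp(tab@energyKeV, tab@mutrRho[, code], energyKeV)
}
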