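CUTOFF_KEV <- 5
CU_DENSITY <- 8.96  # g/cm^3

# closed-form filtered bremsstrahlung fluence density (unnormalized):
# Kramers (kvp - E)/E shaped by exp(-mu_Cu(E) * t); no characteristic lines
.spectrum_density <- function(energyKeV, kvp, filterCuMm) {
  mu <- if (filterCuMm > 0)
    attenuationCoefficient("copper", energyKeV, CU_DENSITY) else 0
  pmax(kvp - energyKeV, 0) / energyKeV * exp(-mu * filterCuMm / 10)
}

#' Generate a filtered x-ray spectrum
#'
#' Kramers bremsstrahlung shaped by copper filtration, binned on a regular
#' energy grid between the 5 keV transport cutoff and the tube potential.
#' Bin weights are per-bin integrals of the closed-form fluence density
#' (Simpson quadrature on each bin, clipped to \[5, kvp\]); the stored mean
#' energy is the continuous fluence-weighted mean of the same density.
#' Hardening monotonicity holds: thicker filtration raises the mean energy.
#'
#' @param kvp tube potential, 40--150 kV
#' @param filterCuMm copper filtration in mm (>= 0)
#' @param binWidthKeV bin width (default 1 keV)
#' @return a [Spectrum-class]
#' @examples
#' s <- generateSpectrum(76, 0.3)
#' meanEnergy(s)
#' @export
generateSpectrum <- function(kvp, filterCuMm = 0, binWidthKeV = 1) {
  if (kvp < 40 || kvp > 150) stop("kvp outside the supported 40-150 kV range")
  if (filterCuMm < 0) stop("negative filtration")
  if (kvp <= CUTOFF_KEV) stop("tube potential below the 5 keV cutoff")
  centers <- seq(CUTOFF_KEV, kvp, by = binWidthKeV)
  w <- binWidthKeV
  weights <- vapply(centers, function(cc) {
    lo <- max(cc - w / 2, CUTOFF_KEV)
    hi <- min(cc + w / 2, kvp)
    if (hi <= lo) return(0)
    xs <- seq(lo, hi, length.out = 21)        # composite Simpson, 20 panels
    ys <- .spectrum_density(xs, kvp, filterCuMm)
    h <- (hi - lo) / 20
    h / 3 * (ys[1] + ys[21] + 4 * sum(ys[seq(2, 20, 2)]) +
             2 * sum(ys[seq(3, 19, 2)]))
  }, numeric(1))
  weights <- weights / sum(weights)
  # continuous mean over [5, kvp] by composite Simpson on a fine grid
  ne <- 4000
  xs <- seq(CUTOFF_KEV, kvp, length.out = 2 * ne + 1)
  ys <- .spectrum_density(xs, kvp, filterCuMm)
  h <- (kvp - CUTOFF_KEV) / (2 * ne)
  simps <- function(v) h / 3 * (v[1] + v[length(v)] +
    4 * sum(v[seq(2, length(v) - 1, 2)]) + 2 * sum(v[seq(3, length(v) - 2, 2)]))
  meanKeV <- simps(xs * ys) / simps(ys)
  new("Spectrum", kvp = kvp, filterCuMm = filterCuMm, energyBins = centers,
      relFluence = weights, meanKeV = meanKeV)
}

#' Sample photon energies from a spectrum
#'
#' Inverse-CDF sampling over the spectrum bins using R's RNG; set
#' \code{set.seed()} for reproducibility.
#'
#' @param spectrum a [Spectrum-class]
#' @param n number of samples
#' @return numeric vector of bin-center energies (keV)
#' @export
sampleEnergy <- function(spectrum, n = 1) {
  stopifnot(is(spectrum, "Spectrum"))
  cdf <- cumsum(spectrum@relFluence)
  cdf[length(cdf)] <- 1
  spectrum@energyBins[findInterval(stats::runif(n), cdf) + 1L]
}
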