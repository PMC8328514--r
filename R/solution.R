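## Solution biophysics: ionic strength, Debye screening, Kyte-Doolittle
## hydropathy, DSF melt-curve analysis and turbidity classification.

#' Construct a buffer composition
#'
#' @param species list of dissolved species, each created by [saltSpecies()].
#' @param temperature degrees Celsius (default 4, cold-room conditions).
#' @return a [BufferComposition-class].
#' @examples
#' BufferComposition(list(saltSpecies("NaCl", 150)))
#' @export
BufferComposition <- function(species, temperature = 4) {
  new("BufferComposition", species = species,
      temperature = as.numeric(temperature))
}

#' Describe a dissolved salt and its dissociation
#'
#' Known formulas (NaCl, KCl, MgCl2, CaCl2, Na2HPO4, NaH2PO4, GdnHCl,
#' NH4OAc) carry built-in full-dissociation ion tables; other species need
#' an explicit \code{ions} data.frame(ion, stoich, z). Phosphates are taken
#' as drawn (H2PO4- monovalent, HPO4 2- divalent), with no acid-base
#' speciation.
#'
#' @param name formula name.
#' @param conc_mM analytical concentration, mM.
#' @param ions optional data.frame(ion, stoich, z) overriding the table.
#' @return a species list element for [BufferComposition()].
#' @export
saltSpecies <- function(name, conc_mM, ions = NULL) {
  if (is.null(ions)) {
    tab <- list(
      NaCl    = data.frame(ion = c("Na+", "Cl-"),  stoich = c(1, 1), z = c(1, -1)),
      KCl     = data.frame(ion = c("K+", "Cl-"),   stoich = c(1, 1), z = c(1, -1)),
      MgCl2   = data.frame(ion = c("Mg2+", "Cl-"), stoich = c(1, 2), z = c(2, -1)),
      CaCl2   = data.frame(ion = c("Ca2+", "Cl-"), stoich = c(1, 2), z = c(2, -1)),
      NaH2PO4 = data.frame(ion = c("Na+", "H2PO4-"), stoich = c(1, 1), z = c(1, -1)),
      Na2HPO4 = data.frame(ion = c("Na+", "HPO4_2-"), stoich = c(2, 1), z = c(1, -2)),
      GdnHCl  = data.frame(ion = c("Gdn+", "Cl-"), stoich = c(1, 1), z = c(1, -1)),
      NH4OAc  = data.frame(ion = c("NH4+", "OAc-"), stoich = c(1, 1), z = c(1, -1)))
    ions <- tab[[name]]
    if (is.null(ions))
      .condStop("validationError",
                paste("unknown salt", name, "- supply an ions table"))
  }
  list(name = name, conc_mM = as.numeric(conc_mM), ions = ions)
}

#' The SEC running-buffer series used for ionic-strength titration
#'
#' Phosphate-buffered compositions whose NaCl concentration (0, 300,
#' 800 mM, alongside 4 mM NaH2PO4 and 49 mM Na2HPO4) brings the total
#' ionic strength to nominally 0.15, 0.45 and 0.95 M.
#'
#' @param temperature degrees Celsius.
#' @return named list of three [BufferComposition-class] objects.
#' @export
defaultSecBuffers <- function(temperature = 4) {
  mk <- function(nacl) BufferComposition(list(
    saltSpecies("NaCl", nacl),
    saltSpecies("NaH2PO4", 4),
    saltSpecies("Na2HPO4", 49)), temperature = temperature)
  list(`0.15M` = mk(0), `0.45M` = mk(300), `0.95M` = mk(800))
}

#' Ionic strength of a buffer
#'
#' I = 1/2 * sum over all dissolved ions of c * z^2, with c the ion
#' concentration (species concentration times stoichiometry, mM) under
#' full dissociation. Additive over species and linear in concentration.
#'
#' @param buffer a [BufferComposition-class].
#' @param ... unused.
#' @return ionic strength in mM.
#' @examples
#' ionicStrength(BufferComposition(list(saltSpecies("MgCl2", 10))))  # 30 mM
#' @rdname ionicStrength
#' @export
setMethod("ionicStrength", "BufferComposition",
function(buffer, ...) {
  sum(vapply(buffer@species, function(sp)
    0.5 * sum(sp$conc_mM * sp$ions$stoich * sp$ions$z^2), 1))
})

## Malmberg-Maryott empirical static dielectric constant of pure water,
## t in degrees Celsius (valid 0-100 C)
.waterEpsilon <- function(tempC) {
  87.740 - 0.40008 * tempC + 9.398e-4 * tempC^2 - 1.410e-6 * tempC^3
}

#' Debye screening length of an electrolyte
#'
#' kappa^-1 = sqrt(eps0 * epsr(T) * kB * T / (2 * NA * e^2 * I * 1000)),
#' reported in Angstrom, with I in mol/L and epsr(T) from an empirical
#' pure-water dielectric model (a constant relative permittivity can be
#' supplied instead). At 25 C this reproduces the familiar closed form
#' kappa^-1(nm) = 0.304 / sqrt(I).
#'
#' @param I ionic strength, mol/L (> 0).
#' @param temperatureK absolute temperature, 273-373 K (default 277.15 K,
#'   i.e. 4 C, the working temperature of the oligomerization assays).
#' @param epsr optional fixed relative permittivity overriding the water
#'   model.
#' @return Debye length in Angstrom.
#' @examples
#' debyeLength(0.34, 277.15)          # ~5 A: screening at cold-room salt
#' debyeLength(0.15, 298.15)          # ~7.85 A
#' @export
debyeLength <- function(I, temperatureK = 277.15, epsr = NULL) {
  if (any(I <= 0)) .condStop("domainError", "ionic strength must be positive")
  if (any(temperatureK < 273) || any(temperatureK > 373))
    .condStop("domainError", "temperature must be within 273-373 K")
  eps0 <- 8.8541878128e-12   # F/m
  kB <- 1.380649e-23         # J/K
  NA_ <- 6.02214076e23       # 1/mol
  e <- 1.602176634e-19       # C
  er <- if (is.null(epsr)) .waterEpsilon(temperatureK - 273.15) else epsr
  kappaInv_m <- sqrt(eps0 * er * kB * temperatureK /
                       (2 * NA_ * e^2 * I * 1e3))
  kappaInv_m * 1e10
}

#' Is an electrostatic interaction screened out?
#'
#' TRUE when the interaction distance strictly exceeds the Debye length at
#' the given ionic strength and temperature (a pair exactly at the Debye
#' length is not called screened).
#'
#' @param distance Angstrom.
#' @param I ionic strength, mol/L.
#' @param temperatureK Kelvin.
#' @param epsr optional fixed relative permittivity.
#' @return logical.
#' @export
isScreened <- function(distance, I, temperatureK = 277.15, epsr = NULL) {
  distance > debyeLength(I, temperatureK, epsr)
}

## Kyte-Doolittle hydropathy scale
.KD_SCALE <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Kyte-Doolittle hydropathy profile
#'
#' Sliding-window mean of Kyte-Doolittle hydropathy values over an
#' amino-acid sequence. Only positions with a full window are reported, so
#' for window w the profile covers positions (w+1)/2 to length-(w-1)/2.
#'
#' @param sequence amino-acid string (one-letter codes).
#' @param window odd window size, default 3.
#' @return data.frame(position, residue, hydropathy); \code{position} is
#'   the centre of each window.
#' @examples
#' hydropathyProfile("AIR")          # (1.8 + 4.5 - 4.5) / 3 = 0.6
#' @export
hydropathyProfile <- function(sequence, window = 3) {
  if (window %% 2 != 1) .condStop("validationError", "window must be odd")
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (window > length(aa))
    .condStop("validationError", "window exceeds sequence length")
  unknown <- which(!aa %in% names(.KD_SCALE))
  if (length(unknown))
    .condStop("validationError", sprintf(
      "unknown residue '%s' at position %d", aa[unknown[1]], unknown[1]))
  v <- .KD_SCALE[aa]
  half <- (window - 1) / 2
  centers <- seq(half + 1, length(aa) - half)
  score <- vapply(centers, function(i) mean(v[(i - half):(i + half)]), 1)
  data.frame(position = centers, residue = aa[centers], hydropathy = score)
}

#' First derivative of a melt curve
#'
#' dRFU/dT by central differences (one-sided at the endpoints) after an
#' optional moving-average smoothing of the fluorescence signal (default
#' 5 points, recorded in DSF analyses before differencing).
#'
#' @param curve a [MeltCurve-class].
#' @param smoothPoints moving-average width (odd; 0 or 1 disables).
#' @param ... unused.
#' @return the curve with its \code{derivative} slot filled.
#' @rdname meltDerivative
#' @export
setMethod("meltDerivative", "MeltCurve",
function(curve, smoothPoints = 5, ...) {
  tt <- curve@temperature; f <- curve@fluorescence
  n <- length(tt)
  if (n < 5) .condStop("validationError", "need at least 5 points")
  if (smoothPoints > 1) {
    k <- smoothPoints %/% 2
    fp <- c(rep(f[1], k), f, rep(f[n], k))
    f <- as.numeric(stats::filter(fp, rep(1 / (2 * k + 1), 2 * k + 1)))[
      (k + 1):(k + n)]
  }
  d <- numeric(n)
  d[1] <- (f[2] - f[1]) / (tt[2] - tt[1])
  d[n] <- (f[n] - f[n - 1]) / (tt[n] - tt[n - 1])
  i <- 2:(n - 1)
  d[i] <- (f[i + 1] - f[i - 1]) / (tt[i + 1] - tt[i - 1])
  new("MeltCurve", temperature = curve@temperature,
      fluorescence = curve@fluorescence, derivative = d)
})

#' Detect melting temperature and aggregation quench in a melt curve
#'
#' Tm is the temperature of the global maximum of the first derivative,
#' provided it exceeds a prominence threshold (relative to the amplitude
#' of the fluorescence signal). The quench onset is the first temperature
#' after Tm where the derivative stays below a negative threshold for at
#' least \code{k} consecutive points - the signature of the abrupt
#' fluorescence collapse when the unfolded protein aggregates. Either
#' event is NA when absent.
#'
#' @param curve a [MeltCurve-class] with its derivative computed.
#' @param minProminence minimum derivative maximum, in units of
#'   (fluorescence amplitude) per degree (default 0.01).
#' @param quenchFraction quench threshold as a fraction of the positive
#'   derivative maximum (default 0.25): derivative below
#'   \code{-quenchFraction * max(derivative)} counts as collapsing.
#' @param k consecutive collapsing points required (default 3).
#' @param ... unused.
#' @return list(tm, quenchT) in degrees Celsius; NA when absent.
#' @rdname detectMeltEvents
#' @export
setMethod("detectMeltEvents", "MeltCurve",
function(curve, minProminence = 0.01, quenchFraction = 0.25, k = 3, ...) {
  if (!length(curve@derivative))
    .condStop("validationError", "derivative missing: run meltDerivative() first")
  tt <- curve@temperature; d <- curve@derivative
  amp <- diff(range(curve@fluorescence))
  iMax <- which.max(d)
  tm <- NA_real_
  if (d[iMax] > minProminence * max(amp, .Machine$double.eps)) {
    ## refine the grid argmax by a local quadratic fit (+-2 C window),
    ## which averages out point noise and grid discretization
    win <- which(abs(tt - tt[iMax]) <= 2)
    tm <- tt[iMax]
    if (length(win) >= 5) {
      q <- lm(d[win] ~ poly(tt[win], 2, raw = TRUE))
      b <- coef(q)
      if (is.finite(b[3]) && b[3] < 0) {
        vertex <- unname(-b[2] / (2 * b[3]))
        if (vertex >= min(tt[win]) && vertex <= max(tt[win])) tm <- vertex
      }
    }
  }
  quenchT <- NA_real_
  if (!is.na(tm)) {
    thr <- -quenchFraction * d[iMax]
    below <- d < thr & seq_along(d) > iMax
    run <- rle(below)
    ends <- cumsum(run$lengths)
    hit <- which(run$values & run$lengths >= k)
    if (length(hit)) {
      start <- ends[hit[1]] - run$lengths[hit[1]] + 1L
      quenchT <- tt[start]
    }
  }
  list(tm = tm, quenchT = quenchT)
})

#' Classify turbidity readings into aggregation states
#'
#' Two configurable A450 thresholds map each condition to soluble,
#' slight (slight aggregation) or aggregated; the state is monotone
#' non-decreasing in A450 by construction.
#'
#' @param series a [TurbiditySeries-class].
#' @param thresholds named numeric c(slight = ..., aggregated = ...);
#'   readings below \code{slight} are soluble, at or above
#'   \code{aggregated} are aggregated.
#' @param ... unused.
#' @return data.frame(ionic_strength, a450, state).
#' @rdname classifyAggregation
#' @export
setMethod("classifyAggregation", "TurbiditySeries",
function(series, thresholds = c(slight = 0.05, aggregated = 0.3), ...) {
  if (any(series@a450 < 0))
    .condStop("validationError", "A450 must be non-negative")
  if (thresholds[["slight"]] > thresholds[["aggregated"]])
    .condStop("validationError", "slight threshold must not exceed aggregated")
  st <- ifelse(series@a450 >= thresholds[["aggregated"]], "aggregated",
               ifelse(series@a450 >= thresholds[["slight"]], "slight",
                      "soluble"))
  data.frame(ionic_strength = series@ionicStrength, a450 = series@a450,
             state = factor(st, levels = c("soluble", "slight", "aggregated")))
})

#' Read a melt curve from a two-column CSV (temperature, fluorescence)
#' @param path file path.
#' @param sep,dec delimiter and decimal mark.
#' @return a [MeltCurve-class].
#' @export
readMeltCurve <- function(path, sep = ",", dec = ".") {
  tab <- .readNumericTable(path, sep = sep, dec = dec, minCols = 2)
  MeltCurve(tab[[1]], tab[[2]])
}

#' Read a turbidity series from a two-column CSV (ionic strength, A450)
#' @param path file path.
#' @param salt identity of the varied salt.
#' @param sep,dec delimiter and decimal mark.
#' @return a [TurbiditySeries-class].
#' @export
readTurbiditySeries <- function(path, salt = "NaCl", sep = ",", dec = ".") {
  tab <- .readNumericTable(path, sep = sep, dec = dec, minCols = 2)
  ord <- order(tab[[1]])
  TurbiditySeries(tab[[1]][ord], tab[[2]][ord], salt = salt)
}
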