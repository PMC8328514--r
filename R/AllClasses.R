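#' @import methods
#' @importFrom stats approx coef cov dnorm lm median na.omit poly qnorm
#'   quantile rnorm runif sd setNames
#' @importFrom utils head read.csv tail write.csv
NULL

.SPECIES <- c("HMW", "DIMER", "MONOMER")

.REGIONS <- c(paste0("TM", 1:7), "H8",
              paste0("ICL", 1:3), paste0("ECL", 1:3), "CTERM", "NTERM")

.SITE_CLASSES <- c("charged+", "charged-", "polar-donor", "polar-acceptor",
                   "nonpolar", "backbone")

#' Chromatogram: a size-exclusion chromatography elution trace
#'
#' Holds one SEC trace: a strictly increasing elution coordinate (mL or s)
#' and the A280 absorbance read at each coordinate, plus a sample label and
#' a flag recording whether the baseline has been corrected.
#'
#' @slot elution numeric, strictly increasing elution coordinates.
#' @slot absorbance numeric, finite A280 readings (arbitrary units), same
#'   length as \code{elution}.
#' @slot label character(1), free-text sample identifier.
#' @slot baselineCorrected logical(1).
#' @seealso [readChromatogram()], [correctBaseline()], [fitPeaks()]
#' @exportClass Chromatogram
setClass("Chromatogram",
  representation(elution = "numeric", absorbance = "numeric",
                 label = "character", baselineCorrected = "logical"),
  prototype(label = "", baselineCorrected = FALSE))

setValidity("Chromatogram", function(object) {
  e <- object@elution; a <- object@absorbance
  if (length(e) != length(a))
    return("elution and absorbance must have equal length")
  if (length(e) < 10)
    return("a chromatogram needs at least 10 points")
  if (any(!is.finite(e)) || any(!is.finite(a)))
    return("elution and absorbance must be finite")
  if (any(diff(e) <= 0))
    return("elution must be strictly increasing")
  if (length(object@label) != 1) return("label must be length 1")
  if (length(object@baselineCorrected) != 1)
    return("baselineCorrected must be length 1")
  TRUE
})

#' Chromatogram constructor
#'
#' @param elution numeric, strictly increasing elution coordinates (mL or s).
#' @param absorbance numeric, A280 readings of the same length.
#' @param label sample identifier.
#' @param baselineCorrected whether the trace is already baseline-corrected.
#' @return a [Chromatogram-class] object.
#' @examples
#' Chromatogram(seq(8, 16, length.out = 50), dnorm(seq(8, 16, length.out = 50), 12, 0.4))
#' @export
Chromatogram <- function(elution, absorbance, label = "",
                         baselineCorrected = FALSE) {
  new("Chromatogram", elution = as.numeric(elution),
      absorbance = as.numeric(absorbance), label = as.character(label),
      baselineCorrected = baselineCorrected)
}

#' PeakFit: a fitted sum-of-Gaussians model of a chromatogram
#'
#' @slot peaks data.frame with columns \code{amplitude}, \code{center},
#'   \code{sigma}, \code{area}, sorted by center ascending; \code{area}
#'   equals \code{amplitude * sigma * sqrt(2*pi)}.
#' @slot covariance parameter covariance matrix in peak-blocked order
#'   (amplitude, center, sigma per peak, peaks sorted by center).
#' @slot rSquared coefficient of determination of the fit.
#' @slot window list describing any manual window / fixed-width constraint
#'   used (empty when none).
#' @slot offset numeric(2), fitted residual-baseline terms of the model
#'   (constant, slope about the mean elution); zeros when disabled.
#' @slot label sample label carried over from the chromatogram.
#' @exportClass PeakFit
setClass("PeakFit",
  representation(peaks = "data.frame", covariance = "matrix",
                 rSquared = "numeric", window = "list", offset = "numeric",
                 label = "character"),
  prototype(window = list(), offset = 0, label = ""))

setValidity("PeakFit", function(object) {
  p <- object@peaks
  need <- c("amplitude", "center", "sigma", "area")
  if (!all(need %in% names(p))) return("peaks must have amplitude/center/sigma/area")
  if (nrow(p) > 1 && any(diff(p$center) < 0)) return("peaks must be sorted by center")
  if (any(p$sigma <= 0)) return("sigma must be positive")
  if (any(abs(p$area - p$amplitude * p$sigma * sqrt(2 * pi)) >
          1e-9 * pmax(abs(p$area), 1e-300)))
    return("area inconsistent with amplitude * sigma * sqrt(2*pi)")
  if (length(object@rSquared) != 1 || object@rSquared > 1 + 1e-12)
    return("rSquared must be a single value <= 1")
  v <- object@covariance
  if (nrow(v) != 3 * nrow(p) || ncol(v) != 3 * nrow(p))
    return("covariance must be 3n x 3n")
  if (max(abs(v - t(v))) > 1e-6 * max(abs(v), 1))
    return("covariance must be symmetric")
  TRUE
})

#' SpeciesAssignment: fitted peaks mapped onto oligomeric species
#'
#' Maps each Gaussian component of a [PeakFit-class] onto one of the species
#' HMW (high-molecular-weight oligomer), DIMER or MONOMER, in their SEC
#' elution order (HMW first), and carries the pooled area per species with
#' its covariance (propagated from the fit covariance) for downstream
#' level computation.
#'
#' @slot assignment named list (HMW, DIMER, MONOMER) of integer peak indices.
#' @slot unassigned integer indices of peaks deliberately left out.
#' @slot areas named numeric(3), pooled area per species.
#' @slot areaCov 3x3 covariance matrix of the pooled areas.
#' @slot label sample label.
#' @exportClass SpeciesAssignment
setClass("SpeciesAssignment",
  representation(assignment = "list", unassigned = "integer",
                 areas = "numeric", areaCov = "matrix", label = "character"),
  prototype(unassigned = integer(), label = ""))

setValidity("SpeciesAssignment", function(object) {
  a <- object@assignment
  if (!identical(sort(names(a)), sort(.SPECIES)))
    return("assignment must have exactly HMW, DIMER, MONOMER entries")
  idx <- unlist(a, use.names = FALSE)
  if (anyDuplicated(c(idx, object@unassigned)))
    return("peak index sets must be disjoint")
  if (!identical(sort(names(object@areas)), sort(.SPECIES)))
    return("areas must be named HMW, DIMER, MONOMER")
  if (any(object@areas < -1e-12)) return("areas must be non-negative")
  TRUE
})

#' OligomerLevels: monomer-equivalent oligomer levels with 95% CIs
#'
#' The headline statistic of the SEC analysis: each oligomeric species'
#' integrated peak area divided by the monomer peak area (dimensionless,
#' arbitrary units), with standard errors propagated from the fit covariance
#' by the delta method and reported as 95% confidence half-widths. Errors
#' reflect fit variance only, not experimental replication.
#'
#' @slot dimerLevel dimer area / monomer area.
#' @slot hmwLevel HMW area / monomer area.
#' @slot totalLevel their sum.
#' @slot se named numeric, delta-method standard error of each level.
#' @slot ci95 named numeric, 95% confidence half-width of each level.
#' @slot label sample label.
#' @exportClass OligomerLevels
setClass("OligomerLevels",
  representation(dimerLevel = "numeric", hmwLevel = "numeric",
                 totalLevel = "numeric", se = "numeric", ci95 = "numeric",
                 label = "character"),
  prototype(label = ""))

setValidity("OligomerLevels", function(object) {
  lv <- c(object@dimerLevel, object@hmwLevel, object@totalLevel)
  if (any(lv < -1e-12)) return("levels must be non-negative")
  if (abs(object@totalLevel - (object@dimerLevel + object@hmwLevel)) >
      1e-12 * max(1, object@totalLevel))
    return("totalLevel must equal dimerLevel + hmwLevel")
  TRUE
})

#' LaneProfile: a densitometric intensity profile along a blot lane
#'
#' @slot position numeric, strictly increasing distances along the lane
#'   (pixels or mm).
#' @slot intensity numeric, non-negative (after background subtraction)
#'   densitometric values.
#' @slot laneLabel character(1).
#' @slot ladder data.frame with columns \code{position}, \code{kda}
#'   (may have zero rows); calibration points used for labeling only.
#' @slot backgroundSubtracted logical(1).
#' @exportClass LaneProfile
setClass("LaneProfile",
  representation(position = "numeric", intensity = "numeric",
                 laneLabel = "character", ladder = "data.frame",
                 backgroundSubtracted = "logical"),
  prototype(laneLabel = "",
            ladder = data.frame(position = numeric(), kda = numeric()),
            backgroundSubtracted = FALSE))

setValidity("LaneProfile", function(object) {
  p <- object@position; i <- object@intensity
  if (length(p) != length(i)) return("position and intensity lengths differ")
  if (any(!is.finite(p)) || any(!is.finite(i))) return("values must be finite")
  if (any(diff(p) <= 0)) return("position must be strictly increasing")
  if (object@backgroundSubtracted && any(i < -1e-9 * max(abs(i), 1)))
    return("intensity must be non-negative after background subtraction")
  if (!all(c("position", "kda") %in% names(object@ladder)))
    return("ladder needs position and kda columns")
  TRUE
})

#' LaneProfile constructor
#' @param position increasing positions along the lane.
#' @param intensity densitometric values.
#' @param laneLabel lane identifier.
#' @param ladder optional data.frame(position, kda) of ladder calibration
#'   points.
#' @param backgroundSubtracted whether a background has been removed.
#' @return a [LaneProfile-class].
#' @export
LaneProfile <- function(position, intensity, laneLabel = "",
                        ladder = data.frame(position = numeric(),
                                            kda = numeric()),
                        backgroundSubtracted = FALSE) {
  new("LaneProfile", position = as.numeric(position),
      intensity = as.numeric(intensity), laneLabel = as.character(laneLabel),
      ladder = ladder, backgroundSubtracted = backgroundSubtracted)
}

#' BandQuant: integrated band areas and the monomer-equivalent dimer level
#'
#' @slot windows named list (MONOMER, DIMER) of c(lo, hi) position ranges.
#' @slot areas named numeric, trapezoidal area per band.
#' @slot dimerLevel dimer area / monomer area.
#' @slot laneLabel character(1).
#' @exportClass BandQuant
setClass("BandQuant",
  representation(windows = "list", areas = "numeric", dimerLevel = "numeric",
                 laneLabel = "character"),
  prototype(laneLabel = ""))

setValidity("BandQuant", function(object) {
  if (object@dimerLevel < 0) return("dimerLevel must be non-negative")
  if (!is.na(object@areas["MONOMER"]) && object@areas["MONOMER"] <= 0)
    return("monomer area must be positive")
  TRUE
})

#' ProtomerModel: an annotated point model of one receptor copy
#'
#' A protomer is represented as a table of labeled coordinate sites:
#' each residue (1-based receptor numbering) carries one or more sites,
#' each with a region label (TM1..TM7, H8, loops, CTERM), an interaction
#' class, Cartesian coordinates in Angstrom and, for hydrogen-bond donors,
#' the position of the attached hydrogen.
#'
#' @slot sites data.frame with columns \code{resid}, \code{resname},
#'   \code{region}, \code{site}, \code{class}, \code{x}, \code{y}, \code{z},
#'   \code{hx}, \code{hy}, \code{hz} (hydrogen columns NA for non-donors),
#'   sorted by residue id.
#' @slot ctermStart first residue id of the C-terminal segment (receptor
#'   default 291).
#' @exportClass ProtomerModel
setClass("ProtomerModel",
  representation(sites = "data.frame", ctermStart = "numeric"),
  prototype(ctermStart = 291))

setValidity("ProtomerModel", function(object) {
  s <- object@sites
  need <- c("resid", "resname", "region", "site", "class",
            "x", "y", "z", "hx", "hy", "hz")
  if (!all(need %in% names(s)))
    return(paste("sites must have columns:", paste(need, collapse = ", ")))
  if (nrow(s) == 0) return("protomer must have at least one site")
  if (is.unsorted(s$resid)) return("sites must be sorted by residue id")
  if (any(!is.finite(as.matrix(s[, c("x", "y", "z")]))))
    return("coordinates must be finite")
  if (!all(s$region %in% .REGIONS))
    return(paste("unknown region label(s):",
                 paste(setdiff(unique(s$region), .REGIONS), collapse = ", ")))
  if (!all(s$class %in% .SITE_CLASSES))
    return(paste("unknown site class(es):",
                 paste(setdiff(unique(s$class), .SITE_CLASSES), collapse = ", ")))
  bad <- unique(s$resid[s$region == "CTERM" & s$resid < object@ctermStart])
  if (length(bad))
    return(paste("CTERM residues below ctermStart:", paste(bad, collapse = ", ")))
  TRUE
})

#' ProtomerModel constructor
#' @param sites site table (see [ProtomerModel-class]).
#' @param ctermStart first residue id of the C-terminal segment.
#' @return a [ProtomerModel-class].
#' @export
ProtomerModel <- function(sites, ctermStart = 291) {
  for (h in c("hx", "hy", "hz"))
    if (is.null(sites[[h]])) sites[[h]] <- NA_real_
  if (is.null(sites$resname)) sites$resname <- "UNK"
  if (is.null(sites$site)) sites$site <- "S"
  sites <- sites[order(sites$resid), , drop = FALSE]
  rownames(sites) <- NULL
  new("ProtomerModel", sites = sites, ctermStart = as.numeric(ctermStart))
}

#' DimerConfiguration: two protomers in one frame
#'
#' @slot protomerA,protomerB [ProtomerModel-class] objects sharing the same
#'   residue schema.
#' @slot frameIndex integer frame number.
#' @slot box numeric(0) for no periodicity, or numeric(3) orthorhombic box
#'   edge lengths in Angstrom (minimum-image convention applied to
#'   distances when present).
#' @exportClass DimerConfiguration
setClass("DimerConfiguration",
  representation(protomerA = "ProtomerModel", protomerB = "ProtomerModel",
                 frameIndex = "integer", box = "numeric"),
  prototype(frameIndex = 1L, box = numeric()))

setValidity("DimerConfiguration", function(object) {
  ra <- unique(object@protomerA@sites$resid)
  rb <- unique(object@protomerB@sites$resid)
  if (!identical(ra, rb))
    return("protomers must share the same residue schema")
  if (!length(object@box) %in% c(0, 3))
    return("box must be empty or length-3")
  if (length(object@box) == 3 && any(object@box <= 0))
    return("box lengths must be positive")
  TRUE
})

#' DimerConfiguration constructor
#' @param protomerA,protomerB the two [ProtomerModel-class] copies.
#' @param frameIndex frame number within a series.
#' @param box optional numeric(3) orthorhombic box (Angstrom).
#' @return a [DimerConfiguration-class].
#' @export
DimerConfiguration <- function(protomerA, protomerB, frameIndex = 1L,
                               box = numeric()) {
  new("DimerConfiguration", protomerA = protomerA, protomerB = protomerB,
      frameIndex = as.integer(frameIndex), box = as.numeric(box))
}

#' ContactSet: typed cross-protomer contacts in one frame
#'
#' @slot contacts data.frame with columns \code{residA}, \code{residB},
#'   \code{regionA}, \code{regionB}, \code{type} (electrostatic, hbond,
#'   nonpolar), \code{distance} (Angstrom) and \code{angle} (degrees,
#'   NA except for hydrogen bonds, where it is the deviation of the
#'   donor-hydrogen-acceptor angle from linearity).
#' @slot frameIndex integer.
#' @exportClass ContactSet
setClass("ContactSet",
  representation(contacts = "data.frame", frameIndex = "integer"),
  prototype(frameIndex = 1L))

setValidity("ContactSet", function(object) {
  cs <- object@contacts
  need <- c("residA", "residB", "regionA", "regionB", "type", "distance",
            "angle")
  if (!all(need %in% names(cs)))
    return(paste("contacts must have columns:", paste(need, collapse = ", ")))
  if (nrow(cs) && !all(cs$type %in% c("electrostatic", "hbond", "nonpolar")))
    return("unknown contact type")
  TRUE
})

.ContactSet <- function(contacts, frameIndex = 1L) {
  if (nrow(contacts)) rownames(contacts) <- NULL
  new("ContactSet", contacts = contacts, frameIndex = as.integer(frameIndex))
}

.emptyContacts <- function() {
  data.frame(residA = integer(), residB = integer(),
             regionA = character(), regionB = character(),
             type = character(), distance = numeric(), angle = numeric())
}

#' InterfaceCall: symmetric / asymmetric / none classification of a dimer
#'
#' @slot classification one of "symmetric", "asymmetric", "none".
#' @slot tallies data.frame of supporting contact counts by region-pair
#'   category.
#' @exportClass InterfaceCall
setClass("InterfaceCall",
  representation(classification = "character", tallies = "data.frame"))

setValidity("InterfaceCall", function(object) {
  if (!object@classification %in% c("symmetric", "asymmetric", "none"))
    return("classification must be symmetric, asymmetric or none")
  TRUE
})

#' ClusterResult: Daura clustering of a frame series
#'
#' @slot clusters list of integer frame-index vectors, disjoint and
#'   exhaustive, ordered by decreasing size (ties by smallest member index).
#' @slot representatives integer, the cluster-center frame of each cluster
#'   (the frame with the most neighbors at selection time).
#' @slot rmsdCutoff numeric(1), Angstrom.
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(clusters = "list", representatives = "integer",
                 rmsdCutoff = "numeric"))

setValidity("ClusterResult", function(object) {
  idx <- unlist(object@clusters)
  if (anyDuplicated(idx)) return("clusters must be disjoint")
  if (length(object@representatives) != length(object@clusters))
    return("one representative per cluster")
  TRUE
})

#' BufferComposition: dissolved species of a buffer
#'
#' Each dissolved species carries its analytical concentration and the ions
#' it fully dissociates into (per-formula-unit stoichiometry and integer
#' charge); each species must be electroneutral.
#'
#' @slot species list; each element a list with \code{name},
#'   \code{conc_mM}, and \code{ions}, a data.frame(ion, stoich, z).
#' @slot temperature numeric(1), degrees Celsius.
#' @exportClass BufferComposition
setClass("BufferComposition",
  representation(species = "list", temperature = "numeric"),
  prototype(temperature = 4))

setValidity("BufferComposition", function(object) {
  for (sp in object@species) {
    if (!all(c("name", "conc_mM", "ions") %in% names(sp)))
      return("each species needs name, conc_mM, ions")
    if (sp$conc_mM < 0) return("concentrations must be non-negative")
    io <- sp$ions
    if (!all(c("ion", "stoich", "z") %in% names(io)))
      return("ions need ion, stoich, z columns")
    if (any(io$z != round(io$z))) return("ion charges must be integers")
    if (abs(sum(io$stoich * io$z)) > 1e-9)
      return(paste0("species '", sp$name, "' is not electroneutral"))
  }
  TRUE
})

#' MeltCurve: a differential scanning fluorimetry melt curve
#'
#' @slot temperature numeric, strictly increasing (degrees Celsius).
#' @slot fluorescence numeric, same length (relative fluorescence units).
#' @slot derivative numeric, dRFU/dT (length 0 until computed by
#'   [meltDerivative()]).
#' @exportClass MeltCurve
setClass("MeltCurve",
  representation(temperature = "numeric", fluorescence = "numeric",
                 derivative = "numeric"),
  prototype(derivative = numeric()))

setValidity("MeltCurve", function(object) {
  if (length(object@temperature) != length(object@fluorescence))
    return("temperature and fluorescence lengths differ")
  if (any(diff(object@temperature) <= 0))
    return("temperature must be strictly increasing")
  if (length(object@derivative) &&
      length(object@derivative) != length(object@temperature))
    return("derivative length must match the curve")
  TRUE
})

#' MeltCurve constructor
#' @param temperature increasing temperatures (Celsius).
#' @param fluorescence RFU readings.
#' @return a [MeltCurve-class].
#' @export
MeltCurve <- function(temperature, fluorescence) {
  new("MeltCurve", temperature = as.numeric(temperature),
      fluorescence = as.numeric(fluorescence))
}

#' TurbiditySeries: A450 turbidity versus ionic strength
#'
#' @slot ionicStrength numeric, ascending ionic strengths (M).
#' @slot a450 numeric, non-negative absorbance at 450 nm.
#' @slot salt character(1), identity of the varied salt (e.g. "NaCl").
#' @exportClass TurbiditySeries
setClass("TurbiditySeries",
  representation(ionicStrength = "numeric", a450 = "numeric",
                 salt = "character"),
  prototype(salt = "NaCl"))

setValidity("TurbiditySeries", function(object) {
  if (length(object@ionicStrength) != length(object@a450))
    return("condition and reading lengths differ")
  if (is.unsorted(object@ionicStrength))
    return("conditions must be sorted ascending")
  if (any(object@a450 < 0)) return("A450 must be non-negative")
  TRUE
})

#' TurbiditySeries constructor
#' @param ionicStrength ascending ionic strengths (M).
#' @param a450 absorbance at 450 nm per condition.
#' @param salt identity of the varied salt.
#' @return a [TurbiditySeries-class].
#' @export
TurbiditySeries <- function(ionicStrength, a450, salt = "NaCl") {
  new("TurbiditySeries", ionicStrength = as.numeric(ionicStrength),
      a450 = as.numeric(a450), salt = as.character(salt))
}
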