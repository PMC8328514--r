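#' Accessors for the core classes
#'
#' Simple extractor functions so user code never touches slots directly.
#'
#' @param x an object of the relevant class.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
elution <- function(x) x@elution

#' @rdname accessors
#' @export
absorbance <- function(x) x@absorbance

#' @rdname accessors
#' @export
isBaselineCorrected <- function(x) x@baselineCorrected

#' @rdname accessors
#' @export
sampleLabel <- function(x) if (.hasSlot(x, "label")) x@label else x@laneLabel

.hasSlot <- function(x, name) name %in% slotNames(class(x))

#' @rdname accessors
#' @export
peakTable <- function(x) x@peaks

#' @rdname accessors
#' @export
fitCovariance <- function(x) x@covariance

#' @rdname accessors
#' @export
rSquared <- function(x) x@rSquared

#' @rdname accessors
#' @export
speciesAreas <- function(x) x@areas

#' @rdname accessors
#' @export
speciesAssignment <- function(x) x@assignment

#' @rdname accessors
#' @export
dimerLevel <- function(x) {
  if (is(x, "BandQuant")) x@dimerLevel else x@dimerLevel
}

#' @rdname accessors
#' @export
hmwLevel <- function(x) x@hmwLevel

#' @rdname accessors
#' @export
totalLevel <- function(x) x@totalLevel

#' @rdname accessors
#' @export
levelCI95 <- function(x) x@ci95

#' @rdname accessors
#' @export
levelSE <- function(x) x@se

#' @rdname accessors
#' @export
bandAreas <- function(x) x@areas

#' @rdname accessors
#' @export
protomerSites <- function(x) x@sites

#' @rdname accessors
#' @export
protomerA <- function(x) x@protomerA

#' @rdname accessors
#' @export
protomerB <- function(x) x@protomerB

#' @rdname accessors
#' @export
contacts <- function(x) x@contacts

#' @rdname accessors
#' @export
interfaceClass <- function(x) x@classification

#' @rdname accessors
#' @export
interfaceTallies <- function(x) x@tallies

#' @rdname accessors
#' @export
clusters <- function(x) x@clusters

#' @rdname accessors
#' @export
representatives <- function(x) x@representatives

#' @rdname accessors
#' @export
meltTemperature <- function(x) x@temperature

#' @rdname accessors
#' @export
meltFluorescence <- function(x) x@fluorescence

#' @rdname accessors
#' @export
meltDerivativeValues <- function(x) x@derivative

setMethod("show", "Chromatogram", function(object) {
  cat("Chromatogram", if (nzchar(object@label)) sQuote(object@label) else "",
      "\n  ", length(object@elution), " points, elution ",
      format(min(object@elution)), "-", format(max(object@elution)),
      "\n  baseline corrected: ", object@baselineCorrected, "\n", sep = "")
})

setMethod("show", "PeakFit", function(object) {
  cat("PeakFit with", nrow(object@peaks), "Gaussian peak(s), R^2 =",
      format(object@rSquared, digits = 6), "\n")
  print(object@peaks, digits = 4)
})

setMethod("show", "SpeciesAssignment", function(object) {
  cat("SpeciesAssignment\n")
  for (sp in .SPECIES)
    cat(sprintf("  %-7s peaks {%s}  area %.4g\n", sp,
                paste(object@assignment[[sp]], collapse = ","),
                object@areas[[sp]]))
})

setMethod("show", "OligomerLevels", function(object) {
  cat(sprintf(
    "OligomerLevels%s\n  dimer %.3f +/- %.3f | HMW %.3f +/- %.3f | total %.3f +/- %.3f  (95%% CI)\n",
    if (nzchar(object@label)) paste0(" ", sQuote(object@label)) else "",
    object@dimerLevel, object@ci95[["dimer_level"]],
    object@hmwLevel, object@ci95[["hmw_level"]],
    object@totalLevel, object@ci95[["total_level"]]))
})

setMethod("show", "DimerConfiguration", function(object) {
  cat("DimerConfiguration frame", object@frameIndex, "with",
      length(unique(object@protomerA@sites$resid)), "residues per protomer",
      if (length(object@box)) paste0("(box ",
        paste(format(object@box), collapse = " x "), " A)") else "", "\n")
})

setMethod("show", "ContactSet", function(object) {
  tab <- table(object@contacts$type)
  cat("ContactSet frame", object@frameIndex, "-", nrow(object@contacts),
      "contact(s)",
      if (length(tab)) paste0("[", paste(names(tab), tab, sep = ":",
                                         collapse = ", "), "]"), "\n")
})

setMethod("show", "InterfaceCall", function(object) {
  cat("InterfaceCall:", object@classification, "\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", length(object@clusters), "cluster(s) at cutoff",
      object@rmsdCutoff, "A; sizes",
      paste(vapply(object@clusters, length, 1L), collapse = ", "), "\n")
})
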