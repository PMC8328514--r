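## Western-blot lane densitometry: background subtraction, band-window
## integration, and the monomer-equivalent dimer level of a lane.

#' Read a lane densitometry profile from CSV
#'
#' @param path two-column file (position, intensity), optional header.
#' @param ladderPath optional two-column file (position, kDa) of ladder
#'   calibration points, used for labeling only.
#' @param sep,dec delimiter and decimal mark.
#' @param laneLabel lane identifier; defaults to the file name.
#' @return a [LaneProfile-class].
#' @export
readLaneProfile <- function(path, ladderPath = NULL, sep = ",", dec = ".",
                            laneLabel = NULL) {
  if (!file.exists(path)) .condStop("ioError", paste("file not found:", path))
  tab <- .readNumericTable(path, sep = sep, dec = dec, minCols = 2)
  ladder <- data.frame(position = numeric(), kda = numeric())
  if (!is.null(ladderPath)) {
    lt <- .readNumericTable(ladderPath, sep = sep, dec = dec, minCols = 2)
    ladder <- data.frame(position = lt[[1]], kda = lt[[2]])
  }
  LaneProfile(tab[[1]], tab[[2]], ladder = ladder,
              laneLabel = laneLabel %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Subtract the background from a lane profile
#'
#' \code{linear} (default): a straight background through the median
#' intensity of the two lane ends (which carry no bands); exact for
#' constant or linearly drifting backgrounds.
#' \code{rolling-min}: morphological opening (rolling minimum then
#' maximum) of a lightly smoothed profile; use for curved backgrounds.
#' Its structuring element must be wider than the bands, and on tilted
#' backgrounds it can overestimate under a band by up to the background
#' slope times the window half-width.
#' Negative residuals are clipped to zero.
#'
#' @param profile a [LaneProfile-class].
#' @param method "linear" or "rolling-min".
#' @param windowFraction rolling-minimum window width as a fraction of the
#'   lane length (default 0.25).
#' @param ... unused.
#' @return a background-subtracted [LaneProfile-class].
#' @rdname subtractBackground
#' @export
setMethod("subtractBackground", "LaneProfile",
function(profile, method = c("linear", "rolling-min"),
         windowFraction = 0.25, ...) {
  method <- match.arg(method)
  x <- profile@position; y <- profile@intensity
  if (diff(range(y)) <= .Machine$double.eps * max(abs(y), 1))
    .condStop("degenerateInput", "constant (or all-zero) lane profile")
  n <- length(y)
  if (method == "rolling-min") {
    ## pre-smooth so the minimum filter tracks the background, not the
    ## noise floor; then morphological opening (erosion + dilation)
    ks <- 3L
    ys <- as.numeric(stats::filter(c(rep(y[1], ks), y, rep(y[n], ks)),
                                   rep(1 / (2 * ks + 1), 2 * ks + 1)))[
      (ks + 1):(ks + n)]
    hw <- max(1L, round(windowFraction * n / 2))
    ero <- vapply(seq_len(n), function(i)
      min(ys[max(1L, i - hw):min(n, i + hw)]), 1)
    bg <- vapply(seq_len(n), function(i)
      max(ero[max(1L, i - hw):min(n, i + hw)]), 1)
    k <- max(3L, hw %/% 4L)
    bg <- stats::filter(c(rep(bg[1], k), bg, rep(bg[n], k)),
                        rep(1 / (2 * k + 1), 2 * k + 1))
    bg <- as.numeric(bg[(k + 1):(k + n)])
  } else {
    nf <- max(3L, round(0.1 * n))
    ax <- c(median(x[seq_len(nf)]), median(x[seq(n - nf + 1L, n)]))
    ay <- c(median(y[seq_len(nf)]), median(y[seq(n - nf + 1L, n)]))
    bg <- ay[1] + (ay[2] - ay[1]) / (ax[2] - ax[1]) * (x - ax[1])
  }
  new("LaneProfile", position = x, intensity = pmax(y - bg, 0),
      laneLabel = profile@laneLabel, ladder = profile@ladder,
      backgroundSubtracted = TRUE)
})

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Quantify monomer and dimer bands in a lane profile
#'
#' Integrates the densitometric trace over user-supplied band windows by
#' the trapezoidal rule and expresses the dimer population relative to the
#' monomer (arbitrary units), the same monomer-equivalent convention used
#' for SEC peak areas.
#'
#' @param profile a background-subtracted [LaneProfile-class].
#' @param windows named list with \code{MONOMER = c(lo, hi)} and
#'   \code{DIMER = c(lo, hi)} position ranges; must not overlap and must
#'   lie within the profile.
#' @param ... unused.
#' @return a [BandQuant-class].
#' @rdname quantifyBands
#' @export
setMethod("quantifyBands", "LaneProfile",
function(profile, windows, ...) {
  if (!all(c("MONOMER", "DIMER") %in% names(windows)))
    .condStop("validationError", "windows must name MONOMER and DIMER")
  x <- profile@position; y <- profile@intensity
  for (w in windows)
    if (w[1] < min(x) || w[2] > max(x) || w[1] >= w[2])
      .condStop("validationError", "band window outside the profile range")
  wm <- windows$MONOMER; wd <- windows$DIMER
  if (max(wm[1], wd[1]) < min(wm[2], wd[2]))
    .condStop("validationError", "MONOMER and DIMER windows overlap")
  areaIn <- function(w) {
    keep <- x >= w[1] & x <= w[2]
    if (sum(keep) < 2) return(0)
    .trapz(x[keep], y[keep])
  }
  areas <- c(MONOMER = areaIn(wm), DIMER = areaIn(wd))
  if (areas[["MONOMER"]] <= 0)
    .condStop("undefinedRatio", "monomer band area is zero: dimer level undefined")
  new("BandQuant", windows = windows[c("MONOMER", "DIMER")], areas = areas,
      dimerLevel = areas[["DIMER"]] / areas[["MONOMER"]],
      laneLabel = profile@laneLabel)
})

#' Automatic band-window proposal
#'
#' Finds the two highest local maxima of the profile and proposes windows
#' of plus/minus \code{k} full-widths-at-half-maximum around each; the
#' later-migrating (larger position) band is labeled MONOMER, the earlier
#' one DIMER (dimers run at higher apparent molecular weight, nearer the
#' top of the lane).
#'
#' @param profile a [LaneProfile-class].
#' @param k window half-width in FWHM units (default 1.5).
#' @return a windows list suitable for [quantifyBands()].
#' @export
proposeBandWindows <- function(profile, k = 1.5) {
  x <- profile@position; y <- profile@intensity
  n <- length(y)
  ## smooth before peak picking so noise wiggles on a band top are not
  ## taken as bands of their own
  ks <- max(2L, round(0.01 * n))
  ys <- as.numeric(stats::filter(c(rep(y[1], ks), y, rep(y[n], ks)),
                                 rep(1 / (2 * ks + 1), 2 * ks + 1)))[
    (ks + 1):(ks + n)]
  imax <- which(diff(sign(diff(ys))) == -2) + 1L
  imax <- imax[ys[imax] > 0.05 * max(ys)]
  imax <- imax[order(ys[imax], decreasing = TRUE)]
  minSep <- 0.05 * diff(range(x))
  pick <- integer()
  for (i in imax)
    if (!length(pick) || all(abs(x[i] - x[pick]) > minSep)) pick <- c(pick, i)
  if (length(pick) < 2)
    .condStop("validationError", "fewer than two bands detected")
  imax <- pick[1:2]
  win <- lapply(imax, function(i) {
    half <- ys[i] / 2
    l <- i; while (l > 1L && ys[l] > half) l <- l - 1L
    r <- i; while (r < n && ys[r] > half) r <- r + 1L
    fwhm <- x[r] - x[l]
    c(max(min(x), x[i] - k * fwhm), min(max(x), x[i] + k * fwhm))
  })
  ord <- order(x[imax])  # earlier position = dimer
  w <- list(DIMER = win[[ord[1]]], MONOMER = win[[ord[2]]])
  ## trim any overlap at the midpoint between the bands
  mid <- mean(c(x[imax][ord[1]], x[imax][ord[2]]))
  w$DIMER[2] <- min(w$DIMER[2], mid)
  w$MONOMER[1] <- max(w$MONOMER[1], mid)
  w
}

#' Label lane positions with molecular weights from a ladder
#'
#' Monotone interpolation of log molecular weight against ladder position;
#' for annotation only, never used in quantification.
#'
#' @param profile a [LaneProfile-class] with ladder points.
#' @param positions positions to label.
#' @return numeric vector of apparent kDa.
#' @export
ladderKda <- function(profile, positions) {
  lad <- profile@ladder
  if (nrow(lad) < 2)
    .condStop("validationError", "need at least two ladder points")
  exp(approx(lad$position, log(lad$kda), xout = positions, rule = 2)$y)
}
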