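## Multi-Gaussian SEC deconvolution and monomer-equivalent oligomer levels.
##
## Species elute largest-first: HMW oligomer, then dimer, then monomer.
## Each level is the integrated Gaussian area of a species divided by the
## monomer area; uncertainties are propagated from the fit covariance by
## the delta method (fit variance only, not experimental replication).

.gaussSum <- function(x, par) {
  n <- length(par) / 3L
  y <- numeric(length(x))
  for (k in seq_len(n)) {
    A <- par[3 * k - 2]; mu <- par[3 * k - 1]; s <- par[3 * k]
    y <- y + A * exp(-((x - mu)^2) / (2 * s^2))
  }
  y
}

## analytic Jacobian of the Gaussian sum wrt (A, mu, sigma) per peak
.gaussJacobian <- function(x, par) {
  n <- length(par) / 3L
  J <- matrix(0, length(x), length(par))
  for (k in seq_len(n)) {
    A <- par[3 * k - 2]; mu <- par[3 * k - 1]; s <- par[3 * k]
    g <- exp(-((x - mu)^2) / (2 * s^2))
    J[, 3 * k - 2] <- g
    J[, 3 * k - 1] <- A * g * (x - mu) / s^2
    J[, 3 * k]     <- A * g * (x - mu)^2 / s^3
  }
  J
}

.condStop <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Read a chromatogram from a two-column delimited file
#'
#' Expects an elution column (mL or s) followed by an absorbance column,
#' with an optional single header line. Malformed rows are reported by line
#' number; a non-monotonic elution axis fails validation.
#'
#' @param path path to the file.
#' @param sep field delimiter (default comma).
#' @param dec decimal mark (default ".").
#' @param label sample label; defaults to the file name without extension.
#' @return a [Chromatogram-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' x <- seq(8, 16, length.out = 60)
#' write.csv(data.frame(volume = x, abs = dnorm(x, 12, 0.4)), f,
#'           row.names = FALSE)
#' readChromatogram(f)
#' @export
readChromatogram <- function(path, sep = ",", dec = ".", label = NULL) {
  if (!file.exists(path)) .condStop("ioError", paste("file not found:", path))
  tab <- .readNumericTable(path, sep = sep, dec = dec, minCols = 2)
  Chromatogram(tab[[1]], tab[[2]],
               label = label %||% sub("\\.[^.]*$", "", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## line-by-line numeric table reader so parse errors can name the offending
## line; tolerates one header line
.readNumericTable <- function(path, sep = ",", dec = ".", minCols = 2) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) .condStop("parseError", paste("empty file:", path))
  parseLine <- function(ln) {
    fields <- trimws(strsplit(ln, sep, fixed = TRUE)[[1]])
    if (dec != ".") fields <- gsub(dec, ".", fields, fixed = TRUE)
    suppressWarnings(as.numeric(fields))
  }
  first <- parseLine(lines[1])
  start <- if (any(is.na(first))) 2L else 1L
  rows <- vector("list", length(lines) - start + 1L)
  for (i in seq(start, length(lines))) {
    v <- parseLine(lines[i])
    if (length(v) < minCols || any(is.na(v[seq_len(minCols)])))
      .condStop("parseError",
                sprintf("malformed row at line %d of %s: '%s'", i, path,
                        lines[i]))
    rows[[i - start + 1L]] <- v[seq_len(minCols)]
  }
  m <- do.call(rbind, rows)
  as.data.frame(m)
}

#' Write a chromatogram to CSV
#' @param chrom a [Chromatogram-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeChromatogram <- function(chrom, path) {
  write.csv(data.frame(elution = chrom@elution,
                       absorbance = chrom@absorbance),
            path, row.names = FALSE)
  invisible(path)
}

#' Baseline-correct a chromatogram
#'
#' Default method fits a straight baseline anchored on a robust quantile
#' (default the median) of the signal in two flanking windows where no
#' peaks elute, and subtracts it; this is simple, auditable and preserves
#' peak areas. On a peak-free flank the median estimates the baseline
#' without bias, whereas a low quantile would systematically undershoot
#' by a multiple of the noise standard deviation and inflate broad-peak
#' areas. An iterative asymmetric-least-squares baseline (Eilers-style,
#' second-difference penalty) is available for drifting baselines that a
#' line cannot follow.
#'
#' @param chrom a [Chromatogram-class], not yet corrected (re-application
#'   is allowed with a warning and is a near-no-op).
#' @param method "linear" (default) or "als".
#' @param flankFraction fraction of points at each end of the trace treated
#'   as peak-free flank (linear method), default 0.05.
#' @param anchorQuantile quantile of the flank signal used as the baseline
#'   anchor (default 0.5; lower it when peaks bleed into the flanks).
#' @param lambda,p,nIter asymmetric-least-squares smoothness, asymmetry and
#'   iteration count (als method).
#' @param ... unused.
#' @return a corrected [Chromatogram-class] with
#'   \code{baselineCorrected = TRUE}.
#' @examples
#' x <- seq(8, 16, length.out = 200)
#' ch <- Chromatogram(x, dnorm(x, 12, 0.4) + 0.05)
#' correctBaseline(ch)
#' @rdname correctBaseline
#' @export
setMethod("correctBaseline", "Chromatogram",
function(chrom, method = c("linear", "als"), flankFraction = 0.05,
         anchorQuantile = 0.5, lambda = 1e5, p = 0.01, nIter = 10, ...) {
  method <- match.arg(method)
  x <- chrom@elution; y <- chrom@absorbance
  if (diff(range(y)) <= .Machine$double.eps * max(abs(y), 1))
    .condStop("degenerateInput",
              "constant (or all-zero) trace: no baseline to correct")
  if (chrom@baselineCorrected)
    warning("chromatogram is already baseline-corrected; re-applying")
  if (method == "linear") {
    nf <- max(3L, round(flankFraction * length(x)))
    li <- seq_len(nf); ri <- seq(length(x) - nf + 1L, length(x))
    ax <- c(median(x[li]), median(x[ri]))
    ay <- c(quantile(y[li], anchorQuantile, names = FALSE),
            quantile(y[ri], anchorQuantile, names = FALSE))
    slope <- (ay[2] - ay[1]) / (ax[2] - ax[1])
    base <- ay[1] + slope * (x - ax[1])
  } else {
    base <- .alsBaseline(y, lambda = lambda, p = p, nIter = nIter)
  }
  new("Chromatogram", elution = x, absorbance = y - base,
      label = chrom@label, baselineCorrected = TRUE)
})

## Eilers asymmetric least squares: sparse (I + lambda D'D) solve with
## asymmetric weights favouring points below the running baseline
.alsBaseline <- function(y, lambda = 1e5, p = 0.01, nIter = 10) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(nIter)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

#' Fit a sum of Gaussian peaks to a baseline-corrected chromatogram
#'
#' Least-squares deconvolution of an SEC trace into \code{nPeaks} Gaussian
#' components by Levenberg-Marquardt, analogous to interactive
#' nonlinear-Gaussian fitting in chromatography software. Initial centers
#' come from local maxima of a Savitzky-Golay-smoothed trace, amplitudes
#' from the trace height and widths from the half-width at half-maximum;
#' on failure the fit restarts up to 5 times with deterministically
#' jittered centers, so identical inputs always give identical fits.
#'
#' For low signal-to-noise traces, a manual window (sub-range of the
#' elution axis) and fixed peak widths can be imposed via \code{window},
#' mirroring the manual definition of integration ranges.
#'
#' @param chrom a baseline-corrected [Chromatogram-class].
#' @param nPeaks number of Gaussians, 1..6; \code{NULL} selects the count
#'   automatically by BIC (adding peaks while BIC improves, capped at 6).
#' @param init optional data.frame/list with \code{amplitude},
#'   \code{center}, \code{sigma} initial values.
#' @param window optional list with \code{range = c(lo, hi)} restricting
#'   the fitted elution range and/or \code{sigma} fixing peak widths
#'   (scalar or one per peak).
#' @param sharedWidth logical; constrain all peaks to one common width.
#' @param fitOffset logical; include free constant and slope baseline
#'   terms in the model (default TRUE), the baseline terms of interactive
#'   chromatography Gaussian fitting, which absorb residual baseline that
#'   would otherwise bias broad-peak areas.
#' @param maxRestarts bounded deterministic restarts on non-convergence.
#' @param ... unused.
#' @return a [PeakFit-class] with peaks sorted by center, the parameter
#'   covariance, and the coefficient of determination.
#' @examples
#' x <- seq(8, 16, by = 0.02)
#' ch <- Chromatogram(x, .75 * exp(-(x - 12)^2 / (2 * 0.4^2)),
#'                    baselineCorrected = TRUE)
#' fitPeaks(ch, nPeaks = 1)
#' @rdname fitPeaks
#' @export
setMethod("fitPeaks", "Chromatogram",
function(chrom, nPeaks = 3, init = NULL, window = NULL, sharedWidth = FALSE,
         fitOffset = TRUE, maxRestarts = 5, ...) {
  if (!chrom@baselineCorrected)
    .condStop("validationError", "fitPeaks requires a baseline-corrected chromatogram")
  x <- chrom@elution; y <- chrom@absorbance
  if (!is.null(window$range)) {
    keep <- x >= window$range[1] & x <= window$range[2]
    if (sum(keep) < 10)
      .condStop("validationError", "window contains fewer than 10 points")
    x <- x[keep]; y <- y[keep]
  }
  if (is.null(nPeaks)) return(.fitPeaksBIC(chrom, x, y, window, sharedWidth,
                                           fitOffset, maxRestarts))
  nPeaks <- as.integer(nPeaks)
  if (nPeaks < 1L || nPeaks > 6L)
    .condStop("validationError", "nPeaks must be between 1 and 6")

  guess <- if (is.null(init)) .initialGuess(x, y, nPeaks) else
    data.frame(amplitude = init$amplitude, center = init$center,
               sigma = init$sigma)
  if (nrow(guess) < nPeaks) {
    warning(sprintf(
      "only %d resolvable peak(s) detected; falling back to that count",
      nrow(guess)))
    nPeaks <- nrow(guess)
  }
  guess <- guess[seq_len(nPeaks), , drop = FALSE]

  fixedSigma <- NULL
  if (!is.null(window$sigma))
    fixedSigma <- rep_len(window$sigma, nPeaks)

  best <- NULL
  jitterSteps <- c(0, 0.5, -0.5, 1, -1, 1.5)
  for (r in seq_len(min(maxRestarts + 1L, length(jitterSteps)))) {
    g <- guess
    g$center <- g$center + jitterSteps[r] * g$sigma
    g$center <- pmin(pmax(g$center, min(x)), max(x))
    res <- .lmGaussFit(x, y, g, fixedSigma, sharedWidth, fitOffset)
    if (!is.null(res) && (is.null(best) || res$rss < best$rss)) best <- res
    if (!is.null(best) && best$converged) break
  }
  if (is.null(best))
    .condStop("fitFailure", "Gaussian fit failed on every restart")
  if (!best$converged)
    .condStop("fitFailure",
              sprintf("Gaussian fit did not converge (best residual sum of squares %.6g)",
                      best$rss))

  .buildPeakFit(x, y, best, chrom@label,
                window = if (is.null(window)) list() else window)
})

## locate initial peak candidates on a Savitzky-Golay smoothed trace
.initialGuess <- function(x, y, nPeaks) {
  n <- length(y)
  fl <- min(max(5L, 2L * (n %/% 40L) + 1L), if (n %% 2L) n else n - 1L)
  ys <- tryCatch(signal::sgolayfilt(y, p = 2, n = fl), error = function(e) y)
  isMax <- which(diff(sign(diff(ys))) == -2) + 1L
  thr <- 0.02 * max(ys)
  isMax <- isMax[ys[isMax] > thr]
  if (!length(isMax)) isMax <- which.max(ys)
  isMax <- isMax[order(ys[isMax], decreasing = TRUE)]
  ## greedy de-duplication: suppress maxima closer than ~2% of the range
  minSep <- 0.02 * diff(range(x))
  pick <- integer()
  for (i in isMax)
    if (!length(pick) || all(abs(x[i] - x[pick]) > minSep)) pick <- c(pick, i)
  pick <- head(pick, nPeaks)
  cent <- x[pick]; amp <- ys[pick]
  sig <- vapply(seq_along(pick), function(j) {
    half <- amp[j] / 2
    i <- pick[j]
    l <- i; while (l > 1L && ys[l] > half) l <- l - 1L
    r <- i; while (r < n && ys[r] > half) r <- r + 1L
    hwhm <- max((x[r] - x[l]) / 2, diff(range(x)) / (20 * nPeaks))
    hwhm / sqrt(2 * log(2))
  }, 1)
  d <- data.frame(amplitude = amp, center = cent, sigma = sig)
  d[order(d$center), , drop = FALSE]
}

## single Levenberg-Marquardt pass; returns NULL on hard failure. The model
## is sum-of-Gaussians plus an optional free constant offset (the y0 term
## of interactive chromatography Gaussian fits), which absorbs residual
## baseline so broad peaks do not.
.lmGaussFit <- function(x, y, guess, fixedSigma, sharedWidth,
                        fitOffset = TRUE) {
  n <- nrow(guess)
  rng <- range(x); span <- diff(rng)
  ymax <- max(abs(y))
  if (!is.null(fixedSigma)) {
    ## free parameters: A, mu per peak
    pack <- function(p) {  # -> full (A, mu, s) vector
      full <- numeric(3 * n)
      full[seq(1, 3 * n, 3)] <- p[seq(1, 2 * n, 2)]
      full[seq(2, 3 * n, 3)] <- p[seq(2, 2 * n, 2)]
      full[seq(3, 3 * n, 3)] <- fixedSigma
      full
    }
    p0 <- as.numeric(rbind(guess$amplitude, guess$center))
    lower <- rep(c(0, rng[1]), n); upper <- rep(c(10 * ymax, rng[2]), n)
  } else if (sharedWidth) {
    pack <- function(p) {
      s <- p[2 * n + 1]
      as.numeric(rbind(p[seq(1, 2 * n, 2)], p[seq(2, 2 * n, 2)], rep(s, n)))
    }
    p0 <- c(as.numeric(rbind(guess$amplitude, guess$center)),
            median(guess$sigma))
    lower <- c(rep(c(0, rng[1]), n), span / 1e4)
    upper <- c(rep(c(10 * ymax, rng[2]), n), span)
  } else {
    pack <- identity
    p0 <- as.numeric(rbind(guess$amplitude, guess$center, guess$sigma))
    lower <- rep(c(0, rng[1], span / 1e4), n)
    upper <- rep(c(10 * ymax, rng[2], span), n)
  }
  xbar <- mean(x)
  if (fitOffset) {
    ## free constant + slope baseline terms, centred for conditioning
    p0 <- c(p0, 0, 0)
    lower <- c(lower, -ymax, -ymax / span)
    upper <- c(upper, ymax, ymax / span)
  }
  resid <- function(p) {
    k <- length(p)
    base <- if (fitOffset) p[k - 1] + p[k] * (x - xbar) else 0
    q <- if (fitOffset) p[seq_len(k - 2)] else p
    y - .gaussSum(x, pack(q)) - base
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, lower = lower, upper = upper, fn = resid,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  k <- length(fit$par)
  off <- if (fitOffset) fit$par[c(k - 1, k)] else c(0, 0)
  par <- pack(if (fitOffset) fit$par[seq_len(k - 2)] else fit$par)
  list(par = par, offset = off[1], slope = off[2], xbar = xbar,
       rss = sum(resid(fit$par)^2),
       converged = fit$info %in% 1:4,
       fixedSigma = fixedSigma, sharedWidth = sharedWidth,
       fitOffset = fitOffset, n = n)
}

## assemble a PeakFit: sort peaks by center, reorder covariance blocks
.buildPeakFit <- function(x, y, best, label, window) {
  par <- best$par; n <- best$n
  A <- par[seq(1, 3 * n, 3)]; mu <- par[seq(2, 3 * n, 3)]
  s <- par[seq(3, 3 * n, 3)]
  rss <- best$rss
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1

  J <- .gaussJacobian(x, par)
  if (!is.null(best$fixedSigma)) J[, seq(3, 3 * n, 3)] <- 0
  if (isTRUE(best$fitOffset)) J <- cbind(J, 1, x - best$xbar)
  dof <- max(length(y) - sum(colSums(abs(J)) > 0), 1)
  sigma2 <- rss / dof
  JtJ <- crossprod(J)
  V <- tryCatch(sigma2 * solve(JtJ), error = function(e) {
    ## rank-deficient (e.g. fixed widths): Moore-Penrose fallback
    sv <- svd(JtJ)
    pos <- sv$d > max(sv$d) * 1e-12
    sigma2 * sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  })
  V <- (V + t(V)) / 2
  ## marginalize out the baseline terms: species areas do not depend on them
  if (isTRUE(best$fitOffset)) V <- V[seq_len(3 * n), seq_len(3 * n),
                                     drop = FALSE]

  ord <- order(mu)
  perm <- as.integer(t(outer(3 * (ord - 1), 1:3, `+`)))
  V <- V[perm, perm, drop = FALSE]
  peaks <- data.frame(amplitude = A[ord], center = mu[ord], sigma = s[ord],
                      area = A[ord] * s[ord] * sqrt(2 * pi))
  new("PeakFit", peaks = peaks, covariance = V, rSquared = r2,
      window = window, offset = c(best$offset %||% 0, best$slope %||% 0),
      label = label)
}

## automatic peak-count selection: add peaks while BIC improves
.fitPeaksBIC <- function(chrom, x, y, window, sharedWidth, fitOffset,
                         maxRestarts) {
  bestFit <- NULL; bestBIC <- Inf
  for (k in 1:6) {
    f <- tryCatch(
      fitPeaks(chrom, nPeaks = k, window = window, sharedWidth = sharedWidth,
               fitOffset = fitOffset, maxRestarts = maxRestarts),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(f)) next
    rss <- sum((y - f@offset[1] - f@offset[2] * (x - mean(x)) -
                  .gaussSum(x, as.numeric(t(
                    f@peaks[, c("amplitude", "center", "sigma")]))))^2)
    bic <- length(y) * log(max(rss, 1e-300) / length(y)) +
      3 * k * log(length(y))
    if (bic < bestBIC) { bestBIC <- bic; bestFit <- f } else break
  }
  if (is.null(bestFit)) .condStop("fitFailure", "no peak count converged")
  bestFit
}

#' Map fitted peaks onto oligomeric species
#'
#' Under the default ordinal policy, peaks are assigned in elution order:
#' the last-eluting peak is the monomer, the previous one the dimer, and
#' all earlier peaks pool into the HMW oligomer (a broad HMW feature is
#' routinely fitted with two Gaussians). Under the window policy, each
#' species owns a calibrated elution range and peaks are assigned by
#' center; a peak whose center falls in two overlapping windows is an
#' error, and one falling in no window is flagged unassigned. Single-peak
#' fits require the window policy (the ordinal rule cannot tell which
#' species the peak is).
#'
#' @param fit a [PeakFit-class].
#' @param policy "ordinal" (default) or "window".
#' @param windows for the window policy: named list
#'   (HMW/DIMER/MONOMER -> c(lo, hi)) of elution ranges.
#' @param ... unused.
#' @return a [SpeciesAssignment-class] carrying pooled species areas and
#'   their covariance propagated from the fit.
#' @rdname assignSpecies
#' @export
setMethod("assignSpecies", "PeakFit",
function(fit, policy = c("ordinal", "window"), windows = NULL, ...) {
  policy <- match.arg(policy)
  p <- fit@peaks
  n <- nrow(p)
  asn <- list(HMW = integer(), DIMER = integer(), MONOMER = integer())
  unassigned <- integer()
  if (policy == "ordinal") {
    if (n < 2)
      .condStop("validationError",
                "ordinal policy needs >= 2 peaks; use the window policy for single-peak traces")
    asn$MONOMER <- n
    asn$DIMER <- n - 1L
    if (n > 2) asn$HMW <- seq_len(n - 2L)
  } else {
    if (is.null(windows) || !all(names(windows) %in% .SPECIES))
      .condStop("validationError",
                "window policy needs windows named HMW/DIMER/MONOMER")
    for (i in seq_len(n)) {
      hits <- names(windows)[vapply(windows, function(w)
        p$center[i] >= w[1] && p$center[i] <= w[2], NA)]
      if (length(hits) > 1)
        .condStop("validationError", sprintf(
          "peak %d (center %.4g) straddles windows: %s", i, p$center[i],
          paste(hits, collapse = ", ")))
      if (length(hits) == 1) asn[[hits]] <- c(asn[[hits]], i)
      else unassigned <- c(unassigned, i)
    }
  }
  ## pooled species areas and their covariance via the area gradients
  V <- fit@covariance
  G <- matrix(0, 3, 3 * n, dimnames = list(.SPECIES, NULL))
  areas <- setNames(numeric(3), .SPECIES)
  for (sp in .SPECIES) {
    for (i in asn[[sp]]) {
      A <- p$amplitude[i]; s <- p$sigma[i]
      areas[sp] <- areas[sp] + A * s * sqrt(2 * pi)
      G[sp, 3 * i - 2] <- G[sp, 3 * i - 2] + s * sqrt(2 * pi)
      G[sp, 3 * i]     <- G[sp, 3 * i]     + A * sqrt(2 * pi)
    }
  }
  areaCov <- G %*% V %*% t(G)
  new("SpeciesAssignment", assignment = asn,
      unassigned = as.integer(unassigned), areas = areas,
      areaCov = areaCov, label = fit@label)
})

#' Compute monomer-equivalent oligomer levels
#'
#' \code{dimer_level = dimer area / monomer area},
#' \code{hmw_level = HMW area / monomer area},
#' \code{total_level} their sum. Standard errors are delta-method
#' propagations of the pooled-area covariance; 95% confidence half-widths
#' use the normal quantile. The levels are invariant under uniform
#' rescaling of the absorbance axis.
#'
#' @param assignment a [SpeciesAssignment-class].
#' @param ... unused.
#' @return an [OligomerLevels-class].
#' @rdname computeLevels
#' @export
setMethod("computeLevels", "SpeciesAssignment",
function(assignment, ...) {
  a <- assignment@areas; V <- assignment@areaCov
  aH <- a[["HMW"]]; aD <- a[["DIMER"]]; aM <- a[["MONOMER"]]
  if (!is.finite(aM) || aM <= 0)
    .condStop("undefinedRatio",
              "monomer area is zero or absent: oligomer levels are undefined")
  rd <- aD / aM; rh <- aH / aM
  grads <- rbind(
    dimer_level = c(0,       1 / aM, -aD / aM^2),
    hmw_level   = c(1 / aM,  0,      -aH / aM^2),
    total_level = c(1 / aM,  1 / aM, -(aD + aH) / aM^2))
  se <- sqrt(pmax(diag(grads %*% V %*% t(grads)), 0))
  names(se) <- rownames(grads)
  ci <- qnorm(0.975) * se
  new("OligomerLevels", dimerLevel = rd, hmwLevel = rh, totalLevel = rd + rh,
      se = se, ci95 = ci, label = assignment@label)
})

#' Convenience wrapper: chromatogram to oligomer levels
#'
#' Runs baseline correction (unless already done), peak fitting, species
#' assignment and level computation in one call.
#'
#' @param chrom a [Chromatogram-class].
#' @param nPeaks number of Gaussians (NULL for BIC selection).
#' @param policy,windows species-assignment policy, see [assignSpecies()].
#' @param baselineMethod passed to [correctBaseline()].
#' @param ... passed to [fitPeaks()].
#' @return a list with elements \code{chromatogram} (corrected),
#'   \code{fit}, \code{assignment}, \code{levels}.
#' @export
secLevels <- function(chrom, nPeaks = 3, policy = "ordinal", windows = NULL,
                      baselineMethod = "linear", ...) {
  if (!chrom@baselineCorrected)
    chrom <- correctBaseline(chrom, method = baselineMethod)
  fit <- fitPeaks(chrom, nPeaks = nPeaks, ...)
  asn <- assignSpecies(fit, policy = policy, windows = windows)
  list(chromatogram = chrom, fit = fit, assignment = asn,
       levels = computeLevels(asn))
}
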