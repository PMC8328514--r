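## Seeded synthetic-data generators. Every generator is a pure function of
## (seed, parameters) and returns both the data object and a ground-truth
## manifest sufficient to recompute the expected analysis result.
##
## Defaults emulate the study conditions: SEC traces carry HMW, dimer and
## monomer Gaussians in elution order with areas giving a wild-type-like
## dimer level of 1.14 (total 1.34); lanes carry dimer and monomer bands;
## dimer configurations are labeled point scaffolds (ideal helices for TM
## regions, a confined random chain for the C-terminus) with planted
## contacts; melt curves are sigmoids with an optional aggregation quench.

## run expr with a private RNG stream; global .Random.seed is untouched
.withSeed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = env)
    else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic SEC chromatogram with known peak areas
#'
#' The trace is a sum of Gaussian elution peaks over a linear baseline
#' with additive i.i.d. Gaussian noise. Signal-to-noise is defined as the
#' smallest planted peak amplitude over the noise standard deviation (the
#' weakest peak is what limits deconvolution, so a trace "at SNR 50"
#' guarantees every species is recoverable at that quality). Default peaks
#' emulate a full-length wild-type receptor trace: HMW oligomer, dimer and
#' monomer eluting in that order with areas 0.20, 1.14 and 1.00
#' (monomer-equivalent dimer level 1.14, total level 1.34).
#'
#' @param seed integer RNG seed.
#' @param peaks data.frame(amplitude, center, sigma) ordered HMW < dimer <
#'   monomer along the elution axis; or use \code{areas} to specify areas
#'   directly.
#' @param areas optional named numeric (HMW, DIMER, MONOMER) of target
#'   areas; converted to amplitudes at the default centers/sigmas
#'   (HMW 9.8/0.50, dimer 11.8/0.35, monomer 13.5/0.35 mL). A zero area
#'   drops the species.
#' @param baseline c(intercept, slope) of the linear baseline (default
#'   c(0.02, 0.003)).
#' @param snr signal-to-noise ratio (default 50); \code{Inf} for a
#'   noiseless trace.
#' @param elutionRange c(lo, hi) in mL, default c(8, 16).
#' @param nPoints trace length, default 600.
#' @param label sample label.
#' @return list(chromatogram, truth) where truth records peaks, per-species
#'   areas, implied levels, baseline and noise.
#' @examples
#' g <- genChromatogram(1)
#' g$truth$levels
#' @export
genChromatogram <- function(seed, peaks = NULL, areas = NULL,
                            baseline = c(0.02, 0.003), snr = 50,
                            elutionRange = c(8, 16), nPoints = 600,
                            label = "synthetic") {
  if (is.null(peaks)) {
    if (is.null(areas)) areas <- c(HMW = 0.20, DIMER = 1.14, MONOMER = 1.00)
    def <- data.frame(species = c("HMW", "DIMER", "MONOMER"),
                      center = c(9.8, 11.8, 13.5),
                      sigma = c(0.50, 0.35, 0.35))
    def$area <- as.numeric(areas[def$species])
    def <- def[def$area > 0, , drop = FALSE]
    peaks <- data.frame(amplitude = def$area / (def$sigma * sqrt(2 * pi)),
                        center = def$center, sigma = def$sigma)
  }
  peaks <- peaks[order(peaks$center), , drop = FALSE]
  if (anyDuplicated(peaks$center))
    .condStop("validationError", "peak centers must be distinct")
  x <- seq(elutionRange[1], elutionRange[2], length.out = nPoints)
  par <- as.numeric(t(peaks[, c("amplitude", "center", "sigma")]))
  signal <- .gaussSum(x, par)
  base <- baseline[1] + baseline[2] * (x - x[1])
  noiseSd <- if (is.finite(snr)) min(peaks$amplitude) / snr else 0
  y <- .withSeed(seed, signal + base + rnorm(length(x), 0, noiseSd))
  pkArea <- peaks$amplitude * peaks$sigma * sqrt(2 * pi)
  n <- nrow(peaks)
  species <- c(rep("HMW", max(0, n - 2)),
               if (n >= 2) "DIMER", "MONOMER")[seq_len(n)]
  areasOut <- vapply(.SPECIES, function(sp) sum(pkArea[species == sp]), 1)
  lv <- c(dimer_level = unname(areasOut["DIMER"] / areasOut["MONOMER"]),
          hmw_level = unname(areasOut["HMW"] / areasOut["MONOMER"]))
  lv["total_level"] <- lv["dimer_level"] + lv["hmw_level"]
  list(chromatogram = Chromatogram(x, y, label = label),
       truth = list(peaks = cbind(peaks, area = pkArea, species = species),
                    areas = areasOut, levels = lv, baseline = baseline,
                    noiseSd = noiseSd, seed = seed))
}

#' Generate a synthetic lane densitometry profile
#'
#' Gaussian dimer and monomer bands (dimer migrating higher, i.e. at a
#' smaller position) over an optional linear background with additive
#' noise. Default band areas emulate a wild-type blot lane before
#' reduction: dimer 1.14, monomer 1.00.
#'
#' @param seed integer RNG seed.
#' @param bands data.frame(species, center, sigma, area); default dimer at
#'   30 mm and monomer at 60 mm, width 3 mm.
#' @param background c(intercept, slope).
#' @param noiseSd additive noise standard deviation (default 0.002).
#' @param positionRange,nPoints lane geometry.
#' @return list(profile, truth).
#' @export
genLaneProfile <- function(seed,
                           bands = data.frame(
                             species = c("DIMER", "MONOMER"),
                             center = c(30, 60), sigma = c(3, 3),
                             area = c(1.14, 1.00)),
                           background = c(0.01, 0), noiseSd = 0.002,
                           positionRange = c(0, 100), nPoints = 500) {
  x <- seq(positionRange[1], positionRange[2], length.out = nPoints)
  amp <- bands$area / (bands$sigma * sqrt(2 * pi))
  y <- rep(0, nPoints)
  for (i in seq_len(nrow(bands)))
    y <- y + amp[i] * exp(-((x - bands$center[i])^2) / (2 * bands$sigma[i]^2))
  y <- y + background[1] + background[2] * (x - x[1])
  y <- .withSeed(seed, y + rnorm(nPoints, 0, noiseSd))
  areas <- setNames(bands$area, bands$species)
  dl <- if ("MONOMER" %in% bands$species && areas[["MONOMER"]] > 0 &&
            "DIMER" %in% bands$species)
    areas[["DIMER"]] / areas[["MONOMER"]] else NA_real_
  windows <- lapply(seq_len(nrow(bands)), function(i)
    c(bands$center[i] - 4 * bands$sigma[i], bands$center[i] + 4 * bands$sigma[i]))
  names(windows) <- bands$species
  list(profile = LaneProfile(x, pmax(y, 0), laneLabel = "synthetic"),
       truth = list(bands = bands, areas = areas, dimer_level = unname(dl),
                    windows = windows, background = background,
                    noiseSd = noiseSd, seed = seed))
}

## ideal alpha-helix backbone coordinates: radius 2.3 A, rise 1.5 A per
## residue, 100 degrees per residue, axis tilted from +z by tiltDeg about y
.idealHelix <- function(n, origin, tiltDeg = 0) {
  i <- seq_len(n) - 1
  local <- cbind(2.3 * cos(i * 100 * pi / 180),
                 2.3 * sin(i * 100 * pi / 180),
                 1.5 * i)
  th <- tiltDeg * pi / 180
  rot <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
                byrow = TRUE)
  sweep(local %*% t(rot), 2, origin, "+")
}

## default residue schema for synthetic protomers
.protomerSchema <- function(helixLength, ctermLength, ctermStart) {
  regions <- c(paste0("TM", 1:7), "ICL2", "ICL3", "ECL2")
  lens <- c(rep(helixLength, 7), 4, 4, 4)
  resid <- integer(); region <- character()
  nxt <- 1L
  for (k in seq_along(regions)) {
    resid <- c(resid, seq(nxt, nxt + lens[k] - 1L))
    region <- c(region, rep(regions[k], lens[k]))
    nxt <- nxt + lens[k]
  }
  resid <- c(resid, seq(ctermStart, ctermStart + ctermLength - 1L))
  region <- c(region, rep("CTERM", ctermLength))
  data.frame(resid = resid, region = region)
}

#' Generate a synthetic dimer configuration series with planted contacts
#'
#' Builds two labeled point-scaffold protomers (ideal helices for the TM
#' regions, clustered loop sites, a confined random chain for the
#' C-terminus) separated across an interface plane, then plants the
#' requested cross-protomer site pairs at their target distances in the
#' interface region. All non-planted cross-protomer site pairs are
#' guaranteed to lie beyond every contact cutoff plus a 1 Angstrom margin.
#' Only geometric predicates are under test, so the scaffolds are not
#' physically plausible receptors.
#'
#' Plan \code{type} values: \code{electrostatic} (opposite charges),
#' \code{samecharge} (like charges - never a contact),
#' \code{hbond} (donor with explicit hydrogen; \code{angleDev} degrees off
#' linear, default 0), \code{nonpolar}.
#'
#' @param seed integer RNG seed.
#' @param plan data.frame(residA, residB, type, distance, angleDev);
#'   default plants a symmetric C-terminal interface with 4 electrostatic
#'   contacts, 2 hydrogen bonds and 3 non-polar contacts.
#' @param topology "symmetric" (planted pairs are CTERM on both protomers)
#'   or "asymmetric" (CTERM of A against ICL3/ICL2 of B).
#' @param tilt named numeric of helix tilt angles in degrees, default
#'   c(TM7 = 10).
#' @param nFrames number of frames (each frame adds i.i.d. positional
#'   noise of \code{noiseSd} to the base coordinates).
#' @param noiseSd positional noise per frame, Angstrom (default 0.05).
#' @param helixLength,ctermLength,ctermStart schema dimensions.
#' @param box optional numeric(3) periodic box.
#' @return list(frames = list of [DimerConfiguration-class], truth).
#' @export
genDimerConfiguration <- function(seed, plan = NULL,
                                  topology = c("symmetric", "asymmetric"),
                                  tilt = c(TM7 = 10), nFrames = 1,
                                  noiseSd = 0.05, helixLength = 18,
                                  ctermLength = 24, ctermStart = 291,
                                  box = numeric()) {
  topology <- match.arg(topology)
  schema <- .protomerSchema(helixLength, ctermLength, ctermStart)
  ctermIds <- schema$resid[schema$region == "CTERM"]
  loopIds <- schema$resid[schema$region %in% c("ICL3", "ICL2", "ECL2")]
  if (is.null(plan)) {
    bIds <- if (topology == "symmetric") ctermIds else loopIds
    nPlant <- 9
    if (length(bIds) < nPlant)
      .condStop("validationError", "schema too small for the default plan")
    plan <- data.frame(
      residA = ctermIds[seq_len(nPlant)],
      residB = rev(bIds)[seq_len(nPlant)],
      type = c(rep("electrostatic", 4), rep("hbond", 2), rep("nonpolar", 3)),
      distance = c(3.5, 4.0, 4.5, 4.8, 2.9, 3.2, 4.0, 4.4, 4.8),
      angleDev = c(rep(NA, 4), 0, 5, rep(NA, 3)))
  }
  if (is.null(plan$angleDev)) plan$angleDev <- NA_real_
  if (anyDuplicated(plan$residA) || anyDuplicated(plan$residB))
    .condStop("generationError",
              "infeasible plan: a residue is required at two planted distances")
  if (!all(plan$residA %in% schema$resid) || !all(plan$residB %in% schema$resid))
    .condStop("validationError", "plan references residues outside the schema")

  .withSeed(seed, {
    buildProtomer <- function(side) {
      sgn <- if (side == "A") -1 else 1
      s <- schema
      s$class <- ifelse(grepl("^TM", s$region), "backbone", "nonpolar")
      s$x <- NA_real_; s$y <- NA_real_; s$z <- NA_real_
      ## TM bundle on a circle of radius 12 A around (sgn*40, 0, 0)
      for (k in 1:7) {
        hx <- paste0("TM", k)
        ang <- 2 * pi * (k - 1) / 7
        org <- c(sgn * 40 + 12 * cos(ang), 12 * sin(ang), 0)
        td <- if (hx %in% names(tilt)) tilt[[hx]] else 0
        xyz <- .idealHelix(helixLength, org, tiltDeg = td)
        s[s$region == hx, c("x", "y", "z")] <- xyz
      }
      ## loops clustered below the bundle
      for (lp in c("ICL2", "ICL3", "ECL2")) {
        idx <- which(s$region == lp)
        zoff <- if (lp == "ECL2") 16 else -6
        s[idx, c("x", "y", "z")] <-
          cbind(sgn * 40 + runif(length(idx), -3, 3),
                runif(length(idx), -3, 3), zoff + runif(length(idx), -2, 2))
      }
      ## C-terminus: confined random chain on the intracellular side
      idx <- which(s$region == "CTERM")
      pos <- c(sgn * 40, 0, -10)
      for (i in idx) {
        step <- rnorm(3); step <- 3.5 * step / sqrt(sum(step^2))
        cand <- pos + step
        ## reflect back into a 8 A-radius slab around the protomer core
        cand[1] <- sgn * 40 + max(min(cand[1] - sgn * 40, 8), -8)
        cand[2] <- max(min(cand[2], 10), -10)
        cand[3] <- max(min(cand[3], -6), -20)
        s[i, c("x", "y", "z")] <- cand
        pos <- cand
      }
      s
    }
    sa <- buildProtomer("A")
    sb <- buildProtomer("B")

    ## plant the interface: row j sits at y = 9*(j-1), z = -12
    for (j in seq_len(nrow(plan))) {
      pr <- plan[j, ]
      anchor <- c(0, 9 * (j - 1) - 4.5 * (nrow(plan) - 1), -12)
      ia <- which(sa$resid == pr$residA)[1]
      ib <- which(sb$resid == pr$residB)[1]
      pa <- anchor + c(-pr$distance / 2, 0, 0)
      pb <- anchor + c(+pr$distance / 2, 0, 0)
      sa[ia, c("x", "y", "z")] <- pa
      sb[ib, c("x", "y", "z")] <- pb
      cls <- switch(pr$type,
        electrostatic = c("charged+", "charged-"),
        samecharge = c("charged+", "charged+"),
        hbond = c("polar-donor", "polar-acceptor"),
        nonpolar = c("nonpolar", "nonpolar"),
        .condStop("validationError", paste("unknown plan type", pr$type)))
      sa$class[ia] <- cls[1]; sb$class[ib] <- cls[2]
      if (pr$type == "hbond") {
        dev <- if (is.na(pr$angleDev)) 0 else pr$angleDev
        u <- c(1, 0, 0)                      # donor -> interface direction
        h <- pa + u                          # H 1 A from donor
        delta <- dev * pi / 180
        v <- c(cos(delta), sin(delta), 0)    # H -> acceptor direction
        dd <- -cos(delta) + sqrt(cos(delta)^2 - 1 + pr$distance^2)
        sb[ib, c("x", "y", "z")] <- h + dd * v
        sa[ia, c("hx", "hy", "hz")] <- h
      }
    }
    for (h in c("hx", "hy", "hz")) {
      if (is.null(sa[[h]])) sa[[h]] <- NA_real_
      if (is.null(sb[[h]])) sb[[h]] <- NA_real_
    }
    sa$resname <- "GLY"; sb$resname <- "GLY"; sa$site <- "S"; sb$site <- "S"

    frames <- lapply(seq_len(nFrames), function(f) {
      ## i.i.d. site noise, except that each planted pair (and any attached
      ## hydrogen) translates rigidly, so planted distances and angles are
      ## realized exactly in every frame
      offA <- matrix(rnorm(3 * nrow(sa), 0, noiseSd), ncol = 3)
      offB <- matrix(rnorm(3 * nrow(sb), 0, noiseSd), ncol = 3)
      for (j in seq_len(nrow(plan))) {
        ia <- which(sa$resid == plan$residA[j])[1]
        ib <- which(sb$resid == plan$residB[j])[1]
        offB[ib, ] <- offA[ia, ]
      }
      jit <- function(s, off) {
        s[, c("x", "y", "z")] <- s[, c("x", "y", "z")] + off
        hok <- is.finite(s$hx)
        s[hok, c("hx", "hy", "hz")] <- s[hok, c("hx", "hy", "hz")] +
          off[hok, , drop = FALSE]
        s
      }
      DimerConfiguration(ProtomerModel(jit(sa, offA), ctermStart = ctermStart),
                         ProtomerModel(jit(sb, offB), ctermStart = ctermStart),
                         frameIndex = f, box = box)
    })
    expected <- table(factor(
      plan$type[(plan$type != "samecharge") &
                  !(plan$type == "hbond" & !is.na(plan$angleDev) &
                      plan$angleDev > 20)],
      levels = c("electrostatic", "hbond", "nonpolar")))
    list(frames = frames,
         truth = list(plan = plan, topology = topology, tilt = tilt,
                      expectedContacts = c(expected), noiseSd = noiseSd,
                      ctermStart = ctermStart, seed = seed))
  })
}

#' Generate a synthetic DSF melt curve
#'
#' Rising sigmoid with inflection at \code{tm}; when \code{quenchT} is
#' given (must exceed \code{tm}), the signal above it collapses
#' exponentially toward baseline, emulating the abrupt fluorescence quench
#' when the unfolded protein aggregates. Temperature ramp defaults follow
#' common DSF practice (20 to 85 C read every 0.25 C).
#'
#' @param seed integer RNG seed.
#' @param tm melting temperature, C (default 50).
#' @param quenchT quench onset, C, or NA for none.
#' @param amplitude,width,baselineF sigmoid amplitude, transition width
#'   (C) and pre-transition fluorescence.
#' @param tau post-quench collapse constant, C (default 1.5).
#' @param noiseSd additive noise (default 0.002).
#' @param tRange,dT temperature grid.
#' @return list(curve = [MeltCurve-class], truth).
#' @export
genMeltCurve <- function(seed, tm = 50, quenchT = NA, amplitude = 1,
                         width = 2, baselineF = 0.05, tau = 1.5,
                         noiseSd = 0.002, tRange = c(20, 85), dT = 0.25) {
  if (!is.na(quenchT) && quenchT <= tm)
    .condStop("validationError", "quenchT must exceed tm")
  tt <- seq(tRange[1], tRange[2], by = dT)
  f <- baselineF + amplitude / (1 + exp(-(tt - tm) / width))
  if (!is.na(quenchT)) {
    post <- tt >= quenchT
    f[post] <- baselineF + (f[post] - baselineF) *
      exp(-(tt[post] - quenchT) / tau)
  }
  f <- .withSeed(seed, f + rnorm(length(tt), 0, noiseSd))
  list(curve = MeltCurve(tt, f),
       truth = list(tm = tm, quenchT = quenchT, amplitude = amplitude,
                    width = width, noiseSd = noiseSd, seed = seed))
}

#' Generate a synthetic turbidity series
#'
#' A450 stays at a soluble baseline, rises to a slight-aggregation plateau
#' over \code{slightRange}, and steps to a high aggregated level above
#' \code{stepAt} (default 1 M, the NaCl concentration above which the
#' C-terminal peptide precipitates).
#'
#' @param seed integer RNG seed.
#' @param conditions ionic strengths, M.
#' @param stepAt aggregation step location, M.
#' @param slightRange c(lo, hi) of the slight-aggregation window, M.
#' @param levels named numeric c(soluble, slight, aggregated) A450 levels.
#' @param noiseSd additive noise.
#' @param salt salt identity.
#' @return list(series = [TurbiditySeries-class], truth).
#' @export
genTurbiditySeries <- function(seed, conditions = seq(0, 4, by = 0.25),
                               stepAt = 1.0, slightRange = c(0.25, 0.5),
                               levels = c(soluble = 0.01, slight = 0.1,
                                          aggregated = 0.6),
                               noiseSd = 0.003, salt = "NaCl") {
  a <- ifelse(conditions > stepAt, levels[["aggregated"]],
              ifelse(conditions >= slightRange[1] &
                       conditions <= slightRange[2],
                     levels[["slight"]], levels[["soluble"]]))
  a <- .withSeed(seed, pmax(a + rnorm(length(a), 0, noiseSd), 0))
  list(series = TurbiditySeries(sort(conditions), a[order(conditions)],
                                salt = salt),
       truth = list(stepAt = stepAt, slightRange = slightRange,
                    levels = levels, noiseSd = noiseSd, seed = seed))
}
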