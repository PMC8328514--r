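## Structure-file and report I/O, plus the three pipeline entry points
## (SEC levels, interface report, solution report). Reports carry a
## machine-readable provenance block (package version, config hash, seed)
## and contain no timestamps, so identical inputs give byte-identical
## output files.

## FNV-1a 32-bit hash of a deparsed R object, for provenance blocks
.configHash <- function(x) {
  s <- paste(deparse(x), collapse = " ")
  h <- 2166136261
  mulmod32 <- function(a, b) {
    lo <- a %% 65536; hi <- a %/% 65536
    (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
  }
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483648), ch) +
      (if (h >= 2147483648) 2147483648 else 0)
    h <- mulmod32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.provenance <- function(config, seed = NULL) {
  list(package = "receptorOligo",
       version = as.character(utils::packageVersion("receptorOligo")),
       config_hash = .configHash(config),
       seed = if (is.null(seed)) NA else seed)
}

#' Write a dimer frame series as a multi-model PDB with an annotation table
#'
#' Each protomer becomes one chain (A, B); each residue's interaction site
#' is written as atom \code{CA} and, when a hydrogen position is attached
#' (donor residues), as an additional atom \code{H}. Region and class
#' labels go into a side-car annotation CSV (chain, resid, region, class). Coordinates are written at PDB precision (1e-3 A).
#'
#' @param frames list of [DimerConfiguration-class] (one site per residue).
#' @param pdbPath output PDB path.
#' @param annotationPath output annotation CSV path.
#' @return invisibly, \code{pdbPath}.
#' @export
writeDimerFrames <- function(frames, pdbPath, annotationPath) {
  f1 <- frames[[1]]
  flatten <- function(config) {
    rows <- list()
    for (side in c("A", "B")) {
      s <- (if (side == "A") config@protomerA else config@protomerB)@sites
      for (i in seq_len(nrow(s))) {
        rows[[length(rows) + 1L]] <- data.frame(
          chain = side, resid = s$resid[i], elety = "CA",
          x = s$x[i], y = s$y[i], z = s$z[i])
        if (is.finite(s$hx[i]))
          rows[[length(rows) + 1L]] <- data.frame(
            chain = side, resid = s$resid[i], elety = "H",
            x = s$hx[i], y = s$hy[i], z = s$hz[i])
      }
    }
    do.call(rbind, rows)
  }
  base <- flatten(f1)
  xyz <- t(vapply(frames, function(fr) {
    m <- flatten(fr)
    as.numeric(t(as.matrix(m[, c("x", "y", "z")])))
  }, numeric(3 * nrow(base))))
  bio3d::write.pdb(file = pdbPath, xyz = xyz,
                   resno = base$resid, chain = base$chain,
                   resid = rep("GLY", nrow(base)), elety = base$elety)
  ann <- do.call(rbind, lapply(c("A", "B"), function(side) {
    s <- (if (side == "A") f1@protomerA else f1@protomerB)@sites
    data.frame(chain = side, resid = s$resid, region = s$region,
               class = s$class)
  }))
  write.csv(ann, annotationPath, row.names = FALSE)
  invisible(pdbPath)
}

#' Read a dimer frame series from a multi-model PDB plus annotation table
#'
#' Inverse of [writeDimerFrames()]: chains A and B become the two
#' protomers; \code{H} atoms are re-attached as hydrogen positions of the
#' site of the same residue; regions and site classes come from the
#' annotation CSV.
#'
#' @param pdbPath multi-model PDB path.
#' @param annotationPath annotation CSV (chain, resid, region, class); a
#'   table without a chain column is applied to both protomers.
#' @param ctermStart first C-terminal residue id (default 291).
#' @param box optional numeric(3) periodic box.
#' @return list of [DimerConfiguration-class].
#' @export
readDimerFrames <- function(pdbPath, annotationPath, ctermStart = 291,
                            box = numeric()) {
  if (!file.exists(pdbPath)) .condStop("ioError", paste("file not found:", pdbPath))
  ann <- read.csv(annotationPath, stringsAsFactors = FALSE)
  if (!all(c("resid", "region", "class") %in% names(ann)))
    .condStop("parseError", "annotation needs resid, region, class columns")
  if (is.null(ann$chain))
    ann <- rbind(cbind(chain = "A", ann), cbind(chain = "B", ann))
  pdb <- bio3d::read.pdb(pdbPath, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  nF <- nrow(pdb$xyz)
  lapply(seq_len(nF), function(f) {
    coords <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
    mkProt <- function(side) {
      sel <- atoms$chain == side
      a <- atoms[sel, ]; xyz <- coords[sel, , drop = FALSE]
      annC <- ann[ann$chain == side, , drop = FALSE]
      main <- a$elety == "CA"
      idx <- match(a$resno[main], annC$resid)
      if (anyNA(idx))
        .condStop("validationError", paste(
          "residues missing from annotation:",
          paste(unique(a$resno[main][is.na(idx)]), collapse = ", ")))
      s <- data.frame(resid = a$resno[main], resname = a$resid[main],
                      region = annC$region[idx], site = "S",
                      class = annC$class[idx],
                      x = xyz[main, 1], y = xyz[main, 2], z = xyz[main, 3],
                      hx = NA_real_, hy = NA_real_, hz = NA_real_)
      hyd <- which(!main)
      if (length(hyd)) {
        hi <- match(a$resno[hyd], s$resid)
        s$hx[hi] <- xyz[hyd, 1]; s$hy[hi] <- xyz[hyd, 2]
        s$hz[hi] <- xyz[hyd, 3]
      }
      ProtomerModel(s, ctermStart = ctermStart)
    }
    DimerConfiguration(mkProt("A"), mkProt("B"), frameIndex = f, box = box)
  })
}

## per-peak area standard errors from the fit covariance
.peakAreaSE <- function(fit) {
  p <- fit@peaks; V <- fit@covariance
  vapply(seq_len(nrow(p)), function(i) {
    g <- numeric(3 * nrow(p))
    g[3 * i - 2] <- p$sigma[i] * sqrt(2 * pi)
    g[3 * i]     <- p$amplitude[i] * sqrt(2 * pi)
    sqrt(max(drop(t(g) %*% V %*% g), 0))
  }, 1)
}

#' Fitted-peak table of a chromatogram deconvolution
#'
#' @param fit a [PeakFit-class].
#' @param assignment optional [SpeciesAssignment-class] adding a species
#'   column.
#' @return data.frame(species, amplitude, center, sigma, area, area_se).
#' @export
peakReport <- function(fit, assignment = NULL) {
  p <- fit@peaks
  species <- rep(NA_character_, nrow(p))
  if (!is.null(assignment))
    for (sp in .SPECIES) species[assignment@assignment[[sp]]] <- sp
  data.frame(species = species, amplitude = p$amplitude, center = p$center,
             sigma = p$sigma, area = p$area, area_se = .peakAreaSE(fit))
}

#' Run the SEC oligomer-level pipeline over chromatogram files
#'
#' For each input CSV: read, baseline-correct, fit \code{nPeaks}
#' Gaussians, assign species and compute monomer-equivalent levels.
#' Writes \code{peaks_<label>.csv} per sample, a pooled
#' \code{levels.csv}, and \code{levels.json} carrying levels, 95%
#' confidence half-widths, fit diagnostics and a provenance block. Any
#' fit failure aborts the run with no partial report.
#'
#' @param inputPaths character vector of chromatogram CSV paths.
#' @param outDir output directory (created if needed).
#' @param nPeaks,policy,windows,baselineMethod pipeline parameters, see
#'   [secLevels()].
#' @param seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return invisibly, a list of per-sample [secLevels()] results.
#' @export
runSecLevels <- function(inputPaths, outDir, nPeaks = 3, policy = "ordinal",
                         windows = NULL, baselineMethod = "linear",
                         seed = NULL) {
  config <- list(nPeaks = nPeaks, policy = policy, windows = windows,
                 baselineMethod = baselineMethod)
  missing <- inputPaths[!file.exists(inputPaths)]
  if (length(missing))
    .condStop("ioError", paste("missing input file(s):",
                               paste(missing, collapse = ", ")))
  results <- lapply(inputPaths, function(pth) {
    ch <- readChromatogram(pth)
    secLevels(ch, nPeaks = nPeaks, policy = policy, windows = windows,
              baselineMethod = baselineMethod)
  })
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (r in results) {
    lab <- r$levels@label
    write.csv(peakReport(r$fit, r$assignment),
              file.path(outDir, paste0("peaks_", lab, ".csv")),
              row.names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      sample = lab, dimer_level = r$levels@dimerLevel,
      hmw_level = r$levels@hmwLevel, total_level = r$levels@totalLevel,
      dimer_ci95 = r$levels@ci95[["dimer_level"]],
      hmw_ci95 = r$levels@ci95[["hmw_level"]],
      total_ci95 = r$levels@ci95[["total_level"]],
      r_squared = r$fit@rSquared)
  }
  tab <- do.call(rbind, rows)
  write.csv(tab, file.path(outDir, "levels.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(provenance = .provenance(config, seed), levels = tab),
    file.path(outDir, "levels.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(results)
}

#' Run the dimer-interface analysis over a frame series
#'
#' Reads frames ([readDimerFrames()] when given file paths, or takes a
#' list of [DimerConfiguration-class] directly), computes per-frame
#' electrostatic / hydrogen-bond / non-polar contacts, classifies each
#' interface, clusters the frames (Daura), measures helix tilt, and
#' averages per-segment residue contact counts. Writes contact, cluster,
#' tilt and averaged tables as CSV and the interface calls plus provenance
#' as JSON.
#'
#' @param frames list of [DimerConfiguration-class], or a PDB path (then
#'   \code{annotationPath} is required).
#' @param outDir output directory.
#' @param annotationPath annotation CSV when \code{frames} is a path.
#' @param elecCutoff,hbondCutoff,hbondAngle,nonpolarCutoff,rmsdCutoff,
#'   dimerCutoff analysis cutoffs (defaults 5.0 A, 3.5 A, 20 deg, 5.0 A,
#'   1.5 A, 5 A).
#' @param hbondScope region scope of the hydrogen-bond analysis
#'   (default "CTERM"; NULL to disable).
#' @param tiltHelices helix region labels to measure (default "TM7").
#' @param segments named list of residue ranges for contact averaging
#'   (default the C-terminal halves 291-334 and 335-412).
#' @param ctermStart,box passed to [readDimerFrames()].
#' @param seed recorded in provenance.
#' @return invisibly, a list with the computed tables.
#' @export
runInterfaceReport <- function(frames, outDir, annotationPath = NULL,
                               elecCutoff = 5.0, hbondCutoff = 3.5,
                               hbondAngle = 20, nonpolarCutoff = 5.0,
                               rmsdCutoff = 1.5, dimerCutoff = 5.0,
                               hbondScope = "CTERM",
                               tiltHelices = "TM7",
                               segments = list(`291-334` = c(291, 334),
                                               `335-412` = c(335, 412)),
                               ctermStart = 291, box = numeric(),
                               seed = NULL) {
  config <- list(elecCutoff = elecCutoff, hbondCutoff = hbondCutoff,
                 hbondAngle = hbondAngle, nonpolarCutoff = nonpolarCutoff,
                 rmsdCutoff = rmsdCutoff, dimerCutoff = dimerCutoff,
                 hbondScope = hbondScope, tiltHelices = tiltHelices,
                 segments = segments)
  if (is.character(frames)) {
    if (is.null(annotationPath))
      .condStop("validationError", "annotationPath required with a PDB input")
    frames <- readDimerFrames(frames, annotationPath,
                              ctermStart = ctermStart, box = box)
  }
  perFrame <- lapply(frames, function(cf) {
    elec <- electrostaticContacts(cf, cutoff = elecCutoff)
    hb <- tryCatch(hydrogenBonds(cf, dCut = hbondCutoff, angCut = hbondAngle,
                                 scope = hbondScope),
                   unsupportedInput = function(e) .ContactSet(
                     .emptyContacts(), cf@frameIndex))
    np <- nonpolarContacts(cf, cutoff = nonpolarCutoff)
    pooled <- poolContacts(elec, hb, np)
    list(frame = cf@frameIndex, dimeric = detectDimer(cf, dimerCutoff),
         elec = elec, hbond = hb, nonpolar = np, pooled = pooled,
         call = classifyInterface(pooled))
  })
  contactTab <- do.call(rbind, lapply(perFrame, function(p) {
    cs <- p$pooled@contacts
    if (!nrow(cs)) return(NULL)
    cbind(frame = p$frame, cs)
  }))
  if (is.null(contactTab)) contactTab <- cbind(frame = integer(),
                                               .emptyContacts())
  cl <- dauraCluster(frames, rmsdCutoff = rmsdCutoff)
  clusterTab <- do.call(rbind, lapply(seq_along(cl@clusters), function(k)
    data.frame(cluster = k, frame = cl@clusters[[k]],
               representative = cl@representatives[k])))
  tiltTab <- do.call(rbind, lapply(frames, function(cf) {
    do.call(rbind, lapply(tiltHelices, function(h)
      data.frame(frame = cf@frameIndex, helix = h,
                 tilt_A = helixTilt(cf@protomerA, h),
                 tilt_B = helixTilt(cf@protomerB, h))))
  }))
  avgTab <- averageContactCounts(lapply(perFrame, `[[`, "pooled"), segments)
  calls <- vapply(perFrame, function(p) p$call@classification, "")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  write.csv(contactTab, file.path(outDir, "contacts.csv"), row.names = FALSE)
  write.csv(clusterTab, file.path(outDir, "clusters.csv"), row.names = FALSE)
  write.csv(tiltTab, file.path(outDir, "tilt.csv"), row.names = FALSE)
  write.csv(avgTab, file.path(outDir, "contact_averages.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(provenance = .provenance(config, seed),
         interface_calls = data.frame(
           frame = vapply(perFrame, `[[`, 1L, "frame"),
           dimeric = vapply(perFrame, `[[`, NA, "dimeric"),
           classification = calls),
         majority_call = names(sort(table(calls), decreasing = TRUE))[1],
         n_clusters = length(cl@clusters)),
    file.path(outDir, "interface.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(list(perFrame = perFrame, clusters = cl, tilt = tiltTab,
                 averages = avgTab, calls = calls))
}

#' Run the solution-biophysics report
#'
#' Computes ionic strengths for a set of buffer compositions, Debye
#' lengths for a query table, and optionally analyses a DSF melt curve
#' (derivative, Tm, quench) and a turbidity series (aggregation states).
#' Everything is assembled into one JSON report with provenance.
#'
#' @param outDir output directory.
#' @param buffers named list of [BufferComposition-class] (default the
#'   phosphate/NaCl SEC buffer series).
#' @param debyeQueries data.frame(I, temperatureK) (default the screening
#'   condition 0.34 M at 277.15 K).
#' @param meltCurve optional [MeltCurve-class] or CSV path.
#' @param turbidity optional [TurbiditySeries-class] or CSV path.
#' @param seed recorded in provenance.
#' @return invisibly, the report list.
#' @export
runSolutionReport <- function(outDir, buffers = defaultSecBuffers(),
                              debyeQueries = data.frame(I = 0.34,
                                                        temperatureK = 277.15),
                              meltCurve = NULL, turbidity = NULL,
                              seed = NULL) {
  config <- list(buffers = names(buffers), debyeQueries = debyeQueries)
  bufferTab <- data.frame(
    buffer = names(buffers),
    ionic_strength_mM = vapply(buffers, ionicStrength, 1),
    ionic_strength_M = round(vapply(buffers, ionicStrength, 1) / 1000, 2))
  debyeTab <- cbind(debyeQueries,
                    debye_length_A = debyeLength(debyeQueries$I,
                                                 debyeQueries$temperatureK))
  report <- list(provenance = .provenance(config, seed),
                 buffers = bufferTab, debye = debyeTab)
  if (!is.null(meltCurve)) {
    if (is.character(meltCurve)) meltCurve <- readMeltCurve(meltCurve)
    mc <- meltDerivative(meltCurve)
    ev <- detectMeltEvents(mc)
    report$melt <- list(tm_C = ev$tm, quench_C = ev$quenchT)
  }
  if (!is.null(turbidity)) {
    if (is.character(turbidity)) turbidity <- readTurbiditySeries(turbidity)
    report$turbidity <- classifyAggregation(turbidity)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(outDir, "solution.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}
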