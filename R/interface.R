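## Geometric analysis of receptor dimer configurations: dimer detection,
## typed cross-protomer contacts, interface symmetry, helical tilt, and
## Daura conformational clustering.
##
## Distance conventions (documented and tested at boundaries):
##   dimer COM criterion        strict  <  (default 5 A)
##   contact cutoffs            inclusive <= (electrostatic 5.0 A,
##                              H-bond 3.5 A donor-acceptor, nonpolar 5.0 A)
##   interacting-helix screen   strict  <  (default 7 A)
## H-bond angle: deviation of the donor-hydrogen-acceptor angle from 180
## degrees must be <= 20 degrees; H-bonds need explicit hydrogen positions
## (atomistic-style input) and are restricted to C-terminal residues by
## default.

.siteXYZ <- function(p) as.matrix(p@sites[, c("x", "y", "z")])

## minimum-image displacement for an orthorhombic box
.minImage <- function(d, box) {
  if (!length(box)) return(d)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

## all cross distances between coordinate matrices a (n x 3) and b (m x 3)
.crossDistances <- function(a, b, box = numeric()) {
  n <- nrow(a); m <- nrow(b)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  if (length(box)) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  sqrt(dx^2 + dy^2 + dz^2)
}

## per-residue centre of mass (unweighted mean over sites)
.residueCOM <- function(p) {
  xyz <- .siteXYZ(p)
  resid <- p@sites$resid
  m <- rowsum(xyz, resid) / as.numeric(table(resid))
  list(resid = as.integer(rownames(m)), xyz = unname(m))
}

#' Minimum residue centre-of-mass distance between two protomers
#'
#' Minimum, over all cross-protomer residue pairs, of the distance between
#' residue centres of mass (whole-protomer COM distance can never reach
#' the few-Angstrom dimer criterion for an intact receptor, so the
#' residue-level minimum is the operative quantity). Minimum-image
#' convention is applied when the configuration carries a periodic box.
#'
#' @param config a [DimerConfiguration-class].
#' @param ... unused.
#' @return distance in Angstrom.
#' @rdname minComDistance
#' @export
setMethod("minComDistance", "DimerConfiguration",
function(config, ...) {
  ca <- .residueCOM(config@protomerA)
  cb <- .residueCOM(config@protomerB)
  min(.crossDistances(ca$xyz, cb$xyz, config@box))
})

#' Dimer detection by the centre-of-mass distance criterion
#'
#' A configuration counts as dimeric when [minComDistance()] is strictly
#' below the cutoff (default 5 Angstrom); exactly at the cutoff is not a
#' dimer.
#'
#' @param config a [DimerConfiguration-class].
#' @param cutoff Angstrom, default 5.0.
#' @param ... unused.
#' @return logical(1).
#' @rdname detectDimer
#' @export
setMethod("detectDimer", "DimerConfiguration",
function(config, cutoff = 5.0, ...) {
  minComDistance(config) < cutoff
})

## shared worker: typed site-pair contacts between protomers
.sitePairContacts <- function(config, classesA, classesB, cutoff, type,
                              scope = NULL, oriented = FALSE) {
  sa <- config@protomerA@sites
  sb <- config@protomerB@sites
  if (!is.null(scope)) {
    sa <- sa[sa$region %in% scope, , drop = FALSE]
    sb <- sb[sb$region %in% scope, , drop = FALSE]
  }
  ia <- which(sa$class %in% classesA)
  ib <- which(sb$class %in% classesB)
  out <- .emptyContacts()
  if (length(ia) && length(ib)) {
    D <- .crossDistances(as.matrix(sa[ia, c("x", "y", "z")]),
                         as.matrix(sb[ib, c("x", "y", "z")]), config@box)
    hit <- which(D <= cutoff, arr.ind = TRUE)
    if (nrow(hit)) {
      out <- data.frame(
        residA = sa$resid[ia[hit[, 1]]], residB = sb$resid[ib[hit[, 2]]],
        regionA = sa$region[ia[hit[, 1]]], regionB = sb$region[ib[hit[, 2]]],
        type = type, distance = D[hit], angle = NA_real_)
    }
  }
  out
}

#' Cross-protomer electrostatic contacts
#'
#' One contact per pair of oppositely charged sites (one on each protomer)
#' within the distance cutoff (inclusive; default 5.0 Angstrom).
#'
#' @param config a [DimerConfiguration-class] with charged site classes
#'   annotated.
#' @param cutoff Angstrom, default 5.0.
#' @param scope optional character vector of region labels restricting both
#'   partners (e.g. "CTERM").
#' @param ... unused.
#' @return a [ContactSet-class].
#' @rdname electrostaticContacts
#' @export
setMethod("electrostaticContacts", "DimerConfiguration",
function(config, cutoff = 5.0, scope = NULL, ...) {
  if (cutoff <= 0) .condStop("validationError", "cutoff must be positive")
  pn <- .sitePairContacts(config, "charged+", "charged-", cutoff,
                          "electrostatic", scope)
  np <- .sitePairContacts(config, "charged-", "charged+", cutoff,
                          "electrostatic", scope)
  out <- rbind(pn, np)
  hasCharged <- function(p) {
    s <- p@sites
    if (!is.null(scope)) s <- s[s$region %in% scope, , drop = FALSE]
    any(s$class %in% c("charged+", "charged-"))
  }
  if (!nrow(out) &&
      (!hasCharged(config@protomerA) || !hasCharged(config@protomerB)))
    warning("no charged sites in scope: empty contact set")
  .ContactSet(out, config@frameIndex)
})

#' Cross-protomer hydrogen bonds
#'
#' Geometric criterion: donor-acceptor distance at most \code{dCut}
#' (default 3.5 Angstrom) and donor-hydrogen-acceptor angle within
#' \code{angCut} degrees of linearity (default 20). Restricted to
#' C-terminal residues by default, and requires explicit hydrogen
#' positions on every donor in scope: coordinate sets without hydrogens
#' (coarse-grained resolution) are rejected.
#'
#' @param config a [DimerConfiguration-class].
#' @param dCut donor-acceptor distance cutoff, Angstrom.
#' @param angCut allowed deviation from linearity, degrees.
#' @param scope region labels both partners must carry; default "CTERM";
#'   \code{NULL} disables the filter.
#' @param ... unused.
#' @return a [ContactSet-class] whose \code{angle} column holds the
#'   deviation from linearity.
#' @rdname hydrogenBonds
#' @export
setMethod("hydrogenBonds", "DimerConfiguration",
function(config, dCut = 3.5, angCut = 20, scope = "CTERM", ...) {
  oneDirection <- function(pd, pa, swap) {
    sd <- pd@sites; sa <- pa@sites
    if (!is.null(scope)) {
      sd <- sd[sd$region %in% scope, , drop = FALSE]
      sa <- sa[sa$region %in% scope, , drop = FALSE]
    }
    don <- sd[sd$class == "polar-donor", , drop = FALSE]
    acc <- sa[sa$class == "polar-acceptor", , drop = FALSE]
    out <- .emptyContacts()
    if (!nrow(don) || !nrow(acc)) return(out)
    noH <- !is.finite(don$hx) | !is.finite(don$hy) | !is.finite(don$hz)
    if (all(noH))
      .condStop("unsupportedInput", paste(
        "no donor in scope carries a hydrogen position:",
        "hydrogen-bond analysis needs atomistic-style coordinates"))
    if (any(noH))
      .condStop("validationError", paste(
        "donor residue(s) missing hydrogen position:",
        paste(unique(don$resid[noH]), collapse = ", ")))
    D <- .crossDistances(as.matrix(don[, c("x", "y", "z")]),
                         as.matrix(acc[, c("x", "y", "z")]), config@box)
    hit <- which(D <= dCut, arr.ind = TRUE)
    if (!nrow(hit)) return(out)
    dev <- vapply(seq_len(nrow(hit)), function(r) {
      i <- hit[r, 1]; j <- hit[r, 2]
      h <- c(don$hx[i], don$hy[i], don$hz[i])
      vd <- .minImage(matrix(c(don$x[i], don$y[i], don$z[i]) - h, 1), config@box)[1, ]
      va <- .minImage(matrix(c(acc$x[j], acc$y[j], acc$z[j]) - h, 1), config@box)[1, ]
      cosang <- sum(vd * va) / sqrt(sum(vd^2) * sum(va^2))
      180 - acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    }, 1)
    keep <- dev <= angCut
    if (!any(keep)) return(out)
    hit <- hit[keep, , drop = FALSE]; dev <- dev[keep]
    df <- data.frame(
      residA = don$resid[hit[, 1]], residB = acc$resid[hit[, 2]],
      regionA = don$region[hit[, 1]], regionB = acc$region[hit[, 2]],
      type = "hbond", distance = D[hit], angle = dev)
    if (swap) df[, c("residA", "residB", "regionA", "regionB")] <-
        df[, c("residB", "residA", "regionB", "regionA")]
    df
  }
  ab <- oneDirection(config@protomerA, config@protomerB, swap = FALSE)
  ba <- oneDirection(config@protomerB, config@protomerA, swap = TRUE)
  .ContactSet(rbind(ab, ba), config@frameIndex)
})

#' Cross-protomer non-polar contacts
#'
#' Pairs of non-polar sites within the cutoff (inclusive). The cutoff has
#' no stated literature value for this analysis and defaults to 5.0
#' Angstrom for consistency with the electrostatic criterion.
#'
#' @param config a [DimerConfiguration-class].
#' @param cutoff Angstrom, default 5.0.
#' @param scope optional region filter.
#' @param ... unused.
#' @return a [ContactSet-class].
#' @rdname nonpolarContacts
#' @export
setMethod("nonpolarContacts", "DimerConfiguration",
function(config, cutoff = 5.0, scope = NULL, ...) {
  if (cutoff <= 0) .condStop("validationError", "cutoff must be positive")
  .ContactSet(.sitePairContacts(config, "nonpolar", "nonpolar", cutoff,
                                "nonpolar", scope), config@frameIndex)
})

#' Helical tilt angle
#'
#' Angle between the helix principal axis and the membrane normal (fixed
#' z-axis by default), folded into [0, 90] degrees. Per-residue backbone
#' positions are first averaged over a sliding window of four residues
#' (about one alpha-helical turn) so the helical winding itself does not
#' bias the axis; the axis is then the leading eigenvector of the
#' covariance of the smoothed positions.
#'
#' @param protomer a [ProtomerModel-class].
#' @param helix region label of the helix (e.g. "TM7").
#' @param normal membrane normal vector, default c(0, 0, 1).
#' @param ... unused.
#' @return angle in degrees.
#' @rdname helixTilt
#' @export
setMethod("helixTilt", "ProtomerModel",
function(protomer, helix, normal = c(0, 0, 1), ...) {
  s <- protomer@sites
  sel <- s$region == helix & s$class == "backbone"
  if (!any(sel)) sel <- s$region == helix
  if (length(unique(s$resid[sel])) < 4)
    .condStop("validationError",
              sprintf("helix %s needs >= 4 residues with backbone sites", helix))
  ## residue-level positions in sequence order
  sub <- s[sel, , drop = FALSE]
  com <- rowsum(as.matrix(sub[, c("x", "y", "z")]), sub$resid) /
    as.numeric(table(sub$resid))
  com <- com[order(as.integer(rownames(com))), , drop = FALSE]
  ## one-turn running mean cancels the helical winding
  if (nrow(com) >= 7) {
    w <- 4L
    com <- t(vapply(seq_len(nrow(com) - w + 1L), function(i)
      colMeans(com[i:(i + w - 1L), , drop = FALSE]), numeric(3)))
  }
  xyz <- com
  cv <- cov(xyz)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[1] < 1e-12)
    .condStop("validationError", "degenerate helix coordinates")
  axis <- ev$vectors[, 1]
  cosang <- sum(axis * normal) / sqrt(sum(axis^2) * sum(normal^2))
  ang <- acos(pmin(pmax(abs(cosang), 0), 1)) * 180 / pi
  ang
})

#' Screen for interacting transmembrane helix pairs
#'
#' Lists cross-protomer TM helix pairs whose minimum inter-site distance is
#' strictly below the cutoff (default 7 Angstrom, the minimum-distance
#' criterion for interacting helices). An empty result certifies that the
#' dimer interface involves no TM-TM packing.
#'
#' @param config a [DimerConfiguration-class] with TM regions annotated.
#' @param cutoff Angstrom, default 7.0.
#' @param ... unused.
#' @return data.frame(helixA, helixB, minDistance), possibly zero rows.
#' @rdname interactingHelices
#' @export
setMethod("interactingHelices", "DimerConfiguration",
function(config, cutoff = 7.0, ...) {
  tms <- paste0("TM", 1:7)
  sa <- config@protomerA@sites; sb <- config@protomerB@sites
  ha <- intersect(tms, unique(sa$region))
  hb <- intersect(tms, unique(sb$region))
  out <- data.frame(helixA = character(), helixB = character(),
                    minDistance = numeric())
  for (a in ha) for (b in hb) {
    da <- as.matrix(sa[sa$region == a, c("x", "y", "z")])
    db <- as.matrix(sb[sb$region == b, c("x", "y", "z")])
    md <- min(.crossDistances(da, db, config@box))
    if (md < cutoff)
      out <- rbind(out, data.frame(helixA = a, helixB = b, minDistance = md))
  }
  out
})

#' Classify a dimer interface as symmetric, asymmetric or none
#'
#' Symmetric: the C-termini of the two protomers contact each other
#' (CTERM-CTERM contacts form at least a plurality of the cross-protomer
#' contacts). Asymmetric: the C-terminus of one protomer contacts
#' non-C-terminal regions (e.g. ICL2, ICL3, ECL2) of the other as the
#' plurality. None: no cross-protomer contacts at all. The call is
#' invariant under swapping protomer labels.
#'
#' @param contacts a [ContactSet-class] (typically pooled electrostatic /
#'   H-bond / non-polar contacts of one frame) carrying region labels.
#' @param ... unused.
#' @return an [InterfaceCall-class].
#' @rdname classifyInterface
#' @export
setMethod("classifyInterface", "ContactSet",
function(contacts, ...) {
  cs <- contacts@contacts
  catOf <- function(ra, rb) {
    ifelse(ra == "CTERM" & rb == "CTERM", "cterm-cterm",
      ifelse(ra == "CTERM" & rb != "CTERM", "ctermA-other",
        ifelse(ra != "CTERM" & rb == "CTERM", "other-ctermB", "other-other")))
  }
  if (!nrow(cs)) {
    tal <- data.frame(category = character(), n = integer())
    return(new("InterfaceCall", classification = "none", tallies = tal))
  }
  cat <- catOf(cs$regionA, cs$regionB)
  tal <- as.data.frame(table(category = cat), stringsAsFactors = FALSE)
  names(tal)[2] <- "n"
  nOf <- function(k) sum(tal$n[tal$category == k])
  cc <- nOf("cterm-cterm"); ca <- nOf("ctermA-other"); cb <- nOf("other-ctermB")
  cls <- if (cc > 0 && cc >= ca && cc >= cb) "symmetric" else "asymmetric"
  new("InterfaceCall", classification = cls, tallies = tal)
})

## coordinates used for superposition/RMSD: backbone sites of both
## protomers in schema order (all sites when no backbone class is present)
.frameCoords <- function(config) {
  pick <- function(p) {
    s <- p@sites
    sel <- s$class == "backbone"
    if (!any(sel)) sel <- rep(TRUE, nrow(s))
    as.matrix(s[sel, c("x", "y", "z")])
  }
  rbind(pick(config@protomerA), pick(config@protomerB))
}

#' Daura conformational clustering of a dimer frame series
#'
#' Pairwise RMSD between frames is computed on backbone sites of the whole
#' dimer after optimal least-squares rigid superposition (a no-fit mode is
#' available). Clustering then proceeds iteratively: the frame with the
#' most neighbours (RMSD at most the cutoff) is taken as a cluster centre,
#' it and its neighbours form a cluster and leave the pool, and the
#' process repeats until the pool is empty. Ties in neighbour count are
#' broken by the lowest frame index, making the result deterministic.
#' Clusters are ordered by decreasing size, ties by smallest member index.
#'
#' @param frames list of [DimerConfiguration-class] sharing one site
#'   schema.
#' @param rmsdCutoff Angstrom, default 1.5.
#' @param fit logical, superpose before RMSD (default TRUE).
#' @return a [ClusterResult-class].
#' @export
dauraCluster <- function(frames, rmsdCutoff = 1.5, fit = TRUE) {
  if (!length(frames)) .condStop("validationError", "need at least one frame")
  coords <- lapply(frames, .frameCoords)
  nsite <- vapply(coords, nrow, 1L)
  if (length(unique(nsite)) != 1)
    .condStop("validationError", "frames do not share one site schema")
  n <- length(frames)
  R <- matrix(0, n, n)
  if (n > 1) {
    xyz <- lapply(coords, function(m) as.numeric(t(m)))
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      r <- if (fit)
        bio3d::rmsd(xyz[[i]], xyz[[j]], fit = TRUE)
      else
        bio3d::rmsd(xyz[[i]], xyz[[j]], fit = FALSE)
      R[i, j] <- r; R[j, i] <- r
    }
  }
  pool <- seq_len(n)
  clusterList <- list(); reps <- integer()
  while (length(pool)) {
    nb <- vapply(pool, function(i) sum(R[i, pool] <= rmsdCutoff), 1L)
    centre <- pool[which.max(nb)]  # which.max takes the first = lowest index
    members <- pool[R[centre, pool] <= rmsdCutoff]
    clusterList[[length(clusterList) + 1L]] <- sort(members)
    reps <- c(reps, centre)
    pool <- setdiff(pool, members)
  }
  sizes <- vapply(clusterList, length, 1L)
  firsts <- vapply(clusterList, min, 1L)
  ord <- order(-sizes, firsts)
  new("ClusterResult", clusters = clusterList[ord],
      representatives = as.integer(reps[ord]), rmsdCutoff = rmsdCutoff)
}

#' Average per-segment residue contact counts over frames
#'
#' For each residue segment (e.g. 291-334, 335-394 of the C-terminus) and
#' each frame, counts the distinct residues of that segment participating
#' in at least one cross-protomer contact (a residue on either protomer
#' counts once per frame, regardless of how many contacts it makes), then
#' reports the mean and standard deviation over frames. Counting contact
#' events instead of distinct residues is available via \code{mode}.
#'
#' @param perFrame list of [ContactSet-class], one per frame.
#' @param segments named list of c(lo, hi) residue-id ranges.
#' @param mode "residues" (default) or "events".
#' @return data.frame(segment, mean, sd, n_frames).
#' @export
averageContactCounts <- function(perFrame, segments,
                                 mode = c("residues", "events")) {
  mode <- match.arg(mode)
  if (!length(perFrame)) .condStop("validationError", "need at least one frame")
  if (!length(segments) || is.null(names(segments)))
    .condStop("validationError", "segments must be a named list of ranges")
  counts <- matrix(0, length(perFrame), length(segments),
                   dimnames = list(NULL, names(segments)))
  for (f in seq_along(perFrame)) {
    cs <- perFrame[[f]]@contacts
    for (g in names(segments)) {
      lo <- segments[[g]][1]; hi <- segments[[g]][2]
      if (mode == "residues") {
        ra <- unique(cs$residA[cs$residA >= lo & cs$residA <= hi])
        rb <- unique(cs$residB[cs$residB >= lo & cs$residB <= hi])
        counts[f, g] <- length(ra) + length(rb)
      } else {
        counts[f, g] <- sum((cs$residA >= lo & cs$residA <= hi) |
                              (cs$residB >= lo & cs$residB <= hi))
      }
    }
  }
  sds <- if (nrow(counts) > 1) apply(counts, 2, sd) else rep(0, ncol(counts))
  data.frame(segment = names(segments),
             mean = colMeans(counts),
             sd = sds,
             n_frames = length(perFrame), row.names = NULL)
}

#' Distinct contacting residues per protomer side
#'
#' @param contactSet a [ContactSet-class].
#' @return named integer: distinct contacting residues on protomer A, on
#'   protomer B, and the total.
#' @export
residueContactCounts <- function(contactSet) {
  cs <- contactSet@contacts
  a <- length(unique(cs$residA)); b <- length(unique(cs$residB))
  c(protomerA = a, protomerB = b, total = a + b)
}

#' Pool several contact sets of one frame
#'
#' @param ... [ContactSet-class] objects from the same frame.
#' @return a combined [ContactSet-class].
#' @export
poolContacts <- function(...) {
  sets <- list(...)
  .ContactSet(do.call(rbind, lapply(sets, function(s) s@contacts)),
              sets[[1]]@frameIndex)
}
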