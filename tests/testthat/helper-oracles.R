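# Brute-force oracles and small hand-built fixtures. The oracles are
# deliberately naive (explicit double loops) and independent of the
# package's vectorized implementations.

# build a protomer from a compact site spec; h = optional hydrogen coords
mkProt <- function(resid, region, class, x, y, z,
                   hx = NA_real_, hy = NA_real_, hz = NA_real_,
                   ctermStart = 0) {
  ProtomerModel(data.frame(resid = resid, region = region, class = class,
                           x = x, y = y, z = z, hx = hx, hy = hy, hz = hz),
                ctermStart = ctermStart)
}

mkConfig <- function(a, b, box = numeric()) {
  DimerConfiguration(a, b, frameIndex = 1L, box = box)
}

.dist3 <- function(p, q) sqrt(sum((p - q)^2))

# naive minimum residue-COM distance
bruteMinCom <- function(config) {
  comOf <- function(p) {
    s <- protomerSites(p)
    do.call(rbind, lapply(split(s, s$resid), function(r)
      colMeans(as.matrix(r[, c("x", "y", "z")]))))
  }
  ca <- comOf(protomerA(config)); cb <- comOf(protomerB(config))
  best <- Inf
  for (i in seq_len(nrow(ca))) for (j in seq_len(nrow(cb)))
    best <- min(best, .dist3(ca[i, ], cb[j, ]))
  best
}

# naive opposite-charge contact count
bruteElectrostatic <- function(config, cutoff = 5.0) {
  sa <- protomerSites(protomerA(config)); sb <- protomerSites(protomerB(config))
  n <- 0L
  for (i in seq_len(nrow(sa))) for (j in seq_len(nrow(sb))) {
    ci <- sa$class[i]; cj <- sb$class[j]
    opp <- (ci == "charged+" && cj == "charged-") ||
      (ci == "charged-" && cj == "charged+")
    if (opp && .dist3(c(sa$x[i], sa$y[i], sa$z[i]),
                      c(sb$x[j], sb$y[j], sb$z[j])) <= cutoff)
      n <- n + 1L
  }
  n
}

# naive nonpolar contact count
bruteNonpolar <- function(config, cutoff = 5.0) {
  sa <- protomerSites(protomerA(config)); sb <- protomerSites(protomerB(config))
  n <- 0L
  for (i in seq_len(nrow(sa))) for (j in seq_len(nrow(sb)))
    if (sa$class[i] == "nonpolar" && sb$class[j] == "nonpolar" &&
        .dist3(c(sa$x[i], sa$y[i], sa$z[i]),
               c(sb$x[j], sb$y[j], sb$z[j])) <= cutoff)
      n <- n + 1L
  n
}

# naive hydrogen-bond count (both directions, optional region scope)
bruteHbond <- function(config, dCut = 3.5, angCut = 20, scope = "CTERM") {
  count <- function(sd, sa) {
    n <- 0L
    for (i in seq_len(nrow(sd))) for (j in seq_len(nrow(sa))) {
      if (sd$class[i] != "polar-donor" || sa$class[j] != "polar-acceptor")
        next
      if (!is.null(scope) &&
          (!sd$region[i] %in% scope || !sa$region[j] %in% scope)) next
      d <- c(sd$x[i], sd$y[i], sd$z[i]); h <- c(sd$hx[i], sd$hy[i], sd$hz[i])
      a <- c(sa$x[j], sa$y[j], sa$z[j])
      if (.dist3(d, a) > dCut) next
      vd <- d - h; va <- a - h
      ang <- acos(sum(vd * va) / sqrt(sum(vd^2) * sum(va^2))) * 180 / pi
      if (180 - ang <= angCut) n <- n + 1L
    }
    n
  }
  count(protomerSites(protomerA(config)), protomerSites(protomerB(config))) +
    count(protomerSites(protomerB(config)), protomerSites(protomerA(config)))
}

# naive interacting-helix scan
bruteInteractingHelices <- function(config, cutoff = 7.0) {
  sa <- protomerSites(protomerA(config)); sb <- protomerSites(protomerB(config))
  tms <- paste0("TM", 1:7)
  out <- character()
  for (ha in intersect(tms, sa$region)) for (hb in intersect(tms, sb$region)) {
    da <- sa[sa$region == ha, ]; db <- sb[sb$region == hb, ]
    best <- Inf
    for (i in seq_len(nrow(da))) for (j in seq_len(nrow(db)))
      best <- min(best, .dist3(c(da$x[i], da$y[i], da$z[i]),
                               c(db$x[j], db$y[j], db$z[j])))
    if (best < cutoff) out <- c(out, paste(ha, hb))
  }
  sort(out)
}

# independent greedy clustering from a precomputed distance matrix
bruteDaura <- function(R, cutoff) {
  pool <- seq_len(nrow(R))
  out <- list()
  while (length(pool)) {
    counts <- sapply(pool, function(i) sum(R[i, pool] <= cutoff))
    centre <- pool[which(counts == max(counts))[1]]
    members <- pool[R[centre, pool] <= cutoff]
    out[[length(out) + 1L]] <- sort(members)
    pool <- setdiff(pool, members)
  }
  sizes <- sapply(out, length)
  out[order(-sizes, sapply(out, min))]
}

# apply a rigid rotation + translation to every site (and hydrogen)
rigidTransform <- function(config, angles = c(0.3, -0.5, 1.1),
                           shift = c(5, -3, 7)) {
  Rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)),
                           3, 3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  R <- Rz(angles[3]) %*% Ry(angles[2]) %*% Rx(angles[1])
  tf <- function(p) {
    s <- protomerSites(p)
    xyz <- as.matrix(s[, c("x", "y", "z")]) %*% t(R)
    s$x <- xyz[, 1] + shift[1]; s$y <- xyz[, 2] + shift[2]
    s$z <- xyz[, 3] + shift[3]
    hok <- is.finite(s$hx)
    if (any(hok)) {
      hxyz <- as.matrix(s[hok, c("hx", "hy", "hz")]) %*% t(R)
      s$hx[hok] <- hxyz[, 1] + shift[1]; s$hy[hok] <- hxyz[, 2] + shift[2]
      s$hz[hok] <- hxyz[, 3] + shift[3]
    }
    ProtomerModel(s, ctermStart = p@ctermStart)
  }
  DimerConfiguration(tf(protomerA(config)), tf(protomerB(config)),
                     frameIndex = config@frameIndex, box = config@box)
}

# a minimal PeakFit with exact areas and zero covariance, for level tests
mkPeakFit <- function(areas, centers = NULL, sigma = 0.4) {
  n <- length(areas)
  if (is.null(centers)) centers <- seq(9, by = 2, length.out = n)
  peaks <- data.frame(amplitude = areas / (sigma * sqrt(2 * pi)),
                      center = centers, sigma = sigma,
                      area = areas)
  new("PeakFit", peaks = peaks, covariance = matrix(0, 3 * n, 3 * n),
      rSquared = 1, window = list(), offset = 0, label = "fixture")
}
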