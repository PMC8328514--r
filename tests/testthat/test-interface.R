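# geometric contact analysis, interface classification, tilt and clustering

test_that("minimum COM distance matches brute force and detects dimers strictly", {
  ## coincident residue centres give zero
  a <- mkProt(1:3, "CTERM", "nonpolar", c(0, 5, 10), 0, 0, ctermStart = 1)
  b <- mkProt(1:3, "CTERM", "nonpolar", c(0, 30, 40), 0, 0, ctermStart = 1)
  cfg <- mkConfig(a, b)
  expect_equal(minComDistance(cfg), 0)

  ## 3x3-residue configuration equals the exhaustive pairwise minimum,
  ## including residues with several sites
  set.seed(42)
  mk3 <- function() {
    n <- 6  # two sites for each of three residues
    mkProt(rep(1:3, each = 2), "ICL3", "nonpolar",
           runif(n, -8, 8), runif(n, -8, 8), runif(n, -8, 8), ctermStart = 99)
  }
  for (i in 1:5) {
    cfg <- mkConfig(mk3(), mk3())
    expect_equal(minComDistance(cfg), bruteMinCom(cfg), tolerance = 1e-12)
  }

  ## strict inequality at the 5 A dimer criterion
  atDist <- function(d) {
    mkConfig(mkProt(1, "CTERM", "nonpolar", 0, 0, 0, ctermStart = 1),
             mkProt(1, "CTERM", "nonpolar", d, 0, 0, ctermStart = 1))
  }
  expect_true(detectDimer(atDist(3)))
  expect_false(detectDimer(atDist(6)))
  expect_false(detectDimer(atDist(5.0)))
})

test_that("geometric measures are invariant under rigid motions", {
  gd <- genDimerConfiguration(21, nFrames = 1)
  cfg <- gd$frames[[1]]
  moved <- rigidTransform(cfg)
  expect_equal(minComDistance(moved), minComDistance(cfg), tolerance = 1e-6)
  expect_equal(nrow(contacts(electrostaticContacts(moved))),
               nrow(contacts(electrostaticContacts(cfg))))
  expect_equal(contacts(electrostaticContacts(moved))$distance,
               contacts(electrostaticContacts(cfg))$distance,
               tolerance = 1e-6)
  expect_equal(nrow(contacts(hydrogenBonds(moved))),
               nrow(contacts(hydrogenBonds(cfg))))
  expect_equal(nrow(contacts(nonpolarContacts(moved))),
               nrow(contacts(nonpolarContacts(cfg))))
})

test_that("periodic minimum-image convention folds distances into the box", {
  a <- mkProt(1, "CTERM", "nonpolar", 1, 1, 1, ctermStart = 1)
  b <- mkProt(1, "CTERM", "nonpolar", 99, 1, 1, ctermStart = 1)
  noBox <- mkConfig(a, b)
  withBox <- mkConfig(a, b, box = c(100, 100, 100))
  expect_equal(minComDistance(noBox), 98)
  expect_equal(minComDistance(withBox), 2)
  expect_true(detectDimer(withBox))
})

test_that("electrostatic contacts pair opposite charges within the cutoff", {
  pair <- function(d, clsA = "charged+", clsB = "charged-") {
    mkConfig(mkProt(1, "CTERM", clsA, 0, 0, 0, ctermStart = 1),
             mkProt(1, "CTERM", clsB, d, 0, 0, ctermStart = 1))
  }
  expect_identical(nrow(contacts(electrostaticContacts(pair(4.0)))), 1L)
  expect_identical(nrow(contacts(electrostaticContacts(pair(5.5)))), 0L)
  expect_identical(nrow(contacts(electrostaticContacts(pair(5.0)))), 1L)  # inclusive
  expect_identical(nrow(contacts(electrostaticContacts(
    pair(4.0, "charged+", "charged+")))), 0L)
  ## reversed polarity also counts
  expect_identical(nrow(contacts(electrostaticContacts(
    pair(4.0, "charged-", "charged+")))), 1L)
  ## no charged sites in scope warns and returns empty
  expect_warning(cs <- electrostaticContacts(
    pair(4.0, "nonpolar", "nonpolar")), "no charged sites")
  expect_identical(nrow(contacts(cs)), 0L)
})

test_that("planted opposite- and like-charge pairs match exhaustive enumeration", {
  plan <- data.frame(
    residA = 291:301, residB = 314:304,
    type = c(rep("electrostatic", 7), rep("samecharge", 4)),
    distance = c(2.5, 3, 3.5, 4, 4.4, 4.7, 4.9, 2.5, 3, 4, 4.8))
  gd <- genDimerConfiguration(31, plan = plan)
  cfg <- gd$frames[[1]]
  cs <- electrostaticContacts(cfg)
  expect_identical(nrow(contacts(cs)), 7L)
  expect_identical(nrow(contacts(cs)), as.integer(bruteElectrostatic(cfg)))
  ## residue-level tally counts each residue once
  expect_identical(unname(residueContactCounts(cs)[["total"]]), 14L)
})

test_that("hydrogen bonds need distance, near-linearity, hydrogens and scope", {
  hbPair <- function(d, dev = 0, region = "CTERM", withH = TRUE) {
    delta <- dev * pi / 180
    h <- c(1, 0, 0)
    dd <- -cos(delta) + sqrt(cos(delta)^2 - 1 + d^2)
    acc <- h + dd * c(cos(delta), sin(delta), 0)
    don <- mkProt(1, region, "polar-donor", 0, 0, 0,
                  hx = if (withH) 1 else NA, hy = if (withH) 0 else NA,
                  hz = if (withH) 0 else NA, ctermStart = 1)
    aP <- mkProt(1, region, "polar-acceptor", acc[1], acc[2], acc[3],
                 ctermStart = 1)
    mkConfig(don, aP)
  }
  expect_identical(nrow(contacts(hydrogenBonds(hbPair(3.4)))), 1L)
  expect_identical(nrow(contacts(hydrogenBonds(hbPair(3.6)))), 0L)
  expect_identical(nrow(contacts(hydrogenBonds(hbPair(3.2, dev = 25)))), 0L)
  expect_identical(nrow(contacts(hydrogenBonds(hbPair(3.2, dev = 15)))), 1L)
  ## recorded angle is the deviation from linearity
  expect_equal(contacts(hydrogenBonds(hbPair(3.2, dev = 15)))$angle, 15,
               tolerance = 1e-6)
  ## C-terminal scope excludes loop residues by default
  expect_identical(nrow(contacts(hydrogenBonds(hbPair(3.2, region = "ICL3")))),
                   0L)
  expect_identical(nrow(contacts(hydrogenBonds(hbPair(3.2, region = "ICL3"),
                                               scope = NULL))), 1L)
  ## donors without hydrogens are unsupported (coarse-grained input)
  expect_error(hydrogenBonds(hbPair(3.2, withH = FALSE)),
               class = "unsupportedInput")
})

test_that("planted hydrogen-bond suites match exhaustive enumeration", {
  plan <- data.frame(
    residA = 291:296, residB = 314:309,
    type = "hbond",
    distance = c(2.8, 3.0, 3.2, 3.4, 3.3, 3.1),
    angleDev = c(0, 5, 10, 19, 25, 40))  # last two fail the angle cut
  gd <- genDimerConfiguration(32, plan = plan)
  cfg <- gd$frames[[1]]
  hb <- hydrogenBonds(cfg)
  expect_identical(nrow(contacts(hb)), 4L)
  expect_identical(nrow(contacts(hb)), as.integer(bruteHbond(cfg)))
  ## a donor missing its hydrogen is named
  s <- protomerSites(protomerA(cfg))
  s$hx[s$class == "polar-donor"][1] <- NA
  broken <- mkConfig(ProtomerModel(s, ctermStart = 291), protomerB(cfg))
  expect_error(hydrogenBonds(broken), "291")
})

test_that("non-polar contacts count planted pairs exactly", {
  plan <- data.frame(residA = 291:295, residB = 314:310, type = "nonpolar",
                     distance = c(3, 3.5, 4, 4.5, 4.9))
  gd <- genDimerConfiguration(33, plan = plan)
  cfg <- gd$frames[[1]]
  np <- nonpolarContacts(cfg)
  expect_identical(nrow(contacts(np)), as.integer(bruteNonpolar(cfg)))
  ## note: chain/loop scaffold sites are nonpolar class but kept far from
  ## the interface, so only the planted pairs are counted
  expect_identical(nrow(contacts(np)), 5L)
  expect_error(nonpolarContacts(cfg, cutoff = -1), class = "validationError")
  ## no nonpolar sites at all
  a <- mkProt(1, "CTERM", "charged+", 0, 0, 0, ctermStart = 1)
  b <- mkProt(1, "CTERM", "charged-", 2, 0, 0, ctermStart = 1)
  expect_identical(nrow(contacts(nonpolarContacts(mkConfig(a, b)))), 0L)
})

test_that("helix tilt reads planted angles and respects geometry", {
  ## axis along the membrane normal and in the membrane plane
  zHelix <- mkProt(1:8, "TM1", "backbone", 0, 0, seq(0, 10.5, length.out = 8),
                   ctermStart = 99)
  expect_equal(helixTilt(zHelix, "TM1"), 0, tolerance = 1e-9)
  xHelix <- mkProt(1:8, "TM1", "backbone", seq(0, 10.5, length.out = 8), 0, 0,
                   ctermStart = 99)
  expect_equal(helixTilt(xHelix, "TM1"), 90, tolerance = 1e-9)

  ## planted 30-degree helices recovered within a degree, frames noisy
  for (seed in 1:5) {
    gd <- genDimerConfiguration(seed, tilt = c(TM7 = 30), noiseSd = 0.2)
    expect_equal(helixTilt(protomerA(gd$frames[[1]]), "TM7"), 30,
                 tolerance = 1 / 30)
  }

  ## complementarity: tilt to the normal plus tilt to an in-plane vector
  ## orthogonal to the normal sums to 90 for a noise-free helix
  gd <- genDimerConfiguration(6, tilt = c(TM7 = 25), noiseSd = 0)
  p <- protomerA(gd$frames[[1]])
  t1 <- helixTilt(p, "TM7", normal = c(0, 0, 1))
  t2 <- helixTilt(p, "TM7", normal = c(1, 0, 0))  # tilt axis lies in xz
  expect_equal(t1 + t2, 90, tolerance = 0.2)

  expect_error(helixTilt(mkProt(1:3, "TM2", "backbone", 1:3, 0, 0,
                                ctermStart = 99), "TM2"),
               class = "validationError")
})

test_that("interacting-helix screening matches an exhaustive scan", {
  ## the default scaffold keeps TM bundles far apart: no interacting pair
  gd <- genDimerConfiguration(41)
  expect_identical(nrow(interactingHelices(gd$frames[[1]])), 0L)

  ## a planted TM4-TM4 approach at 6 A is the single hit
  mkHelixPair <- function(sep) {
    za <- seq(0, 10.5, length.out = 8)
    a <- mkProt(1:16, rep(c("TM4", "TM5"), each = 8), "backbone",
                c(rep(0, 8), rep(-30, 8)), 0, c(za, za), ctermStart = 99)
    b <- mkProt(1:16, rep(c("TM4", "TM5"), each = 8), "backbone",
                c(rep(sep, 8), rep(sep + 30, 8)), 0, c(za, za),
                ctermStart = 99)
    mkConfig(a, b)
  }
  hit <- interactingHelices(mkHelixPair(6))
  expect_identical(nrow(hit), 1L)
  expect_identical(paste(hit$helixA, hit$helixB), "TM4 TM4")
  expect_equal(hit$minDistance, 6, tolerance = 1e-9)
  ## strictly below the cutoff: 7.0 exactly is not interacting
  expect_identical(nrow(interactingHelices(mkHelixPair(7))), 0L)

  ## random configurations equal the brute-force scan
  for (seed in 1:3) {
    set.seed(seed)
    mkr <- function() mkProt(1:14, rep(c("TM1", "TM2"), each = 7), "backbone",
                             runif(14, 0, 15), runif(14, 0, 15),
                             runif(14, 0, 15), ctermStart = 99)
    cfg <- mkConfig(mkr(), mkr())
    got <- interactingHelices(cfg)
    expect_identical(sort(paste(got$helixA, got$helixB)),
                     bruteInteractingHelices(cfg))
  }
})

test_that("interface classification separates symmetric and asymmetric dimers", {
  mkCS <- function(regionA, regionB) {
    n <- max(length(regionA), length(regionB))
    new("ContactSet", contacts = data.frame(
      residA = seq_len(n) + 290, residB = seq_len(n) + 290,
      regionA = regionA, regionB = regionB, type = "electrostatic",
      distance = 4, angle = NA_real_), frameIndex = 1L)
  }
  expect_identical(interfaceClass(classifyInterface(
    mkCS(rep("CTERM", 3), rep("CTERM", 3)))), "symmetric")
  expect_identical(interfaceClass(classifyInterface(
    mkCS(rep("CTERM", 3), rep("ICL3", 3)))), "asymmetric")
  empty <- new("ContactSet", contacts = contacts(mkCS("CTERM", "CTERM"))[0, ],
               frameIndex = 1L)
  expect_identical(interfaceClass(classifyInterface(empty)), "none")

  ## swap invariance: relabeling the protomers preserves the call
  mixed <- mkCS(c("CTERM", "CTERM", "CTERM", "ICL2"),
                c("CTERM", "CTERM", "ICL3", "CTERM"))
  swapped <- new("ContactSet", contacts = within(contacts(mixed), {
    tmp <- regionA; regionA <- regionB; regionB <- tmp; rm(tmp)
  })[, names(contacts(mixed))], frameIndex = 1L)
  expect_identical(interfaceClass(classifyInterface(mixed)),
                   interfaceClass(classifyInterface(swapped)))

  ## generator topologies round-trip through the full contact pipeline
  sym <- genDimerConfiguration(51, topology = "symmetric")
  cfg <- sym$frames[[1]]
  pooled <- poolContacts(electrostaticContacts(cfg),
                         hydrogenBonds(cfg), nonpolarContacts(cfg))
  expect_identical(interfaceClass(classifyInterface(pooled)), "symmetric")
  asym <- genDimerConfiguration(52, topology = "asymmetric")
  cfa <- asym$frames[[1]]
  pooledA <- poolContacts(electrostaticContacts(cfa),
                          hydrogenBonds(cfa, scope = NULL),
                          nonpolarContacts(cfa))
  expect_identical(interfaceClass(classifyInterface(pooledA)), "asymmetric")
})

test_that("Daura clustering reproduces hand-built neighbor structures", {
  base <- genDimerConfiguration(61, nFrames = 1, noiseSd = 0)$frames[[1]]
  shifted <- function(dz, idx) {
    sa <- protomerSites(protomerA(base)); sb <- protomerSites(protomerB(base))
    sa$z <- sa$z + dz; sb$z <- sb$z + dz
    hok <- is.finite(sa$hz); sa$hz[hok] <- sa$hz[hok] + dz
    hok <- is.finite(sb$hz); sb$hz[hok] <- sb$hz[hok] + dz
    DimerConfiguration(ProtomerModel(sa, ctermStart = 291),
                       ProtomerModel(sb, ctermStart = 291),
                       frameIndex = idx)
  }

  ## five identical frames form one cluster
  same <- lapply(1:5, function(i) shifted(0, i))
  cl <- dauraCluster(same, rmsdCutoff = 1.5)
  expect_identical(clusters(cl), list(1:5))

  ## cutoff zero with pairwise-distinct frames: all singletons
  distinct <- lapply(1:4, function(i) shifted(i * 3, i))
  cl0 <- dauraCluster(distinct, rmsdCutoff = 0, fit = FALSE)
  expect_identical(length(clusters(cl0)), 4L)
  expect_true(all(vapply(clusters(cl0), length, 1L) == 1L))

  ## constructed chain graph: z-offsets 0,1,2,10,11,20 at cutoff 1.5
  ## (no-fit RMSD equals the absolute z shift)
  frames <- Map(shifted, c(0, 1, 2, 10, 11, 20), 1:6)
  cl6 <- dauraCluster(frames, rmsdCutoff = 1.5, fit = FALSE)
  expect_identical(clusters(cl6), list(1:3, 4:5, 6L))
  expect_identical(representatives(cl6), c(2L, 4L, 6L))
})

test_that("Daura clustering matches an independent greedy implementation", {
  gd <- genDimerConfiguration(62, nFrames = 8, noiseSd = 1.2)
  frames <- gd$frames
  cl <- dauraCluster(frames, rmsdCutoff = 1.5)
  ## independent RMSD matrix from raw site coordinates
  xyzOf <- function(cfg) {
    sa <- protomerSites(protomerA(cfg)); sb <- protomerSites(protomerB(cfg))
    keep <- function(s) s[s$class == "backbone", c("x", "y", "z")]
    as.numeric(t(as.matrix(rbind(keep(sa), keep(sb)))))
  }
  n <- length(frames)
  R <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    R[i, j] <- bio3d::rmsd(xyzOf(frames[[i]]), xyzOf(frames[[j]]), fit = TRUE)
    R[j, i] <- R[i, j]
  }
  expect_identical(clusters(cl), bruteDaura(R, 1.5))

  ## partition: disjoint and exhaustive
  all_members <- sort(unlist(clusters(cl)))
  expect_identical(all_members, 1:n)

  ## re-clustering the representatives yields only singletons
  reps <- representatives(cl)
  cl2 <- dauraCluster(frames[reps], rmsdCutoff = 1.5)
  expect_true(all(vapply(clusters(cl2), length, 1L) == 1L))

  ## schema mismatch across frames is rejected
  small <- genDimerConfiguration(63, helixLength = 8)$frames[[1]]
  expect_error(dauraCluster(c(frames[1], list(small))),
               class = "validationError")
})

test_that("per-segment residue contact averaging is exact bookkeeping", {
  mkCS <- function(resA, resB) {
    new("ContactSet", contacts = data.frame(
      residA = resA, residB = resB,
      regionA = "CTERM", regionB = "CTERM", type = "electrostatic",
      distance = 4, angle = NA_real_), frameIndex = 1L)
  }
  seg <- list(early = c(291, 334), late = c(335, 394))

  ## identical frames: mean equals the single-frame count, sd zero
  cs <- mkCS(c(291, 292, 292, 340), c(336, 340, 341, 291))
  ## early: A{291,292} + B{291} = 3; late: A{340} + B{336,340,341} = 4
  avg <- averageContactCounts(list(cs, cs, cs), seg)
  expect_equal(avg$mean, c(3, 4))
  expect_equal(avg$sd, c(0, 0))

  ## two frames with planted counts 4 and 6 average to 5
  f1 <- mkCS(291:294, rep(400, 4))    # 4 distinct early residues
  f2 <- mkCS(291:296, rep(400, 6))    # 6 distinct early residues
  avg2 <- averageContactCounts(list(f1, f2), seg)
  expect_equal(avg2$mean[avg2$segment == "early"], 5)

  ## 10-frame planted series against hand bookkeeping
  set.seed(99)
  series <- lapply(1:10, function(i) {
    k <- sample(1:8, 1)
    mkCS(sample(291:334, k), rep(400, k))
  })
  counts <- vapply(series, function(s)
    length(unique(contacts(s)$residA)), 1)
  avg3 <- averageContactCounts(series, seg)
  expect_equal(avg3$mean[avg3$segment == "early"], mean(counts))
  expect_equal(avg3$sd[avg3$segment == "early"], sd(counts))

  ## event-counting mode counts contact rows, not distinct residues
  avgE <- averageContactCounts(list(cs), seg, mode = "events")
  expect_equal(avgE$mean[avgE$segment == "early"], 4)  # rows touching early

  expect_error(averageContactCounts(list(), seg), class = "validationError")
  expect_error(averageContactCounts(list(cs), list(c(1, 2))),
               class = "validationError")
})
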