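# structural module: parsing, SASA, interfaces, contacts, superposition

minipdb <- system.file("extdata", "mini.pdb", package = "epiScan")
minicif <- system.file("extdata", "mini.cif", package = "epiScan")

test_that("minimal PDB and mmCIF fixtures parse to the same 3-atom model", {
  p <- readStructure(minipdb)
  expect_identical(nrow(atoms(p)), 3L)
  expect_identical(unique(atoms(p)$chain), "A")
  expect_identical(unique(atoms(p)$resno), 1L)
  c_ <- readStructure(minicif)
  key <- function(a) a[order(a$elety), c("elety", "x", "y", "z")]
  expect_equal(key(atoms(p)), key(atoms(c_)), ignore_attr = TRUE)
})

test_that("alternate locations keep the highest-occupancy atom; waters drop", {
  a <- atoms(readStructure(system.file("extdata", "altloc.pdb",
                                       package = "epiScan")))
  expect_identical(nrow(a), 4L)               # N, CA, CB, OG; water excluded
  cb <- a[a$elety == "CB", ]
  expect_equal(cb$occ, 0.6)
  expect_equal(cb$x, 2.009)                   # the 0.6-occupancy conformer
  expect_false(any(a$resid == "HOH"))
})

test_that("selections follow chain[:resStart-resEnd] syntax", {
  s <- toyStructure("mini_interface")
  expect_identical(length(selectAtoms(s, "A")), 15L)
  expect_identical(length(selectAtoms(s, "A:2-3")), 10L)
  expect_identical(length(selectAtoms(s, c("A:1-1", "B"))), 20L)
  expect_error(selectAtoms(s, "A:2"), "range")
  expect_error(subsetStructure(s, "C"), "no atoms")
})

test_that("structures round-trip through the PDB writer", {
  s <- toyStructure("mini_interface")
  tf <- tempfile(fileext = ".pdb")
  writeStructurePdb(s, tf)
  back <- readStructure(tf)
  a0 <- atoms(s); a1 <- atoms(back)
  k <- function(a) a[order(a$chain, a$resno, a$elety),
                     c("chain", "resno", "resid", "elety", "x", "y", "z")]
  expect_equal(k(a0), k(a1), ignore_attr = TRUE)
})

test_that("single-sphere SASA matches the analytic sphere area within 1%", {
  s <- toyStructure("single_atom")
  analytic <- 4 * pi * (1.70 + 1.4)^2
  expect_lt(abs(sum(sasa(s)) - analytic) / analytic, 0.01)
})

test_that("distant spheres are unoccluded; overlapping spheres follow the cap formula", {
  far <- toyStructure("two_spheres", separation = 10)   # > 2 (r + probe)
  a_far <- sasa(far)
  full <- 4 * pi * (1.70 + 1.4)^2
  expect_equal(a_far, rep(full, 2), tolerance = 0.01)

  for (d in c(2.5, 4, 5.5)) {
    s <- toyStructure("two_spheres", separation = d)
    expect_equal(sasa(s), twoSphereCapSasa(d), tolerance = 0.02)
  }
})

test_that("SASA converges: doubling quadrature points moves totals < 0.5%", {
  s <- toyStructure("mini_interface")
  t1 <- sum(sasa(s, nPoints = 960))
  t2 <- sum(sasa(s, nPoints = 1920))
  expect_lt(abs(t2 - t1) / t1, 0.005)
})

test_that("unknown elements need an explicit fallback radius", {
  a <- atoms(toyStructure("single_atom"))
  a$element <- "FE"
  s <- Structure(a)
  expect_error(sasa(s), "FE")
  expect_equal(sum(sasa(s, fallbackRadius = 1.7)),
               sum(sasa(toyStructure("single_atom"))))
})

test_that("interface area is half the SASA lost and matches a two-body difference", {
  s <- toyStructure("mini_interface")
  rep_ <- analyzeInterface(s, "A", "B")
  # independent route: three explicit SASA sums on subsets
  sA <- sum(sasa(subsetStructure(s, "A")))
  sB <- sum(sasa(subsetStructure(s, "B")))
  sAB <- sum(sasa(s))
  expect_equal(interfaceArea(rep_), (sA + sB - sAB) / 2, tolerance = 1e-9)
  expect_gt(interfaceArea(rep_), 0)
  # per-residue buried areas sum to twice the interface (both sides count)
  expect_equal(sum(rep_@perResidue$buried), 2 * interfaceArea(rep_),
               tolerance = 0.01)
})

test_that("separated groups bury no area", {
  s <- toyStructure("two_spheres", separation = 30)
  rep_ <- analyzeInterface(s, "A", "B")
  expect_equal(interfaceArea(rep_), 0, tolerance = 1e-9)
})

test_that("interface area is symmetric and rigid-motion invariant", {
  s <- toyStructure("mini_interface")
  ab <- analyzeInterface(s, "A", "B")
  ba <- analyzeInterface(s, "B", "A")
  expect_equal(interfaceArea(ab), interfaceArea(ba), tolerance = 1e-9)
  moved <- applyRigid(s)
  expect_equal(interfaceArea(analyzeInterface(moved, "A", "B")),
               interfaceArea(ab), tolerance = 0.01 * interfaceArea(ab))
})

test_that("partitions must be disjoint and non-empty", {
  s <- toyStructure("mini_interface")
  expect_error(analyzeInterface(s, "A", "A"), "disjoint")
  expect_error(analyzeInterface(s, "C", "B"), "at least one atom")
})

test_that("backbone fraction separates side-chain-only from backbone-only burial", {
  s <- toyStructure("mini_interface")        # buried atoms are CB side chains
  rep_ <- analyzeInterface(s, "A", "B")
  expect_equal(unname(backboneFraction(rep_)[["A"]]), 0)

  # all-glycine strands: every atom is backbone, fraction is 1 on both sides
  a <- atoms(s)
  a <- a[a$elety != "CB", ]
  a$resid <- "GLY"
  a$y <- ifelse(a$chain == "B", a$y - 4.3, a$y)   # close the gap left by CB
  g <- Structure(a)
  repg <- analyzeInterface(g, "A", "B")
  expect_gt(interfaceArea(repg), 0)
  expect_equal(unname(backboneFraction(repg)), c(1, 1))

  # direct per-atom summation oracle on the mixed toy interface
  sA <- sasa(subsetStructure(s, "A"))
  sAB <- sasa(s)[seq_along(sA)]
  dpos <- pmax(0, sA - sAB)
  bb <- atoms(subsetStructure(s, "A"))$elety %in% c("N", "CA", "C", "O")
  expected <- if (sum(dpos) > 0) sum(dpos[bb]) / sum(dpos) else 0
  expect_equal(unname(backboneFraction(rep_)[["A"]]), expected)
})

test_that("the polyalanine toy interface has hydrophobic contacts and no H-bonds", {
  s <- toyStructure("mini_interface")
  ct <- detectContacts(s, "A", "B")
  expect_identical(sum(ct$type == "hydrogen_bond"), 0L)
  expect_gte(sum(ct$type == "hydrophobic"), 1L)
  expect_true(all(ct$atomA[ct$type == "hydrophobic"] == "CB"))
  expect_true(all(ct$distance[ct$type == "hydrophobic"] <= 4.5))
})

test_that("atoms beyond the cutoffs make no contacts", {
  s <- toyStructure("two_spheres", separation = 10)
  ct <- detectContacts(s, "A", "B")
  expect_identical(nrow(ct), 0L)
})

test_that("donor/acceptor typing finds a designed lysine-glutamate hydrogen bond", {
  a <- rbind(
    data.frame(chain = "A", resno = 1L, resid = "LYS", elety = "NZ",
               element = "N", x = 0, y = 0, z = 0, occ = 1),
    data.frame(chain = "B", resno = 1L, resid = "GLU", elety = "OE1",
               element = "O", x = 2.9, y = 0, z = 0, occ = 1),
    data.frame(chain = "B", resno = 2L, resid = "ALA", elety = "CB",
               element = "C", x = 0, y = 8, z = 0, occ = 1))
  ct <- detectContacts(Structure(a), "A", "B")
  expect_identical(nrow(ct), 1L)
  expect_identical(ct$type, "hydrogen_bond")
  expect_equal(ct$distance, 2.9)
  # two acceptors never bond: swap the lysine nitrogen for a carbonyl oxygen
  a2 <- a; a2$elety[1] <- "O"; a2$element[1] <- "O"; a2$resid[1] <- "GLY"
  ct2 <- detectContacts(Structure(a2), "A", "B")
  expect_identical(sum(ct2$type == "hydrogen_bond"), 0L)
})

test_that("contact residue labels collapse to one-letter + author number", {
  a <- rbind(
    data.frame(chain = "A", resno = 89L, resid = "LYS", elety = "NZ",
               element = "N", x = 0, y = 0, z = 0, occ = 1),
    data.frame(chain = "B", resno = 6L, resid = "ILE", elety = "O",
               element = "O", x = 2.9, y = 0, z = 0, occ = 1))
  ct <- detectContacts(Structure(a), "A", "B")
  expect_identical(contactResidues(ct, "A"), "K89")
  expect_identical(contactResidues(ct, "B"), "I6")
})

test_that("superposition of identical and rigidly moved copies gives zero RMSD", {
  s <- toyStructure("mini_interface")
  expect_equal(superposeRmsd(s, s, chainA = "A", chainB = "A")$rmsd, 0)
  set.seed(31)
  for (i in 1:5) {
    moved <- applyRigid(s, angle = runif(1, -pi, pi),
                        axis = rnorm(3), shift = rnorm(3, 0, 20))
    out <- superposeRmsd(s, moved, chainA = "A", chainB = "A",
                         atomNames = NULL)
    expect_lt(out$rmsd, 1e-6)
    expect_identical(out$nPaired, 15L)
  }
})

test_that("RMSD is invariant to rigid transforms of either input", {
  set.seed(32)
  s <- toyStructure("mini_interface")
  noisy <- atoms(s)
  noisy$x <- noisy$x + rnorm(nrow(noisy), 0, 0.3)
  noisy$y <- noisy$y + rnorm(nrow(noisy), 0, 0.3)
  noisy$z <- noisy$z + rnorm(nrow(noisy), 0, 0.3)
  n <- Structure(noisy)
  base <- superposeRmsd(s, n, chainA = "A", chainB = "A", atomNames = NULL)$rmsd
  expect_gt(base, 0)
  m1 <- superposeRmsd(applyRigid(s, 1.1, c(1, 2, 0.5), c(3, 3, 3)), n,
                      chainA = "A", chainB = "A", atomNames = NULL)$rmsd
  m2 <- superposeRmsd(s, applyRigid(n, -0.8, c(0, 1, 1), c(-9, 2, 4)),
                      chainA = "A", chainB = "A", atomNames = NULL)$rmsd
  expect_equal(m1, base, tolerance = 1e-9)
  expect_equal(m2, base, tolerance = 1e-9)
})

test_that("the Kabsch rotation is always proper and agrees with bio3d", {
  set.seed(33)
  for (i in 1:5) {
    P <- matrix(rnorm(30), ncol = 3)
    Q <- matrix(rnorm(30), ncol = 3)
    k <- kabsch(P, Q)
    expect_equal(det(k$rotation), 1, tolerance = 1e-9)
    # independent reference: bio3d's least-squares fit
    ref <- bio3d::rmsd(as.vector(t(Q)), as.vector(t(P)), fit = TRUE)
    expect_equal(k$rmsd, ref, tolerance = 1e-3)
  }
  # mirrored cloud: reflection must be corrected, not used
  P <- matrix(rnorm(30), ncol = 3)
  M <- P %*% diag(c(-1, 1, 1))
  k <- kabsch(P, M)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  expect_gt(k$rmsd, 0)
})

test_that("superposition needs at least three paired atoms", {
  s <- toyStructure("two_spheres")
  expect_error(superposeRmsd(s, s, chainA = "A", chainB = "A"),
               "three paired")
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "three")
})
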