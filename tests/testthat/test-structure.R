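test_that("PDB parsing resolves altlocs and keeps the first model", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   LYS A  15      10.000  10.000  10.000  1.00 20.00           N",
    "ATOM      2  CA  LYS A  15      11.458  10.000  10.000  1.00 20.00           C",
    "ATOM      3  NZ ALYS A  15      14.000  12.000  10.000  0.40 20.00           N",
    "ATOM      4  NZ BLYS A  15      14.500  12.000  10.000  0.60 20.00           N",
    "ATOM      5  CA  ASP A  42      20.000  10.000  10.000  1.00 20.00           C",
    "ATOM      6  OD2 ASP A  42      15.500  14.000  10.000  1.00 20.00           O",
    "ENDMDL",
    "MODEL        2",
    "ATOM      7  CA  LYS A  15      99.000  99.000  99.000  1.00 20.00           C",
    "ENDMDL",
    "END"), pdb)
  m <- loadStructure(pdb)
  a <- m@atoms
  expect_equal(nrow(a[a$elety == "NZ", ]), 1L)
  expect_equal(a$x[a$elety == "NZ"], 14.5)  # higher occupancy wins
  ## model 1 only: CA of LYS 15 at 11.458, not 99
  expect_equal(a$x[a$elety == "CA" & a$resno == 15], 11.458)
  expect_error(loadStructure(tempfile(fileext = ".pdb")), "not found")
  garbage <- tempfile(fileext = ".pdb")
  writeLines("this is not a structure", garbage)
  expect_error(loadStructure(garbage))
})

test_that("atom distances are exact, symmetric and zero on identity", {
  toy <- toyStructure()
  expect_equal(atomDistance(toy, c("A", 15, "CA"), c("A", 15, "CA")), 0)
  ## (2,0,0) -> (5.8,0,0): 3.8 A salt-bridge geometry
  expect_equal(atomDistance(toy, c("A", 15, "NZ"), c("A", 42, "OD2")), 3.8)
  expect_equal(atomDistance(toy, c("A", 42, "OD2"), c("A", 15, "NZ")), 3.8)
  ## 3-4-5 triangle through explicit coordinates
  t2 <- StructureModel(data.frame(
    chain = "A", resno = c(1L, 2L), resid = "GLY", elety = "CA",
    x = c(0, 3), y = c(0, 4), z = 0))
  expect_equal(atomDistance(t2, c("A", 1, "CA"), c("A", 2, "CA")), 5)
  expect_warning(d <- atomDistance(toy, c("A", 15, "NZ"), c("A", 99, "CA")),
                 "not found")
  expect_true(is.na(d))
})

test_that("distances are invariant under rigid-body transformation", {
  set.seed(13)
  toy <- toyStructure()
  ## random rotation (QR of a random matrix) + translation
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  tr <- rnorm(3, 0, 20)
  xyz <- as.matrix(toy@atoms[, c("x", "y", "z")])
  moved <- toy
  moved@atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2, -tr)
  pairs <- list(c(15, 42), c(15, 7), c(42, 7))
  for (p in pairs) {
    d0 <- atomDistance(toy, c("A", p[1], "CA"),
                       c(ifelse(p[2] == 7, "B", "A"), p[2], "CA"))
    d1 <- atomDistance(moved, c("A", p[1], "CA"),
                       c(ifelse(p[2] == 7, "B", "A"), p[2], "CA"))
    expect_equal(d1, d0, tolerance = 1e-9)
  }
})

test_that("crosslink restraint verdicts follow the distance threshold", {
  toy <- toyStructure()
  cmap <- c(P1 = "A", P2 = "B")
  ## CA(A15)=(0,0,0), CA(B7)=(0,20,0): 20 A apart
  chk <- checkCrosslink("P1:15--P2:7", toy, cmap, maxDist = 30)
  expect_equal(chk$distance, 20)
  expect_equal(chk$verdict, "satisfied")
  chk2 <- checkCrosslink("P1:15--P2:7", toy, cmap, maxDist = 15)
  expect_equal(chk2$verdict, "violated")
  ## monotone in the allowed distance
  verdicts <- sapply(c(10, 19, 21, 40), function(mx)
    checkCrosslink("P1:15--P2:7", toy, cmap, maxDist = mx)$verdict)
  expect_equal(verdicts, c("violated", "violated", "satisfied", "satisfied"))
  ## missing residue and unmapped protein are unmappable, not errors
  expect_equal(suppressWarnings(
    checkCrosslink("P1:15--P2:99", toy, cmap)$verdict), "unmappable")
  expect_equal(checkCrosslink("P1:15--Other:1", toy, cmap)$verdict,
               "unmappable")
})

test_that("salt-bridge detection finds acidic oxygens near lysine NZ", {
  toy <- toyStructure()
  ## NZ(A15)=(2,0,0); ASP42 OD2=(5.8,0,0) at 3.8 A
  sb <- detectSaltBridges(toy, c("A", 15), cutoff = 4.0)
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$resid, "ASP")
  expect_equal(sb$atom, "OD2")
  expect_equal(sb$distance, 3.8)
  ## broken bridge: below a tighter cutoff nothing is found
  expect_equal(nrow(detectSaltBridges(toy, c("A", 15), cutoff = 3.0)), 0L)
  ## missing NZ
  expect_warning(r <- detectSaltBridges(toy, c("A", 42)), "NZ not found")
  expect_null(r)
})
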