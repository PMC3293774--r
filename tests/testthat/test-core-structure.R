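test_that("PDB text with a metal heteroatom parses into the hierarchy", {
  txt <- paste(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       1.500   2.500   3.500  1.00  0.00           C",
    "HETATM    3 ZN    ZN A 101       0.000   0.000   0.000  1.00  0.00          ZN",
    "END", sep = "\n")
  s <- read_structure(txt)
  expect_equal(nrow(s), 3)
  expect_equal(unique(s$chain), "A")
  expect_equal(s$het, c(FALSE, FALSE, TRUE))
  expect_equal(s$element[3], "ZN")
  expect_equal(s$x, c(1, 1.5, 0))
})

test_that("write/read round trip preserves names and 3-decimal coordinates", {
  dna <- fx_dna10()
  txt <- write_structure(dna)
  back <- read_structure(txt)
  expect_equal(nrow(back), nrow(dna))
  expect_equal(back$atom, dna$atom)
  expect_equal(back$chain, dna$chain)
  expect_equal(back$resno, dna$resno)
  expect_equal(back$x, round(dna$x, 3))
  expect_equal(back$y, round(dna$y, 3))
  expect_equal(back$z, round(dna$z, 3))
})

test_that("writer output is deterministic, chains are TER-terminated", {
  dna <- fx_dna10()
  t1 <- write_structure(dna)
  t2 <- write_structure(dna)
  expect_identical(t1, t2)
  lines <- strsplit(t1, "\n")[[1]]
  expect_equal(sum(grepl("^TER", lines)), 2)  # two chains
  expect_equal(lines[length(lines)], "END")
  # TER sits between the chains
  terpos <- grep("^TER", lines)
  chainA_last <- max(grep(" A ", lines[seq_len(terpos[1])], fixed = TRUE))
  expect_lt(chainA_last, terpos[1] + 1)
})

test_that("parse errors name the offending line; empty input errors", {
  bad <- paste(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       1.5xx   2.500   3.500  1.00  0.00           C",
    sep = "\n")
  expect_error(read_structure(bad), "line 2")
  expect_error(read_structure(""), "empty")
  expect_error(read_structure("REMARK nothing here"), "no ATOM")
})

test_that("atom names longer than the field width are rejected on write", {
  s <- one_atom()
  s$atom <- "TOOLONG"
  expect_error(write_structure(s), "atom name")
})

test_that("only the first model is read; altlocs keep highest occupancy", {
  multi <- paste(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       9.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL", sep = "\n")
  s <- read_structure(multi)
  expect_equal(nrow(s), 1)
  expect_equal(s$x, 1)
  alt <- paste(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    sep = "\n")
  a <- read_structure(alt)
  expect_equal(nrow(a), 1)
  expect_equal(a$x, 2)
})

test_that("parser agrees with bio3d on a round-tripped structure", {
  skip_if_not_installed("bio3d")
  dna <- fx_dna10()
  tf <- tempfile(fileext = ".pdb")
  write_structure(dna, tf)
  ours <- read_structure(tf)
  theirs <- suppressWarnings(bio3d::read.pdb(tf))
  expect_equal(nrow(ours), nrow(theirs$atom))
  expect_equal(ours$x, theirs$atom$x)
  expect_equal(ours$y, theirs$atom$y)
  expect_equal(ours$z, theirs$atom$z)
  expect_equal(ours$atom, theirs$atom$elety)
})

test_that("superpose recovers a known rigid transform and guards reflections", {
  a <- point_cloud(10)
  expect_equal(superpose(a, a)$rmsd, 0, tolerance = 1e-9)
  id <- superpose(a, a)$transform
  expect_equal(id$R, diag(3), tolerance = 1e-9)

  tf0 <- random_rotation(7)
  tf0 <- rigid_transform(tf0$R, c(4, -2, 9))
  b <- apply_transform(a, tf0)
  fit <- superpose(a, b)
  expect_equal(fit$transform$R, tf0$R, tolerance = 1e-6)
  expect_equal(fit$transform$t, tf0$t, tolerance = 1e-6)
  expect_lt(fit$rmsd, 1e-6)

  # chiral 4-point set mirrored: returned rotation must stay proper
  chir <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE)
  mirr <- chir %*% diag(c(1, 1, -1))
  fitm <- superpose(chir, mirr)
  expect_equal(det(fitm$transform$R), 1, tolerance = 1e-9)
  expect_gt(fitm$rmsd, 0.1)  # a mirror image cannot be superposed rigidly
})

test_that("superpose rejects degenerate input", {
  expect_error(superpose(point_cloud(2), point_cloud(2)), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line), "collinear")
})

test_that("superpose rmsd is invariant to pre-rotation of both sets", {
  a <- point_cloud(12, seed = 5)
  b <- apply_transform(a, random_rotation(9)) + 0.1 * point_cloud(12, seed = 6)
  r1 <- superpose(a, b)$rmsd
  R0 <- random_rotation(11)
  r2 <- superpose(apply_transform(a, R0), b)$rmsd
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("rigid transforms form a group under compose/invert", {
  tfs <- lapply(1:3, function(i) {
    r <- random_rotation(i)
    rigid_transform(r$R, c(i, -i, 2 * i))
  })
  x <- point_cloud(6, seed = 3)
  # composition applies right-to-left
  expect_equal(
    apply_transform(x, compose_transform(tfs[[1]], tfs[[2]])),
    apply_transform(apply_transform(x, tfs[[2]]), tfs[[1]]),
    tolerance = 1e-9)
  # associativity
  lhs <- compose_transform(compose_transform(tfs[[1]], tfs[[2]]), tfs[[3]])
  rhs <- compose_transform(tfs[[1]], compose_transform(tfs[[2]], tfs[[3]]))
  expect_equal(apply_transform(x, lhs), apply_transform(x, rhs),
               tolerance = 1e-9)
  # identity and inverse
  expect_equal(apply_transform(x, compose_transform(tf_identity(), tfs[[1]])),
               apply_transform(x, tfs[[1]]), tolerance = 1e-12)
  rt <- compose_transform(tfs[[1]], invert_transform(tfs[[1]]))
  expect_equal(rt$R, diag(3), tolerance = 1e-9)
  expect_equal(rt$t, c(0, 0, 0), tolerance = 1e-9)
})

test_that("apply_transform preserves all pairwise distances", {
  dna <- fx_dna10()
  tf <- rigid_transform(random_rotation(13)$R, c(10, 20, -5))
  moved <- apply_transform(dna, tf)
  expect_equal(pairwise_dists(moved), pairwise_dists(dna), tolerance = 1e-9)
  # apply then inverse returns the original coordinates
  back <- apply_transform(moved, invert_transform(tf))
  expect_equal(back$x, dna$x, tolerance = 1e-9)
  expect_equal(back$z, dna$z, tolerance = 1e-9)
})

test_that("improper or non-orthonormal rotations are rejected", {
  expect_error(rigid_transform(diag(c(1, 1, -1)), c(0, 0, 0)), "proper")
  expect_error(rigid_transform(matrix(1, 3, 3), c(0, 0, 0)))
})
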