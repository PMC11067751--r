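# Unit cells, coordinate transforms, symmetry operators and PDB parsing.

test_that("symop strings parse to the exact rotation and translation", {
  id <- parse_symop("X,Y,Z")
  expect_equal(id$rotation, diag(3))
  expect_equal(id$translation, c(0, 0, 0))

  op <- parse_symop("-X,-Y,Z+1/2")
  expect_equal(op$rotation, diag(c(-1, -1, 1)))
  expect_equal(op$translation, c(0, 0, 0.5))

  op <- parse_symop("Y+1/2,X+1/2,-Z+1/4")
  expect_equal(op$rotation,
               matrix(c(0, 1, 0, 1, 0, 0, 0, 0, -1), 3, byrow = TRUE))
  expect_equal(op$translation, c(0.5, 0.5, 0.25))

  # case/whitespace tolerant; translations reduced into [0, 1)
  op2 <- parse_symop(" y + 1/2 , x+1/2, -z + 5/4 ")
  expect_equal(op2$rotation, op$rotation)
  expect_equal(op2$translation, op$translation)

  expect_error(parse_symop("W,Y,Z"), "parse")
  expect_error(parse_symop("X,Y"), "three")
})

test_that("the tetragonal operator set is a closed group of 8 with inverses", {
  sg <- space_group("P 43 21 2")
  expect_identical(length(sg$ops), 8L)
  idx_of <- function(op) {
    hits <- which(vapply(sg$ops, metalloscan:::symop_equal, logical(1),
                         b = op))
    expect_length(hits, 1)
    hits
  }
  # closure and inverses, modulo lattice translations
  for (a in sg$ops) {
    for (b in sg$ops) idx_of(metalloscan:::symop_compose(a, b))
    idx_of(metalloscan:::symop_inverse(a))
  }
  # identity present
  idx_of(metalloscan:::symop(diag(3), c(0, 0, 0)))
})

test_that("symmetry operators are isometries of the cell", {
  cell <- unit_cell(81.12, 81.12, 37.19)
  sg <- space_group("p43212")  # spacing/case-insensitive lookup
  set.seed(11)
  for (rep in 1:5) {
    p <- runif(3); q <- runif(3)
    d0 <- sqrt(sum((frac_to_orth(cell, p) - frac_to_orth(cell, q))^2))
    for (op in sg$ops) {
      d1 <- sqrt(sum((frac_to_orth(cell, symop_apply(op, p)) -
                        frac_to_orth(cell, symop_apply(op, q)))^2))
      expect_equal(d1, d0, tolerance = 1e-9)
    }
  }
})

test_that("orthogonal/fractional transforms invert each other", {
  cell <- unit_cell(81.12, 81.12, 37.19)
  expect_equal(orth_to_frac(cell, c(81.12, 0, 0)), c(1, 0, 0),
               tolerance = 1e-12)
  expect_equal(orth_to_frac(cell, c(0, 0, 0)), c(0, 0, 0))
  # componentwise division for an all-90 cell
  expect_equal(orth_to_frac(cell, c(8.112, 16.224, 3.719)),
               c(0.1, 0.2, 0.1), tolerance = 1e-12)
  set.seed(4)
  tric <- unit_cell(30, 40, 50, 80, 95, 110)
  for (rep in 1:10) {
    v <- rnorm(3, sd = 20)
    expect_equal(frac_to_orth(tric, orth_to_frac(tric, v)), v,
                 tolerance = 1e-9)
  }
  expect_error(unit_cell(10, 10, 10, 0, 90, 90), "angles")
  expect_error(unit_cell(-1, 10, 10), "positive")
})

test_that("PDB files round-trip through write and read", {
  cfg <- minimal_config(seed = 3)
  res <- generate_series(cfg, tempfile("rt"))
  path <- file.path(dirname(res$manifest_path), res$manifest[[1]]$path)
  s1 <- read_structure(path, meta = list(week = 1, wavelength = 0.976))
  expect_s3_class(s1, "xtal_structure")
  expect_identical(length(s1$space_group$ops), 8L)
  expect_equal(s1$cell$a, 81.1, tolerance = 1e-6)
  expect_equal(s1$cell$c, 37.2, tolerance = 1e-6)

  p2 <- tempfile(fileext = ".pdb")
  write_structure(s1, p2)
  s2 <- read_structure(p2)
  expect_identical(nrow(s2$atoms), nrow(s1$atoms))
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(s1$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_identical(s2$atoms$element, s1$atoms$element)
  expect_equal(s2$atoms$occ, s1$atoms$occ, tolerance = 1e-6)
})

test_that("parser errors are specific: CRYST1, empty, malformed, unknown group", {
  no_cryst <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      10.000  10.000  10.000  1.00 15.00           C",
    "END"), no_cryst)
  expect_error(read_structure(no_cryst), "CRYST1")

  empty <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   81.120   81.120   37.190  90.00  90.00  90.00 P 43 21 2",
    "END"), empty)
  expect_error(read_structure(empty), "ATOM")

  bad <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   81.120   81.120   37.190  90.00  90.00  90.00 P 43 21 2",
    "ATOM      1  CA  ALA A   1      xx.xxx  10.000  10.000  1.00 15.00           C",
    "END"), bad)
  expect_error(suppressWarnings(read_structure(bad)), "line 2")

  unk <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   50.000   60.000   70.000  90.00  90.00  90.00 P 21 21 21",
    "ATOM      1  CA  ALA A   1      10.000  10.000  10.000  1.00 15.00           C",
    "END"), unk)
  expect_error(read_structure(unk), "P 43 21 2")

  notsquare <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   81.120   80.000   37.190  90.00  90.00  90.00 P 43 21 2",
    "ATOM      1  CA  ALA A   1      10.000  10.000  10.000  1.00 15.00           C",
    "END"), notsquare)
  expect_error(read_structure(notsquare), "tetragonal")
})

test_that("parser keeps altlocs and reads occupancy/B as printed", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   20.000   20.000   20.000  90.00  90.00  90.00 P 1",
    "ATOM      1  CA AALA A   1      10.000  10.000  10.000  0.60 15.50           C",
    "ATOM      2  CA BALA A   1      10.500  10.000  10.000  0.40 16.50           C",
    "HETATM    3 RE   REI A 201       5.000   5.000   5.000  0.68 12.00          RE",
    "END"), p)
  s <- read_structure(p)
  expect_identical(nrow(s$atoms), 3L)
  expect_setequal(s$atoms$altloc[1:2], c("A", "B"))
  expect_equal(s$atoms$occ, c(0.60, 0.40, 0.68))
  expect_equal(s$atoms$b[1], 15.5)
  expect_identical(s$atoms$element[3], "RE")
})
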