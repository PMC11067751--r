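# Ring planes, interplanar angles, stacking classes and the cage network.

pentagon_xy <- function(r = 1.17, z = 0) {
  th <- (0:4) * 2 * pi / 5
  cbind(r * cos(th), r * sin(th), z)
}

test_that("a planar pentagon fits with zero rmsd and a perpendicular normal", {
  ring <- fit_ring(pentagon_xy())
  expect_equal(ring$planarity_rmsd, 0, tolerance = 1e-12)
  expect_equal(abs(ring$normal), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(ring$centroid, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(sqrt(sum(ring$normal^2)), 1, tolerance = 1e-12)
  expect_error(fit_ring(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")
  expect_error(fit_ring(rbind(c(0, 0, 0), c(1, 0, 0))), "3")
})

test_that("least-squares plane matches a brute-force orientation search", {
  pts <- pentagon_xy()
  pts[2, 3] <- 0.1  # one atom displaced out of plane
  ring <- fit_ring(pts)
  rms_about <- function(angles) {
    n <- c(sin(angles[1]) * cos(angles[2]), sin(angles[1]) * sin(angles[2]),
           cos(angles[1]))
    d <- pts %*% n
    sqrt(mean((d - mean(d))^2))
  }
  # coarse grid then local refinement, independent of the SVD route
  grid <- expand.grid(t = seq(0, pi, length.out = 60),
                      p = seq(0, 2 * pi, length.out = 120))
  vals <- apply(grid, 1, rms_about)
  st <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(st, rms_about, method = "Nelder-Mead",
                      control = list(reltol = 1e-14))
  expect_equal(ring$planarity_rmsd, opt$value, tolerance = 1e-6)
})

test_that("interplanar angles fold into [0, 90] degrees", {
  expect_equal(interplanar_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(interplanar_angle(c(0, 0, 1), c(0, 0, -1)), 0)
  expect_equal(interplanar_angle(c(0, 0, 1), c(1, 0, 0)), 90)
  expect_equal(interplanar_angle(c(0, 0, 1), c(0, sin(pi / 3), cos(pi / 3))),
               60, tolerance = 1e-9)
  expect_error(interplanar_angle(c(0, 0, 0), c(0, 0, 1)), "zero")
})

test_that("stacking classes follow the distance/angle criteria", {
  expect_identical(classify_stacking(3.5, 10), "face_to_face")
  expect_identical(classify_stacking(5.0, 85), "edge_to_face")
  expect_identical(classify_stacking(6.0, 10), "none")
  expect_identical(classify_stacking(6.0, 80), "none")
  expect_identical(classify_stacking(4.16, 45.6), "intermediate")
  expect_identical(classify_stacking(4.5, 10), "none")  # the small-molecule gap
  # angles outside [0,90] are folded first
  expect_identical(classify_stacking(5.0, 110), "edge_to_face")
  # macromolecular criteria
  expect_identical(classify_stacking(3.5, 10, "macromolecular"),
                   "face_to_face")
  expect_identical(classify_stacking(4.0, 10, "macromolecular"), "none")
  ef <- classify_stacking(5.2, 70, "macromolecular")
  expect_identical(as.character(ef), "edge_to_face")
  expect_false(attr(ef, "in_ef_band"))
  ef2 <- classify_stacking(4.99, 70, "macromolecular")
  expect_true(attr(ef2, "in_ef_band"))
  expect_error(classify_stacking(-1, 10), "distance")
})

test_that("centroids and angles are invariant under rigid motions", {
  set.seed(17)
  a <- pentagon_xy()
  b <- sweep(pentagon_xy(), 2, c(2.5, 3.0, 1.5), "+")
  d0 <- sqrt(sum((fit_ring(a)$centroid - fit_ring(b)$centroid)^2))
  a0 <- interplanar_angle(fit_ring(a)$normal, fit_ring(b)$normal)
  for (rep in 1:10) {
    r <- random_rotation()
    t <- rnorm(3, sd = 10)
    ar <- sweep(a %*% t(r), 2, t, "+")
    br <- sweep(b %*% t(r), 2, t, "+")
    expect_equal(sqrt(sum((fit_ring(ar)$centroid - fit_ring(br)$centroid)^2)),
                 d0, tolerance = 1e-9)
    expect_equal(interplanar_angle(fit_ring(ar)$normal, fit_ring(br)$normal),
                 a0, tolerance = 1e-9)
  }
})

test_that("the planted four-imidazole cage is recovered with exact distances", {
  res <- generate_series(three_week_config(seed = 8), tempfile("rn"))
  base <- dirname(res$manifest_path)
  e <- res$manifest[[3]]
  s <- read_structure(file.path(base, e$path))
  net <- find_ring_network(s, model = precision_model(0.026))
  expect_identical(nrow(net$pairs), 4L)
  expect_identical(max(net$pairs$cage), 1L)
  # four rings in the single cage component
  expect_identical(sum(!is.na(net$rings$cage)), 4L)
  expect_equal(sort(net$pairs$distance), sort(c(4.16, 4.20, 4.83, 5.04)),
               tolerance = 2e-3)
  expect_true(all(net$pairs$label %in% c("edge_to_face", "intermediate")))
  expect_equal(net$pairs$su, rep(sqrt(2) * 0.026, 4), tolerance = 1e-9)
  expect_true(all(net$pairs$angle >= 0 & net$pairs$angle <= 90))
})

test_that("an isolated ring yields no interactions", {
  res <- generate_series(minimal_config(seed = 3), tempfile("iso"))
  s <- read_structure(file.path(dirname(res$manifest_path),
                                res$manifest[[1]]$path))
  net <- find_ring_network(s)
  # the His ring and its own complex imidazole are metal-bridged: excluded
  expect_identical(nrow(net$pairs), 0L)
  net2 <- find_ring_network(s, exclude_metal_bridged = FALSE)
  expect_gt(nrow(net2$pairs), 0)
})

test_that("ligand imidazole rings are found by connectivity, His by name", {
  res <- generate_series(three_week_config(seed = 8), tempfile("fr"))
  s <- read_structure(file.path(dirname(res$manifest_path),
                                res$manifest[[3]]$path))
  rings <- find_rings(s)
  rn <- vapply(rings, function(r) r$ring_id$res_name, character(1))
  expect_true("HIS" %in% rn)
  expect_true(sum(rn == "VHL") == 4)  # two per ImiImi complex
  expect_true(sum(rn == "REI") == 1)
  # planarity limited only by the 1e-3 A precision of PDB coordinates
  expect_true(all(vapply(rings, function(r) r$planarity_rmsd, numeric(1))
                  < 2e-3))
})
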