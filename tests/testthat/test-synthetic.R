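# The fixture generator: geometry of the planted complexes, determinism,
# and end-to-end parameter recovery.

test_that("the facial complex has ideal octahedral geometry", {
  cx <- build_complex("ImiImi", donor_xyz = c(10, 10, 10),
                      direction = c(0, 0, 1), re_donor_distance = 2.14)
  at <- cx$atoms
  re <- as.numeric(at[at$name == "RE", c("x", "y", "z")])
  vec <- function(nm) as.numeric(at[at$name == nm, c("x", "y", "z")]) - re
  ang <- function(u, v) acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  # three mutually cis carbonyls at 90 degrees
  expect_equal(ang(vec("C1"), vec("C2")), 90, tolerance = 1e-6)
  expect_equal(ang(vec("C1"), vec("C3")), 90, tolerance = 1e-6)
  expect_equal(ang(vec("C2"), vec("C3")), 90, tolerance = 1e-6)
  # Re-C 1.92 and collinear C-O at 1.15
  expect_equal(sqrt(sum(vec("C1")^2)), 1.92, tolerance = 1e-9)
  expect_equal(sqrt(sum(vec("O1")^2)), 1.92 + 1.15, tolerance = 1e-9)
  expect_equal(ang(vec("C1"), vec("O1")), 0, tolerance = 1e-6)
  # imidazole N at the coordination distance, donor at the requested one
  expect_equal(sqrt(sum(vec("N1A")^2)), 2.185, tolerance = 1e-9)
  expect_equal(sqrt(sum((re - c(10, 10, 10))^2)), 2.14, tolerance = 1e-9)
  # ring counts per kind
  expect_identical(sum(grepl("^N1", at$name)), 2L)
  aq <- build_complex("ImiAqua", c(0, 0, 0), c(1, 0, 0), 2.185)
  expect_identical(sum(grepl("^N1", aq$atoms$name)), 1L)
  expect_true("O4" %in% aq$atoms$name)
  expect_error(build_complex("ImiImi", c(0, 0, 0), c(1, 0, 0), 1.0),
               "1.8")
})

test_that("complex internal geometry is rigid under reorientation", {
  d1 <- build_complex("ImiImi", c(0, 0, 0), c(0, 0, 1), 2.14)$atoms
  set.seed(5)
  r <- random_rotation()
  frame <- r %*% diag(3)
  d2 <- build_complex("ImiImi", c(0, 0, 0), frame[, 3], 2.14,
                      frame = frame)$atoms
  dist_all <- function(a) sort(dist(as.matrix(a[, c("x", "y", "z")])))
  expect_equal(dist_all(d2), dist_all(d1), tolerance = 1e-9)
})

test_that("fixture outputs are byte-identical for a fixed seed", {
  d1 <- tempfile("det1"); d2 <- tempfile("det2")
  generate_series(three_week_config(seed = 42, jitter = 0.02), d1)
  generate_series(three_week_config(seed = 42, jitter = 0.02), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  d3 <- tempfile("det3")
  generate_series(three_week_config(seed = 43, jitter = 0.02), d3)
  f1 <- readLines(file.path(d1, list.files(d1)[1]))
  f3 <- readLines(file.path(d3, list.files(d3)[1]))
  expect_false(identical(f1, f3))
})

test_that("manifest statistics reproduce the requested DPI targets", {
  res <- generate_series(three_week_config(seed = 2), tempfile("dpi"))
  targets <- c(0.084, 0.072, 0.026)
  for (i in seq_along(res$manifest)) {
    st <- metalloscan:::stats_from_list(res$manifest[[i]]$stats)
    expect_equal(cruickshank_dpi(st), targets[i], tolerance = 0.002)
  }
})

test_that("config validation names the offending field", {
  expect_error(fixture_config(sites = list(
    list(res_name = "HIS", chain = "A", res_seq = 15, kind = "ImiAqua",
         distance = 2.185, occupancy = rep(1.5, 7), b = 20))),
    "occupancy")
  expect_error(fixture_config(sites = list(
    list(res_name = "HIS", chain = "A", res_seq = 15, kind = "ImiAqua",
         distance = 1.2, occupancy = rep(0.5, 7), b = 20))),
    "distance")
  expect_error(fixture_config(wavelengths = 0.976), "week")
  # unsatisfiable cage geometry fails before writing anything
  bad <- three_week_config(seed = 1)
  bad$cage$distances <- c(1.0, 20.0, 4.8, 5.0)
  out <- tempfile("nofiles")
  expect_error(generate_series(bad, out), "triangle")
})

test_that("zero-jitter series pass occupancies and distances straight through", {
  res <- generate_series(three_week_config(seed = 20), tempfile("e2e"))
  out <- cmd_series(res$manifest_path)
  keys <- vapply(out$trajectories, function(t) t$site_key, character(1))
  his <- out$trajectories[[match("A/HIS15", keys)]]
  expect_equal(his$points$occupancy, c(0.5, 0.6, 0.7))
  expect_equal(his$points$distance, rep(2.185, 3), tolerance = 2e-3)
  expect_identical(
    out$trends$direction[out$trends$site == "A/HIS15" &
                           out$trends$attribute == "occupancy"],
    "increasing")
  # all planted labels recovered
  expect_true(all(his$points$label == "covalent"))
})

test_that("jittered distances are recovered within 3 combined su over 20 seeds", {
  planted <- 2.185
  for (seed in 1:20) {
    cfg <- minimal_config(seed = seed, jitter = 0.02)
    res <- generate_series(cfg, tempfile("jit"))
    e <- res$manifest[[1]]
    base <- dirname(res$manifest_path)
    s <- read_structure(file.path(base, e$path))
    sites <- find_metal_sites(s)
    model <- precision_model(
      cruickshank_dpi(metalloscan:::stats_from_list(e$stats)))
    sites <- attach_precision(sites, model)
    prot <- sites[[1]]$ligands[
      metalloscan:::is_protein_res(sites[[1]]$ligands$res_name), ]
    i <- which.min(prot$distance)
    # combined uncertainty: propagated model su plus the planted jitter
    su_tot <- sqrt(prot$su[i]^2 + 2 * 0.02^2)
    expect_lt(abs(prot$distance[i] - planted), 3 * su_tot)
  }
})

test_that("distance errors scale like sigma * sqrt(2) under jitter", {
  errs <- vapply(1:120, function(seed) {
    cfg <- minimal_config(seed = seed, jitter = 0.02)
    res <- generate_series(cfg, tempfile("sd"))
    s <- read_structure(file.path(dirname(res$manifest_path),
                                  res$manifest[[1]]$path))
    prot <- find_metal_sites(s)[[1]]$ligands
    prot <- prot[metalloscan:::is_protein_res(prot$res_name), ]
    min(prot$distance) - 2.185
  }, numeric(1))
  expect_equal(stats::sd(errs), 0.02 * sqrt(2), tolerance = 0.2)
  expect_lt(abs(mean(errs)), 0.01)
})

test_that("planted covalent and weak labels survive jitter of 0.03", {
  for (seed in 1:6) {
    cfg <- fixture_config(
      weeks = 1, wavelengths = 0.976,
      sites = list(
        list(res_name = "HIS", chain = "A", res_seq = 15, kind = "ImiAqua",
             distance = 2.185, occupancy = 0.8, b = 20),
        list(res_name = "ASN", chain = "A", res_seq = 46, kind = "ImiAqua",
             distance = 2.6, occupancy = 0.3, b = 20)),
      cage = NULL, jitter_sigma = 0.03, peak_noise = 0,
      dpi = 0.026, d_min = 1.23, seed = seed)
    res <- generate_series(cfg, tempfile("lbl"))
    e <- res$manifest[[1]]
    ana <- cmd_analyze(file.path(dirname(res$manifest_path), e$path),
                       stats = e$stats)
    his <- ana$calls[ana$calls$res_seq == 15 & ana$calls$atom == "NE2", ]
    asn <- ana$calls[ana$calls$res_seq == 46 & ana$calls$atom == "ND2", ]
    expect_identical(his$label, "covalent")
    expect_identical(asn$label, "weak")
  }
})
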