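# Site matching across structures, trends, residue shifts, reports.

series_analyses <- function(seed = 1) {
  res <- generate_series(three_week_config(seed = seed), tempfile("ts"))
  cmd_series(res$manifest_path, out_dir = NULL)
}

test_that("conserved sites merge into one trajectory per binding residue", {
  out <- series_analyses(seed = 10)
  keys <- vapply(out$trajectories, function(t) t$site_key, character(1))
  expect_setequal(keys, c("A/HIS15", "A/ASP101", "A/ASP119"))
  his <- out$trajectories[[match("A/HIS15", keys)]]
  expect_identical(nrow(his$points), 3L)
  expect_equal(his$points$week, c(1, 3, 9))
  expect_equal(his$points$occupancy, c(0.5, 0.6, 0.7))
  # trajectories partition the sites: 3 structures x 3 sites = 9 points
  expect_identical(sum(vapply(out$trajectories, function(t)
    nrow(t$points), integer(1))), 9L)
})

test_that("a site present at a single time point becomes a singleton", {
  cfg <- fixture_config(
    weeks = c(1, 3), wavelengths = c(0.976, 0.976),
    sites = list(
      list(res_name = "HIS", chain = "A", res_seq = 15, kind = "ImiAqua",
           distance = 2.185, occupancy = c(0.5, 0.6), b = 20),
      list(res_name = "ASN", chain = "A", res_seq = 46, kind = "ImiAqua",
           distance = 2.43, occupancy = c(NA, 0.2), b = 20)),
    cage = NULL, jitter_sigma = 0, peak_noise = 0,
    dpi = c(0.03, 0.03), d_min = c(1.3, 1.3), seed = 2)
  res <- generate_series(cfg, tempfile("sg"))
  out <- cmd_series(res$manifest_path)
  keys <- vapply(out$trajectories, function(t) t$site_key, character(1))
  asn <- out$trajectories[[match("A/ASN46", keys)]]
  expect_identical(nrow(asn$points), 1L)
  expect_equal(asn$points$week, 3)
})

test_that("duplicate week/wavelength points for one site are rejected", {
  out <- series_analyses(seed = 1)
  dup <- c(out$analyses, out$analyses[1])
  expect_error(match_sites(dup), "duplicate")
})

test_that("non-isomorphous cells trigger a warning", {
  out <- series_analyses(seed = 1)
  mod <- out$analyses
  mod[[2]]$structure$cell <- unit_cell(85, 85, 37.2)
  expect_warning(match_sites(mod), "isomorphous")
})

test_that("Kendall trends match hand-enumerated pair counts", {
  # occupancies over four synchrotron time points: 4 concordant pairs,
  # 1 discordant, 1 tied -> tau-b = 3 / sqrt(6 * 5)
  tr <- site_trend(c(0.75, 0.68, 0.84, 0.84), c(3, 9, 18, 38), "occupancy")
  expect_equal(tr$tau, 3 / sqrt(30), tolerance = 1e-9)
  expect_identical(tr$direction, "increasing")
  # constant series: flat, not NA
  tr <- site_trend(c(0.5, 0.5, 0.5), c(1, 2, 3))
  expect_identical(tr$tau, 0)
  expect_identical(tr$direction, "flat")
  # strictly decreasing
  tr <- site_trend(c(3, 2, 1), c(1, 2, 3))
  expect_identical(tr$tau, -1)
  expect_identical(tr$direction, "decreasing")
  # antisymmetry
  x <- c(0.2, 0.5, 0.4, 0.9)
  expect_equal(site_trend(x, 1:4)$tau, -site_trend(-x, 1:4)$tau)
  # too few points
  tr <- site_trend(c(1, 2), c(1, 2))
  expect_identical(tr$direction, "insufficient")
})

test_that("trends are computed within one wavelength group", {
  cfg <- fixture_config(
    weeks = c(1, 3, 9, 11), wavelengths = c(1.5418, 0.976, 0.976, 0.976),
    sites = list(list(res_name = "HIS", chain = "A", res_seq = 15,
                      kind = "ImiAqua", distance = 2.185,
                      occupancy = c(0.9, 0.5, 0.6, 0.7), b = 20)),
    cage = NULL, jitter_sigma = 0, peak_noise = 0,
    dpi = rep(0.03, 4), d_min = rep(1.3, 4), seed = 3)
  res <- generate_series(cfg, tempfile("wl"))
  out <- cmd_series(res$manifest_path)
  tr <- out$trends
  occ <- tr[tr$attribute == "occupancy", ]
  # laboratory group has 1 point (insufficient); synchrotron group rises
  expect_identical(occ$direction[occ$wavelength == 1.5418], "insufficient")
  expect_identical(occ$direction[occ$wavelength == 0.976], "increasing")
  expect_equal(occ$tau[occ$wavelength == 0.976], 1)
})

test_that("residue shifts measure planted displacements exactly", {
  res <- generate_series(minimal_config(seed = 4), tempfile("rs"))
  s <- read_structure(file.path(dirname(res$manifest_path),
                                res$manifest[[1]]$path))
  sh <- residue_shift(s, s, "A", 15)
  expect_equal(sh$max, 0)
  expect_equal(sh$mean, 0)

  s2 <- s
  move <- s2$atoms$chain == "A" & s2$atoms$res_seq == 15 &
    s2$atoms$name %in% c("NE2", "CE1")
  s2$atoms$x[move] <- s2$atoms$x[move] + 0.3
  s2$atoms$y[move] <- s2$atoms$y[move] + 0.4
  sh <- residue_shift(s, s2, "A", 15)
  expect_equal(sh$max, 0.5, tolerance = 1e-9)
  expect_equal(sort(unique(round(sh$per_atom$displacement, 9))), c(0, 0.5))
  expect_error(residue_shift(s, s2, "A", 999), "absent")
})

test_that("report bundles are deterministic and complete", {
  res <- generate_series(three_week_config(seed = 12), tempfile("rep"))
  d1 <- tempfile("b1"); d2 <- tempfile("b2")
  cmd_series(res$manifest_path, out_dir = d1)
  cmd_series(res$manifest_path, out_dir = d2)
  files <- c("site_timeseries.csv", "distances.csv", "cages.csv",
             "summary.json", "analysis.log")
  expect_setequal(list.files(d1), files)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  ts <- utils::read.csv(file.path(d1, "site_timeseries.csv"))
  # row count equals the planted site x week grid (all sites every week)
  expect_identical(nrow(ts), 9L)
  expect_setequal(unique(ts$site), c("A/HIS15", "A/ASP101", "A/ASP119"))

  # empty inputs still produce a valid skeleton
  d0 <- tempfile("b0")
  build_report(list(), series_trends(list()), list(), d0)
  expect_true(all(file.exists(file.path(d0, files[1:4]))))
})
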