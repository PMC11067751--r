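# Shared fixture builders for the test suite. Everything is generated in
# code; nothing is read from disk except files the tests write themselves.

# a bare structure from an atom spec: list of c(x, y, z) plus options
toy_structure <- function(xyz, cell = c(20, 20, 20), sg = "P 1",
                          element = "C", name = NULL, res_name = "LIG",
                          res_seq = NULL, chain = "A", occ = 1, b = 20) {
  n <- length(xyz)
  xyzm <- do.call(rbind, xyz)
  atoms <- data.frame(
    name = if (is.null(name)) paste0(element, seq_len(n)) else name,
    element = rep_len(element, n),
    x = xyzm[, 1], y = xyzm[, 2], z = xyzm[, 3],
    res_name = rep_len(res_name, n), chain = rep_len(chain, n),
    res_seq = if (is.null(res_seq)) seq_len(n) else rep_len(res_seq, n),
    occ = rep_len(occ, n), b = rep_len(b, n),
    record = "HETATM", altloc = "",
    stringsAsFactors = FALSE)
  metalloscan:::new_structure(unit_cell(cell[1], cell[2], cell[3]),
                              space_group(sg), atoms)
}

# a small fast fixture config: one week, one His site, no cage
minimal_config <- function(seed = 1, jitter = 0, distance = 2.185,
                           res_name = "HIS", kind = "ImiAqua",
                           occupancy = 0.75) {
  fixture_config(
    weeks = 1, wavelengths = 0.976,
    sites = list(list(res_name = res_name, chain = "A", res_seq = 15,
                      kind = kind, distance = distance,
                      occupancy = occupancy, b = 20)),
    cage = NULL, jitter_sigma = jitter, peak_noise = 0,
    dpi = 0.026, d_min = 1.23, seed = seed)
}

# a 3-week config exercising trends, peaks and the cage
three_week_config <- function(seed = 1, jitter = 0) {
  fixture_config(
    weeks = c(1, 3, 9), wavelengths = c(0.976, 0.976, 0.976),
    sites = list(
      list(res_name = "HIS", chain = "A", res_seq = 15, kind = "ImiAqua",
           distance = 2.185, occupancy = c(0.5, 0.6, 0.7), b = 20),
      list(res_name = "ASP", chain = "A", res_seq = 101, kind = "ImiImi",
           distance = 2.14, occupancy = c(0.54, 0.68, 0.44), b = 20,
           cage = "a"),
      list(res_name = "ASP", chain = "A", res_seq = 119, kind = "ImiImi",
           distance = 2.14, occupancy = c(0.44, 0.64, 0.48), b = 20,
           cage = "b")),
    jitter_sigma = jitter, peak_noise = 0,
    dpi = c(0.084, 0.072, 0.026), d_min = c(1.75, 1.68, 1.23), seed = seed)
}

# random proper rotation matrix
random_rotation <- function() {
  qr_out <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_out)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Brute-force symmetry-mate oracle: enumerate every op x shift in the
# 3x3x3 block and keep copies with an atom within `radius`, computing
# everything with plain arithmetic (no package spatial machinery).
brute_force_mates <- function(struct, radius) {
  cellm <- rbind(c(struct$cell$a, 0, 0), c(0, struct$cell$b, 0),
                 c(0, 0, struct$cell$c))  # orthorhombic fixtures only
  ref <- as.matrix(struct$atoms[, c("x", "y", "z")])
  frac <- ref %*% solve(cellm)
  found <- list()
  for (k in seq_along(struct$space_group$ops)) {
    op <- struct$space_group$ops[[k]]
    id <- all(op$rotation == diag(3)) && all(op$translation == 0)
    for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
      if (id && sx == 0 && sy == 0 && sz == 0) next
      tf <- t(op$rotation %*% t(frac))
      tf <- sweep(tf, 2, op$translation + c(sx, sy, sz), "+")
      mate <- tf %*% cellm
      dmin <- Inf
      for (i in seq_len(nrow(ref)))
        for (j in seq_len(nrow(mate)))
          dmin <- min(dmin, sqrt(sum((ref[i, ] - mate[j, ])^2)))
      if (dmin <= radius)
        found[[length(found) + 1]] <- c(k, sx, sy, sz)
    }
  }
  found
}

mate_keys <- function(mates) {
  sort(vapply(mates, function(m)
    paste(c(m$op_index, m$shift), collapse = ","), character(1)))
}

oracle_keys <- function(found) {
  sort(vapply(found, function(v) paste(v, collapse = ","), character(1)))
}
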