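# Ground-truth fixture generator: toy tetragonal crystal structures with
# planted fac-[Re(CO)3(Imi)n(X)] complexes on minimal His/Asp/Asn side
# chain stubs, a symmetry-related four-imidazole cage with configurable
# centroid distances, occupancy schedules over weeks, positional jitter,
# and anomalous peak lists whose heights scale with occupancy and f''.

.imi_bond <- 1.37                      # aromatic ring bond length (A)
.imi_r5 <- .imi_bond / (2 * sin(pi / 5))  # pentagon circumradius, 1.1654 A
.re_c <- 1.92                          # Re-C carbonyl
.c_o <- 1.15                           # C=O
.re_n_imi <- 2.185                     # Re-N(imidazole) coordination
.re_o_aqua <- 2.19                     # Re-OH2
# distance from Re to an imidazole ring centroid along the coordination axis
.re_centroid <- .re_n_imi + .imi_r5

# two unit vectors perpendicular to u (deterministic)
perp_basis <- function(u) {
  u <- u / sqrt(sum(u^2))
  seed <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- seed - sum(seed * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  list(v = v, w = w)
}

# planar regular pentagon: vertex k at angle 72(k-1) degrees from v1
pentagon <- function(center, v1, v2, radius = .imi_r5) {
  th <- (0:4) * 2 * pi / 5
  t(vapply(th, function(a) center + radius * (cos(a) * v1 + sin(a) * v2),
           numeric(3)))
}

atom_row <- function(name, element, xyz, res_name, chain, res_seq,
                     occ = 1, b = 20, record = "HETATM") {
  data.frame(name = name, element = element,
             x = xyz[1], y = xyz[2], z = xyz[3],
             res_name = res_name, chain = chain, res_seq = res_seq,
             occ = occ, b = b, record = record, altloc = "",
             stringsAsFactors = FALSE)
}

#' Build an ideal fac-[Re(CO)3(Imi)(H2O/Imi)(X)] complex
#'
#' Ideal octahedral facial geometry: three mutually cis carbonyls
#' (Re-C 1.92, C-O 1.15 Angstrom, collinear), one or two planar imidazole
#' rings with the coordinating nitrogen at 2.185 Angstrom, a water oxygen
#' completing the octahedron for the `ImiAqua` kind, and the protein donor
#' atom at the requested Re distance on the remaining position.
#'
#' @param kind `"ImiAqua"` (one imidazole + water) or `"ImiImi"` (two
#'   imidazoles).
#' @param donor_xyz Position of the protein donor atom (Angstrom).
#' @param direction Unit vector from the donor towards where Re should sit.
#' @param re_donor_distance Re-donor distance (Angstrom, in (1.8, 3.2)).
#' @param res_name Ligand residue code (default `"REI"` / `"VHL"` style).
#' @param chain,res_seq Residue identifiers for the complex.
#' @param occ,b Occupancy and B factor given to every complex atom.
#' @param frame Optional 3x3 orthonormal matrix (columns e1, e2, e3)
#'   fixing the octahedron orientation; `e3` must point from the donor to
#'   Re. Default built from `direction`.
#' @param twists In-plane twist angles (radians) of the one or two
#'   imidazole rings about their coordination axes.
#' @return List: `atoms` (data frame), `re_xyz`, `ring_centroids` (list),
#'   `frame`.
#' @export
build_complex <- function(kind = c("ImiAqua", "ImiImi"), donor_xyz,
                          direction, re_donor_distance,
                          res_name = NULL, chain = "A", res_seq = 200,
                          occ = 1, b = 20, frame = NULL, twists = c(0, 0)) {
  kind <- match.arg(kind)
  if (!is.finite(re_donor_distance) ||
      re_donor_distance <= 1.8 || re_donor_distance >= 3.2)
    stop("re_donor_distance must lie in (1.8, 3.2) Angstrom")
  if (is.null(res_name)) res_name <- if (kind == "ImiAqua") "REI" else "VHL"
  u <- direction / sqrt(sum(direction^2))
  if (is.null(frame)) {
    pb <- perp_basis(u)
    frame <- cbind(pb$v, pb$w, u)
  }
  e1 <- frame[, 1]; e2 <- frame[, 2]; e3 <- frame[, 3]
  re <- donor_xyz + re_donor_distance * e3

  rows <- list(atom_row("RE", "RE", re, res_name, chain, res_seq, occ, b))
  # three facial carbonyls at +e1, +e2, +e3
  co_axes <- list(e1, e2, e3)
  for (i in 1:3) {
    ax <- co_axes[[i]]
    rows[[length(rows) + 1]] <- atom_row(paste0("C", i), "C",
                                         re + .re_c * ax, res_name, chain,
                                         res_seq, occ, b)
    rows[[length(rows) + 1]] <- atom_row(paste0("O", i), "O",
                                         re + (.re_c + .c_o) * ax, res_name,
                                         chain, res_seq, occ, b)
  }
  ring_centroids <- list()
  add_imidazole <- function(axis_a, axis_b, twist, tag) {
    # coordinating N towards Re along -axis_a; ring extends outwards
    center <- re - .re_centroid * axis_a
    v1 <- axis_a
    v2 <- cos(twist) * axis_b + sin(twist) * e3
    v2 <- v2 - sum(v2 * v1) * v1
    v2 <- v2 / sqrt(sum(v2^2))
    xyz <- pentagon(center, v1, v2)
    nm <- paste0(c("N1", "C2", "N3", "C4", "C5"), tag)
    el <- c("N", "C", "N", "C", "C")
    for (i in 1:5)
      rows[[length(rows) + 1]] <<- atom_row(nm[i], el[i], xyz[i, ],
                                            res_name, chain, res_seq, occ, b)
    ring_centroids[[length(ring_centroids) + 1]] <<- center
  }
  add_imidazole(e1, e2, twists[1], "A")
  if (kind == "ImiImi") {
    add_imidazole(e2, e1, twists[2], "B")
  } else {
    rows[[length(rows) + 1]] <- atom_row("O4", "O", re - .re_o_aqua * e2,
                                         res_name, chain, res_seq, occ, b)
  }
  list(atoms = do.call(rbind, rows), re_xyz = re,
       ring_centroids = ring_centroids, frame = frame)
}

# Minimal side-chain stubs carrying the donor atom at an exact position.
his_stub <- function(chain, res_seq, ne2_xyz, toward, phi = 0) {
  w <- toward / sqrt(sum(toward^2))
  pb <- perp_basis(w)
  v2 <- cos(phi) * pb$v + sin(phi) * pb$w
  center <- ne2_xyz - .imi_r5 * w
  xyz <- pentagon(center, w, v2)
  nm <- c("NE2", "CD2", "CG", "ND1", "CE1")
  el <- c("N", "C", "C", "N", "C")
  rows <- lapply(1:5, function(i)
    atom_row(nm[i], el[i], xyz[i, ], "HIS", chain, res_seq,
             record = "ATOM"))
  cb <- center + (.imi_r5 + 1.5) *
    (cos(2 * 2 * pi / 5) * w + sin(2 * 2 * pi / 5) * v2)
  rows[[6]] <- atom_row("CB", "C", cb, "HIS", chain, res_seq, record = "ATOM")
  do.call(rbind, rows)
}

carboxy_stub <- function(res_name, donor_name, other_name, other_elem,
                         chain, res_seq, donor_xyz, toward) {
  w <- toward / sqrt(sum(toward^2))
  pb <- perp_basis(w)
  cg <- donor_xyz - 1.25 * w
  other <- cg + 1.25 * (-0.5 * w + sin(2 * pi / 3) * pb$v)
  cb <- cg - 1.5 * pb$v
  rbind(atom_row(donor_name, substr(donor_name, 1, 1), donor_xyz, res_name,
                 chain, res_seq, record = "ATOM"),
        atom_row(other_name, other_elem, other, res_name, chain, res_seq,
                 record = "ATOM"),
        atom_row("CG", "C", cg, res_name, chain, res_seq, record = "ATOM"),
        atom_row("CB", "C", cb, res_name, chain, res_seq, record = "ATOM"))
}

asp_stub <- function(chain, res_seq, od1_xyz, toward)
  carboxy_stub("ASP", "OD1", "OD2", "O", chain, res_seq, od1_xyz, toward)

asn_stub <- function(chain, res_seq, nd2_xyz, toward)
  carboxy_stub("ASN", "ND2", "OD1", "O", chain, res_seq, nd2_xyz, toward)

#' Fixture generator configuration
#'
#' Defaults emulate the 38-week tetragonal lysozyme study design: seven
#' time points (weeks 1, 3, 9, 11, 14, 18, 38) alternating between a
#' laboratory Cu K-alpha source (1.5418 Angstrom) and a synchrotron
#' wavelength (0.976 Angstrom), a P 43 21 2 cell of 81.1 x 81.1 x 37.2
#' Angstrom, covalently bound complexes at His- and Asp-like sites with
#' the reported occupancy schedules, a weakly interacting Asn-like site,
#' and a symmetry-related four-imidazole cage.
#'
#' @param cell Cell lengths `c(a, b, c)` in Angstrom.
#' @param sg Space-group name.
#' @param weeks Week labels.
#' @param wavelengths Wavelength (Angstrom) per week.
#' @param sites List of site specs; each a list with `res_name`
#'   (`HIS`/`ASP`/`ASN`), `chain`, `res_seq`, `kind`, `distance`
#'   (Re-donor, Angstrom), `occupancy` (one value per week, `NA` = absent
#'   that week), `b`, and optionally `cage` (`"a"`/`"b"`: member of the
#'   cage pseudo-dimer).
#' @param cage `NULL`, or list with `distances` (four target inter-complex
#'   centroid distances, order (1,3), (2,3), (1,4), (2,4)), `op_index`
#'   (space-group operator relating the two cage complexes), `twists_a`,
#'   `twists_b` (ring twist angles, radians).
#' @param jitter_sigma Gaussian positional jitter sd in Angstrom.
#' @param peak_base Anomalous peak height (sigma) for a fully occupied
#'   site at the reference f'' of 5.9 electrons.
#' @param peak_noise Gaussian sd added to peak heights.
#' @param dpi Target coordinate-uncertainty (DPI) per week; refinement
#'   statistics in the manifest are chosen to reproduce these.
#' @param d_min Resolution per week (Angstrom).
#' @param seed RNG seed; a fixed seed gives byte-identical outputs.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(
    cell = c(81.1, 81.1, 37.2),
    sg = "P 43 21 2",
    weeks = c(1, 3, 9, 11, 14, 18, 38),
    wavelengths = c(1.5418, 0.976, 0.976, 1.5418, 1.5418, 0.976, 0.976),
    sites = list(
      list(res_name = "HIS", chain = "A", res_seq = 15, kind = "ImiAqua",
           distance = 2.185,
           occupancy = c(0.56, 0.75, 0.68, 0.75, 0.65, 0.84, 0.84), b = 20),
      list(res_name = "ASN", chain = "A", res_seq = 46, kind = "ImiAqua",
           distance = 2.43,
           occupancy = c(NA, 0.21, 0.08, NA, NA, 0.20, NA), b = 25),
      list(res_name = "ASP", chain = "A", res_seq = 101, kind = "ImiImi",
           distance = 2.14,
           occupancy = c(0.54, 0.68, 0.44, 0.55, 0.56, 0.58, 0.43), b = 20,
           cage = "a"),
      list(res_name = "ASP", chain = "A", res_seq = 119, kind = "ImiImi",
           distance = 2.14,
           occupancy = c(0.44, 0.64, 0.48, 0.60, 0.65, 0.58, 0.53), b = 20,
           cage = "b")),
    cage = list(distances = c(4.16, 4.20, 4.83, 5.04), op_index = 7,
                twists_a = c(1.1, 0.5), twists_b = c(0.1, 0.9)),
    jitter_sigma = 0, peak_base = 35, peak_noise = 0.5,
    dpi = c(0.084, 0.072, 0.026, 0.042, 0.040, 0.023, 0.022),
    d_min = c(1.75, 1.68, 1.23, 1.23, 1.41, 1.21, 1.15),
    seed = 1) {
  if (length(cage) == 0) cage <- NULL  # JSON round-trips NULL as {}
  cfg <- list(cell = cell, sg = sg, weeks = weeks,
              wavelengths = wavelengths, sites = sites, cage = cage,
              jitter_sigma = jitter_sigma, peak_base = peak_base,
              peak_noise = peak_noise, dpi = dpi, d_min = d_min, seed = seed)
  validate_fixture_config(cfg)
  structure(cfg, class = "fixture_config")
}

validate_fixture_config <- function(cfg) {
  nw <- length(cfg$weeks)
  if (length(cfg$wavelengths) != nw)
    stop("wavelengths must have one entry per week")
  if (length(cfg$dpi) != nw || length(cfg$d_min) != nw)
    stop("dpi and d_min must have one entry per week")
  for (s in cfg$sites) {
    occ <- s$occupancy
    if (length(occ) != nw)
      stop("occupancy schedule for ", s$res_name, s$res_seq,
           " must have one value per week")
    if (any(occ[!is.na(occ)] < 0 | occ[!is.na(occ)] > 1))
      stop("occupancy for ", s$res_name, s$res_seq, " outside [0, 1]")
    if (s$distance <= 1.5 || s$distance >= 3.5)
      stop("planted Re-donor distance for ", s$res_name, s$res_seq,
           " outside (1.5, 3.5)")
  }
  if (!is.null(cfg$cage) && length(cfg$cage$distances) != 4)
    stop("cage$distances must give four target centroid distances")
  invisible(cfg)
}

# Solve the cage layout: two ImiImi complexes A and B whose four
# inter-complex ring-centroid distances match the targets
# (t13, t23, t14, t24), where rings 1,2 belong to A and 3,4 to B.
# Returns centroid positions and Re/frame placements in a local frame.
solve_cage_layout <- function(targets) {
  delta <- .re_centroid * sqrt(2)   # intra-complex centroid separation
  t13 <- targets[1]; t23 <- targets[2]; t14 <- targets[3]; t24 <- targets[4]
  c1 <- c(0, 0, 0); c2 <- c(delta, 0, 0)
  circ <- function(ta, tb) {
    x <- (delta^2 + ta^2 - tb^2) / (2 * delta)
    r2 <- ta^2 - x^2
    if (r2 <= 0)
      stop("cage centroid distances are unsatisfiable (triangle inequality)")
    list(x = x, r = sqrt(r2))
  }
  k3 <- circ(t13, t23)
  k4 <- circ(t14, t24)
  # choose points on the two circles so that |c3 - c4| = delta
  cosphi <- ((k3$x - k4$x)^2 + k3$r^2 + k4$r^2 - delta^2) /
    (2 * k3$r * k4$r)
  if (abs(cosphi) > 1)
    stop("cage centroid distances are unsatisfiable (triangle inequality)")
  psi <- 0.4
  th <- psi + acos(cosphi)
  c3 <- c(k3$x, k3$r * cos(th), k3$r * sin(th))
  c4 <- c(k4$x, k4$r * cos(psi), k4$r * sin(psi))

  place <- function(p, q, flip) {
    # Re with |Re-p| = |Re-q| = .re_centroid and a 90-degree p-Re-q angle
    m <- (p + q) / 2
    axis <- (q - p) / sqrt(sum((q - p)^2))
    pb <- perp_basis(axis)
    nrm <- if (flip) -pb$w else pb$w
    re <- m + (.re_centroid / sqrt(2)) * nrm
    e1 <- (re - p) / .re_centroid
    e2 <- (re - q) / .re_centroid
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    list(re = re, frame = cbind(e1, e2, e3))
  }
  list(A = place(c1, c2, flip = TRUE), B = place(c3, c4, flip = FALSE),
       centroids = list(c1, c2, c3, c4), delta = delta)
}

# jitter helper: adds N(0, sigma) to every coordinate
jitter_atoms <- function(atoms, sigma) {
  if (sigma > 0) {
    n <- nrow(atoms)
    atoms$x <- atoms$x + stats::rnorm(n, 0, sigma)
    atoms$y <- atoms$y + stats::rnorm(n, 0, sigma)
    atoms$z <- atoms$z + stats::rnorm(n, 0, sigma)
  }
  atoms
}

#' Generate a synthetic structure series with ground truth
#'
#' Writes one PDB file and one anomalous peak CSV per week, a JSON series
#' manifest whose refinement statistics reproduce the requested per-week
#' DPI values, and a ground-truth JSON recording every planted quantity.
#' Peak heights follow `peak_base * occupancy * f''(wavelength)/5.9` plus
#' Gaussian noise (a deliberately simple synthetic stand-in for map peak
#' heights, which in real data are noisier than refined occupancies).
#'
#' @param config A [fixture_config()].
#' @param out_dir Output directory (created if needed).
#' @return List with `manifest_path`, `manifest`, `truth_path`, `truth`.
#' @export
generate_series <- function(config, out_dir) {
  validate_fixture_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  cell <- unit_cell(config$cell[1], config$cell[2], config$cell[3])
  sg <- space_group(config$sg)

  # ---- static site placement (same every week; jitter applied per week)
  standalone_anchor <- list(
    HIS = list(xyz = c(20, 20, 12), dir = c(0, 0, 1)),
    ASN = list(xyz = c(60, 55, 8), dir = c(0, 0, 1)),
    ASP = list(xyz = c(15, 60, 25), dir = c(1, 0, 0)))
  cage_members <- which(vapply(config$sites, function(s)
    !is.null(s$cage), logical(1)))
  cage_layout <- NULL
  cage_offset <- c(40, 20, 18)
  inv_op <- NULL
  if (!is.null(config$cage) && length(cage_members) == 2) {
    cage_layout <- solve_cage_layout(config$cage$distances)
    inv_op <- symop_inverse(sg$ops[[config$cage$op_index]])
  }

  site_geom <- list()   # per site: donor_xyz, direction, frame, is_cage_b
  used <- 0
  for (i in seq_along(config$sites)) {
    s <- config$sites[[i]]
    if (!is.null(s$cage) && !is.null(cage_layout)) {
      pl <- if (s$cage == "a") cage_layout$A else cage_layout$B
      re <- pl$re + cage_offset
      e3 <- pl$frame[, 3]
      site_geom[[i]] <- list(donor_xyz = re - s$distance * e3,
                             direction = e3, frame = pl$frame,
                             cage_b = identical(s$cage, "b"),
                             twists = if (s$cage == "a")
                               config$cage$twists_a else config$cage$twists_b)
    } else {
      used <- used + 1
      anchor <- standalone_anchor[[s$res_name]]
      if (is.null(anchor)) anchor <- list(xyz = c(10 + 12 * used, 10, 30),
                                          dir = c(0, 0, 1))
      site_geom[[i]] <- list(donor_xyz = anchor$xyz, direction = anchor$dir,
                             frame = NULL, cage_b = FALSE, twists = c(0, 0))
    }
  }

  # map cage-B coordinates back near the asymmetric unit via the inverse
  # op; the lattice shift is taken from the block centroid so a complex is
  # never split across a cell boundary
  to_asu <- function(atoms) {
    frac <- orth_to_frac(cell, as.matrix(atoms[, c("x", "y", "z")]))
    frac <- symop_apply(inv_op, frac)
    frac <- sweep(frac, 2, floor(colMeans(frac)))
    orth <- frac_to_orth(cell, frac)
    atoms$x <- orth[, 1]; atoms$y <- orth[, 2]; atoms$z <- orth[, 3]
    atoms
  }

  manifest <- list()
  truth_sites <- list()
  truth_cage <- NULL
  for (w in seq_along(config$weeks)) {
    week <- config$weeks[w]
    wl <- config$wavelengths[w]
    rows <- list()
    metals <- list()
    for (i in seq_along(config$sites)) {
      s <- config$sites[[i]]
      g <- site_geom[[i]]
      occ <- s$occupancy[w]
      stub <- switch(s$res_name,
                     HIS = his_stub(s$chain, s$res_seq, g$donor_xyz,
                                    g$direction),
                     ASP = asp_stub(s$chain, s$res_seq, g$donor_xyz,
                                    g$direction),
                     ASN = asn_stub(s$chain, s$res_seq, g$donor_xyz,
                                    g$direction),
                     stop("unsupported stub residue ", s$res_name))
      block <- stub
      has_metal <- !is.na(occ) && occ > 0
      if (has_metal) {
        cx <- build_complex(s$kind, g$donor_xyz, g$direction, s$distance,
                            chain = s$chain, res_seq = 200 + i, occ = occ,
                            b = s$b, frame = g$frame, twists = g$twists)
        block <- rbind(block, cx$atoms)
      }
      if (g$cage_b) block <- to_asu(block)
      rows[[length(rows) + 1]] <- block
      if (has_metal)
        metals[[length(metals) + 1]] <- list(site = i, occ = occ)
    }
    atoms <- do.call(rbind, rows)
    atoms <- jitter_atoms(atoms, config$jitter_sigma)
    struct <- new_structure(cell, sg, atoms)
    pdb_path <- file.path(out_dir, sprintf("week%02d_wl%s.pdb", week,
                                           gsub("\\.", "p", format(wl))))
    write_structure(struct, pdb_path)

    # peak list: one peak per present metal, at the coordinates as written
    fdp <- lookup_fdp("RE", wl)
    pk <- list()
    heights <- list()
    for (m in metals) {
      # metal coordinates after jitter, rounded as printed in the PDB
      sel <- struct$atoms$element == "RE" & struct$atoms$res_seq == 200 + m$site
      xyz <- round(as.numeric(struct$atoms[which(sel)[1], c("x", "y", "z")]), 3)
      h <- config$peak_base * m$occ * (fdp / 5.9)
      if (config$peak_noise > 0) h <- h + stats::rnorm(1, 0, config$peak_noise)
      h <- max(h, 0.1)
      pk[[length(pk) + 1]] <- data.frame(x = xyz[1], y = xyz[2], z = xyz[3],
                                         height = round(h, 3))
      heights[[length(heights) + 1]] <- list(site = m$site, height = round(h, 3))
    }
    peaks_path <- file.path(out_dir, sprintf("week%02d_wl%s_peaks.csv", week,
                                             gsub("\\.", "p", format(wl))))
    pkdf <- if (length(pk)) do.call(rbind, pk) else
      data.frame(x = numeric(), y = numeric(), z = numeric(),
                 height = numeric())
    utils::write.csv(pkdf, peaks_path, row.names = FALSE, quote = FALSE)

    # refinement stats solved so that cruickshank_dpi hits the target
    n_atoms <- nrow(atoms)
    compl <- 0.98
    r_free <- 0.20
    n_refl <- round(n_atoms * (compl^(-1 / 3) * r_free * config$d_min[w] /
                                 config$dpi[w])^2)
    manifest[[length(manifest) + 1]] <- list(
      path = basename(pdb_path), peaks = basename(peaks_path),
      week = week, wavelength = wl,
      label = sprintf("synthetic week %d (%.4f A)", week, wl),
      stats = list(n_atoms = n_atoms, n_reflections = n_refl,
                   completeness = compl, r_free = r_free,
                   r_factor = r_free - 0.04, d_min = config$d_min[w],
                   avg_b = round(mean(atoms$b), 2)))
    truth_sites[[length(truth_sites) + 1]] <- list(
      week = week, wavelength = wl,
      sites = lapply(seq_along(config$sites), function(i) {
        s <- config$sites[[i]]
        hh <- Filter(function(h) h$site == i, heights)
        list(key = sprintf("%s/%s%d", s$chain, s$res_name, s$res_seq),
             occupancy = s$occupancy[w], distance = s$distance,
             peak_height = if (length(hh)) hh[[1]]$height else NA)
      }))
  }

  if (!is.null(cage_layout)) {
    cc <- cage_layout$centroids
    truth_cage <- list(
      op_index = config$cage$op_index,
      distances = config$cage$distances,
      pair_order = c("1-3", "2-3", "1-4", "2-4"),
      intra_complex_centroid_sep = cage_layout$delta)
  }

  truth <- list(seed = config$seed, jitter_sigma = config$jitter_sigma,
                peak_base = config$peak_base, peak_noise = config$peak_noise,
                weeks = truth_sites, cage = truth_cage)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = 10, na = "null")
  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = 10, na = "null")
  list(manifest_path = manifest_path, manifest = manifest,
       truth_path = truth_path, truth = truth)
}
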