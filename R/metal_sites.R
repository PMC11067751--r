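# Metal-site detection: coordination spheres within a distance cutoff,
# symmetry-aware, with occupancies, anomalous peak heights and
# propagated distance uncertainties.

# keep the highest-occupancy altloc per (chain, res_seq, res_name, name)
collapse_altlocs <- function(atoms) {
  has_alt <- atoms$altloc != ""
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$chain, atoms$res_seq, atoms$res_name, atoms$name)
  keep <- rep(TRUE, nrow(atoms))
  for (kk in unique(key[has_alt])) {
    idx <- which(key == kk)
    if (length(idx) > 1) {
      best <- idx[which.max(atoms$occ[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  atoms[keep, , drop = FALSE]
}

#' Locate metal atoms and build their coordination spheres
#'
#' One site per metal atom. Donor candidates are non-metal atoms of the
#' donor elements (N, O, S by default) within `cutoff` of the metal,
#' searched over the reference molecule and its symmetry mates. Atoms
#' closer than 0.8 Angstrom are treated as unphysical and dropped with a
#' warning. Where altlocs exist, the highest-occupancy altloc is used.
#'
#' @param struct An `xtal_structure`.
#' @param metal_elements Element symbols treated as metals (default `"Re"`).
#' @param cutoff Coordination distance cutoff in Angstrom (default 3.0,
#'   the usual bonding-sphere limit for heavy metals).
#' @param donor_elements Elements allowed as coordination donors.
#' @param include_symmetry Also search symmetry mates (default `TRUE`).
#' @return List of `metal_site` objects: `metal` (atom row),
#'   `ligands` (data frame with `distance`, `su`, `op_index`, `sx`, `sy`,
#'   `sz`, `is_sym`), `binding_residues` (amino acids contributing
#'   donors), `occupancy`, `peak_height`, `residual_density`.
#' @export
find_metal_sites <- function(struct, metal_elements = "Re", cutoff = 3.0,
                             donor_elements = c("N", "O", "S"),
                             include_symmetry = TRUE) {
  if (cutoff <= 1.0 || cutoff >= 5.0)
    warning("coordination cutoff ", cutoff, " A is outside the usual (1, 5) range")
  metal_elements <- toupper(metal_elements)
  donor_elements <- toupper(donor_elements)

  atoms <- collapse_altlocs(struct$atoms)
  metals <- atoms[atoms$element %in% metal_elements, , drop = FALSE]
  if (nrow(metals) == 0) return(list())

  donors <- atoms[atoms$element %in% donor_elements &
                    !(atoms$element %in% metal_elements), , drop = FALSE]
  pools <- list(list(atoms = donors, op_index = NA_integer_,
                     shift = c(NA, NA, NA), is_sym = FALSE))
  if (include_symmetry) {
    for (m in symmetry_mates(struct, cutoff)) {
      at <- collapse_altlocs(m$atoms)
      at <- at[at$element %in% donor_elements &
                 !(at$element %in% metal_elements), , drop = FALSE]
      if (nrow(at) > 0)
        pools[[length(pools) + 1]] <- list(atoms = at, op_index = m$op_index,
                                           shift = m$shift, is_sym = TRUE)
    }
  }

  sites <- list()
  for (i in seq_len(nrow(metals))) {
    mx <- as.numeric(metals[i, c("x", "y", "z")])
    lig <- list()
    for (p in pools) {
      d <- sqrt(colSums((t(as.matrix(p$atoms[, c("x", "y", "z")])) - mx)^2))
      sel <- which(d <= cutoff)
      if (any(d[sel] < 0.8)) {
        warning("atoms closer than 0.8 A to metal serial ",
                metals$serial[i], " ignored")
        sel <- sel[d[sel] >= 0.8]
      }
      if (length(sel) == 0) next
      sub <- p$atoms[sel, c("serial", "name", "element", "res_name",
                            "chain", "res_seq", "x", "y", "z", "b"),
                     drop = FALSE]
      sub$distance <- d[sel]
      sub$su <- NA_real_
      sub$op_index <- p$op_index
      sub$sx <- p$shift[1]; sub$sy <- p$shift[2]; sub$sz <- p$shift[3]
      sub$is_sym <- p$is_sym
      lig[[length(lig) + 1]] <- sub
    }
    lig <- if (length(lig)) do.call(rbind, lig) else
      data.frame(serial = integer(), name = character(),
                 element = character(), res_name = character(),
                 chain = character(), res_seq = integer(),
                 x = numeric(), y = numeric(), z = numeric(), b = numeric(),
                 distance = numeric(), su = numeric(),
                 op_index = integer(), sx = integer(), sy = integer(),
                 sz = integer(), is_sym = logical(),
                 stringsAsFactors = FALSE)
    lig <- lig[order(lig$distance), , drop = FALSE]
    rownames(lig) <- NULL
    prot <- lig[is_protein_res(lig$res_name), , drop = FALSE]
    binding <- unique(prot[, c("chain", "res_seq", "res_name")])
    rownames(binding) <- NULL
    sites[[length(sites) + 1]] <- structure(
      list(metal = metals[i, ], ligands = lig, binding_residues = binding,
           occupancy = metals$occ[i], peak_height = NA_real_,
           residual_density = NA_real_),
      class = "metal_site")
  }
  sites
}

#' @export
print.metal_site <- function(x, ...) {
  res <- if (nrow(x$binding_residues) > 0)
    paste(x$binding_residues$res_name, x$binding_residues$res_seq,
          collapse = ", ") else "(no protein residue)"
  cat(sprintf("%s site (serial %d, occ %.2f): %d donors <= cutoff; binds %s\n",
              x$metal$element, x$metal$serial, x$occupancy,
              nrow(x$ligands), res))
  invisible(x)
}

#' Attach a precision model to metal sites
#'
#' Fills the `su` column of every ligand record with the quadrature
#' combination of the metal and donor positional uncertainties.
#'
#' @param sites List of `metal_site`.
#' @param model A [precision_model()].
#' @param avg_b Average B factor (needed only with per-atom scaling).
#' @return The sites, with ligand `su` populated.
#' @export
attach_precision <- function(sites, model, avg_b = NA_real_) {
  lapply(sites, function(site) {
    if (nrow(site$ligands) > 0) {
      su_m <- atom_su(model, site$metal$b, avg_b)
      site$ligands$su <- vapply(seq_len(nrow(site$ligands)), function(i)
        distance_su(su_m, atom_su(model, site$ligands$b[i], avg_b)),
        numeric(1))
    }
    site
  })
}

#' Expected anomalous peak-height ratio between two f'' values
#'
#' Anomalous difference map peak heights scale with the imaginary
#' scattering component f''; the expected ratio between two wavelengths is
#' simply the ratio of the f'' values.
#'
#' @param f2_a,f2_b f'' values in electrons (> 0).
#' @return The dimensionless ratio `f2_a / f2_b`.
#' @examples
#' expected_peak_ratio(12.1, 5.9)           # 2.0508...
#' signif(expected_peak_ratio(12.1, 5.9), 2)  # 2.1
#' @export
expected_peak_ratio <- function(f2_a, f2_b) {
  if (!is.finite(f2_a) || !is.finite(f2_b) || f2_a <= 0 || f2_b <= 0)
    stop("f'' values must be positive")
  f2_a / f2_b
}

#' Bundled f'' values for rhenium
#'
#' Small lookup table: Re at the L1-edge-optimised synchrotron wavelength
#' (0.976 Angstrom, 12.1 electrons) and at Cu K-alpha (1.5418 Angstrom,
#' 5.9 electrons). Users may supply their own table to [lookup_fdp()].
#'
#' @return Data frame with `element`, `wavelength`, `f_double_prime`.
#' @export
fdp_table <- function() {
  data.frame(element = c("RE", "RE"),
             wavelength = c(0.976, 1.5418),
             f_double_prime = c(12.1, 5.9),
             stringsAsFactors = FALSE)
}

#' Look up f'' for an element at a wavelength
#'
#' @param element Element symbol.
#' @param wavelength Wavelength in Angstrom.
#' @param table f'' table (default [fdp_table()]).
#' @param tol Wavelength matching tolerance in Angstrom.
#' @return f'' in electrons.
#' @export
lookup_fdp <- function(element, wavelength, table = fdp_table(), tol = 0.05) {
  rows <- table[table$element == toupper(element), , drop = FALSE]
  if (nrow(rows) == 0) stop("no f'' entries for element ", element)
  d <- abs(rows$wavelength - wavelength)
  if (min(d) > tol)
    stop(sprintf("no f'' entry for %s within %.2f A of wavelength %.4f",
                 element, tol, wavelength))
  rows$f_double_prime[which.min(d)]
}

#' Read an anomalous peak list from CSV
#'
#' Expected header: `x,y,z,height`; positive peak heights in sigma units.
#' Coordinates are orthogonal Angstrom by default; `frame = "fractional"`
#' converts through the cell.
#'
#' @param path CSV file.
#' @param struct Structure providing the cell (needed for fractional
#'   input).
#' @param frame `"orthogonal"` or `"fractional"`.
#' @return Data frame with `x`, `y`, `z`, `height`.
#' @export
read_peaks_csv <- function(path, struct = NULL,
                           frame = c("orthogonal", "fractional")) {
  frame <- match.arg(frame)
  pk <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "z", "height")
  if (!all(need %in% names(pk)))
    stop("peak CSV must have header x,y,z,height: ", path)
  if (any(pk$height <= 0))
    stop("peak heights must be positive (anomalous peaks): ", path)
  if (frame == "fractional") {
    if (is.null(struct)) stop("fractional peaks require `struct` for the cell")
    orth <- frac_to_orth(struct$cell, as.matrix(pk[, c("x", "y", "z")]))
    pk$x <- orth[, 1]; pk$y <- orth[, 2]; pk$z <- orth[, 3]
  }
  pk[, need]
}

# minimum distance from point p to point q over all symmetry images of p
sym_min_dist <- function(struct, p, q) {
  fp <- orth_to_frac(struct$cell, p)
  best <- Inf
  for (op in struct$space_group$ops) {
    img <- symop_apply(op, fp)
    # nearest lattice image of the difference vector
    dfrac <- img - orth_to_frac(struct$cell, q)
    dfrac <- dfrac - round(dfrac)
    d <- sqrt(sum(frac_to_orth(struct$cell, dfrac)^2))
    best <- min(best, d)
  }
  best
}

#' Assign anomalous peaks to metal sites
#'
#' Greedy nearest-first matching: the closest (site, peak) pair within
#' `match_radius` is assigned, both are removed, and the process repeats.
#' Distances are measured over all symmetry images of the peak, so a peak
#' recorded in a different asymmetric-unit copy still matches. Ties (two
#' sites equidistant from one peak within 1e-6) are reported via the
#' `peak_tied` flag rather than duplicating the height.
#'
#' @param sites List of `metal_site`.
#' @param peaks Data frame from [read_peaks_csv()].
#' @param match_radius Maximum site-peak distance in Angstrom.
#' @param struct The structure (for cell and symmetry).
#' @return The sites, with `peak_height` filled where matched.
#' @export
associate_peaks <- function(sites, peaks, match_radius = 1.0, struct) {
  if (length(sites) == 0 || is.null(peaks) || nrow(peaks) == 0) return(sites)
  d <- matrix(Inf, length(sites), nrow(peaks))
  for (i in seq_along(sites)) {
    mx <- as.numeric(sites[[i]]$metal[c("x", "y", "z")])
    for (j in seq_len(nrow(peaks)))
      d[i, j] <- sym_min_dist(struct, as.numeric(peaks[j, c("x", "y", "z")]), mx)
  }
  repeat {
    if (all(!is.finite(d)) || min(d) > match_radius) break
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    tied <- sum(abs(d[, j] - d[i, j]) < 1e-6) > 1
    sites[[i]]$peak_height <- peaks$height[j]
    sites[[i]]$peak_tied <- tied
    d[i, ] <- Inf
    d[, j] <- Inf
  }
  sites
}
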