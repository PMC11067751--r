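# Symmetry expansion and crystal-contact detection.

# Perpendicular widths of the cell along the three lattice directions,
# used to size the lattice-translation search block.
cell_widths <- function(cell) {
  m <- cell_orth_matrix(cell)
  v <- cell_volume(cell)
  cross <- function(u, w) c(u[2] * w[3] - u[3] * w[2],
                            u[3] * w[1] - u[1] * w[3],
                            u[1] * w[2] - u[2] * w[1])
  c(v / sqrt(sum(cross(m[, 2], m[, 3])^2)),
    v / sqrt(sum(cross(m[, 3], m[, 1])^2)),
    v / sqrt(sum(cross(m[, 1], m[, 2])^2)))
}

# Transform the full atom table by op + lattice shift; returns the atom
# data frame with x, y, z replaced and bookkeeping columns appended.
transform_atoms <- function(struct, op, shift) {
  at <- struct$atoms
  frac <- orth_to_frac(struct$cell, as.matrix(at[, c("x", "y", "z")]))
  frac <- symop_apply(op, frac, shift)
  orth <- frac_to_orth(struct$cell, frac)
  at$x <- orth[, 1]; at$y <- orth[, 2]; at$z <- orth[, 3]
  at
}

#' Generate symmetry mates near the reference molecule
#'
#' Applies every space-group operator combined with lattice translations
#' over a 3x3x3 block of neighbouring cells (extended automatically when
#' `radius` exceeds a cell width) and keeps every non-identity copy with at
#' least one atom within `radius` of a reference atom.
#'
#' @param struct An `xtal_structure`.
#' @param radius Distance cutoff in Angstrom (> 0).
#' @return List of `sym_mate` objects: `op_index` (1-based into
#'   `struct$space_group$ops`), `shift` (integer lattice translation) and
#'   `atoms` (transformed atom table).
#' @export
symmetry_mates <- function(struct, radius) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  ops <- struct$space_group$ops
  widths <- cell_widths(struct$cell)
  nshift <- pmax(1, ceiling(radius / widths))
  ref <- as.matrix(struct$atoms[, c("x", "y", "z")])
  lo <- apply(ref, 2, min) - radius
  hi <- apply(ref, 2, max) + radius

  mates <- list()
  for (k in seq_along(ops)) {
    is_id <- symop_equal(ops[[k]], symop(diag(3), c(0, 0, 0)))
    for (sx in -nshift[1]:nshift[1])
      for (sy in -nshift[2]:nshift[2])
        for (sz in -nshift[3]:nshift[3]) {
          if (is_id && sx == 0 && sy == 0 && sz == 0) next
          at <- transform_atoms(struct, ops[[k]], c(sx, sy, sz))
          xyz <- as.matrix(at[, c("x", "y", "z")])
          inbox <- xyz[, 1] >= lo[1] & xyz[, 1] <= hi[1] &
            xyz[, 2] >= lo[2] & xyz[, 2] <= hi[2] &
            xyz[, 3] >= lo[3] & xyz[, 3] <= hi[3]
          if (!any(inbox)) next
          if (min_cross_dist(ref, xyz[inbox, , drop = FALSE]) > radius) next
          mates[[length(mates) + 1]] <- structure(
            list(op_index = k, shift = c(sx, sy, sz), atoms = at),
            class = "sym_mate")
        }
  }
  mates
}

# Smallest distance between two coordinate sets (n x 3, m x 3).
min_cross_dist <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  sqrt(min(cross_dist2(a, b)))
}

# Squared-distance matrix between two coordinate sets.
cross_dist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  d2
}

#' Detect crystal contacts
#'
#' A crystal contact is an interatomic contact between symmetry-related
#' copies of the molecule, i.e. one that exists only because of crystal
#' packing. Every (reference atom, mate atom) pair with distance at or
#' below `cutoff` is reported once, ordered by operator index, lattice
#' shift and atom serials. Note a contact of atom i with the image of atom
#' j and the contact of j with the inverse image of i are listed as
#' separate rows (both views of the same physical interaction), as in
#' conventional contact listings.
#'
#' @param struct An `xtal_structure`.
#' @param cutoff Contact distance cutoff in Angstrom (default 4.0, the
#'   conventional crystal-contact threshold).
#' @param heavy_only Drop hydrogen atoms (default `TRUE`).
#' @param exclude_water Drop water molecules from both sides.
#' @return Data frame with columns `ref_serial`, `ref_name`, `ref_res_name`,
#'   `ref_chain`, `ref_res_seq`, `sym_serial`, `sym_name`, `sym_res_name`,
#'   `sym_chain`, `sym_res_seq`, `distance`, `op_index`, `sx`, `sy`, `sz`.
#' @export
crystal_contacts <- function(struct, cutoff = 4.0, heavy_only = TRUE,
                             exclude_water = FALSE) {
  mates <- symmetry_mates(struct, cutoff)
  ref <- struct$atoms
  keep <- rep(TRUE, nrow(ref))
  if (heavy_only) keep <- keep & ref$element != "H"
  if (exclude_water) keep <- keep & !is_water_res(ref$res_name)
  ref <- ref[keep, , drop = FALSE]
  refxyz <- as.matrix(ref[, c("x", "y", "z")])

  out <- list()
  for (m in mates) {
    at <- m$atoms
    mk <- rep(TRUE, nrow(at))
    if (heavy_only) mk <- mk & at$element != "H"
    if (exclude_water) mk <- mk & !is_water_res(at$res_name)
    at <- at[mk, , drop = FALSE]
    if (nrow(at) == 0 || nrow(ref) == 0) next
    d2 <- cross_dist2(refxyz, as.matrix(at[, c("x", "y", "z")]))
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    out[[length(out) + 1]] <- data.frame(
      ref_serial = ref$serial[hit[, 1]],
      ref_name = ref$name[hit[, 1]],
      ref_res_name = ref$res_name[hit[, 1]],
      ref_chain = ref$chain[hit[, 1]],
      ref_res_seq = ref$res_seq[hit[, 1]],
      sym_serial = at$serial[hit[, 2]],
      sym_name = at$name[hit[, 2]],
      sym_res_name = at$res_name[hit[, 2]],
      sym_chain = at$chain[hit[, 2]],
      sym_res_seq = at$res_seq[hit[, 2]],
      distance = sqrt(d2[hit]),
      op_index = m$op_index,
      sx = m$shift[1], sy = m$shift[2], sz = m$shift[3],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(ref_serial = integer(), ref_name = character(),
                      ref_res_name = character(), ref_chain = character(),
                      ref_res_seq = integer(), sym_serial = integer(),
                      sym_name = character(), sym_res_name = character(),
                      sym_chain = character(), sym_res_seq = integer(),
                      distance = numeric(), op_index = integer(),
                      sx = integer(), sy = integer(), sz = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$op_index, res$sx, res$sy, res$sz,
                   res$ref_serial, res$sym_serial), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Export contacts as CSV
#'
#' @param contacts Data frame from [crystal_contacts()].
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_contacts_csv <- function(contacts, path) {
  utils::write.csv(contacts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
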