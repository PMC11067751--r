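# Aromatic-ring geometry: least-squares planes, centroids, interplanar
# angles, pi-stacking classification, and the symmetry-aware ring
# interaction network (the "cage" analysis).

#' Fit a least-squares plane through ring atoms
#'
#' The centroid is the unweighted mean of the member atoms; the normal is
#' the direction minimising the sum of squared perpendicular deviations
#' (smallest principal axis of the centred coordinates) and
#' `planarity_rmsd` is the rms of those deviations.
#'
#' @param coords n x 3 matrix of atom coordinates (n >= 3, not collinear).
#' @param ring_id Optional identifier list carried through.
#' @return An `aromatic_ring`: `centroid`, `normal` (unit), `planarity_rmsd`,
#'   `coords`, `ring_id`.
#' @export
fit_ring <- function(coords, ring_id = NULL) {
  coords <- as_xyz_matrix(coords)
  if (nrow(coords) < 3) stop("a ring needs at least 3 atoms")
  centroid <- unname(colMeans(coords))
  centred <- sweep(coords, 2, centroid)
  sv <- svd(centred)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("ring atoms are collinear or degenerate; no plane defined")
  normal <- sv$v[, 3]
  normal <- normal / sqrt(sum(normal^2))
  dev <- centred %*% normal
  structure(list(centroid = centroid, normal = normal,
                 planarity_rmsd = sqrt(mean(dev^2)),
                 coords = coords, ring_id = ring_id),
            class = "aromatic_ring")
}

#' Angle between two ring planes
#'
#' `acos(|a . b|)`, folded into `[0, 90]` degrees so that parallel and
#' antiparallel normals both give 0.
#'
#' @param normal_a,normal_b Unit normal vectors.
#' @return Angle in degrees in `[0, 90]`.
#' @export
interplanar_angle <- function(normal_a, normal_b) {
  na <- sqrt(sum(normal_a^2)); nb <- sqrt(sum(normal_b^2))
  if (na < 1e-12 || nb < 1e-12) stop("zero-length normal vector")
  d <- abs(sum(normal_a * normal_b)) / (na * nb)
  acos(min(1, d)) * 180 / pi
}

#' Classify a pi-pi ring interaction
#'
#' Small-molecule criteria: face-to-face when the centroid distance is
#' below 4.0 Angstrom and the interplanar angle below 30 degrees;
#' edge-to-face when the distance is below 5.5 Angstrom and the folded
#' angle at least 60 degrees; `intermediate` when the distance is below
#' 5.5 with an angle in [30, 60); `none` otherwise. Macromolecular
#' criteria: face-to-face for centroid distances in [3.3, 3.8];
#' edge-to-face up to 5.5 Angstrom with angle >= 60 (the narrow
#' 4.96-5.025 band quoted for macromolecular edge-to-face contacts is
#' annotated via the `in_ef_band` attribute, not used as a gate).
#'
#' @param distance Centroid-centroid distance (Angstrom, > 0).
#' @param angle Interplanar angle in degrees, folded into `[0, 90]`.
#' @param criteria `"small_molecule"` (default) or `"macromolecular"`.
#' @return Label: `"face_to_face"`, `"edge_to_face"`, `"intermediate"` or
#'   `"none"`.
#' @export
classify_stacking <- function(distance, angle,
                              criteria = c("small_molecule", "macromolecular")) {
  criteria <- match.arg(criteria)
  if (!is.finite(distance) || distance <= 0) stop("distance must be > 0")
  angle <- interplanar_angle_fold(angle)
  label <-
    if (criteria == "small_molecule") {
      if (distance < 4.0 && angle < 30) "face_to_face"
      else if (distance < 5.5 && angle >= 60) "edge_to_face"
      else if (distance < 5.5 && angle >= 30) "intermediate"
      else "none"
    } else {
      if (distance >= 3.3 && distance <= 3.8 && angle < 30) "face_to_face"
      else if (distance <= 5.5 && angle >= 60) "edge_to_face"
      else if (distance <= 5.5 && angle >= 30) "intermediate"
      else "none"
    }
  if (criteria == "macromolecular" && label == "edge_to_face")
    attr(label, "in_ef_band") <- distance >= 4.96 && distance <= 5.025
  label
}

# fold an angle in degrees into [0, 90]
interplanar_angle_fold <- function(angle) {
  a <- angle %% 180
  if (a > 90) 180 - a else a
}

# His side-chain imidazole ring atom names
.his_ring <- c("CG", "ND1", "CD2", "CE1", "NE2")

# Detect 5-membered rings within one residue's atoms by bond connectivity
# (bond threshold 1.8 A). Returns a list of index vectors.
five_rings_by_connectivity <- function(xyz) {
  n <- nrow(xyz)
  if (n < 5) return(list())
  d2 <- cross_dist2(xyz, xyz)
  adj <- d2 > 1e-6 & d2 < 1.8^2
  rings <- list()
  seen <- character(0)
  # depth-limited cycle search for 5-cycles
  for (start in seq_len(n)) {
    path <- start
    walk <- function(path) {
      last <- path[length(path)]
      if (length(path) == 5) {
        if (adj[last, start]) {
          key <- paste(sort(path), collapse = "-")
          if (!key %in% seen) {
            seen <<- c(seen, key)
            rings[[length(rings) + 1]] <<- sort(path)
          }
        }
        return(invisible())
      }
      for (nxt in which(adj[last, ])) {
        if (nxt %in% path) next
        if (nxt < start) next
        walk(c(path, nxt))
      }
    }
    walk(path)
  }
  rings
}

#' Extract aromatic rings from a structure
#'
#' Default selector: His side-chain imidazoles (by atom name) plus
#' 5-membered nitrogen-containing rings of non-protein, non-water
#' residues (imidazole ligands of metal complexes, detected by
#' connectivity so the ligand residue code does not matter).
#'
#' @param struct An `xtal_structure`.
#' @param atoms Optional atom table (defaults to the structure's); used
#'   internally for symmetry-mate copies.
#' @param copy Descriptor recorded in each `ring_id` (e.g. `"asu"`).
#' @param metal_elements Metal element symbols used to note which metals a
#'   ring coordinates (for the metal-bridged pair exclusion).
#' @return List of `aromatic_ring` with `ring_id` lists containing
#'   `chain`, `res_seq`, `res_name`, `ring_index`, `copy`, `bound_metals`.
#' @export
find_rings <- function(struct, atoms = NULL, copy = "asu",
                       metal_elements = "Re") {
  if (is.null(atoms)) atoms <- struct$atoms
  atoms <- collapse_altlocs(atoms)
  metals <- atoms[atoms$element %in% toupper(metal_elements), , drop = FALSE]
  rings <- list()
  add_ring <- function(sub, idx, ring_index) {
    coords <- as.matrix(sub[idx, c("x", "y", "z")])
    bound <- integer(0)
    nidx <- idx[sub$element[idx] == "N"]
    if (nrow(metals) > 0 && length(nidx) > 0) {
      d2 <- cross_dist2(as.matrix(sub[nidx, c("x", "y", "z"), drop = FALSE]),
                        as.matrix(metals[, c("x", "y", "z")]))
      bound <- metals$serial[apply(d2 <= 2.6^2, 2, any)]
    }
    rid <- list(chain = sub$chain[idx[1]], res_seq = sub$res_seq[idx[1]],
                res_name = sub$res_name[idx[1]], ring_index = ring_index,
                copy = copy, bound_metals = bound)
    rings[[length(rings) + 1]] <<- fit_ring(coords, rid)
  }
  key <- paste(atoms$chain, atoms$res_seq, atoms$res_name)
  for (kk in unique(key)) {
    sub <- atoms[key == kk, , drop = FALSE]
    rn <- toupper(sub$res_name[1])
    if (rn == "HIS") {
      idx <- match(.his_ring, sub$name)
      if (!any(is.na(idx))) add_ring(sub, idx, 1L)
    } else if (!is_protein_res(rn) && !is_water_res(rn)) {
      heavy <- which(sub$element %in% c("C", "N"))
      if (length(heavy) >= 5) {
        found <- five_rings_by_connectivity(
          as.matrix(sub[heavy, c("x", "y", "z")]))
        ri <- 0L
        for (f in found) {
          idx <- heavy[f]
          if (!any(sub$element[idx] == "N")) next  # want imidazole-like rings
          ri <- ri + 1L
          add_ring(sub, idx, ri)
        }
      }
    }
  }
  rings
}

ring_key <- function(ring) {
  id <- ring$ring_id
  sprintf("%s/%s%d.%d@%s", id$chain, id$res_name, id$res_seq,
          id$ring_index, id$copy)
}

#' Ring interaction network across symmetry mates
#'
#' All ring pairs (reference-reference and reference-vs-symmetry-mate)
#' with centroid separation at or below `max_distance` are collected,
#' classified with [classify_stacking()], and grouped into connected
#' components ("cages"). Pairs of rings coordinated to the same metal
#' atom in the same molecule copy (the two cis imidazoles of one complex)
#' are excluded by default: their geometry is set by the coordination
#' sphere, not by pi stacking. Reference-vs-mate pairs are deduplicated so
#' each physical pair appears once.
#'
#' @param struct An `xtal_structure`.
#' @param max_distance Centroid distance cutoff (Angstrom, default 5.5).
#' @param criteria Stacking criteria set (see [classify_stacking()]).
#' @param model Optional [precision_model()]; when present each pair
#'   carries a distance su of `sqrt(2)` times the per-centroid su.
#' @param centroid_su_reduce Divide the centroid su by `sqrt(n_atoms)`
#'   (default `FALSE`: the conservative choice, since ring-atom position
#'   errors are correlated through the refinement restraints).
#' @param include_symmetry Search symmetry mates (default `TRUE`).
#' @param exclude_metal_bridged Drop same-copy pairs sharing a bound metal
#'   (default `TRUE`).
#' @param metal_elements Metals for the bridging test.
#' @return List of class `ring_network`: `pairs` (data frame), `rings`
#'   (data frame of all rings seen, with cage membership).
#' @export
find_ring_network <- function(struct, max_distance = 5.5,
                              criteria = "small_molecule", model = NULL,
                              centroid_su_reduce = FALSE,
                              include_symmetry = TRUE,
                              exclude_metal_bridged = TRUE,
                              metal_elements = "Re") {
  base <- find_rings(struct, copy = "asu", metal_elements = metal_elements)
  all_rings <- base
  if (include_symmetry && length(base) > 0) {
    # ring diameter margin so mate rings with centroids in range are found
    for (m in symmetry_mates(struct, max_distance + 4)) {
      copy <- sprintf("op%d[%d,%d,%d]", m$op_index,
                      m$shift[1], m$shift[2], m$shift[3])
      mr <- find_rings(struct, atoms = m$atoms, copy = copy,
                       metal_elements = metal_elements)
      all_rings <- c(all_rings, mr)
    }
  }
  n <- length(all_rings)
  pairs <- list()
  seen_phys <- character(0)
  n_base <- length(base)
  for (i in seq_len(n)) {
    jstart <- i + 1
    if (jstart > n) break
    for (j in jstart:n) {
      # only pairs with at least one asu ring are reported (mate-mate
      # pairs are images of an asu pair or lie outside the reference shell)
      if (i > n_base && j > n_base) next
      ra <- all_rings[[i]]; rb <- all_rings[[j]]
      d <- sqrt(sum((ra$centroid - rb$centroid)^2))
      if (d > max_distance) next
      same_copy <- identical(ra$ring_id$copy, rb$ring_id$copy)
      if (exclude_metal_bridged && same_copy &&
          length(intersect(ra$ring_id$bound_metals,
                           rb$ring_id$bound_metals)) > 0) next
      # physical-pair dedupe: an asu-mate pair and its mirror map to the
      # same unordered residue-key pair at the same distance
      phys <- paste(sort(c(sub("@.*", "", ring_key(ra)),
                           sub("@.*", "", ring_key(rb)))),
                    collapse = "|")
      phys <- sprintf("%s#%.4f", phys, d)
      if (phys %in% seen_phys) next
      seen_phys <- c(seen_phys, phys)
      ang <- interplanar_angle(ra$normal, rb$normal)
      su <- NA_real_
      if (!is.null(model)) {
        red_a <- if (centroid_su_reduce) sqrt(nrow(ra$coords)) else 1
        red_b <- if (centroid_su_reduce) sqrt(nrow(rb$coords)) else 1
        su <- distance_su(model$dpi / red_a, model$dpi / red_b)
      }
      pairs[[length(pairs) + 1]] <- data.frame(
        ring_a = ring_key(ra), ring_b = ring_key(rb),
        i = i, j = j, distance = d, su = su, angle = ang,
        label = as.character(classify_stacking(d, ang, criteria)),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(ring_a = character(), ring_b = character(),
               i = integer(), j = integer(), distance = numeric(),
               su = numeric(), angle = numeric(), label = character(),
               stringsAsFactors = FALSE)

  # connected components over rings that participate in a pair
  cage_id <- rep(NA_integer_, n)
  if (nrow(pairs) > 0) {
    parent <- seq_len(n)
    findp <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (r in seq_len(nrow(pairs))) {
      a <- findp(pairs$i[r]); b <- findp(pairs$j[r])
      if (a != b) parent[a] <- b
    }
    roots <- vapply(seq_len(n), findp, integer(1))
    used <- sort(unique(roots[c(pairs$i, pairs$j)]))
    for (ci in seq_along(used))
      cage_id[roots == used[ci]] <- ci
    pairs$cage <- cage_id[pairs$i]
  } else {
    pairs$cage <- integer(0)
  }

  rings_df <- data.frame(
    ring = vapply(all_rings, ring_key, character(1)),
    res_name = vapply(all_rings, function(r) r$ring_id$res_name, character(1)),
    res_seq = vapply(all_rings, function(r) r$ring_id$res_seq, numeric(1)),
    copy = vapply(all_rings, function(r) r$ring_id$copy, character(1)),
    planarity_rmsd = vapply(all_rings, function(r) r$planarity_rmsd, numeric(1)),
    cage = cage_id,
    stringsAsFactors = FALSE)

  pairs <- pairs[order(pairs$cage, pairs$distance), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, rings = rings_df,
                 criteria = criteria, max_distance = max_distance),
            class = "ring_network")
}

#' @export
print.ring_network <- function(x, ...) {
  ncage <- if (nrow(x$pairs) > 0) max(x$pairs$cage) else 0
  cat(sprintf("ring network: %d interacting pairs in %d cage(s)\n",
              nrow(x$pairs), ncage))
  if (nrow(x$pairs) > 0)
    print(x$pairs[, c("ring_a", "ring_b", "distance", "su", "angle", "label")],
          digits = 4)
  invisible(x)
}

#' Export a ring network as CSV
#'
#' @param network A `ring_network`.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_cage_csv <- function(network, path) {
  utils::write.csv(network$pairs[, c("ring_a", "ring_b", "distance", "su",
                                     "angle", "label", "cage")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
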