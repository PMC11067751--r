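# Tracking metal-site attributes across a structure time series:
# site matching, wavelength-grouped trends, residue shifts, reports.

site_key_of <- function(site) {
  if (nrow(site$binding_residues) > 0) {
    prot <- site$ligands[is_protein_res(site$ligands$res_name), , drop = FALSE]
    r <- prot[which.min(prot$distance), ]
    sprintf("%s/%s%d", r$chain, r$res_name, r$res_seq)
  } else {
    NA_character_
  }
}

# primary protein-donor distance record of a site (shortest)
primary_donor <- function(site) {
  prot <- site$ligands[is_protein_res(site$ligands$res_name), , drop = FALSE]
  if (nrow(prot) == 0) return(NULL)
  prot[which.min(prot$distance), ]
}

#' Match metal sites across a structure series
#'
#' Sites sharing a binding-residue key (chain + residue) are merged into
#' one trajectory. Metals with no protein residue key are matched by
#' position: under the isomorphous-cell assumption coordinates are
#' directly comparable without superposition, and metals within 1.5
#' Angstrom (minimum over symmetry images) are taken as the same site.
#' Unmatched sites become singleton trajectories.
#'
#' @param analyses List of per-structure analyses, each a list with
#'   `structure` (an `xtal_structure` whose `meta` has `week` and
#'   `wavelength`), `sites` (from [find_metal_sites()]) and optionally
#'   `calls` (from [classify_structure()]).
#' @param position_tol Positional matching tolerance in Angstrom.
#' @param cell_dev_warn Warn when any fractional cell deviation across the
#'   series exceeds this (default 0.02).
#' @return List of `site_trajectory`: `site_key` and `points` (data frame
#'   ordered by week).
#' @export
match_sites <- function(analyses, position_tol = 1.5, cell_dev_warn = 0.02) {
  if (length(analyses) < 2)
    stop("site matching needs at least 2 analysed structures")
  cells <- vapply(analyses, function(a)
    c(a$structure$cell$a, a$structure$cell$b, a$structure$cell$c),
    numeric(3))
  dev <- apply(cells, 1, function(v) (max(v) - min(v)) / stats::median(v))
  if (any(dev > cell_dev_warn))
    warning(sprintf(
      "cells deviate by up to %.1f%% across the series; structures may not be isomorphous",
      100 * max(dev)))

  traj <- list()   # key -> list(points = list of rows, pos = xyz)
  anon <- list()   # positional trajectories for keyless metals
  for (a in analyses) {
    wk <- a$structure$meta$week
    wl <- a$structure$meta$wavelength
    for (site in a$sites) {
      key <- site_key_of(site)
      pd <- primary_donor(site)
      label <- NA_character_
      if (!is.null(a$calls) && nrow(a$calls) > 0 && !is.null(pd)) {
        hit <- a$calls$metal_serial == site$metal$serial &
          a$calls$res_seq == pd$res_seq & a$calls$atom == pd$name
        if (any(hit)) label <- a$calls$label[which(hit)[1]]
      }
      row <- data.frame(
        week = wk, wavelength = wl,
        occupancy = site$occupancy,
        peak_height = site$peak_height,
        residual_density = site$residual_density,
        distance = if (is.null(pd)) NA_real_ else pd$distance,
        su = if (is.null(pd)) NA_real_ else pd$su,
        donor_atom = if (is.null(pd)) NA_character_ else pd$name,
        label = label,
        stringsAsFactors = FALSE)
      if (!is.na(key)) {
        if (is.null(traj[[key]])) traj[[key]] <- list(points = list())
        traj[[key]]$points <- c(traj[[key]]$points, list(row))
      } else {
        pos <- as.numeric(site$metal[c("x", "y", "z")])
        matched <- FALSE
        for (t in seq_along(anon)) {
          if (sym_min_dist(a$structure, pos, anon[[t]]$pos) <= position_tol) {
            anon[[t]]$points <- c(anon[[t]]$points, list(row))
            matched <- TRUE
            break
          }
        }
        if (!matched)
          anon[[length(anon) + 1]] <- list(points = list(row), pos = pos)
      }
    }
  }

  finish <- function(points, key) {
    pts <- do.call(rbind, points)
    dup <- duplicated(pts[, c("week", "wavelength")])
    if (any(dup))
      stop("duplicate (week, wavelength) points for site ", key, ": week ",
           paste(pts$week[dup], collapse = ", "))
    pts <- pts[order(pts$week, pts$wavelength), , drop = FALSE]
    rownames(pts) <- NULL
    structure(list(site_key = key, points = pts), class = "site_trajectory")
  }
  out <- lapply(names(traj), function(k) finish(traj[[k]]$points, k))
  out <- c(out, lapply(seq_along(anon), function(t)
    finish(anon[[t]]$points,
           sprintf("xyz(%.1f,%.1f,%.1f)", anon[[t]]$pos[1],
                   anon[[t]]$pos[2], anon[[t]]$pos[3]))))
  keys <- vapply(out, function(t) t$site_key, character(1))
  out[order(keys)]
}

#' @export
print.site_trajectory <- function(x, ...) {
  cat("site", x$site_key, "-", nrow(x$points), "time points\n")
  print(x$points, digits = 4)
  invisible(x)
}

#' Monotone trend of an attribute over time
#'
#' Tie-corrected Kendall rank correlation (tau-b) of the attribute
#' against week number. Intended to be computed within one wavelength
#' group only: anomalous peak heights (and to a lesser degree
#' occupancies) are not comparable across wavelengths.
#'
#' @param values Attribute values.
#' @param weeks Matching week numbers.
#' @param attribute Name recorded in the summary.
#' @return A `trend_summary`: `attribute`, `tau`, `n`, `direction`
#'   (`increasing` / `decreasing` / `flat`, or `insufficient` for fewer
#'   than 3 usable points).
#' @export
site_trend <- function(values, weeks, attribute = "value") {
  ok <- is.finite(values) & is.finite(weeks)
  values <- values[ok]; weeks <- weeks[ok]
  n <- length(values)
  if (n < 3) {
    return(structure(list(attribute = attribute, tau = NA_real_, n = n,
                          direction = "insufficient"),
                     class = "trend_summary"))
  }
  tau <- if (stats::sd(values) == 0) 0 else
    stats::cor(weeks, values, method = "kendall")
  direction <- if (is.na(tau) || tau == 0) "flat"
  else if (tau > 0) "increasing" else "decreasing"
  structure(list(attribute = attribute, tau = tau, n = n,
                 direction = direction),
            class = "trend_summary")
}

#' @export
print.trend_summary <- function(x, ...) {
  cat(sprintf("%s: tau=%s over %d points (%s)\n", x$attribute,
              if (is.na(x$tau)) "NA" else sprintf("%+.3f", x$tau),
              x$n, x$direction))
  invisible(x)
}

#' Trends for every trajectory, attribute and wavelength group
#'
#' @param trajectories From [match_sites()].
#' @param attributes Attribute columns to examine.
#' @param by_wavelength Compute within wavelength groups (default `TRUE`;
#'   mixing wavelengths conflates signal strength with time and must be
#'   requested explicitly).
#' @return Data frame: `site`, `wavelength`, `attribute`, `tau`, `n`,
#'   `direction`.
#' @export
series_trends <- function(trajectories,
                          attributes = c("occupancy", "peak_height"),
                          by_wavelength = TRUE) {
  rows <- list()
  for (tr in trajectories) {
    pts <- tr$points
    groups <- if (by_wavelength)
      split(pts, pts$wavelength) else list(all = pts)
    for (g in names(groups)) {
      sub <- groups[[g]]
      for (attr_name in attributes) {
        ts <- site_trend(sub[[attr_name]], sub$week, attr_name)
        rows[[length(rows) + 1]] <- data.frame(
          site = tr$site_key,
          wavelength = if (by_wavelength) as.numeric(g) else NA_real_,
          attribute = attr_name, tau = ts$tau, n = ts$n,
          direction = ts$direction, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(site = character(), wavelength = numeric(),
                      attribute = character(), tau = numeric(),
                      n = integer(), direction = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res <- res[order(res$site, res$wavelength, res$attribute), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Displacement of one residue between two isomorphous structures
#'
#' Displacements are computed on shared atom names in the common crystal
#' frame, with no superposition (the isomorphous-cell assumption).
#'
#' @param struct_a,struct_b Two `xtal_structure`s.
#' @param chain Chain identifier.
#' @param res_seq Residue number.
#' @return List: `max`, `mean`, `per_atom` (data frame), `missing`
#'   (atom names present in only one structure).
#' @export
residue_shift <- function(struct_a, struct_b, chain, res_seq) {
  pick <- function(s) {
    at <- collapse_altlocs(s$atoms)
    at[at$chain == chain & at$res_seq == res_seq, , drop = FALSE]
  }
  a <- pick(struct_a); b <- pick(struct_b)
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("residue ", chain, "/", res_seq, " absent from one of the structures")
  shared <- intersect(a$name, b$name)
  if (length(shared) == 0)
    stop("residue ", chain, "/", res_seq, " has no shared atom names")
  ia <- match(shared, a$name); ib <- match(shared, b$name)
  d <- sqrt(rowSums((as.matrix(a[ia, c("x", "y", "z")]) -
                       as.matrix(b[ib, c("x", "y", "z")]))^2))
  list(max = max(d), mean = mean(d),
       per_atom = data.frame(name = shared, displacement = d,
                             stringsAsFactors = FALSE),
       missing = union(setdiff(a$name, shared), setdiff(b$name, shared)))
}

#' Write the full report bundle for a series analysis
#'
#' Emits, with deterministic ordering and content:
#' \itemize{
#'   \item `site_timeseries.csv` - one row per site and time point
#'     (occupancy, anomalous peak height, residual density);
#'   \item `distances.csv` - metal-donor distances with su, references
#'     and covalent/weak labels per time point;
#'   \item `cages.csv` - ring-stacking pairs per time point;
#'   \item `summary.json` - trends and the configuration used.
#' }
#'
#' @param trajectories From [match_sites()].
#' @param trends From [series_trends()].
#' @param analyses The per-structure analyses (for distance and cage
#'   tables).
#' @param out_dir Output directory (created if needed).
#' @param config Configuration list echoed into the summary.
#' @param warnings Character vector of warnings to record.
#' @return `out_dir`, invisibly.
#' @export
build_report <- function(trajectories, trends, analyses, out_dir,
                         config = list(), warnings = character(0)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ts_rows <- lapply(trajectories, function(tr)
    cbind(site = tr$site_key, tr$points, stringsAsFactors = FALSE))
  ts <- if (length(ts_rows)) do.call(rbind, ts_rows) else
    data.frame(site = character(), week = numeric(), wavelength = numeric(),
               occupancy = numeric(), peak_height = numeric(),
               residual_density = numeric(), distance = numeric(),
               su = numeric(), donor_atom = character(), label = character(),
               stringsAsFactors = FALSE)
  ts <- ts[order(ts$site, ts$week, ts$wavelength), , drop = FALSE]
  utils::write.csv(ts, file.path(out_dir, "site_timeseries.csv"),
                   row.names = FALSE, quote = FALSE)

  dist_rows <- list()
  cage_rows <- list()
  for (a in analyses) {
    wk <- a$structure$meta$week; wl <- a$structure$meta$wavelength
    if (!is.null(a$calls) && nrow(a$calls) > 0)
      dist_rows[[length(dist_rows) + 1]] <-
        cbind(week = wk, wavelength = wl, a$calls, stringsAsFactors = FALSE)
    if (!is.null(a$network) && nrow(a$network$pairs) > 0)
      cage_rows[[length(cage_rows) + 1]] <-
        cbind(week = wk, wavelength = wl,
              a$network$pairs[, c("ring_a", "ring_b", "distance", "su",
                                  "angle", "label", "cage")],
              stringsAsFactors = FALSE)
  }
  dists <- if (length(dist_rows)) do.call(rbind, dist_rows) else
    data.frame(week = numeric(), wavelength = numeric())
  if (nrow(dists) > 0)
    dists <- dists[order(dists$week, dists$wavelength, dists$res_seq,
                         dists$atom), , drop = FALSE]
  utils::write.csv(dists, file.path(out_dir, "distances.csv"),
                   row.names = FALSE, quote = FALSE)
  cages <- if (length(cage_rows)) do.call(rbind, cage_rows) else
    data.frame(week = numeric(), wavelength = numeric())
  utils::write.csv(cages, file.path(out_dir, "cages.csv"),
                   row.names = FALSE, quote = FALSE)

  summary <- list(
    n_structures = length(analyses),
    n_trajectories = length(trajectories),
    trends = trends,
    config = config,
    warnings = warnings)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10,
                       na = "null")
  invisible(out_dir)
}
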