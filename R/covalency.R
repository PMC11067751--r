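# Classification of metal-donor distances as covalent bonds or weak
# interactions, against two reference families: sums of Cordero (2008)
# covalent radii, and small-molecule survey mean distances for the
# Re(CO)3 fragment.

#' Load the bundled (or user-supplied) reference tables
#'
#' @param radii_file CSV with columns `element`, `radius`, `spread`
#'   (Angstrom); defaults to the bundled Cordero 2008 excerpt.
#' @param survey_file CSV with columns `metal`, `donor_context`, `mean`,
#'   `su`, `n_hits`; defaults to the bundled Re(CO)3 survey means.
#' @return List with data frames `radii` and `survey`.
#' @export
reference_tables <- function(radii_file = NULL, survey_file = NULL) {
  if (is.null(radii_file))
    radii_file <- system.file("extdata", "covalent_radii.csv",
                              package = "metalloscan", mustWork = TRUE)
  if (is.null(survey_file))
    survey_file <- system.file("extdata", "csd_survey.csv",
                               package = "metalloscan", mustWork = TRUE)
  radii <- utils::read.csv(radii_file, stringsAsFactors = FALSE)
  survey <- utils::read.csv(survey_file, stringsAsFactors = FALSE)
  radii$element <- toupper(radii$element)
  survey$metal <- toupper(survey$metal)
  list(radii = radii, survey = survey)
}

#' Sum of covalent radii for an element pair
#'
#' The expected covalent bond length between two elements is the sum of
#' their tabulated covalent radii; its spread is the quadrature sum of the
#' per-element spreads.
#'
#' @param elem_a,elem_b Element symbols (case-insensitive).
#' @param refs Reference tables from [reference_tables()].
#' @return List with `mean` and `su` in Angstrom.
#' @examples
#' covalent_radius_sum("Re", "O")  # 2.17 A
#' covalent_radius_sum("Re", "N")  # 2.22 A
#' @export
covalent_radius_sum <- function(elem_a, elem_b, refs = reference_tables()) {
  tab <- refs$radii
  pick <- function(e) {
    i <- match(toupper(e), tab$element)
    if (is.na(i)) stop("element '", e, "' not in the covalent radii table")
    tab[i, ]
  }
  ra <- pick(elem_a); rb <- pick(elem_b)
  list(mean = ra$radius + rb$radius,
       su = sqrt(ra$spread^2 + rb$spread^2))
}

# donor context from residue + atom name; NA when no specific context.
donor_context_of <- function(res_name, atom_name, element) {
  res <- toupper(res_name); atm <- toupper(atom_name)
  if (res == "HIS" && atm %in% c("ND1", "NE2")) return("imidazole_N")
  if (res %in% c("ASP", "GLU") && grepl("^O[DE][12]", atm))
    return("carboxylate_O")
  if ((res == "ASN" && atm == "ND2") || (res == "GLN" && atm == "NE2"))
    return("amide_N")
  switch(toupper(element),
         "N" = "generic_N", "O" = "generic_O", "S" = "generic_S",
         NA_character_)
}

context_donor_element <- function(context) {
  switch(context,
         imidazole_N = "N", amide_N = "N", generic_N = "N",
         carboxylate_O = "O", generic_O = "O", generic_S = "S",
         NA_character_)
}

#' Classify one metal-donor distance
#'
#' A distance is `"covalent"` when it is equal within `k` combined
#' standard uncertainties to at least one of the two references (the
#' covalent-radius sum for the element pair, or the matching
#' small-molecule survey distance); `"weak"` when it is within the `cap`
#' but consistent with neither; `"none"` beyond the cap. Both z-scores are
#' always reported.
#'
#' @param distance Observed metal-donor distance (Angstrom).
#' @param su Its standard uncertainty.
#' @param metal Metal element symbol (default `"Re"`).
#' @param donor_context One of `imidazole_N`, `carboxylate_O`, `amide_N`,
#'   `generic_N`, `generic_O`, `generic_S`.
#' @param k Tolerance multiplier (default 2).
#' @param cap Hard distance cap in Angstrom (default 3.0).
#' @param refs Reference tables from [reference_tables()].
#' @return List (class `interaction_call`) with the label, both
#'   references, and z-scores.
#' @export
classify_interaction <- function(distance, su, metal = "Re",
                                 donor_context, k = 2, cap = 3.0,
                                 refs = reference_tables()) {
  if (!is.finite(distance) || distance <= 0) stop("distance must be > 0")
  known <- c("imidazole_N", "carboxylate_O", "amide_N",
             "generic_N", "generic_O", "generic_S")
  if (!donor_context %in% known) {
    warning("unknown donor context '", donor_context,
            "'; falling back to generic_N")
    donor_context <- "generic_N"
  }
  donor_elem <- context_donor_element(donor_context)
  rsum <- covalent_radius_sum(metal, donor_elem, refs)
  w_rad <- within_error(distance, su, rsum$mean, rsum$su, k)

  srow <- refs$survey[refs$survey$metal == toupper(metal) &
                        refs$survey$donor_context == donor_context, ]
  if (nrow(srow) == 1) {
    w_sur <- within_error(distance, su, srow$mean, srow$su, k)
    survey_ref <- list(mean = srow$mean, su = srow$su)
  } else {
    w_sur <- list(consistent = FALSE, z = NA_real_, delta = NA_real_)
    survey_ref <- NULL
  }

  label <- if (distance > cap) "none"
  else if (w_rad$consistent || isTRUE(w_sur$consistent)) "covalent"
  else "weak"

  structure(list(distance = distance, su = su, metal = metal,
                 donor_context = donor_context,
                 radius_sum = rsum, survey = survey_ref,
                 z_radius_sum = w_rad$z, z_survey = w_sur$z,
                 k = k, cap = cap, label = label),
            class = "interaction_call")
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf("%s: %s vs %s [%s] (z_radii=%.2f%s)\n",
              x$label, format_bracket(x$distance, x$su),
              format_bracket(x$radius_sum$mean, x$radius_sum$su),
              x$donor_context, x$z_radius_sum,
              if (!is.na(x$z_survey))
                sprintf(", z_survey=%.2f", x$z_survey) else ""))
  invisible(x)
}

#' Classify every metal-donor pair of a structure's metal sites
#'
#' Produces a distance table in the shape of a per-structure bond-distance
#' report: one row per (site, protein donor atom) pair, ordered by residue
#' number, with the observed distance, its propagated su, both reference
#' distances, z-scores and the covalent/weak/none label. When a carboxylate
#' presents both of its oxygen atoms within the cutoff, both rows appear
#' and the shorter is flagged `primary`.
#'
#' @param sites List of `metal_site` from [find_metal_sites()], with
#'   precision attached (see [attach_precision()]).
#' @param k Tolerance multiplier.
#' @param cap Hard distance cap (Angstrom).
#' @param refs Reference tables.
#' @param protein_only Classify only amino-acid donors (default `TRUE`;
#'   carbonyl and imidazole ligand atoms of the metal complex itself are
#'   coordination, not protein binding).
#' @return Data frame of interaction calls.
#' @export
classify_structure <- function(sites, k = 2, cap = 3.0,
                               refs = reference_tables(),
                               protein_only = TRUE) {
  rows <- list()
  for (site in sites) {
    lig <- site$ligands
    if (protein_only && nrow(lig) > 0)
      lig <- lig[is_protein_res(lig$res_name), , drop = FALSE]
    if (nrow(lig) == 0) next
    for (i in seq_len(nrow(lig))) {
      ctx <- donor_context_of(lig$res_name[i], lig$name[i], lig$element[i])
      call <- classify_interaction(lig$distance[i],
                                   ifelse(is.na(lig$su[i]), 0, lig$su[i]),
                                   metal = site$metal$element,
                                   donor_context = ctx, k = k, cap = cap,
                                   refs = refs)
      rows[[length(rows) + 1]] <- data.frame(
        metal_serial = site$metal$serial,
        metal = site$metal$element,
        chain = lig$chain[i], res_seq = lig$res_seq[i],
        res_name = lig$res_name[i], atom = lig$name[i],
        distance = lig$distance[i], su = lig$su[i],
        donor_context = ctx,
        ref_radius_mean = call$radius_sum$mean,
        ref_radius_su = call$radius_sum$su,
        ref_survey_mean = if (is.null(call$survey)) NA_real_ else call$survey$mean,
        ref_survey_su = if (is.null(call$survey)) NA_real_ else call$survey$su,
        z_radius_sum = call$z_radius_sum,
        z_survey = call$z_survey,
        label = call$label,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(metal_serial = integer(), metal = character(),
                      chain = character(), res_seq = integer(),
                      res_name = character(), atom = character(),
                      distance = numeric(), su = numeric(),
                      donor_context = character(),
                      ref_radius_mean = numeric(), ref_radius_su = numeric(),
                      ref_survey_mean = numeric(), ref_survey_su = numeric(),
                      z_radius_sum = numeric(), z_survey = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$res_seq, res$atom, res$metal_serial), , drop = FALSE]
  # flag the shorter oxygen of a carboxylate pair presented twice
  res$primary <- TRUE
  key <- paste(res$metal_serial, res$chain, res$res_seq)
  for (kk in unique(key[duplicated(key)])) {
    idx <- which(key == kk)
    res$primary[idx] <- seq_along(idx) %in% which.min(res$distance[idx])
  }
  rownames(res) <- NULL
  res
}
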