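# Crystal structure input/output: unit cells, symmetry operators, space
# groups, and PDB-format coordinate files.

#' Construct a unit cell
#'
#' @param a,b,c Cell edge lengths in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#' @return An object of class `unit_cell`.
#' @examples
#' unit_cell(81.12, 81.12, 37.19, 90, 90, 90)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  lens <- c(a = a, b = b, c = c)
  angs <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("unit cell lengths must be positive and finite")
  if (any(!is.finite(angs)) || any(angs <= 0) || any(angs >= 180))
    stop("unit cell angles must lie in (0, 180) degrees")
  cell <- structure(list(a = a, b = b, c = c,
                         alpha = alpha, beta = beta, gamma = gamma),
                    class = "unit_cell")
  if (cell_volume(cell) <= 0) stop("degenerate unit cell (volume <= 0)")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

# Orthogonalization matrix (PDB convention: a along x, b in the xy plane).
# Columns are the cell basis vectors in Angstrom; frac %*% t(M) gives
# orthogonal coordinates.
cell_orth_matrix <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  v <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v <= 0) stop("degenerate unit cell (volume <= 0)")
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0,      0,           cell$c * sqrt(v) / sg),
         nrow = 3, byrow = TRUE)
}

cell_volume <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  v <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v <= 0) return(0)
  cell$a * cell$b * cell$c * sqrt(v)
}

as_xyz_matrix <- function(xyz) {
  if (is.matrix(xyz)) {
    stopifnot(ncol(xyz) == 3)
    xyz
  } else {
    stopifnot(length(xyz) == 3)
    matrix(xyz, ncol = 3)
  }
}

#' Convert orthogonal (Angstrom) coordinates to fractional, and back
#'
#' For an all-90 degree cell this reduces to componentwise division by
#' (a, b, c). Both functions accept a length-3 vector or an n x 3 matrix
#' and return the same shape.
#'
#' @param cell A [unit_cell()].
#' @param xyz Orthogonal coordinates (Angstrom).
#' @param frac Fractional coordinates.
#' @return Coordinates in the other frame.
#' @export
orth_to_frac <- function(cell, xyz) {
  m <- as_xyz_matrix(xyz)
  out <- m %*% t(solve(cell_orth_matrix(cell)))
  if (is.matrix(xyz)) out else drop(out)
}

#' @rdname orth_to_frac
#' @export
frac_to_orth <- function(cell, frac) {
  m <- as_xyz_matrix(frac)
  out <- m %*% t(cell_orth_matrix(cell))
  if (is.matrix(frac)) out else drop(out)
}

#' Parse an xyz-style symmetry operator string
#'
#' Accepts International Tables style triplets such as `"-Y,X+1/2,Z+3/4"`,
#' case-insensitively and ignoring whitespace. The rotation acts on
#' fractional coordinates; translations are reduced modulo 1 into `[0, 1)`.
#'
#' @param text Operator triplet, e.g. `"X,Y,Z"`.
#' @return A `symop`: list with a 3x3 `rotation` and length-3 `translation`.
#' @examples
#' parse_symop("-X,-Y,Z+1/2")
#' @export
parse_symop <- function(text) {
  parts <- strsplit(gsub("[[:space:]]", "", toupper(text)), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3)
    stop("symmetry operator must have three comma-separated terms: ", text)
  rot <- matrix(0, 3, 3)
  trans <- numeric(3)
  for (i in 1:3) {
    # split into signed tokens: axis letters or rational fractions
    toks <- regmatches(parts[i],
                       gregexpr("[+-]?([XYZ]|[0-9]+(/[0-9]+)?)", parts[i]))[[1]]
    if (length(toks) == 0 || sum(nchar(toks)) != nchar(parts[i]))
      stop("cannot parse symmetry operator term '", parts[i], "'")
    for (tok in toks) {
      sign <- if (startsWith(tok, "-")) -1 else 1
      body <- sub("^[+-]", "", tok)
      if (body %in% c("X", "Y", "Z")) {
        j <- match(body, c("X", "Y", "Z"))
        rot[i, j] <- rot[i, j] + sign
      } else if (grepl("/", body, fixed = TRUE)) {
        nd <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
        trans[i] <- trans[i] + sign * nd[1] / nd[2]
      } else {
        trans[i] <- trans[i] + sign * as.numeric(body)
      }
    }
  }
  symop(rot, trans)
}

symop <- function(rotation, translation) {
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (!all(rotation %in% c(-1, 0, 1)))
    stop("symmetry rotation entries must be in {-1, 0, 1}")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("symmetry rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = translation %% 1),
            class = "symop")
}

#' Apply a symmetry operator to fractional coordinates
#'
#' @param op A `symop`.
#' @param frac Fractional coordinates (vector or n x 3 matrix).
#' @param shift Optional integer lattice translation added after the op.
#' @return Transformed fractional coordinates, same shape as the input.
#' @export
symop_apply <- function(op, frac, shift = c(0, 0, 0)) {
  m <- as_xyz_matrix(frac)
  out <- m %*% t(op$rotation)
  out <- sweep(out, 2, op$translation + shift, "+")
  if (is.matrix(frac)) out else drop(out)
}

# Compose two ops: (a o b)(x) = a(b(x)); translation reduced mod 1.
symop_compose <- function(a, b) {
  symop(a$rotation %*% b$rotation,
        (a$rotation %*% b$translation + a$translation) %% 1)
}

symop_inverse <- function(op) {
  rinv <- solve(op$rotation)
  symop(rinv, (-rinv %*% op$translation) %% 1)
}

symop_equal <- function(a, b, tol = 1e-9) {
  all(abs(a$rotation - b$rotation) < tol) &&
    all(abs((a$translation - b$translation) %% 1) < tol |
          abs((a$translation - b$translation) %% 1 - 1) < tol)
}

#' @export
print.symop <- function(x, ...) {
  axes <- c("X", "Y", "Z")
  term <- function(i) {
    s <- ""
    for (j in 1:3) {
      if (x$rotation[i, j] != 0)
        s <- paste0(s, if (x$rotation[i, j] > 0 && nzchar(s)) "+" else
          if (x$rotation[i, j] < 0) "-" else "", axes[j])
    }
    if (abs(x$translation[i]) > 1e-9) {
      fr <- round(x$translation[i] * 12)
      s <- paste0(s, "+", fr, "/12")
    }
    s
  }
  cat(paste(vapply(1:3, term, ""), collapse = ","), "\n")
  invisible(x)
}

# Bundled operator triplets keyed by canonical Hermann-Mauguin name.
.sg_ops <- list(
  "P 1" = c("X,Y,Z"),
  "P 43 21 2" = c(
    "X,Y,Z",
    "-X,-Y,Z+1/2",
    "-Y+1/2,X+1/2,Z+3/4",
    "Y+1/2,-X+1/2,Z+1/4",
    "-X+1/2,Y+1/2,-Z+3/4",
    "X+1/2,-Y+1/2,-Z+1/4",
    "Y,X,-Z",
    "-Y,-X,-Z+1/2")
)

canonical_sg_name <- function(name) {
  key <- gsub("[[:space:]]", "", toupper(name))
  known <- names(.sg_ops)
  hit <- match(key, gsub("[[:space:]]", "", toupper(known)))
  if (is.na(hit)) NA_character_ else known[hit]
}

#' Space group with its symmetry operators
#'
#' Operator lists for `"P 1"` and `"P 43 21 2"` (the tetragonal lysozyme
#' group) are bundled; any other group can be supplied as xyz-style
#' operator strings via `ops`.
#'
#' @param name Hermann-Mauguin name, e.g. `"P 43 21 2"` (spacing and case
#'   are not significant).
#' @param ops Optional character vector of operator triplets overriding the
#'   bundled table.
#' @return An object of class `space_group` with elements `name` and `ops`
#'   (list of `symop`).
#' @export
space_group <- function(name, ops = NULL) {
  if (is.null(ops)) {
    canon <- canonical_sg_name(name)
    if (is.na(canon))
      stop("unknown space group '", name, "'; bundled groups: ",
           paste(names(.sg_ops), collapse = ", "),
           ". Supply operator strings via `ops` for other groups.")
    name <- canon
    ops <- .sg_ops[[canon]]
  }
  oplist <- lapply(ops, parse_symop)
  has_id <- any(vapply(oplist, function(o)
    symop_equal(o, symop(diag(3), c(0, 0, 0))), logical(1)))
  if (!has_id) stop("space group operator list lacks the identity")
  structure(list(name = name, ops = oplist), class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("space group %s (%d symmetry operators)\n",
              x$name, length(x$ops)))
  invisible(x)
}

# ---- PDB reading -----------------------------------------------------------

parse_cryst1 <- function(line) {
  num <- function(i, j) suppressWarnings(as.numeric(substr(line, i, j)))
  cell <- unit_cell(num(7, 15), num(16, 24), num(25, 33),
                    num(34, 40), num(41, 47), num(48, 54))
  sg_name <- trimws(substr(line, 56, 66))
  list(cell = cell, sg_name = sg_name)
}

# Standard amino-acid residue codes (used to tell protein donors from
# ligands and waters downstream).
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "MSE", "PHE", "PRO", "SER", "THR",
          "TRP", "TYR", "VAL")

#' Read a PDB-format crystal structure
#'
#' Atom records are parsed with [bio3d::read.pdb()]; the `CRYST1` cell and
#' space group are parsed here (and are required: the symmetry analysis is
#' meaningless without them). All altlocs and HETATM records are kept;
#' coordinates stay in the file's orthogonal Angstrom frame. Only the first
#' model of a multi-model file is used.
#'
#' @param path PDB file.
#' @param meta Optional list with `week`, `wavelength` (Angstrom) and
#'   `label` describing the dataset.
#' @param stats Optional [refinement_stats()] for the model.
#' @return An object of class `xtal_structure`: list with `cell`,
#'   `space_group`, `atoms` (data frame), `meta` and `stats`.
#' @export
read_structure <- function(path, meta = list(), stats = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  icry <- grep("^CRYST1", lines)
  if (length(icry) == 0)
    stop("no CRYST1 record in ", path,
         ": unit cell and space group are required")
  cr <- parse_cryst1(lines[icry[1]])

  # restrict to the first model
  iend <- grep("^ENDMDL", lines)
  last <- if (length(iend)) iend[1] else length(lines)
  atom_idx <- grep("^(ATOM  |HETATM)", lines[seq_len(last)])
  if (length(atom_idx) == 0)
    stop("no ATOM/HETATM records in ", path)

  # validate the fixed-width numeric fields up front so a malformed record
  # is reported with its line number (bio3d would fail less helpfully)
  for (i in atom_idx) {
    ln <- lines[i]
    fields <- c(substr(ln, 7, 11), substr(ln, 31, 38), substr(ln, 39, 46),
                substr(ln, 47, 54), substr(ln, 55, 60), substr(ln, 61, 66))
    if (any(is.na(suppressWarnings(as.numeric(fields)))))
      stop("malformed atom record at line ", i, " of ", path)
  }

  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE,
                         rm.alt = FALSE, rm.insert = FALSE)
  at <- pdb$atom
  if (nrow(at) != length(atom_idx)) {
    atom_idx <- atom_idx[seq_len(min(nrow(at), length(atom_idx)))]
  }

  elem <- toupper(trimws(at$elesy))
  miss <- which(is.na(elem) | elem == "")
  if (length(miss) > 0)
    elem[miss] <- toupper(bio3d::atom2ele(at$elety[miss]))

  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    res_name = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    res_seq = at$resno,
    x = at$x, y = at$y, z = at$z,
    occ = at$o, b = at$b,
    element = elem,
    record = at$type,
    line = atom_idx[seq_len(nrow(at))],
    stringsAsFactors = FALSE
  )
  if (any(atoms$occ < 0 | atoms$occ > 1))
    warning("occupancies outside [0, 1] in ", path)

  sg <- space_group(cr$sg_name)
  if (startsWith(sg$name, "P 4")) {
    if (abs(cr$cell$a - cr$cell$b) > 1e-3 ||
        any(abs(c(cr$cell$alpha, cr$cell$beta, cr$cell$gamma) - 90) > 1e-3))
      stop("tetragonal space group ", sg$name,
           " requires a == b and all angles 90 in ", path)
  }

  wl <- meta$wavelength
  if (!is.null(wl) && (!is.finite(wl) || wl <= 0))
    stop("meta$wavelength must be positive")

  structure(list(cell = cr$cell, space_group = sg, atoms = atoms,
                 meta = list(week = meta$week, wavelength = wl,
                             label = meta$label),
                 stats = stats),
            class = "xtal_structure")
}

#' @export
print.xtal_structure <- function(x, ...) {
  cat(sprintf("crystal structure: %d atoms, %s, a=%.2f b=%.2f c=%.2f A\n",
              nrow(x$atoms), x$space_group$name, x$cell$a, x$cell$b, x$cell$c))
  if (!is.null(x$meta$week))
    cat(sprintf("  week %s, wavelength %s A\n",
                format(x$meta$week), format(x$meta$wavelength)))
  invisible(x)
}

format_atom_name <- function(name, element) {
  # PDB column 13-16 convention: names start in column 14 unless the
  # element symbol is two characters or the name is four characters long
  if (nchar(element) >= 2 || nchar(name) >= 4) {
    sprintf("%-4s", name)
  } else {
    sprintf(" %-3s", name)
  }
}

#' Write a structure to a PDB-format file
#'
#' Emits `CRYST1`, `ATOM`/`HETATM` and `END` records. bio3d's writer is not
#' used because it does not emit the `CRYST1` record that the symmetry
#' analysis requires.
#'
#' @param struct An `xtal_structure`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(struct, path) {
  cl <- struct$cell
  hdr <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                 cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma,
                 struct$space_group$name)
  at <- struct$atoms
  recs <- sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  at$record, at$serial,
                  vapply(seq_len(nrow(at)),
                         function(i) format_atom_name(at$name[i], at$element[i]),
                         character(1)),
                  at$altloc, at$res_name, at$chain, at$res_seq,
                  at$x, at$y, at$z, at$occ, at$b,
                  sprintf("%2s", at$element))
  writeLines(c(hdr, recs, "END"), path)
  invisible(path)
}

# Construct an xtal_structure from parts (used by the fixture generator).
new_structure <- function(cell, sg, atoms, meta = list(), stats = NULL) {
  atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$record)) atoms$record <- "HETATM"
  if (is.null(atoms$line)) atoms$line <- NA_integer_
  structure(list(cell = cell, space_group = sg, atoms = atoms,
                 meta = meta, stats = stats),
            class = "xtal_structure")
}

is_protein_res <- function(res_name) toupper(res_name) %in% .aa3
is_water_res <- function(res_name) toupper(res_name) %in% c("HOH", "WAT", "DOD")
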