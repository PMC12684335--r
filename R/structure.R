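#' Read a structure from PDB or mmCIF
#'
#' Thin wrapper over bio3d's parsers returning a flat atom table. Alternate
#' locations are resolved by keeping altloc `'A'` (or blank); residues with
#' insertion codes are not supported and raise an error. Hydrogens are
#' retained and can be excluded through selections.
#'
#' @param path file path.
#' @param dialect `"pdb"` or `"cif"`; default guessed from the extension.
#' @return object of class `structure3d`: data.frame with columns `chain`,
#'   `resno`, `resid`, `elety` (atom name, PDB v3), `x`, `y`, `z`, `occ`,
#'   `elesy`.
#' @export
read_structure <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dialect <- dialect %||%
    (if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb")
  pdb <- if (dialect == "cif") bio3d::read.cif(path) else
    bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  if (!is.null(a$insert) && any(!is.na(a$insert) & a$insert != ""))
    stop("insertion codes are not supported")
  alt <- a$alt
  keep <- is.na(alt) | alt == "" | alt == "A"
  a <- a[keep, , drop = FALSE]
  df <- data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                   elety = a$elety, x = a$x, y = a$y, z = a$z,
                   occ = a$o %||% 1,
                   elesy = a$elesy %||% substr(a$elety, 1, 1),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)))
    stop("non-finite coordinates in ", path)
  key <- paste(df$chain, df$resno, df$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom) keys after altloc resolution")
  class(df) <- c("structure3d", "data.frame")
  df
}

#' Build a structure from an atom table
#' @param atoms data.frame with columns chain, resno, resid, elety, x, y, z.
#' @return `structure3d`.
#' @export
as_structure3d <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$elesy)) atoms$elesy <- substr(atoms$elety, 1, 1)
  class(atoms) <- c("structure3d", "data.frame")
  atoms
}

#' Write a structure as PDB ATOM records
#' @param struct `structure3d`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(struct, path) {
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(struct)),
    ifelse(nchar(struct$elety) < 4, paste0(" ", struct$elety), struct$elety),
    struct$resid, struct$chain, struct$resno,
    struct$x, struct$y, struct$z, struct$occ, 0, struct$elesy)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Atom selection
#'
#' @param chain chain id, or `NULL` for any.
#' @param residues integer vector of residue numbers, or `NULL` for all.
#' @param atoms atom-name vector (PDB v3, e.g. `"CA"`), or `NULL` for all.
#' @return `atom_selection` object.
#' @export
atom_selection <- function(chain = NULL, residues = NULL, atoms = "CA") {
  structure(list(chain = chain, residues = residues, atoms = atoms),
            class = "atom_selection")
}

#' Read a selection from JSON (`{chain, residues:[...], atoms:[...]}`)
#' @param path JSON file.
#' @return `atom_selection`.
#' @export
read_selection_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  atom_selection(chain = j$chain %||% NULL,
                 residues = j$residues %||% NULL,
                 atoms = j$atoms %||% "CA")
}

apply_selection <- function(struct, sel) {
  keep <- rep(TRUE, nrow(struct))
  if (!is.null(sel$chain)) keep <- keep & struct$chain %in% sel$chain
  if (!is.null(sel$residues)) keep <- keep & struct$resno %in% sel$residues
  if (!is.null(sel$atoms)) keep <- keep & struct$elety %in% sel$atoms
  out <- struct[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("selection resolves to zero atoms")
  out
}

#' Loop definitions of the anticalin scaffold
#'
#' The four structurally variable loops at the open end of the lipocalin
#' beta-barrel: L1 38-51, L2 70-76, L3 95-105, L4 125-132.
#'
#' @return named list of integer residue ranges.
#' @export
loop_definitions <- function() {
  list(L1 = 38:51, L2 = 70:76, L3 = 95:105, L4 = 125:132)
}

# ordered, matched coordinate pair for a selection present in both structures
matched_coords <- function(reference, mobile, sel, strict = TRUE) {
  ra <- apply_selection(reference, sel)
  ma <- apply_selection(mobile, sel)
  rkey <- paste(ra$chain, ra$resno, ra$elety)
  mkey <- paste(ma$chain, ma$resno, ma$elety)
  common <- intersect(rkey, mkey)
  miss <- union(setdiff(rkey, mkey), setdiff(mkey, rkey))
  if (strict && length(miss) > 0)
    stop("unmatched atoms in superposition selection: ",
         paste(utils::head(miss, 10), collapse = "; "),
         if (length(miss) > 10) " ..." else "")
  if (length(common) == 0) stop("no atoms shared by both structures")
  ra <- ra[match(common, rkey), , drop = FALSE]
  ma <- ma[match(common, mkey), , drop = FALSE]
  list(ref = as.matrix(ra[, c("x", "y", "z")]),
       mob = as.matrix(ma[, c("x", "y", "z")]), keys = common)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal rotation/translation of `mobile` onto `reference` over the atoms
#' resolved by `selection` (matched by chain/residue/atom name), via the
#' standard SVD construction with the reflection branch excluded.
#'
#' @param reference,mobile `structure3d` objects.
#' @param selection an [atom_selection()]; default all Calpha atoms.
#' @return object of class `superposition`: `R` (3x3 rotation, det +1),
#'   `t` (translation), `rmsd_fit` (Angstrom), `n_atoms`. Apply with
#'   [apply_superposition()].
#' @export
superpose <- function(reference, mobile, selection = atom_selection()) {
  mc <- matched_coords(reference, mobile, selection)
  P <- mc$mob; Q <- mc$ref
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- unname(cq - as.numeric(R %*% cp))
  fitted <- sweep(P %*% t(R), 2, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  structure(list(R = R, t = t_vec, rmsd_fit = rmsd, n_atoms = nrow(P)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d atoms, fit rmsd %.3f A\n",
              x$n_atoms, x$rmsd_fit))
  invisible(x)
}

#' Apply a superposition to a structure (or coordinate matrix)
#' @param struct `structure3d` or n x 3 matrix.
#' @param sup a `superposition`.
#' @return transformed object of the same kind.
#' @export
apply_superposition <- function(struct, sup) {
  if (is.matrix(struct))
    return(sweep(struct %*% t(sup$R), 2, sup$t, "+"))
  xyz <- as.matrix(struct[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(sup$R), 2, sup$t, "+")
  struct$x <- xyz[, 1]; struct$y <- xyz[, 2]; struct$z <- xyz[, 3]
  struct
}

#' Per-residue Calpha deviations after superposition
#'
#' @param reference,mobile `structure3d` objects.
#' @param sup `superposition` from [superpose()] (fitted elsewhere, e.g. on
#'   the barrel); `mobile` is transformed by it before measuring.
#' @param chain restrict to a chain (default: all shared).
#' @return data.frame: `chain`, `resno`, `deviation` (Angstrom).
#' @export
per_residue_ca_deviation <- function(reference, mobile, sup, chain = NULL) {
  sel <- atom_selection(chain = chain, atoms = "CA")
  mob <- apply_superposition(mobile, sup)
  mc <- matched_coords(reference, mob, sel, strict = FALSE)
  parts <- do.call(rbind, strsplit(mc$keys, " "))
  data.frame(chain = parts[, 1], resno = as.integer(parts[, 2]),
             deviation = sqrt(rowSums((mc$mob - mc$ref)^2)))
}

#' RMSD over a selection after superposition
#'
#' @inheritParams per_residue_ca_deviation
#' @param selection an [atom_selection()] over which to measure (e.g. the
#'   L3 loop Calpha atoms).
#' @return RMSD in Angstrom.
#' @export
selection_rmsd <- function(reference, mobile, sup, selection) {
  mob <- apply_superposition(mobile, sup)
  mc <- matched_coords(reference, mob, selection, strict = FALSE)
  sqrt(mean(rowSums((mc$mob - mc$ref)^2)))
}

#' Distance between two atoms within one structure
#'
#' @param struct `structure3d`.
#' @param atom_a,atom_b lists/vectors `c(resno=, elety=)` (optionally
#'   `chain=`).
#' @return distance in Angstrom.
#' @export
atom_distance <- function(struct, atom_a, atom_b) {
  xa <- .atom_xyz(struct, atom_a)
  xb <- .atom_xyz(struct, atom_b)
  sqrt(sum((xa - xb)^2))
}

.atom_xyz <- function(struct, spec) {
  spec <- as.list(spec)
  sel <- struct$resno == as.integer(spec$resno) &
    struct$elety == spec$elety
  if (!is.null(spec$chain)) sel <- sel & struct$chain == spec$chain
  hit <- struct[sel, , drop = FALSE]
  if (nrow(hit) == 0)
    stop("atom not found: residue ", spec$resno, " ", spec$elety)
  if (nrow(hit) > 1)
    stop("ambiguous atom spec (give a chain): residue ", spec$resno,
         " ", spec$elety)
  as.numeric(hit[1, c("x", "y", "z")])
}

#' Load the study's reference crystal structures
#'
#' Looks for `6z6z.pdb` (apo), `5nkn.pdb` (colchicine-bound) and `3cmp.pdb`
#' (lipocalin 2 scaffold) in `dir` (default: option
#' `colchidyn.structure_dir`, then env var `COLCHIDYN_STRUCTURES`); missing
#' files are fetched from the PDB via bio3d, which requires network access.
#'
#' @param dir directory holding (or receiving) the coordinate files.
#' @return list of `structure3d`: `apo`, `bound`, `lcn2`.
#' @export
load_reference_structures <- function(dir = NULL) {
  dir <- dir %||% getOption("colchidyn.structure_dir",
                            Sys.getenv("COLCHIDYN_STRUCTURES", ""))
  if (!nzchar(dir)) dir <- tempdir()
  ids <- c(apo = "6z6z", bound = "5nkn", lcn2 = "3cmp")
  paths <- file.path(dir, paste0(ids, ".pdb"))
  names(paths) <- names(ids)
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i])) {
      got <- tryCatch(bio3d::get.pdb(toupper(ids[i]), path = dir,
                                     verbose = FALSE),
                      error = function(e) NA_character_,
                      warning = function(w) NA_character_)
      if (is.na(got) || !file.exists(paths[i]))
        stop("reference structure ", toupper(ids[i]), " not available in ",
             dir, " and could not be fetched (offline?)")
    }
  }
  lapply(paths, read_structure)
}

#' The shipped beta-barrel Calpha fitting selection
#'
#' A 58-residue selection over the eight barrel strands (flanking the four
#' loops), used as the superposition frame for all loop measurements. The
#' exact strand residues are an approximation constructed from the scaffold
#' topology; override by editing the JSON or passing your own selection.
#'
#' @param path optional JSON selection file; default the shipped one.
#' @return `atom_selection` of 58 Calpha residues.
#' @export
barrel_selection <- function(path = NULL) {
  path <- path %||% system.file("extdata", "barrel_selection.json",
                                package = "colchidyn")
  read_selection_json(path)
}

#' Full structural comparison of two states over the barrel frame
#'
#' Superposes `mobile` onto `reference` on the barrel selection and reports
#' loop RMSDs, per-residue deviations and their per-loop maxima.
#'
#' @param reference,mobile `structure3d` objects.
#' @param fit_selection selection for the rigid fit; default
#'   [barrel_selection()].
#' @param loops named residue ranges; default [loop_definitions()].
#' @return list: `superposition`, `deviations` (per residue), `loop_rmsd`,
#'   `loop_max` (named vectors, Angstrom).
#' @export
compare_states <- function(reference, mobile,
                           fit_selection = barrel_selection(),
                           loops = loop_definitions()) {
  sup <- superpose(reference, mobile, fit_selection)
  dev <- per_residue_ca_deviation(reference, mobile, sup)
  loop_rmsd <- vapply(loops, function(rr)
    selection_rmsd(reference, mobile, sup,
                   atom_selection(residues = rr, atoms = "CA")), numeric(1))
  loop_max <- vapply(loops, function(rr) {
    d <- dev$deviation[dev$resno %in% rr]
    if (length(d) == 0) NA_real_ else max(d)
  }, numeric(1))
  list(superposition = sup, deviations = dev,
       loop_rmsd = loop_rmsd, loop_max = loop_max)
}

#' Displacement of one atom between two superposed states
#'
#' Distance moved by an atom (e.g. Ile97 Cd1) between the apo and bound
#' structures after fitting the mobile structure onto the reference frame.
#'
#' @param reference,mobile `structure3d` objects.
#' @param sup `superposition` (e.g. the barrel fit).
#' @param atomspec `c(resno=, elety=)` (optionally `chain=`).
#' @return displacement in Angstrom.
#' @export
atom_displacement_between_states <- function(reference, mobile, sup,
                                             atomspec) {
  mob <- apply_superposition(mobile, sup)
  xa <- .atom_xyz(reference, atomspec)
  xb <- .atom_xyz(mob, atomspec)
  sqrt(sum((xa - xb)^2))
}
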