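# Structure model, PDB I/O and the geometric primitives used for frame
# selection, dihedral analysis and per-atom alignability.

# Atomic masses for the elements that occur in capped peptides + water.
.atom_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974)

.water_resnames <- c("HOH", "WAT", "SOL", "TIP3", "TIP4", "SPC")
.cap_resnames <- c("ACE", "NME", "NMA")
.backbone_names <- c("N", "CA", "C", "O", "H", "HN", "HA", "OXT", "HA2", "HA3")

#' Construct a conformer
#'
#' A conformer is one configuration of the peptide: an ordered atom table plus
#' an identifier and a conformation-group label.  The atom table has one row
#' per atom with columns `atom_name`, `element`, `residue_name`,
#' `residue_number` (1-based, caps may carry 0 or n+1), Cartesian `x`, `y`,
#' `z` in Angstrom, and the logical flags `is_backbone`, `is_cap`, `is_water`.
#'
#' @param atoms data.frame of atom records (see Details); missing flag columns
#'   are derived from residue and atom names.
#' @param conformer_id character identifier.
#' @param group conformation group label, one of `"stretched"`, `"globular"`,
#'   `"unassigned"`.
#' @return An object of class `conformer`.
#' @export
conformer <- function(atoms, conformer_id = "conf1", group = "unassigned") {
  group <- match.arg(group, c("stretched", "globular", "unassigned"))
  req <- c("atom_name", "residue_name", "residue_number", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$element))
    atoms$element <- guess_element(atoms$atom_name)
  if (is.null(atoms$is_water))
    atoms$is_water <- atoms$residue_name %in% .water_resnames
  if (is.null(atoms$is_cap))
    atoms$is_cap <- atoms$residue_name %in% .cap_resnames
  if (is.null(atoms$is_backbone))
    atoms$is_backbone <- atoms$atom_name %in% .backbone_names &
      !atoms$is_cap & !atoms$is_water
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in atom table")
  if (is.unsorted(atoms$residue_number[!atoms$is_water]))
    stop("residue numbering must be non-decreasing along the chain")
  atoms$atom_name <- as.character(atoms$atom_name)
  atoms$residue_name <- as.character(atoms$residue_name)
  atoms$residue_number <- as.integer(atoms$residue_number)
  rownames(atoms) <- NULL
  structure(list(conformer_id = as.character(conformer_id), group = group,
                 atoms = atoms),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer %s> group=%s, %d atoms, %d residues\n",
              x$conformer_id, x$group, nrow(x$atoms),
              length(unique(x$atoms$residue_number[!x$atoms$is_water]))))
  invisible(x)
}

#' Infer the chemical element from a PDB atom name
#'
#' Digits and primes are stripped; a leading `H` in names such as `"1HB"` or
#' `"HG11"` maps to hydrogen.
#'
#' @param atom_name character vector of PDB atom names.
#' @return Character vector of element symbols.
#' @export
guess_element <- function(atom_name) {
  nm <- gsub("[0-9'*]", "", trimws(atom_name))
  el <- toupper(substr(nm, 1, 1))
  # two-letter elements that can appear in force-field PDBs
  two <- toupper(substr(nm, 1, 2))
  el[two == "CL"] <- "CL"
  el[two == "NA" & nchar(nm) == 2] <- "NA"
  el
}

coords <- function(conf, idx = NULL) {
  m <- as.matrix(conf$atoms[, c("x", "y", "z")])
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  dimnames(m) <- NULL
  m
}

#' Resolve an atom selection on a conformer
#'
#' @param conf a `conformer`.
#' @param selection `"backbone"` (backbone heavy atoms, the default for all
#'   superposition and radius-of-gyration work), `"heavy"`, `"all"`, or a
#'   logical/integer index into the atom table.
#' @return Integer atom indices.
#' @export
select_atoms <- function(conf, selection = "backbone") {
  a <- conf$atoms
  if (is.character(selection)) {
    selection <- match.arg(selection, c("backbone", "heavy", "all"))
    idx <- switch(selection,
      backbone = which(a$is_backbone & a$element != "H"),
      heavy = which(a$element != "H" & !a$is_water),
      all = seq_len(nrow(a)))
  } else if (is.logical(selection)) {
    idx <- which(selection)
  } else {
    idx <- as.integer(selection)
  }
  if (length(idx) == 0) stop("empty atom selection")
  idx
}

#' Read conformers from a (multi-model) PDB file
#'
#' `MODEL`/`ENDMDL` blocks yield one conformer per model; a file without
#' `MODEL` records yields a single conformer.  Water residues (HOH/WAT/SOL)
#' and ACE/NME cap groups are flagged.  Atom ordering is preserved exactly.
#'
#' @param pdb_source path to a PDB file, or a character vector of PDB lines.
#' @param group conformation-group label applied to all models.
#' @return List of `conformer` objects.
#' @export
read_conformers <- function(pdb_source, group = "unassigned") {
  lines <- if (length(pdb_source) == 1 && file.exists(pdb_source))
    readLines(pdb_source) else pdb_source
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) == 0) {
    blocks <- list(lines)
    ids <- "1"
  } else {
    model_ends <- which(trimws(rec) == "ENDMDL")
    if (length(model_ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records")
    blocks <- Map(function(s, e) lines[s:e], model_starts, model_ends)
    ids <- trimws(substr(lines[model_starts], 7, 20))
    ids[ids == ""] <- as.character(seq_along(blocks))
  }
  confs <- Map(function(block, id) {
    at <- .parse_pdb_atoms(block)
    conformer(at, conformer_id = id, group = group)
  }, blocks, ids)
  n_atoms <- vapply(confs, function(cf) nrow(cf$atoms), integer(1))
  if (length(unique(n_atoms)) > 1)
    stop("structural mismatch: models have inconsistent atom counts (",
         paste(unique(n_atoms), collapse = ", "), ")")
  unname(confs)
}

.parse_pdb_atoms <- function(lines) {
  is_atom <- substr(lines, 1, 6) %in% c("ATOM  ", "HETATM")
  ln <- lines[is_atom]
  if (length(ln) == 0) stop("no ATOM/HETATM records found")
  atom_name <- trimws(substr(ln, 13, 16))
  residue_name <- trimws(substr(ln, 18, 21))
  residue_number <- as.integer(substr(ln, 23, 26))
  x <- as.numeric(substr(ln, 31, 38))
  y <- as.numeric(substr(ln, 39, 46))
  z <- as.numeric(substr(ln, 47, 54))
  element <- trimws(substr(ln, 77, 78))
  element[element == "" | is.na(element)] <-
    guess_element(atom_name[element == "" | is.na(element)])
  data.frame(atom_name = atom_name, element = toupper(element),
             residue_name = residue_name, residue_number = residue_number,
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

#' Write conformers to a PDB file
#'
#' Multiple conformers are written as MODEL/ENDMDL blocks.
#'
#' @param confs a `conformer` or list of conformers.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(confs, path) {
  if (inherits(confs, "conformer")) confs <- list(confs)
  multi <- length(confs) > 1
  out <- character(0)
  for (i in seq_along(confs)) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", i))
    out <- c(out, .format_pdb_atoms(confs[[i]]$atoms))
    if (multi) out <- c(out, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

.format_pdb_atoms <- function(atoms) {
  name4 <- ifelse(nchar(atoms$atom_name) < 4,
                  sprintf(" %-3s", atoms$atom_name),
                  sprintf("%-4s", atoms$atom_name))
  rec <- ifelse(atoms$is_water, "HETATM", "ATOM  ")
  sprintf("%s%5d %s %-4sA%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          rec, seq_len(nrow(atoms)) %% 100000, name4, atoms$residue_name,
          atoms$residue_number %% 10000, atoms$x, atoms$y, atoms$z,
          atoms$element)
}

#' Mass-weighted radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum_i m_i |r_i - r_{com}|^2 / \sum_i m_i}} over the
#' selected atoms (default: backbone heavy atoms, the compactness measure
#' used for frame selection).
#'
#' @inheritParams select_atoms
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(conf, selection = "backbone") {
  idx <- select_atoms(conf, selection)
  xyz <- coords(conf, idx)
  m <- .atom_masses[conf$atoms$element[idx]]
  m[is.na(m)] <- 12.011
  com <- colSums(xyz * m) / sum(m)
  d2 <- rowSums(sweep(xyz, 2, com)^2)
  sqrt(sum(m * d2) / sum(m))
}

# Kabsch algorithm on bare coordinate matrices; returns rotation R and
# translation t with aligned = mobile %*% R + t, plus the minimal RMSD.
kabsch <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  t_vec <- cr - cm %*% R
  aligned <- A %*% R
  rmsd <- sqrt(mean(rowSums((aligned - B)^2)))
  list(rotation = R, translation = as.numeric(t_vec), rmsd = rmsd)
}

#' Least-squares (Kabsch) superposition
#'
#' Finds the rigid transform minimising the RMSD of the selected atoms of
#' `mobile` onto `reference`.
#'
#' @param mobile,reference conformers with equal selected atom counts.
#' @param selection passed to [select_atoms()]; default backbone heavy atoms.
#' @return List with `rotation` (3x3), `translation` (length 3) such that
#'   `aligned = xyz %*% rotation + translation`, and the minimal `rmsd` (Å).
#' @export
superpose <- function(mobile, reference, selection = "backbone") {
  im <- select_atoms(mobile, selection)
  ir <- select_atoms(reference, selection)
  if (length(im) != length(ir))
    stop("selections differ in size (", length(im), " vs ", length(ir), ")")
  xm <- coords(mobile, im); xr <- coords(reference, ir)
  if (length(im) < 3 || qr(sweep(xm, 2, colMeans(xm)))$rank < 2)
    stop("superposition underdetermined: need >= 3 non-collinear atoms")
  kabsch(xm, xr)
}

# Apply a rigid transform to every atom of a conformer.
transform_conformer <- function(conf, rotation, translation) {
  xyz <- coords(conf) %*% rotation
  xyz <- sweep(xyz, 2, translation, `+`)
  conf$atoms$x <- xyz[, 1]; conf$atoms$y <- xyz[, 2]; conf$atoms$z <- xyz[, 3]
  conf
}

#' Select the most stretched and most globular frames
#'
#' Returns the conformers with maximal and minimal backbone radius of
#' gyration; ties are broken by the lowest frame index.
#'
#' @param conformers list of conformers (>= 2).
#' @param selection selection used for the radius of gyration.
#' @return List with elements `stretched`, `globular` (conformers) and
#'   `indices` (c(max, min), 1-based).
#' @export
select_extreme_frames <- function(conformers, selection = "backbone") {
  if (length(conformers) < 2) stop("need at least two conformers")
  rg <- vapply(conformers, radius_of_gyration, numeric(1),
               selection = selection)
  i_max <- which.max(rg)          # which.max/min take the first maximum: the
  i_min <- which.min(rg)          # lowest-index tie-break for free
  list(stretched = conformers[[i_max]], globular = conformers[[i_min]],
       indices = c(max = i_max, min = i_min), rgyr = rg)
}

#' Select the k most similar conformers to a center
#'
#' Similarity is backbone heavy-atom RMSD after Kabsch superposition.  The
#' returned group contains the center (as its central member) plus the k
#' nearest pool members; ties are broken by pool index.
#'
#' @param conformers pool of candidate conformers.
#' @param center the reference conformer.
#' @param k number of neighbours (0 <= k < length(conformers) is allowed;
#'   k = 0 yields a group holding only the center).
#' @param label group label for the result.
#' @return A `conformer_group`.
#' @export
select_neighbors <- function(conformers, center, k = 4,
                             label = center$group) {
  if (k < 0) stop("k must be non-negative")
  if (k > length(conformers)) stop("k exceeds pool size")
  rmsd <- vapply(conformers, function(cf) superpose(cf, center)$rmsd,
                 numeric(1))
  ord <- order(rmsd, seq_along(rmsd))
  picked <- conformers[ord[seq_len(k)]]
  conformer_group(c(list(center), picked), label = label, central = 1L)
}

#' Construct a conformer group
#'
#' @param members list of conformers sharing one atom ordering.
#' @param label group label.
#' @param central index of the central (reference) member.
#' @return An object of class `conformer_group`.
#' @export
conformer_group <- function(members, label = "group", central = 1L) {
  stopifnot(length(members) >= 1, central >= 1, central <= length(members))
  n <- vapply(members, function(cf) nrow(cf$atoms), integer(1))
  if (length(unique(n)) != 1)
    stop("group members differ in atom count")
  structure(list(label = label, members = members, central = as.integer(central)),
            class = "conformer_group")
}

#' @export
print.conformer_group <- function(x, ...) {
  cat(sprintf("<conformer_group %s> %d members, central = %d\n",
              x$label, length(x$members), x$central))
  invisible(x)
}

# Torsion angle (degrees, in (-180, 180]) defined by four points.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

#' Wrap an angle into (-180, 180] degrees
#' @param x angle(s) in degrees.
#' @return Wrapped angle(s).
#' @export
wrap_angle <- function(x) 180 - ((180 - x) %% 360)

#' Backbone dihedral angles
#'
#' Computes per-residue phi (C_prev-N-CA-C) and psi (N-CA-C-N_next) in
#' degrees.  Terminal residues lacking a peptide neighbour, or residues with
#' incomplete backbones, yield `NA` for the affected angle.  ACE/NME caps
#' supply the flanking C and N atoms but do not get angles of their own.
#'
#' @param conf a `conformer`.
#' @return data.frame with `residue_number`, `residue_name`, `phi`, `psi`.
#' @export
backbone_dihedrals <- function(conf) {
  a <- conf$atoms
  aa <- a[!a$is_water, , drop = FALSE]
  units <- unique(aa$residue_number)
  get_atom <- function(resnum, name) {
    i <- which(aa$residue_number == resnum & aa$atom_name %in% name)
    if (length(i) == 0) return(NULL)
    as.numeric(aa[i[1], c("x", "y", "z")])
  }
  res_units <- units[!(vapply(units, function(u)
    aa$residue_name[match(u, aa$residue_number)], character(1)) %in%
      .cap_resnames)]
  out <- data.frame(residue_number = res_units,
                    residue_name = vapply(res_units, function(u)
                      aa$residue_name[match(u, aa$residue_number)],
                      character(1)),
                    phi = NA_real_, psi = NA_real_)
  warned <- FALSE
  for (r in seq_along(res_units)) {
    u <- res_units[r]
    ui <- match(u, units)
    N <- get_atom(u, "N"); CA <- get_atom(u, "CA"); C <- get_atom(u, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) {
      if (!warned) { warning("incomplete backbone; affected angles set NA")
        warned <- TRUE }
      next
    }
    if (ui > 1) {
      Cp <- get_atom(units[ui - 1], "C")
      if (!is.null(Cp)) out$phi[r] <- dihedral_angle(Cp, N, CA, C)
    }
    if (ui < length(units)) {
      Nn <- get_atom(units[ui + 1], "N")
      if (!is.null(Nn)) out$psi[r] <- dihedral_angle(N, CA, C, Nn)
    }
  }
  out
}

#' Dihedral change between conformations
#'
#' The signed change `stretched - globular`, wrapped to (-180, 180] degrees,
#' i.e. the smallest rotation carrying the globular angle to the stretched
#' one.  `NA` inputs propagate.
#'
#' @param angle_globular,angle_stretched angles in degrees.
#' @return Wrapped difference in degrees.
#' @export
delta_dihedral <- function(angle_globular, angle_stretched) {
  wrap_angle(angle_stretched - angle_globular)
}

#' Per-atom alignability of a conformer group
#'
#' All members are superposed onto the central member on backbone heavy
#' atoms; for every atom the mean distance between its copies over all
#' unordered member pairs is returned.  Zero means the copies coincide.
#'
#' @param group a `conformer_group` with >= 2 members.
#' @param selection superposition selection.
#' @return Numeric vector, one value (Å) per atom.
#' @export
per_atom_alignability <- function(group, selection = "backbone") {
  n <- length(group$members)
  if (n < 2) stop("alignability needs at least two group members")
  ref <- group$members[[group$central]]
  aligned <- lapply(group$members, function(cf) {
    fit <- superpose(cf, ref, selection)
    coords(transform_conformer(cf, fit$rotation, fit$translation))
  })
  n_atoms <- nrow(aligned[[1]])
  acc <- numeric(n_atoms)
  npairs <- 0L
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    acc <- acc + sqrt(rowSums((aligned[[i]] - aligned[[j]])^2))
    npairs <- npairs + 1L
  }
  acc / npairs
}
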