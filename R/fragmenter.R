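# Per-residue QM input fragments: distance-cutoff environment selection,
# ACE/NME capping of chain breaks, and first-solvation-shell extraction.

# Ordered non-water units (residues and terminal cap groups) of a conformer.
chain_units <- function(conf) {
  a <- conf$atoms
  unique(a$residue_number[!a$is_water])
}

unit_atoms <- function(conf, unit) {
  which(conf$atoms$residue_number == unit & !conf$atoms$is_water)
}

# Minimum-distance test between two coordinate sets, inclusive boundary.
.any_within <- function(xa, xb, cutoff) {
  # squared distances via the expanded form; xa, xb are n x 3 matrices
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * tcrossprod(xa, xb)
  any(d2 <= cutoff^2 + 1e-12)
}

#' Select the environment of a central unit
#'
#' Returns the central residue (or terminal cap group) plus every other
#' non-water unit having at least one atom -- hydrogens included -- within
#' `cutoff` of any central-unit atom.  The boundary is inclusive.
#'
#' @param conf a `conformer`.
#' @param central_unit residue number of the central unit.
#' @param cutoff distance cutoff in Angstrom (default 4.0).
#' @return Sorted integer vector of member unit numbers.
#' @export
select_environment <- function(conf, central_unit, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  units <- chain_units(conf)
  if (!central_unit %in% units)
    stop("unknown residue: ", central_unit)
  xc <- coords(conf, unit_atoms(conf, central_unit))
  keep <- vapply(units, function(u) {
    if (u == central_unit) return(TRUE)
    .any_within(coords(conf, unit_atoms(conf, u)), xc, cutoff)
  }, logical(1))
  sort(units[keep])
}

# Ideal tetrahedral methyl hydrogens: carbon at c_pos bonded to bonded_pos;
# ref_pos fixes the staggered orientation.
.methyl_hydrogens <- function(c_pos, bonded_pos, ref_pos, names, d_ch = 1.09) {
  z <- c_pos - bonded_pos; z <- z / sqrt(sum(z^2))
  r <- ref_pos - bonded_pos
  x <- r - sum(r * z) * z
  if (sqrt(sum(x^2)) < 1e-6) x <- if (abs(z[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x <- x - sum(x * z) * z; x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  # H-C-(bonded) angle 109.5 deg, staggered (60, 180, 300 deg) about the bond
  out <- matrix(NA_real_, 3, 3)
  for (i in 1:3) {
    phi <- (c(60, 180, 300)[i]) * pi / 180
    dir <- sin(109.47 * pi / 180) * (cos(phi) * x + sin(phi) * y) +
      cos(109.47 * pi / 180) * z
    out[i, ] <- c_pos + d_ch * dir
  }
  rownames(out) <- names
  out
}

.cap_atom_df <- function(names, elements, xyz, resname, resnum) {
  data.frame(atom_name = names, element = elements, residue_name = resname,
             residue_number = as.integer(resnum),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             is_backbone = FALSE, is_cap = TRUE, is_water = FALSE,
             stringsAsFactors = FALSE)
}

.get_unit_atom <- function(conf, unit, names) {
  i <- which(conf$atoms$residue_number == unit &
               conf$atoms$atom_name %in% names & !conf$atoms$is_water)
  if (length(i) == 0) return(NULL)
  as.numeric(conf$atoms[i[1], c("x", "y", "z")])
}

# Build an ACE cap replacing excluded N-side neighbour `u` of run start.
.build_ace <- function(conf, u, attach) {
  rn <- conf$atoms$residue_name[match(u, conf$atoms$residue_number)]
  c_pos <- .get_unit_atom(conf, u, "C")
  o_pos <- .get_unit_atom(conf, u, "O")
  me_pos <- .get_unit_atom(conf, u, if (rn %in% .cap_resnames)
    c("CH3", "CA") else "CA")
  if (is.null(c_pos) || is.null(o_pos) || is.null(me_pos))
    stop("capping error: residue ", u, " lacks C/O/CA needed for an ACE cap")
  h <- .methyl_hydrogens(me_pos, c_pos, o_pos, c("HH31", "HH32", "HH33"))
  xyz <- rbind(CH3 = me_pos, C = c_pos, O = o_pos, h)
  atoms <- .cap_atom_df(rownames(xyz), c("C", "C", "O", "H", "H", "H"),
                        xyz, "ACE", u)
  structure(list(cap_type = "ACE", attachment_residue = attach,
                 side = "N-side", atoms = atoms), class = "cap_record")
}

# Build an NME cap replacing excluded C-side neighbour `u` of run end.
.build_nme <- function(conf, u, attach) {
  rn <- conf$atoms$residue_name[match(u, conf$atoms$residue_number)]
  n_pos <- .get_unit_atom(conf, u, "N")
  me_pos <- .get_unit_atom(conf, u, if (rn %in% .cap_resnames)
    c("CH3", "CA") else "CA")
  if (is.null(n_pos) || is.null(me_pos))
    stop("capping error: residue ", u, " lacks N/CA needed for an NME cap")
  h_pos <- .get_unit_atom(conf, u, c("H", "HN"))
  if (is.null(h_pos)) {
    # proline-like neighbour: build the amide H in the C(=O)-N-CA plane,
    # bisecting the outside of the C-N-CA angle
    attach_c <- .get_unit_atom(conf, attach, "C")
    if (is.null(attach_c))
      stop("capping error: residue ", attach, " lacks C for NME H placement")
    v1 <- attach_c - n_pos; v1 <- v1 / sqrt(sum(v1^2))
    v2 <- me_pos - n_pos; v2 <- v2 / sqrt(sum(v2^2))
    b <- -(v1 + v2); b <- b / sqrt(sum(b^2))
    h_pos <- n_pos + 1.01 * b
  }
  h <- .methyl_hydrogens(me_pos, n_pos, h_pos, c("HH31", "HH32", "HH33"))
  xyz <- rbind(N = n_pos, H = h_pos, CH3 = me_pos, h)
  atoms <- .cap_atom_df(rownames(xyz), c("N", "H", "C", "H", "H", "H"),
                        xyz, "NME", u)
  structure(list(cap_type = "NME", attachment_residue = attach,
                 side = "C-side", atoms = atoms), class = "cap_record")
}

#' Cap the chain breaks of a residue selection
#'
#' For each maximal contiguous run of selected units: if the run's first unit
#' had an excluded N-side peptide neighbour, an ACE cap is built from that
#' neighbour's C, O and CA positions (CA becomes the acetyl methyl carbon);
#' if the last unit had an excluded C-side neighbour, an NME cap is built
#' from its N, H and CA.  Original peptide termini are never re-capped.
#' Methyl hydrogens are placed with ideal tetrahedral geometry; a missing
#' amide H (proline neighbour) is built in-plane rather than failing.
#'
#' @param conf a `conformer`.
#' @param member_units unit numbers of the selection.
#' @return List of `cap_record` objects.
#' @export
cap_breaks <- function(conf, member_units) {
  if (length(member_units) == 0) stop("empty member selection")
  units <- chain_units(conf)
  pos <- match(sort(unique(member_units)), units)
  if (any(is.na(pos))) stop("member units not present in conformer")
  pos <- sort(pos)
  run_id <- cumsum(c(1, diff(pos) != 1))
  caps <- list()
  for (g in split(pos, run_id)) {
    first <- g[1]; last <- g[length(g)]
    if (first > 1 && !(first - 1) %in% pos)
      caps[[length(caps) + 1]] <-
        .build_ace(conf, units[first - 1], units[first])
    if (last < length(units) && !(last + 1) %in% pos)
      caps[[length(caps) + 1]] <-
        .build_nme(conf, units[last + 1], units[last])
  }
  caps
}

#' Extract the first solvation shell around a central unit
#'
#' Whole water molecules with any atom within `cutoff` of any central-unit
#' atom are returned with unchanged geometry.
#'
#' @inheritParams select_environment
#' @return Object of class `solvation_shell`: list with `cutoff`, `waters`
#'   (residue numbers) and `atoms` (their atom rows).
#' @export
extract_microsolvation <- function(conf, central_unit, cutoff = 4.0) {
  a <- conf$atoms
  xc <- coords(conf, unit_atoms(conf, central_unit))
  wat_units <- unique(a$residue_number[a$is_water])
  keep <- vapply(wat_units, function(w) {
    wi <- which(a$residue_number == w & a$is_water)
    .any_within(coords(conf, wi), xc, cutoff)
  }, logical(1))
  sel <- wat_units[keep]
  rows <- which(a$is_water & a$residue_number %in% sel)
  structure(list(cutoff = cutoff, waters = sel,
                 atoms = a[rows, , drop = FALSE], atom_idx = rows),
            class = "solvation_shell")
}

#' Build one QM fragment
#'
#' @param conf a `conformer`.
#' @param central_unit residue number of the central unit.
#' @param cutoff environment cutoff in Angstrom.
#' @param with_solvent include the first water shell around the central unit.
#' @return Object of class `fragment` with fields `central_unit`,
#'   `member_units`, `caps`, `waters`, `atoms` (assembled atom table) and
#'   `atom_map` (fragment atom index -> source atom index, `NA` for cap
#'   atoms).
#' @export
build_fragment <- function(conf, central_unit, cutoff = 4.0,
                           with_solvent = FALSE) {
  members <- select_environment(conf, central_unit, cutoff)
  caps <- cap_breaks(conf, members)
  # assemble in chain order: [ACE cap] run [NME cap] per contiguous run, so
  # the fragment is itself a valid chain-ordered structure
  units <- chain_units(conf)
  pos <- sort(match(members, units))
  run_id <- cumsum(c(1, diff(pos) != 1))
  parts <- list(); map <- integer(0)
  add_cap <- function(type, attach) {
    for (cp in caps)
      if (cp$cap_type == type && cp$attachment_residue == attach) {
        parts[[length(parts) + 1]] <<- cp$atoms
        map <<- c(map, rep(NA_integer_, nrow(cp$atoms)))
      }
  }
  for (g in split(pos, run_id)) {
    lo <- units[g[1]]; hi <- units[g[length(g)]]
    add_cap("ACE", lo)
    src <- which(conf$atoms$residue_number %in% units[g] & !conf$atoms$is_water)
    parts[[length(parts) + 1]] <- conf$atoms[src, , drop = FALSE]
    map <- c(map, src)
    add_cap("NME", hi)
  }
  atoms <- do.call(rbind, parts)
  waters <- integer(0)
  if (with_solvent) {
    shell <- extract_microsolvation(conf, central_unit, cutoff)
    waters <- shell$waters
    atoms <- rbind(atoms, shell$atoms)
    map <- c(map, shell$atom_idx)
  }
  rownames(atoms) <- NULL
  structure(list(central_unit = central_unit, member_units = members,
                 caps = caps, waters = waters, atoms = atoms,
                 atom_map = map),
            class = "fragment")
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("<fragment> central unit %d, %d member units, %d caps, %d waters\n",
              x$central_unit, length(x$member_units), length(x$caps),
              length(x$waters)))
  invisible(x)
}

#' Fragment a whole conformer
#'
#' One fragment is built per central unit, where the central units are all
#' amino acids plus the two terminal cap groups (a 31-residue ACE/NME-capped
#' peptide therefore yields 33 fragments).  Fragments may overlap; together
#' their central units cover the molecule.
#'
#' @inheritParams build_fragment
#' @return List of `fragment` objects, in chain order of the central units.
#' @export
fragment_all <- function(conf, cutoff = 4.0, with_solvent = FALSE) {
  units <- chain_units(conf)
  if (length(units) < 1) stop("conformer has no residues")
  lapply(units, build_fragment, conf = conf, cutoff = cutoff,
         with_solvent = with_solvent)
}

#' Write a fragment to disk
#'
#' Emits PDB or XYZ, plus a sidecar CSV (`<path>.map.csv`) mapping fragment
#' atoms back to full-peptide atom indices (`NA` for constructed cap atoms).
#'
#' @param fragment a `fragment`.
#' @param path output file path.
#' @param format `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_fragment <- function(fragment, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  a <- fragment$atoms
  if (format == "pdb") {
    writeLines(c(.format_pdb_atoms(a), "END"), path)
  } else {
    hdr <- c(nrow(a), sprintf("fragment central_unit=%d",
                              fragment$central_unit))
    body <- sprintf("%-2s %12.6f %12.6f %12.6f", a$element, a$x, a$y, a$z)
    writeLines(c(hdr, body), path)
  }
  map <- data.frame(fragment_atom = seq_len(nrow(a)),
                    atom_name = a$atom_name,
                    residue_number = a$residue_number,
                    source_atom = fragment$atom_map)
  write.csv(map, paste0(path, ".map.csv"), row.names = FALSE)
  invisible(path)
}
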