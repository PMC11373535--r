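# Seeded synthetic data: ideal-geometry peptide conformers built from
# per-group (phi, psi) targets, pseudo-method shift tables with planted
# between-group separations, and matching experimental / random-coil tables.

.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Specification of a synthetic two-conformation system
#'
#' The stated world the generator emulates: two conformation groups (one
#' extended, one compact backbone) of `n_replicas` near-identical
#' configurations each of a short ACE/NME-capped peptide, plus per-method
#' shift tables in which each atom's stretched and globular shift samples are
#' Gaussian with a planted mean separation (in units of the within-group
#' standard deviation) and an experimental table with a known mean relative
#' error.
#'
#' @param n_residues number of amino acids (default 31, the study scale).
#' @param sequence one-letter sequence string; default is a fixed varied
#'   31-residue sequence (including glycine and proline) recycled/truncated
#'   to `n_residues`.
#' @param phi_psi_stretched,phi_psi_globular per-group backbone (phi, psi)
#'   targets in degrees; defaults are an extended (-135, 135) and a compact
#'   (-75, -30) backbone.
#' @param n_replicas configurations per group (default 5).
#' @param replica_noise Gaussian coordinate jitter sd in Angstrom applied to
#'   replicas 2..n (default 0.5, giving within-group backbone RMSDs of the
#'   order reported for the study's groups).
#' @param n_waters number of water molecules placed around each base
#'   conformer (default 0).
#' @param planted_sensitivities per-atom true separations in sigma units,
#'   recycled over atoms (default 0).
#' @param within_group_sd within-group shift sd in ppm (default 0.1).
#' @param n_methods number of pseudo-methods (default 9, the study's method
#'   count, so the agreement matrix is exercised at scale).
#' @param experimental_offset relative offset of the experimental table: the
#'   construction guarantees that the simulated ensemble mean has exactly
#'   this mean relative error against the experimental table.
#' @param rc_offsets optional data.frame (`residue_number`, `atom_name`,
#'   `offset` in ppm) of planted secondary shifts; the random-coil table is
#'   the experimental table minus these offsets.
#' @param seed master RNG seed; geometry, shifts and water placement use
#'   documented sub-seeds derived from it (seed, seed+1e6, seed+2e6).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_residues = 31, sequence = NULL,
                           phi_psi_stretched = c(-135, 135),
                           phi_psi_globular = c(-75, -30),
                           n_replicas = 5, replica_noise = 0.5,
                           n_waters = 0, planted_sensitivities = 0,
                           within_group_sd = 0.1, n_methods = 9,
                           experimental_offset = 0.05, rc_offsets = NULL,
                           seed = 1) {
  if (n_residues < 3) stop("need at least 3 residues")
  if (within_group_sd < 0) stop("within_group_sd must be non-negative")
  if (any(abs(c(phi_psi_stretched, phi_psi_globular)) > 180))
    stop("invalid dihedral targets")
  if (is.null(sequence)) {
    base <- "ASPKTGLVEQIFNHRDYMWCASPKTGLVEQI"
    sequence <- paste(rep(strsplit(base, "")[[1]],
                          length.out = n_residues), collapse = "")
  }
  if (nchar(sequence) != n_residues)
    stop("sequence length does not match n_residues")
  structure(list(n_residues = n_residues, sequence = sequence,
                 phi_psi_stretched = phi_psi_stretched,
                 phi_psi_globular = phi_psi_globular,
                 n_replicas = n_replicas, replica_noise = replica_noise,
                 n_waters = n_waters,
                 planted_sensitivities = planted_sensitivities,
                 within_group_sd = within_group_sd, n_methods = n_methods,
                 experimental_offset = experimental_offset,
                 rc_offsets = rc_offsets, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# NeRF atom placement: position d bonded to c, with |cd| = bond, angle
# d-c-b = `angle` and torsion(a, b, c, d) = `torsion` (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  angle <- angle * pi / 180; torsion <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(angle), bond * sin(angle) * cos(torsion),
         -bond * sin(angle) * sin(torsion))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Build an ACE/NME-capped peptide with ideal bond geometry from per-residue
# (phi, psi) targets.  Returns an atom data.frame; ACE is unit 0, residues
# 1..n, NME is unit n+1.
build_peptide <- function(sequence, phi, psi) {
  seq1 <- strsplit(sequence, "")[[1]]
  n <- length(seq1)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  res3 <- .aa1to3[seq1]
  if (any(is.na(res3))) stop("unknown residue letter in sequence")

  rows <- list()
  add <- function(name, el, resname, resnum, pos, backbone) {
    rows[[length(rows) + 1]] <<- data.frame(
      atom_name = name, element = el, residue_name = resname,
      residue_number = as.integer(resnum), x = pos[1], y = pos[2], z = pos[3],
      is_backbone = backbone, is_cap = resname %in% .cap_resnames,
      is_water = FALSE, stringsAsFactors = FALSE)
    pos
  }

  # ACE cap (unit 0): CH3-C(=O)-
  ch3 <- add("CH3", "C", "ACE", 0, c(0, 0, 0), FALSE)
  cc <- add("C", "C", "ACE", 0, c(1.52, 0, 0), FALSE)
  oo <- add("O", "O", "ACE", 0,
            c(1.52 + 1.231 * cos(pi * (180 - 120.8) / 180),
              1.231 * sin(pi * (180 - 120.8) / 180), 0), FALSE)
  for (h in seq_len(3))
    add(paste0("HH3", h), "H", "ACE", 0,
        .methyl_hydrogens(ch3, cc, oo, c("a", "b", "c"))[h, ], FALSE)

  prev <- list(N = NULL, CA = ch3, C = cc, O = oo)   # ACE CH3 acts as "CA"
  for (i in seq_len(n)) {
    # N anti to the previous carbonyl O realises psi_(i-1) implicitly,
    # because O_(i-1) was itself placed at torsion psi + 180
    N <- place_atom(prev$O, prev$CA, prev$C, 1.329, 116.2, 180)
    N <- add("N", "N", res3[i], i, N, TRUE)
    CA <- place_atom(prev$CA, prev$C, N, 1.458, 121.7, 180)  # omega = 180
    CA <- add("CA", "C", res3[i], i, CA, TRUE)
    if (res3[i] != "PRO") {
      H <- place_atom(CA, prev$C, N, 1.010, 119.0, 180)
      add("H", "H", res3[i], i, H, TRUE)
    }
    C <- place_atom(prev$C, N, CA, 1.525, 111.2, phi[i])
    C <- add("C", "C", res3[i], i, C, TRUE)
    if (res3[i] != "GLY") {
      CB <- place_atom(N, C, CA, 1.530, 110.6, 122.6)
      add("CB", "C", res3[i], i, CB, FALSE)
    }
    O <- place_atom(N, CA, C, 1.231, 120.8, wrap_angle(psi[i] + 180))
    O <- add("O", "O", res3[i], i, O, TRUE)
    prev <- list(N = N, CA = CA, C = C, O = O)
  }
  # NME cap (unit n+1): -NH-CH3; its N realises psi of the last residue
  N <- place_atom(prev$O, prev$CA, prev$C, 1.329, 116.2, 180)
  N <- add("N", "N", "NME", n + 1, N, FALSE)
  CH3 <- place_atom(prev$CA, prev$C, N, 1.458, 121.7, 180)
  CH3 <- add("CH3", "C", "NME", n + 1, CH3, FALSE)
  H <- place_atom(prev$CA, prev$C, N, 1.010, 119.0, 0)  # anti to the methyl
  add("H", "H", "NME", n + 1, H, FALSE)
  mh <- .methyl_hydrogens(CH3, N, H, c("a", "b", "c"))
  for (h in seq_len(3))
    add(paste0("HH3", h), "H", "NME", n + 1, mh[h, ], FALSE)

  do.call(rbind, rows)
}

# Add n rigid water molecules around random peptide atoms (2.8-4.5 A).
.add_waters <- function(atoms, n_waters, start_unit) {
  if (n_waters == 0) return(atoms)
  pep <- as.matrix(atoms[!atoms$is_water, c("x", "y", "z")])
  out <- list(atoms)
  for (w in seq_len(n_waters)) {
    anchor <- pep[sample(nrow(pep), 1), ]
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    o <- anchor + runif(1, 2.8, 4.5) * dir
    # rigid water: O-H 0.9572 A, H-O-H 104.52 deg, random orientation
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
    h1 <- o + 0.9572 * u
    ang <- 104.52 * pi / 180
    h2 <- o + 0.9572 * (cos(ang) * u + sin(ang) * v)
    out[[w + 1]] <- data.frame(
      atom_name = c("O", "H1", "H2"), element = c("O", "H", "H"),
      residue_name = "HOH", residue_number = as.integer(start_unit + w - 1),
      x = c(o[1], h1[1], h2[1]), y = c(o[2], h1[2], h2[2]),
      z = c(o[3], h1[3], h2[3]),
      is_backbone = FALSE, is_cap = FALSE, is_water = TRUE,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate the two synthetic conformer groups
#'
#' Builds one extended and one compact base conformer from the spec's
#' per-group (phi, psi) targets with ideal bond geometry and ACE/NME caps,
#' optionally places waters, and creates `n_replicas` members per group: the
#' unperturbed base (the central member) plus replicas with iid Gaussian
#' coordinate jitter of sd `replica_noise`.  Fully deterministic under the
#' spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `stretched` and `globular` `conformer_group`s.
#' @export
make_conformer_groups <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    groups <- list()
    for (g in c("stretched", "globular")) {
      tgt <- if (g == "stretched") spec$phi_psi_stretched else
        spec$phi_psi_globular
      atoms <- build_peptide(spec$sequence, tgt[1], tgt[2])
      atoms <- .add_waters(atoms, spec$n_waters,
                           start_unit = spec$n_residues + 2)
      members <- vector("list", spec$n_replicas)
      for (r in seq_len(spec$n_replicas)) {
        a <- atoms
        if (r > 1 && spec$replica_noise > 0) {
          jit <- matrix(rnorm(3 * nrow(a), 0, spec$replica_noise), ncol = 3)
          a$x <- a$x + jit[, 1]; a$y <- a$y + jit[, 2]; a$z <- a$z + jit[, 3]
        }
        members[[r]] <- conformer(a, conformer_id =
                                    paste0(substr(g, 1, 1), r), group = g)
      }
      groups[[g]] <- conformer_group(members, label = g, central = 1L)
    }
    groups
  })
}

# Atom identities that survive filter_atoms (no caps, no O, no waters).
.analysis_atoms <- function(conf) {
  a <- conf$atoms
  keep <- !a$is_water & !a$is_cap & a$element != "O"
  data.frame(residue_number = a$residue_number[keep],
             residue_name = a$residue_name[keep],
             atom_name = a$atom_name[keep], element = a$element[keep],
             stringsAsFactors = FALSE)
}

#' Generate pseudo-method shift tables with planted separations
#'
#' For each atom and pseudo-method the globular samples are drawn from
#' \eqn{N(\mu, sd)} and the stretched samples from
#' \eqn{N(\mu + s_{true} \cdot sd, sd)} with `n_replicas` samples per group,
#' where `s_true` is the planted per-atom sensitivity in sigma units and `sd`
#' the within-group standard deviation.  Base means are element-typical
#' (H ~ 4.5, C ~ 45, N ~ 118 ppm, per-atom jitter).  Ground truth is attached
#' as `attr(, "s_true")`.
#'
#' @param spec a [synthetic_spec()].
#' @param atoms data.frame of atom identities (`residue_number`,
#'   `residue_name`, `atom_name`, `element`); defaults to the analysis atoms
#'   of the spec's stretched central conformer.
#' @return Canonical-schema shift data.frame over all pseudo-methods with a
#'   `s_true` ground-truth attribute.
#' @export
make_shift_tables <- function(spec, atoms = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$within_group_sd < 0) stop("negative within-group sd")
  if (is.null(atoms))
    atoms <- .analysis_atoms(make_conformer_groups(spec)$
                               stretched$members[[1]])
  n_atoms <- nrow(atoms)
  s_true <- rep_len(spec$planted_sensitivities, n_atoms)
  base_mu <- c(H = 4.5, C = 45, N = 118)
  with_seed(spec$seed + 1000000L, {
    mu0 <- base_mu[atoms$element] + rnorm(n_atoms, 0, 2)
    tabs <- lapply(seq_len(spec$n_methods), function(m) {
      nr <- spec$n_replicas
      sdv <- spec$within_group_sd
      # degenerate noise-free case: keep a nonzero planted separation
      # (1 ppm per sigma unit) so the sensitivity correctly diverges
      sep <- s_true * (if (sdv > 0) sdv else 1)
      g <- matrix(rnorm(n_atoms * nr, mu0, sdv), nrow = n_atoms)
      s <- matrix(rnorm(n_atoms * nr, mu0 + sep, sdv), nrow = n_atoms)
      long <- function(mat, grp, pre) {
        do.call(rbind, lapply(seq_len(nr), function(r)
          data.frame(method = paste0("synth", m),
                     conformer_id = paste0(pre, r), group = grp,
                     residue_number = atoms$residue_number,
                     residue_name = atoms$residue_name,
                     atom_name = atoms$atom_name, element = atoms$element,
                     value_ppm = mat[, r], stringsAsFactors = FALSE)))
      }
      rbind(long(s, "stretched", "s"), long(g, "globular", "g"))
    })
    out <- do.call(rbind, tabs)
    attr(out, "s_true") <- data.frame(residue_number = atoms$residue_number,
                                      atom_name = atoms$atom_name,
                                      s_true = s_true)
    out
  })
}

#' Generate matching experimental and random-coil tables
#'
#' The experimental table is the per-atom ensemble mean of the supplied shift
#' table divided by `1 + experimental_offset`, so the ensemble mean has a
#' mean relative error of exactly `experimental_offset` against it.  The
#' random-coil table equals the experimental table minus the planted
#' `rc_offsets`, so the secondary shifts of chosen residues are controlled
#' exactly.
#'
#' @param spec a [synthetic_spec()].
#' @param shift_table canonical-schema shift data.frame.
#' @return List with `experimental` (columns `residue_number`,
#'   `residue_name`, `atom_name`, `element`, `delta_exp`) and `random_coil`
#'   (`residue_number`, `atom_name`, `delta_rc`).
#' @export
make_reference_tables <- function(spec, shift_table) {
  stopifnot(inherits(spec, "synthetic_spec"))
  m <- aggregate(value_ppm ~ residue_number + residue_name + atom_name +
                   element, data = shift_table, FUN = mean)
  exp_tab <- data.frame(residue_number = m$residue_number,
                        residue_name = m$residue_name,
                        atom_name = m$atom_name, element = m$element,
                        delta_exp = m$value_ppm /
                          (1 + spec$experimental_offset))
  rc <- data.frame(residue_number = exp_tab$residue_number,
                   atom_name = exp_tab$atom_name,
                   delta_rc = exp_tab$delta_exp)
  if (!is.null(spec$rc_offsets)) {
    key <- paste(rc$residue_number, rc$atom_name)
    ko <- paste(spec$rc_offsets$residue_number, spec$rc_offsets$atom_name)
    j <- match(key, ko)
    rc$delta_rc <- rc$delta_rc -
      ifelse(is.na(j), 0, spec$rc_offsets$offset[j])
  }
  list(experimental = exp_tab, random_coil = rc)
}
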