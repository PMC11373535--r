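# Shared fixtures: tiny conformers built in code, hand-written PDB text,
# random rigid motions.

# Minimal atom row constructor.
atom_row <- function(name, el, resname, resnum, x, y, z) {
  data.frame(atom_name = name, element = el, residue_name = resname,
             residue_number = as.integer(resnum), x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

# A bare conformer from a coordinate matrix: one CA pseudo-residue per atom.
points_conformer <- function(xyz, element = "C", id = "c") {
  n <- nrow(xyz)
  conformer(data.frame(atom_name = "CA", element = element,
                       residue_name = "GLY",
                       residue_number = seq_len(n),
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       stringsAsFactors = FALSE),
            conformer_id = id)
}

# Random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(conf, R = random_rotation(), t = rnorm(3, 0, 10)) {
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")]) %*% R
  conf$atoms$x <- xyz[, 1] + t[1]
  conf$atoms$y <- xyz[, 2] + t[2]
  conf$atoms$z <- xyz[, 3] + t[3]
  conf
}

# Hand-written 2-model PDB with a tripeptide backbone and one water.
toy_pdb_lines <- function() {
  c("MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       3.983   2.840   0.000  1.00  0.00           C",
    "ATOM      7  C   GLY A   2       5.500   2.700   0.000  1.00  0.00           C",
    "ATOM      8  O   GLY A   2       6.100   1.630   0.000  1.00  0.00           O",
    "HETATM    9  O   HOH A  10      10.000  10.000  10.000  1.00  0.00           O",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1       0.100   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.558   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.109   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.351   2.390   0.000  1.00  0.00           O",
    "ATOM      5  N   GLY A   2       3.432   1.536   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       4.083   2.840   0.000  1.00  0.00           C",
    "ATOM      7  C   GLY A   2       5.600   2.700   0.000  1.00  0.00           C",
    "ATOM      8  O   GLY A   2       6.200   1.630   0.000  1.00  0.00           O",
    "HETATM    9  O   HOH A  10      10.100  10.000  10.000  1.00  0.00           O",
    "ENDMDL",
    "END")
}

# Canonical-schema shift rows for one atom with given per-group samples.
shift_rows <- function(resnum, atom, element, stretched, globular,
                       method = "m1", resname = "ALA") {
  rbind(
    data.frame(method = method,
               conformer_id = paste0("s", seq_along(stretched)),
               group = "stretched", residue_number = as.integer(resnum),
               residue_name = resname, atom_name = atom, element = element,
               value_ppm = stretched, stringsAsFactors = FALSE),
    data.frame(method = method,
               conformer_id = paste0("g", seq_along(globular)),
               group = "globular", residue_number = as.integer(resnum),
               residue_name = resname, atom_name = atom, element = element,
               value_ppm = globular, stringsAsFactors = FALSE))
}

# Independent numeric-integration oracle for the overlap of two unit-variance
# normals separated by d sigma: area under min(pdf1, pdf2).
overlap_numeric <- function(d) {
  stats::integrate(function(x) pmin(stats::dnorm(x), stats::dnorm(x - d)),
                   -Inf, Inf, rel.tol = 1e-10)$value
}
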