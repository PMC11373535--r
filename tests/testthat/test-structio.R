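# Structure I/O and geometry.

test_that("read_conformers parses single- and multi-model PDB with flags", {
  lines <- toy_pdb_lines()
  confs <- read_conformers(lines)
  expect_length(confs, 2)
  expect_identical(nrow(confs[[1]]$atoms), 9L)
  expect_identical(confs[[1]]$atoms$atom_name, confs[[2]]$atoms$atom_name)
  expect_identical(sum(confs[[1]]$atoms$is_water), 1L)
  expect_true(confs[[1]]$atoms$is_water[9])

  single <- read_conformers(lines[2:10])      # no MODEL records
  expect_length(single, 1)
  expect_identical(nrow(single[[1]]$atoms), 9L)

  # inconsistent atom counts across models
  broken <- lines[-3]
  expect_error(read_conformers(broken), "mismatch")
})

test_that("PDB write/read round-trips coordinates at 3-decimal precision", {
  confs <- read_conformers(toy_pdb_lines())
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(confs, path)
  back <- read_conformers(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$atoms$x, confs[[1]]$atoms$x, tolerance = 1e-9)
  expect_identical(back[[2]]$atoms$atom_name, confs[[2]]$atoms$atom_name)
  expect_identical(back[[1]]$atoms$is_water, confs[[1]]$atoms$is_water)
})

test_that("radius_of_gyration matches the mass-weighted oracle", {
  one <- points_conformer(matrix(c(1, 2, 3), 1))
  expect_equal(radius_of_gyration(one, "all"), 0)

  two <- points_conformer(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration(two, "all"), 1.0)

  # toy helix fixture vs direct sum(m r^2) computation with mixed elements
  set.seed(7)
  t_ang <- seq(0, 4 * pi, length.out = 15)
  xyz <- cbind(2.3 * cos(t_ang), 2.3 * sin(t_ang), 1.5 * t_ang / (2 * pi))
  els <- rep(c("C", "N", "O"), 5)
  cf <- points_conformer(xyz)
  cf$atoms$element <- els
  masses <- c(C = 12.011, N = 14.007, O = 15.999)[els]
  com <- colSums(xyz * masses) / sum(masses)
  oracle <- sqrt(sum(masses * rowSums(sweep(xyz, 2, com)^2)) / sum(masses))
  expect_equal(radius_of_gyration(cf, "all"), oracle, tolerance = 1e-12)

  expect_error(radius_of_gyration(cf, integer(0)), "empty")
})

test_that("rgyr and rmsd are rigid-motion invariant", {
  set.seed(11)
  cf <- points_conformer(matrix(rnorm(30, sd = 4), ncol = 3))
  for (i in 1:5) {
    moved <- apply_rigid(cf)
    expect_equal(radius_of_gyration(moved, "all"),
                 radius_of_gyration(cf, "all"), tolerance = 1e-8)
    expect_lt(superpose(moved, cf, "all")$rmsd, 1e-8)
  }
})

test_that("superpose finds the Kabsch-optimal transform", {
  set.seed(3)
  ref <- points_conformer(matrix(rnorm(36, sd = 3), ncol = 3))
  expect_lt(superpose(ref, ref, "all")$rmsd, 1e-12)

  # brute-force oracle: numerically minimise rmsd over Euler angles + shift
  mob <- ref
  mob$atoms$x[1] <- mob$atoms$x[1] + 1.7   # deform one atom
  fit <- superpose(mob, ref, "all")
  rot_from_euler <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3) %*%
      matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3) %*%
      matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  }
  xm <- as.matrix(mob$atoms[, c("x", "y", "z")])
  xr <- as.matrix(ref$atoms[, c("x", "y", "z")])
  obj <- function(p) {
    al <- xm %*% rot_from_euler(p[1:3])
    al <- sweep(al, 2, p[4:6], `+`)
    sqrt(mean(rowSums((al - xr)^2)))
  }
  brute <- optim(rep(0, 6), obj, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(fit$rmsd, brute$value, tolerance = 1e-5)
  expect_lte(fit$rmsd, brute$value + 1e-7)    # never worse than the oracle

  expect_error(superpose(points_conformer(matrix(0, 2, 3)),
                         points_conformer(matrix(0, 2, 3)), "all"),
               "underdetermined")
})

test_that("select_extreme_frames returns argmax/argmin with index ties", {
  base <- matrix(rnorm(30, sd = 2), ncol = 3)
  scaled <- function(f) points_conformer(base * f)
  # scale factors chosen so rgyr ordering is 9.7 : 27.5 : 15.0
  pool <- list(scaled(9.7), scaled(27.5), scaled(15.0))
  ext <- select_extreme_frames(pool, "all")
  expect_identical(unname(ext$indices), c(2L, 1L))

  same <- list(scaled(1), scaled(1), scaled(1))
  ext2 <- select_extreme_frames(same, "all")
  expect_identical(unname(ext2$indices), c(1L, 1L))

  set.seed(23)
  traj <- lapply(1:100, function(i)
    points_conformer(matrix(rnorm(30, sd = runif(1, 1, 5)), ncol = 3)))
  rg <- vapply(traj, radius_of_gyration, numeric(1), selection = "all")
  ext3 <- select_extreme_frames(traj, "all")
  expect_identical(unname(ext3$indices),
                   c(which.max(rg), which.min(rg)))
  expect_error(select_extreme_frames(traj[1]), "at least two")
})

test_that("select_neighbors ranks by superposed RMSD with deterministic ties", {
  set.seed(5)
  spec <- synthetic_spec(n_residues = 5, seed = 5)
  center <- make_conformer_groups(spec)$stretched$members[[1]]
  amp <- seq(0.05, 1, length.out = 20)
  pool <- lapply(seq_along(amp), function(i) {
    cf <- center
    n <- nrow(cf$atoms)
    set.seed(100 + i)
    cf$atoms$x <- cf$atoms$x + rnorm(n, 0, amp[i])
    cf$atoms$y <- cf$atoms$y + rnorm(n, 0, amp[i])
    cf$atoms$z <- cf$atoms$z + rnorm(n, 0, amp[i])
    cf$conformer_id <- paste0("p", i)
    apply_rigid(cf)
  })
  grp <- select_neighbors(pool, center, k = 4)
  rmsd <- vapply(pool, function(cf) superpose(cf, center)$rmsd, numeric(1))
  want <- order(rmsd, seq_along(rmsd))[1:4]
  got <- vapply(grp$members[-1], function(cf) cf$conformer_id, character(1))
  expect_identical(got, paste0("p", want))

  # k = 0 yields the center-only group; a duplicate center ranks first
  expect_length(select_neighbors(pool, center, k = 0)$members, 1)
  dup <- center; dup$conformer_id <- "dup"
  grp2 <- select_neighbors(c(pool, list(dup)), center, k = 1)
  expect_identical(grp2$members[[2]]$conformer_id, "dup")
  expect_error(select_neighbors(pool, center, k = -1), "non-negative")

  # k = pool size returns the whole pool
  grp3 <- select_neighbors(pool, center, k = length(pool))
  expect_length(grp3$members, length(pool) + 1)
})

test_that("backbone_dihedrals recovers constructed targets", {
  # per-residue varying targets, recovered through the geometry
  phi <- c(-60, -135, -75, 60, -120)
  psi <- c(-45, 135, -30, 40, 150)
  atoms <- csens:::build_peptide("AGLVA", phi, psi)
  cf <- conformer(atoms)
  d <- backbone_dihedrals(cf)
  expect_equal(d$phi, phi, tolerance = 1e-6)
  expect_equal(d$psi, psi, tolerance = 1e-6)

  # without caps the first phi / last psi are undefined, not zero
  bare <- conformer(atoms[!atoms$is_cap, , drop = FALSE])
  d2 <- backbone_dihedrals(bare)
  expect_true(is.na(d2$phi[1]))
  expect_true(is.na(d2$psi[nrow(d2)]))
  expect_false(any(is.na(d2$phi[-1])))

  # mirror image negates all torsions
  mir <- cf; mir$atoms$z <- -mir$atoms$z
  dm <- backbone_dihedrals(mir)
  expect_equal(dm$phi, -d$phi, tolerance = 1e-6)
  expect_equal(dm$psi, -d$psi, tolerance = 1e-6)
})

test_that("delta_dihedral wraps into (-180, 180]", {
  expect_equal(delta_dihedral(170, -170), 20)
  expect_equal(delta_dihedral(42.5, 42.5), 0)
  expect_equal(delta_dihedral(-90, 180), -90)

  # brute-force oracle over k in {-1, 0, 1}
  set.seed(17)
  g <- runif(300, -180, 180); s <- runif(300, -180, 180)
  oracle <- vapply(seq_along(g), function(i) {
    cand <- s[i] - g[i] + 360 * (-1:1)
    cand[which.min(abs(cand))]
  }, numeric(1))
  got <- delta_dihedral(g, s)
  expect_equal(got, oracle, tolerance = 1e-12)
  # antisymmetry and bound
  expect_equal(wrap_angle(delta_dihedral(s, g) + delta_dihedral(g, s)),
               rep(0, 300), tolerance = 1e-12)
  expect_true(all(abs(got) <= 180))
})

test_that("per_atom_alignability enumerates inter-copy distances", {
  spec <- synthetic_spec(n_residues = 4, seed = 9, replica_noise = 0)
  grp <- make_conformer_groups(spec)$stretched
  expect_equal(per_atom_alignability(grp), rep(0, nrow(grp$members[[1]]$atoms)))

  # displace one side-chain atom by 1 A in one of five members: the
  # backbone superposition is unaffected and the 10 member pairs give 4/10
  i_cb <- which(grp$members[[1]]$atoms$atom_name == "CB")[1]
  grp$members[[5]]$atoms$x[i_cb] <- grp$members[[5]]$atoms$x[i_cb] + 1
  al <- per_atom_alignability(grp)
  expect_equal(al[i_cb], 0.4, tolerance = 1e-10)
  expect_equal(al[-i_cb], rep(0, length(al) - 1), tolerance = 1e-10)

  # invariant under rigid motion of any member
  set.seed(2)
  grp$members[[2]] <- apply_rigid(grp$members[[2]])
  expect_equal(per_atom_alignability(grp)[i_cb], 0.4, tolerance = 1e-8)

  expect_error(per_atom_alignability(conformer_group(grp$members[1])),
               "two")
})
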