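# Feature construction, encoding and permutation importance.

# Small shared two-group system (cached per test file).
ft_groups <- local({
  spec <- synthetic_spec(n_residues = 12, sequence = "ASPKTGLVEQIF",
                         seed = 21, replica_noise = 0.25)
  make_conformer_groups(spec)
})

test_that("delta distance features honour the 3-residue separation rule", {
  # hand-built conformer: CA-only chain on the x axis, one distant O
  mk <- function(shift_o) {
    rows <- do.call(rbind, lapply(1:7, function(i)
      atom_row("CA", "C", "GLY", i, 3 * (i - 1), 0, 0)))
    rows <- rbind(rows, atom_row("O", "O", "GLY", 7, 18 + shift_o, 0, 0))
    conformer(rows)
  }
  g1 <- conformer_group(list(mk(0)), label = "stretched")
  g2 <- conformer_group(list(mk(2)), label = "globular")

  # identical groups -> 0 where defined; atoms without a qualifying target
  # (|i - j| < 3 only) are NA
  expect_equal(delta_distance_feature(g1, g1, "O"),
               c(0, 0, 0, 0, NA, NA, NA, NA))

  # for atom at residue 4 the only O sits at residue 7 (|i-j| = 3: included)
  dd <- delta_distance_feature(g2, g1, "O")
  expect_equal(dd[4], 2)
  # for the residue-5 atom, |5-7| = 2 < 3: no qualifying target
  expect_true(is.na(dd[5]))

  # brute-force oracle on the synthetic system (RES targets)
  gs <- ft_groups$stretched; gg <- ft_groups$globular
  got <- delta_distance_feature(gs, gg, "RES")
  one <- function(grp) {
    per <- sapply(grp$members, function(cf) {
      a <- cf$atoms
      units <- unique(a$residue_number)
      cog <- t(sapply(units, function(u)
        colMeans(as.matrix(a[a$residue_number == u, c("x", "y", "z")]))))
      sapply(seq_len(nrow(a)), function(i) {
        ok <- abs(units - a$residue_number[i]) >= 3
        if (!any(ok)) return(NA_real_)
        min(sqrt(colSums((t(cog[ok, , drop = FALSE]) -
                            as.numeric(a[i, c("x", "y", "z")]))^2)))
      })
    })
    rowMeans(per)
  }
  expect_equal(got, one(gs) - one(gg), tolerance = 1e-9)
  # antisymmetry under swapping the group roles
  expect_equal(delta_distance_feature(gg, gs, "RES"), -got)
})

test_that("SASA matches closed forms and converges in point count", {
  lone <- conformer(atom_row("CA", "C", "GLY", 1, 0, 0, 0))
  r <- 1.70 + 1.4
  expect_equal(sasa_atoms(lone), 4 * pi * r^2, tolerance = 1e-6)

  # fully buried atom: surrounded by a tight cage
  pts <- csens:::.sphere_points(26) * 2.2
  cage <- conformer(do.call(rbind, c(list(atom_row("CA", "C", "GLY", 1, 0, 0, 0)),
    lapply(seq_len(nrow(pts)), function(i)
      atom_row("CA", "C", "GLY", i + 1, pts[i, 1], pts[i, 2], pts[i, 3])))))
  expect_equal(sasa_atoms(cage)[1], 0, tolerance = 1e-8)

  # two equal spheres: analytic spherical-cap area 2*pi*R*h per sphere
  two <- conformer(rbind(atom_row("CA", "C", "GLY", 1, 0, 0, 0),
                         atom_row("CA", "C", "GLY", 2, 2.5, 0, 0)))
  R <- 1.70 + 1.4
  h <- R - 2.5 / 2                        # buried cap height
  exact <- 4 * pi * R^2 - 2 * pi * R * h
  got <- sasa_atoms(two, n_points = 2000)
  expect_equal(got[1], exact, tolerance = 0.01)
  expect_equal(got[1], got[2], tolerance = 0.02)

  # quadrature convergence: doubling the point count moves the total < 1%
  # and no atom by more than ~one grid cell
  cf <- ft_groups$globular$members[[1]]
  s1 <- sasa_atoms(cf, n_points = 240)
  s2 <- sasa_atoms(cf, n_points = 480)
  expect_lt(abs(sum(s1) - sum(s2)) / sum(s2), 0.01)
  expect_lt(mean(abs(s1 - s2)), 0.5)
})

test_that("build_feature_table has one masked-complete row per atom", {
  spec <- synthetic_spec(n_residues = 12, sequence = "ASPKTGLVEQIF",
                         seed = 21, n_methods = 1)
  tab <- make_shift_tables(spec)
  sens <- compute_sensitivity(tab)
  ft <- build_feature_table(ft_groups$stretched, ft_groups$globular, sens,
                            seed = 3)
  expect_identical(nrow(ft), nrow(sens))
  expect_true(all(c("atom_category", "atom_name", "atom_element",
                    "residue_name", "residue_number", "ddist_O", "ddist_N",
                    "ddist_RES", "dphi", "dpsi", "dsasa", "is_sidechain",
                    "alignability", "neg_control_cont", "neg_control_cat",
                    "sensitivity") %in% names(ft)))
  expect_true(all(ft$neg_control_cont >= 0 & ft$neg_control_cont <= 20))
  expect_true(all(ft$neg_control_cat %in% 0:6))
  # negative controls reproducible under the seed, independent of label
  ft2 <- build_feature_table(ft_groups$stretched, ft_groups$globular, sens,
                             seed = 3)
  expect_identical(ft$neg_control_cont, ft2$neg_control_cont)
  # control bounds respected over many draws
  ctrl <- csens:::with_seed(1, runif(1e5, 0, 20))
  expect_true(min(ctrl) >= 0 && max(ctrl) <= 20)
})

test_that("encode produces grouped one-hot blocks and stable ordinals", {
  tab <- data.frame(atom_category = c("Calpha", "Cbeta", "Hamide"),
                    atom_name = c("CA", "CB", "H"),
                    atom_element = c("C", "C", "H"),
                    residue_name = c("ALA", "GLY", "ALA"),
                    residue_number = 1:3,
                    ddist_O = c(0.1, 0.2, 0.3), ddist_N = 0, ddist_RES = 0,
                    dphi = 0, dpsi = 0, dsasa = 0, is_sidechain = FALSE,
                    alignability = 0.5, neg_control_cont = 1,
                    neg_control_cat = c(0L, 3L, 6L),
                    sensitivity = c(1, 2, 3))
  oh <- encode(tab, "one-hot")
  blk <- oh$x[, oh$col_map$atom_category, drop = FALSE]
  expect_identical(ncol(blk), 3L)
  expect_equal(rowSums(blk), rep(1, 3))
  expect_identical(length(unlist(oh$col_map)), ncol(oh$x))

  od <- encode(tab, "ordinal")
  expect_identical(ncol(od$x), length(od$col_map))
  codes <- od$x[, od$col_map$residue_name]
  expect_identical(decode_ordinal(codes, od$levels$residue_name),
                   tab$residue_name)
  # ordinal codes are stable across runs (sorted levels)
  od2 <- encode(tab[3:1, ], "ordinal")
  expect_identical(od2$levels, od$levels)

  tab_new <- tab; tab_new$residue_name[1] <- "TRP"
  expect_error(encode(tab_new, "one-hot", levels = oh$levels), "unseen")
})

test_that("the random forest fits planted structure and respects nulls", {
  set.seed(61)
  n <- 400
  x <- matrix(runif(n * 5), n, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  # pure-noise label: test R2 hovers around zero
  y_noise <- rnorm(n)
  fit <- csens:::with_seed(1, rf_regressor(x[1:320, ], y_noise[1:320]))
  r2 <- csens:::r_squared(y_noise[321:400], predict(fit, x[321:400, ]))
  expect_lt(abs(r2), 0.35)

  # planted linear signal is learned
  y <- 3 * x[, 2] + rnorm(n, 0, 0.2)
  fit2 <- csens:::with_seed(1, rf_regressor(x[1:320, ], y[1:320]))
  r2b <- csens:::r_squared(y[321:400], predict(fit2, x[321:400, ]))
  expect_gt(r2b, 0.7)
  # determinism under seed
  fit3 <- csens:::with_seed(1, rf_regressor(x[1:320, ], y[1:320]))
  expect_identical(predict(fit2, x), predict(fit3, x))
})

test_that("fit_importance ranks a planted feature first and zeroes controls", {
  spec <- synthetic_spec(n_residues = 12, sequence = "ASPKTGLVEQIF",
                         seed = 21, n_methods = 1)
  sens <- compute_sensitivity(make_shift_tables(spec))
  ft <- build_feature_table(ft_groups$stretched, ft_groups$globular, sens,
                            seed = 3)
  # plant the label on one biophysical feature
  ft$sensitivity <- csens:::with_seed(77,
    0.5 * ft$alignability * 10 + rnorm(nrow(ft), 0, 0.15))
  rep <- fit_importance(ft, seeds = 0:14)
  expect_gt(rep$n_retained, 0)
  expect_identical(rep$importance$feature[1], "alignability")
  first <- apply(rep$per_repeat, 1, function(v) names(which.max(v)))
  expect_gte(mean(first == "alignability"), 0.9)
  ctrl <- rep$importance[rep$importance$feature %in%
                           c("neg_control_cont", "neg_control_cat"), ]
  expect_true(all(abs(ctrl$mean_importance) < 2 * ctrl$se))

  # a label of pure noise leaves little to learn: most repeats dropped or
  # test R2 near zero
  ft2 <- ft
  ft2$sensitivity <- csens:::with_seed(88, rnorm(nrow(ft)))
  rep2 <- suppressWarnings(fit_importance(ft2, seeds = 0:9))
  expect_lt(mean(rep2$scores$r2_test), 0.2)
})
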