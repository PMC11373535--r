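# Per-atom biophysical feature table and the random-forest permutation
# feature-importance procedure.

# Evaluate expr under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Per-atom minimum distance to qualifying targets, averaged over a group's
# members.  Targets are oxygen atoms, nitrogen atoms, or residue centres of
# geometry, restricted to residues at least `min_sep` residues away.
.group_min_distance <- function(group, target_kind, min_sep = 3) {
  per_member <- lapply(group$members, function(cf) {
    a <- cf$atoms
    idx <- which(!a$is_water)
    xyz <- coords(cf, idx)
    res <- a$residue_number[idx]
    if (target_kind %in% c("O", "N")) {
      ti <- which(a$element[idx] == target_kind)
      txyz <- xyz[ti, , drop = FALSE]
      tres <- res[ti]
    } else if (target_kind == "RES") {
      units <- unique(res)
      txyz <- t(vapply(units, function(u)
        colMeans(xyz[res == u, , drop = FALSE]), numeric(3)))
      tres <- units
    } else stop("unknown target kind: ", target_kind)
    if (nrow(txyz) == 0) return(rep(NA_real_, nrow(a)))
    d2 <- outer(rowSums(xyz^2), rowSums(txyz^2), `+`) - 2 * tcrossprod(xyz, txyz)
    d2[d2 < 0] <- 0
    mask <- abs(outer(res, tres, `-`)) < min_sep
    d2[mask] <- Inf
    dmin <- sqrt(apply(d2, 1, min))
    dmin[is.infinite(dmin)] <- NA_real_
    out <- rep(NA_real_, nrow(a))
    out[idx] <- dmin
    out
  })
  rowMeans(do.call(cbind, per_member))
}

#' Signed change in distance-to-nearest-target between conformations
#'
#' Per conformer, the minimum distance from each atom to any qualifying
#' target -- an oxygen atom, a nitrogen atom, or a residue centre of geometry
#' -- belonging to a residue at least three residues away in sequence.  Group
#' values are member means; the feature is `stretched - globular` (signed).
#'
#' @param group_s,group_g `conformer_group`s for the stretched and globular
#'   conformations (shared atom ordering).
#' @param target_kind `"O"`, `"N"` or `"RES"`.
#' @param min_sep minimum sequence separation of the target residue.
#' @return Numeric vector, one value (Å) per atom; `NA` when no qualifying
#'   target exists.
#' @export
delta_distance_feature <- function(group_s, group_g, target_kind,
                                   min_sep = 3) {
  .group_min_distance(group_s, target_kind, min_sep) -
    .group_min_distance(group_g, target_kind, min_sep)
}

#' Signed change in per-atom SASA between conformations
#'
#' Per-atom Shrake-Rupley SASA (see [sasa_atoms()]), averaged over each
#' group's members, differenced `stretched - globular`.
#'
#' @inheritParams delta_distance_feature
#' @param probe probe radius, Å.
#' @param n_points quadrature points per atom.
#' @return Numeric vector (Å^2) per atom.
#' @export
delta_sasa <- function(group_s, group_g, probe = 1.4, n_points = 240) {
  gmean <- function(g) rowMeans(vapply(g$members, sasa_atoms,
                                       numeric(nrow(g$members[[1]]$atoms)),
                                       probe = probe, n_points = n_points))
  gmean(group_s) - gmean(group_g)
}

# Circular group-mean phi/psi per residue over a group's members.
.group_dihedrals <- function(group) {
  per <- lapply(group$members, backbone_dihedrals)
  circ_mean <- function(m) {
    rad <- m * pi / 180
    wrap_angle(atan2(rowMeans(sin(rad)), rowMeans(cos(rad))) * 180 / pi)
  }
  data.frame(residue_number = per[[1]]$residue_number,
             phi = circ_mean(vapply(per, `[[`, numeric(nrow(per[[1]])), "phi")),
             psi = circ_mean(vapply(per, `[[`, numeric(nrow(per[[1]])), "psi")))
}

#' Build the per-atom feature table
#'
#' One row per sensitivity record (i.e. per retained atom), with the
#' biophysical features: atom category/name/element, residue name/number,
#' signed changes in distance to the nearest O / N / residue centre, signed
#' changes in the residue's phi and psi, signed change in per-atom SASA,
#' side-chain flag, per-atom alignability (mean of the two group values), two
#' negative controls drawn independently of the label (uniform real on
#' \[0, 20\] and uniform integer on \{0..6\}), and the conformational
#' sensitivity as label.
#'
#' @param group_s,group_g the stretched and globular `conformer_group`s.
#' @param sensitivity_records output of [compute_sensitivity()].
#' @param seed RNG seed for the negative controls.
#' @param probe,n_points SASA parameters.
#' @return data.frame of feature rows.
#' @export
build_feature_table <- function(group_s, group_g, sensitivity_records,
                                seed = 0, probe = 1.4, n_points = 240) {
  cs <- group_s$members[[group_s$central]]
  a <- cs$atoms
  key_atoms <- paste(a$residue_number, a$atom_name, sep = "|")
  key_rec <- paste(sensitivity_records$residue_number,
                   sensitivity_records$atom_name, sep = "|")
  ai <- match(key_rec, key_atoms)
  if (any(is.na(ai)))
    stop("sensitivity records refer to atoms absent from the structure")

  dd_o <- delta_distance_feature(group_s, group_g, "O")
  dd_n <- delta_distance_feature(group_s, group_g, "N")
  dd_res <- delta_distance_feature(group_s, group_g, "RES")
  dsasa <- delta_sasa(group_s, group_g, probe, n_points)
  align <- (per_atom_alignability(group_s) + per_atom_alignability(group_g)) / 2

  dih_s <- .group_dihedrals(group_s)
  dih_g <- .group_dihedrals(group_g)
  stopifnot(identical(dih_s$residue_number, dih_g$residue_number))
  dphi_res <- delta_dihedral(dih_g$phi, dih_s$phi)
  dpsi_res <- delta_dihedral(dih_g$psi, dih_s$psi)
  ri <- match(a$residue_number[ai], dih_s$residue_number)

  n <- length(ai)
  ctrl <- with_seed(seed, list(cont = runif(n, 0, 20),
                               cat = sample(0:6, n, replace = TRUE)))
  data.frame(
    residue_number = a$residue_number[ai],
    atom_name = a$atom_name[ai],
    atom_category = sensitivity_records$category,
    atom_element = a$element[ai],
    residue_name = a$residue_name[ai],
    ddist_O = dd_o[ai], ddist_N = dd_n[ai], ddist_RES = dd_res[ai],
    dphi = dphi_res[ri], dpsi = dpsi_res[ri],
    dsasa = dsasa[ai],
    is_sidechain = !a$is_backbone[ai],
    alignability = align[ai],
    neg_control_cont = ctrl$cont,
    neg_control_cat = ctrl$cat,
    sensitivity = sensitivity_records$sensitivity,
    stringsAsFactors = FALSE)
}

.categorical_features <- c("atom_category", "atom_name", "atom_element",
                           "residue_name", "neg_control_cat")
.numeric_features <- c("residue_number", "ddist_O", "ddist_N", "ddist_RES",
                       "dphi", "dpsi", "dsasa", "is_sidechain",
                       "alignability", "neg_control_cont")

#' Encode a feature table as a numeric matrix
#'
#' Categorical features become indicator column blocks (one-hot) or stable
#' integer codes (ordinal, levels sorted).  The returned column map relates
#' each feature to its matrix columns, so one-hot blocks can be shuffled
#' jointly during permutation importance.
#'
#' @param table feature table from [build_feature_table()].
#' @param scheme `"one-hot"` or `"ordinal"`.
#' @param levels optional named list of factor levels (from a previous
#'   encoding) to apply at transform time; unseen levels raise an error.
#' @return List with `x` (numeric matrix), `col_map` (named list of column
#'   indices per feature), `levels`, `scheme`, and `label` (the sensitivity
#'   vector) .
#' @export
encode <- function(table, scheme = c("one-hot", "ordinal"), levels = NULL) {
  scheme <- match.arg(scheme)
  cols <- list(); col_map <- list(); lev_out <- list()
  for (f in c(.categorical_features, .numeric_features)) {
    if (!f %in% names(table)) next
    v <- table[[f]]
    if (f %in% .categorical_features) {
      lv <- if (!is.null(levels)) levels[[f]] else sort(unique(as.character(v)))
      if (any(!as.character(v) %in% lv))
        stop("unseen level(s) in feature ", f, ": ",
             paste(setdiff(unique(as.character(v)), lv), collapse = ", "))
      lev_out[[f]] <- lv
      if (scheme == "one-hot") {
        block <- vapply(lv, function(l) as.numeric(as.character(v) == l),
                        numeric(length(v)))
        colnames(block) <- paste(f, lv, sep = "=")
        col_map[[f]] <- length(unlist(col_map)) + seq_len(ncol(block))
        cols[[f]] <- block
      } else {
        code <- match(as.character(v), lv) - 1
        col_map[[f]] <- length(unlist(col_map)) + 1L
        cols[[f]] <- matrix(code, ncol = 1, dimnames = list(NULL, f))
      }
    } else {
      col_map[[f]] <- length(unlist(col_map)) + 1L
      cols[[f]] <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, f))
    }
  }
  x <- do.call(cbind, cols)
  list(x = x, col_map = col_map, levels = lev_out, scheme = scheme,
       label = table$sensitivity)
}

#' Decode ordinal codes back to labels
#'
#' @param codes integer codes produced by ordinal [encode()].
#' @param levels the level vector stored in the encoding for that feature.
#' @return Character vector of labels.
#' @export
decode_ordinal <- function(codes, levels) levels[codes + 1]

#' Fit a random-forest regressor
#'
#' CART trees with squared-error splits, bootstrap rows, `mtry` features per
#' node.  Defaults follow the feature-importance protocol: 100 trees,
#' `max_depth` 10, `min_samples_split` 15, `min_samples_leaf` 10.
#'
#' @param x numeric feature matrix.
#' @param y numeric response.
#' @param n_trees,mtry,max_depth,min_split,min_leaf forest hyperparameters;
#'   `mtry` defaults to one third of the columns.
#' @return Object of class `rf_regressor`.
#' @export
rf_regressor <- function(x, y, n_trees = 100, mtry = max(1L, ncol(x) %/% 3L),
                         max_depth = 10, min_split = 15, min_leaf = 10) {
  stopifnot(nrow(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  forest <- .rf_fit_cpp(x, y, as.integer(n_trees), as.integer(mtry),
                        as.integer(max_depth), as.integer(min_split),
                        as.integer(min_leaf))
  structure(list(forest = forest, n_features = ncol(x)),
            class = "rf_regressor")
}

#' @export
predict.rf_regressor <- function(object, newdata, ...) {
  stopifnot(ncol(newdata) == object$n_features)
  .rf_predict_cpp(object$forest, as.matrix(newdata))
}

# Coefficient of determination on held-out data (test-mean baseline).
r_squared <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Random-forest permutation feature importance
#'
#' For each seed: an 80/20 train/test split, a random forest with the stated
#' hyperparameters, train and test R²; repeats with negative test R² are
#' discarded.  Permutation importance of a feature is the mean drop in test
#' R² over `n_shuffles` joint shuffles of the feature's encoded columns.
#' Remaining importances and scores are averaged over the retained repeats.
#'
#' @param feature_table output of [build_feature_table()]; rows with missing
#'   feature values are dropped with a message.
#' @param scheme encoding scheme, `"one-hot"` (default) or `"ordinal"`.
#' @param seeds integer vector of RNG seeds, one repeat each (default 0:49).
#' @param n_shuffles permutation repeats per feature per model.
#' @param train_frac training fraction of the split.
#' @param redraw_controls redraw the two negative-control columns under each
#'   repeat's seed (default `TRUE`).  Each repeat re-seeds the whole
#'   procedure, so the artificial controls are fresh random draws per model;
#'   a control's chance correlation with the label then averages out across
#'   repeats and the reported control importances are a valid null check.
#'   With `FALSE` the controls are the fixed columns of `feature_table`.
#' @inheritParams rf_regressor
#' @return Object of class `importance_report`: list with `importance`
#'   (data.frame of per-feature mean and sd importance and its standard
#'   error), `scores` (per-repeat train/test R² and retention flag),
#'   `n_retained`, `scheme`.
#' @export
fit_importance <- function(feature_table, scheme = "one-hot", seeds = 0:49,
                           n_trees = 100, max_depth = 10, min_split = 15,
                           min_leaf = 10, n_shuffles = 10, train_frac = 0.8,
                           redraw_controls = TRUE) {
  feat_cols <- c(.categorical_features, .numeric_features)
  feat_cols <- intersect(feat_cols, names(feature_table))
  cc <- stats::complete.cases(feature_table[, c(feat_cols, "sensitivity")]) &
    is.finite(feature_table$sensitivity)
  if (any(!cc))
    message("fit_importance: dropping ", sum(!cc),
            " row(s) with missing values")
  tab <- feature_table[cc, , drop = FALSE]
  if (nrow(tab) < 30)
    stop("need at least 30 complete rows for the 80/20 split")
  enc <- encode(tab, scheme)
  x <- enc$x; y <- enc$label
  n <- nrow(x)
  features <- names(enc$col_map)

  imp_rows <- list(); scores <- list()
  for (s in seeds) {
    res <- with_seed(s, {
      if (redraw_controls) {
        cc_cont <- enc$col_map$neg_control_cont
        if (!is.null(cc_cont)) x[, cc_cont] <- runif(n, 0, 20)
        cc_cat <- enc$col_map$neg_control_cat
        if (!is.null(cc_cat)) {
          lv <- enc$levels$neg_control_cat
          code <- sample(seq_along(lv), n, replace = TRUE)
          x[, cc_cat] <- if (length(cc_cat) > 1)
            vapply(seq_along(lv), function(l) as.numeric(code == l),
                   numeric(n))
          else code - 1
        }
      }
      itr <- sample(n, floor(train_frac * n))
      fit <- rf_regressor(x[itr, , drop = FALSE], y[itr], n_trees = n_trees,
                          max_depth = max_depth, min_split = min_split,
                          min_leaf = min_leaf)
      xte <- x[-itr, , drop = FALSE]; yte <- y[-itr]
      r2_tr <- r_squared(y[itr], predict(fit, x[itr, , drop = FALSE]))
      r2_te <- r_squared(yte, predict(fit, xte))
      imp <- NULL
      if (r2_te >= 0) {
        imp <- vapply(features, function(f) {
          cols <- enc$col_map[[f]]
          drops <- vapply(seq_len(n_shuffles), function(k) {
            xp <- xte
            perm <- sample(nrow(xte))
            xp[, cols] <- xte[perm, cols, drop = FALSE]
            r2_te - r_squared(yte, predict(fit, xp))
          }, numeric(1))
          mean(drops)
        }, numeric(1))
      }
      list(r2_tr = r2_tr, r2_te = r2_te, imp = imp)
    })
    scores[[length(scores) + 1]] <-
      data.frame(seed = s, r2_train = res$r2_tr, r2_test = res$r2_te,
                 retained = res$r2_te >= 0)
    if (!is.null(res$imp)) imp_rows[[length(imp_rows) + 1]] <- res$imp
  }
  scores <- do.call(rbind, scores)
  n_ret <- length(imp_rows)
  if (n_ret == 0) {
    warning("all repeats yielded negative test R2; no importances retained")
    importance <- data.frame(feature = features, mean_importance = NA_real_,
                             sd_importance = NA_real_, se = NA_real_)
  } else {
    im <- do.call(rbind, imp_rows)
    importance <- data.frame(feature = features,
                             mean_importance = colMeans(im),
                             sd_importance = apply(im, 2, sd),
                             se = apply(im, 2, sd) / sqrt(n_ret))
    importance <- importance[order(-importance$mean_importance), ]
    rownames(importance) <- NULL
  }
  structure(list(importance = importance, scores = scores,
                 n_retained = n_ret, scheme = scheme,
                 per_repeat = if (n_ret > 0) do.call(rbind, imp_rows) else NULL),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("<importance_report> %d/%d repeats retained (%s encoding)\n",
              x$n_retained, nrow(x$scores), x$scheme))
  cat(sprintf("mean test R2 (retained): %.3f\n",
              mean(x$scores$r2_test[x$scores$retained])))
  print(x$importance, digits = 3)
  invisible(x)
}
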