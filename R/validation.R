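# Agreement with experiment (mean relative error) and secondary-chemical-
# shift analysis against a random-coil baseline.

#' Mean relative error against experiment
#'
#' Per atom, the simulated mean over the supplied conformers is compared with
#' the experimental value; the metric is the mean over joined atoms of
#' \eqn{|\delta^{sim}_{mean} - \delta^{exp}| / |\delta^{exp}|}.  Atoms with
#' \eqn{\delta^{exp} = 0} are excluded with a warning.  Because ¹H shifts
#' near 0 ppm inflate relative errors, a per-element breakdown is also
#' returned.
#'
#' @param table_exp data.frame with `residue_number`, `atom_name`, `element`,
#'   `delta_exp` (ppm); unique atom keys.
#' @param shift_table canonical-schema shift table whose conformers define
#'   the simulated mean.
#' @return List with `mre` (fraction), `per_element` (named vector),
#'   `n_atoms`, and the joined per-atom table.
#' @export
mean_relative_error <- function(table_exp, shift_table) {
  key_exp <- paste(table_exp$residue_number, table_exp$atom_name, sep = "|")
  if (anyDuplicated(key_exp)) stop("experimental table has duplicate atoms")
  sim <- aggregate(value_ppm ~ residue_number + atom_name + element,
                   data = shift_table, FUN = mean)
  key_sim <- paste(sim$residue_number, sim$atom_name, sep = "|")
  j <- match(key_exp, key_sim)
  keep <- !is.na(j)
  if (!any(keep)) stop("empty join between experiment and simulation")
  joined <- data.frame(residue_number = table_exp$residue_number[keep],
                       atom_name = table_exp$atom_name[keep],
                       element = sim$element[j[keep]],
                       delta_exp = table_exp$delta_exp[keep],
                       delta_sim_mean = sim$value_ppm[j[keep]])
  zero <- joined$delta_exp == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " atom(s) with zero experimental shift")
    joined <- joined[!zero, , drop = FALSE]
  }
  rel <- abs(joined$delta_sim_mean - joined$delta_exp) / abs(joined$delta_exp)
  joined$relative_error <- rel
  per_el <- tapply(rel, joined$element, mean)
  list(mre = mean(rel), per_element = per_el, n_atoms = nrow(joined),
       atoms = joined)
}

#' Secondary chemical shift
#'
#' \eqn{\Delta\delta = \delta_{obs} - \delta_{rc}} (observed minus random
#' coil, the modern sign convention).  `NA` random-coil values propagate.
#'
#' @param delta_obs,delta_rc observed and random-coil shifts, ppm.
#' @return Secondary shift(s), ppm.
#' @export
secondary_shift <- function(delta_obs, delta_rc) delta_obs - delta_rc

#' Secondary-structure identifier from CA/CB secondary shifts
#'
#' \eqn{\Delta\Delta\delta_{\alpha\beta} = \Delta\delta_{C\alpha} -
#' \Delta\delta_{C\beta}}.  Values above `+threshold` indicate alpha
#' propensity, below `-threshold` beta propensity, otherwise random coil.
#' The default threshold of 1.0 ppm is a conventional, deliberately coarse
#' cut.
#'
#' @param ddelta_ca,ddelta_cb secondary shifts of CA and CB, ppm (vectors
#'   recycled to a common length; glycine lacks CB, pass `NA`).
#' @param threshold call threshold, ppm.
#' @return data.frame with `ddelta_ab` and `call` (`"alpha-indication"`,
#'   `"beta-indication"`, `"random-coil"`, `NA` when undefined).
#' @export
secondary_structure_identifier <- function(ddelta_ca, ddelta_cb,
                                           threshold = 1.0) {
  dd <- secondary_shift(ddelta_ca, ddelta_cb)   # same subtraction
  call <- ifelse(is.na(dd), NA_character_,
                 ifelse(dd > threshold, "alpha-indication",
                        ifelse(dd < -threshold, "beta-indication",
                               "random-coil")))
  data.frame(ddelta_ab = dd, call = call, stringsAsFactors = FALSE)
}

#' Per-residue secondary-shift analysis of a shift table
#'
#' Joins per-residue CA/CB mean shifts with a random-coil table and derives
#' \eqn{\Delta\delta_{C\alpha}}, \eqn{\Delta\delta_{C\beta}},
#' \eqn{\Delta\Delta\delta_{\alpha\beta}} and the structure call.
#'
#' @param obs_table either a canonical shift table (averaged over conformers)
#'   or an experimental-style table with `residue_number`, `atom_name` and a
#'   value column named `value_ppm` or `delta_exp`.
#' @param rc_table data.frame with `residue_number`, `atom_name`, `delta_rc`.
#' @param threshold call threshold in ppm.
#' @return data.frame with one row per residue possessing a CA entry.
#' @export
secondary_shift_analysis <- function(obs_table, rc_table, threshold = 1.0) {
  val_col <- if ("value_ppm" %in% names(obs_table)) "value_ppm" else "delta_exp"
  obs <- aggregate(obs_table[[val_col]],
                   by = list(residue_number = obs_table$residue_number,
                             atom_name = obs_table$atom_name),
                   FUN = mean)
  names(obs)[3] <- "delta_obs"
  get_val <- function(d, col, res, atom) {
    i <- which(d$residue_number == res & d$atom_name == atom)
    if (length(i) == 0) NA_real_ else d[[col]][i[1]]
  }
  residues <- sort(unique(obs$residue_number[obs$atom_name == "CA"]))
  rows <- lapply(residues, function(r) {
    d_ca <- secondary_shift(get_val(obs, "delta_obs", r, "CA"),
                            get_val(rc_table, "delta_rc", r, "CA"))
    d_cb <- secondary_shift(get_val(obs, "delta_obs", r, "CB"),
                            get_val(rc_table, "delta_rc", r, "CB"))
    id <- secondary_structure_identifier(d_ca, d_cb, threshold)
    data.frame(residue_number = r, ddelta_ca = d_ca, ddelta_cb = d_cb,
               ddelta_ab = id$ddelta_ab, call = id$call,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read an experimental shift table
#'
#' @param path CSV with columns `residue_number`, `residue_name`,
#'   `atom_name`, `element`, `delta_exp`.
#' @return data.frame.
#' @export
read_experimental_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("residue_number", "atom_name", "delta_exp")
  miss <- setdiff(req, names(d))
  if (length(miss) > 0)
    stop("experimental table lacks columns: ", paste(miss, collapse = ", "))
  d
}
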