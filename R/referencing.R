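# Conversion of isotropic shieldings to chemical shifts and assembly of
# per-fragment central-residue shifts into a full-peptide table.

#' Reference constants for shielding-to-shift conversion
#'
#' The two literature constants are the absolute ¹⁵N shielding of liquid
#' ammonia (the ¹⁵N shift reference, 244.6 ppm) and of methylamine
#' (249.5 ppm); together they place a calculated methylamine shielding on
#' the ammonia shift scale.  `sigma_tms_calc` and `sigma_ch3nh2_calc` are the
#' method-matched calculated reference shieldings and must come from the same
#' level of theory as the shieldings being referenced.
#'
#' @param sigma_tms_calc named numeric, calculated TMS shieldings per element
#'   (`H`, `C`), ppm.
#' @param sigma_ch3nh2_calc calculated methylamine ¹⁵N shielding, ppm.
#' @param sigma_nh3_lit,sigma_ch3nh2_lit literature absolute shieldings, ppm.
#' @return Object of class `reference_constants`.
#' @export
reference_constants <- function(sigma_tms_calc = c(H = NA_real_, C = NA_real_),
                                sigma_ch3nh2_calc = NA_real_,
                                sigma_nh3_lit = 244.6,
                                sigma_ch3nh2_lit = 249.5) {
  structure(list(sigma_tms_calc = sigma_tms_calc,
                 sigma_ch3nh2_calc = sigma_ch3nh2_calc,
                 sigma_nh3_lit = sigma_nh3_lit,
                 sigma_ch3nh2_lit = sigma_ch3nh2_lit),
            class = "reference_constants")
}

#' TMS referencing for ¹H and ¹³C shieldings
#'
#' \deqn{\delta_X = \sigma^{calc}_{TMS} - \sigma^{calc}_X}
#'
#' @param sigma_x isotropic shielding(s) of the nucleus, ppm.
#' @param sigma_tms_calc calculated TMS shielding for the same element and
#'   method, ppm.
#' @return Chemical shift(s) in ppm.
#' @export
shift_from_shielding_hc <- function(sigma_x, sigma_tms_calc) {
  stopifnot(all(is.finite(sigma_x)), is.finite(sigma_tms_calc))
  sigma_tms_calc - sigma_x
}

#' Methylamine secondary-standard referencing for ¹⁵N shieldings
#'
#' The calculated methylamine shielding serves as the primary calculated
#' reference; the literature absolute shieldings of ammonia and methylamine
#' shift the result onto the ammonia scale:
#' \deqn{\delta_X = \sigma^{calc}_{CH_3NH_2} - \sigma^{calc}_X +
#'   (\sigma^{lit}_{NH_3} - \sigma^{lit}_{CH_3NH_2})}
#' With the default constants the fixed offset is \eqn{244.6 - 249.5 =
#' -4.9} ppm.
#'
#' @param sigma_x isotropic ¹⁵N shielding(s), ppm.
#' @param constants a [reference_constants()] object with a finite
#'   `sigma_ch3nh2_calc`.
#' @return Chemical shift(s) in ppm on the NH3 scale.
#' @export
shift_from_shielding_n <- function(sigma_x, constants) {
  if (!is.finite(constants$sigma_ch3nh2_calc))
    stop("missing method-matched calculated CH3NH2 shielding")
  constants$sigma_ch3nh2_calc - sigma_x +
    (constants$sigma_nh3_lit - constants$sigma_ch3nh2_lit)
}

#' Reference a shielding table into a shift table
#'
#' Applies TMS referencing to H and C rows and methylamine secondary-standard
#' referencing to N rows.  Elements other than H/C/N are rejected.
#'
#' @param shieldings data.frame in the canonical long schema with a
#'   `value_ppm` column holding isotropic shieldings (plus `method`,
#'   `conformer_id`, `group`, `residue_number`, `residue_name`, `atom_name`,
#'   `element`).
#' @param constants a [reference_constants()] object.
#' @return The same data.frame with `value_ppm` replaced by chemical shifts.
#' @export
reference_shieldings <- function(shieldings, constants) {
  el <- shieldings$element
  bad <- setdiff(unique(el), c("H", "C", "N"))
  if (length(bad) > 0)
    stop("cannot reference element(s): ", paste(bad, collapse = ", "))
  out <- shieldings
  for (e in c("H", "C")) {
    i <- which(el == e)
    if (length(i) == 0) next
    ref <- constants$sigma_tms_calc[[e]]
    if (is.null(ref) || !is.finite(ref))
      stop("missing calculated TMS shielding for element ", e)
    out$value_ppm[i] <- shift_from_shielding_hc(shieldings$value_ppm[i], ref)
  }
  i <- which(el == "N")
  if (length(i) > 0)
    out$value_ppm[i] <- shift_from_shielding_n(shieldings$value_ppm[i],
                                               constants)
  out
}

#' Assemble per-fragment central-residue shifts into a peptide table
#'
#' Each fragment contributes only the atoms of its own central unit; rows for
#' non-central residues are discarded.  Every peptide unit must be central in
#' exactly one fragment set.
#'
#' @param fragment_shift_sets list of canonical-schema shift data.frames, one
#'   per fragment.
#' @param central_units integer vector parallel to `fragment_shift_sets`
#'   giving each fragment's central residue number.
#' @return A single canonical-schema shift data.frame.
#' @export
assemble_peptide_shifts <- function(fragment_shift_sets, central_units) {
  stopifnot(length(fragment_shift_sets) == length(central_units))
  if (anyDuplicated(central_units))
    stop("coverage error: residue(s) central in more than one fragment: ",
         paste(unique(central_units[duplicated(central_units)]), collapse = ", "))
  covered <- unlist(lapply(fragment_shift_sets, function(d)
    unique(d$residue_number)))
  not_central <- setdiff(covered, central_units)
  if (length(not_central) > 0)
    stop("coverage error: residue(s) never central: ",
         paste(not_central, collapse = ", "))
  parts <- Map(function(d, cu) d[d$residue_number == cu, , drop = FALSE],
               fragment_shift_sets, central_units)
  out <- do.call(rbind, parts[order(central_units)])
  rownames(out) <- NULL
  out
}

#' Read/write canonical shift tables
#'
#' The canonical long schema is `method, conformer_id, group, residue_number,
#' residue_name, atom_name, element, value_ppm`; every downstream module
#' consumes only this schema.
#'
#' @param path CSV file path.
#' @return data.frame in the canonical schema.
#' @export
read_shift_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("method", "conformer_id", "group", "residue_number",
           "residue_name", "atom_name", "element", "value_ppm")
  miss <- setdiff(req, names(d))
  if (length(miss) > 0)
    stop("shift table lacks columns: ", paste(miss, collapse = ", "))
  d
}

#' @rdname read_shift_table
#' @param table canonical-schema data.frame to write.
#' @export
write_shift_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
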