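# The core statistic: per-atom two-group comparison in pooled-sigma units,
# Gaussian-overlap thresholding, atom categorisation, exclusion rules,
# per-residue aggregation and the cross-method agreement matrix.

#' Pooled standard deviation of two samples
#'
#' Classical two-sample pooled estimate with (n-1)-weighted sample variances:
#' \deqn{s_p = \sqrt{\frac{(n_a-1)s_a^2 + (n_b-1)s_b^2}{n_a+n_b-2}}}
#'
#' @param samples_a,samples_b numeric vectors, each of length >= 2.
#' @return Pooled standard deviation.
#' @export
pooled_std <- function(samples_a, samples_b) {
  na <- length(samples_a); nb <- length(samples_b)
  if (na < 2 || nb < 2) stop("each group needs at least two samples")
  sqrt(((na - 1) * var(samples_a) + (nb - 1) * var(samples_b)) /
         (na + nb - 2))
}

#' Overlap of two equal-spread Gaussians
#'
#' The overlapping area of two unit-variance normal densities whose means are
#' `separation` standard deviations apart equals \eqn{2\Phi(-d/2)}: the
#' densities cross midway between the means, and each tail beyond the
#' crossing contributes \eqn{\Phi(-d/2)}.
#'
#' @param separation non-negative separation in multiples of the common sigma.
#' @return Overlap fraction in \[0, 1\]; 1 at zero separation.
#' @export
gaussian_overlap <- function(separation) {
  if (any(separation < 0)) stop("separation must be non-negative")
  2 * pnorm(-separation / 2)
}

#' Separation at which the Gaussian overlap reaches a target
#'
#' Numerically inverts [gaussian_overlap()] by root bracketing.  At the 10%
#' overlap used as sensitivity threshold this yields 3.29 sigma (2 d.p.).
#'
#' @param overlap target overlap fraction in (0, 1\].
#' @param interval search interval in sigma units.
#' @param tol root-finding tolerance.
#' @return Separation in sigma units.
#' @export
overlap_threshold_separation <- function(overlap = 0.10,
                                         interval = c(0, 50),
                                         tol = 1e-10) {
  stopifnot(overlap > 0, overlap <= 1)
  uniroot(function(d) gaussian_overlap(d) - overlap, interval,
          tol = tol)$root
}

#' Conformational sensitivity of one atom's shifts
#'
#' Computes both group means and standard deviations, the pooled standard
#' deviation and the sensitivity \eqn{|\bar\delta_s - \bar\delta_g| / s_p}
#' in multiples of the pooled sigma.  If the pooled sigma is zero the
#' sensitivity is 0 for equal means and `Inf` otherwise.
#'
#' @param samples_stretched,samples_globular per-group shift samples (ppm),
#'   each of length >= 2.
#' @param threshold sensitivity threshold in sigma units.
#' @return One-row data.frame with `mean_stretched`, `mean_globular`,
#'   `sd_stretched`, `sd_globular`, `pooled_sd`, `sensitivity`,
#'   `is_sensitive`.
#' @export
sensitivity_sigma <- function(samples_stretched, samples_globular,
                              threshold = 3.29) {
  sp <- pooled_std(samples_stretched, samples_globular)
  ms <- mean(samples_stretched); mg <- mean(samples_globular)
  sens <- if (sp == 0) {
    if (ms == mg) 0 else Inf
  } else abs(ms - mg) / sp
  data.frame(mean_stretched = ms, mean_globular = mg,
             sd_stretched = sd(samples_stretched),
             sd_globular = sd(samples_globular),
             pooled_sd = sp, sensitivity = sens,
             is_sensitive = classify_sensitive(sens, threshold))
}

#' Classify a sensitivity value against the overlap threshold
#'
#' Strict inequality: a shift is conformationally sensitive iff its
#' sensitivity exceeds the threshold (10% distribution overlap corresponds to
#' 3.29 sigma, so 3.29 exactly is *not* sensitive).
#'
#' @param sensitivity non-negative sensitivity value(s) in sigma units.
#' @param threshold threshold in sigma units (default 3.29).
#' @return Logical vector.
#' @export
classify_sensitive <- function(sensitivity, threshold = 3.29) {
  if (any(sensitivity < 0, na.rm = TRUE)) stop("sensitivity must be >= 0")
  sensitivity > threshold
}

#' Categorise atoms into the eight shift categories
#'
#' Backbone atoms map to `Calpha`, `Ccarbonyl`, `Hamide`, `Namide`; `CB` maps
#' to `Cbeta`; remaining H/C/N atoms map to `Hother`/`Cother`/`Nother`.
#' Oxygen and cap-group atoms must be excluded beforehand (see
#' [filter_atoms()]) and raise an error here.
#'
#' @param atom_name,element character vectors (recycled to common length).
#' @param residue_name optional; used only to reject cap-group atoms.
#' @return Character vector of category labels.
#' @export
categorize_atom <- function(atom_name, element,
                            residue_name = NULL) {
  n <- max(length(atom_name), length(element))
  atom_name <- rep_len(atom_name, n); element <- rep_len(element, n)
  if (!is.null(residue_name) && any(residue_name %in% .cap_resnames))
    stop("cap-group atoms must be filtered out before categorisation")
  if (any(element == "O"))
    stop("oxygen atoms must be filtered out before categorisation")
  if (any(!element %in% c("H", "C", "N")))
    stop("unsupported element(s): ",
         paste(setdiff(unique(element), c("H", "C", "N")), collapse = ", "))
  out <- character(n)
  out[element == "C"] <- "Cother"
  out[element == "H"] <- "Hother"
  out[element == "N"] <- "Nother"
  out[atom_name == "CA"] <- "Calpha"
  out[atom_name == "C"] <- "Ccarbonyl"
  out[atom_name %in% c("H", "HN")] <- "Hamide"
  out[atom_name == "N"] <- "Namide"
  out[atom_name == "CB"] <- "Cbeta"
  out
}

#' Exclude cap-group and oxygen rows from a shift table
#'
#' Shifts of the terminal cap groups and of oxygen atoms are uncommon
#' experimental observables and are dropped before sensitivity analysis; the
#' number of removed rows is reported as a message.
#'
#' @param shift_table canonical-schema shift data.frame.
#' @return Filtered data.frame.
#' @export
filter_atoms <- function(shift_table) {
  drop <- shift_table$element == "O" |
    shift_table$residue_name %in% .cap_resnames
  if (any(drop))
    message("filter_atoms: removed ", sum(drop),
            " cap/oxygen rows of ", nrow(shift_table))
  out <- shift_table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-atom sensitivity records for a whole shift table
#'
#' Splits a (filtered) canonical shift table by atom identity
#' (`residue_number`, `atom_name`), compares the stretched and globular
#' samples, and returns one record per atom including its category.
#'
#' @param shift_table canonical-schema shift data.frame for one method,
#'   containing both groups; pre-filter with [filter_atoms()].
#' @param threshold sensitivity threshold in sigma units.
#' @return data.frame of sensitivity records (one row per atom).
#' @export
compute_sensitivity <- function(shift_table, threshold = 3.29) {
  key <- paste(shift_table$residue_number, shift_table$atom_name, sep = "|")
  parts <- split(shift_table, key)
  rows <- lapply(parts, function(d) {
    s <- d$value_ppm[d$group == "stretched"]
    g <- d$value_ppm[d$group == "globular"]
    if (length(s) < 2 || length(g) < 2)
      stop("atom ", d$residue_number[1], "/", d$atom_name[1],
           " lacks two samples per group")
    rec <- sensitivity_sigma(s, g, threshold)
    cbind(data.frame(method = d$method[1],
                     residue_number = d$residue_number[1],
                     residue_name = d$residue_name[1],
                     atom_name = d$atom_name[1],
                     element = d$element[1],
                     category = categorize_atom(d$atom_name[1], d$element[1],
                                                d$residue_name[1])),
          rec)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$residue_number, out$atom_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-residue sensitivity
#'
#' Mode `"mean"` averages the sensitivities of the residue's backbone atoms
#' and CB (categories `Calpha`, `Ccarbonyl`, `Hamide`, `Namide`, `Cbeta`);
#' mode `"single:<ATOM>"` returns that named atom's sensitivity.
#'
#' @param records sensitivity records of one residue
#'   (rows of [compute_sensitivity()] output).
#' @param mode `"mean"` or e.g. `"single:CA"`.
#' @return Sensitivity value, or `NA` if no qualifying atom exists.
#' @export
residue_sensitivity <- function(records, mode = "mean") {
  if (identical(mode, "mean")) {
    keep <- records$category %in%
      c("Calpha", "Ccarbonyl", "Hamide", "Namide", "Cbeta")
    if (!any(keep)) return(NA_real_)
    return(mean(records$sensitivity[keep]))
  }
  if (startsWith(mode, "single:")) {
    at <- sub("^single:", "", mode)
    i <- which(records$atom_name == at)
    if (length(i) == 0) return(NA_real_)
    return(records$sensitivity[i[1]])
  }
  stop("unknown mode: ", mode)
}

#' Cross-method agreement matrix
#'
#' Joins per-method sensitivity flags by atom identity and counts, per atom,
#' how many methods call it sensitive.  Atoms a method did not compute count
#' as no vote (entry `NA`).
#'
#' @param per_method list of sensitivity-record data.frames (one per method,
#'   as returned by [compute_sensitivity()]), or a single combined data.frame
#'   with a `method` column.
#' @param vote_threshold minimum number of sensitive votes for an atom to be
#'   flagged (default 4, "at least four of nine").
#' @return List with `matrix` (logical atoms x methods, `NA` = not computed),
#'   `votes` (integer per atom) and `flagged` (data.frame of atoms with
#'   `votes >= vote_threshold`).
#' @export
agreement_matrix <- function(per_method, vote_threshold = 4) {
  if (is.data.frame(per_method))
    per_method <- split(per_method, per_method$method)
  methods <- names(per_method)
  if (is.null(methods) || any(methods == ""))
    methods <- paste0("method", seq_along(per_method))
  keyed <- lapply(per_method, function(d) {
    k <- paste(d$residue_number, d$atom_name, sep = "|")
    if (anyDuplicated(k)) stop("join error: duplicate atom identities")
    setNames(d$is_sensitive, k)
  })
  all_keys <- sort(unique(unlist(lapply(keyed, names))))
  m <- matrix(NA, nrow = length(all_keys), ncol = length(per_method),
              dimnames = list(all_keys, methods))
  for (j in seq_along(keyed)) m[names(keyed[[j]]), j] <- keyed[[j]]
  votes <- rowSums(m, na.rm = TRUE)
  parts <- strsplit(all_keys, "|", fixed = TRUE)
  atoms <- data.frame(residue_number = as.integer(vapply(parts, `[`, "", 1)),
                      atom_name = vapply(parts, `[`, "", 2),
                      votes = as.integer(votes),
                      flagged = votes >= vote_threshold)
  list(matrix = m, votes = setNames(as.integer(votes), all_keys),
       flagged = atoms[atoms$flagged, , drop = FALSE], table = atoms)
}
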