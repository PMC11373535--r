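# Shrake-Rupley per-atom solvent accessible surface area.

# van der Waals radii (Å); hydrogens get 1.10 so every atom has a defined
# per-atom SASA (needed as an ML feature for H shifts as well).
.vdw_radii <- c(H = 1.10, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

# Deterministic quasi-uniform sphere points (golden-spiral / Fibonacci grid).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent accessible surface area (Shrake-Rupley)
#'
#' Each atom's solvent-accessible sphere (van der Waals radius plus probe) is
#' sampled with a deterministic golden-spiral grid; points buried inside any
#' neighbour's accessible sphere are removed and the surviving fraction is
#' scaled to the sphere area \eqn{4\pi(r+p)^2}.  Waters are excluded from
#' both the evaluated atoms and the occluders.
#'
#' @param conf a `conformer`.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points quadrature points per atom (default 240).
#' @return Numeric vector of SASA values (Å^2), one per atom of the conformer
#'   (`NA` for water atoms).
#' @export
sasa_atoms <- function(conf, probe = 1.4, n_points = 240) {
  a <- conf$atoms
  idx <- which(!a$is_water)
  xyz <- coords(conf, idx)
  r <- .vdw_radii[a$element[idx]]
  if (any(is.na(r)))
    stop("no van der Waals radius for element(s): ",
         paste(unique(a$element[idx][is.na(r)]), collapse = ", "))
  r <- r + probe
  pts <- .sphere_points(n_points)
  n <- length(idx)
  out_sel <- numeric(n)
  # neighbour lists via a single squared-distance matrix (desk-scale systems)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * tcrossprod(xyz)
  rsum2 <- outer(r, r, `+`)^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < rsum2[i, ] & seq_len(n) != i)
    p <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- rowSums(sweep(p[free, , drop = FALSE], 2, xyz[j, ])^2)
      free[free] <- dj2 > r[j]^2
    }
    out_sel[i] <- 4 * pi * r[i]^2 * sum(free) / n_points
  }
  out <- rep(NA_real_, nrow(a))
  out[idx] <- out_sel
  out
}
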