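# Grid-based molecular interaction fields: steric (Lennard-Jones 6-12) and
# electrostatic (Coulomb with distance-dependent dielectric) probe energies
# on a rectangular lattice around the aligned molecules.

# van der Waals radius (Angstrom) and well depth (kcal/mol) per element,
# Tripos-like values; the probe is an sp3 carbon with charge +1
VDW_PARAMS <- data.frame(
  element = c("C", "H", "CL", "O", "S", "N"),
  r = c(1.70, 1.50, 1.75, 1.52, 1.80, 1.55),
  eps = c(0.107, 0.042, 0.314, 0.116, 0.314, 0.095)
)
PROBE <- list(r = 1.70, eps = 0.107, charge = 1.0)

#' Rectangular field grid around a set of aligned conformers
#'
#' @param conformers list of \code{conformer3d} objects (aligned).
#' @param spacing grid spacing in Angstrom (default 2.0).
#' @param margin margin beyond the union of atoms in Angstrom (default 4.0).
#' @return object of class \code{grid_spec}: \code{origin}, \code{spacing},
#'   \code{counts}, and the matrix of grid point coordinates.
#' @export
grid_spec <- function(conformers, spacing = 2.0, margin = 4.0) {
  stopifnot(spacing > 0, margin >= 0)
  xyz <- do.call(rbind, lapply(conformers, function(c) c$xyz))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  counts <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  axes <- lapply(1:3, function(k) lo[k] + spacing * (seq_len(counts[k]) - 1L))
  pts <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
  colnames(pts) <- c("x", "y", "z")
  structure(list(origin = lo, spacing = spacing, counts = counts, points = pts),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid: %d x %d x %d points, %.1f A spacing\n",
              x$counts[1], x$counts[2], x$counts[3], x$spacing))
  invisible(x)
}

#' Steric and electrostatic fields of one conformer on a grid
#'
#' Steric energy is the summed Lennard-Jones 6-12 probe--atom interaction;
#' electrostatic energy is \code{332.0 * q_atom * q_probe / (eps * r)} with
#' the distance-dependent dielectric \code{eps = r}. Both are truncated to
#' \code{+/-cutoff} kcal/mol, so a probe on top of an atom is finite by
#' construction. Points whose steric value hits the cutoff are flagged
#' (\code{inside}): at the matrix level their electrostatic values are
#' replaced by the column mean over molecules that do not bury the point
#' (see [build_field_matrix()]).
#'
#' @param conf aligned \code{conformer3d}.
#' @param grid \code{grid_spec}.
#' @param probe probe parameters: list with \code{r}, \code{eps} (sp3
#'   carbon by default) and \code{charge} (+1).
#' @param cutoff truncation in kcal/mol (default 30).
#' @return list with \code{steric}, \code{electrostatic} (kcal/mol per grid
#'   point) and logical \code{inside}.
#' @export
compute_fields <- function(conf, grid, probe = PROBE, cutoff = 30) {
  pts <- grid$points
  n_pts <- nrow(pts)
  steric <- numeric(n_pts)
  elec <- numeric(n_pts)
  par <- VDW_PARAMS[match(conf$element, VDW_PARAMS$element), ]
  if (anyNA(par$r)) stop("no vdW parameters for element ",
                         paste(unique(conf$element[is.na(par$r)]), collapse = ","),
                         call. = FALSE)
  for (i in seq_along(conf$element)) {
    d2 <- (pts[, 1] - conf$xyz[i, 1])^2 + (pts[, 2] - conf$xyz[i, 2])^2 +
          (pts[, 3] - conf$xyz[i, 3])^2
    d2 <- pmax(d2, 1e-6)
    rmin <- par$r[i] + probe$r
    epsij <- sqrt(par$eps[i] * probe$eps)
    s6 <- (rmin^2 / d2)^3
    steric <- steric + epsij * (s6^2 - 2 * s6)
    elec <- elec + 332.0 * conf$charge[i] * probe$charge / d2  # 1/(eps*r), eps = r
  }
  steric <- pmin(pmax(steric, -cutoff), cutoff)
  elec <- pmin(pmax(elec, -cutoff), cutoff)
  list(steric = steric, electrostatic = elec, inside = steric >= cutoff)
}

#' Field-descriptor matrix for a set of aligned conformers
#'
#' Stacks each molecule's steric and electrostatic fields into one row per
#' molecule (steric block first). Electrostatic values at points where a
#' molecule's steric energy hits the truncation cutoff carry no information
#' and are replaced by the column mean over the remaining molecules (the
#' column mean of zero-information columns is used as-is).
#'
#' @param conformers list of aligned \code{conformer3d} objects.
#' @param grid \code{grid_spec}; default built from the conformers.
#' @param ... passed to [compute_fields()].
#' @return numeric matrix, molecules x (2 * grid points), with attribute
#'   \code{"block"} marking steric/electrostatic columns and \code{"grid"}.
#' @export
build_field_matrix <- function(conformers, grid = grid_spec(conformers), ...) {
  fl <- lapply(conformers, compute_fields, grid = grid, ...)
  S <- do.call(rbind, lapply(fl, `[[`, "steric"))
  E <- do.call(rbind, lapply(fl, `[[`, "electrostatic"))
  IN <- do.call(rbind, lapply(fl, `[[`, "inside"))
  for (j in seq_len(ncol(E))) {
    if (any(IN[, j]) && !all(IN[, j]))
      E[IN[, j], j] <- mean(E[!IN[, j], j])
  }
  X <- cbind(S, E)
  attr(X, "block") <- rep(c("steric", "electrostatic"), each = ncol(S))
  attr(X, "grid") <- grid
  rownames(X) <- names(conformers)
  X
}
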