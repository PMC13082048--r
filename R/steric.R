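# Steric collision scanning: solvent-excluded-surface (SES) volumes on voxel
# grids and the stepwise walk of a structure along the DNA helical axis.

# Bondi van der Waals radii (A)
.bondi_radii <- c(H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80,
                  S = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
                  I = 1.98, ZN = 1.39, MG = 1.73, K = 2.75, "NA" = 2.27)

#' Surface/grid parameters for SES volume computation
#'
#' The SES is approximated on a boolean voxel grid by morphological closing
#' with the probe sphere: atom spheres are dilated by the probe radius, then
#' the mask is eroded by the probe. Volumes converge to the analytic SES
#' volume as the grid spacing shrinks.
#'
#' @param probe_radius probe sphere radius, Angstrom (water: 1.4).
#' @param grid_spacing voxel edge length, Angstrom.
#' @param radii_set atomic radii set; only `"bondi"` is provided.
#' @param include_hydrogens include hydrogens in the surface?
#' @return Object of class `surface_params`.
#' @export
surface_params <- function(probe_radius = 1.4, grid_spacing = 0.6,
                           radii_set = "bondi", include_hydrogens = FALSE) {
  if (probe_radius <= 0) .stopf("probe_radius must be > 0")
  if (grid_spacing <= 0) .stopf("grid_spacing must be > 0")
  radii_set <- match.arg(radii_set, "bondi")
  structure(list(probe_radius = probe_radius, grid_spacing = grid_spacing,
                 radii_set = radii_set,
                 include_hydrogens = include_hydrogens),
            class = "surface_params")
}

.atom_radii <- function(atoms, params) {
  r <- .bondi_radii[atoms$element]
  if (anyNA(r)) {
    .warnf("no Bondi radius for element(s) %s; using 1.70 A",
           paste(unique(atoms$element[is.na(r)]), collapse = ", "))
    r[is.na(r)] <- 1.70
  }
  unname(r)
}

.surface_atoms <- function(model, params) {
  a <- model$atoms
  if (!params$include_hydrogens) a <- a[!a$hydrogen, , drop = FALSE]
  if (nrow(a) == 0L) .stopf("no non-hydrogen atoms in model '%s'",
                            model$identifier)
  a
}

# grid covering the given coordinate sets, origin snapped to the fixed
# lattice k * spacing so grids over different subsets are commensurate
.make_grid <- function(coord_list, radii_max, params) {
  h <- params$grid_spacing
  pad <- radii_max + 2 * params$probe_radius + 2 * h
  lo <- apply(do.call(rbind, coord_list), 2, min) - pad
  hi <- apply(do.call(rbind, coord_list), 2, max) + pad
  origin <- floor(lo / h) * h
  dims <- as.integer(ceiling((hi - origin) / h)) + 1L
  list(origin = origin, dims = dims, spacing = h)
}

.ses_count <- function(atoms, radii, params, grid) {
  cpp_ses_voxel_count(as.matrix(atoms[, c("x", "y", "z")]), radii,
                      params$probe_radius, grid$spacing,
                      grid$origin, grid$dims)
}

#' Solvent-excluded-surface volume of a structure
#'
#' @param model a [structure_model()].
#' @param params a [surface_params()].
#' @return Volume in cubic Angstrom.
#' @export
molecular_volume <- function(model, params = surface_params()) {
  a <- .surface_atoms(model, params)
  r <- .atom_radii(a, params)
  grid <- .make_grid(list(.xyz(a)), max(r), params)
  .ses_count(a, r, params, grid) * params$grid_spacing^3
}

#' SES overlap volume of two structures
#'
#' `V(a) + V(b) - V(a union b)`, all three volumes computed on one shared
#' grid (identical origin and spacing), so the result is symmetric in the
#' arguments and zero for disjoint bodies up to one voxel layer.
#'
#' @param a,b [structure_model()]s.
#' @param params a [surface_params()].
#' @return Overlap volume in cubic Angstrom.
#' @export
overlap_volume <- function(a, b, params = surface_params()) {
  aa <- .surface_atoms(a, params); ab <- .surface_atoms(b, params)
  ra <- .atom_radii(aa, params); rb <- .atom_radii(ab, params)
  grid <- .make_grid(list(.xyz(aa), .xyz(ab)), max(ra, rb), params)
  va <- .ses_count(aa, ra, params, grid)
  vb <- .ses_count(ab, rb, params, grid)
  vu <- cpp_ses_voxel_count(rbind(as.matrix(aa[, c("x", "y", "z")]),
                                  as.matrix(ab[, c("x", "y", "z")])),
                            c(ra, rb), params$probe_radius, grid$spacing,
                            grid$origin, grid$dims)
  (va + vb - vu) * params$grid_spacing^3
}

.dna_backbone_atoms <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'")

# ordered backbone coordinates of the window residues, shifted by n_steps
.window_backbone <- function(dna, window, n_steps) {
  a <- dna$atoms
  out <- list()
  for (i in seq_len(nrow(window$parts))) {
    part <- window$parts[i, ]
    if (is.na(part$start))
      .stopf("step window must use explicit residue ranges")
    for (r in seq(part$start, part$end)) {
      at <- a[a$chain == part$chain & a$resno == (r + n_steps) &
                a$elety %in% .dna_backbone_atoms, , drop = FALSE]
      if (nrow(at) == 0L)
        .stopf("shifted window out of range: no backbone atoms at %s/%d",
               part$chain, r + n_steps)
      at <- at[match(.dna_backbone_atoms, at$elety), , drop = FALSE]
      at <- at[!is.na(at$resno), , drop = FALSE]
      out[[length(out) + 1L]] <- at
    }
  }
  .xyz(do.call(rbind, out))
}

#' Helical step transform from a DNA window
#'
#' The rigid transform superposing the backbone atoms (P, O5', C5', C4',
#' C3', O3') of the window residues onto the residues `n_steps` further
#' downstream (residue i maps to i + n_steps by position — a homopolymer
#' assumption). On ideal B-DNA this is the helical screw: one step is a
#' 3.4 A rise and ~34.3 deg twist about the helix axis.
#'
#' @param dna [structure_model()] of the duplex.
#' @param window [residue_selection()] of the window residues.
#' @param n_steps integer number of steps downstream (0 gives the identity).
#' @return A [rigid_transform()].
#' @export
step_transform <- function(dna, window, n_steps) {
  n_steps <- as.integer(n_steps)
  if (n_steps == 0L) return(rigid_transform())
  from <- .window_backbone(dna, window, 0L)
  to <- .window_backbone(dna, window, n_steps)
  if (nrow(from) != nrow(to))
    .stopf("window and shifted window have different backbone atom counts")
  kabsch_superpose(from, to)
}

#' Steric collision scan along the DNA axis
#'
#' Places `mobile` at each nucleotide position along the helical axis (via
#' the cumulative [step_transform()] from its current position) and computes
#' the SES overlap volume against the fixed obstacle. Overlaps are rescaled
#' so the value at `reference_position` is zero.
#'
#' @param mobile moving [structure_model()] (e.g. the polymerase), given at
#'   position `mobile_position`.
#' @param fixed stationary [structure_model()] (e.g. the roadblock).
#' @param dna [structure_model()] of the DNA used to derive step transforms.
#' @param window [residue_selection()] step window on `dna`.
#' @param positions integer vector of nt positions to scan.
#' @param params a [surface_params()].
#' @param reference_position nt position whose overlap defines zero
#'   (default 39); must be among `positions`.
#' @param mobile_position nt position of `mobile` as supplied (default
#'   `min(positions)`).
#' @return Object of class `collision_scan`: data.frame `table` with
#'   position, raw_overlap, rescaled_overlap (A^3).
#' @export
scan_collision <- function(mobile, fixed, dna, window, positions,
                           params = surface_params(),
                           reference_position = 39,
                           mobile_position = min(positions)) {
  positions <- as.integer(positions)
  if (!reference_position %in% positions)
    .stopf("reference position %d is not among the scanned positions",
           reference_position)
  raw <- numeric(length(positions))
  for (i in seq_along(positions)) {
    tr <- step_transform(dna, window, positions[i] - mobile_position)
    raw[i] <- overlap_volume(apply_transform(mobile, tr), fixed, params)
  }
  rescaled <- raw - raw[match(reference_position, positions)]
  structure(list(table = data.frame(position = positions,
                                    raw_overlap = raw,
                                    rescaled_overlap = rescaled),
                 reference_position = reference_position,
                 params = params),
            class = "collision_scan")
}

#' @export
print.collision_scan <- function(x, ...) {
  cat(sprintf("collision_scan: %d positions, reference %d nt\n",
              nrow(x$table), x$reference_position))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
plot.collision_scan <- function(x, ...) {
  plot(x$table$position, x$table$rescaled_overlap, type = "b",
       xlab = "RNAP 3' position (nt)",
       ylab = expression("rescaled SES overlap (" * ring(A)^3 * ")"), ...)
  invisible(x)
}
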