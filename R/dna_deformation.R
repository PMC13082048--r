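# Downstream-DNA displacement in a principal-component reference frame.
#
# The frame is built once from the twelve downstream-nucleotide centers of
# mass of the reference elongation complex; query structures are core-aligned
# to the reference and the per-nucleotide center-of-mass displacement is
# projected onto PC1/PC2 of that frame.

#' Build the PCA reference frame over twelve downstream nucleotides
#'
#' Performs an eigendecomposition of the 3x3 population covariance (1/N) of
#' the twelve nucleotide centers of mass. Axis signs are fixed
#' deterministically: PC1 points downstream (positive dot product with the
#' vector from the first to the twelfth center of mass); PC3 is oriented
#' towards `orient_point` (by default the centroid of all reference atoms,
#' i.e. the polymerase body); PC2 completes the right-handed frame
#' (PC2 = PC3 x PC1).
#'
#' @param reference reference [structure_model()].
#' @param nucleotides [residue_selection()] resolving to exactly 12 residues.
#' @param mass_weighted passed to [residue_centers_of_mass()].
#' @param orient_point 3-vector used to orient PC3; default the centroid of
#'   all atoms of `reference`.
#' @return Object of class `dna_frame`: `origin`, unit axes `pc1`, `pc2`,
#'   `pc3`, `reference_coms` (12 x 3), `eigenvalues` (descending, A^2).
#' @export
build_dna_frame <- function(reference, nucleotides, mass_weighted = TRUE,
                            orient_point = NULL) {
  coms <- residue_centers_of_mass(reference, nucleotides,
                                  mass_weighted = mass_weighted)
  if (nrow(coms) != 12L)
    .stopf("nucleotide selection resolves to %d residues, need exactly 12",
           nrow(coms))
  X <- .xyz(coms)
  origin <- colMeans(X)
  C <- sweep(X, 2, origin)
  cov3 <- crossprod(C) / nrow(C)      # population covariance
  ei <- eigen(cov3, symmetric = TRUE) # eigenvalues descending
  if (ei$values[2] < 1e-9 * max(ei$values[1], 1e-300))
    .stopf("degenerate covariance: centers of mass are collinear, PC2 undefined")
  pc1 <- ei$vectors[, 1]; pc3 <- ei$vectors[, 3]
  if (sum(pc1 * (X[12, ] - X[1, ])) < 0) pc1 <- -pc1
  if (is.null(orient_point))
    orient_point <- colMeans(.xyz(reference$atoms))
  if (sum(pc3 * (orient_point - origin)) < 0) pc3 <- -pc3
  pc2 <- .cross3(pc3, pc1)
  pc2 <- pc2 / sqrt(sum(pc2^2))
  pc3 <- .cross3(pc1, pc2)            # exact right-handed orthonormal triad
  structure(list(origin = as.numeric(origin), pc1 = as.numeric(pc1),
                 pc2 = as.numeric(pc2), pc3 = as.numeric(pc3),
                 reference_coms = coms, eigenvalues = ei$values),
            class = "dna_frame")
}

#' @export
print.dna_frame <- function(x, ...) {
  cat(sprintf(
    "dna_frame: origin (%.2f, %.2f, %.2f), eigenvalues %.2f/%.2f/%.2f A^2\n",
    x$origin[1], x$origin[2], x$origin[3],
    x$eigenvalues[1], x$eigenvalues[2], x$eigenvalues[3]))
  invisible(x)
}

#' Project downstream-DNA displacement of a query onto PC1/PC2
#'
#' The query is aligned to the reference over paired core CA atoms (as in
#' [compute_swivel()]); the displacement of each nucleotide center of mass
#' relative to the frame's reference centers is projected onto PC1 and PC2,
#' and the twelve signed projections are averaged. The result is invariant
#' to any prior global rigid motion of the query.
#'
#' @param query,reference [structure_model()]s.
#' @param frame a `dna_frame` from [build_dna_frame()] on `reference`.
#' @param core core [residue_selection()] used for the superposition.
#' @param nucleotides [residue_selection()] of the same 12 nucleotides in the
#'   query.
#' @param mass_weighted passed to [residue_centers_of_mass()].
#' @return Object of class `displacement_result`: `mean_pc1`, `mean_pc2`
#'   (Angstrom), `per_nucleotide` (12 rows: chain, resno, pc1, pc2),
#'   `core_rmsd`.
#' @export
project_displacement <- function(query, reference, frame, core, nucleotides,
                                 mass_weighted = TRUE) {
  stopifnot(inherits(frame, "dna_frame"))
  pairing <- .paired_calpha(query, reference, core)
  .check_coverage(pairing, "core")
  t_core <- kabsch_superpose(pairing$q, pairing$r)

  qcoms <- residue_centers_of_mass(query, nucleotides,
                                   mass_weighted = mass_weighted)
  ref <- frame$reference_coms
  key_q <- paste(qcoms$chain, qcoms$resno)
  key_r <- paste(ref$chain, ref$resno)
  miss <- setdiff(key_r, key_q)
  if (length(miss))
    .stopf("query lacks nucleotide(s): %s", paste(miss, collapse = ", "))
  qcoms <- qcoms[match(key_r, key_q), ]
  Q <- apply_transform(.xyz(qcoms), t_core)
  D <- Q - .xyz(ref)
  p1 <- as.numeric(D %*% frame$pc1)
  p2 <- as.numeric(D %*% frame$pc2)
  per <- data.frame(chain = ref$chain, resno = ref$resno, pc1 = p1, pc2 = p2)
  structure(list(mean_pc1 = mean(p1), mean_pc2 = mean(p2),
                 per_nucleotide = per, core_rmsd = t_core$rmsd),
            class = "displacement_result")
}

#' @export
print.displacement_result <- function(x, ...) {
  cat(sprintf(
    "displacement_result: mean PC1 %.4f A, mean PC2 %.4f A (core rmsd %.3f A)\n",
    x$mean_pc1, x$mean_pc2, x$core_rmsd))
  invisible(x)
}

#' Linear fit of displacement against swivel angle
#'
#' Ordinary least squares of displacement on angle plus the Pearson
#' correlation, quantifying the coupling between DNA deformation and
#' swivel-module rotation.
#'
#' @param angle swivel angles (degrees).
#' @param displacement displacements (Angstrom).
#' @return List with `slope`, `intercept`, `r`, `n`.
#' @export
coupling_fit <- function(angle, displacement) {
  stopifnot(length(angle) == length(displacement))
  if (length(angle) < 3L) .stopf("need at least 3 points")
  if (var(angle) == 0) .stopf("zero variance in angle")
  fit <- lm(displacement ~ angle)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = cor(angle, displacement), n = length(angle))
}
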