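# Synthetic inputs with known ground truth: mock two-module polymerases,
# ideal B-form DNA, collision scenes, paired reads, decay curves and
# titration tables. Every generator is a pure function of its seed and
# parameters; RNG state of the caller is preserved.

.with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  force(expr)
}

# smooth pseudo-CA space curve: cumulative 3.8-A steps whose directions drift
# slowly (moving-average of Gaussian increments), started at a random point
.smooth_curve <- function(n, origin, step = 3.8) {
  dirs <- matrix(rnorm(3 * (n + 10)), ncol = 3)
  w <- 11
  sm <- apply(dirs, 2, function(col) stats::filter(col, rep(1 / w, w),
                                                   sides = 2))
  sm <- sm[!apply(is.na(sm), 1, any), , drop = FALSE][seq_len(n - 1), ,
                                                      drop = FALSE]
  sm <- sm / sqrt(rowSums(sm^2))
  rbind(origin, origin + apply(sm * step, 2, cumsum))
}

#' Default residue layout of the mock polymerase
#'
#' Chain ranges covering the default core/swivel module definition under the
#' canonical chain labels.
#'
#' @return Named list chain -> c(start, end).
#' @export
mock_polymerase_layout <- function() {
  m <- default_chain_map()
  setNames(list(c(1, 300), c(1, 300), c(1, 1341), c(1, 1375), c(1, 91)),
           unname(m[c("alpha1", "alpha2", "beta", "betap", "omega")]))
}

#' Generate a mock two-module polymerase pair with a known swivel rotation
#'
#' The reference carries one CA pseudo-atom per residue on a smooth random
#' space curve per chain; the query equals the reference with the
#' swivel-module residues rotated by `swivel_angle` about the given axis
#' (anchored at the swivel-module centroid by default), plus optional
#' Gaussian coordinate noise on all query atoms. CA-only models suffice
#' because the swivel and displacement measurements touch only CA positions
#' and centers of mass.
#'
#' @param seed integer seed (bit-reproducible output).
#' @param swivel_angle true rotation, degrees.
#' @param swivel_axis rotation axis (normalized internally).
#' @param axis_point anchor point; default the swivel-module CA centroid.
#' @param coordinate_noise Gaussian noise SD per coordinate, Angstrom.
#' @param layout chain layout as from [mock_polymerase_layout()].
#' @param module_def the [module_definition()] whose swivel selection is
#'   rotated.
#' @return List with `reference`, `query` ([structure_model()]s) and
#'   `truth` (angle, axis, point).
#' @export
make_mock_polymerase <- function(seed = 1, swivel_angle = 3,
                                 swivel_axis = c(0, 0, 1),
                                 axis_point = NULL, coordinate_noise = 0,
                                 layout = mock_polymerase_layout(),
                                 module_def = default_module_definition()) {
  .with_seed(seed, {
    atoms <- list()
    for (ch in names(layout)) {
      rng <- layout[[ch]]
      n <- rng[2] - rng[1] + 1L
      origin <- runif(3, -40, 40)
      xyz <- .smooth_curve(n, origin)
      atoms[[ch]] <- data.frame(chain = ch, resno = seq(rng[1], rng[2]),
                                resid = "ALA", elety = "CA", element = "C",
                                x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                stringsAsFactors = FALSE)
    }
    at <- do.call(rbind, atoms)
    reference <- structure_model(at, "mock-reference")

    sw <- module_def$swivel
    in_swivel <- mapply(function(ch, r) selection_contains(sw, ch, r),
                        at$chain, at$resno)
    if (is.null(axis_point))
      axis_point <- colMeans(.xyz(at[in_swivel, , drop = FALSE]))
    axis <- swivel_axis / sqrt(sum(swivel_axis^2))
    R <- axis_angle_to_rotation(axis, swivel_angle)
    qat <- at
    xyzs <- .xyz(at[in_swivel, , drop = FALSE])
    rotated <- sweep(tcrossprod(sweep(xyzs, 2, axis_point), R), 2,
                     axis_point, "+")
    qat[in_swivel, c("x", "y", "z")] <- rotated
    if (coordinate_noise > 0)
      qat[, c("x", "y", "z")] <- .xyz(qat) +
        matrix(rnorm(3 * nrow(qat), sd = coordinate_noise), ncol = 3)
    query <- structure_model(qat, "mock-query")
    list(reference = reference, query = query,
         truth = list(angle = swivel_angle, axis = axis,
                      point = as.numeric(axis_point)))
  })
}

# local backbone template of one nucleotide (radius A, phase deg, z-offset A)
# for the six standard backbone atoms; idealized, bases omitted
.bdna_backbone_template <- data.frame(
  elety = c("P", "O5'", "C5'", "C4'", "C3'", "O3'"),
  radius = c(8.9, 8.8, 9.4, 9.1, 8.6, 8.9),
  phase = c(-5.2, -1.0, 3.1, 7.5, 10.1, 14.3),
  zoff = c(2.0, 1.4, 1.0, 0.3, -0.6, -1.2),
  stringsAsFactors = FALSE)

#' Generate an idealized B-form DNA duplex (backbone only)
#'
#' Two antiparallel strands of backbone pseudo-atoms (P, O5', C5', C4', C3',
#' O3') on a helix with the given per-base-pair rise and twist; the default
#' twist 360/10.5 deg/bp reproduces the ~10.5-bp helical pitch of B-DNA.
#' Residues are numbered 1..n_bp on both strands (chains "T" and "N"), base
#' pair i on both strands at the same helical register, so residue i+1 is
#' the helical screw image of residue i on each strand.
#'
#' @param n_bp number of base pairs (>= 2).
#' @param rise helical rise per bp, Angstrom (default 3.4).
#' @param twist helical twist per bp, degrees (default 360/10.5).
#' @return A [structure_model()]; the helix axis is z through the origin.
#' @export
make_bdna <- function(n_bp, rise = 3.4, twist = 360 / 10.5) {
  if (n_bp < 2) .stopf("need at least 2 base pairs")
  tmpl <- .bdna_backbone_template
  strand <- function(chain, mirror) {
    rows <- list()
    for (i in seq_len(n_bp)) {
      th <- (i - 1) * twist * pi / 180
      # strand 2: reflect the local template (z and phase negated) and offset
      # its phase by the groove angle so the strands are antiparallel
      ph <- tmpl$phase * pi / 180
      zo <- tmpl$zoff
      if (mirror) { ph <- -ph + 154 * pi / 180; zo <- -zo }
      rows[[i]] <- data.frame(
        chain = chain, resno = i, resid = if (mirror) "DC" else "DG",
        elety = tmpl$elety, element = substr(tmpl$elety, 1, 1),
        x = tmpl$radius * cos(th + ph),
        y = tmpl$radius * sin(th + ph),
        z = (i - 1) * rise + zo, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  structure_model(rbind(strand("T", FALSE), strand("N", TRUE)),
                  sprintf("bdna-%dbp", n_bp))
}

# deterministic pseudo-atom blob: carbon atoms on a 2-A lattice (through the
# center) inside a sphere; identical for identical radius
.blob_atoms <- function(center, radius, chain) {
  r0 <- 2 * floor(radius / 2)
  g <- seq(-r0, r0, by = 2)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
  data.frame(chain = chain, resno = seq_len(nrow(pts)), resid = "BLB",
             elety = "C", element = "C",
             x = pts[, 1] + center[1], y = pts[, 2] + center[2],
             z = pts[, 3] + center[3], stringsAsFactors = FALSE)
}

#' Generate a synthetic collision scene on an ideal helix
#'
#' Two pseudo-atom blobs anchored on the helix axis at the given base-pair
#' positions, plus the helix itself for deriving step transforms. Because
#' both blobs are centered on the axis, walking the mobile blob downstream
#' moves it towards the fixed blob by exactly `rise` per step, so the
#' ground-truth first-contact position follows from the blob radii.
#'
#' @param seed integer seed (kept for interface symmetry; the scene is
#'   deterministic).
#' @param helix a [make_bdna()] specification: list with `n_bp` and
#'   optionally `rise`, `twist`.
#' @param mobile_radius,fixed_radius blob radii, Angstrom.
#' @param fixed_position bp position of the fixed blob.
#' @param mobile_position bp position of the mobile blob.
#' @return List with `mobile`, `fixed`, `dna` ([structure_model()]s) and
#'   `truth` (axis positions, contact distance).
#' @export
make_collision_scene <- function(seed = 1, helix = list(n_bp = 60),
                                 mobile_radius = 5, fixed_radius = 5,
                                 fixed_position = 40, mobile_position = 1) {
  rise <- helix$rise %||% 3.4
  twist <- helix$twist %||% (360 / 10.5)
  dna <- make_bdna(helix$n_bp, rise = rise, twist = twist)
  if (fixed_position > helix$n_bp || mobile_position > helix$n_bp)
    .stopf("blob position outside the helix")
  zpos <- function(p) c(0, 0, (p - 1) * rise)
  mobile <- structure_model(.blob_atoms(zpos(mobile_position), mobile_radius,
                                        "M"), "mobile-blob")
  fixed <- structure_model(.blob_atoms(zpos(fixed_position), fixed_radius,
                                       "F"), "fixed-blob")
  # axial extent of a lattice blob: outermost on-axis atom + carbon vdW
  extent <- function(r) 2 * floor(r / 2) + 1.7
  list(mobile = mobile, fixed = fixed, dna = dna,
       truth = list(mobile_position = mobile_position,
                    fixed_position = fixed_position, rise = rise,
                    contact_distance = extent(mobile_radius) +
                      extent(fixed_radius)))
}

.revcomp <- function(s) chartr("ACGT", "TGCA",
                               paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""))

.mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "")[[1]]
  hit <- runif(length(ch)) < rate
  if (any(hit)) {
    alt <- c("A", "C", "G", "T")
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(alt, b), 1),
                      character(1))
  }
  paste(ch, collapse = "")
}

#' Simulate paired 5'/3' reads from a template with a truth table
#'
#' Reads are sampled from the forward or reverse RNA: 5' ends at the TSS
#' plus a small jitter, 3' ends from the end model (uniform over a range,
#' optionally piled at the hairpin boundary), substitution errors at the
#' given per-base rate.
#'
#' @param template a [template_spec()].
#' @param n number of read pairs.
#' @param end_model list: `type` `"uniform"` (fields `min`, `max`) or
#'   `"hairpin"` (`prob` of a 3' end at the hairpin boundary, else uniform
#'   over `min`..`max`).
#' @param error_rate per-base substitution rate in \[0, 0.2\].
#' @param seed integer seed.
#' @param read_length maximal read length (nt).
#' @param tss_jitter maximal 5'-start jitter (nt, uniform 0..jitter).
#' @param forward_fraction probability a pair is forward-oriented.
#' @return List with `five_reads`, `three_reads` (character vectors) and
#'   `truth` data.frame (orientation, five_prime, three_prime).
#' @export
simulate_reads <- function(template, n, end_model = list(type = "uniform"),
                           error_rate = 0, seed = 1, read_length = 40,
                           tss_jitter = 0, forward_fraction = 0.5) {
  stopifnot(inherits(template, "template_spec"))
  if (error_rate < 0 || error_rate > 0.2)
    .stopf("error rate must be in [0, 0.2]")
  .with_seed(seed, {
    five <- character(n); three <- character(n)
    orient <- character(n); fp <- integer(n); tp <- integer(n)
    for (i in seq_len(n)) {
      is_fwd <- runif(1) < forward_fraction
      rna <- if (is_fwd) template$forward_rna else template$reverse_rna
      tss <- if (is_fwd) template$forward_tss else template$reverse_tss
      L <- nchar(rna)
      start <- tss + if (tss_jitter > 0) sample(0:tss_jitter, 1) else 0
      emin <- end_model$min %||% min(start + template$min_end_separation + 5,
                                     L)
      emax <- end_model$max %||% L
      end <- if (identical(end_model$type, "hairpin") &&
                 runif(1) < (end_model$prob %||% 0.8)) {
        bnd <- end_model$boundary %||% template$hairpin_region[2]
        if (is.null(bnd)) .stopf("hairpin end model needs a boundary")
        bnd
      } else sample(seq(emin, emax), 1)
      end <- min(max(end, start + 1), L)
      five[i] <- .mutate_seq(substr(rna, start,
                                    min(start + read_length - 1, end)),
                             error_rate)
      three[i] <- .mutate_seq(substr(rna, max(end - read_length + 1, start),
                                     end), error_rate)
      orient[i] <- if (is_fwd) "forward" else "reverse"
      fp[i] <- as.integer(start); tp[i] <- as.integer(end)
    }
    list(five_reads = five, three_reads = three,
         truth = data.frame(read_id = sprintf("read%05d", seq_len(n)),
                            orientation = orient, five_prime = fp,
                            three_prime = tp, stringsAsFactors = FALSE))
  })
}

#' Simulate a bi-exponential complex-decay curve
#'
#' @param a1,k1,a2,k2 decay parameters (amplitudes sum <= 1, rates min^-1,
#'   k1 >= k2 >= 0).
#' @param timepoints sampling times, minutes.
#' @param noise_sd Gaussian noise SD on the fraction scale.
#' @param seed integer seed.
#' @param no_ntp_control,pk_control control signal levels mapping fractions
#'   back to raw signal units.
#' @return List with `timepoints`, `signal`, `no_ntp_control`, `pk_control`,
#'   `fraction_true`.
#' @export
simulate_decay <- function(a1, k1, a2, k2, timepoints, noise_sd = 0,
                           seed = 1, no_ntp_control = 100, pk_control = 5) {
  if (a1 < 0 || a2 < 0 || k1 < k2 || k2 < 0)
    .stopf("need a1, a2 >= 0 and k1 >= k2 >= 0")
  .with_seed(seed, {
    f <- .biexp(timepoints, a1, k1, a2, k2)
    fn <- f + if (noise_sd > 0) rnorm(length(timepoints), sd = noise_sd)
    else 0
    list(timepoints = timepoints,
         signal = pk_control + fn * (no_ntp_control - pk_control),
         no_ntp_control = no_ntp_control, pk_control = pk_control,
         fraction_true = f)
  })
}

#' Simulate a salt-titration gel table with known E_RB values
#'
#' Lane intensities are constructed so that [rescale_titration()] recovers
#' the supplied per-salt E_RB values exactly in the absence of noise.
#'
#' @param true_erb_by_salt named numeric: names are salt concentrations
#'   (mM), values the true E_RB (anchor salt must map to 1 by convention of
#'   the assay, but any positive anchor value is handled).
#' @param intensity_scale scaffold band intensity (arbitrary units).
#' @param noise_sd relative Gaussian noise on band intensities (fraction of
#'   the band value).
#' @param seed integer seed.
#' @param anchor_salt anchor concentration, mM.
#' @param anchor_ratio raw roadblock/scaffold ratio at the anchor.
#' @return data.frame of lanes (salt_mM, roadblock, scaffold, background)
#'   suitable for [rescale_titration()].
#' @export
simulate_titration <- function(true_erb_by_salt, intensity_scale = 1000,
                               noise_sd = 0, seed = 1, anchor_salt = 50,
                               anchor_ratio = 0.8) {
  salts <- as.numeric(names(true_erb_by_salt))
  if (!anchor_salt %in% salts) .stopf("anchor salt missing from input map")
  .with_seed(seed, {
    bg <- 0.05 * intensity_scale
    scaffold <- rep(bg + intensity_scale, length(salts))
    roadblock <- bg + unname(true_erb_by_salt) * anchor_ratio *
      intensity_scale
    if (noise_sd > 0) {
      scaffold <- scaffold * (1 + rnorm(length(salts), sd = noise_sd))
      roadblock <- roadblock * (1 + rnorm(length(salts), sd = noise_sd))
    }
    data.frame(salt_mM = salts, roadblock = roadblock, scaffold = scaffold,
               background = bg)
  })
}
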