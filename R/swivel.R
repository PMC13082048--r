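# Swivel-angle measurement: rotation of the RNAP swivel module relative to a
# reference elongation complex after superposition of the structural cores.

#' Default canonical chain labels for bacterial RNAP subunits
#'
#' Deposited RNAP entries label the alpha/beta/beta'/omega chains
#' inconsistently; analyses here work in canonical labels which a chain map
#' translates to the labels of a concrete model.
#'
#' @return Named character vector (alpha1, alpha2, beta, betap, omega).
#' @export
default_chain_map <- function() {
  c(alpha1 = "A", alpha2 = "B", beta = "C", betap = "D", omega = "E")
}

#' Rigid-module definition (core + swivel selections)
#'
#' @param core,swivel [residue_selection()]s; must be disjoint.
#' @return Object of class `module_definition`.
#' @export
module_definition <- function(core, swivel) {
  stopifnot(inherits(core, "residue_selection"),
            inherits(swivel, "residue_selection"))
  # disjointness across the two selections, chain by chain
  for (ch in intersect(core$parts$chain, swivel$parts$chain)) {
    pc <- core$parts[core$parts$chain == ch, ]
    ps <- swivel$parts[swivel$parts$chain == ch, ]
    if (any(is.na(pc$start)) || any(is.na(ps$start)))
      .stopf("core and swivel selections both claim chain %s entirely", ch)
    for (i in seq_len(nrow(pc)))
      for (j in seq_len(nrow(ps)))
        if (pc$start[i] <= ps$end[j] && ps$start[j] <= pc$end[i])
          .stopf("core and swivel overlap in chain %s (%d-%d vs %d-%d)",
                 ch, pc$start[i], pc$end[i], ps$start[j], ps$end[j])
  }
  structure(list(core = core, swivel = swivel), class = "module_definition")
}

#' Default RNAP core and swivel module definition
#'
#' Core: all alpha-subunit residues, beta 3-27/142-152/445-455/520-713/786-828,
#' beta' 343-368/421-524/530-552/569-701/720-786, all omega residues. Swivel:
#' beta 1241-1341, beta' 1-342/369-420/787-930/1135-1375. The beta' core
#' segment starts at 421 (not 412) so the core stays disjoint from the
#' 369-420 swivel segment; see the methods vignette for the rationale.
#'
#' @param chain_map named chain map as from [default_chain_map()].
#' @return A [module_definition()].
#' @export
default_module_definition <- function(chain_map = default_chain_map()) {
  need <- c("alpha1", "alpha2", "beta", "betap", "omega")
  miss <- setdiff(need, names(chain_map))
  if (length(miss)) .stopf("chain map lacks: %s", paste(miss, collapse = ", "))
  b <- chain_map[["beta"]]; bp <- chain_map[["betap"]]
  core <- residue_selection(
    chain = c(chain_map[["alpha1"]], chain_map[["alpha2"]],
              rep(b, 5), rep(bp, 5), chain_map[["omega"]]),
    start = c(NA, NA, 3, 142, 445, 520, 786, 343, 421, 530, 569, 720, NA),
    end   = c(NA, NA, 27, 152, 455, 713, 828, 368, 524, 552, 701, 786, NA),
    label = "core")
  swivel <- residue_selection(
    chain = c(b, rep(bp, 4)),
    start = c(1241, 1, 369, 787, 1135),
    end   = c(1341, 342, 420, 930, 1375),
    label = "swivel")
  module_definition(core, swivel)
}

# pair CA positions of two structures over a selection by (chain, resno);
# returns list(q = matrix, r = matrix, coverage_q, coverage_r, n)
.paired_calpha <- function(query, reference, selection,
                           query_chain_map = NULL, reference_chain_map = NULL) {
  sel_for <- function(map) {
    if (is.null(map)) return(selection)
    p <- selection$parts
    mapped <- map[p$chain]
    if (anyNA(mapped))
      .stopf("chain map does not cover chain(s): %s",
             paste(unique(p$chain[is.na(mapped)]), collapse = ", "))
    residue_selection(unname(mapped), p$start, p$end, label = selection$label)
  }
  caq <- select_calpha(query, sel_for(query_chain_map))
  car <- select_calpha(reference, sel_for(reference_chain_map))
  # key in canonical chain space: invert maps if given
  canon <- function(df, map) {
    if (is.null(map)) return(df$chain)
    inv <- setNames(names(map), map)
    inv[df$chain]
  }
  kq <- paste(canon(caq, query_chain_map), caq$resno)
  kr <- paste(canon(car, reference_chain_map), car$resno)
  common <- intersect(kq, kr)
  iq <- match(common, kq); ir <- match(common, kr)
  list(q = .xyz(caq[iq, ]), r = .xyz(car[ir, ]),
       coverage_q = length(common) / nrow(caq),
       coverage_r = length(common) / nrow(car),
       n = length(common))
}

.check_coverage <- function(pairing, what) {
  cov <- min(pairing$coverage_q, pairing$coverage_r)
  if (pairing$n < 3L || cov < 0.5)
    .stopf("%s coverage too low: %d pairs (query %.0f%%, reference %.0f%%)",
           what, pairing$n, 100 * pairing$coverage_q,
           100 * pairing$coverage_r)
  if (cov < 0.8)
    .warnf("%s coverage below 80%% (query %.0f%%, reference %.0f%%)",
           what, 100 * pairing$coverage_q, 100 * pairing$coverage_r)
  invisible(cov)
}

#' Swivel angle of a query structure relative to a reference
#'
#' The structural cores of query and reference are superposed by
#' least-squares over paired core CA atoms (pairing by identical canonical
#' chain and author residue number, unpaired residues dropped symmetrically).
#' With the query moved into the reference core frame, a second superposition
#' maps the reference swivel-module CA set onto the query's; the rotation part
#' of that transform, expressed as an axis-angle, is the swivel angle. The
#' result is invariant to any prior global rigid motion of the query; only
#' the rotation defines the angle (the translation is reported via the screw
#' anchor but unused).
#'
#' @param query,reference [structure_model()]s.
#' @param module_def a [module_definition()]; default
#'   [default_module_definition()].
#' @param query_chain_map,reference_chain_map optional named vectors mapping
#'   canonical chain labels (those used in `module_def`) to the labels used
#'   in the respective structure.
#' @return Object of class `swivel_result`: `angle` (degrees), `axis`
#'   ([rotation_to_axis_angle()] output), `core_rmsd`, `swivel_rmsd`,
#'   `n_core_pairs`, `n_swivel_pairs`.
#' @export
compute_swivel <- function(query, reference,
                           module_def = default_module_definition(),
                           query_chain_map = NULL,
                           reference_chain_map = NULL) {
  stopifnot(inherits(module_def, "module_definition"))
  core <- .paired_calpha(query, reference, module_def$core,
                         query_chain_map, reference_chain_map)
  .check_coverage(core, "core")
  t_core <- kabsch_superpose(core$q, core$r)

  sw <- .paired_calpha(query, reference, module_def$swivel,
                       query_chain_map, reference_chain_map)
  .check_coverage(sw, "swivel")
  q_moved <- apply_transform(sw$q, t_core)
  t_swivel <- kabsch_superpose(sw$r, q_moved)
  aa <- rotation_to_axis_angle(t_swivel)
  structure(list(angle = aa$angle, axis = aa,
                 core_rmsd = t_core$rmsd, swivel_rmsd = t_swivel$rmsd,
                 n_core_pairs = core$n, n_swivel_pairs = sw$n),
            class = "swivel_result")
}

#' @export
print.swivel_result <- function(x, ...) {
  cat(sprintf(
    "swivel_result: %.3f deg (core rmsd %.3f A over %d CA; swivel rmsd %.3f A over %d CA)\n",
    x$angle, x$core_rmsd, x$n_core_pairs, x$swivel_rmsd, x$n_swivel_pairs))
  invisible(x)
}

#' Swivel angles over a series of frames
#'
#' Applies [compute_swivel()] to each frame (e.g. per-frame models fitted
#' along a flexibility trajectory) and summarises the angle range.
#'
#' @param frames list of [structure_model()]s.
#' @param reference reference [structure_model()].
#' @param module_def a [module_definition()].
#' @param ... passed to [compute_swivel()].
#' @return Object of class `swivel_series`: `results` (list of
#'   `swivel_result`), `angles`, and `range` (min, max).
#' @export
swivel_series <- function(frames, reference,
                          module_def = default_module_definition(), ...) {
  if (!length(frames)) .stopf("no frames supplied")
  results <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    results[[i]] <- tryCatch(
      compute_swivel(frames[[i]], reference, module_def, ...),
      error = function(e) .stopf("frame %d: %s", i, conditionMessage(e)))
  }
  angles <- vapply(results, `[[`, numeric(1), "angle")
  structure(list(results = results, angles = angles,
                 range = c(min = min(angles), max = max(angles))),
            class = "swivel_series")
}

#' @export
print.swivel_series <- function(x, ...) {
  cat(sprintf("swivel_series: %d frames, angle range %.3f-%.3f deg\n",
              length(x$angles), x$range[["min"]], x$range[["max"]]))
  invisible(x)
}
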