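# Structure input/output and residue-range selections.
#
# A structure_model is a light container around an atom table (one row per
# atom) in Angstrom coordinates, author residue numbering. Parsing of PDB and
# mmCIF files is delegated to bio3d; alternate-location filtering, element
# inference and atomic masses are handled here.

# standard atomic weights (Da) for elements seen in macromolecular models
.atomic_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
  S = 32.06, SE = 78.971, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  MG = 24.305, MN = 54.938, FE = 55.845, ZN = 65.38, "NA" = 22.99,
  K = 39.098,
  CA = 40.078, CU = 63.546, NI = 58.693, CO = 58.933, MO = 95.95
)

.element_mass <- function(element) {
  m <- .atomic_masses[toupper(element)]
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    .stopf("unknown element(s): %s", paste(bad, collapse = ", "))
  }
  unname(m)
}

# infer the element symbol from a PDB atom name when the element column is
# blank ("1H5'" -> H, "CA" in a nucleotide/protein context -> C is wrong, so
# only the standard left-justified convention is applied)
.infer_element <- function(elety) {
  nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", elety))
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "MN"), two, one)
}

#' Construct a structure model from an atom table
#'
#' The atom table is the substrate of all geometric analyses in this package:
#' one row per atom with chain identifier, author residue number (1-based),
#' residue and atom names, element, occupancy, alternate-location indicator
#' and Cartesian coordinates in Angstrom. Atomic masses are filled in from
#' standard atomic weights when not supplied.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`
#'   (atom name), `x`, `y`, `z`; optional `element`, `occ`, `altloc`, `mass`.
#' @param identifier character label for the model.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, identifier = "model") {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) .stopf("atom table lacks column(s): %s",
                           paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) .stopf("empty model: no atoms")
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  atoms$resid <- as.character(atoms$resid)
  atoms$elety <- as.character(atoms$elety)
  if (is.null(atoms$element) || all(is.na(atoms$element)) ||
      all(!nzchar(atoms$element))) {
    atoms$element <- .infer_element(atoms$elety)
  } else {
    blank <- is.na(atoms$element) | !nzchar(trimws(atoms$element))
    atoms$element[blank] <- .infer_element(atoms$elety[blank])
    atoms$element <- toupper(trimws(atoms$element))
  }
  atoms$occ <- if (is.null(atoms$occ)) 1 else {
    o <- as.numeric(atoms$occ); o[is.na(o)] <- 1; o
  }
  atoms$altloc <- if (is.null(atoms$altloc)) "" else {
    a <- as.character(atoms$altloc); a[is.na(a)] <- ""; a
  }
  if (is.null(atoms$mass)) atoms$mass <- .element_mass(atoms$element)
  atoms$hydrogen <- atoms$element %in% c("H", "D")

  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) .stopf("non-finite coordinates in atom table")
  if (any(atoms$mass <= 0)) .stopf("non-positive atomic mass")
  if (any(atoms$occ < 0 | atoms$occ > 1))
    .stopf("occupancy outside [0, 1]")
  key <- paste(atoms$chain, atoms$resno, atoms$elety, atoms$altloc, sep = "\r")
  if (anyDuplicated(key))
    .stopf("duplicate (chain, residue, atom, altloc) record(s), e.g. %s",
           gsub("\r", "/", key[duplicated(key)][1]))
  rownames(atoms) <- NULL
  structure(list(identifier = identifier, atoms = atoms),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure_model '%s': %d atoms, %d residues, chains %s\n",
              x$identifier, nrow(a),
              length(unique(paste(a$chain, a$resno))),
              paste(sort(unique(a$chain)), collapse = " ")))
  invisible(x)
}

#' Number of atoms in a structure model
#' @param x a `structure_model`.
#' @export
natoms <- function(x) nrow(x$atoms)

# keep, per (chain, resno, atom name), only the highest-occupancy conformer;
# ties broken by lexicographically smallest altloc
.filter_altloc <- function(atoms) {
  alt <- atoms[nzchar(atoms$altloc), , drop = FALSE]
  if (nrow(alt) == 0L) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$elety, sep = "\r")
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  key <- key[ord]
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  # restore file order
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

#' Read an atomic structure from a PDB or mmCIF file
#'
#' All ATOM/HETATM coordinate records are captured. When a (chain, residue,
#' atom) position carries alternate locations, only the highest-occupancy
#' conformer is kept (ties resolved by the lexicographically smallest altloc
#' code). Hydrogens are retained and flagged in the atom table.
#'
#' @param path path to the structure file.
#' @param format one of `"auto"` (by file extension), `"pdb"`, `"cif"`.
#' @param identifier model label; defaults to the file base name.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           identifier = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "cif",
                     mmcif = "cif",
                     .stopf("cannot infer structure format of '%s'; pass format=", path))
  }
  parsed <- tryCatch(
    withCallingHandlers(
      if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
      else bio3d::read.cif(path, verbose = FALSE),
      warning = function(w) {
        # muffle bio3d's informational chatter, keep real warnings
        if (grepl("beta version|helix/sheet", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) .stopf("failed to parse %s file '%s': %s",
                               format, path, conditionMessage(e)))
  a <- parsed$atom
  if (is.null(a) || nrow(a) == 0L) .stopf("empty model in '%s'", path)
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno,
    resid = a$resid,
    elety = a$elety,
    element = if ("elesy" %in% names(a)) a$elesy else NA_character_,
    occ = ifelse(is.na(a$o), 1, a$o),
    altloc = if ("alt" %in% names(a)) ifelse(is.na(a$alt), "", a$alt) else "",
    x = a$x, y = a$y, z = a$z,
    stringsAsFactors = FALSE
  )
  rownames(atoms) <- seq_len(nrow(atoms))
  atoms <- .filter_altloc(atoms)
  atoms$altloc <- ""  # conformer choice is resolved; drop the marker
  structure_model(atoms, identifier %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a structure model as a PDB file
#'
#' Chain identifiers longer than one character cannot be represented in
#' fixed-column PDB; they are remapped to single letters and the mapping is
#' emitted both as the return value and as a sidecar file
#' `<path>.chains.tsv`.
#'
#' @param model a [structure_model()].
#' @param path output file path.
#' @return Invisibly, a data.frame mapping original to written chain ids.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  if (nrow(a) == 0L) .stopf("empty model")
  chains <- unique(a$chain)
  written <- chains
  short <- nchar(chains) == 1L
  if (any(!short)) {
    pool <- setdiff(c(LETTERS, letters, as.character(0:9)), chains[short])
    if (sum(!short) > length(pool)) .stopf("too many chains to remap")
    written[!short] <- pool[seq_len(sum(!short))]
  }
  map <- data.frame(chain = chains, written = written,
                    stringsAsFactors = FALSE)
  wchain <- map$written[match(a$chain, map$chain)]
  ok <- tryCatch({
    n <- nrow(a)
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = rep("ATOM", n), eleno = seq_len(n),
                     resno = a$resno, resid = a$resid, chain = wchain,
                     elety = a$elety, o = a$occ, b = rep(0, n),
                     elesy = a$element)
    TRUE
  }, error = function(e) .stopf("cannot write '%s': %s", path,
                                conditionMessage(e)))
  if (!identical(map$chain, map$written)) {
    write.table(map, paste0(path, ".chains.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(map)
}

#' Residue-range selection
#'
#' Selections name sets of residues as inclusive author-numbered ranges per
#' chain, e.g. the rigid-module residue lists used for superposition. A part
#' with `NA` bounds means every residue present in that chain.
#'
#' @param chain character vector of chain ids (recycled against ranges).
#' @param start,end inclusive 1-based residue range bounds; `NA` for "all of
#'   the chain".
#' @param label optional selection label.
#' @return Object of class `residue_selection` with a `parts` data.frame.
#' @export
residue_selection <- function(chain, start = NA_integer_, end = start,
                              label = "") {
  parts <- data.frame(chain = as.character(chain),
                      start = as.integer(start), end = as.integer(end),
                      stringsAsFactors = FALSE)
  bad <- !is.na(parts$start) & !is.na(parts$end) & parts$start > parts$end
  if (any(bad)) .stopf("selection range with start > end (%s %d-%d)",
                       parts$chain[bad][1], parts$start[bad][1],
                       parts$end[bad][1])
  # non-overlap within a chain (NA ranges overlap everything in that chain)
  for (ch in unique(parts$chain)) {
    p <- parts[parts$chain == ch, , drop = FALSE]
    if (nrow(p) < 2L) next
    if (any(is.na(p$start))) .stopf(
      "chain %s mixes an all-residues part with other parts", ch)
    p <- p[order(p$start), ]
    if (any(p$start[-1] <= p$end[-nrow(p)]))
      .stopf("overlapping selection ranges in chain %s", ch)
  }
  structure(list(parts = parts, label = label), class = "residue_selection")
}

#' @export
print.residue_selection <- function(x, ...) {
  rng <- ifelse(is.na(x$parts$start), "all",
                paste0(x$parts$start, "-", x$parts$end))
  cat(sprintf("residue_selection%s: %s\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              paste(x$parts$chain, rng, collapse = ", ")))
  invisible(x)
}

#' Read a selection file ("CHAIN START END" per line, "-" or "*" for all)
#' @param path path to a whitespace-delimited selection file.
#' @param label selection label.
#' @return A [residue_selection()].
#' @export
read_selection <- function(path, label = basename(path)) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chain", "start", "end"),
                    colClasses = c("character", "character", "character"))
  s <- suppressWarnings(as.integer(tab$start))
  e <- suppressWarnings(as.integer(tab$end))
  residue_selection(tab$chain, s, e, label = label)
}

#' Test whether a selection contains a residue
#' @param selection a [residue_selection()].
#' @param chain chain id.
#' @param resno residue number.
#' @return Logical.
#' @export
selection_contains <- function(selection, chain, resno) {
  p <- selection$parts
  any(p$chain == chain &
        (is.na(p$start) | (p$start <= resno & p$end >= resno)))
}

# residues of the model matched by one selection part, in ascending resno
.part_residues <- function(atoms, part) {
  res <- sort(unique(atoms$resno[atoms$chain == part$chain]))
  if (!is.na(part$start)) res <- res[res >= part$start & res <= part$end]
  res
}

#' Extract ordered C-alpha positions for a selection
#'
#' One CA position per selected residue, ordered by (selection part, residue
#' number). Residues inside an explicit range that are absent from the model
#' or lack a CA atom are skipped and reported in the `"skipped"` attribute;
#' for all-chain parts only CA-less residues that are present can be
#' reported.
#'
#' @param model a [structure_model()].
#' @param selection a [residue_selection()].
#' @return data.frame (chain, resno, x, y, z) with attribute `skipped`.
#' @export
select_calpha <- function(model, selection) {
  stopifnot(inherits(model, "structure_model"),
            inherits(selection, "residue_selection"))
  a <- model$atoms
  out <- list(); skipped <- list()
  for (i in seq_len(nrow(selection$parts))) {
    part <- selection$parts[i, ]
    if (!part$chain %in% a$chain) next
    res <- .part_residues(a, part)
    ca <- a[a$chain == part$chain & a$elety == "CA" & a$resno %in% res, ,
            drop = FALSE]
    ca <- ca[order(ca$resno), , drop = FALSE]
    expected <- if (is.na(part$start)) res else seq(part$start, part$end)
    miss <- setdiff(expected, ca$resno)
    if (length(miss))
      skipped[[length(skipped) + 1L]] <-
        data.frame(chain = part$chain, resno = miss)
    if (nrow(ca))
      out[[length(out) + 1L]] <- data.frame(
        chain = ca$chain, resno = ca$resno,
        x = ca$x, y = ca$y, z = ca$z, stringsAsFactors = FALSE)
  }
  if (!length(out))
    .stopf("selection%s matches no CA atoms in model '%s'",
           if (nzchar(selection$label)) paste0(" '", selection$label, "'") else "",
           model$identifier)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "skipped") <- if (length(skipped)) {
    s <- do.call(rbind, skipped); rownames(s) <- NULL; s
  } else data.frame(chain = character(), resno = integer())
  res
}

#' Per-residue centers of mass over a selection
#'
#' Default is the mass-weighted center over non-hydrogen atoms, emulating the
#' center-of-mass extraction of standard molecular viewers; flags expose the
#' unweighted and hydrogen-inclusive alternatives.
#'
#' @param model a [structure_model()].
#' @param selection a [residue_selection()].
#' @param mass_weighted weight positions by standard atomic mass?
#' @param include_hydrogens include hydrogen/deuterium atoms?
#' @return data.frame (chain, resno, x, y, z) in selection order.
#' @export
residue_centers_of_mass <- function(model, selection, mass_weighted = TRUE,
                                    include_hydrogens = FALSE) {
  stopifnot(inherits(model, "structure_model"),
            inherits(selection, "residue_selection"))
  a <- model$atoms
  if (!include_hydrogens) a <- a[!a$hydrogen, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(selection$parts))) {
    part <- selection$parts[i, ]
    res <- .part_residues(model$atoms, part)
    for (r in res) {
      at <- a[a$chain == part$chain & a$resno == r, , drop = FALSE]
      if (nrow(at) == 0L)
        .stopf("residue %s/%d has no atoms passing the hydrogen filter",
               part$chain, r)
      w <- if (mass_weighted) at$mass else rep(1, nrow(at))
      out[[length(out) + 1L]] <- data.frame(
        chain = part$chain, resno = r,
        x = sum(w * at$x) / sum(w),
        y = sum(w * at$y) / sum(w),
        z = sum(w * at$z) / sum(w), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) .stopf("selection matches no residues in model '%s'",
                           model$identifier)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# coordinate matrix helpers used across modules
.xyz <- function(df) as.matrix(df[, c("x", "y", "z"), drop = FALSE])
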