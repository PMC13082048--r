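# Fixtures built in code: handwritten structure files and small models.

# fixed-column PDB ATOM line
pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, altloc = " ", element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1, 1)
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, altloc, resn, chain, resno, x, y, z, occ, 0,
          element)
}

write_mini_pdb <- function(path, atoms) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    pdb_atom_line(i, a$name, a$resn, a$chain, a$resno, a$x, a$y, a$z,
                  occ = a$occ %||% 1, altloc = a$altloc %||% " ")
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# same content as a minimal mmCIF atom_site loop
write_mini_cif <- function(path, atoms) {
  header <- c(
    "data_mini",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num")
  rows <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    el <- substr(trimws(a$name), 1, 1)
    sprintf("ATOM %d %s %s . %s A 1 %d ? %.3f %.3f %.3f %.2f 0.00 ? %d %s %s %s 1",
            i, el, a$name, a$resn, a$resno, a$x, a$y, a$z, a$occ %||% 1,
            a$resno, a$resn, a$chain, a$name)
  }, character(1))
  writeLines(c(header, rows, "#"), path)
  path
}

mini_atoms <- function() {
  data.frame(name = c("N", "CA", "C"), resn = "GLY", chain = "B",
             resno = c(5, 5, 5),
             x = c(1.234, 2.345, 3.456), y = c(0.111, 1.222, 2.333),
             z = c(-1.5, -0.5, 0.5), stringsAsFactors = FALSE)
}

# structure model straight from a coordinate table
quick_model <- function(chain, resno, elety, x, y, z, element = NULL,
                        id = "fixture") {
  structure_model(data.frame(
    chain = chain, resno = resno, resid = "ALA", elety = elety,
    element = element %||% substr(elety, 1, 1), x = x, y = y, z = z,
    stringsAsFactors = FALSE), id)
}

# protein-with-DNA fixture for the displacement analysis: a CA "core" chain
# plus 12 nucleotide pseudo-residues (3 atoms each) along a helix
displacement_fixture <- function(seed = 1) {
  set.seed(seed)
  core_xyz <- matrix(rnorm(3 * 40, sd = 12), ncol = 3)
  core <- data.frame(chain = "P", resno = 1:40, resid = "ALA", elety = "CA",
                     element = "C", x = core_xyz[, 1] + 30,
                     y = core_xyz[, 2], z = core_xyz[, 3],
                     stringsAsFactors = FALSE)
  # nucleotide pseudo-residues on a helix; their centers of mass sit ~4.5 A
  # off the axis, as real nucleotide COMs do
  nt <- do.call(rbind, lapply(1:12, function(i) {
    th <- (i - 1) * 2 * pi / 10.5
    cx <- 4.5 * cos(th); cy <- 4.5 * sin(th); cz <- (i - 1) * 3.4
    data.frame(chain = "T", resno = i, resid = "DG",
               elety = c("P", "C4'", "C1'"), element = c("P", "C", "C"),
               x = cx + c(0, 0.8, -0.5), y = cy + c(0, -0.4, 0.7),
               z = cz + c(0, 0.3, -0.2), stringsAsFactors = FALSE)
  }))
  structure_model(rbind(core, nt), "displacement-fixture")
}

core_sel <- function() residue_selection("P", 1, 40, label = "core")
nt_sel <- function() residue_selection("T", 1, 12, label = "downstream-dna")

# shift the 12 nucleotide residues of a displacement fixture by a vector
shift_nucleotides <- function(model, delta) {
  sel <- model$atoms$chain == "T"
  model$atoms[sel, c("x", "y", "z")] <-
    sweep(as.matrix(model$atoms[sel, c("x", "y", "z")]), 2, delta, "+")
  model
}
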