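# Bondi-style van der Waals radii (Angstrom); unknown elements get carbon's
.vdw_table <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
.vdw_default <- 1.70

.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Parse ATOM records from a PDB file
#'
#' Fixed-column PDB v3.3 parsing of `ATOM` (and optionally `HETATM`)
#' records. The element is taken from columns 77-78 when present, otherwise
#' inferred from the atom name. Multi-model files yield the first model with
#' a warning. For predicted structures, the B-factor column carries the
#' per-residue model confidence (pLDDT, 0-100).
#'
#' @param path PDB file path.
#' @param include_hetatm Keep HETATM records too. Default FALSE.
#' @return Data frame of atoms: `serial`, `name`, `resname`, `chain`,
#'   `residue_index`, `x`, `y`, `z`, `b_factor`, `element`, `hetatm`,
#'   `vdw_radius`.
#' @export
parse_pdb <- function(path, include_hetatm = FALSE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) > 1) {
    warning("multi-model file; using the first model only")
    endm <- which(trimws(rec) == "ENDMDL")
    lines <- lines[seq(model_starts[1], endm[1])]
    rec <- substr(lines, 1, 6)
  }
  want <- trimws(rec) == "ATOM" |
    (include_hetatm & trimws(rec) == "HETATM")
  n_het <- sum(trimws(rec) == "HETATM")
  idx <- which(want)
  if (!length(idx)) {
    if (n_het > 0 && !include_hetatm)
      warning("file contains only HETATM records; returning zero atoms")
    return(data.frame(serial = integer(), name = character(),
                      resname = character(), chain = character(),
                      residue_index = integer(), x = numeric(), y = numeric(),
                      z = numeric(), b_factor = numeric(),
                      element = character(), hetatm = logical(),
                      vdw_radius = numeric(), stringsAsFactors = FALSE))
  }
  al <- lines[idx]
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(al, from, to)))
    bad <- which(is.na(v))
    if (length(bad))
      stop("malformed ATOM record (", what, ") at line ", idx[bad[1]],
           ": '", lines[idx[bad[1]]], "'")
    v
  }
  name <- trimws(substr(al, 13, 16))
  element <- trimws(substr(al, 77, 78))
  no_el <- element == ""
  element[no_el] <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                        name[no_el]), 1, 1))
  atoms <- data.frame(
    serial = as.integer(num(7, 11, "serial")),
    name = name,
    resname = trimws(substr(al, 18, 20)),
    chain = trimws(substr(al, 22, 22)),
    residue_index = as.integer(num(23, 26, "residue number")),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    b_factor = num(61, 66, "B-factor"),
    element = element,
    hetatm = trimws(substr(al, 1, 6)) == "HETATM",
    stringsAsFactors = FALSE
  )
  r <- .vdw_table[atoms$element]
  r[is.na(r)] <- .vdw_default
  atoms$vdw_radius <- unname(r)
  atoms
}

#' Per-residue model confidence from atom B-factors
#'
#' Predicted-structure files store one pLDDT value per residue, replicated
#' on every atom; this collapses the atom table accordingly. Residues whose
#' atoms disagree get the mean, with a warning.
#'
#' @param atoms Atom data frame from [parse_pdb()].
#' @return Named numeric vector, residue index -> pLDDT.
#' @export
plddt_per_residue <- function(atoms) {
  if (!nrow(atoms)) return(setNames(numeric(), character()))
  sp <- split(atoms$b_factor, atoms$residue_index)
  disagree <- vapply(sp, function(v) length(unique(v)) > 1, logical(1))
  if (any(disagree))
    warning(sum(disagree), " residue(s) with disagreeing atom B-factors; ",
            "using the mean")
  vapply(sp, mean, numeric(1))
}

# deterministic quasi-uniform points on the unit sphere (golden-section
# spiral); no RNG involved
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  theta <- pi * (3 - sqrt(5)) * (i - 0.5)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Point-sampling SASA: `n_points` quasi-uniform points are placed on each
#' atom's solvent-expanded sphere (van der Waals radius + probe radius); a
#' point is accessible when it lies strictly outside every neighboring
#' atom's expanded sphere (points exactly on a neighbor's surface count as
#' accessible, which keeps coincident-atom cases deterministic). The atom's
#' SASA is the accessible fraction of its expanded-sphere area. Neighbor
#' candidates are limited to atoms within the sum of both expanded radii.
#'
#' @param atoms Atom data frame from [parse_pdb()] (needs coordinates and
#'   `vdw_radius`).
#' @param probe Probe radius in Angstrom. Default 1.4 (water).
#' @param n_points Sphere sample points per atom. Default 100.
#' @param include_hydrogens Drop hydrogen atoms first when FALSE.
#' @return Numeric vector of per-atom SASA (Angstrom^2), aligned with the
#'   (possibly hydrogen-filtered) atom rows; the filtered atom table is
#'   attached as the `atoms` attribute.
#' @export
shrake_rupley <- function(atoms, probe = 1.4, n_points = 100L,
                          include_hydrogens = TRUE) {
  stopifnot(n_points >= 16, probe > 0)
  if (!include_hydrogens) atoms <- atoms[atoms$element != "H", , drop = FALSE]
  n <- nrow(atoms)
  if (!n) return(structure(numeric(), atoms = atoms))
  pts <- golden_spiral_points(n_points)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- atoms$vdw_radius + probe
  d2 <- as.matrix(dist(xyz))^2
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    Ri <- rad[i]
    nb <- which(d2[i, ] < (Ri + rad)^2 & seq_len(n) != i)
    sphere <- sweep(pts * Ri, 2, xyz[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(accessible)) break
      dj2 <- (sphere[, 1] - xyz[j, 1])^2 + (sphere[, 2] - xyz[j, 2])^2 +
        (sphere[, 3] - xyz[j, 3])^2
      accessible <- accessible & dj2 >= rad[j]^2
    }
    sasa[i] <- 4 * pi * Ri^2 * mean(accessible)
  }
  structure(sasa, atoms = atoms)
}

#' Per-residue SASA
#'
#' @param atom_sasa Result of [shrake_rupley()].
#' @return Named numeric vector, residue index -> summed member-atom SASA.
#' @export
residue_sasa <- function(atom_sasa) {
  atoms <- attr(atom_sasa, "atoms")
  if (!length(atom_sasa)) return(setNames(numeric(), character()))
  vapply(split(as.numeric(atom_sasa), atoms$residue_index), sum, numeric(1))
}

#' Per-residue structural context of one protein
#'
#' Parses a predicted-structure PDB file and returns per-residue pLDDT and
#' SASA in one table.
#'
#' @param path PDB file path.
#' @param cfg An [atlas_config()] supplying probe radius, point count and
#'   the hydrogen/HETATM toggles.
#' @return Data frame: `residue_index`, `aa` (one-letter), `plddt`, `sasa`.
#' @export
residue_structure <- function(path, cfg = atlas_config()) {
  atoms <- parse_pdb(path, include_hetatm = cfg$sasa_include_hetatm)
  if (!nrow(atoms))
    return(data.frame(residue_index = integer(), aa = character(),
                      plddt = numeric(), sasa = numeric(),
                      stringsAsFactors = FALSE))
  pl <- plddt_per_residue(atoms)
  sa <- residue_sasa(shrake_rupley(atoms, probe = cfg$sasa_probe_radius,
                                   n_points = cfg$sasa_n_points,
                                   include_hydrogens = cfg$sasa_include_hydrogens))
  resno <- sort(unique(atoms$residue_index))
  resname <- atoms$resname[match(resno, atoms$residue_index)]
  aa <- unname(.aa3to1[resname])
  aa[is.na(aa)] <- "X"
  data.frame(residue_index = resno, aa = aa,
             plddt = unname(pl[as.character(resno)]),
             sasa = unname(sa[as.character(resno)]),
             stringsAsFactors = FALSE)
}

#' Join acetyl sites to structural context
#'
#' Adds pLDDT and SASA to each site from its protein's per-residue
#' structure table. Residue numbering of predicted models equals sequence
#' position, so the join is on (protein, position). Sites whose structural
#' residue is not lysine are flagged (`mismatch`) and should be excluded
#' from distributions; sites without a structure are dropped and counted in
#' the `n_unmapped` attribute.
#'
#' @param sites An `acetyl_sites` object (collapsed).
#' @param structures Named list protein id -> per-residue table from
#'   [residue_structure()].
#' @return Data frame: `protein_id`, `collapse_key`, `position`, `aa`,
#'   `plddt`, `sasa`, `mismatch`.
#' @export
join_site_structure <- function(sites, structures) {
  stopifnot(inherits(sites, "acetyl_sites"))
  m <- sites$meta
  have <- m$protein_id %in% names(structures)
  n_unmapped <- sum(!have)
  m <- m[have, , drop = FALSE]
  rows <- lapply(seq_len(nrow(m)), function(i) {
    st <- structures[[m$protein_id[i]]]
    j <- match(m$position[i], st$residue_index)
    if (is.na(j))
      return(data.frame(protein_id = m$protein_id[i],
                        collapse_key = m$collapse_key[i],
                        position = m$position[i], aa = NA_character_,
                        plddt = NA_real_, sasa = NA_real_, mismatch = TRUE,
                        stringsAsFactors = FALSE))
    data.frame(protein_id = m$protein_id[i],
               collapse_key = m$collapse_key[i],
               position = m$position[i], aa = st$aa[j],
               plddt = st$plddt[j], sasa = st$sasa[j],
               mismatch = !identical(st$aa[j], "K"),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), collapse_key = character(),
               position = integer(), aa = character(), plddt = numeric(),
               sasa = numeric(), mismatch = logical(),
               stringsAsFactors = FALSE)
  attr(out, "n_unmapped") <- n_unmapped
  out
}
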