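#' List cysteine sites in a PDB-format structure
#'
#' Returns one site per CYS residue that has an SG atom. Optionally drops
#' cysteines participating in disulfide bonds, detected geometrically: any
#' CYS whose SG atom lies within `ss_threshold` Angstrom of another CYS SG
#' is considered bonded. Free cysteines are the usual centers of interest
#' because disulfide-bonded ones are dominated by the bond itself.
#'
#' @param structure_file path to a PDB-format file.
#' @param exclude_disulfides drop disulfide-bonded cysteines (default TRUE).
#' @param ss_threshold SG-SG distance threshold in Angstrom (default 2.5;
#'   the covalent S-S bond length is about 2.05).
#' @return data.frame of site identifiers (structure_id, chain,
#'   residue_number, residue_name).
#' @export
extract_cys_sites <- function(structure_file, exclude_disulfides = TRUE,
                              ss_threshold = 2.5) {
  pdb <- tryCatch(bio3d::read.pdb(structure_file, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file '",
                                           structure_file, "': ",
                                           conditionMessage(e)))
  at <- pdb$atom
  sg <- at[at$resid == "CYS" & at$elety == "SG", , drop = FALSE]
  empty <- data.frame(structure_id = character(), chain = character(),
                      residue_number = integer(), residue_name = character(),
                      stringsAsFactors = FALSE)
  if (nrow(sg) == 0) return(empty)
  # one SG per (chain, resno); keep first altloc
  key <- paste(sg$chain, sg$resno)
  sg <- sg[!duplicated(key), , drop = FALSE]
  keep <- rep(TRUE, nrow(sg))
  if (exclude_disulfides && nrow(sg) > 1) {
    xyz <- as.matrix(sg[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    diag(d) <- Inf
    keep <- apply(d, 1, min) > ss_threshold
  }
  sid <- structure_id_from_path(structure_file)
  data.frame(structure_id = sid,
             chain = sg$chain[keep],
             residue_number = as.integer(sg$resno[keep]),
             residue_name = "CYS",
             stringsAsFactors = FALSE)
}

structure_id_from_path <- function(path) {
  toupper(substr(tools::file_path_sans_ext(basename(path)), 1, 4))
}

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")

# atoms of planar aromatic rings
AROMATIC_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

# representative side-chain terminus atoms carrying +/-1 formal charge
CHARGE_ATOMS <- data.frame(
  resid = c("LYS", "ARG", "ASP", "GLU"),
  elety = c("NZ", "CZ", "CG", "CD"),
  charge = c(1, 1, -1, -1),
  stringsAsFactors = FALSE)

#' Simplified microenvironment property vector for one site
#'
#' Computes a configurable surrogate property set over `n_shells`
#' equal-width concentric shells centered on the site's SG atom (falling
#' back to CB, then CA, with a warning). This is deliberately NOT the
#' original 44-property microenvironment representation, whose definitions
#' live outside this package; it provides compatible plumbing for building
#' raw microenvironment vectors directly from structures.
#'
#' Shell assignment is half-open `[inner, outer)` from the center, with the
#' outermost shell closed, so an atom sitting exactly on an internal
#' boundary belongs to the outer of the two shells.
#'
#' Default properties per shell: number of residues of each of the 20
#' standard amino-acid types with at least one atom in the shell; counts of
#' C, N, O, S atoms; count of aromatic-ring atoms (PHE/TYR/TRP/HIS rings);
#' and the sum of +/-1 formal charges on LYS/ARG/ASP/GLU side-chain
#' terminus atoms (the only entries that may be negative).
#'
#' @param structure_file path to a PDB-format file.
#' @param site one-row data.frame (or list) with chain and residue_number.
#' @param n_shells number of shells (default 6).
#' @param radius total radius in Angstrom (default 7.5).
#' @param properties subset of
#'   `c("residue_counts", "element_counts", "aromatic", "charge")`.
#' @return named numeric vector of length n_properties x n_shells,
#'   shell-major order, names of the form `property@shellK`.
#' @export
simple_properties <- function(structure_file, site, n_shells = 6L,
                              radius = 7.5,
                              properties = c("residue_counts",
                                             "element_counts",
                                             "aromatic", "charge")) {
  stopifnot(radius > 0, n_shells >= 1)
  properties <- match.arg(properties, several.ok = TRUE)
  pdb <- bio3d::read.pdb(structure_file, verbose = FALSE)
  at <- pdb$atom
  res <- at[at$chain == site$chain & at$resno == site$residue_number &
              at$type == "ATOM", , drop = FALSE]
  if (nrow(res) == 0) {
    stop("site ", site$chain, ":", site$residue_number,
         " not found in ", structure_file)
  }
  center <- NULL
  for (a in c("SG", "CB", "CA")) {
    hit <- res[res$elety == a, , drop = FALSE]
    if (nrow(hit)) { center <- as.numeric(hit[1, c("x", "y", "z")]); break }
    if (a == "SG") warning("site has no SG atom; falling back to CB/CA")
  }
  if (is.null(center)) stop("site has no SG, CB or CA atom")

  xyz <- as.matrix(at[, c("x", "y", "z")])
  d <- sqrt(colSums((t(xyz) - center)^2))
  width <- radius / n_shells
  shell <- floor(d / width) + 1L           # half-open [inner, outer)
  shell[d == radius] <- n_shells           # outermost shell closed
  inside <- shell >= 1L & shell <= n_shells

  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(gsub("^[0-9]", "", at$elety), 1, 1)
  }
  elem <- toupper(trimws(elem))

  prop_names <- character(0)
  if ("residue_counts" %in% properties) prop_names <- c(prop_names, paste0("res_", AMINO3))
  if ("element_counts" %in% properties) prop_names <- c(prop_names, paste0("elem_", c("C", "N", "O", "S")))
  if ("aromatic" %in% properties) prop_names <- c(prop_names, "aromatic_atoms")
  if ("charge" %in% properties) prop_names <- c(prop_names, "charge_sum")

  out <- numeric(0)
  for (s in seq_len(n_shells)) {
    idx <- which(inside & shell == s)
    block <- numeric(0)
    if ("residue_counts" %in% properties) {
      rk <- unique(paste(at$chain[idx], at$resno[idx], at$resid[idx]))
      rtypes <- sub("^.* ", "", rk)
      block <- c(block, as.numeric(table(factor(rtypes, levels = AMINO3))))
    }
    if ("element_counts" %in% properties) {
      block <- c(block, as.numeric(table(factor(elem[idx], levels = c("C", "N", "O", "S")))))
    }
    if ("aromatic" %in% properties) {
      arom <- mapply(function(r, a) r %in% names(AROMATIC_ATOMS) &&
                       a %in% AROMATIC_ATOMS[[r]],
                     at$resid[idx], at$elety[idx])
      block <- c(block, sum(as.logical(arom)))
    }
    if ("charge" %in% properties) {
      m <- merge(data.frame(resid = at$resid[idx], elety = at$elety[idx],
                            stringsAsFactors = FALSE),
                 CHARGE_ATOMS, by = c("resid", "elety"))
      block <- c(block, if (nrow(m)) sum(m$charge) else 0)
    }
    names(block) <- paste0(prop_names, "@shell", s)
    out <- c(out, block)
  }
  out
}

#' Parse HETATM ligand codes from a PDB-format file
#'
#' @param structure_file path to a PDB-format file.
#' @param exclude het codes to drop (default water).
#' @return data.frame(structure_id, het_code), one row per distinct code.
#' @export
read_hetatm_codes <- function(structure_file, exclude = c("HOH", "DOD")) {
  lines <- readLines(structure_file, warn = FALSE)
  het <- lines[startsWith(lines, "HETATM")]
  codes <- unique(trimws(substr(het, 18, 20)))
  codes <- sort(setdiff(codes, exclude))
  data.frame(structure_id = structure_id_from_path(structure_file),
             het_code = codes, stringsAsFactors = FALSE)
}
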