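# Multi-model PDB in and out. Parsing is delegated to bio3d; a light
# pre-scan validates that every MODEL block carries the same atom count,
# which bio3d does not always diagnose cleanly.

#' Read a multi-model PDB file into a coordinate ensemble
#'
#' Frames are ordered by MODEL number; a file without MODEL records is
#' read as a single-frame ensemble. Coordinates are in Angstrom with
#' 1-based PDB residue numbering.
#'
#' @param path PDB file path
#' @param atom_names optional atom-name filter (e.g. "CA"), applied
#'   identically to all frames
#' @param residue_ids optional residue-number filter
#' @param chain_ids optional chain filter
#' @return a `coord_ensemble`
#' @export
read_multimodel_pdb <- function(path, atom_names = NULL, residue_ids = NULL,
                                chain_ids = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  model_starts <- grepl("^MODEL", lines)
  if (any(model_starts)) {
    counts <- integer(0); inside <- FALSE; n <- 0L
    for (ln in lines) {
      if (startsWith(ln, "MODEL")) { inside <- TRUE; n <- 0L }
      else if (startsWith(ln, "ENDMDL")) { counts <- c(counts, n); inside <- FALSE }
      else if (inside && (startsWith(ln, "ATOM") || startsWith(ln, "HETATM")))
        n <- n + 1L
    }
    if (length(unique(counts)) > 1)
      .stopf("inconsistent atom count across models: %s",
             paste(unique(counts), collapse = ", "))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_at <- nrow(pdb$atom)
  frames <- nrow(xyz)
  coords <- array(NA_real_, dim = c(frames, n_at, 3))
  for (f in seq_len(frames)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  ens <- coord_ensemble(coords,
                        atom_names = pdb$atom$elety,
                        residue_ids = pdb$atom$resno,
                        residue_names = pdb$atom$resid,
                        chain_ids = ifelse(is.na(pdb$atom$chain), "A",
                                           pdb$atom$chain))
  if (!is.null(atom_names) || !is.null(residue_ids) || !is.null(chain_ids))
    ens <- select_atoms(ens, atom_names = atom_names,
                        residue_ids = residue_ids, chain_ids = chain_ids)
  ens
}

#' Write a coordinate ensemble as a multi-model PDB file
#'
#' @param x a `coord_ensemble`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_multimodel_pdb <- function(x, path) {
  d <- dim(x$coords)
  xyz <- matrix(NA_real_, nrow = d[1], ncol = d[2] * 3)
  for (f in seq_len(d[1])) xyz[f, ] <- as.vector(t(x$coords[f, , ]))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", d[2]),
                   resno = x$residue_ids, resid = x$residue_names,
                   eleno = seq_len(d[2]), elety = x$atom_names,
                   chain = x$chain_ids)
  invisible(path)
}
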