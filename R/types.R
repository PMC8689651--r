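# Domain containers. Each is a plain data frame (or array) carrying its
# metadata as attributes, validated on construction. Canonical units are
# kelvin, seconds, s^-1, mM, nm, Angstrom throughout.

#' Stopped-flow absorbance transient
#'
#' @param time numeric, seconds, strictly increasing, at least 8 points
#' @param absorbance numeric, AU at 340 nm, same length as `time`
#' @param temperature kelvin (scalar, optional)
#' @param label free-text label
#' @return data frame of class `absorbance_transient` with columns
#'   `time`, `absorbance` and attributes `temperature`, `label`
#' @export
absorbance_transient <- function(time, absorbance, temperature = NA_real_,
                                 label = "") {
  time <- as.numeric(time); absorbance <- as.numeric(absorbance)
  if (length(time) != length(absorbance))
    .stopf("time and absorbance lengths differ (%d vs %d)",
           length(time), length(absorbance))
  if (anyNA(time) || anyNA(absorbance))
    .stopf("missing values in transient data")
  if (length(time) < 8)
    .stopf("a transient needs at least 8 points, got %d", length(time))
  if (any(diff(time) <= 0))
    .stopf("time must be strictly increasing")
  out <- data.frame(time = time, absorbance = absorbance)
  attr(out, "temperature") <- as.numeric(temperature)
  attr(out, "label") <- as.character(label)
  class(out) <- c("absorbance_transient", "data.frame")
  out
}

#' Rate versus substrate concentration series at one temperature
#'
#' @param conc substrate concentration, mM, non-negative
#' @param rate observed rate (canonical s^-1 after any input conversion)
#' @param temperature kelvin
#' @param enzyme_conc enzyme (active-site) concentration, uM; used to turn
#'   Vmax into kcat
#' @param substrate substrate label
#' @param isotopologue isotopologue label, e.g. "H" or "1-D"
#' @return data frame of class `rate_conc_series` with columns `conc`,
#'   `rate` and metadata attributes
#' @export
rate_conc_series <- function(conc, rate, temperature = NA_real_,
                             enzyme_conc = NA_real_, substrate = "",
                             isotopologue = "H") {
  conc <- as.numeric(conc); rate <- as.numeric(rate)
  if (length(conc) != length(rate)) .stopf("conc and rate lengths differ")
  if (anyNA(conc) || anyNA(rate)) .stopf("missing values in rate series")
  if (any(conc < 0)) .stopf("substrate concentrations must be non-negative")
  out <- data.frame(conc = conc, rate = rate)
  attr(out, "temperature") <- as.numeric(temperature)
  attr(out, "enzyme_conc") <- as.numeric(enzyme_conc)
  attr(out, "substrate") <- as.character(substrate)
  attr(out, "isotopologue") <- as.character(isotopologue)
  class(out) <- c("rate_conc_series", "data.frame")
  out
}

#' Temperature versus rate series for MMRT fitting
#'
#' Rows are sorted by temperature on construction; duplicate temperatures
#' are rejected because each row is one independent determination of the
#' rate at that temperature.
#'
#' @param temperature kelvin, all positive, no duplicates
#' @param rate s^-1, strictly positive (the fit is in ln k)
#' @param rate_se optional standard errors on `rate`
#' @param substrate substrate label
#' @param isotopologue isotopologue label
#' @return data frame of class `temperature_rate_series`
#' @export
temperature_rate_series <- function(temperature, rate, rate_se = NULL,
                                    substrate = "", isotopologue = "H") {
  temperature <- as.numeric(temperature); rate <- as.numeric(rate)
  if (length(temperature) != length(rate))
    .stopf("temperature and rate lengths differ")
  if (anyNA(temperature) || anyNA(rate))
    .stopf("missing values in temperature-rate series")
  if (any(temperature <= 0)) .stopf("temperatures must be positive kelvin")
  if (anyDuplicated(temperature)) .stopf("duplicate temperatures")
  if (any(rate <= 0)) .stopf("rates must be strictly positive")
  ord <- order(temperature)
  out <- data.frame(temperature = temperature[ord], rate = rate[ord])
  if (!is.null(rate_se)) {
    rate_se <- as.numeric(rate_se)
    if (length(rate_se) != nrow(out)) .stopf("rate_se length mismatch")
    out$rate_se <- rate_se[ord]
  }
  attr(out, "substrate") <- as.character(substrate)
  attr(out, "isotopologue") <- as.character(isotopologue)
  class(out) <- c("temperature_rate_series", "data.frame")
  out
}

#' Excitation-emission matrix (EEM)
#'
#' @param excitation excitation wavelengths, nm (rows of `intensity`)
#' @param emission emission wavelengths, nm (columns of `intensity`)
#' @param intensity non-negative matrix, excitation x emission
#' @param label free-text label
#' @return object of class `eem`
#' @export
eem <- function(excitation, emission, intensity, label = "") {
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(excitation) ||
      ncol(intensity) != length(emission))
    .stopf("intensity matrix is %dx%d but wavelength vectors imply %dx%d",
           nrow(intensity), ncol(intensity),
           length(excitation), length(emission))
  if (anyNA(intensity)) .stopf("missing values in EEM intensity")
  tot <- rowSums(intensity)
  if (any(tot <= 0))
    .stopf("excitation row at %g nm has nonpositive total intensity",
           excitation[which(tot <= 0)[1]])
  structure(list(excitation = as.numeric(excitation),
                 emission = as.numeric(emission),
                 intensity = intensity, label = as.character(label)),
            class = "eem")
}

#' Coordinate ensemble (frames x atoms x 3)
#'
#' @param coords numeric array, frames x atoms x 3, Angstrom
#' @param atom_names character, one per atom
#' @param residue_ids integer residue numbers (1-based, PDB convention)
#' @param residue_names character residue names
#' @param chain_ids character chain identifiers (monomer labels)
#' @param frame_times optional frame times, ns
#' @return object of class `coord_ensemble`
#' @export
coord_ensemble <- function(coords, atom_names = NULL, residue_ids = NULL,
                           residue_names = NULL, chain_ids = NULL,
                           frame_times = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    .stopf("coords must be a frames x atoms x 3 array")
  n_atoms <- dim(coords)[2]
  if (is.null(atom_names)) atom_names <- rep("CA", n_atoms)
  if (is.null(residue_ids)) residue_ids <- seq_len(n_atoms)
  if (is.null(residue_names)) residue_names <- rep("ALA", n_atoms)
  if (is.null(chain_ids)) chain_ids <- rep("A", n_atoms)
  for (v in list(atom_names, residue_ids, residue_names, chain_ids))
    if (length(v) != n_atoms) .stopf("atom annotation length != atom count")
  if (!is.null(frame_times) && length(frame_times) != dim(coords)[1])
    .stopf("frame_times length != frame count")
  structure(list(coords = coords,
                 atom_names = as.character(atom_names),
                 residue_ids = as.integer(residue_ids),
                 residue_names = as.character(residue_names),
                 chain_ids = as.character(chain_ids),
                 frame_times = frame_times),
            class = "coord_ensemble")
}

#' @export
print.coord_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("Coordinate ensemble: %d frames, %d atoms, %d chains\n",
              d[1], d[2], length(unique(x$chain_ids))))
  invisible(x)
}

#' Number of frames in a coordinate ensemble
#' @param x a `coord_ensemble`
#' @return integer frame count
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' Subset the atoms of a coordinate ensemble
#'
#' @param x a `coord_ensemble`
#' @param atom_names keep atoms whose name is in this set (NULL = all)
#' @param residue_ids keep atoms whose residue number is in this set
#' @param chain_ids keep atoms whose chain is in this set
#' @param atoms explicit atom indices (applied after the name filters)
#' @return a `coord_ensemble` restricted to the selection
#' @export
select_atoms <- function(x, atom_names = NULL, residue_ids = NULL,
                         chain_ids = NULL, atoms = NULL) {
  keep <- rep(TRUE, length(x$atom_names))
  if (!is.null(atom_names)) keep <- keep & x$atom_names %in% atom_names
  if (!is.null(residue_ids)) keep <- keep & x$residue_ids %in% residue_ids
  if (!is.null(chain_ids)) keep <- keep & x$chain_ids %in% chain_ids
  idx <- which(keep)
  if (!is.null(atoms)) idx <- intersect(idx, atoms)
  if (length(idx) == 0) .stopf("atom selection is empty")
  coord_ensemble(x$coords[, idx, , drop = FALSE],
                 x$atom_names[idx], x$residue_ids[idx],
                 x$residue_names[idx], x$chain_ids[idx], x$frame_times)
}
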