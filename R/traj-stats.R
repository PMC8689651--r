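# Fluctuation and correlation statistics on aligned coordinate ensembles.

#' Root-mean-square fluctuations of an aligned ensemble
#'
#' Per atom: `RMSF_i = sqrt(mean_f |r_i(f) - <r_i>|^2)`. With
#' `group_by = "residue"` per-residue values are the mean over that
#' residue's selected atoms. With `average_chains = TRUE` the chains are
#' mapped onto a common residue numbering (by position along each chain)
#' and averaged to a single monomer profile; chains of unequal length are
#' an error rather than a silent truncation.
#'
#' @param x an aligned `coord_ensemble` (see [average_structure()]); a
#'   warning is issued if the ensemble does not carry the aligned flag
#' @param sel optional atom indices to restrict to (e.g. CA atoms)
#' @param group_by "atom" or "residue"
#' @param average_chains collapse all chains to one monomer profile
#' @return data frame with `residue` (or `atom`), `chain` and `rmsf`
#'   (Angstrom); for `average_chains = TRUE`, `position` and `rmsf`
#' @export
rmsf <- function(x, sel = NULL, group_by = c("residue", "atom"),
                 average_chains = FALSE) {
  stopifnot(inherits(x, "coord_ensemble"))
  group_by <- match.arg(group_by)
  if (!isTRUE(attr(x, "aligned")))
    .warnf("ensemble is not flagged as aligned; RMSF includes rigid-body motion")
  if (!is.null(sel)) {
    if (length(sel) == 0) .stopf("empty selection")
    x <- select_atoms(x, atoms = sel)
  }
  co <- x$coords
  mean_pos <- apply(co, c(2, 3), mean)
  dev2 <- sweep(co, c(2, 3), mean_pos)^2
  per_atom <- sqrt(apply(dev2, 2, mean) * 3)  # mean over frames of summed sq
  # apply over margin 2 averages frames AND xyz; multiply by 3 to recover
  # the per-frame squared displacement mean
  if (group_by == "atom" && !average_chains) {
    return(data.frame(atom = seq_along(per_atom), chain = x$chain_ids,
                      residue = x$residue_ids, rmsf = per_atom))
  }
  key <- paste(x$chain_ids, x$residue_ids, sep = ":")
  agg <- tapply(per_atom, key, mean)
  parts <- do.call(rbind, strsplit(names(agg), ":", fixed = TRUE))
  out <- data.frame(chain = parts[, 1], residue = as.integer(parts[, 2]),
                    rmsf = as.numeric(agg))
  out <- out[order(out$chain, out$residue), ]
  rownames(out) <- NULL
  if (!average_chains) return(out)
  chains <- split(out, out$chain)
  lens <- vapply(chains, nrow, integer(1))
  if (length(unique(lens)) > 1)
    .stopf("chains have unequal residue counts (%s); cannot average monomers",
           paste(lens, collapse = ", "))
  mat <- vapply(chains, function(ch) ch$rmsf[order(ch$residue)],
                numeric(lens[1]))
  data.frame(position = seq_len(lens[1]),
             rmsf = rowMeans(as.matrix(mat)))
}

#' Per-residue two-tailed Welch t-tests between RMSF replicate sets
#'
#' Compares two groups of replicate RMSF profiles (e.g. from independent
#' simulations) residue by residue with a two-sample, two-tailed Welch
#' t-test, and reports Benjamini-Hochberg adjusted p-values alongside the
#' raw ones. Residues with zero variance in both groups get `p = 1` and
#' a flag.
#'
#' @param a matrix of RMSF profiles for group A, residues x replicates
#'   (at least 2 columns)
#' @param b matrix for group B, same residue count
#' @return data frame with `residue`, `t`, `p`, `p_adj`, `zero_var`
#' @export
rmsf_difference_test <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) .stopf("profiles have different residue counts")
  if (ncol(a) < 2 || ncol(b) < 2) .stopf("need at least 2 replicates per group")
  n <- nrow(a)
  t_stat <- p <- numeric(n); zero_var <- logical(n)
  for (i in seq_len(n)) {
    if (stats::var(a[i, ]) == 0 && stats::var(b[i, ]) == 0) {
      zero_var[i] <- TRUE; t_stat[i] <- 0; p[i] <- 1
    } else {
      tt <- stats::t.test(a[i, ], b[i, ], alternative = "two.sided",
                          var.equal = FALSE)
      t_stat[i] <- unname(tt$statistic); p[i] <- tt$p.value
    }
  }
  data.frame(residue = seq_len(n), t = t_stat, p = p,
             p_adj = stats::p.adjust(p, method = "BH"), zero_var = zero_var)
}

#' Dynamical cross-correlation matrix
#'
#' Isotropic (dot-product) definition:
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)`, with `dr` the
#' deviation from the time-mean position after alignment. The result is
#' symmetric, has unit diagonal and entries in [-1, 1]. Atoms with zero
#' variance get zero off-diagonal entries and are flagged.
#'
#' @param x an aligned `coord_ensemble`
#' @param sel optional atom indices (conventionally one atom, e.g. CA,
#'   per residue)
#' @return matrix of class `dccm_matrix` with residue ids as dimnames and
#'   attributes `residue_ids`, `chain_ids`, `zero_variance`
#' @export
dccm <- function(x, sel = NULL) {
  stopifnot(inherits(x, "coord_ensemble"))
  if (!isTRUE(attr(x, "aligned")))
    .warnf("ensemble is not flagged as aligned; DCCM includes rigid-body motion")
  if (!is.null(sel)) x <- select_atoms(x, atoms = sel)
  co <- x$coords
  d <- dim(co)
  mean_pos <- apply(co, c(2, 3), mean)
  dev <- sweep(co, c(2, 3), mean_pos)
  # <dr_i . dr_j> = (1/F) sum_f sum_xyz dev[f,i,ax]*dev[f,j,ax]
  flat <- matrix(dev, nrow = d[1])            # frames x (atoms*3)
  cross <- matrix(0, d[2], d[2])
  for (ax in 1:3) {
    m <- flat[, ((ax - 1) * d[2] + 1):(ax * d[2]), drop = FALSE]
    cross <- cross + crossprod(m) / d[1]
  }
  v <- diag(cross)
  zero <- v < .Machine$double.eps
  denom <- sqrt(outer(pmax(v, .Machine$double.eps),
                      pmax(v, .Machine$double.eps)))
  C <- cross / denom
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  dimnames(C) <- list(x$residue_ids, x$residue_ids)
  structure(C, class = c("dccm_matrix", "matrix"),
            residue_ids = x$residue_ids, chain_ids = x$chain_ids,
            zero_variance = which(zero))
}

#' @export
print.dccm_matrix <- function(x, ...) {
  cat(sprintf("DCCM: %d x %d, range [%.3f, %.3f]\n", nrow(x), ncol(x),
              min(x), max(x)))
  invisible(x)
}

#' Per-frame donor-acceptor distances
#'
#' Euclidean distance between two atoms in every frame (e.g. the hydride
#' donor C1 of a pyranose ring and the acceptor C4 of the nicotinamide
#' ring), plus a fixed-width histogram.
#'
#' @param x a `coord_ensemble`
#' @param donor atom index of the donor
#' @param acceptor atom index of the acceptor
#' @param bin_width histogram bin width, Angstrom
#' @return list with `distances` (per frame, Angstrom), `histogram`
#'   (data frame of `mid`, `count`)
#' @export
donor_acceptor_distances <- function(x, donor, acceptor, bin_width = 0.1) {
  stopifnot(inherits(x, "coord_ensemble"))
  n_at <- dim(x$coords)[2]
  for (a in c(donor, acceptor))
    if (a < 1 || a > n_at) .stopf("atom index %d not present (1..%d)", a, n_at)
  dvec <- x$coords[, donor, , drop = FALSE] - x$coords[, acceptor, , drop = FALSE]
  distances <- sqrt(apply(dvec^2, 1, sum))
  lo <- floor(min(distances) / bin_width) * bin_width
  breaks <- seq(lo, max(distances) + bin_width, by = bin_width)
  h <- graphics::hist(distances, breaks = breaks, plot = FALSE)
  list(distances = distances,
       histogram = data.frame(mid = h$mids, count = h$counts))
}

#' Hydrogen-bond occupancy over an ensemble
#'
#' A frame counts as bonded when the donor-heavy-atom to acceptor
#' distance is at most `dist_cutoff` and the donor-H...acceptor angle is
#' at least `angle_cutoff` degrees. Defaults (3.0 Angstrom, 135 degrees)
#' are common trajectory-analysis settings and fully configurable.
#'
#' @param x a `coord_ensemble`
#' @param donor index of the donor heavy atom
#' @param hydrogen index of the donor hydrogen (set `angle_cutoff = NULL`
#'   to skip the angular criterion and omit the hydrogen)
#' @param acceptor index of the acceptor atom
#' @param dist_cutoff heavy-atom distance cutoff, Angstrom
#' @param angle_cutoff D-H...A angle cutoff, degrees in (0, 180], or NULL
#' @return list with `occupancy` (fraction in [0, 1]) and `flags`
#'   (per-frame logical)
#' @export
hbond_occupancy <- function(x, donor, acceptor, hydrogen = NULL,
                            dist_cutoff = 3.0, angle_cutoff = 135) {
  stopifnot(inherits(x, "coord_ensemble"), dist_cutoff > 0)
  if (!is.null(angle_cutoff)) {
    if (angle_cutoff <= 0 || angle_cutoff > 180)
      .stopf("angle cutoff must be in (0, 180]")
    if (is.null(hydrogen))
      .stopf("angle criterion enabled but no donor hydrogen given")
  }
  n_at <- dim(x$coords)[2]
  for (a in c(donor, acceptor, hydrogen))
    if (a < 1 || a > n_at) .stopf("atom index %d not present (1..%d)", a, n_at)
  D <- x$coords[, donor, , drop = FALSE]
  A <- x$coords[, acceptor, , drop = FALSE]
  dist_ok <- sqrt(apply((D - A)^2, 1, sum)) <= dist_cutoff
  flags <- dist_ok
  if (!is.null(angle_cutoff)) {
    H <- x$coords[, hydrogen, , drop = FALSE]
    v1 <- D - H; v2 <- A - H   # angle at the hydrogen
    dotp <- apply(v1 * v2, 1, sum)
    ang <- acos(pmin(pmax(dotp / (sqrt(apply(v1^2, 1, sum)) *
                                    sqrt(apply(v2^2, 1, sum))), -1), 1)) *
      180 / pi
    flags <- flags & (ang >= angle_cutoff)
  }
  list(occupancy = mean(flags), flags = flags)
}
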