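# Seed-deterministic synthetic-data generators for every input class the
# pipeline consumes. Each generator draws its randomness through a
# per-point (or per-frame) seed split, so extending a grid never
# reshuffles earlier points, and attaches a manifest sufficient to
# regenerate the data bit-identically.

#' Generate a synthetic stopped-flow transient
#'
#' Clean values come from [eval_transient()]; noise is applied per point.
#'
#' @param phases list of per-phase parameter vectors, each with named
#'   elements `A` (AU), `k` (s^-1) and optionally `b` (default 1)
#' @param offset baseline absorbance, AU
#' @param times time grid, seconds
#' @param noise_sd noise sigma (absolute AU for additive noise)
#' @param noise_kind "additive-gaussian" (default for absorbance data) or
#'   "multiplicative-lognormal"
#' @param temperature kelvin, stored as metadata
#' @param label free-text label
#' @param seed integer seed
#' @return an `absorbance_transient` with a `manifest` attribute
#' @export
gen_transient <- function(phases, offset = 0, times = seq(0, 2, length.out = 500),
                          noise_sd = 0, noise_kind = "additive-gaussian",
                          temperature = 298.15, label = "synthetic", seed = 1) {
  A <- vapply(phases, function(p) p[["A"]], numeric(1))
  k <- vapply(phases, function(p) p[["k"]], numeric(1))
  b <- vapply(phases, function(p) if ("b" %in% names(p)) p[["b"]] else 1,
              numeric(1))
  clean <- eval_transient(times, A, k, b, offset)
  y <- .apply_noise(clean, noise_kind, noise_sd, seed)
  out <- absorbance_transient(times, y, temperature = temperature,
                              label = label)
  attr(out, "manifest") <- .manifest("gen_transient",
    list(phases = phases, offset = offset, times = range(times),
         n = length(times), noise_sd = noise_sd, noise_kind = noise_kind),
    seed)
  out
}

#' Generate a synthetic Michaelis-Menten concentration series
#'
#' @param kcat turnover number, s^-1
#' @param Km Michaelis constant, mM
#' @param Ki substrate-inhibition constant, mM, or NULL
#' @param enzyme_conc enzyme concentration (Vmax = kcat * enzyme_conc)
#' @param conc substrate concentration grid, mM
#' @param temperature kelvin
#' @param substrate,isotopologue labels
#' @param noise_sd relative sigma of the multiplicative log-normal noise
#' @param seed integer seed
#' @return a `rate_conc_series` with a `manifest` attribute
#' @export
gen_mm_series <- function(kcat, Km, Ki = NULL, enzyme_conc = 1,
                          conc = c(0.1, 0.25, 0.5, 1, 2, 4, 8, 12, 16, 20),
                          temperature = 348.15, substrate = "",
                          isotopologue = "H", noise_sd = 0, seed = 1) {
  clean <- eval_michaelis(conc, Vmax = kcat * enzyme_conc, Km = Km, Ki = Ki)
  v <- .apply_noise(clean, "multiplicative-lognormal", noise_sd, seed)
  out <- rate_conc_series(conc, v, temperature = temperature,
                          enzyme_conc = enzyme_conc, substrate = substrate,
                          isotopologue = isotopologue)
  attr(out, "manifest") <- .manifest("gen_mm_series",
    list(kcat = kcat, Km = Km, Ki = Ki, enzyme_conc = enzyme_conc,
         conc = conc, noise_sd = noise_sd), seed)
  out
}

#' Generate a synthetic MMRT temperature-rate series
#'
#' The activation entropy is not taken as an input: it is solved
#' internally so that the noiseless model passes exactly through the
#' anchor point `(anchor_T, anchor_k)`. Anchoring the intercept through a
#' known rate avoids committing to any particular entropy convention.
#'
#' @param dH_T0 activation enthalpy at `T0`, kJ mol^-1
#' @param dCp heat capacity of activation, kJ mol^-1 K^-1
#' @param T0 reference temperature, kelvin
#' @param anchor_T anchor temperature, kelvin
#' @param anchor_k rate at the anchor temperature, s^-1
#' @param temperatures temperature grid, kelvin
#' @param noise_sd relative sigma of multiplicative log-normal rate noise
#' @param substrate,isotopologue labels
#' @param seed integer seed
#' @return a `temperature_rate_series` with a `manifest` attribute; the
#'   solved `dS_T0` is recorded in the manifest
#' @export
gen_mmrt_series <- function(dH_T0, dCp, T0 = 348, anchor_T = 348,
                            anchor_k = 10,
                            temperatures = seq(293, 358, length.out = 14),
                            noise_sd = 0, substrate = "", isotopologue = "H",
                            seed = 1) {
  stopifnot(anchor_k > 0, all(temperatures > 0))
  # ln k is affine in dS_T0 with slope 1000/R
  lnk0 <- mmrt_ln_rate(mmrt_params(dH_T0, 0, dCp, T0), anchor_T)
  dS_T0 <- (log(anchor_k) - lnk0) * .Rgas / 1000
  params <- mmrt_params(dH_T0, dS_T0, dCp, T0)
  k_clean <- exp(mmrt_ln_rate(params, temperatures))
  k <- .apply_noise(k_clean, "multiplicative-lognormal", noise_sd, seed)
  out <- temperature_rate_series(temperatures, k, substrate = substrate,
                                 isotopologue = isotopologue)
  attr(out, "manifest") <- .manifest("gen_mmrt_series",
    list(dH_T0 = dH_T0, dS_T0 = dS_T0, dCp = dCp, T0 = T0,
         anchor_T = anchor_T, anchor_k = anchor_k,
         temperatures = temperatures, noise_sd = noise_sd), seed)
  attr(out, "true_params") <- params
  out
}

# discrete CSM of a Gaussian band on the emission grid, as a function of
# the band center
.gauss_csm <- function(center, emission, width) {
  f <- exp(-0.5 * ((emission - center) / width)^2)
  sum(f * emission) / sum(f)
}

#' Generate a synthetic excitation-emission matrix with QUBES structure
#'
#' Each excitation row is a Gaussian emission band whose center is solved
#' numerically so that the row's discrete CSM equals
#' `csm0 + A * exp(R * (lEx - min(lEx)))` exactly at zero noise (the
#' finite emission window shifts the CSM of a truncated Gaussian away
#' from its center, so the center cannot simply be set to the target).
#'
#' @param csm0 baseline CSM, nm
#' @param A amplitude, nm
#' @param R curvature, nm^-1 (positive)
#' @param width Gaussian band SD, nm
#' @param excitation excitation grid, nm
#' @param emission emission grid, nm
#' @param peak_intensity maximum intensity, arbitrary units
#' @param noise_sd absolute sigma of additive Gaussian intensity noise
#'   (negative values are clipped at 0)
#' @param label free-text label
#' @param seed integer seed
#' @return an `eem` with a `manifest` attribute
#' @export
gen_eem <- function(csm0, A, R, width = 25, excitation = 292:310,
                    emission = 325:500, peak_intensity = 1000,
                    noise_sd = 0, label = "synthetic", seed = 1) {
  stopifnot(width > 0, R > 0)
  dl <- excitation - min(excitation)
  targets <- csm0 + A * exp(R * dl)
  if (any(targets <= min(emission) | targets >= max(emission)))
    .stopf("target CSM outside the emission window")
  intensity <- matrix(0, length(excitation), length(emission))
  for (i in seq_along(excitation)) {
    center <- stats::uniroot(function(c0) .gauss_csm(c0, emission, width) -
                               targets[i],
                             interval = range(emission) + c(-200, 200),
                             tol = 1e-12)$root
    row <- peak_intensity * exp(-0.5 * ((emission - center) / width)^2)
    if (noise_sd > 0) {
      row <- .with_point_seed(seed, i,
                              row + stats::rnorm(length(row), 0, noise_sd))
      row[row < 0] <- 0
    }
    intensity[i, ] <- row
  }
  out <- eem(excitation, emission, intensity, label = label)
  attr(out, "manifest") <- .manifest("gen_eem",
    list(csm0 = csm0, A = A, R = R, width = width,
         excitation = range(excitation), emission = range(emission),
         noise_sd = noise_sd), seed)
  out
}

# per-frame random rotation matrix with angle ~ N(0, sd) degrees about a
# random axis
.small_rotation <- function(angle_sd_deg) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::rnorm(1, 0, angle_sd_deg * pi / 180)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

#' Generate a synthetic coordinate ensemble
#'
#' Frames are the reference structure plus correlated Gaussian
#' displacements built from a one-factor-per-axis model: atoms inside a
#' block share a common factor with weight `sqrt(corr)` (signed per
#' block, so blocks with opposite signs are anticorrelated), plus
#' independent noise with weight `sqrt(1 - corr)`. This construction is
#' positive semidefinite for any block layout. Optional per-frame
#' rigid-body motion and a two-pose substrate orientation mixture can be
#' layered on top.
#'
#' @param reference atoms x 3 coordinate matrix, Angstrom
#' @param n_frames number of frames
#' @param blocks list of blocks, each `list(atoms = indices, corr = rho in
#'   [0, 1), sign = +1 or -1, amplitude = per-axis displacement SD in
#'   Angstrom)`; atoms outside every block move independently with
#'   `base_amplitude`
#' @param base_amplitude per-axis displacement SD for unblocked atoms
#' @param rigid_body optional `list(angle_sd = degrees, trans_sd =
#'   Angstrom)` random rigid-body motion applied per frame
#' @param orientation_mixture optional `list(atoms = indices, pose =
#'   replacement coordinates for those atoms, fraction = probability of
#'   the reference pose)`; each frame keeps the reference pose with the
#'   given probability and takes the displaced pose otherwise
#' @param atom_names,residue_ids,residue_names,chain_ids optional atom
#'   annotations passed to [coord_ensemble()]
#' @param seed integer seed
#' @return a `coord_ensemble` with a `manifest` attribute and a
#'   `pose_labels` attribute (1 = reference pose, 2 = displaced) when an
#'   orientation mixture is used
#' @export
gen_ensemble <- function(reference, n_frames, blocks = NULL,
                         base_amplitude = 0.3, rigid_body = NULL,
                         orientation_mixture = NULL,
                         atom_names = NULL, residue_ids = NULL,
                         residue_names = NULL, chain_ids = NULL, seed = 1) {
  reference <- as.matrix(reference)
  stopifnot(ncol(reference) == 3, n_frames >= 1)
  n_at <- nrow(reference)
  amp <- rep(base_amplitude, n_at)
  block_of <- rep(0L, n_at)
  if (!is.null(blocks)) {
    for (bi in seq_along(blocks)) {
      bl <- blocks[[bi]]
      stopifnot(bl$corr >= 0, bl$corr < 1)
      block_of[bl$atoms] <- bi
      amp[bl$atoms] <- if (!is.null(bl$amplitude)) bl$amplitude else base_amplitude
    }
  }
  coords <- array(NA_real_, dim = c(n_frames, n_at, 3))
  pose_labels <- rep(1L, n_frames)
  for (f in seq_len(n_frames)) {
    res <- .with_point_seed(seed, f, {
      pose <- 1L
      base <- reference
      if (!is.null(orientation_mixture)) {
        if (stats::runif(1) > orientation_mixture$fraction) {
          base[orientation_mixture$atoms, ] <- orientation_mixture$pose
          pose <- 2L
        }
      }
      disp <- matrix(0, n_at, 3)
      for (ax in 1:3) {
        g <- stats::rnorm(1)  # shared factor for this axis
        e <- stats::rnorm(n_at)
        w_shared <- numeric(n_at); w_ind <- rep(1, n_at)
        for (bi in seq_along(blocks)) {
          bl <- blocks[[bi]]
          idx <- bl$atoms
          sgn <- if (!is.null(bl$sign)) bl$sign else 1
          w_shared[idx] <- sgn * sqrt(bl$corr)
          w_ind[idx] <- sqrt(1 - bl$corr)
        }
        disp[, ax] <- amp * (w_shared * g + w_ind * e)
      }
      fr <- base + disp
      if (!is.null(rigid_body)) {
        rot <- .small_rotation(rigid_body$angle_sd)
        tr <- stats::rnorm(3, 0, rigid_body$trans_sd)
        cm <- colMeans(fr)
        fr <- sweep(sweep(fr, 2, cm) %*% t(rot), 2, cm + tr, "+")
      }
      list(fr = fr, pose = pose)
    })
    coords[f, , ] <- res$fr
    pose_labels[f] <- res$pose
  }
  out <- coord_ensemble(coords, atom_names, residue_ids, residue_names,
                        chain_ids)
  attr(out, "manifest") <- .manifest("gen_ensemble",
    list(n_atoms = n_at, n_frames = n_frames, blocks = blocks,
         base_amplitude = base_amplitude, rigid_body = rigid_body,
         mixture_fraction = orientation_mixture$fraction), seed)
  if (!is.null(orientation_mixture)) attr(out, "pose_labels") <- pose_labels
  out
}
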