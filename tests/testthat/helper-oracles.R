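# Independent brute-force oracles and small fixture builders. These are
# deliberately naive (plain loops, textbook formulas) so they stay
# independent of the vectorised implementations they check.

naive_rmsf <- function(coords) {
  # coords: frames x atoms x 3
  n_at <- dim(coords)[2]
  out <- numeric(n_at)
  for (i in seq_len(n_at)) {
    xyz <- coords[, i, , drop = FALSE]
    mu <- c(mean(xyz[, 1, 1]), mean(xyz[, 1, 2]), mean(xyz[, 1, 3]))
    s <- 0
    for (f in seq_len(dim(coords)[1]))
      s <- s + sum((coords[f, i, ] - mu)^2)
    out[i] <- sqrt(s / dim(coords)[1])
  }
  out
}

naive_dccm <- function(coords) {
  n_at <- dim(coords)[2]; n_fr <- dim(coords)[1]
  mu <- apply(coords, c(2, 3), mean)
  C <- matrix(0, n_at, n_at)
  for (i in seq_len(n_at)) for (j in seq_len(n_at)) {
    num <- 0; vi <- 0; vj <- 0
    for (f in seq_len(n_fr)) {
      di <- coords[f, i, ] - mu[i, ]; dj <- coords[f, j, ] - mu[j, ]
      num <- num + sum(di * dj)
      vi <- vi + sum(di * di); vj <- vj + sum(dj * dj)
    }
    C[i, j] <- num / sqrt(vi * vj)
  }
  C
}

# naive average-linkage agglomeration; returns merge heights in order
naive_average_linkage_heights <- function(dmat) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- mean(dmat[clusters[[a]], clusters[[b]]])
      if (dd < best_d) { best_d <- dd; best <- c(a, b) }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# random non-degenerate reference coordinates
make_ref_coords <- function(n_atoms, seed = 1, spread = 5) {
  set.seed(seed)
  matrix(rnorm(n_atoms * 3, sd = spread), n_atoms, 3)
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

make_csm_curve <- function(excitation, csm, label = "") {
  out <- data.frame(excitation = excitation, csm = csm)
  attr(out, "label") <- label
  class(out) <- c("csm_curve", "data.frame")
  out
}

# reference study-condition parameters used by generator-based checks
tab1 <- list(
  glucose   = list(kcat_min = 651.9, Km = 1.0,  dH = 54.7, dCp = -3.0),
  galactose = list(kcat_min = 613.4, Km = 1.0,  dH = 67.9, dCp = -1.1),
  deoxy4    = list(kcat_min = 761.4, Km = 15.04, dH = 70.4, dCp = 1.4,
                   Ki = 29.5)
)
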