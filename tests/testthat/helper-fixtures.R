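# Shared fixtures and independent oracle implementations. Oracles are
# deliberately written as plain, brute-force computations so they stay
# independent of the package code paths they check.

# independent mass table (same physical constants, separate object)
oracle_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, K = 39.098)

# minimal hand-built frame: a helix-like two-chain toy with a HIS at
# (A, 122) used by parser round-trip tests
toy_two_chain_frame <- function() {
  atoms <- data.frame(
    chain_id = c("A", "A", "A", "A", "B", "B"),
    resseq = c(122L, 122L, 122L, 130L, 122L, 130L),
    resname = c("HIS", "HIS", "HIS", "GLY", "HIS", "GLY"),
    atom_name = c("CA", "ND1", "NE2", "CA", "CA", "CA"),
    element = c("C", "N", "N", "C", "C", "C"),
    x = c(0, 1.5, 2.5, 3, -1, -3),
    y = c(0, 0.5, -0.5, 1, 0.2, -1),
    z = c(0, 1, 1.2, 2, 0.5, -2),
    stringsAsFactors = FALSE
  )
  structure_frame(atoms)
}

# random single-residue pair frame for geometry oracles
random_geometry_frame <- function(rng) {
  coords <- matrix(rng$runif(3 * 9, -10, 10), ncol = 3)
  atoms <- data.frame(
    chain_id = "A",
    resseq = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 67L, 171L),
    resname = c("HIS", "HIS", "HIS", "HIS", "GLU", "GLU", "GLU",
                "HIS", "ARG"),
    atom_name = c("CA", "ND1", "NE2", "CB", "CA", "CB", "OE1",
                  "CA", "CA"),
    element = c("C", "N", "N", "C", "C", "C", "O", "C", "C"),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE
  )
  structure_frame(atoms)
}

# brute-force mass-weighted side-chain COM (independent implementation)
oracle_sidechain_com <- function(frame, chain, resseq) {
  a <- frame$atoms
  sel <- a$chain_id == chain & a$resseq == resseq &
    !(a$atom_name %in% c("N", "CA", "C", "O", "OXT")) & a$element != "H"
  rows <- a[sel, , drop = FALSE]
  m <- oracle_masses[rows$element]
  c(sum(rows$x * m), sum(rows$y * m), sum(rows$z * m)) / sum(m)
}

# independent angle computation from raw coordinates
oracle_angle <- function(axis, ca, p1, p2) {
  mid <- (p1 + p2) / 2
  v <- mid - ca
  acos(sum(v * axis) / sqrt(sum(v^2)) / sqrt(sum(axis^2))) * 180 / pi
}

# rigid-body motion: random rotation (QR of a Gaussian matrix) and
# translation applied to every atom of a frame
apply_rigid_motion <- function(frame, rng) {
  m <- matrix(rng$rnorm(9), 3, 3)
  qrd <- qr(m)
  R <- qr.Q(qrd)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t_vec <- rng$runif(3, -20, 20)
  xyz <- as.matrix(frame$atoms[, c("x", "y", "z")]) %*% t(R)
  frame$atoms$x <- xyz[, 1] + t_vec[1]
  frame$atoms$y <- xyz[, 2] + t_vec[2]
  frame$atoms$z <- xyz[, 3] + t_vec[3]
  frame
}

# brute-force exact titration oracle: literal loop over all microstates
oracle_microstate_theta <- function(intrinsic, site_class, W, pH) {
  n <- length(intrinsic)
  states <- expand.grid(rep(list(0:1), n))
  weights <- numeric(nrow(states))
  for (s in seq_len(nrow(states))) {
    x <- as.numeric(states[s, ])
    q <- ifelse(site_class == "acid", x - 1, x)
    G <- sum(x * (pH - intrinsic))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        G <- G + W[i, j] * q[i] * q[j]
      }
    }
    weights[s] <- 10^(-G)
  }
  p <- weights / sum(weights)
  vapply(seq_len(n), function(i) sum(as.numeric(states[, i]) * p),
         numeric(1))
}

# build a small TitrationSystem directly from an explicit coupling matrix
make_system <- function(resnames, intrinsic, W, temperature = 310) {
  sites <- data.frame(chain_id = "A",
                      resseq = seq_along(resnames) * 10L,
                      resname = resnames,
                      intrinsic_pKa = intrinsic,
                      stringsAsFactors = FALSE)
  titration_system(sites, couplings = W, temperature = temperature)
}

local_rng <- function(seed) titrascape:::new_rng(seed)

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
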