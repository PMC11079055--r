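# Synthetic stand-ins for microsecond-scale MD: a two-subunit toy channel
# scaffold carrying the residues tracked by the analysis, a hidden-Markov
# conformational trajectory generator whose per-frame side-chain placements
# realize configured distance/angle distributions exactly, and random
# coupled titratable-site systems.
#
# The generator makes no attempt at per-atom physical realism: only the
# metrics the downstream stages compute (side-chain COM distances, the
# residue-122 orientation angle, the principal axis, the length proxy)
# match their configured targets.

# Side-chain heavy-atom templates: offsets from CA, Angstrom. Geometry is
# schematic but respects which atoms exist for each residue type.
SIDECHAIN_TEMPLATES <- list(
  SER = rbind(CB = c(1.2, 0.6, 0.4), OG = c(2.2, 1.0, 0.8)),
  PHE = rbind(CB = c(1.2, 0.6, 0.3), CG = c(2.4, 1.0, 0.5),
              CD1 = c(3.2, 0.2, 0.8), CD2 = c(2.9, 2.2, 0.6),
              CE1 = c(4.4, 0.5, 1.0), CE2 = c(4.1, 2.5, 0.8),
              CZ = c(4.9, 1.7, 1.0)),
  HIS = rbind(CB = c(1.2, 0.6, 0.3), CG = c(2.4, 1.0, 0.6),
              ND1 = c(3.2, 0.2, 1.1), CD2 = c(2.9, 2.2, 0.7),
              CE1 = c(4.4, 0.8, 1.2), NE2 = c(4.2, 2.1, 0.9)),
  ASN = rbind(CB = c(1.2, 0.6, 0.3), CG = c(2.4, 1.0, 0.6),
              OD1 = c(3.1, 0.2, 1.0), ND2 = c(3.0, 2.1, 0.8)),
  ASP = rbind(CB = c(1.2, 0.6, 0.3), CG = c(2.4, 1.0, 0.6),
              OD1 = c(3.1, 0.2, 1.0), OD2 = c(3.0, 2.1, 0.8)),
  GLU = rbind(CB = c(1.2, 0.6, 0.3), CG = c(2.4, 1.0, 0.6),
              CD = c(3.6, 1.4, 0.9), OE1 = c(4.3, 0.6, 1.3),
              OE2 = c(4.2, 2.5, 1.0)),
  LYS = rbind(CB = c(1.2, 0.6, 0.3), CG = c(2.4, 1.0, 0.6),
              CD = c(3.6, 1.4, 0.9), CE = c(4.8, 1.8, 1.2),
              NZ = c(6.0, 2.2, 1.5)),
  ARG = rbind(CB = c(1.2, 0.6, 0.3), CG = c(2.4, 1.0, 0.6),
              CD = c(3.6, 1.4, 0.9), NE = c(4.8, 1.8, 1.2),
              CZ = c(6.0, 2.2, 1.4), NH1 = c(6.8, 1.5, 1.8),
              NH2 = c(6.5, 3.4, 1.4))
)

# (resseq, resname, CA position in chain A). The scaffold's long axis is
# z; chain B is the C2 rotation about z, so the Calpha covariance is
# diagonal and the principal axis is exactly (0, 0, 1). His67 sits at the
# CAP apex (largest z), Arg171 at the intracellular end.
TOY_RESIDUES <- data.frame(
  resseq = c(67L, 86L, 106L, 109L, 122L, 131L, 171L, 230L, 235L, 246L),
  resname = c("HIS", "SER", "SER", "PHE", "HIS", "LYS", "ARG", "ASP",
              "GLU", "LYS"),
  ca_x = c(1.0, 4.5, 5.5, 5.0, 4.0, 6.0, 3.5, 5.0, 6.5, 6.0),
  ca_y = c(0.5, 2.0, -1.5, 1.0, 2.5, -2.0, 1.5, -1.0, 0.5, 2.5),
  ca_z = c(30, 18, 12, 10, 15, 14, -15, 13, 12, 10),
  stringsAsFactors = FALSE
)

element_of_atom <- function(name) toupper(substr(gsub("[0-9]", "", name),
                                                 1, 1))

build_residue_atoms <- function(chain_id, resseq, resname, ca) {
  bb <- rbind(N = ca + c(-1.2, 0.4, -0.5), CA = ca,
              C = ca + c(1.0, -0.9, -0.4), O = ca + c(1.4, -1.9, -0.9))
  sc <- sweep(SIDECHAIN_TEMPLATES[[resname]], 2L, ca, "+")
  atoms <- rbind(bb, sc)
  data.frame(chain_id = chain_id, resseq = resseq, resname = resname,
             atom_name = rownames(atoms),
             element = element_of_atom(rownames(atoms)),
             x = atoms[, 1], y = atoms[, 2], z = atoms[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the two-subunit toy channel scaffold
#'
#' A schematic homodimeric channel carrying, in each of chains A and B,
#' the residues the analyses track: His67 (CAP apex), Ser86, Ser106,
#' Phe109, His122 (the pH sensor; Asn122 when `variant = "H122N"`),
#' Lys131, Arg171 (intracellular anchor), Asp230, Glu235 and Lys246. Each
#' residue has a backbone (N, CA, C, O) and its side-chain heavy atoms
#' (ND1/NE2 for histidine, OD1/ND2 for asparagine, full heavy sets
#' otherwise). The scaffold's long axis lies on z, with chain B the C2
#' rotation of chain A about z.
#'
#' @param variant `"WT"` or `"H122N"`.
#' @return `StructureFrame`.
#' @export
build_toy_channel <- function(variant = c("WT", "H122N")) {
  variant <- match.arg(variant)
  res <- TOY_RESIDUES
  if (variant == "H122N") res$resname[res$resseq == 122L] <- "ASN"
  chain_a <- do.call(rbind, lapply(seq_len(nrow(res)), function(i) {
    build_residue_atoms("A", res$resseq[i], res$resname[i],
                        c(res$ca_x[i], res$ca_y[i], res$ca_z[i]))
  }))
  chain_b <- chain_a
  chain_b$chain_id <- "B"
  chain_b$x <- -chain_a$x
  chain_b$y <- -chain_a$y
  structure_frame(rbind(chain_a, chain_b), time_ns = 0)
}

#' Define a conformational state for the trajectory generator
#'
#' @param label state name (e.g. `"a"`, `"b"`, `"c"`, `"collapsed"`).
#' @param d_235_246,d_122_235 target side-chain COM distance means,
#'   Angstrom, for the Glu235-Lys246 and residue122-Glu235 pairs.
#' @param d_122_246 optional mean for the residue122-Lys246 pair; when
#'   `NULL` it is implied by placing residue 122 perpendicular to the
#'   Glu235-Lys246 axis.
#' @param dist_sd Gaussian sd of the sampled distances, Angstrom.
#' @param angle_mean,angle_sd residue-122 orientation angle target,
#'   degrees.
#' @param occupancy state probability (per condition; must sum to 1 over
#'   the states of a config).
#' @return list of class `ConformationalState`.
#' @export
conformational_state <- function(label, d_235_246, d_122_235,
                                 d_122_246 = NULL, dist_sd = 0.25,
                                 angle_mean = 80, angle_sd = 8,
                                 occupancy = 1) {
  stopifnot(dist_sd > 0, angle_sd > 0, occupancy >= 0,
            d_235_246 > 0, d_122_235 > 0)
  if (!is.null(d_122_246)) {
    a <- (d_122_235^2 + d_235_246^2 - d_122_246^2) / (2 * d_235_246)
    if (d_122_235^2 - a^2 < -1e-9) {
      stop(sprintf(
        "state '%s': distance triple (%.2f, %.2f, %.2f) violates the %s",
        label, d_235_246, d_122_235, d_122_246, "triangle inequality"))
    }
  }
  structure(list(label = label, d_235_246 = d_235_246,
                 d_122_235 = d_122_235, d_122_246 = d_122_246,
                 dist_sd = dist_sd, angle_mean = angle_mean,
                 angle_sd = angle_sd, occupancy = occupancy),
            class = "ConformationalState")
}

#' Generator configuration
#'
#' @param states list of [conformational_state()]s; occupancies must sum
#'   to 1.
#' @param n_frames number of frames (>= 1).
#' @param dt_ns frame spacing, ns (default 1).
#' @param switching_prob per-frame probability of redrawing the hidden
#'   state from the occupancy distribution (default 0.02, giving state
#'   dwell times of ~50 frames; the redraw may land on the same state, so
#'   the stationary distribution equals the occupancies).
#' @param noise_sd isotropic positional jitter applied to scaffold atoms
#'   (not to the placed side chains), Angstrom.
#' @param seed mandatory integer seed.
#' @param variant `"WT"` or `"H122N"`.
#' @param pH_label `"high"` or `"low"` condition tag.
#' @param replicate_id trajectory identifier.
#' @return list of class `GeneratorConfig`.
#' @export
generator_config <- function(states, n_frames, dt_ns = 1,
                             switching_prob = 0.02, noise_sd = 0.05,
                             seed, variant = "WT", pH_label = NA,
                             replicate_id = NA) {
  if (missing(seed)) stop("generator configs require an explicit seed")
  stopifnot(n_frames >= 1, switching_prob >= 0, switching_prob <= 1,
            noise_sd >= 0, length(states) >= 1)
  occ <- vapply(states, function(s) s$occupancy, numeric(1))
  if (abs(sum(occ) - 1) > 1e-9) {
    stop("state occupancies must sum to 1 (got ", sum(occ), ")")
  }
  structure(list(states = states, n_frames = as.integer(n_frames),
                 dt_ns = dt_ns, switching_prob = switching_prob,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 variant = variant, pH_label = pH_label,
                 replicate_id = replicate_id),
            class = "GeneratorConfig")
}

# Move a residue's side-chain heavy atoms rigidly so their mass-weighted
# COM lands on `target`. Operates on the frame's atom table in place.
place_sidechain_com <- function(atoms, chain_id, resseq, target) {
  in_res <- atoms$chain_id == chain_id & atoms$resseq == resseq
  sc <- in_res & !(atoms$atom_name %in% c("N", "CA", "C", "O", "OXT")) &
    atoms$element != "H"
  m <- ATOMIC_MASSES[atoms$element[sc]]
  com <- colSums(as.matrix(atoms[sc, c("x", "y", "z")]) * m) / sum(m)
  shift <- target - com
  atoms$x[sc] <- atoms$x[sc] + shift[1]
  atoms$y[sc] <- atoms$y[sc] + shift[2]
  atoms$z[sc] <- atoms$z[sc] + shift[3]
  atoms
}

# Place residue 122's side chain so that (i) the midpoint of its two
# reference atoms (ND1/NE2 or OD1/ND2) sits at `midpoint` and (ii) the
# side-chain COM sits at `com_target`. The reference atoms go at
# midpoint +/- delta; the remaining side-chain atoms are clustered around
# the point that balances the total COM.
place_sensor_sidechain <- function(atoms, chain_id, com_target, midpoint) {
  in_res <- atoms$chain_id == chain_id & atoms$resseq == 122L
  resname <- atoms$resname[in_res][1]
  pair <- DEFAULT_PAIR_MAP[[resname]]
  sc <- in_res & !(atoms$atom_name %in% c("N", "CA", "C", "O", "OXT")) &
    atoms$element != "H"
  sc_names <- atoms$atom_name[sc]
  masses <- ATOMIC_MASSES[atoms$element[sc]]
  is_pair <- sc_names %in% pair
  delta <- c(0.7, 0, 0)
  pair_pos <- rbind(midpoint + delta, midpoint - delta)
  m_pair <- sum(masses[is_pair])
  m_rest <- sum(masses[!is_pair])
  # COM of the pair atoms is `midpoint` (equal masses by construction of
  # the pair map: N/N or O/N, treated at their true masses here)
  pair_com <- colSums(pair_pos * masses[is_pair]) / m_pair
  rest_center <- (com_target * (m_pair + m_rest) - pair_com * m_pair) /
    m_rest
  # spread the remaining atoms around rest_center with zero-sum offsets
  n_rest <- sum(!is_pair)
  offsets <- matrix(0, n_rest, 3)
  if (n_rest > 1L) {
    ang <- 2 * pi * (seq_len(n_rest) - 1) / n_rest
    offsets <- 0.6 * cbind(cos(ang), sin(ang), 0)
    offsets <- sweep(offsets, 2L, colMeans(offsets))
  }
  xyz <- matrix(NA_real_, length(sc_names), 3)
  xyz[is_pair, ] <- pair_pos
  xyz[!is_pair, ] <- sweep(offsets, 2L, rest_center, "+")
  atoms$x[sc] <- xyz[, 1]
  atoms$y[sc] <- xyz[, 2]
  atoms$z[sc] <- xyz[, 3]
  atoms
}

#' Simulate a conformational trajectory
#'
#' Draws a hidden-Markov state sequence per subunit (each subunit is an
#' independent replicate), then realizes each frame on the toy channel
#' scaffold: the Glu235 and Lys246 side-chain COMs and the residue-122
#' side chain are placed so that the tracked pairwise distances and the
#' residue-122 orientation angle are Gaussian around the active state's
#' targets. Scaffold atoms receive isotropic jitter; Calpha positions stay
#' near their construction values so the principal axis remains stable.
#' Deterministic under a fixed seed; the hidden state sequence is attached
#' as attribute `"states"` (a data.frame) for recovery tests.
#'
#' @param config `GeneratorConfig`.
#' @return `Trajectory` with condition metadata from the config.
#' @export
simulate_conformational_trajectory <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  rng <- new_rng(config$seed)
  base <- build_toy_channel(config$variant)
  chains <- c("A", "B")
  n <- config$n_frames
  k <- length(config$states)
  occ <- vapply(config$states, function(s) s$occupancy, numeric(1))
  draw_chain_states <- function() {
    s <- integer(n)
    s[1] <- rng$sample_int(k, 1L, prob = occ)
    if (n > 1L) {
      flips <- rng$runif(n - 1L) < config$switching_prob
      redraws <- rng$sample_int(k, n - 1L, replace = TRUE, prob = occ)
      for (i in 2:n) s[i] <- if (flips[i - 1L]) redraws[i - 1L] else s[i - 1L]
    }
    s
  }
  state_seq <- lapply(chains, function(ch) draw_chain_states())
  names(state_seq) <- chains
  # anchors: construction-time COMs/CA positions per chain
  anchors <- lapply(chains, function(ch) {
    ca122 <- as.numeric(select_atoms(base, ch, 122L, "CA")[1, c("x", "y", "z")])
    e_com <- sidechain_com(base, ch, 235L)
    list(ca122 = ca122, e_com = e_com,
         lat = if (ch == "A") c(1, 0, 0) else c(-1, 0, 0))
  })
  names(anchors) <- chains
  frames <- vector("list", n)
  for (f in seq_len(n)) {
    atoms <- base$atoms
    # jitter scaffold atoms (the placed side chains are overwritten below)
    if (config$noise_sd > 0) {
      jit <- matrix(rng$rnorm(3L * nrow(atoms), 0, config$noise_sd),
                    ncol = 3L)
      atoms$x <- atoms$x + jit[, 1]
      atoms$y <- atoms$y + jit[, 2]
      atoms$z <- atoms$z + jit[, 3]
    }
    for (ch in chains) {
      st <- config$states[[state_seq[[ch]][f]]]
      an <- anchors[[ch]]
      d_ek <- rng$rnorm(1L, st$d_235_246, st$dist_sd)
      d_he <- rng$rnorm(1L, st$d_122_235, st$dist_sd)
      d_ek <- max(d_ek, 0.5)
      d_he <- max(d_he, 0.5)
      u1 <- an$lat
      u2 <- c(0, if (an$lat[1] > 0) 1 else -1, 0)
      e_pos <- an$e_com
      k_pos <- e_pos + d_ek * u1
      if (is.null(st$d_122_246)) {
        h_pos <- e_pos + d_he * u2
      } else {
        d_hk <- max(rng$rnorm(1L, st$d_122_246, st$dist_sd), 0.5)
        a <- (d_he^2 + d_ek^2 - d_hk^2) / (2 * d_ek)
        b2 <- max(d_he^2 - a^2, 0)
        h_pos <- e_pos + a * u1 + sqrt(b2) * u2
      }
      atoms <- place_sidechain_com(atoms, ch, 235L, e_pos)
      atoms <- place_sidechain_com(atoms, ch, 246L, k_pos)
      # residue-122: COM at h_pos, pair midpoint realizing the angle
      theta <- rng$rnorm(1L, st$angle_mean, st$angle_sd) * pi / 180
      v <- sin(theta) * u1 + cos(theta) * c(0, 0, 1)
      ca122 <- as.numeric(atoms[atoms$chain_id == ch &
                                  atoms$resseq == 122L &
                                  atoms$atom_name == "CA",
                                c("x", "y", "z")])
      midpoint <- ca122 + 3.0 * v
      atoms <- place_sensor_sidechain(atoms, ch, h_pos, midpoint)
    }
    frames[[f]] <- structure_frame(atoms,
                                   time_ns = (f - 1) * config$dt_ns)
  }
  labels <- vapply(config$states, function(s) s$label, character(1))
  states_df <- data.frame(
    frame = rep(seq_len(n), times = length(chains)),
    time_ns = rep((seq_len(n) - 1) * config$dt_ns, times = length(chains)),
    subunit = rep(chains, each = n),
    state = labels[unlist(state_seq)]
  )
  traj <- trajectory(frames,
                     condition = list(pH_label = config$pH_label,
                                      variant = config$variant,
                                      replicate_id = config$replicate_id),
                     dt_ns = config$dt_ns)
  attr(traj, "states") <- states_df
  traj
}

#' Generator presets for the four studied conditions
#'
#' Returns a [generator_config()] emulating the qualitative conformational
#' statistics of each condition. Distance means follow the approximate
#' printed values for the high-pH multi-region pattern (state a:
#' Glu235-Lys246 ~4 A; state b: residue122-Glu235 ~5 A with Glu235-Lys246
#' ~8 A; state c: no interaction) and the low-pH single-region collapse
#' (His122-Glu235 salt bridge ~4 A at Glu235-Lys246 ~8 A). Angle means are
#' ~80 deg (high pH) and ~50 deg (low pH) for the wild type and ~90 deg at
#' both pH values for H122N, which also keeps the multi-region distance
#' pattern at low pH. These are presets documenting approximate values,
#' not ground truth.
#'
#' @param preset one of `"high_pH_WT"`, `"low_pH_WT"`, `"high_pH_H122N"`,
#'   `"low_pH_H122N"`.
#' @param n_frames,dt_ns,seed,replicate_id passed to [generator_config()].
#' @return `GeneratorConfig`.
#' @export
preset_config <- function(preset = c("high_pH_WT", "low_pH_WT",
                                     "high_pH_H122N", "low_pH_H122N"),
                          n_frames = 350L, dt_ns = 1, seed,
                          replicate_id = NA) {
  preset <- match.arg(preset)
  if (missing(seed)) stop("presets require an explicit seed")
  multi_region <- function(angle_mean) list(
    conformational_state("a", d_235_246 = 4, d_122_235 = 8,
                         angle_mean = angle_mean, occupancy = 0.40),
    conformational_state("b", d_235_246 = 8, d_122_235 = 5,
                         angle_mean = angle_mean, occupancy = 0.35),
    conformational_state("c", d_235_246 = 10, d_122_235 = 10,
                         angle_mean = angle_mean, occupancy = 0.25)
  )
  collapsed <- function(angle_mean) list(
    conformational_state("e", d_235_246 = 8, d_122_235 = 4,
                         angle_mean = angle_mean, occupancy = 1)
  )
  spec <- switch(preset,
    high_pH_WT = list(states = multi_region(80), variant = "WT",
                      pH_label = "high"),
    low_pH_WT = list(states = collapsed(50), variant = "WT",
                     pH_label = "low"),
    high_pH_H122N = list(states = multi_region(90), variant = "H122N",
                         pH_label = "high"),
    low_pH_H122N = list(states = multi_region(90), variant = "H122N",
                        pH_label = "low")
  )
  generator_config(spec$states, n_frames = n_frames, dt_ns = dt_ns,
                   seed = seed, variant = spec$variant,
                   pH_label = spec$pH_label, replicate_id = replicate_id)
}

#' Simulate a random coupled titratable-site system
#'
#' Draws `n_sites` residues of random titratable type, places them
#' uniformly in a cubic box with a minimum pairwise separation (rejection
#' sampling), optionally jitters their intrinsic pKas around the standard
#' values, and derives the coupling matrix from the positions with the
#' screened-Coulomb rule.
#'
#' @param n_sites number of sites (>= 1).
#' @param seed mandatory integer seed.
#' @param box_A box edge, Angstrom (default 15).
#' @param min_separation_A minimum inter-site distance (default 3).
#' @param pka_jitter_sd sd of Gaussian jitter added to the standard
#'   intrinsic pKas (default 0: standard values).
#' @param dielectric,temperature coupling model parameters.
#' @return `TitrationSystem`.
#' @export
simulate_titration_system <- function(n_sites, seed, box_A = 15,
                                      min_separation_A = 3,
                                      pka_jitter_sd = 0,
                                      dielectric = 80, temperature = 310) {
  if (missing(seed)) stop("simulate_titration_system requires a seed")
  stopifnot(n_sites >= 1)
  rng <- new_rng(seed)
  resnames <- c(ACID_RESNAMES, BASE_RESNAMES)
  picks <- resnames[rng$sample_int(length(resnames), n_sites,
                                   replace = TRUE)]
  pos <- matrix(NA_real_, n_sites, 3)
  for (i in seq_len(n_sites)) {
    for (try in seq_len(1000L)) {
      cand <- rng$runif(3L, 0, box_A)
      if (i == 1L ||
          min(sqrt(rowSums(sweep(pos[seq_len(i - 1L), , drop = FALSE],
                                 2L, cand)^2))) >= min_separation_A) {
        pos[i, ] <- cand
        break
      }
    }
    if (anyNA(pos[i, ])) {
      stop("could not place sites with the requested minimum separation")
    }
  }
  pka <- INTRINSIC_PKAS[picks]
  if (pka_jitter_sd > 0) {
    pka <- pka + rng$rnorm(n_sites, 0, pka_jitter_sd)
  }
  sites <- data.frame(chain_id = "A", resseq = seq_len(n_sites) * 10L,
                      resname = picks, intrinsic_pKa = as.numeric(pka),
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      stringsAsFactors = FALSE)
  titration_system(sites, dielectric = dielectric,
                   temperature = temperature)
}
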