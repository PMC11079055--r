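# Self-consistent protonation-state protocol with a pluggable per-site pKa
# backend, a screened-Coulomb coupling model standing in for a
# Poisson-Boltzmann solver, and an exact microstate-enumeration oracle.
#
# Conventions. Each titratable site is an acid (Asp/Glu/Tyr: charge -1
# deprotonated, 0 protonated) or a base (His/Lys/Arg: 0 deprotonated, +1
# protonated), so binding a proton always adds +1 charge. Couplings w_ij
# are in pK units per unit-charge product, symmetric, zero diagonal, and
# non-negative: the sign of an interaction enters through q_i * q_j.

# CODATA-derived Coulomb constant e^2/(4 pi eps0) in kcal*Angstrom/mol,
# and Boltzmann's constant in kcal/mol/K.
COULOMB_KCAL_A <- 332.06371
KB_KCAL_MOL_K <- 1.987204259e-3

ACID_RESNAMES <- c("ASP", "GLU", "TYR")
BASE_RESNAMES <- c("HIS", "LYS", "ARG")

# Standard intrinsic (model-compound) pKas; overridable per site.
INTRINSIC_PKAS <- c(ASP = 4.0, GLU = 4.25, HIS = 6.5, LYS = 10.4,
                    ARG = 12.0, TYR = 9.6)

site_class_for <- function(resname) {
  ifelse(resname %in% ACID_RESNAMES, "acid",
         ifelse(resname %in% BASE_RESNAMES, "base", NA_character_))
}

#' Pairwise electrostatic coupling of two titratable sites
#'
#' Screened-Coulomb coupling in pK units:
#' `w = e^2 / (4 pi eps0 * dielectric * r) / (kB T ln 10)`. This is the
#' simplified continuum-electrostatics backend used in place of a
#' finite-difference Poisson-Boltzmann solver; it is monotonically
#' decreasing in both `r` and `dielectric`.
#'
#' @param r_ij site separation, Angstrom (> 0).
#' @param dielectric relative dielectric constant (default 80,
#'   solvent-like).
#' @param temperature Kelvin (default 310, body temperature).
#' @return Coupling in pK units (per unit-charge product).
#' @export
coulomb_coupling <- function(r_ij, dielectric = 80, temperature = 310) {
  if (any(r_ij <= 0)) stop("site separation must be positive")
  if (dielectric <= 0 || temperature <= 0) {
    stop("dielectric and temperature must be positive")
  }
  ke <- COULOMB_KCAL_A / (KB_KCAL_MOL_K * temperature * log(10))
  ke / (dielectric * r_ij)
}

#' Build a titratable-site system
#'
#' @param sites data.frame with columns `chain_id`, `resseq`, `resname`,
#'   optional `intrinsic_pKa` (standard values filled in when absent) and
#'   positions `x`, `y`, `z` (Angstrom).
#' @param couplings symmetric non-negative coupling matrix in pK units
#'   with zero diagonal; computed from positions via [coulomb_coupling()]
#'   when `NULL`.
#' @param dielectric,temperature passed to [coulomb_coupling()] when
#'   couplings are derived from positions.
#' @return Object of class `TitrationSystem`.
#' @export
titration_system <- function(sites, couplings = NULL, dielectric = 80,
                             temperature = 310) {
  stopifnot(is.data.frame(sites), nrow(sites) >= 1L)
  sites <- as.data.frame(sites)
  sites$site_class <- site_class_for(sites$resname)
  if (anyNA(sites$site_class)) {
    stop("non-titratable residue type(s): ",
         paste(unique(sites$resname[is.na(sites$site_class)]),
               collapse = ", "))
  }
  if (is.null(sites$intrinsic_pKa)) sites$intrinsic_pKa <- NA_real_
  fill <- is.na(sites$intrinsic_pKa)
  sites$intrinsic_pKa[fill] <- INTRINSIC_PKAS[sites$resname[fill]]
  if (any(!is.finite(sites$intrinsic_pKa))) {
    stop("non-finite intrinsic pKa")
  }
  n <- nrow(sites)
  if (is.null(couplings)) {
    if (!all(c("x", "y", "z") %in% names(sites))) {
      stop("need site positions (x, y, z) or an explicit coupling matrix")
    }
    pos <- as.matrix(sites[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(pos))
    if (any(d[upper.tri(d)] == 0)) {
      stop("duplicate site positions give a singular coupling")
    }
    couplings <- matrix(0, n, n)
    couplings[upper.tri(d)] <- coulomb_coupling(d[upper.tri(d)],
                                                dielectric, temperature)
    couplings <- couplings + t(couplings)
  }
  couplings <- as.matrix(couplings)
  if (!all(dim(couplings) == c(n, n))) {
    stop("coupling matrix dimension does not match the site count")
  }
  if (max(abs(couplings - t(couplings))) > 1e-9) {
    stop("coupling matrix must be symmetric")
  }
  if (any(diag(couplings) != 0)) stop("coupling diagonal must be zero")
  if (any(couplings < 0)) {
    stop("couplings must be non-negative (signs enter through charges)")
  }
  rownames(couplings) <- colnames(couplings) <- NULL
  structure(list(sites = sites, couplings = couplings,
                 temperature = temperature),
            class = "TitrationSystem")
}

#' @export
print.TitrationSystem <- function(x, ...) {
  cat(sprintf("TitrationSystem: %d sites (%d acids, %d bases), T = %g K\n",
              nrow(x$sites), sum(x$sites$site_class == "acid"),
              sum(x$sites$site_class == "base"), x$temperature))
  invisible(x)
}

n_sites <- function(system) nrow(system$sites)

#' Charges of a protonation vector
#'
#' Acid sites carry `x - 1`, base sites carry `x`, so adding a proton adds
#' +1 charge for both classes.
#'
#' @param system `TitrationSystem`.
#' @param x 0/1 protonation vector (1 = proton bound).
#' @return Integer charges in -1/0/+1.
#' @export
site_charges <- function(system, x) {
  stopifnot(length(x) == n_sites(system), all(x %in% c(0, 1)))
  as.integer(ifelse(system$sites$site_class == "acid", x - 1, x))
}

#' Mean-field pKa of one site in a protonation context
#'
#' `pKa_i = intrinsic_pKa_i - sum_{j != i} w_ij q_j`: a negatively charged
#' neighbour raises the pKa (favours proton binding), a positive neighbour
#' lowers it. Site i's own state does not contribute.
#'
#' @param system `TitrationSystem`.
#' @param site_i site index.
#' @param context 0/1 protonation vector for all sites (entry `site_i` is
#'   ignored).
#' @return pKa in pK units.
#' @export
mean_field_pka <- function(system, site_i, context) {
  q <- site_charges(system, context)
  q[site_i] <- 0L
  system$sites$intrinsic_pKa[site_i] - sum(system$couplings[site_i, ] * q)
}

mean_field_pkas <- function(system, context) {
  q <- site_charges(system, context)
  shift <- as.vector(system$couplings %*% q) -
    diag(system$couplings) * q  # diagonal is zero; kept for clarity
  system$sites$intrinsic_pKa - shift
}

#' Threshold protonation assignment
#'
#' A site is protonated iff its pKa exceeds the pH (strictly; a site with
#' pKa exactly equal to the pH is left deprotonated).
#'
#' @param pkas per-site pKa values.
#' @param pH target pH.
#' @return 0/1 protonation vector.
#' @export
assign_states <- function(pkas, pH) {
  if (any(!is.finite(pkas))) stop("non-finite pKa")
  as.integer(pkas > pH)
}

#' Exact protonation probabilities by microstate enumeration
#'
#' Enumerates all `2^N` protonation microstates. The microstate energy in
#' pK units is `G(x) = sum_i x_i (pH - pKa_int_i) +
#' sum_{i<j} w_ij q_i(x_i) q_j(x_j)` and `P(x) ~ 10^(-G(x))`. Per-site
#' protonation probabilities are `theta_i = sum_x x_i P(x)` and the
#' effective pKa is `pH + log10(theta_i / (1 - theta_i))`. With zero
#' couplings this reduces to the Henderson-Hasselbalch formula per site.
#'
#' @param system `TitrationSystem` with at most 20 sites.
#' @param pH target pH.
#' @return list with `theta` (per-site probabilities), `effective_pKa`,
#'   and `majority` (0/1 vector, `theta > 0.5`).
#' @export
exact_microstate_probabilities <- function(system, pH) {
  n <- n_sites(system)
  if (n > 20L) {
    stop("microstate enumeration is limited to 20 sites; ",
         "use the mean-field path for larger systems")
  }
  # all 2^n protonation vectors, one per row
  X <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))[, seq_len(n),
                                                     drop = FALSE]
  dimnames(X) <- NULL
  qref <- ifelse(system$sites$site_class == "acid", -1, 0)
  Q <- X + matrix(qref, nrow(X), n, byrow = TRUE)  # charges: x + qref
  G <- as.vector(X %*% (pH - system$sites$intrinsic_pKa)) +
    0.5 * rowSums((Q %*% system$couplings) * Q)
  logp <- -G * log(10)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  theta <- as.vector(crossprod(X, p))
  # 1 - theta computed as its own microstate sum: avoids catastrophic
  # cancellation when theta is within 1e-10 of 0 or 1
  theta_bar <- as.vector(crossprod(1 - X, p))
  eff <- pH + log10(theta) - log10(theta_bar)
  list(theta = theta, effective_pKa = eff,
       majority = as.integer(theta > 0.5))
}

#' Mean-field pKa backend
#'
#' The default per-frame backend for [self_consistent_titration()]:
#' estimates every site's pKa from the frame's coupling matrix and the
#' current protonation context via [mean_field_pka()].
#'
#' @param system `TitrationSystem` (one relaxation frame).
#' @param context 0/1 protonation vector.
#' @return Numeric vector of per-site pKas.
#' @export
mean_field_backend <- function(system, context) {
  mean_field_pkas(system, context)
}

#' Identity relaxer
#'
#' The default structural relaxation stage: returns the input system as a
#' single-frame ensemble. In the original protocol this stage was a short
#' (10 ns) molecular-dynamics run from which 6 frames at 2 ns spacing were
#' extracted; any callable mapping `(system, protonation)` to a list of
#' systems can be substituted.
#'
#' @param system `TitrationSystem`.
#' @param x current 0/1 protonation vector (unused).
#' @return list of `TitrationSystem` frames.
#' @export
identity_relaxer <- function(system, x) list(system)

#' Position-jitter relaxer factory
#'
#' Returns a relaxer that emulates thermal relaxation by jittering site
#' positions with isotropic Gaussian noise and recomputing couplings,
#' producing `n_frames` frames (default 6, the 0-10 ns / 2 ns-spacing
#' sampling convention).
#'
#' @param n_frames frames per round.
#' @param sd_A positional noise, Angstrom.
#' @param dielectric,temperature coupling model parameters.
#' @param seed integer seed (mandatory; no global RNG state is consumed).
#' @return function(system, x) -> list of `TitrationSystem`s.
#' @export
jitter_relaxer <- function(n_frames = 6L, sd_A = 0.3, dielectric = 80,
                           temperature = 310, seed) {
  if (missing(seed)) stop("jitter_relaxer requires an explicit seed")
  rng <- new_rng(seed)
  function(system, x) {
    if (!all(c("x", "y", "z") %in% names(system$sites))) {
      stop("jitter relaxer needs site positions")
    }
    lapply(seq_len(n_frames), function(i) {
      s <- system$sites
      jit <- matrix(rng$rnorm(3L * nrow(s), 0, sd_A), ncol = 3L)
      s[, c("x", "y", "z")] <- s[, c("x", "y", "z")] + jit
      titration_system(s[, setdiff(names(s), "site_class")],
                       dielectric = dielectric, temperature = temperature)
    })
  }
}

new_pka_report <- function(site_ids, mat, multiplicity = 1L) {
  # mat: sites x frames matrix of per-frame pKa estimates
  n <- ncol(mat) * multiplicity
  rpt <- data.frame(
    site = site_ids,
    mean_pKa = rowMeans(mat),
    sd_pKa = if (ncol(mat) > 1L) apply(mat, 1L, stats::sd) else 0,
    n = n
  )
  class(rpt) <- c("PkaReport", "data.frame")
  rpt
}

site_ids_of <- function(system) {
  paste0(system$sites$resname, system$sites$resseq,
         ifelse(is.null(system$sites$chain_id), "",
                paste0(".", system$sites$chain_id)))
}

#' Self-consistent protonation titration
#'
#' Iterates relax -> per-frame pKa estimation -> averaging -> threshold
#' assignment until the assigned protonation vector no longer changes
#' ("no residues had to be modified") or `max_rounds` is reached. A
#' period-2 oscillation of the assignment (typical of strongly
#' anti-cooperative pairs under a mean-field backend) is detected and the
#' cycling sites are resolved by the exact microstate oracle's per-site
#' majority, after which the remaining sites are re-relaxed to a fixed
#' point.
#'
#' @param system `TitrationSystem`.
#' @param pH target pH.
#' @param backend function(system_frame, context) -> per-site pKa vector;
#'   default [mean_field_backend()].
#' @param relaxer function(system, x) -> list of system frames; default
#'   [identity_relaxer()].
#' @param max_rounds maximum protocol rounds (>= 1).
#' @param multiplicity number of identical copies of each site in the
#'   assembly (2 for a symmetric dimer); only scales the reported `n`.
#' @return list with `protonation` (0/1 vector), `report` (`PkaReport`
#'   of the final round), `history` (per-round vectors and reports),
#'   `converged`, and `cycle_resolved`.
#' @export
self_consistent_titration <- function(system, pH,
                                      backend = mean_field_backend,
                                      relaxer = identity_relaxer,
                                      max_rounds = 25L,
                                      multiplicity = 1L) {
  stopifnot(max_rounds >= 1L)
  ids <- site_ids_of(system)
  x <- assign_states(system$sites$intrinsic_pKa, pH)
  history <- list()
  converged <- FALSE
  cycle_resolved <- FALSE
  frozen <- rep(FALSE, n_sites(system))
  round_of <- function(x) {
    frames <- relaxer(system, x)
    mat <- vapply(frames, function(fr) backend(fr, x),
                  numeric(n_sites(system)))
    if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(frames))
    new_pka_report(ids, mat, multiplicity)
  }
  x_init <- x
  for (round in seq_len(max_rounds)) {
    report <- round_of(x)
    x_new <- assign_states(report$mean_pKa, pH)
    x_new[frozen] <- x[frozen]
    history[[round]] <- list(round = round, report = report,
                             protonation = x_new)
    if (identical(x_new, x)) {
      converged <- TRUE
      break
    }
    # period-2 cycle: the new assignment equals the one two updates ago
    x_two_ago <- if (round == 2L) x_init else
      if (round > 2L) history[[round - 2L]]$protonation else NULL
    if (round >= 2L && identical(x_new, x_two_ago)) {
      # oscillation between x and x_new: freeze the cycling sites at the
      # exact-oracle per-site majority and let the rest re-converge
      cyc <- which(x_new != x)
      oracle <- exact_microstate_probabilities(system, pH)
      x_new[cyc] <- oracle$majority[cyc]
      frozen[cyc] <- TRUE
      cycle_resolved <- TRUE
    }
    x <- x_new
  }
  list(protonation = x,
       report = history[[length(history)]]$report,
       history = history,
       converged = converged,
       cycle_resolved = cycle_resolved)
}

#' Select sites inside a pKa window
#'
#' Returns the rows of a pKa report whose mean pKa lies in the closed
#' interval `[low, high]`, sorted by decreasing mean pKa.
#'
#' @param report `PkaReport` (data.frame with `site`, `mean_pKa`, ...).
#' @param low,high window bounds (default 4 and 8, the physiologically
#'   responsive range).
#' @return The selected report rows, sorted decreasing.
#' @export
select_pka_window <- function(report, low = 4, high = 8) {
  keep <- report$mean_pKa >= low & report$mean_pKa <= high
  out <- report[keep, , drop = FALSE]
  out[order(-out$mean_pKa), , drop = FALSE]
}

#' Reference protonation pattern near the residue-122 pH sensor
#'
#' The converged protonation pattern of the titratable residues within
#' 12 Angstrom of the Calpha of residue 122: His122, Glu45, Glu49 and
#' Asp230 are protonated at low pH only; Glu235 stays deprotonated
#' (negatively charged) and Lys246/Lys131 stay deprotonated (neutral) at
#' both pH values. For the H122N variant, site 122 is not titratable and
#' is absent from the set.
#'
#' @param pH_label `"high"` or `"low"`.
#' @param variant `"WT"` or `"H122N"`.
#' @return data.frame with columns `site`, `resname`, `resseq`,
#'   `protonated` (0/1).
#' @export
protonation_preset <- function(pH_label = c("high", "low"),
                               variant = c("WT", "H122N")) {
  pH_label <- match.arg(pH_label)
  variant <- match.arg(variant)
  sites <- data.frame(
    site = c("His122", "Glu45", "Glu49", "Asp230", "Glu235",
             "Lys246", "Lys131"),
    resname = c("HIS", "GLU", "GLU", "ASP", "GLU", "LYS", "LYS"),
    resseq = c(122L, 45L, 49L, 230L, 235L, 246L, 131L),
    stringsAsFactors = FALSE
  )
  ph_switched <- c("His122", "Glu45", "Glu49", "Asp230")
  sites$protonated <- ifelse(sites$site %in% ph_switched &
                               pH_label == "low", 1L, 0L)
  if (variant == "H122N") {
    sites <- sites[sites$resseq != 122L, , drop = FALSE]
    rownames(sites) <- NULL
  }
  sites
}

#' Write / read a titratable-site table
#'
#' TSV with columns `chain_id`, `resseq`, `resname`, `site_class`,
#' `intrinsic_pKa`, `x`, `y`, `z`.
#'
#' @param system `TitrationSystem`.
#' @param path file path.
#' @return `path` (write) or `TitrationSystem` (read).
#' @export
write_site_table <- function(system, path) {
  cols <- intersect(c("chain_id", "resseq", "resname", "site_class",
                      "intrinsic_pKa", "x", "y", "z"),
                    names(system$sites))
  write_table(system$sites[, cols], path)
}

#' @rdname write_site_table
#' @param dielectric,temperature coupling model parameters used to rebuild
#'   couplings from the stored positions.
#' @export
read_site_table <- function(path, dielectric = 80, temperature = 310) {
  titration_system(read_table(path), dielectric = dielectric,
                   temperature = temperature)
}
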