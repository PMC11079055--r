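# Titration: coupling model, mean-field pKas, threshold assignment,
# exact microstate oracle, self-consistent protocol, window selection,
# and the reference protonation pattern.

test_that("coulomb_coupling matches a constants-derived value at 310 K", {
  # independent derivation from CODATA constants:
  # e^2/(4 pi eps0) = e^2 * ke; per mole; in kcal; over kB*T*ln(10)
  e <- 1.602176634e-19       # C
  ke <- 8.9875517923e9       # N m^2 C^-2
  NA_ <- 6.02214076e23       # mol^-1
  kcal <- 4184               # J
  kB <- 1.380649e-23         # J/K
  r <- 3.5e-10               # m (3.5 A)
  w_expected <- (e^2 * ke / r) / (kB * 310 * log(10))
  expect_equal(coulomb_coupling(3.5, dielectric = 1, temperature = 310),
               w_expected, tolerance = 1e-6)
  # 1/r law and screening limit
  expect_equal(coulomb_coupling(7, 80), coulomb_coupling(3.5, 80) / 2)
  expect_lt(coulomb_coupling(3.5, 1e9), 1e-6)
  expect_gt(coulomb_coupling(3.5, 80, 310),
            coulomb_coupling(3.5, 80, 400))
  expect_error(coulomb_coupling(0, 80), "positive")
})

test_that("mean-field pKa follows the charge-shift formula", {
  W <- matrix(0, 3, 3)
  sys <- make_system(c("ASP", "HIS", "LYS"), c(4, 6.5, 10.4), W)
  # all neighbours neutral -> intrinsic
  x_neutral <- c(1, 0, 0)  # protonated acid (q=0), deprot bases (q=0)
  expect_identical(site_charges(sys, x_neutral), c(0L, 0L, 0L))
  for (i in 1:3) {
    expect_equal(mean_field_pka(sys, i, x_neutral),
                 sys$sites$intrinsic_pKa[i])
  }
  # one negative neighbour with w = 1 raises the pKa by exactly 1
  W2 <- matrix(0, 3, 3); W2[1, 2] <- W2[2, 1] <- 1
  sys2 <- make_system(c("ASP", "HIS", "LYS"), c(4, 6.5, 10.4), W2)
  x <- c(0, 0, 0)  # deprotonated ASP: q1 = -1
  expect_equal(mean_field_pka(sys2, 2, x), 6.5 + 1)
  # protonated base neighbour lowers it
  x2 <- c(1, 0, 1)  # ASP protonated (q=0), LYS protonated (q=+1)
  W3 <- matrix(0, 3, 3); W3[2, 3] <- W3[3, 2] <- 0.8
  sys3 <- make_system(c("ASP", "HIS", "LYS"), c(4, 6.5, 10.4), W3)
  expect_equal(mean_field_pka(sys3, 2, x2), 6.5 - 0.8)
})

test_that("mean-field pKas match a second, literal implementation", {
  rng <- local_rng(101)
  for (rep in 1:20) {
    n <- 6L
    resnames <- c("ASP", "GLU", "HIS", "LYS", "ARG", "TYR")[
      rng$sample_int(6, n, replace = TRUE)]
    intrinsic <- rng$runif(n, 3, 11)
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- rng$runif(n * (n - 1) / 2, 0, 2)
    W <- W + t(W)
    sys <- make_system(resnames, intrinsic, W)
    x <- as.numeric(rng$runif(n) > 0.5)
    q <- ifelse(resnames %in% c("ASP", "GLU", "TYR"), x - 1, x)
    for (i in seq_len(n)) {
      manual <- intrinsic[i] - sum(W[i, -i] * q[-i])
      expect_equal(mean_field_pka(sys, i, x), manual, tolerance = 1e-12)
    }
  }
})

test_that("assign_states thresholds strictly at the pH", {
  expect_identical(assign_states(6.5, 6.0), 1L)
  expect_identical(assign_states(6.5, 7.4), 0L)
  expect_identical(assign_states(6.5, 6.5), 0L)  # tie -> deprotonated
  expect_identical(assign_states(c(9.1, 6.0, 3.2), 7),
                   c(1L, 0L, 0L))
})

test_that("exact oracle reduces to Henderson-Hasselbalch for one site", {
  sys <- make_system("HIS", 6.5, matrix(0, 1, 1))
  for (pH in c(4, 6.5, 7.4, 9)) {
    ex <- exact_microstate_probabilities(sys, pH)
    expect_equal(ex$theta, 1 / (1 + 10^(pH - 6.5)), tolerance = 1e-12)
  }
  ex <- exact_microstate_probabilities(sys, 6.5)
  expect_equal(ex$theta, 0.5, tolerance = 1e-12)
  expect_equal(ex$effective_pKa, 6.5, tolerance = 1e-12)
})

test_that("zero couplings factorize exactly for every residue class", {
  resnames <- c("ASP", "GLU", "HIS", "LYS", "ARG", "TYR")
  intrinsic <- c(4.0, 4.25, 6.5, 10.4, 12.0, 9.6)
  sys <- make_system(resnames, intrinsic, matrix(0, 6, 6))
  for (pH in c(3, 6.2, 7.4, 11)) {
    ex <- exact_microstate_probabilities(sys, pH)
    hh <- 1 / (1 + 10^(pH - intrinsic))
    expect_equal(ex$theta, hh, tolerance = 1e-12)
    expect_equal(ex$effective_pKa, intrinsic, tolerance = 1e-10)
  }
  # self-consistent protocol recovers the intrinsic pKas exactly
  res <- self_consistent_titration(sys, 7.0)
  expect_true(res$converged)
  expect_equal(res$report$mean_pKa, intrinsic, tolerance = 1e-10)
  expect_identical(res$protonation, as.integer(intrinsic > 7.0))
})

test_that("3-site coupled system matches a literal 8-term enumeration", {
  resnames <- c("GLU", "HIS", "LYS")
  intrinsic <- c(4.5, 6.8, 10.0)
  W <- matrix(c(0, 1.2, 0.4,
                1.2, 0, 0.9,
                0.4, 0.9, 0), 3, 3)
  sys <- make_system(resnames, intrinsic, W)
  for (pH in c(5.5, 7.0)) {
    ex <- exact_microstate_probabilities(sys, pH)
    theta_oracle <- oracle_microstate_theta(
      intrinsic, c("acid", "base", "base"), W, pH)
    expect_equal(ex$theta, theta_oracle, tolerance = 1e-12)
  }
  expect_error(
    exact_microstate_probabilities(
      make_system(rep("HIS", 21), rep(6.5, 21), matrix(0, 21, 21)), 7),
    "20 sites")
})

test_that("exact theta is monotone non-increasing in pH at physiological
           coupling strengths", {
  rng <- local_rng(77)
  for (rep in 1:10) {
    sys <- simulate_titration_system(6, seed = rng$sample_int(1e6, 1),
                                     pka_jitter_sd = 1.5)
    pHs <- seq(2, 12, by = 0.5)
    thetas <- vapply(pHs, function(p)
      exact_microstate_probabilities(sys, p)$theta, numeric(6))
    expect_true(all(diff(t(thetas)) <= 1e-12))
  }
  # ... but NOT in general: strongly coupled mixed acid/base triples are
  # genuine counterexamples (deprotonating the base removes the positive
  # charge that stabilized a neighbouring acid's deprotonated form, so
  # that acid transiently re-protonates as pH rises)
  W <- matrix(c(0, 5.76, 6.59,
                5.76, 0, 0.87,
                6.59, 0.87, 0), 3, 3)
  sys_frustrated <- make_system(c("GLU", "ARG", "ASP"),
                                c(10.65, 8.2, 8.51), W)
  pHs <- seq(1, 13, by = 0.25)
  th <- vapply(pHs, function(p)
    exact_microstate_probabilities(sys_frustrated, p)$theta, numeric(3))
  expect_gt(max(diff(t(th))), 0.1)
})

test_that("site relabelling permutes outputs identically", {
  rng <- local_rng(55)
  n <- 5L
  resnames <- c("ASP", "HIS", "GLU", "LYS", "HIS")
  intrinsic <- c(4.2, 6.6, 4.5, 10.2, 6.1)
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- rng$runif(n * (n - 1) / 2, 0, 1.5)
  W <- W + t(W)
  sys <- make_system(resnames, intrinsic, W)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  sys_p <- make_system(resnames[perm], intrinsic[perm], W[perm, perm])
  ex <- exact_microstate_probabilities(sys, 6.5)
  ex_p <- exact_microstate_probabilities(sys_p, 6.5)
  expect_equal(ex_p$theta, ex$theta[perm], tolerance = 1e-12)
  res <- self_consistent_titration(sys, 6.5)
  res_p <- self_consistent_titration(sys_p, 6.5)
  expect_identical(res_p$protonation, res$protonation[perm])
})

test_that("uncoupled system converges in one round to the HH threshold", {
  sys <- make_system(c("ASP", "HIS", "LYS"), c(4, 6.5, 10.4),
                     matrix(0, 3, 3))
  res <- self_consistent_titration(sys, 7.0)
  expect_true(res$converged)
  expect_length(res$history, 1L)
  expect_identical(res$protonation, c(0L, 0L, 1L))
})

test_that("anti-cooperative acid pair: cycle detected, oracle resolves it", {
  # two acids with pKas just below the pH and a coupling much larger
  # than the pKa-pH gaps: deprotonating both costs w = 3 pK, so the
  # mean-field update oscillates between (0,0) and (1,1)
  W <- matrix(c(0, 3, 3, 0), 2, 2)
  sys <- make_system(c("ASP", "GLU"), c(5.9, 5.5), W)
  pH <- 6.0
  res <- self_consistent_titration(sys, pH)
  expect_true(res$cycle_resolved)
  expect_true(res$converged)
  # exact physics: exactly one proton bound, on the higher-pKa site
  expect_identical(res$protonation, c(1L, 0L))
  ex <- exact_microstate_probabilities(sys, pH)
  expect_identical(res$protonation, ex$majority)
})

test_that("pKa report averages over relaxer frames with the n convention", {
  sys <- simulate_titration_system(4, seed = 9, pka_jitter_sd = 1)
  relax <- jitter_relaxer(n_frames = 6, sd_A = 0.2, seed = 14)
  res <- self_consistent_titration(sys, 7.0, relaxer = relax,
                                   multiplicity = 2L)
  # n = identical residues per assembly (2) x frames (6)
  expect_true(all(res$report$n == 12L))
  expect_true(all(res$report$sd_pKa >= 0))
})

test_that("select_pka_window filters a closed interval, sorted decreasing", {
  rpt <- data.frame(site = paste0("s", 1:6),
                    mean_pKa = c(9.1, 6.0, 3.2, 8.0, 4.0, 7.3),
                    sd_pKa = 0.1, n = 12)
  sel <- select_pka_window(rpt)
  expect_identical(sel$site, c("s4", "s6", "s2", "s5"))  # 8.0 included
  expect_identical(sel$mean_pKa, sort(sel$mean_pKa, decreasing = TRUE))
  # random report equals brute filter + sort
  rng <- local_rng(8)
  rpt2 <- data.frame(site = paste0("r", 1:40),
                     mean_pKa = rng$runif(40, 0, 14))
  sel2 <- select_pka_window(rpt2, low = 4, high = 8)
  brute <- rpt2[rpt2$mean_pKa >= 4 & rpt2$mean_pKa <= 8, ]
  brute <- brute[order(-brute$mean_pKa), ]
  expect_equal(sel2$site, brute$site)
})

test_that("reference protonation pattern matches the published convention", {
  low_wt <- protonation_preset("low", "WT")
  expect_equal(sum(low_wt$protonated), 4L)
  expect_setequal(low_wt$site[low_wt$protonated == 1],
                  c("His122", "Glu45", "Glu49", "Asp230"))
  high_wt <- protonation_preset("high", "WT")
  expect_equal(sum(high_wt$protonated), 0L)
  # Glu235 charged, Lys246/Lys131 deprotonated at both pH labels
  for (p in list(low_wt, high_wt)) {
    expect_equal(p$protonated[p$site %in% c("Glu235", "Lys246", "Lys131")],
                 c(0L, 0L, 0L))
  }
  low_mut <- protonation_preset("low", "H122N")
  expect_equal(sum(low_mut$protonated), 3L)
  expect_false(122L %in% low_mut$resseq)
})

test_that("site tables round-trip through TSV", {
  sys <- simulate_titration_system(5, seed = 21, pka_jitter_sd = 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(sys, path)
  sys2 <- read_site_table(path)
  expect_equal(sys2$sites$resname, sys$sites$resname)
  expect_equal(sys2$sites$intrinsic_pKa, sys$sites$intrinsic_pKa,
               tolerance = 1e-5)
  expect_equal(sys2$couplings, sys$couplings, tolerance = 1e-4)
})
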