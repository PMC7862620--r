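mk_pair <- function(el_r, el_l, d, q_r = NA, q_l = NA) {
  rec <- assign_parameters(pl_molecule(el_r, matrix(c(0, 0, 0), 1, 3)))
  lig <- assign_parameters(pl_molecule(el_l, matrix(c(d, 0, 0), 1, 3)))
  if (!is.na(q_r)) { rec$atoms$partial_charge <- q_r; rec$net_charge <- round(q_r) }
  if (!is.na(q_l)) { lig$atoms$partial_charge <- q_l; lig$net_charge <- round(q_l) }
  pl_complex(rec, lig)
}

test_that("dielectric functions reproduce limits and printed formulas", {
  ram4 <- dielectric_model("ramstein", D_i = 4)
  ram1 <- dielectric_model("ramstein", D_i = 1)
  hin <- dielectric_model("hingerty")
  expect_equal(dielectric_constant(0, ram4), 4)
  expect_equal(dielectric_constant(0, ram1), 1)
  # rs = 1 at r = 1/0.16 = 6.25: D - (D - D_i)/2 * 5/e
  expect_equal(dielectric_constant(6.25, ram4), 78 - 37 * 5 / exp(1),
               tolerance = 1e-12)
  expect_equal(dielectric_constant(1e-9, hin), 1, tolerance = 1e-6)
  expect_equal(dielectric_constant(100, hin), 78, tolerance = 1e-6)
  # the Ramstein tail decays as r^2 exp(-rs): ~1e-3 from 78 at r = 100,
  # below 1e-6 by r = 300
  expect_lt(abs(dielectric_constant(100, ram4) - 78), 2e-3)
  expect_lt(abs(dielectric_constant(300, ram4) - 78), 1e-6)
  expect_error(dielectric_constant(-1, ram4), "domain")
})

test_that("dielectric functions are monotone and bounded on [0, 50]", {
  r <- seq(0, 50, by = 0.05)
  for (model in list(dielectric_model("ramstein", D_i = 4),
                     dielectric_model("ramstein", D_i = 1),
                     dielectric_model("hingerty"))) {
    eps <- dielectric_constant(r, model)
    expect_true(all(diff(eps) >= -1e-12))
    expect_true(all(eps >= 1 - 1e-9 & eps <= 78 + 1e-9))
  }
})

test_that("Coulomb term: unit pair, zero charge, brute-force equivalence", {
  cfg <- term_config()
  cx <- mk_pair("N", "N", 0.95, 1, 1)
  expect_equal(coulomb_term(cx, dielectric_model("constant"), cfg),
               332.0716, tolerance = 1e-12)
  cx0 <- mk_pair("N", "N", 0.95, 0, 1)
  expect_equal(coulomb_term(cx0, dielectric_model("constant"), cfg), 0)
  for (seed in c(1, 2, 3)) {
    cx <- random_complex(10, 10, seed = seed)
    for (model in list(dielectric_model("ramstein", D_i = 4),
                       dielectric_model("hingerty"))) {
      expect_equal(coulomb_term(cx, model, cfg),
                   oracle_coulomb(cx, model, cfg), tolerance = 1e-9)
    }
  }
})

test_that("buffered 14-7: minimum -eps_ij at R* for both deltas, decay, softening", {
  eps_ij <- sqrt(0.070 * 0.105)
  rstar <- (3.88 + 3.40) / 2
  # the true minimum of the buffered form sits exactly at R* only when
  # delta = gamma; for gamma = 0.12 the minimum is slightly displaced.
  # Constants frozen from an independent 1-d optimize() of the pair formula.
  min_loc <- c(`0.07` = 0.99618269, `0.67` = 1.03626632)    # r_min / R*
  min_depth <- c(`0.07` = 1.00056485, `0.67` = 1.03402687)  # |E_min| / eps
  for (delta in c(0.07, 0.67)) {
    cfg <- term_config(delta_vdw = delta)
    expect_equal(vdw_term(mk_pair("C", "O", rstar), cfg), -eps_ij,
                 tolerance = 1e-12)
    # grid-search oracle against the frozen optimum constants
    r <- seq(2.5, 8, by = 1e-4)
    e <- plscore:::buf147_pair(r, eps_ij, rstar, delta, 0.12)
    key <- sprintf("%.2f", delta)
    expect_equal(min(e), -eps_ij * min_depth[[key]], tolerance = 1e-6)
    expect_equal(r[which.min(e)], rstar * min_loc[[key]], tolerance = 1e-3)
    # long-range decay
    expect_lt(abs(vdw_term(mk_pair("C", "O", 50), cfg)), 1e-6 * eps_ij)
  }
  # softened potential is less repulsive in the repulsive region
  # (the two curves cross near 0.89 R*)
  for (r in seq(1.5, 0.85 * rstar, by = 0.25)) {
    e_soft <- vdw_term(mk_pair("C", "O", r), term_config(delta_vdw = 0.67))
    e_orig <- vdw_term(mk_pair("C", "O", r), term_config(delta_vdw = 0.07))
    expect_lt(e_soft, e_orig)
  }
  # brute-force equivalence on random complexes
  cfg <- term_config()
  for (seed in c(4, 5)) {
    cx <- random_complex(10, 10, seed = seed)
    expect_equal(vdw_term(cx, cfg), oracle_vdw(cx, cfg), tolerance = 1e-9)
  }
})

test_that("lipophilic contact: breakpoints, continuity, monotonicity, oracle", {
  cfg <- term_config()
  dv <- 1.70 + 1.70  # C...C contact radii sum
  vals <- vapply(c(0.3, 2.0, 4.0), function(pad) {
    lipophilic_term(mk_pair("C", "C", dv + pad), cfg)
  }, 1.0)
  expect_equal(vals, c(1, 0.5, 0), tolerance = 1e-12)
  # continuity at both breakpoints and non-increasing overall
  d <- seq(dv, dv + 4, by = 1e-3)
  w <- plscore:::lipo_contact(d, rep(dv, length(d)))
  expect_true(all(diff(w) <= 1e-12))
  expect_lt(max(abs(diff(w))), 1e-3)  # no jumps at dv+0.5 or dv+3.5
  # eligibility: charged atoms drop out of the charge-window variant
  cx_chg <- mk_pair("C", "C", dv + 0.3, 0.9, 0)
  expect_equal(lipophilic_term(cx_chg, cfg), 0)
  expect_equal(lipophilic_term(cx_chg, term_config(lipo_variant = "carbons")), 1)
  # hydrogens never eligible
  cx_h <- mk_pair("H", "C", 2.0)
  expect_equal(lipophilic_term(cx_h, cfg), 0)
  # brute-force equivalence
  for (variant in c("charge_window", "carbons")) {
    cfgv <- term_config(lipo_variant = variant)
    cx <- random_complex(12, 8, seed = 6, spread = 4)
    expect_equal(lipophilic_term(cx, cfgv), oracle_lipo(cx, cfgv),
                 tolerance = 1e-9)
  }
})

test_that("polar solvation counts buried unpaired charges only", {
  cfg <- term_config()
  # no atom above the charge threshold
  cx <- mk_pair("C", "C", 4.0)
  expect_equal(polar_solvation_term(cx, cfg), 0L)

  # one buried ligand charge, no partner: counts 1
  tc1 <- make_toy_complex(toy_complex_spec(
    "charged_pair", "cage", enclose_atoms = 1:2,
    charge_overrides = c(ligand.1 = -0.9)))
  expect_equal(polar_solvation_term(tc1$complex, cfg), 1L)

  # same burial but a charged partner within d_vdW + 1.0 suppresses it
  tc2 <- make_toy_complex(toy_complex_spec(
    "charged_pair", "cage", enclose_atoms = 1:2,
    charge_overrides = c(ligand.1 = -0.9, ligand.2 = 0.9)))
  expect_equal(polar_solvation_term(tc2$complex, cfg), 0L)

  # partner on the receptor side: flip a cage occluder into a charged N
  tc3 <- make_toy_complex(toy_complex_spec(
    "charged_pair", "cage", enclose_atoms = 1:2,
    charge_overrides = c(ligand.1 = -0.9)))
  rec <- tc3$complex$receptor
  rec$atoms$element[1] <- "N"
  rec$atoms$partial_charge[1] <- 0.9
  rec$net_charge <- round(sum(rec$atoms$partial_charge))
  cx3 <- pl_complex(rec, tc3$complex$ligand)
  expect_equal(polar_solvation_term(cx3, cfg), 0L)

  # an exposed charge does not count even without partners
  cx4 <- mk_pair("N", "O", 25, 0.9, -0.9)
  expect_equal(polar_solvation_term(cx4, cfg), 0L)
})

test_that("nonpolar solvation closed forms", {
  cfg <- term_config()
  # separated molecules: areas cancel, constant offset survives
  cx_far <- mk_pair("C", "C", 30)
  expect_equal(nonpolar_solvation_term(cx_far, cfg), -0.82, tolerance = 1e-6)
  # two C..C pairs each burying an analytic 50 A^2 -> 100 A^2 total
  R <- 1.7 + 1.4
  d <- 2 * R - 25 / (pi * R)
  rec <- assign_parameters(pl_molecule(c("C", "C"), rbind(c(0, 0, 0), c(40, 0, 0))))
  lig <- assign_parameters(pl_molecule(c("C", "C"), rbind(c(d, 0, 0), c(40 + d, 0, 0))))
  expect_equal(nonpolar_solvation_term(pl_complex(rec, lig), cfg),
               0.0092 * (-100) - 0.82, tolerance = 0.01)
})

test_that("oneSolv equals the heavy-atom nonpolar term and is monotone in burial", {
  cfg <- term_config()
  # hydrogen-free fixture: identical when np term is also heavy-only
  cx <- mk_pair("C", "C", 3.6)
  cfg_heavy <- term_config(include_hydrogens_in_sas = FALSE)
  expect_equal(one_solv_term(cx, cfg), nonpolar_solvation_term(cx, cfg_heavy),
               tolerance = 1e-12)
  expect_equal(one_solv_term(mk_pair("C", "C", 30), cfg), -0.82,
               tolerance = 1e-6)
  # deeper burial -> more negative
  vals <- vapply(c(8, 5, 3.6), function(d) one_solv_term(mk_pair("C", "C", d), cfg), 1.0)
  expect_true(all(diff(vals) < 0))
})

test_that("frozen-bond entropy follows the two-sided 50% rule", {
  cfg <- term_config()
  # rigid ligand
  tc <- make_toy_complex(toy_complex_spec("rigid_probe", "shell", gap = 0.5))
  expect_equal(torsional_entropy_term(tc$complex, cfg), 0L)
  # far-apart complex: no bond frozen
  tc0 <- make_toy_complex(toy_complex_spec("rotor_chain", "none",
                                           n_rotors = 3, pair_distance = 25))
  expect_equal(torsional_entropy_term(tc0$complex, cfg), 0L)
  # tight capsule shell: every rotor frozen, sides both >= 50% lost
  tcS <- make_toy_complex(toy_complex_spec("rotor_chain", "shell",
                                           n_rotors = 3, gap = 1.0))
  expect_equal(torsional_entropy_term(tcS$complex, cfg), 3L)
  # slab near one end only: fractions stay below 50%, nothing freezes
  tcL <- make_toy_complex(toy_complex_spec("rotor_chain", "slab",
                                           n_rotors = 3, enclose_atoms = 1:2,
                                           gap = 0.2))
  expect_equal(torsional_entropy_term(tcL$complex, cfg), 0L)
  rot <- detect_rotatable_bonds(tcL$complex$ligand)
  adj <- plscore:::adjacency_list(tcL$complex$ligand)
  fr <- vapply(seq_len(nrow(rot)), function(k) {
    side <- c(rot$i[k], setdiff(adj[[rot$i[k]]], rot$j[k]))
    delta_sas(tcL$complex, side, "ligand")$fraction_lost
  }, 1.0)
  expect_true(all(fr < 0.5))
})

test_that("partial cage freezes exactly the enclosed rotors (Fig-style cases)", {
  cfg <- term_config()
  tcC <- make_toy_complex(toy_complex_spec("rotor_chain", "cage",
                                           n_rotors = 3, enclose_atoms = 1:5))
  expect_equal(tcC$annotations$intended_frozen, 2L)
  expect_equal(torsional_entropy_term(tcC$complex, cfg), 2L)
  # the not-frozen bond has one side clearly below 50%, the other above
  rot <- detect_rotatable_bonds(tcC$complex$ligand)
  adj <- plscore:::adjacency_list(tcC$complex$ligand)
  k <- which(rot$i == 4 & rot$j == 5)
  side_i <- c(4L, setdiff(adj[[4]], 5L))
  side_j <- c(5L, setdiff(adj[[5]], 4L))
  fi <- delta_sas(tcC$complex, side_i, "ligand")$fraction_lost
  fj <- delta_sas(tcC$complex, side_j, "ligand")$fraction_lost
  expect_gt(fi, 0.5)
  expect_lt(fj, 0.5)
})

test_that("compute_descriptors composes the individual terms deterministically", {
  cfg <- term_config()
  model <- dielectric_model()
  tc <- make_toy_complex(toy_complex_spec("rotor_chain", "shell",
                                          n_rotors = 2, gap = 1.0))
  cx <- tc$complex
  d1 <- compute_descriptors(cx, cfg, model)
  expect_named(d1, c("E_coul", "E_vdW", "E_lipo", "E_entropy",
                     "E_polar_solv", "E_np_solv"))
  expect_equal(d1[["E_coul"]], coulomb_term(cx, model, cfg))
  expect_equal(d1[["E_vdW"]], vdw_term(cx, cfg))
  expect_equal(d1[["E_lipo"]], lipophilic_term(cx, cfg))
  expect_equal(d1[["E_entropy"]], as.numeric(torsional_entropy_term(cx, cfg)))
  expect_equal(d1[["E_polar_solv"]], as.numeric(polar_solvation_term(cx, cfg)))
  expect_equal(d1[["E_np_solv"]], nonpolar_solvation_term(cx, cfg))
  # bitwise determinism
  expect_identical(unclass(d1), unclass(compute_descriptors(cx, cfg, model)))
  # one-solv layout
  d2 <- compute_descriptors(cx, cfg, model, solvation = "one_solv")
  expect_named(d2, c("E_coul", "E_vdW", "E_lipo", "E_entropy", "oneSolv"))
  expect_equal(d2[["oneSolv"]], one_solv_term(cx, cfg))
  # degenerate input
  empty <- pl_molecule(character(0), matrix(0, 0, 3))
  expect_error(pl_complex(cx$receptor, empty), "usage error")
  # entropy never exceeds the rotatable-bond count
  expect_lte(d1[["E_entropy"]], tc$annotations$n_rotatable)
})
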