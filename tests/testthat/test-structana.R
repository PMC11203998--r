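# small helper: complex with one group of two receptor beads, one ligand
# heavy bead + one hydrogen, and a single water
two_bead_complex <- function(lig_y_A, hyd_y_A = 30, water = c(100, 0, 0)) {
  toy_complex(
    ligand_coords = rbind(c(0, A_to_nm(lig_y_A), 0), c(0, A_to_nm(hyd_y_A), 0)),
    ligand_masses = c(12, 1), ligand_heavy = c(TRUE, FALSE),
    receptor_coords = rbind(c(0, 0, 0), c(A_to_nm(8), 0, 0)),
    groups = list(site = c(1L, 2L)),
    water_coords = matrix(A_to_nm(water), 1, 3))
}

frame_of <- function(cx) list(ligand = cx$ligand_coords,
                              receptor = cx$receptor_coords,
                              water = cx$water_coords)

test_that("contact criterion is heavy-atom, boundary-inclusive, at 5 A", {
  expect_identical(heavy_atom_contacts(frame_of(two_bead_complex(4.9)),
                                       two_bead_complex(4.9)), "site")
  expect_identical(heavy_atom_contacts(frame_of(two_bead_complex(5.1)),
                                       two_bead_complex(5.1)), character(0))
  expect_identical(heavy_atom_contacts(frame_of(two_bead_complex(5.0)),
                                       two_bead_complex(5.0)), "site")
  # hydrogen at 3 A never counts while the nearest heavy pair is at 6 A
  cxh <- two_bead_complex(6, hyd_y_A = 3)
  expect_identical(heavy_atom_contacts(frame_of(cxh), cxh), character(0))
})

test_that("contact detection is invariant under global rigid motion", {
  cx <- two_bead_complex(4.7)
  fr <- frame_of(cx)
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(1.2, -0.7, 2.2)
  move <- function(m) sweep(m %*% t(R), 2, shift, "+")
  fr2 <- list(ligand = move(fr$ligand), receptor = move(fr$receptor),
              water = move(fr$water))
  expect_identical(heavy_atom_contacts(fr, cx),
                   heavy_atom_contacts(fr2, cx))
})

test_that("contact table equals recorded draws and sorts by frequency", {
  tr <- synth_contact_trajectory(c("bAsn215", "aTyr190", "midasMg"),
                                 p_contact = c(0.3, 0.9, 0.6),
                                 p_water = c(0.5, 0.25, 0.05),
                                 n_frames = 400, seed = 31)
  tab <- contact_frequency_table(tr)
  gt <- tr$ground_truth
  truth <- tapply(gt$contact, gt$group, sum)
  for (g in names(truth))
    expect_identical(tab$count[tab$group == g], as.integer(truth[[g]]))
  expect_true(all(diff(tab$percentage) <= 0))
  expect_equal(tab$percentage, 100 * tab$count / tab$total)
})

test_that("water mediation counts nested tiers exactly and monotonically", {
  tr <- synth_contact_trajectory(c("aAsp224", "aAsp232"),
                                 p_contact = c(0.8, 0.5),
                                 p_water = c(0.7, 0.4, 0.1),
                                 n_frames = 400, seed = 57)
  rep <- water_mediated_fraction(tr)
  gt <- tr$ground_truth
  for (g in rep$group) {
    gg <- gt[gt$group == g & gt$contact, ]
    expect_equal(rep$n_contact_frames[rep$group == g], nrow(gg))
    expect_equal(rep$frac_4[rep$group == g], mean(gg$water_4))
    expect_equal(rep$frac_3.3[rep$group == g], mean(gg$water_3.3))
    expect_equal(rep$frac_2.6[rep$group == g], mean(gg$water_2.6))
  }
  # tier monotonicity 4 >= 3.3 >= 2.6 on every row
  expect_true(all(rep$frac_4 >= rep$frac_3.3 - 1e-15))
  expect_true(all(rep$frac_3.3 >= rep$frac_2.6 - 1e-15))
})

test_that("hand-placed waters hit exactly the intended tiers", {
  # water equidistant at 2.5 A from both partners: all three tiers
  cx <- two_bead_complex(4.0, water = c(sqrt(2.5^2 - 2^2), 2, 0))
  tr <- list(complex = cx, n_frames = 1,
             ligand = array(cx$ligand_coords, c(1, 2, 3)),
             water = array(cx$water_coords, c(1, 1, 3)))
  class(tr) <- "toy_trajectory"
  rep <- water_mediated_fraction(tr)
  expect_equal(unlist(rep[1, c("frac_4", "frac_3.3", "frac_2.6")]),
               c(frac_4 = 1, frac_3.3 = 1, frac_2.6 = 1))
  # water 3.5 A from the receptor bead, 2.0 A from the ligand bead:
  # counted at the 4 A tier only (both <= 4; receptor side fails 3.3)
  w2 <- c(sqrt(12.25 - 3.03125^2), 3.03125, 0)
  stopifnot(abs(sqrt(sum(w2^2)) - 3.5) < 1e-9,
            abs(sqrt(sum((w2 - c(0, 4, 0))^2)) - 2.0) < 1e-9)
  cx2 <- two_bead_complex(4.0, water = w2)
  tr2 <- list(complex = cx2, n_frames = 1,
              ligand = array(cx2$ligand_coords, c(1, 2, 3)),
              water = array(cx2$water_coords, c(1, 1, 3)))
  class(tr2) <- "toy_trajectory"
  rep2 <- water_mediated_fraction(tr2)
  expect_equal(unlist(rep2[1, c("frac_4", "frac_3.3", "frac_2.6")]),
               c(frac_4 = 1, frac_3.3 = 0, frac_2.6 = 0))
  # no waters nearby: all fractions zero
  w3 <- c(30, 0, 0)
  cx3 <- two_bead_complex(4.0, water = w3)
  tr3 <- list(complex = cx3, n_frames = 1,
              ligand = array(cx3$ligand_coords, c(1, 2, 3)),
              water = array(cx3$water_coords, c(1, 1, 3)))
  class(tr3) <- "toy_trajectory"
  rep3 <- water_mediated_fraction(tr3)
  expect_equal(unlist(rep3[1, c("frac_4", "frac_3.3", "frac_2.6")]),
               c(frac_4 = 0, frac_3.3 = 0, frac_2.6 = 0))
})

test_that("Kabsch recovers pure rotations and matches the bio3d oracle", {
  skip_if_not_installed("bio3d")
  set.seed(12)
  ref <- matrix(rnorm(30), ncol = 3)
  expect_equal(kabsch_align(ref, ref)$rmsd_A, 0, tolerance = 1e-12)
  expect_equal(kabsch_align(ref, ref)$rotation, diag(3), tolerance = 1e-10)
  # known rotation: zero RMSD, recovered inverse
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mob <- sweep(ref %*% t(R), 2, c(0.5, -1, 2), "+")
  fit <- kabsch_align(mob, ref)
  expect_lt(fit$rmsd_A, 1e-10)
  expect_equal(fit$rotation %*% R, diag(3), tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
  # perturbed pair: RMSD matches an independent superposition (bio3d)
  for (i in 1:5) {
    mob2 <- mob + matrix(rnorm(30, sd = 0.05), ncol = 3)
    ours <- kabsch_align(mob2, ref)$rmsd_A
    fxyz <- bio3d::fit.xyz(fixed = as.vector(t(ref)),
                           mobile = matrix(as.vector(t(mob2)), nrow = 1),
                           fixed.inds = 1:30, mobile.inds = 1:30)
    fitted <- matrix(as.vector(fxyz), ncol = 3, byrow = TRUE)
    oracle <- sqrt(mean(rowSums((fitted - ref)^2)))  # nm
    expect_lt(abs(ours / 10 - oracle), 1e-10)
  }
  # RMSD invariant under pre-rotation of the mobile set
  pre <- mob + matrix(rnorm(30, sd = 0.1), ncol = 3)
  r1 <- kabsch_align(pre, ref)$rmsd_A
  r2 <- kabsch_align(sweep(pre %*% t(R), 2, c(3, 3, 3), "+"), ref)$rmsd_A
  expect_equal(r1, r2, tolerance = 1e-10)
  expect_error(kabsch_align(matrix(c(0, 0, 0, 1, 1, 1, 2, 2, 2), 3, byrow = TRUE),
                            ref[1:3, ]), "collinear")
})

test_that("reference distances behave under shifts and rigid motions", {
  set.seed(13)
  ref <- matrix(rnorm(24), ncol = 3)
  expect_equal(reference_distance(ref, ref, 3), 0)
  expect_equal(reference_distance(ref, ref, c(2, 5, 7),
                                  align_selection = 1:8), 0, tolerance = 1e-10)
  # 3-4-5 triangle with alignment disabled (Angstrom in, Angstrom out)
  shifted <- sweep(ref, 2, A_to_nm(c(3, 4, 0)), "+")
  expect_equal(reference_distance(shifted, ref, 1), 5, tolerance = 1e-10)
  # random rigid motion + all-atom alignment restores the original distance
  th <- 1.1
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  frame <- ref
  frame[5, ] <- frame[5, ] + c(0.12, -0.08, 0.3)   # genuine internal change
  d0 <- reference_distance(frame, ref, 5)
  moved <- sweep(frame %*% t(R), 2, c(-2, 1, 0.5), "+")
  expect_equal(reference_distance(moved, ref, 5, align_selection = c(1:4, 6:8)),
               d0, tolerance = 1e-8)
  expect_error(reference_distance(ref, ref, 99), "resolvable")
})

test_that("torsion angles match bio3d and drive the helicity window", {
  skip_if_not_installed("bio3d")
  set.seed(14)
  for (i in 1:10) {
    pts <- matrix(rnorm(12), ncol = 3)
    ours <- torsion_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    oracle <- bio3d::torsion.xyz(as.vector(t(pts)), atm.inc = 4)
    oracle <- oracle[!is.na(oracle)][1]
    expect_equal(ours, oracle, tolerance = 1e-6)
  }
})

test_that("helicity fraction classifies ideal secondary structures", {
  n <- 10
  expect_equal(helicity_fraction(rep(-57, n), rep(-47, n)), 100)
  expect_equal(helicity_fraction(rep(-135, n), rep(135, n)), 0)
  expect_equal(helicity_fraction(c(rep(-57, 5), rep(-135, 5)),
                                 c(rep(-47, 5), rep(135, 5))), 50)
  # NA termini excluded from the denominator
  expect_equal(helicity_fraction(c(NA, rep(-57, 4)), c(rep(-47, 4), NA)), 100)
  expect_error(helicity_fraction(-57, -47), "3 residues")
  # window is configurable
  expect_equal(helicity_fraction(rep(-57, 4), rep(-47, 4),
                                 phi_window = c(-56, -30)), 0)
})

test_that("phi/psi from backbone coordinates give full helicity for a helix", {
  # ideal alpha-helix backbone built from standard geometry
  skip_if_not_installed("bio3d")
  n_res <- 8
  # build a helix via successive rotation/translation along z
  t_rise <- 0.15; t_turn <- 100 * pi / 180
  at <- function(i, r, phase, zoff)
    c(r * cos(i * t_turn + phase), r * sin(i * t_turn + phase),
      i * t_rise + zoff)
  N <- t(sapply(1:n_res, at, r = 0.157, phase = -0.53, zoff = -0.08))
  CA <- t(sapply(1:n_res, at, r = 0.228, phase = 0, zoff = 0))
  C <- t(sapply(1:n_res, at, r = 0.168, phase = 0.76, zoff = 0.106))
  dih <- backbone_dihedrals(N, CA, C)
  expect_true(all(is.na(dih$phi[1]), is.na(dih$psi[n_res])))
  frac <- helicity_fraction(dih$phi, dih$psi)
  expect_gt(frac, 99)
})
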