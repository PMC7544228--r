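test_that("dihedral reproduces planar cis/trans and matches a brute-force oracle", {
  expect_equal(dihedral(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(1, 1, 1)), 0)
  expect_equal(dihedral(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(-1, -1, 1)), 180)
  set.seed(101)
  for (i in 1:100) {
    repeat {
      pts <- matrix(stats::rnorm(12, sd = 3), 4, 3)
      ok <- tryCatch({
        dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]); TRUE
      }, error = function(e) FALSE)
      if (ok) break
    }
    expect_equal(dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 dihedral_oracle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 tolerance = 1e-9)
  }
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "geometry error")
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "geometry error")
})

test_that("mirror reflection negates every dihedral modulo 360", {
  set.seed(11)
  for (i in 1:20) {
    pts <- matrix(stats::rnorm(12, sd = 3), 4, 3)
    d <- tryCatch(dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                  error = function(e) NA)
    if (is.na(d)) next
    ref <- pts
    ref[, 1] <- -ref[, 1]
    dm <- dihedral(ref[1, ], ref[2, ], ref[3, ], ref[4, ])
    expect_equal(g4conform:::wrap360(d + dm), 0, tolerance = 1e-9)
  }
})

test_that("glycosidic chi hits the built target and is rigid-motion invariant", {
  for (chi in c(60, 240, 320)) {
    res <- build_nucleotide("G", chi = chi, P = 18, tau_m = 38)
    expect_equal(glycosidic_chi(res), chi, tolerance = 0.5)
    moved <- rigid_move(res, seed = chi)
    expect_equal(glycosidic_chi(moved), glycosidic_chi(res), tolerance = 1e-6)
  }
  res <- build_nucleotide("C", chi = 200, P = 18, tau_m = 38)
  expect_equal(glycosidic_chi(res), 200, tolerance = 0.5)
  broken <- res[res$elety != "N1", ]
  expect_error(glycosidic_chi(broken), "named-atom error")
})

test_that("pseudorotation inverts the phase-amplitude cosine relation exactly", {
  nu <- 38 * cos(g4conform:::deg2rad(0 + 144 * ((0:4) - 2)))
  pk <- pseudorotation(nu)
  expect_equal(pk$P, 0, tolerance = 1e-9)
  expect_equal(pk$tau_m, 38, tolerance = 1e-9)
  for (P in seq(0, 350, by = 17)) for (tm in c(15, 38, 65)) {
    nu <- tm * cos(g4conform:::deg2rad(P + 144 * ((0:4) - 2)))
    pk <- pseudorotation(nu)
    expect_equal(pk$P, P, tolerance = 1e-6)
    expect_equal(pk$tau_m, tm, tolerance = 1e-6)
  }
  expect_error(pseudorotation(rep(0.1, 5)), "undefined-pucker")
})

test_that("ring coordinates built at a target pucker re-analyse to it", {
  r <- build_ring(162, 35)
  res <- build_nucleotide("G", chi = 240, P = 162, tau_m = 35)
  pk <- pseudorotation(sugar_torsions(res))
  expect_equal(pk$P, 162, tolerance = 1)
  expect_equal(pk$tau_m, 35, tolerance = 1)
  ## all torsions and the pucker are rigid-motion invariant
  moved <- rigid_move(res, seed = 5)
  expect_equal(unname(sugar_torsions(moved)), unname(sugar_torsions(res)),
               tolerance = 1e-6)
})

test_that("chi and pucker domains partition their circles with no gaps or overlaps", {
  grid <- seq(0, 359.95, by = 0.1)
  doms <- classify_chi(grid)
  expect_true(all(doms %in% c("syn", "intermediate", "anti", "low_syn")))
  expect_identical(classify_chi(320), "low_syn")
  expect_identical(classify_chi(60), "syn")
  expect_identical(classify_chi(240), "anti")
  expect_identical(classify_chi(150), "intermediate")
  ## each domain is one contiguous arc of the expected width
  expect_equal(as.vector(table(doms)[c("syn", "intermediate", "anti", "low_syn")]),
               c(1200, 600, 1200, 600))

  pk <- classify_pucker(grid)
  expect_true(all(pk$pucker_domain %in% c("north", "south")))
  expect_equal(sum(pk$pucker_domain == "north"), sum(pk$pucker_domain == "south"))
  expect_true(all(nchar(pk$conformer_label) > 0))
  expect_identical(classify_pucker(18)$pucker_domain, "north")
  expect_identical(classify_pucker(18)$conformer_label, "C3'-endo")
  expect_identical(classify_pucker(162)$pucker_domain, "south")
  expect_identical(classify_pucker(162)$conformer_label, "C2'-endo")
  expect_identical(classify_pucker(54)$conformer_label, "C4'-exo")
  expect_identical(classify_pucker(90)$conformer_label, "O4'-endo")
})

test_that("a locked sugar built at high amplitude reports C3'-endo near 60 degrees", {
  res <- build_nucleotide("G", chi = 240, P = 18, tau_m = 57, chemistry = "locked")
  pk <- pseudorotation(sugar_torsions(res))
  expect_equal(pk$tau_m, 57, tolerance = 1.5)
  cls <- classify_pucker(pk$P)
  expect_identical(cls$pucker_domain, "north")
  expect_identical(cls$conformer_label, "C3'-endo")
})

test_that("torsion_profile reports every nucleotide of every model with domains", {
  mk <- fixture_mock("antiparallel", sigma = 0.1, n_models = 2, seed = 3)
  prof <- torsion_profile(mk$ensemble)
  expect_setequal(unique(prof$model), 1:2)
  n_res <- length(model_residues(ensemble_model(mk$ensemble, 1),
                                 nucleotides = TRUE))
  expect_equal(nrow(prof), 2 * n_res)
  expect_true(all(c("chi", "chi_domain", "P", "tau_m", "pucker_domain",
                    "conformer_label", "sugar_chemistry") %in% names(prof)))
  core <- prof[prof$model == 1 & !is.na(prof$chi_domain), ]
  expect_true(all(abs(g4conform:::wrap180(core$nu2 -
    core$tau_m * cos(g4conform:::deg2rad(core$P)))) < 1e-6))
})
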