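test_that("H8 reconstruction matches built hydrogens and stays in the base plane", {
  for (chi in c(60, 240)) for (P in c(18, 162)) {
    res <- build_nucleotide("G", chi = chi, P = P, tau_m = 38)
    h8_file <- g4conform:::residue_atom(res, "H8")
    h8_rec <- reconstruct_h8(res)
    expect_lt(g4conform:::vnorm(h8_file - h8_rec), 0.05)
    ## coplanar with the ring at machine precision on the ideal base
    ring <- as.matrix(res[res$elety %in% c("N9", "C8", "N7", "C5", "C4"),
                          c("x", "y", "z")])
    ctr <- colMeans(ring)
    n <- svd(sweep(ring, 2, ctr))$v[, 3]
    expect_lt(abs(sum((h8_rec - ctr) * n)), 1e-6)
  }
  res <- build_nucleotide("G")
  expect_error(reconstruct_h8(res[res$elety != "N7", ]), "named-atom error")
})

test_that("contact distance, angle and call behave as constructed", {
  base <- build_nucleotide("G", chi = 240, P = 162, tau_m = 38, resno = 2)
  h8 <- g4conform:::residue_atom(base, "H8")
  c8 <- g4conform:::residue_atom(base, "C8")
  ## acceptor placed exactly 2.70 A from H8
  dir <- g4conform:::vunit(h8 - c8)
  acc_pos <- h8 + 2.70 * dir
  acceptor <- data.frame(model = 1L, chain = "A", resno = 1L, resid = "DG",
                         elety = "O4'", elem = "O",
                         x = acc_pos[1], y = acc_pos[2], z = acc_pos[3],
                         het = FALSE, is_nucleotide = TRUE)
  ct <- measure_contact(acceptor, "O4'", base)
  expect_equal(ct$distance, 2.70, tolerance = 1e-9)
  expect_equal(ct$angle, 180, tolerance = 1e-6)
  expect_identical(ct$call, "present")
  expect_identical(ct$h8_source, "file")
  expect_error(measure_contact(acceptor, "F2'", base), "named-atom error")

  ## the presence call partitions distance with no gaps and is monotone
  d <- seq(0.05, 6, by = 0.01)
  calls <- g4conform:::contact_call(d)
  expect_true(all(calls %in% c("present", "ambiguous", "absent")))
  code <- c(present = 1, ambiguous = 2, absent = 3)[calls]
  expect_true(all(diff(code) >= 0))
  expect_identical(g4conform:::contact_call(3.5), "present")
  expect_identical(g4conform:::contact_call(3.51), "ambiguous")
  expect_identical(g4conform:::contact_call(4.0), "absent")
})

test_that("reconstructed and file H8 give near-identical contact distances", {
  mk <- fixture_mock("vloop_conventional", sigma = 0, n_models = 1, seed = 13)
  model <- ensemble_model(mk$ensemble, 1)
  topo <- g4_topology(model)
  v <- topo$vloops[[1]]
  res <- model_residues(model, nucleotides = TRUE)
  names(res) <- vapply(res, g4conform:::residue_key, character(1))
  a3 <- res[[v$anchor3]]
  nxt <- res[[v$next_core]]
  with_h <- measure_contact(a3, "O5'", nxt)
  no_h <- measure_contact(a3, "O5'", nxt[nxt$elety != "H8", ])
  expect_identical(no_h$h8_source, "reconstructed")
  expect_lt(abs(with_h$distance - no_h$distance), 0.1)
  ## rigid-motion invariance of distance and angle
  moved_model <- rigid_move(model, seed = 31)
  res_m <- model_residues(moved_model, nucleotides = TRUE)
  names(res_m) <- vapply(res_m, g4conform:::residue_key, character(1))
  moved <- measure_contact(res_m[[v$anchor3]], "O5'", res_m[[v$next_core]])
  expect_equal(moved$distance, with_h$distance, tolerance = 1e-6)
  expect_equal(moved$angle, with_h$angle, tolerance = 1e-6)
})

test_that("the conventional V-loop carries the O5'-H8 contact; the alternative does not", {
  conv <- fixture_mock("vloop_conventional", sigma = 0.1, n_models = 4, seed = 5)
  topo <- ensemble_topology(conv$ensemble)$consensus
  sc <- scan_vloop_contacts(topo, conv$ensemble)
  o5 <- sc$summary[grepl("^O5'", sc$summary$contact), ]
  expect_equal(o5$occupancy, 1.0)
  expect_lt(o5$mean, 3.3)

  alt <- fixture_mock("vloop_alternative", sigma = 0.1, n_models = 4, seed = 5)
  topo_a <- ensemble_topology(alt$ensemble)$consensus
  sc_a <- scan_vloop_contacts(topo_a, alt$ensemble)
  o5_a <- sc_a$summary[grepl("^O5'", sc_a$summary$contact), ]
  expect_equal(o5_a$occupancy, 0)
  expect_gt(o5_a$min, 4.0)
})

test_that("occupancy counts the fraction of models with a present contact", {
  mk <- build_mock_quadruplex(mock_spec("vloop_conventional", sigma = 0,
                                        n_models = 10))
  topo <- g4_topology(ensemble_model(mk$ensemble, 1))
  v <- topo$vloops[[1]]
  ens <- mk$ensemble
  ## push the O5' acceptor far away in exactly 5 of the 10 models
  key <- paste(ens$atoms$chain, ens$atoms$resno)
  sel <- key == v$anchor3 & ens$atoms$elety == "O5'" & ens$atoms$model <= 5
  ens$atoms$z[sel] <- ens$atoms$z[sel] + 30
  sc <- scan_vloop_contacts(topo, ens)
  o5 <- sc$summary[grepl("^O5'", sc$summary$contact), ]
  expect_equal(o5$occupancy, 0.5)
})
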