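## Synthetic nucleotide construction with prescribed conformational
## parameters. Fixtures built here are idealized: standard bond lengths,
## planar bases, and only the geometric predicates the analysis modules
## read (torsions, pucker, H-bond geometry, backbone linkage) are
## guaranteed.

## Idealized planar nucleobase geometry (standard chemical-component
## reference coordinates, planarized). Columns x, y, z in Angstrom.
base_template <- local({
  mk <- function(v) {
    m <- matrix(unlist(v[c(FALSE, TRUE, TRUE, TRUE)]), ncol = 3, byrow = TRUE)
    rownames(m) <- unlist(v[c(TRUE, FALSE, FALSE, FALSE)])
    ## planarize exactly: project onto the best-fit plane
    c0 <- colMeans(m)
    s <- svd(sweep(m, 2, c0))
    n <- s$v[, 3]
    m - outer(drop(sweep(m, 2, c0) %*% n), n)
  }
  list(
    G = mk(list(
      "N9", -0.068, 0.111, -1.575, "C8", -1.172, 0.877, -1.341,
      "N7", -1.804, 1.094, -2.458, "C5", -1.145, 0.482, -3.472,
      "C6", -1.361, 0.377, -4.866, "O6", -2.321, 0.914, -5.391,
      "N1", -0.473, -0.327, -5.601, "C2", 0.593, -0.928, -5.003,
      "N2", 1.474, -1.643, -5.774, "N3", 0.804, -0.839, -3.709,
      "C4", -0.027, -0.152, -2.917, "H8", -1.477, 1.248, -0.373,
      "H1", -0.601, -0.413, -6.559, "H21", 2.240, -2.073, -5.363,
      "H22", 1.329, -1.722, -6.730)),
    A = mk(list(
      "N9", -0.078, -0.047, 1.852, "C8", 0.962, 0.817, 1.689,
      "N7", 1.535, 1.044, 2.835, "C5", 0.897, 0.346, 3.805,
      "C6", 1.069, 0.196, 5.191, "N6", 2.079, 0.869, 5.856,
      "N1", 0.236, -0.603, 5.850, "C2", -0.729, -1.249, 5.224,
      "N3", -0.925, -1.144, 3.927, "C4", -0.142, -0.368, 3.184,
      "H8", 1.266, 1.250, 0.748, "H2", -1.383, -1.889, 5.798)),
    C = mk(list(
      "N1", -0.267, -0.584, 2.528, "C2", 0.270, 0.648, 2.563,
      "O2", 0.052, 1.424, 1.647, "N3", 1.037, 1.035, 3.581,
      "C4", 1.291, 0.212, 4.589, "N4", 2.085, 0.622, 5.635,
      "C5", 0.746, -1.088, 4.580, "C6", -0.035, -1.465, 3.541,
      "H5", 0.943, -1.771, 5.394, "H6", -0.467, -2.454, 3.514)),
    T = mk(list(
      "N1", 1.164, -2.047, 0.989, "C2", 2.333, -2.544, 0.374,
      "O2", 3.410, -1.945, 0.363, "N3", 2.194, -3.793, -0.240,
      "C4", 1.047, -4.570, -0.300, "O4", 0.995, -5.663, -0.857,
      "C5", -0.143, -3.980, 0.369, "C7", -1.420, -4.757, 0.347,
      "C6", -0.013, -2.784, 0.958, "H3", 3.023, -4.171, -0.689,
      "H6", -0.857, -2.318, 1.458))
  )
})

## ---- furanose ring closure ---------------------------------------------

## Target endocyclic torsions for a given phase/amplitude.
nu_targets <- function(P, tau_m) {
  tau_m * cos(deg2rad(P + 144 * ((0:4) - 2)))
}

RING_BONDS <- c(1.52, 1.52, 1.52, 1.41, 1.41)  # C1'C2', C2'C3', C3'C4', C4'O4', O4'C1'

#' Build a furanose ring with a prescribed pucker
#'
#' Solves ring closure numerically for five ring atoms with standard bond
#' lengths (C-C 1.52 A, C-O 1.41 A) whose endocyclic torsions realise the
#' requested pseudorotation phase angle and amplitude to within 1 degree.
#'
#' @param P Pseudorotation phase angle, degrees.
#' @param tau_m Pucker amplitude, degrees, in `[0, 65]`.
#' @return A 5 x 3 coordinate matrix with rows `C1'`, `C2'`, `C3'`,
#'   `C4'`, `O4'`.
#' @export
build_ring <- function(P, tau_m) {
  if (tau_m < 0 || tau_m > 65)
    stop("build_ring: tau_m must lie in [0, 65] degrees")
  memo_key <- sprintf("ring|%.6f|%.6f", wrap360(P), tau_m)
  if (!is.null(.g4cache[[memo_key]])) return(.g4cache[[memo_key]])
  tgt <- nu_targets(P, tau_m)

  ## parameters: bond angles at C2', C3', C4' (radians) and the two
  ## construction torsions (degrees). The target torsion set is not
  ## always exactly closable with rigid standard bonds, so the error is
  ## spread in least squares over all five torsions; its component
  ## orthogonal to the pseudorotation cosine wave leaves the recovered
  ## (P, tau_m) essentially on target.
  build <- function(par) {
    a1 <- c(0, 0, 0)
    a2 <- c(RING_BONDS[1], 0, 0)
    a3 <- a2 + RING_BONDS[2] * c(-cos(par[1]), sin(par[1]), 0)
    a4 <- place_atom(a1, a2, a3, RING_BONDS[3], rad2deg(par[2]), par[4])
    a5 <- place_atom(a2, a3, a4, RING_BONDS[4], rad2deg(par[3]), par[5])
    rbind(a1, a2, a3, a4, a5)
  }
  objective <- function(par) {
    r <- build(par)
    dclose <- vnorm(r[5, ] - r[1, ]) - RING_BONDS[5]
    n4 <- dihedral_signed(r[3, ], r[4, ], r[5, ], r[1, ])
    n0 <- dihedral_signed(r[4, ], r[5, ], r[1, ], r[2, ])
    n1 <- dihedral_signed(r[5, ], r[1, ], r[2, ], r[3, ])
    1e4 * dclose^2 + wrap180(n4 - tgt[5])^2 + wrap180(n0 - tgt[1])^2 +
      wrap180(n1 - tgt[2])^2 + wrap180(par[4] - tgt[3])^2 +
      wrap180(par[5] - tgt[4])^2
  }
  best <- NULL
  for (start in c(103, 99, 106, 96, 93)) {
    fit <- stats::optim(c(rep(deg2rad(start), 3), tgt[3], tgt[4]), objective,
                        method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-15))
    fit <- stats::optim(fit$par, objective, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-15))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < 1e-8) break
  }
  r <- build(best$par)
  rownames(r) <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  ## verify the realised pucker
  nu <- c(dihedral_signed(r[4, ], r[5, ], r[1, ], r[2, ]),
          dihedral_signed(r[5, ], r[1, ], r[2, ], r[3, ]),
          dihedral_signed(r[1, ], r[2, ], r[3, ], r[4, ]),
          dihedral_signed(r[2, ], r[3, ], r[4, ], r[5, ]),
          dihedral_signed(r[3, ], r[4, ], r[5, ], r[1, ]))
  if (tau_m >= 2) {
    got <- pseudorotation(nu)
    if (angdiff(got$P, P) > 1 || abs(got$tau_m - tau_m) > 1)
      stop("g4conform builder-convergence error: ring closure missed the target pucker")
  } else if (max(abs(nu - tgt)) > 1) {
    stop("g4conform builder-convergence error: ring closure missed the target torsions")
  }
  .g4cache[[memo_key]] <- r
  r
}

## ---- nucleotide ---------------------------------------------------------

## canonical residue codes used by the fixture writer
chem_resid <- function(base, chemistry) {
  if (base == "G") {
    switch(chemistry,
           deoxyribose = "DG", ribose = "G", locked = "LNG",
           "2'F-ribo" = "GFR", "2'F-arabino" = "GFA", "DG")
  } else paste0("D", base)
}

#' Build an idealized nucleotide with prescribed conformation
#'
#' Combines a furanose ring from [build_ring()] with an idealized planar
#' base rotated to the requested glycosidic torsion, plus the backbone
#' and chemistry decorations (O2' for ribose, F2' on the ribo or arabino
#' face, the 2'-O-4'-C methylene bridge for locked sugars).
#'
#' @param base One of `"G"`, `"A"`, `"C"`, `"T"`.
#' @param chi Glycosidic torsion target, degrees.
#' @param P,tau_m Sugar pucker target passed to [build_ring()].
#' @param chemistry Sugar chemistry: `"deoxyribose"`, `"ribose"`,
#'   `"locked"`, `"2'F-ribo"` or `"2'F-arabino"`.
#' @param hydrogens Include base hydrogens (H8 etc.)?
#' @param resno,chain Residue numbering for the returned data frame.
#' @return A residue data frame (same layout as one element of
#'   [model_residues()]).
#' @export
build_nucleotide <- function(base = "G", chi = 240, P = 162, tau_m = 38,
                             chemistry = "deoxyribose", hydrogens = TRUE,
                             resno = 1L, chain = "A") {
  base <- match.arg(base, c("G", "A", "C", "T"))
  ring <- build_ring(P, tau_m)
  c1 <- ring["C1'", ]; c2 <- ring["C2'", ]; c3 <- ring["C3'", ]
  c4 <- ring["C4'", ]; o4 <- ring["O4'", ]
  ctr <- colMeans(ring)
  nrm <- {
    s <- svd(sweep(ring, 2, ctr))
    v <- s$v[, 3]
    ## canonical orientation so "up" is reproducible
    if (sum(v * vcross(c2 - c1, o4 - c1)) < 0) v <- -v
    v
  }
  face_of <- function(p, anchor) sign(sum((p - anchor) * nrm))

  ## exocyclic C5' (same face as the base, the +nrm face), O3', O5'
  cand <- lapply(c(120, -120), function(off)
    place_atom(c2, c3, c4, 1.51, 115,
               dihedral_signed(c2, c3, c4, o4) + off))
  c5 <- cand[[which(vapply(cand, face_of, numeric(1), anchor = c4) > 0)[1]]]
  o3cand <- lapply(c(120, -120), function(off)
    place_atom(o4, c4, c3, 1.42, 110.5,
               dihedral_signed(o4, c4, c3, c2) + off))
  ## O3' on the face opposite the base (standard beta-D configuration)
  o3 <- o3cand[[which(vapply(o3cand, face_of, numeric(1), anchor = c3) < 0)[1]]]
  o5 <- place_atom(c3, c4, c5, 1.42, 111, 60)

  ## base attachment nitrogen on the +nrm face
  nb_name <- if (base %in% c("G", "A")) "N9" else "N1"
  cb_name <- if (base %in% c("G", "A")) "C4" else "C2"
  ce_name <- if (base %in% c("G", "A")) "C8" else "C6"
  tmpl <- base_template[[base]]
  nbt <- tmpl[nb_name, ]; cbt <- tmpl[cb_name, ]; cet <- tmpl[ce_name, ]
  ncand <- lapply(c(240, 120), function(t9)
    place_atom(c4, o4, c1, 1.47, 108.2, t9))
  nb <- ncand[[which(vapply(ncand, face_of, numeric(1), anchor = c1) > 0)[1]]]
  ## place the two base anchor carbons with the template's own internal
  ## geometry so the rigid alignment below is exact and chi lands exactly
  cb <- place_atom(o4, c1, nb, vnorm(cbt - nbt), 126.4, chi)
  ce <- place_atom(c1, cb, nb, vnorm(cet - nbt),
                   bond_angle(cbt, nbt, cet), 180)
  fit <- kabsch_fit(rbind(nb, cb, ce), rbind(nbt, cbt, cet))
  placed <- sweep(tmpl %*% fit$rot, 2, -fit$trans)
  rownames(placed) <- rownames(tmpl)

  names <- c("C1'", "C2'", "C3'", "C4'", "O4'", "C5'", "O3'", "O5'")
  coords <- rbind(ring, c5, o3, o5)
  elem <- c("C", "C", "C", "C", "O", "C", "O", "O")

  if (chemistry %in% c("ribose", "locked")) {
    o2cand <- lapply(c(120, -120), function(off)
      place_atom(o4, c1, c2, 1.41, 110,
                 dihedral_signed(o4, c1, c2, c3) + off))
    o2 <- o2cand[[which(vapply(o2cand, face_of, numeric(1), anchor = c2) < 0)[1]]]
    if (chemistry == "locked") {
      ## tilt O2' towards C4' so the 2'-O-4'-C bridge can close
      ## (O2'...C4' about 2.4 A in the bicyclic sugar)
      u <- vunit(c4 - c2)
      w <- (o2 - c2) - sum((o2 - c2) * u) * u
      phi <- deg2rad(73)
      o2 <- c2 + 1.41 * (cos(phi) * u + sin(phi) * vunit(w))
    }
    coords <- rbind(coords, o2); names <- c(names, "O2'"); elem <- c(elem, "O")
    if (chemistry == "locked") {
      br <- sphere_bridge(o2, 1.43, c4, 1.52, away_from = ctr)
      coords <- rbind(coords, br); names <- c(names, "C6'"); elem <- c(elem, "C")
    }
  } else if (chemistry %in% c("2'F-ribo", "2'F-arabino")) {
    want <- if (chemistry == "2'F-ribo") -1 else 1
    fcand <- lapply(c(120, -120), function(off)
      place_atom(o4, c1, c2, 1.39, 109,
                 dihedral_signed(o4, c1, c2, c3) + off))
    f2 <- fcand[[which(vapply(fcand, face_of, numeric(1), anchor = c2) == want)[1]]]
    coords <- rbind(coords, f2); names <- c(names, "F2'"); elem <- c(elem, "F")
  } else if (chemistry != "deoxyribose") {
    stop("build_nucleotide: unknown chemistry: ", chemistry)
  }

  keep <- rownames(placed)
  if (!hydrogens) keep <- keep[!startsWith(keep, "H")]
  coords <- rbind(coords, placed[keep, , drop = FALSE])
  names <- c(names, keep)
  elem <- c(elem, substr(keep, 1, 1))

  data.frame(model = 1L, chain = chain, resno = as.integer(resno),
             resid = chem_resid(base, chemistry),
             elety = names, elem = elem,
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             het = FALSE, is_nucleotide = TRUE,
             stringsAsFactors = FALSE, row.names = NULL)
}

## point at given distances from two anchors, on the side away from `away_from`
sphere_bridge <- function(a, ra, b, rb, away_from) {
  ab <- b - a
  d <- vnorm(ab)
  if (d >= ra + rb) {  # degenerate: fall back to the joining segment
    return(a + (ra / d) * ab)
  }
  x <- (ra^2 - rb^2 + d^2) / (2 * d)
  h <- sqrt(max(0, ra^2 - x^2))
  u <- vunit(ab)
  w <- (a + x * u) - away_from
  w <- w - sum(w * u) * u
  if (vnorm(w) < 1e-6) {
    w <- vcross(u, c(1, 0, 0))
    if (vnorm(w) < 1e-6) w <- vcross(u, c(0, 1, 0))
  }
  a + x * u + h * vunit(w)
}
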