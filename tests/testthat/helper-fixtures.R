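## Shared fixtures and independent oracles for the test suite.
## Mocks used by several files are built once and memoized.

.fix <- new.env(parent = emptyenv())

fixture_mock <- function(preset, ...) {
  key <- paste(preset, paste(deparse(list(...)), collapse = ""), collapse = "|")
  if (is.null(.fix[[key]]))
    .fix[[key]] <- build_mock_quadruplex(mock_spec(preset, ...))
  .fix[[key]]
}

## apply a random rigid motion to an atom data frame (all models)
rigid_move <- function(atoms, seed = 1) {
  set.seed(seed)
  rot <- g4conform:::random_rotation()
  tr <- stats::rnorm(3, 0, 10)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% rot
  atoms$x <- xyz[, 1] + tr[1]
  atoms$y <- xyz[, 2] + tr[2]
  atoms$z <- xyz[, 3] + tr[3]
  atoms
}

## independent dihedral oracle: project the outer bonds onto the plane
## perpendicular to the central bond and measure the angle between the
## projections, signing it with the triple product (different
## construction from the package's normal-vector atan2 form)
dihedral_oracle <- function(p1, p2, p3, p4) {
  b <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  u <- (p1 - p2) - sum((p1 - p2) * b) * b
  v <- (p4 - p3) - sum((p4 - p3) * b) * b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[1] * v[3] - u[3] * v[1],
          u[1] * v[2] - u[2] * v[1])
  s <- sum(c(cr[1], -cr[2], cr[3]) * b)
  ## u x v along +b means p4 is rotated counterclockwise from p1:
  ## torsion negative in the IUPAC convention
  out <- if (s >= 0) ang else -ang
  ((out %% 360) + 360) %% 360
}

## independent superposition oracle: Horn's quaternion method
superpose_oracle <- function(ref, mov) {
  cr <- colMeans(ref); cm <- colMeans(mov)
  a <- sweep(mov, 2, cm); b <- sweep(ref, 2, cr)
  m <- t(a) %*% b
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy, szx - sxz, sxy - syx,
    syz - szy, sxx - syy - szz, sxy + syx, szx + sxz,
    szx - sxz, sxy + syx, -sxx + syy - szz, syz + szy,
    sxy - syx, szx + sxz, syz + szy, -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  e <- eigen(k, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  fitted <- sweep(a %*% t(rot), 2, -cr)
  list(rot = t(rot),
       rmsd = sqrt(mean(rowSums((fitted - ref)^2))))
}

## compare a detected topology against generator truth; returns a
## character vector of mismatched label groups (empty when perfect)
topology_mismatches <- function(topo, truth) {
  bad <- character(0)
  if (is.null(topo)) return("no-topology")
  if (!identical(lapply(topo$layers, function(q) sort(q$members)),
                 truth$layers))
    bad <- c(bad, "layers")
  det_cols <- vapply(1:4, function(cc)
    paste(sort(names(topo$column_of)[topo$column_of == cc]), collapse = ","),
    character(1))
  tru_cols <- vapply(truth$columns, paste, character(1), collapse = ",")
  if (!setequal(det_cols, tru_cols)) bad <- c(bad, "columns")
  if (!identical(topo$loops$type, truth$loop_types)) bad <- c(bad, "loops")
  det_tracts <- vapply(topo$tracts, function(t)
    paste(paste(t$members, collapse = ","), t$orientation), character(1))
  tru_tracts <- vapply(truth$tracts, function(t)
    paste(paste(t$members, collapse = ","), t$orientation), character(1))
  if (!setequal(det_tracts, tru_tracts)) bad <- c(bad, "tracts")
  det_rel <- ifelse(topo$polarity[-1] == topo$polarity[-length(topo$polarity)],
                    "homopolar", "heteropolar")
  if (!identical(det_rel, truth$relative_polarities))
    bad <- c(bad, "relative_polarities")
  det_v <- if (length(topo$vloops))
    paste(topo$vloops[[1]]$subtype, topo$vloops[[1]]$polarity_class) else "none"
  tru_v <- if (!is.null(truth$vloop))
    paste(truth$vloop$subtype, truth$vloop$polarity_class) else "none"
  if (!identical(det_v, tru_v)) bad <- c(bad, "vloop")
  bad
}
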