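## Mock quadruplex generator.
##
## Builds complete stacked-quartet structures with a prescribed topology
## plan (tract slots, loop types, V-loop inversion site, per-layer tetrad
## polarity, per-residue chi/pucker), plus Gaussian coordinate noise, and
## returns the ground-truth labels alongside the coordinates. Backbones
## between core anchors are idealized, not energy-minimized: only the
## geometric predicates the analysis reads (H-bond distances, torsions,
## axis-projected backbone orientations, P-O3' linkage) are guaranteed.

.g4cache <- new.env(parent = emptyenv())

## guanine base template rotated into the xy-plane, face (the side the
## Hoogsteen donor->acceptor cycle is viewed counterclockwise from) up
planar_g_template <- function() {
  if (!is.null(.g4cache$planarG)) return(.g4cache$planarG)
  tmpl <- base_template$G
  ctr <- colMeans(tmpl)
  s <- svd(sweep(tmpl, 2, ctr))
  rot <- s$v  ## columns: in-plane axes + normal
  m <- sweep(tmpl, 2, ctr) %*% rot  ## third column ~ 0 (planar)
  ## put the face normal (N9 -> C4 x N9 -> C8 chirality) along +z
  n <- vcross(m["C4", ] - m["N9", ], m["C8", ] - m["N9", ])
  if (n[3] < 0) m[, 3] <- -m[, 3] * 1  # reflect z (atoms are at z = 0 anyway)
  if (n[3] < 0) m[, 2] <- -m[, 2]      # in-plane flip to keep chirality proper
  m[, 3] <- 0
  .g4cache$planarG <- m
  m
}

## counterclockwise rotation about +z for row-vector coordinates
rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

## Solve the in-plane placement of a guanine so that four 90-degree
## rotated copies form a Hoogsteen-bonded quartet (N1->O6 and N2->N7 both
## 2.9 A around the cycle).
quartet_placement <- function() {
  if (!is.null(.g4cache$quartet_par)) return(.g4cache$quartet_par)
  tmpl <- planar_g_template()
  place <- function(par) sweep(tmpl %*% rot_z(par[3]), 2, -c(par[1], par[2], 0))
  ## the donor edge (N1/N2) of the copy at azimuth 0 bonds the acceptor
  ## edge (O6/N7) of the copy at azimuth +90: the hydrogen-bond cycle of
  ## a face-up quartet runs counterclockwise viewed from +z
  obj <- function(par) {
    b0 <- place(par)
    b1 <- b0 %*% rot_z(90)
    (vnorm(b0["N1", ] - b1["O6", ]) - 2.9)^2 +
      (vnorm(b0["N2", ] - b1["N7", ]) - 2.9)^2 +
      0.5 * (vnorm(colMeans(b0)) - 4.5)^2
  }
  best <- NULL
  for (psi in seq(0, 330, by = 30)) {
    fit <- stats::optim(c(4.5, 0, psi), obj, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  b0 <- place(best$par)
  b1 <- b0 %*% rot_z(90)
  if (abs(vnorm(b0["N1", ] - b1["O6", ]) - 2.9) > 0.1 ||
      abs(vnorm(b0["N2", ] - b1["N7", ]) - 2.9) > 0.1)
    stop("g4conform: quartet geometry solve failed")
  .g4cache$quartet_par <- best$par
  best$par
}

## Base coordinates of the four quartet slots for one layer.
## Returns a list of 4 coordinate matrices indexed by column position
## (columns sit at azimuth 0, 90, 180, 270 plus the layer twist).
## polarity +1 cycles counterclockwise viewed from +z; -1 is the
## in-plane mirror image (cycle reversed, base faces flipped).
quartet_slots <- function(polarity = 1, twist = 0, z = 0) {
  par <- quartet_placement()
  tmpl <- planar_g_template()
  b0 <- sweep(tmpl %*% rot_z(par[3]), 2, -c(par[1], par[2], 0))
  ## re-center so the base-ring centroid sits exactly at azimuth 0: the
  ## in-plane mirror (tetrad polarity reversal) then leaves each slot's
  ## centroid azimuth unchanged and column matching stays unambiguous
  ring_ctr <- colMeans(b0[intersect(BASE_RING_ATOMS, rownames(b0)), ])
  b0 <- b0 %*% rot_z(-rad2deg(atan2(ring_ctr[2], ring_ctr[1])))
  copies <- lapply(0:3, function(k) b0 %*% rot_z(90 * k))
  ## the face-up quartet detects as polarity +1; mirror for -1
  if (polarity < 0) {
    copies <- lapply(copies, function(m) {
      m[, 2] <- -m[, 2]
      m
    })
  }
  copies <- lapply(copies, function(m) {
    m <- m %*% rot_z(twist)
    m[, 3] <- m[, 3] + z
    m
  })
  ## assign copies to column positions by azimuth of their centroid
  target <- c(0, 90, 180, 270) + twist
  got <- vapply(copies, function(m) {
    ctr <- colMeans(m)
    wrap360(rad2deg(atan2(ctr[2], ctr[1])))
  }, numeric(1))
  idx <- vapply(target, function(a) which.min(angdiff(got, a)), integer(1))
  copies[idx]
}

#' Build an ideal Hoogsteen-bonded G-quartet
#'
#' Four guanosines in a planar quartet with both Hoogsteen hydrogen
#' bonds (N1...O6, N2...N7) at 2.9 A around the donor-to-acceptor cycle.
#' `polarity_sign = +1` makes the cycle counterclockwise viewed from +z
#' (so [quartet_polarity()] with axis `c(0, 0, 1)` returns `+1`);
#' `-1` builds the mirror image.
#'
#' @param polarity_sign `+1` or `-1`.
#' @param chi,P,tau_m Nucleoside conformation of the four guanosines.
#' @param chemistry Sugar chemistry for all four residues.
#' @return An atom data frame (one model, residues 1-4).
#' @export
build_quartet <- function(polarity_sign = 1, chi = 240, P = 162, tau_m = 38,
                          chemistry = "deoxyribose") {
  slots <- quartet_slots(polarity = polarity_sign)
  out <- list()
  for (k in 1:4) {
    res <- place_residue_on_base(
      build_nucleotide("G", chi = chi, P = P, tau_m = tau_m,
                       chemistry = chemistry, resno = k),
      slots[[k]])
    out[[k]] <- res
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

## rigidly place a built residue so its base atoms coincide with the
## target base coordinates (planar bases make this exact for both
## quartet mirror images)
place_residue_on_base <- function(residue, base_target) {
  nm <- intersect(rownames(base_target), residue$elety)
  nm <- setdiff(nm, c("H8", "H1", "H21", "H22"))
  src <- as.matrix(residue[match(nm, residue$elety), c("x", "y", "z")])
  fit <- kabsch_fit(base_target[nm, , drop = FALSE], src)
  xyz <- as.matrix(residue[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% fit$rot, 2, -fit$trans)
  residue$x <- xyz[, 1]; residue$y <- xyz[, 2]; residue$z <- xyz[, 3]
  residue
}

## ---- topology plans -----------------------------------------------------

## A plan is a data frame: resno, chain, role (core/loop), base, column,
## layer (NA for loops), chi (NA = derive), orient (planned backbone
## orientation +1/-1 along +z, NA = free), plus attributes:
## loop_types (expected labels in order), vloop (list or NULL).

plan_tract <- function(resno0, column, layers, chain = "A", chi = NA) {
  data.frame(resno = resno0 + seq_along(layers) - 1, chain = chain,
             role = "core", base = "G", column = column, layer = layers,
             chi = rep_len(chi, length(layers)), orient = NA_real_,
             stringsAsFactors = FALSE)
}

plan_loop <- function(resno0, n, chain = "A", bases = c("T", "T", "A")) {
  if (n == 0) return(NULL)
  data.frame(resno = resno0 + seq_len(n) - 1, chain = chain, role = "loop",
             base = rep_len(bases, n), column = NA, layer = NA,
             chi = NA_real_, orient = NA_real_, stringsAsFactors = FALSE)
}

mock_plan <- function(preset, n_layers = 3, chi_plan = NULL,
                      vloop_nt = 0) {
  up <- seq_len(n_layers)
  dn <- rev(up)
  rows <- list()
  r <- 1
  add <- function(x) {
    rows[[length(rows) + 1L]] <<- x
    if (!is.null(x)) r <<- max(x$resno) + 1
  }
  loop_types <- character(0)
  vloop <- NULL
  if (preset == "parallel") {
    for (col in 1:4) {
      add(plan_tract(r, col, up))
      if (col < 4) add(plan_loop(r, 2))
    }
    loop_types <- rep("propeller", 3)
  } else if (preset == "hybrid") {
    add(plan_tract(r, 1, up)); add(plan_loop(r, 2))
    add(plan_tract(r, 2, up)); add(plan_loop(r, 5, bases = c("A", "C", "A", "C", "A")))
    add(plan_tract(r, 3, dn)); add(plan_loop(r, 2))
    add(plan_tract(r, 4, up))
    loop_types <- c("propeller", "lateral", "lateral")
  } else if (preset == "antiparallel") {
    add(plan_tract(r, 1, up)); add(plan_loop(r, 2))
    add(plan_tract(r, 2, dn)); add(plan_loop(r, 2))
    add(plan_tract(r, 3, up)); add(plan_loop(r, 2))
    add(plan_tract(r, 4, dn))
    loop_types <- rep("lateral", 3)
  } else if (preset == "diagonal") {
    add(plan_tract(r, 1, up)); add(plan_loop(r, 2))
    add(plan_tract(r, 2, dn)); add(plan_loop(r, 3))
    add(plan_tract(r, 4, up)); add(plan_loop(r, 2))
    add(plan_tract(r, 3, dn))
    loop_types <- c("lateral", "diagonal", "lateral")
  } else if (preset %in% c("vloop_conventional", "vloop_alternative")) {
    if (n_layers != 3)
      stop("g4conform spec error: V-loop presets span exactly 3 layers")
    add(plan_tract(r, 1, up)); add(plan_loop(r, 2))
    add(plan_tract(r, 2, dn)); add(plan_loop(r, 2))
    a5 <- plan_tract(r, 3, 1)  # isolated anchor at layer 1
    add(a5)
    if (vloop_nt > 0) add(plan_loop(r, vloop_nt))
    a3row <- r
    add(plan_tract(r, 4, c(3, 2, 1)))  # anchor3 tract descends after the V
    ## second chain completes the interrupted column (layers 3 and 2)
    rows[[length(rows) + 1L]] <- plan_tract(1, 3, c(3, 2), chain = "B")
    loop_types <- c("lateral", "lateral", "V")
    idx <- function(df, resno) which(df$resno == resno & df$chain == "A")
    if (preset == "vloop_conventional") {
      orient <- c(a5 = 1, a3 = 1, nxt = -1)
    } else {
      orient <- c(a5 = 1, a3 = -1, nxt = -1)
    }
    vloop <- list(anchor5 = a5$resno[1], anchor3 = a3row,
                  next_core = a3row + 1, n_intervening = vloop_nt,
                  orient = orient,
                  subtype = sub("vloop_", "", preset))
  } else stop("g4conform spec error: unknown preset: ", preset)

  plan <- do.call(rbind, rows)
  if (!is.null(vloop)) {
    plan$orient[plan$resno == vloop$anchor5 & plan$chain == "A"] <- vloop$orient[["a5"]]
    plan$orient[plan$resno == vloop$anchor3 & plan$chain == "A"] <- vloop$orient[["a3"]]
    plan$orient[plan$resno == vloop$next_core & plan$chain == "A"] <- vloop$orient[["nxt"]]
  }
  if (!is.null(chi_plan)) {
    ci <- which(plan$role == "core")
    plan$chi[ci] <- rep_len(chi_plan, length(ci))
  }
  attr(plan, "loop_types") <- loop_types
  attr(plan, "vloop") <- vloop
  plan
}

#' Specification for a mock quadruplex
#'
#' Collects the generator parameters: the topology preset, layer count,
#' stack geometry (rise, twist), per-layer tetrad polarity plan,
#' optional per-residue glycosidic angles, V-loop length, ensemble size,
#' coordinate noise and seed. Defaults emulate a three-layer
#' potassium-form quadruplex: 3.3 A rise, 26 degree twist, 10 models and
#' 0.2 A coordinate noise (an NMR-ensemble-like spread).
#'
#' @param preset One of `"parallel"`, `"hybrid"`, `"antiparallel"`,
#'   `"diagonal"`, `"vloop_conventional"`, `"vloop_alternative"`.
#' @param n_layers Number of stacked quartets (V-loop presets require 3).
#' @param polarity Per-layer tetrad polarity signs (+1/-1), recycled.
#' @param chi_plan Optional per-core-residue glycosidic angles (degrees),
#'   recycled over core residues in sequence order.
#' @param vloop_nt Number of intervening nucleotides in the V-loop (0-2).
#' @param rise,twist Stack rise (Angstrom) and twist (degrees) per layer.
#' @param P,tau_m Default sugar pucker of built residues.
#' @param sigma Gaussian coordinate noise, Angstrom.
#' @param n_models Ensemble size.
#' @param seed RNG seed for the noise.
#' @return A `mock_spec` list.
#' @export
mock_spec <- function(preset = "hybrid", n_layers = 3, polarity = 1,
                      chi_plan = NULL, vloop_nt = 0, rise = 3.3, twist = 26,
                      P = 162, tau_m = 38, sigma = 0.2, n_models = 10,
                      seed = 0) {
  if (vloop_nt < 0 || vloop_nt > 2)
    stop("g4conform spec error: V-loop intervening count must be 0-2")
  ## the antiparallel preset carries the characteristic chair-type
  ## pattern: reversed central tetrad, two syn-syn-anti and two
  ## syn-anti-anti tracts (6 syn guanines in a 3-layer core)
  if (preset == "antiparallel" && n_layers == 3) {
    if (is.null(chi_plan))
      chi_plan <- c(60, 60, 240, 60, 240, 240, 60, 60, 240, 60, 240, 240)
    if (missing(polarity)) polarity <- c(1, -1, 1)
  }
  structure(list(preset = preset, n_layers = n_layers,
                 polarity = rep_len(polarity, n_layers),
                 chi_plan = chi_plan, vloop_nt = vloop_nt,
                 rise = rise, twist = twist, P = P, tau_m = tau_m,
                 sigma = sigma, n_models = n_models, seed = seed),
            class = "mock_spec")
}

#' Build a mock quadruplex ensemble with ground-truth labels
#'
#' Realizes a [mock_spec()]: stacks ideal quartets at the given rise and
#' twist, threads the chain through the planned tract slots, places loop
#' residues on idealized arcs, bridges consecutive residues with
#' phosphates (P-O3' linkage 1.6 A), adds Gaussian noise per model, and
#' returns the ensemble together with the labels the analysis modules are
#' expected to recover.
#'
#' @param spec A `mock_spec` (or preset name passed to [mock_spec()]).
#' @param ... Overrides forwarded to [mock_spec()] when `spec` is a name.
#' @return List with `ensemble` (a `g4_ensemble`), `truth` (layers,
#'   columns, tracts, loop types, V-loop labels, polarity plan, syn
#'   count) and `spec`.
#' @export
build_mock_quadruplex <- function(spec = "hybrid", ...) {
  if (is.character(spec)) spec <- mock_spec(spec, ...)
  plan <- mock_plan(spec$preset, spec$n_layers, spec$chi_plan, spec$vloop_nt)
  vloop <- attr(plan, "vloop")

  ## base slots per layer
  slots <- lapply(seq_len(spec$n_layers), function(l)
    quartet_slots(polarity = spec$polarity[l],
                  twist = spec$twist * (l - 1),
                  z = spec$rise * (l - 1)))

  residues <- vector("list", nrow(plan))
  ## core residues first (loop placement needs their positions)
  for (i in which(plan$role == "core")) {
    tgt <- slots[[plan$layer[i]]][[plan$column[i]]]
    chi_cands <- if (!is.na(plan$chi[i])) plan$chi[i]
    else if (!is.na(plan$orient[i])) c(240, 60)
    else 240
    best <- NULL
    for (chi in chi_cands) {
      res <- place_residue_on_base(
        build_nucleotide("G", chi = chi, P = spec$P, tau_m = spec$tau_m,
                         resno = plan$resno[i], chain = plan$chain[i]),
        tgt)
      dz <- res$z[res$elety == "C3'"] - res$z[res$elety == "C5'"]
      if (is.na(plan$orient[i]) || sign(dz) == plan$orient[i]) {
        best <- res
        break
      }
      if (is.null(best)) best <- res
    }
    residues[[i]] <- best
  }
  ## loop residues on arcs between flanking placed residues
  runs <- split(seq_len(nrow(plan)), cumsum(plan$role == "core"))
  for (run in runs) {
    li <- run[plan$role[run] == "loop"]
    if (!length(li)) next
    prev <- max(which(plan$role == "core" & seq_len(nrow(plan)) < li[1] &
                        plan$chain == plan$chain[li[1]]))
    nxt <- min(which(plan$role == "core" & seq_len(nrow(plan)) > li[length(li)] &
                       plan$chain == plan$chain[li[1]]))
    s <- with(residues[[prev]], c(x[elety == "C1'"], y[elety == "C1'"], z[elety == "C1'"]))
    e <- with(residues[[nxt]], c(x[elety == "C1'"], y[elety == "C1'"], z[elety == "C1'"]))
    k <- length(li)
    for (j in seq_len(k)) {
      t <- j / (k + 1)
      p <- (1 - t) * s + t * e
      radial <- c(p[1], p[2], 0)
      out <- if (vnorm(radial) < 1e-6) c(1, 0, 0) else vunit(radial)
      p <- p + 4 * sin(pi * t) * out
      res <- build_nucleotide(plan$base[li[j]], chi = 240, P = spec$P,
                              tau_m = spec$tau_m, resno = plan$resno[li[j]],
                              chain = plan$chain[li[j]])
      residues[[li[j]]] <- place_residue_at(res, p, out, e - s)
    }
  }

  residues <- residues[order(plan$chain, plan$resno)]
  plan_ord <- plan[order(plan$chain, plan$resno), ]

  ## V-loop contact geometry: the O5' of the 3'-anchor either forms the
  ## characteristic contact with the following guanine H8 (conventional)
  ## or points away from it (alternative)
  if (!is.null(vloop)) {
    i3 <- which(plan_ord$resno == vloop$anchor3 & plan_ord$chain == "A")
    inx <- which(plan_ord$resno == vloop$next_core & plan_ord$chain == "A")
    h8 <- with(residues[[inx]], c(x[elety == "H8"], y[elety == "H8"], z[elety == "H8"]))
    r3 <- residues[[i3]]
    c5 <- c(r3$x[r3$elety == "C5'"], r3$y[r3$elety == "C5'"], r3$z[r3$elety == "C5'"])
    o5i <- which(r3$elety == "O5'")
    if (vloop$subtype == "conventional") {
      o5 <- h8 + 2.9 * vunit(c5 - h8)
    } else {
      o5 <- c(r3$x[o5i], r3$y[o5i], r3$z[o5i])
      if (vnorm(o5 - h8) < 4.5) o5 <- c5 + 1.42 * vunit(c5 - h8)
    }
    r3$x[o5i] <- o5[1]; r3$y[o5i] <- o5[2]; r3$z[o5i] <- o5[3]
    residues[[i3]] <- r3
  }

  ## phosphate bridges: P placed 1.6 A from the previous O3' towards O5'
  for (i in seq_along(residues)[-1]) {
    if (plan_ord$chain[i] != plan_ord$chain[i - 1]) next
    prev <- residues[[i - 1]]
    cur <- residues[[i]]
    o3 <- c(prev$x[prev$elety == "O3'"], prev$y[prev$elety == "O3'"],
            prev$z[prev$elety == "O3'"])
    o5 <- c(cur$x[cur$elety == "O5'"], cur$y[cur$elety == "O5'"],
            cur$z[cur$elety == "O5'"])
    dir <- if (vnorm(o5 - o3) < 1e-6) c(0, 0, 1) else vunit(o5 - o3)
    p <- o3 + 1.6 * dir
    prow <- cur[1, ]
    prow$elety <- "P"; prow$elem <- "P"
    prow$x <- p[1]; prow$y <- p[2]; prow$z <- p[3]
    residues[[i]] <- rbind(prow, cur)
  }

  ideal <- do.call(rbind, residues)
  rownames(ideal) <- NULL

  ## ensemble with per-model Gaussian noise
  set.seed(spec$seed)
  models <- lapply(seq_len(spec$n_models), function(m) {
    a <- ideal
    a$model <- m
    n <- nrow(a)
    a$x <- a$x + stats::rnorm(n, 0, spec$sigma)
    a$y <- a$y + stats::rnorm(n, 0, spec$sigma)
    a$z <- a$z + stats::rnorm(n, 0, spec$sigma)
    a
  })
  ens <- new_g4_ensemble(do.call(rbind, models),
                         format = "mock", entry_id = toupper(spec$preset))

  ## ground truth
  core <- plan_ord[plan_ord$role == "core", ]
  key <- function(df) paste(df$chain, df$resno)
  layers <- lapply(seq_len(spec$n_layers), function(l)
    sort(key(core[core$layer == l, ])))
  columns <- lapply(1:4, function(cc) sort(key(core[core$column == cc, ])))
  tracts <- list()
  cur <- NULL
  for (i in seq_len(nrow(core))) {
    if (!is.null(cur) && core$chain[i] == cur$chain &&
        core$column[i] == cur$column) {
      cur$rows <- c(cur$rows, i)
    } else {
      if (!is.null(cur)) tracts[[length(tracts) + 1L]] <- cur
      cur <- list(chain = core$chain[i], column = core$column[i], rows = i)
    }
  }
  tracts[[length(tracts) + 1L]] <- cur
  tracts <- lapply(tracts, function(t) {
    rows <- core[t$rows, ]
    orientation <- if (nrow(rows) > 1) {
      if (rows$layer[nrow(rows)] > rows$layer[1]) "up" else "down"
    } else if (!is.na(rows$orient[1])) {
      if (rows$orient[1] > 0) "up" else "down"
    } else "up"
    list(members = key(rows), orientation = orientation,
         complete = nrow(rows) == spec$n_layers)
  })
  rel <- ifelse(spec$polarity[-1] == spec$polarity[-spec$n_layers],
                "homopolar", "heteropolar")
  truth <- list(
    preset = spec$preset, n_layers = spec$n_layers,
    layers = layers, columns = columns, tracts = tracts,
    loop_types = attr(plan, "loop_types"),
    polarity_plan = spec$polarity, relative_polarities = rel,
    syn_count = sum(classify_chi(core$chi[!is.na(core$chi)]) == "syn"),
    vloop = if (is.null(vloop)) NULL else list(
      anchor5 = paste("A", vloop$anchor5), anchor3 = paste("A", vloop$anchor3),
      n_intervening = vloop$n_intervening, layers_spanned = 3,
      subtype = vloop$subtype,
      inversion_site = if (vloop$subtype == "conventional") "after_loop" else "within_loop",
      polarity_class = if (spec$polarity[1] == spec$polarity[3]) "V_S" else "V_R"),
    seed = spec$seed, sigma = spec$sigma)

  list(ensemble = ens, truth = truth, spec = spec)
}

## place a residue so C1' sits at `at`, the glycosidic direction points
## along `out` and the backbone roughly along `tangent`
place_residue_at <- function(residue, at, out, tangent) {
  c1 <- residue_atom(residue, "C1'")
  nb <- residue_atom(residue, if (base_type(residue) == "purine") "N9" else "N1")
  c5 <- residue_atom(residue, "C5'")
  c3 <- residue_atom(residue, "C3'")
  l1 <- vunit(nb - c1)
  l2 <- (c3 - c5) - sum((c3 - c5) * l1) * l1
  l2 <- vunit(l2)
  t1 <- vunit(out)
  t2 <- tangent - sum(tangent * t1) * t1
  t2 <- if (vnorm(t2) < 1e-6) vunit(vcross(t1, c(0, 0, 1))) else vunit(t2)
  src <- rbind(c1, c1 + l1, c1 + l2, c1 + vcross(l1, l2))
  dst <- rbind(at, at + t1, at + t2, at + vcross(t1, t2))
  fit <- kabsch_fit(dst, src)
  xyz <- as.matrix(residue[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% fit$rot, 2, -fit$trans)
  residue$x <- xyz[, 1]; residue$y <- xyz[, 2]; residue$z <- xyz[, 3]
  residue
}

#' Random mock specification
#'
#' Draws a random valid topology plan (preset, layer count, polarity
#' signs, V-loop subtype and length, twist) with coordinate noise up to
#' `sigma_max`, for property-style pipeline-recovery tests.
#'
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param sigma_max Upper bound for the coordinate noise (Angstrom).
#' @param n_models Ensemble size of the generated mock.
#' @return A `mock_spec`.
#' @export
random_mock_spec <- function(seed, sigma_max = 0.3, n_models = 3) {
  set.seed(seed)
  preset <- sample(c("parallel", "hybrid", "antiparallel", "diagonal",
                     "vloop_conventional", "vloop_alternative"), 1)
  vl <- startsWith(preset, "vloop")
  n_layers <- if (vl) 3 else sample(2:4, 1)
  mock_spec(preset = preset, n_layers = n_layers,
            polarity = sample(c(1, -1), n_layers, replace = TRUE),
            vloop_nt = if (vl) sample(0:2, 1) else 0,
            twist = sample(c(20, 26, 30), 1),
            sigma = stats::runif(1, 0, sigma_max),
            n_models = n_models,
            seed = sample.int(1e6, 1))
}
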