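## G-quartet detection and quadruplex topology classification.
##
## A quartet is a directed 4-cycle in the Hoogsteen hydrogen-bond graph
## (edge A -> B iff both N1(A)..O6(B) and N2(A)..N7(B) are within the
## heavy-atom cutoff). Stacked quartets define layers along the stack
## axis; guanines matched across adjacent layers form columns; maximal
## runs of sequence-consecutive core guanines sharing a column are
## G-tracts; non-core residues between consecutive core anchors are
## loops, classified as lateral, diagonal, propeller or V-shaped.

BASE_RING_ATOMS <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")

base_centroid <- function(residue) {
  sel <- residue$elety %in% BASE_RING_ATOMS
  if (!any(sel)) stop("g4conform: residue has no base ring atoms")
  colMeans(as.matrix(residue[sel, c("x", "y", "z")]))
}

#' Detect Hoogsteen hydrogen-bond edges between guanines
#'
#' An ordered donor-to-acceptor edge A -> B exists iff both heavy-atom
#' criteria hold: `d(N1_A, O6_B) <= cutoff` and `d(N2_A, N7_B) <= cutoff`.
#' The criterion is distance-only so that it works for deposits without
#' hydrogens.
#'
#' @param model An atom data frame (one model), see [ensemble_model()].
#' @param dist_cutoff Heavy-atom distance cutoff in Angstrom.
#' @return Data frame with columns `donor`, `acceptor` (residue keys
#'   `"chain resno"`), `d_n1o6`, `d_n2n7`.
#' @export
detect_hoogsteen_edges <- function(model, dist_cutoff = 3.5) {
  res <- model_residues(model, nucleotides = TRUE)
  gs <- Filter(is_guanine, res)
  out <- list()
  if (length(gs) >= 2) {
    n1 <- t(vapply(gs, residue_atom, numeric(3), name = "N1"))
    n2 <- t(vapply(gs, residue_atom, numeric(3), name = "N2"))
    o6 <- t(vapply(gs, residue_atom, numeric(3), name = "O6"))
    n7 <- t(vapply(gs, residue_atom, numeric(3), name = "N7"))
    keys <- vapply(gs, residue_key, character(1))
    for (i in seq_along(gs)) for (j in seq_along(gs)) {
      if (i == j) next
      d1 <- vnorm(n1[i, ] - o6[j, ])
      d2 <- vnorm(n2[i, ] - n7[j, ])
      if (d1 <= dist_cutoff && d2 <= dist_cutoff) {
        out[[length(out) + 1L]] <- data.frame(
          donor = keys[i], acceptor = keys[j],
          d_n1o6 = d1, d_n2n7 = d2, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(donor = character(0), acceptor = character(0),
                      d_n1o6 = numeric(0), d_n2n7 = numeric(0)))
  }
  do.call(rbind, out)
}

## residue-key ordering: chain, then numeric residue number
key_order <- function(keys) {
  parts <- strsplit(keys, " ", fixed = TRUE)
  order(vapply(parts, `[`, character(1), 1),
        as.integer(vapply(parts, `[`, character(1), 2)))
}

#' Detect G-quartets as directed 4-cycles of Hoogsteen edges
#'
#' Each directed 4-cycle is reported once, rotated to start at its lowest
#' (chain, seq_index) member; cycles sharing three or more members are
#' merged, keeping the cycle with the smaller mean hydrogen-bond distance.
#'
#' @inheritParams detect_hoogsteen_edges
#' @param edges Edge table from [detect_hoogsteen_edges()]; recomputed
#'   when omitted.
#' @return List of quartets; each has `members` (keys in donor-to-acceptor
#'   cycle order), `mean_dist`, `centroid`, `normal` and `base_centroids`.
#' @export
detect_quartets <- function(model, edges = NULL, dist_cutoff = 3.5) {
  if (is.null(edges)) edges <- detect_hoogsteen_edges(model, dist_cutoff)
  if (!nrow(edges)) return(list())
  nodes <- unique(c(edges$donor, edges$acceptor))
  nodes <- nodes[key_order(nodes)]
  adj <- split(edges$acceptor, factor(edges$donor, levels = nodes))
  edist <- (edges$d_n1o6 + edges$d_n2n7) / 2
  names(edist) <- paste(edges$donor, edges$acceptor, sep = ">")
  cycles <- list()
  for (a in nodes) {
    for (b in adj[[a]]) {
      if (b == a) next
      for (cc in adj[[b]]) {
        if (cc %in% c(a, b)) next
        for (d in adj[[cc]]) {
          if (d %in% c(a, b, cc)) next
          if (a %in% adj[[d]]) {
            mem <- c(a, b, cc, d)
            ## canonical: cycle starts at its lowest member; since `a`
            ## iterates in key order, keep only cycles whose lowest is `a`
            if (key_order(mem)[1] == 1) {
              id <- paste(mem, collapse = "|")
              if (is.null(cycles[[id]])) {
                md <- mean(edist[paste(mem, c(mem[-1], mem[1]), sep = ">")])
                cycles[[id]] <- list(members = mem, mean_dist = md)
              }
            }
          }
        }
      }
    }
  }
  cycles <- unname(cycles)
  if (!length(cycles)) return(list())
  ## merge cycles sharing >= 3 members (keep smaller mean H-bond distance)
  keep <- rep(TRUE, length(cycles))
  ord <- order(vapply(cycles, `[[`, numeric(1), "mean_dist"))
  for (i in seq_along(ord)) {
    if (!keep[ord[i]]) next
    for (j in ord[-seq_len(i)]) {
      if (keep[j] &&
          length(intersect(cycles[[ord[i]]]$members, cycles[[j]]$members)) >= 3)
        keep[j] <- FALSE
    }
  }
  cycles <- cycles[keep]
  res <- model_residues(model, nucleotides = TRUE)
  names(res) <- vapply(res, residue_key, character(1))
  out <- lapply(cycles, function(q) {
    bc <- t(vapply(q$members, function(k) base_centroid(res[[k]]), numeric(3)))
    ctr <- colMeans(bc)
    ring <- do.call(rbind, lapply(q$members, function(k) {
      r <- res[[k]]
      as.matrix(r[r$elety %in% BASE_RING_ATOMS, c("x", "y", "z")])
    }))
    s <- svd(sweep(ring, 2, colMeans(ring)))
    q$base_centroids <- bc
    q$centroid <- ctr
    q$normal <- s$v[, 3]
    q
  })
  ## quartets are planar side-by-side arrangements: drop cycles whose
  ## base centroids straddle the fitted plane by more than 1 A or whose
  ## members come closer than 5 A center-to-center (stacked, not
  ## hydrogen-bonded, neighbours) - guards against cross-layer cycles
  Filter(function(q) {
    dev_ok <- max(abs(drop(sweep(q$base_centroids, 2, q$centroid) %*%
                             q$normal))) < 1
    sep <- stats::dist(q$base_centroids)
    dev_ok && min(sep) >= 5
  }, out)
}

#' Tetrad polarity of a quartet relative to the stack axis
#'
#' The polarity sign is the rotational sense of the donor-to-acceptor
#' hydrogen-bond cycle: the sign of the summed axis-projected cross
#' products of consecutive centroid-relative base positions. Adjacent
#' layers with equal sign stack homopolar, with opposite sign heteropolar.
#'
#' @param quartet A quartet from [detect_quartets()].
#' @param axis Unit 3-vector of the stack axis.
#' @return `+1` or `-1`.
#' @export
quartet_polarity <- function(quartet, axis) {
  r <- sweep(quartet$base_centroids, 2, quartet$centroid)
  s <- 0
  for (i in 1:4) {
    j <- if (i == 4) 1 else i + 1
    s <- s + sum(axis * vcross(r[i, ], r[j, ]))
  }
  if (s >= 0) 1L else -1L
}

#' Stack detected quartets into layers and columns
#'
#' The stack axis is the first principal direction of the quartet
#' centroids, oriented so that layer 1 contains the 5'-most core guanine.
#' Columns are formed by matching each guanine to the nearest base
#' centroid of the adjacent layer (must be within `col_cutoff`).
#'
#' @param quartets List from [detect_quartets()] (at least 2).
#' @param model The atom data frame the quartets came from.
#' @param col_cutoff Maximum adjacent-layer base-centroid distance
#'   (Angstrom) for column matching.
#' @return List with `axis`, `layers` (quartet list ordered along the
#'   axis), `column_of` (named vector residue key -> column id),
#'   `layer_of`, `flags` (stacking warnings).
#' @export
stack_quartets <- function(quartets, model, col_cutoff = 5) {
  if (length(quartets) < 2)
    stop("g4conform topology error: need at least 2 quartets to stack")
  ctr <- t(vapply(quartets, `[[`, numeric(3), "centroid"))
  axis <- prcomp(ctr)$rotation[, 1]
  core <- unique(unlist(lapply(quartets, `[[`, "members")))
  first_core <- core[key_order(core)][1]
  qi_first <- which(vapply(quartets, function(q) first_core %in% q$members,
                           logical(1)))[1]
  proj <- drop(ctr %*% axis)
  if (proj[qi_first] > mean(proj)) {
    axis <- -axis
    proj <- -proj
  }
  ord <- order(proj)
  layers <- quartets[ord]
  proj <- proj[ord]
  flags <- character(0)
  gaps <- diff(proj)
  if (any(gaps < 2.5 | gaps > 5.5))
    flags <- c(flags, sprintf("stacking warning: adjacent layer spacing %.2f A outside [2.5, 5.5]",
                              gaps[which(gaps < 2.5 | gaps > 5.5)[1]]))
  ## columns: optimal 1-1 matching between adjacent layers (4! = 24 cases)
  perms <- permutations4()
  col_of <- stats::setNames(seq_len(4), layers[[1]]$members)
  for (l in seq_along(layers)[-1]) {
    prev <- layers[[l - 1]]
    cur <- layers[[l]]
    dmat <- outer(1:4, 1:4, Vectorize(function(i, j)
      vnorm(prev$base_centroids[i, ] - cur$base_centroids[j, ])))
    costs <- apply(perms, 1, function(p) sum(dmat[cbind(1:4, p)]))
    p <- perms[which.min(costs), ]
    if (any(dmat[cbind(1:4, p)] > col_cutoff))
      stop("g4conform topology error: unmatched column between layers ",
           l - 1, " and ", l)
    col_of[cur$members[p]] <- col_of[prev$members]
  }
  layer_of <- integer(0)
  for (l in seq_along(layers))
    layer_of[layers[[l]]$members] <- l
  list(axis = axis, layers = layers, column_of = col_of,
       layer_of = layer_of, flags = flags)
}

permutations4 <- function() {
  m <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  m <- as.matrix(m[apply(m, 1, function(r) length(unique(r)) == 4), ])
  dimnames(m) <- NULL
  m
}

## per-residue backbone orientation along the axis: sign of the
## axis-projected 5'->3' sugar vector (C5' -> C3')
backbone_orientation <- function(residue, axis) {
  c5 <- residue_atom(residue, "C5'", required = FALSE)
  c3 <- residue_atom(residue, "C3'", required = FALSE)
  if (is.null(c5) || is.null(c3)) return(NA_integer_)
  if (sum(axis * (c3 - c5)) >= 0) 1L else -1L
}

#' Full quadruplex topology of one model
#'
#' Runs the complete chain: Hoogsteen edge detection, quartet detection,
#' stacking, tetrad polarity, tract assembly and loop classification
#' including V-shaped loop subtyping.
#'
#' @param model Atom data frame of one model.
#' @param hbond_cutoff Heavy-atom Hoogsteen distance cutoff (Angstrom).
#' @param col_cutoff Column-matching cutoff (Angstrom).
#' @return A `g4_topology` object: `n_layers`, `axis`, `layers`,
#'   `polarity` (per layer), `relative_polarities`, `column_of`,
#'   `layer_of`, `core`, `tracts`, `loops`, `vloops`, `flags`.
#' @export
g4_topology <- function(model, hbond_cutoff = 3.5, col_cutoff = 5) {
  ## moderate cutoff ladder: use the smallest cutoff that recovers the
  ## maximal quartet count, and likewise relax column matching on
  ## failure, flagging any relaxation so noisy ensemble members degrade
  ## visibly instead of silently
  factors <- c(1, 1.15, 1.3)
  dets <- lapply(factors, function(f) {
    edges <- detect_hoogsteen_edges(model, hbond_cutoff * f)
    list(f = f, edges = edges, quartets = detect_quartets(model, edges))
  })
  counts <- vapply(dets, function(d) length(d$quartets), integer(1))
  pick <- dets[[which(counts == max(counts))[1]]]
  relax_flags <- if (pick$f > 1)
    sprintf("H-bond cutoff relaxed by factor %.2f", pick$f) else character(0)
  edges <- pick$edges
  quartets <- pick$quartets
  if (length(quartets) < 2)
    stop("g4conform topology error: fewer than 2 quartets detected")
  st <- NULL
  for (extra in c(0, 0.75, 1.5)) {
    st <- tryCatch(stack_quartets(quartets, model, col_cutoff + extra),
                   error = function(e) e)
    if (!inherits(st, "error")) {
      if (extra > 0)
        relax_flags <- c(relax_flags,
                         sprintf("column cutoff relaxed by %.2f A", extra))
      break
    }
  }
  if (inherits(st, "error")) stop(st)
  st$flags <- c(st$flags, relax_flags)
  polarity <- vapply(st$layers, quartet_polarity, integer(1), axis = st$axis)
  relpol <- if (length(polarity) > 1) {
    ifelse(polarity[-1] == polarity[-length(polarity)],
           "homopolar", "heteropolar")
  } else character(0)

  res <- model_residues(model, nucleotides = TRUE)
  keys <- vapply(res, residue_key, character(1))
  names(res) <- keys
  core <- names(st$layer_of)
  topo <- list(n_layers = length(st$layers), axis = st$axis,
               layers = st$layers, polarity = polarity,
               relative_polarities = relpol,
               column_of = st$column_of, layer_of = st$layer_of,
               core = core, flags = st$flags)
  class(topo) <- "g4_topology"

  topo$tracts <- build_tracts(topo, res)
  lp <- classify_loops(topo, model)
  topo$loops <- lp$loops
  topo$vloops <- lp$vloops
  topo$flags <- c(topo$flags, lp$flags)
  topo
}

## tracts: maximal runs of sequence-consecutive core Gs sharing a column
## (chain-internal sequence adjacency only)
build_tracts <- function(topo, res) {
  keys <- names(res)
  core_keys <- keys[keys %in% topo$core]
  core_keys <- core_keys[key_order(core_keys)]
  tracts <- list()
  cur <- character(0)
  flush <- function(tracts, cur) {
    if (length(cur)) tracts[[length(tracts) + 1L]] <- cur
    tracts
  }
  for (k in core_keys) {
    if (!length(cur)) { cur <- k; next }
    last <- cur[length(cur)]
    same_chain <- strsplit(last, " ")[[1]][1] == strsplit(k, " ")[[1]][1]
    same_col <- topo$column_of[[last]] == topo$column_of[[k]]
    if (same_chain && same_col) cur <- c(cur, k) else {
      tracts <- flush(tracts, cur); cur <- k
    }
  }
  tracts <- flush(tracts, cur)
  lapply(tracts, function(keys) {
    l1 <- topo$layer_of[[keys[1]]]
    l2 <- topo$layer_of[[keys[length(keys)]]]
    orientation <- if (length(keys) > 1) {
      if (l2 > l1) "up" else "down"
    } else {
      o <- backbone_orientation(res[[keys[1]]], topo$axis)
      if (is.na(o)) "up" else if (o > 0) "up" else "down"
    }
    list(members = keys, column = unname(topo$column_of[[keys[1]]]),
         orientation = orientation,
         complete = length(keys) == topo$n_layers)
  })
}

## column angular adjacency around the axis
column_angles <- function(topo) {
  ctr <- colMeans(t(vapply(topo$layers, `[[`, numeric(3), "centroid")))
  ang <- numeric(4)
  ref <- NULL
  for (col in 1:4) {
    pts <- list()
    for (q in topo$layers) {
      i <- which(topo$column_of[q$members] == col)
      if (length(i)) pts[[length(pts) + 1L]] <- q$base_centroids[i, ]
    }
    v <- colMeans(do.call(rbind, pts)) - ctr
    v <- v - sum(v * topo$axis) * topo$axis
    if (is.null(ref)) {
      ref <- vunit(v)
      ref2 <- vcross(topo$axis, ref)
    }
    ang[col] <- rad2deg(atan2(sum(v * ref2), sum(v * ref)))
  }
  ang
}

#' Classify the loops of a quadruplex topology
#'
#' For each pair of sequence-consecutive core anchors in different
#' columns: a same-layer connection is lateral (adjacent columns) or
#' diagonal (across the diagonal); an opposite-end connection is a
#' propeller loop when both anchor tracts fill their columns, and a
#' V-shaped loop when the column pair is interrupted, the columns are
#' neighbours, at most 2 residues intervene and at least 3 layers are
#' spanned. Anchors sharing a column are tract continuations, not loops.
#'
#' @param topology A `g4_topology` (layers/columns/tracts assigned).
#' @param model The atom data frame.
#' @return List with `loops` (data frame: anchor5, anchor3, type,
#'   n_intervening, layers_spanned, residues), `vloops` (list of V-loop
#'   records from [classify_vloop()]), `flags`.
#' @export
classify_loops <- function(topology, model) {
  res <- model_residues(model, nucleotides = TRUE)
  keys <- vapply(res, residue_key, character(1))
  names(res) <- keys
  ang <- column_angles(topology)
  adjacent <- function(c1, c2) angdiff(ang[c1], ang[c2]) < 135

  tract_of <- integer(0)
  for (i in seq_along(topology$tracts))
    tract_of[topology$tracts[[i]]$members] <- i

  core_idx <- which(keys %in% topology$core)
  loops <- list()
  vloops <- list()
  flags <- character(0)
  for (i in seq_along(core_idx)[-1]) {
    a <- keys[core_idx[i - 1]]
    b <- keys[core_idx[i]]
    if (strsplit(a, " ")[[1]][1] != strsplit(b, " ")[[1]][1]) next
    ca <- topology$column_of[[a]]
    cb <- topology$column_of[[b]]
    if (ca == cb) next  # tract continuation
    between <- keys[setdiff(seq(core_idx[i - 1] + 1, core_idx[i] - 1),
                            integer(0))]
    between <- between[!(between %in% topology$core)]
    if (core_idx[i] - core_idx[i - 1] == 1) between <- character(0)
    la <- topology$layer_of[[a]]
    lb <- topology$layer_of[[b]]
    span <- abs(lb - la) + 1
    adj <- adjacent(ca, cb)
    ta <- topology$tracts[[tract_of[[a]]]]
    tb <- topology$tracts[[tract_of[[b]]]]
    type <- if (la == lb) {
      if (adj) "lateral" else "diagonal"
    } else if (span == topology$n_layers) {
      if (ta$complete && tb$complete) "propeller"
      else if (adj && length(between) <= 2 && span >= 3) "V"
      else "propeller"
    } else {
      flags <- c(flags, sprintf("irregular loop geometry between %s and %s", a, b))
      if (adj) "lateral" else "diagonal"
    }
    loops[[length(loops) + 1L]] <- data.frame(
      anchor5 = a, anchor3 = b, type = type,
      n_intervening = length(between), layers_spanned = span,
      residues = paste(between, collapse = ";"),
      stringsAsFactors = FALSE)
    if (type == "V") {
      rec <- tryCatch(
        classify_vloop(list(anchor5 = a, anchor3 = b, intervening = between,
                            layers_spanned = span),
                       topology, model),
        error = function(e) {
          flags <<- c(flags, conditionMessage(e))
          NULL
        })
      if (!is.null(rec)) vloops[[length(vloops) + 1L]] <- rec
    }
  }
  loops <- if (length(loops)) do.call(rbind, loops) else
    data.frame(anchor5 = character(0), anchor3 = character(0),
               type = character(0), n_intervening = integer(0),
               layers_spanned = integer(0), residues = character(0))
  list(loops = loops, vloops = vloops, flags = flags)
}

#' Subtype a V-shaped loop
#'
#' The inversion site is located from per-residue backbone orientations
#' (the sign of the axis-projected C5'-to-C3' vector): an orientation
#' change between the two anchors puts the strand-polarity inversion
#' within the loop (alternative V-loop); anchors with equal orientation
#' but an orientation change towards the next core guanine put it after
#' the loop (conventional V-loop). The polarity class compares the tetrad
#' polarity signs of the two linked quartets: equal signs give V_S,
#' opposite give V_R.
#'
#' @param vloop List with `anchor5`, `anchor3` (residue keys),
#'   `intervening`, `layers_spanned`.
#' @param topology The `g4_topology`.
#' @param model The atom data frame.
#' @return A `VLoopRecord` list: anchors, intervening, layers_spanned,
#'   `inversion_site` (`"within_loop"`/`"after_loop"`), `subtype`
#'   (`"alternative"`/`"conventional"`), `polarity_class`
#'   (`"V_R"`/`"V_S"`).
#' @export
classify_vloop <- function(vloop, topology, model) {
  res <- model_residues(model, nucleotides = TRUE)
  keys <- vapply(res, residue_key, character(1))
  names(res) <- keys
  a <- vloop$anchor5; b <- vloop$anchor3
  core_keys <- keys[keys %in% topology$core]
  ib <- which(core_keys == b)
  if (ib == length(core_keys))
    stop("g4conform inconsistent-V-loop error: no core guanine follows the V-loop 3'-anchor")
  nxt <- core_keys[ib + 1]
  o5 <- backbone_orientation(res[[a]], topology$axis)
  o3 <- backbone_orientation(res[[b]], topology$axis)
  on <- backbone_orientation(res[[nxt]], topology$axis)
  if (any(is.na(c(o5, o3, on))))
    stop("g4conform inconsistent-V-loop error: missing backbone atoms at the V-loop anchors")
  inversion <- if (o5 != o3) "within_loop"
  else if (o3 != on) "after_loop"
  else stop("g4conform inconsistent-V-loop error: no backbone orientation change across the V-loop")
  pol_a <- topology$polarity[topology$layer_of[[a]]]
  pol_b <- topology$polarity[topology$layer_of[[b]]]
  list(anchor5 = a, anchor3 = b, intervening = vloop$intervening,
       layers_spanned = vloop$layers_spanned,
       inversion_site = inversion,
       subtype = if (inversion == "after_loop") "conventional" else "alternative",
       polarity_class = if (pol_a == pol_b) "V_S" else "V_R",
       next_core = nxt)
}

#' @export
print.g4_topology <- function(x, ...) {
  cat(sprintf("g4_topology: %d layers, %d core guanines\n",
              x$n_layers, length(x$core)))
  cat(" polarity per layer:", paste(sprintf("%+d", x$polarity), collapse = " "), "\n")
  if (nrow(x$loops)) {
    cat(" loops:", paste(x$loops$type, collapse = ", "), "\n")
  }
  for (v in x$vloops)
    cat(sprintf(" V-loop %s -> %s: %s (%s), %d nt, %d layers\n",
                v$anchor5, v$anchor3, v$subtype, v$polarity_class,
                length(v$intervening), v$layers_spanned))
  if (length(x$flags)) cat(" flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Consensus topology of a multi-model ensemble
#'
#' Computes the topology of every model independently and takes a
#' majority vote over the discrete labels (layer count, loop types,
#' tract orientations, tetrad polarities, V-loop subtypes). Models that
#' fail topology detection or disagree with the majority are flagged, so
#' partially unfolded states never silently flip a call.
#'
#' @param ensemble A `g4_ensemble`.
#' @param ... Passed to [g4_topology()].
#' @return List with `consensus` (a `g4_topology` from a model matching
#'   the majority signature), `signatures`, `agreement` (fraction of
#'   models matching the majority), `flags`, `per_model`.
#' @export
ensemble_topology <- function(ensemble, ...) {
  models <- ensemble_models(ensemble)
  per <- lapply(models, function(m)
    tryCatch(g4_topology(ensemble_model(ensemble, m), ...),
             error = function(e) conditionMessage(e)))
  names(per) <- models
  ok <- vapply(per, inherits, logical(1), "g4_topology")
  flags <- character(0)
  if (any(!ok))
    flags <- c(flags, sprintf("model %s: %s", models[!ok],
                              unlist(per[!ok])))
  if (!any(ok)) {
    return(list(consensus = NULL, signatures = character(0), agreement = 0,
                flags = c(flags, "no model yielded a topology"),
                per_model = per))
  }
  sig <- vapply(per[ok], topology_signature, character(1))
  tab <- sort(table(sig), decreasing = TRUE)
  agreement <- as.integer(tab[1]) / length(models)
  if (length(tab) > 1 && tab[1] == tab[2])
    flags <- c(flags, "majority tie between topology signatures; per-model labels reported")
  if (agreement < 1)
    flags <- c(flags, sprintf("only %d/%d models match the majority topology",
                              as.integer(tab[1]), length(models)))
  rep_model <- which(ok)[which(sig == names(tab)[1])[1]]
  consensus <- per[[rep_model]]
  consensus$flags <- unique(c(consensus$flags, flags,
                              unlist(lapply(per[ok], `[[`, "flags"))))
  list(consensus = consensus, signatures = sig, agreement = agreement,
       flags = consensus$flags, per_model = per)
}

topology_signature <- function(topo) {
  paste(
    topo$n_layers,
    paste(topo$polarity, collapse = ","),
    paste(vapply(topo$tracts, function(t)
      paste0(t$column, t$orientation, length(t$members)), character(1)),
      collapse = "|"),
    paste(topo$loops$type, collapse = ","),
    paste(vapply(topo$vloops, function(v)
      paste(v$subtype, v$polarity_class), character(1)), collapse = ","),
    sep = " / ")
}
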