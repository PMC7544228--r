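## Base-backbone contact geometry: O4'/O5'/F2'/O2' ... H8-C8 contacts
## with hydrogen reconstruction for deposits without hydrogens.

#' Reconstruct the purine H8 position
#'
#' H8 is placed in the N7-C8-N9 plane along the external bisector at C8
#' with a 1.08 A bond, which reproduces file hydrogens to within a few
#' hundredths of an Angstrom.
#'
#' @param residue A purine residue data frame with N7, C8, N9.
#' @return 3-vector, Angstrom.
#' @export
reconstruct_h8 <- function(residue) {
  n7 <- residue_atom(residue, "N7")
  c8 <- residue_atom(residue, "C8")
  n9 <- residue_atom(residue, "N9")
  dir <- vunit(vunit(c8 - n7) + vunit(c8 - n9))
  c8 + 1.08 * dir
}

contact_call <- function(distance, present = 3.5, absent = 4.0) {
  ifelse(distance <= present, "present",
         ifelse(distance >= absent, "absent", "ambiguous"))
}

#' Measure a base-backbone contact
#'
#' Computes the acceptor-H8 distance and the acceptor-H8-C8 angle, using
#' the file H8 when present and a reconstructed one otherwise. The
#' presence call is a pure function of the distance (`present` at or
#' below 3.5 A, `absent` at or above 4.0 A, `ambiguous` between); the
#' angle is reported but never gates the call, since these CH...O-type
#' contacts are genuinely acute.
#'
#' @param acceptor_residue Residue data frame holding the acceptor atom.
#' @param acceptor_atom Acceptor atom name (`"O4'"`, `"O5'"`, `"F2'"`,
#'   `"O2'"`).
#' @param base_residue Purine residue supplying H8/C8.
#' @param present,absent Distance thresholds (Angstrom).
#' @return One-row data frame: `acceptor_res`, `acceptor_atom`,
#'   `base_res`, `distance`, `angle`, `h8_source`, `call`.
#' @export
measure_contact <- function(acceptor_residue, acceptor_atom, base_residue,
                            present = 3.5, absent = 4.0) {
  acc <- residue_atom(acceptor_residue, acceptor_atom)
  c8 <- residue_atom(base_residue, "C8")
  h8 <- residue_atom(base_residue, "H8", required = FALSE)
  src <- "file"
  if (is.null(h8)) {
    h8 <- reconstruct_h8(base_residue)
    src <- "reconstructed"
  }
  d <- vnorm(acc - h8)
  data.frame(acceptor_res = residue_key(acceptor_residue),
             acceptor_atom = acceptor_atom,
             base_res = residue_key(base_residue),
             distance = d,
             angle = bond_angle(acc, h8, c8),
             h8_source = src,
             call = contact_call(d, present, absent),
             stringsAsFactors = FALSE)
}

#' Scan the characteristic V-loop base-backbone contacts of an ensemble
#'
#' For every model, measures the contacts from the V-loop 3'-anchor's
#' backbone/sugar acceptors (O4', O5', and O2'/F2' where the chemistry
#' provides them) to H8 of the core guanine following the anchor, plus
#' the anchor-internal 5'-side contact (anchor O4' to the H8 of the
#' 5'-anchor). Occupancy is the fraction of models in which a contact is
#' called present.
#'
#' @param topology A `g4_topology` with at least one V-loop.
#' @param ensemble The `g4_ensemble` the topology was derived from.
#' @param present,absent Thresholds passed to [measure_contact()].
#' @return List with `contacts` (per-model rows) and `summary`
#'   (per-contact mean/min/max distance, mean angle, occupancy).
#' @export
scan_vloop_contacts <- function(topology, ensemble, present = 3.5,
                                absent = 4.0) {
  stopifnot(inherits(topology, "g4_topology"))
  if (!length(topology$vloops))
    stop("g4conform: topology has no V-loop to scan")
  rows <- list()
  for (m in ensemble_models(ensemble)) {
    model <- ensemble_model(ensemble, m)
    res <- model_residues(model, nucleotides = TRUE)
    names(res) <- vapply(res, residue_key, character(1))
    for (v in topology$vloops) {
      a3 <- res[[v$anchor3]]
      a5 <- res[[v$anchor5]]
      nxt <- res[[v$next_core]]
      for (atom in c("O4'", "O5'", "O2'", "F2'")) {
        if (!has_atom(a3, atom)) next
        row <- measure_contact(a3, atom, nxt, present, absent)
        row$model <- m
        row$contact <- paste0(atom, "(", v$anchor3, ")->H8(", v$next_core, ")")
        rows[[length(rows) + 1L]] <- row
      }
      row <- measure_contact(a3, "O4'", a5, present, absent)
      row$model <- m
      row$contact <- paste0("O4'(", v$anchor3, ")->H8(", v$anchor5, ")")
      rows[[length(rows) + 1L]] <- row
    }
  }
  contacts <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(contacts, contacts$contact), function(d)
    data.frame(contact = d$contact[1],
               mean = mean(d$distance), min = min(d$distance),
               max = max(d$distance), mean_angle = mean(d$angle),
               occupancy = mean(d$call == "present"),
               stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  list(contacts = contacts, summary = summary)
}
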