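## Glycosidic and sugar torsion analysis.
##
## Endocyclic torsion indexing follows the convention that makes
## nu2 = tau_m * cos(P) hold as written:
##   nu0 = C4'-O4'-C1'-C2'
##   nu1 = O4'-C1'-C2'-C3'
##   nu2 = C1'-C2'-C3'-C4'
##   nu3 = C2'-C3'-C4'-O4'
##   nu4 = C3'-C4'-O4'-C1'

NU_PATHS <- list(
  nu0 = c("C4'", "O4'", "C1'", "C2'"),
  nu1 = c("O4'", "C1'", "C2'", "C3'"),
  nu2 = c("C1'", "C2'", "C3'", "C4'"),
  nu3 = c("C2'", "C3'", "C4'", "O4'"),
  nu4 = c("C3'", "C4'", "O4'", "C1'")
)

#' Glycosidic torsion angle of a nucleotide residue
#'
#' For purines the torsion is O4'-C1'-N9-C4, for pyrimidines
#' O4'-C1'-N1-C2, reported on `[0, 360)`.
#'
#' @param residue A residue as returned by [model_residues()] (a data frame
#'   of its atoms).
#' @return Chi in degrees on `[0, 360)`.
#' @export
glycosidic_chi <- function(residue) {
  bt <- base_type(residue)
  atoms <- switch(bt,
    purine = c("O4'", "C1'", "N9", "C4"),
    pyrimidine = c("O4'", "C1'", "N1", "C2"),
    stop("g4conform named-atom error: residue has no recognisable base attachment")
  )
  p <- lapply(atoms, function(a) residue_atom(residue, a))
  dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
}

#' Endocyclic sugar torsions nu0-nu4
#'
#' @inheritParams glycosidic_chi
#' @return Named numeric vector `nu0..nu4`, signed degrees on `(-180, 180]`.
#' @export
sugar_torsions <- function(residue) {
  vapply(NU_PATHS, function(path) {
    p <- lapply(path, function(a) residue_atom(residue, a))
    dihedral_signed(p[[1]], p[[2]], p[[3]], p[[4]])
  }, numeric(1))
}

#' Pseudorotation phase angle and pucker amplitude
#'
#' Computes the phase angle P and amplitude tau_m of the furanose
#' pseudorotation cycle from the five endocyclic torsions, using the
#' classical phase relation `nu_j = tau_m * cos(P + 144 (j - 2))`. With
#' `x = nu2 = tau_m cos P` and
#' `y = (nu4 + nu1 - nu3 - nu0) / (2 (sin 36 + sin 72)) = tau_m sin P`,
#' P is `atan2(y, x)` on `[0, 360)` and tau_m the vector magnitude, which
#' keeps the quadrant of P consistent with the signs of numerator and nu2.
#'
#' @param nu Numeric vector of five endocyclic torsions (degrees, signed
#'   or wrapped; values are re-wrapped internally).
#' @return List with elements `P` (degrees on `[0, 360)`) and `tau_m`
#'   (degrees, `>= 0`).
#' @export
pseudorotation <- function(nu) {
  if (length(nu) != 5) stop("pseudorotation expects five torsions nu0..nu4")
  nu <- wrap180(nu)
  if (all(abs(nu) < 1)) {
    stop("g4conform undefined-pucker error: ring is planar (all |nu| < 1 degree)")
  }
  y <- (nu[5] + nu[2] - nu[4] - nu[1]) / (2 * (sin(deg2rad(36)) + sin(deg2rad(72))))
  x <- nu[3]
  list(P = unname(wrap360(rad2deg(atan2(y, x)))),
       tau_m = unname(sqrt(x^2 + y^2)))
}

#' Classify a glycosidic torsion angle into its conformational domain
#'
#' Domains partition `[0, 360)`: syn `[0, 120)`, intermediate `[120, 180)`,
#' anti `[180, 300)` and low-syn `[300, 360)`. The low-syn band collects
#' torsions beyond the typical high-anti range that behave syn-like.
#'
#' @param chi Glycosidic torsion(s) in degrees.
#' @return Character vector: `"syn"`, `"intermediate"`, `"anti"` or
#'   `"low_syn"`.
#' @export
classify_chi <- function(chi) {
  chi <- wrap360(chi)
  out <- character(length(chi))
  out[chi < 120] <- "syn"
  out[chi >= 120 & chi < 180] <- "intermediate"
  out[chi >= 180 & chi < 300] <- "anti"
  out[chi >= 300] <- "low_syn"
  out
}

## The 20 canonical envelope/twist conformers on the pseudorotation wheel,
## 18 degrees wide each; envelopes sit at odd multiples of 18 (C3'-endo at
## 18, C4'-exo at 54, ...), twists in between.
CONFORMER_WHEEL <- c(
  "C3'-endo/C2'-exo twist",  #   0
  "C3'-endo",                #  18
  "C3'-endo/C4'-exo twist",  #  36
  "C4'-exo",                 #  54
  "O4'-endo/C4'-exo twist",  #  72
  "O4'-endo",                #  90
  "O4'-endo/C1'-exo twist",  # 108
  "C1'-exo",                 # 126
  "C2'-endo/C1'-exo twist",  # 144
  "C2'-endo",                # 162
  "C2'-endo/C3'-exo twist",  # 180
  "C3'-exo",                 # 198
  "C4'-endo/C3'-exo twist",  # 216
  "C4'-endo",                # 234
  "O4'-exo/C4'-endo twist",  # 252
  "O4'-exo",                 # 270
  "O4'-exo/C1'-endo twist",  # 288
  "C1'-endo",                # 306
  "C2'-exo/C1'-endo twist",  # 324
  "C2'-exo"                  # 342
)

#' Classify a pseudorotation phase angle
#'
#' The north domain is `P` in `[270, 360) U [0, 90)` and south is the
#' complement; the conformer label is the nearest of the 20 canonical
#' envelope/twist names on the 18-degree pseudorotation wheel.
#'
#' @param P Phase angle(s) in degrees.
#' @return Data frame with columns `pucker_domain` (`"north"`/`"south"`)
#'   and `conformer_label`.
#' @export
classify_pucker <- function(P) {
  P <- wrap360(P)
  domain <- ifelse(P >= 270 | P < 90, "north", "south")
  idx <- (round(P / 18) %% 20) + 1
  data.frame(pucker_domain = domain,
             conformer_label = CONFORMER_WHEEL[idx],
             stringsAsFactors = FALSE)
}

#' Per-residue torsion and pucker profile of an ensemble
#'
#' Computes chi, nu0-nu4, the pseudorotation phase angle and amplitude and
#' their domain classifications for every nucleotide residue of every
#' model. Residues whose sugar ring is incomplete or planar get `NA`
#' pucker fields.
#'
#' @param ensemble A [g4_ensemble] object.
#' @return Data frame with one row per residue and model: `entry`,
#'   `model`, `chain`, `seq_index`, `name`, `sugar_chemistry`, `chi`,
#'   `chi_domain`, `nu0..nu4`, `P`, `tau_m`, `pucker_domain`,
#'   `conformer_label`.
#' @export
torsion_profile <- function(ensemble) {
  stopifnot(inherits(ensemble, "g4_ensemble"))
  out <- list()
  for (m in ensemble_models(ensemble)) {
    model <- ensemble_model(ensemble, m)
    for (res in model_residues(model, nucleotides = TRUE)) {
      chem <- classify_sugar_chemistry(res)
      chi <- tryCatch(glycosidic_chi(res), error = function(e) NA_real_)
      nu <- tryCatch(sugar_torsions(res), error = function(e) rep(NA_real_, 5))
      pk <- tryCatch(pseudorotation(nu), error = function(e) list(P = NA_real_, tau_m = NA_real_))
      cls <- if (is.finite(pk$P)) classify_pucker(pk$P) else
        data.frame(pucker_domain = NA_character_, conformer_label = NA_character_)
      out[[length(out) + 1L]] <- data.frame(
        entry = ensemble$provenance$entry_id,
        model = m,
        chain = res$chain[1],
        seq_index = res$resno[1],
        name = res$resid[1],
        sugar_chemistry = chem,
        chi = chi,
        chi_domain = if (is.finite(chi)) classify_chi(chi) else NA_character_,
        nu0 = nu[1], nu1 = nu[2], nu2 = nu[3], nu3 = nu[4], nu4 = nu[5],
        P = pk$P, tau_m = pk$tau_m,
        pucker_domain = cls$pucker_domain,
        conformer_label = cls$conformer_label,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
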