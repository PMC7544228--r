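## Analysis driver and report generation: per-residue torsion tables,
## topology JSON, contact and RMSD tables, and the pucker-vs-glycosidic
## scatter table for V-loop flanking residues. All numbers in reports
## are produced by the analysis modules; the report layer only formats
## (angles to 0.1 degree, distances and RMSD to 0.01 A) so outputs are
## byte-stable across reruns.

#' Analysis configuration
#'
#' @param inputs Character vector of coordinate file paths.
#' @param out_dir Output directory for report files.
#' @param models `"all"`, `"first"`, or an integer vector of model numbers.
#' @param hbond_cutoff Hoogsteen heavy-atom distance cutoff (Angstrom).
#' @param contact_present,contact_absent Contact call thresholds (Angstrom).
#' @param log_level `"info"` or `"quiet"`.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(inputs = character(0), out_dir = ".",
                            models = "all", hbond_cutoff = 3.5,
                            contact_present = 3.5, contact_absent = 4.0,
                            log_level = "info") {
  structure(list(inputs = inputs, out_dir = out_dir, models = models,
                 hbond_cutoff = hbond_cutoff,
                 contact_present = contact_present,
                 contact_absent = contact_absent,
                 log_level = log_level),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param path Config file path (JSON).
#' @param config An `analysis_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, x)
}

msg <- function(config, ...) {
  if (!identical(config$log_level, "quiet")) message(...)
}

fmt1 <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))
fmt2 <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))

#' Run the full analysis and write the report bundle
#'
#' For every input structure: reads the ensemble, writes the per-residue
#' torsion/pucker CSV, the topology JSON (layers, polarities, tracts,
#' loops, V-loop records), the V-loop contact CSV where a V-loop is
#' present, the pairwise G-core RMSD CSV, and appends the V-loop
#' flanking residues to a scatter-ready TSV of pseudorotation phase
#' angle versus glycosidic torsion.
#'
#' @param config An [analysis_config()] (or a character vector of input
#'   paths, taken as `analysis_config(inputs = ...)`).
#' @return Invisibly, a list of per-entry result bundles.
#' @export
analyze <- function(config) {
  if (is.character(config)) config <- analysis_config(inputs = config)
  if (!length(config$inputs))
    stop("g4conform usage error: no input files given")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fig9 <- list()
  bundles <- list()
  for (path in config$inputs) {
    ens <- read_structure(path)
    if (identical(config$models, "first")) {
      ens$atoms <- ens$atoms[ens$atoms$model == ensemble_models(ens)[1], ]
    } else if (is.numeric(config$models)) {
      ens$atoms <- ens$atoms[ens$atoms$model %in% config$models, ]
    }
    entry <- ens$provenance$entry_id
    msg(config, "analyzing ", entry, " (", length(ensemble_models(ens)),
        " models)")
    prof <- torsion_profile(ens)
    pf <- prof
    for (cc in c("chi", "nu0", "nu1", "nu2", "nu3", "nu4", "P", "tau_m"))
      pf[[cc]] <- fmt1(pf[[cc]])
    write.csv(pf, file.path(config$out_dir, paste0(entry, "_torsions.csv")),
              row.names = FALSE)

    et <- ensemble_topology(ens, hbond_cutoff = config$hbond_cutoff)
    topo <- et$consensus
    bundle <- list(entry = entry, profile = prof, topology = topo,
                   agreement = et$agreement, flags = et$flags)
    if (!is.null(topo)) {
      jsonlite::write_json(topology_report(topo, et),
                           file.path(config$out_dir, paste0(entry, "_topology.json")),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      sel <- function(a) select_core_guanines(a, topo)
      if (length(ensemble_models(ens)) > 1) {
        pr <- pairwise_rmsd(ens, sel)
        rm <- as.data.frame(round(pr$matrix, 2))
        write.csv(cbind(model = rownames(pr$matrix), rm),
                  file.path(config$out_dir, paste0(entry, "_rmsd.csv")),
                  row.names = FALSE)
        bundle$rmsd <- pr
      }
      if (length(topo$vloops)) {
        vc <- scan_vloop_contacts(topo, ens, config$contact_present,
                                  config$contact_absent)
        ct <- vc$contacts
        ct$distance <- fmt2(ct$distance)
        ct$angle <- fmt1(ct$angle)
        write.csv(ct[, c("model", "contact", "acceptor_res", "acceptor_atom",
                         "base_res", "distance", "angle", "h8_source", "call")],
                  file.path(config$out_dir, paste0(entry, "_contacts.csv")),
                  row.names = FALSE)
        bundle$contacts <- vc
        fig9[[entry]] <- fig9_rows(entry, prof, topo)
      }
    }
    bundles[[entry]] <- bundle
  }
  if (length(fig9)) {
    tab <- do.call(rbind, fig9)
    utils::write.table(tab, file.path(config$out_dir, "vloop_ppa_chi.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(bundles)
}

## circular ensemble means of chi and P for the V-loop flanking residues
fig9_rows <- function(entry, prof, topo) {
  out <- list()
  for (v in topo$vloops) {
    for (role in c("anchor5", "anchor3")) {
      k <- v[[role]]
      parts <- strsplit(k, " ", fixed = TRUE)[[1]]
      rows <- prof[prof$chain == parts[1] & prof$seq_index == as.integer(parts[2]), ]
      chi <- circular_mean(rows$chi)
      P <- circular_mean(rows$P)
      out[[length(out) + 1L]] <- data.frame(
        entry = entry, residue = k, role = role,
        chi = fmt1(chi), P = fmt1(P),
        chi_domain = classify_chi(chi),
        pucker_domain = classify_pucker(P)$pucker_domain,
        subtype = v$subtype, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

topology_report <- function(topo, et = NULL) {
  list(
    n_layers = topo$n_layers,
    layers = lapply(seq_along(topo$layers), function(i) list(
      members = topo$layers[[i]]$members,
      polarity_sign = topo$polarity[i])),
    relative_polarities = as.list(topo$relative_polarities),
    columns = lapply(1:4, function(cc)
      names(topo$column_of)[topo$column_of == cc]),
    tracts = lapply(topo$tracts, function(t)
      list(members = t$members, orientation = t$orientation,
           complete = t$complete)),
    loops = topo$loops,
    vloops = lapply(topo$vloops, function(v)
      list(anchor5 = v$anchor5, anchor3 = v$anchor3,
           n_intervening = length(v$intervening),
           layers_spanned = v$layers_spanned,
           inversion_site = v$inversion_site, subtype = v$subtype,
           polarity_class = v$polarity_class)),
    agreement = if (is.null(et)) NULL else et$agreement,
    flags = topo$flags)
}

#' Write a deterministic synthetic fixture to disk
#'
#' Builds a preset (or custom `mock_spec`) quadruplex and writes the
#' coordinates as PDB together with the ground-truth labels as JSON.
#' Rebuilding with the same spec and seed is bit-identical.
#'
#' @param spec A preset name (see [mock_spec()]) or a `mock_spec`.
#' @param out_dir Output directory.
#' @param seed Seed for the coordinate noise.
#' @param ... Further [mock_spec()] overrides when `spec` is a name.
#' @return Paths of the files written, invisibly.
#' @export
write_fixture <- function(spec = "hybrid", out_dir = ".", seed = 0, ...) {
  if (is.character(spec)) {
    presets <- c("parallel", "hybrid", "antiparallel", "diagonal",
                 "vloop_conventional", "vloop_alternative")
    if (!spec %in% presets)
      stop("g4conform usage error: unknown preset '", spec, "'; use one of ",
           paste(presets, collapse = ", "))
    spec <- mock_spec(spec, seed = seed, ...)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mk <- build_mock_quadruplex(spec)
  stem <- file.path(out_dir, tolower(spec$preset))
  pdb <- paste0(stem, ".pdb")
  truth <- paste0(stem, "_truth.json")
  write_pdb(mk$ensemble, pdb)
  jsonlite::write_json(mk$truth, truth, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(pdb = pdb, truth = truth))
}
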