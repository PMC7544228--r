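## Structure container and coordinate I/O.
##
## An ensemble is a list with:
##   atoms      data frame: model, chain, resno, resid, elety, elem,
##              x, y, z, het, is_nucleotide
##   provenance list(path, format, entry_id)
## All models are validated to share one residue sequence and atom
## inventory (after atom-name normalisation), so per-model views are
## plain row subsets.

#' @rdname read_structure
#' @name g4_ensemble
NULL

## ---- atom-name normalisation -------------------------------------------

## Deposited files mix prime dialects (O4', O4*, O4<U+2032>) and old
## phosphate-oxygen names; normalise once at read time.
normalize_atom_name <- function(name) {
  name <- gsub("[*′]", "'", trimws(name))
  map <- c("O1P" = "OP1", "O2P" = "OP2", "O3P" = "OP3", "C5M" = "C7")
  hit <- match(name, names(map))
  name[!is.na(hit)] <- map[hit[!is.na(hit)]]
  name
}

infer_element <- function(name) {
  core <- gsub("[^A-Za-z]", "", name)
  el <- toupper(substr(core, 1, 1))
  ## two-letter elements that occur in nucleic-acid context
  two <- toupper(substr(core, 1, 2))
  ifelse(two %in% c("CL", "BR", "MG", "MN", "ZN", "NA", "FE"), two, el)
}

new_g4_ensemble <- function(atoms, path = NA_character_, format = NA_character_,
                            entry_id = NA_character_) {
  atoms$elety <- normalize_atom_name(atoms$elety)
  blank <- is.na(atoms$elem) | atoms$elem == ""
  atoms$elem[blank] <- infer_element(atoms$elety[blank])
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("g4conform format error: non-finite coordinates")
  atoms <- flag_nucleotides(atoms)
  check_inventory(atoms)
  structure(list(atoms = atoms,
                 provenance = list(path = path, format = format,
                                   entry_id = entry_id)),
            class = "g4_ensemble")
}

flag_nucleotides <- function(atoms) {
  key <- paste(atoms$model, atoms$chain, atoms$resno)
  has <- function(a) tapply(atoms$elety == a, key, any)
  h <- has("C1'"); o <- has("O4'"); n9 <- has("N9"); n1 <- has("N1")
  nt <- h & o & (n9 | n1)
  atoms$is_nucleotide <- as.vector(nt[key])
  atoms
}

check_inventory <- function(atoms) {
  models <- sort(unique(atoms$model))
  if (!length(models)) stop("g4conform format error: file contains no atoms")
  sig <- function(m) {
    a <- atoms[atoms$model == m, ]
    paste(a$chain, a$resno, a$resid, a$elety, sep = "|")
  }
  ref <- sort(sig(models[1]))
  for (m in models[-1]) {
    s <- sort(sig(m))
    if (!identical(ref, s)) {
      bad <- c(setdiff(ref, s), setdiff(s, ref))
      res <- paste(strsplit(bad[1], "|", fixed = TRUE)[[1]][1:3], collapse = " ")
      stop(sprintf(
        "g4conform inventory error: model %s disagrees with model %s at residue %s",
        m, models[1], res))
    }
  }
  invisible(TRUE)
}

## ---- accessors ----------------------------------------------------------

#' @export
print.g4_ensemble <- function(x, ...) {
  cat(sprintf("g4_ensemble: %d model(s), %d residues, %d atoms/model\n",
              length(ensemble_models(x)),
              nrow(unique(x$atoms[x$atoms$model == x$atoms$model[1],
                                  c("chain", "resno")])),
              sum(x$atoms$model == x$atoms$model[1])))
  if (!is.na(x$provenance$entry_id))
    cat(" entry:", x$provenance$entry_id, "\n")
  invisible(x)
}

#' Ensemble accessors
#'
#' `ensemble_models()` lists model numbers, `ensemble_model()` extracts one
#' model as an atom data frame, and `model_residues()` splits a model into
#' residues in chain order.
#'
#' @param ensemble A `g4_ensemble`.
#' @param model A model number from `ensemble_models()`.
#' @return `ensemble_model()` returns a data frame of atoms;
#'   `model_residues()` a list of per-residue data frames.
#' @export
ensemble_models <- function(ensemble) sort(unique(ensemble$atoms$model))

#' @rdname ensemble_models
#' @export
ensemble_model <- function(ensemble, model) {
  out <- ensemble$atoms[ensemble$atoms$model == model, ]
  if (!nrow(out)) stop("g4conform: no such model: ", model)
  out
}

#' @rdname ensemble_models
#' @param nucleotides If `TRUE`, only residues with a resolvable
#'   nucleotide core (C1', O4' and a base attachment nitrogen) are kept;
#'   waters and ions are retained in the ensemble but flagged out here.
#' @export
model_residues <- function(model, nucleotides = FALSE) {
  if (nucleotides) model <- model[model$is_nucleotide, ]
  if (!nrow(model)) return(list())
  keys <- unique(paste(model$chain, model$resno))
  ## canonical chain order (chain, then numeric residue number) so that
  ## results are invariant to atom/residue reordering in the input
  keys <- keys[key_order(keys)]
  key <- factor(paste(model$chain, model$resno), levels = keys)
  unname(split(model, key))
}

## xyz of a named atom in a residue data frame; errors name the atom.
residue_atom <- function(residue, name, required = TRUE) {
  i <- which(residue$elety == name)[1]
  if (is.na(i)) {
    if (required)
      stop(sprintf("g4conform named-atom error: atom %s missing in residue %s %s%s",
                   name, residue$resid[1], residue$chain[1], residue$resno[1]))
    return(NULL)
  }
  c(residue$x[i], residue$y[i], residue$z[i])
}

has_atom <- function(residue, name) any(residue$elety == name)

residue_key <- function(residue) paste(residue$chain[1], residue$resno[1])

#' Base type of a residue from its atom inventory
#'
#' @param residue A residue data frame.
#' @return `"purine"`, `"pyrimidine"` or `"other"`.
#' @export
base_type <- function(residue) {
  if (all(c("N9", "C8", "N7") %in% residue$elety)) return("purine")
  if (all(c("N1", "C2") %in% residue$elety) && "C1'" %in% residue$elety)
    return("pyrimidine")
  "other"
}

is_guanine <- function(residue) {
  base_type(residue) == "purine" && all(c("O6", "N2", "N1") %in% residue$elety)
}

## ---- sugar chemistry ----------------------------------------------------

#' Classify the sugar chemistry of a residue from its atom inventory
#'
#' Residue codes for modified nucleotides vary between deposits, so the
#' chemistry is always derived from geometry: a carbon bridging O2' and
#' C4' (both bonds inferred by a 1.8 A distance cutoff) marks a locked
#' (LNA) sugar; a fluorine bonded to C2' marks a 2'-fluoro sugar, with the
#' ribo/arabino epimer decided by whether the fluorine sits on the
#' opposite or the same face of the sugar ring as the base attachment;
#' an O2' without bridge is ribose, otherwise deoxyribose.
#'
#' @param residue A residue data frame.
#' @return One of `"deoxyribose"`, `"ribose"`, `"locked"`, `"2'F-ribo"`,
#'   `"2'F-arabino"`, `"unknown"`.
#' @export
classify_sugar_chemistry <- function(residue) {
  ring <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  if (!all(ring %in% residue$elety)) return("unknown")
  c1 <- residue_atom(residue, "C1'")
  c2 <- residue_atom(residue, "C2'")
  c3 <- residue_atom(residue, "C3'")
  c4 <- residue_atom(residue, "C4'")

  xyz <- function(i) c(residue$x[i], residue$y[i], residue$z[i])
  dist_to <- function(i, p) vnorm(xyz(i) - p)

  ## O2' bonded to C2'
  o2_idx <- which(residue$elety == "O2'" | (residue$elem == "O" &
                    vapply(seq_len(nrow(residue)), function(i)
                      dist_to(i, c2) < 1.8, logical(1)) &
                    !residue$elety %in% ring))
  o2_idx <- o2_idx[vapply(o2_idx, function(i) dist_to(i, c2) < 1.8, logical(1))]
  o2_idx <- setdiff(o2_idx, which(residue$elety %in% ring))

  ## locked: any carbon outside the ring bonded to both O2' and C4'
  if (length(o2_idx)) {
    o2 <- xyz(o2_idx[1])
    bridge <- which(residue$elem == "C" & !residue$elety %in% c(ring, "C5'"))
    for (i in bridge) {
      if (dist_to(i, o2) < 1.8 && dist_to(i, c4) < 1.8) return("locked")
    }
  }

  ## 2'-fluoro: F bonded to C2'; epimer from the ring-face sign
  f_idx <- which(residue$elem == "F")
  f_idx <- f_idx[vapply(f_idx, function(i) dist_to(i, c2) < 1.8, logical(1))]
  if (length(f_idx)) {
    nb_name <- if (base_type(residue) == "pyrimidine") "N1" else "N9"
    if (!has_atom(residue, nb_name)) return("unknown")
    nb <- residue_atom(residue, nb_name)
    n <- vcross(c1 - c2, c3 - c2)   # ring-plane normal at C2'
    s_f <- sign(sum((xyz(f_idx[1]) - c2) * n))
    s_b <- sign(sum((nb - c1) * n))
    ## same face as the base -> arabino epimer, opposite -> ribo
    return(if (s_f == s_b) "2'F-arabino" else "2'F-ribo")
  }

  if (length(o2_idx)) "ribose" else "deoxyribose"
}

## ---- readers ------------------------------------------------------------

#' Read a multi-model nucleic-acid structure
#'
#' Reads PDB v3.3 or mmCIF coordinate files (multi-model via MODEL/ENDMDL
#' records or `pdbx_PDB_model_num`), normalises atom-name dialects
#' (`O4'`/`O4*` prime markers, `O1P`/`OP1`), keeps only blank or "A"
#' alternate locations, and validates that all models share one residue
#' sequence and atom inventory.
#'
#' @param path Path to the coordinate file.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (sniffed from the file).
#' @return A `g4_ensemble` object.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("g4conform format error: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE) ||
                  any(grepl("^data_|^_atom_site\\.", utils::head(lines, 50))))
      "mmcif" else "pdb"
  }
  atoms <- switch(format, pdb = parse_pdb(lines), mmcif = parse_mmcif(lines))
  if (!nrow(atoms)) stop("g4conform format error: no atom records in ", path)
  entry <- toupper(sub("\\.[^.]*$", "", basename(path)))
  new_g4_ensemble(atoms, path = path, format = format, entry_id = entry)
}

parse_pdb <- function(lines) {
  rec <- substr(lines, 1, 6)
  model_no <- integer(length(lines))
  cur <- 1L
  seen_model <- FALSE
  for (i in seq_along(lines)) {
    if (rec[i] == "MODEL ") {
      cur <- suppressWarnings(as.integer(substr(lines[i], 7, 80)))
      if (is.na(cur)) cur <- 1L
      seen_model <- TRUE
    }
    model_no[i] <- cur
  }
  keep <- rec %in% c("ATOM  ", "HETATM")
  if (!any(keep)) return(data.frame())
  ln <- lines[keep]
  altloc <- substr(ln, 17, 17)
  ok <- altloc %in% c(" ", "", "A")
  ln <- ln[ok]
  num <- function(a, b) suppressWarnings(as.numeric(substr(ln, a, b)))
  atoms <- data.frame(
    model = model_no[keep][ok],
    chain = trimws(substr(ln, 22, 22)),
    resno = suppressWarnings(as.integer(substr(ln, 23, 26))),
    resid = trimws(substr(ln, 18, 20)),
    elety = substr(ln, 13, 16),
    elem = trimws(substr(ln, 77, 78)),
    x = num(31, 38), y = num(39, 46), z = num(47, 54),
    het = substr(ln, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
  if (any(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z) | is.na(atoms$resno)))
    stop("g4conform format error: malformed ATOM/HETATM record")
  atoms$chain[atoms$chain == ""] <- "A"
  atoms
}

parse_mmcif <- function(lines) {
  lines <- trimws(lines)
  i <- 1L
  n <- length(lines)
  tags <- character(0)
  rows <- list()
  while (i <= n) {
    if (lines[i] == "loop_") {
      j <- i + 1L
      hdr <- character(0)
      while (j <= n && startsWith(lines[j], "_")) {
        hdr <- c(hdr, lines[j]); j <- j + 1L
      }
      if (length(hdr) && all(startsWith(hdr, "_atom_site."))) {
        tags <- sub("^_atom_site\\.", "", hdr)
        while (j <= n && nzchar(lines[j]) && !startsWith(lines[j], "_") &&
               !startsWith(lines[j], "loop_") && !startsWith(lines[j], "#") &&
               !startsWith(lines[j], "data_")) {
          rows[[length(rows) + 1L]] <- lines[j]
          j <- j + 1L
        }
        i <- j
        next
      }
      i <- j
    } else i <- i + 1L
  }
  if (!length(rows)) stop("g4conform format error: no _atom_site loop found")
  tok <- lapply(rows, function(l)
    scan(text = l, what = "character", quiet = TRUE))
  bad <- which(lengths(tok) != length(tags))
  if (length(bad))
    stop("g4conform format error: malformed atom_site row ", bad[1])
  m <- do.call(rbind, tok)
  colnames(m) <- tags
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% tags) return(m[, nm])
    rep(NA_character_, nrow(m))
  }
  alt <- pick("label_alt_id")
  keep <- is.na(alt) | alt %in% c(".", "?", "", "A")
  m <- m[keep, , drop = FALSE]
  pick2 <- function(...) {
    for (nm in c(...)) if (nm %in% tags) return(m[, nm])
    rep(NA_character_, nrow(m))
  }
  mdl <- pick2("pdbx_PDB_model_num")
  mdl[is.na(mdl) | mdl %in% c(".", "?")] <- "1"
  data.frame(
    model = as.integer(mdl),
    chain = ifelse(is.na(pick2("auth_asym_id", "label_asym_id")), "A",
                   pick2("auth_asym_id", "label_asym_id")),
    resno = as.integer(pick2("auth_seq_id", "label_seq_id")),
    resid = pick2("auth_comp_id", "label_comp_id"),
    elety = gsub('"', "", pick2("auth_atom_id", "label_atom_id")),
    elem = pick2("type_symbol"),
    x = as.numeric(pick2("Cartn_x")),
    y = as.numeric(pick2("Cartn_y")),
    z = as.numeric(pick2("Cartn_z")),
    het = pick2("group_PDB") == "HETATM",
    stringsAsFactors = FALSE
  )
}

## ---- writer -------------------------------------------------------------

#' Write an ensemble as a PDB file
#'
#' Multi-model ensembles are wrapped in MODEL/ENDMDL records. Coordinates
#' are written at the standard 0.001 A precision, so a read/write/read
#' round trip preserves them to 1e-3 A.
#'
#' @param ensemble A `g4_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "g4_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  models <- ensemble_models(ensemble)
  multi <- length(models) > 1
  for (m in models) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    a <- ensemble_model(ensemble, m)
    name4 <- vapply(seq_len(nrow(a)), function(i) {
      nm <- a$elety[i]
      if (nchar(nm) >= 4) substr(nm, 1, 4)
      else if (nchar(a$elem[i]) == 2) sprintf("%-4s", nm)
      else sprintf(" %-3s", nm)
    }, character(1))
    lines <- sprintf(
      "%-6s%5d %s%s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(a$het, "HETATM", "ATOM"),
      (seq_len(nrow(a)) - 1L) %% 99999L + 1L,
      name4, " ", a$resid, a$chain, a$resno,
      a$x, a$y, a$z, 1, 0, a$elem)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---- fetch helper (opt-in, requires network) ---------------------------

#' Download a quadruplex entry from the Protein Data Bank
#'
#' Opt-in convenience helper: nothing in the package downloads by default.
#' Files are cached in `dir` and not re-downloaded.
#'
#' @param id Four-character PDB accession (e.g. `"6YCV"`).
#' @param dir Cache directory.
#' @param timeout Seconds before the download attempt is abandoned.
#' @return Path to the downloaded PDB file.
#' @export
fetch_quadruplex_entry <- function(id, dir = file.path(tempdir(), "g4-pdb"),
                                   timeout = 30) {
  id <- toupper(id)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(dir, paste0(id, ".pdb"))
  if (file.exists(dest)) return(dest)
  old <- options(timeout = timeout)
  on.exit(options(old))
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", id)
  utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  dest
}
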