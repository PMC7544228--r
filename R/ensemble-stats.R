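## Least-squares superposition and ensemble precision statistics.

## Kabsch fit: proper rotation + translation minimising RMSD of mov onto ref.
kabsch_fit <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  cr <- colMeans(ref); cm <- colMeans(mov)
  a <- sweep(ref, 2, cr); b <- sweep(mov, 2, cm)
  h <- t(b) %*% a
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rot <- t(rot)  # row-vector convention: fitted = mov %*% rot
  trans <- cr - drop(cm %*% rot)
  list(rot = rot, trans = trans)
}

#' Least-squares rigid-body superposition
#'
#' Finds the proper rotation (determinant +1) and translation that
#' minimise the RMSD of the moving coordinate set onto the reference
#' (Kabsch algorithm via singular value decomposition).
#'
#' @param ref,mov Paired n x 3 coordinate matrices, n >= 3.
#' @return List with `rot` (3 x 3, applied as `mov %*% rot`), `trans`
#'   (length-3), `rmsd`, and `fitted` (the transformed moving set).
#' @export
superpose <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (!all(dim(ref) == dim(mov)) || ncol(ref) != 3)
    stop("g4conform degenerate-selection error: coordinate sets must be paired n x 3")
  if (nrow(ref) < 3)
    stop("g4conform degenerate-selection error: need at least 3 paired atoms")
  if (any(svd(sweep(ref, 2, colMeans(ref)))$d < 1e-9) && nrow(ref) == 3)
    stop("g4conform degenerate-selection error: collinear selection")
  fit <- kabsch_fit(ref, mov)
  fitted <- sweep(mov %*% fit$rot, 2, -fit$trans)
  list(rot = fit$rot, trans = fit$trans,
       rmsd = sqrt(mean(rowSums((fitted - ref)^2))), fitted = fitted)
}

## ---- selections ---------------------------------------------------------

#' Atom selections for superposition statistics
#'
#' A selection is a predicate over atom rows. `select_heavy()` keeps
#' non-hydrogen atoms; `select_residues()` restricts to a set of residue
#' keys (`"chain resno"`); `select_core_guanines()` builds the selection
#' for the quartet-forming guanines of a detected topology, so the
#' G-core selection follows quartet detection rather than hard-coded
#' residue numbers.
#'
#' @param atoms An atom data frame (one model).
#' @return Logical vector over atom rows.
#' @export
select_heavy <- function(atoms) atoms$elem != "H"

#' @rdname select_heavy
#' @param keys Character vector of `"chain resno"` residue keys.
#' @export
select_residues <- function(atoms, keys) {
  paste(atoms$chain, atoms$resno) %in% keys
}

#' @rdname select_heavy
#' @param topology A `g4_topology` object (see [g4_topology()]).
#' @param heavy Drop hydrogens?
#' @export
select_core_guanines <- function(atoms, topology, heavy = TRUE) {
  sel <- select_residues(atoms, topology$core)
  if (heavy) sel <- sel & select_heavy(atoms)
  sel
}

## ---- pairwise RMSD ------------------------------------------------------

#' Mean pairwise RMSD across an ensemble
#'
#' For every unordered model pair, superposes model j onto model i on the
#' selection and records the RMSD measured on the same selection
#' (fit-on equals measure-on by default; pass `fit_selection` to fit on a
#' different atom set).
#'
#' @param ensemble A `g4_ensemble` with >= 2 models.
#' @param selection Predicate function over an atom data frame returning a
#'   logical row mask (e.g. [select_heavy]), or a precomputed logical
#'   vector valid for every model.
#' @param fit_selection Optional distinct selection used for the fit.
#' @return List with `mean` (mean pairwise RMSD, Angstrom), `matrix`
#'   (symmetric model x model RMSD matrix) and `n_atoms`.
#' @export
pairwise_rmsd <- function(ensemble, selection = select_heavy,
                          fit_selection = NULL) {
  stopifnot(inherits(ensemble, "g4_ensemble"))
  models <- ensemble_models(ensemble)
  if (length(models) < 2)
    stop("g4conform degenerate-selection error: need at least 2 models")
  get_mask <- function(sel, atoms) {
    if (is.function(sel)) sel(atoms) else sel
  }
  coords <- lapply(models, function(m) {
    a <- ensemble_model(ensemble, m)
    a <- a[order(a$chain, a$resno, a$elety), ]
    mask <- get_mask(selection, a)
    fmask <- if (is.null(fit_selection)) mask else get_mask(fit_selection, a)
    list(meas = as.matrix(a[mask, c("x", "y", "z")]),
         fit = as.matrix(a[fmask, c("x", "y", "z")]))
  })
  n_sel <- nrow(coords[[1]]$meas)
  if (n_sel == 0)
    stop("g4conform degenerate-selection error: empty selection")
  k <- length(models)
  mat <- matrix(0, k, k, dimnames = list(models, models))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    fit <- superpose(coords[[i]]$fit, coords[[j]]$fit)
    moved <- sweep(coords[[j]]$meas %*% fit$rot, 2, -fit$trans)
    r <- sqrt(mean(rowSums((moved - coords[[i]]$meas)^2)))
    mat[i, j] <- mat[j, i] <- r
  }
  list(mean = mean(mat[upper.tri(mat)]), matrix = mat, n_atoms = n_sel)
}
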