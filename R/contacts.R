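# ---------------------------------------------------------------------------
# Intermolecular residue contacts and cross-complex contact conservation
# ---------------------------------------------------------------------------

#' Contact detection configuration
#'
#' @param cutoff contact cutoff, Angstrom (default 4.0; a residue pair is in
#'   contact when its minimum interatomic distance is <= cutoff, inclusive).
#' @param heavy_atoms_only ignore hydrogens (default TRUE).
#' @param conservation_fraction fraction of complexes that must show a
#'   contact at a receptor residue for it to be flagged conserved
#'   (default 0.75).
#' @return list of class `ContactConfig`.
#' @export
contact_config <- function(cutoff = 4.0, heavy_atoms_only = TRUE,
                           conservation_fraction = 0.75) {
  stopifnot(cutoff > 0, conservation_fraction > 0, conservation_fraction <= 1)
  structure(list(cutoff = cutoff, heavy_atoms_only = heavy_atoms_only,
                 conservation_fraction = conservation_fraction),
            class = "ContactConfig")
}

sel_atoms <- function(structure, chains, heavy_only) {
  at <- structure$atoms
  idx <- which(at$chain %in% chains)
  if (heavy_only) idx <- intersect(idx, heavy_atoms(structure))
  idx
}

#' Find intermolecular residue contacts in a complex
#'
#' A receptor-partner residue pair is reported iff the minimum distance over
#' their (heavy) atom pairs is <= `config$cutoff`; each pair appears once
#' with that minimum distance.
#'
#' @param complex a `Structure` holding both molecules.
#' @param receptor_sel,partner_sel character vectors of chain ids; must be
#'   non-empty and disjoint.
#' @param config a [contact_config()].
#' @return data.frame with receptor chain/resseq/resname, partner
#'   chain/resseq/resname and `min_distance` (Angstrom), sorted by receptor
#'   then partner residue.
#' @export
find_contacts <- function(complex, receptor_sel, partner_sel,
                          config = contact_config()) {
  if (!length(receptor_sel) || !length(partner_sel))
    stop("empty chain selection")
  if (length(intersect(receptor_sel, partner_sel)))
    stop("receptor and partner selections overlap: ",
         paste(intersect(receptor_sel, partner_sel), collapse = ", "))
  at <- complex$atoms
  ri <- sel_atoms(complex, receptor_sel, config$heavy_atoms_only)
  pi_ <- sel_atoms(complex, partner_sel, config$heavy_atoms_only)
  if (!length(ri) || !length(pi_)) stop("selection matches no atoms")
  R <- as.matrix(at[ri, c("x", "y", "z")])
  P <- as.matrix(at[pi_, c("x", "y", "z")])
  # all-pairs distance; fixtures and single complexes are small enough
  d2 <- outer(rowSums(R^2), rowSums(P^2), "+") - 2 * R %*% t(P)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= config$cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) {
    return(data.frame(receptor_chain = character(), receptor_resseq = integer(),
                      receptor_resname = character(), partner_chain = character(),
                      partner_resseq = integer(), partner_resname = character(),
                      min_distance = numeric(), stringsAsFactors = FALSE))
  }
  ia <- ri[hit[, 1]]
  ja <- pi_[hit[, 2]]
  key <- paste(at$chain[ia], at$resseq[ia], at$icode[ia], "::",
               at$chain[ja], at$resseq[ja], at$icode[ja])
  dmin <- tapply(sqrt(d2[hit]), key, min)
  first <- !duplicated(key)
  out <- data.frame(receptor_chain = at$chain[ia][first],
                    receptor_resseq = at$resseq[ia][first],
                    receptor_resname = at$resname[ia][first],
                    partner_chain = at$chain[ja][first],
                    partner_resseq = at$resseq[ja][first],
                    partner_resname = at$resname[ja][first],
                    min_distance = as.numeric(dmin[key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$receptor_chain, out$receptor_resseq,
                   out$partner_chain, out$partner_resseq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tabulate contact conservation across complexes
#'
#' Builds, per receptor residue contacted in at least one complex, the list
#' of contacted partner residues in each complex, and flags the residue
#' conserved when it is contacted in at least
#' `config$conservation_fraction` of the complexes.  Cross-complex residue
#' correspondence is by receptor residue number (the receptor numbering
#' must be shared across entries).
#'
#' @param complexes list; each element a list with `structure` (a
#'   `Structure`), `receptor_sel` and `partner_sel` (chain vectors), and
#'   optionally `label`.
#' @param config a [contact_config()].
#' @return list of class `ConservationTable`: `table` (data.frame with one
#'   row per receptor residue, one column per complex with contacted
#'   partner residue(s) or `"-"`, `n_contacting` and `conserved`),
#'   `n_complexes`, `fraction`.
#' @export
conservation_table <- function(complexes, config = contact_config()) {
  stopifnot(length(complexes) >= 1)
  labels <- vapply(seq_along(complexes), function(i) {
    lb <- complexes[[i]]$label
    if (is.null(lb)) paste0("complex", i) else lb
  }, character(1))
  per <- lapply(complexes, function(cx)
    find_contacts(cx$structure, cx$receptor_sel, cx$partner_sel, config))
  rows <- list()
  for (i in seq_along(per)) {
    cp <- per[[i]]
    if (!nrow(cp)) next
    key <- paste0(cp$receptor_resname, cp$receptor_resseq)
    for (k in unique(key)) {
      sub <- cp[key == k, , drop = FALSE]
      partners <- paste0(sub$partner_resname, sub$partner_resseq,
                         collapse = ",")
      if (is.null(rows[[k]]))
        rows[[k]] <- list(resseq = sub$receptor_resseq[1],
                          resname = sub$receptor_resname[1],
                          cells = setNames(rep("-", length(per)), labels))
      rows[[k]]$cells[i] <- partners
    }
  }
  if (!length(rows)) {
    tab <- data.frame(receptor_resseq = integer(), receptor_resname = character())
    return(structure(list(table = tab, n_complexes = length(per),
                          fraction = config$conservation_fraction),
                     class = "ConservationTable"))
  }
  ord <- order(vapply(rows, function(r) r$resseq, numeric(1)))
  rows <- rows[ord]
  cells <- do.call(rbind, lapply(rows, function(r) r$cells))
  n_contacting <- rowSums(cells != "-")
  tab <- data.frame(receptor_resseq = vapply(rows, function(r) r$resseq, numeric(1)),
                    receptor_resname = vapply(rows, function(r) r$resname, character(1)),
                    cells, n_contacting = n_contacting,
                    conserved = n_contacting / length(per) >=
                      config$conservation_fraction,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, n_complexes = length(per),
                 fraction = config$conservation_fraction),
            class = "ConservationTable")
}

#' @export
print.ConservationTable <- function(x, ...) {
  cat(sprintf("<ConservationTable: %d receptor residues x %d complexes, conserved >= %.0f%%>\n",
              nrow(x$table), x$n_complexes, 100 * x$fraction))
  print(x$table)
  invisible(x)
}

#' Superpose complexes onto a common receptor reference
#'
#' Each complex is fitted to `reference` on CA atoms of the receptor
#' selection, matched by residue number; at least 3 matched CA atoms are
#' required.
#'
#' @param complexes list of `Structure`s.
#' @param reference reference `Structure`.
#' @param receptor_sel chain ids of the receptor in every structure.
#' @return list with `structures` (transformed copies) and `fit_rmsd`
#'   (numeric vector, Angstrom).
#' @export
superpose_complexes <- function(complexes, reference, receptor_sel) {
  ref_at <- reference$atoms
  ref_ca <- which(ref_at$chain %in% receptor_sel & ref_at$name == "CA")
  ref_key <- paste(ref_at$chain[ref_ca], ref_at$resseq[ref_ca])
  out <- vector("list", length(complexes))
  fit_rmsd <- numeric(length(complexes))
  for (i in seq_along(complexes)) {
    cx <- complexes[[i]]
    at <- cx$atoms
    ca <- which(at$chain %in% receptor_sel & at$name == "CA")
    key <- paste(at$chain[ca], at$resseq[ca])
    shared <- intersect(key, ref_key)
    if (length(shared) < 3)
      stop("complex ", i, ": fewer than 3 matched receptor CA atoms")
    mi <- ca[match(shared, key)]
    ri <- ref_ca[match(shared, ref_key)]
    fit <- superpose(as.matrix(at[mi, c("x", "y", "z")]),
                     as.matrix(ref_at[ri, c("x", "y", "z")]))
    out[[i]] <- set_coords(cx, apply_transform(coords(cx), fit))
    fit_rmsd[i] <- fit$rmsd
  }
  list(structures = out, fit_rmsd = fit_rmsd)
}
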