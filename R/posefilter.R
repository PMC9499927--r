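# ---------------------------------------------------------------------------
# Post-docking pose triage cascade:
#   Ramachandran compliance -> peptide-bond planarity/cis -> intramolecular
#   steric clashes -> merge-and-sort -> docking-energy cut.
# ---------------------------------------------------------------------------

#' Pose-filter configuration
#'
#' @param top_n_poses number of top-ranked poses examined per compound
#'   (default 20).
#' @param energy_cutoff docking-energy cut, kcal/mol; poses with
#'   score <= cutoff are kept, boundary inclusive (default -8.0).
#' @param omega_cis_max peptide bond classified cis when |omega| <= this,
#'   degrees (default 30).
#' @param omega_trans_min classified trans when |omega| >= this, degrees
#'   (default 150); in between = non-planar.
#' @param clash_overlap allowed vdW interpenetration, Angstrom (default 0.4):
#'   a heavy-atom pair clashes when d < r_i + r_j - clash_overlap.
#' @param min_bond_separation pairs closer than this many bonds along the
#'   covalent graph are exempt from the clash check (default 4, i.e. 1-2,
#'   1-3 and 1-4 neighbours are excluded).
#' @return list of class `FilterConfig`.
#' @export
filter_config <- function(top_n_poses = 20L, energy_cutoff = -8.0,
                          omega_cis_max = 30, omega_trans_min = 150,
                          clash_overlap = 0.4, min_bond_separation = 4L) {
  stopifnot(top_n_poses >= 1, omega_cis_max > 0,
            omega_cis_max < omega_trans_min, omega_trans_min <= 180,
            clash_overlap >= 0, min_bond_separation >= 1)
  structure(list(top_n_poses = as.integer(top_n_poses),
                 energy_cutoff = energy_cutoff,
                 omega_cis_max = omega_cis_max,
                 omega_trans_min = omega_trans_min,
                 clash_overlap = clash_overlap,
                 min_bond_separation = as.integer(min_bond_separation)),
            class = "FilterConfig")
}

# ---- Ramachandran map ------------------------------------------------------

#' Load a Ramachandran allowed-region map
#'
#' The map is a per-class (general / glycine / proline) boolean mask over a
#' (phi, psi) grid.  The bundled default is a coarse mask rasterised from
#' rectangular allowed regions (alpha, beta/PPII, alpha-L) stored as a TSV
#' so stricter masks can be substituted; a (phi, psi) bin is allowed when
#' its centre falls inside any rectangle for the class.
#'
#' @param path TSV with columns class, phi_min, phi_max, psi_min, psi_max;
#'   default the bundled region file.
#' @param bin_width grid bin width, degrees (default 10; must divide 360).
#' @return list of class `RamachandranMap` with `bin_width` and `classes`
#'   (named list of logical matrices, phi bins x psi bins).
#' @export
ramachandran_map <- function(path = system.file("extdata",
                                                "ramachandran_regions.tsv",
                                                package = "ppitriage"),
                             bin_width = 10) {
  stopifnot(360 %% bin_width == 0)
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  nb <- as.integer(360 / bin_width)
  centers <- -180 + bin_width * (seq_len(nb) - 0.5)
  classes <- list()
  for (cls in unique(reg$class)) {
    m <- matrix(FALSE, nb, nb)
    sub <- reg[reg$class == cls, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      pf <- centers >= sub$phi_min[r] & centers <= sub$phi_max[r]
      ps <- centers >= sub$psi_min[r] & centers <= sub$psi_max[r]
      m[pf, ps] <- TRUE
    }
    if (!any(m)) stop("class '", cls, "' has no allowed bins")
    classes[[cls]] <- m
  }
  structure(list(bin_width = bin_width, classes = classes),
            class = "RamachandranMap")
}

angle_bin <- function(a, bin_width) {
  a <- wrap_angle(a)
  idx <- floor((a + 180 - 1e-9) / bin_width) + 1L
  pmax(1L, pmin(as.integer(360 / bin_width), as.integer(idx)))
}

residue_class <- function(resname, has_cb) {
  ifelse(resname == "PRO", "proline",
         ifelse(resname == "GLY" | !has_cb, "glycine", "general"))
}

#' Check whether (phi, psi) pairs fall in allowed map regions
#' @param map a [ramachandran_map()].
#' @param phi,psi angles, degrees.
#' @param class residue class: "general", "glycine" or "proline".
#' @return logical vector.
#' @export
rama_allowed <- function(map, phi, psi, class = "general") {
  stopifnot(length(phi) == length(psi))
  class <- rep_len(class, length(phi))
  vapply(seq_along(phi), function(i) {
    m <- map$classes[[class[i]]]
    if (is.null(m)) m <- map$classes[["general"]]
    m[angle_bin(phi[i], map$bin_width), angle_bin(psi[i], map$bin_width)]
  }, logical(1))
}

ligand_torsions <- function(lig) {
  chains <- unique(lig$atoms$chain)
  do.call(rbind, lapply(chains, function(ch) backbone_torsions(lig, ch)))
}

#' Ramachandran compliance of a docked pose
#'
#' Fails iff any residue with both phi and psi defined falls into a
#' disallowed bin for its class (Pro -> proline; Gly or residues lacking a
#' CB atom -> glycine; else general).  Undefined angles never fail.
#'
#' @param pose a `Pose`.
#' @param map a [ramachandran_map()].
#' @return list with `pass` (logical) and `failures` (data.frame of
#'   offending residues with their phi/psi).
#' @export
filter_ramachandran <- function(pose, map = ramachandran_map()) {
  lig <- pose$ligand
  if (!any(lig$atoms$name == "CA"))
    stop("pose ligand has no resolvable peptide backbone")
  tor <- ligand_torsions(lig)
  has_cb <- vapply(seq_len(nrow(tor)), function(i)
    any(lig$atoms$chain == tor$chain[i] & lig$atoms$resseq == tor$resseq[i] &
          lig$atoms$name == "CB"), logical(1))
  defined <- !is.na(tor$phi) & !is.na(tor$psi)
  cls <- residue_class(tor$resname, has_cb)
  ok <- rep(TRUE, nrow(tor))
  ok[defined] <- rama_allowed(map, tor$phi[defined], tor$psi[defined],
                              cls[defined])
  list(pass = all(ok),
       failures = tor[!ok, c("chain", "resseq", "resname", "phi", "psi"),
                      drop = FALSE])
}

#' Peptide-bond planarity / cis check of a docked pose
#'
#' Each peptide bond is classified by |omega|: trans when
#' >= `omega_trans_min`, cis when <= `omega_cis_max`, otherwise non-planar.
#' The pose fails iff any bond is cis or non-planar.  Bonds whose
#' omega-defining atoms are missing are skipped.
#'
#' @param pose a `Pose`.
#' @param config a [filter_config()].
#' @return list with `pass` and `failures` (data.frame with residue, omega
#'   and classification).
#' @export
filter_peptide_bonds <- function(pose, config = filter_config()) {
  tor <- ligand_torsions(pose$ligand)
  om <- tor$omega
  have <- !is.na(om)
  cls <- rep(NA_character_, nrow(tor))
  cls[have] <- ifelse(abs(om[have]) >= config$omega_trans_min, "trans",
                      ifelse(abs(om[have]) <= config$omega_cis_max, "cis",
                             "non-planar"))
  bad <- have & cls != "trans"
  fails <- tor[bad, c("chain", "resseq", "resname", "omega"), drop = FALSE]
  fails$class <- cls[bad]
  list(pass = !any(bad), failures = fails)
}

# covalent graph of a peptide ligand: template bonds on standard atom names,
# distance-based inference (0.8-1.8 A) for anything nonstandard
bond_list <- function(structure) {
  at <- structure$atoms
  n <- nrow(at)
  bonds <- list()
  add <- function(i, j) bonds[[length(bonds) + 1]] <<- c(i, j)
  reskey <- paste(at$chain, at$resseq, at$icode)
  resids <- unique(reskey)
  templ <- rbind(c("N", "CA"), c("CA", "C"), c("C", "O"), c("CA", "CB"),
                 c("C", "OXT"))
  prev_c <- NA_integer_
  prev_chain <- ""
  templated <- rep(FALSE, n)
  for (rk in resids) {
    idx <- which(reskey == rk)
    for (b in seq_len(nrow(templ))) {
      i <- idx[at$name[idx] == templ[b, 1]]
      j <- idx[at$name[idx] == templ[b, 2]]
      if (length(i) && length(j)) {
        add(i[1], j[1])
        templated[c(i[1], j[1])] <- TRUE
      }
    }
    ni <- idx[at$name[idx] == "N"]
    if (length(ni) && !is.na(prev_c) && at$chain[idx[1]] == prev_chain)
      add(prev_c, ni[1])
    ci <- idx[at$name[idx] == "C"]
    prev_c <- if (length(ci)) ci[1] else NA_integer_
    prev_chain <- at$chain[idx[1]]
  }
  # distance-based fallback for atoms not covered by the template
  loose <- which(!templated)
  if (length(loose)) {
    xyz <- coords(structure)
    for (i in loose) {
      d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
      near <- which(d > 0.8 & d < 1.8)
      for (j in near[near > i]) add(i, j)
    }
  }
  bonds
}

# per-atom-pair minimum bond-path length up to depth `maxd` (Inf beyond)
bond_separation <- function(n, bonds, maxd) {
  adj <- vector("list", n)
  for (b in bonds) {
    adj[[b[1]]] <- c(adj[[b[1]]], b[2])
    adj[[b[2]]] <- c(adj[[b[2]]], b[1])
  }
  sep <- matrix(Inf, n, n)
  diag(sep) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    for (d in seq_len(maxd)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[sep[s, nxt] == Inf]
      if (!length(nxt)) break
      sep[s, nxt] <- d
      frontier <- nxt
    }
  }
  sep
}

#' Intramolecular steric-clash check of a docked pose
#'
#' A heavy-atom pair separated by at least `min_bond_separation` covalent
#' bonds clashes when its distance is below
#' r_i + r_j - `clash_overlap`.  The pose fails iff any pair clashes.
#' Atoms must carry vdW radii (see [annotate()]).
#'
#' @param pose a `Pose` with an annotated ligand.
#' @param config a [filter_config()].
#' @return list with `pass` and `failures` (data.frame of clashing pairs
#'   with distances and thresholds).
#' @export
filter_clashes <- function(pose, config = filter_config()) {
  lig <- pose$ligand
  if (anyNA(lig$atoms$vdw))
    stop("pose ligand atoms lack vdW radii; run annotate() first")
  hv <- heavy_atoms(lig)
  at <- lig$atoms[hv, , drop = FALSE]
  sub <- Structure(at, label = lig$label)
  n <- nrow(at)
  sep <- bond_separation(n, bond_list(sub), config$min_bond_separation - 1L)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  fails <- NULL
  for (i in seq_len(max(0, n - 1))) {
    js <- which(seq_len(n) > i & !is.finite(sep[i, ]))
    if (!length(js)) next
    d <- sqrt(colSums((t(xyz[js, , drop = FALSE]) - xyz[i, ])^2))
    thr <- at$vdw[i] + at$vdw[js] - config$clash_overlap
    bad <- which(d < thr)
    if (length(bad))
      fails <- rbind(fails, data.frame(
        atom_i = paste0(at$resname[i], at$resseq[i], ":", at$name[i]),
        atom_j = paste0(at$resname[js[bad]], at$resseq[js[bad]], ":",
                        at$name[js[bad]]),
        distance = d[bad], threshold = thr[bad], stringsAsFactors = FALSE))
  }
  if (is.null(fails))
    fails <- data.frame(atom_i = character(), atom_j = character(),
                        distance = numeric(), threshold = numeric(),
                        stringsAsFactors = FALSE)
  list(pass = nrow(fails) == 0, failures = fails)
}

#' Apply the docking-energy cut to a pose set
#'
#' Keeps poses with score <= `config$energy_cutoff` (boundary inclusive:
#' a score of exactly -8.0 kcal/mol survives the default cut).  Order is
#' preserved.
#'
#' @param poses list of `Pose` objects.
#' @param config a [filter_config()].
#' @return the surviving poses (same class).
#' @export
apply_energy_cut <- function(poses, config = filter_config()) {
  keep <- vapply(poses, function(p) p$score <= config$energy_cutoff,
                 logical(1))
  out <- poses[keep]
  class(out) <- class(poses)
  out
}

#' Run the full pose-triage cascade over a compound library
#'
#' For each compound only the `top_n_poses` top-ranked poses are examined.
#' Each is screened for Ramachandran compliance, peptide-bond geometry and
#' intramolecular clashes; the surviving poses of every compound (if any)
#' are merged, sorted by ascending docking score (ties: compound id, then
#' rank), and the energy cut is applied.
#'
#' @param pose_library named list: compound id -> list of `Pose` objects
#'   pre-ranked by score.
#' @param map a [ramachandran_map()].
#' @param config a [filter_config()].
#' @return list of class `SelectionReport`: `verdicts` (one row per
#'   examined pose with per-filter pass flags), `merged` (surviving poses
#'   after the energy cut, sorted), `counts` (poses surviving each cascade
#'   stage), `survivor_compounds`.
#' @export
run_cascade <- function(pose_library, map = ramachandran_map(),
                        config = filter_config()) {
  if (!length(pose_library)) stop("empty pose library")
  if (is.null(names(pose_library)) || any(!nzchar(names(pose_library))))
    stop("pose library must be a named list (compound ids)")
  verdicts <- NULL
  survivors <- list()
  for (cid in names(pose_library)) {
    poses <- pose_library[[cid]]
    poses <- poses[seq_len(min(length(poses), config$top_n_poses))]
    for (p in poses) {
      vr <- filter_ramachandran(p, map)
      vb <- filter_peptide_bonds(p, config)
      vc <- filter_clashes(p, config)
      pass_geom <- vr$pass && vb$pass && vc$pass
      verdicts <- rbind(verdicts, data.frame(
        compound_id = cid, rank = p$rank, score = p$score,
        pass_ramachandran = vr$pass, pass_peptide_bonds = vb$pass,
        pass_clashes = vc$pass,
        pass_energy = p$score <= config$energy_cutoff,
        pass_overall = pass_geom && p$score <= config$energy_cutoff,
        stringsAsFactors = FALSE))
      if (pass_geom) survivors[[length(survivors) + 1]] <- p
    }
  }
  counts <- c(examined = nrow(verdicts),
              after_ramachandran = sum(verdicts$pass_ramachandran),
              after_peptide_bonds = sum(verdicts$pass_ramachandran &
                                          verdicts$pass_peptide_bonds),
              after_clashes = sum(verdicts$pass_ramachandran &
                                    verdicts$pass_peptide_bonds &
                                    verdicts$pass_clashes))
  # deterministic merge-and-sort: score, then compound id, then rank
  if (length(survivors)) {
    key <- order(vapply(survivors, function(p) p$score, numeric(1)),
                 vapply(survivors, function(p) p$compound_id, character(1)),
                 vapply(survivors, function(p) p$rank, integer(1)))
    survivors <- survivors[key]
  }
  merged <- apply_energy_cut(survivors, config)
  counts["after_energy"] <- length(merged)
  structure(list(verdicts = verdicts, merged = merged, counts = counts,
                 survivor_compounds =
                   unique(vapply(merged, function(p) p$compound_id,
                                 character(1)))),
            class = "SelectionReport")
}

#' @export
print.SelectionReport <- function(x, ...) {
  cat("<SelectionReport>\n  stage counts:\n")
  for (nm in names(x$counts))
    cat(sprintf("    %-22s %d\n", nm, x$counts[[nm]]))
  cat(sprintf("  surviving compounds: %d\n", length(x$survivor_compounds)))
  invisible(x)
}
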