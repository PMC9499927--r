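# ---------------------------------------------------------------------------
# Domain containers
#
# A Structure holds one model's atom records as a data.frame (one row per
# atom) plus a label and free-text provenance.  An Ensemble holds an ordered
# set of coordinate frames sharing the topology of one Structure.  A Pose is
# a ligand Structure with a docking score, rank and compound id.
# ---------------------------------------------------------------------------

ATOM_COLS <- c("serial", "name", "altloc", "resname", "chain", "resseq",
               "icode", "x", "y", "z", "occupancy", "bfactor", "element",
               "het", "vdw", "polar", "hydrogen")

new_atom_frame <- function(n = 0L) {
  data.frame(serial = integer(n), name = character(n), altloc = character(n),
             resname = character(n), chain = character(n), resseq = integer(n),
             icode = character(n), x = numeric(n), y = numeric(n),
             z = numeric(n), occupancy = numeric(n), bfactor = numeric(n),
             element = character(n), het = logical(n), vdw = numeric(n),
             polar = logical(n), hydrogen = logical(n),
             stringsAsFactors = FALSE)
}

#' Construct a Structure
#'
#' A `Structure` is the package's single-model container: an ordered atom
#' table (coordinates in Angstrom, residue/chain identifiers, element,
#' assigned van der Waals radius and polarity flag) plus a label and
#' free-text provenance.
#'
#' @param atoms data.frame of atom records (see [read_structure()]).
#' @param label short text label.
#' @param provenance free-text origin metadata.
#' @return An object of class `Structure`.
#' @export
Structure <- function(atoms, label = "", provenance = "") {
  stopifnot(is.data.frame(atoms))
  missing_cols <- setdiff(ATOM_COLS, names(atoms))
  for (cl in missing_cols) {
    atoms[[cl]] <- switch(cl,
      vdw = NA_real_, polar = NA, hydrogen = NA,
      het = FALSE, occupancy = 1, bfactor = 0,
      altloc = "", icode = "", element = "",
      stop("atom table lacks required column: ", cl))
  }
  atoms <- atoms[, ATOM_COLS]
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  structure(list(atoms = atoms, label = label, provenance = provenance),
            class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("<Structure '%s': %d atoms, %d chains, %d residues>\n",
              x$label, nrow(x$atoms), length(unique(x$atoms$chain)),
              nrow(unique(x$atoms[, c("chain", "resseq", "icode")]))))
  invisible(x)
}

#' Number of atoms in a Structure
#' @param structure a `Structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Coordinates of a Structure as an n x 3 matrix
#' @param structure a `Structure`.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a Structure
#' @param structure a `Structure`.
#' @param xyz n x 3 numeric matrix.
#' @return the updated `Structure`.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(is.matrix(xyz), nrow(xyz) == n_atoms(structure), ncol(xyz) == 3)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Construct an Ensemble of coordinate frames
#'
#' An `Ensemble` is an ordered sequence of coordinate frames (trajectory
#' snapshots or conformers) sharing one atom topology.  Frame `k` is taken
#' to sit at time `k * frame_interval` picoseconds; the initial (t = 0)
#' configuration is not stored as a frame.
#'
#' @param topology a `Structure` giving the atom order.
#' @param frames list of n_atoms x 3 coordinate matrices.
#' @param frame_interval time between consecutive frames, ps (> 0).
#' @param label text label.
#' @return An object of class `Ensemble`.
#' @export
Ensemble <- function(topology, frames, frame_interval = 1, label = "") {
  stopifnot(inherits(topology, "Structure"), is.list(frames),
            frame_interval > 0)
  na <- n_atoms(topology)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == na &&
                 ncol(f) == 3, logical(1))
  if (length(frames) && !all(ok))
    stop("every frame must be an n_atoms x 3 matrix (n_atoms = ", na, ")")
  structure(list(topology = topology, frames = frames,
                 frame_interval = frame_interval, label = label),
            class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat(sprintf("<Ensemble '%s': %d frames x %d atoms, dt = %g ps>\n",
              x$label, length(x$frames), n_atoms(x$topology),
              x$frame_interval))
  invisible(x)
}

#' Number of frames in an Ensemble
#' @param ensemble an `Ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) length(ensemble$frames)

#' Construct a docking Pose
#' @param ligand a `Structure` holding the posed ligand.
#' @param score docking energy, kcal/mol (finite; more negative = better).
#' @param rank integer rank >= 1 within the compound's pose list.
#' @param compound_id compound identifier.
#' @return An object of class `Pose`.
#' @export
Pose <- function(ligand, score, rank = 1L, compound_id = "") {
  stopifnot(inherits(ligand, "Structure"), is.finite(score), rank >= 1)
  structure(list(ligand = ligand, score = as.numeric(score),
                 rank = as.integer(rank), compound_id = compound_id),
            class = "Pose")
}

# ---------------------------------------------------------------------------
# PDB fixed-column reading
# ---------------------------------------------------------------------------

parse_atom_lines <- function(lines, lineno, path) {
  n <- length(lines)
  # fixed-column PDB v3 layout
  sub2 <- function(a, b) substr(lines, a, b)
  num <- function(txt, what) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.finite(v) & nzchar(trimws(txt)))
    empty <- which(!nzchar(trimws(txt)))
    v[empty] <- NA_real_
    if (length(bad))
      stop(sprintf("malformed %s field at line %d of '%s'", what,
                   lineno[bad[1]], path))
    v
  }
  x <- num(sub2(31, 38), "x")
  y <- num(sub2(39, 46), "y")
  z <- num(sub2(47, 54), "z")
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    bad <- which(is.na(x) | is.na(y) | is.na(z))[1]
    stop(sprintf("malformed coordinate at line %d of '%s'", lineno[bad], path))
  }
  serial <- suppressWarnings(as.integer(trimws(sub2(7, 11))))
  serial[is.na(serial)] <- seq_len(n)[is.na(serial)]
  resseq <- suppressWarnings(as.integer(trimws(sub2(23, 26))))
  if (anyNA(resseq))
    stop(sprintf("malformed residue number at line %d of '%s'",
                 lineno[which(is.na(resseq))[1]], path))
  occ <- num(sub2(55, 60), "occupancy"); occ[is.na(occ)] <- 1
  bf <- num(sub2(61, 66), "B-factor"); bf[is.na(bf)] <- 0
  name <- trimws(sub2(13, 16))
  element <- trimws(sub2(77, 78))
  data.frame(serial = serial, name = name, altloc = trimws(sub2(17, 17)),
             resname = trimws(sub2(18, 20)), chain = trimws(sub2(22, 22)),
             resseq = resseq, icode = trimws(sub2(27, 27)),
             x = x, y = y, z = z, occupancy = occ, bfactor = bf,
             element = element, het = startsWith(lines, "HETATM"),
             vdw = NA_real_, polar = NA, hydrogen = NA,
             stringsAsFactors = FALSE)
}

resolve_altloc <- function(atoms) {
  has_alt <- nzchar(atoms$altloc)
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name, sep = "|")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[has_alt])) {
    idx <- which(key == k)
    if (length(idx) > 1) {
      # highest occupancy wins; ties resolved to the first encountered
      best <- idx[which.max(atoms$occupancy[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' Read structures from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records.  Files with MODEL/ENDMDL blocks
#' yield one `Structure` per model (or only the first, under
#' `model_policy = "first"`).  Alternate locations are resolved to the
#' highest-occupancy copy (ties: first encountered).  Coordinates are kept
#' to the 3 decimal places of the format.
#'
#' @param path PDB file path.
#' @param model_policy `"first"` (default) or `"all"`.
#' @return A list of `Structure` objects (length 1 under `"first"`).
#' @export
read_structure <- function(path, model_policy = c("first", "all")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) stop("no ATOM/HETATM records in '", path, "'")
  model_id <- cumsum(startsWith(lines, "MODEL"))
  model_id[model_id == 0L] <- 1L
  atom_idx <- which(is_atom)
  split_idx <- split(atom_idx, model_id[atom_idx])
  out <- vector("list", length(split_idx))
  for (i in seq_along(split_idx)) {
    idx <- split_idx[[i]]
    atoms <- parse_atom_lines(lines[idx], idx, path)
    atoms <- resolve_altloc(atoms)
    out[[i]] <- Structure(atoms, label = basename(path),
                          provenance = paste0("read from ", path,
                                              " (model ", i, ")"))
    if (model_policy == "first") return(out[1])
  }
  out
}

fmt_atom_line <- function(a) {
  rec <- ifelse(a$het, "HETATM", "ATOM  ")
  # atom-name column convention: 1-3 char names start in column 14
  nm <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
               sprintf(" %-3s", a$name))
  sprintf("%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, a$serial %% 100000L, nm, substr(a$altloc, 1, 1), a$resname,
          substr(a$chain, 1, 1), a$resseq %% 10000L, substr(a$icode, 1, 1),
          a$x, a$y, a$z, a$occupancy, a$bfactor, a$element)
}

#' Write a Structure or Ensemble to a PDB file
#'
#' Ensembles are written as multi-model PDB (one MODEL/ENDMDL block per
#' frame), which doubles as the trajectory format.
#'
#' @param structure a `Structure` or an `Ensemble`.
#' @param path destination path.
#' @param remarks optional character vector of REMARK payloads, one per
#'   model (prefixed with `"REMARK "` on output).
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, remarks = NULL) {
  if (inherits(structure, "Ensemble")) {
    frames <- structure$frames
    if (!length(frames)) stop("ensemble has no frames")
    topo <- structure$topology
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(frames)) {
      writeLines(sprintf("MODEL     %4d", i), con)
      if (!is.null(remarks)) writeLines(paste("REMARK", remarks[[i]]), con)
      fr <- set_coords(topo, frames[[i]])
      writeLines(fmt_atom_line(fr$atoms), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    return(invisible(path))
  }
  stopifnot(inherits(structure, "Structure"))
  if (n_atoms(structure) == 0) stop("refusing to write an empty structure")
  out <- c(if (!is.null(remarks)) paste("REMARK", remarks),
           fmt_atom_line(structure$atoms), "END")
  writeLines(out, path)
  invisible(path)
}

#' Write a set of poses as a scored multi-model PDB
#'
#' Each pose becomes one MODEL block carrying a
#' `REMARK VINA RESULT: <score>` line, the dialect [read_pose_set()]
#' expects by default.
#'
#' @param poses list of `Pose` objects (one compound).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_pose_set <- function(poses, path) {
  stopifnot(length(poses) >= 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(poses)) {
    p <- poses[[i]]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf("REMARK VINA RESULT: %10.4f", p$score), con)
    writeLines(fmt_atom_line(p$ligand$atoms), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a docking pose set from a scored multi-model PDB
#'
#' Each MODEL block must carry a score record (by default a
#' `REMARK VINA RESULT: <value>` line; override with `score_regex`, whose
#' first capture group is the numeric score).  Poses are returned sorted by
#' ascending score (most negative first, ties keep file order) with ranks
#' 1..n.
#'
#' @param path scored multi-model PDB path.
#' @param compound_id compound identifier stamped onto every pose.
#' @param score_regex regex with one capture group for the score.
#' @return list of `Pose` objects ordered by rank (class `PoseSet`).
#' @export
read_pose_set <- function(path, compound_id = basename(path),
                          score_regex = "REMARK VINA RESULT:\\s*(-?[0-9.]+)") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- which(startsWith(lines, "MODEL"))
  if (!length(starts)) stop("no MODEL records in '", path, "'")
  ends <- which(startsWith(lines, "ENDMDL"))
  if (length(ends) != length(starts)) stop("unbalanced MODEL/ENDMDL in '", path, "'")
  models <- read_structure(path, model_policy = "all")
  scores <- numeric(length(starts))
  for (i in seq_along(starts)) {
    block <- lines[starts[i]:ends[i]]
    m <- regmatches(block, regexec(score_regex, block))
    hit <- which(lengths(m) == 2)
    if (!length(hit))
      stop("model ", i, " of '", path, "' has no score record")
    scores[i] <- as.numeric(m[[hit[1]]][2])
  }
  ord <- order(scores)  # stable: ties keep file order
  poses <- lapply(seq_along(ord), function(r)
    Pose(models[[ord[r]]], score = scores[ord[r]], rank = r,
         compound_id = compound_id))
  class(poses) <- c("PoseSet", "list")
  poses
}

# ---------------------------------------------------------------------------
# Annotation: vdW radii and polarity
# ---------------------------------------------------------------------------

#' Default element-to-van-der-Waals-radius table (Bondi-style, Angstrom)
#'
#' @return named numeric vector, element symbol to radius.
#' @export
default_vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
}

infer_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  el <- ifelse(two %in% c("CL", "BR", "SE"), two, substr(nm, 1, 1))
  # numeric-prefixed hydrogen names like 1HB
  el[grepl("^[0-9]", el)] <- substr(sub("^[0-9]+", "", nm[grepl("^[0-9]", el)]), 1, 1)
  el
}

#' Annotate a structure with vdW radii and polarity flags
#'
#' Elements are taken from the element column or inferred from atom names.
#' Polar atoms are N, O, S in thiols (an S bonded to an H), and hydrogens
#' bonded to N or O; bonds for the hydrogen rule are inferred by distance
#' (H within 1.25 Angstrom of a heavy atom).
#'
#' @param structure a `Structure`.
#' @param radius_set named element-to-radius vector
#'   (default [default_vdw_radii()]).
#' @param fallback_radius radius for unknown elements; `NA` (default) makes
#'   unknown elements an error.
#' @return the annotated `Structure`.  Idempotent.
#' @export
annotate <- function(structure, radius_set = default_vdw_radii(),
                     fallback_radius = NA_real_) {
  at <- structure$atoms
  el <- toupper(trimws(at$element))
  el[!nzchar(el)] <- infer_element(at$name[!nzchar(el)])
  unknown <- !(el %in% names(radius_set))
  if (any(unknown)) {
    if (is.na(fallback_radius))
      stop("unknown element(s) with no fallback radius: ",
           paste(unique(paste0(el[unknown], " (atom ", at$name[unknown], " ",
                               at$resname[unknown], at$resseq[unknown], ")")),
                 collapse = ", "))
    at$vdw <- ifelse(unknown, fallback_radius, radius_set[el])
  } else {
    at$vdw <- unname(radius_set[el])
  }
  at$element <- el
  at$hydrogen <- el == "H"
  polar <- el %in% c("N", "O")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  if (any(at$hydrogen)) {
    # polar hydrogens: bonded (< 1.25 A) to N or O
    hv <- which(!at$hydrogen & el %in% c("N", "O", "S"))
    for (ih in which(at$hydrogen)) {
      if (!length(hv)) break
      d2 <- colSums((t(xyz[hv, , drop = FALSE]) - xyz[ih, ])^2)
      j <- hv[which.min(d2)]
      if (d2[which.min(d2)] < 1.25^2 && el[j] %in% c("N", "O"))
        polar[ih] <- TRUE
      if (d2[which.min(d2)] < 1.45^2 && el[j] == "S")
        polar[j] <- TRUE  # thiol sulfur
    }
  }
  at$polar <- polar
  structure$atoms <- at
  structure
}

#' Heavy-atom row indices of a Structure
#' @param structure a `Structure` (annotation optional; falls back to
#'   element inference).
#' @return integer vector of non-hydrogen atom indices.
#' @export
heavy_atoms <- function(structure) {
  el <- structure$atoms$element
  el[!nzchar(el)] <- infer_element(structure$atoms$name[!nzchar(el)])
  which(toupper(el) != "H")
}
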