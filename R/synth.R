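# ---------------------------------------------------------------------------
# Seeded synthetic-fixture generators.  Every generator is a pure function
# of (parameters, seed) and returns ground-truth labels sufficient to
# predict the default-config verdict of the pipeline stage it exercises.
# ---------------------------------------------------------------------------

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

# ideal backbone geometry constants (bond lengths A, angles deg); exact
# values are conventional — generator tests assert self-consistency, not
# these numbers
IDEAL <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
              b_ca_cb = 1.530,
              a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
              a_ca_c_o = 120.8, a_n_ca_cb = 110.5)

# natural extension reference frame: place D bonded to C, given the chain
# A-B-C, with |C-D| = bond, angle(B,C,D) = ang, torsion(A,B,C,D) = tor
nerf_place <- function(A, B, C, bond, ang, tor) {
  ang <- ang * pi / 180
  tor <- tor * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d_local <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
               -bond * sin(ang) * sin(tor))
  C + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' Build an ideal-geometry peptide with prescribed backbone torsions
#'
#' Constructs N/CA/C/O (and CB for non-Gly) atoms by sequential
#' internal-coordinate placement from ideal bond lengths and angles, so
#' that [backbone_torsions()] on the result reproduces the requested
#' phi/psi/omega within numerical precision.  The build is fully
#' deterministic.
#'
#' @param sequence one-letter residue codes, e.g. `"AAAA"`.
#' @param torsions n x 3 matrix or data.frame of per-residue
#'   (phi, psi, omega), degrees; the chain-initial phi and chain-final
#'   omega are ignored (the final psi only orients the terminal carbonyl).
#' @param chain_id chain identifier (default `"L"`).
#' @return an annotated `Structure`.
#' @export
build_peptide <- function(sequence, torsions, chain_id = "L") {
  codes <- strsplit(sequence, "")[[1]]
  if (any(!codes %in% names(AA3)))
    stop("unknown residue code(s): ",
         paste(setdiff(codes, names(AA3)), collapse = ", "))
  torsions <- as.matrix(torsions)
  if (nrow(torsions) != length(codes))
    stop("torsion list length must match sequence length")
  nres <- length(codes)
  rows <- list()
  serial <- 0L
  emit <- function(name, resname, resseq, pos, element) {
    serial <<- serial + 1L
    rows[[length(rows) + 1]] <<- data.frame(
      serial = serial, name = name, altloc = "", resname = resname,
      chain = chain_id, resseq = resseq, icode = "",
      x = pos[1], y = pos[2], z = pos[3], occupancy = 1, bfactor = 0,
      element = element, het = FALSE, vdw = NA_real_, polar = NA,
      hydrogen = FALSE, stringsAsFactors = FALSE)
  }
  # residue 1 backbone laid out in the xy-plane
  N <- c(0, 0, 0)
  CA <- c(IDEAL$b_n_ca, 0, 0)
  th <- (180 - IDEAL$a_n_ca_c) * pi / 180
  C <- CA + IDEAL$b_ca_c * c(cos(th), sin(th), 0)
  for (i in seq_len(nres)) {
    rn <- AA3[[codes[i]]]
    emit("N", rn, i, N, "N")
    emit("CA", rn, i, CA, "C")
    emit("C", rn, i, C, "C")
    psi <- torsions[i, 2]
    if (is.na(psi)) psi <- 180
    O <- nerf_place(N, CA, C, IDEAL$b_c_o, IDEAL$a_ca_c_o,
                    wrap_angle(psi + 180))
    emit("O", rn, i, O, "O")
    if (rn != "GLY") {
      CB <- nerf_place(C, N, CA, IDEAL$b_ca_cb, IDEAL$a_n_ca_cb, -122.6)
      emit("CB", rn, i, CB, "C")
    }
    if (i < nres) {
      omega <- torsions[i, 3]
      if (is.na(omega)) omega <- 180
      phi_next <- torsions[i + 1, 1]
      if (is.na(phi_next)) phi_next <- -60
      N2 <- nerf_place(N, CA, C, IDEAL$b_c_n, IDEAL$a_ca_c_n, psi)
      CA2 <- nerf_place(CA, C, N2, IDEAL$b_n_ca, IDEAL$a_c_n_ca, omega)
      C2 <- nerf_place(C, N2, CA2, IDEAL$b_ca_c, IDEAL$a_n_ca_c, phi_next)
      N <- N2; CA <- CA2; C <- C2
    }
  }
  annotate(Structure(do.call(rbind, rows),
                     label = paste0("synthetic peptide ", sequence),
                     provenance = "build_peptide"))
}

sample_allowed_torsions <- function(nres) {
  # interior points of the bundled allowed regions (alpha and beta), so a
  # clean pose can never straddle a disallowed bin
  out <- matrix(NA_real_, nres, 3)
  for (i in seq_len(nres)) {
    if (stats::runif(1) < 0.5) {
      out[i, ] <- c(stats::runif(1, -100, -60), stats::runif(1, -50, -20), 180)
    } else {
      out[i, ] <- c(stats::runif(1, -150, -90), stats::runif(1, 100, 160), 180)
    }
  }
  out
}

# sample allowed torsions whose ideal-geometry build is clash-free, so a
# clean pose is guaranteed to pass every geometric filter
sample_clean_torsions <- function(seqc, nres, max_tries = 50) {
  for (k in seq_len(max_tries)) {
    tor <- sample_allowed_torsions(nres)
    pep <- build_peptide(seqc, tor)
    if (filter_clashes(Pose(pep, 0))$pass) return(list(tor = tor, pep = pep))
  }
  stop("could not sample a clash-free clean conformation for ", seqc)
}

#' Generate a labelled decoy pose library
#'
#' Each pose is built clean (ideal geometry, allowed torsions, all-trans
#' bonds), then independently corrupted with each defect at its stated
#' rate: one internal residue pushed to a disallowed (phi, psi); one omega
#' set to 0 (cis) or 100 (non-planar); one CB displaced to 1.0 Angstrom
#' from a non-bonded backbone carbon.  Scores are Gaussian.  The labels
#' record exactly which defects each pose carries, so expected cascade
#' verdicts are fully determined.
#'
#' @param n_compounds,poses_per_compound library dimensions.
#' @param defect_rates named list with elements `rama`, `omega`, `clash`,
#'   probabilities in `[0, 1]` (default 0.25 each).
#' @param score_mean,score_sd docking-score distribution, kcal/mol
#'   (defaults -8, 1 — straddling the energy cut).
#' @param seed integer seed (mandatory).
#' @return list with `library` (named list compound id -> rank-ordered list
#'   of annotated `Pose`s) and `labels` (data.frame: compound_id, rank,
#'   score, defect_rama, defect_omega, defect_clash).
#' @export
make_pose_library <- function(n_compounds, poses_per_compound,
                              defect_rates = list(rama = 0.25, omega = 0.25,
                                                  clash = 0.25),
                              score_mean = -8, score_sd = 1, seed) {
  stopifnot(!missing(seed), all(unlist(defect_rates) >= 0),
            all(unlist(defect_rates) <= 1))
  set.seed(seed)
  alphabet <- c("A", "F", "L", "K", "S", "V")  # non-Gly/Pro: general class
  library <- list()
  labels <- NULL
  for (ci in seq_len(n_compounds)) {
    cid <- sprintf("CPD%03d", ci)
    nres <- sample(3:4, 1)
    seqc <- paste(sample(alphabet, nres, replace = TRUE), collapse = "")
    poses <- list()
    for (pi_ in seq_len(poses_per_compound)) {
      clean <- sample_clean_torsions(seqc, nres)
      tor <- clean$tor
      d_rama <- stats::runif(1) < defect_rates$rama
      d_omega <- stats::runif(1) < defect_rates$omega
      d_clash <- stats::runif(1) < defect_rates$clash
      if (d_rama) {
        # internal residue (phi and psi both defined) forced off-map
        internal <- 2:(nres - 1)  # phi and psi both defined there
        r <- internal[sample.int(length(internal), 1)]
        tor[r, 1:2] <- c(75, -60)
      }
      if (d_omega) {
        r <- sample(seq_len(nres - 1), 1)
        tor[r, 3] <- if (stats::runif(1) < 0.5) 0 else 100
      }
      lig <- if (d_rama || d_omega) build_peptide(seqc, tor) else clean$pep
      if (d_clash) {
        at <- lig$atoms
        cb <- which(at$name == "CB" & at$resseq == 1)[1]
        target <- which(at$name == "C" & at$resseq == nres)[1]
        if (is.na(cb)) cb <- which(at$name == "O" & at$resseq == 1)[1]
        at[cb, c("x", "y", "z")] <-
          at[target, c("x", "y", "z")] + c(1.0, 0, 0)
        lig$atoms <- at
      }
      score <- stats::rnorm(1, score_mean, score_sd)
      poses[[pi_]] <- list(lig = lig, score = score, rama = d_rama,
                           omega = d_omega, clash = d_clash)
    }
    ord <- order(vapply(poses, function(p) p$score, numeric(1)))
    ranked <- lapply(seq_along(ord), function(r)
      Pose(poses[[ord[r]]]$lig, poses[[ord[r]]]$score, rank = r,
           compound_id = cid))
    class(ranked) <- c("PoseSet", "list")
    library[[cid]] <- ranked
    labels <- rbind(labels, data.frame(
      compound_id = cid, rank = seq_along(ord),
      score = vapply(poses[ord], function(p) p$score, numeric(1)),
      defect_rama = vapply(poses[ord], function(p) p$rama, logical(1)),
      defect_omega = vapply(poses[ord], function(p) p$omega, logical(1)),
      defect_clash = vapply(poses[ord], function(p) p$clash, logical(1)),
      stringsAsFactors = FALSE))
  }
  list(library = library, labels = labels)
}

#' Generate a Gaussian-noise trajectory around a reference structure
#'
#' Frame i = reference coordinates + iid N(0, sigma^2) per coordinate.
#'
#' @param reference a `Structure`.
#' @param sigma per-coordinate noise, Angstrom (>= 0).
#' @param n_frames number of frames.
#' @param frame_interval ps per frame (default 1).
#' @param seed integer seed (mandatory).
#' @param atoms optional integer indices: noise only these atoms (e.g. the
#'   ligand, keeping the receptor rigid); default all.
#' @return an `Ensemble`; its label records sigma.
#' @export
make_noisy_trajectory <- function(reference, sigma, n_frames,
                                  frame_interval = 1, seed, atoms = NULL) {
  stopifnot(!missing(seed), sigma >= 0, n_frames >= 1)
  set.seed(seed)
  base <- coords(reference)
  if (is.null(atoms)) atoms <- seq_len(nrow(base))
  frames <- lapply(seq_len(n_frames), function(i) {
    fr <- base
    fr[atoms, ] <- fr[atoms, , drop = FALSE] +
      matrix(stats::rnorm(3 * length(atoms), 0, sigma), length(atoms), 3)
    fr
  })
  Ensemble(reference, frames, frame_interval = frame_interval,
           label = sprintf("gaussian-noise sigma=%g", sigma))
}

#' Generate a protein + organic-probe trajectory with a planted hotspot
#'
#' The protein stays fixed; each of `n_probes` single-site probe molecules
#' is, per frame, placed at the planted site (isotropic Gaussian, sigma
#' 1 Angstrom) with probability `enrichment`, otherwise uniformly in the
#' simulation box (protein bounding box + margin).
#'
#' @param protein a `Structure`.
#' @param site planted hotspot centre, 3-vector, Angstrom; must lie inside
#'   the box.
#' @param enrichment probability a probe visits the site in a frame,
#'   `[0, 1]`.
#' @param n_probes,n_frames counts.
#' @param seed integer seed (mandatory).
#' @param margin box padding around the protein, Angstrom (default 10).
#' @param probe_type probe label (default `"ethylamine"`).
#' @return list with `ensemble` (protein + probe atoms; chain `"P"`),
#'   `probe_groups` (as [accumulate_occupancy()] expects) and `label`
#'   (site, enrichment, box).
#' @export
make_probe_trajectory <- function(protein, site, enrichment, n_probes,
                                  n_frames, seed, margin = 10,
                                  probe_type = "ethylamine") {
  stopifnot(!missing(seed), enrichment >= 0, enrichment <= 1)
  set.seed(seed)
  pxyz <- coords(protein)
  lo <- apply(pxyz, 2, min) - margin
  hi <- apply(pxyz, 2, max) + margin
  if (any(site < lo) || any(site > hi))
    stop("planted site lies outside the simulation box")
  np <- n_atoms(protein)
  probe_atoms <- data.frame(
    serial = np + seq_len(n_probes), name = "N", altloc = "",
    resname = "ETA", chain = "P", resseq = seq_len(n_probes), icode = "",
    x = site[1], y = site[2], z = site[3], occupancy = 1, bfactor = 0,
    element = "N", het = TRUE, vdw = NA_real_, polar = NA, hydrogen = NA,
    stringsAsFactors = FALSE)
  topo <- Structure(rbind(protein$atoms[, ATOM_COLS], probe_atoms),
                    label = "probe trajectory topology",
                    provenance = "make_probe_trajectory")
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- rbind(pxyz, matrix(0, n_probes, 3))
    for (p in seq_len(n_probes)) {
      if (stats::runif(1) < enrichment) {
        pos <- site + stats::rnorm(3, 0, 1)
      } else {
        pos <- stats::runif(3, lo, hi)
      }
      xyz[np + p, ] <- pos
    }
    frames[[f]] <- xyz
  }
  groups <- list(lapply(seq_len(n_probes), function(p) np + p))
  names(groups) <- probe_type
  list(ensemble = Ensemble(topo, frames, frame_interval = 1,
                           label = "planted-hotspot probe trajectory"),
       probe_groups = groups,
       label = list(site = site, enrichment = enrichment,
                    box = rbind(lo, hi)))
}

#' Generate a toy receptor-partner complex with planted contacts
#'
#' Receptor residues (chain `"R"`) sit on a line 8 Angstrom apart; partner
#' residues (chain `"E"`) sit on a distant parallel line, except that each
#' planted pair's partner residue is placed exactly at its stated distance
#' from its receptor residue.  Every non-planted residue pair is farther
#' than cutoff + 2 Angstrom for any cutoff up to 6.  Residues are
#' single-CA pseudo-residues.
#'
#' @param n_receptor_res,n_partner_res chain lengths.
#' @param planted_contacts data.frame with columns `receptor_res`,
#'   `partner_res` (1-based indices) and `distance` (Angstrom).
#' @param seed integer seed (mandatory; reserved for interface uniformity —
#'   the construction is deterministic).
#' @return list with `structure` (a `Structure`) and `label` (the planted
#'   contact table).
#' @export
make_toy_complex <- function(n_receptor_res, n_partner_res,
                             planted_contacts, seed) {
  stopifnot(!missing(seed), all(planted_contacts$distance > 0))
  if (anyDuplicated(planted_contacts$partner_res))
    stop("infeasible: one partner residue planted on several receptors")
  if (any(planted_contacts$receptor_res > n_receptor_res) ||
      any(planted_contacts$partner_res > n_partner_res))
    stop("planted residue index out of range")
  if (any(planted_contacts$distance > 6))
    stop("infeasible: planted distances above 6 A collide with the far-line guarantee")
  mk <- function(chain, i, pos) data.frame(
    serial = i, name = "CA", altloc = "", resname = "ALA", chain = chain,
    resseq = i, icode = "", x = pos[1], y = pos[2], z = pos[3],
    occupancy = 1, bfactor = 0, element = "C", het = FALSE,
    vdw = NA_real_, polar = NA, hydrogen = NA, stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(n_receptor_res))
    rows[[length(rows) + 1]] <- mk("R", i, c(8 * i, 0, 0))
  for (j in seq_len(n_partner_res)) {
    hit <- which(planted_contacts$partner_res == j)
    pos <- if (length(hit)) {
      i <- planted_contacts$receptor_res[hit]
      c(8 * i, planted_contacts$distance[hit], 0)
    } else c(8 * j, 30, 0)
    rows[[length(rows) + 1]] <- mk("E", j, pos)
  }
  st <- Structure(do.call(rbind, rows), label = "synthetic toy complex",
                  provenance = "make_toy_complex")
  list(structure = st, label = planted_contacts)
}
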