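# ---------------------------------------------------------------------------
# Shrake-Rupley solvent-accessible surface area, conformer-ensemble polar
# area averaging, and the passive-permeability verdicts.
# ---------------------------------------------------------------------------

#' Permeability configuration
#'
#' @param probe_radius solvent probe radius, Angstrom (default 1.4, water).
#' @param n_sphere_points points per atom on the sampling sphere
#'   (default 960).
#' @param screen_threshold polar-area screening threshold, Angstrom^2
#'   (default 150; permeable iff the ensemble-average polar area is
#'   strictly below it).
#' @param synthesis_threshold stricter synthesis-selection threshold,
#'   Angstrom^2 (default 130).
#' @param snapshot_interval conformer-extraction interval, ps (default 4).
#' @return list of class `PermeabilityConfig`.
#' @export
permeability_config <- function(probe_radius = 1.4, n_sphere_points = 960L,
                                screen_threshold = 150,
                                synthesis_threshold = 130,
                                snapshot_interval = 4) {
  stopifnot(probe_radius > 0, n_sphere_points >= 12,
            screen_threshold > 0, synthesis_threshold > 0,
            synthesis_threshold <= screen_threshold, snapshot_interval > 0)
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 screen_threshold = screen_threshold,
                 synthesis_threshold = synthesis_threshold,
                 snapshot_interval = snapshot_interval),
            class = "PermeabilityConfig")
}

# deterministic quasi-uniform unit-sphere lattice (golden spiral)
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples each atom's solvent-expanded sphere (radius r_i + probe) with a
#' deterministic golden-spiral point lattice and counts points not buried
#' inside any neighbour's expanded sphere; per-atom area is
#' 4 pi (r_i + probe)^2 times the accessible fraction.  Results are
#' bit-for-bit reproducible at fixed `n_sphere_points`.  Hydrogens, when
#' present, are included as atoms.
#'
#' @param structure an annotated `Structure` (vdW radii and polarity set).
#' @param config a [permeability_config()].
#' @return list of class `SasaResult`: `per_atom_area`, `total_area`,
#'   `polar_area`, `probe_radius`, `n_sphere_points` (areas in Angstrom^2).
#' @export
sasa <- function(structure, config = permeability_config()) {
  at <- structure$atoms
  if (anyNA(at$vdw) || anyNA(at$polar))
    stop("structure lacks radius/polarity annotation; run annotate() first")
  n <- nrow(at)
  xyz <- coords(structure)
  rr <- at$vdw + config$probe_radius
  pts <- golden_spiral_points(config$n_sphere_points)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d < rr[i] + rr & d > 0)
    p <- pts * rr[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(p))
    for (j in nb) {
      if (!any(acc)) break
      d2 <- colSums((t(p[acc, , drop = FALSE]) - xyz[j, ])^2)
      acc[acc] <- d2 >= rr[j]^2
    }
    per_atom[i] <- 4 * pi * rr[i]^2 * sum(acc) / config$n_sphere_points
  }
  structure(list(per_atom_area = per_atom, total_area = sum(per_atom),
                 polar_area = sum(per_atom[at$polar]),
                 probe_radius = config$probe_radius,
                 n_sphere_points = config$n_sphere_points),
            class = "SasaResult")
}

#' Extract evenly spaced snapshots from a trajectory
#'
#' Keeps the frames at times `interval`, `2*interval`, ... — the t = 0
#' configuration is excluded — so a 100 ps trajectory sampled every 4 ps
#' yields exactly 25 conformers.
#'
#' @param traj an `Ensemble` (frame k at time k * frame_interval ps).
#' @param interval snapshot interval, ps; must be a positive multiple of
#'   the frame spacing.
#' @return an `Ensemble` with the extracted frames and `frame_interval =
#'   interval`.
#' @export
extract_snapshots <- function(traj, interval) {
  dt <- traj$frame_interval
  if (interval < dt) stop("interval (", interval,
                          " ps) below frame spacing (", dt, " ps)")
  step <- interval / dt
  if (abs(step - round(step)) > 1e-9)
    stop("interval must be a multiple of the frame spacing")
  step <- as.integer(round(step))
  idx <- seq.int(step, n_frames(traj), by = step)
  Ensemble(traj$topology, traj$frames[idx], frame_interval = interval,
           label = traj$label)
}

#' Concatenate ensembles sharing one topology
#'
#' @param ensembles non-empty list of `Ensemble`s with identical atom
#'   counts and ordering.
#' @return one `Ensemble` whose frame count is the sum of the inputs',
#'   input order preserved.
#' @export
combine_ensembles <- function(ensembles) {
  if (!length(ensembles)) stop("no ensembles to combine")
  na <- n_atoms(ensembles[[1]]$topology)
  nm <- ensembles[[1]]$topology$atoms$name
  for (e in ensembles)
    if (n_atoms(e$topology) != na || !identical(e$topology$atoms$name, nm))
      stop("ensemble topologies differ")
  Ensemble(ensembles[[1]]$topology,
           do.call(c, lapply(ensembles, function(e) e$frames)),
           frame_interval = ensembles[[1]]$frame_interval,
           label = ensembles[[1]]$label)
}

#' Ensemble-averaged polar accessible surface area and permeability verdict
#'
#' Computes the polar SASA of every frame and averages; the compound is
#' predicted membrane-permeable when the average is strictly below the
#' screening threshold (150 Angstrom^2 default) and passes the synthesis
#' cut when strictly below the stricter threshold (130 Angstrom^2 default).
#'
#' @param ensemble an `Ensemble` with an annotated topology.
#' @param config a [permeability_config()].
#' @return list of class `PermeabilityVerdict`: `pol_asa_avg`,
#'   `per_frame_polar_area`, `n_frames`, `permeable_screen`,
#'   `pass_synthesis_cut`.
#' @export
ensemble_polar_asa <- function(ensemble, config = permeability_config()) {
  if (!n_frames(ensemble)) stop("empty ensemble")
  topo <- ensemble$topology
  if (anyNA(topo$atoms$polar))
    stop("ensemble topology lacks polarity annotation; run annotate() first")
  per_frame <- vapply(ensemble$frames, function(fr)
    sasa(set_coords(topo, fr), config)$polar_area, numeric(1))
  avg <- mean(per_frame)
  structure(list(pol_asa_avg = avg, per_frame_polar_area = per_frame,
                 n_frames = length(per_frame),
                 permeable_screen = avg < config$screen_threshold,
                 pass_synthesis_cut = avg < config$synthesis_threshold),
            class = "PermeabilityVerdict")
}

#' @export
print.PermeabilityVerdict <- function(x, ...) {
  cat(sprintf("<PermeabilityVerdict: polASA_avg = %.1f A^2 over %d frames; screen %s, synthesis cut %s>\n",
              x$pol_asa_avg, x$n_frames,
              if (x$permeable_screen) "PASS" else "fail",
              if (x$pass_synthesis_cut) "PASS" else "fail"))
  invisible(x)
}
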