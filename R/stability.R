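# ---------------------------------------------------------------------------
# Ligand binding-stability classification from complex trajectories
# ---------------------------------------------------------------------------

#' Binding-stability configuration
#'
#' The default window — the trailing half of the trajectory — generalises
#' "the last 1.5 ns of a 3 ns run"; `window_ps` expresses it as an absolute
#' trailing duration instead.
#'
#' @param window trailing fraction of frames averaged (default 0.5).
#' @param window_ps trailing duration in ps (overrides `window` when set).
#' @param threshold stability threshold, Angstrom (default 3.0; stable iff
#'   the windowed mean ligand RMSD is strictly below it).
#' @param ligand_sel,receptor_sel chain ids selecting ligand and receptor.
#' @param align_on_receptor superpose each frame onto the reference using
#'   receptor heavy atoms before measuring the ligand (default TRUE).
#' @return list of class `StabilityConfig`.
#' @export
stability_config <- function(window = 0.5, window_ps = NULL, threshold = 3.0,
                             ligand_sel = "L", receptor_sel = "A",
                             align_on_receptor = TRUE) {
  stopifnot(window > 0, window <= 1, threshold > 0)
  structure(list(window = window, window_ps = window_ps,
                 threshold = threshold, ligand_sel = ligand_sel,
                 receptor_sel = receptor_sel,
                 align_on_receptor = align_on_receptor),
            class = "StabilityConfig")
}

#' Per-frame ligand RMSD against the docked reference pose
#'
#' For every frame, optionally superposes the frame onto the reference
#' complex using receptor heavy atoms (Kabsch), then reports the unfitted
#' heavy-atom RMSD of the ligand selection against the reference ligand —
#' so ligand drift out of the binding mode counts, receptor tumbling does
#' not.
#'
#' @param traj an `Ensemble` whose topology contains both selections.
#' @param reference the docked complex `Structure` (same atom order as the
#'   trajectory topology).
#' @param config a [stability_config()].
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
ligand_rmsd_series <- function(traj, reference, config = stability_config()) {
  topo <- traj$topology
  if (n_atoms(reference) != n_atoms(topo))
    stop("reference and trajectory topology have different atom counts")
  lig <- intersect(which(topo$atoms$chain %in% config$ligand_sel),
                   heavy_atoms(topo))
  rec <- intersect(which(topo$atoms$chain %in% config$receptor_sel),
                   heavy_atoms(topo))
  if (!length(lig)) stop("ligand selection matches no atoms")
  if (config$align_on_receptor && !length(rec))
    stop("receptor selection matches no atoms")
  ref_xyz <- coords(reference)
  vapply(traj$frames, function(fr) {
    if (config$align_on_receptor) {
      fit <- superpose(fr[rec, , drop = FALSE], ref_xyz[rec, , drop = FALSE])
      fr <- apply_transform(fr, fit)
    }
    rmsd(fr[lig, , drop = FALSE], ref_xyz[lig, , drop = FALSE], fit = FALSE)
  }, numeric(1))
}

#' Classify binding stability from a ligand RMSD series
#'
#' Averages the series over the trailing window and calls the compound a
#' stable binder iff that mean is strictly below the threshold (a mean of
#' exactly 3.0 Angstrom is not stable).
#'
#' @param series per-frame ligand RMSD, Angstrom.
#' @param config a [stability_config()].
#' @param frame_interval ps per frame, needed when `config$window_ps` is
#'   used.
#' @return list of class `StabilityVerdict`: `lig_rmsd_series`,
#'   `lig_rmsd_avg`, `window_frames`, `stable`.
#' @export
assess_stability <- function(series, config = stability_config(),
                             frame_interval = NULL) {
  n <- length(series)
  if (!n) stop("empty RMSD series")
  if (!is.null(config$window_ps)) {
    if (is.null(frame_interval))
      stop("frame_interval required when the window is given in ps")
    wf <- as.integer(round(config$window_ps / frame_interval))
  } else {
    wf <- as.integer(ceiling(config$window * n))
  }
  if (wf < 1 || wf > n)
    stop("window of ", wf, " frames incompatible with series of length ", n)
  tail_mean <- mean(series[(n - wf + 1):n])
  structure(list(lig_rmsd_series = series, lig_rmsd_avg = tail_mean,
                 window_frames = wf,
                 stable = tail_mean < config$threshold),
            class = "StabilityVerdict")
}

#' @export
print.StabilityVerdict <- function(x, ...) {
  cat(sprintf("<StabilityVerdict: LigRMSD_avg = %.3f A over trailing %d frames -> %s>\n",
              x$lig_rmsd_avg, x$window_frames,
              if (x$stable) "STABLE" else "not stable"))
  invisible(x)
}
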