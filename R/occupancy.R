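# ---------------------------------------------------------------------------
# Mixed-solvent probe-occupancy mapping: voxel accumulation over a trailing
# trajectory window and hotspot-to-residue reporting.
# ---------------------------------------------------------------------------

#' Occupancy grid specification
#'
#' @param origin grid origin (corner), 3-vector, Angstrom.
#' @param spacing voxel edge, Angstrom (default 1.0).
#' @param shape integer 3-vector of voxel counts along x/y/z.
#' @param window trailing fraction of frames accumulated (default 0.5,
#'   mirroring analysis of the last half of a probe simulation).
#' @return list of class `GridSpec`.
#' @export
grid_spec <- function(origin, spacing = 1.0, shape, window = 0.5) {
  stopifnot(length(origin) == 3, spacing > 0, length(shape) == 3,
            all(shape >= 1), window > 0, window <= 1)
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 shape = as.integer(shape), window = window),
            class = "GridSpec")
}

#' Grid specification covering a structure's bounding box
#' @param structure a `Structure`.
#' @param spacing voxel edge, Angstrom.
#' @param margin padding added on every side, Angstrom (default 8).
#' @param window trailing fraction of frames (default 0.5).
#' @return a [grid_spec()].
#' @export
grid_spec_for <- function(structure, spacing = 1.0, margin = 8,
                          window = 0.5) {
  xyz <- coords(structure)
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  grid_spec(lo, spacing, ceiling((hi - lo) / spacing), window)
}

voxel_index <- function(pos, spec) {
  ijk <- floor((pos - spec$origin) / spec$spacing) + 1
  if (any(ijk < 1) || any(ijk > spec$shape)) return(NA_integer_)
  as.integer(ijk[1] + (ijk[2] - 1) * spec$shape[1] +
               (ijk[3] - 1) * spec$shape[1] * spec$shape[2])
}

#' Accumulate probe-occupancy counts over a trajectory window
#'
#' For every frame in the trailing window, the heavy-atom geometric centre
#' of each probe molecule increments one voxel of its probe type's grid;
#' positions outside the grid are counted in a sentinel bin so that total
#' counts are conserved (frames_used x n_probes per type).
#'
#' @param ensemble probe trajectory (`Ensemble`).
#' @param probe_groups named list: probe type -> list of integer atom-index
#'   vectors, one per probe molecule (indices into the topology).
#' @param spec a [grid_spec()].
#' @return list of class `OccupancyGrid`: `spec`, `counts` (per type, an
#'   array of `spec$shape`), `out_of_grid` (sentinel counts per type),
#'   `n_frames_used`, `n_probes`.
#' @export
accumulate_occupancy <- function(ensemble, probe_groups, spec) {
  if (!length(probe_groups) ||
      any(!vapply(probe_groups, length, integer(1))))
    stop("empty probe selection")
  nf <- n_frames(ensemble)
  n_used <- as.integer(ceiling(spec$window * nf))
  use <- ensemble$frames[(nf - n_used + 1):nf]
  topo <- ensemble$topology
  hv <- heavy_atoms(topo)
  counts <- lapply(probe_groups, function(g)
    array(0L, dim = spec$shape))
  oog <- setNames(integer(length(probe_groups)), names(probe_groups))
  for (fr in use) {
    for (ty in names(probe_groups)) {
      for (mol in probe_groups[[ty]]) {
        idx <- intersect(mol, hv)
        if (!length(idx)) idx <- mol
        centre <- colMeans(fr[idx, , drop = FALSE])
        v <- voxel_index(centre, spec)
        if (is.na(v)) oog[ty] <- oog[ty] + 1L
        else counts[[ty]][v] <- counts[[ty]][v] + 1L
      }
    }
  }
  structure(list(spec = spec, counts = counts, out_of_grid = oog,
                 n_frames_used = n_used,
                 n_probes = vapply(probe_groups, length, integer(1))),
            class = "OccupancyGrid")
}

voxel_center <- function(lin, spec) {
  lin <- lin - 1L
  i <- lin %% spec$shape[1]
  j <- (lin %/% spec$shape[1]) %% spec$shape[2]
  k <- lin %/% (spec$shape[1] * spec$shape[2])
  spec$origin + (c(i, j, k) + 0.5) * spec$spacing
}

# 6-connected components over a set of linear voxel indices
connected_components <- function(lin, spec) {
  set <- new.env(hash = TRUE)
  for (v in lin) assign(as.character(v), TRUE, envir = set)
  nx <- spec$shape[1]; nxy <- spec$shape[1] * spec$shape[2]
  comp <- integer(length(lin))
  names(comp) <- as.character(lin)
  cid <- 0L
  for (v in lin) {
    if (comp[[as.character(v)]] != 0L) next
    cid <- cid + 1L
    queue <- v
    comp[[as.character(v)]] <- cid
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      u0 <- u - 1L
      i <- u0 %% nx; j <- (u0 %/% nx) %% spec$shape[2]; k <- u0 %/% nxy
      nbr <- c(if (i > 0) u - 1L, if (i < nx - 1) u + 1L,
               if (j > 0) u - nx, if (j < spec$shape[2] - 1) u + nx,
               if (k > 0) u - nxy, if (k < spec$shape[3] - 1) u + nxy)
      for (w in nbr) {
        key <- as.character(w)
        if (!is.null(set[[key]]) && comp[[key]] == 0L) {
          comp[[key]] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  split(lin, comp[as.character(lin)])
}

#' Report probe-occupancy hotspots and their flanking residues
#'
#' Voxels whose occupancy fraction (count / (frames_used x n_probes of the
#' type)) reaches `min_fraction` are merged into 6-connected components and
#' ranked by peak fraction; each site reports the protein residues with any
#' heavy atom within `report_radius` of the component's peak voxel centre,
#' sorted by distance.
#'
#' @param grid an [accumulate_occupancy()] result.
#' @param protein a `Structure` in the grid's frame of reference.
#' @param report_radius flanking-residue radius, Angstrom (default 6).
#' @param min_fraction occupancy-fraction threshold (default 0.05).
#' @return data.frame of sites: probe type, peak voxel centre, peak
#'   fraction, component voxel count, and flanking residues (text,
#'   distance-sorted).  Empty when nothing concentrates.
#' @export
hotspot_sites <- function(grid, protein, report_radius = 6,
                          min_fraction = 0.05) {
  spec <- grid$spec
  at <- protein$atoms
  hv <- heavy_atoms(protein)
  xyz <- as.matrix(at[hv, c("x", "y", "z")])
  sites <- NULL
  for (ty in names(grid$counts)) {
    denom <- grid$n_frames_used * grid$n_probes[[ty]]
    frac <- grid$counts[[ty]] / denom
    lin <- which(frac >= min_fraction)
    if (!length(lin)) next
    for (cmp in connected_components(lin, spec)) {
      peak <- cmp[which.max(frac[cmp])]
      pc <- voxel_center(peak, spec)
      d <- sqrt(colSums((t(xyz) - pc)^2))
      near <- which(d <= report_radius)
      if (length(near)) {
        ord <- near[order(d[near])]
        reskey <- paste0(at$chain[hv][ord], ":", at$resname[hv][ord],
                         at$resseq[hv][ord])
        flank <- paste(unique(reskey), collapse = ",")
      } else flank <- ""
      sites <- rbind(sites, data.frame(
        probe_type = ty, x = pc[1], y = pc[2], z = pc[3],
        peak_fraction = frac[peak], n_voxels = length(cmp),
        flanking_residues = flank, stringsAsFactors = FALSE))
    }
  }
  if (is.null(sites))
    return(data.frame(probe_type = character(), x = numeric(), y = numeric(),
                      z = numeric(), peak_fraction = numeric(),
                      n_voxels = integer(), flanking_residues = character(),
                      stringsAsFactors = FALSE))
  sites <- sites[order(-sites$peak_fraction), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}
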