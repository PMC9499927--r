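test_that("occupancy accumulation conserves counts and bins correctly", {
  pocket <- acidic_pocket_protein()
  # one stationary probe: a single voxel collects every windowed frame
  pt <- make_probe_trajectory(pocket$protein, pocket$site, enrichment = 0,
                              n_probes = 1, n_frames = 10, seed = 1)
  # freeze the probe: every frame at the site exactly
  np <- n_atoms(pocket$protein)
  pt$ensemble$frames <- lapply(pt$ensemble$frames, function(fr) {
    fr[np + 1, ] <- pocket$site
    fr
  })
  spec <- grid_spec_for(pocket$protein, spacing = 1, window = 1)
  g <- accumulate_occupancy(pt$ensemble, pt$probe_groups, spec)
  expect_equal(max(g$counts[[1]]), 10)
  expect_equal(sum(g$counts[[1]] > 0), 1)
  expect_error(accumulate_occupancy(pt$ensemble, list(eta = list()), spec),
               "empty probe")
})

test_that("random probes conserve totals; counts match a re-binning oracle", {
  pocket <- acidic_pocket_protein()
  pt <- make_probe_trajectory(pocket$protein, pocket$site, enrichment = 0.3,
                              n_probes = 10, n_frames = 40, seed = 6)
  spec <- grid_spec_for(pocket$protein, spacing = 1.5, margin = 12,
                        window = 0.5)
  g <- accumulate_occupancy(pt$ensemble, pt$probe_groups, spec)
  n_used <- g$n_frames_used
  expect_equal(n_used, 20)
  expect_equal(sum(g$counts[[1]]) + g$out_of_grid[[1]], n_used * 10)
  # brute-force re-binning oracle over the windowed frames
  np <- n_atoms(pocket$protein)
  oracle <- array(0L, dim = spec$shape)
  oog <- 0L
  for (fr in pt$ensemble$frames[21:40]) {
    for (p in 1:10) {
      ijk <- floor((fr[np + p, ] - spec$origin) / spec$spacing) + 1
      if (any(ijk < 1) || any(ijk > spec$shape)) oog <- oog + 1L
      else oracle[ijk[1], ijk[2], ijk[3]] <- oracle[ijk[1], ijk[2], ijk[3]] + 1L
    }
  }
  expect_equal(g$counts[[1]], oracle)
  expect_equal(g$out_of_grid[[1]], oog)
})

test_that("uniform probes produce no hotspot at a 0.2 fraction threshold", {
  pocket <- acidic_pocket_protein()
  pt <- make_probe_trajectory(pocket$protein, pocket$site, enrichment = 0,
                              n_probes = 20, n_frames = 100, seed = 13)
  spec <- grid_spec_for(pocket$protein, spacing = 1, margin = 10)
  g <- accumulate_occupancy(pt$ensemble, pt$probe_groups, spec)
  expect_equal(nrow(hotspot_sites(g, pocket$protein, min_fraction = 0.2)), 0)
})

test_that("a planted cluster is recovered with its acidic flanking residues", {
  pocket <- acidic_pocket_protein()
  pt <- make_probe_trajectory(pocket$protein, pocket$site, enrichment = 0.3,
                              n_probes = 20, n_frames = 200, seed = 41)
  spec <- grid_spec_for(pocket$protein, spacing = 1, margin = 12)
  g <- accumulate_occupancy(pt$ensemble, pt$probe_groups, spec)
  hs <- hotspot_sites(g, pocket$protein, report_radius = 6,
                      min_fraction = 0.005)
  expect_gt(nrow(hs), 0)
  top <- hs[1, ]
  expect_lt(sqrt(sum((c(top$x, top$y, top$z) - pocket$site)^2)), 2)
  expect_true(grepl("ASP21", top$flanking_residues) &&
                grepl("ASP22", top$flanking_residues))
})

test_that("two planted clusters rank by peak fraction", {
  pocket <- acidic_pocket_protein()
  siteB <- pocket$site + c(-20, 0, 0)
  strong <- make_probe_trajectory(pocket$protein, pocket$site,
                                  enrichment = 0.5, n_probes = 10,
                                  n_frames = 100, seed = 3)
  weak <- make_probe_trajectory(pocket$protein, siteB, enrichment = 0.15,
                                n_probes = 10, n_frames = 100, seed = 4)
  # merge the two probe populations into one topology/trajectory
  np <- n_atoms(pocket$protein)
  topo <- Structure(rbind(strong$ensemble$topology$atoms,
                          transform(weak$ensemble$topology$atoms[np + 1:10, ],
                                    serial = np + 11:20, resseq = 11:20)))
  frames <- Map(function(a, b) rbind(a, b[np + 1:10, , drop = FALSE]),
                strong$ensemble$frames, weak$ensemble$frames)
  ens <- Ensemble(topo, frames)
  groups <- list(eta = lapply(1:20, function(p) np + p))
  spec <- grid_spec_for(pocket$protein, spacing = 1, margin = 25)
  g <- accumulate_occupancy(ens, groups, spec)
  hs <- hotspot_sites(g, pocket$protein, min_fraction = 0.004)
  expect_gte(nrow(hs), 2)
  expect_true(all(diff(hs$peak_fraction) <= 0))
  expect_lt(sqrt(sum((c(hs$x[1], hs$y[1], hs$z[1]) - pocket$site)^2)), 2.5)
})

test_that("coarsening the grid does not split a planted cluster", {
  pocket <- acidic_pocket_protein()
  pt <- make_probe_trajectory(pocket$protein, pocket$site, enrichment = 0.4,
                              n_probes = 20, n_frames = 100, seed = 8)
  for (sp in c(1, 2)) {
    spec <- grid_spec_for(pocket$protein, spacing = sp, margin = 12)
    g <- accumulate_occupancy(pt$ensemble, pt$probe_groups, spec)
    hs <- hotspot_sites(g, pocket$protein, min_fraction = 0.01)
    near <- hs[sqrt((hs$x - pocket$site[1])^2 + (hs$y - pocket$site[2])^2 +
                      (hs$z - pocket$site[3])^2) < 2 * sp + 1, ]
    expect_equal(nrow(near), 1)
  }
})
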