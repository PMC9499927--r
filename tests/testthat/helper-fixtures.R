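# Shared fixture builders and independent brute-force oracles.

# minimal atom row / structure constructors -------------------------------

atom_row <- function(serial, name, resname, chain, resseq, x, y, z,
                     element = substr(name, 1, 1), occupancy = 1,
                     altloc = "", het = FALSE) {
  data.frame(serial = serial, name = name, altloc = altloc,
             resname = resname, chain = chain, resseq = resseq, icode = "",
             x = x, y = y, z = z, occupancy = occupancy, bfactor = 0,
             element = element, het = het, vdw = NA_real_, polar = NA,
             hydrogen = NA, stringsAsFactors = FALSE)
}

# chain of single-CA pseudo-residues at given coordinates
ca_chain <- function(chain, xyz, resname = "ALA", serial0 = 0L) {
  do.call(rbind, lapply(seq_len(nrow(xyz)), function(i)
    atom_row(serial0 + i, "CA", resname, chain, i,
             xyz[i, 1], xyz[i, 2], xyz[i, 3], element = "C")))
}

random_ca_structure <- function(n, chain = "A", scale = 20) {
  Structure(ca_chain(chain, matrix(stats::runif(3 * n, 0, scale), n, 3)))
}

helical_torsions <- function(n) {
  matrix(rep(c(-60, -45, 180), n), n, 3, byrow = TRUE)
}

# receptor(A, 100 CA) + ligand(L, 50 CA) complex used by stability tests
noise_complex <- function(seed = 1) {
  set.seed(seed)
  Structure(rbind(
    ca_chain("A", matrix(stats::runif(300, 0, 30), 100, 3)),
    ca_chain("L", matrix(stats::runif(150, 0, 15) + 40, 50, 3),
             serial0 = 100L)))
}

# toy protein with two acidic residues flanking a known pocket site
acidic_pocket_protein <- function() {
  set.seed(99)
  body <- ca_chain("A", matrix(stats::runif(60, 0, 30), 20, 3))
  asp <- rbind(
    atom_row(21, "CA", "ASP", "A", 21, 33, 15, 15, element = "C"),
    atom_row(22, "CA", "ASP", "A", 22, 36, 15, 18, element = "C"))
  list(protein = Structure(rbind(body, asp)), site = c(34.5, 15, 16.5),
       acidic = c(21L, 22L))
}

# brute-force oracles ------------------------------------------------------

# O(n^2) per-atom-pair residue contact scan, independent of find_contacts
oracle_contacts <- function(structure, rec_chains, par_chains, cutoff,
                            heavy_only = TRUE) {
  at <- structure$atoms
  if (heavy_only) at <- at[toupper(at$element) != "H", , drop = FALSE]
  ri <- which(at$chain %in% rec_chains)
  pj <- which(at$chain %in% par_chains)
  pairs <- character()
  for (i in ri) for (j in pj) {
    d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                (at$z[i] - at$z[j])^2)
    if (d <= cutoff)
      pairs <- c(pairs, paste(at$chain[i], at$resseq[i], "-",
                              at$chain[j], at$resseq[j]))
  }
  sort(unique(pairs))
}

contact_keys <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(unique(paste(df$receptor_chain, df$receptor_resseq, "-",
                    df$partner_chain, df$partner_resseq)))
}

# Monte-Carlo union-of-spheres surface integration (random directions),
# independent of the deterministic golden-spiral lattice
oracle_sasa_mc <- function(structure, probe = 1.4, n_samples = 1e5,
                           seed = 1234) {
  set.seed(seed)
  at <- structure$atoms
  xyz <- coords(structure)
  rr <- at$vdw + probe
  total <- 0
  for (i in seq_len(nrow(at))) {
    u <- matrix(stats::rnorm(3 * n_samples), n_samples, 3)
    u <- u / sqrt(rowSums(u^2))
    p <- u * rr[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_samples)
    for (j in seq_len(nrow(at))) {
      if (j == i) next
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & d2 >= rr[j]^2
    }
    total <- total + 4 * pi * rr[i]^2 * mean(acc)
  }
  total
}

# random annotated atom cluster for SASA tests
random_cluster <- function(n = 20, scale = 6, seed = 1) {
  set.seed(seed)
  els <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
  at <- do.call(rbind, lapply(seq_len(n), function(i)
    atom_row(i, els[i], "UNK", "A", i, stats::runif(1, 0, scale),
             stats::runif(1, 0, scale), stats::runif(1, 0, scale),
             element = els[i])))
  annotate(Structure(at))
}

wrap_diff <- function(a, b) (a - b + 180) %% 360 - 180

random_rigid_transform <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(rotation = R, translation = stats::rnorm(3, 0, 10))
}
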