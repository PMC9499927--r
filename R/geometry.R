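# ---------------------------------------------------------------------------
# Geometric kernels: dihedrals, backbone torsions, Kabsch superposition, RMSD
# ---------------------------------------------------------------------------

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking down the p2-p3 axis, the angle from the
#' p1-p2 bond projection to the p3-p4 bond projection, positive clockwise;
#' cis = 0, trans = 180.  Returned in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, Angstrom.
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sum(b2^2) == 0) stop("dihedral: p2 and p3 coincide")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9)
    stop("dihedral: collinear points, angle undefined")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}

#' Backbone phi/psi/omega torsions for one chain
#'
#' One record per residue.  phi(i) = C(i-1)-N(i)-CA(i)-C(i);
#' psi(i) = N(i)-CA(i)-C(i)-N(i+1); omega(i) = CA(i)-C(i)-N(i+1)-CA(i+1)
#' (the torsion of the peptide bond joining residue i to i+1, assigned to
#' residue i).  Chain-initial phi and chain-final psi/omega, and any angle
#' with a missing defining atom, are `NA`.
#'
#' @param structure a `Structure`.
#' @param chain_id chain identifier.
#' @return data.frame with columns chain, resseq, resname, phi, psi, omega
#'   (degrees).
#' @export
backbone_torsions <- function(structure, chain_id) {
  at <- structure$atoms
  at <- at[at$chain == chain_id, , drop = FALSE]
  if (!nrow(at)) stop("chain '", chain_id, "' not present")
  reskey <- paste(at$resseq, at$icode)
  resids <- unique(reskey)
  n <- length(resids)
  get_atom <- function(i, nm) {
    j <- which(reskey == resids[i] & at$name == nm)
    if (!length(j)) return(NULL)
    c(at$x[j[1]], at$y[j[1]], at$z[j[1]])
  }
  res_of <- function(i) {
    j <- which(reskey == resids[i])[1]
    list(resseq = at$resseq[j], resname = at$resname[j])
  }
  safe_dihedral <- function(a, b, c_, d) {
    if (is.null(a) || is.null(b) || is.null(c_) || is.null(d)) return(NA_real_)
    tryCatch(dihedral(a, b, c_, d), error = function(e) NA_real_)
  }
  out <- data.frame(chain = rep(chain_id, n), resseq = integer(n),
                    resname = character(n), phi = NA_real_, psi = NA_real_,
                    omega = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    info <- res_of(i)
    out$resseq[i] <- info$resseq
    out$resname[i] <- info$resname
    N <- get_atom(i, "N"); CA <- get_atom(i, "CA"); C <- get_atom(i, "C")
    if (i > 1) out$phi[i] <- safe_dihedral(get_atom(i - 1, "C"), N, CA, C)
    if (i < n) {
      N2 <- get_atom(i + 1, "N"); CA2 <- get_atom(i + 1, "CA")
      out$psi[i] <- safe_dihedral(N, CA, C, N2)
      out$omega[i] <- safe_dihedral(CA, C, N2, CA2)
    }
  }
  out
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimising the RMSD of
#' `mobile %*% t(R) + t` against `reference` under positional
#' correspondence.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3.
#' @return list with `rotation` (3 x 3, det +1), `translation` (3-vector),
#'   and `rmsd` (post-fit, Angstrom).
#' @export
superpose <- function(mobile, reference) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3, ncol(reference) == 3)
  if (nrow(mobile) != nrow(reference)) stop("atom counts differ")
  if (nrow(mobile) < 3) stop("need at least 3 atoms to superpose")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  if (qr(Q)$rank < 2) stop("degenerate (collinear) reference")
  H <- crossprod(P, Q)              # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  Rm <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tv <- as.numeric(cr - Rm %*% cm)
  fitted <- t(Rm %*% t(mobile)) + matrix(tv, nrow(mobile), 3, byrow = TRUE)
  list(rotation = Rm, translation = tv,
       rmsd = rmsd(fitted, reference, fit = FALSE))
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param transform list with `rotation` and `translation` as returned by
#'   [superpose()].
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  t(transform$rotation %*% t(xyz)) +
    matrix(transform$translation, nrow(xyz), 3, byrow = TRUE)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param A,B n x 3 coordinate matrices with positional correspondence.
#' @param fit if `TRUE`, superpose first (Kabsch) and report the post-fit
#'   value; if `FALSE` (default) the raw deviation.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(A, B, fit = FALSE) {
  stopifnot(is.matrix(A), is.matrix(B), ncol(A) == 3, ncol(B) == 3)
  if (nrow(A) != nrow(B)) stop("coordinate shapes differ")
  if (nrow(A) == 0) stop("empty coordinate set")
  if (fit) return(superpose(A, B)$rmsd)
  sqrt(mean(rowSums((A - B)^2)))
}
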