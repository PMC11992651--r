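#' @title Geometry metrics
#' @description Loop distances, Kabsch superposition, RMSD/RMSF, backbone
#'   torsions, Ramachandran secondary-structure classification, and the
#'   Loop 2 vs Loop 1 regression.
#' @name geometry-metrics
NULL

.find_atom <- function(atoms, chain, resno, name) {
  j <- which(atoms$chain == chain & atoms$resno == resno & atoms$name == name)
  if (length(j) == 0) {
    stop(sprintf("residue %s:%d has no %s atom", chain, resno, name),
         call. = FALSE)
  }
  j[1]
}

#' Per-frame C-alpha pair distance
#'
#' Euclidean CA-CA distance in every frame, computed frame-internally (no
#' superposition: the two atoms live in the same frame). This is the Loop 1
#' (residues 46-71) / Loop 2 (residues 67-78) metric.
#'
#' @param trajectory an `md_trajectory`.
#' @param resA,resB residue specifications, each `list(chain=, resno=)` or a
#'   bare residue number (chain taken as the topology's first chain).
#' @return numeric vector, Angstrom per frame, with attribute `times`.
#' @export
pair_distance_series <- function(trajectory, resA, resB) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  a <- trajectory$topology$atoms
  norm_res <- function(r) {
    if (is.list(r)) r else list(chain = a$chain[1], resno = r)
  }
  resA <- norm_res(resA); resB <- norm_res(resB)
  iA <- .find_atom(a, resA$chain, resA$resno, "CA")
  iB <- .find_atom(a, resB$chain, resB$resno, "CA")
  d <- sqrt(rowSums((trajectory$coords[, iA, , drop = FALSE] -
                       trajectory$coords[, iB, , drop = FALSE])^2, dims = 1))
  d <- as.numeric(d)
  attr(d, "times") <- trajectory$times
  d
}

#' Kabsch least-squares rigid superposition
#'
#' Optimal proper rotation and translation minimising the (weighted) sum of
#' squared deviations of `mobile` onto `reference`, via SVD of the
#' cross-covariance matrix with reflection correction (det = +1).
#'
#' @param mobile n x 3 coordinate matrix.
#' @param reference n x 3 coordinate matrix (same point count, >= 3
#'   non-collinear points).
#' @param weights optional non-negative per-point weights (default uniform).
#' @return list with `rotation` (3 x 3, to be applied on the right:
#'   `x %*% rotation`), `translation` (length-3), `transformed`
#'   (`mobile %*% rotation + translation`), and `rmsd` after fitting.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("point counts differ", call. = FALSE)
  if (n < 3) stop("at least 3 points are required", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  M <- sweep(mobile, 2, cm); R <- sweep(reference, 2, cr)
  H <- t(M * w) %*% R
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300)) {
    stop("degenerate point set (collinear or coincident); superposition undefined",
         call. = FALSE)
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  rot <- sv$u %*% D %*% t(sv$v)
  trans <- cr - as.numeric(cm %*% rot)
  transformed <- mobile %*% rot + matrix(trans, n, 3, byrow = TRUE)
  rmsd <- sqrt(sum(w * rowSums((transformed - reference)^2)))
  list(rotation = rot, translation = trans, transformed = transformed,
       rmsd = rmsd)
}

.selection_ca <- function(structure, selection) {
  # selection: data.frame(chain, resno) or NULL = all residues with CA
  a <- structure$atoms
  if (is.null(selection)) {
    ca <- which(a$name == "CA")
    if (length(ca) == 0) stop("structure has no CA atoms", call. = FALSE)
    return(ca)
  }
  if (nrow(selection) == 0) stop("empty selection", call. = FALSE)
  vapply(seq_len(nrow(selection)), function(i)
    .find_atom(a, selection$chain[i], selection$resno[i], "CA"), integer(1))
}

#' Per-frame C-alpha RMSD against a reference structure
#'
#' Root-mean-square deviation of the selected CA atoms in every frame,
#' after an optional least-squares Kabsch fit of the frame onto the
#' reference (the default, matching standard MD convergence analysis against
#' the energy-minimised starting structure).
#'
#' @param trajectory an `md_trajectory`.
#' @param reference a `pdb_structure`; defaults to the trajectory topology.
#' @param selection residue table (chain, resno) or NULL for all CA atoms.
#' @param superpose fit each frame onto the reference first (default TRUE).
#' @return numeric vector, Angstrom per frame, with attribute `times`.
#' @export
rmsd_series <- function(trajectory, reference = NULL, selection = NULL,
                        superpose = TRUE) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  if (is.null(reference)) reference <- trajectory$topology
  idx_t <- .selection_ca(trajectory$topology, selection)
  idx_r <- .selection_ca(reference, selection)
  if (length(idx_t) != length(idx_r)) {
    stop("selection resolves to different atom counts in trajectory and reference",
         call. = FALSE)
  }
  ref <- as.matrix(reference$atoms[idx_r, c("x", "y", "z")])
  n_frames <- dim(trajectory$coords)[1]
  out <- vapply(seq_len(n_frames), function(t) {
    x <- trajectory$coords[t, idx_t, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, ncol = 3)
    if (superpose) {
      kabsch_superpose(x, ref)$rmsd
    } else {
      sqrt(mean(rowSums((x - ref)^2)))
    }
  }, numeric(1))
  attr(out, "times") <- trajectory$times
  out
}

#' Per-residue C-alpha RMSF about a reference structure
#'
#' For each selected residue, the root-mean-square fluctuation
#' sqrt(mean over frames of |x_i(t) - x_i(ref)|^2), computed after fitting
#' each frame's selection onto the reference by Kabsch superposition. The
#' fluctuation is taken about the supplied reference structure (e.g. the
#' energy-minimised starting structure); set `about = "mean"` for the common
#' alternative of fluctuation about the trajectory mean after fitting.
#'
#' @inheritParams rmsd_series
#' @param about `"reference"` (default) or `"mean"`.
#' @return named numeric vector, Angstrom per residue.
#' @export
rmsf_profile <- function(trajectory, reference = NULL, selection = NULL,
                         about = c("reference", "mean")) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  about <- match.arg(about)
  if (is.null(reference)) reference <- trajectory$topology
  idx_t <- .selection_ca(trajectory$topology, selection)
  idx_r <- .selection_ca(reference, selection)
  ref <- as.matrix(reference$atoms[idx_r, c("x", "y", "z")])
  n_frames <- dim(trajectory$coords)[1]
  fitted <- array(NA_real_, dim = c(n_frames, length(idx_t), 3))
  for (t in seq_len(n_frames)) {
    x <- trajectory$coords[t, idx_t, , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, ncol = 3)
    fitted[t, , ] <- kabsch_superpose(x, ref)$transformed
  }
  centre <- if (about == "reference") ref else apply(fitted, c(2, 3), mean)
  dev2 <- vapply(seq_along(idx_t), function(i) {
    di <- matrix(fitted[, i, ], ncol = 3)
    di <- sweep(di, 2, centre[i, ])
    mean(rowSums(di^2))
  }, numeric(1))
  out <- sqrt(dev2)
  names(out) <- paste0(trajectory$topology$atoms$chain[idx_t],
                       trajectory$topology$atoms$resno[idx_t])
  out
}

#' Signed dihedral (torsion) angle of four points
#'
#' IUPAC sign convention (right-handed positive), range (-180, 180], with the
#' trans arrangement at 180 degrees, via the standard atan2 construction.
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop("undefined dihedral: consecutive points are collinear or coincident",
         call. = FALSE)
  }
  x <- sum(n1 * n2)
  y <- sum(cross(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi angles per residue and frame
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1). Chain
#' termini, and residues missing backbone atoms, yield NA with a per-residue
#' report attached as attribute `"report"`.
#'
#' @param trajectory an `md_trajectory`.
#' @param chain chain id (default: first chain in the topology).
#' @return data frame with columns frame, time_ns, chain, resno, phi, psi.
#' @export
phi_psi_series <- function(trajectory, chain = NULL) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  a <- trajectory$topology$atoms
  if (is.null(chain)) chain <- a$chain[1]
  resno <- sort(unique(a$resno[a$chain == chain]))
  if (length(resno) == 0) stop(sprintf("no residues in chain '%s'", chain),
                               call. = FALSE)
  idx_of <- function(rn, nm) {
    j <- which(a$chain == chain & a$resno == rn & a$name == nm)
    if (length(j)) j[1] else NA_integer_
  }
  bb <- data.frame(resno = resno,
                   N = vapply(resno, idx_of, integer(1), nm = "N"),
                   CA = vapply(resno, idx_of, integer(1), nm = "CA"),
                   C = vapply(resno, idx_of, integer(1), nm = "C"))
  n_frames <- dim(trajectory$coords)[1]
  report <- character(0)
  rows <- vector("list", length(resno))
  for (k in seq_along(resno)) {
    prevC <- if (k > 1) bb$C[k - 1] else NA_integer_
    nextN <- if (k < length(resno)) bb$N[k + 1] else NA_integer_
    phi_ok <- !anyNA(c(prevC, bb$N[k], bb$CA[k], bb$C[k]))
    psi_ok <- !anyNA(c(bb$N[k], bb$CA[k], bb$C[k], nextN))
    if (!phi_ok || !psi_ok) {
      why <- if (anyNA(bb[k, c("N", "CA", "C")])) "missing backbone atom"
      else "chain terminus"
      report <- c(report, sprintf("%s:%d %s (phi %s, psi %s)", chain, resno[k],
                                  why, ifelse(phi_ok, "ok", "absent"),
                                  ifelse(psi_ok, "ok", "absent")))
    }
    phi <- psi <- rep(NA_real_, n_frames)
    for (t in seq_len(n_frames)) {
      pt <- function(i) trajectory$coords[t, i, ]
      if (phi_ok) phi[t] <- dihedral(pt(prevC), pt(bb$N[k]), pt(bb$CA[k]), pt(bb$C[k]))
      if (psi_ok) psi[t] <- dihedral(pt(bb$N[k]), pt(bb$CA[k]), pt(bb$C[k]), pt(nextN))
    }
    rows[[k]] <- data.frame(frame = seq_len(n_frames),
                            time_ns = trajectory$times, chain = chain,
                            resno = resno[k], phi = phi, psi = psi,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$frame, out$resno), ]
  rownames(out) <- NULL
  attr(out, "report") <- report
  out
}

#' Classify a (phi, psi) pair into a secondary-structure motif
#'
#' Rectangular Ramachandran regions, chosen to contain the canonical motif
#' angles with generous margins while staying pairwise disjoint:
#' right-handed helix phi in \[-100, -30), psi in \[-80, -5);
#' left-handed helix phi in (30, 100\], psi in (5, 80\];
#' beta phi in \[-180, -45), psi in \[90, 180\] or \[-180, -150);
#' everything else is `"other"`. Vectorised over inputs.
#'
#' @param phi,psi angles in degrees, range (-180, 180].
#' @return character vector in `c("beta", "rh_helix", "lh_helix", "other")`;
#'   NA input yields NA.
#' @export
classify_ss <- function(phi, psi) {
  out <- rep(NA_character_, length(phi))
  ok <- !is.na(phi) & !is.na(psi)
  p <- phi[ok]; s <- psi[ok]
  lab <- rep("other", length(p))
  lab[p >= -100 & p < -30 & s >= -80 & s < -5] <- "rh_helix"
  lab[p > 30 & p <= 100 & s > 5 & s <= 80] <- "lh_helix"
  lab[p >= -180 & p < -45 & ((s >= 90 & s <= 180) | (s >= -180 & s < -150))] <- "beta"
  out[ok] <- lab
  out
}

#' Count region residues per secondary-structure motif, per frame
#'
#' For each frame, counts how many residues of `region` fall in each motif
#' class; also reports the window mean ("true average") per motif.
#'
#' @param angles data frame from [phi_psi_series()] (columns frame, time_ns,
#'   chain, resno, phi, psi).
#' @param region residue table (chain, resno) restricting the count, or NULL
#'   for all residues present.
#' @return data frame with columns frame, time_ns, beta, rh_helix, lh_helix
#'   and attribute `window_mean` (named means over frames); class
#'   `ss_counts`.
#' @export
count_ss_residues <- function(angles, region = NULL) {
  stopifnot(all(c("frame", "time_ns", "resno", "phi", "psi") %in% names(angles)))
  if (!is.null(region)) {
    keep <- paste(angles$chain, angles$resno) %in%
      paste(region$chain, region$resno)
    if (!any(keep)) {
      warning("region does not overlap the angle table", call. = FALSE)
    }
    angles <- angles[keep, , drop = FALSE]
  }
  motifs <- c("beta", "rh_helix", "lh_helix")
  if (nrow(angles) == 0) {
    out <- data.frame(frame = integer(0), time_ns = numeric(0),
                      beta = integer(0), rh_helix = integer(0),
                      lh_helix = integer(0))
    attr(out, "window_mean") <- stats::setNames(rep(NaN, 3), motifs)
    class(out) <- c("ss_counts", class(out))
    return(out)
  }
  angles$motif <- classify_ss(angles$phi, angles$psi)
  frames <- sort(unique(angles$frame))
  counts <- vapply(frames, function(f) {
    m <- angles$motif[angles$frame == f]
    vapply(motifs, function(mo) sum(m == mo, na.rm = TRUE), integer(1))
  }, integer(3))
  out <- data.frame(frame = frames,
                    time_ns = angles$time_ns[match(frames, angles$frame)],
                    beta = counts["beta", ], rh_helix = counts["rh_helix", ],
                    lh_helix = counts["lh_helix", ])
  attr(out, "window_mean") <- colMeans(out[, motifs, drop = FALSE])
  class(out) <- c("ss_counts", class(out))
  out
}

#' Ordinary least-squares line fit (Loop 2 vs Loop 1)
#'
#' OLS with intercept; r-squared = 1 - SS_res/SS_tot, with the degenerate
#' constant-response case defined as r-squared = 0.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
fit_linear <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::var(x) == 0) {
    stop("undefined slope: predictor has zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, n = length(x))
}
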