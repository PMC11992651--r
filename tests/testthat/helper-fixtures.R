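# Fixture builders and independent oracles used across the test files.
# Oracles deliberately avoid the code paths they check.

# ---- structure fixtures -----------------------------------------------------

# Build a pdb_structure directly from a coordinate table.
make_structure <- function(resno, xyz, name = "CA", chain = "A",
                           resname = "ALA", element = "C") {
  xyz <- as.matrix(xyz)
  n <- length(resno) * length(name) / length(resno) # atoms per call
  df <- data.frame(
    serial = seq_len(nrow(xyz)),
    name = rep_len(name, nrow(xyz)),
    resname = rep_len(resname, nrow(xyz)),
    chain = rep_len(chain, nrow(xyz)),
    resno = rep_len(resno, nrow(xyz)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = rep_len(element, nrow(xyz)),
    is_heavy = rep_len(element, nrow(xyz)) != "H",
    stringsAsFactors = FALSE
  )
  trem2flex:::.new_structure(df)
}

# Trajectory from a list of n_atoms x 3 coordinate matrices.
make_trajectory <- function(topology, frames, dt = 0.5, t0 = 0) {
  coords <- array(NA_real_, dim = c(length(frames), nrow(topology$atoms), 3))
  for (i in seq_along(frames)) coords[i, , ] <- as.matrix(frames[[i]])
  trem2flex:::.new_trajectory(topology, coords,
                              times = t0 + dt * (seq_along(frames) - 1))
}

# CA-only chain with the given residue numbers laid out on a jittered line,
# numbered like the TREM2 Ig domain.
make_trem2_like <- function(resno = 19:131, seed = 42) {
  set.seed(seed)
  xyz <- cbind(3.8 * seq_along(resno) + rnorm(length(resno), 0, 0.2),
               rnorm(length(resno), 0, 1.5),
               rnorm(length(resno), 0, 1.5))
  make_structure(resno, xyz)
}

# ---- ideal backbone construction (NeRF internal-coordinate chain) -----------

.unit <- function(v) v / sqrt(sum(v^2))
.cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

# Place atom D given A-B-C, bond length r (C-D), bond angle theta (B-C-D, deg)
# and torsion tau (A-B-C-D, deg).
place_atom <- function(A, B, C, r, theta_deg, tau_deg) {
  th <- theta_deg * pi / 180
  ta <- tau_deg * pi / 180
  bc <- .unit(C - B)
  n <- .unit(.cross3(B - A, bc))
  m <- .cross3(n, bc)
  C + r * (-cos(th) * bc + sin(th) * (cos(ta) * m + sin(ta) * n))
}

# Ideal N-CA-C backbone with constant (phi, psi), omega = 180. Returns a
# pdb_structure with backbone atoms for n_res residues (chain "A", resno 1..n).
build_backbone <- function(phi, psi, n_res, chain = "A") {
  b_NCa <- 1.458; b_CaC <- 1.525; b_CN <- 1.329
  a_NCaC <- 111.2; a_CaCN <- 116.2; a_CNCa <- 121.7
  coords <- list()
  N <- c(0, 0, 0); CA <- c(b_NCa, 0, 0)
  C <- place_atom(c(0, 1, 0), N, CA, b_CaC, a_NCaC, 60) # arbitrary start frame
  coords[[1]] <- rbind(N = N, CA = CA, C = C)
  for (i in seq_len(n_res - 1) + 1) {
    prev <- coords[[i - 1]]
    Nn <- place_atom(prev["N", ], prev["CA", ], prev["C", ], b_CN, a_CaCN, psi)
    CAn <- place_atom(prev["CA", ], prev["C", ], Nn, b_NCa, a_CNCa, 180)
    Cn <- place_atom(prev["C", ], Nn, CAn, b_CaC, a_NCaC, phi)
    coords[[i]] <- rbind(N = Nn, CA = CAn, C = Cn)
  }
  xyz <- do.call(rbind, coords)
  make_structure(resno = rep(seq_len(n_res), each = 3), xyz,
                 name = rep(c("N", "CA", "C"), n_res), chain = chain,
                 element = rep(c("N", "C", "C"), n_res))
}

# ---- independent geometric oracles ------------------------------------------

quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Brute-force minimum RMSD over proper rotations: quaternion multistart plus
# Nelder-Mead refinement. Independent of the SVD route.
brute_force_min_rmsd <- function(mobile, reference, n_starts = 12) {
  M <- sweep(mobile, 2, colMeans(mobile))
  R <- sweep(reference, 2, colMeans(reference))
  obj <- function(q) {
    Q <- quat_to_mat(q)
    sqrt(mean(rowSums((M %*% t(Q) - R)^2)))
  }
  starts <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1),
                  matrix(rnorm(4 * n_starts), ncol = 4))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (fit$value < best) best <- fit$value
  }
  best
}

# Exhaustive all-atom-pairs contact search between two structures.
brute_force_contacts <- function(structA, structB, cutoff,
                                 heavy_only = TRUE) {
  aA <- structA$atoms; aB <- structB$atoms
  if (heavy_only) { aA <- aA[aA$is_heavy, ]; aB <- aB[aB$is_heavy, ] }
  hits <- character(0)
  for (i in seq_len(nrow(aA))) {
    for (j in seq_len(nrow(aB))) {
      d <- sqrt((aA$x[i] - aB$x[j])^2 + (aA$y[i] - aB$y[j])^2 +
                  (aA$z[i] - aB$z[j])^2)
      if (d <= cutoff) {
        hits <- c(hits, paste0(aA$chain[i], ":", aA$resno[i], "|",
                               aB$chain[j], ":", aB$resno[j]))
      }
    }
  }
  sort(unique(hits))
}

# Residue-pair keys of a contacts() table (empty-safe: paste0 would recycle
# a zero-length column against the separator).
contact_keys <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste0(df$resA, "|", df$resB))
}

# ---- text PDB fixture -------------------------------------------------------

pdb_three_ca_lines <- function() {
  c("ATOM      1  CA  ALA A   1       0.000   0.000   0.000           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000           C",
    "ATOM      3  CA  SER A   3       7.600   0.000   0.000           C")
}
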