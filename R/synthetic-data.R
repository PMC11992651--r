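#' @title Synthetic-data generators
#' @description Generators that emulate the statistical structure of the MD
#'   observables the pipeline consumes: two-state (open/closed) loop dynamics
#'   with Gaussian jitter, cluster-structured interaction-energy tables,
#'   docked poses with a controlled interface-contact fraction, and
#'   Ramachandran angle sets. Every generator is a pure function of its
#'   parameters and seed and leaves the global RNG state untouched.
#' @name synthetic-data
NULL

# Run `expr` under a private RNG stream seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Parameters for the two-state loop-dynamics generator
#'
#' @param mu_closed mean anchor distance in the closed state, Angstrom.
#' @param mu_open mean anchor distance in the open state, Angstrom; must
#'   exceed `mu_closed`.
#' @param sigma Gaussian jitter SD around the state mean, Angstrom.
#' @param switch_prob per-frame probability of switching state (symmetric
#'   two-state Markov chain).
#' @param n_frames number of frames (>= 2).
#' @param dt frame spacing, ns.
#' @param seed RNG seed.
#' @return a `loop_dynamics_params` list.
#' @export
loop_dynamics_params <- function(mu_closed = 14, mu_open = 22, sigma = 0.8,
                                 switch_prob = 0.02, n_frames = 1000,
                                 dt = 0.5, seed = 1) {
  if (!(mu_open > mu_closed)) stop("mu_open must exceed mu_closed", call. = FALSE)
  if (!(sigma > 0)) stop("sigma must be positive", call. = FALSE)
  if (switch_prob < 0 || switch_prob > 1) {
    stop("switch_prob must lie in [0, 1]", call. = FALSE)
  }
  if (n_frames < 2) stop("n_frames must be at least 2", call. = FALSE)
  structure(list(mu_closed = mu_closed, mu_open = mu_open, sigma = sigma,
                 switch_prob = switch_prob, n_frames = as.integer(n_frames),
                 dt = dt, seed = as.integer(seed)),
            class = "loop_dynamics_params")
}

# Toy CA-only protein: a 20-residue rigid core (resno 40-59, incl. anchor 46)
# and a 12-residue loop (resno 67-78, incl. anchor 71). Loop opening is a
# rigid translation of the loop along +x so that the 46-71 anchor distance
# equals the target exactly when jitter is added to the target, not the
# geometry.
.toy_topology <- function() {
  core_resno <- 40:59
  loop_resno <- 67:78
  # core: two staggered rows so the point set is non-degenerate
  core_xyz <- cbind(x = -seq_along(core_resno) * 3.8,
                    y = rep(c(0, 1.9), length.out = length(core_resno)),
                    z = rep(c(0, 0.8, 1.6, 0.8), length.out = length(core_resno)))
  # loop: arc in the xy plane, anchored so residue 71 sits on the +x axis
  th <- seq(-0.6, 0.6, length.out = length(loop_resno))
  loop_xyz <- cbind(x = 6 * cos(th), y = 6 * sin(th), z = 0.5 * seq_along(th))
  i71 <- which(loop_resno == 71)
  loop_xyz <- sweep(loop_xyz, 2, loop_xyz[i71, ]) # anchor at origin for now
  resno <- c(core_resno, loop_resno)
  resname <- rep("ALA", length(resno))
  resname[resno == 46] <- "ARG"; resname[resno == 67] <- "HIS"
  resname[resno == 71] <- "LEU"; resname[resno == 78] <- "TRP"
  atoms <- data.frame(
    serial = seq_along(resno), name = "CA", resname = resname,
    chain = "A", resno = resno,
    x = c(core_xyz[, 1], loop_xyz[, 1]),
    y = c(core_xyz[, 2], loop_xyz[, 2]),
    z = c(core_xyz[, 3], loop_xyz[, 3]),
    element = "C", is_heavy = TRUE, stringsAsFactors = FALSE
  )
  list(structure = .new_structure(atoms),
       anchor_idx = which(resno == 46),
       loop_idx = which(resno %in% 67:78),
       anchor_loop_idx = which(resno == 71))
}

#' Generate a two-state open/closed loop trajectory
#'
#' Builds a CA-only toy protein (20-residue rigid core, 12-residue loop
#' numbered 67-78 to mirror CDR2) whose Loop 1-style anchor distance
#' (residues 46 and 71) at frame t equals the hidden-state mean plus
#' N(0, sigma^2) jitter. The hidden state follows a symmetric two-state
#' Markov chain with per-frame switch probability `switch_prob`. Loop opening
#' is realised by rigidly translating the loop along a fixed unit vector, so
#' the anchor distance equals the target exactly.
#'
#' @param params a [loop_dynamics_params()] object.
#' @param start_state `"closed"` or `"open"` initial state.
#' @return list with `trajectory` (an `md_trajectory`), `states`
#'   (character vector, `"closed"`/`"open"` per frame), and `target_distance`
#'   (the per-frame anchor distance the geometry realises, Angstrom).
#' @export
generate_two_state_loop_trajectory <- function(params,
                                               start_state = c("closed", "open")) {
  stopifnot(inherits(params, "loop_dynamics_params"))
  start_state <- match.arg(start_state)
  topo <- .toy_topology()
  n <- params$n_frames
  dat <- .with_seed(params$seed, {
    switches <- stats::runif(n - 1) < params$switch_prob
    jitter <- stats::rnorm(n, 0, params$sigma)
    list(switches = switches, jitter = jitter)
  })
  state <- integer(n) # 0 closed, 1 open
  state[1] <- if (start_state == "open") 1L else 0L
  for (t in 2:n) state[t] <- if (dat$switches[t - 1]) 1L - state[t - 1] else state[t - 1]
  target <- ifelse(state == 1L, params$mu_open, params$mu_closed) + dat$jitter
  target <- pmax(target, 0.1) # distances stay physical
  atoms <- topo$structure$atoms
  base <- as.matrix(atoms[, c("x", "y", "z")])
  anchor <- base[topo$anchor_idx, ]
  # unit opening vector: +x from the core anchor
  u <- c(1, 0, 0)
  coords <- array(NA_real_, dim = c(n, nrow(atoms), 3))
  for (t in seq_len(n)) {
    fr <- base
    # place loop anchor at anchor + target * u; rest of loop rides along
    shift <- anchor + target[t] * u - base[topo$anchor_loop_idx, ]
    fr[topo$loop_idx, ] <- sweep(base[topo$loop_idx, , drop = FALSE], 2, -shift)
    coords[t, , ] <- fr
  }
  traj <- .new_trajectory(topo$structure, coords,
                          times = params$dt * (seq_len(n) - 1))
  list(trajectory = traj,
       states = ifelse(state == 1L, "open", "closed"),
       target_distance = target)
}

#' Generate an i.i.d. Gaussian loop-distance series
#'
#' Null model for the cluster-occupancy law: on N(mu, sigma^2) data the
#' A/B/C occupancies converge to the normal tail masses
#' (15.87/68.27/15.87 percent).
#'
#' @param mu mean distance, Angstrom.
#' @param sigma SD, Angstrom (> 0).
#' @param n number of values (> 0).
#' @param seed RNG seed.
#' @return numeric vector of length `n`.
#' @export
generate_gaussian_loop_series <- function(mu, sigma, n, seed = 1) {
  if (!(sigma > 0)) stop("sigma must be positive", call. = FALSE)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  .with_seed(seed, stats::rnorm(n, mu, sigma))
}

#' Parameters for the synthetic energy-table generator
#'
#' @param cluster_means named list/vector (`A`, `B`, `C`) of mean interaction
#'   energies, kcal/mol.
#' @param cluster_sds matching SDs (> 0), kcal/mol.
#' @param occupancies matching non-negative integer frame counts; their sum
#'   is the table length.
#' @param seed RNG seed.
#' @return an `energy_table_params` list.
#' @export
energy_table_params <- function(cluster_means = c(A = -20, B = -35, C = -28),
                                cluster_sds = c(A = 4, B = 4, C = 4),
                                occupancies = c(A = 16, B = 69, C = 16),
                                seed = 1) {
  lab <- c("A", "B", "C")
  stopifnot(all(lab %in% names(cluster_means)),
            all(lab %in% names(cluster_sds)),
            all(lab %in% names(occupancies)))
  occupancies <- occupancies[lab]
  if (any(occupancies < 0) || any(occupancies != round(occupancies))) {
    stop("occupancies must be non-negative integers", call. = FALSE)
  }
  if (sum(occupancies) == 0) stop("occupancies sum to zero", call. = FALSE)
  if (any(cluster_sds[lab] <= 0)) stop("cluster_sds must be positive", call. = FALSE)
  structure(list(cluster_means = unlist(cluster_means)[lab],
                 cluster_sds = unlist(cluster_sds)[lab],
                 occupancies = as.integer(occupancies),
                 seed = as.integer(seed)),
            class = "energy_table_params")
}

#' Generate a synthetic per-frame interaction-energy table
#'
#' For each cluster, `occupancies[cluster]` frames are drawn
#' N(mean, sd^2); each frame is paired with a Loop 1 distance constructed to
#' map back to that cluster under the supplied loop statistics (A strictly
#' above mean + sd, B within the closed band, C strictly below mean - sd).
#' Cluster blocks are interleaved by a seeded permutation and laid on the
#' analysis time grid starting at `t_start`.
#'
#' @param params an [energy_table_params()] object.
#' @param loop_stats list/vector with elements `mean` and `sd` (Angstrom): the
#'   pooled Loop 1 statistics that define the cluster thresholds.
#' @param complex_id label for the complex (default "synthetic").
#' @param variant TREM2 variant label.
#' @param isoform ApoE isoform label.
#' @param t_start first frame time, ns.
#' @param dt frame spacing, ns.
#' @return data frame with columns time_ns, complex_id, variant, isoform,
#'   energy, loop1, cluster_true.
#' @export
generate_energy_table <- function(params, loop_stats,
                                  complex_id = "synthetic",
                                  variant = "WT", isoform = "E3",
                                  t_start = 450, dt = 0.5) {
  stopifnot(inherits(params, "energy_table_params"))
  m <- loop_stats[["mean"]]; s <- loop_stats[["sd"]]
  stopifnot(is.finite(m), is.finite(s), s > 0)
  occ <- params$occupancies
  n <- sum(occ)
  lab <- rep(c("A", "B", "C"), times = occ)
  dat <- .with_seed(params$seed, {
    energy <- stats::rnorm(n, mean = rep(params$cluster_means, occ),
                           sd = rep(params$cluster_sds, occ))
    # loop1 values guaranteed to classify back into the generating cluster
    loop1 <- numeric(n)
    loop1[lab == "A"] <- m + s * (1 + stats::runif(sum(lab == "A"), 0.05, 1))
    loop1[lab == "B"] <- m + s * stats::runif(sum(lab == "B"), -0.95, 0.95)
    loop1[lab == "C"] <- m - s * (1 + stats::runif(sum(lab == "C"), 0.05, 1))
    ord <- sample.int(n)
    list(energy = energy[ord], loop1 = loop1[ord], lab = lab[ord])
  })
  data.frame(
    time_ns = t_start + dt * (seq_len(n) - 1),
    complex_id = complex_id, variant = variant, isoform = isoform,
    energy = dat$energy, loop1 = dat$loop1, cluster_true = dat$lab,
    stringsAsFactors = FALSE
  )
}

#' Generate a docked two-chain pose with a controlled contact fraction
#'
#' Builds a query chain (chain `"T"`, one pseudo-heavy atom per residue,
#' numbered over the TREM2 CDR residues) and a target chain (chain `"E"`,
#' hinge residues from 167 up) such that exactly `k_in_contact` query
#' residues have an atom within `cutoff` of the target chain and every other
#' query residue stays at least `cutoff + 2` Angstrom away from all target
#' atoms.
#'
#' @param n_query_residues number of query (CDR) residues (<= 26).
#' @param k_in_contact number of query residues placed in contact
#'   (0 <= k <= n).
#' @param cutoff contact cutoff, Angstrom.
#' @param seed RNG seed (chooses which residues are in contact).
#' @param n_target_residues number of target (hinge) residues.
#' @return list with `query` and `target` (`pdb_structure`s) and
#'   `contact_resno` (query residue numbers placed in contact).
#' @export
generate_complex_pose <- function(n_query_residues = 26, k_in_contact = 5,
                                  cutoff = 4.0, seed = 1,
                                  n_target_residues = max(24, n_query_residues)) {
  cdr_resno <- c(40:47, 67:78, 115:120)
  if (n_query_residues > length(cdr_resno)) {
    stop(sprintf("n_query_residues must be <= %d", length(cdr_resno)),
         call. = FALSE)
  }
  if (k_in_contact > n_query_residues) {
    stop("k_in_contact cannot exceed n_query_residues", call. = FALSE)
  }
  if (k_in_contact < 0) stop("k_in_contact must be non-negative", call. = FALSE)
  qres <- cdr_resno[seq_len(n_query_residues)]
  tres <- 167:(167 + n_target_residues - 1)
  spacing <- 8
  gap <- cutoff + 6 # baseline separation: comfortably out of contact
  contact_idx <- .with_seed(seed, sort(sample.int(n_query_residues, k_in_contact)))
  qy <- rep(0, n_query_residues)
  qy[contact_idx] <- gap - (cutoff - 1) # slide those residues to cutoff - 1
  query_atoms <- data.frame(
    serial = seq_len(n_query_residues), name = "CB", resname = "ALA",
    chain = "T", resno = qres,
    x = spacing * seq_len(n_query_residues), y = qy, z = 0,
    element = "C", is_heavy = TRUE, stringsAsFactors = FALSE
  )
  # target atoms sit directly opposite the query positions
  tx <- spacing * seq_len(n_target_residues)
  target_atoms <- data.frame(
    serial = seq_len(n_target_residues), name = "CB", resname = "GLY",
    chain = "E", resno = tres,
    x = tx, y = gap, z = 0,
    element = "C", is_heavy = TRUE, stringsAsFactors = FALSE
  )
  list(query = .new_structure(query_atoms),
       target = .new_structure(target_atoms),
       contact_resno = qres[contact_idx])
}

# canonical motif centres (phi, psi), degrees
.canonical_motifs <- function() {
  list(rh_helix = c(-57, -47), lh_helix = c(57, 47), beta = c(-120, 135))
}

#' Generate a labelled set of Ramachandran angle pairs
#'
#' Draws angle pairs at the canonical motif centres (right-handed helix
#' (-57, -47); left-handed helix (57, 47); beta (-120, 135)) plus uniform
#' jitter in both angles. Warns if the requested jitter can push a canonical
#' angle across the classification-region boundaries used by
#' [classify_ss()].
#'
#' @param composition named integer vector/list, motif -> count (names among
#'   `rh_helix`, `lh_helix`, `beta`).
#' @param jitter_deg half-width of the uniform jitter, degrees.
#' @param seed RNG seed.
#' @return data frame with columns phi, psi, motif_true.
#' @export
generate_phi_psi_set <- function(composition, jitter_deg = 0, seed = 1) {
  motifs <- .canonical_motifs()
  composition <- unlist(composition)
  if (!all(names(composition) %in% names(motifs))) {
    stop("composition names must be among: rh_helix, lh_helix, beta",
         call. = FALSE)
  }
  if (jitter_deg < 0) stop("jitter_deg must be non-negative", call. = FALSE)
  margins <- c(rh_helix = 27, lh_helix = 27, beta = 45) # to nearest boundary
  used <- names(composition)[composition > 0]
  if (length(used) && jitter_deg >= min(margins[used])) {
    warning("jitter_deg can cross a classification-region boundary",
            call. = FALSE)
  }
  n <- sum(composition)
  lab <- rep(names(composition), times = composition)
  centres <- do.call(rbind, motifs[lab])
  ang <- .with_seed(seed, {
    cbind(phi = centres[, 1] + stats::runif(n, -jitter_deg, jitter_deg),
          psi = centres[, 2] + stats::runif(n, -jitter_deg, jitter_deg))
  })
  data.frame(phi = ang[, "phi"], psi = ang[, "psi"], motif_true = lab,
             stringsAsFactors = FALSE)
}
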