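test_that("pair distances are frame-internal Euclidean CA-CA distances", {
  s <- make_structure(1:2, rbind(c(0, 0, 0), c(3, 4, 0)))
  traj <- make_trajectory(s, list(rbind(c(0, 0, 0), c(3, 4, 0)),
                                  rbind(c(1, 1, 1), c(1, 1, 1))))
  d <- pair_distance_series(traj, 1, 2)
  expect_equal(as.numeric(d), c(5, 0))

  # brute-force element-wise recomputation on a synthetic trajectory
  sim <- generate_two_state_loop_trajectory(
    loop_dynamics_params(n_frames = 100, seed = 12))
  traj2 <- sim$trajectory
  a <- traj2$topology$atoms
  i <- which(a$resno == 46 & a$name == "CA")
  j <- which(a$resno == 71 & a$name == "CA")
  brute <- sapply(seq_len(100), function(t)
    sqrt(sum((traj2$coords[t, i, ] - traj2$coords[t, j, ])^2)))
  expect_equal(as.numeric(pair_distance_series(traj2, 46, 71)), brute,
               tolerance = 1e-12)
})

test_that("Kabsch superposition recovers rigid transforms and is optimal", {
  set.seed(5)
  ref <- matrix(rnorm(18, sd = 5), 6, 3)
  # identity case
  fit <- kabsch_superpose(ref, ref)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(as.numeric(fit$translation), rep(0, 3), tolerance = 1e-10)
  expect_lt(fit$rmsd, 1e-12)
  # 90-degree rotation about z plus a shift is inverted exactly
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  mob <- ref %*% t(Rz) + matrix(c(3, -2, 7), 6, 3, byrow = TRUE)
  fit <- kabsch_superpose(mob, ref)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$transformed, ref, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # distorted point set: matches the quaternion brute-force minimum
  mob2 <- mob + matrix(rnorm(18, sd = 0.3), 6, 3)
  fit2 <- kabsch_superpose(mob2, ref)
  expect_equal(fit2$rmsd, brute_force_min_rmsd(mob2, ref), tolerance = 1e-6)
  # reflections are corrected: determinant +1 even for mirrored inputs
  mir <- ref %*% diag(c(-1, 1, 1))
  expect_equal(det(kabsch_superpose(mir, ref)$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "3 points")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("RMSD series honours the superposition contract", {
  s <- make_trem2_like(1:10)
  base <- as.matrix(s$atoms[, c("x", "y", "z")])
  traj_same <- make_trajectory(s, list(base, base, base))
  expect_true(all(rmsd_series(traj_same) < 1e-9))
  # rigidly rotated copies: zero with fitting, nonzero without
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rot <- base %*% t(Rz) + 5
  traj_rot <- make_trajectory(s, list(base, rot))
  expect_true(all(rmsd_series(traj_rot, superpose = TRUE) < 1e-9))
  expect_gt(rmsd_series(traj_rot, superpose = FALSE)[2], 1)
  # drifting trajectory matches the brute-force rotational minimum per frame
  set.seed(8)
  drift <- lapply(1:5, function(k) base + matrix(rnorm(30, sd = 0.5), 10, 3))
  traj_d <- make_trajectory(s, drift)
  r <- rmsd_series(traj_d)
  for (t in 1:5) {
    expect_equal(r[t], brute_force_min_rmsd(drift[[t]], base),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  # fitted RMSD is symmetric and never exceeds unfitted RMSD
  r_off <- rmsd_series(traj_d, superpose = FALSE)
  expect_true(all(r <= r_off + 1e-12))
  expect_equal(kabsch_superpose(drift[[2]], base)$rmsd,
               kabsch_superpose(base, drift[[2]])$rmsd, tolerance = 1e-9)
})

test_that("RMSF measures per-residue fluctuation about the reference", {
  s <- make_trem2_like(1:40)
  base <- as.matrix(s$atoms[, c("x", "y", "z")])
  static <- make_trajectory(s, list(base, base, base))
  expect_true(all(rmsf_profile(static) < 1e-9))
  # one atom alternating at +/- 1 A along x, many fixed anchors
  up <- base; up[40, 1] <- up[40, 1] + 1
  dn <- base; dn[40, 1] <- dn[40, 1] - 1
  prof <- rmsf_profile(make_trajectory(s, list(up, dn, up, dn)))
  expect_equal(unname(prof[40]), 1, tolerance = 0.05)
  expect_true(all(prof[1:39] < 0.1))
  # random trajectory: matches the explicit double-loop definition
  set.seed(13)
  frames <- lapply(1:50, function(k) base + matrix(rnorm(120, sd = 0.4), 40, 3))
  traj <- make_trajectory(s, frames)
  prof2 <- rmsf_profile(traj)
  fitted <- lapply(frames, function(f) kabsch_superpose(f, base)$transformed)
  brute <- sapply(1:40, function(i) {
    acc <- 0
    for (t in 1:50) acc <- acc + sum((fitted[[t]][i, ] - base[i, ])^2)
    sqrt(acc / 50)
  })
  expect_equal(unname(prof2), brute, tolerance = 1e-9)
  # single-frame trajectory is allowed: per-frame deviation
  one <- rmsf_profile(make_trajectory(s, frames[1]))
  expect_true(all(one >= 0))
})

test_that("metrics are invariant under global rigid motion of all frames", {
  s <- make_trem2_like(1:12)
  base <- as.matrix(s$atoms[, c("x", "y", "z")])
  set.seed(3)
  frames <- lapply(1:4, function(k) base + matrix(rnorm(36, sd = 0.5), 12, 3))
  traj <- make_trajectory(s, frames)
  th <- 0.7
  Q <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  moved <- make_trajectory(s, lapply(frames, function(f) f %*% t(Q) + 11))
  expect_equal(as.numeric(pair_distance_series(traj, 1, 12)),
               as.numeric(pair_distance_series(moved, 1, 12)), tolerance = 1e-9)
  expect_equal(as.numeric(rmsd_series(traj)), as.numeric(rmsd_series(moved)),
               tolerance = 1e-9)
  expect_equal(rmsf_profile(traj), rmsf_profile(moved), tolerance = 1e-9)
})

test_that("dihedral follows the IUPAC convention with trans at 180", {
  # planar trans zig-zag
  expect_equal(dihedral(c(0, 1, 0), c(1, 0, 0), c(2, 1, 0), c(3, 0, 0)), 180)
  # planar cis
  expect_equal(dihedral(c(0, 1, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)), 0)
  # +90 degrees out of plane, checked against an independent vector formula
  p1 <- c(0, 1, 0); p2 <- c(1, 0, 0); p3 <- c(2, 0, 0); p4 <- c(2, 0, 0) + c(1, 0, 1)
  got <- dihedral(p1, p2, p3, p4)
  # oracle: signed angle between normal-plane projections
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  u <- b2 / sqrt(sum(b2^2))
  v1 <- b1 - sum(b1 * u) * u
  v2 <- b3 - sum(b3 * u) * u
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  sinsign <- sign(sum(u * c(v1[2] * v2[3] - v1[3] * v2[2],
                            v1[3] * v2[1] - v1[1] * v2[3],
                            v1[1] * v2[2] - v1[2] * v2[1])))
  oracle <- -sinsign * acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  expect_equal(got, oracle, tolerance = 1e-9)
  expect_equal(abs(got), 90, tolerance = 1e-9)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
               "undefined dihedral")
})

test_that("phi/psi series recover construction angles and flag termini", {
  bb <- build_backbone(-57, -47, 6)
  traj <- make_trajectory(bb, list(as.matrix(bb$atoms[, c("x", "y", "z")])))
  pp <- phi_psi_series(traj)
  inner <- pp[pp$resno %in% 2:5, ]
  expect_true(all(abs(inner$phi - (-57)) < 1e-3))
  expect_true(all(abs(inner$psi - (-47)) < 1e-3))
  expect_true(is.na(pp$phi[pp$resno == 1]))
  expect_true(is.na(pp$psi[pp$resno == 6]))
  # two-residue chain: only the shared peptide torsions are defined
  bb2 <- build_backbone(-57, -47, 2)
  pp2 <- phi_psi_series(make_trajectory(bb2, list(as.matrix(bb2$atoms[, c("x", "y", "z")]))))
  expect_true(is.na(pp2$phi[pp2$resno == 1]) && is.na(pp2$psi[pp2$resno == 2]))
  # CA-only chain: everything absent, with a per-residue report
  ca <- make_trem2_like(1:4)
  pp3 <- phi_psi_series(make_trajectory(ca, list(as.matrix(ca$atoms[, c("x", "y", "z")]))))
  expect_true(all(is.na(pp3$phi)) && all(is.na(pp3$psi)))
  expect_length(attr(pp3, "report"), 4)
})

test_that("secondary-structure regions classify canonical angles and are disjoint", {
  expect_equal(classify_ss(-57, -47), "rh_helix")
  expect_equal(classify_ss(57, 47), "lh_helix")
  expect_equal(classify_ss(-120, 135), "beta")
  expect_equal(classify_ss(0, 0), "other")
  expect_true(is.na(classify_ss(NA, 10)))
  # pairwise disjoint: each grid point gets exactly one label
  grid <- expand.grid(phi = seq(-179.5, 180, by = 3.7),
                      psi = seq(-179.5, 180, by = 3.7))
  lab <- classify_ss(grid$phi, grid$psi)
  expect_true(all(lab %in% c("beta", "rh_helix", "lh_helix", "other")))
  in_rh <- grid$phi >= -100 & grid$phi < -30 & grid$psi >= -80 & grid$psi < -5
  in_lh <- grid$phi > 30 & grid$phi <= 100 & grid$psi > 5 & grid$psi <= 80
  in_beta <- grid$phi >= -180 & grid$phi < -45 &
    ((grid$psi >= 90 & grid$psi <= 180) | (grid$psi >= -180 & grid$psi < -150))
  expect_true(all(in_rh + in_lh + in_beta <= 1))
  expect_identical(lab == "rh_helix", in_rh)
})

test_that("secondary-structure counts per region match hand computation", {
  ang <- generate_phi_psi_set(c(beta = 7, rh_helix = 3), jitter_deg = 0,
                              seed = 1)
  tab <- data.frame(frame = rep(1:2, each = 10), time_ns = rep(c(0, 0.5), each = 10),
                    chain = "A", resno = rep(1:10, 2),
                    phi = rep(ang$phi, 2), psi = rep(ang$psi, 2))
  counts <- count_ss_residues(tab)
  expect_equal(counts$beta, c(7, 7))
  expect_equal(counts$rh_helix, c(3, 3))
  expect_equal(counts$lh_helix, c(0, 0))
  # all-other angles
  tab0 <- transform(tab, phi = 0, psi = 0)
  c0 <- count_ss_residues(tab0)
  expect_true(all(c0$beta == 0 & c0$rh_helix == 0 & c0$lh_helix == 0))
  # mixed two-frame series: window means are the hand-computed averages
  tab$phi[tab$frame == 2][1:2] <- 0; tab$psi[tab$frame == 2][1:2] <- 0
  cm <- count_ss_residues(tab)
  expect_equal(unname(attr(cm, "window_mean")["beta"]), (7 + 5) / 2)
  # restriction to a region subsets the counts
  reg <- data.frame(chain = "A", resno = 1:5)
  cr <- count_ss_residues(tab, reg)
  expect_true(all(cr$beta + cr$rh_helix + cr$lh_helix <= 5))
})

test_that("linear fits reproduce exact and degenerate cases", {
  x <- 1:10
  f <- fit_linear(x, 2 * x + 1)
  expect_equal(f$slope, 2); expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)
  fc <- fit_linear(x, rep(3, 10))
  expect_equal(fc$slope, 0); expect_equal(fc$r_squared, 0)
  expect_error(fit_linear(rep(1, 5), 1:5), "zero variance")
  # noisy fit matches the normal equations
  set.seed(2)
  y <- 1.5 * x - 2 + rnorm(10)
  f2 <- fit_linear(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(f2$intercept, beta[1], tolerance = 1e-9)
  expect_equal(f2$slope, beta[2], tolerance = 1e-9)
  expect_true(f2$r_squared >= 0 && f2$r_squared <= 1)
})
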