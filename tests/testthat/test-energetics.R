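test_that("analysis windows form exact inclusive grids", {
  w <- window_frame_times(450, 500, 0.5)
  expect_length(w, 101)
  expect_equal(w[1], 450); expect_equal(w[101], 500)
  expect_equal(window_frame_times(0, 1, 0.5), c(0, 0.5, 1.0))
  expect_error(window_frame_times(0, 1, 0.3), "multiple")
  expect_error(window_frame_times(5, 5, 0.5), "exceed")
  # 18 complexes on the production window -> 1818 records
  expect_equal(18 * length(w), 1818)
})

test_that("energy frames are classified by Loop 1 with strict time alignment", {
  st <- list(mean = 15, sd = 2)
  prm <- energy_table_params(occupancies = c(A = 50, B = 30, C = 21), seed = 3)
  tab <- generate_energy_table(prm, st)
  rec <- classify_energy_frames(tab[, c("time_ns", "energy")],
                                tab[, c("time_ns", "loop1")], st)
  expect_equal(as.integer(attr(rec, "counts")[c("A", "B", "C")]),
               c(50, 30, 21))
  expect_identical(as.character(rec$cluster), tab$cluster_true)
  # loop1 exactly at the mean is B everywhere
  flat <- data.frame(time_ns = 1:5, energy = rnorm(5))
  rec2 <- classify_energy_frames(flat, rep(15, 5), st)
  expect_true(all(rec2$cluster == "B"))
  # misaligned grids and missing energies are hard errors
  off <- tab[, c("time_ns", "loop1")]; off$time_ns <- off$time_ns + 0.25
  expect_error(classify_energy_frames(tab[, c("time_ns", "energy")], off, st),
               "align")
  nae <- tab[, c("time_ns", "energy")]; nae$energy[3] <- NA
  expect_error(classify_energy_frames(nae, tab[, c("time_ns", "loop1")], st),
               "missing energy")
})

test_that("group summaries report n, mean, sd, sem, min, max per cell", {
  rec <- data.frame(variant = "WT", isoform = "E2",
                    cluster = c("A", "A", "A", "B"),
                    energy = c(-10, -20, -30, -5))
  sm <- summarize_groups(rec)
  a <- sm[sm$cluster == "A", ]
  expect_equal(a$n, 3); expect_equal(a$mean, -20); expect_equal(a$sd, 10)
  expect_equal(a$sem, 10 / sqrt(3))
  expect_equal(a$min, -30); expect_equal(a$max, -10)
  b <- sm[sm$cluster == "B", ]
  expect_equal(b$n, 1); expect_true(is.na(b$sd))
  expect_error(summarize_groups(rec[0, ]), "empty")
})

test_that("two-way ANOVA recovers constructed effects and matches manual SS", {
  # balanced 2x2, additive shift on factor A only
  set.seed(10)
  d <- expand.grid(cluster = c("A", "B"), isoform = c("E2", "E3"),
                   rep = 1:20)
  d$energy <- ifelse(d$cluster == "A", 3, 0) + rnorm(nrow(d), sd = 1)
  tab <- two_way_anova(d, "cluster", "isoform")
  expect_lt(tab$p[tab$effect == "cluster"], 0.05)
  expect_lt(tab$F[tab$effect == "cluster:isoform"], 5)
  # hand-computable balanced 2x2 with n=2 per cell: classic SS decomposition
  d2 <- data.frame(cluster = rep(c("A", "A", "B", "B"), 2),
                   isoform = rep(c("E2", "E3"), each = 4),
                   energy = c(1, 2, 5, 6, 3, 4, 4, 5))
  tab2 <- two_way_anova(d2, "cluster", "isoform")
  g <- mean(d2$energy)
  ssA <- sum(tapply(d2$energy, d2$cluster, function(v) length(v) * (mean(v) - g)^2))
  ssB <- sum(tapply(d2$energy, d2$isoform, function(v) length(v) * (mean(v) - g)^2))
  cellm <- tapply(d2$energy, list(d2$cluster, d2$isoform), mean)
  am <- tapply(d2$energy, d2$cluster, mean)
  bm <- tapply(d2$energy, d2$isoform, mean)
  ssAB <- 2 * sum((cellm - outer(am, bm, "+") + g)^2)
  expect_equal(tab2$sumsq[tab2$effect == "cluster"], ssA, tolerance = 1e-9)
  expect_equal(tab2$sumsq[tab2$effect == "isoform"], ssB, tolerance = 1e-9)
  expect_equal(tab2$sumsq[tab2$effect == "cluster:isoform"], ssAB,
               tolerance = 1e-9)
  # identical values in every cell: degenerate variance
  d3 <- transform(d2, energy = 1)
  expect_error(two_way_anova(d3, "cluster", "isoform"), "degenerate")
  # empty cell: interaction dropped and reported
  d4 <- d[!(d$cluster == "A" & d$isoform == "E3"), ]
  tab4 <- two_way_anova(d4, "cluster", "isoform")
  expect_true(attr(tab4, "dropped_interaction"))
  expect_false("cluster:isoform" %in% tab4$effect)
})

test_that("Tukey-Kramer agrees with the reference implementation", {
  set.seed(20)
  rec <- data.frame(group = rep(c("a", "b", "c"), times = c(8, 12, 10)))
  rec$energy <- rnorm(30) + ifelse(rec$group == "b", 1.5, 0)
  tk <- tukey_kramer(rec, "group")
  ref <- TukeyHSD(aov(energy ~ group, data = rec))$group
  expect_equal(tk$p_adj, unname(ref[, "p adj"]), tolerance = 1e-8)
  expect_equal(tk$diff, unname(ref[, "diff"]), tolerance = 1e-9)
  # q agrees with the studentized-range quantile at the adjusted p
  k <- 3; dfree <- 27
  q_oracle <- qtukey(1 - tk$p_adj, nmeans = k, df = dfree)
  expect_equal(tk$q, q_oracle, tolerance = 1e-6)
  # adjusted p is never below the unadjusted pooled-t pairwise p
  p_unadj <- 2 * pt(-tk$q / sqrt(2), df = dfree)
  expect_true(all(tk$p_adj >= p_unadj - 1e-12))
  # identical groups -> q = 0, p = 1
  flat <- data.frame(group = rep(c("a", "b"), each = 5), energy = 1)
  tk0 <- tukey_kramer(flat, "group")
  expect_equal(tk0$q, 0); expect_equal(tk0$p_adj, 1)
  # two groups 10 pooled SDs apart are overwhelmingly significant
  far <- data.frame(group = rep(c("a", "b"), each = 10))
  set.seed(1); far$energy <- rnorm(20, sd = 1) + ifelse(far$group == "b", 10, 0)
  expect_lt(tukey_kramer(far, "group")$p_adj, 1e-4)
})

test_that("occupancy-weighted means equal the record-wise mean", {
  sm <- data.frame(cluster = c("A", "B", "C"), n = c(50, 30, 21),
                   mean = c(-10, -20, -30))
  expect_equal(weighted_cluster_mean(sm), (-500 - 600 - 630) / 101)
  expect_equal(weighted_cluster_mean(sm[2, ]), -20)
  # algebraic identity against the raw records
  prm <- energy_table_params(occupancies = c(A = 40, B = 35, C = 26), seed = 5)
  tab <- generate_energy_table(prm, list(mean = 15, sd = 2))
  rec <- classify_energy_frames(tab[, c("time_ns", "energy")],
                                tab[, c("time_ns", "loop1")],
                                list(mean = 15, sd = 2))
  sm2 <- summarize_groups(rec, "cluster")
  expect_equal(weighted_cluster_mean(sm2), mean(rec$energy), tolerance = 1e-12)
  # bounded by the cluster means
  expect_gte(weighted_cluster_mean(sm), min(sm$mean))
  expect_lte(weighted_cluster_mean(sm), max(sm$mean))
  expect_error(weighted_cluster_mean(data.frame(n = 0, mean = 1)), "zero")
})

test_that("MP-cluster extraction uses population with energy tie-breaks", {
  sm <- data.frame(cluster = c("A", "B", "C"), n = c(50, 30, 21),
                   mean = c(-10, -20, -30))
  expect_equal(mp_cluster(sm)$cluster, "A")
  tie <- data.frame(cluster = c("A", "B", "C"), n = c(40, 40, 21),
                    mean = c(-5, -9, -30))
  mp <- mp_cluster(tie)
  expect_equal(mp$cluster, "B")
  expect_true(attr(mp, "tie"))
  # round-trip with the generator's occupancies
  prm <- energy_table_params(occupancies = c(A = 10, B = 70, C = 21), seed = 2)
  tab <- generate_energy_table(prm, list(mean = 15, sd = 2))
  rec <- classify_energy_frames(tab[, c("time_ns", "energy")],
                                tab[, c("time_ns", "loop1")],
                                list(mean = 15, sd = 2))
  sm2 <- summarize_groups(rec, "cluster")
  sm2$cluster <- sm2$cluster
  expect_equal(mp_cluster(sm2)$cluster, "B")
  expect_error(mp_cluster(data.frame(cluster = "A", n = 0, mean = 1)), "empty")
})

test_that("rank concordance follows Spearman correlation on affinities", {
  e <- c(E2 = -20, E3 = -25, E4 = -30) # E4 strongest binder
  aff <- c(E2 = 1, E3 = 2, E4 = 3)
  expect_equal(rank_concordance(e, aff), 1)
  expect_equal(rank_concordance(e, rev(unname(aff))), -1)
  # tie case matches brute-force mid-ranks
  e2 <- c(a = -10, b = -10, c = -30, d = -5)
  a2 <- c(a = 2, b = 1, c = 4, d = 0.5)
  got <- rank_concordance(e2, a2)
  mid_rank <- function(v) rank(v, ties.method = "average")
  r1 <- mid_rank(-e2); r2 <- mid_rank(a2)
  oracle <- sum((r1 - mean(r1)) * (r2 - mean(r2))) /
    sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(rank_concordance(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(rank_concordance(c(1, 2), c(1, 2)), "three")
})
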