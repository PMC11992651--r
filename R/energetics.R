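#' @title Interaction-energy statistics
#' @description Windowed per-frame energy ingestion, cluster classification
#'   of energy frames via Loop 1, group summaries, two-way ANOVA (Type II)
#'   with Tukey-Kramer pairwise comparisons, occupancy-weighted ensemble
#'   energies, most-populated-cluster extraction, and rank concordance with
#'   experimental affinities.
#' @name energetics
NULL

#' Frame times of an analysis window
#'
#' Inclusive arithmetic grid `t_start, t_start + dt, ..., t_end`; the window
#' span must be an exact multiple of `dt`. The production analysis window is
#' 450-500 ns every 0.5 ns: 101 frames per complex.
#'
#' @param t_start,t_end window bounds, ns (`t_end > t_start`).
#' @param dt frame spacing, ns (> 0).
#' @return numeric vector of frame times.
#' @examples
#' length(window_frame_times(450, 500, 0.5)) # 101
#' @export
window_frame_times <- function(t_start = 450, t_end = 500, dt = 0.5) {
  if (!(t_end > t_start)) stop("t_end must exceed t_start", call. = FALSE)
  if (!(dt > 0)) stop("dt must be positive", call. = FALSE)
  k <- (t_end - t_start) / dt
  if (abs(k - round(k)) > 1e-9) {
    stop("window span is not an exact multiple of dt", call. = FALSE)
  }
  t_start + dt * (0:round(k))
}

#' Classify per-frame energies into Clusters A/B/C via Loop 1
#'
#' Joins an energy table to a Loop 1 series on exactly matching frame times
#' and labels each record with [assign_clusters()].
#'
#' @param energies data frame with columns `time_ns` and `energy`
#'   (kcal/mol); any additional columns (complex_id, variant, isoform) are
#'   carried through.
#' @param loop1 data frame with columns `time_ns` and `loop1` (Angstrom), or
#'   a numeric vector aligned to `energies` rows.
#' @param stats a [loop_stats()] object for the relevant variant.
#' @return the energy table with added `loop1` (if joined) and `cluster`
#'   columns, plus attribute `counts` (frames per label).
#' @export
classify_energy_frames <- function(energies, loop1, stats) {
  stopifnot(is.data.frame(energies), all(c("time_ns", "energy") %in% names(energies)))
  if (anyNA(energies$energy)) {
    bad <- energies$time_ns[is.na(energies$energy)]
    stop(sprintf("missing energy at time(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  if (is.data.frame(loop1)) {
    stopifnot(all(c("time_ns", "loop1") %in% names(loop1)))
    pos <- match(round(energies$time_ns, 9), round(loop1$time_ns, 9))
    if (anyNA(pos)) {
      bad <- energies$time_ns[is.na(pos)]
      stop(sprintf("time grids do not align; no Loop 1 value at: %s",
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
    energies$loop1 <- loop1$loop1[pos]
  } else {
    if (length(loop1) != nrow(energies)) {
      stop("loop1 vector length does not match the energy table", call. = FALSE)
    }
    energies$loop1 <- as.numeric(loop1)
  }
  energies$cluster <- assign_clusters(energies$loop1, stats)
  attr(energies, "counts") <- table(energies$cluster)
  energies
}

#' Group summaries of energy records
#'
#' Per-group frame count, mean, sample SD (n - 1), SEM, min and max of the
#' energy. Single-frame groups report NA SD/SEM.
#'
#' @param records data frame with an `energy` column.
#' @param keys character vector of grouping columns (default
#'   `c("variant", "isoform", "cluster")`, intersected with available
#'   columns).
#' @return data frame with one row per group: keys, n, mean, sd, sem, min,
#'   max.
#' @export
summarize_groups <- function(records,
                             keys = c("variant", "isoform", "cluster")) {
  stopifnot(is.data.frame(records), "energy" %in% names(records))
  if (nrow(records) == 0) stop("empty record table", call. = FALSE)
  keys <- intersect(keys, names(records))
  if (length(keys) == 0) stop("no grouping columns present", call. = FALSE)
  grp <- interaction(records[keys], drop = TRUE, sep = "\r")
  agg <- function(f) as.numeric(tapply(records$energy, grp, f))
  n <- as.integer(tapply(records$energy, grp, length))
  sdv <- agg(function(v) if (length(v) > 1) stats::sd(v) else NA_real_)
  keysplit <- do.call(rbind, strsplit(levels(grp), "\r", fixed = TRUE))
  out <- data.frame(keysplit, stringsAsFactors = FALSE)
  names(out) <- keys
  out$n <- n
  out$mean <- agg(mean)
  out$sd <- sdv
  out$sem <- sdv / sqrt(n)
  out$min <- agg(min)
  out$max <- agg(max)
  rownames(out) <- NULL
  out
}

#' Two-way ANOVA on energy records (Type II sums of squares)
#'
#' Fits `energy ~ factorA * factorB` by least squares and computes Type II
#' sums of squares, appropriate for the unbalanced cell counts that
#' SD-threshold clustering produces. The interaction is dropped (and
#' reported) when empty cells make it unestimable.
#'
#' @param records data frame with an `energy` column and the two factor
#'   columns.
#' @param factorA,factorB names of the factor columns (default `"cluster"`
#'   and `"isoform"`).
#' @return data frame with one row per effect: effect, sumsq, df, F, p; the
#'   attribute `dropped_interaction` records whether the interaction was
#'   unestimable.
#' @export
two_way_anova <- function(records, factorA = "cluster", factorB = "isoform") {
  stopifnot(all(c("energy", factorA, factorB) %in% names(records)))
  d <- data.frame(energy = records$energy,
                  A = droplevels(factor(records[[factorA]])),
                  B = droplevels(factor(records[[factorB]])))
  if (nlevels(d$A) < 2 || nlevels(d$B) < 2) {
    stop("each factor needs at least two observed levels", call. = FALSE)
  }
  cells <- table(d$A, d$B)
  dropped <- any(cells == 0)
  form <- if (dropped) energy ~ A + B else energy ~ A * B
  fit <- stats::lm(form, data = d)
  if (stats::df.residual(fit) < 1) {
    stop("no residual degrees of freedom", call. = FALSE)
  }
  if (sum(stats::residuals(fit)^2) < 1e-12 * max(1, sum(d$energy^2))) {
    stop("degenerate variance: residual sum of squares is zero", call. = FALSE)
  }
  tab <- car::Anova(fit, type = 2)
  eff <- rownames(tab)
  keep <- eff != "Residuals"
  out <- data.frame(
    effect = gsub("^A$", factorA, gsub("^B$", factorB,
             gsub("^A:B$", paste0(factorA, ":", factorB), eff[keep]))),
    sumsq = tab$`Sum Sq`[keep], df = tab$Df[keep],
    F = tab$`F value`[keep], p = tab$`Pr(>F)`[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "dropped_interaction") <- dropped
  attr(out, "residual_df") <- stats::df.residual(fit)
  out
}

#' Tukey-Kramer pairwise comparisons
#'
#' All pairwise group-mean comparisons using the pooled one-way MSE, the
#' Tukey-Kramer standard error for unequal group sizes, and p-values from
#' the studentized-range distribution.
#'
#' @param records data frame with an `energy` column.
#' @param grouping name of the grouping column, or character vector of
#'   columns whose interaction defines the groups (default
#'   `c("variant", "isoform", "cluster")` intersected with available
#'   columns).
#' @return data frame with columns group1, group2, diff, q, p_adj.
#' @export
tukey_kramer <- function(records, grouping = c("variant", "isoform", "cluster")) {
  stopifnot(is.data.frame(records), "energy" %in% names(records))
  grouping <- intersect(grouping, names(records))
  if (length(grouping) == 0) stop("no grouping columns present", call. = FALSE)
  g <- droplevels(interaction(records[grouping], drop = TRUE, sep = "/"))
  k <- nlevels(g)
  if (k < 2) stop("at least two groups are required", call. = FALSE)
  n_i <- as.integer(table(g))
  if (any(n_i < 1)) stop("every group needs at least one record", call. = FALSE)
  means <- tapply(records$energy, g, mean)
  df_err <- length(g) - k
  if (df_err < 1) stop("no residual degrees of freedom", call. = FALSE)
  mse <- sum(tapply(records$energy, g,
                    function(v) sum((v - mean(v))^2))) / df_err
  pairs <- utils::combn(levels(g), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    n1 <- n_i[match(g1, levels(g))]; n2 <- n_i[match(g2, levels(g))]
    diff <- means[[g2]] - means[[g1]]
    se <- sqrt(mse / 2 * (1 / n1 + 1 / n2))
    q <- if (se == 0) 0 else abs(diff) / se
    p <- if (mse == 0) 1 else stats::ptukey(q, nmeans = k, df = df_err,
                                            lower.tail = FALSE)
    data.frame(group1 = g1, group2 = g2, diff = diff, q = q, p_adj = p,
               stringsAsFactors = FALSE)
  }))
  attr(out, "mse") <- mse
  attr(out, "df") <- df_err
  out
}

#' Occupancy-weighted ensemble mean energy
#'
#' Weights each cluster's mean binding free energy by its frame count and
#' sums over clusters: `sum(n_c * mean_c) / sum(n_c)`. Algebraically equal
#' to the plain record-wise mean over all frames of the complex.
#'
#' @param summaries data frame from [summarize_groups()] restricted to one
#'   complex (columns `n` and `mean`); absent clusters count as n = 0.
#' @return weighted mean energy, kcal/mol.
#' @export
weighted_cluster_mean <- function(summaries) {
  stopifnot(is.data.frame(summaries), all(c("n", "mean") %in% names(summaries)))
  n <- summaries$n
  if (sum(n) <= 0) stop("cluster frame counts sum to zero", call. = FALSE)
  sum(n * summaries$mean) / sum(n)
}

#' Most-populated (MP) cluster of a complex
#'
#' The cluster with the largest frame count; ties break to the cluster with
#' the lowest (most favourable) mean energy, and the tie is reported.
#'
#' @param summaries data frame with columns `cluster`, `n`, `mean` for one
#'   complex.
#' @return one-row data frame (the MP cluster's summary) with attribute
#'   `tie` (logical).
#' @export
mp_cluster <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("cluster", "n", "mean") %in% names(summaries)))
  summaries <- summaries[summaries$n > 0, , drop = FALSE]
  if (nrow(summaries) == 0) stop("all clusters are empty", call. = FALSE)
  top <- summaries[summaries$n == max(summaries$n), , drop = FALSE]
  tie <- nrow(top) > 1
  if (tie) top <- top[order(top$mean), , drop = FALSE]
  out <- top[1, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tie") <- tie
  out
}

#' Rank concordance between model energies and experimental affinities
#'
#' Spearman rank correlation between binding strength implied by the model
#' (negated interaction free energy: more negative energy = stronger
#' binding) and experimental affinity expressed as 1/K_D.
#'
#' @param model_means named numeric vector of mean interaction free energies
#'   per isoform, kcal/mol.
#' @param affinities named numeric vector of 1/K_D values on the same
#'   isoforms.
#' @return Spearman correlation in \[-1, 1\].
#' @export
rank_concordance <- function(model_means, affinities) {
  if (!is.null(names(model_means)) && !is.null(names(affinities))) {
    affinities <- affinities[names(model_means)]
  }
  stopifnot(length(model_means) == length(affinities))
  if (length(model_means) < 3) {
    stop("at least three paired values are required", call. = FALSE)
  }
  if (stats::sd(model_means) == 0 || stats::sd(affinities) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  stats::cor(-model_means, affinities, method = "spearman")
}
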