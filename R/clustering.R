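#' @title SD-threshold conformational clustering (Clusters A/B/C)
#' @description Loop 1 distances pooled over all replicates of a variant
#'   define a mean and standard deviation; frames are labelled Cluster A
#'   (more than one SD above the mean), Cluster B (within one SD of the
#'   mean, boundaries inclusive), or Cluster C (more than one SD below).
#' @name clustering
NULL

#' Pooled Loop 1 statistics for a variant
#'
#' Mean and sample SD (n - 1 denominator) over all frames of all replicates
#' pooled together, giving the single per-variant threshold pair that the
#' shared Cluster A/B/C definitions imply.
#'
#' @param series a numeric vector, or a list of numeric vectors (one per
#'   replicate), of Loop 1 distances in Angstrom.
#' @param variant variant label stored with the statistics.
#' @return list with `mean`, `sd`, `n_frames`, `variant` (class
#'   `loop_stats`).
#' @export
loop_stats <- function(series, variant = "WT") {
  values <- if (is.list(series)) unlist(series, use.names = FALSE) else series
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("at least two frames are required to compute loop statistics",
         call. = FALSE)
  }
  s <- stats::sd(values)
  if (s == 0) {
    warning("loop distances are constant: sd = 0, clustering is degenerate",
            call. = FALSE)
  }
  structure(list(mean = mean(values), sd = s, n_frames = length(values),
                 variant = variant),
            class = "loop_stats")
}

#' @export
print.loop_stats <- function(x, ...) {
  cat(sprintf("<loop_stats> %s: mean %.3f A, sd %.3f A over %d frames\n",
              x$variant, x$mean, x$sd, x$n_frames))
  cat(sprintf("  thresholds: A > %.3f, C < %.3f, B otherwise\n",
              x$mean + x$sd, x$mean - x$sd))
  invisible(x)
}

#' Assign frames to Clusters A/B/C
#'
#' A: value strictly above mean + sd; C: strictly below mean - sd; B
#' otherwise (values exactly on a threshold are "within the mean +/- one
#' standard deviation", hence B). With sd = 0 every frame is B, with a
#' warning.
#'
#' @param values Loop 1 distances, Angstrom.
#' @param stats a [loop_stats()] object (or list with `mean`, `sd`).
#' @return factor with levels A, B, C, plus attribute `thresholds`
#'   (`c(lower, upper)`).
#' @export
assign_clusters <- function(values, stats) {
  m <- stats[["mean"]]; s <- stats[["sd"]]
  stopifnot(is.finite(m), is.finite(s), s >= 0)
  lab <- rep("B", length(values))
  if (s == 0) {
    # a degenerate band has zero width; treat every frame as within it
    warning("sd is zero: all frames assigned to Cluster B", call. = FALSE)
  } else {
    lab[values > m + s] <- "A"
    lab[values < m - s] <- "C"
  }
  out <- factor(lab, levels = c("A", "B", "C"))
  attr(out, "thresholds") <- c(lower = m - s, upper = m + s)
  out
}

#' Cluster occupancy counts and fractions
#'
#' @param assignment factor from [assign_clusters()] (levels A, B, C).
#' @return data frame with columns cluster, n, fraction; counts sum to the
#'   number of frames and fractions to 1.
#' @export
cluster_occupancy <- function(assignment) {
  if (length(assignment) == 0) stop("empty assignment", call. = FALSE)
  assignment <- factor(assignment, levels = c("A", "B", "C"))
  n <- table(assignment)
  data.frame(cluster = names(n), n = as.integer(n),
             fraction = as.numeric(n) / length(assignment),
             stringsAsFactors = FALSE)
}

#' Fit the SD-threshold cluster model to Loop 1 series
#'
#' The model-fitting front end: pools all supplied replicate series, derives
#' the mean +/- SD thresholds, and labels every frame. The returned object
#' supports `print`, `summary`, `coef` (mean, sd and thresholds), `fitted`
#' (training labels), `predict` (labels for new distances), and `plot`
#' (distance histogram with thresholds).
#'
#' @param series numeric vector or list of numeric vectors (replicates) of
#'   Loop 1 distances, Angstrom.
#' @param variant variant label.
#' @return an object of class `loop_clusters`.
#' @examples
#' d <- generate_gaussian_loop_series(mu = 15, sigma = 2, n = 2000, seed = 7)
#' fit <- loop_clusters(d, variant = "WT")
#' summary(fit)
#' predict(fit, c(10, 15, 20))
#' @export
loop_clusters <- function(series, variant = "WT") {
  st <- loop_stats(series, variant = variant)
  values <- if (is.list(series)) unlist(series, use.names = FALSE) else series
  values <- as.numeric(values)
  labels <- assign_clusters(values, st)
  structure(list(stats = st, values = values, labels = labels,
                 call = match.call()),
            class = "loop_clusters")
}

#' @export
print.loop_clusters <- function(x, ...) {
  cat("SD-threshold loop-conformation clustering\n")
  print(x$stats)
  occ <- cluster_occupancy(x$labels)
  cat(sprintf("  occupancy: A %d (%.1f%%), B %d (%.1f%%), C %d (%.1f%%)\n",
              occ$n[1], 100 * occ$fraction[1], occ$n[2], 100 * occ$fraction[2],
              occ$n[3], 100 * occ$fraction[3]))
  invisible(x)
}

#' @export
summary.loop_clusters <- function(object, ...) {
  occ <- cluster_occupancy(object$labels)
  out <- list(stats = object$stats, occupancy = occ,
              thresholds = attr(object$labels, "thresholds"))
  class(out) <- "summary.loop_clusters"
  out
}

#' @export
print.summary.loop_clusters <- function(x, ...) {
  print(x$stats)
  cat("occupancy:\n")
  print(x$occupancy, row.names = FALSE)
  invisible(x)
}

#' @export
coef.loop_clusters <- function(object, ...) {
  c(mean = object$stats$mean, sd = object$stats$sd,
    lower = object$stats$mean - object$stats$sd,
    upper = object$stats$mean + object$stats$sd)
}

#' @export
fitted.loop_clusters <- function(object, ...) object$labels

#' @export
predict.loop_clusters <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$labels)
  assign_clusters(as.numeric(newdata), object$stats)
}

#' @export
plot.loop_clusters <- function(x, breaks = 40, main = NULL, ...) {
  thr <- attr(x$labels, "thresholds")
  if (is.null(main)) {
    main <- sprintf("Loop 1 clustering (%s)", x$stats$variant)
  }
  graphics::hist(x$values, breaks = breaks, main = main,
                 xlab = "Loop 1 distance (Å)", ...)
  graphics::abline(v = thr, lty = 2, col = "red3")
  invisible(x)
}

#' Medoid representative frame of a cluster
#'
#' The frame minimising the summed pairwise CA RMSD (after Kabsch
#' superposition) to all other member frames; ties break to the earliest
#' frame. This is the deterministic representative-structure criterion used
#' to pick docking inputs per cluster.
#'
#' @param trajectory an `md_trajectory`.
#' @param member_frames integer vector of frame indices (1-based) belonging
#'   to the cluster.
#' @param selection residue table (chain, resno) or NULL for all CA atoms.
#' @return the selected frame index, with attribute `total_rmsd` (summed
#'   pairwise RMSD per member, Angstrom).
#' @export
select_representative <- function(trajectory, member_frames, selection = NULL) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  member_frames <- sort(as.integer(member_frames))
  if (length(member_frames) == 0) stop("empty member set", call. = FALSE)
  if (length(member_frames) == 1) {
    out <- member_frames
    attr(out, "total_rmsd") <- 0
    return(out)
  }
  idx <- .selection_ca(trajectory$topology, selection)
  m <- length(member_frames)
  coords <- lapply(member_frames, function(f) {
    x <- trajectory$coords[f, idx, , drop = TRUE]
    if (is.null(dim(x))) matrix(x, ncol = 3) else x
  })
  d <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      d[i, j] <- d[j, i] <- kabsch_superpose(coords[[i]], coords[[j]])$rmsd
    }
  }
  tot <- rowSums(d)
  best <- which(tot == min(tot))[1] # earliest frame on ties
  out <- member_frames[best]
  attr(out, "total_rmsd") <- stats::setNames(tot, member_frames)
  out
}
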