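#' @title Interface contact analysis and docking-model selection
#' @description Residue-residue minimum-distance maps between two chains,
#'   cutoff-thresholded contact sets, the fraction of TREM2 CDR residues
#'   within 4.0 Angstrom of the ApoE hinge (the docking-model selection
#'   filter), model ranking, and overlap with literature binding residues.
#' @name interface-analysis
NULL

.atoms_for_mode <- function(structure, residues, atom_mode) {
  a <- structure$atoms
  keep <- paste(a$chain, a$resno) %in% paste(residues$chain, residues$resno)
  a <- a[keep, , drop = FALSE]
  if (atom_mode == "heavy") a <- a[a$is_heavy, , drop = FALSE]
  if (atom_mode == "ca") a <- a[a$name == "CA", , drop = FALSE]
  if (nrow(a) == 0) stop("selection resolves to zero atoms", call. = FALSE)
  a
}

#' Residue-by-residue minimum-distance map
#'
#' Entry (i, j) is the minimum distance over atom pairs between residue i of
#' the first selection and residue j of the second; by default only heavy
#' atoms (element != H) are considered, matching the usual "within X
#' Angstrom" selection semantics on crystal structures.
#'
#' @param structA,structB `pdb_structure`s (may be the same object).
#' @param selA,selB residue tables (chain, resno), e.g. from
#'   [select_region()].
#' @param atom_mode `"heavy"` (default), `"ca"`, or `"all"`.
#' @return a `contact_map`: numeric matrix (rows = selA residues, cols =
#'   selB residues, dimnames `"chain:resno"`), Angstrom.
#' @export
residue_min_distance_map <- function(structA, selA, structB, selB,
                                     atom_mode = c("heavy", "ca", "all")) {
  atom_mode <- match.arg(atom_mode)
  if (nrow(selA) == 0 || nrow(selB) == 0) {
    stop("empty selection", call. = FALSE)
  }
  aA <- .atoms_for_mode(structA, selA, atom_mode)
  aB <- .atoms_for_mode(structB, selB, atom_mode)
  xyzA <- as.matrix(aA[, c("x", "y", "z")])
  xyzB <- as.matrix(aB[, c("x", "y", "z")])
  # all-pairs atom distances, then aggregate minima by residue pair
  d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), "+") - 2 * xyzA %*% t(xyzB)
  d2[d2 < 0] <- 0
  dist <- sqrt(d2)
  ridA <- factor(paste0(aA$chain, ":", aA$resno),
                 levels = unique(paste0(selA$chain, ":", selA$resno)))
  ridB <- factor(paste0(aB$chain, ":", aB$resno),
                 levels = unique(paste0(selB$chain, ":", selB$resno)))
  lvA <- levels(droplevels(ridA)); lvB <- levels(droplevels(ridB))
  out <- matrix(Inf, length(lvA), length(lvB), dimnames = list(lvA, lvB))
  ia <- match(as.character(ridA), lvA); ib <- match(as.character(ridB), lvB)
  for (i in seq_along(ia)) {
    row <- dist[i, ]
    cur <- out[ia[i], ]
    agg <- tapply(row, ib, min)
    upd <- pmin(cur[as.integer(names(agg))], agg)
    out[ia[i], as.integer(names(agg))] <- upd
  }
  structure(out, class = c("contact_map", "matrix"), atom_mode = atom_mode)
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d x %d residues (%s atoms), min %.2f A\n",
              nrow(x), ncol(x), attr(x, "atom_mode"), min(x)))
  invisible(x)
}

#' Contact pairs below a distance cutoff
#'
#' @param map a `contact_map` from [residue_min_distance_map()].
#' @param cutoff distance cutoff in Angstrom (> 0); pairs with minimum
#'   distance less than or equal to the cutoff are contacts.
#' @return data frame with columns resA, resB, min_dist.
#' @export
contacts <- function(map, cutoff = 4.0) {
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  hit <- which(map <= cutoff, arr.ind = TRUE)
  out <- data.frame(resA = rownames(map)[hit[, 1]],
                    resB = colnames(map)[hit[, 2]],
                    min_dist = map[hit],
                    stringsAsFactors = FALSE)
  out[order(out$resA, out$resB), , drop = FALSE]
}

#' Fraction of CDR residues in contact with the hinge
#'
#' The docking-model selection score: the count of distinct TREM2 CDR
#' residues (CDR1 aa40-47, CDR2 aa67-78, CDR3 aa115-120; 26 residues when
#' complete) having at least one heavy atom within `cutoff` of any heavy
#' atom of the ApoE hinge (aa167-231), divided by the number of CDR residues
#' present.
#'
#' @param query `pdb_structure` holding the TREM2 chain.
#' @param target `pdb_structure` holding the ApoE chain.
#' @param scheme a `region_scheme`; its CDR1/CDR2/CDR3 regions select query
#'   residues and `full_hinge` selects target residues.
#' @param cutoff contact cutoff, Angstrom (default 4.0).
#' @param model_id label carried into the score.
#' @param excluded artifact-exclusion flag (visual-inspection result taken
#'   as input).
#' @param exclusion_reason free text stored when `excluded` is TRUE.
#' @param atom_mode `"heavy"` (default) or `"ca"`.
#' @return a `dock_model_score`: list with model_id, cdr_residues_total,
#'   cdr_residues_in_contact, fraction, contact_resno, excluded, reason.
#' @export
cdr_hinge_fraction <- function(query, target, scheme = default_region_scheme(),
                               cutoff = 4.0, model_id = "model",
                               excluded = FALSE, exclusion_reason = NA_character_,
                               atom_mode = c("heavy", "ca")) {
  atom_mode <- match.arg(atom_mode)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  cdr <- do.call(rbind, lapply(c("CDR1", "CDR2", "CDR3"), function(nm)
    suppressWarnings(select_region(query, scheme, nm))))
  cdr <- unique(cdr)
  hinge <- suppressWarnings(select_region(target, scheme, "full_hinge"))
  if (nrow(cdr) == 0 || nrow(hinge) == 0) {
    stop("CDR or hinge regions resolve to no residues in the supplied structures",
         call. = FALSE)
  }
  map <- residue_min_distance_map(query, cdr, target, hinge,
                                  atom_mode = atom_mode)
  in_contact <- apply(map, 1, min) <= cutoff
  structure(list(
    model_id = model_id,
    cdr_residues_total = nrow(cdr),
    cdr_residues_in_contact = sum(in_contact),
    fraction = sum(in_contact) / nrow(cdr),
    contact_resno = sort(cdr$resno[in_contact]),
    excluded = isTRUE(excluded),
    reason = exclusion_reason
  ), class = "dock_model_score")
}

#' @export
print.dock_model_score <- function(x, ...) {
  cat(sprintf("<dock_model_score> %s: %d/%d CDR residues in contact (%.1f%%)%s\n",
              x$model_id, x$cdr_residues_in_contact, x$cdr_residues_total,
              100 * x$fraction,
              if (x$excluded) sprintf(" [EXCLUDED: %s]", x$reason) else ""))
  invisible(x)
}

#' Rank docked models by CDR-hinge contact fraction
#'
#' Stable descending sort by fraction with ties broken by model id; the
#' selected model is the first non-excluded one (models flagged as docking
#' artifacts are skipped but retained in the ranking).
#'
#' @param scores list of `dock_model_score` objects.
#' @return data frame (model_id, fraction, in_contact, total, excluded,
#'   selected) ordered by rank, with attribute `selected` (the chosen model
#'   id).
#' @export
rank_dock_models <- function(scores) {
  if (length(scores) == 0) stop("no models to rank", call. = FALSE)
  df <- do.call(rbind, lapply(scores, function(s) data.frame(
    model_id = s$model_id, fraction = s$fraction,
    in_contact = s$cdr_residues_in_contact, total = s$cdr_residues_total,
    excluded = s$excluded, stringsAsFactors = FALSE)))
  df <- df[order(-df$fraction, df$model_id), , drop = FALSE]
  rownames(df) <- NULL
  eligible <- which(!df$excluded)
  if (length(eligible) == 0) {
    stop("all models are excluded as artifacts; no valid model", call. = FALSE)
  }
  df$selected <- seq_len(nrow(df)) == eligible[1]
  attr(df, "selected") <- df$model_id[eligible[1]]
  df
}

#' Overlap between observed and literature interface residues
#'
#' @param observed,literature vectors of residue identifiers (numbers or
#'   labels).
#' @return list with `intersection` (count), `jaccard` (|intersection| /
#'   |union|), and `shared` (the common residues).
#' @export
residue_set_overlap <- function(observed, literature) {
  observed <- unique(observed); literature <- unique(literature)
  if (length(observed) == 0 && length(literature) == 0) {
    stop("Jaccard index undefined: both sets empty", call. = FALSE)
  }
  shared <- intersect(observed, literature)
  list(intersection = length(shared),
       jaccard = length(shared) / length(union(observed, literature)),
       shared = shared)
}
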