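#' @title Structural data model and PDB input/output
#' @description Internal data model: a `pdb_structure` holds an atom table
#'   (serial, name, resname, chain, resno, x, y, z, element, is_heavy); an
#'   `md_trajectory` holds one topology plus a frames x atoms x 3 coordinate
#'   array and per-frame times in nanoseconds.
#' @name structure-io
NULL

# fixed PDB columns (1-based, inclusive)
.pdb_cols <- list(
  record = c(1L, 6L), serial = c(7L, 11L), name = c(13L, 16L),
  altloc = c(17L, 17L), resname = c(18L, 20L), chain = c(22L, 22L),
  resno = c(23L, 26L), icode = c(27L, 27L), x = c(31L, 38L),
  y = c(39L, 46L), z = c(47L, 54L), element = c(77L, 78L)
)

.substr_col <- function(lines, col) trimws(substring(lines, col[1], col[2]))

.num_field <- function(txt, lineno, field) {
  val <- suppressWarnings(as.numeric(txt))
  bad <- is.na(val) | !is.finite(val)
  if (any(bad)) {
    stop(sprintf("malformed %s field '%s' in PDB line %d", field,
                 txt[which(bad)[1]], lineno[which(bad)[1]]), call. = FALSE)
  }
  val
}

.guess_element <- function(name) {
  # strip digits/primes; two-letter elements in toy data are rare, first
  # alphabetic character is the element for standard protein atoms
  stripped <- gsub("[^A-Za-z]", "", name)
  toupper(substring(stripped, 1, 1))
}

# Parse ATOM/HETATM lines (with their original line numbers) into an atom table.
.parse_atom_lines <- function(lines, lineno) {
  if (length(lines) == 0) {
    stop("no ATOM/HETATM records found (empty input)", call. = FALSE)
  }
  icode <- .substr_col(lines, .pdb_cols$icode)
  if (any(icode != "")) {
    stop(sprintf("insertion codes are not supported (first at line %d)",
                 lineno[which(icode != "")[1]]), call. = FALSE)
  }
  atoms <- data.frame(
    serial  = .num_field(.substr_col(lines, .pdb_cols$serial), lineno, "serial"),
    name    = .substr_col(lines, .pdb_cols$name),
    altloc  = .substr_col(lines, .pdb_cols$altloc),
    resname = .substr_col(lines, .pdb_cols$resname),
    chain   = .substr_col(lines, .pdb_cols$chain),
    resno   = as.integer(.num_field(.substr_col(lines, .pdb_cols$resno),
                                    lineno, "residue-number")),
    x = .num_field(.substr_col(lines, .pdb_cols$x), lineno, "x"),
    y = .num_field(.substr_col(lines, .pdb_cols$y), lineno, "y"),
    z = .num_field(.substr_col(lines, .pdb_cols$z), lineno, "z"),
    element = .substr_col(lines, .pdb_cols$element),
    stringsAsFactors = FALSE
  )
  missing_el <- atoms$element == ""
  atoms$element[missing_el] <- .guess_element(atoms$name[missing_el])
  # keep the first altloc per (chain, resno, name)
  key <- paste(atoms$chain, atoms$resno, atoms$name, sep = "\r")
  keep <- !duplicated(key)
  atoms <- atoms[keep, , drop = FALSE]
  atoms$altloc <- NULL
  atoms$is_heavy <- atoms$element != "H"
  rownames(atoms) <- NULL
  atoms
}

.new_structure <- function(atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  structure(list(atoms = atoms), class = "pdb_structure")
}

.read_source_lines <- function(source) {
  if (inherits(source, "connection")) return(readLines(source))
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    return(readLines(source))
  }
  unlist(strsplit(source, "\n", fixed = TRUE))
}

#' Read a single-model PDB file
#'
#' Parses ATOM/HETATM records with fixed-column semantics. Hydrogens are
#' parsed and flagged (`is_heavy = FALSE`); only the first alternate location
#' of an atom is kept; insertion codes are rejected. Residue numbers are kept
#' exactly as authored in the file (no renumbering).
#'
#' @param source a file path, connection, or character vector/string of PDB
#'   text.
#' @return a `pdb_structure`: a list with element `atoms`, a data frame with
#'   columns serial, name, resname, chain, resno, x, y, z, element, is_heavy.
#' @examples
#' pdb <- read_pdb(c(
#'   "ATOM      1  CA  ALA A   1       0.000   0.000   0.000           C",
#'   "ATOM      2  CA  GLY A   2       3.800   0.000   0.000           C"))
#' nrow(pdb$atoms)
#' @export
read_pdb <- function(source) {
  lines <- .read_source_lines(source)
  if (sum(startsWith(lines, "MODEL ") | lines == "MODEL") > 1) {
    stop("multiple MODEL records found; use read_multimodel_pdb()",
         call. = FALSE)
  }
  rec <- substring(lines, 1, 6)
  is_atom <- startsWith(rec, "ATOM") | startsWith(rec, "HETATM")
  .new_structure(.parse_atom_lines(lines[is_atom], which(is_atom)))
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL/ENDMDL block becomes one frame; all models must share the same
#' atoms in the same order. Frame times are `0, dt, 2 dt, ...` nanoseconds. A
#' file without MODEL records is read as a single-frame trajectory.
#'
#' @param source file path, connection, or PDB text.
#' @param frame_dt time spacing between successive models, ns.
#' @param t0 time of the first frame, ns (default 0).
#' @return an `md_trajectory`: list with `topology` (a `pdb_structure`),
#'   `coords` (frames x atoms x 3 array, Angstrom) and `times` (ns).
#' @export
read_multimodel_pdb <- function(source, frame_dt = 0.5, t0 = 0) {
  lines <- .read_source_lines(source)
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0) {
    s <- read_pdb(lines)
    return(.new_trajectory(s, array(as.matrix(s$atoms[, c("x", "y", "z")]),
                                    dim = c(1, nrow(s$atoms), 3)),
                           times = t0))
  }
  model_ends <- which(startsWith(lines, "ENDMDL"))
  if (length(model_ends) != length(model_starts)) {
    stop("unbalanced MODEL/ENDMDL records", call. = FALSE)
  }
  frames <- vector("list", length(model_starts))
  topo_atoms <- NULL
  for (m in seq_along(model_starts)) {
    block <- seq(model_starts[m] + 1L, model_ends[m] - 1L)
    rec <- substring(lines[block], 1, 6)
    is_atom <- startsWith(rec, "ATOM") | startsWith(rec, "HETATM")
    atoms <- .parse_atom_lines(lines[block][is_atom], block[is_atom])
    if (m == 1) {
      topo_atoms <- atoms
    } else {
      if (nrow(atoms) != nrow(topo_atoms)) {
        stop(sprintf(
          "structural inconsistency: model %d has %d atoms, model 1 has %d",
          m, nrow(atoms), nrow(topo_atoms)), call. = FALSE)
      }
      same <- all(atoms$chain == topo_atoms$chain) &&
        all(atoms$resno == topo_atoms$resno) &&
        all(atoms$name == topo_atoms$name)
      if (!same) {
        stop(sprintf("structural inconsistency: model %d atom identity differs from model 1", m),
             call. = FALSE)
      }
    }
    frames[[m]] <- as.matrix(atoms[, c("x", "y", "z")])
  }
  n <- length(frames)
  coords <- array(NA_real_, dim = c(n, nrow(topo_atoms), 3))
  for (m in seq_len(n)) coords[m, , ] <- frames[[m]]
  .new_trajectory(.new_structure(topo_atoms), coords,
                  times = t0 + frame_dt * (seq_len(n) - 1))
}

.new_trajectory <- function(topology, coords, times) {
  stopifnot(inherits(topology, "pdb_structure"),
            length(dim(coords)) == 3,
            dim(coords)[2] == nrow(topology$atoms),
            dim(coords)[3] == 3,
            dim(coords)[1] == length(times))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  structure(list(topology = topology, coords = coords, times = as.numeric(times)),
            class = "md_trajectory")
}

.format_atom_line <- function(a, serial) {
  name <- a$name
  # standard PDB alignment: 1-3 character names start in column 14
  name <- ifelse(nchar(name) < 4, sprintf(" %-3s", name), name)
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, a$resname, a$chain, a$resno, a$x, a$y, a$z, a$element)
}

#' Write a structure as a single-model PDB file
#'
#' @param structure a `pdb_structure`.
#' @param file path or connection; if `NULL` the PDB text is returned as a
#'   character vector.
#' @return invisibly, the PDB lines.
#' @export
write_pdb <- function(structure, file = NULL) {
  stopifnot(inherits(structure, "pdb_structure"))
  a <- structure$atoms
  lines <- c(vapply(seq_len(nrow(a)),
                    function(i) .format_atom_line(a[i, ], i), character(1)),
             "TER", "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param trajectory an `md_trajectory`.
#' @param file path or connection; if `NULL` the text is returned.
#' @return invisibly, the PDB lines.
#' @export
write_multimodel_pdb <- function(trajectory, file = NULL) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  a <- trajectory$topology$atoms
  n_frames <- dim(trajectory$coords)[1]
  out <- character(0)
  for (m in seq_len(n_frames)) {
    am <- a
    am$x <- trajectory$coords[m, , 1]
    am$y <- trajectory$coords[m, , 2]
    am$z <- trajectory$coords[m, , 3]
    out <- c(out, sprintf("MODEL     %4d", m),
             vapply(seq_len(nrow(am)),
                    function(i) .format_atom_line(am[i, ], i), character(1)),
             "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' Extract one frame of a trajectory as a structure
#' @param trajectory an `md_trajectory`.
#' @param frame frame index (1-based).
#' @return a `pdb_structure` with that frame's coordinates.
#' @export
trajectory_frame <- function(trajectory, frame) {
  stopifnot(inherits(trajectory, "md_trajectory"),
            frame >= 1, frame <= dim(trajectory$coords)[1])
  a <- trajectory$topology$atoms
  a$x <- trajectory$coords[frame, , 1]
  a$y <- trajectory$coords[frame, , 2]
  a$z <- trajectory$coords[frame, , 3]
  .new_structure(a)
}

#' @export
print.pdb_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<pdb_structure> %d atoms, %d residues, chains: %s\n",
              nrow(a), nrow(unique(a[, c("chain", "resno")])),
              paste(unique(a$chain), collapse = ", ")))
  invisible(x)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d atoms, t = %.3g..%.3g ns\n",
              dim(x$coords)[1], dim(x$coords)[2],
              min(x$times), max(x$times)))
  invisible(x)
}

#' Define a region scheme (named residue-range sets)
#'
#' A region scheme names sets of residue numbers (author numbering as stored
#' in the PDB) such as the TREM2 CDR loops or the ApoE hinge. An optional
#' per-chain numbering offset maps scheme numbering onto a structure whose
#' author numbering is shifted (offset is added to scheme residue numbers
#' before matching).
#'
#' @param regions named list of integer vectors of residue numbers.
#' @param chains optional named character vector mapping region name to a
#'   chain id; regions without an entry match any chain.
#' @param offsets named numeric vector of per-chain numbering offsets
#'   (chain id -> offset); chains not listed use 0.
#' @param note free-text numbering note.
#' @return a `region_scheme` object.
#' @export
region_scheme <- function(regions, chains = NULL, offsets = numeric(0),
                          note = "") {
  stopifnot(is.list(regions), length(regions) > 0,
            !is.null(names(regions)), all(nzchar(names(regions))))
  regions <- lapply(regions, function(r) sort(unique(as.integer(r))))
  if (any(vapply(regions, length, integer(1)) == 0)) {
    stop("region residue sets must be non-empty", call. = FALSE)
  }
  structure(list(regions = regions, chains = chains,
                 offsets = offsets, note = note),
            class = "region_scheme")
}

#' Default TREM2/ApoE region scheme
#'
#' CDR1 aa40-47, CDR2 aa67-78, CDR3 aa115-120 on the TREM2 Ig-like domain;
#' ApoE canonical hinge aa167-191, extended hinge aa192-231, and the combined
#' hinge aa167-231 used by the docking filter.
#'
#' @return a `region_scheme`.
#' @export
default_region_scheme <- function() {
  region_scheme(
    regions = list(
      CDR1 = 40:47, CDR2 = 67:78, CDR3 = 115:120,
      hinge = 167:191, extended_hinge = 192:231, full_hinge = 167:231
    ),
    note = paste("TREM2 Ig domain author numbering (residues ~20-131);",
                 "ApoE mature-protein numbering 1-299")
  )
}

#' @export
print.region_scheme <- function(x, ...) {
  cat("<region_scheme>\n")
  for (nm in names(x$regions)) {
    r <- x$regions[[nm]]
    cat(sprintf("  %-14s %d residues (%d-%d)\n", nm, length(r), min(r), max(r)))
  }
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Resolve a named region against a structure
#'
#' Returns the residues of the structure that fall inside the named region,
#' sorted by (chain, residue number). Region residues absent from the
#' structure are skipped and reported via the `"skipped"` attribute; an empty
#' intersection raises a warning and returns a zero-row table.
#'
#' @param structure a `pdb_structure`.
#' @param scheme a `region_scheme`.
#' @param name region name present in the scheme.
#' @return data frame with columns chain, resno, resname and attribute
#'   `skipped` (region residue numbers not present in the structure).
#' @export
select_region <- function(structure, scheme, name) {
  stopifnot(inherits(structure, "pdb_structure"),
            inherits(scheme, "region_scheme"))
  if (!name %in% names(scheme$regions)) {
    stop(sprintf("unknown region '%s'; available: %s", name,
                 paste(names(scheme$regions), collapse = ", ")), call. = FALSE)
  }
  want <- scheme$regions[[name]]
  chain_filter <- if (!is.null(scheme$chains) && name %in% names(scheme$chains))
    scheme$chains[[name]] else NA_character_
  res <- unique(structure$atoms[, c("chain", "resno", "resname")])
  if (!is.na(chain_filter)) res <- res[res$chain == chain_filter, , drop = FALSE]
  off <- function(ch) {
    if (length(scheme$offsets) && ch %in% names(scheme$offsets))
      scheme$offsets[[ch]] else 0
  }
  res$scheme_resno <- res$resno - vapply(res$chain, off, numeric(1))
  hit <- res[res$scheme_resno %in% want, , drop = FALSE]
  hit <- hit[order(hit$chain, hit$resno), c("chain", "resno", "resname")]
  rownames(hit) <- NULL
  skipped <- setdiff(want, res$scheme_resno[res$scheme_resno %in% want])
  if (nrow(hit) == 0) {
    warning(sprintf("region '%s' has no residues in this structure", name),
            call. = FALSE)
  }
  attr(hit, "skipped") <- skipped
  hit
}

#' C-alpha coordinates of selected residues, per frame
#'
#' @param trajectory an `md_trajectory`.
#' @param residues data frame with columns chain, resno (e.g. from
#'   [select_region()]); column order is preserved in the output.
#' @return frames x residues x 3 array of CA coordinates (Angstrom).
#' @export
ca_coordinates <- function(trajectory, residues) {
  stopifnot(inherits(trajectory, "md_trajectory"), nrow(residues) >= 1)
  a <- trajectory$topology$atoms
  idx <- vapply(seq_len(nrow(residues)), function(i) {
    j <- which(a$chain == residues$chain[i] & a$resno == residues$resno[i] &
                 a$name == "CA")
    if (length(j) == 0) {
      stop(sprintf("residue %s:%d has no CA atom",
                   residues$chain[i], residues$resno[i]), call. = FALSE)
    }
    j[1]
  }, integer(1))
  out <- trajectory$coords[, idx, , drop = FALSE]
  dimnames(out) <- list(NULL, paste0(residues$chain, residues$resno), c("x", "y", "z"))
  out
}
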