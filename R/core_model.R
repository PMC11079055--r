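# Structure / trajectory data model and plain-text I/O shared by all
# analysis stages. A StructureFrame stores its atoms as a flat data.frame
# (one row per atom), the representation used by most R structural tools;
# residues are row groups keyed by (chain_id, resseq).

ATOM_COLUMNS <- c("chain_id", "resseq", "resname", "atom_name", "element",
                  "x", "y", "z")

# Standard atomic masses (u) for centre-of-mass computations.
ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, K = 39.098)

#' Create a structure frame
#'
#' A `StructureFrame` is one conformation: a table of atoms grouped into
#' residues and chains, with coordinates in Angstrom and PDB-style 1-based
#' residue numbering.
#'
#' @param atoms data.frame with columns `chain_id`, `resseq`, `resname`,
#'   `atom_name`, `element`, `x`, `y`, `z`.
#' @param time_ns optional non-negative frame time in nanoseconds.
#' @return An object of class `StructureFrame`.
#' @export
structure_frame <- function(atoms, time_ns = NA_real_) {
  stopifnot(is.data.frame(atoms))
  missing_cols <- setdiff(ATOM_COLUMNS, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[, ATOM_COLUMNS]
  atoms$resseq <- as.integer(atoms$resseq)
  for (cc in c("x", "y", "z")) atoms[[cc]] <- as.numeric(atoms[[cc]])
  if (nrow(atoms) == 0L) stop("a StructureFrame needs at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  if (any(!nzchar(atoms$atom_name))) stop("empty atom names in atom table")
  if (!is.na(time_ns) && time_ns < 0) stop("time_ns must be non-negative")
  # (chain, resseq) must map to a single residue name
  key <- paste(atoms$chain_id, atoms$resseq)
  pairs <- unique(data.frame(key = key, rn = atoms$resname))
  if (nrow(pairs) > length(unique(key))) {
    stop("conflicting residue names for the same (chain, resseq)")
  }
  structure(list(atoms = atoms, time_ns = time_ns), class = "StructureFrame")
}

#' @export
print.StructureFrame <- function(x, ...) {
  cat(sprintf("StructureFrame: %d atoms, %d residues, chains [%s]%s\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain_id", "resseq")])),
              paste(unique(x$atoms$chain_id), collapse = ", "),
              if (is.na(x$time_ns)) "" else sprintf(", t = %g ns", x$time_ns)))
  invisible(x)
}

#' Select atoms of a frame
#'
#' @param frame `StructureFrame`.
#' @param chain_id,resseq,atom_name optional filters (vectors allowed).
#' @param heavy_only drop hydrogens (by element, not name prefix).
#' @return data.frame of matching atom rows.
#' @export
select_atoms <- function(frame, chain_id = NULL, resseq = NULL,
                         atom_name = NULL, heavy_only = FALSE) {
  a <- frame$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain_id)) keep <- keep & a$chain_id %in% chain_id
  if (!is.null(resseq))   keep <- keep & a$resseq %in% as.integer(resseq)
  if (!is.null(atom_name)) keep <- keep & a$atom_name %in% atom_name
  if (heavy_only) keep <- keep & a$element != "H"
  a[keep, , drop = FALSE]
}

#' Look up one residue of a frame
#'
#' @inheritParams select_atoms
#' @return data.frame of the residue's atom rows (error if absent).
#' @export
get_residue <- function(frame, chain_id, resseq) {
  r <- select_atoms(frame, chain_id = chain_id, resseq = resseq)
  if (nrow(r) == 0L) {
    stop(sprintf("no residue (%s, %d) in frame", chain_id, as.integer(resseq)))
  }
  r
}

# Side chain = heavy atoms excluding backbone N, CA, C, O.
sidechain_atoms <- function(residue_atoms) {
  keep <- !(residue_atoms$atom_name %in% c("N", "CA", "C", "O", "OXT")) &
    residue_atoms$element != "H"
  residue_atoms[keep, , drop = FALSE]
}

atom_xyz <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

same_topology <- function(f1, f2) {
  a1 <- f1$atoms; a2 <- f2$atoms
  nrow(a1) == nrow(a2) &&
    all(a1$chain_id == a2$chain_id) && all(a1$resseq == a2$resseq) &&
    all(a1$atom_name == a2$atom_name)
}

#' Create a trajectory
#'
#' @param frames list of `StructureFrame`s sharing one topology, with
#'   strictly increasing times.
#' @param condition list with `pH_label` ("high"/"low"), `variant`
#'   ("WT"/"H122N"/other) and `replicate_id`.
#' @param dt_ns frame spacing in ns; inferred from frame times when `NULL`.
#' @return Object of class `Trajectory`.
#' @export
trajectory <- function(frames,
                       condition = list(pH_label = NA, variant = NA,
                                        replicate_id = NA),
                       dt_ns = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  times <- vapply(frames, function(f) f$time_ns, numeric(1))
  if (anyNA(times)) {
    if (is.null(dt_ns)) dt_ns <- 1
    times <- (seq_along(frames) - 1) * dt_ns
    for (i in seq_along(frames)) frames[[i]]$time_ns <- times[i]
  }
  if (any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  for (i in seq_along(frames)[-1]) {
    if (!same_topology(frames[[1]], frames[[i]])) {
      stop(sprintf("frame %d does not share the topology of frame 1", i))
    }
  }
  if (is.null(dt_ns)) {
    dt_ns <- if (length(times) > 1L) times[2] - times[1] else NA_real_
  }
  structure(list(frames = frames, condition = condition, dt_ns = dt_ns),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, dt = %s ns, pH=%s variant=%s rep=%s\n",
              length(x$frames), format(x$dt_ns),
              x$condition$pH_label, x$condition$variant,
              x$condition$replicate_id))
  invisible(x)
}

frame_times <- function(traj) {
  vapply(traj$frames, function(f) f$time_ns, numeric(1))
}

# ---------------------------------------------------------------------------
# PDB I/O (ATOM/HETATM/MODEL/ENDMDL subset)

parse_pdb_atoms <- function(lines, lineno) {
  n <- length(lines)
  field <- function(from, to) trimws(substr(lines, from, to))
  altloc <- substr(lines, 17, 17)
  icode <- substr(lines, 27, 27)
  bad_icode <- which(!icode %in% c(" ", ""))
  if (length(bad_icode) > 0L) {
    stop(sprintf("insertion codes are unsupported (line %d)",
                 lineno[bad_icode[1]]))
  }
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(field(from, to)))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop(sprintf("malformed %s field in PDB record at line %d",
                   what, lineno[bad[1]]))
    }
    v
  }
  element <- field(77, 78)
  name <- field(13, 16)
  if (any(!nzchar(name))) {
    stop(sprintf("missing atom name in PDB record at line %d",
                 lineno[which(!nzchar(name))[1]]))
  }
  # infer element from the name when column 77-78 is absent
  miss <- !nzchar(element)
  if (any(miss)) {
    stripped <- gsub("[^A-Za-z]", "", name[miss])
    element[miss] <- toupper(substr(stripped, 1, 1))
  }
  occ <- suppressWarnings(as.numeric(field(55, 60)))
  occ[!is.finite(occ)] <- 1
  atoms <- data.frame(
    chain_id = substr(lines, 22, 22),
    resseq = as.integer(num(23, 26, "residue number")),
    resname = field(18, 20),
    atom_name = name,
    element = element,
    x = num(31, 38, "x coordinate"),
    y = num(39, 46, "y coordinate"),
    z = num(47, 54, "z coordinate"),
    stringsAsFactors = FALSE
  )
  # altloc: keep the highest-occupancy conformer, ties resolved toward 'A'
  # (then alphabetically), applied per (chain, resseq, atom name)
  alt <- ifelse(altloc %in% c(" ", ""), "", altloc)
  if (any(nzchar(alt))) {
    key <- paste(atoms$chain_id, atoms$resseq, atoms$atom_name)
    ord <- order(key, -occ, alt)
    keep <- ord[!duplicated(key[ord])]
    atoms <- atoms[sort(keep), , drop = FALSE]
  }
  atoms
}

#' Read a structure from a PDB file
#'
#' Parses the ATOM/HETATM records of a PDB file into a [structure_frame()].
#' For multi-model files only the first model is read (use
#' [read_trajectory()] for all models). Alternate locations keep the
#' highest-occupancy conformer; insertion codes are rejected.
#'
#' @param path PDB file path.
#' @return `StructureFrame`.
#' @export
read_structure <- function(path) {
  models <- read_pdb_models(path)
  models[[1]]
}

read_pdb_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty PDB file: ", path)
  rec <- substr(lines, 1, 6)
  is_atom <- trimws(rec) %in% c("ATOM", "HETATM")
  model_id <- cumsum(trimws(rec) == "MODEL")
  if (max(model_id) == 0L) model_id <- model_id + 1L
  atom_idx <- which(is_atom)
  if (length(atom_idx) == 0L) stop("no ATOM/HETATM records in ", path)
  models <- split(atom_idx, model_id[atom_idx])
  lapply(models, function(idx) {
    structure_frame(parse_pdb_atoms(lines[idx], idx))
  })
}

format_pdb_atom_line <- function(serial, a) {
  name <- a$atom_name
  # PDB convention: 1-3 character names start in column 14
  name_field <- if (nchar(name) >= 4L) {
    substr(name, 1, 4)
  } else {
    sprintf(" %-3s", name)
  }
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, name_field, substr(a$resname, 1, 3),
          substr(a$chain_id, 1, 1), a$resseq %% 10000L,
          a$x, a$y, a$z, 1, 0, a$element)
}

write_frame_lines <- function(frame) {
  a <- frame$atoms
  vapply(seq_len(nrow(a)),
         function(i) format_pdb_atom_line(i, a[i, ]),
         character(1))
}

#' Write a structure to a PDB file
#'
#' @param frame `StructureFrame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(frame, path) {
  writeLines(c(write_frame_lines(frame), "END"), path)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj `Trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  out <- unlist(lapply(seq_along(traj$frames), function(i) {
    c(sprintf("MODEL     %4d", i),
      write_frame_lines(traj$frames[[i]]),
      "ENDMDL")
  }))
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read a trajectory
#'
#' Reads either a multi-model PDB file (models become frames, spaced by
#' `dt_ns`) or a delimited per-frame coordinate table with columns
#' `time_ns`, `chain_id`, `resseq`, `resname`, `atom_name`, `element`,
#' `x`, `y`, `z` (frame spacing inferred from the time column).
#'
#' @param path input file.
#' @param dt_ns frame spacing in ns for multi-model PDB input (default 1).
#' @param condition condition metadata list, see [trajectory()].
#' @return `Trajectory`.
#' @export
read_trajectory <- function(path,
                            dt_ns = NULL,
                            condition = list(pH_label = NA, variant = NA,
                                             replicate_id = NA)) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^(MODEL|ATOM|HETATM|REMARK|HEADER|TITLE|CRYST)", first)) {
    models <- read_pdb_models(path)
    n_atoms <- vapply(models, function(m) nrow(m$atoms), integer(1))
    if (length(unique(n_atoms)) != 1L) {
      stop("inconsistent atom counts across PDB models")
    }
    if (is.null(dt_ns)) dt_ns <- 1
    for (i in seq_along(models)) models[[i]]$time_ns <- (i - 1) * dt_ns
    trajectory(models, condition = condition, dt_ns = dt_ns)
  } else {
    tab <- read_table(path)
    need <- c("time_ns", ATOM_COLUMNS)
    if (!all(need %in% names(tab))) {
      stop("coordinate table needs columns: ", paste(need, collapse = ", "))
    }
    times <- sort(unique(tab$time_ns))
    frames <- lapply(times, function(tt) {
      structure_frame(tab[tab$time_ns == tt, ATOM_COLUMNS],
                      time_ns = tt)
    })
    trajectory(frames, condition = condition, dt_ns = dt_ns)
  }
}

# ---------------------------------------------------------------------------
# Tabular I/O. All numeric output uses a fixed %.6g precision so that
# write -> read round-trips are stable to ~1e-6 relative error.

TABLE_DIGITS <- 6L

#' Write a rectangular table as TSV/CSV with a header
#'
#' Numbers are serialized with 6 significant digits; re-reading reproduces
#' values within that precision.
#'
#' @param records data.frame.
#' @param path output file.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- sprintf(paste0("%.", TABLE_DIGITS, "g"), out[[j]])
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = if (format == "tsv") "\t" else ",",
                       quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a TSV/CSV table written by [write_table()]
#'
#' @param path input file.
#' @return data.frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
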