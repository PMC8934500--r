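#' Protein structure and trajectory containers
#'
#' A `polymer_structure` is a light S3 record holding an atom table (one row
#' per atom, with fixed columns `serial`, `atom_name`, `residue_code`,
#' `chain_id`, `residue_index`, `x`, `y`, `z`; coordinates in Angstrom) plus
#' free-form metadata. A `trajectory` couples one reference topology (a
#' `polymer_structure`) with an ordered list of coordinate frames and their
#' times in nanoseconds.
#'
#' @param atoms A data frame with the atom columns listed above.
#' @param metadata A named list of free-form metadata.
#' @return `polymer_structure()` returns an object of class
#'   `polymer_structure`.
#' @export
polymer_structure <- function(atoms, metadata = list()) {
  atoms <- as_tibble(atoms)
  required <- c("serial", "atom_name", "residue_code", "chain_id",
                "residue_index", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "coilscreen_validation_error")
  }
  atoms <- atoms[required]
  atoms$serial <- as.integer(atoms$serial)
  atoms$residue_index <- as.integer(atoms$residue_index)
  s <- structure(list(atoms = atoms, metadata = metadata),
                 class = "polymer_structure")
  validate_structure(s)
  s
}

validate_structure <- function(s) {
  atoms <- s$atoms
  if (nrow(atoms) == 0) {
    abort("structure has no atoms", class = "coilscreen_validation_error")
  }
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    abort("atom coordinates must be finite",
          class = "coilscreen_validation_error")
  }
  if (any(!nzchar(atoms$atom_name))) {
    abort("atom_name must be non-empty",
          class = "coilscreen_validation_error")
  }
  bad_code <- setdiff(unique(atoms$residue_code), unname(.aa_three))
  if (length(bad_code) > 0) {
    abort(paste0("non-standard residue code(s): ",
                 paste(bad_code, collapse = ", ")),
          class = "coilscreen_validation_error")
  }
  if (any(atoms$residue_index < 1L) || any(atoms$serial < 1L)) {
    abort("serial and residue_index must be positive",
          class = "coilscreen_validation_error")
  }
  # one residue_code per (chain, residue_index)
  res <- unique(atoms[c("chain_id", "residue_index", "residue_code")])
  key <- paste(res$chain_id, res$residue_index)
  if (anyDuplicated(key)) {
    abort("conflicting residue codes for the same (chain, residue_index)",
          class = "coilscreen_validation_error")
  }
  invisible(s)
}

#' @export
print.polymer_structure <- function(x, ...) {
  res <- residues(x)
  cat(sprintf("<polymer_structure> %d chain(s), %d residues, %d atoms\n",
              length(chains(x)), nrow(res), nrow(x$atoms)))
  invisible(x)
}

#' @rdname polymer_structure
#' @param s,x A `polymer_structure`.
#' @return `chains()` returns the ordered chain identifiers.
#' @export
chains <- function(s) unique(s$atoms$chain_id)

#' @rdname polymer_structure
#' @return `residues()` returns a tibble with one row per residue
#'   (`chain_id`, `residue_index`, `residue_code`) in atom order.
#' @export
residues <- function(s) {
  as_tibble(unique(s$atoms[c("chain_id", "residue_index", "residue_code")]))
}

#' @rdname polymer_structure
#' @param chain Chain identifier.
#' @return `chain_sequence()` returns the chain's 1-letter sequence string.
#' @export
chain_sequence <- function(s, chain) {
  res <- residues(s)
  res <- res[res$chain_id == chain, ]
  if (nrow(res) == 0) {
    abort(paste0("no such chain: ", chain),
          class = "coilscreen_validation_error")
  }
  paste(aa3_to_aa1(res$residue_code), collapse = "")
}

coords_matrix <- function(s) {
  m <- cbind(s$atoms$x, s$atoms$y, s$atoms$z)
  colnames(m) <- c("x", "y", "z")
  m
}

set_coords <- function(s, m) {
  stopifnot(nrow(m) == nrow(s$atoms), ncol(m) == 3)
  s$atoms$x <- m[, 1]
  s$atoms$y <- m[, 2]
  s$atoms$z <- m[, 3]
  s
}

#' @rdname polymer_structure
#' @param topology A `polymer_structure` giving the shared topology.
#' @param frames List of n_atoms-by-3 coordinate matrices (Angstrom).
#' @param frame_times Numeric vector of frame times in nanoseconds,
#'   strictly increasing, one per frame.
#' @param replicate_id Integer tag for the simulation replicate.
#' @return `trajectory()` returns an object of class `trajectory`.
#' @export
trajectory <- function(topology, frames, frame_times,
                       replicate_id = 1L, metadata = list()) {
  n_atoms <- nrow(topology$atoms)
  if (length(frames) == 0) {
    abort("trajectory must have at least one frame",
          class = "coilscreen_validation_error")
  }
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n_atoms &&
                 ncol(f) == 3, logical(1))
  if (!all(ok)) {
    abort("every frame must be an n_atoms-by-3 matrix congruent with the topology",
          class = "coilscreen_topology_error")
  }
  if (length(frame_times) != length(frames)) {
    abort("frame_times length must equal frame count",
          class = "coilscreen_validation_error")
  }
  if (length(frame_times) > 1 && any(diff(frame_times) <= 0)) {
    abort("frame_times must be strictly increasing",
          class = "coilscreen_validation_error")
  }
  structure(list(topology = topology, frames = frames,
                 frame_times = as.numeric(frame_times),
                 replicate_id = as.integer(replicate_id),
                 metadata = metadata),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames (%.3g-%.3g ns), %d atoms, replicate %d\n",
              length(x$frames), min(x$frame_times), max(x$frame_times),
              nrow(x$topology$atoms), x$replicate_id))
  invisible(x)
}

#' @rdname polymer_structure
#' @param t A `trajectory`.
#' @param i Frame number.
#' @return `frame_structure()` returns frame `i` as a `polymer_structure`.
#' @export
frame_structure <- function(t, i) {
  if (i < 1 || i > length(t$frames)) {
    abort("frame index out of range", class = "coilscreen_validation_error")
  }
  set_coords(t$topology, t$frames[[i]])
}

# ---------------------------------------------------------------------------
# PDB reading

parse_atom_line <- function(line, lineno) {
  get <- function(a, b) trimws(substr(line, a, b))
  altloc <- get(17, 17)
  icode <- get(27, 27)
  if (nzchar(altloc)) {
    abort(sprintf("line %d: alternate locations are not supported", lineno),
          class = "coilscreen_parse_error")
  }
  if (nzchar(icode)) {
    abort(sprintf("line %d: insertion codes are not supported", lineno),
          class = "coilscreen_parse_error")
  }
  serial <- suppressWarnings(as.integer(get(7, 11)))
  resseq <- suppressWarnings(as.integer(get(23, 26)))
  xyz <- suppressWarnings(as.numeric(c(get(31, 38), get(39, 46), get(47, 54))))
  atom_name <- get(13, 16)
  res_code <- get(18, 20)
  chain <- get(22, 22)
  if (is.na(serial) || is.na(resseq) || anyNA(xyz) ||
      !nzchar(atom_name) || !nzchar(res_code) || !nzchar(chain)) {
    abort(sprintf("line %d: malformed ATOM record", lineno),
          class = "coilscreen_parse_error")
  }
  list(serial = serial, atom_name = atom_name, residue_code = res_code,
       chain_id = chain, residue_index = resseq,
       x = xyz[1], y = xyz[2], z = xyz[3])
}

#' Read structures from PDB-format text
#'
#' Parses fixed-column `ATOM` records; `MODEL`/`ENDMDL` blocks are returned as
#' separate structures. Residue numbering is taken verbatim from the `resSeq`
#' column. `HETATM` records, alternate locations and insertion codes are
#' rejected with a parse error; `TER`, `END`, and remark-style records are
#' ignored.
#'
#' @param text A single string (or character vector of lines) of PDB text.
#' @return A list of [polymer_structure()] objects, one per model.
#' @export
read_pdb <- function(text) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  rec <- substr(lines, 1, 6)
  models <- list()
  current <- list()
  n_open <- 0L
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (startsWith(r, "HETATM")) {
      abort(sprintf("line %d: HETATM records are not supported", i),
            class = "coilscreen_parse_error")
    } else if (startsWith(r, "MODEL")) {
      if (length(current) > 0) {
        models[[length(models) + 1L]] <- current
        current <- list()
      }
      n_open <- n_open + 1L
    } else if (startsWith(r, "ENDMDL")) {
      models[[length(models) + 1L]] <- current
      current <- list()
    } else if (r == "ATOM  " || startsWith(r, "ATOM ") || r == "ATOM") {
      current[[length(current) + 1L]] <- parse_atom_line(lines[i], i)
    }
  }
  if (length(current) > 0) models[[length(models) + 1L]] <- current
  models <- models[vapply(models, length, integer(1)) > 0]
  if (length(models) == 0) {
    abort("no ATOM records found in input",
          class = "coilscreen_parse_error")
  }
  lapply(models, function(atom_list) {
    atoms <- bind_rows(lapply(atom_list, as_tibble))
    polymer_structure(atoms)
  })
}

# ---------------------------------------------------------------------------
# PDB writing

format_atom_lines <- function(atoms) {
  if (any(abs(c(atoms$x, atoms$y, atoms$z)) >= 1e5)) {
    abort("coordinate magnitude >= 1e5 Angstrom overflows the PDB field width",
          class = "coilscreen_overflow_error")
  }
  name4 <- ifelse(nchar(atoms$atom_name) < 4,
                  sprintf("%-4s", paste0(" ", atoms$atom_name)),
                  substr(atoms$atom_name, 1, 4))
  body <- sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                  atoms$serial, name4, atoms$residue_code, atoms$chain_id,
                  atoms$residue_index, atoms$x, atoms$y, atoms$z, 1, 0)
  # TER after each chain
  out <- character(0)
  for (ch in unique(atoms$chain_id)) {
    idx <- which(atoms$chain_id == ch)
    out <- c(out, body[idx], "TER")
  }
  out
}

#' Write structures and trajectories as PDB text
#'
#' Emits standard fixed-column `ATOM` records (coordinates to 3 decimals) with
#' `TER` after each chain. Trajectories are written as `MODEL`/`ENDMDL`
#' blocks, making multi-model PDB the on-disk trajectory format.
#'
#' @param s A [polymer_structure()], a [trajectory()], or a list of
#'   structures (written as models).
#' @return A single PDB-format string.
#' @export
write_pdb <- function(s) {
  if (inherits(s, "polymer_structure")) {
    lines <- c(format_atom_lines(s$atoms), "END")
  } else {
    structures <- if (inherits(s, "trajectory")) {
      lapply(seq_along(s$frames), function(i) frame_structure(s, i))
    } else if (is.list(s) && length(s) > 0 &&
                 all(vapply(s, inherits, logical(1), "polymer_structure"))) {
      s
    } else {
      abort("write_pdb() expects a polymer_structure, trajectory, or list of structures",
            class = "coilscreen_validation_error")
    }
    lines <- unlist(lapply(seq_along(structures), function(i) {
      c(sprintf("MODEL     %4d", i),
        format_atom_lines(structures[[i]]$atoms),
        "ENDMDL")
    }))
    lines <- c(lines, "END")
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Read a trajectory from multi-model PDB text
#'
#' All models must be topologically identical (same atoms in the same order).
#' Frame times are taken from `frame_times` when given, else spaced uniformly
#' at `dt` nanoseconds starting at `dt`.
#'
#' @inheritParams read_pdb
#' @param dt Uniform frame spacing in nanoseconds (ignored when `frame_times`
#'   is given).
#' @param frame_times Optional explicit frame times (ns).
#' @param replicate_id Integer replicate tag.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(text, dt = 1, frame_times = NULL,
                            replicate_id = 1L) {
  structures <- read_pdb(text)
  topo <- structures[[1]]
  key <- function(s) paste(s$atoms$atom_name, s$atoms$chain_id,
                           s$atoms$residue_index, s$atoms$residue_code)
  ref_key <- key(topo)
  for (i in seq_along(structures)) {
    if (nrow(structures[[i]]$atoms) != nrow(topo$atoms) ||
        !identical(key(structures[[i]]), ref_key)) {
      abort(sprintf("model %d does not match the topology of model 1", i),
            class = "coilscreen_topology_error")
    }
  }
  if (is.null(frame_times)) {
    frame_times <- dt * seq_along(structures)
  }
  trajectory(topo, lapply(structures, coords_matrix), frame_times,
             replicate_id = replicate_id)
}
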