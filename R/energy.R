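#' Residue-centroid contact potential
#'
#' A pluggable pairwise scoring model over side-chain centroid (`SC`)
#' pseudo-atoms: two residues in contact (centroid distance at or below
#' `contact_cutoff`) contribute the symmetric `pair_energies` entry for
#' their types; pairs at or below `clash_distance` additionally incur
#' `clash_penalty`. Energies are in abstract units.
#'
#' @param pair_energies Symmetric 20x20 numeric matrix with 1-letter row and
#'   column names covering the 20 standard residues.
#' @param contact_cutoff Contact cutoff in Angstrom (default 8.0).
#' @param clash_distance Clash distance in Angstrom (default 2.5); must be
#'   smaller than `contact_cutoff`.
#' @param clash_penalty Energy added per clashing pair (default +10).
#' @return An object of class `contact_potential`.
#' @export
contact_potential <- function(pair_energies,
                              contact_cutoff = 8.0,
                              clash_distance = 2.5,
                              clash_penalty = 10) {
  if (!is.matrix(pair_energies) || !identical(dim(pair_energies), c(20L, 20L))) {
    abort("pair_energies must be a 20x20 matrix",
          class = "coilscreen_validation_error")
  }
  if (!setequal(rownames(pair_energies), .aa_codes) ||
      !setequal(colnames(pair_energies), .aa_codes)) {
    abort("pair_energies must be named by the 20 standard 1-letter codes",
          class = "coilscreen_validation_error")
  }
  pair_energies <- pair_energies[.aa_codes, .aa_codes]
  if (!isTRUE(all.equal(unname(pair_energies), unname(t(pair_energies)),
                        tolerance = 1e-12))) {
    abort("pair_energies must be symmetric",
          class = "coilscreen_validation_error")
  }
  if (!(contact_cutoff > clash_distance && clash_distance > 0)) {
    abort("require contact_cutoff > clash_distance > 0",
          class = "coilscreen_validation_error")
  }
  structure(list(pair_energies = pair_energies,
                 contact_cutoff = contact_cutoff,
                 clash_distance = clash_distance,
                 clash_penalty = clash_penalty),
            class = "contact_potential")
}

#' Default toy contact potential
#'
#' A simple physically-motivated matrix: hydrophobic-hydrophobic attraction
#' (-1.0), an extra aromatic stacking bonus (-0.5 between F/W/Y/H),
#' opposite-charge attraction (-1.5 between K/R and D/E), like-charge
#' repulsion (+1.0), and a weak polar-polar term (-0.2). Fully replaceable
#' via [read_potential()].
#'
#' @inheritParams contact_potential
#' @return A [contact_potential()].
#' @export
default_contact_potential <- function(contact_cutoff = 8.0,
                                      clash_distance = 2.5,
                                      clash_penalty = 10) {
  hydrophobic <- c("A", "V", "L", "I", "M", "F", "W", "C")
  aromatic <- c("F", "W", "Y", "H")
  positive <- c("K", "R")
  negative <- c("D", "E")
  polar <- c("S", "T", "N", "Q", "Y", "H")
  e <- matrix(0, 20, 20, dimnames = list(.aa_codes, .aa_codes))
  e[hydrophobic, hydrophobic] <- e[hydrophobic, hydrophobic] - 1.0
  e[aromatic, aromatic] <- e[aromatic, aromatic] - 0.5
  e[positive, negative] <- e[positive, negative] - 1.5
  e[negative, positive] <- e[negative, positive] - 1.5
  e[positive, positive] <- e[positive, positive] + 1.0
  e[negative, negative] <- e[negative, negative] + 1.0
  e[polar, polar] <- e[polar, polar] - 0.2
  contact_potential(e, contact_cutoff, clash_distance, clash_penalty)
}

#' Read and write contact-potential tables
#'
#' The on-disk format is a whitespace-delimited 20x20 table with a header
#' row and first column of 1-letter residue codes.
#'
#' @param path File path.
#' @param ... Passed to [contact_potential()] (cutoffs, clash penalty).
#' @return `read_potential()` returns a [contact_potential()].
#' @export
read_potential <- function(path, ...) {
  m <- as.matrix(utils::read.table(path, header = TRUE, check.names = FALSE,
                                   row.names = 1))
  contact_potential(m, ...)
}

#' @rdname read_potential
#' @param p A [contact_potential()].
#' @export
write_potential <- function(p, path) {
  utils::write.table(format(p$pair_energies, trim = TRUE), path,
                     quote = FALSE, sep = "\t", col.names = NA)
  invisible(path)
}

# SC centroid table for a structure: indices, 1-letter codes, chain, resno.
sc_table <- function(s) {
  sel <- s$atoms$atom_name == "SC"
  if (!any(sel)) {
    abort("structure has no SC pseudo-atoms; scoring requires them",
          class = "coilscreen_validation_error")
  }
  list(coords = coords_matrix(s)[sel, , drop = FALSE],
       code = aa3_to_aa1(s$atoms$residue_code[sel]),
       chain = s$atoms$chain_id[sel],
       resno = s$atoms$residue_index[sel])
}

# Pair mask over an SC table: excluded are self pairs and (i, i+-1) within a
# chain; returns upper-triangle logical matrix.
pair_mask <- function(chain, resno) {
  n <- length(chain)
  same_chain <- outer(chain, chain, "==")
  near <- abs(outer(resno, resno, "-")) <= 1
  mask <- upper.tri(matrix(TRUE, n, n)) & !(same_chain & near)
  mask
}

score_from_tables <- function(coords, code, chain, resno, p,
                              subset = NULL) {
  if (!is.null(subset)) {
    keep <- chain %in% subset
    coords <- coords[keep, , drop = FALSE]
    code <- code[keep]
    chain <- chain[keep]
    resno <- resno[keep]
  }
  n <- length(code)
  if (n < 2) return(0)
  d <- as.matrix(dist(coords))
  mask <- pair_mask(chain, resno)
  e <- matrix(p$pair_energies[code, code], n, n)
  contact <- mask & (d <= p$contact_cutoff)
  clash <- mask & (d <= p$clash_distance)
  sum(e[contact]) + p$clash_penalty * sum(clash)
}

#' Score a structure with a contact potential
#'
#' Sums pair energies over all unordered residue pairs whose `SC` centroid
#' distance is at or below the contact cutoff, excluding self pairs and
#' sequence neighbours (i, i+-1) within a chain, and adds the clash penalty
#' for every pair at or below the clash distance.
#'
#' @param s A [polymer_structure()] with `SC` pseudo-atoms.
#' @param p A [contact_potential()].
#' @param chain_subset Optional chain identifiers to restrict scoring to.
#' @return The energy (a scalar).
#' @export
score_structure <- function(s, p = default_contact_potential(),
                            chain_subset = NULL) {
  st <- sc_table(s)
  score_from_tables(st$coords, st$code, st$chain, st$resno, p,
                    subset = chain_subset)
}

#' Score a homodimer: total, monomer, and binding energy
#'
#' Computes `total_score` (both chains in the complex), `mono_score` (chain
#' A alone, in its bound conformation), and the binding energy
#' `dG = total_score - score(A) - score(B)` under the rigid-separation
#' convention. For an exact homodimer `dG = total_score - 2 * mono_score`.
#'
#' @inheritParams score_structure
#' @return A one-row tibble with columns `total_score`, `mono_score`, `dG`.
#' @export
score_triple <- function(s, p = default_contact_potential()) {
  ch <- chains(s)
  if (length(ch) != 2) {
    abort("score_triple() requires exactly 2 chains",
          class = "coilscreen_validation_error")
  }
  st <- sc_table(s)
  total <- score_from_tables(st$coords, st$code, st$chain, st$resno, p)
  a <- score_from_tables(st$coords, st$code, st$chain, st$resno, p,
                         subset = ch[1])
  b <- score_from_tables(st$coords, st$code, st$chain, st$resno, p,
                         subset = ch[2])
  tibble(total_score = total, mono_score = a, dG = total - a - b)
}
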