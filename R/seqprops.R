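#' Apply point mutations to a protein sequence
#'
#' Substitutes 1-based positions, verifying that the wild-type letter
#' encoded in each mutation name matches the sequence.
#'
#' @param seq_string 1-letter amino-acid string.
#' @param m A mutation spec (see [mutations()]); a string such as
#'   `"T30R_S33E"` is accepted.
#' @return The mutated sequence string (same length).
#' @export
apply_mutations <- function(seq_string, m) {
  m <- mutations(m)
  letters1 <- check_sequence_letters(seq_string)
  if (any(m$position > length(letters1))) {
    abort("mutation position beyond sequence end",
          class = "coilscreen_validation_error")
  }
  for (r in seq_len(nrow(m))) {
    found <- letters1[m$position[r]]
    if (!is.na(m$wt[r]) && found != m$wt[r]) {
      abort(sprintf("position %d: expected %s, found %s",
                    m$position[r], m$wt[r], found),
            class = "coilscreen_validation_error")
    }
    letters1[m$position[r]] <- m$new[r]
  }
  paste(letters1, collapse = "")
}

#' Average molecular weight of a protein
#'
#' Sum of average isotopic residue masses plus one water (the convention of
#' the ExPASy Compute pI/Mw tool). Returned at full precision; round to two
#' decimals for reporting.
#'
#' @param seq_string 1-letter amino-acid string.
#' @return Mass in Dalton.
#' @export
average_mass <- function(seq_string) {
  letters1 <- check_sequence_letters(seq_string)
  if (length(letters1) == 0) {
    abort("empty sequence", class = "coilscreen_validation_error")
  }
  sum(.aa_avg_mass[letters1]) + .water_avg_mass
}

# Net charge at a given pH under the Henderson-Hasselbalch model with the
# Bjellqvist/ExPASy pKa set (D, E, C, Y, H, K, R side chains plus termini).
net_charge <- function(letters1, ph) {
  pos_charge <- function(pka) 1 / (1 + 10^(ph - pka))
  neg_charge <- function(pka) -1 / (1 + 10^(pka - ph))
  first <- letters1[1]
  last <- letters1[length(letters1)]
  nterm_pka <- if (first %in% names(.pka_nterm)) {
    .pka_nterm[[first]]
  } else {
    .pka_nterm_default
  }
  cterm_pka <- if (last %in% names(.pka_cterm)) {
    .pka_cterm[[last]]
  } else {
    .pka_cterm_default
  }
  counts <- table(factor(letters1, levels = .aa_codes))
  charge <- pos_charge(nterm_pka) + neg_charge(cterm_pka)
  for (aa in c("K", "R", "H")) {
    charge <- charge + counts[[aa]] * pos_charge(.pka_side[[aa]])
  }
  for (aa in c("D", "E", "C", "Y")) {
    charge <- charge + counts[[aa]] * neg_charge(.pka_side[[aa]])
  }
  charge
}

#' Isoelectric point of a protein
#'
#' The pH at which the modelled net charge is zero, located by bisection on
#' pH 0-14 (converged far below the 0.002 pH reporting tolerance, so the
#' residual net charge at the returned pH is negligible). Net charge is
#' strictly decreasing in pH, so the root is unique.
#'
#' @param seq_string 1-letter amino-acid string.
#' @return The pI (dimensionless).
#' @export
isoelectric_point <- function(seq_string) {
  letters1 <- check_sequence_letters(seq_string)
  if (length(letters1) == 0) {
    abort("empty sequence", class = "coilscreen_validation_error")
  }
  lo <- 0
  hi <- 14
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (net_charge(letters1, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Sequence properties table
#'
#' Computes length, average molecular weight and isoelectric point for each
#' sequence, rounding the reported values to two decimals in the style of
#' the ExPASy Compute pI/Mw output.
#'
#' @param sequences A named character vector of sequences, or a data frame
#'   with columns `id` and `sequence`.
#' @return A tibble with columns `id`, `length`, `mw`, `pi`.
#' @export
seq_properties <- function(sequences) {
  if (is.data.frame(sequences)) {
    df <- as_tibble(sequences)[c("id", "sequence")]
  } else {
    ids <- names(sequences)
    if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
    df <- tibble(id = ids, sequence = unname(sequences))
  }
  df |>
    mutate(length = nchar(.data$sequence),
           mw = round(unname(vapply(.data$sequence, average_mass,
                                    numeric(1))), 2),
           pi = round(unname(vapply(.data$sequence, isoelectric_point,
                                    numeric(1))), 2)) |>
    select("id", "length", "mw", "pi")
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a plain-text amino-acid FASTA file.
#' @return A tibble with columns `id`, `sequence`.
#' @export
read_fasta_sequences <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  tibble(id = names(recs),
         sequence = toupper(unname(vapply(recs,
                                          function(r) as.character(r)[1],
                                          ""))))
}
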