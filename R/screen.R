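#' Design window over the dimerization domain
#'
#' Defaults mirror a 44-position window (residues 3-46) with pairs allowed
#' up to four intervening residues apart.
#'
#' @param first_position,last_position 1-based residue bounds (inclusive).
#' @param max_intervening Maximum number of residues allowed between the two
#'   members of a designed pair (pair index difference at most
#'   `max_intervening + 1`).
#' @return An object of class `design_window`.
#' @export
design_window <- function(first_position = 3, last_position = 46,
                          max_intervening = 4) {
  if (first_position > last_position) {
    abort("first_position must be <= last_position",
          class = "coilscreen_validation_error")
  }
  if (first_position < 1 || max_intervening < 0) {
    abort("positions must be >= 1 and max_intervening >= 0",
          class = "coilscreen_validation_error")
  }
  structure(list(first = as.integer(first_position),
                 last = as.integer(last_position),
                 max_intervening = as.integer(max_intervening)),
            class = "design_window")
}

#' Enumerate candidate design sites
#'
#' `enumerate_single_sites()` lists every position in the window, ascending.
#' `enumerate_pairs()` lists all unordered in-window pairs `(i, j)`, `i < j`,
#' with at most `max_intervening` residues between them, in lexicographic
#' order.
#'
#' @param w A [design_window()].
#' @return An integer vector of positions, or a tibble with columns
#'   `pos_i`, `pos_j`.
#' @export
enumerate_single_sites <- function(w = design_window()) {
  seq.int(w$first, w$last)
}

#' @rdname enumerate_single_sites
#' @export
enumerate_pairs <- function(w = design_window()) {
  pos <- enumerate_single_sites(w)
  grid <- expand.grid(pos_i = pos, pos_j = pos)
  grid <- grid[grid$pos_j > grid$pos_i &
                 (grid$pos_j - grid$pos_i - 1) <= w$max_intervening, ]
  grid <- grid[order(grid$pos_i, grid$pos_j), ]
  as_tibble(grid)
}

canonical_signature <- function(positions, codes) {
  if (length(positions) == 0) return("")
  ord <- order(positions)
  paste0(positions[ord], codes[ord], collapse = "_")
}

# Precompute per-structure tables used by the fast design loop.
design_member_tables <- function(s) {
  st <- sc_table(s)
  atoms <- s$atoms
  sel_ca <- atoms$atom_name == "CA"
  ca <- coords_matrix(s)[sel_ca, , drop = FALSE]
  # rows of st align with residues in atom order; CA rows align the same way
  stopifnot(nrow(ca) == nrow(st$coords))
  dir <- st$coords - ca
  nrm <- sqrt(rowSums(dir^2))
  nrm[nrm == 0] <- 1
  list(sc = st$coords, ca = ca, dir = dir / nrm,
       code = st$code, chain = st$chain, resno = st$resno,
       mask = pair_mask(st$chain, st$resno))
}

score_design_tables <- function(tb, sc, code, p) {
  d <- as.matrix(dist(sc))
  n <- length(code)
  e <- matrix(p$pair_energies[code, code], n, n)
  contact <- tb$mask & (d <= p$contact_cutoff)
  clash <- tb$mask & (d <= p$clash_distance)
  total <- sum(e[contact]) + p$clash_penalty * sum(clash)
  chain1 <- unique(tb$chain)[1]
  in1 <- tb$chain == chain1
  m1 <- contact & outer(in1, in1, "&")
  c1 <- clash & outer(in1, in1, "&")
  mono_a <- sum(e[m1]) + p$clash_penalty * sum(c1)
  in2 <- !in1
  m2 <- contact & outer(in2, in2, "&")
  c2 <- clash & outer(in2, in2, "&")
  mono_b <- sum(e[m2]) + p$clash_penalty * sum(c2)
  c(total = total, mono = mono_a, dG = total - mono_a - mono_b)
}

#' Run an ensemble design screen
#'
#' For every (ensemble member, design site or site pair) combination,
#' generates `n_models` designed models. Each model draws the amino acid at
#' each designed site uniformly from the 20 standard residues *including the
#' native one* (so wild-type-like models arise naturally and provide the
#' reference group), applies it symmetrically to both chains, and records
#' the score triple. The record count is always
#' `length(ensemble) * n_sites * n_models`.
#'
#' @param ensemble A list of homodimeric [polymer_structure()] objects.
#' @param sites An integer vector of single positions, or a data frame of
#'   pairs with columns `pos_i`, `pos_j` (as from [enumerate_pairs()]).
#' @param n_models Designed models per (member, site) combination.
#' @param p A [contact_potential()].
#' @param seed Integer RNG seed.
#' @param scoring `"contact"` scores every model with `p`; `"none"` skips
#'   scoring (scores set to `NA`) for fast bookkeeping checks.
#' @return A tibble of design records with columns `ensemble_member`,
#'   `site_label`, `model_index`, `signature`, `total_score`, `mono_score`,
#'   `dG`.
#' @export
run_design <- function(ensemble, sites, n_models = 20,
                       p = default_contact_potential(), seed = 1,
                       scoring = c("contact", "none")) {
  scoring <- match.arg(scoring)
  if (length(ensemble) == 0) {
    abort("ensemble must be non-empty", class = "coilscreen_validation_error")
  }
  if (n_models < 1) {
    abort("n_models must be >= 1", class = "coilscreen_validation_error")
  }
  if (is.data.frame(sites)) {
    if (nrow(sites) == 0) {
      abort("sites must be non-empty", class = "coilscreen_validation_error")
    }
    site_pos <- lapply(seq_len(nrow(sites)),
                       function(i) c(sites$pos_i[i], sites$pos_j[i]))
  } else {
    if (length(sites) == 0) {
      abort("sites must be non-empty", class = "coilscreen_validation_error")
    }
    site_pos <- as.list(as.integer(sites))
  }
  n_sites <- length(site_pos)
  n_members <- length(ensemble)
  width <- length(site_pos[[1]])
  n_records <- n_members * n_sites * n_models

  # draw all designed residues up-front so record identity is independent of
  # the scoring mode
  draws <- withr_seed(seed, {
    matrix(sample(.aa_codes, n_records * width, replace = TRUE),
           ncol = width)
  })

  member_col <- rep(seq_len(n_members), each = n_sites * n_models)
  site_col <- rep(rep(seq_len(n_sites), each = n_models), times = n_members)
  model_col <- rep(seq_len(n_models), times = n_members * n_sites)
  site_label <- vapply(site_pos, paste, "", collapse = "+")

  # native sequence per position (homodimer: same on both chains)
  res <- residues(ensemble[[1]])
  res <- res[res$chain_id == res$chain_id[1], ]
  native <- setNames(aa3_to_aa1(res$residue_code), res$residue_index)
  all_pos <- unique(unlist(site_pos))
  bad <- setdiff(all_pos, as.integer(names(native)))
  if (length(bad) > 0) {
    abort(paste0("design position(s) absent from structure: ",
                 paste(bad, collapse = ", ")),
          class = "coilscreen_validation_error")
  }

  signature <- character(n_records)
  total <- mono <- dg <- rep(NA_real_, n_records)

  tables <- NULL
  current_member <- 0L
  for (r in seq_len(n_records)) {
    pos <- site_pos[[site_col[r]]]
    aa <- draws[r, ]
    diff_mask <- aa != native[as.character(pos)]
    signature[r] <- canonical_signature(pos[diff_mask], aa[diff_mask])
    if (scoring == "contact") {
      if (member_col[r] != current_member) {
        tables <- design_member_tables(ensemble[[member_col[r]]])
        current_member <- member_col[r]
      }
      sc <- tables$sc
      code <- tables$code
      for (k in seq_along(pos)) {
        idx <- which(tables$resno == pos[k])   # both chains
        code[idx] <- aa[k]
        sc[idx, ] <- tables$ca[idx, , drop = FALSE] +
          .sc_centroid_distance[aa[k]] * tables$dir[idx, , drop = FALSE]
      }
      sc3 <- score_design_tables(tables, sc, code, p)
      total[r] <- sc3["total"]
      mono[r] <- sc3["mono"]
      dg[r] <- sc3["dG"]
    }
  }

  tibble(ensemble_member = member_col,
         site_label = site_label[site_col],
         model_index = model_col,
         signature = signature,
         total_score = total,
         mono_score = mono,
         dG = dg)
}

#' Group design records by sequence and reference them to wild type
#'
#' Groups records by their designed-sequence signature (the empty signature
#' is the wild-type-like group), averages `dG` and `mono_score` within each
#' group, and subtracts the wild-type-like group's means to obtain `ddG` and
#' `d_mono`. The wild-type-like group therefore has `ddG = d_mono = 0`
#' exactly.
#'
#' @param records A design-record tibble from [run_design()].
#' @return A `variant_summary` tibble with columns `signature`, `n_models`,
#'   `mean_dG`, `mean_mono_score`, `ddG`, `d_mono`, `selected`.
#' @export
summarize_variants <- function(records) {
  if (!any(records$signature == "")) {
    abort("reference group empty: no wild-type-like records",
          class = "coilscreen_reference_error")
  }
  out <- records |>
    group_by(.data$signature) |>
    summarise(n_models = n(),
              mean_dG = mean(.data$dG),
              mean_mono_score = mean(.data$mono_score),
              .groups = "drop")
  wt <- out[out$signature == "", ]
  out <- out |>
    mutate(ddG = .data$mean_dG - wt$mean_dG,
           d_mono = .data$mean_mono_score - wt$mean_mono_score,
           selected = FALSE) |>
    arrange(.data$ddG, .data$signature)
  class(out) <- c("variant_summary", class(out))
  out
}

#' Select dimer-stabilizing candidates
#'
#' Keeps variants whose `ddG` is negative (stronger predicted dimerization)
#' while `|d_mono|` stays within `epsilon_mono` (unaffected monomer
#' stability), sorted by ascending `ddG` with lexicographic signature
#' tie-break.
#'
#' @param summaries A `variant_summary` tibble from [summarize_variants()].
#' @param epsilon_mono Tolerance on `|d_mono|` (energy units, >= 0).
#' @return The selected rows, with `selected = TRUE`.
#' @export
select_candidates <- function(summaries, epsilon_mono = 0.5) {
  if (nrow(summaries) == 0) {
    abort("summaries must be non-empty", class = "coilscreen_validation_error")
  }
  if (epsilon_mono < 0) {
    abort("epsilon_mono must be >= 0", class = "coilscreen_validation_error")
  }
  out <- summaries |>
    filter(.data$signature != "", .data$ddG < 0,
           abs(.data$d_mono) <= epsilon_mono) |>
    mutate(selected = TRUE) |>
    arrange(.data$ddG, .data$signature)
  out
}

#' @method glance variant_summary
#' @export
glance.variant_summary <- function(x, ...) {
  tibble(n_variants = sum(x$signature != ""),
         n_wt_models = x$n_models[x$signature == ""],
         n_models = sum(x$n_models),
         min_ddG = min(x$ddG),
         n_selected = sum(x$selected))
}

#' Scatter plot of a design screen
#'
#' Monomer-stability change (`d_mono`) against binding-energy change
#' (`ddG`); selected candidates are highlighted. Points below the dashed
#' zero line are predicted dimer-stabilizing.
#'
#' @param object A `variant_summary` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot variant_summary
#' @export
autoplot.variant_summary <- function(object, ...) {
  df <- object[object$signature != "", ]
  ggplot(df, aes(x = .data$d_mono, y = .data$ddG,
                 colour = .data$selected)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = 0, linetype = "dashed") +
    labs(x = "Δmono_score (energy units)",
         y = "ΔΔG (energy units)",
         colour = "selected") +
    theme_minimal()
}
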