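#' Restrict a trajectory to its final analysis window
#'
#' Mirrors the common practice of analysing only the equilibrated tail of a
#' production run (e.g. the last 100 ns of a 200 ns simulation). With
#' `fraction`, the last `ceiling(fraction * n)` frames are kept; with
#' `span`, exactly the frames with `time > t_end - span` are kept.
#'
#' @param t A [trajectory()].
#' @param fraction Fraction of frames to keep from the end (0 < f <= 1).
#' @param span Time span in nanoseconds to keep from the end (overrides
#'   `fraction` when given).
#' @return The windowed [trajectory()]; the window is recorded in metadata.
#' @export
window_frames <- function(t, fraction = 0.5, span = NULL) {
  n <- length(t$frames)
  if (!is.null(span)) {
    keep <- which(t$frame_times > max(t$frame_times) - span)
  } else {
    if (fraction <= 0 || fraction > 1) {
      abort("fraction must be in (0, 1]", class = "coilscreen_validation_error")
    }
    keep <- seq_len(n) > n - ceiling(fraction * n)
    keep <- which(keep)
  }
  if (length(keep) == 0) {
    abort("analysis window selects zero frames",
          class = "coilscreen_validation_error")
  }
  meta <- t$metadata
  meta$window <- if (is.null(span)) {
    list(type = "fraction", value = fraction)
  } else {
    list(type = "span_ns", value = span)
  }
  trajectory(t$topology, t$frames[keep], t$frame_times[keep],
             replicate_id = t$replicate_id, metadata = meta)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (determinant +1) and translation minimizing the
#' RMSD between selected atoms of `moving` and `reference`.
#'
#' @param moving,reference n-by-3 coordinate matrices.
#' @param selection Optional row indices used both for the fit and the RMSD.
#' @return A list with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom), and `transform(m)`, a function applying the fit to any
#'   coordinate matrix. The fitted coordinates are
#'   `moving %*% rotation + translation` (rows).
#' @export
superpose_kabsch <- function(moving, reference, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(moving))
  pm <- moving[selection, , drop = FALSE]
  pr <- reference[selection, , drop = FALSE]
  if (nrow(pm) != nrow(pr)) {
    abort("selections must have equal atom counts",
          class = "coilscreen_validation_error")
  }
  if (nrow(pm) < 3) {
    abort("superposition needs at least 3 atoms",
          class = "coilscreen_degeneracy_error")
  }
  cm <- colMeans(pm)
  cr <- colMeans(pr)
  pm_c <- sweep(pm, 2, cm)
  pr_c <- sweep(pr, 2, cr)
  if (svd(pr_c)$d[2] < 1e-8 || svd(pm_c)$d[2] < 1e-8) {
    abort("degenerate (collinear) atom selection",
          class = "coilscreen_degeneracy_error")
  }
  h <- crossprod(pm_c, pr_c)           # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  corr <- diag(c(1, 1, d))
  rot <- sv$u %*% corr %*% t(sv$v)     # row-vector convention: x %*% rot
  translation <- as.numeric(cr - cm %*% rot)
  fitted <- pm_c %*% rot
  rmsd <- sqrt(sum((fitted - pr_c)^2) / nrow(pm))
  transform <- function(m) sweep(m %*% rot, 2, translation, "+")
  list(rotation = rot, translation = translation, rmsd = rmsd,
       transform = transform)
}

#' Backbone RMSD profile of a trajectory
#'
#' Per-frame backbone (N, CA, C, O) RMSD against a reference structure after
#' Kabsch superposition, in frame order.
#'
#' @param t A [trajectory()].
#' @param reference A [polymer_structure()] congruent with the topology
#'   (defaults to the topology itself).
#' @return An `rmsd_profile` tibble with columns `time` (ns) and `rmsd`
#'   (Angstrom).
#' @export
rmsd_profile <- function(t, reference = t$topology) {
  if (nrow(reference$atoms) != nrow(t$topology$atoms)) {
    abort("reference topology does not match the trajectory",
          class = "coilscreen_topology_error")
  }
  idx <- backbone_indices(t$topology)
  ref <- coords_matrix(reference)
  rmsd <- vapply(t$frames, function(f) {
    superpose_kabsch(f, ref, selection = idx)$rmsd
  }, numeric(1))
  out <- tibble(time = t$frame_times, rmsd = rmsd)
  class(out) <- c("rmsd_profile", class(out))
  out
}

#' @method autoplot rmsd_profile
#' @export
autoplot.rmsd_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$rmsd)) +
    geom_line() +
    labs(x = "time (ns)", y = "backbone RMSD (Å)") +
    theme_minimal()
}

#' Specify a pairwise interaction to monitor
#'
#' Selectors name one atom each as `(chain, residue_index, atom)`; the
#' side-chain centroid `SC` is the default atom. Default distance cutoffs:
#' salt bridge 4.0 A, stacking 5.5 A, generic contact 8.0 A.
#'
#' @param id Interaction identifier string.
#' @param kind One of `"salt_bridge"`, `"stacking"`, `"generic_contact"`.
#' @param selector_a,selector_b Lists with elements `chain`,
#'   `residue_index`, and optionally `atom`.
#' @param distance_cutoff Cutoff in Angstrom; defaults by kind.
#' @return An object of class `interaction_spec`.
#' @export
interaction_spec <- function(id, kind = c("salt_bridge", "stacking",
                                          "generic_contact"),
                             selector_a, selector_b,
                             distance_cutoff = NULL) {
  kind <- match.arg(kind)
  if (is.null(distance_cutoff)) {
    distance_cutoff <- switch(kind, salt_bridge = 4.0, stacking = 5.5,
                              generic_contact = 8.0)
  }
  if (distance_cutoff <= 0) {
    abort("distance_cutoff must be positive",
          class = "coilscreen_validation_error")
  }
  norm_sel <- function(sel) {
    if (is.null(sel$atom)) sel$atom <- "SC"
    sel[c("chain", "residue_index", "atom")]
  }
  structure(list(id = id, kind = kind,
                 selector_a = norm_sel(selector_a),
                 selector_b = norm_sel(selector_b),
                 distance_cutoff = distance_cutoff),
            class = "interaction_spec")
}

resolve_selector <- function(s, sel, id = "?") {
  idx <- which(s$atoms$chain_id == sel$chain &
                 s$atoms$residue_index == sel$residue_index &
                 s$atoms$atom_name == sel$atom)
  if (length(idx) != 1) {
    abort(sprintf(
      "interaction '%s': selector (chain %s, residue %s, atom %s) resolves to %d atoms",
      id, sel$chain, sel$residue_index, sel$atom, length(idx)),
      class = "coilscreen_selector_error")
  }
  idx
}

#' Interaction occupancy over a trajectory
#'
#' A frame counts as "present" when the selector-pair distance is at or
#' below the spec's cutoff; occupancy is the present fraction of evaluated
#' frames.
#'
#' @param t A [trajectory()].
#' @param spec One [interaction_spec()] or a list of them.
#' @return A tibble with one row per interaction: `id`, `kind`,
#'   `frames_evaluated`, `frames_present`, `occupancy`.
#' @export
interaction_occupancy <- function(t, spec) {
  specs <- if (inherits(spec, "interaction_spec")) list(spec) else spec
  rows <- lapply(specs, function(sp) {
    ia <- resolve_selector(t$topology, sp$selector_a, sp$id)
    ib <- resolve_selector(t$topology, sp$selector_b, sp$id)
    d <- vapply(t$frames,
                function(f) sqrt(sum((f[ia, ] - f[ib, ])^2)),
                numeric(1))
    present <- d <= sp$distance_cutoff
    tibble(id = sp$id, kind = sp$kind,
           frames_evaluated = length(present),
           frames_present = sum(present),
           occupancy = sum(present) / length(present))
  })
  bind_rows(rows)
}

#' Average structure over a trajectory
#'
#' Superposes every frame onto the first (Kabsch fit on backbone atoms) and
#' takes the per-atom arithmetic mean of the coordinates. No energy
#' minimization is applied; this is recorded in the result metadata.
#'
#' @param t A [trajectory()].
#' @return A [polymer_structure()] with the mean coordinates.
#' @export
average_structure <- function(t) {
  idx <- backbone_indices(t$topology)
  ref <- t$frames[[1]]
  acc <- matrix(0, nrow(ref), 3)
  for (f in t$frames) {
    fit <- superpose_kabsch(f, ref, selection = idx)
    acc <- acc + fit$transform(f)
  }
  s <- set_coords(t$topology, acc / length(t$frames))
  s$metadata$average_of_frames <- length(t$frames)
  s$metadata$minimized <- FALSE
  s
}

#' Per-frame binding-energy aggregation
#'
#' For every frame of a two-chain complex, computes
#' `dG = E(complex) - E(chain A) - E(chain B)` with the contact potential
#' (single-trajectory convention: the monomers keep their bound
#' conformation), then aggregates the mean and its standard error. This is
#' the contact-potential analogue of per-frame MM-GBSA decomposition into
#' complex, receptor and ligand.
#'
#' @param t A [trajectory()] whose topology has exactly 2 chains.
#' @param p A [contact_potential()].
#' @param replicate_id Replicate tag carried into the result (defaults to
#'   the trajectory's).
#' @return An object of class `binding_energy_estimate` with fields
#'   `per_frame` (tibble `time`, `dG`), `mean_dG`, `sem_dG`, `n_frames`,
#'   `replicate_id`.
#' @export
binding_energy_over_frames <- function(t, p = default_contact_potential(),
                                       replicate_id = t$replicate_id) {
  ch <- chains(t$topology)
  if (length(ch) != 2) {
    abort("binding energy decomposition requires exactly 2 chains",
          class = "coilscreen_validation_error")
  }
  st <- sc_table(t$topology)
  sel <- t$topology$atoms$atom_name == "SC"
  dg <- vapply(t$frames, function(f) {
    sc <- f[sel, , drop = FALSE]
    total <- score_from_tables(sc, st$code, st$chain, st$resno, p)
    a <- score_from_tables(sc, st$code, st$chain, st$resno, p, subset = ch[1])
    b <- score_from_tables(sc, st$code, st$chain, st$resno, p, subset = ch[2])
    total - a - b
  }, numeric(1))
  new_binding_energy(tibble(time = t$frame_times, dG = dg),
                     replicate_id = replicate_id)
}

new_binding_energy <- function(per_frame, replicate_id,
                               replicate_means = NULL) {
  n <- nrow(per_frame)
  structure(list(per_frame = per_frame,
                 mean_dG = mean(per_frame$dG),
                 sem_dG = if (n > 1) sd(per_frame$dG) / sqrt(n) else 0,
                 n_frames = n,
                 replicate_id = replicate_id,
                 replicate_means = replicate_means),
            class = "binding_energy_estimate")
}

#' @export
print.binding_energy_estimate <- function(x, ...) {
  cat(sprintf(
    "<binding_energy_estimate> mean dG = %.4f +/- %.4f (SEM), %d frames\n",
    x$mean_dG, x$sem_dG, x$n_frames))
  invisible(x)
}

#' @method tidy binding_energy_estimate
#' @export
tidy.binding_energy_estimate <- function(x, ...) x$per_frame

#' @method glance binding_energy_estimate
#' @export
glance.binding_energy_estimate <- function(x, ...) {
  tibble(mean_dG = x$mean_dG, sem_dG = x$sem_dG, n_frames = x$n_frames,
         replicate_id = paste(x$replicate_id, collapse = "+"))
}

#' @method autoplot binding_energy_estimate
#' @export
autoplot.binding_energy_estimate <- function(object, ...) {
  ggplot(object$per_frame, aes(x = .data$time, y = .data$dG)) +
    geom_line(alpha = 0.6) +
    geom_hline(yintercept = object$mean_dG, linetype = "dashed") +
    labs(x = "time (ns)", y = "per-frame binding ΔG (energy units)") +
    theme_minimal()
}

#' Pool binding-energy estimates across replicates
#'
#' Concatenates the per-frame binding energies of independent replicates and
#' recomputes the pooled mean and SEM; per-replicate means are retained.
#'
#' @param estimates A list of `binding_energy_estimate` objects.
#' @return A pooled `binding_energy_estimate` whose `replicate_means` field
#'   is a tibble of per-replicate means.
#' @export
merge_replicates <- function(estimates) {
  if (length(estimates) == 0) {
    abort("estimates must be non-empty", class = "coilscreen_validation_error")
  }
  per_frame <- bind_rows(lapply(estimates, function(e) e$per_frame))
  rep_means <- bind_rows(lapply(estimates, glance))
  new_binding_energy(per_frame,
                     replicate_id = vapply(estimates, function(e)
                       e$replicate_id[1], integer(1)),
                     replicate_means = rep_means)
}
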