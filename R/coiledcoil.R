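#' Crick parameterization for an ideal two-chain parallel coiled coil
#'
#' Defaults describe a canonical left-handed two-stranded coiled coil:
#' superhelix radius 4.9 A, minor helix radius 2.26 A, 3.5 residues per
#' minor-helix turn (102.857 degrees of phase advance per residue),
#' superhelix pitch 140 A, and an axial rise of 1.51 A per residue. The two
#' chains are related by a 2-fold rotation about the superhelix axis
#' (`phase_offsets` 0 and 180 degrees), giving a parallel homodimer.
#' `minor_phase` positions the heptad a/d seam toward the partner chain.
#'
#' @param superhelix_radius_R0,helix_radius_R1 Radii in Angstrom; must
#'   satisfy `R0 > R1 > 0`.
#' @param residues_per_turn_minor Residues per minor-helix turn.
#' @param superhelix_pitch Superhelix pitch in Angstrom.
#' @param rise_per_residue Axial rise per residue in Angstrom.
#' @param phase_offsets Per-chain superhelical phase offsets in degrees.
#' @param minor_phase Minor-helix phase of residue 1 in degrees.
#' @return An object of class `crick_params`.
#' @export
crick_params <- function(superhelix_radius_R0 = 4.9,
                         helix_radius_R1 = 2.26,
                         residues_per_turn_minor = 3.5,
                         superhelix_pitch = 140,
                         rise_per_residue = 1.51,
                         phase_offsets = c(0, 180),
                         minor_phase = 205.7) {
  if (!(superhelix_radius_R0 > helix_radius_R1 && helix_radius_R1 > 0)) {
    abort("require R0 > R1 > 0", class = "coilscreen_validation_error")
  }
  if (superhelix_pitch <= 0 || rise_per_residue <= 0 ||
      residues_per_turn_minor <= 0) {
    abort("pitch, rise and residues-per-turn must be positive",
          class = "coilscreen_validation_error")
  }
  if (length(phase_offsets) != 2) {
    abort("exactly two chains are supported",
          class = "coilscreen_validation_error")
  }
  structure(list(R0 = superhelix_radius_R0, R1 = helix_radius_R1,
                 rpt = residues_per_turn_minor, pitch = superhelix_pitch,
                 rise = rise_per_residue, phase_offsets = phase_offsets,
                 minor_phase = minor_phase),
            class = "crick_params")
}

# Backbone + SC geometry for one chain; returns a list of per-atom rows.
build_chain_atoms <- function(letters1, params, chain_id, phase_deg,
                              serial_start) {
  n <- length(letters1)
  i <- seq_len(n) - 1
  theta <- 2 * pi * params$rise * i / params$pitch + phase_deg * pi / 180
  dtheta <- 2 * pi * params$rise / params$pitch
  axis <- cbind(params$R0 * cos(theta), params$R0 * sin(theta),
                params$rise * i)
  # local frame on the superhelix: radial u, tangent t, binormal w; the
  # minor circle lies in the (u, w) plane normal to the superhelix tangent
  u <- cbind(cos(theta), sin(theta), 0)
  tang <- cbind(-params$R0 * sin(theta) * dtheta,
                params$R0 * cos(theta) * dtheta,
                params$rise)
  tang <- tang / sqrt(rowSums(tang^2))
  w <- cbind(tang[, 2] * u[, 3] - tang[, 3] * u[, 2],
             tang[, 3] * u[, 1] - tang[, 1] * u[, 3],
             tang[, 1] * u[, 2] - tang[, 2] * u[, 1])
  psi <- (params$minor_phase + i * 360 / params$rpt) * pi / 180
  ca <- axis + params$R1 * (cos(psi) * u + sin(psi) * w)

  # local chain direction from neighbouring CA positions
  tvec <- rbind(ca[2, ] - ca[1, ],
                if (n > 2) ca[3:n, ] - ca[1:(n - 2), ] else NULL,
                ca[n, ] - ca[n - 1, ])
  tvec <- tvec / sqrt(rowSums(tvec^2))
  out_dir <- ca - axis
  out_dir <- out_dir / sqrt(rowSums(out_dir^2))

  npos <- ca - 1.46 * tvec
  cpos <- ca + 1.52 * tvec
  opos <- cpos + 1.23 * out_dir
  scd <- .sc_centroid_distance[letters1]
  scpos <- ca + scd * out_dir

  rows <- vector("list", n)
  serial <- serial_start
  for (j in seq_len(n)) {
    coords <- rbind(npos[j, ], ca[j, ], cpos[j, ], opos[j, ], scpos[j, ])
    rows[[j]] <- tibble(
      serial = serial + 0:4,
      atom_name = c("N", "CA", "C", "O", "SC"),
      residue_code = aa1_to_aa3(rep(letters1[j], 5)),
      chain_id = chain_id,
      residue_index = j,
      x = coords[, 1], y = coords[, 2], z = coords[, 3]
    )
    serial <- serial + 5L
  }
  bind_rows(rows)
}

#' Build an ideal parallel coiled-coil homodimer
#'
#' Places backbone N/CA/C/O atoms on a Crick-parameterized superhelix and one
#' side-chain centroid pseudo-atom (`SC`) per residue along the outward
#' normal from the chain's own helical axis, at a per-residue-type distance.
#' The same sequence is threaded onto both chains (A and B), which are
#' related by the 2-fold superhelical symmetry.
#'
#' @param sequence 1-letter amino-acid string, length >= 7.
#' @param params A [crick_params()] object.
#' @return A [polymer_structure()] homodimer with `2 * nchar(sequence)`
#'   residues.
#' @export
build_coiled_coil <- function(sequence, params = crick_params()) {
  letters1 <- check_sequence_letters(sequence)
  if (length(letters1) < 7) {
    abort("sequence must be at least 7 residues (one heptad)",
          class = "coilscreen_validation_error")
  }
  atoms_a <- build_chain_atoms(letters1, params, "A",
                               params$phase_offsets[1], 1L)
  atoms_b <- build_chain_atoms(letters1, params, "B",
                               params$phase_offsets[2],
                               nrow(atoms_a) + 1L)
  polymer_structure(bind_rows(atoms_a, atoms_b),
                    metadata = list(generator = "build_coiled_coil",
                                    params = unclass(params),
                                    sequence = sequence))
}

#' Parse a mutation signature string
#'
#' Accepts the conventional underscore-joined form, e.g. `"K21W"` or
#' `"T30R_S33E"`: wild-type letter, 1-based position, new letter.
#'
#' @param spec A signature string, or a data frame with columns
#'   `position` and `new` (and optionally `wt`).
#' @return A tibble with columns `wt` (may be `NA`), `position`, `new`.
#' @export
mutations <- function(spec) {
  if (is.data.frame(spec)) {
    out <- as_tibble(spec)
    if (!all(c("position", "new") %in% names(out))) {
      abort("mutation table needs columns position, new",
            class = "coilscreen_validation_error")
    }
    if (!"wt" %in% names(out)) out$wt <- NA_character_
    out <- out[c("wt", "position", "new")]
  } else {
    tokens <- strsplit(spec, "_", fixed = TRUE)[[1]]
    m <- regmatches(tokens, regexec("^([A-Z])([0-9]+)([A-Z])$", tokens))
    bad <- tokens[vapply(m, length, integer(1)) != 4]
    if (length(bad) > 0) {
      abort(paste0("cannot parse mutation token(s): ",
                   paste(bad, collapse = ", ")),
            class = "coilscreen_validation_error")
    }
    out <- tibble(wt = vapply(m, `[`, "", 2),
                  position = as.integer(vapply(m, `[`, "", 3)),
                  new = vapply(m, `[`, "", 4))
  }
  if (anyDuplicated(out$position)) {
    abort("mutation positions must be unique",
          class = "coilscreen_validation_error")
  }
  check_sequence_letters(paste(out$new, collapse = ""))
  out$position <- as.integer(out$position)
  out
}

#' Mutate a homodimer in silico
#'
#' Applies each substitution identically to both chains: the residue code is
#' updated and the `SC` pseudo-atom is moved along its existing CA->SC
#' direction to the new residue type's centroid distance. Backbone
#' coordinates are untouched.
#'
#' @param s A homodimeric [polymer_structure()].
#' @param m A mutation spec (see [mutations()]); a string is accepted.
#' @return The mutated structure.
#' @export
mutate_structure <- function(s, m) {
  m <- mutations(m)
  atoms <- s$atoms
  missing_pos <- setdiff(m$position,
                         unique(atoms$residue_index))
  if (length(missing_pos) > 0) {
    abort(paste0("position(s) absent from structure: ",
                 paste(missing_pos, collapse = ", ")),
          class = "coilscreen_validation_error")
  }
  for (r in seq_len(nrow(m))) {
    pos <- m$position[r]
    new3 <- aa1_to_aa3(m$new[r])
    sel <- atoms$residue_index == pos
    if (!is.na(m$wt[r])) {
      found1 <- unique(aa3_to_aa1(atoms$residue_code[sel]))
      if (!all(found1 == m$wt[r])) {
        abort(sprintf("expected %s at position %d, found %s",
                      m$wt[r], pos, paste(found1, collapse = "/")),
              class = "coilscreen_validation_error")
      }
    }
    if (all(atoms$residue_code[sel] == new3)) next  # native re-introduction
    for (ch in unique(atoms$chain_id[sel])) {
      rs <- sel & atoms$chain_id == ch
      ca <- which(rs & atoms$atom_name == "CA")
      sc <- which(rs & atoms$atom_name == "SC")
      if (length(ca) == 1 && length(sc) == 1) {
        dir <- c(atoms$x[sc] - atoms$x[ca], atoms$y[sc] - atoms$y[ca],
                 atoms$z[sc] - atoms$z[ca])
        nrm <- sqrt(sum(dir^2))
        if (nrm > 0) {
          dir <- dir / nrm
          d <- .sc_centroid_distance[m$new[r]]
          atoms$x[sc] <- atoms$x[ca] + d * dir[1]
          atoms$y[sc] <- atoms$y[ca] + d * dir[2]
          atoms$z[sc] <- atoms$z[ca] + d * dir[3]
        }
      }
    }
    atoms$residue_code[sel] <- new3
  }
  s$atoms <- atoms
  s
}

#' Generate a perturbed structure ensemble
#'
#' Member 1 is the unperturbed input; members 2..n add i.i.d. Gaussian
#' coordinate noise of scale `sigma` to every coordinate. Deterministic for a
#' given seed.
#'
#' @param s A [polymer_structure()].
#' @param n Ensemble size (>= 1).
#' @param sigma Noise scale in Angstrom (>= 0).
#' @param seed Integer RNG seed.
#' @return A list of `n` structures.
#' @export
generate_ensemble <- function(s, n = 100, sigma = 0.3, seed = 1) {
  if (n < 1) {
    abort("ensemble size must be >= 1", class = "coilscreen_validation_error")
  }
  if (sigma < 0) {
    abort("sigma must be >= 0", class = "coilscreen_validation_error")
  }
  base <- coords_matrix(s)
  out <- vector("list", n)
  out[[1]] <- s
  if (n > 1) {
    withr_seed(seed, {
      for (i in 2:n) {
        noise <- matrix(rnorm(length(base), sd = sigma), ncol = 3)
        out[[i]] <- set_coords(s, base + noise)
      }
    })
  }
  out
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

backbone_indices <- function(s) {
  which(s$atoms$atom_name %in% c("N", "CA", "C", "O"))
}

# Pairwise minimal (Kabsch) backbone RMSD matrix between frames.
pairwise_rmsd_matrix <- function(frames, idx) {
  n <- length(frames)
  centered <- lapply(frames, function(f) {
    m <- f[idx, , drop = FALSE]
    sweep(m, 2, colMeans(m))
  })
  e0 <- vapply(centered, function(m) sum(m^2), numeric(1))
  np <- length(idx)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sv <- svd(crossprod(centered[[i]], centered[[j]]))
      sg <- sv$d
      if (det(sv$v %*% t(sv$u)) < 0) sg[3] <- -sg[3]
      msd <- (e0[i] + e0[j] - 2 * sum(sg)) / np
      d[i, j] <- d[j, i] <- sqrt(max(msd, 0))
    }
  }
  d
}

#' Pick cluster representatives from a trajectory
#'
#' Runs k-medoids (PAM) on the pairwise backbone-RMSD matrix of the frames
#' and returns the medoid frames as structures, mirroring the practice of
#' clustering a trajectory to obtain a representative conformational
#' ensemble for design.
#'
#' @param t A [trajectory()].
#' @param k Number of representatives (<= number of frames).
#' @param seed Integer seed, recorded for reproducibility (PAM's BUILD
#'   initialisation is itself deterministic).
#' @return A list of `k` [polymer_structure()] objects.
#' @export
cluster_representatives <- function(t, k, seed = 1) {
  n <- length(t$frames)
  if (k > n) {
    abort("k must not exceed the number of frames",
          class = "coilscreen_validation_error")
  }
  if (k == n) {
    return(lapply(seq_len(n), function(i) frame_structure(t, i)))
  }
  idx <- backbone_indices(t$topology)
  d <- pairwise_rmsd_matrix(t$frames, idx)
  fit <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE)
  medoids <- sort(as.integer(fit$id.med))
  lapply(medoids, function(i) frame_structure(t, i))
}

#' Programmable interaction schedule for synthetic trajectories
#'
#' Couples an [interaction_spec()] with a per-frame presence vector and the
#' distances at which the interaction is geometrically realized: the second
#' selector's atom is placed at `target_distance` from the first when the
#' frame is marked present, and at `absent_distance` otherwise. This gives
#' trajectory occupancy analysis an exactly known ground truth.
#'
#' @param spec An [interaction_spec()].
#' @param present Logical vector, one element per frame.
#' @param target_distance,absent_distance Realized distances in Angstrom;
#'   defaults are 80% and 250% of the spec's cutoff.
#' @return An object of class `interaction_schedule`.
#' @export
interaction_schedule <- function(spec, present,
                                 target_distance = 0.8 * spec$distance_cutoff,
                                 absent_distance = 2.5 * spec$distance_cutoff) {
  if (!is.logical(present) || anyNA(present)) {
    abort("present must be a logical vector without NA",
          class = "coilscreen_validation_error")
  }
  if (target_distance > spec$distance_cutoff ||
      absent_distance <= spec$distance_cutoff) {
    abort("target_distance must be <= cutoff and absent_distance > cutoff",
          class = "coilscreen_validation_error")
  }
  structure(list(spec = spec, present = present,
                 target_distance = target_distance,
                 absent_distance = absent_distance),
            class = "interaction_schedule")
}

#' Generate a synthetic trajectory
#'
#' Frames are the input coordinates plus i.i.d. Gaussian noise of scale
#' `sigma`; scheduled interactions are then realized exactly by moving the
#' schedule's second atom along the current inter-atom direction to the
#' present/absent distance. Frame times are `dt, 2 dt, ..., n dt`.
#'
#' @param s A [polymer_structure()] used as topology and mean conformation.
#' @param n_frames Number of frames (>= 1).
#' @param dt Frame spacing in nanoseconds.
#' @param sigma Coordinate noise scale in Angstrom.
#' @param schedules `NULL`, one [interaction_schedule()], or a list of them.
#' @param seed Integer RNG seed.
#' @param replicate_id Integer replicate tag.
#' @return A [trajectory()].
#' @export
generate_trajectory <- function(s, n_frames, dt = 1, sigma = 0,
                                schedules = NULL, seed = 1,
                                replicate_id = 1L) {
  if (n_frames < 1) {
    abort("n_frames must be >= 1", class = "coilscreen_validation_error")
  }
  if (inherits(schedules, "interaction_schedule")) schedules <- list(schedules)
  for (sch in schedules) {
    if (length(sch$present) != n_frames) {
      abort(sprintf("schedule '%s' has %d entries for %d frames",
                    sch$spec$id, length(sch$present), n_frames),
            class = "coilscreen_validation_error")
    }
  }
  base <- coords_matrix(s)
  sched_idx <- lapply(schedules, function(sch) {
    c(a = resolve_selector(s, sch$spec$selector_a, sch$spec$id),
      b = resolve_selector(s, sch$spec$selector_b, sch$spec$id))
  })
  frames <- vector("list", n_frames)
  withr_seed(seed, {
    for (f in seq_len(n_frames)) {
      m <- base
      if (sigma > 0) {
        m <- m + matrix(rnorm(length(base), sd = sigma), ncol = 3)
      }
      for (si in seq_along(schedules)) {
        sch <- schedules[[si]]
        ia <- sched_idx[[si]]["a"]
        ib <- sched_idx[[si]]["b"]
        dir <- m[ib, ] - m[ia, ]
        nrm <- sqrt(sum(dir^2))
        dir <- if (nrm > 0) dir / nrm else c(1, 0, 0)
        d <- if (sch$present[f]) sch$target_distance else sch$absent_distance
        m[ib, ] <- m[ia, ] + d * dir
      }
      frames[[f]] <- m
    }
  })
  trajectory(s, frames, dt * seq_len(n_frames),
             replicate_id = replicate_id,
             metadata = list(sigma = sigma, seed = seed))
}

#' Synthetic stand-in sequence for a coiled-coil dimerization domain
#'
#' A 46-residue idealized heptad sequence built for demonstrations and
#' synthetic benchmarks. It is *not* the natural SIP sequence; it is designed
#' so the well-known SIP variant names remain applicable: Lys at 21, Thr at
#' 30, Ser at 33 (and Glu at 34, the salt-bridge partner of an introduced
#' Arg30), with Leu/Ile/Val at the heptad a/d core positions.
#'
#' @return A 46-character string.
#' @export
sip_cc_demo_sequence <- function() {
  paste0("LEAIEAK", "LQAVENK", "LASIEQK", "LEAIKAE", "LTAVSEK",
         "LQAIENR", "LAAI")
}
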