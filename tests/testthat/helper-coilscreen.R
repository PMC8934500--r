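# Shared fixtures and independent oracles, all built in code.

aa_codes <- strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]]

# Hand-written two-residue, two-atom PDB text (verbatim fixed columns).
tiny_pdb_text <- function() {
  paste(
    "ATOM      1  CA  ALA A   5       1.000   2.000   3.000  1.00  0.00",
    "ATOM      2  CA  GLY A   6       4.500   2.000   3.000  1.00  0.00",
    "END",
    sep = "\n")
}

# A small two-chain structure with explicit CA and SC positions, for energy
# tests: `sc` is a list of rows (chain, resno, code1, x, y, z); CA is placed
# 1 A below each SC so mutation direction vectors are well defined.
make_sc_structure <- function(sc) {
  rows <- list()
  serial <- 1L
  for (r in sc) {
    code3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
               E = "GLU", Q = "GLN", G = "GLY", H = "HIS", I = "ILE",
               L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
               S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")[[r$code]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      serial = serial, atom_name = "CA", residue_code = code3,
      chain_id = r$chain, residue_index = r$resno,
      x = r$x, y = r$y, z = r$z - 1)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      serial = serial + 1L, atom_name = "SC", residue_code = code3,
      chain_id = r$chain, residue_index = r$resno,
      x = r$x, y = r$y, z = r$z)
    serial <- serial + 2L
  }
  polymer_structure(dplyr::bind_rows(rows))
}

# Random two-chain toy with n residues per chain in a compact box.
random_sc_structure <- function(n_per_chain, seed, box = 10) {
  set.seed(seed)
  sc <- list()
  for (ch in c("A", "B")) {
    for (i in seq_len(n_per_chain)) {
      sc[[length(sc) + 1L]] <- list(
        chain = ch, resno = i, code = sample(aa_codes, 1),
        x = runif(1, 0, box), y = runif(1, 0, box),
        z = runif(1, 0, box) + if (ch == "B") box / 2 else 0)
    }
  }
  make_sc_structure(sc)
}

# Independent brute-force contact score: double loop over all residue pairs.
brute_force_score <- function(s, p, chain_subset = NULL) {
  atoms <- s$atoms[s$atoms$atom_name == "SC", ]
  if (!is.null(chain_subset)) atoms <- atoms[atoms$chain_id %in% chain_subset, ]
  one <- setNames(aa_codes, c("ALA", "ARG", "ASN", "ASP", "CYS", "GLU",
                              "GLN", "GLY", "HIS", "ILE", "LEU", "LYS",
                              "MET", "PHE", "PRO", "SER", "THR", "TRP",
                              "TYR", "VAL"))
  total <- 0
  n <- nrow(atoms)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (atoms$chain_id[i] == atoms$chain_id[j] &&
          abs(atoms$residue_index[i] - atoms$residue_index[j]) <= 1) next
      d <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
                  (atoms$z[i] - atoms$z[j])^2)
      if (d <= p$contact_cutoff) {
        total <- total + p$pair_energies[one[[atoms$residue_code[i]]],
                                         one[[atoms$residue_code[j]]]]
      }
      if (d <= p$clash_distance) total <- total + p$clash_penalty
    }
  }
  total
}

# Brute-force binding energy: sum of inter-chain contact terms only.
brute_force_inter_chain <- function(s, p) {
  brute_force_score(s, p) -
    brute_force_score(s, p, "A") - brute_force_score(s, p, "B")
}

# A zero pair-energy matrix to build custom potentials from.
zero_pair_matrix <- function() {
  matrix(0, 20, 20, dimnames = list(aa_codes, aa_codes))
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

apply_rigid <- function(s, rot, shift) {
  m <- cbind(s$atoms$x, s$atoms$y, s$atoms$z) %*% rot
  s$atoms$x <- m[, 1] + shift[1]
  s$atoms$y <- m[, 2] + shift[2]
  s$atoms$z <- m[, 3] + shift[3]
  s
}

# Grid-search RMSD oracle: exhaustive Euler-angle scan (coarse), then a fine
# local scan, with optimal translation handled by centering. Independent of
# the SVD route.
grid_search_rmsd <- function(moving, reference) {
  pm <- sweep(moving, 2, colMeans(moving))
  pr <- sweep(reference, 2, colMeans(reference))
  euler <- function(a, b, c) {
    rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
                 byrow = TRUE)
    rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    rz1 %*% ry %*% rz2
  }
  rmsd_of <- function(r) sqrt(mean(rowSums((pm %*% r - pr)^2)))
  best <- c(0, 0, 0)
  best_val <- Inf
  scan <- function(centers, step, half_n) {
    for (a in centers[1] + step * (-half_n:half_n)) {
      for (b in centers[2] + step * (-half_n:half_n)) {
        for (c in centers[3] + step * (-half_n:half_n)) {
          v <- rmsd_of(euler(a, b, c))
          if (v < best_val) {
            best_val <<- v
            best <<- c(a, b, c)
          }
        }
      }
    }
  }
  scan(c(pi, pi / 2, pi), 10 * pi / 180, 18)    # 10 deg over full ranges
  scan(best, 0.5 * pi / 180, 21)                # 0.5 deg local refinement
  scan(best, 0.05 * pi / 180, 12)               # 0.05 deg polish
  best_val
}

small_run_config <- function(dir, ...) {
  cfg <- default_run_config()
  cfg$output_dir <- dir
  cfg$design$ensemble_size <- 2L
  cfg$design$n_models <- 5L
  cfg$design$first_position <- 5L
  cfg$design$last_position <- 6L
  cfg$trajectory$n_frames <- 10L
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg
}
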