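test_that("frame windowing keeps exactly the trailing frames", {
  s <- build_coiled_coil("LEAIEAK")
  tr <- generate_trajectory(s, n_frames = 200, dt = 1, sigma = 0.1, seed = 1)
  half <- window_frames(tr, fraction = 0.5)
  expect_equal(half$frame_times, 101:200)
  expect_identical(window_frames(tr, fraction = 1)$frames, tr$frames)

  # non-uniform times, "last 100 ns of a 200 ns run" on a 7-frame toy:
  # times 5, 50, 99, 100.5, 120, 180, 200 -> keep the 4 frames after 100 ns
  toy <- trajectory(s, tr$frames[1:7],
                    c(5, 50, 99, 100.5, 120, 180, 200))
  win <- window_frames(toy, span = 100)
  expect_equal(win$frame_times, c(100.5, 120, 180, 200))
  expect_identical(win$frames, tr$frames[4:7])

  expect_error(window_frames(tr, fraction = 0),
               class = "coilscreen_validation_error")
  expect_error(window_frames(toy, span = -5),
               class = "coilscreen_validation_error")
})

test_that("Kabsch superposition recovers rigid motions exactly", {
  s <- build_coiled_coil(sip_cc_demo_sequence())
  m <- coilscreen:::coords_matrix(s)
  expect_lt(superpose_kabsch(m, m)$rmsd, 1e-12)
  set.seed(8)
  for (i in 1:10) {
    moved <- m %*% random_rotation()
    moved <- sweep(moved, 2, rnorm(3, sd = 50), "+")
    fit <- superpose_kabsch(moved, m)
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    expect_equal(fit$transform(moved), m, ignore_attr = TRUE,
                 tolerance = 1e-6)
  }
})

test_that("RMSD agrees with a rotation-grid brute force on a 4-point toy", {
  p <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  q <- p
  q[4, ] <- q[4, ] + c(1, 0, 0)                 # one point displaced by 1 A
  fit <- superpose_kabsch(q, p)
  oracle <- grid_search_rmsd(q, p)
  expect_equal(fit$rmsd, oracle, tolerance = 1e-3)
  expect_lte(fit$rmsd, oracle + 1e-9)           # Kabsch is the minimum
})

test_that("degenerate selections are refused", {
  m <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_error(superpose_kabsch(m, m), "3 atoms",
               class = "coilscreen_degeneracy_error")
  line <- cbind(0:4, 0, 0)
  expect_error(superpose_kabsch(line, line), "collinear",
               class = "coilscreen_degeneracy_error")
})

test_that("RMSD profiles track the generator noise", {
  s <- build_coiled_coil(sip_cc_demo_sequence())
  flat <- rmsd_profile(generate_trajectory(s, 10, sigma = 0, seed = 1))
  expect_equal(nrow(flat), 10)
  expect_true(all(flat$rmsd < 1e-9))
  means <- sapply(c(0.1, 0.5, 1.0), function(sg) {
    mean(rmsd_profile(generate_trajectory(s, 30, sigma = sg,
                                          seed = 77))$rmsd)
  })
  expect_true(all(diff(means) > 0))
  bad_ref <- build_coiled_coil("LEAIEAK")
  expect_error(rmsd_profile(generate_trajectory(s, 3, seed = 1), bad_ref),
               class = "coilscreen_topology_error")
})

test_that("occupancy equals the per-frame distance check", {
  s <- build_coiled_coil(sip_cc_demo_sequence())
  spec <- interaction_spec("sb", "salt_bridge",
                           list(chain = "A", residue_index = 30),
                           list(chain = "B", residue_index = 34))
  set.seed(12)
  sched <- interaction_schedule(spec, present = sample(rep(c(TRUE, FALSE),
                                                           c(37, 13))))
  tr <- generate_trajectory(s, 50, sigma = 0.3, schedules = sched, seed = 6)
  occ <- interaction_occupancy(tr, spec)
  expect_identical(occ$occupancy, 0.74)

  # independent per-frame check straight from the coordinates
  ia <- which(s$atoms$chain_id == "A" & s$atoms$residue_index == 30 &
                s$atoms$atom_name == "SC")
  ib <- which(s$atoms$chain_id == "B" & s$atoms$residue_index == 34 &
                s$atoms$atom_name == "SC")
  present <- vapply(tr$frames, function(f)
    sqrt(sum((f[ia, ] - f[ib, ])^2)) <= 4.0, logical(1))
  expect_identical(occ$frames_present, sum(present))
  expect_identical(occ$frames_evaluated, 50L)

  always <- interaction_schedule(spec, present = rep(TRUE, 20))
  tr2 <- generate_trajectory(s, 20, sigma = 0.2, schedules = always,
                             seed = 2)
  expect_identical(interaction_occupancy(tr2, spec)$occupancy, 1)

  bad <- interaction_spec("nope", "salt_bridge",
                          list(chain = "A", residue_index = 999),
                          list(chain = "B", residue_index = 34))
  expect_error(interaction_occupancy(tr, bad), "nope",
               class = "coilscreen_selector_error")
})

test_that("average structures are superposed per-atom means", {
  s <- build_coiled_coil("LEAIEAKLQAVENK")
  one <- generate_trajectory(s, 1, sigma = 0, seed = 1)
  expect_equal(coilscreen:::coords_matrix(average_structure(one)),
               coilscreen:::coords_matrix(s), ignore_attr = TRUE)

  # +/- d displacement of one SC atom averages to the midpoint
  base <- coilscreen:::coords_matrix(s)
  sc1 <- which(s$atoms$atom_name == "SC")[1]
  up <- base; up[sc1, 1] <- up[sc1, 1] + 1
  dn <- base; dn[sc1, 1] <- dn[sc1, 1] - 1
  tr <- trajectory(s, list(up, dn), c(1, 2))
  expect_equal(coilscreen:::coords_matrix(average_structure(tr)), base,
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_false(isTRUE(average_structure(tr)$metadata$minimized))

  # brute-force oracle: superpose each frame independently, then average
  noisy <- generate_trajectory(s, 8, sigma = 0.4, seed = 21)
  bb <- which(s$atoms$atom_name %in% c("N", "CA", "C", "O"))
  acc <- 0
  for (f in noisy$frames) {
    acc <- acc + superpose_kabsch(f, noisy$frames[[1]],
                                  selection = bb)$transform(f)
  }
  expect_equal(coilscreen:::coords_matrix(average_structure(noisy)),
               acc / 8, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("per-frame binding energies match brute-force decomposition", {
  e <- zero_pair_matrix()
  e["L", "L"] <- -2.0
  p <- contact_potential(e)
  dimer <- make_sc_structure(list(
    list(chain = "A", resno = 1, code = "L", x = 0, y = 0, z = 0),
    list(chain = "B", resno = 1, code = "L", x = 4, y = 0, z = 0)))
  tr <- generate_trajectory(dimer, 5, sigma = 0, seed = 1)
  be <- binding_energy_over_frames(tr, p)
  expect_equal(be$mean_dG, -2)
  expect_equal(be$sem_dG, 0)
  expect_equal(tidy(be)$dG, rep(-2, 5))

  pd <- default_contact_potential()
  s <- random_sc_structure(6, seed = 3)
  noisy <- generate_trajectory(s, 6, sigma = 0.3, seed = 4)
  be2 <- binding_energy_over_frames(noisy, pd)
  brute <- vapply(seq_len(6), function(i)
    brute_force_inter_chain(frame_structure(noisy, i), pd), numeric(1))
  expect_equal(be2$per_frame$dG, brute, tolerance = 1e-9)

  apart <- s
  bsel <- apart$atoms$chain_id == "B"
  apart$atoms$x[bsel] <- apart$atoms$x[bsel] + 100
  far <- generate_trajectory(apart, 4, sigma = 0.1, seed = 5)
  expect_equal(binding_energy_over_frames(far, pd)$mean_dG, 0)
})

test_that("replicate pooling recomputes mean and SEM over all frames", {
  mk <- function(dgs, id) {
    coilscreen:::new_binding_energy(
      tibble::tibble(time = seq_along(dgs), dG = dgs), replicate_id = id)
  }
  a <- mk(c(-1, -1, -1), 1L)
  b <- mk(c(-3, -3, -3), 2L)
  pooled <- merge_replicates(list(a, b))
  expect_equal(pooled$mean_dG, -2)
  expect_identical(merge_replicates(list(a))$mean_dG, a$mean_dG)

  set.seed(9)
  x <- mk(rnorm(10, -2), 1L)
  y <- mk(rnorm(7, -1), 2L)
  pooled2 <- merge_replicates(list(x, y))
  all_dg <- c(x$per_frame$dG, y$per_frame$dG)
  expect_equal(pooled2$mean_dG, mean(all_dg), tolerance = 1e-12)
  expect_equal(pooled2$sem_dG, sd(all_dg) / sqrt(17), tolerance = 1e-12)
  # convexity: the pooled mean lies between the replicate means
  expect_gte(pooled2$mean_dG, min(x$mean_dG, y$mean_dG))
  expect_lte(pooled2$mean_dG, max(x$mean_dG, y$mean_dG))
  expect_equal(pooled2$replicate_means$mean_dG, c(x$mean_dG, y$mean_dG))
  expect_error(merge_replicates(list()),
               class = "coilscreen_validation_error")
})
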