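test_that("site enumeration reproduces the window combinatorics", {
  w <- design_window()                          # residues 3-46
  expect_identical(enumerate_single_sites(w), 3:46)
  expect_length(enumerate_single_sites(w), 44)
  pairs <- enumerate_pairs(w)
  expect_equal(nrow(pairs), 205)
  expect_true(all(pairs$pos_j - pairs$pos_i - 1 <= 4))

  expect_identical(enumerate_single_sites(design_window(5, 5, 0)), 5L)
  expect_length(enumerate_single_sites(design_window(1, 10)), 10)
  expect_equal(nrow(enumerate_pairs(design_window(7, 8, 0))), 1)

  # brute-force enumeration oracle on a small window
  w2 <- design_window(1, 5, max_intervening = 1)
  brute <- list()
  for (i in 1:5) for (j in 1:5) {
    if (j > i && (j - i - 1) <= 1) brute[[length(brute) + 1]] <- c(i, j)
  }
  p2 <- enumerate_pairs(w2)
  expect_equal(nrow(p2), length(brute))         # sum_{d=1..2}(5-d) = 7
  expect_equal(unname(as.matrix(p2)), do.call(rbind, brute))
  expect_error(design_window(10, 5), class = "coilscreen_validation_error")
})

test_that("the record count is |ensemble| x |sites| x n_models, always", {
  s <- build_coiled_coil(sip_cc_demo_sequence())
  ens <- generate_ensemble(s, 3, 0.2, seed = 1)
  cases <- list(list(sites = 5:9, n_models = 4),
                list(sites = enumerate_pairs(design_window(5, 9, 1)),
                     n_models = 2),
                list(sites = 12L, n_models = 1))
  for (cs in cases) {
    n_sites <- if (is.data.frame(cs$sites)) nrow(cs$sites) else
      length(cs$sites)
    rec <- run_design(ens, cs$sites, n_models = cs$n_models, seed = 2,
                      scoring = "none")
    expect_equal(nrow(rec), 3 * n_sites * cs$n_models)
  }
  rec1 <- run_design(ens[1], 5L, n_models = 1, seed = 1)
  expect_equal(nrow(rec1), 1)
  expect_error(run_design(list(), 5L), class = "coilscreen_validation_error")
  expect_error(run_design(ens, integer(0)),
               class = "coilscreen_validation_error")
})

test_that("designed records are seeded and include wild-type re-introduction", {
  s <- build_coiled_coil(sip_cc_demo_sequence())
  ens <- generate_ensemble(s, 2, 0.2, seed = 1)
  rec_a <- run_design(ens, 3:10, n_models = 20, seed = 7)
  rec_b <- run_design(ens, 3:10, n_models = 20, seed = 7)
  expect_identical(rec_a, rec_b)
  expect_gt(sum(rec_a$signature == ""), 0)      # natives re-introduced
  # signatures only touch designed positions, at most one per single screen
  sig_pos <- as.integer(sub("[A-Z]$", "", rec_a$signature[
    rec_a$signature != ""]))
  expect_true(all(sig_pos %in% 3:10))
})

test_that("variant summaries match a brute-force group-and-average pass", {
  set.seed(31)
  sigs <- c("", "5W", "7E", "5W_9K")
  records <- tibble::tibble(
    ensemble_member = 1L, site_label = "x", model_index = 1L,
    signature = sample(sigs, 30, replace = TRUE, prob = c(.4, .2, .2, .2)),
    total_score = rnorm(30), mono_score = rnorm(30), dG = rnorm(30))
  summ <- summarize_variants(records)

  wt_dg <- mean(records$dG[records$signature == ""])
  wt_mono <- mean(records$mono_score[records$signature == ""])
  for (sg in unique(records$signature)) {
    rows <- records[records$signature == sg, ]
    got <- summ[summ$signature == sg, ]
    expect_equal(got$n_models, nrow(rows))
    expect_equal(got$mean_dG, mean(rows$dG), tolerance = 1e-12)
    expect_equal(got$mean_mono_score, mean(rows$mono_score),
                 tolerance = 1e-12)
    expect_equal(got$ddG, mean(rows$dG) - wt_dg, tolerance = 1e-12)
    expect_equal(got$d_mono, mean(rows$mono_score) - wt_mono,
                 tolerance = 1e-12)
  }
  # the reference group is exactly zero by construction
  expect_identical(summ$ddG[summ$signature == ""], 0)
  expect_identical(summ$d_mono[summ$signature == ""], 0)

  no_wt <- records[records$signature != "", ]
  expect_error(summarize_variants(no_wt), "reference group",
               class = "coilscreen_reference_error")
})

test_that("worked arithmetic: variant {-1, -3} against wt mean -1", {
  records <- tibble::tibble(
    ensemble_member = 1L, site_label = "5", model_index = 1:4,
    signature = c("", "", "5W", "5W"),
    total_score = 0, mono_score = c(2, 2, 2.5, 2.5),
    dG = c(-1, -1, -1, -3))
  summ <- summarize_variants(records)
  v <- summ[summ$signature == "5W", ]
  expect_equal(v$mean_dG, -2)
  expect_equal(v$ddG, -1)
  expect_equal(v$d_mono, 0.5)
})

test_that("selection keeps negative ddG with near-zero monomer shift", {
  base <- tibble::tibble(
    signature = c("", sprintf("%dX", 1:12)),
    n_models = 10,
    mean_dG = 0, mean_mono_score = 0,
    ddG = c(0, -0.5, 0.2, -0.1, -2, 0.4, -0.3, 1, -0.9, 0.1, -0.05, 0.3, -4),
    d_mono = c(0, 0.1, 0, 0.9, 0.2, 0, 1.2, 0, -0.4, 0, 0.51, 0, -0.5),
    selected = FALSE)
  class(base) <- c("variant_summary", class(base))
  picked <- select_candidates(base, epsilon_mono = 0.5)
  # by hand: rows with ddG < 0 AND |d_mono| <= 0.5 -> signatures 1X, 4X, 8X, 12X
  expect_identical(picked$signature, c("12X", "4X", "8X", "1X"))
  expect_equal(nrow(picked), 4)
  expect_true(all(picked$selected))
  expect_true(all(diff(picked$ddG) >= 0))       # ascending ddG
  expect_error(select_candidates(base, -1),
               class = "coilscreen_validation_error")

  one <- base[base$signature %in% c("", "2X"), ]
  expect_equal(nrow(select_candidates(one, 0.5)), 0)
})

test_that("a rigged interface reward is recovered as the top single variant", {
  # reward Trp contacting the lone Ile placed at position 25: across the
  # dimer interface only position 22 reaches it, so (22, W) must win
  wt <- paste(rep("A", 46), collapse = "")
  substr(wt, 25, 25) <- "I"
  s <- build_coiled_coil(wt)
  e <- zero_pair_matrix()
  e["W", "I"] <- e["I", "W"] <- -5
  p <- contact_potential(e, contact_cutoff = 5, clash_distance = 2,
                         clash_penalty = 10)
  for (seed in 1:2) {
    ens <- generate_ensemble(s, 4, 0.15, seed = seed)
    rec <- run_design(ens, enumerate_single_sites(design_window()),
                      n_models = 20, p = p, seed = seed)
    summ <- summarize_variants(rec)
    top <- summ[summ$signature != "", ][1, ]
    expect_identical(top$signature, "22W")
    expect_lt(top$ddG, 0)
  }
})

test_that("uniformly strengthening a residue's row never raises its ddG", {
  wt <- paste(rep("A", 46), collapse = "")
  substr(wt, 25, 25) <- "I"
  s <- build_coiled_coil(wt)
  ens <- generate_ensemble(s, 2, 0.15, seed = 3)
  base <- default_contact_potential()
  e2 <- base$pair_energies
  e2["W", ] <- e2["W", ] - 1
  e2[, "W"] <- e2["W", ]
  stronger <- contact_potential(e2)
  sites <- enumerate_single_sites(design_window())
  s1 <- summarize_variants(run_design(ens, sites, 10, p = base, seed = 5))
  s2 <- summarize_variants(run_design(ens, sites, 10, p = stronger, seed = 5))
  w_sigs <- s1$signature[grepl("W$", s1$signature)]
  merged <- merge(s1[s1$signature %in% w_sigs, c("signature", "ddG")],
                  s2[s2$signature %in% w_sigs, c("signature", "ddG")],
                  by = "signature")
  expect_gt(nrow(merged), 5)
  expect_true(all(merged$ddG.y <= merged$ddG.x + 1e-9))
})

test_that("glance and autoplot summarise a screen", {
  s <- build_coiled_coil(sip_cc_demo_sequence())
  ens <- generate_ensemble(s, 2, 0.2, seed = 1)
  summ <- summarize_variants(run_design(ens, 3:12, n_models = 10, seed = 2))
  g <- glance(summ)
  expect_equal(g$n_models, 2 * 10 * 10)
  expect_s3_class(autoplot(summ), "ggplot")
})
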