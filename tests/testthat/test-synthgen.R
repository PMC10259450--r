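test_that("generators are pure functions of their seed", {
  expect_equal(ape::write.tree(gen_tree(10, seed = 5)),
               ape::write.tree(gen_tree(10, seed = 5)))
  expect_false(ape::write.tree(gen_tree(10, seed = 5)) ==
                 ape::write.tree(gen_tree(10, seed = 6)))

  i1 <- gen_islands(5, seed = 9); i2 <- gen_islands(5, seed = 9)
  expect_equal(i1$polygons, i2$polygons)

  im <- gen_islands(4, seed = 1)
  g1 <- gen_pair_scenario("parapatric", im, seed = 3)
  g2 <- gen_pair_scenario("parapatric", im, seed = 3)
  expect_identical(g1$occurrences, g2$occurrences)
  expect_identical(g1$leaves, g2$leaves)

  tr <- gen_tree(12, seed = 2)
  expect_equal(gen_trait_bm(tr, seed = 4), gen_trait_bm(tr, seed = 4))

  st <- build_states(c("A", "B"))
  cfg <- biogeo_config("DEC", d = 0.2, e = 0.02)
  expect_equal(gen_range_history(tr, cfg, st, seed = 7)$tip_ranges,
               gen_range_history(tr, cfg, st, seed = 7)$tip_ranges)

  # the global RNG stream is left untouched
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(gen_tree(10, seed = 5)); after <- stats::runif(1)
  expect_equal(before, after)
})

test_that("simulated trees are ultrametric with the requested size", {
  t2 <- gen_tree(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_equal(nrow(extract_cherries(t2)), 1)
  t30 <- gen_tree(30, seed = 1)
  expect_true(ape::is.ultrametric(t30, tol = 1e-8))
  expect_error(gen_tree(1), "n_tips")

  # mean height grows with tip count at fixed birth rate
  h10 <- mean(vapply(1:25, function(s) tree_height(gen_tree(10, seed = s)), 0))
  h80 <- mean(vapply(1:25, function(s) tree_height(gen_tree(80, seed = s)), 0))
  expect_gt(h80, h10)
})

test_that("generated islands are disjoint with optional bioregion grouping", {
  im <- gen_islands(9, n_bioregions = 3, seed = 2)
  expect_equal(length(im$polygons), 9)
  expect_equal(sort(unique(im$bioregion)), c("R1", "R2", "R3"))
  # pairwise disjoint: no vertex of one polygon inside another
  for (i in seq_along(im$polygons)) for (k in seq_along(im$polygons)) {
    if (i == k) next
    p <- im$polygons[[i]]; q <- im$polygons[[k]]
    inside <- any(vapply(seq_len(nrow(p)), function(r)
      sisterdiv:::point_in_polygon(p[r, 1], p[r, 2], q), TRUE))
    expect_false(inside)
  }
  expect_error(gen_islands(2, island_size = 2, spacing = 1), "spacing")
})

test_that("pair scenarios place occurrences and shift leaf areas as labelled", {
  im <- gen_islands(6, seed = 10)
  alo <- gen_pair_scenario("allopatric_conserved", im, seed = 1)
  sets <- assign_islands(alo$occurrences, im)$sets
  expect_equal(length(intersect(sets$sp1, sets$sp2)), 0)
  expect_equal(alo$truth$delta, 0)

  par <- gen_pair_scenario("parapatric", im, delta = 2, seed = 1)
  setsp <- assign_islands(par$occurrences, im)$sets
  expect_gt(length(intersect(setsp$sp1, setsp$sp2)), 0)
  m <- species_mean_log_area(par$leaves)
  expect_gt(m["sp2"] - m["sp1"], 1)   # delta = 2 with se ~ 0.1

  expect_equal(gen_pair_scenario("inconclusive", im, seed = 2)$truth$delta, 0)
  one <- gen_islands(1, seed = 1)
  expect_error(gen_pair_scenario("allopatric_diverged", one), "2 islands")
})

test_that("lambda-scaled Brownian draws have the advertised covariance", {
  tr <- parse_chronogram("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  # iid at lambda = 0: off-diagonal correlations vanish
  X0 <- vapply(1:400, function(s) gen_trait_bm(tr, lambda = 0, seed = s),
               numeric(4))
  C0 <- stats::cov(t(X0))
  expect_lt(max(abs(C0[upper.tri(C0)])), 0.15)
  expect_equal(unname(diag(C0)), rep(2, 4), tolerance = 0.35)

  X1 <- vapply(1:400, function(s) gen_trait_bm(tr, lambda = 0.7, seed = s),
               numeric(4))
  C1 <- stats::cov(t(X1))
  expect_equal(unname(C1), unname(lambda_covariance(tr, 0.7)),
               tolerance = 0.35, ignore_attr = TRUE)
})

test_that("forward range simulation matches the anagenetic kernel and conventions", {
  st <- build_states(c("A", "B"))
  # without anagenetic events and with range-copying cladogenesis, every
  # tip inherits the root state exactly
  cfg0 <- biogeo_config("BAYAREALIKE", d = 0, e = 0)
  tr <- gen_tree(8, seed = 3)
  sim0 <- gen_range_history(tr, cfg0, st, seed = 4)
  states_hit <- unique(vapply(sim0$tip_ranges, paste, "", collapse = ""))
  expect_equal(length(states_hit), 1)   # all tips inherit the root state

  # empirical branch-transition frequencies vs exp(Q t)
  cfg <- biogeo_config("DEC", d = 0.3, e = 0.15)
  Q <- anagenetic_Q(cfg, st)
  masks_full <- c(0L, st$masks)
  t_br <- 1.7
  set.seed(55)
  ends <- replicate(8000, sisterdiv:::sim_branch(1L, t_br, Q, masks_full))
  emp <- as.numeric(table(factor(ends, levels = masks_full))) / 8000
  theo <- as.numeric(sisterdiv:::transition_probs(Q, t_br)[[1]][2, ])
  expect_true(all(abs(emp - theo) < 0.02))

  # survival conditioning: no tip ever carries the null range
  cfge <- biogeo_config("DEC", d = 0.05, e = 0.4)
  sim <- gen_range_history(gen_tree(10, seed = 6), cfge, st, seed = 7)
  expect_true(all(vapply(sim$tip_ranges, length, 0L) > 0))
  expect_gte(sim$n_redraws, 0)
})

test_that("a simulated study round-trips through the pipeline readers", {
  sd <- simulate_study(n_pairs = 3,
                       scenarios = c("allopatric_conserved", "parapatric",
                                     "inconclusive"), seed = 8)
  expect_equal(nrow(sd$pairs), 3)
  expect_equal(length(sd$truth), 3)

  tmp <- withr::local_tempdir()
  occ_csv <- file.path(tmp, "occ.csv")
  leaf_csv <- file.path(tmp, "leaves.csv")
  isl_json <- file.path(tmp, "islands.geojson")
  utils::write.csv(sd$occurrences, occ_csv, row.names = FALSE)
  utils::write.csv(sd$leaves, leaf_csv, row.names = FALSE)
  write_islands(sd$islands, isl_json)
  occ2 <- load_occurrences(occ_csv)
  expect_equal(nrow(occ2), nrow(sd$occurrences))
  expect_equal(nrow(load_leaf_table(leaf_csv)), nrow(sd$leaves))
  expect_equal(names(read_islands(isl_json)$polygons),
               names(sd$islands$polygons))
})
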