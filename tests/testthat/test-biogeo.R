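st2 <- build_states(c("A", "B"))
st3 <- build_states(c("A", "B", "C"))

test_that("state enumeration is complete, ordered and guarded", {
  expect_equal(length(build_states(LETTERS[1:8])$masks), 255)
  expect_equal(st2$labels, c("A", "B", "AB"))
  expect_equal(length(build_states(LETTERS[1:3], max_size = 2)$masks), 6)
  expect_error(build_states(c("A", "A")), "unique")
  expect_error(build_states(LETTERS[1:3], max_size = 5), "max_size")
})

test_that("the anagenetic rate matrix encodes expansion/contraction and conserves rate", {
  cfg <- biogeo_config("DEC", d = 0.1, e = 0.05)
  Q <- anagenetic_Q(cfg, st2)
  expect_equal(Q["A", "AB"], 0.1)     # expansion
  expect_equal(Q["AB", "A"], 0.05)    # contraction
  expect_equal(Q["A", "-"], 0.05)     # single-area loss -> null
  expect_equal(Q["-", "A"], 0)        # null is absorbing
  expect_true(all(abs(rowSums(Q)) < 1e-12))

  expect_true(all(anagenetic_Q(biogeo_config("DEC", d = 0, e = 0), st3) == 0))

  set.seed(8)
  for (i in 1:5) {
    cfgr <- biogeo_config(sample(c("DEC", "DIVALIKE", "BAYAREALIKE"), 1),
                          d = stats::runif(1, 0, 2),
                          e = stats::runif(1, 0, 2))
    expect_true(all(abs(rowSums(anagenetic_Q(cfgr, st3))) < 1e-10))
  }

  # max_size caps expansion
  stc <- build_states(c("A", "B", "C"), max_size = 1)
  Qc <- anagenetic_Q(biogeo_config("DEC", d = 0.1, e = 0), stc)
  expect_true(all(Qc == 0))
})

test_that("cladogenetic tables match each model's event classes", {
  dec <- biogeo_config("DEC")
  # single-area ancestor: identical daughters with probability 1
  tabE <- clado_table(dec, "A", st3)
  expect_equal(nrow(tabE), 1)
  expect_equal(tabE$prob, 1)
  expect_equal(tabE$left, "A"); expect_equal(tabE$right, "A")

  # widespread DEC ancestor {A,B}: 6 equiprobable ordered outcomes,
  # 4 subset-sympatric + 2 vicariant (frozen enumeration)
  tabAB <- clado_table(dec, c("A", "B"), st2)
  expect_equal(nrow(tabAB), 6)
  expect_equal(tabAB$prob, rep(1 / 6, 6))
  key <- paste(tabAB$left, tabAB$right, sep = "|")
  expect_setequal(key, c("A|AB", "AB|A", "B|AB", "AB|B", "A|B", "B|A"))

  # DIVALIKE widespread: vicariance only, widespread splits included
  diva <- biogeo_config("DIVALIKE")
  tabD <- clado_table(diva, c("A", "B", "C"), st3)
  expect_equal(nrow(tabD), 6)   # 2^3 - 2 ordered splits
  expect_false(any(tabD$left == "ABC" | tabD$right == "ABC"))

  # BAYAREALIKE: full-range inheritance
  bay <- biogeo_config("BAYAREALIKE")
  tabB <- clado_table(bay, c("A", "C"), st3)
  expect_equal(nrow(tabB), 1)
  expect_equal(tabB$left, "AC"); expect_equal(tabB$right, "AC")

  # probabilities always sum to 1; j = 0 reproduces the base table
  for (m in c("DEC", "DIVALIKE", "BAYAREALIKE")) {
    for (anc in list("A", c("A", "B"), c("A", "B", "C"))) {
      t0 <- clado_table(biogeo_config(m), anc, st3)
      tj0 <- clado_table(biogeo_config(m, plus_j = TRUE, j = 0), anc, st3)
      tj <- clado_table(biogeo_config(m, plus_j = TRUE, j = 1.2), anc, st3)
      expect_equal(sum(t0$prob), 1)
      expect_equal(sum(tj$prob), 1)
      expect_equal(t0, tj0)
    }
  }

  # jump daughters are single unoccupied areas
  tj <- clado_table(biogeo_config("DEC", plus_j = TRUE, j = 1), "A", st3)
  jumps <- tj[tj$left != tj$right, ]
  expect_setequal(unique(c(jumps$left, jumps$right)), c("A", "B", "C"))
  expect_error(clado_table(dec, integer(0), st3))
})

test_that("branch transition matrices are proper stochastic matrices", {
  set.seed(3)
  for (i in 1:5) {
    cfg <- biogeo_config("DEC", d = stats::runif(1, 0, 1),
                         e = stats::runif(1, 0, 1))
    Q <- anagenetic_Q(cfg, st3)
    for (t in c(0.01, 0.5, 3)) {
      P <- sisterdiv:::transition_probs(Q, t)[[1]]
      expect_true(all(P >= 0))
      expect_true(all(abs(rowSums(P) - 1) < 1e-10))
    }
  }
})

test_that("pruning likelihood equals brute-force enumeration on small trees", {
  tr2 <- parse_chronogram("(A:1,B:1);")
  tr3 <- parse_chronogram("((A:0.6,B:0.6):0.9,C:1.5);")
  tips2 <- list(A = "A", B = "B")
  tips3 <- list(A = "A", B = c("A", "B"), C = "C")
  cfgs <- list(
    biogeo_config("DEC", d = 0.2, e = 0.1),
    biogeo_config("DEC", plus_j = TRUE, d = 0.05, e = 0.02, j = 0.7),
    biogeo_config("DIVALIKE", d = 0.3, e = 0.05),
    biogeo_config("DIVALIKE", plus_j = TRUE, d = 0.1, e = 0.1, j = 1.5),
    biogeo_config("BAYAREALIKE", d = 0.2, e = 0.3),
    biogeo_config("BAYAREALIKE", plus_j = TRUE, d = 0.15, e = 0.01, j = 0.3))
  for (cfg in cfgs) {
    expect_equal(model_lnL(tr2, tips2, cfg, st2),
                 log(oracle_biogeo_lik(tr2, tips2, cfg, st2)),
                 tolerance = 1e-8, info = model_name(cfg))
    expect_equal(model_lnL(tr3, tips3, cfg, st3),
                 log(oracle_biogeo_lik(tr3, tips3, cfg, st3)),
                 tolerance = 1e-8, info = paste(model_name(cfg), "3tip"))
  }
})

test_that("likelihood conventions: no-event certainty, tip-order invariance, +J nesting", {
  tr <- parse_chronogram("((A:1,B:1):1,C:2);")
  cfg0 <- biogeo_config("DEC", d = 0, e = 0)
  # no events possible and all tips identical: probability 1
  expect_equal(model_lnL(tr, list(A = "A", B = "A", C = "A"), cfg0, st3), 0)

  cfg <- biogeo_config("DIVALIKE", d = 0.2, e = 0.05)
  tips <- list(A = "A", B = c("B", "C"), C = "C")
  expect_equal(model_lnL(tr, tips, cfg, st3),
               model_lnL(tr, tips[c(3, 1, 2)], cfg, st3))

  # +J with j = 0 collapses to the base model
  for (m in c("DEC", "DIVALIKE", "BAYAREALIKE")) {
    base <- biogeo_config(m, d = 0.1, e = 0.05)
    pj <- biogeo_config(m, plus_j = TRUE, d = 0.1, e = 0.05, j = 0)
    expect_equal(model_lnL(tr, tips, pj, st3),
                 model_lnL(tr, tips, base, st3), tolerance = 1e-10)
  }

  expect_error(model_lnL(tr, list(A = "A", B = "B"), cfg, st3),
               "tip without range")
})

test_that("model fitting respects nesting and the AIC identity", {
  tr <- gen_tree(25, seed = 41)
  sim <- gen_range_history(tr, biogeo_config("DEC", d = 0.2, e = 0.05),
                           st3, seed = 42)
  base <- fit_model(tr, sim$tip_ranges, biogeo_config("DEC"), st3)
  plus <- fit_model(tr, sim$tip_ranges,
                    biogeo_config("DEC", plus_j = TRUE), st3)
  expect_gte(plus$lnl, base$lnl - 1e-6)   # nested models
  expect_equal(base$aic, 2 * 2 - 2 * base$lnl)
  expect_equal(plus$aic, 2 * 3 - 2 * plus$lnl)
  expect_gte(base$config$d, 0)
  expect_lte(base$config$d, 5)
})

test_that("ancestral marginals are proper and match enumeration at the root", {
  tr3 <- parse_chronogram("((A:0.6,B:0.6):0.9,C:1.5);")
  tips3 <- list(A = "A", B = c("A", "B"), C = "C")
  cfg <- biogeo_config("DEC", d = 0.15, e = 0.05)
  fit <- list(config = cfg, tree = tr3, tip_ranges = tips3, states = st3)
  class(fit) <- "biogeo_fit"
  anc <- ancestral_ranges(fit)
  expect_true(all(abs(rowSums(anc$prob) - 1) < 1e-9))
  root_row <- anc$prob["A|B|C", ]
  oracle <- oracle_root_marginal(tr3, tips3, cfg, st3)
  expect_equal(unname(root_row), unname(oracle[colnames(anc$prob)]),
               tolerance = 1e-6)

  # degenerate certainty: no events, single shared area
  fit0 <- list(config = biogeo_config("DEC", d = 0, e = 0), tree = tr3,
               tip_ranges = list(A = "A", B = "A", C = "A"), states = st3)
  class(fit0) <- "biogeo_fit"
  anc0 <- ancestral_ranges(fit0)
  expect_equal(unname(anc0$prob[, "A"]), c(1, 1))
  expect_equal(unname(anc0$mpr), c("A", "A"))
})

test_that("model ranking sorts by AIC with parameter-count tie-breaks", {
  tab <- data.frame(model = c("M1", "M2", "M3"),
                    lnl = c(-10, -10, -9), k = c(3L, 2L, 3L))
  r <- rank_models(tab)
  expect_equal(r$model, c("M2", "M3", "M1"))  # AIC tie at 24 -> smaller k
  expect_equal(r$delta[1], 0)
  expect_equal(r$aic, 2 * r$k - 2 * r$lnl)

  # mixed datasets refuse to rank
  trA <- gen_tree(6, seed = 1); trB <- gen_tree(7, seed = 2)
  fA <- list(tree = trA, lnl = -5, k = 2L,
             config = biogeo_config("DEC"))
  fB <- list(tree = trB, lnl = -5, k = 2L,
             config = biogeo_config("DEC"))
  class(fA) <- class(fB) <- "biogeo_fit"
  expect_error(model_selection(list(fA, fB)), "different datasets")
})

test_that("tip ranges are coded from occurrences in bioregions and round-trip", {
  im <- gen_islands(4, n_bioregions = 2, seed = 5)
  cent <- t(vapply(im$polygons, colMeans, numeric(2)))
  occ <- load_occurrences(data.frame(
    species = c("x", "x", "y"),
    lon = cent[c(1, 3, 2), 1], lat = cent[c(1, 3, 2), 2]))
  tr <- code_tip_ranges(occ, im)
  expect_setequal(tr$x, unique(im$bioregion[c(1, 3)]))
  expect_equal(tr$y, im$bioregion[2])

  out <- load_occurrences(data.frame(species = "z", lon = 170, lat = -80))
  expect_error(code_tip_ranges(out, im), "outside every bioregion")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_tip_ranges(tr, sort(unique(im$bioregion)), path)
  back <- read_tip_ranges(path)
  expect_equal(lapply(back, sort), lapply(tr[names(back)], sort))
})
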