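# Synthetic data with known ground truth: trees, island geographies,
# occurrence clusters, lognormal leaf areas, lambda-scaled Brownian traits,
# and forward-simulated range histories. Every generator is a pure function
# of (arguments, seed).

#' Simulate an ultrametric pure-birth chronogram
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per Myr.
#' @param seed RNG seed.
#' @return a `phylo` tree with tips `t1..tn`.
#' @export
gen_tree <- function(n_tips, birth_rate = 1, seed = 1) {
  if (n_tips < 2) abort("n_tips must be >= 2")
  with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
}

#' Generate a map of disjoint rectangular habitat islands
#'
#' Islands are laid out on a jittered lattice so polygons never overlap —
#' the geometry mimics mountaintop habitat patches separated by unsuitable
#' lowlands. Optionally islands are grouped into contiguous bioregions.
#'
#' @param n_islands number of islands (>= 1).
#' @param n_bioregions optional number of bioregions to partition islands
#'   into (labels `R1..Rk`); `NULL` for none.
#' @param island_size polygon edge length, degrees.
#' @param spacing lattice pitch, degrees; must exceed `island_size`.
#' @param origin lattice lower-left corner (lon, lat).
#' @param seed RNG seed (controls the jitter).
#' @return an `island_map` with ids `I1..In`.
#' @export
gen_islands <- function(n_islands, n_bioregions = NULL, island_size = 0.3,
                        spacing = 1, origin = c(-75, 2), seed = 1) {
  if (n_islands < 1) abort("n_islands must be >= 1")
  if (spacing <= island_size)
    abort("spacing must exceed island_size for disjoint islands")
  ncol_ <- ceiling(sqrt(n_islands))
  with_seed(seed, {
    jit <- (spacing - island_size) * 0.5
    polys <- list()
    for (i in seq_len(n_islands)) {
      gx <- (i - 1) %% ncol_
      gy <- (i - 1) %/% ncol_
      x0 <- origin[1] + gx * spacing + stats::runif(1, 0, jit)
      y0 <- origin[2] + gy * spacing + stats::runif(1, 0, jit)
      polys[[paste0("I", i)]] <- cbind(
        c(x0, x0 + island_size, x0 + island_size, x0),
        c(y0, y0, y0 + island_size, y0 + island_size))
    }
    bior <- if (!is.null(n_bioregions))
      paste0("R", rep(seq_len(n_bioregions), length.out = n_islands))
    else NULL
    m <- island_map(polys, bior)
    # internal sanity check: lattice layout guarantees disjointness
    cents <- t(vapply(polys, colMeans, numeric(2)))
    if (nrow(cents) > 1 && min(stats::dist(cents)) < island_size)
      abort("generated islands overlap")
    m
  })
}

# uniform points inside a rectangle polygon
runif_in_polygon <- function(n, poly) {
  cbind(lon = stats::runif(n, min(poly[, 1]), max(poly[, 1])),
        lat = stats::runif(n, min(poly[, 2]), max(poly[, 2])))
}

#' Generate one sister pair under a named speciation scenario
#'
#' Emulates the four speciation scenarios of the decision matrix:
#' `allopatric_conserved` and `allopatric_diverged` place the two species'
#' occurrence clusters in disjoint islands, `parapatric` and `inconclusive`
#' place both in one island. `allopatric_diverged` and `parapatric` shift
#' the second species' log leaf-area mean by `delta`; the conserved and
#' inconclusive scenarios use `delta = 0`. Leaf areas are lognormal —
#' strictly positive with multiplicative variation, matching how leaf area
#' scales across habitats.
#'
#' @param scenario one of `"allopatric_conserved"`, `"allopatric_diverged"`,
#'   `"parapatric"`, `"inconclusive"`.
#' @param islands an `island_map` with at least 2 islands for allopatric
#'   scenarios.
#' @param species length-2 character vector of species names.
#' @param delta between-sister shift of log leaf area (log-mm^2 units).
#' @param sigma within-species SD of log leaf area.
#' @param log_mean log leaf-area mean of the first species.
#' @param n_leaves leaves measured per species (study design: 30).
#' @param n_occurrences occurrence records per species.
#' @param which_islands optional length-2 island ids (second ignored for
#'   same-island scenarios).
#' @param seed RNG seed.
#' @return list with `occurrences`, `leaves`, and `truth` (scenario label
#'   and generating parameters).
#' @export
gen_pair_scenario <- function(scenario = c("allopatric_conserved",
                                           "allopatric_diverged",
                                           "parapatric", "inconclusive"),
                              islands, species = c("sp1", "sp2"),
                              delta = 2, sigma = 0.5, log_mean = 3,
                              n_leaves = 30, n_occurrences = 20,
                              which_islands = NULL, seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(length(species) == 2, n_leaves >= 1, n_occurrences >= 1,
            sigma > 0, delta >= 0)
  allopatric <- scenario %in% c("allopatric_conserved", "allopatric_diverged")
  shifted <- scenario %in% c("allopatric_diverged", "parapatric")
  ids <- names(islands$polygons)
  if (allopatric && length(ids) < 2)
    abort("allopatric scenarios need at least 2 islands")
  with_seed(seed, {
    if (is.null(which_islands))
      which_islands <- if (allopatric) sample(ids, 2) else
        rep(sample(ids, 1), 2)
    isl <- if (allopatric) which_islands[1:2] else rep(which_islands[1], 2)
    occ <- do.call(rbind, lapply(1:2, function(k) {
      pts <- runif_in_polygon(n_occurrences, islands$polygons[[isl[k]]])
      data.frame(species = species[k], lon = pts[, "lon"],
                 lat = pts[, "lat"])
    }))
    mu <- c(log_mean, log_mean + if (shifted) delta else 0)
    leaves <- do.call(rbind, lapply(1:2, function(k) {
      data.frame(species = species[k],
                 specimen = paste0(species[k], "_ind",
                                   rep(seq_len(max(1, n_leaves %/% 5)),
                                       length.out = n_leaves)),
                 area_mm2 = stats::rlnorm(n_leaves, mu[k], sigma))
    }))
    list(occurrences = load_occurrences(occ),
         leaves = load_leaf_table(leaves),
         truth = list(scenario = scenario, delta = if (shifted) delta else 0,
                      sigma = sigma, islands = isl,
                      expected_category = switch(scenario,
                        allopatric_conserved = "geographic_isolation",
                        allopatric_diverged = "geographic_isolation",
                        parapatric = "parapatric_ecological",
                        inconclusive = "inconclusive")))
  })
}

#' Simulate a continuous trait under lambda-scaled Brownian motion
#'
#' Draws one multivariate-normal realisation with covariance
#' `lambda_covariance(tree, lambda) * sigma2` around `root`.
#'
#' @param tree a `phylo` chronogram.
#' @param sigma2 Brownian rate.
#' @param lambda phylogenetic-signal dial in `[0, 1]` (0 = iid tips,
#'   1 = Brownian motion).
#' @param root root (mean) value.
#' @param seed RNG seed.
#' @return named numeric vector of tip values.
#' @export
gen_trait_bm <- function(tree, sigma2 = 1, lambda = 1, root = 0, seed = 1) {
  C <- lambda_covariance(tree, lambda) * sigma2
  with_seed(seed, {
    L <- chol(C + diag(1e-12, nrow(C)))
    x <- root + as.numeric(t(L) %*% stats::rnorm(nrow(C)))
    stats::setNames(x, rownames(C))
  })
}

# Gillespie simulation of the anagenetic process along one branch:
# exponential waiting times at the current state's total rate, jump
# proportional to the off-diagonal rates. Null (mask 0) is absorbing.
# Exposed at top level so the anagenetic simulator can be validated against
# exp(Q t) directly.
sim_branch <- function(mask, t, Q, masks_full) {
  sidx <- integer(max(masks_full) + 1L)
  sidx[masks_full + 1L] <- seq_along(masks_full)
  repeat {
    i <- sidx[mask + 1L]
    rate <- -Q[i, i]
    if (rate <= 0) return(mask)
    w <- stats::rexp(1, rate)
    if (w > t) return(mask)
    t <- t - w
    probs <- Q[i, ]
    probs[i] <- 0
    nxt <- sample.int(length(probs), 1, prob = probs)
    mask <- masks_full[nxt]
    if (mask == 0L) return(0L)
  }
}

#' Forward-simulate a discrete range history on a tree
#'
#' Anagenesis: exponential waiting times between events with rates from
#' [anagenetic_Q()]. Cladogenesis: daughter ranges drawn from the
#' [clado_table()] distribution at each node. The root state is drawn
#' uniformly from the non-null states. A lineage that contracts to the null
#' range kills the replicate, which is re-drawn (conditioning on survival);
#' the re-draw count is returned since the likelihood models do not
#' condition on survival.
#'
#' @param tree a `phylo` chronogram.
#' @param config a [biogeo_config()] with the generating rates.
#' @param states a [build_states()] object.
#' @param seed RNG seed.
#' @param max_redraws give up after this many extinct replicates.
#' @return list: `tip_ranges` (named list of area-label vectors), `truth`
#'   (generating parameters), `n_redraws`.
#' @export
gen_range_history <- function(tree, config, states, seed = 1,
                              max_redraws = 1000) {
  Q <- anagenetic_Q(config, states)
  masks_full <- c(0L, states$masks)
  ntip <- ape::Ntip(tree)
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  elen <- ape::reorder.phylo(tree, "cladewise")$edge.length

  evolve_branch <- function(mask, t) sim_branch(mask, t, Q, masks_full)

  with_seed(seed, {
    for (attempt in seq_len(max_redraws)) {
      node_state <- integer(ntip + tree$Nnode)
      root <- ntip + 1L
      node_state[root] <- sample(states$masks, 1)
      extinct <- FALSE
      pending_clado <- new.env()
      for (r in seq_len(nrow(edge))) {
        par <- edge[r, 1]; ch <- edge[r, 2]
        key <- as.character(par)
        if (is.null(pending_clado[[key]])) {
          ev <- clado_events(config, node_state[par], states)
          pick <- sample.int(nrow(ev), 1, prob = ev$w)
          pending_clado[[key]] <- c(ev$left[pick], ev$right[pick])
        }
        start <- pending_clado[[key]][1]
        pending_clado[[key]] <- pending_clado[[key]][-1]
        end <- evolve_branch(start, elen[r])
        if (end == 0L) { extinct <- TRUE; break }
        node_state[ch] <- end
      }
      if (!extinct) {
        tips <- stats::setNames(
          lapply(seq_len(ntip), function(i)
            mask_areas(node_state[i], states$areas)),
          tree$tip.label)
        return(list(tip_ranges = tips,
                    truth = list(model = model_name(config), d = config$d,
                                 e = config$e, j = config$j),
                    n_redraws = attempt - 1L))
      }
    }
    abort("excessive re-draws: all ", max_redraws,
          " simulated histories went extinct; lower e or raise d")
  })
}

#' Simulate a full synthetic sister-pair study
#'
#' Builds `n_pairs` independent pairs with a stated scenario mix, giving a
#' dataset (occurrences + leaf table + island map) that runs through the
#' whole classification pipeline, with per-pair truth labels for recovery
#' checks. The default mix emulates an island-dominated radiation: mostly
#' geographically isolated pairs, a couple with later ecological
#' divergence, one parapatric pair, one inconclusive.
#'
#' @param n_pairs total number of sister pairs.
#' @param scenarios character vector of length `n_pairs` (recycled) of
#'   scenario names for [gen_pair_scenario()].
#' @param delta,sigma,n_leaves,n_occurrences forwarded to
#'   [gen_pair_scenario()].
#' @param seed RNG seed.
#' @return list: `occurrences`, `leaves`, `islands`, `pairs` (a
#'   `sister_pairs` table), `truth` (per-pair list).
#' @export
simulate_study <- function(n_pairs = 20,
                           scenarios = c(rep("allopatric_conserved", 16),
                                         rep("allopatric_diverged", 2),
                                         "parapatric", "inconclusive"),
                           delta = 2, sigma = 0.5, n_leaves = 30,
                           n_occurrences = 20, seed = 1) {
  scenarios <- rep(scenarios, length.out = n_pairs)
  islands <- gen_islands(n_islands = 2 * n_pairs, seed = seed)
  ids <- names(islands$polygons)
  occ <- NULL; leaves <- NULL; truth <- list()
  for (i in seq_len(n_pairs)) {
    sp <- c(sprintf("sp%02da", i), sprintf("sp%02db", i))
    # dedicated islands per pair keep pairs independent
    isl <- ids[c(2 * i - 1, 2 * i)]
    g <- gen_pair_scenario(scenarios[i], islands, species = sp,
                           delta = delta, sigma = sigma,
                           n_leaves = n_leaves,
                           n_occurrences = n_occurrences,
                           which_islands = isl, seed = seed + 1000 + i)
    occ <- if (is.null(occ)) g$occurrences else rbind(occ, g$occurrences)
    leaves <- if (is.null(leaves)) g$leaves else rbind(leaves, g$leaves)
    truth[[i]] <- g$truth
  }
  pairs <- sister_pairs(
    sister1 = sprintf("sp%02da", seq_len(n_pairs)),
    sister2 = sprintf("sp%02db", seq_len(n_pairs)),
    source = rep("phylogeny", n_pairs))
  occ <- load_occurrences(as.data.frame(occ))
  leaves <- load_leaf_table(as.data.frame(leaves))
  list(occurrences = occ, leaves = leaves, islands = islands,
       pairs = pairs, truth = truth)
}
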