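# Likelihood-based ancestral-range inference: DEC, DIVALIKE and BAYAREALIKE
# anagenetic/cladogenetic models, optional founder-event (+J) cladogenesis,
# maximum-likelihood fitting and AIC model selection.
#
# Range states are subsets of the area set, encoded as integer bitmasks
# (bit i set = area i occupied); mask 0 is the null (empty) range, which the
# anagenetic process can enter but cladogenesis cannot leave.

PARAMO_AREAS <- c("N", "T", "M", "E", "A", "W", "C", "S")

popcount <- function(m) {
  n <- integer(length(m))
  while (any(m > 0)) {
    n <- n + (m %% 2L)
    m <- m %/% 2L
  }
  n
}

mask_areas <- function(mask, areas) areas[bitwAnd(mask, bitwShiftL(1L, seq_along(areas) - 1L)) != 0L]

mask_label <- function(mask, areas) {
  if (mask == 0L) return("-")
  paste(mask_areas(mask, areas), collapse = "")
}

areas_to_mask <- function(x, areas) {
  idx <- match(x, areas)
  if (anyNA(idx)) abort("unknown area label: ",
                        paste(x[is.na(idx)], collapse = ", "))
  sum(bitwShiftL(1L, idx - 1L))
}

#' Enumerate range states over an area set
#'
#' All non-empty subsets of the areas up to `max_size`, in deterministic
#' order (by subset size, then by bit pattern). The null (empty) range is
#' handled internally by the likelihood machinery and is not listed.
#'
#' @param areas character vector of unique area labels (at most 10).
#' @param max_size largest allowed range size; default all areas.
#' @return a `range_states` list: `areas`, `max_size`, `masks` (integer
#'   bitmasks), `labels`.
#' @export
build_states <- function(areas = PARAMO_AREAS, max_size = length(areas)) {
  if (anyDuplicated(areas)) abort("area labels must be unique")
  if (length(areas) > 10) abort("at most 10 areas are supported")
  if (max_size > length(areas)) abort("max_size exceeds the number of areas")
  all_masks <- seq_len(2L^length(areas) - 1L)
  sz <- popcount(all_masks)
  keep <- all_masks[sz <= max_size]
  keep <- keep[order(popcount(keep), keep)]
  if (length(keep) > 4096) abort("state space too large (> 4096 states)")
  structure(list(areas = areas, max_size = max_size, masks = keep,
                 labels = vapply(keep, mask_label, "", areas = areas)),
            class = "range_states")
}

#' Configure a biogeographic model
#'
#' @param model `"DEC"`, `"DIVALIKE"` or `"BAYAREALIKE"`.
#' @param plus_j include founder-event (jump) cladogenesis.
#' @param d per-area dispersal (range-expansion) rate, per Myr.
#' @param e per-area extinction (range-contraction) rate, per Myr.
#' @param j founder-event weight in `[0, 3)`; ignored unless `plus_j`.
#' @return a `biogeo_config` list; `k` is the free-parameter count
#'   (2, or 3 with `+J`).
#' @export
biogeo_config <- function(model = c("DEC", "DIVALIKE", "BAYAREALIKE"),
                          plus_j = FALSE, d = 0.1, e = 0.01, j = 0) {
  model <- match.arg(model)
  if (d < 0 || e < 0) abort("rates d and e must be >= 0")
  if (j < 0 || j >= 3) abort("j must lie in [0, 3)")
  structure(list(model = model, plus_j = plus_j, d = d, e = e,
                 j = if (plus_j) j else 0,
                 k = if (plus_j) 3L else 2L),
            class = "biogeo_config")
}

model_name <- function(config)
  paste0(config$model, if (config$plus_j) "+J" else "")

#' Anagenetic rate matrix over range states
#'
#' Along a branch a range expands by one area at rate `d` per addable area
#' (respecting `max_size`) and contracts by one occupied area at rate `e`
#' per removable area; a single-area range contracts to the null range,
#' which is absorbing. Rows sum to zero.
#'
#' @param config a [biogeo_config()].
#' @param states a [build_states()] object.
#' @return square rate matrix over (null + listed) states, labelled; the
#'   null state is row/column `"-"`.
#' @export
anagenetic_Q <- function(config, states) {
  masks <- c(0L, states$masks)
  labs <- c("-", states$labels)
  n <- length(masks)
  idx <- integer(max(masks) + 1L)
  idx[masks + 1L] <- seq_len(n)
  nb <- length(states$areas)
  Q <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    S <- masks[i]
    if (S == 0L) next   # null range is absorbing anagenetically
    for (a in seq_len(nb)) {
      bit <- bitwShiftL(1L, a - 1L)
      if (bitwAnd(S, bit) == 0L) {
        Sp <- bitwOr(S, bit)
        if (popcount(Sp) <= states$max_size)
          Q[i, idx[Sp + 1L]] <- Q[i, idx[Sp + 1L]] + config$d
      } else {
        Sm <- bitwAnd(S, bitwNot(bit))
        Q[i, idx[Sm + 1L]] <- Q[i, idx[Sm + 1L]] + config$e
      }
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

# Enumerate ordered cladogenetic events for one ancestor range.
# Returns data.frame(left, right, w) of daughter masks and unnormalized
# weights; normalization to a probability distribution happens in
# clado_table().
clado_events <- function(config, ancestor, states) {
  if (ancestor == 0L) abort("null ancestor range cannot speciate")
  areas_in <- which(bitwAnd(ancestor, bitwShiftL(1L, seq_along(states$areas) - 1L)) != 0L)
  singles <- bitwShiftL(1L, areas_in - 1L)
  base_w <- (3 - config$j) / 3
  L <- integer(0); R <- integer(0); W <- numeric(0)
  add <- function(l, r, w) {
    L <<- c(L, l); R <<- c(R, r); W <<- c(W, w)
  }
  sz <- length(areas_in)
  if (config$model == "BAYAREALIKE") {
    # widely sympatric: both daughters inherit the full range
    add(ancestor, ancestor, base_w)
  } else if (sz == 1L) {
    add(ancestor, ancestor, base_w)   # narrow sympatry
  } else if (config$model == "DEC") {
    for (s in singles) {
      add(s, ancestor, base_w)                    # subset sympatry
      add(ancestor, s, base_w)
      rest <- bitwAnd(ancestor, bitwNot(s))
      add(s, rest, base_w)                        # single-area vicariance
      # when the complement is itself a single area, the mirrored event is
      # produced by the complement's own iteration — avoid double counting
      if (popcount(rest) > 1L) add(rest, s, base_w)
    }
  } else { # DIVALIKE: vicariance only, widespread splits allowed
    # iterate proper non-empty submasks of ancestor
    sub <- bitwAnd(ancestor - 1L, ancestor)
    while (sub > 0L) {
      add(sub, bitwAnd(ancestor, bitwNot(sub)), base_w)
      sub <- bitwAnd(sub - 1L, ancestor)
    }
  }
  if (config$plus_j && config$j > 0) {
    out <- setdiff(seq_along(states$areas), areas_in)
    for (a in out) {
      s <- bitwShiftL(1L, a - 1L)
      add(ancestor, s, config$j)                  # founder event
      add(s, ancestor, config$j)
    }
  }
  data.frame(left = L, right = R, w = W)
}

#' Cladogenetic event distribution for an ancestor range
#'
#' Ordered daughter-pair probabilities at a speciation node. DEC: identical
#' daughters for a single-area ancestor; equal-weight subset sympatry and
#' single-area vicariance for widespread ancestors. DIVALIKE: sympatry only
#' from single areas, otherwise vicariance (widespread splits allowed).
#' BAYAREALIKE: both daughters inherit the full range. With `+J`, jump
#' events (one daughter keeps the range, the other founds a single
#' unoccupied area) get per-event weight `j` against `(3 - j)/3` for each
#' base event; the distribution is normalised per ancestor.
#'
#' @param config a [biogeo_config()].
#' @param ancestor ancestor range: a character vector of area labels or an
#'   integer bitmask.
#' @param states a [build_states()] object.
#' @return data.frame with `left`, `right` (daughter labels), `left_mask`,
#'   `right_mask`, and `prob` summing to 1.
#' @export
clado_table <- function(config, ancestor, states) {
  mask <- if (is.character(ancestor)) areas_to_mask(ancestor, states$areas)
          else as.integer(ancestor)
  ev <- clado_events(config, mask, states)
  ev$prob <- ev$w / sum(ev$w)
  data.frame(left = vapply(ev$left, mask_label, "", areas = states$areas),
             right = vapply(ev$right, mask_label, "", areas = states$areas),
             left_mask = ev$left, right_mask = ev$right,
             prob = ev$prob)
}

# Transition probability matrices exp(Q t) for a set of branch lengths.
# Eigendecomposition once, then one diagonal scaling per branch; falls back
# to Matrix::expm when Q is near-defective.
transition_probs <- function(Q, times) {
  n <- nrow(Q)
  use_eigen <- FALSE
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi) &&
        max(Mod(eg$vectors %*% Vi - diag(n))) < 1e-8)
      use_eigen <- TRUE
  }
  lapply(times, function(t) {
    P <- if (use_eigen) {
      Re(eg$vectors %*% (exp(eg$values * t) * Vi))
    } else {
      as.matrix(Matrix::expm(Q * t))
    }
    P[P < 0] <- 0
    P / rowSums(P)
  })
}

# Shared pruning engine. tip_masks: named integer vector (species -> mask).
# Pmats: list of transition matrices indexed by edge. clamp_node /
# clamp_state_idx optionally restrict one internal node to one state index
# (within full state indexing, null first) — used for marginal ancestral
# states. Returns list(lnl, cond) where cond are post-clado conditional
# vectors per node.
prune_lnl <- function(tree, tip_masks, config, states, Pmats,
                      clamp_node = NA, clamp_state = NA) {
  masks <- c(0L, states$masks)
  nstate <- length(masks)
  sidx <- integer(max(masks) + 1L)
  sidx[masks + 1L] <- seq_len(nstate)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  edge <- tree$edge
  # children per internal node
  cond <- matrix(0, ntip + nnode, nstate)
  for (i in seq_len(ntip)) {
    m <- tip_masks[[tree$tip.label[i]]]
    cond[i, sidx[m + 1L]] <- 1
  }
  logscale <- 0
  # cladogenetic event distributions are identical across nodes: hoist
  clado <- vector("list", nstate)
  for (i in seq_len(nstate)) {
    if (masks[i] == 0L) next
    ev <- clado_events(config, masks[i], states)
    clado[[i]] <- list(p = ev$w / sum(ev$w),
                       li = sidx[ev$left + 1L],
                       ri = sidx[ev$right + 1L])
  }
  # postorder traversal: children are processed before parents
  nodes_post <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  for (nd in nodes_post) {
    ch_rows <- which(edge[, 1] == nd)
    downs <- lapply(ch_rows, function(r) {
      as.numeric(Pmats[[r]] %*% cond[edge[r, 2], ])
    })
    v <- numeric(nstate)
    for (i in seq_len(nstate)) {
      cl <- clado[[i]]
      if (is.null(cl)) next
      v[i] <- sum(cl$p * downs[[1]][cl$li] * downs[[2]][cl$ri])
    }
    if (!is.na(clamp_node) && nd == clamp_node) {
      keep <- v[clamp_state]
      v[] <- 0
      v[clamp_state] <- keep
    }
    mx <- max(v)
    if (mx <= 0) return(list(lnl = -Inf, cond = cond))
    cond[nd, ] <- v / mx
    logscale <- logscale + log(mx)
  }
  root <- ntip + 1L
  # uniform (unnormalized) root weighting over non-null states: every root
  # state contributes with weight 1, so a data-free process scores
  # probability 1 (lnL = 0); normalization would only shift lnL by a
  # constant and cancels in model comparison
  w <- c(0, rep(1, length(states$masks)))
  lik <- sum(w * cond[root, ])
  list(lnl = log(lik) + logscale, cond = cond)
}

normalize_tip_ranges <- function(tip_ranges, states) {
  out <- vapply(tip_ranges, function(r) {
    m <- if (is.character(r)) areas_to_mask(r, states$areas) else as.integer(r)
    if (m == 0L) abort("tip with empty range")
    if (!m %in% states$masks) abort("tip range outside the state space")
    m
  }, 0L)
  out
}

#' Log-likelihood of tip ranges under a biogeographic model
#'
#' Felsenstein pruning over range states: anagenetic transitions along
#' branches via `exp(Q t)`, cladogenetic mixing at internal nodes via the
#' event distribution of [clado_table()], uniform root weighting over
#' non-null states. Partial likelihoods are rescaled per node to avoid
#' underflow on large state spaces.
#'
#' @param tree a `phylo` chronogram.
#' @param tip_ranges named list/vector: species -> character vector of area
#'   labels (or bitmask). Every tip must have a range.
#' @param config a [biogeo_config()].
#' @param states a [build_states()] object; default built from `config`'s
#'   areas... supply explicitly for non-default areas.
#' @return log-likelihood (numeric scalar).
#' @export
model_lnL <- function(tree, tip_ranges, config, states) {
  missing_tips <- setdiff(tree$tip.label, names(tip_ranges))
  if (length(missing_tips))
    abort("tip without range: ", paste(missing_tips, collapse = ", "))
  tm <- normalize_tip_ranges(tip_ranges[tree$tip.label], states)
  Q <- anagenetic_Q(config, states)
  Pmats <- transition_probs(Q, tree$edge.length)
  prune_lnl(tree, as.list(tm), config, states, Pmats)$lnl
}

#' Fit a biogeographic model by maximum likelihood
#'
#' Bounded multi-start optimisation (at least 3 starts) of `d`, `e` (and `j`
#' for `+J` models): `d, e` in `[1e-12, 5]` per Myr, `j` in `[0, 2.99]`.
#'
#' @inheritParams model_lnL
#' @param starts optional list of numeric start vectors `c(d, e[, j])`.
#' @return a `biogeo_fit`: `config` (with fitted rates), `lnl`, `k`, `aic`,
#'   plus the data needed by [ancestral_ranges()].
#' @export
fit_model <- function(tree, tip_ranges, config, states, starts = NULL) {
  if (is.null(starts)) {
    starts <- if (config$plus_j)
      list(c(0.05, 0.01, 0.1), c(0.2, 0.05, 0.5), c(0.01, 0.001, 1.5))
    else list(c(0.05, 0.01), c(0.2, 0.05), c(0.01, 0.001))
  }
  lower <- c(1e-12, 1e-12, if (config$plus_j) 0)
  upper <- c(5, 5, if (config$plus_j) 2.99)
  missing_tips <- setdiff(tree$tip.label, names(tip_ranges))
  if (length(missing_tips))
    abort("tip without range: ", paste(missing_tips, collapse = ", "))
  tm <- as.list(normalize_tip_ranges(tip_ranges[tree$tip.label], states))
  negll <- function(par) {
    cf <- config
    cf$d <- par[1]; cf$e <- par[2]
    if (cf$plus_j) cf$j <- par[3]
    Q <- anagenetic_Q(cf, states)
    Pmats <- transition_probs(Q, tree$edge.length)
    ll <- prune_lnl(tree, tm, cf, states, Pmats)$lnl
    if (!is.finite(ll)) 1e10 else -ll
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) abort("optimizer failed to converge from all starts")
  cf <- config
  cf$d <- best$par[1]; cf$e <- best$par[2]
  if (cf$plus_j) cf$j <- best$par[3]
  lnl <- -best$value
  structure(list(config = cf, lnl = lnl, k = cf$k, aic = aic(lnl, cf$k),
                 tree = tree, tip_ranges = tip_ranges, states = states),
            class = "biogeo_fit")
}

#' Akaike information criterion
#' @param lnl model log-likelihood.
#' @param k number of free parameters.
#' @return `2k - 2 lnl`.
#' @export
aic <- function(lnl, k) 2 * k - 2 * lnl

#' Small-sample AIC
#' @inheritParams aic
#' @param n sample size (number of tips).
#' @return AICc value.
#' @export
aicc <- function(lnl, k, n) aic(lnl, k) + 2 * k * (k + 1) / (n - k - 1)

#' @export
#' @method print biogeo_fit
print.biogeo_fit <- function(x, ...) {
  cf <- x$config
  cat(sprintf("%s fit: d = %.4g, e = %.4g%s\n  lnL = %.5f  k = %d  AIC = %.4f\n",
              model_name(cf), cf$d, cf$e,
              if (cf$plus_j) sprintf(", j = %.4g", cf$j) else "",
              x$lnl, x$k, x$aic))
  invisible(x)
}

#' Marginal ancestral-range probabilities at internal nodes
#'
#' For each internal node and each range state, the marginal probability is
#' the likelihood with that node clamped to that state divided by the
#' unclamped likelihood (the state refers to the ancestor range immediately
#' before cladogenesis). Marginals sum to 1 per node.
#'
#' @param fit a `biogeo_fit` from [fit_model()].
#' @return list with `prob` (matrix: internal nodes x states, rows sum to
#'   1) and `mpr` (most-probable state label per node). Node rows are named
#'   by the sorted tip set they subtend.
#' @export
ancestral_ranges <- function(fit) {
  tree <- fit$tree; states <- fit$states; cf <- fit$config
  tm <- as.list(normalize_tip_ranges(fit$tip_ranges[tree$tip.label], states))
  Q <- anagenetic_Q(cf, states)
  Pmats <- transition_probs(Q, tree$edge.length)
  base <- prune_lnl(tree, tm, cf, states, Pmats)
  ntip <- ape::Ntip(tree)
  nodes <- ntip + seq_len(tree$Nnode)
  nstate_full <- length(states$masks) + 1L
  probs <- matrix(0, length(nodes), length(states$masks),
                  dimnames = list(NULL, states$labels))
  node_label <- character(length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[i]
    tipset <- sort(tree$tip.label[
      intersect(seq_len(ntip),
                unlist(tips_under(tree, nd)))])
    node_label[i] <- paste(tipset, collapse = "|")
    for (s in seq_len(nstate_full - 1L)) {
      ll <- prune_lnl(tree, tm, cf, states, Pmats,
                      clamp_node = nd, clamp_state = s + 1L)$lnl
      probs[i, s] <- exp(ll - base$lnl)
    }
  }
  probs <- probs / rowSums(probs)
  rownames(probs) <- node_label
  list(prob = probs,
       mpr = stats::setNames(colnames(probs)[max.col(probs)], node_label))
}

# tip indices descending from a node (self for tips); small recursive helper
tips_under <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_under, tree = tree))
}

#' Rank fitted biogeographic models by AIC
#'
#' @param fits list of `biogeo_fit` objects on identical data.
#' @param use_aicc rank by small-sample AICc instead of AIC.
#' @return data.frame sorted by the criterion (ascending), with `delta`
#'   column; AIC ties break toward fewer parameters.
#' @export
model_selection <- function(fits, use_aicc = FALSE) {
  if (length(fits) > 1) {
    sig <- vapply(fits, function(f)
      paste(f$tree$tip.label, collapse = ","), "")
    if (length(unique(sig)) != 1)
      abort("fits computed on different datasets cannot be ranked together")
  }
  n <- ape::Ntip(fits[[1]]$tree)
  tab <- data.frame(
    model = vapply(fits, function(f) model_name(f$config), ""),
    lnl = vapply(fits, function(f) f$lnl, 0),
    k = vapply(fits, function(f) f$k, 0L),
    d = vapply(fits, function(f) f$config$d, 0),
    e = vapply(fits, function(f) f$config$e, 0),
    j = vapply(fits, function(f) f$config$j, 0))
  rank_models(tab, use_aicc = use_aicc, n = n)
}

#' Rank a model-score table by information criterion
#'
#' Workhorse behind [model_selection()], usable directly on a table of
#' published or externally computed scores.
#'
#' @param tab data.frame with columns `model`, `lnl`, `k` (others carried
#'   through).
#' @param use_aicc rank by AICc (needs `n`).
#' @param n sample size for AICc.
#' @return the table sorted ascending by the criterion with `aic` (and
#'   `aicc` when `n` given) and `delta` columns; ties break toward fewer
#'   parameters.
#' @export
rank_models <- function(tab, use_aicc = FALSE, n = NULL) {
  stopifnot(all(c("model", "lnl", "k") %in% names(tab)))
  tab$aic <- aic(tab$lnl, tab$k)
  if (!is.null(n)) tab$aicc <- aicc(tab$lnl, tab$k, n)
  crit <- if (use_aicc) tab$aicc else tab$aic
  tab <- tab[order(crit, tab$k), ]
  crit <- if (use_aicc) tab$aicc else tab$aic
  tab$delta <- crit - min(crit)
  rownames(tab) <- NULL
  tab
}

#' Code tip ranges from occurrences and bioregion polygons
#'
#' A species' range state is the set of bioregions containing at least one
#' of its records. Bioregions are taken from the polygons' `bioregion`
#' labels when present, else the island ids.
#'
#' @param occs an `occurrences` table.
#' @param bioregions an `island_map` whose polygons (or their `bioregion`
#'   labels) define the areas.
#' @return named list: species -> character vector of area labels.
#' @export
code_tip_ranges <- function(occs, bioregions) {
  asg <- assign_islands(occs, bioregions)
  region_of <- function(ids) {
    if (is.null(bioregions$bioregion)) return(ids)
    unique(bioregions$bioregion[match(ids, names(bioregions$polygons))])
  }
  out <- lapply(asg$sets, region_of)
  empty <- names(out)[vapply(out, length, 0L) == 0]
  if (length(empty))
    abort("species with all records outside every bioregion: ",
          paste(empty, collapse = ", "))
  out
}

#' Write/read a species x area presence matrix
#' @param tip_ranges named list: species -> character vector of areas.
#' @param areas area label order for columns.
#' @param path TSV file.
#' @return `path` (write) or the named list (read).
#' @export
write_tip_ranges <- function(tip_ranges, areas, path) {
  m <- t(vapply(tip_ranges, function(r) as.integer(areas %in% r),
                integer(length(areas))))
  colnames(m) <- areas
  df <- data.frame(species = names(tip_ranges), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tip_ranges
#' @export
read_tip_ranges <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  areas <- setdiff(names(df), "species")
  out <- lapply(seq_len(nrow(df)), function(i)
    areas[as.logical(as.integer(df[i, areas]))])
  names(out) <- df$species
  out
}
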