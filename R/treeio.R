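# Chronogram input, sister-pair (cherry) extraction, taxonomic substitution
# of unsampled species, and node ages.

#' Parse and validate an ultrametric chronogram
#'
#' Reads a newick string (or file) into an [ape::read.tree()] `phylo` object
#' and validates it as a chronogram: rooted binary topology, unique tip
#' labels, finite non-negative branch lengths in time units (Myr). Trees that
#' deviate from ultrametricity by more than `tol` times the tree height
#' trigger a warning, not an error — published chronograms carry rounding
#' noise.
#'
#' @param newick a newick string, or a path to a newick file when
#'   `file = TRUE`.
#' @param file logical; treat `newick` as a file path.
#' @param tol relative ultrametricity tolerance (fraction of tree height).
#' @return an object of class `phylo`, validated.
#' @examples
#' tr <- parse_chronogram("((A:1,B:1):1,C:2);")
#' tree_height(tr)
#' @export
parse_chronogram <- function(newick, file = FALSE, tol = 1e-6) {
  tr <- if (file) {
    ape::read.tree(newick)
  } else {
    tryCatch(suppressWarnings(ape::read.tree(text = newick)),
             error = function(e) NULL)
  }
  if (is.null(tr) || !inherits(tr, "phylo"))
    abort("malformed newick: could not parse a tree")
  if (is.null(tr$edge.length))
    abort("chronogram must have branch lengths")
  if (anyDuplicated(tr$tip.label))
    abort("duplicate tip names: ",
          paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (any(!is.finite(tr$edge.length)) || any(tr$edge.length < 0))
    abort("every branch length must be finite and >= 0")
  if (!ape::is.binary(tr))
    abort("polytomies are not supported; resolve the tree before use")
  h <- node_depths(tr)[seq_len(ape::Ntip(tr))]
  height <- max(h)
  if (height > 0 && diff(range(h)) > tol * height)
    warning("tree is not ultrametric within tolerance (max tip-depth spread ",
            signif(diff(range(h)), 3), "); node ages may be approximate",
            call. = FALSE)
  tr
}

# Depth (distance from root) of every node, in branch-length units.
node_depths <- function(tree) ape::node.depth.edgelength(tree)

#' Tree height (root-to-tip distance)
#' @param tree a `phylo` chronogram.
#' @return height in branch-length units (Myr for a chronogram).
#' @export
tree_height <- function(tree) max(node_depths(tree)[seq_len(ape::Ntip(tree))])

# Height above the present of an internal node (ultrametric convention:
# tree height minus node depth).
node_age <- function(tree, node) tree_height(tree) - node_depths(tree)[node]

#' Age of the most recent common ancestor of two tips
#'
#' @param tree a `phylo` chronogram.
#' @param a,b tip labels.
#' @return MRCA height above the present, in Myr. Symmetric in `(a, b)`.
#' @export
mrca_age <- function(tree, a, b) {
  tips <- tree$tip.label
  if (!a %in% tips) abort("unknown species name: ", a)
  if (!b %in% tips) abort("unknown species name: ", b)
  if (a == b) abort("mrca_age needs two distinct tips")
  node_age(tree, ape::getMRCA(tree, c(a, b)))
}

#' Extract sister-species pairs (cherries) from a chronogram
#'
#' A cherry is an internal node whose two children are both tips; each cherry
#' is a pair of putative sister species. Cherries from one tree are disjoint
#' by construction.
#'
#' @param tree a `phylo` chronogram.
#' @return a data.frame with columns `sister1`, `sister2`, `alternates`
#'   (list column of alternate sisters for `sister2`, usually length 1),
#'   `source` (`"phylogeny"`), and `mrca_age` (Myr).
#' @export
extract_cherries <- function(tree) {
  ntip <- ape::Ntip(tree)
  edge <- tree$edge
  is_tip <- edge[, 2] <= ntip
  pairs <- list()
  for (nd in unique(edge[, 1])) {
    ch <- edge[edge[, 1] == nd, 2]
    if (length(ch) == 2 && all(ch <= ntip)) {
      labs <- sort(tree$tip.label[ch])
      pairs[[length(pairs) + 1]] <- list(
        sister1 = labs[1], sister2 = labs[2], age = node_age(tree, nd))
    }
  }
  sister_pairs(
    sister1 = vapply(pairs, `[[`, "", "sister1"),
    sister2 = vapply(pairs, `[[`, "", "sister2"),
    source  = rep("phylogeny", length(pairs)),
    mrca_age = vapply(pairs, `[[`, 0, "age")
  )
}

# Constructor for the sister-pair table used throughout the pipeline.
sister_pairs <- function(sister1 = character(), sister2 = character(),
                         alternates = NULL, source = character(),
                         mrca_age = numeric()) {
  if (is.null(alternates)) alternates <- as.list(sister2)
  stopifnot(length(sister1) == length(sister2))
  df <- data.frame(sister1 = sister1, sister2 = sister2,
                   source = source,
                   mrca_age = if (length(mrca_age)) mrca_age else
                     rep(NA_real_, length(sister1)),
                   stringsAsFactors = FALSE)
  df$alternates <- alternates
  ok <- mapply(function(s1, alts) length(alts) >= 1 && !s1 %in% alts,
               df$sister1, df$alternates)
  if (length(ok) && !all(ok))
    abort("invalid pair: sister1 must differ from every alternate and ",
          "alternates must be non-empty")
  class(df) <- c("sister_pairs", "data.frame")
  df
}

#' Read a substitution table pairing unsampled with sampled species
#'
#' Two-column delimited text: first column the unsampled species, second the
#' most morphologically similar species that is present in the tree.
#'
#' @param path file path, or a two-column data.frame.
#' @param tree the chronogram the sampled species must belong to.
#' @return data.frame with columns `unsampled`, `sampled`.
#' @export
read_substitutions <- function(path, tree) {
  tab <- if (is.data.frame(path)) path else
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  if (ncol(tab) < 2) abort("substitution table needs two columns")
  subs <- data.frame(unsampled = as.character(tab[[1]]),
                     sampled = as.character(tab[[2]]),
                     stringsAsFactors = FALSE)
  bad <- setdiff(subs$sampled, tree$tip.label)
  if (length(bad))
    abort("substitution references species absent from the tree: ",
          paste(bad, collapse = ", "))
  intree <- intersect(subs$unsampled, tree$tip.label)
  if (length(intree))
    abort("species listed as unsampled are present in the tree: ",
          paste(intree, collapse = ", "))
  subs
}

#' Apply taxonomic substitutions for unsampled species to a pair list
#'
#' For each substitution (unsampled species C, most-similar sampled species
#' A): if A belongs to a phylogeny pair (A, B), that pair becomes (A, C) with
#' source `"substituted"` — the morphology-proposed sister replaces the
#' phylogeny partner. If A is in no pair, a new substituted pair (A, C) is
#' appended. Several proposed sisters for the same sampled species accumulate
#' as alternates on a single pair, which counts once in all tallies.
#'
#' Idempotent: applying the same table twice gives the same pair list.
#'
#' @param pairs a `sister_pairs` table from [extract_cherries()].
#' @param subs a substitution table from [read_substitutions()].
#' @return an updated `sister_pairs` table.
#' @export
apply_substitutions <- function(pairs, subs) {
  if (nrow(subs) == 0) return(pairs)
  out <- pairs
  for (i in seq_len(nrow(subs))) {
    unsmp <- subs$unsampled[i]
    smp <- subs$sampled[i]
    hit1 <- which(out$sister1 == smp)
    hit2 <- which(vapply(seq_len(nrow(out)), function(k)
      smp %in% c(out$sister2[k], out$alternates[[k]]), TRUE) &
      out$sister1 != smp)
    if (length(hit1)) {
      k <- hit1[1]
      alts <- out$alternates[[k]]
      if (out$source[k] == "substituted") {
        # same sampled species targeted again: accumulate alternate
        if (!unsmp %in% alts) out$alternates[[k]] <- c(alts, unsmp)
      } else {
        out$alternates[[k]] <- unsmp
      }
      out$sister2[k] <- paste(out$alternates[[k]], collapse = "/")
      out$source[k] <- "substituted"
    } else if (length(hit2)) {
      # sampled species is the second member: swap so it anchors the pair
      k <- hit2[1]
      if (out$source[k] == "substituted") {
        if (!unsmp %in% out$alternates[[k]])
          out$alternates[[k]] <- c(out$alternates[[k]], unsmp)
      } else {
        out$sister1[k] <- smp
        out$alternates[[k]] <- unsmp
      }
      out$sister2[k] <- paste(out$alternates[[k]], collapse = "/")
      out$source[k] <- "substituted"
    } else {
      add <- sister_pairs(sister1 = smp, sister2 = unsmp,
                          source = "substituted", mrca_age = NA_real_)
      out <- rbind_pairs(out, add)
    }
  }
  out
}

rbind_pairs <- function(a, b) {
  alts <- c(a$alternates, b$alternates)
  df <- rbind(as.data.frame(a)[setdiff(names(a), "alternates")],
              as.data.frame(b)[setdiff(names(b), "alternates")])
  df$alternates <- alts
  class(df) <- c("sister_pairs", "data.frame")
  df
}

#' Write a sister-pair table as TSV
#'
#' @param pairs a `sister_pairs` table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  out <- data.frame(
    sister1 = pairs$sister1,
    sister2 = vapply(pairs$alternates, function(a) a[1], ""),
    alternates = vapply(pairs$alternates, paste, "", collapse = "/"),
    source = pairs$source,
    age = pairs$mrca_age)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
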