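# The speciation-mode decision matrix and tallying of categories.

#' Classify one sister pair's speciation mode
#'
#' The four-cell decision matrix over the distribution call and the
#' leaf-area verdict:
#'
#' * allopatric + similar  -> `geographic_isolation` (islands isolated the
#'   sisters; niche conserved)
#' * allopatric + different -> `geographic_isolation` with
#'   `subsequent_divergence = TRUE` (isolation first, local adaptation after)
#' * sympatric + similar   -> `inconclusive` (secondary contact, sympatric
#'   speciation, or divergence in an unmeasured trait are indistinguishable)
#' * sympatric + different -> `parapatric_ecological`
#'
#' Pairs lacking leaf data classify on distribution alone: allopatric ->
#' `geographic_isolation`, sympatric -> `inconclusive`. An undetermined
#' distribution call is `inconclusive`.
#'
#' @param call `"allopatric"`, `"sympatric"` or `"undetermined"`.
#' @param verdict a `leaf_verdict` (or its `verdict` string).
#' @return list with `category` in `{"geographic_isolation",
#'   "parapatric_ecological", "inconclusive"}` and logical
#'   `subsequent_divergence`.
#' @export
classify_pair <- function(call, verdict) {
  v <- if (inherits(verdict, "leaf_verdict")) verdict$verdict else verdict
  stopifnot(call %in% c("allopatric", "sympatric", "undetermined"),
            v %in% c("similar", "different", "missing"))
  if (call == "undetermined")
    return(list(category = "inconclusive", subsequent_divergence = FALSE))
  if (call == "allopatric")
    return(list(category = "geographic_isolation",
                subsequent_divergence = identical(v, "different")))
  # sympatric
  if (identical(v, "different"))
    list(category = "parapatric_ecological", subsequent_divergence = FALSE)
  else
    list(category = "inconclusive", subsequent_divergence = FALSE)
}

category_levels <- c("geographic_isolation", "parapatric_ecological",
                     "inconclusive")

#' Tally speciation-mode categories over evaluated pairs
#'
#' One evaluation per pair: a pair with alternate sisters counts once, using
#' its collapsed category (alternates that disagree on category are flagged
#' and the pair is counted as inconclusive). Percentages are computed on the
#' pair count and rounded half up to one decimal.
#'
#' @param evaluations data.frame with at least a `category` column (one row
#'   per pair; see [evaluate_pairs()]).
#' @return a `tally_report` list: `n_pairs`, `counts`, `percent`.
#' @export
tally <- function(evaluations) {
  cat <- factor(evaluations$category, levels = category_levels)
  if (anyNA(cat)) abort("unknown category in evaluations")
  counts <- table(cat)
  n <- nrow(evaluations)
  pct <- if (n > 0) round_half_up(100 * as.numeric(counts) / n, 1)
         else rep(0, length(category_levels))
  structure(list(n_pairs = n,
                 counts = stats::setNames(as.integer(counts), category_levels),
                 percent = stats::setNames(pct, category_levels)),
            class = "tally_report")
}

#' @export
#' @method print tally_report
print.tally_report <- function(x, ...) {
  cat("Speciation-mode tally over", x$n_pairs, "sister pairs\n")
  for (k in names(x$counts))
    cat(sprintf("  %-22s %2d (%s%%)\n", k, x$counts[[k]],
                format(x$percent[[k]], nsmall = 1)))
  invisible(x)
}

#' Collapse alternate-sister evaluations onto one category per pair
#'
#' @param categories character vector of categories, one per alternate.
#' @return list(category, agreed): the shared category, or `inconclusive`
#'   with `agreed = FALSE` when alternates disagree.
#' @export
collapse_alternates <- function(categories) {
  u <- unique(categories)
  if (length(u) == 1) list(category = u, agreed = TRUE)
  else list(category = "inconclusive", agreed = FALSE)
}

#' Build the per-pair report table
#'
#' Mirrors the published table layout: one row per pair with the leaf test
#' p-value, the distribution call, the inferred divergence mode, the node
#' age, and the grid overlap/asymmetry at each grid size.
#'
#' @param evaluations data.frame from [evaluate_pairs()].
#' @return a data.frame (header-only when `evaluations` is empty).
#' @export
build_report <- function(evaluations) {
  cols <- c("sister1", "sister2", "p_value", "distribution", "category",
            "subsequent_divergence", "age",
            grep("^(overlap|asymmetry)_", names(evaluations), value = TRUE))
  if (nrow(evaluations) == 0) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
    return(out)
  }
  evaluations[, intersect(cols, names(evaluations)), drop = FALSE]
}

#' Write the pair report and a JSON tally summary
#'
#' @param evaluations data.frame from [evaluate_pairs()].
#' @param tsv_path,json_path output files (either may be `NULL` to skip).
#' @return the tally report, invisibly.
#' @export
write_report <- function(evaluations, tsv_path = NULL, json_path = NULL) {
  tl <- tally(evaluations)
  if (!is.null(tsv_path)) {
    rep <- build_report(evaluations)
    num <- vapply(rep, is.numeric, TRUE)
    for (k in names(rep)[num]) {
      rep[[k]] <- ifelse(
        is.na(rep[[k]]), "-",
        ifelse(rep[[k]] < 0.001 & rep[[k]] > 0 & k == "p_value",
               formatC(rep[[k]], format = "e", digits = 2),
               formatC(rep[[k]], format = "f", digits = ifelse(k == "p_value", 4, 1))))
    }
    utils::write.table(rep, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(n_pairs = tl$n_pairs,
           counts = as.list(tl$counts),
           percent = as.list(tl$percent),
           pairs = evaluations[, intersect(
             c("sister1", "sister2", "distribution", "category"),
             names(evaluations))]),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tl)
}
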