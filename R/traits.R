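# Leaf-area data handling, log transform, and rank tests of divergence
# between sister species and between clades.

#' Load and validate a leaf-area table
#'
#' Columns: `species`, `specimen`, `area_mm2`. Areas must be strictly
#' positive (the log transform requires it). The study design targeted 30
#' leaves from six individuals per species; any positive count is accepted.
#'
#' @param x CSV file path or data.frame.
#' @return a validated `leaf_table` data.frame.
#' @export
load_leaf_table <- function(x) {
  df <- if (is.data.frame(x)) x else utils::read.csv(x, stringsAsFactors = FALSE)
  need <- c("species", "specimen", "area_mm2")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort("missing columns: ", paste(miss, collapse = ", "))
  df$area_mm2 <- as.numeric(df$area_mm2)
  if (any(is.na(df$area_mm2)) || any(df$area_mm2 <= 0))
    abort("leaf areas must be strictly positive numbers")
  df <- df[, need]
  class(df) <- c("leaf_table", "data.frame")
  df
}

#' Natural-log transform of leaf areas
#'
#' Leaf area grows multiplicatively across habitats (microphyllous
#' open-paramo shrubs to broad-leaved forest trees), so areas are analysed
#' on the log scale. Rank tests are invariant to the base; natural log is
#' used for summaries.
#'
#' @param areas positive numeric vector (mm^2).
#' @return log areas.
#' @export
log_transform <- function(areas) {
  if (any(!is.finite(areas)) || any(areas <= 0))
    abort("non-positive area: log transform requires areas > 0")
  log(areas)
}

#' Per-species mean of log leaf area
#'
#' @param leaves a `leaf_table`.
#' @return named numeric vector of species means of log area.
#' @export
species_mean_log_area <- function(leaves) {
  vapply(split(leaves$area_mm2, leaves$species),
         function(a) mean(log_transform(a)), 0)
}

#' Two-sided rank test between two samples of log leaf areas
#'
#' The default is the two-sample rank-sum (Mann-Whitney) test: sister
#' species contribute independent sets of leaves from different specimens,
#' which is the design the rank-sum test matches. A paired signed-rank
#' variant is available behind `paired = TRUE` for equal-length matched
#' samples. The exact null distribution is used for small tie-free samples
#' (combined n <= 16); otherwise the normal approximation with midranks,
#' tie-corrected variance and continuity correction.
#'
#' @param x,y numeric vectors (log areas), non-empty.
#' @param paired use the signed-rank variant (requires equal lengths).
#' @param exact_limit combined-size threshold for the exact branch.
#' @return two-sided p-value in (0, 1]; symmetric in `(x, y)`.
#' @export
rank_sum_test <- function(x, y, paired = FALSE, exact_limit = 16) {
  if (length(x) == 0 || length(y) == 0) abort("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && (length(x) + length(y) <= exact_limit)
  res <- suppressWarnings(
    stats::wilcox.test(x, y, paired = paired, exact = use_exact,
                       correct = TRUE, alternative = "two.sided"))
  min(res$p.value, 1)
}

#' Verdict on leaf-area divergence for one sister pair
#'
#' @param p two-sided p-value from [rank_sum_test()], or `NA`.
#' @param alpha significance level (fixed 0.05; tallies use uncorrected
#'   per-pair tests).
#' @param available whether leaf data exist for both species.
#' @return a `leaf_verdict` list: `p`, `alpha`, `verdict` in
#'   `{"similar", "different", "missing"}`.
#' @export
pair_leaf_verdict <- function(p, alpha = 0.05, available = !is.na(p)) {
  verdict <- if (!available || is.na(p)) "missing"
             else if (p < alpha) "different" else "similar"
  structure(list(p = if (available) p else NA_real_,
                 alpha = alpha, verdict = verdict),
            class = "leaf_verdict")
}

#' Leaf-area contrast between two clades
#'
#' Pools all log leaf areas across the tips of each clade and applies the
#' two-sample rank test — used for deep contrasts such as a forest-dwelling
#' clade against its open-paramo sister clade.
#'
#' @param leaves a `leaf_table`.
#' @param tipsA,tipsB disjoint character vectors of species names.
#' @return two-sided p-value.
#' @export
clade_contrast <- function(leaves, tipsA, tipsB) {
  if (length(intersect(tipsA, tipsB)))
    abort("clades overlap: ", paste(intersect(tipsA, tipsB), collapse = ", "))
  a <- leaves$area_mm2[leaves$species %in% tipsA]
  b <- leaves$area_mm2[leaves$species %in% tipsB]
  if (length(a) == 0 || length(b) == 0)
    abort("both clades need leaf data")
  rank_sum_test(log_transform(a), log_transform(b))
}
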