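# Cross-species conservation scoring, two-group comparisons (Welch t and
# Fisher-Snedecor F), gene-set overlap percentage, and the generic
# hypergeometric enrichment statistic.

#' Cross-species conservation score of a human miRNA
#'
#' Score 0 for human-specific sequences (the species list contains only
#' human), 2 for sequences conserved in more than 2 taxonomic orders, and 1
#' otherwise (conserved in primates, or in exactly two orders — the
#' conservative reading of the scoring rule, flagged in the vignette).
#'
#' @param orders_present character vector of taxonomic orders in which the
#'   miRNA is conserved.
#' @param species character vector of species codes; must include human
#'   (`"Hsa"`, case-insensitive, or `"human"`).
#' @return integer score in {0, 1, 2}.
#' @export
#' @examples
#' conservation_score("Primates", "Hsa")                          # 0
#' conservation_score("Primates", c("Hsa", "Ptr", "Ppy"))         # 1
#' conservation_score(c("Primates", "Glires", "Carnivora",
#'                      "Perissodactyla", "Cetartiodactyla"),
#'                    c("Hsa", "Ptr", "Mmu", "Cfa", "Eca", "Ssc"))  # 2
conservation_score <- function(orders_present, species) {
  species <- unique(trimws(species))
  orders_present <- unique(trimws(orders_present))
  if (length(species) == 0) stop("empty species list", call. = FALSE)
  is_human <- tolower(species) %in% c("hsa", "human", "homo sapiens")
  if (!any(is_human))
    stop("species list does not include human; the score presumes a human miRNA",
         call. = FALSE)
  if (all(is_human)) return(0L)
  if (length(orders_present) > 2) return(2L)
  1L
}

#' Score a conservation table
#'
#' @param x data frame with columns `mirna`, `species` (comma-separated
#'   codes) and `orders` (comma-separated taxonomic orders), as read by
#'   [read_conservation_table()].
#' @return `x` with an integer `score` column appended.
#' @export
score_conservation <- function(x) {
  split_field <- function(s) trimws(strsplit(s, ",")[[1]])
  x$score <- vapply(seq_len(nrow(x)), function(i) {
    conservation_score(split_field(x$orders[i]), split_field(x$species[i]))
  }, integer(1))
  x
}

#' @rdname score_conservation
#' @param path tab-separated file with columns `mirna`, `species`, `orders`.
#' @export
read_conservation_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("mirna", "species", "orders")
  if (!all(need %in% names(x)))
    stop("conservation table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  x
}

#' Welch's two-sample t test (two-tailed, unequal variance)
#'
#' Closed-form Welch statistic with Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b numeric samples (each of size >= 2 with finite variance).
#' @return list with `t`, `df`, `p_value`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (!is.finite(va) || !is.finite(vb) || va + vb == 0)
    stop("samples have no variance", call. = FALSE)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p_value = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Fisher-Snedecor F test for equality of variances (two-sided)
#'
#' Symmetric convention: F is the larger sample variance over the smaller,
#' and the upper-tail probability is doubled (capped at 1), so swapping the
#' samples leaves the result unchanged.
#'
#' @param a,b numeric samples (each of size >= 2).
#' @return list with `F`, `df1`, `df2`, `p_value`.
#' @export
f_variance_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("both samples have zero variance", call. = FALSE)
  if (va >= vb) {
    F <- va / vb; df1 <- length(a) - 1; df2 <- length(b) - 1
  } else {
    F <- vb / va; df1 <- length(b) - 1; df2 <- length(a) - 1
  }
  p <- min(1, 2 * stats::pf(F, df1, df2, lower.tail = FALSE))
  list(F = F, df1 = df1, df2 = df2, p_value = p)
}

#' Compare a feature between two groups
#'
#' Reports group means and SDs, the Welch t test and the F variance test
#' side by side (the two tests asked of every feature), with significance
#' flags at `alpha`.
#'
#' @param values numeric vector of feature values.
#' @param groups factor/character of the same length with exactly 2 levels.
#' @param feature name of the feature (for the output row).
#' @param alpha significance level (default 0.05).
#' @return one-row data frame with means, SDs, `t`, `t_p`, `F`, `F_p`,
#'   `t_significant`, `F_significant`.
#' @export
compare_groups <- function(values, groups, feature = "feature", alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required", call. = FALSE)
  g <- levels(groups)
  a <- values[groups == g[1]]; b <- values[groups == g[2]]
  tt <- welch_t_test(a, b)
  ft <- f_variance_test(a, b)
  data.frame(feature = feature,
             group1 = g[1], mean1 = mean(a), sd1 = stats::sd(a),
             group2 = g[2], mean2 = mean(b), sd2 = stats::sd(b),
             t = tt$t, t_p = tt$p_value, t_significant = tt$p_value < alpha,
             F = ft$F, F_p = ft$p_value, F_significant = ft$p_value < alpha,
             stringsAsFactors = FALSE)
}

#' Percentage of a target gene set found in a reference set
#'
#' @param target_set character vector of gene ids (nonempty).
#' @param reference_set character vector of gene ids.
#' @return `100 * |target intersect reference| / |target|`.
#' @export
overlap_percentage <- function(target_set, reference_set) {
  target_set <- unique(target_set)
  if (length(target_set) == 0) stop("empty target set", call. = FALSE)
  100 * length(intersect(target_set, unique(reference_set))) / length(target_set)
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability that a list of `n` genes drawn from a universe of
#' `N` (of which `K` belong to the category) contains at least `k` category
#' members by chance.
#'
#' @param k observed hits in the list.
#' @param n list size.
#' @param K category size in the universe.
#' @param N universe size.
#' @return p-value `P(X >= k)`.
#' @export
hypergeom_enrichment <- function(k, n, K, N) {
  if (k > min(n, K) || n > N || K > N || k < 0)
    stop("inconsistent counts for hypergeometric enrichment", call. = FALSE)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment helper for enrichment scans
#'
#' @param p numeric vector of p-values.
#' @param fdr false-discovery-rate threshold (default 0.05).
#' @return data frame with `p`, `p_adj` (BH), and `significant`.
#' @export
adjust_enrichment <- function(p, fdr = 0.05) {
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, p_adj = p_adj, significant = p_adj < fdr)
}
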