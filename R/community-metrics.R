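#' Abundance-class thresholds
#'
#' Taxa are stratified by their relative abundance in the pooled data set:
#' abundant above `abundant_min` (default 0.1%), rare below `rare_max`
#' (default 0.01%), moderate in the closed interval between.
#'
#' @param abundant_min fraction above which a taxon is abundant.
#' @param rare_max fraction below which a taxon is rare.
#' @export
class_thresholds <- function(abundant_min = 0.001, rare_max = 0.0001) {
  if (!(rare_max > 0 && rare_max < abundant_min && abundant_min < 1))
    passar_error("need 0 < rare_max < abundant_min < 1", "passar_bad_thresholds")
  structure(list(abundant_min = abundant_min, rare_max = rare_max),
            class = "class_thresholds")
}

#' Classify taxa into abundant / moderate / rare classes
#'
#' Relative abundance is the taxon's total count over ALL samples divided by
#' the grand total (the pooled, not per-sample, fraction). Values exactly on
#' a threshold fall in the moderate class.
#'
#' @param table an [abundance_table()].
#' @param thresholds a [class_thresholds()] object.
#' @return an `abundance_classification`: factor of classes named by taxon ID,
#'   with the thresholds attached.
#' @export
classify_abundance <- function(table, thresholds = class_thresholds()) {
  totals <- colSums(table)
  grand <- sum(totals)
  if (grand <= 0)
    passar_error("all-zero table cannot be classified", "passar_empty_table")
  p <- totals / grand
  cls <- ifelse(p > thresholds$abundant_min, "abundant",
                ifelse(p < thresholds$rare_max, "rare", "moderate"))
  structure(factor(cls, levels = c("abundant", "moderate", "rare")),
            names = colnames(table), thresholds = thresholds,
            class = c("abundance_classification", "factor"))
}

#' Per-sample alpha diversity
#'
#' Richness (taxa with positive count), Shannon entropy in nats, Gini-Simpson
#' (1 - sum p^2), and the abundance-based coverage estimator ACE with the
#' standard rare-species cutoff of 10.
#'
#' @param table an [abundance_table()].
#' @return data.frame with columns `sample_id`, `richness`, `shannon`,
#'   `simpson`, `ace`.
#' @export
alpha_diversity <- function(table) {
  if (any(rowSums(table) <= 0))
    passar_error("alpha diversity undefined for an empty sample",
                 "passar_empty_sample")
  res <- t(apply(unclass(table), 1L, function(x) {
    x <- x[x > 0]
    p <- x / sum(x)
    c(richness = length(x),
      shannon = -sum(p * log(p)),
      simpson = 1 - sum(p^2),
      ace = ace_estimate(x))
  }))
  data.frame(sample_id = rownames(table), res, row.names = NULL)
}

# Chao & Lee ACE; x = positive counts only. All-singleton samples have
# zero sample coverage and ACE diverges (Inf), reported with a warning.
ace_estimate <- function(x, rare_cutoff = 10L) {
  rare <- x[x <= rare_cutoff]
  s_abund <- sum(x > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0L) return(s_abund)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0) {
    warning("ACE undefined: zero coverage among rare taxa (all singletons)")
    return(Inf)
  }
  i <- seq_len(rare_cutoff)
  fi <- vapply(i, function(k) sum(rare == k), numeric(1))
  gamma2 <- max(s_rare / c_ace * sum(i * (i - 1) * fi) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Rank-abundance profile of one sample
#'
#' Positive taxa sorted by descending relative abundance; ties are broken by
#' taxon ID (lexicographic) so the ranking is deterministic.
#'
#' @param table an [abundance_table()].
#' @param sample_id sample to profile.
#' @return data.frame `rank`, `taxon_id`, `relative_abundance` (sums to 1).
#' @export
rank_abundance <- function(table, sample_id) {
  if (!sample_id %in% rownames(table))
    passar_error(paste0("unknown sample: ", sample_id), "passar_unknown_sample")
  x <- unclass(table)[sample_id, ]
  x <- x[x > 0]
  if (sum(x) <= 0)
    passar_error("sample has zero total count", "passar_empty_sample")
  ord <- order(-x, names(x), method = "radix")
  x <- x[ord]
  data.frame(rank = seq_along(x), taxon_id = names(x),
             relative_abundance = as.numeric(x / sum(x)), row.names = NULL)
}
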