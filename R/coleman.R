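#' Random-placement (Coleman) expected richness
#'
#' The passive-sampling null: n_i individuals of species i fall uniformly at
#' random over a region of area A_T; an island of area a_j captures each with
#' probability a_j / A_T. The expected island richness is
#' E(S_j) = sum_i (1 - (1 - a_j/A_T)^{n_i}), computed through log1p/expm1 so
#' large n_i do not underflow.
#'
#' @param n per-species abundances (positive integers).
#' @param a_j island area, 0 <= a_j <= A_T.
#' @param A_T total region area (> 0).
#' @return expected species richness (real, in [0, length(n)]).
#' @export
coleman_expectation <- function(n, a_j, A_T) {
  if (A_T <= 0) passar_error("A_T must be > 0", "passar_bad_area")
  if (a_j < 0 || a_j > A_T + 1e-12)
    passar_error("need 0 <= a_j <= A_T", "passar_bad_area")
  if (length(n) == 0L) return(0)
  if (any(n < 1)) passar_error("all n_i must be >= 1", "passar_bad_spec")
  q <- a_j / A_T
  if (q >= 1) return(length(n))
  # 1 - (1-q)^n = -expm1(n * log1p(-q))
  sum(-expm1(n * log1p(-q)))
}

#' Class-stratified random-placement predictions
#'
#' For each abundance class and island area, the Coleman expectation computed
#' from that class's species. Species weights n_i come from `n_mode`:
#' `"reads"` (total count of the species over all source samples — the
#' default) or `"incidence"` (number of samples occupied).
#'
#' @param table the source [abundance_table()].
#' @param classification an [classify_abundance()] result for `table`.
#' @param areas island areas to predict for.
#' @param A_T total area; defaults to the sum of all source sample areas —
#'   supply it explicitly when the sampled islands cover only part of the
#'   region.
#' @param n_mode `"reads"` or `"incidence"`.
#' @param observed optional data.frame `area`, `class`, `richness` of
#'   observed class richness to attach (e.g. from [observed_class_richness()]).
#' @return data.frame `area`, `class`, `n_species`, `expected` and, when
#'   supplied, `observed`. Classes with zero species carry expectation 0 and
#'   `flag = "empty-class"`.
#' @export
predict_by_class <- function(table, classification, areas, A_T,
                             n_mode = c("reads", "incidence"),
                             observed = NULL) {
  n_mode <- match.arg(n_mode)
  stopifnot(identical(names(classification), colnames(table)))
  if (any(areas < 0) || any(areas > A_T + 1e-9))
    passar_error("areas must lie in [0, A_T]", "passar_bad_area")
  n_all <- if (n_mode == "reads") colSums(table) else colSums(unclass(table) > 0)
  out <- expand.grid(area = areas, class = levels(classification),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_species <- NA_integer_
  out$expected <- NA_real_
  out$flag <- ""
  for (r in seq_len(nrow(out))) {
    keep <- classification == out$class[r] & n_all >= 1
    n <- n_all[keep]
    out$n_species[r] <- length(n)
    out$expected[r] <- coleman_expectation(n, out$area[r], A_T)
    if (length(n) == 0L) out$flag[r] <- "empty-class"
  }
  if (!is.null(observed)) {
    key <- paste(signif(out$area, 12), out$class)
    okey <- paste(signif(observed$area, 12), observed$class)
    out$observed <- observed$richness[match(key, okey)]
  }
  out
}

#' Observed class richness of island groups
#'
#' Counts, for each island group and abundance class, the taxa of that class
#' present in the group's aggregated counts. With several models, richness is
#' averaged over models per group size.
#'
#' @param models island models from [build_island_models()].
#' @param classification the source table's [classify_abundance()] result.
#' @param aggregate `"mean"` across models per size, or `"none"` (long form).
#' @return data.frame `area`, `class`, `richness` (plus `model`, `group_size`
#'   when not aggregated).
#' @export
observed_class_richness <- function(models, classification,
                                    aggregate = c("mean", "none")) {
  aggregate <- match.arg(aggregate)
  long <- do.call(rbind, lapply(models, function(m) {
    do.call(rbind, lapply(m$groups, function(g) {
      stopifnot(identical(names(g$counts), names(classification)))
      pres <- g$counts > 0
      data.frame(model = m$model, group_size = length(g$members),
                 area = g$area,
                 class = levels(classification),
                 richness = vapply(levels(classification), function(cl)
                   sum(pres & classification == cl), numeric(1)),
                 row.names = NULL)
    }))
  }))
  if (aggregate == "none") return(long)
  agg <- aggregate(richness ~ area + class, data = long, FUN = mean)
  agg[order(agg$class, agg$area), c("area", "class", "richness")]
}

#' Paired t-test of Coleman expectation against observation
#'
#' Differences are expected - observed (the sign convention under which an
#' underestimating model yields negative means); t = mean / (sd / sqrt(n))
#' with df = n - 1 and a two-sided p from the t distribution.
#'
#' @param observed,expected equal-length vectors (n >= 2), paired by area.
#' @return a `paired_comparison`: list with `differences`, `mean_diff`,
#'   `sd_diff` (sample SD), `t`, `df`, `p`.
#' @export
compare_to_coleman <- function(observed, expected) {
  n <- length(observed)
  if (n < 2L || length(expected) != n)
    passar_error("need equal-length vectors with n >= 2", "passar_bad_spec")
  d <- expected - observed
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (m == 0) {
      t <- 0; p <- 1
    } else {
      warning("zero SD of differences with non-zero mean: t is infinite")
      t <- sign(m) * Inf; p <- 0
    }
  } else {
    t <- m / (s / sqrt(n))
    p <- 2 * pt(-abs(t), df = n - 1L)
  }
  structure(list(differences = d, mean_diff = m, sd_diff = s,
                 t = t, df = n - 1L, p = p),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("paired comparison (expected - observed): mean %.4g, SD %.4g, t = %.4g, df = %d, p = %.4g\n",
              x$mean_diff, x$sd_diff, x$t, x$df, x$p))
  invisible(x)
}
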