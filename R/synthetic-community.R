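#' Specify a regional species pool
#'
#' The pool is the regional reservoir of colonists: `n_species` taxa with a
#' long-tailed species-abundance distribution (SAD) summing exactly to
#' `total_individuals`. Two SAD families are supported: Fisher's log-series
#' (parameter `alpha`) and a lognormal (`meanlog`, `sdlog`). Defaults emulate
#' an amplicon survey: 5,000 taxa, 200,000 individuals, log-series alpha 1500
#' (rare-dominated, roughly three quarters of taxa below the 0.01% line).
#'
#' @param n_species number of species in the pool.
#' @param sad `"logseries"` or `"lognormal"`.
#' @param total_individuals pool size (>= n_species).
#' @param alpha Fisher's alpha (log-series only). The default `NULL` derives
#'   the Fisher-consistent value from `n_species` and `total_individuals`
#'   (solving S = alpha log(1 + N/alpha)), so draws need essentially no
#'   rescaling and the realized SAD keeps its log-series shape.
#' @param meanlog,sdlog lognormal parameters.
#' @param seed integer seed.
#' @export
pool_spec <- function(n_species = 5000L, sad = c("logseries", "lognormal"),
                      total_individuals = 200000L, alpha = NULL,
                      meanlog = 0, sdlog = 1.5, seed = 1L) {
  sad <- match.arg(sad)
  if (n_species < 1L)
    passar_error("n_species must be >= 1", "passar_bad_spec")
  if (total_individuals < n_species)
    passar_error("total_individuals must be >= n_species", "passar_bad_spec")
  if (sad == "logseries" && !is.null(alpha) && alpha <= 0)
    passar_error("alpha must be > 0", "passar_bad_spec")
  if (sad == "lognormal" && sdlog <= 0)
    passar_error("sdlog must be > 0", "passar_bad_spec")
  structure(list(n_species = as.integer(n_species), sad = sad,
                 total_individuals = as.integer(total_individuals),
                 alpha = alpha, meanlog = meanlog, sdlog = sdlog,
                 seed = as.integer(seed)),
            class = "pool_spec")
}

#' Fisher's alpha consistent with a pool of S species and N individuals
#'
#' Solves S = alpha * log(1 + N / alpha) for alpha; the corresponding
#' log-series parameter is x = N / (N + alpha).
#'
#' @param n_species S. @param total_individuals N (> S).
#' @return alpha (positive real).
#' @export
fisher_alpha <- function(n_species, total_individuals) {
  if (total_individuals <= n_species * 1.0001)
    passar_error("log-series needs total_individuals > n_species",
                 "passar_bad_spec")
  f <- function(a) a * log1p(total_individuals / a) - n_species
  stats::uniroot(f, c(1e-3, 1e9), tol = 1e-9)$root
}

# inverse-CDF draw from the log-series pmf P(n) = -x^n / (n log(1-x))
rlogseries <- function(n, x, nmax = 1e6) {
  u <- runif(n)
  # closed-form CDF via cumulated pmf on a growing support
  k <- 1000L
  repeat {
    pmf <- -x^seq_len(k) / (seq_len(k) * log1p(-x))
    cdf <- cumsum(pmf)
    if (cdf[k] > max(u) || k >= nmax) break
    k <- k * 10L
  }
  findInterval(u, cdf) + 1L
}

#' Generate a regional species pool
#'
#' Draws per-species abundances from the requested SAD, then rescales and
#' integerizes so the total is exactly `total_individuals` with every species
#' at least 1: real values are floored and the remaining individuals go to
#' the largest fractional parts. Deterministic given `spec$seed`.
#'
#' @param spec a [pool_spec()].
#' @return a `regional_pool`: list with `taxon_ids` and integer `abundance`.
#' @export
generate_pool <- function(spec) {
  stopifnot(inherits(spec, "pool_spec"))
  set.seed(spec$seed)
  s <- spec$n_species
  raw <- if (spec$sad == "logseries") {
    alpha <- if (is.null(spec$alpha))
      fisher_alpha(s, spec$total_individuals) else spec$alpha
    x <- spec$total_individuals / (spec$total_individuals + alpha)
    as.numeric(rlogseries(s, x))
  } else {
    exp(rnorm(s, spec$meanlog, spec$sdlog))
  }
  abundance <- integerize_total(raw, spec$total_individuals)
  structure(list(taxon_ids = sprintf("sp%0*d", nchar(s), seq_len(s)),
                 abundance = abundance,
                 total_individuals = spec$total_individuals, spec = spec),
            class = "regional_pool")
}

# scale positive reals to sum to `total` with every entry >= 1: floor the
# scaled values, clamp at 1, then hand missing individuals to the largest
# fractional parts (or reclaim surplus from the largest entries). Keeps
# singleton draws as singletons when the scale factor is near 1.
integerize_total <- function(raw, total) {
  s <- length(raw)
  scaled <- raw / sum(raw) * total
  base <- pmax(floor(scaled), 1)
  frac <- scaled - base  # negative for clamped entries: lowest priority
  diff <- total - sum(base)
  if (diff > 0) {
    ord <- order(-frac, seq_len(s))
    base[ord[seq_len(diff)]] <- base[ord[seq_len(diff)]] + 1
  }
  while (diff < 0) {  # clamping overshot: shave the largest entries
    i <- which.max(base)
    base[i] <- base[i] - 1
    diff <- diff + 1
  }
  out <- as.integer(base)
  stopifnot(sum(out) == total, all(out >= 1L))
  out
}

#' @export
print.regional_pool <- function(x, ...) {
  cat(sprintf("regional_pool: %d species, %s individuals (%s SAD)\n",
              length(x$abundance), format(x$total_individuals, big.mark = ","),
              x$spec$sad))
  invisible(x)
}

#' Specify a passive-sampling (dart-throwing) placement
#'
#' Islands of areas `areas` sit inside a region of total area `total_area`
#' (>= sum of island areas; the slack is environment that is not sampled).
#' Each individual of species i lands on island j with probability
#' `multiplier[i] * areas[j] / total_area` and misses all islands with the
#' residual probability. Multipliers in (0,1] depress a species' landing
#' probability, breaking the equal-probability assumption of the random
#' placement null.
#'
#' @param areas island areas (positive; named to become sample IDs).
#' @param total_area region area A_T; defaults to `sum(areas)` (no miss).
#' @param multipliers per-species landing multipliers in (0,1]; recycled.
#' @param seed integer seed.
#' @export
placement_spec <- function(areas = rep(0.36, 8), total_area = sum(areas),
                           multipliers = 1, seed = 1L) {
  if (any(areas <= 0)) passar_error("island areas must be > 0", "passar_bad_area")
  if (total_area < sum(areas) - 1e-9)
    passar_error("total_area must be >= sum of island areas", "passar_bad_area")
  if (any(multipliers <= 0 | multipliers > 1))
    passar_error("multipliers must lie in (0, 1]", "passar_bad_spec")
  if (is.null(names(areas))) names(areas) <- sprintf("tw%d", seq_along(areas))
  structure(list(areas = areas, total_area = total_area,
                 multipliers = multipliers, seed = as.integer(seed)),
            class = "placement_spec")
}

#' Simulate passive sampling of a pool onto islands
#'
#' The dart-throwing null made concrete: per species, one multinomial draw
#' distributes its individuals over the k islands and the "missed" remainder
#' (distributionally identical to per-individual placement, far faster).
#' Deterministic given `placement$seed`.
#'
#' @param pool a [generate_pool()] result.
#' @param placement a [placement_spec()].
#' @return an island-by-species [abundance_table()].
#' @export
simulate_passive_sampling <- function(pool, placement) {
  stopifnot(inherits(pool, "regional_pool"), inherits(placement, "placement_spec"))
  set.seed(placement$seed)
  k <- length(placement$areas)
  m <- rep_len(placement$multipliers, length(pool$abundance))
  counts <- matrix(0, nrow = k, ncol = length(pool$abundance),
                   dimnames = list(names(placement$areas), pool$taxon_ids))
  p_land <- placement$areas / placement$total_area
  for (i in seq_along(pool$abundance)) {
    probs <- c(m[i] * p_land, 1 - m[i] * sum(p_land))
    counts[, i] <- rmultinom(1L, pool$abundance[i], probs)[seq_len(k), 1L]
  }
  abundance_table(counts)
}

#' Monte-Carlo island richness under passive sampling
#'
#' Vectorized replicate machinery for checking the random-placement
#' expectation: returns, per island, the per-replicate richness of a chosen
#' species set. Used by the simulator-vs-formula tests; one rmultinom call
#' per species covers all replicates.
#'
#' @param pool a [generate_pool()] result.
#' @param placement a [placement_spec()].
#' @param replicates number of independent placements.
#' @param species optional index/logical vector restricting the species set.
#' @return matrix replicates x islands of richness values.
#' @export
simulate_richness <- function(pool, placement, replicates = 1000L,
                              species = NULL) {
  stopifnot(inherits(pool, "regional_pool"), inherits(placement, "placement_spec"))
  set.seed(placement$seed)
  idx <- seq_along(pool$abundance)
  if (!is.null(species)) idx <- idx[species]
  k <- length(placement$areas)
  m <- rep_len(placement$multipliers, length(pool$abundance))
  p_land <- placement$areas / placement$total_area
  rich <- matrix(0L, nrow = replicates, ncol = k,
                 dimnames = list(NULL, names(placement$areas)))
  for (i in idx) {
    probs <- c(m[i] * p_land, 1 - m[i] * sum(p_land))
    draws <- rmultinom(replicates, pool$abundance[i], probs)
    rich <- rich + t(draws[seq_len(k), , drop = FALSE] > 0)
  }
  rich
}

#' Random rooted phylogeny over given taxa
#'
#' Strictly bifurcating, random topology and positive branch lengths (via
#' ape), leaves labelled by `taxon_ids`. Deterministic given `seed`.
#'
#' @param taxon_ids at least two leaf labels.
#' @param seed integer seed.
#' @return an [ape::rtree()]-style `phylo` object.
#' @export
random_tree <- function(taxon_ids, seed = 1L) {
  if (length(taxon_ids) < 2L)
    passar_error("a tree needs at least 2 taxa", "passar_bad_spec")
  set.seed(seed)
  ape::rtree(length(taxon_ids), rooted = TRUE, tip.label = taxon_ids)
}
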