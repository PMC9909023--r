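# Independent oracles and tiny fixture builders. Everything here is coded
# from first principles, separately from the package's own code paths.

# ordinary least squares, closed form
ols_oracle <- function(x, y) {
  z <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - z * mean(x), slope = z)
}

# expected richness on one island by exhaustive enumeration of every
# individual landing pattern (feasible for pools of <= 12 individuals)
enum_coleman_oracle <- function(n, q) {
  N <- sum(n)
  stopifnot(N <= 12)
  sp <- rep(seq_along(n), n)
  E <- 0
  for (mask in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(N)]
    E <- E + q^sum(bits) * (1 - q)^(N - sum(bits)) *
      length(unique(sp[bits == 1]))
  }
  E
}

# two-sided t-test p for df = 2, closed form: CDF(t) = 1/2 + t/(2*sqrt(t^2+2))
t_p_df2_oracle <- function(t) {
  t <- abs(t)
  2 * (1 - (0.5 + t / (2 * sqrt(t^2 + 2))))
}

# UniFrac by explicit root-to-leaf path enumeration: for every tip walk the
# parent pointers to the root, then tally per-edge mass from the paths.
oracle_unifrac <- function(tree, x, y, metric = c("unweighted", "weighted")) {
  metric <- match.arg(metric)
  nE <- nrow(tree$edge)
  parent <- integer(max(tree$edge))
  edge_of <- integer(max(tree$edge))
  for (r in seq_len(nE)) {
    parent[tree$edge[r, 2]] <- tree$edge[r, 1]
    edge_of[tree$edge[r, 2]] <- r
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  px <- numeric(nE); py <- numeric(nE)
  for (tip in seq_along(tree$tip.label)) {
    path <- integer(0); node <- tip
    while (node != root) {
      path <- c(path, edge_of[node])
      node <- parent[node]
    }
    lab <- tree$tip.label[tip]
    cx <- if (lab %in% names(x)) x[[lab]] else 0
    cy <- if (lab %in% names(y)) y[[lab]] else 0
    px[path] <- px[path] + cx
    py[path] <- py[path] + cy
  }
  px <- px / sum(x); py <- py / sum(y)
  len <- tree$edge.length
  if (metric == "unweighted") {
    a <- px > 0; b <- py > 0
    sum(len[xor(a, b)]) / sum(len[a | b])
  } else {
    sum(len * abs(px - py)) / sum(len * (px + py))
  }
}

# fixtures ------------------------------------------------------------------

make_table <- function(counts, samples = NULL, taxa = NULL) {
  m <- as.matrix(counts)
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(nrow(m)))
  if (is.null(taxa)) taxa <- sprintf("t%d", seq_len(ncol(m)))
  abundance_table(m, sample_ids = samples, taxon_ids = taxa)
}

random_table <- function(n_samples, n_taxa, lambda = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa)
  if (any(rowSums(m) == 0)) m[rowSums(m) == 0, 1] <- 1
  make_table(m)
}

# Table 2 of the source study: per-class (observed, expected) richness at the
# seven island areas; used as printed input data.
table2 <- list(
  area = c(0.36, 0.72, 1.08, 1.44, 1.80, 2.16, 2.52),
  abundant_obs = c(117, 126, 132, 142, 144, 144, 145),
  abundant_exp = c(116.99, 126, 132, 142, 144, 144, 145),
  moderate_obs = c(428, 550, 589, 838, 920, 1075, 1181),
  moderate_exp = c(408.81, 547.52, 588.82, 837.99, 919.99, 1074.99, 1180.99),
  rare_obs = c(1071, 1317, 1736, 2924, 3752, 4532, 4924),
  rare_exp = c(344.64, 845.93, 1318.16, 2419.99, 3375.47, 4253.83, 4808.07)
)
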