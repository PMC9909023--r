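#' Podani-family beta-diversity decomposition of one sample pair
#'
#' Counts are binarized; with a = shared taxa, b = taxa only in x, c = taxa
#' only in y, the pair's dissimilarity D splits into a replacement component
#' Repl = 2 min(b,c) / den and a richness-difference component
#' RichDiff = |b - c| / den, with similarity completing the unit sum.
#' Jaccard family: den = a + b + c; Sorensen family: den = 2a + b + c.
#'
#' @param x,y count or presence vectors over the same taxon universe.
#' @param family `"jaccard"` or `"sorensen"`.
#' @return a `beta_triplet`: list with `similarity`, `replacement`,
#'   `richness_difference`, `dissimilarity`, `family` and the a/b/c tallies.
#' @export
decompose_beta <- function(x, y, family = c("jaccard", "sorensen")) {
  family <- match.arg(family)
  if (length(x) != length(y))
    passar_error("x and y must share one taxon universe", "passar_bad_spec")
  px <- x > 0; py <- y > 0
  a <- sum(px & py); b <- sum(px & !py); c <- sum(!px & py)
  if (a + b + c == 0L)
    passar_error("both communities are empty", "passar_empty_sample")
  den <- if (family == "jaccard") a + b + c else 2 * a + b + c
  sim <- if (family == "jaccard") a / den else 2 * a / den
  structure(list(similarity = sim,
                 replacement = 2 * min(b, c) / den,
                 richness_difference = abs(b - c) / den,
                 dissimilarity = (b + c) / den,
                 family = family, a = a, b = b, c = c),
            class = "beta_triplet")
}

#' Decompose all sample pairs of a table
#'
#' @param table an [abundance_table()].
#' @param family `"jaccard"` or `"sorensen"`.
#' @return data.frame with one row per unordered pair: `sample_1`,
#'   `sample_2`, `similarity`, `replacement`, `richness_difference`,
#'   `dissimilarity`, `family`.
#' @export
beta_triplets <- function(table, family = c("jaccard", "sorensen")) {
  family <- match.arg(family)
  ids <- rownames(table)
  pairs <- utils::combn(ids, 2L)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    tr <- decompose_beta(unclass(table)[pairs[1L, k], ],
                         unclass(table)[pairs[2L, k], ], family)
    data.frame(sample_1 = pairs[1L, k], sample_2 = pairs[2L, k],
               similarity = tr$similarity, replacement = tr$replacement,
               richness_difference = tr$richness_difference,
               dissimilarity = tr$dissimilarity, family = family,
               row.names = NULL)
  }))
}

#' Summarize a set of beta-diversity triplets
#'
#' Component means (the ternary-plot centroid) and the percentage of total
#' dissimilarity contributed by replacement, sum(Repl) / sum(D) * 100 over
#' all pairs (richness difference contributes the complement).
#'
#' @param triplets data.frame from [beta_triplets()] (or a list of
#'   [decompose_beta()] results), one family only.
#' @return list with `family`, `n_pairs`, `mean_similarity`,
#'   `mean_replacement`, `mean_richness_difference`,
#'   `replacement_contribution_pct`, `richness_difference_contribution_pct`
#'   (the contributions are NA when every pair has D = 0).
#' @export
summarize_decomposition <- function(triplets) {
  if (is.list(triplets) && !is.data.frame(triplets) &&
      all(vapply(triplets, inherits, logical(1), "beta_triplet"))) {
    triplets <- do.call(rbind, lapply(triplets, function(tr)
      data.frame(similarity = tr$similarity, replacement = tr$replacement,
                 richness_difference = tr$richness_difference,
                 dissimilarity = tr$dissimilarity, family = tr$family)))
  }
  if (nrow(triplets) == 0L)
    passar_error("no triplets supplied", "passar_bad_spec")
  if (length(unique(triplets$family)) != 1L)
    passar_error("mixed decomposition families", "passar_mixed_families")
  td <- sum(triplets$dissimilarity)
  list(family = triplets$family[1L],
       n_pairs = nrow(triplets),
       mean_similarity = mean(triplets$similarity),
       mean_replacement = mean(triplets$replacement),
       mean_richness_difference = mean(triplets$richness_difference),
       replacement_contribution_pct =
         if (td > 0) 100 * sum(triplets$replacement) / td else NA_real_,
       richness_difference_contribution_pct =
         if (td > 0) 100 * sum(triplets$richness_difference) / td else NA_real_)
}

# per-edge presence/abundance mass flowing through each branch of a rooted
# tree: postorder accumulation over ape's edge matrix.
edge_masses <- function(tree, counts) {
  present <- names(counts)[counts > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing) > 0L)
    passar_error(paste0("taxa absent from tree: ",
                        paste(missing, collapse = ", ")),
                 "passar_taxon_not_in_tree")
  total <- sum(counts)
  if (total <= 0)
    passar_error("zero-total community", "passar_empty_sample")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  mass <- numeric(nnode)
  tipc <- counts[match(tree$tip.label, names(counts))]
  tipc[is.na(tipc)] <- 0
  mass[seq_len(ntip)] <- tipc / total
  edges <- tree$edge
  # postorder: children before parents
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(ord)))
    mass[ord[r, 1L]] <- mass[ord[r, 1L]] + mass[ord[r, 2L]]
  # one value per edge: the mass descending through it (child-side node)
  mass[edges[, 2L]]
}

#' Unweighted UniFrac distance
#'
#' Fraction of tree branch length leading to taxa present in exactly one of
#' the two communities, over branch length leading to taxa present in either.
#'
#' @param tree rooted `phylo` with branch lengths; leaf labels cover all
#'   taxa with positive counts.
#' @param x,y named count vectors (presence is what matters here).
#' @return distance in [0, 1].
#' @export
unweighted_unifrac <- function(tree, x, y) {
  px <- edge_masses(tree, x) > 0
  py <- edge_masses(tree, y) > 0
  len <- tree$edge.length
  covered <- sum(len[px | py])
  if (covered == 0) return(0)
  sum(len[xor(px, py)]) / covered
}

#' Weighted UniFrac distance
#'
#' Branch lengths weighted by the difference in relative-abundance mass each
#' community sends through them: raw = sum_b len_b |p_x - p_y|; the default
#' normalized form divides by sum_b len_b (p_x + p_y), bounding it in [0, 1].
#' Invariant to scaling either community's counts.
#'
#' @inheritParams unweighted_unifrac
#' @param normalized divide by the maximal attainable value (default TRUE).
#' @return distance (in [0, 1] when normalized).
#' @export
weighted_unifrac <- function(tree, x, y, normalized = TRUE) {
  px <- edge_masses(tree, x)
  py <- edge_masses(tree, y)
  len <- tree$edge.length
  raw <- sum(len * abs(px - py))
  if (!normalized) return(raw)
  den <- sum(len * (px + py))
  if (den == 0) return(0)
  raw / den
}

#' Pairwise UniFrac distance matrix
#'
#' @param table an [abundance_table()] whose taxa are leaves of `tree`.
#' @param tree rooted `phylo` with branch lengths.
#' @param metric `"unweighted"` or `"weighted"` (normalized).
#' @return symmetric matrix with zero diagonal, labelled by sample IDs.
#' @export
unifrac_matrix <- function(table, tree, metric = c("unweighted", "weighted")) {
  metric <- match.arg(metric)
  ids <- rownames(table)
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  f <- if (metric == "unweighted") unweighted_unifrac else weighted_unifrac
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    d[i, j] <- d[j, i] <- f(tree, unclass(table)[ids[i], ],
                            unclass(table)[ids[j], ])
  }
  attr(d, "metric") <- metric
  d
}

#' Read / write Newick trees (ape-backed)
#' @param path Newick file.
#' @return a `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path))
    passar_error(paste0("file not found: ", path), "passar_missing_file")
  ape::read.tree(path)
}

#' @rdname read_newick
#' @param tree a `phylo` object to write.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}
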