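#' Build area-nested island models by superimposing samples
#'
#' The combination procedure: for each model and each group size k, draw k
#' distinct samples uniformly at random and superimpose them (sum their
#' counts, add their areas). Draws are independent across sizes and models by
#' default; `nested = TRUE` instead grows each model by adding one sample at
#' a time, and `within_replacement = TRUE` allows the same sample to be drawn
#' twice within one group (the literal "allow replicates" reading — area then
#' double-counts without new individuals, so it is off by default).
#'
#' @param table an [abundance_table()].
#' @param areas a [sample_areas()] covering every sample in `table`.
#' @param n_models number of independent model series (default 8).
#' @param group_sizes sizes of the groups in each model (default 1..K-1).
#' @param seed integer seed; membership is reproducible.
#' @param nested grow groups by accretion instead of independent draws.
#' @param within_replacement sample members with replacement within a group.
#' @return list of `island_model` objects; each holds `groups`, a list of
#'   `island_group`s with `members`, `area`, `counts`, `richness`.
#' @export
build_island_models <- function(table, areas, n_models = 8L,
                                group_sizes = NULL, seed = 1L,
                                nested = FALSE, within_replacement = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  ids <- rownames(table)
  if (!all(ids %in% names(areas)))
    passar_error("every sample needs an area", "passar_missing_area")
  if (is.null(group_sizes)) group_sizes <- seq_len(max(nrow(table) - 1L, 1L))
  if (!within_replacement && max(group_sizes) > nrow(table))
    passar_error("group size exceeds sample count", "passar_bad_group_size")
  if (n_models < 1L) passar_error("n_models must be >= 1", "passar_bad_spec")
  set.seed(seed)
  a <- as.numeric(areas)[match(ids, names(areas))]
  names(a) <- ids
  lapply(seq_len(n_models), function(mi) {
    if (nested) {
      perm <- sample(ids)
      members <- lapply(group_sizes, function(k) perm[seq_len(k)])
    } else {
      members <- lapply(group_sizes, function(k)
        sample(ids, k, replace = within_replacement))
    }
    groups <- lapply(members, function(mm) {
      counts <- colSums(unclass(table)[mm, , drop = FALSE])
      structure(list(members = mm, area = sum(a[mm]), counts = counts,
                     richness = sum(counts > 0)),
                class = "island_group")
    })
    structure(list(model = mi, groups = groups, group_sizes = group_sizes,
                   area_unit = attr(areas, "unit")),
              class = "island_model")
  })
}

#' @export
print.island_model <- function(x, ...) {
  cat(sprintf("island_model %d: %d groups, areas %s\n", x$model,
              length(x$groups),
              paste(signif(vapply(x$groups, `[[`, numeric(1), "area"), 4),
                    collapse = ", ")))
  invisible(x)
}

#' Extract (area, richness) points from island models
#'
#' @param models list of island models from [build_island_models()].
#' @return data.frame `model`, `group_size`, `area`, `richness`, `members`.
#' @export
group_richness_points <- function(models) {
  if (length(models) == 0L)
    passar_error("no island models supplied", "passar_bad_spec")
  do.call(rbind, lapply(models, function(m) {
    data.frame(
      model = m$model,
      group_size = vapply(m$groups, function(g) length(g$members), integer(1)),
      area = vapply(m$groups, `[[`, numeric(1), "area"),
      richness = vapply(m$groups, `[[`, numeric(1), "richness"),
      members = vapply(m$groups, function(g) paste(g$members, collapse = ","),
                       character(1)),
      row.names = NULL)
  }))
}
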