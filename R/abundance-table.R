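#' @importFrom stats pt sd lm coef confint rmultinom runif rnorm setNames aggregate
#' @importFrom utils read.delim write.table modifyList
NULL

passar_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "passar_error", "error", "condition")))
}

#' Construct a sample-by-taxon abundance table
#'
#' The universal input of the pipeline: a non-negative integer count matrix
#' with one row per sample and one column per taxon (an ASV feature table).
#'
#' @param counts numeric matrix of non-negative integers; rownames are sample
#'   IDs, colnames are taxon IDs (or supply `sample_ids`/`taxon_ids`).
#' @param sample_ids,taxon_ids optional character vectors overriding dimnames.
#' @param require_positive_samples if TRUE (the analysis-ready default),
#'   every sample row must have total count > 0.
#' @return an `abundance_table` object (a classed integer matrix).
#' @export
abundance_table <- function(counts, sample_ids = NULL, taxon_ids = NULL,
                            require_positive_samples = FALSE) {
  counts <- as.matrix(counts)
  if (!is.null(sample_ids)) rownames(counts) <- sample_ids
  if (!is.null(taxon_ids)) colnames(counts) <- taxon_ids
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    passar_error("abundance_table needs sample and taxon IDs (dimnames)",
                 "passar_missing_ids")
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    passar_error("abundance_table must have at least one sample and one taxon",
                 "passar_empty_table")
  if (anyDuplicated(rownames(counts)))
    passar_error("duplicated sample IDs", "passar_duplicate_ids")
  if (anyDuplicated(colnames(counts)))
    passar_error("duplicated taxon IDs", "passar_duplicate_ids")
  if (!is.numeric(counts) || anyNA(counts))
    passar_error("counts must be numeric and non-missing", "passar_bad_counts")
  if (any(counts < 0))
    passar_error("negative counts", "passar_bad_counts")
  if (any(abs(counts - round(counts)) > 1e-8))
    passar_error("non-integer counts", "passar_bad_counts")
  storage.mode(counts) <- "double"  # doubles hold integral counts > .Machine$integer.max
  counts <- round(counts)
  if (require_positive_samples && any(rowSums(counts) <= 0))
    passar_error("every sample must have total count > 0 for analysis",
                 "passar_empty_sample")
  structure(counts, class = c("abundance_table", class(counts)))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa, total count %s\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

sample_ids <- function(table) rownames(table)
taxon_ids <- function(table) colnames(table)

#' Read an abundance table from TSV or BIOM-style JSON
#'
#' TSV convention: taxa as rows (first column taxon IDs, header = sample IDs).
#' A first header field of `sample_id` (or `#SampleID`) flags the transposed
#' samples-as-rows layout; `orientation` overrides auto-detection. BIOM JSON
#' follows the 1.0 spec (rows = observations/taxa), dense or sparse.
#'
#' @param path input file.
#' @param format `"tsv"` or `"biom-json"` (`"auto"` by file extension).
#' @param orientation `"auto"`, `"taxa_rows"` or `"samples_rows"` (TSV only).
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path, format = c("auto", "tsv", "biom-json"),
                                 orientation = c("auto", "taxa_rows", "samples_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    passar_error(paste0("file not found: ", path), "passar_missing_file")
  if (format == "auto")
    format <- if (grepl("\\.(biom|json)$", path, ignore.case = TRUE)) "biom-json" else "tsv"
  if (format == "biom-json") return(read_biom_json(path))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    passar_error("TSV table needs an ID column plus at least one data column",
                 "passar_bad_counts")
  id_header <- names(df)[1L]
  samples_as_rows <- switch(orientation,
    auto = tolower(id_header) %in% c("sample_id", "#sampleid", "sampleid"),
    taxa_rows = FALSE,
    samples_rows = TRUE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    passar_error("non-numeric count cells", "passar_bad_counts")
  rownames(m) <- ids
  if (!samples_as_rows) m <- t(m)
  abundance_table(m)
}

#' Write an abundance table to TSV or BIOM-style JSON
#'
#' @param table an [abundance_table()].
#' @param path output file.
#' @param format `"tsv"` or `"biom-json"`.
#' @param samples_as_rows write the transposed TSV layout.
#' @return `path`, invisibly; the file round-trips through
#'   [read_abundance_table()] exactly.
#' @export
write_abundance_table <- function(table, path, format = c("tsv", "biom-json"),
                                  samples_as_rows = FALSE) {
  format <- match.arg(format)
  stopifnot(inherits(table, "abundance_table"))
  if (format == "biom-json") return(write_biom_json(table, path))
  if (samples_as_rows) {
    df <- data.frame(sample_id = rownames(table), as.data.frame(unclass(table)),
                     check.names = FALSE)
  } else {
    tt <- t(unclass(table))
    df <- data.frame(taxon_id = rownames(tt), as.data.frame(tt),
                     check.names = FALSE)
  }
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) passar_error(paste0("cannot write: ", path), "passar_unwritable_path")
  invisible(path)
}

read_biom_json <- function(path) {
  b <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  taxa <- vapply(b$rows, function(r) r$id, character(1))
  samples <- vapply(b$columns, function(c) c$id, character(1))
  m <- matrix(0, nrow = length(taxa), ncol = length(samples),
              dimnames = list(taxa, samples))
  if (identical(b$matrix_type, "sparse")) {
    for (trip in b$data) m[trip[[1]] + 1L, trip[[2]] + 1L] <- trip[[3]]
  } else {
    for (i in seq_along(b$data)) m[i, ] <- unlist(b$data[[i]])
  }
  abundance_table(t(m))
}

write_biom_json <- function(table, path) {
  m <- t(unclass(table))  # BIOM rows are observations (taxa)
  b <- list(
    id = "passar table", format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table", generated_by = "passar",
    date = "1970-01-01T00:00:00",
    matrix_type = "dense", matrix_element_type = "int",
    shape = c(nrow(m), ncol(m)),
    rows = lapply(rownames(m), function(id) list(id = id, metadata = NULL)),
    columns = lapply(colnames(m), function(id) list(id = id, metadata = NULL)),
    data = lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  )
  ok <- tryCatch({
    jsonlite::write_json(b, path, auto_unbox = TRUE, digits = NA, null = "null")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) passar_error(paste0("cannot write: ", path), "passar_unwritable_path")
  invisible(path)
}

#' Sample areas
#'
#' Maps each sample ID to the habitat (filter paper) area it represents.
#' Areas are stored in the unit given; the study design is eight papers of
#' 0.36 m2 each.
#'
#' @param areas named numeric vector (names = sample IDs) or two-column
#'   data.frame `sample_id`, `area`.
#' @param unit `"m2"` or `"cm2"`.
#' @return a `sample_areas` object (named numeric with a `unit` attribute).
#' @export
sample_areas <- function(areas, unit = c("m2", "cm2")) {
  unit <- match.arg(unit)
  if (is.data.frame(areas)) areas <- setNames(areas[[2L]], as.character(areas[[1L]]))
  if (is.null(names(areas)) || anyDuplicated(names(areas)))
    passar_error("areas need unique sample IDs as names", "passar_duplicate_ids")
  if (!is.numeric(areas) || anyNA(areas) || any(areas <= 0))
    passar_error("all areas must be positive", "passar_bad_area")
  structure(as.numeric(areas), names = names(areas), unit = unit,
            class = "sample_areas")
}

#' @export
print.sample_areas <- function(x, ...) {
  cat(sprintf("sample_areas (%s): %s\n", attr(x, "unit"),
              paste0(names(x), "=", unclass(x), collapse = ", ")))
  invisible(x)
}

#' Read a sample-areas TSV (`sample_id<TAB>area`)
#' @param path input file.
#' @param unit area unit of the file, `"m2"` (default) or `"cm2"`.
#' @return a [sample_areas()] object.
#' @export
read_sample_areas <- function(path, unit = c("m2", "cm2")) {
  if (!file.exists(path))
    passar_error(paste0("file not found: ", path), "passar_missing_file")
  df <- read.delim(path, stringsAsFactors = FALSE)
  sample_areas(df, unit = match.arg(unit))
}

#' @rdname read_sample_areas
#' @param areas a [sample_areas()] object to write.
#' @export
write_sample_areas <- function(areas, path) {
  df <- data.frame(sample_id = names(areas), area = as.numeric(areas))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert areas between square metres and square centimetres
#' @param areas a [sample_areas()] object or bare numeric vector.
#' @param to target unit.
#' @export
convert_area_unit <- function(areas, to = c("cm2", "m2")) {
  to <- match.arg(to)
  from <- attr(areas, "unit")
  if (is.null(from)) from <- "m2"
  f <- c(m2 = 1, cm2 = 1e4)
  out <- as.numeric(areas) * f[[to]] / f[[from]]
  structure(out, names = names(areas), unit = to, class = class(areas))
}
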