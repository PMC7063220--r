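# Tab-separated table I/O with schema validation. All readers report the
# offending line number (header = line 1) so malformed database extracts can
# be fixed at the source.

.read_tsv_checked <- function(path, required, numeric_cols = character(),
                              id_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(df))) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad)) {
      stop(sprintf("%s: malformed number in column '%s' at line %d (value '%s')",
                   path, col, bad[1] + 1L, raw[bad[1]]), call. = FALSE)
    }
    df[[col]] <- val
  }
  if (!is.null(id_col)) {
    dup <- which(duplicated(df[[id_col]]))
    if (length(dup)) {
      stop(sprintf("%s: duplicate %s '%s' at line %d", path, id_col,
                   df[[id_col]][dup[1]], dup[1] + 1L), call. = FALSE)
    }
  }
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write the compound table
#'
#' Schema: `compound_id`, `name`, `herbs` (semicolon-separated herb ids),
#' `ob`, `caco2`, `dl`, `whitelisted` (logical), `whitelist_reason`,
#' optionally `descriptor` (comma-separated numbers). Tab-separated, UTF-8.
#'
#' @param path File path.
#' @return A validated data frame.
#' @export
read_compound_table <- function(path) {
  df <- .read_tsv_checked(path,
                          required = c("compound_id", "name", "herbs",
                                       "ob", "caco2", "dl"),
                          numeric_cols = c("ob", "caco2", "dl"),
                          id_col = "compound_id")
  if (is.null(df$whitelisted)) df$whitelisted <- FALSE
  df$whitelisted <- as.logical(df$whitelisted)
  df$whitelisted[is.na(df$whitelisted)] <- FALSE
  if (is.null(df$whitelist_reason)) df$whitelist_reason <- ""
  df$whitelist_reason <- as.character(df$whitelist_reason)
  df$whitelist_reason[is.na(df$whitelist_reason)] <- ""
  df
}

#' @rdname read_compound_table
#' @param compounds Data frame in the compound-table schema.
#' @export
write_compound_table <- function(compounds, path) {
  .write_tsv(compounds, path)
}

#' Read the compound-target prediction table
#'
#' Schema: `compound_id`, `target`, `source` (curated/sea/swiss), `max_tc`,
#' `possibility`, `species`.
#'
#' @param path File path.
#' @return A validated data frame.
#' @export
read_prediction_table <- function(path) {
  .read_tsv_checked(path,
                    required = c("compound_id", "target", "source", "species"),
                    numeric_cols = c("max_tc", "possibility"))
}

#' @rdname read_prediction_table
#' @param preds Data frame in the prediction schema.
#' @export
write_prediction_table <- function(preds, path) {
  .write_tsv(preds, path)
}

#' Read target-to-module annotations
#'
#' Schema: `target`, `module` (hemorheology / coagulopathy).
#' @param path File path.
#' @return A validated data frame.
#' @export
read_module_annotations <- function(path) {
  .read_tsv_checked(path, required = c("target", "module"))
}

#' @rdname read_module_annotations
#' @param annotations Data frame with columns `target`, `module`.
#' @export
write_module_annotations <- function(annotations, path) {
  .write_tsv(annotations, path)
}

#' Read and write GMT gene-set files
#'
#' One category per line: id, description, then member gene symbols, all
#' tab-separated (the standard GMT layout). Single-member sets are valid.
#'
#' @param path File path.
#' @param name Collection label.
#' @param background Optional background gene universe (default: union of
#'   members).
#' @return An [annotation_collection()].
#' @export
read_gmt <- function(path, name = basename(path), background = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stop(sprintf("%s: GMT line %d has fewer than 3 fields", path, short[1]),
         call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  dup <- which(duplicated(ids))
  if (length(dup)) {
    stop(sprintf("%s: duplicate category '%s' at line %d", path,
                 ids[dup[1]], dup[1]), call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  descriptions <- stats::setNames(vapply(fields, `[[`, character(1), 2), ids)
  annotation_collection(sets, name = name, background = background,
                        descriptions = descriptions)
}

#' @rdname read_gmt
#' @param collection An [annotation_collection()].
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "annotation_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read and write a cohort matrix
#'
#' Schema: `group` column followed by the ten index columns in canonical
#' order (see [cohort_index_names()]).
#'
#' @param path File path.
#' @return Data frame with `group` as a factor in file order.
#' @export
read_cohort <- function(path) {
  df <- .read_tsv_checked(path, required = c("group", cohort_index_names()),
                          numeric_cols = cohort_index_names())
  if (anyNA(df[cohort_index_names()])) {
    stop(path, ": cohort matrix contains missing cells", call. = FALSE)
  }
  df$group <- factor(df$group, levels = unique(df$group))
  df
}

#' @rdname read_cohort
#' @param cohort Data frame in the cohort schema.
#' @export
write_cohort <- function(cohort, path) {
  .write_tsv(cohort, path)
}

#' Export a module network
#'
#' `write_sif()` writes the Cytoscape SIF layout
#' (`nodeA<TAB>interaction<TAB>nodeB`, using the edge kind as interaction
#' type); `write_graphml()` writes GraphML with a `type` node attribute via
#' igraph.
#'
#' @param net A [build_network()] result.
#' @param path File path.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "module_network"))
  lines <- sprintf("%s\t%s\t%s", net$edges$from, net$edges$kind, net$edges$to)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_sif
#' @export
write_graphml <- function(net, path) {
  g <- .as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
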