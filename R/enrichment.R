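#' One-sided hypergeometric over-representation test
#'
#' Probability of observing at least `k` query genes inside an annotation
#' category of size `K`, when `n` genes are drawn from a background of `N`,
#' i.e. the upper tail of Hypergeometric(N, K, n). `mode = "ease"` applies
#' the conservative EASE correction used by DAVID, which discounts one
#' overlapping gene (k of 0 or 1 gives p = 1).
#'
#' @param k Observed overlap between query and category.
#' @param n Query-set size.
#' @param K Category size.
#' @param N Background size.
#' @param mode `"standard"` or `"ease"`.
#' @return p-value in (0, 1\].
#' @examples
#' hypergeometric_test(4, 4, 5, 10) # 5/210
#' @export
hypergeometric_test <- function(k, n, K, N, mode = c("standard", "ease")) {
  mode <- match.arg(mode)
  stopifnot(length(k) == 1, length(n) == 1, length(K) == 1, length(N) == 1)
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > min(n, K) || n > N || K > N) {
    stop(sprintf("inconsistent counts: k=%d, n=%d, K=%d, N=%d", k, n, K, N),
         call. = FALSE)
  }
  k_eff <- if (mode == "ease") k - 1L else k
  if (k_eff <= 0) return(1.0)
  stats::phyper(k_eff - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; a thin validating wrapper around
#' [stats::p.adjust()] that preserves input order.
#'
#' @param p_values Numeric vector of p-values in (0, 1\].
#' @return Adjusted q-values in the same order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Annotation collection for over-representation analysis
#'
#' Bundles named gene sets (GO terms, KEGG pathways, ...) with a background
#' gene universe. When `background` is omitted it defaults to the union of
#' all annotated genes.
#'
#' @param sets Named list of character vectors (category id -> member gene
#'   symbols); optionally each element may carry a `"description"` attribute,
#'   or supply `descriptions` separately.
#' @param name Collection label, e.g. `"KEGG"`.
#' @param background Optional character vector of background gene symbols.
#' @param descriptions Optional named character vector of category names.
#' @return An object of class `annotation_collection`.
#' @export
annotation_collection <- function(sets, name = "collection",
                                  background = NULL, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(!lengths(sets))) stop("annotation sets must be non-empty", call. = FALSE)
  if (is.null(background)) {
    background <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    background <- unique(as.character(background))
    stray <- setdiff(unlist(sets, use.names = FALSE), background)
    if (length(stray)) {
      stop("annotation members outside the supplied background: ",
           paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  }
  structure(list(name = name, sets = sets, background = background,
                 descriptions = descriptions),
            class = "annotation_collection")
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat(sprintf("annotation collection '%s': %d sets, background %d genes\n",
              x$name, length(x$sets), length(x$background)))
  invisible(x)
}

#' Over-representation analysis of a target set
#'
#' Tests every annotation category with at least one query hit by the
#' one-sided hypergeometric tail, adjusts across tested categories by
#' Benjamini-Hochberg, and flags categories with q below `alpha`. Query
#' genes outside the background are dropped before testing.
#'
#' @param query Character vector of gene symbols.
#' @param collection An [annotation_collection()].
#' @param mode Test mode, see [hypergeometric_test()].
#' @param alpha Significance level on the q-value. Default 0.05.
#' @return Data frame sorted by ascending p with columns `category_id`,
#'   `name`, `k`, `n`, `K`, `N`, `p_value`, `q_value`, `significant`,
#'   `members_hit` (semicolon-separated).
#' @export
enrich <- function(query, collection, mode = c("standard", "ease"),
                   alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(collection, "annotation_collection"))
  query <- unique(as.character(query))
  query <- intersect(query, collection$background)
  empty <- data.frame(category_id = character(), name = character(),
                      k = integer(), n = integer(), K = integer(), N = integer(),
                      p_value = numeric(), q_value = numeric(),
                      significant = logical(), members_hit = character())
  if (!length(query)) {
    warning("query has no genes in the annotation background")
    return(empty)
  }
  N <- length(collection$background)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(id) {
    members <- collection$sets[[id]]
    hit <- intersect(query, members)
    if (!length(hit)) return(NULL)
    data.frame(category_id = id,
               name = unname(collection$descriptions[id]),
               k = length(hit), n = n, K = length(members), N = N,
               p_value = hypergeometric_test(length(hit), n, length(members), N,
                                             mode = mode),
               members_hit = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value <= alpha
  out <- out[order(out$p_value, out$category_id),
             c("category_id", "name", "k", "n", "K", "N",
               "p_value", "q_value", "significant", "members_hit")]
  rownames(out) <- NULL
  out
}
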