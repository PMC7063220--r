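#' Build a tripartite herb-compound-target module network
#'
#' Constructs the undirected, unweighted herb-compound-target (H-C-T) network
#' of one pathological module. Only herb-compound attribution edges and
#' compound-target interaction edges are admitted; any other edge type
#' (herb-target, or within one node class) violates the tripartite constraint
#' and raises an error, as does an edge naming an undeclared node.
#'
#' @param herbs Character vector of herb identifiers.
#' @param compounds Character vector of compound identifiers.
#' @param targets Character vector of target gene symbols.
#' @param attribution_edges Data frame with columns `herb`, `compound`.
#' @param interaction_edges Data frame with columns `compound`, `target`.
#' @param module_name Label for the module, e.g. `"hemorheology"`.
#' @param prune_isolated Logical; drop zero-degree nodes. Default `FALSE`.
#' @return An object of class `module_network`: a list with `module_name`,
#'   `nodes` (data frame `id`, `type`) and `edges` (data frame `from`, `to`,
#'   `kind` in herb-compound / compound-target).
#' @examples
#' net <- build_network("H1", "C1", "T1",
#'                      data.frame(herb = "H1", compound = "C1"),
#'                      data.frame(compound = "C1", target = "T1"))
#' net
#' @export
build_network <- function(herbs, compounds, targets,
                          attribution_edges, interaction_edges,
                          module_name = "module", prune_isolated = FALSE) {
  herbs <- unique(as.character(herbs))
  compounds <- unique(as.character(compounds))
  targets <- unique(as.character(targets))
  ids <- c(herbs, compounds, targets)
  if (anyDuplicated(ids)) {
    stop("node identifiers must be unique across herb/compound/target types: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  stopifnot(is.data.frame(attribution_edges), is.data.frame(interaction_edges))

  .check_endpoints <- function(values, universe, what) {
    missing <- setdiff(values, universe)
    if (length(missing)) {
      stop(sprintf("edge references undeclared %s: %s", what,
                   paste(utils::head(missing, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  .check_endpoints(attribution_edges$herb, herbs, "herb")
  .check_endpoints(attribution_edges$compound, compounds, "compound")
  .check_endpoints(interaction_edges$compound, compounds, "compound")
  .check_endpoints(interaction_edges$target, targets, "target")

  edges <- rbind(
    if (nrow(attribution_edges)) data.frame(
      from = as.character(attribution_edges$herb),
      to = as.character(attribution_edges$compound),
      kind = "herb-compound", stringsAsFactors = FALSE),
    if (nrow(interaction_edges)) data.frame(
      from = as.character(interaction_edges$compound),
      to = as.character(interaction_edges$target),
      kind = "compound-target", stringsAsFactors = FALSE)
  )
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(), kind = character())
  }
  edges <- edges[!duplicated(paste(edges$from, edges$to, sep = "\r")), , drop = FALSE]
  rownames(edges) <- NULL

  nodes <- data.frame(
    id = c(herbs, compounds, targets),
    type = rep(c("herb", "compound", "target"),
               c(length(herbs), length(compounds), length(targets))),
    stringsAsFactors = FALSE)
  if (prune_isolated) {
    connected <- unique(c(edges$from, edges$to))
    nodes <- nodes[nodes$id %in% connected, , drop = FALSE]
    rownames(nodes) <- NULL
  }
  structure(list(module_name = module_name, nodes = nodes, edges = edges),
            class = "module_network")
}

#' @export
print.module_network <- function(x, ...) {
  tab <- table(factor(x$nodes$type, levels = c("herb", "compound", "target")))
  cat(sprintf("H-C-T network '%s': %d nodes (%d herbs, %d compounds, %d targets), %d edges\n",
              x$module_name, nrow(x$nodes), tab[["herb"]], tab[["compound"]],
              tab[["target"]], nrow(x$edges)))
  invisible(x)
}

# igraph view of a module network; keeps isolated declared nodes.
.as_igraph <- function(net) {
  stopifnot(inherits(net, "module_network"))
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = FALSE, vertices = net$nodes)
  g
}

#' Node centralities of a module network
#'
#' Computes, for every node, the degree (number of incident edges), the
#' target-facing degree of compounds (compound-target edges only; for herbs
#' and targets `target_degree` equals `degree` restricted to their single
#' admissible edge kind) and betweenness centrality (Brandes' algorithm over
#' all-pairs shortest paths with fractional credit for ties, via igraph).
#' Normalized betweenness divides the raw value by `(n-1)(n-2)/2` with `n`
#' the node count of the whole network, matching Cytoscape's convention for
#' undirected graphs.
#'
#' @param net A [build_network()] result.
#' @param normalized Logical; return normalized betweenness (default `TRUE`).
#' @return A `centrality_table` data frame with columns `node_id`,
#'   `node_type`, `degree`, `target_degree`, `betweenness`.
#' @export
centrality_table <- function(net, normalized = TRUE) {
  g <- .as_igraph(net)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = normalized)
  ct_edges <- net$edges[net$edges$kind == "compound-target", , drop = FALSE]
  td <- table(c(ct_edges$from, ct_edges$to))
  out <- data.frame(
    node_id = igraph::V(g)$name,
    node_type = igraph::V(g)$type,
    degree = as.integer(deg),
    target_degree = as.integer(ifelse(is.na(td[igraph::V(g)$name]), 0L,
                                      td[igraph::V(g)$name])),
    betweenness = as.numeric(btw),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' @rdname centrality_table
#' @export
degree_centrality <- function(net) {
  centrality_table(net, normalized = TRUE)[, c("node_id", "node_type",
                                               "degree", "target_degree")]
}

#' @rdname centrality_table
#' @export
betweenness_centrality <- function(net, normalized = TRUE) {
  centrality_table(net, normalized = normalized)[, c("node_id", "node_type",
                                                     "betweenness")]
}

#' Rank the top-k nodes of a centrality table
#'
#' Sorts descending by the chosen metric. Ties are broken by the other
#' metric (descending) and then by node id (lexicographic), so the ranking is
#' deterministic.
#'
#' @param table A [centrality_table()] result.
#' @param metric `"degree"` or `"betweenness"`.
#' @param k Number of rows to return.
#' @param node_type Optional filter: `"herb"`, `"compound"` or `"target"`.
#' @return The top-k rows of `table`, re-ranked.
#' @export
rank_top_k <- function(table, metric = c("degree", "betweenness"), k = 10,
                       node_type = NULL) {
  metric <- match.arg(metric)
  stopifnot(k >= 1)
  secondary <- setdiff(c("degree", "betweenness"), metric)
  if (!is.null(node_type)) {
    table <- table[table$node_type %in% node_type, , drop = FALSE]
  }
  if (!nrow(table)) return(table)
  ord <- order(-table[[metric]], -table[[secondary]], table$node_id)
  out <- table[ord, , drop = FALSE][seq_len(min(k, nrow(table))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap of two sets with inclusion-exclusion
#'
#' Summarises how much two node/pathway sets share, either from explicit
#' membership vectors or from printed sizes alone. In size-only mode
#' `universe_size` is interpreted as the size of the union and the
#' intersection is recovered by inclusion-exclusion:
#' \eqn{|A \cap B| = |A| + |B| - |A \cup B|}.
#'
#' @param set_a,set_b Character vectors (membership mode) or single counts
#'   (size-only mode).
#' @param universe_size Required in size-only mode: the size of the union.
#' @return An `overlap_summary` list: `size_a`, `size_b`, `size_union`,
#'   `size_intersection`, and `members_intersection` (NULL in size-only mode).
#' @examples
#' overlap(185, 184, universe_size = 195)$size_intersection # 174
#' overlap(c("a", "b"), c("b", "c"))$members_intersection   # "b"
#' @export
overlap <- function(set_a, set_b, universe_size = NULL) {
  size_mode <- is.numeric(set_a) && length(set_a) == 1 &&
    is.numeric(set_b) && length(set_b) == 1
  if (size_mode) {
    if (is.null(universe_size)) {
      stop("size-only mode requires universe_size (= |A union B|)", call. = FALSE)
    }
    a <- as.integer(set_a); b <- as.integer(set_b); u <- as.integer(universe_size)
    inter <- a + b - u
    if (inter < 0 || inter > min(a, b) || u < max(a, b)) {
      stop(sprintf("inconsistent sizes: |A|=%d, |B|=%d, union=%d imply intersection %d",
                   a, b, u, inter), call. = FALSE)
    }
    members <- NULL
  } else {
    A <- unique(as.character(set_a)); B <- unique(as.character(set_b))
    a <- length(A); b <- length(B)
    members <- sort(intersect(A, B))
    inter <- length(members)
    u <- length(union(A, B))
  }
  structure(list(size_a = a, size_b = b, size_union = u,
                 size_intersection = inter,
                 members_intersection = members),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("overlap: |A|=%d, |B|=%d, union=%d, shared=%d\n",
              x$size_a, x$size_b, x$size_union, x$size_intersection))
  invisible(x)
}

#' Per-herb compound contribution across modules
#'
#' Counts, for each herb, its attributed active compounds overall and within
#' each module network. A compound attributed to several herbs counts once
#' for each of them (quercetin-style sharing), so column sums may exceed the
#' number of distinct compounds.
#'
#' @param net_hemo,net_coag [build_network()] results for the hemorheology
#'   and coagulopathy modules (compounds present in a network are the ones
#'   counted for that module).
#' @param compound_herbs Data frame with columns `compound_id` and `herbs`
#'   (semicolon-separated herb ids) or columns `compound_id`, `herb` in long
#'   form.
#' @return Data frame with columns `herb`, `total`, `hemorheology`,
#'   `coagulopathy`, one row per herb, sorted by herb id.
#' @export
herb_contribution <- function(net_hemo, net_coag, compound_herbs) {
  stopifnot(is.data.frame(compound_herbs))
  if ("herb" %in% names(compound_herbs)) {
    long <- data.frame(compound_id = as.character(compound_herbs$compound_id),
                       herb = as.character(compound_herbs$herb),
                       stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("compound_id", "herbs") %in% names(compound_herbs)))
    hl <- strsplit(as.character(compound_herbs$herbs), ";", fixed = TRUE)
    long <- data.frame(
      compound_id = rep(as.character(compound_herbs$compound_id), lengths(hl)),
      herb = trimws(unlist(hl)), stringsAsFactors = FALSE)
  }
  long <- long[nzchar(long$herb), , drop = FALSE]
  long <- long[!duplicated(paste(long$compound_id, long$herb)), , drop = FALSE]

  in_net <- function(net) {
    if (is.null(net)) return(character())
    net$nodes$id[net$nodes$type == "compound"]
  }
  hemo_c <- in_net(net_hemo); coag_c <- in_net(net_coag)
  herbs <- sort(unique(long$herb))
  out <- data.frame(
    herb = herbs,
    total = vapply(herbs, function(h) sum(long$herb == h), integer(1)),
    hemorheology = vapply(herbs, function(h) {
      sum(long$herb == h & long$compound_id %in% hemo_c)
    }, integer(1)),
    coagulopathy = vapply(herbs, function(h) {
      sum(long$herb == h & long$compound_id %in% coag_c)
    }, integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
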