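# Independent brute-force oracles, deliberately naive: used only to verify
# the package's fast paths on tiny inputs.

# All simple paths between s and t by depth-first enumeration.
.all_simple_paths <- function(adj, s, t) {
  paths <- list()
  walk <- function(v, seen) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- seen
      return(invisible())
    }
    for (w in adj[[v]]) {
      if (!w %in% seen) walk(w, c(seen, w))
    }
  }
  walk(s, s)
  paths
}

# Raw betweenness of every node of an undirected graph by exhaustive
# shortest-path enumeration; edges given as a 2-column matrix of node ids.
brute_betweenness <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  btw <- stats::setNames(numeric(length(nodes)), nodes)
  pairs <- utils::combn(nodes, 2)
  for (j in seq_len(ncol(pairs))) {
    s <- pairs[1, j]; t <- pairs[2, j]
    paths <- .all_simple_paths(adj, s, t)
    if (!length(paths)) next
    lens <- lengths(paths)
    shortest <- paths[lens == min(lens)]
    for (v in nodes) {
      if (v == s || v == t) next
      through <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
      btw[v] <- btw[v] + through / length(shortest)
    }
  }
  btw
}

# Upper-tail hypergeometric probability by enumerating every possible draw
# of n items from a universe of N containing K marked items.
brute_hypergeom_tail <- function(k, n, K, N) {
  universe <- seq_len(N)
  marked <- seq_len(K)
  draws <- utils::combn(universe, n)
  hits <- colSums(matrix(draws %in% marked, nrow = n))
  mean(hits >= k)
}

# Small random tripartite network plus its raw edge matrix.
random_tripartite <- function(seed, n_h = 2, n_c = 5, n_t = 5,
                              p_attr = 0.6, p_int = 0.4) {
  set.seed(seed)
  herbs <- paste0("h", seq_len(n_h))
  comps <- paste0("c", seq_len(n_c))
  targs <- paste0("t", seq_len(n_t))
  attr <- expand.grid(herb = herbs, compound = comps,
                      stringsAsFactors = FALSE)
  attr <- attr[stats::runif(nrow(attr)) < p_attr, , drop = FALSE]
  int <- expand.grid(compound = comps, target = targs,
                     stringsAsFactors = FALSE)
  int <- int[stats::runif(nrow(int)) < p_int, , drop = FALSE]
  net <- build_network(herbs, comps, targs, attr, int, prune_isolated = FALSE)
  edges <- rbind(as.matrix(attr), as.matrix(int))
  dimnames(edges) <- NULL
  list(net = net, nodes = c(herbs, comps, targs), edges = edges)
}

# Control + model group specs at the printed cohort parameters.
control_model_specs <- function(n = 8) {
  qsbss_reference_groups(n = n, groups = c("control", "model"))
}
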