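#' Spearman rank correlation for one endpoint pair
#'
#' Computes Spearman's rho on average ranks after pairwise deletion of
#' incomplete observations. The two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' the default of the mainstream statistics packages this workflow mirrors.
#' A perfect |rho| = 1 is reported with the exact permutation value
#' `2 / n!`. Setting `exact = TRUE` replaces the approximation by the exact
#' two-sided permutation p-value from full enumeration of all `n!` rank
#' permutations (feasible for n <= 8; used as a small-sample oracle).
#'
#' @param x,y paired numeric vectors.
#' @param exact use full-enumeration permutation p instead of the
#'   t approximation.
#' @return list with `rho`, `p_value`, `n_obs`. Fewer than 4 complete pairs
#'   or a zero-variance margin yields `rho = NA` (edge not evaluable).
#' @export
spearman_edge <- function(x, y, exact = FALSE) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L || var(x) == 0 || var(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n_obs = n))
  }
  rho <- stats::cor(x, y, method = "spearman")
  p <- if (exact) {
    exact_spearman_p(x, y)
  } else {
    spearman_p_approx(rho, n)
  }
  list(rho = rho, p_value = p, n_obs = n)
}

# two-sided t-approximation p; |rho| = 1 reported as the exact 2/n!
# (tolerance guards against cor() returning 1 - 2e-16 on perfect rankings)
spearman_p_approx <- function(rho, n) {
  if (abs(rho) >= 1 - 1e-12) return(2 / factorial(n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tstat), df = n - 2)
}

# exact two-sided permutation p by full enumeration of n! rank assignments:
# P(|rho_perm| >= |rho_obs|)
exact_spearman_p <- function(x, y) {
  n <- length(x)
  if (n > 8L) stop("exact permutation p limited to n <= 8", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(stats::cor(rx, ry))
  perms <- permutations_of(n)
  rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
  mean(abs(rhos) >= obs - 1e-12)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Significant correlation edges for one group x compartment
#'
#' Evaluates every unordered endpoint pair (C(p, 2) pairs; 435 for the
#' 30-endpoint panel) and keeps those with `rho >= rho_min` and
#' `p_value <= p_max`. The rho condition is one-sided positive by default,
#' taken literally from the significance rule `rho >= 0.75 with p <= 0.01`;
#' `abs_rho = TRUE` filters on |rho| instead. Pairs with fewer than 4
#' complete observations are not evaluable and are recorded in `dropped`.
#'
#' @param values numeric matrix or wide data frame, rows = cases, columns =
#'   endpoints (missing values allowed; pairwise-complete deletion per edge).
#' @param group group label (e.g. `"high_ratio"`).
#' @param compartment `"epithelium"` or `"stroma"`.
#' @param rho_min,p_max significance thresholds (defaults 0.75, 0.01).
#' @param abs_rho filter on |rho| instead of signed rho.
#' @return an `edge_set`: list with `group`, `compartment`, `edges` (data
#'   frame `endpoint_a`, `endpoint_b`, `rho`, `p_value`, `n_obs`, pairs in
#'   canonical lexicographic order), `n_pairs_evaluated`, `dropped`.
#' @export
significant_edges <- function(values, group, compartment,
                              rho_min = 0.75, p_max = 0.01,
                              abs_rho = FALSE) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  eps <- colnames(m)
  if (is.null(eps) || anyDuplicated(eps)) {
    stop("endpoint columns must be uniquely named", call. = FALSE)
  }
  ord <- order(eps)
  m <- m[, ord, drop = FALSE]
  eps <- eps[ord]
  p <- length(eps)
  if (nrow(m) < 4L) stop("at least 4 cases required", call. = FALSE)
  pairs <- utils::combn(p, 2L)
  res <- apply(pairs, 2L, function(ij) {
    e <- spearman_edge(m[, ij[1L]], m[, ij[2L]])
    c(e$rho, e$p_value, e$n_obs)
  })
  edges <- data.frame(
    endpoint_a = eps[pairs[1L, ]],
    endpoint_b = eps[pairs[2L, ]],
    rho = res[1L, ],
    p_value = res[2L, ],
    n_obs = as.integer(res[3L, ]),
    stringsAsFactors = FALSE
  )
  dropped <- edges[is.na(edges$rho), c("endpoint_a", "endpoint_b", "n_obs")]
  keep <- !is.na(edges$rho) &
    (if (abs_rho) abs(edges$rho) else edges$rho) >= rho_min &
    edges$p_value <= p_max
  out <- list(
    group = group,
    compartment = compartment,
    edges = edges[keep, , drop = FALSE],
    n_pairs_evaluated = ncol(pairs),
    dropped = dropped
  )
  rownames(out$edges) <- NULL
  class(out) <- "edge_set"
  out
}

#' @export
print.edge_set <- function(x, ...) {
  cat("<edge_set>", x$group, "/", x$compartment, "-",
      nrow(x$edges), "significant of", x$n_pairs_evaluated,
      "pairs evaluated\n")
  invisible(x)
}

edge_keys <- function(es) {
  if (nrow(es$edges) == 0L) return(character(0))
  paste(es$edges$endpoint_a, es$edges$endpoint_b, sep = "~")
}

#' Partition two edge sets into shared and exclusive edges
#'
#' Edges significant in both ratio groups of the same compartment are
#' *shared* and excluded from the differential networks; each group keeps
#' only its *exclusive* edges (with its own rho). The three sets are
#' pairwise disjoint and `|shared| + |exclusive_a| = |edges_a|`.
#'
#' @param edges_a,edges_b `edge_set` objects from the same compartment.
#' @return list with `shared` (data frame of pairs with both groups' rho),
#'   `exclusive_a`, `exclusive_b` (edge sets).
#' @export
shared_and_exclusive <- function(edges_a, edges_b) {
  if (!identical(edges_a$compartment, edges_b$compartment)) {
    stop("edge sets come from different compartments", call. = FALSE)
  }
  ka <- edge_keys(edges_a); kb <- edge_keys(edges_b)
  shared_keys <- intersect(ka, kb)
  shared <- edges_a$edges[ka %in% shared_keys,
                          c("endpoint_a", "endpoint_b", "rho"), drop = FALSE]
  names(shared)[3L] <- "rho_a"
  shared$rho_b <- edges_b$edges$rho[match(paste(shared$endpoint_a,
                                                shared$endpoint_b, sep = "~"),
                                          kb)]
  rownames(shared) <- NULL
  ex_a <- edges_a; ex_a$edges <- edges_a$edges[!ka %in% shared_keys, , drop = FALSE]
  ex_b <- edges_b; ex_b$edges <- edges_b$edges[!kb %in% shared_keys, , drop = FALSE]
  rownames(ex_a$edges) <- rownames(ex_b$edges) <- NULL
  list(shared = shared, exclusive_a = ex_a, exclusive_b = ex_b)
}

#' Build a differential network graph from an edge set
#'
#' Nodes are endpoints with at least one incident significant edge (node
#' `size` = degree, the count of incident edges); edge `weight` = rho.
#' Vertex order is deterministic (lexicographic).
#'
#' @param edge_set an `edge_set` (typically an exclusive set).
#' @return an undirected [igraph::igraph] graph with graph attributes
#'   `group` and `compartment`.
#' @export
build_network <- function(edge_set) {
  ed <- edge_set$edges
  if (nrow(ed) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    verts <- sort(unique(c(ed$endpoint_a, ed$endpoint_b)))
    g <- igraph::graph_from_data_frame(
      ed[, c("endpoint_a", "endpoint_b")],
      directed = FALSE,
      vertices = data.frame(name = verts, stringsAsFactors = FALSE)
    )
    igraph::E(g)$weight <- ed$rho
    igraph::V(g)$size <- igraph::degree(g)
  }
  g <- igraph::set_graph_attr(g, "group", edge_set$group %||% NA_character_)
  igraph::set_graph_attr(g, "compartment",
                         edge_set$compartment %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect modularity subgroups in a differential network
#'
#' Seeded Louvain modularity maximization with Spearman rho edge weights,
#' the documented analogue of the modularity grouping that graph
#' visualization software applies to these networks. Community ids are
#' contiguous integers starting at 0, numbered by first appearance in
#' vertex order; the partition is reproducible for a fixed seed.
#'
#' @param network igraph graph from [build_network()].
#' @param seed integer RNG seed.
#' @param resolution Louvain resolution parameter (default 1).
#' @return list with `membership` (named integer vector, 0-based) and
#'   `n_subgroups`.
#' @export
detect_subgroups <- function(network, seed = 1L, resolution = 1) {
  if (igraph::vcount(network) == 0L) {
    return(list(membership = integer(0), n_subgroups = 0L))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  cl <- igraph::cluster_louvain(network, weights = igraph::E(network)$weight,
                                resolution = resolution)
  mem <- igraph::membership(cl)
  relabel <- match(mem, unique(mem)) - 1L
  names(relabel) <- igraph::V(network)$name
  list(membership = relabel, n_subgroups = length(unique(relabel)))
}

#' Export / import a differential network
#'
#' GraphML goes through igraph's writer; GEXF is written and parsed here
#' (nodes with label and size, edges with rho weight, optional community
#' attribute). Both formats round-trip node count, edge count and weights.
#'
#' @param network igraph graph (vertex attr `size`, optional `community`;
#'   edge attr `weight`).
#' @param path output file path.
#' @param format `"graphml"` or `"gexf"`.
#' @export
export_network <- function(network, path, format = c("graphml", "gexf")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    write_gexf(network, path)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("graphml", "gexf")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (!is.null(igraph::vertex_attr(g, "name")) ||
        !is.null(igraph::vertex_attr(g, "id"))) {
      if (is.null(igraph::vertex_attr(g, "name"))) {
        igraph::V(g)$name <- igraph::vertex_attr(g, "id")
      }
    }
    g
  } else {
    read_gexf(path)
  }
}

write_gexf <- function(network, path) {
  doc <- xml2::xml_new_root(
    "gexf",
    xmlns = "http://www.gexf.net/1.2draft",
    version = "1.2"
  )
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "0", title = "size",
                      type = "double")
  xml2::xml_add_child(attrs, "attribute", id = "1", title = "community",
                      type = "integer")
  nodes <- xml2::xml_add_child(graph, "nodes")
  vnames <- igraph::V(network)$name
  vsize <- igraph::vertex_attr(network, "size") %||% rep(0, length(vnames))
  vcomm <- igraph::vertex_attr(network, "community")
  for (i in seq_along(vnames)) {
    nd <- xml2::xml_add_child(nodes, "node", id = vnames[i],
                              label = vnames[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0",
                        value = format(vsize[i], digits = 17))
    if (!is.null(vcomm)) {
      xml2::xml_add_child(av, "attvalue", `for` = "1",
                          value = as.character(vcomm[i]))
    }
  }
  edges <- xml2::xml_add_child(graph, "edges")
  if (igraph::ecount(network) > 0L) {
    el <- igraph::as_edgelist(network)
    w <- igraph::E(network)$weight %||% rep(1, nrow(el))
    for (i in seq_len(nrow(el))) {
      xml2::xml_add_child(edges, "edge", id = as.character(i - 1L),
                          source = el[i, 1L], target = el[i, 2L],
                          weight = format(w[i], digits = 17))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  node_xml <- xml2::xml_find_all(doc, ".//g:node", ns)
  ids <- xml2::xml_attr(node_xml, "id")
  size <- vapply(node_xml, function(nd) {
    v <- xml2::xml_find_first(nd, ".//g:attvalue[@for='0']", ns)
    as.numeric(xml2::xml_attr(v, "value"))
  }, numeric(1))
  comm <- vapply(node_xml, function(nd) {
    v <- xml2::xml_find_first(nd, ".//g:attvalue[@for='1']", ns)
    if (inherits(v, "xml_missing")) NA_integer_ else
      as.integer(xml2::xml_attr(v, "value"))
  }, integer(1))
  edge_xml <- xml2::xml_find_all(doc, ".//g:edge", ns)
  if (length(edge_xml) > 0L) {
    el <- data.frame(
      from = xml2::xml_attr(edge_xml, "source"),
      to = xml2::xml_attr(edge_xml, "target"),
      stringsAsFactors = FALSE
    )
    g <- igraph::graph_from_data_frame(
      el, directed = FALSE,
      vertices = data.frame(name = ids, stringsAsFactors = FALSE)
    )
    igraph::E(g)$weight <- as.numeric(xml2::xml_attr(edge_xml, "weight"))
  } else {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    if (length(ids) > 0L) g <- igraph::add_vertices(g, length(ids), name = ids)
  }
  if (length(ids) > 0L) {
    igraph::V(g)$size <- size
    if (!all(is.na(comm))) igraph::V(g)$community <- comm
  }
  g
}
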