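test_that("Spearman edge handles monotone, reversed and degenerate input", {
  e <- spearman_edge(1:9, (1:9) * 2)
  expect_equal(e$rho, 1)
  expect_equal(e$p_value, 2 / factorial(9)) # exact permutation value at |rho| = 1
  expect_equal(spearman_edge(1:5, 5:1)$rho, -1)
  expect_true(is.na(spearman_edge(1:3, 3:1)$rho))          # < 4 pairs
  expect_true(is.na(spearman_edge(1:5, rep(2, 5))$rho))    # zero variance
  # pairwise deletion of incomplete observations
  e2 <- spearman_edge(c(1:5, NA), c(2, 4, 6, 8, 10, 1))
  expect_identical(e2$n_obs, 5L)
  expect_equal(e2$rho, 1)
})

test_that("Spearman rho is invariant under increasing transforms and flips sign on reversal", {
  set.seed(33)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    e <- spearman_edge(x, y)
    et <- spearman_edge(exp(x), y^3 + 5 * y)   # strictly increasing maps
    expect_equal(et$rho, e$rho)
    expect_equal(et$p_value, e$p_value)
    er <- spearman_edge(x, -y)
    expect_equal(er$rho, -e$rho)
    expect_equal(er$p_value, e$p_value)
  }
})

test_that("ties use average ranks and are deterministic", {
  x <- c(1, 2, 2, 3, 4, 4)
  y <- c(1, 3, 3, 2, 5, 5)
  e1 <- spearman_edge(x, y)
  e2 <- spearman_edge(x, y)
  expect_identical(e1, e2)
  expect_equal(e1$rho, cor(rank(x), rank(y)))
})

test_that("t-approximation p agrees in rank order with the exact permutation oracle at n = 5", {
  x <- 1:5
  perms <- oracle_permutations(5)
  res <- apply(perms, 1L, function(y) {
    e <- spearman_edge(x, as.numeric(y))
    c(rho = e$rho, p = e$p_value, exact = oracle_perm_p(x, as.numeric(y)))
  })
  res <- as.data.frame(t(res))
  # both p-values must be monotone in |rho|: ordering by either agrees
  expect_equal(order(res$p, abs(res$rho)), order(res$exact, abs(res$rho)))
  # and the package's own exact mode matches the oracle everywhere
  exact_pkg <- apply(perms, 1L, function(y)
    spearman_edge(x, as.numeric(y), exact = TRUE)$p_value)
  expect_equal(exact_pkg, res$exact)
})

test_that("a 30-endpoint panel evaluates exactly 435 unordered pairs", {
  m <- simulate_endpoint_matrix(9, 30, seed = 4)
  es <- significant_edges(m, group = "high_ratio", compartment = "stroma")
  expect_equal(es$n_pairs_evaluated, choose(30, 2))
  expect_identical(es$n_pairs_evaluated, 435L)
  expect_lte(nrow(es$edges), 435L)
})

test_that("duplicated columns give a perfect significant edge", {
  set.seed(8)
  m <- cbind(A = rnorm(9), B = rnorm(9))
  m <- cbind(m, C = m[, "A"])
  es <- significant_edges(m, "g", "stroma")
  key <- paste(es$edges$endpoint_a, es$edges$endpoint_b)
  expect_true("A C" %in% key)
  expect_equal(es$edges$rho[key == "A C"], 1)
})

test_that("both threshold conditions are enforced: rho above 0.75 alone is not enough at n = 9", {
  # frozen permutation with rho = 0.7667 but two-sided p = 0.016 > 0.01
  x <- 1:9
  y <- c(1, 4, 3, 5, 6, 2, 8, 9, 7)
  e <- spearman_edge(x, y)
  expect_gte(e$rho, 0.75)
  expect_gt(e$p_value, 0.01)
  m <- cbind(EPa = x, EPb = y, EPc = rnorm(9))
  es <- significant_edges(m, "g", "stroma")
  expect_false("EPa~EPb" %in% paste(es$edges$endpoint_a, es$edges$endpoint_b,
                                    sep = "~"))
})

test_that("edge sets honour missing data rules", {
  set.seed(10)
  m <- matrix(rnorm(9 * 4), 9, 4,
              dimnames = list(NULL, c("A", "B", "C", "D")))
  m[1:6, "D"] <- NA # only 3 complete pairs against D
  es <- significant_edges(m, "g", "epithelium")
  expect_true(all(c("D") %in% c(es$dropped$endpoint_a, es$dropped$endpoint_b)))
  expect_identical(nrow(es$dropped), 3L)
})

test_that("shared/exclusive partition obeys the set identities", {
  a <- list(group = "high_ratio", compartment = "stroma",
            edges = data.frame(endpoint_a = c("A", "B"),
                               endpoint_b = c("B", "C"),
                               rho = c(0.9, 0.8), p_value = c(0.001, 0.002),
                               n_obs = 9L))
  class(a) <- "edge_set"
  b <- a; b$group <- "low_ratio"
  res <- shared_and_exclusive(a, b)
  expect_identical(nrow(res$shared), 2L)
  expect_identical(nrow(res$exclusive_a$edges), 0L)
  expect_identical(nrow(res$exclusive_b$edges), 0L)

  b2 <- a
  b2$edges <- data.frame(endpoint_a = "C", endpoint_b = "D", rho = 0.85,
                         p_value = 0.001, n_obs = 9L)
  res2 <- shared_and_exclusive(a, b2)
  expect_identical(nrow(res2$shared), 0L)
  expect_identical(nrow(res2$exclusive_a$edges), 2L)
  expect_identical(nrow(res2$exclusive_b$edges), 1L)

  mismatch <- a; mismatch$compartment <- "epithelium"
  expect_error(shared_and_exclusive(a, mismatch), "different compartments")
})

test_that("partition identity holds on random thresholded edge sets", {
  for (seed in 1:8) {
    blocks <- list(list(endpoints = 1:4, rho = 0.85))
    ma <- simulate_endpoint_matrix(9, 12, blocks, seed = seed)
    mb <- simulate_endpoint_matrix(9, 12, blocks, seed = seed + 100)
    ea <- significant_edges(ma, "high_ratio", "stroma")
    eb <- significant_edges(mb, "low_ratio", "stroma")
    res <- shared_and_exclusive(ea, eb)
    key <- function(df) paste(df$endpoint_a, df$endpoint_b, sep = "~")
    ka <- key(ea$edges); kb <- key(eb$edges)
    ks <- key(res$shared); kxa <- key(res$exclusive_a$edges)
    kxb <- key(res$exclusive_b$edges)
    expect_identical(length(ks) + length(kxa) + length(kxb),
                     length(union(ka, kb)))
    expect_length(intersect(ks, kxa), 0)
    expect_length(intersect(ks, kxb), 0)
    expect_length(intersect(kxa, kxb), 0)
    expect_identical(length(ks) + length(kxa), length(ka))
    expect_identical(length(ks) + length(kxb), length(kb))
  }
})

test_that("networks carry degree as node size and satisfy the handshake identity", {
  star <- list(group = "g", compartment = "stroma",
               edges = data.frame(endpoint_a = c("A", "A", "A"),
                                  endpoint_b = c("B", "C", "D"),
                                  rho = c(0.9, 0.8, 0.85),
                                  p_value = 0.001, n_obs = 9L))
  class(star) <- "edge_set"
  g <- build_network(star)
  deg <- igraph::V(g)$size
  names(deg) <- igraph::V(g)$name
  expect_equal(unname(deg["A"]), 3)
  expect_equal(unname(deg[c("B", "C", "D")]), c(1, 1, 1))
  expect_equal(sort(igraph::E(g)$weight), sort(star$edges$rho))

  empty <- star; empty$edges <- star$edges[0, ]
  expect_equal(igraph::vcount(build_network(empty)), 0)

  for (seed in 1:5) {
    m <- simulate_endpoint_matrix(9, 10,
                                  list(list(endpoints = 1:5, rho = 0.9)),
                                  seed = seed)
    es <- significant_edges(m, "g", "stroma")
    gg <- build_network(es)
    expect_equal(sum(igraph::degree(gg)), 2 * nrow(es$edges))
    expect_equal(igraph::V(gg)$size, as.numeric(igraph::degree(gg)))
  }
})

test_that("modularity subgrouping finds cliques and is seed-reproducible", {
  clique4 <- igraph::make_full_graph(4)
  igraph::V(clique4)$name <- LETTERS[1:4]
  igraph::E(clique4)$weight <- 0.9
  expect_identical(detect_subgroups(clique4, seed = 3)$n_subgroups, 1L)

  three <- igraph::disjoint_union(igraph::make_full_graph(5),
                                  igraph::make_full_graph(5),
                                  igraph::make_full_graph(5))
  igraph::V(three)$name <- paste0("N", 1:15)
  igraph::E(three)$weight <- 0.8
  res <- detect_subgroups(three, seed = 3)
  expect_identical(res$n_subgroups, 3L)
  expect_identical(sort(unique(res$membership)), 0:2)
  expect_identical(detect_subgroups(three, seed = 3)$membership,
                   res$membership)

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_identical(detect_subgroups(empty, seed = 1)$n_subgroups, 0L)
})

test_that("three planted dense blocks are found as three subgroups", {
  set.seed(61)
  found <- replicate(40, {
    n <- 15; blocks <- rep(1:3, each = 5)
    pairs <- utils::combn(n, 2)
    keep <- runif(ncol(pairs)) <
      ifelse(blocks[pairs[1, ]] == blocks[pairs[2, ]], 0.9, 0.05)
    g <- igraph::graph_from_data_frame(
      data.frame(from = paste0("N", pairs[1, keep]),
                 to = paste0("N", pairs[2, keep])),
      directed = FALSE)
    igraph::E(g)$weight <- 0.8
    detect_subgroups(g, seed = 99)$n_subgroups == 3L
  })
  expect_gte(mean(found), 0.9)
})

test_that("network export round-trips in both formats", {
  set.seed(12)
  m <- simulate_endpoint_matrix(12, 20,
                                list(list(endpoints = 1:6, rho = 0.9),
                                     list(endpoints = 7:12, rho = 0.85)),
                                seed = 12)
  es <- significant_edges(m, "high_ratio", "epithelium")
  g <- build_network(es)
  sub <- detect_subgroups(g, seed = 5)
  igraph::V(g)$community <- unname(sub$membership[igraph::V(g)$name])
  for (fmt in c("graphml", "gexf")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_network(g, path, format = fmt)
    back <- import_network(path, format = fmt)
    expect_identical(igraph::vcount(back), igraph::vcount(g))
    expect_identical(igraph::ecount(back), igraph::ecount(g))
    expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
    ord <- match(igraph::V(g)$name, igraph::V(back)$name)
    expect_equal(igraph::V(back)$size[ord], igraph::V(g)$size)
    key <- function(gr) {
      el <- igraph::as_edgelist(gr)
      paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    }
    expect_setequal(key(back), key(g))
    expect_equal(sort(igraph::E(back)$weight), sort(igraph::E(g)$weight))
  }
  # empty network still exports valid files
  empty <- build_network(structure(list(group = "g", compartment = "s",
                                        edges = es$edges[0, ]),
                                   class = "edge_set"))
  for (fmt in c("graphml", "gexf")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_network(empty, path, format = fmt)
    expect_equal(igraph::vcount(import_network(path, fmt)), 0)
  }
  expect_error(export_network(g, tempfile(), format = "dot"), "arg")
})
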