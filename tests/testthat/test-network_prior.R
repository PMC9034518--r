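test_that("GO network weights equal summed shared-term information content", {
  # A and B alone share T, annotated in 2 of 4 genes -> -log2(0.5) = 1
  gt <- list(A = "T", B = "T", C = "U", D = character(0))
  net <- build_go_network(gt)
  expect_identical(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 1.0)
  expect_true(all(c("C", "D") %in% net$nodes))

  # no shared terms -> no edge
  net2 <- build_go_network(list(A = "T1", B = "T2"))
  expect_identical(nrow(net2$edges), 0L)

  # brute-force double loop over a random assignment
  set.seed(7)
  genes <- paste0("g", 1:10)
  terms <- paste0("t", 1:6)
  gt3 <- lapply(genes, function(g) sample(terms, sample(0:4, 1)))
  names(gt3) <- genes
  net3 <- build_go_network(gt3)
  freq <- table(unlist(lapply(gt3, unique))) / length(genes)
  for (r in seq_len(nrow(net3$edges))) {
    shared <- intersect(gt3[[net3$edges$gene1[r]]], gt3[[net3$edges$gene2[r]]])
    expect_equal(net3$edges$weight[r],
                 sum(-log2(as.numeric(freq[unique(shared)]))))
  }
  # and every positive-weight pair appears
  for (i in 1:9) for (j in (i + 1):10) {
    shared <- intersect(unique(gt3[[i]]), unique(gt3[[j]]))
    w <- sum(-log2(as.numeric(freq[shared])))
    present <- any((net3$edges$gene1 == genes[i] & net3$edges$gene2 == genes[j]) |
                   (net3$edges$gene1 == genes[j] & net3$edges$gene2 == genes[i]))
    expect_identical(present, w > 0)
  }
})

test_that("transition matrix is row-stochastic with self-loops on isolates", {
  tm <- to_transition_matrix(toy_triangle())
  W <- as.matrix(tm$W)
  expect_true(all(abs(rowSums(W) - 1) < 1e-12))
  expect_equal(unname(W["A", c("B", "C")]), c(0.5, 0.5))

  star <- gene_network(data.frame(gene1 = c("A", "A"), gene2 = c("B", "C"),
                                  weight = c(1, 3)))
  Ws <- as.matrix(to_transition_matrix(star)$W)
  expect_equal(unname(Ws["A", ]), c(0, 0.25, 0.75))

  iso <- to_transition_matrix(toy_triangle(), universe = c("A", "B", "C", "Z"))
  expect_identical(iso$missing, "Z")
  lone <- gene_network(data.frame(gene1 = "A", gene2 = "B", weight = 1),
                       nodes = c("A", "B", "L"))
  Wl <- as.matrix(to_transition_matrix(lone)$W)
  expect_equal(unname(Wl["L", ]), c(0, 0, 1))
})

test_that("edge ingestion drops self-edges and sums duplicates", {
  df <- data.frame(gene1 = c("A", "B", "A"), gene2 = c("B", "A", "A"),
                   weight = c(1, 2, 5))
  expect_warning(expect_warning(net <- gene_network(df), "self-edge"),
                 "duplicate")
  expect_identical(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 3)
})

test_that("RWR fixed point matches restart-only limit and analytic 2-node solution", {
  pair <- gene_network(data.frame(gene1 = "A", gene2 = "B", weight = 1))
  tm <- to_transition_matrix(pair)
  p1 <- rwr(tm, "A", restart = 1)$probabilities
  expect_identical(unname(p1), c(1, 0))
  p <- rwr(tm, "A", restart = 0.5)$probabilities
  expect_equal(unname(p), c(2 / 3, 1 / 3), tolerance = 1e-9)
  expect_error(rwr(tm, "Q"), "not in the network")
})

test_that("iterative RWR agrees with the direct linear solve on random graphs", {
  set.seed(99)
  for (trial in 1:8) {
    n <- sample(10:60, 1)
    nodes <- paste0("v", seq_len(n))
    ne <- sample((n - 1):(3 * n), 1)
    e <- data.frame(gene1 = nodes[sample(n, ne, replace = TRUE)],
                    gene2 = nodes[sample(n, ne, replace = TRUE)],
                    weight = runif(ne, 0.1, 2))
    e <- e[e$gene1 != e$gene2, , drop = FALSE]
    net <- suppressWarnings(gene_network(e, nodes = nodes))
    tm <- to_transition_matrix(net)
    r <- runif(1, 0.05, 0.95)
    src <- sample(tm$nodes, 1)
    p_iter <- rwr(tm, src, restart = r, tol = 1e-13)$probabilities
    ei <- as.numeric(tm$nodes == src)
    A <- diag(length(tm$nodes)) - (1 - r) * t(as.matrix(tm$W))
    p_direct <- as.numeric(r * solve(A, ei))
    expect_lt(max(abs(p_iter - p_direct)), 1e-8)
    expect_equal(sum(p_iter), 1, tolerance = 1e-9)
    expect_true(all(p_iter >= 0))
  }
})

test_that("batched seed-reach solve equals per-gene iteration and linear solve", {
  set.seed(5)
  nodes <- paste0("n", 1:12)
  e <- data.frame(gene1 = nodes[sample(12, 30, TRUE)],
                  gene2 = nodes[sample(12, 30, TRUE)],
                  weight = runif(30, 0.2, 1.5))
  e <- e[e$gene1 != e$gene2, ]
  tm <- to_transition_matrix(suppressWarnings(gene_network(e, nodes = nodes)))
  seeds <- c("n2", "n7")
  p_solve <- avg_reach_to_seeds(tm, seeds, restart = 0.4)
  p_iter <- avg_reach_to_seeds(tm, seeds, restart = 0.4, method = "iterative",
                               tol = 1e-13)
  expect_equal(p_solve, p_iter, tolerance = 1e-8)

  # list-of-profiles interface gives the same answer
  profiles <- lapply(tm$nodes, function(g) rwr(tm, g, 0.4, tol = 1e-13))
  p_prof <- avg_reach_to_seeds(profiles, seeds)
  expect_equal(unname(p_prof), unname(p_iter), tolerance = 1e-8)

  # absent seeds are skipped with a warning; all absent is an error
  expect_warning(p2 <- avg_reach_to_seeds(tm, c(seeds, "ZZ"), restart = 0.4),
                 "skipped")
  expect_equal(p2, p_solve, tolerance = 1e-12)
  expect_error(avg_reach_to_seeds(tm, "ZZ"), "no seed gene")
})

test_that("seed reach is invariant to global edge-weight rescaling", {
  set.seed(21)
  nodes <- paste0("n", 1:15)
  e <- data.frame(gene1 = nodes[sample(15, 40, TRUE)],
                  gene2 = nodes[sample(15, 40, TRUE)],
                  weight = runif(40, 0.1, 3))
  e <- e[e$gene1 != e$gene2, ]
  net1 <- suppressWarnings(gene_network(e, nodes = nodes))
  e2 <- e; e2$weight <- e2$weight * 37.5
  net2 <- suppressWarnings(gene_network(e2, nodes = nodes))
  p1 <- avg_reach_to_seeds(to_transition_matrix(net1), c("n1", "n5"))
  p2 <- avg_reach_to_seeds(to_transition_matrix(net2), c("n1", "n5"))
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("reach to a single seed decays with hop distance on a path graph", {
  nodes <- paste0("p", 1:7)
  e <- data.frame(gene1 = nodes[1:6], gene2 = nodes[2:7], weight = 1)
  tm <- to_transition_matrix(gene_network(e, nodes = nodes))
  p <- avg_reach_to_seeds(tm, "p1", restart = 0.5)
  expect_true(all(diff(p[nodes[2:7]]) < 0))
})

test_that("prior odds follow the genome-wide constant and normalization modes", {
  p_ns <- c(a = 0, b = 1, c = 0.25)
  lit <- prior_odds(p_ns)
  expect_identical(unname(lit["a"]), 0)
  expect_equal(unname(lit["b"]), 1000 / 17000)
  mn <- prior_odds(p_ns, mode = "mean_normalized")
  expect_equal(mean(mn), 1000 / 17000, tolerance = 1e-12)
  expect_error(prior_odds(c(x = 0, y = 0), mode = "mean_normalized"), "zero")
})

test_that("seeds' block-mates get higher reach than out-of-block genes", {
  cfg <- simulation_config(n_genes = 300L, n_risk = 40L,
                           n_seeds_observed = 20L, rng_seed = 3)
  b <- simulate_universe(cfg)
  tm <- to_transition_matrix(b$network, universe = b$universe)
  p <- avg_reach_to_seeds(tm, b$seeds)
  inblock <- setdiff(b$risk, b$seeds)
  outblock <- setdiff(b$universe, c(b$risk, b$seeds))
  expect_gt(mean(p[inblock]), mean(p[intersect(outblock, names(p))]))
})
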