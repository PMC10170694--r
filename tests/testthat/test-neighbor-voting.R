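# Cell network construction and neighbor-voting AUROC, checked against
# independent brute-force oracles on printed toys.

test_that("network matches hand-computed Spearman + midrank standardization", {
  # printed 4-cell x 3-gene toy
  x <- matrix(c(1, 2, 3,
                2, 4, 6,
                3, 2, 1,
                1, 5, 2), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  net <- build_cell_network(x, colnames(x))

  # oracle: Pearson on within-cell ranks, then midrank-standardize off-diag
  rk <- t(apply(x, 1, rank))
  s <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) s[i, j] <- cor(rk[i, ], rk[j, ])
  up <- upper.tri(s)
  std <- rank(s[up], ties.method = "average") / sum(up)
  expected <- diag(1, 4)
  expected[up] <- std
  expected <- expected + t(expected) - diag(1, 4)
  dimnames(expected) <- dimnames(net)
  expect_equal(net, expected, tolerance = 1e-12)
})

test_that("identical profiles give all-tied off-diagonal similarities", {
  x <- matrix(rep(c(1, 5, 3), each = 3), nrow = 3,
              dimnames = list(paste0("c", 1:3), paste0("g", 1:3)))
  net <- build_cell_network(x, colnames(x))
  off <- net[upper.tri(net)]
  expect_true(all(off == off[1]))
  expect_true(isSymmetric(net))
  expect_true(all(diag(net) == 1))
})

test_that("networks are symmetric with unit diagonal and (0,1] entries", {
  spec <- null_spec()
  d <- simulate_dataset(spec)
  nm <- log_normalize(d$counts)
  net <- build_cell_network(nm, colnames(d$counts)[1:25])
  expect_true(isSymmetric(net))
  expect_true(all(diag(net) == 1))
  off <- net[upper.tri(net)]
  expect_true(all(off > 0 & off <= 1))
  expect_error(build_cell_network(nm, colnames(d$counts)[1]),
               "fewer than 2")
})

test_that("voting AUROC equals exhaustive Mann-Whitney on a fixed toy", {
  # 6 cells, labels a,a,a,b,b,b; fixed train partition; known network
  set.seed(42)
  net <- matrix(runif(36), 6, 6)
  net <- (net + t(net)) / 2
  diag(net) <- 1
  labels <- rep(c("a", "b"), each = 3)
  train <- c(1L, 2L, 4L, 5L)
  test <- c(3L, 6L)
  got <- neighbor_voting_auroc(net, labels, splits = list(train))

  # oracle: explicit votes + brute-force pair enumeration
  w <- net[test, train]
  deg <- rowSums(w)
  for (l in c("a", "b")) {
    votes <- as.numeric(w %*% (labels[train] == l)) / deg
    expect_equal(unname(got[l]),
                 auroc_bruteforce(votes, labels[test] == l),
                 tolerance = 1e-12)
  }
})

test_that("midrank AUROC primitive matches pair enumeration with ties", {
  set.seed(9)
  for (i in 1:20) {
    scores <- sample(1:6, 12, replace = TRUE)  # heavy ties
    pos <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    if (!any(pos) || all(pos)) next
    expect_equal(auroc_midrank(scores, pos),
                 auroc_bruteforce(scores, pos), tolerance = 1e-12)
  }
})

test_that("perfectly separated clusters score AUROC 1 for both labels", {
  n <- 10
  net <- matrix(0, 2 * n, 2 * n)
  net[1:n, 1:n] <- 1
  net[(n + 1):(2 * n), (n + 1):(2 * n)] <- 1
  diag(net) <- 1
  labels <- rep(c("a", "b"), each = n)
  au <- neighbor_voting_auroc(net, labels, n_splits = 3, seed = 1)
  expect_equal(unname(au), c(1, 1))
})

test_that("AUROC is invariant under strictly monotone vote transforms", {
  # exp() of a network preserves similarity order within each test row only
  # if applied to votes; emulate by rank-preserving rescale of the network
  set.seed(5)
  net <- matrix(runif(100), 10, 10)
  net <- (net + t(net)) / 2
  diag(net) <- 1
  labels <- rep(c("a", "b"), each = 5)
  splits <- list(c(1:3, 6:8))
  a1 <- neighbor_voting_auroc(net, labels, splits = splits)
  # monotone transform of the votes directly via the exported primitive
  w <- net[c(4, 5, 9, 10), c(1:3, 6:8)]
  votes <- as.numeric(w %*% (labels[c(1:3, 6:8)] == "a")) / rowSums(w)
  expect_equal(auroc_midrank(votes, labels[c(4, 5, 9, 10)] == "a"),
               auroc_midrank(exp(3 * votes), labels[c(4, 5, 9, 10)] == "a"),
               tolerance = 1e-12)
  expect_equal(a1, neighbor_voting_auroc(net, labels, splits = splits))
})

test_that("permuted labels give chance-level AUROC", {
  spec <- simulation_spec(2, 2, 50, 120, seed = 13)  # 200 cells, 4 types
  d <- simulate_dataset(spec)
  nm <- log_normalize(d$counts)
  net <- build_cell_network(nm, colnames(d$counts)[1:30])
  set.seed(77)
  perm <- sample(d$labels$cell_type)
  au <- neighbor_voting_auroc(net, perm, n_splits = 10, seed = 3)
  expect_lt(abs(mean(au) - 0.5), 0.05)
})

test_that("voting is deterministic given seed and split count", {
  spec <- null_spec()
  d <- simulate_dataset(spec)
  nm <- log_normalize(d$counts)
  net <- build_cell_network(nm, colnames(d$counts)[1:20])
  a <- neighbor_voting_auroc(net, d$labels$cell_class, n_splits = 5,
                             seed = 11)
  b <- neighbor_voting_auroc(net, d$labels$cell_class, n_splits = 5,
                             seed = 11)
  expect_identical(a, b)
  expect_error(neighbor_voting_auroc(net, rep("x", nrow(net))),
               "at least 2 labels")
})

test_that("score_gene_sets scores terms and skips tiny ones", {
  spec <- demo_spec(effect_size = 8)
  d <- simulate_dataset(spec, overlap_fraction = 0.5, n_random_terms = 1)
  nm <- log_normalize(d$counts)
  sets <- c(d$ontology$members,
            list(tiny = colnames(d$counts)[1],
                 whole = colnames(d$counts)))
  tab <- score_gene_sets(nm, d$labels$cell_type, sets, seed = 2)
  expect_true("tiny" %in% attr(tab, "skipped"))
  expect_false("tiny" %in% tab$gene_set_id)
  expect_true(all(c("term_module1", "whole") %in% tab$gene_set_id))

  # planted discrete module: target-label AUROC > 0.9 at fold 8
  expect_gt(tab[tab$gene_set_id == "term_module1", "class1.type1"], 0.9)

  # summed_auroc equals the row sum of per-label AUROCs
  lab_cols <- sort(unique(d$labels$cell_type))
  expect_equal(tab$summed_auroc,
               unname(rowSums(tab[, lab_cols])), tolerance = 1e-12)
  expect_true(all(as.matrix(tab[, lab_cols]) >= 0 &
                    as.matrix(tab[, lab_cols]) <= 1))

  # consistency: one term equal to all genes reproduces the
  # whole-matrix discriminability
  whole_net <- build_cell_network(nm, colnames(d$counts))
  whole_au <- neighbor_voting_auroc(whole_net, d$labels$cell_type,
                                    seed = 2)
  expect_equal(unlist(tab[tab$gene_set_id == "whole", lab_cols]),
               whole_au[lab_cols], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("family comparison flags constructed shifts, not identical sets", {
  same <- list(f1 = c(0.5, 0.6, 0.7, 0.55), f2 = c(0.5, 0.6, 0.7, 0.55))
  res <- compare_gene_sets(same)
  expect_gt(res$p_value, 0.9)

  set.seed(8)
  base <- runif(30, 0.4, 0.6)
  shifted <- list(a = base, b = base + 0.2, c = runif(30, 0.4, 0.6))
  res2 <- compare_gene_sets(shifted)
  p_ab <- res2$p_value[res2$family_a == "a" & res2$family_b == "b"]
  expect_lt(p_ab, 1e-4)
  # BH q-values are monotone in ranked p and never below p
  o <- order(res2$p_value)
  expect_true(all(diff(res2$q_value[o]) >= -1e-12))
  expect_true(all(res2$q_value >= res2$p_value - 1e-12))

  expect_warning(compare_gene_sets(list(a = 1, b = c(0.4, 0.5),
                                        c = c(0.6, 0.7))),
                 "skipped")
  expect_error(suppressWarnings(compare_gene_sets(list(a = 1, b = c(1, 2)))),
               "at least 2")
})
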