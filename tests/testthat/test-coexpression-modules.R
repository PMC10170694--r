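# Adjacency, topological overlap (with brute-force oracle), consensus module
# cuts, profiles, gradient classification and module correlation.

test_that("soft adjacency follows |cor|^beta", {
  set.seed(1)
  t_ <- rnorm(50)
  x <- cbind(g1 = t_, g2 = 2 * t_ + 1, g3 = rnorm(50), g4 = -t_)
  rownames(x) <- sprintf("c%02d", 1:50)
  a <- soft_adjacency(x, beta = 4)
  expect_equal(a["g1", "g2"], 1, tolerance = 1e-12)  # perfectly correlated
  expect_equal(a["g1", "g4"], 1, tolerance = 1e-12)  # unsigned
  expect_lt(a["g1", "g3"], 0.05)                     # independent
  expect_equal(unname(a["g1", "g3"]),
               unname(abs(cor(x[, "g1"], x[, "g3"]))^4), tolerance = 1e-12)
  # printed example: cor 0.5, beta 4 -> 0.0625
  expect_equal(0.5^4, 0.0625)
  expect_error(soft_adjacency(x, beta = 0), "beta")
  xc <- cbind(x, g5 = rep(1, 50))
  expect_warning(soft_adjacency(xc, beta = 4), "zero-variance")
})

test_that("TOM matches the brute-force triple loop and closed forms", {
  # complete graph: all off-diagonal TOM = 1
  a1 <- matrix(1, 4, 4)
  t1 <- topological_overlap(a1)
  expect_true(all(t1 == 1))

  # empty graph: off-diagonal TOM = 0
  a0 <- diag(1, 5)
  t0 <- topological_overlap(a0)
  expect_true(all(t0[upper.tri(t0)] == 0))

  # random adjacencies vs the independent triple-loop oracle
  set.seed(6)
  for (i in 1:5) {
    a <- matrix(runif(36), 6, 6)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    expect_equal(topological_overlap(a), tom_bruteforce(a),
                 tolerance = 1e-12)
  }
})

test_that("TOM stays in [0, 1] for random valid adjacencies", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- topological_overlap(a)
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
    expect_true(isSymmetric(tom))
  }
})

test_that("consensus cut recovers separable blocks and applies size filter", {
  # two planted blocks: within-distance ~0, between ~1
  n1 <- 25; n2 <- 30
  d <- matrix(0.99, n1 + n2, n1 + n2)
  set.seed(2)
  d[1:n1, 1:n1] <- 0.05 + runif(n1 * n1, 0, 0.01)
  d[(n1 + 1):(n1 + n2), (n1 + 1):(n1 + n2)] <-
    0.05 + runif(n2 * n2, 0, 0.01)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  rownames(d) <- colnames(d) <- sprintf("g%03d", seq_len(n1 + n2))
  cat2 <- cut_modules(d, min_module_size = 20)
  expect_length(cat2$modules, 2)
  expect_setequal(cat2$modules[[1]], sprintf("g%03d", (n1 + 1):(n1 + n2)))
  expect_setequal(cat2$modules[[2]], sprintf("g%03d", 1:n1))
  # size-descending palette naming
  expect_equal(names(cat2$modules), c("turquoise", "blue"))

  # a 10-gene block dissolves under min_module_size = 20
  d3 <- matrix(0.99, 35, 35)
  d3[1:25, 1:25] <- 0.05
  d3[26:35, 26:35] <- 0.05
  diag(d3) <- 0
  rownames(d3) <- colnames(d3) <- sprintf("h%02d", 1:35)
  cat3 <- cut_modules(d3, min_module_size = 20)
  expect_length(cat3$modules, 1)
  expect_true(all(cat3$assignments[sprintf("h%02d", 26:35)] ==
                    "unassigned"))
})

test_that("module assignment is invariant to gene input order", {
  spec <- demo_spec(effect_size = 6, target = "class1", n_genes = 120)
  d <- simulate_dataset(spec)
  nm <- as.matrix(log_normalize(d$counts))
  tom <- topological_overlap(soft_adjacency(nm, beta = 4))
  cat1 <- cut_modules(1 - tom, min_module_size = 20)
  set.seed(10)
  perm <- sample(ncol(nm))
  tom_p <- topological_overlap(soft_adjacency(nm[, perm], beta = 4))
  cat_p <- cut_modules(1 - tom_p, min_module_size = 20)
  expect_identical(lapply(cat1$modules, sort), lapply(cat_p$modules, sort))
})

test_that("planted modules are recovered with high ARI at fold 4", {
  plan <- data.frame(size = rep(40, 5), kind = "discrete",
                     target = paste0("class", 1:5), effect_size = 4,
                     stringsAsFactors = FALSE)
  spec <- simulation_spec(5, 3, 20, 300, module_plan = plan, seed = 3)
  d <- simulate_dataset(spec)
  nm <- log_normalize(d$counts)
  tom <- topological_overlap(soft_adjacency(nm, beta = 4))
  catalog <- cut_modules(1 - tom, min_module_size = 20)
  truth <- rep("bg", ncol(d$counts))
  names(truth) <- colnames(d$counts)
  for (m in names(d$modules)) truth[d$modules[[m]]] <- m
  ari <- adjusted_rand_index(truth, catalog$assignments)
  expect_gte(ari, 0.9)
  # independent oracle for the ARI computation itself
  expect_equal(ari,
               mclust::adjustedRandIndex(truth, catalog$assignments),
               tolerance = 1e-12)
})

test_that("module profiles are background-normalized and scale-free", {
  spec <- demo_spec(effect_size = 8, target = "class1.type1")
  d <- simulate_dataset(spec)
  nm <- as.matrix(log_normalize(d$counts))
  # module = all genes -> self-normalization gives profile ~ 1
  cat_all <- module_profiles(nm, module_catalog(
    list(everything = colnames(nm)), colnames(nm)), seed = 1)
  expect_equal(unname(cat_all$profiles_norm[, 1]),
               rep(1, nrow(nm)), tolerance = 1e-9)

  # elevation is assessed on linear-scale normalized expression (the log
  # transform would compress the fold change)
  lin <- expm1(nm)
  cat_m <- module_profiles(lin, module_catalog(
    d$modules["module1"], colnames(nm)), seed = 1)
  target <- d$labels$cell_type == "class1.type1"
  expect_gt(mean(cat_m$profiles_norm[target, 1]) /
              mean(cat_m$profiles_norm[!target, 1]), 2)

  # doubling the normalized values leaves the normalized profile unchanged
  cat_2x <- module_profiles(lin * 2, module_catalog(
    d$modules["module1"], colnames(nm)), seed = 1)
  expect_equal(cat_2x$profiles_norm, cat_m$profiles_norm,
               tolerance = 1e-12)
})

test_that("gradient classes are recovered for 12 planted modules", {
  plan <- data.frame(
    size = rep(40, 12),
    kind = rep(c("discrete", "intermediate", "pure_gradient"), each = 4),
    target = c("class1.type1", "class2.type2", "class3.type3",
               "class4.type1", "class1", "class2", "class3", "class4",
               rep("all", 4)),
    effect_size = 6, stringsAsFactors = FALSE)
  spec <- simulation_spec(4, 3, 20, 560, module_plan = plan, seed = 11)
  d <- simulate_dataset(spec)
  nm <- log_normalize(d$counts)
  tom <- topological_overlap(soft_adjacency(nm, beta = 4))
  catalog <- cut_modules(1 - tom, min_module_size = 20)
  expect_gte(length(catalog$modules), 12)
  catalog <- module_profiles(nm, catalog, seed = 1)
  catalog <- classify_gradients(catalog, d$labels, k = 3, seed = 1)

  truth <- rep("bg", ncol(d$counts))
  names(truth) <- colnames(d$counts)
  for (m in names(d$modules)) truth[d$modules[[m]]] <- m
  planted_kind <- c(discrete = "discrete", intermediate = "intermediate",
                    pure_gradient = "pure")
  detected_kind <- vapply(catalog$modules, function(g) {
    pm <- names(which.max(table(truth[g])))
    if (pm == "bg") return(NA_character_)
    planted_kind[plan$kind[as.integer(sub("module", "", pm))]]
  }, character(1))
  acc <- sum(catalog$gradient_class == detected_kind, na.rm = TRUE)
  expect_gte(acc, 10)
  expect_gte(catalog$pc1_variance_explained, 1 / 3)
  expect_lte(catalog$pc1_variance_explained, 1)
})

test_that("a flat module lands at the pure extreme", {
  # three synthetic profiles: one uneven, one moderate, one exactly flat
  cells <- sprintf("c%03d", 1:60)
  lab <- data.frame(cell_id = cells,
                    cell_class = rep(c("k1", "k2", "k3"), each = 20),
                    cell_type = rep(c("k1.t", "k2.t", "k3.t"), each = 20),
                    category = "x", stringsAsFactors = FALSE)
  set.seed(3)
  catalog <- module_catalog(list(m1 = "a", m2 = "b", m3 = "c"),
                            c("a", "b", "c"))
  catalog$profiles <- cbind(
    m1 = c(rnorm(20, sd = 4), rnorm(40, sd = 0.1)),
    m2 = c(rnorm(40, sd = 1.2), rnorm(20, sd = 0.6)),
    m3 = rep(5, 60))
  rownames(catalog$profiles) <- cells
  catalog <- classify_gradients(catalog, lab, k = 3, seed = 2)
  expect_equal(unname(catalog$gradient_class["m3"]), "pure")
  expect_equal(unname(catalog$gradient_class["m1"]), "discrete")
})

test_that("anti-regulated modules anticorrelate; correlation is proper", {
  plan <- data.frame(size = c(40, 40), kind = "pure_gradient",
                     target = "all", effect_size = 4,
                     stringsAsFactors = FALSE)
  spec <- simulation_spec(2, 3, 20, 120, module_plan = plan,
                          anti_pair = c(1, 2), seed = 5)
  d <- simulate_dataset(spec)
  nm <- log_normalize(d$counts)
  catalog <- module_profiles(nm, module_catalog(d$modules,
                                                colnames(d$counts)),
                             seed = 1)
  mc <- module_correlation(catalog)
  expect_true(isSymmetric(mc))
  expect_equal(unname(diag(mc)), rep(1, 2))
  expect_lt(mc["module1", "module2"], 0)
})
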