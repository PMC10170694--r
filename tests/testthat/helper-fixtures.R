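# Shared fixtures: small simulation designs used across test files.

# two classes x three types, one discrete module targeting class1.type1
demo_spec <- function(effect_size = 8, seed = 7, n_genes = 200,
                      cells_per_type = 20,
                      kind = "discrete", target = "class1.type1",
                      module_size = 40) {
  simulation_spec(
    n_classes = 2, types_per_class = 3, cells_per_type = cells_per_type,
    n_genes = n_genes,
    module_plan = data.frame(size = module_size, kind = kind,
                             target = target, effect_size = effect_size,
                             stringsAsFactors = FALSE),
    seed = seed)
}

# structureless spec: no modules (every gene is background noise)
null_spec <- function(seed = 7, n_genes = 150, n_classes = 2,
                      types_per_class = 2, cells_per_type = 30) {
  simulation_spec(n_classes = n_classes, types_per_class = types_per_class,
                  cells_per_type = cells_per_type, n_genes = n_genes,
                  seed = seed)
}

# independent brute-force AUROC: enumerate all positive/negative pairs
auroc_bruteforce <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# independent brute-force topological overlap (triple loop)
tom_bruteforce <- function(a) {
  n <- nrow(a)
  diag(a) <- 1
  k <- rowSums(a) - 1
  tom <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) {
      if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    }
    tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# independent hypergeometric upper tail by direct enumeration
hyper_tail_bruteforce <- function(k, K, n, N) {
  tot <- 0
  for (x in k:min(K, n)) {
    tot <- tot + choose(K, x) * choose(N - K, n - x)
  }
  tot / choose(N, n)
}
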