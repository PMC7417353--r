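# shared fixtures built in code

# adjacency matrix from an edge list over given actor names
adj <- function(edges, actors) {
  m <- matrix(0L, length(actors), length(actors),
              dimnames = list(actors, actors))
  for (e in edges) m[e[1], e[2]] <- 1L
  m
}

# a closed herd: n actors all present from week 1
closed_herd <- function(n, n_waves, age = 5) {
  actor_table(data.frame(actor_id = sprintf("a%02d", seq_len(n)),
                         age = age, entry_week = 1L), n_waves)
}

# simple two-effect ground truth panel used by estimation tests
recovery_config <- function(seed, n = 30) {
  synth_config(n_actors = n, n_waves = 6,
               entry_schedule = c(n, 0, 0, 0, 0, 0),
               beta_true = c(outdegree = -2, reciprocity = 1.2),
               rate_true = rep(5, 5), density_target = 0.15, seed = seed)
}

recovery_panel <- function(seed, n = 30) {
  gen_wave_panel(closed_herd(n, 6), recovery_config(seed, n))
}

# independent brute-force evaluation of every effect statistic by explicit
# loops over (j, h); deliberately naive so it can serve as an oracle
brute_effect_statistic <- function(name, i, x, v = NULL) {
  n <- nrow(x)
  outdeg <- vapply(seq_len(n), function(a) sum(x[a, ]), 0)
  indeg <- vapply(seq_len(n), function(a) sum(x[, a]), 0)
  s <- 0
  if (name == "outdegree") {
    for (j in seq_len(n)) s <- s + x[i, j]
  } else if (name == "reciprocity") {
    for (j in seq_len(n)) s <- s + x[i, j] * x[j, i]
  } else if (name == "transitive_triplets") {
    for (j in seq_len(n)) for (h in seq_len(n))
      s <- s + x[i, h] * x[h, j] * x[i, j]
  } else if (name == "transitive_recip_triplets") {
    for (j in seq_len(n)) for (h in seq_len(n))
      s <- s + x[i, j] * x[j, i] * x[i, h] * x[h, j]
  } else if (name == "three_cycles") {
    for (j in seq_len(n)) for (h in seq_len(n))
      s <- s + x[i, j] * x[j, h] * x[h, i]
  } else if (name == "indegree_popularity") {
    for (j in seq_len(n)) s <- s + x[i, j] * indeg[j]
  } else if (name == "outdegree_popularity_sqrt") {
    for (j in seq_len(n)) s <- s + x[i, j] * sqrt(outdeg[j])
  } else if (name == "outdegree_activity_sqrt") {
    s <- outdeg[i]^1.5
  } else if (name == "out_out_assortativity") {
    for (j in seq_len(n)) s <- s + x[i, j] * sqrt(outdeg[i]) * sqrt(outdeg[j])
  } else if (name == "cov_ego") {
    s <- v[i] * outdeg[i]
  } else if (name == "cov_alter") {
    for (j in seq_len(n)) s <- s + x[i, j] * v[j]
  } else if (name == "cov_same") {
    for (j in seq_len(n)) s <- s + x[i, j] * (v[i] == v[j])
  } else if (name == "cov_similarity") {
    rng <- max(v) - min(v)
    simval <- function(a, b) if (rng == 0) 1 else 1 - abs(v[a] - v[b]) / rng
    sims <- c()
    for (a in seq_len(n)) for (b in seq_len(n)) if (a != b)
      sims <- c(sims, simval(a, b))
    ctr <- mean(sims)
    for (j in seq_len(n)) if (j != i)
      s <- s + x[i, j] * (simval(i, j) - ctr)
  } else if (name == "same_cov_x_reciprocity") {
    for (j in seq_len(n)) s <- s + x[i, j] * x[j, i] * (v[i] == v[j])
  } else stop("unknown effect in oracle: ", name)
  s
}

# decode a graph index (0 .. 2^(n(n-1))-1) into an n-node digraph
digraph_from_index <- function(idx, n) {
  m <- matrix(0L, n, n)
  off <- which(row(m) != col(m))
  bits <- as.integer(intToBits(idx))[seq_along(off)]
  m[off] <- bits
  m
}

random_digraph <- function(n, p = 0.3) {
  m <- matrix(rbinom(n * n, 1, p), n, n)
  diag(m) <- 0L
  storage.mode(m) <- "integer"
  m
}

# all-pairs shortest path lengths by Floyd-Warshall (independent oracle)
floyd_warshall <- function(x) {
  n <- nrow(x)
  d <- matrix(Inf, n, n)
  d[x == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}
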