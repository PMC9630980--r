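# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so individual files stay fast.

tiny_map <- function(n_chrom = 2, n_markers = 10, len = 100000, seed = 11) {
  make_marker_map(n_chrom, n_markers, len, seed = seed)
}

# a small but complete simulated experiment shared by several test files
small_sim <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    map <- make_marker_map(4, 15, 300000, seed = 501)
    geno <- simulate_cross(map, 150, 2, seed = 502)
    em <- simulate_effect_model(map, 2, 1, 0.2, min_distance_bp = 150000,
                                seed = 503)
    asg <- make_barcode_assignment(rownames(geno), 30, seed = 504)
    des <- make_experiment_design(depth = 5e4)
    sim <- simulate_experiment(geno, asg, em, des, seed = 505)
    cache <<- list(map = map, geno = geno, em = em, asg = asg, des = des,
                   sim = sim)
    cache
  }
})

# independent brute-force Viterbi oracle: enumerate all 2^n state paths and
# return the maximum-probability path (ties resolved toward the all-lower
# path by enumeration order), using log probabilities
brute_force_viterbi <- function(calls, stay = 0.9999, concordant = 0.75) {
  n <- length(calls)
  paths <- as.matrix(expand.grid(rep(list(0:1), n))[, n:1, drop = FALSE])
  logp <- apply(paths, 1, function(st) {
    lp <- log(0.5)
    for (t in seq_len(n)) {
      if (t > 1)
        lp <- lp + log(if (st[t] == st[t - 1]) stay else 1 - stay)
      if (!is.na(calls[t]))
        lp <- lp + log(if (calls[t] == st[t]) concordant else 1 - concordant)
    }
    lp
  })
  list(path = unname(paths[which.max(logp), ]), logp = max(logp))
}

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

read_tsv_for_test <- function(path)
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)

# log-probability of a specific state path under the same 2-state model
brute_force_viterbi_logp <- function(calls, path, stay = 0.9999,
                                     concordant = 0.75) {
  lp <- log(0.5)
  for (t in seq_along(calls)) {
    if (t > 1)
      lp <- lp + log(if (path[t] == path[t - 1]) stay else 1 - stay)
    if (!is.na(calls[t]))
      lp <- lp + log(if (calls[t] == path[t]) concordant else 1 - concordant)
  }
  lp
}

# independent interval connected-components oracle (adjacency + BFS)
brute_force_components <- function(start, end) {
  n <- length(start)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    start[i] <= end[j] & start[j] <= end[i])
  comp <- rep(NA_integer_, n)
  cc <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cc <- cc + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cc
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# all permutations of 1..n (for exhaustive permutation-threshold checks)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
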