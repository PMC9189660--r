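# Fixtures built in code for the test suite.

# Noiseless binned fold-change curve straight from the model.
make_model_curve <- function(delta_eps, fc_max = 0, n_ns = 4.6e6,
                             tf = 10^seq(0, 3, length.out = 10)) {
  p <- thermo_params(delta_eps, fc_max, n_ns)
  tibble::tibble(mean_tf = tf, mean_fc = fold_change(tf, p),
                 sem_fc = 0, n = 30L)
}

# Normalized growth-rate profile matrix built from six phenotype
# templates (flat-fast, rescue-up, flat-slow, decline,
# rescue-then-decline, collapse) with Gaussian jitter.
make_six_template_matrix <- function(n_per_template = 8, noise_sd = 0.05,
                                     seed = 1) {
  set.seed(seed)
  atc <- c(0, 1, 3, 5, 7, 9, 15)
  templates <- list(
    flat_fast = rep(1.15, 7),
    rescue_up = seq(0.4, 1.0, length.out = 7),
    flat_slow = rep(0.7, 7),
    decline = seq(1.0, 0.4, length.out = 7),
    rescue_decline = c(0.5, 0.75, 1.0, 1.0, 0.85, 0.65, 0.5),
    collapse = c(1.0, 0.95, 0.85, 0.1, 0.05, 0.05, 0.05)
  )
  rows <- list(); labels <- character(0)
  for (nm in names(templates)) {
    for (i in seq_len(n_per_template)) {
      rows[[length(rows) + 1L]] <-
        templates[[nm]] + rnorm(7, 0, noise_sd)
      labels <- c(labels, nm)
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("%s_%d", labels, seq_along(labels))
  colnames(m) <- as.character(atc)
  list(matrix = m, labels = labels)
}

# Best assignment accuracy over all label permutations (6 clusters max).
cluster_accuracy <- function(assignments, labels) {
  labs <- unique(labels)
  clus <- sort(unique(assignments))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- 0
  for (p in perms(clus)) {
    map <- stats::setNames(labs[seq_along(p)], p)
    acc <- mean(map[as.character(assignments)] == labels)
    best <- max(best, acc)
  }
  best
}
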