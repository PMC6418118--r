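# Independent oracles used across test files. These deliberately re-derive
# quantities by direct enumeration/loops, not by calling the fast paths they
# check.

# Expected posterior entropy by explicit two-outcome enumeration.
brute_expected_entropy <- function(post, deltas) {
  vapply(deltas, function(d) {
    p1 <- sum(post$mass * likelihood_slice(post$grid, d, TRUE))
    h1 <- posterior_entropy(update_posterior(post, d, TRUE))
    h0 <- posterior_entropy(update_posterior(post, d, FALSE))
    p1 * h1 + (1 - p1) * h0
  }, numeric(1))
}

# Connected-component labelling by breadth-first flood fill over voxel
# coordinates (independent of the package's union-find and adjacency code).
flood_fill_labels <- function(mask, in_set, connectivity) {
  shape <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- switch(as.character(connectivity),
                 "6" = offs[rowSums(abs(offs)) == 1, , drop = FALSE],
                 "18" = offs[rowSums(abs(offs)) <= 2, , drop = FALSE],
                 "26" = offs)
  set_idx <- which(mask)[in_set]
  co <- arrayInd(set_idx, shape)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  pos <- setNames(seq_len(nrow(co)), key(co))
  labels <- integer(nrow(co))
  lab <- 0L
  for (s in seq_len(nrow(co))) {
    if (labels[s] > 0) next
    lab <- lab + 1L
    queue <- s
    labels[s] <- lab
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- sweep(offs, 2, as.numeric(co[v, ]), "+")
      hits <- pos[key(nb)]
      hits <- hits[!is.na(hits)]
      fresh <- hits[labels[hits] == 0]
      labels[fresh] <- lab
      queue <- c(queue, fresh)
    }
  }
  list(index = set_idx, labels = labels)
}

# Tiny deterministic 3x3x1 grid used by several engine tests.
toy_grid <- function() {
  psy_grid(alpha_range = c(50, 250), beta_range = c(-1.5, 0), lam_range = c(0.02, 0.02),
           n_alpha = 3, n_beta = 3, n_lam = 1)
}

# A synthetic permutation-result shell for cluster-extraction tests.
fake_ptest <- function(mask, p_corr, direction = "negative", connectivity = 26L) {
  adjacency <- mask_adjacency(mask, connectivity)
  structure(list(t = rep(0, length(p_corr)), tfce = 1 - p_corr, p_corr = p_corr,
                 max_null = numeric(0), direction = direction, n_perm = 0L,
                 mask = mask, adjacency = adjacency,
                 adjacency_connectivity = connectivity, df = NA_integer_,
                 seed = NA_integer_),
            class = "voxel_ptest")
}

# Small, fast null cohort spec used for permutation tests.
small_cohort_spec <- function(...) {
  cohort_spec(shape = c(32L, 32L, 32L), mask_fraction = 0.012,
              region_size = 0L, effect_size = 0, ...)
}

# Shared cache so expensive study objects are computed once per test run.
.psivox_test_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .psivox_test_cache)) {
    assign(name, force(expr), envir = .psivox_test_cache)
  }
  get(name, envir = .psivox_test_cache)
}

cached_recovery <- function() {
  cached("recovery", recovery_study(n_observers = 200L, seed = 20260926L))
}
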