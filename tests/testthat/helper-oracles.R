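# Independent oracles used across tests.  These deliberately take
# different computational routes from the package implementation.

# Flood-fill connected-components oracle: plain stack-based BFS over an
# explicit neighbour loop.
oracle_largest_component <- function(mask, voxel_volume = 1,
                                     connectivity = 26L) {
  dims <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6L) {
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  }
  seen <- array(FALSE, dims)
  best <- 0L
  for (v in which(mask == 1)) {
    if (seen[v]) next
    stack <- v
    seen[v] <- TRUE
    size <- 0L
    while (length(stack) > 0L) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      pos <- arrayInd(cur, dims)
      for (k in seq_len(nrow(offs))) {
        q <- pos + c(offs$dx[k], offs$dy[k], offs$dz[k])
        if (any(q < 1) || any(q > dims)) next
        lin <- (q[3] - 1) * dims[1] * dims[2] + (q[2] - 1) * dims[1] + q[1]
        if (mask[lin] == 1 && !seen[lin]) {
          seen[lin] <- TRUE
          stack <- c(stack, lin)
        }
      }
    }
    best <- max(best, size)
  }
  best * voxel_volume
}

# Brute-force LOOCV oracle: refits the model once per held-out row using
# base lm (full-rank designs).
oracle_loocv <- function(X, y) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    df <- data.frame(y = y[-i], X[-i, , drop = FALSE])
    fit <- lm(y ~ ., data = df)
    unname(predict(fit, newdata = data.frame(X[i, , drop = FALSE])))
  }, numeric(1))
}

# Dense-grid quadrature oracle for the correlation Bayes factor:
# midpoint rule on u in (0,1) with g = u/(1-u), `nodes` nodes.
oracle_bf_correlation <- function(r, n, nodes = 1e6) {
  u <- (seq_len(nodes) - 0.5) / nodes
  g <- u / (1 - u)
  logf <- (n - 2) / 2 * log1p(g) - (n - 1) / 2 * log1p((1 - r^2) * g) -
    1.5 * log(g) - n / (2 * g) - 2 * log1p(-u)
  m <- max(logf)
  exp(m) * mean(exp(logf - m)) * sqrt(n / 2) / sqrt(pi)
}

# Small deterministic toy atlas: disjoint axis-aligned blocks.
block_atlas <- function(dims = c(8L, 8L, 8L), voxel_volume = 1) {
  arr <- array(seq_len(prod(dims)), dims)
  regions <- list(
    A = as.integer(arr[1:2, 1:2, 1:2]),
    B = as.integer(arr[5:8, 1:4, 1:2]),
    C = as.integer(arr[1:4, 5:8, 5:8])
  )
  toy_atlas(dims, voxel_volume, regions)
}

mask_from_voxels <- function(vox, dims) {
  arr <- array(0L, dims)
  arr[vox] <- 1L
  arr
}

# One moderate cohort shared across test files (built once per run).
.fixture_env <- new.env(parent = emptyenv())
shared_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- simulation_config(n_group_a = 60L, n_group_b = 15L,
                             n_regions = 12L, n_tasks = 4L,
                             lambda_sensitivity = 1.5, seed = 42L)
    .fixture_env$cohort <- generate_cohort(cfg)
  }
  .fixture_env$cohort
}
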