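# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture_cached <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

# a single-colony training scene (400 px tile)
training_scene <- function(seed, class = "esc_like", irr = 0.05, fib = 0.1,
                           halo = 60, tex = 12, noise_sd = 4, debris = 2) {
  set.seed(seed)
  cs <- colony_spec(c(200, 200) + stats::runif(2, -20, 20),
                    stats::runif(1, 90, 130),
                    edge_irregularity = irr, fibrousness = fib,
                    halo_strength = halo, interior_texture_sd = tex,
                    morph_class = class, check_floor = FALSE)
  render_scene(scene_spec(image_size_px = 400, colonies = list(cs),
                          debris_count = debris, noise_sd = noise_sd,
                          seed = seed))
}

# texture model trained on one scene of each morphology
fixture_model <- function() {
  fixture_cached("model", function() {
    tr1 <- training_scene(11, "esc_like", 0.05, 0.1, 60, 12)
    tr2 <- training_scene(12, "collapsed_edge", 0.28, 1.5, 30, 9)
    train_texture_model(
      list(flatten_background(tr1$image), flatten_background(tr2$image)),
      list(tr1$truth$label_image > 0, tr2$truth$label_image > 0),
      n_candidates = 50, seed = 5)
  })
}

# segment + profile every scene of a benchmark tibble
profile_benchmark <- function(bench, model, cfg = segmentation_config()) {
  rows <- lapply(seq_len(nrow(bench)), function(i) {
    col <- segment_image(bench$image[[i]], model, cfg,
                         image_id = bench$scene_id[i])
    if (nrow(col) == 0) return(NULL)
    pr <- compute_profiles(col, bench$image[[i]])
    pr$morph_class <- bench$morph_class[i]
    pr
  })
  dplyr::bind_rows(rows)
}

# the calibrated two-population study: DB half and held-out half
fixture_benchmark_profiles <- function() {
  fixture_cached("bench_profiles", function() {
    mdl <- fixture_model()
    list(db = profile_benchmark(
           make_two_population_benchmark(20, effect = 1, seed = 101), mdl),
         heldout = profile_benchmark(
           make_two_population_benchmark(20, effect = 1, seed = 202), mdl))
  })
}

# a structured synthetic profile table: two morphology groups separated on
# a 12-parameter panel of realistic magnitude (all CVs below the filter,
# no near-duplicate pairs), so a pruned database yields a small number of
# clusters as in real colony panels
make_structured_profiles <- function(n = 24, seed = 13, n_params = 12) {
  set.seed(seed)
  cls <- rep(c(0, 1), each = ceiling(n / 2))[seq_len(n)]
  mus <- stats::runif(n_params, 10, 100)
  dirs <- sample(c(-1, 1), n_params, replace = TRUE)
  prof <- tibble::tibble(colony_id = paste0("c", seq_len(n)))
  for (j in seq_len(n_params)) {
    prof[[sprintf("p%02d", j)]] <-
      mus[j] + dirs[j] * 0.25 * mus[j] * cls + stats::rnorm(n, 0, 0.06 * mus[j])
  }
  list(profiles = prof, class = cls)
}

# brute-force O(n^3) average-linkage oracle on a similarity matrix,
# smallest-pair tie-break; returns hclust-convention merges and heights
brute_force_average_linkage <- function(S) {
  n <- nrow(S)
  D <- 1 - S
  diag(D) <- NA
  members <- as.list(seq_len(n))
  nodes <- -(seq_len(n))
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- which(D == min(D, na.rm = TRUE), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- min(best); j <- max(best)
    merges[step, ] <- sort(c(nodes[i], nodes[j]))
    heights[step] <- D[i, j]
    ni <- length(members[[i]]); nj <- length(members[[j]])
    newd <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    members[[i]] <- c(members[[i]], members[[j]])
    D[i, ] <- newd; D[, i] <- newd; D[i, i] <- NA
    D <- D[-j, -j, drop = FALSE]
    members <- members[-j]
    nodes[i] <- step
    nodes <- nodes[-j]
  }
  list(merge = merges, height = heights)
}

expect_tree_equals_oracle <- function(tree, S) {
  o <- brute_force_average_linkage(S)
  expect_equal(t(apply(tree$merge, 1, sort)), o$merge, ignore_attr = TRUE)
  expect_equal(unname(1 - tree$similarity), unname(o$height),
               tolerance = 1e-12)
}

# brute-force Benjamini-Hochberg step-up
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# adjusted Rand index (used where mclust is unavailable is not a concern,
# but keeping the oracle explicit documents the computation)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
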