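test_that("percentile-shift normalisation anchors every colony's 75th percentile at zero", {
  se <- synth_expression(200, c(A = 4, B = 6), seed = 3)
  nm <- percentile_shift_normalize(se$matrix)
  q75 <- apply(nm, 2, stats::quantile, 0.75, names = FALSE)
  expect_equal(unname(q75), rep(0, ncol(nm)), tolerance = 1e-12)
  # idempotent and shift invariant
  expect_equal(percentile_shift_normalize(nm), nm, tolerance = 1e-12,
               ignore_attr = TRUE)
  shifted <- sweep(se$matrix, 2, runif(ncol(se$matrix), -3, 3), `+`)
  expect_equal(percentile_shift_normalize(shifted), nm, tolerance = 1e-12,
               ignore_attr = TRUE)
  # the documented linear-interpolation rule: {1,2,3,4} -> subtract 3.25
  m <- matrix(c(1, 2, 3, 4), ncol = 1, dimnames = list(NULL, "c1"))
  expect_equal(as.numeric(percentile_shift_normalize(m)),
               c(1, 2, 3, 4) - 3.25)
  mc <- matrix(5, 4, 1, dimnames = list(NULL, "c1"))
  expect_error(percentile_shift_normalize(mc), "constant")
})

test_that("BH adjustment matches the brute-force step-up on random p-vectors", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(c(5, 50, 500, 5000), 1)
    p <- runif(n)^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, "BH"), brute_force_bh(p),
                 tolerance = 1e-12)
  }
})

test_that("cluster-vs-rest testing matches t.test per probe and controls errors", {
  se <- synth_expression(80, c(A = 5, B = 9), seed = 12)
  de <- cluster_vs_rest(se$matrix, se$cluster_of, "A")
  in_cols <- names(se$cluster_of)[se$cluster_of == "A"]
  out_cols <- setdiff(colnames(se$matrix), in_cols)
  for (i in c(1, 40, 80)) {
    ref <- stats::t.test(se$matrix[i, in_cols], se$matrix[i, out_cols])
    expect_equal(de$p_raw[i], ref$p.value, tolerance = 1e-12)
  }
  expect_true(all(de$p_adjusted >= de$p_raw))
  expect_equal(de$significant, de$p_adjusted < 0.05)
  # identical groups: p ~ 1, not significant
  m <- matrix(rep(c(5, 6, 5, 6, 5, 6), 1), nrow = 1,
              dimnames = list("p1", paste0("c", 1:6)))
  cl <- stats::setNames(rep(c("A", "B"), 3), paste0("c", 1:6))
  d1 <- cluster_vs_rest(m, cl, "A")
  expect_gt(d1$p_raw, 0.99)
  expect_false(d1$significant)
  expect_error(cluster_vs_rest(se$matrix, se$cluster_of, "missing"),
               "at least 2")
})

test_that("the null simulation keeps the observed FDR within Monte-Carlo error of 5%", {
  set.seed(55)
  fdrs <- vapply(1:200, function(i) {
    se <- synth_expression(100, c(A = 6, B = 8), spike = list(n_spiked = 0, fold = 1),
                           seed = 1000 + i)
    de <- cluster_vs_rest(se$matrix, se$cluster_of, "A")
    v <- sum(de$significant)  # every rejection is false under the null
    v / max(sum(de$significant), 1)
  }, numeric(1))
  se_hat <- stats::sd(fdrs) / sqrt(length(fdrs))
  expect_lte(mean(fdrs), 0.05 + 2 * se_hat)
})

test_that("spiked 4-fold probes are recovered with at least 90% power", {
  se <- synth_expression(2000, c(A = 6, B = 26),
                         spike = list(n_spiked = 100, fold = 4), seed = 71)
  de <- cluster_vs_rest(se$matrix, se$cluster_of, "A")
  power <- mean(de$significant[se$truth$spiked])
  expect_gte(power, 0.9)
  # spiked probes carry the fold change on the linear scale
  expect_gt(median(de$fold_change[se$truth$spiked]), 3)
})

test_that("fold-change screens split by direction with strict nesting", {
  res <- tibble::tibble(probe_id = paste0("p", 1:4),
                        mean_in = 1, mean_out = 1,
                        fold_change = c(5, 3.5, 2, 0.2),
                        p_raw = 0.001, p_adjusted = 0.01,
                        significant = TRUE)
  class(res) <- c("diff_exp", class(res))
  s3 <- fold_change_screen(res, 3)
  expect_setequal(s3$higher$probe_id, c("p1", "p2"))
  expect_equal(s3$lower$probe_id, "p4")
  s4 <- fold_change_screen(res, 4)
  expect_true(all(s4$higher$probe_id %in% s3$higher$probe_id))
  expect_true(all(s4$lower$probe_id %in% s3$lower$probe_id))
  # folds of exactly 1 fall in neither list
  res1 <- dplyr::mutate(res, fold_change = 1)
  s1 <- fold_change_screen(res1, 1 + 1e-9)
  expect_equal(s1$n_higher + s1$n_lower, 0)
  expect_error(fold_change_screen(res, 1), "min_fold")
})

test_that("expression clustering uses the shared average-linkage engine", {
  # two identical colonies merge first at similarity 1
  m <- matrix(c(1, 2, 3, 1, 2, 3, 3, 1, 2), nrow = 3,
              dimnames = list(paste0("p", 1:3), paste0("c", 1:3)))
  tr <- cluster_expression(m, baseline_shift = FALSE)
  expect_equal(sort(tr$merge[1, ]), c(-2, -1))
  expect_equal(tr$similarity[1], 1)
  # oracle equivalence for n <= 8 colonies
  set.seed(19)
  for (i in 1:30) {
    nc <- sample(3:8, 1)
    mm <- matrix(rnorm(12 * nc, 8), 12, nc,
                 dimnames = list(paste0("p", 1:12), paste0("c", seq_len(nc))))
    tr <- cluster_expression(mm, baseline_shift = FALSE)
    expect_tree_equals_oracle(tr, similarity_matrix(t(mm)))
  }
  # a strong two-group structure is recovered at the top split
  se <- synth_expression(300, c(A = 4, B = 5),
                         spike = list(n_spiked = 120, fold = 6),
                         noise_sd = 0.3, seed = 23)
  tr2 <- cluster_expression(se$matrix)
  top <- prune_tree(tr2, tr2$similarity[length(tr2$similarity)] + 1e-9)
  expect_equal(adjusted_rand(top[names(se$cluster_of)],
                             unname(se$cluster_of)), 1)
})

test_that("PCA projection matches the hand example with fixed signs", {
  m <- matrix(c(0, 0, 2, 2), nrow = 2,
              dimnames = list(c("p1", "p2"), c("c1", "c2")))
  pp <- pca_project(m)
  expect_equal(sort(abs(pp$scores$PC1)), c(sqrt(2), sqrt(2)))
  expect_equal(pp$explained[1], 1)
  # largest-magnitude loading is positive
  expect_gt(max(pp$loadings[, 1]), 0)
  # identical colonies: zero scores, zero variance fractions
  mi <- matrix(rep(c(1, 5, 3), 3), nrow = 3,
               dimnames = list(paste0("p", 1:3), paste0("c", 1:3)))
  p0 <- pca_project(mi)
  expect_true(all(abs(p0$scores$PC1) < 1e-12))
  expect_true(all(p0$explained == 0))
  # variance fractions are non-increasing and sum to <= 1
  se <- synth_expression(50, c(A = 5, B = 5), seed = 4)
  pv <- pca_project(se$matrix, k = 5)
  expect_true(all(diff(pv$explained) <= 1e-12))
  expect_lte(sum(pv$explained), 1 + 1e-12)
})

test_that("synthetic expression matrices are deterministic with a faithful truth table", {
  a <- synth_expression(60, c(A = 3, B = 4),
                        spike = list(n_spiked = 10, fold = 4), seed = 9)
  b <- synth_expression(60, c(A = 3, B = 4),
                        spike = list(n_spiked = 10, fold = 4), seed = 9)
  expect_identical(a, b)
  expect_equal(sum(a$truth$spiked), 10)
  # noise-free spikes separate exactly
  c0 <- synth_expression(60, c(A = 3, B = 4),
                         spike = list(n_spiked = 10, fold = 4),
                         noise_sd = 0, seed = 9)
  gap <- rowMeans(c0$matrix[, c0$cluster_of == "A"]) -
    rowMeans(c0$matrix[, c0$cluster_of == "B"])
  expect_equal(unname(gap[c0$truth$spiked]), rep(2, 10), tolerance = 1e-12)
  expect_equal(unname(gap[!c0$truth$spiked]), rep(0, 50), tolerance = 1e-12)
  # TSV round trip
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(a$matrix, tmp)
  expect_equal(read_expression_tsv(tmp), a$matrix, tolerance = 1e-12)
})

test_that("morphology clusters and expression clustering agree when they share the partition", {
  # colonies whose morphology class also drives a spiked expression module
  n <- 16
  sp <- make_structured_profiles(n, seed = 61)
  prof <- sp$profiles
  cls <- sp$class
  db <- build_colony_db(prof)
  morph_cl <- db$cluster_of[prof$colony_id]
  se <- synth_expression(400, c(state1 = n / 2, state0 = n / 2),
                         spike = list(n_spiked = 150, fold = 5),
                         noise_sd = 0.4, seed = 62)
  # align expression colonies with the morphology colonies by class
  colnames(se$matrix) <- c(prof$colony_id[cls == 1], prof$colony_id[cls == 0])
  tr <- cluster_expression(se$matrix)
  top <- prune_tree(tr, tr$similarity[length(tr$similarity)] + 1e-9)
  expect_gte(adjusted_rand(morph_cl[prof$colony_id],
                           top[prof$colony_id]), 0.8)
})
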