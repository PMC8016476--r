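test_that("growth-intercept scaling matches the closed form", {
  d <- make_design(mu = seq(0.1, 0.5, 0.1), reps = 2)
  em <- design_matrix_em(d, list(
    lin = function(mu, i) 2 + 4 * mu,     # intercept 2
    flat = function(mu, i) 5,             # constant gene
    neg = function(mu, i) -0.1 + 2 * mu)) # nonpositive intercept
  sc <- scale_by_growth_intercept(em, d)
  expect_equal(unname(sc$constants["lin"]), 2, tolerance = 1e-9)
  expect_equal(unname(sc$values["lin", "c5"]), log2(4 / 2), tolerance = 1e-9)
  expect_true(all(abs(sc$values["flat", ]) < 1e-9))
  expect_false("neg" %in% rownames(sc$values))
  expect_equal(sc$excluded$reason[sc$excluded$gene == "neg"],
               "nonpositive intercept")

  d2 <- make_design(mu = c(0.1, 0.2), reps = 2)
  em2 <- design_matrix_em(d2, list(g = function(mu, i) 1 + mu))
  expect_error(scale_by_growth_intercept(em2, d2), ">= 3 distinct")
})

test_that("reference-mean scaling zeroes the reference state", {
  m <- tiny_em(matrix(c(2, 2, 8), 1, 3), genes = "g",
               samples = c("ref1", "ref2", "s3"))
  sc <- scale_by_reference_mean(m, c("ref1", "ref2"))
  expect_equal(unname(sc$values["g", ]), c(0, 0, 2))

  const <- tiny_em(matrix(3, 2, 4), genes = c("a", "b"))
  scc <- scale_by_reference_mean(const, em_samples(const)[1:2])
  expect_true(all(scc$values == 0))

  # the arithmetic reference mean of back-transformed values is exactly 1
  set.seed(3)
  r <- tiny_em(matrix(10^runif(40, -2, 2), 5, 8))
  scr <- scale_by_reference_mean(r, em_samples(r)[c(1, 4, 6)])
  back <- rowMeans(2^scr$values[, c(1, 4, 6)])
  expect_equal(unname(back), rep(1, 5), tolerance = 1e-12)

  expect_error(scale_by_reference_mean(m, character(0)), "empty")
  expect_error(scale_by_reference_mean(m, "nope"), "nope")
})

# hand-made ScaledMatrix around a profile matrix
as_scaled <- function(x) {
  structure(list(values = x, mode = "GR_intercept",
                 constants = setNames(rep(1, nrow(x)), rownames(x)),
                 excluded = data.frame(gene = character(0),
                                       reason = character(0))),
            class = "ScaledMatrix")
}

gauss_groups <- function(centers, n_per, sd, seed) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_along(centers), function(i) {
    matrix(rnorm(n_per * 5, centers[[i]], sd), n_per, 5, byrow = TRUE)
  }))
  rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  x
}

test_that("validity indices agree with brute-force small-instance oracles", {
  x <- gauss_groups(list(rep(0, 5), rep(10, 5)), 6, 0.5, seed = 1)
  ct <- rep(1:2, each = 6)
  dm <- as.matrix(dist(x))

  # silhouette oracle: explicit double loop
  sil_oracle <- mean(sapply(seq_len(nrow(x)), function(i) {
    a <- mean(dm[i, setdiff(which(ct == ct[i]), i)])
    b <- min(sapply(setdiff(unique(ct), ct[i]),
                    function(g) mean(dm[i, ct == g])))
    (b - a) / max(a, b)
  }))
  expect_equal(steadyomics:::index_silhouette(dm, ct), sil_oracle,
               tolerance = 1e-12)

  # Calinski-Harabasz oracle from the definition
  gm <- colMeans(x)
  w <- sum(sapply(1:2, function(g)
    sum(sweep(x[ct == g, ], 2, colMeans(x[ct == g, ]))^2)))
  b <- sum(sapply(1:2, function(g)
    sum(ct == g) * sum((colMeans(x[ct == g, ]) - gm)^2)))
  ch_oracle <- (b / 1) / (w / (nrow(x) - 2))
  expect_equal(steadyomics:::index_calinski_harabasz(x, ct), ch_oracle,
               tolerance = 1e-12)

  # Dunn oracle
  dunn_oracle <- min(dm[ct == 1, ct == 2]) /
    max(max(dm[ct == 1, ct == 1]), max(dm[ct == 2, ct == 2]))
  expect_equal(steadyomics:::index_dunn(dm, ct), dunn_oracle,
               tolerance = 1e-12)

  # C-index oracle
  dv <- as.numeric(dist(x))
  wmask <- steadyomics:::within_pair_mask(ct)
  pairs <- t(combn(seq_len(nrow(x)), 2))
  expect_identical(wmask, ct[pairs[, 1]] == ct[pairs[, 2]])
  nw <- sum(wmask)
  ci_oracle <- (sum(dv[wmask]) - sum(sort(dv)[1:nw])) /
    (sum(sort(dv, decreasing = TRUE)[1:nw]) - sum(sort(dv)[1:nw]))
  expect_equal(steadyomics:::index_c(dv, wmask), ci_oracle, tolerance = 1e-12)

  # McClain-Rao oracle
  mr_oracle <- mean(dv[wmask]) / mean(dv[!wmask])
  expect_equal(steadyomics:::index_mcclain_rao(dv, wmask), mr_oracle,
               tolerance = 1e-12)
})

test_that("index vote recovers well-separated planted group counts", {
  for (seed in 1:3) {
    x2 <- gauss_groups(list(rep(0, 5), rep(25, 5)), 30, 0.5, seed = seed)
    r2 <- optimal_cluster_number(as_scaled(x2), k_range = 2:6)
    expect_equal(r2$k, 2L)
    x3 <- gauss_groups(list(rep(0, 5), rep(25, 5), rep(-25, 5)), 20, 0.5,
                       seed = seed)
    r3 <- optimal_cluster_number(as_scaled(x3), k_range = 2:6)
    expect_equal(r3$k, 3L)
  }
})

test_that("a single-index vote equals that index's argmax", {
  x <- gauss_groups(list(rep(0, 5), rep(8, 5), rep(30, 5)), 15, 1, seed = 4)
  sil_only <- optimal_cluster_number(as_scaled(x), k_range = 2:6,
                                     indices = "silhouette")
  expect_equal(unname(sil_only$votes["silhouette"]), sil_only$k)
  dm <- as.matrix(dist(x))
  hc <- hclust(dist(x), "ward.D2")
  sil <- sapply(2:6, function(k)
    steadyomics:::index_silhouette(dm, cutree(hc, k)))
  expect_equal(sil_only$k, (2:6)[which.max(sil)])
})

test_that("clustering is deterministic and permutation-invariant", {
  x <- gauss_groups(list(rep(0, 5), rep(6, 5)), 25, 0.8, seed = 9)
  cl <- cluster_genes(as_scaled(x), k = 2)
  # duplicate profiles receive identical labels
  xd <- rbind(x, dup1 = x[1, ], dup2 = x[1, ])
  cld <- cluster_genes(as_scaled(xd), k = 2)
  expect_equal(cld$assignments[["dup1"]], cld$assignments[[rownames(x)[1]]])
  expect_equal(cld$assignments[["dup2"]], cld$assignments[[rownames(x)[1]]])

  perm <- sample(nrow(x))
  clp <- cluster_genes(as_scaled(x[perm, ]), k = 2)
  expect_identical(clp$assignments[names(cl$assignments)], cl$assignments)

  # labels are ordered by descending cluster size
  x_uneq <- gauss_groups(list(rep(0, 5), rep(9, 5)), 10, 0.5, seed = 2)
  x_uneq <- rbind(x_uneq, gauss_groups(list(rep(9, 5)), 25, 0.5, seed = 3))
  rownames(x_uneq) <- sprintf("h%03d", seq_len(nrow(x_uneq)))
  clu <- cluster_genes(as_scaled(x_uneq), k = 2)
  expect_true(sum(clu$assignments == 1) >= sum(clu$assignments == 2))
})

test_that("flat genes concentrate in one cluster on generated growth series", {
  for (seed in 1:3) {
    sim <- simulate_chemostat_dataset(
      simulation_config(n_genes = 600, sigma = 0.1, seed = seed))
    gr <- sim$design[grepl("^GR", sim$design$condition), ]
    sc <- scale_by_growth_intercept(
      em_subset(sim$mrna, samples = gr$sample), condition_design(gr))
    cl <- cluster_genes(sc, k = 3)
    flat <- intersect(sim$truth$params$gene[
      sim$truth$params$class == "ccm_like"], names(cl$assignments))
    tab <- table(cl$assignments[flat])
    expect_gte(max(tab) / length(flat), 0.95)
  }
})
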