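test_that("Shannon index matches its closed form", {
  expect_equal(shannonIndex(c(1, 1, 1, 1)), log(4), tolerance = 1e-12)
  expect_equal(shannonIndex(c(5, 0, 0)), 0, tolerance = 1e-12)
  ## -sum(p log p) with p = (0.25, 0.25, 0.5)
  expect_equal(shannonIndex(c(1, 1, 2)), 1.039721, tolerance = 1e-6)
  expect_error(shannonIndex(c(0, 0, 0)), class = "undefinedDiversityError")
  expect_error(shannonIndex(c(1, -1)), class = "invalidArgumentError")
})

test_that("Shannon is permutation- and scale-invariant", {
  for (s in 1:20) {
    x <- withSeed(s, rexp(12))
    expect_equal(shannonIndex(x), shannonIndex(withSeed(s, sample(x))),
                 tolerance = 1e-12)
    expect_equal(shannonIndex(x), shannonIndex(x * 37.5), tolerance = 1e-12)
  }
})

test_that("Shannon agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  m <- withSeed(3, matrix(rexp(8 * 15), 8, 15))
  expect_equal(unname(shannonIndex(m)),
               unname(vegan::diversity(m, index = "shannon")),
               tolerance = 1e-12)
})

test_that("Hellinger transform normalizes each row", {
  expect_equal(drop(hellingerTransform(matrix(c(4, 0), 1))), c(1, 0))
  expect_equal(drop(hellingerTransform(matrix(c(1, 1), 1))),
               c(1, 1) / sqrt(2))
  m <- withSeed(5, matrix(rexp(6 * 10), 6, 10))
  H <- hellingerTransform(m)
  expect_equal(unname(rowSums(H^2)), rep(1, 6), tolerance = 1e-12)
  expect_error(hellingerTransform(rbind(c(1, 2), c(0, 0))),
               class = "undefinedTransformError")
  skip_if_not_installed("vegan")
  expect_equal(unname(H), unname(vegan::decostand(m, "hellinger")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Bray-Curtis dissimilarity matches its formula", {
  m <- rbind(a = c(2, 1), b = c(1, 1), c = c(2, 1))
  D <- brayCurtis(m)
  expect_equal(D["a", "b"], 1 / 5)       # sum|diff| = 1, sum(sums) = 5
  expect_equal(D["a", "c"], 0)           # identical rows
  expect_equal(brayCurtis(rbind(c(1, 0), c(0, 1)))[1, 2], 1)  # disjoint
  expect_true(isSymmetric(D))
  expect_true(all(D >= 0 & D <= 1))
  expect_error(brayCurtis(rbind(c(0, 0), c(0, 0))),
               class = "undefinedDistanceError")
  skip_if_not_installed("vegan")
  m2 <- withSeed(8, matrix(rexp(7 * 12), 7, 12))
  expect_equal(unname(brayCurtis(m2)[lower.tri(diag(7))]),
               unname(as.vector(vegan::vegdist(m2, "bray"))),
               tolerance = 1e-12)
})

test_that("PCA ordination handles the rank-1 case and stays orthogonal", {
  ## two distinct compositions only: centered Hellinger rows span one axis
  m <- rbind(s1 = c(4, 1), s2 = c(4, 1), s3 = c(1, 4), s4 = c(1, 4))
  ord <- ordinateCommunity(m, "pca_hellinger")
  expect_equal(ncol(ord$scores), 1L)
  expect_equal(ord$variance_explained, 1, tolerance = 1e-12)
  ## orthogonality of scores on a generic table
  m2 <- withSeed(9, matrix(rexp(20 * 30), 20, 30))
  ord2 <- ordinateCommunity(m2, "pca_hellinger", cum_var_target = 1,
                            max_axes = 5)
  G <- crossprod(ord2$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_lt(max(abs(colMeans(ord2$scores))), 1e-9)
  expect_error(ordinateCommunity(rbind(c(1, 2), c(1, 2), c(1, 2))),
               class = "noVariationError")
})

test_that("PCoA reconstructs Bray-Curtis distances for a collinear triple", {
  m <- rbind(s1 = c(1, 0), s2 = c(0.5, 0.5), s3 = c(0, 1))
  D <- brayCurtis(m)
  ord <- ordinateCommunity(m, "pcoa_bray_curtis", cum_var_target = 1)
  rec <- as.matrix(dist(ord$scores[, 1]))
  expect_equal(unname(rec), unname(D), tolerance = 1e-8)
})

test_that("ordination output is deterministic under the sign convention", {
  m <- withSeed(10, matrix(rexp(15 * 25), 15, 25))
  for (method in c("pca_hellinger", "pcoa_bray_curtis"))
    expect_identical(ordinateCommunity(m, method),
                     ordinateCommunity(m, method))
})

test_that("axis retention follows the cumulative-variance rule with a cap", {
  m <- withSeed(11, matrix(rexp(50 * 40), 50, 40))
  ord <- ordinateCommunity(m, "pca_hellinger", cum_var_target = 0.7)
  cumv <- cumsum(ord$eigenvalues / sum(ord$eigenvalues))
  k <- ord$provenance$axes_retained
  expect_lte(k, max(1, floor(50 / 10)))
  expect_true(k == ord$provenance$axis_cap || cumv[k] >= 0.7)
  ord1 <- ordinateCommunity(m, "pca_hellinger", max_axes = 2)
  expect_equal(ncol(ord1$scores), 2L)
})

test_that("condense produces the right block per data flavor", {
  ds <- generateDataset(tinyConfig(seed = 51))
  blk <- condensePredictors(ds)
  expect_s4_class(blk, "PredictorBlock")
  expect_gte(ncol(axisScores(blk)), 1L)
  expect_length(shannonValues(blk), nSamples(ds))
  expect_equal(ncol(geneAbundances(blk)), 0L)
  expect_equal(provenance(blk)$method, "pca_hellinger")
  expect_length(provenance(blk)$variance_explained,
                ncol(axisScores(blk)))
  ## two gene columns: pass-through, no ordination, no functional diversity
  dsG2 <- generateDataset(tinyConfig(seed = 52, data_flavor = "functional_gene",
                                     n_genes = 2))
  blkG2 <- condensePredictors(dsG2)
  expect_equal(ncol(axisScores(blkG2)), 0L)
  expect_equal(ncol(geneAbundances(blkG2)), 2L)
  expect_length(shannonValues(blkG2), 0L)
  ## three gene columns: functional diversity (Shannon over genes) added
  ## (gene columns are driven by latent axes, so three axes are needed)
  dsG3 <- generateDataset(simulationConfig(
    n_samples = 30, n_env = 3, n_latent_axes = 3,
    beta_env = c(0.5, 0.4, 0.3), beta_community = c(0.3, 0.2, 0.1),
    data_flavor = "functional_gene", n_genes = 3, seed = 53))
  blkG3 <- condensePredictors(dsG3)
  expect_length(shannonValues(blkG3), nSamples(dsG3))
  expect_true(provenance(blkG3)$functional_diversity)
})
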