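test_that("whitened scores reproduce brute-force Mahalanobis distances", {
  pan <- make_panel(sep = 3, n = 25, p = 5, seed = 13)
  model <- fit_within_group_pca(pan)
  Winv <- solve(pan$pooled_cov)   # explicit-inverse oracle

  set.seed(99)
  for (i in 1:100) {
    x <- rnorm(5, sd = 4)
    cls <- classify_ancestry(x, model)
    for (g in rownames(pan$group_means)) {
      d <- x - pan$group_means[g, ]
      d2_oracle <- drop(t(d) %*% Winv %*% d)
      expect_lt(abs(cls$distances[[g]] - d2_oracle), 1e-8)
    }
    expect_lt(abs(sum(cls$posteriors) - 1), 1e-9)
    expect_equal(names(which.min(cls$distances)),
                 names(which.max(cls$posteriors)))
  }
})

test_that("with identity pooled covariance, scores are centered measurements", {
  pan <- identity_panel()
  expect_equal(unname(pan$pooled_cov), diag(2), tolerance = 1e-12)
  model <- fit_within_group_pca(pan)
  x <- c(V1 = 2, V2 = -1)
  s <- pca_scores(model, x)
  # whitened D2 to the grand mean equals plain squared Euclidean distance
  expect_equal(sum(s^2), sum((x - pan$grand_mean)^2), tolerance = 1e-10)
  # a group's own transformed mean gives D2 = 0
  cls <- classify_ancestry(pan$group_means["G1", ], model,
                           id = "at-mean") |> suppressWarnings()
  expect_lt(cls$distances[["G1"]], 1e-20)
})

test_that("posterior follows the closed-form equal-prior softmax", {
  # two groups, x at A's mean, D2 to B = 2 ln 3 -> posterior_A = 0.75
  pan <- two_group_1d_panel(delta = sqrt(2 * log(3)))
  model <- fit_within_group_pca(pan)
  cls <- classify_ancestry(c(V1 = 0), model)
  expect_equal(unname(cls$posteriors["A"]), 0.75, tolerance = 1e-10)
  expect_equal(cls$assigned, "A")

  # equidistant point: posteriors 0.5/0.5, tie broken by name with warning
  expect_warning(tie <- classify_ancestry(c(V1 = pan$group_means["B", ] / 2),
                                          model), "tied")
  expect_equal(unname(tie$posteriors), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(tie$assigned, "A")

  # softmax shift invariance: adding a constant to all D2 leaves posteriors
  d2 <- cls$distances
  expect_equal(cranioprofile:::softmax_posteriors(d2),
               cranioprofile:::softmax_posteriors(d2 + 7.3),
               tolerance = 1e-12)
})

test_that("missing measurements are rejected by name, not imputed", {
  pan <- make_panel(sep = 3, n = 20, p = 4, seed = 2)
  model <- fit_within_group_pca(pan)
  x <- pan$group_means["A", ]
  x["M03"] <- NA
  expect_error(classify_ancestry(x, model), "M03")
})

test_that("retained-component control and singular covariance handling", {
  # rank-deficient measurements: duplicate a column
  pan <- make_panel(sep = 3, n = 20, p = 3, seed = 4)
  dup <- lapply(pan$groups, function(g) cbind(g, M04 = g[, 1]))
  pan_dup <- reference_panel(dup)
  expect_error(fit_within_group_pca(pan_dup, retain = 4), "singular")
  model <- fit_within_group_pca(pan_dup)        # default drops null axis
  expect_equal(model$retained_k, 3L)
  expect_equal(fit_within_group_pca(pan, retain = 2)$retained_k, 2L)
})

test_that("pairwise Mahalanobis matrix is symmetric with zero diagonal", {
  pan <- make_panel(sep = 5, n = 20, p = 4, seed = 8)
  model <- fit_within_group_pca(pan)
  set.seed(1)
  X <- matrix(rnorm(21 * 4, sd = 3), 21, 4)
  X[5, ] <- X[2, ]   # duplicated cranium
  D <- pairwise_mahalanobis(X, model)
  expect_equal(dim(D), c(21L, 21L))
  expect_lt(max(abs(D - t(D))), 1e-12)
  expect_true(all(diag(D) == 0))
  expect_lt(D[2, 5], 1e-12)
  expect_error(pairwise_mahalanobis(X[1, , drop = FALSE], model),
               "at least 2")

  # identity covariance: equals the ordinary Euclidean distance matrix
  pan_id <- identity_panel()
  model_id <- fit_within_group_pca(pan_id)
  X2 <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("V1", "V2")))
  expect_equal(unname(pairwise_mahalanobis(X2, model_id)),
               unname(as.matrix(dist(X2))), tolerance = 1e-10)
})

test_that("principal coordinates reconstruct Euclidean-embeddable distances", {
  set.seed(12)
  pts <- matrix(rnorm(20 * 3), 20, 3)
  D <- as.matrix(dist(pts))
  res <- principal_coordinates(D)
  Dhat <- as.matrix(dist(res$coordinates))
  expect_lt(max(abs(Dhat - D)), 1e-8)
  expect_true(all(diff(res$eigenvalues) <= 1e-9))

  # agreement with the classical-scaling reference implementation
  cmds <- stats::cmdscale(D, k = res$retained_k, eig = TRUE)
  expect_equal(res$eigenvalues[seq_len(res$retained_k)],
               cmds$eig[seq_len(res$retained_k)], tolerance = 1e-8)
  expect_equal(abs(res$coordinates), abs(cmds$points), tolerance = 1e-6,
               ignore_attr = TRUE)

  # n = 2: coordinates are +/- d/2 on a single axis
  d <- 3.7
  res2 <- principal_coordinates(matrix(c(0, d, d, 0), 2))
  expect_equal(res2$retained_k, 1L)
  expect_equal(sort(res2$coordinates[, 1]), c(-d / 2, d / 2),
               tolerance = 1e-12)

  expect_error(principal_coordinates(matrix(c(0, 1, 2, 0), 2)),
               "symmetric")
})

test_that("PCoA axis signs are deterministic and PC1 sign-separates two clusters", {
  pan <- make_panel(sep = 8, n = 20, p = 4, seed = 31)
  model <- fit_within_group_pca(pan)
  set.seed(55)
  X <- rbind(
    MASS::mvrnorm(10, pan$group_means["A", ], diag(4)),
    MASS::mvrnorm(11, pan$group_means["B", ], diag(4)))
  D <- pairwise_mahalanobis(X, model)
  res <- principal_coordinates(D)
  # largest-magnitude entry of each axis is positive
  for (j in seq_len(res$retained_k)) {
    expect_gt(res$coordinates[which.max(abs(res$coordinates[, j])), j], 0)
  }
  pc1 <- res$coordinates[, 1]
  labels <- rep(c("A", "B"), c(10, 11))
  expect_true(all(sign(pc1[labels == "A"]) !=
                    sign(pc1[labels == "B"][1])))
})

test_that("pooled t-test on PC1 scores matches hand-computed oracle", {
  # {1,2,3} vs {4,5,6}: pooled sd = 1, t = -3/sqrt(2/3) = -3.6742, df = 4
  res <- pc1_group_ttest(c(1, 2, 3, 4, 5, 6),
                         c("a", "a", "a", "b", "b", "b"))
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(res$df, 4)

  # identical groups: t = 0, p = 1
  res0 <- pc1_group_ttest(c(1, 2, 3, 1, 2, 3),
                          rep(c("a", "b"), each = 3))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  # pooling convention: df = n1 + n2 - 2 (10 vs 8 gives 16)
  set.seed(3)
  expect_equal(pc1_group_ttest(rnorm(18), rep(c("a", "b"), c(10, 8)))$df, 16)

  expect_error(pc1_group_ttest(c(1, 2, 3), c("a", "a", "b")),
               "at least 2")
})

test_that("metric sex discriminant behaves like a pooled-covariance LDA", {
  set.seed(77)
  n <- 120
  mu_m <- c(GLS = 16, ZYB = 135, MDH = 32)
  mu_f <- c(GLS = 11, ZYB = 125, MDH = 27)
  S <- diag(c(2, 16, 4))
  X <- rbind(MASS::mvrnorm(n, mu_m, S), MASS::mvrnorm(n, mu_f, S))
  colnames(X) <- names(mu_m)
  sex <- rep(c("M", "F"), each = n)
  disc <- train_sex_discriminant(X, sex)

  # classifies its own training means correctly with posterior > 0.5
  cm <- classify_sex_metric(disc$class_means["M", ], disc)
  cf <- classify_sex_metric(disc$class_means["F", ], disc)
  expect_equal(cm$category, "M")
  expect_equal(cf$category, "F")
  expect_gt(cm$posterior, 0.5)

  # agreement with the standard LDA implementation on the training set
  ld <- MASS::lda(X, grouping = sex)
  pred <- predict(ld)$class
  ours <- vapply(seq_len(nrow(X)), function(i)
    if (classify_sex_metric(X[i, ], disc)$p_male > 0.5) "M" else "F", "")
  expect_gt(mean(ours == as.character(pred)), 0.995)

  # strongly dimorphic training sample: accuracy >= 0.98
  expect_gt(mean(ours == sex), 0.98)

  expect_error(train_sex_discriminant(X, rep("M", 2 * n)), "both sexes")
  expect_error(classify_sex_metric(c(GLS = 15, ZYB = 130), disc), "MDH")
})

test_that("mirror-image classes give a midpoint threshold and leaning calls near it", {
  set.seed(5)
  base <- MASS::mvrnorm(200, c(0, 0), diag(2))
  X <- rbind(sweep(base, 2, c(2, 0), "+"), sweep(base, 2, c(-2, 0), "+"))
  colnames(X) <- c("GLS", "ZYB")
  sex <- rep(c("M", "F"), each = 200)
  disc <- train_sex_discriminant(X, sex, variables = c("GLS", "ZYB"))

  # mirror symmetry puts the decision boundary at the class-mean midpoint
  mid <- (disc$class_means["M", ] + disc$class_means["F", ]) / 2
  boundary <- classify_sex_metric(mid, disc)
  expect_equal(boundary$p_male, 0.5, tolerance = 1e-9)
  expect_equal(boundary$posterior, 0.5, tolerance = 1e-9)
  expect_true(boundary$category %in% c("M/F", "F/M"))

  # posterior within the margin of 0.5 gives a leaning two-letter call
  eps <- uniroot(function(e) {
    classify_sex_metric(mid + c(e, 0), disc)$p_male - 0.52
  }, c(0, 2))$root
  near <- classify_sex_metric(mid + c(eps, 0), disc)
  expect_equal(near$category, "M/F")
  expect_equal(near$posterior, 0.52, tolerance = 1e-3)
  strict <- classify_sex_metric(mid + c(eps, 0), disc,
                                ambiguity_margin = 0.01)
  expect_equal(strict$category, "M")
})

test_that("classifier accuracy approaches 1 with separation and 1/k without", {
  # 10-sigma separation: essentially no misclassification
  pan <- make_panel(sep = 10, n = 30, p = 4, seed = 17)
  model <- fit_within_group_pca(pan)
  set.seed(18)
  test_x <- do.call(rbind, lapply(c("A", "B", "C"), function(g)
    MASS::mvrnorm(100, pan$group_means[g, ], diag(4))))
  truth <- rep(c("A", "B", "C"), each = 100)
  assigned <- classify_crania(test_x, model)$assigned
  expect_gte(mean(assigned == truth), 0.99)

  # zero separation: accuracy near chance (1/3)
  pan0 <- make_panel(sep = 0, n = 30, p = 4, seed = 19)
  model0 <- fit_within_group_pca(pan0)
  set.seed(20)
  test0 <- MASS::mvrnorm(300, rep(0, 4), diag(4))
  a0 <- classify_crania(test0, model0)$assigned
  expect_lt(max(abs(table(a0) / 300 - 1 / 3)), 0.15)
})
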