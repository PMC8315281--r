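test_that("disease eligibility applies the minimum-known-microbes floor", {
  cat <- as_catalog(data.frame(
    microbe = c(sprintf("m%d", 1:5), sprintf("m%d", 1:4)),
    disease = rep(c("dFive", "dFour"), c(5, 4))))
  expect_equal(eligible_diseases(cat, 5), "dFive")
  # counting oracle on a random catalog
  cat2 <- random_catalog(30, 8, p = 0.25, seed = 13)
  counts <- table(cat2$disease)
  expect_equal(eligible_diseases(cat2, 4),
               sort(names(counts)[counts >= 4]))
})

test_that("fold plans are balanced, disjoint, exhaustive and seed-deterministic", {
  microbes <- sprintf("m%02d", 1:23)
  folds <- make_folds(microbes, "kfold", k = 5, seed = 7)
  expect_equal(sort(lengths(folds), decreasing = TRUE), c(5, 5, 5, 4, 4))
  expect_setequal(unlist(folds), microbes)
  expect_equal(sum(lengths(folds)), 23) # disjoint: sizes add up
  expect_identical(folds, make_folds(microbes, "kfold", k = 5, seed = 7))
  expect_false(identical(folds, make_folds(microbes, "kfold", k = 5, seed = 8)))

  loo <- make_folds(sprintf("m%d", 1:7), "loocv")
  expect_equal(lengths(loo), rep(1L, 7))

  expect_error(make_folds(c("a", "b"), "kfold", k = 5), "at least 5")
  expect_error(make_folds("a", "loocv"), "at least 2")
})

test_that("AUC equals brute-force pair counting with half-credit ties", {
  got <- roc_auc(c(0.9, 0.4), c(0.8, 0.2, 0.1))
  expect_equal(got$auc, 5 / 6, tolerance = 1e-12)
  expect_equal(roc_auc(rep(0.3, 4), rep(0.3, 6))$auc, 0.5)

  withr::local_seed(99)
  for (i in 1:1000) {
    n_pos <- sample(1:8, 1); n_neg <- sample(1:10, 1)
    # coarse grid forces frequent ties
    pos <- sample(seq(0, 1, 0.25), n_pos, replace = TRUE)
    neg <- sample(seq(0, 1, 0.25), n_neg, replace = TRUE)
    expect_equal(roc_auc(pos, neg)$auc, auc_bruteforce(pos, neg),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(numeric(0), 1), "at least one")
})

test_that("ROC curves are monotone from (0,0) to (1,1) and integrate to the AUC", {
  withr::local_seed(3)
  for (i in 1:50) {
    pos <- round(stats::runif(sample(2:10, 1)), 2)
    neg <- round(stats::runif(sample(2:15, 1)), 2)
    got <- roc_auc(pos, neg)
    roc <- got$roc
    expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(trapezoid_area(roc), got$auc, tolerance = 1e-12)
  }
})

test_that("no held-out link leaks into the kernels, operator or seed of its fold", {
  sim <- simulate_catalog(n_microbes = 40, n_diseases = 8, n_blocks = 2,
                          p_in = 0.4, p_out = 0.05, seed = 5)
  cat_full <- sim$catalog
  dis <- eligible_diseases(cat_full)[1]
  known <- sort(cat_full$microbe[cat_full$disease == dis])
  # held-out microbe chosen with another association so the entity indices
  # are identical with and without the link in the input file
  degs <- table(cat_full$microbe)
  held <- known[degs[known] >= 2][1]
  training <- setdiff(known, held)

  artifacts <- function(catalog, mask) {
    B <- to_profile_matrix(catalog)
    if (mask) B[held, dis] <- 0
    KM <- gip_kernel(B)
    KD <- gip_kernel(t(B))
    SD <- fuse_disease_similarity(KD, sim$spwd)
    T_op <- compile_transition(build_network(KM, SD, B, 0.5))
    p0 <- make_seed(T_op, dis, training)
    rlang::hash(list(B, KM, KD, SD, unclass(T_op), p0))
  }
  cat_removed <- as_catalog(
    dplyr::filter(tibble::as_tibble(cat_full),
                  !(.data$microbe == held & .data$disease == dis)))
  expect_identical(artifacts(cat_full, mask = TRUE),
                   artifacts(cat_removed, mask = FALSE))
})

test_that("cross-validation recovers planted structure and reports coherent pools", {
  sim <- simulate_catalog(n_microbes = 60, n_diseases = 10, n_blocks = 2,
                          p_in = 0.5, p_out = 0.02, seed = 11)
  res <- mdrank_cv(sim$catalog, spwd = sim$spwd, scheme = "loocv", seed = 1)
  expect_s3_class(res, "mdrank_cv")
  expect_equal(res$disease, eligible_diseases(sim$catalog))
  expect_true(all(res$auc > 0.5)) # planted signal beats the null everywhere
  counts <- table(sim$catalog$disease)
  expect_equal(res$n_pos, as.integer(counts[res$disease]))
  n_m <- length(unique(sim$catalog$microbe))
  expect_equal(res$n_neg, res$n_pos * (n_m - as.integer(counts[res$disease])))
})

test_that("repeated k-fold averages per-repeat AUCs and is seed-deterministic", {
  sim <- simulate_catalog(n_microbes = 50, n_diseases = 6, n_blocks = 2,
                          p_in = 0.5, p_out = 0.02, seed = 19)
  res <- mdrank_cv(sim$catalog, spwd = sim$spwd, scheme = "kfold",
                   k = 3, repeats = 3, seed = 5)
  expect_equal(res$auc, vapply(res$per_repeat_aucs, mean, 1))
  expect_equal(res$repeats, rep(3L, nrow(res)))
  res2 <- mdrank_cv(sim$catalog, spwd = sim$spwd, scheme = "kfold",
                    k = 3, repeats = 3, seed = 5)
  expect_identical(res$auc, res2$auc)
})

test_that("cv tidiers and glance expose per-disease and summary views", {
  sim <- simulate_catalog(n_microbes = 40, n_diseases = 6, n_blocks = 2,
                          p_in = 0.5, p_out = 0.02, seed = 23)
  res <- mdrank_cv(sim$catalog, spwd = sim$spwd, scheme = "kfold",
                   k = 3, repeats = 2, seed = 2)
  td <- tidy(res, per_repeat = TRUE)
  expect_equal(nrow(td), 2 * nrow(res))
  expect_true(all(c("auc", "repeat_index") %in% names(td)))
  g <- glance(res)
  expect_equal(g$mean_auc, mean(res$auc))
  expect_equal(g$n_diseases, nrow(res))
  expect_s3_class(autoplot(res), "ggplot")
})
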