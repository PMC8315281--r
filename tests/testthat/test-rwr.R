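test_that("seed vectors split mass between the disease and its training microbes", {
  net <- random_network(4, 2, seed = 1)
  T_op <- compile_transition(net)
  p0 <- make_seed(T_op, "d001", c("m001", "m002"), eta_seed = 0.5)
  expect_equal(unname(p0[c("m001", "m002", "d001")]), c(0.25, 0.25, 0.5))
  expect_equal(sum(p0), 1)

  expect_equal(unname(make_seed(T_op, "d002")["d002"]), 1)
  p1 <- make_seed(T_op, "d001", c("m001", "m003"), eta_seed = 1)
  expect_equal(unname(p1["d001"]), 1)
  expect_equal(sum(p1 != 0), 1)

  expect_error(make_seed(T_op, "nope"), "unknown disease")
  expect_error(make_seed(T_op, "d001", "m999"), "unknown training microbe")
  expect_error(make_seed(T_op, "d001", eta_seed = 2), "eta_seed")
})

test_that("the walk is dominated by the seed as the restart probability approaches 1", {
  T_op <- random_transition(10, seed = 4)
  p0 <- c(1, rep(0, 9))
  names(p0) <- rownames(T_op)
  steady <- propagate(T_op, p0, r = 1 - 1e-12)
  expect_equal(as.numeric(steady), as.numeric(p0), tolerance = 1e-9)
})

test_that("the 2-node swap chain converges to the closed-form steady state", {
  ids <- c("a", "b")
  Tc <- structure(matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(ids, ids)),
                  class = "mdrank_transition", n_microbes = 2L,
                  n_diseases = 0L, isolated = c(FALSE, FALSE))
  p0 <- c(a = 1, b = 0)
  steady <- propagate(Tc, p0, r = 0.1)
  expect_equal(as.numeric(steady), c(10 / 19, 9 / 19), tolerance = 1e-9)
  expect_equal(unname(solve_exact(Tc, p0, r = 0.1)), c(10 / 19, 9 / 19),
               tolerance = 1e-12)
})

test_that("iteration matches the exact linear solve on random operators", {
  for (i in 1:50) {
    n <- sample(5:30, 1)
    T_op <- random_transition(n, seed = 100 + i)
    p0 <- withr::with_seed(200 + i, {
      v <- stats::runif(n); v / sum(v)
    })
    names(p0) <- rownames(T_op)
    it <- propagate(T_op, p0, r = 0.1)
    ex <- solve_exact(T_op, p0, r = 0.1)
    expect_lt(sum(abs(it - ex)), 1e-8)
    expect_equal(sum(it), 1, tolerance = 1e-10)
  }
})

test_that("every iterate conserves probability mass and the residual contracts geometrically", {
  T_op <- random_transition(15, seed = 9)
  p0 <- rep(1 / 15, 15); names(p0) <- rownames(T_op)
  r <- 0.1
  p <- p0
  prev_res <- Inf
  for (t in 1:60) {
    p_next <- as.vector((1 - r) * (unclass(T_op) %*% p)) + r * p0
    expect_equal(sum(p_next), 1, tolerance = 1e-12)
    res <- sum(abs(p_next - p))
    expect_lte(res, 2 * (1 - r)^t + 1e-12)
    if (is.finite(prev_res) && prev_res > 0) {
      expect_lte(res, prev_res * (1 - r) + 1e-12)
    }
    prev_res <- res
    p <- p_next
  }
  # with r = 0.1 the default tolerance is reached well inside ~225 steps
  expect_lte(attr(propagate(T_op, p0, r = 0.1), "iterations"), 250)
})

test_that("non-convergence raises instead of returning silently", {
  T_op <- random_transition(8, seed = 2)
  p0 <- c(1, rep(0, 7)); names(p0) <- rownames(T_op)
  expect_error(propagate(T_op, p0, r = 0.1, max_iter = 2L), "converge")
  expect_error(propagate(T_op, p0, r = 0), "\\(0, 1\\)")
})

test_that("the exact solve at T = identity returns the seed", {
  T_id <- structure(diag(6), class = "mdrank_transition", n_microbes = 6L,
                    n_diseases = 0L, isolated = rep(FALSE, 6))
  dimnames(T_id) <- list(letters[1:6], letters[1:6])
  p0 <- c(0.5, 0.5, 0, 0, 0, 0); names(p0) <- letters[1:6]
  expect_equal(solve_exact(T_id, p0, r = 0.5), p0)
})

test_that("candidate ranking drops training microbes and breaks ties by id", {
  net <- random_network(4, 2, seed = 6)
  T_op <- compile_transition(net)
  steady <- c(m001 = 0.1, m002 = 0.3, m003 = 0.3, m004 = 0.05,
              d001 = 0.15, d002 = 0.1)
  rk <- rank_candidates(steady, T_op)
  expect_equal(rk$microbe, c("m002", "m003", "m001", "m004"))
  expect_equal(rk$rank, 1:4)
  rk2 <- rank_candidates(steady, T_op, training_microbes = "m002")
  expect_false("m002" %in% rk2$microbe)
  expect_equal(rk2$rank, 1:3)
})

test_that("microbes linked to the seed disease get strictly positive steady mass", {
  cat <- random_catalog(12, 5, p = 0.3, seed = 21)
  dis <- eligible_diseases(cat, min_known = 2)[1]
  rk <- rank_microbes(cat, dis, eta_seed = 1, include_known = TRUE)
  linked <- cat$microbe[cat$disease == dis]
  expect_true(all(rk$score[rk$microbe %in% linked] > 0))
  # known microbes flagged and excluded by default
  expect_setequal(rk$microbe[rk$known == 1], linked)
  rk_def <- rank_microbes(cat, dis)
  expect_false(any(linked %in% rk_def$microbe))
})
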