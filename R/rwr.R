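#' Build the initial probability vector for a query disease
#'
#' Places mass `eta_seed` on the query disease node and splits the remaining
#' `1 - eta_seed` uniformly over the disease's training microbes. With an
#' empty training set (or `eta_seed = 1`) all mass sits on the disease node.
#'
#' @param T_op An `mdrank_transition` (supplies the node order).
#' @param disease Query disease id.
#' @param training_microbes Character vector of microbe ids used as seeds
#'   alongside the disease; may be empty.
#' @param eta_seed Fraction of seed mass on the disease node, in \[0, 1\];
#'   default 0.5 mirrors the even layer-jump split.
#' @return Named nonnegative vector over `[microbes; diseases]` summing to 1.
#' @export
make_seed <- function(T_op, disease, training_microbes = character(),
                      eta_seed = 0.5) {
  stopifnot(inherits(T_op, "mdrank_transition"))
  if (!is.numeric(eta_seed) || eta_seed < 0 || eta_seed > 1) {
    stop("eta_seed must lie in [0, 1]", call. = FALSE)
  }
  ids <- rownames(T_op)
  n_m <- attr(T_op, "n_microbes")
  if (!disease %in% ids[-seq_len(n_m)]) {
    stop("unknown disease id: ", disease, call. = FALSE)
  }
  training_microbes <- unique(training_microbes)
  bad <- setdiff(training_microbes, ids[seq_len(n_m)])
  if (length(bad) > 0L) {
    stop("unknown training microbe id(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p0 <- stats::setNames(numeric(length(ids)), ids)
  if (length(training_microbes) == 0L) {
    p0[disease] <- 1
  } else {
    p0[disease] <- eta_seed
    p0[training_microbes] <- (1 - eta_seed) / length(training_microbes)
  }
  p0
}

#' Random walk with restart to steady state
#'
#' Iterates `p_{t+1} = (1 - r) T p_t + r p_0` until the L1 difference between
#' successive iterates falls below `tol`. With a column-stochastic operator
#' the residual contracts at least geometrically with ratio `1 - r`, so the
#' default tolerance is reached in a few hundred steps.
#'
#' @param T_op Column-stochastic `mdrank_transition` (or plain matrix).
#' @param p0 Initial probability vector (sums to 1).
#' @param r Restart probability in (0, 1); default 0.1, the best-performing
#'   value for this method.
#' @param tol L1 convergence threshold; default 1e-10.
#' @param max_iter Iteration cap; exceeding it is an error, not a silent
#'   return.
#' @return Steady-state probability vector with attribute `iterations`.
#' @export
propagate <- function(T_op, p0, r = 0.1, tol = 1e-10, max_iter = 10000L) {
  if (!is.numeric(r) || r <= 0 || r >= 1) {
    stop("restart probability r must lie in (0, 1)", call. = FALSE)
  }
  Tm <- unclass(T_op)
  stopifnot(nrow(Tm) == length(p0))
  p <- p0
  for (it in seq_len(max_iter)) {
    p_next <- as.vector((1 - r) * (Tm %*% p)) + r * p0
    res <- sum(abs(p_next - p))
    p <- p_next
    if (res < tol) {
      names(p) <- names(p0)
      attr(p, "iterations") <- it
      return(p)
    }
  }
  stop(sprintf("random walk did not converge in %d iterations (L1 residual %.3e)",
               max_iter, res), call. = FALSE)
}

#' Exact steady state by linear solve
#'
#' Direct solution of the restart fixed point
#' `p = r (I - (1 - r) T)^{-1} p0`; used as an oracle against [propagate()].
#'
#' @inheritParams propagate
#' @return Exact steady-state probability vector.
#' @export
solve_exact <- function(T_op, p0, r = 0.1) {
  if (!is.numeric(r) || r <= 0 || r >= 1) {
    stop("restart probability r must lie in (0, 1)", call. = FALSE)
  }
  Tm <- unclass(T_op)
  n <- nrow(Tm)
  A <- diag(n) - (1 - r) * Tm
  p <- tryCatch(solve(A, r * p0),
                error = function(e) stop("restart system is singular: ",
                                         conditionMessage(e), call. = FALSE))
  stats::setNames(as.vector(p), names(p0))
}

#' Rank candidate microbes for a query disease
#'
#' Extracts the microbe-layer steady probabilities, drops the training
#' microbes, and ranks the rest by decreasing score with deterministic
#' lexicographic tie-breaking.
#'
#' @param steady Steady-state vector from [propagate()] or [solve_exact()].
#' @param T_op The `mdrank_transition` the walk was run on.
#' @param training_microbes Microbe ids to exclude from the ranking.
#' @param exclude_isolated Drop fully isolated microbes (default `TRUE`);
#'   when kept they appear at the bottom with score 0.
#' @return A tibble `rank`, `microbe`, `score`, classed `mdrank_ranking`.
#' @export
rank_candidates <- function(steady, T_op, training_microbes = character(),
                            exclude_isolated = TRUE) {
  stopifnot(inherits(T_op, "mdrank_transition"))
  n_m <- attr(T_op, "n_microbes")
  ids <- rownames(T_op)[seq_len(n_m)]
  iso <- attr(T_op, "isolated")[seq_len(n_m)]
  keep <- !ids %in% training_microbes
  if (exclude_isolated) keep <- keep & !iso
  out <- tibble::tibble(microbe = ids[keep],
                        score = as.numeric(steady[seq_len(n_m)][keep])) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$microbe) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  class(out) <- c("mdrank_ranking", class(out))
  out
}

#' One-call prioritization of microbes for a disease
#'
#' Convenience pipeline: profile matrix, GIP kernels, similarity fusion,
#' network assembly, transition compilation, restart walk, ranking. Known
#' microbes of the query disease act as training seeds and are excluded from
#' the returned ranking unless `include_known` is set.
#'
#' @param catalog An `mdrank_catalog` (or data frame with `microbe`,
#'   `disease` columns).
#' @param disease Query disease id.
#' @param spwd Optional semantic disease similarity matrix (see
#'   [read_spwd()]).
#' @param r,lambda,eta_seed,gamma_prime,tol,max_iter Method parameters; see
#'   [propagate()], [build_network()], [make_seed()], [gip_kernel()].
#' @param include_known Keep the disease's known microbes in the output with
#'   a `known` indicator column.
#' @return An `mdrank_ranking` tibble.
#' @export
rank_microbes <- function(catalog, disease, spwd = NULL, r = 0.1,
                          lambda = 0.5, eta_seed = 0.5, gamma_prime = 1,
                          tol = 1e-10, max_iter = 10000L,
                          include_known = FALSE) {
  catalog <- as_catalog(catalog)
  B <- to_profile_matrix(catalog)
  KM <- gip_kernel(B, gamma_prime)
  KD <- gip_kernel(t(B), gamma_prime)
  SD <- if (is.null(spwd)) KD / 2 else fuse_disease_similarity(KD, spwd)
  net <- build_network(KM, SD, B, lambda)
  T_op <- compile_transition(net)
  known <- catalog$microbe[catalog$disease == disease]
  p0 <- make_seed(T_op, disease, known, eta_seed)
  steady <- propagate(T_op, p0, r = r, tol = tol, max_iter = max_iter)
  training <- if (include_known) character() else known
  out <- rank_candidates(steady, T_op, training_microbes = training)
  if (include_known) {
    out$known <- as.integer(out$microbe %in% known)
  }
  attr(out, "disease") <- disease
  out
}

#' @export
print.mdrank_ranking <- function(x, ...) {
  d <- attr(x, "disease")
  if (!is.null(d)) cat(sprintf("# microbe ranking for disease %s\n", d))
  NextMethod()
}
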