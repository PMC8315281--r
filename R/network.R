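#' Assemble the composite two-layer heterogeneous network
#'
#' Stores the three building blocks of the composite weighted network: the
#' microbe-microbe similarity `M`, the disease-disease similarity `D`, the
#' binary microbe-disease association matrix `B`, and the layer-jump
#' probability `lambda`. Similarity diagonals are zeroed (no self-loops): GIP
#' self-similarity is 1 by construction and keeping it would let the walker
#' idle on its own node.
#'
#' @param M Microbe similarity matrix (`n_m x n_m`).
#' @param D Disease similarity matrix (`n_d x n_d`).
#' @param B Binary association matrix (`n_m x n_d`), microbes in rows.
#' @param lambda Probability of the walker jumping between layers, in
#'   \[0, 1\]; 0.5 is the value at which the method performs best.
#' @return An `mdrank_network` list with elements `M`, `D`, `B`, `lambda`.
#' @export
build_network <- function(M, D, B, lambda = 0.5) {
  M <- as.matrix(M); D <- as.matrix(D); B <- as.matrix(B)
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a scalar in [0, 1]", call. = FALSE)
  }
  if (nrow(M) != ncol(M)) stop("block M must be square", call. = FALSE)
  if (nrow(D) != ncol(D)) stop("block D must be square", call. = FALSE)
  if (nrow(B) != nrow(M)) {
    stop("block B has ", nrow(B), " rows but M is ", nrow(M), "x", ncol(M),
         call. = FALSE)
  }
  if (ncol(B) != nrow(D)) {
    stop("block B has ", ncol(B), " columns but D is ", nrow(D), "x", ncol(D),
         call. = FALSE)
  }
  diag(M) <- 0
  diag(D) <- 0
  structure(list(M = M, D = D, B = B, lambda = lambda),
            class = "mdrank_network")
}

#' Compile the column-stochastic transition operator
#'
#' Turns the composite network into the transition operator used by the
#' restart iteration. For a node with at least one cross-layer association,
#' probability mass `lambda` leaves its layer (split proportionally to its
#' association row) and mass `1 - lambda` stays within the layer (split
#' proportionally to its similarity row); a node with no cross-layer edge
#' keeps full mass within its layer. Dangling cases: a node with cross edges
#' but no within-layer similarity sends all its mass across regardless of
#' `lambda`; a fully isolated node gets a self-loop. The per-node
#' normalizations are row-wise; the returned operator is the transpose, so
#' that entry `[i, j]` is the probability of moving from node j to node i and
#' every column sums to 1.
#'
#' @param net An `mdrank_network` from [build_network()].
#' @return An `mdrank_transition` object: the `(n_m + n_d)` square
#'   column-stochastic matrix with node order `[microbes; diseases]`, plus
#'   attributes `n_microbes`, `n_diseases`, `isolated` (logical per node).
#' @export
compile_transition <- function(net) {
  stopifnot(inherits(net, "mdrank_network"))
  M <- net$M; D <- net$D; B <- net$B; lam <- net$lambda
  n_m <- nrow(M); n_d <- nrow(D)

  row_block <- function(sim, cross, lam) {
    # sim: within-layer similarity (diag 0); cross: this layer's association
    # rows into the other layer. Returns the row-normalized [intra | cross]
    # blocks plus a flag for fully isolated nodes.
    intra_sum <- rowSums(sim)
    cross_sum <- rowSums(cross)
    has_intra <- intra_sum > 0
    has_cross <- cross_sum > 0
    intra_w <- ifelse(has_cross & has_intra, 1 - lam,
                      ifelse(has_intra, 1, 0))
    cross_w <- ifelse(has_cross & has_intra, lam,
                      ifelse(has_cross, 1, 0))
    intra <- sim * ifelse(has_intra, intra_w / ifelse(has_intra, intra_sum, 1), 0)
    crossm <- cross * ifelse(has_cross, cross_w / ifelse(has_cross, cross_sum, 1), 0)
    isolated <- !has_intra & !has_cross
    list(intra = intra, cross = crossm, isolated = isolated)
  }

  mb <- row_block(M, B, lam)
  db <- row_block(D, t(B), lam)

  W <- rbind(cbind(mb$intra, mb$cross),
             cbind(db$cross, db$intra))
  isolated <- c(mb$isolated, db$isolated)
  diag(W) <- replace(diag(W), isolated, 1)
  ids <- c(rownames(M), rownames(D))
  dimnames(W) <- list(ids, ids)

  structure(t(W), class = "mdrank_transition",
            n_microbes = n_m, n_diseases = n_d, isolated = isolated)
}

#' Export a transition operator as a sparse edge list
#'
#' @param T_op An `mdrank_transition`.
#' @param path Output TSV path with columns `from_id`, `to_id`, `prob`.
#' @return A tibble of the written edges, invisibly.
#' @export
write_transition <- function(T_op, path) {
  nz <- which(T_op != 0, arr.ind = TRUE)
  ids <- rownames(T_op)
  out <- tibble::tibble(
    from_id = ids[nz[, "col"]],
    to_id = ids[nz[, "row"]],
    prob = T_op[nz]
  ) |>
    dplyr::arrange(.data$from_id, .data$to_id)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}
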