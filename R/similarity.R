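#' Gaussian interaction profile kernel similarity
#'
#' Computes the GIP kernel over the rows of a binary interaction profile
#' matrix: `S[i, j] = exp(-gamma * ||IP(i) - IP(j)||^2)`, where the bandwidth
#' `gamma = gamma_prime / mean_k ||IP(k)||^2` is normalized by the mean
#' squared profile norm. For disease similarity, pass the transposed profile
#' matrix so diseases are rows.
#'
#' @param profiles Numeric matrix, one entity per row (binary interaction
#'   profiles); row names are the entity ids.
#' @param gamma_prime Positive raw bandwidth; the field's conventional default
#'   is 1.
#' @return A symmetric similarity matrix with unit diagonal and entries in
#'   \[0, 1\], carrying the entity ids as dimnames.
#' @examples
#' B <- rbind(m1 = c(1, 0), m2 = c(0, 1))
#' gip_kernel(B) # off-diagonal exp(-2)
#' @export
gip_kernel <- function(profiles, gamma_prime = 1) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) {
    stop("gip_kernel needs at least two entities", call. = FALSE)
  }
  if (!is.numeric(gamma_prime) || length(gamma_prime) != 1L ||
      !is.finite(gamma_prime) || gamma_prime <= 0) {
    stop("gamma_prime must be a positive scalar", call. = FALSE)
  }
  sq <- rowSums(profiles^2)
  mean_sq <- mean(sq)
  if (mean_sq == 0) {
    stop("kernel bandwidth undefined: all interaction profiles are all-zero",
         call. = FALSE)
  }
  gamma <- gamma_prime / mean_sq
  # ||a-b||^2 = ||a||^2 + ||b||^2 - 2 a.b; clamp tiny negatives from rounding
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0
  S <- exp(-gamma * d2)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(rownames(profiles), rownames(profiles))
  S
}

#' Fuse disease GIP similarity with an external semantic similarity
#'
#' The fused disease similarity is the unweighted arithmetic mean of the GIP
#' kernel and the external semantic score for each disease pair:
#' `SD = (KD + SPWD) / 2`. Pairs absent from the supplied semantic matrix
#' contribute a semantic score of 0. When no semantic matrix is given at all,
#' the global factor 1/2 is kept (`SD = KD / 2`) and a warning is issued; the
#' constant factor cancels under the row normalization of the transition
#' operator, so rankings are unaffected.
#'
#' @param KD Disease GIP similarity matrix (from [gip_kernel()] on transposed
#'   profiles), with disease ids as dimnames.
#' @param SPWD Optional symmetric semantic disease similarity matrix with
#'   entries in \[0, 1\] and disease ids as dimnames; may cover only a subset
#'   of the catalog's diseases.
#' @return Fused symmetric similarity matrix over the diseases of `KD`.
#' @export
fuse_disease_similarity <- function(KD, SPWD = NULL) {
  KD <- as.matrix(KD)
  ids <- rownames(KD)
  if (is.null(SPWD)) {
    warning("no semantic disease similarity supplied; using SD = KD / 2",
            call. = FALSE)
    return(KD / 2)
  }
  SPWD <- as.matrix(SPWD)
  if (is.null(rownames(SPWD)) || is.null(colnames(SPWD))) {
    stop("SPWD matrix must carry disease ids as dimnames", call. = FALSE)
  }
  if (nrow(SPWD) != ncol(SPWD) ||
      max(abs(SPWD - t(SPWD))) > 1e-12) {
    stop("SPWD matrix must be symmetric (tolerance 1e-12)", call. = FALSE)
  }
  if (any(SPWD < 0) || any(SPWD > 1)) {
    stop("SPWD entries must lie in [0, 1]", call. = FALSE)
  }
  full <- matrix(0, nrow(KD), ncol(KD), dimnames = dimnames(KD))
  shared <- intersect(ids, rownames(SPWD))
  full[shared, shared] <- SPWD[shared, shared]
  (KD + full) / 2
}

#' Read a semantic disease similarity matrix
#'
#' Accepts either a square TSV matrix (first column holding disease ids, the
#' header naming them again) or a 3-column long form with header
#' `disease_a`, `disease_b`, `score`. Long form is symmetrized; the diagonal
#' is set to 1 for every disease mentioned.
#'
#' @param path TSV path.
#' @return Symmetric numeric matrix with disease-id dimnames.
#' @export
read_spwd <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (all(c("disease_a", "disease_b", "score") %in% names(raw))) {
    ids <- stringr::str_sort(unique(c(raw$disease_a, raw$disease_b)),
                             locale = "en")
    S <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    S[cbind(match(raw$disease_a, ids), match(raw$disease_b, ids))] <- raw$score
    S[cbind(match(raw$disease_b, ids), match(raw$disease_a, ids))] <- raw$score
    diag(S) <- 1
    return(S)
  }
  ids <- as.character(raw[[1]])
  S <- as.matrix(raw[, -1, drop = FALSE])
  mode(S) <- "numeric"
  rownames(S) <- ids
  if (!identical(sort(ids), sort(colnames(S)))) {
    stop("square SPWD file must have matching row and column disease ids",
         call. = FALSE)
  }
  S[, ids, drop = FALSE]
}

#' Write a similarity matrix as a square TSV
#'
#' @param S Similarity matrix with id dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(S, path) {
  df <- tibble::as_tibble(as.data.frame(S), rownames = "id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
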