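#' Diseases eligible for cross-validation
#'
#' @param catalog An `mdrank_catalog`.
#' @param min_known Minimum number of known associated microbes; the
#'   evaluation keeps diseases with at least this many (default 5).
#' @return Sorted character vector of disease ids.
#' @export
eligible_diseases <- function(catalog, min_known = 5L) {
  counts <- dplyr::count(tibble::as_tibble(catalog), .data$disease)
  stringr::str_sort(counts$disease[counts$n >= min_known], locale = "en")
}

#' Split a disease's known microbes into cross-validation folds
#'
#' LOOCV yields one singleton fold per known microbe (in lexicographic
#' order). k-fold applies a seeded shuffle followed by a round-robin split,
#' so fold sizes differ by at most one and the plan is reproducible from the
#' seed.
#'
#' @param known_microbes Character vector of the disease's known microbes.
#' @param scheme `"loocv"` or `"kfold"`.
#' @param k Number of folds for `"kfold"` (default 5).
#' @param seed Integer seed for the shuffle (ignored for LOOCV).
#' @return List of disjoint character vectors partitioning `known_microbes`.
#' @export
make_folds <- function(known_microbes, scheme = c("loocv", "kfold"), k = 5L,
                       seed = 1L) {
  scheme <- match.arg(scheme)
  known_microbes <- stringr::str_sort(unique(known_microbes), locale = "en")
  n <- length(known_microbes)
  if (scheme == "loocv") {
    if (n < 2L) stop("LOOCV needs at least 2 known microbes", call. = FALSE)
    return(as.list(known_microbes))
  }
  if (n < k) {
    stop(sprintf("k-fold with k=%d needs at least %d known microbes, got %d",
                 k, k, n), call. = FALSE)
  }
  shuffled <- with_local_seed(seed, known_microbes[sample.int(n)])
  unname(split(shuffled, rep_len(seq_len(k), n)))
}

# Run code under a temporary RNG seed without disturbing the caller's stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic per-(disease, repeat) child seed below 2^31.
child_seed <- function(master, disease_idx, repeat_idx) {
  as.integer((as.numeric(master) * 1000003 + disease_idx * 10007 +
                repeat_idx * 101) %% 2147483629)
}

#' ROC curve and AUC from score pools
#'
#' The AUC is the Mann-Whitney statistic: the fraction of
#' (positive, negative) score pairs in which the positive outscores the
#' negative, with half credit for ties. ROC points come from a threshold
#' sweep over the pooled unique scores (tied scores enter as one step), so
#' the trapezoidal area under the returned curve equals the AUC.
#'
#' @param positive_scores,negative_scores Non-empty numeric vectors.
#' @return List with `auc` (scalar) and `roc` (tibble `fpr`, `tpr` from
#'   (0,0) to (1,1), both coordinates non-decreasing).
#' @examples
#' roc_auc(c(0.9, 0.4), c(0.8, 0.2, 0.1))$auc # 5/6
#' @export
roc_auc <- function(positive_scores, negative_scores) {
  n_pos <- length(positive_scores)
  n_neg <- length(negative_scores)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: need at least one positive and one negative score",
         call. = FALSE)
  }
  r <- rank(c(positive_scores, negative_scores), ties.method = "average")
  auc <- (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(c(positive_scores, negative_scores)), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(positive_scores >= t), 1L)
  fp <- vapply(thr, function(t) sum(negative_scores >= t), 1L)
  roc <- tibble::tibble(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  list(auc = auc, roc = roc)
}

# Score one fold: mask the held-out links, rebuild everything that depends on
# the association matrix, walk, and return the microbe-layer scores.
score_fold <- function(B, disease, test_microbes, training_microbes, spwd,
                       r, lambda, eta_seed, gamma_prime, tol, max_iter) {
  B_masked <- B
  B_masked[test_microbes, disease] <- 0
  KM <- gip_kernel(B_masked, gamma_prime)
  KD <- gip_kernel(t(B_masked), gamma_prime)
  SD <- if (is.null(spwd)) KD / 2 else fuse_disease_similarity(KD, spwd)
  T_op <- compile_transition(build_network(KM, SD, B_masked, lambda))
  p0 <- make_seed(T_op, disease, training_microbes, eta_seed)
  steady <- propagate(T_op, p0, r = r, tol = tol, max_iter = max_iter)
  steady[seq_len(nrow(B))]
}

#' Cross-validated recovery of known microbe-disease associations
#'
#' For every eligible disease, held-out known microbes are removed from the
#' association matrix, the GIP kernels and transition operator are recomputed
#' on the masked data (so no held-out link can leak through the similarity
#' layer), the walk is seeded with the disease plus its remaining training
#' microbes, and the held-out microbes' steady-state scores are compared
#' against all candidate microbes (those not known for the disease). Folds of
#' one repeat are pooled into a single per-disease ROC/AUC; k-fold AUCs are
#' averaged over repeats.
#'
#' @inheritParams rank_microbes
#' @param scheme `"loocv"` (each known microbe held out in turn) or
#'   `"kfold"` (seeded balanced split).
#' @param k Folds for `"kfold"` (default 5).
#' @param repeats Number of random re-partitions for `"kfold"` (default 10).
#' @param min_known Eligibility floor on known microbes per disease
#'   (default 5).
#' @param diseases Optional subset of disease ids to evaluate (still subject
#'   to `min_known`).
#' @param seed Master seed; per-(disease, repeat) child seeds are derived
#'   deterministically from it.
#' @param keep_roc Keep per-disease pooled ROC points (first repeat) as a
#'   list-column.
#' @return An `mdrank_cv` tibble with one row per disease: `disease`,
#'   `scheme`, `auc`, `n_pos`, `n_neg`, `repeats`, and for k-fold a
#'   `per_repeat_aucs` list-column.
#' @export
mdrank_cv <- function(catalog, spwd = NULL, scheme = c("loocv", "kfold"),
                      k = 5L, repeats = 10L, min_known = 5L, diseases = NULL,
                      r = 0.1, lambda = 0.5, eta_seed = 0.5, gamma_prime = 1,
                      tol = 1e-10, max_iter = 10000L, seed = 42L,
                      keep_roc = FALSE) {
  scheme <- match.arg(scheme)
  catalog <- as_catalog(catalog)
  B <- to_profile_matrix(catalog)
  eligible <- eligible_diseases(catalog, min_known)
  if (!is.null(diseases)) eligible <- intersect(eligible, diseases)
  if (length(eligible) == 0L) {
    stop("no disease meets the min_known = ", min_known, " floor",
         call. = FALSE)
  }
  microbes <- rownames(B)

  rows <- purrr::imap(eligible, function(dis, d_idx) {
    known <- stringr::str_sort(catalog$microbe[catalog$disease == dis],
                               locale = "en")
    candidates <- setdiff(microbes, known)
    n_reps <- if (scheme == "loocv") 1L else repeats
    rep_aucs <- numeric(n_reps)
    first_roc <- NULL
    n_pos_tot <- 0L
    n_neg_tot <- 0L
    for (rep_i in seq_len(n_reps)) {
      folds <- if (scheme == "loocv") {
        make_folds(known, "loocv")
      } else {
        make_folds(known, "kfold", k = k,
                   seed = child_seed(seed, d_idx, rep_i))
      }
      pos <- numeric(0)
      neg <- numeric(0)
      for (fold in folds) {
        training <- setdiff(known, fold)
        scores <- score_fold(B, dis, fold, training, spwd, r, lambda,
                             eta_seed, gamma_prime, tol, max_iter)
        pos <- c(pos, scores[fold])
        neg <- c(neg, scores[candidates])
      }
      ra <- roc_auc(pos, neg)
      rep_aucs[rep_i] <- ra$auc
      if (rep_i == 1L) {
        first_roc <- ra$roc
        n_pos_tot <- length(pos)
        n_neg_tot <- length(neg)
      }
    }
    tibble::tibble(
      disease = dis, scheme = scheme, auc = mean(rep_aucs),
      n_pos = n_pos_tot, n_neg = n_neg_tot, repeats = n_reps,
      per_repeat_aucs = list(rep_aucs),
      roc = if (keep_roc) list(first_roc) else list(NULL)
    )
  })

  out <- dplyr::bind_rows(rows)
  if (scheme == "loocv") out$per_repeat_aucs <- NULL
  if (!keep_roc) out$roc <- NULL
  class(out) <- c("mdrank_cv", class(out))
  attr(out, "params") <- list(scheme = scheme, k = k, repeats = repeats,
                              min_known = min_known, r = r, lambda = lambda,
                              eta_seed = eta_seed, gamma_prime = gamma_prime,
                              seed = seed)
  out
}

#' @export
print.mdrank_cv <- function(x, ...) {
  cat(sprintf("# cross-validation (%s): %d diseases, mean AUC %.4f\n",
              attr(x, "params")$scheme %||% x$scheme[1], nrow(x),
              mean(x$auc)))
  NextMethod()
}
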