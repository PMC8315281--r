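# Shared fixture builders. All randomness is locally seeded so tests are
# order-independent.

# Write an association TSV and return its path.
write_assoc_file <- function(rows, path = tempfile(fileext = ".tsv"),
                             delim = "\t", header = c("microbe", "disease")) {
  lines <- c(paste(header, collapse = delim),
             vapply(rows, paste, "", collapse = delim))
  writeLines(lines, path)
  path
}

# Random catalog over n_m microbes / n_d diseases with expected density p.
random_catalog <- function(n_m, n_d, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(rbinom(n_m * n_d, 1, p), n_m, n_d)
    # guarantee at least one association so profile matrices are valid
    if (sum(A) == 0) A[1, 1] <- 1
    idx <- which(A == 1, arr.ind = TRUE)
    as_catalog(data.frame(
      microbe = sprintf("m%03d", idx[, "row"]),
      disease = sprintf("d%03d", idx[, "col"])
    ))
  })
}

# Random binary profile matrix with at least one nonzero row.
random_profiles <- function(n, d, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    P <- matrix(rbinom(n * d, 1, p), n, d,
                dimnames = list(sprintf("e%03d", seq_len(n)), NULL))
    if (all(P == 0)) P[1, 1] <- 1
    P
  })
}

# Random column-stochastic operator shaped like a compiled transition.
random_transition <- function(n, seed = 1) {
  withr::with_seed(seed, {
    W <- matrix(stats::runif(n * n), n, n)
    W <- sweep(W, 2, colSums(W), "/")
    ids <- sprintf("n%03d", seq_len(n))
    dimnames(W) <- list(ids, ids)
    structure(W, class = "mdrank_transition", n_microbes = n,
              n_diseases = 0L, isolated = rep(FALSE, n))
  })
}

# Random composite network (microbe/disease similarities + associations).
random_network <- function(n_m, n_d, lambda = 0.5, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    mids <- sprintf("m%03d", seq_len(n_m))
    dids <- sprintf("d%03d", seq_len(n_d))
    sym <- function(n, ids) {
      S <- matrix(stats::runif(n * n), n, n, dimnames = list(ids, ids))
      (S + t(S)) / 2
    }
    B <- matrix(rbinom(n_m * n_d, 1, p), n_m, n_d,
                dimnames = list(mids, dids))
    build_network(sym(n_m, mids), sym(n_d, dids), B, lambda)
  })
}

# Brute-force pair-counting AUC: the independent oracle for roc_auc().
auc_bruteforce <- function(pos, neg) {
  wins <- 0
  for (p in pos) {
    for (q in neg) {
      wins <- wins + (p > q) + 0.5 * (p == q)
    }
  }
  wins / (length(pos) * length(neg))
}

# Trapezoidal area under an (fpr, tpr) polyline.
trapezoid_area <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}
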