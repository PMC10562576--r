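# Independent oracles, deliberately coded differently from the package
# internals they check.

# box count by hashing per-voxel cell index strings
oracle_box_count <- function(mask, s, offset = c(0, 0, 0)) {
  idx <- which(mask$occupancy, arr.ind = TRUE) - 1L
  keys <- apply(idx, 1L, function(v)
    paste(floor((v - offset) / s), collapse = "/"))
  length(unique(keys))
}

# exhaustive scaling-window scorer via stats::lm and summary()$adj.r.squared
oracle_select_window <- function(scales, counts) {
  n <- length(scales)
  cand <- do.call(rbind, lapply(seq_len(n - 2L), function(st) {
    ends <- (st + 2L):n
    data.frame(start = st, end = ends)
  }))
  cand$len <- cand$end - cand$start + 1L
  cand$score <- vapply(seq_len(nrow(cand)), function(i) {
    sel <- cand$start[i]:cand$end[i]
    y <- log(counts[sel]); x <- log(scales[sel])
    if (var(y) < 1e-28) return(1)   # constant series: residual-free fit
    # lm warns "essentially perfect fit" on exact power laws; irrelevant here
    round(suppressWarnings(summary(stats::lm(y ~ x))$adj.r.squared), 2)
  }, numeric(1))
  # max score; ties -> longer window, then smaller starting scale
  best <- cand[order(-cand$score, -cand$len, cand$start), ][1L, ]
  list(start = best$start, end = best$end, score = best$score)
}

# AUC by brute-force concordant-pair counting
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

# path-dependent conditional expectation of a single tree: features in S
# follow x, others split by cover fractions
oracle_expvalue <- function(tree, x, S, node = 1L) {
  f <- tree$feature[node]
  if (f < 0) return(tree$value[node])
  l <- tree$left[node] + 1L; r <- tree$right[node] + 1L
  if ((f + 1L) %in% S) {
    nxt <- if (x[f + 1L] < tree$threshold[node]) l else r
    oracle_expvalue(tree, x, S, nxt)
  } else {
    wl <- tree$cover[l] / tree$cover[node]
    wl * oracle_expvalue(tree, x, S, l) +
      (1 - wl) * oracle_expvalue(tree, x, S, r)
  }
}

# exact Shapley values of one tree by subset enumeration over all M features
oracle_shap_tree <- function(tree, x, M) {
  phi <- numeric(M)
  others <- function(j) setdiff(seq_len(M), j)
  for (j in seq_len(M)) {
    for (size in 0:(M - 1L)) {
      subsets <- if (size == 0L) list(integer(0)) else
        asplit(utils::combn(others(j), size), 2L)
      w <- factorial(size) * factorial(M - size - 1L) / factorial(M)
      for (S in subsets) {
        S <- as.integer(S)
        phi[j] <- phi[j] + w * (oracle_expvalue(tree, x, c(S, j)) -
                                  oracle_expvalue(tree, x, S))
      }
    }
  }
  phi
}

# exact one-tailed signed-rank p by enumerating all sign assignments
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1L, function(s) sum(r[s]))
  mean(w_all >= w_obs)
}

random_mask <- function(dim3 = c(16L, 16L, 16L), p = 0.3) {
  occ <- array(runif(prod(dim3)) < p, dim = dim3)
  if (!any(occ)) occ[1L] <- TRUE
  voxel_mask(occ)
}

scale_series_for_test <- function(scales, counts)
  fracdem:::scale_series(scales, counts)

feature_values <- function(tab) as.matrix(tab$data[names(tab$categories)])
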