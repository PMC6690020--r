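#' TMM scaling factors for an expression matrix
#'
#' Trimmed mean of M-values adapted to depth-normalized expression units
#' (FPKM): the library-size term is dropped, so `M = log2(x / x_ref)` and
#' `A = log2(x * x_ref) / 2` over genes positive in both samples. The
#' reference sample is the one whose upper-quartile expression is closest
#' to the mean upper quartile. Per sample, the top/bottom `trim_m` of M
#' and `trim_a` of A are removed and the factor is `2^` the precision-
#' weighted mean of the remaining M. The inverse-variance weights
#' (`1/x + 1/x_ref` on the delta-method scale) are computed on
#' column-total-normalized abundances, so they — and hence the factors —
#' are equivariant under rescaling of a sample. Factors are rescaled to
#' geometric mean 1.
#'
#' @param mat Nonnegative gene-by-sample matrix (>= 2 samples).
#' @param trim_m,trim_a Two-sided trim fractions for M and A
#'   (defaults 0.30 and 0.05).
#' @return Named numeric vector of per-sample scaling factors; divide
#'   columns by these to normalize (see [tmm_normalize()]).
#' @export
tmm_factors <- function(mat, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2, all(mat >= 0))
  # upper quartile on column-total-normalized values, so the reference
  # choice is invariant under rescaling of any one sample
  uq <- apply(sweep(mat, 2, colSums(mat), "/"), 2, quantile,
              probs = 0.75, names = FALSE)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(mat)), function(j) {
    if (j == ref) return(1)
    keep <- mat[, j] > 0 & mat[, ref] > 0
    if (sum(keep) < 2) {
      warning("fewer than 2 genes positive in both sample ", j,
              " and the reference; factor set to 1")
      return(1)
    }
    x <- mat[keep, j]; r <- mat[keep, ref]
    M <- log2(x / r)
    A <- 0.5 * log2(x * r)
    xn <- x / sum(mat[, j]); rn <- r / sum(mat[, ref])
    w <- 1 / (1 / xn + 1 / rn)             # inverse asymptotic variance,
                                           # scale-free in either sample
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(sel)) return(1)
    2^(sum(w[sel] * M[sel]) / sum(w[sel]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(mat)
  f
}

#' @rdname tmm_factors
#' @param ... Passed to [tmm_factors()].
#' @export
tmm_normalize <- function(mat, ...) {
  sweep(mat, 2, tmm_factors(mat, ...), "/")
}

#' Row-wise z-scores of log2(x + 1), capped at +/- 2
#'
#' Each gene row is transformed to `log2(x + 1)`, centred and scaled to
#' unit variance, then clipped to `[-cap, cap]`. Rows with zero variance
#' on the log scale carry no pattern and are excluded (listed in the
#' `"excluded"` attribute, with a warning).
#'
#' @param mat Nonnegative gene-by-sample matrix.
#' @param cap Cap magnitude (default 2).
#' @return Matrix of capped z-scores (possibly fewer rows), with
#'   attribute `"excluded"` naming dropped genes.
#' @export
log_z_capped <- function(mat, cap = 2) {
  l <- log2(mat + 1)
  sds <- apply(l, 1, sd)
  keep <- sds > 0
  if (any(!keep))
    warning(sum(!keep), " zero-variance gene row(s) excluded from z-scoring")
  z <- (l[keep, , drop = FALSE] - rowMeans(l[keep, , drop = FALSE])) /
    sds[keep]
  z <- pmin(pmax(z, -cap), cap)
  attr(z, "excluded") <- rownames(mat)[!keep]
  z
}

#' Filter genes by maximum pairwise fold change
#'
#' A gene is kept when the ratio `(max + pseudocount) / (min +
#' pseudocount)` across samples is at least `fc`, i.e. some sample pair
#' shows a fold change of `fc` or more.
#'
#' @param mat Nonnegative gene-by-sample matrix.
#' @param fc Fold-change threshold (> 1; default 4).
#' @param pseudocount Added to both sides of the ratio (default 1).
#' @return Character vector of retained gene ids.
#' @export
fold_change_filter <- function(mat, fc = 4, pseudocount = 1) {
  stopifnot(fc > 1)
  ratio <- apply(mat + pseudocount, 1, max) /
    apply(mat + pseudocount, 1, min)
  rownames(mat)[ratio >= fc]
}

#' Deterministic PAM (k-medoids) clustering
#'
#' Classic partitioning-around-medoids with a greedy BUILD phase (the
#' first medoid minimizes total distance; each next medoid maximizes the
#' cost reduction) followed by a SWAP phase that repeatedly applies the
#' best strictly-improving medoid/non-medoid exchange until none exists.
#' There are no random restarts, so the result is a pure function of the
#' input; all ties break toward the lower row index. Cluster labels are
#' canonicalized by sorting medoids by row index.
#'
#' BUILD+SWAP is a 1-exchange local search and can stall in a local
#' optimum even on tiny inputs; when the exhaustive medoid search is
#' tractable (`choose(n, k) <= exact_limit`) the solver therefore
#' enumerates all medoid sets and returns the global optimum (first
#' lexicographic set on cost ties), so small instances are solved
#' exactly while large ones use the local search.
#'
#' @param x Numeric matrix (rows are objects, e.g. the z-score matrix
#'   with genes as rows) or a `dist` object.
#' @param k Number of clusters (`1 <= k <= n`).
#' @param exact_limit Enumerate all medoid sets when `choose(n, k)` is
#'   at most this (default 10000); set to 0 to force pure BUILD+SWAP.
#' @return List with `cluster` (named integer vector of labels),
#'   `medoids` (row names of the k medoids, sorted by row index),
#'   `cost` (total distance of objects to their medoids), and
#'   `build_cost` (cost after the BUILD phase).
#' @export
pam_cluster <- function(x, k, exact_limit = 10000) {
  d <- if (inherits(x, "dist")) as.matrix(x) else as.matrix(dist(x))
  n <- nrow(d)
  stopifnot(k >= 1, k <= n)
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  # BUILD
  med <- which.min(colSums(d))
  dn <- d[med, ]
  while (length(med) < k) {
    gains <- colSums(pmax(dn - d, 0))   # gains[h] = reduction if h added
    gains[med] <- -Inf
    h <- which.max(gains)
    med <- c(med, h)
    dn <- pmin(dn, d[h, ])
  }
  build_cost <- sum(dn)

  # SWAP: best strictly-improving exchange, repeated to convergence
  cost <- build_cost
  repeat {
    dm <- d[med, , drop = FALSE]
    near <- apply(dm, 2, which.min)               # position within med
    d1 <- dm[cbind(near, seq_len(n))]
    d2 <- if (length(med) > 1)
      apply(dm, 2, function(col) sort(col, partial = 2)[2]) else
      rep(Inf, n)
    best <- list(cost = cost)
    nonmed <- setdiff(seq_len(n), med)
    for (t in seq_along(med)) {
      base <- ifelse(near == t, d2, d1)
      for (h in nonmed) {
        cand <- sum(pmin(base, d[h, ]))
        if (cand < best$cost - 1e-12) best <- list(cost = cand, t = t, h = h)
      }
    }
    if (is.null(best$t)) break
    med[best$t] <- best$h
    cost <- best$cost
  }

  # exact refinement on small instances
  if (choose(n, k) <= exact_limit) {
    sets <- utils::combn(n, k)
    costs <- apply(sets, 2, function(m)
      sum(apply(d[m, , drop = FALSE], 2, min)))
    opt <- which.min(costs)                 # ties -> first lexicographic set
    if (costs[opt] < cost - 1e-12) {
      med <- sets[, opt]
      cost <- costs[opt]
    }
  }

  med <- sort(med)
  dm <- d[med, , drop = FALSE]
  cl <- apply(dm, 2, which.min)                   # ties -> lower medoid index
  list(cluster = setNames(as.integer(cl), ids),
       medoids = ids[med],
       cost = sum(dm[cbind(cl, seq_len(n))]),
       build_cost = build_cost)
}

#' Map regions to their high-expression cluster and derive BRSG sets
#'
#' For each region (column of the z-score matrix) the assigned cluster is
#' the one with the highest mean z in that region; the region-specific
#' gene set (BRSG) of a region is the membership of its assigned cluster.
#' The mapping need not be a bijection: a warning is raised when two
#' regions select the same cluster, and when `k` differs from the number
#' of regions.
#'
#' @param assignment Result of [pam_cluster()].
#' @param z Capped z-score matrix (genes x regions) the clustering was
#'   computed on.
#' @return List with `region_cluster` (named integer vector region ->
#'   cluster), `brsg` (named list region -> character vector of gene
#'   ids), and `bijective` (logical).
#' @export
assign_region_clusters <- function(assignment, z) {
  cl <- assignment$cluster[rownames(z)]
  k <- max(cl)
  if (k != ncol(z))
    warning("number of clusters (", k, ") differs from number of regions (",
            ncol(z), ")")
  means <- rowsum(z, cl) / as.vector(table(cl))   # cluster x region mean z
  sel <- apply(means, 2, which.max)
  region_cluster <- setNames(as.integer(rownames(means)[sel]), colnames(z))
  if (anyDuplicated(region_cluster))
    warning("two or more regions selected the same cluster")
  brsg <- lapply(region_cluster, function(ci) names(cl)[cl == ci])
  list(region_cluster = region_cluster, brsg = brsg,
       bijective = !anyDuplicated(region_cluster) &&
         length(unique(region_cluster)) == k)
}
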