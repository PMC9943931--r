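#' Principal coordinates of neighbour matrices (classic PCNM)
#'
#' Spatial eigenfunctions of the window: distances larger than the
#' truncation threshold `t` (the longest edge of the minimum spanning tree
#' of the site distance graph, so the graph stays connected) are replaced
#' by `4 t`; the truncated matrix is double-centred as in principal
#' coordinate analysis and the eigenvectors with positive eigenvalues are
#' retained as spatial predictors.
#'
#' @param d Euclidean distance matrix among sites (>= 3 sites).
#' @param threshold Optional truncation distance; default = longest MST
#'   edge.
#' @return List of class `nn_pcnm`: `vectors` (sites x k, columns
#'   `PCNM1..k`), `values` (positive eigenvalues), `threshold`.
#' @export
pcnm <- function(d, threshold = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 sites")
  if (max(d) == 0) stop("degenerate coordinates: all distances zero")
  if (is.null(threshold)) threshold <- mst_max_edge(d)
  dt <- d
  dt[dt > threshold] <- 4 * threshold
  A <- -0.5 * dt^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  e <- eigen(G, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-9
  v <- e$vectors[, pos, drop = FALSE]
  colnames(v) <- paste0("PCNM", seq_len(ncol(v)))
  structure(list(vectors = v, values = e$values[pos], threshold = threshold),
            class = "nn_pcnm")
}

# longest edge of the minimum spanning tree (Prim), on a dense distance
# matrix: the smallest truncation that keeps the site graph connected
mst_max_edge <- function(d) {
  n <- nrow(d)
  intree <- rep(FALSE, n); intree[1] <- TRUE
  best <- d[1, ]
  maxe <- 0
  for (k in seq_len(n - 1)) {
    cand <- which(!intree)
    j <- cand[which.min(best[cand])]
    maxe <- max(maxe, best[j])
    intree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  maxe
}

#' Sturges rule for the number of distance classes
#'
#' `ceiling(1 + log2(n_pairs))`, applied to the number of site pairs.
#'
#' @param n_pairs Number of distinct site pairs (>= 2).
#' @return Integer class count.
#' @examples
#' sturges_classes(choose(100, 2))   # 14
#' @export
sturges_classes <- function(n_pairs) {
  if (n_pairs < 2) stop("need at least 2 pairs")
  as.integer(ceiling(1 + log2(n_pairs)))
}

#' Moran's I correlogram
#'
#' Moran's I per equal-width distance class with binary within-class
#' weights: `I = (n / W) * sum_ij w_ij z_i z_j / sum z^2` over ordered
#' pairs in the class.
#'
#' @param x Site values (nonzero variance).
#' @param d Distance matrix among the sites.
#' @param n_classes Number of equal-width classes; default from
#'   [sturges_classes()] on the pair count.
#' @return Data frame of class `nn_correlogram`: `class, break_lo,
#'   break_hi, I, n_pairs`. Classes without pairs are dropped.
#' @export
morans_correlogram <- function(x, d, n_classes = NULL) {
  d <- as.matrix(d)
  n <- length(x)
  if (stats::var(x) == 0) stop("constant values: Moran's I undefined")
  np <- n * (n - 1) / 2
  if (is.null(n_classes)) n_classes <- sturges_classes(np)
  dv <- d[upper.tri(d)]
  breaks <- seq(min(dv), max(dv), length.out = n_classes + 1)
  z <- x - mean(x)
  s2 <- sum(z^2)
  out <- lapply(seq_len(n_classes), function(k) {
    lo <- breaks[k]; hi <- breaks[k + 1]
    w <- if (k == 1) d >= lo & d <= hi else d > lo & d <= hi
    diag(w) <- FALSE
    W <- sum(w)
    if (W == 0) return(NULL)
    I <- (n / W) * sum(w * outer(z, z)) / s2
    data.frame(class = k, break_lo = lo, break_hi = hi, I = I, n_pairs = W / 2)
  })
  out <- do.call(rbind, out)
  class(out) <- c("nn_correlogram", "data.frame")
  out
}

#' Mantel correlation between two species-pair tables
#'
#' Pearson correlation over the off-diagonal upper-triangle entries, with a
#' permutation test that simultaneously permutes rows and columns of the
#' second table. The design's alternative hypothesis is `r < 0` (lower
#' tail): ecologically-equivalent species have positively correlated
#' abundances and similar correlograms, so correlation and
#' correlogram-distance tables anti-covary under niche structure.
#'
#' @param A,B Symmetric matrices over the same species set (>= 3 species).
#' @param n_perm Permutations, default 999.
#' @param tail `"lower"` (default) or `"upper"`.
#' @param seed Optional seed.
#' @return List: `r`, `p_value`, `n_perm`.
#' @export
mantel <- function(A, B, n_perm = 999, tail = c("lower", "upper"),
                   seed = NULL) {
  tail <- match.arg(tail)
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("A and B must have the same dimensions")
  n <- nrow(A)
  if (n < 3) stop("need at least 3 species")
  ut <- upper.tri(A)
  if (stats::sd(A[ut]) == 0 || stats::sd(B[ut]) == 0)
    stop("zero variance in a species-pair table")
  if (!is.null(seed)) set.seed(as.integer(seed))
  r_obs <- stats::cor(A[ut], B[ut])
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    pm <- sample.int(n)
    rp <- stats::cor(A[ut], B[pm, pm][ut])
    if (tail == "lower") { if (rp <= r_obs) cnt <- cnt + 1L }
    else if (rp >= r_obs) cnt <- cnt + 1L
  }
  list(r = r_obs, p_value = (1 + cnt) / (1 + n_perm), n_perm = n_perm)
}
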