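#' @include AllClasses.R
NULL

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over strictly positive relative abundances
#' `p_i = x_i / sum(x)`, natural logarithm. Applied row-wise when given a
#' matrix. H is invariant to permuting taxa and to rescaling a sample by any
#' positive constant; a uniform community of `S` taxa gives `log(S)` and a
#' single-taxon community gives 0.
#'
#' @param x nonnegative abundance vector, or matrix of samples in rows.
#' @return A single diversity value, or a named vector for matrix input.
#' @examples
#' shannonIndex(c(1, 1, 1, 1))   # log(4)
#' shannonIndex(c(5, 0, 0))      # 0
#' @export
shannonIndex <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    return(vapply(seq_len(nrow(x)), function(i) shannonIndex(x[i, ]),
                  numeric(1), USE.NAMES = FALSE) |>
             setNames(rownames(x)))
  }
  if (!is.numeric(x) || !length(x))
    .mmiStop("invalidArgumentError", "abundances must be a numeric vector")
  if (anyNA(x) || any(x < 0))
    .mmiStop("invalidArgumentError", "abundances must be nonnegative")
  tot <- sum(x)
  if (tot == 0)
    .mmiStop("undefinedDiversityError",
             "Shannon index is undefined for an all-zero sample")
  p <- x[x > 0] / tot
  -sum(p * log(p))
}

#' Hellinger transform of an abundance table
#'
#' `sqrt(x_ij / rowsum_i)`: square-rooted relative abundances, so each output
#' row's squared entries sum to 1. This is the standard variance-stabilizing
#' transform that makes Euclidean-based ordination appropriate for community
#' composition data.
#'
#' @param m nonnegative matrix, samples in rows.
#' @return Matrix of the same shape.
#' @export
hellingerTransform <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m) || any(m < 0))
    .mmiStop("invalidArgumentError", "abundances must be nonnegative")
  rs <- rowSums(m)
  if (any(rs == 0))
    .mmiStop("undefinedTransformError",
             "Hellinger transform undefined for all-zero rows (rows: %s)",
             paste(which(rs == 0), collapse = ", "))
  sqrt(sweep(m, 1L, rs, "/"))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d_ab = sum|x_a - x_b| / sum(x_a + x_b)`, in `[0,1]`, 0 on the diagonal,
#' symmetric; 1 for samples with disjoint taxa.
#'
#' @param m nonnegative matrix, samples in rows.
#' @return Symmetric numeric matrix with the sample ids as dimnames.
#' @export
brayCurtis <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m) || any(m < 0))
    .mmiStop("invalidArgumentError", "abundances must be nonnegative")
  rs <- rowSums(m)
  num <- as.matrix(stats::dist(m, method = "manhattan"))
  den <- outer(rs, rs, "+")
  if (any(den == 0 & upper.tri(den)))
    .mmiStop("undefinedDistanceError",
             "Bray-Curtis undefined when both samples are all-zero")
  D <- num / den
  diag(D) <- 0
  dimnames(D) <- list(rownames(m), rownames(m))
  D
}

## Flip eigen-axis signs so the first nonzero loading (or score, for PCoA)
## of each axis is nonnegative -- removes eigenvector sign indeterminacy.
.fixSigns <- function(scores, loadings = NULL, tol = 1e-9) {
  ref <- if (is.null(loadings)) scores else loadings
  flip <- vapply(seq_len(ncol(ref)), function(j) {
    v <- ref[, j]
    nz <- which(abs(v) > tol)
    if (!length(nz)) FALSE else v[nz[1L]] < 0
  }, logical(1))
  scores[, flip] <- -scores[, flip, drop = FALSE]
  if (!is.null(loadings)) loadings[, flip] <- -loadings[, flip, drop = FALSE]
  list(scores = scores, loadings = loadings)
}

#' Ordination of a community table
#'
#' Condenses a multivariate community table into a few axis scores. The
#' default method is a principal component analysis of the
#' Hellinger-transformed table (deterministic, variance-preserving); a
#' principal coordinates analysis of Bray-Curtis dissimilarities is offered as
#' an alternative, with negative eigenvalues dropped and noted in provenance.
#'
#' Axis retention: the smallest number of leading axes reaching
#' `cum_var_target` cumulative variance (default 70%), capped at
#' `max(1, floor(n/10))` axes unless `max_axes` overrides the cap — the cap
#' protects the downstream all-subsets model search from overfitting at small
#' sample sizes. Eigenvector sign indeterminacy is resolved by forcing the
#' first nonzero loading (PCA) or score (PCoA) of each axis to be
#' nonnegative, so output is identical across runs and platforms.
#'
#' @param m nonnegative community matrix, samples in rows (`n >= 3`).
#' @param method `"pca_hellinger"` or `"pcoa_bray_curtis"`.
#' @param cum_var_target cumulative-variance retention target in (0, 1].
#' @param max_axes optional hard cap on retained axes.
#' @return List with `scores` (centered, samples x retained axes),
#'   `variance_explained` (per retained axis, as fractions of total),
#'   `eigenvalues` (all positive eigenvalues) and `provenance`.
#' @export
ordinateCommunity <- function(m,
                              method = c("pca_hellinger", "pcoa_bray_curtis"),
                              cum_var_target = 0.7,
                              max_axes = NULL) {
  method <- match.arg(method)
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 3L)
    .mmiStop("invalidArgumentError", "ordination needs at least 3 samples")
  neg_dropped <- 0L
  if (method == "pca_hellinger") {
    H <- hellingerTransform(m)
    Hc <- scale(H, center = TRUE, scale = FALSE)
    sv <- svd(Hc)
    eig <- sv$d^2 / (n - 1)
    keep <- eig > max(eig) * 1e-9
    if (max(eig) == 0 || !any(keep))
      .mmiStop("noVariationError", "community matrix has no variation")
    eig <- eig[keep]
    scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
    fixed <- .fixSigns(scores, sv$v[, keep, drop = FALSE])
    scores <- fixed$scores
  } else {
    D <- brayCurtis(m)
    cm <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = n - 1L,
                                           eig = TRUE))
    eig_all <- cm$eig
    if (max(eig_all) <= 0)
      .mmiStop("noVariationError", "community matrix has no variation")
    pos <- which(eig_all > max(eig_all) * 1e-9)
    neg_dropped <- sum(eig_all < -max(eig_all) * 1e-9)
    eig <- eig_all[pos]
    scores <- cm$points[, seq_along(pos), drop = FALSE]
    scores <- .fixSigns(scores)$scores
  }
  ve <- eig / sum(eig)
  cumve <- cumsum(ve)
  k_target <- which(cumve >= cum_var_target - 1e-12)[1L]
  if (is.na(k_target)) k_target <- length(ve)
  cap <- if (is.null(max_axes)) max(1L, floor(n / 10)) else
    .checkCount(max_axes, "max_axes")
  k <- max(1L, min(k_target, cap, length(ve)))
  scores <- scores[, seq_len(k), drop = FALSE]
  dimnames(scores) <- list(rownames(m), paste0("axis", seq_len(k)))
  ## enforce exact column centering (guards against accumulated fp error)
  scores <- sweep(scores, 2L, colMeans(scores), "-")
  list(
    scores = scores,
    variance_explained = ve[seq_len(k)],
    eigenvalues = eig,
    provenance = list(
      method = method,
      transform = if (method == "pca_hellinger") "hellinger" else "bray_curtis",
      axes_retained = k,
      variance_explained = ve[seq_len(k)],
      cumulative_variance = cumve[k],
      axis_cap = cap,
      cum_var_target = cum_var_target,
      negative_eigenvalues_dropped = neg_dropped,
      sign_convention = "first nonzero loading >= 0"
    )
  )
}

#' Condense a dataset's microbial data into predictor vectors
#'
#' For taxon-table flavors (abundance tables, PLFA profiles — the latter are
#' treated as relative-abundance profiles and ordinated identically), the
#' block holds ordination axis scores plus per-sample Shannon diversity. For
#' the functional-gene flavor, the 1-3 gene columns are passed through
#' unchanged (they enter models directly); when at least 3 gene columns exist
#' a per-sample Shannon index over genes is added as a functional-diversity
#' metric.
#'
#' @param dataset a [ProcessDataset-class].
#' @param method,cum_var_target,max_axes forwarded to [ordinateCommunity()].
#' @return A [PredictorBlock-class].
#' @export
condensePredictors <- function(dataset,
                               method = c("pca_hellinger", "pcoa_bray_curtis"),
                               cum_var_target = 0.7,
                               max_axes = NULL) {
  method <- match.arg(method)
  comm <- communityData(dataset)
  if (!ncol(comm))
    .mmiStop("missingPredictorsError",
             "dataset has neither a community table nor gene abundances")
  flavor <- datasetMetadata(dataset)$data_flavor
  if (identical(flavor, "functional_gene")) {
    sh <- if (ncol(comm) >= 3L) shannonIndex(comm) else numeric(0)
    new("PredictorBlock",
        axisScores = matrix(numeric(0), nrow(comm), 0,
                            dimnames = list(rownames(comm), NULL)),
        shannon = sh,
        geneAbundances = comm,
        provenance = list(flavor = "functional_gene",
                          n_genes = ncol(comm),
                          functional_diversity = ncol(comm) >= 3L))
  } else {
    ord <- ordinateCommunity(comm, method = method,
                             cum_var_target = cum_var_target,
                             max_axes = max_axes)
    new("PredictorBlock",
        axisScores = ord$scores,
        shannon = shannonIndex(comm),
        geneAbundances = matrix(numeric(0), nrow(comm), 0,
                                dimnames = list(rownames(comm), NULL)),
        provenance = c(ord$provenance, list(flavor = flavor)))
  }
}
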