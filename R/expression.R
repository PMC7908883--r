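#' Expressed-gene calls, tissue-preference clustering, stress response
#'
#' @name expression
NULL

#' Call expressed genes
#'
#' A gene is expressed when its maximum TPM over the considered samples is
#' strictly greater than the threshold.
#'
#' @param em [ExpressionMatrix][expression_matrix].
#' @param threshold TPM threshold (default 0.5, strict `>`).
#' @param scope optional character vector of sample ids to restrict to.
#' @return data.table: `gene_id`, `expressed`, `max_tpm`, `threshold`.
#' @export
call_expressed <- function(em, threshold = 0.5, scope = NULL) {
  vals <- em$values
  if (!is.null(scope)) {
    if (!length(scope)) stop("empty sample scope")
    missing <- setdiff(scope, colnames(vals))
    if (length(missing)) stop("scope sample not in matrix: ", missing[1])
    vals <- vals[, scope, drop = FALSE]
  }
  mx <- apply(vals, 1, max)
  data.table(gene_id = rownames(vals), expressed = mx > threshold,
             max_tpm = mx, threshold = threshold)
}

# k-means++ seeding (Arthur & Vassilvitskii 2007): first center uniform,
# then each next center sampled with probability proportional to squared
# distance to the nearest chosen center.
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1)) {
    if (all(d2 == 0)) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = d2)
    centers[i + 1, ] <- x[idx, ]
    nd <- rowSums((x - matrix(centers[i + 1, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  centers
}

#' Cluster genes by expression profile and assign tissue preference
#'
#' Features are per-tissue mean TPM, log2(x+1)-transformed. k-means uses
#' k-means++ seeding with `n_init` restarts under a fixed seed (best total
#' within-cluster sum of squares kept), so results are reproducible. Each
#' cluster then receives a preference label from [assign_preference()]
#' computed on its centroid's tissue-class means (back on the TPM scale);
#' tissue class `root` counts as vegetative and `other` is ignored for the
#' preference call.
#'
#' @param em [ExpressionMatrix][expression_matrix].
#' @param k number of clusters (default 10).
#' @param seed RNG seed (default 1); local, does not disturb the caller's RNG.
#' @param n_init number of k-means++ restarts (default 10).
#' @param ratio dominance ratio for [assign_preference()].
#' @param threshold expression threshold for the `not_expressed` label.
#' @return list: `assignments` (data.table `gene_id`, `cluster`,
#'   `preference`), `centers` (k x tissues, log2 scale), `tot_withinss`,
#'   `cluster_preference` (data.table `cluster`, `preference`).
#' @export
cluster_expression <- function(em, k = 10, seed = 1, n_init = 10, ratio = 2,
                               threshold = 0.5) {
  tissues <- unique(em$meta$tissue)
  feat <- sapply(tissues, function(tis) {
    cols <- em$meta[tissue == tis, sample_id]
    rowMeans(em$values[, cols, drop = FALSE])
  })
  feat <- matrix(feat, nrow = nrow(em$values),
                 dimnames = list(rownames(em$values), tissues))
  x <- log2(feat + 1)
  if (nrow(x) < k) {
    stop(sprintf("only %d genes but k=%d clusters requested; lower k", nrow(x), k))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    ctr <- .kmeanspp_centers(x, k)
    fit <- suppressWarnings(kmeans(x, centers = ctr, iter.max = 100))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }

  class_of <- em$meta[match(tissues, tissue), tissue_class]
  class_of[class_of == "root"] <- "vegetative"
  prefs <- vapply(seq_len(k), function(ci) {
    centroid_tpm <- 2^best$centers[ci, ] - 1
    use <- class_of %in% c("vegetative", "reproductive")
    means <- tapply(centroid_tpm[use], class_of[use], mean)
    assign_preference(means, ratio = ratio, threshold = threshold)
  }, character(1))

  list(
    assignments = data.table(gene_id = rownames(x), cluster = best$cluster,
                             preference = prefs[best$cluster]),
    centers = best$centers,
    tot_withinss = best$tot.withinss,
    cluster_preference = data.table(cluster = seq_len(k), preference = prefs)
  )
}

#' Assign a tissue-preference label to a cluster centroid
#'
#' If every class mean is at or below the expression threshold the cluster
#' is `not_expressed`; if the largest class mean is at least `ratio` times
#' every other class mean the cluster prefers that class; otherwise it is
#' `ubiquitous`.
#'
#' @param means named numeric vector of mean TPM per tissue class.
#' @param ratio dominance ratio (default 2).
#' @param threshold expression threshold (default 0.5).
#' @return preference label (a class name, `"ubiquitous"` or
#'   `"not_expressed"`).
#' @export
assign_preference <- function(means, ratio = 2, threshold = 0.5) {
  stopifnot(length(means) >= 1, !is.null(names(means)))
  if (all(means <= threshold)) return("not_expressed")
  top <- which.max(means)
  others <- means[-top]
  if (!length(others) || all(means[top] >= ratio * others)) return(names(means)[top])
  "ubiquitous"
}

#' Stress/control log2 fold change with 0.5 pseudo-TPM
#'
#' `log2((stress + 0.5) / (control + 0.5))`; antisymmetric under swapping
#' stress and control.
#'
#' @param stress_tpm,control_tpm non-negative TPM vectors.
#' @return log2 fold changes.
#' @export
stress_log_ratio <- function(stress_tpm, control_tpm) {
  if (any(stress_tpm < 0) || any(control_tpm < 0)) stop("negative TPM")
  log2((stress_tpm + 0.5) / (control_tpm + 0.5))
}

#' Flag stress-induced genes
#'
#' @param lfc data.table: `gene_id`, `condition`, `lfc` (from
#'   [stress_log_ratio()]).
#' @param lfc_min induction threshold on log2 fold change (default 1,
#'   inclusive).
#' @param min_conditions report genes induced in at least this many
#'   conditions (default 1).
#' @return list: `calls` (lfc with `induced` flag), `summary` (data.table
#'   `gene_id`, `n_induced` for genes meeting `min_conditions`).
#' @export
flag_induced <- function(lfc, lfc_min = 1, min_conditions = 1) {
  calls <- as.data.table(lfc)
  calls[, induced := lfc >= lfc_min]
  summ <- calls[induced == TRUE, .(n_induced = .N), by = gene_id][n_induced >= min_conditions]
  setorder(summ, -n_induced, gene_id)
  list(calls = calls[], summary = summ[])
}
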