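#' Homoeolog triads and expression-bias classification
#'
#' In an allohexaploid (subgenomes A, B, D) a homoeologous group with exactly
#' one member per subgenome is a 1:1:1 triad. Per tissue, the triad's TPMs
#' are normalized to relative abundances (rA, rB, rD) summing to 1 and the
#' triad is assigned the nearest of seven archetypes by plain Euclidean
#' distance in 3-space. Triads whose summed TPM falls below a floor are
#' excluded from classification.
#'
#' @name triad_bias
NULL

#' The seven homoeolog-bias archetypes
#'
#' Balanced = equal thirds; X-dominant = all expression from X;
#' X-suppressed = X silent and the other two equal. Row order is the fixed
#' tie-break order.
#'
#' @return 7 x 3 numeric matrix, rows named by category, columns A, B, D.
#' @export
bias_archetypes <- function() {
  m <- rbind(
    balanced       = c(1, 1, 1) / 3,
    `A-dominant`   = c(1, 0, 0),
    `B-dominant`   = c(0, 1, 0),
    `D-dominant`   = c(0, 0, 1),
    `A-suppressed` = c(0, 0.5, 0.5),
    `B-suppressed` = c(0.5, 0, 0.5),
    `D-suppressed` = c(0.5, 0.5, 0)
  )
  colnames(m) <- c("A", "B", "D")
  m
}

#' Detect 1:1:1 homoeolog triads
#'
#' @param genes gene models with `gene_id` and `subgenome` (from
#'   [read_gff3()]).
#' @param groups data.table: `gene_id`, `homoeolog_group`.
#' @return list: `triads` (data.table `group`, `a_id`, `b_id`, `d_id`),
#'   `non_triads` (data.table `group`, `cardinality` as "a:b:d" string).
#' @export
detect_triads <- function(genes, groups) {
  genes <- as.data.table(genes)
  groups <- as.data.table(groups)
  if (anyDuplicated(groups$gene_id)) {
    stop("gene assigned to more than one homoeolog group: ",
         groups$gene_id[duplicated(groups$gene_id)][1])
  }
  g <- merge(groups, genes[, .(gene_id, subgenome)], by = "gene_id", sort = FALSE)
  if (anyNA(g$subgenome)) stop("gene without subgenome label: ",
                               g$gene_id[is.na(g$subgenome)][1])
  triads <- list(); non <- list()
  for (grp in sort(unique(g$homoeolog_group))) {
    rows <- g[homoeolog_group == grp]
    na <- rows[subgenome == "A", gene_id]
    nb <- rows[subgenome == "B", gene_id]
    nd <- rows[subgenome == "D", gene_id]
    if (length(na) == 1 && length(nb) == 1 && length(nd) == 1) {
      triads[[length(triads) + 1]] <- data.table(group = grp, a_id = na, b_id = nb, d_id = nd)
    } else {
      non[[length(non) + 1]] <- data.table(
        group = grp,
        cardinality = paste(length(na), length(nb), length(nd), sep = ":"))
    }
  }
  list(
    triads = if (length(triads)) rbindlist(triads) else
      data.table(group = character(), a_id = character(), b_id = character(), d_id = character()),
    non_triads = if (length(non)) rbindlist(non) else
      data.table(group = character(), cardinality = character())
  )
}

#' Fraction of family genes retained in triads
#'
#' @param family_size number of genes in the family (> 0).
#' @param n_triads number of detected triads.
#' @return list: `fraction`, `numerator` (3 x triads), `denominator`.
#' @export
triad_retention_rate <- function(family_size, n_triads) {
  stopifnot(family_size > 0, n_triads >= 0)
  num <- 3L * n_triads
  if (num > family_size) stop("more triad genes than family genes")
  list(fraction = num / family_size, numerator = num, denominator = family_size)
}

#' Classify homoeolog expression bias for triads in one sample/tissue
#'
#' Vectorized over triads: each row of (`tpm_a`, `tpm_b`, `tpm_d`) is
#' normalized and assigned the archetype with the shortest Euclidean
#' distance. Triads with summed TPM below `min_total` are marked filtered.
#' Ties break in archetype row order (balanced, then dominants A/B/D, then
#' suppressed A/B/D).
#'
#' @param tpm_a,tpm_b,tpm_d non-negative TPM vectors of equal length.
#' @param min_total summed-TPM floor below which a triad is filtered
#'   (default 0.5).
#' @return data.table: `total`, `filtered`, `rA`, `rB`, `rD`, one distance
#'   column per archetype (`dist.<category>`), `category` (NA when filtered).
#' @export
classify_bias <- function(tpm_a, tpm_b, tpm_d, min_total = 0.5) {
  tpm <- cbind(tpm_a, tpm_b, tpm_d)
  if (any(!is.finite(tpm))) stop("non-finite TPM")
  if (any(tpm < 0)) stop("negative TPM")
  total <- rowSums(tpm)
  filtered <- total < min_total
  rel <- tpm / ifelse(total > 0, total, NA_real_)
  arch <- bias_archetypes()
  d <- sapply(seq_len(nrow(arch)), function(i) {
    sqrt((rel[, 1] - arch[i, 1])^2 + (rel[, 2] - arch[i, 2])^2 + (rel[, 3] - arch[i, 3])^2)
  })
  d <- matrix(d, ncol = nrow(arch))
  colnames(d) <- rownames(arch)
  cat_idx <- apply(d, 1, function(r) if (anyNA(r)) NA_integer_ else which.min(r))
  category <- rownames(arch)[cat_idx]
  category[filtered] <- NA_character_
  out <- data.table(total = total, filtered = filtered,
                    rA = rel[, 1], rB = rel[, 2], rD = rel[, 3])
  out[filtered == TRUE, c("rA", "rB", "rD") := NA_real_]
  dist_dt <- as.data.table(d)
  setnames(dist_dt, paste0("dist.", colnames(d)))
  out <- cbind(out, dist_dt)
  out[, category := category]
  out[]
}

#' Per-tissue bias calls for a set of triads
#'
#' For each tissue, each homoeolog's TPM is averaged over that tissue's
#' samples (replicates / intermediate stages) before classification.
#'
#' @param triads data.table `group`, `a_id`, `b_id`, `d_id`.
#' @param em [ExpressionMatrix][expression_matrix].
#' @param min_total summed-TPM floor.
#' @return data.table: `group`, `tissue`, plus [classify_bias()] columns.
#' @export
classify_triads <- function(triads, em, min_total = 0.5) {
  triads <- as.data.table(triads)
  need <- unique(c(triads$a_id, triads$b_id, triads$d_id))
  missing <- setdiff(need, rownames(em$values))
  if (length(missing)) stop("triad gene absent from expression matrix: ", missing[1])
  tissues <- unique(em$meta$tissue)
  out <- lapply(tissues, function(tis) {
    cols <- em$meta[tissue == tis, sample_id]
    mt <- em$values[, cols, drop = FALSE]
    mean_tpm <- rowMeans(mt)
    calls <- classify_bias(mean_tpm[triads$a_id], mean_tpm[triads$b_id],
                           mean_tpm[triads$d_id], min_total = min_total)
    cbind(data.table(group = triads$group, tissue = tis), calls)
  })
  rbindlist(out)
}

#' Map simplex relative abundances to ternary plot coordinates
#'
#' Standard simplex-to-plane map with vertex order (A, B, D):
#' `x = rB + rD/2`, `y = sqrt(3)/2 * rD`. Invertible on the simplex.
#'
#' @param rel numeric matrix (n x 3) or length-3 vector of (rA, rB, rD)
#'   summing to 1.
#' @return data.table: `x`, `y`.
#' @export
ternary_coordinates <- function(rel) {
  if (is.null(dim(rel))) rel <- matrix(rel, nrow = 1)
  if (ncol(rel) != 3) stop("rel must have 3 components")
  if (any(rel < -1e-9) || any(abs(rowSums(rel) - 1) > 1e-6)) {
    stop("rel must lie on the unit simplex")
  }
  data.table(x = rel[, 2] + rel[, 3] / 2, y = sqrt(3) / 2 * rel[, 3])
}

#' Invert ternary plot coordinates back to the simplex
#'
#' @param x,y coordinates from [ternary_coordinates()].
#' @return matrix (n x 3) of (rA, rB, rD).
#' @export
ternary_invert <- function(x, y) {
  rD <- y / (sqrt(3) / 2)
  rB <- x - rD / 2
  rA <- 1 - rB - rD
  cbind(rA = rA, rB = rB, rD = rD)
}

#' Summarize bias calls per tissue
#'
#' Filtered triads are excluded from denominators. Also returns the
#' aggregate over all calls (tissue = "all"), since a category's share can
#' be quoted per triad x tissue call.
#'
#' @param calls data.table from [classify_triads()] (needs `tissue`,
#'   `filtered`, `category`).
#' @return data.table: `tissue`, `category`, `n`, `fraction`; fractions sum
#'   to 1 within tissue.
#' @export
bias_summary <- function(calls) {
  calls <- as.data.table(calls)
  kept <- calls[filtered == FALSE]
  if (!nrow(kept)) {
    warning("all bias calls filtered; empty summary")
    return(data.table(tissue = character(), category = character(),
                      n = integer(), fraction = numeric()))
  }
  kept_all <- rbindlist(list(kept, copy(kept)[, tissue := "all"]))
  out <- kept_all[, .(n = .N), by = .(tissue, category)]
  out[, fraction := n / sum(n), by = tissue]
  setorder(out, tissue, -n)
  out[]
}
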