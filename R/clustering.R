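# Differential-expression filtering, per-gene scaling, k-means clustering
# of time-course profiles, JNK-dependence assignment, cluster overlaps and
# half-life cross-referencing.

.deg_required_cols <- c("gene_id", "biotype", "fdr", "max_group_mean")

deg_fc_cols <- function(table) {
  fc <- grep("^log2fc_", names(table), value = TRUE)
  if (!length(fc)) stop("missing log2fc_* columns")
  fc
}

check_deg_table <- function(table) {
  missing <- setdiff(.deg_required_cols, names(table))
  if (length(missing)) {
    stop("DEG table is missing required columns: ",
         paste(missing, collapse = ", "))
  }
  invisible(deg_fc_cols(table))
}

#' Filter differentially expressed genes
#'
#' Keeps genes with FDR-adjusted p value < 0.05, absolute log2 fold
#' change > 1 at one or more timepoints, maximal group mean
#' expression > 1, and protein-coding biotype.
#'
#' @param table DEG table: data.frame with columns `gene_id`, `biotype`,
#'   `fdr`, `max_group_mean`, `log2fc_<t>h` for the measured timepoints,
#'   and optionally `condition`.
#' @param condition optional condition to subset on first.
#' @return Character vector of passing gene ids.
#' @export
filter_degs <- function(table, condition = NULL) {
  check_deg_table(table)
  if (!is.null(condition)) {
    if (!"condition" %in% names(table)) stop("table has no condition column")
    table <- table[table$condition == condition, , drop = FALSE]
  }
  if (!nrow(table)) return(character(0))
  fc <- as.matrix(table[, deg_fc_cols(table), drop = FALSE])
  pass <- table$fdr < 0.05 &
    apply(abs(fc) > 1, 1, any) &
    table$max_group_mean > 1 &
    table$biotype == "protein_coding"
  unique(table$gene_id[pass])
}

#' Per-gene scaled profile matrix
#'
#' Builds the clustering input: one row per gene with the t = 0 point
#' anchored at 0 fold change (control-relative) followed by the measured
#' log2 fold changes, then min-max scaled per gene.
#'
#' @inheritParams filter_degs
#' @param genes gene ids to include (typically from [filter_degs()]).
#' @return Numeric matrix (genes x timepoints) scaled to \[0, 1\] per
#'   row, with `timepoints` attribute in hours.
#' @export
build_profile_matrix <- function(table, genes, condition = NULL) {
  check_deg_table(table)
  if (!is.null(condition)) {
    table <- table[table$condition == condition, , drop = FALSE]
  }
  idx <- match(genes, table$gene_id)
  if (anyNA(idx)) {
    stop("genes absent from table: ",
         paste(genes[is.na(idx)], collapse = ", "))
  }
  fc_cols <- deg_fc_cols(table)
  tps <- as.numeric(sub("^log2fc_(.*)h$", "\\1", fc_cols))
  fc <- as.matrix(table[idx, fc_cols, drop = FALSE])
  M <- cbind(0, fc)
  M <- t(apply(M, 1, minmax_scale))
  rownames(M) <- genes
  colnames(M) <- paste0("t_", c(0, tps), "h")
  attr(M, "timepoints") <- c(0, tps)
  M
}

#' Choose the number of k-means clusters
#'
#' Computes, for every candidate k, the mean silhouette width, the total
#' within-cluster sum of squares (elbow curve) and the coefficient of
#' variation of cluster sizes. The recommended k maximizes the silhouette
#' among candidates whose smallest cluster still holds at least 5% of the
#' genes; the full diagnostics table supports manual override.
#'
#' @param matrix scaled profile matrix (genes x timepoints).
#' @param k_range candidate cluster numbers.
#' @param seed RNG seed (k-means restarts).
#' @param n_restarts random restarts per k.
#' @return List with `k` (recommendation), `diagnostics` (data.frame:
#'   k, silhouette, wss, size_cv, min_size_frac) and `degenerate`
#'   (TRUE when the rows are indistinguishable and the silhouette is
#'   undefined; the recommendation falls back to `min(k_range)`).
#' @export
choose_k <- function(matrix, k_range = 2:10, seed = 1, n_restarts = 10) {
  if (nrow(matrix) < max(k_range) + 1) {
    stop("too few rows for the requested k range")
  }
  D <- stats::dist(matrix)
  if (max(D) == 0) {
    diagnostics <- data.frame(k = k_range, silhouette = NA_real_,
                              wss = 0, size_cv = NA_real_,
                              min_size_frac = NA_real_)
    return(list(k = min(k_range), diagnostics = diagnostics,
                degenerate = TRUE))
  }
  rows <- lapply(k_range, function(k) {
    km <- with_local_seed(seed + k, stats::kmeans(matrix, centers = k,
                                                  nstart = n_restarts,
                                                  iter.max = 100))
    sil <- mean(cluster::silhouette(km$cluster, D)[, "sil_width"])
    sizes <- as.numeric(table(km$cluster))
    data.frame(k = k, silhouette = sil, wss = km$tot.withinss,
               size_cv = stats::sd(sizes) / mean(sizes),
               min_size_frac = min(sizes) / nrow(matrix))
  })
  diagnostics <- do.call(rbind, rows)
  ok <- diagnostics$min_size_frac >= 0.05
  pick <- if (any(ok)) {
    diagnostics$k[ok][which.max(diagnostics$silhouette[ok])]
  } else {
    diagnostics$k[which.max(diagnostics$silhouette)]
  }
  list(k = pick, diagnostics = diagnostics, degenerate = FALSE)
}

#' K-means clustering of scaled expression profiles
#'
#' Euclidean k-means (best of `n_restarts` random starts by within-cluster
#' sum of squares, deterministic given `seed`). Cluster labels are
#' renumbered by descending peak time of the cluster mean profile (ties
#' broken by ascending original label), giving a stable, documented
#' ordering.
#'
#' @inheritParams choose_k
#' @param k number of clusters (>= 2; `k` equal to the number of genes
#'   puts every gene in its own cluster).
#' @param condition optional condition label stored on the result.
#' @return Object of class `cluster_set`: list with `condition`, `k`,
#'   `labels` (named integer vector), `sizes`, `centers` (k x timepoints
#'   scaled mean profiles), `center_sd`, `timepoints`, `seed`.
#' @export
cluster_genes <- function(matrix, k, seed = 1, n_restarts = 10,
                          condition = NULL) {
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(matrix)) stop("k exceeds the number of genes")
  if (k == nrow(matrix)) {
    cl <- seq_len(k)
    centers <- matrix
  } else {
    km <- with_local_seed(seed, stats::kmeans(matrix, centers = k,
                                              nstart = n_restarts,
                                              iter.max = 100))
    cl <- km$cluster
    centers <- km$centers
  }
  tps <- attr(matrix, "timepoints")
  if (is.null(tps)) tps <- seq_len(ncol(matrix)) - 1
  peak_time <- tps[apply(centers, 1, which.max)]
  relabel <- order(-peak_time, seq_len(k))
  new_id <- match(seq_len(k), relabel)
  labels <- new_id[cl]
  names(labels) <- rownames(matrix)
  centers <- centers[relabel, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  center_sd <- t(vapply(seq_len(k), function(i) {
    rows <- matrix[labels == i, , drop = FALSE]
    if (nrow(rows) > 1) apply(rows, 2, stats::sd) else rep(0, ncol(matrix))
  }, numeric(ncol(matrix))))
  structure(list(condition = condition, k = k, labels = labels,
                 sizes = as.integer(table(factor(labels, levels = seq_len(k)))),
                 centers = centers, center_sd = center_sd,
                 timepoints = tps, seed = seed),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster set (%s): k = %d, %d genes\n",
              if (is.null(x$condition)) "unlabeled" else x$condition,
              x$k, length(x$labels)))
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Mean scaled profile of one cluster as an expression profile
#'
#' Convenience accessor for fitting: extracts cluster `i`'s mean scaled
#' profile, rescaled to \[0, 1\], as an [expression_profile()].
#'
#' @param cluster_set a [cluster_genes()] result with a condition label.
#' @param i cluster number.
#' @return An `expression_profile`.
#' @export
cluster_profile <- function(cluster_set, i) {
  if (is.null(cluster_set$condition)) {
    stop("cluster_set needs a condition label for fitting")
  }
  expression_profile(cluster_set$condition,
                     minmax_scale(cluster_set$centers[i, ]),
                     cluster_set$timepoints,
                     id = paste0("cluster_", i))
}

#' Identify JNK-dependent genes from an inhibitor contrast
#'
#' Genes whose expression differs between the stimulated condition and the
#' same stimulation under JNK inhibition (absolute log2 fold change > 1 at
#' one or more timepoints; set `signed = TRUE` to require up-regulation in
#' the uninhibited condition). When a cluster set is supplied, the genes
#' are tallied per cluster.
#'
#' @param contrast data.frame with `gene_id` and `log2fc_*` columns for
#'   the stimulated-vs-inhibited comparison.
#' @param cluster_set optional [cluster_genes()] result for per-cluster
#'   counts.
#' @param signed require positive fold change rather than absolute.
#' @return List with `genes` (character vector) and `per_cluster`
#'   (named integer vector, or NULL without a cluster set).
#' @export
jnk_dependent_genes <- function(contrast, cluster_set = NULL,
                                signed = FALSE) {
  if (!"gene_id" %in% names(contrast)) stop("contrast must have gene_id")
  fc <- as.matrix(contrast[, deg_fc_cols(contrast), drop = FALSE])
  hits <- if (signed) apply(fc > 1, 1, any) else apply(abs(fc) > 1, 1, any)
  genes <- unique(contrast$gene_id[hits])
  per_cluster <- NULL
  if (!is.null(cluster_set)) {
    lab <- cluster_set$labels[intersect(genes, names(cluster_set$labels))]
    per_cluster <- table(factor(lab, levels = seq_len(cluster_set$k)))
    per_cluster <- stats::setNames(as.integer(per_cluster),
                                   names(per_cluster))
  }
  list(genes = genes, per_cluster = per_cluster)
}

#' Overlap between two gene sets
#'
#' Reports the intersection size, the Jaccard index and both directional
#' shared fractions; the headline figure is the shared fraction of the
#' smaller set.
#'
#' @param set_a,set_b non-empty character vectors of gene ids.
#' @return List with `n_intersect`, `jaccard`, `frac_a` (|A n B| / |A|),
#'   `frac_b`, `headline_fraction`.
#' @export
cluster_overlap <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!length(set_a) || !length(set_b)) {
    stop("both gene sets must be non-empty")
  }
  ni <- length(intersect(set_a, set_b))
  nu <- length(union(set_a, set_b))
  list(n_intersect = ni,
       jaccard = ni / nu,
       frac_a = ni / length(set_a),
       frac_b = ni / length(set_b),
       headline_fraction = ni / min(length(set_a), length(set_b)))
}

#' Cross-reference cluster genes with published half-life tables
#'
#' For every (cluster, study) pair, averages the measured mRNA half-lives
#' of the cluster's genes found in that study. Genes absent from a study
#' are counted, never imputed; a pair with zero matches is reported as
#' missing (NA), not zero.
#'
#' @param cluster_set a [cluster_genes()] result.
#' @param halflife_tables data.frame with columns `study_id`, `gene_id`,
#'   `half_life_h` (one or more studies stacked), or a list of such
#'   data.frames.
#' @return data.frame with one row per (cluster, study): `cluster`,
#'   `study_id`, `mean_half_life_h`, `n_matched`, `n_unmatched`.
#' @export
crossref_halflives <- function(cluster_set, halflife_tables) {
  if (is.data.frame(halflife_tables)) halflife_tables <- list(halflife_tables)
  if (!length(halflife_tables)) stop("at least one study table is required")
  tab <- do.call(rbind, halflife_tables)
  if (!all(c("study_id", "gene_id", "half_life_h") %in% names(tab))) {
    stop("half-life tables need columns study_id, gene_id, half_life_h")
  }
  if (any(tab$half_life_h <= 0)) stop("half-lives must be > 0")
  studies <- unique(tab$study_id)
  rows <- list()
  for (cl in seq_len(cluster_set$k)) {
    genes <- names(cluster_set$labels)[cluster_set$labels == cl]
    for (st in studies) {
      sub <- tab[tab$study_id == st, ]
      hl <- sub$half_life_h[match(genes, sub$gene_id)]
      n_matched <- sum(!is.na(hl))
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, study_id = st,
        mean_half_life_h = if (n_matched) mean(hl, na.rm = TRUE) else NA_real_,
        n_matched = n_matched,
        n_unmatched = length(genes) - n_matched,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
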