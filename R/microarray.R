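# One-colour microarray pipeline: feature reliability filtering, log2 +
# quantile normalization, gene-symbol collapse, per-comparison t-tests, DEG
# union with an expected-false-positive FDR estimate, PCA and clustered
# log2 fold-change summaries.

FLAG_COLS <- c("above_noise", "below_saturation", "population_outlier",
               "uniform_spot", "is_control")

#' Construct a feature-level expression table
#'
#' @param features Data frame with columns `feature_id`, `symbol` and the
#'   five quality-flag columns `above_noise`, `below_saturation`,
#'   `population_outlier`, `uniform_spot`, `is_control` (logical).
#' @param intensity Numeric matrix, features x samples, raw (positive)
#'   fluorescence intensities; rows align with `features`.
#' @param samples Data frame with one row per column of `intensity`:
#'   `sample`, `cell_line`, `exposure`, `replicate`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, intensity, samples) {
  miss <- setdiff(c("feature_id", "symbol", FLAG_COLS), names(features))
  if (length(miss)) {
    stop("feature table is missing column(s): ", paste(miss, collapse = ", "))
  }
  stopifnot(nrow(features) == nrow(intensity),
            nrow(samples) == ncol(intensity))
  for (cl in FLAG_COLS) {
    if (!is.logical(features[[cl]])) stop(sprintf("flag '%s' must be logical", cl))
  }
  structure(list(features = features,
                 intensity = as.matrix(intensity),
                 samples = samples),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d features x %d samples>\n",
              nrow(x$features), ncol(x$intensity)))
  invisible(x)
}

#' Keep reliable features
#'
#' A feature is reliable when it is (1) above the noise level, (2) below the
#' saturation level, (3) not a population outlier, (4) a uniform spot and
#' (5) not a control feature.
#'
#' @param table A [feature_table()].
#' @return The filtered [feature_table()].
#' @export
filter_reliable <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  f <- table$features
  keep <- f$above_noise & f$below_saturation & !f$population_outlier &
    f$uniform_spot & !f$is_control
  feature_table(f[keep, , drop = FALSE],
                table$intensity[keep, , drop = FALSE],
                table$samples)
}

#' Log2-transform and quantile normalize
#'
#' After normalization every sample shares the same empirical distribution
#' (identical sorted value vectors) while within-sample ranks are preserved.
#'
#' @param table A [feature_table()] (or a bare positive matrix).
#' @return An `expression_matrix`: list with `values` (features/genes x
#'   samples, log2 scale), `rows` (feature annotation or gene symbols) and
#'   `samples`.
#' @export
log2_quantile_normalize <- function(table) {
  if (inherits(table, "feature_table")) {
    m <- table$intensity
    rows <- table$features
    samples <- table$samples
  } else {
    m <- as.matrix(table)
    rows <- data.frame(feature_id = rownames(m) %||% seq_len(nrow(m)),
                       symbol = rownames(m) %||% seq_len(nrow(m)))
    samples <- data.frame(sample = colnames(m) %||% seq_len(ncol(m)))
  }
  if (any(m <= 0)) {
    bad <- which(rowSums(m <= 0) > 0)
    stop("non-positive intensities for feature row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  v <- limma::normalizeQuantiles(log2(m))
  dimnames(v) <- dimnames(m)
  structure(list(values = v, rows = rows, samples = samples),
            class = "expression_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix: %d rows x %d samples>\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Collapse features to gene symbols
#'
#' One row per gene symbol; multiple features mapping to the same symbol are
#' aggregated by the per-sample median. Features with an empty or missing
#' symbol are dropped (their count is reported as an attribute).
#'
#' @param em An `expression_matrix` whose `rows` carry a `symbol` column.
#' @return An `expression_matrix` keyed by gene symbol, with attribute
#'   `n_dropped` (features without a symbol).
#' @export
collapse_by_symbol <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  sym <- as.character(em$rows$symbol)
  bad <- is.na(sym) | sym == ""
  n_dropped <- sum(bad)
  v <- em$values[!bad, , drop = FALSE]
  sym <- sym[!bad]
  idx <- split(seq_along(sym), sym)
  genes <- names(idx)
  out <- matrix(NA_real_, length(genes), ncol(v),
                dimnames = list(genes, colnames(v)))
  single <- lengths(idx) == 1L
  if (any(single)) out[single, ] <- v[unlist(idx[single]), , drop = FALSE]
  for (g in genes[!single]) {
    out[g, ] <- apply(v[idx[[g]], , drop = FALSE], 2, stats::median)
  }
  res <- structure(list(values = out,
                        rows = data.frame(symbol = genes,
                                          stringsAsFactors = FALSE),
                        samples = em$samples),
                   class = "expression_matrix")
  attr(res, "n_dropped") <- n_dropped
  res
}

# Vectorized two-sample Student t-test (equal variance) per row.
.row_t_equalvar <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2); vy <- rowSums((y - my)^2)
  sp2 <- (vx + vy) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  t <- (mx - my) / se
  df <- nx + ny - 2
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  zero <- se == 0
  if (any(zero)) {
    # zero variance in both groups: p = 1 when the means agree, else 0
    p[zero] <- ifelse(mx[zero] == my[zero], 1, 0)
    t[zero] <- ifelse(mx[zero] == my[zero], 0, Inf * sign(mx - my)[zero])
  }
  list(t = t, p = p, log2fc = mx - my)
}

#' Per-gene differential expression (two-sample t-test)
#'
#' Student (equal-variance) two-sample t-test on log2 values; the log2 fold
#' change is the difference of group means (exposed minus control).
#'
#' @param em An `expression_matrix` (gene level).
#' @param group Logical/character selector of exposed samples: either a
#'   logical vector over columns or a list `list(exposure=, cell_line=)`
#'   matched against the sample sheet.
#' @param control Selector of control samples, same forms as `group`.
#' @param label Comparison label.
#' @param variant `"student"` (default) or `"welch"`.
#' @return A `comparison_result`: data frame (gene, log2fc, t, p) with
#'   attribute `label`.
#' @export
differential_expression <- function(em, group, control,
                                    label = "comparison",
                                    variant = c("student", "welch")) {
  stopifnot(inherits(em, "expression_matrix"))
  variant <- match.arg(variant)
  sel <- function(s) {
    if (is.logical(s)) return(which(s))
    if (is.list(s)) {
      keep <- rep(TRUE, nrow(em$samples))
      for (nm in names(s)) keep <- keep & em$samples[[nm]] %in% s[[nm]]
      return(which(keep))
    }
    which(em$samples$sample %in% s)
  }
  gi <- sel(group); ci <- sel(control)
  if (length(gi) < 2 || length(ci) < 2) {
    stop("need >= 2 replicates per group")
  }
  x <- em$values[, gi, drop = FALSE]
  y <- em$values[, ci, drop = FALSE]
  if (variant == "student") {
    r <- .row_t_equalvar(x, y)
  } else {
    nx <- ncol(x); ny <- ncol(y)
    mx <- rowMeans(x); my <- rowMeans(y)
    vx <- rowSums((x - mx)^2) / (nx - 1); vy <- rowSums((y - my)^2) / (ny - 1)
    se <- sqrt(vx / nx + vy / ny)
    t <- (mx - my) / se
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
    p[se == 0] <- ifelse(mx[se == 0] == my[se == 0], 1, 0)
    r <- list(t = t, p = p, log2fc = mx - my)
  }
  res <- data.frame(gene = rownames(em$values), log2fc = r$log2fc,
                    t = r$t, p = r$p, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "label") <- label
  class(res) <- c("comparison_result", "data.frame")
  res
}

#' Select differentially expressed genes across comparisons
#'
#' The DEG set is the union of genes significant at `p < alpha` in at least
#' one comparison; per-comparison counts and pairwise overlaps are reported.
#'
#' @param results List of `comparison_result` objects.
#' @param alpha Significance level (default 0.001).
#' @return A `deg_set`: list with `genes` (union), `per_comparison` (named
#'   counts), `overlap` (pairwise overlap matrix), `total_calls` (sum of
#'   per-comparison counts) and `alpha`.
#' @export
select_degs <- function(results, alpha = 0.001) {
  if (!length(results)) stop("need >= 1 comparison")
  universes <- lapply(results, function(r) sort(r$gene))
  for (u in universes[-1]) {
    if (!identical(u, universes[[1]])) {
      stop("comparisons have inconsistent gene universes")
    }
  }
  labs <- vapply(seq_along(results), function(i) {
    attr(results[[i]], "label") %||% paste0("comparison", i)
  }, "")
  sig <- lapply(results, function(r) r$gene[r$p < alpha])
  names(sig) <- labs
  counts <- vapply(sig, length, 0L)
  k <- length(sig)
  overlap <- matrix(0L, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    overlap[i, j] <- length(intersect(sig[[i]], sig[[j]]))
  }
  structure(list(genes = sort(unique(unlist(sig))),
                 per_comparison = counts,
                 significant = sig,
                 overlap = overlap,
                 total_calls = sum(counts),
                 alpha = alpha),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("<deg_set: %d genes in union; %d calls over %d comparisons (alpha=%g)>\n",
              length(x$genes), x$total_calls, length(x$per_comparison), x$alpha))
  invisible(x)
}

#' Estimate the false discovery rate of a DEG selection
#'
#' Expected false positives across all comparisons (`n_comparisons * n_genes
#' * alpha`) divided by the total number of significant calls.
#'
#' @param deg_set A [select_degs()] result (or a total call count).
#' @param n_genes Number of genes tested per comparison.
#' @param n_comparisons Number of comparisons.
#' @param alpha Per-test significance level.
#' @return FDR as a fraction in `[0, 1]` (capped at 1); `NA_real_` with a
#'   warning when there are no calls.
#' @export
estimate_fdr <- function(deg_set, n_genes, n_comparisons, alpha = 0.001) {
  calls <- if (inherits(deg_set, "deg_set")) deg_set$total_calls else deg_set
  if (alpha == 0) return(0)
  if (calls == 0) {
    warning("no significant calls: FDR not available")
    return(NA_real_)
  }
  min(n_comparisons * n_genes * alpha / calls, 1)
}

#' PCA sample scores over a gene list
#'
#' Centered (unscaled) principal component analysis of the samples in the
#' space of the listed genes.
#'
#' @param em An `expression_matrix`.
#' @param genes Gene list (default: all rows).
#' @return List with `scores` (samples x components), `variance_fraction`
#'   (non-increasing, sums to <= 1) and `samples`.
#' @export
pca_scores <- function(em, genes = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  v <- em$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing) == length(genes)) stop("none of the genes are present")
    v <- v[intersect(genes, rownames(v)), , drop = FALSE]
  }
  if (nrow(v) < 2 || ncol(v) < 2) stop("need >= 2 genes and >= 2 samples")
  x <- t(v)
  if (all(apply(x, 2, stats::var) == 0)) stop("no variance in the input matrix")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, variance_fraction = vf, samples = em$samples)
}

#' Per-comparison log2 fold-change matrix with hierarchical clustering
#'
#' Computes the mean log2 fold change of each listed gene in each
#' comparison (group mean minus control mean) and orders genes by
#' hierarchical clustering of their fold-change profiles (Euclidean
#' distance, average linkage by default).
#'
#' @param em Gene-level `expression_matrix`.
#' @param comparisons Named list; each element is `list(group=, control=)`
#'   with selectors as in [differential_expression()].
#' @param genes Gene list (rows of the heatmap).
#' @param method,metric Linkage and distance for [stats::hclust()] /
#'   [stats::dist()].
#' @return List with `log2fc` (genes x comparisons, rows in dendrogram
#'   order), `order` (leaf order), `hclust` (the tree, NULL for a single
#'   gene), `skipped` (genes absent from the matrix).
#' @export
log2fc_heatmap <- function(em, comparisons, genes,
                           method = "average", metric = "euclidean") {
  stopifnot(inherits(em, "expression_matrix"), length(genes) > 0)
  skipped <- setdiff(genes, rownames(em$values))
  genes <- intersect(genes, rownames(em$values))
  if (!length(genes)) stop("no requested genes present in the matrix")
  sel <- function(s) {
    if (is.logical(s)) return(which(s))
    if (is.list(s)) {
      keep <- rep(TRUE, nrow(em$samples))
      for (nm in names(s)) keep <- keep & em$samples[[nm]] %in% s[[nm]]
      return(which(keep))
    }
    which(em$samples$sample %in% s)
  }
  fc <- vapply(comparisons, function(cmp) {
    gi <- sel(cmp$group); ci <- sel(cmp$control)
    rowMeans(em$values[genes, gi, drop = FALSE]) -
      rowMeans(em$values[genes, ci, drop = FALSE])
  }, numeric(length(genes)))
  fc <- matrix(fc, nrow = length(genes),
               dimnames = list(genes, names(comparisons)))
  if (length(genes) == 1L) {
    return(list(log2fc = fc, order = 1L, hclust = NULL, skipped = skipped))
  }
  hc <- stats::hclust(stats::dist(fc, method = metric), method = method)
  list(log2fc = fc[hc$order, , drop = FALSE], order = hc$order,
       hclust = hc, skipped = skipped)
}

#' Read per-sample feature TSVs plus a sample sheet into a feature table
#'
#' Each sample file is a TSV with columns `feature_id`, `symbol`,
#' `intensity` and the five flag columns; the sample sheet is a TSV with
#' columns `sample`, `file`, `cell_line`, `exposure`, `replicate` (paths
#' relative to the sheet's directory).
#'
#' @param sheet_path Path to the sample sheet TSV.
#' @return A [feature_table()].
#' @export
read_feature_tables <- function(sheet_path) {
  sheet <- utils::read.delim(sheet_path, stringsAsFactors = FALSE)
  dir <- dirname(sheet_path)
  tabs <- lapply(file.path(dir, sheet$file), utils::read.delim,
                 stringsAsFactors = FALSE)
  f0 <- tabs[[1]][, c("feature_id", "symbol", FLAG_COLS)]
  for (cl in FLAG_COLS) f0[[cl]] <- as.logical(f0[[cl]])
  intensity <- vapply(tabs, function(t) t$intensity, numeric(nrow(f0)))
  colnames(intensity) <- sheet$sample
  feature_table(f0, intensity, sheet[, setdiff(names(sheet), "file")])
}
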