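# Gene set enrichment analysis: weighted Kolmogorov-Smirnov running-sum
# enrichment score over a ranked gene list, with a gene-label permutation
# null, normalized scores and Benjamini-Hochberg q-values.

#' Rank genes by a signed statistic
#'
#' Genes are sorted in descending order of the metric (the signed
#' t-statistic of a comparison by default); ties are broken by gene symbol
#' in lexicographic order so the ranking is deterministic.
#'
#' @param comparison A `comparison_result` from [differential_expression()],
#'   or a data frame with columns `gene` and a metric column.
#' @param metric Column to rank by (default `"t"`).
#' @return A `ranked_list`: data frame (gene, metric) sorted descending.
#' @export
rank_genes <- function(comparison, metric = "t") {
  if (!all(c("gene", metric) %in% names(comparison))) {
    stop(sprintf("need columns 'gene' and '%s'", metric))
  }
  m <- comparison[[metric]]
  if (any(is.na(m))) stop("ranking metric contains missing values")
  if (any(is.infinite(m))) {
    # zero-variance genes yield infinite t; place them just beyond the
    # finite extremes so the ranking stays defined and deterministic
    cap <- max(abs(m[is.finite(m)]), 0) + 1
    m[is.infinite(m)] <- sign(m[is.infinite(m)]) * cap
  }
  ord <- order(-m, comparison$gene, method = "radix")
  res <- data.frame(gene = comparison$gene[ord], metric = m[ord],
                    stringsAsFactors = FALSE)
  class(res) <- c("ranked_list", "data.frame")
  res
}

# Core running-sum computation from hit positions. Hits are weighted by
# |metric|^p (normalized to sum 1), misses decrement by 1/(N - Nh). The ES
# is the maximum deviation of the running sum from zero, signed by whichever
# extreme is larger in magnitude. O(Nh) using the fact that extremes occur
# at a hit (positive side) or just before a hit (negative side).
.es_from_positions <- function(absw_p, pos, N) {
  nh <- length(pos)
  if (nh == 0L || nh == N) return(list(es = 0, degenerate = TRUE))
  pos <- sort(pos)
  w <- absw_p[pos]
  sw <- sum(w)
  if (sw == 0) {
    # all hit metrics are exactly zero: fall back to equal weights
    w <- rep(1, nh); sw <- nh
  }
  cw <- cumsum(w) / sw
  miss <- 1 / (N - nh)
  i <- seq_len(nh)
  top <- cw - (pos - i) * miss          # running sum right after each hit
  bot <- c(0, cw[-nh]) - (pos - i) * miss       # just before each hit
  es_pos <- max(top)
  es_neg <- min(bot)
  # exact +/- ties resolve to the positive branch (tolerance guards fp noise)
  es <- if (es_pos >= -es_neg - 1e-12) es_pos else es_neg
  list(es = es, degenerate = FALSE)
}

#' Enrichment score of a gene set in a ranked list
#'
#' Weighted Kolmogorov-Smirnov running sum: walking down the ranked list,
#' the sum increases by `|metric|^p` (normalized) at each set member ("hit")
#' and decreases by `1/(N - Nh)` at each non-member. The enrichment score ES
#' is the signed maximum deviation from zero.
#'
#' @param ranked A [rank_genes()] result.
#' @param set Character vector of gene symbols.
#' @param p Weight exponent (default 1; `p = 0` gives the classic KS form).
#' @return List with `es`, `running_sum` (profile over the list), `hits`
#'   (logical over the list), `size` (set size in the universe),
#'   `degenerate` (TRUE when the set covers none or all of the universe).
#' @export
enrichment_score <- function(ranked, set, p = 1) {
  stopifnot(inherits(ranked, "ranked_list") || is.data.frame(ranked))
  N <- nrow(ranked)
  hits <- ranked$gene %in% set
  nh <- sum(hits)
  if (nh == 0L) stop("gene set has empty intersection with the universe")
  absw <- abs(ranked$metric)^p
  if (nh == N) {
    return(list(es = 0, running_sum = rep(0, N), hits = hits, size = nh,
                degenerate = TRUE))
  }
  inc <- ifelse(hits, absw, 0)
  sw <- sum(inc)
  if (sw == 0) { inc <- as.numeric(hits); sw <- nh }
  steps <- inc / sw - ifelse(hits, 0, 1 / (N - nh))
  rs <- cumsum(steps)
  es_pos <- max(rs); es_neg <- min(rs)
  es <- if (es_pos >= -es_neg - 1e-12) es_pos else es_neg
  list(es = es, running_sum = rs, hits = hits, size = nh, degenerate = FALSE)
}

#' Read a GMT gene-set file
#'
#' @param path GMT path (set name, description, then member genes, tab
#'   separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, "")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

#' Permutation significance for gene-set enrichment
#'
#' Gene-label permutation null: set membership is reassigned to random
#' positions of the ranked list (`n_perm` draws), preserving set size.
#' `p = (1 + #{|ES_null| >= |ES_obs|}) / (1 + n_perm)`; NES is the observed
#' ES divided by the mean |null ES| of matching sign; q-values are
#' Benjamini-Hochberg over the tested sets.
#'
#' @param ranked A [rank_genes()] result.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for reproducibility.
#' @param weight Weight exponent passed to the running sum.
#' @param min_size,max_size Size bounds applied after intersecting each set
#'   with the measured universe.
#' @return An `enrichment_result` data frame: set, size, es, nes, p, q,
#'   direction; sets with empty intersection are skipped and listed in the
#'   `skipped` attribute.
#' @export
permutation_significance <- function(ranked, sets, n_perm = 1000, seed = 1,
                                     weight = 1, min_size = 2,
                                     max_size = Inf) {
  if (n_perm < 100) warning("n_perm < 100: permutation p-values are coarse")
  N <- nrow(ranked)
  universe <- ranked$gene
  absw <- abs(ranked$metric)^weight
  kept <- list(); skipped <- character()
  for (nm in names(sets)) {
    s <- intersect(sets[[nm]], universe)
    if (length(s) == 0) { skipped <- c(skipped, nm); next }
    if (length(s) < min_size || length(s) > max_size || length(s) == N) {
      skipped <- c(skipped, nm); next
    }
    kept[[nm]] <- s
  }
  if (!length(kept)) stop("no testable gene sets after universe intersection")
  sizes <- sort(unique(vapply(kept, length, 0L)))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  null_by_size <- lapply(sizes, function(k) {
    vapply(seq_len(n_perm), function(i) {
      .es_from_positions(absw, sample.int(N, k), N)$es
    }, 0)
  })
  names(null_by_size) <- as.character(sizes)
  rows <- lapply(names(kept), function(nm) {
    s <- kept[[nm]]
    es <- enrichment_score(ranked, s, p = weight)$es
    null <- null_by_size[[as.character(length(s))]]
    pval <- (1 + sum(abs(null) >= abs(es))) / (1 + n_perm)
    same <- null[sign(null) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    data.frame(set = nm, size = length(s), es = es, nes = nes, p = pval,
               direction = if (es >= 0) "up" else "down",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[, c("set", "size", "es", "nes", "p", "q", "direction")]
  attr(res, "skipped") <- skipped
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Report filter mirroring a "repeatedly significant" pathway callout
#'
#' Selects sets significant at `p < p_cut` in at least `min_times`
#' comparisons, or ranked in the per-comparison top `top_n` by |NES| at
#' least `min_times` times.
#'
#' @param results Named list of `enrichment_result` objects (one per
#'   comparison).
#' @param p_cut Significance threshold (default 0.001).
#' @param top_n Per-comparison top list size (default 20).
#' @param min_times Minimum number of comparisons meeting either criterion.
#' @return Data frame: set x comparison grid of NES with significance flags,
#'   restricted to the selected sets.
#' @export
enrichment_summary_grid <- function(results, p_cut = 0.001, top_n = 20,
                                    min_times = 2) {
  stopifnot(length(results) >= 1)
  labs <- names(results) %||% paste0("comparison", seq_along(results))
  hits <- new.env()
  for (i in seq_along(results)) {
    r <- results[[i]]
    sig <- r$set[r$p < p_cut]
    top <- r$set[order(-abs(r$nes))][seq_len(min(top_n, nrow(r)))]
    for (s in union(sig, top)) {
      assign(s, (if (exists(s, hits)) get(s, hits) else 0L) + 1L, hits)
    }
  }
  keep <- names(which(unlist(as.list(hits)) >= min_times))
  if (!length(keep)) return(data.frame(set = character()))
  grid <- data.frame(set = sort(keep), stringsAsFactors = FALSE)
  for (i in seq_along(results)) {
    r <- results[[i]]
    m <- match(grid$set, r$set)
    grid[[paste0("nes_", labs[i])]] <- r$nes[m]
    grid[[paste0("sig_", labs[i])]] <- !is.na(m) & r$p[m] < p_cut
  }
  grid
}
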