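# Gene set enrichment: ranking, weighted running-sum ES, permutation null.

toy_ranked <- function(metric, genes = sprintf("g%02d", seq_along(metric))) {
  r <- data.frame(gene = genes, metric = metric)
  r <- r[order(-r$metric, r$gene), ]
  rownames(r) <- NULL
  class(r) <- c("ranked_list", "data.frame")
  r
}

test_that("gene ranking is by descending statistic with lexicographic ties", {
  cmp <- data.frame(gene = c("b", "a", "d", "c", "e"),
                    t = c(2, 5, -1, 2, 0))
  r <- rank_genes(cmp)
  expect_equal(r$gene, c("a", "b", "c", "e", "d"))  # tie 2: b before c? no: lexicographic
  expect_equal(r$metric, c(5, 2, 2, 0, -1))
  # all-equal statistics: pure lexicographic order
  r0 <- rank_genes(data.frame(gene = c("z", "m", "a"), t = c(1, 1, 1)))
  expect_equal(r0$gene, c("a", "m", "z"))
  # negating the metric exactly reverses the order up to tie blocks
  rn <- rank_genes(transform(cmp, t = -t))
  expect_equal(rn$metric, rev(r$metric) * -1)
  # infinite statistics are clamped beyond the finite extremes, kept in order
  ri <- rank_genes(data.frame(gene = c("a", "b", "c"), t = c(Inf, 0, -Inf)))
  expect_equal(ri$gene, c("a", "b", "c"))
  expect_error(rank_genes(data.frame(gene = "a", t = NA_real_)), "missing")
})

test_that("enrichment score equals the plain running-sum oracle", {
  set.seed(21)
  # 10-gene universe, 3-gene set, fixed metrics
  r <- toy_ranked(round(rnorm(10, 0, 2), 2))
  set3 <- r$gene[c(1, 4, 9)]
  es <- enrichment_score(r, set3, p = 1)
  expect_equal(es$es, oracle_es(r$metric, r$gene %in% set3, p = 1),
               tolerance = 1e-12)
  # running-sum profile ends at ~0 and attains the ES
  expect_equal(es$running_sum[10], 0, tolerance = 1e-12)
  expect_equal(max(abs(es$running_sum)), abs(es$es), tolerance = 1e-12)
  # members packed at the top: ES = 1
  top <- enrichment_score(r, r$gene[1:3], p = 1)
  expect_equal(top$es, 1, tolerance = 1e-12)
  # set = universe: degenerate zero profile, flagged
  all_ <- enrichment_score(r, r$gene, p = 1)
  expect_true(all_$degenerate)
  expect_equal(all_$es, 0)
  expect_error(enrichment_score(r, c("absent1", "absent2")), "empty intersection")
})

test_that("ES is invariant to shuffling genes outside the set and antisymmetric at p = 0", {
  set.seed(22)
  r <- toy_ranked(sort(rnorm(30), decreasing = TRUE))
  s <- r$gene[c(3, 11, 12, 25)]
  es0 <- enrichment_score(r, s, p = 1)$es
  # relabel non-members (hit positions unchanged)
  r2 <- r
  out <- !(r2$gene %in% s)
  r2$gene[out] <- paste0("x", seq_len(sum(out)))
  expect_equal(enrichment_score(r2, s, p = 1)$es, es0, tolerance = 1e-15)
  # reversing the list negates the ES exactly at weight p = 0
  rrev <- r[nrow(r):1, ]
  class(rrev) <- class(r)
  expect_equal(enrichment_score(rrev, s, p = 0)$es,
               -enrichment_score(r, s, p = 0)$es, tolerance = 1e-12)
})

test_that("fast positional ES agrees with fgsea on random cases", {
  skip_if_not_installed("fgsea")
  set.seed(23)
  for (i in 1:20) {
    n <- sample(15:60, 1)
    metric <- sort(rnorm(n, 0, 2), decreasing = TRUE)
    r <- toy_ranked(metric)
    k <- sample(2:8, 1)
    s <- sample(r$gene, k)
    es <- enrichment_score(r, s, p = 1)
    ref <- fgsea::calcGseaStat(metric, selectedStats = which(r$gene %in% s),
                               gseaParam = 1)
    tie <- abs(max(es$running_sum) + min(es$running_sum)) < 1e-12
    if (tie) {
      # fgsea reports 0 on an exact extreme tie; we keep the positive branch
      expect_equal(ref, 0)
      expect_equal(es$es, max(es$running_sum), tolerance = 1e-12)
    } else {
      expect_equal(es$es, ref, tolerance = 1e-9)
    }
  }
})

test_that("permutation significance is deterministic, floors at 1/(n+1), uniform on null", {
  set.seed(24)
  r <- toy_ranked(rnorm(200))
  sets <- list(spiked = r$gene[1:8],
               random = sample(r$gene, 10))
  e1 <- permutation_significance(r, sets, n_perm = 200, seed = 7)
  e2 <- permutation_significance(r, sets, n_perm = 200, seed = 7)
  expect_identical(e1, e2)
  # a set occupying the very top hits the permutation floor
  spiked <- toy_ranked(c(seq(9, 5, length.out = 8), rnorm(192, 0, 0.5)))
  ef <- permutation_significance(spiked, list(s = spiked$gene[1:8]),
                                 n_perm = 200, seed = 3)
  expect_equal(ef$p, 1 / 201)
  expect_equal(ef$direction, "up")
  # null data, random sets: p-values approximately uniform
  set.seed(25)
  rnull <- toy_ranked(rnorm(300))
  nsets <- lapply(1:60, function(i) sample(rnull$gene, 12))
  names(nsets) <- paste0("s", 1:60)
  en <- permutation_significance(rnull, nsets, n_perm = 400, seed = 11)
  ks <- suppressWarnings(ks.test(en$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # q-values are the BH adjustment of p
  expect_equal(en$q, p.adjust(en$p, "BH"))
  expect_warning(permutation_significance(r, sets, n_perm = 50, seed = 1),
                 "coarse")
})

test_that("GMT round trip and universe intersection filtering", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
  r <- toy_ranked(rnorm(6), genes = paste0("g", 1:6))
  res <- permutation_significance(r, c(sets, list(gone = c("zz", "yy"))),
                                  n_perm = 100, seed = 1)
  expect_equal(sort(res$set), c("alpha", "beta"))
  expect_equal(attr(res, "skipped"), "gone")
})

test_that("summary grid selects repeatedly significant or top-ranked sets", {
  mk <- function(p_alpha, nes_alpha) {
    r <- data.frame(set = c("alpha", "beta", "gamma"), size = 5,
                    es = c(0.9, 0.2, -0.4), nes = c(nes_alpha, 0.5, -1),
                    p = c(p_alpha, 0.8, 0.9), q = 1,
                    direction = c("up", "up", "down"))
    class(r) <- c("enrichment_result", "data.frame")
    r
  }
  grid <- enrichment_summary_grid(list(c1 = mk(1e-4, 3), c2 = mk(1e-4, 3)),
                                  p_cut = 0.001, top_n = 1, min_times = 2)
  expect_true("alpha" %in% grid$set)
  expect_true(all(grid$sig_c1[grid$set == "alpha"]))
})
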