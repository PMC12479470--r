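test_that("gene ranking is descending in t with lexicographic tie-break", {
  expect_equal(rank_genes(c(A = 3, B = -1, C = 2))$genes, c("A", "C", "B"))
  expect_equal(rank_genes(c(B = 1, A = 1))$genes, c("A", "B"))
  expect_equal(rank_genes(c(X = 0.5))$genes, "X")
  expect_error(rank_genes(data.frame(gene = c("a", "a"), t_stat = 1:2)),
               "duplicate")
})

test_that("running-sum score reproduces the worked 5-gene example", {
  ranked <- rank_genes(c(A = 3, B = 2, C = 1, D = -1, E = -2))
  res <- enrichment_score(ranked, c("A", "C"), weight_p = 1)
  expect_equal(res$profile, c(0.75, 0.75 - 1 / 3, 2 / 3, 1 / 3, 0),
               tolerance = 1e-12)
  expect_equal(res$es, 0.75)
  expect_equal(res$argmax_pos, 1L)
  expect_equal(res$n_hit, 2L)
})

test_that("a lone top-ranked hit with unit weights scores ES = 1 at position 1", {
  # direct enumeration of the running sums: P_hit jumps to 1 at position 1
  # while P_miss is still 0, so the maximum deviation is 1 there
  ranked <- rank_genes(setNames(10:1, paste0("g", 1:10)))
  res <- enrichment_score(ranked, "g1", weight_p = 0)
  expect_equal(res$es, 1)
  expect_equal(res$argmax_pos, 1L)
  expect_equal(res$profile[2], 1 - 1 / 9, tolerance = 1e-12)
})

test_that("running sum telescopes to zero, stays in [-1,1], and mirrors under list reversal", {
  set.seed(5)
  for (i in 1:20) {
    N <- sample(6:40, 1)
    metric <- setNames(rnorm(N), paste0("g", seq_len(N)))
    k <- sample(1:(N - 1), 1)
    s <- sample(names(metric), k)
    res <- enrichment_score(rank_genes(metric), s)
    expect_lt(abs(res$profile[N]), 1e-12)
    expect_true(all(res$profile >= -1 - 1e-12 & res$profile <= 1 + 1e-12))
    expect_true(abs(res$es) <= 1 + 1e-12)
    # reversing the ranking negates the extremum
    res_rev <- enrichment_score(rank_genes(-metric), s)
    expect_equal(res_rev$es, -res$es, tolerance = 1e-12)
  }
})

test_that("running-sum score rejects empty and full overlaps", {
  ranked <- rank_genes(c(A = 2, B = 1, C = -1))
  expect_error(enrichment_score(ranked, "Z"), "no overlap")
  expect_error(enrichment_score(ranked, c("A", "B", "C")), "covers")
})

test_that("the closed-form permutation scorer agrees with the full profile", {
  set.seed(8)
  for (i in 1:50) {
    N <- sample(8:60, 1)
    metric <- setNames(rnorm(N), sprintf("g%03d", seq_len(N)))
    ranked <- rank_genes(metric)
    k <- sample(1:(N - 2), 1)
    idx <- sort(sample.int(N, k))
    s <- ranked$genes[idx]
    full <- enrichment_score(ranked, s)
    fast <- prgskit:::es_from_positions(idx, abs(ranked$metric)[idx], N)
    expect_equal(fast, full$es, tolerance = 1e-12)
  }
})

test_that("permutation p-value is deterministic under a seed and hits the add-one floor for a planted top set", {
  metric <- setNames(c(seq(10, 9, length.out = 20), rnorm(1980)),
                     sprintf("g%04d", 1:2000))
  ranked <- rank_genes(metric)
  planted <- names(metric)[1:20]
  r1 <- gsea_like_test(ranked, planted, n_perm = 999, seed = 42)
  r2 <- gsea_like_test(ranked, planted, n_perm = 999, seed = 42)
  expect_identical(r1, r2)
  expect_equal(r1$p_value, 1 / 1000)
  expect_error(gsea_like_test(ranked, planted, n_perm = 50), ">= 100")
})

test_that("permutation p-values are uniform for random null sets", {
  set.seed(3)
  metric <- setNames(rnorm(300), sprintf("g%03d", 1:300))
  ranked <- rank_genes(metric)
  ps <- replicate(250, {
    s <- sample(names(metric), 12)
    gsea_like_test(ranked, s, n_perm = 199)$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("hypergeometric tail matches exact enumeration and handles boundary cases", {
  uni <- sprintf("u%02d", 1:20)
  res <- hypergeom_test(degs = c(uni[1:3], uni[7:8]),     # n=5, k=3 in M=6
                        prgs_discrete = uni[1:6], universe = uni)
  expect_equal(res$p_value, enum_hyper_tail(20, 6, 5, 3), tolerance = 1e-12)
  expect_equal(res$p_value, 0.1313209, tolerance = 1e-6)
  expect_equal(res$details[c("N", "M", "n", "k")],
               list(N = 20L, M = 6L, n = 5L, k = 3L), ignore_attr = TRUE)

  # no overlap -> certain event, p = 1
  expect_equal(hypergeom_test(uni[7:9], uni[1:3], uni)$p_value, 1)
  # universe = query = signature -> k = min(n, M), p = 1
  expect_equal(hypergeom_test(uni, uni, uni)$p_value, 1)
  expect_error(hypergeom_test(c(uni, "zz"), uni[1:3], uni), "outside")
  expect_error(hypergeom_test(uni[1:3], "zz", uni), "disjoint")
})

test_that("hypergeometric tail equals enumeration across a parameter sweep", {
  for (N in c(5, 8, 11)) {
    uni <- sprintf("u%02d", seq_len(N))
    for (M in c(1, floor(N / 2), N - 1)) for (n in c(1, floor(N / 2), N - 1)) {
      for (k in 0:min(n, M)) {
        if (n - k > N - M) next
        degs <- c(uni[seq_len(k)], if (n > k) uni[M + seq_len(n - k)])
        p <- hypergeom_test(degs, uni[seq_len(M)], uni)$p_value
        expect_equal(p, enum_hyper_tail(N, M, n, k), tolerance = 1e-12,
                     info = sprintf("N=%d M=%d n=%d k=%d", N, M, n, k))
      }
    }
  }
})

test_that("LOESS-scaled z is ~1 for constant signal, scale-invariant, and guarded", {
  set.seed(12)
  me <- runif(60, 2, 10)
  lfc <- rep(0.7, 60)
  z <- loess_z(lfc, me)
  expect_true(all(abs(z - 1) < 0.05))
  lfc2 <- rnorm(60, 0, 0.5) * (1 + me / 10)
  expect_equal(loess_z(lfc2 * 10, me), loess_z(lfc2, me), tolerance = 1e-6)
  expect_error(loess_z(rep(1, 10), runif(10)), ">= 20")
  expect_error(loess_z(rep(1, 30), runif(29)), "mismatch")
  expect_error(loess_z(rep(0, 30), runif(30)), "zero")
})
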