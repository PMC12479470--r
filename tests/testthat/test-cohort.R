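test_that("group assignment takes the 8 lowest and up to 12 highest AUC lines around the 0.8 boundary", {
  tab <- toy_auc()
  g <- assign_groups(tab, "paclitaxel")
  expect_s3_class(g, "drug_groups")
  expect_equal(nrow(g$sensitive), 8)
  expect_equal(nrow(g$resistant), 10)     # all 10 qualifying, max is 12
  expect_true(all(g$sensitive$auc < 0.8))
  expect_true(all(g$resistant$auc >= 0.8))
  # a line at exactly the threshold is resistant
  expect_true("CL11" %in% g$resistant$cell_line)  # AUC exactly 0.80
  expect_equal(g$sensitive$cell_line, sprintf("CL%02d", 1:8))

  # resistant capped at 12
  tab2 <- rbind(tab, data.frame(cell_line = sprintf("CX%02d", 1:5),
                                drug = "paclitaxel", auc = 0.99))
  expect_equal(nrow(assign_groups(tab2, "paclitaxel")$resistant), 12)

  few <- tab[tab$auc >= 0.7, ]
  expect_error(assign_groups(few, "paclitaxel"), "need 8 sensitive")
})

test_that("group assignment is invariant to row order and breaks AUC ties lexicographically", {
  tab <- toy_auc()
  tab$auc[1:3] <- 0.5                      # tie among CL01..CL03
  shuffled <- tab[rev(seq_len(nrow(tab))), ]
  g1 <- assign_groups(tab, "paclitaxel")
  g2 <- assign_groups(shuffled, "paclitaxel")
  expect_equal(g1$sensitive, g2$sensitive)
  expect_equal(g1$resistant, g2$resistant)
  expect_equal(g1$sensitive$cell_line[order(g1$sensitive$auc)][1:3],
               c("CL01", "CL02", "CL03"))
})

test_that("extreme response bias drops drugs with >90% of lines on one side (strictly)", {
  tab <- data.frame(cell_line = sprintf("c%02d", 1:20), drug = "d",
                    auc = c(rep(0.9, 19), 0.5))
  expect_false(extreme_bias_filter(tab, "d"))          # 19/20 = 0.95 > 0.9
  tab$auc <- c(rep(0.9, 18), 0.5, 0.5)
  expect_true(extreme_bias_filter(tab, "d"))           # 0.90 is not > 0.9
  tab$auc <- c(rep(0.9, 10), rep(0.5, 10))
  expect_true(extreme_bias_filter(tab, "d"))
  expect_error(extreme_bias_filter(tab[1:5, ], "d"), ">= 10")
})

test_that("differential expression matches t.test, orients resistant minus sensitive, handles degenerate genes", {
  set.seed(3)
  lines <- sprintf("CL%02d", 1:20)
  expr <- matrix(rnorm(20 * 6), 6, 20,
                 dimnames = list(paste0("g", 1:6), lines))
  expr["g1", ] <- 7                                    # constant gene
  expr["g2", 11:20] <- expr["g2", 11:20] + 5           # up in resistant
  g <- assign_groups(toy_auc(), "paclitaxel")
  de <- differential_expression(expr, g)

  expect_equal(de$t_stat[de$gene == "g1"], 0)
  expect_equal(de$p_value[de$gene == "g1"], 1)
  expect_equal(de$direction[de$gene == "g2"], "up")

  # cross-check a regular gene against stats::t.test (pooled)
  x <- expr["g3", g$resistant$cell_line]
  y <- expr["g3", g$sensitive$cell_line]
  tt <- t.test(x, y, var.equal = TRUE)
  i <- which(de$gene == "g3")
  expect_equal(de$t_stat[i], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(de$p_value[i], tt$p.value, tolerance = 1e-12)
  # Welch variant cross-check
  deW <- differential_expression(expr, g, var_equal = FALSE)
  ttW <- t.test(x, y)
  expect_equal(deW$t_stat[i], unname(ttW$statistic), tolerance = 1e-12)
  expect_equal(deW$p_value[i], ttW$p.value, tolerance = 1e-12)

  expect_error(differential_expression(expr[, 1:15], g), "CL16")
})

test_that("swapping group labels negates t and flips direction, p unchanged", {
  set.seed(4)
  expr <- matrix(rnorm(20 * 30), 30, 20,
                 dimnames = list(paste0("g", 1:30), sprintf("CL%02d", 1:20)))
  g <- assign_groups(toy_auc(), "paclitaxel")
  swapped <- g
  swapped$sensitive <- g$resistant
  swapped$resistant <- g$sensitive
  de1 <- differential_expression(expr, g)
  de2 <- differential_expression(expr, swapped)
  expect_equal(de2$t_stat, -de1$t_stat)
  expect_equal(de2$p_value, de1$p_value)
  nz <- de1$t_stat != 0
  expect_true(all(de1$direction[nz] != de2$direction[nz]))
})

test_that("detection of a 2-sigma shift with 8v8 lines matches the exact power of the pooled t-test", {
  # analytic power at alpha = 0.01: power.t.test gives 0.826
  pow <- power.t.test(n = 8, delta = 2, sd = 1, sig.level = 0.01)$power
  set.seed(11)
  lines <- sprintf("CL%02d", 1:16)
  auc <- data.frame(cell_line = lines, drug = "d",
                    auc = rep(c(0.5, 0.9), each = 8))
  expr <- matrix(rnorm(200 * 16), 200, 16,
                 dimnames = list(paste0("g", 1:200), lines))
  expr[, 9:16] <- expr[, 9:16] + 2
  de <- differential_expression(expr, assign_groups(auc, "d"))
  hit_rate <- mean(de$p_value < 0.01)
  expect_lt(abs(hit_rate - pow), 3 * sqrt(pow * (1 - pow) / 200))
})

test_that("DEG selection applies strict cutoffs and reports the direction partition", {
  rec <- data.frame(gene = c("a", "b", "c", "d"),
                    t_stat = c(3.0, -2.8, 2.81, 0.5),
                    p_value = c(0.005, 0.01, 0.004, 0.6),
                    direction = c("up", "down", "up", "up"))
  out <- select_degs(rec)                       # p < 0.01 strict
  expect_setequal(out$gene, c("a", "c"))
  out2 <- select_degs(rec, t_min_abs = 2.8)     # |t| > 2.8 strict
  expect_setequal(out2$gene, c("a", "c"))
  out3 <- select_degs(rec, p_max = 0.011, t_min_abs = 2.8)
  expect_false("b" %in% out3$gene)              # |t| = 2.8 excluded
  expect_equal(attr(out, "n_up"), 2L)
  expect_equal(attr(out, "n_down"), 0L)
  null_rec <- data.frame(gene = "a", t_stat = 0, p_value = 1, direction = "up")
  expect_equal(nrow(select_degs(null_rec)), 0)
})

test_that("under a global null the DEG fraction at p<0.01 stays near the nominal rate", {
  set.seed(29)
  lines <- sprintf("CL%02d", 1:16)
  auc <- data.frame(cell_line = lines, drug = "d",
                    auc = rep(c(0.5, 0.9), each = 8))
  expr <- matrix(rnorm(2000 * 16), 2000, 16,
                 dimnames = list(paste0("g", 1:2000), lines))
  de <- differential_expression(expr, assign_groups(auc, "d"))
  frac <- nrow(select_degs(de)) / nrow(de)
  expect_gte(frac, 0.004)
  expect_lte(frac, 0.016)
})
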