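# Gene table construction, the logistic enrichment model and its
# satellites.

test_that("gene table applies biotype, expression and recurrence rules", {
  genes <- make_genes("chr1", c(100, 20000, 40000, 60000),
                      c(10000, 30000, 50000, 70000), "+",
                      gene_id = c("H", "A", "B", "NC"),
                      biotype = c("protein_coding", "protein_coding",
                                  "protein_coding", "lincRNA"))
  mir <- make_mirnas("chr1", 5000, 5080, "+", mirna_id = "mir-x")
  asg <- assign_hosts(mir, genes)
  calls <- make_calls(
    make_call("S1", "A", "H", "chr1:25000:+", "chr1:2000:+"),
    make_call("S2", "A", "H", "chr1:25000:+", "chr1:2000:+"),
    make_call("S3", "B", "H", "chr1:45000:+", "chr1:2000:+"),
    make_call("S4", "B", "A", "chr1:45000:+", "chr1:25000:+"))
  gt <- build_gene_table(genes, asg, calls, min_tumors = 3)
  expect_equal(sort(gt$gene_id), c("A", "B", "H"))  # lincRNA dropped
  expect_true(gt$is_host[gt$gene_id == "H"])
  expect_true(gt$fused_recurrent[gt$gene_id == "H"])   # 3 tumors as 3p
  # 2 tumors as 5p + 1 as 3p: 3 tumors overall, but recurrence demands a
  # maintained role
  expect_false(gt$fused_recurrent[gt$gene_id == "A"])
  expect_true(gt$fused_any[gt$gene_id == "B"])
  expect_equal(gt$log2_size[gt$gene_id == "H"], log2(9901), tolerance = 1e-12)
  expect_equal(gt$log2_size[gt$gene_id == "A"], log2(10001), tolerance = 1e-12)

  # expression filter: B not expressed, absent genes dropped
  expr <- matrix(c(5, 5, 5, 5, 0.2, 0.2), 3, 2, byrow = TRUE,
                 dimnames = list(c("H", "A", "B"), c("S1", "S2")))
  gt2 <- build_gene_table(genes, asg, calls, expression = expr)
  expect_equal(sort(gt2$gene_id), c("A", "H"))

  # partner absent from the annotation warns and is skipped
  calls2 <- rbind(calls, make_call("S5", "GHOST", "H", "chr1:1:+",
                                   "chr1:2000:+", call_index = 5L))
  expect_warning(gt3 <- build_gene_table(genes, asg, calls2), "absent")
  expect_false("GHOST" %in% gt3$gene_id)
})

test_that("crossover arithmetic and its degenerate branches", {
  expect_equal(mirfusion:::.crossover_bp(2.0, -0.2), 1024)
  expect_true(is.na(mirfusion:::.crossover_bp(2.0, 0)))
  expect_true(is.na(mirfusion:::.crossover_bp(1.0, 0.1)))   # host wins everywhere
  expect_false(is.na(mirfusion:::.crossover_bp(-1.0, 0.1))) # crossing from below
})

test_that("a null host effect is estimated near zero", {
  set.seed(41)
  n <- 5000
  H <- rbinom(n, 1, 0.1)
  S <- rnorm(n, 14, 2)
  y <- rbinom(n, 1, plogis(-4 + 0.25 * S))
  tab <- data.frame(fused_any = y == 1, is_host = H == 1, log2_size = S)
  f <- fit_logistic(tab)
  expect_true(f$converged)
  expect_lt(abs(f$coefficients[["betaH"]]), 3 * f$se[["betaH"]])
})

test_that("coefficients match a brute-force likelihood maximiser on a hand dataset", {
  tab <- data.frame(
    fused_any = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE,
                  TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    is_host = c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0) == 1,
    log2_size = c(10, 11, 12, 13, 14, 15, 10, 11, 12, 13, 14, 15))
  f <- fit_logistic(tab, with_interaction = FALSE)
  X <- cbind(1, tab$is_host, tab$log2_size)
  y <- as.numeric(tab$fused_any)
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  gr <- function(b) -drop(crossprod(X, y - plogis(drop(X %*% b))))
  opt <- optim(c(0, 0, 0), nll, gr, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 5000))
  expect_equal(unname(f$coefficients[c("beta0", "betaH", "betaS")]),
               opt$par, tolerance = 1e-5)
})

test_that("size-adjusted OR is exp(betaH) with a Wald interval, and errors unconverged", {
  fake <- structure(list(coefficients = c(beta0 = -1, betaH = log(2),
                                          betaS = 0.1, betaHS = NA),
                         se = c(beta0 = 0.1, betaH = 0.25, betaS = 0.01,
                                betaHS = NA),
                         wald_p = c(beta0 = 0, betaH = 0.005, betaS = 0,
                                    betaHS = NA),
                         converged = TRUE, with_interaction = FALSE),
                    class = "logistic_fit")
  or <- size_adjusted_odds_ratio(fake)
  expect_equal(or$odds_ratio, 2)
  expect_equal(or$ci_low, exp(log(2) - qnorm(0.975) * 0.25))
  fake$converged <- FALSE
  expect_error(size_adjusted_odds_ratio(fake), "converge")
})

test_that("the size-adjusted OR is invariant to rescaling size units", {
  set.seed(17)
  n <- 4000
  H <- rbinom(n, 1, 0.1)
  S <- rnorm(n, 14, 2)
  y <- rbinom(n, 1, plogis(-4 + 0.8 * H + 0.25 * S))
  t1 <- data.frame(fused_any = y == 1, is_host = H == 1, log2_size = S)
  t2 <- t1; t2$log2_size <- log2(1000 * 2^S)  # kb instead of bp
  f1 <- fit_logistic(t1); f2 <- fit_logistic(t2)
  expect_equal(size_adjusted_odds_ratio(f1)$odds_ratio,
               size_adjusted_odds_ratio(f2)$odds_ratio, tolerance = 1e-6)
})

test_that("degenerate model inputs error cleanly", {
  tab <- data.frame(fused_any = rep(TRUE, 10), is_host = rep(c(TRUE, FALSE), 5),
                    log2_size = rnorm(10, 14))
  expect_error(fit_logistic(tab), "single class")
  tab$fused_any <- rep(c(TRUE, FALSE), 5)
  tab$is_host <- TRUE
  expect_error(fit_logistic(tab), "constant predictor")
})

test_that("control-element selection is rate-driven and null elements fit near zero", {
  set.seed(23)
  n <- 10000
  tab <- data.frame(
    fused_any = rbinom(n, 1, 0.3) == 1,
    is_host = rbinom(n, 1, 0.06) == 1,
    log2_size = rnorm(n, 14, 2),
    element_everywhere = TRUE,
    element_attarget = rbinom(n, 1, 0.06) == 1,
    element_null = rbinom(n, 1, 0.055) == 1)
  tab$element_everywhere <- runif(n) < 0.9
  sel <- select_control_elements(tab, target_rate = 0.06)
  expect_false(sel$rates$selected[sel$rates$class == "everywhere"])
  expect_true(sel$rates$selected[sel$rates$class == "attarget"])
  expect_true(sel$rates$selected[sel$rates$class == "null"])
  # elements drawn independently of the outcome: betaH consistent with 0
  hits <- replicate(100, {
    t2 <- data.frame(fused_any = rbinom(n, 1, 0.3) == 1,
                     is_host = rbinom(n, 1, 0.06) == 1,
                     log2_size = rnorm(n, 14, 2),
                     element_x = rbinom(n, 1, 0.06) == 1)
    f <- select_control_elements(t2, target_rate = 0.06,
                                 with_interaction = FALSE)$fits$x
    abs(f$coefficients[["betaH"]]) < qnorm(0.975) * f$se[["betaH"]]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("in-frame fractions per gene and group means match a tally", {
  genes <- make_genes("chr1", c(100, 20000, 40000), c(10000, 30000, 50000),
                      "+", gene_id = c("H", "A", "B"))
  mir <- make_mirnas("chr1", 5000, 5080, "+", mirna_id = "mir-x")
  asg <- assign_hosts(mir, genes)
  calls <- make_calls(
    make_call("S1", "A", "H", "chr1:25000:+", "chr1:2000:+", "in-frame"),
    make_call("S2", "A", "H", "chr1:25000:+", "chr1:2500:+", "other"),
    make_call("S3", "A", "H", "chr1:25000:+", "chr1:3000:+", "in-frame"),
    make_call("S4", "A", "H", "chr1:25000:+", "chr1:3500:+", "out-of-frame"),
    make_call("S5", "B", "A", "chr1:45000:+", "chr1:25000:+", "other"))
  res <- inframe_fraction_analysis(calls, asg, mir, genes)
  hrow <- res$per_gene[res$per_gene$gene_id == "H" & res$per_gene$role == "3p", ]
  expect_equal(hrow$frac_inframe, 0.5)
  expect_equal(hrow$n_fusions, 4L)
  expect_true(hrow$has_mirna)
  arow <- res$per_gene[res$per_gene$gene_id == "A" & res$per_gene$role == "3p", ]
  expect_equal(arow$frac_inframe, 0)
  expect_false(arow$has_mirna)
  expect_true(all(res$cdf$cum_fraction > 0 & res$cdf$cum_fraction <= 1))

  co <- random_cohort(19)
  res2 <- inframe_fraction_analysis(co$filtered, co$assignments, co$mirnas,
                                    co$genes)
  calls <- dedupe_fusion_calls(co$filtered)
  g3 <- res2$per_gene[res2$per_gene$role == "3p", ]
  for (g in head(g3$gene_id, 5)) {
    sub <- calls[!is.na(calls$gene3_id) & calls$gene3_id == g, ]
    expect_equal(g3$frac_inframe[g3$gene_id == g],
                 mean(sub$frame_class == "in-frame"))
  }
})

test_that("5' partner expression: equal inputs give p = 1, planted shifts are detected", {
  genes <- make_genes("chr1", seq(100, by = 30000, length.out = 8),
                      seq(100, by = 30000, length.out = 8) + 10000, "+",
                      gene_id = sprintf("G%d", 1:8))
  mir <- make_mirnas("chr1", start(genes)[1] + 5000, start(genes)[1] + 5080,
                     "+", mirna_id = "mir-x")
  asg <- assign_hosts(mir, genes)
  samples <- paste0("S", 1:6)
  # G1 hosts mir-x; calls place G2..G4 as 5' partners over an including
  # breakpoint, G5..G7 as 5' partners of a non-host 3' gene (G8)
  calls <- make_calls(
    make_call("S1", "G2", "G1", "chr1:35000:+", sprintf("chr1:%d:+", start(genes)[1] + 1000)),
    make_call("S2", "G3", "G1", "chr1:65000:+", sprintf("chr1:%d:+", start(genes)[1] + 1000)),
    make_call("S3", "G4", "G1", "chr1:95000:+", sprintf("chr1:%d:+", start(genes)[1] + 1000)),
    make_call("S4", "G5", "G8", "chr1:125000:+", sprintf("chr1:%d:+", start(genes)[8] + 1000)),
    make_call("S5", "G6", "G8", "chr1:155000:+", sprintf("chr1:%d:+", start(genes)[8] + 1000)),
    make_call("S6", "G7", "G8", "chr1:185000:+", sprintf("chr1:%d:+", start(genes)[8] + 1000)))
  ev <- map_mirnas_to_fusions(calls, asg, mir, genes)

  flat <- matrix(7, 8, 6, dimnames = list(sprintf("G%d", 1:8), samples))
  res <- partner5_expression_by_category(calls, ev, flat, pseudocount = 0)
  expect_true(all(res$tests$p_value[!is.na(res$tests$p_value)] == 1))

  shifted <- flat
  shifted[c("G2", "G3", "G4"), ] <- 28    # +2 in log2
  res2 <- partner5_expression_by_category(calls, ev, shifted, pseudocount = 0)
  row <- res2$tests[res2$tests$category_a == "host_mirna_included" &
                      res2$tests$category_b == "non_host", ]
  expect_equal(row$mean_diff, 2, tolerance = 1e-9)
})

test_that("a planted 1-log2 shift in 5' partner expression is recovered", {
  diffs <- sapply(1:10, function(seed) {
    set.seed(seed)
    co <- random_cohort(seed, partner5_shift = 1)
    res <- partner5_expression_by_category(co$filtered, co$events,
                                           co$expression$gene_fpkm)
    row <- res$tests[res$tests$category_a == "host_mirna_included" &
                       res$tests$category_b == "no_fusion", ]
    if (nrow(row) == 0 || is.na(row$mean_diff)) NA_real_ else row$mean_diff
  })
  expect_equal(mean(diffs, na.rm = TRUE), 1, tolerance = 0.35)
})
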