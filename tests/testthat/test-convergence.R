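# Recurrence summaries, convergence counts, Fisher overlap machinery.

mk_event <- function(mirna, sample, role, partner = "P1", included = TRUE,
                     host = "H1", frame = "other", idx = 1L) {
  data.frame(mirna_id = mirna, host_gene_id = host, role = role,
             sample_id = sample, partner_gene_id = partner,
             included = included, frame_class = frame,
             breakpoint = "chr1:1:+", bp_pos = 1, call_index = idx,
             stringsAsFactors = FALSE)
}

test_that("recurrence counts distinct tumors per role with the >=3 threshold", {
  ev <- rbind(mk_event("mir-a", "S1", "3p"))
  r <- recurrence_summary(ev)
  expect_equal(r$n_tumors_any, 1L)
  expect_false(r$recurrent_any)

  ev <- rbind(mk_event("mir-a", "S1", "3p"), mk_event("mir-a", "S2", "3p"),
              mk_event("mir-a", "S3", "3p"), mk_event("mir-a", "S4", "5p"))
  r <- recurrence_summary(ev)
  expect_equal(r$n_tumors_3p, 3L)
  expect_equal(r$n_tumors_5p, 1L)
  expect_true(r$recurrent_3p)
  expect_false(r$recurrent_5p)
  expect_true(r$recurrent_any)
  expect_equal(recurrence_census(r)$any, c(1L, 1L))

  # counts are invariant to duplicated events in one (sample, role) cell
  r2 <- recurrence_summary(rbind(ev, ev, ev))
  expect_equal(r, r2)

  # excluded events never count
  ev$included <- FALSE
  expect_equal(nrow(recurrence_summary(ev)), 0L)
})

test_that("convergence counts distinct 5' partners and multi-partner tumors", {
  ev <- rbind(mk_event("mir-a", "S1", "3p", "P1"),
              mk_event("mir-a", "S1", "3p", "P2"))
  ct <- convergence_table(ev)
  expect_equal(ct$n_partner5_genes, 2L)
  expect_equal(ct$n_tumors_multi_partner, 1L)
  expect_equal(ct$n_tumors_3p, 1L)

  ev <- rbind(mk_event("mir-a", "S1", "3p", "P1"),
              mk_event("mir-a", "S2", "3p", "P1"),
              mk_event("mir-a", "S3", "3p", "P1"))
  ct <- convergence_table(ev)
  expect_equal(ct$n_partner5_genes, 1L)
  expect_equal(ct$n_tumors_multi_partner, 0L)
  expect_equal(ct$n_tumors_3p, 3L)
})

test_that("convergence and recurrence match a group-by oracle on random event sets", {
  set.seed(77)
  for (draw in 1:200) {
    n <- sample(1:40, 1)
    ev <- do.call(rbind, lapply(seq_len(n), function(i) {
      mk_event(sample(paste0("mir-", 1:5), 1), sample(paste0("S", 1:8), 1),
               sample(c("3p", "5p"), 1),
               sample(c(paste0("P", 1:6), NA), 1),
               included = runif(1) < 0.8, idx = i)
    }))
    ct <- convergence_table(ev)
    inc <- ev[ev$included, , drop = FALSE]
    for (mid in unique(inc$mirna_id)) {
      e <- inc[inc$mirna_id == mid, ]
      e3 <- e[e$role == "3p", ]
      row <- ct[ct$mirna_id == mid, ]
      expect_equal(row$n_tumors_any, length(unique(e$sample_id)))
      expect_equal(row$n_tumors_3p, length(unique(e3$sample_id)))
      expect_equal(row$n_partner5_genes,
                   length(unique(na.omit(e3$partner_gene_id))))
      multi <- sum(vapply(split(e3$partner_gene_id, e3$sample_id),
                          function(p) length(unique(na.omit(p))) > 1,
                          logical(1)))
      expect_equal(row$n_tumors_multi_partner, multi)
      # invariant chain
      expect_lte(row$n_tumors_multi_partner, row$n_tumors_3p)
      expect_lte(row$n_tumors_3p, row$n_tumors_any)
    }
  }
})

test_that("fisher_exact handles symmetry, boundaries and zero margins", {
  r <- fisher_exact(5, 5, 5, 5)
  expect_equal(r$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(r$p_value, 1)

  r <- fisher_exact(0, 10, 10, 0)
  expect_equal(r$odds_ratio, 0)
  o <- enum_fisher(0, 10, 10, 0)
  expect_equal(r$p_value, o$p, tolerance = 1e-10)

  r <- fisher_exact(10, 2, 3, 15)
  o <- enum_fisher(10, 2, 3, 15)
  expect_equal(r$p_value, o$p, tolerance = 1e-9)
  expect_equal(r$odds_ratio, o$or, tolerance = 1e-4)
  expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)

  z <- fisher_exact(0, 0, 5, 5)
  expect_true(z$or_undefined)
  expect_equal(z$p_value, 1)
  expect_error(fisher_exact(0, 0, 0, 0), "margin")
  expect_error(fisher_exact(-1, 1, 1, 1), "non-negative")
})

test_that("confidence limits invert the noncentral hypergeometric tails", {
  for (cells in list(c(10, 2, 3, 15), c(4, 9, 7, 3), c(1, 12, 5, 20))) {
    r <- do.call(fisher_exact, as.list(cells))
    lo <- enum_nchg_cdf(cells[1], cells[2], cells[3], cells[4], r$ci_low)
    hi <- enum_nchg_cdf(cells[1], cells[2], cells[3], cells[4], r$ci_high)
    # the estimator inverts the tails by numeric root finding, so allow
    # its root tolerance
    expect_equal(unname(lo["upper"]), 0.025, tolerance = 0.01)
    expect_equal(unname(hi["lower"]), 0.025, tolerance = 0.01)
  }
})

test_that("external overlap builds the right 2x2 over the universe", {
  universe <- paste0("mir-", 1:20)
  r <- external_overlap(paste0("mir-", 1:10), paste0("mir-", 11:20), universe)
  expect_equal(r$odds_ratio, 0)
  r <- external_overlap(paste0("mir-", 1:8), paste0("mir-", 1:8), universe)
  expect_equal(r$odds_ratio, Inf)
  o <- enum_fisher(8, 0, 0, 12)
  expect_equal(r$p_value, o$p, tolerance = 1e-9)
  expect_error(external_overlap("a", "b", character(0)), "universe")
  expect_error(external_overlap("zzz", "mir-1", universe), "subsets")

  set.seed(5)
  for (i in 1:100) {
    a <- sample(universe, sample(0:20, 1))
    b <- sample(universe, sample(0:20, 1))
    r <- external_overlap(a, b, universe)
    m <- c(length(intersect(a, b)), length(setdiff(a, b)),
           length(setdiff(b, a)))
    want <- fisher_exact(m[1], m[2], m[3], 20 - sum(m))
    expect_equal(r$p_value, want$p_value)
    expect_equal(r$odds_ratio, want$odds_ratio)
  }
})

test_that("catalogue matching: symbols over-approximates coordinates", {
  genes <- make_genes("chr1", c(100, 20000, 40000), c(10000, 30000, 50000),
                      "+", gene_id = c("H1", "H2", "P"),
                      symbol = c("VMP1", "MCM7", "PX"))
  mir <- make_mirnas("chr1", c(8000, 21000), c(8080, 21080), "+",
                     mirna_id = c("mir-21x", "mir-93x"))
  asg <- assign_hosts(mir, genes)

  cat_sym <- data.frame(gene5_symbol = c("PX", "PX"),
                        gene3_symbol = c("VMP1", "ZZZ"),
                        stringsAsFactors = FALSE)
  got <- match_external_catalogue(cat_sym, "symbols", genes, mir, asg)
  expect_equal(got, "mir-21x")

  # coordinates mode applies the inclusion rule: breakpoint downstream of
  # the hairpin does not match
  cat_co <- make_calls(
    make_call("C1", "P", "H1", "chr1:45000:+", "chr1:9000:+"),
    make_call("C2", "P", "H2", "chr1:45000:+", "chr1:20500:+"))
  got <- match_external_catalogue(cat_co, "coordinates", genes, mir, asg)
  expect_equal(got, "mir-93x")
  expect_error(match_external_catalogue(cat_sym, "coordinates", genes, mir,
                                        asg), "coordinates mode")

  # subset property over random catalogues
  set.seed(13)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    hosts <- sample(c("H1", "H2"), n, replace = TRUE)
    bps <- sample(seq(200, 29000, by = 250), n)
    cc <- do.call(make_calls, lapply(seq_len(n), function(k)
      make_call(paste0("C", k), "P", hosts[k], "chr1:45000:+",
                sprintf("chr1:%d:+", bps[k]))))
    cc$gene5_symbol <- "PX"
    cc$gene3_symbol <- genes$symbol[match(cc$gene3_id, genes$gene_id)]
    co_set <- suppressWarnings(
      match_external_catalogue(cc, "coordinates", genes, mir, asg))
    sy_set <- match_external_catalogue(cc, "symbols", genes, mir, asg)
    expect_true(all(co_set %in% sy_set))
  }
})

test_that("miRNA content fractions hit 0 and 1 in the degenerate cases and match a tally", {
  genes <- make_genes("chr1", c(100, 20000), c(10000, 30000), "+",
                      gene_id = c("H", "P"))
  mir <- make_mirnas("chr1", 5000, 5080, "+", mirna_id = "mir-x")
  asg <- assign_hosts(mir, genes)
  # every fused gene (just H as 3p with upstream bp) contains the miRNA
  calls <- make_calls(make_call("S1", "P", "H", "chr1:25000:+", "chr1:2000:+"))
  fr <- mirna_content_fractions(calls, asg, mir, genes)
  expect_equal(fr$fraction[fr$scope == "all" & fr$role == "3p"], 1)
  expect_equal(fr$n_genes[fr$scope == "all" & fr$role == "any"], 2L)
  # no inclusion at all
  calls2 <- make_calls(make_call("S1", "P", "H", "chr1:25000:+", "chr1:9000:+"))
  fr2 <- mirna_content_fractions(calls2, asg, mir, genes)
  expect_true(all(fr2$fraction == 0))

  co <- random_cohort(31)
  fr3 <- mirna_content_fractions(co$filtered, co$assignments, co$mirnas,
                                 co$genes)
  # brute-force tally for the all/3p cell
  calls <- dedupe_fusion_calls(co$filtered)
  ev <- co$events
  denom <- unique(na.omit(calls$gene3_id))
  denom <- denom[denom %in% co$genes$gene_id]
  num <- intersect(denom,
                   unique(ev$host_gene_id[ev$included & ev$role == "3p"]))
  row <- fr3[fr3$scope == "all" & fr3$role == "3p", ]
  expect_equal(row$n_genes, length(denom))
  expect_equal(row$fraction, length(num) / length(denom))
})
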