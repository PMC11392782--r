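test_that("gene_layer_status applies the causal/coloc rules", {
  # strongly supported probe: causal and coloc-supported
  p <- data.frame(probe_id = "cg00348858", q_smr = 1.77e-5, p_heidi = 0.5,
                  pp_h4 = 0.86)
  st <- gene_layer_status(p)
  expect_true(st$causal); expect_true(st$coloc)
  expect_equal(st$best_probe, "cg00348858")

  # pleiotropy exclusion and FDR failure
  expect_false(gene_layer_status(
    data.frame(probe_id = "a", q_smr = 0.04, p_heidi = 0.01, pp_h4 = 0.9))$causal)
  expect_false(gene_layer_status(
    data.frame(probe_id = "a", q_smr = 0.06, p_heidi = 0.5, pp_h4 = 0.9))$causal)

  # multiple probes aggregate by "any passes"; best = coloc-preferred min q
  p2 <- data.frame(probe_id = c("a", "b", "c"),
                   q_smr = c(0.001, 0.01, 0.2),
                   p_heidi = c(0.5, 0.5, 0.5),
                   pp_h4 = c(0.1, 0.8, 0.9))
  st2 <- gene_layer_status(p2)
  expect_true(st2$causal); expect_true(st2$coloc)
  expect_equal(st2$best_probe, "b")
})

test_that("assign_tier implements the tier definitions", {
  mk <- function(causal, coloc) list(causal = causal, coloc = coloc, best_probe = "x")
  expect_equal(assign_tier(list(m = mk(TRUE, TRUE), e = mk(TRUE, TRUE)))$tier, "tier1")
  expect_equal(assign_tier(list(m = mk(TRUE, TRUE), e = mk(TRUE, FALSE)))$tier, "tier2")
  expect_equal(assign_tier(list(m = mk(TRUE, FALSE), e = mk(TRUE, FALSE),
                                p = mk(TRUE, FALSE)))$tier, "tier3")
  expect_equal(assign_tier(list(m = mk(TRUE, TRUE)))$tier, "unclassified")
  expect_equal(assign_tier(list(m = mk(FALSE, FALSE), e = mk(TRUE, FALSE)))$tier,
               "unclassified")
})

test_that("the bundled multi-omics evidence table reproduces every printed tier", {
  ev <- multiomics_evidence_example()
  tiers <- classify_tiers(ev)
  expect_equal(nrow(tiers), 18L)
  expect_equal(sum(tiers$tier == "tier1"), 3L)
  expect_equal(sum(tiers$tier == "tier2"), 2L)
  expect_equal(sum(tiers$tier == "tier3"), 13L)
  expected <- unique(ev[, c("gene_id", "expected_tier")])
  got <- tiers$tier[match(expected$gene_id, tiers$gene_id)]
  expect_equal(got, expected$expected_tier)
  # spot checks of the headline genes
  expect_equal(tiers$tier[tiers$gene_id == "TUFM"], "tier1")
  expect_equal(tiers$tier[tiers$gene_id == "COX19"], "tier2")
  expect_equal(tiers$tier[tiers$gene_id == "GATM"], "tier3")
})

test_that("tier assignment is permutation-invariant and monotone in pp_h4", {
  ev <- multiomics_evidence_example()
  set.seed(3)
  sh <- ev[sample(nrow(ev)), ]
  expect_equal(classify_tiers(sh)[order(classify_tiers(sh)$gene_id), ],
               classify_tiers(ev)[order(classify_tiers(ev)$gene_id), ],
               ignore_attr = TRUE)

  # raising any probe's pp_h4 can only move a gene toward a lower tier number
  tiers0 <- classify_tiers(ev)
  rank0 <- match(tiers0$tier, c("tier1", "tier2", "tier3"))
  set.seed(4)
  for (k in 1:10) {
    ev2 <- ev
    i <- sample(nrow(ev2), 1)
    ev2$pp_h4[i] <- min(1, ev2$pp_h4[i] + runif(1))
    t2 <- classify_tiers(ev2)
    r2 <- match(t2$tier[match(tiers0$gene_id, t2$gene_id)],
                c("tier1", "tier2", "tier3"))
    expect_true(all(r2 <= rank0))
  }

  # an unreachable pp threshold forces every classified gene to tier3
  all3 <- classify_tiers(ev, pp_threshold = 1.01)
  expect_true(all(all3$tier == "tier3"))
})

test_that("tissue validation reproduces the printed six-gene result", {
  tv <- tissue_validate(tissue_validation_example())
  expect_equal(tv$validated_genes,
               sort(c("HIBCH", "SPATA20", "STYXL1", "TUFM", "MTHFS", "DCXR")))
  tab <- tv$table
  liver <- tab[tab$gene_id == "HIBCH" & tab$tissue == "Liver", ]
  expect_true(liver$validated)
  expect_equal(liver$coloc_support, "strong")
  # HEIDI failures are not validated even with small p
  tp <- tab[tab$gene_id == "TUFM" & tab$tissue == "Pancreas", ]
  expect_false(tp$validated)

  # a gene with no tissue data is flagged, not validated
  nd <- rbind(tissue_validation_example()[, c("gene_id", "tissue", "p_smr",
                                              "p_heidi", "pp_h4")],
              data.frame(gene_id = "ISCA2", tissue = "Liver", p_smr = NA,
                         p_heidi = NA, pp_h4 = NA))
  tv2 <- tissue_validate(nd)
  expect_equal(tv2$table$status[tv2$table$gene_id == "ISCA2"], "no data")
  expect_false("ISCA2" %in% tv2$validated_genes)
})

test_that("cross-omics MR recovers chain directions and flags consistency", {
  reg <- simulate_region(region_spec(25, rho = 0.8), seed = 19)
  gene <- data.frame(probe_id = "cg1", gene_id = "GENE1",
                     chr = reg$snps$chr[1], start = min(reg$snps$pos),
                     end = max(reg$snps$pos), layer = "methylation")
  ch <- chain_spec(theta_me = -0.5, theta_ed = 0.5, causal_index = 12,
                   var_qtl = 0.05, n_meth = 20000, n_expr = 50000,
                   n_cases = 10000, n_controls = 40000)
  n_consistent <- 0; n_me_neg <- 0
  for (s in 1:100) {
    lay <- simulate_chain(reg, ch, seed = s)
    me <- cross_omics_mr(lay$methylation, lay$expression, gene, reg$ld)
    ed <- run_layer(lay$expression, lay$disease, gene, reg$ld)
    md <- run_layer(lay$methylation, lay$disease, gene, reg$ld)
    if (nrow(me) && nrow(ed) && nrow(md)) {
      n_me_neg <- n_me_neg + (me$b_xy < 0)
      n_consistent <- n_consistent +
        direction_consistent(me$b_xy, ed$b_xy, md$b_xy)
    }
  }
  expect_gte(n_consistent / 100, 0.8)
  expect_gte(n_me_neg / 100, 0.95)

  # null chain: methylation -> expression rarely significant
  ch0 <- chain_spec(theta_me = 0, theta_ed = 0, causal_index = 12,
                    var_qtl = 0.05, n_meth = 20000, n_expr = 50000)
  n_sig <- 0
  for (s in 1:100) {
    lay <- simulate_chain(reg, ch0, seed = s)
    me <- run_layer(lay$methylation, lay$expression, gene, reg$ld)
    if (nrow(me) && me$flag == "significant") n_sig <- n_sig + 1
  }
  expect_lte(n_sig / 100, 0.1)

  # the headline mediation pattern: meth->expr negative, expr->disease
  # positive, meth->disease negative is directionally consistent
  expect_true(direction_consistent(-0.4, 0.3, -0.12))
})
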