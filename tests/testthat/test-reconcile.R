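test_that("congruent trees reconcile to zero under both models", {
  st <- parse_newick("((A,B),(C,D));")
  gt <- parse_newick("((a,b),(c,d));")
  map <- c(a = "A", b = "B", c = "C", d = "D")
  dl <- lca_reconcile_dl(gt, st, map)
  dtl <- dtl_reconcile(gt, st, map)
  expect_equal(dl$score, 0)
  expect_equal(dtl$score, 0)
  expect_equal(dtl$n_transfer, 0)
  expect_identical(compare_models(gt, st, map)$verdict, "no signal")
})

test_that("score is the cost-weighted event count, at the printed costs", {
  costs <- event_costs()       # Notung defaults 1.5 / 3.0 / 1.0
  st <- parse_newick("((A,B),C);")
  gt <- parse_newick("((a,c),b);")
  map <- c(a = "A", b = "B", c = "C")
  dl <- lca_reconcile_dl(gt, st, map, costs)
  expect_equal(dl$score,
               costs$dup * dl$n_dup + costs$loss * dl$n_loss)
  dtl <- dtl_reconcile(gt, st, map, costs)
  expect_equal(dtl$score, costs$dup * dtl$n_dup +
                 costs$transfer * dtl$n_transfer + costs$loss * dtl$n_loss)
  expect_lte(dtl$score, dl$score)
})

test_that("DL via LCA equals the exhaustive optimum on small instances", {
  set.seed(31)
  species3 <- all_rooted_topologies(c("A", "B", "C"))
  genes4 <- all_rooted_topologies(c("a", "b", "c", "d"))
  maps <- list(c(a = "A", b = "B", c = "C", d = "A"),
               c(a = "A", b = "A", c = "B", d = "C"),
               c(a = "C", b = "B", c = "B", d = "A"))
  costs <- event_costs()
  for (sn in species3) {
    st <- parse_newick(paste0(sn, ";"))
    for (gn in genes4[seq(1, length(genes4), by = 3)]) {
      gt <- parse_newick(paste0(gn, ";"))
      for (map in maps) {
        dl <- lca_reconcile_dl(gt, st, map, costs)
        want <- oracle_dtl(gt, st, map, costs, allow_transfer = FALSE)
        expect_equal(dl$score, want,
                     info = paste(gn, "in", sn, paste(map, collapse = "")))
      }
    }
  }
})

test_that("DTL dynamic program equals brute-force enumeration exhaustively", {
  costs <- event_costs()
  # all 5-leaf gene topologies into all 3-leaf species topologies
  species3 <- all_rooted_topologies(c("A", "B", "C"))
  genes5 <- all_rooted_topologies(c("a", "b", "c", "d", "e"))
  map5 <- c(a = "A", b = "B", c = "C", d = "A", e = "B")
  for (sn in species3) {
    st <- parse_newick(paste0(sn, ";"))
    for (gn in genes5) {
      gt <- parse_newick(paste0(gn, ";"))
      dtl <- dtl_reconcile(gt, st, map5, costs)
      expect_equal(dtl$score, oracle_dtl(gt, st, map5, costs),
                   info = paste(gn, "in", sn))
    }
  }
  # a sample of 4-leaf gene topologies into all 4-leaf species topologies
  species4 <- all_rooted_topologies(c("A", "B", "C", "D"))
  genes4 <- all_rooted_topologies(c("a", "b", "c", "d"))
  map4 <- c(a = "A", b = "B", c = "C", d = "D")
  set.seed(8)
  for (sn in species4) {
    st <- parse_newick(paste0(sn, ";"))
    for (gn in sample(genes4, 4)) {
      gt <- parse_newick(paste0(gn, ";"))
      dtl <- dtl_reconcile(gt, st, map4, costs)
      expect_equal(dtl$score, oracle_dtl(gt, st, map4, costs),
                   info = paste(gn, "in", sn))
    }
  }
})

test_that("DTL never exceeds DL and a planted transfer is HGT-favored", {
  sp <- simulate_species_tree(10, seed = 3)
  favored <- 0; tried <- 0
  for (s in 1:40) {
    sim <- simulate_gene_tree(sp, rates = c(dup = 0, transfer = 0.08,
                                            loss = 0), seed = s)
    res <- compare_models(sim$gene_tree, sp, sim$leaf_map)
    expect_lte(res$dtl$score, res$dl$score)
    if (sum(sim$events$type == "transfer") >= 1 && res$dl$score > 0) {
      tried <- tried + 1
      if (res$verdict == "HGT-favored") favored <- favored + 1
    }
  }
  expect_gte(tried, 5)
  expect_gte(favored / tried, 0.95)
})

test_that("planted transfer counts are recovered without dups and losses", {
  sp <- simulate_species_tree(10, seed = 17)
  match_n <- 0
  for (s in 1:60) {
    sim <- simulate_gene_tree(sp, rates = c(dup = 0, transfer = 0.08,
                                            loss = 0), seed = 200 + s)
    planted <- sum(sim$events$type == "transfer")
    est <- dtl_reconcile(sim$gene_tree, sp, sim$leaf_map)$n_transfer
    if (est == planted) match_n <- match_n + 1
  }
  expect_gte(match_n / 60, 0.9)
})

test_that("reconciliation rejects bad input", {
  st <- parse_newick("((A,B),C);")
  gt <- parse_newick("((a,b),c);")
  expect_error(lca_reconcile_dl(gt, st, c(a = "A", b = "B")), "unmapped")
  expect_error(dtl_reconcile(gt, st, c(a = "A", b = "B", c = "Z")),
               "not in species tree")
  multi <- parse_newick("(a,b,c);")
  expect_error(dtl_reconcile(multi, st, c(a = "A", b = "B", c = "C")),
               "binary")
  expect_error(event_costs(dup = -1), ">= 0")
})
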