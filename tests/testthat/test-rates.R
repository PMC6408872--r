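test_that("NG86 handles identical and single-difference codon pairs", {
  r0 <- ng86("ATGGGTCAT", "ATGGGTCAT")
  expect_equal(r0$Sd, 0)
  expect_equal(r0$Nd, 0)
  expect_equal(r0$dS, 0)
  expect_equal(r0$dN, 0)
  expect_equal(r0$S + r0$N, 9)

  # TTT -> TTC is one synonymous change; on a single codon pS = 1/S >= 3/4
  r1 <- ng86("TTT", "TTC")
  expect_equal(r1$Sd, 1)
  expect_equal(r1$Nd, 0)
  expect_equal(r1$S, 1 / 3)
  expect_true(r1$saturated_s)
  expect_true(is.na(r1$dS))

  expect_error(ng86("ATG", "ATGA"), "equal length")
  expect_error(ng86("ATGA", "ATGA"), "divisible")
  expect_error(ng86("TGAATG", "ATGATG"), "stop codon at codon index 1")
})

test_that("NG86 is symmetric and conserves S + N", {
  set.seed(51)
  for (i in 1:10) {
    p <- evolve_codon_pair(omega = 0.5, t = 0.2, n_codons = 40,
                           seed = 600 + i)
    a <- ng86(p$cds1, p$cds2)
    b <- ng86(p$cds2, p$cds1)
    expect_equal(a$Sd, b$Sd, tolerance = 1e-9)
    expect_equal(a$Nd, b$Nd, tolerance = 1e-9)
    expect_equal(a$S, b$S, tolerance = 1e-9)
    expect_equal(a$S + a$N, 3 * a$codons_used)
  }
})

test_that("NG86 counts equal the exhaustive codon-path enumeration", {
  set.seed(52)
  for (i in 1:6) {
    p <- evolve_codon_pair(omega = 0.4, t = 0.6, n_codons = 30,
                           seed = 700 + i)
    got <- ng86(p$cds1, p$cds2)
    want <- oracle_ng86_counts(p$cds1, p$cds2)
    expect_equal(got$S, want$S, tolerance = 1e-9)
    expect_equal(got$N, want$N, tolerance = 1e-9)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-9)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-9)
  }
})

test_that("dS and dN grow with divergence time and omega is recovered", {
  times <- c(0.05, 0.2, 0.5)
  ds <- dn <- numeric(length(times))
  for (k in seq_along(times)) {
    acc_s <- acc_n <- 0
    for (s in 1:10) {
      p <- evolve_codon_pair(omega = 0.2, t = times[k], n_codons = 300,
                             seed = 800 + 10 * k + s)
      r <- ng86(p$cds1, p$cds2)
      acc_s <- acc_s + r$dS; acc_n <- acc_n + r$dN
    }
    ds[k] <- acc_s / 10; dn[k] <- acc_n / 10
  }
  expect_true(all(diff(ds) > 0))
  expect_true(all(diff(dn) > 0))

  omegas <- vapply(1:50, function(s) {
    p <- evolve_codon_pair(omega = 0.2, t = 0.3, n_codons = 500,
                           seed = 900 + s)
    ng86(p$cds1, p$cds2)$omega
  }, numeric(1))
  expect_gte(mean(omegas), 0.1)
  expect_lte(mean(omegas), 0.3)

  # t = 0 leaves the sequences identical
  p0 <- evolve_codon_pair(omega = 1, t = 0, n_codons = 100, seed = 1)
  expect_identical(p0$cds1, p0$cds2)
})

test_that("identical loci give unit ratios; genus pairs with gaps warn", {
  tr <- parse_newick("((A1:0.1,A2:0.1):0.3,(B1:0.1,B2:0.1):0.3);")
  params <- gtr_gamma_params()
  aln <- evolve_sequences(tr, params, 800, seed = 3)
  genus_map <- c(A1 = "GenA", A2 = "GenA", B1 = "GenB", B2 = "GenB")
  tab <- genus_distance_ratios(list(rpb2 = aln, toxin = aln), genus_map)
  expect_equal(tab$ratio, 1, tolerance = 1e-9)

  sub <- aln[names(aln) != "B1"]
  aln_sub <- msa(stats::setNames(unclass(sub), names(sub)))
  genus_map2 <- c(A1 = "GenA", A2 = "GenA", B2 = "GenB")
  tab2 <- genus_distance_ratios(list(rpb2 = aln, toxin = aln_sub),
                                genus_map)
  expect_equal(nrow(tab2), 1)   # still one pair, computed on shared taxa
})

test_that("a recently transferred locus shows depressed inter-genus distance", {
  # housekeeping divergence at realistic rpb2 depth (cross-genus paths
  # 0.30-0.57 subst/site); the toxin locus moved recently, so its
  # cross-genus paths are 0.11-0.13 (true ratios 2.7-4.4, inside the
  # published 2-6x band)
  vertical <- parse_newick(paste0(
    "((A1:0.05,A2:0.05):0.25,((B1:0.05,B2:0.05):0.1,",
    "(C1:0.05,C2:0.05):0.1):0.12);"))
  transferred <- parse_newick(paste0(
    "((A1:0.05,A2:0.05):0.02,((B1:0.05,B2:0.05):0.005,",
    "(C1:0.05,C2:0.05):0.005):0.005);"))
  params <- gtr_gamma_params(shape = 1)
  genus_map <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B", C1 = "C", C2 = "C")
  ok <- 0
  for (s in 1:100) {
    rpb2 <- evolve_sequences(vertical, params, 1000, seed = 3000 + s)
    popb <- evolve_sequences(transferred, params, 1000, seed = 6000 + s)
    tab <- genus_distance_ratios(list(rpb2 = rpb2, POPB = popb), genus_map)
    if (min(tab$ratio) > 2) ok <- ok + 1
  }
  expect_gte(ok, 95)
})
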