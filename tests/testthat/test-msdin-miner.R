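test_that("leader profile training behaves and thresholds cover training set", {
  prof <- build_leader_profile(c("MSDINAARLP", "MSDINAARLP"), leader_len = 5)
  # identical training leaders put maximal weight on the observed residue
  for (p in 1:5) {
    aa <- substr("MSDIN", p, p)
    expect_equal(names(which.max(prof$probs[, p])), aa)
  }
  train <- msdin_training("MDAN", n = 5)
  prof2 <- build_leader_profile(train, leader_len = 5)
  expect_true(all(prof2$training_scores >= prof2$threshold))
  expect_error(build_leader_profile("MSDIN"), "at least 2")
  # the Lepiota precursor outscores shuffled 5-mers
  real <- score_leader(prof2, "MDANATRLPIWGIGCNPWTPESVNDTLTKDLS")
  set.seed(9)
  rand <- vapply(1:200, function(i) {
    score_leader(prof2, paste0(sample(amatox:::.AA20, 9, TRUE), collapse = ""))
  }, numeric(1))
  expect_gt(real, max(rand))
})

test_that("extract_core decomposes precursors by the proline rule", {
  p <- extract_core("MDANATRLPIWGIGCNPWTPESVNDTLTKDLS")
  expect_identical(p$leader, "MDANATRLP")
  expect_identical(p$core, "IWGIGCNP")
  expect_identical(p$follower, "WTPESVNDTLTKDLS")
  expect_equal(p$core_span, c(10, 17))
  # decomposition concatenates back to the input
  expect_identical(paste0(p$leader, p$core, p$follower), p$peptide)

  expect_error(extract_core("MXXPAAAAAAAAQQQ"), "NoCoreFound")

  # generator round trip over assorted cores
  cores <- c("IWGIGCNP", "GAYDDVP", "FFQPPEFRP", "LIQRGERP", "AWLVDCPP")
  for (s in 1:10) {
    g <- plant_msdin_contig(length = 600, gc = 0.45,
                            core = cores[(s %% 5) + 1],
                            leader_style = "MSDIN", n_introns = 0,
                            seed = 900 + s)
    dec <- extract_core(g$truth$precursor)
    expect_identical(dec$core, g$truth$core)
    expect_identical(paste0(dec$leader, dec$core, dec$follower),
                     g$truth$precursor)
  }
})

test_that("scan_orfs recovers planted genes exactly and flags none elsewhere", {
  train <- msdin_training("MDAN", n = 5)
  prof <- build_leader_profile(train, leader_len = 5)

  # intron-less plant scanned without intron moves: exactly one exact hit
  g0 <- plant_msdin_contig(length = 1500, gc = 0.49, core = "IWGIGCNP",
                           leader_style = "MDAN", n_introns = 0, seed = 21)
  hits0 <- scan_orfs(g0$contig, prof, max_introns = 0)
  expect_equal(length(hits0), 1)
  expect_equal(hits0[[1]]$gene_model$interval, g0$truth$gene_interval)
  expect_identical(hits0[[1]]$precursor$peptide, g0$truth$precursor)
  # with spliced scanning on, the exact model is still present at one locus
  hits0b <- scan_orfs(g0$contig, prof)
  expect_true(any(vapply(hits0b, function(h) {
    all(h$gene_model$interval == g0$truth$gene_interval) &&
      identical(h$precursor$peptide, g0$truth$precursor)
  }, logical(1))))
  expect_equal(length(mine_loci(hits0b)), 1)

  # intron-bearing plant: exact model among reported splice variants
  g1 <- plant_msdin_contig(length = 1500, gc = 0.49, core = "IWGIGCNP",
                           leader_style = "MDAN", n_introns = 1, seed = 22)
  hits1 <- scan_orfs(g1$contig, prof)
  expect_gte(length(hits1), 1)
  exact <- vapply(hits1, function(h) {
    all(h$gene_model$interval == g1$truth$gene_interval) &&
      h$gene_model$strand == g1$truth$strand &&
      identical(h$precursor$peptide, g1$truth$precursor)
  }, logical(1))
  expect_true(any(exact))
  expect_equal(length(mine_loci(hits1)), 1)
  for (h in hits1) {
    expect_true(validate_gene_model(h$gene_model, g1$contig[[1]]))
  }
})

test_that("random GC-matched contigs yield essentially no hits", {
  train <- msdin_training("MDAN", n = 5)
  prof <- build_leader_profile(train, leader_len = 5)
  set.seed(99)
  clean <- 0
  for (s in 1:50) {
    bg <- paste0(sample(c("G", "C", "A", "T"), 1500, TRUE,
                        prob = c(0.245, 0.245, 0.255, 0.255)), collapse = "")
    hits <- scan_orfs(c(rand = bg), prof)
    if (length(hits) == 0) clean <- clean + 1
  }
  expect_gte(clean, 48)
})

test_that("mutated planted genes are still recovered most of the time", {
  train <- msdin_training("MDAN", n = 5)
  prof <- build_leader_profile(train, leader_len = 5)
  found <- 0
  for (s in 1:30) {
    g <- plant_msdin_contig(length = 1500, gc = 0.49, core = "IWGIGCNP",
                            leader_style = "MDAN", n_introns = 1,
                            seed = 400 + s, mutate_aa = 0.05)
    hits <- scan_orfs(g$contig, prof)
    hit_ok <- any(vapply(hits, function(h) {
      all(h$gene_model$interval == g$truth$gene_interval) &&
        identical(h$precursor$peptide, g$truth$precursor)
    }, logical(1)))
    if (hit_ok) found <- found + 1
  }
  expect_gte(found / 30, 0.9)
})

test_that("emitted gene models satisfy the exon/translation invariant", {
  train <- msdin_training("MSDIN", n = 5)
  prof <- build_leader_profile(train, leader_len = 5)
  for (s in 31:35) {
    g <- plant_msdin_contig(length = 1200, gc = 0.5, core = "IWGIGCNP",
                            leader_style = "MSDIN", n_introns = 1, seed = s)
    for (h in scan_orfs(g$contig, prof)) {
      gm <- h$gene_model
      total <- sum(vapply(gm$exons, function(e) e[2] - e[1], numeric(1)))
      expect_equal(total, 3 * (nchar(gm$protein) + 1))
      expect_true(validate_gene_model(gm, g$contig[[1]]))
    }
  }
})

test_that("spliced_align recovers exact exon structure", {
  # genomic == CDS: single exon covering everything
  cds <- paste0(c(amatox:::.reverse_translate("MDANATRLPIWGIGCNPW", 0.5),
                  "TAA"), collapse = "")
  gm <- spliced_align(cds, cds)
  expect_equal(length(gm$exons), 1)
  expect_equal(gm$exons[[1]], c(0, nchar(cds)))

  # one synthetic intron at a known position: two exons, exact boundaries
  set.seed(12)
  intron <- paste0("GT", paste0(sample(c("A", "T", "G", "C"), 51, TRUE),
                                collapse = ""), "AG")
  pos <- 25
  genomic <- paste0(substr(cds, 1, pos), intron,
                    substr(cds, pos + 1, nchar(cds)))
  gm2 <- spliced_align(genomic, cds)
  expect_equal(length(gm2$exons), 2)
  expect_equal(gm2$exons[[1]], c(0, pos))
  expect_equal(gm2$exons[[2]], c(pos + nchar(intron), nchar(genomic)))
  expect_identical(gm2$cds, cds)
})

test_that("spliced_align equals exhaustive intron-placement enumeration", {
  # brute force: try every (GT..AG) placement set with <= 2 introns whose
  # removal leaves exactly the CDS length, score = matches/mismatches plus
  # the intron penalty; the DP must attain the same optimum
  brute <- function(genomic, cds, match = 2, mismatch = -3,
                    intron_open = -10, min_intron = 40) {
    n <- nchar(genomic); m <- nchar(cds)
    gch <- strsplit(genomic, "")[[1]]; cch <- strsplit(cds, "")[[1]]
    gts <- which(gch == "G" & c(gch[-1], "") == "T")
    ags <- which(c("", gch[-n]) == "A" & gch == "G")
    score_exons <- function(introns) {
      keep <- rep(TRUE, n)
      for (iv in introns) keep[iv[1]:iv[2]] <- FALSE
      ex <- gch[keep]
      if (length(ex) != m) return(-Inf)
      sum(ifelse(ex == cch, match, mismatch)) +
        intron_open * length(introns)
    }
    best <- if (n == m) score_exons(list()) else -Inf
    cands <- list()
    for (g1 in gts) for (a1 in ags[ags >= g1 + min_intron - 1]) {
      cands[[length(cands) + 1L]] <- c(g1, a1)
    }
    for (iv in cands) {
      best <- max(best, score_exons(list(iv)))
    }
    if (length(cands) >= 2) {
      for (i in seq_along(cands)) for (j in seq_along(cands)) {
        if (cands[[i]][2] < cands[[j]][1] - 1) {
          best <- max(best, score_exons(list(cands[[i]], cands[[j]])))
        }
      }
    }
    best
  }
  set.seed(33)
  for (rep in 1:6) {
    aa <- paste0(sample(amatox:::.AA20, sample(20:28, 1), TRUE),
                 collapse = "")
    cds <- paste0(c(amatox:::.reverse_translate(aa, 0.5), "TAA"),
                  collapse = "")
    genomic <- cds
    n_intr <- sample(0:2, 1)
    at <- sort(sample(5:(nchar(cds) - 5), n_intr))
    for (k in rev(seq_len(n_intr))) {
      ilen <- sample(40:60, 1)
      intron <- paste0("GT", paste0(sample(c("A", "T", "C", "G"), ilen - 4,
                                           TRUE), collapse = ""), "AG")
      genomic <- paste0(substr(genomic, 1, at[k]), intron,
                        substr(genomic, at[k] + 1, nchar(genomic)))
    }
    gm <- spliced_align(genomic, cds, gap_open = -1e4, gap_ext = -1e4)
    expect_equal(attr(gm, "score"), brute(genomic, cds), tolerance = 1e-9)
  }
})

test_that("toxin gene distance reports clustering verdicts", {
  mk <- function(contig, s, e, id) {
    gene_model(contig, "+", list(c(s, e)), protein = "M", cds = "ATGTAA",
               id = id)
  }
  near <- toxin_gene_distance(list(mk("c1", 1000, 1100, "a"),
                                   mk("c1", 2100, 2200, "b")))
  expect_true(near$clustered)
  expect_equal(near$gap_bp, 1000)

  far <- toxin_gene_distance(list(mk("c4", 0, 100, "popb"),
                                  mk("c27", 0, 100, "ama1")))
  expect_false(far$same_contig)
  expect_false(far$clustered)

  # strict inequality at the threshold boundary
  edge <- toxin_gene_distance(list(mk("c1", 0, 100, "a"),
                                   mk("c1", 50100, 50200, "b")),
                              threshold = 50000)
  expect_equal(edge$gap_bp, 50000)
  expect_false(edge$clustered)

  single <- toxin_gene_distance(list(mk("c1", 0, 100, "a")))
  expect_equal(nrow(single), 0)
  expect_identical(attr(single, "note"), "single gene")
})
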