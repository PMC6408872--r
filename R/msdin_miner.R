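# Mining MSDIN-family toxin precursor genes from assembled contigs:
# leader-peptide profile scan over six-frame ORFs (optionally spliced across
# one GT..AG intron), precursor decomposition into leader | core | follower,
# splice-aware alignment of homolog CDS for POP-style gene models, and the
# toxin-gene clustering report.

.AA20 <- c("A","R","N","D","C","E","Q","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

#' Build a leader-peptide position weight matrix
#'
#' Trains a PWM (Laplace pseudocount, log2 odds against a uniform background)
#' on the leader region of known precursor peptides. MSDIN-family leaders are
#' strongly conserved in their first residues (MSDIN in Amanita, MFDTN in
#' Galerina, M-DAN in Lepiota), which is what makes a short profile an
#' effective mining probe.
#'
#' @param known_precursors character vector (>= 2) of precursor amino-acid
#'   sequences.
#' @param leader_len number of leading residues to model.
#' @param pseudocount Laplace pseudocount added per residue.
#' @param margin bits subtracted from the minimum training score to set the
#'   reporting threshold.
#' @return A `motif_profile`: list with `pwm` (20 x leader_len log2-odds
#'   matrix), `probs`, `leader_len`, `threshold`.
#' @export
build_leader_profile <- function(known_precursors, leader_len = 5,
                                 pseudocount = 1, margin = 1) {
  if (length(known_precursors) < 2L) {
    stop("need at least 2 training precursors")
  }
  if (any(nchar(known_precursors) < leader_len)) {
    stop("leader_len exceeds the shortest training sequence")
  }
  leaders <- toupper(substr(known_precursors, 1L, leader_len))
  counts <- matrix(pseudocount, nrow = 20, ncol = leader_len,
                   dimnames = list(.AA20, NULL))
  for (s in leaders) {
    aa <- strsplit(s, "")[[1]]
    ok <- aa %in% .AA20
    for (p in which(ok)) counts[aa[p], p] <- counts[aa[p], p] + 1
  }
  probs <- sweep(counts, 2, colSums(counts), "/")
  pwm <- log2(probs / (1 / 20))
  scores <- vapply(leaders, function(s) .score_leader_pwm(pwm, s), numeric(1))
  out <- list(pwm = pwm, probs = probs, leader_len = leader_len,
              threshold = min(scores) - margin, training_scores = scores)
  class(out) <- "motif_profile"
  out
}

.score_leader_pwm <- function(pwm, leader) {
  aa <- strsplit(toupper(leader), "")[[1]]
  L <- ncol(pwm)
  if (length(aa) < L) return(-Inf)
  s <- 0
  for (p in seq_len(L)) {
    s <- s + if (aa[p] %in% rownames(pwm)) pwm[aa[p], p] else min(pwm[, p])
  }
  s
}

#' Score a candidate leader against a profile
#'
#' @param profile a `motif_profile`.
#' @param peptide candidate peptide (scored on its first `leader_len`
#'   residues).
#' @return Log2-odds score (bits).
#' @export
score_leader <- function(profile, peptide) {
  stopifnot(inherits(profile, "motif_profile"))
  .score_leader_pwm(profile$pwm, substr(peptide, 1L, profile$leader_len))
}

#' Decompose an MSDIN precursor into leader, core and follower
#'
#' The mature toxin core is the 7-10 residue, proline-terminated segment
#' released by prolyl oligopeptidase cleavage after the leader's terminal
#' proline. Among admissible (leader-P, core-P) pairs the one whose leader
#' length is closest to 9 is chosen (ties to the shorter leader).
#'
#' @param precursor_aa precursor amino-acid sequence (25-45 aa typical).
#' @return An `msdin_precursor`: list with `peptide`, `leader`, `core`,
#'   `follower`, `core_span` (1-based residue interval).
#' @examples
#' extract_core("MDANATRLPIWGIGCNPWTPESVNDTLTKDLS")
#' @export
extract_core <- function(precursor_aa) {
  pep <- toupper(precursor_aa)
  aa <- strsplit(pep, "")[[1]]
  ppos <- which(aa == "P")
  cand <- NULL
  for (i in ppos) {
    nxt <- ppos[ppos > i]
    for (j in nxt) {
      len <- j - i
      if (len >= 7 && len <= 10) {
        cand <- rbind(cand, c(i = i, j = j, dev = abs(i - 9)))
      }
    }
  }
  if (is.null(cand)) {
    stop("NoCoreFound: no admissible proline pair with a 7-10 residue core")
  }
  cand <- cand[order(cand[, "dev"], cand[, "i"]), , drop = FALSE]
  i <- unname(cand[1, "i"]); j <- unname(cand[1, "j"])
  out <- list(peptide = pep,
              leader = substr(pep, 1L, i),
              core = substr(pep, i + 1L, j),
              follower = substr(pep, j + 1L, nchar(pep)),
              core_span = c(i + 1L, j))
  class(out) <- "msdin_precursor"
  out
}

#' @export
print.msdin_precursor <- function(x, ...) {
  cat(sprintf("MSDIN precursor (%d aa): %s | %s | %s  core %d-%d\n",
              nchar(x$peptide), x$leader, x$core, x$follower,
              x$core_span[1], x$core_span[2]))
  invisible(x)
}

#' Construct a gene model
#'
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons list of 0-based half-open coding intervals on the forward
#'   strand, in genomic order.
#' @param protein deduced protein (no terminal stop symbol).
#' @param cds spliced coding sequence including the stop codon.
#' @param id optional identifier.
#' @return A `gene_model` with the genomic span in `interval`.
#' @export
gene_model <- function(contig, strand, exons, protein, cds, id = NULL) {
  stopifnot(strand %in% c("+", "-"), length(exons) >= 1L)
  exons <- exons[order(vapply(exons, `[`, numeric(1), 1L))]
  starts <- vapply(exons, `[`, numeric(1), 1L)
  ends <- vapply(exons, `[`, numeric(1), 2L)
  if (any(starts >= ends)) stop("empty exon interval")
  if (length(exons) > 1L && any(starts[-1] < ends[-length(ends)])) {
    stop("overlapping exons")
  }
  out <- list(contig = contig, strand = strand,
              interval = c(min(starts), max(ends)),
              exons = exons, protein = protein, cds = cds, id = id)
  class(out) <- "gene_model"
  out
}

#' Intron intervals of a gene model
#'
#' @param gm a `gene_model`.
#' @return List of 0-based half-open intervals between consecutive exons.
#' @export
gene_introns <- function(gm) {
  ex <- gm$exons
  if (length(ex) < 2L) return(list())
  lapply(seq_len(length(ex) - 1L), function(i) c(ex[[i]][2], ex[[i + 1L]][1]))
}

.CODE_VEC <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::GENETIC_CODE
    code
  }
})

# fast codon-lookup translation (unknown/ambiguous codons -> X)
.translate_dna <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  starts <- 3L * (seq_len(n) - 1L) + 1L
  aa <- unname(.CODE_VEC()[substring(dna, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

.revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Check gene-model invariants against genomic sequence
#'
#' Verifies that exons are disjoint and ordered, every intron starts GT and
#' ends AG, and the concatenated exons translate to the stored protein with
#' a terminal stop (so that `sum(|exon|) == 3 * (nchar(protein) + 1)`).
#'
#' @param gm a `gene_model`.
#' @param contig_seq forward-strand contig sequence.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_gene_model <- function(gm, contig_seq) {
  for (intr in gene_introns(gm)) {
    s <- substr(contig_seq, intr[1] + 1L, intr[2])
    if (gm$strand == "-") s <- .revcomp(s)
    if (substr(s, 1L, 2L) != "GT" || substr(s, nchar(s) - 1L, nchar(s)) != "AG") {
      stop("non-canonical intron (not GT..AG)")
    }
  }
  pieces <- vapply(gm$exons, function(e) {
    substr(contig_seq, e[1] + 1L, e[2])
  }, character(1))
  cds <- paste0(pieces, collapse = "")
  if (gm$strand == "-") cds <- .revcomp(cds)
  if (nchar(cds) != 3L * (nchar(gm$protein) + 1L)) {
    stop("exon lengths do not sum to 3*(protein length + 1)")
  }
  prot <- .translate_dna(cds)
  if (substr(prot, nchar(prot), nchar(prot)) != "*" ||
      substr(prot, 1L, nchar(prot) - 1L) != gm$protein) {
    stop("exon concatenation does not translate to the stored protein")
  }
  invisible(TRUE)
}

# Enumerate candidate precursors from one strand of a contig.
# Returns a list of candidates: list(a, stop_end, exons (strand-local,
# 0-based half-open), protein, cds).
.scan_strand <- function(S, min_aa, max_aa, max_introns, intron_len) {
  L <- nchar(S)
  chars <- strsplit(S, "")[[1]]
  atg <- which(chars == "A" & c(chars[-1], "") == "T" &
               c(chars[-(1:2)], "", "") == "G") - 1L   # 0-based
  gt <- which(chars == "G" & c(chars[-1], "") == "T") - 1L
  ag_end <- which(c("", chars[-L]) == "A" & chars == "G")  # 1-based end pos
  out <- list()
  max_cds <- 3L * (max_aa + 1L)
  try_candidate <- function(a, exons) {
    # trim the last exon so the spliced length is a codon multiple
    total <- sum(vapply(exons, function(e) e[2] - e[1], numeric(1)))
    rem <- total %% 3L
    if (rem > 0L) {
      last <- exons[[length(exons)]]
      if (last[2] - last[1] <= rem) return(NULL)
      exons[[length(exons)]] <- c(last[1], last[2] - rem)
    }
    cds <- paste0(vapply(exons, function(e) substr(S, e[1] + 1L, e[2]),
                         character(1)), collapse = "")
    if (nchar(cds) < 3L) return(NULL)
    prot <- .translate_dna(cds)
    k <- regexpr("*", prot, fixed = TRUE)
    if (k < 1L) return(NULL)
    naa <- k - 1L
    if (naa < min_aa || naa > max_aa) return(NULL)
    # trim exons to end exactly at the stop codon
    keep <- 3L * (naa + 1L)
    trimmed <- list(); used <- 0L
    for (e in exons) {
      w <- e[2] - e[1]
      if (used + w >= keep) {
        trimmed[[length(trimmed) + 1L]] <- c(e[1], e[1] + (keep - used))
        used <- keep
        break
      }
      trimmed[[length(trimmed) + 1L]] <- e
      used <- used + w
    }
    if (used < keep) return(NULL)
    cds <- paste0(vapply(trimmed, function(e) substr(S, e[1] + 1L, e[2]),
                         character(1)), collapse = "")
    list(a = a, exons = trimmed, protein = substr(prot, 1L, naa), cds = cds)
  }
  for (a in atg) {
    # intron-less ORF
    cand <- try_candidate(a, list(c(a, min(L, a + max_cds))))
    if (!is.null(cand)) out[[length(out) + 1L]] <- cand
    if (max_introns >= 1L) {
      g_ok <- gt[gt > a & gt < a + max_cds]
      for (g in g_ok) {
        e_ok <- ag_end[ag_end - g >= intron_len[1] & ag_end - g <= intron_len[2]]
        for (e in e_ok) {
          if (e >= L) next
          cand <- try_candidate(a, list(c(a, g),
                                        c(e, min(L, e + max_cds - (g - a)))))
          if (!is.null(cand) && length(cand$exons) == 2L) {
            out[[length(out) + 1L]] <- cand
          }
        }
      }
    }
  }
  out
}

#' Scan a contig for MSDIN-family precursor genes
#'
#' Translates ATG..stop open reading frames on both strands (all six
#' frames), optionally re-assembled across one canonical GT..AG intron
#' inside the coding region, and keeps candidates whose leader scores at or
#' above the profile threshold and whose peptide decomposes into
#' leader | core | follower under [extract_core()]. Overlapping candidates
#' sharing a stop codon are collapsed to the highest-scoring (then longest)
#' one.
#'
#' @param contig contig sequence (string) or a length-1 named character
#'   vector.
#' @param profile a `motif_profile` from [build_leader_profile()].
#' @param min_aa,max_aa precursor length bounds (aa).
#' @param max_introns 0 or 1 coding introns considered.
#' @param intron_len intron length range (bp).
#' @param contig_name contig name for reported models.
#' @return A list of `mine_hit` objects: each has `gene_model`, `precursor`,
#'   `score`, `family = "MSDIN"`.
#' @export
scan_orfs <- function(contig, profile, min_aa = 25, max_aa = 45,
                      max_introns = 1, intron_len = c(40, 200),
                      contig_name = NULL) {
  if (is.null(contig_name)) {
    contig_name <- if (!is.null(names(contig))) names(contig)[1] else "contig"
  }
  S_fwd <- toupper(unname(contig[1]))
  L <- nchar(S_fwd)
  hits <- list()
  for (strand in c("+", "-")) {
    S <- if (strand == "+") S_fwd else .revcomp(S_fwd)
    for (cand in .scan_strand(S, min_aa, max_aa, max_introns, intron_len)) {
      sc <- score_leader(profile, cand$protein)
      if (sc < profile$threshold) next
      prec <- tryCatch(extract_core(cand$protein), error = function(e) NULL)
      if (is.null(prec)) next
      exons <- cand$exons
      if (strand == "-") {
        exons <- rev(lapply(exons, function(e) c(L - e[2], L - e[1])))
      }
      gm <- gene_model(contig_name, strand, exons, cand$protein, cand$cds)
      hit <- list(gene_model = gm, precursor = prec, score = sc,
                  family = "MSDIN")
      class(hit) <- "mine_hit"
      hits[[length(hits) + 1L]] <- hit
    }
  }
  if (!length(hits)) return(list())
  # drop exact duplicates (same strand + exon set), then rank: leader score
  # (desc), precursor length closest to the canonical 34 aa, leftmost start
  key <- vapply(hits, function(h) {
    paste(h$gene_model$strand,
          paste(unlist(h$gene_model$exons), collapse = ","))
  }, character(1))
  hits <- hits[!duplicated(key)]
  sc <- vapply(hits, `[[`, numeric(1), "score")
  dev <- vapply(hits, function(h) abs(nchar(h$gene_model$protein) - 34),
                numeric(1))
  at <- vapply(hits, function(h) h$gene_model$interval[1], numeric(1))
  hits[order(-sc, dev, at)]
}

#' Group mine hits into loci
#'
#' Splice variants of one gene share genomic space; this groups hits whose
#' genomic spans overlap on the same strand. Within a locus the first hit in
#' [scan_orfs()] ranking order is the representative.
#'
#' @param hits list of `mine_hit` from [scan_orfs()].
#' @return List of loci; each is a list with `best` (representative hit),
#'   `hits` (all variants) and `span` (union interval).
#' @export
mine_loci <- function(hits) {
  if (!length(hits)) return(list())
  loci <- list()
  for (h in hits) {
    iv <- h$gene_model$interval
    placed <- FALSE
    for (i in seq_along(loci)) {
      l <- loci[[i]]
      if (identical(l$strand, h$gene_model$strand) &&
          identical(l$contig, h$gene_model$contig) &&
          iv[1] < l$span[2] && l$span[1] < iv[2]) {
        loci[[i]]$hits <- c(l$hits, list(h))
        loci[[i]]$span <- c(min(l$span[1], iv[1]), max(l$span[2], iv[2]))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      loci[[length(loci) + 1L]] <- list(best = h, hits = list(h),
                                        span = iv,
                                        strand = h$gene_model$strand,
                                        contig = h$gene_model$contig)
    }
  }
  loci
}

#' Splice-aware alignment of a coding sequence to genomic DNA
#'
#' Aligns a homolog (or the gene's own) CDS end-to-end against genomic DNA
#' with affine gaps plus an intron move that opens only at GT, closes only
#' at AG, costs a fixed opening penalty and nothing per base. Genomic flanks
#' outside the alignment are free. Ties prefer the leftmost intron start.
#'
#' @param genomic genomic DNA (string).
#' @param reference_cds in-frame coding sequence of a homolog, including the
#'   stop codon.
#' @param intron_len minimum intron length is taken from `intron_len[1]`
#'   (canonical fungal introns are short; no upper bound is enforced by the
#'   recursion).
#' @param match,mismatch,gap_open,gap_ext,intron_open alignment scores.
#' @param contig_name,strand annotation for the returned model.
#' @param score_floor minimum acceptable score; below it the function errors
#'   with `NoModel`.
#' @return A `gene_model` carrying the exon intervals, deduced protein and
#'   spliced CDS, with the alignment score in `attr(, "score")`.
#' @export
spliced_align <- function(genomic, reference_cds, intron_len = c(40, 2000),
                          match = 2, mismatch = -3, gap_open = -6,
                          gap_ext = -2, intron_open = -10,
                          contig_name = "contig", strand = "+",
                          score_floor = 0) {
  g <- toupper(unname(genomic[1]))
  cds <- toupper(unname(reference_cds[1]))
  res <- .spliced_align_cpp(g, cds, match, mismatch, gap_open, gap_ext,
                            intron_open, as.integer(intron_len[1]))
  if (res$score < score_floor) {
    stop("NoModel: best spliced-alignment score ", res$score,
         " below floor ", score_floor)
  }
  exons <- mapply(function(s, e) c(s, e), res$exon_start, res$exon_end,
                  SIMPLIFY = FALSE)
  spliced <- paste0(vapply(exons, function(e) substr(g, e[1] + 1L, e[2]),
                           character(1)), collapse = "")
  prot <- if (nchar(spliced) %% 3L == 0L) .translate_dna(spliced) else
    .translate_dna(substr(spliced, 1L, 3L * (nchar(spliced) %/% 3L)))
  prot <- sub("\\*$", "", prot)
  gm <- gene_model(contig_name, strand, exons, prot, spliced)
  attr(gm, "score") <- res$score
  gm
}

#' Pairwise distance report for mined toxin genes
#'
#' Same-contig pairs report their genomic gap in bp; different-contig pairs
#' are unlinked at assembly level. The clustering verdict is `TRUE` only for
#' a same-contig gap strictly below the threshold.
#'
#' @param hits list of `mine_hit` or `gene_model` objects (>= 1).
#' @param threshold clustering distance threshold in bp (default 50 kb).
#' @return Data frame with one row per pair: `gene_a`, `gene_b`,
#'   `same_contig`, `gap_bp` (NA across contigs), `clustered`; or a
#'   zero-row frame with attribute `note = "single gene"` for < 2 hits.
#' @export
toxin_gene_distance <- function(hits, threshold = 50000) {
  gms <- lapply(hits, function(h) if (inherits(h, "mine_hit")) h$gene_model else h)
  n <- length(gms)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      same_contig = logical(), gap_bp = numeric(),
                      clustered = logical())
  if (n < 2L) {
    attr(empty, "note") <- "single gene"
    return(empty)
  }
  rows <- list()
  ids <- vapply(seq_along(gms), function(i) {
    if (!is.null(gms[[i]]$id)) gms[[i]]$id else paste0("gene", i)
  }, character(1))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- gms[[i]]; b <- gms[[j]]
    same <- identical(a$contig, b$contig)
    gap <- if (same) {
      max(0, max(a$interval[1], b$interval[1]) -
             min(a$interval[2], b$interval[2]))
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = ids[i], gene_b = ids[j], same_contig = same, gap_bp = gap,
      clustered = same && !is.na(gap) && gap < threshold)
  }
  do.call(rbind, rows)
}
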