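# Pairwise codon statistics: Nei-Gojobori (1986) synonymous/nonsynonymous
# site and difference counting with Jukes-Cantor correction, and the
# genus-level distance-ratio table contrasting a housekeeping locus with
# the toxin loci.

.codon_tables <- local({
  tabs <- NULL
  function() {
    if (!is.null(tabs)) return(tabs)
    code <- Biostrings::GENETIC_CODE
    codons <- names(code)
    syn_sites <- stats::setNames(numeric(length(codons)), codons)
    for (cd in codons) {
      if (code[[cd]] == "*") next
      b <- strsplit(cd, "")[[1]]
      s <- 0
      for (p in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), b[p])) {
        cb <- b; cb[p] <- nt
        alt <- paste0(cb, collapse = "")
        # changes to stop codons count as nonsynonymous
        if (code[[alt]] == code[[cd]]) s <- s + 1 / 3
      }
      syn_sites[cd] <- s
    }
    tabs <<- list(code = code, syn_sites = syn_sites)
    tabs
  }
})

# average synonymous/nonsynonymous differences between two codons over all
# orderings of the single-nucleotide steps; paths through stop codons are
# discarded (all-stop path sets fall back to ignoring the restriction)
.codon_path_diffs <- function(c1, c2, code) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  count_paths <- function(allow_stop) {
    perms <- if (k == 1L) list(pos) else if (k == 2L) {
      list(pos, rev(pos))
    } else {
      list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
           pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
    }
    tot_s <- 0; tot_n <- 0; nvalid <- 0L
    t2 <- strsplit(c2, "")[[1]]
    for (pm in perms) {
      cur <- strsplit(c1, "")[[1]]
      s <- 0; n <- 0; ok <- TRUE
      for (p in pm) {
        nxt <- cur; nxt[p] <- t2[p]
        a1 <- code[[paste0(cur, collapse = "")]]
        a2 <- code[[paste0(nxt, collapse = "")]]
        if (a2 == "*" && !allow_stop) { ok <- FALSE; break }
        if (a1 == a2) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; nvalid <- nvalid + 1L }
    }
    if (nvalid == 0L) return(NULL)
    c(sd = tot_s / nvalid, nd = tot_n / nvalid)
  }
  res <- count_paths(allow_stop = FALSE)
  if (is.null(res)) res <- count_paths(allow_stop = TRUE)
  res
}

.jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (NG86) pairwise codon statistics
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon (fraction of
#' the three single-nucleotide changes at each position that preserve the
#' amino acid, averaged over both sequences; changes to stops count as
#' nonsynonymous), counts differences by averaging over all orderings of
#' multi-position codon changes (paths through stop codons discarded), and
#' applies the Jukes-Cantor correction `d = -3/4 log(1 - 4p/3)`. Proportions
#' `p >= 3/4` are flagged saturated with the distance undefined.
#'
#' Codons containing non-ACGT characters in either sequence are excluded
#' (pairwise deletion); internal stop codons are an error.
#'
#' @param cds1,cds2 equal-length in-frame coding sequences (strings,
#'   length divisible by 3). A terminal stop codon pair is tolerated and
#'   dropped.
#' @return List of class `ng86`: `codons_used`, `S`, `N`, `Sd`, `Nd`, `pS`,
#'   `pN`, `dS`, `dN`, `omega`, `saturated_s`, `saturated_n`.
#' @export
ng86 <- function(cds1, cds2) {
  cds1 <- toupper(cds1); cds2 <- toupper(cds2)
  if (nchar(cds1) != nchar(cds2)) stop("sequences must be equal length")
  if (nchar(cds1) %% 3 != 0) stop("length must be divisible by 3")
  tabs <- .codon_tables()
  n_cod <- nchar(cds1) %/% 3
  starts <- 3 * (seq_len(n_cod) - 1) + 1
  co1 <- substring(cds1, starts, starts + 2)
  co2 <- substring(cds2, starts, starts + 2)
  # tolerate one aligned terminal stop pair
  if (n_cod > 1 && tabs$code[co1[n_cod]] == "*" &&
      tabs$code[co2[n_cod]] == "*") {
    co1 <- co1[-n_cod]; co2 <- co2[-n_cod]; n_cod <- n_cod - 1
  }
  clean <- grepl("^[ACGT]{3}$", co1) & grepl("^[ACGT]{3}$", co2)
  stop1 <- clean & tabs$code[co1] == "*"
  stop2 <- clean & tabs$code[co2] == "*"
  if (any(stop1 | stop2)) {
    stop("internal stop codon at codon index ", which(stop1 | stop2)[1])
  }
  use <- which(clean)
  if (!length(use)) stop("no comparable codons after filtering")
  S <- mean(c(sum(tabs$syn_sites[co1[use]]), sum(tabs$syn_sites[co2[use]])))
  N <- 3 * length(use) - S
  Sd <- 0; Nd <- 0
  for (i in use) {
    d <- .codon_path_diffs(co1[i], co2[i], tabs$code)
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- .jc_correct(pS)
  dN <- .jc_correct(pN)
  out <- list(codons_used = length(use), S = S, N = N, Sd = Sd, Nd = Nd,
              pS = pS, pN = pN, dS = dS, dN = dN,
              omega = if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS
                      else NA_real_,
              saturated_s = !is.na(pS) && pS >= 0.75,
              saturated_n = !is.na(pN) && pN >= 0.75)
  class(out) <- "ng86"
  out
}

#' @export
print.ng86 <- function(x, ...) {
  cat(sprintf(paste0("NG86: %d codons | S %.2f N %.2f | Sd %.2f Nd %.2f | ",
                     "dS %s dN %s omega %s\n"),
              x$codons_used, x$S, x$N, x$Sd, x$Nd,
              ifelse(is.na(x$dS), "sat.", sprintf("%.4f", x$dS)),
              ifelse(is.na(x$dN), "sat.", sprintf("%.4f", x$dN)),
              ifelse(is.na(x$omega), "NA", sprintf("%.3f", x$omega))))
  invisible(x)
}

#' Genus-level distance ratios across loci
#'
#' For every genus pair present in an alignment, computes the mean corrected
#' nucleotide distance over cross-genus taxon pairs, then the fold-ratio of
#' the reference (housekeeping) locus distance to each other locus. A locus
#' evolving vertically matches the reference (ratio near 1); a recently
#' transferred locus is much less diverged between genera (ratio >> 1).
#'
#' @param locus_alignments named list of [msa] objects; one name must be
#'   `reference`.
#' @param genus_map named character vector: taxon -> genus.
#' @param reference name of the housekeeping locus (default `"rpb2"`).
#' @param model distance model passed to [nucleotide_distance()].
#' @return Data frame: `locus`, `genus_a`, `genus_b`, `distance`,
#'   `ref_distance`, `ratio` (reference / locus). Pairs with a missing
#'   genus are skipped with a warning.
#' @export
genus_distance_ratios <- function(locus_alignments, genus_map,
                                  reference = "rpb2", model = "JC") {
  stopifnot(reference %in% names(locus_alignments))
  mean_pair_dist <- function(aln) {
    dm <- nucleotide_distance(aln, model = model)
    gm <- genus_map[rownames(dm)]
    genera <- sort(unique(stats::na.omit(gm)))
    out <- list()
    for (i in seq_along(genera)) for (j in seq_along(genera)) {
      if (i >= j) next
      a <- which(gm == genera[i]); b <- which(gm == genera[j])
      vals <- dm[a, b, drop = FALSE]
      vals <- vals[is.finite(vals)]
      out[[paste(genera[i], genera[j], sep = "|")]] <-
        if (length(vals)) mean(vals) else NA_real_
    }
    out
  }
  ref <- mean_pair_dist(locus_alignments[[reference]])
  rows <- list()
  for (locus in setdiff(names(locus_alignments), reference)) {
    loc <- mean_pair_dist(locus_alignments[[locus]])
    for (pair in names(ref)) {
      gpair <- strsplit(pair, "|", fixed = TRUE)[[1]]
      if (!pair %in% names(loc) || is.na(loc[[pair]]) || is.na(ref[[pair]])) {
        warning("genus pair ", pair, " missing for locus ", locus,
                "; skipped")
        next
      }
      ratio <- if (loc[[pair]] > 0) ref[[pair]] / loc[[pair]] else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        locus = locus, genus_a = gpair[1], genus_b = gpair[2],
        distance = loc[[pair]], ref_distance = ref[[pair]], ratio = ratio)
    }
  }
  if (!length(rows)) {
    return(data.frame(locus = character(), genus_a = character(),
                      genus_b = character(), distance = numeric(),
                      ref_distance = numeric(), ratio = numeric()))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
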