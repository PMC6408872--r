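# Assembly summary statistics (N50/N90, GC content) and windowed GC /
# GC-skew tracks exported as Circos-style flat TSV files.

#' Nxx contig statistic
#'
#' The smallest contig length `L` such that contigs of length `>= L` together
#' cover at least `x` percent of the assembly (ties resolved toward the
#' larger contig, the common assembler-report convention).
#'
#' @param lengths positive contig lengths (bp).
#' @param x percentage in (0, 100); 50 gives the N50.
#' @return The Nxx length in bp.
#' @examples
#' nxx(c(5, 4, 3, 2, 1), 50)  # 4
#' @export
nxx <- function(lengths, x = 50) {
  if (!length(lengths)) stop("empty length list")
  if (any(lengths <= 0)) stop("contig lengths must be positive")
  if (x <= 0 || x >= 100) stop("x must be in (0, 100)")
  l <- sort(unname(lengths), decreasing = TRUE)
  target <- sum(l) * x / 100
  l[which(cumsum(l) >= target)[1]]
}

.base_counts <- function(seqs) {
  tab <- Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(unname(seqs)), baseOnly = TRUE)
  colSums(tab[, c("A", "C", "G", "T"), drop = FALSE])
}

#' GC fraction of DNA sequences
#'
#' Ambiguous bases (N etc.) are excluded from both numerator and
#' denominator.
#'
#' @param seqs named character vector of DNA sequences.
#' @return `(G + C) / (A + C + G + T)`.
#' @export
gc_content <- function(seqs) {
  cnt <- .base_counts(seqs)
  denom <- sum(cnt)
  if (denom == 0) stop("no unambiguous bases (A/C/G/T) in input")
  (cnt[["G"]] + cnt[["C"]]) / denom
}

#' Windowed GC content and GC skew tracks
#'
#' Tiles a sequence with windows of size `window` every `step` bp and
#' computes per-window GC fraction or GC skew `(G - C) / (G + C)`. Windows
#' with no G or C emit value 0 and are flagged in the `zero_gc` column.
#' A window larger than the sequence collapses to a single whole-sequence
#' window.
#'
#' @param seq a single DNA sequence (string).
#' @param window window size (bp), `>= step`.
#' @param step step size (bp), `>= 1`.
#' @param contig contig name for the track.
#' @return Data frame with columns `contig`, `start`, `end` (0-based
#'   half-open), `gc`, `skew`, `zero_gc`.
#' @export
gc_skew <- function(seq, window = 10000, step = window, contig = "contig") {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (step < 1 || window < step) stop("need window >= step >= 1")
  n <- nchar(seq)
  if (window > n) window <- n
  starts <- seq(0L, max(0L, n - window), by = step)
  ss <- Biostrings::DNAStringSet(substring(seq, starts + 1L, starts + window))
  tab <- Biostrings::alphabetFrequency(ss, baseOnly = TRUE)
  g <- tab[, "G"]; c_ <- tab[, "C"]
  acgt <- tab[, "A"] + tab[, "C"] + tab[, "G"] + tab[, "T"]
  zero <- (g + c_) == 0
  skew <- ifelse(zero, 0, (g - c_) / (g + c_))
  gc <- ifelse(acgt == 0, 0, (g + c_) / acgt)
  data.frame(contig = contig, start = starts, end = starts + window,
             gc = gc, skew = skew, zero_gc = zero)
}

#' Assembly summary statistics
#'
#' @param contigs named character vector of contig sequences, or a numeric
#'   vector of contig lengths together with `seqs = FALSE` semantics (GC is
#'   then `NA`).
#' @return List of class `assembly_stats`: `total_bp`, `n_contigs`, `n50`,
#'   `n90`, `max_len`, `gc_fraction`.
#' @export
assembly_summary <- function(contigs) {
  if (is.numeric(contigs)) {
    lens <- contigs
    gc <- NA_real_
  } else {
    lens <- nchar(contigs)
    gc <- gc_content(contigs)
  }
  if (!length(lens)) stop("no contigs")
  out <- list(total_bp = sum(lens), n_contigs = length(lens),
              n50 = nxx(lens, 50), n90 = nxx(lens, 90),
              max_len = max(lens), gc_fraction = gc)
  class(out) <- "assembly_stats"
  out
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "Assembly: %d contigs, %s bp total\n",
    "  N50 %s bp | N90 %s bp | longest %s bp | GC %s\n"),
    x$n_contigs, format(x$total_bp, big.mark = ","),
    format(x$n50, big.mark = ","), format(x$n90, big.mark = ","),
    format(x$max_len, big.mark = ","),
    if (is.na(x$gc_fraction)) "NA" else sprintf("%.2f%%", 100 * x$gc_fraction)))
  invisible(x)
}

#' Export a window track as a 4-column Circos-style TSV
#'
#' @param track data frame from [gc_skew()].
#' @param path output path.
#' @param value which column to export as the track value.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path, value = c("gc", "skew")) {
  value <- match.arg(value)
  utils::write.table(track[, c("contig", "start", "end", value)], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
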