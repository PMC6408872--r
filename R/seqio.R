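# Readers/writers for the external formats the pipeline touches: FASTA,
# relaxed sequential PHYLIP, Newick, GFF3 and TSV/CSV peak tables, plus the
# coordinate conventions used throughout.
#
# All internal coordinates are 0-based half-open; GFF3 output (and
# human-facing reports) are 1-based inclusive.

#' Read a FASTA file
#'
#' @param path path to a FASTA file (DNA or protein).
#' @return A named character vector of uppercase sequences; names are the
#'   first whitespace-delimited token of each header, with the full header
#'   kept in `attr(, "descriptions")`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  if (any(!nzchar(seqs))) stop("empty sequence for id: ", ids[!nzchar(seqs)][1])
  names(seqs) <- ids
  attr(seqs, "descriptions") <- stats::setNames(headers, ids)
  seqs
}

#' Write sequences to FASTA
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @param wrap line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60) {
  if (length(records) == 0L) stop("no records to write")
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("all records must be named")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    starts <- seq(1L, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a multiple sequence alignment object
#'
#' @param seqs named character vector, all the same length.
#' @param type `"nucleotide"` or `"protein"` (guessed from the residues when
#'   missing).
#' @return An object of class `msa`: the named vector with attributes
#'   `type` and `n_sites`.
#' @export
msa <- function(seqs, type = NULL) {
  if (length(seqs) < 1L) stop("alignment needs at least one sequence")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("alignment rows must have unique names")
  }
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) {
    off <- names(seqs)[w != w[1]][1]
    stop("ragged alignment: row '", off, "' has ", nchar(seqs[[off]]),
         " columns, expected ", w[1])
  }
  w <- unname(w)
  seqs <- toupper(seqs)
  if (is.null(type)) {
    res <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
    nuc <- c("A", "C", "G", "T", "U", "N", "-", "?", ".")
    type <- if (all(res %in% nuc)) "nucleotide" else "protein"
  }
  structure(seqs, type = type, n_sites = w[1], class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("Alignment:", length(x), attr(x, "type"), "sequences x",
      attr(x, "n_sites"), "columns\n")
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Accepts relaxed sequential PHYLIP (whitespace-delimited names, the
#' supplementary-file convention) or aligned FASTA; the dialect is sniffed
#' from the first line. Interleaved PHYLIP is rejected.
#'
#' @param path path to the alignment.
#' @param dialect `"auto"`, `"phylip"` or `"fasta"`.
#' @return An [msa] object.
#' @export
read_alignment <- function(path, dialect = c("auto", "phylip", "fasta")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty alignment file: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("^\\s*\\d+\\s+\\d+\\s*$", lines[1])) "phylip" else "fasta"
  }
  if (dialect == "fasta") {
    return(msa(read_fasta(path)))
  }
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  ntax <- hdr[1]; nsites <- hdr[2]
  body <- lines[-1]
  ids <- character(0)
  seqs <- character(0)
  cur <- 0L
  for (ln in body) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    joined <- paste0(tok, collapse = "")
    is_cont <- cur > 0L && nchar(seqs[cur]) < nsites &&
      nchar(joined) <= nsites - nchar(seqs[cur])
    if (is_cont) {
      # continuation of the current taxon (sequential dialect)
      seqs[cur] <- paste0(seqs[cur], joined)
    } else {
      # new taxon row: first token is the name, the rest is sequence
      ids <- c(ids, tok[1])
      seqs <- c(seqs, paste0(tok[-1], collapse = ""))
      cur <- cur + 1L
    }
  }
  if (length(ids) > ntax) {
    bad <- which(nchar(seqs) != nsites)[1]
    stop("ragged PHYLIP row for taxon '", ids[bad], "': ",
         nchar(seqs[bad]), " columns, expected ", nsites)
  }
  if (length(ids) != ntax) {
    stop("PHYLIP header promises ", ntax, " taxa but ", length(ids),
         " were parsed; interleaved PHYLIP is not supported")
  }
  bad <- which(nchar(seqs) != nsites)
  if (length(bad)) {
    stop("ragged PHYLIP row for taxon '", ids[bad[1]], "': ",
         nchar(seqs[bad[1]]), " columns, expected ", nsites,
         " (interleaved PHYLIP is not supported)")
  }
  names(seqs) <- ids
  msa(seqs)
}

#' Write an alignment in relaxed sequential PHYLIP
#'
#' @param aln an [msa] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(aln, path) {
  stopifnot(inherits(aln, "msa"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(aln), attr(aln, "n_sites")), con)
  writeLines(paste(names(aln), unclass(aln)), con)
  invisible(path)
}

#' Parse and write Newick trees
#'
#' Thin wrappers over ape's Newick machinery with up-front syntax checks:
#' unbalanced parentheses are reported with their character position.
#'
#' @param text a Newick string (one tree).
#' @return `parse_newick`: an ape `phylo` tree. `write_newick`: a Newick
#'   string with terminal semicolon.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty Newick string")
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L) stop("unbalanced '(': ", depth, " unclosed at end of string")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("Newick parse failure: ", substr(text, 1, 60))
  tr
}

#' @rdname parse_newick
#' @param tree an ape `phylo` object.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Write gene models as GFF3
#'
#' Gene models use 0-based half-open coordinates internally; GFF3 rows are
#' 1-based inclusive. Each model emits gene, mRNA, exon and CDS rows with
#' exons sorted in genomic order.
#'
#' @param gene_models a list of `gene_model` objects (see [gene_model()]).
#' @param path output path.
#' @param source source tag for column 2.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gene_models, path, source = "amatox") {
  if (inherits(gene_models, "gene_model")) gene_models <- list(gene_models)
  rows <- character(0)
  rows <- c(rows, "##gff-version 3")
  for (k in seq_along(gene_models)) {
    gm <- gene_models[[k]]
    stopifnot(inherits(gm, "gene_model"))
    ex <- gm$exons[order(vapply(gm$exons, `[`, numeric(1), 1L))]
    starts <- vapply(ex, `[`, numeric(1), 1L)
    ends <- vapply(ex, `[`, numeric(1), 2L)
    if (any(starts[-1] < ends[-length(ends)])) {
      stop("overlapping exons in gene model ", k)
    }
    gid <- if (!is.null(gm$id)) gm$id else paste0("gene", k)
    g1 <- gm$interval[1] + 1L; g2 <- gm$interval[2]
    fmt <- function(type, s, e, id, parent = NULL) {
      attrs <- if (is.null(parent)) paste0("ID=", id)
               else paste0("ID=", id, ";Parent=", parent)
      paste(gm$contig, source, type, s, e, ".", gm$strand, ".", attrs,
            sep = "\t")
    }
    rows <- c(rows, fmt("gene", g1, g2, gid),
              fmt("mRNA", g1, g2, paste0(gid, ".t1"), gid))
    for (i in seq_along(ex)) {
      rows <- c(rows,
        fmt("exon", starts[i] + 1L, ends[i], paste0(gid, ".t1.exon", i),
            paste0(gid, ".t1")),
        fmt("CDS", starts[i] + 1L, ends[i], paste0(gid, ".t1.cds"),
            paste0(gid, ".t1")))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read an MS1 peak table
#'
#' Accepts TSV or CSV (sniffed from the extension and the header) with an
#' `mz` column and an optional `intensity` column (default 1.0). An empty
#' table is allowed and yields zero peaks.
#'
#' @param path path to the table.
#' @return Data frame with columns `mz` and `intensity`, sorted by `mz`.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && !grepl(sep, first, fixed = TRUE) && grepl(",", first)) {
    sep <- ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (!"mz" %in% names(df)) stop("peak table must have an 'mz' column")
  if (nrow(df) == 0L) {
    return(data.frame(mz = numeric(0), intensity = numeric(0)))
  }
  mz <- suppressWarnings(as.numeric(df$mz))
  if (anyNA(mz)) {
    stop("non-numeric mz at line ", which(is.na(mz))[1] + 1L)
  }
  if (any(mz <= 0)) stop("mz must be positive (line ",
                         which(mz <= 0)[1] + 1L, ")")
  intensity <- if ("intensity" %in% names(df)) {
    suppressWarnings(as.numeric(df$intensity))
  } else rep(1, length(mz))
  o <- order(mz)
  data.frame(mz = mz[o], intensity = intensity[o])
}

# --- coordinate convention helpers -----------------------------------------

#' Convert between 0-based half-open and 1-based inclusive intervals
#'
#' @param interval numeric length-2 vector.
#' @return The converted interval.
#' @export
to_one_based <- function(interval) c(interval[1] + 1L, interval[2])

#' @rdname to_one_based
#' @export
to_zero_based <- function(interval) c(interval[1] - 1L, interval[2])
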