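# End-to-end orchestration: run the mining -> mass-matching -> phylogenetics
# -> reconciliation -> rates chain from a single config (YAML path or list),
# with stage-labelled errors and a machine-readable report.

.cfg_get <- function(block, key, default = NULL) {
  if (!is.null(block[[key]])) block[[key]] else default
}

.validate_config <- function(config) {
  known <- c("out_dir", "seed", "stats", "mine", "mass_match", "au",
             "reconcile", "rates")
  problems <- character(0)
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    problems <- c(problems, paste("unknown config block(s):",
                                  paste(unknown, collapse = ", ")))
  }
  need_file <- function(block, key) {
    p <- config[[block]][[key]]
    if (is.null(p)) {
      problems <<- c(problems, paste0(block, ": missing required '", key, "'"))
    } else if (!file.exists(p)) {
      problems <<- c(problems, paste0(block, ": input file not found: ", p))
    }
  }
  if (!is.null(config$stats)) need_file("stats", "fasta")
  if (!is.null(config$mine)) {
    need_file("mine", "fasta"); need_file("mine", "train_fasta")
  }
  if (!is.null(config$mass_match)) need_file("mass_match", "peaks")
  if (!is.null(config$au)) { need_file("au", "aln"); need_file("au", "trees") }
  if (!is.null(config$reconcile)) {
    need_file("reconcile", "gene_tree"); need_file("reconcile", "species_tree")
  }
  if (!is.null(config$rates)) {
    if (is.null(config$rates$loci) || length(config$rates$loci) < 2) {
      problems <- c(problems,
                    "rates: needs 'loci', a named list of >= 2 alignments")
    } else {
      for (p in unlist(config$rates$loci)) {
        if (!file.exists(p)) {
          problems <- c(problems, paste0("rates: input file not found: ", p))
        }
      }
    }
  }
  if (length(problems)) {
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  invisible(TRUE)
}

.run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline from a config
#'
#' Stages present in the config run in dependency order: assembly `stats`,
#' MSDIN/POP `mine`, `mass_match` of mined (or listed) cores against an MS1
#' peak table, the `au` topology test, DL/DTL `reconcile`, and genus
#' distance `rates`. Each stage's parameters and seed are echoed into the
#' report, which is also written as JSON when `out_dir` is set. The
#' pipeline is a pure function of (inputs, config, seed).
#'
#' @param config a named list or path to a YAML file. Blocks (all optional):
#'   `stats` (`fasta`, `window`, `step`), `mine` (`fasta`, `train_fasta`,
#'   `leader_len`, `max_introns`, `cluster_threshold`), `mass_match`
#'   (`peaks`, `tol_ppm`, `adduct`, optional `cores` data frame/path),
#'   `au` (`aln`, `trees`, `B`, `shape`, `p_inv`), `reconcile`
#'   (`gene_tree`, `species_tree`, optional `map` TSV, `costs`),
#'   `rates` (`loci` named paths, `genus_map` TSV, `reference`), plus
#'   top-level `seed` and `out_dir`.
#' @return The report (nested list), invisibly if written to disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  .validate_config(config)
  seed <- .cfg_get(config, "seed", 1L)
  report <- list(seed = seed, stages = list())

  if (!is.null(config$stats)) {
    report$stages$stats <- .run_stage("stats", {
      contigs <- read_fasta(config$stats$fasta)
      st <- assembly_summary(contigs)
      window <- .cfg_get(config$stats, "window", 10000)
      step <- .cfg_get(config$stats, "step", window)
      tracks <- do.call(rbind, lapply(names(contigs), function(nm) {
        gc_skew(contigs[[nm]], window = window, step = step, contig = nm)
      }))
      if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
        write_track_tsv(tracks, file.path(config$out_dir, "gc_content.tsv"),
                        "gc")
        write_track_tsv(tracks, file.path(config$out_dir, "gc_skew.tsv"),
                        "skew")
      }
      list(params = list(window = window, step = step),
           stats = unclass(st))
    })
  }

  if (!is.null(config$mine)) {
    report$stages$mine <- .run_stage("mine", {
      contigs <- read_fasta(config$mine$fasta)
      train <- read_fasta(config$mine$train_fasta)
      leader_len <- .cfg_get(config$mine, "leader_len", 5)
      profile <- build_leader_profile(train, leader_len = leader_len)
      hits <- list()
      for (nm in names(contigs)) {
        hs <- scan_orfs(contigs[nm], profile,
                        max_introns = .cfg_get(config$mine, "max_introns", 1),
                        contig_name = nm)
        hits <- c(hits, hs)
      }
      thr <- .cfg_get(config$mine, "cluster_threshold", 50000)
      dist_report <- toxin_gene_distance(hits, threshold = thr)
      if (!is.null(config$out_dir) && length(hits)) {
        dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
        write_gff3(lapply(hits, `[[`, "gene_model"),
                   file.path(config$out_dir, "mined_genes.gff3"))
      }
      list(params = list(leader_len = leader_len, threshold = profile$threshold,
                         cluster_threshold = thr),
           n_hits = length(hits),
           precursors = vapply(hits, function(h) h$precursor$peptide,
                               character(1)),
           cores = vapply(hits, function(h) h$precursor$core, character(1)),
           clustering = dist_report)
    })
  }

  if (!is.null(config$mass_match)) {
    report$stages$mass_match <- .run_stage("mass_match", {
      peaks <- read_peak_table(config$mass_match$peaks)
      cores <- config$mass_match$cores
      if (is.null(cores) && !is.null(report$stages$mine)) {
        mined <- unique(report$stages$mine$cores)
        if (length(mined)) {
          cores <- data.frame(name = paste0("core", seq_along(mined)),
                              core = mined, stringsAsFactors = FALSE)
        }
      }
      if (is.null(cores) || !nrow(cores)) stop("no cores to match")
      if (is.character(cores)) {
        cores <- utils::read.table(cores, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
      }
      tol <- .cfg_get(config$mass_match, "tol_ppm", 10)
      modset <- .cfg_get(config$mass_match, "modset", "amatoxin")
      cand <- data.frame(
        name = cores$name,
        mz = vapply(cores$core, function(cr) {
          f <- apply_mods(peptide_formula(cr, "cyclic"), mod_set(modset))
          adduct_mz(monoisotopic_mass(f))
        }, numeric(1)),
        stringsAsFactors = FALSE)
      matches <- match_peaks(peaks, cand, tol_ppm = tol)
      list(params = list(tol_ppm = tol, modset = modset, adduct = "M+H"),
           candidates = cand, n_matches = nrow(matches), matches = matches)
    })
  }

  if (!is.null(config$au)) {
    report$stages$au <- .run_stage("au", {
      aln <- read_alignment(config$au$aln)
      trees <- ape::read.tree(config$au$trees)
      if (inherits(trees, "phylo")) trees <- list(trees)
      params <- gtr_gamma_params(shape = .cfg_get(config$au, "shape", 1),
                                 p_inv = .cfg_get(config$au, "p_inv", 0))
      B <- .cfg_get(config$au, "B", 10000)
      tab <- au_table(aln, trees, params, B = B, seed = seed)
      attr(tab, "site_lnl") <- NULL
      list(params = list(B = B, seed = seed), table = tab)
    })
  }

  if (!is.null(config$reconcile)) {
    report$stages$reconcile <- .run_stage("reconcile", {
      gt <- parse_newick(paste(readLines(config$reconcile$gene_tree),
                               collapse = ""))
      st <- parse_newick(paste(readLines(config$reconcile$species_tree),
                               collapse = ""))
      map <- if (!is.null(config$reconcile$map)) {
        m <- utils::read.table(config$reconcile$map, header = FALSE,
                               sep = "\t", stringsAsFactors = FALSE)
        stats::setNames(m[[2]], m[[1]])
      } else {
        stats::setNames(sub("_[0-9]+$", "", gt$tip.label), gt$tip.label)
      }
      costs <- .cfg_get(config$reconcile, "costs", c(1.5, 3.0, 1.0))
      cmp <- compare_models(gt, st, map,
                            event_costs(costs[1], costs[2], costs[3]))
      list(params = list(costs = costs),
           dl = unclass(cmp$dl)[c("n_dup", "n_transfer", "n_loss", "score")],
           dtl = unclass(cmp$dtl)[c("n_dup", "n_transfer", "n_loss", "score")],
           verdict = cmp$verdict)
    })
  }

  if (!is.null(config$rates)) {
    report$stages$rates <- .run_stage("rates", {
      loci <- lapply(config$rates$loci, read_alignment)
      gm <- utils::read.table(config$rates$genus_map, header = FALSE,
                              sep = "\t", stringsAsFactors = FALSE)
      genus_map <- stats::setNames(gm[[2]], gm[[1]])
      reference <- .cfg_get(config$rates, "reference", "rpb2")
      tab <- genus_distance_ratios(loci, genus_map, reference = reference)
      list(params = list(reference = reference), table = tab)
    })
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(invisible(report))
  }
  report
}
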