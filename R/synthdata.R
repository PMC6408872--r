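# Seeded ground-truth generators: contigs with planted MSDIN genes, species
# trees with gene trees evolved inside them (duplication / transfer / loss),
# GTR+Gamma sequence evolution, omega-scaled codon pairs, and noisy MS1 peak
# lists with decoys. Every generator returns the truth needed to score the
# corresponding analysis stage.

.LEADER_STYLES <- list(
  MSDIN = "MSDIN",   # Amanita-style conserved leader start
  MFDTN = "MFDTN",   # Galerina-style
  MDAN  = "MDAN"     # Lepiota-style (second residue missing)
)

.sample_bases <- function(n, gc) {
  sample(c("G", "C", "A", "T"), n, replace = TRUE,
         prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2))
}

# reverse-translate with GC-biased codon choice: codons weighted by an iid
# base model at the target GC (composition is all the miner sees)
.reverse_translate <- function(aa_seq, gc) {
  code <- Biostrings::GENETIC_CODE
  aa <- strsplit(toupper(aa_seq), "")[[1]]
  vapply(aa, function(a) {
    cods <- names(code)[code == a]
    gcn <- vapply(strsplit(cods, ""), function(b) sum(b %in% c("G", "C")),
                  numeric(1))
    w <- gc^gcn * (1 - gc)^(3 - gcn)
    sample(cods, 1L, prob = w)
  }, character(1), USE.NAMES = FALSE)
}

#' Plant a synthetic MSDIN gene in a background contig
#'
#' Builds a precursor (leader + core + follower, honouring the proline
#' cleavage rule), reverse-translates it with GC-matched codon choice,
#' optionally inserts one canonical GT..AG intron inside the coding region,
#' and embeds the gene at a random position and strand in an iid background
#' of the stated GC.
#'
#' @param length contig length (bp).
#' @param gc background (and codon-choice) GC fraction, in (0.2, 0.8).
#' @param core core peptide, 7-10 aa ending in P.
#' @param leader_style `"MSDIN"`, `"MFDTN"` or `"MDAN"`.
#' @param n_introns 0 or 1.
#' @param seed RNG seed (integer); the output is a pure function of the
#'   arguments and this seed.
#' @param intron_len intron length range (bp) when `n_introns == 1`.
#' @param precursor optional full precursor amino-acid sequence overriding
#'   the leader/core/follower construction (must decompose under
#'   [extract_core()]).
#' @param mutate_aa per-residue substitution probability applied outside the
#'   anchor positions (conserved leader start, the two cleavage prolines and
#'   the core) after construction; default 0.
#' @return List with `contig` (named character), and `truth`: gene interval
#'   (0-based half-open, forward coordinates), strand, precursor, leader,
#'   core, cds, intron interval (or NULL), seed.
#' @export
plant_msdin_contig <- function(length = 3000, gc = 0.49, core = "IWGIGCNP",
                               leader_style = c("MSDIN", "MFDTN", "MDAN"),
                               n_introns = 1, seed = 1,
                               intron_len = c(40, 120), precursor = NULL,
                               mutate_aa = 0) {
  leader_style <- match.arg(leader_style)
  if (gc <= 0.2 || gc >= 0.8) stop("gc must be in (0.2, 0.8)")
  core <- toupper(core)
  if (nchar(core) < 7 || nchar(core) > 10) stop("core must be 7-10 aa")
  if (substr(core, nchar(core), nchar(core)) != "P") {
    stop("core must end with P")
  }
  set.seed(seed)
  aa_no_p <- setdiff(.AA20, c("P", "M", "W", "C"))
  if (is.null(precursor)) {
    lead5 <- .LEADER_STYLES[[leader_style]]
    leader <- paste0(lead5,
                     paste0(sample(aa_no_p, 9L - nchar(lead5) - 1L, TRUE),
                            collapse = ""), "P")
    follower <- paste0(sample(aa_no_p, sample(12:17, 1L), TRUE),
                       collapse = "")
    precursor <- paste0(leader, core, follower)
  } else {
    precursor <- toupper(precursor)
  }
  if (mutate_aa > 0) {
    dec <- extract_core(precursor)
    aa <- strsplit(precursor, "")[[1]]
    lead5 <- nchar(.LEADER_STYLES[[leader_style]])
    anchors <- c(seq_len(lead5), nchar(dec$leader),
                 dec$core_span[1]:dec$core_span[2])
    for (p in setdiff(seq_along(aa), anchors)) {
      if (stats::runif(1) < mutate_aa) aa[p] <- sample(aa_no_p, 1L)
    }
    precursor <- paste0(aa, collapse = "")
  }
  codons <- .reverse_translate(precursor, gc)
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
  cds <- paste0(c(codons, stop_codon), collapse = "")
  ncds <- nchar(cds)
  gene <- cds
  intron_rel <- NULL
  if (n_introns >= 1L) {
    ilen <- if (intron_len[1] == intron_len[2]) intron_len[1] else
      sample(intron_len[1]:intron_len[2], 1L)
    interior <- paste0(.sample_bases(ilen - 4L, gc), collapse = "")
    intron <- paste0("GT", interior, "AG")
    pos <- sample(3:(ncds - 4L), 1L)   # insertion point within the CDS
    gene <- paste0(substr(cds, 1L, pos), intron,
                   substr(cds, pos + 1L, ncds))
    intron_rel <- c(pos, pos + ilen)   # 0-based half-open within the gene
  }
  glen <- nchar(gene)
  if (glen + 20L > length) stop("contig length too small for the gene")
  strand <- sample(c("+", "-"), 1L)
  placed <- if (strand == "+") gene else .revcomp(gene)
  at <- sample(10:(length - glen - 10L), 1L)   # 0-based insertion offset
  bg <- .sample_bases(length - glen, gc)
  contig_seq <- paste0(paste0(bg[seq_len(at)], collapse = ""), placed,
                       paste0(bg[(at + 1L):(length - glen)], collapse = ""))
  gene_iv <- c(at, at + glen)
  intron_iv <- NULL
  if (!is.null(intron_rel)) {
    intron_iv <- if (strand == "+") at + intron_rel
                 else c(gene_iv[2] - intron_rel[2], gene_iv[2] - intron_rel[1])
  }
  contig <- stats::setNames(contig_seq, "synthetic_contig")
  list(contig = contig,
       truth = list(gene_interval = gene_iv, strand = strand,
                    precursor = precursor, leader = extract_core(precursor)$leader,
                    core = extract_core(precursor)$core, cds = cds,
                    intron = intron_iv, seed = seed))
}

#' Simulate a Yule species tree
#'
#' @param n_taxa number of extant taxa (>= 3).
#' @param birth_rate speciation rate.
#' @param seed RNG seed.
#' @return An ultrametric rooted `phylo` tree with tips `t1..tn`.
#' @export
simulate_species_tree <- function(n_taxa, birth_rate = 1, seed = 1) {
  if (n_taxa < 3) stop("need n_taxa >= 3")
  set.seed(seed)
  ape::rphylo(n_taxa, birth = birth_rate, death = 0)
}

#' Evolve a gene tree inside a species tree with duplication, transfer, loss
#'
#' Chronological birth-death simulation of gene lineages along an
#' ultrametric species tree. Duplications copy a lineage in place; losses
#' prune it; transfers copy the lineage into a contemporaneous species
#' branch incomparable to the donor and *replace* any resident copies there
#' (replacing HGT). The returned truth records every realized event.
#'
#' @param species_tree ultrametric rooted `phylo`.
#' @param rates named numeric: `dup`, `transfer`, `loss` (events per lineage
#'   per unit time).
#' @param seed RNG seed.
#' @param max_retries resample attempts when all lineages die.
#' @return List: `gene_tree` (rooted `phylo`, tips `<species>_<copy>`),
#'   `leaf_map` (named vector gene tip -> species tip), `events` (data frame
#'   of transfers/duplications/losses with times and branches).
#' @export
simulate_gene_tree <- function(species_tree, rates = c(dup = 0, transfer = 0,
                                                       loss = 0),
                               seed = 1, max_retries = 20) {
  stopifnot(inherits(species_tree, "phylo"))
  rates <- rates[c("dup", "transfer", "loss")]
  if (any(is.na(rates))) stop("rates must name dup, transfer, loss")
  if (any(rates < 0)) stop("rates must be >= 0")
  set.seed(seed)
  for (try in seq_len(max_retries)) {
    sim <- .simulate_gene_tree_once(species_tree, rates)
    if (!is.null(sim)) return(sim)
  }
  stop("all gene lineages were lost in every attempt; lower the loss rate")
}

.simulate_gene_tree_once <- function(sp, rates) {
  nt <- length(sp$tip.label)
  ages <- c(stats::setNames(rep(0, nt), seq_len(nt)),
            ape::branching.times(sp))
  ages <- ages[as.character(seq_len(nt + sp$Nnode))]
  parent <- rep(NA_integer_, nt + sp$Nnode)
  parent[sp$edge[, 2]] <- sp$edge[, 1]
  root <- nt + 1L
  children <- lapply(seq_len(nt + sp$Nnode), function(v) {
    sp$edge[sp$edge[, 1] == v, 2]
  })
  is_anc <- function(a, b) {       # a ancestor-or-equal of b
    while (!is.na(b)) { if (a == b) return(TRUE); b <- parent[b] }
    FALSE
  }
  branch_label <- function(v) {
    if (v <= nt) sp$tip.label[v] else paste0("n", v)
  }
  # gene nodes: grown as a list; children indices filled as lineages resolve
  nodes <- list()
  new_node <- function(type, time) {
    nodes[[length(nodes) + 1L]] <<- list(type = type, time = time,
                                         children = integer(0),
                                         roles = character(0), label = NA)
    length(nodes)
  }
  events <- list()
  # active lineage: (branch = species node the branch leads to, node = gene
  # parent node index awaiting this lineage's resolution slot, role = how
  # this lineage descends from its parent node)
  attach_child <- function(pnode, cnode, role = "descent") {
    if (!is.na(pnode)) {
      nodes[[pnode]]$children <<- c(nodes[[pnode]]$children, cnode)
      nodes[[pnode]]$roles <<- c(nodes[[pnode]]$roles, role)
    }
  }
  # start: the gene root is the species root speciation
  t0 <- ages[root]
  rootnode <- new_node("speciation", t0)
  active <- lapply(children[[root]], function(ch) {
    list(branch = ch, pnode = rootnode, role = "descent")
  })
  spec_times <- sort(unique(ages[ages > 0 & ages < t0]), decreasing = TRUE)
  timeline <- c(spec_times, 0)
  now <- t0
  total_rate <- sum(rates)
  for (t_next in timeline) {
    repeat {
      if (!length(active)) return(NULL)
      dt <- if (total_rate > 0) {
        stats::rexp(1, total_rate * length(active))
      } else Inf
      if (now - dt <= t_next) { now <- t_next; break }
      now <- now - dt
      k <- sample.int(length(active), 1L)
      lin <- active[[k]]
      type <- sample(c("dup", "transfer", "loss"), 1L, prob = rates)
      if (type == "loss") {
        active[[k]] <- NULL
        events[[length(events) + 1L]] <- data.frame(
          type = "loss", time = now, donor = branch_label(lin$branch),
          recipient = NA_character_, node = NA_integer_)
      } else if (type == "dup") {
        nd <- new_node("duplication", now)
        attach_child(lin$pnode, nd, lin$role)
        active[[k]] <- list(branch = lin$branch, pnode = nd,
                            role = "descent")
        active[[length(active) + 1L]] <- list(branch = lin$branch,
                                              pnode = nd, role = "descent")
        events[[length(events) + 1L]] <- data.frame(
          type = "duplication", time = now, donor = branch_label(lin$branch),
          recipient = NA_character_, node = nd)
      } else {
        alive <- which(vapply(seq_along(ages), function(v) {
          v != root && ages[v] < now && ages[parent[v]] > now
        }, logical(1)))
        # recipients: contemporaneous, incomparable, and not the donor's
        # direct sister branch (a sister transfer replacing the resident
        # copy is indistinguishable from vertical descent; the HGT being
        # emulated crosses distant lineages)
        recips <- alive[vapply(alive, function(v) {
          !is_anc(v, lin$branch) && !is_anc(lin$branch, v) &&
            !identical(parent[v], parent[lin$branch])
        }, logical(1))]
        if (!length(recips)) next
        r <- if (length(recips) == 1L) recips else sample(recips, 1L)
        # replacing transfer: resident copies in the recipient branch die
        resident <- which(vapply(active, function(a) a$branch == r,
                                 logical(1)))
        resident <- setdiff(resident, k)
        if (length(resident)) active[resident] <- NULL
        k <- which(vapply(active, function(a) identical(a, lin),
                          logical(1)))[1]
        nd <- new_node("transfer", now)
        attach_child(lin$pnode, nd, lin$role)
        active[[k]] <- list(branch = lin$branch, pnode = nd,
                            role = "descent")
        active[[length(active) + 1L]] <- list(branch = r, pnode = nd,
                                              role = "recipient")
        events[[length(events) + 1L]] <- data.frame(
          type = "transfer", time = now, donor = branch_label(lin$branch),
          recipient = branch_label(r), node = nd)
      }
    }
    if (t_next == 0) {
      # lineages reach the species tips
      cnt <- integer(nt)
      for (lin in active) {
        v <- lin$branch
        cnt[v] <- cnt[v] + 1L
        nd <- new_node("leaf", 0)
        nodes[[nd]]$label <- paste0(sp$tip.label[v], "_", cnt[v])
        attach_child(lin$pnode, nd, lin$role)
      }
      break
    }
    # speciation at t_next: split lineages sitting in the branch that ends
    v_splits <- which(abs(ages - t_next) < 1e-12)
    v_splits <- v_splits[v_splits > nt]
    new_active <- list()
    for (lin in active) {
      if (lin$branch %in% v_splits) {
        nd <- new_node("speciation", t_next)
        attach_child(lin$pnode, nd, lin$role)
        for (ch in children[[lin$branch]]) {
          new_active[[length(new_active) + 1L]] <- list(branch = ch,
                                                        pnode = nd,
                                                        role = "descent")
        }
      } else {
        new_active[[length(new_active) + 1L]] <- lin
      }
    }
    active <- new_active
  }
  # prune dead subtrees and suppress unifurcations
  surv <- logical(length(nodes))
  order_post <- rev(seq_along(nodes))  # children always created after parents
  for (i in order_post) {
    nd <- nodes[[i]]
    surv[i] <- if (nd$type == "leaf") TRUE else {
      any(surv[nd$children])
    }
  }
  if (!surv[1]) return(NULL)
  build <- function(i) {
    nd <- nodes[[i]]
    if (nd$type == "leaf") return(nd$label)
    kids <- nd$children[surv[nd$children]]
    subs <- lapply(kids, build)
    subs <- subs[!vapply(subs, is.null, logical(1))]
    if (!length(subs)) return(NULL)
    if (length(subs) == 1L) return(subs[[1]])
    paste0("(", paste0(unlist(subs), collapse = ","), ")")
  }
  nwk <- build(1)
  if (is.null(nwk) || !grepl(",", nwk)) return(NULL)
  gt <- parse_newick(paste0(nwk, ";"))
  leaf_map <- stats::setNames(sub("_[0-9]+$", "", gt$tip.label),
                              gt$tip.label)
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(), time = numeric(), donor = character(),
               recipient = character(), node = integer())
  # a transfer is part of the observable history only if its recipient copy
  # survives to the tips (replacing transfers can erase earlier ones)
  if (nrow(ev)) {
    ev$surviving <- vapply(seq_len(nrow(ev)), function(i) {
      if (ev$type[i] != "transfer") return(NA)
      nd <- ev$node[i]
      if (!surv[nd]) return(FALSE)
      rec <- nodes[[nd]]$children[nodes[[nd]]$roles == "recipient"]
      length(rec) > 0 && any(surv[rec])
    }, logical(1))
  } else ev$surviving <- logical(0)
  list(gene_tree = gt, leaf_map = leaf_map,
       events = ev[is.na(ev$surviving) | ev$surviving, , drop = FALSE],
       events_all = ev)
}

#' Simulate sequences under GTR+Gamma(+I) on a tree
#'
#' Root states are drawn from the stationary frequencies; site rates come
#' from the discrete gamma (mean-of-quantile categories) with an optional
#' zero-rate invariant class.
#'
#' @param tree `phylo` with branch lengths.
#' @param params a [gtr_gamma_params()] object.
#' @param n_sites alignment length.
#' @param seed RNG seed.
#' @return An [msa] with attribute `site_rates`.
#' @export
evolve_sequences <- function(tree, params, n_sites, seed = 1) {
  stopifnot(inherits(params, "gtr_params"), n_sites >= 1)
  set.seed(seed)
  k <- params$k
  rates <- phangorn::discrete.gamma(params$shape, k)
  cls <- sample.int(k, n_sites, replace = TRUE)
  inv <- stats::runif(n_sites) < params$p_inv
  cols <- matrix("", nrow = length(tree$tip.label), ncol = n_sites,
                 dimnames = list(tree$tip.label, NULL))
  for (ci in seq_len(k)) {
    idx <- which(cls == ci & !inv)
    if (!length(idx)) next
    simd <- phangorn::simSeq(tree, l = length(idx), Q = params$exch,
                             bf = params$bf, rate = rates[ci])
    m <- toupper(as.character(simd))
    cols[, idx] <- m[tree$tip.label, , drop = FALSE]
  }
  if (any(inv)) {
    base <- sample(c("A", "C", "G", "T"), sum(inv), replace = TRUE,
                   prob = params$bf)
    cols[, inv] <- matrix(base, nrow = nrow(cols), ncol = sum(inv),
                          byrow = TRUE)
  }
  seqs <- apply(cols, 1, paste0, collapse = "")
  out <- msa(seqs, type = "nucleotide")
  attr(out, "site_rates") <- ifelse(inv, 0, rates[cls])
  out
}

.codon_universe <- function() {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  list(code = code, sense = sense)
}

#' Simulate a diverged codon-sequence pair at a given omega
#'
#' An ancestor of `n_codons` uniform sense codons evolves independently down
#' two branches of length `t/2` under a simple codon process: single-
#' nucleotide changes at rate 1/3 per position, multiplied by `omega` when
#' nonsynonymous; changes to stop codons are forbidden.
#'
#' @param omega dN/dS of the simulation.
#' @param t total divergence time (expected neutral substitutions per site).
#' @param n_codons number of codons.
#' @param seed RNG seed.
#' @return List `cds1`, `cds2` (strings), `omega`, `t`.
#' @export
evolve_codon_pair <- function(omega, t, n_codons, seed = 1) {
  set.seed(seed)
  u <- .codon_universe()
  anc <- sample(u$sense, n_codons, replace = TRUE)
  evolve_one <- function(codon, time) {
    repeat {
      b <- strsplit(codon, "")[[1]]
      neigh <- character(0); nrate <- numeric(0)
      for (p in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), b[p])) {
        cb <- b; cb[p] <- nt
        cc <- paste0(cb, collapse = "")
        if (u$code[[cc]] == "*") next
        neigh <- c(neigh, cc)
        nrate <- c(nrate, if (u$code[[cc]] == u$code[[codon]]) 1 / 3
                          else omega / 3)
      }
      R <- sum(nrate)
      if (R <= 0) return(codon)
      dt <- stats::rexp(1, R)
      if (dt > time) return(codon)
      time <- time - dt
      codon <- sample(neigh, 1L, prob = nrate)
    }
  }
  cds1 <- vapply(anc, evolve_one, character(1), time = t / 2)
  cds2 <- vapply(anc, evolve_one, character(1), time = t / 2)
  list(cds1 = paste0(cds1, collapse = ""), cds2 = paste0(cds2, collapse = ""),
       omega = omega, t = t)
}

#' Synthetic MS1 peak list with ppm noise and decoys
#'
#' True masses are perturbed with Gaussian noise of the stated ppm scale;
#' decoy peaks are drawn uniformly over the m/z range, excluding windows of
#' +/- 3 sigma ppm around every true mass.
#'
#' @param true_masses numeric vector of true m/z values (may be empty).
#' @param ppm_sigma noise scale in ppm (>= 0).
#' @param n_decoys number of decoy peaks.
#' @param mz_range decoy m/z range.
#' @param seed RNG seed.
#' @return Data frame `mz`, `intensity` sorted by mz, with
#'   `attr(, "truth")` holding the noiseless masses.
#' @export
synth_peaks <- function(true_masses, ppm_sigma = 2, n_decoys = 50,
                        mz_range = c(300, 1500), seed = 1) {
  if (ppm_sigma < 0) stop("ppm_sigma must be >= 0")
  set.seed(seed)
  obs <- true_masses * (1 + stats::rnorm(length(true_masses)) * ppm_sigma * 1e-6)
  decoys <- numeric(0)
  guard <- 3 * ppm_sigma * 1e-6
  while (length(decoys) < n_decoys) {
    cand <- stats::runif(n_decoys, mz_range[1], mz_range[2])
    if (length(true_masses)) {
      ok <- vapply(cand, function(x) {
        all(abs(x - true_masses) > guard * true_masses + 1e-3)
      }, logical(1))
      cand <- cand[ok]
    }
    decoys <- c(decoys, cand)
  }
  decoys <- decoys[seq_len(n_decoys)]
  mz <- c(obs, decoys)
  df <- data.frame(mz = mz,
                   intensity = stats::rlnorm(length(mz), 10, 1))
  df <- df[order(df$mz), ]
  rownames(df) <- NULL
  attr(df, "truth") <- true_masses
  df
}
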