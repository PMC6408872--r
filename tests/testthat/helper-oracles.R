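# Shared fixtures and independent oracles used across the suite.

# --- training precursors -----------------------------------------------------

# small MSDIN-family training sets, one per leader style; generated once from
# the planting generator so leader conservation matches the mining target
msdin_training <- function(style = "MDAN", n = 5, core = "IWGIGCNP") {
  vapply(seq_len(n), function(i) {
    plant_msdin_contig(length = 600, gc = 0.49, core = core,
                       leader_style = style, n_introns = 0,
                       seed = 5000 + i)$truth$precursor
  }, character(1))
}

# --- brute-force likelihood oracle ------------------------------------------

# GTR rate matrix from exchangeabilities (AC, AG, AT, CG, CT, GT) and base
# frequencies, scaled to mean rate 1 (states a, c, g, t)
oracle_gtr_q <- function(exch, bf) {
  Q <- matrix(0, 4, 4, dimnames = list(c("a", "c", "g", "t"),
                                       c("a", "c", "g", "t")))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    Q[i, j] <- exch[k] * bf[j]
    Q[j, i] <- exch[k] * bf[i]
  }
  diag(Q) <- -rowSums(Q)
  Q / sum(-diag(Q) * bf)
}

oracle_pmat <- function(Q, t) {
  e <- eigen(Q)
  Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
}

# total log-likelihood by summing over all internal-state assignments,
# mixing over discrete gamma categories; tree is a rooted binary ape phylo
# with <= 4 tips, aln a named character vector of equal-length DNA strings
oracle_loglik <- function(tree, aln, exch, bf, shape, k = 4, p_inv = 0) {
  states <- c("a", "c", "g", "t")
  Q <- oracle_gtr_q(exch, bf)
  rates <- phangorn::discrete.gamma(shape, k)
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  parent <- rep(NA_integer_, nn); parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- rep(NA_real_, nn); elen[tree$edge[, 2]] <- tree$edge.length
  root <- nt + 1L
  internals <- (nt + 1L):nn
  L <- nchar(aln[[1]])
  mats <- lapply(rates, function(r) {
    lapply(seq_len(nn), function(v) {
      if (v == root) NULL else oracle_pmat(Q, r * elen[v])
    })
  })
  site_ll <- numeric(L)
  tipchar <- lapply(tree$tip.label, function(tl) {
    match(strsplit(tolower(aln[[tl]]), "")[[1]], states)
  })
  names(tipchar) <- tree$tip.label
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  for (s in seq_len(L)) {
    like_cat <- numeric(k)
    obs <- vapply(seq_len(nt), function(v) tipchar[[tree$tip.label[v]]][s],
                  integer(1))
    for (ci in seq_len(k)) {
      tot <- 0
      for (g in seq_len(nrow(grid))) {
        assign_int <- grid[g, ]
        state_of <- function(v) {
          if (v <= nt) obs[v] else assign_int[match(v, internals)]
        }
        p <- bf[state_of(root)]
        for (v in seq_len(nn)) {
          if (v == root) next
          p <- p * mats[[ci]][[v]][state_of(parent[v]), state_of(v)]
        }
        tot <- tot + p
      }
      like_cat[ci] <- tot
    }
    lik <- mean(like_cat) * (1 - p_inv)
    if (p_inv > 0 && length(unique(obs)) == 1L) {
      lik <- lik + p_inv * bf[obs[1]]
    }
    site_ll[s] <- log(lik)
  }
  list(total = sum(site_ll), site = site_ll)
}

# --- brute-force DTL reconciliation oracle ----------------------------------

# exhaustive scenario enumeration: every assignment of gene internal nodes to
# species vertices, with the cheapest consistent event at each node.
oracle_dtl <- function(gene_tree, species_tree, leaf_map, costs,
                       allow_transfer = TRUE) {
  gi <- amatox:::.tree_index(gene_tree)
  si <- amatox:::.tree_index(species_tree)
  S <- si$n_nodes
  sp_id <- stats::setNames(seq_len(si$n_tips), species_tree$tip.label)
  anc <- matrix(FALSE, S, S)
  ddist <- matrix(Inf, S, S)
  for (b in seq_len(S)) {
    a <- b; d <- 0
    while (!is.na(a)) { anc[a, b] <- TRUE; ddist[a, b] <- d
                        a <- si$parent[a]; d <- d + 1 }
  }
  incomp <- !(anc | t(anc))
  internals <- gi$postorder[gi$postorder > gi$n_tips]
  leafM <- vapply(seq_len(gi$n_tips), function(g) {
    sp_id[[leaf_map[[gene_tree$tip.label[g]]]]]
  }, integer(1))
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), length(internals))))
  best <- Inf
  node_cost <- function(s, s1, s2) {
    opts <- numeric(0)
    if (s > si$n_tips) {
      sl <- si$kids[[s]][1]; sr <- si$kids[[s]][2]
      if (anc[sl, s1] && anc[sr, s2]) {
        opts <- c(opts, costs$loss * (ddist[sl, s1] + ddist[sr, s2]))
      }
      if (anc[sl, s2] && anc[sr, s1]) {
        opts <- c(opts, costs$loss * (ddist[sl, s2] + ddist[sr, s1]))
      }
    }
    if (anc[s, s1] && anc[s, s2]) {
      opts <- c(opts, costs$dup + costs$loss * (ddist[s, s1] + ddist[s, s2]))
    }
    if (allow_transfer) {
      if (anc[s, s1] && incomp[s, s2]) {
        opts <- c(opts, costs$transfer + costs$loss * ddist[s, s1])
      }
      if (anc[s, s2] && incomp[s, s1]) {
        opts <- c(opts, costs$transfer + costs$loss * ddist[s, s2])
      }
    }
    if (length(opts)) min(opts) else Inf
  }
  for (g in seq_len(nrow(grid))) {
    asg <- grid[g, ]
    pos <- function(v) {
      if (v <= gi$n_tips) leafM[v] else asg[match(v, internals)]
    }
    tot <- 0
    for (v in internals) {
      ks <- gi$kids[[v]]
      tot <- tot + node_cost(pos(v), pos(ks[1]), pos(ks[2]))
      if (!is.finite(tot)) break
    }
    if (tot < best) best <- tot
  }
  best
}

# all rooted binary topologies (as newick strings) on the given labels
all_rooted_topologies <- function(labels) {
  if (length(labels) == 1L) return(labels)
  out <- character(0)
  n <- length(labels)
  first <- labels[1]
  # split the remaining labels: enumerate subsets containing the first label
  rest <- labels[-1]
  subsets <- unlist(lapply(0:(length(rest) - 1), function(k) {
    utils::combn(rest, k, simplify = FALSE)
  }), recursive = FALSE)
  for (sub in subsets) {
    left <- c(first, sub)
    right <- setdiff(labels, left)
    if (!length(right)) next
    for (l in all_rooted_topologies(left)) {
      for (r in all_rooted_topologies(right)) {
        out <- c(out, paste0("(", l, ",", r, ")"))
      }
    }
  }
  out
}

# --- NG86 path-enumeration oracle -------------------------------------------

oracle_ng86_counts <- function(cds1, cds2) {
  code <- Biostrings::GENETIC_CODE
  n_cod <- nchar(cds1) %/% 3
  starts <- 3 * (seq_len(n_cod) - 1) + 1
  co1 <- substring(cds1, starts, starts + 2)
  co2 <- substring(cds2, starts, starts + 2)
  syn_site <- function(cd) {
    b <- strsplit(cd, "")[[1]]
    s <- 0
    for (p in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), b[p])) {
      cb <- b; cb[p] <- nt
      if (code[[paste0(cb, collapse = "")]] == code[[cd]]) s <- s + 1 / 3
    }
    s
  }
  # recursive path enumeration between two codons
  paths <- function(from, to) {
    pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(pos)) return(list(c(s = 0, n = 0)))
    out <- list()
    fb <- strsplit(from, "")[[1]]; tb <- strsplit(to, "")[[1]]
    for (p in pos) {
      nb <- fb; nb[p] <- tb[p]
      mid <- paste0(nb, collapse = "")
      if (code[[mid]] == "*") next
      step <- if (code[[mid]] == code[[from]]) c(s = 1, n = 0) else c(s = 0, n = 1)
      for (tail in paths(mid, to)) {
        out[[length(out) + 1L]] <- step + tail
      }
    }
    out
  }
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_len(length(co1))) {
    S <- S + (syn_site(co1[i]) + syn_site(co2[i])) / 2
    pp <- paths(co1[i], co2[i])
    if (!length(pp)) {
      # all paths blocked by stops: ignore the restriction
      pos <- which(strsplit(co1[i], "")[[1]] != strsplit(co2[i], "")[[1]])
      perms <- if (length(pos) <= 1) list(pos) else {
        ps <- combinat_perms(pos)
        ps
      }
      pp <- list()
      for (pm in perms) {
        cur <- strsplit(co1[i], "")[[1]]; tb <- strsplit(co2[i], "")[[1]]
        acc <- c(s = 0, n = 0)
        for (p in pm) {
          nb <- cur; nb[p] <- tb[p]
          if (code[[paste0(nb, collapse = "")]] ==
              code[[paste0(cur, collapse = "")]]) {
            acc["s"] <- acc["s"] + 1
          } else acc["n"] <- acc["n"] + 1
          cur <- nb
        }
        pp[[length(pp) + 1L]] <- acc
      }
    }
    m <- colMeans(do.call(rbind, pp))
    Sd <- Sd + m[["s"]]; Nd <- Nd + m[["n"]]
  }
  list(S = S, N = 3 * length(co1) - S, Sd = Sd, Nd = Nd)
}

combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

# --- small tree helpers ------------------------------------------------------

random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  list(tree = tr, dist = ape::cophenetic.phylo(tr))
}

splits_of <- function(tree) {
  tips <- sort(tree$tip.label)
  s <- amatox:::.tree_splits(tree)
  canon <- vapply(s, function(x) {
    if (!(tips[1] %in% x)) x <- setdiff(tips, x)   # canonical side
    paste(sort(x), collapse = "|")
  }, character(1))
  sort(unique(canon))
}
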