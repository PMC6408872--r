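# Distance and maximum-likelihood machinery behind the tree analyses:
# pairwise nucleotide distances and neighbor joining, GTR+Gamma(+I)
# likelihood with per-site log-likelihood vectors, branch-length / parameter
# optimization, NNI hill-climbing under topology constraints, and
# monophyly / bipartition-conflict tests. Likelihood evaluation and
# optimization are delegated to phangorn's pruning implementation; the
# search, constraint and conflict logic live here.

#' GTR+Gamma(+I) parameter bundle
#'
#' @param exch six exchangeabilities in phangorn order
#'   (AC, AG, AT, CG, CT, GT), last conventionally 1.
#' @param bf base frequencies (A, C, G, T), summing to 1.
#' @param shape gamma shape alpha (> 0).
#' @param k number of discrete gamma categories (mean-of-quantile bins).
#' @param p_inv proportion of invariant sites in [0, 1).
#' @return A `gtr_params` list.
#' @export
gtr_gamma_params <- function(exch = c(1, 1, 1, 1, 1, 1),
                             bf = c(0.25, 0.25, 0.25, 0.25),
                             shape = 1, k = 4, p_inv = 0) {
  stopifnot(length(exch) == 6, length(bf) == 4, shape > 0,
            p_inv >= 0, p_inv < 1)
  if (abs(sum(bf) - 1) > 1e-9) stop("base frequencies must sum to 1")
  structure(list(exch = exch, bf = bf, shape = shape, k = as.integer(k),
                 p_inv = p_inv), class = "gtr_params")
}

#' Convert an alignment to phangorn's phyDat
#'
#' @param aln an [msa] object.
#' @return A `phyDat` object (gaps treated as missing data).
#' @export
as_phydat <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- names(aln)
  type <- if (attr(aln, "type") == "nucleotide") "DNA" else "AA"
  phangorn::phyDat(m, type = type)
}

#' Pairwise nucleotide distances
#'
#' Jukes-Cantor or Kimura two-parameter corrected distances with pairwise
#' deletion of gap/ambiguous columns. Saturated pairs (correction log
#' argument <= 0) are flagged `Inf`.
#'
#' @param aln an [msa] (nucleotide).
#' @param model `"JC"` or `"K80"`.
#' @return A symmetric distance matrix; saturated entries are `Inf` and the
#'   attribute `saturated` counts them.
#' @export
nucleotide_distance <- function(aln, model = c("JC", "K80")) {
  model <- match.arg(model)
  if (length(aln) < 2) stop("need >= 2 taxa")
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- names(aln)
  d <- ape::dist.dna(ape::as.DNAbin(tolower(m)),
                     model = c(JC = "JC69", K80 = "K80")[model],
                     pairwise.deletion = TRUE)
  dm <- as.matrix(d)
  sat <- !is.finite(dm) | is.nan(dm)
  diag(sat) <- FALSE
  dm[sat] <- Inf
  attr(dm, "saturated") <- sum(sat) / 2
  dm
}

#' Neighbor-joining tree
#'
#' @param dist_matrix symmetric distance matrix (all finite).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dist_matrix) {
  dm <- as.matrix(dist_matrix)
  if (nrow(dm) < 3) stop("need >= 3 taxa")
  if (any(!is.finite(dm))) {
    stop("distance matrix has non-finite entries (saturated pairs); ",
         "use a different substitution model or drop the offending taxa")
  }
  ape::nj(stats::as.dist(dm))
}

.check_leaves <- function(tree, aln) {
  miss <- setdiff(tree$tip.label, names(aln))
  extra <- setdiff(names(aln), tree$tip.label)
  if (length(miss) || length(extra)) {
    stop("tree/alignment taxon mismatch; missing from alignment: ",
         paste(miss, collapse = ", "), "; missing from tree: ",
         paste(extra, collapse = ", "))
  }
}

.pml_fit <- function(tree, aln, params) {
  dat <- as_phydat(aln)
  withCallingHandlers(
    phangorn::pml(tree, dat, bf = params$bf, Q = params$exch,
                  shape = params$shape, k = params$k, inv = params$p_inv),
    warning = function(w) {
      if (grepl("unrooted the tree", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

#' Total and site-wise log-likelihood under GTR+Gamma(+I)
#'
#' Felsenstein-pruning likelihood (via phangorn) of a tree with branch
#' lengths on a nucleotide alignment; the per-site vector sums to the total.
#'
#' @param tree `phylo` with branch lengths; tips must match the alignment.
#' @param aln an [msa].
#' @param params a [gtr_gamma_params()].
#' @return List with `total` and `site` (length = alignment columns).
#' @export
log_likelihood <- function(tree, aln, params = gtr_gamma_params()) {
  .check_leaves(tree, aln)
  fit <- .pml_fit(tree, aln, params)
  idx <- attr(fit$data, "index")
  list(total = as.numeric(fit$logLik), site = fit$siteLik[idx])
}

#' Optimize branch lengths and model parameters
#'
#' Coordinate-ascent optimization (phangorn's `optim.pml`): branch lengths
#' always; optionally the gamma shape, invariant proportion,
#' exchangeabilities and base frequencies. The log-likelihood is
#' non-decreasing across iterations.
#'
#' @param tree starting `phylo` (branch lengths required; zero lengths get a
#'   small floor).
#' @param aln an [msa].
#' @param params starting [gtr_gamma_params()].
#' @param opt_shape,opt_inv,opt_exch,opt_bf which parameters to free.
#' @return List: `tree` (optimized lengths), `params` (fitted), `logLik`,
#'   `site` (site log-likelihood vector).
#' @export
optimize_ml <- function(tree, aln, params = gtr_gamma_params(),
                        opt_shape = FALSE, opt_inv = FALSE,
                        opt_exch = FALSE, opt_bf = FALSE) {
  .check_leaves(tree, aln)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree$edge.length[tree$edge.length < 1e-8] <- 1e-8
  fit <- .pml_fit(tree, aln, params)
  fit <- withCallingHandlers(
    phangorn::optim.pml(fit, optEdge = TRUE, optGamma = opt_shape,
                        optInv = opt_inv, optQ = opt_exch,
                        optBf = opt_bf, optNni = FALSE,
                        control = phangorn::pml.control(trace = 0,
                                                        epsilon = 1e-6)),
    warning = function(w) {
      if (grepl("unrooted the tree", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  idx <- attr(fit$data, "index")
  out_params <- gtr_gamma_params(exch = fit$Q, bf = fit$bf,
                                 shape = fit$shape, k = fit$k,
                                 p_inv = fit$inv)
  list(tree = fit$tree, params = out_params,
       logLik = as.numeric(fit$logLik), site = fit$siteLik[idx])
}

#' Is a leaf set monophyletic on the unrooted tree?
#'
#' A set is monophyletic when it (or its complement) is induced by some
#' branch of the unrooted tree, i.e. forms one side of a bipartition.
#' Trivial sets (size <= 1 or the whole taxon set) are monophyletic.
#'
#' @param tree a `phylo` tree.
#' @param leafset character vector of tip labels.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, leafset) {
  tips <- tree$tip.label
  if (!all(leafset %in% tips)) {
    stop("unknown tip(s): ", paste(setdiff(leafset, tips), collapse = ", "))
  }
  set <- unique(leafset)
  if (length(set) <= 1L || length(set) >= length(tips)) return(TRUE)
  for (side in .tree_splits(tree)) {
    if (setequal(side, set) || setequal(setdiff(tips, side), set)) {
      return(TRUE)
    }
  }
  FALSE
}

# nontrivial splits of an unrooted tree: list of tip-label vectors (one side)
.tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sides <- lapply(pp, function(i) labs[i])
  sides <- sides[vapply(sides, length, integer(1)) >= 2 &
                 vapply(sides, length, integer(1)) <= length(labs) - 2]
  unique(sides)
}

#' Gene-tree bipartitions conflicting with a species tree
#'
#' Maps gene-tree tips to species via `leaf_map`, collapses duplicate
#' species within a split side, and reports every gene bipartition that is
#' incompatible with the species tree (two splits are compatible when one of
#' the four side intersections on the shared taxon set is empty). Split
#' sides containing the same species on both sides are skipped as
#' uninformative about the species tree.
#'
#' @param gene_tree,species_tree `phylo` trees.
#' @param leaf_map named character vector: gene tip -> species tip.
#' @return List of conflicting gene splits, each a character vector of
#'   species names (one side).
#' @export
conflicting_bipartitions <- function(gene_tree, species_tree, leaf_map) {
  unmapped <- setdiff(gene_tree$tip.label, names(leaf_map))
  if (length(unmapped)) {
    stop("unmapped gene tip(s): ", paste(unmapped, collapse = ", "))
  }
  sp_tips <- species_tree$tip.label
  bad_target <- setdiff(unique(leaf_map[gene_tree$tip.label]), sp_tips)
  if (length(bad_target)) {
    stop("leaf_map targets absent from species tree: ",
         paste(bad_target, collapse = ", "))
  }
  sp_splits <- .tree_splits(species_tree)
  shared <- unique(leaf_map[gene_tree$tip.label])
  conflicts <- list()
  for (side in .tree_splits(gene_tree)) {
    a <- unique(leaf_map[side])
    b <- unique(leaf_map[setdiff(gene_tree$tip.label, side)])
    if (length(intersect(a, b))) next   # same species on both sides
    if (length(a) < 2 || length(b) < 2) next
    ok <- TRUE
    for (sside in sp_splits) {
      a2 <- intersect(sside, shared); b2 <- intersect(setdiff(sp_tips, sside),
                                                      shared)
      if (length(a2) < 2 || length(b2) < 2) next
      inter <- c(length(intersect(a, a2)), length(intersect(a, b2)),
                 length(intersect(b, a2)), length(intersect(b, b2)))
      if (all(inter > 0)) { ok <- FALSE; break }
    }
    if (!ok) conflicts[[length(conflicts) + 1L]] <- sort(a)
  }
  unique(conflicts)
}

.satisfies_constraints <- function(tree, constraints) {
  all(vapply(constraints, function(cs) is_monophyletic(tree, cs), logical(1)))
}

#' NNI hill-climbing tree search under clade constraints
#'
#' Starting from `start_tree`, repeatedly evaluates all nearest-neighbor
#' interchanges (branch lengths re-optimized per candidate), never accepts a
#' topology violating any constraint, and stops at a local optimum. The
#' move list is evaluated in a fixed order, so the search is deterministic.
#'
#' @param aln an [msa].
#' @param start_tree starting `phylo`; must satisfy the constraints.
#' @param params a [gtr_gamma_params()].
#' @param constraints list of tip-label vectors, each required to stay
#'   monophyletic.
#' @param max_rounds maximum accepted moves.
#' @return List: `tree`, `logLik`, `site`, `params`, `n_moves`.
#' @export
nni_search <- function(aln, start_tree, params = gtr_gamma_params(),
                       constraints = list(), max_rounds = 50) {
  if (!.satisfies_constraints(start_tree, constraints)) {
    stop("start tree violates the constraint set")
  }
  cur <- optimize_ml(start_tree, aln, params)
  n_moves <- 0L
  repeat {
    if (n_moves >= max_rounds) break
    nbrs0 <- phangorn::nni(cur$tree)
    nbrs <- lapply(seq_along(nbrs0), function(i) nbrs0[[i]])
    best <- NULL
    for (nb in nbrs) {
      if (!.satisfies_constraints(nb, constraints)) next
      cand <- optimize_ml(nb, aln, cur$params)
      if (cand$logLik > cur$logLik + 1e-6 &&
          (is.null(best) || cand$logLik > best$logLik)) {
        best <- cand
      }
    }
    if (is.null(best)) break
    cur <- best
    n_moves <- n_moves + 1L
  }
  cur$n_moves <- n_moves
  cur
}
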