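# Gene-tree / species-tree reconciliation with weighted event scores:
# duplication-loss (DL) via the LCA mapping (optimal for DL costs) and
# duplication-transfer-loss (DTL) via a dynamic program over gene nodes x
# species vertices on an undated species tree (transfers allowed between
# incomparable branches only). Default costs follow Notung: duplication
# 1.5, transfer 3.0, loss 1.0.

#' Event costs for reconciliation
#'
#' @param dup,transfer,loss non-negative event costs.
#' @return An `event_costs` list.
#' @export
event_costs <- function(dup = 1.5, transfer = 3.0, loss = 1.0) {
  if (any(c(dup, transfer, loss) < 0)) stop("costs must be >= 0")
  structure(list(dup = dup, transfer = transfer, loss = loss),
            class = "event_costs")
}

.recon_result <- function(n_dup, n_transfer, n_loss, costs, model,
                          n_optimal = NA_integer_) {
  out <- list(n_dup = n_dup, n_transfer = n_transfer, n_loss = n_loss,
              score = costs$dup * n_dup + costs$transfer * n_transfer +
                      costs$loss * n_loss,
              costs = costs, model = model, n_optimal = n_optimal)
  class(out) <- "reconciliation_result"
  out
}

#' @export
print.reconciliation_result <- function(x, ...) {
  cat(sprintf("%s reconciliation: score %.1f (dups %d, transfers %d, losses %d%s)\n",
              x$model, x$score, x$n_dup, x$n_transfer, x$n_loss,
              if (is.na(x$n_optimal)) "" else
                paste0("; optimal solutions ", x$n_optimal)))
  invisible(x)
}

# rooted binary tree bookkeeping for ape phylo objects
.tree_index <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  parent <- rep(NA_integer_, nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  kids <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  }
  if (any(vapply(kids[(nt + 1):nn], length, integer(1)) != 2L)) {
    stop("tree must be rooted and binary (non-binary node found)")
  }
  root <- nt + 1L
  depth <- rep(NA_integer_, nn); depth[root] <- 0L
  ord <- root
  i <- 1L
  while (i <= length(ord)) {
    v <- ord[i]
    for (ch in kids[[v]]) { depth[ch] <- depth[v] + 1L; ord <- c(ord, ch) }
    i <- i + 1L
  }
  list(n_tips = nt, n_nodes = nn, parent = parent, kids = kids, root = root,
       depth = depth, preorder = ord, postorder = rev(ord))
}

.check_map <- function(gene_tree, species_tree, leaf_map) {
  unmapped <- setdiff(gene_tree$tip.label, names(leaf_map))
  if (length(unmapped)) {
    stop("unmapped gene leaf(s): ", paste(unmapped, collapse = ", "))
  }
  bad <- setdiff(unname(leaf_map[gene_tree$tip.label]),
                 species_tree$tip.label)
  if (length(bad)) {
    stop("leaf_map target(s) not in species tree: ",
         paste(bad, collapse = ", "))
  }
}

#' Duplication-loss reconciliation via the LCA mapping
#'
#' Maps every gene node to the species LCA of its descendants; a gene node
#' is a duplication when it maps to the same species vertex as one of its
#' children, and losses are counted from the depth differences along each
#' child mapping path (minus one traversed speciation for speciation
#' nodes). The LCA mapping minimizes the weighted DL cost.
#'
#' @param gene_tree,species_tree rooted binary `phylo` trees.
#' @param leaf_map named character vector: gene tip -> species tip.
#' @param costs an [event_costs()].
#' @return A `reconciliation_result` (model `"DL"`); the per-node mapping is
#'   in `attr(, "mapping")`.
#' @export
lca_reconcile_dl <- function(gene_tree, species_tree, leaf_map,
                             costs = event_costs()) {
  .check_map(gene_tree, species_tree, leaf_map)
  gi <- .tree_index(gene_tree)
  si <- .tree_index(species_tree)
  sp_id <- stats::setNames(seq_len(si$n_tips), species_tree$tip.label)
  lca2 <- function(a, b) {
    while (a != b) {
      if (si$depth[a] >= si$depth[b]) a <- si$parent[a] else b <- si$parent[b]
    }
    a
  }
  M <- rep(NA_integer_, gi$n_nodes)
  n_dup <- 0L; n_loss <- 0L
  for (g in gi$postorder) {
    if (g <= gi$n_tips) {
      M[g] <- sp_id[[leaf_map[[gene_tree$tip.label[g]]]]]
    } else {
      c1 <- gi$kids[[g]][1]; c2 <- gi$kids[[g]][2]
      M[g] <- lca2(M[c1], M[c2])
      dup <- (M[g] == M[c1]) || (M[g] == M[c2])
      if (dup) n_dup <- n_dup + 1L
      for (ch in c(c1, c2)) {
        k <- si$depth[M[ch]] - si$depth[M[g]]
        n_loss <- n_loss + if (dup) k else k - 1L
      }
    }
  }
  out <- .recon_result(n_dup, 0L, n_loss, costs, "DL")
  attr(out, "mapping") <- M
  out
}

# tuple comparator: cost, then transfers, then first-come (deterministic
# enumeration order: species vertices ascending)
.better <- function(cost_a, nt_a, cost_b, nt_b, eps = 1e-9) {
  if (cost_a < cost_b - eps) return(TRUE)
  if (cost_a > cost_b + eps) return(FALSE)
  nt_a < nt_b
}

#' Duplication-transfer-loss reconciliation (undated species tree)
#'
#' Dynamic program over gene nodes x species vertices. Events: speciation
#' (free), duplication, transfer (the recipient may be any species vertex
#' incomparable to the donor: no ancestor/descendant transfers), and loss
#' charged once per species edge a gene lineage descends through without
#' the expected sister copy. Ties prefer fewer transfers, then the smallest
#' species vertex in a fixed enumeration order; the count of co-optimal
#' event placements (under cost alone) is reported.
#'
#' @inheritParams lca_reconcile_dl
#' @return A `reconciliation_result` (model `"DTL"`).
#' @export
dtl_reconcile <- function(gene_tree, species_tree, leaf_map,
                          costs = event_costs()) {
  .check_map(gene_tree, species_tree, leaf_map)
  gi <- .tree_index(gene_tree)
  si <- .tree_index(species_tree)
  S <- si$n_nodes
  sp_id <- stats::setNames(seq_len(si$n_tips), species_tree$tip.label)
  # ancestry: anc[a, b] TRUE when a is ancestor-or-equal of b
  anc <- matrix(FALSE, S, S)
  for (b in seq_len(S)) {
    a <- b
    while (!is.na(a)) { anc[a, b] <- TRUE; a <- si$parent[a] }
  }
  incomp <- !(anc | t(anc))
  INF <- Inf
  # per gene node: cost/dup/trans/loss/count vectors over species vertices
  C <- list(); ND <- list(); NT <- list(); NL <- list(); CNT <- list()
  IN <- list(); IND <- list(); INT <- list(); INL <- list(); INC <- list()
  for (g in gi$postorder) {
    cost <- rep(INF, S); nd <- integer(S); ntr <- integer(S); nl <- integer(S)
    cnt <- rep(0, S)
    if (g <= gi$n_tips) {
      s0 <- sp_id[[leaf_map[[gene_tree$tip.label[g]]]]]
      cost[s0] <- 0; cnt[s0] <- 1
    } else {
      c1 <- gi$kids[[g]][1]; c2 <- gi$kids[[g]][2]
      in1 <- IN[[c1]]; in2 <- IN[[c2]]
      # out(g, s): best c over vertices incomparable to s
      out_of <- function(ch) {
        cc <- C[[ch]]
        vapply(seq_len(S), function(s) {
          v <- cc[incomp[s, ]]
          if (length(v)) min(v) else INF
        }, numeric(1))
      }
      pick_out <- function(ch, s) {
        cand <- which(incomp[s, ] & abs(C[[ch]] - min(C[[ch]][incomp[s, ]])) < 1e-9)
        cand[which.min(NT[[ch]][cand])]
      }
      out1 <- out_of(c1); out2 <- out_of(c2)
      for (s in seq_len(S)) {
        best_cost <- INF; best <- NULL; ties <- 0
        consider <- function(cc, dd, tt, ll, mult) {
          if (!is.finite(cc)) return()
          if (abs(cc - best_cost) < 1e-9) {
            ties <<- ties + mult
            if (.better(cc, tt, best_cost, best$tt)) {
              best <<- list(dd = dd, tt = tt, ll = ll)
            }
          } else if (cc < best_cost) {
            best_cost <<- cc
            ties <<- mult
            best <<- list(dd = dd, tt = tt, ll = ll)
          }
        }
        if (s > si$n_tips) {
          sl <- si$kids[[s]][1]; sr <- si$kids[[s]][2]
          consider(in1[sl] + in2[sr],
                   IND[[c1]][sl] + IND[[c2]][sr],
                   INT[[c1]][sl] + INT[[c2]][sr],
                   INL[[c1]][sl] + INL[[c2]][sr],
                   INC[[c1]][sl] * INC[[c2]][sr])
          consider(in1[sr] + in2[sl],
                   IND[[c1]][sr] + IND[[c2]][sl],
                   INT[[c1]][sr] + INT[[c2]][sl],
                   INL[[c1]][sr] + INL[[c2]][sl],
                   INC[[c1]][sr] * INC[[c2]][sl])
        }
        consider(costs$dup + in1[s] + in2[s],
                 1L + IND[[c1]][s] + IND[[c2]][s],
                 INT[[c1]][s] + INT[[c2]][s],
                 INL[[c1]][s] + INL[[c2]][s],
                 INC[[c1]][s] * INC[[c2]][s])
        if (is.finite(out2[s])) {
          r <- pick_out(c2, s)
          consider(costs$transfer + in1[s] + out2[s],
                   IND[[c1]][s] + ND[[c2]][r],
                   1L + INT[[c1]][s] + NT[[c2]][r],
                   INL[[c1]][s] + NL[[c2]][r],
                   INC[[c1]][s] * sum(CNT[[c2]][incomp[s, ] &
                                                abs(C[[c2]] - out2[s]) < 1e-9]))
        }
        if (is.finite(out1[s])) {
          r <- pick_out(c1, s)
          consider(costs$transfer + in2[s] + out1[s],
                   IND[[c2]][s] + ND[[c1]][r],
                   1L + INT[[c2]][s] + NT[[c1]][r],
                   INL[[c2]][s] + NL[[c1]][r],
                   INC[[c2]][s] * sum(CNT[[c1]][incomp[s, ] &
                                                abs(C[[c1]] - out1[s]) < 1e-9]))
        }
        if (!is.null(best)) {
          cost[s] <- best_cost; nd[s] <- best$dd; ntr[s] <- best$tt
          nl[s] <- best$ll; cnt[s] <- ties
        }
      }
    }
    C[[g]] <- cost; ND[[g]] <- nd; NT[[g]] <- ntr; NL[[g]] <- nl
    CNT[[g]] <- cnt
    # in(g, s) = min over s' <= s of c(g, s') + loss per descended edge
    icost <- cost; id <- nd; it <- ntr; il <- nl; ic <- cnt
    for (s in si$postorder) {
      for (ch in si$kids[[s]]) {
        cand <- icost[ch] + costs$loss
        if (!is.finite(cand)) next
        if (abs(cand - icost[s]) < 1e-9) {
          ic[s] <- ic[s] + ic[ch]
          if (it[ch] < it[s]) {
            id[s] <- id[ch]; it[s] <- it[ch]; il[s] <- il[ch] + 1L
          }
        } else if (cand < icost[s]) {
          icost[s] <- cand; id[s] <- id[ch]; it[s] <- it[ch]
          il[s] <- il[ch] + 1L; ic[s] <- ic[ch]
        }
      }
    }
    IN[[g]] <- icost; IND[[g]] <- id; INT[[g]] <- it; INL[[g]] <- il
    INC[[g]] <- ic
  }
  groot <- gi$root
  cost <- C[[groot]]
  s_best <- which(abs(cost - min(cost)) < 1e-9)
  s_best <- s_best[order(NT[[groot]][s_best], s_best)][1]
  out <- .recon_result(ND[[groot]][s_best], NT[[groot]][s_best],
                       NL[[groot]][s_best], costs, "DTL",
                       n_optimal = sum(CNT[[groot]][abs(cost - min(cost)) < 1e-9]))
  attr(out, "root_vertex") <- s_best
  out
}

#' Compare DL and DTL reconciliations
#'
#' Runs both models at the same costs; the verdict is `"HGT-favored"` when
#' the DTL optimum is strictly cheaper than the DL optimum, `"no signal"`
#' when both are zero, and `"DL-adequate"` otherwise.
#'
#' @inheritParams lca_reconcile_dl
#' @return List: `dl`, `dtl`, `verdict`.
#' @export
compare_models <- function(gene_tree, species_tree, leaf_map,
                           costs = event_costs()) {
  dl <- lca_reconcile_dl(gene_tree, species_tree, leaf_map, costs)
  dtl <- dtl_reconcile(gene_tree, species_tree, leaf_map, costs)
  verdict <- if (dl$score == 0 && dtl$score == 0) "no signal"
             else if (dtl$score < dl$score) "HGT-favored"
             else "DL-adequate"
  list(dl = dl, dtl = dtl, verdict = verdict)
}
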