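## Maximum-likelihood phylogenetic placement of query fragments on a fixed
## annotated reference tree, conditioned on the reference alignment and its
## branch lengths.  The query is attached by a new node at each edge midpoint
## with a pendant branch whose length is the only free parameter (bounded
## scalar search); the argmax edge is reported with a likelihood weight
## ratio, and the edge's position relative to the annotated clades yields the
## eukaryote/prokaryote (and mitochondrial/cytosolic) classification.
##
## The engine precomputes, per edge and per Gamma category, the product of
## the inward conditional likelihoods from both sides of the edge midpoint,
## so evaluating a candidate pendant length costs one 20x20 P(t) and one
## elementwise product per site.  Reference trees here are small curated
## families (tens of tips), so per-site partials stay comfortably inside
## double range without rescaling.

#' Build a placement engine for one reference family
#'
#' @param atree an [annotate_tree()] object (tips annotated with domains).
#' @param ref_msa amino-acid `msa`; row ids must cover the tree's tips.
#' @param model an [aa_model()]; the pipeline default is WAG with
#'   discrete-Gamma (alpha 1, 4 categories).
#' @return object of class `"placement_engine"`.
#' @export
placement_engine <- function(atree, ref_msa, model = wag_model(1.0, 4L)) {
  stopifnot(inherits(atree, "annotated_tree"), inherits(ref_msa, "msa"))
  tr <- atree$tree
  if (!all(tr$tip.label %in% rownames(ref_msa)))
    stop("alignment missing tree tip(s): ",
         paste(setdiff(tr$tip.label, rownames(ref_msa)), collapse = ", "))
  enc <- .encode_msa(ref_msa)[tr$tip.label, , drop = FALSE]
  S <- ncol(enc)
  ncat <- model$n_categories
  rates <- model$category_rates
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  post <- ape::postorder(tr)
  edge <- tr$edge; elen <- tr$edge.length
  nedge <- nrow(edge)

  ## per-category transition matrices per edge (full and half lengths)
  Pfull <- Phalf <- vector("list", nedge)
  for (e in seq_len(nedge)) {
    Pfull[[e]] <- lapply(rates, function(r) transition_probs(model, elen[e] * r))
    Phalf[[e]] <- lapply(rates, function(r) transition_probs(model, elen[e] / 2 * r))
  }

  tip_partial <- function(i) {
    # 20 x S, indicator columns; missing data = ones
    Fm <- matrix(1, 20L, S)
    obs <- which(!is.na(enc[i, ]))
    Fm[, obs] <- 0
    Fm[cbind(enc[i, obs], obs)] <- 1
    Fm
  }

  ## inward (rootward) partials per node, per category
  Fpart <- vector("list", ncat)
  msg <- vector("list", ncat)          # per edge: P(t_e) %*% F_child
  for (cc in seq_len(ncat)) {
    Fc <- vector("list", nnode)
    for (i in seq_len(ntip)) Fc[[i]] <- tip_partial(i)
    mg <- vector("list", nedge)
    for (e in post) {
      p <- edge[e, 1]; ch <- edge[e, 2]
      mg[[e]] <- Pfull[[e]][[cc]] %*% Fc[[ch]]
      Fc[[p]] <- if (is.null(Fc[[p]])) mg[[e]] else Fc[[p]] * mg[[e]]
    }
    Fpart[[cc]] <- Fc
    msg[[cc]] <- mg
  }

  ## outward partials per edge (conditioned on the state at the parent node)
  parent_edge <- integer(nnode)        # edge above each node (0 for root)
  for (e in seq_len(nedge)) parent_edge[edge[e, 2]] <- e
  Opart <- vector("list", ncat)
  for (cc in seq_len(ncat)) {
    Oc <- vector("list", nedge)
    for (e in rev(post)) {             # parents before children
      p <- edge[e, 1]
      pe <- parent_edge[p]
      up <- if (pe == 0L) matrix(1, 20L, S)
            else Pfull[[pe]][[cc]] %*% Oc[[pe]]
      sibs <- which(edge[, 1] == p & seq_len(nedge) != e)
      for (sb in sibs) up <- up * msg[[cc]][[sb]]
      Oc[[e]] <- up
    }
    Opart[[cc]] <- Oc
  }

  ## per-edge midpoint site weights W[a, site] = pi_a * down_a * up_a
  W <- vector("list", nedge)
  for (e in seq_len(nedge)) {
    W[[e]] <- lapply(seq_len(ncat), function(cc) {
      dn <- Phalf[[e]][[cc]] %*% Fpart[[cc]][[edge[e, 2]]]
      up <- Phalf[[e]][[cc]] %*% Opart[[cc]][[e]]
      model$freqs * dn * up
    })
  }
  W0 <- lapply(W, function(we) vapply(we, colSums, numeric(S)))  # S x ncat

  structure(list(atree = atree, tree = tr, model = model, enc = enc,
                 n_sites = S, edge = edge, edge_length = elen,
                 W = W, W0 = W0,
                 tipsets = .edge_tipsets(tr)),
            class = "placement_engine")
}

#' @export
print.placement_engine <- function(x, ...) {
  cat(sprintf("placement engine: %d-tip reference tree, %d sites, %d Gamma categories\n",
              length(x$tree$tip.label), x$n_sites, x$model$n_categories))
  invisible(x)
}

## attachment log-likelihood of a query on one edge at pendant length s
.attach_loglik <- function(engine, e, qidx, obs, s) {
  model <- engine$model
  ncat <- model$n_categories
  tot <- numeric(engine$n_sites)
  for (cc in seq_len(ncat)) {
    P <- transition_probs(model, s * model$category_rates[cc])
    lik <- engine$W0[[e]][, cc]                    # missing sites: sum_a W
    if (length(obs)) {
      Wo <- engine$W[[e]][[cc]][, obs, drop = FALSE]
      lik[obs] <- colSums(Wo * P[, qidx[obs], drop = FALSE])
    }
    tot <- tot + lik / ncat
  }
  sum(log(tot))
}

#' Place a query row on the reference tree by maximum likelihood
#'
#' The query must already be in reference-alignment coordinates (see
#' [align_hit_to_reference()]); its gapped sites are treated as missing data.
#' For every edge the pendant length is optimized on \[1e-8, 5\] (tolerance
#' 1e-6); the best edge, its optimized log-likelihood, the likelihood weight
#' ratio over edges and the clade classification are reported.
#'
#' @param engine a [placement_engine()].
#' @param query_row gapped amino-acid string of `engine$n_sites` characters.
#' @param query_id id carried into the result.
#' @return object of class `"placement_result"`.
#' @export
place_query <- function(engine, query_row, query_id = "query") {
  q <- strsplit(toupper(query_row), "", fixed = TRUE)[[1]]
  if (length(q) != engine$n_sites)
    stop("query row has ", length(q), " columns; reference has ", engine$n_sites)
  qidx <- .aa_index(q)
  obs <- which(!is.na(qidx))
  if (!length(obs)) stop("query has zero ungapped sites")
  nedge <- nrow(engine$edge)
  ll <- pend <- numeric(nedge)
  for (e in seq_len(nedge)) {
    opt <- stats::optimize(function(s) .attach_loglik(engine, e, qidx, obs, s),
                           interval = c(1e-8, 5), maximum = TRUE, tol = 1e-6)
    ll[e] <- opt$objective; pend[e] <- opt$maximum
  }
  best <- which.max(ll)
  lwr <- exp(ll - max(ll)); lwr <- lwr / sum(lwr)
  cls <- classify_placement(best, engine$atree, tipsets = engine$tipsets)
  structure(list(query_id = query_id, best_edge = best,
                 pendant_length = pend[best], log_likelihood = ll[best],
                 like_weight_ratio = lwr[best], all_log_likelihoods = ll,
                 all_pendants = pend, classification = cls$domain,
                 lineage = cls$lineage, low_confidence = cls$low_confidence),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat(sprintf("placement of '%s': edge %d (pendant %.4f, logL %.3f, LWR %.3f) -> %s/%s%s\n",
              x$query_id, x$best_edge, x$pendant_length, x$log_likelihood,
              x$like_weight_ratio, x$classification, x$lineage,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Classify a placement edge against the tree's clade annotations
#'
#' An attachment is called eukaryote iff the edge's subtended tip set (child
#' side) is purely eukaryote-annotated, or the edge is the stem edge of a
#' maximal eukaryote-only clade (checked from both sides for the edge
#' separating the domains); stem-edge placements are flagged low-confidence.
#' Mixed subtrees on both sides give prokaryote (not retained).  The same
#' rule over mitochondrial/cytosolic labels of the subtended eukaryote tips
#' yields the lineage call.
#'
#' @param edge_index row index into `atree$tree$edge`.
#' @param atree an [annotate_tree()] object.
#' @param tipsets optional precomputed `.edge_tipsets` result.
#' @return list: `domain`, `lineage`, `low_confidence`.
#' @export
classify_placement <- function(edge_index, atree, tipsets = NULL) {
  tr <- atree$tree
  if (any(atree$domain == "")) stop("unannotated tips")
  if (is.null(tipsets)) tipsets <- .edge_tipsets(tr)
  ntip <- length(tr$tip.label)
  below <- tipsets[[edge_index]]
  above <- setdiff(seq_len(ntip), below)
  dom <- function(idx) unname(atree$domain[tr$tip.label[idx]])
  pure_euk <- function(idx) length(idx) > 0L && all(dom(idx) == "eukaryote")

  side <- NULL; low_conf <- FALSE
  if (pure_euk(below)) {
    side <- below
    # stem edge of a maximal eukaryote-only clade: the parent node also
    # subtends prokaryotes (its own subtended set is mixed) or is the root
    p <- tr$edge[edge_index, 1]
    pe <- which(tr$edge[, 2] == p)
    low_conf <- if (length(pe)) !pure_euk(tipsets[[pe]]) && !pure_euk(above)
                else !pure_euk(above)
    if (pure_euk(above)) low_conf <- FALSE     # all-eukaryote tree
  } else if (pure_euk(above)) {
    side <- above; low_conf <- TRUE            # stem edge seen from the far side
  }
  if (is.null(side))
    return(list(domain = "prokaryote", lineage = "none", low_confidence = FALSE))
  lin <- unname(atree$lineage[tr$tip.label[side]])
  lin <- lin[lin != "unknown"]
  lineage <- if (!length(lin)) "unknown"
             else if (all(lin == "mitochondrial")) "mitochondrial"
             else if (all(lin == "cytosolic")) "cytosolic"
             else "ambiguous"
  list(domain = "eukaryote", lineage = lineage, low_confidence = low_conf)
}

#' Independent attachment log-likelihood (naive oracle)
#'
#' Grafts the query onto the tree at the midpoint of an edge with an explicit
#' pendant branch and recomputes the full-tree log-likelihood by plain
#' recursive pruning, sharing no code with the placement engine's
#' precomputed-partials path.  Used to validate [place_query()].
#'
#' @param atree annotated tree.
#' @param ref_msa reference alignment.
#' @param model amino-acid model.
#' @param query_row gapped query string in reference coordinates.
#' @param edge_index edge to attach to (row of `tree$edge`).
#' @param pendant pendant branch length.
#' @param query_id tip label for the grafted query.
#' @export
naive_attach_loglik <- function(atree, ref_msa, model, query_row, edge_index,
                                pendant, query_id = "query") {
  tr <- atree$tree
  child <- tr$edge[edge_index, 2]
  tq <- ape::read.tree(text = sprintf("(%s:%.10f);", query_id, pendant))
  grafted <- ape::bind.tree(tr, tq, where = child,
                            position = tr$edge.length[edge_index] / 2)
  qmat <- matrix(strsplit(toupper(query_row), "", fixed = TRUE)[[1]], nrow = 1,
                 dimnames = list(query_id, NULL))
  aln <- msa(rbind(unclass(ref_msa)[tr$tip.label, , drop = FALSE], qmat), "AA")
  pruning_loglik(grafted, aln, model)
}

#' Felsenstein pruning log-likelihood of an alignment on a tree
#'
#' Straightforward post-order recursion (with discrete-Gamma averaging when
#' the model carries categories); gaps and ambiguities are missing data.
#'
#' @param tree `"phylo"` with branch lengths; tips must index alignment rows.
#' @param alignment amino-acid `msa`.
#' @param model an [aa_model()].
#' @export
pruning_loglik <- function(tree, alignment, model) {
  enc <- .encode_msa(alignment)[tree$tip.label, , drop = FALSE]
  S <- ncol(enc)
  ntip <- length(tree$tip.label)
  post <- ape::postorder(tree)
  root <- tree$edge[post[length(post)], 1]
  site_lik <- numeric(S)
  for (cc in seq_len(model$n_categories)) {
    r <- model$category_rates[cc]
    Fc <- vector("list", ntip + tree$Nnode)
    for (i in seq_len(ntip)) {
      Fm <- matrix(1, 20L, S)
      obs <- which(!is.na(enc[i, ]))
      Fm[, obs] <- 0
      Fm[cbind(enc[i, obs], obs)] <- 1
      Fc[[i]] <- Fm
    }
    for (e in post) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      P <- transition_probs(model, tree$edge.length[e] * r)
      m <- P %*% Fc[[ch]]
      Fc[[p]] <- if (is.null(Fc[[p]])) m else Fc[[p]] * m
    }
    site_lik <- site_lik + colSums(model$freqs * Fc[[root]]) / model$n_categories
  }
  sum(log(site_lik))
}

#' Write placements to a jplace (version 3) file
#'
#' @param placements list of `"placement_result"` objects.
#' @param engine the [placement_engine()] they were computed on.
#' @param path output file.
#' @export
write_jplace <- function(placements, engine, path) {
  tr <- engine$tree
  nwk <- .newick_with_edge_numbers(tr)
  recs <- lapply(placements, function(p) {
    list(p = list(c(p$best_edge - 1L, p$log_likelihood, p$like_weight_ratio,
                    p$pendant_length)),
         n = list(p$query_id))
  })
  obj <- list(tree = nwk,
              placements = recs,
              fields = c("edge_num", "likelihood", "like_weight_ratio",
                         "pendant_length"),
              version = 3L,
              metadata = list(invocation = "cytonuc placement"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

## Newick string with {edge_number} after each branch length; edge numbers
## are 0-based row indices of tree$edge.
.newick_with_edge_numbers <- function(tr) {
  ntip <- length(tr$tip.label)
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  rec <- function(node, in_edge) {
    lab <- if (node <= ntip) tr$tip.label[node] else ""
    sub <- if (node > ntip) {
      es <- kids[[as.character(node)]]
      paste0("(", paste(vapply(es, function(e) rec(tr$edge[e, 2], e), ""),
                        collapse = ","), ")")
    } else ""
    core <- paste0(sub, lab)
    if (is.na(in_edge)) paste0(core, ";")
    else sprintf("%s:%.10g{%d}", core, tr$edge.length[in_edge], in_edge - 1L)
  }
  post <- ape::postorder(tr)
  root <- tr$edge[post[length(post)], 1]
  rec(root, NA)
}
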