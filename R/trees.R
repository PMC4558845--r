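## Reference phylogenies: ape "phylo" objects plus per-tip clade annotations.
##
## Placement filtering needs every tip labelled with a domain
## ("eukaryote"/"prokaryote") and, within eukaryotes, optionally a lineage
## ("mitochondrial"/"cytosolic"/"unknown").  Annotations travel alongside the
## tree in an "annotated_tree" list so they can be validated once.

#' Read a Newick reference tree
#'
#' Branch lengths must be present on every edge unless `default_length` is
#' given.  Duplicate tip labels are an error.
#'
#' @param path Newick file.
#' @param default_length branch length substituted for missing ones; `NULL`
#'   (default) makes missing lengths an error.
#' @return an [ape::read.tree()] `"phylo"` object, validated.
#' @export
read_ref_tree <- function(path, default_length = NULL) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  validate_tree(tr, default_length)
}

#' Validate a phylo object for use as a reference tree
#' @param tr a `"phylo"` object.
#' @param default_length see [read_ref_tree()].
#' @export
validate_tree <- function(tr, default_length = NULL) {
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup)) stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "))
  if (is.null(tr$edge.length)) {
    if (is.null(default_length)) stop("tree has no branch lengths")
    tr$edge.length <- rep(default_length, nrow(tr$edge))
  }
  miss <- is.na(tr$edge.length) | !is.finite(tr$edge.length)
  if (any(miss)) {
    if (is.null(default_length)) stop("missing branch length on ", sum(miss), " edge(s)")
    tr$edge.length[miss] <- default_length
  }
  if (any(tr$edge.length < 0)) stop("negative branch length")
  tr
}

#' Write a tree to Newick
#' @param tr `"phylo"` object.
#' @param path output file.
#' @param digits significant digits for branch lengths.
#' @export
write_ref_tree <- function(tr, path, digits = 10L) {
  ape::write.tree(tr, file = path, digits = digits)
  invisible(path)
}

#' Attach clade annotations to a tree
#'
#' @param tr `"phylo"` object.
#' @param domain named character vector over all tips, values in
#'   `c("eukaryote", "prokaryote")`.
#' @param lineage optional named vector over (a subset of) tips, values in
#'   `c("mitochondrial", "cytosolic", "unknown")`.
#' @return list of class `"annotated_tree"` with elements `tree`, `domain`,
#'   `lineage`.
#' @export
annotate_tree <- function(tr, domain, lineage = NULL) {
  tr <- validate_tree(tr)
  tips <- tr$tip.label
  if (!all(tips %in% names(domain)))
    stop("domain annotation missing for tip(s): ",
         paste(setdiff(tips, names(domain)), collapse = ", "))
  domain <- domain[tips]
  if (!all(domain %in% c("eukaryote", "prokaryote")))
    stop("domain values must be 'eukaryote' or 'prokaryote'")
  if (is.null(lineage)) {
    lineage <- rep("unknown", length(tips)); names(lineage) <- tips
  } else {
    full <- rep("unknown", length(tips)); names(full) <- tips
    full[intersect(names(lineage), tips)] <- lineage[intersect(names(lineage), tips)]
    lineage <- full
    if (!all(lineage %in% c("mitochondrial", "cytosolic", "unknown")))
      stop("lineage values must be 'mitochondrial', 'cytosolic' or 'unknown'")
  }
  structure(list(tree = tr, domain = domain, lineage = lineage),
            class = "annotated_tree")
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat(sprintf("annotated reference tree: %d tips (%d eukaryote, %d prokaryote)\n",
              length(x$tree$tip.label), sum(x$domain == "eukaryote"),
              sum(x$domain == "prokaryote")))
  invisible(x)
}

## Tip indices subtended by each edge (child side).  Returns a list indexed by
## edge row of tr$edge.
.edge_tipsets <- function(tr) {
  ntip <- length(tr$tip.label)
  desc <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  # postorder guarantees children before parents
  for (e in ape::postorder(tr)) {
    p <- tr$edge[e, 1]; c <- tr$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  lapply(seq_len(nrow(tr$edge)), function(e) sort(desc[[tr$edge[e, 2]]]))
}
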