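## Seeded synthetic-data generators.  These state the world the pipeline is
## tested in: ortholog families evolved along annotated reference trees,
## contaminated search databases with fragmentary transcripts, rate tables
## obeying the compensatory linear model, and mitochondrial genomes with
## planted codon reassignments.  One global seed expands into per-component
## child seeds through a fixed polynomial hash, so stages re-run
## independently yet reproducibly.

#' Derive a child seed from a global seed and a label
#'
#' Deterministic polynomial hash, result in \[1, 2^31 - 2\].
#' @param seed integer global seed.
#' @param label character tag of the component.
#' @export
child_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483587
  as.integer((abs(seed) %% 2147483587 * 48271 + h) %% 2147483629 + 1)
}

## evaluate expr under a seed, restoring the caller's RNG state afterwards
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate an alignment along a tree
#'
#' Root states are drawn from the model's equilibrium distribution and evolved
#' edge-wise through P(t); per-site discrete-Gamma rates are used when the
#' amino-acid model carries them.  Alignments are simulated gap-free.
#'
#' @param tree `"phylo"` object with branch lengths.
#' @param model an [aa_model()] or [k80_model()].
#' @param n_sites number of columns (>= 1).
#' @param seed integer seed (mandatory).
#' @return an `msa` with one row per tip.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed) {
  stopifnot(n_sites >= 1L)
  tree <- validate_tree(tree)
  .with_seed(seed, {
    if (inherits(model, "k80_model")) {
      states <- c("A", "C", "G", "T")
      freqs <- rep(0.25, 4)
      pmat <- function(t) {
        pr <- k80_probs(model, t)
        ts <- pr$p_transition; tv <- pr$p_transversion / 2
        same <- 1 - ts - 2 * tv
        # A<->G, C<->T transitions
        m <- matrix(tv, 4, 4, dimnames = list(states, states))
        diag(m) <- same
        m["A", "G"] <- m["G", "A"] <- m["C", "T"] <- m["T", "C"] <- ts
        m
      }
      rates <- 1
    } else {
      states <- AA_LETTERS
      freqs <- model$freqs
      pmat <- function(t) transition_probs(model, t)
      rates <- model$category_rates
    }
    ns <- length(states)
    site_rate <- if (length(rates) > 1L)
      rates[sample.int(length(rates), n_sites, replace = TRUE)] else rep(1, n_sites)
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    seqs <- matrix(NA_integer_, nnode, n_sites)
    root <- ntip + 1L
    seqs[root, ] <- sample.int(ns, n_sites, replace = TRUE, prob = freqs)
    ord <- rev(ape::postorder(tree))     # parents before children
    for (e in ord) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      t <- tree$edge.length[e]
      seqs[ch, ] <- .evolve_sites(seqs[p, ], t * site_rate, pmat, ns)
    }
    m <- matrix(states[seqs[1:ntip, , drop = FALSE]], ntip, n_sites,
                dimnames = list(tree$tip.label, NULL))
    msa(m, alphabet = if (inherits(model, "k80_model")) "DNA" else "AA")
  })
}

## evolve a state vector over per-site times; groups identical times to reuse P
.evolve_sites <- function(parent, times, pmat, ns) {
  out <- integer(length(parent))
  for (t in unique(times)) {
    idx <- which(times == t)
    P <- pmax(pmat(t), 0)
    for (s in unique(parent[idx])) {
      j <- idx[parent[idx] == s]
      out[j] <- sample.int(ns, length(j), replace = TRUE, prob = P[s, ])
    }
  }
  out
}

#' Default synthetic reference family
#'
#' A coalescent-shaped family with 8 eukaryote and 6 prokaryote taxa, branch
#' lengths drawn Exponential(mean 0.15), eukaryote tips split between
#' mitochondrial and cytosolic paralog lineages, and an alignment simulated
#' under WAG.
#'
#' @param seed integer seed.
#' @param n_euk,n_prok taxa per domain.
#' @param n_sites alignment columns.
#' @param mean_branch mean branch length (subst/site).
#' @param model amino-acid model for sequence simulation.
#' @return list with `msa`, `atree` (an [annotate_tree()] object).
#' @export
simulate_family <- function(seed, n_euk = 8L, n_prok = 6L, n_sites = 200L,
                            mean_branch = 0.15, model = wag_model()) {
  .with_seed(child_seed(seed, "family_tree"), {
    euk <- ape::rcoal(n_euk, tip.label = sprintf("euk%02d", seq_len(n_euk)))
    prok <- ape::rcoal(n_prok, tip.label = sprintf("prok%02d", seq_len(n_prok)))
    # stitch the two clades as sisters so each domain is monophyletic
    nw <- sprintf("(%s:0.1,%s:0.1);",
                  sub(";$", "", ape::write.tree(euk)),
                  sub(";$", "", ape::write.tree(prok)))
    tr <- ape::read.tree(text = nw)
    tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / mean_branch)
    domain <- c(stats::setNames(rep("eukaryote", n_euk), euk$tip.label),
                stats::setNames(rep("prokaryote", n_prok), prok$tip.label))
    # first half of eukaryote tips mitochondrial paralogs, rest cytosolic
    lin <- stats::setNames(rep("cytosolic", n_euk), euk$tip.label)
    lin[seq_len(n_euk %/% 2)] <- "mitochondrial"
    atree <- annotate_tree(tr, domain, lin)
    aln <- simulate_alignment(tr, model, n_sites, child_seed(seed, "family_aln"))
    list(msa = aln, atree = atree)
  })
}

#' Simulate a contaminated search database with truth labels
#'
#' Orthologs are evolved from random eukaryote tips of the family with a short
#' pendant branch; contaminants from prokaryote tips.  Sequences are
#' optionally truncated to fragments with truncated-geometric lengths
#' (floor `min_len`), emulating fragmentary transcripts.
#'
#' @param family list with `msa` and `atree` (see [simulate_family()]).
#' @param n_orthologs,n_contaminants counts of each class.
#' @param seed integer seed.
#' @param pendant branch length from source tip to simulated sequence.
#' @param fragment apply fragmenter (FALSE gives full-length sequences).
#' @param min_len fragment length floor (residues).
#' @param mean_len mean fragment length (residues).
#' @param model amino-acid model.
#' @return list: `db` (amino-acid [seq_set()]) and `truth` (data.frame with
#'   `id`, `class`, `source_tip`).
#' @export
simulate_profiling_db <- function(family, n_orthologs = 100L,
                                  n_contaminants = 100L, seed = 1L,
                                  pendant = 0.1, fragment = TRUE,
                                  min_len = 30L, mean_len = 100L,
                                  model = wag_model()) {
  atree <- family$atree
  aln <- family$msa
  enc <- .encode_msa(aln)
  euk_tips <- names(atree$domain)[atree$domain == "eukaryote"]
  prok_tips <- names(atree$domain)[atree$domain == "prokaryote"]
  .with_seed(child_seed(seed, "profiling_db"), {
    P <- pmax(transition_probs(model, pendant), 0)
    sim_one <- function(tip) {
      src <- enc[tip, ]
      obs <- which(!is.na(src))
      res <- src
      for (s in unique(src[obs]))
        res[obs][src[obs] == s] <- sample.int(20L, sum(src[obs] == s),
                                              replace = TRUE, prob = P[s, ])
      paste(AA_LETTERS[res[obs]], collapse = "")
    }
    frag_one <- function(s) {
      L <- nchar(s)
      if (!fragment || L <= min_len) return(s)
      len <- min(min_len + stats::rgeom(1L, 1 / (mean_len - min_len + 1)), L)
      start <- sample.int(L - len + 1L, 1L)
      substring(s, start, start + len - 1L)
    }
    ids <- c(sprintf("orth%03d", seq_len(n_orthologs)),
             sprintf("cont%03d", seq_len(n_contaminants)))
    srcs <- c(sample(euk_tips, n_orthologs, replace = TRUE),
              sample(prok_tips, n_contaminants, replace = TRUE))
    seqs <- vapply(srcs, function(tip) frag_one(sim_one(tip)), "")
    names(seqs) <- ids
    truth <- data.frame(id = ids,
                        class = rep(c("eukaryote", "prokaryote"),
                                    c(n_orthologs, n_contaminants)),
                        source_tip = srcs, row.names = NULL)
    list(db = seq_set(seqs, "AA"), truth = truth)
  })
}

#' Simulate a rate table under the compensatory linear model
#'
#' Generates paired mitochondrial/cytosolic rows per amino-acid specificity
#' with \eqn{Y = \beta_0 + \beta_1 \delta_{mt} + \beta_2 X + \beta_3 X
#' \delta_{mt} + \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2)}.  The Gaussian
#' noise is kept as-is (no truncation at zero) so that ordinary-least-squares
#' recovery of the generating coefficients stays unbiased.
#'
#' @param betas numeric length 4: (beta0, beta1, beta2, beta3).
#' @param n_specificities number of specificities (2 rows each).
#' @param sigma residual standard deviation (>= 0).
#' @param seed integer seed.
#' @param x_range interval for the uniform mt-tRNA rate draw.
#' @return a `"rate_table"` data.frame; generating values in
#'   `attr(, "truth")`.
#' @export
simulate_rate_table <- function(betas, n_specificities = 10L, sigma = 0.05,
                                seed = 1L, x_range = c(0.1, 0.6)) {
  stopifnot(length(betas) == 4L, sigma >= 0, n_specificities >= 2L)
  .with_seed(child_seed(seed, "rate_table"), {
    spec <- if (n_specificities <= 20L) AA_LETTERS[seq_len(n_specificities)]
            else sprintf("s%03d", seq_len(n_specificities))
    X <- stats::runif(n_specificities, x_range[1], x_range[2])
    tab <- data.frame(
      specificity = rep(spec, each = 2L),
      delta_mt = rep(c(1L, 0L), n_specificities),
      X = rep(X, each = 2L))
    mu <- betas[1] + betas[2] * tab$delta_mt + betas[3] * tab$X +
      betas[4] * tab$X * tab$delta_mt
    tab$Y <- mu + stats::rnorm(nrow(tab), 0, sigma)
    out <- rate_table(tab, allow_negative = TRUE)
    attr(out, "truth") <- list(betas = betas, sigma = sigma)
    out
  })
}

#' Simulate mitochondrial genes with a planted codon reassignment
#'
#' Builds per-gene reference amino-acid alignments whose per-column
#' conservation controls entropy, and a focal coding sequence that carries
#' `target_codon` at a subset of positions: in a `planted_fraction` of those,
#' the references' plurality residue is `planted_residue`; in the rest it is a
#' random other residue.  Remaining positions encode the column consensus
#' under `code`.
#'
#' @param n_genes number of genes.
#' @param gene_length_codons codons per gene.
#' @param target_codon scanned codon (DNA, e.g. `"TGA"`).
#' @param planted_residue one-letter amino acid planted at target positions.
#' @param planted_fraction fraction of target positions agreeing with the
#'   planted residue.
#' @param n_refs reference taxa per alignment (>= 2).
#' @param conservation per-column probability that a reference copies the
#'   column consensus (controls entropy).
#' @param target_density fraction of positions carrying the target codon.
#' @param gap_prob per-reference-per-column gap probability.
#' @param code a [genetic_code()]; default table 4 (mold/protozoan mt), the
#'   default for non-bilaterian animal mtDNA.
#' @param seed integer seed.
#' @return list: `cds` (named nucleotide strings), `alignments` (named list of
#'   `msa`, focal row id `"focal"`), `truth` (per-gene data.frame of column
#'   labels).
#' @export
simulate_reassigned_genome <- function(n_genes = 3L, gene_length_codons = 120L,
                                       target_codon = "TGA",
                                       planted_residue = "S",
                                       planted_fraction = 0.8,
                                       n_refs = 10L, conservation = 0.95,
                                       target_density = 0.15,
                                       gap_prob = 0.05,
                                       code = genetic_code(4L), seed = 1L) {
  stopifnot(planted_fraction >= 0, planted_fraction <= 1, n_refs >= 2L)
  target_codon <- toupper(target_codon)
  # codons encoding each residue under the code, excluding the target codon
  by_aa <- split(names(code), unname(code))
  .with_seed(child_seed(seed, "reassigned_genome"), {
    cds <- character(0); alns <- list(); truth <- list()
    for (g in seq_len(n_genes)) {
      gid <- sprintf("gene%02d", g)
      L <- gene_length_codons
      n_target <- max(1L, round(target_density * L))
      target_pos <- sort(sample.int(L, n_target))
      n_agree <- round(planted_fraction * n_target)
      agree_pos <- if (n_agree > 0L) target_pos[seq_len(n_agree)] else integer(0)
      consensus <- sample(setdiff(AA_LETTERS, planted_residue), L, replace = TRUE)
      consensus[agree_pos] <- planted_residue
      # references copy the consensus with per-column conservation
      refs <- matrix("", n_refs, L)
      for (j in seq_len(L)) {
        copy <- stats::runif(n_refs) < conservation
        refs[, j] <- ifelse(copy, consensus[j],
                            sample(AA_LETTERS, n_refs, replace = TRUE))
        gapped <- stats::runif(n_refs) < gap_prob
        refs[gapped, j] <- "-"
      }
      # focal codons: target codon at target positions, else a synonymous
      # codon for the consensus residue
      codons <- vapply(seq_len(L), function(j) {
        if (j %in% target_pos) return(target_codon)
        opts <- setdiff(by_aa[[consensus[j]]], target_codon)
        if (!length(opts)) opts <- setdiff(by_aa[["L"]], target_codon)
        sample(opts, 1L)
      }, "")
      cds[gid] <- paste(codons, collapse = "")
      focal_aa <- strsplit(translate_cds(cds[gid], code, mask_codon = target_codon),
                           "", fixed = TRUE)[[1]]
      m <- rbind(focal = focal_aa, refs)
      rownames(m) <- c("focal", sprintf("ref%02d", seq_len(n_refs)))
      alns[[gid]] <- msa(m, "AA")
      truth[[gid]] <- data.frame(
        gene_id = gid, codon_index = seq_len(L) - 1L,
        is_target = seq_len(L) %in% target_pos,
        consensus = consensus, row.names = NULL)
    }
    list(cds = cds, alignments = alns, truth = do.call(rbind, truth))
  })
}
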