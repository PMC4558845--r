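fam <- fixture_family()
gmodel <- wag_model(1.0, 4L)
engine <- placement_engine(fam$atree, fam$msa, gmodel)

test_that("a query identical to a tip places on that tip's pendant edge", {
  for (tip in c("euk01", "euk05", "prok03")) {
    row <- msa_strings(fam$msa)[[tip]]
    pl <- place_query(engine, row, tip)
    tip_edge <- which(engine$edge[, 2] == match(tip, engine$tree$tip.label))
    expect_equal(pl$best_edge, tip_edge)
    expect_lt(pl$pendant_length, 1e-4)
  }
})

test_that("attachment likelihood matches the naive pruning oracle", {
  set.seed(8)
  for (i in 1:5) {
    tip <- sample(fam$atree$tree$tip.label, 1)
    row <- msa_strings(fam$msa)[[tip]]
    # fragment the query to exercise missing data
    chars <- strsplit(row, "")[[1]]
    chars[1:60] <- "-"
    qrow <- paste(chars, collapse = "")
    pl <- place_query(engine, qrow, "frag")
    nl <- naive_attach_loglik(fam$atree, fam$msa, gmodel, qrow,
                              pl$best_edge, pl$pendant_length)
    expect_equal(pl$log_likelihood, nl, tolerance = 1e-6)
  }
})

test_that("likelihood weight ratios are normalized and the best edge attains the max", {
  row <- msa_strings(fam$msa)[["euk07"]]
  pl <- place_query(engine, row, "q")
  expect_equal(pl$log_likelihood, max(pl$all_log_likelihoods))
  lwr <- exp(pl$all_log_likelihoods - max(pl$all_log_likelihoods))
  expect_equal(pl$like_weight_ratio, max(lwr / sum(lwr)))
  expect_lte(pl$like_weight_ratio, 1)
  expect_gt(pl$like_weight_ratio, 0)
  expect_error(place_query(engine, strrep("-", engine$n_sites)), "zero ungapped")
})

test_that("clade classification follows the subtended-tips/stem-edge rule", {
  tr <- fam$atree$tree
  ntip <- length(tr$tip.label)
  tipsets <- cytonuc:::.edge_tipsets(tr)
  doms <- fam$atree$domain[tr$tip.label]
  for (e in seq_len(nrow(tr$edge))) {
    cls <- classify_placement(e, fam$atree)
    below <- doms[tipsets[[e]]]
    above <- doms[setdiff(seq_len(ntip), tipsets[[e]])]
    if (all(below == "eukaryote") || all(above == "eukaryote"))
      expect_equal(cls$domain, "eukaryote")
    else
      expect_equal(cls$domain, "prokaryote")
  }
  # the stem edge separating the domains is retained but low-confidence
  euk_tips <- which(doms == "eukaryote")
  stem <- which(vapply(tipsets, function(s) setequal(s, euk_tips), TRUE))
  expect_length(stem, 1L)
  cls_stem <- classify_placement(stem, fam$atree)
  expect_equal(cls_stem$domain, "eukaryote")
  expect_true(cls_stem$low_confidence)
  # a pendant eukaryote tip edge is high-confidence eukaryote
  pend <- which(tr$edge[, 2] == euk_tips[1])
  cls_pend <- classify_placement(pend, fam$atree)
  expect_equal(cls_pend$domain, "eukaryote")
  expect_false(cls_pend$low_confidence)
  # deep inside the prokaryote clade
  prok_tip <- which(doms == "prokaryote")[1]
  pe <- which(tr$edge[, 2] == prok_tip)
  expect_equal(classify_placement(pe, fam$atree)$domain, "prokaryote")
})

test_that("queries simulated inside the eukaryote clade classify as eukaryote", {
  db <- simulate_profiling_db(fam, n_orthologs = 30, n_contaminants = 0,
                              seed = 21, fragment = FALSE)
  prof <- calibrate_evalues(build_profile(fam$msa), seed = 4)
  ok <- 0L
  for (id in names(db$db)) {
    hits <- search_database(prof, db$db[id], e_cutoff = Inf)
    hit <- hits[1, , drop = FALSE]
    attr(hit, "profile_id") <- attr(hits, "profile_id")
    row <- align_hit_to_reference(hit, prof, db$db)
    pl <- place_query(engine, row, id)
    if (pl$classification == "eukaryote") ok <- ok + 1L
  }
  expect_gte(ok / 30, 0.95)
})

test_that("jplace output carries an edge-numbered tree and placement records", {
  row <- msa_strings(fam$msa)[["euk04"]]
  pl <- place_query(engine, row, "euk04_query")
  f <- tempfile(fileext = ".jplace")
  write_jplace(list(pl), engine, f)
  jp <- jsonlite::read_json(f)
  expect_equal(jp$version, 3L)
  expect_identical(unlist(jp$fields),
                   c("edge_num", "likelihood", "like_weight_ratio",
                     "pendant_length"))
  expect_match(jp$tree, "\\{[0-9]+\\}")
  rec <- jp$placements[[1]]
  expect_identical(rec$n[[1]], "euk04_query")
  expect_equal(rec$p[[1]][[1]], pl$best_edge - 1L)
  expect_equal(rec$p[[1]][[2]], pl$log_likelihood, tolerance = 1e-6)
  # every edge number appears exactly once in the tree string
  nums <- as.integer(gsub("[{}]", "",
                          regmatches(jp$tree, gregexpr("\\{[0-9]+\\}", jp$tree))[[1]]))
  expect_setequal(nums, seq_len(nrow(engine$edge)) - 1L)
})
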