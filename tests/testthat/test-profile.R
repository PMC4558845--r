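fam <- fixture_family()

test_that("profile construction obeys the match-column and normalization rules", {
  ident <- msa(setNames(rep("ACDEF", 5), paste0("s", 1:5)), "AA")
  p <- build_profile(ident, gap_threshold = 0.5)
  expect_equal(p$n_match, 5L)
  modal <- AA20[apply(p$match_emissions, 1, which.max)]
  expect_identical(paste(modal, collapse = ""), "ACDEF")

  gappy <- msa(c(s1 = "A-DEF", s2 = "A-DEF", s3 = "ACDEF", s4 = "A-DEF",
                 s5 = "ACDEF"), "AA")
  pg <- build_profile(gappy, gap_threshold = 0.5)
  expect_equal(pg$n_match, 4L)          # column 2 has 3/5 gaps, excluded
  expect_identical(pg$match_columns, c(1L, 3L, 4L, 5L))

  big <- build_profile(fam$msa)
  expect_lt(max(abs(rowSums(big$match_emissions) - 1)), 1e-9)
  expect_true(all(big$match_emissions > 0))
  expect_lt(max(abs(rowSums(big$transitions[, c("MM","MI","MD")]) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(big$transitions[, c("IM","II")]) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(big$transitions[, c("DM","DD")]) - 1)), 1e-9)
  expect_error(build_profile(msa(c(a = "A---", b = "-A--", c = "--AA"), "AA"),
                             gap_threshold = 0.3), "no match columns")
})

test_that("forward score dominates Viterbi and rewards profile-like targets", {
  prof <- build_profile(fam$msa)
  cons <- paste(AA20[apply(prof$match_emissions, 1, which.max)], collapse = "")
  set.seed(31)
  wins <- 0L
  for (i in 1:25) {
    sc <- score_sequence(prof, cons)
    shuf <- paste(sample(strsplit(cons, "")[[1]]), collapse = "")
    ssh <- score_sequence(prof, shuf)
    expect_gte(sc$bit_score, sc$viterbi_bits - 1e-9)
    expect_gte(ssh$bit_score, ssh$viterbi_bits - 1e-9)
    if (sc$bit_score > ssh$bit_score) wins <- wins + 1L
  }
  expect_equal(wins, 25L)
  # random targets: forward >= viterbi holds too
  for (i in 1:10) {
    r <- paste(sample(AA20, 80, replace = TRUE), collapse = "")
    s <- score_sequence(prof, r)
    expect_gte(s$bit_score, s$viterbi_bits - 1e-9)
  }
})

test_that("Viterbi match path is strictly increasing in both coordinates", {
  prof <- build_profile(fam$msa)
  row <- gsub("-", "", msa_strings(fam$msa)[["euk01"]])
  frag <- substring(row, 40, 150)
  mp <- score_sequence(prof, frag)$match_path
  expect_gt(nrow(mp), 10)
  expect_true(all(diff(mp$target_pos) > 0))
  expect_true(all(diff(mp$match_col) > 0))
})

test_that("Gumbel calibration is seeded and E-values behave", {
  prof <- build_profile(fam$msa)
  c1 <- calibrate_evalues(prof, n_decoys = 150, seed = 7)
  c2 <- calibrate_evalues(prof, n_decoys = 150, seed = 7)
  expect_identical(c1$calibration$mu, c2$calibration$mu)
  expect_identical(c1$calibration$beta, c2$calibration$beta)
  # median decoy score should have E-value near n_decoys/2
  scores <- replicate(150, {
    s <- paste(sample(AA20, prof$n_match, replace = TRUE,
                      prob = prof$background), collapse = "")
    score_sequence(c1, s)$bit_score
  })
  ev_med <- profile_evalue(c1, median(scores), n_db = 150)
  expect_gt(ev_med, 150 / 2 * 0.8)
  expect_lt(ev_med, 150 / 2 * 1.2)
  # monotone decreasing in score
  ss <- sort(scores)
  expect_true(all(diff(profile_evalue(c1, ss, 150)) <= 0))
})

test_that("database search gates on E-value with deterministic tie-breaking", {
  prof <- calibrate_evalues(build_profile(fam$msa), seed = 3)
  cons <- paste(AA20[apply(prof$match_emissions, 1, which.max)], collapse = "")
  set.seed(12)
  db <- seq_set(c(real = cons,
                  d1 = paste(sample(strsplit(cons, "")[[1]]), collapse = ""),
                  d2 = paste(sample(strsplit(cons, "")[[1]]), collapse = ""),
                  d3 = paste(sample(strsplit(cons, "")[[1]]), collapse = "")), "AA")
  hits <- search_database(prof, db, e_cutoff = 1e-5)
  expect_identical(hits$target_id, "real")
  all_hits <- search_database(prof, db, e_cutoff = Inf)
  expect_equal(nrow(all_hits), 4L)
  expect_true(!is.unsorted(all_hits$e_value))
  empty <- search_database(prof, seq_set(character(0), "AA"), e_cutoff = 1e-5)
  expect_equal(nrow(empty), 0L)
})

test_that("hits align back into reference coordinates", {
  prof <- calibrate_evalues(build_profile(fam$msa), seed = 3)
  ref_row <- msa_strings(fam$msa)[["euk02"]]
  full <- gsub("-", "", ref_row)
  db <- seq_set(c(q = full), "AA")
  hits <- search_database(prof, db, e_cutoff = Inf)
  hit <- hits[1, , drop = FALSE]; attr(hit, "profile_id") <- attr(hits, "profile_id")
  placed <- align_hit_to_reference(hit, prof, db)
  expect_equal(nchar(placed), n_columns(fam$msa))
  # identical input: placed row matches the reference row on match columns
  pc <- strsplit(placed, "")[[1]]; rc <- strsplit(ref_row, "")[[1]]
  agree <- mean(pc[prof$match_columns] == rc[prof$match_columns])
  expect_gt(agree, 0.95)
  # half-length fragment leaves the uncovered interval gapped
  half <- substring(full, 1, nchar(full) %/% 2)
  dbh <- seq_set(c(q = half), "AA")
  hh <- search_database(prof, dbh, e_cutoff = Inf)
  hith <- hh[1, , drop = FALSE]; attr(hith, "profile_id") <- attr(hh, "profile_id")
  ph <- align_hit_to_reference(hith, prof, dbh)
  tail_cols <- prof$match_columns[prof$match_columns > 0.75 * n_columns(fam$msa)]
  expect_true(all(strsplit(ph, "")[[1]][tail_cols] == "-"))
  # provenance mismatch errors
  other <- build_profile(fam$msa, id = "other_profile")
  expect_error(align_hit_to_reference(hith, other, dbh), "provenance")
})

test_that("profile serialization round-trips", {
  prof <- build_profile(fam$msa, id = "famA")
  f <- tempfile()
  write_profile(prof, f)
  back <- read_profile(f)
  expect_equal(back$match_emissions, prof$match_emissions, tolerance = 1e-7)
  expect_equal(back$transitions, prof$transitions, tolerance = 1e-7)
  expect_identical(back$match_columns, prof$match_columns)
  expect_identical(back$source_alignment_id, "famA")
})
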