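test_that("Shannon entropy matches closed forms", {
  expect_equal(shannon_entropy(c(S = 7)), 0)
  expect_equal(shannon_entropy(c(A = 1, C = 1, D = 1, E = 1)), log(4))
  expect_equal(shannon_entropy(c(S = 3, L = 1)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(S = 3, L = 1), base = 2),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)), tolerance = 1e-12)
  expect_error(shannon_entropy(c(S = 0)), "all-zero")
})

test_that("codon-to-column mapping handles gaps and validates inputs", {
  code <- genetic_code(4)
  # ungapped focal row: codon k maps to column k
  cds <- "ATGTCATGA"                      # M S X(masked TGA)
  aln <- msa(c(focal = "MSX", r1 = "MSS", r2 = "MSS", r3 = "MSL"), "AA")
  cc <- map_codons_to_columns(cds, aln, code, target_codon = "TGA")
  expect_equal(cc$column_index, 0:2)
  expect_equal(cc$focal_codon, c("ATG", "TCA", "TGA"))
  expect_equal(cc$plurality[3], "S")
  expect_equal(cc$gap_fraction, rep(0, 3))
  # leading gap columns shift the map
  aln2 <- msa(c(focal = "--MSX", r1 = "AAMSS", r2 = "CCMSS", r3 = "GGMSL"), "AA")
  cc2 <- map_codons_to_columns(cds, aln2, code, target_codon = "TGA")
  expect_equal(cc2$column_index, 2:4)
  expect_error(map_codons_to_columns("ATGT", aln, code), "divisible by 3")
  expect_error(map_codons_to_columns(cds, aln, code, focal_id = "nope"),
               "absent")
  expect_error(map_codons_to_columns("ATGTCATGATGA", aln, code,
                                     target_codon = "TGA"), "translates")
})

test_that("the reassignment scan filters, counts and calls correctly", {
  # 10 retained TGA columns, 4 with Ser plurality
  rows <- lapply(1:10, function(i) {
    plur <- if (i <= 4) "S" else "L"
    data.frame(gene_id = "g", codon_index = i - 1L, column_index = i - 1L,
               focal_codon = "TGA", n_refs = 10L, gap_fraction = 0,
               entropy = 0.2, plurality = plur)
  })
  cols <- do.call(rbind, rows)
  repx <- scan_codon_reassignment(cols, "TGA")
  expect_equal(repx$n_retained, 10L)
  expect_equal(unname(repx$modal_fractions["S"]), 0.40)
  expect_equal(unname(repx$modal_fractions["L"]), 0.60)
  expect_identical(repx$call, "L")
  # all columns too gappy: nothing retained
  gappy <- cols; gappy$gap_fraction <- 0.5
  expect_equal(scan_codon_reassignment(gappy, "TGA")$n_retained, 0L)
  # ties split fractionally
  tied <- cols[1:2, ]; tied$plurality <- c("S/L", "S")
  rt <- scan_codon_reassignment(tied, "TGA")
  expect_equal(unname(rt$modal_fractions["S"]), 0.75)
  expect_equal(unname(rt$modal_fractions["L"]), 0.25)
  expect_lte(sum(rt$modal_fractions), 1 + 1e-12)
})

test_that("filters are monotone and reports permutation-invariant", {
  g <- simulate_reassigned_genome(seed = 53, n_genes = 2)
  cc <- do.call(rbind, lapply(names(g$cds), function(gid)
    map_codons_to_columns(g$cds[[gid]], g$alignments[[gid]], genetic_code(4),
                          target_codon = "TGA", gene_id = gid)))
  n_ret <- function(emax, gmax)
    scan_codon_reassignment(cc, "TGA", emax, gmax)$n_retained
  base <- n_ret(1.0, 0.2)
  expect_gte(n_ret(1.5, 0.2), base)
  expect_gte(n_ret(1.0, 0.4), base)
  expect_gte(n_ret(2.0, 0.9), n_ret(1.5, 0.2))
  # permuting reference rows changes nothing
  gid <- names(g$cds)[1]
  aln <- g$alignments[[gid]]
  set.seed(3)
  perm <- c("focal", sample(setdiff(rownames(aln), "focal")))
  aln_p <- msa(unclass(aln)[perm, ], "AA")
  c1 <- map_codons_to_columns(g$cds[[gid]], aln, genetic_code(4),
                              target_codon = "TGA", gene_id = gid)
  c2 <- map_codons_to_columns(g$cds[[gid]], aln_p, genetic_code(4),
                              target_codon = "TGA", gene_id = gid)
  expect_equal(c1$entropy, c2$entropy)
  expect_identical(c1$plurality, c2$plurality)
})

test_that("a single reference row gives zero entropy and its own plurality", {
  aln <- msa(c(focal = "MX", ref1 = "MS"), "AA")
  cc <- map_codons_to_columns("ATGTGA", aln, genetic_code(4),
                              target_codon = "TGA")
  expect_equal(cc$entropy, c(0, 0))
  expect_identical(cc$plurality, c("M", "S"))
})

test_that("reports serialize to TSV and JSON", {
  g <- simulate_reassigned_genome(seed = 53, n_genes = 1)
  gid <- names(g$cds)[1]
  cc <- map_codons_to_columns(g$cds[[gid]], g$alignments[[gid]],
                              genetic_code(4), target_codon = "TGA",
                              gene_id = gid)
  repx <- scan_codon_reassignment(cc, "TGA")
  ft <- tempfile(); fj <- tempfile(fileext = ".json")
  write_reassignment_report(repx, ft, fj)
  tab <- read.table(ft, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 20L)
  js <- jsonlite::read_json(fj)
  expect_equal(js$n_retained, repx$n_retained)
})
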