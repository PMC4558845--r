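wag <- wag_model()

test_that("K80 distance matches the closed form and flags saturation", {
  a <- strrep("A", 100)
  expect_equal(k80_distance(a, a)$distance, 0)
  # P = 0.1, Q = 0.05 over 100 sites
  b <- c(rep("G", 10), rep("C", 5), rep("A", 85))
  d <- k80_distance(strsplit(a, "")[[1]], b)
  expect_equal(d$distance, -0.5 * log(0.75) - 0.25 * log(0.9), tolerance = 1e-12)
  expect_equal(d$distance, 0.1701812, tolerance = 1e-6)
  # P = 0.5, Q = 0.25: log argument <= 0
  sat <- k80_distance(strrep("A", 4), "GGCA")
  expect_true(sat$saturated)
  expect_identical(sat$distance, Inf)
})

test_that("K80 closed form equals the likelihood grid maximizer", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 500L
    t_true <- runif(1, 0.05, 0.8)
    pr <- k80_probs(k80_model(runif(1, 1, 4)), t_true)
    n_ts <- rbinom(1, n, pr$p_transition)
    n_tv <- rbinom(1, n - n_ts, pr$p_transversion / (1 - pr$p_transition))
    # build a concrete pair with those counts
    a <- rep("A", n)
    b <- c(rep("G", n_ts), rep("C", n_tv), rep("A", n - n_ts - n_tv))
    d <- k80_distance(a, b)
    if (d$saturated) next
    t_grid <- oracle_k80_grid(n, n_ts, n_tv)
    expect_lt(abs(d$distance - t_grid), 1e-4)
  }
})

test_that("distances are symmetric and strictly increase with divergence", {
  set.seed(5)
  aseq <- paste(sample(AA20, 300, replace = TRUE), collapse = "")
  bseq <- paste(sample(AA20, 300, replace = TRUE), collapse = "")
  expect_equal(wag_ml_distance(aseq, bseq, wag)$distance,
               wag_ml_distance(bseq, aseq, wag)$distance)
  nt_a <- paste(sample(c("A","C","G","T"), 300, replace = TRUE), collapse = "")
  nt_b <- paste(sample(c("A","C","G","T"), 300, replace = TRUE), collapse = "")
  expect_equal(k80_distance(nt_a, nt_b)$distance,
               k80_distance(nt_b, nt_a)$distance)
  # monotone gradient: progressively mutate single sites
  base <- strsplit(aseq, "")[[1]]
  prev <- 0
  mut <- base
  for (k in c(10, 30, 60, 100)) {
    idx <- seq_len(k)
    mut2 <- base
    mut2[idx] <- AA20[(match(base[idx], AA20) %% 20) + 1L]
    d <- wag_ml_distance(base, mut2, wag)$distance
    expect_gt(d, prev)
    prev <- d
  }
})

test_that("gapped and ambiguous columns are excluded pairwise", {
  d <- k80_distance("AC-GTN", "ACCG-T")
  expect_equal(d$n_sites, 3L)   # columns 1, 2, 4 comparable
  expect_equal(d$distance, 0)
  expect_error(k80_distance("----", "AAAA"), "no comparable")
})

test_that("WAG ML distance agrees with a dense likelihood grid", {
  set.seed(23)
  tr <- ape::read.tree(text = "(a:0.15,b:0.15);")
  for (rep in 1:5) {
    aln <- simulate_alignment(tr, wag, 400, seed = 100 + rep)
    s <- msa_strings(aln)
    est <- wag_ml_distance(s[["a"]], s[["b"]], wag)$distance
    grid <- oracle_wag_grid(s[["a"]], s[["b"]], wag,
                            c(max(est - 0.05, 1e-4), est + 0.05))
    expect_lt(abs(est - grid), 1e-4)
  }
})

test_that("WAG estimator recovers a simulated divergence", {
  tr <- ape::read.tree(text = "(a:0.2,b:0.2);")
  aln <- simulate_alignment(tr, wag, 2000, seed = 11)
  s <- msa_strings(aln)
  d <- wag_ml_distance(s[["a"]], s[["b"]], wag)
  # 3 SE of truth with SE ~ sqrt(t/n) heuristic for a 2000-site pair
  expect_lt(abs(d$distance - 0.4), 3 * sqrt(0.4 / 2000) * 2)
})

test_that("mean outgroup distance averages pairs and excludes saturated ones", {
  rows <- c(out = "AAAAAAAAAA", in1 = "AAAAAGAAAA", in2 = "AAGGAAAAAA")
  aln <- msa(rows, "DNA")
  d1 <- k80_distance(rows[["out"]], rows[["in1"]])$distance
  d2 <- k80_distance(rows[["out"]], rows[["in2"]])$distance
  m1 <- mean_outgroup_distance(aln, "out", c("in1"), "K80")
  expect_equal(as.numeric(m1), d1)
  m2 <- mean_outgroup_distance(aln, "out", c("in1", "in2"), "K80")
  expect_equal(as.numeric(m2), (d1 + d2) / 2)
  # star tree recovery: outgroup at 0.3 from each of 5 tips
  star <- ape::read.tree(text = "(out:0.3,t1:0,t2:0,t3:0,t4:0,t5:0);")
  sa <- simulate_alignment(star, wag, 1500, seed = 77)
  mm <- mean_outgroup_distance(sa, "out", paste0("t", 1:5), "WAG", model = wag)
  expect_lt(abs(as.numeric(mm) - 0.3), 3 * sqrt(0.3 / 1500) * 2)
  # saturated ingroup member is dropped with a warning
  aln2 <- msa(c(out = strrep("A", 8), in1 = paste0("G", strrep("A", 7)),
                in2 = "GGCCGGCC"), "DNA")
  expect_warning(m3 <- mean_outgroup_distance(aln2, "out", c("in1", "in2"), "K80"),
                 "saturated")
  expect_equal(attr(m3, "n_saturated"), 1L)
})

test_that("distance matrices write as 6-decimal TSV", {
  d <- matrix(c(0, 0.123456789, 0.123456789, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  f <- tempfile()
  write_distance_matrix(d, f)
  got <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(got$a[2], 0.123457)
})
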