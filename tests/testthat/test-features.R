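test_that("compute_oaac matches the worked examples", {
  v <- compute_oaac("AAAA")
  expect_equal(unname(v["A"]), 1)
  expect_equal(sum(v != 0), 1L)
  v <- compute_oaac("ACDC")
  expect_equal(unname(v[c("A", "C", "D")]),
               c(sqrt(0.25), sqrt(0.5), sqrt(0.25)))
  expect_equal(names(v), aa_alphabet())
})

test_that("OAAC squared values sum to 1 for random sequences", {
  set.seed(101)
  for (L in c(1, 2, 7, 50, 200, 731)) {
    v <- compute_oaac(random_sequence(L))
    expect_equal(sum(v^2), 1, tolerance = 1e-12)
  }
})

test_that("compute_dipeptide matches the worked examples", {
  v <- compute_dipeptide("AAA", 0)
  expect_equal(unname(v["AA_s0"]), 1)
  expect_equal(sum(v), 1)
  v <- compute_dipeptide("AGAG", 1)
  expect_equal(unname(v[c("AA_s1", "GG_s1")]), c(1 / 3, 1 / 3))
  expect_equal(sum(v != 0), 2L)
  v <- compute_dipeptide("AGAG", 0)
  expect_equal(unname(v[c("AG_s0", "GA_s0")]), c(2 / 3, 1 / 3))
})

test_that("dipeptide frequencies agree with brute-force enumeration", {
  # scaled-down version of the 1000-sequence sweep run in test-acceptance.R
  set.seed(202)
  for (rep in 1:50) {
    s <- sample(0:2, 1)
    L <- sample((s + 2):200, 1)
    q <- random_sequence(L)
    expect_equal(unname(compute_dipeptide(q, s)), oracle_dipeptide(q, s))
  }
})

test_that("dipeptide cell sums equal (N-1-s)/(N-1) and short sequences error", {
  set.seed(303)
  for (s in 0:2) {
    L <- sample((s + 2):100, 5)
    for (Li in L) {
      q <- random_sequence(Li)
      expect_equal(sum(compute_dipeptide(q, s)), (Li - 1 - s) / (Li - 1))
    }
    if (s > 0) expect_error(compute_dipeptide(random_sequence(s + 1), s),
                            "pairs")
  }
})

test_that("compute_dipeptide_all concatenates the three interval blocks", {
  q <- random_sequence(50)
  v <- compute_dipeptide_all(q)
  expect_length(v, 1200L)
  expect_equal(v[1:400], compute_dipeptide(q, 0))
  expect_equal(v[401:800], compute_dipeptide(q, 1))
  expect_equal(v[801:1200], compute_dipeptide(q, 2))
  v4 <- compute_dipeptide_all("AAAA")
  expect_equal(sum(v4 != 0), 3L)
  expect_true(all(grepl("^AA_s", names(v4)[v4 != 0])))
})

test_that("saa_partition reproduces the three case layouts", {
  lens <- function(p) unname(vapply(p$regions, diff, numeric(1)))
  pA <- saa_partition(130)
  expect_equal(pA$case, "A")
  expect_equal(lens(pA), c(25, 25, 25, 25, 20, 10))
  pB <- saa_partition(100)
  expect_equal(pB$case, "B")
  expect_equal(lens(pB), c(20, 20, 20, 20, 10, 10))
  pC <- saa_partition(50)
  expect_equal(pC$case, "C")
  expect_equal(lens(pC), c(20, 20, 20, 20, 20, 10))
  expect_equal(pC$regions$N1, pC$regions$N4)  # aliased undivided N
  expect_error(saa_partition(11), "12")
})

test_that("saa_partition tiles [0, L) with closed-form lengths for all L", {
  for (L in 12:2000) {
    p <- saa_partition(L)
    r <- p$regions
    # N1..N4 + M + C tile the sequence (N aliased in case C)
    if (p$case == "C") {
      expect_equal(r$N1[1], 0L)
      expect_equal(r$M[1], r$N1[2])
      expect_equal(unname(r$N1[2] - r$N1[1]), (L - 10L) %/% 2L)
    } else {
      d_n <- if (p$case == "A") 25L else 20L
      expect_equal(unname(c(r$N1, r$N2, r$N3, r$N4)),
                   c(0L, d_n, d_n, 2L * d_n, 2L * d_n, 3L * d_n, 3L * d_n,
                     4L * d_n))
      expect_equal(r$M[1], 4L * d_n)
    }
    expect_equal(r$M[2], r$C[1])
    expect_equal(unname(r$C), c(L - 10L, L))
    expect_equal(p$case, if (L >= 130) "A" else if (L >= 90) "B" else "C")
  }
})

test_that("encode_aaindex averages table values over SAA regions", {
  tab <- generate_aaindex_table(2, seed = 4)
  # constant sequence: every region mean equals the residue's value
  v <- encode_aaindex(strrep("K", 150), tab)
  expect_length(v, 12L)
  expect_equal(unname(v[1:6]), rep(unname(tab[1, "K"]), 6))
  # direct-slice oracle for N1 in case A
  q <- random_sequence(130)
  v <- encode_aaindex(q, tab)
  res <- strsplit(q, "")[[1]]
  expect_equal(unname(v["SYN0001_N1"]),
               mean(tab[1, res[1:25]]))
  expect_equal(unname(v["SYN0002_M"]), mean(tab[2, res[101:120]]))
  full <- encode_aaindex(q, load_aaindex_table())
  expect_length(full, 168L)
})

test_that("encode_pssm averages profile columns over SAA regions", {
  L <- 130
  q <- random_sequence(L)
  zeros <- structure(list(id = "z", scores = matrix(0, L, 20,
                          dimnames = list(NULL, aa_alphabet()))),
                     class = "pssm_profile")
  expect_equal(unname(encode_pssm(q, zeros)), rep(0, 120))
  ones <- zeros; ones$scores[] <- 1
  expect_equal(unname(encode_pssm(q, ones)), rep(1, 120))
  set.seed(6)
  rnd <- zeros; rnd$scores[] <- rnorm(L * 20)
  v <- encode_pssm(q, rnd)
  expect_equal(unname(v["PSSM_A_N1"]), mean(rnd$scores[1:25, "A"]))
  expect_equal(unname(v["PSSM_Y_C"]), mean(rnd$scores[121:130, "Y"]))
  # row-count mismatch names the offender
  short <- zeros; short$scores <- short$scores[1:50, ]
  expect_error(encode_pssm(q, short), "z")
})

test_that("region aggregation is permutation-invariant within a region", {
  set.seed(7)
  tab <- generate_aaindex_table(3, seed = 7)
  q <- random_sequence(200)
  res <- strsplit(q, "")[[1]]
  # shuffle inside N2 (positions 26..50 in case A)
  res2 <- res
  res2[26:50] <- sample(res[26:50])
  q2 <- paste(res2, collapse = "")
  expect_false(identical(q, q2))
  # shuffling inside one region leaves every region mean unchanged
  expect_equal(encode_aaindex(q, tab), encode_aaindex(q2, tab))
  pss <- generate_pssm_profiles(protein_set("a", q), seed = 7)[["a"]]
  pss2 <- pss
  pss2$scores[26:50, ] <- pss$scores[sample(26:50), ]
  expect_equal(encode_pssm(q, pss), encode_pssm(q, pss2))
})

test_that("featurize produces constant per-family dimensions", {
  ds <- tiny_dataset(6, 3, seed = 8)
  pss <- generate_pssm_profiles(ds, seed = 8)
  fs <- featurize(ds, aaindex = load_aaindex_table(), pssms = pss)
  expect_named(fs, c("OAAC", "DIPEP0", "DIPEP1", "DIPEP2", "AAINDEX", "PSSM"))
  expect_equal(unname(vapply(fs, ncol, integer(1))),
               c(20L, 400L, 400L, 400L, 168L, 120L))
  expect_true(all(vapply(fs, nrow, integer(1)) == nrow(ds)))
  expect_true(all(vapply(fs, function(m) !anyNA(m), logical(1))))
  # without PSSMs the family is dropped
  fs5 <- featurize(ds, aaindex = load_aaindex_table())
  expect_named(fs5, c("OAAC", "DIPEP0", "DIPEP1", "DIPEP2", "AAINDEX"))
  # missing profile errors with the id
  expect_error(featurize(ds, pssms = pss[-1L]), ds$id[1L])
})

test_that("feature matrices round-trip through delimited text", {
  ds <- tiny_dataset(4, 2, seed = 10)
  fs <- featurize(ds, families = c("OAAC"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fs$OAAC, f)
  back <- read_feature_matrix(f)
  expect_equal(back, fs$OAAC)
})
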