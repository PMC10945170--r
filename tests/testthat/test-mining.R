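mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(bait_locus = r[[1]], subject_accession = r[[2]],
               pct_identity = r[[3]], aln_length = r[[4]],
               bait_start = 0L, bait_end = r[[4]],
               subject_start = 0L, subject_end = r[[4]],
               strand = "+", evalue = r[[5]], bitscore = r[[6]])))
}

test_that("hit filtering applies thresholds and best-locus assignment", {
  empty <- mk_hits(list(1L, "S0", 98, 400, 1e-50, 200))[0, ]
  expect_equal(nrow(filter_hits(empty)), 0L)
  h <- mk_hits(list(3L, "S1", 98, 400, 1e-50, 200),
               list(9L, "S1", 97, 400, 1e-50, 150),
               list(1L, "S2", 98, 400, 1e-3, 300),   # fails e-value
               list(1L, "S3", 70, 400, 1e-50, 300),  # fails identity
               list(1L, "S4", 98, 50, 1e-50, 300))   # fails length
  out <- filter_hits(h, lh_config())
  expect_equal(out$subject_accession, "S1")
  expect_equal(out$bait_locus, 3L)  # best bitscore wins
  # bitscore tie goes to the lowest locus id
  tie <- mk_hits(list(7L, "S1", 98, 400, 1e-50, 200),
                 list(2L, "S1", 98, 400, 1e-50, 200))
  expect_equal(filter_hits(tie)$bait_locus, 2L)
})

test_that("selection maximizes unambiguous content, then length, then accession", {
  # 500 bp clean beats 600 bp with 150 Ns (500 > 450 unambiguous)
  pool <- data.frame(accession = c("A", "B"),
                     length_bp = c(500L, 600L),
                     unambiguous_count = c(500L, 450L))
  expect_equal(select_best(pool)$chosen, "A")
  # full tie falls to lexicographically smaller accession ("AB10" < "AB2")
  tie <- data.frame(accession = c("AB2", "AB10"),
                    length_bp = 300L, unambiguous_count = 300L)
  expect_equal(select_best(tie)$chosen, "AB10")
  expect_equal(select_best(tie[0, ])$chosen, NA_character_)
})

test_that("selection order is invariant to pool input permutation", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    pool <- data.frame(
      accession = sprintf("AC%d", sample(100, n)),
      length_bp = sample(200:600, n, replace = TRUE))
    pool$unambiguous_count <- pool$length_bp -
      sample(0:50, n, replace = TRUE)
    ref <- select_best(pool)
    perm <- select_best(pool[sample(n), , drop = FALSE])
    expect_identical(perm$chosen, ref$chosen)
    expect_identical(perm$ranking, ref$ranking)
  }
})

test_that("self-search verification compares the best non-self hit's species", {
  syn <- toy_synonymy()
  ss <- data.frame(
    query_accession = "Q1",
    subject_accession = c("Q1", "R1", "R2"),
    subject_organism = c("Pieris napi", "Papilio brassicae",
                         "Danaus plexippus"),
    bitscore = c(500, 400, 300))
  # best non-self hit is a conspecific under synonymy -> pass
  expect_equal(verify_identity("Q1", "Pieris brassicae", ss, syn), "pass")
  # for another species the same top hit fails
  expect_equal(verify_identity("Q1", "Anthocharis cardamines", ss, syn),
               "fail")
  # genus-rank relaxation
  expect_equal(verify_identity("Q1", "Pieris napi", ss, syn,
                               lh_config(verify_rank = "genus")), "pass")
  # only hit is the sequence itself -> skipped
  only_self <- ss[ss$subject_accession == "Q1", ]
  expect_equal(verify_identity("Q1", "Pieris napi", only_self, syn),
               "skipped")
})

test_that("contamination screen flags cross-family pairs at >= 99% only", {
  syn <- toy_synonymy()
  entries <- data.frame(
    accession = c("P1", "P2", "N1"),
    organism_raw = c("Pieris napi", "Pieris brassicae",
                     "Danaus plexippus"),
    residues = "ACGT", length_bp = 4L, unambiguous_count = 4L)
  idt <- function(a, b, pid, ov)
    data.frame(acc_a = a, acc_b = b, pct_identity = pid, overlap_bp = ov)
  expect_setequal(
    contamination_screen(entries, idt("P1", "N1", 99.5, 400), syn),
    c("P1", "N1"))
  expect_length(
    contamination_screen(entries, idt("P1", "N1", 98.9, 400), syn), 0L)
  expect_length(  # same-family exemption
    contamination_screen(entries, idt("P1", "P2", 99.9, 400), syn), 0L)
  expect_length(  # overlap floor
    contamination_screen(entries, idt("P1", "N1", 99.9, 50), syn), 0L)
  expect_warning(
    contamination_screen(entries, idt("P1", "ZZ", 99.9, 400), syn),
    "ZZ")
})

test_that("raising the identity threshold never flags more sequences", {
  syn <- toy_synonymy()
  set.seed(11)
  entries <- data.frame(
    accession = sprintf("E%02d", 1:10),
    organism_raw = sample(c("Pieris napi", "Danaus plexippus"), 10,
                          replace = TRUE),
    residues = "ACGT", length_bp = 4L, unambiguous_count = 4L)
  idt <- data.frame(acc_a = sample(entries$accession, 30, replace = TRUE),
                    acc_b = sample(entries$accession, 30, replace = TRUE),
                    pct_identity = runif(30, 95, 100),
                    overlap_bp = sample(50:500, 30, replace = TRUE))
  prev <- NULL
  for (thr in c(95, 97, 99, 99.9)) {
    fl <- contamination_screen(entries, idt, syn,
                               lh_config(identity_min = thr))
    if (!is.null(prev)) expect_true(all(fl %in% prev))
    prev <- fl
  }
})

test_that("pool assembly groups by (valid species, locus) and reports exclusions", {
  syn <- toy_synonymy()
  entries <- data.frame(
    accession = c("A1", "A2", "B1", "B2", "U1", "H1"),
    organism_raw = c("Pieris napi", "Papilio brassicae", "Pieris napi",
                     "Pieris brassicae", "Mystery bug", "Pieris napi"),
    residues = "ACGTACGT", length_bp = 8L, unambiguous_count = 8L)
  h <- mk_hits(list(1L, "A1", 98, 300, 1e-50, 200),
               list(1L, "A2", 98, 300, 1e-50, 200),
               list(2L, "B1", 98, 300, 1e-50, 200),
               list(2L, "B2", 98, 300, 1e-50, 200))
  pools <- assemble_pools(entries, h, syn)
  # 2 species x 2 loci -> 4 pools
  expect_equal(nrow(unique(pools[, c("valid_name", "locus_id")])), 4L)
  # two specimens of one species on one locus share a pool
  h2 <- rbind(h, mk_hits(list(1L, "H1", 97, 250, 1e-40, 150)))
  pools2 <- assemble_pools(entries, h2, syn)
  p_napi1 <- pools2[pools2$valid_name == "Pieris napi" &
                      pools2$locus_id == 1L, ]
  expect_setequal(p_napi1$accession, c("A1", "H1"))
  # unresolved entries appear only in the exclusion report
  excl <- attr(pools, "excluded")
  expect_true("U1" %in% excl$accession[excl$reason == "unresolved_name"])
  expect_false("U1" %in% pools$accession)
  expect_true("H1" %in% excl$accession[excl$reason == "no_passing_hits"])
})
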