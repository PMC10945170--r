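test_that("IUPAC union consensus follows the ambiguity-code algebra", {
  expect_equal(collapse_consensus("ACGT"), "ACGT")
  expect_equal(collapse_consensus(c("ACGT", "ACGA")), "ACGW")
  expect_equal(collapse_consensus(c("A", "R")), "R")   # A u {A,G} = R
  expect_equal(collapse_consensus(c("A-", "-C")), "AC")  # gap ignored
  expect_equal(collapse_consensus(c("-", "-")), "-")     # all-gap kept
  expect_equal(collapse_consensus(c("AC", "GT")), "RY")
  expect_error(collapse_consensus(c("AC", "ACG")), "length")
})

test_that("consensus is idempotent and stable under self-application", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(2:5, 1L)
    copies <- replicate(n, paste(
      sample(names(locusharvest::IUPAC_CODES), 12, replace = TRUE),
      collapse = ""))
    cons <- collapse_consensus(copies)
    expect_equal(collapse_consensus(rep(cons, 3L)), cons)
    expect_equal(collapse_consensus(c(cons, copies)), cons)
  }
})

test_that("locus mapping is the identity on shared ids and resolves conflicts", {
  set13 <- data.frame(locus_id = 7L, valid_name = "Pieris napi",
                      accession = "A13", residues = "ACGTACGT")
  set425 <- data.frame(locus_id = c(7L, 20L),
                       valid_name = c("Pieris napi", "Pieris napi"),
                       accession = c("A425", "B425"),
                       residues = c("ACGTNNNN", "GGGG"))
  u <- map_loci(set13, set425)
  expect_equal(sort(u$locus_id), c(7L, 20L))
  # the 8-unambiguous sequence beats the 4-unambiguous one
  expect_equal(u$accession[u$locus_id == 7L], "A13")
  cf <- attr(u, "conflicts")
  expect_equal(cf$winner, "A13")
  expect_equal(cf$loser, "A425")
  # species only in one set keep their loci, others missing
  set13b <- data.frame(locus_id = 1L, valid_name = "Colias hyale",
                       accession = "C1", residues = "TTTT")
  u2 <- map_loci(set13b, set425)
  expect_equal(u2$valid_name[u2$locus_id == 1L], "Colias hyale")
  expect_error(map_loci(data.frame(locus_id = 14L, valid_name = "X y",
                                   accession = "Z", residues = "A"),
                        set425), "1..13")
})

test_that("concatenation records prefix-sum partitions and fills missing blocks", {
  l1 <- locus_matrix(1L, c("Sp a" = strrep("A", 10),
                           "Sp b" = strrep("C", 10)))
  l2 <- locus_matrix(2L, c("Sp a" = strrep("G", 20)))
  sm <- concatenate_loci(list(l2, l1))  # order by id, not input order
  expect_equal(sm$total_width, 30L)
  expect_equal(sm$partitions$start, c(1L, 11L))
  expect_equal(sm$partitions$end, c(10L, 30L))
  expect_equal(unname(sm$rows["Sp b"]),
               paste0(strrep("C", 10), strrep("-", 20)))
  occ <- sm$occupancy
  expect_equal(occ$n_loci[occ$species == "Sp b"], 1L)
  expect_equal(occ$locus_fraction[occ$species == "Sp b"], 0.5)
  # single-locus concatenation is the identity
  sm1 <- concatenate_loci(list(l1))
  expect_equal(unname(sm1$rows), unname(l1$rows))
  expect_error(concatenate_loci(list(l1, l1)), "duplicate locus")
  expect_error(locus_matrix(1L, c(a = "AC", a = "GT")), "duplicate species")
})

test_that("occupancy fractions are 1 for complete matrices and ordered otherwise", {
  full <- concatenate_loci(list(
    locus_matrix(1L, c(x = "ACGT", y = "ACGT")),
    locus_matrix(2L, c(x = "GGGG", y = "TTTT"))))
  expect_true(all(full$occupancy$site_fraction == 1))
  part <- concatenate_loci(list(
    locus_matrix(1L, c(x = "ACGT", y = "ACGT")),
    locus_matrix(2L, c(x = "GGGG"))))
  occ <- part$occupancy
  expect_gt(occ$site_fraction[occ$species == "x"],
            occ$site_fraction[occ$species == "y"])
  expect_equal(as.integer(attr(occ, "histogram")), c(1L, 1L))
})

test_that("width conservation and slice round-trip hold over random matrices", {
  set.seed(99)
  for (i in 1:40) {
    n_loci <- sample(1:6, 1L)
    species <- sprintf("Sp %02d", 1:sample(2:8, 1L))
    lms <- lapply(seq_len(n_loci), function(l) {
      w <- sample(5:40, 1L)
      present <- sample(species, max(1L, rbinom(1, length(species), 0.7)))
      locus_matrix(l, stats::setNames(
        vapply(present, function(s) paste(
          sample(c("A", "C", "G", "T", "N"), w, replace = TRUE),
          collapse = ""), character(1)), present))
    })
    sm <- concatenate_loci(lms)
    expect_equal(sm$total_width,
                 sum(vapply(lms, `[[`, integer(1), "width")))
    for (l in seq_len(n_loci))
      expect_identical(slice_locus(sm, l)$rows, lms[[l]]$rows)
  }
})

test_that("sampling fractions reproduce the reported clade percentages", {
  expect_equal(sampling_fraction(593, 1159), 51)
  expect_equal(sampling_fraction(541, 593), 91)
  expect_equal(sampling_fraction(5, 5), 100)
  expect_equal(sampling_fraction(1, 3, rounding = "none"), 100 / 3)
  expect_error(sampling_fraction(10, 5), "exceeds")
})
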