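test_that("snapshot reading pairs FASTA with metadata and derives counts", {
  d <- withr::local_tempdir()
  writeLines(c(">A1", "ACGTACGT", ">A2", "ACGTNN-R", ">A3", "GGGG"),
             file.path(d, "s.fasta"))
  utils::write.table(
    data.frame(accession = c("A1", "A2", "A3"),
               organism = c("Pieris napi", "Pieris napi", "Pieris napi"),
               locus_hint = 1L, voucher = c("V1", "V2", "V3"),
               extra = "ignored"),
    file.path(d, "m.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  e <- read_snapshot(file.path(d, "s.fasta"), file.path(d, "m.tsv"))
  expect_equal(nrow(e), 3L)
  expect_equal(e$length_bp, c(8L, 8L, 4L))
  # gap and ambiguity codes count to length but never to unambiguous
  expect_equal(e$unambiguous_count[e$accession == "A2"], 4L)
})

test_that("snapshot mismatches and duplicates are hard errors naming offenders", {
  d <- withr::local_tempdir()
  p <- write_toy_snapshot(d, c("A1", "A2"), "Pieris napi",
                          c("ACGT", "GGCC"))
  meta1 <- utils::read.delim(p$meta)
  utils::write.table(meta1[1L, ], p$meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_snapshot(p$fasta, p$meta), "A2")
  writeLines(c(">A1", "ACGT", ">A1", "ACGT"), p$fasta)
  expect_error(read_snapshot(p$fasta, p$meta), "duplicate")
})

test_that("records with residues outside the alphabet are rejected with a warning", {
  d <- withr::local_tempdir()
  p <- write_toy_snapshot(d, c("A1", "A2"), "Pieris napi",
                          c("ACGT", "ACXT"))
  expect_warning(e <- read_snapshot(p$fasta, p$meta), "A2")
  expect_equal(e$accession, "A1")
  expect_equal(attr(e, "rejected"), "A2")
})

test_that("snapshot write/read round-trips field-for-field", {
  d <- withr::local_tempdir()
  p <- write_toy_snapshot(d, c("A1", "A2"), c("Pieris napi", "X y"),
                          c("ACGTRY-N", "GG-CC"), locus_hint = c(1L, 2L))
  e1 <- read_snapshot(p$fasta, p$meta)
  f2 <- file.path(d, "s2.fasta"); m2 <- file.path(d, "m2.tsv")
  write_snapshot(e1, f2, m2)
  e2 <- read_snapshot(f2, m2)
  attr(e1, "rejected") <- attr(e2, "rejected") <- NULL
  expect_identical(e1, e2)
  # and the writer itself is byte-deterministic
  f3 <- file.path(d, "s3.fasta"); m3 <- file.path(d, "m3.tsv")
  write_snapshot(e2, f3, m3)
  expect_identical(readLines(f2), readLines(f3))
  expect_identical(readLines(m2), readLines(m3))
})

test_that("hit ingestion converts 1-based inclusive to 0-based half-open", {
  d <- withr::local_tempdir()
  rows <- c("L1\tS1\t98.5\t100\t1\t0\t1\t100\t1\t100\t1e-50\t180",
            "L1\tS2\t97.0\t100\t3\t0\t1\t100\t200\t101\t1e-40\t170")
  writeLines(rows, file.path(d, "h.tsv"))
  bl <- data.frame(locus_id = 1L, length = 100L)
  h <- read_hits(file.path(d, "h.tsv"), bl)
  expect_equal(h$bait_start, c(0L, 0L))
  expect_equal(h$bait_end, c(100L, 100L))
  # covered-position count equals qend - qstart + 1 of the raw row
  expect_equal(h$bait_end - h$bait_start, c(100L, 100L))
  # descending subject coordinates mean a minus-strand hit, normalized
  expect_equal(h$strand, c("+", "-"))
  expect_equal(h$subject_start[2L], 100L)
  expect_equal(h$subject_end[2L], 200L)
})

test_that("hits beyond bait bounds or on unknown baits are rejected", {
  d <- withr::local_tempdir()
  writeLines("L1\tS1\t98\t150\t1\t0\t1\t150\t1\t150\t1e-50\t200",
             file.path(d, "h.tsv"))
  bl <- data.frame(locus_id = 1L, length = 100L)
  expect_error(read_hits(file.path(d, "h.tsv"), bl), "bounds")
  writeLines("L9\tS1\t98\t50\t1\t0\t1\t50\t1\t50\t1e-50\t90",
             file.path(d, "h.tsv"))
  expect_error(read_hits(file.path(d, "h.tsv"), bl), "unknown bait")
})

test_that("partition files use 1-based inclusive prefix-sum coordinates", {
  sm <- concatenate_loci(list(
    locus_matrix(1L, c(sp1 = strrep("A", 10))),
    locus_matrix(2L, c(sp1 = strrep("C", 20)))))
  p <- withr::local_tempfile()
  write_partitions(sm, p)
  expect_identical(readLines(p),
                   c("DNA, L1 = 1-10", "DNA, L2 = 11-30"))
  # single locus of width L spans 1-L
  sm1 <- concatenate_loci(list(locus_matrix(1L, c(sp1 = strrep("G", 7)))))
  write_partitions(sm1, p)
  expect_identical(readLines(p), "DNA, L1 = 1-7")
})

test_that("per-locus FASTA writing is deterministic and round-trips", {
  d <- withr::local_tempdir()
  tab <- data.frame(locus_id = c(2L, 1L, 1L),
                    name = c("Sp b", "Sp b", "Sp a"),
                    residues = c("GGGG", "ACGT", "TTTT"))
  write_locus_fasta(tab, file.path(d, "o1"))
  write_locus_fasta(tab, file.path(d, "o2"))
  f1 <- list.files(file.path(d, "o1"), full.names = TRUE)
  f2 <- list.files(file.path(d, "o2"), full.names = TRUE)
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))
  back <- read_locus_dir(file.path(d, "o1"))
  expect_equal(back$locus_id, c(1L, 1L, 2L))
  expect_equal(back$residues[back$locus_id == 2L], "GGGG")
})
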