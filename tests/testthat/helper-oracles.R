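# Independent brute-force oracle for the tiling objective: exhaustive
# subset search over all 2^n tile subsets, via a bitmask DP in which
# the coverage vector of a subset extends the subset without its
# lowest set bit.  Returns the lexicographic optimum
# (max coverage, then min cardinality).
exhaustive_tiling_optimum <- function(tiles) {
  n <- nrow(tiles)
  L <- max(tiles$end)
  masks <- lapply(seq_len(n), function(i) {
    v <- logical(L)
    v[(tiles$start[i] + 1L):tiles$end[i]] <- TRUE
    v
  })
  n_sub <- bitwShiftL(1L, n)
  cov <- vector("list", n_sub)
  cov[[1L]] <- logical(L)
  best_cov <- -1L
  best_card <- n + 1L
  for (s in seq_len(n_sub - 1L)) {
    low <- bitwAnd(s, -s)
    i <- as.integer(log2(low)) + 1L
    cov[[s + 1L]] <- cov[[s - low + 1L]] | masks[[i]]
    covered <- sum(cov[[s + 1L]])
    card <- sum(bitwAnd(bitwShiftR(s, 0:(n - 1L)), 1L))
    if (covered > best_cov ||
        (covered == best_cov && card < best_card)) {
      best_cov <- covered
      best_card <- card
    }
  }
  list(covered = best_cov, cardinality = best_card)
}

# random tile set on a small bait
random_tile_set <- function(n_tiles, bait_length) {
  start <- sample.int(bait_length - 1L, n_tiles, replace = TRUE) - 1L
  len <- sample.int(bait_length %/% 2L, n_tiles, replace = TRUE)
  end <- pmin(start + len, bait_length)
  data.frame(accession = sprintf("T%03d", seq_len(n_tiles)),
             start = start, end = end)
}

# tiny in-memory synonymy table used across tests
toy_synonymy <- function() {
  synonymy_table(data.frame(
    published_name = c("Papilio brassicae", "Pieris napi",
                       "Anthocharis cardamines", "Danaus plexippus"),
    valid_name = c("Pieris brassicae", "Pieris napi",
                   "Anthocharis cardamines", "Danaus plexippus"),
    family = c("Pieridae", "Pieridae", "Pieridae", "Nymphalidae")))
}

# write a small snapshot (FASTA + TSV) into a temp dir
write_toy_snapshot <- function(dir, acc, organism, residues,
                               locus_hint = 1L, voucher = "V1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "s.fasta")
  writeLines(paste0(">", acc, "\n", residues), fa)
  tsv <- file.path(dir, "m.tsv")
  utils::write.table(
    data.frame(accession = acc, organism = organism,
               locus_hint = locus_hint, voucher = voucher),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fa, meta = tsv)
}
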