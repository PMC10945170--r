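# Seeded synthetic snapshots with planted ground truth, so selection,
# screening, tiling and matrix assembly are each testable offline
# against a manifest of intended outcomes.
#
# Construction guarantees:
#  * the intended best sequence of every pool strictly dominates its
#    decoys under the selection key (decoys are truncated or carry at
#    least one N);
#  * each bait's planted tile chain is the unique optimum of the
#    fewest-tiles/highest-coverage objective (every chain tile owns a
#    privately covered position; decoy tiles are contained in chain
#    tiles);
#  * contaminants form a cross-family cluster of near-identical
#    copies of one bait reference, so the symmetric >=99% screen flags
#    exactly them.

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute k = max(1, round(rate * width)) positions with a
# different base (or with `to` when given, e.g. "N")
.mutate <- function(seq, rate, to = NULL) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  k <- max(1L, round(rate * length(ch)))
  pos <- sample(length(ch), k)
  if (is.null(to)) {
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  } else {
    ch[pos] <- to
  }
  paste(ch, collapse = "")
}

.pct_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  100 * mean(ca == cb)
}

#' Specify a synthetic snapshot
#'
#' @param n_species number of species (the first is the dedicated
#'   tiling species, represented only by fragments; when
#'   `contaminant_count > 0` the last two belong to a second family).
#' @param n_loci number of bait loci.
#' @param synonyms_per_species historical synonyms generated per
#'   species.
#' @param fragments_per_locus candidate sequences per (species, locus)
#'   pool (the planted best plus decoys); must be at least 1.
#' @param ambiguity_rate fraction of positions replaced by `N` in
#'   ambiguity decoys, in `[0, 1]`.
#' @param contaminant_count planted cross-family contaminants; 0 or
#'   at least 2 (a single contaminant cannot be flagged by the
#'   symmetric cross-family rule without flagging its partner).
#' @param seed integer seed; the same spec and seed reproduce the
#'   snapshot byte-for-byte.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_species = 50, n_loci = 20,
                         synonyms_per_species = 2,
                         fragments_per_locus = 3,
                         ambiguity_rate = 0.1,
                         contaminant_count = 3, seed = 1) {
  stopifnot(n_species >= 2, n_loci >= 1, synonyms_per_species >= 0,
            ambiguity_rate >= 0, ambiguity_rate <= 1,
            contaminant_count >= 0, seed == as.integer(seed))
  if (fragments_per_locus < 1L)
    stop("fixture_spec: fragments_per_locus must be >= 1 ",
         "(tiling truth needs fragments)")
  if (contaminant_count == 1L)
    stop("fixture_spec: a single contaminant is infeasible under the ",
         "symmetric cross-family screen; use 0 or >= 2")
  if (contaminant_count > 0L && n_species < 4L)
    stop("fixture_spec: planting contaminants needs >= 4 species")
  structure(list(n_species = as.integer(n_species),
                 n_loci = as.integer(n_loci),
                 synonyms_per_species = as.integer(synonyms_per_species),
                 fragments_per_locus = as.integer(fragments_per_locus),
                 ambiguity_rate = ambiguity_rate,
                 contaminant_count = as.integer(contaminant_count),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic snapshot with planted ground truth
#'
#' Writes `snapshot.fasta`, `metadata.tsv`, `hits.tsv` (12-column
#' tabular), `baits.tsv`, `synonymy.csv`, `identity.tsv` and
#' `manifest.json` into `out_dir` and returns the truth manifest.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest: `species` (with family and role),
#'   `best_choices` (intended winner per species x locus pool),
#'   `tilings` (unique optimal tile chain per bait), `contaminants`,
#'   `synonyms`, `files`, `spec`.
#' @export
generate_snapshot <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)

  # --- loci ---------------------------------------------------------
  bait_len <- sample(450:750, spec$n_loci, replace = TRUE)
  refs <- vapply(bait_len, .rand_dna, character(1))

  # --- species ------------------------------------------------------
  ns <- spec$n_species
  n_genera <- max(1L, ns %/% 5L)
  genus <- sprintf("Genus%02d", ((seq_len(ns) - 1L) %% n_genera) + 1L)
  valid <- sprintf("%s species%03d", genus, seq_len(ns))
  family <- rep("Pieridae", ns)
  role <- rep("normal", ns)
  role[1L] <- "tiling"
  if (spec$contaminant_count > 0L) {
    family[c(ns - 1L, ns)] <- "Nymphalidae"
    role[c(ns - 1L, ns)] <- "other_family"
  }

  syn_rows <- data.frame(published_name = valid, valid_name = valid,
                         family = family)
  if (spec$synonyms_per_species > 0L) {
    for (k in seq_len(spec$synonyms_per_species)) {
      syn_rows <- rbind(syn_rows, data.frame(
        published_name = sprintf("Syngenus%03d%s species%03d",
                                 seq_len(ns), letters[k], seq_len(ns)),
        valid_name = valid, family = family))
    }
  }
  synonyms <- syn_rows[syn_rows$published_name != syn_rows$valid_name, ,
                       drop = FALSE]

  # a published-name variant for an entry of species s, all of which
  # resolve to valid[s]
  variant <- function(s) {
    kinds <- c("valid", "trinomial", "authority",
               if (spec$synonyms_per_species > 0L) "synonym")
    switch(sample(kinds, 1L),
           valid = valid[s],
           trinomial = paste(valid[s], "borealis"),
           authority = paste0(valid[s], " (Author, 1901)"),
           synonym = {
             k <- sample(spec$synonyms_per_species, 1L)
             sprintf("Syngenus%03d%s species%03d", s, letters[k], s)
           })
  }

  # --- entries, hits, truths ----------------------------------------
  acc_i <- 0L
  next_acc <- function() {
    acc_i <<- acc_i + 1L
    sprintf("ACC%06d", acc_i)
  }
  entries <- list(); hits <- list()
  best_choices <- list(); tilings <- list()

  add_hit <- function(acc, locus, b0, b1, s0, s1, strand, pident,
                      evalue, bitscore) {
    hits[[length(hits) + 1L]] <<- data.frame(
      qseqid = sprintf("L%d", locus), sseqid = acc,
      pident = round(pident, 1), length = b1 - b0,
      mismatch = round((100 - pident) / 100 * (b1 - b0)), gapopen = 0L,
      qstart = b0 + 1L, qend = b1,
      sstart = if (strand == "+") s0 + 1L else s1,
      send = if (strand == "+") s1 else s0 + 1L,
      evalue = evalue, bitscore = bitscore)
  }
  add_entry <- function(acc, s, residues, locus) {
    entries[[length(entries) + 1L]] <<- data.frame(
      accession = acc, organism_raw = variant(s),
      locus_hint = locus, voucher = sprintf("V%05d", acc_i),
      residues = residues)
  }

  for (s in seq_len(ns)) {
    for (l in seq_len(spec$n_loci)) {
      L <- bait_len[l]
      true_seq <- .mutate(refs[l], 0.02)
      pid_ref <- .pct_identity(true_seq, refs[l])
      if (role[s] == "tiling") {
        # chain of 3 tiles with privately covered positions, plus two
        # decoys contained in chain tiles
        b1 <- round(L * 0.40); b2 <- round(L * 0.75); ov <- 20L
        chain <- data.frame(start = c(0L, b1 - ov, b2 - ov),
                            end = c(b1, b2, L))
        decoys <- data.frame(start = c(10L, b2 + 10L),
                             end = c(b1 - 10L, min(b2 + 110L, L - 5L)))
        chain_acc <- character(nrow(chain))
        for (i in seq_len(nrow(chain))) {
          acc <- next_acc(); chain_acc[i] <- acc
          frag <- substr(true_seq, chain$start[i] + 1L, chain$end[i])
          add_entry(acc, s, frag, l)
          add_hit(acc, l, chain$start[i], chain$end[i], 0L, nchar(frag),
                  "+", pid_ref, 1e-120, 2 * nchar(frag))
        }
        for (i in seq_len(nrow(decoys))) {
          acc <- next_acc()
          frag <- substr(true_seq, decoys$start[i] + 1L, decoys$end[i])
          add_entry(acc, s, frag, l)
          add_hit(acc, l, decoys$start[i], decoys$end[i], 0L,
                  nchar(frag), "+", pid_ref, 1e-120, 2 * nchar(frag))
        }
        tilings[[sprintf("L%d", l)]] <- data.frame(
          accession = chain_acc, start = chain$start, end = chain$end)
      } else {
        # planted best: full-length, fully unambiguous
        best_acc <- next_acc()
        add_entry(best_acc, s, true_seq, l)
        add_hit(best_acc, l, 0L, L, 0L, L, "+", pid_ref, 1e-150, 2 * L)
        best_choices[[length(best_choices) + 1L]] <- data.frame(
          valid_name = valid[s], locus_id = l, accession = best_acc)
        # decoys: strictly dominated (shorter, or carrying >= 1 N)
        n_decoy <- spec$fragments_per_locus - 1L
        for (d in seq_len(n_decoy)) {
          acc <- next_acc()
          if (d %% 2L == 1L) {                  # truncated fragment
            off <- sample(0:(L %/% 5L), 1L)
            len <- round(L * stats::runif(1, 0.5, 0.8))
            frag <- substr(true_seq, off + 1L, off + len)
            minus <- d == 1L && l %% 4L == 0L   # exercise minus strand
            if (minus) {
              add_entry(acc, s, .revcomp(frag), l)
              add_hit(acc, l, off, off + len, 0L, len, "-", pid_ref,
                      1e-90, 2 * len)
            } else {
              add_entry(acc, s, frag, l)
              add_hit(acc, l, off, off + len, 0L, len, "+", pid_ref,
                      1e-90, 2 * len)
            }
          } else {                              # ambiguity decoy
            frag <- .mutate(true_seq, max(spec$ambiguity_rate, 0.01),
                            to = "N")
            add_entry(acc, s, frag, l)
            add_hit(acc, l, 0L, L, 0L, L, "+", pid_ref, 1e-110,
                    2 * L - 1)
          }
        }
        # threshold-failing junk hit and a weaker cross-locus hit for
        # the planted best (dropped by filter / locus assignment)
        add_hit(best_acc, l, 0L, min(150L, L), 0L, min(150L, L), "+",
                95, 1e-3, 250)
        if (spec$n_loci > 1L) {
          l2 <- (l %% spec$n_loci) + 1L
          w <- min(150L, bait_len[l2])
          add_hit(best_acc, l2, 0L, w, 0L, w, "+", 85, 1e-20, L * 0.5)
        }
      }
    }
  }

  # --- contaminants: cross-family cluster on locus 1 ----------------
  contaminants <- character(0)
  identity <- list()
  if (spec$contaminant_count > 0L) {
    hosts_focal <- which(role == "normal" & family == "Pieridae")
    hosts_other <- which(role == "other_family")
    copies <- character(spec$contaminant_count)
    for (i in seq_len(spec$contaminant_count)) {
      acc <- next_acc(); contaminants <- c(contaminants, acc)
      host <- if (i %% 2L == 1L)
        hosts_focal[((i - 1L) %/% 2L) %% length(hosts_focal) + 1L]
      else hosts_other[(i %/% 2L - 1L) %% length(hosts_other) + 1L]
      copies[i] <- .mutate(refs[1L], 0.002)
      entries[[length(entries) + 1L]] <- data.frame(
        accession = acc, organism_raw = valid[host], locus_hint = 1L,
        voucher = sprintf("V%05d", acc_i), residues = copies[i])
      add_hit(acc, 1L, 0L, bait_len[1L], 0L, bait_len[1L], "+", 99.5,
              1e-150, 2 * bait_len[1L])
      if (i > 1L) {
        identity[[length(identity) + 1L]] <- data.frame(
          acc_a = contaminants[i - 1L], acc_b = acc,
          pct_identity = round(.pct_identity(copies[i - 1L], copies[i]),
                               2),
          overlap_bp = bait_len[1L])
      }
    }
    # non-flagging noise: a same-family near-identical pair and a
    # below-threshold cross-family pair
    bc <- do.call(rbind, best_choices)
    focal_accs <- bc$accession[bc$valid_name %in% valid[hosts_focal]]
    other_accs <- bc$accession[bc$valid_name %in% valid[hosts_other]]
    identity[[length(identity) + 1L]] <- data.frame(
      acc_a = focal_accs[1L], acc_b = focal_accs[2L],
      pct_identity = 99.9, overlap_bp = 300L)
    identity[[length(identity) + 1L]] <- data.frame(
      acc_a = focal_accs[1L], acc_b = other_accs[1L],
      pct_identity = 97.5, overlap_bp = 400L)
  }

  # --- write files --------------------------------------------------
  entries <- do.call(rbind, entries)
  entries$length_bp <- nchar(entries$residues)
  entries$unambiguous_count <- unambiguous_count(entries$residues)
  hits <- do.call(rbind, hits)
  f <- list(
    fasta = file.path(out_dir, "snapshot.fasta"),
    metadata = file.path(out_dir, "metadata.tsv"),
    hits = file.path(out_dir, "hits.tsv"),
    baits = file.path(out_dir, "baits.tsv"),
    synonymy = file.path(out_dir, "synonymy.csv"),
    identity = file.path(out_dir, "identity.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_snapshot(entries, f$fasta, f$metadata)
  utils::write.table(hits, f$hits, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(locus_id = seq_len(spec$n_loci), length = bait_len),
    f$baits, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(syn_rows, f$synonymy, row.names = FALSE, quote = FALSE)
  id_tab <- if (length(identity)) do.call(rbind, identity) else
    data.frame(acc_a = character(0), acc_b = character(0),
               pct_identity = numeric(0), overlap_bp = integer(0))
  utils::write.table(id_tab, f$identity, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(
    spec = unclass(spec),
    species = data.frame(valid_name = valid, family = family,
                         role = role),
    synonyms = synonyms,
    best_choices = do.call(rbind, best_choices),
    tilings = tilings,
    contaminants = contaminants,
    bait_lengths = data.frame(locus_id = seq_len(spec$n_loci),
                              length = bait_len),
    files = lapply(f, normalizePath, mustWork = FALSE)
  )
  jsonlite::write_json(manifest[setdiff(names(manifest), "files")],
                       f$manifest, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(manifest)
}
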