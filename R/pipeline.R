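# Full-pipeline orchestration: resolve -> screen -> filter -> pool ->
# select -> verify -> tile -> concatenate, with machine-readable
# exclusion reports and a run manifest.  The stage order is fixed;
# in particular contamination screening precedes selection, so a
# flagged sequence can never win a pool.

#' Assemble a run configuration
#'
#' Validates paths and thresholds before any stage runs; the
#' configuration is serialized verbatim into the run manifest.
#'
#' @param snapshot_fasta,snapshot_meta snapshot files
#'   ([read_snapshot()]).
#' @param hits 12-column tabular search results ([read_hits()]).
#' @param baits bait length table ([read_bait_lengths()]).
#' @param synonymy synonymy CSV ([load_synonymy()]).
#' @param out_dir output directory.
#' @param identity optional pairwise-identity table for the
#'   contamination screen (TSV: acc_a, acc_b, pct_identity,
#'   overlap_bp); `NULL` skips the screen.
#' @param selfsearch optional self-search hit table for verification
#'   (TSV: query_accession, subject_accession, subject_organism,
#'   bitscore); `NULL` records verification as skipped.
#' @param config thresholds from [lh_config()].
#' @return object of class `run_config`.
#' @export
run_config <- function(snapshot_fasta, snapshot_meta, hits, baits,
                       synonymy, out_dir, identity = NULL,
                       selfsearch = NULL, config = lh_config()) {
  paths <- c(snapshot_fasta = snapshot_fasta,
             snapshot_meta = snapshot_meta, hits = hits, baits = baits,
             synonymy = synonymy, identity = identity,
             selfsearch = selfsearch)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files))
    stop("run_config: missing input file(s): ",
         paste(names(missing_files), "=", missing_files,
               collapse = ", "))
  structure(list(snapshot_fasta = snapshot_fasta,
                 snapshot_meta = snapshot_meta, hits = hits,
                 baits = baits, synonymy = synonymy,
                 identity = identity, selfsearch = selfsearch,
                 out_dir = out_dir, config = config),
            class = "run_config")
}

# representative/tiling decision for one pool; returns the bait-frame
# sequence, the accessions used, and how
.pool_sequence <- function(pool, bait_length, selfsearch, synonymy,
                           config) {
  entry_rows <- pool[!duplicated(pool$accession), , drop = FALSE]
  sel <- select_best(entry_rows)
  failed <- character(0)
  chosen <- NA_character_
  verification <- "skipped"
  for (acc in sel$ranking) {
    if (is.null(selfsearch)) { chosen <- acc; break }
    v <- verify_identity(acc, pool$valid_name[1L], selfsearch,
                         synonymy, config)
    if (v %in% c("pass", "skipped")) {
      chosen <- acc; verification <- v; break
    }
    failed <- c(failed, acc)
  }
  if (is.na(chosen))
    return(list(row = NULL, used = character(0), failed = failed,
                mode = "all_failed_verification",
                verification = "fail"))
  # verification-failed candidates leave the pool entirely, so they
  # cannot re-enter through the tiling path
  pool <- pool[!(pool$accession %in% failed), , drop = FALSE]
  tiles <- data.frame(accession = pool$accession,
                      start = pool$bait_start, end = pool$bait_end)
  sol <- tile_select(tiles, bait_length)

  # does the chosen representative alone attain the coverage ceiling?
  own <- tiles[tiles$accession == chosen, , drop = FALSE]
  own_sol <- tile_select(own, bait_length)
  if (own_sol$covered_positions == sol$covered_positions) {
    use <- own_sol; mode <- "representative"
  } else {
    use <- sol; mode <- "tiling"
  }
  frag_rows <- merge(use$chosen, pool,
                     by.x = c("accession", "start", "end"),
                     by.y = c("accession", "bait_start", "bait_end"))
  frag_rows$residues_frag <- vapply(seq_len(nrow(frag_rows)),
                                    function(i) {
    r <- substr(frag_rows$residues[i], frag_rows$subject_start[i] + 1L,
                frag_rows$subject_end[i])
    if (frag_rows$strand[i] == "-") r <- .revcomp(r)
    want <- frag_rows$end[i] - frag_rows$start[i]
    if (nchar(r) > want) r <- substr(r, 1L, want)
    if (nchar(r) < want) r <- paste0(r, strrep("N", want - nchar(r)))
    r
  }, character(1))
  use$chosen <- data.frame(accession = frag_rows$accession,
                           start = frag_rows$start,
                           end = frag_rows$end,
                           residues = frag_rows$residues_frag)
  use$chosen <- use$chosen[order(use$chosen$start, use$chosen$end,
                                 use$chosen$accession,
                                 method = "radix"), , drop = FALSE]
  row <- stitch_tiles(use, bait_length, config$missing_char)
  list(row = row, used = use$per_specimen, failed = failed,
       mode = mode, verification = verification)
}

#' Run the full mining-to-supermatrix pipeline
#'
#' Executes the fixed stage order (resolve, contamination screen,
#' hit filtering, pooling, selection with optional verification,
#' tiling, bait-frame assembly, concatenation) and writes the matrix
#' (FASTA + relaxed PHYLIP), the partition file, the occupancy
#' report, per-accession provenance, the exclusion report, and a run
#' manifest with input checksums.  Re-running with identical inputs
#' and configuration is byte-identical: no stage draws random
#' numbers and every ordering is explicit.
#'
#' No record is dropped silently: every snapshot accession ends up
#' either in `provenance.tsv` (used in the matrix) or in
#' `exclusions.tsv` with a machine-readable reason.
#'
#' @param rc a [run_config()].
#' @return invisibly, a list: `supermatrix`, `provenance`,
#'   `exclusions`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  cfg <- rc$config
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)

  synonymy <- load_synonymy(rc$synonymy)
  entries <- read_snapshot(rc$snapshot_fasta, rc$snapshot_meta)
  baits <- read_bait_lengths(rc$baits)
  hits <- read_hits(rc$hits, baits)
  selfsearch <- if (!is.null(rc$selfsearch))
    utils::read.delim(rc$selfsearch, colClasses = "character") else NULL
  if (!is.null(selfsearch))
    selfsearch$bitscore <- as.numeric(selfsearch$bitscore)

  exclusions <- data.frame(accession = character(0),
                           reason = character(0))
  exclude <- function(acc, reason) {
    if (length(acc))
      exclusions <<- rbind(exclusions,
                           data.frame(accession = acc, reason = reason))
  }
  exclude(attr(entries, "rejected"), "invalid_residues")

  # contamination screen before pooling, so flagged sequences never
  # win a pool
  flagged <- character(0)
  if (!is.null(rc$identity)) {
    idt <- utils::read.delim(rc$identity)
    flagged <- contamination_screen(entries, idt, synonymy, cfg)
    exclude(flagged, "contamination")
    entries <- entries[!(entries$accession %in% flagged), , drop = FALSE]
  }

  kept_hits <- filter_hits(hits, cfg)
  pools <- assemble_pools(entries, kept_hits, synonymy)
  exclusions <- rbind(exclusions, attr(pools, "excluded"))

  keys <- unique(pools[, c("valid_name", "locus_id")])
  keys <- keys[order(keys$valid_name, keys$locus_id,
                     method = "radix"), , drop = FALSE]
  locus_rows <- list()
  provenance <- list()
  for (i in seq_len(nrow(keys))) {
    vn <- keys$valid_name[i]; lid <- keys$locus_id[i]
    pool <- pools[pools$valid_name == vn & pools$locus_id == lid, ,
                  drop = FALSE]
    L <- baits$length[match(lid, baits$locus_id)]
    ps <- .pool_sequence(pool, L, selfsearch, synonymy, cfg)
    exclude(ps$failed, "verification_failed")
    if (is.null(ps$row)) next
    locus_rows[[length(locus_rows) + 1L]] <- data.frame(
      locus_id = lid, valid_name = vn, residues = as.character(ps$row))
    provenance[[length(provenance) + 1L]] <- data.frame(
      accession = ps$used, valid_name = vn, locus_id = lid,
      role = ps$mode, verification = ps$verification)
  }
  if (!length(locus_rows))
    stop("run_pipeline: no pool yielded a sequence; nothing to build")
  locus_rows <- do.call(rbind, locus_rows)
  provenance <- do.call(rbind, provenance)
  provenance <- provenance[order(provenance$accession,
                                 provenance$locus_id,
                                 method = "radix"), , drop = FALSE]

  # pooled candidates that were neither chosen nor tiled
  used_acc <- unique(provenance$accession)
  pooled_unused <- setdiff(unique(pools$accession),
                           c(used_acc, exclusions$accession))
  exclude(pooled_unused, "not_selected")
  exclusions <- exclusions[order(exclusions$accession,
                                 method = "radix"), , drop = FALSE]

  lms <- lapply(sort(unique(locus_rows$locus_id)), function(lid) {
    sub <- locus_rows[locus_rows$locus_id == lid, , drop = FALSE]
    locus_matrix(lid, stats::setNames(sub$residues, sub$valid_name))
  })
  sm <- concatenate_loci(lms, cfg$missing_char)

  # outputs
  out <- function(p) file.path(rc$out_dir, p)
  write_supermatrix(sm, out("matrix.fasta"), out("matrix.phy"))
  write_partitions(sm, out("partitions.txt"))
  utils::write.table(sm$occupancy, out("occupancy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(provenance, out("provenance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(exclusions, out("exclusions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  inputs <- c(rc$snapshot_fasta, rc$snapshot_meta, rc$hits, rc$baits,
              rc$synonymy, rc$identity, rc$selfsearch)
  manifest <- list(
    tool = "locusharvest",
    version = as.character(utils::packageVersion("locusharvest")),
    config = cfg,
    inputs = stats::setNames(as.list(unname(tools::md5sum(inputs))),
                             basename(inputs)),
    n_species = length(sm$species),
    n_loci = nrow(sm$partitions),
    total_width = sm$total_width,
    n_excluded = nrow(exclusions),
    n_provenance = length(used_acc)
  )
  jsonlite::write_json(manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(supermatrix = sm, provenance = provenance,
                 exclusions = exclusions, manifest = manifest,
                 out_dir = rc$out_dir))
}
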