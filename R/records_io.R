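# Readers and writers for every external format the toolkit touches.
#
# Conventions (fixed, documented dialects):
#  * sequences       FASTA; ids are accessions
#  * metadata        TSV with header: accession, organism, locus_hint,
#                    voucher (extra columns preserved but ignored)
#  * search hits     12-column tabular output (qseqid sseqid pident
#                    length mismatch gapopen qstart qend sstart send
#                    evalue bitscore), 1-based inclusive coordinates;
#                    the query is the bait locus
#  * partitions      RAxML-style "DNA, L<id> = <start>-<end>"
#
# Coordinates are stored 0-based half-open internally and emitted
# 1-based inclusive in every file a user sees.

.META_COLS <- c("accession", "organism", "locus_hint", "voucher")

#' Read a sequence snapshot (FASTA + metadata)
#'
#' Pairs every FASTA record with its metadata row and populates the
#' derived selection quantities `length_bp` and `unambiguous_count`.
#' Records whose residues fall outside the IUPAC DNA alphabet plus gap
#' are dropped with a warning naming them (they are recorded in the
#' `"rejected"` attribute).
#'
#' @param fasta_path FASTA file; record ids must match the metadata
#'   `accession` column exactly.
#' @param metadata_path tab-separated metadata with header columns
#'   `accession`, `organism`, `locus_hint`, `voucher`.  Unknown extra
#'   columns are preserved but ignored.
#' @return data.frame with one row per record: `accession`,
#'   `organism_raw`, `locus_hint`, `voucher`, `residues`, `length_bp`,
#'   `unambiguous_count`; attribute `"rejected"` holds accessions
#'   dropped for invalid residues.
#' @export
read_snapshot <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("read_snapshot: duplicate accession(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  meta <- utils::read.delim(metadata_path, sep = "\t",
                            colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(.META_COLS, names(meta))
  if (length(missing_cols))
    stop("read_snapshot: metadata lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$accession))
    stop("read_snapshot: duplicate accession(s) in metadata: ",
         paste(unique(meta$accession[duplicated(meta$accession)]),
               collapse = ", "))
  only_fa <- setdiff(ids, meta$accession)
  only_meta <- setdiff(meta$accession, ids)
  if (length(only_fa) || length(only_meta))
    stop("read_snapshot: FASTA/metadata mismatch.",
         if (length(only_fa))
           paste0(" In FASTA only: ", paste(only_fa, collapse = ", "), "."),
         if (length(only_meta))
           paste0(" In metadata only: ", paste(only_meta, collapse = ", "), "."))

  res <- toupper(as.character(seqs))
  ok <- .valid_residues(res)
  rejected <- ids[!ok]
  if (length(rejected))
    warning("read_snapshot: rejected record(s) with residues outside the ",
            "IUPAC DNA alphabet: ", paste(rejected, collapse = ", "))
  ids <- ids[ok]; res <- res[ok]
  meta <- meta[match(ids, meta$accession), , drop = FALSE]
  out <- data.frame(
    accession = ids,
    organism_raw = meta$organism,
    locus_hint = suppressWarnings(as.integer(meta$locus_hint)),
    voucher = meta$voucher,
    residues = unname(res),
    length_bp = nchar(res),
    unambiguous_count = unambiguous_count(res),
    row.names = NULL
  )
  attr(out, "rejected") <- rejected
  out
}

#' Write a sequence snapshot (FASTA + metadata)
#'
#' Inverse of [read_snapshot()]: emits the FASTA and the tab-separated
#' metadata with deterministic record order (as given).  Writing then
#' reading reproduces the entries field-for-field, and re-running the
#' writer on the same input is byte-identical.
#'
#' @param entries data.frame as returned by [read_snapshot()].
#' @param fasta_path,metadata_path output paths.
#' @return invisibly, the two paths.
#' @export
write_snapshot <- function(entries, fasta_path, metadata_path) {
  stopifnot(is.data.frame(entries), nrow(entries) >= 1L)
  ss <- Biostrings::BStringSet(entries$residues)
  names(ss) <- entries$accession
  Biostrings::writeXStringSet(ss, fasta_path)
  meta <- data.frame(
    accession = entries$accession,
    organism = entries$organism_raw,
    locus_hint = ifelse(is.na(entries$locus_hint), "NA",
                        as.character(entries$locus_hint)),
    voucher = entries$voucher
  )
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, metadata_path))
}

#' Read bait locus lengths
#'
#' @param path TSV with header columns `locus_id`, `length`.
#' @return data.frame with integer `locus_id` and `length`.
#' @export
read_bait_lengths <- function(path) {
  x <- utils::read.delim(path, sep = "\t")
  stopifnot(all(c("locus_id", "length") %in% names(x)))
  data.frame(locus_id = as.integer(x$locus_id), length = as.integer(x$length))
}

# parse "L7"/"7" bait ids to integer locus ids
.parse_locus_id <- function(x) suppressWarnings(as.integer(sub("^L", "", x)))

#' Read 12-column tabular search hits
#'
#' Ingests BLAST-style tabular output (outfmt-6 dialect) in which the
#' query is the bait locus.  Coordinates arrive 1-based inclusive and
#' are converted to 0-based half-open on the bait.  Hits whose bait or
#' subject coordinates descend are flagged minus-strand and
#' normalized so bait coordinates always ascend.
#'
#' @param tabular_path tab-separated file without header; columns
#'   qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#'   sstart, send, evalue, bitscore.
#' @param bait_lengths data.frame from [read_bait_lengths()]; hits on
#'   unknown baits, or extending past the bait length, are errors.
#' @return data.frame of hits: `bait_locus`, `subject_accession`,
#'   `pct_identity`, `aln_length`, `bait_start`, `bait_end` (0-based
#'   half-open), `subject_start`, `subject_end` (0-based half-open on
#'   the subject's plus strand), `strand`, `evalue`, `bitscore`.
#' @export
read_hits <- function(tabular_path, bait_lengths) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- tryCatch(
    utils::read.delim(tabular_path, sep = "\t", header = FALSE,
                      col.names = cols, colClasses = c(
                        "character", "character", "numeric", "integer",
                        "integer", "integer", "integer", "integer",
                        "integer", "integer", "numeric", "numeric")),
    error = function(e) stop("read_hits: malformed table: ",
                             conditionMessage(e)))
  bad <- which(is.na(x$qstart) | is.na(x$qend) | is.na(x$sstart) |
                 is.na(x$send) | is.na(x$evalue) | is.na(x$bitscore))
  if (length(bad))
    stop("read_hits: malformed row(s) at line(s) ",
         paste(bad, collapse = ", "))
  locus <- .parse_locus_id(x$qseqid)
  if (anyNA(locus))
    stop("read_hits: unparseable bait id(s): ",
         paste(unique(x$qseqid[is.na(locus)]), collapse = ", "))
  unknown <- setdiff(locus, bait_lengths$locus_id)
  if (length(unknown))
    stop("read_hits: unknown bait id(s): ", paste(unknown, collapse = ", "))

  # strand: minus iff exactly one of the coordinate pairs descends
  q_rev <- x$qstart > x$qend
  s_rev <- x$sstart > x$send
  strand <- ifelse(xor(q_rev, s_rev), "-", "+")
  qlo <- pmin(x$qstart, x$qend); qhi <- pmax(x$qstart, x$qend)
  slo <- pmin(x$sstart, x$send); shi <- pmax(x$sstart, x$send)

  blen <- bait_lengths$length[match(locus, bait_lengths$locus_id)]
  over <- qhi > blen | qlo < 1L
  if (any(over))
    stop("read_hits: hit(s) outside bait bounds at line(s) ",
         paste(which(over), collapse = ", "))

  data.frame(
    bait_locus = locus,
    subject_accession = x$sseqid,
    pct_identity = x$pident,
    aln_length = x$length,
    bait_start = qlo - 1L,
    bait_end = qhi,
    subject_start = slo - 1L,
    subject_end = shi,
    strand = strand,
    evalue = x$evalue,
    bitscore = x$bitscore
  )
}

#' Write per-locus FASTA files
#'
#' One FASTA per locus (`L<id>.fasta`), loci ascending by id, records
#' in lexicographic (C-locale) order of their names, so re-running the
#' writer on identical input is byte-identical.
#'
#' @param locus_table data.frame with columns `locus_id`, `name`
#'   (sequence header, usually the valid species name), `residues`.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_locus_fasta <- function(locus_table, out_dir) {
  stopifnot(all(c("locus_id", "name", "residues") %in% names(locus_table)))
  if (nrow(locus_table) == 0L) stop("write_locus_fasta: empty table")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (lid in sort(unique(locus_table$locus_id))) {
    sub <- locus_table[locus_table$locus_id == lid, , drop = FALSE]
    sub <- sub[order(sub$name, method = "radix"), , drop = FALSE]
    ss <- Biostrings::BStringSet(sub$residues)
    names(ss) <- sub$name
    p <- file.path(out_dir, sprintf("L%d.fasta", lid))
    Biostrings::writeXStringSet(ss, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a directory of per-locus FASTA files
#'
#' Inverse of [write_locus_fasta()]: files named `L<id>.fasta` are
#' read into one long table.
#'
#' @param dir directory of `L<id>.fasta` files.
#' @return data.frame with `locus_id`, `name`, `residues`.
#' @export
read_locus_dir <- function(dir) {
  files <- list.files(dir, pattern = "^L[0-9]+\\.fasta$", full.names = TRUE)
  if (!length(files)) stop("read_locus_dir: no L<id>.fasta files in ", dir)
  out <- lapply(files, function(p) {
    lid <- as.integer(sub("^L([0-9]+)\\.fasta$", "\\1", basename(p)))
    ss <- Biostrings::readBStringSet(p)
    data.frame(locus_id = lid, name = trimws(names(ss)),
               residues = toupper(unname(as.character(ss))))
  })
  out <- do.call(rbind, out)
  out[order(out$locus_id, out$name, method = "radix"), , drop = FALSE]
}

#' Write a RAxML-style partition file
#'
#' Lines of the form `DNA, L<id> = <start>-<end>` with 1-based
#' inclusive coordinates, loci ascending by id.
#'
#' @param supermatrix a [concatenate_loci()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_partitions <- function(supermatrix, path) {
  stopifnot(inherits(supermatrix, "supermatrix"))
  p <- supermatrix$partitions
  if (nrow(p) == 0L) stop("write_partitions: empty matrix")
  writeLines(sprintf("DNA, L%d = %d-%d", p$locus_id, p$start, p$end), path)
  invisible(path)
}
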