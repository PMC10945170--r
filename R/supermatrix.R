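# Locus-set merging, concatenation into a partitioned supermatrix,
# occupancy reporting, and the sampling-fraction arithmetic used by
# downstream diversification analyses.

#' Construct a per-locus alignment matrix
#'
#' @param locus_id integer locus id.
#' @param rows named character vector: species -> residue string; all
#'   rows must have equal width and unique names.
#' @return object of class `locus_matrix` with fields `locus_id`,
#'   `width`, `rows`.
#' @export
locus_matrix <- function(locus_id, rows) {
  if (length(rows) == 0L) stop("locus_matrix: no rows")
  if (is.null(names(rows)) || any(names(rows) == ""))
    stop("locus_matrix: rows must be named by species")
  if (anyDuplicated(names(rows)))
    stop("locus_matrix: duplicate species in locus ", locus_id, ": ",
         paste(unique(names(rows)[duplicated(names(rows))]),
               collapse = ", "))
  w <- unique(nchar(rows))
  if (length(w) != 1L)
    stop("locus_matrix: unequal row widths in locus ", locus_id)
  structure(list(locus_id = as.integer(locus_id), width = as.integer(w),
                 rows = rows[order(names(rows), method = "radix")]),
            class = "locus_matrix")
}

#' Merge a 13-locus and a 425-locus dataset into one locus space
#'
#' The 13 curated loci are included, under the same ids 1 through 13,
#' in the 425-locus set, so the mapping between the two is the
#' identity on 1..13.  Species present in both sets are merged; when
#' both contribute a sequence for the same species and locus the
#' winner is chosen by the representative-selection key (most
#' unambiguous bases, then non-gap length, then accession) and the
#' conflict is logged.
#'
#' @param set13,set425 data.frames with columns `locus_id`,
#'   `valid_name`, `accession`, `residues`; locus ids must lie in
#'   1..13 and 1..425 respectively.
#' @return unified data.frame of the same shape, one row per
#'   (species, locus); attribute `"conflicts"` records every resolved
#'   collision (`valid_name`, `locus_id`, `winner`, `loser`).
#' @export
map_loci <- function(set13, set425) {
  need <- c("locus_id", "valid_name", "accession", "residues")
  stopifnot(all(need %in% names(set13)), all(need %in% names(set425)))
  if (nrow(set13) && (min(set13$locus_id) < 1L || max(set13$locus_id) > 13L))
    stop("map_loci: 13-locus set has locus id(s) outside 1..13")
  if (nrow(set425) && (min(set425$locus_id) < 1L ||
                       max(set425$locus_id) > 425L))
    stop("map_loci: 425-locus set has locus id(s) outside 1..425")
  all_rows <- rbind(set13[, need, drop = FALSE],
                    set425[, need, drop = FALSE])
  all_rows$unambiguous_count <- unambiguous_count(all_rows$residues)
  all_rows$nongap_len <- nchar(gsub("-", "", all_rows$residues,
                                    fixed = TRUE))
  o <- order(all_rows$valid_name, all_rows$locus_id,
             -all_rows$unambiguous_count, -all_rows$nongap_len,
             all_rows$accession, method = "radix")
  all_rows <- all_rows[o, , drop = FALSE]
  key <- paste(all_rows$valid_name, all_rows$locus_id)
  dup <- duplicated(key)
  conflicts <- data.frame(
    valid_name = all_rows$valid_name[dup],
    locus_id = all_rows$locus_id[dup],
    winner = all_rows$accession[match(key[dup], key)],
    loser = all_rows$accession[dup]
  )
  out <- all_rows[!dup, need, drop = FALSE]
  out <- out[order(out$locus_id, out$valid_name, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "conflicts") <- conflicts
  out
}

#' Concatenate per-locus alignments into a partitioned supermatrix
#'
#' Takes the species union across loci, fills blocks absent for a
#' species with the missing character, and records contiguous 1-based
#' inclusive partitions in ascending locus-id order.  Species rows are
#' ordered lexicographically (C locale) so output is byte-stable.
#'
#' @param locus_matrices list of [locus_matrix()] objects with
#'   distinct locus ids.
#' @param missing_char fill character for absent blocks (`"-"`
#'   default, `"?"` accepted).
#' @return object of class `supermatrix`: `species`, `total_width`,
#'   `partitions` (data.frame `locus_id`, `start`, `end`, `width`),
#'   `rows` (named character vector), `occupancy` (see
#'   [occupancy_report()]), `missing_char`.
#' @export
concatenate_loci <- function(locus_matrices, missing_char = "-") {
  stopifnot(missing_char %in% c("-", "?"))
  if (length(locus_matrices) == 0L)
    stop("concatenate_loci: no loci")
  stopifnot(all(vapply(locus_matrices, inherits, logical(1),
                       "locus_matrix")))
  ids <- vapply(locus_matrices, `[[`, integer(1), "locus_id")
  if (anyDuplicated(ids))
    stop("concatenate_loci: duplicate locus id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  locus_matrices <- locus_matrices[order(ids)]
  ids <- sort(ids)
  widths <- vapply(locus_matrices, `[[`, integer(1), "width")
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  species <- sort(unique(unlist(lapply(locus_matrices,
                                       function(l) names(l$rows)))),
                  method = "radix")
  blocks <- vapply(locus_matrices, function(l) {
    filler <- strrep(missing_char, l$width)
    out <- l$rows[species]
    out[is.na(out)] <- filler
    unname(out)
  }, character(length(species)))
  if (length(species) == 1L) blocks <- matrix(blocks, nrow = 1L)
  rows <- apply(blocks, 1L, paste, collapse = "")
  names(rows) <- species
  sm <- structure(list(
    species = species,
    total_width = sum(widths),
    partitions = data.frame(locus_id = ids, start = starts, end = ends,
                            width = widths),
    rows = rows,
    missing_char = missing_char
  ), class = "supermatrix")
  sm$occupancy <- occupancy_report(sm)
  sm
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("supermatrix:", length(x$species), "species x", x$total_width,
      "sites in", nrow(x$partitions), "loci; mean non-missing fraction",
      sprintf("%.3f", mean(x$occupancy$site_fraction)), "\n")
  invisible(x)
}

#' Per-species occupancy of a supermatrix
#'
#' Missing data in a combined matrix varies because some taxa carry
#' only the small curated locus set and others the full capture set;
#' this report quantifies it per species.
#'
#' @param supermatrix a [concatenate_loci()] result.
#' @return data.frame: `species`, `n_loci` (loci with at least one
#'   non-missing site), `locus_fraction`, `site_fraction` (share of
#'   sites not equal to the missing character).  Attribute
#'   `"histogram"` tabulates species by loci-present count.
#' @export
occupancy_report <- function(supermatrix) {
  stopifnot(inherits(supermatrix, "supermatrix"))
  p <- supermatrix$partitions
  mc <- supermatrix$missing_char
  n_loci <- vapply(supermatrix$rows, function(r) {
    sum(vapply(seq_len(nrow(p)), function(i) {
      block <- substr(r, p$start[i], p$end[i])
      block != strrep(mc, p$width[i])
    }, logical(1)))
  }, integer(1))
  site_fraction <- vapply(supermatrix$rows, function(r) {
    1 - lengths(regmatches(r, gregexpr(mc, r, fixed = TRUE))) /
      supermatrix$total_width
  }, numeric(1))
  out <- data.frame(species = supermatrix$species,
                    n_loci = unname(n_loci),
                    locus_fraction = unname(n_loci) / nrow(p),
                    site_fraction = unname(site_fraction),
                    row.names = NULL)
  attr(out, "histogram") <- table(out$n_loci)
  out
}

#' Extract one locus block from a supermatrix
#'
#' Partition-wise slicing inverts concatenation: slicing every
#' partition and dropping the all-missing filler rows recovers the
#' input locus matrices exactly.
#'
#' @param supermatrix a [concatenate_loci()] result.
#' @param locus_id locus to extract.
#' @param drop_missing drop species whose block is entirely the
#'   missing character (default `TRUE`).
#' @return a [locus_matrix()].
#' @export
slice_locus <- function(supermatrix, locus_id, drop_missing = TRUE) {
  stopifnot(inherits(supermatrix, "supermatrix"))
  p <- supermatrix$partitions
  i <- match(locus_id, p$locus_id)
  if (is.na(i)) stop("slice_locus: no locus ", locus_id)
  block <- substr(supermatrix$rows, p$start[i], p$end[i])
  names(block) <- supermatrix$species
  if (drop_missing) {
    filler <- strrep(supermatrix$missing_char, p$width[i])
    block <- block[block != filler]
  }
  locus_matrix(locus_id, block)
}

#' Write a supermatrix as FASTA and relaxed PHYLIP
#'
#' @param supermatrix a [concatenate_loci()] result.
#' @param fasta_path,phylip_path output paths (either may be `NULL`
#'   to skip that format).
#' @return invisibly, the written paths.
#' @export
write_supermatrix <- function(supermatrix, fasta_path = NULL,
                              phylip_path = NULL) {
  stopifnot(inherits(supermatrix, "supermatrix"))
  written <- character(0)
  if (!is.null(fasta_path)) {
    ss <- Biostrings::BStringSet(supermatrix$rows)
    names(ss) <- supermatrix$species
    Biostrings::writeXStringSet(ss, fasta_path)
    written <- c(written, fasta_path)
  }
  if (!is.null(phylip_path)) {
    con <- file(phylip_path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d %d", length(supermatrix$species),
                       supermatrix$total_width), con)
    writeLines(sprintf("%s  %s", gsub("\\s+", "_", supermatrix$species),
                       unname(supermatrix$rows)), con)
    written <- c(written, phylip_path)
  }
  invisible(written)
}

#' Sampling fraction of described species
#'
#' The share of a clade's described species present in a phylogeny,
#' supplied to diversification analyses to correct for incomplete
#' sampling and reported as a percent.
#'
#' @param n_sampled species present in the phylogeny (or dataset).
#' @param n_described described species of the clade; must be at
#'   least `n_sampled`.
#' @param rounding `"nearest"` (default; integer percent as reported
#'   in text) or `"none"` (full precision, for export to
#'   diversification tools).
#' @return percent on 0-100.
#' @examples
#' sampling_fraction(593, 1159)  # 51
#' sampling_fraction(541, 593)   # 91
#' @export
sampling_fraction <- function(n_sampled, n_described,
                              rounding = c("nearest", "none")) {
  rounding <- match.arg(rounding)
  stopifnot(n_sampled > 0, n_described > 0)
  if (n_sampled > n_described)
    stop("sampling_fraction: n_sampled exceeds n_described")
  pct <- 100 * n_sampled / n_described
  if (rounding == "nearest") round(pct) else pct
}
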