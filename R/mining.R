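# Candidate-pool construction, representative selection, identity
# verification, and contamination screening.

#' Default configuration for mining and screening
#'
#' All thresholds are exposed because the method's description fixes
#' none of them; defaults are conventional values for curated-locus
#' mining.
#'
#' @param evalue_max maximum e-value for a retained hit.
#' @param pident_min minimum percent identity for a retained hit.
#' @param min_hit_len minimum alignment length (bp) for a retained hit.
#' @param identity_min percent identity at or above which a
#'   cross-family pair flags contamination.
#' @param overlap_min minimum pairwise overlap (bp) for the
#'   contamination screen.
#' @param verify_rank taxonomic rank at which self-search verification
#'   compares: `"species"` (default) or `"genus"`.
#' @param missing_char character used for missing blocks in the
#'   supermatrix (`"-"` or `"?"`).
#' @return named list of validated settings.
#' @export
lh_config <- function(evalue_max = 1e-10, pident_min = 80,
                      min_hit_len = 100, identity_min = 99,
                      overlap_min = 100,
                      verify_rank = c("species", "genus"),
                      missing_char = "-") {
  verify_rank <- match.arg(verify_rank)
  stopifnot(evalue_max >= 0, pident_min >= 0, pident_min <= 100,
            min_hit_len >= 0, identity_min >= 0, identity_min <= 100,
            overlap_min >= 0, missing_char %in% c("-", "?"))
  list(evalue_max = evalue_max, pident_min = pident_min,
       min_hit_len = min_hit_len, identity_min = identity_min,
       overlap_min = overlap_min, verify_rank = verify_rank,
       missing_char = missing_char)
}

#' Filter search hits and assign each subject to one bait locus
#'
#' Retains hits passing the e-value, identity and length thresholds,
#' then assigns every subject sequence to the single bait locus of its
#' best-bitscore retained hit (ties broken toward the lowest locus
#' id); hits on other loci are dropped.
#'
#' @param hits data.frame from [read_hits()].
#' @param config list from [lh_config()].
#' @return the retained hits, each on its subject's assigned locus.
#' @export
filter_hits <- function(hits, config = lh_config()) {
  keep <- hits$evalue <= config$evalue_max &
    hits$pct_identity >= config$pident_min &
    hits$aln_length >= config$min_hit_len
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  # best locus per subject: max bitscore, ties -> lowest locus id
  o <- order(hits$subject_accession, -hits$bitscore, hits$bait_locus,
             method = "radix")
  h <- hits[o, , drop = FALSE]
  best <- h[!duplicated(h$subject_accession),
            c("subject_accession", "bait_locus")]
  key <- paste(hits$subject_accession, hits$bait_locus)
  hits <- hits[key %in% paste(best$subject_accession, best$bait_locus), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# rank order of pool members under the selection key:
# unambiguous bases desc, total length desc, accession asc (C locale)
.rank_members <- function(pool) {
  pool[order(-pool$unambiguous_count, -pool$length_bp, pool$accession,
             method = "radix"), , drop = FALSE]
}

#' Select the representative sequence of a candidate pool
#'
#' When multiple sequences are available for the same locus of a
#' species, the one with the most unambiguous DNA content is chosen;
#' ties fall back to total length, then to the lexicographically
#' smallest accession so the choice is a total deterministic order.
#' The full ranking is retained so a candidate failing downstream
#' verification can be demoted in favour of the next-ranked one.
#'
#' @param pool data.frame of candidate entries with at least
#'   `accession`, `length_bp`, `unambiguous_count`.
#' @return object of class `selection_result`: `chosen` (accession or
#'   `NA`), `rank_key` for the chosen entry, `ranking` (accessions in
#'   rank order), `reason`.
#' @export
select_best <- function(pool) {
  if (is.null(pool) || nrow(pool) == 0L) {
    return(structure(list(chosen = NA_character_, rank_key = NULL,
                          ranking = character(0),
                          reason = "empty pool"),
                     class = "selection_result"))
  }
  r <- .rank_members(pool)
  structure(list(
    chosen = r$accession[1L],
    rank_key = list(unambiguous_count = r$unambiguous_count[1L],
                    length_bp = r$length_bp[1L],
                    accession = r$accession[1L]),
    ranking = r$accession,
    reason = "ranked by (unambiguous_count, length_bp, accession)"
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result: chosen =", x$chosen,
      "of", length(x$ranking), "candidate(s)\n")
  invisible(x)
}

#' Verify a chosen sequence by self-search
#'
#' Mirrors verification against a reference nucleotide collection: the
#' best-bitscore hit of the chosen sequence, excluding the sequence
#' itself, must resolve to the same valid species (or, with
#' `verify_rank = "genus"`, the same genus).  With no non-self hits
#' the check is recorded as skipped, not failed.
#'
#' @param accession the chosen accession.
#' @param valid_name the valid species it is supposed to represent.
#' @param selfsearch_hits data.frame with columns `query_accession`,
#'   `subject_accession`, `subject_organism`, `bitscore`.
#' @param synonymy a `synonymy_table` for resolving subject organisms.
#' @param config list from [lh_config()] (uses `verify_rank`).
#' @return `"pass"`, `"fail"` or `"skipped"`.
#' @export
verify_identity <- function(accession, valid_name, selfsearch_hits,
                            synonymy, config = lh_config()) {
  h <- selfsearch_hits[selfsearch_hits$query_accession == accession &
                         selfsearch_hits$subject_accession != accession, ,
                       drop = FALSE]
  if (nrow(h) == 0L) return("skipped")
  h <- h[order(-h$bitscore, h$subject_accession, method = "radix"), ,
         drop = FALSE]
  top <- resolve_names(h$subject_organism[1L], synonymy)
  if (is.na(top$valid_name)) return("fail")
  if (config$verify_rank == "species") {
    if (normalize_name(top$valid_name) == normalize_name(valid_name))
      "pass" else "fail"
  } else {
    g1 <- strsplit(normalize_name(top$valid_name), " ")[[1L]][1L]
    g2 <- strsplit(normalize_name(valid_name), " ")[[1L]][1L]
    if (identical(g1, g2)) "pass" else "fail"
  }
}

#' Screen entries for cross-family contamination
#'
#' An entry is flagged when a precomputed pairwise-identity row links
#' it, at or above `identity_min` percent identity over at least
#' `overlap_min` bp, to an entry whose species resolves to a different
#' family.  The rule is symmetric: both members of a qualifying pair
#' are flagged.  Same-family pairs are exempt regardless of identity.
#'
#' @param entries snapshot data.frame ([read_snapshot()]).
#' @param identity_table data.frame with columns `acc_a`, `acc_b`,
#'   `pct_identity`, `overlap_bp`.
#' @param synonymy a `synonymy_table` (families come from resolving
#'   each entry's organism name).
#' @param config list from [lh_config()] (uses `identity_min`,
#'   `overlap_min`).
#' @return character vector of flagged accessions (sorted).
#' @export
contamination_screen <- function(entries, identity_table, synonymy,
                                 config = lh_config()) {
  if (is.null(identity_table) || nrow(identity_table) == 0L)
    return(character(0))
  res <- resolve_names(entries$organism_raw, synonymy)
  fam <- stats::setNames(res$family, entries$accession)
  known <- entries$accession
  miss_a <- !(identity_table$acc_a %in% known)
  miss_b <- !(identity_table$acc_b %in% known)
  if (any(miss_a | miss_b)) {
    offender <- unique(c(identity_table$acc_a[miss_a],
                         identity_table$acc_b[miss_b]))
    warning("contamination_screen: skipping row(s) with accession(s) ",
            "absent from snapshot: ", paste(offender, collapse = ", "))
    identity_table <- identity_table[!(miss_a | miss_b), , drop = FALSE]
  }
  fa <- unname(fam[identity_table$acc_a])
  fb <- unname(fam[identity_table$acc_b])
  hit <- !is.na(fa) & !is.na(fb) & fa != fb &
    identity_table$pct_identity >= config$identity_min &
    identity_table$overlap_bp >= config$overlap_min
  sort(unique(c(identity_table$acc_a[hit], identity_table$acc_b[hit])))
}

#' Assemble per-(species, locus) candidate pools
#'
#' Joins resolved snapshot entries with their filtered, locus-assigned
#' hits into one row per (entry, hit).  Entries with unresolved names
#' are excluded and reported, never dropped silently.
#'
#' @param entries snapshot data.frame.
#' @param hits filtered hits ([filter_hits()]).
#' @param synonymy a `synonymy_table`.
#' @return data.frame of pool members keyed by (`valid_name`,
#'   `locus_id`), one row per hit, carrying entry fields and hit
#'   intervals; attribute `"excluded"` is a data.frame of
#'   (`accession`, `reason`) for unresolved entries and entries with
#'   no retained hit.
#' @export
assemble_pools <- function(entries, hits, synonymy) {
  res <- resolve_names(entries$organism_raw, synonymy)
  entries$valid_name <- res$valid_name
  unresolved <- entries$accession[is.na(entries$valid_name)]
  ok <- entries[!is.na(entries$valid_name), , drop = FALSE]
  m <- merge(ok, hits, by.x = "accession", by.y = "subject_accession")
  nohit <- setdiff(ok$accession, m$accession)
  m <- data.frame(
    valid_name = m$valid_name, locus_id = m$bait_locus,
    accession = m$accession, residues = m$residues,
    length_bp = m$length_bp, unambiguous_count = m$unambiguous_count,
    bait_start = m$bait_start, bait_end = m$bait_end,
    subject_start = m$subject_start, subject_end = m$subject_end,
    strand = m$strand, bitscore = m$bitscore
  )
  m <- m[order(m$valid_name, m$locus_id, m$accession, m$bait_start,
               method = "radix"), , drop = FALSE]
  rownames(m) <- NULL
  attr(m, "excluded") <- data.frame(
    accession = c(unresolved, nohit),
    reason = c(rep("unresolved_name", length(unresolved)),
               rep("no_passing_hits", length(nohit)))
  )
  m
}
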