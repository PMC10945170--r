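# Tiling of sequence fragments along a bait locus, and barcode-locus
# grafting between conspecific specimens.
#
# The tiling objective is lexicographic: maximize the number of bait
# positions covered first, then minimize the number of tiles.  On
# intervals this is solved exactly by, per maximal coverable segment,
# greedy farthest-reach interval covering: the union of all tiles
# fixes the attainable coverage, and within each maximal segment of
# that union the greedy cover is a minimum-cardinality cover.

#' Choose the fewest tiles with the highest bait coverage
#'
#' Selects a subset of tiles that covers every coverable bait position
#' (the union of all tiles) with the minimum possible number of tiles.
#' Among equally optimal choices the tie-break is deterministic:
#' prefer the tile reaching farthest, then the tile with the larger
#' individual coverage, then the lexicographically smaller accession.
#' One species may thereby be represented by fragments from multiple
#' specimens when no single sequence spans the bait.
#'
#' @param tiles data.frame with columns `accession`, `start`, `end`
#'   (0-based half-open intervals on the bait); at least one row.
#' @param bait_length optional bait length for bounds checking.
#' @return object of class `tiling_solution`: `chosen` (the selected
#'   rows, in ascending start order), `covered_positions`,
#'   `cardinality`, `per_specimen` (unique accessions used).
#' @examples
#' t <- data.frame(accession = c("a", "b", "c", "d"),
#'                 start = c(0, 39, 0, 69), end = c(60, 100, 30, 100))
#' tile_select(t)  # tiles a and b: coverage 100 with 2 tiles
#' @export
tile_select <- function(tiles, bait_length = NULL) {
  if (is.null(tiles) || nrow(tiles) == 0L)
    stop("tile_select: empty tile set")
  stopifnot(all(c("accession", "start", "end") %in% names(tiles)))
  if (any(tiles$start >= tiles$end))
    stop("tile_select: empty or inverted interval(s)")
  if (any(tiles$start < 0))
    stop("tile_select: negative coordinates")
  if (!is.null(bait_length) && any(tiles$end > bait_length))
    stop("tile_select: interval(s) beyond bait length")

  # maximal segments of the union of all tiles
  o <- order(tiles$start, -tiles$end, method = "radix")
  t_ord <- tiles[o, , drop = FALSE]
  segs <- list()
  cur_s <- t_ord$start[1L]; cur_e <- t_ord$end[1L]
  for (i in seq_len(nrow(t_ord))[-1L]) {
    if (t_ord$start[i] <= cur_e) {
      cur_e <- max(cur_e, t_ord$end[i])
    } else {
      segs[[length(segs) + 1L]] <- c(cur_s, cur_e)
      cur_s <- t_ord$start[i]; cur_e <- t_ord$end[i]
    }
  }
  segs[[length(segs) + 1L]] <- c(cur_s, cur_e)
  covered <- sum(vapply(segs, function(s) s[2L] - s[1L], numeric(1)))

  chosen_idx <- integer(0)
  for (s in segs) {
    cur <- s[1L]
    while (cur < s[2L]) {
      cand <- which(tiles$start <= cur & tiles$end > cur)
      # farthest reach, then larger tile, then smaller accession
      len <- tiles$end[cand] - tiles$start[cand]
      ord <- order(-tiles$end[cand], -len, tiles$accession[cand],
                   method = "radix")
      pick <- cand[ord[1L]]
      chosen_idx <- c(chosen_idx, pick)
      cur <- tiles$end[pick]
    }
  }
  chosen <- tiles[chosen_idx, , drop = FALSE]
  chosen <- chosen[order(chosen$start, chosen$end, chosen$accession,
                         method = "radix"), , drop = FALSE]
  rownames(chosen) <- NULL
  structure(list(chosen = chosen,
                 covered_positions = as.integer(covered),
                 cardinality = nrow(chosen),
                 per_specimen = sort(unique(chosen$accession))),
            class = "tiling_solution")
}

#' @export
print.tiling_solution <- function(x, ...) {
  cat("tiling_solution:", x$cardinality, "tile(s) covering",
      x$covered_positions, "bait position(s) from",
      length(x$per_specimen), "specimen(s)\n")
  invisible(x)
}

#' Stitch chosen tiles into a bait-frame sequence
#'
#' Places each tile's residues at its bait interval; where chosen
#' tiles overlap, the residue comes from the tile whose interval
#' starts first.  Positions covered by no tile receive the missing
#' character.  Conflicting residues at overlaps are counted and
#' reported via the `"conflicts"` attribute.
#'
#' @param solution a `tiling_solution` whose `chosen` rows carry a
#'   `residues` column of bait-frame fragments (each of length
#'   `end - start`).
#' @param bait_length bait length in bp.
#' @param missing_char fill character for uncovered positions.
#' @return character scalar of length `bait_length`, with attribute
#'   `"conflicts"` = number of overlap positions where later tiles
#'   disagreed with the residue kept.
#' @export
stitch_tiles <- function(solution, bait_length, missing_char = "-") {
  stopifnot(inherits(solution, "tiling_solution"))
  ch <- solution$chosen
  stopifnot("residues" %in% names(ch))
  row <- rep(missing_char, bait_length)
  conflicts <- 0L
  for (i in seq_len(nrow(ch))) {
    frag <- strsplit(ch$residues[i], "", fixed = TRUE)[[1L]]
    idx <- seq.int(ch$start[i] + 1L, ch$end[i])
    stopifnot(length(frag) == length(idx))
    open <- row[idx] == missing_char
    conflicts <- conflicts + sum(!open & row[idx] != frag)
    row[idx[open]] <- frag[open]
  }
  out <- paste(row, collapse = "")
  attr(out, "conflicts") <- conflicts
  out
}

#' Graft a barcode locus from a donor specimen onto a recipient
#'
#' Builds a chimeric per-species record set by adding the COI barcode
#' locus from one conspecific sample to another sample that has more
#' loci available but lacks COI.  Only the donor's COI is copied;
#' provenance of every locus is recorded.
#'
#' @param recipient,donor data.frames with columns `valid_name`,
#'   `locus_id`, `accession`, `residues`; each must carry a single
#'   valid species name, and it must be the same species.
#' @param coi_locus integer id of the COI locus (default 1).
#' @return merged record set ordered by locus id, with a `provenance`
#'   column (`"recipient"`/`"donor"`).
#' @export
build_chimera <- function(recipient, donor, coi_locus = 1L) {
  need <- c("valid_name", "locus_id", "accession", "residues")
  stopifnot(all(need %in% names(recipient)), all(need %in% names(donor)))
  sp_r <- unique(recipient$valid_name)
  sp_d <- unique(donor$valid_name)
  if (length(sp_r) != 1L || length(sp_d) != 1L)
    stop("build_chimera: each record set must carry exactly one species")
  if (normalize_name(sp_r) != normalize_name(sp_d))
    stop("build_chimera: different valid species ('", sp_r, "' vs '",
         sp_d, "')")
  if (coi_locus %in% recipient$locus_id)
    stop("build_chimera: recipient already has the COI locus (",
         coi_locus, "); refusing to overwrite")
  d_coi <- donor[donor$locus_id == coi_locus, , drop = FALSE]
  if (nrow(d_coi) == 0L)
    stop("build_chimera: donor lacks the COI locus (", coi_locus, ")")
  out <- rbind(
    cbind(recipient[, need, drop = FALSE], provenance = "recipient"),
    cbind(d_coi[, need, drop = FALSE], provenance = "donor")
  )
  out <- out[order(out$locus_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
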