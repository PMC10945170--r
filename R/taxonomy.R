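# Resolution of published organism names to valid species names via a
# user-supplied synonymy table.  GenBank organism strings carry
# trinomials, authorities and historical combinations; the table plus
# a conservative normalization rule map them onto a single valid
# binomial each.

#' Normalize a published organism name
#'
#' Case-folds, collapses whitespace, drops parenthesized groups and any
#' token containing a 4-digit year (authorities), and truncates to the
#' first two tokens (genus + specific epithet), so trinomials collapse
#' to their species.
#'
#' @param x character vector of names.
#' @return normalized names (lower case binomials).
#' @export
normalize_name <- function(x) {
  x <- tolower(x)
  x <- gsub("\\([^)]*\\)", " ", x)        # parenthesized authorities
  x <- gsub("\\S*[0-9]{4}\\S*", " ", x)   # year tokens
  x <- gsub("[,]", " ", x)
  x <- gsub("\\s+", " ", trimws(x))
  vapply(strsplit(x, " ", fixed = TRUE), function(tok) {
    paste(utils::head(tok, 2L), collapse = " ")
  }, character(1))
}

#' Load a synonymy table
#'
#' Reads a CSV mapping published names to valid species names with
#' family assignment, auto-inserts a self-row for every valid name,
#' and applies transitive closure so that after loading every
#' resolvable name maps to its valid name in a single lookup (chains
#' `A -> B`, `B -> C` collapse to `A -> C`; cycles are an error).
#'
#' @param csv_path CSV with header `published_name,valid_name,family`.
#' @return object of class `synonymy_table`.
#' @export
load_synonymy <- function(csv_path) {
  x <- utils::read.csv(csv_path, colClasses = "character")
  need <- c("published_name", "valid_name", "family")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("load_synonymy: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  synonymy_table(x[, need, drop = FALSE])
}

#' Construct a synonymy table from a data.frame
#'
#' @param df data.frame with columns `published_name`, `valid_name`,
#'   `family`.
#' @return object of class `synonymy_table`.
#' @rdname load_synonymy
#' @export
synonymy_table <- function(df) {
  df <- unique(df[, c("published_name", "valid_name", "family"),
                  drop = FALSE])
  key <- normalize_name(df$published_name)
  dup <- unique(key[duplicated(key)])
  conf <- dup[vapply(dup, function(k)
    length(unique(df$valid_name[key == k])) > 1L, logical(1))]
  if (length(conf))
    stop("synonymy_table: conflicting rows for published name(s): ",
         paste(conf, collapse = ", "))
  df <- df[!duplicated(key), , drop = FALSE]
  key <- key[!duplicated(key)]

  # self-rows for valid names not already present as published names
  vkey <- normalize_name(df$valid_name)
  selfrows <- !(vkey %in% key)
  if (any(selfrows)) {
    add <- unique(data.frame(published_name = df$valid_name[selfrows],
                             valid_name = df$valid_name[selfrows],
                             family = df$family[selfrows]))
    add <- add[!duplicated(normalize_name(add$published_name)), ,
               drop = FALSE]
    df <- rbind(df, add)
    key <- c(key, normalize_name(add$published_name))
  }

  # transitive closure with cycle detection
  map <- stats::setNames(df$valid_name, key)
  fam <- stats::setNames(df$family, key)
  n <- length(map)
  for (i in seq_len(n)) {
    seen <- character(0)
    k <- key[i]
    repeat {
      v <- unname(map[[k]])
      vk <- normalize_name(v)
      if (vk == k || !(vk %in% key)) break
      if (vk %in% seen)
        stop("synonymy_table: cycle involving: ",
             paste(c(seen, vk), collapse = " -> "))
      seen <- c(seen, k)
      k <- vk
    }
    map[[key[i]]] <- unname(map[[k]])
    fam[[key[i]]] <- unname(fam[[k]])
  }

  structure(list(map = map, family = fam,
                 exact = stats::setNames(unname(map),
                                         df$published_name)),
            class = "synonymy_table")
}

#' @export
print.synonymy_table <- function(x, ...) {
  cat("synonymy_table:", length(x$map), "published names ->",
      length(unique(x$map)), "valid species,",
      length(unique(x$family)), "families\n")
  invisible(x)
}

#' Resolve published organism names to valid species
#'
#' Exact match against the table's published names is tried first,
#' then a normalized match (case-fold, drop subspecific epithets and
#' authority tokens).  Unresolved is a value, not an error: such names
#' are quarantined by callers into reports rather than dropped
#' silently.  Resolution is idempotent: a valid name resolves to
#' itself.
#'
#' @param organism_raw character vector of published names.
#' @param table a `synonymy_table`.
#' @return data.frame with `organism_raw`, `valid_name` (`NA` when
#'   unresolved), `family`, `match_kind`
#'   (`"exact"`/`"normalized"`/`"unresolved"`).
#' @export
resolve_names <- function(organism_raw, table) {
  stopifnot(inherits(table, "synonymy_table"))
  valid <- unname(table$exact[organism_raw])
  kind <- ifelse(is.na(valid), NA_character_, "exact")
  todo <- is.na(valid)
  if (any(todo)) {
    key <- normalize_name(organism_raw[todo])
    hit <- unname(table$map[key])
    valid[todo] <- hit
    kind[todo] <- ifelse(is.na(hit), "unresolved", "normalized")
    fam_key <- key
  }
  fam <- unname(table$family[normalize_name(ifelse(is.na(valid),
                                                   organism_raw, valid))])
  data.frame(organism_raw = organism_raw, valid_name = valid,
             family = ifelse(is.na(valid), NA_character_, fam),
             match_kind = kind)
}

#' @rdname resolve_names
#' @export
resolve_name <- function(organism_raw, table) {
  resolve_names(organism_raw[1L], table)
}

# family of a valid species name (NA if unknown)
.family_of <- function(valid_name, table) {
  unname(table$family[normalize_name(valid_name)])
}
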