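#' Table dialect for expression input
#'
#' Describes how a tissue-resolved expression table is laid out: the field
#' separator and the names of the gene-ID and per-tissue signal columns.
#' The default matches a TSV with header \code{gene FUN CSC DSC}.
#'
#' @param sep field separator (default tab).
#' @param gene,fun,csc,dsc column names for the locus ID and the raw
#'   funiculus, chalazal-seed-coat and distal-seed-coat signals.
#' @return a list of class \code{"expression_dialect"}.
#' @export
expression_dialect <- function(sep = "\t", gene = "gene", fun = "FUN",
                               csc = "CSC", dsc = "DSC") {
  structure(list(sep = sep, gene = gene, fun = fun, csc = csc, dsc = dsc),
            class = "expression_dialect")
}

#' Read a tissue-resolved expression table
#'
#' Reads one row per gene with raw microarray signals in the funiculus (FUN),
#' chalazal seed coat (CSC) and distal seed coat (DSC).  Gene IDs are
#' canonicalized (see [canonicalize_gene_id()]); signals must be numeric and
#' non-negative; duplicate loci are an error.  The area-normalized DSC column
#' (\code{dsc_norm}) is left unset -- apply [normalize_dsc()] afterwards.
#'
#' @param path path to a delimited text file.
#' @param dialect an [expression_dialect()] describing the layout.
#' @return a data frame of class \code{"expression_profiles"} with columns
#'   \code{gene_id}, \code{fun}, \code{csc}, \code{dsc_raw}, \code{dsc_norm}
#'   (all \code{NA} until normalized).
#' @export
load_expression_table <- function(path, dialect = expression_dialect()) {
  stopifnot(inherits(dialect, "expression_dialect"))
  if (!file.exists(path)) stop("expression table not found: ", path)
  raw <- utils::read.table(path, sep = dialect$sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  needed <- c(dialect$gene, dialect$fun, dialect$csc, dialect$dsc)
  missing <- setdiff(needed, names(raw))
  if (length(missing))
    stop("expression table is missing required column(s): ",
         paste(missing, collapse = ", "))

  parse_signal <- function(col) {
    txt <- raw[[col]]
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(val))
    if (length(bad))
      stop("non-numeric ", col, " signal at data row ",
           paste(bad, collapse = ", "), " (value ",
           paste(sQuote(txt[bad]), collapse = ", "), ")")
    if (any(val < 0))
      stop("negative ", col, " signal at data row ",
           paste(which(val < 0), collapse = ", "))
    val
  }

  gene_id <- canonicalize_gene_id(raw[[dialect$gene]])
  bad_id <- which(is.na(gene_id))
  if (length(bad_id))
    stop("unparseable gene ID at data row ", paste(bad_id, collapse = ", "),
         ": ", paste(sQuote(raw[[dialect$gene]][bad_id]), collapse = ", "))
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup))
    stop("duplicate gene ID(s) after canonicalization: ",
         paste(dup, collapse = ", "))

  out <- data.frame(
    gene_id = gene_id,
    fun = parse_signal(dialect$fun),
    csc = parse_signal(dialect$csc),
    dsc_raw = parse_signal(dialect$dsc),
    dsc_norm = NA_real_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("expression_profiles", "data.frame")
  out
}

#' Construct expression profiles from vectors (mainly for tests/simulation)
#' @param gene_id,fun,csc,dsc_raw parallel vectors.
#' @param dsc_norm optional normalized DSC signal.
#' @return an \code{"expression_profiles"} data frame.
#' @export
expression_profiles <- function(gene_id, fun, csc, dsc_raw,
                                dsc_norm = NA_real_) {
  gene_id <- canonicalize_gene_id(gene_id)
  if (anyNA(gene_id)) stop("unparseable gene ID")
  if (anyDuplicated(gene_id)) stop("duplicate gene ID")
  if (any(c(fun, csc, dsc_raw) < 0)) stop("signals must be non-negative")
  out <- data.frame(gene_id = gene_id, fun = as.numeric(fun),
                    csc = as.numeric(csc), dsc_raw = as.numeric(dsc_raw),
                    dsc_norm = as.numeric(dsc_norm),
                    stringsAsFactors = FALSE)
  class(out) <- c("expression_profiles", "data.frame")
  out
}

#' Write an expression table back to disk
#'
#' Inverse of [load_expression_table()]: writes the raw signal columns under
#' the dialect's column names so that a load/write cycle round-trips.
#'
#' @param profiles an \code{"expression_profiles"} data frame.
#' @param path output path.
#' @param dialect an [expression_dialect()].
#' @export
write_expression_table <- function(profiles, path,
                                   dialect = expression_dialect()) {
  out <- data.frame(profiles$gene_id,
                    format_signal(profiles$fun),
                    format_signal(profiles$csc),
                    format_signal(profiles$dsc_raw),
                    stringsAsFactors = FALSE)
  names(out) <- c(dialect$gene, dialect$fun, dialect$csc, dialect$dsc)
  write_tsv(out, path, sep = dialect$sep)
  invisible(path)
}

#' Read a hormone-regulon gene list
#'
#' One gene ID per line (or the first column of a delimited table); blank
#' lines and \code{#} comments are ignored.  IDs are canonicalized and
#' de-duplicated; unparseable lines are skipped with a warning; an empty file
#' yields an empty regulon with a warning.
#'
#' @param path path to the gene list.
#' @param hormone one of \code{"auxin"}, \code{"ABA"}, \code{"brassinosteroid"}.
#' @param direction \code{"up"} or \code{"down"}.
#' @return a list of class \code{"regulon"} with fields \code{hormone},
#'   \code{direction}, \code{genes} (sorted character vector), \code{source}.
#' @export
load_regulon <- function(path,
                         hormone = c("auxin", "ABA", "brassinosteroid"),
                         direction = c("up", "down")) {
  hormone <- match.arg(hormone)
  direction <- match.arg(direction)
  if (!file.exists(path)) stop("regulon file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  # keep only the first whitespace/tab-delimited token of each line
  lines <- sub("[\t ,].*$", "", lines)
  lines <- lines[nzchar(lines)]
  ids <- canonicalize_gene_id(lines)
  bad <- is.na(ids)
  if (any(bad))
    warning("skipped ", sum(bad), " unparseable regulon line(s) in ",
            basename(path), ": ",
            paste(utils::head(lines[bad], 5), collapse = ", "))
  genes <- sort(unique(ids[!bad]))
  if (!length(genes)) warning("regulon file ", basename(path), " is empty")
  regulon(genes, hormone, direction, source = basename(path))
}

#' Construct a regulon in memory
#' @param genes character vector of locus IDs (canonicalized, de-duplicated).
#' @param hormone,direction regulon identity.
#' @param source free-text provenance tag used as edge evidence downstream.
#' @return a \code{"regulon"} list.
#' @export
regulon <- function(genes, hormone = c("auxin", "ABA", "brassinosteroid"),
                    direction = c("up", "down"), source = "in-memory") {
  hormone <- match.arg(hormone)
  direction <- match.arg(direction)
  genes <- canonicalize_gene_id(genes)
  if (anyNA(genes)) stop("unparseable gene ID in regulon")
  structure(list(hormone = hormone, direction = direction,
                 genes = sort(unique(genes)), source = source),
            class = "regulon")
}

#' Enforce up/down disjointness within a hormone
#'
#' A gene listed as both up- and downregulated by the same hormone is
#' uninformative; such conflicts are reported and the offending genes dropped
#' from both sets.
#'
#' @param up,down \code{"regulon"} objects for the same hormone.
#' @return list with elements \code{up}, \code{down} (conflict-free regulons)
#'   and \code{conflicts} (character vector of dropped genes).
#' @export
reconcile_regulons <- function(up, down) {
  stopifnot(inherits(up, "regulon"), inherits(down, "regulon"),
            up$hormone == down$hormone,
            up$direction == "up", down$direction == "down")
  conflicts <- intersect(up$genes, down$genes)
  if (length(conflicts))
    warning(up$hormone, " regulon conflict: ",
            paste(conflicts, collapse = ", "),
            " present in both directions; dropped from both")
  up$genes <- setdiff(up$genes, conflicts)
  down$genes <- setdiff(down$genes, conflicts)
  list(up = up, down = down, conflicts = conflicts)
}

#' Read a paired germination-assay table
#'
#' Expects columns \code{genotype}, \code{dish_id}, \code{germinated},
#' \code{total}, \code{paired_control_dish}.  Control dishes leave
#' \code{paired_control_dish} empty; every mutant dish must reference exactly
#' one existing control dish.
#'
#' @param path path to a TSV file.
#' @return data frame of class \code{"germination_assays"}.
#' @export
load_germination_table <- function(path) {
  if (!file.exists(path)) stop("germination table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  needed <- c("genotype", "dish_id", "germinated", "total",
              "paired_control_dish")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("germination table is missing column(s): ",
         paste(missing, collapse = ", "))
  tab$germinated <- suppressWarnings(as.integer(tab$germinated))
  tab$total <- suppressWarnings(as.integer(tab$total))
  if (anyNA(tab$germinated) || anyNA(tab$total))
    stop("non-integer germinated/total count in germination table")
  validate_germination(tab)
}

validate_germination <- function(tab) {
  if (any(tab$total <= 0L)) stop("total seeds per dish must be positive")
  if (any(tab$germinated < 0L)) stop("germinated counts must be non-negative")
  over <- tab$germinated > tab$total
  if (any(over))
    stop("germinated > total for dish(es): ",
         paste(tab$dish_id[over], collapse = ", "))
  if (anyDuplicated(tab$dish_id))
    stop("duplicate dish_id: ",
         paste(unique(tab$dish_id[duplicated(tab$dish_id)]), collapse = ", "))
  is_mut <- nzchar(tab$paired_control_dish)
  ref <- tab$paired_control_dish[is_mut]
  unmatched <- setdiff(ref, tab$dish_id[!is_mut])
  if (length(unmatched))
    stop("paired_control_dish references nonexistent control dish(es): ",
         paste(unmatched, collapse = ", "))
  if (anyDuplicated(ref))
    stop("control dish paired with more than one mutant dish: ",
         paste(unique(ref[duplicated(ref)]), collapse = ", "))
  class(tab) <- c("germination_assays", "data.frame")
  tab
}

# -- small shared writers ----------------------------------------------------

#' @keywords internal
format_signal <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 6))
}

#' Write a data frame as TSV with stable column order and no quoting
#' @keywords internal
write_tsv <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     eol = "\n")
  invisible(path)
}
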