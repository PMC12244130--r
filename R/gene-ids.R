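#' Canonicalize Arabidopsis locus identifiers
#'
#' Locus IDs such as \code{"AT2G28470"}, \code{"at2g28470"} and
#' \code{"At2g28470"} all denote the same gene; published tables mix the
#' casings freely.  The canonical form used throughout this package is
#' \code{"At"} + chromosome (a digit, or \code{C}/\code{M} for the organellar
#' genomes) + \code{"g"} + five digits, e.g. \code{"At2g28470"}.
#'
#' @param ids character vector of putative locus identifiers.
#' @return character vector of the same length; entries that do not match the
#'   locus pattern are returned as \code{NA}.
#' @examples
#' canonicalize_gene_id(c("AT2G28470", "at4g30080", "not-a-locus"))
#' @export
canonicalize_gene_id <- function(ids) {
  ids <- trimws(as.character(ids))
  m <- regexec("^[Aa][Tt]([0-9CcMm])[Gg]([0-9]{5})$", ids)
  parts <- regmatches(ids, m)
  vapply(parts, function(p) {
    if (length(p) != 3L) return(NA_character_)
    paste0("At", toupper(p[2L]), "g", p[3L])
  }, character(1))
}

#' Test whether identifiers are already in canonical locus form
#' @param ids character vector.
#' @return logical vector.
#' @keywords internal
is_canonical_gene_id <- function(ids) {
  !is.na(ids) & ids == canonicalize_gene_id(ids)
}
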