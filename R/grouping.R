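#' Default mapping from (auxin response, FUN->CSC gradient) to group IDs
#'
#' G1 (auxin-down, up-gradient) and G4 (auxin-up, up-gradient) are fixed by
#' the seed-germination gene tables; the two down-gradient combinations are
#' assigned G2 = (down, down) and G3 = (up, down).
#'
#' @return data frame with columns \code{group_id}, \code{auxin_response},
#'   \code{gradient}.
#' @export
default_group_map <- function() {
  data.frame(group_id = c("G1", "G2", "G3", "G4"),
             auxin_response = c("down", "down", "up", "up"),
             gradient = c("up", "down", "down", "up"),
             stringsAsFactors = FALSE)
}

#' Standard TAIR loci of the six auxin co-receptor F-box genes
#' @return named character vector (names TIR1, AFB1..AFB5).
#' @export
afb_loci <- function() {
  c(TIR1 = "At3g62980", AFB1 = "At4g03190", AFB2 = "At3g26810",
    AFB3 = "At1g12820", AFB4 = "At4g24390", AFB5 = "At5g49980")
}

#' Classify a gene's FUN-to-CSC expression gradient
#'
#' Returns \code{"down"} when the funiculus signal exceeds the chalazal
#' seed-coat signal by more than \code{tie_epsilon * max(fun, csc)},
#' \code{"up"} for the reverse, and \code{"flat"} otherwise.  With the
#' default \code{tie_epsilon = 0} any strict inequality defines a gradient.
#' The DSC signal is never consulted.
#'
#' @param fun,csc raw signal vectors (recycled to common length).
#' @param tie_epsilon non-negative relative tolerance for calling a tie.
#' @return character vector in \code{c("down", "up", "flat")}.
#' @export
classify_gradient <- function(fun, csc, tie_epsilon = 0) {
  stopifnot(tie_epsilon >= 0)
  band <- tie_epsilon * pmax(fun, csc)
  ifelse(fun - csc > band, "down", ifelse(csc - fun > band, "up", "flat"))
}

#' Assign auxin-regulated genes to the four gradient groups
#'
#' Intersects filter-surviving expression profiles with the auxin up/down
#' regulons and partitions the auxin-regulated genes by (response direction,
#' FUN->CSC gradient).  Genes in neither regulon, in both regulons, or with a
#' flat gradient go to the excluded report with a reason.
#'
#' @param profiles normalized, low-signal-filtered
#'   \code{"expression_profiles"}.
#' @param auxin_up,auxin_down auxin [regulon()] objects.
#' @param tie_epsilon passed to [classify_gradient()].
#' @param group_map see [default_group_map()].
#' @return a list of class \code{"gradient_grouping"} with elements
#'   \code{groups} (named list of four \code{"gradient_group"} objects, gene
#'   lists sorted lexicographically) and \code{excluded} (data frame
#'   \code{gene_id}, \code{reason}).
#' @export
assign_groups <- function(profiles, auxin_up, auxin_down, tie_epsilon = 0,
                          group_map = default_group_map()) {
  stopifnot(inherits(auxin_up, "regulon"), inherits(auxin_down, "regulon"),
            auxin_up$direction == "up", auxin_down$direction == "down")
  key <- paste(group_map$auxin_response, group_map$gradient)
  if (anyDuplicated(key) || nrow(group_map) != 4L)
    stop("group_map must cover the four (response, gradient) combinations")

  ord <- order(profiles$gene_id)
  profiles <- profiles[ord, , drop = FALSE]
  in_up <- profiles$gene_id %in% auxin_up$genes
  in_down <- profiles$gene_id %in% auxin_down$genes
  gradient <- classify_gradient(profiles$fun, profiles$csc, tie_epsilon)

  reason <- rep(NA_character_, nrow(profiles))
  reason[!in_up & !in_down] <- "no regulon membership"
  reason[in_up & in_down] <- "conflicting regulon"
  reason[is.na(reason) & gradient == "flat"] <- "flat gradient"
  excluded <- data.frame(gene_id = profiles$gene_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)

  keep <- is.na(reason)
  response <- ifelse(in_up, "up", "down")
  groups <- lapply(seq_len(nrow(group_map)), function(i) {
    sel <- keep & response == group_map$auxin_response[i] &
      gradient == group_map$gradient[i]
    structure(list(group_id = group_map$group_id[i],
                   auxin_response = group_map$auxin_response[i],
                   gradient = group_map$gradient[i],
                   genes = profiles$gene_id[sel]),
              class = "gradient_group")
  })
  names(groups) <- group_map$group_id
  structure(list(groups = groups, excluded = excluded),
            class = "gradient_grouping")
}

#' Partition the six AFB loci into the two expression-gradient groups
#'
#' AFBs with a FUN->CSC down-gradient form the AFB1 group and those with an
#' up-gradient the AFB5 group.  If every AFB has an unambiguous gradient the
#' partition is data-derived; if any AFB is flat the canonical partition
#' (TIR1/AFB1/AFB4 vs AFB2/AFB3/AFB5) is used with a warning.
#'
#' @param profiles \code{"expression_profiles"} containing all six AFB loci.
#' @param tie_epsilon passed to [classify_gradient()].
#' @param loci named locus map, see [afb_loci()].
#' @return a list of class \code{"afb_groups"} with fields \code{afb1_group},
#'   \code{afb5_group} (character vectors of AFB names) and
#'   \code{derived_from_data} (logical).
#' @export
assign_afb_groups <- function(profiles, tie_epsilon = 0, loci = afb_loci()) {
  idx <- match(loci, profiles$gene_id)
  if (anyNA(idx))
    stop("missing locus ", paste(names(loci)[is.na(idx)], collapse = ", "))
  grad <- classify_gradient(profiles$fun[idx], profiles$csc[idx], tie_epsilon)
  names(grad) <- names(loci)
  if (any(grad == "flat")) {
    warning("flat FUN->CSC gradient for ",
            paste(names(grad)[grad == "flat"], collapse = ", "),
            "; falling back to the canonical AFB partition")
    return(structure(list(afb1_group = c("TIR1", "AFB1", "AFB4"),
                          afb5_group = c("AFB2", "AFB3", "AFB5"),
                          derived_from_data = FALSE),
                     class = "afb_groups"))
  }
  structure(list(afb1_group = names(grad)[grad == "down"],
                 afb5_group = names(grad)[grad == "up"],
                 derived_from_data = TRUE),
            class = "afb_groups")
}

#' Flatten a gradient grouping to the groups.tsv layout
#'
#' @param grouping result of [assign_groups()].
#' @param profiles the same profiles that were grouped (for signal columns).
#' @return data frame with columns \code{gene_id}, \code{group_id},
#'   \code{auxin_response}, \code{gradient}, \code{fun}, \code{csc},
#'   \code{dsc_norm}, sorted by group then gene.
#' @export
grouping_table <- function(grouping, profiles) {
  stopifnot(inherits(grouping, "gradient_grouping"))
  rows <- lapply(grouping$groups, function(g) {
    if (!length(g$genes)) return(NULL)
    data.frame(gene_id = g$genes, group_id = g$group_id,
               auxin_response = g$auxin_response, gradient = g$gradient,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(gene_id = character(), group_id = character(),
                      auxin_response = character(), gradient = character(),
                      stringsAsFactors = FALSE)
  i <- match(tab$gene_id, profiles$gene_id)
  tab$fun <- profiles$fun[i]
  tab$csc <- profiles$csc[i]
  tab$dsc_norm <- profiles$dsc_norm[i]
  tab[order(tab$group_id, tab$gene_id), , drop = FALSE]
}
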