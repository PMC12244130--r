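#' Build the gene-by-tissue profile matrix used for correlation analysis
#'
#' Each gene's three-point profile is the ordered triple
#' (FUN, CSC, area-normalized DSC).  Profiles require [normalize_dsc()] to
#' have been applied.
#'
#' @param profiles an \code{"expression_profiles"} data frame with
#'   \code{dsc_norm} set.
#' @return numeric matrix, one row per gene (rownames = gene IDs), columns
#'   \code{fun}, \code{csc}, \code{dsc_norm}.
#' @export
profile_matrix <- function(profiles) {
  if (anyNA(profiles$dsc_norm))
    stop("dsc_norm unset; call normalize_dsc() first")
  m <- cbind(fun = profiles$fun, csc = profiles$csc,
             dsc_norm = profiles$dsc_norm)
  rownames(m) <- profiles$gene_id
  m
}

#' Squared Pearson correlation of two three-point profiles
#'
#' The subgroup criterion of this pipeline: R-squared of the ordered tissue
#' triples, identical to the coefficient of determination of a simple linear
#' regression with intercept (the spreadsheet trendline default).  A triple
#' with zero variance has no defined correlation; such profiles are flagged
#' with \code{NA} (not coerced to 0) and must be excluded from subgrouping.
#'
#' @param a,b numeric vectors of length 3 (or any equal length).
#' @return squared Pearson correlation in \code{[0, 1]}, or \code{NA} if
#'   either profile is degenerate (zero variance).
#' @export
pairwise_r2 <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' All-pairs R-squared matrix for a set of profiles
#'
#' @param mat profile matrix (genes x tissues), see [profile_matrix()].
#' @return symmetric matrix of squared Pearson correlations, unit diagonal;
#'   rows/columns for degenerate (zero-variance) profiles are \code{NA}.
#' @export
r2_matrix <- function(mat) {
  sds <- apply(mat, 1L, stats::sd)
  r <- suppressWarnings(stats::cor(t(mat)))
  r2 <- r^2
  r2[sds == 0, ] <- NA_real_
  r2[, sds == 0] <- NA_real_
  diag(r2) <- ifelse(sds == 0, NA_real_, 1)
  r2
}

#' Pearson slope sign between two profiles
#' @keywords internal
pair_slope_sign <- function(a, b) sign(stats::cov(a, b))

#' Partition a gradient group into co-expression subgroups
#'
#' Deterministic greedy agglomeration under the all-pairs R-squared
#' criterion: seed a new subgroup with the lexicographically smallest
#' unassigned gene; repeatedly admit the unassigned gene with the highest
#' linkage score, provided that score is at least \code{r2_min} (ties broken
#' by smallest gene ID); close the subgroup when no gene qualifies.  With
#' \code{linkage = "complete"} the score is the minimum R-squared to all
#' current members (every emitted subgroup then satisfies the all-pairs
#' constraint); with \code{linkage = "reference"} it is the R-squared to the
#' seed gene only.  The published analysis assigned subgroups manually; this
#' algorithm is the package's deterministic formalization of that procedure.
#'
#' @param genes character vector of member gene IDs (a gradient group).
#' @param mat profile matrix covering at least these genes.
#' @param r2_min minimum pairwise R-squared within a subgroup (default 0.90).
#' @param linkage \code{"complete"} (all-pairs, default) or
#'   \code{"reference"} (against the seed gene).
#' @param sign_constraint \code{"any"} (default; R-squared alone, matching
#'   the published criterion) or \code{"positive_slope_only"} (additionally
#'   require a positive correlation with every current member).
#' @param parent_group label used to build subgroup IDs (e.g. \code{"G1"} ->
#'   \code{"G1A"}, \code{"G1B"}, ...).  Letters are ordered by decreasing
#'   subgroup size, ties broken by smallest member ID.
#' @return list of class \code{"subgroup_set"}: each element a
#'   \code{"subgroup"} with fields \code{subgroup_id}, \code{parent_group},
#'   \code{members} (sorted), \code{min_pairwise_r2}; plus an attribute
#'   \code{degenerate} listing zero-variance genes excluded from clustering.
#' @export
cluster_subgroups <- function(genes, mat, r2_min = 0.90,
                              linkage = c("complete", "reference"),
                              sign_constraint = c("any", "positive_slope_only"),
                              parent_group = "G") {
  linkage <- match.arg(linkage)
  sign_constraint <- match.arg(sign_constraint)
  if (!is.numeric(r2_min) || length(r2_min) != 1L || is.na(r2_min) ||
      r2_min < 0 || r2_min > 1)
    stop("r2_min must lie in [0, 1]")
  missing <- setdiff(genes, rownames(mat))
  if (length(missing))
    stop("no profile for gene(s): ", paste(missing, collapse = ", "))

  genes <- sort(genes)
  sub <- mat[genes, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  degenerate <- genes[sds == 0]
  genes <- genes[sds != 0]

  r2 <- if (length(genes)) r2_matrix(mat[genes, , drop = FALSE]) else
    matrix(numeric(), 0, 0)
  rsign <- if (length(genes))
    sign(suppressWarnings(stats::cor(t(mat[genes, , drop = FALSE])))) else
    matrix(numeric(), 0, 0)

  unassigned <- genes
  members_list <- list()
  while (length(unassigned)) {
    seed <- unassigned[1L]
    current <- seed
    unassigned <- unassigned[-1L]
    repeat {
      if (!length(unassigned)) break
      score <- vapply(unassigned, function(g) {
        ref <- if (linkage == "complete") current else seed
        s <- min(r2[g, ref])
        if (sign_constraint == "positive_slope_only" &&
            any(rsign[g, current] <= 0)) s <- -1
        s
      }, numeric(1))
      ok <- score >= r2_min
      if (!any(ok)) break
      # highest score wins; ties by smallest gene ID (unassigned is sorted)
      pick <- unassigned[ok][which.max(score[ok])]
      current <- c(current, pick)
      unassigned <- setdiff(unassigned, pick)
    }
    members_list[[length(members_list) + 1L]] <- sort(current)
  }

  # label by decreasing size, ties by smallest member ID
  if (length(members_list)) {
    sizes <- lengths(members_list)
    first <- vapply(members_list, `[`, character(1), 1L)
    ord <- order(-sizes, first)
    members_list <- members_list[ord]
  }
  subgroups <- lapply(seq_along(members_list), function(i) {
    mem <- members_list[[i]]
    minr2 <- if (length(mem) > 1L)
      min(r2[mem, mem][upper.tri(r2[mem, mem])]) else 1
    structure(list(subgroup_id = paste0(parent_group, LETTERS[i]),
                   parent_group = parent_group,
                   members = mem,
                   min_pairwise_r2 = minr2),
              class = "subgroup")
  })
  structure(subgroups, class = "subgroup_set", degenerate = degenerate)
}

#' Leave-one-out group-sum correlation
#'
#' The subgroup-validation statistic: the elementwise sum of every member's
#' three-point profile except one is correlated against the excluded
#' member's profile.  For genuinely co-expressed (mutually proportional)
#' genes this R-squared stays near 1.
#'
#' @param members character vector of subgroup member gene IDs.
#' @param mat profile matrix.
#' @param excluded_gene the member to leave out.
#' @return squared Pearson correlation.
#' @export
loo_group_sum_r2 <- function(members, mat, excluded_gene) {
  if (!excluded_gene %in% members)
    stop("excluded gene ", excluded_gene, " is not a subgroup member")
  if (length(members) < 2L)
    stop("leave-one-out sum undefined for a singleton subgroup")
  rest <- setdiff(members, excluded_gene)
  pairwise_r2(colSums(mat[rest, , drop = FALSE]), mat[excluded_gene, ])
}

#' Correlation between two subgroups' leave-one-out sum profiles
#'
#' @param members_a,members_b member gene IDs of the two subgroups.
#' @param mat profile matrix.
#' @param excluded_a,excluded_b the member left out of each sum.
#' @return squared Pearson correlation between the two sum profiles.
#' @export
between_subgroup_r2 <- function(members_a, members_b, mat,
                                excluded_a, excluded_b) {
  for (chk in list(list(members_a, excluded_a), list(members_b, excluded_b))) {
    if (!chk[[2]] %in% chk[[1]])
      stop("excluded gene ", chk[[2]], " is not a subgroup member")
    if (length(chk[[1]]) < 2L)
      stop("leave-one-out sum undefined for a singleton subgroup")
  }
  sum_a <- colSums(mat[setdiff(members_a, excluded_a), , drop = FALSE])
  sum_b <- colSums(mat[setdiff(members_b, excluded_b), , drop = FALSE])
  pairwise_r2(sum_a, sum_b)
}

#' Flatten a subgroup set to the subgroups.tsv layout
#' @param subgroups a \code{"subgroup_set"}.
#' @return data frame \code{gene_id}, \code{subgroup_id},
#'   \code{min_pairwise_r2}.
#' @export
subgroup_table <- function(subgroups) {
  rows <- lapply(subgroups, function(s) {
    data.frame(gene_id = s$members, subgroup_id = s$subgroup_id,
               min_pairwise_r2 = s$min_pairwise_r2,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(gene_id = character(), subgroup_id = character(),
                      min_pairwise_r2 = numeric(), stringsAsFactors = FALSE)
  tab[order(tab$subgroup_id, tab$gene_id), , drop = FALSE]
}
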