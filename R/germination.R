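#' Per-dish germination frequency
#'
#' @param germinated,total seed counts (vectors recycled to common length).
#' @return germinated / total, in \code{[0, 1]}.
#' @export
germination_frequency <- function(germinated, total) {
  if (any(total <= 0)) stop("total seeds must be positive")
  if (any(germinated < 0) || any(germinated > total))
    stop("germinated counts must lie in [0, total]")
  germinated / total
}

#' Paired two-tailed t-test on germination frequencies
#'
#' Classical paired t statistic on the per-dish differences
#' d = mutant - wild type: t = mean(d) / (sd(d) / sqrt(n)), compared to a
#' t distribution with n - 1 degrees of freedom.  Degenerate inputs are
#' handled explicitly: all-zero differences give t = 0, p = 1; zero variance
#' with nonzero mean gives an infinite t (flagged) and p = 0.
#'
#' @param mut_freqs,wt_freqs equal-length numeric vectors (length >= 2) of
#'   paired per-dish frequencies; element i of each vector is one
#'   mutant/control dish pair.
#' @param genotype optional label carried into the result.
#' @return list of class \code{"paired_result"}: \code{genotype},
#'   \code{n_pairs}, \code{mean_mut}, \code{mean_wt}, \code{t_stat},
#'   \code{p_value}, \code{direction} ("higher"/"lower"), \code{degenerate}.
#' @export
paired_t_test <- function(mut_freqs, wt_freqs, genotype = NA_character_) {
  if (length(mut_freqs) != length(wt_freqs))
    stop("mutant and wild-type frequency lists differ in length")
  n <- length(mut_freqs)
  if (n < 2L) stop("paired t-test needs at least 2 pairs")
  d <- mut_freqs - wt_freqs
  md <- mean(d)
  sdd <- stats::sd(d)
  degenerate <- FALSE
  if (sdd == 0) {
    if (md == 0) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(md) * Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    t_stat <- md / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1L)
  }
  structure(list(genotype = genotype, n_pairs = n,
                 mean_mut = mean(mut_freqs), mean_wt = mean(wt_freqs),
                 t_stat = t_stat, p_value = p,
                 direction = if (md >= 0) "higher" else "lower",
                 degenerate = degenerate),
            class = "paired_result")
}

#' Score a germination-assay table genotype by genotype
#'
#' Uses the explicit dish pairing (each mutant dish against its
#' \code{paired_control_dish}) to assemble the paired frequency lists, then
#' runs [paired_t_test()] per mutant genotype.  No multiple-testing
#' correction is applied by default, matching the published analysis; set
#' \code{bonferroni = TRUE} to multiply p-values by the number of genotypes
#' (capped at 1).
#'
#' @param assays a \code{"germination_assays"} table
#'   (see [load_germination_table()]).
#' @param bonferroni logical; apply a Bonferroni correction across genotypes.
#' @return data frame, one row per mutant genotype, with the
#'   \code{"paired_result"} fields.
#' @export
germination_results <- function(assays, bonferroni = FALSE) {
  is_mut <- nzchar(assays$paired_control_dish)
  mut <- assays[is_mut, , drop = FALSE]
  if (!nrow(mut)) stop("no mutant dishes (empty paired_control_dish only)")
  ctrl_idx <- match(mut$paired_control_dish, assays$dish_id)
  mut$mut_freq <- germination_frequency(mut$germinated, mut$total)
  mut$wt_freq <- germination_frequency(assays$germinated[ctrl_idx],
                                       assays$total[ctrl_idx])
  genotypes <- sort(unique(mut$genotype))
  rows <- lapply(genotypes, function(g) {
    sel <- mut$genotype == g
    res <- paired_t_test(mut$mut_freq[sel], mut$wt_freq[sel], genotype = g)
    data.frame(genotype = g, n_pairs = res$n_pairs,
               mean_mut = res$mean_mut, mean_wt = res$mean_wt,
               t_stat = res$t_stat, p_value = res$p_value,
               direction = res$direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni) out$p_value <- pmin(1, out$p_value * nrow(out))
  out
}
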