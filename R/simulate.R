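#' Simulation configuration for planted co-expression benchmarks
#'
#' The generator emulates the statistical structure of a three-tissue
#' microarray compendium: genes within a planted subgroup are scalar
#' multiples of a shared three-point base profile under multiplicative
#' log-normal noise; background genes draw their three signals
#' independently; a fraction of genes is planted below the low-signal
#' filter.  Defaults mirror the published dataset's shape: roughly 118
#' auxin-regulated structured genes split over 12 subgroups, with
#' unstructured background around them.
#'
#' @param n_subgroups number of planted subgroups (>= 1).
#' @param genes_per_subgroup genes per planted subgroup (>= 1).
#' @param base_profiles \code{"random"} (default; rejection-sampled so all
#'   pairwise base R-squared <= \code{base_r2_max}) or a list of 3-vectors.
#' @param base_r2_max collinearity bound for random base profiles.
#' @param scale_range range of the per-gene proportionality constants.
#' @param noise_cv coefficient of variation of the per-signal multiplicative
#'   log-normal noise (0 = exact proportionality).
#' @param frac_auxin_up,frac_auxin_down fractions of subgroups labelled
#'   auxin-up / auxin-down (sum <= 1; the remainder gets no regulon label).
#' @param gradient_pattern \code{"alternate"} (default: planted FUN->CSC
#'   gradients alternate up/down within each auxin class, spreading
#'   subgroups over the four gradient groups) or a character vector of
#'   \code{"up"}/\code{"down"} with one entry per subgroup.
#' @param background_genes number of unstructured noise genes.
#' @param low_signal_frac fraction of background genes planted with both FUN
#'   and CSC below 10 (exercises the filter).
#' @param seed integer RNG seed; all randomness derives from it.
#' @return list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_subgroups = 12, genes_per_subgroup = 10,
                              base_profiles = "random", base_r2_max = 0.5,
                              scale_range = c(0.5, 2), noise_cv = 0.05,
                              frac_auxin_up = 0.5, frac_auxin_down = 0.5,
                              gradient_pattern = "alternate",
                              background_genes = 400, low_signal_frac = 0.1,
                              seed = 1L) {
  stopifnot(n_subgroups >= 1, genes_per_subgroup >= 1,
            length(scale_range) == 2, all(scale_range > 0),
            noise_cv >= 0, background_genes >= 0,
            low_signal_frac >= 0, low_signal_frac <= 1)
  if (frac_auxin_up < 0 || frac_auxin_down < 0 ||
      frac_auxin_up + frac_auxin_down > 1)
    stop("frac_auxin_up + frac_auxin_down must lie in [0, 1]")
  if (!identical(gradient_pattern, "alternate") &&
      !(length(gradient_pattern) == n_subgroups &&
        all(gradient_pattern %in% c("up", "down"))))
    stop("gradient_pattern must be \"alternate\" or one up/down per subgroup")
  structure(list(n_subgroups = n_subgroups,
                 genes_per_subgroup = genes_per_subgroup,
                 base_profiles = base_profiles, base_r2_max = base_r2_max,
                 scale_range = scale_range, noise_cv = noise_cv,
                 frac_auxin_up = frac_auxin_up,
                 frac_auxin_down = frac_auxin_down,
                 gradient_pattern = gradient_pattern,
                 background_genes = background_genes,
                 low_signal_frac = low_signal_frac,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# run expr with a private RNG stream; global .Random.seed is untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic sub-seed derivation, kept below 2^31
split_seed <- function(seed, k) (as.double(seed) * 48271 + k * 9973) %% 2147483647

#' Simulate a tissue-resolved expression dataset with planted structure
#'
#' Gene g of subgroup s gets signal_t = c_g * base_s[t] * exp(eps) with
#' eps ~ Normal(0, sigma), sigma = sqrt(log(1 + noise_cv^2)), for the tissue
#' order (FUN, CSC, intended normalized DSC).  The DSC column is emitted as
#' raw signal (26.8 x the intended normalized value) so the pipeline's
#' normalization step is exercised rather than bypassed.  Each subgroup's
#' base profile has a clear FUN-vs-CSC gradient, so every subgroup lands in
#' a known gradient group; auxin-up/-down labels are planted per the
#' configured fractions.
#'
#' @param config a [simulation_config()].
#' @param area_ratio factor used to de-normalize the DSC column (default
#'   26.8, matching [normalization_config()]).
#' @return list with \code{profiles} (an \code{"expression_profiles"} data
#'   frame), \code{auxin_up}/\code{auxin_down} ([regulon()] objects) and
#'   \code{truth} (data frame \code{gene_id}, \code{subgroup},
#'   \code{gradient}, \code{auxin} in c("up","down","none")).
#' @export
simulate_dataset <- function(config = simulation_config(), area_ratio = 26.8) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    k <- config$n_subgroups

    # plant the auxin label per subgroup: first n_down subgroups down, next
    # n_up up, remainder unlabelled (deterministic allocation, stated world)
    n_down <- round(config$frac_auxin_down * k)
    n_up <- min(k - n_down, round(config$frac_auxin_up * k))
    auxin_lab <- rep("none", k)
    if (n_down > 0) auxin_lab[seq_len(n_down)] <- "down"
    if (n_up > 0) auxin_lab[n_down + seq_len(n_up)] <- "up"

    # planted FUN->CSC gradient per subgroup; together with the auxin label
    # this fixes the gradient group each subgroup lands in
    gradients <- if (identical(config$gradient_pattern, "alternate")) {
      g <- character(k)
      for (lab in unique(auxin_lab)) {
        idx <- which(auxin_lab == lab)
        g[idx] <- rep(c("up", "down"), length.out = length(idx))
      }
      g
    } else config$gradient_pattern

    # Collinearity bound on base profiles is enforced within each
    # (auxin label, gradient) cell: centred 3-point profiles span a 2-D
    # plane, so at most four mutually R2 <= 0.5 directions exist globally,
    # while co-clustering only ever happens inside one gradient group.
    bases <- make_base_profiles(config, k, paste(auxin_lab, gradients))

    gene_rows <- list()
    truth_rows <- list()
    gid <- 0L
    next_id <- function() {
      gid <<- gid + 1L
      # synthetic loci on "chromosome 9" never collide with real loci
      sprintf("At9g%05d", gid)
    }
    for (s in seq_len(k)) {
      base <- bases[[s]]
      gradient <- gradients[s]
      for (j in seq_len(config$genes_per_subgroup)) {
        id <- next_id()
        cg <- stats::runif(1, config$scale_range[1], config$scale_range[2])
        sig <- cg * base * lognormal_noise(3, config$noise_cv)
        gene_rows[[length(gene_rows) + 1L]] <-
          c(sig[1], sig[2], sig[3] * area_ratio)
        truth_rows[[length(truth_rows) + 1L]] <-
          data.frame(gene_id = id, subgroup = paste0("S", s),
                     gradient = gradient, auxin = auxin_lab[s],
                     stringsAsFactors = FALSE)
      }
    }
    for (b in seq_len(config$background_genes)) {
      id <- next_id()
      low <- b <= config$low_signal_frac * config$background_genes
      sig <- if (low) stats::runif(3, 0, 9.5) else stats::runif(3, 10, 1000)
      gene_rows[[length(gene_rows) + 1L]] <- c(sig[1], sig[2],
                                               sig[3] * area_ratio)
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(gene_id = id, subgroup = "background",
                   gradient = classify_gradient(sig[1], sig[2]),
                   auxin = "none", stringsAsFactors = FALSE)
    }
    m <- do.call(rbind, gene_rows)
    truth <- do.call(rbind, truth_rows)
    profiles <- expression_profiles(truth$gene_id, m[, 1], m[, 2], m[, 3])
    list(profiles = profiles,
         auxin_up = regulon(truth$gene_id[truth$auxin == "up"], "auxin",
                            "up", source = "simulated"),
         auxin_down = regulon(truth$gene_id[truth$auxin == "down"], "auxin",
                              "down", source = "simulated"),
         truth = truth)
  })
}

make_base_profiles <- function(config, k, cells) {
  if (!identical(config$base_profiles, "random")) {
    stopifnot(length(config$base_profiles) == k)
    return(lapply(config$base_profiles, as.numeric))
  }
  draw_one <- function(want_grad) {
    repeat {
      # lower bound 30 keeps structured genes clear of the <10 raw-signal
      # filter at the smallest proportionality constant (0.5 * 30 = 15)
      cand <- stats::runif(3, 30, 500)
      # clear FUN-vs-CSC separation so noise cannot flip the gradient
      if (abs(cand[1] - cand[2]) < 0.2 * max(cand[1], cand[2])) next
      # orient the profile to the planted gradient
      if ((want_grad == "down") != (cand[1] > cand[2]))
        cand[1:2] <- cand[2:1]
      return(cand)
    }
  }
  # Each cell's base set is sampled jointly with whole-cell restarts: an
  # unlucky early direction can leave no feasible arc for later ones
  # (centred 3-point profiles are directions on a half-circle), and a
  # restart re-draws it instead of stalling.
  bases <- vector("list", k)
  for (cell in unique(cells)) {
    idx <- which(cells == cell)
    want_grad <- sub("^.* ", "", cell)
    for (restart in seq_len(200L)) {
      got <- list()
      tries <- 0L
      while (length(got) < length(idx) && tries < 2000L) {
        tries <- tries + 1L
        cand <- draw_one(want_grad)
        ok <- all(vapply(got, function(b) {
          r2 <- pairwise_r2(b, cand)
          !is.na(r2) && r2 <= config$base_r2_max
        }, logical(1)))
        if (ok) got[[length(got) + 1L]] <- cand
      }
      if (length(got) == length(idx)) break
      got <- NULL
    }
    if (is.null(got))
      stop("could not sample ", length(idx), " base profiles for cell '",
           cell, "' with pairwise R2 <= ", config$base_r2_max)
    bases[idx] <- got
  }
  bases
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sigma))
}

#' Simulate a paired germination assay
#'
#' Per dish pair i, a shared environmental germination propensity is drawn
#' from a beta distribution with mean \code{wt_mean} and standard deviation
#' \code{dispersion}; the mutant dish mean is shifted by \code{effect}
#' (clamped to [0, 1]) and per-dish counts are binomial.  The paired layout
#' (each mutant dish with one control dish in the same cluster) matches the
#' experimental design the paired t-test assumes.
#'
#' @param n_pairs number of mutant/control dish pairs (>= 2).
#' @param wt_mean wild-type mean germination frequency.
#' @param effect additive shift of the mutant frequency
#'   (\code{wt_mean + effect} must stay in [0, 1]).
#' @param dispersion between-pair standard deviation of the dish propensity
#'   (0 = no environmental variation).
#' @param total_per_dish seeds per dish.
#' @param seed integer RNG seed.
#' @param genotype label written into the table.
#' @return a \code{"germination_assays"} data frame (mutant rows paired to
#'   control rows), as produced by [load_germination_table()].
#' @export
simulate_germination <- function(n_pairs = 8, wt_mean = 0.5, effect = 0,
                                 dispersion = 0.05, total_per_dish = 120,
                                 seed = 1L, genotype = "mutant") {
  stopifnot(n_pairs >= 2, total_per_dish >= 1, dispersion >= 0)
  if (wt_mean < 0 || wt_mean > 1 || wt_mean + effect < 0 ||
      wt_mean + effect > 1)
    stop("germination probabilities must lie in [0, 1]")
  with_seed(seed, {
    base <- if (dispersion == 0) rep(wt_mean, n_pairs) else {
      v <- dispersion^2
      conc <- wt_mean * (1 - wt_mean) / v - 1
      if (conc <= 0) stop("dispersion too large for wt_mean")
      stats::rbeta(n_pairs, wt_mean * conc, (1 - wt_mean) * conc)
    }
    p_wt <- pmin(1, pmax(0, base))
    p_mut <- pmin(1, pmax(0, base + effect))
    wt_counts <- stats::rbinom(n_pairs, total_per_dish, p_wt)
    mut_counts <- stats::rbinom(n_pairs, total_per_dish, p_mut)
    ctrl <- data.frame(genotype = "Col-0",
                       dish_id = sprintf("wt_%02d", seq_len(n_pairs)),
                       germinated = wt_counts, total = total_per_dish,
                       paired_control_dish = "", stringsAsFactors = FALSE)
    mut <- data.frame(genotype = genotype,
                      dish_id = sprintf("mut_%02d", seq_len(n_pairs)),
                      germinated = mut_counts, total = total_per_dish,
                      paired_control_dish = ctrl$dish_id,
                      stringsAsFactors = FALSE)
    validate_germination(rbind(ctrl, mut))
  })
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a recovered partition and a planted
#' ground truth; 1 for identical partitions (up to label permutation), about
#' 0 for independent ones.
#'
#' @param a,b equal-length label vectors.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}
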