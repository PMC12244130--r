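#' Read a pipeline configuration file
#'
#' YAML with keys: \code{expression} (path), \code{regulons} (named paths:
#' \code{auxin_up}, \code{auxin_down}, optionally \code{aba_up},
#' \code{aba_down}, \code{br_up}, \code{br_down}), and optional scalars
#' \code{area_ratio}, \code{low_signal_threshold}, \code{tie_epsilon},
#' \code{r2_min}, \code{linkage}, \code{sign_constraint}, plus optional
#' paths \code{annotation} and \code{germination}.  Relative paths are
#' resolved against the config file's directory.
#'
#' @param path YAML file.
#' @return a named list of settings with defaults filled in.
#' @export
load_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || is.na(p)) return(NULL)
    if (startsWith(p, "/")) p else file.path(base, p)
  }
  cfg$expression <- resolve(cfg$expression)
  cfg$regulons <- lapply(cfg$regulons, resolve)
  cfg$annotation <- resolve(cfg$annotation)
  cfg$germination <- resolve(cfg$germination)
  fill_config_defaults(cfg)
}

fill_config_defaults <- function(cfg) {
  defaults <- list(area_ratio = 26.8, low_signal_threshold = 10,
                   tie_epsilon = 0, r2_min = 0.90, linkage = "complete",
                   sign_constraint = "any")
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg
}

#' Run the full gradient-network pipeline
#'
#' Stages: load -> normalize -> low-signal filter -> gradient grouping ->
#' subgrouping -> leave-one-out validation -> network assembly.  Writes
#' \code{groups.tsv}, \code{excluded.tsv}, \code{subgroups.tsv},
#' \code{r2_matrix.tsv}, \code{loo_validation.tsv}, \code{net.sif},
#' \code{net.graphml}, \code{nodes.tsv}, \code{edges.tsv} and
#' \code{manifest.json} (and \code{germination_results.tsv} when a
#' germination table is configured).  All data outputs are deterministic:
#' identical config and inputs give byte-identical files (the manifest
#' additionally carries a timestamp).  Any stage error aborts with the stage
#' name; files already written by the failed run are removed.
#'
#' @param config a config list (see [load_pipeline_config()]) or a path to a
#'   YAML config file.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-stage progress messages.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- load_pipeline_config(config)
  config <- fill_config_defaults(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv(df, p)
    written <<- c(written, p)
    p
  }
  say <- function(...) if (!quiet) message(...)
  stage <- "setup"
  result <- tryCatch({
    stage <- "load"
    say("[load] ", config$expression)
    profiles <- load_expression_table(config$expression)
    if (is.null(config$regulons$auxin_up) ||
        is.null(config$regulons$auxin_down))
      stop("config must name auxin_up and auxin_down regulon files")
    for (p in unlist(config$regulons))
      if (!file.exists(p)) stop("regulon file not found: ", p)
    auxin <- reconcile_regulons(
      load_regulon(config$regulons$auxin_up, "auxin", "up"),
      load_regulon(config$regulons$auxin_down, "auxin", "down"))

    stage <- "normalize"
    ncfg <- normalization_config(config$area_ratio,
                                 config$low_signal_threshold)
    profiles <- normalize_dsc(profiles, ncfg)

    stage <- "filter"
    flt <- filter_low_signal(profiles, ncfg)
    say("[filter] kept ", nrow(flt$kept), " of ", nrow(profiles), " genes")

    stage <- "group"
    grouping <- assign_groups(flt$kept, auxin$up, auxin$down,
                              tie_epsilon = config$tie_epsilon)
    gtab <- grouping_table(grouping, flt$kept)
    for (col in c("fun", "csc", "dsc_norm")) gtab[[col]] <- signif(gtab[[col]], 6)
    emit(gtab, "groups.tsv")
    emit(grouping$excluded, "excluded.tsv")

    stage <- "subgroup"
    mat <- profile_matrix(flt$kept)
    all_subgroups <- list()
    r2_rows <- list()
    for (g in grouping$groups) {
      if (!length(g$genes)) next
      sgs <- cluster_subgroups(g$genes, mat, r2_min = config$r2_min,
                               linkage = config$linkage,
                               sign_constraint = config$sign_constraint,
                               parent_group = g$group_id)
      all_subgroups <- c(all_subgroups, sgs)
      members <- sort(setdiff(g$genes, attr(sgs, "degenerate")))
      if (length(members) > 1L) {
        r2 <- r2_matrix(mat[members, , drop = FALSE])
        idx <- which(upper.tri(r2), arr.ind = TRUE)
        r2_rows[[g$group_id]] <- data.frame(
          group_id = g$group_id,
          gene_a = members[idx[, 1]], gene_b = members[idx[, 2]],
          r2 = round(r2[idx], 6), stringsAsFactors = FALSE)
      }
    }
    stab <- subgroup_table(all_subgroups)
    stab$min_pairwise_r2 <- signif(stab$min_pairwise_r2, 6)
    emit(stab, "subgroups.tsv")
    r2_tab <- do.call(rbind, unname(r2_rows))
    if (is.null(r2_tab))
      r2_tab <- data.frame(group_id = character(), gene_a = character(),
                           gene_b = character(), r2 = numeric())
    emit(r2_tab, "r2_matrix.tsv")

    stage <- "validate"
    loo_rows <- lapply(all_subgroups, function(s) {
      if (length(s$members) < 2L) return(NULL)
      excl <- s$members[1L]  # lexicographically smallest member left out
      data.frame(subgroup_id = s$subgroup_id, excluded_gene = excl,
                 loo_r2 = round(loo_group_sum_r2(s$members, mat, excl), 6),
                 stringsAsFactors = FALSE)
    })
    loo_tab <- do.call(rbind, loo_rows)
    if (is.null(loo_tab))
      loo_tab <- data.frame(subgroup_id = character(),
                            excluded_gene = character(), loo_r2 = numeric())
    emit(loo_tab, "loo_validation.tsv")

    stage <- "network"
    afb <- tryCatch(assign_afb_groups(flt$kept,
                                      tie_epsilon = config$tie_epsilon),
                    error = function(e) {
                      say("[network] AFB loci absent; using canonical ",
                          "partition")
                      structure(list(afb1_group = c("TIR1", "AFB1", "AFB4"),
                                     afb5_group = c("AFB2", "AFB3", "AFB5"),
                                     derived_from_data = FALSE),
                                class = "afb_groups")
                    })
    edges <- infer_afb_edges(grouping, afb)
    hormone_regs <- list()
    reg_spec <- list(aba_up = c("ABA", "up"), aba_down = c("ABA", "down"),
                     br_up = c("brassinosteroid", "up"),
                     br_down = c("brassinosteroid", "down"))
    for (k in names(reg_spec)) {
      if (!is.null(config$regulons[[k]]))
        hormone_regs[[k]] <- load_regulon(config$regulons[[k]],
                                          reg_spec[[k]][1], reg_spec[[k]][2])
    }
    for (h in c("aba", "br")) {
      up_k <- paste0(h, "_up"); down_k <- paste0(h, "_down")
      if (!is.null(hormone_regs[[up_k]]) && !is.null(hormone_regs[[down_k]])) {
        rec <- reconcile_regulons(hormone_regs[[up_k]],
                                  hormone_regs[[down_k]])
        hormone_regs[[up_k]] <- rec$up
        hormone_regs[[down_k]] <- rec$down
      }
    }
    gene_nodes <- unique(unlist(lapply(grouping$groups, `[[`, "genes")))
    if (length(hormone_regs))
      edges <- sort_edges(rbind(edges,
                                merge_hormone_edges(gene_nodes,
                                                    hormone_regs)))
    annotation <- if (!is.null(config$annotation))
      load_annotation(config$annotation) else NULL
    pathway_nodes <- if (length(hormone_regs))
      unique(unlist(default_pathway_map())) else character()
    nodes <- network_nodes(sort(gene_nodes), annotation,
                           extra_nodes = c("AFB1-group", "AFB5-group",
                                           pathway_nodes))
    written <- c(written,
                 export_network(nodes, edges, file.path(out_dir, "net.sif"),
                                "sif"),
                 export_network(nodes, edges,
                                file.path(out_dir, "net.graphml"), "graphml"),
                 export_network(nodes, edges, out_dir, "tsv"))

    germ <- NULL
    if (!is.null(config$germination)) {
      stage <- "germination"
      germ <- germination_results(load_germination_table(config$germination))
      out <- germ
      out$mean_mut <- round(out$mean_mut, 6)
      out$mean_wt <- round(out$mean_wt, 6)
      out$t_stat <- round(out$t_stat, 6)
      emit(out, "germination_results.tsv")
    }

    stage <- "manifest"
    inputs <- c(config$expression, unlist(config$regulons),
                config$annotation, config$germination)
    manifest <- list(
      tool = "gradientnet",
      version = as.character(utils::packageVersion("gradientnet")),
      timestamp = format(Sys.time(), tz = "UTC"),
      config = config[c("area_ratio", "low_signal_threshold", "tie_epsilon",
                        "r2_min", "linkage", "sign_constraint")],
      input_md5 = as.list(tools::md5sum(inputs)),
      counts = list(
        loaded = nrow(profiles),
        kept = nrow(flt$kept),
        dropped = nrow(flt$dropped),
        grouped = sum(vapply(grouping$groups,
                             function(g) length(g$genes), integer(1))),
        excluded = nrow(grouping$excluded),
        group_sizes = lapply(grouping$groups,
                             function(g) length(g$genes)),
        subgroups = length(all_subgroups),
        edges = nrow(edges)))
    mp <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, mp)
    manifest
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Write a simulated dataset to disk in pipeline-ready layout
#'
#' Emits \code{expression.tsv}, \code{auxin_up.txt}, \code{auxin_down.txt}
#' and \code{truth.tsv} under \code{out_dir}, byte-identical for a fixed
#' config, and valid inputs for [run_pipeline()].
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory.
#' @return named character vector of written paths, invisibly.
#' @export
simulate_to_dir <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_dataset(config)
  paths <- c(expression = file.path(out_dir, "expression.tsv"),
             auxin_up = file.path(out_dir, "auxin_up.txt"),
             auxin_down = file.path(out_dir, "auxin_down.txt"),
             truth = file.path(out_dir, "truth.tsv"))
  write_expression_table(sim$profiles, paths[["expression"]])
  writeLines(sim$auxin_up$genes, paths[["auxin_up"]])
  writeLines(sim$auxin_down$genes, paths[["auxin_down"]])
  write_tsv(sim$truth, paths[["truth"]])
  invisible(paths)
}
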