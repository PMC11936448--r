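#' Pipeline configuration
#'
#' One object configuring an end-to-end run: which stages execute, where
#' outputs go, and the per-stage options. Stages consume each other's
#' outputs only through the documented file formats, so any stage can be
#' re-run from files produced elsewhere.
#'
#' @param out_dir Output directory (created if absent).
#' @param stages Character subset of `c("simulate", "stats", "network")`.
#' @param count_table_csv Path to an existing tidy count CSV; required
#'   when `"simulate"` is not among the stages.
#' @param simulate A [count_table_spec()] for the simulate stage.
#' @param control_group,peak_group Group labels for the statistics stage
#'   (Dunnett control and the region-wise comparison group).
#' @param network_group Group whose animals define the correlation matrix.
#' @param densities Density grid for [eco_select_density()]; `NULL`
#'   uses that function's mean-degree-aware default.
#' @param n_rand Erdos-Renyi draws for small-worldness.
#' @param seed Master seed for the stochastic network steps.
#' @param louvain_restarts Restarts for [louvain_partition()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "fishmap-output",
                            stages = c("simulate", "stats", "network"),
                            count_table_csv = NULL,
                            simulate = count_table_spec(),
                            control_group = "HT",
                            peak_group = "15min",
                            network_group = "15min",
                            densities = NULL,
                            n_rand = 1000,
                            seed = 1L,
                            louvain_restarts = 20L) {
  stages <- match.arg(stages, c("simulate", "stats", "network"),
                      several.ok = TRUE)
  if (!"simulate" %in% stages && is.null(count_table_csv)) {
    abort("need count_table_csv when the simulate stage is disabled",
          class = "fishmap_error_validation")
  }
  if (!is.null(count_table_csv) && !file.exists(count_table_csv)) {
    abort(sprintf("count_table_csv does not exist: %s", count_table_csv),
          class = "fishmap_error_validation")
  }
  structure(list(out_dir = out_dir, stages = stages,
                 count_table_csv = count_table_csv, simulate = simulate,
                 control_group = control_group, peak_group = peak_group,
                 network_group = network_group, densities = densities,
                 n_rand = n_rand, seed = as.integer(seed),
                 louvain_restarts = as.integer(louvain_restarts)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulate:` block holds [count_table_spec()] arguments.
#'
#' @param path Config file (`.yaml`/`.yml`/`.json`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  sim_args <- raw$simulate %||% list()
  if (!is.null(sim_args$groups)) sim_args$groups <- as_tibble(sim_args$groups)
  if (!is.null(sim_args$fold_change)) sim_args$fold_change <- unlist(sim_args$fold_change)
  raw$simulate <- do.call(count_table_spec, sim_args)
  do.call(pipeline_config, raw)
}

run_stage <- function(name, expr) {
  t0 <- Sys.time()
  message(sprintf("[fishmap] stage %-9s started", name))
  out <- tryCatch(force(expr), error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
          class = "fishmap_error_stage", parent = e)
  })
  message(sprintf("[fishmap] stage %-9s done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the pipeline end to end
#'
#' Executes the configured stages -- simulate (or load) a count table,
#' time-course and region-wise statistics, and the network stage
#' (correlation matrix, ECO density selection, communities, node roles,
#' centralities, small-worldness) -- writing every product as CSV/JSON
#' under `out_dir` plus a manifest with content hashes. Reruns with an
#' identical config are bit-identical for the deterministic stages.
#'
#' @param config A [pipeline_config()].
#' @return The manifest tibble (`file`, `md5`, `bytes`), invisibly; also
#'   written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(fname) {
    outputs <<- c(outputs, file.path(config$out_dir, fname))
    file.path(config$out_dir, fname)
  }

  if ("simulate" %in% config$stages) {
    table <- run_stage("simulate", {
      tbl <- simulate_count_table(config$simulate)
      write_count_table(tbl, emit("count_table.csv"))
      tbl
    })
  } else {
    table <- read_count_table(config$count_table_csv)
  }

  if ("stats" %in% config$stages) {
    run_stage("stats", {
      totals <- table |>
        dplyr::group_by(.data$subject_id, .data$sex, .data$group) |>
        dplyr::summarise(total = sum(.data$count, na.rm = TRUE), .groups = "drop")
      aov2 <- anova_eta2(totals, "total", "sex", "group")
      write.csv(as.data.frame(tidy(aov2)), emit("anova_timecourse.csv"),
                row.names = FALSE)
      dn <- dunnett_vs_control(totals, "total", "group", config$control_group)
      write.csv(as.data.frame(dn), emit("dunnett_timecourse.csv"),
                row.names = FALSE)
      rw <- regionwise_tests(table, config$peak_group, config$control_group)
      write.csv(as.data.frame(rw), emit("regionwise_tests.csv"),
                row.names = FALSE)
    })
  }

  if ("network" %in% config$stages) {
    run_stage("network", {
      cm <- correlation_matrix(table, group = config$network_group)
      write.csv(cm$r, emit("correlation_matrix.csv"))
      eco <- eco_select_density(cm, config$densities)
      write.csv(as.data.frame(tidy(eco)), emit("eco_curve.csv"),
                row.names = FALSE)
      bg <- eco$best_graph
      write_network(bg, emit("network_edges.csv"),
                    emit("network.graphml"))
      part <- louvain_partition(bg, seed = config$seed,
                                restarts = config$louvain_restarts)
      roles <- node_roles(bg, part)
      write.csv(as.data.frame(roles), emit("node_roles.csv"),
                row.names = FALSE)
      cent <- suppressWarnings(centralities(bg))
      write.csv(as.data.frame(cent), emit("centralities.csv"),
                row.names = FALSE)
      sw <- small_worldness(bg, n_rand = config$n_rand, seed = config$seed)
      summary <- c(as.list(glance(bg)),
                   as.list(sw)[c("sigma", "C_g", "L_g", "C_rand", "L_rand",
                                 "n_rand")],
                   list(modularity = part$modularity,
                        n_communities = part$n_communities,
                        seed = config$seed))
      jsonlite::write_json(summary, emit("network_summary.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }

  manifest <- tibble(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs)),
    bytes = unname(file.size(outputs))
  )
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("fishmap")),
         seed = config$seed, stages = config$stages,
         files = manifest),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
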