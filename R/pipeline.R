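#' Assemble and validate a pipeline configuration
#'
#' One flat, human-editable configuration for the full strain-design
#' workflow: load model -> delete gene -> FBA (wild-type vs knockout) ->
#' robustness sweep -> enforced-production scan -> ranked targets. Defaults
#' mirror the standard study settings (glucose uptake 10 mmol gDCW^-1 h^-1,
#' scan control level 0.4).
#'
#' @param model_path path to the model file (SBML-FBC or COBRA-JSON).
#' @param output_dir directory the pipeline writes into (created if needed).
#' @param dialect model dialect, `"auto"` by default.
#' @param deletion_gene gene knocked out for the engineered model
#'   (default `"FUM1"`; `"none"` analyses the unmodified model only).
#' @param product_exchange_id product exchange (default `"EX_fum_e"`).
#' @param sim a [sim_config()].
#' @param robustness list with `control_reaction` (default: the substrate
#'   exchange), `lo`, `hi`, `steps`, `uptake`.
#' @param scan a [scan_config()].
#' @param make_plot write a robustness plot (PNG, needs ggplot2;
#'   default `TRUE` when ggplot2 is installed).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(model_path,
                            output_dir,
                            dialect = "auto",
                            deletion_gene = "FUM1",
                            product_exchange_id = "EX_fum_e",
                            sim = sim_config(),
                            robustness = list(
                              control_reaction = NULL,
                              lo = 0, hi = 20, steps = 21, uptake = TRUE
                            ),
                            scan = scan_config(product_exchange_id = product_exchange_id),
                            make_plot = requireNamespace("ggplot2", quietly = TRUE)) {
  stopifnot(is.character(model_path), length(model_path) == 1)
  robustness$control_reaction <- robustness$control_reaction %||% sim$substrate_exchange_id
  robustness$lo <- robustness$lo %||% 0
  robustness$hi <- robustness$hi %||% 20
  robustness$steps <- robustness$steps %||% 21
  robustness$uptake <- robustness$uptake %||% TRUE
  structure(
    list(
      model_path = model_path, output_dir = output_dir, dialect = dialect,
      deletion_gene = deletion_gene, product_exchange_id = product_exchange_id,
      sim = sim, robustness = robustness, scan = scan, make_plot = isTRUE(make_plot)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the [pipeline_config()] arguments, with `sim`,
#' `robustness` and `scan` as nested mappings of the corresponding
#' constructor arguments. Relative paths are resolved against the YAML
#' file's directory.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  pipeline_config(
    model_path = resolve(y$model_path %||% stop("config lacks model_path")),
    output_dir = resolve(y$output_dir %||% "fluxscan_out"),
    dialect = y$dialect %||% "auto",
    deletion_gene = y$deletion_gene %||% "FUM1",
    product_exchange_id = y$product_exchange_id %||% "EX_fum_e",
    sim = do.call(sim_config, y$sim %||% list()),
    robustness = y$robustness %||% list(),
    scan = do.call(scan_config, utils::modifyList(
      list(product_exchange_id = y$product_exchange_id %||% "EX_fum_e"),
      y$scan %||% list()
    )),
    make_plot = y$make_plot %||% requireNamespace("ggplot2", quietly = TRUE)
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
}

#' Run the full strain-design pipeline
#'
#' Executes load -> delete -> FBA -> robustness -> scan -> rank from one
#' configuration and writes, into `output_dir`:
#'
#' * `fba.tsv` -- wild-type and knockout flux states, both as-is and
#'   normalized to a glucose uptake of 100 (a pure output transform, never
#'   fed back into the LP);
#' * `robustness.tsv` (and `robustness.png` when plotting is enabled) --
#'   the substrate-uptake vs growth curves of both models;
#' * `scan.tsv` -- the enforced-production flux table with per-level fluxes,
#'   class labels and folds;
#' * `targets.tsv` -- the ranked overexpression candidates;
#' * `manifest.json` -- model checksum, configuration echo, solver and
#'   tolerance: enough to re-run the pipeline bit-identically.
#'
#' Any stage error aborts the run with the stage name; partial outputs are
#' removed.
#'
#' @param config a `pipeline_config` or the path to a YAML file for
#'   [read_pipeline_config()].
#' @return named character vector of output paths, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(config$model_path)) {
    stop("pipeline stage 'load': model file does not exist: ", config$model_path)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(outputs), add = TRUE)
  emit <- function(name) {
    p <- file.path(config$output_dir, name)
    outputs <<- c(outputs, stats::setNames(p, name))
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  model <- stage("load", read_model(config$model_path, config$dialect))
  sim <- config$sim

  del <- stage(
    "deletion",
    simulate_deletion(model, sim, config$deletion_gene, config$product_exchange_id)
  )
  ko_model <- if (identical(config$deletion_gene, "none")) {
    model
  } else {
    delete_gene(model, config$deletion_gene)
  }

  stage("fba", {
    wt_fl <- del$wildtype_state$fluxes
    ko_fl <- del$knockout_state$fluxes
    g <- abs(wt_fl[[sim$substrate_exchange_id]])
    gk <- abs(ko_fl[[sim$substrate_exchange_id]])
    norm_wt <- if (g > 0) wt_fl * (100 / g) else wt_fl * NA
    norm_ko <- if (gk > 0) ko_fl * (100 / gk) else ko_fl * NA
    write_tsv(data.frame(
      reaction_id = names(wt_fl),
      subsystem = model$reactions$subsystem,
      wildtype_flux = unname(wt_fl),
      knockout_flux = unname(ko_fl),
      wildtype_flux_per100glc = unname(norm_wt),
      knockout_flux_per100glc = unname(norm_ko)
    ), emit("fba.tsv"))
  })

  rob_cfg <- config$robustness
  rob <- stage("robustness", {
    wt_prof <- robustness_scan(
      model, sim, rob_cfg$control_reaction,
      rob_cfg$lo, rob_cfg$hi, rob_cfg$steps,
      uptake = rob_cfg$uptake
    )
    ko_prof <- robustness_scan(
      ko_model, sim, rob_cfg$control_reaction,
      rob_cfg$lo, rob_cfg$hi, rob_cfg$steps,
      uptake = rob_cfg$uptake
    )
    df <- data.frame(
      parameter = wt_prof$parameter_values,
      wildtype_growth = wt_prof$objective_values,
      wildtype_feasible = wt_prof$feasible,
      knockout_growth = ko_prof$objective_values,
      knockout_feasible = ko_prof$feasible
    )
    write_tsv(df, emit("robustness.tsv"))
    df
  })
  if (config$make_plot && requireNamespace("ggplot2", quietly = TRUE)) {
    stage("robustness-plot", {
      long <- rbind(
        data.frame(parameter = rob$parameter, growth = rob$wildtype_growth, model = "wild-type"),
        data.frame(parameter = rob$parameter, growth = rob$knockout_growth, model = paste0("Δ", config$deletion_gene))
      )
      p <- ggplot2::ggplot(long, ggplot2::aes(
        x = .data$parameter, y = .data$growth, colour = .data$model
      )) +
        ggplot2::geom_line() +
        ggplot2::geom_point(size = 1) +
        ggplot2::labs(
          x = paste0(rob_cfg$control_reaction, if (rob_cfg$uptake) " uptake rate" else " flux"),
          y = "growth rate (1/h)", colour = NULL
        ) +
        ggplot2::theme_minimal()
      ggplot2::ggsave(emit("robustness.png"), p, width = 6, height = 4, dpi = 150)
    })
  }

  scn <- stage("scan", enforced_production_scan(ko_model, sim, config$scan))
  stage("write-scan", {
    write_tsv(as.data.frame(scn), emit("scan.tsv"))
    write_tsv(rank_targets(scn), emit("targets.tsv"))
  })

  stage("manifest", {
    manifest <- list(
      model_path = config$model_path,
      model_md5 = unname(tools::md5sum(config$model_path)),
      model_id = model$id,
      deletion_gene = config$deletion_gene,
      disabled_reactions = del$disabled_reaction_ids,
      product_exchange_id = config$product_exchange_id,
      sim = unclass(sim),
      robustness = rob_cfg,
      scan = unclass(config$scan),
      solver = "fluxscan bounded-variable primal simplex (dense, two-phase)",
      oxygen_policy_note = if (identical(sim$oxygen_policy, "unbounded-uptake")) {
        "aerobic: O2 uptake unconstrained"
      } else {
        sprintf("O2 uptake capped at %g mmol/gDCW/h", sim$oxygen_policy)
      },
      degenerate_optimum_policy = "per-reaction FVA at fraction 1.0; midpoint reported",
      package_version = as.character(utils::packageVersion("fluxscan"))
    )
    jsonlite::write_json(manifest, emit("manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  })

  ok <- TRUE
  invisible(outputs)
}
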