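# End-to-end pipeline: load -> transform -> FBA/FVA -> envelope ->
# per-condition integration MILP -> optional evaluation and flux-change
# outputs, with a JSON run manifest written on success or failure.

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults (`omega = 0.001`, `U_default = 1000`, `p = 1`,
#' `ctilde = "B"`, `variant = "base"`, `transform = "mean_reference"`,
#' `exp_mode = "equality"`), rejects unknown keys, and type-checks the rest.
#' Accepts a list, or a path to a JSON/YAML file holding one.
#'
#' @param config Named list or file path.
#' @return Normalized config list (class `fluxweaver_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs requires the yaml package", call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  defaults <- list(
    model = NULL, expression = NULL, conditions = NULL, out = NULL,
    transform = "mean_reference", variant = "base", ctilde = "B",
    p = 1.0, U_default = 1000, exp_mode = "equality", exp_band = 0.01,
    omega = 0.001, omega_flux = 0.001, mean_low = "monotone",
    or_mode = "max", mip_gap = 1e-9, retention_tol = 1e-6,
    evaluate = NULL, fluxchange = NULL, seed = 1L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  for (key in c("model", "expression", "conditions", "out")) {
    if (is.null(cfg[[key]])) stop("config is missing required key: ", key,
                                  call. = FALSE)
    if (!is.character(cfg[[key]]) || length(cfg[[key]]) != 1L) {
      stop("config key '", key, "' must be a single path", call. = FALSE)
    }
  }
  allowed <- list(
    transform = c("mean_reference", "max_reference", "minmax"),
    variant = c("base", "l1", "l2"),
    exp_mode = c("equality", "upper", "lower"),
    mean_low = c("monotone", "as_printed"),
    or_mode = c("max", "sum"))
  for (key in names(allowed)) {
    if (!cfg[[key]] %in% allowed[[key]]) {
      stop("config key '", key, "' must be one of: ",
           paste(allowed[[key]], collapse = ", "), call. = FALSE)
    }
  }
  for (key in c("p", "U_default", "exp_band", "omega", "omega_flux",
                "mip_gap", "retention_tol")) {
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1L) {
      stop("config key '", key, "' must be a single number", call. = FALSE)
    }
  }
  class(cfg) <- "fluxweaver_config"
  cfg
}

config_to_integration <- function(cfg) {
  integration_config(ctilde = cfg$ctilde, transform = cfg$transform, p = cfg$p,
             U_default = cfg$U_default, exp_mode = cfg$exp_mode,
             exp_band = cfg$exp_band, mip_gap = cfg$mip_gap,
             retention_tol = cfg$retention_tol, omega = cfg$omega,
             omega_flux = cfg$omega_flux, mean_low = cfg$mean_low,
             or_mode = cfg$or_mode, variant = cfg$variant)
}

#' Run the full pipeline from a configuration
#'
#' Stages: load model -> read expression and conditions -> transform ->
#' FBA/FVA per condition -> shared envelope -> integration MILP per condition
#' -> write per-condition flux and activity tables plus a JSON run manifest
#' under `config$out`. The manifest records the config echo, input digests,
#' per-stage status and wall-clock, the solver backend, and the output file
#' list; it is written even when a stage fails.
#'
#' @param config A config list or file path (see [validate_config()]).
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config = unclass(cfg),
    inputs = list(),
    stages = list(),
    solver = tryCatch(solver_backend_info(), error = function(e) NULL),
    outputs = character())
  t_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    result <- tryCatch(fun(), error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    ok <- !inherits(result, "error")
    manifest$stages[[name]] <<- list(
      status = if (ok) "ok" else "failed",
      seconds = round(elapsed, 3),
      error = if (ok) NULL else conditionMessage(result))
    if (!ok) stop(result)
    result
  }
  finish <- function() {
    path <- file.path(cfg$out, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    manifest$outputs <- c(manifest$outputs, path)
    manifest
  }
  out <- tryCatch({
    for (key in c("model", "expression", "conditions")) {
      if (!file.exists(cfg[[key]])) stop("input file not found: ", cfg[[key]],
                                         call. = FALSE)
      manifest$inputs[[key]] <- list(
        path = cfg[[key]], md5 = unname(tools::md5sum(cfg[[key]])))
    }
    net <- t_stage("load_model", function() to_irreversible(load_network(cfg$model)))
    expr <- t_stage("read_expression", function() read_expression(cfg$expression))
    conditions <- t_stage("read_conditions", function() read_conditions(cfg$conditions))
    icfg <- config_to_integration(cfg)
    run <- t_stage("integrate", function()
      run_multi_condition(net, expr, conditions, icfg))
    if (length(run$errors)) {
      stop("condition(s) failed: ", paste(names(run$errors), collapse = ", "),
           call. = FALSE)
    }
    t_stage("write_outputs", function() {
      flux <- do.call(cbind, lapply(run$solutions, `[[`, "flux_net"))
      fpath <- file.path(cfg$out, "fluxes.tsv")
      utils::write.table(
        data.frame(reaction = rownames(flux), flux, check.names = FALSE),
        fpath, sep = "\t", quote = FALSE, row.names = FALSE)
      g <- do.call(cbind, lapply(run$solutions, `[[`, "g"))
      gpath <- file.path(cfg$out, "gene_activity.tsv")
      utils::write.table(
        data.frame(gene = rownames(g), g, check.names = FALSE),
        gpath, sep = "\t", quote = FALSE, row.names = FALSE)
      summary <- lapply(run$solutions, function(s)
        list(z_star = s$z_star, biomass = s$biomass, status = s$status,
             gap = if (is.null(s$gap) || is.na(s$gap)) NULL else s$gap,
             deviation_gene = s$deviation_gene,
             deviation_flux = s$deviation_flux))
      spath <- file.path(cfg$out, "summary.json")
      jsonlite::write_json(list(conditions = summary, B = as.list(run$B),
                                config = unclass(cfg)),
                           spath, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      manifest$outputs <<- c(manifest$outputs, fpath, gpath, spath)
      if (!is.null(cfg$fluxchange) && length(run$solutions) >= 2) {
        st <- subsystem_table(run$solutions, run$net)
        stpath <- file.path(cfg$out, "subsystem_flux.tsv")
        utils::write.table(
          data.frame(subsystem = rownames(st$normalized), st$normalized,
                     check.names = FALSE),
          stpath, sep = "\t", quote = FALSE, row.names = FALSE)
        manifest$outputs <<- c(manifest$outputs, stpath)
      }
      invisible(NULL)
    })
    finish()
  }, error = function(e) {
    manifest$error <<- conditionMessage(e)
    finish()
    stop(e)
  })
  invisible(out)
}
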