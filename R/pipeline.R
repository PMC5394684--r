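schema_defs <- function() {
  list(
    cross_section = list(
      required = c("id", "age", "dx", "mta_l", "mta_r", "pa", "gca_f"),
      optional = c("sex", "education", "mmse", "cdr", "apoe4", "csf_ab_abn",
                   "csf_tau_abn", avlt_item_cols(),
                   default_battery_structure()$tests),
      checks = list(
        age = function(x) x >= 18 & x <= 110,
        mta_l = function(x) x %in% 0:4,
        mta_r = function(x) x %in% 0:4,
        pa = function(x) x %in% 0:3,
        gca_f = function(x) x %in% 0:3,
        mmse = function(x) x >= 0 & x <= 30
      )
    ),
    longitudinal = list(
      required = c("id", "time"),
      optional = c("group", "cdr", "mmse", "mta_l", "mta_r", "pa", "gca_f"),
      checks = list(
        time = function(x) x >= 0,
        mta_l = function(x) x %in% 0:4,
        mta_r = function(x) x %in% 0:4,
        pa = function(x) x %in% 0:3,
        gca_f = function(x) x %in% 0:3
      ),
      # model-scale outcomes are continuous and may stray past the nominal
      # instrument bounds; flag but do not abort
      warn_checks = list(
        mmse = function(x) x >= 0 & x <= 30
      )
    )
  )
}

#' Validate a table against a named schema
#'
#' Checks column presence and per-column type/range rules for the two
#' interchange tables (cross-sectional and long-format longitudinal).
#' Missing required columns and out-of-range values are fatal; missing
#' optional columns are warnings. Issues name the offending rows.
#'
#' @param data Data frame to validate.
#' @param schema `"cross_section"` or `"longitudinal"`.
#' @param strict If `TRUE` (default) fatal issues raise an error; otherwise
#'   they are returned.
#' @return Invisibly, a list with `data` and `issues` (data.frame `severity`,
#'   `column`, `message`).
#' @export
validate_schema <- function(data, schema = c("cross_section", "longitudinal"),
                            strict = TRUE) {
  schema <- match.arg(schema)
  def <- schema_defs()[[schema]]
  issues <- data.frame(severity = character(0), column = character(0),
                       message = character(0))
  add <- function(severity, column, message) {
    issues <<- rbind(issues, data.frame(severity = severity, column = column,
                                        message = message))
  }
  for (cl in setdiff(def$required, names(data)))
    add("fatal", cl, "required column missing")
  for (cl in setdiff(def$optional, names(data)))
    add("warning", cl, "optional column missing")
  range_issues <- function(checks, severity) {
    for (cl in intersect(names(checks), names(data))) {
      x <- data[[cl]]
      ok <- is.na(x) | checks[[cl]](x)
      if (!all(ok))
        add(severity, cl,
            paste("out-of-range values in rows",
                  paste(utils::head(which(!ok), 10), collapse = ", ")))
    }
  }
  range_issues(def$checks, "fatal")
  range_issues(def$warn_checks, "warning")
  fatal <- issues[issues$severity == "fatal", ]
  if (strict && nrow(fatal))
    stop("schema validation failed:\n",
         paste(sprintf("  [%s] %s: %s", fatal$severity, fatal$column,
                       fatal$message), collapse = "\n"))
  invisible(list(data = data, issues = issues))
}

write_csv_utf8 <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
}

#' Read a cohort table written by the pipeline
#'
#' @param path CSV path (UTF-8, header row, '.' decimal).
#' @return Data frame.
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Default end-to-end run configuration
#'
#' All stage toggles, seeds and thresholds of the pipeline in one list that
#' round-trips losslessly through YAML.
#'
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param out_dir Output directory for stage tables.
#' @return Named list (class `run_config`).
#' @export
default_config <- function(seed = 1L, out_dir = "pipeline_out") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(simulate = TRUE, classify = TRUE, memory = TRUE,
                  dominance = TRUE, trajectories = TRUE,
                  characterization = TRUE),
    impairment_sd = 1.5,
    removal_alpha = 0.10,
    stability_floor = 0.01,
    bootstrap_B = 200,
    rf_trees = 500,
    clamp_age = FALSE
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return For `read_config`, a `run_config` list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(unclass(default_config()), cfg)
  structure(out, class = "run_config")
}

#' @rdname read_config
#' @param config A `run_config` list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # stable FNV-1a over the serialized config; recorded in every output
  bytes <- utf8ToInt(as.character(json))
  # 31-bit polynomial rolling hash over the serialized config
  h <- 7
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes the study's analysis flow on a synthetic cohort (or user tables):
#' simulate/ingest, subtype classification, memory profiling, per-group
#' regression + dominance, longitudinal slope models, and random-forest
#' characterization. Every stage writes its tables under
#' `config$out_dir` and the run is fully determined by the config (seeded).
#'
#' @param config A `run_config`, see [default_config()].
#' @param cohort Optional pre-built cohort (list with `cross_section`,
#'   `longitudinal`); by default one is simulated from the config seed.
#' @return A run report: list with per-stage results, `config`,
#'   `config_hash`, `warnings`.
#' @export
run_pipeline <- function(config = default_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = config, config_hash = config_hash(config),
                 stages = list(), warnings = character(0))
  st <- config$stages
  run_stage <- function(name, expr) {
    if (!isTRUE(st[[name]])) {
      report$stages[[name]] <<- "skipped"
      return(NULL)
    }
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  # simulate / ingest ---------------------------------------------------
  if (is.null(cohort)) {
    cohort <- run_stage("simulate", {
      co <- generate_cohort(cohort_spec(seed = config$seed))
      write_csv_utf8(co$cross_section,
                     file.path(config$out_dir, "cross_section.csv"))
      write_csv_utf8(co$longitudinal,
                     file.path(config$out_dir, "longitudinal.csv"))
      write_csv_utf8(co$cross_section[c("id", "group")],
                     file.path(config$out_dir, "truth_labels.csv"))
      co
    })
    if (is.null(cohort)) stop("no cohort: simulate stage disabled and none supplied")
    report$stages$simulate <- list(
      n_subjects = nrow(cohort$cross_section),
      n_visits = nrow(cohort$longitudinal))
  }
  validate_schema(cohort$cross_section, "cross_section", strict = TRUE)
  validate_schema(cohort$longitudinal, "longitudinal", strict = TRUE)
  cs <- cohort$cross_section

  # classify ------------------------------------------------------------
  cls <- run_stage("classify", {
    res <- classify_cohort(cs, clamp = config$clamp_age)
    write_csv_utf8(res$labels, file.path(config$out_dir, "labels.csv"))
    jsonlite::write_json(res$prevalence,
                         file.path(config$out_dir, "prevalence.json"),
                         dataframe = "rows", digits = NA)
    res
  })
  if (!is.null(cls)) report$stages$classify <- cls$prevalence

  labels <- if (!is.null(cls)) cls$labels else {
    # classify stage disabled: fall back to the generating labels
    data.frame(id = cs$id,
               subtype = factor(ifelse(cs$dx == "AD", cs$group, NA),
                                levels = subtype_levels()))
  }

  # memory profile -------------------------------------------------------
  mem <- run_stage("memory", {
    comp <- derive_components(cs)
    norms <- fit_norms(comp[cs$dx == "CN", ])
    itab <- impairment_table(comp, labels, norms,
                             threshold = config$impairment_sd)
    anova <- component_by_group_anova(
      comp[cs$dx == "AD", ],
      stats::setNames(labels, c("id", "group")), norms)
    write_csv_utf8(comp, file.path(config$out_dir, "components.csv"))
    write_csv_utf8(itab, file.path(config$out_dir, "impairment_table.csv"))
    jsonlite::write_json(anova$interaction,
                         file.path(config$out_dir, "anova_interaction.json"),
                         auto_unbox = TRUE, digits = NA)
    list(norms = norms, impairment = itab, interaction = anova$interaction)
  })
  if (!is.null(mem)) report$stages$memory <- mem$interaction

  # dominance regression --------------------------------------------------
  dom <- run_stage("dominance", {
    comp <- derive_components(cs)
    d <- merge(cs, comp[c("id", "learning", "delayed")], by = "id")
    d$group_lab <- ifelse(d$dx == "CN", "hc",
                          as.character(labels$subtype[match(d$id, labels$id)]))
    d <- d[!is.na(d$group_lab), ]
    res <- dominance_table(
      d, outcome = "delayed",
      predictors = c("tmtb", "ds", "bnt", "vegetables", "learning"),
      group = "group_lab", alpha = config$removal_alpha,
      B = config$bootstrap_B, seed = config$seed,
      floor = config$stability_floor)
    tab <- do.call(rbind, lapply(names(res), function(g) {
      r <- res[[g]]$reported$reported
      if (!nrow(r)) return(NULL)
      cbind(group = g, r)
    }))
    if (!is.null(tab))
      write_csv_utf8(tab, file.path(config$out_dir, "dominance_table.csv"))
    res
  })
  if (!is.null(dom))
    report$stages$dominance <- lapply(dom, function(r) r$reported$reported)

  # trajectories ----------------------------------------------------------
  traj <- run_stage("trajectories", {
    long <- cohort$longitudinal
    out <- lapply(c("cdr", "mmse"), function(oc) {
      fit <- fit_lmm(long, oc, ref_group = "hc")
      sl <- group_slopes(fit)
      ct <- slope_contrasts(fit)
      write_csv_utf8(sl, file.path(config$out_dir,
                                   paste0("slopes_", oc, ".csv")))
      write_csv_utf8(ct, file.path(config$out_dir,
                                   paste0("contrasts_", oc, ".csv")))
      list(slopes = sl, contrasts = ct)
    })
    names(out) <- c("cdr", "mmse")
    rt <- rating_trajectories(long)
    write_csv_utf8(rt, file.path(config$out_dir, "rating_trajectories.csv"))
    out
  })
  if (!is.null(traj))
    report$stages$trajectories <- lapply(traj, function(x) x$slopes)

  # characterization -------------------------------------------------------
  ch <- run_stage("characterization", {
    feats <- cs[c("age", "education", "mmse", "cdr", "apoe4",
                  default_battery_structure()$tests)]
    grp <- ifelse(cs$dx == "CN", "hc",
                  as.character(labels$subtype[match(cs$id, labels$id)]))
    rf <- rf_group_error(feats[!is.na(grp), ], grp[!is.na(grp)],
                         n_trees = config$rf_trees, seed = config$seed)
    jsonlite::write_json(
      list(per_group_error = as.list(rf$per_group_error),
           chance_error = rf$chance_error),
      file.path(config$out_dir, "rf_screen.json"),
      auto_unbox = TRUE, digits = NA)
    rf
  })
  if (!is.null(ch))
    report$stages$characterization <- list(
      per_group_error = ch$per_group_error, chance = ch$chance_error)

  jsonlite::write_json(
    list(config_hash = report$config_hash,
         stages_run = names(report$stages)),
    file.path(config$out_dir, "run_report.json"),
    auto_unbox = TRUE)
  report
}
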