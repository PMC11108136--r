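# End-to-end pipeline (estimate -> interpolate -> simulate ->
# expectancies -> optional Sullivan comparison) with a YAML config and
# a command-line front end.

#' Build a run configuration
#'
#' @param records Path to a records CSV, or `NULL` to generate a
#'   synthetic panel.
#' @param synthetic_scale Scale of the synthetic population used when
#'   `records` is `NULL` (see [default_study_like_spec()]).
#' @param out_dir Directory for stage artifacts (created if needed).
#' @param seed Integer master seed: the synthetic panel uses `seed`, the
#'   trajectory engine `seed + 1000` (females) and `seed + 1001`
#'   (males).
#' @param n_per_sex Trajectories per sex (default 10000).
#' @param max_age Last interpolated single year of age (default 90).
#' @param max_attained_age Simulation censoring age (default 110).
#' @param min_cell Low-exposure diagnostic threshold (default 30).
#' @param ages Ages of interest for the expectancy report.
#' @param sullivan Optional path to a Sullivan inputs CSV with columns
#'   `age`, `sex`, `qx` (or `mx`) and `pi`; enables the comparison
#'   stage.
#' @param figure Whether to write the stacked-area expectancy figure.
#' @return An object of class `run_config`.
#' @export
run_config <- function(records = NULL, synthetic_scale = 0.05,
                       out_dir = "hlemms_output", seed = 1L,
                       n_per_sex = 10000L, max_age = 90L,
                       max_attained_age = 110L, min_cell = 30L,
                       ages = c(0, 65), sullivan = NULL, figure = FALSE) {
  structure(list(records = records, synthetic_scale = synthetic_scale,
                 out_dir = out_dir, seed = as.integer(seed),
                 n_per_sex = as.integer(n_per_sex),
                 max_age = as.integer(max_age),
                 max_attained_age = as.integer(max_attained_age),
                 min_cell = as.integer(min_cell), ages = ages,
                 sullivan = sullivan, figure = isTRUE(figure)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys are the arguments of [run_config()]; unknown keys
#' fail validation.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown)) {
    stop_validation(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' Run the full estimation-to-expectancy pipeline
#'
#' Stages: (1) read or synthesize the two-year panel; (2) estimate
#' group-centred transition matrices; (3) interpolate to single years of
#' age; (4) draw the initial state distribution from the under-1 group
#' and simulate lifetime trajectories; (5) compute expectancy tables and
#' the report at the ages of interest; (6) optionally run the Sullivan
#' comparator. Every artifact is written under `config$out_dir`
#' together with a provenance file recording the configuration and
#' package version; identical configurations yield bit-identical
#' outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory artifacts: `records`,
#'   `group_set`, `diagnostics`, `yearly_set`, `init`, `sample`,
#'   `expectancies`, `report`, and (when requested) `sullivan` and
#'   `comparison`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  scheme <- age_group_scheme()

  if (!is.null(config$records)) {
    if (!file.exists(config$records)) {
      stop_validation(paste0("records file not found: '", config$records, "'"))
    }
    records <- read_records(config$records)
  } else if (!is.null(config$synthetic_scale)) {
    spec <- default_study_like_spec(scale = config$synthetic_scale,
                                    seed = config$seed)
    records <- generate_panel(spec)
    write_records(records, file.path(config$out_dir, "synthetic_records.csv"))
  } else {
    stop_validation("config must provide either a records path or a synthetic scale")
  }

  est <- estimate_group_matrices(count_transitions(records, scheme),
                                 min_cell = config$min_cell)
  write_matrix_set(est$set, file.path(config$out_dir, "group_matrices.json"))
  utils::write.csv(est$diagnostics,
                   file.path(config$out_dir, "estimation_diagnostics.csv"),
                   row.names = FALSE)

  yearly <- interpolate_yearly(est$set, scheme, max_age = config$max_age)
  write_matrix_set(yearly, file.path(config$out_dir, "yearly_matrices.json"))

  init <- initial_state_distribution(records, scheme)
  sample <- simulate_trajectories(yearly, init, n_per_sex = config$n_per_sex,
                                  seed = config$seed + 1000L,
                                  max_attained_age = config$max_attained_age)
  write_trajectories(sample, file.path(config$out_dir, "trajectories.csv"))

  expectancies <- expectancies_from_sample(sample)
  utils::write.csv(expectancies, file.path(config$out_dir, "expectancy_table.csv"),
                   row.names = FALSE)
  report <- expectancy_report(
    expectancies, ages = config$ages,
    file = file.path(config$out_dir, "expectancy_report.csv"),
    figure = if (config$figure) file.path(config$out_dir, "expectancies.png"))

  result <- list(records = records, group_set = est$set,
                 diagnostics = est$diagnostics, yearly_set = yearly,
                 init = init, sample = sample, expectancies = expectancies,
                 report = report)

  if (!is.null(config$sullivan)) {
    si <- utils::read.csv(config$sullivan)
    if (!all(c("age", "sex", "pi") %in% names(si)) ||
        !any(c("qx", "mx") %in% names(si))) {
      stop_validation("sullivan inputs need columns age, sex, pi and qx or mx")
    }
    sull <- do.call(rbind, lapply(SEXES, function(sex) {
      s <- si[si$sex == sex, ]
      s <- s[order(s$age), ]
      if (!nrow(s)) return(NULL)
      qx <- if ("qx" %in% names(s)) s$qx else mx_to_qx(s$mx)
      lt <- build_life_table(qx, ages = s$age)
      h <- sullivan_hle(lt, s$pi)
      cbind(sex = sex, h)
    }))
    utils::write.csv(sull, file.path(config$out_dir, "sullivan_hle.csv"),
                     row.names = FALSE)
    comparison <- do.call(rbind, lapply(SEXES, function(sex) {
      m <- report[report$sex == sex, ]
      s <- sull[sull$sex == sex, ]
      ages <- intersect(m$age, s$age)
      compare_hle(m$hle[match(ages, m$age)], s$hle[match(ages, s$age)],
                  age = ages, sex = sex)
    }))
    utils::write.csv(comparison, file.path(config$out_dir, "hle_comparison.csv"),
                     row.names = FALSE)
    result$sullivan <- sull
    result$comparison <- comparison
  }

  provenance <- list(config = unclass(config),
                     package_version = as.character(utils::packageVersion("hlemms")),
                     n_records = nrow(records),
                     censored_trajectories = sum(sample$censored))
  jsonlite::write_json(provenance, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(result)
}

# ---- command-line front end ------------------------------------------------

# Minimal --flag value parser; flags map onto run_config()/subcommand
# arguments.
parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) {
      stop_validation(paste0("unexpected argument '", args[i], "'"))
    }
    key <- sub("^--", "", args[i])
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

flag_num <- function(flags, key, default) {
  if (is.null(flags[[key]])) default else as.numeric(flags[[key]])
}

#' Command-line entry point
#'
#' Implements the subcommands `simulate-data`, `estimate`,
#' `interpolate`, `simulate`, `expectancies`, `sullivan`, `compare` and
#' `run` (end to end, driven by a YAML config via `--config` or by
#' flags). Designed to be called from the thin wrapper script installed
#' under `inst/cli/`.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit status: 0 on success, 2 on a validation error,
#'   3 on any other stage failure.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  res <- tryCatch({
    if (!length(args)) {
      cat("usage: hlemms <simulate-data|estimate|interpolate|simulate|expectancies|sullivan|compare|run> [--flags]\n")
      return(0L)
    }
    cmd <- args[1]
    flags <- parse_cli_flags(args[-1])
    scheme <- age_group_scheme()
    switch(
      cmd,
      "simulate-data" = {
        spec <- default_study_like_spec(scale = flag_num(flags, "scale", 1),
                                        seed = flag_num(flags, "seed", 1))
        write_records(generate_panel(spec), flags$out %||% "records.csv")
      },
      "estimate" = {
        records <- read_records(flags[["in"]] %||% "records.csv")
        est <- estimate_group_matrices(count_transitions(records, scheme),
                                       min_cell = flag_num(flags, "min-cell", 30))
        write_matrix_set(est$set, flags$out %||% "group_matrices.json")
        if (!is.null(flags$diagnostics)) {
          utils::write.csv(est$diagnostics, flags$diagnostics, row.names = FALSE)
        }
      },
      "interpolate" = {
        groups <- read_matrix_set(flags[["in"]] %||% "group_matrices.json")
        yearly <- interpolate_yearly(groups, scheme,
                                     max_age = flag_num(flags, "max-age", 90))
        write_matrix_set(yearly, flags$out %||% "yearly_matrices.json")
      },
      "simulate" = {
        yearly <- read_matrix_set(flags[["in"]] %||% "yearly_matrices.json")
        init <- initial_state_distribution(read_records(flags$records), scheme)
        sample <- simulate_trajectories(
          yearly, init, n_per_sex = flag_num(flags, "n-per-sex", 10000),
          seed = flag_num(flags, "seed", 1),
          max_attained_age = flag_num(flags, "max-age", 110))
        write_trajectories(sample, flags$out %||% "trajectories.csv")
      },
      "expectancies" = {
        sample <- read_trajectories(flags[["in"]] %||% "trajectories.csv")
        tab <- expectancies_from_sample(sample)
        ages <- if (is.null(flags$ages)) c(0, 65) else
          as.numeric(strsplit(flags$ages, ",")[[1]])
        expectancy_report(tab, ages = ages,
                          file = flags$out %||% "expectancy_report.csv",
                          figure = flags$figure)
        utils::write.csv(tab, flags$table %||% "expectancy_table.csv",
                         row.names = FALSE)
      },
      "sullivan" = {
        si <- utils::read.csv(flags[["in"]])
        out <- do.call(rbind, lapply(unique(si$sex), function(sex) {
          s <- si[si$sex == sex, ]; s <- s[order(s$age), ]
          qx <- if ("qx" %in% names(s)) s$qx else mx_to_qx(s$mx)
          cbind(sex = sex, sullivan_hle(build_life_table(qx, ages = s$age), s$pi))
        }))
        utils::write.csv(out, flags$out %||% "sullivan_hle.csv", row.names = FALSE)
      },
      "compare" = {
        mms <- utils::read.csv(flags$mms)
        sull <- utils::read.csv(flags$sullivan)
        key <- paste(mms$sex, mms$age)
        skey <- paste(sull$sex, sull$age)
        common <- intersect(key, skey)
        cmp <- compare_hle(mms$hle[match(common, key)],
                           sull$hle[match(common, skey)],
                           age = mms$age[match(common, key)],
                           sex = mms$sex[match(common, key)])
        utils::write.csv(cmp, flags$out %||% "hle_comparison.csv", row.names = FALSE)
      },
      "run" = {
        config <- if (!is.null(flags$config)) read_run_config(flags$config) else
          run_config(records = flags$records,
                     synthetic_scale = flag_num(flags, "scale", 0.05),
                     out_dir = flags[["out-dir"]] %||% "hlemms_output",
                     seed = flag_num(flags, "seed", 1),
                     n_per_sex = flag_num(flags, "n-per-sex", 10000))
        run_pipeline(config)
      },
      stop_validation(paste0("unknown subcommand '", cmd, "'"))
    )
    0L
  },
  hlemms_validation_error = function(e) {
    message("validation error: ", conditionMessage(e)); 2L
  },
  error = function(e) {
    message("stage failure: ", conditionMessage(e)); 3L
  })
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
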