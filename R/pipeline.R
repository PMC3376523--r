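#' Read a participant-level table from delimited text
#'
#' Expects a tab-delimited file whose header names the documented columns
#' (`id`, `arm`, `completed`, `grade`, `wtp_c1`..`wtp_c4`, `satisfaction`).
#' Empty strings and `"NA"` map to missing. Malformed rows (wrong field
#' count, unknown arm label, non-numeric grade/WTP/satisfaction) are
#' reported by line number in a warning and skipped; well-formed rows are
#' still returned. A header-only file yields an empty table.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return a tibble with the participant schema; skipped line numbers, if
#'   any, are attached as attribute `"skipped_lines"`.
#' @export
read_participant_table <- function(path, sep = "\t") {
  required <- c("id", "arm", "completed", "grade",
                paste0("wtp_c", 1:4), "satisfaction")
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty file: ", path, call. = FALSE)
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  if (!setequal(header, required)) {
    stop("header must contain exactly the columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  idx <- match(required, header)
  arms_ok <- c("face_to_face", "web")

  parse_num <- function(x) {
    if (x %in% c("", "NA")) return(NA_real_)
    suppressWarnings(as.numeric(x))
  }
  rows <- list()
  bad <- integer(0)
  bad_why <- character(0)
  for (i in seq_along(lines)[-1]) {
    if (lines[i] == "") next
    raw <- strsplit(lines[i], sep, fixed = TRUE)[[1]]
    nraw <- length(raw)
    length(raw) <- length(header)   # pad trailing empties
    raw[is.na(raw)] <- ""
    f <- raw[idx]
    err <- NULL
    if (nraw > length(header) || nraw < length(header) - 1) {
      err <- "wrong field count"
    } else if (!f[2] %in% arms_ok) {
      err <- paste0("unknown arm label '", f[2], "'")
    }
    num <- vapply(f[4:9], parse_num, numeric(1))
    if (is.null(err) && any(is.na(num) & !(f[4:9] %in% c("", "NA")))) {
      err <- "non-numeric value"
    }
    completed <- switch(tolower(f[3]),
                        "true" = TRUE, "1" = TRUE,
                        "false" = FALSE, "0" = FALSE, NA)
    if (is.null(err) && is.na(completed)) err <- "bad completed flag"
    if (!is.null(err)) {
      bad <- c(bad, i)
      bad_why <- c(bad_why, err)
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = f[1], arm = f[2], completed = completed, grade = num[1],
      wtp_c1 = num[2], wtp_c2 = num[3], wtp_c3 = num[4], wtp_c4 = num[5],
      satisfaction = as.integer(num[6])
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(id = character(0), arm = character(0),
                   completed = logical(0), grade = numeric(0),
                   wtp_c1 = numeric(0), wtp_c2 = numeric(0),
                   wtp_c3 = numeric(0), wtp_c4 = numeric(0),
                   satisfaction = integer(0))
  if (length(bad)) {
    warning("skipped malformed row(s) at line ",
            paste0(bad, " (", bad_why, ")", collapse = ", "),
            call. = FALSE)
    attr(out, "skipped_lines") <- bad
  }
  out
}

#' Write a participant-level table as delimited text
#'
#' Tab-delimited, `NA` for missing fields; round-trips exactly through
#' [read_participant_table()].
#'
#' @param cohort a participant-level table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_participant_table <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read and validate a pipeline run configuration
#'
#' Strict-schema YAML: unknown keys at any level are rejected with the
#' offending key path, so every number a report reproduces is traceable to
#' an explicit configuration entry. See
#' `system.file("extdata", "run_config.yaml", package = "eduecon")` for the
#' packaged default encoding the study's parameters.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra)) {
      stop("unknown configuration key: ", where, "$", extra[1],
           call. = FALSE)
    }
  }
  check_keys(cfg, c("cost_structures", "wage_policy", "time_profile",
                    "breakeven", "cea", "cba", "cohort",
                    "participant_table"), "config")
  for (req in c("cost_structures", "breakeven", "cea", "cba")) {
    if (is.null(cfg[[req]])) {
      stop("configuration is missing required section: ", req,
           call. = FALSE)
    }
  }
  if (is.null(cfg$cohort) && is.null(cfg$participant_table)) {
    stop("configuration must provide either a cohort section or a ",
         "participant_table path", call. = FALSE)
  }
  if (!is.null(cfg$wage_policy)) {
    check_keys(cfg$wage_policy,
               c("base_rate", "on_cost_multiplier", "penalty_loading"),
               "config$wage_policy")
  }
  if (!is.null(cfg$breakeven)) {
    check_keys(cfg$breakeven, c("max_enrollments", "enrollment_fee",
                                "modes"), "config$breakeven")
    for (m in names(cfg$breakeven$modes)) {
      check_keys(cfg$breakeven$modes[[m]],
                 c("facilitator_hours", "facilitator_rate", "other_fixed",
                   "variable_per_participant", "class_capacity", "axes"),
                 paste0("config$breakeven$modes$", m))
      check_keys(cfg$breakeven$modes[[m]]$axes,
                 c("facilitator_hours", "facilitator_rate",
                   "class_capacity", "enrollment_fee", "all_costs_scale"),
                 paste0("config$breakeven$modes$", m, "$axes"))
    }
  }
  if (!is.null(cfg$cea)) {
    check_keys(cfg$cea, c("enrolled", "completers", "mean_grade",
                          "qase_override", "in_work_hours",
                          "enrollment_fee", "alt_fee_factor"),
               "config$cea")
  }
  if (!is.null(cfg$cba)) {
    check_keys(cfg$cba, c("enrollment_fee", "time_hours",
                          "benefit_context"), "config$cba")
  }
  if (!is.null(cfg$cohort)) {
    for (a in names(cfg$cohort)) {
      check_keys(cfg$cohort[[a]],
                 c("n_enrolled", "completion_probability", "grade_mean",
                   "grade_sd", "wtp_mean", "wtp_sd", "rho",
                   "satisfaction_levels", "wtp_missing",
                   "satisfaction_missing"),
                 paste0("config$cohort$", a))
    }
  }
  cfg
}

# internal: wage policy / arm-spec construction from config fragments
policy_from_config <- function(cfg) {
  p <- cfg$wage_policy
  if (is.null(p)) return(wage_policy())
  wage_policy(base_rate = p$base_rate %||% 45,
              on_cost_multiplier = p$on_cost_multiplier %||% 1.17,
              penalty_loading = p$penalty_loading %||% 1.5)
}

cohort_spec_from_config <- function(cfg) {
  if (is.null(cfg$cohort)) return(default_cohort_spec())
  out <- lapply(cfg$cohort, function(a) {
    cohort_arm_spec(
      n_enrolled = a$n_enrolled,
      completion_probability = a$completion_probability,
      grade_mean = a$grade_mean, grade_sd = a$grade_sd,
      wtp_mean = unlist(a$wtp_mean), wtp_sd = unlist(a$wtp_sd),
      rho = unlist(a$rho),
      satisfaction_levels = a$satisfaction_levels %||% 5,
      wtp_missing = a$wtp_missing %||% 0,
      satisfaction_missing = a$satisfaction_missing %||% 0
    )
  })
  names(out) <- names(cfg$cohort)
  out
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' Run the full three-perspective evaluation pipeline
#'
#' Executes, from one configuration, the provider break-even sweeps, the
#' health-service cost-effectiveness table and the participant cost-benefit
#' tables (on a supplied or freshly simulated cohort), and writes one
#' delimited table per report (`cost_structure.tsv`,
#' `breakeven_web.tsv`, `breakeven_f2f.tsv`, `cea.tsv`, `expenses.tsv`,
#' `wtp.tsv`, `net_benefit.tsv`) plus a machine-readable `results.json`
#' recording every resolved parameter and the seed. Deterministic for a
#' fixed configuration and seed; the break-even tables are
#' cohort-independent and never change with the seed.
#'
#' @param config a configuration list (from [read_run_config()]) or a path
#'   to a YAML configuration file.
#' @param out_dir output directory (created if absent).
#' @param seed integer seed for cohort simulation.
#' @return invisibly, a list with every computed table and the resolved
#'   parameters.
#' @export
run_pipeline <- function(config, out_dir, seed = 1) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  policy <- policy_from_config(config)

  # --- cost structures -----------------------------------------------------
  structures <- if (identical(config$cost_structures, "default")) {
    default_cost_structures()
  } else if (is.character(config$cost_structures)) {
    read_cost_structures(config$cost_structures)
  } else {
    default_cost_structures()
  }
  cost_rows <- do.call(rbind, lapply(names(structures), function(m) {
    s <- structures[[m]]
    do.call(rbind, lapply(s$items, function(it) {
      tibble::tibble(mode = m, item = it$name, amount = it$amount,
                     recurrence = it$recurrence, payer = it$payer)
    }))
  }))
  totals <- lapply(structures, fixed_and_variable_totals)
  write_tsv(cost_rows, file.path(out_dir, "cost_structure.tsv"))

  # --- break-even sweeps ---------------------------------------------------
  be <- config$breakeven
  be_tables <- list()
  for (m in names(be$modes)) {
    mm <- be$modes[[m]]
    base <- breakeven_scenario(
      facilitator_hours = mm$facilitator_hours,
      facilitator_rate = mm$facilitator_rate,
      other_fixed = mm$other_fixed,
      variable_per_participant = mm$variable_per_participant,
      enrollment_fee = be$enrollment_fee %||% 250,
      class_capacity = mm$class_capacity,
      max_enrollments = be$max_enrollments %||% 60
    )
    seg0 <- breakeven_segments(base)
    primary <- tibble::tibble(
      axis = "primary", value = NA_real_,
      fixed_per_class = base$fixed_per_class,
      variable_per_participant = base$variable_per_participant,
      enrollment_fee = base$enrollment_fee,
      class_capacity = base$class_capacity,
      segments = format(seg0), breaks_even = seg0$breaks_even,
      first_breakeven = if (seg0$breaks_even)
        as.integer(seg0$segments[[1]][1]) else NA_integer_,
      rounded_ratio = breakeven_rounded_ratio(base),
      segments_list = list(seg0$segments)
    )
    sweeps <- lapply(names(mm$axes), function(ax) {
      sensitivity_sweep(base, ax, unlist(mm$axes[[ax]]))
    })
    tab <- do.call(rbind, c(list(primary), sweeps))
    be_tables[[m]] <- tab
    out_name <- if (m == "web") "breakeven_web.tsv" else "breakeven_f2f.tsv"
    write_tsv(tab[, setdiff(names(tab), "segments_list")],
              file.path(out_dir, out_name))
  }

  # --- cohort --------------------------------------------------------------
  cohort <- if (!is.null(config$participant_table)) {
    read_participant_table(config$participant_table)
  } else {
    generate_cohort(cohort_spec_from_config(config), seed = seed)
  }
  summary <- summarize_cohort(cohort)
  validity <- wtp_construct_validity(wtp_long(cohort))
  write_tsv(merge(summary$wtp, validity, by = "context",
                  suffixes = c("", "_validity")),
            file.path(out_dir, "wtp.tsv"))

  # --- cost-effectiveness --------------------------------------------------
  cea_cfg <- config$cea
  arms <- list(
    face_to_face = qase_record(
      cea_cfg$enrolled %||% 20, cea_cfg$completers$face_to_face,
      cea_cfg$mean_grade$face_to_face,
      qase = cea_cfg$qase_override$face_to_face
    ),
    web = qase_record(
      cea_cfg$enrolled %||% 20, cea_cfg$completers$web,
      cea_cfg$mean_grade$web, qase = cea_cfg$qase_override$web
    )
  )
  hours <- c(face_to_face = cea_cfg$in_work_hours$face_to_face %||% 8,
             web = cea_cfg$in_work_hours$web %||% 9.6)
  cea_tab <- cea_sensitivity_table(
    arms,
    default_cea_scenarios(
      enrollment_fee = cea_cfg$enrollment_fee %||% 250,
      alt_fee_factor = cea_cfg$alt_fee_factor %||% 2.1,
      policy = policy, in_work_hours = hours,
      enrolled = cea_cfg$enrolled %||% 20
    )
  )
  write_tsv(cea_tab, file.path(out_dir, "cea.tsv"))

  # --- cost-benefit --------------------------------------------------------
  cba_cfg <- config$cba
  ctx <- cba_cfg$benefit_context %||% 3
  long <- wtp_long(cohort)
  benefit <- c(
    face_to_face = mean_wtp(long, "face_to_face", ctx)$mean,
    web = mean_wtp(long, "web", ctx)$mean
  )
  t_hours <- c(face_to_face = cba_cfg$time_hours$face_to_face %||% 12,
               web = cba_cfg$time_hours$web %||% 14.4)
  cba_tab <- cba_sensitivity_table(
    fee = cba_cfg$enrollment_fee %||% 250, time_hours = t_hours,
    benefit = benefit, policy = policy
  )
  write_tsv(cba_tab, file.path(out_dir, "expenses.tsv"))
  nb_rows <- do.call(rbind, lapply(
    split(cba_tab, factor(cba_tab$label, unique(cba_tab$label))),
    function(d) tibble::tibble(label = d$label[1],
                               cost_f2f = d$total[d$arm == "face_to_face"],
                               cost_web = d$total[d$arm == "web"],
                               benefit_f2f = benefit[["face_to_face"]],
                               benefit_web = benefit[["web"]],
                               net_benefit = d$net_benefit[1])
  ))
  write_tsv(nb_rows, file.path(out_dir, "net_benefit.tsv"))

  # --- machine-readable bundle --------------------------------------------
  primary_icer <- cea_tab[1, ]
  results <- list(
    seed = seed,
    parameters = list(
      wage_policy = unclass(policy),
      cost_totals = totals,
      enrollment_fee = be$enrollment_fee %||% 250,
      in_work_hours = as.list(hours),
      participant_hours = as.list(t_hours),
      benefit_context = ctx
    ),
    breakeven = lapply(be_tables, function(t) {
      list(primary_segments = t$segments[1],
           first_breakeven = t$first_breakeven[1],
           rounded_ratio = t$rounded_ratio[1])
    }),
    cea = list(qase_f2f = primary_icer$qase_f2f,
               qase_web = primary_icer$qase_web,
               primary_cost_f2f = primary_icer$cost_f2f,
               primary_cost_web = primary_icer$cost_web,
               primary_icer = primary_icer$icer_ratio,
               primary_note = primary_icer$icer_note),
    cba = list(benefit = as.list(benefit),
               primary_total_f2f = nb_rows$cost_f2f[1],
               primary_total_web = nb_rows$cost_web[1],
               primary_net_benefit = nb_rows$net_benefit[1]),
    cohort = list(arms = summary$arms)
  )
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(list(cost_structures = structures, breakeven = be_tables,
                 cohort = cohort, cohort_summary = summary,
                 wtp_validity = validity, cea = cea_tab, cba = cba_tab,
                 net_benefit = nb_rows, results = results))
}
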