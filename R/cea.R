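#' Quality-adjusted students educated (QASE)
#'
#' The effectiveness unit of the cost-effectiveness analysis: the number of
#' completing students weighted by the group's mean assessment grade, with
#' non-completers contributing zero. A completer with a perfect grade counts
#' as one full quality-adjusted student.
#'
#' @param completers number of course completers (>= 0).
#' @param mean_grade mean grade of completers as a fraction in \[0, 1\].
#' @return QASE units (unrounded; tables report 2 decimals).
#' @examples
#' qase(14, 0.816)   # 11.424, printed as 11.42
#' @export
qase <- function(completers, mean_grade) {
  if (!is.numeric(completers) || completers < 0) {
    stop("completers must be >= 0", call. = FALSE)
  }
  if (!is.numeric(mean_grade) || mean_grade < 0 || mean_grade > 1) {
    stop("mean_grade must lie in [0, 1]", call. = FALSE)
  }
  completers * mean_grade
}

#' Arm effectiveness record
#'
#' Bundles enrollment, completion and grade for one arm together with its
#' QASE. By default QASE is computed as `completers * mean_grade`; an
#' explicit `qase` value may be supplied when reproducing published rows in
#' which the two are inconsistent (the record then carries both as given).
#'
#' @param enrolled number enrolled.
#' @param completers number completing (<= enrolled).
#' @param mean_grade mean grade, fraction in \[0, 1\].
#' @param qase optional explicit QASE override.
#' @return an object of class `qase_record`.
#' @export
qase_record <- function(enrolled, completers, mean_grade, qase = NULL) {
  if (completers > enrolled) {
    stop("completers must not exceed enrolled", call. = FALSE)
  }
  if (mean_grade < 0 || mean_grade > 1) {
    stop("mean_grade must lie in [0, 1]", call. = FALSE)
  }
  q <- if (is.null(qase)) completers * mean_grade else qase
  structure(
    list(enrolled = as.integer(enrolled), completers = as.integer(completers),
         mean_grade = mean_grade, qase = q,
         qase_overridden = !is.null(qase)),
    class = "qase_record"
  )
}

#' Health-service costing scenario
#'
#' One row of the cost-effectiveness sensitivity analysis: when the course
#' is taken (`working_hours`, `unpaid_leave`, or `leisure`), whether the
#' health service pays the enrollment fee, and whether backfill (replacement
#' staff) is needed. Participant wages, with 17% on-costs, are charged to
#' the service whenever training displaces paid or leave time
#' (`working_hours` or `unpaid_leave`); backfill doubles the wage component
#' and is only coherent during working hours. Transport and Internet costs
#' are borne by the participant and never appear here.
#'
#' @param timing `"working_hours"`, `"unpaid_leave"` or `"leisure"`.
#' @param fee_paid_by_service does the service pay the enrollment fee?
#' @param backfill replacement staff required? (implies working hours).
#' @param policy a [wage_policy()].
#' @param in_work_hours named numeric vector of in-work course hours per arm,
#'   e.g. `c(face_to_face = 8, web = 9.6)`.
#' @param enrollment_fee fee per enrollment, either a single number or a
#'   named per-arm vector.
#' @param enrolled number of participants enrolled per arm (a full class).
#' @return an object of class `cea_scenario`.
#' @export
cea_scenario <- function(timing = c("working_hours", "unpaid_leave",
                                    "leisure"),
                         fee_paid_by_service = FALSE,
                         backfill = FALSE,
                         policy = wage_policy(),
                         in_work_hours = c(face_to_face = 8, web = 9.6),
                         enrollment_fee = 250,
                         enrolled = 20) {
  timing <- match.arg(timing)
  if (isTRUE(backfill) && timing != "working_hours") {
    stop("backfill requires timing = \"working_hours\": replacement staff ",
         "are only needed when training displaces work", call. = FALSE)
  }
  structure(
    list(timing = timing, fee_paid_by_service = isTRUE(fee_paid_by_service),
         backfill = isTRUE(backfill), policy = policy,
         in_work_hours = in_work_hours, enrollment_fee = enrollment_fee,
         enrolled = as.integer(enrolled)),
    class = "cea_scenario"
  )
}

#' Cost to the health service of one arm under a scenario
#'
#' Assembles the service-perspective cost: the enrollment fee component (if
#' the service pays), plus on-cost-loaded participant wages for the in-work
#' hours when the timing displaces work or leave, plus an equal backfill wage
#' component when replacement staff are required. Leisure-time delivery
#' carries no wage cost to the service.
#'
#' @param arm `"face_to_face"` or `"web"`.
#' @param scenario a [cea_scenario()].
#' @return cost in AUD, exact to cents.
#' @examples
#' s <- cea_scenario("working_hours", fee_paid_by_service = FALSE,
#'                   backfill = TRUE)
#' service_cost("face_to_face", s)   # 16848: 20 x 8 x 45 x 1.17 x 2
#' @export
service_cost <- function(arm = c("face_to_face", "web"), scenario) {
  arm <- match.arg(arm)
  stopifnot(inherits(scenario, "cea_scenario"))
  if (!arm %in% names(scenario$in_work_hours)) {
    stop("no in-work hours entry for arm ", arm, call. = FALSE)
  }
  hours <- scenario$in_work_hours[[arm]]
  fee <- scenario$enrollment_fee
  if (length(fee) > 1) fee <- fee[[arm]]
  total <- 0
  if (scenario$fee_paid_by_service) {
    total <- total + fee * scenario$enrolled
  }
  if (scenario$timing %in% c("working_hours", "unpaid_leave")) {
    wages <- wage_cost(hours, scenario$policy, apply_on_costs = TRUE) *
      scenario$enrolled
    total <- total + wages
    if (scenario$backfill) total <- total + wages
  }
  round_half_up(total, 2)
}

#' Incremental cost-effectiveness ratio with dominance handling
#'
#' Computes the incremental cost and incremental effect (QASE) of arm A
#' versus arm B and maps degenerate cases to dominance markers rather than
#' errors: equal costs give a ratio of exactly 0 with the higher-QASE arm
#' preferred; equal effects with unequal costs make the cheaper arm
#' dominant; a cheaper-and-more-effective arm is dominant outright.
#'
#' @param cost_a,cost_b arm costs (AUD).
#' @param qase_a,qase_b arm effectiveness (QASE units).
#' @param arm_a,arm_b labels used in `preferred_arm`.
#' @return an object of class `icer_result`: list with `delta_cost`,
#'   `delta_effect`, `ratio` (AUD per QASE; 0 under the equal-cost marker,
#'   `NA` when the effect difference is zero), `dominance` (one of
#'   `"none"`, `"equal_cost"`, `"equal_effect"`, `"dominant_a"`,
#'   `"dominant_b"`) and `preferred_arm` (`NA` when the trade-off depends on
#'   the decision-maker's willingness to pay per QASE).
#' @examples
#' icer(5000, 5000, 11.42, 11.63)  # ratio 0, web preferred (higher QASE)
#' icer(1000, 600, 10, 8)$ratio    # 200 per QASE
#' @export
icer <- function(cost_a, cost_b, qase_a, qase_b,
                 arm_a = "face_to_face", arm_b = "web") {
  dc <- cost_a - cost_b
  de <- qase_a - qase_b
  dominance <- "none"
  ratio <- NA_real_
  preferred <- NA_character_
  if (dc == 0) {
    dominance <- "equal_cost"
    ratio <- 0
    preferred <- if (de > 0) arm_a else if (de < 0) arm_b else NA_character_
  } else if (de == 0) {
    dominance <- "equal_effect"
    preferred <- if (dc < 0) arm_a else arm_b
  } else {
    ratio <- dc / de
    if (dc < 0 && de > 0) {
      dominance <- "dominant_a"
      preferred <- arm_a
    } else if (dc > 0 && de < 0) {
      dominance <- "dominant_b"
      preferred <- arm_b
    }
  }
  structure(
    list(delta_cost = dc, delta_effect = de, ratio = ratio,
         dominance = dominance, preferred_arm = preferred,
         arm_a = arm_a, arm_b = arm_b),
    class = "icer_result"
  )
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("<icer_result> dCost = %s, dQASE = %.2f\n",
              fmt_money(x$delta_cost), x$delta_effect))
  if (x$dominance == "equal_cost") {
    cat(sprintf("  ratio 0 (%s preferred due to higher QASE)\n",
                x$preferred_arm))
  } else if (is.na(x$ratio)) {
    cat(sprintf("  equal effect: %s dominant (cheaper)\n", x$preferred_arm))
  } else {
    cat(sprintf("  ratio %s per QASE\n", fmt_money(x$ratio)))
  }
  invisible(x)
}

#' Default cost-effectiveness scenario grid
#'
#' The eight scenario rows of the service-perspective sensitivity analysis:
#' leisure, working-hours and unpaid-leave timings crossed with who pays the
#' enrollment fee, plus an equal-attrition variant and an alternative-fee
#' variant in which the face-to-face fee is inflated by a configurable
#' factor (default 2.1, giving $525 on a $250 base).
#'
#' @param enrollment_fee base fee (AUD).
#' @param alt_fee_factor inflation factor for the alternative face-to-face
#'   fee structure.
#' @param policy a [wage_policy()].
#' @param in_work_hours named per-arm in-work hours.
#' @param enrolled class size.
#' @return a list of scenario descriptors consumed by
#'   [cea_sensitivity_table()].
#' @export
default_cea_scenarios <- function(enrollment_fee = 250, alt_fee_factor = 2.1,
                                  policy = wage_policy(),
                                  in_work_hours = c(face_to_face = 8,
                                                    web = 9.6),
                                  enrolled = 20) {
  base <- function(label, timing, fee_by_service, backfill,
                   equal_attrition = FALSE, fee = enrollment_fee) {
    list(label = label, timing = timing, fee_paid_by_service = fee_by_service,
         backfill = backfill, equal_attrition = equal_attrition,
         enrollment_fee = fee, policy = policy,
         in_work_hours = in_work_hours, enrolled = enrolled)
  }
  alt_fee <- c(face_to_face = round_half_up(enrollment_fee * alt_fee_factor,
                                            2),
               web = enrollment_fee)
  list(
    base("leisure, fee by participant", "leisure", FALSE, FALSE),
    base("leisure, fee by service", "leisure", TRUE, FALSE),
    base("working hours, fee by service", "working_hours", TRUE, TRUE),
    base("working hours, fee by participant", "working_hours", FALSE, TRUE),
    base("unpaid leave, fee by service", "unpaid_leave", TRUE, FALSE),
    base("unpaid leave, fee by participant", "unpaid_leave", FALSE, FALSE),
    base("leisure, fee by participant, equal attrition", "leisure", FALSE,
         FALSE, equal_attrition = TRUE),
    base("leisure, fee by service, alternative f2f fee", "leisure", TRUE,
         FALSE, fee = alt_fee)
  )
}

#' Cost-effectiveness sensitivity table
#'
#' Evaluates both arms' service costs and the incremental cost per QASE for
#' each scenario in a list (see [default_cea_scenarios()] for the standard
#' grid). The equal-attrition variant forces the second arm's completers to
#' match the first and recomputes its QASE from its own mean grade (unless
#' the record carries an explicit QASE override, which is preserved).
#'
#' @param arms named list with elements `face_to_face` and `web`, each a
#'   [qase_record()].
#' @param scenarios list of scenario descriptors (as built by
#'   [default_cea_scenarios()]).
#' @return a tibble, one row per scenario: flags, completers, QASE, per-arm
#'   costs, `icer_ratio`, `dominance`, `preferred_arm` and a formatted
#'   `icer_note`.
#' @export
cea_sensitivity_table <- function(arms, scenarios = default_cea_scenarios()) {
  if (!all(c("face_to_face", "web") %in% names(arms))) {
    stop("arms must be a named list with face_to_face and web qase_records",
         call. = FALSE)
  }
  rows <- lapply(scenarios, function(sc) {
    f2f <- arms$face_to_face
    web <- arms$web
    if (isTRUE(sc$equal_attrition)) {
      web <- qase_record(web$enrolled, f2f$completers, web$mean_grade,
                         qase = if (web$qase_overridden) web$qase)
    }
    s <- cea_scenario(sc$timing, sc$fee_paid_by_service, sc$backfill,
                      policy = sc$policy, in_work_hours = sc$in_work_hours,
                      enrollment_fee = sc$enrollment_fee,
                      enrolled = sc$enrolled)
    cost_f2f <- service_cost("face_to_face", s)
    cost_web <- service_cost("web", s)
    ic <- icer(cost_f2f, cost_web, f2f$qase, web$qase)
    note <- if (ic$dominance == "equal_cost" && !is.na(ic$preferred_arm)) {
      sprintf("0 (%s preferred due to higher QASE)", ic$preferred_arm)
    } else if (is.na(ic$ratio)) {
      sprintf("%s dominant (cheaper, equal QASE)", ic$preferred_arm)
    } else {
      fmt_money(ic$ratio)
    }
    tibble::tibble(
      label = sc$label, timing = sc$timing,
      fee_paid_by_service = sc$fee_paid_by_service, backfill = sc$backfill,
      enrolled = sc$enrolled,
      completers_f2f = f2f$completers, completers_web = web$completers,
      qase_f2f = round_half_up(f2f$qase, 2),
      qase_web = round_half_up(web$qase, 2),
      cost_f2f = cost_f2f, cost_web = cost_web,
      icer_ratio = ic$ratio, dominance = ic$dominance,
      preferred_arm = ic$preferred_arm, icer_note = note
    )
  })
  do.call(rbind, rows)
}
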