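#' Itemized cost line
#'
#' One cost item of a delivery mode's cost structure. Amounts are AUD and
#' are kept exact to cents. `recurrence` distinguishes costs incurred once
#' per class delivered ("per-class-fixed", e.g. venue rental, facilitator
#' contract) from costs incurred per enrolled participant
#' ("per-participant-variable", e.g. catering, consumables).
#'
#' @param name short label for the item.
#' @param amount non-negative amount in AUD.
#' @param recurrence `"per-class-fixed"` or `"per-participant-variable"`.
#' @param payer who bears the cost: `"provider"`, `"health_service"` or
#'   `"participant"`.
#' @return an object of class `cost_item`.
#' @export
cost_item <- function(name, amount,
                      recurrence = c("per-class-fixed",
                                     "per-participant-variable"),
                      payer = c("provider", "health_service", "participant")) {
  recurrence <- match.arg(recurrence)
  payer <- match.arg(payer)
  check_nonneg(amount, "amount")
  structure(
    list(name = as.character(name),
         amount = round_half_up(amount, 2),
         recurrence = recurrence,
         payer = payer),
    class = "cost_item"
  )
}

#' Cost structure for one delivery mode
#'
#' Bundles the itemized fixed and variable costs of a delivery mode with its
#' class capacity and the facilitator contract (hours and hourly rate; the
#' facilitator remuneration itself is carried once inside `items`, the
#' contract fields exist so sensitivity sweeps can recompute it).
#'
#' @param mode `"face_to_face"` or `"web"`.
#' @param items list of [cost_item()] objects, non-empty.
#' @param class_capacity maximum participants per class (>= 1).
#' @param facilitator_hours contracted facilitator hours.
#' @param facilitator_rate facilitator hourly rate (AUD/h).
#' @return an object of class `delivery_cost_structure`.
#' @seealso [fixed_and_variable_totals()], [read_cost_structures()]
#' @export
delivery_cost_structure <- function(mode = c("face_to_face", "web"), items,
                                    class_capacity,
                                    facilitator_hours = NA_real_,
                                    facilitator_rate = NA_real_) {
  mode <- match.arg(mode)
  if (!is.list(items) || length(items) == 0) {
    stop("items must be a non-empty list of cost_item objects", call. = FALSE)
  }
  ok <- vapply(items, inherits, logical(1), what = "cost_item")
  if (!all(ok)) stop("all items must be cost_item objects", call. = FALSE)
  if (!is.numeric(class_capacity) || class_capacity < 1) {
    stop("class_capacity must be >= 1", call. = FALSE)
  }
  structure(
    list(mode = mode, items = items,
         class_capacity = as.integer(class_capacity),
         facilitator_hours = facilitator_hours,
         facilitator_rate = facilitator_rate),
    class = "delivery_cost_structure"
  )
}

#' Wage valuation policy
#'
#' The hourly wage used as the opportunity-cost proxy for participant time
#' (default AUD $45/h, an early-career physiotherapist rate), the employer
#' on-cost loading applied in health-service-perspective costs (default 17%,
#' i.e. multiplier 1.17), and the penalty loading applied when participation
#' occurs outside regular hours (default time-and-a-half, 1.5).
#'
#' @param base_rate hourly wage, AUD/h.
#' @param on_cost_multiplier employer on-cost multiplier, >= 1.
#' @param penalty_loading out-of-hours loading multiplier, >= 1.
#' @return an object of class `wage_policy`.
#' @export
wage_policy <- function(base_rate = 45, on_cost_multiplier = 1.17,
                        penalty_loading = 1.5) {
  if (base_rate <= 0 || on_cost_multiplier < 1 || penalty_loading < 1) {
    stop("base_rate must be > 0; multipliers must be >= 1", call. = FALSE)
  }
  structure(
    list(base_rate = base_rate, on_cost_multiplier = on_cost_multiplier,
         penalty_loading = penalty_loading),
    class = "wage_policy"
  )
}

#' Course time profiles per delivery mode
#'
#' Hours spent on the course enter the analyses at two different bases: the
#' in-work contact hours used in health-service costing (8 h face-to-face;
#' Web adds 1.6 h of extra engagement with learning resources) and the total
#' participant time used in participant costing (12 h and 14.4 h by default).
#' Both bases are configurable because different perspectives value different
#' slices of the time commitment.
#'
#' @param contact_hours_f2f face-to-face contact hours.
#' @param extra_hours_web additional Web engagement hours beyond the
#'   face-to-face contact time.
#' @param participant_total_hours_f2f total participant hours, face-to-face.
#' @param participant_total_hours_web total participant hours, Web.
#' @return an object of class `time_profile`.
#' @export
time_profile <- function(contact_hours_f2f = 8, extra_hours_web = 1.6,
                         participant_total_hours_f2f = 12,
                         participant_total_hours_web = 14.4) {
  vals <- c(contact_hours_f2f, extra_hours_web,
            participant_total_hours_f2f, participant_total_hours_web)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all hours must be non-negative", call. = FALSE)
  }
  structure(
    list(contact_hours_f2f = contact_hours_f2f,
         extra_hours_web = extra_hours_web,
         participant_total_hours_f2f = participant_total_hours_f2f,
         participant_total_hours_web = participant_total_hours_web),
    class = "time_profile"
  )
}

#' Wage cost of a block of hours
#'
#' Values time at the policy wage, optionally loaded with employer on-costs
#' (health-service perspective) and/or the out-of-hours penalty loading.
#' Result is exact to cents.
#'
#' @param hours non-negative hours.
#' @param policy a [wage_policy()].
#' @param apply_on_costs apply the on-cost multiplier?
#' @param apply_penalty apply the penalty (out-of-hours) loading?
#' @return monetary cost, AUD, rounded half-up to cents.
#' @examples
#' wage_cost(8, wage_policy(), apply_on_costs = TRUE)   # 421.20
#' wage_cost(12, wage_policy())                         # 540.00
#' @export
wage_cost <- function(hours, policy = wage_policy(),
                      apply_on_costs = FALSE, apply_penalty = FALSE) {
  if (!is.numeric(hours) || length(hours) != 1 || is.na(hours) || hours < 0) {
    stop("hours must be a single non-negative number", call. = FALSE)
  }
  stopifnot(inherits(policy, "wage_policy"))
  x <- hours * policy$base_rate
  if (isTRUE(apply_on_costs)) x <- x * policy$on_cost_multiplier
  if (isTRUE(apply_penalty)) x <- x * policy$penalty_loading
  round_half_up(x, 2)
}

#' Fixed and variable cost totals of a cost structure
#'
#' Sums the per-class-fixed and per-participant-variable items of a
#' delivery mode's cost structure.
#'
#' @param structure a [delivery_cost_structure()].
#' @return named numeric vector `c(fixed = ..., variable = ...)` in AUD.
#' @examples
#' s <- default_cost_structures()$web
#' fixed_and_variable_totals(s)   # fixed 1590, variable 8
#' @export
fixed_and_variable_totals <- function(structure) {
  stopifnot(inherits(structure, "delivery_cost_structure"))
  rec <- vapply(structure$items, `[[`, character(1), "recurrence")
  bad <- setdiff(rec, c("per-class-fixed", "per-participant-variable"))
  if (length(bad)) stop("unknown recurrence tag: ", bad[1], call. = FALSE)
  amt <- vapply(structure$items, `[[`, numeric(1), "amount")
  c(fixed = round_half_up(sum(amt[rec == "per-class-fixed"]), 2),
    variable = round_half_up(sum(amt[rec == "per-participant-variable"]), 2))
}

#' Cumulative fixed cost with capacity-stepped replication
#'
#' Fixed costs are incurred once per class; each time enrollment exceeds a
#' multiple of class capacity a new class must be opened and the per-class
#' fixed cost replicates. The result is a non-decreasing step function of
#' enrollments with steps at capacity multiples + 1, and 0 for zero
#' enrollments (no class is opened).
#'
#' @param enrollments number of enrolled participants (>= 0).
#' @param fixed_per_class fixed cost per class, AUD.
#' @param capacity class capacity (>= 1).
#' @return total fixed cost, AUD.
#' @examples
#' cumulative_fixed_cost(20, 3060, 20)   # 3060
#' cumulative_fixed_cost(21, 3060, 20)   # 6120
#' @export
cumulative_fixed_cost <- function(enrollments, fixed_per_class, capacity) {
  if (!is.numeric(capacity) || capacity < 1) {
    stop("capacity must be >= 1", call. = FALSE)
  }
  if (!is.numeric(enrollments) || any(enrollments < 0)) {
    stop("enrollments must be >= 0", call. = FALSE)
  }
  check_nonneg(fixed_per_class, "fixed_per_class")
  round_half_up(fixed_per_class * ceiling(enrollments / capacity), 2)
}

#' Read itemized cost structures from a configuration file
#'
#' Parses a YAML file with one top-level entry per delivery mode, each
#' holding `class_capacity`, optional `facilitator_hours`/`facilitator_rate`,
#' and an `items` list of `{name, amount, recurrence, payer}` records. A
#' packaged fixture (`system.file("extdata", "course_costs.yaml",
#' package = "eduecon")`) encodes the study's cost tables.
#'
#' @param path path to the YAML file.
#' @return named list of [delivery_cost_structure()] objects.
#' @export
read_cost_structures <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(mode) {
    m <- cfg[[mode]]
    items <- lapply(m$items, function(it) {
      cost_item(it$name, it$amount, it$recurrence, it$payer)
    })
    delivery_cost_structure(
      mode = mode, items = items, class_capacity = m$class_capacity,
      facilitator_hours = m$facilitator_hours %||% NA_real_,
      facilitator_rate = m$facilitator_rate %||% NA_real_
    )
  })
  names(out) <- names(cfg)
  out
}

#' Default cost structures for the two delivery modes
#'
#' Loads the packaged itemization: face-to-face (venue 1000, presentation
#' equipment 500, facilitator 810, ICT support 500, administration 250 fixed;
#' catering 25, stationery 5, DVD 5 per participant) and Web (facilitator
#' 840, ICT support 500, administration 250 fixed; stationery 3, DVD 5 per
#' participant), both at class capacity 20.
#'
#' @return named list with elements `face_to_face` and `web`.
#' @export
default_cost_structures <- function() {
  read_cost_structures(
    system.file("extdata", "course_costs.yaml", package = "eduecon",
                mustWork = TRUE)
  )
}

#' @export
print.delivery_cost_structure <- function(x, ...) {
  tot <- fixed_and_variable_totals(x)
  cat(sprintf("<delivery_cost_structure: %s>\n", x$mode))
  for (it in x$items) {
    cat(sprintf("  %-28s %9s  %s\n", it$name, fmt_money(it$amount),
                it$recurrence))
  }
  cat(sprintf("  fixed/class %s  variable/participant %s  capacity %d\n",
              fmt_money(tot[["fixed"]]), fmt_money(tot[["variable"]]),
              x$class_capacity))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
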