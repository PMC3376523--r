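#' Break-even scenario (provider perspective)
#'
#' Parameters of one provider-perspective break-even evaluation: per-class
#' fixed cost FC, per-participant variable cost VC, enrollment fee S, class
#' capacity, and the enrollment range scanned. FC can be supplied directly or
#' decomposed into a facilitator contract (`facilitator_hours` x
#' `facilitator_rate`) plus `other_fixed`; the decomposition is required for
#' sensitivity sweeps over the facilitator axes.
#'
#' @param fixed_per_class per-class fixed cost FC (AUD). If `NULL`, computed
#'   as `facilitator_hours * facilitator_rate + other_fixed`.
#' @param variable_per_participant per-participant variable cost VC (AUD).
#' @param enrollment_fee fee per enrollment S (AUD).
#' @param class_capacity class capacity (>= 1).
#' @param max_enrollments upper end of the scanned enrollment range
#'   (default 60).
#' @param facilitator_hours,facilitator_rate,other_fixed optional FC
#'   decomposition.
#' @return an object of class `breakeven_scenario`.
#' @examples
#' # Web primary scenario: FC = 14 h x $60/h + $750 = 1590
#' breakeven_scenario(facilitator_hours = 14, facilitator_rate = 60,
#'                    other_fixed = 750, variable_per_participant = 8,
#'                    enrollment_fee = 250, class_capacity = 20)
#' @export
breakeven_scenario <- function(fixed_per_class = NULL,
                               variable_per_participant,
                               enrollment_fee,
                               class_capacity,
                               max_enrollments = 60,
                               facilitator_hours = NULL,
                               facilitator_rate = NULL,
                               other_fixed = NULL) {
  if (is.null(fixed_per_class)) {
    if (is.null(facilitator_hours) || is.null(facilitator_rate) ||
        is.null(other_fixed)) {
      stop("supply fixed_per_class or all of facilitator_hours, ",
           "facilitator_rate, other_fixed", call. = FALSE)
    }
    fixed_per_class <- facilitator_hours * facilitator_rate + other_fixed
  }
  check_nonneg(fixed_per_class, "fixed_per_class")
  check_nonneg(variable_per_participant, "variable_per_participant")
  check_nonneg(enrollment_fee, "enrollment_fee")
  if (class_capacity < 1) stop("class_capacity must be >= 1", call. = FALSE)
  if (max_enrollments < 1) stop("max_enrollments must be >= 1", call. = FALSE)
  structure(
    list(fixed_per_class = round_half_up(fixed_per_class, 2),
         variable_per_participant = round_half_up(variable_per_participant, 2),
         enrollment_fee = round_half_up(enrollment_fee, 2),
         class_capacity = as.integer(class_capacity),
         max_enrollments = as.integer(max_enrollments),
         facilitator_hours = facilitator_hours,
         facilitator_rate = facilitator_rate,
         other_fixed = other_fixed),
    class = "breakeven_scenario"
  )
}

#' Scenario from a cost structure
#'
#' Builds a [breakeven_scenario()] from an itemized
#' [delivery_cost_structure()] and a fee.
#'
#' @param structure a [delivery_cost_structure()].
#' @param enrollment_fee fee per enrollment (AUD).
#' @param max_enrollments scanned range upper end.
#' @return a `breakeven_scenario`.
#' @export
breakeven_scenario_from_costs <- function(structure, enrollment_fee,
                                          max_enrollments = 60) {
  tot <- fixed_and_variable_totals(structure)
  other <- tot[["fixed"]]
  h <- structure$facilitator_hours
  r <- structure$facilitator_rate
  if (is.finite(h) && is.finite(r)) other <- other - h * r
  breakeven_scenario(
    fixed_per_class = tot[["fixed"]],
    variable_per_participant = tot[["variable"]],
    enrollment_fee = enrollment_fee,
    class_capacity = structure$class_capacity,
    max_enrollments = max_enrollments,
    facilitator_hours = if (is.finite(h)) h,
    facilitator_rate = if (is.finite(r)) r,
    other_fixed = if (is.finite(h) && is.finite(r)) other
  )
}

#' Net financial position at a given enrollment
#'
#' Fee revenue net of variable costs, minus the capacity-stepped cumulative
#' fixed cost: `q * (S - VC) - FC * ceiling(q / capacity)`. Zero enrollments
#' open no class and return exactly 0.
#'
#' @param enrollments enrollment count, 0..`max_enrollments`.
#' @param scenario a [breakeven_scenario()].
#' @return net position in AUD (negative = loss).
#' @examples
#' web <- breakeven_scenario(1590, 8, 250, 20)
#' net_position(7, web)   #  104: first non-loss-making enrollment
#' net_position(6, web)   # -138
#' @export
net_position <- function(enrollments, scenario) {
  stopifnot(inherits(scenario, "breakeven_scenario"))
  if (!is.numeric(enrollments) || enrollments != floor(enrollments) ||
      enrollments < 0 || enrollments > scenario$max_enrollments) {
    stop("enrollments must be an integer in [0, max_enrollments]",
         call. = FALSE)
  }
  margin <- scenario$enrollment_fee - scenario$variable_per_participant
  round_half_up(
    enrollments * margin -
      cumulative_fixed_cost(enrollments, scenario$fixed_per_class,
                            scenario$class_capacity),
    2
  )
}

#' Profitability segments by exhaustive integer scan
#'
#' Scans every enrollment count q = 1..`max_enrollments` and returns the
#' maximal runs over which the net position is non-negative (a net of
#' exactly zero counts as break-even). Because fixed costs replicate each
#' time a class fills, a course that has broken even can fall back into loss
#' when the next class opens, producing multiple segments.
#'
#' @param scenario a [breakeven_scenario()].
#' @return an object of class `profitability_segments`: a list with
#'   `segments` (list of `c(start, end)` integer pairs, disjoint and sorted),
#'   `breaks_even` (flag, `FALSE` iff no segment exists) and
#'   `max_enrollments`.
#' @examples
#' breakeven_segments(breakeven_scenario(1590, 8, 250, 20))  # 7-60
#' breakeven_segments(breakeven_scenario(3060, 35, 250, 20)) # three segments
#' @export
breakeven_segments <- function(scenario) {
  stopifnot(inherits(scenario, "breakeven_scenario"))
  q <- seq_len(scenario$max_enrollments)
  net <- vapply(q, net_position, numeric(1), scenario = scenario)
  ok <- net >= 0
  segs <- list()
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i]) segs[[length(segs) + 1L]] <- c(starts[i], ends[i])
  }
  structure(
    list(segments = segs, breaks_even = length(segs) > 0,
         max_enrollments = scenario$max_enrollments),
    class = "profitability_segments"
  )
}

#' Format profitability segments in table notation
#'
#' Renders segments as "a–b; c–d" (en dash ranges); a segment whose
#' start equals its end prints the single number; no segments prints
#' "does not break even".
#'
#' @param x a `profitability_segments` object.
#' @param ... unused.
#' @return a single character string.
#' @export
format.profitability_segments <- function(x, ...) {
  if (!x$breaks_even) return("does not break even")
  paste(vapply(x$segments, function(s) {
    if (s[1] == s[2]) as.character(s[1]) else paste0(s[1], "–", s[2])
  }, character(1)), collapse = "; ")
}

#' @export
print.profitability_segments <- function(x, ...) {
  cat("<profitability_segments> ", format(x), "\n", sep = "")
  invisible(x)
}

#' First break-even enrollment
#'
#' Convenience accessor: the start of the first profitability segment, or
#' `NA` when the scenario never breaks even.
#'
#' @param scenario a [breakeven_scenario()].
#' @return integer enrollment count or `NA`.
#' @export
first_breakeven <- function(scenario) {
  seg <- breakeven_segments(scenario)
  if (!seg$breaks_even) return(NA_integer_)
  as.integer(seg$segments[[1]][1])
}

#' Break-even point by the rounded-ratio convention
#'
#' Legacy single-class mode: Q = FC / (S - VC), rounded half-up to the
#' nearest integer. This is the convention behind most headline single-number
#' break-even points in published tables; it ignores fixed-cost replication
#' and can differ by one from the exact integer scan (e.g. 3060/215 = 14.23
#' rounds to 14 while the scan finds 15). `NA` when the margin S - VC is not
#' positive.
#'
#' @param scenario a [breakeven_scenario()].
#' @return integer count or `NA`.
#' @export
breakeven_rounded_ratio <- function(scenario) {
  stopifnot(inherits(scenario, "breakeven_scenario"))
  margin <- scenario$enrollment_fee - scenario$variable_per_participant
  if (margin <= 0) return(NA_integer_)
  as.integer(round_half_up(scenario$fixed_per_class / margin, 0))
}

#' One-way sensitivity sweep over a break-even scenario
#'
#' Varies a single parameter across the supplied values, holding all others
#' at the base scenario, and solves each resulting scenario. The facilitator
#' axes recompute FC as `hours * rate + other_fixed` and therefore require a
#' base scenario built with the FC decomposition; `all_costs_scale`
#' multiplies FC and VC jointly (fee untouched).
#'
#' @param base a [breakeven_scenario()].
#' @param axis one of `"facilitator_hours"`, `"facilitator_rate"`,
#'   `"class_capacity"`, `"enrollment_fee"`, `"all_costs_scale"`.
#' @param values numeric vector of axis values.
#' @return a tibble with one row per value: `axis`, `value`, the resolved
#'   `fixed_per_class`/`variable_per_participant`/`enrollment_fee`/
#'   `class_capacity`, `segments` (formatted), `breaks_even`,
#'   `first_breakeven`, `rounded_ratio`, and a `segments_list` list-column.
#' @examples
#' web <- breakeven_scenario(facilitator_hours = 14, facilitator_rate = 60,
#'                           other_fixed = 750, variable_per_participant = 8,
#'                           enrollment_fee = 250, class_capacity = 20)
#' sensitivity_sweep(web, "class_capacity", c(10, 30, 40, 50, 60))
#' @export
sensitivity_sweep <- function(base, axis, values) {
  stopifnot(inherits(base, "breakeven_scenario"))
  axes <- c("facilitator_hours", "facilitator_rate", "class_capacity",
            "enrollment_fee", "all_costs_scale")
  if (!is.character(axis) || length(axis) != 1 || !axis %in% axes) {
    stop("unknown axis: ", axis, "; must be one of ",
         paste(axes, collapse = ", "), call. = FALSE)
  }
  if (axis %in% c("facilitator_hours", "facilitator_rate") &&
      (is.null(base$facilitator_hours) || is.null(base$facilitator_rate) ||
       is.null(base$other_fixed))) {
    stop("facilitator axes need a base scenario with the FC decomposition ",
         "(facilitator_hours, facilitator_rate, other_fixed)", call. = FALSE)
  }
  rows <- lapply(values, function(v) {
    s <- base
    if (axis == "facilitator_hours") {
      s$facilitator_hours <- v
      s$fixed_per_class <- v * s$facilitator_rate + s$other_fixed
    } else if (axis == "facilitator_rate") {
      s$facilitator_rate <- v
      s$fixed_per_class <- s$facilitator_hours * v + s$other_fixed
    } else if (axis == "class_capacity") {
      s$class_capacity <- as.integer(v)
    } else if (axis == "enrollment_fee") {
      s$enrollment_fee <- v
    } else { # all_costs_scale
      s$fixed_per_class <- round_half_up(s$fixed_per_class * v, 2)
      s$variable_per_participant <-
        round_half_up(s$variable_per_participant * v, 2)
    }
    seg <- breakeven_segments(s)
    tibble::tibble(
      axis = axis, value = v,
      fixed_per_class = s$fixed_per_class,
      variable_per_participant = s$variable_per_participant,
      enrollment_fee = s$enrollment_fee,
      class_capacity = s$class_capacity,
      segments = format(seg),
      breaks_even = seg$breaks_even,
      first_breakeven = if (seg$breaks_even)
        as.integer(seg$segments[[1]][1]) else NA_integer_,
      rounded_ratio = breakeven_rounded_ratio(s),
      segments_list = list(seg$segments)
    )
  })
  do.call(rbind, rows)
}

#' Cost and savings curves over the enrollment range
#'
#' The data series behind a cost-versus-savings plot: for each enrollment
#' count, cumulative cost (stepped fixed plus variable) and cumulative
#' savings (fee revenue).
#'
#' @param scenario a [breakeven_scenario()].
#' @return a tibble with columns `enrollments`, `cost`, `savings`, `net`.
#' @export
breakeven_curve <- function(scenario) {
  stopifnot(inherits(scenario, "breakeven_scenario"))
  q <- 0:scenario$max_enrollments
  cost <- cumulative_fixed_cost(q, scenario$fixed_per_class,
                                scenario$class_capacity) +
    round_half_up(q * scenario$variable_per_participant, 2)
  savings <- round_half_up(q * scenario$enrollment_fee, 2)
  tibble::tibble(enrollments = q, cost = cost, savings = savings,
                 net = round_half_up(savings - cost, 2))
}
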