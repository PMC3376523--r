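# Shared fixtures and independent oracles, built in code.

# itemized costs for the two delivery modes (class capacity 20)
f2f_items <- function() {
  list(
    cost_item("venue", 1000, "per-class-fixed", "provider"),
    cost_item("presentation equipment", 500, "per-class-fixed", "provider"),
    cost_item("facilitator", 810, "per-class-fixed", "provider"),
    cost_item("ICT support", 500, "per-class-fixed", "provider"),
    cost_item("administration", 250, "per-class-fixed", "provider"),
    cost_item("catering", 25, "per-participant-variable", "provider"),
    cost_item("stationery", 5, "per-participant-variable", "provider"),
    cost_item("DVD", 5, "per-participant-variable", "provider")
  )
}

web_items <- function() {
  list(
    cost_item("facilitator", 840, "per-class-fixed", "provider"),
    cost_item("ICT support", 500, "per-class-fixed", "provider"),
    cost_item("administration", 250, "per-class-fixed", "provider"),
    cost_item("stationery", 3, "per-participant-variable", "provider"),
    cost_item("DVD", 5, "per-participant-variable", "provider")
  )
}

# primary break-even scenarios, with the facilitator decomposition so the
# sweep axes are available
web_primary <- function() {
  breakeven_scenario(facilitator_hours = 14, facilitator_rate = 60,
                     other_fixed = 750, variable_per_participant = 8,
                     enrollment_fee = 250, class_capacity = 20)
}

f2f_primary <- function() {
  breakeven_scenario(facilitator_hours = 9, facilitator_rate = 90,
                     other_fixed = 2250, variable_per_participant = 35,
                     enrollment_fee = 250, class_capacity = 20)
}

# Independent brute-force profitability scanner: counts classes by repeated
# subtraction (no ceiling), accumulates runs with an explicit state machine.
# Deliberately written differently from the package's rle-based scan.
naive_segments <- function(fixed, variable, fee, capacity, max_q) {
  segs <- list()
  run_start <- NA_integer_
  for (q in seq_len(max_q)) {
    classes <- 0L
    left <- q
    while (left > 0) {
      classes <- classes + 1L
      left <- left - capacity
    }
    net <- q * fee - q * variable - classes * fixed
    # all inputs sit on the cents grid, so the exact net is a multiple of
    # 0.01; the tolerance only absorbs binary round-off around exact zero
    if (net >= -1e-6) {
      if (is.na(run_start)) run_start <- q
    } else if (!is.na(run_start)) {
      segs[[length(segs) + 1L]] <- c(run_start, q - 1L)
      run_start <- NA_integer_
    }
  }
  if (!is.na(run_start)) segs[[length(segs) + 1L]] <- c(run_start, max_q)
  segs
}

# random but valid break-even scenario, on a cents grid
random_scenario <- function() {
  breakeven_scenario(
    fixed_per_class = round(stats::runif(1, 0, 5000), 2),
    variable_per_participant = round(stats::runif(1, 0, 300), 2),
    enrollment_fee = round(stats::runif(1, 0, 400), 2),
    class_capacity = sample(1:25, 1),
    max_enrollments = 60
  )
}

# set of profitable enrollment counts (for monotonicity comparisons)
profitable_set <- function(scenario) {
  seg <- breakeven_segments(scenario)
  unlist(lapply(seg$segments, function(s) seq(s[1], s[2])))
}

# two-pass mean/SD oracle
naive_mean_sd <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- sum(x) / n
  list(n = n, mean = m,
       sd = if (n > 1) sqrt(sum((x - m)^2) / (n - 1)) else NA_real_)
}

# Pearson correlation from first principles (for hand-ranked Spearman)
pearson_by_hand <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}
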