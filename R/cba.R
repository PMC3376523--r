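#' Itemized participant expense
#'
#' Assembles the out-of-pocket and opportunity costs borne by one
#' participant: Internet download costs (Web arm only; broadband $20 or
#' satellite $25 by default), transport ($20, face-to-face arm only), the
#' enrollment fee, and the opportunity cost of time valued at the policy
#' wage without on-costs (on-costs are an employer overhead, irrelevant from
#' the participant's perspective). Leisure-time participation applies the
#' time-and-a-half penalty loading to the time cost.
#'
#' @param arm `"face_to_face"` or `"web"`.
#' @param fee enrollment fee (AUD).
#' @param time_hours total participant hours on the course.
#' @param policy a [wage_policy()].
#' @param timing `"working_hours"`, `"unpaid_leave"` or `"leisure"`.
#' @param internet_variant `"broadband"` or `"satellite"` (Web arm only).
#' @param download_cost named costs of the two Internet variants.
#' @param transport_cost face-to-face transport cost.
#' @return an object of class `participant_expense`: list with `downloads`,
#'   `transport`, `fee`, `time_cost`, `total` (all AUD, exact to cents).
#' @examples
#' participant_expense("face_to_face", 250, 12)$total            # 810
#' participant_expense("web", 250, 14.4)$total                   # 918
#' participant_expense("web", 250, 14.4,
#'                     internet_variant = "satellite")$total     # 923
#' @export
participant_expense <- function(arm = c("face_to_face", "web"),
                                fee = 250, time_hours,
                                policy = wage_policy(),
                                timing = c("working_hours", "unpaid_leave",
                                           "leisure"),
                                internet_variant = c("broadband",
                                                     "satellite"),
                                download_cost = c(broadband = 20,
                                                  satellite = 25),
                                transport_cost = 20) {
  arm <- match.arg(arm)
  timing <- match.arg(timing)
  internet_variant <- match.arg(internet_variant)
  check_nonneg(fee, "fee")
  check_nonneg(time_hours, "time_hours")
  downloads <- if (arm == "web") download_cost[[internet_variant]] else 0
  transport <- if (arm == "face_to_face") transport_cost else 0
  time_cost <- wage_cost(time_hours, policy, apply_on_costs = FALSE,
                         apply_penalty = (timing == "leisure"))
  structure(
    list(downloads = round_half_up(downloads, 2),
         transport = round_half_up(transport, 2),
         fee = round_half_up(fee, 2),
         time_cost = time_cost,
         total = round_half_up(downloads + transport + fee + time_cost, 2),
         arm = arm, timing = timing),
    class = "participant_expense"
  )
}

#' @export
print.participant_expense <- function(x, ...) {
  cat(sprintf("<participant_expense: %s>\n", x$arm))
  for (f in c("downloads", "transport", "fee", "time_cost", "total")) {
    cat(sprintf("  %-10s %9s\n", f, fmt_money(x[[f]])))
  }
  invisible(x)
}

#' Willingness-to-pay responses in long form
#'
#' Reshapes a participant-level cohort table (wide, one `wtp_c1`..`wtp_c4`
#' column per context) into one row per participant-context with columns
#' `id`, `arm`, `context`, `amount`, `satisfaction`.
#'
#' @param cohort a participant-level table as produced by
#'   [generate_cohort()] or [read_participant_table()].
#' @return a tibble in long form.
#' @export
wtp_long <- function(cohort) {
  cols <- paste0("wtp_c", 1:4)
  missing_cols <- setdiff(c("id", "arm", "satisfaction", cols),
                          names(cohort))
  if (length(missing_cols)) {
    stop("cohort table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- lapply(1:4, function(ctx) {
    tibble::tibble(id = cohort$id, arm = cohort$arm, context = ctx,
                   amount = cohort[[cols[ctx]]],
                   satisfaction = cohort$satisfaction)
  })
  do.call(rbind, out)
}

#' Mean stated willingness to pay for one arm and context
#'
#' Arithmetic mean and sample standard deviation over the non-missing
#' stated amounts. Respondent counts vary by context because participants
#' could skip fields; missing amounts are dropped, never imputed.
#'
#' @param responses long-form WTP table (see [wtp_long()]).
#' @param arm `"face_to_face"` or `"web"`.
#' @param context integer 1..4.
#' @return list with `n`, `mean`, `sd` (`mean`/`sd` are `NA` when no
#'   responses exist; `sd` is `NA` for a single response).
#' @examples
#' r <- tibble::tibble(id = 1:3, arm = "web", context = 1,
#'                     amount = c(100, 200, 180), satisfaction = 3)
#' mean_wtp(r, "web", 1)   # n 3, mean 160, sd 52.92
#' @export
mean_wtp <- function(responses, arm, context) {
  if (!context %in% 1:4) stop("context must be in 1..4", call. = FALSE)
  x <- responses$amount[responses$arm == arm &
                          responses$context == context]
  x <- x[!is.na(x)]
  n <- length(x)
  list(n = n,
       mean = if (n > 0) mean(x) else NA_real_,
       sd = if (n > 1) stats::sd(x) else NA_real_)
}

#' Net benefit of face-to-face over Web delivery
#'
#' Participant-perspective comparison: net benefit = (mean benefit
#' face-to-face - mean cost face-to-face) - (mean benefit Web - mean cost
#' Web), with benefit measured by stated willingness to pay. Positive values
#' favor face-to-face delivery.
#'
#' @param benefit_f2f,cost_f2f mean benefit and cost per face-to-face
#'   participant (AUD).
#' @param benefit_web,cost_web mean benefit and cost per Web participant.
#' @return an object of class `net_benefit_result`: list with `benefit`
#'   and `cost` (named per-arm vectors) and `net_benefit` (AUD, positive
#'   favors face-to-face).
#' @examples
#' net_benefit(200, 810, 160, 918)$net_benefit   # 148
#' @export
net_benefit <- function(benefit_f2f, cost_f2f, benefit_web, cost_web) {
  nb <- (benefit_f2f - cost_f2f) - (benefit_web - cost_web)
  structure(
    list(benefit = c(face_to_face = benefit_f2f, web = benefit_web),
         cost = c(face_to_face = cost_f2f, web = cost_web),
         net_benefit = round_half_up(nb, 2)),
    class = "net_benefit_result"
  )
}

#' @export
print.net_benefit_result <- function(x, ...) {
  cat("<net_benefit_result>\n")
  cat(sprintf("  face_to_face: benefit %s - cost %s\n",
              fmt_money(x$benefit[["face_to_face"]]),
              fmt_money(x$cost[["face_to_face"]])))
  cat(sprintf("  web:          benefit %s - cost %s\n",
              fmt_money(x$benefit[["web"]]), fmt_money(x$cost[["web"]])))
  cat(sprintf("  net benefit %s (positive favors face-to-face)\n",
              fmt_money(x$net_benefit)))
  invisible(x)
}

#' Construct validity of willingness-to-pay responses
#'
#' If stated willingness to pay measures perceived benefit, it should rise
#' with overall course satisfaction. This computes, per context, the
#' Spearman rank correlation (average-rank tie handling) between stated
#' amount and satisfaction rating over pairs with both fields present,
#' with a two-sided significance probability (exact permutation
#' distribution for n <= 10 without ties, t approximation otherwise).
#'
#' @param responses long-form WTP table (see [wtp_long()]); rows missing
#'   either field are dropped per context.
#' @param min_n contexts with fewer complete pairs than this yield an
#'   empty-result row (`NA` rho) rather than an error.
#' @return a tibble with columns `context`, `n`, `rho`, `p_value`. `rho` is
#'   `NA` when a context has fewer than `min_n` pairs or zero rank variance
#'   in either variable.
#' @export
wtp_construct_validity <- function(responses, min_n = 3) {
  rows <- lapply(1:4, function(ctx) {
    d <- responses[responses$context == ctx &
                     !is.na(responses$amount) &
                     !is.na(responses$satisfaction), , drop = FALSE]
    n <- nrow(d)
    if (n < min_n) {
      return(tibble::tibble(context = ctx, n = n, rho = NA_real_,
                            p_value = NA_real_))
    }
    rx <- rank(d$amount)
    ry <- rank(d$satisfaction)
    if (stats::var(rx) == 0 || stats::var(ry) == 0) {
      return(tibble::tibble(context = ctx, n = n, rho = NA_real_,
                            p_value = NA_real_))
    }
    rho <- stats::cor(rx, ry)
    has_ties <- anyDuplicated(d$amount) > 0 ||
      anyDuplicated(d$satisfaction) > 0
    p <- if (n <= 10 && !has_ties) {
      stats::cor.test(d$amount, d$satisfaction, method = "spearman",
                      exact = TRUE)$p.value
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tt), df = n - 2)
    }
    tibble::tibble(context = ctx, n = n, rho = rho, p_value = min(p, 1))
  })
  do.call(rbind, rows)
}

#' Default participant cost-benefit sensitivity scenarios
#'
#' The standard expense sensitivity block: fee scalings (+50%, +100%,
#' +200%, -50%), all-cost scalings (+/-25%, +/-50%), and the
#' satellite-Internet variant for the Web arm.
#'
#' @return list of scenario descriptors for [cba_sensitivity_table()].
#' @export
default_cba_scenarios <- function() {
  list(
    list(label = "primary"),
    list(label = "fee +50%", fee_scale = 1.5),
    list(label = "fee +100%", fee_scale = 2),
    list(label = "fee +200%", fee_scale = 3),
    list(label = "fee -50%", fee_scale = 0.5),
    list(label = "all costs +25%", cost_scale = 1.25),
    list(label = "all costs +50%", cost_scale = 1.5),
    list(label = "all costs -25%", cost_scale = 0.75),
    list(label = "all costs -50%", cost_scale = 0.5),
    list(label = "satellite Internet", internet_variant = "satellite"),
    list(label = "leisure time", timing = "leisure")
  )
}

#' Participant cost-benefit sensitivity table
#'
#' Recomputes itemized participant expenses, and the net benefit of
#' face-to-face over Web, for each scenario. Every row is rebuilt from
#' components (fee scaling applies to the fee item, cost scaling applies to
#' every component, timing changes re-derive the time cost), never by
#' scaling a previous total.
#'
#' @param fee base enrollment fee (AUD).
#' @param time_hours named per-arm participant hours,
#'   e.g. `c(face_to_face = 12, web = 14.4)`.
#' @param benefit named per-arm mean benefit (mean WTP, AUD); optional —
#'   when `NULL`, net-benefit columns are `NA` and only expenses are
#'   reported.
#' @param policy a [wage_policy()].
#' @param scenarios list of descriptors with optional fields `fee_scale`,
#'   `cost_scale`, `timing`, `internet_variant` (see
#'   [default_cba_scenarios()]).
#' @return a tibble, one row per scenario and arm, with expense components,
#'   `total`, and (when benefits are supplied) `net_benefit` repeated on
#'   both arm rows of a scenario.
#' @export
cba_sensitivity_table <- function(fee = 250,
                                  time_hours = c(face_to_face = 12,
                                                 web = 14.4),
                                  benefit = NULL,
                                  policy = wage_policy(),
                                  scenarios = default_cba_scenarios()) {
  rows <- lapply(scenarios, function(sc) {
    fee_scale <- sc$fee_scale %||% 1
    cost_scale <- sc$cost_scale %||% 1
    timing <- sc$timing %||% "working_hours"
    variant <- sc$internet_variant %||% "broadband"
    exp_arm <- function(arm) {
      e <- participant_expense(arm, fee = fee * fee_scale,
                               time_hours = time_hours[[arm]],
                               policy = policy, timing = timing,
                               internet_variant = variant)
      # all-costs scaling multiplies every component, then re-totals
      comp <- vapply(c("downloads", "transport", "fee", "time_cost"),
                     function(f) round_half_up(e[[f]] * cost_scale, 2),
                     numeric(1))
      c(comp, total = round_half_up(sum(comp), 2))
    }
    f2f <- exp_arm("face_to_face")
    web <- exp_arm("web")
    nb <- if (!is.null(benefit)) {
      net_benefit(benefit[["face_to_face"]], f2f[["total"]],
                  benefit[["web"]], web[["total"]])$net_benefit
    } else NA_real_
    tibble::tibble(
      label = sc$label, arm = c("face_to_face", "web"),
      downloads = c(f2f[["downloads"]], web[["downloads"]]),
      transport = c(f2f[["transport"]], web[["transport"]]),
      fee = c(f2f[["fee"]], web[["fee"]]),
      time_cost = c(f2f[["time_cost"]], web[["time_cost"]]),
      total = c(f2f[["total"]], web[["total"]]),
      net_benefit = nb
    )
  })
  do.call(rbind, rows)
}
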