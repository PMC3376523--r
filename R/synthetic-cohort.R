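#' Synthetic cohort specification for one arm
#'
#' Distributional parameters from which trial-like participant records are
#' generated: enrollment, independent per-participant completion, grades
#' from a normal distribution truncated to \[0, 100\] (completers only),
#' per-context stated willingness to pay from a moment-matched log-normal
#' (non-negative and right-skewed, as stated SDs exceeding means require),
#' and an ordinal satisfaction rating rank-correlated with WTP at a target
#' Spearman rho through a Gaussian copula on a shared latent trait.
#'
#' @param n_enrolled participants beginning the course.
#' @param completion_probability per-participant completion probability.
#' @param grade_mean,grade_sd grade distribution, percent scale.
#' @param wtp_mean,wtp_sd length-4 vectors: stated-WTP mean and SD (AUD)
#'   for the four recognition contexts.
#' @param rho length-4 vector: target Spearman correlation between each
#'   context's WTP and the satisfaction rating.
#' @param satisfaction_levels number of ordinal satisfaction levels.
#' @param wtp_missing per-field probability that a completer leaves a WTP
#'   field blank.
#' @param satisfaction_missing probability the satisfaction rating is blank.
#' @return an object of class `cohort_arm_spec`.
#' @export
cohort_arm_spec <- function(n_enrolled, completion_probability,
                            grade_mean, grade_sd,
                            wtp_mean, wtp_sd, rho,
                            satisfaction_levels = 5,
                            wtp_missing = 0, satisfaction_missing = 0) {
  if (completion_probability < 0 || completion_probability > 1) {
    stop("completion_probability must lie in [0, 1]", call. = FALSE)
  }
  if (grade_sd < 0 || any(wtp_sd < 0)) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (any(abs(rho) > 1)) stop("|rho| must be <= 1", call. = FALSE)
  if (length(wtp_mean) != 4 || length(wtp_sd) != 4 || length(rho) != 4) {
    stop("wtp_mean, wtp_sd and rho must have length 4 (one per context)",
         call. = FALSE)
  }
  if (any(wtp_sd == 0 & wtp_mean > 0)) {
    stop("cannot moment-match a right-skewed WTP distribution with sd = 0",
         call. = FALSE)
  }
  structure(
    list(n_enrolled = as.integer(n_enrolled),
         completion_probability = completion_probability,
         grade_mean = grade_mean, grade_sd = grade_sd,
         wtp_mean = wtp_mean, wtp_sd = wtp_sd, rho = rho,
         satisfaction_levels = as.integer(satisfaction_levels),
         wtp_missing = wtp_missing,
         satisfaction_missing = satisfaction_missing),
    class = "cohort_arm_spec"
  )
}

#' Default synthetic cohort specification
#'
#' The trial's study conditions: 68 face-to-face enrollments with 49
#' completing (grades mean 81.6, SD 9.5) and 67 Web enrollments with 44
#' completing (mean 83.2, SD 9.9); per-context WTP means/SDs as observed in
#' the trial; per-context Spearman targets 0.46, 0.43, 0.53, 0.45 (pooled
#' values, applied to both arms); WTP missingness matching the observed
#' respondent counts (~42% face-to-face, ~24% Web).
#'
#' @param n_scale optional multiplier applied to both arms' enrollments
#'   (e.g. for parameter-recovery studies at larger n).
#' @return named list of two [cohort_arm_spec()]s (`face_to_face`, `web`).
#' @export
default_cohort_spec <- function(n_scale = 1) {
  rho <- c(0.46, 0.43, 0.53, 0.45)
  list(
    face_to_face = cohort_arm_spec(
      n_enrolled = round(68 * n_scale), completion_probability = 49 / 68,
      grade_mean = 81.6, grade_sd = 9.5,
      wtp_mean = c(129.17, 192.26, 199, 314.14),
      wtp_sd = c(117.25, 201.46, 260.83, 423.01),
      rho = rho, wtp_missing = 0.42, satisfaction_missing = 0.10
    ),
    web = cohort_arm_spec(
      n_enrolled = round(67 * n_scale), completion_probability = 44 / 67,
      grade_mean = 83.2, grade_sd = 9.9,
      wtp_mean = c(96.33, 165.57, 159.72, 190.94),
      wtp_sd = c(56.37, 102.16, 103.61, 131.40),
      rho = rho, wtp_missing = 0.24, satisfaction_missing = 0.10
    )
  )
}

# log-normal parameters matching a target mean and sd
lognormal_moments <- function(mean, sd) {
  if (mean <= 0) stop("log-normal moment match needs mean > 0",
                      call. = FALSE)
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# mean and sd of a normal(mu, sigma) truncated to [lo, hi], closed form
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  list(mean = m, sd = sqrt(v))
}

# underlying normal parameters whose [lo, hi]-truncation has the target
# mean and sd (moment matching, so truncation introduces no bias in the
# generated marginal); memoized — repeated cohort draws reuse the solve
.calibration_cache <- new.env(parent = emptyenv())

truncnorm_match <- function(mean, sd, lo, hi) {
  key <- paste("tn", mean, sd, lo, hi, sep = "|")
  if (!is.null(.calibration_cache[[key]])) return(.calibration_cache[[key]])
  obj <- function(par) {
    m <- truncnorm_moments(par[1], exp(par[2]), lo, hi)
    (m$mean - mean)^2 + (m$sd - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  out <- list(mu = fit$par[1], sigma = exp(fit$par[2]))
  .calibration_cache[[key]] <- out
  out
}

# truncated-normal draws on [lo, hi] by inverse-CDF, parameterized by the
# target (post-truncation) mean and sd; degenerate sd = 0 collapses to the
# (clamped) mean
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 100) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  p <- truncnorm_match(mean, sd, lo, hi)
  plo <- stats::pnorm(lo, p$mu, p$sigma)
  phi <- stats::pnorm(hi, p$mu, p$sigma)
  stats::qnorm(stats::runif(n, plo, phi), p$mu, p$sigma)
}

# large-sample Spearman correlation between a standard-normal latent score
# and a K-level equiprobable discretization of a correlated latent (Gaussian
# copula, latent correlation r), using midrank CDF values for the ties
spearman_discretized <- function(r, k) {
  cuts <- stats::qnorm(seq(0, 1, length.out = k + 1))
  g <- (seq_len(k) - 0.5) / k   # midrank fraction of each category
  s <- 0
  for (j in seq_len(k)) {
    f <- function(v) {
      stats::dnorm(v) * stats::pnorm(r * v / sqrt(2 - r^2))
    }
    s <- s + g[j] * stats::integrate(f, cuts[j], cuts[j + 1],
                                     rel.tol = 1e-10)$value
  }
  12 * s - 3
}

# latent correlation that yields the target Spearman rho after the ordinal
# discretization (inverts spearman_discretized)
latent_corr_for_spearman <- function(rho_target, k) {
  if (rho_target == 0) return(0)
  key <- paste("sp", rho_target, k, sep = "|")
  if (!is.null(.calibration_cache[[key]])) return(.calibration_cache[[key]])
  out <- stats::uniroot(function(r) spearman_discretized(r, k) - rho_target,
                        lower = -0.9999, upper = 0.9999, tol = 1e-9)$root
  .calibration_cache[[key]] <- out
  out
}

generate_arm <- function(spec, arm_label, id_offset = 0) {
  n <- spec$n_enrolled
  if (n == 0) {
    return(tibble::tibble(id = character(0), arm = character(0),
                          completed = logical(0), grade = numeric(0),
                          wtp_c1 = numeric(0), wtp_c2 = numeric(0),
                          wtp_c3 = numeric(0), wtp_c4 = numeric(0),
                          satisfaction = integer(0)))
  }
  completed <- stats::runif(n) < spec$completion_probability
  grade <- rtruncnorm(n, spec$grade_mean, spec$grade_sd)
  grade[!completed] <- NA_real_

  # shared latent trait driving both satisfaction and the WTP contexts
  latent <- stats::rnorm(n)
  wtp <- matrix(NA_real_, n, 4)
  for (ctx in 1:4) {
    m <- spec$wtp_mean[ctx]
    if (m == 0) {
      wtp[, ctx] <- 0
      next
    }
    lp <- lognormal_moments(m, spec$wtp_sd[ctx])
    # latent correlation calibrated so the realized Spearman rho against
    # the K-level satisfaction rating hits the target despite the
    # discretization's attenuation
    r <- latent_corr_for_spearman(spec$rho[ctx], spec$satisfaction_levels)
    z <- r * latent + sqrt(1 - r^2) * stats::rnorm(n)
    wtp[, ctx] <- stats::qlnorm(stats::pnorm(z), lp$meanlog, lp$sdlog)
  }
  k <- spec$satisfaction_levels
  satisfaction <- as.integer(cut(stats::pnorm(latent),
                                 breaks = seq(0, 1, length.out = k + 1),
                                 include.lowest = TRUE, labels = FALSE))

  # survey fields exist only for completers; completers may skip fields
  for (ctx in 1:4) {
    drop <- !completed | stats::runif(n) < spec$wtp_missing
    wtp[drop, ctx] <- NA_real_
  }
  satisfaction[!completed |
                 stats::runif(n) < spec$satisfaction_missing] <- NA_integer_

  tibble::tibble(
    id = sprintf("P%05d", id_offset + seq_len(n)),
    arm = arm_label, completed = completed, grade = grade,
    wtp_c1 = wtp[, 1], wtp_c2 = wtp[, 2], wtp_c3 = wtp[, 3],
    wtp_c4 = wtp[, 4], satisfaction = satisfaction
  )
}

#' Generate a synthetic participant-level cohort
#'
#' Draws a two-arm participant table under the given specification.
#' Deterministic for a fixed seed: the same seed always yields the same
#' table. Non-completers carry no grade, WTP or satisfaction fields (they
#' are scored zero only inside the QASE computation, not here).
#'
#' @param spec named list of [cohort_arm_spec()]s, one per arm
#'   (default [default_cohort_spec()]).
#' @param seed integer RNG seed.
#' @return a tibble with columns `id`, `arm`, `completed`, `grade`,
#'   `wtp_c1`..`wtp_c4`, `satisfaction`.
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' summarize_cohort(cohort)
#' @export
generate_cohort <- function(spec = default_cohort_spec(), seed = 1) {
  stopifnot(is.list(spec), length(spec) >= 1, !is.null(names(spec)))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  offset <- 0
  arms <- lapply(names(spec), function(a) {
    tab <- generate_arm(spec[[a]], a, id_offset = offset)
    offset <<- offset + nrow(tab)
    tab
  })
  do.call(rbind, arms)
}

#' Summarize a participant-level cohort
#'
#' Per-arm headcounts and grade moments, and per-arm/context WTP respondent
#' counts, means and SDs, computed with the same estimators the analysis
#' stages use ([mean_wtp()]).
#'
#' @param cohort a participant-level table.
#' @return list with `arms` (tibble: `arm`, `n`, `completers`,
#'   `grade_mean`, `grade_sd`) and `wtp` (tibble: `arm`, `context`, `n`,
#'   `mean`, `sd`).
#' @export
summarize_cohort <- function(cohort) {
  required <- c("id", "arm", "completed", "grade",
                paste0("wtp_c", 1:4), "satisfaction")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("cohort table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  arms <- unique(cohort$arm)
  arm_rows <- lapply(arms, function(a) {
    d <- cohort[cohort$arm == a, , drop = FALSE]
    g <- d$grade[!is.na(d$grade)]
    tibble::tibble(
      arm = a, n = nrow(d), completers = sum(d$completed),
      grade_mean = if (length(g) > 0) mean(g) else NA_real_,
      grade_sd = if (length(g) > 1) stats::sd(g) else NA_real_
    )
  })
  long <- if (nrow(cohort) > 0) wtp_long(cohort) else NULL
  wtp_rows <- lapply(arms, function(a) {
    do.call(rbind, lapply(1:4, function(ctx) {
      m <- mean_wtp(long, a, ctx)
      tibble::tibble(arm = a, context = ctx, n = m$n, mean = m$mean,
                     sd = m$sd)
    }))
  })
  list(
    arms = if (length(arm_rows)) do.call(rbind, arm_rows) else
      tibble::tibble(arm = character(0), n = integer(0),
                     completers = integer(0), grade_mean = numeric(0),
                     grade_sd = numeric(0)),
    wtp = if (length(wtp_rows)) do.call(rbind, wtp_rows) else
      tibble::tibble(arm = character(0), context = integer(0),
                     n = integer(0), mean = numeric(0), sd = numeric(0))
  )
}
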