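test_that("net position matches revenue minus stepped costs", {
  web <- web_primary()
  expect_equal(net_position(7, web), 104)
  expect_equal(net_position(6, web), -138)
  expect_equal(net_position(0, web), 0)
  # one past capacity forces a second class's fixed costs
  expect_equal(net_position(21, web), 21 * 242 - 2 * 1590)
  expect_error(net_position(61, web), "max_enrollments")
  expect_error(net_position(2.5, web))
})

test_that("integer scan finds the reference profitability segments", {
  web_seg <- breakeven_segments(web_primary())
  expect_equal(web_seg$segments, list(c(7, 60)))
  expect_true(web_seg$breaks_even)
  expect_equal(format(web_seg), "7–60")

  f2f_seg <- breakeven_segments(f2f_primary())
  expect_equal(f2f_seg$segments, list(c(15, 20), c(29, 40), c(43, 60)))

  # fee below variable cost: every enrollment loses money
  losing <- breakeven_scenario(1590, 260, 250, 20)
  seg <- breakeven_segments(losing)
  expect_false(seg$breaks_even)
  expect_equal(length(seg$segments), 0)
  expect_equal(format(seg), "does not break even")
})

test_that("rounded-ratio mode reproduces the headline single numbers", {
  expect_equal(breakeven_rounded_ratio(web_primary()), 7L)
  expect_equal(breakeven_rounded_ratio(f2f_primary()), 14L)
  halved <- breakeven_scenario(795, 4, 250, 20)
  expect_equal(breakeven_rounded_ratio(halved), 3L)
  no_margin <- breakeven_scenario(1590, 250, 250, 20)
  expect_true(is.na(breakeven_rounded_ratio(no_margin)))
})

test_that("one-way sweeps hold other parameters at base", {
  web <- web_primary()
  cap <- sensitivity_sweep(web, "class_capacity", c(10, 30, 40, 50, 60))
  expect_equal(cap$first_breakeven, rep(7L, 5))
  expect_equal(cap$fixed_per_class, rep(1590, 5))

  fee <- sensitivity_sweep(web, "enrollment_fee", c(100, 1000))
  expect_equal(fee$segments_list[[1]],
               list(c(18, 20), c(35, 40), c(52, 60)))
  expect_equal(fee$first_breakeven[2], 2L)

  hrs <- sensitivity_sweep(web, "facilitator_hours", 8)
  expect_equal(hrs$fixed_per_class, 8 * 60 + 750)
  # 1230/242 = 5.08: rounded convention says 5, exact scan needs 6
  expect_equal(hrs$rounded_ratio, 5L)
  expect_equal(hrs$first_breakeven, 6L)

  rate <- sensitivity_sweep(web, "facilitator_rate", 35)
  expect_equal(rate$fixed_per_class, 14 * 35 + 750)

  dbl <- sensitivity_sweep(f2f_primary(), "all_costs_scale", 2)
  expect_false(dbl$breaks_even)
  expect_equal(dbl$fixed_per_class, 6120)
  expect_equal(dbl$variable_per_participant, 70)

  expect_error(sensitivity_sweep(web, "venue_cost", 1), "unknown axis")
  bare <- breakeven_scenario(1590, 8, 250, 20)
  expect_error(sensitivity_sweep(bare, "facilitator_hours", 8),
               "decomposition")
})

test_that("scan agrees with an independent brute-force scanner", {
  set.seed(401)
  for (i in 1:200) {
    s <- random_scenario()
    expect_equal(
      breakeven_segments(s)$segments,
      naive_segments(s$fixed_per_class, s$variable_per_participant,
                     s$enrollment_fee, s$class_capacity,
                     s$max_enrollments)
    )
  }
})

test_that("profitability is monotone in fee and anti-monotone in costs", {
  set.seed(402)
  for (i in 1:50) {
    s <- random_scenario()
    p0 <- profitable_set(s)
    up_fee <- s; up_fee$enrollment_fee <- s$enrollment_fee + 50
    expect_true(all(p0 %in% profitable_set(up_fee)))
    up_fc <- s; up_fc$fixed_per_class <- s$fixed_per_class + 500
    expect_true(all(profitable_set(up_fc) %in% p0))
    up_vc <- s
    up_vc$variable_per_participant <- s$variable_per_participant + 20
    expect_true(all(profitable_set(up_vc) %in% p0))
  }
})

test_that("degenerate and boundary scenarios resolve exactly", {
  # no fixed costs and one giant class: profitable from the first enrollee
  free <- breakeven_scenario(0, 10, 20, class_capacity = 100,
                             max_enrollments = 60)
  expect_equal(breakeven_segments(free)$segments, list(c(1, 60)))
  # FC an exact multiple of the margin: net of zero counts as break-even
  f2f_800 <- breakeven_scenario(3060, 35, 800, 20)
  expect_equal(breakeven_segments(f2f_800)$segments[[1]][1], 4)
  expect_equal(net_position(4, f2f_800), 0)
})

test_that("cost and savings curves are consistent with the net position", {
  s <- f2f_primary()
  curve <- breakeven_curve(s)
  expect_equal(nrow(curve), 61)
  expect_equal(curve$net,
               vapply(0:60, net_position, numeric(1), scenario = s))
  expect_equal(curve$savings, 250 * (0:60))
  # stepped cost: jump of FC at each new class
  expect_equal(curve$cost[22] - curve$cost[21], 3060 + 35)
})
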