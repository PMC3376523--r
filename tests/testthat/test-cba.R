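test_that("participant expenses itemize per mode and variant", {
  f2f <- participant_expense("face_to_face", 250, 12)
  expect_equal(f2f$total, 810)
  expect_equal(f2f$transport, 20)
  expect_equal(f2f$downloads, 0)
  expect_equal(f2f$time_cost, 540)

  web <- participant_expense("web", 250, 14.4)
  expect_equal(web$total, 918)
  expect_equal(web$downloads, 20)
  expect_equal(web$transport, 0)
  expect_equal(web$time_cost, 648)

  sat <- participant_expense("web", 250, 14.4,
                             internet_variant = "satellite")
  expect_equal(sat$total, 923)
  expect_equal(sat$downloads, 25)

  # leisure time: time valued at time-and-a-half, no on-costs ever
  leis <- participant_expense("face_to_face", 250, 12, timing = "leisure")
  expect_equal(leis$time_cost, 810)
  expect_equal(leis$total, 1080)

  # total is additive in its components
  for (e in list(f2f, web, sat, leis)) {
    expect_equal(e$total,
                 e$downloads + e$transport + e$fee + e$time_cost)
  }
  expect_error(participant_expense("web", 250, 14.4,
                                   internet_variant = "dialup"))
  expect_error(participant_expense("web", -1, 14.4))
})

test_that("mean WTP matches a naive two-pass oracle and handles gaps", {
  r <- tibble::tibble(id = as.character(1:3), arm = "web", context = 1,
                      amount = c(100, 200, 180), satisfaction = 3L)
  m <- mean_wtp(r, "web", 1)
  expect_equal(m$n, 3)
  expect_equal(m$mean, 160)
  expect_equal(m$sd, sqrt(2800))

  set.seed(404)
  for (i in 1:20) {
    x <- c(rlnorm(sample(2:40, 1), 5, 0.8), NA, NA)
    r <- tibble::tibble(id = as.character(seq_along(x)), arm = "web",
                        context = 2, amount = x, satisfaction = NA_integer_)
    oracle <- naive_mean_sd(x)
    m <- mean_wtp(r, "web", 2)
    expect_equal(m$n, oracle$n)
    expect_equal(m$mean, oracle$mean)
    expect_equal(m$sd, oracle$sd)
  }

  single <- tibble::tibble(id = "1", arm = "web", context = 3,
                           amount = 42, satisfaction = NA_integer_)
  m1 <- mean_wtp(single, "web", 3)
  expect_equal(m1$n, 1)
  expect_equal(m1$mean, 42)
  expect_true(is.na(m1$sd))

  none <- mean_wtp(single, "face_to_face", 3)
  expect_equal(none$n, 0)
  expect_true(is.na(none$mean))
  expect_error(mean_wtp(single, "web", 5), "context")
})

test_that("net benefit follows the sign convention and its symmetries", {
  expect_equal(net_benefit(200, 810, 160, 918)$net_benefit, 148)
  expect_equal(net_benefit(100, 500, 100, 500)$net_benefit, 0)
  set.seed(405)
  for (i in 1:30) {
    v <- runif(4, 0, 2000)
    nb <- net_benefit(v[1], v[2], v[3], v[4])$net_benefit
    # swapping arm labels negates the result
    expect_equal(net_benefit(v[3], v[4], v[1], v[2])$net_benefit, -nb)
    # invariant under a common shift of both arms' costs and benefits
    k <- runif(1, -500, 500)
    expect_equal(net_benefit(v[1] + k, v[2] + k, v[3] + k,
                             v[4] + k)$net_benefit, nb)
  }
})

test_that("WTP construct validity uses tie-aware ranks per context", {
  # perfectly monotone: rho exactly 1
  mono <- tibble::tibble(id = as.character(1:5), arm = "web", context = 1,
                         amount = c(10, 50, 90, 130, 200),
                         satisfaction = 1:5)
  v <- wtp_construct_validity(mono)
  expect_equal(v$rho[1], 1)
  expect_lt(v$p_value[1], 0.05)

  # constant satisfaction: zero rank variance, undefined marker
  flat <- tibble::tibble(id = as.character(1:6), arm = "web", context = 2,
                         amount = rnorm(6, 100, 10), satisfaction = 3L)
  expect_true(is.na(wtp_construct_validity(flat)$rho[2]))

  # 6-pair fixture with ties: matches a hand-ranked Pearson computation
  tied <- tibble::tibble(id = as.character(1:6), arm = "web", context = 3,
                         amount = c(10, 20, 20, 35, 50, 60),
                         satisfaction = c(1L, 2L, 3L, 3L, 4L, 5L))
  hand_rho <- pearson_by_hand(c(1, 2.5, 2.5, 4, 5, 6),
                              c(1, 2, 3.5, 3.5, 5, 6))
  expect_equal(wtp_construct_validity(tied)$rho[3], hand_rho)

  # fewer than 3 complete pairs: empty-result marker, not an error
  sparse <- tibble::tibble(id = as.character(1:2), arm = "web", context = 4,
                           amount = c(10, 20), satisfaction = c(1L, 2L))
  expect_true(is.na(wtp_construct_validity(sparse)$rho[4]))

  # incomplete pairs are dropped per context before ranking
  mixed <- rbind(mono,
                 tibble::tibble(id = "x", arm = "web", context = 1,
                                amount = 500, satisfaction = NA_integer_))
  expect_equal(wtp_construct_validity(mixed)$n[1], 5)

  # exact and approximate p-values agree with the reference implementation
  set.seed(406)
  x <- rlnorm(8, 5, 0.6)
  y <- sample(seq(10, 80, 10))
  small <- tibble::tibble(id = as.character(1:8), arm = "web", context = 1,
                          amount = x, satisfaction = as.integer(y))
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  got <- wtp_construct_validity(small)
  expect_equal(got$rho[1], unname(ref$estimate))
  expect_equal(got$p_value[1], ref$p.value)
})

test_that("expense sensitivity rows recompute from components", {
  tab <- cba_sensitivity_table()
  web <- function(lbl) tab[tab$label == lbl & tab$arm == "web", ]
  f2f <- function(lbl) tab[tab$label == lbl & tab$arm == "face_to_face", ]

  expect_equal(web("primary")$total, 918)
  expect_equal(f2f("primary")$total, 810)
  expect_equal(web("fee +50%")$total, 1043)
  expect_equal(f2f("fee +50%")$total, 935)
  expect_equal(web("all costs -50%")$total, 459)
  expect_equal(f2f("all costs -50%")$total, 405)
  expect_equal(web("satellite Internet")$total, 923)

  # homogeneity: every component of a scaled row is the scaled component
  base <- web("primary")
  half <- web("all costs -50%")
  for (f in c("downloads", "transport", "fee", "time_cost", "total")) {
    expect_equal(half[[f]], base[[f]] / 2)
  }

  # leisure applies time-and-a-half to both arms' time costs
  leis <- tab[tab$label == "leisure time", ]
  expect_equal(leis$time_cost[leis$arm == "face_to_face"], 810)
  expect_equal(leis$time_cost[leis$arm == "web"], 972)

  # with benefits supplied, net benefit appears on every scenario row
  with_nb <- cba_sensitivity_table(
    benefit = c(face_to_face = 200, web = 160),
    scenarios = list(list(label = "primary"))
  )
  expect_equal(unique(with_nb$net_benefit), (200 - 810) - (160 - 918))
})
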