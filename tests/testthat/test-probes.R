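# Force-spectroscopy protocol machinery: pole selection, the analytic
# driven-spring limit, spring-constant estimation, plate compression, and
# the replicate statistics.

test_that("pole selection returns disjoint uniform samples from the caps", {
  nuc <- mini_nucleus()
  prot <- pull_protocol(nuc)
  sel <- select_pulled_subunits(nuc, prot, seed = 3)
  expect_length(sel$north, prot$n_pole)
  expect_length(sel$south, prot$n_pole)
  expect_length(intersect(sel$north, sel$south), 0)
  ax <- nuc$positions[, 2]
  ctr <- mean(ax[nucmech:::lamina_indices(nuc)])
  expect_true(all(ax[sel$north] - ctr >= prot$pole_cut - 1e-9))
  expect_true(all(ax[sel$south] - ctr <= -prot$pole_cut + 1e-9))
  expect_true(all(sel$north %in% nucmech:::lamina_indices(nuc)))
  sel2 <- select_pulled_subunits(nuc, prot, seed = 3)
  expect_identical(sel, sel2)
})

test_that("an empty pole cap raises a protocol error suggesting a lower cut", {
  nuc <- mini_nucleus()
  prot <- pull_protocol(nuc, pole_cut = 2 * nuc$R0, n_steps = 100L)
  expect_error(select_pulled_subunits(nuc, prot, seed = 1),
               "lower `pole_cut`")
})

test_that("free particles under moving anchors follow the damped driven-spring solution", {
  # two non-interacting beads, one per pole, no thermal noise:
  # x'' = K (a(t) - x) - gamma x'  ->  steady state x = a(t) - gamma v / K
  nuc <- nucmech:::new_nucleus(
    positions = rbind(c(0, 5, 0), c(0, -5, 0)), class_code = c(5L, 5L),
    chromosome = rep(NA_integer_, 2), subunit = rep(NA_integer_, 2),
    bonds = tibble::tibble(i = integer(0), j = integer(0),
                           type = character(0), rest = numeric(0)),
    n_chromatin = 0L, n_lamina = 2L, R_i = 5, R0 = 5, relaxed = TRUE)
  st <- sim_state(nuc, temperature = 0, seed = 1)
  K <- 20; v_tau <- 0.1
  prot <- pull_protocol(nuc, K = K, v_pull = v_tau, n_pole = 1,
                        pole_cut = 4.9, n_steps = 20000L,
                        series_every = 1000L)
  pull <- stretch(st, prot, seed = 1)
  v <- v_tau / tau_steps() / st$dt     # sigma per unit time
  lag <- st$friction * v / K           # steady-state spring extension
  tail_rows <- pull$curve[pull$curve$step > 5000, ]
  # recorded positions/forces are interval averages; evaluate the analytic
  # solution at the interval midpoints
  t_mid <- (tail_rows$step - 500) * st$dt
  want_ext <- 2 * v * t_mid - 2 * lag  # both beads track their anchors
  expect_lt(max(abs(tail_rows$extension - want_ext) / want_ext), 0.02)
  # per-pole force equals the analytic drag force gamma v
  expect_lt(max(abs(tail_rows$force - st$friction * v)), 0.01)
})

test_that("anchor separation grows exactly linearly at 2 v_pull", {
  nuc <- mini_nucleus()
  st <- sim_state(nuc, seed = 6)
  prot <- pull_protocol(nuc, n_steps = 3000L)
  pull <- stretch(st, prot, seed = 2)
  s <- pull$curve
  sep <- 2 * s$anchor_y  # symmetric anchors
  slope <- diff(sep) / diff(s$step)
  expect_equal(slope, rep(2 * prot$v_pull / tau_steps(), length(slope)),
               tolerance = 1e-9)
})

test_that("spring constant recovers exact slopes of synthetic curves", {
  strain <- seq(0, 0.6, by = 0.005)
  R0 <- 10
  ext <- strain * R0
  linear <- tibble::tibble(force = 3 * ext, extension = ext, strain = strain)
  expect_equal(spring_constant(linear, 0.3, 0.05), 3, tolerance = 1e-10)

  quad <- tibble::tibble(force = 0.5 * ext^2, extension = ext, strain = strain)
  # analytic derivative at the window center: d(0.5 x^2)/dx = x = 3
  expect_equal(spring_constant(quad, 0.3, 0.05), 3, tolerance = 0.01)

  expect_error(spring_constant(linear, 0.65, 0.05), "window")
})

test_that("v_pull = 0 produces near-zero force and strain", {
  nuc <- mini_nucleus()
  st <- sim_state(nuc, seed = 9)
  prot <- pull_protocol(nuc, v_pull = 0, n_steps = 3000L)
  pull <- stretch(st, prot, seed = 3)
  # thermal shape fluctuations at this small scale move the pole centers a
  # little even without loading
  expect_lt(max(abs(pull$curve$strain)), 0.12)
  expect_lt(abs(mean(pull$curve$force)), 5)
})

test_that("plates beyond the nucleus at zero speed exert zero force", {
  nuc <- mini_nucleus()
  st <- sim_state(nuc, seed = 2)
  prot <- plate_protocol(v_plate = 0, gap_pad = 3, n_steps = 500L)
  cmp <- compress(st, prot)
  expect_equal(max(abs(cmp$curve$force)), 0)
  expect_equal(max(abs(cmp$curve$strain)), 0)
})

test_that("a single particle against an advancing wall feels the wall spring force", {
  nuc <- nucmech:::new_nucleus(
    positions = matrix(0, 1, 3), class_code = 5L,
    chromosome = NA_integer_, subunit = NA_integer_,
    bonds = tibble::tibble(i = integer(0), j = integer(0),
                           type = character(0), rest = numeric(0)),
    n_chromatin = 0L, n_lamina = 1L, R_i = 1, R0 = 1, relaxed = TRUE)
  st <- sim_state(nuc, temperature = 0, seed = 1)
  K <- 20
  prot <- plate_protocol(K_wall = K, v_plate = 0.1, gap_pad = 1,
                         n_steps = 8000L, series_every = 400L)
  cmp <- compress(st, prot)
  # the particle stays at the midplane by symmetry; once the walls reach it,
  # each penetrates by -gap/2 and the recorded total force is the analytic
  # derivative of the two wall springs. Forces are interval averages, so the
  # analytic value is evaluated at the interval-midpoint gap.
  gap_rate <- 2 * prot$v_plate / tau_steps()
  gap_mid <- cmp$curve$gap + gap_rate * prot$series_every / 2
  want <- 2 * K * pmax(0, -gap_mid / 2)
  expect_lt(max(abs(cmp$curve$force - want)[-1]), 1.0)
})

test_that("two identical groups are not distinguished; separated groups are", {
  a <- c(1.01, 0.99, 1.02, 0.98, 1.00)
  same <- compare_conditions(list(g1 = a, g2 = a))
  expect_gt(same$p_value, 0.99)
  expect_equal(tidy(same)$estimate, 0, tolerance = 1e-12)

  set.seed(1)
  g1 <- rnorm(10); g2 <- rnorm(10, mean = 5)
  sep <- compare_conditions(list(low = g1, high = g2))
  expect_lt(sep$p_value, 1e-3)
  expect_identical(sep$method, "t-test")
})

test_that("three groups yield an ANOVA with three Tukey pairs", {
  set.seed(2)
  groups <- list(a = rnorm(6), b = rnorm(6, 1), c = rnorm(6, 2))
  cmp <- compare_conditions(groups)
  expect_identical(cmp$method, "anova-tukey")
  expect_identical(nrow(tidy(cmp)), 3L)
  expect_identical(nrow(cmp$group_stats), 3L)
  expect_true(all(c("mean", "sem", "n") %in% names(cmp$group_stats)))
  expect_identical(glance(cmp)$n_groups, 3L)
})

test_that("degenerate statistics inputs raise errors", {
  expect_error(compare_conditions(list(a = 1, b = c(1, 2))), ">= 2")
  expect_error(compare_conditions(list(a = c(1, 2))), ">= 2")
})
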