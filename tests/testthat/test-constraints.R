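# Tether/crosslink assignment and heterochromatin-fraction conversion,
# checked on hand-built geometries where the expected sets are enumerable.

# A flat test geometry: n_chr heterochromatin subunits on a line near a row
# of lamina subunits a fixed distance away.
flat_geometry <- function(n_chr = 40, dist = 1.5, cls = 3L) {
  chr_pos <- cbind(seq_len(n_chr) * 1.0, 0, 0)
  lam_pos <- cbind(seq_len(n_chr) * 1.0, dist, 0)
  bonds <- tibble::tibble(i = integer(0), j = integer(0), type = character(0),
                          rest = numeric(0))
  nucmech:::new_nucleus(
    positions = rbind(chr_pos, lam_pos),
    class_code = c(rep(cls, n_chr), rep(5L, n_chr)),
    chromosome = c(rep(1L, n_chr), rep(NA_integer_, n_chr)),
    subunit = c(seq_len(n_chr), rep(NA_integer_, n_chr)),
    bonds = bonds, n_chromatin = n_chr, n_lamina = n_chr, R_i = 100,
    relaxed = TRUE)
}

test_that("P_t = 1 tethers every in-range eligible subunit to its nearest lamina partner", {
  nuc <- flat_geometry(dist = 1.5)
  t1 <- assign_tethers(nuc, P_t = 1, seed = 1)
  expect_identical(nrow(t1), 40L)
  expect_identical(t1$lamina, t1$chromatin + 40L)  # directly opposite bead
  expect_true(all(t1$distance <= 2.5))

  out_of_range <- flat_geometry(dist = 3.0)
  expect_identical(nrow(assign_tethers(out_of_range, P_t = 1, seed = 1)), 0L)
})

test_that("P_t = 0 yields no tethers and invalid P_t errors", {
  nuc <- flat_geometry()
  expect_identical(nrow(assign_tethers(nuc, P_t = 0, seed = 1)), 0L)
  expect_error(assign_tethers(nuc, P_t = 1.2, seed = 1), "\\[0, 1\\]")
})

test_that("tether counts are binomial in P_t and saturate at P_t = 1", {
  nuc <- flat_geometry(n_chr = 200)
  n <- 200
  p <- 0.5
  counts <- vapply(1:10, function(s) {
    nrow(assign_tethers(nuc, P_t = p, seed = s))
  }, numeric(1))
  expect_true(all(abs(counts - p * n) <= 4 * sqrt(n * p * (1 - p))))
  n_full <- nrow(assign_tethers(nuc, P_t = 1, seed = 1))
  expect_true(all(n_full >= counts))
})

test_that("euchromatin and telomeres are never tethered", {
  nuc <- flat_geometry(cls = 4L)  # euchromatin row
  expect_identical(nrow(assign_tethers(nuc, P_t = 1, seed = 1)), 0L)
})

test_that("each chromatin subunit acquires at most one lamina partner", {
  nuc <- mini_nucleus()
  t1 <- assign_tethers(nuc, P_t = 1, seed = 3)
  expect_gt(nrow(t1), 0)
  expect_false(any(duplicated(t1$chromatin)))
  expect_true(all(t1$distance <= 2.5))
  lam_rng <- range(nucmech:::lamina_indices(nuc))
  expect_true(all(t1$lamina >= lam_rng[1] & t1$lamina <= lam_rng[2]))
})

test_that("crosslink degree never exceeds two and pairs are same-type in-contact", {
  nuc <- mini_nucleus()
  xl <- assign_crosslinks(nuc, P_c = 1, r_H = 2.5, seed = 5)
  expect_gt(nrow(xl), 0)
  deg <- table(c(xl$i, xl$j))
  expect_lte(max(deg), 2)
  expect_true(all(xl$class_i == xl$class_j))
  expect_true(all(xl$class_i %in% c("CON", "FAC")))
  expect_true(all(xl$distance <= 2.5))
  expect_false(any(xl$i == xl$j))
  expect_false(any(duplicated(paste(xl$i, xl$j))))
})

test_that("P_c = 0 gives no crosslinks; counts grow with P_c", {
  nuc <- mini_nucleus()
  expect_identical(nrow(assign_crosslinks(nuc, P_c = 0, seed = 1)), 0L)
  n_02 <- mean(vapply(1:5, function(s) {
    nrow(assign_crosslinks(nuc, P_c = 0.2, seed = s))
  }, numeric(1)))
  n_08 <- mean(vapply(1:5, function(s) {
    nrow(assign_crosslinks(nuc, P_c = 0.8, seed = s))
  }, numeric(1)))
  expect_gt(n_08, n_02)
})

test_that("dense-cluster crosslinking at P_c = 1 matches a greedy matching oracle", {
  # beads on a tight line: everyone is in contact with everyone
  n <- 8
  pos <- cbind(seq_len(n) * 0.3, 0, 0)
  nuc <- nucmech:::new_nucleus(
    positions = pos, class_code = rep(3L, n),
    chromosome = rep(1L, n), subunit = seq_len(n),
    bonds = tibble::tibble(i = integer(0), j = integer(0),
                           type = character(0), rest = numeric(0)),
    n_chromatin = n, n_lamina = 0L, R_i = 10, relaxed = TRUE)
  xl <- assign_crosslinks(nuc, P_c = 1, seed = 9)
  # greedy capacity-2 matching on a complete graph saturates almost all
  # capacity: every subunit ends with degree >= 1, and the total is within
  # one link of the capacity bound n * 2 / 2
  deg <- table(factor(c(xl$i, xl$j), levels = seq_len(n)))
  expect_true(all(deg >= 1))
  expect_lte(max(deg), 2)
  expect_gte(nrow(xl), n - 1)
})

test_that("fraction conversion hits the target exactly and only touches FAC/EUC", {
  nuc <- mini_nucleus()
  comp <- which(nuc$class_code %in% c(3L, 4L))
  n_comp <- length(comp)
  before_con <- sum(nuc$class_code == 2L)
  f_cur <- mean(nuc$class_code[comp] == 3L)

  same <- convert_heterochromatin_fraction(nuc, f_cur, seed = 1)
  expect_identical(same$class_code, nuc$class_code)  # target equals current

  up <- convert_heterochromatin_fraction(nuc, 0.60, seed = 1)
  expect_identical(sum(up$class_code[comp] == 3L),
                   as.integer(round(0.60 * n_comp)))
  expect_identical(sum(up$class_code == 2L), before_con)
  expect_identical(up$positions, nuc$positions)
  # only EUC -> FAC flips, by exactly the count difference
  expect_identical(sum(up$class_code[comp] == 3L) -
                     sum(nuc$class_code[comp] == 3L),
                   as.integer(round(0.60 * n_comp)) -
                     sum(nuc$class_code[comp] == 3L))
  flipped <- which(up$class_code != nuc$class_code)
  expect_true(all(nuc$class_code[flipped] == 4L))

  down <- convert_heterochromatin_fraction(nuc, 0, seed = 1)
  expect_identical(sum(down$class_code[comp] == 3L), 0L)
  expect_identical(sum(down$class_code == 2L), before_con)
})

test_that("full-scale fraction arithmetic: 45% to 60% converts 750 subunits", {
  # 5000 compartment subunits: 2250 -> 3000 FAC
  expect_identical(round(0.60 * 5000) - round(0.45 * 5000), 750)
})

test_that("installed constraint bonds persist through dynamics", {
  nuc <- mini_nucleus()
  teth <- assign_tethers(nuc, P_t = 1, seed = 2)
  xl <- assign_crosslinks(nuc, P_c = 0.2, seed = 2)
  nt <- install_constraints(nuc, teth, xl)
  expect_identical(sum(nt$bonds$type == "tether"), nrow(teth))
  expect_identical(sum(nt$bonds$type == "crosslink"), nrow(xl))
  st <- sim_state(nt, seed = 2)
  traj <- run_dynamics(st, 300)
  expect_identical(traj$state$nucleus$bonds, nt$bonds)
})

test_that("constant-tether-number subsampling is uniform and exact", {
  nuc <- mini_nucleus()
  teth <- assign_tethers(nuc, P_t = 1, seed = 4)
  sub <- subsample_tethers(teth, 10, seed = 1)
  expect_identical(nrow(sub), 10L)
  expect_true(all(paste(sub$chromatin, sub$lamina) %in%
                    paste(teth$chromatin, teth$lamina)))
  expect_error(subsample_tethers(teth, nrow(teth) + 1), "exceeds")
})

test_that("affinity edits are symmetric, validated, and support the fourfold sweep", {
  m <- default_interaction()
  m2 <- set_affinity(m, c("FAC", "LAM"), 2.0)
  expect_identical(m2["FAC", "LAM"], 2.0)
  expect_identical(m2["LAM", "FAC"], 2.0)
  m4 <- scale_lamina_affinity(default_interaction(), 4)
  expect_identical(m4["CON", "LAM"], 4 * 0.5)
  expect_identical(m4["FAC", "LAM"], 4 * 0.5)
  expect_error(set_affinity(m, c("FAC", "LAM"), -1), "non-negative")
  expect_error(set_affinity(m, c("FAC", "XXX"), 1), "unknown class")
})
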