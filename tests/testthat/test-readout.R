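# Contact analyses checked against brute-force enumeration and hand-built
# snapshots with known contact structure.

# A nucleus-shaped container for arbitrary chromatin coordinates.
snapshot_nucleus <- function(chr_pos, classes, chromosome = NULL,
                             lam_pos = NULL) {
  n <- nrow(chr_pos)
  if (is.null(chromosome)) chromosome <- rep(1L, n)
  sub <- stats::ave(seq_len(n), chromosome, FUN = seq_along)
  n_lam <- if (is.null(lam_pos)) 0L else nrow(lam_pos)
  nucmech:::new_nucleus(
    positions = rbind(chr_pos, lam_pos),
    class_code = c(classes, rep(5L, n_lam)),
    chromosome = c(chromosome, rep(NA_integer_, n_lam)),
    subunit = c(as.integer(sub), rep(NA_integer_, n_lam)),
    bonds = tibble::tibble(i = integer(0), j = integer(0),
                           type = character(0), rest = numeric(0)),
    n_chromatin = n, n_lamina = n_lam, R_i = 100, R0 = 10, relaxed = TRUE)
}

test_that("contact radius is boundary-inclusive at exactly 2.5 sigma", {
  nuc <- snapshot_nucleus(rbind(c(0, 0, 0), c(2.5, 0, 0), c(5.2, 0, 0)),
                          rep(4L, 3))
  cp <- contact_pairs(nuc$positions, nuc)
  expect_identical(nrow(cp[cp$i == 1 & cp$j == 2, ]), 1L)   # r = 2.5: in
  expect_identical(nrow(cp[cp$i == 2 & cp$j == 3, ]), 0L)   # r = 2.7: out
})

test_that("spatially partitioned contact pairs equal brute-force enumeration", {
  for (seed in c(2, 9)) {
    set.seed(seed)
    n <- 300
    pos <- matrix(runif(3 * n, 0, 12), n, 3)
    nuc <- snapshot_nucleus(pos, rep(4L, n))
    cp <- contact_pairs(pos, nuc)
    got <- sort(paste(cp$i, cp$j))
    d <- as.matrix(dist(pos))
    idx <- which(upper.tri(d) & d <= 2.5, arr.ind = TRUE)
    want <- sort(paste(idx[, 1], idx[, 2]))
    expect_identical(got, want)
  }
})

test_that("P(s) counts a known single contact and averaging is idempotent", {
  # chain of 12 subunits stretched out, except subunits 1 and 11 (s = 10)
  # folded to within contact range
  pos <- cbind(seq_len(12) * 3, 0, 0)
  pos[11, ] <- pos[1, ] + c(0, 2.0, 0)  # fold subunit 11 onto subunit 1
  nuc <- snapshot_nucleus(pos, rep(3L, 12))
  ps1 <- ps_curve(list(pos), nuc, class_filter = "FAC")
  expect_identical(ps1$p[ps1$s == 10], 1 / 2)  # pairs at s=10: (1,11), (2,12)
  expect_true(all(ps1$p[!ps1$s %in% c(10)] == 0))
  ps5 <- ps_curve(rep(list(pos), 5), nuc, class_filter = "FAC")
  expect_equal(ps5$p, ps1$p)
})

test_that("P(s) is invariant under rigid rotation and translation", {
  nuc <- mini_nucleus()
  frame <- nuc$positions
  rot <- nucmech:::local_seed(3, nucmech:::random_rotation())
  moved <- frame %*% t(rot) + matrix(rep(c(5, -3, 2), each = nrow(frame)),
                                     ncol = 3)
  ps_a <- ps_curve(list(frame), nuc, class_filter = c("FAC", "EUC"))
  ps_b <- ps_curve(list(moved), nuc, class_filter = c("FAC", "EUC"))
  expect_equal(ps_a$p, ps_b$p, tolerance = 1e-12)
})

test_that("P(s) decreases with separation for an equilibrated confined chain", {
  nuc <- mini_nucleus()
  ps <- ps_curve(list(nuc$positions), nuc, class_filter = c("FAC", "EUC"),
                 bins = "log")
  # compare mean P over short (<8) vs long (>50) separations
  short <- mean(ps$p[ps$s < 8])
  long <- mean(ps$p[ps$s > 50])
  expect_gt(short, long)
})

test_that("empty class filters and filters matching nothing raise errors", {
  nuc <- snapshot_nucleus(cbind(1:4, 0, 0), rep(4L, 4))
  expect_error(ps_curve(list(nuc$positions), nuc, class_filter = "CON"),
               "matches no chromatin")
  expect_error(ps_curve(list(), nuc), "at least one snapshot")
})

test_that("contact index is 1 within 2.5 sigma of the lamina and 0 at the center", {
  lam <- rbind(c(10, 0, 0), c(0, 10, 0))
  chr <- rbind(c(8, 0, 0),    # 2.0 from lamina bead: index 1
               c(0, 0, 0),    # far from both: index 0
               c(0, 7.4, 0))  # 2.6 away: index 0
  nuc <- snapshot_nucleus(chr, c(3L, 4L, 3L), lam_pos = lam)
  prof <- damid_profile(list(nuc$positions), nuc)
  expect_equal(prof$contact_index, c(1, 0, 0))
})

test_that("profile averages per-frame indicators over frames", {
  lam <- matrix(c(10, 0, 0), 1, 3)
  near <- rbind(c(8, 0, 0)); far <- rbind(c(0, 0, 0))
  nuc <- snapshot_nucleus(near, 3L, lam_pos = lam)
  f1 <- rbind(near, lam); f2 <- rbind(far, lam)
  prof <- damid_profile(list(f1, f2, f1, f1), nuc)
  expect_equal(prof$contact_index, 3 / 4)
  expect_error(damid_profile(list(f1), snapshot_nucleus(near, 3L)),
               "no lamina")
})

test_that("LAD percentage spans 0 to 100 for all-center vs all-peripheral heterochromatin", {
  lam <- rbind(c(10, 0, 0), c(-10, 0, 0))
  center <- rbind(c(0, 0, 0), c(1, 0, 0))
  nuc0 <- snapshot_nucleus(center, c(2L, 3L), lam_pos = lam)
  p0 <- damid_profile(list(nuc0$positions), nuc0)
  expect_equal(lad_percentage(p0), 0)
  touching <- rbind(c(9, 0, 0), c(-9, 0, 0))
  nuc1 <- snapshot_nucleus(touching, c(2L, 3L), lam_pos = lam)
  p1 <- damid_profile(list(nuc1$positions), nuc1)
  expect_equal(lad_percentage(p1), 100)
  # euchromatin does not enter the LAD denominator
  mixed <- snapshot_nucleus(rbind(c(9, 0, 0), c(0, 0, 0)), c(3L, 4L),
                            lam_pos = lam)
  pm <- damid_profile(list(mixed$positions), mixed)
  expect_equal(lad_percentage(pm), 100)
})

test_that("delta_rel identity is zero, scalar scaling is exact, and axes must match", {
  pos <- cbind(seq_len(20), 0, 0)
  nuc <- snapshot_nucleus(pos, rep(3L, 20))
  ps <- ps_curve(list(nuc$positions), nuc, class_filter = "FAC")
  d0 <- suppressWarnings(delta_rel(ps, ps))
  expect_equal(max(abs(d0$delta_rel)), 0)
  expect_equal(delta_rel_total(d0), 0)

  ps_up <- ps
  ps_up$p <- ps$p * 1.5
  keep <- ps$p > 0
  d <- suppressWarnings(delta_rel(ps, ps_up))
  if (any(keep)) expect_true(all(abs(d$delta_rel - 0.5) < 1e-12))

  ps_bad <- ps[-1, ]
  expect_error(delta_rel(ps, ps_bad), "separation axis")
  expect_warning(delta_rel(ps, ps), "zero baseline")
})

test_that("snapshot sampler honors phase windows and fails without the crossing", {
  fake_pull <- structure(
    list(frames = lapply(1:60, function(i) matrix(i, 1, 3)),
         frame_steps = seq_len(60) * 100,
         frame_strain = seq(0, 0.59, by = 0.01)),
    class = "nm_pull")
  before <- snapshot_sampler(fake_pull, "before", n_before = 10, n_after = 20)
  expect_length(before, 10)
  expect_true(all(unlist(lapply(before, `[`, 1, 1)) <= 30))
  after <- snapshot_sampler(fake_pull, "after", n_before = 10, n_after = 20)
  expect_length(after, 20)
  expect_true(all(unlist(lapply(after, `[`, 1, 1)) >= 31))

  shallow <- fake_pull
  shallow$frame_strain <- seq(0, 0.2, length.out = 60)
  expect_error(snapshot_sampler(shallow, "before"), "never reaches")
  expect_error(snapshot_sampler(fake_pull, "after", n_after = 1000),
               "only .* frames available")
})

test_that("profiles and curves export to the documented text formats", {
  lam <- rbind(c(10, 0, 0))
  nuc <- snapshot_nucleus(rbind(c(8, 0, 0), c(0, 0, 0)), c(3L, 4L),
                          lam_pos = lam)
  prof <- damid_profile(list(nuc$positions), nuc)
  bed <- withr::local_tempfile(fileext = ".bedgraph")
  write_profile(prof, bed)
  fields <- strsplit(readLines(bed)[1], "\t")[[1]]
  expect_identical(fields[1:3], c("chr1", "0", "40000"))
  expect_equal(as.numeric(fields[4]), 1)

  ps <- ps_curve(list(nuc$positions), nuc, class_filter = c("FAC", "EUC"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_curve_tsv(ps, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_identical(names(back), c("s", "s_mb", "p", "n_pairs"))
})
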