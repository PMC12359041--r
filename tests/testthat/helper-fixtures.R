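# Shared fixtures. Heavy objects (relaxed nuclei, pulls) are built once per
# session and memoized so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# Desk-scale nucleus: 2 x 300 chromatin subunits, 600 lamina; phi-matched
# radii. Small enough for minutes-scale property tests.
mini_annotation <- function(seed = 7) {
  generate_genome(n_chromosomes = 2, n_distinct = 2, n_subunits = 300,
                  n_con = 50, f = 0.45, mean_block_len = 12, seed = seed)
}

build_mini_nucleus <- function(seed = 7, relax_steps = 8000) {
  ann <- mini_annotation(seed)
  rr <- scaled_radii(nrow(ann))
  nuc <- build_nucleus(ann, n_lamina = 600, R_i = rr$R_i, seed = seed)
  assemble_and_relax(
    nuc,
    relax_schedule(rr$R_s, soft_steps = 1500, n_stages = 10,
                   stage_steps = 500, relax_steps = relax_steps),
    seed = seed)
}

mini_nucleus <- function() fixture("mini_nucleus", function() build_mini_nucleus())

# A random gas of particles with mixed classes for force oracles; minimum
# separation keeps core forces moderate so absolute force tolerances are
# meaningful.
random_gas <- function(n, seed, box = 6, classes = c(2L, 3L, 4L, 5L),
                       min_sep = 0.85) {
  set.seed(seed)
  pos <- matrix(NA_real_, n, 3)
  placed <- 0
  while (placed < n) {
    cand <- runif(3, 0, box)
    if (placed == 0 ||
        min(colSums((t(pos[seq_len(placed), , drop = FALSE]) - cand)^2)) >=
          min_sep^2) {
      placed <- placed + 1
      pos[placed, ] <- cand
    }
  }
  cls <- sample(classes, n, replace = TRUE)
  bonds <- tibble::tibble(i = integer(0), j = integer(0), type = character(0),
                          rest = numeric(0))
  nuc <- nucmech:::new_nucleus(
    positions = pos, class_code = cls,
    chromosome = rep(NA_integer_, n), subunit = rep(NA_integer_, n),
    bonds = bonds, n_chromatin = 0L, n_lamina = 0L, R_i = box)
  sim_state(nuc, seed = seed)
}

# Single chain along x with given spacings, for bond-force oracles.
chain_state <- function(spacing, seed = 1) {
  n <- length(spacing) + 1
  xs <- c(0, cumsum(spacing))
  pos <- cbind(xs, rep(0, n), rep(0, n))
  bonds <- tibble::tibble(i = seq_len(n - 1), j = seq(2, n), type = "chain",
                          rest = NA_real_)
  nuc <- nucmech:::new_nucleus(
    positions = pos, class_code = rep(4L, n),
    chromosome = rep(1L, n), subunit = seq_len(n),
    bonds = bonds, n_chromatin = n, n_lamina = 0L, R_i = 10)
  sim_state(nuc, seed = seed)
}
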