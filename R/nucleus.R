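# Nucleus construction: a random bead-spring spherical shell (the lamina)
# enclosing compact chromatid-like polymers, shrunk in stages and relaxed to
# the working configuration.
#
# Full-scale geometry: 15 000 lamina subunits at initial radius R_i = 42
# sigma, shrunk to R_s = 32 sigma, relaxing to R_0 ~ 29 sigma with eight
# 6002-subunit chromosomes, i.e. a chromatin volume fraction phi ~ 0.23.
# Reduced-scale presets preserve phi and the radius ratios.

#' Build a random bead-spring spherical shell
#'
#' Lamina subunits are placed uniformly at random on a sphere and connected
#' to near neighbors; the bond graph is then pruned/augmented so every degree
#' lies within `degree_bounds`, and patched to a single connected component.
#'
#' @param n_lamina Number of shell subunits (full scale: 15000).
#' @param radius Sphere radius in sigma (full scale initial: 42).
#' @param degree_bounds Length-2 integer vector of allowed bond degrees
#'   (default `c(5, 8)`).
#' @param seed Integer seed.
#' @param rest_factor Ratio of each bond's rest length to its build length
#'   (default 0.5). The rest geometry pre-tensions the membrane so that, with
#'   chromatin inside, the composite relaxes near the target volume fraction
#'   with R0/R_s close to the full-scale 29/32.
#' @param max_retries Rebuild attempts before raising a construction error.
#' @return List with `positions` (n x 3), `bonds` (tibble `i`, `j`, `rest`),
#'   `radius`, `degrees`.
#' @export
build_shell <- function(n_lamina, radius, degree_bounds = c(5L, 8L), seed = 1L,
                        rest_factor = 0.5, max_retries = 5L) {
  n_lamina <- check_count(n_lamina, "n_lamina", min = 12)
  if (radius <= 0) abort("`radius` must be positive")
  dmin <- degree_bounds[1]; dmax <- degree_bounds[2]
  for (attempt in seq_len(max_retries)) {
    out <- try(local_seed(derive_seed(seed, "shell", attempt),
                          shell_attempt(n_lamina, radius, dmin, dmax,
                                        rest_factor)),
               silent = TRUE)
    if (!inherits(out, "try-error")) return(out)
  }
  abort(sprintf("could not build a degree-[%d,%d] shell with %d subunits after %d attempts",
                dmin, dmax, n_lamina, max_retries))
}

shell_attempt <- function(n, radius, dmin, dmax, rest_factor = 0.5) {
  # uniform points on the sphere
  v <- matrix(rnorm(3 * n), n, 3)
  pos <- radius * v / sqrt(rowSums(v^2))
  spacing <- sqrt(4 * pi * radius^2 / n)
  cand <- cpp_pairs_within(pos, 2.2 * spacing, seq_len(n), integer(0))
  if (nrow(cand) == 0) abort("no candidate neighbor pairs found")
  d <- sqrt(rowSums((pos[cand[, 1], , drop = FALSE] -
                       pos[cand[, 2], , drop = FALSE])^2))
  ord <- order(d)
  cand <- cand[ord, , drop = FALSE]; d <- d[ord]
  # k-nearest union graph (k = 6 targets the mean of the degree window)
  keep <- logical(nrow(cand))
  taken <- integer(n)
  for (node in seq_len(n)) {
    rows <- which(cand[, 1] == node | cand[, 2] == node)
    rows <- rows[seq_len(min(6L, length(rows)))]
    keep[rows] <- TRUE
  }
  edges <- cand[keep, , drop = FALSE]
  elen <- d[keep]
  deg <- tabulate(c(edges[, 1], edges[, 2]), n)
  # prune high-degree nodes (longest removable edge first)
  repeat {
    hot <- which(deg > dmax)
    if (length(hot) == 0) break
    removed <- FALSE
    for (node in hot) {
      rows <- which((edges[, 1] == node | edges[, 2] == node))
      rows <- rows[order(-elen[rows])]
      for (r in rows) {
        other <- if (edges[r, 1] == node) edges[r, 2] else edges[r, 1]
        if (deg[node] > dmax && deg[other] > dmin) {
          deg[node] <- deg[node] - 1L; deg[other] <- deg[other] - 1L
          edges <- edges[-r, , drop = FALSE]; elen <- elen[-r]
          removed <- TRUE
          break
        }
      }
    }
    if (!removed) break
  }
  # augment low-degree nodes with near partners, swapping out a saturated
  # partner's longest edge when needed so added bonds stay local
  cold <- which(deg < dmin)
  for (node in cold) {
    while (deg[node] < dmin) {
      dist_all <- sqrt(colSums((t(pos) - pos[node, ])^2))
      nbrs <- c(edges[edges[, 1] == node, 2], edges[edges[, 2] == node, 1])
      cand <- setdiff(order(dist_all), c(node, nbrs))
      added <- FALSE
      for (p in cand[seq_len(min(30, length(cand)))]) {
        if (deg[p] >= dmax) {
          rows <- which(edges[, 1] == p | edges[, 2] == p)
          rows <- rows[order(-elen[rows])]
          swapped <- FALSE
          for (r in rows) {
            q <- if (edges[r, 1] == p) edges[r, 2] else edges[r, 1]
            if (deg[q] > dmin && elen[r] > dist_all[p]) {
              edges <- edges[-r, , drop = FALSE]; elen <- elen[-r]
              deg[p] <- deg[p] - 1L; deg[q] <- deg[q] - 1L
              swapped <- TRUE
              break
            }
          }
          if (!swapped) next
        }
        edges <- rbind(edges, c(min(node, p), max(node, p)))
        elen <- c(elen, dist_all[p])
        deg[node] <- deg[node] + 1L; deg[p] <- deg[p] + 1L
        added <- TRUE
        break
      }
      if (!added) abort("degree augmentation failed")
    }
  }
  if (any(deg < dmin) || any(deg > dmax)) abort("degree bounds unsatisfied")
  # enforce a single connected component
  comp <- graph_components(edges, n)
  while (max(comp) > 1) {
    main <- which(comp == 1)
    other_id <- which.max(tabulate(comp[comp != 1], max(comp)))
    other <- which(comp == if (other_id == 1) 2 else other_id)
    best <- c(NA, NA, Inf)
    for (node in other) {
      dist_all <- sqrt(colSums((t(pos[main, , drop = FALSE]) - pos[node, ])^2))
      k <- which.min(dist_all)
      if (dist_all[k] < best[3]) best <- c(node, main[k], dist_all[k])
    }
    edges <- rbind(edges, c(min(best[1:2]), max(best[1:2])))
    deg[best[1]] <- deg[best[1]] + 1L; deg[best[2]] <- deg[best[2]] + 1L
    comp <- graph_components(edges, n)
  }
  # drop overlong edges where degrees allow, then verify no edge is far
  # above the typical spacing (overlong bonds make weak spots and can
  # approach the finite bond extension)
  final_len <- sqrt(rowSums((pos[edges[, 1], , drop = FALSE] -
                               pos[edges[, 2], , drop = FALSE])^2))
  for (r in order(-final_len)) {
    if (final_len[r] <= 2.2 * spacing) break
    u <- edges[r, 1]; w <- edges[r, 2]
    if (deg[u] > dmin && deg[w] > dmin) {
      deg[u] <- deg[u] - 1L; deg[w] <- deg[w] - 1L
      final_len[r] <- NA
    }
  }
  keep_rows <- !is.na(final_len)
  edges <- edges[keep_rows, , drop = FALSE]
  final_len <- final_len[keep_rows]
  if (max(final_len) > 2.9 * spacing) abort("overlong shell edge; rebuilding")
  comp <- graph_components(edges, n)
  if (max(comp) > 1) abort("pruning disconnected the shell; rebuilding")
  list(positions = pos,
       bonds = tibble::tibble(i = as.integer(edges[, 1]),
                              j = as.integer(edges[, 2]),
                              rest = final_len * rest_factor),
       radius = radius, degrees = deg)
}

# Connected components by BFS; returns component id per node (1 = component
# containing node 1's tree first discovered).
graph_components <- function(edges, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n)
  cid <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

#' Build a compact chromatid-like initial conformation
#'
#' The chain is laid out as a space-filling serpentine walk through a cubic
#' lattice region (spacing 1 sigma), giving a compact self-avoiding
#' conformation with unit bond lengths. A random cube symmetry (axis
#' permutation and reflections) plus coordinate jitter randomizes the
#' conformation while keeping the block axis-aligned, so several chromatids
#' can be packed without overlap; [build_nucleus()] applies a global random
#' rotation to the assembled chromatin.
#'
#' @param n_subunits Chain length.
#' @param seed Integer seed (controls orientation and jitter; topology is
#'   fixed).
#' @param center Length-3 placement center (sigma).
#' @return List with `positions`, `bonds` (chain pairs), `bounding_radius`.
#' @export
build_chromatid <- function(n_subunits, seed = 1L, center = c(0, 0, 0)) {
  n_subunits <- check_count(n_subunits, "n_subunits", min = 2)
  side <- ceiling(n_subunits^(1 / 3))
  path <- serpentine_path(side)[seq_len(n_subunits), , drop = FALSE]
  path <- sweep(path, 2, colMeans(path))
  local_seed(seed, {
    sym <- diag(sample(c(-1, 1), 3, replace = TRUE)) %*%
      diag(3)[sample(3), , drop = FALSE]
    pos <- path %*% t(sym)
    pos <- pos + matrix(rnorm(3 * n_subunits, sd = 0.02), ncol = 3)
  })
  pos <- sweep(pos, 2, center, `+`)
  list(positions = pos,
       bonds = tibble::tibble(i = seq_len(n_subunits - 1L),
                              j = seq(2L, n_subunits)),
       bounding_radius = max(sqrt(rowSums(sweep(pos, 2, center)^2))))
}

# Boustrophedon walk through a side^3 cube; consecutive sites are lattice
# neighbors (all bond lengths exactly 1 before rotation/jitter).
serpentine_path <- function(side) {
  out <- matrix(0, side^3, 3)
  r <- 1L
  for (z in 0:(side - 1)) {
    ys <- if (z %% 2 == 0) 0:(side - 1) else (side - 1):0
    for (y in ys) {
      xs <- if ((y + z) %% 2 == 0) 0:(side - 1) else (side - 1):0
      for (x in xs) {
        out[r, ] <- c(x, y, z)
        r <- r + 1L
      }
    }
  }
  out
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

new_nucleus <- function(positions, class_code, chromosome, subunit, bonds,
                        n_chromatin, n_lamina, R_i, R_s = NA_real_,
                        R0 = NA_real_, phi = NA_real_, annotation = NULL,
                        relaxed = FALSE) {
  structure(
    list(positions = positions, class_code = as.integer(class_code),
         chromosome = chromosome, subunit = subunit, bonds = bonds,
         n_chromatin = as.integer(n_chromatin),
         n_lamina = as.integer(n_lamina),
         R_i = R_i, R_s = R_s, R0 = R0, phi = phi,
         annotation = annotation, relaxed = relaxed),
    class = "nm_nucleus")
}

chromatin_indices <- function(nucleus) seq_len(nucleus$n_chromatin)

lamina_indices <- function(nucleus) {
  nucleus$n_chromatin + seq_len(nucleus$n_lamina)
}

#' Assemble an unrelaxed nucleus from an annotation and shell parameters
#'
#' Builds the lamina shell at `R_i` and one compact chromatid per annotated
#' chromosome, placed at random orientations near the nuclear center. The
#' returned model still needs [assemble_and_relax()].
#'
#' @param annotation An `nm_annotation` covering all chromosomes, or `NULL`
#'   for an empty (lamina-only) shell.
#' @param n_lamina Number of lamina subunits.
#' @param R_i Initial shell radius (sigma).
#' @param seed Integer seed.
#' @return An unrelaxed `nm_nucleus`.
#' @export
build_nucleus <- function(annotation, n_lamina, R_i, seed = 1L) {
  shell <- build_shell(n_lamina, R_i, seed = derive_seed(seed, "shell"))
  if (is.null(annotation)) {
    nuc <- new_nucleus(
      positions = shell$positions, class_code = rep(5L, n_lamina),
      chromosome = rep(NA_integer_, n_lamina),
      subunit = rep(NA_integer_, n_lamina),
      bonds = dplyr::mutate(shell$bonds, type = "shell"),
      n_chromatin = 0L, n_lamina = n_lamina, R_i = R_i)
    return(nuc)
  }
  stopifnot(inherits(annotation, "nm_annotation"))
  chroms <- split(annotation, annotation$chromosome_id)
  side <- ceiling(max(vapply(chroms, nrow, 1L))^(1 / 3))
  centers <- local_seed(derive_seed(seed, "placement"),
                        place_centers(length(chroms), side))
  pos_list <- list(); bond_list <- list()
  class_code <- integer(0); chrom_vec <- integer(0); sub_vec <- integer(0)
  offset <- 0L
  for (k in seq_along(chroms)) {
    tr <- chroms[[k]]
    ch <- build_chromatid(nrow(tr), seed = derive_seed(seed, "chromatid", k),
                          center = centers[k, ])
    pos_list[[k]] <- ch$positions
    bond_list[[k]] <- dplyr::mutate(ch$bonds, i = .data$i + offset,
                                    j = .data$j + offset, type = "chain")
    class_code <- c(class_code, class_code_of(tr))
    chrom_vec <- c(chrom_vec, tr$chromosome_id)
    sub_vec <- c(sub_vec, tr$subunit)
    offset <- offset + nrow(tr)
  }
  n_chr <- offset
  chromatin_pos <- do.call(rbind, pos_list)
  chromatin_pos <- chromatin_pos %*%
    t(local_seed(derive_seed(seed, "orientation"), random_rotation()))
  rmax <- max(sqrt(rowSums(chromatin_pos^2)))
  if (rmax > 0.97 * R_i) {
    abort(sprintf(
      "chromatids do not fit inside the shell (extent %.1f vs R_i = %.1f sigma)",
      rmax, R_i))
  }
  positions <- rbind(chromatin_pos, shell$positions)
  bonds <- dplyr::bind_rows(
    dplyr::bind_rows(bond_list),
    dplyr::mutate(shell$bonds, i = .data$i + n_chr, j = .data$j + n_chr,
                  type = "shell"))
  new_nucleus(
    positions = positions,
    class_code = c(class_code, rep(5L, n_lamina)),
    chromosome = c(chrom_vec, rep(NA_integer_, n_lamina)),
    subunit = c(sub_vec, rep(NA_integer_, n_lamina)),
    bonds = bonds, n_chromatin = n_chr, n_lamina = n_lamina, R_i = R_i,
    annotation = annotation)
}

class_code_of <- function(track) class_code(as.character(track$class))

# Overlap-free chromatid slots: centers on an axis-aligned grid with one
# lattice-spacing clearance, shuffled so the slot assignment is random.
place_centers <- function(k, side) {
  if (k == 1) return(matrix(0, 1, 3))
  pitch <- side + 1.2
  if (k <= 2) {
    slots <- rbind(c(-pitch / 2, 0, 0), c(pitch / 2, 0, 0))
  } else if (k <= 8) {
    g <- expand.grid(x = c(-0.5, 0.5), y = c(-0.5, 0.5), z = c(-0.5, 0.5))
    slots <- as.matrix(g) * pitch
  } else {
    abort("at most 8 chromosomes are supported by the slot placement")
  }
  slots[sample(nrow(slots), k), , drop = FALSE]
}

#' Relaxation schedule for nucleus assembly
#'
#' The shell is shrunk from `R_i` to `R_s` by `n_stages` affine rescalings of
#' the lamina coordinates with `stage_steps` of dynamics between stages,
#' preceded by a displacement-capped soft start and followed by free
#' relaxation of `relax_steps` during which the relaxed radius `R0` is
#' measured.
#'
#' @param R_s Reduced shell radius (sigma; full scale: 32).
#' @param soft_steps Displacement-capped initial steps (default 2000).
#' @param n_stages Number of affine shrink stages (default 10).
#' @param stage_steps Dynamics steps per stage (default 1000).
#' @param relax_steps Free-relaxation steps (default 20000).
#' @return A schedule list.
#' @export
relax_schedule <- function(R_s, soft_steps = 2000L, n_stages = 10L,
                           stage_steps = 1000L, relax_steps = 20000L) {
  list(R_s = R_s, soft_steps = as.integer(soft_steps),
       n_stages = as.integer(n_stages), stage_steps = as.integer(stage_steps),
       relax_steps = as.integer(relax_steps))
}

#' Shrink and relax an assembled nucleus
#'
#' Runs the staged shrink schedule and free relaxation, measures the relaxed
#' shell radius `R0` (time-averaged mean lamina radius over the relaxation
#' tail) and the chromatin volume fraction
#' \eqn{\phi = n_{chr} (\pi/6) \sigma^3 / (4\pi/3 R_0^3) = n_{chr} / (8 R_0^3)}.
#'
#' @param nucleus An unrelaxed `nm_nucleus` from [build_nucleus()].
#' @param schedule A [relax_schedule()].
#' @param interaction An `nm_interaction` matrix.
#' @param seed Integer seed for the thermostat.
#' @return The relaxed `nm_nucleus` with `R_s`, `R0` and `phi` filled in.
#' @export
assemble_and_relax <- function(nucleus, schedule,
                               interaction = default_interaction(),
                               seed = 1L) {
  stopifnot(inherits(nucleus, "nm_nucleus"))
  state <- sim_state(nucleus, interaction, seed = derive_seed(seed, "soft"))
  traj <- run_dynamics(state, schedule$soft_steps, max_disp = 0.02)
  state <- traj$state
  radii <- seq(nucleus$R_i, schedule$R_s, length.out = schedule$n_stages + 1L)[-1]
  lam <- lamina_indices(nucleus)
  for (st in seq_along(radii)) {
    pos <- state$nucleus$positions
    cur <- mean(sqrt(rowSums(sweep(pos[lam, , drop = FALSE], 2,
                                   colMeans(pos[lam, , drop = FALSE]))^2)))
    pos[lam, ] <- pos[lam, , drop = FALSE] * (radii[st] / cur)
    state$nucleus$positions <- pos
    state$seed <- derive_seed(seed, "shrink", st)
    traj <- run_dynamics(state, schedule$stage_steps, max_disp = 0.02)
    state <- traj$state
  }
  state$seed <- derive_seed(seed, "relax")
  traj <- run_dynamics(state, schedule$relax_steps,
                       record_every = TAU_STEPS)
  state <- traj$state
  tail_n <- max(1L, min(10L, length(traj$frames) %/% 2))
  tail_frames <- traj$frames[seq(length(traj$frames) - tail_n + 1,
                                 length(traj$frames))]
  r0 <- mean(vapply(tail_frames, function(fr) {
    p <- fr[lam, , drop = FALSE]
    mean(sqrt(rowSums(sweep(p, 2, colMeans(p))^2)))
  }, numeric(1)))
  out <- state$nucleus
  out$R_s <- schedule$R_s
  out$R0 <- r0
  out$phi <- out$n_chromatin / (8 * r0^3)
  out$relaxed <- TRUE
  out
}

# Shift coordinates so the lamina centroid sits at the origin (the nucleus
# diffuses freely during relaxation; protocols are defined about the center).
recenter_nucleus <- function(nucleus) {
  ctr <- colMeans(nucleus$positions[lamina_indices(nucleus), , drop = FALSE])
  nucleus$positions <- sweep(nucleus$positions, 2, ctr)
  nucleus
}

#' Measured mean shell radius
#'
#' @param nucleus An `nm_nucleus`.
#' @return Mean distance of lamina subunits from their centroid (sigma).
#' @export
shell_radius <- function(nucleus) {
  p <- nucleus$positions[lamina_indices(nucleus), , drop = FALSE]
  mean(sqrt(rowSums(sweep(p, 2, colMeans(p))^2)))
}

#' Chromatin volume fraction recomputed from the model
#'
#' @param nucleus A relaxed `nm_nucleus`.
#' @param R0 Reference radius (defaults to the stored relaxed radius).
#' @return phi, dimensionless.
#' @export
nucleus_phi <- function(nucleus, R0 = nucleus$R0) {
  nucleus$n_chromatin / (8 * R0^3)
}

#' Reduced-scale geometry preserving the full-scale dimensionless state
#'
#' Chooses shell radii so that the target volume fraction is reached at a
#' relaxed radius whose ratios to `R_s` and `R_i` match the full-scale
#' 29:32:42 proportions.
#'
#' @param n_chromatin Total chromatin subunits.
#' @param phi_target Target volume fraction (default 0.23).
#' @return List with `R0_target`, `R_s`, `R_i`.
#' @export
scaled_radii <- function(n_chromatin, phi_target = 0.23) {
  r0 <- (n_chromatin / (8 * phi_target))^(1 / 3)
  list(R0_target = r0, R_s = r0 * 32 / 29, R_i = r0 * 42 / 29)
}

#' @export
print.nm_nucleus <- function(x, ...) {
  cat(sprintf("<nm_nucleus> %d chromatin + %d lamina subunits, %d bonds\n",
              x$n_chromatin, x$n_lamina, nrow(x$bonds)))
  if (x$relaxed) {
    cat(sprintf("  relaxed: R0 = %.2f sigma (R_s = %.2f), phi = %.3f\n",
                x$R0, x$R_s, x$phi))
  } else {
    cat(sprintf("  unrelaxed at R_i = %.2f sigma\n", x$R_i))
  }
  invisible(x)
}

#' @describeIn tidy_nucmech Per-subunit view of a nucleus model.
#' @export
tidy.nm_nucleus <- function(x, ...) {
  pos <- x$positions
  tibble::tibble(
    index = seq_len(nrow(pos)),
    chromosome = x$chromosome,
    subunit = x$subunit,
    class = factor(class_label(x$class_code), levels = NM_CLASSES),
    x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

#' Broom-style summaries of nucmech objects
#'
#' `tidy()` returns per-record tibbles (subunits, pairwise tests); `glance()`
#' returns one-row model summaries.
#'
#' @param x A nucmech object.
#' @param ... Unused.
#' @name tidy_nucmech
NULL

#' @describeIn tidy_nucmech One-row summary of a nucleus model.
#' @export
glance.nm_nucleus <- function(x, ...) {
  tibble::tibble(
    n_chromatin = x$n_chromatin, n_lamina = x$n_lamina,
    n_bonds = nrow(x$bonds), R_i = x$R_i, R_s = x$R_s, R0 = x$R0,
    phi = x$phi, relaxed = x$relaxed)
}
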