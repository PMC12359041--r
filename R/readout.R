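# In-silico DamID and Hi-C style readouts.
#
# Contacts are subunit pairs within r_c = 2.5 sigma (boundary inclusive);
# the lamina contact index is 1 for chromatin subunits within r_L = 2.5
# sigma of any lamina subunit and 0 otherwise, averaged over frames. P(s) is
# the mean contact frequency of intra-chromosome pairs at genomic separation
# s (optionally restricted by chromatin class), with 40 kb per subunit for
# Mb coordinates.

MB_PER_SUBUNIT <- 0.04

#' Chromatin contact pairs in one snapshot
#'
#' All unordered chromatin-chromatin pairs within `r_c` (inclusive),
#' computed by spatial partitioning.
#'
#' @param positions N x 3 coordinate matrix (a trajectory frame), or an
#'   `nm_nucleus` to use its stored positions.
#' @param nucleus The `nm_nucleus` providing topology.
#' @param r_c Contact radius (sigma, default 2.5).
#' @return Tibble `i`, `j` (model indices, i < j), `same_chromosome`, `s`
#'   (genomic separation in subunits; `NA` for inter-chromosome pairs).
#' @export
contact_pairs <- function(positions, nucleus, r_c = 2.5) {
  if (inherits(positions, "nm_nucleus")) {
    nucleus <- positions
    positions <- nucleus$positions
  }
  chr <- chromatin_indices(nucleus)
  pairs <- cpp_pairs_within(positions, r_c, chr, integer(0))
  if (nrow(pairs) == 0) {
    return(tibble::tibble(i = integer(0), j = integer(0),
                          same_chromosome = logical(0), s = integer(0)))
  }
  same <- nucleus$chromosome[pairs[, 1]] == nucleus$chromosome[pairs[, 2]]
  s <- ifelse(same, abs(nucleus$subunit[pairs[, 1]] -
                          nucleus$subunit[pairs[, 2]]), NA_integer_)
  tibble::tibble(i = pairs[, 1], j = pairs[, 2], same_chromosome = same,
                 s = as.integer(s))
}

# Eligible intra-chromosome pair counts at each separation s for a class
# filter; returns integer vector indexed by s = 1..(max chain length - 1).
eligible_pair_counts <- function(nucleus, filter_code) {
  chr <- chromatin_indices(nucleus)
  out <- NULL
  for (cid in unique(nucleus$chromosome[chr])) {
    idx <- chr[which(nucleus$chromosome[chr] == cid)]
    idx <- idx[order(nucleus$subunit[idx])]
    e <- nucleus$class_code[idx] %in% filter_code
    n <- length(e)
    counts <- vapply(seq_len(n - 1), function(s) {
      sum(e[seq_len(n - s)] & e[seq(1 + s, n)])
    }, numeric(1))
    if (is.null(out)) out <- counts
    else {
      len <- max(length(out), length(counts))
      out <- c(out, rep(0, len - length(out))) +
        c(counts, rep(0, len - length(counts)))
    }
  }
  out
}

#' Contact-frequency curve P(s)
#'
#' For each genomic separation `s`, the probability that an eligible
#' intra-chromosome pair (both subunits in `class_filter`) is in contact,
#' averaged over snapshots. Supports raw per-separation output or log-spaced
#' binning (8 bins per decade).
#'
#' @param frames List of coordinate matrices (snapshots).
#' @param nucleus The `nm_nucleus` providing topology and classes.
#' @param class_filter Chromatin classes included (default `"FAC"`); both
#'   pair members must belong to it.
#' @param r_c Contact radius (sigma, default 2.5).
#' @param s_range Optional length-2 separation range in subunits.
#' @param bins `"raw"` or `"log"` (8 log-spaced bins per decade).
#' @return An `nm_ps` tibble: `s` (subunits), `s_mb`, `p`, `n_pairs`
#'   (eligible pair-frames per row).
#' @export
ps_curve <- function(frames, nucleus, class_filter = "FAC", r_c = 2.5,
                     s_range = NULL, bins = c("raw", "log")) {
  bins <- match.arg(bins)
  if (!is.list(frames)) frames <- list(frames)
  if (length(frames) == 0) abort("need at least one snapshot")
  filter_code <- class_code(class_filter)
  chr <- chromatin_indices(nucleus)
  if (!any(nucleus$class_code[chr] %in% filter_code)) {
    abort("class filter matches no chromatin subunits")
  }
  eligible <- eligible_pair_counts(nucleus, filter_code)
  s_max <- length(eligible)
  counts <- numeric(s_max)
  for (fr in frames) {
    cp <- contact_pairs(fr, nucleus, r_c)
    cp <- cp[cp$same_chromosome &
               nucleus$class_code[cp$i] %in% filter_code &
               nucleus$class_code[cp$j] %in% filter_code, , drop = FALSE]
    if (nrow(cp) > 0) {
      tab <- tabulate(cp$s, s_max)
      counts <- counts + tab
    }
  }
  df <- tibble::tibble(
    s = seq_len(s_max),
    p = ifelse(eligible > 0, counts / (eligible * length(frames)), NA_real_),
    n_pairs = eligible * length(frames))
  df <- df[!is.na(df$p), , drop = FALSE]
  if (!is.null(s_range)) {
    df <- df[df$s >= s_range[1] & df$s <= s_range[2], , drop = FALSE]
  }
  if (bins == "log") {
    edges <- 10^(seq(0, ceiling(log10(max(df$s))) + 1 / 8, by = 1 / 8))
    df$bin <- cut(df$s, breaks = unique(c(0, edges)), labels = FALSE)
    df <- df %>%
      dplyr::group_by(.data$bin) %>%
      dplyr::summarise(
        s = exp(sum(log(.data$s) * .data$n_pairs) / sum(.data$n_pairs)),
        p = sum(.data$p * .data$n_pairs) / sum(.data$n_pairs),
        n_pairs = sum(.data$n_pairs), .groups = "drop") %>%
      dplyr::select(-dplyr::any_of("bin"))
  }
  df$s_mb <- df$s * MB_PER_SUBUNIT
  df <- df[, c("s", "s_mb", "p", "n_pairs")]
  structure(df, class_filter = class_filter, r_c = r_c,
            n_frames = length(frames),
            class = c("nm_ps", class(df)))
}

#' Simulated DamID: lamina contact-index profile
#'
#' Per chromatin subunit, the fraction of snapshots in which the subunit lies
#' within `r_L` of any lamina subunit (per-frame index 0/1, averaged).
#'
#' @param frames List of coordinate matrices.
#' @param nucleus The `nm_nucleus`.
#' @param r_L Lamina contact radius (sigma, default 2.5).
#' @return An `nm_profile` tibble: `chromosome`, `subunit`, `start_mb`,
#'   `class`, `contact_index` in `[0, 1]`.
#' @export
damid_profile <- function(frames, nucleus, r_L = 2.5) {
  if (!is.list(frames)) frames <- list(frames)
  if (length(frames) == 0) abort("need at least one snapshot")
  if (nucleus$n_lamina == 0) abort("model has no lamina subunits")
  chr <- chromatin_indices(nucleus)
  lam <- lamina_indices(nucleus)
  hits <- numeric(length(chr))
  for (fr in frames) {
    pairs <- cpp_pairs_within(fr, r_L, chr, lam)
    idx <- unique(pairs[, 1])
    hits[idx] <- hits[idx] + 1
  }
  df <- tibble::tibble(
    chromosome = nucleus$chromosome[chr],
    subunit = nucleus$subunit[chr],
    start_mb = (nucleus$subunit[chr] - 1) * MB_PER_SUBUNIT,
    class = factor(class_label(nucleus$class_code[chr]), levels = NM_CLASSES),
    contact_index = hits / length(frames))
  structure(df, r_L = r_L, frames_used = length(frames),
            class = c("nm_profile", class(df)))
}

#' Percentage of heterochromatin in lamina contact (LAD percentage)
#'
#' A subunit counts as lamina-contacting when its mean contact index is at
#' least `threshold` (default: contact in >= 50% of sampled frames).
#'
#' @param profile An `nm_profile`.
#' @param classes Classes counted as heterochromatin
#'   (default `c("CON", "FAC")`).
#' @param threshold Mean contact-index threshold (default 0.5).
#' @return Percentage in `[0, 100]`.
#' @export
lad_percentage <- function(profile, classes = c("CON", "FAC"),
                           threshold = 0.5) {
  het <- profile[as.character(profile$class) %in% classes, , drop = FALSE]
  if (nrow(het) == 0) return(0)
  100 * mean(het$contact_index >= threshold)
}

#' Relative change in contact frequency after deformation
#'
#' Elementwise absolute relative change
#' \eqn{|\Delta_{rel}(s)| = |(P_{after}(s) - P_{before}(s)) / P_{before}(s)|}
#' between two P(s) curves on matching separation axes, plus the total
#' summed over all genomic distances.
#'
#' @param before,after `nm_ps` curves on the same `s` axis.
#' @return An `nm_delta` tibble (`s`, `s_mb`, `delta_rel`) with a `total`
#'   attribute; bins with zero baseline are dropped with a warning.
#' @export
delta_rel <- function(before, after) {
  if (nrow(before) != nrow(after) ||
      max(abs(before$s - after$s)) > 1e-8 * max(before$s)) {
    abort("`before` and `after` must share the same separation axis")
  }
  zero <- before$p == 0
  if (any(zero)) {
    warn(sprintf("dropping %d separation bin(s) with zero baseline P(s)",
                 sum(zero)))
  }
  df <- tibble::tibble(
    s = before$s[!zero], s_mb = before$s_mb[!zero],
    delta_rel = abs((after$p[!zero] - before$p[!zero]) / before$p[!zero]))
  structure(df, total = sum(df$delta_rel),
            class = c("nm_delta", class(df)))
}

#' Total absolute relative contact change
#'
#' @param delta An `nm_delta` from [delta_rel()].
#' @return Scalar: summed `|delta_rel|` over all separations.
#' @export
delta_rel_total <- function(delta) attr(delta, "total")

#' Sample snapshots before/after the 30%-strain crossing
#'
#' Evenly spaced frames from a pulling trajectory: the `before` window holds
#' frames with strain below `strain_threshold`, the `after` window frames at
#' or beyond the crossing.
#'
#' @param pull An `nm_pull` from [stretch()].
#' @param phase `"before"` or `"after"`.
#' @param n_before,n_after Number of frames requested per phase (full-scale
#'   convention: 10 and 110).
#' @param strain_threshold Strain defining the crossing (default 0.30).
#' @return List of coordinate matrices, with frame steps as the
#'   `frame_steps` attribute.
#' @export
snapshot_sampler <- function(pull, phase = c("before", "after"),
                             n_before = 10L, n_after = 110L,
                             strain_threshold = 0.30) {
  phase <- match.arg(phase)
  stopifnot(inherits(pull, "nm_pull"))
  if (max(pull$frame_strain) < strain_threshold) {
    abort(sprintf("trajectory never reaches %.0f%% strain (max %.1f%%)",
                  100 * strain_threshold, 100 * max(pull$frame_strain)))
  }
  idx <- if (phase == "before") {
    which(pull$frame_strain < strain_threshold)
  } else {
    which(pull$frame_strain >= strain_threshold)
  }
  want <- if (phase == "before") n_before else n_after
  if (length(idx) < want) {
    abort(sprintf("only %d frames available in the %s window (requested %d)",
                  length(idx), phase, want))
  }
  pick <- idx[unique(round(seq(1, length(idx), length.out = want)))]
  structure(pull$frames[pick], frame_steps = pull$frame_steps[pick])
}

#' Aggregate contact map over snapshots
#'
#' Sparse per-pair contact counts (model indices), summed over frames.
#'
#' @inheritParams ps_curve
#' @return Tibble `i`, `j`, `count`.
#' @export
contact_map <- function(frames, nucleus, r_c = 2.5) {
  if (!is.list(frames)) frames <- list(frames)
  acc <- list()
  for (fr in frames) {
    cp <- contact_pairs(fr, nucleus, r_c)
    acc[[length(acc) + 1]] <- cp[, c("i", "j")]
  }
  dplyr::bind_rows(acc) %>%
    dplyr::count(.data$i, .data$j, name = "count") %>%
    dplyr::arrange(.data$i, .data$j)
}

#' Export a contact-index profile as bedGraph-like text
#'
#' @param profile An `nm_profile`.
#' @param path Output path (`chrom`, `start`, `end`, `contact_index`).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  bed <- tibble::tibble(
    chrom = paste0("chr", profile$chromosome),
    start = (profile$subunit - 1L) * SUBUNIT_BP,
    end = profile$subunit * SUBUNIT_BP,
    contact_index = profile$contact_index)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Export a P(s) or delta-rel curve as TSV
#'
#' @param x An `nm_ps` or `nm_delta` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}
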