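# Synthetic chromatin class annotations.
#
# Each model chromosome is a triblock copolymer: a telomere subunit at each
# end, one contiguous block of constitutive heterochromatin (CON) adjacent to
# one telomere, and a "compartment" region in which facultative
# heterochromatin (FAC, B-type) and euchromatin (EUC, A-type) alternate in
# blocks. The generator stands in for compartment tracks derived from real
# Hi-C data: only the facultative fraction f and the existence of
# compartment-scale blocks are fixed by the model; block lengths are drawn
# geometrically (mean `mean_block_len` for FAC, scaled for EUC so that the
# expected FAC fraction is f) and then boundary-adjusted to hit the exact
# FAC count.

SUBUNIT_BP <- 40000L  # genomic span per subunit: 40 kb

new_annotation <- function(df, f, mean_block_len) {
  structure(
    df,
    f = f,
    mean_block_len = mean_block_len,
    subunit_size = SUBUNIT_BP,
    class = c("nm_annotation", class(tibble::tibble()))
  )
}

#' Generate a synthetic chromatin class annotation for one chromosome
#'
#' Produces a per-subunit class track with the triblock layout used by the
#' nucleus model: `TEL` at both ends, one contiguous `CON` block of
#' `n_con` subunits adjacent to the first telomere, and an interior
#' compartment region of alternating `FAC`/`EUC` blocks whose realized `FAC`
#' count is exactly `round(f * n_comp)`.
#'
#' @param n_subunits Total subunits per chromosome (full scale: 6002; each
#'   subunit is 40 kb of chromatin, size \eqn{\sigma}).
#' @param n_con Size of the constitutive-heterochromatin block (full scale:
#'   1000).
#' @param f Facultative-heterochromatin fraction of the compartment region
#'   (control: 0.45).
#' @param mean_block_len Mean FAC block length, in subunits (default 25,
#'   i.e. 1 Mb).
#' @param seed Integer seed; identical seeds give identical tracks.
#' @param chromosome_id Integer chromosome identifier stored in the track.
#' @return An `nm_annotation` tibble with columns `chromosome_id`, `subunit`
#'   and `class` (factor over [nm_classes()]), carrying `f`,
#'   `mean_block_len` and `subunit_size` attributes.
#' @examples
#' track <- generate_annotation(602, 100, 0.45, 25, seed = 1)
#' table(track$class)
#' @export
generate_annotation <- function(n_subunits, n_con, f, mean_block_len = 25,
                                seed, chromosome_id = 1L) {
  n_subunits <- check_count(n_subunits, "n_subunits", min = 3)
  n_con <- check_count(n_con, "n_con", min = 0)
  check_fraction(f, "f")
  if (mean_block_len < 1) abort("`mean_block_len` must be >= 1")
  if (n_con + 2 > n_subunits) {
    abort("`n_subunits` must be at least `n_con + 2` (telomeres + CON block)")
  }
  n_comp <- n_subunits - n_con - 2L
  comp <- local_seed(seed, compartment_blocks(n_comp, f, mean_block_len))
  labels <- c("TEL", rep("CON", n_con), comp, "TEL")
  df <- tibble::tibble(
    chromosome_id = as.integer(chromosome_id),
    subunit = seq_len(n_subunits),
    class = factor(labels, levels = NM_CLASSES)
  )
  new_annotation(df, f = f, mean_block_len = mean_block_len)
}

# Alternating FAC/EUC blocks with geometric-like lengths; exact FAC count.
compartment_blocks <- function(n_comp, f, mean_block_len) {
  if (n_comp == 0) return(character(0))
  target <- round(f * n_comp)
  if (target == 0) return(rep("EUC", n_comp))
  if (target == n_comp) return(rep("FAC", n_comp))
  mean_fac <- mean_block_len
  mean_euc <- mean_block_len * (1 - f) / f
  draw_len <- function(mean_len) {
    # geometric on {1, 2, ...} with the requested mean
    rgeom(1L, prob = 1 / max(mean_len, 1)) + 1L
  }
  labels <- character(0)
  cur <- if (runif(1) < f) "FAC" else "EUC"
  while (length(labels) < n_comp) {
    len <- draw_len(if (cur == "FAC") mean_fac else mean_euc)
    labels <- c(labels, rep(cur, len))
    cur <- if (cur == "FAC") "EUC" else "FAC"
  }
  labels <- labels[seq_len(n_comp)]
  # boundary flips to reach the exact FAC count without destroying blocks
  repeat {
    excess <- sum(labels == "FAC") - target
    if (excess == 0) break
    from <- if (excess > 0) "FAC" else "EUC"
    to <- if (excess > 0) "EUC" else "FAC"
    is_from <- labels == from
    nbr_other <- (c(FALSE, !is_from[-n_comp]) | c(!is_from[-1], FALSE))
    edge <- which(is_from & nbr_other)
    if (length(edge) == 0) edge <- which(is_from)
    k <- min(length(edge), abs(excess))
    labels[sample(edge, k)] <- to
  }
  labels
}

#' Generate the model genome: several chromosomes from few distinct tracks
#'
#' The full-scale nucleus carries eight chromosomes built as four copies each
#' of two independently generated tracks (mirroring two source chromosomes
#' used four times each). At reduced scale any `n_chromosomes` /
#' `n_distinct` combination can be requested.
#'
#' @inheritParams generate_annotation
#' @param n_chromosomes Number of chromosomes in the nucleus.
#' @param n_distinct Number of independently generated distinct tracks; copies
#'   are assigned round-robin.
#' @return An `nm_annotation` tibble covering all chromosomes.
#' @export
generate_genome <- function(n_chromosomes = 8L, n_distinct = 2L,
                            n_subunits = 6002L, n_con = 1000L, f = 0.45,
                            mean_block_len = 25, seed = 1L) {
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes")
  n_distinct <- check_count(n_distinct, "n_distinct")
  base <- lapply(seq_len(n_distinct), function(k) {
    generate_annotation(n_subunits, n_con, f, mean_block_len,
                        seed = derive_seed(seed, "annotation", k))
  })
  out <- lapply(seq_len(n_chromosomes), function(c) {
    tr <- base[[(c - 1L) %% n_distinct + 1L]]
    tr$chromosome_id <- as.integer(c)
    tr
  })
  new_annotation(dplyr::bind_rows(out), f = f, mean_block_len = mean_block_len)
}

#' Write an annotation track as BED-like text
#'
#' One line per subunit: `chrom`, `start`, `end`, `class`, tab-separated,
#' 0-based half-open coordinates at 40-kb resolution (subunit `i` maps to
#' `[(i-1)*40000, i*40000)`).
#'
#' @param track An `nm_annotation` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(track, path) {
  stopifnot(inherits(track, "nm_annotation"))
  bed <- tibble::tibble(
    chrom = paste0("chr", track$chromosome_id),
    start = (track$subunit - 1L) * SUBUNIT_BP,
    end = track$subunit * SUBUNIT_BP,
    class = as.character(track$class)
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED-like annotation track
#'
#' Parses the format written by [write_annotation()], validating interval
#' width, contiguity and class labels; malformed input raises a format error
#' naming the offending line.
#'
#' @param path Input file path.
#' @param f Facultative fraction to record on the track (recomputed from the
#'   labels when `NULL`).
#' @return An `nm_annotation` tibble.
#' @export
read_annotation <- function(path, f = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    fl <- fields[[i]]
    if (length(fl) != 4) {
      abort(sprintf("line %d: expected 4 tab-separated fields, found %d",
                    i, length(fl)))
    }
    if (!fl[4] %in% NM_CLASSES) {
      abort(sprintf("line %d: unknown class label '%s'", i, fl[4]))
    }
    start <- suppressWarnings(as.numeric(fl[2]))
    end <- suppressWarnings(as.numeric(fl[3]))
    if (is.na(start) || is.na(end) || end - start != SUBUNIT_BP) {
      abort(sprintf("line %d: interval must span exactly %d bp", i, SUBUNIT_BP))
    }
  }
  chrom <- vapply(fields, `[`, character(1), 1)
  start <- as.numeric(vapply(fields, `[`, character(1), 2))
  cls <- vapply(fields, `[`, character(1), 4)
  chr_id <- as.integer(sub("^chr", "", chrom))
  if (anyNA(chr_id)) abort("chromosome names must be of the form 'chr<integer>'")
  df <- tibble::tibble(
    chromosome_id = chr_id,
    subunit = as.integer(start / SUBUNIT_BP) + 1L,
    class = factor(cls, levels = NM_CLASSES)
  )
  df <- dplyr::arrange(df, .data$chromosome_id, .data$subunit)
  for (cid in unique(df$chromosome_id)) {
    sub <- df$subunit[df$chromosome_id == cid]
    if (any(diff(sub) != 1) || sub[1] != 1) {
      bad <- which(df$chromosome_id == cid)[which(c(sub[1] != 1, diff(sub) != 1))[1]]
      abort(sprintf("line %d: intervals for chr%d are not contiguous/non-overlapping",
                    bad, cid))
    }
  }
  comp <- as.character(df$class) %in% c("FAC", "EUC")
  f_real <- if (any(comp)) mean(df$class[comp] == "FAC") else 0
  new_annotation(df, f = if (is.null(f)) f_real else f, mean_block_len = NA_real_)
}

#' @export
print.nm_annotation <- function(x, ...) {
  counts <- table(x$class)
  cat(sprintf("<nm_annotation> %d chromosome(s), %d subunits (f = %.3f)\n",
              length(unique(x$chromosome_id)), nrow(x), attr(x, "f")))
  print(counts)
  invisible(x)
}
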