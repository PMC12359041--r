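# Plain-text model snapshot IO: an extended-XYZ-compatible coordinate file
# (per-subunit class, chromosome, subunit index, x, y, z) plus a bond-list
# sidecar table.

#' Write a nucleus model as text
#'
#' @param nucleus An `nm_nucleus`.
#' @param path_xyz Coordinate file path (XYZ-style: count line, metadata
#'   line, then `class chromosome subunit x y z` rows).
#' @param path_bonds Bond sidecar TSV path (`i`, `j`, `type`).
#' @return `path_xyz`, invisibly.
#' @export
write_model <- function(nucleus, path_xyz,
                        path_bonds = sub("\\.[^.]+$", "_bonds.tsv", path_xyz)) {
  stopifnot(inherits(nucleus, "nm_nucleus"))
  n <- nrow(nucleus$positions)
  meta <- sprintf(
    "n_chromatin=%d n_lamina=%d R_i=%.8g R_s=%.8g R0=%.8g phi=%.8g relaxed=%d",
    nucleus$n_chromatin, nucleus$n_lamina, nucleus$R_i,
    nucleus$R_s, nucleus$R0, nucleus$phi, as.integer(nucleus$relaxed))
  rows <- sprintf("%s %d %d %.10g %.10g %.10g",
                  class_label(nucleus$class_code),
                  ifelse(is.na(nucleus$chromosome), 0L, nucleus$chromosome),
                  ifelse(is.na(nucleus$subunit), 0L, nucleus$subunit),
                  nucleus$positions[, 1], nucleus$positions[, 2],
                  nucleus$positions[, 3])
  writeLines(c(as.character(n), meta, rows), path_xyz)
  readr::write_tsv(nucleus$bonds, path_bonds)
  invisible(path_xyz)
}

#' Read a nucleus model written by [write_model()]
#'
#' @param path_xyz Coordinate file path.
#' @param path_bonds Bond sidecar TSV path.
#' @return An `nm_nucleus` (without annotation).
#' @export
read_model <- function(path_xyz,
                       path_bonds = sub("\\.[^.]+$", "_bonds.tsv", path_xyz)) {
  lines <- readLines(path_xyz)
  n <- as.integer(lines[1])
  meta <- strsplit(strsplit(lines[2], " ", fixed = TRUE)[[1]], "=", fixed = TRUE)
  mv <- setNames(vapply(meta, `[`, character(1), 2),
                 vapply(meta, `[`, character(1), 1))
  fields <- strsplit(lines[seq(3, 2 + n)], " ", fixed = TRUE)
  cls <- vapply(fields, `[`, character(1), 1)
  chrom <- as.integer(vapply(fields, `[`, character(1), 2))
  sub <- as.integer(vapply(fields, `[`, character(1), 3))
  pos <- matrix(as.numeric(unlist(lapply(fields, `[`, 4:6))), ncol = 3,
                byrow = TRUE)
  bonds <- readr::read_tsv(path_bonds, show_col_types = FALSE)
  bonds$i <- as.integer(bonds$i)
  bonds$j <- as.integer(bonds$j)
  new_nucleus(
    positions = pos, class_code = class_code(cls),
    chromosome = ifelse(chrom == 0L, NA_integer_, chrom),
    subunit = ifelse(sub == 0L, NA_integer_, sub),
    bonds = bonds,
    n_chromatin = as.integer(mv[["n_chromatin"]]),
    n_lamina = as.integer(mv[["n_lamina"]]),
    R_i = as.numeric(mv[["R_i"]]), R_s = as.numeric(mv[["R_s"]]),
    R0 = as.numeric(mv[["R0"]]), phi = as.numeric(mv[["phi"]]),
    relaxed = mv[["relaxed"]] == "1")
}

#' Write a force-strain curve as TSV
#'
#' Columns: `step`, `time_tau`, `anchor_y`, `force`, `extension`, `strain`.
#'
#' @param curve An `nm_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  readr::write_tsv(tibble::as_tibble(curve), path)
  invisible(path)
}
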