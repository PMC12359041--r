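# Class-pair interaction matrix.
#
# Pairwise short-range attractions are truncated 12-6 wells of depth E_ij
# (in kT) cut at 2.5 sigma; class pairs with zero depth interact through a
# purely repulsive core cut at 2^(1/6) sigma. Heterochromatin self-affinities
# and the nonspecific heterochromatin-lamina affinity E_HL drive microphase
# separation and peripheral heterochromatin localization.

ATTRACT_CUTOFF <- 2.5
REPEL_CUTOFF <- 2^(1 / 6)

#' Default class-pair interaction matrix
#'
#' Well depths in kT: CON-CON 0.5, FAC-FAC 0.4, CON-FAC 0.3, and a
#' nonspecific heterochromatin-lamina attraction `E_HL` applied to both
#' CON-LAM and FAC-LAM. All pairs involving EUC or TEL are purely repulsive.
#'
#' @param E_HL Heterochromatin-lamina well depth (kT, default 0.5).
#' @param E_CC,E_FF,E_CF Heterochromatin self/cross well depths (kT).
#' @param sigma_LL Lamina-lamina pair diameter in sigma (default 0.8): the
#'   meshwork nodes are smaller than chromatin subunits so that the shell can
#'   contract to its stress-free radius without its cores jamming first.
#' @param sigma_CL Chromatin-lamina pair diameter in sigma (default 1.2):
#'   the meshwork presents an effective excluded thickness to chromatin,
#'   preventing subunits from slipping through bond-network gaps while the
#'   shell is still sparse during assembly.
#' @return An `nm_interaction` matrix (5 x 5, symmetric, classes as dimnames)
#'   with `attract_cutoff`/`repel_cutoff`/`sigma` attributes.
#' @export
default_interaction <- function(E_HL = 0.5, E_CC = 0.5, E_FF = 0.4,
                                E_CF = 0.3, sigma_LL = 0.8, sigma_CL = 1.2) {
  m <- matrix(0, 5, 5, dimnames = list(NM_CLASSES, NM_CLASSES))
  m["CON", "CON"] <- E_CC
  m["FAC", "FAC"] <- E_FF
  m["CON", "FAC"] <- m["FAC", "CON"] <- E_CF
  m["CON", "LAM"] <- m["LAM", "CON"] <- E_HL
  m["FAC", "LAM"] <- m["LAM", "FAC"] <- E_HL
  s <- matrix(1, 5, 5, dimnames = list(NM_CLASSES, NM_CLASSES))
  s["LAM", ] <- s[, "LAM"] <- sigma_CL
  s["LAM", "LAM"] <- sigma_LL
  structure(m, attract_cutoff = ATTRACT_CUTOFF, repel_cutoff = REPEL_CUTOFF,
            sigma = s, class = c("nm_interaction", "matrix", "array"))
}

sigma_of <- function(interaction) {
  s <- attr(interaction, "sigma")
  if (is.null(s)) s <- matrix(1, 5, 5)
  unclass(s)[seq_len(5), seq_len(5)]
}

#' Set a class-pair affinity
#'
#' Returns a new interaction matrix with the well depth of `class_pair`
#' (and its transpose) replaced. Use `c("CON", "LAM")` and `c("FAC", "LAM")`
#' to sweep the heterochromatin-lamina affinity E_HL, or the heterochromatin
#' self pairs to sweep E_HH.
#'
#' @param interaction An `nm_interaction` matrix.
#' @param class_pair Character vector of two class labels.
#' @param depth Well depth in kT (must be >= 0).
#' @return The updated `nm_interaction` matrix.
#' @export
set_affinity <- function(interaction, class_pair, depth) {
  stopifnot(inherits(interaction, "nm_interaction"))
  if (length(class_pair) != 2) abort("`class_pair` must name two classes")
  code <- class_code(class_pair)  # errors on unknown labels
  if (!is.numeric(depth) || length(depth) != 1 || is.na(depth) || depth < 0) {
    abort("`depth` must be a single non-negative number (kT)")
  }
  interaction[code[1], code[2]] <- depth
  interaction[code[2], code[1]] <- depth
  interaction
}

#' Scale the heterochromatin-lamina affinity
#'
#' Convenience wrapper multiplying both CON-LAM and FAC-LAM well depths,
#' e.g. `fold = 4` for a fourfold affinity sweep.
#'
#' @param interaction An `nm_interaction` matrix.
#' @param fold Multiplicative factor (>= 0).
#' @return The updated matrix.
#' @export
scale_lamina_affinity <- function(interaction, fold) {
  interaction <- set_affinity(interaction, c("CON", "LAM"),
                              interaction["CON", "LAM"] * fold)
  set_affinity(interaction, c("FAC", "LAM"),
               interaction["FAC", "LAM"] * fold)
}

check_interaction <- function(m) {
  stopifnot(inherits(m, "nm_interaction"))
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE))) {
    abort("interaction matrix must be symmetric")
  }
  if (any(m < 0)) abort("interaction well depths must be >= 0")
  invisible(m)
}
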