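# Post-equilibration perturbation operators: lamina tethering, intra-
# heterochromatin crosslinking, and heterochromatin-fraction conversion.
# Tethers and crosslinks are permanent bonds of the same finite-extensible
# family as chain bonds, assigned from contact geometry after equilibration.

#' Assign chromatin-lamina tethers
#'
#' Every eligible chromatin subunit (classes in `eligible_classes`) with at
#' least one lamina subunit within the capture radius `r_L` is, with
#' probability `P_t`, tethered to its nearest lamina subunit. Each chromatin
#' subunit gets at most one lamina partner.
#'
#' @param nucleus A relaxed `nm_nucleus`.
#' @param P_t Tethering probability (default 1).
#' @param r_L Capture radius in sigma (default 2.5).
#' @param eligible_classes Chromatin classes eligible for tethering
#'   (default `c("CON", "FAC")`).
#' @param seed Integer seed for the Bernoulli draws.
#' @return An `nm_tethers` tibble with columns `chromatin`, `lamina`,
#'   `distance`, plus `P_t`, `r_L` and `n_eligible` attributes. The tether
#'   count N_T is `nrow()` of the result.
#' @export
assign_tethers <- function(nucleus, P_t = 1, r_L = 2.5,
                           eligible_classes = c("CON", "FAC"), seed = 1L) {
  stopifnot(inherits(nucleus, "nm_nucleus"))
  check_fraction(P_t, "P_t")
  elig_code <- class_code(eligible_classes)
  chr_idx <- chromatin_indices(nucleus)
  elig <- chr_idx[nucleus$class_code[chr_idx] %in% elig_code]
  pairs <- cpp_pairs_within(nucleus$positions, r_L, elig,
                            lamina_indices(nucleus))
  empty <- tibble::tibble(chromatin = integer(0), lamina = integer(0),
                          distance = numeric(0))
  if (nrow(pairs) == 0) {
    return(structure(empty, P_t = P_t, r_L = r_L, n_eligible = 0L,
                     class = c("nm_tethers", class(empty))))
  }
  dist <- sqrt(rowSums((nucleus$positions[pairs[, 1], , drop = FALSE] -
                          nucleus$positions[pairs[, 2], , drop = FALSE])^2))
  df <- tibble::tibble(chromatin = pairs[, 1], lamina = pairs[, 2],
                       distance = dist) %>%
    dplyr::group_by(.data$chromatin) %>%
    dplyr::slice_min(.data$distance, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup()
  n_in_range <- nrow(df)
  keep <- local_seed(seed, runif(n_in_range) < P_t)
  df <- df[keep, , drop = FALSE]
  structure(df, P_t = P_t, r_L = r_L, n_eligible = n_in_range,
            class = c("nm_tethers", class(empty)))
}

#' Subsample a tether set to a fixed count
#'
#' Used for constant-tether-number comparisons across heterochromatin
#' fractions: the saturated (`P_t = 1`) tether set is subsampled uniformly
#' to `n`.
#'
#' @param tethers An `nm_tethers` set.
#' @param n Target tether count (must not exceed `nrow(tethers)`).
#' @param seed Integer seed.
#' @return The subsampled `nm_tethers`.
#' @export
subsample_tethers <- function(tethers, n, seed = 1L) {
  stopifnot(inherits(tethers, "nm_tethers"))
  n <- check_count(n, "n", min = 0)
  if (n > nrow(tethers)) abort("`n` exceeds the available tether count")
  keep <- local_seed(seed, sample(nrow(tethers), n))
  out <- tethers[sort(keep), , drop = FALSE]
  attributes(out)[c("P_t", "r_L", "n_eligible")] <-
    attributes(tethers)[c("P_t", "r_L", "n_eligible")]
  class(out) <- class(tethers)
  out
}

#' Assign intra-heterochromatin crosslinks
#'
#' Heterochromatin subunits (CON, FAC; telomeres excluded) are visited in
#' seeded random order; each is selected with probability `P_c` and, if
#' selected, greedily linked to in-contact partners (within `r_H`, same class
#' when `same_type_only`) that still have capacity, until its own degree
#' reaches `max_partners`. No subunit ever exceeds `max_partners` crosslinks.
#'
#' @param nucleus A relaxed `nm_nucleus`.
#' @param P_c Crosslinking probability (default 0.2).
#' @param r_H Contact radius in sigma (default 2.5).
#' @param max_partners Maximum crosslinks per subunit (default 2).
#' @param same_type_only Restrict partners to the same heterochromatin class
#'   (default TRUE).
#' @param seed Integer seed.
#' @return An `nm_crosslinks` tibble with columns `i`, `j`, `class_i`,
#'   `class_j`; attributes record `P_c`, `r_H` and the per-class pair counts
#'   `n_FHC` (FAC-FAC) and `n_CHC` (CON-CON).
#' @export
assign_crosslinks <- function(nucleus, P_c = 0.2, r_H = 2.5,
                              max_partners = 2L, same_type_only = TRUE,
                              seed = 1L) {
  stopifnot(inherits(nucleus, "nm_nucleus"))
  check_fraction(P_c, "P_c")
  max_partners <- check_count(max_partners, "max_partners", min = 1)
  chr_idx <- chromatin_indices(nucleus)
  het <- chr_idx[nucleus$class_code[chr_idx] %in% c(2L, 3L)]
  empty <- tibble::tibble(i = integer(0), j = integer(0),
                          class_i = character(0), class_j = character(0),
                          distance = numeric(0))
  finish <- function(df) {
    cls_i <- class_label(nucleus$class_code[df$i])
    cls_j <- class_label(nucleus$class_code[df$j])
    dist <- if (nrow(df) == 0) numeric(0) else {
      sqrt(rowSums((nucleus$positions[df$i, , drop = FALSE] -
                      nucleus$positions[df$j, , drop = FALSE])^2))
    }
    out <- tibble::tibble(i = df$i, j = df$j, class_i = cls_i,
                          class_j = cls_j, distance = dist)
    structure(out, P_c = P_c, r_H = r_H,
              n_FHC = sum(cls_i == "FAC" & cls_j == "FAC"),
              n_CHC = sum(cls_i == "CON" & cls_j == "CON"),
              class = c("nm_crosslinks", class(empty)))
  }
  if (length(het) < 2 || P_c == 0) return(finish(empty))
  pairs <- cpp_pairs_within(nucleus$positions, r_H, het, integer(0))
  if (same_type_only && nrow(pairs) > 0) {
    same <- nucleus$class_code[pairs[, 1]] == nucleus$class_code[pairs[, 2]]
    pairs <- pairs[same, , drop = FALSE]
  }
  if (nrow(pairs) == 0) return(finish(empty))
  # adjacency of contact candidates
  nbr <- split(c(pairs[, 2], pairs[, 1]), c(pairs[, 1], pairs[, 2]))
  deg <- setNames(integer(length(het)), het)
  sel <- local_seed(seed, {
    order_idx <- sample(het)
    picked <- runif(length(order_idx)) < P_c
    partner_perm <- sample.int(1e9, length(order_idx))  # per-subunit stream
    list(order_idx = order_idx, picked = picked, partner_perm = partner_perm)
  })
  out_i <- integer(0); out_j <- integer(0)
  linked <- new.env(hash = TRUE)
  for (k in seq_along(sel$order_idx)) {
    if (!sel$picked[k]) next
    v <- sel$order_idx[k]
    vkey <- as.character(v)
    if (deg[vkey] >= max_partners) next
    cands <- nbr[[vkey]]
    if (is.null(cands)) next
    cands <- local_seed(sel$partner_perm[k], sample(cands))
    for (w in cands) {
      if (deg[vkey] >= max_partners) break
      wkey <- as.character(w)
      if (deg[wkey] >= max_partners) next
      ekey <- paste(min(v, w), max(v, w))
      if (!is.null(linked[[ekey]])) next
      linked[[ekey]] <- TRUE
      out_i <- c(out_i, min(v, w)); out_j <- c(out_j, max(v, w))
      deg[vkey] <- deg[vkey] + 1L
      deg[wkey] <- deg[wkey] + 1L
    }
  }
  finish(tibble::tibble(i = out_i, j = out_j))
}

#' Install tether and/or crosslink bonds into a nucleus
#'
#' Appends the assigned pairs to the bond list as permanent finite-extensible
#' bonds of type `"tether"` / `"crosslink"`. Once installed, the bonds are
#' present in every subsequent frame.
#'
#' @param nucleus An `nm_nucleus`.
#' @param tethers Optional `nm_tethers` set.
#' @param crosslinks Optional `nm_crosslinks` set.
#' @return The nucleus with augmented bonds.
#' @export
install_constraints <- function(nucleus, tethers = NULL, crosslinks = NULL) {
  stopifnot(inherits(nucleus, "nm_nucleus"))
  add <- list()
  if (!is.null(tethers) && nrow(tethers) > 0) {
    add <- c(add, list(tibble::tibble(i = tethers$chromatin,
                                      j = tethers$lamina, type = "tether",
                                      rest = tethers$distance)))
  }
  if (!is.null(crosslinks) && nrow(crosslinks) > 0) {
    add <- c(add, list(tibble::tibble(i = crosslinks$i, j = crosslinks$j,
                                      type = "crosslink",
                                      rest = crosslinks$distance)))
  }
  if (length(add) > 0) {
    nucleus$bonds <- dplyr::bind_rows(c(list(nucleus$bonds), add))
  }
  nucleus
}

#' Convert facultative heterochromatin to/from euchromatin
#'
#' Flips `FAC`/`EUC` labels uniformly at random until the compartment-region
#' FAC fraction equals `f_target` (within one subunit). Constitutive
#' heterochromatin and telomeres are untouched, and positions are unchanged;
#' apply before tether/crosslink assignment.
#'
#' @param nucleus An `nm_nucleus`.
#' @param f_target Target facultative fraction of the compartment region.
#' @param seed Integer seed.
#' @return The relabeled nucleus (its annotation, when present, is updated
#'   consistently).
#' @export
convert_heterochromatin_fraction <- function(nucleus, f_target, seed = 1L) {
  stopifnot(inherits(nucleus, "nm_nucleus"))
  check_fraction(f_target, "f_target")
  code <- nucleus$class_code
  comp <- which(code %in% c(3L, 4L))
  n_comp <- length(comp)
  if (n_comp == 0) return(nucleus)
  target <- round(f_target * n_comp)
  current <- sum(code[comp] == 3L)
  delta <- target - current
  if (delta != 0) {
    flip <- local_seed(seed, {
      if (delta > 0) sample(comp[code[comp] == 4L], delta)
      else sample(comp[code[comp] == 3L], -delta)
    })
    code[flip] <- if (delta > 0) 3L else 4L
    nucleus$class_code <- code
    if (!is.null(nucleus$annotation)) {
      ann <- nucleus$annotation
      key_model <- paste(nucleus$chromosome, nucleus$subunit)
      key_ann <- paste(ann$chromosome_id, ann$subunit)
      ann$class <- factor(class_label(code[match(key_ann, key_model)]),
                          levels = NM_CLASSES)
      attr(ann, "f") <- f_target
      nucleus$annotation <- ann
    }
  }
  nucleus
}

#' Write a tether or crosslink set as a two-column index table
#'
#' @param set An `nm_tethers` or `nm_crosslinks` object.
#' @param path Output TSV path; header comment lines record the assignment
#'   parameters.
#' @return `path`, invisibly.
#' @export
write_constraints <- function(set, path) {
  meta <- if (inherits(set, "nm_tethers")) {
    sprintf("# tethers P_t=%g r_L=%g", attr(set, "P_t"), attr(set, "r_L"))
  } else {
    sprintf("# crosslinks P_c=%g r_H=%g", attr(set, "P_c"), attr(set, "r_H"))
  }
  cols <- if (inherits(set, "nm_tethers")) c("chromatin", "lamina") else c("i", "j")
  writeLines(c(meta, paste(cols, collapse = "\t"),
               paste(set[[cols[1]]], set[[cols[2]]], sep = "\t")), path)
  invisible(path)
}
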