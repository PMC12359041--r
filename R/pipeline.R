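# Config-driven pipeline: one schema drives annotation -> build -> perturb ->
# probe -> readout, with every stochastic stage seeded deterministically from
# (master_seed, stage, replicate).

#' Build a validated run configuration
#'
#' Scale presets: `"full"` (8 x 6002 chromatin subunits, 15000 lamina,
#' radii 42/32 sigma — the headline geometry, hours of compute),
#' `"reduced"` (2 x 600 chromatin, 1500 lamina, radii scaled to preserve
#' phi = 0.23) and `"mini"` (2 x 300 chromatin, 600 lamina, for desk-scale
#' work). Any field can be overridden via `...` using nested lists, e.g.
#' `nm_config("mini", perturb = list(tether = FALSE))`.
#'
#' @param scale Preset name.
#' @param ... Nested overrides merged over the preset.
#' @param master_seed Master seed for all stage streams.
#' @param replicate_index Replicate number (>= 1).
#' @param output_dir Artifact directory for [run_pipeline()].
#' @return A validated `nm_config` list.
#' @export
nm_config <- function(scale = c("reduced", "mini", "full"), ...,
                      master_seed = 1L, replicate_index = 1L,
                      output_dir = tempfile("nucmech_run_")) {
  scale <- match.arg(scale)
  preset <- switch(scale,
    full = list(
      annotation = list(n_chromosomes = 8L, n_distinct = 2L,
                        n_subunits = 6002L, n_con = 1000L, f = 0.45,
                        mean_block_len = 25),
      build = list(n_lamina = 15000L, R_i = 42, R_s = 32, phi_target = 0.23,
                   soft_steps = 5000L, n_stages = 10L, stage_steps = 2000L,
                   relax_steps = 50000L)),
    reduced = list(
      annotation = list(n_chromosomes = 2L, n_distinct = 2L,
                        n_subunits = 600L, n_con = 100L, f = 0.45,
                        mean_block_len = 25),
      build = list(n_lamina = 1500L, R_i = NA, R_s = NA, phi_target = 0.23,
                   soft_steps = 2000L, n_stages = 10L, stage_steps = 800L,
                   relax_steps = 15000L)),
    mini = list(
      annotation = list(n_chromosomes = 2L, n_distinct = 2L,
                        n_subunits = 300L, n_con = 50L, f = 0.45,
                        mean_block_len = 12),
      build = list(n_lamina = 600L, R_i = NA, R_s = NA, phi_target = 0.23,
                   soft_steps = 2000L, n_stages = 10L, stage_steps = 500L,
                   relax_steps = 10000L)))
  base <- c(preset, list(
    interaction = list(E_HL = 0.5, E_CC = 0.5, E_FF = 0.4, E_CF = 0.3),
    perturb = list(tether = TRUE, P_t = 1.0, crosslink = FALSE, P_c = 0.2,
                   same_type_only = TRUE, f_target = NULL),
    probe = list(K = 20, v_pull = 0.1, n_steps = NULL,
                 strain_target = 0.30, window = 0.05,
                 record_every = TAU_STEPS, series_every = TAU_STEPS),
    readout = list(n_before = 10L, n_after = 110L, strain_threshold = 0.30,
                   class_filter = "FAC")))
  cfg <- merge_config(base, list(...))
  cfg$scale <- scale
  cfg$master_seed <- master_seed
  cfg$replicate_index <- as.integer(replicate_index)
  cfg$output_dir <- output_dir
  validate_config(cfg)
  structure(cfg, class = "nm_config")
}

merge_config <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]])) {
      base[[nm]] <- utils::modifyList(base[[nm]], overrides[[nm]],
                                      keep.null = TRUE)
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  bad <- function(path, msg) {
    abort(sprintf("config field `%s` %s", path, msg))
  }
  p <- cfg$perturb
  if (!is.numeric(p$P_t) || p$P_t < 0 || p$P_t > 1) {
    bad("perturb.P_t", "must lie in [0, 1]")
  }
  if (!is.numeric(p$P_c) || p$P_c < 0 || p$P_c > 1) {
    bad("perturb.P_c", "must lie in [0, 1]")
  }
  if (!is.null(p$f_target) && (p$f_target < 0 || p$f_target > 1)) {
    bad("perturb.f_target", "must lie in [0, 1]")
  }
  a <- cfg$annotation
  if (a$n_con + 2 > a$n_subunits) {
    bad("annotation.n_con", "leaves no compartment region")
  }
  if (a$f < 0 || a$f > 1) bad("annotation.f", "must lie in [0, 1]")
  if (cfg$build$n_lamina < 12) bad("build.n_lamina", "must be >= 12")
  if (cfg$probe$K <= 0) bad("probe.K", "must be > 0")
  invisible(cfg)
}

config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, digits.d = 10)),
             collapse = "\n")
  h <- 2166136261
  for (ch in utf8ToInt(s)) h <- bitwAnd((h * 16777619) %% 2^31 + ch, 2^31 - 1)
  sprintf("%08x", h)
}

#' Run the full pipeline for one configuration
#'
#' Stages: synthetic annotation, nucleus build + relaxation, constraint
#' perturbation (fraction conversion, tethers, crosslinks), force
#' spectroscopy, and genomic readouts. Artifacts are written under
#' `config$output_dir`; the expensive build stage is cached by a config hash
#' and reused when unchanged.
#'
#' @param config An `nm_config`.
#' @return A manifest tibble (`file`, `stage`, `md5`) with the computed
#'   summary quantities attached as the `summary` attribute.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "nm_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  seed_for <- function(stage) {
    derive_seed(config$master_seed, stage, config$replicate_index)
  }
  # --- annotation + build (cached) ---
  build_cfg <- config[c("annotation", "build", "interaction", "scale",
                        "master_seed", "replicate_index")]
  hash <- config_hash(build_cfg)
  hash_file <- out("build.hash")
  interaction <- do.call(default_interaction, config$interaction)
  if (file.exists(hash_file) && readLines(hash_file)[1] == hash &&
      file.exists(out("model.xyz"))) {
    nucleus <- read_model(out("model.xyz"))
    annotation <- read_annotation(out("annotation.bed"))
    nucleus$annotation <- annotation
  } else {
    a <- config$annotation
    annotation <- generate_genome(
      n_chromosomes = a$n_chromosomes, n_distinct = a$n_distinct,
      n_subunits = a$n_subunits, n_con = a$n_con, f = a$f,
      mean_block_len = a$mean_block_len, seed = seed_for("annotation"))
    write_annotation(annotation, out("annotation.bed"))
    b <- config$build
    if (is.na(b$R_i)) {
      rr <- scaled_radii(nrow(annotation), b$phi_target)
      b$R_i <- rr$R_i; b$R_s <- rr$R_s
    }
    nucleus <- build_nucleus(annotation, b$n_lamina, b$R_i,
                             seed = seed_for("build"))
    nucleus <- assemble_and_relax(
      nucleus,
      relax_schedule(b$R_s, b$soft_steps, b$n_stages, b$stage_steps,
                     b$relax_steps),
      interaction = interaction, seed = seed_for("relax"))
    write_model(nucleus, out("model.xyz"))
    writeLines(hash, hash_file)
  }
  # --- perturb ---
  p <- config$perturb
  if (!is.null(p$f_target)) {
    nucleus <- convert_heterochromatin_fraction(nucleus, p$f_target,
                                                seed = seed_for("fraction"))
  }
  tethers <- NULL; crosslinks <- NULL
  if (isTRUE(p$tether)) {
    tethers <- assign_tethers(nucleus, P_t = p$P_t, seed = seed_for("tether"))
    write_constraints(tethers, out("tethers.tsv"))
  }
  if (isTRUE(p$crosslink)) {
    crosslinks <- assign_crosslinks(nucleus, P_c = p$P_c,
                                    same_type_only = p$same_type_only,
                                    seed = seed_for("crosslink"))
    write_constraints(crosslinks, out("crosslinks.tsv"))
  }
  nucleus <- install_constraints(nucleus, tethers, crosslinks)
  # --- probe ---
  pr <- config$probe
  state <- sim_state(nucleus, interaction, seed = seed_for("dynamics"))
  protocol <- pull_protocol(nucleus, K = pr$K, v_pull = pr$v_pull,
                            n_steps = pr$n_steps,
                            record_every = pr$record_every,
                            series_every = pr$series_every)
  pull <- stretch(state, protocol, seed = seed_for("poles"))
  write_curve(pull$curve, out("curve.tsv"))
  k_nuc <- tryCatch(
    spring_constant(pull$curve, pr$strain_target, pr$window),
    error = function(e) NA_real_)
  # --- readout ---
  rd <- config$readout
  summary <- list(
    k_nuc = k_nuc, R0 = nucleus$R0, phi = nucleus$phi,
    n_tethers = if (is.null(tethers)) 0L else nrow(tethers),
    n_crosslinks = if (is.null(crosslinks)) 0L else nrow(crosslinks),
    terminal_strain = pull$curve$strain[nrow(pull$curve)])
  readout_ok <- max(pull$frame_strain) >= rd$strain_threshold
  if (readout_ok) {
    before <- snapshot_sampler(pull, "before", n_before = rd$n_before,
                               n_after = rd$n_after,
                               strain_threshold = rd$strain_threshold)
    after <- snapshot_sampler(pull, "after", n_before = rd$n_before,
                              n_after = rd$n_after,
                              strain_threshold = rd$strain_threshold)
    prof_before <- damid_profile(before, nucleus)
    prof_after <- damid_profile(after, nucleus)
    write_profile(prof_before, out("damid_before.bedgraph"))
    write_profile(prof_after, out("damid_after.bedgraph"))
    ps_before <- ps_curve(before, nucleus, class_filter = rd$class_filter)
    ps_after <- ps_curve(after, nucleus, class_filter = rd$class_filter)
    write_curve_tsv(ps_before, out("ps_before.tsv"))
    write_curve_tsv(ps_after, out("ps_after.tsv"))
    dr <- suppressWarnings(delta_rel(ps_before, ps_after))
    write_curve_tsv(dr, out("delta_rel.tsv"))
    summary$lad_pct_before <- lad_percentage(prof_before)
    summary$lad_pct_after <- lad_percentage(prof_after)
    summary$delta_rel_total <- delta_rel_total(dr)
  }
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- list.files(config$output_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- tibble::tibble(
    file = basename(files),
    stage = stage_of_file(basename(files)),
    md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("nucmech")),
         config_hash = config_hash(unclass(config)),
         files = manifest),
    out("manifest.json"), auto_unbox = TRUE, digits = NA)
  structure(manifest, summary = summary, class = c("nm_manifest",
                                                   class(manifest)))
}

stage_of_file <- function(f) {
  dplyr::case_when(
    grepl("^annotation", f) ~ "annotation",
    grepl("^(model|build)", f) ~ "build",
    grepl("^(tethers|crosslinks)", f) ~ "perturb",
    grepl("^curve", f) ~ "probe",
    TRUE ~ "readout")
}

#' Run replicates of one condition and aggregate
#'
#' Replicates use distinct derived seed streams; spring constants, LAD
#' percentages and total contact changes are aggregated as mean plus/minus
#' the standard error of the mean.
#'
#' @param config An `nm_config`.
#' @param n_replicates Number of replicates (>= 2).
#' @return A tibble with one row per quantity: `quantity`, `n`, `mean`,
#'   `sem`. Partial failures are dropped with a warning and the remaining
#'   count disclosed.
#' @export
replicate_sweep <- function(config, n_replicates) {
  stopifnot(inherits(config, "nm_config"))
  n_replicates <- check_count(n_replicates, "n_replicates", min = 2)
  sums <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$replicate_index <- as.integer(r)
    cfg$output_dir <- file.path(config$output_dir, sprintf("rep%02d", r))
    res <- try(run_pipeline(cfg), silent = TRUE)
    if (inherits(res, "try-error")) {
      warn(sprintf("replicate %d failed: %s", r, attr(res, "condition")$message))
    } else {
      sums[[r]] <- attr(res, "summary")
    }
  }
  sums <- Filter(Negate(is.null), sums)
  if (length(sums) < 2) abort("fewer than 2 replicates completed")
  nums <- c("k_nuc", "R0", "phi", "n_tethers", "n_crosslinks",
            "terminal_strain", "lad_pct_before", "lad_pct_after",
            "delta_rel_total")
  rows <- lapply(nums, function(q) {
    vals <- unlist(lapply(sums, function(s) s[[q]]))
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0) return(NULL)
    tibble::tibble(quantity = q, n = length(vals), mean = mean(vals),
                   sem = sd(vals) / sqrt(length(vals)))
  })
  dplyr::bind_rows(rows)
}

#' Read or write a run configuration as YAML
#'
#' The YAML file holds the same nested structure as [nm_config()]: a `scale`
#' key plus any subset of the `annotation`, `build`, `interaction`,
#' `perturb`, `probe` and `readout` sections, along with `master_seed`,
#' `replicate_index` and `output_dir`; unspecified fields fall back to the
#' preset. The result is validated like any other config.
#'
#' @param path YAML file path.
#' @return An `nm_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  scale <- raw$scale %||% "reduced"
  sections <- raw[intersect(names(raw),
                            c("annotation", "build", "interaction",
                              "perturb", "probe", "readout"))]
  do.call(nm_config, c(
    list(scale = scale),
    sections,
    list(master_seed = raw$master_seed %||% 1L,
         replicate_index = raw$replicate_index %||% 1L,
         output_dir = raw$output_dir %||% tempfile("nucmech_run_"))))
}

#' @rdname read_config
#' @param config An `nm_config` to serialize.
#' @return For `write_config`, `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "nm_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
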