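# Pipeline configuration: plain-text "key = value" entries grouped under
# [section] headers. Unknown sections or keys are rejected so typos cannot
# silently fall back to defaults.

#' @keywords internal
#' @noRd
pipeline_config_schema <- function() {
  list(
    global = c("seed", "output_dir", "log_level"),
    simulate = c("sweep_noise_sd", "ssto_amplitude", "ssto_frequency",
                 "membrane_R", "membrane_C", "sampling_rate",
                 "extracell_duration", "ss_rate", "cs_rate",
                 "tissue_true_n", "n_genes"),
    features = c("dvdt_min", "min_prominence", "refractory", "smooth_ms",
                 "lt_halfwidth_max", "adp_min_prominence",
                 "exclude_low_threshold", "junction_potential"),
    invivo = c("noise_k", "min_sep_ms", "min_gap_ratio", "manual_threshold"),
    morph = c("eps_min", "n_ladder", "dendrites_only"),
    stereo = c("section_interval", "frame_x", "frame_y", "grid_x", "grid_y",
               "counting_depth", "section_thickness", "guard_zone"),
    enrich = character(0))
}

#' Parse a pipeline configuration file
#'
#' @param path config file: `[section]` headers with `key = value` lines;
#'   `#` comments allowed. Unknown sections or keys are rejected.
#' @return nested named list of character values (callers coerce types).
#' @export
parse_pipeline_config <- function(path) {
  if (is.null(path)) return(list())
  if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path))
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  schema <- pipeline_config_schema()
  cfg <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (!section %in% names(schema))
        stop(sprintf("unknown config section '[%s]'", section))
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) stop("config entries must appear under a [section]")
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      key <- trimws(kv[1L])
      if (!key %in% schema[[section]])
        stop(sprintf("unknown config key '%s' in section [%s]", key, section))
      cfg[[section]][[key]] <- trimws(paste(kv[-1L], collapse = "="))
    } else {
      stop(sprintf("unparseable config line: '%s'", ln))
    }
  }
  cfg
}

#' @keywords internal
#' @noRd
cfg_num <- function(cfg, section, key, default) {
  v <- cfg[[section]][[key]]
  if (is.null(v)) default else as.numeric(v)
}

#' @keywords internal
#' @noRd
cfg_flag <- function(cfg, section, key, default) {
  v <- cfg[[section]][[key]]
  if (is.null(v)) default else as.logical(v)
}

#' @keywords internal
#' @noRd
write_resolved_config <- function(cfg, out_dir, subcommand, seed) {
  lines <- c(sprintf("# resolved configuration (%s)", subcommand),
             "[global]", sprintf("seed = %d", seed),
             sprintf("output_dir = %s", out_dir))
  for (sec in setdiff(names(cfg), "global")) {
    lines <- c(lines, sprintf("[%s]", sec),
               vapply(names(cfg[[sec]]), function(k)
                 sprintf("%s = %s", k, cfg[[sec]][[k]]), character(1L)))
  }
  writeLines(lines, file.path(out_dir, "resolved-config.txt"))
}

#' @keywords internal
#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @keywords internal
#' @noRd
write_sidecar <- function(values, path) {
  writeLines(sprintf("%s = %s", names(values),
                     vapply(values, function(v)
                       paste(format(v, digits = 12, trim = TRUE),
                             collapse = " "),
                       character(1L))), path)
  invisible(path)
}

#' Run a pipeline stage
#'
#' Thin orchestration over the package's analysis functions: each
#' subcommand reads the declared inputs, runs one stage and writes
#' plain-text artifacts (plus the resolved configuration) into
#' `output_dir`. Outputs are deterministic for a fixed seed.
#'
#' Subcommands: `simulate` (generate every synthetic input with
#' ground-truth sidecars), `convert` (sweep-format conversion), `features`
#' (per-spike/per-cell intracellular features), `invivo` (filtering and
#' complex-spike classification), `morph` (SWC morphometrics), `stereo`
#' (fractionator/Cavalieri/CE estimates from a count table), `enrich`
#' (gene-table enrichment), and `reproduce-enrichment` (no inputs; runs the
#' ion-channel worked example from the published summary counts: 31
#' channel genes among 1374 DEGs against 270 channel genes among 30973
#' assessed transcripts).
#'
#' @param subcommand one of the stages above.
#' @param inputs character vector of input paths (stage-specific).
#' @param config optional path to a config file
#'   (see [parse_pipeline_config()]).
#' @param output_dir output directory (created if missing).
#' @param format_to target format for `convert`.
#' @return invisibly, a character vector of written artifact paths.
#' @export
run_pipeline <- function(subcommand = c("simulate", "convert", "features",
                                        "invivo", "morph", "stereo",
                                        "enrich", "reproduce-enrichment"),
                         inputs = character(0), config = NULL,
                         output_dir = ".", format_to = "rds") {
  subcommand <- match.arg(subcommand)
  cfg <- parse_pipeline_config(config)
  seed <- as.integer(cfg_num(cfg, "global", "seed", 1))
  if (!is.null(cfg$global$output_dir) && missing(output_dir))
    output_dir <- cfg$global$output_dir
  for (f in inputs)
    if (!file.exists(f)) stop(sprintf("input not found: '%s'", f))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- switch(
    subcommand,
    "simulate" = pipeline_simulate(cfg, seed, output_dir),
    "convert" = {
      from <- if (grepl("\\.rds$", inputs[1L])) "rds" else "delimited"
      sw <- read_sweeps(inputs[1L], from)
      out <- file.path(output_dir,
                       paste0("sweeps.", if (format_to == "rds") "rds" else "tsv"))
      write_sweeps(sw, out, format_to)
      out
    },
    "features" = pipeline_features(cfg, inputs, output_dir),
    "invivo" = pipeline_invivo(cfg, inputs, output_dir),
    "morph" = pipeline_morph(cfg, inputs, output_dir),
    "stereo" = pipeline_stereo(cfg, inputs, output_dir),
    "enrich" = pipeline_enrich(inputs, output_dir),
    "reproduce-enrichment" = pipeline_reproduce_enrichment(output_dir))
  write_resolved_config(cfg, output_dir, subcommand, seed)
  invisible(c(artifacts, file.path(output_dir, "resolved-config.txt")))
}

#' @keywords internal
#' @noRd
pipeline_simulate <- function(cfg, seed, out_dir) {
  fs <- cfg_num(cfg, "simulate", "sampling_rate", 2e4)
  params <- synth_ephys_params(
    sampling_rate = fs,
    ssto_frequency = cfg_num(cfg, "simulate", "ssto_frequency", 5),
    ssto_amplitude = 0,
    noise_sd = cfg_num(cfg, "simulate", "sweep_noise_sd", 0.2),
    membrane_R = cfg_num(cfg, "simulate", "membrane_R", 230),
    membrane_C = cfg_num(cfg, "simulate", "membrane_C", 100),
    seed = seed)
  proto <- step_protocol(c(-100, -50, seq(0, 800, by = 50)))
  gen <- gen_intracellular_sweeps(params, proto)
  p_sweeps <- file.path(out_dir, "sweeps.tsv")
  write_sweeps(gen$sweeps, p_sweeps, "delimited")
  truth_all <- do.call(rbind, lapply(seq_along(gen$truth), function(i)
    if (nrow(gen$truth[[i]])) cbind(sweep = i, gen$truth[[i]]) else NULL))
  p_truth <- file.path(out_dir, "sweeps-truth.tsv")
  if (is.null(truth_all)) truth_all <- data.frame()
  write_tsv(truth_all, p_truth)

  sp <- synth_ephys_params(
    sampling_rate = fs,
    ssto_amplitude = cfg_num(cfg, "simulate", "ssto_amplitude", 10),
    ssto_frequency = cfg_num(cfg, "simulate", "ssto_frequency", 5),
    noise_sd = cfg_num(cfg, "simulate", "sweep_noise_sd", 0.2),
    seed = seed + 1L)
  ss <- gen_ssto_trace(sp, duration = 20, spont_rate = 0.5)
  ssto_set <- sweep_set(list(ss$trace), 0,
                        step_protocol(0, onset = 0, duration = 20, tail = 0,
                                      holding_potential = sp$baseline_vm))
  p_ssto <- file.path(out_dir, "ssto.tsv")
  write_sweeps(ssto_set, p_ssto, "delimited")

  ep <- synth_extracell_params(
    ss_rate = cfg_num(cfg, "simulate", "ss_rate", 50),
    cs_rate = cfg_num(cfg, "simulate", "cs_rate", 1),
    duration = cfg_num(cfg, "simulate", "extracell_duration", 60),
    seed = seed + 2L)
  ex <- gen_extracellular_recording(ep)
  ex_set <- sweep_set(list(ex$trace), 0,
                      step_protocol(0, onset = 0, duration = ep$duration,
                                    tail = 0, holding_potential = 0))
  p_ex <- file.path(out_dir, "extracellular.tsv")
  write_sweeps(ex_set, p_ex, "delimited")
  p_ex_truth <- file.path(out_dir, "extracellular-truth.txt")
  write_sidecar(list(true_ss_times = ex$true_ss_times,
                     true_cs_times = ex$true_cs_times), p_ex_truth)

  mo <- gen_morphology(synth_morph_params(seed = seed + 3L))
  p_swc <- file.path(out_dir, "morphology.swc")
  write_swc(mo$tree, p_swc)
  p_swc_truth <- file.path(out_dir, "morphology-truth.txt")
  write_sidecar(mo$truth, p_swc_truth)

  tp <- synth_tissue_params(
    true_N = c(NeuN = as.integer(cfg_num(cfg, "simulate", "tissue_true_n", 1000)),
               NeuN_Calb = as.integer(0.8 * cfg_num(cfg, "simulate",
                                                    "tissue_true_n", 1000))),
    seed = seed + 4L)
  tg <- gen_tissue_and_sample(tp, fractionator_design())
  p_counts <- file.path(out_dir, "tissue-counts.tsv")
  write_tsv(tg$counts, p_counts)
  p_counts_truth <- file.path(out_dir, "tissue-truth.txt")
  write_sidecar(list(N = tg$truth$N, volume = tg$truth$volume),
                p_counts_truth)

  gp <- synth_transcriptome_params(
    n_genes = as.integer(cfg_num(cfg, "simulate", "n_genes", 30973)),
    seed = seed + 5L)
  genes <- gen_transcriptome(gp)
  p_genes <- file.path(out_dir, "genes.tsv")
  write_gene_table(genes, p_genes)

  c(p_sweeps, p_truth, p_ssto, p_ex, p_ex_truth, p_swc, p_swc_truth,
    p_counts, p_counts_truth, p_genes)
}

#' @keywords internal
#' @noRd
pipeline_features <- function(cfg, inputs, out_dir) {
  if (!length(inputs)) stop("features: a sweep file input is required")
  fmt <- if (grepl("\\.rds$", inputs[1L])) "rds" else "delimited"
  sw <- read_sweeps(inputs[1L], fmt)
  jp <- cfg_num(cfg, "features", "junction_potential", 0)
  if (jp != 0 && !sw$junction_corrected)
    sw <- correct_junction_potential(sw, jp)
  config <- feature_config(
    dvdt_min = cfg_num(cfg, "features", "dvdt_min", 10),
    min_prominence = cfg_num(cfg, "features", "min_prominence", 20),
    refractory = cfg_num(cfg, "features", "refractory", 2),
    smooth_ms = cfg_num(cfg, "features", "smooth_ms", 0.1),
    lt_halfwidth_max = cfg_num(cfg, "features", "lt_halfwidth_max", 1),
    adp_min_prominence = cfg_num(cfg, "features", "adp_min_prominence", 1))
  proto <- sw$protocol
  feats <- do.call(rbind, lapply(seq_along(sw$sweeps), function(i) {
    fe <- extract_spike_features(sw$sweeps[[i]], config,
                                 step_start = proto$onset,
                                 step_end = proto$onset + proto$duration)
    if (nrow(fe)) cbind(sweep = i,
                        injected_current = sw$injected_current[i], fe)
    else NULL
  }))
  if (is.null(feats)) feats <- data.frame()
  fi <- fi_curve(sw, exclude_low_threshold =
                   cfg_flag(cfg, "features", "exclude_low_threshold", TRUE),
                 config = config)
  rin <- tryCatch(input_resistance(sw, config), error = function(e) NA_real_)
  p_spikes <- file.path(out_dir, "spike-features.tsv")
  write_tsv(feats, p_spikes)
  p_fi <- file.path(out_dir, "fi-curve.tsv")
  write_tsv(as.data.frame(fi), p_fi)
  p_cell <- file.path(out_dir, "cell-summary.tsv")
  write_tsv(data.frame(
    n_spikes_total = if (nrow(feats)) nrow(feats) else 0L,
    input_resistance_mohm = rin,
    mean_ahp_depth_from_threshold =
      if (nrow(feats)) mean(feats$ahp_depth_from_threshold) else NA_real_),
    p_cell)
  c(p_spikes, p_fi, p_cell)
}

#' @keywords internal
#' @noRd
pipeline_invivo <- function(cfg, inputs, out_dir) {
  if (!length(inputs)) stop("invivo: an extracellular trace input is required")
  fmt <- if (grepl("\\.rds$", inputs[1L])) "rds" else "delimited"
  sw <- read_sweeps(inputs[1L], fmt)
  tr <- sw$sweeps[[1L]]
  filt <- highpass_10hz(tr)
  mt <- cfg[["invivo"]][["manual_threshold"]]
  cls <- classify_events(
    filt,
    noise_k = cfg_num(cfg, "invivo", "noise_k", 4),
    min_sep_ms = cfg_num(cfg, "invivo", "min_sep_ms", 2),
    min_gap_ratio = cfg_num(cfg, "invivo", "min_gap_ratio", 1.2),
    manual_threshold = if (is.null(mt)) NULL else as.numeric(mt))
  ev <- rbind(
    data.frame(time = cls$simple_spike_times, class = "simple"),
    data.frame(time = cls$complex_spike_times, class = "complex"))
  ev <- ev[order(ev$time), , drop = FALSE]
  p_ev <- file.path(out_dir, "events.tsv")
  write_tsv(ev, p_ev)
  p_sum <- file.path(out_dir, "invivo-summary.tsv")
  write_tsv(data.frame(
    duration_s = cls$duration,
    n_simple = length(cls$simple_spike_times),
    n_complex = length(cls$complex_spike_times),
    ss_frequency_hz = cls$ss_frequency,
    cs_frequency_hz = cls$cs_frequency,
    amplitude_threshold = cls$amplitude_threshold_used), p_sum)
  c(p_ev, p_sum)
}

#' @keywords internal
#' @noRd
pipeline_morph <- function(cfg, inputs, out_dir) {
  if (!length(inputs)) stop("morph: an SWC input is required")
  rows <- lapply(inputs, function(p) {
    tree <- read_swc(p)
    m <- compute_morphometrics(
      tree, dendrites_only = cfg_flag(cfg, "morph", "dendrites_only", TRUE))
    hd <- tryCatch(
      hausdorff_dimension(tree,
                          eps_min = cfg_num(cfg, "morph", "eps_min", 1),
                          n_ladder = cfg_num(cfg, "morph", "n_ladder", 10)),
      error = function(e) list(dimension = NA_real_, r_squared = NA_real_))
    data.frame(file = basename(p), n_tips = m$n_tips,
               n_bifurcations = m$n_bifurcations,
               total_length_um = m$total_length,
               width_um = m$width, height_um = m$height, depth_um = m$depth,
               soma_surface_area_um2 = m$soma_surface_area,
               hausdorff_dimension = hd$dimension,
               dimension_fit_r2 = hd$r_squared)
  })
  p_out <- file.path(out_dir, "morphometrics.tsv")
  write_tsv(do.call(rbind, rows), p_out)
  p_out
}

#' @keywords internal
#' @noRd
pipeline_stereo <- function(cfg, inputs, out_dir) {
  if (!length(inputs)) stop("stereo: a section-count table input is required")
  counts <- utils::read.delim(inputs[1L])
  design <- fractionator_design(
    section_interval = cfg_num(cfg, "stereo", "section_interval", 4),
    frame_x = cfg_num(cfg, "stereo", "frame_x", 200),
    frame_y = cfg_num(cfg, "stereo", "frame_y", 200),
    grid_x = cfg_num(cfg, "stereo", "grid_x", 50),
    grid_y = cfg_num(cfg, "stereo", "grid_y", 50),
    counting_depth = cfg_num(cfg, "stereo", "counting_depth", 20),
    section_thickness = cfg_num(cfg, "stereo", "section_thickness", 30),
    guard_zone = cfg_num(cfg, "stereo", "guard_zone", 1))
  nh <- fractionator_estimate(counts, design)
  cols <- grep("^Qminus_", names(counts), value = TRUE)
  ce <- vapply(cols, function(cl) gundersen_ce(counts[[cl]]), numeric(1L))
  vol <- if ("region_area" %in% names(counts))
    cavalieri_volume(counts$region_area, design$section_interval,
                     design$section_thickness) else NA_real_
  p_out <- file.path(out_dir, "stereology-estimates.tsv")
  write_tsv(data.frame(marker = sub("^Qminus_", "", cols),
                       sum_Q = vapply(cols, function(cl) sum(counts[[cl]]),
                                      numeric(1L)),
                       N_hat = as.numeric(nh), ce_gundersen = as.numeric(ce),
                       volume_hat_um3 = vol), p_out)
  p_out
}

#' @keywords internal
#' @noRd
pipeline_enrich <- function(inputs, out_dir) {
  if (!length(inputs)) stop("enrich: a gene table input is required")
  genes <- read_gene_table(inputs[1L])
  res <- run_paper_enrichments(genes)
  df <- do.call(rbind, lapply(res, function(r)
    data.frame(set = r$set_name, annotation = r$annotation_name,
               a = r$table$a, b = r$table$b, c = r$table$c, d = r$table$d,
               fold_enrichment = r$fold_enrichment,
               p_two_sided = r$p_two_sided)))
  p_out <- file.path(out_dir, "enrichment-results.tsv")
  write_tsv(df, p_out)
  p_rep <- file.path(out_dir, "enrichment-report.txt")
  writeLines(unlist(lapply(res, function(r) utils::capture.output(print(r)))),
             p_rep)
  c(p_out, p_rep)
}

#' @keywords internal
#' @noRd
pipeline_reproduce_enrichment <- function(out_dir) {
  # published summary counts: 31 ion-channel genes among 1374 DEGs; 270
  # ion-channel genes among 30973 assessed transcripts
  tab <- contingency_table(31, 1374 - 31, 270 - 31, 30973 - 1374 - (270 - 31))
  fold <- fold_enrichment(tab)
  p <- fisher_exact_two_sided(tab)
  lines <- c(
    "Ion-channel enrichment among medullary DEGs (worked example)",
    sprintf("table: a=%d b=%d c=%d d=%d", tab$a, tab$b, tab$c, tab$d),
    sprintf("fold enrichment = %.2f", fold),
    sprintf("Fisher's exact test, two-sided P = %.3G", p))
  p_out <- file.path(out_dir, "reproduce-enrichment.txt")
  writeLines(lines, p_out)
  cat(lines, sep = "\n")
  p_out
}
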