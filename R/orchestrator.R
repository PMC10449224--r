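#' Run a full simulation experiment from a configuration
#'
#' Executes a grid of scenarios (inheritance mode x dominance x sex-bias, as
#' listed under `grid`), writes per-cell coverage tables, final-generation
#' tract tables, timecourse summaries, bootstrap aut:chrX ratio estimates per
#' (h, p) pairing, and a JSON run manifest recording the configuration
#' snapshot, per-cell seeds and realized pulse diagnostics. Per-cell seeds are
#' derived from the master seed by a fixed counter scheme
#' (`master_seed + cell_index`), so cells are independent but the whole grid
#' reruns identically.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list. Top-level blocks: `genome` (either `exon_bed`/`recomb_bed`/
#'   `length_bp` or the [synthesize_chromosome_map()] parameters), `dfe`,
#'   `sim` (shared [sim_config()] fields), `grid` (`inheritance`,
#'   `dominance_h`, `female_fraction_pulse` vectors), `sampling`
#'   (`sample_size`, optional `schedule`), `analysis` (`n_boot`,
#'   `n_per_draw`), and `seed`.
#' @param out_dir output directory; all artifacts are written beneath it.
#' @return Invisibly, the manifest list.
#' @export
run_experiment <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg))
  for (block in c("genome", "sim", "grid")) {
    if (is.null(cfg[[block]])) {
      stop("schema violation: missing required config block '", block, "'")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  master_seed <- as.integer(cfg$seed %||% 1L)

  g <- cfg$genome
  make_map <- function(inheritance) {
    if (!is.null(g$exon_bed)) {
      load_chromosome_map(g$exon_bed, g$recomb_bed, g$length_bp, inheritance)
    } else {
      synthesize_chromosome_map(
        length_bp = g$length_bp %||% 1e7,
        exon_fraction = g$exon_fraction %||% 0.015,
        mean_exon_len = g$mean_exon_len %||% 160,
        mean_recomb_rate = g$mean_recomb_rate %||% 1e-8,
        n_rate_pieces = g$n_rate_pieces %||% 50,
        seed = g$seed %||% master_seed,
        inheritance = inheritance)
    }
  }
  # default: one shared map used for both inheritance modes
  maps <- list(autosomal = make_map("autosomal"), chrX = make_map("chrX"))

  d <- cfg$dfe %||% list()
  sim <- cfg$sim
  grid <- expand.grid(
    inheritance = cfg$grid$inheritance %||% c("autosomal", "chrX"),
    dominance_h = cfg$grid$dominance_h %||% c(0, 0.5),
    female_fraction_pulse = cfg$grid$female_fraction_pulse %||% c(0, 0.5, 1),
    stringsAsFactors = FALSE
  )
  sampling <- cfg$sampling %||% list()
  analysis <- cfg$analysis %||% list()

  cells <- list()
  for (i in seq_len(nrow(grid))) {
    cell_seed <- master_seed + i
    label <- sprintf("%s_h%s_p%s", grid$inheritance[i],
                     gsub("[.]", "", format(grid$dominance_h[i])),
                     gsub("[.]", "", format(grid$female_fraction_pulse[i])))
    cell <- tryCatch({
      dfe <- dfe_params(
        shape_k = d$shape_k %||% 0.186,
        scale_theta = d$scale_theta %||% 0.07068995,
        dominance_h = grid$dominance_h[i],
        mutation_rate = d$mutation_rate %||% 1.5e-8)
      conf <- sim_config(
        N_recipient = sim$N_recipient %||% 25000,
        N_source = sim$N_source %||% 250,
        isolation_generations = sim$isolation_generations %||% 20000,
        post_pulse_generations = sim$post_pulse_generations %||% 15000,
        pulse_fraction = sim$pulse_fraction %||% 0.05,
        female_fraction_pulse = grid$female_fraction_pulse[i],
        recipient_female_fraction = sim$recipient_female_fraction %||% 0.5,
        inheritance = grid$inheritance[i],
        dominance_h = grid$dominance_h[i],
        scaling_factor = sim$scaling_factor %||% 2,
        pulse_mode = sim$pulse_mode %||% "exact",
        seed = cell_seed)
      res <- run_scenario(conf, maps[[grid$inheritance[i]]], dfe,
                          sample_schedule = sampling$schedule,
                          sample_size = sampling$sample_size %||% 1000)
      cov_path <- file.path(out_dir, paste0(label, "_coverage.tsv"))
      utils::write.table(res$coverage, cov_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      final_gen <- max(res$coverage$generation)
      tr <- res$tracts[[as.character(final_gen)]]
      tr_tab <- do.call(rbind, lapply(seq_along(tr), function(k) {
        if (nrow(tr[[k]]) == 0) return(NULL)
        data.frame(generation = final_gen, haplotype_id = k,
                   start = tr[[k]][, 1], end = tr[[k]][, 2])
      }))
      tr_path <- file.path(out_dir, paste0(label, "_tracts.tsv"))
      utils::write.table(
        tr_tab %||% data.frame(generation = integer(0),
                               haplotype_id = integer(0),
                               start = numeric(0), end = numeric(0)),
        tr_path, sep = "\t", quote = FALSE, row.names = FALSE)
      tc <- timecourse_summary(res$coverage,
                               n_boot = analysis$n_boot %||% 500,
                               seed = cell_seed)
      list(label = label, seed = cell_seed,
           inheritance = grid$inheritance[i],
           dominance_h = grid$dominance_h[i],
           female_fraction_pulse = grid$female_fraction_pulse[i],
           pulse = res$pulse[c("n_migrants", "n_female",
                               "archaic_haplotypes",
                               "realized_pulse_fraction",
                               "realized_female_fraction")],
           final_mean_coverage = mean(final_coverage(res)),
           half_decay = half_decay_generation(tc),
           coverage_table = cov_path, tract_table = tr_path,
           timecourse = tc, final_coverage = final_coverage(res),
           error = NULL)
    }, error = function(e) {
      list(label = label, seed = cell_seed, error = conditionMessage(e))
    })
    cells[[label]] <- cell
  }

  # bootstrap aut:chrX ratios for every (h, p) pairing present in both modes
  ratios <- list()
  ok <- Filter(function(c) is.null(c$error), cells)
  for (ci in ok) {
    if (ci$inheritance != "autosomal") next
    partner <- Filter(function(c) {
      c$inheritance == "chrX" && c$dominance_h == ci$dominance_h &&
        c$female_fraction_pulse == ci$female_fraction_pulse
    }, ok)
    if (length(partner) == 0) next
    est <- tryCatch(
      bootstrap_ratio(ci$final_coverage, partner[[1]]$final_coverage,
                      n_per_draw = analysis$n_per_draw %||% 10000,
                      n_boot = analysis$n_boot %||% 2000,
                      seed = ci$seed)[
        c("mean_ratio", "ci_low", "ci_high", "n_boot", "n_per_draw")],
      error = function(e) list(error = conditionMessage(e)))
    ratios[[sprintf("h%s_p%s", ci$dominance_h, ci$female_fraction_pulse)]] <- est
  }

  manifest <- list(
    config = cfg, master_seed = master_seed,
    package_version = as.character(utils::packageVersion("archaicx")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    cells = lapply(cells, function(c) {
      c$timecourse <- NULL
      c$final_coverage <- NULL
      c
    }),
    ratio_estimates = ratios
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(c(manifest, list(cells_full = cells)))
}
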