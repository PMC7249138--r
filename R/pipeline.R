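# One-config pipeline driver: charge model at the requested pH values,
# system generation or loading, turn assignment, aggregate analysis, and
# a reproducible JSON/CSV report.

#' @keywords internal
pipeline_config_defaults <- function() {
  list(ph = c(2, 7, 8, 11),
       pka_set = "bjellqvist",
       turn_criteria = list(ca_dist_max = 7.0, hbond_ON_max = 3.5,
                            hbond_angle_min = 120, combine = "either",
                            exclude_helix = TRUE),
       cluster_cutoff = 4.5,
       dielectric = 78.5,
       electrostatic_cutoff_nm = 1.4)
}

#' @keywords internal
validate_pipeline_config <- function(cfg) {
  def <- pipeline_config_defaults()
  for (k in names(def))
    if (is.null(cfg[[k]])) cfg[[k]] <- def[[k]]
    else if (is.list(def[[k]]))
      for (k2 in names(def[[k]]))
        if (is.null(cfg[[k]][[k2]])) cfg[[k]][[k2]] <- def[[k]][[k2]]
  if (is.null(cfg$peptide) || is.null(cfg$peptide$sequence))
    stop("config error at 'peptide.sequence': missing", call. = FALSE)
  has_path <- !is.null(cfg$system)
  has_gen <- !is.null(cfg$generator)
  if (has_path == has_gen)
    stop("config error: exactly one of 'system' (input path) or 'generator' must be present",
         call. = FALSE)
  if (any(unlist(cfg$ph) < 0) || any(unlist(cfg$ph) > 14))
    stop("config error at 'ph': values must lie in [0, 14]", call. = FALSE)
  if (has_gen && is.null(cfg$generator$seed))
    stop("config error at 'generator.seed': a seed is mandatory",
         call. = FALSE)
  cfg
}

#' @keywords internal
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    cfg <- yaml::read_yaml(config)
  } else if (is.list(config)) cfg <- config
  else stop("'config' must be a YAML file path or a list", call. = FALSE)
  validate_pipeline_config(cfg)
}

#' @keywords internal
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline from one configuration
#'
#' Stages, in order: per-pH charge model, system generation (or loading
#' from a PDB/GRO path), turn/beta-turn content, aggregate analysis per
#' pH. All thresholds in force are echoed in the report; identical
#' configurations reproduce identical numeric content. On any stage
#' error the run aborts with the stage name and partially written
#' outputs are removed.
#'
#' @param config Path to a YAML configuration or an equivalent list.
#'   Required keys: `peptide` (with `sequence`, optional `n_term`,
#'   `c_term`) and exactly one of `system` (coordinate file path) or
#'   `generator` (keys as [make_system()] arguments; `seed` mandatory).
#'   Optional: `ph` (default 2, 7, 8, 11), `pka_set`, `turn_criteria`,
#'   `cluster_cutoff`, `output_dir`.
#' @param output_dir Overrides the config's `output_dir`; `NULL` (and no
#'   config entry) writes no files.
#' @param quiet Suppress per-stage log lines.
#' @return Object of class `pipeline_report` (also written to
#'   `output_dir/report.json` with CSV side tables when an output
#'   directory is set).
#' @examples
#' cfg <- system.file("extdata", "a6k_ph8_micellar.yaml",
#'                    package = "pepassembly")
#' rep <- run_pipeline(cfg, quiet = TRUE)
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  cfg <- read_pipeline_config(config)
  if (is.null(output_dir)) output_dir <- cfg$output_dir
  log_line <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }
  written <- character()
  stage <- "config"
  result <- tryCatch({
    pep <- peptide(cfg$peptide$sequence,
                   n_term = if (is.null(cfg$peptide$n_term)) "free"
                            else cfg$peptide$n_term,
                   c_term = if (is.null(cfg$peptide$c_term)) "free"
                            else cfg$peptide$c_term)
    set <- pka_set(cfg$pka_set)
    ph <- as.numeric(unlist(cfg$ph))

    stage <- "charge"
    model <- protonation_model(pep, set)
    states <- lapply(ph, function(h) charge_state(model, h))
    pI <- tryCatch(isoelectric_point(model, digits = NULL),
                   error = function(e) NA_real_)
    log_line(stage, sprintf("%d pH value(s), %d site(s), pI %.2f",
                            length(ph), nrow(model$sites), pI))

    stage <- if (is.null(cfg$generator)) "load" else "generate"
    if (is.null(cfg$generator)) {
      path <- cfg$system
      sys <- if (grepl("\\.gro$", path, ignore.case = TRUE)) read_gro(path)
             else read_pdb(path)
    } else {
      g <- cfg$generator
      sys <- make_system(
        pep,
        n_chains = if (is.null(g$n_chains)) 80L else g$n_chains,
        box_nm = if (is.null(g$box_nm)) 8 else g$box_nm,
        placement = if (is.null(g$placement)) "dispersed" else g$placement,
        min_dist_A = if (is.null(g$min_dist_A)) 4 else g$min_dist_A,
        seed = g$seed,
        per_chain_motif = if (is.null(g$motif)) "coil" else unlist(g$motif),
        turn_position = if (is.null(g$turn_position)) 2L else g$turn_position,
        n_frames = if (is.null(g$n_frames)) 1L else g$n_frames)
    }
    log_line(stage, sprintf("%d frame(s) x %d chain(s)",
                            length(sys$frames), length(sys$frames[[1]])))

    stage <- "turns"
    tc <- cfg$turn_criteria
    crit <- turn_criteria(ca_dist_max = tc$ca_dist_max,
                          hbond_ON_max = tc$hbond_ON_max,
                          hbond_angle_min = tc$hbond_angle_min,
                          combine = tc$combine,
                          exclude_helix = tc$exclude_helix)
    turns <- turn_content(sys, crit)
    log_line(stage, sprintf("turn %.1f%%, beta-turn %.1f%%",
                            turns$turn_percent, turns$beta_turn_percent))

    stage <- "aggregates"
    aggs <- lapply(ph, function(h)
      aggregate_report(sys$frames[[1]], cutoff_A = cfg$cluster_cutoff,
                       pH = h, pka = set, dielectric = cfg$dielectric,
                       cutoff_nm = cfg$electrostatic_cutoff_nm))
    log_line(stage, sprintf("%d aggregate(s) at cutoff %.1f A",
                            length(aggs[[1]]$clusters$sizes),
                            cfg$cluster_cutoff))

    report <- structure(list(
      config = cfg,
      config_hash = config_hash(cfg),
      version = as.character(utils::packageVersion("pepassembly")),
      seed = if (is.null(cfg$generator)) NA_integer_ else cfg$generator$seed,
      thresholds = list(
        turn_criteria = unclass(crit),
        cluster_cutoff_A = cfg$cluster_cutoff,
        dielectric = cfg$dielectric,
        electrostatic_cutoff_nm = cfg$electrostatic_cutoff_nm,
        pka_set = set$name),
      pI = pI,
      charge = lapply(states, function(st) list(
        pH = st$pH, net_charge = st$net_charge,
        rounded_net_charge = st$rounded_net_charge,
        sites = st$sites[, c("site_kind", "residue", "residue_index",
                             "charge", "label")])),
      turn_content = list(
        turn_percent = turns$turn_percent,
        beta_turn_percent = turns$beta_turn_percent,
        per_frame = turns$per_frame),
      aggregates = lapply(seq_along(ph), function(i) list(
        pH = ph[i],
        sizes = aggs[[i]]$clusters$sizes,
        table = aggs[[i]]$aggregates,
        electrostatic_total = sum(aggs[[i]]$electrostatic) / 2))),
      class = "pipeline_report")

    if (!is.null(output_dir)) {
      stage <- "write"
      dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
      out <- function(name) file.path(output_dir, name)
      if (!is.null(cfg$generator)) {
        write_pdb(sys, out("system.pdb")); written <- c(written, out("system.pdb"))
      }
      utils::write.csv(titration_curve(model, seq(0, 14, by = 0.1)),
                       out("titration.csv"), row.names = FALSE)
      utils::write.csv(turns$per_frame, out("turns.csv"), row.names = FALSE)
      utils::write.csv(aggs[[1]]$aggregates, out("aggregates.csv"),
                       row.names = FALSE)
      written <- c(written, out("titration.csv"), out("turns.csv"),
                   out("aggregates.csv"))
      jsonlite::write_json(
        rapply(unclass(report), function(x)
          if (is.data.frame(x)) x else x, how = "replace"),
        out("report.json"), auto_unbox = TRUE, digits = NA, force = TRUE,
        dataframe = "rows")
      written <- c(written, out("report.json"))
    }
    report
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report (pepassembly %s, config %s)\n",
              x$version, substr(x$config_hash, 1, 8)))
  for (ch in x$charge)
    cat(sprintf("  pH %g: net %+.3f e (rounds to %+d e)\n",
                ch$pH, ch$net_charge, ch$rounded_net_charge))
  if (!is.na(x$pI)) cat(sprintf("  pI: %.2f\n", x$pI))
  cat(sprintf("  turn %.1f%%, beta-turn %.1f%%\n",
              x$turn_content$turn_percent, x$turn_content$beta_turn_percent))
  cat(sprintf("  aggregates at pH %g: sizes %s\n", x$aggregates[[1]]$pH,
              paste(x$aggregates[[1]]$sizes, collapse = ", ")))
  invisible(x)
}
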