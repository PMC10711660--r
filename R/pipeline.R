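# Pipeline orchestration: a structured YAML config drives the stages
# fragments -> manifest -> contacts -> consensus (plus optional
# simulate and MD stages).  Every output file carries a provenance
# header (config hash, package version, seed), and reruns with an
# unchanged config are byte-identical.

PIPELINE_KEYS <- c("sequences", "prey_id", "tail_span", "bait_domains",
                   "scan", "cutoffs", "hotspot", "chains", "runs_dir",
                   "output_dir", "seed", "simulate", "md")

default_pipeline_config <- function() {
  list(scan = list(init_len = 5L, step = 5L,
                   anchors = c("start", "middle", "end")),
       cutoffs = list(model_contact = 5.0, md_contact = 4.5,
                      hbond_dist = 3.5, hbond_angle = 150),
       hotspot = list(threshold = 0.5, min_size = 3L),
       chains = list(bait = "A", prey = "B"),
       seed = 1L)
}

#' Read and validate a pipeline configuration
#'
#' The YAML file declares sequence paths, the tail span, named bait
#' domains, scan geometry, cutoffs, hotspot parameters, run layout and
#' seeds.  Unknown keys are rejected; all validation failures are
#' reported at once.  Defaults carry the standard parameterisation:
#' model-contact cutoff 5 A (strict), trajectory cutoff 4.5 A
#' (inclusive), fragment series init 5 / step 5, hotspot threshold 0.5
#' with minimum size 3.
#'
#' @param path YAML file, or a named list (already-parsed config).
#' @return Validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  bad <- setdiff(names(raw), PIPELINE_KEYS)
  errs <- character()
  if (length(bad))
    errs <- c(errs, sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  cfg <- default_pipeline_config()
  for (k in names(raw)) {
    cfg[[k]] <- if (is.list(raw[[k]]) && is.list(cfg[[k]]))
      utils::modifyList(cfg[[k]], raw[[k]]) else raw[[k]]
  }
  if (is.null(cfg$tail_span)) errs <- c(errs, "tail_span is required")
  if (is.null(cfg$bait_domains)) errs <- c(errs, "bait_domains is required")
  for (nm in c("model_contact", "md_contact", "hbond_dist")) {
    v <- cfg$cutoffs[[nm]]
    if (!is.numeric(v) || v <= 0)
      errs <- c(errs, sprintf("cutoffs$%s must be > 0", nm))
  }
  if (!is.null(cfg$tail_span)) {
    ok <- tryCatch({ as_span(cfg$tail_span); TRUE }, error = function(e) FALSE)
    if (!ok) errs <- c(errs, "tail_span is not a valid span")
  }
  if (!is.null(cfg$bait_domains)) {
    if (is.null(names(cfg$bait_domains)))
      errs <- c(errs, "bait_domains must be named")
    else for (nm in names(cfg$bait_domains)) {
      ok <- tryCatch({ as_span(cfg$bait_domains[[nm]]); TRUE },
                     error = function(e) FALSE)
      if (!ok) errs <- c(errs, sprintf("bait domain '%s' is not a valid span", nm))
    }
  }
  if (length(errs))
    stop_slimscan(paste0("invalid pipeline config:\n  - ",
                         paste(errs, collapse = "\n  - ")),
                  "slimscan_config_error")
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

pipeline_provenance <- function(cfg) {
  list(package = sprintf("slimscan %s",
                         as.character(utils::packageVersion("slimscan"))),
       config_md5 = config_hash(cfg),
       seed = cfg$seed,
       model_contact_cutoff = cfg$cutoffs$model_contact,
       md_contact_cutoff = cfg$cutoffs$md_contact,
       hotspot_threshold = cfg$hotspot$threshold,
       hotspot_min_size = cfg$hotspot$min_size)
}

#' Run the fragment-scan pipeline
#'
#' Executes the requested stages in dependency order:
#' \describe{
#'   \item{fragments}{enumerate tail fragments, build and write the run
#'     manifest (`manifest.tsv`).}
#'   \item{simulate}{generate a mock prediction-run tree under
#'     `runs_dir` from `config$simulate` (`motif_span`, `pocket_span`,
#'     optional `noise_rate`).}
#'   \item{contacts}{for every manifest entry, select the top-ranked
#'     model in `runs_dir/<run_id>`, extract inter-chain contacts at the
#'     model cutoff, remap them to global coordinates, and write
#'     `contacts.tsv`.}
#'   \item{consensus}{accumulate runs into per-domain consensus
#'     matrices, write `consensus_<domain>.tsv` and a hotspot report
#'     (`hotspots.tsv`).}
#' }
#' Every output carries a provenance header; reruns with identical
#' config and inputs are byte-identical.
#'
#' @param config a `pipeline_config` (or path to one).
#' @param stages character subset of
#'   `c("fragments", "simulate", "contacts", "consensus")`.
#' @return Invisibly, a list with the in-memory stage results
#'   (`manifest`, `runs`, `consensus`, `hotspots`, `paths`).
#' @export
run_pipeline <- function(config,
                         stages = c("fragments", "contacts", "consensus")) {
  if (!inherits(config, "pipeline_config"))
    config <- read_pipeline_config(config)
  stages <- match.arg(stages,
                      c("fragments", "simulate", "contacts", "consensus"),
                      several.ok = TRUE)
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- pipeline_provenance(config)
  res <- list(paths = character())
  t_all <- proc.time()[["elapsed"]]

  need_manifest <- function() {
    if (!is.null(res$manifest)) return(res$manifest)
    p <- file.path(out_dir, "manifest.tsv")
    if (!file.exists(p))
      stop_slimscan("no manifest available: run the 'fragments' stage first",
                    "slimscan_stage_error")
    read_manifest(p)
  }

  if ("fragments" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    cfgscan <- scan_config(as_span(config$tail_span),
                           config$scan$init_len, config$scan$step,
                           config$scan$anchors)
    frags <- enumerate_fragments(cfgscan)
    doms <- lapply(config$bait_domains, as_span)
    res$manifest <- build_manifest(frags, doms)
    p <- file.path(out_dir, "manifest.tsv")
    write_manifest(res$manifest, p, prov)
    res$paths <- c(res$paths, p)
    message(sprintf("[fragments] %d fragments, %d runs (%.2fs)",
                    nrow(frags), nrow(res$manifest),
                    proc.time()[["elapsed"]] - t0))
  }

  if ("simulate" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    sim <- config$simulate
    if (is.null(sim))
      stop_slimscan("stage 'simulate' requested but config$simulate is absent",
                    "slimscan_stage_error")
    manifest <- need_manifest()
    if (is.null(config$runs_dir))
      stop_slimscan("config$runs_dir is required for the simulate stage",
                    "slimscan_stage_error")
    make_mock_scan(manifest, as_span(sim$motif_span), as_span(sim$pocket_span),
                   config$runs_dir, noise_rate = sim$noise_rate %||% 0,
                   seed = config$seed)
    message(sprintf("[simulate] %d run dirs under %s (%.2fs)",
                    nrow(manifest), config$runs_dir,
                    proc.time()[["elapsed"]] - t0))
  }

  if ("contacts" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    manifest <- need_manifest()
    if (is.null(config$runs_dir) || !dir.exists(config$runs_dir))
      stop_slimscan("runs_dir missing or nonexistent: run predictions or the 'simulate' stage first",
                    "slimscan_stage_error")
    runs <- vector("list", nrow(manifest))
    for (r in seq_len(nrow(manifest))) {
      e <- as.list(manifest[r, ])
      run_dir <- file.path(config$runs_dir, e$run_id)
      if (!dir.exists(run_dir))
        stop_slimscan(sprintf("run directory missing for %s: run predictions or the 'simulate' stage first",
                              e$run_id),
                      "slimscan_stage_error")
      model <- load_structure(select_top_model(run_dir),
                              config$chains$bait, config$chains$prey)
      local <- interchain_contacts(model, config$cutoffs$model_contact)
      runs[[r]] <- list(entry = e, contacts = remap_contacts(local, e))
    }
    res$runs <- runs
    df <- do.call(rbind, lapply(runs, function(x)
      cbind(run_id = x$entry$run_id, as.data.frame(x$contacts))))
    p <- file.path(out_dir, "contacts.tsv")
    write_tsv_prov(df, p, prov)
    res$paths <- c(res$paths, p)
    message(sprintf("[contacts] %d runs, %d contact pairs (%.2fs)",
                    length(runs), nrow(df), proc.time()[["elapsed"]] - t0))
  }

  if ("consensus" %in% stages) {
    t0 <- proc.time()[["elapsed"]]
    if (is.null(res$runs))
      stop_slimscan("consensus needs in-memory contacts: include the 'contacts' stage",
                    "slimscan_stage_error")
    res$consensus <- accumulate_runs(res$runs)
    hs_rows <- list()
    for (bn in names(res$consensus)) {
      p <- file.path(out_dir, sprintf("consensus_%s.tsv", bn))
      write_consensus(res$consensus[[bn]], p, prov)
      res$paths <- c(res$paths, p)
      hs <- detect_hotspots(res$consensus[[bn]],
                            config$hotspot$threshold, config$hotspot$min_size)
      for (h in hs)
        hs_rows[[length(hs_rows) + 1L]] <- data.frame(
          bait_domain = bn,
          bait_from = min(h$bait_residues), bait_to = max(h$bait_residues),
          prey_from = min(h$prey_residues), prey_to = max(h$prey_residues),
          n_cells = h$n_cells, peak_freq = h$peak_freq,
          mean_freq = h$mean_freq)
    }
    res$hotspots <- if (length(hs_rows)) do.call(rbind, hs_rows) else
      data.frame(bait_domain = character(), bait_from = integer(),
                 bait_to = integer(), prey_from = integer(),
                 prey_to = integer(), n_cells = integer(),
                 peak_freq = numeric(), mean_freq = numeric())
    p <- file.path(out_dir, "hotspots.tsv")
    write_tsv_prov(res$hotspots, p, prov)
    res$paths <- c(res$paths, p)
    message(sprintf("[consensus] %d domain(s), %d hotspot(s) (%.2fs)",
                    length(res$consensus), nrow(res$hotspots),
                    proc.time()[["elapsed"]] - t0))
  }

  message(sprintf("[pipeline] done (%.2fs)",
                  proc.time()[["elapsed"]] - t_all))
  invisible(res)
}
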