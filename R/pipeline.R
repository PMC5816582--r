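# Pipeline orchestration: a single structured (JSON) config drives
# simulate -> qc -> normalize -> de -> enrich -> modules, with a summary
# report.  Identical config + seed gives identical outputs.

#' Build a pipeline configuration
#'
#' Defaults equal the published thresholds wherever the source states one:
#' SNR window \[3, 10\], e-value 1e-10, alignment length > 150 bp,
#' |log2 FC| > 1 at alpha 0.05 with Bonferroni correction, minimum module
#' size 5.  The remaining knobs (loess span 0.4, positivity delta 1, soft
#' power 6, static cut height 0.95) are package defaults documented in the
#' methods vignette.
#'
#' @param seed integer seed.
#' @param simulate if `TRUE`, inputs are generated by the simulator with
#'   `sim` parameters; otherwise the `inputs` paths are read.
#' @param sim list passed to [sim_params()] (e.g. `n_genes`).
#' @param inputs list of paths: `spots`, `design`, `aln` (named list per
#'   species), `go`, `fasta`.
#' @param qc,normalization,de,enrichment,coexpression stage parameter
#'   lists; see the individual stage functions.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            simulate = TRUE,
                            sim = list(),
                            inputs = list(),
                            qc = list(snr_low = 3, snr_high = 10,
                                      evalue_max = 1e-10,
                                      min_align_len = 150),
                            normalization = list(span = 0.4, delta = 1.0,
                                                 model_scale = "log2"),
                            de = list(lfc = 1.0, alpha = 0.05,
                                      adjust = "bonferroni"),
                            enrichment = list(term = "water",
                                              direction = "both"),
                            coexpression = list(power = 6,
                                                cut_height = 0.95,
                                                min_module_size = 5,
                                                date = "day18",
                                                trait = "species"),
                            out_dir = NULL) {
  cfg <- list(seed = as.integer(seed), simulate = isTRUE(simulate),
              sim = sim, inputs = inputs, qc = qc,
              normalization = normalization, de = de,
              enrichment = enrichment, coexpression = coexpression,
              out_dir = out_dir)
  if (!cfg$simulate) {
    need <- c("spots", "design")
    missing <- setdiff(need, names(cfg$inputs))
    if (length(missing)) {
      stop_fmt("pipeline_config: missing input path(s): %s",
               paste(missing, collapse = ", "))
    }
    flat <- c(cfg$inputs$spots, cfg$inputs$design, unlist(cfg$inputs$aln),
              cfg$inputs$go, cfg$inputs$fasta)
    absent <- flat[!file.exists(flat)]
    if (length(absent)) {
      stop_fmt("pipeline_config: input file(s) not found: %s",
               paste(absent, collapse = ", "))
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Keys mirror the arguments of [pipeline_config()]; absent keys take the
#' defaults.
#'
#' @param path JSON file.
#' @param overrides named list of values overriding config keys (CLI
#'   flags), using `$`-free top-level names such as `seed` or `out_dir`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in names(overrides)) raw[[k]] <- overrides[[k]]
  args <- raw[intersect(names(raw), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

.merge_defaults <- function(given, defaults) {
  for (k in names(defaults)) if (is.null(given[[k]])) given[[k]] <- defaults[[k]]
  given
}

#' Run the full pipeline
#'
#' Executes simulate (optional), QC, normalization, differential
#' expression, enrichment and coexpression modules, collecting a summary
#' report.  With `out_dir` set, writes the normalized matrix, per-factor
#' ratio tables, DE table, enrichment table, module assignments and a JSON
#' report.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with all stage outputs and `report` (the
#'   summary counts).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  report <- list(seed = config$seed,
                 package_version = as.character(utils::packageVersion("hetarray")))

  stage <- "inputs"
  out <- tryCatch({
    if (config$simulate) {
      sp_args <- .merge_defaults(config$sim, list(seed = config$seed))
      params <- do.call(sim_params, sp_args)
      sim <- simulate_experiment(params)
      spots <- sim$spots
      design <- sim$design
      hits <- simulate_alignments(params)
      ann <- simulate_annotations(params)
      truth <- sim$truth
    } else {
      spots <- read_spot_table(config$inputs$spots, dialect = "tsv")
      design <- read_design_table(config$inputs$design)
      hits <- do.call(rbind, lapply(names(config$inputs$aln), function(sp) {
        read_alignment_table(config$inputs$aln[[sp]], species_db = sp)
      }))
      ann <- if (!is.null(config$inputs$go) && !is.null(config$inputs$fasta)) {
        list(map = read_annotation_map(config$inputs$go,
                                       config$inputs$fasta))
      } else NULL
      truth <- NULL
    }
    report$n_probes <- length(unique(spots$probe_id))
    report$n_arrays <- length(unique(design$array_id))
    report$n_samples <- length(unique(design$sample_id))

    stage <- "qc"
    cfg <- do.call(qc_config, .merge_defaults(config$qc, list()))
    qc <- included_sets(spots, design, hits, cfg)
    inc <- qc$included
    report$qc <- list(
      summary = inc$summary,
      n_snr_pass_probes = length(unique(qc$snr_pass$probe_id)))
    keep_probes <- Reduce(union, inc$per_species)
    spots_kept <- qc$snr_pass[qc$snr_pass$probe_id %in% keep_probes, ]
    if (nrow(spots_kept) == 0) stop_fmt("no probes survive QC")

    stage <- "normalize"
    np <- .merge_defaults(config$normalization,
                          list(span = 0.4, delta = 1.0, model_scale = "log2"))
    signals <- background_correct(spots_kept)
    fit <- fit_array_dye_model(signals, design, model_scale = np$model_scale)
    adjusted <- adjust_residuals_positive(fit, delta = np$delta)
    ratios <- lapply(names(.FACTORS), function(f) {
      rs <- compute_factor_log_ratios(adjusted, f)
      if (nrow(rs) >= 20) rs <- loess_correct_ratios(rs, span = np$span)
      rs
    })
    names(ratios) <- names(.FACTORS)
    report$normalize <- list(n_genes = nrow(adjusted$values),
                             shift = adjusted$shift,
                             model_scale = np$model_scale)

    stage <- "de"
    dep <- .merge_defaults(config$de,
                           list(lfc = 1.0, alpha = 0.05,
                                adjust = "bonferroni"))
    overall <- fit_overall_model(adjusted)
    res <- fit_per_gene_models(adjusted)
    res <- bonferroni_adjust(res, method = if (dep$adjust == "BH") "BH"
                             else "bonferroni")
    res <- call_de(res, lfc_threshold = dep$lfc, alpha = dep$alpha)
    desum <- de_summary(res)
    report$de <- list(overall = as.data.frame(overall), summary = desum)

    stage <- "enrich"
    enr <- NULL
    if (!is.null(ann)) {
      ep <- .merge_defaults(config$enrichment,
                            list(term = "water", direction = "both"))
      tested <- res[res$term == ep$term, ]
      tested <- tested[tested$probe_id %in% names(ann$map$lengths), ]
      de_status <- stats::setNames(tested$call != "ns", tested$probe_id)
      if (ep$direction == "up") de_status <- stats::setNames(tested$call == "up", tested$probe_id)
      if (ep$direction == "down") de_status <- stats::setNames(tested$call == "down", tested$probe_id)
      if (any(de_status) && !all(de_status)) {
        pwf <- fit_pwf(de_status, ann$map$lengths[names(de_status)])
        enr <- wallenius_enrichment(de_status, ann$map, pwf)
        report$enrich <- list(term = ep$term, direction = ep$direction,
                              n_universe = length(de_status),
                              n_de = sum(de_status),
                              n_categories = nrow(enr),
                              n_significant = sum(enr$p_adj < 0.05))
      } else {
        report$enrich <- list(term = ep$term, skipped = "no DE contrast")
      }
    }

    stage <- "modules"
    cp <- .merge_defaults(config$coexpression,
                          list(power = 6, cut_height = 0.95,
                               min_module_size = 5, date = "day18",
                               trait = "species"))
    expr <- sample_expression(adjusted)
    sdes <- attr(expr, "sample_design")
    mods <- list()
    for (w in .FACTORS$water) {
      sel <- sdes$date == cp$date & sdes$water == w
      sub <- expr[, sel, drop = FALSE]
      sub <- sub[stats::complete.cases(sub), , drop = FALSE]
      mr <- tryCatch({
        tom <- compute_tom(sub, power = cp$power)
        m <- detect_modules(tom, min_module_size = cp$min_module_size,
                            cut_height = cp$cut_height)
        module_trait_association(m, sub[rownames(tom), , drop = FALSE],
                                 sdes[[cp$trait]][sel])
      }, error = function(e) {
        message(sprintf("modules (%s): skipped: %s", w, conditionMessage(e)))
        NULL
      })
      mods[[w]] <- mr
    }
    report$modules <- lapply(mods, function(m) {
      if (is.null(m)) return(list(skipped = TRUE))
      list(n_modules = max(m$labels), n_unassigned = sum(m$labels == 0),
           trait = m$trait_association)
    })

    list(spots = spots, design = design, qc = qc, adjusted = adjusted,
         ratios = ratios, overall = overall, de = res, de_summary = desum,
         enrichment = enr, modules = mods, truth = truth, report = report)
  }, error = function(e) {
    stop_fmt("pipeline failed at stage '%s': %s", stage,
             conditionMessage(e))
  })

  if (!is.null(config$out_dir)) .write_pipeline_outputs(out, config)
  invisible(out)
}

.write_pipeline_outputs <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  adj <- data.frame(probe_id = rownames(out$adjusted$values),
                    out$adjusted$values, check.names = FALSE)
  .write_tsv(adj, p("adjusted.tsv"))
  for (f in names(out$ratios)) {
    .write_tsv(as.data.frame(out$ratios[[f]]), p(sprintf("ratios_%s.tsv", f)))
  }
  .write_tsv(as.data.frame(out$de), p("de.tsv"))
  .write_tsv(out$de_summary, p("de_summary.tsv"))
  .write_tsv(as.data.frame(out$overall), p("overall_model.tsv"))
  .write_tsv(out$qc$included$summary, p("qc_summary.tsv"))
  if (!is.null(out$enrichment)) {
    .write_tsv(as.data.frame(out$enrichment), p("enrichment.tsv"))
  }
  mod_rows <- list()
  for (w in names(out$modules)) {
    m <- out$modules[[w]]
    if (is.null(m)) next
    mod_rows[[w]] <- data.frame(water = w, probe_id = names(m$labels),
                                module = unname(m$labels),
                                stringsAsFactors = FALSE)
  }
  if (length(mod_rows)) .write_tsv(do.call(rbind, mod_rows), p("modules.tsv"))
  jsonlite::write_json(out$report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(config$out_dir)
}
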