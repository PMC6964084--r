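# Manifest-driven end-to-end pipeline: read summary statistics, select
# instruments, run the requested analyses, write TSV tables and a JSON
# report.

#' Read a run manifest
#'
#' A manifest names the trait files (with optional column maps), the
#' selection parameters, the analyses to run and the output directory.
#' YAML (`.yml`/`.yaml`) and JSON are supported. Structure:
#' \preformatted{
#' exposure:  {path, trait_id, trait_type, column_map}
#' mediator:  {path, ...}          # optional
#' outcome:   {path, ...}
#' selection: {pval_threshold, clump_r2, clump_window_bp, het_alpha,
#'             method, alpha, ld_path}
#' analyses:  [mr, egger, loo, network, bidirectional, power]
#' power:     {n, case_fraction, r2, or, alpha}   # for the power analysis
#' out_dir:   path
#' seed:      integer
#' }
#'
#' @param path Manifest file path.
#' @return The manifest as a validated list.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  manifest <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_manifest(manifest)
  manifest
}

validate_manifest <- function(manifest) {
  if (is.null(manifest$exposure$path) || is.null(manifest$outcome$path)) {
    stop("manifest must name exposure and outcome files")
  }
  analyses <- manifest$analyses %||% "mr"
  known <- c("mr", "egger", "loo", "network", "bidirectional", "power")
  bad <- setdiff(analyses, known)
  if (length(bad) > 0) stop("unknown analysis: ", paste(bad, collapse = ", "))
  if (("network" %in% analyses) && is.null(manifest$mediator$path)) {
    stop("the network analysis requires a mediator file in the manifest")
  }
  for (role in c("exposure", "mediator", "outcome")) {
    p <- manifest[[role]]$path
    if (!is.null(p) && !file.exists(p)) stop(role, " file not found: ", p)
  }
  if ("power" %in% analyses) {
    need <- c("n", "case_fraction", "r2", "or")
    miss <- setdiff(need, names(manifest$power))
    if (length(miss) > 0) {
      stop("power analysis needs manifest$power fields: ", paste(miss, collapse = ", "))
    }
  }
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.manifest_config <- function(manifest) {
  s <- manifest$selection %||% list()
  ld <- if (!is.null(s$ld_path)) read_ld(s$ld_path) else NULL
  selection_config(
    pval_threshold = s$pval_threshold %||% 5e-4,
    clump_r2 = s$clump_r2 %||% 0.001,
    clump_window_bp = s$clump_window_bp %||% 5e5,
    clump = s$clump %||% TRUE,
    ld = ld,
    method = s$method %||% "greedy",
    het_alpha = s$het_alpha %||% 0.05,
    palindromic_eaf_window = s$palindromic_eaf_window %||% 0.08,
    alpha = s$alpha %||% 0.05,
    random_effects = isTRUE(s$random_effects)
  )
}

.read_trait <- function(entry, default_id, default_type = "continuous") {
  cm <- entry$column_map
  if (!is.null(cm)) cm <- unlist(cm)
  read_sumstats(entry$path, column_map = cm,
                trait_id = entry$trait_id %||% default_id,
                trait_type = entry$trait_type %||% default_type)
}

.log_kv <- function(stage, quiet, ...) {
  if (quiet) return(invisible())
  kv <- list(...)
  message("stage=", stage, if (length(kv) > 0) " " else "",
          paste(names(kv), unname(vapply(kv, as.character, character(1))),
                sep = "=", collapse = " "))
}

#' Run the full analysis pipeline from a manifest
#'
#' Executes the requested stages in dependency order: reading the trait
#' files, instrument selection and IVW (`mr`), MR-Egger (`egger`),
#' leave-one-out with influence flags (`loo`), the three-step network
#' analysis (`network`), bidirectional MR (`bidirectional`) and the
#' analytic power calculation (`power`). Tables are written as TSV and the
#' aggregated report as JSON under `out_dir`. The run is a pure function of
#' the manifest, the input files and the seed.
#'
#' @param manifest A manifest list (see [read_manifest()]) or a path to a
#'   manifest file.
#' @param quiet Suppress `key=value` progress logging.
#' @return The report list, invisibly. Side effects: `report.json`,
#'   `mr_results.tsv` and (as requested) `leave_one_out.tsv`,
#'   `network.tsv` under `out_dir`.
#' @export
run_pipeline <- function(manifest, quiet = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  validate_manifest(manifest)
  analyses <- manifest$analyses %||% "mr"
  out_dir <- manifest$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(manifest$seed)) set.seed(manifest$seed)
  config <- .manifest_config(manifest)

  exposure <- .read_trait(manifest$exposure, "exposure")
  outcome <- .read_trait(manifest$outcome, "outcome", "binary")
  mediator <- if (!is.null(manifest$mediator$path)) {
    .read_trait(manifest$mediator, "mediator")
  } else NULL
  .log_kv("read", quiet, exposure = nrow(exposure), outcome = nrow(outcome),
          mediator = if (is.null(mediator)) 0L else nrow(mediator))

  report <- list(
    manifest = manifest[setdiff(names(manifest), "out_dir")],
    selection = config[setdiff(names(config), "ld")]
  )
  mr_rows <- list()

  leg <- NULL
  if (any(c("mr", "egger", "loo") %in% analyses)) {
    leg <- select_and_fit(exposure, outcome, config)
    if (leg$status != "ok") stop("mr stage failed: no usable instruments")
    .log_kv("select", quiet, n_iv = leg$mr$n_snps,
            r2_total = if (is.null(leg$instruments)) NA else leg$instruments$r2_total)
  }
  if ("mr" %in% analyses) {
    report$mr <- unclass(leg$mr)
    report$instruments <- if (is.null(leg$instruments)) NULL else {
      x <- unclass(leg$instruments)
      x$selection_log <- NULL
      x$snp_ids <- as.list(x$snp_ids)
      x
    }
    report$harmonization <- leg$report
    mr_rows <- c(mr_rows, list(mr_result_row(leg$mr, "exposure->outcome")))
    .log_kv("mr", quiet, beta = signif(leg$mr$beta, 4), pval = signif(leg$mr$pval, 3))
  }
  if ("egger" %in% analyses) {
    egger <- mr_egger(leg$pairs)
    report$egger <- unclass(egger)
    mr_rows <- c(mr_rows, list(mr_result_row(egger, "exposure->outcome")))
    .log_kv("egger", quiet, intercept = signif(egger$egger_intercept, 4),
            intercept_pval = signif(egger$egger_intercept_pval, 3))
  }
  if ("loo" %in% analyses) {
    loo <- leave_one_out(leg$pairs, random_effects = config$random_effects)
    flags <- flag_influential(loo, alpha = config$alpha)
    write.table(loo, file.path(out_dir, "leave_one_out.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$loo_flags <- as.list(flags)
    .log_kv("loo", quiet, n_flagged = length(flags))
  }
  if ("network" %in% analyses) {
    net <- run_network(exposure, mediator, outcome, config, reverse = TRUE)
    tab <- network_report(net,
                          exposure = exposure$trait_id[1],
                          mediator = mediator$trait_id[1],
                          outcome = outcome$trait_id[1])
    write.table(tab, file.path(out_dir, "network.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$network <- list(
      total = unclass(net$total$mr), a_path = unclass(net$a_path$mr),
      b_path = unclass(net$b_path$mr),
      reverse = if (is.null(net$reverse)) NULL else unclass(net$reverse$mr),
      mediated_proportion = net$mediated_proportion,
      mediator_declared = net$mediator_declared,
      status = net$status
    )
    for (nm in c("total", "a_path", "b_path")) {
      if (!is.null(net[[nm]]$mr)) {
        mr_rows <- c(mr_rows, list(mr_result_row(net[[nm]]$mr, paste0("network_", nm))))
      }
    }
    .log_kv("network", quiet, mediated_proportion = signif(net$mediated_proportion, 4),
            declared = net$mediator_declared)
  }
  if ("bidirectional" %in% analyses) {
    if (is.null(mediator)) stop("bidirectional analysis requires a mediator file")
    bi <- bidirectional(exposure, mediator, config)
    report$bidirectional <- list(
      forward = if (is.null(bi$forward$mr)) NULL else unclass(bi$forward$mr),
      reverse = if (is.null(bi$reverse$mr)) NULL else unclass(bi$reverse$mr)
    )
    for (nm in c("forward", "reverse")) {
      if (!is.null(bi[[nm]]$mr)) {
        mr_rows <- c(mr_rows, list(mr_result_row(bi[[nm]]$mr, paste0("bidirectional_", nm))))
      }
    }
    .log_kv("bidirectional", quiet)
  }
  if ("power" %in% analyses) {
    p <- manifest$power
    pw <- mr_power_binary(p$n, p$case_fraction, p$r2, p$or, p$alpha %||% 0.05)
    report$power <- list(power = pw, power_2dp = round(pw, 2), spec = p)
    .log_kv("power", quiet, power = round(pw, 4))
  }

  if (length(mr_rows) > 0) {
    write.table(do.call(rbind, mr_rows), file.path(out_dir, "mr_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(report)
}
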