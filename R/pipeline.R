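# Orchestration: run the survey stages (scan -> classify -> genome ->
# evolution -> expression) from a single configuration, write per-stage
# TSV outputs and a machine-readable JSON survey report.
#
# The configuration is an R list (or a JSON file holding one). Keys:
#   inputs:  proteome_fasta, gene_map_tsv, synteny_tsv, cds_fasta,
#            pairs_tsv, kaks_tsv, expression_tsv, qpcr_csv
#   params:  max_ch (35), array_gap_kb (100), array_max_intervening (1),
#            k_groups (7), clock_rate (1.5e-8), qpcr_control ("CK")
#   stages:  subset of c("scan", "genome", "kaks", "express", "qpcr")
#   seed:    integer, used for any randomness

default_params <- function() {
  list(max_ch = 35L, array_gap_kb = 100, array_max_intervening = 1L,
       k_groups = 7L, clock_rate = 1.5e-8, qpcr_control = "CK")
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config$params <- utils::modifyList(default_params(),
                                     as.list(config$params))
  if (is.null(config$stages)) {
    config$stages <- c("scan", "genome", "kaks", "express", "qpcr")
  }
  if (is.null(config$seed)) config$seed <- 1L
  config
}

require_input <- function(config, key, stage) {
  path <- config$inputs[[key]]
  if (is.null(path) || !file.exists(path)) {
    stop(sprintf("stage '%s' needs input '%s' (missing or not found)",
                 stage, key), call. = FALSE)
  }
  path
}

write_stage_tsv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.table(df, file.path(out_dir, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Run the family survey over the configured stages
#'
#' Stages run in dependency order; a failing stage aborts only the
#' stages downstream of it (recorded under `$errors`). All outputs are
#' deterministic given the configuration and seed.
#'
#' @param config Configuration list or path to a JSON config file (see
#'   the package vignette for the key schema).
#' @param out_dir Optional output directory for per-stage TSVs and the
#'   JSON report (`survey_report.json`).
#' @return The survey report, a nested list with one section per
#'   executed stage plus `provenance` (seed, config digest, input file
#'   digests).
#' @export
run_survey <- function(config, out_dir = NULL) {
  config <- read_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  set.seed(config$seed)
  p <- config$params
  report <- list(schema_version = "1.0",
                 provenance = survey_provenance(config))
  errors <- list()
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(NULL)
    tryCatch(fun(), error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  classified <- NULL
  report$scan <- run_stage("scan", function() {
    path <- require_input(config, "proteome_fasta", "scan")
    seqs <- as_protein_set(path)
    matches <- classify_domains(scan_proteome(seqs, max_ch = p$max_ch))
    classified <<- classify_proteome(matches, proteins = names(seqs))
    write_stage_tsv(matches, out_dir, "domains.tsv")
    write_stage_tsv(classified, out_dir, "classification.tsv")
    xt <- crosstab_subsets(classified$subset, classified$n_domains)
    list(n_proteins = length(seqs),
         n_domains = nrow(matches),
         domain_types = as.list(table(factor(matches$type_label,
                                             levels = TYPE_LEVELS))),
         subset_counts = as.list(table(factor(classified$subset,
                                              levels = SUBSET_LEVELS))),
         crosstab = xt)
  })

  report$genome <- run_stage("genome", function() {
    out <- list()
    if (!is.null(config$inputs$gene_map_tsv)) {
      genes <- utils::read.delim(require_input(config, "gene_map_tsv",
                                               "genome"))
      genes$in_family <- as.logical(genes$in_family)
      arrays <- call_tandem_arrays(genes, max_gap_kb = p$array_gap_kb,
                                   max_intervening = p$array_max_intervening)
      write_stage_tsv(arrays, out_dir, "tandem_arrays.tsv")
      out$n_arrays <- length(unique(arrays$array_id))
      out$n_array_genes <- nrow(arrays)
      out$genes_per_chromosome <- as.list(table(
        genes$chrom[genes$in_family]))
    }
    if (!is.null(config$inputs$synteny_tsv)) {
      rec <- utils::read.delim(require_input(config, "synteny_tsv",
                                             "genome"),
                               na.strings = c("NA", ""))
      sgs <- subgenome_summary(rec)
      out$subgenome_counts <- as.list(sgs$subgenome_counts)
      out$copy_number <- as.list(sgs$copy_number)
      out$n_anchors <- sgs$n_anchors
      out$n_no_anchor <- sgs$n_no_anchor
    }
    if (length(out) == 0L) {
      stop("stage 'genome' needs gene_map_tsv and/or synteny_tsv",
           call. = FALSE)
    }
    out
  })

  report$kaks <- run_stage("kaks", function() {
    if (!is.null(config$inputs$kaks_tsv)) {
      tab <- utils::read.delim(require_input(config, "kaks_tsv", "kaks"))
      tab$t_my <- divergence_time(tab$ks, rate = p$clock_rate)
    } else {
      pairs <- utils::read.delim(require_input(config, "pairs_tsv", "kaks"))
      cds <- as_protein_set(require_input(config, "cds_fasta", "kaks"))
      tab <- kaks_table(pairs, cds, rate = p$clock_rate)
    }
    write_stage_tsv(tab, out_dir, "kaks.tsv")
    sel <- suppressWarnings(selection_summary(tab$omega))
    list(n_pairs = nrow(tab), selection = sel,
         t_my = list(min = min(tab$t_my, na.rm = TRUE),
                     mean = mean(tab$t_my, na.rm = TRUE),
                     max = max(tab$t_my, na.rm = TRUE)),
         estimator = if (is.null(config$inputs$kaks_tsv)) "NG86"
                     else "precomputed")
  })

  report$express <- run_stage("express", function() {
    path <- require_input(config, "expression_tsv", "express")
    tab <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
    mat <- as.matrix(tab)
    lm <- filter_and_transform(mat)
    cl <- cluster_expression(lm, k = p$k_groups)
    gdf <- data.frame(gene_id = names(cl$groups), group = cl$groups,
                      stringsAsFactors = FALSE)
    write_stage_tsv(gdf, out_dir, "expression_groups.tsv")
    out <- list(n_genes = nrow(mat), n_removed = attr(lm, "n_removed"),
                group_sizes = as.list(table(cl$groups)))
    if (!is.null(classified)) {
      subs <- stats::setNames(classified$subset, classified$protein_id)
      xt <- suppressWarnings(expression_by_subset(cl$groups, subs))
      out$by_subset <- xt$counts
      write_stage_tsv(as.data.frame(xt$counts), out_dir,
                      "expression_by_subset.tsv")
    }
    out
  })

  report$qpcr <- run_stage("qpcr", function() {
    path <- require_input(config, "qpcr_csv", "qpcr")
    tab <- utils::read.csv(path)
    fc <- ddct_fold_change(tab, control = p$qpcr_control)
    write_stage_tsv(fc, out_dir, "fold_changes.tsv")
    list(n_genes = length(unique(fc$gene)),
         max_fold = max(fc$fold_change))
  })

  report$errors <- errors
  validate_report(report)
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "survey_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

survey_provenance <- function(config) {
  inputs <- config$inputs
  digests <- list()
  for (key in names(inputs)) {
    if (is.character(inputs[[key]]) && file.exists(inputs[[key]])) {
      digests[[key]] <- unname(tools::md5sum(inputs[[key]]))
    }
  }
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  on.exit(unlink(tmp))
  list(seed = config$seed,
       config_md5 = unname(tools::md5sum(tmp)),
       input_md5 = digests,
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' Validate the structure of a survey report
#'
#' Checks the minimal schema: a version string, provenance with seed and
#' config digest, and internally consistent scan totals when present.
#'
#' @param report A report as returned by [run_survey()].
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  stopifnot(is.list(report),
            identical(report$schema_version, "1.0"),
            !is.null(report$provenance$seed),
            !is.null(report$provenance$config_md5))
  if (!is.null(report$scan)) {
    stopifnot(report$scan$n_domains ==
                sum(unlist(report$scan$domain_types)),
              report$scan$n_proteins ==
                sum(unlist(report$scan$subset_counts)))
  }
  invisible(TRUE)
}
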