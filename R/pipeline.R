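#' Pipeline configuration
#'
#' Collects the file paths, comparison template and the decided analysis
#' defaults for a full multi-comparison run. Unknown arguments are errors
#' (there are no silently ignored keys).
#'
#' @param expression Path to the expression TSV ([read_expression_table()]
#'   format).
#' @param design Path to the design TSV.
#' @param gmt Path to the gene-set GMT file.
#' @param dag Optional path to the two-column term-DAG TSV.
#' @param ct_panel Optional path to a qPCR Ct panel TSV.
#' @param out_dir Output directory (created if absent).
#' @param comparisons List of [comparison()] objects; defaults to the
#'   five-comparison template of [default_comparisons()].
#' @param normalize Quantile-normalize the expression matrix first.
#' @param span IBMT local-regression span.
#' @param min_size,max_size Gene-set size window.
#' @param directional Directional enrichment (signed scores).
#' @param level Score level, `"probe"` or `"gene"`.
#' @param gene_map Optional path to a probe-to-gene TSV (`probe_id`,
#'   `gene_id`).
#' @param set_fdr FDR threshold flagging a set as enriched.
#' @param overlap_threshold Jaccard threshold for term collapsing.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed feeds any resampling diagnostics).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, design, gmt, dag = NULL,
                            ct_panel = NULL, out_dir,
                            comparisons = default_comparisons(),
                            normalize = TRUE, span = 0.75,
                            min_size = 10L, max_size = 500L,
                            directional = TRUE,
                            level = c("probe", "gene"), gene_map = NULL,
                            set_fdr = 0.01, overlap_threshold = 0.7,
                            seed = 1L) {
  level <- match.arg(level)
  for (p in c(expression, design, gmt, dag, ct_panel, gene_map))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  stopifnot(set_fdr > 0, set_fdr < 1, overlap_threshold > 0,
            overlap_threshold <= 1, span > 0, span <= 1)
  structure(list(expression = expression, design = design, gmt = gmt,
                 dag = dag, ct_panel = ct_panel, out_dir = out_dir,
                 comparisons = comparisons, normalize = normalize,
                 span = span, min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 directional = directional, level = level,
                 gene_map = gene_map, set_fdr = set_fdr,
                 overlap_threshold = overlap_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis chain in memory
#'
#' For each comparison, in order: per-gene contrast fit, empirical-Bayes
#' hyperparameter estimation, moderated test with BH FDR, signed
#' significance scores, logistic-regression enrichment, and term
#' collapsing over the DAG; finally the signed enrichment matrix across
#' comparisons.
#'
#' @param study An [expression_study()].
#' @param sets A `gene_set_collection`.
#' @param dag Optional `term_dag` (without it, collapsing is skipped and
#'   all enriched terms are retained).
#' @param comparisons List of [comparison()] objects.
#' @inheritParams pipeline_config
#' @param gene_map Optional probe-to-gene data frame.
#' @return List with `per_comparison` (per comparison: `stats`, `hyper`,
#'   `moderated`, `scores`, `enrichment`, `retained`, `drop_log`) and
#'   `matrix` (signed enrichment matrix).
#' @export
run_analysis <- function(study, sets, dag = NULL,
                         comparisons = default_comparisons(),
                         span = 0.75, min_size = 10L, max_size = 500L,
                         directional = TRUE, level = "probe",
                         gene_map = NULL, set_fdr = 0.01,
                         overlap_threshold = 0.7) {
  stage <- function(what, cmp_name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", what, "' failed for comparison '", cmp_name, "': ",
           conditionMessage(e), call. = FALSE))
  }
  per <- lapply(comparisons, function(cmp) {
    st <- stage("fit_gene_stats", cmp$name, fit_gene_stats(study, cmp))
    hy <- stage("estimate_eb_hyperparameters", cmp$name,
                estimate_eb_hyperparameters(st, span = span))
    mo <- stage("moderated_test", cmp$name, moderated_test(st, hy))
    sc <- stage("build_significance_scores", cmp$name,
                build_significance_scores(mo, gene_map = gene_map,
                                          level = level))
    en <- stage("run_lrpath", cmp$name,
                run_lrpath(sc, sets, min_size = min_size,
                           max_size = max_size, directional = directional,
                           fdr_threshold = set_fdr))
    sig <- en$set_id[en$enriched]
    if (!is.null(dag)) {
      col <- stage("collapse_significant_terms", cmp$name,
                   collapse_significant_terms(sig, dag, sets,
                                              overlap_threshold))
    } else {
      col <- list(retained = sig,
                  drop_log = data.frame(dropped_id = character(),
                                        kept_id = character(),
                                        rule = character(),
                                        jaccard = numeric()))
    }
    list(stats = st, hyper = hy, moderated = mo, scores = sc,
         enrichment = en, retained = col$retained, drop_log = col$drop_log)
  })
  names(per) <- vapply(comparisons, `[[`, "", "name")
  mat <- enrichment_matrix(lapply(per, `[[`, "enrichment"))
  list(per_comparison = per, matrix = mat)
}

write_tsv_full <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  cols <- lapply(df, function(col)
    if (is.double(col)) sprintf("%.17g", col) else as.character(col))
  if (nrow(df)) writeLines(do.call(paste, c(cols, sep = "\t")), con,
                           sep = "\n")
  invisible(path)
}

#' Run the config-driven pipeline and write its output directory
#'
#' Reads the configured inputs, runs [run_analysis()] over all
#' comparisons, and writes per-comparison gene-statistics and enrichment
#' TSVs, retained-term lists with drop logs, the signed enrichment
#' matrix, an optional qPCR concordance table, and a machine-readable
#' manifest recording the package version, an MD5 hash of the effective
#' configuration, the estimated prior degrees of freedom per comparison
#' and every decided default. All numbers are written at full double
#' precision, so identical inputs give byte-identical outputs. Any stage
#' error aborts with the stage and comparison named.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, the result of [run_analysis()] plus
#'   `out_dir`/`manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  vals <- read_expression_table(config$expression)
  design <- read_design_table(config$design)
  study <- expression_study(vals, design)
  if (config$normalize) study$values <- quantile_normalize(study$values)
  sets <- read_gmt(config$gmt, universe = rownames(study$values))
  dag <- if (!is.null(config$dag)) read_dag(config$dag)
  gene_map <- if (!is.null(config$gene_map))
    utils::read.delim(config$gene_map, stringsAsFactors = FALSE)
  say("loaded ", nrow(study$values), " probes x ", ncol(study$values),
      " samples; ", length(sets), " gene sets")

  res <- run_analysis(study, sets, dag = dag,
                      comparisons = config$comparisons,
                      span = config$span, min_size = config$min_size,
                      max_size = config$max_size,
                      directional = config$directional,
                      level = config$level, gene_map = gene_map,
                      set_fdr = config$set_fdr,
                      overlap_threshold = config$overlap_threshold)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  d0_per <- numeric(0)
  counts <- list()
  for (nm in names(res$per_comparison)) {
    pc <- res$per_comparison[[nm]]
    write_tsv_full(pc$moderated[c("probe_id", "b", "a", "s2", "d", "s0_2",
                                  "t_mod", "df", "p", "q", "sign")],
                   file.path(config$out_dir,
                             paste0(nm, "_gene_stats.tsv")))
    write_tsv_full(pc$enrichment[c("set_id", "name", "n", "beta1",
                                   "odds_ratio", "direction", "p", "fdr",
                                   "enriched")],
                   file.path(config$out_dir, paste0(nm, "_enrichment.tsv")))
    write_tsv_full(data.frame(term = pc$retained,
                              stringsAsFactors = FALSE),
                   file.path(config$out_dir,
                             paste0(nm, "_retained_terms.tsv")))
    write_tsv_full(pc$drop_log,
                   file.path(config$out_dir, paste0(nm, "_drop_log.tsv")))
    d0_per[nm] <- pc$hyper$d0
    counts[[nm]] <- list(probes_tested = attr(pc$moderated, "m_tested"),
                         sets_tested = nrow(pc$enrichment),
                         enriched = sum(pc$enrichment$enriched),
                         retained = length(pc$retained))
    say(nm, ": d0 = ", format(pc$hyper$d0, digits = 4), "; ",
        counts[[nm]]$enriched, " enriched sets, collapsed to ",
        counts[[nm]]$retained)
  }
  write_enrichment_matrix(res$matrix,
                          file.path(config$out_dir,
                                    "enrichment_matrix.tsv"))

  concordance <- NULL
  if (!is.null(config$ct_panel)) {
    panel <- utils::read.delim(config$ct_panel, stringsAsFactors = FALSE)
    pairedres <- Filter(function(pc) attr(pc$stats, "mode") == "paired",
                        res$per_comparison)
    concordance <- platform_concordance(
      lapply(pairedres, `[[`, "moderated"), panel,
      gene_map = gene_map)
    write_tsv_full(concordance$pairs,
                   file.path(config$out_dir, "concordance_pairs.tsv"))
    ccr <- concordance$concordance
    write_tsv_full(data.frame(rho = ccr$rho, p = ccr$p, n = ccr$n),
                   file.path(config$out_dir, "concordance_summary.tsv"))
    say("platform concordance: rho = ", format(ccr$rho, digits = 3),
        " over ", ccr$n, " pairs")
  }

  eff <- config[setdiff(names(config), "comparisons")]
  eff$comparisons <- lapply(config$comparisons, unclass)
  cfg_json <- jsonlite::toJSON(eff, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(
    package = "ibmtlr",
    version = as.character(utils::packageVersion("ibmtlr")),
    config = eff,
    config_md5 = cfg_hash,
    defaults = list(span = config$span,
                    d0_search = c(0.01, 1e6),
                    d0_bisection_tol = 1e-8,
                    score_log_base = "natural",
                    set_size_window = c(config$min_size, config$max_size),
                    irls_max_iter = 50L, irls_tol = 1e-8,
                    irls_separation_bound = 20,
                    fdr_family = "all sets tested in one run",
                    bh_family_size = "tested probes per comparison",
                    set_fdr = config$set_fdr,
                    overlap_threshold = config$overlap_threshold,
                    qpcr_efficiency = 2,
                    qpcr_fold_average = "mean of per-subject log2 folds",
                    two_sided_tests = TRUE,
                    normalize = config$normalize,
                    level = config$level),
    d0 = as.list(d0_per),
    counts = counts,
    seed = config$seed)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(res, list(out_dir = config$out_dir, manifest = manifest,
                        concordance = concordance)))
}
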