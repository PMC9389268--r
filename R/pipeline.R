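.defaultRunConfig <- function() {
  list(inputs = list(counts = NULL, counts_format = "tsv", design = NULL,
                     lengths = NULL, annotation = NULL,
                     annotation_format = "gmt"),
       thresholds = list(p = 0.05, fc = 2, use_q = FALSE),
       filter = list(min_fpkm = 0, scope = "all_genotypes"),
       de = list(method = "nb_wald"),
       pattern = list(universe = "degs"),
       enrichment = list(min_term_size = 2),
       outdir = NULL,
       seed = 1L)
}

.mergeConfig <- function(default, user) {
  for (k in names(user)) {
    if (is.list(default[[k]]) && is.list(user[[k]]))
      default[[k]] <- .mergeConfig(default[[k]], user[[k]])
    else default[[k]] <- user[[k]]
  }
  default
}

.loadRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      .stopf("missing_file", "config file not found: '%s'", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- .mergeConfig(.defaultRunConfig(), config)
  for (f in c("counts", "design", "lengths"))
    if (is.null(cfg$inputs[[f]]))
      .stopf("config", "config is missing required input '%s'", f)
  if (is.null(cfg$outdir)) .stopf("config", "config needs an 'outdir'")
  if (cfg$thresholds$fc <= 1) .stopf("config", "fc threshold must be > 1")
  cfg
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full trio heterosis pipeline
#'
#' Orchestrates normalize, filter, differential expression on the three
#' canonical contrasts, inheritance-pattern classification, per-gene
#' expression heterosis and (when an annotation is supplied) term
#' enrichment per three-way category, writing deterministic TSV/JSON
#' outputs plus a machine-readable run summary.  Reruns with identical
#' inputs and config reproduce every output byte for byte; progress is
#' logged to stderr only.
#'
#' @param config path to a YAML run config, or an equivalent nested list.
#'   Required entries: \code{inputs: counts / design / lengths} (paths) and
#'   \code{outdir}; optional: \code{inputs: annotation},
#'   \code{thresholds: p / fc / use_q}, \code{filter: min_fpkm / scope},
#'   \code{de: method}, \code{pattern: universe},
#'   \code{enrichment: min_term_size}, \code{seed}.
#' @return invisibly, a list with the main in-memory results
#'   (\code{experiment}, \code{fpkm}, \code{de}, \code{assignments},
#'   \code{summary}, \code{heterosis}, \code{enrichment}, \code{paths}).
#' @export
runPipeline <- function(config) {
  cfg <- .loadRunConfig(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- function(fmt, ...) message(sprintf(paste0("[triohet] ", fmt), ...))

  log("reading inputs")
  x <- readTrioExperiment(cfg$inputs$counts, cfg$inputs$design,
                          cfg$inputs$lengths,
                          format = cfg$inputs$counts_format)
  ann <- if (!is.null(cfg$inputs$annotation))
    readAnnotation(cfg$inputs$annotation, cfg$inputs$annotation_format)

  log("normalizing (%d genes, %d samples)", nrow(x), ncol(x))
  sf <- sizeFactorsMedianRatio(x)
  fpkm <- computeFPKM(x)
  expressed <- filterExpressed(fpkm, x, minFpkm = cfg$filter$min_fpkm,
                               scope = cfg$filter$scope)

  log("differential expression (%s)", cfg$de$method)
  de <- lapply(trioContrasts(), function(ct)
    deTest(x, ct, method = cfg$de$method,
           pThresh = cfg$thresholds$p, fcThresh = cfg$thresholds$fc,
           useQ = cfg$thresholds$use_q, sizeFactors = sf))
  degSets <- lapply(de, degSet)
  venn <- overlapCounts(degSets)

  log("classifying inheritance patterns")
  assignments <- assignPatterns(de$H_vs_F, de$H_vs_M, de$F_vs_M,
                                universe = cfg$pattern$universe)
  summary <- summarizePatterns(assignments)

  log("expression heterosis")
  heterosis <- trioExpressionHeterosis(fpkm, x,
                                       genes = assignments$gene_id)
  heterosis <- heterosis[order(-heterosis$h_pct, heterosis$gene_id), ,
                         drop = FALSE]
  heterosisOut <- formatHeterosisTable(heterosis)

  enrichment <- list()
  if (!is.null(ann)) {
    log("term enrichment")
    background <- union(expressed, assignments$gene_id)
    for (cat in c("additive", "dominant", "over_dominant")) {
      study <- as.character(
        assignments$gene_id[assignments$category3 == cat])
      if (!length(study)) next
      enrichment[[cat]] <- enrichTerms(study, background, ann,
                                       minTermSize =
                                         cfg$enrichment$min_term_size)
    }
  }

  log("writing outputs to %s", cfg$outdir)
  paths <- list(
    fpkm = file.path(cfg$outdir, "fpkm.tsv"),
    size_factors = file.path(cfg$outdir, "size_factors.tsv"),
    expressed = file.path(cfg$outdir, "expressed_genes.txt"),
    venn = file.path(cfg$outdir, "venn_degs.json"),
    patterns = file.path(cfg$outdir, "patterns.tsv"),
    pattern_summary = file.path(cfg$outdir, "pattern_summary.json"),
    heterosis = file.path(cfg$outdir, "heterosis_genes.tsv"),
    run_summary = file.path(cfg$outdir, "run_summary.json"),
    report = file.path(cfg$outdir, "report.md"))
  .writeTsv(data.frame(gene_id = rownames(fpkm),
                       round(fpkm, 6), check.names = FALSE), paths$fpkm)
  .writeTsv(data.frame(sample_id = names(sf), size_factor = sf),
            paths$size_factors)
  writeLines(expressed, paths$expressed)
  for (lab in names(de)) {
    p <- file.path(cfg$outdir, paste0("de_", lab, ".tsv"))
    paths[[paste0("de_", lab)]] <- p
    .writeTsv(as.data.frame(de[[lab]]), p)
  }
  .writeJson(list(totals = as.list(venn$totals),
                  regions = as.list(venn$regions)), paths$venn)
  .writeTsv(as.data.frame(assignments), paths$patterns)
  .writeJson(summary, paths$pattern_summary)
  .writeTsv(heterosisOut, paths$heterosis)
  for (cat in names(enrichment)) {
    p <- file.path(cfg$outdir, paste0("enrichment_", cat, ".tsv"))
    paths[[paste0("enrichment_", cat)]] <- p
    .writeTsv(enrichment[[cat]], p)
  }
  degCounts <- lapply(de, function(d)
    list(up = sum(d$call == "up"), down = sum(d$call == "down"),
         tested = sum(d$call != "untested")))
  cat3 <- summary$category3
  cfgEcho <- cfg
  cfgEcho$outdir <- NULL    # output location is not part of the record
  .writeJson(list(
    package = as.character(utils::packageVersion("triohet")),
    config = cfgEcho,
    n_genes = nrow(x), n_samples = ncol(x),
    n_expressed = length(expressed),
    deg_counts = degCounts,
    venn_regions = as.list(venn$regions),
    n_assigned = summary$n_total,
    n_classified = summary$n_classified,
    category3 = stats::setNames(as.list(cat3$proportion), cat3$label)),
    paths$run_summary)
  makeReport(cfg$outdir)
  invisible(list(experiment = x, fpkm = fpkm, sizeFactors = sf,
                 expressed = expressed, de = de, venn = venn,
                 assignments = assignments, summary = summary,
                 heterosis = heterosis, enrichment = enrichment,
                 paths = paths))
}

#' Write a human-readable markdown summary of a pipeline run
#'
#' Tabulates pattern counts and proportions, the top expression-heterosis
#' genes and (when present) the top enrichment rows from the files a
#' [runPipeline()] run left in \code{outdir}.
#'
#' @param outdir a completed pipeline output directory.
#' @param topN rows to show in the gene and term tables (default 10).
#' @return the report path, invisibly.
#' @export
makeReport <- function(outdir, topN = 10L) {
  need <- file.path(outdir, c("pattern_summary.json", "patterns.tsv",
                              "heterosis_genes.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    .stopf("missing_file", "missing pipeline output: %s", missing[1L])
  summary <- jsonlite::read_json(need[1L], simplifyVector = TRUE)
  het <- .readTsv(need[3L], "heterosis")
  lines <- c("# Trio heterosis run report", "",
             sprintf("Genes assigned a pattern: %d (classified: %d)",
                     summary$n_total, summary$n_classified), "",
             "## Inheritance patterns", "",
             "| pattern | n | proportion |", "|---|---|---|",
             sprintf("| %s | %d | %s |", summary$patterns$label,
                     summary$patterns$n,
                     ifelse(is.na(summary$patterns$proportion), "-",
                            sprintf("%.4f", summary$patterns$proportion))),
             "",
             "## Three-way categories (share of classified genes)", "",
             "| category | n | proportion |", "|---|---|---|",
             sprintf("| %s | %d | %s |", summary$category3$label,
                     summary$category3$n,
                     ifelse(is.na(summary$category3$proportion), "-",
                            sprintf("%.4f", summary$category3$proportion))),
             "",
             "## Top expression-heterosis genes", "",
             "| gene_id | F1 | MP | FC | H |", "|---|---|---|---|---|")
  top <- utils::head(het, topN)
  lines <- c(lines, sprintf("| %s | %.2f | %.2f | %.2f | %s |",
                            top$gene_id, top$f1, top$mp, top$fc,
                            top$h_pct))
  enrFiles <- list.files(outdir, pattern = "^enrichment_.*\\.tsv$",
                         full.names = TRUE)
  for (f in sort(enrFiles)) {
    cat3 <- sub("^enrichment_(.*)\\.tsv$", "\\1", basename(f))
    e <- utils::head(.readTsv(f, "enrichment"), topN)
    if (!nrow(e)) next
    lines <- c(lines, "", sprintf("## Top enriched terms: %s", cat3), "",
               "| term | k/n | M/N | fold | p | q |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %d/%d | %d/%d | %.2f | %.3g | %.3g |",
                       e$term_id, e$k, e$n, e$M, e$N, e$fold, e$p, e$q))
  }
  path <- file.path(outdir, "report.md")
  writeLines(lines, path)
  invisible(path)
}

#' Worked-example table: potassium-related genes of a tobacco trio
#'
#' Mean hybrid FPKM (\code{f1}), mid-parent FPKM (\code{mp}), fold change
#' (\code{fc}) and expression-heterosis percent (\code{h_fpkm_pct}) of 28
#' potassium-uptake- and root-development-related genes from a tobacco
#' G70 x GDH11 parent-hybrid trio, split into over-dominant and dominant
#' inheritance patterns.  Values are as printed in the source report
#' (2-decimal precision); the table drives the worked example in the
#' README and the consistency checks of [expressionHeterosis()].
#'
#' @return data.frame with columns pattern, gene_id, description, f1, mp,
#'   fc, h_fpkm_pct.
#' @export
kHeterosisGenes <- function() {
  path <- system.file("extdata", "k_heterosis_genes.tsv",
                      package = "triohet", mustWork = TRUE)
  df <- .readTsv(path, "example table")
  df$h_fpkm_pct <- as.numeric(sub("%$", "", df$h_fpkm_pct))
  df
}
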