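#' Pipeline configuration
#'
#' Collects the tunable parameters of [run_pipeline()] with the study
#' defaults: pseudo-count 0.05, abundance justification +4, 5% PIF tails,
#' top 40 proteins for clustering, DE filter |fold| in \[1.3, 15\] at
#' p < 0.05, activation threshold |z| > 2 with qualified bands 1.7/1.5/1.0.
#'
#' @param pseudo_count,a_offset,tail_fraction,top_k,min_fold,max_fold,alpha
#'   see [pif_fit()].
#' @param z_threshold,qualified_bands see [classify_regulator()].
#' @param seed integer recorded in the run summary.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(pseudo_count = 0.05, a_offset = 4,
                            tail_fraction = 0.05, top_k = 40,
                            min_fold = 1.3, max_fold = 15, alpha = 0.05,
                            z_threshold = 2, qualified_bands = c(1.7, 1.5, 1.0),
                            seed = 1L) {
  if (tail_fraction <= 0 || tail_fraction >= 0.5)
    stop("tail_fraction must be in (0, 0.5)", call. = FALSE)
  if (min_fold <= 1 || min_fold > max_fold)
    stop("need 1 < min_fold <= max_fold", call. = FALSE)
  if (top_k %% 2 != 0 || top_k < 2) stop("top_k must be a positive even number", call. = FALSE)
  if (length(qualified_bands) != 3 || any(diff(qualified_bands) >= 0) ||
      any(qualified_bands <= 0))
    stop("qualified_bands must be three strictly decreasing positive cut points",
         call. = FALSE)
  structure(list(pseudo_count = pseudo_count, a_offset = a_offset,
                 tail_fraction = tail_fraction, top_k = top_k,
                 min_fold = min_fold, max_fold = max_fold, alpha = alpha,
                 z_threshold = z_threshold, qualified_bands = qualified_bands,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline to disk
#'
#' Orchestrates every stage on a raw count matrix: normalization, MA
#' table, moderated-t DE table, PIF ranking with tails and top-k,
#' compartment skew (when a symbol list is supplied), two-way clustering
#' of the top-k proteins, tail enrichment (when term sets are supplied)
#' and upstream-regulator predictions (when a network is supplied).
#' Stages whose optional inputs are absent are skipped and recorded as
#' such in the JSON run summary. A `.partial` marker is present in the
#' output directory while the run is incomplete; it is removed on
#' success.
#'
#' @param counts a [count_matrix()] or path to a counts TSV.
#' @param groups group map (ignored when `counts` is a `count_matrix`):
#'   named vector or path to a groups TSV.
#' @param out_dir output directory (created if missing).
#' @param mito_list optional compartment symbols: character vector or path.
#' @param gmt optional term sets: named list or GMT path.
#' @param network optional regulator network: data.frame or TSV path.
#' @param phenotypes optional named per-sample phenotype values (e.g. feed
#'   efficiency); their high-minus-low contrast is reported in the
#'   summary.
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the fitted `"pif_fit"`, the per-stage
#'   results and the summary (also written as `summary.json`).
#' @export
run_pipeline <- function(counts, groups = NULL, out_dir,
                         mito_list = NULL, gmt = NULL, network = NULL,
                         phenotypes = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  marker <- file.path(out_dir, ".partial")
  writeLines(format(Sys.time()), marker)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  cm <- stage("input", {
    if (is.character(counts)) read_count_matrix(counts, groups)
    else if (inherits(counts, "count_matrix")) count_matrix(counts$counts, counts$groups)
    else count_matrix(counts, groups)
  })
  if (is.character(mito_list) && length(mito_list) == 1 && file.exists(mito_list))
    mito_list <- read_symbol_list(mito_list)
  if (is.character(gmt)) gmt <- read_gmt(gmt)
  if (is.character(network)) network <- read_regulator_network(network)

  fit <- stage("fit", pif_fit(cm,
                              pseudo_count = config$pseudo_count,
                              a_offset = config$a_offset,
                              tail_fraction = config$tail_fraction,
                              top_k = config$top_k, min_fold = config$min_fold,
                              max_fold = config$max_fold, alpha = config$alpha))

  stage("tables", {
    write_tsv_matrix(fit$normalized$counts, file.path(out_dir, "normalized_counts.tsv"),
                     id_col = "protein")
    write_tsv(as.data.frame(fit$ma), file.path(out_dir, "ma_table.tsv"))
    write_tsv(as.data.frame(fit$de), file.path(out_dir, "de_table.tsv"))
    write_tsv(as.data.frame(fit$pif), file.path(out_dir, "pif_table.tsv"))
  })

  skipped <- character()
  mito <- NULL
  if (is.null(mito_list)) skipped <- c(skipped, "mito_skew")
  else mito <- stage("mito_skew", {
    rep <- mito_skew_report(fit$ma, mito_list, fit$tails)
    write_tsv(data.frame(n_listed = rep$n_listed, n_matched = rep$n_matched,
                         k_pos = rep$k_pos, k_neg = rep$k_neg,
                         n_ties = rep$n_ties, p_binom = rep$p_binom,
                         tail_overlap_up = rep$tail_overlap_up,
                         tail_overlap_down = rep$tail_overlap_down),
              file.path(out_dir, "mito_skew.tsv"))
    rep
  })

  clus <- stage("cluster", {
    idx <- match(fit$topk$protein, rownames(fit$normalized$counts))
    L <- log2(fit$normalized$counts[idx, , drop = FALSE] + config$pseudo_count)
    std <- row_standardize(L)
    cr <- hierarchical_cluster(std, groups = fit$normalized$groups)
    export_heatmap(cr, std, file.path(out_dir, "cluster_ordered.tsv"))
    write_tsv(data.frame(sample = names(cr$column_partition),
                         cluster = unname(cr$column_partition),
                         group = unname(fit$normalized$groups[names(cr$column_partition)])),
              file.path(out_dir, "cluster_samples.tsv"))
    cr
  })

  enr <- NULL
  if (is.null(gmt)) skipped <- c(skipped, "enrichment")
  else enr <- stage("enrichment", {
    bg <- toupper(trimws(fit$ma$protein))
    res <- lapply(c(up = "up", down = "down"), function(side) {
      hypergeom_enrichment(toupper(trimws(fit$tails[[side]])), bg, gmt)
    })
    tab <- rbind(cbind(tail = "up", as.data.frame(res$up)),
                 cbind(tail = "down", as.data.frame(res$down)))
    write_tsv(tab, file.path(out_dir, "enrichment.tsv"))
    res
  })

  reg <- NULL
  if (is.null(network)) skipped <- c(skipped, "regulators")
  else reg <- stage("regulators", {
    res <- regulator_predictions(network, fit$de, config$z_threshold,
                                 config$qualified_bands, config$alpha)
    write_tsv(as.data.frame(res), file.path(out_dir, "regulators.tsv"))
    res
  })

  filt <- de_filter(fit$de, config$min_fold, config$max_fold, config$alpha)
  summary <- list(
    n_proteins = nrow(fit$normalized$counts),
    n_samples = ncol(fit$normalized$counts),
    stages = list(
      ma_table = nrow(fit$ma), de_table = nrow(fit$de),
      pif_table = nrow(fit$pif),
      de_pass = nrow(filt), de_up = attr(filt, "n_up"),
      de_down = attr(filt, "n_down"),
      tail_size = fit$tails$k, top_k = nrow(fit$topk),
      cluster_rows = length(clus$row_order)),
    prior = list(d0 = if (is.infinite(fit$prior$d0)) "Inf" else fit$prior$d0,
                 s0_2 = fit$prior$s0_2),
    cluster_purity = clus$purity,
    skipped = as.list(skipped),
    seed = config$seed,
    versions = list(pifomics = as.character(packageVersion("pifomics")),
                    R = paste(R.version$major, R.version$minor, sep = "."))
  )
  if (!is.null(mito))
    summary$mito_skew <- list(n_matched = mito$n_matched, k_pos = mito$k_pos,
                              k_neg = mito$k_neg, p_binom = mito$p_binom,
                              tail_overlap_up = mito$tail_overlap_up,
                              tail_overlap_down = mito$tail_overlap_down)
  if (!is.null(phenotypes))
    summary$phenotype_contrast <- group_contrast(phenotypes, fit$normalized$groups)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  unlink(marker)
  invisible(list(fit = fit, mito = mito, cluster = clus, enrichment = enr,
                 regulators = reg, summary = summary))
}
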