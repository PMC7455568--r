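#' Read a plain-text key = value pipeline configuration
#'
#' Lines of the form `key = value`; `#` starts a comment; blank lines
#' ignored.  Recognized keys (all optional): `tpm_min`, `pseudocount`,
#' `quantile_rule` (an integer quantile type), `quartile_scope`
#' (`per_week` or `pooled`), `week_policy` (`per_week` or `mean`).
#'
#' @param path Path to the config file.
#' @return Named list of parsed values.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) io_error(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    kv <- strsplit(lines[i], "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      fmt_error(sprintf("config line %d is not of the form key = value", i))
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  known <- c("tpm_min", "pseudocount", "quantile_rule", "quartile_scope",
             "week_policy")
  unknown <- setdiff(names(out), known)
  if (length(unknown))
    fmt_error(sprintf("unknown config key '%s'", unknown[1L]))
  out
}

#' Run the full attenuation-selection pipeline
#'
#' Sequences filter -> per-genotype contrasts -> DIF scores and quartile
#' thresholds -> per-week selection -> intersection -> overlap p-value ->
#' gene-wise scaling -> ortholog mapping and hallmark enrichment -> table
#' exports, and writes a JSON run manifest recording the configuration,
#' input digests and headline numbers.
#'
#' @param matrix_path,sample_sheet_path Expression inputs
#'   (see [read_expression_matrix()]).
#' @param gmt_path Optional GMT gene-set collection; when `NULL` or missing
#'   and `skip_enrichment_on_missing` is set, enrichment is skipped with a
#'   warning.
#' @param ortholog_path Optional ortholog map (required when enrichment
#'   runs).
#' @param out_dir Output directory.
#' @param tpm_min,pseudocount,quantile_type,quartile_scope,week_policy
#'   Tuning parameters; see the stage functions.
#' @param skip_enrichment_on_missing Skip (with a warning) rather than
#'   error when the GMT or ortholog map is absent.
#' @param id_map Optional id-to-symbol map forwarded to
#'   [read_expression_matrix()].
#' @param verbose Log stage summaries with `message()`.
#' @return Invisibly, a list with all intermediate and final results
#'   (`universe`, `contrasts`, `difs`, `selected` per week, `common`,
#'   `overlap`, `scaled`, `enrichment`, `manifest`).
#' @export
run_pipeline <- function(matrix_path, sample_sheet_path,
                         gmt_path = NULL, ortholog_path = NULL,
                         out_dir = "difatten_results",
                         tpm_min = 1, pseudocount = 1,
                         quantile_type = 7,
                         quartile_scope = c("per_week", "pooled"),
                         week_policy = c("per_week", "mean"),
                         skip_enrichment_on_missing = FALSE,
                         id_map = NULL, verbose = TRUE) {
  quartile_scope <- match.arg(quartile_scope)
  week_policy <- match.arg(week_policy)
  say <- function(...) if (verbose) message(sprintf(...))

  se <- read_expression_matrix(matrix_path, sample_sheet_path, id_map)
  filt <- filter_expressed(se, tpm_min)
  universe <- rownames(filt)
  say("universe: %d of %d genes with TPM > %g in >= 1 sample",
      length(universe), nrow(se), tpm_min)

  contrasts <- log2_contrast(filt, pseudocount)
  difs <- dif_scores(contrasts, quantile_type, quartile_scope)
  sel <- lapply(WEEKS, function(w) select_week(contrasts, difs, w))
  names(sel) <- paste0("wk", WEEKS)
  common <- common_genes(sel$wk2, sel$wk4)
  p_overlap <- overlap_pvalue(length(common), length(sel$wk2),
                              length(sel$wk4), length(universe))
  say("selected: %d (wk2), %d (wk4); common: %d; overlap p = %.3g",
      length(sel$wk2), length(sel$wk4), length(common), p_overlap)

  scaled <- if (length(common)) genewise_scale(filt, common) else
    matrix(numeric(0L), 0L, ncol(filt),
           dimnames = list(NULL, colnames(filt)))

  enrichment <- NULL
  gmt_ready <- !is.null(gmt_path) && file.exists(gmt_path)
  orth_ready <- !is.null(ortholog_path) && file.exists(ortholog_path)
  if (gmt_ready && orth_ready) {
    collection <- read_gmt(gmt_path)
    orth <- read_ortholog_map(ortholog_path)
    query <- map_orthologs(common, orth)
    universe_h <- map_orthologs(universe, orth)
    enrichment <- enrich_collection(query, collection, universe_h)
    say("enrichment: top set %s (score %.3f)", enrichment$set[1L],
        enrichment$score[1L])
  } else if (skip_enrichment_on_missing) {
    warning("GMT or ortholog map missing; enrichment skipped")
  } else {
    io_error("enrichment stage: GMT or ortholog map missing (use skip_enrichment_on_missing to proceed without)")
  }

  cw <- split(contrasts, contrasts$week)
  dt <- split(difs$table, difs$table$week)
  selected_genes <- data.frame(gene = common, stringsAsFactors = FALSE)
  for (w in WEEKS) {
    wchr <- as.character(w)
    idx <- match(common, cw[[wchr]]$gene)
    selected_genes[[paste0("L_WT_wk", w)]] <- cw[[wchr]]$L_WT[idx]
    selected_genes[[paste0("L_KO_wk", w)]] <- cw[[wchr]]$L_KO[idx]
    selected_genes[[paste0("DIF_wk", w)]] <-
      dt[[wchr]]$dif[match(common, dt[[wchr]]$gene)]
    selected_genes[[paste0("pass_wk", w)]] <- common %in% sel[[paste0("wk", w)]]
  }
  if (!length(common)) selected_genes <- selected_genes[0L, , drop = FALSE]

  overlap_tab <- data.frame(n_week2 = length(sel$wk2),
                            n_week4 = length(sel$wk4),
                            n_common = length(common),
                            universe_size = length(universe),
                            p_hypergeometric = p_overlap)
  node_attr <- export_dif_attributes(difs, common, week_policy)
  scaled_tab <- data.frame(gene = rownames(scaled), scaled,
                           check.names = FALSE, stringsAsFactors = FALSE)

  write_results(list(selected_genes = selected_genes,
                     overlap = overlap_tab,
                     enrichment = enrichment,
                     node_attributes = node_attr,
                     scaled_expression = scaled_tab), out_dir)

  inputs <- c(matrix = matrix_path, sample_sheet = sample_sheet_path,
              gmt = if (gmt_ready) gmt_path,
              orthologs = if (orth_ready) ortholog_path)
  manifest <- list(
    tool = "difatten",
    version = as.character(packageVersion("difatten")),
    config = list(tpm_min = tpm_min, pseudocount = pseudocount,
                  quantile_type = quantile_type,
                  quartile_scope = quartile_scope,
                  week_policy = week_policy),
    inputs = as.list(inputs),
    input_md5 = as.list(stats::setNames(tools::md5sum(unname(inputs)),
                                        names(inputs))),
    universe_size = length(universe),
    selected_week2 = length(sel$wk2),
    selected_week4 = length(sel$wk4),
    n_common = length(common),
    overlap_p = p_overlap,
    dif_q25 = as.list(difs$q25),
    top_enrichment = if (!is.null(enrichment))
      head(enrichment, 5L) else NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(matrix = se, filtered = filt, universe = universe,
                 contrasts = contrasts, difs = difs, selected = sel,
                 common = common, overlap_p = p_overlap, scaled = scaled,
                 enrichment = enrichment, manifest = manifest))
}
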