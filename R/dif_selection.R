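#' Filter to expressed genes
#'
#' Retains exactly the genes whose TPM exceeds `tpm_min` in at least one
#' sample (strict inequality).  The retained set is the gene universe for
#' every downstream statistic: contrasts, the DIF lower-quartile threshold,
#' the overlap test and the enrichment background.
#'
#' @param matrix A `SummarizedExperiment` with assay `"tpm"`.
#' @param tpm_min Expression floor (TPM); default 1.
#' @return The filtered `SummarizedExperiment`.
#' @export
filter_expressed <- function(matrix, tpm_min = 1) {
  mat <- SummarizedExperiment::assay(matrix, "tpm")
  keep <- rowSums(mat > tpm_min) > 0L
  if (!any(keep))
    val_error(sprintf("no expressed genes: no gene has TPM > %g in any sample",
                      tpm_min))
  matrix[keep, ]
}

# Average replicate samples into the 8 canonical design cells.
# Returns a gene x cell matrix with columns "<genotype>.<condition>.<week>".
.cell_means <- function(se) {
  cd <- SummarizedExperiment::colData(se)
  mat <- SummarizedExperiment::assay(se, "tpm")
  cells <- expand.grid(genotype = GENOTYPES, condition = CONDITIONS,
                       week = WEEKS, stringsAsFactors = FALSE)
  out <- matrix(NA_real_, nrow = nrow(mat), ncol = nrow(cells),
                dimnames = list(rownames(mat),
                                paste(cells$genotype, cells$condition,
                                      cells$week, sep = ".")))
  for (i in seq_len(nrow(cells))) {
    sel <- cd$genotype == cells$genotype[i] &
      cd$condition == cells$condition[i] & cd$week == cells$week[i]
    if (!any(sel))
      comp_error(sprintf("design cell %s/%s/%d has no sample",
                         cells$genotype[i], cells$condition[i],
                         cells$week[i]))
    out[, i] <- rowMeans(mat[, sel, drop = FALSE])
  }
  out
}

#' Per-genotype log2 DMM/sham contrasts
#'
#' For each gene, genotype and week computes
#' `L = log2((E_DMM + eps) / (E_sham + eps))` where `E_x` is the (cell-mean)
#' TPM under operation `x` and `eps` is a pseudocount.  With `pseudocount =
#' 0` every TPM entering a ratio must be strictly positive.
#'
#' @param matrix A filtered `SummarizedExperiment`.
#' @param pseudocount Pseudocount `eps` in TPM units; default 1.
#' @return A data frame with columns `gene`, `week`, `L_WT`, `L_KO`
#'   (two rows per gene, one per week).
#' @export
log2_contrast <- function(matrix, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      is.na(pseudocount) || pseudocount < 0)
    arg_error("pseudocount must be a single non-negative number")
  cm <- .cell_means(matrix)
  genes <- rownames(cm)
  res <- vector("list", length(WEEKS))
  for (w in seq_along(WEEKS)) {
    wk <- WEEKS[w]
    L <- matrix(NA_real_, nrow = length(genes), ncol = 2L,
                dimnames = list(NULL, GENOTYPES))
    for (gt in GENOTYPES) {
      e_sham <- cm[, paste(gt, "sham", wk, sep = ".")]
      e_dmm <- cm[, paste(gt, "DMM", wk, sep = ".")]
      if (pseudocount == 0) {
        z <- which(e_sham == 0 | e_dmm == 0)
        if (length(z))
          dom_error(sprintf(
            "pseudocount 0 with zero TPM for gene '%s' in cell %s/%s/%d",
            genes[z[1L]],
            gt, if (e_sham[z[1L]] == 0) "sham" else "DMM", wk))
      }
      L[, gt] <- log2((e_dmm + pseudocount) / (e_sham + pseudocount))
    }
    res[[w]] <- data.frame(gene = genes, week = wk,
                           L_WT = L[, "WT"], L_KO = L[, "KO"],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' DIF attenuation scores and lower-quartile thresholds
#'
#' The DIF score is `L_KO - L_WT`: the difference between the knockout's and
#' the wild-type's log2(DMM/sham) contrast.  Negative DIF marks
#' transcriptional suppression of the treatment response in the knockout.
#' The selection threshold `dif_q25` is the lower quartile of DIF over the
#' whole filtered universe, computed per week by default or pooled across
#' weeks.
#'
#' @param contrasts A contrast table from [log2_contrast()].
#' @param quantile_type Quantile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @param quartile_scope `"per_week"` (default) computes one threshold per
#'   week; `"pooled"` computes a single threshold over all weeks' DIF
#'   values.
#' @return A list of class `"dif_table"` with elements `table` (data frame
#'   `gene`, `week`, `dif`), `q25` (named numeric, one entry per week) and
#'   `quartile_scope`.
#' @export
dif_scores <- function(contrasts, quantile_type = 7,
                       quartile_scope = c("per_week", "pooled")) {
  quartile_scope <- match.arg(quartile_scope)
  need <- c("gene", "week", "L_WT", "L_KO")
  if (!all(need %in% colnames(contrasts)))
    arg_error("contrasts must have columns gene, week, L_WT, L_KO")
  if (any(is.na(contrasts$L_WT)) || any(is.na(contrasts$L_KO)))
    comp_error("contrast table has missing L values (genotype absent for some gene)")
  dif <- contrasts$L_KO - contrasts$L_WT
  tab <- data.frame(gene = contrasts$gene, week = contrasts$week, dif = dif,
                    stringsAsFactors = FALSE)
  weeks <- sort(unique(tab$week))
  q25 <- if (quartile_scope == "pooled") {
    stats::setNames(rep(quantile(dif, 0.25, type = quantile_type,
                                 names = FALSE), length(weeks)),
                    as.character(weeks))
  } else {
    vapply(weeks, function(w)
      quantile(tab$dif[tab$week == w], 0.25, type = quantile_type,
               names = FALSE), numeric(1L)) |>
      stats::setNames(as.character(weeks))
  }
  structure(list(table = tab, q25 = q25, quartile_scope = quartile_scope),
            class = "dif_table")
}

#' @export
print.dif_table <- function(x, ...) {
  cat(sprintf("DIF table: %d genes x %d week(s); quartile scope: %s\n",
              length(unique(x$table$gene)), length(x$q25),
              x$quartile_scope))
  for (w in names(x$q25))
    cat(sprintf("  week %s: dif_q25 = %.4f\n", w, x$q25[[w]]))
  invisible(x)
}

#' Select attenuated genes for one week
#'
#' Applies the three per-week requirements, all strict:
#' `L_KO < 0` (no positive DMM response in the knockout), `L_WT > 0`
#' (positive DMM response in the wild type) and `DIF < dif_q25(week)` (the
#' response loss is in the lower quartile of the universe).
#'
#' @param contrasts A contrast table from [log2_contrast()].
#' @param difs A `dif_table` from [dif_scores()].
#' @param week Week to select (2 or 4).
#' @return Character vector of selected gene symbols (universe order).
#' @export
select_week <- function(contrasts, difs, week) {
  if (!length(week) == 1L || !(week %in% unique(contrasts$week)))
    arg_error(sprintf("week %s is not in the design", paste(week, collapse = ",")))
  cw <- contrasts[contrasts$week == week, ]
  dw <- difs$table[difs$table$week == week, ]
  dif <- dw$dif[match(cw$gene, dw$gene)]
  if (any(is.na(dif)))
    comp_error("contrast and DIF tables cover different gene universes")
  thr <- difs$q25[[as.character(week)]]
  cw$gene[cw$L_KO < 0 & cw$L_WT > 0 & dif < thr]
}

#' Intersection of per-week selections
#'
#' The "common genes": those meeting all per-week requirements at both
#' timepoints.
#'
#' @param set_w2,set_w4 Character vectors of selected genes.
#' @return Their intersection (order of `set_w2`).
#' @export
common_genes <- function(set_w2, set_w4) {
  intersect(set_w2, set_w4)
}

#' Hypergeometric overlap significance
#'
#' Upper-tail probability `P(X >= k)` of observing at least the achieved
#' intersection between two gene sets of sizes `n1` and `n2` drawn without
#' replacement from a universe of `N` genes.
#'
#' @param k Observed intersection size.
#' @param n1,n2 Sizes of the two sets.
#' @param N Universe size.
#' @param log10p If `TRUE`, return `-log10(p)` computed on the log scale
#'   (stable for p-values far below double underflow).
#' @return The p-value in `(0, 1]`, or `-log10(p)` when `log10p = TRUE`.
#' @export
overlap_pvalue <- function(k, n1, n2, N, log10p = FALSE) {
  for (v in list(k = k, n1 = n1, n2 = n2, N = N)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != round(v))
      arg_error("k, n1, n2, N must be single non-negative integers")
  }
  if (n1 > N || n2 > N || k > min(n1, n2))
    arg_error(sprintf(
      "inconsistent counts: need 0 <= k <= min(n1, n2) <= N (k=%d n1=%d n2=%d N=%d)",
      k, n1, n2, N))
  if (log10p)
    return(-phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE,
                   log.p = TRUE) / log(10))
  p <- phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE)
  max(min(p, 1), .Machine$double.xmin)
}

#' Gene-wise z-score scaling
#'
#' Scales each requested gene's expression row to mean 0 and sample
#' standard deviation 1 across the samples (the convention behind gene-wise
#' scaled heat maps).  Constant rows cannot be scaled and are emitted as all
#' zeros with a warning.
#'
#' @param matrix A `SummarizedExperiment`.
#' @param genes Genes to scale; must all be present in `matrix`.
#' @return A genes x samples numeric matrix of z-scores.
#' @export
genewise_scale <- function(matrix, genes) {
  mat <- SummarizedExperiment::assay(matrix, "tpm")
  absent <- setdiff(genes, rownames(mat))
  if (length(absent))
    key_error(sprintf("gene '%s' absent from matrix", absent[1L]))
  sub <- mat[genes, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1L, sd)
  flat <- sdv == 0
  if (any(flat)) {
    warning(sprintf("%d constant row(s) emitted as zeros (no variance to scale)",
                    sum(flat)))
    sdv[flat] <- 1
  }
  out <- (sub - mu) / sdv
  out[flat, ] <- 0
  out
}

#' Export DIF node attributes
#'
#' Builds a `(gene, DIF)` attribute table for the selected genes, suitable
#' for import as node attributes by network-visualization software.
#'
#' @param difs A `dif_table` from [dif_scores()].
#' @param genes Genes to export (subset of the universe).
#' @param week_policy `"per_week"` emits one DIF column per week
#'   (`DIF_wk2`, `DIF_wk4`); `"mean"` emits their mean as a single `DIF`
#'   column.
#' @return A data frame, one row per gene.
#' @export
export_dif_attributes <- function(difs, genes,
                                  week_policy = c("per_week", "mean")) {
  week_policy <- match.arg(week_policy)
  tab <- difs$table
  absent <- setdiff(genes, unique(tab$gene))
  if (length(absent))
    key_error(sprintf("gene '%s' absent from DIF table", absent[1L]))
  weeks <- sort(unique(tab$week))
  cols <- lapply(weeks, function(w) {
    tw <- tab[tab$week == w, ]
    tw$dif[match(genes, tw$gene)]
  })
  if (week_policy == "per_week") {
    out <- data.frame(gene = genes, stringsAsFactors = FALSE)
    for (i in seq_along(weeks))
      out[[paste0("DIF_wk", weeks[i])]] <- cols[[i]]
  } else {
    out <- data.frame(gene = genes,
                      DIF = rowMeans(do.call(cbind, cols)),
                      stringsAsFactors = FALSE)
  }
  if (!length(genes)) out <- out[0L, , drop = FALSE]
  out
}
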