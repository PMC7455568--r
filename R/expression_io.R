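#' Read a TPM expression matrix with its sample sheet
#'
#' Loads a gene x sample TPM table (TSV, header row of sample ids, first
#' column of gene identifiers) together with a sample sheet assigning each
#' sample a genotype (`WT`/`KO`), a condition (`sham`/`DMM`) and a week
#' (2/4), and returns a validated
#' [SummarizedExperiment::SummarizedExperiment] with the TPM values in
#' assay `"tpm"` and the design in `colData()`.
#'
#' Duplicate gene symbols are collapsed to the single row with the largest
#' total TPM (ties broken by comparing the value vectors, so the result does
#' not depend on input row order).  Samples are reordered to follow the
#' sample sheet.  All eight design cells (genotype x condition x week) must
#' be present; replicated cells are accepted and are averaged later by
#' [log2_contrast()].
#'
#' @param matrix_path Path to the TPM TSV.
#' @param sample_sheet_path Path to the sample-sheet TSV with columns
#'   `sample_id`, `genotype`, `condition`, `week`.
#' @param id_map Optional two-column data frame (`id`, `symbol`) translating
#'   the matrix's row identifiers (e.g. Ensembl ids) to gene symbols before
#'   validation; rows whose id has no mapping are dropped with a message.
#' @return A `SummarizedExperiment`.
#' @export
read_expression_matrix <- function(matrix_path, sample_sheet_path,
                                   id_map = NULL) {
  if (!file.exists(matrix_path))
    io_error(sprintf("expression matrix file not found: %s", matrix_path))
  if (!file.exists(sample_sheet_path))
    io_error(sprintf("sample sheet file not found: %s", sample_sheet_path))

  raw <- read.delim(matrix_path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2L)
    fmt_error("expression matrix must have a gene column plus >=1 sample column")
  genes <- as.character(raw[[1L]])
  sample_ids <- colnames(raw)[-1L]

  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids),
                 dimnames = list(NULL, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad))
      val_error(sprintf(
        "non-numeric or missing TPM value '%s' at row %d, sample '%s'",
        col[bad[1L]], bad[1L], sample_ids[j]))
    neg <- which(num < 0)
    if (length(neg))
      val_error(sprintf("negative TPM value %g at row %d, sample '%s'",
                        num[neg[1L]], neg[1L], sample_ids[j]))
    if (any(!is.finite(num)))
      val_error(sprintf("non-finite TPM value at row %d, sample '%s'",
                        which(!is.finite(num))[1L], sample_ids[j]))
    vals[, j] <- num
  }

  if (!is.null(id_map)) {
    id_map <- as.data.frame(id_map, stringsAsFactors = FALSE)
    if (ncol(id_map) < 2L)
      arg_error("id_map must have two columns: id, symbol")
    lut <- stats::setNames(as.character(id_map[[2L]]),
                           as.character(id_map[[1L]]))
    mapped <- lut[genes]
    n_drop <- sum(is.na(mapped))
    if (n_drop > 0L)
      message(sprintf("id_map: dropping %d row(s) with unmapped identifiers",
                      n_drop))
    keep <- !is.na(mapped)
    genes <- unname(mapped[keep])
    vals <- vals[keep, , drop = FALSE]
  }

  # collapse duplicate symbols: keep the row with the largest total TPM;
  # break exact ties lexicographically on the value vector so permuting the
  # input rows cannot change the result
  if (anyDuplicated(genes)) {
    totals <- rowSums(vals)
    keys <- apply(format(vals, digits = 15L, trim = TRUE), 1L,
                  paste, collapse = "\r")
    ord <- order(genes, -totals, keys)
    keep <- ord[!duplicated(genes[ord])]
    keep <- sort(keep)
    genes <- genes[keep]
    vals <- vals[keep, , drop = FALSE]
  }
  rownames(vals) <- genes

  sheet <- read.delim(sample_sheet_path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "condition", "week")
  miss <- setdiff(need, colnames(sheet))
  if (length(miss))
    fmt_error(sprintf("sample sheet is missing column(s): %s",
                      paste(miss, collapse = ", ")))
  sheet$sample_id <- as.character(sheet$sample_id)

  only_sheet <- setdiff(sheet$sample_id, sample_ids)
  if (length(only_sheet))
    fmt_error(sprintf("sample '%s' is in the sample sheet but not the matrix",
                      only_sheet[1L]))
  only_mat <- setdiff(sample_ids, sheet$sample_id)
  if (length(only_mat))
    fmt_error(sprintf("sample '%s' is in the matrix but not the sample sheet",
                      only_mat[1L]))
  if (anyDuplicated(sheet$sample_id))
    fmt_error("duplicate sample_id in sample sheet")

  bad_gt <- setdiff(unique(sheet$genotype), GENOTYPES)
  if (length(bad_gt))
    meta_error(sprintf("unknown genotype token '%s' (expected WT or KO)",
                       bad_gt[1L]))
  bad_cn <- setdiff(unique(sheet$condition), CONDITIONS)
  if (length(bad_cn))
    meta_error(sprintf("unknown condition token '%s' (expected sham or DMM)",
                       bad_cn[1L]))
  week <- suppressWarnings(as.integer(sheet$week))
  if (any(is.na(week)) || length(setdiff(unique(week), WEEKS)))
    meta_error(sprintf("unknown week token '%s' (expected 2 or 4)",
                       sheet$week[which(!(week %in% WEEKS))[1L]]))

  # canonical design: every genotype x condition x week cell represented
  cells <- interaction(sheet$genotype, sheet$condition, week, sep = "/")
  wanted <- as.vector(outer(
    as.vector(outer(GENOTYPES, CONDITIONS, paste, sep = "/")),
    WEEKS, paste, sep = "/"))
  absent <- setdiff(wanted, as.character(cells))
  if (length(absent))
    meta_error(sprintf("design cell %s has no sample", absent[1L]))

  vals <- vals[, sheet$sample_id, drop = FALSE]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = vals),
    colData = S4Vectors::DataFrame(
      genotype = sheet$genotype,
      condition = sheet$condition,
      week = week,
      row.names = sheet$sample_id))
}

#' Write an expression matrix and sample sheet to TSV
#'
#' Inverse of [read_expression_matrix()]: writes the `"tpm"` assay as a
#' gene x sample TSV and the design as a sample-sheet TSV.
#'
#' @param se A `SummarizedExperiment` as produced by
#'   [read_expression_matrix()] or [simulate_study()].
#' @param matrix_path,sample_sheet_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression_matrix <- function(se, matrix_path, sample_sheet_path) {
  mat <- SummarizedExperiment::assay(se, "tpm")
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, matrix_path)
  cd <- SummarizedExperiment::colData(se)
  sheet <- data.frame(sample_id = rownames(cd),
                      genotype = cd$genotype,
                      condition = cd$condition,
                      week = cd$week,
                      stringsAsFactors = FALSE)
  .write_tsv(sheet, sample_sheet_path)
  invisible(c(matrix_path, sample_sheet_path))
}

#' Read a GMT gene-set collection
#'
#' Parses the MSigDB GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then one or more member symbols.  Members are
#' uppercased into a single (human) symbol namespace and deduplicated.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (set name -> member symbols).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) io_error(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  names(sets) <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      fmt_error(sprintf("GMT line %d has %d field(s); need name, description and >=1 member",
                        i, length(f)))
    members <- unique(toupper(f[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members))
      fmt_error(sprintf("GMT line %d ('%s') has no non-empty members", i, f[1L]))
    if (f[1L] %in% names(sets)[seq_len(i - 1L)])
      fmt_error(sprintf("duplicate gene-set name '%s' at GMT line %d", f[1L], i))
    names(sets)[i] <- f[1L]
    sets[[i]] <- members
  }
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param collection Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to `"na"`).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(collection))
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], descriptions[i], collection[[i]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a human/mouse ortholog map
#'
#' Two-column TSV of `(human_symbol, mouse_symbol)` pairs, optional header.
#' Human symbols are uppercased, mouse symbols capitalized (first letter
#' upper, rest lower — the MGI convention), and duplicate pairs dropped.
#' The map may be many-to-many.
#'
#' @param path Path to the TSV.
#' @return A data frame with columns `human` and `mouse`.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path))
    io_error(sprintf("ortholog map file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) fmt_error("ortholog map file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  f1 <- tolower(trimws(fields[[1L]]))
  if (length(f1) >= 2L && grepl("human", f1[1L]) && grepl("mouse", f1[2L]))
    start <- 2L
  human <- character(0L); mouse <- character(0L)
  for (i in seq(start, length(lines))) {
    f <- trimws(fields[[i]])
    if (length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L]))
      fmt_error(sprintf("ortholog map line %d is missing a field", i))
    human <- c(human, toupper(f[1L]))
    mouse <- c(mouse, .capitalize(f[2L]))
  }
  df <- unique(data.frame(human = human, mouse = mouse,
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

#' Write an ortholog map as TSV
#'
#' @param map Data frame with columns `human`, `mouse`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ortholog_map <- function(map, path) {
  .write_tsv(map[, c("human", "mouse")], path)
  invisible(path)
}

.capitalize <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), tolower(substring(x, 2L)))
}

.write_tsv <- function(df, path) {
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) io_error(sprintf("cannot write to '%s'", path))
  invisible(path)
}

#' Write the pipeline's result tables
#'
#' Writes the standard output files under `out_dir`:
#' \describe{
#'   \item{selected_genes.tsv}{one row per common selected gene: per-week
#'     contrasts (`L_WT`, `L_KO`), DIF scores and pass flags.}
#'   \item{overlap.tsv}{per-week selected-set sizes, intersection size,
#'     universe size and the hypergeometric overlap p-value.}
#'   \item{enrichment.tsv}{one row per gene set: `set,k,K,n,N,p,q,score`
#'     (may be absent when enrichment was skipped).}
#'   \item{node_attributes.tsv}{`(gene, DIF)` table for import into
#'     network-visualization software.}
#' }
#'
#' @param tables Named list with elements `selected_genes`, `overlap`,
#'   `node_attributes` and optionally `enrichment` and `scaled_expression`
#'   (data frames; `NULL` entries are skipped).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- tryCatch(dir.create(out_dir, recursive = TRUE),
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!isTRUE(ok) && !dir.exists(out_dir))
      io_error(sprintf("cannot create output directory '%s'", out_dir))
  }
  paths <- character(0L)
  for (nm in c("selected_genes", "overlap", "enrichment", "node_attributes",
               "scaled_expression")) {
    tab <- tables[[nm]]
    if (is.null(tab)) next
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    .write_tsv(as.data.frame(tab), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
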