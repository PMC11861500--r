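#' Read a gene-by-sample expression matrix from TSV
#'
#' The expected layout is genes in rows: a header row of sample IDs and a
#' first column of gene symbols. Duplicate gene rows are collapsed by their
#' mean with a warning; missing or non-numeric cells are errors (the
#' relative-rank pairing statistic is undefined on missing values).
#'
#' @param path path to a tab-separated file.
#' @param transpose set `TRUE` if the file stores samples in rows. Orientation
#'   is never auto-detected.
#' @return numeric matrix, genes x samples, with unique dimnames.
#' @export
read_expression <- function(path, transpose = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) {
    stop_pairsig(sprintf("'%s' is empty or has no data rows.", path),
                 "pairsig_format_error")
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  widths <- lengths(rows)
  # header may or may not carry a label for the gene column
  n_fields <- widths[1]
  if (length(header) == n_fields - 1) header <- c("gene", header)
  if (length(header) != n_fields) {
    stop_pairsig(sprintf(
      "'%s': header has %d sample fields but line 2 has %d value fields.",
      path, length(header) - 1, n_fields - 1), "pairsig_format_error")
  }
  bad <- which(widths != n_fields)
  if (length(bad)) {
    stop_pairsig(sprintf(
      "'%s': line %d has %d fields, expected %d.",
      path, bad[1] + 1L, widths[bad[1]], n_fields), "pairsig_format_error")
  }
  gene <- trimws(vapply(rows, `[[`, "", 1L))
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(rows, `[`, -1L))),
           nrow = length(rows), byrow = TRUE))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop_pairsig(sprintf(
      "'%s': non-numeric expression value at line %d, column %d.",
      path, idx[1] + 1L, idx[2] + 1L), "pairsig_parse_error")
  }
  samples <- trimws(header[-1])
  if (anyDuplicated(samples)) {
    stop_pairsig(sprintf("'%s': duplicated sample IDs in header.", path),
                 "pairsig_format_error")
  }
  rownames(vals) <- gene
  colnames(vals) <- samples
  if (anyDuplicated(gene)) {
    dup <- unique(gene[duplicated(gene)])
    warn(paste0("Collapsing duplicated gene rows by mean: ",
                paste(dup, collapse = ", ")))
    vals <- rowsum(vals, group = gene, reorder = FALSE) /
      as.vector(table(factor(gene, levels = unique(gene))))
  }
  if (transpose) vals <- t(vals)
  assert_expression_matrix(vals, "expression file")
  vals
}

#' Write an expression matrix as TSV (genes in rows)
#' @param expr numeric matrix, genes x samples.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  assert_expression_matrix(expr)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Requires columns `sample_id`, `os_time`, `os_event`, `age`, `gender`,
#' `tnm_stage`, `mutation`. Stage tokens I--IV are matched case-insensitively;
#' unrecognized tokens become missing values (kept, excluded from stage-using
#' models) with a warning.
#'
#' @param path path to a tab-separated file.
#' @return tibble with typed columns; `tnm_stage` is an ordered factor I < II
#'   < III < IV.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  required <- c("sample_id", "os_time", "os_event", "age", "gender",
                "tnm_stage", "mutation")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_pairsig(paste0("Clinical table is missing columns: ",
                        paste(missing_cols, collapse = ", ")),
                 "pairsig_format_error")
  }
  if (anyDuplicated(df$sample_id)) {
    stop_pairsig("Clinical table has duplicated sample IDs.",
                 "pairsig_validation_error")
  }
  if (any(!df$os_event %in% c(0, 1))) {
    stop_pairsig("`os_event` must be 0/1.", "pairsig_validation_error")
  }
  if (any(!is.finite(df$os_time)) || any(df$os_time <= 0)) {
    stop_pairsig("`os_time` must be positive.", "pairsig_validation_error")
  }
  stage <- toupper(trimws(as.character(df$tnm_stage)))
  ok <- stage %in% c("I", "II", "III", "IV")
  if (any(!ok)) {
    warn(sprintf("%d sample(s) have unrecognized TNM stage tokens; kept with missing stage.",
                 sum(!ok)))
    stage[!ok] <- NA
  }
  tibble::tibble(
    sample_id = as.character(df$sample_id),
    os_time = as.numeric(df$os_time),
    os_event = as.integer(df$os_event),
    age = as.numeric(df$age),
    gender = toupper(substr(as.character(df$gender), 1, 1)),
    tnm_stage = factor(stage, levels = c("I", "II", "III", "IV"),
                       ordered = TRUE),
    mutation = as.integer(df$mutation))
}

#' Write a clinical table as TSV
#' @param clinical tibble as returned by [read_clinical()].
#' @param path output path.
#' @export
write_clinical <- function(clinical, path) {
  out <- clinical
  out$tnm_stage <- as.character(out$tnm_stage)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields name, description,
#' then member genes. Duplicate genes within a set are dropped; duplicate set
#' names are an error.
#'
#' @param path path to a `.gmt` file.
#' @return named list of unique gene character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stop_pairsig(sprintf("'%s': line %d has fewer than 3 fields.",
                         path, short[1]), "pairsig_format_error")
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop_pairsig(sprintf("'%s': duplicated gene-set name '%s'.",
                         path, nm[duplicated(nm)][1]), "pairsig_format_error")
  }
  sets <- lapply(fields, function(f) unique(trimws(f[-(1:2)])))
  names(sets) <- nm
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of gene character vectors.
#' @param path output path.
#' @param description optional description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a gene-pair signature object
#'
#' A pair signature is an ordered list of gene pairs with Cox coefficients
#' and, optionally, a risk-score cutoff. The per-sample risk score is the
#' coefficient-weighted sum of the binary indicators
#' `expression(gene_a) > expression(gene_b)`.
#'
#' @param pairs data frame with columns `gene_a`, `gene_b`, `coefficient`.
#' @param cutoff risk-score cutoff separating high from low risk, or `NA`.
#' @return object of class `pair_signature` with elements `pairs` (tibble
#'   with `pair_label`, `gene_a`, `gene_b`, `coefficient`) and `cutoff`.
#' @export
pair_signature <- function(pairs, cutoff = NA_real_) {
  stopifnot(all(c("gene_a", "gene_b", "coefficient") %in% names(pairs)))
  pairs <- tibble::as_tibble(pairs)
  if (any(pairs$gene_a == pairs$gene_b)) {
    stop_pairsig("A signature pair cannot pair a gene with itself.",
                 "pairsig_validation_error")
  }
  pairs$pair_label <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
  if (anyDuplicated(pairs$pair_label)) {
    stop_pairsig("Signature pair labels must be unique.",
                 "pairsig_validation_error")
  }
  if (any(!is.finite(pairs$coefficient))) {
    stop_pairsig("Signature coefficients must be finite.",
                 "pairsig_validation_error")
  }
  structure(list(
    pairs = pairs[, c("pair_label", "gene_a", "gene_b", "coefficient")],
    cutoff = as.numeric(cutoff)), class = "pair_signature")
}

#' @export
print.pair_signature <- function(x, ...) {
  cat(sprintf("<pair_signature> %d pairs over %d genes; cutoff = %s\n",
              nrow(x$pairs), length(signature_genes(x)),
              ifelse(is.na(x$cutoff), "none", format(x$cutoff))))
  print(x$pairs, ...)
  invisible(x)
}

#' Genes referenced by a pair signature
#' @param signature a [pair_signature()].
#' @return character vector of unique gene symbols.
#' @export
signature_genes <- function(signature) {
  unique(c(signature$pairs$gene_a, signature$pairs$gene_b))
}

#' @export
tidy.pair_signature <- function(x, ...) x$pairs

#' @export
glance.pair_signature <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs),
                 n_genes = length(signature_genes(x)),
                 cutoff = x$cutoff)
}

#' Read / write a pair signature as TSV
#'
#' Serialization is a two-column TSV (`pair_label` as `"GENEA|GENEB"`,
#' `coefficient`) with the cutoff stored in a `# cutoff:` header comment.
#'
#' @param path file path.
#' @return [read_signature()] returns a `pair_signature`.
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  cutoff <- NA_real_
  cut_line <- grep("^#\\s*cutoff:", lines, value = TRUE)
  if (length(cut_line)) {
    cutoff <- as.numeric(sub("^#\\s*cutoff:\\s*", "", cut_line[1]))
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                          stringsAsFactors = FALSE)
  parts <- strsplit(df$pair_label, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    stop_pairsig(sprintf("'%s': malformed pair label '%s'.",
                         path, df$pair_label[bad[1]]), "pairsig_format_error")
  }
  pair_signature(
    tibble::tibble(gene_a = vapply(parts, `[[`, "", 1L),
                   gene_b = vapply(parts, `[[`, "", 2L),
                   coefficient = as.numeric(df$coefficient)),
    cutoff = cutoff)
}

#' @rdname read_signature
#' @param signature a [pair_signature()].
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "pair_signature"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(signature$cutoff)) {
    writeLines(sprintf("# cutoff: %.15g", signature$cutoff), con)
  }
  writeLines("pair_label\tcoefficient", con)
  writeLines(sprintf("%s\t%.15g", signature$pairs$pair_label,
                     signature$pairs$coefficient), con)
  invisible(path)
}

#' The published 26-pair LUSC prognostic signature
#'
#' Returns the published immune-related gene-pair signature for lung squamous
#' cell carcinoma that ships with the package: 26 ordered gene pairs with
#' their Cox coefficients and the published risk-score cutoff of -0.024.
#' Gene identifiers are HGNC symbols.
#'
#' @return a [pair_signature()] with 26 pairs.
#' @export
lusc_signature <- function() {
  path <- system.file("extdata", "lusc_irgsp26_signature.tsv",
                      package = "pairsig", mustWork = TRUE)
  read_signature(path)
}

#' Demographic and clinical characteristics of the emulated LUSC cohort
#'
#' Published contingency counts of the mutant/wild-type LUSC cohort the
#' synthetic generator emulates (gender, age, smoking, tumor location, TNM
#' stage by driver-mutation status), packaged as a fixture.
#'
#' @return tibble with columns `characteristic`, `level`, `ros1_mut`,
#'   `ros1_wt`.
#' @export
lusc_characteristics <- function() {
  path <- system.file("extdata", "tcga_lusc_characteristics.tsv",
                      package = "pairsig", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Read an undirected edge list from a two-column TSV
#' @param path file path; first two columns are node names, a header is
#'   detected when present.
#' @return tibble with columns `from`, `to`.
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          header = FALSE)
  if (ncol(df) < 2) {
    stop_pairsig(sprintf("'%s': edge list needs two columns.", path),
                 "pairsig_format_error")
  }
  if (identical(tolower(trimws(df[1, 1])), "from")) df <- df[-1, , drop = FALSE]
  tibble::tibble(from = as.character(df[[1]]), to = as.character(df[[2]]))
}

#' Write a simulated cohort and its fixtures to a directory
#'
#' Emits the standard on-disk formats consumed by the readers: expression TSV,
#' clinical TSV, gene sets as GMT, edge list TSV and the truth record as JSON.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @param fixtures optional result of [simulate_fixtures()].
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir, fixtures = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  truth <- cohort$truth
  truth$true_pairs <- as.data.frame(truth$true_pairs)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE)
  if (!is.null(fixtures)) {
    write_gmt(fixtures$gene_sets, file.path(dir, "gene_sets.gmt"))
    readr::write_tsv(fixtures$edges, file.path(dir, "edges.tsv"))
  }
  invisible(dir)
}
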