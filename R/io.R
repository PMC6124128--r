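# Readers/writers for the package's plain-text formats.  Missing markers
# accepted on read: empty cell or "NA" (R-flavoured CSV).

#' Read a trait table
#'
#' CSV with a header; first column must be `society_id`, all other
#' columns numeric.  Empty cells and `NA` are missing.
#'
#' @param path file path.
#' @return data.frame with character `society_id` and numeric variables.
#' @export
read_trait_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                 check.names = FALSE)
  if (names(df)[1] != "society_id") {
    stop("first column of a trait table must be 'society_id'")
  }
  if (anyDuplicated(df$society_id)) {
    dup <- unique(df$society_id[duplicated(df$society_id)])
    stop("duplicate society_id: ", paste(dup, collapse = ", "))
  }
  for (v in names(df)[-1]) {
    col <- df[[v]]
    if (is.numeric(col)) next
    parsed <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(parsed))
    if (length(bad)) {
      stop("non-numeric value in column '", v, "', row ", bad[1],
           " (society ", df$society_id[bad[1]], "): '", col[bad[1]], "'")
    }
    df[[v]] <- parsed
  }
  df$society_id <- as.character(df$society_id)
  df
}

#' Write a trait table
#'
#' @param traits data.frame as returned by [read_trait_table()].
#' @param path file path.
#' @export
write_trait_table <- function(traits, path) {
  write.csv(traits, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a taxonomy and clade table pair
#'
#' Taxonomy CSV columns: `tip_id`, `language_code`, `clade_id`, `path`
#' (pipe-delimited), `sample_level`.  Clade CSV columns: `clade_id`,
#' `relative_height`, `max_level`, `n_languages`.  Both are validated
#' against the hierarchy invariants.
#'
#' @param path_taxa,path_clades file paths.
#' @return list with `taxonomy` and `clades` data.frames.
#' @export
read_taxonomy <- function(path_taxa, path_clades) {
  taxonomy <- read.csv(path_taxa, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  clades <- read.csv(path_clades, stringsAsFactors = FALSE,
                     na.strings = c("", "NA"))
  val <- .validate_taxonomy(taxonomy, clades) # errors on violations
  val$.path <- NULL
  list(taxonomy = val, clades = clades)
}

#' Write/read a hierarchy as Newick
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]; the
#' round trip preserves topology and node heights to 1e-9.
#'
#' @param tree an [ape::phylo].
#' @param path file path.
#' @return `read_newick` returns an [ape::phylo].
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) NULL)
  if (is.null(tree)) stop("failed to parse Newick file: ", path)
  tree
}

#' Render a winnowing report to files
#'
#' Writes one TSV per stage table, a plain-text status trail, and a
#' machine-readable JSON twin, all with deterministic ordering.
#'
#' @param report a `cc_winnow_report`.
#' @param outdir output directory (created if absent).
#' @return invisible character vector of files written.
#' @export
render_report <- function(report, outdir) {
  stopifnot(inherits(report, "cc_winnow_report"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character(0)
  wtsv <- function(df, name, header_cols) {
    f <- file.path(outdir, name)
    if (is.null(df) || nrow(df) == 0) {
      df <- as.data.frame(setNames(rep(list(character(0)),
                                       length(header_cols)), header_cols))
    }
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, f)
  }
  wtsv(report$stage1$table, "stage1_univariate.tsv",
       c("y", "x", "n", "beta_u", "se_u", "t_u", "p_u", "logLik_u",
         "beta_c", "se_c", "t_c", "p_c", "logLik_c", "contribution",
         "significant_05", "significant_bonferroni", "error"))
  wtsv(report$stage2$table, "stage2_covariation.tsv",
       c("y", "x", "covariates", "n", "logLik_m1", "logLik_m2", "LR", "p",
         "significant", "note"))
  wtsv(report$stage3$lrt_table, "stage3_lrt.tsv",
       c("y", "x", "covariate_set", "covariates", "n", "logLik_m1",
         "logLik_m2", "LR", "p", "significant"))
  wtsv(report$stage3$aic_table, "stage3_aic.tsv",
       c("y", "x", "covariate_set", "covariates", "n", "AIC_cov",
         "AIC_par", "delta_AIC", "covariate_better", "equivalent"))

  trail_file <- file.path(outdir, "status_trail.txt")
  lines <- c("winnowing status trail", "----------------------")
  for (i in seq_len(nrow(report$trail))) {
    r <- report$trail[i, ]
    lines <- c(lines, sprintf(
      "%s: %s%s%s", r$variable, r$status,
      if (!is.na(r$stage_dropped))
        sprintf(" at stage %d (%s)", r$stage_dropped, r$dropped_by) else "",
      if (!is.na(r$verdict)) sprintf(" [verdict: %s]", r$verdict) else ""))
  }
  lines <- c(lines, "",
             paste("final retained:",
                   if (length(report$retained))
                     paste(report$retained, collapse = ", ") else "(none)"))
  writeLines(lines, trail_file)
  written <- c(written, trail_file)

  json_file <- file.path(outdir, "report.json")
  jsonlite::write_json(
    list(trail = report$trail, retained = report$retained,
         stage1 = report$stage1$table, stage2 = report$stage2$table,
         stage3_lrt = report$stage3$lrt_table,
         stage3_aic = report$stage3$aic_table,
         verdicts = report$stage3$verdicts),
    json_file, dataframe = "rows", na = "null", auto_unbox = TRUE,
    digits = NA)
  written <- c(written, json_file)
  invisible(written)
}
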