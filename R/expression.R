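#' Expression matrix container
#'
#' Patients-in-rows, genes-in-columns numeric matrix carrying a scale flag
#' (`"raw"` for nonnegative RSEM-style values, `"log2p1"` after
#' [log_transform()]).  Gene symbols must be unique.
#'
#' @param values numeric matrix with patient row names and gene column
#'   names.
#' @param scale `"raw"` or `"log2p1"`.
#' @return Object of class `expr_matrix` (a matrix with a `scale`
#'   attribute).
#' @export
expr_matrix <- function(values, scale = c("raw", "log2p1")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs patient row names and gene column names")
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene symbols: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyDuplicated(rownames(values)))
    stop("duplicate patient ids")
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (scale == "raw" && any(values < 0))
    stop("raw expression values must be nonnegative")
  structure(values, scale = scale,
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d patients x %d genes [%s]\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

expr_scale <- function(x) attr(x, "scale") %||% "raw"

#' Variance-compressing log transform of expression values
#'
#' Applies `log2(1 + x)` entry-wise.  Counts can legitimately be zero,
#' hence the shift by one before the logarithm.  Double transformation is
#' refused.
#'
#' @param matrix an [expr_matrix()] on the raw scale.
#' @return The transformed [expr_matrix()] with scale `"log2p1"`.
#' @export
log_transform <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (expr_scale(matrix) != "raw")
    stop("expression is already on the log2(1+x) scale; refusing to transform twice")
  expr_matrix(log2(1 + unclass(matrix)), scale = "log2p1")
}

#' Invert [log_transform()]
#' @param matrix an [expr_matrix()] on the `log2p1` scale.
#' @return The raw-scale [expr_matrix()].
#' @export
inverse_log_transform <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (expr_scale(matrix) != "log2p1")
    stop("expression is not on the log2(1+x) scale")
  expr_matrix(pmax(2^unclass(matrix) - 1, 0), scale = "raw")
}

#' Gene panel
#'
#' Ordered list of target gene symbols with a per-symbol flag marking the
#' intrinsic-subtype (PAM50-style) subset used by the subtype classifier.
#' The concrete panel is configuration, not code: it is loaded from a
#' two-column TSV (`symbol`, `pam50`).  A synthetic 138-gene placeholder
#' panel (symbols `G001..G138`, 50 flagged) ships with the package for
#' fixture-driven work.
#'
#' @param symbols character vector of unique gene symbols.
#' @param pam50 logical vector flagging the subtype subset.
#' @return Object of class `gene_panel` (a data frame).
#' @export
gene_panel <- function(symbols, pam50 = rep(FALSE, length(symbols))) {
  symbols <- as.character(symbols)
  if (length(symbols) == 0) stop("gene panel is empty")
  if (anyDuplicated(symbols))
    stop("duplicate symbols in panel: ",
         paste(unique(symbols[duplicated(symbols)]), collapse = ", "))
  stopifnot(length(pam50) == length(symbols))
  structure(data.frame(symbol = symbols, pam50 = as.logical(pam50),
                       stringsAsFactors = FALSE),
            class = c("gene_panel", "data.frame"))
}

#' @rdname gene_panel
#' @param path TSV file with columns `symbol` and `pam50` (0/1 or
#'   TRUE/FALSE).
#' @export
load_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("symbol", "pam50") %in% names(df)))
    stop("panel file must have columns 'symbol' and 'pam50'")
  gene_panel(df$symbol, as.logical(df$pam50))
}

#' @rdname gene_panel
#' @details `synthetic_panel()` returns the placeholder panel bundled at
#'   `inst/extdata/synthetic_panel.tsv`.
#' @export
synthetic_panel <- function() {
  load_panel(system.file("extdata", "synthetic_panel.tsv",
                         package = "histexpr", mustWork = TRUE))
}

#' Restrict an expression matrix to a gene panel
#'
#' Columns are restricted and re-ordered to the panel order.  Missing
#' symbols are an error; a case-only mismatch is resolved when the match
#' is unambiguous.
#'
#' @param matrix an [expr_matrix()].
#' @param panel a [gene_panel()].
#' @return The restricted [expr_matrix()], columns in panel order.
#' @export
select_panel <- function(matrix, panel) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(panel, "gene_panel"))
  have <- colnames(matrix)
  idx <- match(panel$symbol, have)
  if (anyNA(idx)) {
    # attempt unambiguous case-insensitive resolution
    lower_have <- tolower(have)
    for (i in which(is.na(idx))) {
      hit <- which(lower_have == tolower(panel$symbol[i]))
      if (length(hit) == 1) idx[i] <- hit
    }
  }
  if (anyNA(idx))
    stop("panel symbols missing from expression matrix: ",
         paste(panel$symbol[is.na(idx)], collapse = ", "))
  expr_matrix(unclass(matrix)[, idx, drop = FALSE], scale = expr_scale(matrix))
}

#' Read / write expression tables as TSV
#'
#' The on-disk format is a tab-separated table whose first column is
#' either `patient_id` (patients in rows) or `gene_symbol` (genes in
#' rows); orientation is auto-detected from that header token and the
#' matrix is returned patients-in-rows either way.  A `# scale:` comment
#' line records the scale flag.  Round-trips are lossless to at least six
#' significant digits.
#'
#' @param path file path.
#' @param matrix an [expr_matrix()].
#' @param orientation `"patients"` or `"genes"`: which dimension to place
#'   in rows when writing.
#' @return `load_expression_tsv()`: an [expr_matrix()];
#'   `write_expression_tsv()`: the path, invisibly.
#' @export
load_expression_tsv <- function(path) {
  first <- readLines(path, n = 5L)
  scale <- "raw"
  sc_line <- grep("^#\\s*scale:", first, value = TRUE)
  if (length(sc_line))
    scale <- trimws(sub("^#\\s*scale:", "", sc_line[1]))
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression table needs at least two columns")
  key <- names(df)[1]
  if (anyDuplicated(df[[1]]))
    stop("duplicate ", key, " entries: ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in expression table")
  rownames(m) <- df[[1]]
  if (identical(key, "gene_symbol")) m <- t(m)
  else if (!identical(key, "patient_id"))
    stop("first column must be 'patient_id' or 'gene_symbol', found '",
         key, "'")
  out <- expr_matrix(m, scale = scale)
  attr(out, "orientation") <- if (identical(key, "gene_symbol"))
    "genes" else "patients"
  out
}

#' @rdname load_expression_tsv
#' @export
write_expression_tsv <- function(matrix, path,
                                 orientation = c("patients", "genes")) {
  stopifnot(inherits(matrix, "expr_matrix"))
  orientation <- match.arg(orientation)
  m <- unclass(matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scale: %s", expr_scale(matrix)), con)
  if (orientation == "patients") {
    df <- data.frame(patient_id = rownames(m), m, check.names = FALSE)
  } else {
    df <- data.frame(gene_symbol = colnames(m), t(m), check.names = FALSE)
  }
  utils::write.table(format(df, digits = 9, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
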