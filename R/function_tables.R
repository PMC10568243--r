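# Gene-level functional evidence: phenotypes, cancer involvement,
# transcription-factor class, RNA-binding-protein function and tissue
# expression, merged into one index keyed by gene identifier. Lookups are
# total: unknown genes return an all-empty record, never an error, so joins
# over sparse tables cannot fail.

strip_gene_version <- function(x) sub("\\.\\d+$", "", x)

#' Load gene-level function tables
#'
#' Each table is a TSV with a `gene_id` column; any subset may be supplied.
#' Expected value columns: `phenotype` (phenotype table, one row per
#' gene-phenotype pair), `tf_class` (`TF` or `co-TF`), `rbp_function`; the
#' cancer table needs only `gene_id`; the expression table is wide
#' (`gene_id` x tissue columns, TPM-like non-negative values). Duplicate
#' gene rows union their phenotype/function lists. A trailing `.N` version
#' suffix on gene identifiers is ignored when joining.
#'
#' @param phenotypes,cancer,tf,rbp,expression File paths (or `NULL` to skip).
#' @return An object of class `gene_function_index`; query it with
#'   [gene_function()].
#' @export
load_function_tables <- function(phenotypes = NULL, cancer = NULL, tf = NULL,
                                 rbp = NULL, expression = NULL) {
  read_tab <- function(path, value_col = NULL) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"gene_id" %in% names(df)) {
      stop(sprintf("function table %s is missing the 'gene_id' column", path))
    }
    df$gene_id <- strip_gene_version(as.character(df$gene_id))
    if (!is.null(value_col) && !value_col %in% names(df)) {
      stop(sprintf("function table %s is missing the '%s' column", path, value_col))
    }
    df
  }
  idx <- structure(
    list(phenotypes = list(), cancer = character(), tf = character(),
         rbp = list(), expression = NULL, tissues = character()),
    class = "gene_function_index")
  if (!is.null(phenotypes)) {
    df <- read_tab(phenotypes, "phenotype")
    idx$phenotypes <- lapply(split(df$phenotype, df$gene_id),
                             function(p) sort(unique(p[nzchar(p)])))
  }
  if (!is.null(cancer)) {
    df <- read_tab(cancer)
    idx$cancer <- unique(df$gene_id)
  }
  if (!is.null(tf)) {
    df <- read_tab(tf, "tf_class")
    bad <- setdiff(unique(df$tf_class), c("TF", "co-TF"))
    if (length(bad) > 0L) {
      stop(sprintf("TF table %s has unknown tf_class value(s): %s", tf,
                   paste(bad, collapse = ", ")))
    }
    # a gene listed both as TF and co-TF keeps the stronger TF class
    cls <- vapply(split(df$tf_class, df$gene_id),
                  function(v) if ("TF" %in% v) "TF" else "co-TF", character(1))
    idx$tf <- cls
  }
  if (!is.null(rbp)) {
    df <- read_tab(rbp, "rbp_function")
    idx$rbp <- lapply(split(df$rbp_function, df$gene_id),
                      function(p) sort(unique(p[nzchar(p)])))
  }
  if (!is.null(expression)) {
    df <- read_tab(expression)
    tissues <- setdiff(names(df), "gene_id")
    for (t in tissues) df[[t]] <- as.numeric(df[[t]])
    df <- df[!duplicated(df$gene_id), , drop = FALSE]
    rownames(df) <- df$gene_id
    idx$expression <- df
    idx$tissues <- tissues
  }
  idx
}

#' Look up the functional record of a gene
#'
#' @param index A [load_function_tables()] index.
#' @param gene_id Gene identifier (a trailing `.N` version suffix is
#'   stripped before lookup).
#' @return A list with `gene_id`, `phenotypes` (character vector, possibly
#'   empty), `is_cancer_gene`, `tf_class` (`"TF"`, `"co-TF"` or `"none"`),
#'   `rbp_functions` and `expression` (named numeric vector over tissues).
#'   Unknown genes yield an all-empty record.
#' @export
gene_function <- function(index, gene_id) {
  stopifnot(inherits(index, "gene_function_index"))
  gid <- strip_gene_version(gene_id)
  expr <- if (!is.null(index$expression) && gid %in% rownames(index$expression)) {
    v <- as.numeric(index$expression[gid, index$tissues])
    stats::setNames(v, index$tissues)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  list(
    gene_id = gid,
    phenotypes = index$phenotypes[[gid]] %||% character(0),
    is_cancer_gene = gid %in% index$cancer,
    tf_class = if (gid %in% names(index$tf)) unname(index$tf[[gid]]) else "none",
    rbp_functions = index$rbp[[gid]] %||% character(0),
    expression = expr)
}

#' @export
print.gene_function_index <- function(x, ...) {
  cat(sprintf(paste0("<gene_function_index> phenotypes:%d gene(s), cancer:%d,",
                     " TF:%d, RBP:%d, expression:%d x %d tissue(s)\n"),
              length(x$phenotypes), length(x$cancer), length(x$tf),
              length(x$rbp),
              if (is.null(x$expression)) 0L else nrow(x$expression),
              length(x$tissues)))
  invisible(x)
}
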