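# On-disk GCT column-metadata field names (L1000 convention) <-> the
# column_meta names used internally.
.gct_col_fields <- c(
  pert_iname = "compound",
  pert_id    = "compound_id",
  cell_id    = "cell_line",
  pert_idose = "dose",
  pert_itime = "time",
  pert_type  = "pert_type"
)

.default_class_vocabulary <- c("statin", "antidepressant", "control",
                               "background", "other")

#' Construct a signature matrix
#'
#' A `signature_matrix` holds per-gene z-scores for a collection of
#' perturbations (one column per compound x cell line x dose x time), the
#' landmark flag for each gene (directly measured vs computationally
#' inferred), and per-column metadata.
#'
#' @param values Numeric matrix, genes x perturbations, with gene ids as
#'   rownames and perturbation ids as colnames.  Values are unitless
#'   z-scores and must be finite.
#' @param is_landmark Logical vector, one entry per gene; defaults to all
#'   `TRUE`.  At least one gene must be landmark.
#' @param column_meta Data frame with one row per column of `values`
#'   (matched by rownames or by order) providing `compound`,
#'   `compound_id`, `cell_line`, `dose`, `time` and `pert_type`.  Missing
#'   fields are filled with defaults.
#' @return An object of class `signature_matrix`.
#' @export
signature_matrix <- function(values, is_landmark = NULL, column_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and column ids as colnames")
  if (is.null(is_landmark)) is_landmark <- rep(TRUE, nrow(values))
  is_landmark <- as.logical(is_landmark)
  cm <- data.frame(
    compound = colnames(values), compound_id = colnames(values),
    cell_line = "UNKNOWN", dose = "", time = "", pert_type = "trt_cp",
    stringsAsFactors = FALSE, row.names = colnames(values)
  )
  if (!is.null(column_meta)) {
    column_meta <- as.data.frame(column_meta, stringsAsFactors = FALSE)
    if (nrow(column_meta) != ncol(values))
      stop("`column_meta` must have one row per column of `values`")
    if (!is.null(rownames(column_meta)) &&
        !all(rownames(column_meta) == as.character(seq_len(nrow(column_meta))))) {
      if (!setequal(rownames(column_meta), colnames(values)))
        stop("`column_meta` rownames do not cover every column id")
      column_meta <- column_meta[colnames(values), , drop = FALSE]
    }
    for (f in names(column_meta)) cm[[f]] <- column_meta[[f]]
    rownames(cm) <- colnames(values)
  }
  obj <- structure(
    list(values = values, gene_is_landmark = is_landmark, column_meta = cm),
    class = "signature_matrix"
  )
  validate_signature_matrix(obj)
  obj
}

#' Validate a signature matrix
#'
#' Checks the structural invariants: unique gene and column ids, finite
#' values, at least one landmark gene, and complete column metadata.
#'
#' @param x A `signature_matrix`.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_signature_matrix <- function(x) {
  stopifnot(inherits(x, "signature_matrix"))
  gid <- rownames(x$values); cid <- colnames(x$values)
  if (anyDuplicated(gid)) stop("duplicate gene ids in signature matrix")
  if (anyDuplicated(cid)) stop("duplicate column ids in signature matrix")
  if (!all(is.finite(x$values))) stop("signature values must be finite")
  if (length(x$gene_is_landmark) != length(gid) || anyNA(x$gene_is_landmark))
    stop("gene_is_landmark must be a complete logical vector over genes")
  if (!any(x$gene_is_landmark)) stop("at least one landmark gene required")
  if (!identical(rownames(x$column_meta), cid))
    stop("column_meta must cover every column id")
  invisible(x)
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("signature_matrix: %d genes (%d landmark) x %d perturbations\n",
              nrow(x$values), sum(x$gene_is_landmark), ncol(x$values)))
  cat("cell lines:", paste(unique(x$column_meta$cell_line), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.signature_matrix <- function(x) dim(x$values)

.fmt_num <- function(x) {
  # full round-trip precision for decimal text
  sprintf("%.17g", x)
}

#' Read a GCT 1.3 text file
#'
#' Parses the text GCT 1.3 format (version line `#1.3`, a dimension line,
#' then a header block carrying row and column metadata).  The landmark
#' flag is read from a row-metadata column (default `pr_is_lm`, values
#' 0/1); if that column is absent every gene is flagged landmark, with a
#' warning.
#'
#' @param path Path to a GCT 1.3 file.
#' @param landmark_field Name of the row-metadata column carrying the
#'   landmark flag.
#' @return A [signature_matrix()].
#' @export
read_gct <- function(path, landmark_field = "pr_is_lm") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3) stop("GCT parse error at line 1: truncated file")
  if (trimws(lines[1]) != "#1.3")
    stop("GCT parse error at line 1: expected version tag '#1.3', got '",
         lines[1], "'")
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2]), "[ \t]+")[[1]]))
  if (length(dims) != 4 || anyNA(dims))
    stop("GCT parse error at line 2: dimension line must hold 4 integers")
  nr <- dims[1]; nc <- dims[2]; nrm <- dims[3]; ncm <- dims[4]
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  if (length(body) != 1 + ncm + nr)
    stop(sprintf(
      "GCT parse error: dimension line promises %d data rows and %d column-metadata rows but body has %d lines",
      nr, ncm, length(body) - 1))
  header <- body[[1]]
  if (length(header) != 1 + nrm + nc)
    stop("GCT parse error at line 3: header width inconsistent with dimensions")
  row_meta_names <- if (nrm > 0) header[2:(1 + nrm)] else character(0)
  col_ids <- header[(2 + nrm):(1 + nrm + nc)]
  if (anyDuplicated(col_ids))
    stop("GCT parse error at line 3: duplicate column ids")
  cm <- data.frame(row.names = col_ids)
  for (i in seq_len(ncm)) {
    ln <- body[[1 + i]]
    if (length(ln) != 1 + nrm + nc)
      stop(sprintf("GCT parse error at line %d: column-metadata row width mismatch",
                   3 + i))
    field <- ln[1]
    nm <- if (field %in% names(.gct_col_fields)) .gct_col_fields[[field]] else field
    v <- ln[(2 + nrm):(1 + nrm + nc)]
    v[v == "-666"] <- ""   # GCT missing-value sentinel
    cm[[nm]] <- v
  }
  gene_ids <- character(nr)
  row_meta <- matrix("", nr, nrm)
  vals <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ln <- body[[1 + ncm + i]]
    if (length(ln) != 1 + nrm + nc)
      stop(sprintf("GCT parse error at line %d: data row width mismatch",
                   3 + ncm + i))
    gene_ids[i] <- ln[1]
    if (nrm > 0) row_meta[i, ] <- ln[2:(1 + nrm)]
    v <- suppressWarnings(as.numeric(ln[(2 + nrm):(1 + nrm + nc)]))
    if (anyNA(v))
      stop(sprintf("GCT parse error at line %d: non-numeric z-score",
                   3 + ncm + i))
    vals[i, ] <- v
  }
  if (anyDuplicated(gene_ids)) stop("GCT parse error: duplicate gene ids")
  if (landmark_field %in% row_meta_names) {
    lm <- row_meta[, match(landmark_field, row_meta_names)] %in% c("1", "TRUE")
  } else {
    warning("row-metadata column '", landmark_field,
            "' absent; treating all genes as landmark")
    lm <- rep(TRUE, nr)
  }
  dimnames(vals) <- list(gene_ids, col_ids)
  signature_matrix(vals, is_landmark = lm,
                   column_meta = if (ncol(cm) > 0) cm else NULL)
}

#' Write a signature matrix as GCT 1.3 text
#'
#' Values are written at full double precision so that
#' `read_gct(write_gct(m))` reproduces `m` exactly.
#'
#' @param x A [signature_matrix()].
#' @param path Output path.
#' @param landmark_field Row-metadata column name for the landmark flag.
#' @return `path`, invisibly.
#' @export
write_gct <- function(x, path, landmark_field = "pr_is_lm") {
  validate_signature_matrix(x)
  nr <- nrow(x$values); nc <- ncol(x$values)
  cm <- x$column_meta
  disk_fields <- names(.gct_col_fields)[match(names(cm), .gct_col_fields)]
  disk_fields[is.na(disk_fields)] <- names(cm)[is.na(disk_fields)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.3",
               paste(nr, nc, 1L, ncol(cm), sep = "\t")), con)
  writeLines(paste(c("id", landmark_field, colnames(x$values)),
                   collapse = "\t"), con)
  for (j in seq_along(cm)) {
    vals <- as.character(cm[[j]])
    vals[vals == ""] <- "-666"   # GCT missing-value sentinel; "" would be
                                 # dropped as a trailing empty field
    writeLines(paste(c(disk_fields[j], "na", vals), collapse = "\t"), con)
  }
  lm <- ifelse(x$gene_is_landmark, "1", "0")
  rows <- vapply(seq_len(nr), function(i) {
    paste(c(rownames(x$values)[i], lm[i], .fmt_num(x$values[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}

#' Read COJO-style summary statistics
#'
#' Expects a whitespace-delimited header file with columns
#' `SNP A1 A2 freq b se p N` (the `.ma` dialect).  Other dialects can be
#' mapped via `col_map`.  Rows violating the record invariants
#' (non-distinct or non-ACGT alleles, `se <= 0`, `p` outside (0, 1],
#' `freq` outside \[0, 1\]) are dropped with a message; the reported
#' p-value is compared against the two-sided normal tail of `b/se` and a
#' discrepancy is flagged (attribute `n_p_inconsistent`), not treated as
#' an error.
#'
#' @param path Path to the summary-statistics file.
#' @param col_map Optional named character vector mapping the canonical
#'   names (`SNP`, `A1`, ...) to the names used in the file.
#' @return A data frame of class `sumstats` with canonical columns.
#' @export
read_sumstats <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "", header = TRUE, stringsAsFactors = FALSE)
  required <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "N")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(df))
        names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required summary-statistics column(s): ",
         paste(missing, collapse = ", "))
  df <- df[required]
  sumstats(df)
}

#' Construct/validate a summary-statistics table
#'
#' @param df Data frame with columns `SNP A1 A2 freq b se p N`.
#' @return A validated `sumstats` data frame; invalid rows are dropped
#'   with a message.
#' @export
sumstats <- function(df) {
  df$SNP <- as.character(df$SNP)
  df$A1 <- toupper(as.character(df$A1)); df$A2 <- toupper(as.character(df$A2))
  for (cc in c("freq", "b", "se", "p")) df[[cc]] <- as.numeric(df[[cc]])
  df$N <- as.numeric(df$N)
  ok_allele <- df$A1 %in% c("A", "C", "G", "T") &
    df$A2 %in% c("A", "C", "G", "T") & df$A1 != df$A2
  ok <- ok_allele &
    is.finite(df$b) & is.finite(df$se) & df$se > 0 &
    is.finite(df$p) & df$p > 0 & df$p <= 1 &
    is.finite(df$freq) & df$freq >= 0 & df$freq <= 1
  n_bad <- sum(!ok)
  if (n_bad > 0)
    message(n_bad, " summary-statistics row(s) dropped (invalid alleles, se, p or freq)")
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) stop("no valid summary-statistics rows")
  # soft consistency check: p vs two-sided normal tail of b/se
  p_re <- 2 * pnorm(-abs(df$b / df$se))
  incons <- abs(log10(pmax(df$p, 1e-300)) - log10(pmax(p_re, 1e-300))) > 1
  attr(df, "n_p_inconsistent") <- sum(incons)
  rownames(df) <- NULL
  class(df) <- c("sumstats", "data.frame")
  df
}

#' Write summary statistics in the `.ma` dialect
#' @param df A `sumstats` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(df, path) {
  out <- as.data.frame(df)
  for (cc in c("freq", "b", "se", "p")) out[[cc]] <- .fmt_num(out[[cc]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' LD correlation matrix from genotype dosages
#'
#' Computes the signed Pearson correlation `r` between variants from a
#' variants x samples dosage matrix (values in \[0, 2\]).  `r`, not
#' `r^2`, is stored because the HEIDI covariance needs the sign.
#'
#' @param dosages Numeric matrix, variants x samples, rownames = variant
#'   ids.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
ld_from_dosages <- function(dosages) {
  if (!is.matrix(dosages) || ncol(dosages) < 2)
    stop("`dosages` must be a variants x samples matrix with >= 2 samples")
  v <- apply(dosages, 1, var)
  if (any(v <= 0)) {
    bad <- rownames(dosages)[v <= 0] %||% which(v <= 0)
    stop("monomorphic variant(s): ", paste(bad, collapse = ", "))
  }
  r <- cor(t(dosages))
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Validate an LD matrix
#' @param r Square numeric matrix.
#' @param tol Symmetry tolerance.
#' @return `r`, invisibly.
#' @export
validate_ld_matrix <- function(r, tol = 1e-8) {
  if (!is.matrix(r) || nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (max(abs(r - t(r))) > tol) stop("LD matrix not symmetric within ", tol)
  if (max(abs(diag(r) - 1)) > tol) stop("LD matrix diagonal must be 1")
  if (any(r > 1 + tol | r < -1 - tol)) stop("LD entries must lie in [-1, 1]")
  invisible(r)
}

#' Read/write a square LD matrix as TSV
#' @param path File path.
#' @return For `read_ld_matrix`, a validated matrix.
#' @export
read_ld_matrix <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  r <- as.matrix(df)
  colnames(r) <- colnames(df)
  validate_ld_matrix(r)
  r
}

#' @rdname read_ld_matrix
#' @param r Symmetric correlation matrix with unit diagonal.
#' @export
write_ld_matrix <- function(r, path) {
  validate_ld_matrix(r)
  out <- data.frame(id = rownames(r),
                    apply(r, 2, .fmt_num),
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a compound metadata table
#'
#' @param df Data frame with columns `compound_id`, `name`, and optional
#'   `atc_code`, `class_label`, `in_touchstone`.
#' @param vocabulary Allowed class labels.
#' @return Validated data frame of class `compound_table`.
#' @export
compound_table <- function(df, vocabulary = .default_class_vocabulary) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "name") %in% names(df)))
    stop("compound table needs `compound_id` and `name` columns")
  if (anyDuplicated(df$compound_id)) stop("duplicate compound_id")
  if (is.null(df$atc_code)) df$atc_code <- NA_character_
  if (is.null(df$class_label)) df$class_label <- "other"
  if (is.null(df$in_touchstone)) df$in_touchstone <- TRUE
  bad <- !is.na(df$class_label) & !(df$class_label %in% vocabulary)
  if (any(bad))
    stop("class_label outside declared vocabulary: ",
         paste(unique(df$class_label[bad]), collapse = ", "))
  df$in_touchstone <- as.logical(df$in_touchstone)
  class(df) <- c("compound_table", "data.frame")
  df
}

#' @rdname compound_table
#' @param path TSV file with the compound-table columns.
#' @export
read_compound_table <- function(path, vocabulary = .default_class_vocabulary) {
  compound_table(read.delim(path, stringsAsFactors = FALSE), vocabulary)
}

#' @rdname compound_table
#' @param x A `compound_table`.
#' @export
write_compound_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Construct a term graph
#'
#' A directed acyclic graph of ontology terms (edges point child ->
#' parent) plus direct gene -> term annotations.  Ancestor closure is
#' computed on demand by [materialize_annotations()].
#'
#' @param edges Data frame with columns `child`, `parent`.
#' @param annotations Data frame with columns `gene`, `term`.
#' @param term_names Optional named character vector of display names.
#' @return Object of class `term_graph`.
#' @export
term_graph <- function(edges, annotations, term_names = NULL) {
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      stringsAsFactors = FALSE)
  annotations <- data.frame(gene = as.character(annotations$gene),
                            term = as.character(annotations$term),
                            stringsAsFactors = FALSE)
  terms <- unique(c(edges$child, edges$parent, annotations$term))
  g <- igraph::graph_from_data_frame(edges[c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = terms))
  if (!igraph::is_dag(g)) stop("term graph contains a cycle")
  obj <- structure(list(edges = edges, annotations = annotations,
                        term_names = term_names, igraph = g, terms = terms),
                   class = "term_graph")
  obj
}

#' @rdname term_graph
#' @param edges_path,annotations_path,names_path TSV paths (`names_path`
#'   optional: columns `term`, `name`).
#' @export
read_term_graph <- function(edges_path, annotations_path, names_path = NULL) {
  edges <- read.delim(edges_path, stringsAsFactors = FALSE)
  ann <- read.delim(annotations_path, stringsAsFactors = FALSE)
  nm <- NULL
  if (!is.null(names_path)) {
    nd <- read.delim(names_path, stringsAsFactors = FALSE)
    nm <- setNames(nd$name, nd$term)
  }
  term_graph(edges, ann, nm)
}

#' @rdname term_graph
#' @param x A `term_graph`.
#' @param edges_path,annotations_path Output TSV paths.
#' @export
write_term_graph <- function(x, edges_path, annotations_path) {
  write.table(x$edges, edges_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(x$annotations, annotations_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(edges_path)
}

#' Read/write a dosage matrix (variants x samples) as TSV
#' @param path File path.
#' @export
read_dosages <- function(path) {
  as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
}

#' @rdname read_dosages
#' @param dosages Variants x samples numeric matrix.
#' @export
write_dosages <- function(dosages, path) {
  out <- data.frame(id = rownames(dosages), dosages, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
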