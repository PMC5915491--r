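#' @title Labeled-TSV readers and writers
#' @description All on-disk formats are plain tab-separated UTF-8 text with
#'   '.' as decimal separator and no quoting. A similarity matrix is written
#'   with a header row of labels (first header cell ignored) and a leading
#'   label column; associations and family tables are two-column edge lists.
#' @name io_formats
NULL

# Symmetry handling for input similarity matrices: deviations up to 1e-8 are
# treated as representation noise, up to 1e-6 are warned about; both are
# repaired by averaging with the transpose. Anything larger is an error.
.sym_warn_tol <- 1e-8
.sym_err_tol <- 1e-6

.validate_similarity <- function(m, what = "similarity matrix") {
  if (anyNA(m)) stop(what, " contains missing values", call. = FALSE)
  if (min(m) < 0) stop(what, " contains negative entries", call. = FALSE)
  asym <- max(abs(m - t(m)))
  if (asym > .sym_err_tol)
    stop(what, " is grossly asymmetric (max |M - t(M)| = ", format(asym), ")",
         call. = FALSE)
  if (asym > 0) {
    if (asym > .sym_warn_tol)
      warning(what, " slightly asymmetric (max deviation ", format(asym),
              "); symmetrized as (M + t(M))/2", call. = FALSE)
    m <- (m + t(m)) / 2
  }
  m
}

#' Read a labeled similarity matrix
#'
#' Reads a square similarity matrix from TSV: header row of entity labels
#' (first cell ignored), leading label column, numeric body. Row labels must
#' match the header labels in order. Mild asymmetry (at most 1e-6) is repaired
#' by averaging with the transpose; larger asymmetry is an error.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with identical row and column names, symmetric,
#'   entries non-negative.
#' @seealso [write_similarity_matrix()]
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("'", path, "': no matrix body found", call. = FALSE)
  labels <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  if (nrow(body) != ncol(body))
    stop("'", path, "': non-square matrix body (", nrow(body), " rows x ",
         ncol(body), " columns)", call. = FALSE)
  if (anyDuplicated(labels))
    stop("'", path, "': duplicate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  if (!identical(colnames(body), labels))
    stop("'", path, "': row labels do not match header labels", call. = FALSE)
  suppressWarnings(m <- vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) m <- matrix(m, 1L, ncol(body))
  if (anyNA(m))
    stop("'", path, "': non-numeric cell in matrix body", call. = FALSE)
  dimnames(m) <- list(labels, labels)
  .validate_similarity(m, paste0("'", path, "'"))
}

#' Write a labeled similarity (or any labeled square) matrix
#'
#' Writes values at full double precision (17 significant digits) so that a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param m A numeric matrix with row and column names.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_similarity_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  body <- apply(m, 2L, function(x) formatC(x, digits = 17, format = "g"))
  if (!is.matrix(body)) body <- matrix(body, nrow = nrow(m))
  lines <- c(paste(c("id", colnames(m)), collapse = "\t"),
             paste(rownames(m), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read known associations into a binary matrix
#'
#' Reads a two-column TSV edge list (miRNA id, disease id), one known pair per
#' line, and returns the binary association matrix over the supplied label
#' universes. Duplicate lines collapse to a single 1. An empty file yields an
#' all-zero matrix with a warning (legitimate for orphan scenarios).
#'
#' @param path Path to the edge-list TSV (no header).
#' @param mirna_labels Ordered miRNA identifiers (matrix rows).
#' @param disease_labels Ordered disease identifiers (matrix columns).
#' @return An integer 0/1 matrix, rows = miRNAs, columns = diseases.
#' @export
read_associations <- function(path, mirna_labels, disease_labels) {
  stopifnot(!anyDuplicated(mirna_labels), !anyDuplicated(disease_labels))
  a <- matrix(0L, length(mirna_labels), length(disease_labels),
              dimnames = list(mirna_labels, disease_labels))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("'", path, "': no association pairs; returning all-zero matrix",
            call. = FALSE)
    return(a)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop("'", path, "': line ", which(bad)[1L], " does not have two columns",
         call. = FALSE)
  mi <- vapply(parts, `[[`, character(1L), 1L)
  di <- vapply(parts, `[[`, character(1L), 2L)
  unknown_m <- setdiff(mi, mirna_labels)
  if (length(unknown_m))
    stop("'", path, "': unknown miRNA identifier(s): ",
         paste(utils::head(unknown_m, 5L), collapse = ", "), call. = FALSE)
  unknown_d <- setdiff(di, disease_labels)
  if (length(unknown_d))
    stop("'", path, "': unknown disease identifier(s): ",
         paste(utils::head(unknown_d, 5L), collapse = ", "), call. = FALSE)
  a[cbind(match(mi, mirna_labels), match(di, disease_labels))] <- 1L
  a
}

#' Write an association matrix as an edge list
#'
#' @param a Binary association matrix with dimnames.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_associations <- function(a, path) {
  stopifnot(is.matrix(a), !is.null(rownames(a)), !is.null(colnames(a)))
  idx <- which(a != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  writeLines(paste(rownames(a)[idx[, 1L]], colnames(a)[idx[, 2L]], sep = "\t"),
             path)
  invisible(path)
}

#' Read an miRNA family table
#'
#' Reads a two-column TSV (miRNA id, family id), no header. Repeated identical
#' lines collapse; an miRNA mapped to two different families is an error.
#'
#' @param path Path to the family TSV.
#' @return A named character vector mapping miRNA id to family id.
#' @export
read_family_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(stats::setNames(character(0L), character(0L)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop("'", path, "': line ", which(bad)[1L], " does not have two columns",
         call. = FALSE)
  mi <- vapply(parts, `[[`, character(1L), 1L)
  fam <- vapply(parts, `[[`, character(1L), 2L)
  keep <- !duplicated(paste(mi, fam, sep = "\r"))
  mi <- mi[keep]; fam <- fam[keep]
  if (anyDuplicated(mi)) {
    conf <- unique(mi[duplicated(mi)])
    stop("'", path, "': miRNA(s) mapped to more than one family: ",
         paste(conf, collapse = ", "), call. = FALSE)
  }
  stats::setNames(fam, mi)
}

#' Build the 0/1 family co-membership matrix
#'
#' `SMfam(i, j) = 1` when miRNAs i and j belong to the same family and
#' `i != j`; the diagonal is 0 and miRNAs without a family assignment get
#' all-zero rows.
#'
#' @param family Named character vector as returned by [read_family_table()];
#'   miRNAs absent from its names are treated as unassigned.
#' @param labels Ordered miRNA labels for the matrix.
#' @return A symmetric integer 0/1 matrix over `labels` with zero diagonal.
#' @export
family_matrix <- function(family, labels) {
  stopifnot(!anyDuplicated(labels))
  fam <- family[intersect(names(family), labels)]
  fm <- matrix(0L, length(labels), length(labels),
               dimnames = list(labels, labels))
  for (f in unique(fam)) {
    members <- names(fam)[fam == f]
    if (length(members) > 1L) fm[members, members] <- 1L
  }
  diag(fm) <- 0L
  fm
}

#' Write ranked association scores
#'
#' Long-format TSV with one row per (miRNA, disease) pair: score, rank of the
#' pair within its disease column (descending score, ties share the minimum
#' rank), and whether the pair was a known association in the training matrix.
#'
#' @param scores Score matrix, rows = miRNAs, columns = diseases, dimnames set.
#' @param assoc Binary association matrix aligned with `scores` (the training
#'   associations used to flag known pairs).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_scores <- function(scores, assoc, path) {
  stopifnot(identical(dim(scores), dim(assoc)),
            identical(dimnames(scores), dimnames(assoc)))
  ranks <- apply(scores, 2L, function(x) rank(-x, ties.method = "min"))
  df <- data.frame(
    mirna_id = rep(rownames(scores), times = ncol(scores)),
    disease_id = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores),
    rank_within_disease = as.integer(ranks),
    known_flag = as.integer(assoc != 0),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reconcile label universes across inputs
#'
#' Checks that the association matrix rows/columns match the similarity matrix
#' labels exactly (same sets, same order). Family-table miRNAs outside the
#' similarity universe are dropped with a warning; entities without known
#' associations are kept (required for orphan/new-entity prediction).
#'
#' @param sm miRNA similarity matrix.
#' @param sd Disease similarity matrix.
#' @param a Association matrix.
#' @param family Optional named family vector.
#' @return A list with the (possibly pruned) `family` vector, invisibly
#'   validated inputs unchanged.
#' @export
reconcile_labels <- function(sm, sd, a, family = NULL) {
  if (!identical(rownames(a), rownames(sm)))
    stop("association matrix rows do not match miRNA similarity labels",
         call. = FALSE)
  if (!identical(colnames(a), rownames(sd)))
    stop("association matrix columns do not match disease similarity labels",
         call. = FALSE)
  if (!is.null(family)) {
    extra <- setdiff(names(family), rownames(sm))
    if (length(extra)) {
      warning(length(extra), " family-table miRNA(s) absent from the ",
              "similarity matrix were dropped", call. = FALSE)
      family <- family[setdiff(names(family), extra)]
    }
  }
  list(sm = sm, sd = sd, a = a, family = family)
}
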