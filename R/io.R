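# Readers/writers: 10x-style MatrixMarket triplets with feature/barcode
# lists, delimited genes x cells tables, and a versioned JSON container
# for fitted models.

.FIT_SCHEMA <- 1L

#' Read a count matrix
#'
#' MatrixMarket input expects \code{matrix.mtx} plus companion
#' \code{features.tsv} (or \code{genes.tsv}) and \code{barcodes.tsv} in
#' the same directory (a path to either the directory or the .mtx file is
#' accepted); 1-based on-disk coordinates are handled by the reader.
#' Orientation is genes x cells; when the identifier files imply the
#' transpose, the matrix is flipped with a message. Delimited input is a
#' genes x cells table with header row and gene identifiers in the first
#' column.
#'
#' @param path directory, .mtx file, or delimited text file.
#' @param format "auto" (from the path), "mtx" or "tsv".
#' @return dense validated count matrix with identifiers.
#' @export
readCounts <- function(path, format = c("auto", "mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "mtx") {
    dirp <- if (dir.exists(path)) path else dirname(path)
    mtx <- if (dir.exists(path)) file.path(path, "matrix.mtx") else path
    if (!file.exists(mtx)) stop("MatrixMarket file not found: ", mtx)
    M <- as.matrix(Matrix::readMM(mtx))
    featFile <- Filter(file.exists,
      file.path(dirp, c("features.tsv", "genes.tsv")))
    bcFile <- file.path(dirp, "barcodes.tsv")
    genes <- if (length(featFile))
      read.delim(featFile[1], header = FALSE)[, 1] else NULL
    cells <- if (file.exists(bcFile))
      read.delim(bcFile, header = FALSE)[, 1] else NULL
    if (!is.null(genes) && !is.null(cells)) {
      if (nrow(M) == length(cells) && ncol(M) == length(genes) &&
          length(genes) != length(cells)) {
        message("matrix orientation flipped to genes x cells")
        M <- t(M)
      }
      if (nrow(M) != length(genes) || ncol(M) != length(cells))
        stop("identifier files do not match matrix dimensions")
      dimnames(M) <- list(genes, cells)
    } else {
      message("no identifier files; assuming genes x cells")
    }
    return(validateCounts(M))
  }
  tab <- read.delim(path, header = TRUE, row.names = 1, check.names = FALSE)
  validateCounts(as.matrix(tab))
}

#' Write a count matrix as MatrixMarket triplets
#'
#' Writes \code{matrix.mtx}, \code{features.tsv} and \code{barcodes.tsv}
#' under \code{dir} (created if needed).
#'
#' @param Y count matrix, genes x cells.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeCounts <- function(Y, dir) {
  Y <- validateCounts(Y)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(Matrix::Matrix(Y, sparse = TRUE), "generalMatrix"),
    file.path(dir, "matrix.mtx"))
  writeLines(rownames(Y), file.path(dir, "features.tsv"))
  writeLines(colnames(Y), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Persist and restore a fitted model
#'
#' Lossless JSON round trip of every \code{\link{BilinearFit}} field plus
#' the gene and cell identifiers, under a versioned schema. Numbers are
#' written at full precision.
#'
#' @param fit a \code{\link{BilinearFit}}.
#' @param path output .json path.
#' @return \code{writeFit}: the path, invisibly. \code{readFit}: the
#'   restored \code{\link{BilinearFit}}.
#' @export
writeFit <- function(fit, path) {
  obj <- list(
    schema_version = .FIT_SCHEMA,
    alpha = unname(fit@alpha), beta = unname(fit@beta),
    U = unname(fit@U), sigma = fit@sigma, V = unname(fit@V),
    tau = fit@tau, trace = fit@trace, converged = fit@converged,
    projected = fit@projected,
    gene_ids = names(fit@alpha), cell_ids = names(fit@beta))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(path)
}

#' @rdname writeFit
#' @export
readFit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("schema_version", "alpha", "beta", "U", "sigma", "V",
    "tau", "converged", "projected")
  missing <- setdiff(required, names(obj))
  if (length(missing))
    stop("fit schema error: missing field(s) ", paste(missing, collapse = ", "))
  if (obj$schema_version != .FIT_SCHEMA)
    stop("fit schema version ", obj$schema_version, " not supported")
  M <- length(obj$sigma)
  asMat <- function(x, nr) {
    if (is.null(x) || length(x) == 0) return(matrix(0, nr, 0))
    matrix(as.numeric(x), nr, M)
  }
  U <- if (is.matrix(obj$U)) obj$U else asMat(obj$U, length(obj$alpha))
  V <- if (is.matrix(obj$V)) obj$V else asMat(obj$V, length(obj$beta))
  fit <- .newFit(obj$alpha, obj$beta, U, as.numeric(obj$sigma), V,
    tau = obj$tau, trace = as.numeric(obj$trace),
    converged = obj$converged, projected = obj$projected)
  if (!is.null(obj$gene_ids)) {
    names(fit@alpha) <- obj$gene_ids
    rownames(fit@U) <- obj$gene_ids
  }
  if (!is.null(obj$cell_ids)) {
    names(fit@beta) <- obj$cell_ids
    rownames(fit@V) <- obj$cell_ids
  }
  fit
}

#' Export factor scores or loadings as delimited text
#'
#' Writes a table with one row per cell (scores) or gene (loadings),
#' identifiers in the first column, one column per factor.
#'
#' @param fit a \code{\link{BilinearFit}}.
#' @param path output .tsv path.
#' @param what "scores" (V), "scaled" (V Sigma) or "loadings" (U).
#' @return the path, invisibly.
#' @export
exportScores <- function(fit, path, what = c("scores", "scaled", "loadings")) {
  what <- match.arg(what)
  A <- switch(what, scores = factorScores(fit),
    scaled = scaledScores(fit), loadings = factorLoadings(fit))
  ids <- if (what == "loadings") names(fit@alpha) else names(fit@beta)
  df <- if (ncol(A) > 0) data.frame(id = ids, A, check.names = FALSE) else
    data.frame(id = ids)
  colnames(df) <- c("id",
    if (ncol(A) > 0) paste0("factor", seq_len(ncol(A))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readScoresTSV <- function(path) {
  tab <- read.delim(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}
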