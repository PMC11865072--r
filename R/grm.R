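#' Genomic relationship matrix container
#'
#' Wraps an `N x N` genomic relationship matrix (GRM) together with the
#' individual identifiers labelling its rows and columns, and validates the
#' structural assumptions the design machinery relies on: symmetry,
#' strictly positive diagonal, unique identifiers and nonsingularity
#' (smallest eigenvalue above `eig_floor`).
#'
#' @param G numeric matrix of relationship coefficients, `N x N`.
#' @param ids character vector of `N` unique individual labels. Defaults to
#'   the dimnames of `G`, or `"id1".."idN"` when `G` carries none.
#' @param eig_floor smallest admissible eigenvalue of `G`; below this the
#'   matrix is treated as singular. Default `1e-8`.
#' @param blend optional regularization weight `eps` in `[0, 1]`; when
#'   positive, `G` is replaced by `(1 - eps) * G + eps * I` before
#'   validation. Default `0` (off). Useful for marker-derived GRMs that are
#'   numerically rank-deficient.
#'
#' @return An object of class `"grm"`: a list with elements `ids`, `G` and
#'   `N`.
#' @examples
#' g <- grm(diag(3) + 0.1)
#' g$N
#' @export
grm <- function(G, ids = NULL, eig_floor = 1e-8, blend = 0) {
  G <- as.matrix(G)
  if (!is.numeric(G) || nrow(G) != ncol(G)) {
    stop("'G' must be a square numeric matrix", call. = FALSE)
  }
  N <- nrow(G)
  if (is.null(ids)) {
    ids <- rownames(G)
    if (is.null(ids)) ids <- paste0("id", seq_len(N))
  }
  ids <- as.character(ids)
  if (length(ids) != N) stop("'ids' must have one label per row of 'G'", call. = FALSE)
  if (anyDuplicated(ids)) stop("individual ids must be unique", call. = FALSE)
  if (blend < 0 || blend > 1) stop("'blend' must lie in [0, 1]", call. = FALSE)
  if (blend > 0) G <- (1 - blend) * G + blend * diag(N)

  asym <- max(abs(G - t(G)))
  if (asym > 1e-10) {
    stop(sprintf("'G' is not symmetric (max |G - t(G)| = %.3e)", asym), call. = FALSE)
  }
  G <- (G + t(G)) / 2
  if (any(diag(G) <= 0)) {
    stop("diagonal entries of 'G' must be strictly positive", call. = FALSE)
  }
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= eig_floor) {
    stop(sprintf(
      "'G' is singular or near-singular (smallest eigenvalue %.3e <= floor %.3e); consider blend > 0",
      ev_min, eig_floor
    ), call. = FALSE)
  }
  dimnames(G) <- list(ids, ids)
  structure(list(ids = ids, G = G, N = N), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("Genomic relationship matrix: %d individuals\n", x$N))
  cat(sprintf(
    "  diag mean %.3f, off-diag mean %.3f\n",
    mean(diag(x$G)), mean(x$G[upper.tri(x$G)])
  ))
  invisible(x)
}

#' Read a GRM from a dense CSV file
#'
#' Expects the dialect written by [write_grm()]: the first row holds
#' individual ids (header), the first column repeats them as row labels, and
#' the remaining cells are the relationship coefficients in full double
#' precision.
#'
#' @param path path to the CSV file.
#' @inheritParams grm
#' @return A `"grm"` object.
#' @export
read_grm <- function(path, eig_floor = 1e-8, blend = 0) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  G <- as.matrix(df)
  if (!identical(rownames(G), colnames(G))) {
    stop("row and column ids in the GRM file disagree", call. = FALSE)
  }
  grm(G, ids = rownames(G), eig_floor = eig_floor, blend = blend)
}

#' Write a GRM to a dense CSV file
#'
#' @param x a `"grm"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grm <- function(x, path) {
  stopifnot(inherits(x, "grm"))
  header <- paste(c("", x$ids), collapse = ",")
  rows <- vapply(seq_len(x$N), function(i) {
    paste(c(x$ids[i], formatC(x$G[i, ], format = "g", digits = 17)), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
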