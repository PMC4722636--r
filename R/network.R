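#' Bipartite drug-target interaction network
#'
#' Container for a binary interaction matrix over a set of drugs and a set
#' of targets.  The matrix is stored with a fixed orientation: rows are
#' targets, columns are drugs.  All kernel matrices and dual-coefficient
#' matrices in the package follow the same convention, so that the
#' column-major vectorization `as.vector(Y)` agrees with [pair_index()].
#'
#' @param Y numeric matrix of 0/1 entries, targets in rows, drugs in
#'   columns.  Dimnames, when present, must agree with `targets`/`drugs`.
#' @param drugs character vector of unique drug identifiers (column order).
#' @param targets character vector of unique target identifiers (row order).
#' @return an object of class `dti_network`: a list with elements `Y`
#'   (targets x drugs 0/1 matrix with dimnames), `drugs`, `targets`,
#'   `n_drugs`, `n_targets` and `n_pairs`.
#' @examples
#' net <- dti_network(matrix(c(1, 0, 0, 1), 2), c("d1", "d2"), c("t1", "t2"))
#' net$n_pairs
#' @export
dti_network <- function(Y, drugs = colnames(Y), targets = rownames(Y)) {
  Y <- as.matrix(Y)
  if (is.null(drugs) || is.null(targets))
    stop("drug and target identifiers are required (arguments or dimnames)")
  drugs <- as.character(drugs)
  targets <- as.character(targets)
  .check_ids(drugs, "drug")
  .check_ids(targets, "target")
  if (nrow(Y) != length(targets) || ncol(Y) != length(drugs))
    stop("Y must be ", length(targets), " targets x ", length(drugs),
         " drugs; got ", nrow(Y), " x ", ncol(Y))
  bad <- which(!(Y %in% c(0, 1)))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(Y))
    stop("non-binary interaction value ", Y[bad[1L]], " at target '",
         targets[i[1L]], "', drug '", drugs[i[2L]], "'")
  }
  storage.mode(Y) <- "double"
  dimnames(Y) <- list(targets, drugs)
  structure(
    list(Y = Y, drugs = drugs, targets = targets,
         n_drugs = length(drugs), n_targets = length(targets),
         n_pairs = length(drugs) * length(targets)),
    class = "dti_network")
}

.check_ids <- function(ids, side) {
  if (length(ids) == 0L) stop("empty ", side, " identifier set")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", side, " identifiers: ", paste(dup, collapse = ", "))
  invisible(ids)
}

#' @export
print.dti_network <- function(x, ...) {
  cat("Bipartite drug-target network\n")
  cat("  drugs:   ", x$n_drugs, "\n")
  cat("  targets: ", x$n_targets, "\n")
  cat(sprintf("  known interactions: %d of %d pairs (%.2f%%)\n",
              sum(x$Y), x$n_pairs, 100 * sum(x$Y) / x$n_pairs))
  invisible(x)
}

#' Read an interaction table
#'
#' Reads a tab-separated adjacency table in the layout of the Yamanishi
#' gold-standard files: header row of drug identifiers, first column of
#' target identifiers, binary cells.
#'
#' @param path path to a TSV file.
#' @return a [dti_network()].
#' @export
read_interaction_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, row.names = NULL,
                           colClasses = "character", quote = "")
  targets <- tab[[1L]]
  drugs <- colnames(tab)[-1L]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) | !(num %in% c(0, 1)))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(num))
    stop("non-binary cell '", vals[bad[1L]], "' at target '", targets[i[1L]],
         "', drug '", drugs[i[2L]], "' in ", path)
  }
  dti_network(num, drugs = drugs, targets = targets)
}

#' Write an interaction or score table
#'
#' Writes a targets x drugs matrix in the same labeled TSV layout that
#' [read_interaction_table()] reads.  Used both for binary interaction
#' matrices and for real-valued score matrices.
#'
#' @param x a `dti_network` or a matrix with dimnames.
#' @param path output file path.
#' @export
write_interaction_table <- function(x, path) {
  M <- if (inherits(x, "dti_network")) x$Y else as.matrix(x)
  df <- data.frame(id = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# real-valued labeled TSV matrix (score/coefficient tables)
.read_labeled_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, row.names = NULL, quote = "")
  M <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- as.character(tab[[1L]])
  M
}

#' Linear pair index for drug-target pairs
#'
#' Maps a (drug, target) position pair to the 1-based linear index of the
#' column-major vectorization of the targets x drugs matrix, i.e.
#' `pair_index(d, t, n_t)` is the position of cell `(t, d)` in
#' `as.vector(Y)`.  `pair_from_index()` is the inverse.
#'
#' @param drug_pos,target_pos 1-based positions (vectorized).
#' @param n_targets number of targets (rows).
#' @param index 1-based linear pair index.
#' @return `pair_index`: integer vector of linear indices;
#'   `pair_from_index`: data.frame with columns `drug_pos`, `target_pos`.
#' @examples
#' pair_index(1, 1, n_targets = 5)  # 1
#' pair_index(2, 1, n_targets = 5)  # 6
#' @export
pair_index <- function(drug_pos, target_pos, n_targets) {
  if (any(drug_pos < 1L) || any(target_pos < 1L) || any(target_pos > n_targets))
    stop("pair position out of range")
  as.integer((drug_pos - 1L) * n_targets + target_pos)
}

#' @rdname pair_index
#' @export
pair_from_index <- function(index, n_targets) {
  index <- as.integer(index)
  if (any(index < 1L)) stop("pair index out of range")
  data.frame(drug_pos = (index - 1L) %/% n_targets + 1L,
             target_pos = (index - 1L) %% n_targets + 1L)
}

#' Read a kernel (similarity) matrix
#'
#' Reads a square labeled TSV similarity table, symmetrizes it as
#' `(K + t(K))/2`, and reorders rows and columns to a reference identifier
#' ordering.  Entries of `ids` missing from the table are an error; extra
#' table entries are dropped.
#'
#' @param path path to a TSV file (first column and header are identifiers).
#' @param ids character vector giving the authoritative entity ordering
#'   (e.g. `net$drugs`).  Default `NULL` keeps the file ordering.
#' @return a symmetric numeric matrix with dimnames.
#' @export
read_kernel_matrix <- function(path, ids = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, row.names = NULL, quote = "")
  rn <- as.character(tab[[1L]])
  K <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(K) <- "double"
  rownames(K) <- rn
  if (nrow(K) != ncol(K))
    stop("kernel table in ", path, " is not square: ", nrow(K), " x ", ncol(K))
  if (!setequal(rn, colnames(K)))
    stop("row and column identifier sets differ in ", path)
  K <- K[, rn, drop = FALSE]          # align columns to row order
  K <- (K + t(K)) / 2
  if (!is.null(ids)) {
    ids <- as.character(ids)
    missing <- setdiff(ids, rn)
    if (length(missing))
      stop("kernel file ", path, " is missing entities: ",
           paste(missing, collapse = ", "))
    K <- K[ids, ids, drop = FALSE]
  }
  K
}

#' @rdname read_kernel_matrix
#' @param K square symmetric matrix with dimnames.
#' @export
write_kernel_matrix <- function(K, path) {
  write_interaction_table(K, path)
}

#' Validate a kernel matrix
#'
#' Reports the symmetry error, eigenvalue range and diagonal range of a
#' square similarity matrix, and flags matrices that are not positive
#' semidefinite within a tolerance.  Report-only: no error is raised.
#'
#' @param K square numeric matrix.
#' @param tol nonnegative tolerance on the smallest eigenvalue.
#' @return a list of class `kernel_validation` with elements `n`,
#'   `max_asymmetry`, `min_eigenvalue`, `max_eigenvalue`, `diag_range`, and
#'   logical `psd` (`TRUE` when `min_eigenvalue >= -tol`).
#' @export
validate_kernel <- function(K, tol = 1e-8) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("kernel matrix must be square")
  asym <- max(abs(K - t(K)))
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  structure(
    list(n = nrow(K), max_asymmetry = asym,
         min_eigenvalue = min(ev), max_eigenvalue = max(ev),
         diag_range = range(diag(K)), psd = min(ev) >= -tol, tol = tol),
    class = "kernel_validation")
}

#' @export
print.kernel_validation <- function(x, ...) {
  cat(sprintf("Kernel validation (n = %d)\n", x$n))
  cat(sprintf("  max asymmetry : %.3g\n", x$max_asymmetry))
  cat(sprintf("  eigenvalues   : [%.6g, %.6g]\n",
              x$min_eigenvalue, x$max_eigenvalue))
  cat(sprintf("  diagonal      : [%.6g, %.6g]\n",
              x$diag_range[1L], x$diag_range[2L]))
  cat(sprintf("  PSD (tol %.1g): %s\n", x$tol,
              if (x$psd) "yes" else "VIOLATED"))
  invisible(x)
}

#' Repair an indefinite kernel matrix
#'
#' Similarity matrices (e.g. alignment scores) need not be positive
#' semidefinite, but indefinite kernels can make the regularized Kronecker
#' system ill-conditioned.  `clip` eigendecomposes and zeroes negative
#' eigenvalues (the least distorting repair), `shift` adds
#' `|min eigenvalue| * I` when the minimum eigenvalue is negative, `off`
#' passes the matrix through unchanged.
#'
#' @param K square symmetric matrix.
#' @param mode one of `"clip"`, `"shift"`, `"off"`.
#' @param tol eigenvalues above `-tol` are treated as nonnegative.
#' @return a symmetric matrix with minimum eigenvalue `>= -tol`.
#' @export
make_psd <- function(K, mode = c("clip", "shift", "off"), tol = 1e-8) {
  mode <- match.arg(mode)
  K <- as.matrix(K)
  dn <- dimnames(K)
  if (mode == "off") return(K)
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  mn <- min(eg$values)
  if (mn >= -tol) return(K)
  out <- switch(mode,
    clip = eg$vectors %*% (pmax(eg$values, 0) * t(eg$vectors)),
    shift = K + abs(mn) * diag(nrow(K)))
  out <- (out + t(out)) / 2
  dimnames(out) <- dn
  out
}
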