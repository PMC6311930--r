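#' Drug vector length implied by a catalog
#'
#' Sum of the four namespace sizes; the length of every encoded drug
#' vector (block order: substructures, targets, substituents, pathways).
#'
#' @param catalog A `drug_catalog`.
#' @return Integer scalar.
#' @export
drug_vector_length <- function(catalog) {
  sum(lengths(catalog$features))
}

#' Encode one drug as a binary presence/absence vector
#'
#' Concatenates the four per-namespace indicator vectors: bit `i` of block
#' `k` is 1 iff the `i`-th identifier (in the catalog's lexicographic
#' order) of namespace `k` belongs to the drug's feature set.
#'
#' @param catalog A `drug_catalog`.
#' @param drug_id Drug identifier present in the catalog.
#' @return Integer 0/1 vector of length [drug_vector_length()].
#' @export
encode_drug <- function(catalog, drug_id) {
  sets <- catalog$sets[[drug_id]]
  if (is.null(sets)) stop("unknown drug: ", drug_id, call. = FALSE)
  blocks <- lapply(FEATURE_NAMESPACES, function(ns) {
    pool <- catalog$features[[ns]]
    ids <- sets[[ns]]
    stray <- setdiff(ids, pool)
    if (length(stray) > 0L) {
      stop("unknown feature in namespace '", ns, "': ", stray[1L],
           call. = FALSE)
    }
    v <- integer(length(pool))
    v[match(ids, pool)] <- 1L
    v
  })
  unlist(blocks, use.names = FALSE)
}

#' Encode a canonical drug pair as a concatenated binary vector
#'
#' The pair vector is the vector of the first drug followed by the vector
#' of the second: length `2L` where `L` is the single-drug length.
#'
#' @param catalog A `drug_catalog`.
#' @param a,b Drug identifiers in canonical order (`a < b`).
#' @return Integer 0/1 vector of length `2 * drug_vector_length(catalog)`.
#' @export
encode_pair <- function(catalog, a, b) {
  stopifnot(a < b)
  c(encode_drug(catalog, a), encode_drug(catalog, b))
}

## Sparse drugs-by-features indicator matrix, one row per catalog drug.
## Backbone of build_pair_matrix; value-equivalent to stacking
## encode_drug() rows.
drug_feature_matrix <- function(catalog) {
  L <- drug_vector_length(catalog)
  offsets <- c(0L, cumsum(lengths(catalog$features)))
  names(offsets) <- c(FEATURE_NAMESPACES, "end")
  ii <- integer(0); jj <- integer(0)
  for (d in seq_along(catalog$drugs)) {
    sets <- catalog$sets[[catalog$drugs[d]]]
    for (k in seq_along(FEATURE_NAMESPACES)) {
      ns <- FEATURE_NAMESPACES[k]
      cols <- match(sets[[ns]], catalog$features[[ns]])
      if (anyNA(cols)) {
        stop("unknown feature in namespace '", ns, "' for drug ",
             catalog$drugs[d], call. = FALSE)
      }
      ii <- c(ii, rep.int(d, length(cols)))
      jj <- c(jj, offsets[k] + cols)
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj,
                       dims = c(length(catalog$drugs), L),
                       dimnames = list(catalog$drugs, NULL), x = 1)
}

#' Build the pair-feature matrix for a list of drug pairs
#'
#' Row `i` is the pair vector of `pairs[i, ]`; rows follow the input
#' order, duplicates included. Stored sparse (`dgCMatrix`); densify with
#' `as.matrix()` when a dense matrix is required.
#'
#' @param catalog A `drug_catalog`.
#' @param pairs Data.frame with columns `drug_a`, `drug_b` in canonical
#'   order.
#' @return Sparse binary matrix with `nrow(pairs)` rows and `2L` columns.
#' @export
build_pair_matrix <- function(catalog, pairs) {
  V <- drug_feature_matrix(catalog)
  L <- ncol(V)
  if (nrow(pairs) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                dims = c(0L, 2L * L)))
  }
  ia <- match(pairs$drug_a, catalog$drugs)
  ib <- match(pairs$drug_b, catalog$drugs)
  if (anyNA(ia) || anyNA(ib)) {
    row <- which(is.na(ia) | is.na(ib))[1L]
    stop("unknown drug in pair row ", row, ": ",
         pairs$drug_a[row], " / ", pairs$drug_b[row], call. = FALSE)
  }
  out <- cbind(V[ia, , drop = FALSE], V[ib, , drop = FALSE])
  rownames(out) <- pair_key(pairs$drug_a, pairs$drug_b)
  out
}

#' Export a pair matrix in MatrixMarket format
#'
#' Writes the sparse pair matrix as `.mtx` plus a row-index TSV mapping
#' row numbers to pair identifiers.
#'
#' @param mat Sparse matrix from [build_pair_matrix()].
#' @param mtx_path Output `.mtx` path.
#' @param index_path Output TSV path for the row index.
#' @export
write_pair_matrix <- function(mat, mtx_path, index_path) {
  Matrix::writeMM(mat, mtx_path)
  keys <- rownames(mat)
  idx <- data.frame(row = seq_len(nrow(mat)),
                    drug_a = sub("\t.*$", "", keys),
                    drug_b = sub("^.*\t", "", keys))
  utils::write.table(idx, index_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mtx_path)
}
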