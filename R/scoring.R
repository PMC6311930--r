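## Tripartite-network interaction scoring.
##
## A candidate drug pair is scored by three components computed on the
## drug-disease-gene network, each in [0, 1]:
##   inter_g  — Jaccard overlap of the two drugs' associated gene sets;
##   inter_d  — Jaccard overlap of their disease sets, damped by the
##              fraction of all network diseases the shared diseases
##              represent;
##   inter_gd — fraction of the shared genes that belong to the gene set
##              of at least one shared disease.
## The total score is the plain sum of the three, in [0, 3]. Low totals
## mark pairs with no network evidence of interaction; those are the
## highly-credible negative candidates.
##
## Empty-set conventions: every ratio whose denominator is empty is 0 —
## the conservative "no evidence" value, consistent with selecting low
## scores as negatives.

#' Gene-overlap component of the pair interaction score
#'
#' Jaccard index of the two drugs' associated gene sets:
#' `|G1 n G2| / |G1 u G2|`, with 0 when both sets are empty.
#'
#' @param g1,g2 Character vectors of gene identifiers.
#' @return Numeric scalar in `[0, 1]`.
#' @export
inter_g <- function(g1, g2) {
  g1 <- unique(g1); g2 <- unique(g2)
  u <- length(union(g1, g2))
  if (u == 0L) return(0)
  length(intersect(g1, g2)) / u
}

#' Disease-therapeutic component of the pair interaction score
#'
#' The Jaccard overlap of the two drugs' disease sets multiplied by the
#' share of all network diseases they have in common:
#' `(|D1 n D2| / |D1 u D2|) * (|D1 n D2| / |V_d|)`; 0 when `D1 u D2` is
#' empty.
#'
#' @param d1,d2 Character vectors of disease identifiers.
#' @param n_diseases Total number of diseases in the network (`|V_d|`,
#'   must be >= 1).
#' @return Numeric scalar in `[0, 1]`.
#' @export
inter_d <- function(d1, d2, n_diseases) {
  if (n_diseases < 1L) {
    stop("configuration error: network has no diseases (|V_d| = 0)",
         call. = FALSE)
  }
  d1 <- unique(d1); d2 <- unique(d2)
  u <- length(union(d1, d2))
  if (u == 0L) return(0)
  m <- length(intersect(d1, d2))
  (m / u) * (m / n_diseases)
}

#' Gene-disease-bridge component of the pair interaction score
#'
#' Fraction of the drugs' shared genes that are also genes of at least
#' one of their shared diseases:
#' `|U_k ((G1 n G2) n DG_k)| / |G1 n G2|`, where `DG_k` is the gene set
#' of the k-th shared disease; 0 when there are no shared genes or no
#' shared diseases.
#'
#' @param g1,g2 Character vectors of gene identifiers.
#' @param shared_disease_genes List of gene-identifier vectors, one per
#'   shared disease.
#' @return Numeric scalar in `[0, 1]`.
#' @export
inter_gd <- function(g1, g2, shared_disease_genes) {
  shared <- intersect(unique(g1), unique(g2))
  if (length(shared) == 0L || length(shared_disease_genes) == 0L) return(0)
  covered <- unique(unlist(lapply(shared_disease_genes,
                                  function(dg) intersect(shared, dg))))
  length(covered) / length(shared)
}

## Per-drug association sets pulled from the network edge tables.
network_sets <- function(network, drug_id) {
  list(genes = unique(network$drug_gene$right_id[
         network$drug_gene$left_id == drug_id]),
       diseases = unique(network$drug_disease$right_id[
         network$drug_disease$left_id == drug_id]))
}

#' Interaction score of one drug pair
#'
#' Computes the three components and their sum for a single pair from
#' the network's association edges.
#'
#' @param network An `rdg_network`.
#' @param a,b Drug identifiers; both must be network drug nodes.
#' @return One-row data.frame with columns `drug_a`, `drug_b`, `inter_g`,
#'   `inter_d`, `inter_gd`, `inter_score`.
#' @export
inter_score <- function(network, a, b) {
  ab <- canonical_pair(a, b)
  for (d in ab) {
    if (!d %in% network$drugs) stop("unknown drug: ", d, call. = FALSE)
  }
  s1 <- network_sets(network, ab[1L])
  s2 <- network_sets(network, ab[2L])
  shared_dis <- intersect(s1$diseases, s2$diseases)
  dg <- lapply(shared_dis, function(ds) {
    unique(network$disease_gene$right_id[network$disease_gene$left_id == ds])
  })
  cg <- inter_g(s1$genes, s2$genes)
  cd <- inter_d(s1$diseases, s2$diseases, length(network$diseases))
  cgd <- inter_gd(s1$genes, s2$genes, dg)
  data.frame(drug_a = ab[1L], drug_b = ab[2L],
             inter_g = cg, inter_d = cd, inter_gd = cgd,
             inter_score = cg + cd + cgd,
             stringsAsFactors = FALSE)
}

## Sparse incidence matrix from an edge table: rows %in% row_ids,
## columns %in% col_ids.
incidence <- function(edges, row_ids, col_ids) {
  i <- match(edges$left_id, row_ids)
  j <- match(edges$right_id, col_ids)
  keep <- !is.na(i) & !is.na(j)
  Matrix::sparseMatrix(i = i[keep], j = j[keep],
                       dims = c(length(row_ids), length(col_ids)), x = 1)
}

#' Score and rank all candidate drug pairs
#'
#' Enumerates every canonical pair of the given drugs (`n(n-1)/2` pairs),
#' computes the three score components and their total for each, and
#' returns the list sorted ascending by total score (ties broken by the
#' lexicographic pair identifier). Pairs at the head of the list have the
#' least network evidence of interaction and are the preferred negative
#' candidates.
#'
#' The pairwise gene and disease intersections are computed with sparse
#' incidence-matrix cross-products; the gene-disease bridge term is
#' accumulated drug-by-drug against that drug's own gene and disease
#' neighbourhoods, so runtime scales with network sparsity rather than
#' with the gene pool size.
#'
#' @param network An `rdg_network`.
#' @param drugs Character vector of candidate drugs; defaults to the
#'   network drug nodes. Drugs without network edges are allowed and
#'   score 0 against everything.
#' @return Data.frame of all canonical pairs with the four score columns,
#'   sorted ascending; class `ranked_pairs`.
#' @export
rank_pairs <- function(network, drugs = NULL) {
  if (is.null(drugs)) drugs <- network$drugs
  drugs <- sort(unique(drugs))
  n <- length(drugs)
  if (n < 2L) stop("need at least 2 drugs to form pairs", call. = FALSE)
  nd <- length(network$diseases)
  if (nd < 1L) {
    stop("configuration error: network has no diseases (|V_d| = 0)",
         call. = FALSE)
  }

  Ag <- incidence(network$drug_gene, drugs, network$genes)
  Ad <- incidence(network$drug_disease, drugs, network$diseases)
  Dg <- incidence(stats::setNames(network$disease_gene,
                                  c("left_id", "right_id")),
                  network$diseases, network$genes)

  ng <- Matrix::rowSums(Ag)
  ndd <- Matrix::rowSums(Ad)
  Mg <- as.matrix(Matrix::tcrossprod(Ag))   # |G_i n G_j|
  Md <- as.matrix(Matrix::tcrossprod(Ad))   # |D_i n D_j|

  Ug <- outer(ng, ng, "+") - Mg             # |G_i u G_j|
  Ud <- outer(ndd, ndd, "+") - Md
  cg <- ifelse(Ug > 0, Mg / Ug, 0)
  cd <- ifelse(Ud > 0, (Md / Ud) * (Md / nd), 0)

  # Bridge term, one row sweep per drug i over partners j > i.
  cgd <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    if (ng[i] == 0 || ndd[i] == 0) next
    gi <- which(Ag[i, ] > 0)
    di <- which(Ad[i, ] > 0)
    # shared diseases of (i, j) restricted to i's diseases, then the
    # genes of those diseases restricted to i's genes
    B <- Ad[js, di, drop = FALSE]                  # partners x |D_i|
    C <- Dg[di, gi, drop = FALSE]                  # |D_i| x |G_i|
    covered <- (B %*% C) > 0                       # partners x |G_i|
    hasg <- Ag[js, gi, drop = FALSE] > 0
    num <- Matrix::rowSums(covered & hasg)
    denom <- Mg[i, js]
    cgd[i, js] <- ifelse(denom > 0, num / denom, 0)
  }

  iu <- which(upper.tri(Mg), arr.ind = TRUE)
  out <- data.frame(drug_a = drugs[iu[, 1L]], drug_b = drugs[iu[, 2L]],
                    inter_g = cg[iu], inter_d = cd[iu], inter_gd = cgd[iu],
                    stringsAsFactors = FALSE)
  out$inter_score <- out$inter_g + out$inter_d + out$inter_gd
  ord <- order(out$inter_score, out$drug_a, out$drug_b, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_pairs", "data.frame")
  out
}

#' Write a ranked pair list as TSV
#'
#' @param ranked A `ranked_pairs` data.frame.
#' @param path Output TSV path.
#' @export
write_ranked_pairs <- function(ranked, path) {
  utils::write.table(as.data.frame(ranked), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select highly-credible negative pairs for one ADR
#'
#' Walks the ascending ranked list, skips any pair that is a known
#' positive for the ADR, and keeps pairs until `round(nsr * n_positives)`
#' have been collected (round-half-to-even). The result is a prefix of
#' the ranked list minus the positives, guaranteed disjoint from them.
#'
#' @param ranked A `ranked_pairs` data.frame from [rank_pairs()].
#' @param positives Data.frame of the ADR's positive pairs (columns
#'   `drug_a`, `drug_b`, canonical order).
#' @param nsr Negative sample ratio (> 0): negatives per positive.
#' @param exclude Optional data.frame of additional pairs to skip
#'   without affecting the requested count (e.g. every ADR's positives
#'   for the stricter global exclusion).
#' @return Data.frame of selected pairs (columns `drug_a`, `drug_b`).
#' @export
select_negatives <- function(ranked, positives, nsr = 1, exclude = NULL) {
  stopifnot(nsr > 0)
  need <- round(nsr * nrow(positives))
  pos_keys <- pair_key(positives$drug_a, positives$drug_b)
  if (!is.null(exclude)) {
    pos_keys <- c(pos_keys, pair_key(exclude$drug_a, exclude$drug_b))
  }
  keys <- pair_key(ranked$drug_a, ranked$drug_b)
  keep <- which(!(keys %in% pos_keys))
  if (length(keep) < need) {
    stop("capacity error: need ", need, " negatives but only ",
         length(keep), " non-positive candidates exist (short by ",
         need - length(keep), ")", call. = FALSE)
  }
  out <- ranked[keep[seq_len(need)], c("drug_a", "drug_b"), drop = FALSE]
  rownames(out) <- NULL
  out
}
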