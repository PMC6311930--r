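#' @keywords internal
"_PACKAGE"

## Namespaces of the drug feature vector, in fixed block order.
FEATURE_NAMESPACES <- c("substructure", "target", "substituent", "pathway")

#' Canonical ordering of a drug pair
#'
#' Unordered drug pairs are stored with the lexicographically smaller
#' identifier first, so that `(x, y)` and `(y, x)` map to the same pair.
#' Self-pairs are rejected: a drug combined with itself is not a combined
#' medication.
#'
#' @param x,y Character vectors of drug identifiers (recycled to common
#'   length).
#' @return For `canonical_pair`, a character vector `c(a, b)` with `a < b`
#'   (scalar inputs only). For `canonical_pairs`, a data.frame with columns
#'   `drug_a` and `drug_b`, one row per input pair.
#' @examples
#' canonical_pair("DB2", "DB1")
#' @export
canonical_pair <- function(x, y) {
  stopifnot(length(x) == 1L, length(y) == 1L)
  if (identical(x, y)) {
    stop("self-pair: '", x, "' cannot be combined with itself", call. = FALSE)
  }
  if (x < y) c(x, y) else c(y, x)
}

#' @rdname canonical_pair
#' @export
canonical_pairs <- function(x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(as.character(x), n)
  y <- rep_len(as.character(y), n)
  if (any(x == y)) {
    bad <- which(x == y)[1L]
    stop("self-pair at row ", bad, ": '", x[bad], "'", call. = FALSE)
  }
  swap <- x > y
  a <- ifelse(swap, y, x)
  b <- ifelse(swap, x, y)
  data.frame(drug_a = a, drug_b = b, stringsAsFactors = FALSE)
}

## Stable single-string key for a canonical pair.
pair_key <- function(a, b) paste(a, b, sep = "\t")

#' Read a two-column association table from delimited text
#'
#' Reads a CSV or TSV file (dialect auto-detected from the file extension:
#' `.csv` is comma-separated, anything else tab-separated) with a header
#' row, extracts the two identifier columns, trims surrounding whitespace
#' and drops duplicate rows while preserving first-occurrence order.
#'
#' @param path Path to the delimited file.
#' @param left,right Names of the left and right identifier columns.
#' @return A data.frame with columns `left_id` and `right_id`.
#' @export
read_association_table <- function(path, left, right) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "\"",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  for (col in c(left, right)) {
    if (!col %in% names(df)) {
      stop("schema error: column '", col, "' not found in ", path,
           " (columns: ", paste(names(df), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  out <- data.frame(left_id = trimws(df[[left]]),
                    right_id = trimws(df[[right]]),
                    stringsAsFactors = FALSE)
  empty <- which(out$left_id == "" | out$right_id == "")
  if (length(empty) > 0L) {
    stop("validation error: empty identifier on data line ", empty[1L],
         " of ", path, call. = FALSE)
  }
  out[!duplicated(out), , drop = FALSE]
}

#' Write a two-column association table as delimited text
#'
#' Inverse of [read_association_table()]: writes the table with the given
#' column names, choosing comma or tab separation from the file extension.
#'
#' @param tab Data.frame with columns `left_id` and `right_id`.
#' @param path Output file path.
#' @param left,right Header names for the two columns.
#' @export
write_association_table <- function(tab, path, left = "left_id",
                                    right = "right_id") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- stats::setNames(tab[, c("left_id", "right_id")], c(left, right))
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Build a drug catalog from association tables
#'
#' Integrates per-namespace feature tables (drug to substructure, target,
#' substituent, pathway) with drug-gene and drug-disease association
#' tables into a single catalog. The catalog drug set is the union of all
#' drug identifiers seen in any table; a drug missing from a table simply
#' has the empty set there. Feature ordering within each namespace is the
#' lexicographic sort of the identifiers, which fixes the column order of
#' all derived vectors.
#'
#' @param substructure,target,substituent,pathway Association tables
#'   (data.frames with `left_id` = drug, `right_id` = feature) or `NULL`.
#' @param drug_gene,drug_disease Association tables of CTD-style drug-gene
#'   and drug-disease links, or `NULL`.
#' @param extra_drugs Character vector of drug identifiers to retain even
#'   if absent from every table (e.g. drugs seen only in a drug-drug-ADR
#'   table); retained with all-empty feature sets, with a warning.
#' @return An object of class `drug_catalog`: a list with `drugs` (sorted
#'   identifier vector), `features` (named list of the four sorted
#'   namespace identifier vectors) and `sets` (per-drug named list of the
#'   six identifier sets).
#' @export
build_catalog <- function(substructure = NULL, target = NULL,
                          substituent = NULL, pathway = NULL,
                          drug_gene = NULL, drug_disease = NULL,
                          extra_drugs = character()) {
  tabs <- list(substructure = substructure, target = target,
               substituent = substituent, pathway = pathway,
               ctd_genes = drug_gene, ctd_diseases = drug_disease)
  if (all(vapply(tabs, is.null, logical(1))) && length(extra_drugs) == 0L) {
    stop("at least one non-empty table is required", call. = FALSE)
  }
  drug_ids <- character()
  for (tab in tabs) {
    if (!is.null(tab)) drug_ids <- c(drug_ids, tab$left_id)
  }
  orphans <- setdiff(extra_drugs, drug_ids)
  if (length(orphans) > 0L) {
    warning(length(orphans), " drug(s) have no feature associations: ",
            paste(utils::head(orphans, 5L), collapse = ", "),
            if (length(orphans) > 5L) ", ..." else "", call. = FALSE)
  }
  drugs <- sort(unique(c(drug_ids, extra_drugs)))

  features <- lapply(tabs[FEATURE_NAMESPACES], function(tab) {
    if (is.null(tab)) character() else sort(unique(tab$right_id))
  })

  sets <- lapply(drugs, function(d) {
    lapply(tabs, function(tab) {
      if (is.null(tab)) character()
      else sort(unique(tab$right_id[tab$left_id == d]))
    })
  })
  names(sets) <- drugs

  structure(list(drugs = drugs, features = features, sets = sets),
            class = "drug_catalog")
}

#' @export
print.drug_catalog <- function(x, ...) {
  cat("drug_catalog:", length(x$drugs), "drugs;",
      paste(sprintf("%s=%d", names(x$features),
                    lengths(x$features)), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a drug-disease-gene tripartite network
#'
#' The network holds three node layers (drugs, diseases, genes) and the
#' three association edge sets between them. Node sets default to the
#' union of edge endpoints; every edge endpoint must be a member of its
#' layer.
#'
#' @param drug_gene,drug_disease,disease_gene Association tables
#'   (`left_id`/`right_id` data.frames) for the three edge types.
#' @param drugs,diseases,genes Optional explicit node sets.
#' @return Object of class `rdg_network` with node vectors and the three
#'   edge tables.
#' @export
rdg_network <- function(drug_gene, drug_disease, disease_gene,
                        drugs = NULL, diseases = NULL, genes = NULL) {
  empty_tab <- data.frame(left_id = character(), right_id = character(),
                          stringsAsFactors = FALSE)
  if (is.null(drug_gene)) drug_gene <- empty_tab
  if (is.null(drug_disease)) drug_disease <- empty_tab
  if (is.null(disease_gene)) disease_gene <- empty_tab
  drugs <- sort(unique(c(drugs, drug_gene$left_id, drug_disease$left_id)))
  diseases <- sort(unique(c(diseases, drug_disease$right_id,
                            disease_gene$left_id)))
  genes <- sort(unique(c(genes, drug_gene$right_id, disease_gene$right_id)))
  chk <- function(ids, pool, what) {
    bad <- setdiff(ids, pool)
    if (length(bad) > 0L) {
      stop("edge endpoint(s) not in ", what, " node set: ",
           paste(utils::head(bad, 3L), collapse = ", "), call. = FALSE)
    }
  }
  chk(drug_gene$left_id, drugs, "drug")
  chk(drug_disease$left_id, drugs, "drug")
  chk(drug_disease$right_id, diseases, "disease")
  chk(disease_gene$left_id, diseases, "disease")
  chk(drug_gene$right_id, genes, "gene")
  chk(disease_gene$right_id, genes, "gene")
  structure(list(drugs = drugs, diseases = diseases, genes = genes,
                 drug_gene = drug_gene, drug_disease = drug_disease,
                 disease_gene = disease_gene),
            class = "rdg_network")
}

#' @export
print.rdg_network <- function(x, ...) {
  cat("rdg_network:", length(x$drugs), "drugs,", length(x$diseases),
      "diseases,", length(x$genes), "genes;",
      nrow(x$drug_gene) + nrow(x$drug_disease) + nrow(x$disease_gene),
      "edges\n")
  invisible(x)
}

#' Read a drug-drug-ADR association table
#'
#' Reads `(drug_a, drug_b, adr)` triples from delimited text, stores each
#' pair in canonical order and drops duplicate `(pair, adr)` rows.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param drug_a,drug_b,adr Column names of the two drug identifiers and
#'   the ADR identifier.
#' @return Data.frame with columns `drug_a`, `drug_b`, `adr_id`.
#' @export
read_ddaa <- function(path, drug_a = "drug_a", drug_b = "drug_b",
                      adr = "adr_id") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(drug_a, drug_b, adr)) {
    if (!col %in% names(df)) {
      stop("schema error: column '", col, "' not found in ", path,
           call. = FALSE)
    }
  }
  ddaa_table(trimws(df[[drug_a]]), trimws(df[[drug_b]]), trimws(df[[adr]]))
}

#' Assemble a canonical drug-drug-ADR table
#'
#' @param drug_a,drug_b,adr_id Equal-length character vectors of triples.
#' @return Deduplicated data.frame with canonical pair order per row.
#' @export
ddaa_table <- function(drug_a, drug_b, adr_id) {
  cp <- canonical_pairs(drug_a, drug_b)
  out <- data.frame(drug_a = cp$drug_a, drug_b = cp$drug_b,
                    adr_id = as.character(adr_id),
                    stringsAsFactors = FALSE)
  out[!duplicated(out), , drop = FALSE]
}

#' Write a drug-drug-ADR table to delimited text
#'
#' @param ddaa Data.frame from [ddaa_table()].
#' @param path Output path (`.csv` for comma-separated).
#' @export
write_ddaa <- function(ddaa, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(ddaa, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Catalog manifest
#'
#' Summarizes a catalog as a small JSON-ready list: namespace sizes, drug
#' count and the number of canonical candidate pairs `n(n-1)/2`. Written
#' next to outputs so matrix layouts are reproducible.
#'
#' @param catalog A `drug_catalog`.
#' @param path Optional path; when given the manifest is written as JSON.
#' @return The manifest list, invisibly when written to file.
#' @export
catalog_manifest <- function(catalog, path = NULL) {
  n <- length(catalog$drugs)
  m <- list(n_drugs = n,
            namespace_sizes = as.list(lengths(catalog$features)),
            vector_length = sum(lengths(catalog$features)),
            n_candidate_pairs = n * (n - 1) / 2)
  if (!is.null(path)) {
    jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(m))
  }
  m
}
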