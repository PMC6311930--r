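## Synthetic fixture generator with planted structure.
##
## The generator emulates the statistical premises the negative-selection
## score relies on: planted interacting drug pairs share target genes and
## diseases, and their shared genes belong to the gene set of a shared
## disease; ADR-positive pairs additionally carry a per-ADR signature in
## the binary feature namespaces. Non-interacting drugs draw genes and
## diseases from disjoint per-drug allocations, so with zero noise every
## non-planted pair scores exactly 0 on the tripartite network.

#' Configuration for the synthetic fixture generator
#'
#' @param n_drugs Number of drugs.
#' @param n_interacting_pairs Number of planted interacting pairs (at
#'   most `n_drugs * (n_drugs - 1) / 2`).
#' @param n_adrs Number of ADR labels.
#' @param n_positives_per_adr Positive pairs per ADR, drawn from the
#'   planted pairs.
#' @param n_genes,n_diseases Gene and disease pool sizes; defaults are
#'   the minimum the disjoint allocation requires.
#' @param private_genes_per_drug,private_diseases_per_drug Per-drug
#'   private association counts.
#' @param shared_genes_per_pair Genes planted into both drugs of each
#'   interacting pair.
#' @param feature_pool Named integer vector of per-namespace feature-pool
#'   sizes.
#' @param signature_per_namespace Signature features per ADR and
#'   namespace.
#' @param background_per_namespace Background features drawn per drug and
#'   namespace.
#' @param signal_strength Probability in `[0, 1]` that a positive pair's
#'   drug carries each signature feature.
#' @param noise_rate Probability in `[0, 1]` of spurious feature bits and
#'   spurious network edges.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_drugs = 40L, n_interacting_pairs = 30L,
                         n_adrs = 3L, n_positives_per_adr = 10L,
                         n_genes = NULL, n_diseases = NULL,
                         private_genes_per_drug = 3L,
                         private_diseases_per_drug = 2L,
                         shared_genes_per_pair = 2L,
                         feature_pool = c(substructure = 120L,
                                          target = 150L,
                                          substituent = 80L,
                                          pathway = 100L),
                         signature_per_namespace = 6L,
                         background_per_namespace = 8L,
                         signal_strength = 0.9, noise_rate = 0,
                         seed = 1L) {
  need_genes <- n_drugs * private_genes_per_drug +
    n_interacting_pairs * shared_genes_per_pair
  need_diseases <- n_drugs * private_diseases_per_drug +
    n_interacting_pairs
  if (is.null(n_genes)) n_genes <- need_genes
  if (is.null(n_diseases)) n_diseases <- need_diseases
  cfg <- list(n_drugs = as.integer(n_drugs),
              n_interacting_pairs = as.integer(n_interacting_pairs),
              n_adrs = as.integer(n_adrs),
              n_positives_per_adr = as.integer(n_positives_per_adr),
              n_genes = as.integer(n_genes),
              n_diseases = as.integer(n_diseases),
              private_genes_per_drug = as.integer(private_genes_per_drug),
              private_diseases_per_drug =
                as.integer(private_diseases_per_drug),
              shared_genes_per_pair = as.integer(shared_genes_per_pair),
              feature_pool = feature_pool,
              signature_per_namespace = as.integer(signature_per_namespace),
              background_per_namespace =
                as.integer(background_per_namespace),
              signal_strength = signal_strength,
              noise_rate = noise_rate,
              seed = as.integer(seed))
  max_pairs <- n_drugs * (n_drugs - 1) / 2
  if (n_interacting_pairs > max_pairs) {
    stop("config error: ", n_interacting_pairs,
         " interacting pairs exceed the ", max_pairs,
         " possible canonical pairs", call. = FALSE)
  }
  if (n_positives_per_adr > n_interacting_pairs) {
    stop("config error: more positives per ADR than planted pairs",
         call. = FALSE)
  }
  if (n_genes < need_genes || n_diseases < need_diseases) {
    stop("config error: gene/disease pools too small for the disjoint ",
         "allocation (need ", need_genes, " genes, ", need_diseases,
         " diseases)", call. = FALSE)
  }
  if (any(feature_pool < n_adrs * signature_per_namespace +
            background_per_namespace)) {
    stop("config error: feature pool smaller than signatures plus ",
         "background", call. = FALSE)
  }
  if (signal_strength < 0 || signal_strength > 1 ||
      noise_rate < 0 || noise_rate > 1) {
    stop("config error: rates must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

tab <- function(left, right) {
  data.frame(left_id = left, right_id = right, stringsAsFactors = FALSE)
}

#' Generate a synthetic fixture with planted interaction structure
#'
#' Produces every input table the pipeline consumes (four feature
#' namespaces, drug-gene, drug-disease, disease-gene associations and a
#' drug-drug-ADR table) together with the ground truth used by tests.
#' Planted pairs share `shared_genes_per_pair` genes and one disease
#' whose gene set contains those shared genes; each drug additionally
#' holds private genes and diseases from disjoint allocations. Positive
#' pairs of an ADR carry the ADR's signature feature bits at rate
#' `signal_strength`; `noise_rate` adds spurious bits and edges.
#'
#' @param config A [synth_config()].
#' @return List with `tables` (named list of association data.frames plus
#'   `ddaa`), `truth` (planted pairs, per-ADR positives and signatures)
#'   and `config`.
#' @export
synth_generate <- function(config = synth_config()) {
  cfg <- config
  set.seed(derive_seed(cfg$seed, "synth"))
  drugs <- sprintf("DR%04d", seq_len(cfg$n_drugs))
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  diseases <- sprintf("DS%05d", seq_len(cfg$n_diseases))

  # planted interacting pairs
  all_idx <- which(upper.tri(diag(cfg$n_drugs)), arr.ind = TRUE)
  pick <- sort(sample.int(nrow(all_idx), cfg$n_interacting_pairs))
  planted <- data.frame(drug_a = drugs[all_idx[pick, 1L]],
                        drug_b = drugs[all_idx[pick, 2L]],
                        stringsAsFactors = FALSE)

  pg <- cfg$private_genes_per_drug
  pd <- cfg$private_diseases_per_drug
  sg <- cfg$shared_genes_per_pair

  drug_gene <- list()
  drug_disease <- list()
  disease_gene <- list()
  for (i in seq_len(cfg$n_drugs)) {
    gidx <- ((i - 1L) * pg + 1L):(i * pg)
    didx <- ((i - 1L) * pd + 1L):(i * pd)
    drug_gene[[i]] <- tab(drugs[i], genes[gidx])
    drug_disease[[i]] <- tab(drugs[i], diseases[didx])
    # private diseases point at one private gene for realism
    disease_gene[[i]] <- tab(diseases[didx[1L]], genes[gidx[1L]])
  }
  g_off <- cfg$n_drugs * pg
  d_off <- cfg$n_drugs * pd
  for (p in seq_len(cfg$n_interacting_pairs)) {
    shared_g <- genes[(g_off + (p - 1L) * sg + 1L):(g_off + p * sg)]
    shared_d <- diseases[d_off + p]
    pair <- unlist(planted[p, c("drug_a", "drug_b")], use.names = FALSE)
    drug_gene <- c(drug_gene, list(tab(rep(pair, each = sg),
                                       rep(shared_g, 2L))))
    drug_disease <- c(drug_disease, list(tab(pair, shared_d)))
    disease_gene <- c(disease_gene, list(tab(shared_d, shared_g)))
  }
  # spurious association edges
  if (cfg$noise_rate > 0) {
    flip <- stats::runif(cfg$n_drugs) < cfg$noise_rate
    if (any(flip)) {
      drug_gene <- c(drug_gene, list(tab(drugs[flip],
        genes[sample.int(cfg$n_genes, sum(flip), replace = TRUE)])))
    }
    flip <- stats::runif(cfg$n_drugs) < cfg$noise_rate
    if (any(flip)) {
      drug_disease <- c(drug_disease, list(tab(drugs[flip],
        diseases[sample.int(cfg$n_diseases, sum(flip), replace = TRUE)])))
    }
  }

  # ADR labels: positives drawn from the planted pairs
  adrs <- sprintf("ADR%03d", seq_len(cfg$n_adrs))
  adr_positives <- lapply(adrs, function(a) {
    planted[sort(sample.int(nrow(planted), cfg$n_positives_per_adr)), ,
            drop = FALSE]
  })
  names(adr_positives) <- adrs
  ddaa <- do.call(rbind, lapply(adrs, function(a) {
    cbind(adr_positives[[a]], adr_id = a, stringsAsFactors = FALSE)
  }))
  ddaa <- ddaa_table(ddaa$drug_a, ddaa$drug_b, ddaa$adr_id)

  # feature namespaces: per-ADR signatures (disjoint across ADRs) plus
  # per-drug random background, plus noise bits
  ns_pools <- lapply(names(cfg$feature_pool), function(ns) {
    sprintf("%s%04d", toupper(substr(ns, 1L, 3L)),
            seq_len(cfg$feature_pool[[ns]]))
  })
  names(ns_pools) <- names(cfg$feature_pool)
  spn <- cfg$signature_per_namespace
  signatures <- list()
  feature_tabs <- list()
  for (ns in names(ns_pools)) {
    pool <- ns_pools[[ns]]
    sig_idx <- sample.int(length(pool), cfg$n_adrs * spn)
    sig <- split(pool[sig_idx], rep(adrs, each = spn))
    signatures[[ns]] <- sig
    background <- setdiff(pool, pool[sig_idx])
    rows <- list()
    for (i in seq_len(cfg$n_drugs)) {
      feats <- sample(background, cfg$background_per_namespace)
      for (a in adrs) {
        on <- stats::runif(spn) < cfg$noise_rate
        feats <- c(feats, sig[[a]][on])
      }
      rows[[i]] <- tab(drugs[i], unique(feats))
    }
    # positive pairs carry the signature at rate signal_strength
    for (a in adrs) {
      pos <- adr_positives[[a]]
      for (p in seq_len(nrow(pos))) {
        for (d in unlist(pos[p, ], use.names = FALSE)) {
          on <- stats::runif(spn) < cfg$signal_strength
          if (any(on)) rows <- c(rows, list(tab(d, sig[[a]][on])))
        }
      }
    }
    ft <- do.call(rbind, rows)
    feature_tabs[[ns]] <- ft[!duplicated(ft), , drop = FALSE]
  }

  collapse <- function(lst) {
    out <- do.call(rbind, lst)
    out <- out[!duplicated(out), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  # per-ADR signatures reshaped as adr -> namespace -> ids
  sig_by_adr <- lapply(adrs, function(a) {
    lapply(signatures, function(s) s[[a]])
  })
  names(sig_by_adr) <- adrs

  list(tables = c(feature_tabs,
                  list(drug_gene = collapse(drug_gene),
                       drug_disease = collapse(drug_disease),
                       disease_gene = collapse(disease_gene),
                       ddaa = ddaa)),
       truth = list(interacting_pairs = planted,
                    adr_positives = adr_positives,
                    adr_signatures = sig_by_adr,
                    drugs = drugs, genes = genes, diseases = diseases),
       config = cfg)
}

#' Analytic score-separation bound for a noise-free fixture
#'
#' For `noise_rate = 0` the disjoint allocation makes every non-planted
#' pair score exactly 0, while each planted pair scores at least a bound
#' computable from the configuration: its shared genes give
#' `inter_g >= s / (2p + (2m - 1)s)` where `s` is the shared-gene count,
#' `p` the private-gene count and `m` the maximum number of planted pairs
#' a single drug can belong to; the single shared disease gives a
#' positive `inter_d` term; and the shared disease's gene set covers all
#' shared genes, so `inter_gd = 1`.
#'
#' @param config A [synth_config()] with `noise_rate = 0`.
#' @return List with `nonplanted_mean` (exactly 0), `planted_lower_bound`
#'   and `gap` (their difference).
#' @export
expected_separation <- function(config) {
  cfg <- config
  if (cfg$noise_rate > 0) {
    stop("unsupported: the analytic bound requires noise_rate = 0 ",
         "(use Monte-Carlo for noisy configs)", call. = FALSE)
  }
  m <- min(cfg$n_interacting_pairs, cfg$n_drugs - 1L)
  s <- cfg$shared_genes_per_pair
  p <- cfg$private_genes_per_drug
  pd <- cfg$private_diseases_per_drug
  g_bound <- s / (2 * p + (2 * m - 1) * s)
  d_bound <- (1 / (2 * pd + 2 * m - 1)) * (1 / cfg$n_diseases)
  gd_bound <- 1
  bound <- g_bound + d_bound + gd_bound
  list(nonplanted_mean = 0, planted_lower_bound = bound, gap = bound)
}

#' Write a generated fixture as delimited text plus ground-truth JSON
#'
#' @param fixture Result of [synth_generate()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  heads <- list(substructure = c("drug_id", "substructure_id"),
                target = c("drug_id", "target_id"),
                substituent = c("drug_id", "substituent_id"),
                pathway = c("drug_id", "pathway_id"),
                drug_gene = c("drug_id", "gene_id"),
                drug_disease = c("drug_id", "disease_id"),
                disease_gene = c("disease_id", "gene_id"))
  for (nm in names(heads)) {
    write_association_table(fixture$tables[[nm]],
                            file.path(dir, paste0(nm, ".csv")),
                            left = heads[[nm]][1L],
                            right = heads[[nm]][2L])
  }
  write_ddaa(fixture$tables$ddaa, file.path(dir, "ddaa.csv"))
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}

#' Load a written fixture into catalog, network and DDAA objects
#'
#' @param dir Directory written by [write_fixture()].
#' @return List with `catalog`, `network`, `ddaa`.
#' @export
read_fixture <- function(dir) {
  rd <- function(nm, l, r) {
    read_association_table(file.path(dir, paste0(nm, ".csv")), l, r)
  }
  substructure <- rd("substructure", "drug_id", "substructure_id")
  target <- rd("target", "drug_id", "target_id")
  substituent <- rd("substituent", "drug_id", "substituent_id")
  pathway <- rd("pathway", "drug_id", "pathway_id")
  drug_gene <- rd("drug_gene", "drug_id", "gene_id")
  drug_disease <- rd("drug_disease", "drug_id", "disease_id")
  disease_gene <- rd("disease_gene", "disease_id", "gene_id")
  ddaa <- read_ddaa(file.path(dir, "ddaa.csv"))
  catalog <- build_catalog(substructure, target, substituent, pathway,
                           drug_gene, drug_disease,
                           extra_drugs = unique(c(ddaa$drug_a,
                                                  ddaa$drug_b)))
  network <- rdg_network(drug_gene, drug_disease, disease_gene,
                         drugs = catalog$drugs)
  list(catalog = catalog, network = network, ddaa = ddaa)
}

#' Build in-memory catalog, network and DDAA from a generated fixture
#'
#' Convenience equivalent of [write_fixture()] followed by
#' [read_fixture()] without touching disk.
#'
#' @param fixture Result of [synth_generate()].
#' @return List with `catalog`, `network`, `ddaa`.
#' @export
fixture_objects <- function(fixture) {
  t <- fixture$tables
  catalog <- build_catalog(t$substructure, t$target, t$substituent,
                           t$pathway, t$drug_gene, t$drug_disease,
                           extra_drugs = fixture$truth$drugs)
  network <- rdg_network(t$drug_gene, t$drug_disease, t$disease_gene,
                         drugs = catalog$drugs)
  list(catalog = catalog, network = network, ddaa = t$ddaa)
}
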