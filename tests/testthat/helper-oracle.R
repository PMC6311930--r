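# Independent brute-force oracle for the tripartite interaction score:
# plain nested loops over identifier sets, no shared code with the
# package implementation.

oracle_jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  inter <- 0
  for (x in a) if (x %in% b) inter <- inter + 1
  uni <- length(unique(c(a, b)))
  if (uni == 0) 0 else inter / uni
}

oracle_score <- function(network, d1, d2) {
  g1 <- unique(network$drug_gene$right_id[network$drug_gene$left_id == d1])
  g2 <- unique(network$drug_gene$right_id[network$drug_gene$left_id == d2])
  dd1 <- unique(network$drug_disease$right_id[
    network$drug_disease$left_id == d1])
  dd2 <- unique(network$drug_disease$right_id[
    network$drug_disease$left_id == d2])
  cg <- oracle_jaccard(g1, g2)
  shared_d <- character()
  for (x in dd1) if (x %in% dd2) shared_d <- c(shared_d, x)
  uni_d <- length(unique(c(dd1, dd2)))
  cd <- if (uni_d == 0) 0 else {
    (length(shared_d) / uni_d) *
      (length(shared_d) / length(network$diseases))
  }
  shared_g <- character()
  for (x in g1) if (x %in% g2) shared_g <- c(shared_g, x)
  covered <- character()
  for (ds in shared_d) {
    dg <- network$disease_gene$right_id[network$disease_gene$left_id == ds]
    for (g in shared_g) if (g %in% dg) covered <- c(covered, g)
  }
  cgd <- if (length(shared_g) == 0) 0 else {
    length(unique(covered)) / length(shared_g)
  }
  c(inter_g = cg, inter_d = cd, inter_gd = cgd,
    inter_score = cg + cd + cgd)
}

# Random small tripartite network for oracle-equivalence sweeps.
random_network <- function(seed, max_drugs = 10, max_diseases = 8,
                           max_genes = 15) {
  set.seed(seed)
  nr <- sample(2:max_drugs, 1)
  nd <- sample(1:max_diseases, 1)
  ng <- sample(1:max_genes, 1)
  drugs <- sprintf("R%02d", seq_len(nr))
  diseases <- sprintf("D%02d", seq_len(nd))
  genes <- sprintf("G%02d", seq_len(ng))
  rand_edges <- function(left, right, p) {
    grid <- expand.grid(left_id = left, right_id = right,
                        stringsAsFactors = FALSE)
    grid[stats::runif(nrow(grid)) < p, , drop = FALSE]
  }
  rdg_network(rand_edges(drugs, genes, 0.3),
              rand_edges(drugs, diseases, 0.3),
              rand_edges(diseases, genes, 0.3),
              drugs = drugs, diseases = diseases, genes = genes)
}

# Tiny two-namespace catalog used across featurization tests.
toy_catalog <- function() {
  build_catalog(
    substructure = data.frame(left_id = c("DB1", "DB1", "DB2"),
                              right_id = c("s1", "s2", "s2")),
    target = data.frame(left_id = c("DB1", "DB3"),
                        right_id = c("t1", "t2")),
    substituent = NULL,
    pathway = data.frame(left_id = "DB2", right_id = "p1"))
}
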