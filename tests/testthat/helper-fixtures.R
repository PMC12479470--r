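# Small deterministic fixtures, built in code at test time.

make_exp <- function(gene, z, pathway = "WNT", ptype = "activation",
                     accession = "EXP1") {
  perturbation_experiment(pathway, ptype, accession, gene, z)
}

# A two-pathway, two-experiment-per-pathway compendium on a 6-gene universe.
tiny_compendium <- function() {
  g <- c("A", "B", "C", "D", "E", "F")
  list(
    WNT = pathway_experiment_set("WNT", list(
      make_exp(g, c(3, -1, 0.5, 4, -2, 1), accession = "W1"),
      make_exp(g, c(-2.5, 1, -0.2, -3.5, 2, -1), ptype = "inhibition",
               accession = "W2"))),
    TNFA = pathway_experiment_set("TNFA", list(
      make_exp(g, c(0.1, 2, -3, 0.4, 1.5, -0.6), pathway = "TNFA",
               accession = "T1"),
      make_exp(g, c(-0.3, 2.5, -2.8, 0.2, 1.1, -0.9), pathway = "TNFA",
               accession = "T2"))))
}

# Exact enumeration oracle for the hypergeometric upper tail: fraction of all
# n-subsets of 1..N whose overlap with 1..M is at least k.
enum_hyper_tail <- function(N, M, n, k) {
  subsets <- utils::combn(N, n)
  ov <- colSums(subsets <= M)
  mean(ov >= k)
}

# A small drug-response table: 10 sensitive lines (AUC .40...76), 10 resistant
# (AUC .80...98), lexicographic ids.
toy_auc <- function(drug = "paclitaxel") {
  data.frame(
    cell_line = sprintf("CL%02d", 1:20),
    drug = drug,
    auc = c(seq(0.40, 0.76, length.out = 10), seq(0.80, 0.98, length.out = 10)))
}
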