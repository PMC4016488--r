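# Small hand-built genomes and environments used across the suite.

# single isolated gene: alpha, delta, optional gamma on factor O2
single_gene_gtrn <- function(alpha = 2, delta = 1, gamma = numeric(),
                             beta = numeric()) {
  g1 <- gene("g1", delta = delta, orf_seq_ref = "orf_g1",
             native_rbs_ref = "rbs_g1", home_operon = "op1")
  p1 <- regulatory_function(alpha, beta = beta, gamma = gamma,
                            region_ref = "prom_P1")
  op1 <- operon("op1", genes = "g1", primary_promoter = "P1",
                terminator_ref = "term_op1", locus = 1)
  gtrn(list(g1 = g1), list(op1 = op1), list(P1 = p1),
       sequence_store = c(orf_g1 = "ATGAAACCC", rbs_g1 = strrep("A", 20),
                          prom_P1 = strrep("G", 30),
                          term_op1 = strrep("T", 25)))
}

# two-gene cascade: g1 constitutive-ish, g2 activated by g1
cascade_gtrn <- function(alpha1 = 1, alpha2 = 0.5, b21 = 0.5,
                         d1 = 1, d2 = 1) {
  mk_store <- c(orf_g1 = "ATGAAACCC", rbs_g1 = strrep("A", 20),
                orf_g2 = "ATGCCCGGG", rbs_g2 = strrep("C", 20),
                prom_P1 = strrep("G", 30), prom_P2 = strrep("G", 30),
                term_op1 = strrep("T", 25), term_op2 = strrep("T", 25))
  g1 <- gene("g1", d1, categories = "TF", orf_seq_ref = "orf_g1",
             native_rbs_ref = "rbs_g1", home_operon = "op1")
  g2 <- gene("g2", d2, orf_seq_ref = "orf_g2", native_rbs_ref = "rbs_g2",
             home_operon = "op2")
  p1 <- regulatory_function(alpha1, region_ref = "prom_P1")
  p2 <- regulatory_function(alpha2, beta = c(g1 = b21),
                            region_ref = "prom_P2")
  gtrn(list(g1 = g1, g2 = g2),
       list(op1 = operon("op1", "g1", "P1", terminator_ref = "term_op1",
                         locus = 1),
            op2 = operon("op2", "g2", "P2", terminator_ref = "term_op2",
                         locus = 2)),
       list(P1 = p1, P2 = p2), sequence_store = mk_store)
}

# environment over O2 with deviation dv (v_opt = 75)
o2_env <- function(dv = 0, id = NA_character_) {
  environment_state(v = c(O2 = 75 + dv), v_opt = c(O2 = 75), id = id)
}

# factor-free environment
null_env <- function(id = "null") {
  environment_state(v = stats::setNames(numeric(), character()),
                    v_opt = stats::setNames(numeric(), character()), id = id)
}

# small random genome + matching environments for property-style loops
small_world <- function(n_genes = 12, seed = 1, n_env = 2,
                        redundancy = 3, tandem_candidate_fraction = 0.25) {
  g <- generate_gtrn(synthesis_spec(
    n_genes = n_genes, seed = seed, redundancy = redundancy,
    tandem_candidate_fraction = tandem_candidate_fraction))
  envs <- generate_environments("multi", n = n_env, seed = seed + 1000)
  list(g = g, envs = envs)
}
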