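# Semantics of the four transcriptional modifications, undo, proposal
# statistics, and the Metropolis acceptance rule.

test_that("a moved gene adopts the destination operon's regulation exactly", {
  # genome A: g1 under P1, g2 under P2 (alpha=3, beta on tf)
  tf <- gene("tf", 1, categories = "TF")
  g1 <- gene("g1", 0.7)
  g2 <- gene("g2", 1.3)
  proms <- list(
    Ptf = regulatory_function(1, gamma = c(O2 = 0.01)),
    P1 = regulatory_function(1, gamma = c(O2 = 0.02)),
    P2 = regulatory_function(3, beta = c(tf = 0.4), gamma = c(O2 = 0.01)))
  gA <- gtrn(list(tf = tf, g1 = g1, g2 = g2),
             list(optf = operon("optf", "tf", "Ptf"),
                  op1 = operon("op1", "g1", "P1"),
                  op2 = operon("op2", "g2", "P2")),
             proms)
  moved <- move_gene(gA, "g1", "op2")$gtrn
  # genome B: g1 natively under P2 with the same delta
  gB <- gtrn(list(tf = tf, g1 = g1, g2 = g2),
             list(optf = operon("optf", "tf", "Ptf"),
                  op2 = operon("op2", c("g2", "g1"), "P2")),
             proms)
  env <- o2_env(dv = 12)
  expect_equal(steady_state(moved, env)[["g1"]],
               steady_state(gB, env)[["g1"]], tolerance = 1e-12)

  # source operon deleted when emptied; gene count conserved
  expect_false("op1" %in% names(moved$operons))
  expect_setequal(names(moved$genes), names(gA$genes))
})

test_that("moves to or from constitutive promoters are rejected", {
  g <- cascade_gtrn()  # P1 constitutive, P2 regulated
  expect_error(move_gene(g, "g1", "op2"), "constitutive")
  expect_error(move_gene(g, "g2", "op1"), "constitutive")
})

test_that("tandem addition respects candidacy and the cap of three", {
  w <- small_world(n_genes = 8, seed = 5, tandem_candidate_fraction = 0.5)
  g <- w$g
  cands <- g$tandem_candidates
  skip_if(length(cands) < 4)
  oid <- names(g$operons)[[1]]
  cands <- setdiff(cands, g$operons[[oid]]$primary_promoter)
  for (k in 1:3) g <- add_tandem(g, oid, cands[k])$gtrn
  expect_length(g$operons[[oid]]$tandem_promoters, 3L)
  expect_error(add_tandem(g, oid, cands[4]), "3 tandem")
  # non-candidate promoter rejected
  non_cand <- setdiff(names(w$g$promoters), w$g$tandem_candidates)[1]
  expect_error(add_tandem(w$g, oid, non_cand), "not a tandem candidate")
})

test_that("add/remove and replace compose as documented", {
  w <- small_world(n_genes = 8, seed = 5, tandem_candidate_fraction = 0.5)
  g <- w$g
  oid <- names(g$operons)[[2]]
  cands <- setdiff(g$tandem_candidates, g$operons[[oid]]$primary_promoter)
  skip_if(length(cands) < 2)

  # add then remove restores the original genome
  r_add <- add_tandem(g, oid, cands[1])
  r_rem <- remove_tandem(r_add$gtrn, oid, cands[1])
  expect_true(gtrn_equal(g, r_rem$gtrn))

  # replace == remove-then-add at the effective-regulation level
  g_t <- r_add$gtrn
  g_repl <- replace_tandem(g_t, oid, cands[1], cands[2])$gtrn
  g_two_step <- add_tandem(remove_tandem(g_t, oid, cands[1])$gtrn,
                           oid, cands[2])$gtrn
  rf1 <- effective_regulation(g_repl, oid)
  rf2 <- effective_regulation(g_two_step, oid)
  expect_equal(rf1$alpha, rf2$alpha)
  expect_equal(rf1$beta[sort(names(rf1$beta))],
               rf2$beta[sort(names(rf2$beta))])
  expect_equal(rf1$gamma[sort(names(rf1$gamma))],
               rf2$gamma[sort(names(rf2$gamma))])

  # replacing a promoter by itself changes nothing
  expect_true(gtrn_equal(g_t, replace_tandem(g_t, oid, cands[1],
                                             cands[1])$gtrn))

  # removing from an empty tandem list is rejected; primary never removable
  expect_error(remove_tandem(g, oid, cands[1]), "not in tandem")
  expect_error(remove_tandem(g_t, oid, g$operons[[oid]]$primary_promoter),
               "primary")
})

test_that("every move undoes to structural equality and conserves genes", {
  w <- small_world(n_genes = 10, seed = 8, tandem_candidate_fraction = 0.4)
  g <- w$g
  sch <- annealing_schedule(population = 1, seed = 1)
  set.seed(99)
  for (i in 1:50) {
    prop <- propose(g, sch)
    validate_gtrn(prop$gtrn)
    expect_setequal(names(prop$gtrn$genes), names(g$genes))
    restored <- undo_move(prop$gtrn, prop$record)
    expect_true(gtrn_equal(g, restored))
    g <- prop$gtrn  # walk on, keeps the state space moving
  }
})

test_that("proposal frequencies honor the 10-fold add/remove vs replace rule", {
  w <- small_world(n_genes = 15, seed = 21, tandem_candidate_fraction = 0.5)
  g <- w$g
  # give operons some tandems so all four kinds are available
  set.seed(1)
  for (oid in names(g$operons)[1:8]) {
    cand <- setdiff(g$tandem_candidates, g$operons[[oid]]$primary_promoter)
    g <- add_tandem(g, oid, sample(cand, 1))$gtrn
  }
  sch <- annealing_schedule(population = 1, seed = 1)
  set.seed(42)
  n <- 10000
  kinds <- character(n)
  for (i in seq_len(n)) kinds[i] <- propose(g, sch)$record$kind
  n_ar <- sum(kinds %in% c("add_tandem", "remove_tandem"))
  n_rep <- sum(kinds == "replace_tandem")
  p_ar <- sum(sch$probs[c("add_tandem", "remove_tandem")])
  p_rep <- sch$probs[["replace_tandem"]]
  expect_equal(p_ar / p_rep, 10, tolerance = 1e-9)
  # each frequency within 3 binomial sigma of its target
  expect_lt(abs(n_ar - n * p_ar), 3 * sqrt(n * p_ar * (1 - p_ar)))
  expect_lt(abs(n_rep - n * p_rep), 3 * sqrt(n * p_rep * (1 - p_rep)))
})

test_that("degenerate genomes admit no legal move", {
  # single constitutive operon, no tandem candidates
  g <- single_gene_gtrn()
  sch <- annealing_schedule(population = 1, seed = 1)
  set.seed(7)
  expect_error(propose(g, sch), "no legal")
})

test_that("proposals are reproducible under a fixed seed", {
  w <- small_world(n_genes = 10, seed = 3, tandem_candidate_fraction = 0.4)
  sch <- annealing_schedule(population = 1, seed = 1)
  seq1 <- {
    set.seed(123)
    replicate(20, propose(w$g, sch)$record$kind)
  }
  seq2 <- {
    set.seed(123)
    replicate(20, propose(w$g, sch)$record$kind)
  }
  expect_identical(seq1, seq2)
})

test_that("Metropolis acceptance matches its defining probabilities", {
  # improvements always accepted
  set.seed(5)
  expect_true(all(replicate(100, accept(-1, -0.5, 0.01))))
  expect_true(accept(0, 0, 1e-6))  # ties accepted

  # worsening: empirical rate ~ exp(-1) at delta = -1, t = 1
  set.seed(11)
  n <- 1e5
  acc <- sum(replicate(n, accept(0, -1, 1)))
  p <- exp(-1)
  expect_lt(abs(acc - n * p), 3 * sqrt(n * p * (1 - p)))

  # greedy limit: t -> 0 rejects all worsening moves
  set.seed(12)
  expect_false(any(replicate(200, accept(0, -0.1, 1e-9))))
  expect_error(accept(0, 1, 0), "positive")
})
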