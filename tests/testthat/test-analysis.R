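# Complexity ratios, optimality degree, functional similarity, topology.

test_that("complexity ratios are 1 on identity and count operon-level edges", {
  w <- small_world(n_genes = 10, seed = 14)
  rep_id <- complexity_ratios(w$g, w$g)
  expect_identical(rep_id$xi, 1)
  expect_identical(rep_id$theta, 1)

  # wt: 4 singleton operons each with 1 regulator; ref: 1 operon, 1 regulator
  tf <- gene("tf", 1, categories = "TF")
  mk <- function(merged) {
    gs <- list(tf = tf)
    for (i in 1:4) gs[[paste0("g", i)]] <- gene(paste0("g", i), 1)
    proms <- list(Ptf = regulatory_function(1))
    for (i in 1:4) proms[[paste0("P", i)]] <-
        regulatory_function(1, beta = c(tf = 0.1))
    if (merged) {
      ops <- list(optf = operon("optf", "tf", "Ptf"),
                  op1 = operon("op1", paste0("g", 1:4), "P1"))
    } else {
      ops <- list(optf = operon("optf", "tf", "Ptf"))
      for (i in 1:4) ops[[paste0("op", i)]] <-
          operon(paste0("op", i), paste0("g", i), paste0("P", i))
    }
    gtrn(gs, ops, proms)
  }
  wt <- mk(FALSE); ref <- mk(TRUE)
  out <- complexity_ratios(ref, wt)
  expect_equal(out$xi, 0.25)
  expect_equal(out$theta, 2 / 5)  # 2 operons (incl. the TF's) vs 5

  # wild type without any interaction is rejected
  g0 <- single_gene_gtrn()
  expect_error(complexity_ratios(g0, g0), "no regulatory interactions")
})

test_that("optimality degree is zero at the optimum and sign-correct", {
  # candidate matches wild type exactly at dv=0 but deviates at dv != 0
  wt <- single_gene_gtrn(alpha = 1, delta = 1, gamma = c(O2 = 0.05))
  cand_worse <- single_gene_gtrn(alpha = 1, delta = 1, gamma = c(O2 = 0.02))
  spec <- fitness_spec("all", list(o2_env(0)))
  expect_identical(optimality_degree(cand_worse, wt, spec, o2_env(0)), 0)
  # worse tracking in the target than at the optimum: sub-optimal, xi > 0
  expect_gt(optimality_degree(cand_worse, wt, spec, o2_env(40)), 0)

  # candidate matching better at the target than at the optimum: xi < 0
  cand_shift <- single_gene_gtrn(alpha = 1.5, delta = 1,
                                 gamma = c(O2 = 0.0375))
  # at dv = 40: wt y = 3, cand y = 3 (match); at dv = 0: wt 1 vs cand 1.5
  expect_lt(optimality_degree(cand_shift, wt, spec, o2_env(40)), 0)
})

test_that("optimality degree is antisymmetric under swapping environments", {
  w <- small_world(n_genes = 8, seed = 19)
  g2 <- w$g
  pid <- g2$operons[[1]]$primary_promoter
  g2$promoters[[pid]]$alpha <- g2$promoters[[pid]]$alpha * 1.5
  spec <- fitness_spec("all", w$envs)
  env_a <- w$envs[[2]]
  # xi evaluated optimal->target vs target->optimal differ only in sign:
  # S_exp(opt) - S_exp(a) = -(S_exp(a) - S_exp(opt))
  s_opt_minus_a <- optimality_degree(g2, w$g, spec, env_a)
  wt_fn <- function(env) steady_state(w$g, env)
  # direct recomputation with roles swapped
  spec1 <- fitness_spec("all", list(env_a))
  prof_a <- expression_profile(w$g, list(env_a))
  s_a <- expression_score(g2, prof_a, spec1)
  opt_env <- environment_state(env_a$v_opt, env_a$v_opt)
  prof_o <- expression_profile(w$g, list(opt_env))
  spec0 <- fitness_spec("all", list(opt_env))
  s_o <- expression_score(g2, prof_o, spec0)
  expect_equal(s_opt_minus_a, s_o - s_a, tolerance = 1e-12)
})

test_that("adaptation report averages per-environment degrees", {
  w <- small_world(n_genes = 6, seed = 25)
  g2 <- w$g
  pid <- g2$operons[[2]]$primary_promoter
  g2$promoters[[pid]]$alpha <- g2$promoters[[pid]]$alpha + 0.5
  spec <- fitness_spec("all", w$envs)
  rep <- adaptation_report(g2, w$g, spec, w$envs)
  expect_identical(nrow(rep$per_environment), length(w$envs))
  expect_equal(rep$mean_xi, mean(rep$per_environment$xi))
  # the optimal environment contributes exactly zero
  expect_identical(rep$per_environment$xi[[1]], 0)
})

test_that("functional similarity follows the max-shared-function rule", {
  fns <- list(a = c("F1", "F2"), b = "F1", c = c("F1", "F3"), d = "F4",
              e = character())
  # singleton: 0 by convention
  expect_identical(functional_similarity("a", fns), 0)
  # 4 genes, 3 sharing F1 -> 0.75
  expect_equal(functional_similarity(c("a", "b", "c", "d"), fns), 0.75)
  # all sharing -> 1
  expect_equal(functional_similarity(c("a", "b", "c"), fns), 1)
  # unannotated gene set: 0
  expect_identical(functional_similarity(c("d", "e"), fns), 0.5)
  expect_error(functional_similarity(c("a", "zz"), fns), "zz")
})

test_that("functional similarity matches a brute-force oracle and bounds", {
  brute <- function(gene_ids, fns) {
    if (length(gene_ids) == 1) return(0)
    labels <- unique(unlist(fns[gene_ids]))
    if (!length(labels)) return(0)
    max(vapply(labels, function(f)
      sum(vapply(gene_ids, function(g) f %in% fns[[g]], TRUE)), 0)) /
      length(gene_ids)
  }
  set.seed(31)
  vocab <- sprintf("F%02d", 1:12)
  ids <- sprintf("g%02d", 1:30)
  fns <- stats::setNames(
    lapply(ids, function(i) sample(vocab, sample(0:4, 1))), ids)
  for (rep in 1:200) {
    op_genes <- sample(ids, sample(1:6, 1))
    phi <- functional_similarity(op_genes, fns)
    expect_identical(phi, brute(op_genes, fns))
    expect_true(phi == 0 ||
                  (phi >= 1 / length(op_genes) && phi <= 1))
    # invariant to gene order
    expect_identical(phi, functional_similarity(sample(op_genes), fns))
  }
})

test_that("topology statistics count promoter load, tandems and clustering", {
  w <- small_world(n_genes = 8, seed = 16)
  ts0 <- topology_stats(w$g)
  # singleton genome without tandems: all mass at zero tandems
  expect_identical(unname(ts0$tandem_histogram),
                   c(length(w$g$operons), 0L, 0L, 0L))

  # a promoter driving one 5-gene operon scores the point (1, 5)
  tf <- gene("tf", 1, categories = "TF")
  gs <- list(tf = tf)
  for (i in 1:5) gs[[paste0("g", i)]] <- gene(paste0("g", i), 1)
  g5 <- gtrn(gs,
             list(optf = operon("optf", "tf", "Ptf"),
                  op1 = operon("op1", paste0("g", 1:5), "P1")),
             list(Ptf = regulatory_function(1),
                  P1 = regulatory_function(1, beta = c(tf = 0.1))))
  ts <- topology_stats(g5)
  row <- ts$promoter_load[ts$promoter_load$promoter == "P1", ]
  expect_identical(row$n_operons, 1L)
  expect_identical(row$n_genes, 5L)

  # two TFs co-regulating every operon: clustering coefficient 1
  t1 <- gene("t1", 1, categories = "TF")
  t2 <- gene("t2", 1, categories = "TF")
  ga <- gene("ga", 1); gb <- gene("gb", 1)
  p_co <- regulatory_function(1, beta = c(t1 = 0.1, t2 = -0.1))
  g_co <- gtrn(list(t1 = t1, t2 = t2, ga = ga, gb = gb),
               list(o1 = operon("o1", c("t1", "t2"), "Pc"),
                    o2 = operon("o2", "ga", "Pa"),
                    o3 = operon("o3", "gb", "Pb")),
               list(Pc = regulatory_function(2), Pa = p_co, Pb = p_co))
  expect_identical(topology_stats(g_co)$clustering_coefficient, 1)
})
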