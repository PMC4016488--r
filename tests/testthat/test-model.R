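# Steady state, dynamics and response time of the linear transcription model.

test_that("steady state matches closed forms on hand-built genomes", {
  # isolated gene: y = alpha / delta
  g <- single_gene_gtrn(alpha = 2, delta = 1)
  expect_equal(unname(steady_state(g, null_env())[["g1"]]), 2)

  # environmental drive: y = (alpha + gamma * dv) / delta
  g2 <- single_gene_gtrn(alpha = 1, delta = 1, gamma = c(O2 = 0.2))
  expect_equal(unname(steady_state(g2, o2_env(dv = 5))[["g1"]]), 2)

  # two-gene cascade via forward substitution:
  # y1 = 1, y2 = (0.5 + 0.5 * y1) / 1 = 1
  g3 <- cascade_gtrn(alpha1 = 1, alpha2 = 0.5, b21 = 0.5)
  y <- steady_state(g3, null_env())
  expect_equal(unname(y[c("g1", "g2")]), c(1, 1))
})

test_that("steady state agrees with numerical ODE integration", {
  g <- single_gene_gtrn(alpha = 1, delta = 1, gamma = c(O2 = 0.2))
  env <- o2_env(dv = 5)
  y_alg <- steady_state(g, env)
  tr <- simulate_dynamics(g, env, y0 = c(g1 = 0),
                          t_grid = c(0, 10, 100, 1000))
  expect_equal(unname(tr[nrow(tr), "g1"]), unname(y_alg[["g1"]]),
               tolerance = 1e-8)

  g3 <- cascade_gtrn()
  tr3 <- simulate_dynamics(g3, null_env(), y0 = c(g1 = 0, g2 = 0),
                           t_grid = c(0, 10, 100, 1000))
  expect_equal(unname(tr3[nrow(tr3), ]),
               unname(steady_state(g3, null_env())[colnames(tr3)]),
               tolerance = 1e-8)
})

test_that("unregulated genomes return alpha/delta exactly, any environment", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:8, 1)
    genes <- list(); ops <- list(); proms <- list()
    for (i in seq_len(n)) {
      gid <- paste0("g", i)
      genes[[gid]] <- gene(gid, delta = runif(1, 0.2, 2))
      proms[[paste0("P", i)]] <- regulatory_function(runif(1, 0.1, 4))
      ops[[paste0("op", i)]] <- operon(paste0("op", i), gid, paste0("P", i))
    }
    g <- gtrn(genes, ops, proms)
    y <- steady_state(g, o2_env(dv = runif(1, -50, 50)))
    expected <- vapply(seq_len(n), function(i)
      proms[[paste0("P", i)]]$alpha / genes[[paste0("g", i)]]$delta, 0)
    expect_equal(as.numeric(y), expected)
  }
})

test_that("steady-state response to environmental deviations is affine", {
  w <- small_world(n_genes = 10, seed = 3)
  g <- w$g
  v_opt <- c(O2 = 75, glc = 20)
  env0 <- environment_state(v = v_opt, v_opt = v_opt)
  env1 <- environment_state(v = v_opt + c(O2 = 30, glc = 0), v_opt = v_opt)
  env2 <- environment_state(v = v_opt + c(O2 = 0, glc = -7), v_opt = v_opt)
  env12 <- environment_state(v = v_opt + c(O2 = 30, glc = -7), v_opt = v_opt)
  y0 <- steady_state(g, env0, clip = FALSE)
  d1 <- steady_state(g, env1, clip = FALSE) - y0
  d2 <- steady_state(g, env2, clip = FALSE) - y0
  d12 <- steady_state(g, env12, clip = FALSE) - y0
  expect_equal(unname(d12), unname(d1 + d2), tolerance = 1e-9)
})

test_that("negative solutions are clipped and flagged", {
  # strong negative environmental drive forces y < 0 algebraically
  g <- single_gene_gtrn(alpha = 1, delta = 1, gamma = c(O2 = 0.2))
  y <- steady_state(g, o2_env(dv = -50))
  expect_identical(unname(y[["g1"]]), 0)
  expect_identical(attr(y, "clipped"), "g1")
  y_raw <- steady_state(g, o2_env(dv = -50), clip = FALSE)
  expect_lt(y_raw[["g1"]], 0)
})

test_that("singular systems and unknown factors raise errors", {
  # beta exactly cancelling delta on a self-loop makes D - B singular
  g1 <- gene("g1", 1, categories = "TF")
  p <- regulatory_function(1, beta = c(g1 = 1))
  g <- gtrn(list(g1 = g1), list(op1 = operon("op1", "g1", "P1")),
            list(P1 = p))
  expect_error(steady_state(g, null_env()), "ill-conditioned|singular")

  g2 <- single_gene_gtrn(alpha = 1, delta = 1, gamma = c(O2 = 0.2))
  expect_error(steady_state(g2, null_env()), "O2")
})

test_that("dynamics reproduce the scalar relaxation solution", {
  # y(t) = 1 - exp(-t) for alpha = delta = 1, y0 = 0
  g <- single_gene_gtrn(alpha = 1, delta = 1)
  t_grid <- c(0, 0.5, 1, 2)
  tr <- simulate_dynamics(g, null_env(), y0 = c(g1 = 0), t_grid = t_grid)
  expect_equal(unname(tr[, "g1"]), 1 - exp(-t_grid), tolerance = 1e-7)

  # starting at the fixed point the trajectory is constant
  tr2 <- simulate_dynamics(g, null_env(), y0 = c(g1 = 1),
                           t_grid = c(0, 1, 5))
  expect_equal(unname(tr2[, "g1"]), rep(1, 3), tolerance = 1e-9)
})

test_that("independent genes evolve as concatenated scalar solutions", {
  g <- cascade_gtrn(alpha1 = 1, alpha2 = 2, b21 = 0, d1 = 1, d2 = 0.5)
  t_grid <- seq(0, 3, by = 0.5)
  tr <- simulate_dynamics(g, null_env(), y0 = c(g1 = 0, g2 = 0),
                          t_grid = t_grid)
  expect_equal(unname(tr[, "g1"]), 1 * (1 - exp(-t_grid)), tolerance = 1e-7)
  expect_equal(unname(tr[, "g2"]), (2 / 0.5) * (1 - exp(-0.5 * t_grid)),
               tolerance = 1e-7)
})

test_that("unstable dynamics are flagged, not silently diverged", {
  g1 <- gene("g1", 0.5, categories = "TF")
  p <- regulatory_function(1, beta = c(g1 = 2))  # growth rate 1.5 > 0
  g <- gtrn(list(g1 = g1), list(op1 = operon("op1", "g1", "P1")),
            list(P1 = p))
  expect_warning(
    tr <- simulate_dynamics(g, null_env(), y0 = c(g1 = 0),
                            t_grid = c(0, 1)),
    "unstable")
  expect_true(attr(tr, "unstable"))
})

test_that("response time follows exponential relaxation closed forms", {
  # single gene delta = 1: t* = ln(1/epsilon)
  g <- single_gene_gtrn(alpha = 1, delta = 1, gamma = c(O2 = 0.1))
  t1 <- response_time(g, o2_env(0), o2_env(30), epsilon = 0.05)
  expect_equal(t1, log(1 / 0.05), tolerance = 1e-6)

  # identical environments: zero response time
  expect_identical(response_time(g, o2_env(10), o2_env(10)), 0)

  # doubling delta halves the response time
  g2 <- single_gene_gtrn(alpha = 1, delta = 2, gamma = c(O2 = 0.1))
  t2 <- response_time(g2, o2_env(0), o2_env(30), epsilon = 0.05)
  expect_equal(t2, t1 / 2, tolerance = 1e-6)
})
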