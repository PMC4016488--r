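# ---------------------------------------------------------------------------
# Evaluation metrics for refactored genomes: complexity ratios, adaptation
# optimality degree, operon functional similarity, and regulatory-topology
# statistics.
# ---------------------------------------------------------------------------

# number of operon-level regulatory interactions: operon x TF pairs with a
# nonzero beta in the operon's effective regulation. Environmental (gamma)
# edges are counted separately.
.interaction_counts <- function(g) {
  n_beta <- 0L; n_gamma <- 0L
  for (op in g$operons) {
    rf <- effective_regulation(g, op)
    n_beta <- n_beta + sum(rf$beta != 0)
    n_gamma <- n_gamma + sum(rf$gamma != 0)
  }
  c(beta = n_beta, gamma = n_gamma)
}

#' Complexity reduction of a refactored genome
#'
#' The two headline ratios of refactoring: `xi`, the ratio of
#' regulatory-interaction counts (refactored / wild type), and `theta`, the
#' ratio of operon counts. Interactions are counted at the operon level
#' (operon x TF pairs with nonzero beta in the effective regulation);
#' environmental (gamma) edges are reported separately as diagnostics.
#'
#' @param refactored,wildtype [gtrn()] objects.
#' @return A list of class `complexity_report`: `xi`, `theta`,
#'   `interactions` (named counts for both genomes) and `gamma_ratio`.
#' @export
complexity_ratios <- function(refactored, wildtype) {
  cr <- .interaction_counts(refactored)
  cw <- .interaction_counts(wildtype)
  if (cw[["beta"]] == 0L)
    stop("wild-type genome has no regulatory interactions")
  structure(
    list(xi = cr[["beta"]] / cw[["beta"]],
         theta = length(refactored$operons) / length(wildtype$operons),
         interactions = list(refactored = cr, wildtype = cw),
         gamma_ratio = if (cw[["gamma"]] > 0L)
           cr[["gamma"]] / cw[["gamma"]] else NA_real_),
    class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("<complexity> Xi = %.4g (interactions), Theta = %.4g (operons)\n",
              x$xi, x$theta))
  invisible(x)
}

# wild-type profile provider: accept a gtrn (profile computed on demand) or
# a function(env) -> named expression vector
.wt_profile_fn <- function(wildtype) {
  if (inherits(wildtype, "gtrn")) {
    function(env) steady_state(wildtype, env)
  } else if (is.function(wildtype)) {
    wildtype
  } else stop("wildtype must be a gtrn or a function of an environment")
}

#' Optimality degree in a target environment
#'
#' `xi_dv = S_exp(optimal) - S_exp(target)`: the expression score of the
#' genome against the wild type evaluated in the optimal environment (all
#' deviations zero) minus that in the target environment. Positive values
#' mean the genome tracks the wild type worse in the target than in the
#' optimum (sub-optimal adaptation); negative values mean over-optimality.
#'
#' @param g Candidate [gtrn()].
#' @param wildtype Wild-type [gtrn()] or a function mapping an environment
#'   to the wild-type steady-state expression vector.
#' @param spec A [fitness_spec()] (gene subset and normalization; its
#'   environment list is not used here).
#' @param target_env Target [environment_state()].
#' @return The optimality degree (dimensionless; 0 in the optimal
#'   environment).
#' @export
optimality_degree <- function(g, wildtype, spec, target_env) {
  wt_fn <- .wt_profile_fn(wildtype)
  opt_env <- environment_state(v = target_env$v_opt,
                               v_opt = target_env$v_opt, id = "optimal")
  s_exp_in <- function(env) {
    wt <- wt_fn(env)
    prof <- matrix(wt, ncol = 1L, dimnames = list(names(wt), "e"))
    sp1 <- fitness_spec(gene_subset = spec$gene_subset,
                        environments = list(env),
                        weight_expression = spec$weight_expression,
                        weight_modularity = spec$weight_modularity,
                        epsilon_norm = spec$epsilon_norm)
    expression_score(g, prof, sp1)
  }
  s_exp_in(opt_env) - s_exp_in(target_env)
}

#' Adaptation report over an environment set
#'
#' Computes the optimality degree for every target environment and the mean
#' degree over the set.
#'
#' @inheritParams optimality_degree
#' @param envs List of target [environment_state()] objects.
#' @return A list of class `adaptation_report` with `per_environment`
#'   (data frame: env, xi) and `mean_xi`.
#' @export
adaptation_report <- function(g, wildtype, spec, envs) {
  if (inherits(envs, "gtrn_environment")) envs <- list(envs)
  xi <- vapply(envs, function(e) optimality_degree(g, wildtype, spec, e), 0)
  ids <- vapply(seq_along(envs), function(j) {
    id <- envs[[j]]$id; if (is.na(id)) paste0("env", j) else id
  }, "")
  structure(list(per_environment = data.frame(env = ids, xi = xi),
                 mean_xi = mean(xi)),
            class = "adaptation_report")
}

#' Functional similarity of an operon
#'
#' The fraction of the operon's genes sharing its most common biological
#' function: `Phi_op = max_f |{g in op : f in functions(g)}| / |op|`.
#' Operons containing a single gene score 0, because more than one gene is
#' needed to assess similarity.
#'
#' @param op An operon (a [operon()] object or character vector of gene
#'   ids).
#' @param functions Named list mapping gene id to a character vector of
#'   function labels (possibly empty), or a [gtrn()] whose gene annotations
#'   supply it.
#' @return `Phi_op` in `[0, 1]`.
#' @export
functional_similarity <- function(op, functions) {
  gene_ids <- if (inherits(op, "gtrn_operon")) op$genes else as.character(op)
  if (inherits(functions, "gtrn"))
    functions <- lapply(functions$genes, `[[`, "functions")
  missing <- setdiff(gene_ids, names(functions))
  if (length(missing))
    stop("genes without a function annotation entry: ",
         paste(missing, collapse = ", "))
  if (length(gene_ids) == 1L) return(0)
  labels <- unlist(functions[gene_ids], use.names = FALSE)
  if (!length(labels)) return(0)
  max(table(labels)) / length(gene_ids)
}

#' Regulatory-topology statistics
#'
#' Summarizes the regulatory structure of a genome: how many operons and
#' genes each promoter drives (as primary or tandem), the histogram of
#' tandem-promoter counts per operon, and the average clustering
#' coefficient of the TF co-regulation projection (two TFs linked when
#' they both regulate some operon's effective promoter; TFs whose
#' neighborhood is too small to form a triangle count as fully clustered).
#'
#' @param g A [gtrn()] object.
#' @return A list of class `topology_stats`: `promoter_load` (data frame:
#'   promoter, n_operons, n_genes), `tandem_histogram` (named counts for
#'   0..3 tandems), `clustering_coefficient`.
#' @export
topology_stats <- function(g) {
  pids <- names(g$promoters)
  n_op <- stats::setNames(integer(length(pids)), pids)
  n_gene <- stats::setNames(integer(length(pids)), pids)
  tf_pairs <- list()
  tf_nodes <- character()
  for (op in g$operons) {
    drivers <- c(op$primary_promoter, op$tandem_promoters)
    n_op[drivers] <- n_op[drivers] + 1L
    n_gene[drivers] <- n_gene[drivers] + length(op$genes)
    rf <- effective_regulation(g, op)
    tfs <- names(rf$beta)[rf$beta != 0]
    tf_nodes <- union(tf_nodes, tfs)
    if (length(tfs) >= 2L)
      tf_pairs[[length(tf_pairs) + 1L]] <- t(utils::combn(sort(tfs), 2L))
  }
  tand <- vapply(g$operons, function(op) length(op$tandem_promoters), 0L)
  hist <- vapply(0:3, function(k) sum(tand == k), 0L)
  names(hist) <- as.character(0:3)

  cc <- NA_real_
  if (length(tf_nodes)) {
    edges <- if (length(tf_pairs)) unique(do.call(rbind, tf_pairs)) else
      matrix(character(), ncol = 2L)
    gr <- igraph::graph_from_data_frame(
      as.data.frame(edges, stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = tf_nodes, stringsAsFactors = FALSE))
    loc <- igraph::transitivity(gr, type = "local", isolates = "NaN")
    loc[!is.finite(loc)] <- 1  # degree < 2: vacuously clustered
    cc <- mean(loc)
  }
  structure(
    list(promoter_load = data.frame(promoter = pids,
                                    n_operons = as.integer(n_op),
                                    n_genes = as.integer(n_gene)),
         tandem_histogram = hist,
         clustering_coefficient = cc),
    class = "topology_stats")
}

#' @export
print.topology_stats <- function(x, ...) {
  cat(sprintf("<topology> clustering coefficient %.3f; tandem histogram: %s\n",
              x$clustering_coefficient,
              paste(names(x$tandem_histogram), x$tandem_histogram,
                    sep = ":", collapse = " ")))
  invisible(x)
}
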