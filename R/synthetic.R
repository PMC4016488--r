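# ---------------------------------------------------------------------------
# Synthetic genome and environment generators.
#
# These produce GTRNs with the structure the refactoring method assumes —
# singleton operons under natural promoters, TF and environmental
# regulation, redundant promoter groups that make consolidation possible,
# nucleotide parts for the compiler — so that the whole pipeline is
# testable without any external data.
# ---------------------------------------------------------------------------

.ef_names <- function(n_efs) {
  base <- c("O2", "glc")
  if (n_efs <= 2L) base[seq_len(n_efs)]
  else c(base, paste0("EF", seq(3L, n_efs)))
}

.ef_vopt <- function(factors) {
  vapply(factors, function(f) switch(f, O2 = 75, glc = 20, 10), 0)
}

#' Specify a synthetic genome
#'
#' The defaults emulate the scale features of an enterobacterial genome
#' model: a TF fraction near 330/4298 (about 7.7%) and a 184-label
#' biological-function vocabulary.
#'
#' @param n_genes Number of genes.
#' @param n_tfs Number of transcription-factor genes (< `n_genes`); default
#'   `max(2, round(0.077 * n_genes))`.
#' @param n_efs Number of environmental factors (default 2: oxygen and
#'   glucose uptake).
#' @param regulators_per_promoter_mean Mean number of TF regulators per
#'   promoter group (Poisson; default 1.5).
#' @param redundancy Size of each group of promoters sharing an identical
#'   regulatory function (default 5); `n_genes / redundancy` is the
#'   ground-truth consolidated operon count.
#' @param tandem_candidate_fraction Fraction of promoters eligible for
#'   tandem insertion (default 0.06).
#' @param n_functions Size of the GO-like function vocabulary (default 184).
#' @param seed RNG seed.
#' @return An object of class `synthesis_spec`.
#' @export
synthesis_spec <- function(n_genes = 100L,
                           n_tfs = max(2L, round(0.077 * n_genes)),
                           n_efs = 2L,
                           regulators_per_promoter_mean = 1.5,
                           redundancy = 5L,
                           tandem_candidate_fraction = 0.06,
                           n_functions = 184L,
                           seed = 1L) {
  stopifnot(n_genes >= 2L, n_tfs >= 1L, n_tfs < n_genes, n_efs >= 0L,
            regulators_per_promoter_mean >= 0, redundancy >= 1L,
            tandem_candidate_fraction >= 0, tandem_candidate_fraction <= 1,
            n_functions >= 1L)
  structure(
    list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
         n_efs = as.integer(n_efs),
         regulators_per_promoter_mean = regulators_per_promoter_mean,
         redundancy = as.integer(redundancy),
         tandem_candidate_fraction = tandem_candidate_fraction,
         n_functions = as.integer(n_functions), seed = as.integer(seed)),
    class = "synthesis_spec")
}

.random_orf <- function(n_codons) {
  codons <- apply(matrix(sample(c("A", "C", "G", "T"), 3L * n_codons,
                                replace = TRUE), ncol = 3L),
                  1L, paste, collapse = "")
  # avoid internal stop codons so the ORF body is a clean coding sequence
  codons[codons %in% c("TAA", "TAG", "TGA")] <- "AAA"
  paste0("ATG", paste(codons, collapse = ""))
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic GTRN
#'
#' Builds a stable genome in singleton-operon starting condition: one
#' natural promoter per gene, promoters organized in `redundancy`-sized
#' groups sharing an exactly identical regulatory function (the redundancy
#' that makes consolidation possible), TF and environmental-factor
#' regulation, category tags covering TF/enzyme/stress/defense, GO-like
#' function labels, and nucleotide parts (ORF, RBS, promoter region,
#' terminator) for every element. TF coefficients are globally rescaled so
#' that every promoter's summed |beta| stays below `0.2 * min(delta)`,
#' which keeps the transcription system diagonally dominant — hence
#' nonsingular and stable — under any operon rearrangement and any
#' combination of up to three tandem promoters.
#'
#' @param spec A [synthesis_spec()].
#' @return A [gtrn()] object; identical seeds give identical genomes.
#' @export
generate_gtrn <- function(spec = synthesis_spec()) {
  stopifnot(inherits(spec, "synthesis_spec"))
  old_seed_state <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed_state))
    assign(".Random.seed", old_seed_state, globalenv()))
  set.seed(spec$seed)

  n <- spec$n_genes
  gene_ids <- sprintf("g%03d", seq_len(n))
  tf_ids <- gene_ids[seq_len(spec$n_tfs)]
  efs <- .ef_names(spec$n_efs)
  vocab <- sprintf("F%03d", seq_len(spec$n_functions))

  delta <- exp(stats::runif(n, log(0.1), log(2)))
  strands <- sample(c("+", "-"), n, replace = TRUE, prob = c(0.7, 0.3))
  cat_pool <- c("enzyme", "stress", "defense")

  # promoter parameter groups: ceiling(n / redundancy) distinct functions,
  # each shared verbatim by `redundancy` consecutive promoters
  n_groups <- ceiling(n / spec$redundancy)
  group_of <- rep(seq_len(n_groups), each = spec$redundancy)[seq_len(n)]
  group_params <- vector("list", n_groups)
  for (k in seq_len(n_groups)) {
    alpha <- stats::runif(1, 0.5, 5)
    n_reg <- stats::rpois(1, spec$regulators_per_promoter_mean)
    n_reg <- min(n_reg, length(tf_ids))
    beta <- if (n_reg > 0) {
      stats::setNames(stats::rnorm(n_reg, 0, 1), sample(tf_ids, n_reg))
    } else stats::setNames(numeric(), character())
    gamma <- stats::setNames(numeric(), character())
    if (length(efs) && stats::runif(1) < 0.5) {
      n_g <- sample.int(length(efs), 1L)
      gamma <- stats::setNames(stats::rnorm(n_g, 0, 0.05),
                               sample(efs, n_g))
    }
    group_params[[k]] <- list(alpha = alpha, beta = beta, gamma = gamma)
  }
  # global beta rescale: diagonal dominance with headroom for 3 tandems
  max_abs <- max(c(0, vapply(group_params,
                             function(p) sum(abs(p$beta)), 0)))
  if (max_abs > 0) {
    scale <- (0.2 * min(delta)) / max_abs
    for (k in seq_len(n_groups))
      group_params[[k]]$beta <- group_params[[k]]$beta * scale
  }

  genes <- list(); promoters <- list(); operons <- list()
  store <- character()
  for (i in seq_len(n)) {
    gid <- gene_ids[i]
    pid <- paste0("P_", gid)
    oid <- paste0("op_", gid)
    cats <- sample(cat_pool, 1L)
    if (gid %in% tf_ids) cats <- c("TF", cats)
    funs <- sample(vocab, sample(1:3, 1L))
    genes[[gid]] <- gene(
      id = gid, delta = delta[i], categories = cats, functions = funs,
      orf_seq_ref = paste0("orf_", gid),
      native_rbs_ref = paste0("rbs_", gid), strand = strands[i],
      home_operon = oid)
    gp <- group_params[[group_of[i]]]
    promoters[[pid]] <- regulatory_function(
      alpha = gp$alpha, beta = gp$beta, gamma = gp$gamma,
      region_ref = paste0("prom_", pid))
    operons[[oid]] <- operon(
      id = oid, genes = gid, primary_promoter = pid,
      terminator_ref = paste0("term_", oid), strand = strands[i],
      locus = i)
    store[[paste0("orf_", gid)]] <- .random_orf(sample(30:60, 1L))
    store[[paste0("rbs_", gid)]] <- .random_seq(60L)
    store[[paste0("prom_", pid)]] <- .random_seq(40L)
    store[[paste0("term_", oid)]] <- .random_seq(30L)
  }

  n_cand <- round(spec$tandem_candidate_fraction * n)
  cands <- if (n_cand > 0) sample(names(promoters), n_cand) else character()

  g <- gtrn(genes, operons, promoters, tandem_candidates = cands,
            sequence_store = store)
  for (try in seq_len(20L)) {
    if (spectral_abscissa(g) < 0) return(g)
    # defensive rescale; unreachable under the dominance construction
    for (pid in names(g$promoters))
      g$promoters[[pid]]$beta <- g$promoters[[pid]]$beta * 0.5
  }
  stop("could not generate a stable genome for this synthesis spec")
}

#' Generate perturbation environment sets
#'
#' Emulates the environmental exploration used to test adaptation:
#' `"oxygen"` draws uptake fluxes uniformly from a fully anaerobic
#' condition up to 4-fold the optimal flux of 75 mmol g^-1 h^-1;
#' `"glucose"` draws from minus to plus the optimal uptake of
#' 20 mmol g^-1 h^-1; `"multi"` perturbs every factor jointly (all
#' deviations nonzero). The optimal environment (all fluxes at their
#' optimum) is always included as the first element.
#'
#' @param kind `"oxygen"`, `"glucose"` or `"multi"`.
#' @param n Number of perturbed environments (>= 1).
#' @param seed RNG seed.
#' @param factors Factor ids the genome senses; defaults to the factors the
#'   chosen kind perturbs (`"O2"`, `"glc"`, or both). Factors present but
#'   not perturbed by the kind sit at their optimum.
#' @return List of [environment_state()] objects of length `n + 1`; element
#'   1 is the optimal environment.
#' @export
generate_environments <- function(kind = c("oxygen", "glucose", "multi"),
                                  n = 100L, seed = 1L, factors = NULL) {
  kind <- match.arg(kind)
  stopifnot(n >= 1L)
  if (is.null(factors))
    factors <- switch(kind, oxygen = "O2", glucose = "glc",
                      multi = c("O2", "glc"))
  if (kind == "oxygen" && !"O2" %in% factors) factors <- c("O2", factors)
  if (kind == "glucose" && !"glc" %in% factors) factors <- c("glc", factors)
  v_opt <- .ef_vopt(factors)
  old_seed_state <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed_state))
    assign(".Random.seed", old_seed_state, globalenv()))
  set.seed(seed)

  draw <- function(f) {
    switch(f,
      O2 = stats::runif(1, 0, 4 * 75),
      glc = stats::runif(1, -20, 20),
      stats::runif(1, 0, 2 * v_opt[[f]]))
  }
  envs <- vector("list", n + 1L)
  envs[[1L]] <- environment_state(v = v_opt, v_opt = v_opt, id = "optimal")
  for (j in seq_len(n)) {
    v <- v_opt
    perturbed <- switch(kind, oxygen = "O2", glucose = "glc", multi = factors)
    for (f in perturbed) {
      val <- draw(f)
      while (val == v_opt[[f]]) val <- draw(f)  # multi: dv != 0 for all k
      v[[f]] <- val
    }
    envs[[j + 1L]] <- environment_state(v = v, v_opt = v_opt,
                                        id = sprintf("%s_%03d", kind, j))
  }
  envs
}
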