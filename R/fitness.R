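# ---------------------------------------------------------------------------
# Objective function: expression similarity to wild type + genome modularity.
# ---------------------------------------------------------------------------

#' Define a fitness specification
#'
#' Which genes and environments the expression score is computed over, and
#' how the expression and modularity components are weighted. The gene
#' subset mirrors the four selective pressures used in refactoring runs:
#' the whole genome, or only stress-, defense- or enzyme-tagged genes.
#'
#' @param gene_subset `"all"`, `"stress"`, `"defense"`, `"enzymes"`, or an
#'   explicit character vector of gene ids.
#' @param environments List of [environment_state()] objects.
#' @param weight_expression,weight_modularity Nonnegative weights (default
#'   1 and 1); they may not both be zero.
#' @param epsilon_norm Small positive constant protecting the normalization
#'   when wild-type expression is near zero (default `1e-6`).
#' @return An object of class `fitness_spec`.
#' @export
fitness_spec <- function(gene_subset = "all", environments,
                         weight_expression = 1, weight_modularity = 1,
                         epsilon_norm = 1e-6) {
  if (inherits(environments, "gtrn_environment"))
    environments <- list(environments)
  stopifnot(length(environments) >= 1L)
  if (weight_expression < 0 || weight_modularity < 0)
    stop("weights must be nonnegative")
  if (weight_expression == 0 && weight_modularity == 0)
    stop("weights may not both be zero")
  if (epsilon_norm < 0) stop("epsilon_norm must be >= 0")
  if (is.character(gene_subset) && length(gene_subset) == 1L &&
      !gene_subset %in% c("all", "stress", "defense", "enzymes")) {
    # a single explicit gene id is allowed; keep as-is
  }
  structure(
    list(gene_subset = gene_subset, environments = environments,
         weight_expression = weight_expression,
         weight_modularity = weight_modularity,
         epsilon_norm = epsilon_norm),
    class = "fitness_spec")
}

# resolve a subset keyword to gene ids of a genome
resolve_gene_subset <- function(g, gene_subset) {
  tags <- c(stress = "stress", defense = "defense", enzymes = "enzyme")
  if (length(gene_subset) == 1L && gene_subset %in% c("all", names(tags))) {
    if (gene_subset == "all") return(names(g$genes))
    tag <- tags[[gene_subset]]
    ids <- names(g$genes)[vapply(g$genes, function(gn) tag %in% gn$categories,
                                 TRUE)]
    if (!length(ids)) stop("no genes carry the '", tag, "' category tag")
    return(ids)
  }
  missing <- setdiff(gene_subset, names(g$genes))
  if (length(missing))
    stop("fitness gene subset contains unknown gene(s): ",
         paste(missing, collapse = ", "))
  gene_subset
}

#' Expression-similarity score
#'
#' Mean normalized squared deviation of the candidate's steady-state profile
#' from the wild type over the scored genes and environments, negated so
#' that 0 is a perfect match and more dissimilar profiles score lower:
#' `S_exp = -(1/(|G||E|)) * sum (y_cand - y_wt)^2 / (y_wt^2 + eps)`.
#'
#' @param candidate A [gtrn()] object.
#' @param wildtype_profile An [expression_profile()] matrix covering the
#'   scored genes and environments (rows = gene ids, columns = environment
#'   ids in the order of `spec$environments`).
#' @param spec A [fitness_spec()].
#' @param candidate_profile Optional precomputed candidate profile (same
#'   shape as `wildtype_profile`); computed from `candidate` when `NULL`.
#' @return `S_exp` (a number \eqn{\le 0}; 0 iff profiles agree exactly on
#'   the subset).
#' @export
expression_score <- function(candidate, wildtype_profile, spec,
                             candidate_profile = NULL) {
  ids <- resolve_gene_subset(candidate, spec$gene_subset)
  missing <- setdiff(ids, rownames(wildtype_profile))
  if (length(missing))
    stop("wild-type profile lacks gene(s): ", paste(missing, collapse = ", "))
  nE <- length(spec$environments)
  if (ncol(wildtype_profile) < nE)
    stop("wild-type profile lacks environments: has ", ncol(wildtype_profile),
         ", spec needs ", nE)
  if (is.null(candidate_profile))
    candidate_profile <- expression_profile(candidate, spec$environments)
  Yw <- wildtype_profile[ids, seq_len(nE), drop = FALSE]
  Yc <- candidate_profile[ids, seq_len(nE), drop = FALSE]
  -mean((Yc - Yw)^2 / (Yw^2 + spec$epsilon_norm))
}

#' Genome modularity score
#'
#' Normalized entropy of the operon size distribution, negated:
#' `S_mod = -H / H_max` with `H = -sum p_op log p_op`,
#' `p_op = |genes in op| / N` and `H_max = log(#operons)`. The score is 0
#' (maximal) when all genes share one operon and -1 (minimal) when every
#' gene sits in its own operon; consolidating genes into fewer operons
#' raises it. A single-operon genome scores 0 by convention.
#'
#' @param g A [gtrn()] object (or an integer vector of operon sizes).
#' @return `S_mod` in `[-1, 0]`.
#' @export
modularity_score <- function(g) {
  sizes <- if (inherits(g, "gtrn")) {
    vapply(g$operons, function(op) length(op$genes), 0L)
  } else {
    as.integer(g)
  }
  if (!length(sizes) || sum(sizes) == 0L) stop("empty genome")
  if (length(sizes) == 1L) return(0)
  p <- sizes / sum(sizes)
  H <- -sum(p * log(p))
  -H / log(length(sizes))
}

#' Total fitness of a candidate genome
#'
#' Weighted combination of expression similarity to the wild type and
#' genome modularity; higher is better.
#'
#' @inheritParams expression_score
#' @return A list of class `fitness_value` with components `s_exp`, `s_mod`
#'   and `s_total = w_exp * s_exp + w_mod * s_mod`.
#' @export
total_fitness <- function(candidate, wildtype_profile, spec,
                          candidate_profile = NULL) {
  s_exp <- expression_score(candidate, wildtype_profile, spec,
                            candidate_profile)
  s_mod <- modularity_score(candidate)
  structure(
    list(s_exp = s_exp, s_mod = s_mod,
         s_total = spec$weight_expression * s_exp +
           spec$weight_modularity * s_mod),
    class = "fitness_value")
}

#' @export
print.fitness_value <- function(x, ...) {
  cat(sprintf("<fitness> S_exp = %.6g, S_mod = %.6g, S = %.6g\n",
              x$s_exp, x$s_mod, x$s_total))
  invisible(x)
}
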