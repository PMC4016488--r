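# ---------------------------------------------------------------------------
# Core genome (GTRN) data structures.
#
# A GTRN is the full genotype handled by the optimizer and the compiler:
# genes with degradation rates and annotations, operons grouping genes under
# a primary promoter (plus up to three tandem promoters), promoters carrying
# a linear regulatory function (alpha, beta, gamma), a set of promoters
# eligible for tandem insertion, and a sequence store holding the nucleotide
# parts (ORFs, RBSs, promoter regions, terminators).
# ---------------------------------------------------------------------------

#' Create a gene
#'
#' A gene carries its degradation/dilution rate constant `delta` (h^-1), its
#' functional annotations, and references into the genome sequence store for
#' its ORF and native ribosome binding site.
#'
#' @param id Gene identifier (unique genome-wide).
#' @param delta Degradation and dilution rate constant, h^-1, strictly
#'   positive.
#' @param categories Character vector of category tags; recognised tags are
#'   `"TF"`, `"enzyme"`, `"stress"`, `"defense"`.
#' @param functions Character vector of biological function labels (GO-like).
#' @param orf_seq_ref Key of the ORF sequence in the sequence store.
#' @param native_rbs_ref Key of the native RBS sequence in the sequence store.
#' @param strand `"+"` or `"-"`.
#' @param home_operon Id of the operon the gene is native to (used by the
#'   sequence compiler to decide whether the gene keeps its native RBS);
#'   `NA` when unknown.
#' @return An object of class `gtrn_gene`.
#' @export
gene <- function(id, delta, categories = character(), functions = character(),
                 orf_seq_ref = NA_character_, native_rbs_ref = NA_character_,
                 strand = "+", home_operon = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= 0) {
    stop("gene '", id, "': delta must be a single positive finite number")
  }
  if (!strand %in% c("+", "-")) stop("gene '", id, "': strand must be '+' or '-'")
  structure(
    list(id = id, delta = as.numeric(delta),
         categories = unique(as.character(categories)),
         functions = unique(as.character(functions)),
         orf_seq_ref = orf_seq_ref, native_rbs_ref = native_rbs_ref,
         strand = strand, home_operon = home_operon),
    class = "gtrn_gene")
}

#' Create a promoter regulatory function
#'
#' A promoter's contribution to the transcription ODE of every gene it
#' drives: a constitutive rate `alpha`, signed transcription-factor
#' coefficients `beta` (keyed by regulator gene id), and signed
#' environmental-factor coefficients `gamma` (keyed by factor id). A promoter
#' is constitutive exactly when it has no `beta` and no `gamma` terms.
#'
#' @param alpha Constitutive transcription rate (expression h^-1, >= 0).
#' @param beta Named numeric vector: regulator gene id -> coefficient (h^-1).
#' @param gamma Named numeric vector: environmental factor id -> coefficient
#'   (expression h^-1 per mmol g^-1 h^-1).
#' @param region_ref Optional key of the promoter-region sequence in the
#'   sequence store.
#' @return An object of class `regulatory_function` with an
#'   `is_constitutive` field.
#' @export
regulatory_function <- function(alpha, beta = numeric(), gamma = numeric(),
                                region_ref = NA_character_) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0) {
    stop("alpha must be a single nonnegative finite number")
  }
  beta <- unlist(beta); gamma <- unlist(gamma)
  if (length(beta) == 0L) beta <- stats::setNames(numeric(), character())
  if (length(gamma) == 0L) gamma <- stats::setNames(numeric(), character())
  if (length(beta) && (is.null(names(beta)) || any(!nzchar(names(beta)))))
    stop("beta coefficients must be named by regulator gene id")
  if (length(gamma) && (is.null(names(gamma)) || any(!nzchar(names(gamma)))))
    stop("gamma coefficients must be named by environmental factor id")
  structure(
    list(alpha = as.numeric(alpha), beta = beta, gamma = gamma,
         is_constitutive = length(beta) == 0L && length(gamma) == 0L,
         region_ref = region_ref),
    class = "regulatory_function")
}

#' Create an operon
#'
#' The transcription unit: an ordered, non-empty list of gene ids driven by a
#' primary promoter, optionally extended by up to three tandem promoters
#' whose regulatory functions combine additively with the primary's.
#'
#' @param id Operon identifier.
#' @param genes Ordered character vector of member gene ids (first element is
#'   the first cistron).
#' @param primary_promoter Promoter id of the native/primary promoter.
#' @param tandem_promoters Ordered character vector of tandem promoter ids
#'   (at most 3; never containing the primary).
#' @param terminator_ref Sequence-store key of the terminator.
#' @param strand `"+"` or `"-"`.
#' @param locus Numeric rank of the operon's original chromosomal position
#'   (primary promoter locus); used to order operons in compiled output.
#' @return An object of class `gtrn_operon`.
#' @export
operon <- function(id, genes, primary_promoter,
                   tandem_promoters = character(),
                   terminator_ref = NA_character_, strand = "+",
                   locus = NA_real_) {
  genes <- as.character(genes)
  tandem_promoters <- as.character(tandem_promoters)
  if (length(genes) == 0L) stop("operon '", id, "': gene list must be non-empty")
  if (anyDuplicated(genes)) stop("operon '", id, "': duplicated gene ids")
  if (length(tandem_promoters) > 3L)
    stop("operon '", id, "': at most 3 tandem promoters are allowed")
  if (primary_promoter %in% tandem_promoters)
    stop("operon '", id, "': primary promoter cannot also be in tandem")
  if (!strand %in% c("+", "-")) stop("operon '", id, "': bad strand")
  structure(
    list(id = id, genes = genes, primary_promoter = primary_promoter,
         tandem_promoters = tandem_promoters,
         terminator_ref = terminator_ref, strand = strand,
         locus = as.numeric(locus)),
    class = "gtrn_operon")
}

#' Create an environment
#'
#' An environment is a set of uptake fluxes `v` together with their optimal
#' values `v_opt` (both mmol g^-1 h^-1). The model is driven by the
#' deviations `dv = v - v_opt`.
#'
#' @param v Named numeric vector: factor id -> uptake flux.
#' @param v_opt Named numeric vector: factor id -> optimal uptake flux; must
#'   cover every name in `v`.
#' @param id Optional environment label.
#' @return An object of class `gtrn_environment` with a precomputed `dv`.
#' @export
environment_state <- function(v, v_opt, id = NA_character_) {
  v <- unlist(v); v_opt <- unlist(v_opt)
  if (length(v) && (is.null(names(v)) || any(!nzchar(names(v)))))
    stop("v must be named by factor id")
  if (length(v_opt) && (is.null(names(v_opt)) || any(!nzchar(names(v_opt)))))
    stop("v_opt must be named by factor id")
  missing <- setdiff(names(v), names(v_opt))
  if (length(missing))
    stop("environment: factors without an optimum: ",
         paste(missing, collapse = ", "))
  dv <- stats::setNames(as.numeric(v) - as.numeric(v_opt[names(v)]), names(v))
  structure(list(id = id, v = v, v_opt = v_opt, dv = dv),
            class = "gtrn_environment")
}

#' Assemble a GTRN genome
#'
#' @param genes Named list of [gene()] objects (names = gene ids).
#' @param operons Named list of [operon()] objects (names = operon ids).
#' @param promoters Named list of [regulatory_function()] objects
#'   (names = promoter ids).
#' @param tandem_candidates Character vector of promoter ids eligible for
#'   tandem insertion.
#' @param sequence_store Named character vector of nucleotide sequences.
#' @param validate Check all structural invariants (default `TRUE`).
#' @return An object of class `gtrn`.
#' @export
gtrn <- function(genes, operons, promoters,
                 tandem_candidates = character(),
                 sequence_store = character(), validate = TRUE) {
  if (is.null(names(genes))) names(genes) <- vapply(genes, `[[`, "", "id")
  if (is.null(names(operons))) names(operons) <- vapply(operons, `[[`, "", "id")
  g <- structure(
    list(genes = genes, operons = operons, promoters = promoters,
         tandem_candidates = sort(unique(as.character(tandem_candidates))),
         sequence_store = sequence_store),
    class = "gtrn")
  if (validate) validate_gtrn(g)
  g
}

#' Validate GTRN structural invariants
#'
#' Checks that every gene belongs to exactly one operon, that all promoter
#' references resolve, the 3-tandem cap, the primary-not-in-tandem rule, and
#' the constitutivity flags.
#'
#' @param g A [gtrn()] object.
#' @return `g`, invisibly; errors describe the first violation found.
#' @export
validate_gtrn <- function(g) {
  stopifnot(inherits(g, "gtrn"))
  gene_ids <- names(g$genes)
  if (anyDuplicated(gene_ids)) stop("duplicated gene ids")
  membership <- unlist(lapply(g$operons, `[[`, "genes"), use.names = FALSE)
  dup <- membership[duplicated(membership)]
  if (length(dup))
    stop("genes in more than one operon: ", paste(unique(dup), collapse = ", "))
  orphan <- setdiff(gene_ids, membership)
  if (length(orphan))
    stop("genes not assigned to any operon: ", paste(orphan, collapse = ", "))
  unknown <- setdiff(membership, gene_ids)
  if (length(unknown))
    stop("operons reference unknown genes: ", paste(unknown, collapse = ", "))
  for (op in g$operons) {
    proms <- c(op$primary_promoter, op$tandem_promoters)
    bad <- setdiff(proms, names(g$promoters))
    if (length(bad))
      stop("operon '", op$id, "' references unknown promoter(s): ",
           paste(bad, collapse = ", "))
    if (length(op$tandem_promoters) > 3L)
      stop("operon '", op$id, "' exceeds the 3-tandem-promoter cap")
    if (op$primary_promoter %in% op$tandem_promoters)
      stop("operon '", op$id, "': primary promoter listed in tandem")
  }
  badc <- setdiff(g$tandem_candidates, names(g$promoters))
  if (length(badc))
    stop("tandem candidates not in promoter set: ", paste(badc, collapse = ", "))
  for (pid in names(g$promoters)) {
    p <- g$promoters[[pid]]
    if (p$is_constitutive != (length(p$beta) == 0L && length(p$gamma) == 0L))
      stop("promoter '", pid, "': is_constitutive flag inconsistent")
  }
  invisible(g)
}

#' Effective regulation of an operon
#'
#' Tandem promoters combine strictly additively with the primary promoter:
#' the operon's effective regulatory function is the elementwise sum of
#' `alpha`, `beta` and `gamma` over the primary and all tandem promoters.
#' Every gene in the operon is governed by this summed function.
#'
#' @param g A [gtrn()] object.
#' @param op An operon id or a [operon()] object belonging to `g`.
#' @return A [regulatory_function()] (the sum); its `is_constitutive` flag
#'   reflects the summed terms.
#' @export
effective_regulation <- function(g, op) {
  if (is.character(op)) {
    opid <- op
    op <- g$operons[[opid]]
    if (is.null(op)) stop("unknown operon '", opid, "'")
  }
  pids <- c(op$primary_promoter, op$tandem_promoters)
  missing <- setdiff(pids, names(g$promoters))
  if (length(missing))
    stop("operon '", op$id, "': unknown promoter id(s) ",
         paste(missing, collapse = ", "))
  alpha <- 0
  beta <- stats::setNames(numeric(), character())
  gamma <- stats::setNames(numeric(), character())
  for (pid in pids) {
    p <- g$promoters[[pid]]
    alpha <- alpha + p$alpha
    beta <- .add_named(beta, p$beta)
    gamma <- .add_named(gamma, p$gamma)
  }
  regulatory_function(alpha, beta, gamma)
}

# elementwise sum of two named numeric vectors (union of names)
.add_named <- function(a, b) {
  if (!length(b)) return(a)
  if (!length(a)) return(b)
  keys <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(keys)), keys)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + b
  out
}

#' Split a genome into singleton operons
#'
#' Rebuilds the genome so that each gene sits alone in its own operon under
#' its current effective primary promoter — the optimizer's default starting
#' condition (each gene controlled only by its natural promoter). Tandem
#' promoters are dropped; per-gene operons are named `<operon>.<gene>` when
#' splitting a multi-gene operon.
#'
#' @param g A [gtrn()] object.
#' @return A [gtrn()] with one gene per operon.
#' @export
explode_operons <- function(g) {
  new_ops <- list()
  for (op in g$operons) {
    if (length(op$genes) == 1L && length(op$tandem_promoters) == 0L) {
      new_ops[[op$id]] <- op
      next
    }
    for (i in seq_along(op$genes)) {
      gid <- op$genes[[i]]
      oid <- if (length(op$genes) == 1L) op$id else paste0(op$id, ".", gid)
      new_ops[[oid]] <- operon(
        id = oid, genes = gid, primary_promoter = op$primary_promoter,
        terminator_ref = op$terminator_ref, strand = op$strand,
        locus = op$locus + (i - 1L) / length(op$genes))
    }
  }
  gtrn(g$genes, new_ops, g$promoters, g$tandem_candidates, g$sequence_store)
}

#' Structural equality of two genomes
#'
#' Compares genes (all fields), operon structure (membership order, promoter
#' assignments, strand, terminator), the regulatory functions of every
#' promoter referenced by either genome, tandem-candidate sets, and the
#' sequence-store entries referenced by the genomes. Numeric fields are
#' compared exactly.
#'
#' @param a,b [gtrn()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
gtrn_equal <- function(a, b) {
  isTRUE(all.equal(.gtrn_canonical(a), .gtrn_canonical(b), tolerance = 0))
}

# canonical representation: sorted names, only referenced store entries
.gtrn_canonical <- function(g) {
  refs <- character()
  for (gn in g$genes) refs <- c(refs, gn$orf_seq_ref, gn$native_rbs_ref)
  for (op in g$operons) refs <- c(refs, op$terminator_ref)
  for (p in g$promoters) refs <- c(refs, p$region_ref)
  refs <- refs[!is.na(refs)]
  store <- g$sequence_store[sort(intersect(refs, names(g$sequence_store)))]
  norm_rf <- function(p) {
    list(alpha = p$alpha, beta = p$beta[order(names(p$beta))],
         gamma = p$gamma[order(names(p$gamma))],
         is_constitutive = p$is_constitutive, region_ref = p$region_ref)
  }
  ops <- lapply(g$operons[sort(names(g$operons))], function(op) {
    op$locus <- NULL  # layout rank, not structure
    op
  })
  list(genes = g$genes[sort(names(g$genes))],
       operons = ops,
       promoters = lapply(g$promoters[sort(names(g$promoters))], norm_rf),
       tandem_candidates = sort(unique(g$tandem_candidates)),
       store = store)
}

#' Locate the operon containing a gene
#'
#' @param g A [gtrn()] object.
#' @param gene_id A gene id.
#' @return The operon id, or an error if the gene is unknown.
#' @export
operon_of <- function(g, gene_id) {
  for (op in g$operons) if (gene_id %in% op$genes) return(op$id)
  stop("gene '", gene_id, "' not found in any operon")
}

#' @export
print.gtrn <- function(x, ...) {
  n_tand <- sum(vapply(x$operons, function(o) length(o$tandem_promoters), 0L))
  cat(sprintf(
    "<gtrn> %d genes in %d operons; %d promoters (%d tandem candidates); %d tandem placements; %d sequence parts\n",
    length(x$genes), length(x$operons), length(x$promoters),
    length(x$tandem_candidates), n_tand, length(x$sequence_store)))
  invisible(x)
}
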