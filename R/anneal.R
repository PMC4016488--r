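# ---------------------------------------------------------------------------
# Monte Carlo Simulated Annealing over GTRN space.
#
# A population of independent chains starts from the wild-type genome in
# singleton-operon form (each gene under its natural promoter), proposes
# the four transcriptional modifications with configured probabilities,
# scores each candidate with the combined expression/modularity objective,
# and accepts by the Metropolis rule under an exponentially decaying
# temperature.
# ---------------------------------------------------------------------------

#' Define an annealing schedule
#'
#' @param t0 Initial temperature, in fitness units (> 0).
#' @param cooling Exponential decay factor applied per iteration,
#'   `T(n) = t0 * cooling^n`, with `0 < cooling < 1`.
#' @param iterations Number of proposal steps per chain.
#' @param population Number of independent chains ("cells"); default 10.
#' @param p_move_gene,p_add,p_remove,p_replace Proposal probabilities of the
#'   four move types; renormalized to sum to 1. The defaults keep
#'   add/remove tandem proposals 10-fold more likely than replacements.
#' @param seed Master RNG seed; per-chain streams are derived from it.
#' @return An object of class `annealing_schedule`.
#' @export
annealing_schedule <- function(t0 = 1, cooling = 0.999, iterations = 20000L,
                               population = 10L, p_move_gene = 0.60,
                               p_add = 0.18, p_remove = 0.18,
                               p_replace = 0.036, seed = 1L) {
  stopifnot(t0 > 0, cooling > 0, cooling < 1, iterations >= 0,
            population >= 1)
  p <- c(move_gene = p_move_gene, add_tandem = p_add,
         remove_tandem = p_remove, replace_tandem = p_replace)
  if (any(p < 0) || sum(p) <= 0) stop("move probabilities must be nonnegative")
  structure(
    list(t0 = t0, cooling = cooling, iterations = as.integer(iterations),
         population = as.integer(population), probs = p / sum(p),
         seed = as.integer(seed)),
    class = "annealing_schedule")
}

# operon ids whose primary promoter is non-constitutive
.nonconstitutive_operons <- function(g) {
  keep <- vapply(g$operons, function(op) {
    !g$promoters[[op$primary_promoter]]$is_constitutive
  }, TRUE)
  names(g$operons)[keep]
}

#' Propose one random transcriptional modification
#'
#' Draws a move type from the schedule's probabilities and uniformly random
#' valid actors for it; when the drawn type has no valid actor the type is
#' resampled (bounded retries). Uses R's global RNG stream.
#'
#' @param g A [gtrn()] object.
#' @param schedule An [annealing_schedule()].
#' @param max_retries Resampling bound before giving up (default 100).
#' @return `list(gtrn, record)` as returned by the selected move.
#' @export
propose <- function(g, schedule, max_retries = 100L) {
  kinds <- names(schedule$probs)
  for (try in seq_len(max_retries)) {
    kind <- sample(kinds, 1L, prob = schedule$probs)
    res <- switch(kind,
      move_gene = {
        ops <- .nonconstitutive_operons(g)
        if (length(ops) < 2L) NULL else {
          src <- ops[sample.int(length(ops), 1L)]
          gene_pool <- g$operons[[src]]$genes
          gid <- gene_pool[sample.int(length(gene_pool), 1L)]
          dests <- setdiff(ops, src)
          dest <- dests[sample.int(length(dests), 1L)]
          move_gene(g, gid, dest)
        }
      },
      add_tandem = {
        if (!length(g$tandem_candidates)) NULL else {
          ok <- names(g$operons)[vapply(g$operons, function(op) {
            length(op$tandem_promoters) < 3L &&
              length(setdiff(g$tandem_candidates, op$primary_promoter)) > 0L
          }, TRUE)]
          if (!length(ok)) NULL else {
            oid <- ok[sample.int(length(ok), 1L)]
            cand <- setdiff(g$tandem_candidates,
                            g$operons[[oid]]$primary_promoter)
            add_tandem(g, oid, cand[sample.int(length(cand), 1L)])
          }
        }
      },
      remove_tandem = {
        ok <- names(g$operons)[vapply(g$operons, function(op) {
          length(op$tandem_promoters) > 0L
        }, TRUE)]
        if (!length(ok)) NULL else {
          oid <- ok[sample.int(length(ok), 1L)]
          tps <- g$operons[[oid]]$tandem_promoters
          remove_tandem(g, oid, tps[sample.int(length(tps), 1L)])
        }
      },
      replace_tandem = {
        ok <- names(g$operons)[vapply(g$operons, function(op) {
          length(op$tandem_promoters) > 0L
        }, TRUE)]
        if (!length(ok) || !length(g$tandem_candidates)) NULL else {
          oid <- ok[sample.int(length(ok), 1L)]
          tps <- g$operons[[oid]]$tandem_promoters
          old <- tps[sample.int(length(tps), 1L)]
          cand <- setdiff(g$tandem_candidates,
                          g$operons[[oid]]$primary_promoter)
          if (!length(cand)) NULL else
            replace_tandem(g, oid, old, cand[sample.int(length(cand), 1L)])
        }
      })
    if (!is.null(res)) return(res)
  }
  stop("no legal transcriptional modification could be proposed")
}

#' Metropolis acceptance rule
#'
#' An improving candidate (`s_new >= s_old`) is always accepted; a worsening
#' one is accepted with probability `exp((s_new - s_old) / t)`.
#'
#' @param s_old,s_new Old and proposed objective values (higher is better).
#' @param t Temperature (> 0).
#' @return Logical: accept the candidate. Uses R's global RNG stream.
#' @export
accept <- function(s_old, s_new, t) {
  if (t <= 0) stop("temperature must be positive")
  if (s_new >= s_old) return(TRUE)
  stats::runif(1) < exp((s_new - s_old) / t)
}

# refresh the model-matrix rows of the genes governed by one operon
.mm_refresh_operon <- function(mm, g, opid) {
  op <- g$operons[[opid]]
  rf <- effective_regulation(g, op)
  rows <- op$genes
  mm$alpha[rows] <- rf$alpha
  mm$B[rows, ] <- 0
  if (length(rf$beta))
    mm$B[rows, names(rf$beta)] <-
      matrix(rf$beta, length(rows), length(rf$beta), byrow = TRUE)
  if (ncol(mm$G)) {
    mm$G[rows, ] <- 0
    if (length(rf$gamma))
      mm$G[rows, names(rf$gamma)] <-
        matrix(rf$gamma, length(rows), length(rf$gamma), byrow = TRUE)
  }
  mm
}

# refresh only the moved gene's rows (its new regulation = dest operon's)
.mm_refresh_gene <- function(mm, g, gid, opid) {
  rf <- effective_regulation(g, g$operons[[opid]])
  mm$alpha[gid] <- rf$alpha
  mm$B[gid, ] <- 0
  if (length(rf$beta)) mm$B[gid, names(rf$beta)] <- rf$beta
  if (ncol(mm$G)) {
    mm$G[gid, ] <- 0
    if (length(rf$gamma)) mm$G[gid, names(rf$gamma)] <- rf$gamma
  }
  mm
}

# candidate profile from prebuilt matrices (clipped), given a dv matrix
# (factors x environments)
.profile_from_mm <- function(mm, dvmat) {
  n <- length(mm$gene_ids)
  rhs <- matrix(mm$alpha, n, ncol(dvmat))
  if (ncol(mm$G)) rhs <- rhs + mm$G %*% dvmat
  A <- diag(mm$delta, nrow = n) - mm$B
  Y <- solve(A, rhs)
  Y[Y < 0] <- 0
  rownames(Y) <- mm$gene_ids
  Y
}

#' Refactor a genome by simulated annealing
#'
#' Runs `schedule$population` independent annealing chains over the space of
#' operon rearrangements and tandem-promoter edits, scoring candidates
#' against the wild-type expression profile on the fitness spec's gene
#' subset and environments. By default each chain starts from the genome in
#' singleton-operon form (every gene under its natural promoter alone);
#' `start = "as_is"` starts from the wild-type operon structure instead.
#'
#' @param wildtype The wild-type [gtrn()]; its expression profile under the
#'   spec's environments is the design target.
#' @param spec A [fitness_spec()].
#' @param schedule An [annealing_schedule()].
#' @param start `"singleton"` (default) or `"as_is"`.
#' @param trace_every Record the objective every this many iterations
#'   (default 1 = full trace).
#' @return A list of class `anneal_result`, one element per chain, each with
#'   `best` (best-so-far [gtrn()]), `best_fitness` ([total_fitness()] value),
#'   `final` (the chain's last genome), `trace` (data frame: iteration,
#'   temperature, s_exp, s_mod, s_total, accepted), `acceptance_rate`, and
#'   `seed` (the chain's derived seed). The wild-type profile is attached as
#'   attribute `wildtype_profile`.
#' @export
anneal <- function(wildtype, spec, schedule, start = c("singleton", "as_is"),
                   trace_every = 1L) {
  start <- match.arg(start)
  validate_gtrn(wildtype)
  wt_profile <- expression_profile(wildtype, spec$environments)
  g0 <- if (start == "singleton") explode_operons(wildtype) else wildtype
  ids <- resolve_gene_subset(g0, spec$gene_subset)
  eps <- spec$epsilon_norm
  Yw <- wt_profile[ids, , drop = FALSE]
  denom <- Yw^2 + eps
  all_factors <- sort(unique(unlist(lapply(g0$promoters,
                                           function(p) names(p$gamma)))))
  mm0 <- model_matrices(g0, factors = all_factors)
  dvmat <- vapply(spec$environments, function(e) .model_dv(mm0, e),
                  numeric(length(all_factors)))
  dvmat <- matrix(dvmat, nrow = length(all_factors),
                  ncol = length(spec$environments))
  s_exp_of <- function(mm) {
    Yc <- .profile_from_mm(mm, dvmat)
    -mean((Yc[ids, , drop = FALSE] - Yw)^2 / denom)
  }
  old_seed_state <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed_state))
    assign(".Random.seed", old_seed_state, globalenv()))
  set.seed(schedule$seed)
  chain_seeds <- sample.int(.Machine$integer.max, schedule$population)

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    g <- g0
    mm <- mm0
    s_exp <- s_exp_of(mm)
    s_mod <- modularity_score(g)
    s_total <- spec$weight_expression * s_exp + spec$weight_modularity * s_mod
    best <- g; best_val <- list(s_exp = s_exp, s_mod = s_mod,
                                s_total = s_total)
    iters <- schedule$iterations
    keep <- if (iters == 0L) integer(0) else
      unique(c(seq(1L, iters, by = max(1L, as.integer(trace_every))), iters))
    tr_n <- length(keep)
    tr <- list(iteration = integer(tr_n), temperature = numeric(tr_n),
               s_exp = numeric(tr_n), s_mod = numeric(tr_n),
               s_total = numeric(tr_n), accepted = logical(tr_n))
    ki <- 1L
    n_acc <- 0L
    temp <- schedule$t0
    for (it in seq_len(iters)) {
      temp <- temp * schedule$cooling
      prop <- tryCatch(propose(g, schedule), error = function(e) NULL)
      acc <- FALSE
      if (!is.null(prop)) {
        g_new <- prop$gtrn
        rec <- prop$record
        mm_new <- switch(rec$kind,
          move_gene = .mm_refresh_gene(mm, g_new, rec$actors$gene,
                                       rec$actors$to),
          .mm_refresh_operon(mm, g_new, rec$actors$operon))
        se_new <- tryCatch(s_exp_of(mm_new), error = function(e) NULL)
        if (!is.null(se_new)) {
          sm_new <- modularity_score(g_new)
          st_new <- spec$weight_expression * se_new +
            spec$weight_modularity * sm_new
          if (accept(s_total, st_new, temp)) {
            acc <- TRUE
            g <- g_new; mm <- mm_new
            s_exp <- se_new; s_mod <- sm_new; s_total <- st_new
            n_acc <- n_acc + 1L
            if (s_total > best_val$s_total) {
              best <- g
              best_val <- list(s_exp = s_exp, s_mod = s_mod,
                               s_total = s_total)
            }
          }
        }
      }
      if (ki <= tr_n && it == keep[ki]) {
        tr$iteration[ki] <- it; tr$temperature[ki] <- temp
        tr$s_exp[ki] <- s_exp; tr$s_mod[ki] <- s_mod
        tr$s_total[ki] <- s_total; tr$accepted[ki] <- acc
        ki <- ki + 1L
      }
    }
    list(best = best,
         best_fitness = structure(best_val, class = "fitness_value"),
         final = g, trace = as.data.frame(tr),
         acceptance_rate = if (iters > 0L) n_acc / iters else NA_real_,
         seed = chain_seed)
  }

  out <- lapply(chain_seeds, run_chain)
  attr(out, "wildtype_profile") <- wt_profile
  class(out) <- "anneal_result"
  out
}

#' @export
print.anneal_result <- function(x, ...) {
  cat(sprintf("<anneal_result> %d chain(s)\n", length(x)))
  for (i in seq_along(x)) {
    r <- x[[i]]
    cat(sprintf(
      "  chain %d: best S = %.6g (S_exp = %.3g, S_mod = %.3g), %d operons, acceptance %.1f%%\n",
      i, r$best_fitness$s_total, r$best_fitness$s_exp, r$best_fitness$s_mod,
      length(r$best$operons), 100 * r$acceptance_rate))
  }
  invisible(x)
}
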