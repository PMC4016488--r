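# ---------------------------------------------------------------------------
# The four transcriptional modifications explored by the optimizer:
# moving a gene between operons, and adding / removing / replacing a tandem
# promoter. Each returns the edited genome plus a move_record carrying
# enough information to undo the edit exactly.
# ---------------------------------------------------------------------------

new_move_record <- function(kind, actors, inverse) {
  structure(list(kind = kind, actors = actors, inverse = inverse),
            class = "move_record")
}

#' @export
print.move_record <- function(x, ...) {
  cat(sprintf("<move %s> %s\n", x$kind,
              paste(names(x$actors), unlist(lapply(x$actors, paste,
                                                   collapse = "+")),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Move a gene to another operon
#'
#' The gene leaves its current operon and is appended at the end of the
#' destination's cistron list (downstream, in transcription order, of the
#' ORFs that did not move; on reverse-strand operons that position is
#' upstream in genomic coordinates). Its transcription equation thereby
#' acquires the destination operon's effective regulatory function. Both
#' the source and destination primary promoters must be non-constitutive:
#' constitutively driven genes are excluded from the design. A source
#' operon left empty is deleted.
#'
#' @param g A [gtrn()] object.
#' @param gene_id Gene to move.
#' @param dest_operon Destination operon id.
#' @return `list(gtrn = <edited genome>, record = <move_record>)`.
#' @export
move_gene <- function(g, gene_id, dest_operon) {
  if (!gene_id %in% names(g$genes)) stop("unknown gene '", gene_id, "'")
  src_id <- operon_of(g, gene_id)
  if (identical(src_id, dest_operon))
    stop("destination operon equals source operon for gene '", gene_id, "'")
  dest <- g$operons[[dest_operon]]
  if (is.null(dest)) stop("unknown destination operon '", dest_operon, "'")
  src <- g$operons[[src_id]]
  if (g$promoters[[src$primary_promoter]]$is_constitutive)
    stop("move rejected: source operon '", src_id,
         "' has a constitutive primary promoter")
  if (g$promoters[[dest$primary_promoter]]$is_constitutive)
    stop("move rejected: destination operon '", dest_operon,
         "' has a constitutive primary promoter")
  src_index <- match(gene_id, src$genes)
  src_deleted <- length(src$genes) == 1L
  record <- new_move_record(
    kind = "move_gene",
    actors = list(gene = gene_id, from = src_id, to = dest_operon),
    inverse = list(gene = gene_id, src_id = src_id, src_index = src_index,
                   dest_id = dest_operon,
                   src_state = if (src_deleted) src else NULL))
  dest$genes <- c(dest$genes, gene_id)
  g$operons[[dest_operon]] <- dest
  if (src_deleted) {
    g$operons[[src_id]] <- NULL
  } else {
    src$genes <- src$genes[-src_index]
    g$operons[[src_id]] <- src
  }
  list(gtrn = g, record = record)
}

#' Add a tandem promoter to an operon
#'
#' Appends a promoter from the tandem-candidate library to the operon's
#' tandem list (at most three), adding its regulatory term to the effective
#' regulation of every member gene.
#'
#' @param g A [gtrn()] object.
#' @param operon_id Operon to extend.
#' @param promoter_id Promoter to append; must be a tandem candidate.
#' @return `list(gtrn, record)` as in [move_gene()].
#' @export
add_tandem <- function(g, operon_id, promoter_id) {
  op <- g$operons[[operon_id]]
  if (is.null(op)) stop("unknown operon '", operon_id, "'")
  if (!promoter_id %in% g$tandem_candidates)
    stop("move rejected: promoter '", promoter_id,
         "' is not a tandem candidate")
  if (length(op$tandem_promoters) >= 3L)
    stop("move rejected: operon '", operon_id,
         "' already carries 3 tandem promoters")
  if (identical(promoter_id, op$primary_promoter))
    stop("move rejected: promoter '", promoter_id,
         "' is the primary promoter of operon '", operon_id, "'")
  op$tandem_promoters <- c(op$tandem_promoters, promoter_id)
  g$operons[[operon_id]] <- op
  record <- new_move_record(
    kind = "add_tandem",
    actors = list(operon = operon_id, promoter = promoter_id),
    inverse = list(operon = operon_id, index = length(op$tandem_promoters)))
  list(gtrn = g, record = record)
}

#' Remove a tandem promoter from an operon
#'
#' Deletes one occurrence of the promoter from the tandem list, removing
#' its term from the effective regulation. The primary promoter can never
#' be removed.
#'
#' @inheritParams add_tandem
#' @param promoter_id Tandem promoter to remove.
#' @return `list(gtrn, record)`.
#' @export
remove_tandem <- function(g, operon_id, promoter_id) {
  op <- g$operons[[operon_id]]
  if (is.null(op)) stop("unknown operon '", operon_id, "'")
  if (identical(promoter_id, op$primary_promoter))
    stop("the primary promoter of operon '", operon_id,
         "' cannot be removed")
  idx <- match(promoter_id, op$tandem_promoters)
  if (is.na(idx))
    stop("move rejected: promoter '", promoter_id,
         "' is not in tandem on operon '", operon_id, "'")
  op$tandem_promoters <- op$tandem_promoters[-idx]
  g$operons[[operon_id]] <- op
  record <- new_move_record(
    kind = "remove_tandem",
    actors = list(operon = operon_id, promoter = promoter_id),
    inverse = list(operon = operon_id, promoter = promoter_id, index = idx))
  list(gtrn = g, record = record)
}

#' Replace a tandem promoter
#'
#' Substitutes one tandem promoter's regulatory term by another candidate's,
#' in place.
#'
#' @inheritParams add_tandem
#' @param old_promoter Tandem promoter to replace.
#' @param new_promoter Replacement; must be a tandem candidate.
#' @return `list(gtrn, record)`.
#' @export
replace_tandem <- function(g, operon_id, old_promoter, new_promoter) {
  op <- g$operons[[operon_id]]
  if (is.null(op)) stop("unknown operon '", operon_id, "'")
  if (!new_promoter %in% g$tandem_candidates)
    stop("move rejected: promoter '", new_promoter,
         "' is not a tandem candidate")
  idx <- match(old_promoter, op$tandem_promoters)
  if (is.na(idx))
    stop("move rejected: promoter '", old_promoter,
         "' is not in tandem on operon '", operon_id, "'")
  if (identical(new_promoter, op$primary_promoter))
    stop("move rejected: promoter '", new_promoter,
         "' is the primary promoter of operon '", operon_id, "'")
  op$tandem_promoters[idx] <- new_promoter
  g$operons[[operon_id]] <- op
  record <- new_move_record(
    kind = "replace_tandem",
    actors = list(operon = operon_id, old = old_promoter, new = new_promoter),
    inverse = list(operon = operon_id, index = idx, old = old_promoter,
                   new = new_promoter))
  list(gtrn = g, record = record)
}

#' Undo a move
#'
#' Applies the inverse of a recorded move, restoring a genome structurally
#' equal to the one the move was applied to.
#'
#' @param g The genome returned by the move.
#' @param record The `move_record` returned alongside it.
#' @return The restored [gtrn()].
#' @export
undo_move <- function(g, record) {
  stopifnot(inherits(record, "move_record"))
  inv <- record$inverse
  switch(record$kind,
    move_gene = {
      dest <- g$operons[[inv$dest_id]]
      if (is.null(dest) || dest$genes[length(dest$genes)] != inv$gene)
        stop("cannot undo: gene '", inv$gene,
             "' is not the last cistron of '", inv$dest_id, "'")
      dest$genes <- dest$genes[-length(dest$genes)]
      g$operons[[inv$dest_id]] <- dest
      if (!is.null(inv$src_state)) {
        g$operons[[inv$src_id]] <- inv$src_state
      } else {
        src <- g$operons[[inv$src_id]]
        src$genes <- append(src$genes, inv$gene, after = inv$src_index - 1L)
        g$operons[[inv$src_id]] <- src
      }
      g
    },
    add_tandem = {
      op <- g$operons[[inv$operon]]
      op$tandem_promoters <- op$tandem_promoters[-inv$index]
      g$operons[[inv$operon]] <- op
      g
    },
    remove_tandem = {
      op <- g$operons[[inv$operon]]
      op$tandem_promoters <- append(op$tandem_promoters, inv$promoter,
                                    after = inv$index - 1L)
      g$operons[[inv$operon]] <- op
      g
    },
    replace_tandem = {
      op <- g$operons[[inv$operon]]
      op$tandem_promoters[inv$index] <- inv$old
      g$operons[[inv$operon]] <- op
      g
    },
    stop("unknown move kind '", record$kind, "'"))
}
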