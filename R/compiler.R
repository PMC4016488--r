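# ---------------------------------------------------------------------------
# GTRN -> nucleotide sequence compiler.
#
# Each operon is laid down strand-aware as
#   [tandem promoter regions, each followed by an isolation spacer]
#   + primary promoter region + first-cistron RBS
#   + for each cistron: (assigned RBS if not first) + ORF with appended TAA
#   + terminator,
# with operons ordered along the chromosome by the original locus of their
# primary promoter. The inverse parser reconstructs the genome from the
# annotated output.
# ---------------------------------------------------------------------------

.DNA_ALPHABET <- c("A", "C", "G", "T")

#' Create a sequence part
#'
#' @param key Sequence-store key (or `NA`).
#' @param seq Nucleotide string over A/C/G/T.
#' @param role One of `"orf"`, `"rbs"`, `"promoter_region"`, `"terminator"`,
#'   `"isolation_spacer"`.
#' @return An object of class `sequence_part`.
#' @export
sequence_part <- function(key, seq, role) {
  role <- match.arg(role, c("orf", "rbs", "promoter_region", "terminator",
                            "isolation_spacer"))
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) < 1L)
    stop("sequence part must be a non-empty nucleotide string")
  if (grepl("[^ACGT]", seq))
    stop("sequence part contains non-ACGT characters")
  structure(list(key = key, seq = seq, role = role), class = "sequence_part")
}

#' Compiler configuration
#'
#' @param isolation_spacer Fixed neutral sequence inserted between stacked
#'   promoter regions (default a 20 bp constant).
#' @param rbs_policy RBS given to cistrons that are not in their native
#'   operon: `"first_orf_rbs"` (reuse the destination's first-cistron RBS,
#'   the default) or `"standard_rbs"`.
#' @param standard_rbs The standardized RBS sequence used under
#'   `"standard_rbs"`.
#' @return A list of class `compile_config`.
#' @export
compile_config <- function(isolation_spacer = "CGCTGATCGGCACGTAAGAG",
                           rbs_policy = c("first_orf_rbs", "standard_rbs"),
                           standard_rbs = "TTTAAGAAGGAGATATACAT") {
  rbs_policy <- match.arg(rbs_policy)
  if (grepl("[^ACGT]", isolation_spacer) || grepl("[^ACGT]", standard_rbs))
    stop("spacer and standard RBS must be ACGT strings")
  structure(list(isolation_spacer = isolation_spacer,
                 rbs_policy = rbs_policy, standard_rbs = standard_rbs),
            class = "compile_config")
}

#' Infer a ribosome binding site from genome coordinates
#'
#' Applies the three 5'UTR rules: (a) a known transcription start with a
#' 5'UTR of at least 15 bp yields the fragment from the +1 position to the
#' base before the start codon; (b) an unknown transcription start yields
#' the 60 bp immediately upstream of the start codon; (c) a known
#' transcription start with a 5'UTR shorter than 15 bp yields the 5'UTR
#' enlarged by an additional 60 bp upstream. Coordinates are 1-based
#' inclusive on the orientation of `genome_seq` (the caller resolves
#' strand orientation; leaderless 5'UTRs are treated like any other).
#'
#' @param tss Transcription start (+1) position, or `NA` if unknown.
#' @param start_codon Position of the first base of the start codon.
#' @param genome_seq Nucleotide string the positions index into.
#' @param strand `"+"` or `"-"` (recorded on the part).
#' @return A [sequence_part()] with role `"rbs"`.
#' @export
infer_rbs <- function(tss, start_codon, genome_seq, strand = "+") {
  L <- nchar(genome_seq)
  stopifnot(start_codon >= 1L, start_codon <= L)
  if (is.na(tss)) {
    from <- start_codon - 60L
    if (from < 1L)
      stop("start codon within 60 bp of the contig edge and the ",
           "transcription start is unknown")
    seq <- substr(genome_seq, from, start_codon - 1L)
  } else {
    if (tss >= start_codon) stop("transcription start must precede the start codon")
    utr_len <- start_codon - tss
    if (utr_len >= 15L) {
      seq <- substr(genome_seq, tss, start_codon - 1L)
    } else {
      from <- tss - 60L
      if (from < 1L)
        stop("cannot enlarge a short 5'UTR: fewer than 60 bp upstream of ",
             "the transcription start")
      seq <- substr(genome_seq, from, start_codon - 1L)
    }
  }
  part <- sequence_part(NA_character_, seq, "rbs")
  part$strand <- strand
  part
}

#' Prepare an ORF for rearrangement
#'
#' Systematically appends a TAA stop codon to the ORF (even when it already
#' ends in a stop), turning it into a standalone rearrangeable module.
#'
#' @param orf_seq ORF nucleotide string.
#' @return A [sequence_part()] with role `"orf"` whose sequence is
#'   `orf_seq` plus `"TAA"`.
#' @export
prepare_orf <- function(orf_seq) {
  if (!is.character(orf_seq) || length(orf_seq) != 1L || nchar(orf_seq) == 0L)
    stop("ORF sequence must be a non-empty string")
  if (grepl("[^ACGT]", orf_seq))
    stop("ORF contains non-ACGT characters")
  if (nchar(orf_seq) %% 3L != 0L)
    warning("ORF length is not divisible by 3")
  sequence_part(NA_character_, paste0(orf_seq, "TAA"), "orf")
}

#' Separate two opposite-strand operons sharing sequence
#'
#' When an ORF of one operon overlaps a small portion of the promoter
#' region of an operon on the other strand, both operons receive an
#' independent copy of the shared bases so each becomes a standalone
#' rearrangeable module. The total unique sequence is preserved and the
#' duplication is reported.
#'
#' @param operon_a,operon_b Lists with fields `id`, `strand`, `seq` (the
#'   operon's region including the shared bases) and `orf_seqs` (character
#'   vector of its ORF sequences).
#' @param shared_region The overlapping bases, written on `operon_a`'s
#'   strand.
#' @return `list(parts_a, parts_b)` of [sequence_part()]s (each operon's
#'   self-contained region), with attribute `duplicated_bp`.
#' @export
resolve_overlap <- function(operon_a, operon_b, shared_region) {
  if (identical(operon_a$strand, operon_b$strand))
    stop("overlap resolution applies to operons on opposite strands only")
  if (nchar(shared_region) == 0L) {
    out <- list(parts_a = sequence_part(operon_a$id, operon_a$seq, "orf"),
                parts_b = sequence_part(operon_b$id, operon_b$seq, "orf"))
    attr(out, "duplicated_bp") <- 0L
    return(out)
  }
  shared_rc <- revcomp(shared_region)
  if (!grepl(shared_region, operon_a$seq, fixed = TRUE))
    stop("shared region not found in operon '", operon_a$id, "'")
  if (!grepl(shared_rc, operon_b$seq, fixed = TRUE) &&
      !grepl(shared_region, operon_b$seq, fixed = TRUE))
    stop("shared region not found in operon '", operon_b$id, "'")
  all_orfs <- c(operon_a$orf_seqs, operon_b$orf_seqs)
  for (orf in all_orfs) {
    if (nchar(orf) <= nchar(shared_region) &&
        (grepl(orf, shared_region, fixed = TRUE) ||
         grepl(revcomp(orf), shared_region, fixed = TRUE)))
      stop("shared region spans an entire ORF; only small portions of ",
           "promoter regions may be duplicated")
  }
  out <- list(parts_a = sequence_part(operon_a$id, operon_a$seq, "orf"),
              parts_b = sequence_part(operon_b$id, operon_b$seq, "orf"))
  attr(out, "duplicated_bp") <- nchar(shared_region)
  out
}

#' RBS assigned to a gene arriving in an operon
#'
#' Every ORF arriving at the same destination operon receives the same RBS:
#' either the RBS inferred for the destination's first cistron
#' (`"first_orf_rbs"`) or a configured standardized sequence
#' (`"standard_rbs"`). A gene sitting in its native operon keeps its native
#' RBS and this function is not consulted for it.
#'
#' @param g A [gtrn()] object.
#' @param dest_operon Destination operon id.
#' @param incoming_gene Id of the arriving gene (recorded on the part).
#' @param policy `"first_orf_rbs"` or `"standard_rbs"`.
#' @param config A [compile_config()] providing the standardized sequence.
#' @return A [sequence_part()] with role `"rbs"`.
#' @export
assign_rbs <- function(g, dest_operon, incoming_gene,
                       policy = c("first_orf_rbs", "standard_rbs"),
                       config = compile_config()) {
  policy <- match.arg(policy)
  op <- g$operons[[dest_operon]]
  if (is.null(op)) stop("unknown operon '", dest_operon, "'")
  if (policy == "standard_rbs") {
    part <- sequence_part(NA_character_, config$standard_rbs, "rbs")
  } else {
    first_gene <- g$genes[[op$genes[[1L]]]]
    key <- first_gene$native_rbs_ref
    seq <- g$sequence_store[[key]]
    if (is.null(seq) || is.na(seq))
      stop("operon '", dest_operon, "': first-cistron RBS '", key,
           "' missing from the sequence store")
    part <- sequence_part(key, seq, "rbs")
  }
  part$gene <- incoming_gene
  part
}

#' Reverse complement
#'
#' @param seq Nucleotide string.
#' @return Its reverse complement.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.store_get <- function(g, key, what) {
  if (is.na(key) || !key %in% names(g$sequence_store))
    stop("missing sequence part '", key, "' (", what, ")")
  g$sequence_store[[key]]
}

#' Compile a GTRN into an annotated genome
#'
#' Deterministically assembles the full nucleotide sequence and its feature
#' annotation (promoter, RBS, CDS, terminator). Operons are placed along
#' the chromosome in the order of their primary promoter's original locus;
#' reverse-strand operons are assembled on the coding strand and
#' reverse-complemented into place. Cistrons outside their native operon
#' receive the destination RBS per the configured policy.
#'
#' @param g A [gtrn()] object.
#' @param config A [compile_config()].
#' @param name Locus name written to the output record.
#' @return A list of class `compiled_genome` with `sequence` (string),
#'   `features` (list of feature records: type, start, end, strand,
#'   qualifiers), `meta` (promoter parameters, gene metadata,
#'   tandem candidates, auxiliary sequences needed for exact round trips),
#'   and `name`.
#' @export
compile_gtrn <- function(g, config = compile_config(), name = "refactored") {
  validate_gtrn(g)
  ord <- order(vapply(g$operons, function(op) {
    if (is.na(op$locus)) Inf else op$locus
  }, 0), names(g$operons))
  op_ids <- names(g$operons)[ord]

  seq_chunks <- character()
  features <- list()
  pos <- 0L
  add_feature <- function(flist, type, start, end, strand, qualifiers) {
    flist[[length(flist) + 1L]] <- list(type = type, start = start,
                                        end = end, strand = strand,
                                        qualifiers = qualifiers)
    flist
  }

  for (oid in op_ids) {
    op <- g$operons[[oid]]
    # assemble the block 5'->3' on the coding strand, tracking local spans
    local <- list(); block <- character(); at <- 0L
    push <- function(seq, type, qualifiers) {
      local[[length(local) + 1L]] <<- list(type = type, start = at + 1L,
                                           end = at + nchar(seq),
                                           qualifiers = qualifiers)
      block[[length(block) + 1L]] <<- seq
      at <<- at + nchar(seq)
    }
    for (tp in op$tandem_promoters) {
      pseq <- .store_get(g, g$promoters[[tp]]$region_ref,
                         paste0("tandem promoter region of ", oid))
      push(pseq, "promoter",
           list(promoter_id = tp, operon_id = oid, role = "tandem",
                region_ref = g$promoters[[tp]]$region_ref))
      push(config$isolation_spacer, "spacer", list(operon_id = oid))
    }
    pp <- op$primary_promoter
    pseq <- .store_get(g, g$promoters[[pp]]$region_ref,
                       paste0("primary promoter region of ", oid))
    push(pseq, "promoter",
         list(promoter_id = pp, operon_id = oid, role = "primary",
              region_ref = g$promoters[[pp]]$region_ref))
    for (i in seq_along(op$genes)) {
      gid <- op$genes[[i]]
      gn <- g$genes[[gid]]
      native_here <- !is.na(gn$home_operon) && identical(gn$home_operon, oid)
      if (i == 1L || native_here) {
        rseq <- .store_get(g, gn$native_rbs_ref,
                           paste0("native RBS of gene ", gid))
        push(rseq, "RBS",
             list(gene = gid, operon_id = oid, source = "native",
                  seq_ref = gn$native_rbs_ref))
      } else {
        part <- assign_rbs(g, oid, gid, config$rbs_policy, config)
        push(part$seq, "RBS",
             list(gene = gid, operon_id = oid, source = "assigned"))
      }
      orf <- .store_get(g, gn$orf_seq_ref, paste0("ORF of gene ", gid))
      prepared <- prepare_orf(orf)
      push(prepared$seq, "CDS",
           list(gene = gid, operon_id = oid, seq_ref = gn$orf_seq_ref))
    }
    tseq <- .store_get(g, op$terminator_ref,
                       paste0("terminator of operon ", oid))
    push(tseq, "terminator",
         list(operon_id = oid, seq_ref = op$terminator_ref))

    block_seq <- paste(block, collapse = "")
    blen <- nchar(block_seq)
    if (op$strand == "-") {
      block_seq <- revcomp(block_seq)
      for (f in local) {
        features <- add_feature(features, f$type,
                                pos + (blen - f$end + 1L),
                                pos + (blen - f$start + 1L),
                                "-", f$qualifiers)
      }
    } else {
      for (f in local) {
        features <- add_feature(features, f$type, pos + f$start,
                                pos + f$end, "+", f$qualifiers)
      }
    }
    seq_chunks[[length(seq_chunks) + 1L]] <- block_seq
    pos <- pos + blen
  }

  genome_seq <- paste(seq_chunks, collapse = "")

  # metadata needed for an exact inverse: promoter parameters, gene model
  # metadata, the tandem-candidate set, and any referenced store sequence
  # the annotated sequence itself does not realize (e.g. the native RBS of
  # a relocated gene, or the region of an unused candidate promoter).
  realized <- unique(unlist(lapply(features, function(f) f$qualifiers$seq_ref)))
  realized <- c(realized,
                unlist(lapply(features, function(f) f$qualifiers$region_ref)))
  realized <- realized[!is.na(realized)]
  refs <- character()
  for (gn in g$genes) refs <- c(refs, gn$orf_seq_ref, gn$native_rbs_ref)
  for (op in g$operons) refs <- c(refs, op$terminator_ref)
  for (p in g$promoters) refs <- c(refs, p$region_ref)
  refs <- unique(refs[!is.na(refs)])
  aux_keys <- setdiff(intersect(refs, names(g$sequence_store)), realized)
  # canonical (sorted) metadata order: structurally equal genomes compile
  # to byte-identical records regardless of internal list order
  meta <- list(
    format = "gtrnr-genome-1",
    tandem_candidates = as.list(sort(g$tandem_candidates)),
    promoters = lapply(g$promoters[sort(names(g$promoters))], function(p) {
      list(alpha = p$alpha, beta = as.list(p$beta),
           gamma = as.list(p$gamma), region_ref = p$region_ref)
    }),
    genes = lapply(g$genes[sort(names(g$genes))], function(gn) {
      list(delta = gn$delta, categories = as.list(gn$categories),
           functions = as.list(gn$functions), strand = gn$strand,
           orf_seq_ref = gn$orf_seq_ref,
           native_rbs_ref = gn$native_rbs_ref,
           home_operon = gn$home_operon)
    }),
    aux_store = as.list(g$sequence_store[sort(aux_keys)]))

  structure(list(name = name, sequence = genome_seq, features = features,
                 meta = meta),
            class = "compiled_genome")
}

#' @export
print.compiled_genome <- function(x, ...) {
  cat(sprintf("<compiled_genome> '%s': %d bp, %d features\n",
              x$name, nchar(x$sequence), length(x$features)))
  invisible(x)
}

#' Parse an annotated genome back to a GTRN
#'
#' Inverse of [compile_gtrn()]: reconstructs operon structure, gene order,
#' promoter assignments and parameters, and every referenced sequence part
#' from a compiled record (or a GenBank file written by
#' [write_genbank()]). `compile_gtrn()` of the result is byte-identical to
#' the input.
#'
#' @param x A `compiled_genome` or a path to a GenBank file.
#' @return A [gtrn()] object.
#' @export
parse_genome <- function(x) {
  if (is.character(x)) x <- read_genbank(x)
  stopifnot(inherits(x, "compiled_genome"))
  meta <- x$meta
  if (is.null(meta) || !identical(meta$format, "gtrnr-genome-1"))
    stop("record lacks the compiled-genome metadata block")
  seq_len_total <- nchar(x$sequence)

  feat_seq <- function(f) {
    if (f$start < 1L || f$end > seq_len_total || f$start > f$end)
      stop("feature with out-of-range coordinates [", f$start, ", ", f$end,
           "]")
    s <- substr(x$sequence, f$start, f$end)
    if (f$strand == "-") revcomp(s) else s
  }

  store <- character()
  promoters <- list()
  for (pid in names(meta$promoters)) {
    p <- meta$promoters[[pid]]
    promoters[[pid]] <- regulatory_function(
      alpha = p$alpha, beta = unlist(p$beta), gamma = unlist(p$gamma),
      region_ref = p$region_ref)
  }

  # group features by operon in file order
  op_order <- character()
  by_op <- list()
  for (f in x$features) {
    oid <- f$qualifiers$operon_id
    if (is.null(oid)) stop("feature without operon_id at [", f$start, "]")
    if (!oid %in% op_order) op_order <- c(op_order, oid)
    by_op[[oid]] <- c(by_op[[oid]], list(f))
  }

  genes <- list(); operons <- list()
  locus <- 0L
  for (oid in op_order) {
    fs <- by_op[[oid]]
    strand <- fs[[1L]]$strand
    # order features 5'->3' in transcription order
    starts <- vapply(fs, `[[`, 0L, "start")
    fs <- fs[order(if (strand == "-") -starts else starts)]
    tandems <- character(); primary <- NULL; gene_order <- character()
    terminator_ref <- NA_character_
    for (f in fs) {
      q <- f$qualifiers
      if (f$type == "promoter") {
        pid <- q$promoter_id
        if (!pid %in% names(promoters))
          stop("promoter '", pid, "' missing from the metadata block")
        store[[q$region_ref]] <- feat_seq(f)
        if (identical(q$role, "primary")) primary <- pid
        else tandems <- c(tandems, pid)
      } else if (f$type == "CDS") {
        gid <- q$gene
        cds <- feat_seq(f)
        if (nchar(cds) < 6L || substr(cds, nchar(cds) - 2L, nchar(cds)) != "TAA")
          stop("CDS of gene '", gid, "' lacks the appended TAA stop codon")
        gm <- meta$genes[[gid]]
        if (is.null(gm)) stop("gene '", gid, "' missing from metadata block")
        store[[q$seq_ref]] <- substr(cds, 1L, nchar(cds) - 3L)
        gene_order <- c(gene_order, gid)
        genes[[gid]] <- gene(
          id = gid, delta = gm$delta,
          categories = unlist(c(gm$categories, list(character()))),
          functions = unlist(c(gm$functions, list(character()))),
          orf_seq_ref = gm$orf_seq_ref, native_rbs_ref = gm$native_rbs_ref,
          strand = strand,
          home_operon = if (is.null(gm$home_operon)) NA_character_
                        else gm$home_operon)
      } else if (f$type == "RBS") {
        if (identical(q$source, "native"))
          store[[q$seq_ref]] <- feat_seq(f)
      } else if (f$type == "terminator") {
        terminator_ref <- q$seq_ref
        store[[q$seq_ref]] <- feat_seq(f)
      }
    }
    if (is.null(primary))
      stop("operon '", oid, "' has no primary promoter feature")
    if (!length(gene_order))
      stop("operon '", oid, "' has no CDS features")
    locus <- locus + 1L
    operons[[oid]] <- operon(
      id = oid, genes = gene_order, primary_promoter = primary,
      tandem_promoters = tandems, terminator_ref = terminator_ref,
      strand = strand, locus = locus)
  }

  aux <- unlist(meta$aux_store)
  if (length(aux)) store[names(aux)] <- aux
  # gene strand metadata: genes keep their own strand; the CDS strand above
  # is the operon's. Restore per-gene strand when recorded.
  for (gid in names(genes)) {
    gm <- meta$genes[[gid]]
    if (!is.null(gm$strand)) genes[[gid]]$strand <- gm$strand
  }
  gtrn(genes, operons, promoters,
       tandem_candidates = unlist(c(meta$tandem_candidates,
                                    list(character()))),
       sequence_store = store)
}
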